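# Exposure codings: the 7-level smoking phenotype, the 3-level
# smoking-change variable, and beta/M-value conversion utilities.

#' Derive the seven-level smoking phenotype
#'
#' Combines smoking status with lifetime pack-years into a single ordinal
#' exposure: 0 never; 1 former <=10.0 pack-years; 2 former 10.1-20.0;
#' 3 former >=20.1; 4 current <=10.0; 5 current 10.1-20.0; 6 current >=20.1.
#' The printed band edges leave values in (10.0, 10.1) and (20.0, 20.1)
#' unassigned; this implementation uses the half-open convention
#' \code{<=10.0} / \code{(10.0, 20.0]} / \code{>20.0} so every nonnegative
#' real pack-years value maps to exactly one band.
#'
#' @param status character vector with values "never", "former", "current".
#' @param pack_years nonnegative numeric vector of lifetime pack-years;
#'   may be \code{NA} for never smokers.
#' @return integer vector of levels 0-6; \code{NA} where an ever-smoker has
#'   missing pack-years (such records are excluded downstream).
#' @export
#' @examples
#' derive_smoking_phenotype(c("never", "former", "current"), c(0, 15, 25))
derive_smoking_phenotype <- function(status, pack_years) {
  status <- match.arg_vec(status)
  if (length(pack_years) != length(status)) {
    stop("`status` and `pack_years` must have equal length", call. = FALSE)
  }
  if (any(pack_years < 0, na.rm = TRUE)) {
    stop("`pack_years` must be nonnegative", call. = FALSE)
  }
  band <- function(py) ifelse(py <= 10, 0L, ifelse(py <= 20, 1L, 2L))
  out <- rep(NA_integer_, length(status))
  out[status == "never"] <- 0L
  ever <- status != "never"
  known <- ever & !is.na(pack_years)
  base <- ifelse(status[known] == "former", 1L, 4L)
  out[known] <- base + band(pack_years[known])
  out
}

match.arg_vec <- function(status) {
  status <- as.character(status)
  bad <- !status %in% c("never", "former", "current")
  if (any(bad)) {
    stop("unknown smoking status: ",
         paste(unique(status[bad]), collapse = ", "), call. = FALSE)
  }
  status
}

#' Classify change in smoking status between two waves
#'
#' Maps each (wave-1, wave-2) status pair to an ordinal change code:
#' 0 decrease (current to former), 1 no change (never to never, former to
#' former), 2 increase (never to former, never to current, former to
#' current, and current to current -- continuing smokers keep accumulating
#' exposure, so they count as an increase).  Transitions back to "never"
#' are impossible by definition and raise an error.
#'
#' @param status_w1,status_w2 character vectors of smoking status at the
#'   two waves ("never", "former", "current").
#' @return integer vector with values 0 (decrease), 1 (no change),
#'   2 (increase).
#' @export
#' @examples
#' classify_smoking_change("current", "former")   # 0: decrease
#' classify_smoking_change("current", "current")  # 2: increase
classify_smoking_change <- function(status_w1, status_w2) {
  s1 <- match.arg_vec(status_w1)
  s2 <- match.arg_vec(status_w2)
  if (length(s1) != length(s2)) {
    stop("wave status vectors must have equal length", call. = FALSE)
  }
  illegal <- s2 == "never" & s1 != "never"
  if (any(illegal)) {
    stop(sprintf("impossible transition(s) to 'never' at position(s) %s",
                 paste(which(illegal), collapse = ", ")), call. = FALSE)
  }
  out <- rep(NA_integer_, length(s1))
  out[s1 == "current" & s2 == "former"] <- 0L
  out[s1 == s2 & s1 %in% c("never", "former")] <- 1L
  inc <- (s1 == "never" & s2 %in% c("former", "current")) |
    (s1 == "former" & s2 == "current") |
    (s1 == "current" & s2 == "current")
  out[inc] <- 2L
  out
}

#' Tabulate smoking-change categories over a roster of status pairs
#'
#' @param status_w1,status_w2 character vectors of per-individual statuses.
#' @return named integer vector with counts for \code{decrease},
#'   \code{no_change} and \code{increase}; the counts sum to the roster
#'   size.
#' @export
tabulate_changes <- function(status_w1, status_w2) {
  ch <- classify_smoking_change(status_w1, status_w2)
  c(decrease = sum(ch == 0L), no_change = sum(ch == 1L),
    increase = sum(ch == 2L))
}

#' Beta-value / M-value conversion
#'
#' \code{beta_to_m} computes \code{log2(beta / (1 - beta))};
#' \code{m_to_beta} is its exact inverse \code{2^m / (2^m + 1)}.  The pair
#' is a strictly monotone bijection between (0, 1) and the real line.
#'
#' @param beta numeric vector of methylation proportions, strictly in
#'   (0, 1) unless \code{clamp = TRUE}.
#' @param m numeric vector of M-values.
#' @param clamp if \code{TRUE}, beta-values outside (0, 1) are clamped to
#'   \code{[eps, 1 - eps]} instead of raising an error.
#' @param eps clamping margin (default \code{1e-6}).
#' @return numeric vector of M-values (resp. beta-values).
#' @export
#' @examples
#' beta_to_m(0.8)          # 2: log2(4)
#' m_to_beta(beta_to_m(0.31))
beta_to_m <- function(beta, clamp = FALSE, eps = 1e-6) {
  if (clamp) {
    beta <- pmin(pmax(beta, eps), 1 - eps)
  } else if (any(beta <= 0 | beta >= 1, na.rm = TRUE)) {
    stop("beta-values must lie strictly in (0, 1); set clamp = TRUE to clamp",
         call. = FALSE)
  }
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  # 1 / (1 + 2^-m) is stable for large |m| in both directions
  1 / (1 + 2^(-m))
}

#' Odds ratio per 1\% methylation increase
#'
#' Converts a logistic coefficient expressed per full beta-value change
#' (0 to 1) into the odds ratio for a 1 percentage-point increase in
#' methylation: \code{exp(coef / 100)}.
#'
#' @param coef numeric vector of log-odds coefficients per beta 0 -> 1.
#' @param digits rounding applied for reporting (default 2, as in result
#'   tables); use \code{NULL} to skip rounding.
#' @return numeric vector of odds ratios.
#' @export
#' @examples
#' or_per_percent(-11.854)  # 0.89
or_per_percent <- function(coef, digits = 2) {
  stopifnot(is.numeric(coef))
  or <- exp(coef / 100)
  if (!is.null(digits)) or <- round(or, digits)
  or
}
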