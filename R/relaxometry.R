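#' Power-law T1 dispersion model
#'
#' Longitudinal relaxation of tissues lengthens with field strength; the
#' package models this as T1(B0) = A * B0^B with A the T1 at 1 T (ms) and B
#' a dimensionless dispersion exponent. T2 is treated as field-constant
#' throughout (user-supplied tables may override any value).
#'
#' @param a_ms T1 at 1 T in ms, > 0.
#' @param b dimensionless exponent.
#' @return object of class `t1_dispersion_model`.
#' @export
t1_dispersion_model <- function(a_ms, b) {
  if (!is.finite(a_ms) || a_ms <= 0) stop("A must be > 0")
  structure(list(a_ms = a_ms, b = b), class = "t1_dispersion_model")
}

#' Evaluate a T1 dispersion model at a field strength
#'
#' @param model a [t1_dispersion_model()].
#' @param b0 Tesla, > 0.
#' @return T1 in ms.
#' @export
t1_at_field <- function(model, b0) {
  stopifnot(inherits(model, "t1_dispersion_model"))
  if (any(b0 <= 0)) stop("b0 must be > 0")
  model$a_ms * b0^model$b
}

#' Fit the power-law T1 dispersion model to (B0, T1) samples
#'
#' Ordinary least squares in log-log space: log T1 = log A + B log B0. With
#' noiseless power-law samples the fit recovers (A, B) exactly; with
#' multiplicative scatter (the typical heterogeneity of literature values)
#' log-space OLS is the maximum-likelihood estimator.
#'
#' @param b0 Tesla values (>= 2 distinct, all > 0).
#' @param t1_ms matching T1 values in ms (> 0).
#' @return a [t1_dispersion_model()].
#' @export
fit_t1_dispersion <- function(b0, t1_ms) {
  if (length(b0) != length(t1_ms)) stop("b0 and t1_ms lengths differ")
  if (any(b0 <= 0) || any(t1_ms <= 0)) stop("samples must be positive")
  if (length(unique(b0)) < 2)
    stop("need samples at >= 2 distinct field strengths")
  fit <- stats::lm(log(t1_ms) ~ log(b0))
  t1_dispersion_model(exp(unname(stats::coef(fit)[1])),
                      unname(stats::coef(fit)[2]))
}

#' Read (B0, T1) literature points from CSV
#'
#' Expects columns `b0_t` and `t1_ms`, one row per literature value.
#'
#' @param path CSV file path.
#' @return data.frame with columns `b0_t`, `t1_ms`.
#' @export
read_t1_samples_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("b0_t", "t1_ms") %in% names(df)))
    stop("CSV must have columns 'b0_t' and 't1_ms'")
  df[, c("b0_t", "t1_ms")]
}
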