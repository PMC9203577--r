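#' Pearson correlation with explicit degenerate-input handling
#'
#' Thin wrapper around [stats::cor()] that validates its inputs: series must
#' have equal length of at least 3, and a zero-variance input is signalled as
#' an error (undefined correlation) rather than silently returning `NA`.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3L) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: zero-variance input")
  stats::cor(a, b)
}

#' Partial correlation controlling for a third series
#'
#' Correlation between the OLS residuals of `a ~ control` and `b ~ control`
#' (intercept included). Used to isolate the water-storage signal in the
#' global NEE series from the co-varying temperature signal and vice versa.
#'
#' @param a,b,control numeric vectors of equal length >= 3.
#' @return Partial correlation coefficient.
#' @export
partial_r <- function(a, b, control) {
  n <- length(a)
  if (length(b) != n || length(control) != n) stop("series lengths differ")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(control) == 0) stop("control series has zero variance")
  resid_on <- function(y) {
    x <- cbind(1, control)
    y - x %*% qr.solve(x, y)
  }
  ra <- resid_on(a)
  rb <- resid_on(b)
  tol <- 1e-12 * max(stats::sd(a), stats::sd(b), 1)
  if (stats::sd(ra) <= tol || stats::sd(rb) <= tol)
    stop("partial correlation undefined: control is collinear with an input")
  as.numeric(stats::cor(ra, rb))
}
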