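# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# FWHM of a Gaussian with standard deviation sigma, and back.
GAUSS_FWHM <- 2 * sqrt(2 * log(2))  # 2.354820

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_num <- function(x, name, len = NULL, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || anyNA(x))
    stopf("`%s` must be numeric without NA", name)
  if (!is.null(len) && length(x) != len)
    stopf("`%s` must have length %d", name, len)
  if (positive && any(x <= 0)) stopf("`%s` must be > 0", name)
  if (nonneg && any(x < 0)) stopf("`%s` must be >= 0", name)
  invisible(x)
}

is_strictly_monotone <- function(x) {
  d <- diff(x)
  all(d > 0) || all(d < 0)
}

# Linear-interpolated half-maximum crossing width of y(x) around its peak.
# Errors when the peak sits at the grid edge (crossings not bracketed).
half_max_width <- function(x, y) {
  y <- as.numeric(y)
  i <- which.max(y)
  if (i == 1L || i == length(y))
    stopf("peak lies at the grid edge; enlarge the grid")
  half <- y[i] / 2
  left <- which(y[seq_len(i)] < half)
  right <- which(y[seq(i, length(y))] < half)
  if (length(left) == 0L || length(right) == 0L)
    stopf("half-maximum level is not crossed inside the grid")
  il <- max(left)                     # last point below half on the left
  ir <- i - 1L + min(right)           # first point below half on the right
  interp <- function(ya, xa) {
    o <- order(ya)
    stats::approx(ya[o], xa[o], xout = half)$y
  }
  xl <- interp(y[c(il, il + 1L)], x[c(il, il + 1L)])
  xr <- interp(y[c(ir - 1L, ir)], x[c(ir - 1L, ir)])
  xr - xl
}
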