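# round half away from zero, matching how breeding tables print dyadic
# fractions (0.625 -> 0.63); base round() would go half-to-even
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mb <- function(msg, class) {
  abort(msg, class = c(class, "multibreed_error"))
}

# symmetric 2x2 inverse with a PD check
inv2 <- function(m) {
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (!is.finite(det) || det <= 0 || m[1, 1] <= 0) {
    stop_mb("2x2 covariance matrix is not positive definite", "mb_not_pd")
  }
  matrix(c(m[2, 2], -m[1, 2], -m[2, 1], m[1, 1]), 2, 2) / det
}

is_pd2 <- function(m) {
  is.finite(m[1, 1]) && m[1, 1] > 0 &&
    (m[1, 1] * m[2, 2] - m[1, 2]^2) > 0
}
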