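#' Genetic (co)variance component set
#'
#' Container for the eleven scalar (co)variance components of the multibreed
#' maternal model: a 2-by-2 direct/maternal genetic covariance matrix `G0X`
#' per source of variability (breed A, breed B, segregation), the maternal
#' permanent-environment variance and the residual variance.
#'
#' @param G0A,G0B,G0S Symmetric positive-definite 2-by-2 matrices, ordered
#'   (direct, maternal).
#' @param sigma2_pe,sigma2_e Positive scalars.
#' @return An object of class `mb_varcomp`.
#' @export
varcomp <- function(G0A, G0B, G0S, sigma2_pe, sigma2_e) {
  for (nm in c("G0A", "G0B", "G0S")) {
    m <- get(nm)
    if (!is.matrix(m) || !all(dim(m) == 2) || abs(m[1, 2] - m[2, 1]) > 1e-10) {
      stop_mb(paste0(nm, " must be a symmetric 2x2 matrix"), "mb_input_error")
    }
    if (!is_pd2(m)) {
      stop_mb(paste0(nm, " is not positive definite"), "mb_not_pd")
    }
  }
  if (sigma2_pe <= 0 || sigma2_e <= 0) {
    stop_mb("sigma2_pe and sigma2_e must be positive", "mb_input_error")
  }
  out <- list(G0A = G0A, G0B = G0B, G0S = G0S,
              sigma2_pe = sigma2_pe, sigma2_e = sigma2_e)
  class(out) <- "mb_varcomp"
  out
}

#' Coerce eleven named components to a variance-component set
#'
#' @param x Named numeric vector (or single-row data frame) with elements
#'   `sigma2_Ao`, `sigma_AoAm`, `sigma2_Am`, `sigma2_Bo`, `sigma_BoBm`,
#'   `sigma2_Bm`, `sigma2_So`, `sigma_SoSm`, `sigma2_Sm`, `sigma2_pe`,
#'   `sigma2_e`.
#' @return An `mb_varcomp`.
#' @export
as_varcomp <- function(x) {
  if (inherits(x, "mb_varcomp")) return(x)
  if (is.data.frame(x)) x <- unlist(x[1, mb_components()])
  miss <- setdiff(mb_components(), names(x))
  if (length(miss) > 0) {
    stop_mb(paste0("missing components: ", paste(miss, collapse = ", ")),
            "mb_input_error")
  }
  g0 <- function(o, om, m) matrix(c(x[[o]], x[[om]], x[[om]], x[[m]]),
                                  2, 2)
  varcomp(G0A = g0("sigma2_Ao", "sigma_AoAm", "sigma2_Am"),
          G0B = g0("sigma2_Bo", "sigma_BoBm", "sigma2_Bm"),
          G0S = g0("sigma2_So", "sigma_SoSm", "sigma2_Sm"),
          sigma2_pe = x[["sigma2_pe"]], sigma2_e = x[["sigma2_e"]])
}

# named vector in canonical component order; a fully named numeric vector
# passes through unvalidated so that boundary cases (zero variances) can be
# inspected by the derived-parameter code, which applies its own checks
vc_vector <- function(vc) {
  if (is.numeric(vc) && all(mb_components() %in% names(vc))) {
    return(vc[mb_components()])
  }
  vc <- as_varcomp(vc)
  setNames(c(vc$G0A[1, 1], vc$G0A[1, 2], vc$G0A[2, 2],
             vc$G0B[1, 1], vc$G0B[1, 2], vc$G0B[2, 2],
             vc$G0S[1, 1], vc$G0S[1, 2], vc$G0S[2, 2],
             vc$sigma2_pe, vc$sigma2_e),
           mb_components())
}

#' @method tidy mb_varcomp
#' @export
tidy.mb_varcomp <- function(x, ...) {
  v <- vc_vector(x)
  tibble(component = names(v), value = unname(v))
}

#' @export
print.mb_varcomp <- function(x, ...) {
  cat("# Multibreed (co)variance components\n")
  print(tidy(x), n = 11)
  invisible(x)
}
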