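#' Prior specification for the hierarchical multibreed model
#'
#' Conjugate priors for the eleven (co)variance components: an inverse
#' Wishart per source (parameterized by a 2-by-2 prior scale matrix `G0X`
#' interpreted as the prior location, with degrees of belief `nu_X`, i.e.
#' density kernel `|G|^-(nu+3)/2 exp(-tr(nu G0X G^-1) / 2)`), and scaled
#' inverse chi-squared priors for the permanent-environment and residual
#' variances. Fixed effects get a vague normal prior with variance `k`.
#' Defaults are the prior values of the published Angus x Hereford analysis.
#'
#' @param G0A,G0B,G0S 2-by-2 positive-definite prior scale matrices,
#'   (direct, maternal) order.
#' @param nu_A,nu_B,nu_S,nu_pe,nu_e Degrees of belief (> 0; the Wishart
#'   draws need `nu_X > 1`).
#' @param s2_pe,s2_e Prior scale values for the scalar variances.
#' @param k Fixed-effect prior variance, at least `1e7`.
#' @return An object of class `mb_priors`.
#' @export
mb_priors <- function(G0A = matrix(c(85, -25, -25, 35), 2, 2), nu_A = 20,
                      G0B = matrix(c(76, -50, -50, 70), 2, 2), nu_B = 20,
                      G0S = matrix(c(10, 8, 8, 9), 2, 2), nu_S = 5,
                      s2_pe = 80, nu_pe = 100,
                      s2_e = 170, nu_e = 100,
                      k = 1e7) {
  for (nm in c("G0A", "G0B", "G0S")) {
    if (!is_pd2(get(nm))) {
      stop_mb(paste0("prior scale ", nm, " must be positive definite"),
              "mb_not_pd")
    }
  }
  if (any(c(nu_A, nu_B, nu_S, nu_pe, nu_e) <= 1)) {
    stop_mb("degrees of belief must exceed 1", "mb_input_error")
  }
  if (s2_pe <= 0 || s2_e <= 0) {
    stop_mb("scalar prior scales must be positive", "mb_input_error")
  }
  if (k < 1e7) {
    stop_mb("fixed-effect prior variance k must be at least 1e7",
            "mb_input_error")
  }
  structure(list(G0A = G0A, nu_A = nu_A, G0B = G0B, nu_B = nu_B,
                 G0S = G0S, nu_S = nu_S, s2_pe = s2_pe, nu_pe = nu_pe,
                 s2_e = s2_e, nu_e = nu_e, k = k),
            class = "mb_priors")
}

# variance-component set at the prior scales (chain starting values)
prior_varcomp <- function(priors) {
  varcomp(G0A = priors$G0A, G0B = priors$G0B, G0S = priors$G0S,
          sigma2_pe = priors$s2_pe, sigma2_e = priors$s2_e)
}

#' Chain configuration
#'
#' @param n_iter Total iterations (default 20000, a desk-scale chain).
#' @param burn_in Iterations discarded (default 2000); must be < `n_iter`.
#' @param thin Keep every `thin`-th post-burn-in draw (default 10).
#' @param seed Integer seed for R's RNG; recorded in the chain object and
#'   any file written from it.
#' @param keep_locations If `TRUE`, store thinned draws of all location
#'   parameters (memory scales with system size).
#' @return An object of class `mb_chain_control`.
#' @export
mb_chain_control <- function(n_iter = 20000, burn_in = 2000, thin = 10,
                             seed = NULL, keep_locations = FALSE) {
  if (burn_in >= n_iter) stop_mb("burn_in must be < n_iter", "mb_input_error")
  if (thin < 1) stop_mb("thin must be >= 1", "mb_input_error")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed,
                 keep_locations = isTRUE(keep_locations)),
            class = "mb_chain_control")
}

# pattern-preserving 0/1 indicator of a sparse matrix's nonzero slots
pattern_ones <- function(M) {
  Mg <- as(as(M, "generalMatrix"), "CsparseMatrix")
  Matrix::sparseMatrix(i = Mg@i + 1L,
                       j = rep.int(seq_len(ncol(Mg)), diff(Mg@p)),
                       x = 1, dims = dim(Mg))
}

# 1-based keys of the stored entries of a general CsparseMatrix
entry_keys <- function(M, m) {
  j <- rep.int(seq_len(ncol(M)), diff(M@p))
  (j - 1) * as.numeric(m) + (M@i + 1)
}

#' Gibbs sampler for the multibreed maternal model
#'
#' Runs the single-site, systematic-scan Gibbs sampler over all location
#' parameters and the eleven (co)variance components. The scan order is
#' fixed: fixed effects, then for each source (breed A, breed B,
#' segregation) the direct then the maternal breeding values, then the
#' maternal permanent-environment effects; each scalar is drawn from its
#' normal full conditional under the current mixed-model system, after
#' which the residual, permanent-environment and per-source 2-by-2 genetic
#' covariance components are drawn from their conjugate full conditionals
#' (scaled inverse chi-squared / inverse Wishart). Starting values are
#' zeros for locations and the prior scales for variances.
#'
#' @param records,ped,fixed,cross_effects See [build_design()].
#' @param priors An [mb_priors()] object.
#' @param control An [mb_chain_control()] object.
#' @return An object of class `mb_chain`: `samples` (tibble with
#'   `iteration` plus the eleven components), `location_means` (posterior
#'   means of all location parameters, long tibble), `locations` (thinned
#'   location draws if requested), `priors`, `control`, `seed`,
#'   `config_hash`, `n_records`.
#' @export
mb_gibbs <- function(records, ped, fixed, priors = mb_priors(),
                     control = mb_chain_control(), cross_effects = TRUE) {
  stopifnot(inherits(priors, "mb_priors"), inherits(control,
                                                    "mb_chain_control"))
  design <- build_design(records, ped, fixed, cross_effects = cross_effects,
                         sources = c("A", "B", "S"))
  mme <- build_mme(design, prior_varcomp(priors), k = priors$k)
  prep <- gibbs_prepare(mme, priors)
  if (!is.null(control$seed)) set.seed(control$seed)

  res <- gibbs_chain_cpp(
    Wmat = prep$W, y = design$y, Cp = prep$Cp, Ci = prep$Ci,
    wtw_x = prep$wtw_x, static_x = prep$static_x, diag_pos = prep$diag_pos,
    pe_idx = prep$pe_idx, sources = prep$sources,
    nu_e = priors$nu_e, ss0_e = priors$nu_e * priors$s2_e,
    nu_pe = priors$nu_pe, ss0_pe = priors$nu_pe * priors$s2_pe,
    G0_init = prep$G0_init, s2pe_init = priors$s2_pe,
    s2e_init = priors$s2_e,
    n_iter = control$n_iter, burn_in = control$burn_in, thin = control$thin,
    keep_locations = control$keep_locations)

  samples <- as_tibble(as.data.frame(res$samples))
  names(samples) <- mb_components()
  samples <- dplyr::bind_cols(tibble(iteration = res$iteration), samples)

  config_hash <- rlang::hash(list(priors = unclass(priors),
                                  control = unclass(control),
                                  fixed = deparse(fixed),
                                  n = length(design$y)))

  structure(list(samples = samples,
                 location_means = location_tibble(mme, res$theta_mean),
                 locations = if (control$keep_locations) res$locations,
                 priors = priors, control = control, seed = control$seed,
                 config_hash = config_hash, n_records = length(design$y),
                 index = mme$index),
            class = "mb_chain")
}

# flatten the C sparsity bookkeeping the C++ sampler needs
gibbs_prepare <- function(mme, priors) {
  design <- mme$design
  W <- as(as(mme$W, "generalMatrix"), "CsparseMatrix")
  m <- ncol(W)

  prec_patt <- list(Matrix::Diagonal(length(mme$index$fixed), 1))
  for (src in design$sources) {
    if (nrow(design$maps[[src]]) > 0) {
      prec_patt <- c(prec_patt, list(Matrix::kronecker(
        matrix(1, 2, 2), pattern_ones(mme$Ainv[[src]]))))
    }
  }
  prec_patt <- c(prec_patt, list(Matrix::Diagonal(ncol(design$Zp), 1)))
  patt <- pattern_ones(Matrix::crossprod(W)) + Matrix::bdiag(prec_patt)
  patt <- as(as(patt, "generalMatrix"), "CsparseMatrix")
  pkeys <- entry_keys(patt, m)

  wtw <- as(as(Matrix::crossprod(W), "generalMatrix"), "CsparseMatrix")
  wtw_x <- numeric(length(pkeys))
  wtw_x[match(entry_keys(wtw, m), pkeys)] <- wtw@x

  diag_pos <- match((seq_len(m) - 1) * as.numeric(m) + seq_len(m), pkeys)
  static_x <- numeric(length(pkeys))
  static_x[diag_pos[mme$index$fixed]] <- 1 / mme$k

  sources <- list()
  G0_init <- matrix(0, 3, length(design$sources))
  for (s in seq_along(design$sources)) {
    src <- design$sources[s]
    Ainv <- as(as(mme$Ainv[[src]], "generalMatrix"), "CsparseMatrix")
    io <- mme$index[[paste0(src, "_o")]]
    im <- mme$index[[paste0(src, "_m")]]
    arow <- Ainv@i + 1L
    acol <- rep.int(seq_len(ncol(Ainv)), diff(Ainv@p))
    key_of <- function(r, c) (c - 1) * as.numeric(m) + r
    pos <- function(ridx, cidx) {
      p <- match(key_of(ridx[arow], cidx[acol]), pkeys)
      stopifnot(!anyNA(p))
      p - 1L
    }
    G0p <- priors[[paste0("G0", src)]]
    nu <- priors[[paste0("nu_", src)]]
    sources[[src]] <- list(
      idx_o = io - 1L, idx_m = im - 1L,
      Ap = Ainv@p, Ai = Ainv@i, Ax = Ainv@x,
      pos_oo = if (length(io) > 0) pos(io, io) else integer(0),
      pos_om = if (length(io) > 0) pos(io, im) else integer(0),
      pos_mo = if (length(io) > 0) pos(im, io) else integer(0),
      pos_mm = if (length(io) > 0) pos(im, im) else integer(0),
      Psi = nu * c(G0p[1, 1], G0p[1, 2], G0p[2, 2]),
      nu = nu)
    G0_init[, s] <- c(G0p[1, 1], G0p[1, 2], G0p[2, 2])
  }

  list(W = list(i = W@i, p = W@p, x = W@x),
       Cp = patt@p, Ci = patt@i, wtw_x = wtw_x, static_x = static_x,
       diag_pos = diag_pos - 1L, pe_idx = mme$index$pe - 1L,
       sources = unname(sources), G0_init = G0_init)
}

# label the posterior means of location parameters
location_tibble <- function(mme, theta_mean) {
  design <- mme$design
  out <- list(tibble(block = "fixed", term = colnames(design$X),
                     source = NA_character_, effect = NA_character_,
                     value = theta_mean[mme$index$fixed]))
  for (src in design$sources) {
    map <- design$maps[[src]]
    for (eff in c("o", "m")) {
      out <- c(out, list(tibble(
        block = "genetic", term = map$animal, source = src,
        effect = ifelse(eff == "o", "direct", "maternal"),
        value = theta_mean[mme$index[[paste0(src, "_", eff)]]])))
    }
  }
  out <- c(out, list(tibble(block = "pe", term = design$dams$animal,
                            source = NA_character_, effect = NA_character_,
                            value = theta_mean[mme$index$pe])))
  dplyr::bind_rows(out)
}

#' @method tidy mb_chain
#' @export
tidy.mb_chain <- function(x, ...) {
  tidyr::pivot_longer(x$samples, -"iteration", names_to = "component",
                      values_to = "value")
}

#' @method glance mb_chain
#' @export
glance.mb_chain <- function(x, ...) {
  tibble(n_saved = nrow(x$samples), n_iter = x$control$n_iter,
         burn_in = x$control$burn_in, thin = x$control$thin,
         seed = x$seed %||% NA_integer_, n_records = x$n_records)
}

#' @export
print.mb_chain <- function(x, ...) {
  cat("# Multibreed Gibbs chain:", nrow(x$samples), "saved draws (",
      x$control$n_iter, "iterations, burn-in", x$control$burn_in,
      ", thin", x$control$thin, ")\n")
  print(glance(x))
  invisible(x)
}

#' Write / read a chain sample file
#'
#' Plain tab-delimited text, one row per saved iteration and one column per
#' component, preceded by header comment lines recording the seed and the
#' configuration hash.
#'
#' @param chain An `mb_chain`.
#' @param path Output file.
#' @return `write_chain` returns `path` invisibly; `read_chain` returns a
#'   tibble with the seed and hash in attributes `seed` and `config_hash`.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "mb_chain"))
  header <- c(paste0("# seed: ", chain$seed %||% "NA"),
              paste0("# config_hash: ", chain$config_hash))
  writeLines(header, path)
  readr::write_tsv(chain$samples, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  lines <- readLines(path, n = 10)
  hdr <- lines[startsWith(lines, "#")]
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  attr(out, "seed") <- sub("^# seed: ", "", hdr[1])
  attr(out, "config_hash") <- sub("^# config_hash: ", "", hdr[2])
  out
}

#' Conjugate reference samplers
#'
#' Direct draws from the full conditionals used by the Gibbs sampler, kept
#' as plain R reference implementations: a scaled inverse chi-squared draw
#' for a scalar variance (degrees of freedom `nu + n_terms`, scale
#' `(sum_sq + nu * s2_0) / (nu + n_terms)`), an inverse-Wishart draw for a
#' 2-by-2 genetic covariance matrix (degrees of freedom `nu + q`, scale
#' `nu * G0_0 + S`), and one systematic single-site scan of a normal system
#' `C theta = r`.
#'
#' @param sum_sq Residual quadratic form (>= 0).
#' @param n_terms Number of contributing terms (0 gives a prior draw).
#' @param s2_0,nu Prior scale and degrees of belief.
#' @return A single variance draw.
#' @export
sample_scalar_variance <- function(sum_sq, n_terms, s2_0, nu) {
  if (sum_sq < 0) stop_mb("sum_sq must be non-negative", "mb_input_error")
  (sum_sq + nu * s2_0) / rchisq(1, nu + n_terms)
}

#' @rdname sample_scalar_variance
#' @param S 2-by-2 quadratic-form matrix
#'   `[u_o' Ainv u_o, u_o' Ainv u_m; ., u_m' Ainv u_m]`.
#' @param q Number of contributors.
#' @param G0_0 2-by-2 prior scale matrix.
#' @return A symmetric positive-definite 2-by-2 draw.
#' @export
sample_g0 <- function(S, q, G0_0, nu) {
  scale <- nu * G0_0 + S
  if (!is_pd2(scale)) {
    stop_mb("inverse-Wishart scale is not positive definite", "mb_not_pd")
  }
  Wdraw <- rWishart(1, df = nu + q, Sigma = solve(scale))[, , 1]
  out <- solve(Wdraw)
  (out + t(out)) / 2
}

#' @rdname sample_scalar_variance
#' @param theta Current location vector.
#' @param C Symmetric positive-definite coefficient matrix (dense or
#'   sparse).
#' @param r Right-hand side.
#' @return Updated location vector after one full scan.
#' @export
sample_locations_single_site <- function(theta, C, r) {
  C <- as.matrix(C)
  for (j in seq_along(theta)) {
    lin <- sum(C[, j] * theta) - C[j, j] * theta[j]
    mn <- (r[j] - lin) / C[j, j]
    theta[j] <- rnorm(1, mn, sqrt(1 / C[j, j]))
    if (!is.finite(theta[j])) {
      stop_mb(paste0("non-finite location draw at coordinate ", j),
              "mb_divergence")
    }
  }
  theta
}
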