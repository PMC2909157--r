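#' Design matrices for the maternal multibreed model
#'
#' Assembles the incidence matrices of the model
#' `y = X b + sum_X (Z_oX a_oX + Z_mX a_mX) + Z_p e_p + e`:
#' a full-rank fixed-effect matrix `X` (treatment contrasts, first level of
#' each factor absorbed, optional breed/heterosis covariates), one
#' direct and one maternal indicator matrix per source of variability
#' mapping records to the collapsed codes of contributing animals (records
#' on non-contributors get all-zero rows), and the indicator of maternal
#' permanent-environment effects for dams with records.
#'
#' @param records Data frame with a column `animal` plus the variables named
#'   in `fixed`; the dam of each record is resolved through the pedigree.
#' @param ped An `mb_pedigree`.
#' @param fixed Two-sided formula for the response and fixed effects, e.g.
#'   `weight ~ sex + age_of_dam + day_of_birth`.
#' @param cross_effects If `TRUE` (default), direct/maternal breed and
#'   heterosis covariates from [cross_covariates()] are appended to `X`.
#' @param sources Character vector of sources to fit, default
#'   `c("A", "B", "S")`; order controls the block order of the system.
#' @return A list of class `mb_design`: `y`, `X`, `Z` (per source, elements
#'   `o` and `m`), `Zp`, `maps` (contributor tibbles), `dams` (tibble of
#'   dams with records), `records`, `sources`.
#' @export
build_design <- function(records, ped, fixed, cross_effects = TRUE,
                         sources = c("A", "B", "S")) {
  check_pedigree(ped)
  records <- as_tibble(records)
  if (!"animal" %in% names(records)) {
    stop_mb("records need an 'animal' column", "mb_input_error")
  }
  code <- match(as.character(records$animal), ped$animal)
  if (anyNA(code)) {
    bad <- unique(records$animal[is.na(code)])
    stop_mb(paste0("records reference animals absent from the pedigree: ",
                   paste(utils::head(bad, 5), collapse = ", ")),
            "mb_input_error")
  }
  dam_code <- ped$dam_code[code]
  if (any(dam_code == 0)) {
    bad <- unique(records$animal[dam_code == 0])
    stop_mb(paste0("records on animals without a resolvable dam (maternal ",
                   "effects need one): ", paste(utils::head(bad, 5),
                                                collapse = ", ")),
            "mb_input_error")
  }

  dat <- records
  if (cross_effects) {
    cc <- cross_covariates(ped)
    dat <- dplyr::bind_cols(
      dat,
      cc[code, c("direct_breed", "maternal_breed",
                 "direct_heterosis", "maternal_heterosis")])
    fixed <- stats::update(fixed, . ~ . + direct_breed + maternal_breed +
                             direct_heterosis + maternal_heterosis)
  }
  mf <- stats::model.frame(fixed, data = dat)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(fixed, data = mf)
  zero_col <- Matrix::colSums(abs(X)) == 0
  if (any(zero_col)) {
    stop_mb(paste0("all-zero fixed-effect columns: ",
                   paste(colnames(X)[zero_col], collapse = ", ")),
            "mb_input_error")
  }
  n <- length(y)

  maps <- lapply(setNames(sources, sources),
                 function(src) contributors(ped, src))
  ind <- function(codes, map) {
    collapsed <- integer(nrow(ped))
    collapsed[map$code] <- map$collapsed
    j <- collapsed[codes]
    keep <- which(j > 0)
    Matrix::sparseMatrix(i = keep, j = j[keep], x = rep(1, length(keep)),
                         dims = c(length(codes), nrow(map)))
  }
  Z <- lapply(maps, function(map) list(o = ind(code, map),
                                       m = ind(dam_code, map)))

  dams <- tibble(code = sort(unique(dam_code)))
  dams$animal <- ped$animal[dams$code]
  dams$ep <- seq_len(nrow(dams))
  Zp <- Matrix::sparseMatrix(i = seq_len(n),
                             j = dams$ep[match(dam_code, dams$code)],
                             x = rep(1, n), dims = c(n, nrow(dams)))

  structure(list(y = as.numeric(y), X = Matrix::Matrix(X, sparse = TRUE),
                 Z = Z, Zp = Zp, maps = maps, dams = dams,
                 records = records, animal_code = code, dam_code = dam_code,
                 sources = sources, ped = ped),
            class = "mb_design")
}

#' Mixed-model equations of the multibreed maternal model
#'
#' Builds the sparse symmetric coefficient matrix and right-hand side
#' `C = W'W / sigma2_e + blockdiag of K^-1, per-source G0X^-1 (x) A*X^-1, and I / sigma2_pe`
#' and right-hand side `W'y / sigma2_e`, with `W = [X | Z blocks | Zp]`. Within each
#' source the unknowns are ordered (all direct | all maternal) so the
#' Kronecker structure with the 2-by-2 `G0X` holds. The vague fixed-effect
#' prior `K = k I` keeps the system positive definite.
#'
#' @param design An `mb_design` from [build_design()].
#' @param vc An `mb_varcomp` (or named component vector).
#' @param k Fixed-effect prior variance, default `1e7` (larger is allowed).
#' @return A list of class `mb_mme`: `C`, `r`, `index` (named list of
#'   column index vectors), `W`, `Ainv` (per-source sparse inverses),
#'   `design`, `vc`, `k`.
#' @export
build_mme <- function(design, vc, k = 1e7) {
  stopifnot(inherits(design, "mb_design"))
  if (k < 1e7) {
    stop_mb("fixed-effect prior variance k must be at least 1e7",
            "mb_input_error")
  }
  vc <- as_varcomp(vc)
  Ainv <- lapply(setNames(design$sources, design$sources),
                 function(src) collapsed_inverse(design$ped, src))

  blocks <- list(design$X)
  prec <- list(Matrix::Diagonal(ncol(design$X)) / k)
  index <- list(fixed = seq_len(ncol(design$X)))
  pos <- ncol(design$X)
  for (src in design$sources) {
    qx <- nrow(design$maps[[src]])
    blocks <- c(blocks, list(design$Z[[src]]$o, design$Z[[src]]$m))
    index[[paste0(src, "_o")]] <- pos + seq_len(qx)
    index[[paste0(src, "_m")]] <- pos + qx + seq_len(qx)
    pos <- pos + 2 * qx
    G0 <- vc[[paste0("G0", src)]]
    if (qx > 0) {
      prec <- c(prec, list(Matrix::kronecker(inv2(G0), Ainv[[src]])))
    }
  }
  blocks <- c(blocks, list(design$Zp))
  d <- ncol(design$Zp)
  index$pe <- pos + seq_len(d)
  prec <- c(prec, list(Matrix::Diagonal(d) / vc$sigma2_pe))

  W <- do.call(cbind, blocks)
  C <- Matrix::crossprod(W) / vc$sigma2_e + Matrix::bdiag(prec)
  r <- as.numeric(Matrix::crossprod(W, design$y)) / vc$sigma2_e
  structure(list(C = Matrix::forceSymmetric(C), r = r, index = index, W = W,
                 Ainv = Ainv, design = design, vc = vc, k = k),
            class = "mb_mme")
}

#' BLUP for the multibreed maternal model
#'
#' Solves the mixed-model equations at fixed (co)variance components and
#' reconstructs total direct and maternal breeding values per animal by
#' summing the per-source solutions expanded over the contributor maps.
#'
#' @param records,ped,fixed,cross_effects,sources See [build_design()].
#' @param vc An `mb_varcomp` (or named component vector).
#' @param k Fixed-effect prior variance (default `1e7`).
#' @return An object of class `mb_blup` with elements `fixed` (tibble),
#'   `random` (long tibble: `animal`, `source`, `effect`, `value`),
#'   `pe` (tibble), `total` (tibble: `animal`, `direct`, `maternal`),
#'   `mme`, `solution` (full solution vector).
#' @export
mb_blup <- function(records, ped, fixed, vc, cross_effects = TRUE,
                    sources = c("A", "B", "S"), k = 1e7) {
  design <- build_design(records, ped, fixed, cross_effects = cross_effects,
                         sources = sources)
  mme <- build_mme(design, vc, k = k)
  sol <- solve_mme(mme)
  q <- nrow(ped)

  random <- list()
  direct <- numeric(q)
  maternal <- numeric(q)
  for (src in design$sources) {
    map <- design$maps[[src]]
    for (eff in c("o", "m")) {
      v <- sol[mme$index[[paste0(src, "_", eff)]]]
      full <- expand_collapsed(v, map, q)
      if (eff == "o") direct <- direct + full else maternal <- maternal + full
      random[[paste0(src, eff)]] <- tibble(animal = map$animal, source = src,
                                           effect = ifelse(eff == "o",
                                                           "direct",
                                                           "maternal"),
                                           value = v)
    }
  }
  structure(list(
    fixed = tibble(term = colnames(design$X), estimate = sol[mme$index$fixed]),
    random = dplyr::bind_rows(random),
    pe = tibble(animal = design$dams$animal, value = sol[mme$index$pe]),
    total = tibble(animal = ped$animal, direct = direct, maternal = maternal),
    mme = mme, solution = sol), class = "mb_blup")
}

# exact sparse solve with a relative-residual guard
solve_mme <- function(mme) {
  sol <- tryCatch(as.numeric(Matrix::solve(mme$C, mme$r)),
                  error = function(e) {
                    stop_mb(paste0("mixed-model equations are singular: ",
                                   conditionMessage(e)), "mb_singular")
                  })
  res <- as.numeric(mme$C %*% sol) - mme$r
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(mme$r^2)), 1e-300)
  if (!is.finite(rel) || rel > 1e-8) {
    stop_mb(paste0("linear-system residual too large: ", format(rel)),
            "mb_singular")
  }
  sol
}

#' Total breeding values from a fitted BLUP model
#'
#' @param fit An `mb_blup`.
#' @return A tibble with columns `animal`, `direct`, `maternal` (sums of the
#'   per-source breeding values over the contributor maps).
#' @export
total_breeding_values <- function(fit) {
  stopifnot(inherits(fit, "mb_blup"))
  fit$total
}

#' @method tidy mb_blup
#' @export
tidy.mb_blup <- function(x, effects = c("random", "fixed", "pe"), ...) {
  effects <- match.arg(effects)
  switch(effects,
         fixed = x$fixed,
         random = x$random,
         pe = x$pe)
}

#' @method glance mb_blup
#' @export
glance.mb_blup <- function(x, ...) {
  tibble(n_records = length(x$mme$design$y),
         n_fixed = length(x$mme$index$fixed),
         n_equations = length(x$solution),
         sources = paste(x$mme$design$sources, collapse = ","))
}

#' @export
print.mb_blup <- function(x, ...) {
  cat("# Multibreed maternal BLUP fit:", length(x$mme$design$y), "records,",
      length(x$solution), "equations\n")
  print(glance(x))
  invisible(x)
}
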