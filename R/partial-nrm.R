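#' Partial numerator relationship matrix, tabular method
#'
#' Builds the full q-by-q partial numerator relationship matrix for one
#' source of variability (breed `"A"`, breed `"B"`, or segregation `"S"`)
#' by the tabular recursion run in pedigree order. Off-diagonals are parent
#' averages, `a(i, j) = (a(sire, j) + a(dam, j)) / 2`; the diagonal is
#' `a(i, i) = b_i + a(sire, dam) / 2`, where the base term `b_i` is the
#' animal's breed fraction `f_X(i)` for the breed sources and the
#' segregation coefficient `s_i` (see [segregation_coefficients()]) for the
#' segregation source. Rows and columns of animals that do not contribute to
#' the source are identically zero. The total additive genetic covariance is
#' `G = sigma2_A * A_A + sigma2_B * A_B + sigma2_S * A_S`.
#'
#' This full-size variant is a reference/oracle path; production code uses
#' the collapsed matrices over contributors and their sparse inverses.
#'
#' @param ped An `mb_pedigree`.
#' @param source One of `"A"`, `"B"`, `"S"`.
#' @return A dense symmetric q-by-q matrix with animal identifiers as
#'   dimnames.
#' @export
partial_nrm_tabular <- function(ped, source = c("A", "B", "S")) {
  check_pedigree(ped)
  source <- match.arg(source)
  q <- nrow(ped)
  b <- base_terms(ped, source)
  A <- matrix(0, q, q, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(q)) {
    s <- ped$sire_code[i]
    d <- ped$dam_code[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row_s <- if (s > 0) A[s, j] else 0
      row_d <- if (d > 0) A[d, j] else 0
      aij <- (row_s + row_d) / 2
      A[i, j] <- aij
      A[j, i] <- aij
    }
    asd <- if (s > 0 && d > 0) A[s, d] else 0
    A[i, i] <- b[i] + asd / 2
  }
  A
}

# per-animal base term of the Mendelian-sampling recursion
base_terms <- function(ped, source) {
  switch(source,
         A = ped$f_A,
         B = ped$f_B,
         S = segregation_coefficients(ped)$s)
}

#' Contributor map for a source of variability
#'
#' Animals with a non-null contribution to a source: for the breed sources,
#' animals with a positive expected breed fraction; for the segregation
#' source, animals with a positive segregation coefficient or with a
#' contributing parent. These are exactly the animals with a nonzero
#' diagonal in the tabular partial relationship matrix; all other rows and
#' columns are null and are collapsed out.
#'
#' @param ped An `mb_pedigree`.
#' @param source One of `"A"`, `"B"`, `"S"`.
#' @return A tibble with one row per contributor, columns `animal`, `code`
#'   (global pedigree code) and `collapsed` (1-based index into the
#'   collapsed system), in pedigree order.
#' @export
contributors <- function(ped, source = c("A", "B", "S")) {
  check_pedigree(ped)
  source <- match.arg(source)
  if (source %in% c("A", "B")) {
    member <- base_terms(ped, source) > MB_EPS
  } else {
    s <- segregation_coefficients(ped)$s
    member <- logical(nrow(ped))
    for (i in seq_len(nrow(ped))) {
      ps <- ped$sire_code[i]
      pd <- ped$dam_code[i]
      member[i] <- s[i] > MB_EPS ||
        (ps > 0 && member[ps]) || (pd > 0 && member[pd])
    }
  }
  tibble(animal = ped$animal[member], code = ped$code[member],
         collapsed = seq_len(sum(member)))
}

#' Within-family (Mendelian-sampling) partial variance coefficients
#'
#' Computes, row by row without storing the full relationship matrix, the
#' coefficient `d_X(i)` of the within-family variance of each contributor:
#' `d_X(i) = b_i - (a_X(s, s) + a_X(d, d)) / 4`, with `b_i` the breed
#' fraction (breed sources) or segregation coefficient (segregation source)
#' and absent-parent terms zero. Parent diagonals are obtained by tracing
#' the parent-average rows against the already-computed coefficients, in the
#' style of the row-wise inbreeding algorithm of Meuwissen and Luo, so the
#' values equal the tabular ones exactly.
#'
#' @param ped An `mb_pedigree`.
#' @param source One of `"A"`, `"B"`, `"S"`.
#' @return A tibble with columns `animal`, `code`, `contributor` (logical),
#'   `d` (zero for non-contributors) and `diag` (the diagonal of the partial
#'   relationship matrix).
#' @export
mendelian_variances <- function(ped, source = c("A", "B", "S")) {
  check_pedigree(ped)
  source <- match.arg(source)
  q <- nrow(ped)
  b <- base_terms(ped, source)
  member <- logical(q)
  member[contributors(ped, source)$code] <- TRUE
  dvec <- numeric(q)
  diag_a <- numeric(q)
  sire <- ped$sire_code
  dam <- ped$dam_code
  for (i in seq_len(q)) {
    if (!member[i]) next
    s <- sire[i]
    d <- dam[i]
    ass <- if (s > 0) diag_a[s] else 0
    add <- if (d > 0) diag_a[d] else 0
    asd <- if (s > 0 && d > 0) trace_relationship(s, d, sire, dam, dvec) else 0
    dvec[i] <- b[i] - (ass + add) / 4
    diag_a[i] <- b[i] + asd / 2
    if (dvec[i] <= MB_EPS) {
      stop_mb(paste0("within-family variance for source ", source,
                     " vanishes for animal '", ped$animal[i],
                     "' (completely inbred contributing parents)"),
              "mb_degenerate_family")
    }
  }
  tibble(animal = ped$animal, code = ped$code, contributor = member,
         d = dvec, diag = diag_a)
}

# a_X(s, d) = sum_k T[s, k] T[d, k] d_X(k): trace the parent-average rows of
# s and d down the pedigree, then combine with the Mendelian coefficients
trace_relationship <- function(s, d, sire, dam, dvec) {
  top <- max(s, d)
  xs <- numeric(top)
  xd <- numeric(top)
  xs[s] <- 1
  xd[d] <- 1
  acc <- 0
  for (k in rev(seq_len(top))) {
    if (xs[k] != 0 && xd[k] != 0) acc <- acc + xs[k] * xd[k] * dvec[k]
    if (xs[k] != 0) {
      if (sire[k] > 0) xs[sire[k]] <- xs[sire[k]] + xs[k] / 2
      if (dam[k] > 0) xs[dam[k]] <- xs[dam[k]] + xs[k] / 2
    }
    if (xd[k] != 0) {
      if (sire[k] > 0) xd[sire[k]] <- xd[sire[k]] + xd[k] / 2
      if (dam[k] > 0) xd[dam[k]] <- xd[dam[k]] + xd[k] / 2
    }
  }
  acc
}

#' Collapsed partial relationship matrix
#'
#' The partial numerator relationship matrix restricted to its contributors
#' (the non-null rows and columns). Equals the tabular matrix with null rows
#' and columns removed.
#'
#' @param ped An `mb_pedigree`.
#' @param source One of `"A"`, `"B"`, `"S"`.
#' @return A list of class `mb_pnrm` with elements `source`, `members` (the
#'   contributor tibble) and `matrix` (dense symmetric matrix over
#'   contributors).
#' @export
collapsed_nrm <- function(ped, source = c("A", "B", "S")) {
  source <- match.arg(source)
  mem <- contributors(ped, source)
  A <- partial_nrm_tabular(ped, source)
  out <- list(source = source, members = mem,
              matrix = A[mem$code, mem$code, drop = FALSE])
  class(out) <- "mb_pnrm"
  out
}

#' Sparse inverse of the collapsed partial relationship matrix
#'
#' Assembles the inverse directly from the Mendelian-sampling coefficients by
#' the Henderson/Quaas rules restricted to contributors: for each contributor
#' `i` with `w = 1 / d_X(i)`, add `w` at `(i, i)`, `-w/2` between `i` and
#' each contributing parent, and `w/4` between contributing parents. The
#' product with the collapsed matrix is the identity (within 1e-8; verified
#' in the test suite).
#'
#' @param ped An `mb_pedigree`.
#' @param source One of `"A"`, `"B"`, `"S"`.
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) over contributors
#'   with the contributor tibble attached as attribute `members`.
#' @export
collapsed_inverse <- function(ped, source = c("A", "B", "S")) {
  source <- match.arg(source)
  mem <- contributors(ped, source)
  md <- mendelian_variances(ped, source)
  qx <- nrow(mem)
  if (qx == 0) {
    out <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(0, 0), symmetric = TRUE)
    attr(out, "members") <- mem
    return(out)
  }
  collapsed_of <- integer(nrow(ped))
  collapsed_of[mem$code] <- mem$collapsed
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_len(qx)) {
    g <- mem$code[k]
    w <- 1 / md$d[g]
    par <- c(ped$sire_code[g], ped$dam_code[g])
    par <- par[par > 0]
    par <- collapsed_of[par]
    par <- par[par > 0]
    ii <- c(ii, k); jj <- c(jj, k); xx <- c(xx, w)
    for (p in par) {
      ii <- c(ii, k, p); jj <- c(jj, p, k); xx <- c(xx, -w / 2, -w / 2)
    }
    if (length(par) > 0) {
      pp <- expand.grid(p1 = par, p2 = par)
      ii <- c(ii, pp$p1); jj <- c(jj, pp$p2)
      xx <- c(xx, rep(w / 4, nrow(pp)))
    }
  }
  out <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(qx, qx))
  out <- Matrix::forceSymmetric((out + Matrix::t(out)) / 2)
  attr(out, "members") <- mem
  out
}

#' Scatter collapsed values back to the full pedigree
#'
#' Applies the expansion map: values defined on the contributors of a source
#' are scattered into a full-length vector with zeros at non-contributors.
#'
#' @param values Numeric vector over contributors (collapsed order).
#' @param members Contributor tibble from [contributors()] (or the
#'   `members` attribute of a collapsed matrix).
#' @param q Total number of animals in the pedigree.
#' @return Numeric vector of length `q`.
#' @export
expand_collapsed <- function(values, members, q) {
  if (length(values) != nrow(members)) {
    stop_mb(paste0("expected ", nrow(members), " collapsed values, got ",
                   length(values)), "mb_dim_error")
  }
  out <- numeric(q)
  out[members$code] <- values
  out
}

#' Assemble the total additive genetic covariance matrix
#'
#' `G = sigma2_A * A_A + sigma2_B * A_B + sigma2_S * A_S` from the full
#' tabular partial relationship matrices. Reference path for small
#' pedigrees.
#'
#' @param ped An `mb_pedigree`.
#' @param sigma2 Named numeric vector with elements `A`, `B`, `S` (the
#'   additive variances of each breed and the segregation variance).
#' @return Dense symmetric q-by-q matrix.
#' @export
assemble_total_g <- function(ped, sigma2) {
  check_pedigree(ped)
  if (!all(c("A", "B", "S") %in% names(sigma2))) {
    stop_mb("sigma2 must be named with elements A, B, S", "mb_input_error")
  }
  if (any(sigma2 < 0)) {
    stop_mb("variance components must be non-negative", "mb_input_error")
  }
  sigma2[["A"]] * partial_nrm_tabular(ped, "A") +
    sigma2[["B"]] * partial_nrm_tabular(ped, "B") +
    sigma2[["S"]] * partial_nrm_tabular(ped, "S")
}
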