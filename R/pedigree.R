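#' Read a pedigree file
#'
#' Reads a delimited pedigree file with columns `animal`, `sire`, `dam` and,
#' for base animals, the expected breed-A gene fraction, and returns a
#' validated, topologically ordered pedigree. Unknown parents are coded as
#' `"0"`, `""` or `NA`.
#'
#' @param path Path to a delimited text file (CSV or TSV, sniffed from the
#'   extension unless `delim` is given).
#' @param delim Field delimiter; `NULL` uses `","` unless the file extension
#'   is `.tsv`/`.txt`.
#' @param ... Passed on to [as_pedigree()] (column names, phantom policy).
#' @return An `mb_pedigree` tibble; see [as_pedigree()].
#' @export
read_pedigree <- function(path, delim = NULL, ...) {
  if (!file.exists(path)) {
    stop_mb(paste0("pedigree file not found: ", path), "mb_io_error")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  as_pedigree(df, ...)
}

#' Build a validated multibreed pedigree
#'
#' Validates identifiers, resolves unknown parents, fills phantom base parents
#' where requested, orders the pedigree so every parent precedes its
#' offspring, assigns dense integer codes `1..q` (0 = unknown), and computes
#' the expected breed fractions `f_A`, `f_B` of every animal by the
#' parent-average recursion `f_i = (f_sire + f_dam) / 2`.
#'
#' Base animals (both parents unknown) must carry a declared breed-A fraction
#' in `f_A_col`. They are purebred by default; a crossbred base animal is
#' accepted, but operations that need its parental breed fractions
#' (segregation coefficients, heterosis covariates) require the optional
#' columns `base_sire_f_A` and `base_dam_f_A`. An animal with exactly one
#' unknown parent is completed with a phantom base parent whose breed-A
#' fraction must be supplied in a `phantom_f_A` column; the default policy
#' refuses to guess.
#'
#' @param df Data frame with columns `animal`, `sire`, `dam`, optionally
#'   `f_A` (base fractions), `sex`, `base_sire_f_A`, `base_dam_f_A`,
#'   `phantom_f_A`; further columns are carried through.
#' @param animal_col,sire_col,dam_col,f_A_col Column names.
#' @return An `mb_pedigree` tibble in topological order with columns
#'   `animal`, `sire`, `dam` (character, `NA` = unknown), `code`,
#'   `sire_code`, `dam_code` (integer, 0 = unknown), `base` (logical),
#'   `f_A`, `f_B`, `base_sire_f_A`, `base_dam_f_A`, plus passthrough columns.
#' @export
as_pedigree <- function(df, animal_col = "animal", sire_col = "sire",
                        dam_col = "dam", f_A_col = "f_A") {
  df <- as_tibble(df)
  for (col in c(animal_col, sire_col, dam_col)) {
    if (!col %in% names(df)) {
      stop_mb(paste0("pedigree is missing column '", col, "'"),
              "mb_pedigree_error")
    }
  }
  animal <- as.character(df[[animal_col]])
  sire <- normalize_parent(df[[sire_col]])
  dam <- normalize_parent(df[[dam_col]])
  if (anyNA(animal) || any(animal %in% c("", "0"))) {
    stop_mb("animal identifiers must be non-missing and not '0'",
            "mb_pedigree_error")
  }
  if (anyDuplicated(animal)) {
    dup <- animal[duplicated(animal)][1]
    stop_mb(paste0("duplicate animal identifier: ", dup), "mb_pedigree_error")
  }
  missing_parents <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(missing_parents) > 0) {
    stop_mb(paste0("parents not listed as animals (add base rows with breed ",
                   "fractions): ", paste(missing_parents, collapse = ", ")),
            "mb_pedigree_error")
  }

  fA_declared <- if (f_A_col %in% names(df)) as.numeric(df[[f_A_col]]) else
    rep(NA_real_, nrow(df))
  phantom_fA <- if ("phantom_f_A" %in% names(df))
    as.numeric(df$phantom_f_A) else rep(NA_real_, nrow(df))
  bsf <- if ("base_sire_f_A" %in% names(df))
    as.numeric(df$base_sire_f_A) else rep(NA_real_, nrow(df))
  bdf <- if ("base_dam_f_A" %in% names(df))
    as.numeric(df$base_dam_f_A) else rep(NA_real_, nrow(df))

  extra <- df[setdiff(names(df), c(animal_col, sire_col, dam_col, f_A_col,
                                   "phantom_f_A", "base_sire_f_A",
                                   "base_dam_f_A"))]

  ped <- tibble(animal = animal, sire = sire, dam = dam,
                f_A_declared = fA_declared, base_sire_f_A = bsf,
                base_dam_f_A = bdf)
  ped <- dplyr::bind_cols(ped, extra)

  # phantom-fill single unknown parents
  one_unknown <- xor(is.na(ped$sire), is.na(ped$dam))
  if (any(one_unknown)) {
    need <- one_unknown & is.na(phantom_fA)
    if (any(need)) {
      stop_mb(paste0("animals with one unknown parent need a 'phantom_f_A' ",
                     "breed fraction for the phantom base parent: ",
                     paste(ped$animal[need], collapse = ", ")),
              "mb_pedigree_error")
    }
    idx <- which(one_unknown)
    phantom <- tibble(animal = paste0(ped$animal[idx], ".phantom"),
                      sire = NA_character_, dam = NA_character_,
                      f_A_declared = phantom_fA[idx],
                      base_sire_f_A = NA_real_, base_dam_f_A = NA_real_)
    miss_sire <- idx[is.na(ped$sire[idx])]
    ped$sire[miss_sire] <- paste0(ped$animal[miss_sire], ".phantom")
    miss_dam <- idx[is.na(ped$dam[idx])]
    ped$dam[miss_dam] <- paste0(ped$animal[miss_dam], ".phantom")
    ped <- dplyr::bind_rows(phantom, ped)
  }

  ped$base <- is.na(ped$sire) & is.na(ped$dam)
  bad_base <- ped$base & (is.na(ped$f_A_declared) | ped$f_A_declared < 0 |
                            ped$f_A_declared > 1)
  if (any(bad_base)) {
    stop_mb(paste0("base animals lacking a valid breed fraction in [0, 1]: ",
                   paste(ped$animal[bad_base], collapse = ", ")),
            "mb_pedigree_error")
  }

  ord <- topo_order(ped$animal, ped$sire, ped$dam)
  ped <- ped[ord, ]
  ped$code <- seq_len(nrow(ped))
  ped$sire_code <- match(ped$sire, ped$animal)
  ped$dam_code <- match(ped$dam, ped$animal)
  ped$sire_code[is.na(ped$sire_code)] <- 0L
  ped$dam_code[is.na(ped$dam_code)] <- 0L

  # breed-fraction recursion in pedigree order
  fA <- numeric(nrow(ped))
  for (i in seq_len(nrow(ped))) {
    if (ped$base[i]) {
      fA[i] <- ped$f_A_declared[i]
    } else {
      fA[i] <- (fA[ped$sire_code[i]] + fA[ped$dam_code[i]]) / 2
    }
  }
  ped$f_A <- fA
  ped$f_B <- 1 - fA

  # purebred base animals descend from the same purebred stock
  pure <- ped$base & (ped$f_A < MB_EPS | ped$f_B < MB_EPS)
  ped$base_sire_f_A[pure] <- ped$f_A[pure]
  ped$base_dam_f_A[pure] <- ped$f_A[pure]

  front <- c("animal", "sire", "dam", "code", "sire_code", "dam_code",
             "base", "f_A", "f_B", "base_sire_f_A", "base_dam_f_A")
  ped <- ped[c(front, setdiff(names(ped), c(front, "f_A_declared")))]
  class(ped) <- c("mb_pedigree", class(tibble()))
  ped
}

normalize_parent <- function(x) {
  x <- as.character(x)
  x[x %in% c("", "0", "NA")] <- NA_character_
  x
}

# Kahn topological sort, stable in input order; rejects cycles
topo_order <- function(animal, sire, dam) {
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue) > 0) {
    i <- queue[1]
    queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    bad <- animal[setdiff(seq_len(n), out)]
    stop_mb(paste0("pedigree contains a cycle (an animal is its own ",
                   "ancestor) involving: ", paste(bad, collapse = ", ")),
            "mb_pedigree_cycle")
  }
  out
}

#' Expected breed fractions
#'
#' Returns the expected proportion of breed-A and breed-B genes for every
#' animal, computed by the parent-average recursion from the declared base
#' fractions.
#'
#' @param ped An `mb_pedigree`.
#' @return A tibble with columns `animal`, `code`, `f_A`, `f_B`.
#' @export
breed_fractions <- function(ped) {
  check_pedigree(ped)
  tibble(animal = ped$animal, code = ped$code, f_A = ped$f_A, f_B = ped$f_B)
}

#' Segregation Mendelian-sampling coefficients
#'
#' The coefficient of the segregation variance in the Mendelian-sampling
#' variance of each animal:
#' `s_i = 2 * (f_A(sire) * f_B(sire) + f_A(dam) * f_B(dam))`.
#' Zero when both parents are purebred; 1 for F2 progeny of F1 parents.
#'
#' @param ped An `mb_pedigree`.
#' @return A tibble with columns `animal`, `code`, `s`.
#' @export
segregation_coefficients <- function(ped) {
  check_pedigree(ped)
  pf <- parental_fractions(ped)
  s <- 2 * (pf$sire_f_A * (1 - pf$sire_f_A) + pf$dam_f_A * (1 - pf$dam_f_A))
  tibble(animal = ped$animal, code = ped$code, s = s)
}

# breed-A fraction of each animal's sire and dam, falling back to declared
# base parental fractions for base animals
parental_fractions <- function(ped) {
  sfa <- ifelse(ped$sire_code > 0, ped$f_A[pmax(ped$sire_code, 1L)],
                ped$base_sire_f_A)
  dfa <- ifelse(ped$dam_code > 0, ped$f_A[pmax(ped$dam_code, 1L)],
                ped$base_dam_f_A)
  bad <- is.na(sfa) | is.na(dfa)
  if (any(bad)) {
    stop_mb(paste0("crossbred base animals need declared parental breed ",
                   "fractions (base_sire_f_A / base_dam_f_A): ",
                   paste(ped$animal[bad], collapse = ", ")),
            "mb_pedigree_error")
  }
  tibble(sire_f_A = sfa, dam_f_A = dfa)
}

#' Breed and heterosis covariates
#'
#' Regressors for mean differences between breed groups: the animal's own
#' expected breed-A fraction (direct breed), the dam's fraction (maternal
#' breed), the expected probability that a random locus of the animal pairs
#' one breed-A with one breed-B allele (direct heterosis,
#' `f_A(sire) * f_B(dam) + f_B(sire) * f_A(dam)`), and the dam's own
#' heterosis (maternal heterosis).
#'
#' @param ped An `mb_pedigree`.
#' @return A tibble with columns `animal`, `code`, `direct_breed`,
#'   `maternal_breed`, `direct_heterosis`, `maternal_heterosis`. Maternal
#'   covariates are `NA` for animals whose dam is a declared base parent
#'   without its own pedigree row.
#' @export
cross_covariates <- function(ped) {
  check_pedigree(ped)
  pf <- parental_fractions(ped)
  het <- pf$sire_f_A * (1 - pf$dam_f_A) + (1 - pf$sire_f_A) * pf$dam_f_A
  dam_idx <- ped$dam_code
  mat_breed <- ifelse(dam_idx > 0, ped$f_A[pmax(dam_idx, 1L)], NA_real_)
  mat_het <- ifelse(dam_idx > 0, het[pmax(dam_idx, 1L)], NA_real_)
  tibble(animal = ped$animal, code = ped$code,
         direct_breed = ped$f_A, maternal_breed = mat_breed,
         direct_heterosis = het, maternal_heterosis = mat_het)
}

check_pedigree <- function(ped) {
  if (!inherits(ped, "mb_pedigree")) {
    stop_mb("expected an 'mb_pedigree' (see as_pedigree())",
            "mb_pedigree_error")
  }
  invisible(ped)
}

#' @export
print.mb_pedigree <- function(x, ...) {
  cat("# A multibreed pedigree:", nrow(x), "animals (",
      sum(x$base), "base )\n")
  NextMethod()
}
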