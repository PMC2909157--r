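#' Read and write run configurations
#'
#' A run configuration bundles the file paths, prior specification, chain
#' settings and reference groups of an analysis in one YAML document, so a
#' run can be reproduced from a single file. The representation
#' round-trips: `read_run_config(write_run_config(cfg, path))` returns an
#' identical object.
#'
#' @param path YAML file.
#' @return `read_run_config` returns a list of class `mb_run_config` with
#'   elements `paths` (named list: `pedigree`, `data`, `output`), `fixed`
#'   (model formula as character), `priors` (an [mb_priors()]), `control`
#'   (an [mb_chain_control()]) and `groups` (named list of
#'   [reference_group()] weights).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_mb(paste0("config file not found: ", path), "mb_io_error")
  }
  raw <- yaml::read_yaml(path)
  g0 <- function(x) matrix(as.numeric(unlist(x)), 2, 2)
  pr <- lapply(raw$priors, function(x)
    if (is.character(x)) as.numeric(x) else x)
  priors <- mb_priors(
    G0A = g0(pr$G0A), nu_A = pr$nu_A,
    G0B = g0(pr$G0B), nu_B = pr$nu_B,
    G0S = g0(pr$G0S), nu_S = pr$nu_S,
    s2_pe = pr$s2_pe, nu_pe = pr$nu_pe,
    s2_e = pr$s2_e, nu_e = pr$nu_e,
    k = pr$k %||% 1e7)
  ct <- raw$control
  control <- mb_chain_control(
    n_iter = ct$n_iter %||% 20000, burn_in = ct$burn_in %||% 2000,
    thin = ct$thin %||% 10, seed = ct$seed,
    keep_locations = ct$keep_locations %||% FALSE)
  groups <- lapply(raw$groups %||% list(F2 = c(0.5, 0.5, 1)), function(w) {
    w <- as.numeric(unlist(w))
    reference_group(w[1], w[2], w[3])
  })
  structure(list(paths = raw$paths, fixed = raw$fixed, priors = priors,
                 control = control, groups = groups),
            class = "mb_run_config")
}

#' @rdname read_run_config
#' @param config An `mb_run_config` (or a bare list with the same shape).
#' @return `write_run_config` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  pr <- config$priors
  ct <- config$control
  doc <- list(
    paths = config$paths,
    fixed = config$fixed,
    priors = list(G0A = as.numeric(pr$G0A), nu_A = pr$nu_A,
                  G0B = as.numeric(pr$G0B), nu_B = pr$nu_B,
                  G0S = as.numeric(pr$G0S), nu_S = pr$nu_S,
                  s2_pe = pr$s2_pe, nu_pe = pr$nu_pe,
                  s2_e = pr$s2_e, nu_e = pr$nu_e, k = pr$k),
    control = list(n_iter = ct$n_iter, burn_in = ct$burn_in,
                   thin = ct$thin, seed = ct$seed,
                   keep_locations = ct$keep_locations),
    groups = lapply(config$groups, function(g) as.numeric(unclass(g))))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Write simulated fixtures as delimited text
#'
#' Writes the pedigree and phenotype files of a simulated data set in the
#' formats the readers expect (`read_pedigree()`, a phenotype CSV), plus
#' the true generating components as a two-column table.
#'
#' @param dataset A list from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped_path <- file.path(dir, "pedigree.csv")
  rec_path <- file.path(dir, "records.csv")
  truth_path <- file.path(dir, "truth.csv")
  ped <- dataset$pedigree
  out <- tibble(animal = ped$animal,
                sire = ifelse(is.na(ped$sire), "0", ped$sire),
                dam = ifelse(is.na(ped$dam), "0", ped$dam),
                f_A = ifelse(ped$base, ped$f_A, NA_real_),
                sex = ped$sex, genotype = ped$genotype)
  readr::write_csv(out, ped_path, na = "")
  readr::write_csv(dataset$records, rec_path, na = "")
  readr::write_csv(tidy(dataset$truth), truth_path)
  invisible(c(pedigree = ped_path, records = rec_path, truth = truth_path))
}
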