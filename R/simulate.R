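#' Crossbred mating plan
#'
#' Describes a synthetic crossbred design: base population sizes of the two
#' parental breeds plus a table of genotype classes with target progeny
#' counts. The default plan emulates the genotype classes of the Angus x
#' Hereford experiment (parental purebreds, F1 in both directions, F2-F4
#' inter-se, backcrosses, rotational R3/R4 and advanced crosses), with
#' counts scaled from the published record numbers.
#'
#' @param classes Tibble with columns `genotype` and `n` (one of the class
#'   labels of [angus_hereford_classes()]).
#' @param n_base_A,n_base_B Base-animal counts per breed.
#' @param progeny_per_dam Target mean number of progeny per dam (dams are
#'   cycled so most have several progeny, as maternal-effect designs need).
#' @param progeny_per_sire Target mean number of progeny per sire.
#' @return An object of class `mb_plan`.
#' @export
mating_plan <- function(classes, n_base_A = 60, n_base_B = 40,
                        progeny_per_dam = 2.5, progeny_per_sire = 15) {
  classes <- as_tibble(classes)
  stopifnot(all(c("genotype", "n") %in% names(classes)))
  unknown <- setdiff(classes$genotype, names(class_recipes()))
  if (length(unknown) > 0) {
    stop_mb(paste0("unknown genotype classes: ",
                   paste(unknown, collapse = ", ")), "mb_input_error")
  }
  if (any(classes$n < 0) || n_base_A < 2 || n_base_B < 2) {
    stop_mb("class counts must be >= 0 and base counts >= 2",
            "mb_input_error")
  }
  structure(list(classes = classes, n_base_A = n_base_A,
                 n_base_B = n_base_B, progeny_per_dam = progeny_per_dam,
                 progeny_per_sire = progeny_per_sire), class = "mb_plan")
}

#' @rdname mating_plan
#' @param scale Multiplier applied to the published class counts (records
#'   round up, so every class keeps at least one animal).
#' @export
angus_hereford_plan <- function(scale = 1, progeny_per_dam = 2.5,
                                progeny_per_sire = 15) {
  cls <- angus_hereford_classes()[c("genotype", "n")]
  cls$n <- as.integer(ceiling(cls$n * scale))
  mating_plan(cls,
              n_base_A = max(4L, as.integer(ceiling(120 * scale))),
              n_base_B = max(4L, as.integer(ceiling(80 * scale))),
              progeny_per_dam = progeny_per_dam,
              progeny_per_sire = progeny_per_sire)
}

# sire/dam pools per genotype class; BASE_A / BASE_B are the founders,
# other labels refer to previously generated classes
class_recipes <- function() {
  list(
    "ANGUS"          = list(s = "BASE_A", d = "BASE_A"),
    "HEREFORD"       = list(s = "BASE_B", d = "BASE_B"),
    "F1(HxA)"        = list(s = "BASE_B", d = "BASE_A"),
    "F1(AxH)"        = list(s = "BASE_A", d = "BASE_B"),
    "F2(HAxHA)"      = list(s = "F1(HxA)", d = "F1(HxA)"),
    "F2(AHxAH)"      = list(s = "F1(AxH)", d = "F1(AxH)"),
    "F3(F2xF2)"      = list(s = c("F2(HAxHA)", "F2(AHxAH)"),
                            d = c("F2(HAxHA)", "F2(AHxAH)")),
    "F4(F3xF3)"      = list(s = "F3(F2xF2)", d = "F3(F2xF2)"),
    "B1(AxHA)"       = list(s = "BASE_A", d = "F1(HxA)"),
    "B1(AxAH)"       = list(s = "BASE_A", d = "F1(AxH)"),
    "B1(HxHA)"       = list(s = "BASE_B", d = "F1(HxA)"),
    "B1(HxAH)"       = list(s = "BASE_B", d = "F1(AxH)"),
    "B1(AHxA)"       = list(s = "F1(AxH)", d = "BASE_A"),
    "B1(HAxH)"       = list(s = "F1(HxA)", d = "BASE_B"),
    "R3[AxB1(HxHA)]" = list(s = "BASE_A", d = "B1(HxHA)"),
    "R3[AxB1(HxAH)]" = list(s = "BASE_A", d = "B1(HxAH)"),
    "R3[HxB1(AxHA)]" = list(s = "BASE_B", d = "B1(AxHA)"),
    "R3[HxB1(AHxA)]" = list(s = "BASE_B", d = "B1(AHxA)"),
    "R4(AxR3)"       = list(s = "BASE_A", d = c("R3[HxB1(AxHA)]",
                                                "R3[HxB1(AHxA)]")),
    "R4(HxR3)"       = list(s = "BASE_B", d = c("R3[AxB1(HxHA)]",
                                                "R3[AxB1(HxAH)]")),
    "F3xF1(HA)"      = list(s = "F3(F2xF2)", d = "F1(HxA)"),
    "F3xF1(AH)"      = list(s = "F3(F2xF2)", d = "F1(AxH)"),
    "F3xF4"          = list(s = "F3(F2xF2)", d = "F4(F3xF3)"),
    "AxR4"           = list(s = "BASE_A", d = "R4(HxR3)"),
    "HxR4"           = list(s = "BASE_B", d = "R4(AxR3)")
  )
}

#' Simulate a crossbred pedigree
#'
#' Generates a pedigree realizing a [mating_plan()]: purebred base animals
#' of both breeds, then each genotype class in dependency order, drawing
#' sires from a small rotating pool of males of the sire class (polygyny)
#' and dams by cycling through the females of the dam class (so dams
#' accumulate several progeny across classes). Every animal carries its
#' genotype-class label and sex.
#'
#' @param plan An `mb_plan`.
#' @return An `mb_pedigree` with extra columns `genotype` and `sex`.
#' @export
simulate_pedigree <- function(plan) {
  stopifnot(inherits(plan, "mb_plan"))
  recipes <- class_recipes()
  classes <- plan$classes[order(match(plan$classes$genotype,
                                      names(recipes))), ]

  base <- tibble(
    animal = c(sprintf("A%03d", seq_len(plan$n_base_A)),
               sprintf("B%03d", seq_len(plan$n_base_B))),
    sire = NA_character_, dam = NA_character_,
    f_A = rep(c(1, 0), c(plan$n_base_A, plan$n_base_B)),
    genotype = rep(c("BASE_A", "BASE_B"), c(plan$n_base_A, plan$n_base_B)),
    sex = c(rep_len(c("M", "F"), plan$n_base_A),
            rep_len(c("M", "F"), plan$n_base_B)))

  rows <- list(base)
  pool <- function(cls, sex) {
    df <- dplyr::bind_rows(rows)
    df$animal[df$genotype %in% cls & df$sex == sex]
  }
  counter <- 0L
  for (ci in seq_len(nrow(classes))) {
    gt <- classes$genotype[ci]
    n <- classes$n[ci]
    if (n == 0) next
    rec <- recipes[[gt]]
    sires <- pool(rec$s, "M")
    dams <- pool(rec$d, "F")
    if (length(sires) == 0 || length(dams) == 0) {
      stop_mb(paste0("no available parents for class ", gt,
                     " (plan references more parents than generated)"),
              "mb_plan_error")
    }
    n_sires <- max(1L, min(length(sires),
                           ceiling(n / plan$progeny_per_sire)))
    n_dams <- max(1L, min(length(dams), ceiling(n / plan$progeny_per_dam)))
    sires <- sires[seq_len(n_sires)]
    dams <- dams[seq_len(n_dams)]
    s <- sires[((seq_len(n) - 1L) %% n_sires) + 1L]
    d <- dams[((seq_len(n) - 1L) %% n_dams) + 1L]
    clash <- s == d
    if (any(clash)) d[clash] <- dams[(match(d[clash], dams) %% n_dams) + 1L]
    rows <- c(rows, list(tibble(
      animal = sprintf("X%05d", counter + seq_len(n)),
      sire = s, dam = d, f_A = NA_real_, genotype = gt,
      sex = rep_len(c("F", "M"), n))))
    counter <- counter + n
  }
  as_pedigree(dplyr::bind_rows(rows))
}

#' Simulate breeding values by source of variability
#'
#' Sequential generation in pedigree order: for each source, a
#' contributor's (direct, maternal) pair is the mean of its contributing
#' parents' pairs plus a bivariate normal Mendelian deviation with
#' covariance `d_X(i) * G0X`; non-contributors get exact zeros. The
#' resulting covariance across animals is `G0X (x) A*X`.
#'
#' @param ped An `mb_pedigree`.
#' @param vc An `mb_varcomp` (true components).
#' @return A tibble with columns `animal`, `code`, per-source pairs
#'   (`a_Ao`, `a_Am`, `a_Bo`, `a_Bm`, `a_So`, `a_Sm`) and totals
#'   (`direct`, `maternal`).
#' @export
simulate_breeding_values <- function(ped, vc) {
  check_pedigree(ped)
  vc <- as_varcomp(vc)
  q <- nrow(ped)
  out <- tibble(animal = ped$animal, code = ped$code)
  direct <- numeric(q)
  maternal <- numeric(q)
  for (src in mb_sources()) {
    md <- mendelian_variances(ped, src)
    G0 <- vc[[paste0("G0", src)]]
    U <- chol(G0)
    a <- matrix(0, q, 2)
    for (i in seq_len(q)) {
      if (!md$contributor[i]) next
      s <- ped$sire_code[i]
      d <- ped$dam_code[i]
      pa <- (if (s > 0) a[s, ] else c(0, 0)) +
        (if (d > 0) a[d, ] else c(0, 0))
      a[i, ] <- pa / 2 + sqrt(md$d[i]) * as.numeric(crossprod(U, rnorm(2)))
    }
    out[[paste0("a_", src, "o")]] <- a[, 1]
    out[[paste0("a_", src, "m")]] <- a[, 2]
    direct <- direct + a[, 1]
    maternal <- maternal + a[, 2]
  }
  out$direct <- direct
  out$maternal <- maternal
  out
}

#' True fixed-effect values for the simulator
#'
#' @param mu Baseline mean (kg).
#' @param sex_M Additive effect of male sex.
#' @param age_of_dam Named effects for dam-age classes 3, 4, 5 relative to
#'   class 2.
#' @param day_slope Slope on day of birth (kg/day).
#' @param direct_breed,maternal_breed Breed-A substitution effects.
#' @param direct_heterosis,maternal_heterosis Heterosis effects (kg).
#' @return A list of class `mb_fixed_truth`.
#' @export
fixed_effect_truth <- function(mu = 150, sex_M = 6,
                               age_of_dam = c("3" = 4, "4" = 7, "5" = 8),
                               day_slope = 0.15,
                               direct_breed = 5, maternal_breed = 3,
                               direct_heterosis = 8, maternal_heterosis = 4) {
  structure(list(mu = mu, sex_M = sex_M, age_of_dam = age_of_dam,
                 day_slope = day_slope, direct_breed = direct_breed,
                 maternal_breed = maternal_breed,
                 direct_heterosis = direct_heterosis,
                 maternal_heterosis = maternal_heterosis),
            class = "mb_fixed_truth")
}

#' Simulate maternally influenced phenotypes
#'
#' One weaning-weight record per non-base animal:
#' `y = fixed + direct BV(animal) + maternal BV(dam) + e_p(dam) + e`, with
#' one permanent-environment deviate per dam shared by all her progeny.
#' Fixed effects comprise sex, dam-age class, day-of-birth covariate and
#' the breed/heterosis regressors.
#'
#' @param ped An `mb_pedigree` from [simulate_pedigree()] (needs `sex`).
#' @param bv Breeding values from [simulate_breeding_values()].
#' @param vc An `mb_varcomp` (for `sigma2_pe`, `sigma2_e`).
#' @param fixed_truth An [fixed_effect_truth()] list.
#' @return A records tibble with columns `animal`, `sex`, `age_of_dam`,
#'   `day_of_birth`, `weight` (plus `genotype`), ready for
#'   [build_design()].
#' @export
simulate_phenotypes <- function(ped, bv, vc,
                                fixed_truth = fixed_effect_truth()) {
  check_pedigree(ped)
  vc <- as_varcomp(vc)
  ft <- fixed_truth
  rec_idx <- which(ped$dam_code > 0)
  n <- length(rec_idx)
  dam_code <- ped$dam_code[rec_idx]
  dams <- sort(unique(dam_code))
  ep <- setNames(rnorm(length(dams), 0, sqrt(vc$sigma2_pe)), dams)

  sex <- if ("sex" %in% names(ped)) ped$sex[rec_idx] else
    rep_len(c("F", "M"), n)
  age <- sample(names(c("2" = 0, ft$age_of_dam)), n, replace = TRUE)
  day <- round(runif(n, 1, 90))
  cc <- cross_covariates(ped)
  xb <- ft$mu + ft$sex_M * (sex == "M") +
    unname(c("2" = 0, ft$age_of_dam)[age]) + ft$day_slope * day +
    ft$direct_breed * cc$direct_breed[rec_idx] +
    ft$maternal_breed * cc$maternal_breed[rec_idx] +
    ft$direct_heterosis * cc$direct_heterosis[rec_idx] +
    ft$maternal_heterosis * cc$maternal_heterosis[rec_idx]
  y <- xb + bv$direct[rec_idx] + bv$maternal[dam_code] +
    ep[as.character(dam_code)] + rnorm(n, 0, sqrt(vc$sigma2_e))
  tibble(animal = ped$animal[rec_idx], sex = sex, age_of_dam = age,
         day_of_birth = day,
         genotype = if ("genotype" %in% names(ped)) ped$genotype[rec_idx]
         else NA_character_,
         weight = as.numeric(y))
}

#' Simulate a complete data set
#'
#' Pedigree, breeding values and phenotypes in one call.
#'
#' @param plan An `mb_plan`.
#' @param vc True (co)variance components; default the published prior
#'   scales ([angus_hereford_priors()] scale matrices).
#' @param fixed_truth An [fixed_effect_truth()] list.
#' @param seed Optional integer seed.
#' @return A list with elements `pedigree`, `records`, `breeding_values`,
#'   `truth` (the `mb_varcomp` used).
#' @export
simulate_dataset <- function(plan = angus_hereford_plan(scale = 0.2),
                             vc = NULL, fixed_truth = fixed_effect_truth(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(vc)) {
    p <- angus_hereford_priors()
    vc <- varcomp(p$G0A, p$G0B, p$G0S, p$s2_pe, p$s2_e)
  }
  vc <- as_varcomp(vc)
  ped <- simulate_pedigree(plan)
  bv <- simulate_breeding_values(ped, vc)
  records <- simulate_phenotypes(ped, bv, vc, fixed_truth)
  list(pedigree = ped, records = records, breeding_values = bv, truth = vc)
}

#' Gene-dropping oracle for the additive covariance decomposition
#'
#' Monte-Carlo check of the partial-relationship-matrix construction that
#' shares no code with it: every base animal receives two allele effects
#' per locus drawn from its breed's allele-effect distribution (breed-A
#' alleles `N(mu_A, v_A)` per locus, breed-B analogous), alleles descend
#' through the pedigree by fair Mendelian transmission, and the genotypic
#' value of an animal is the sum of its `2 * n_loci` allele effects. With
#' per-locus allele variances `v_X = sigma2_X / (2 n_loci)` and a breed
#' mean difference `delta = sqrt(2 sigma2_S / n_loci)` per locus, the
#' implied components are exactly `sigma2_A`, `sigma2_B` and the
#' segregation variance `sigma2_S`, so the empirical covariance of
#' genotypic values estimates
#' `sigma2_A * A_A + sigma2_B * A_B + sigma2_S * A_S`.
#'
#' @param ped A small `mb_pedigree` with purebred base animals.
#' @param sigma2 Named vector `c(A =, B =, S =)` of target variances.
#' @param n_loci Number of unlinked loci (default 100).
#' @param n_rep Number of independent gene-dropping replicates.
#' @param n_batches Replicates are split into this many independent batches
#'   to estimate Monte-Carlo standard errors empirically.
#' @return A list with `cov` (empirical q-by-q covariance matrix), `mean`
#'   (empirical means), `implied` (the implied variance components), and
#'   `se` (empirical Monte-Carlo standard errors of `cov`, from the spread
#'   across batches).
#' @export
gene_drop_oracle <- function(ped, sigma2, n_loci = 100, n_rep = 10000,
                             n_batches = 20) {
  check_pedigree(ped)
  stopifnot(all(c("A", "B", "S") %in% names(sigma2)), all(sigma2 >= 0))
  crossbred_base <- ped$base & ped$f_A > MB_EPS & ped$f_B > MB_EPS
  if (any(crossbred_base)) {
    stop_mb("gene dropping requires purebred base animals",
            "mb_input_error")
  }
  base_breed <- ifelse(ped$base, ifelse(ped$f_A > 0.5, 0L, 1L), -1L)
  delta <- sqrt(2 * sigma2[["S"]] / n_loci)
  mu <- cbind(rep(delta / 2, n_loci), rep(-delta / 2, n_loci))
  vl <- cbind(rep(sigma2[["A"]] / (2 * n_loci), n_loci),
              rep(sigma2[["B"]] / (2 * n_loci), n_loci))
  q <- nrow(ped)
  n_batches <- max(2L, as.integer(n_batches))
  per_batch <- max(3L, as.integer(floor(n_rep / n_batches)))
  covs <- array(NA_real_, c(q, q, n_batches))
  means <- matrix(NA_real_, n_batches, q)
  for (b in seq_len(n_batches)) {
    res <- gene_drop_cpp(ped$sire_code, ped$dam_code, base_breed, mu, vl,
                         per_batch)
    covs[, , b] <- res$cov
    means[b, ] <- res$mean
  }
  G <- apply(covs, 1:2, mean)
  se <- apply(covs, 1:2, sd) / sqrt(n_batches)
  dimnames(G) <- dimnames(se) <- list(ped$animal, ped$animal)
  list(cov = G, mean = setNames(colMeans(means), ped$animal),
       implied = c(A = sigma2[["A"]], B = sigma2[["B"]], S = sigma2[["S"]]),
       se = se)
}
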