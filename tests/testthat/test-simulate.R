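test_that("simulated pedigrees realize the requested mating structure", {
  # only parental matings: everyone stays purebred
  plan <- mating_plan(tibble::tibble(genotype = c("ANGUS", "HEREFORD"),
                                     n = c(20, 15)),
                      n_base_A = 10, n_base_B = 8)
  ped <- simulate_pedigree(plan)
  bf <- breed_fractions(ped)
  expect_true(all(bf$f_A %in% c(0, 1)))
  expect_equal(nrow(contributors(ped, "S")), 0)

  # an F2 plan expresses the full segregation coefficient
  plan2 <- mating_plan(tibble::tibble(
    genotype = c("F1(HxA)", "F2(HAxHA)"), n = c(12, 10)),
    n_base_A = 6, n_base_B = 6)
  ped2 <- simulate_pedigree(plan2)
  f2 <- ped2$genotype == "F2(HAxHA)"
  expect_equal(unique(ped2$f_A[f2]), 0.5)
  expect_equal(unique(segregation_coefficients(ped2)$s[f2]), 1)

  # every class label reproduces the published breed fractions
  ped3 <- simulate_pedigree(angus_hereford_plan(scale = 0.02))
  printed <- angus_hereford_classes()
  for (i in seq_len(nrow(printed))) {
    members <- ped3$genotype == printed$genotype[i]
    expect_true(any(members))
    expect_equal(unique(round_print(ped3$f_A[members])),
                 printed$f_individual[i])
  }
  # dams accumulate several progeny (maternal designs need repeat dams)
  progeny <- table(ped3$dam_code[ped3$dam_code > 0])
  expect_gt(mean(progeny), 1.5)

  # plans referencing parents that were never generated fail loudly
  bad <- mating_plan(tibble::tibble(genotype = "F2(HAxHA)", n = 5),
                     n_base_A = 4, n_base_B = 4)
  expect_error(simulate_pedigree(bad), class = "mb_plan_error")
})

test_that("simulated breeding values carry the requested covariance", {
  vc <- as_varcomp(setNames(c(85, -25, 35, 76, -50, 70, 10, 8, 9, 80, 170),
                            mb_components()))
  # base-animal direct variance matches the breed component
  base <- as_pedigree(data.frame(animal = paste0("b", 1:4000),
                                 sire = NA, dam = NA, f_A = 1))
  set.seed(47)
  bv <- simulate_breeding_values(base, vc)
  expect_equal(var(bv$a_Ao), 85, tolerance = 3 * sqrt(2 / 4000) * 1.2)
  expect_equal(cov(bv$a_Ao, bv$a_Am), -25, tolerance = 5)
  expect_equal(max(abs(bv$a_So)), 0)  # purebreds carry no segregation term

  # F1s of purebreds have exactly zero segregation values
  ped <- f2_pedigree()
  bv1 <- simulate_breeding_values(ped, vc)
  expect_equal(bv1$a_So[bv1$animal %in% c("f1a", "f1b")], c(0, 0))

  # across a small pedigree the empirical covariance matches G0X (x) A*X
  set.seed(49)
  R <- 3000
  a_o <- matrix(NA_real_, R, nrow(ped))
  a_m <- matrix(NA_real_, R, nrow(ped))
  for (r in seq_len(R)) {
    b <- simulate_breeding_values(ped, vc)
    a_o[r, ] <- b$a_So
    a_m[r, ] <- b$a_Sm
  }
  AS <- partial_nrm_tabular(ped, "S")
  se <- function(target) sqrt((10 * 9 + 8^2) / R) * 3  # crude 3 SE bound
  expect_lt(max(abs(cov(a_o) - vc$G0S[1, 1] * AS)), se())
  expect_lt(max(abs(cov(a_o, a_m) - vc$G0S[1, 2] * AS)), se())
})

test_that("phenotypes assemble the maternal model", {
  vc <- as_varcomp(setNames(c(85, -25, 35, 76, -50, 70, 10, 8, 9, 80, 170),
                            mb_components()))
  set.seed(53)
  ped <- simulate_pedigree(angus_hereford_plan(scale = 0.03))
  # all variances tiny: the phenotype is the fixed part exactly
  tiny <- as_varcomp(setNames(c(1e-10, 0, 1e-10, 1e-10, 0, 1e-10,
                                1e-10, 0, 1e-10, 1e-10, 1e-10),
                              mb_components()))
  bv0 <- simulate_breeding_values(ped, tiny)
  rec0 <- simulate_phenotypes(ped, bv0, tiny)
  ft <- fixed_effect_truth()
  cc <- cross_covariates(ped)
  i <- match(rec0$animal, ped$animal)
  fixed_part <- ft$mu + ft$sex_M * (rec0$sex == "M") +
    unname(c("2" = 0, ft$age_of_dam)[rec0$age_of_dam]) +
    ft$day_slope * rec0$day_of_birth +
    ft$direct_breed * cc$direct_breed[i] +
    ft$maternal_breed * cc$maternal_breed[i] +
    ft$direct_heterosis * cc$direct_heterosis[i] +
    ft$maternal_heterosis * cc$maternal_heterosis[i]
  expect_equal(rec0$weight, fixed_part, tolerance = 1e-3)

  # residual variance appears at the stated magnitude
  set.seed(55)
  novar <- as_varcomp(setNames(c(1e-10, 0, 1e-10, 1e-10, 0, 1e-10,
                                 1e-10, 0, 1e-10, 1e-10, 170),
                               mb_components()))
  ped2 <- simulate_pedigree(angus_hereford_plan(scale = 0.25))
  bv2 <- simulate_breeding_values(ped2, novar)
  rec2 <- simulate_phenotypes(ped2, bv2, novar)
  resid <- rec2$weight - (fixed_effect_truth()$mu +
    fixed_effect_truth()$sex_M * (rec2$sex == "M") +
    unname(c("2" = 0, fixed_effect_truth()$age_of_dam)[rec2$age_of_dam]) +
    fixed_effect_truth()$day_slope * rec2$day_of_birth +
    5 * cross_covariates(ped2)$direct_breed[match(rec2$animal,
                                                  ped2$animal)] +
    3 * cross_covariates(ped2)$maternal_breed[match(rec2$animal,
                                                    ped2$animal)] +
    8 * cross_covariates(ped2)$direct_heterosis[match(rec2$animal,
                                                      ped2$animal)] +
    4 * cross_covariates(ped2)$maternal_heterosis[match(rec2$animal,
                                                        ped2$animal)])
  expect_equal(var(resid), 170, tolerance = 170 * 4 * sqrt(2 / length(resid)))
})

test_that("gene dropping recovers classical relationship results", {
  sg <- c(A = 100, B = 64, S = 16)
  # purebred parent-offspring covariance is half the additive variance
  po <- as_pedigree(data.frame(animal = c("p", "m", "o"),
                               sire = c(NA, NA, "p"), dam = c(NA, NA, "m"),
                               f_A = c(1, 1, NA)))
  set.seed(59)
  gd <- gene_drop_oracle(po, sg, n_loci = 50, n_rep = 1e5)
  expect_equal(gd$cov["p", "o"], 50, tolerance = 3 * gd$se["p", "o"])
  expect_equal(gd$cov["o", "o"], 100, tolerance = 3 * gd$se["o", "o"])

  # the F2 variance carries half of each breed variance plus the full
  # segregation variance
  ped <- f2_pedigree()
  set.seed(61)
  gd2 <- gene_drop_oracle(ped, sg, n_loci = 50, n_rep = 1e5)
  expect_equal(gd2$cov["f2", "f2"], 0.5 * 100 + 0.5 * 64 + 16,
               tolerance = 3 * gd2$se["f2", "f2"])
  # and the whole matrix agrees with the assembled decomposition
  G <- assemble_total_g(ped, sg)
  expect_lt(max(abs(gd2$cov - G) / gd2$se), 3.5)
  # crossbred base animals are refused
  xb <- as_pedigree(data.frame(animal = "z", sire = NA, dam = NA,
                               f_A = 0.5))
  expect_error(gene_drop_oracle(xb, sg), class = "mb_input_error")
})

test_that("fixture files round-trip through the readers", {
  ds <- small_dataset(scale = 0.02, seed = 67)
  dir <- withr::local_tempdir()
  files <- write_dataset(ds, dir)
  ped <- read_pedigree(files[["pedigree"]])
  expect_equal(nrow(ped), nrow(ds$pedigree))
  expect_equal(sort(ped$animal), sort(ds$pedigree$animal))
  expect_equal(breed_fractions(ped), breed_fractions(ds$pedigree))
  rec <- readr::read_csv(files[["records"]], show_col_types = FALSE)
  expect_equal(nrow(rec), nrow(ds$records))
  truth <- readr::read_csv(files[["truth"]], show_col_types = FALSE)
  expect_equal(as_varcomp(setNames(truth$value, truth$component)),
               ds$truth)

  cfg <- list(paths = list(pedigree = files[["pedigree"]],
                           data = files[["records"]], output = dir),
              fixed = "weight ~ sex + age_of_dam + day_of_birth",
              priors = mb_priors(), control = mb_chain_control(seed = 2),
              groups = list(F2 = f2_group()))
  cfg_path <- file.path(dir, "run.yaml")
  write_run_config(cfg, cfg_path)
  cfg2 <- read_run_config(cfg_path)
  expect_equal(cfg2$priors, cfg$priors)
  expect_equal(cfg2$control, cfg$control)
  expect_equal(unclass(cfg2$groups$F2), unclass(cfg$groups$F2),
               ignore_attr = TRUE)
})
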