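#' Published posterior summaries for the Angus x Hereford weaning-weight
#' analysis
#'
#' Reference values from the published hierarchical Bayes analysis of the
#' Angus x Hereford crossbred weaning-weight experiment: prior degrees of
#' belief `nu` and prior scale `S0` together with the marginal posterior
#' mean, standard deviation, median, kernel-density mode and 95% HPD bounds
#' of each of the eleven (co)variance components (kg^2; covariances in kg^2
#' as well). Breed A is Angus, breed B is Hereford. These are shipped as
#' reference data for plug-in derived-parameter arithmetic and for setting
#' priors; the package does not recompute them (the underlying records are
#' proprietary).
#'
#' @return A tibble with columns `component`, `nu`, `S0`, `mean`, `sd`,
#'   `median`, `mode`, `lower`, `upper`.
#' @export
angus_hereford_summaries <- function() {
  tibble(
    component = mb_components(),
    nu     = c(20, 20, 20, 20, 20, 20, 5, 5, 5, 100, 100),
    S0     = c(85, -25, 35, 76, -50, 70, 10, 8, 9, 80, 170),
    mean   = c(120.74, -27.00, 37.63, 100.24, -56.31, 95.18,
               9.62, 9.55, 13.37, 95.53, 187.34),
    sd     = c(20.43, 13.26, 11.35, 20.12, 19.64, 24.61,
               6.24, 7.01, 12.55, 9.91, 10.21),
    median = c(119.54, -26.11, 35.94, 98.86, -55.12, 92.96,
               8.10, 7.82, 9.48, 95.24, 187.35),
    mode   = c(115.82, -23.89, 32.35, 98.42, -56.55, 88.29,
               3.68, 3.20, 3.65, 98.75, 187.09),
    lower  = c(82.22, -53.70, 18.25, 62.38, -95.65, 50.29,
               1.28, 0.36, 1.03, 76.47, 167.17),
    upper  = c(161.46, -2.15, 60.38, 140.33, -19.13, 144.21,
               21.96, 24.18, 37.93, 115.17, 207.22)
  )
}

#' Published posterior means as a variance-component set
#'
#' @return An `mb_varcomp` holding the eleven posterior means from
#'   [angus_hereford_summaries()].
#' @export
angus_hereford_posterior_means <- function() {
  s <- angus_hereford_summaries()
  as_varcomp(setNames(s$mean, s$component))
}

#' Priors used in the published Angus x Hereford analysis
#'
#' Builds an [mb_priors()] specification from the prior scale and
#' degrees-of-belief columns of [angus_hereford_summaries()].
#'
#' @return An `mb_priors` object.
#' @export
angus_hereford_priors <- function() {
  s <- angus_hereford_summaries()
  v <- setNames(s$S0, s$component)
  nu <- setNames(s$nu, s$component)
  g0 <- function(o, om, m) matrix(c(v[[o]], v[[om]], v[[om]], v[[m]]), 2, 2)
  mb_priors(
    G0A = g0("sigma2_Ao", "sigma_AoAm", "sigma2_Am"), nu_A = nu[["sigma2_Ao"]],
    G0B = g0("sigma2_Bo", "sigma_BoBm", "sigma2_Bm"), nu_B = nu[["sigma2_Bo"]],
    G0S = g0("sigma2_So", "sigma_SoSm", "sigma2_Sm"), nu_S = nu[["sigma2_So"]],
    s2_pe = v[["sigma2_pe"]], nu_pe = nu[["sigma2_pe"]],
    s2_e = v[["sigma2_e"]], nu_e = nu[["sigma2_e"]]
  )
}

#' Genotype classes of the Angus x Hereford mating design
#'
#' The 25 genotype classes of the crossbred experiment (parental, inter-se
#' F1-F4, backcrosses, rotational R3/R4, advanced crosses) with their record
#' counts and the published expected breed-A gene fractions of the
#' individual, its sire and its dam, rounded to two decimals.
#'
#' @return A tibble with columns `mating_type`, `genotype`, `n`,
#'   `f_individual`, `f_sire`, `f_dam`.
#' @export
angus_hereford_classes <- function() {
  tibble::tribble(
    ~mating_type, ~genotype,            ~n,  ~f_individual, ~f_sire, ~f_dam,
    "Parental",   "ANGUS",              711L, 1.00, 1.00, 1.00,
    "Parental",   "HEREFORD",           431L, 0.00, 0.00, 0.00,
    "Inter-se",   "F1(HxA)",            393L, 0.50, 0.00, 1.00,
    "Inter-se",   "F1(AxH)",            301L, 0.50, 1.00, 0.00,
    "Inter-se",   "F2(HAxHA)",          235L, 0.50, 0.50, 0.50,
    "Inter-se",   "F2(AHxAH)",          183L, 0.50, 0.50, 0.50,
    "Inter-se",   "F3(F2xF2)",          254L, 0.50, 0.50, 0.50,
    "Inter-se",   "F4(F3xF3)",          104L, 0.50, 0.50, 0.50,
    "Back-cross", "B1(AxHA)",            78L, 0.75, 1.00, 0.50,
    "Back-cross", "B1(AxAH)",            72L, 0.75, 1.00, 0.50,
    "Back-cross", "B1(HxHA)",            77L, 0.25, 0.00, 0.50,
    "Back-cross", "B1(HxAH)",            67L, 0.25, 0.00, 0.50,
    "Back-cross", "B1(AHxA)",           180L, 0.75, 0.50, 1.00,
    "Back-cross", "B1(HAxH)",           132L, 0.25, 0.50, 0.00,
    "Rotational", "R3[AxB1(HxHA)]",      77L, 0.63, 1.00, 0.25,
    "Rotational", "R3[AxB1(HxAH)]",      51L, 0.63, 1.00, 0.25,
    "Rotational", "R3[HxB1(AxHA)]",      96L, 0.38, 0.00, 0.75,
    "Rotational", "R3[HxB1(AHxA)]",      51L, 0.38, 0.00, 0.75,
    "Rotational", "R4(AxR3)",            67L, 0.69, 1.00, 0.38,
    "Rotational", "R4(HxR3)",            68L, 0.31, 0.00, 0.63,
    "Advanced",   "F3xF1(HA)",           19L, 0.50, 0.50, 0.50,
    "Advanced",   "F3xF1(AH)",           27L, 0.50, 0.50, 0.50,
    "Advanced",   "F3xF4",               30L, 0.50, 0.50, 0.50,
    "Advanced",   "AxR4",                21L, 0.66, 1.00, 0.31,
    "Advanced",   "HxR4",                24L, 0.34, 0.00, 0.69
  )
}

#' Pedigree of genotype-class representatives
#'
#' Builds a small pedigree containing one representative individual for each
#' of the 25 genotype classes of [angus_hereford_classes()], chained through
#' the required intermediate crosses (F1s of both directions, F2-F4,
#' backcrosses, rotational generations). Breed fractions of every class then
#' follow from the parent-average recursion alone.
#'
#' @return A list with elements `pedigree` (an `mb_pedigree`) and `classes`
#'   (a tibble mapping `genotype` to the representative `animal` id).
#' @export
genotype_class_pedigree <- function() {
  rows <- list(
    c("A.1", NA, NA), c("A.2", NA, NA), c("H.1", NA, NA), c("H.2", NA, NA),
    c("A", "A.1", "A.2"),
    c("H", "H.1", "H.2"),
    c("F1HA.s", "H.1", "A.2"), c("F1HA.d", "H.1", "A.2"),
    c("F1AH.s", "A.1", "H.2"), c("F1AH.d", "A.1", "H.2"),
    c("F2HA.s", "F1HA.s", "F1HA.d"), c("F2HA.d", "F1HA.s", "F1HA.d"),
    c("F2AH", "F1AH.s", "F1AH.d"),
    c("F3.s", "F2HA.s", "F2HA.d"), c("F3.d", "F2HA.s", "F2HA.d"),
    c("F4", "F3.s", "F3.d"),
    c("B1.AxHA", "A.1", "F1HA.d"),
    c("B1.AxAH", "A.1", "F1AH.d"),
    c("B1.HxHA", "H.1", "F1HA.d"),
    c("B1.HxAH", "H.1", "F1AH.d"),
    c("B1.AHxA", "F1AH.s", "A.2"),
    c("B1.HAxH", "F1HA.s", "H.2"),
    c("R3.A.HxHA", "A.1", "B1.HxHA"),
    c("R3.A.HxAH", "A.1", "B1.HxAH"),
    c("R3.H.AxHA", "H.1", "B1.AxHA"),
    c("R3.H.AHxA", "H.1", "B1.AHxA"),
    c("R4.AxR3", "A.1", "R3.H.AxHA"),
    c("R4.HxR3", "H.1", "R3.A.HxHA"),
    c("ADV.F3xF1HA", "F3.s", "F1HA.d"),
    c("ADV.F3xF1AH", "F3.s", "F1AH.d"),
    c("ADV.F3xF4", "F3.s", "F4"),
    c("ADV.AxR4", "A.1", "R4.HxR3"),
    c("ADV.HxR4", "H.1", "R4.AxR3")
  )
  df <- tibble(animal = vapply(rows, `[`, "", 1),
               sire = vapply(rows, `[`, "", 2),
               dam = vapply(rows, `[`, "", 3))
  df$f_A <- ifelse(is.na(df$sire) & grepl("^A", df$animal), 1,
                   ifelse(is.na(df$sire), 0, NA_real_))
  ped <- as_pedigree(df)
  classes <- tibble(
    genotype = angus_hereford_classes()$genotype,
    animal = c("A", "H", "F1HA.s", "F1AH.s", "F2HA.s", "F2AH", "F3.s", "F4",
               "B1.AxHA", "B1.AxAH", "B1.HxHA", "B1.HxAH", "B1.AHxA",
               "B1.HAxH", "R3.A.HxHA", "R3.A.HxAH", "R3.H.AxHA", "R3.H.AHxA",
               "R4.AxR3", "R4.HxR3", "ADV.F3xF1HA", "ADV.F3xF1AH",
               "ADV.F3xF4", "ADV.AxR4", "ADV.HxR4")
  )
  list(pedigree = ped, classes = classes)
}
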