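#' Reference breed group
#'
#' Weights defining the breed group in which variance partitions and
#' genetic parameters are expressed: breed weights `w_A`, `w_B` applied to
#' the per-breed (co)variances and `w_S` applied to the segregation
#' (co)variances. The F2 group (the package default) has weights
#' `(0.5, 0.5, 1)`: half of each breed's additive variance plus the full
#' segregation variance.
#'
#' @param w_A,w_B Non-negative breed weights summing to 1.
#' @param w_S Non-negative segregation weight.
#' @return A named numeric vector of class `mb_ref_group`.
#' @export
reference_group <- function(w_A, w_B, w_S) {
  if (w_A < 0 || w_B < 0 || w_S < 0 || abs(w_A + w_B - 1) > 1e-9) {
    stop_mb("breed weights must be non-negative with w_A + w_B = 1",
            "mb_input_error")
  }
  structure(c(w_A = w_A, w_B = w_B, w_S = w_S), class = "mb_ref_group")
}

#' @rdname reference_group
#' @export
f2_group <- function() reference_group(0.5, 0.5, 1)

#' Source-wise partition of the additive variance in a reference group
#'
#' Total direct additive variance `V_o = w_A * sigma2_Ao + w_B * sigma2_Bo
#' + w_S * sigma2_So` (and analogously for the maternal variance and the
#' direct-maternal covariance), with the percentage contribution of each
#' source.
#'
#' @param vc An `mb_varcomp` or named component vector.
#' @param group An [reference_group()]; default F2.
#' @return A tibble with columns `trait` (`"direct"`, `"maternal"`,
#'   `"covariance"`), `source`, `weight`, `component`, `value` and
#'   `percent` (percent of the trait total; percentages per trait sum
#'   to 100).
#' @export
variance_partition <- function(vc, group = f2_group()) {
  v <- vc_vector(vc)
  w <- unclass(group)[c("w_A", "w_B", "w_S")]
  out <- tidyr::expand_grid(trait = c("direct", "maternal", "covariance"),
                            source = c("A", "B", "S"))
  comp <- c(direct = "o", maternal = "m")
  out$component <- ifelse(
    out$trait == "covariance",
    paste0("sigma_", out$source, "o", out$source, "m"),
    paste0("sigma2_", out$source, comp[out$trait]))
  out$weight <- rep(unname(w), 3)
  out$value <- out$weight * unname(v[out$component])
  out <- dplyr::group_by(out, .data$trait)
  out <- dplyr::mutate(out, percent = 100 * .data$value /
                         sum(.data$value))
  out <- dplyr::ungroup(out)
  totals <- dplyr::summarise(dplyr::group_by(out, .data$trait),
                             total = sum(.data$value))
  if (any(totals$total[totals$trait != "covariance"] <= 0)) {
    stop_mb("total additive variance is not positive in this group",
            "mb_input_error")
  }
  out
}

#' Genetic parameters for a reference breed group
#'
#' Heritabilities and the direct-maternal genetic correlation implied by a
#' set of (co)variance components in a reference breed group: the
#' phenotypic variance is assembled as
#' `V_P = V_o + V_m + C_om + sigma2_pe + sigma2_e` (the direct-maternal
#' covariance enters once), and `h2_direct = V_o / V_P`,
#' `h2_maternal = V_m / V_P`, `r_om = C_om / sqrt(V_o * V_m)`.
#'
#' @param vc An `mb_varcomp` or named component vector.
#' @param group An [reference_group()]; default F2.
#' @param include_environment If `FALSE`, `V_P` omits the
#'   permanent-environment and residual variances (genetic-only
#'   denominator; not the published definition).
#' @return A one-row tibble with columns `V_o`, `V_m`, `C_om`, `V_P`,
#'   `h2_direct`, `h2_maternal`, `r_om`.
#' @export
genetic_parameters <- function(vc, group = f2_group(),
                               include_environment = TRUE) {
  v <- vc_vector(vc)
  w <- unclass(group)
  V_o <- w[["w_A"]] * v[["sigma2_Ao"]] + w[["w_B"]] * v[["sigma2_Bo"]] +
    w[["w_S"]] * v[["sigma2_So"]]
  V_m <- w[["w_A"]] * v[["sigma2_Am"]] + w[["w_B"]] * v[["sigma2_Bm"]] +
    w[["w_S"]] * v[["sigma2_Sm"]]
  C_om <- w[["w_A"]] * v[["sigma_AoAm"]] + w[["w_B"]] * v[["sigma_BoBm"]] +
    w[["w_S"]] * v[["sigma_SoSm"]]
  V_P <- V_o + V_m + C_om +
    if (include_environment) v[["sigma2_pe"]] + v[["sigma2_e"]] else 0
  if (V_o * V_m <= 0) {
    stop_mb("direct-maternal correlation undefined: V_o * V_m <= 0",
            "mb_input_error")
  }
  tibble(V_o = V_o, V_m = V_m, C_om = C_om, V_P = V_P,
         h2_direct = V_o / V_P, h2_maternal = V_m / V_P,
         r_om = C_om / sqrt(V_o * V_m))
}

# draws as a plain numeric data frame
chain_draws <- function(x) {
  if (inherits(x, "mb_chain")) return(x$samples[mb_components()])
  x <- as_tibble(x)
  x[vapply(x, is.numeric, TRUE) & names(x) != "iteration"]
}

#' Posterior summaries of a chain
#'
#' Sample mean, standard deviation and median; the mode of a Gaussian
#' kernel density estimate (Silverman bandwidth, 512-point grid); the 95%
#' highest-posterior-density interval (shortest window over the sorted
#' samples); and the effective sample size (initial-positive-sequence
#' estimator).
#'
#' @param x An `mb_chain`, or a data frame of draws (one column per
#'   quantity).
#' @param prob HPD mass, default 0.95.
#' @param min_samples Minimum number of draws required (default 100).
#' @return A tibble with columns `component`, `mean`, `sd`, `median`,
#'   `mode`, `lower`, `upper`, `ess`, `n`.
#' @export
summarize_chain <- function(x, prob = 0.95, min_samples = 100) {
  draws <- chain_draws(x)
  n <- nrow(draws)
  if (n < min_samples) {
    stop_mb(paste0("need at least ", min_samples, " draws, got ", n),
            "mb_input_error")
  }
  purrr::map_dfr(names(draws), function(nm) {
    v <- draws[[nm]]
    h <- hpd_interval(v, prob)
    tibble(component = nm, mean = mean(v), sd = sd(v), median = median(v),
           mode = kde_mode(v), lower = h[1], upper = h[2],
           ess = ess_ips(v), n = n)
  })
}

#' Highest-posterior-density interval
#'
#' Shortest interval containing `prob` of the sorted samples.
#'
#' @param x Numeric draws.
#' @param prob Probability mass (default 0.95).
#' @return Length-2 numeric vector `(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- ceiling(prob * n)
  if (k >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - k + 1)
  widths <- x[starts + k - 1] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}

#' Kernel-density mode
#'
#' Argmax of a Gaussian-kernel density estimate (Silverman's rule-of-thumb
#' bandwidth) on a 512-point grid.
#'
#' @param x Numeric draws.
#' @return The grid point of maximum estimated density.
#' @export
kde_mode <- function(x) {
  if (sd(x) == 0) return(x[1])
  d <- density(x, bw = "nrd0", n = 512)
  d$x[which.max(d$y)]
}

#' Effective sample size (initial positive sequence)
#'
#' Sums autocorrelations over pairs of consecutive lags until a pair sum
#' turns negative (Geyer's initial positive sequence), then returns
#' `n / (2 * sum(pair sums) - 1)`. For a constant chain, returns `NA`.
#'
#' @param x Numeric draws.
#' @return Estimated effective sample size.
#' @export
ess_ips <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(NA_real_)
  lag_max <- min(n - 1, max(100, floor(n / 4)))
  rho <- as.numeric(acf(x, lag.max = lag_max, plot = FALSE,
                        demean = TRUE)$acf)
  tau <- 0
  m <- 0
  repeat {
    i1 <- 2 * m + 1
    i2 <- 2 * m + 2
    if (i2 > length(rho)) break
    g <- rho[i1] + rho[i2]
    if (g <= 0) break
    tau <- tau + g
    m <- m + 1
  }
  tau <- max(2 * tau - 1, 1)
  min(n / tau, n)
}

#' Chain diagnostics
#'
#' Per component: effective sample size, lag-1 autocorrelation, a
#' first-half/second-half posterior-mean z-score (standard errors scaled by
#' the effective sample size of each half), a degeneracy flag, and the
#' autocorrelation function as a nested tibble.
#'
#' @param x An `mb_chain` or data frame of draws.
#' @param lag_max Maximum ACF lag (default 50).
#' @return A tibble with columns `component`, `ess`, `rho1`, `z_halves`,
#'   `degenerate`, `acf` (list of tibbles `lag`, `rho`).
#' @export
chain_diagnostics <- function(x, lag_max = 50) {
  draws <- chain_draws(x)
  n <- nrow(draws)
  purrr::map_dfr(names(draws), function(nm) {
    v <- draws[[nm]]
    degenerate <- sd(v) == 0
    if (degenerate) {
      return(tibble(component = nm, ess = NA_real_, rho1 = NA_real_,
                    z_halves = NA_real_, degenerate = TRUE,
                    acf = list(tibble(lag = integer(0),
                                      rho = numeric(0)))))
    }
    lm <- min(lag_max, n - 1)
    rho <- as.numeric(acf(v, lag.max = lm, plot = FALSE)$acf)[-1]
    h1 <- v[seq_len(floor(n / 2))]
    h2 <- v[(floor(n / 2) + 1):n]
    se2 <- var(h1) / max(ess_ips(h1), 1) + var(h2) / max(ess_ips(h2), 1)
    tibble(component = nm, ess = ess_ips(v), rho1 = rho[1],
           z_halves = (mean(h1) - mean(h2)) / sqrt(se2),
           degenerate = FALSE,
           acf = list(tibble(lag = seq_len(lm), rho = rho)))
  })
}

#' Posterior distribution of derived genetic parameters
#'
#' Applies [genetic_parameters()] to every saved draw of a chain and
#' summarizes the derived quantities. The plug-in values at the posterior
#' means of the components are reported alongside (ratios of means and
#' means of ratios differ; both are of interest).
#'
#' @param x An `mb_chain` or data frame of component draws.
#' @param group An [reference_group()]; default F2.
#' @return A tibble of posterior summaries for `V_o`, `V_m`, `C_om`, `V_P`,
#'   `h2_direct`, `h2_maternal`, `r_om`, with the per-draw values in
#'   attribute `draws` and the plug-in values (derived parameters at the
#'   posterior-mean components) in attribute `plugin`.
#' @export
posterior_parameters <- function(x, group = f2_group()) {
  draws <- chain_draws(x)
  w <- unclass(group)
  V_o <- w[["w_A"]] * draws$sigma2_Ao + w[["w_B"]] * draws$sigma2_Bo +
    w[["w_S"]] * draws$sigma2_So
  V_m <- w[["w_A"]] * draws$sigma2_Am + w[["w_B"]] * draws$sigma2_Bm +
    w[["w_S"]] * draws$sigma2_Sm
  C_om <- w[["w_A"]] * draws$sigma_AoAm + w[["w_B"]] * draws$sigma_BoBm +
    w[["w_S"]] * draws$sigma_SoSm
  V_P <- V_o + V_m + C_om + draws$sigma2_pe + draws$sigma2_e
  per_draw <- tibble(V_o = V_o, V_m = V_m, C_om = C_om, V_P = V_P,
                     h2_direct = V_o / V_P, h2_maternal = V_m / V_P,
                     r_om = C_om / sqrt(V_o * V_m))
  out <- summarize_chain(per_draw, min_samples = min(100, nrow(per_draw)))
  attr(out, "draws") <- per_draw
  attr(out, "plugin") <- genetic_parameters(
    setNames(colMeans(draws), names(draws)), group)
  out
}
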