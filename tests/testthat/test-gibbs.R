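test_that("scalar variance draws follow the scaled inverse chi-squared", {
  # forced arithmetic: df = nu + n, scale = (sum_sq + nu s2) / df
  set.seed(5)
  draws <- replicate(2e5, sample_scalar_variance(10, 5, 2, 4))
  # analytic mean of inv-chi2(df = 9, scale = 2) is 9 * 2 / 7
  expect_equal(mean(draws), 9 * 2 / 7, tolerance = 0.02)
  # distributional check: 18 / draw ~ chi-squared with 9 df
  ks <- suppressWarnings(stats::ks.test(18 / draws, stats::pchisq, df = 9))
  expect_lt(unname(ks$statistic), 0.01)
  # no data: a draw from the prior
  set.seed(6)
  prior <- replicate(2e5, sample_scalar_variance(0, 0, 2, 4))
  expect_equal(mean(prior), 4 * 2 / 2, tolerance = 0.05)
})

test_that("2x2 covariance draws follow the inverse Wishart", {
  G0 <- matrix(c(10, 8, 8, 9), 2, 2)
  S <- matrix(c(50, 10, 10, 30), 2, 2)
  nu <- 5
  q <- 12
  set.seed(7)
  draws <- replicate(1e5, sample_g0(S, q, G0, nu))
  # analytic inverse-Wishart mean: scale / (df - p - 1)
  expected <- (nu * G0 + S) / (nu + q - 3)
  expect_equal(apply(draws, 1:2, mean), expected, tolerance = 0.02)
  expect_true(all(apply(draws, 3, function(m) det(m) > 0 & m[1, 1] > 0)))
  # rank-1 quadratic form when both vectors coincide under identity A*
  u <- c(1, 2, 3)
  Srank1 <- matrix(sum(u^2), 2, 2)
  expect_equal(Srank1[1, 1], Srank1[2, 2])
  # no contributors: prior draw, mean nu G0 / (nu - 3)
  set.seed(8)
  prior <- replicate(1e5, sample_g0(matrix(0, 2, 2), 0, G0, 6))
  expect_equal(apply(prior, 1:2, mean), 6 * G0 / 3, tolerance = 0.05)
})

test_that("the single-site scan targets the right normal posterior", {
  # toy: two means with correlated design, known residual variance;
  # long single-site run must match the closed-form Gaussian posterior
  set.seed(9)
  X <- cbind(1, rep(c(0, 1), each = 20))
  y <- rnorm(40, X %*% c(3, 2), 1)
  C <- crossprod(X) + diag(2) * 1e-7
  r <- crossprod(X, y)
  post_mean <- solve(C, r)
  post_var <- solve(C)
  th <- c(0, 0)
  keep <- matrix(NA_real_, 4000, 2)
  for (i in 1:8000) {
    th <- sample_locations_single_site(th, C, r)
    if (i > 4000) keep[i - 4000, ] <- th
  }
  expect_equal(colMeans(keep), as.numeric(post_mean), tolerance = 0.05)
  expect_equal(unname(cov(keep)), unname(post_var), tolerance = 0.25)
})

test_that("chains are reproducible and their files carry the seed", {
  ds <- small_dataset(scale = 0.02, seed = 13)
  fml <- weight ~ sex + day_of_birth
  ctl <- mb_chain_control(n_iter = 300, burn_in = 50, thin = 2, seed = 5)
  c1 <- mb_gibbs(ds$records, ds$pedigree, fml, control = ctl)
  c2 <- mb_gibbs(ds$records, ds$pedigree, fml, control = ctl)
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$config_hash, c2$config_hash)
  # every saved state is a valid component set
  expect_true(all(vapply(seq_len(nrow(c1$samples)), function(i) {
    v <- unlist(c1$samples[i, -1])
    all(is.finite(v)) &&
      v["sigma2_Ao"] * v["sigma2_Am"] > v["sigma_AoAm"]^2 &&
      v["sigma2_So"] * v["sigma2_Sm"] > v["sigma_SoSm"]^2
  }, TRUE)))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_chain(c1, path)
  back <- read_chain(path)
  expect_equal(as.data.frame(back), as.data.frame(c1$samples),
               ignore_attr = TRUE)
  expect_match(attr(back, "seed"), "5")

  # a different seed moves the chain
  c3 <- mb_gibbs(ds$records, ds$pedigree, fml,
                 control = mb_chain_control(300, 50, 2, seed = 6))
  expect_false(identical(c1$samples$sigma2_e, c3$samples$sigma2_e))
})

test_that("overwhelming degrees of belief pin components to the prior
          scales", {
  ds <- small_dataset(scale = 0.03, seed = 17)
  pr <- mb_priors(nu_A = 1e6, nu_B = 1e6, nu_S = 1e6, nu_pe = 1e6,
                  nu_e = 1e6)
  ch <- mb_gibbs(ds$records, ds$pedigree, weight ~ sex + day_of_birth,
                 priors = pr, control = mb_chain_control(800, 200, 2,
                                                         seed = 19))
  m <- colMeans(ch$samples[-1])
  scales <- c(85, -25, 35, 76, -50, 70, 10, 8, 9, 80, 170)
  expect_equal(unname(m), scales, tolerance = 0.01)
})

test_that("posterior location means approach BLUP when variances are
          pinned", {
  ds <- small_dataset(scale = 0.02, seed = 3)
  fml <- weight ~ sex + day_of_birth
  pr <- mb_priors(nu_A = 1e8, nu_B = 1e8, nu_S = 1e8, nu_pe = 1e8,
                  nu_e = 1e8)
  ch <- mb_gibbs(ds$records, ds$pedigree, fml, priors = pr,
                 control = mb_chain_control(12000, 2000, 10, seed = 29))
  vc <- as_varcomp(setNames(c(85, -25, 35, 76, -50, 70, 10, 8, 9, 80, 170),
                            mb_components()))
  fit <- mb_blup(ds$records, ds$pedigree, fml, vc)
  gen <- ch$location_means[ch$location_means$block == "genetic", ]
  cmp <- dplyr::inner_join(gen, fit$random,
                           by = c(term = "animal", source = "source",
                                  effect = "effect"))
  expect_gt(stats::cor(cmp$value.x, cmp$value.y), 0.95)
  expect_lt(sqrt(mean((cmp$value.x - cmp$value.y)^2)) / sd(cmp$value.y),
            0.35)
})
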