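test_that("design matrices route records through collapsed codes", {
  ds <- small_dataset()
  ped <- ds$pedigree
  des <- build_design(ds$records, ped,
                      weight ~ sex + age_of_dam + day_of_birth)
  n <- nrow(ds$records)
  expect_equal(nrow(des$X), n)
  expect_equal(length(des$y), n)
  # each Z row has at most one unit entry
  for (src in c("A", "B", "S")) {
    expect_true(all(Matrix::rowSums(des$Z[[src]]$o) %in% c(0, 1)))
    expect_true(all(des$Z[[src]]$o@x == 1))
  }
  # records on purebred Angus animals have all-zero rows in B and S
  pure_rows <- which(ds$records$genotype == "ANGUS")
  expect_equal(sum(Matrix::rowSums(des$Z$B$o)[pure_rows]), 0)
  expect_equal(sum(Matrix::rowSums(des$Z$S$o)[pure_rows]), 0)
  # F2 records carry breed covariate 0.5 and heterosis 0.5
  f2_rows <- which(ds$records$genotype == "F2(HAxHA)")
  expect_equal(unname(as.matrix(des$X)[f2_rows, "direct_breed"]),
               rep(0.5, length(f2_rows)))
  expect_equal(unname(as.matrix(des$X)[f2_rows, "direct_heterosis"]),
               rep(0.5, length(f2_rows)))
  # unknown animals are rejected
  bad <- ds$records
  bad$animal[1] <- "nobody"
  expect_error(build_design(bad, ped, weight ~ sex),
               class = "mb_input_error")
})

test_that("mixed-model equations are symmetric positive definite", {
  ds <- small_dataset()
  des <- build_design(ds$records, ds$pedigree,
                      weight ~ sex + age_of_dam + day_of_birth)
  mme <- build_mme(des, ds$truth)
  expect_true(Matrix::isSymmetric(mme$C))
  ev <- min(eigen(as.matrix(mme$C), symmetric = TRUE,
                  only.values = TRUE)$values)
  expect_gt(ev, 0)
  expect_error(build_mme(des, ds$truth, k = 1e3), class = "mb_input_error")
})

test_that("collapsed multi-source BLUP equals the dense single-covariance
          fit", {
  ds <- small_dataset(scale = 0.011, seed = 21)
  ped <- ds$pedigree
  q <- nrow(ped)
  expect_lte(q, 70)
  vc <- ds$truth
  fml <- weight ~ sex + day_of_birth
  fit <- mb_blup(ds$records, ped, fml, vc)

  # oracle: one genetic effect pair per animal with covariance
  # sum_X G0X (x) A_X built by the full tabular path
  Gbig <- matrix(0, 2 * q, 2 * q)
  for (src in c("A", "B", "S")) {
    Gbig <- Gbig + kronecker(vc[[paste0("G0", src)]],
                             partial_nrm_tabular(ped, src))
  }
  des <- build_design(ds$records, ped, fml)
  X <- as.matrix(des$X)
  n <- nrow(X)
  Zo <- matrix(0, n, q); Zo[cbind(seq_len(n), des$animal_code)] <- 1
  Zm <- matrix(0, n, q); Zm[cbind(seq_len(n), des$dam_code)] <- 1
  W <- cbind(X, Zo, Zm, as.matrix(des$Zp))
  p <- ncol(X)
  d <- ncol(des$Zp)
  prec <- matrix(0, ncol(W), ncol(W))
  prec[seq_len(p), seq_len(p)] <- diag(p) / 1e7
  prec[p + seq_len(2 * q), p + seq_len(2 * q)] <- solve(Gbig)
  prec[p + 2 * q + seq_len(d), p + 2 * q + seq_len(d)] <-
    diag(d) / vc$sigma2_pe
  sol <- solve(crossprod(W) / vc$sigma2_e + prec,
               crossprod(W, des$y) / vc$sigma2_e)

  tot <- total_breeding_values(fit)
  expect_lt(max(abs(tot$direct - sol[p + seq_len(q)])), 1e-6)
  expect_lt(max(abs(tot$maternal - sol[p + q + seq_len(q)])), 1e-6)
})

test_that("BLUP is invariant to source block order and reduces correctly", {
  ds <- small_dataset(scale = 0.02, seed = 9)
  fml <- weight ~ sex + day_of_birth
  f1 <- mb_blup(ds$records, ds$pedigree, fml, ds$truth)
  f2 <- mb_blup(ds$records, ds$pedigree, fml, ds$truth,
                sources = c("S", "B", "A"))
  expect_equal(total_breeding_values(f1), total_breeding_values(f2),
               tolerance = 1e-9)

  # vanishing genetic variance shrinks all genetic solutions to zero
  tiny <- ds$truth
  for (src in c("G0A", "G0B", "G0S")) tiny[[src]] <- diag(2) * 1e-8
  tiny <- varcomp(tiny$G0A, tiny$G0B, tiny$G0S, tiny$sigma2_pe,
                  tiny$sigma2_e)
  f0 <- mb_blup(ds$records, ds$pedigree, fml, tiny)
  expect_lt(max(abs(total_breeding_values(f0)$direct)), 1e-5)
})

test_that("a purebred pedigree reduces to the standard animal model", {
  # purebred-A data: only source A is active; compare against a dense
  # single-NRM maternal animal model solved directly
  set.seed(301)
  base <- data.frame(animal = paste0("b", 1:8), sire = NA, dam = NA,
                     f_A = 1)
  kids <- data.frame(animal = paste0("k", 1:12),
                     sire = sample(paste0("b", 1:4), 12, replace = TRUE),
                     dam = rep(paste0("b", 5:8), 3), f_A = NA)
  ped <- as_pedigree(rbind(base, kids))
  vc <- as_varcomp(setNames(c(90, -20, 40, 1e-6, 0, 1e-6, 1e-6, 0, 1e-6,
                              60, 150), mb_components()))
  q <- nrow(ped)
  records <- data.frame(animal = kids$animal,
                        x = rnorm(12), weight = rnorm(12, 150, 10))
  fit <- mb_blup(records, ped, weight ~ x, vc, cross_effects = FALSE)

  A <- nrm_tabular(ped)
  des <- build_design(records, ped, weight ~ x, cross_effects = FALSE)
  X <- as.matrix(des$X)
  n <- nrow(X)
  Zo <- matrix(0, n, q); Zo[cbind(seq_len(n), des$animal_code)] <- 1
  Zm <- matrix(0, n, q); Zm[cbind(seq_len(n), des$dam_code)] <- 1
  W <- cbind(X, Zo, Zm, as.matrix(des$Zp))
  p <- ncol(X)
  d <- ncol(des$Zp)
  prec <- matrix(0, ncol(W), ncol(W))
  prec[seq_len(p), seq_len(p)] <- diag(p) / 1e7
  prec[p + seq_len(2 * q), p + seq_len(2 * q)] <-
    kronecker(solve(vc$G0A), solve(A))
  prec[p + 2 * q + seq_len(d), p + 2 * q + seq_len(d)] <-
    diag(d) / vc$sigma2_pe
  sol <- solve(crossprod(W) / vc$sigma2_e + prec,
               crossprod(W, des$y) / vc$sigma2_e)
  tot <- total_breeding_values(fit)
  expect_lt(max(abs(tot$direct - sol[p + seq_len(q)])), 2e-4)

  # and the total equals the source-A component alone
  rnd <- tidy(fit)
  a_only <- rnd[rnd$source == "A" & rnd$effect == "direct", ]
  expect_equal(tot$direct[match(a_only$animal, tot$animal)], a_only$value,
               tolerance = 1e-6)
})
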