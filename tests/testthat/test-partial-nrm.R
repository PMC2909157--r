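test_that("tabular partial matrices match hand-derived small cases", {
  trio <- trio_pedigree()
  AA <- partial_nrm_tabular(trio, "A")
  expect_equal(unname(AA),
               matrix(c(1, 0, 0.5, 0, 0, 0, 0.5, 0, 0.5), 3, 3))
  expect_equal(unname(partial_nrm_tabular(trio, "S")), matrix(0, 3, 3))
  # F2 of unrelated F1s expresses the full segregation variance
  ped <- f2_pedigree()
  AS <- partial_nrm_tabular(ped, "S")
  expect_equal(AS["f2", "f2"], 1)
  expect_equal(sum(abs(AS[c("a1", "h1"), ])), 0)
})

test_that("breed partials sum to the classical relationship matrix", {
  set.seed(97)
  for (rep in 1:5) {
    ped <- random_pedigree()
    AA <- partial_nrm_tabular(ped, "A")
    AB <- partial_nrm_tabular(ped, "B")
    expect_lt(max(abs(AA + AB - nrm_tabular(ped))), 1e-10)
  }
  # purebred limit: one breed carries everything
  pure <- oracle_pedigrees()$pure
  expect_equal(partial_nrm_tabular(pure, "A"), nrm_tabular(pure))
  expect_equal(max(abs(partial_nrm_tabular(pure, "B"))), 0)
  expect_equal(max(abs(partial_nrm_tabular(pure, "S"))), 0)
})

test_that("row-wise Mendelian variances equal the tabular values exactly", {
  set.seed(11)
  peds <- c(oracle_pedigrees(), list(r1 = random_pedigree(),
                                     r2 = random_pedigree()))
  for (ped in peds) {
    for (src in c("A", "B", "S")) {
      A <- partial_nrm_tabular(ped, src)
      md <- mendelian_variances(ped, src)
      expect_equal(md$diag, unname(diag(A)))
      # within-family variance of the parent-average decomposition
      for (i in which(md$contributor)) {
        s <- ped$sire_code[i]
        d <- ped$dam_code[i]
        expected <- A[i, i] -
          (if (s > 0) A[s, s] / 4 else 0) -
          (if (d > 0) A[d, d] / 4 else 0) -
          (if (s > 0 && d > 0) A[s, d] / 2 else 0)
        expect_equal(md$d[i], expected)
        expect_gt(md$d[i], 0)
      }
    }
  }
  # the reference examples: F1 of non-inbred purebreds, F2 of unrelated F1s
  expect_equal(mendelian_variances(trio_pedigree(), "A")$d[3], 0.25)
  expect_equal(mendelian_variances(f2_pedigree(), "S")$d[7], 1)
})

test_that("contributor maps match the non-null diagonal of the tabular
          matrix", {
  set.seed(23)
  peds <- c(oracle_pedigrees(), list(r = random_pedigree()))
  for (ped in peds) {
    for (src in c("A", "B", "S")) {
      A <- partial_nrm_tabular(ped, src)
      mem <- contributors(ped, src)
      expect_equal(mem$code, unname(which(diag(A) > 1e-12)))
      # null rows are exactly zero
      nulls <- setdiff(ped$code, mem$code)
      if (length(nulls) > 0) expect_equal(max(abs(A[nulls, ])), 0)
    }
  }
  expect_equal(nrow(contributors(oracle_pedigrees()$pure, "S")), 0)
  trio <- trio_pedigree()
  expect_equal(contributors(trio, "A")$animal, c("s", "x"))
  expect_equal(contributors(trio, "B")$animal, c("d", "x"))
})

test_that("collapsed inverses invert the collapsed matrices", {
  trio <- trio_pedigree()
  expect_equal(as.matrix(collapsed_inverse(trio, "A")),
               matrix(c(2, -2, -2, 4), 2, 2))
  set.seed(59)
  peds <- c(oracle_pedigrees(), list(r1 = random_pedigree(),
                                     r2 = random_pedigree()))
  for (ped in peds) {
    for (src in c("A", "B", "S")) {
      cn <- collapsed_nrm(ped, src)
      if (nrow(cn$members) == 0) next
      Inv <- as.matrix(collapsed_inverse(ped, src))
      expect_lt(max(abs(cn$matrix %*% Inv - diag(nrow(cn$matrix)))), 1e-8)
      expect_gt(min(eigen(cn$matrix, symmetric = TRUE,
                          only.values = TRUE)$values), 0)
    }
  }
  # purebred limit: the collapsed inverse is the classical NRM inverse
  pure <- oracle_pedigrees()$pure
  expect_lt(max(abs(as.matrix(collapsed_inverse(pure, "A")) -
                      solve(nrm_tabular(pure)))), 1e-8)
})

test_that("collapsed values expand with zeros at non-contributors", {
  ped <- f2_pedigree()
  mem <- contributors(ped, "S")
  v <- seq_len(nrow(mem))
  full <- expand_collapsed(v, mem, nrow(ped))
  expect_length(full, nrow(ped))
  expect_equal(full[mem$code], v)
  expect_equal(sum(full != 0), nrow(mem))
  expect_error(expand_collapsed(c(v, 99), mem, nrow(ped)),
               class = "mb_dim_error")
  empty <- contributors(oracle_pedigrees()$pure, "S")
  expect_equal(expand_collapsed(numeric(0), empty, 6), rep(0, 6))
})

test_that("assembled total covariance weights the partials correctly", {
  ped <- f2_pedigree()
  sg <- c(A = 120.74, B = 100.24, S = 9.62)
  G <- assemble_total_g(ped, sg)
  expect_equal(G["f2", "f2"],
               0.5 * sg[["A"]] + 0.5 * sg[["B"]] + sg[["S"]] +
                 0.5 * G["f1a", "f1b"])
  expect_equal(G, t(G))
  pure <- oracle_pedigrees()$pure
  expect_equal(assemble_total_g(pure, c(A = 2, B = 1, S = 1)),
               2 * nrm_tabular(pure))
  expect_error(assemble_total_g(ped, c(A = -1, B = 1, S = 1)),
               class = "mb_input_error")
})
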