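# Independent oracles and fixture pedigrees used across the test files.
# The oracles deliberately re-derive quantities by routes that share no code
# with the package implementation they gate.

# classical single-population numerator relationship matrix, tabular method
nrm_tabular <- function(ped) {
  q <- nrow(ped)
  A <- matrix(0, q, q, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(q)) {
    s <- ped$sire_code[i]
    d <- ped$dam_code[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      A[i, j] <- A[j, i] <- ((if (s > 0) A[s, j] else 0) +
                               (if (d > 0) A[d, j] else 0)) / 2
    }
    A[i, i] <- 1 + (if (s > 0 && d > 0) A[s, d] / 2 else 0)
  }
  A
}

# A-sire x B-dam trio
trio_pedigree <- function() {
  as_pedigree(data.frame(animal = c("s", "d", "x"),
                         sire = c(NA, NA, "s"), dam = c(NA, NA, "d"),
                         f_A = c(1, 0, NA)))
}

# two F1 families and an F2 (the F1 parents are unrelated)
f2_pedigree <- function() {
  as_pedigree(data.frame(
    animal = c("a1", "a2", "h1", "h2", "f1a", "f1b", "f2"),
    sire = c(NA, NA, NA, NA, "a1", "a2", "f1a"),
    dam = c(NA, NA, NA, NA, "h1", "h2", "f1b"),
    f_A = c(1, 1, 0, 0, NA, NA, NA)))
}

# five small fixed pedigrees covering the mating types of the crossbred
# design: purebreds, F1s, F2 inter-se, backcrosses, rotational and advanced
# generations, including inbred matings
oracle_pedigrees <- function() {
  pure <- as_pedigree(data.frame(
    animal = c("s1", "d1", "d2", "o1", "o2", "o3"),
    sire = c(NA, NA, NA, "s1", "s1", "o1"),
    dam = c(NA, NA, NA, "d1", "d2", "o2"),
    f_A = c(1, 1, 1, NA, NA, NA)))
  backcross <- as_pedigree(data.frame(
    animal = c("a1", "a2", "h1", "f1", "b1", "b2", "bb"),
    sire = c(NA, NA, NA, "a1", "a2", "a2", "b1"),
    dam = c(NA, NA, NA, "h1", "f1", "f1", "b2"),
    f_A = c(1, 1, 0, NA, NA, NA, NA)))
  interse <- as_pedigree(data.frame(
    animal = c("a1", "a2", "h1", "h2", "f1a", "f1b", "f2a", "f2b", "f3",
               "f4"),
    sire = c(NA, NA, NA, NA, "a1", "a1", "f1a", "f1a", "f2a", "f3"),
    dam = c(NA, NA, NA, NA, "h1", "h2", "f1b", "f1b", "f2b", "f2b"),
    f_A = c(1, 1, 0, 0, NA, NA, NA, NA, NA, NA)))
  rotational <- as_pedigree(data.frame(
    animal = c("a1", "a2", "h1", "h2", "f1", "b1", "r3", "r4", "adv"),
    sire = c(NA, NA, NA, NA, "h1", "a1", "h2", "a2", "a1"),
    dam = c(NA, NA, NA, NA, "a2", "f1", "b1", "r3", "r4"),
    f_A = c(1, 1, 0, 0, NA, NA, NA, NA, NA)))
  advanced <- as_pedigree(data.frame(
    animal = c("a1", "h1", "h2", "f1a", "f1b", "f2", "b1", "x1", "x2"),
    sire = c(NA, NA, NA, "a1", "a1", "f1a", "a1", "f2", "x1"),
    dam = c(NA, NA, NA, "h1", "h2", "f1b", "f1a", "b1", "f2"),
    f_A = c(1, 0, 0, NA, NA, NA, NA, NA, NA)))
  list(pure = pure, backcross = backcross, interse = interse,
       rotational = rotational, advanced = advanced)
}

# random crossbred pedigree built from the current RNG stream
random_pedigree <- function(n_base = 6, n_desc = 14) {
  animal <- paste0("p", seq_len(n_base + n_desc))
  sire <- rep(NA_character_, n_base + n_desc)
  dam <- rep(NA_character_, n_base + n_desc)
  f_A <- c(rep(c(1, 0), length.out = n_base), rep(NA_real_, n_desc))
  for (i in n_base + seq_len(n_desc)) {
    pair <- sample(i - 1, 2)
    sire[i] <- animal[pair[1]]
    dam[i] <- animal[pair[2]]
  }
  as_pedigree(data.frame(animal = animal, sire = sire, dam = dam,
                         f_A = f_A))
}

# round half away from zero, as breeding tables print dyadic fractions
round_print <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# small simulated data set shared by model/gibbs tests
small_dataset <- function(scale = 0.05, seed = 3) {
  simulate_dataset(angus_hereford_plan(scale = scale), seed = seed)
}

table3_means <- function() {
  s <- angus_hereford_summaries()
  setNames(s$mean, s$component)
}
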