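test_that("codon frequency schemes match direct counting", {
  pf <- codon_frequencies(
    aln_from_seqs(c(a = "ATGCTA", b = "TTACGA")), "fequal")
  expect_equal(unname(pf), rep(1 / 60, 60))

  tr <- tree5()
  aln <- simulate_codon_alignment(tr, 2, data.frame(omega = 0.5, weight = 1),
                                  150, code = mito_code, seed = 8)$aln
  # oracle: direct position-wise nucleotide counting
  cods <- unclass(aln)[!is.na(unclass(aln))]
  nuc <- c("A", "C", "G", "T")
  fm <- sapply(1:3, function(p) {
    prop.table(table(factor(substr(cods, p, p), levels = nuc)))
  })
  sense <- mito_code$sense
  expected <- fm[, 1][substr(sense, 1, 1)] * fm[, 2][substr(sense, 2, 2)] *
    fm[, 3][substr(sense, 3, 3)]
  expected <- expected / sum(expected)
  expect_equal(unname(codon_frequencies(aln, "f3x4")), unname(expected),
               tolerance = 1e-12)

  pooled <- rowMeans(fm)
  exp1 <- pooled[substr(sense, 1, 1)] * pooled[substr(sense, 2, 2)] *
    pooled[substr(sense, 3, 3)]
  exp1 <- exp1 / sum(exp1)
  expect_equal(unname(codon_frequencies(aln, "f1x4")), unname(exp1),
               tolerance = 1e-12)
})

test_that("rate matrix obeys the single-step codon model structure", {
  pi <- uniform_pi()
  Q <- build_rate_matrix(kappa = 5, omega = 0.3, pi, mito_code)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)

  # codons differing at >1 position get rate exactly zero
  expect_identical(Q["ATG", "TTA"], 0)
  expect_identical(Q["AAA", "CCA"], 0)

  # detailed balance pi_i q_ij = pi_j q_ji
  F <- pi * Q  # rows scaled by pi_i
  expect_lt(max(abs(F - t(F))), 1e-15)

  # nonsynonymous/synonymous transition-rate ratio equals omega under Fequal:
  # CTT->CTC is a synonymous transition (L->L), TTA->TCA a nonsynonymous one
  expect_equal(Q["TTA", "TCA"] / Q["CTT", "CTC"], 0.3, tolerance = 1e-12)

  # kappa = omega = 1 with Fequal: all single-step rates identical
  Q1 <- build_rate_matrix(1, 1, pi, mito_code)
  off <- Q1[mitosel:::single_step_types(mito_code) > 0]
  expect_lt(diff(range(off)), 1e-15)
})

test_that("transition probabilities agree with an independent matrix
           exponential and satisfy semigroup and ergodic limits", {
  set.seed(1)
  pi <- prop.table(runif(60, 0.5, 2))
  names(pi) <- mito_code$sense
  Q <- build_rate_matrix(3, 0.2, pi, mito_code)
  P <- transition_probabilities(Q, 0.4)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  expect_true(all(P >= 0))
  # oracle: Matrix::expm (independent algorithm)
  Pe <- as.matrix(Matrix::expm(Matrix::Matrix(unclass(Q) * 0.4)))
  expect_lt(max(abs(P - Pe)), 1e-10)

  expect_equal(unname(transition_probabilities(Q, 0)), diag(60),
               tolerance = 1e-12)
  Pbig <- transition_probabilities(Q, 500)
  expect_lt(max(abs(sweep(Pbig, 2, pi, `-`))), 1e-8)
  # semigroup P(t1+t2) = P(t1) P(t2)
  expect_lt(max(abs(transition_probabilities(Q, 0.7) -
                    P %*% transition_probabilities(Q, 0.3))), 1e-10)
  expect_error(transition_probabilities(Q, -0.1), "non-negative")
})

test_that("beta discretization uses equal-weight bin medians", {
  d <- discretize_beta(1, 1, 2)
  expect_equal(d$omega, c(0.25, 0.75))
  expect_equal(d$weight, c(0.5, 0.5))

  d1 <- discretize_beta(2, 3, 1)
  expect_equal(d1$omega, qbeta(0.5, 2, 3))

  d10 <- discretize_beta(0.7, 1.9, 200)
  expect_equal(sum(d10$omega * d10$weight), 0.7 / (0.7 + 1.9),
               tolerance = 5e-3)
  expect_true(all(d10$omega > 0 & d10$omega < 1))
})
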