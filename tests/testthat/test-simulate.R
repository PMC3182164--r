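test_that("codon simulation is reproducible and respects degenerate limits", {
  tr <- tree5()
  cls <- data.frame(omega = 0.5, weight = 1)
  a1 <- simulate_codon_alignment(tr, 2, cls, 25, code = mito_code, seed = 7)
  a2 <- simulate_codon_alignment(tr, 2, cls, 25, code = mito_code, seed = 7)
  expect_identical(unclass(a1$aln)[, ], unclass(a2$aln)[, ])
  expect_identical(a1$true_class, a2$true_class)

  tr0 <- read_phylo_tree("(A:0,B:0,C:0);")
  a0 <- simulate_codon_alignment(tr0, 2, cls, 30, code = mito_code, seed = 1)
  m <- unclass(a0$aln)
  expect_true(all(m[1, ] == m[2, ] & m[2, ] == m[3, ]))
})

test_that("omega = 0 permits no nonsynonymous change on a long branch", {
  tr2 <- read_phylo_tree("(A:3,B:3);")
  sim <- simulate_codon_alignment(tr2, 2,
                                  data.frame(omega = 0, weight = 1),
                                  400, code = mito_code, seed = 15)
  aa <- translate_codons(sim$aln)
  expect_true(all(unclass(aa)[1, ] == unclass(aa)[2, ]))
  # but synonymous changes did occur
  expect_gt(sum(unclass(sim$aln)[1, ] != unclass(sim$aln)[2, ]), 0)
})

test_that("two-taxon substitution fraction matches the P(t) expectation", {
  tr2 <- read_phylo_tree("(A:0.4,B:0.4);")
  kap <- 3
  pi <- uniform_pi()
  sim <- simulate_codon_alignment(tr2, kap,
                                  data.frame(omega = 0.3, weight = 1),
                                  6000, pi = pi, code = mito_code, seed = 33)
  obs <- mean(unclass(sim$aln)[1, ] != unclass(sim$aln)[2, ])
  Q <- build_rate_matrix(kap, 0.3, pi, mito_code)
  P <- transition_probabilities(Q, 0.8)   # A-to-B path length
  expected <- 1 - sum(pi * diag(P))
  expect_equal(obs, expected, tolerance = 0.03 / expected)
})

test_that("foreground switching elevates divergence only on flagged edges", {
  tr <- set_foreground(tree5(), "t5")
  cls <- data.frame(omega = 0.02, weight = 1, fg_omega = 30)
  sim <- simulate_codon_alignment(tr, 2, cls, 500, code = mito_code,
                                  seed = 27)
  aa <- unclass(translate_codons(sim$aln))
  # t5 should differ from the rest far more often than t1 vs t2 do
  d_fg <- mean(aa["t5", ] != aa["t1", ])
  d_bg <- mean(aa["t1", ] != aa["t2", ])
  expect_gt(d_fg, 3 * d_bg)
})

test_that("coupled-MSA simulation honors rho limits and conservation", {
  sim1 <- simulate_coupled_msa(M = 150, L = 10, conservation = 0,
                               coupling = data.frame(a = 2, b = 7, rho = 1),
                               seed = 3)
  partner <- setNames(rev(AA20), AA20)
  m <- unclass(sim1$msa)
  expect_true(all(m[, 7] == partner[m[, 2]]))

  # rho = 0: empirical independence (chi-square on the contingency table)
  sim0 <- simulate_coupled_msa(M = 600, L = 4, conservation = 0,
                               coupling = data.frame(a = 1, b = 3, rho = 0),
                               seed = 5)
  m0 <- unclass(sim0$msa)
  p <- suppressWarnings(chisq.test(table(m0[, 1], m0[, 3])))$p.value
  expect_gt(p, 1e-3)

  simc <- simulate_coupled_msa(M = 50, L = 5, conservation = 1, seed = 9)
  expect_true(all(apply(unclass(simc$msa), 2,
                        function(col) length(unique(col))) == 1))

  expect_error(simulate_coupled_msa(M = 10, L = 5,
    coupling = data.frame(a = c(1, 2), b = c(2, 3), rho = 1), seed = 1),
    "disjoint")
})

test_that("reference pools recover their generating frequencies", {
  g <- setNames(prop.table(c(5, rep(1, 19))), AA20)
  pool <- make_reference_set(g, 2000, 500, seed = 12)   # 1e6 draws
  ghat <- reference_frequencies(pool)$g
  expect_lt(max(abs(ghat - g)), 0.005)
  p2 <- make_reference_set(g, 10, 20, seed = 8)
  expect_identical(unclass(p2)[, ],
                   unclass(make_reference_set(g, 10, 20, seed = 8))[, ])
})
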