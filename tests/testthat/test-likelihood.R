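test_that("pruning equals exhaustive ancestral-state enumeration", {
  set.seed(3)
  pi <- prop.table(runif(60, 0.5, 2))
  names(pi) <- mito_code$sense
  classes <- data.frame(omega = c(0.1, 1.8), weight = c(0.8, 0.2))
  trees <- list(
    read_phylo_tree("(A:0.15,B:0.4);"),
    read_phylo_tree("(A:0.2,B:0.1,C:0.35);"),
    read_phylo_tree("((A:0.2,B:0.1):0.15,C:0.35,D:0.05);"))
  for (tr in trees) {
    sim <- simulate_codon_alignment(tr, 2.5, classes, 3, pi = pi,
                                    code = mito_code, seed = 6)
    ll <- codon_loglik(sim$aln, tr, 2.5, classes, pi = pi)
    bf <- brute_force_loglik(sim$aln, tr, 2.5, classes, pi)
    expect_equal(ll$lnL, bf, tolerance = 1e-10)
  }
})

test_that("zero branch lengths give site likelihood pi for constant sites", {
  tr <- read_phylo_tree("(A:0,B:0,C:0);")
  a <- aln_from_seqs(c(A = "ATGCTA", B = "ATGCTA", C = "ATGCTA"))
  pi <- uniform_pi()
  ll <- codon_loglik(a, tr, 2, data.frame(omega = 0.5, weight = 1), pi = pi)
  expect_equal(ll$lnL, log(pi["ATG"]) + log(pi["CTA"]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a one-class mixture equals the single model and duplicated
           classes leave the likelihood unchanged", {
  tr <- tree5()
  sim <- simulate_codon_alignment(tr, 2, data.frame(omega = 0.3, weight = 1),
                                  30, code = mito_code, seed = 12)
  pi <- uniform_pi()
  one <- codon_loglik(sim$aln, tr, 2, data.frame(omega = 0.3, weight = 1),
                      pi = pi)
  dup <- codon_loglik(sim$aln, tr, 2,
                      data.frame(omega = c(0.3, 0.3), weight = c(0.5, 0.5)),
                      pi = pi)
  expect_equal(one$lnL, dup$lnL, tolerance = 1e-12)
})

test_that("likelihood is invariant to taxon row order", {
  tr <- tree5()
  sim <- simulate_codon_alignment(tr, 2, m8_classes(), 40,
                                  code = mito_code, seed = 9)
  pi <- codon_frequencies(sim$aln, "f3x4")
  perm <- unclass(sim$aln)[c(3, 1, 5, 2, 4), ]
  aperm <- codon_alignment(perm, code = mito_code)
  l1 <- codon_loglik(sim$aln, tr, 2, m8_classes(), pi = pi)
  l2 <- codon_loglik(aperm, tr, 2, m8_classes(), pi = pi)
  expect_equal(l1$lnL, l2$lnL, tolerance = 1e-12)
})

test_that("invalid mixtures and mismatched taxa are rejected", {
  tr <- tree5()
  sim <- simulate_codon_alignment(tr, 2, data.frame(omega = 1, weight = 1),
                                  5, code = mito_code, seed = 1)
  expect_error(
    codon_loglik(sim$aln, tr, 2, data.frame(omega = 1, weight = 0.7)),
    "sum to 1")
  rownames(sim$aln) <- paste0("x", 1:5)
  expect_error(codon_loglik(sim$aln, tr, 2,
                            data.frame(omega = 1, weight = 1)),
               "match")
})
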