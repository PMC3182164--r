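ref20 <- reference_frequencies(
  make_reference_set(setNames(rep(0.05, 20), AA20), 100, 400, seed = 7))

test_that("reference frequencies pool counts, ignore order, and floor", {
  one <- reference_frequencies("AAAA")
  expect_equal(unname(one$g["A"]), 1, tolerance = 1e-4)
  expect_true(all(one$g > 0))
  expect_equal(sum(one$g), 1)

  a <- c("ACDEF", "GHIKL", "MNPQR")
  expect_identical(reference_frequencies(a)$g,
                   reference_frequencies(rev(a))$g)
  expect_error(reference_frequencies(character(0)))

  g <- setNames(prop.table(1:20), AA20)
  rec <- reference_frequencies(make_reference_set(g, 100, 500, seed = 3))
  expect_lt(max(abs(rec$g - g)), 0.01)
})

test_that("site energy matches a direct binomial computation", {
  # two columns: one near the reference expectation, one fixed to one residue
  set.seed(5)
  col1 <- sample(AA20, 40, replace = TRUE)           # reference-like
  col2 <- rep("W", 40)                               # fixed rare residue
  msa <- amino_msa(cbind(col1, col2))
  prof <- site_energy(msa, ref20)
  expect_equal(attr(prof, "kT_star"), 1 / 40)
  # oracle: direct dbinom computation
  for (j in 1:2) {
    y <- table(factor(unclass(msa)[, j], levels = AA20))
    lp <- dbinom(as.numeric(y), 40, ref20$g, log = TRUE)
    expect_equal(prof$dG[j], sqrt(sum(lp^2)) / 40, tolerance = 1e-12)
  }
  expect_gt(prof$dG[2], prof$dG[1])
  expect_true(all(prof$dG >= 0))
})

test_that("all-gap columns are reported missing and kT* scales as 1/M", {
  m <- amino_msa(cbind(rep("A", 10), rep("-", 10)))
  prof <- site_energy(m, ref20)
  expect_true(is.na(prof$dG[2]))
  expect_false(is.na(prof$dG[1]))

  # doubling M with identical composition halves kT* exactly
  m2 <- amino_msa(rbind(unclass(m), unclass(m)))
  expect_equal(attr(site_energy(m2, ref20), "kT_star"),
               attr(prof, "kT_star") / 2)
})

test_that("perturbation selects the modal residue with alphabetical ties", {
  col <- c(rep("L", 5), rep("F", 3), rep("-", 2))
  msa <- amino_msa(cbind(col, rep("A", 10)))
  pt <- perturb(msa, 1)
  expect_equal(pt$s, 5)
  expect_equal(pt$residue, "L")
  expect_equal(nrow(pt$msa), 5)

  # fixed column: identity perturbation
  ptid <- perturb(msa, 2)
  expect_equal(ptid$s, 10)

  tie <- amino_msa(cbind(c(rep("L", 4), rep("F", 4)), rep("A", 8)))
  expect_warning(ptt <- perturb(tie, 1), "tie")
  expect_equal(ptt$residue, "F")  # alphabetical

  allgap <- amino_msa(cbind(rep("-", 4), rep("A", 4)))
  expect_error(perturb(allgap, 1), "all-gap")
})

test_that("identity perturbation gives exactly zero coupling energy", {
  sim <- simulate_coupled_msa(M = 60, L = 20, conservation = 0.2, seed = 4)
  ce <- coupling_energy(sim$msa, sim$msa, ref20, 1:20)
  expect_true(all(ce$ddG == 0))
})

test_that("energies are invariant to MSA row order", {
  sim <- simulate_coupled_msa(M = 50, L = 15, conservation = 0.3, seed = 8)
  shuf <- amino_msa(unclass(sim$msa)[sample(50), ])
  expect_equal(site_energy(sim$msa, ref20)$dG,
               site_energy(shuf, ref20)$dG, tolerance = 1e-12)
  pt1 <- perturb(sim$msa, 3)
  pt2 <- perturb(shuf, 3)
  expect_equal(coupling_energy(sim$msa, pt1$msa, ref20, 1:15)$ddG,
               coupling_energy(shuf, pt2$msa, ref20, 1:15)$ddG,
               tolerance = 1e-12)
})

test_that("planted coupled columns outscore independent columns", {
  cons <- rep(0, 30); cons[4] <- 0.25
  sim <- simulate_coupled_msa(M = 300, L = 30, conservation = cons,
                              coupling = data.frame(a = 4, b = 20, rho = 1),
                              seed = 11)
  vs <- setdiff(variable_sites(sim$msa), 4)
  pt <- perturb(sim$msa, 4)
  ce <- coupling_energy(sim$msa, pt$msa, ref20, vs)
  q95 <- quantile(ce$ddG[ce$site != 20], 0.95, na.rm = TRUE)
  expect_gt(ce$ddG[ce$site == 20], q95)
})

test_that("half-deletion diagnostic: no spread for identical sequences,
           means near full-MSA energies otherwise", {
  ident <- amino_msa(matrix("A", 20, 5))
  d <- half_deletion_diagnostic(ident, ref20, 1:5, n_reps = 5, seed = 1)
  expect_equal(d$sd, rep(0, 5))

  # mildly constrained (low but nonzero dG) sites: energies are dominated by
  # the composition divergence term, which the kT* = 1/M scaling makes
  # stable under subsampling
  sim <- simulate_coupled_msa(M = 200, L = 12, conservation = 0.3, seed = 13)
  d2 <- half_deletion_diagnostic(sim$msa, ref20, 1:12, n_reps = 10, seed = 2)
  expect_equal(nrow(d2), 12)
  expect_named(d2, c("site", "dG_full", "mean", "sd"))
  expect_lt(max(abs(d2$mean - d2$dG_full) / d2$dG_full), 0.35)
})

test_that("size-matched diagnostic degenerates to the full MSA at s = M", {
  fixedcol <- amino_msa(cbind(rep("K", 30),
                              matrix(sample(AA20, 60, TRUE), 30, 2)))
  d <- size_matched_diagnostic(fixedcol, ref20, 1, n_reps = 4, seed = 1)
  expect_equal(d$s, 30)
  expect_equal(d$sd, 0)
  expect_equal(d$mean, d$dG_full)
})

test_that("disparity subsampling keeps one sequence per near-identical
           cluster and audits its own postcondition", {
  dup <- amino_msa(rbind(unclass(make_reference_set(
    setNames(rep(.05, 20), AA20), 1, 40, seed = 2))[c(1, 1), , drop = FALSE]))
  kept <- disparity_subsample(dup, 0.05)
  expect_equal(nrow(kept), 1)

  # 10 clusters of near-identical sequences -> 10 kept
  set.seed(21)
  base <- matrix(sample(AA20, 10 * 50, TRUE), 10, 50)
  rows <- do.call(rbind, lapply(1:10, function(i) {
    do.call(rbind, lapply(1:4, function(r) {
      s <- base[i, ]
      flip <- sample(50, 1)          # 2% divergence within cluster
      s[flip] <- sample(AA20, 1)
      s
    }))
  }))
  msa <- amino_msa(rows)
  kept10 <- disparity_subsample(msa, 0.05)
  expect_equal(nrow(kept10), 10)

  # postcondition audit: all kept pairs above threshold
  km <- unclass(kept10)
  for (i in seq_len(nrow(km) - 1)) {
    for (j in (i + 1):nrow(km)) {
      expect_gt(mitosel:::p_distance(km[i, ], km[j, ]), 0.05)
    }
  }

  # already-diverged input is a no-op
  far <- amino_msa(matrix(rep(c("A", "C", "D"), each = 30), 3, 30,
                          byrow = TRUE))
  expect_equal(nrow(disparity_subsample(far, 0.05)), 3)
})
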