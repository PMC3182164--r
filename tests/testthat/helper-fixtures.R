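# Shared fixtures and independent oracles, built in code at test time.

mito_code <- genetic_code(2)

uniform_pi <- function(code = mito_code) {
  stats::setNames(rep(1 / length(code$sense), length(code$sense)), code$sense)
}

# the balanced 8-taxon tree used by the recovery experiments
bal8_tree <- function(bl = 0.3) {
  read_phylo_tree(gsub("BL", bl, paste0(
    "(((t1:BL,t2:BL):BL,(t3:BL,t4:BL):BL):BL,",
    "((t5:BL,t6:BL):BL,t7:BL):BL,t8:BL);")))
}

tree5 <- function() {
  read_phylo_tree("((t1:0.2,t2:0.2):0.1,(t3:0.2,t4:0.2):0.1,t5:0.3);")
}

# an M8-style mixture: beta(p,q) background plus a selected class
m8_classes <- function(p0 = 0.95, p = 0.2, q = 1.0, ws = 4, K = 10) {
  b <- discretize_beta(p, q, K)
  data.frame(omega = c(b$omega, ws), weight = c(b$weight * p0, 1 - p0))
}

# Exhaustive ancestral-state enumeration likelihood: the independent oracle
# for the pruning algorithm (feasible for <= 4 taxa, few sites).
brute_force_loglik <- function(aln, tree, kappa, classes, pi,
                               code = mito_code) {
  td <- mitosel:::tree_prune_data(tree)
  m <- unclass(aln)
  ns <- length(code$sense)
  states <- match(m, code$sense)
  dim(states) <- dim(m)
  # shared time scale across classes, as in the likelihood convention
  rates <- vapply(classes$omega, function(w) {
    attr(build_rate_matrix(kappa, w, pi, code, scale = FALSE), "rate")
  }, 0)
  cs <- sum(classes$weight * rates)
  Ps <- lapply(seq_len(nrow(classes)), function(k) {
    Q <- build_rate_matrix(kappa, classes$omega[k], pi, code, scale = FALSE)
    lapply(td$blen, function(t) transition_probabilities(Q / cs, t))
  })
  ntip <- td$ntip
  nint <- td$nnode - ntip
  tipord <- match(td$tree$tip.label, rownames(m))
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nint)))
  lnL <- 0
  for (s in seq_len(ncol(m))) {
    lik <- 0
    for (k in seq_len(nrow(classes))) {
      tot <- 0
      for (gi in seq_len(nrow(grid))) {
        nodes <- c(states[tipord, s], grid[gi, ])
        pr <- pi[grid[gi, td$root - ntip]]
        for (e in seq_len(nrow(td$edge))) {
          a <- nodes[td$edge[e, 1]]
          b <- nodes[td$edge[e, 2]]
          pr <- pr * Ps[[k]][[e]][a, b]
          if (pr == 0) break
        }
        tot <- tot + pr
      }
      lik <- lik + classes$weight[k] * tot
    }
    lnL <- lnL + log(lik)
  }
  unname(lnL)
}

# small deterministic codon alignment from explicit sequences
aln_from_seqs <- function(seqs, code = mito_code) {
  codon_alignment(seqs, code = code)
}
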