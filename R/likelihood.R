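# Site-pattern compression: identical codon columns share one likelihood
# evaluation.  States are 0-based sense-codon indices, -1 = missing.
pattern_data <- function(aln, code = attr(aln, "code")) {
  m <- unclass(aln)
  idx <- matrix(match(m, code$sense) - 1L, nrow(m), ncol(m))
  idx[is.na(idx)] <- -1L
  key <- apply(idx, 2, paste, collapse = ",")
  u <- !duplicated(key)
  pat_of_site <- match(key, key[u])
  tip <- idx[, u, drop = FALSE]
  list(tipstate = tip, patwt = as.numeric(tabulate(pat_of_site, sum(u))),
       pat_of_site = pat_of_site, taxa = rownames(m), nsite = ncol(m))
}

# Mixture class table: data.frame(omega, weight[, fg_omega]).  fg_omega, if
# present, replaces omega on foreground edges (branch-site Model A).
class_table <- function(omega, weight, fg_omega = NULL) {
  d <- data.frame(omega = omega, weight = weight)
  if (!is.null(fg_omega)) d$fg_omega <- fg_omega
  d
}

#' Mixture codon-model log-likelihood
#'
#' Felsenstein-pruning likelihood of a codon alignment on a tree under a
#' mixture of codon substitution models sharing `kappa` and `pi` but
#' differing in omega.  The per-site likelihood is the class-weighted sum of
#' per-class pruning likelihoods, and the total log-likelihood sums the log
#' site likelihoods (sites independent).  If the tree carries foreground
#' edges (see [set_foreground()]) and `classes` has an `fg_omega` column,
#' those edges evolve under the foreground omega of each class.
#'
#' @param aln a [codon_alignment()].
#' @param tree a `phylo` tree whose tip labels match the alignment taxa.
#' @param kappa transition/transversion ratio.
#' @param classes `data.frame` with columns `omega`, `weight` (summing to 1)
#'   and optionally `fg_omega`.
#' @param pi equilibrium sense-codon frequencies (default `f3x4` from the
#'   alignment).
#' @return list with `lnL`, `site_lik` (sites x classes conditional
#'   likelihoods), `weights`.
#' @export
codon_loglik <- function(aln, tree, kappa, classes,
                         pi = codon_frequencies(aln, "f3x4")) {
  code <- attr(aln, "code")
  pd <- pattern_data(aln, code)
  td <- tree_prune_data(tree)
  if (!setequal(td$tree$tip.label, pd$taxa)) {
    stop("tree tip labels do not match alignment taxa")
  }
  if (abs(sum(classes$weight) - 1) > 1e-8) {
    stop("class weights must sum to 1")
  }
  tip <- pd$tipstate[match(td$tree$tip.label, pd$taxa), , drop = FALSE]
  res <- prune_mix(tip, pd$patwt, td, kappa, classes, pi, code)
  if (!is.finite(res$lnL)) {
    bad <- which(res$sitelik %*% classes$weight <= 0)[1]
    site <- which(pd$pat_of_site == bad)[1]
    stop("non-finite likelihood at codon site ", site)
  }
  list(lnL = res$lnL,
       site_lik = res$sitelik[pd$pat_of_site, , drop = FALSE],
       weights = classes$weight)
}

# Core dispatcher shared by codon_loglik and the fitters: builds the per-class
# generator decompositions and the class-by-edge decomposition map, then calls
# the C++ pruning kernel.  `td` comes from tree_prune_data(); `tip` rows must
# already be in tree tip order.
#
# All classes share one time scale: generators are rescaled by the weighted
# average of the class rates (background omegas), so that branch lengths are
# expected substitutions per codon averaged over site classes and high-omega
# classes evolve proportionally faster.
prune_mix <- function(tip, patwt, td, kappa, classes, pi, code) {
  has_fg <- !is.null(classes$fg_omega) && length(td$foreground) > 0
  omegas <- classes$omega
  all_om <- if (has_fg) c(omegas, classes$fg_omega) else omegas
  uom <- unique(all_om)
  Qs <- lapply(uom, function(w) {
    build_rate_matrix(kappa, w, pi, code, scale = FALSE)
  })
  rates <- vapply(Qs, attr, 0, "rate")
  c_scale <- sum(classes$weight * rates[match(omegas, uom)])
  decomps <- lapply(Qs, function(Q) {
    d <- decompose_generator(Q)
    d$lambda <- d$lambda / c_scale
    d
  })
  nedge <- nrow(td$edge)
  K <- nrow(classes)
  dmap <- matrix(match(omegas, uom), K, nedge)
  if (has_fg) {
    dmap[, td$foreground] <- match(classes$fg_omega, uom)
  }
  cpp_prune_mix(tip, td$edge, td$blen, td$nnode, td$root,
                decomps, dmap, classes$weight, patwt)
}
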