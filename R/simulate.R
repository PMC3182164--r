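# Simulators for both analysis tracks: codon alignments evolved on a tree
# under mixture (and branch-site) codon models, and amino-acid MSAs with a
# known background distribution and planted pairwise column couplings.

#' Simulate a codon alignment under a mixture codon model
#'
#' Each site draws an omega class from the mixture, the root codon is drawn
#' from the equilibrium frequencies, and the site evolves down the tree with
#' the class's transition probabilities per branch.  If the tree carries
#' foreground edges and `classes` has an `fg_omega` column, those edges
#' evolve under the class's foreground omega (branch-site semantics: the
#' switch applies to the entire flagged edge).
#'
#' @param tree a `phylo` tree with branch lengths (expected substitutions
#'   per codon); foreground edges via [set_foreground()] if needed.
#' @param kappa transition/transversion ratio.
#' @param classes `data.frame` with columns `omega`, `weight` and optionally
#'   `fg_omega`.
#' @param n_sites number of codon sites.
#' @param pi equilibrium sense-codon frequencies (default uniform).
#' @param code a [genetic_code()].
#' @param seed integer seed (mandatory for reproducibility).
#' @return list with `aln` (a [codon_alignment()]) and `true_class`
#'   (integer vector of generating class per site).
#' @export
simulate_codon_alignment <- function(tree, kappa, classes, n_sites,
                                     pi = NULL, code = genetic_code(2),
                                     seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  ns <- length(code$sense)
  if (is.null(pi)) pi <- stats::setNames(rep(1 / ns, ns), code$sense)
  if (abs(sum(classes$weight) - 1) > 1e-8) stop("class weights must sum to 1")
  td <- tree_prune_data(tree)
  ntip <- td$ntip
  has_fg <- !is.null(classes$fg_omega) && length(td$foreground) > 0

  true_class <- sample.int(nrow(classes), n_sites, replace = TRUE,
                           prob = classes$weight)
  # one shared time scale across classes (mixture-average rate), matching
  # the likelihood convention in codon_loglik()
  rate_of <- function(w) {
    attr(build_rate_matrix(kappa, w, pi, code, scale = FALSE), "rate")
  }
  c_scale <- sum(classes$weight * vapply(classes$omega, rate_of, 0))
  dec_cache <- new.env(parent = emptyenv())
  get_dec <- function(w) {
    key <- sprintf("%.12g", w)
    if (is.null(dec_cache[[key]])) {
      d <- decompose_generator(
        build_rate_matrix(kappa, w, pi, code, scale = FALSE))
      d$lambda <- d$lambda / c_scale
      dec_cache[[key]] <- d
    }
    dec_cache[[key]]
  }
  state <- matrix(NA_integer_, td$nnode, n_sites)
  state[td$root, ] <- sample.int(ns, n_sites, replace = TRUE, prob = pi)
  # preorder = reverse postorder
  for (e in rev(seq_len(nrow(td$edge)))) {
    par <- td$edge[e, 1]; ch <- td$edge[e, 2]
    fg_edge <- has_fg && (e %in% td$foreground)
    for (k in seq_len(nrow(classes))) {
      idx <- which(true_class == k)
      if (!length(idx)) next
      w <- if (fg_edge) classes$fg_omega[k] else classes$omega[k]
      d <- get_dec(w)
      P <- cpp_pmat(d$V, d$lambda, d$sqpi, td$blen[e])
      ps <- state[par, idx]
      for (s in unique(ps)) {
        at <- idx[ps == s]
        state[ch, at] <- sample.int(ns, length(at), replace = TRUE,
                                    prob = P[s, ])
      }
    }
  }
  m <- matrix(code$sense[state[seq_len(ntip), , drop = FALSE]], ntip, n_sites)
  rownames(m) <- td$tree$tip.label
  list(aln = codon_alignment(m, code = code), true_class = true_class)
}

#' Simulate an amino-acid MSA with planted column couplings
#'
#' Uncoupled columns draw residues independently from a site distribution
#' that mixes the background frequencies `g` with a conserved residue
#' (`conservation` = weight on the conserved residue; 0 gives pure
#' background, 1 a fixed column).  For each coupled pair (a, b) with
#' strength `rho`, the residue at b is, with probability `rho`, a
#' deterministic partner of the residue drawn at a (a fixed bijection on the
#' 20 amino acids), and otherwise drawn independently.
#'
#' @param M number of sequences.
#' @param L number of columns.
#' @param g named background frequency 20-vector (default uniform).
#' @param conservation scalar or length-`L` vector in `[0, 1]`.
#' @param coupling `data.frame` with columns `a`, `b`, `rho`; pairs must be
#'   disjoint.
#' @param gap_rate per-cell gap probability (default 0).
#' @param seed integer seed.
#' @return list with `msa` (an [amino_msa()]) and `truth` (the coupling
#'   table, plus the per-column conserved residues as attribute).
#' @export
simulate_coupled_msa <- function(M, L, g = NULL, conservation = 0.3,
                                 coupling = NULL, gap_rate = 0, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  if (is.null(g)) g <- stats::setNames(rep(0.05, 20), AA20)
  g <- g[AA20] / sum(g)
  if (length(conservation) == 1) conservation <- rep(conservation, L)
  stopifnot(length(conservation) == L,
            all(conservation >= 0 & conservation <= 1))
  if (!is.null(coupling)) {
    ids <- c(coupling$a, coupling$b)
    if (anyDuplicated(ids)) stop("coupling pairs must be disjoint")
    stopifnot(all(ids >= 1 & ids <= L), all(coupling$rho >= 0 & coupling$rho <= 1))
  }
  partner <- stats::setNames(rev(AA20), AA20)   # fixed bijection
  cons_res <- sample(AA20, L, replace = TRUE, prob = g)
  col_dist <- function(j) {
    d <- (1 - conservation[j]) * g
    d[cons_res[j]] <- d[cons_res[j]] + conservation[j]
    d
  }
  m <- matrix(NA_character_, M, L)
  for (j in seq_len(L)) {
    m[, j] <- sample(AA20, M, replace = TRUE, prob = col_dist(j))
  }
  if (!is.null(coupling)) {
    for (r in seq_len(nrow(coupling))) {
      a <- coupling$a[r]; b <- coupling$b[r]; rho <- coupling$rho[r]
      linked <- stats::runif(M) < rho
      m[linked, b] <- partner[m[linked, a]]
    }
  }
  if (gap_rate > 0) m[stats::runif(M * L) < gap_rate] <- "-"
  rownames(m) <- paste0("seq", seq_len(M))
  truth <- coupling %||% data.frame(a = integer(0), b = integer(0),
                                    rho = numeric(0))
  attr(truth, "conserved_residue") <- cons_res
  list(msa = amino_msa(m), truth = truth)
}

#' Simulate a reference sequence pool
#'
#' Draws sequences with residues i.i.d. from a known frequency vector; a
#' synthetic stand-in for a large reference database, so that
#' [reference_frequencies()] recovers `g` within sampling error.
#'
#' @param g named 20-vector of amino-acid frequencies.
#' @param n_seqs number of sequences.
#' @param length sequence length.
#' @param seed integer seed.
#' @return an [amino_msa()].
#' @export
make_reference_set <- function(g, n_seqs, length, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  g <- g[AA20] / sum(g)
  m <- matrix(sample(AA20, n_seqs * length, replace = TRUE, prob = g),
              n_seqs, length)
  rownames(m) <- paste0("ref", seq_len(n_seqs))
  amino_msa(m)
}

#' A deterministic simulation tree
#'
#' Random topology and branch lengths under a fixed seed; branch lengths are
#' exponential with the given mean (expected substitutions per codon).
#'
#' @param n_taxa number of tips.
#' @param mean_blen mean branch length.
#' @param seed integer seed.
#' @return an unrooted `phylo` tree with tip labels `t1..tn`.
#' @export
sim_tree <- function(n_taxa, mean_blen = 0.1, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) stats::rexp(n, 1 / mean_blen))
  tr
}
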