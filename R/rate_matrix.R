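#' Equilibrium codon frequencies
#'
#' Estimates the equilibrium frequency vector over the sense codons of the
#' alignment's genetic code.  `fequal` assumes all sense codons equally
#' frequent; `f1x4` uses the nucleotide frequencies pooled over the whole
#' alignment; `f3x4` uses the nucleotide frequencies observed at each of the
#' three codon positions separately.  Stop codons are excluded and the
#' vector renormalized; zero entries are floored at `floor` before
#' renormalization so the likelihood stays finite on small alignments.
#'
#' @param aln a [codon_alignment()].
#' @param scheme one of `"f3x4"`, `"f1x4"`, `"fequal"`.
#' @param floor lower bound applied to each sense-codon frequency.
#' @return named numeric vector over the sense codons, summing to one.
#' @export
codon_frequencies <- function(aln, scheme = c("f3x4", "f1x4", "fequal"),
                              floor = 1e-10) {
  scheme <- match.arg(scheme)
  code <- attr(aln, "code")
  sense <- code$sense
  if (scheme == "fequal") {
    pi <- rep(1 / length(sense), length(sense))
    names(pi) <- sense
    return(pi)
  }
  cods <- unclass(aln)[!is.na(unclass(aln))]
  if (length(cods) == 0) stop("alignment has no scored codons")
  nuc <- c("A", "C", "G", "T")
  posfreq <- function(p) {
    f <- table(factor(substr(cods, p, p), levels = nuc))
    as.numeric(f) / sum(f)
  }
  if (scheme == "f1x4") {
    f <- (posfreq(1) + posfreq(2) + posfreq(3)) / 3
    fmat <- matrix(f, 3, 4, byrow = TRUE, dimnames = list(NULL, nuc))
  } else {
    fmat <- rbind(posfreq(1), posfreq(2), posfreq(3))
    colnames(fmat) <- nuc
  }
  pi <- fmat[1, substr(sense, 1, 1)] *
        fmat[2, substr(sense, 2, 2)] *
        fmat[3, substr(sense, 3, 3)]
  pi <- pmax(pi, floor)
  pi <- pi / sum(pi)
  names(pi) <- sense
  pi
}

#' Codon substitution rate matrix
#'
#' Builds the generator matrix Q over the sense codons of a genetic code for
#' the standard codon model: the rate from codon i to codon j is zero if the
#' codons differ at more than one nucleotide position, and otherwise
#' proportional to the target frequency `pi[j]`, multiplied by `kappa` for a
#' transition and by `omega` for a nonsynonymous change.  The diagonal is set
#' so rows sum to zero and the matrix is rescaled so the expected number of
#' substitutions per codon per unit time at equilibrium is one.
#'
#' In a mixture of site classes the classes must share one time scale, so
#' that high-omega classes accumulate proportionally more substitutions per
#' branch; [codon_loglik()] and the simulator therefore rescale the class
#' generators by the mixture-average rate rather than per class.  The
#' unscaled per-unit-time rate is kept in the `"rate"` attribute for that
#' purpose.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi equilibrium frequency vector over the sense codons.
#' @param code a [genetic_code()].
#' @param scale if `TRUE` (single-model convention) rescale so the expected
#'   number of substitutions per codon per unit time at equilibrium is 1.
#' @return the generator matrix with attributes `pi`, `kappa`, `omega`,
#'   `rate` (the pre-scaling equilibrium rate).
#' @export
build_rate_matrix <- function(kappa, omega, pi, code = genetic_code(2),
                              scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == length(code$sense))
  types <- single_step_types(code)
  mult <- c(1, kappa, omega, kappa * omega)
  Q <- matrix(0, nrow(types), ncol(types), dimnames = dimnames(types))
  nz <- types > 0L
  Q[nz] <- mult[types[nz]]
  Q <- Q * rep(pi, each = nrow(Q))   # q_ij ~ pi_j
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (scale && rate > 0) Q <- Q / rate
  structure(Q, pi = pi, kappa = kappa, omega = omega, rate = rate)
}

# Eigendecomposition of the reversible generator via its symmetrized form
# B = D^{1/2} Q D^{-1/2}; P(t) = D^{-1/2} V exp(Lambda t) V' D^{1/2}.
decompose_generator <- function(Q, pi = attr(Q, "pi")) {
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))
  e <- cpp_sym_eig(B)
  list(V = e$vectors, lambda = e$values, sqpi = sq, pi = as.numeric(pi))
}

#' Transition probability matrix
#'
#' Computes P(t) = exp(Qt) through the eigendecomposition of the reversible
#' generator.
#'
#' @param Q generator from [build_rate_matrix()].
#' @param t branch length (>= 0), expected substitutions per codon.
#' @return stochastic matrix of codon transition probabilities.
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("branch length must be non-negative")
  d <- decompose_generator(Q)
  P <- cpp_pmat(d$V, d$lambda, d$sqpi, t)
  dimnames(P) <- dimnames(Q)
  P
}

#' Discretize a beta distribution of omega
#'
#' Equal-probability discretization of Beta(p, q) into `K` categories, each
#' represented by its bin median (the quantile at the bin midpoint), as used
#' by the M7 and M8 site models.
#'
#' @param p,q beta shape parameters (> 0).
#' @param K number of categories.
#' @return `data.frame` with columns `omega` (in (0,1)) and `weight`
#'   (all `1/K`).
#' @export
discretize_beta <- function(p, q, K = 10L) {
  stopifnot(p > 0, q > 0, K >= 1)
  omega <- stats::qbeta((seq_len(K) - 0.5) / K, p, q)
  omega <- pmin(pmax(omega, 1e-9), 1 - 1e-9)
  data.frame(omega = omega, weight = rep(1 / K, K))
}
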