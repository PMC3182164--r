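# Statistical coupling analysis of amino-acid alignments.
#
# Per-site statistical energy: with y_x the count of amino acid x at site i,
# n_i the non-gap count, and g_x the reference frequency of x,
#   dG_i = kT* * sqrt( sum_x [ ln Binom(y_x; n_i, g_x) ]^2 ),  kT* = 1/M,
# where M is the number of sequences in the MSA.  The coupling energy after
# perturbing at a focal site i (sub-sampling on its modal residue) is
#   ddG_{i,j} = kT* * sqrt( sum_x [ ln P_x^{j|di} - ln P_x^{j} ]^2 ),
# the change in the site-j log binomial probability vector.  Log
# probabilities are evaluated exactly on the log scale, so rare residues at
# large n do not underflow.

#' Reference amino-acid frequencies
#'
#' Pools residue counts over all positions of a sequence collection (gaps
#' excluded), floors each of the 20 frequencies and renormalizes, giving the
#' background distribution that the statistical energy compares against.
#'
#' @param seqs an [amino_msa()], a character matrix, or a character vector
#'   of sequences.
#' @param floor minimum frequency per residue.
#' @return object of class `"reference_freqs"`: list with `g` (named
#'   20-vector summing to 1) and `n_source` (number of source sequences).
#' @export
reference_frequencies <- function(seqs, floor = 1e-6) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    seqs <- amino_msa(seqs)
  } else if (!inherits(seqs, "amino_msa")) {
    seqs <- amino_msa(seqs)
  }
  cnt <- table(factor(unclass(seqs), levels = AA20))
  if (sum(cnt) == 0) stop("no residues in reference sequence collection")
  g <- pmax(as.numeric(cnt) / sum(cnt), floor)
  g <- g / sum(g)
  names(g) <- AA20
  structure(list(g = g, n_source = nrow(seqs)), class = "reference_freqs")
}

# 20 x L matrix of residue counts per column
site_counts <- function(msa) {
  apply(unclass(msa), 2, function(col) {
    table(factor(col, levels = AA20))
  })
}

# log binomial probability vector at one site: ln Binom(y_x; n, g_x)
log_binom_vec <- function(y, n, g) stats::dbinom(y, n, g, log = TRUE)

#' Per-site statistical energy profile
#'
#' @param msa an [amino_msa()] with at least two sequences.
#' @param ref a [reference_frequencies()] object.
#' @return object of class `"energy_profile"`: `data.frame` with columns
#'   `site`, `n` (non-gap count) and `dG` (`NA` for all-gap columns), with
#'   attributes `kT_star` (= 1/M), `M` and the per-site count matrix.
#' @export
site_energy <- function(msa, ref) {
  M <- nrow(msa)
  if (M < 2) stop("statistical energy needs an MSA of at least 2 sequences")
  cnt <- site_counts(msa)
  n <- colSums(cnt)
  kT <- 1 / M
  dG <- vapply(seq_len(ncol(cnt)), function(j) {
    if (n[j] == 0) return(NA_real_)
    lp <- log_binom_vec(cnt[, j], n[j], ref$g)
    kT * sqrt(sum(lp^2))
  }, 0)
  structure(data.frame(site = seq_len(ncol(cnt)), n = n, dG = dG),
            kT_star = kT, M = M, counts = cnt, class = c("energy_profile",
                                                         "data.frame"))
}

#' Perturb an MSA at a focal site
#'
#' Sub-samples the alignment to the sequences carrying the most common
#' (modal) residue at the focal site.  Ties for the modal residue are broken
#' alphabetically, with a warning.
#'
#' @param msa an [amino_msa()].
#' @param site focal column index.
#' @return list with `msa` (the sub-MSA), `residue` (modal residue) and
#'   `s` (number of sequences retained, the perturbation size).
#' @export
perturb <- function(msa, site) {
  col <- unclass(msa)[, site]
  cnt <- table(factor(col[col %in% AA20], levels = AA20))
  if (sum(cnt) == 0) stop("focal site ", site, " is all-gap")
  top <- which(cnt == max(cnt))
  if (length(top) > 1) {
    warning("modal residue tie at site ", site, " (",
            paste(names(cnt)[top], collapse = "/"),
            "); choosing alphabetically first")
  }
  res <- names(cnt)[top[1]]
  keep <- which(col == res)
  list(msa = amino_msa(unclass(msa)[keep, , drop = FALSE]),
       residue = res, s = length(keep))
}

#' Coupling energy profile for one perturbation
#'
#' Compares the site-wise log binomial probability vectors of the sub-MSA
#' (after perturbation at a focal site) against those of the full MSA.  The
#' energy unit kT* = 1/M uses the full MSA size, so the identity
#' perturbation gives exactly zero everywhere.
#'
#' @param msa the full [amino_msa()].
#' @param sub_msa the perturbed sub-MSA (rows must be a subset of `msa`).
#' @param ref a [reference_frequencies()].
#' @param sites columns at which to evaluate the coupling energy (typically
#'   the low-dG half of the variable sites).
#' @return `data.frame` with columns `site` and `ddG` (`NA` where either
#'   alignment is all-gap at the site), with attribute `unreliable` set to
#'   `TRUE` when the sub-MSA holds fewer than 2 sequences.
#' @export
coupling_energy <- function(msa, sub_msa, ref, sites) {
  stopifnot(length(sites) >= 1)
  M <- nrow(msa)
  kT <- 1 / M
  unreliable <- nrow(sub_msa) < 2
  if (unreliable) {
    warning("perturbed sub-MSA has fewer than 2 sequences; ",
            "coupling energies flagged unreliable")
  }
  cnt_full <- site_counts(msa)
  cnt_sub <- site_counts(sub_msa)
  nf <- colSums(cnt_full)
  ns <- colSums(cnt_sub)
  ddG <- vapply(sites, function(j) {
    if (nf[j] == 0 || ns[j] == 0) return(NA_real_)
    lp_full <- log_binom_vec(cnt_full[, j], nf[j], ref$g)
    lp_sub <- log_binom_vec(cnt_sub[, j], ns[j], ref$g)
    kT * sqrt(sum((lp_sub - lp_full)^2))
  }, 0)
  structure(data.frame(site = sites, ddG = ddG), unreliable = unreliable)
}

#' Variable columns of an MSA
#' @param msa an [amino_msa()].
#' @return integer vector of columns with at least two distinct non-gap
#'   residues.
#' @export
variable_sites <- function(msa) {
  which(apply(unclass(msa), 2, function(col) {
    length(unique(col[col %in% AA20])) >= 2
  }))
}

#' Low-energy analysis set
#'
#' Ranks the variable sites by statistical energy and keeps the lowest
#' fraction — the weakly constrained sites at which coupling energies are
#' evaluated.
#'
#' @param profile an [site_energy()] profile.
#' @param msa the [amino_msa()] the profile came from.
#' @param fraction fraction of variable sites retained (default one half).
#' @return sorted integer vector of column indices.
#' @export
analysis_sites <- function(profile, msa, fraction = 0.5) {
  vs <- variable_sites(msa)
  vs <- vs[!is.na(profile$dG[vs])]
  keep <- ceiling(length(vs) * fraction)
  sort(vs[order(profile$dG[vs])][seq_len(keep)])
}

#' Half-deletion robustness diagnostic
#'
#' Randomly deletes half of the sequences (floor(M/2)) and recomputes the
#' statistical energy, `n_reps` times; a suitable MSA gives replicate means
#' close to the full-MSA values with small spread.
#'
#' @param msa an [amino_msa()] with at least 4 sequences.
#' @param ref a [reference_frequencies()].
#' @param sites columns to report.
#' @param n_reps number of replicates.
#' @param seed integer seed for the random deletions.
#' @return `data.frame` with columns `site`, `dG_full`, `mean`, `sd`.
#' @export
half_deletion_diagnostic <- function(msa, ref, sites, n_reps = 10L,
                                     seed = 1L) {
  M <- nrow(msa)
  stopifnot(M >= 4, n_reps >= 2)
  full <- site_energy(msa, ref)
  set.seed(seed)
  reps <- vapply(seq_len(n_reps), function(r) {
    drop <- sample.int(M, floor(M / 2))
    sub <- amino_msa(unclass(msa)[-drop, , drop = FALSE])
    site_energy(sub, ref)$dG[sites]
  }, numeric(length(sites)))
  reps <- matrix(reps, nrow = length(sites))
  data.frame(site = sites, dG_full = full$dG[sites],
             mean = rowMeans(reps), sd = apply(reps, 1, stats::sd))
}

#' Size-matched subsampling diagnostic
#'
#' For each focal site, draws random subsets whose size equals the
#' perturbation size s at that site (the count of its modal residue) and
#' reports the spread of the site's statistical energy across subsets,
#' against the full-MSA value.
#'
#' @inheritParams half_deletion_diagnostic
#' @param focal_sites focal columns (each must have perturbation size >= 2).
#' @return `data.frame` with columns `site`, `s`, `dG_full`, `mean`, `sd`.
#' @export
size_matched_diagnostic <- function(msa, ref, focal_sites, n_reps = 10L,
                                    seed = 1L) {
  M <- nrow(msa)
  full <- site_energy(msa, ref)
  set.seed(seed)
  rows <- lapply(focal_sites, function(fs) {
    s <- perturb(msa, fs)$s
    if (s < 2) stop("perturbation size at site ", fs, " is below 2")
    dg <- vapply(seq_len(n_reps), function(r) {
      keep <- sample.int(M, s)
      sub <- amino_msa(unclass(msa)[keep, , drop = FALSE])
      site_energy(sub, ref)$dG[fs]
    }, 0)
    data.frame(site = fs, s = s, dG_full = full$dG[fs],
               mean = mean(dg), sd = stats::sd(dg))
  })
  do.call(rbind, rows)
}

#' Phylogenetic-disparity subsample
#'
#' Greedy scan in input order keeping a sequence only if its uncorrected
#' p-distance (mismatches over shared non-gap columns) to every sequence
#' already kept exceeds the threshold.  Pairs sharing no non-gap column are
#' treated as maximally distant.
#'
#' @param msa an [amino_msa()].
#' @param min_dissimilarity p-distance threshold in (0, 1).
#' @return the reduced [amino_msa()], with attribute `kept` (row indices).
#' @export
disparity_subsample <- function(msa, min_dissimilarity = 0.05) {
  stopifnot(min_dissimilarity > 0, min_dissimilarity < 1)
  m <- unclass(msa)
  M <- nrow(m)
  kept <- integer(0)
  for (i in seq_len(M)) {
    ok <- TRUE
    for (k in kept) {
      if (p_distance(m[i, ], m[k, ]) <= min_dissimilarity) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- amino_msa(m[kept, , drop = FALSE])
  attr(out, "kept") <- kept
  out
}

# uncorrected p-distance between two aligned sequences
p_distance <- function(a, b) {
  shared <- a %in% AA20 & b %in% AA20
  if (!any(shared)) return(1)
  mean(a[shared] != b[shared])
}
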