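# Orchestration of the two analysis tracks and the tabular report surface.

# Starting points that embed a fitted null model into a richer model, so
# every alternative fit begins at (essentially) the null optimum and the
# nesting inequalities hold by construction.
embed_start <- function(fit, model) {
  p <- fit$params
  kap <- fit$kappa
  eps <- 1e-8
  switch(model,
    M1a = list(p0 = 0.95, w0 = min(p$w, 0.95), kappa = kap),
    M2a = list(p0 = p$p0 * (1 - eps), p1 = (1 - p$p0) * (1 - eps),
               w0 = p$w0, w2 = 2, kappa = kap),
    M3 = list(p0 = 1 / 3, p1 = 1 / 3, w = rep(max(p$w, 1e-6), 3),
              kappa = kap),
    M8 = list(p0 = 1 - eps, p = p$p, q = p$q, ws = 2, kappa = kap),
    Anull = list(p0 = p$p0 * (1 - eps), p1 = (1 - p$p0) * (1 - eps),
                 w0 = p$w0, kappa = kap),
    Aalt = list(p0 = p$p0, p1 = p$p1, w0 = p$w0, w2 = 1 + 1e-8,
                kappa = kap),
    stop("no embedding into ", model))
}

#' Run the codon-model selection scan
#'
#' Fits the M-series site models (M0, M1a, M2a, M3, M7, M8) and, when a
#' foreground taxon is given, branch-site Model A (null and alternative);
#' runs the standard likelihood-ratio contrasts (M0-M1a, M1a-M2a, M0-M3,
#' M7-M8 and the branch-site test); and reports positively selected sites.
#' A site is reported as under long-term selection when its M8 posterior
#' probability of the omega > 1 class exceeds the threshold and an explicit
#' site-model LRT (M1a-M2a or M7-M8) is significant; as under episodic
#' selection when flagged the same way by the branch-site alternative with
#' a significant branch-site LRT.  Sites are reported as (gene, within-gene
#' position) through the alignment's gene map.
#'
#' Branch lengths are estimated jointly once under M0 and rescaled by a free
#' tree-scale factor under every other model; each alternative model starts
#' from its null's optimum plus deterministic spread starts.
#'
#' @param aln a [codon_alignment()].
#' @param tree a `phylo` tree over the alignment taxa.
#' @param foreground tip label for the branch-site foreground branch
#'   (`NULL` skips the branch-site track).
#' @param freq_scheme codon frequency scheme.
#' @param pp_threshold posterior probability cutoff for selected sites.
#' @param alpha significance level for the gating LRTs.
#' @param K beta categories for M7/M8.
#' @param method site identification method for the reported PP column
#'   (`"BEB"` with NEB also reported).
#' @param n_starts deterministic multi-start count per fit.
#' @return object of class `"scan_report"`: list with `fits`, `lrt`,
#'   `sites`, `config`.
#' @export
run_selection_scan <- function(aln, tree, foreground = NULL,
                               freq_scheme = "f3x4", pp_threshold = 0.90,
                               alpha = 0.05, K = 10L, method = "BEB",
                               n_starts = 2L) {
  pi <- codon_frequencies(aln, freq_scheme)
  fits <- list()
  fits$M0 <- fit_model(aln, tree, "M0", pi = pi, branch_mode = "joint",
                       n_starts = n_starts)
  # chain each alternative from its null: the null's fitted tree (and kappa)
  # seed the start, so nested lnL orderings hold by construction
  fit_sub <- function(model, null_fit) {
    fit_model(aln, tree, model, pi = pi, base_fit = null_fit,
              foreground = if (model %in% c("Anull", "Aalt")) foreground,
              K = K, start = list(embed_start(null_fit, model)),
              n_starts = n_starts)
  }
  fits$M1a <- fit_sub("M1a", fits$M0)
  fits$M2a <- fit_sub("M2a", fits$M1a)
  fits$M3 <- fit_sub("M3", fits$M0)
  fits$M7 <- fit_model(aln, tree, "M7", pi = pi, base_fit = fits$M0, K = K,
                       n_starts = max(n_starts, 2L))
  fits$M8 <- fit_sub("M8", fits$M7)
  if (!is.null(foreground)) {
    fits$Anull <- fit_sub("Anull", fits$M1a)
    fits$Aalt <- fit_sub("Aalt", fits$Anull)
  }

  pairs <- list(c("M0", "M1a"), c("M1a", "M2a"), c("M0", "M3"),
                c("M7", "M8"))
  if (!is.null(foreground)) pairs <- c(pairs, list(c("Anull", "Aalt")))
  lrt <- do.call(rbind, lapply(pairs, function(pr) {
    t <- likelihood_ratio_test(fits[[pr[1]]], fits[[pr[2]]])
    data.frame(null = pr[1], alt = pr[2], stat = t$stat, df = t$df,
               p = t$p, stringsAsFactors = FALSE)
  }))

  site_rows <- list()
  long_gate <- with(lrt, any(p[alt %in% c("M2a", "M8")] < alpha))
  if (long_gate) {
    neb <- site_posteriors(fits$M8, "NEB", pp_threshold)
    beb <- site_posteriors(fits$M8, "BEB", pp_threshold)
    sel <- beb$selected$site
    if (length(sel)) {
      site_rows$long <- data.frame(
        site = sel, NEB = neb$pp_selected[sel], BEB = beb$pp_selected[sel],
        type = "long-term", stringsAsFactors = FALSE)
    }
  }
  if (!is.null(foreground)) {
    bs_gate <- lrt$p[lrt$alt == "Aalt"] < alpha
    if (bs_gate) {
      neb <- site_posteriors(fits$Aalt, "NEB", pp_threshold)
      beb <- site_posteriors(fits$Aalt, "BEB", pp_threshold)
      sel <- beb$selected$site
      if (length(sel)) {
        site_rows$epi <- data.frame(
          site = sel, NEB = neb$pp_selected[sel],
          BEB = beb$pp_selected[sel], type = "episodic",
          stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(site = integer(0), NEB = numeric(0), BEB = numeric(0),
               type = character(0), stringsAsFactors = FALSE)
  gm <- attr(aln, "gene_map")
  loc <- site_to_gene(sites$site, gm)
  sites <- cbind(gene = loc$gene, position = loc$position, sites)
  rownames(sites) <- NULL

  structure(list(
    fits = fits, lrt = lrt, sites = sites,
    config = list(freq_scheme = freq_scheme, pp_threshold = pp_threshold,
                  alpha = alpha, K = K, foreground = foreground,
                  code_id = attr(aln, "code")$code_id)),
    class = "scan_report")
}

# concatenated codon-site index -> (gene, 1-based within-gene position)
site_to_gene <- function(sites, gene_map) {
  if (!length(sites)) {
    return(data.frame(gene = character(0), position = integer(0)))
  }
  gi <- vapply(sites, function(s) {
    which(gene_map$start <= s & gene_map$end >= s)[1]
  }, 0L)
  data.frame(gene = gene_map$gene[gi],
             position = as.integer(sites - gene_map$start[gi] + 1L),
             stringsAsFactors = FALSE)
}

#' @export
print.scan_report <- function(x, ...) {
  cat("Selection scan (", x$config$freq_scheme, " frequencies)\n", sep = "")
  for (f in x$fits) {
    cat(sprintf("  %-5s lnL = %12.3f  kappa = %6.3f\n", f$model, f$lnL,
                f$kappa))
  }
  cat("LRTs:\n")
  print(x$lrt, row.names = FALSE)
  cat(nrow(x$sites), "selected site(s)\n")
  if (nrow(x$sites)) print(x$sites, row.names = FALSE)
  invisible(x)
}

#' Robustness scans over frequency schemes and topologies
#'
#' Repeats the selection scan under each codon-frequency scheme and each
#' supplied tree topology, to check that the same sites are identified with
#' similar posterior probabilities regardless of those modeling choices.
#'
#' @param aln a [codon_alignment()].
#' @param trees list of `phylo` trees (alternative topologies).
#' @param foreground tip label for the branch-site foreground.
#' @param freq_schemes character vector of schemes to try.
#' @param ... passed to [run_selection_scan()].
#' @return named list of `"scan_report"` objects, one per
#'   `scheme:topology` combination.
#' @export
run_robustness_scans <- function(aln, trees, foreground = NULL,
                                 freq_schemes = c("f3x4", "f1x4", "fequal"),
                                 ...) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  out <- list()
  for (sc in freq_schemes) {
    for (tn in names(trees)) {
      out[[paste(sc, tn, sep = ":")]] <-
        run_selection_scan(aln, trees[[tn]], foreground = foreground,
                           freq_scheme = sc, ...)
    }
  }
  out
}

#' Run the statistical coupling track
#'
#' Computes the per-site statistical energy profile, restricts attention to
#' the lowest-`low_dg_fraction` of the variable sites by energy, perturbs
#' the alignment at each focal site, and emits one coupling-energy track per
#' focal site together with the three alignment-suitability diagnostics
#' (half-deletion, size-matched subsampling, and the phylogenetic-disparity
#' subsample audit).
#'
#' @param msa an [amino_msa()].
#' @param ref a [reference_frequencies()].
#' @param focal_sites columns at which to perturb (e.g. the positively
#'   selected sites, in MSA coordinates).
#' @param low_dg_fraction fraction of variable sites analyzed.
#' @param low_dg_cutoff absolute energy cutoff defining the "weakly
#'   constrained" site list used by the half-deletion diagnostic.
#' @param n_reps diagnostic replicate count.
#' @param min_dissimilarity p-distance threshold for the disparity
#'   subsample.
#' @param seed integer seed for the randomized diagnostics.
#' @return object of class `"sca_report"`.
#' @export
run_sca <- function(msa, ref, focal_sites, low_dg_fraction = 0.5,
                    low_dg_cutoff = 0.3, n_reps = 10L,
                    min_dissimilarity = 0.05, seed = 1L) {
  profile <- site_energy(msa, ref)
  asites <- analysis_sites(profile, msa, low_dg_fraction)
  tracks <- list()
  sizes <- integer(0)
  for (fs in focal_sites) {
    if (is.na(profile$dG[fs])) {
      warning("focal site ", fs, " is all-gap; skipped")
      next
    }
    pt <- perturb(msa, fs)
    tracks[[as.character(fs)]] <- coupling_energy(msa, pt$msa, ref, asites)
    sizes[as.character(fs)] <- pt$s
  }
  diag_sites <- profile$site[!is.na(profile$dG) &
                             profile$dG < low_dg_cutoff]
  diag_sites <- intersect(diag_sites, variable_sites(msa))
  if (!length(diag_sites)) diag_sites <- utils::head(asites, 10)
  s1 <- half_deletion_diagnostic(msa, ref, diag_sites, n_reps, seed)
  disp <- disparity_subsample(msa, min_dissimilarity)
  s1$dG_disparity <- site_energy(disp, ref)$dG[diag_sites]
  s2 <- size_matched_diagnostic(msa, ref,
                                as.integer(names(tracks)), n_reps, seed)
  structure(list(
    profile = profile, analyzed_sites = asites, tracks = tracks,
    perturbation_sizes = sizes,
    diagnostics = list(half_deletion = s1, size_matched = s2),
    disparity = list(kept = attr(disp, "kept"),
                     n_kept = nrow(disp), n_full = nrow(msa)),
    config = list(low_dg_fraction = low_dg_fraction,
                  low_dg_cutoff = low_dg_cutoff, n_reps = n_reps,
                  min_dissimilarity = min_dissimilarity, seed = seed)),
    class = "sca_report")
}

#' @export
print.sca_report <- function(x, ...) {
  cat("SCA report: ", nrow(x$profile), " columns, ",
      length(x$analyzed_sites), " analyzed (low-dG) sites, ",
      length(x$tracks), " coupling track(s)\n", sep = "")
  cat("Disparity subsample kept ", x$disparity$n_kept, "/",
      x$disparity$n_full, " sequences\n", sep = "")
  invisible(x)
}

#' Map selected sites onto structural annotation
#'
#' Interval lookup of sites (1-based amino-acid positions within a gene)
#' against a feature table with closed intervals; sites outside every
#' feature are labeled `"unannotated"`.
#'
#' @param sites `data.frame` with columns `gene` and `position`.
#' @param annotation `data.frame` with columns `gene`, `feature`, `start`,
#'   `end`, `kind` (e.g. transmembrane / loop / piston-arm).
#' @param gene_lengths optional named vector of gene lengths (amino acids);
#'   a site beyond its gene's length is an error.
#' @return `data.frame` with one row per (site, matching feature), columns
#'   `gene`, `position`, `feature`, `kind`.
#' @export
map_sites_to_annotation <- function(sites, annotation, gene_lengths = NULL) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    gene <- sites$gene[i]
    pos <- sites$position[i]
    if (!is.null(gene_lengths) && gene %in% names(gene_lengths) &&
        pos > gene_lengths[[gene]]) {
      stop("site ", pos, " beyond length of gene ", gene)
    }
    hit <- annotation[annotation$gene == gene &
                      annotation$start <= pos & annotation$end >= pos, ,
                      drop = FALSE]
    out[[i]] <- if (nrow(hit)) {
      data.frame(gene = gene, position = pos, feature = hit$feature,
                 kind = hit$kind, stringsAsFactors = FALSE)
    } else {
      data.frame(gene = gene, position = pos, feature = "unannotated",
                 kind = "unannotated", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(0), position = integer(0),
                      feature = character(0), kind = character(0)))
  }
  do.call(rbind, out)
}

#' Read a transmembrane-domain annotation table
#'
#' Tab-separated table with columns `gene`, `feature`, `start`, `end`,
#' `kind` (1-based inclusive amino-acid coordinates).
#' @param path file path.
#' @return `data.frame`.
#' @export
read_tm_annotation <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "feature", "start", "end", "kind") %in% names(a)))
  stopifnot(all(a$start >= 1), all(a$end >= a$start))
  a
}

# ---- report serialization --------------------------------------------------

fmt_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(x) sprintf("%.10g", x))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read a selection scan report as TSV tables
#'
#' Emits `models.tsv` (per-model lnL, kappa and parameter estimates),
#' `lrt.tsv` and `sites.tsv` into a directory; the reader returns the three
#' tables with numeric columns restored.
#'
#' @param report a `"scan_report"`.
#' @param dir output directory (created if needed).
#' @export
write_scan_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  models <- do.call(rbind, lapply(report$fits, function(f) {
    data.frame(model = f$model, lnL = f$lnL, np = f$np, kappa = f$kappa,
               params = paste(names(unlist(f$params)),
                              sprintf("%.6g", unlist(f$params)),
                              sep = "=", collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  fmt_tsv(models, file.path(dir, "models.tsv"))
  fmt_tsv(report$lrt, file.path(dir, "lrt.tsv"))
  fmt_tsv(report$sites, file.path(dir, "sites.tsv"))
  invisible(dir)
}

#' @rdname write_scan_report
#' @export
read_scan_report <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE)
  list(models = rd("models.tsv"), lrt = rd("lrt.tsv"),
       sites = rd("sites.tsv"))
}

#' Write an SCA report as TSV tables
#'
#' Emits `profile.tsv` (site, n, dG), `tracks.tsv` (focal_site, site, ddG),
#' and the two diagnostic tables `diagnostic_half_deletion.tsv` /
#' `diagnostic_size_matched.tsv`.
#'
#' @param report an `"sca_report"`.
#' @param dir output directory.
#' @export
write_sca_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_tsv(report$profile, file.path(dir, "profile.tsv"))
  tracks <- do.call(rbind, lapply(names(report$tracks), function(fs) {
    cbind(focal_site = as.integer(fs), report$tracks[[fs]])
  }))
  if (is.null(tracks)) {
    tracks <- data.frame(focal_site = integer(0), site = integer(0),
                         ddG = numeric(0))
  }
  fmt_tsv(tracks, file.path(dir, "tracks.tsv"))
  fmt_tsv(report$diagnostics$half_deletion,
          file.path(dir, "diagnostic_half_deletion.tsv"))
  fmt_tsv(report$diagnostics$size_matched,
          file.path(dir, "diagnostic_size_matched.tsv"))
  invisible(dir)
}
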