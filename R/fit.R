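#' Fit a codon site model by maximum likelihood
#'
#' Maximizes the mixture codon-model likelihood over the model's class
#' parameters, the transition/transversion ratio kappa, and the branch
#' lengths.  Parameters are optimized in unconstrained space (log for kappa
#' and branch lengths, logit for proportions and omegas bounded in (0,1),
#' `1 + exp()` for omegas bounded below by 1) with `stats::nlminb` from
#' several deterministic starting points; the best solution is kept.
#'
#' Branch lengths are handled in one of three modes.  `"joint"` (the default
#' for M0) estimates every branch length freely.  `"scale"` fixes the
#' relative branch lengths to those of `base_fit` (or of the input tree) and
#' estimates a single tree-scale factor, which is how the mixture models are
#' fitted by default: the expensive joint estimation is done once under M0
#' and the richer models rescale that tree.  `"fixed"` holds the input
#' branch lengths.
#'
#' @param aln a [codon_alignment()].
#' @param tree a `phylo` tree over the alignment taxa.
#' @param model one of `"M0"`, `"M1a"`, `"M2a"`, `"M3"`, `"M7"`, `"M8"`,
#'   `"Anull"`, `"Aalt"`.
#' @param freq_scheme codon frequency scheme, see [codon_frequencies()].
#' @param pi optional explicit frequency vector (overrides `freq_scheme`).
#' @param K beta discretization categories for M7/M8.
#' @param foreground tip label(s) whose terminal branch is the foreground
#'   for branch-site models (required for `"Anull"`/`"Aalt"` unless the tree
#'   already carries foreground edges).
#' @param branch_mode `"auto"`, `"joint"`, `"scale"` or `"fixed"`.
#' @param base_fit an existing `"model_fit"` (typically M0) providing branch
#'   lengths for `"scale"` mode and a kappa starting value.
#' @param start optional list of extra starting points; each element is a
#'   list of natural-scale class parameters, optionally with `$kappa`.
#'   Extra starts are tried before the deterministic defaults.
#' @param n_starts how many of the model's deterministic default starts to
#'   try (0 to rely on `start` alone).
#' @param control passed to `stats::nlminb` (merged over sensible defaults).
#' @return an object of class `"model_fit"`.
#' @export
fit_model <- function(aln, tree, model = "M0",
                      freq_scheme = c("f3x4", "f1x4", "fequal"),
                      pi = NULL, K = 10L, foreground = NULL,
                      branch_mode = c("auto", "joint", "scale", "fixed"),
                      base_fit = NULL, start = NULL, n_starts = 3L,
                      kappa = NULL, control = list()) {
  model <- match.arg(model, MODEL_NAMES)
  freq_scheme <- match.arg(freq_scheme)
  branch_mode <- match.arg(branch_mode)
  code <- attr(aln, "code")
  if (is.null(pi)) pi <- codon_frequencies(aln, freq_scheme)

  if (!is.null(foreground)) tree <- set_foreground(tree, foreground)
  if (model %in% c("Anull", "Aalt") && is.null(tree$foreground)) {
    stop("branch-site models need foreground edges; ",
         "use `foreground =` or set_foreground()")
  }

  if (branch_mode == "auto") {
    if (model == "M0" && is.null(base_fit)) {
      branch_mode <- "joint"
    } else {
      if (is.null(base_fit)) {
        base_fit <- fit_model(aln, tree, "M0", pi = pi,
                              branch_mode = "joint", n_starts = 2L)
      }
      branch_mode <- "scale"
    }
  }
  if (branch_mode == "scale" && !is.null(base_fit)) {
    tree$edge.length <- base_tree_lengths(base_fit, tree)
  }

  spec <- model_spec(model, K)
  pd <- pattern_data(aln, code)
  td <- tree_prune_data(tree)
  if (!setequal(td$tree$tip.label, pd$taxa)) {
    stop("tree tip labels do not match alignment taxa")
  }
  tip <- pd$tipstate[match(td$tree$tip.label, pd$taxa), , drop = FALSE]

  nedge <- nrow(td$edge)
  bl0 <- pmax(td$blen, 1e-8)
  nc <- length(spec$lower)
  est_kappa <- is.null(kappa)
  nk <- if (est_kappa) 1L else 0L

  decode <- function(theta) {
    par <- spec$from_theta(theta[seq_len(nc)])
    kap <- if (est_kappa) exp(theta[nc + 1]) else kappa
    blen <- switch(branch_mode,
                   joint = exp(theta[nc + nk + seq_len(nedge)]),
                   scale = bl0 * exp(theta[nc + nk + 1]),
                   fixed = bl0)
    list(par = par, kappa = kap, blen = blen)
  }
  obj <- function(theta) {
    d <- decode(theta)
    classes <- spec$classes(d$par, spec$K)
    td$blen <- d$blen
    r <- prune_mix(tip, pd$patwt, td, d$kappa, classes, pi, code)
    if (!is.finite(r$lnL)) return(1e10)
    -r$lnL
  }

  lower <- c(spec$lower, if (est_kappa) log(0.05),
             switch(branch_mode, joint = rep(log(1e-8), nedge),
                    scale = -8, fixed = numeric(0)))
  upper <- c(spec$upper, if (est_kappa) log(500),
             switch(branch_mode, joint = rep(log(60), nedge),
                    scale = 8, fixed = numeric(0)))

  kappa0 <- if (!is.null(base_fit)) base_fit$kappa else 2
  mk_theta <- function(s) {
    kap <- if (!is.null(s$kappa)) s$kappa else kappa0
    s$kappa <- NULL
    c(spec$to_theta(s), if (est_kappa) log(kap),
      switch(branch_mode, joint = log(bl0), scale = 0, fixed = numeric(0)))
  }
  starts <- c(start %||% list(),
              if (n_starts > 0) spec$starts[seq_len(min(n_starts, 3L))])
  if (length(starts) == 0) stop("no starting points")

  ctl <- utils::modifyList(
    list(iter.max = 500L, eval.max = 4000L, rel.tol = 1e-10), control)
  best <- NULL
  for (s in starts) {
    th0 <- pmin(pmax(mk_theta(s), lower), upper)
    res <- stats::nlminb(th0, obj, lower = lower, upper = upper,
                         control = ctl)
    # guard against the rare non-monotone finish in flat directions: never
    # report worse than the starting point itself
    o0 <- obj(th0)
    if (o0 < res$objective) {
      res$objective <- o0
      res$par <- th0
    }
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (best$convergence != 0 &&
      !grepl("relative convergence|singular|both X", best$message %||% "")) {
    warning("optimizer flagged non-convergence for ", model, ": ",
            best$message)
  }

  d <- decode(best$par)
  classes <- spec$classes(d$par, spec$K)
  td$blen <- d$blen
  final <- prune_mix(tip, pd$patwt, td, d$kappa, classes, pi, code)
  fitted_tree <- td$tree
  fitted_tree$edge.length <- d$blen
  fitted_tree$foreground <- if (length(td$foreground)) td$foreground else NULL

  structure(list(
    model = model, lnL = -best$objective, np = spec$np,
    kappa = d$kappa, params = d$par, classes = classes,
    pi = pi, freq_scheme = freq_scheme, K = spec$K,
    tree = fitted_tree, branch_mode = branch_mode,
    site_lik = final$sitelik[pd$pat_of_site, , drop = FALSE],
    weights = classes$weight,
    convergence = best$convergence, message = best$message,
    n_starts = length(starts), aln = aln,
    code_id = code$code_id), class = "model_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# carry branch lengths of a fitted (postorder) tree onto `tree`'s edge order
base_tree_lengths <- function(base_fit, tree) {
  bt <- base_fit$tree
  key_b <- paste(bt$edge[, 1], bt$edge[, 2])
  key_t <- paste(tree$edge[, 1], tree$edge[, 2])
  idx <- match(key_t, key_b)
  if (anyNA(idx)) {
    stop("base_fit tree topology does not match the supplied tree")
  }
  bt$edge.length[idx]
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Codon model ", x$model, ": lnL = ", sprintf("%.3f", x$lnL),
      ", kappa = ", sprintf("%.3f", x$kappa), "\n", sep = "")
  cls <- x$classes
  cat("  classes (omega / weight):\n")
  for (i in seq_len(nrow(cls))) {
    cat(sprintf("    %d: omega = %.5f  weight = %.5f", i,
                cls$omega[i], cls$weight[i]))
    if (!is.null(cls$fg_omega)) {
      cat(sprintf("  foreground omega = %.4f", cls$fg_omega[i]))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
logLik.model_fit <- function(object, ...) {
  structure(object$lnL, df = object$np, class = "logLik")
}

#' Fit branch-site Model A
#'
#' Convenience wrapper around [fit_model()] for the branch-site test: the
#' null fixes the foreground omega at 1, the alternative frees it above 1.
#'
#' @inheritParams fit_model
#' @param null if `TRUE` fit the null model, else the alternative.
#' @param ... passed on to [fit_model()].
#' @return a `"model_fit"`.
#' @export
fit_branch_site <- function(aln, tree, foreground = NULL, null = TRUE, ...) {
  fit_model(aln, tree, model = if (null) "Anull" else "Aalt",
            foreground = foreground, ...)
}

#' Likelihood-ratio test between nested codon models
#'
#' Twice the log-likelihood difference (clipped at zero) referred to a
#' chi-square distribution whose degrees of freedom equal the difference in
#' the number of free model parameters (M0-M3: 4, M1a-M2a: 2, M7-M8: 2,
#' Model A null-alternative: 1).
#'
#' @param null_fit,alt_fit `"model_fit"` objects forming a nested pair.
#' @return list with `stat` (2 delta lnL), `df` and `p`.
#' @export
likelihood_ratio_test <- function(null_fit, alt_fit) {
  ok <- alt_fit$model %in% (NESTED_PAIRS[[null_fit$model]] %||% character(0))
  if (!ok) {
    stop(null_fit$model, " is not nested in ", alt_fit$model)
  }
  stat <- max(0, 2 * (alt_fit$lnL - null_fit$lnL))
  df <- alt_fit$np - null_fit$np
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       null = null_fit$model, alt = alt_fit$model)
}
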