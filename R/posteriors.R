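# Pattern-level site likelihoods under arbitrary class structures at the
# fitted kappa, branch lengths and codon frequencies.  `classes` is a
# class_table(); weights are ignored (conditional likelihoods per class).
pattern_class_liks <- function(fit, classes) {
  code <- attr(fit$aln, "code")
  pd <- pattern_data(fit$aln, code)
  td <- tree_prune_data(fit$tree)
  tip <- pd$tipstate[match(td$tree$tip.label, pd$taxa), , drop = FALSE]
  classes$weight <- rep(1 / nrow(classes), nrow(classes))
  r <- prune_mix(tip, pd$patwt, td, fit$kappa, classes, fit$pi, code)
  list(L = r$sitelik, patwt = pd$patwt, pat_of_site = pd$pat_of_site)
}

#' Per-site posterior probabilities of omega classes
#'
#' Naive empirical Bayes (NEB) applies Bayes' rule to the per-class site
#' likelihoods at the maximum-likelihood estimates, treating the estimates
#' as known without error.  Bayes empirical Bayes (BEB) instead averages the
#' posterior over a discrete uniform grid prior on the class parameters
#' (proportions, the omegas, and the beta shapes for M8), which accounts for
#' their sampling error; it is available for the models with an omega > 1
#' class (M2a, M8 and the branch-site Model A alternative).  A site is
#' reported as positively selected when its posterior probability of
#' belonging to an omega > 1 class exceeds `threshold`.
#'
#' @param fit a `"model_fit"`.
#' @param method `"NEB"` or `"BEB"`.
#' @param threshold posterior probability cutoff for the selected-site list.
#' @param grid_points BEB grid resolution per free prior dimension.
#' @return object of class `"site_posteriors"`: list with `pp_selected`
#'   (per-site posterior of the omega > 1 class; zero-filled when the model
#'   has none), `class_post` (sites x classes NEB matrix; `NULL` for BEB),
#'   `selected` (`data.frame` of sites above threshold) and bookkeeping.
#' @export
site_posteriors <- function(fit, method = c("NEB", "BEB"), threshold = 0.90,
                            grid_points = 10L) {
  method <- match.arg(method)
  sel_class <- selected_classes(fit)
  if (method == "NEB") {
    w <- fit$weights
    num <- sweep(fit$site_lik, 2, w, `*`)
    post <- num / rowSums(num)
    pp <- if (length(sel_class)) {
      rowSums(post[, sel_class, drop = FALSE])
    } else {
      rep(0, nrow(post))
    }
    class_post <- post
  } else {
    if (!length(sel_class)) {
      pp <- rep(0, nrow(fit$site_lik))
    } else {
      pp <- switch(fit$model,
                   M2a = beb_m2a(fit, grid_points),
                   M8 = beb_m8(fit, grid_points),
                   Aalt = beb_branch_site(fit, grid_points),
                   stop("BEB is implemented for M2a, M8 and Aalt (got ",
                        fit$model, ")"))
    }
    class_post <- NULL
  }
  sel <- which(pp > threshold)
  structure(list(
    pp_selected = pp, class_post = class_post, method = method,
    threshold = threshold, model = fit$model,
    selected = data.frame(site = sel, pp = pp[sel])),
    class = "site_posteriors")
}

# classes whose (foreground) omega estimate exceeds 1
selected_classes <- function(fit) {
  cls <- fit$classes
  om <- if (!is.null(cls$fg_omega)) cls$fg_omega else cls$omega
  which(om > 1)
}

#' @export
print.site_posteriors <- function(x, ...) {
  cat("Site posteriors (", x$method, ", model ", x$model, "): ",
      nrow(x$selected), " site(s) with PP > ", x$threshold, "\n", sep = "")
  if (nrow(x$selected)) print(x$selected, row.names = FALSE)
  invisible(x)
}

# ---- BEB machinery ---------------------------------------------------------
# Uniform grid priors, `g` points per free dimension, at midpoints:
#   proportions: p0 (and p1 via the simplex triangle where applicable),
#   omega0 ~ U(0,1), omega_s / omega2 ~ U(1,11), beta shapes p,q ~ U(0,2).
# The posterior of the selected class at site h is averaged over the grid
# with weights proportional to the marginal likelihood of the whole
# alignment at each grid point (computed from the fitted kappa, branch
# lengths and codon frequencies).

grid_mid <- function(a, b, g) a + (b - a) * (seq_len(g) - 0.5) / g

# accumulate sum over theta of w_theta * ppsel_h given per-theta closures
beb_average <- function(thetas, loglik_fun, ppsel_fun, patwt, pat_of_site) {
  logml <- vapply(thetas, loglik_fun, 0)
  wts <- exp(logml - max(logml))
  wts <- wts / sum(wts)
  acc <- 0
  for (i in seq_along(thetas)) {
    if (wts[i] > 1e-12) acc <- acc + wts[i] * ppsel_fun(thetas[[i]])
  }
  acc[pat_of_site]
}

simplex_triangle <- function(g) {
  pts <- expand.grid(i = seq_len(g), j = seq_len(g))
  p0 <- (pts$i - 0.5) / g
  p1 <- (pts$j - 0.5) / g
  keep <- p0 + p1 < 1
  data.frame(p0 = p0[keep], p1 = p1[keep])
}

beb_m2a <- function(fit, g = 10L) {
  w0g <- grid_mid(0, 1, g)
  w2g <- grid_mid(1, 11, g)
  cl <- class_table(c(w0g, 1, w2g), rep(1, 2 * g + 1))
  pl <- pattern_class_liks(fit, cl)
  L0 <- pl$L[, seq_len(g), drop = FALSE]
  L1 <- pl$L[, g + 1]
  L2 <- pl$L[, g + 1 + seq_len(g), drop = FALSE]
  tri <- simplex_triangle(g)
  thetas <- list()
  for (t in seq_len(nrow(tri))) for (a in seq_len(g)) for (b in seq_len(g)) {
    thetas[[length(thetas) + 1L]] <- c(tri$p0[t], tri$p1[t], a, b)
  }
  f_of <- function(th) {
    th[1] * L0[, th[3]] + th[2] * L1 + (1 - th[1] - th[2]) * L2[, th[4]]
  }
  beb_average(
    thetas,
    loglik_fun = function(th) sum(pl$patwt * log(pmax(f_of(th), 1e-300))),
    ppsel_fun = function(th) {
      f <- pmax(f_of(th), 1e-300)
      (1 - th[1] - th[2]) * L2[, th[4]] / f
    },
    pl$patwt, pl$pat_of_site)
}

beb_m8 <- function(fit, g = 10L, K = 10L, snap_step = 0.005) {
  # snap beta bin medians to a fixed omega grid so all (p,q) grid points
  # share one batch of pruning passes (documented approximation knob)
  og <- seq(snap_step / 2, 1 - snap_step / 2, by = snap_step)
  pg <- grid_mid(0, 2, g)
  qg <- grid_mid(0, 2, g)
  wsg <- grid_mid(1, 11, g)
  p0g <- grid_mid(0, 1, g)
  pq <- expand.grid(p = pg, q = qg)
  snap <- lapply(seq_len(nrow(pq)), function(i) {
    om <- stats::qbeta((seq_len(K) - 0.5) / K, pq$p[i], pq$q[i])
    pmin(pmax(findInterval(om, og - snap_step / 2), 1L), length(og))
  })
  used <- sort(unique(unlist(snap)))
  cl <- class_table(c(og[used], wsg), rep(1, length(used) + g))
  pl <- pattern_class_liks(fit, cl)
  Lom <- pl$L[, seq_along(used), drop = FALSE]
  Lws <- pl$L[, length(used) + seq_len(g), drop = FALSE]
  Lbeta <- vapply(snap, function(ix) {
    rowMeans(Lom[, match(ix, used), drop = FALSE])
  }, numeric(nrow(Lom)))
  thetas <- list()
  for (i in seq_len(nrow(pq))) for (l in seq_len(g)) for (m in seq_len(g)) {
    thetas[[length(thetas) + 1L]] <- c(i, l, p0g[m])
  }
  f_of <- function(th) th[3] * Lbeta[, th[1]] + (1 - th[3]) * Lws[, th[2]]
  beb_average(
    thetas,
    loglik_fun = function(th) sum(pl$patwt * log(pmax(f_of(th), 1e-300))),
    ppsel_fun = function(th) {
      (1 - th[3]) * Lws[, th[2]] / pmax(f_of(th), 1e-300)
    },
    pl$patwt, pl$pat_of_site)
}

beb_branch_site <- function(fit, g = 10L) {
  w0g <- grid_mid(0, 1, g)
  w2g <- grid_mid(1, 11, g)
  pairs <- expand.grid(i = seq_len(g), j = seq_len(g))
  cl <- class_table(
    omega = c(w0g, 1, w0g[pairs$i], rep(1, g)),
    weight = rep(1, 2 * g + 1 + nrow(pairs)),
    fg_omega = c(w0g, 1, w2g[pairs$j], w2g))
  pl <- pattern_class_liks(fit, cl)
  L00 <- pl$L[, seq_len(g), drop = FALSE]           # class 0 at omega0_i
  L11 <- pl$L[, g + 1]                               # class 1
  L2a <- pl$L[, g + 1 + seq_len(nrow(pairs)), drop = FALSE]
  L2b <- pl$L[, g + 1 + nrow(pairs) + seq_len(g), drop = FALSE]
  pair_col <- matrix(seq_len(nrow(pairs)), g, g)     # [i, j]
  tri <- simplex_triangle(g)
  thetas <- list()
  for (t in seq_len(nrow(tri))) for (a in seq_len(g)) for (b in seq_len(g)) {
    thetas[[length(thetas) + 1L]] <- c(tri$p0[t], tri$p1[t], a, b)
  }
  parts <- function(th) {
    p0 <- th[1]; p1 <- th[2]; p2 <- 1 - p0 - p1
    w <- c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
    selpart <- w[3] * L2a[, pair_col[th[3], th[4]]] + w[4] * L2b[, th[4]]
    list(f = w[1] * L00[, th[3]] + w[2] * L11 + selpart, sel = selpart)
  }
  beb_average(
    thetas,
    loglik_fun = function(th) {
      sum(pl$patwt * log(pmax(parts(th)$f, 1e-300)))
    },
    ppsel_fun = function(th) {
      p <- parts(th)
      p$sel / pmax(p$f, 1e-300)
    },
    pl$patwt, pl$pat_of_site)
}
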