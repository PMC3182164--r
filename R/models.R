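# Site-model specifications: the M-series random-sites models and branch-site
# Model A.  Each spec knows its free class parameters (count follows the
# conventional parameter count for these models: M0 1, M1a 2, M2a 4, M3 5,
# M7 2, M8 4, Model A null 3 / alternative 4), the transform between natural
# and unconstrained optimizer space, and how to expand parameters into the
# mixture class table.

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

OMEGA_CAP <- 999        # upper bound on any omega during optimization
.W2 <- function(x) 1 + exp(x)            # omega > 1
.W2inv <- function(w) log(pmax(w - 1, 1e-9))

# stick-breaking for (p0, p1, p2) on the simplex
simplex3_to <- function(p0, p1) c(logit(p0), logit(p1 / (1 - p0)))
simplex3_from <- function(x) {
  p0 <- invlogit(x[1]); p1 <- (1 - p0) * invlogit(x[2])
  c(p0, p1, 1 - p0 - p1)
}

#' Site model catalogue
#'
#' @param model one of `"M0"`, `"M1a"`, `"M2a"`, `"M3"`, `"M7"`, `"M8"`,
#'   `"Anull"`, `"Aalt"` (branch-site Model A, null and alternative).
#' @param K number of beta discretization categories for M7/M8.
#' @return internal spec list (parameter transforms, class expansion,
#'   deterministic starting points).
#' @keywords internal
model_spec <- function(model, K = 10L) {
  BIG <- log(OMEGA_CAP)
  switch(model,
    M0 = list(
      model = "M0", np = 1L, K = 1L,
      to_theta = function(p) log(p$w),
      from_theta = function(x) list(w = exp(x[1])),
      lower = -18, upper = BIG,
      classes = function(p, K) class_table(p$w, 1),
      starts = list(list(w = 0.2), list(w = 0.02), list(w = 1))),
    M1a = list(
      model = "M1a", np = 2L, K = 2L,
      to_theta = function(p) c(logit(p$p0), logit(p$w0)),
      from_theta = function(x) list(p0 = invlogit(x[1]), w0 = invlogit(x[2])),
      lower = c(-18, -18), upper = c(18, 18),
      classes = function(p, K) class_table(c(p$w0, 1), c(p$p0, 1 - p$p0)),
      starts = list(list(p0 = 0.8, w0 = 0.1),
                    list(p0 = 0.95, w0 = 0.01),
                    list(p0 = 0.5, w0 = 0.5))),
    M2a = list(
      model = "M2a", np = 4L, K = 3L,
      to_theta = function(p) c(simplex3_to(p$p0, p$p1), logit(p$w0),
                               .W2inv(p$w2)),
      from_theta = function(x) {
        s <- simplex3_from(x[1:2])
        list(p0 = s[1], p1 = s[2], w0 = invlogit(x[3]), w2 = .W2(x[4]))
      },
      lower = c(-18, -18, -18, -20), upper = c(18, 18, 18, BIG),
      classes = function(p, K) class_table(c(p$w0, 1, p$w2),
                                           c(p$p0, p$p1, 1 - p$p0 - p$p1)),
      starts = list(list(p0 = 0.8, p1 = 0.15, w0 = 0.1, w2 = 2),
                    list(p0 = 0.9, p1 = 0.05, w0 = 0.05, w2 = 5),
                    list(p0 = 0.6, p1 = 0.3, w0 = 0.3, w2 = 1.5))),
    M3 = list(
      model = "M3", np = 5L, K = 3L,
      to_theta = function(p) c(simplex3_to(p$p0, p$p1), log(p$w)),
      from_theta = function(x) {
        s <- simplex3_from(x[1:2])
        list(p0 = s[1], p1 = s[2], w = exp(x[3:5]))
      },
      lower = c(-18, -18, rep(-15, 3)), upper = c(18, 18, rep(BIG, 3)),
      classes = function(p, K) class_table(p$w,
                                           c(p$p0, p$p1, 1 - p$p0 - p$p1)),
      starts = list(list(p0 = 0.7, p1 = 0.2, w = c(0.05, 0.5, 1.5)),
                    list(p0 = 0.34, p1 = 0.33, w = c(0.01, 0.2, 2)),
                    list(p0 = 0.9, p1 = 0.08, w = c(0.002, 0.1, 3)))),
    M7 = list(
      model = "M7", np = 2L, K = K,
      to_theta = function(p) log(c(p$p, p$q)),
      from_theta = function(x) list(p = exp(x[1]), q = exp(x[2])),
      lower = log(c(5e-3, 5e-3)), upper = log(c(99, 99)),
      classes = function(p, K) {
        b <- discretize_beta(p$p, p$q, K)
        class_table(b$omega, b$weight)
      },
      starts = list(list(p = 0.5, q = 2), list(p = 0.2, q = 1),
                    list(p = 1, q = 1))),
    M8 = list(
      model = "M8", np = 4L, K = K + 1L,
      to_theta = function(p) c(logit(p$p0), log(p$p), log(p$q),
                               .W2inv(p$ws)),
      from_theta = function(x) list(p0 = invlogit(x[1]), p = exp(x[2]),
                                    q = exp(x[3]), ws = .W2(x[4])),
      lower = c(-18, log(5e-3), log(5e-3), -20),
      upper = c(18, log(99), log(99), BIG),
      classes = function(p, K) {
        b <- discretize_beta(p$p, p$q, K - 1L)  # K counts the omega_s class
        class_table(c(b$omega, p$ws), c(b$weight * p$p0, 1 - p$p0))
      },
      starts = list(list(p0 = 0.9, p = 0.5, q = 2, ws = 2),
                    list(p0 = 0.99, p = 0.2, q = 1, ws = 4),
                    list(p0 = 0.8, p = 1, q = 1, ws = 1.5))),
    Anull = list(
      model = "Anull", np = 3L, K = 4L,
      to_theta = function(p) c(simplex3_to(p$p0, p$p1), logit(p$w0)),
      from_theta = function(x) {
        s <- simplex3_from(x[1:2])
        list(p0 = s[1], p1 = s[2], w0 = invlogit(x[3]), w2 = 1)
      },
      lower = c(-18, -18, -18), upper = c(18, 18, 18),
      classes = function(p, K) branch_site_classes(p),
      starts = list(list(p0 = 0.8, p1 = 0.1, w0 = 0.1),
                    list(p0 = 0.95, p1 = 0.04, w0 = 0.01),
                    list(p0 = 0.5, p1 = 0.4, w0 = 0.4))),
    Aalt = list(
      model = "Aalt", np = 4L, K = 4L,
      to_theta = function(p) c(simplex3_to(p$p0, p$p1), logit(p$w0),
                               .W2inv(p$w2)),
      from_theta = function(x) {
        s <- simplex3_from(x[1:2])
        list(p0 = s[1], p1 = s[2], w0 = invlogit(x[3]), w2 = .W2(x[4]))
      },
      lower = c(-18, -18, -18, -20), upper = c(18, 18, 18, BIG),
      classes = function(p, K) branch_site_classes(p),
      starts = list(list(p0 = 0.8, p1 = 0.1, w0 = 0.1, w2 = 3),
                    list(p0 = 0.95, p1 = 0.04, w0 = 0.01, w2 = 2),
                    list(p0 = 0.7, p1 = 0.2, w0 = 0.3, w2 = 10))),
    stop("unknown model: ", model)
  )
}

# Branch-site Model A class structure: four site classes.  Classes 0 and 1
# evolve with omega0 (<1) and 1 on all branches; classes 2a and 2b share the
# foreground omega2 on flagged edges while keeping omega0 / 1 on background
# edges.  The proportions of 2a and 2b split 1-p0-p1 in proportion p0:p1.
branch_site_classes <- function(p) {
  p2 <- 1 - p$p0 - p$p1
  ptot <- p$p0 + p$p1
  class_table(omega = c(p$w0, 1, p$w0, 1),
              weight = c(p$p0, p$p1, p2 * p$p0 / ptot, p2 * p$p1 / ptot),
              fg_omega = c(p$w0, 1, p$w2, p$w2))
}

MODEL_NAMES <- c("M0", "M1a", "M2a", "M3", "M7", "M8", "Anull", "Aalt")

# nested (null -> alternatives) pairs accepted by the LRT
NESTED_PAIRS <- list(M0 = c("M1a", "M2a", "M3"), M1a = "M2a",
                     M7 = "M8", Anull = "Aalt")
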