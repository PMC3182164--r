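---
title: "Codon-model selection scans and statistical coupling analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-model selection scans and statistical coupling analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mitosel` detects positive Darwinian selection in mitochondrial
protein-coding genes with maximum-likelihood codon substitution models, and
searches for co-evolving residues in the encoded proteins with a modified
statistical coupling analysis. This vignette is the package's account of
the underlying models, the choices made where the methods literature leaves
options open, and what the synthetic-data experiments do and do not
demonstrate.

## The codon substitution model

Codon sequences are modeled over the sense codons of a declared genetic
code — by default NCBI translation table 2 (vertebrate mitochondrial; 60
sense codons, with TGA = Trp, ATA = Met, and AGA/AGG as additional stops),
since every gene analyzed here is mtDNA-encoded. The instantaneous rate
from codon $i$ to codon $j$ is

$$q_{ij} \propto \begin{cases}
0 & \text{more than one position differs} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\kappa \omega \pi_j & \text{nonsynonymous transition,}
\end{cases}$$

where $\kappa > 0$ is the transition/transversion rate ratio,
$\omega = d_N/d_S \ge 0$ the selection parameter, and $\pi$ the equilibrium
codon frequencies (`fequal`, `f1x4`, or the default `f3x4`, estimated from
the nucleotide frequencies at each codon position separately; frequencies
are floored at $10^{-10}$ and renormalized so small alignments cannot
produce $-\infty$ log-likelihoods). The chain is time-reversible
($\pi_i q_{ij} = \pi_j q_{ji}$ by construction), so $P(t) = e^{Qt}$ is
computed stably through the eigendecomposition of the symmetrized
generator; branch lengths $t$ are expected numbers of substitutions per
codon.

**Shared time scale across mixture classes.** In the site models, $\omega$
varies across sites as a finite mixture. The class generators are rescaled
by a single factor — the mixture-weighted average of the class
equilibrium rates — rather than class by class, so that branch lengths are
substitutions per codon *averaged over site classes* and a class with
$\omega > 1$ accumulates proportionally more substitutions along the same
branch. This is essential, not cosmetic: normalizing each class separately
silently removes the elevated substitution rate that is the main
per-site signature of positive selection, and in our simulations cuts
site-identification power to near zero. For branch-site models the scaling
factor is computed from the background-branch omegas and shared by the
foreground matrices.

## Site models, branch-site model, and tests

The fitted catalogue follows the standard M-series: M0 (one ratio), M1a
(nearly neutral: $\omega_0 < 1$, $\omega_1 = 1$), M2a (M1a plus
$\omega_2 > 1$), M3 (three free discrete classes), M7 (Beta($p,q$) on
$(0,1)$), M8 (M7 plus $\omega_s > 1$), and branch-site Model A (four
classes; the foreground branch carries $\omega_2$, fixed at 1 under the
null and free $\ge 1$ under the alternative). The beta distributions are
discretized into $K = 10$ equal-probability categories represented by bin
medians (quantiles at bin midpoints) — the standard choice. Free model
parameter counts are the conventional ones (M0 1, M1a 2, M2a 4, M3 5, M7
2, M8 4, Model A 3/4), so the likelihood-ratio tests use plain $\chi^2$
with df 4 (M0–M3), 2 (M1a–M2a, M7–M8) and 1 (branch-site), without a
boundary mixture correction; the branch-site test is therefore
conservative, which the type-I error simulation confirms.

## Optimization

Parameters are transformed to unconstrained space — log for $\kappa$,
branch lengths and free omegas; logit for proportions and omegas in
$(0,1)$; $1 + e^x$ for omegas bounded below by 1, capped at 999 because
near-boundary estimates (very large foreground omegas at tiny class
proportions) do occur — and maximized with box-constrained quasi-Newton
(`nlminb`), from up to three deterministic spread starting points per
model.

Two further choices keep a full eight-model scan tractable and make the
nesting inequalities structural rather than hoped-for:

* **Branch lengths.** All branch lengths are estimated jointly once, under
  M0. Every richer model then re-estimates a single free tree-scale factor
  on top of the M0 relative branch lengths. The search spaces of a nested
  pair are then identical apart from the class parameters. Joint
  re-estimation per model remains available (`branch_mode = "joint"`)
  and changes log-likelihoods negligibly at these data sizes.
* **Embedded starts.** Each alternative model's optimization starts from
  its null model's optimum embedded in the richer parameterization (e.g.
  M8 at $p_0 \to 1$ with the fitted M7 shape parameters). Since the
  optimizer never returns a point worse than its start (this is enforced),
  $\ell(\text{alt}) \ge \ell(\text{null})$ holds up to the tiny boundary
  clamp error of the embedding, below $10^{-4}$ log-units in practice.

Convergence targets a relative tolerance of $10^{-10}$ on the objective;
non-convergence reported by the optimizer is attached to the fit and
warned about, never silent.

## Empirical Bayes site identification

NEB applies Bayes' rule to the per-class site likelihoods at the MLEs. BEB
averages the class posterior over a discrete uniform prior grid on the
class parameters, weighting each grid point by the marginal likelihood of
the whole alignment; this accounts for parameter-estimation error, which
matters most in small datasets. Grids use 10 midpoints per free dimension:
proportions on the simplex triangle ($p_0 + p_1 < 1$, equal cell weights),
$\omega_0 \sim U(0,1)$, $\omega_s, \omega_2 \sim U(1,11)$, and for M8 the
beta shapes $p, q \sim U(0,2)$. For M8 the beta bin medians at each
$(p,q)$ grid cell are snapped to a fixed $\omega$ grid of step 0.005 so
all cells share one batch of pruning passes; both the grid resolutions and
the snap step are approximation knobs. Sites are reported as positively
selected at posterior probability > 0.90 for an $\omega > 1$ class, and
only when the corresponding LRT is significant — the scan labels
M8-flagged sites "long-term" and branch-site-flagged sites "episodic".

## Statistical coupling analysis

For an alignment column $i$ with residue counts $y_x$ over $n_i$ non-gap
sequences, and reference frequencies $g_x$ (pooled from a large reference
collection, floored at $10^{-6}$ and renormalized),

$$\Delta G_i = kT^* \sqrt{\sum_x \left[\ln \mathrm{Binom}(y_x; n_i, g_x)\right]^2},
\qquad kT^* = 1/M .$$

Binomial probabilities are evaluated on the log scale, so nearly-fixed
columns at large $M$ do not underflow. Gaps are excluded from the counts
($n_i$ is the non-gap count, keeping each binomial a proper probability),
residues with $y_x = 0$ contribute the literal binomial at zero, and
all-gap columns are reported as missing. The perturbation at a focal site
keeps exactly the sequences carrying its modal residue (ties broken
alphabetically, with a warning), and

$$\Delta\Delta G_{i,j} = kT^* \sqrt{\sum_x \left[\ln \wp_x^{\,j\mid\delta i} -
\ln \wp_x^{\,j}\right]^2}$$

compares site $j$'s log binomial vector after versus before the
perturbation, with $kT^*$ from the full-M alignment so the identity
perturbation gives exactly zero. Coupling is evaluated on the analysis
set: variable sites ranked by $\Delta G$, lowest 50% retained (fraction
configurable), i.e. the weakly constrained, reference-like sites. The
$\Delta G < 0.3$ cutoff used by the suitability diagnostics is exposed as
a knob. Three diagnostics mirror the method's assumptions: half-deletion
replicates (default 10), size-matched random subsets per focal site
(default 10), and a greedy input-order subsample enforcing > 5%
uncorrected pairwise dissimilarity (p-distance over shared non-gap
columns; pairs sharing none are maximally distant), whose output is
audited against its own postcondition.

One property worth stating precisely: for *reference-like* columns the
null distribution of $\Delta\Delta G$ concentrates near zero as $M$ grows
(the test suite checks $M = 100, 400, 1600$ at fixed seeds via the
acceptance conditions). For strongly conserved columns it does not — the
binomial comparison between the full alignment ($n$) and the sub-alignment
($s < n$) is dominated by the $n$-mismatch term, which grows linearly in
$n$ for composition-divergent columns and cancels only for columns near
the reference distribution. This is the quantitative reason the coupling
track restricts itself to the low-$\Delta G$ analysis set.

## The synthetic-data generator

The simulator draws a class per site, a root codon from $\pi$, and evolves
each site down the tree with the class transition matrices under the same
shared-time-scale convention as the likelihood; foreground edges switch to
the class's foreground omega along the entire flagged edge. The MSA
simulator draws columns from mixtures of a conserved residue and the
background frequencies, and plants pairwise couplings: with probability
$\rho$ the residue at column $b$ is a fixed bijective partner of the
residue drawn at column $a$. Gaps can be injected at a configured rate
(default 0, isolating gap-handling tests). All generators require an
explicit seed.

The recovery experiments use, as their fixed study conditions: a balanced
8-taxon tree with equal branch lengths of 0.3 substitutions per codon
(a deep mitochondrial divergence scale), $\kappa = 2$ (the field's
canonical starting value), uniform codon frequencies, 2000 codon sites,
and an M8 mixture with $p_0 = 0.95$, Beta(0.2, 1.0) background and
$\omega_s = 4$. The branch-site type-I experiment uses 200 replicates of
5 taxa × 60 codons with branch lengths and $\kappa$ estimated once per
replicate under M0 — sizes chosen so the full suite runs on one CPU in
minutes while leaving the statistical conclusions unchanged.

**What these experiments show, and their ceiling.** With 8 taxa the
per-site information about $\omega$ is modest. Evaluating the posterior at
the *true* generating parameters (no estimation error at all) puts the
expected fraction of truly selected sites reaching posterior probability
0.9 at roughly 0.65–0.75 across seeds for these conditions, regardless of
tree depth — deeper trees saturate sites rather than adding signal. The
fitted-model BEB recall sits at this ceiling (about 0.8 at the canonical
seed, with essentially zero false positives and decisive M7–M8 LRTs), so
seed-to-seed variation can take it a few points below 0.8: that reflects
the information content of an 8-taxon design, not optimizer failure. Real
mitogenome surveys gain power by adding taxa, not sites.

Simulated data also lack several features of real mitochondrial
alignments — among-gene compositional heterogeneity, alignment error,
indels, and phylogenetic autocorrelation of the SCA reference set — so
green tests certify the estimators and their calibration under the model,
not robustness to model violation. The robustness mode
(`run_robustness_scans()`) addresses part of this by repeating the scan
across frequency schemes and topologies.

## Known limitations

* Codon models with physicochemical exchangeabilities, clade models,
  counting-method dN/dS, and tree search are out of scope; trees are
  inputs.
* BEB accuracy is bounded by its 10-point grids; posterior probabilities
  within ~0.01 of a threshold should not be over-interpreted.
* The M2a boundary pathology (an $\omega_2$ class fitted with proportion
  ~0) is reported as returned by the optimizer; selected-site lists are
  gated on the LRTs, so such fits do not generate spurious sites.
* The coupling statistic is exploratory: it ranks candidate co-evolving
  sites but carries no hypothesis test, and phylogenetic relatedness in
  the MSA inflates $\Delta G$ slightly (the disparity diagnostic
  quantifies this).
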