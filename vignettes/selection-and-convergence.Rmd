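---
title: "Measuring selection and convergent substitution with hypoxsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selection and convergent substitution with hypoxsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Lineages that tolerate chronic hypoxia — high-altitude, cave-dwelling,
fully aquatic and semi-aquatic mammals — face elevated oxidative stress,
and their antioxidant-system genes are natural candidates for adaptive
evolution. Two questions recur in this literature. First, does the
strength of selection on a gene differ between habitat classes of
branches? Second, have independent hypoxia-tolerant lineages fixed the
*same* amino-acid replacements more often than neutral evolution predicts?
`hypoxsel` implements the full analysis chain for both questions, together
with a simulator so that every stage can be validated on data with known
truth.

# The substitution model

All likelihood computations use the Goldman–Yang codon model on the 61
sense codons of the standard genetic code (mammalian nuclear genes).
The instantaneous rate from codon $i$ to $j$ is

$$q_{ij} = \begin{cases}
0 & \text{more than one position differs}\\
\pi_j & \text{synonymous transversion}\\
\kappa \pi_j & \text{synonymous transition}\\
\omega \pi_j & \text{nonsynonymous transversion}\\
\kappa \omega \pi_j & \text{nonsynonymous transition,}
\end{cases}$$

normalized so that one unit of branch length is one expected substitution
per codon at stationarity. $\omega = dN/dS$ measures selection: $<1$
purifying, $=1$ neutral, $>1$ positive. Codon frequencies $\pi$ default to
F3x4 (products of position-specific nucleotide frequencies renormalized
over sense codons); F61 and uniform are available, and reports record the
scheme used. The matrix exponential $P(t) = e^{Qt}$ is computed by
symmetrized eigendecomposition, exploiting reversibility; rows sum to 1
within $10^{-10}$ and round-off negatives are clipped to zero.

Alignment likelihoods are computed by Felsenstein pruning over unique
site patterns with per-node rescaling. Gap and ambiguous codons are
treated as fully missing states (partial vectors of one), the analogue of
running CodeML with `cleandata = 0`; a strict mode that drops gapped
columns can be emulated by subsetting the alignment first. The likelihood
is evaluated on the rooted tree as given: under a reversible model it is
invariant to root placement, which the test suite verifies by re-rooting.
A consequence worth knowing is that the two root-adjacent branch lengths
are identifiable only through their sum; the optimizer may return any
point on that ridge without affecting the log-likelihood, $\omega$, or
$\kappa$. Parameter counts follow the rooted-tree convention ($2n-2$
branch lengths for $n$ taxa, plus $\kappa$, plus the model's $\omega$
structure), which reproduces the published table's `np` column (86 for a
43-taxon one-ratio fit).

**Rate scaling across site classes.** In a site-class mixture the classes
share one scale factor per branch — the proportion-weighted mean of the
classes' unnormalized rates — so a unit of branch length is one expected
substitution per codon *averaged over classes*, while a class with
$\omega_s = 4$ genuinely evolves several-fold faster than a purifying
class. (Normalizing each class separately would equalize total rates and
leave only compositional signal; the package's own validation caught
exactly this failure mode.) For single-class branch models the convention
reduces to the usual per-branch normalization. The simulator uses the same
convention, and BEB holds the scale at its MLE value. Fits with fixed
branch lengths evaluate the scale from the current mixture proportions at
every optimizer step, exactly as when branch lengths are re-estimated.

# Models and tests

* **Branch models.** One-ratio (M0); free-ratio (independent $\omega$ per
  branch); and the habitat ladder built by collapsing the five-category
  branch partition: 2$\omega$ (hypoxia-tolerant vs background), 3$\omega$
  (terrestrial vs aquatic hypoxia-tolerant vs background), 5$\omega$
  (high-altitude, cave, fully aquatic, semi-aquatic, background). The
  collapse is idempotent and order-independent, and the ladder's nested
  LRTs use df 1, 1 and 2 respectively.
* **Site models.** M8: a 10-category discretized Beta($p$, $q$) over
  $\omega \in (0,1)$ (equal-probability bins represented by their
  conditional means, computed in closed form from the incomplete beta
  function) plus one class at $\omega_s \ge 1$ with proportion $1 - p_0$.
  M8a fixes $\omega_s = 1$; the LRT has df 1.
* **Branch-site model A.** Four site classes (0, 1, 2a, 2b) with
  $\omega_2 \ge 1$ on designated foreground branches; the null fixes
  $\omega_2 = 1$; df 1.
* **LRT convention.** All p-values use the plain $\chi^2$ tail, as in the
  published analyses this package mirrors. For the boundary-null site and
  branch-site tests this is conservative; a 50:50 mixture correction is a
  documented alternative the analyst can apply to the reported statistic.
  No multiple-testing correction is applied across genes or branches
  (again mirroring standard practice); report tables are plain data
  frames, so `p.adjust` is one line away.

# Optimization

Fits alternate two bounded quasi-Newton (L-BFGS-B) steps: (1) the model
parameters ($\kappa$ and the $\omega$/class structure), with multiple
seeded restarts in the first round; (2) all branch lengths jointly, using
*analytic* gradients obtained from the standard inside/outside two-pass
computation (so a full gradient costs about two likelihood evaluations
regardless of the number of branches). Rounds repeat until the
log-likelihood improves by less than `tol` (default $10^{-4}$).
Bounds: $\omega$ slots in $[10^{-6}, 999]$, $\kappa$ in $[0.05, 99]$,
beta shapes in $[0.005, 99]$, branch lengths in $[10^{-8}, 50]$.
Estimates within a relative $10^{-3}$ of a bound are flagged as boundary
fits; non-convergence raises a warning and is recorded in
`diagnostics$converged`, and downstream stages (BEB, ancestral
reconstruction) refuse unconverged input rather than propagate it.

Site and branch-site fits re-estimate branch lengths by default. The
package's own power and calibration studies instead fix branch lengths at
the gene's M0 estimates (`fitOptions(branchLengths = "m0")`), a standard
pipeline shortcut that changes the LRT negligibly under the conditions
simulated there while cutting each fit from dozens of free parameters to
a handful. Nested alternatives are warm-started from their null's
parameters, and a fit that lands below its null (a boundary artifact) is
automatically restarted at the boundary.

# BEB site identification

Per-site posteriors for the positive-selection class follow the published
Bayes empirical Bayes construction: a uniform prior over a grid (10 points
per dimension by default, a config knob) on the mixture parameters — for
M8, $(p_0, \omega_s)$ with $p$ and $q$ fixed at their MLEs; for model A,
$(p_0, p_1, \omega_2)$ with $\omega_0$ fixed — with the whole-alignment
likelihood of each grid point as its weight. NEB (MLE plug-in) is
available for comparison and agrees with BEB in rank order on informative
data. Sites are called at posterior probability $\ge 0.8$ (inclusive),
and reports give both alignment columns and reference-sequence residue
numbers via an explicit coordinate map, since gapped references make the
two numberings diverge.

# Ancestral reconstruction and convergence

Marginal ancestral reconstruction uses the same inside/outside passes:
the posterior at a node is proportional to the product of its inside
partial and outside message. The default mode reconstructs at codon level
under the gene's M0 fit and collapses to amino acids by summation before
taking the MAP state; a direct amino-acid mode (F81-style chain on 20
states with empirical frequencies) is provided for comparison, and the
mode is recorded in the result. Substitutions on a branch are called
where parent and child MAP states differ; calls where either endpoint's
posterior falls below 0.7 are flagged rather than dropped.

For a pair of focal branches, a site with substitutions to the same
derived amino acid on both branches is *parallel* if the two ancestral
states agree and *convergent* if they differ. The expected number of such
events under independent evolution is computed per site from each
branch's parent-node posterior and the amino-acid substitution process
induced by the fitted codon model on that branch (codon $P(t)$ collapsed
through the genetic code); a flat-target alternative (uniform over the 19
other amino acids) is available because the historical tool's internal
model is not documented. Observed counts are tested against the expected
total with an upper-tail Poisson probability; observed 0 gives p = 1, and
expected 0 with observed positive gives p = 0. Focal pairs in an
ancestor–descendant relation are rejected — shared history makes the
comparison meaningless. Expected counts are reported at full precision;
they are positive whenever both branches have positive length, so a
printed "0" in a historical table should be read as rounding.

A caveat the simulator makes visible: MAP-based substitution calls
inherit the uncertainty of marginal reconstruction. When a forced
ancestral state is supported by only one nearby lineage, the MAP state at
that node can legitimately differ from the truth (the posterior prefers a
one-step intermediate). The forced-event machinery therefore composes
nested forcings rootward-first, so a scenario can first establish an
intermediate state across a clade and then overwrite one branch —
producing convergence histories that are actually identifiable from tip
data.

# The simulator and what passing tests mean

`simulateAlignment` draws root codons from $\pi$ and evolves each site
along each branch with the transition matrix of its branch/site-class
$\omega$; with `recordEvents = TRUE` branches are simulated as Gillespie
jump chains so every realized substitution is recorded. Defaults emulate
the study conditions this package targets: mammalian-like mildly
GC-skewed F3x4 frequencies, $\kappa = 3$, background purifying
$\omega \approx 0.06$–$0.26$ (the published M0 range for antioxidase
genes), trees of tens of taxa with branch lengths of a few hundredths to
a few tenths of a substitution per codon. One integer seed governs all
randomness and is embedded in the output.

The simulator does **not** model indels, alignment error, selection on
synonymous codon usage, rate variation beyond the $\omega$ classes in
scope, or non-stationary composition. Passing parameter-recovery and
calibration tests therefore demonstrates the estimator's correctness
under the model's own assumptions — not robustness to misalignment or
model violation in real data.

Problem sizes used by the validation suite (chosen to exercise each claim
at meaningful scale): one-ratio recovery at 40 taxa × 300 codons
($\hat\omega$ within ±0.05 of 0.2); 2/3-ratio slot recovery at 20 taxa ×
300 codons (±0.1); M8 detection power ($\omega_s = 3$, 10% of sites,
400 codons) on a 16-taxon tree of total length ≈ 10 substitutions/codon —
a deliberately deep tree, since distinguishing $\omega_s = 3$ from the
null's $\omega = 1$ class requires repeated substitutions per site —
with 15 replicates; ladder and Poisson calibration under the null at 8
taxa × 100 codons with 50 replicates each; branch-site BEB recovery of 5
planted foreground-selected sites ($\omega_2 = 4$ on a three-branch
foreground clade, conserved elsewhere) in a 600-codon alignment.
Exhaustive-enumeration oracles cover every likelihood path on trees of up
to 5 taxa.

# Known limitations

* Pure-R pruning is flop-bound around $10^2$ taxa × $10^3$ codons for
  11-class site models; the free-ratio model's per-branch $\omega$s are
  optimized by finite differences and should be kept to moderate trees.
* The BEB grid is the published 10-point-per-dimension construction;
  very small foreground proportions can sit between grid points.
* Branch categories label whole clades or pendant branches; reticulate
  or partial-clade labellings must be expressed branch by branch.
* The two root-adjacent branch lengths are reported as given by the
  optimizer anywhere on their ridge; only their sum is meaningful.
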