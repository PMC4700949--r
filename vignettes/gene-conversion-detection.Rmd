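---
title: "Detecting interlocus gene conversion among WGD paralogs"
author: "ohnoconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting interlocus gene conversion among WGD paralogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohnoconv)
```

## The problem

A whole-genome duplication (WGD) creates two copies of every gene. In the
yeasts descending from the ancient WGD, surviving duplicate pairs ("ohnologs")
sit on two syntenic tracks, and synteny-based orthology inference can assign
each post-WGD gene to its track independently of sequence similarity. That
independence is what makes gene conversion (GC) detectable: if two paralogs
from one species are more similar to each other than either is to its
*ortholog* in a close relative — while synteny insists they diverged at the
WGD, long before the speciation — then some process has homogenized their
sequences after duplication. Interlocus gene conversion, the nonreciprocal
overwriting of one locus by the homologous other, is the standard explanation.

`ohnoconv` implements a four-stage likelihood pipeline for this situation,
together with a synthetic post-WGD family generator so that every stage can
be exercised, calibrated and power-checked without any external data.

1. **Screen** — flag species whose two paralogs are closer to each other (at
   the protein level) than either is to any homolog in the nearest relative.
2. **Triplet test** — a branch-specific Ka/Ks relative-rate LRT on the
   (D1, D2, O) star tree, where D1 and D2 are the paralogs and O is D1's
   ortholog.
3. **Topology test** — compare the expected species topology against every
   "GC tree" (the species topology with one paralog regrafted as sister to
   its partner), with significance from a parametric bootstrap.
4. **SG model** — a similarity-groups codon model asking whether the
   converted branches show an excess of radical (polarity-changing) over
   conservative amino acid substitutions.

## The codon substitution model

All likelihoods use a Muse–Gaut-style codon model over the 61 sense codons of
the standard code. A single-nucleotide change from codon $i$ to codon $j$ at
position $p$ has instantaneous rate

$$ q_{ij} = \pi_{p}(j_p)\,\kappa^{\mathbb{1}[\text{transition}]}\,
  \omega^{\mathbb{1}[\text{nonsynonymous}]}, $$

where $\pi_p(\cdot)$ are position-specific nucleotide frequencies (estimated
empirically from the alignment), $\kappa > 0$ is the transition/transversion
ratio and $\omega \ge 0$ the nonsynonymous/synonymous ratio. Multi-nucleotide
changes have rate zero. Equilibrium codon frequencies are the F3×4-style
product of the position frequencies renormalized over sense codons, which
makes the chain time-reversible; the generator is rescaled so that branch
lengths are expected substitutions per codon. Tree likelihoods use
Felsenstein pruning over compressed site patterns; gap codons (`---`) and
ambiguous codons are treated as missing data (a partial-likelihood vector of
ones). Because the model is reversible, the likelihood does not depend on
root placement — one of the properties the test suite asserts.

Assumptions worth keeping in mind: sites evolve independently (a gene
conversion *track* violates this, which is precisely why the pipeline tests
for conversion by rejecting a null model rather than modelling conversion
itself), there is no among-site rate variation, and frequencies are shared
across branches.

### Numerical choices

* Transition matrices come from the eigendecomposition of the symmetrized
  generator $\Pi^{1/2} Q\, \Pi^{-1/2}$ (real spectrum by reversibility), so
  repeated $P(t)$ evaluations are cheap.
* Optimization is L-BFGS-B on log-transformed parameters, bounded in
  $[10^{-8}, 100]$, with analytic gradients for branch lengths (an
  outside-pass computation in the C++ core) and forward differences for rate
  parameters. Convergence tolerance is about $10^{-6}$ lnL units for data
  fits; bootstrap replicate refits use a looser tolerance (~$10^{-4}$), which
  is far below the scale of the ΔlnL statistic they feed.
* User-facing fits default to random restarts around the starting point
  (`restarts`); inner bootstrap refits are warm-started from the generating
  maximum-likelihood estimates and use none.
* Degenerate inputs: identical sequences drive branch lengths to the lower
  bound; parameters at the $10^{-8}$ floor are reported as such, and the SG
  ratio $R_r/R_c$ is reported as *undefined* (not infinite) when $R_c$ sits
  on the floor.

## The triplet relative-rate test

For a triplet (D1, D2, O) on an unrooted star tree, each branch $b$ carries
its own $(K_a^b, K_s^b)$: the generator for branch $b$ is
$s_b Q_\text{syn} + a_b Q_\text{nonsyn}$ with the linear coefficients chosen
so that the branch produces exactly $K_s^b$ synonymous substitutions per
synonymous site and $K_a^b$ nonsynonymous substitutions per nonsynonymous
site, sites being counted from the neutral mutational flux of the model at
equilibrium. $\kappa$ is shared across the three branches (a parsimony
choice; it is a nuisance parameter here).

Without conversion, D1 and O are separated from the star's center by the same
recent speciation, so their divergences should match. Conversion from D2 into
D1 (or vice versa) pulls D1's divergence below O's. The null model therefore
ties the chosen rate (Ka or Ks) on the D1 branch to the O branch, and
$2(\ln L_\text{free} - \ln L_\text{null})$ is referred to $\chi^2_1$.

Two design points were genuinely open. First, the null constraint is
implemented as strict *equality* with the two-sided $\chi^2$ tail (the
cleaner operational definition, since an inequality null makes the reference
distribution a boundary mixture), with a `one.sided` option that returns
$P = 1$ when the free estimates already satisfy
$K(D1) \ge K(O)$ and halves the tail otherwise. Second, when true rates sit
at the boundary (a rate of zero), the $\chi^2_1$ reference is kept even
though boundary nulls make it conservative; fidelity of the procedure was
preferred over a boundary-corrected mixture.

## The topology test and its parametric bootstrap

The expected gene-level topology is the species tree doubled at the root into
two tracks, with lost genes pruned. For every same-species paralog pair
(identified from the orthology table) and both directions, a *GC tree* is
built by pruning one paralog and regrafting it at the midpoint of its
partner's terminal branch; duplicate topologies are removed and pairs already
sisters contribute nothing. Branch lengths are fully re-optimized for every
topology, so the midpoint placement is only a starting value.

The test statistic is $\Delta = \ln L(\text{best GC tree}) -
\ln L(\text{species tree})$. Because the topologies are not nested, a
$\chi^2$ reference is unavailable; instead, replicates of the same length are
simulated under the species tree at its maximum-likelihood parameters, the
whole comparison (species tree plus every GC tree, all re-fit, $\kappa$ and
$\omega$ re-estimated per replicate by default — a `refit_params` flag fixes
them instead) is repeated per replicate, and

$$ p = \frac{\#\{\Delta_\text{null} \ge \Delta_\text{obs}\} + 1}{N + 1}. $$

The $+1$ convention means "no exceedance in $N$ replicates" reports
$p = 1/(N+1)$, never zero. The null $\Delta$ can legitimately be positive
(extra free branch arrangements can soak up noise), so the test never assumes
nonnegativity. Failed replicate fits are re-drawn, capped at 5% of $N$.

## The similarity-groups (SG) model

The SG extension splits the 20 amino acids into polar and nonpolar groups and
replaces the single $\omega$ with $R_c$ (conservative: nonsynonymous change
within a group) and $R_r$ (radical: change between groups). The default
partition — polar = {R, N, D, C, Q, E, G, H, K, S, T, Y}, nonpolar = {A, I,
L, M, F, P, W, V} — is a package choice, user-overridable, and recorded in
every SG output; conclusions about radical excess should be robustness-checked
against the partition when it matters. Branches are divided into a
*converted* class — the two converted tip branches plus the branch above
their common ancestor, which exists as a distinct branch only on the GC
topology, so SG fits for converted families run on the best GC tree — and a
*background* class, each with its own $(R_c, R_r)$, fit jointly with shared
$\kappa$ and branch lengths. The per-class null $R_r = R_c$ is a
$\chi^2_1$ LRT; across a family of such tests, Benjamini–Hochberg FDR is
applied. A one-sided binomial sign test summarizes how often $R_r > R_c$
across families under a fair-coin null. When the partition has a single
group there are no radical changes and the model provably collapses to the
plain MG/GY fit — the test suite asserts lnL equality to $10^{-6}$.

## The synthetic generator

`conversion_scenario()` + `generate_family()` produce families with known
ground truth: a rooted species tree is doubled at its root (the WGD), codon
sequences evolve along the doubled tree, and each conversion event
instantaneously overwrites a contiguous codon window of the recipient track
with the donor track's sequence at a stated fraction of the terminal branch
before the present, after which both lineages evolve independently. Windows
are codon-aligned; overlapping windows on one species are rejected; optional
losses delete tips. The generator emits the alignment, the species tree, the
converted-window genealogy (recipient regrafted beside its donor at the event
time) and a ground-truth orthology table with probability 1.

The bundled default scenario is six species in three cherries, tip-to-root
depth ≈ 0.15 expected substitutions per codon (so WGD paralogs span roughly
$K_s$ 0.1–0.5 across branches), $\omega = 0.05$, $\kappa = 2$, 150 codons —
values chosen once to be histone-like: short, extremely conserved coding
sequences a few speciations deep.

What the generator deliberately does **not** emulate: alignment error and
indel processes (only whole-codon gaps via explicit losses), among-site rate
variation, nucleotide-resolution conversion breakpoints, selection on the
fixation of conversion events, and subgenome-biased (allopolyploid)
evolution. Passing tests therefore demonstrate the statistical machinery is
correct and calibrated under the model's own assumptions — not that real
alignments satisfy those assumptions.

## Problem sizes in the test suite

The suite keeps every stochastic check at desk scale, chosen as the smallest
sizes at which the property is informative: oracle equivalence on 3–4-tip,
≤ 20-codon instances; triplet size at 500 null replicates of 300 codons;
triplet power at 100 replicates; bootstrap behaviour at $N = 200$ replicates
on the six-species fixture and calibration as 50 independent bootstraps of
$N = 100$ on a three-species family of 100 codons; SG recovery at 50
replicates of 2000 codons on the doubled six-species tree. The full-analysis
default for the bootstrap remains $N = 1000$.

## Known limitations

* The screen is a strict-inequality rule on amino-acid p-distances; under
  extreme conservation (few substitutions in total) ties are common and the
  screen loses power long before the likelihood tests do.
* The triplet test conditions on a single ortholog O of D1 chosen from the
  orthology table; uncertainty in that assignment (the table's posterior
  probability) is reported but not propagated.
* The $\chi^2_1$ reference is conservative at rate boundaries (true rates of
  zero), so the triplet test's realized size runs slightly below nominal in
  highly conserved families.
* Conversion-track breakpoint localization is out of scope; windows enter
  only through the generator.
* At desk-scale alignment lengths the parametric-bootstrap p-value is mildly
  *conservative* (under-dispersed): the observed ΔlnL is strongly coupled to
  the fitted branch lengths that also generate the null sample, so p-values
  concentrate away from both tails rather than being exactly uniform. The
  coupling shrinks with alignment length. Conservatism means the test does
  not produce spuriously small p under the null — the direction that matters
  when conversion calls are made — but exact uniformity should not be
  expected from short alignments.
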