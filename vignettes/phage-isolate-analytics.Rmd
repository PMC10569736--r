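---
title: "Models and methods for phage-isolate analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for phage-isolate analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagehost)
```

This vignette is the package's own account of the statistics and models it
implements: the assumptions behind each, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where a design was genuinely open.

## Icosahedral capsid model and packing density

Tailed-phage capsids are, to a good approximation, icosahedral. A negative
stain TEM protocol that circumscribes a circle around the projected capsid
measures the *vertex* (circumscribed) diameter $D$. The package models the
DNA-holding cavity as a regular icosahedron concentric with the capsid whose
circumradius is the measured circumradius minus one uniform protein-shell
thickness $t$:

$$R = D/2 - t, \qquad a = \frac{4R}{\sqrt{10+2\sqrt5}}, \qquad
  V = \frac{5}{12}\left(3+\sqrt5\right)a^3, \qquad \rho = L/V$$

with genome length $L$ in bp and $\rho$ in bp/nm³. The single free parameter
$t$ is not directly observable in negative stain; `calibrate_thickness()`
recovers it from one anchor phage whose density is known, by 1-D root finding
(density is strictly increasing in $t$, so the root is unique when
bracketed; tolerance $10^{-6}$ nm). The model's joint-consistency check —
run by the test suite and the acceptance script — is that the thickness
calibrated on one isolate (≈ 5 nm) predicts the packing densities of the
other two isolates to two decimals. Rounding for comparison against reported
two-decimal densities is half-up.

Radius conventions matter when comparing diameters across laboratories:
cryo-EM and some earlier reports quote the *inscribed* (face-to-face) or
*midsphere* diameter. The exact conversion factors follow from the
closed-form radii of the regular icosahedron
($R_\mathrm{circ} = 0.95106\,a$, $R_\mathrm{mid} = 0.80902\,a$,
$R_\mathrm{in} = 0.75576\,a$); inscribed → circumscribed multiplies by
1.2584, i.e. a +25.8 % correction. A rounder "+22 %" figure circulates for
this correction; it matches neither the exact circumscribed/inscribed ratio
(+25.8 %) nor circumscribed/midsphere (+17.6 %), and likely reflects an
unstated projection convention. The package implements the exact ratios
only.

Two further choices: measurement SD propagates to a density interval simply
by evaluating at $D \pm \mathrm{SD}$ (no distributional assumption is
imposed on five-virion averages), and genome lengths that differ by ~100 bp
between assembly polishing rounds are accepted as-is — at two decimals the
densities are insensitive to differences of this size.

## Cophylogenetic congruence test

The global test asks whether parasites attach to hosts in a way that mirrors
the two phylogenies, using only distance matrices and a binary association
matrix $A$ (parasites × hosts). Both matrices are first made
Euclidean-embeddable by the Cailliez correction — the smallest additive
constant $c$ (largest real eigenvalue of the standard $2n \times 2n$
companion matrix) such that $d_{ij}+c$ has no appreciably negative
principal-coordinate eigenvalue — then ordinated by principal coordinates
(Gower double-centring of $-d^2/2$; axes with eigenvalues below $10^{-8}$ of
the leading one are dropped as numerical noise). With host coordinates $B$
and parasite coordinates $C$, the statistic is
$\mathrm{ParaFitGlobal} = \sum \left(C^{t} A B\right)^2_{ij}$.

The null hypothesis is random association: independently for each parasite
(each row of $A$), the host assignments are permuted. The p-value is
one-tailed upper with the add-one estimator $(1+\#\{perm \ge obs\})/(1+N)$,
which can never return 0. Note the exhaustive null space for a system of
$n$ parasites is the product of per-row permutation images — for one-to-one
links, $n^n$ weighted host assignments, not the $n!$ bijections; the exact
enumerator `parafit_exact()` and the Monte-Carlo permutation p agree to
Monte-Carlo error, which the acceptance suite checks at $n=4$ with
100,000 permutations.

Distances from alignments default to the uncorrected p-distance with
pairwise deletion of gapped columns, matching the default of the classic
`distmat` utility; a Jukes–Cantor option is provided. The seed is a required
argument: permutation results are bit-reproducible.

Calibration properties, both computed by the acceptance suite: on 200
simulated independent systems (6 × 6, 999 permutations) the rejection rate
at $\alpha = 0.05$ stays within the exact binomial 95 % interval, and on 100
noise-free congruent systems (8 × 8) power is ≥ 0.8.

## Li–Wu–Luo dN/dS and the neutrality z-test

Each position of a sense codon is classified by how many of its three
single-base changes are synonymous: none → nondegenerate (0-fold), all
three → fourfold, otherwise twofold. Site totals $L_0, L_2, L_4$ are
averaged over the two sequences (always summing to 3 per compared codon).
Differences at codons differing at 2–3 positions are averaged over all
minimal mutational pathways that avoid stop codons, weighted equally; each
step's changed site is classed half by its degeneracy in the step's source
codon and half in its destination codon, and counted as transitional or
transversional. Per class, the Kimura two-parameter formulas convert
proportions $P_i, Q_i$ into transition ($A_i$) and transversion ($B_i$)
distances, assembled as

$$K_s = \frac{3\left[L_2A_2 + L_4(A_4+B_4)\right]}{L_2+3L_4}, \qquad
  K_a = \frac{3\left[L_0(A_0+B_0) + L_2B_2\right]}{3L_0+2L_2}.$$

A pair is invalid (saturated) when a required logarithm is undefined; small
negative class estimates from sampling noise are floored at zero. The
pathway tables are verified against a brute-force enumeration oracle over
every 2- and 3-difference sense-codon pair.

The z-test averages $K_a$ (dN) and $K_s$ (dS) over all valid sequence pairs
and estimates the variance of their difference by resampling codon *columns*
with replacement (the same columns for every pair, preserving cross-pair
correlation), with 100 bootstrap replicates by default;
$z = (\overline{dN}-\overline{dS})/\mathrm{SE}$ is referred to the standard
normal. The direction of the alternative is deliberately a required
argument — a test used both to claim diversifying selection ($dN > dS$) and
purifying selection ($dN < dS$) should never have a silent default.
Identical sequences give a degenerate-variance error rather than a p-value:
there is no information in them.

### A structural caveat on "neutral" codon processes

The simulator (below) never generates stop codons, as any sensible coding
simulation must. But forbidding nonsense mutations *is* purifying
selection: every blocked route is nonsynonymous, so even at $\omega = 1$
the realized dN/dS of a sense-codon-restricted process is ≈ 0.93, not 1,
independent of divergence. The strict-neutrality null $dN = dS$ is
therefore genuinely (if mildly) false under such a process, and with enough
data the z-test correctly rejects it — at the reference size
(10 × 300 codons) the measured two-sided rejection rate is ≈ 0.09–0.10
rather than 0.05. This is a property of the null hypothesis under
stop-avoiding evolution, not an estimator defect; repairing it would
require mutation-opportunity-weighted site counts, which would depart from
the published degeneracy-class bookkeeping ($L_0+L_2+L_4 = 3$ per codon)
that this package implements. Users testing genes where this distinction
matters should prefer the one-sided purifying alternative with effect-size
inspection over the raw two-sided p-value.

## Average nucleotide identity and species demarcation

The classic fragment scheme: the query genome is cut into consecutive
1020-bp fragments (the trailing remainder is excluded from numerator and
denominator alike, so self-comparison is exactly 100 % / 100 %), each
fragment is locally aligned to the full reference (Smith–Waterman, match
+1, mismatch −1, gap open 2, gap extend 1), and fragments are retained when
they align over ≥ 70 % of their length at ≥ 30 % identity. ANI is the mean
identity of retained fragments; coverage is the retained fraction of the
fragmented query. All four parameters are exposed. Full local alignment is
used rather than a seeded heuristic: at single-genome scale it is
affordable and strictly more sensitive.

The species rule is inclusive at both cutoffs — identity ≥ 95 % *and*
coverage ≥ 85 % — because demarcation "cutoff" language without stated
strictness is conventionally read as inclusive. An undefined identity (no
retained fragment) yields an indeterminate (`NA`) call, never `FALSE`: a
comparison that aligned nothing is evidence of non-identity at the genome
scale but not a measurement of it.

Orthogroup filters are set operations over an orthology table: an
orthogroup is host-specific when every member gene comes from genomes
mapped to that host (sets for distinct hosts are provably disjoint), and
the duplication flag marks orthogroups where at least half (inclusive) of
member genomes retain ≥ 2 gene copies.

## Genome triage

From assembly metadata, one complete phage genome per sample: candidates
must strictly exceed 90 kb, be flagged viral, and be classified
`"complete"`; the highest read coverage wins. Ties — never observed in real
assemblies but possible in principle — break deterministically by length
(longer first) and then lexicographic contig id, making the selection a
pure function of the record multiset. Samples with no candidate are
reported absent with a warning rather than silently dropped.

## What the generators emulate — and what they do not

* `sim_codon_alignment()` evolves codons on a *star* tree under a
  continuous-time Markov process on the 61 sense codons: single-nucleotide
  changes only, transitions scaled by $\kappa$, nonsynonymous changes by
  $\omega$, rates normalised to one expected substitution per site per unit
  branch length, transition probabilities computed by uniformization.
  Defaults ($\omega = 1$, $\kappa = 1$, branch length 0.1
  substitutions/site, 10 × 300 codons) define the reference conditions:
  $\kappa = 1$ because the degeneracy-class weighting of the estimator
  (one-third of twofold sites counted synonymous) is exact only without
  transition bias, and branch length 0.1 gives pairwise divergence ≈ 0.2,
  informative but far from saturation. The generator does *not* emulate
  codon-usage bias, rate heterogeneity across sites, tree structure beyond
  a star, or recombination — so passing calibration/power checks speak to
  the estimator and test under clean conditions, not to robustness against
  those real-data features.
* `sim_cophylo_system()` generates distance matrices directly (Euclidean
  distances among Gaussian points in five dimensions) rather than
  simulating trees — only the distance structure enters the statistic.
  Congruent mode copies the host matrix with one-to-one links; independent
  mode draws both at random with uniform random links. Real systems with
  partial congruence fall between these poles (`"noisy"` mode
  interpolates).
* `sim_capsid_measurements()` reports the mean and SD of $n$ Gaussian
  virion diameters rounded to integer nm, emulating few-virion averaging;
  it does not model stain- or tilt-induced systematic bias.
* `sim_contig_table()` plants one correct contig per sample among decoys
  that each violate exactly one triage criterion while carrying *higher*
  coverage (so a missing filter would select them), plus one decoy passing
  all filters at lower coverage. Recovery is exact by construction when the
  rule is implemented correctly, which is precisely what it tests.

All generators take a single integer seed and are bit-reproducible; every
simulation records its ground truth (`omega`, planted contigs, link
structure) for recovery tests.

## Problem sizes and numerical tolerances

The test suite and acceptance script use the reference sizes quoted above
(200/100 cophylogeny systems at 999 permutations; 500/200 codon alignments
of 10 × 300 codons; five 3000-codon alignments for parameter recovery; 8–12
kb genomes for ANI simulations; 100 triage samples), chosen to hold
Monte-Carlo error well below the decision margins while keeping a full run
in the minutes range on one CPU. Key tolerances: icosahedral volume vs the
convex-hull oracle, relative $10^{-9}$; radius round-trips, $10^{-12}$;
PCoA distance reconstruction, $10^{-9}$; eigenvalue retention, $10^{-8}$
relative; distance-matrix symmetry, silent to $10^{-8}$, warned to
$10^{-6}$, error beyond; thickness calibration, $10^{-6}$ nm.

## Known limitations

* The dN/dS machinery assumes the standard genetic code (no stop-codon
  reassignment) and equal-weight pathway averaging; genes from genomes with
  reassigned codes need a different code table before these estimates are
  meaningful.
* The neutrality z-test inherits the structural caveat above under
  stop-avoiding evolution, and Li–Wu–Luo class weighting is biased under
  strong transition/transversion asymmetry.
* ANI by full Smith–Waterman scales as (fragment × reference) per fragment;
  for many-genome all-vs-all comparisons a seeded aligner is the right
  tool, and this implementation is intended for the handful of pairwise
  comparisons a species-demarcation question needs.
* The cophylogeny test consumes distances, not trees: patristic distances
  from a tree are fine inputs, but no tree inference or per-link test is
  provided.
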