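---
title: "Models and methods behind the xenosig screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the xenosig screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenosig)
```

# Scope

`xenosig` asks, for a gene family with a patchy phylogenetic
distribution, whether the sequence data carry the compositional
signature expected of recent horizontal transfer. The package covers
four stages: (i) family building by reciprocal best hits; (ii) the
per-gene compositional battery and its aggregation; (iii) type-I
functional divergence between two designated subfamilies; (iv)
phenotype enrichment between family-containing and other strains. A
synthetic-data layer generates all inputs with known truth. Alignment
construction and tree inference are inputs, not outputs: the package
consumes a protein alignment plus a rooted tree and never infers
either.

# The compositional battery

## GC content by codon position

For each gene, codons containing any non-`ACGT` base are excluded, and
GC1–GC3 are the fractions of G/C at each codon position over the
remaining codons; GCt is their mean. Genome aggregates are unweighted
per-gene means — a long gene counts once, like a short one — because
the deviation rule is a statement about the per-gene distribution.

The deviation rule flags a gene when |GCt deviation| ≥ 2 dispersion
units, or when the GC1 and GC3 deviations share a sign and at least one
reaches 2 units. The dispersion defaults to the standard deviation of
the per-gene GC distribution rather than SD/√n: with thousands of genes
the standard error of the mean is tiny and essentially every gene would
deviate by "2 SE", which cannot be the intent of a rule designed to
flag rare outliers. Both readings are implemented
(`gc_dispersion = "sd" | "sem"`); `sd` is the default everywhere.

## The 3:1 dinucleotide signature

Dinucleotide relative abundances ρ\*~XY~ = f~XY~/(f~X~·f~Y~) are a
stable genome signature; the screen restricts them to the junction
formed by a codon's third base and the succeeding codon's first base,
the context least shaped by selection on the protein. Two choices are
worth stating:

* Mononucleotide frequencies are **position-specific**: f~X~ is taken
  over third-position bases and f~Y~ over first-position bases of the
  same sequence set. Pooled base frequencies would not be the marginals
  of the junction distribution, making ρ\* = 1 unattainable even for
  an unbiased sequence.
* Junctions never span gene boundaries, and a junction touching a codon
  with an ambiguous base is dropped together with that codon's
  positional base counts.

Profiles are compared by the σ difference (mean absolute ρ\* difference
over exactly 16 terms) and by Spearman and Kendall rank covariation.
The gene's own junctions stay inside the genome profile by default:
with realistic genome sizes the leave-one-out correction is far below
the sampling noise of a single gene's 16-value signature, and keeping
it avoids recomputing the genome profile per gene
(`leave_one_out = TRUE` restores the purist comparison). Rank-test
p-values use the standard large-sample approximations; an exact
permutation null over 16 paired values is only practical by Monte
Carlo, which is available seeded
(`rank_covariation(..., p_method = "montecarlo")`).

## RSCU, the χ² comparison, and CAI

RSCU normalizes a codon's count by the count expected under equal
synonymous usage; start, stop and Trp codons are excluded, leaving 59
sense codons over 18 degenerate amino acids. The gene-vs-genome test
apportions the gene's per-amino-acid totals by the genome's
within-amino-acid proportions and reports χ² with **df fixed at 41**
(59 − 18, recomputed from the genetic-code table at run time). The df
is fixed even when a gene lacks some amino acids — the battery treats
the test as a genome-calibrated index rather than an exact multinomial
test — and the effective cell count is emitted alongside for
transparency.

The genome reference RSCU pools codon counts across all genes
(`rscu_pooling = "pooled"`); a per-gene-mean alternative exists because
the two differ when gene lengths and biases covary.

CAI is the ratio CAI~obs~/CAI~max~ of two occurrence-weighted means of
reference RSCU values. CAI~max~ is weighted by the gene's own
amino-acid composition, which makes CAI = 1 exactly attainable by a
gene using only optimal codons regardless of its amino-acid usage; an
unweighted genome-level CAI~max~ is available
(`cai_max_weighting = "reference"`). The arithmetic mean of RSCUs is
used (the classical DAMBE-style formulation), not the geometric mean of
relative adaptiveness values used by other CAI variants — the two are
not interchangeable and the deviation rule (1.5 dispersion units of the
genome CAI distribution) is calibrated on the former.

## Aggregation and the verdict

Each gene accumulates up to four evidence lines: the GC flag, a
covariation flag (Spearman ρ negative **or** not significant at
α = 0.05 — significant positive covariation argues against transfer),
the χ² flag (p < α), and the CAI flag. A failed stage is recorded as
missing and never counted. The verdict maps evidence 0 / 1–2 / 3–4 to
`no_signature` / `weak_signature` / `strong_signature`. This mapping is
a reporting convention, not a calibrated classifier; all raw statistics
are emitted so users can apply their own rule. Where a single operating
point is needed (e.g. the sensitivity/specificity checks in the test
suite) the package uses *evidence ≥ 2*: with four tests each near its
nominal level, requiring two concordant lines keeps the native
false-flag rate below ~5% while fresh transfers from a distinct donor
typically trip three or four lines at once.

# Reciprocal best hits

Hits are filtered at E ≤ 1e−5 and bit score ≥ 50; the full-length
criterion is implemented as mutual coverage
(alignment length / sequence length on both sides) with a default of
0.8, active only when the 14-column BLAST dialect supplies lengths. A
pair is emitted iff each gene is the other's best surviving hit. Best
is maximum bit score with deterministic tie-breaking (lower E-value,
then lexicographically smaller subject id), so outputs are reproducible
across runs and platforms.

# Type-I functional divergence

## Model

Two subfamilies (clusters) are compared through per-site substitution
counts. Site rates λ follow a gamma distribution with shape *a* and
rate *b*. With probability 1 − θ a site draws one shared λ for both
clusters; with probability θ it draws independent rates — the signature
of altered selective constraints. Counts are Poisson with mean λ·d~k~,
d~k~ the cluster depth (default d₁ = d₂ = 1, the common scale being
absorbed into *b*). Both mixture components then have closed forms: the
marginal is negative binomial, and the shared-rate pair has the
bivariate Poisson–gamma kernel
Γ(x₁+x₂+a)/(x₁!·x₂!·Γ(a)) · d₁^x₁·d₂^x₂·b^a/(d₁+d₂+b)^(x₁+x₂+a).
The per-site posterior of the diverged class is
Q~k~ = θ·P₁(x₁ₖ)·P₁(x₂ₖ) / [(1−θ)·P₀ + θ·P₁·P₁], reported with
critical-site lists at Q~k~ > 0.7 and > 0.95.

## Site counts

Counts are minimum substitution numbers by Fitch small parsimony on
each cluster's induced subtree (each cluster must be monophyletic in
the rooted input tree). Gaps and unknown residues carry the universal
state set, so they never force a change; columns missing in more than
half of a cluster's leaves are masked out of the likelihood. Parsimony
counts under-count on deep trees; because both the null and the
alternative are fitted to the same counts, θ and the LRT are
comparative quantities and published values from other implementations
are approximated, not reproduced bit-for-bit.

## Estimation and testing

The likelihood is maximized over (θ, a, b) by bounded quasi-Newton from
a 3 × 3 multi-start grid (θ ∈ {0.1, 0.5, 0.9} × a ∈ {0.5, 1, 2}, *b*
started at its moment estimate), with *a* and *b* on the log scale.
The null (θ = 0) is fitted separately and the alternative is clamped to
it if any start ends below — the models are nested, so LRT ≥ 0 by
construction. The LRT is referred to χ² with one degree of freedom; a
θ̂ at the zero boundary is reported as θ = 0, LRT = 0, p = 1. The
half-and-half boundary mixture ½χ²₀ + ½χ²₁ is available
(`boundary_mix = TRUE`) but off by default, matching the plain-χ²
convention of the divergence literature; the practical consequence,
visible in the calibration tests, is a null rejection rate slightly
*below* the nominal 5%. The standard error of θ̂ comes from the inverse
observed information at the optimum and is suppressed at the
boundaries, where the quadratic approximation is meaningless.

# Enrichment

Each categorical trait is tested one category at a time against the
rest, over strains with a non-missing value for that trait; categories
with fewer than `min_count = 5` in-family strains are marked not
tested, reproducing the usual "ND" convention for sparse cells.
Fisher's exact test (two-sided, minimum-likelihood rule) and the
pooled-variance Student t (df = n₁ + n₂ − 2) are used as is; no
multiple-testing correction is applied to the headline p-values, with
BH and Bonferroni columns emitted for information.

# The synthetic-data layer

The generators define the study conditions under which the package's
claims are tested:

* **Codon model.** Within each amino acid, codon log-weights are a
  seeded jitter (sd 0.3) plus a tilt toward G/C-ending codons solved by
  `uniroot` so the marginal GC3 matches `gc3_target`; the tilt is
  capped at `bias_strength` (default 2; 0 gives exactly uniform
  synonymous usage, an unreachable target is clamped with a warning).
  Amino-acid frequencies default to a typical bacterial proteome
  composition and are shared between host and donor, so compositional
  signals come from synonymous usage only.
* **Dinucleotide signature.** A doubly-centered 4 × 4 junction
  preference matrix (scale 0.4) tilts codon choice at generation time.
  Codons are sampled **right to left**, the third base responding to
  the already-chosen first base of the succeeding codon. The direction
  matters: first-position bases are nearly fixed given the amino acid,
  so a forward pass could create junction dependence only through the
  few families with variable first bases, whereas the backward pass
  recruits the third-base degeneracy of every amino acid and yields a
  genuine, controllable 3:1 signature shared by all genes of a genome.
  The scale 0.4 puts the signature spread (~0.3 on the log-ρ\* scale)
  comfortably above the estimation noise of a 300-codon gene (~0.23),
  so native genes covary positively and significantly with their genome
  in ≥ 95% of cases.
* **Transfers and amelioration.** Alien genes draw each codon from the
  mixture (1 − α)·donor + α·host. The single knob α mirrors the
  amelioration process — α = 0 is a fresh transfer with full donor
  signature, α = 1 is fully host-like — without modelling substitution
  dynamics over time.
* **Gene lengths** are lognormal around 300 codons (sdlog 0.25, floored
  at 100): long enough that per-gene GC and signature noise resemble
  real bacterial genes, short enough to keep simulations fast.
* **Site counts** for divergence calibration use b = 0.5 at d₁ = d₂ = 1
  (about two substitutions per site per cluster) — deep enough for θ to
  be identifiable from the cross-cluster count correlation, shallow
  enough that parsimony-style counts are realistic.
* **Trait tables** plant one category at a chosen odds ratio among
  family members (probability transformed on the odds scale, other
  categories rescaled), with per-cell missingness (default 5%).

What the generators deliberately do **not** emulate: amino-acid
composition shifts between donor and host (available as a knob but off
by default), strand- or replication-associated skews, intergenic
context, operon structure, and length/bias covariation. Passing the
screen's sensitivity tests on synthetic genomes therefore shows the
statistics and decision rules work as specified under their own model —
not that real HGT detection achieves those operating characteristics,
which depends on how strongly real donors differ and how much
amelioration has erased.

# Problem sizes and numerical choices

The test suite runs at deliberately modest sizes: 200-gene genomes with
10 implants for the end-to-end screen; 200 null replicates at L = 300
and 50 recovery replicates at L = 500 for LRT calibration; exhaustive
Fisher enumeration over all 2 × 2 tables with n ≤ 40; brute-force
parsimony oracles on trees up to 6 leaves; 50 seeds for enrichment
recovery at n = 1000 strains. Optimizer tolerance is `factr = 1e4`
(about 1e-12 relative on the objective); quadrature cross-checks hold
to 1e-8 relative. Ties in best-hit selection, rank tests and category
ordering are all broken deterministically, and every stochastic
generator takes an explicit seed, so identical inputs give
byte-identical outputs.

# Known limitations

* The compositional battery cannot see ancient or short transfers, by
  design of the underlying signal.
* θ estimates depend on parsimony counts and the shared-shape gamma
  assumption; they approximate, and need not equal, values from other
  divergence software on the same alignment.
* The verdict mapping is a convention; users with calibrated priors
  should work from the raw statistics.
* The χ² test's fixed df = 41 is anti-conservative for very short genes
  with few amino acids represented; the effective cell count is
  reported for users who prefer to recalibrate.
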