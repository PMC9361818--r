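---
title: "Models and methods behind nodpool"
author: "nodpool authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nodpool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodpool)
```

# Scope

`nodpool` analyses select-and-resequence experiments on legume–rhizobium
symbiosis: a defined mixture of strains competes for nodule occupancy on
host plants, the pooled nodule contents are resequenced, and strain
frequency changes measure host-imposed selection. This vignette documents
the models, the tunable parameters, the numerical decisions, and what the
accompanying simulator does and does not emulate. It states no empirical
result beyond what the package's tests and acceptance script themselves
compute.

# The read–mixture model

## Haplotype panel

The reference is a strains × SNP-sites matrix of allele indices. Only sites
at which *every* strain has an unambiguous single-allele call are used for
estimation (`filterUnambiguous()`); heterozygous genotypes in these haploid
bacteria indicate mapping artifacts and are treated as ambiguous, the
strictest reading of "unambiguous call". Sites that stop segregating after
this restriction are dropped because they cannot discriminate strains.
Multiallelic SNP records are retained (allele indices `0..k`); indels and
other non-SNP records are skipped at load with a message.
`validatePanel()` reports all pairwise differing-site counts and flags
pairs below a threshold (default 1000 differing SNPs, the separation regime
in which pooled short reads retain discriminating power) without failing:
strain pairs may legitimately be close, but the user should know.

Internally all site and strain indices are 1-based (the R convention);
file formats keep their own conventions — VCF positions are 1-based, the
observation TSV's `site_index` column is 0-based and converted at the I/O
boundary. Allele indices are 0-based everywhere, matching VCF (`0` = REF).

## Read likelihood

A read reduced to calls at panel sites has, given source strain $s$ with
per-site error rate $e$:

$$\log P(r \mid s) \;=\; \sum_{\text{calls}} \begin{cases}
\log(1-e) & \text{call matches strain } s\\
\log(e/3) & \text{otherwise.}
\end{cases}$$

Errors are uniform over the three other bases. This per-site product is the
simplest model consistent with scoring reads against a panel already
reduced to unambiguous SNPs; it deliberately ignores base qualities and
within-read error correlation (see *Limitations*). With $e = 0$ a mismatch
gives $-\infty$, a representable sentinel; reads with $-\infty$ likelihood
under every strain carry no usable signal and are excluded with a logged
count.

The default $e = 0.005$ is a typical post-trimming Illumina per-base error
rate. It is fixed, not estimated: at a few tens of thousands of reads and
dozens of strains, jointly estimating $e$ buys little and risks
identifiability problems with near-tied strains.

## EM estimation

A pooled sample is the finite mixture $P(r \mid f) = \sum_s f_s
P(r \mid s)$ on the frequency simplex. `emEstimate()` runs standard EM:
responsibilities $r_{is} \propto f_s P(r_i \mid s)$, then $f_s \leftarrow
\frac1R \sum_i r_{is}$. Numerical choices:

* Likelihood rows are scaled by their maximum before exponentiation, so
  the computation is overflow/underflow-safe at any read length.
* Initialisation is uniform and deterministic. A mixture over *fixed*,
  well-separated components is well behaved, and a deterministic default
  avoids seed sensitivity; seeded random restarts are available
  (`nRestarts`) for stress tests.
* Convergence: stop when the log-likelihood improves by less than `tol`
  (default 1e-8) or after `maxIter` (default 1000) iterations. At
  study-scale problems the estimate is accurate well before the strict
  `tol` is met, so a `converged = FALSE` flag with `maxIter` reached is a
  statement about the tolerance, not the estimate.
* After each M-step the frequency vector is checked to sum to 1 within
  1e-9 and renormalised against floating-point drift; EM monotonicity is
  asserted in the test suite on every fit, with a $-10^{-7}$ floating-point
  guard on the trace differences.
* No frequency floor is applied: strains may go to exactly 0, and
  downstream fitness handles zeros explicitly (below). Frequencies below
  1e-6 are displayed as 0 in `show()` output but kept exact in slots and
  files.

`gridOracle()` exhaustively evaluates the mixture log-likelihood on the
simplex lattice (≤ 3 strains; the lattice blows up combinatorially beyond
that) and exists purely as an independent check: tests require the EM
optimum to dominate the lattice optimum. Lattice ties break to the
lexicographically smallest frequency vector, making the oracle
deterministic. `bootstrapCI()` resamples reads with replacement and
re-runs the EM on a precomputed likelihood matrix — the same computation,
reused for speed — reporting percentile intervals.

# Community measures

**Strain fitness** is $\log_2((q_{\text{selected}} +
\epsilon)/q_{\text{initial}})$ per community member, with the initial
frequency taken as the mean over sequencing replicates of the inoculum.
The zero-handling policy $\epsilon$ is deliberately explicit because the
choice is not forced by the data: the default (`"auto"`) uses
$\epsilon = 0$ when every member strain was detected and half the smallest
nonzero selected frequency otherwise, applied to all entries and recorded
in the output. This keeps fitness finite and rank-preserving while leaving
the no-zeros case exact (selected = initial gives exactly 0). Setting
`zeroPseudo = 0` restores $-\infty$ sentinels for sensitivity analysis.
Strains not declared community members are excluded rather than
zero-filled; non-member strains estimated above a contamination threshold
(default 0.001) trigger a warning.

**Diversity** is the exponent of Shannon entropy — the order-1 Hill
number, the number of equally frequent strains with the same entropy —
with $0 \log 0 = 0$. Alternative Hill orders are out of scope.

**Host benefit** is $\sum_x q_x w'_x / \sum_x q_x$ over strains with a
single-strain plant-weight estimate, where $w'$ is min–max scaled within
host (0 = full occupancy by the least, 1 by the most beneficial strain).
Because scaling is per host, scores are not comparable across hosts; the
self-normalisation makes the score invariant to rescaling $q$. Strains
without weight estimates are dropped from numerator and denominator; a
sample with all mass on weightless strains has no defined benefit and
errors.

# Variance partitioning

`rdaFit()` implements redundancy analysis directly: the response matrix is
column-centered and scaled to unit variance (zero-variance columns dropped
with a warning), the design is expanded with treatment contrasts
(reference levels A17, low density, N− when present), and each term's sum
of squares is the increment in fitted sum of squares when added after all
preceding terms (sequential / Type I), computed from cumulative QR
projections. Rank-deficient designs error naming the aliased term.
Pseudo-F uses the full-model residual; adjusted
$R^2 = 1-(1-R^2)(n-1)/(n-p-1)$. A PCA of the full-model fitted values
gives the constrained axes. Degrees-of-freedom bookkeeping (terms +
residual $= n-1$) and the unit sum of variance proportions are asserted on
every fit. For balanced designs the sequential proportions are invariant
to the contrast coding.

`permutationTest()` permutes response rows as whole units (free
permutation, no conditioning), recomputes every term's sequential pseudo-F
under the same permutation per iteration for coherence across terms, and
reports $p = (1 + \#\{F^* \ge F\})/(1 + n_{\text{perm}})$ — the observed
statistic counts itself, so 999 permutations give a minimum p of 0.001.
The exact permutation scheme used by other RDA implementations varies (by
term, residualised, restricted); ours is declared, not claimed to be
bit-compatible with any of them. On a perfect fit the residual sum of
squares is clamped at zero and F becomes $+\infty$, which compares
correctly against permuted statistics.

Scalar responses (diversity, benefit, plant traits) go through
`anovaTerms()`, a thin wrapper over `stats::lm()` + `stats::anova()`
(sequential SS, parametric F) — a deliberate buy-not-build for the one
step that is textbook linear modelling. A constant response reports
all-zero SS with `NA` statistics and a warning rather than failing.

# Rank-order consistency

The pairwise winner is the strain with the higher mean frequency across
replicates of the two-strain community; an exact tie of means leaves the
winner undefined and is flagged. Consistency in a larger community is the
proportion of replicates in which the winner's relative frequency within
the focal pair, $f_w/(f_w+f_l)$, exceeds one half — algebraically the same
comparison as the raw frequencies but robust to the other strains' mass.
Exact within-replicate ties count 0.5, the symmetric and unbiased choice,
giving the identity $c(w,l) + c(l,w) = 1$ on tie-free data. Rankings sort
by mean frequency with lexicographic tie-breaks, flagged. No inferential
statistics are attached: the report is the raw proportions, as in the
experimental design this mirrors. Near-tied pairs are reported exactly as
computed — no numeric "near-tie" threshold is imposed.

# What the simulator emulates — and what it does not

`simulateExperiment()` generates, under one seed: a random biallelic panel
with a chosen expected pairwise difference probability; per-community
inocula as equal frequencies with lognormal jitter (default sd 0.2,
chosen so a 68-strain inoculum spans roughly half to double the uniform
frequency, the spread expected from mixing equal culture volumes) plus
multinomial sequencing-replicate estimates; selection as a single
exponential tilt $p_x \propto q_x e^{s_x}$ at nodule formation, followed
by multinomial sampling of a finite, singly occupied nodule pool; and
reads as random contiguous 3-site blocks with per-site errors. Defaults
mirror the study design this package serves: 68 strains, 1000 unambiguous
SNPs, hosts A17 (selection sd 1.0, 300–500 nodules) and R108 (selection
sd 0.5, 100–200 nodules — less selective, fewer nodules, hence stronger
drift), a 100-fold density contrast implemented as a per-host multiplier
on selection coefficients (A17 1.3, R108 0.8; increased density
strengthens selection in one host and weakens it in the other), a weak
nitrogen multiplier (A17 1.05, R108 1.0), replicate pots 6/5/5/4 for the
full/8-strain/3-strain/pairwise communities, and 21667 reads of 3 sites
(~65× depth at 1000 sites) with $e = 0.005$. The full community receives
the complete host × density × nitrogen factorial (48 samples); the
complexity communities are grown at the shared reference condition (high
density, no added nitrogen). Synthetic single-strain plant weights are
lognormal with host-specific missing fractions (9/68 and 29/68).

The density and nitrogen multipliers are scenario knobs, not inferences:
no mechanistic model of density-dependent selection is attempted
(quorum sensing, motility, root-hair contact rates are all collapsed into
one multiplier). Likewise the simulator does not emulate: mixed-occupancy
nodules, within-nodule proliferation as a second selection stage, strains
absent from the panel, base-quality profiles or FASTQ-level artifacts,
alignment and variant-calling errors upstream of the panel, or plant
phenotypes beyond factor labels. Passing tests on generator output
therefore demonstrate the estimator and statistics are correct *under the
stated model*, not that the model captures every feature of real nodule
pools.

One scenario used by the tests deserves note: for rank-consistency checks
the three focal strains are planted at selection coefficients (2, 0.7,
−2.6) whose pairwise frequencies (≈0.79:0.21, 0.99:0.01, 0.96:0.04)
reproduce the separations observed among focal strains in this
experimental system, with all other strains random. With ~300-nodule
pools, rare strains in a 68-strain community occupy only a handful of
nodules, so winner propagation is only expected to be near-perfect for
pairs that are clearly separated — which is exactly the regime the focal
strains of such experiments occupy.

# Problem sizes in the test suite

The suite validates the estimator at the full study scale (68 strains,
1000 sites, ~65× depth, 300-nodule pools) over three seeds, checks EM
against the exhaustive grid oracle on twenty ≤3-strain instances, and
calibrates the permutation test on 200 null datasets of 16 samples with
199 permutations each (199 keeps the attainable p-values on a 1/200
lattice so the nominal level is exact). Pipeline smoke tests run a reduced
design (8 strains, 120 sites, 400 reads) — large enough to exercise every
stage, small enough to keep the suite fast.

# Known limitations

* The read model ignores base qualities and windowed haplotype structure;
  it scores isolated SNP calls. This is adequate for well-separated
  panels (hundreds of differing sites) and short site-blocks per read.
* Strains missing from the panel are not modelled; their reads are
  absorbed by the nearest panel strains.
* `bootstrapCI()` resamples reads, capturing sequencing noise only — not
  the nodule-sampling (drift) variance between replicate pots, which the
  experimental design addresses with replication.
* Host-benefit scores are not comparable across hosts by construction.
* The RDA permutation scheme is free row permutation; restricted or
  residualised schemes are not implemented.
* With pairwise communities of near-equal competitors, winner/consistency
  statistics are dominated by drift at realistic nodule numbers; the
  package reports the proportions as computed and flags exact ties only.
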