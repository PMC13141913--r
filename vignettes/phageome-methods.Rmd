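---
title: "Methods: mining and quantifying the infant gut phageome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and quantifying the infant gut phageome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagemine)
```

# The problem

The gut virome of infants is dominated by bacteriophages, but shotgun
metagenomes of stool are overwhelmingly bacterial: phage signal arrives
both as free viral particles and as prophages integrated in bacterial
contigs, and its relative abundance is distorted by the bacterial
background. This package implements the computational stages that such a
study needs after the standard external tools have run — assembly,
alignment, phage classifiers, binning, and taxonomy/lifestyle/host
predictors, all of which the package consumes only as tabular output. Every
stage is exercised end-to-end on synthetic fixtures with planted ground
truth.

# Reference unphaging

Bacterial reference catalogs themselves contain prophages. If such a
reference is used to flag and remove "bacterial" contigs from an assembly,
genuine phages are lost with them. `unphage_database()` therefore excises
viral regions from the reference first:

1. `filter_hits()` keeps an alignment of a viral reference genome against a
   bacterial contig iff percent identity ≥ 70 **and** aligned length ≥ 70%
   of the viral query length. Both thresholds are inclusive; this boundary
   convention is a package decision, fixed and tested. The coverage
   denominator is the viral query — the question asked is "is this viral
   genome present here", so a short local match of a long virus does not
   qualify.
2. `merge_intervals()` unions overlapping and book-ended intervals per
   contig (interval algebra on 0-based half-open coordinates; the alignment
   dialect's 1-based inclusive coordinates are converted on read). Merging
   before excision guarantees each viral base is excised exactly once even
   when several viral queries hit the same locus.
3. `excise_and_split()` cuts the merged intervals out as prophage records
   and splits the residue into fragments. Residual fragments shorter than
   `min_fragment_len` (default 2,000 bp, matching the pipeline's global
   contig floor) are dropped but accounted, so the invariant
   *fragment bp + prophage bp + dropped bp = original bp* holds exactly and
   is asserted in the tests.

# The mining cascade

`mine_phages()` chains four per-contig stages:

- **Length floor.** Contigs shorter than 2,000 bp are discarded (inclusive
  boundary: exactly 2,000 bp is kept), the minimum input size of the
  downstream classifiers.
- **Prophage extraction.** Predicted prophage coordinates (CheckV- or
  PhageBoost-style) are merged and excised with the same machinery as
  unphaging; each region becomes a candidate phage contig (`*_pp<k>`), and
  the parent is replaced by its host-side fragments.
- **Bacterial removal.** Contigs flagged bacterial by the read classifier
  (run against the unphaged reference) are dropped; extracted candidates
  survive independently of their parent's fate.
- **Consensus calling.** A contig is called phage iff its PhaMer-style
  score is ≥ 0.9 and the sum of PhaMer-style and MetaPhaPred-like scores is
  strictly greater than 1. A missing MetaPhaPred-style score contributes 0;
  a missing PhaMer-style score is an error because its threshold is
  mandatory. The two supplementary classifiers (DeepVirFinder-style score,
  VirSorter2-style flag) are recorded in the decision trace but do not flip
  the verdict by default — the conservative reading, since the consensus
  rule exists to remove false positives. `dvf_rescue = TRUE` enables an
  optional rescue for contigs that fail the agreement rule but have both
  supplementary calls positive; it is off everywhere in this package's own
  analyses.

The decision function is monotone in both scores (tested by property), so
the cascade's stage order cannot change the final set — also asserted.

# Dereplication

Phage contigs are dereplicated at ≥ 98% identity over ≥ 85% coverage.
Neither an alignment definition nor a tool is prescribed by those two
numbers alone, so the package fixes the standard ANI-style convention:

- identity = matched bases / aligned columns of an exact local alignment
  (match +1, mismatch −1, gap open 2, gap extend 1);
- coverage = aligned span of the **shorter** sequence / its length, making
  coverage symmetric and scoring containment as 1;
- both strands are tried (phage contigs are unoriented);
- clustering is greedy longest-first: each contig joins the first
  representative it matches at both thresholds, ties on length broken by
  lexicographic ID for determinism.

On every random instance the greedy result is compared against a
brute-force oracle (full pairwise matrix, same order). Scalability beyond a
few thousand contigs is out of scope.

# Annotation post-processing

Taxonomy calls are nulled when the rejection score is below 0.7 or the
family is absent from the reference-catalog whitelist; lifestyle calls are
nulled below 0.7; host predictions need confidence ≥ 95 and at least one
shared protein. All rejection boundaries are inclusive (a score equal to
the threshold passes) — the package's convention where the cutoffs are
stated without boundary semantics. Two-source taxonomy is merged by
agreement (disagreement nulls the call), switchable to priority for the
graph-classifier source.

Bin-level propagation assigns a bin's single distinct member family to all
members; bins with two or more distinct families are *discarded at the
annotation level only* — the member contigs keep flowing into
quantification as unclassified, since abundance bookkeeping must not lose
them. Host calls merge with the protein-sharing-based predictor taking
precedence over the read-classifier fill, conflicts flagged.

# Viral relative units

Read counts under-represent viruses in mixed metagenomes, so abundance is
expressed as viral relative units. For contig *i* in one sample,

$$\mathrm{VRU}_i = \frac{\mathrm{mdepth}_i \cdot \mathrm{coverage}_i}
{\sum_j \mathrm{mdepth}_j \cdot \mathrm{coverage}_j}$$

with `mdepth` the mean depth over covered bases and `coverage` the covered
fraction of the contig. The product equals total mapped bases divided by
contig length, so the "mean over covered bases" and "mean over the whole
contig" readings of mean depth coincide once multiplied by coverage — the
reason this parameterisation was kept. Samples with no viral signal yield
an all-zero vector with a flag, not an error. Groups are formed by summing
contigs sharing (family, lifestyle, host genus); missing annotations map to
an explicit `unclassified` level so row sums stay exactly 1. Presence is
strictly `VRU > 0`.

# Statistical layer

- **Alpha diversity**: Shannon index in natural-log units (the reference
  implementation's default base).
- **Log transform**: the default pseudocount is half the smallest nonzero
  value in the table — small enough not to compress real signal, finite for
  exact zeros; configurable.
- **Distance**: d(i,j) = 1 − Pearson r between sample profiles, in [0, 2].
  This distance is not Euclidean-embeddable in general, hence:
- **PCoA**: classical scaling (Gower double centering +
  eigendecomposition). Negative eigenvalues are reported but excluded from
  the proportion-explained denominator; on Euclidean inputs the
  configuration reproduces the input distances to 1e-9, which is tested.
- **PERMANOVA**: authored here with sequential sums of squares in formula
  order from the Gower-centered matrix, pseudo-F against the residual mean
  square, and p = (1 + #{F\* ≥ F}) / (1 + n_perm) over label permutations
  (999 by default, seeded, bit-reproducible). The partition (SS, R², F) is
  cross-checked in the tests against the independent community-ecology
  implementation, and the permutation p against complete enumeration at
  n = 7. Permutations are of raw sample labels, matching the classic
  formulation.
- **Mixed models**: Gaussian on log abundance and binomial (logit) on
  presence, both with a random intercept per infant time series, fitted by
  the standard mixed-model library (REML for Gaussian, Laplace for
  binomial); Wald z p-values. Acceptance is *parameter recovery on planted
  cohorts*, not coefficient equality with any particular backend. Singular
  or non-converged fits are flagged in the result, never raised.
  Per-family screens adjust the focal term's p-values with
  Benjamini–Hochberg across families, reported alongside the raw values.

# Synthetic data: what it emulates, what it does not

The generators plant ground truth for every contract: a bacterial database
with recorded prophage insertions and matching alignment hits at
configurable identity/coverage (so threshold behaviour is testable on both
sides); classifier score tables drawn from Beta(30, 1) for true phages and
Beta(1, 30) for non-phages — a deliberately strong classifier profile —
with configurable flip rates, or degenerate 1/0 scores for exact-recovery
fixtures; depth summaries (log-normal depths, Beta covered fractions); and
a miniature longitudinal cohort.

The cohort defaults to 8 infants × 10 samples so the full suite runs in
minutes; the acceptance experiments run 200 such replicates and larger
single cohorts (40 × 20) where single-fit precision is asserted. Treatment
and age vary within infant (in the study a subset of each series was
enriched and infants appear in both age windows), delivery between infants;
random intercepts are Normal(0, 0.5), residual SD 0.5, default effects 0.8
(treatment, log scale), 0.5 (delivery), 1.0 (age, log-odds for presence).

What the fixtures do **not** emulate: phylogenetically realistic sequence
composition (contigs are iid uniform nucleotides, plus a substitution
operator for dereplication fixtures), read-level noise (depth tables are
the contract; no FASTQ), compositional correlation structure between phage
groups, and real classifier error patterns (errors are independent flips).
Passing tests therefore demonstrate the correctness of the algorithms and
the statistical calibration of the layer on data matching their model
assumptions — not robustness to real-data pathologies such as chimeric
assemblies or classifier biases.

# Numerical choices and degenerate inputs

- Interval coordinates: 0-based half-open internally; 1-based inclusive
  alignment coordinates converted on read (minus-strand pairs order-
  normalised).
- All filter thresholds inclusive (≥); the score-sum agreement is strict
  (> 1) as stated by its rule.
- VRU row sums are asserted to 1e-9; distance/ordination oracles to 1e-10
  or better.
- Dereplication fixture mutation rates: instances used for exact planted
  cluster counts are planted at 0.4% per copy (expected pairwise
  divergence 0.8%, safely inside the 2% threshold), because at ~1% per
  copy the expected pairwise identity of two copies (≈ 98.4%) straddles
  the 98% threshold and the planted truth stops being determinate; the
  oracle-equivalence suite deliberately keeps the near-threshold rate,
  since greedy-equals-oracle must hold there too.
- Empty inputs: empty hit tables, contigs without intervals, all-zero
  depth vectors and samples lacking annotations all have defined,
  non-throwing behaviour (tested); truly invalid states (duplicate IDs,
  out-of-range coordinates, constant binary response) raise errors naming
  the offending record.

# Known limitations

- The greedy dereplication is quadratic in the number of representatives;
  it is meant for post-mining contig sets, not all-vs-all catalogs.
- PERMANOVA supports sequential (type-I) sums of squares only, so factor
  order matters, as in the classic implementation.
- The binomial mixed model uses the Laplace approximation; with very few
  clusters its estimates carry the usual small-sample bias (visible as a
  few-percent inflation of planted effects at 80 observations) and its
  Wald intervals are approximate.
- Host/taxonomy/lifestyle predictions are consumed, never recomputed: the
  package's guarantees start at their tabular outputs.
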