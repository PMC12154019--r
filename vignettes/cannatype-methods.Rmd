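---
title: "Methods: chemotype and genotype classification of Cannabis sativa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemotype and genotype classification of Cannabis sativa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cannatype)
```

## The model

Cannabis chemotypes are set by two synthase genes competing for the
precursor cannabigerolic acid (CBGA): tetrahydrocannabinolic acid
synthase (*THCAS*) and cannabidiolic acid synthase (*CBDAS*). The
package works with a deliberately simple two-locus, dominant-marker
model:

* a **functional THCAS** produces THCA (decarboxylating to THC), a
  **functional CBDAS** produces CBDA (to CBD);
* the chemical phenotype is summarised by one statistic,
  `log10(%THC / %CBD)`, trimodal across populations: chemotype I
  (drug, ratio above 0), II (intermediate, between −1 and 0) and III
  (fiber, below −1);
* the allelic state of each gene is observable in two independent ways:
  structurally (ORF integrity of the coding sequence) and through an
  allele-specific PCR marker whose primer ends on a diagnostic SNP.

The pipeline classifies samples on each side independently and then
quantifies agreement. Nothing in the model requires the two sides to
agree; their concordance is the scientific result being measured.

### Assumptions

* Presence/absence (dominant) marker logic: a visible band means at
  least one amplifiable functional allele; heterozygosity and dosage are
  not modelled.
* Activity is equated with structural integrity of the CDS. A synthase
  inactivated by catalytic-site substitutions in an intact ORF is
  invisible to the ORF analysis (a documented source of divergence for
  some real fiber-type THCAS alleles) — the marker side, which types the
  SNP directly, is the primary genotype evidence.
* %THC and %CBD are the neutral-form contents in percent w/w of dry
  tissue; the statistic uses their ratio only.

## The chemotype classifier

`compute_log_ratio(pct_thc, pct_cbd, floor = 0.001)` floors both
contents before the ratio. The floor (percent w/w) absorbs zeros and
below-detection values; 0.001 is the smallest content the packaged
reference table prints, so the statistic reproduces that table's printed
log column wherever the printed inputs allow it.

`classify_fixed()` applies the conventional cutoffs 0 and −1 (class II
includes the boundary values: `(−1, 0]`). These cutoffs are the default
classification method because they reproduce the packaged reference
table's chemotype column exactly.

`cluster_samples()` mirrors a clustered two-column log-content heatmap:
complete-linkage agglomerative clustering, Euclidean distance, on
`(log10 %THC, log10 %CBD)`. Its floor is deliberately **higher**
(default 0.01): contents printed at the 0.001 reporting resolution are
below-quantitation values, and mapping them to log10 = −3 manufactures
up to two decades of spread inside the drug-type class that the assay
cannot support — with the 0.001 floor the drug class splits and the
smallest chemotype-pure cut is k = 4, an artifact of print resolution
rather than chemistry. At the 0.01 quantitation floor the k = 3 cut of
the packaged table is identical to its chemotype column and k = 3 is the
smallest pure cut (verified in the test suite). Cluster-to-chemotype
labels are assigned by decreasing mean log ratio. Tie-breaking follows
`stats::hclust`'s deterministic merge order; the packaged table contains
no exact distance ties.

Reported group ranges are rounded **half away from zero** to two
decimals (`round_half_away()`), the convention under which −1.085
reports as −1.09.

## The in-silico PCR engine

`find_binding_sites()` scans both strands. A site qualifies iff

* the primer's 3′-terminal window (default 1 base) is exactly
  IUPAC-compatible with the template, and
* internal mismatches are at most `max_internal_mismatch_fraction`
  (default 0.10) of the primer length.

This is mismatch counting, not thermodynamics: the assays being emulated
report binary band presence on agarose, and a Tm/ΔG model would add
parameters without changing any presence/absence decision the package
makes. The 3′-exact window is the ARMS principle — a polymerase cannot
extend a mismatched 3′ end — and is what makes a primer ending on the
SNP allele-specific.

`amplify()` pairs every plus-strand site with every downstream
minus-strand site (single-primer products included) up to
`max_product_len` (default 3000 nt; products span primer 5′ end to
primer 5′ end). `run_assay()` scores a band present when some product is
within `size_tolerance` (default ±10 %, roughly agarose resolution) of
the pair's expected size. All coordinates are 1-based inclusive.

The packaged assay (`make_reference_fixtures()`) is engineered so the
four bands fall at the published sizes — THCASd 384 nt, CBDASf 346 nt,
THCASint 291 nt, CBDASint 169 nt — with the allele-specific forward
primers ending exactly on *THCAS* 1349 and *CBDAS* 645. The original
assay's primer sequences live in an appendix not reproduced here, so the
engine is primer-agnostic: real primers can be supplied as a YAML assay
file (`read_assay()`) without code changes. Which of G/T (1349) and C/G
(645) is the active allele is not stated in the source; the package
adopts G and C respectively as a convention — only the consistency
between generator, assay and caller matters.

## Genotype calling

`call_gene()` codes target-band presence as the uppercase allele symbol,
absence (with a positive internal control) as lowercase. When the
internal control also fails there is no evidence of amplifiable
template; the default policy still calls the lowercase symbol but flags
`internal_control_failed` — the lenient behaviour matches how such a
sample was retained in the reference study — while `policy = "strict"`
returns `no_call`. `combine_and_predict()` maps Td→I, TD→II, tD→III;
the never-observed fourth pattern `td` is reported as `undetermined`
with an `atypical_genotype` flag rather than guessed at.

## ORF integrity

`assess_integrity()` aligns a sample CDS to an active reference with
affine-gap scoring (match +1, mismatch −1, gap open −4, gap extend −1
per position; end gaps free) via `pairwise_align()`, and calls a copy
inactive if it has an internal indel of length not divisible by 3
(frameshift) or translates to less than `length_threshold` (default
0.90) of the reference protein. The threshold tolerates terminal
sequencing ragged ends while catching a mid-gene premature stop
unambiguously. The aligner is validated against an exhaustive
affine-gap dynamic program on short sequences in the test suite.

## Phylogenies

The original analysis aligned with MAFFT and inferred
maximum-likelihood trees (TIM1+G / TIM1+I, 1000 bootstraps). The
package deliberately substitutes a lighter, fully-deterministic stack —
star-progressive alignment, JC69 distances, neighbor joining, column
bootstrap — because the quantity being tested is clade composition, not
likelihoods. This is a documented simplification, not a re-implementation
of the original inference.

* `align_progressive()`: every sequence is aligned pairwise to the first
  (center) sequence and merged under "once a gap, always a gap".
  Adequate for the intra-gene problem here (sequences within a gene
  differ by point substitutions and one short indel); not a general MSA.
* `jc69_distance()`: d = −(3/4)·ln(1 − (4/3)·p) with p the mismatch
  fraction over mutually ungapped columns. Pairs at p ≥ 0.75 exceed what
  the model can express and are capped (default 5) and flagged. Pairs
  with no shared columns are an error by default, or capped under
  `allow_zero_overlap = TRUE`.
* `nj_tree()`: canonical neighbor joining (Q criterion,
  Studier–Keppler updates), deterministic lexicographic tie-breaking,
  negative branch lengths clamped to zero with a count attribute. On
  additive matrices it recovers the generating tree exactly (tested).
* `bootstrap_support()`: resamples alignment columns with replacement,
  seeded; support is the fraction of replicate trees containing a split.

Two tree views mirror the two published analyses. The **gene-copy
tree** places every THCAS and CBDAS copy as a separate leaf: per-gene
alignments are pooled block-diagonally (`pool_alignments()`) and
cross-family pairs sit at the saturation cap — the supermatrix
convention for non-overlapping partitions, used here because the
synthetic ancestors are unrelated by design (see below). Its expected
structure is four clades: active THCAS (drug + intermediate), inactive
THCAS (fiber), active CBDAS (intermediate + fiber), inactive CBDAS
(drug). The **concatenated tree** joins each sample's two genes
column-wise (`concatenate_alignments()`, partitions recoverable); on it,
intermediate samples sit between the drug and fiber groups because they
share the active THCAS haplotype with drug-type and the active CBDAS
haplotype with fiber-type plants. Both properties, with bootstrap
supports, are asserted in the test suite on a 12-sample panel
(4 drug / 5 intermediate / 3 fiber — the composition of the original
sequencing selection) at 100 replicates, sizes chosen to keep the full
suite fast while leaving the splits unambiguous.

## The synthetic panel generator

`make_panel(panel_config())` produces a panel in which every downstream
stage has a known right answer.

**Cannabinoids.** Each chemotype has a %THC range, a %CBD range and a
log-ratio band (defaults read from the packaged table's extremes:
drug 0.76–3.14, intermediate −0.58 – −0.10, fiber −1.61 – −1.09). The
ratio is drawn uniformly from the band, then %THC uniformly from the
part of its range compatible with that ratio and the %CBD range. Ranges
alone would not do: the drug %THC and %CBD ranges overlap in ratio space,
and independent uniform draws could produce a "drug" sample with a
negative log ratio. Sampling the ratio first keeps every draw inside the
configured ranges *and* the classes linearly separable at the (0, −1)
cutoffs, which the configuration validator enforces up front. Uniform
distributions are used because only observed ranges, not distributions,
are available.

**Sequences.** Each gene descends from a shared ancestral CDS, re-drawn
randomly per panel seed *except* at codon-aligned windows — primer
footprints and functional positions — whose content is fixed to the
engineered reference, so the packaged assay amplifies every panel. Per
chemotype:

* drug: active THCAS; CBDAS with the inactive SNP allele plus a 4-nt
  deletion at position 153 (config accepts 6 nt for completeness, with a
  warning that 6 is in frame and cannot shift the reading frame);
* intermediate: both genes active;
* fiber: THCAS with the inactive allele plus a premature stop at 60 % of
  the CDS (far enough from the 90 % length threshold that truncation is
  unambiguous); active CBDAS.

Inactive alleles are modelled as **diverged haplotype lineages**, not
point mutants: `allele_divergence` (default 0.01/site) fixed
substitutions separate the inactive from the active haplotype of each
gene, shared by all carriers. This mirrors the deep active/inactive
splits of real reference phylogenies and is what gives the activity
clades their strong bootstrap support; a lone diagnostic SNP would leave
a one-column signal (the frameshift falls in gap columns and contributes
nothing to distances). On top, each sample receives independent
background substitutions (`background_mutation_rate`, default
0.001/site ≈ 1–2 per gene copy, within-cultivar scale) outside the
masked windows, never creating an in-frame stop — so active copies stay
active by construction.

**What is not emulated.** Real THCAS/CBDAS homology (~84 % identity):
the two ancestors are unrelated random ORFs, which is why the gene-copy
tree uses the pooled-supermatrix convention instead of a cross-family
alignment. Also absent: chromatograms and peak integration, measurement
noise correlated between THC and CBD, heterozygous plants, CBCAS-type
paralogs that can cross-react, and gel-intensity effects of template
concentration. Passing tests therefore demonstrate the pipeline's logic
and numerics, not robustness to instrument noise or to paralogous
amplification in real genomic DNA.

## Numerical and degenerate-input conventions

* Rounding for reported ranges and printed-precision comparisons: half
  away from zero.
* Duplicate sample ids, empty tables, mismatched sample sets, non-finite
  log ratios, asymmetric distance matrices and empty sequences are
  errors, each naming the offending records.
* A missing gene sequence is not an error: the assay reports absent
  bands with a `missing_<gene>` flag and the caller degrades as the
  policy dictates.
* Same seed, same configuration: byte-identical panels, identical
  bootstrap supports; generators and bootstraps restore the caller's RNG
  state.

## Known limitations

* ORF-intact but catalytically dead alleles are called active by the
  sequence side (see Assumptions).
* The fixed-cutoff classifier is only as good as the cutoffs; the
  packaged table is consistent with (0, −1), but populations with ratio
  modes near a cutoff would need the clustering route.
* The printed contents of the packaged reference table are rounded to
  3 decimals; its printed log-ratio column was computed from unrounded
  instrument values, so rows whose %CBD sits at the 0.001–0.002
  reporting limit cannot be reproduced from the printed inputs at
  ±0.005. The package reproduces the printed classes 85/85 and the
  anchor log values exactly; the residual per-row discrepancies are a
  property of the source table, not of the computation.
* The NJ/JC69 stack is a stand-in for ML inference by design; branch
  lengths and supports are not comparable to published ML trees, only
  clade composition is.
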