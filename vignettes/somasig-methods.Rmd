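---
title: "somasig: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somasig: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`somasig` implements the somatic-genomics machinery of a tumor/normal
cohort analysis: consensus variant filtering with panels of normals,
structural-variant consensus, gene-level copy-number calling, 96-context
mutational-signature extraction and attribution, and the nonparametric
association framework that relates driver-gene mutation status to
signature activity — most prominently the balance between the homologous
recombination deficiency (HRD) and APOBEC mutational processes. This
vignette documents the models, the thresholds and their rationale, what
the synthetic cohort generator does and does not emulate, and the design
choices made where the procedure was genuinely open.

## The filter cascades

**SNVs.** A call enters the analysis only if both callers emit it with
`PASS` status for the same tumor-normal pair (`consensus_snvs()`); the
intersection is keyed by `(chrom, pos, ref, alt)` after left-normalizing
indel-style representations. A panel of normals (`build_pon()`) then
removes recurrent artifacts and germline leakage: a normal sample
supports a site when it covers it with at least 10 reads and at least 5%
of reads carry the alternate allele at MAPQ ≥ 20 and base quality ≥ 20;
two or more supporting normals blacklist the site. Blacklisted calls can
be *rescued* when they carry positive evidence of being recurrent somatic
events — a COSMIC overlap count strictly greater than 1 together with
1000 Genomes and ExAC frequencies at or below 0.005
(`apply_pon_with_rescue()`).

Two ambiguities in this procedure are settled by explicit switches:

* *Rescue vs gate.* We read the COSMIC/population-frequency criteria as a
  rescue of otherwise-removed panel hits (the criteria demand positive
  annotation evidence, and calls meeting them "were retained"), which is
  the `cosmic_mode = "rescue"` default; `"gate"` instead requires the
  criteria of every call.
* *Denominator of the alt fraction.* The quality filter is applied to the
  numerator only by default (`pon_denominator = "all_reads"`); a
  quality-filtered denominator is available (`"q20_reads"`).

Missing annotations never satisfy a rescue criterion: rescue demands
observed evidence, so an absent population frequency fails the
conjunction. Conversely, in germline classification
(`classify_germline()`) a missing ExAC frequency does *not* discard a
variant — discarding demands observed commonness. Variants at or above
5% ExAC frequency are discarded; the rest are deleterious when annotated
HIGH impact or missense with CADD strictly above 25.

**Indels.** Retention requires at least 4 alternate reads in the tumor,
no alternate reads in the normal, tumor VAF of at least 5%, a position
outside repetitive regions, absence from the known-germline set, and
absence from a *pseudo panel of normals* built by aggregating calls that
failed upstream with `HighVafNormal` or `HighAltCountNormal` in two or
more samples (`build_indel_pseudo_pon()`). All thresholds are inclusive
("minimum of", "5% or more") except where a strict inequality is the
stated rule.

**Significantly-mutated-gene pre/post filters** (`smg_filters()`) cap
non-silent indels at one per gene per sample (keeping the
lowest-coordinate record — a deterministic tie-break) and require more
than two distinct mutated individuals per eligible gene. The background
mutation model itself is out of scope.

## Structural-variant consensus

`consensus_svs()` is anchored: the result is always a subset of the
anchor caller's calls. In pipeline order: (1) anchors matching the SV
panel of normals are dropped — the panel (`build_sv_pon()`) contains
every normal-sample call regardless of `PASS`/`LowQual` status; (2) an
anchor is corroborated when a support call of identical type has both
breakpoints within the 500 bp window; the nearest support by summed
breakpoint distance |Δstart| + |Δend| is recorded, ties broken by lower
start; (3) pairs with any of their four breakpoints in the repeat mask
are dropped; (4) inversions need at least one split read from *both*
members of the matched pair. Panel matching tolerates breakpoint jitter
using the same windowed same-type rule as corroboration — exact-key
matching would make the panel ineffective against jittered normals — with
`sv_pon_match = "exact"` available. The split-read requirement is
evaluated on the matched pair, not on arbitrary overlapping calls.
Translocations and insertions are out of scope.

## Copy number

Gene-level calls (`call_gene_cn()`) take the median over exons of the
copy number of the segment containing each exon midpoint. Amplification
requires a median of at least 6 for focal gains or at least 7 for
non-focal gains, where focality is a property of the *gain*: the
genomically contiguous run of segments at or above the focal threshold
spanning the gene must be shorter than 3 Mb. Non-focal amplifications of
tumor suppressor genes are excluded; a median of 0 is a loss. Segments
are half-open (`start <= p < end`), so lengths are `end - start`.

Chromosomal instability (`compute_cin()`) is the fraction of
segment-covered length whose total copy number differs from baseline.
The baseline is integer 2 by default; because "alteration" could equally
be read against rounded ploidy, a per-sample ploidy override is
provided. Segment counts merge consecutive same-CN runs so that the
count is invariant to re-splitting. HER2 status from copy number
(`call_her2_cn_status()`) mirrors clinical FISH-ratio practice: ERBB2
median CN over the length-weighted median chromosome 17 CN, positive at
ratio ≥ 2 (a declared default — the exact clinical decision rule is not
standardized), indeterminate without chr17 coverage.

## Mutational signatures

Catalogs (`build_catalog()`) classify each SNV into the 96
pyrimidine-centered classes (six substitution types × sixteen flank
pairs); purine-reference sites are reverse-complemented, and contexts
containing `N` are dropped with a warning. Samples need at least 100
SNVs (inclusive) to enter factorization; excluded samples stay in the
object. `normalize_catalog()` rescales each context count by the ratio
of its trinucleotide frequency in the target territory to the source
territory — making exome and genome samples comparable — and then
row-normalizes, addressing both stated needs of the normalization step
(variable mutation counts, joint exome+genome factorization); the
rescale can be disabled.

`extract_signatures()` minimizes the generalized Kullback–Leibler
divergence with multiplicative updates (the classic Poisson-NMF choice
for count spectra): iteration cap 5000, relative tolerance 1e-8, best of
30 seeded restarts by final divergence, scale fixed by making profiles
row-stochastic. The objective is non-increasing under these updates,
which the test suite asserts iteration by iteration. k = 9 is the
default rank. Factors are labeled by greedy one-to-one cosine matching
against the bundled reference profiles at a 0.8 cosine threshold (a
declared default; no criterion is stated in the source procedure).

Contributions — the per-tumor proportion of mutations assigned to each
signature — are computed by non-negative least squares
(`compute_contributions()`): the sample's normalized spectrum is refit
against the profiles and the coefficients renormalized to the simplex.
We chose an NNLS refit over reading back training exposures because the
source description ("matrix algebra on the exposure and mutation
matrices") is ambiguous and the refit gives a deterministic contract
that also works out-of-sample; tests verify the NNLS against a dense
simplex grid search at step 0.01. `combine_apobec()` sums the two
APOBEC-labeled contributions. Context lookup accepts either a
per-variant context column or chromosome sequences, so tests never
require a reference download.

## Associations

All tests are thin, explicit surfaces over the standard machinery:
Mann–Whitney U (exact by enumeration when the smaller group has ≤ 8
observations and no ties, otherwise the tie-corrected normal
approximation with continuity correction), Benjamini–Hochberg step-up
adjustment, Kruskal–Wallis with hand-computed Dunn post-hoc z tests from
pooled tie-corrected ranks (pairwise p unadjusted by default, BH
optional — the adjustment statements in the source figures do not name
Dunn), Fisher's exact per cohort pair with BH across genes within each
pair, Pearson chi-square without continuity correction, permutation
Spearman (p = (1 + #{|ρ*| ≥ |ρ|})/(B + 1), permuting one variable's
labels), and pairwise-complete Pearson correlations with one BH family
across all unordered pairs. BH families are per analysis table: the
driver × feature grid is one family, each cohort-pair comparison is one
family, the correlation matrix is one family.

The driver–feature grid (`associate_drivers()`) compares mutated vs
wild-type per (gene, feature), declares a direction only below the FDR
level (default 0.05) by group medians, skips pairs with fewer than two
samples per status, and supports an IHC-subtype restriction. The
four-way balance grouping (`assign_balance_group()`) partitions tumors
by {CDH1 or PIK3CA} vs {TP53 or BRCA1/2 incl. germline} status. The
multivariate HRD model (`hrd_multivariate()`) is OLS of the
logit-transformed (ε = 1e-3 clamped) HRD contribution on cohort
indicators, age, log1p missense burden, and the four driver indicators —
the exact model family of the original supplementary analysis is
unspecified, so the logit link is the declared default with identity
available; collinear covariates are rejected by a rank check naming the
offending term.

## The synthetic cohort generator

Every downstream stage is exercised against data with a known answer.
`simulate_cohort()` draws cohort labels (abstract A/B/C — the mapping to
named populations is presentation only, deliberately avoiding any claim
that the synthetic data reproduces real cohort frequencies), IHC
subtypes and driver statuses at per-cohort prevalences taken from the
published frequency tables (e.g. TP53 62/46/29%), and a per-sample true
signature mixture from a Dirichlet centered on the sample's balance
group mean with concentration 50. The group means place HRD at 0.45 for
TP53/BRCA vs 0.15 for CDH1/PIK3CA with the reciprocal combined-APOBEC
effect, the Both group between them, and Neither shaped like TP53/BRCA —
matching the reported direction that the Neither group's signature
pattern most resembles TP53/BRCA. Because mixtures live on the simplex,
planted HRD and combined APOBEC shares are negatively correlated across
the cohort, mirroring the observed anticorrelation. An `effect_scale`
knob interpolates to the null (all groups at the grand mean) for
calibration studies. Mutation counts are log-normal with median ≈ 500
and a heavy tail, so the ≥ 100-SNV gate is genuinely exercised; the
recovery studies instead draw counts uniformly (500–5000 for
factorization recovery at 200 samples; exactly 1000 for attribution
recovery at 300 samples — sizes chosen to make the Monte-Carlo error
small relative to the 0.05 tolerances while keeping the default test run
fast).

Catalogs are exact multinomial draws from the mixture-weighted profiles
(row sums equal true counts by construction). The caller simulator
emits true SNVs through two pseudo-callers at 95% sensitivity, adds
caller-unique false positives, and plants 20 recurrent artifact sites
that appear in tumors through both callers *and* carry qualifying
support in 3 normals; a quarter of artifact sites carry rescue
annotations. The indel simulator plants one violation of each filter
rule per sample plus shared pseudo-panel artifacts; the SV simulator
jitters each breakpoint independently and uniformly within ±250 bp (half
the window, so a true pair can never be separated by more than the
500 bp corroboration window) and plants panel-matching, repeat-region,
and split-read-failing events; the copy-number simulator plants focal
and non-focal gains, CN-6 non-focal gains (which must stay neutral),
losses, and ERBB2 amplifications, with the altered genome fraction
recorded exactly as a ratio of integers so CIN has an arithmetic truth.
Generator bookkeeping (the expected survivor sets) is computed from the
planting flags, *not* by running the pipeline; the test suite
additionally re-derives the expected sets by independent brute-force
rule application, so implementation, bookkeeping, and oracle are three
separate routes that must agree.

The bundled reference profiles are nine fixed probability vectors: two
APOBEC-like profiles peaked at TCW contexts (C>T and C>G), a CpG-focused
aging-like profile, a flat HRD-like profile, a broad C>A profile
standing in for signature 8, and four sparse profiles from a fixed
internal seed. They are synthetic stand-ins shaped like the named
processes, not COSMIC downloads, so the package runs fully offline.

What the generator does *not* emulate: read-level errors, alignment and
mapping artifacts, germline haplotypes, purity/ploidy confounding of
segmentation, subclonal structure, or real cohort allele-frequency
spectra. Passing tests therefore demonstrate the correctness of the
*rules and estimators*, not the field performance of the upstream
callers these rules consume.

## Numerical choices and degenerate inputs

* NMF initializations are uniform on [0.1, 1]; restart r uses seed
  `seed + r − 1`; divergence guards use ε = 1e-12; non-convergence at
  the iteration cap is a warning, never silent.
* NNLS uses the Lawson–Hanson active-set solver; an all-zero fit (no
  signature explains the spectrum) yields missing contributions.
* Exact Mann–Whitney switches off in the presence of ties; identical
  multisets give p = 1 at U = n1·n2/2.
* Zero-margin 2×2 tables return p = 1 and are logged; empty contingency
  categories are dropped with a warning; expected counts below 5 warn.
* Degenerate all-zero catalog rows are rejected by the factorization
  with the offending sample names; a rank-deficient HRD design matrix is
  an error naming the aliased term.
* Mask membership uses the half-open BED convention: the 1-based point p
  is inside (start, end] iff start < p ≤ end.
* `write_table()` emits doubles at 17 significant digits so re-reading
  round-trips exactly.

## Problem sizes used by the checks

The bundled verification runs use 200 samples for factorization
recovery, 300 for attribution and association recovery, the 200-sample
default cohort for the filter cascades, a 100-SV single-sample fixture
(plus 50 caller-unique, 20 panel, 10 repeat, 5 split-read-failing
events) for consensus, 30 samples for copy number, 200–1000 replicates
for null calibration, and 199–9999 permutations for permutation tests —
sizes at which every planted effect is decisively detectable and the
stochastic tolerances hold with large margins.

## Known limitations

Rank selection (choosing k) is out of scope, as are signature
extraction on indels/SVs, segmentation and purity/ploidy inference,
translocation handling, and expression-based immune scoring (immune
scores are consumed as given). The HER2 copy-number rule and the CIN
baseline are declared defaults where the source procedures are
unstated; both are configurable.
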