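---
title: "CDR3delta repertoire deconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CDR3delta repertoire deconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdr3delta)
```

# Scope and data model

`cdr3delta` analyses T-cell receptor δ-chain (TRD) clonotype tables from
sorted γ9δ2 T-cell subsets.  The unit of observation is the *nucleotype*: a
unique junction nucleotide sequence together with its V and J calls in one
sample.  The junction spans the conserved V-segment cysteine (Cys104)
through the conserved J-segment phenylalanine/tryptophan (Phe/Trp118),
inclusive; the CDR3 excludes these two anchors, so CDR3 length is the
junction amino-acid length minus two.  Amino-acid clonotypes are sets of
nucleotypes translating to one junction amino-acid sequence; convergent
recombination — independent generation of the same amino-acid sequence from
distinct nucleotide rearrangements — is what makes a clonotype *public*
(observed in two or more unrelated donors).

Raw-read processing is out of scope: inputs are AIRR Rearrangement TSVs
(clonotypes with read counts) plus a sample metadata table (donor,
replicate, sorted subset, sorted cell count).

# Annotation conventions

**Read filter.** Clonotypes supported by more than one read
(`duplicate_count >= 2`) are retained; the filter is applied per sample
before every downstream statistic, and clonotype frequencies are percent of
the post-filter sample total.  Per-sample filtering (rather than per donor
pool) is the stricter, self-consistent choice; the alternative can be
obtained by pooling before filtering.

**Productivity.** A record is productive when its junction length is a
multiple of three, its translation matches `junction_aa` without stop
codons, and the anchors (leading C, trailing F/W) are present.
Nonproductive records are retained and flagged but excluded from
amino-acid-level analyses.

**Position 5 and the invariant T.** CDR3 position 5 (IMGT 109) is the sixth
junction residue.  It is hydrophobic when in {A, V, L, I, P, W, F, M}.  The
invariant T is operationalised as a template T at the second position of
junction codon 6 (nucleotide 17); the codon structure of the genetic code
then forces one of F/L/I/M/V, so `inv_t` implies `is_haa5` on all inputs.
Any T qualifies regardless of its germline or inserted origin — the
simplest reading; a variant requiring germline origin would need a reliable
D-frame assignment that exact matching cannot always provide.  Junctions
shorter than 7 amino acids have no defined position 5 and are excluded from
position-5 analyses with a logged count.

**J region.** The J call decides the region label when present; otherwise
the junction is classified by the longest amino-acid suffix overlap (at
least 4 residues) with a packaged J head translation, and junctions with no
sufficient overlap are excluded from J-usage statistics with a counter.

# Junction decomposition and N insertions

The decomposition attributes junction nucleotides to ordered contiguous
blocks V, N1, D, N2, J.  V and J matches are exact and anchored (a prefix
of the TRDV2 3' end from Cys104; a suffix of a J 5' head up to Phe118); the
optional D block is an exact contiguous substring of a D segment of at
least `min_d_match` nucleotides (default 3 — shorter matches are
indistinguishable from chance).  Among all decompositions the one
maximising the germline-attributed score (junction length minus
unattributed N nucleotides) is chosen; ties prefer larger V match, then
larger J match, then a D segment over none, then the lexicographically
smallest D identifier, so the result is deterministic.  The implementation
enumerates D placements with a dynamic-programming diagonal-run search; the
test suite checks its score against an independent exhaustive enumeration
over every (V length, D placement, J length) triple.

Two consequences of exact matching are worth keeping in mind.  P
(palindromic) nucleotides are not modelled separately and count as N, so
`germline_encoded` (`total_n == 0`) means "decomposable with zero
unattributed nucleotides under exact matching", and absolute N counts run
slightly high relative to junction tools that model P additions.
Conversely, inserted nucleotides that happen to extend a germline match are
reabsorbed, so recovered N counts never exceed, and on average sit ~1.3 nt
below, the generative truth at the default simulation settings (four block
boundaries, each with a ~1/3 nt expected chance extension).  Analyses in
the package therefore rely on orderings and contrasts of N counts, not on
their absolute values.  Sequencing errors are upstream's problem: no
mismatches are tolerated.

**Germline reference.** The packaged reference carries the
junction-proximal regions of the standard *01 alleles (one TRDV2, three
TRDD, four TRDJ segments), 0-based half-open coordinates, anchor offsets
pointing at the first nucleotide of the anchor codon, and is validated on
load (alphabet, anchor translation, segment counts).  It is a curated
constant — region-level J usage is the analysis target, so allele-level
polymorphism is deliberately ignored — and can be exported to FASTA for
audit.

# Expansion, publicity, diversity

**Frequency classes.** Non-expanded (*f* < 0.1%), expanded
(0.1% ≤ *f* < 1%), hyperexpanded (*f* ≥ 1%); left-closed boundaries, so
exactly 0.1% is expanded and exactly 1% is hyperexpanded.

**Publicity.** To avoid calling publicity on barely detected sequences,
the universe is restricted to nucleotypes detected (post-filter) in at
least two samples of the same donor; donors with a single sample are
rejected with an instruction to skip them.  Concordant nucleotypes are
collapsed by amino-acid sequence with read-count conservation; a clonotype
is public when shared by at least two donors and highly common when shared
by a strict majority (> 50%) of the cohort.  Sharing counts are monotone
under donor addition, which the property suite asserts.

**Diversity.** Shannon entropy uses the natural logarithm; comparisons are
within-study, so the base is immaterial but fixed for reproducibility.
D75 is the standard DXX estimator: counts sorted decreasing (ties broken by
junction sequence for determinism), `k` the smallest number of top clones
reaching a 75% read share, D75 = 100·k / richness; it is computed on read
shares, following the verbal definition of the metric.  Head-to-head
diversity comparisons refuse samples with unequal sorted cell counts unless
explicitly overridden; a seeded read-downsampling utility is provided as an
extension, but equalising sorted cells at the experiment level is the
supported contract.

# Association analyses

Feature proportions within frequency classes are clonotype-weighted (each
unique clonotype counts once in its class): the classes already encode
abundance, and the quantity of interest is the composition of the distinct
sequences at each expansion level.  Replicate proportions are averaged per
donor; both levels are emitted.  Group contrasts use the unpaired
two-sided Wilcoxon rank-sum test with midranks: exact enumeration when the
pooled size is at most 16 without ties, otherwise the normal approximation
with tie and continuity correction.  The reported effect is the plain
difference of group medians; no multiple-testing correction is applied by
default (raw p-values with optional Benjamini–Hochberg columns are an
extension for callers).  Spearman matrices for per-donor phenotype
fractions use midranks, with constant columns emitted as missing.

# The simulator: what it emulates, and what it does not

The generator exists so that every pipeline stage can be validated against
known ground truth without any external download.  Per donor, a naive
clone pool is drawn: V = TRDV2; D and J by configurable usage (defaults
J1-dominant, TRDD3-dominant); geometric end trimming (default mean 3 nt
per trimmed end); uniform-ACGT N blocks of Poisson length (default mean
4 nt per block); nonproductive junctions rejected and redrawn.  D remnants
of one or two nucleotides are dropped at generation because they cannot be
certified by exact matching — this keeps the ground-truth "germline route"
label aligned with what any decomposition could recover.  Convergent
recombination is emulated by seeding a configurable public pool (default:
fourteen widely shared public Vδ2 sequences) across donors through
donor-specific synonymous codon routes, so multiple nucleotypes per public
amino-acid sequence arise naturally.

Clonal structure: each clone receives an expansion weight
`w = exp(β_hAA5·I(hAA5) + β_J1·I(J1) − β_len·(CDR3 length − 12))`; each
subset samples its clones from the donor pool with probability
proportional to `w` (peripheral selection) and draws clone fractions from
a continuous power law (Pareto tail, subset-specific exponent) reweighted
by `w`; each replicate library is a multinomial sample of exactly
`reads_per_sample` reads.  The logistic coupling is a simple, monotone,
controllable stand-in for a coupling the literature implies but does not
parameterise; the power law matches the heavy-tailed look of real
repertoires without claiming a fitted exponent.

Defaults mirror the cohort design the package targets: 9 donors, duplicate
libraries, CD27pos/CD27neg subsets, 50,000 sorted cells per sample.  Depth
and pool sizes are not published for such cohorts at clonotype resolution;
20,000 reads per sample and 3,000 naive clones per donor (CD27neg drawn
10× smaller with a steeper size law) were chosen once as realistic for
bulk TRD libraries of sorted subsets and are not revisited.  Determinism:
one root seed; per-donor substreams derived by fixed integer hashing (one
generation stream, one sampling stream per donor), so cohorts are
byte-identical across runs and adding a donor leaves the others unchanged.

What the simulator does *not* model — and hence what passing tests do not
show about real data: thymic selection and biophysically realistic
generation probabilities, TCRγ pairing, sequencing error and UMI
artefacts, inter-donor heterogeneity in usage or depth, and P-nucleotide
structure.  It validates the pipeline's statistical behaviour, not
biological realism.

# Validation design and problem sizes

The test suite pairs every nontrivial algorithm with an independent
oracle: decomposition scores against exhaustive enumeration on 500
junctions (250 random, 250 simulator-drawn, ≤ 48 nt); exact Wilcoxon
p-values against full permutation enumeration for all group sizes up to 8;
diversity identities against closed forms (uniform K-clone repertoires
give H = ln K and D75 = 75%; a single clone gives H = 0 and D75 = 100%).
Type-I calibration simulates 1000 null cohorts (β = 0) of 16 donors split
8 vs 8 — equivalent to independent cohort pairs at half the cost — with
120-clone pools and 1,500 reads per sample, and requires the rank-sum
rejection rate at α = 0.05 to fall in [0.035, 0.065].  Effect-direction
recovery uses β = 1.5 couplings across 10 donors (600-clone pools, 6,000
reads) and a 10-seed CD27neg-focusing design (60 vs 600 clones, exponents
1.6 vs 2.5); these sizes were chosen as the smallest at which the
programmed effects are comfortably identified.

# Known limitations

* Absolute N-insertion counts are a lower bound under exact matching and
  are not comparable across tools that model P nucleotides.
* The TRDJ2/TRDJ4 reference entries back-code the documented junction-frame
  amino-acid heads; both segments are rare in Vδ2 repertoires and play no
  role in the headline analyses.
* Publicity is defined at the whole-donor level ("shared among at least
  two donors"), not per sorted subset; per-subset sharing can be obtained
  by filtering the input before the concordance step.
* The equal-cell-number contract is enforced, not corrected for; the
  downsampling utility is a convenience, not a statistical equivalence
  claim.
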