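---
title: "Methods: miRNA discovery, target prediction and degradome validation in mirseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery, target prediction and degradome validation in mirseed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mirseed reimplements, as a tested and reusable pipeline, the analysis
protocol used in plant (cereal) embryo small-RNA studies: read cleaning,
classification of sequencing tags against structural-RNA references,
identification of known miRNAs against a miRBase-style database, novel
miRNA prediction from genome-excised fold-back precursors, miRNA target
prediction under the six plant complementarity rules, degradome
(PARE)-based cleavage-site validation, and tag-count expression
statistics. This vignette describes the models and procedures, the
parameters that matter, the numerical choices made where the protocol
leaves them open, and what the synthetic benchmark does and does not
demonstrate.

## Data model and conventions

All sequences are held internally in the DNA alphabet (`T`, never `U`);
conversion to RNA notation happens only at display and energy-model
boundaries. One canonical alphabet prevents U/T mismatches between stages
that exchange sequences. All coordinates are 1-based and inclusive, the
convention of published binding-site tables (a site printed as 839–858
occupies positions 839 through 858 of the CDS).

The unit of quantification is the *tag record*: one distinct small-RNA
sequence with per-library read counts. Raw reads are collapsed to tag
records immediately after cleaning; every later stage (classification,
miRNA calling, expression) operates on tags weighted by their counts.

## Read cleaning

`clean_reads()` applies, in order: a low-quality filter, a 5'-adaptor
contaminant filter, 3'-adapter trimming, an N-content filter, and the
length window. Defaults:

* length window **18–30 nt** (inclusive), the insert size selected at
  small-RNA library construction;
* *low quality* is not defined precisely in the protocols this package
  follows, so the package adopts a simple documented contract: discard a
  read if any base has Phred quality below 20. The rule only applies when
  qualities exist (FASTQ input); FASTA input passes through.
* adapters are likewise platform-specific configuration, not claims:
  reads *beginning with* the 5' adapter are discarded as contaminants
  (exact prefix match), and the 3' adapter is located by an exact match of
  its first 8 nt anywhere in the read, trimming everything from the match
  on.

The cleaning statistics are conservative by construction: the counts
removed per rule plus the surviving count always equal the input count,
and cleaning is idempotent. Length distributions are computed on read
counts, not distinct sequences, matching how published length profiles
(24-nt dominant, 21-nt secondary in cereal embryos) are reported.

## Tag classification and known-miRNA identification

Tags are classified against an ordered list of reference sets (rRNA,
tRNA, snRNA, snoRNA, repeat, exon, intron): a tag takes the class of the
*first* set containing it as an exact substring on either strand, so
classification is a partition and structural RNA is removed before miRNA
prediction, as in the standard annotation cascade. Reverse-complement
matches count here because sequencing tags are strandless with respect to
an arbitrary reference. They do **not** count for miRNA calling, where
mature miRNAs are single-stranded entities.

Known miRNAs are identified by three tiered rules, checked in order:

1. **precursor_exact** — the tag is an exact substring of a same-species
   precursor;
2. **overlap** — an ungapped overlap alignment with a same-species mature
   covering at least 16 positions with no mismatch in the overlap. The
   16-nt rule is stated without a mismatch budget in the protocols this
   package follows; zero mismatches is the strictest reading and the
   budget is exposed as `overlap_mismatches`;
3. **cross-species** — an alignment to any plant mature or precursor with
   at most 2 mismatches *or gaps* (one pooled budget, following the
   "two mismatches or free gaps" convention), accepted only if a hairpin
   precursor can be verified at the tag's genomic locus (delegated to the
   novel-miRNA folder below).

Same-species rules always take precedence over the cross-species rule.

## Folding model and novel-miRNA calling

Secondary structure is predicted by a stacking-energy dynamic programme:
a Nussinov-style pseudoknot-free recursion that minimises the summed
nearest-neighbour stacking energy over helices, using the published
Turner 2004 RNA/RNA stack table (Watson–Crick and G·U pairs; minimum
hairpin loop 3 nt; lone pairs contribute 0, so MFE ≤ 0 always). This
model deliberately omits loop, bulge and multiloop penalties: it is fast,
exactly reproducible, and sufficient for the discrete hairpin-geometry
decisions the pipeline makes. It is **not** a substitute thermodynamic
model for absolute energies — MFE and hence MFEI values are
model-dependent, which is why the package's tests are phrased as
planted-truth recovery rather than literature MFEI comparisons, and why
`parse_fold_file()` accepts externally computed RNAfold-format structures
wherever a fold result is used.

Candidate precursors for a genome-mapped tag are excised as two windows
per locus: 250 nt upstream + 20 nt downstream, and 20 nt upstream +
250 nt downstream, clipped to the chromosome (minus-strand loci are
reverse-complemented so the mature reads 5'→3' on the window). Because
precursor boundaries are unknown a priori and long windows let unrelated
flanking sequence distort a maximising fold, each locus is additionally
folded at nested tighter extents (100 and 60 nt of far-side context) and
the best passing window wins.

A window is accepted as a miRNA hairpin when:

* the mature lies wholly on one arm, with at most 4 unpaired bases;
* a star segment exists — the span of the mature's partners, extended
  2 nt at its 3' end for the Dicer duplex overhang — with at most 4
  defects in the mature/star duplex. Defects count unpaired mature bases
  *plus bulged star positions inside the pairing span*, so scattered
  pairing that happens to sit on one side does not qualify;
* at most one loop separates mature and star;
* **MFEI ≥ 0.9**, computed as AMFE / GC%, AMFE = −MFE/length × 100.
  The MFEI formula is the standard definition (the protocols cite the
  threshold, not the formula). MFEI is computed on the *trimmed
  precursor* — the mature-to-star span — not on the raw 270-nt excision
  window, where background sequence would dilute AMFE and make a fixed
  threshold meaningless;
* expression support of at least 5 reads (config-exposed; published
  screens report families at ≥ 1 RPM, which is not computable per-tag
  without the library total, so a small absolute floor is used).

The star-duplex tolerances mirror the defaults of the Mireap-style
predictors these criteria descend from; they are assumptions exposed as
parameters, not published claims. Ties between passing windows are broken
by lower precursor MFE.

Reverse-complement invariance of MFEI holds exactly for Watson–Crick-only
folds (the stack table is strand-symmetric); G·U wobbles break the
symmetry, since their reverse complement (C·A) does not pair. The test
suite checks the invariant on WC-only folds.

## Target prediction: the six rules

A candidate site is an *ungapped* antiparallel duplex between the miRNA
(5'→3', positions 1..L from its 5' end) and an equal-length transcript
window; position *i* of the miRNA pairs site position L−i+1. Gapped
duplexes are excluded: the rules speak only of mismatches, and bulge
support would require a scoring the protocol does not define. The rules:

1. at most 4 mismatches, G·U wobbles counting 0.5;
2. no more than two adjacent mismatches;
3. no adjacent mismatches in positions 2–12;
4. no mismatch at positions 10–11 (the slicing positions);
5. at most 2.5 mismatches in positions 1–12;
6. duplex free energy at least 75% of the energy of the miRNA bound to
   its perfect complement.

G·U wobbles count 0.5 toward the totals of rules 1 and 5 but are treated
as pairs (not mismatches) for the adjacency/position rules 2–4, following
Allen-style plant target scoring; whether the original protocol counted
them as mismatches there is not stated, so `gu_is_mismatch = TRUE`
selects the stricter behaviour.

Duplex energy is the sum of negative nearest-neighbour stack terms over
maximal runs of consecutive paired positions, from the same embedded
stack table as the folder; mismatches contribute nothing and break
stacks, so degrading a pair can never strengthen the duplex. Because the
numerator and denominator of the rule-6 ratio use the same model, the
75% criterion is model-consistent even though absolute energies are
approximate.

Every transcript window is evaluated; all passing windows are reported
(no non-maximum suppression) sorted by (mismatch total, decreasing energy
ratio, start), and downstream degradome validation disambiguates
overlapping calls. The expected cleavage coordinate of a site is
**end − 9**: slicing occurs opposite miRNA positions 10–11, i.e. 10 nt
upstream of the transcript position paired with the miRNA's 5' end. This
single identity reproduces every published (binding site, cut site) pair
used as test fixtures, e.g. 839–858 → 849 and 1560–1580 → 1571.

## Degradome mapping and validation

Degradome 5' tags are mapped by exact sense-strand matching: a tag
increments transcript position *p* when it matches exactly starting at
*p*. Mapping is sense-only because PARE tags derive from the cleaved mRNA
itself; multi-mapping tags increment every locus, conserving tag mass.

A predicted site is validated when the maximum tag count within ±1 nt of
its expected cut (the window absorbs 1-nt mapping ambiguity and is
config-exposed) reaches 2 reads. The minimum abundance is an assumption —
the protocols do not state one — and is likewise exposed. Peaks carry the
de-facto degradome categories: 0 = unique transcript maximum, 1 = tied
maximum, 2 = above the median of nonzero positions, 3 = at or below the
median with more than one read, 4 = single read. Categories are reported;
only the read gate decides validation. Off-site positions with abundance
at least the on-site peak are listed alongside each validated site,
mirroring published tables that print a secondary transcript-wide peak
next to the site cut.

## Expression statistics

* **TPM** = count / total clean reads × 10⁶ (tags per million). Over all
  features of a library whose total equals the column sum, TPM sums to
  exactly 10⁶.
* **log2 fold change** = log2(treatment/control) on TPM, with both values
  floored at 0.01 TPM so zero counts stay finite. The floor affects fold
  changes only, never p-values.
* **Differential expression**: the Audic–Claverie tag-count test
  (default) or Fisher's exact test. The AC posterior of count *b* given
  count *a* and the library-size ratio is the negative binomial
  NB(a+1, N₁/(N₁+N₂)); the implementation evaluates its tails with
  `pnbinom` and symmetrises by summing the smaller tail in both
  directions, so p(a,b) = p(b,a) exactly and identical evidence gives
  p = 1. The test-count screens this package follows used one pooled
  library per condition, so no replicate dispersion model is fitted and
  no multiple-testing correction is applied to DE calls: a feature is
  significant iff |log2FC| ≥ 1 *and* p < 10⁻⁵. "Fold change of at least
  2" is read as linear two-fold (|log2FC| ≥ 1); reading it as log2FC ≥ 2
  would contradict the log2 definition of fold change, and the threshold
  is a parameter in any case.
* **Enrichment**: upper-tail hypergeometric test per term against a
  background gene set, raw p < 0.05 by convention, optional
  Benjamini–Hochberg column.
* **ΔΔCt**: 2^−ΔΔCt relative quantification with a reference gene and a
  calibrator sample (calibrator = 1.0).

## The synthetic benchmark

`make_genome()`, `make_srna_library()` and `make_targets_and_degradome()`
generate a fully specified cohort with known truth; all generators are
pure functions of (parameters, seed). The defaults emulate the cereal
embryo study conditions:

* libraries with a 24-nt-dominant (70%), 21-nt secondary (20%) length
  mix, drawn multinomially over an i.i.d.-uniform background genome;
* 50 planted hairpins (stems ≥ 25 bp, ≥ 80% Watson–Crick with the rest
  G·U wobbles, loops 6–12 nt, 21-nt mature on a random arm at 50 planted
  reads) and 50 decoys — dinucleotide-shuffled hairpin sequences, which
  preserve composition but not the fold-back;
* 40 planted target sites, half rule-compliant (perfect or one benign
  3'-region mismatch), half deliberate violators of a recorded rule
  (a slicing-position mismatch, three adjacent mismatches, or five
  scattered mismatches);
* degradome libraries with 50 signal reads starting exactly at each
  planted cut (site end − 9) over Poisson(0.1) per-position background
  noise.

On this cohort the pipeline recovers ≥ 90% of planted miRNAs with ≤ 10%
decoy acceptance, validates ≥ 90% of compliant sites with ≤ 5% null
(signal-free) validation, and detects planted 8-fold expression changes
at ≥ 90% power with type-I error within twice nominal — the quantities
recomputed by `scripts/acceptance.R`.

What passing these tests shows is internal correctness: the rules,
geometry and statistics do what they claim on data whose truth is known.
What it does not show is performance on real barley libraries: the
background model is i.i.d. uniform (no repeats, no transcriptome
structure, no sequencing error), hairpins are cleaner than many genuine
precursors, and the built-in energy model is simpler than full
thermodynamic folding. Published headline counts (thousands of known
families, hundreds of novel candidates) depend on the original libraries
and genome build and are not reproducible at this scale.

### Problem sizes

The shipped benchmark uses a ~15-kb genome (50 + 50 inserts with 120-nt
spacing), 10,000-read libraries, 40 transcripts of 1.2 kb and
2,000-feature DE simulations. These sizes give stable rates (binomial
standard errors of a few percent on the recovery quantities) while
keeping the full suite and the acceptance script fast on a single CPU.

## Known limitations

* The built-in folder has no loop penalties or partition function;
  borderline MFEI values near 0.9 should be re-checked with an external
  thermodynamic folder via `parse_fold_file()`.
* Ungapped duplexes only; targets with genuine bulges are missed.
* Degradome mapping is exact and ungapped; spliced or edited transcripts
  are out of scope.
* No replicate-aware dispersion modelling in DE.
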