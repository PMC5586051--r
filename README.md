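# mirseed

An R package implementing the complete computational protocol of plant
small-RNA sequencing studies of seed development: identification of known
and novel miRNAs from sequencing tags, expression quantification and
differential-expression calling, miRNA target prediction under the six
plant complementarity rules, and degradome (PARE)-based validation of
cleavage sites. It is aimed at analysts who want the classic cereal
miRNA-annotation cascade as tested, scriptable functions rather than a
chain of web services, and at methodologists who need a benchmark with
planted ground truth.

## What it computes

**miRNA identification.** Cleaned 18–30-nt tags are classified against
ordered structural-RNA references (rRNA → tRNA → snRNA → snoRNA → repeat
→ exon → intron, exact substring, first match wins). Remaining tags are
called as known miRNAs by tiered rules — exact substring of a
same-species precursor; an ungapped ≥ 16-nt mismatch-free overlap with a
same-species mature; or ≤ 2 mismatches-or-gaps against any plant
mature/precursor plus a verifiable hairpin at the locus. Unannotated tags
enter novel-miRNA prediction: candidate windows excised around each
genomic locus are folded with a built-in nearest-neighbour
stacking-energy DP (Turner 2004 stack table, Watson–Crick and G·U
pairs), and a hairpin is accepted when the mature sits on one arm
(≤ 4 unpaired bases), a star with 2-nt 3′-overhang geometry exists
(≤ 4 duplex defects), at most one loop separates them, and

```
MFEI = (−MFE / L × 100) / GC%  ≥  0.9
```

computed on the trimmed precursor.

**Target prediction.** Each transcript window of miRNA length is scored
as an ungapped antiparallel duplex (position *i* of the miRNA pairs site
position L−i+1) under the six rules: ≤ 4 mismatches with G·U = 0.5;
no run of > 2 adjacent mismatches; no adjacent mismatches in positions
2–12; no mismatch at positions 10–11; ≤ 2.5 mismatches in positions
1–12; duplex energy ≥ 75% of the perfect-complement energy. The expected
cleavage coordinate is **site end − 9** (opposite miRNA positions
10–11).

**Degradome validation.** 5′ tags are mapped sense-strand exactly; a site
is validated by a ≥ 2-read peak within ±1 nt of its expected cut, with
CleaveLand-style abundance categories 0–4.

**Expression.** TPM = count/total × 10⁶; fold change =
log2(treatment/control); Audic–Claverie (or Fisher) tag-count tests with
significance at |log2FC| ≥ 1 and p < 10⁻⁵; hypergeometric term
enrichment; ΔΔCt relative quantification.

**Synthetic data.** `make_genome()`, `make_srna_library()`,
`make_targets_and_degradome()` and `simulate_cohort()` generate genomes
with planted hairpins and shuffled decoys, 24-nt-dominant libraries,
transcripts with rule-compliant and rule-violating binding sites, and
degradome libraries peaked at the planted cuts — so every stage is
testable against known truth.

## Worked example

```r
library(mirseed)

# a genome with 5 planted miRNA hairpins and 5 shuffled decoys
gen <- make_genome(n_hairpins = 5, n_decoys = 5, seed = 42)
tag <- gen$truth$mirnas$mature[1]          # "ACTTAGTTGTATCGGGAGTAT"

# novel-miRNA calling from the genome alone
hp <- call_novel(tag, excise_candidates(tag, gen$genome), count = 50)
sprintf("arm=%s MFE=%.1f GC=%.1f%% MFEI=%.2f", hp$arm,
        hp$precursor_mfe, hp$gc_percent, hp$mfei)
#> "arm=3p MFE=-49.7 GC=40.0% MFEI=2.07"

# transcripts with planted target sites + a degradome library
td <- make_targets_and_degradome(gen$truth, transcripts_n = 6,
                                 signal_reads = 50, noise_rate = 0.1,
                                 seed = 43)
s1 <- td$sites[td$sites$class == "compliant", ][1, ]
sites <- scan_transcript(s1$mirna, td$transcripts[[s1$transcript_id]],
                         transcript_id = s1$transcript_id,
                         mirna_id = s1$mirna_id)
sites[, c("start", "end", "expected_cut", "mismatch_total", "energy_ratio")]
#>  start end expected_cut mismatch_total energy_ratio
#>    906 926          917              1    0.9100257

profiles <- map_tags(td$degradome, td$transcripts)
report_validated_pairs(sites, profiles)[
  , c("start", "end", "expected_cut", "peak_position", "peak_count",
      "category")]
#>  start end expected_cut peak_position peak_count category
#>    906 926          917           917         50        0
```

The planted site at 906–926 passes the six rules with one benign
mismatch (energy ratio 0.91 ≥ 0.75), its expected cut 917 = 926 − 9, and
the degradome peak of 50 reads at exactly that coordinate validates it
at category 0 (unique transcript-wide maximum).

## Layout

| path | contents |
|---|---|
| `R/sio.R` | FASTA/FASTQ/collapsed-FASTA/TSV readers and writers, tag records, count matrices |
| `R/preprocess.R` | read cleaning, length distributions |
| `R/annotate.R` | ordered classification, known-miRNA calling |
| `R/fold.R`, `R/energy.R`, `src/fold.cpp` | folding DP, stack table, structure import |
| `R/novel.R` | precursor excision, hairpin geometry, MFEI, novel calls |
| `R/target.R` | six-rule duplex scoring and transcript scanning |
| `R/degradome.R` | PARE tag mapping, T-plot profiles, site validation |
| `R/expression.R` | TPM, DE tests, enrichment, ΔΔCt |
| `R/synthetic.R` | planted-truth generators |
| `R/pipeline.R` | stage orchestration, config, manifest |
| `vignettes/mirseed-methods.Rmd` | the methods account: models, parameters, limitations |
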