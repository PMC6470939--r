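---
title: "Profiling mobile xylem-sap miRNAs under cadmium stress: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling mobile xylem-sap miRNAs under cadmium stress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylemiR)
library(dplyr)
```

## The problem

MicroRNAs move systemically in plants, and the xylem sap — the root-to-shoot
stream — is one of the compartments that can carry them. Profiling the small
RNAs of xylem sap from heavy-metal-stressed seedlings asks four questions in
sequence: which 20–22-nt tags in the sequencing libraries are miRNAs (known,
precursor-arm-derived, cross-species homologs, or genuinely novel)? Which of
them respond to cadmium exposure? Which transcripts do they silence, and by
what mode? And is there degradome (PARE) evidence that the predicted
cleavage actually happens?

xylemiR implements that analysis chain as composable, data-frame-first
functions, together with a fully seeded synthetic-data generator so that the
whole pipeline can be exercised — and its recovery quantified against known
ground truth — without any external download. This vignette explains the
models, the tunable parameters, and the design decisions taken where the
underlying methodology left genuine freedom.

## Read processing

Raw reads are adapter-trimmed (`trim_adapter()`), collapsed to unique tags
with per-library counts, and filtered (`collapse_and_filter()`):

* **Adapter**: the default 3' adapter `TGGAATTCTCGGGTGCCAAGG` is the common
  small-RNA kit sequence; it is a parameter everywhere. Matching accepts a
  full internal occurrence or a 3'-terminal prefix of at least
  `min_overlap = 6` nt, with a mismatch rate up to 10% of the overlap.
  Inserts shorter than 15 nt are discarded as adapter dimers/junk.
* **Contaminants**: tags that are exact substrings (either strand) of the
  contaminant reference are removed. The bundled reference
  (`synthetic_contaminants()`) is *synthetic* rRNA/tRNA/snRNA-like sequence
  — a stand-in set, clearly labelled as such, because contaminant filtering
  is a mechanism of this pipeline, not a claim about any database.
* **Low complexity**: a tag is removed when a mono- or di-nucleotide repeat
  covers ≥ 80% of it. The 80% value is a concrete, testable choice for the
  otherwise vague notion of "low complexity".
* **Lengths**: processing keeps 18–30 nt so that qRT-PCR-size small RNAs
  survive; the stricter 20–22-nt miRNA window is applied at annotation.

Every read is assigned to exactly one ledger class (`kept`, `no_adapter`,
`too_short`, `contaminant`, `low_complexity`, `out_of_range`); the ledger is
an attribute of the tag table and a tested conservation invariant.

## Variant-aware matching and isomiR naming

`match_tag()` matches tags against reference matures allowing up to 2 nt of
5'/3' end shift (extensions verified against precursor context) and at most
1 internal substitution — bounds implied by the isomiR naming convention the
field uses (`_L±n`, `_R±n`, `_kssPPXY`). The best match minimises
(substitutions, total shift), then prefers own-species references, then the
lexicographically smallest id. Applying the recorded shifts and
substitutions to the reference reproduces the tag exactly; that
reconstruction is a tested invariant.

## Hairpin folding: the SLF-1 model

Candidate precursors are folded with a deliberately simple, fully specified
single stem-loop model rather than a nearest-neighbour thermodynamic one:

* pair energies GC/CG −3.0, AT/TA −2.0, GT/TG −1.0 (model kcal/mol);
* +3.0 to close the terminal loop (minimum 3 unpaired nt);
* +0.5 per unpaired nucleotide interior to the stem;
* dangling ends outside the outermost pair are free.

The optimum over all nested pair ladders is computed exactly by a two-state
dynamic program in integer half-units (so ties are exact), with ties broken
toward more pairs and then a fixed traceback order. An independent
enumeration oracle written directly from the definition validates the DP on
hundreds of random sequences in the test suite. A `backend` hook on
`fold_best_hairpin()` accepts a substitute folding engine with the same
contract; all bundled validation uses SLF-1.

Two model properties are worth knowing:

* **Symmetry**: the model is symmetric under sequence *reversal*. It is
  *not* symmetric under reverse complementation, because complementing maps
  a G·U wobble to the unpairable A·C — true of any wobble-aware model.
* **Diffuse folds**: a random 260-nt window folds to roughly −155 to −180
  under SLF-1, because long internal loops are cheap (+0.5/nt). Genuine
  hairpin detection therefore leans on the duplex criteria below, not on
  the raw MFE, and the synthetic generator plants stems strong enough to be
  the unique optimum of their windows (see *Synthetic data*).

`evaluate_precursor()` folds three windows anchored on the mapped tag
(tag ± 120 nt; tag at the 5' end with 240 nt downstream; the mirror), since
a mature may sit on either arm of its hairpin, and keeps the best-passing
window. The criteria, all configurable via `precursor_thresholds()`:

| criterion | default | meaning |
|---|---|---|
| mature on one arm | — | the tag must not span the terminal loop |
| duplex mismatches | ≤ 4 | mature positions unpaired against the star arm |
| asymmetric bulge | ≤ 2 nt | within the mature/star duplex |
| MFE | ≤ −18 | model stability floor |
| MFEI | ≥ 0.85 | AMFE (= −MFE/length × 100) divided by GC% |

The MFEI ≥ 0.85 rule is the classical plant pre-miRNA stability index
threshold. The duplex values are explicit stand-ins for criteria that the
plant miRNA-annotation literature states in several variants.

## Annotation decision tree

`classify_tags()` assigns each 20–22-nt tag the first class that applies:
**known** (variant match to an own-species mature), **novel_arm** (exact hit
on the arm opposite an annotated mature, named `PRECURSOR-p5`/`-p3`),
**homolog** (match to another monocot's mature or precursor whose precursor
also occurs in the own genome), **novel_pc** (genome-mapped tag whose locus
passes precursor evaluation, named `PC-{5p|3p}-{serial}_{count}` with
serials in genome order so runs are reproducible). Everything else is
dropped with a recorded reason; classes plus drops always partition the
input, and a tag matching both an own mature and a monocot reference is
always `known`.

Choices worth stating:

* The confidence filter keeps records with **normalized count ≥ 10**
  (inclusive) in at least one library: the reported tables this mirrors
  contain rows whose maximum is exactly 10, so the inclusive reading is the
  self-consistent one.
* "Support in at least two libraries" is read as ≥ 1 raw read in ≥ 2
  libraries; the structural criteria are a property of the sequence and do
  not vary by library.
* IsomiR length variants on the same precursor arm share a `-pN` name;
  since names must be unique in a run, same-name records are merged
  (counts summed, most abundant tag kept as representative).
* Significance ("expressed with p ≤ 0.05 in at least one comparison") uses
  the **minimum over pairwise** library comparisons — the pooled-versus-
  pairwise choice is not dictated by the method description, and pairwise
  is the documented choice here.

## Differential expression

Counts from single libraries (no replicates) are compared per tag with
exact 2×2 tests on raw counts versus library totals: Pearson's chi-squared
(1 df, no continuity correction; Yates optional) when all four expected
counts are ≥ 5, Fisher's exact test otherwise — a concrete reading of
"selectively using" both tests; `method = "fisher"` forces the exact test.
The two-sided Fisher p sums all hypergeometric outcomes no more probable
than the observed table, computed in log space; the test suite checks it
against full enumeration for every table with margins ≤ 30.

Fold changes are computed on normalized counts (reads per million by
default), with a 0.5 pseudocount applied **only** to a zero side, and a tag
is called up/down when |log2FC| ≥ 1 and p ≤ 0.05. Regulation classes are
de-duplicated by miRNA name, so a miRNA expressed from two loci counts
once.

**Limitation, stated plainly**: single-library exact tests assume roughly
Poisson sampling. Under biological overdispersion (the generator's default
NB dispersion of 0.1), tags with mean counts above ~20 exceed the nominal
type-I rate, and the |log2FC| ≥ 1 gate is what keeps the aggregate false
positive rate low for realistic, heavily low-count-skewed abundance
profiles. The null-calibration test measures exactly that aggregate.

## Target prediction

Two independent complementarity schemes scan the transcriptome antiparallel
(miRNA 5' end pairs the site's 3' end):

* **Expectation scheme** (`scan_targets_expectation()`): per-position
  penalties — mismatch 1, G:U wobble 0.5, gap 2 — doubled over miRNA
  positions 2–13 (the seed), sites kept at expectation ≤ 5. Gaps are miRNA
  positions opposite a deletion in the site, at most 2, never opposite
  positions 10–11. Sites are found by an exact DP validated against
  brute-force enumeration of all gapped alignments.
* **Penalty scheme** (`scan_targets_penalty()`): gapless, penalties
  mismatch 1 / wobble 0.5 doubled over positions 2–17, cutoff 2.5
  ("moderate" stringency). This is defined as a scheme of this package,
  deliberately independent of scheme A in its weighting window and its
  treatment of gaps.

Gaps are modelled as target-site deletions only: this keeps the pairing
string exactly one symbol per miRNA position, so the reported expectation
is always recomputable from the reported pairing — a tested invariant.
Predicted **inhibition is Cleavage** when miRNA positions 9–11 are all
Watson–Crick paired, else Translation: a concrete reading of the
cleavage-site requirement at the duplex core. `intersect_predictions()`
keeps (miRNA, transcript) pairs called by both schemes with ≥ 50% site
overlap; gene-level roll-ups use an explicit transcript→gene map or the
`GENE_Tnn` suffix convention. `upe_proxy()` estimates site accessibility as
the SLF-1 energy cost of forcing the site open in its ±17-nt context — a
proxy on the model's own scale, not a thermodynamic energy.

## Degradome evidence

The expected cleavage position is the transcript base pairing miRNA
position 10, walked through any gap columns. Each predicted site is scored
per degradome library with the standard five-tier T-plot category (0 unique
maximum, 1 tied maximum, 2 above the occupied-position median, 3 otherwise,
4 a single tag), and `deg_count` counts libraries with category ≤
`category_max` (default 2) within ± 1 nt. Both knobs are logged in every
run manifest.

Category 2 ("above median") is weak evidence: on a dense uniform tag
profile, a queried position beats the median roughly half the time, and the
±1-nt tolerance raises per-library "support" to ~0.8. Dominant-peak
stringency (`category_max = 1`) is the setting under which uniform noise
yields zero support, and the tests assert exactly that; the synthetic
validation plants 80% peaks, for which the default settings give
unambiguous category-0 support.

## Synthetic data: what it emulates, and what it does not

The generator produces three libraries (C0/C1 untreated, Cd1 treated) with
planted, re-derivable ground truth:

* **Genome and hairpins** (`synth_genome()`): hairpins are
  `arm + loop(6–12) + revcomp(arm)` with 0–3 planted star-arm mispairs,
  embedded non-overlapping in random background; the mature 20–22-mer is
  unique genome-wide outside its own hairpin (the star arm may carry its
  reverse complement — as real miRNA* arms do). Two constraints exist so
  the truth is *re-derivable by the pipeline's own model*: arms are drawn
  80–90 nt at GC 55–65% (stem energies ≈ −205 to −235, below the −155 to
  −180 band of random 260-nt windows, so the planted stem is the unique
  window optimum), and the mature is placed within 120 nt of both hairpin
  ends (otherwise no tag-anchored ±120-nt window contains the star arm and
  the duplex can never be evaluated).
* **Libraries** (`synth_libraries()`): per-miRNA counts are negative
  binomial (dispersion 0.1 by default; 0 gives Poisson) with mean
  proportional to `baseline`, multiplied by `fold_change` in Cd1. Baselines
  are *relative* abundances: a common scale factor fills
  `depth × (1 − background_fraction)` reads with miRNAs (default background
  20%, half contaminant fragments, half fragments from a finite
  Zipf-weighted pool of genomic/random sequences). Reads carry ±1-nt
  end-variant isoforms at fixed rates, the 3' adapter, and are truncated to
  36 nt. Identical seeds reproduce the FASTQ byte for byte.
* **Null baselines**: for calibration runs, baselines default to a
  truncated Pareto (α = 1 on [1, 1000]) — the heavily low-count-skewed
  shape of real unique-tag abundance (libraries of this kind carry on the
  order of one million unique tags in a few million reads).
* **Transcriptome and degradome** (`synth_transcriptome()`,
  `synth_degradome()`): planted sites are reverse complements of their
  miRNAs with stated edits (mismatch, wobble, bulge) at stated positions,
  with the expected scores recorded in the truth table; degradome tags put
  `peak_fraction` of a transcript's 5' ends exactly at the true cleavage
  position, the rest uniform.

The bundled study fixture (`synth_study_fixture()`) plants 10 hairpins, two
8-fold up- and one 8-fold down-regulated miRNA (an 8-fold effect keeps the
observed log2 ratio ≈ 3 standard deviations above the call threshold under
dispersion 0.1, so detection does not hinge on the seed), 50 target sites
whose edits pass both scanning schemes, and three degradome libraries at
peak fraction 0.8.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: sequencing errors and quality
variation, the full sequence complexity of real libraries (background comes
from a finite pool; real backgrounds are vastly more diverse), multi-copy
miRNA families, transcript-side bulges in target sites, secondary-structure
context of real UTRs, or real degradome noise structure.

## Numerical and engineering choices

* All energies and scores are held in integer half-units internally, so
  tie-breaking is exact and platform-independent.
* Windows at chromosome ends are clipped; windows shorter than 15 nt are
  skipped.
* All-zero 2×2 tables return p = 1 by convention; zero GC content is a
  degenerate-sequence error for MFEI.
* Validation problem sizes: folding and scanning oracles run 200 random
  cases each; the Fisher oracle enumerates all ~20,000 margin
  configurations ≤ 30; null calibration simulates 1,500 tags at depth
  10,000 (about 5 reads per planted tag, near the reads-per-unique-tag
  ratio of real libraries of this kind); the end-to-end fixture runs one
  million reads per library. These sizes were chosen so the full suite
  validates every layer on a single CPU in minutes.

## A short tour

```{r, eval = FALSE}
fx <- synth_study_fixture(seed = 1, depth = 1e5)
res <- run_pipeline(fx$config)

count(res$records, class)
glance(res$de$C1_Cd1)
autoplot(res$de$C1_Cd1)
filter(res$supported, deg_count >= 1)
```

## Known limitations

SLF-1 is not a thermodynamic model: its MFE and MFEI values live on the
model's own scale, its diffuse folds make raw stability weakly informative
for long windows, and `upe_proxy()` is an accessibility *ranking* aid, not
an energy. The DE stage inherits the single-replicate design it implements:
no dispersion estimation, no multiple-testing correction by default (an
optional BH flag is the extent of it), and nominal p-values that are only
honest under near-Poisson sampling. Target prediction does not model
translational efficiency, and degradome categories summarise one
transcript's profile at a time. These are boundaries of the method being
implemented, reproduced faithfully rather than silently repaired.
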