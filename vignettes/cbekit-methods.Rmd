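---
title: "Models and methods behind cbekit"
author: "cbekit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cbekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, and numerical choices in
`cbekit` — what each component assumes, where the defaults come from, and
what the synthetic-data validation does and does not demonstrate about
real data.

## Coordinates and the distance-from-PAM convention

All containers are standard Bioconductor objects: guide sets are
`GRanges` (1-based closed intervals on the forward strand of the
reference, the interchange convention throughout R/Bioconductor), and
sequence containers are `Biostrings` objects. Positions within a
protospacer are expressed as *distance from the PAM*: the PAM-adjacent
base is distance 1, so the canonical CBE editing window of 13–19 bp
upstream of the PAM covers protospacer positions 2–8 counted from the
protospacer's 5' end. For a `+` guide whose protospacer starts at forward
position $s$, distance $d$ maps to forward position $s + 20 - d$; for a
`-` guide, to $s + d - 1$.

Two window presets are exposed and neither is asserted as truth: the
canonical `c(13, 19)` and the extended `c(12, 19)` motivated by observed
editing at 12 bp from the PAM with near-PAM-less editors. Whether
editing at distance 12 (and non-editing at 18 at some loci) reflects a
genuinely different window shape or sequence context cannot be decided
from pool-level data, so the choice is left to the user per experiment.

## Guide enumeration and PAM classes

`scanProtospacers()` slides a 20-mer + 3-mer template along both strands.
PAM matching is positionwise IUPAC set membership with one conservative
exception: an `N` in the *reference* matches only a pattern position whose
code is itself `N`, and never matches any protospacer base. This avoids
calling guides across ambiguous reference stretches.

Observed PAMs are binned by their informative second base: `NGG`
(canonical), `NAN`/`NGN` (the purine, NRN tier), `NCN`/`NTN` (pyrimidine,
NYN tier). `rankGuides()` orders candidates by tier (NGG, then other NRN,
then NYN — the qualitative efficacy ordering reported for near-PAM-less
CBEs), then by how central the target Cs sit in the window (mean absolute
distance to the window midpoint — mid-window Cs edit best), then by
bystander count, with genomic coordinate as the final tie-break. The
policy is explicit configuration, not a learned score: the source
experiments support only a qualitative ordering, and we prefer a
transparent, reproducible sort over a pseudo-quantitative model.

## STOP design

`stopEditsForCodon()` enumerates, per codon, every non-empty subset of
sense-strand C→T edits and every non-empty subset of sense-strand G→A
edits (antisense C→T), keeping subsets that produce TAA/TAG/TGA. Mixed
sense/antisense subsets are rejected because one guide exposes one strand
to the deaminase. Six codons are convertible: CAA and CAG (Gln, sense),
CGA (Arg, sense), TGG (Trp, antisense, three routes), and the TAG/TGA
stops themselves (inter-stop conversions, retained for completeness).
`designStopGuides()` then intersects the required C positions with the
editing window of every candidate guide on the correct strand. Bystander
window Cs are annotated by translating the edited codon with the standard
genetic code (synonymous / missense / nonsense / noncoding).

## Read alignment

The quantifier's aligner (in C++) performs a fitting alignment: the read
is consumed end-to-end, leading and trailing *reference* bases are free —
the right geometry for amplicon sequencing, where every read is a
full-length copy of one known reference. Scoring defaults are match +2,
mismatch −3, gap open −8, gap extend −1 (a gap of length $L$ costs
$8 + L$); the defaults are declared, standard amplicon settings — the
underlying experimental pipeline publishes none. Both read orientations
are aligned and the higher score wins, forward on ties. Tie-breaking
inside the DP is fixed (diagonal over deletion over insertion; gap
extension over opening; leftmost end column), so results are
reproducible to the byte. `Biostrings::pairwiseAlignment` with the same
parameters is used in the test suite as an independent score oracle.

For full-length reads the quantifier restricts the DP to a diagonal band
of half-width 32 (`alignParams(band = )`). The band is only engaged when
read and reference lengths differ by at most half the band, which makes
it exact whenever indels are shorter than the band — the regime of
amplicon data — and falls back to the exhaustive DP otherwise (e.g. for
short reads against longer references). `alignRead()` itself defaults to
the exhaustive DP.

## Read classification and rates

Categories, in precedence order:

1. **discarded** — alignment identity < 0.75 or the editing window not
   fully covered (both configurable);
2. **indel** — an insertion/deletion whose reference footprint intersects
   the spacer; an insertion exactly at a spacer boundary counts only when
   strictly inside;
3. **other_substitution** — any window substitution that is not an
   expected edit (whole-read accounting is available behind
   `wholeReadSubstitutions`, but the default follows the window-scoped
   convention of counting substitutions in the base-editor window);
4. **expected_edit_only** — at least one expected C→T on the guide strand
   and nothing else;
5. **WT**.

This makes `pct_unwanted` the exact complement of clean outcomes among
analyzed reads. Per-target conversion rates divide by reads *covering*
the position (deletions count as coverage with a `del` base), so indel
reads do not silently inflate or deflate rates. Whether "other
substitutions" should be counted per read or per base is ambiguous in
the source description; both views are reported — the summary percentage
is per read, the per-position count matrix is per base. No quality
trimming is applied by default and paired ends are assumed merged
upstream; neither step is described for the original pipeline, so we do
not invent one.

## Sanger quantification

`editProportion()` is the two-channel ratio
$100\,h_{edited}/(h_{edited}+h_{target})$ at a called position, matching
how C-vs-T percentages are reported from chromatograms. `detectEdit()`
replaces the zero-adjusted-gamma null of EditR with a deliberately
simpler, documented rule: the detection threshold is the mean + 3·SD of
the edited-base channel proportion over background positions (positions
agreeing with the reference, outside the window, and whose reference base
is neither the target nor the edited base). This reproduces the *spirit*
of "n.d." calls, not EditR's exact cutoff, which is not published to the
precision needed for bit-exact agreement. A minimal ABIF reader/writer
(PBAS/PLOC/DATA9–12/FWO_ tags) is included because no installed R
package parses AB1 chromatograms; it round-trips against the 5-column
tabular trace dialect in the test suite.

## Co-selection model

The enrichment claim behind phenotype co-selection — embryos most edited
at a visible selection locus are most edited at unselectable cargo loci —
is qualitative in the source experiments. `cbekit` formalises it as a
latent-dose model, and labels it as this package's own formalisation:
each embryo draws a dose $u \sim \mathrm{Beta}(\alpha, \beta)$ (how much
active editor it received), and locus $\ell$ responds with mean edit
fraction $\mathrm{logit}^{-1}(a_\ell + b_\ell u)$. In `shared-dose` mode
one dose drives all loci (positive inter-locus dependence, the
co-selection premise); `independent` mode redraws the dose per locus and
breaks it. Per-embryo scatter around the link mean is Beta with
concentration 20 by default — per-embryo dispersion is unreported for
the source cohorts, so this default is a declared, realistic choice for
mosaic F0 animals, not a fitted value (`Inf` gives deterministic
fractions). Phenotype groups (wt-like/mild/severe/albino) threshold the
selection-locus fraction at (0.25, 0.6, 0.9), chosen so simulated group
proportions resemble observed depigmentation spreads; all of these are
configurable.

`trendTest()` uses Spearman rank correlation between ordinal group and
cargo fraction (average ranks for ties) with a label-permutation p-value
$(1 + \#\{|\rho^*| \ge |\rho|\})/(1 + n_{perm})$; for $n \le 9$ an exact
mode enumerates all $n!$ permutations, where the identity permutation
guarantees $p > 0$. Permuted statistics are compared with an absolute
tolerance of $10^{-8}$ so floating-point ties do not flip counts.
`germlineProportion()` uses the exact Clopper–Pearson interval
(`binom.test`) rather than a Wald approximation because founder-cross
counts are small.

## Synthetic data and what the tests show

Generators are pure functions of (parameters, seed). Reads are
full-length amplicon copies — a merged-read abstraction — to which the
expected edits (per-target Bernoulli at the true fraction), at most one
spacer indel per read (deletion or insertion, geometric length with mean
2), and uniform substitution errors (0.1% per base by default) are
applied, with half the reads emitted reverse-complemented; a sidecar
table records every read's ground truth. Traces add a zero-truncated
(half-normal) Gaussian noise term to each channel so heights stay
non-negative and baseline channels carry positive noise, as real
chromatogram baselines do.

The error model is deliberately conservative and declared rather than
inferred: no quality profiles, PCR chimeras, strand bias, or
context-dependent errors are simulated. Consequently the validation
suite demonstrates *estimator correctness* — that the pipeline recovers
known truth within binomial error at realistic depth (6,800+ reads per
condition, the depth floor of the motivating experiments), that
classification partitions exactly, that alignment and off-target scans
match independent oracles — not robustness to every artefact of real
sequencing runs. Problem sizes used by the default test run: 6,800-read
simulations across 20 seeds for rate recovery, a 20 kb genome at up to 3
mismatches for the off-target oracle, 1,000 null traces for the
detection-threshold calibration, and 1,000 replicate cohorts (n = 60,
199 permutations) for the trend-test null; these sizes give the property
checks comfortable statistical resolution while keeping a full run in a
few minutes.

## Known limitations

* The designer scores no efficiency or chromatin features; ranking is a
  transparent heuristic tier sort.
* The off-target scan is a naive Hamming scan (no bulges, no CFD/MIT
  scores) — appropriate for enumerating candidate loci to sequence, not
  for genome-wide specificity claims.
* Sanger thresholds are calibrated under the package's own noise model;
  "n.d." entries produced by other tools will not be reproduced
  bit-exactly.
* UMI handling, demultiplexing, read merging, and SAM/BAM output are out
  of scope.
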