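# cbekit

Design and quantification toolkit for PAM-flexible cytosine base editing.

## The problem

Cytosine base editors (CBEs) — a Cas9 nickase fused to a cytidine
deaminase — convert C:G pairs to T:A without double-strand breaks, but only
inside a narrow editing window 13–19 bp upstream of the PAM (possibly
extending to 12 bp for near-PAM-less variants such as SpRY). Classical
SpCas9 needs an NGG PAM, which leaves many target Cs unreachable;
near-PAM-less editors lift that constraint (working best with NRN PAMs,
less well with NYN) and make essentially every C in a genome addressable —
at the cost of a much larger design space, bystander edits, and unwanted
on-target products that need careful quantification.

`cbekit` provides the computational workflow around such experiments, for
groups engineering point mutations (e.g. premature STOP codons in
zebrafish pigmentation genes, or cancer-associated missense alleles) in
mosaic F0 animals:

* **Guide design** — enumerate 20-nt protospacers under any IUPAC PAM
  pattern, find guides that install a premature STOP at a chosen residue
  through single-strand C→T (or antisense G→A) edits, annotate bystander
  Cs with their coding consequence, and scan a genome for mismatch
  off-targets.
* **Amplicon-NGS quantification** — align reads end-to-end to an amplicon
  reference (affine gaps, free reference end gaps), and classify every
  read as wild-type, expected-edit-only, other-substitution, or
  spacer-overlapping indel; report per-position conversion rates and the
  percent of unwanted outcomes.
* **Sanger quantification** — EditR-style editing percentages from
  chromatogram peak heights, `100 * h(T) / (h(T) + h(C))` at each target,
  with a mean + 3·SD background noise threshold replacing "n.d." calls.
* **Co-selection statistics** — a latent-dose cohort simulator for
  phenotype-based co-selection (embryos most depigmented at the selection
  locus are most edited everywhere), a Spearman permutation trend test
  across ordinal phenotype groups, and exact Clopper–Pearson intervals
  for germline-transmission counts.
* **Synthetic data** — seeded generators for references with planted
  guide sites, amplicon reads with known per-position edit fractions,
  sequencing errors and indels, and four-channel Sanger traces, so every
  stage can be validated against ground truth.

## Core quantities

For a guide with protospacer positions indexed by their distance *d* from
the PAM (PAM-adjacent base = 1, window 13 ≤ *d* ≤ 19 by default), the
per-position conversion rate from NGS is

    rate(d) = reads showing T at the target / reads covering it × 100

on the protospacer strand (equivalently G→A on the forward strand for
antisense guides). A read is *unwanted* if it carries a non-expected
window substitution or an indel whose reference footprint overlaps the
spacer; `pct_unwanted` is their fraction of analyzed reads. The
co-selection trend statistic is the Spearman rank correlation between the
ordinal pigmentation group (wt-like < mild < severe < albino) and the
cargo-locus edit fraction, with a label-permutation p-value
`p = (1 + #{|ρ*| ≥ |ρ|}) / (1 + n_perm)`.

## Worked example

Plant a guide site with target Cs at 15 and 16 bp from an AGG PAM,
simulate 300 reads at 40% true conversion, and quantify:

```r
library(cbekit)

proto <- paste0("GATT", "CC", strrep("A", 14))     # Cs at d = 16, 15
ps <- plantGuideSite(makeReference(240, seed = 3), protospacer = proto,
                     pam = "AGG", position = 101, strand = "+",
                     targetDists = 15)
sim <- simulateReads(ps$spec, simTruth(editFractions = c(`15` = 0.4),
                                       nReads = 300, seed = 9))
quantifyAmplicon(sim$reads, ps$spec)
#> QuantResult: 300 reads in, 300 analyzed (0 discarded)
#>   categories: WT=173, expected_edit_only=126, other_substitution=1, indel=0
#>   expected-edit rate (%): 106:42.0
#>   other substitutions 0.33%, indels 0.00%, unwanted 0.33%
```

The estimated 42.0% at amplicon position 106 (distance 15 from the PAM)
recovers the simulated 40% within binomial noise; the lone
other-substitution read is a sequencing-error artefact, as intended at the
default 0.1% error rate. Germline-transmission arithmetic:

```r
germlineProportion(28, 54)
#> 51.9% (28/54; 95% CI 37.8-65.7%)
```

A command-line wrapper with `design`, `scan-offtargets`, `quantify-ngs`,
`quantify-sanger`, `coselect-sim`, `simulate` and `run` subcommands lives
at `inst/scripts/cbekit` (see `?cbeCli`).

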