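---
title: "Modeling unbalanced MYC break-apart FISH patterns from structural variants"
author: "bapfish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling unbalanced MYC break-apart FISH patterns from structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bapfish)
```

## The problem

The *MYC* break-apart (BAP) probe set flanks the *MYC* gene with a red
probe hybridising 5' (centromeric) and a green probe 3' (telomeric) of the
gene. An intact locus yields a fused red-green signal (F); a classical
rearrangement separates the colours, giving an isolated red (R) and an
isolated green (G) signal beside the remaining fusion — the balanced
RGF-type pattern that is reported as a *MYC* rearrangement.

A substantial minority of abnormal results are *unbalanced*: isolated red
signals without isolated green (RF-type, e.g. 1R1F), or the converse
(GF-type, e.g. 1G1F). Laboratories disagree on whether these patterns
constitute a rearrangement, and genome sequencing shows why the question is
genuinely hard: most unbalanced patterns are produced by true structural
variants juxtaposing *MYC* with a partner locus, but some arise from pure
copy-number changes that current lymphoma classification schemes do not
count as a *MYC* rearrangement.

`bapfish` makes the genotype-to-pattern relationship explicit and
computable. It has three layers:

1. an **ISCN layer** that parses and re-emits "nuc ish" nomenclature for
   the two-probe assay;
2. a **genome layer** that represents derivative chromosomes assembled from
   reference segments and simulates in-silico hybridisation of the probe
   pair against them;
3. an **interpretation layer** that reconciles observed and predicted
   patterns and renders a guarded clinical interpretation of unbalanced
   results.

## Signal arithmetic

For one clone with red total $R$, green total $G$ and a colocalisation
("con") or separation ("sep") relation term, the fusion count is

$$
F = \begin{cases}
\text{con count} & \text{con term present} \\
\min(R, G) - \text{sep count} & \text{sep term present} \\
\min(R, G) & \text{no relation term,}
\end{cases}
$$

and the isolated counts are $R_{iso} = R - F$ and $G_{iso} = G - F$.
Printed count ranges such as `x2~3` are carried as intervals end to end and
every quantity is evaluated at both endpoints; a negative count at either
endpoint is rejected as inconsistent nomenclature rather than clamped.

Classification follows the field's convention:

| class       | rule |
|-------------|------|
| `RGF`       | $R_{iso} \ge 1$ and $G_{iso} \ge 1$ |
| `RF`        | $R_{iso} \ge 1$, $G_{iso} = 0$ |
| `GF`        | $G_{iso} \ge 1$, $R_{iso} = 0$ |
| `NORMAL`    | no isolated signals, $F$ = ploidy |
| `FUSION_CN` | no isolated signals, $F \ne$ ploidy |
| `AMBIGUOUS` | the two endpoints of a range classify differently |

A multi-clone result is classified by its *dominant abnormal clone* — the
non-normal clone observed in the most cells — because the reported group of
a specimen describes its abnormal population, not admixed normal cells.

## The nomenclature dialect

Published nuc ish strings mix Unicode primes (`′`), right single quotes
(`’`) and ASCII apostrophes; tildes (`~`, `∼`) and hyphens as range
separators; and irregular interior whitespace (one table even prints a
stray comma directly after `nuc ish`). The parser normalises all of these
before tokenising, and the writer emits one canonical dialect (ASCII
apostrophe, `~`, single spaces only around `con`/`sep`). The round-trip
property — parse, format, re-parse yields an identical structure — is
enforced by tests over every shipped string and a thousand fuzzed dialect
variants. When both `con` and `sep` appear in one clone the parser refuses
the string: no published example does this, and guessing semantics would be
worse than failing loudly.

Whether a printed range reflects cell-to-cell heterogeneity or a subclone
mixture is not recoverable from the nomenclature; the package treats it as
an interval throughout and never resolves it into a mixture.

## In-silico hybridisation

A genome configuration is a set of derivative chromosomes, each an ordered
list of oriented reference segments. Derivative structure is always
supplied explicitly (ordered segments plus one junction per adjacency);
inferring derivative order from an unordered breakend set is a genome-graph
problem the package deliberately does not attempt, because its inputs are
calls from external SV pipelines that already commit to adjacencies.

Hybridisation maps each probe footprint onto each derivative: every maximal
contiguous run of footprint bases emits a spot if it covers at least
`min_visible_frac` of the footprint, and red/green spots on the same
derivative whose gap is at most `d_fuse` merge into fusions by greedy
nearest-pair matching with a deterministic left-to-right tie-break.

Two tunables matter, and neither is a published number:

* **`d_fuse`** (default 1 Mb) — the colocalisation distance below which two
  spots fuse in interphase nuclei. The default is of the order of the
  optical resolution of interphase FISH relative to genomic distance.
* **`min_visible_frac`** (default 0.3) — the fraction of a ~400 kb
  footprint that must remain to give a visible signal. How a partially
  deleted footprint manifests (dim vs absent) is not described in the
  source material; this threshold is the package's explicit stand-in.

All shipped case reconstructions and synthetic archetypes are required by
test to classify identically when `d_fuse` is halved or doubled, so no
conclusion in the package hinges on the exact values. The implementation is
cross-checked against an independent per-base oracle (exhaustive run
enumeration and pairwise merging) on hundreds of random configurations of a
miniature locus; the logic is scale-free, so the miniature coordinates
exercise the same code paths as genomic ones.

## Probe coordinates

Vendor probe coordinates are unpublished. The shipped defaults are
illustrative ~400 kb blocks on GRCh38-like chr8 coordinates: red at
127.35–127.71 Mb ending centromeric of *MYC* (127.735–127.743 Mb), green at
128.10–128.50 Mb starting telomeric of the PVT1 block (127.794–128.08 Mb).
Every analysis in the package depends only on the relative layout — red
centromeric, green telomeric, a gap spanning the gene and PVT1 — which is
exactly what the assay's documentation does specify. The red–green gap
(390 kb) is kept below half the default `d_fuse` so that the intact locus
fuses across the required two-fold parameter range. Footprints are
configurable via a 4-column BED for users with exact coordinates.

## The validation set

The package ships 14 encoded cases: verbatim nomenclature strings, printed
group labels (5 RF, 2 GF, 7 RGF), partner genes, breakpoint position
classes relative to *MYC*, gene-juxtaposition and IHC-overexpression flags,
and a derivative-chromosome reconstruction of each described event. The
source material gives breakpoint descriptions (centromeric/telomeric/genic
relative to *MYC*), not coordinates, so the encoded coordinates are
**illustrative reconstructions** consistent with those descriptions; the
fixture file and each affected record say so. Two cases with multiple
printed events admit several derivative orders; one consistent order is
encoded and flagged. Validation therefore checks *consistency* — that each
reconstruction reproduces its printed pattern class and copy-number
direction end to end — not recovery of unpublished coordinates.

The directional claim that makes unbalanced patterns intelligible is tested
on every unbalanced case: material 5' of *MYC* sits at higher copy number
than 3' material in all RF-type cases, and the reverse in GF-type cases.

## Synthetic rearrangement archetypes

`generate_scenario()` produces seeded configurations with analytically
known truth classes:

| archetype | construction | truth |
|---|---|---|
| `NORMAL` | two intact homologues | `NORMAL` |
| `BALANCED_TRANSLOCATION` | reciprocal exchange at a break between the footprints | `RGF` |
| `UNBALANCED_5P_GAIN` | extra 5'-side copy joined to a partner, homologues intact | `RF` |
| `UNBALANCED_3P_LOSS` | one homologue keeps only the 5' side | `RF` |
| `WHOLE_LOCUS_GAIN` | third intact copy of the locus | `FUSION_CN` |
| `DELETION_5P_AND_MYC` | focal deletion removing the red footprint and *MYC* | `GF` |
| `TEMPLATED_INSERTION` | 5' region copied into a partner locus, source intact | `RF` |
| `GENIC_INTRON1_BREAK` | break inside *MYC* intron 1 | `RGF` or `GF` |

Breakpoints are drawn uniformly within archetype-legal windows whose bounds
are explicit parameters; positions outside the modeled locus are rejected.
Partner loci are abstract labelled chromosomes because pattern class
depends only on topology, which keeps the generator reference-free.

For the intron-1 archetype the break always lies centromeric of a 3' green
footprint, so the break position alone cannot decide between the balanced
and unbalanced outcome; the `retain_reciprocal` parameter does (`TRUE`
keeps both reciprocal derivatives → `RGF`; `FALSE` retains only the
green-bearing derivative, mirroring the observed GF-type intron-1 case →
`GF`). This is the package's resolution of a genuinely underdetermined
specification point, and it is stated here rather than hidden in a default.

The generator's headline property — simulated class equals analytic truth —
is enforced over 500 seeded scenarios across all archetypes. What the
generator does *not* emulate: optical noise, probabilistic signal dropout,
FFPE artifacts, nuclear geometry, or cell-to-cell count heterogeneity
(every simulated cell of a clone shows the same counts). Passing tests
therefore demonstrate the correctness of the genotype-to-pattern logic, not
robustness to microscopy-level noise.

## Interpretation of unbalanced results

`interpret_result()` renders the guarded interpretation: a normal pattern
is negative *with the caveat* that BAP-only testing carries a false
negative rate of at least 4%; RGF is positive; RF/GF without further data
is **likely positive** with recommended confirmatory testing (IG/MYC
dual-fusion FISH, MYC IHC, WGS or RNA-seq); orthogonally confirmed
juxtaposition upgrades to positive, and a confirmed pure copy-number change
is reported as a CN alteration not classified as a rearrangement.

The published guidance is prose plus a flowchart whose full branch
structure is not recoverable from text. The decision table is therefore
*data-driven* (`inst/extdata/decision_table.json`): the shipped table
encodes the branches that are unambiguous, totality over the input space is
enforced by test, and a laboratory wishing to order the recommended tests
differently or split a branch can edit a copy and pass it in, rather than
patch code. "Confirmed juxtaposition" is an input flag, never an inference:
deciding what counts as confirmation belongs to classification schemes
outside this package's scope.

Survey percentages use half-up integer rounding (`23/54 → 43`), matching
every published figure; base R's banker's rounding would not.

## Numerical and design choices

* Coordinates are 0-based half-open internally, converted at the VCF
  boundary (1-based) and the BED boundary.
* Fusion merging is greedy nearest-pair with ties broken on the leftmost
  red then green spot; determinism is part of the contract and the oracle
  checks it.
* Symbolic `<DEL>`/`<DUP>` VCF records are single-homologue events by
  default, matching the heterozygous context of the described cases.
* Synthetic VCFs carry `DERID`/`ORD`/`HOMREPL` INFO tags so a configuration
  can be rebuilt without graph inference; equivalence after a round trip is
  defined as equal footprint copy numbers plus an identical simulated
  pattern. Foreign VCFs without tags are handled conservatively (one
  additional derivative per junction).
* Whole-chromosome gains are modeled as an extra full-length derivative.

## Problem sizes and limitations

The property suites run 200 random configurations against the per-base
oracle, 1,000 fuzzed nomenclature variants, and 500 synthetic scenarios —
sizes chosen so the whole suite completes in about a minute while each
property is exercised far past the point where new failures appear.

Known limitations: no sequence-level content (no FASTA), no repeat or
mappability modeling, no dual-fusion (D-FISH) simulation, no probabilistic
dropout, and no inference of derivative order from unordered breakends.
Cell-fraction information is carried through but plays no role in
classification beyond selecting the dominant abnormal clone.

## A worked example

```{r example}
# observed result: isolated red signals only
obs <- "nuc ish(5'MYCx2,3'MYCx1)(5'MYC con 3'MYCx1)[100]"
classify_result(obs)

# genome: one intact homologue, one derivative keeping only the 5' side
sc <- generate_scenario(scenario_spec("UNBALANCED_3P_LOSS", seed = 5))
rep <- reconcile(obs, sc$config)
rep

interpret_result(rep$observed_class)$category
```
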