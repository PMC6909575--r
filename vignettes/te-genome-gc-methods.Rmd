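---
title: "Methods: GC content of transposable elements and fish genome composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GC content of transposable elements and fish genome composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tegc)
library(dplyr)
```

## The scientific problem

Fish and amphibian genomes are AT/GC *homogeneous*: their GC content varies
over a narrow range of the classical isochore families, typically spanning
only two neighbouring light bands, whereas birds and mammals span all five
(L1 through H3) and are AT/GC *heterogeneous*. Transposable elements (TEs)
occupy a large and variable share of fish genomes (from a few percent to
more than half), fish genome size correlates positively with TE load, and
genomic GC correlates negatively with genome size. Because TEs carry their
own nucleotide composition into every insertion, the GC content of a
species' mobilome is a candidate contributor to how genomic GC is shaped
over evolutionary time. This package provides the measurement machinery for
that question:

* **GC_G** — GC% of a whole assembly;
* **GC_REP / GC_NONREP** — GC% of the repeat-masked (lowercase,
  soft-masked) versus non-repetitive (uppercase) fraction of an assembly;
* **GC_TE** — GC% of a species' TE consensus library, each family counted
  once (copy-number-unweighted), overall and broken down by TE class
  (Class I retroelements vs Class II DNA transposons) and group (LTR, LINE,
  DIRS, CMC, TcMar, hAT, ...);
* cross-species correlations among genome size, TE load and these GC
  quantities, with explicit lineage filters.

## Composition conventions

Every GC statistic reduces to one tally (`count_bases()`): uppercase and
lowercase A/C/G/T counted separately, `N` (either case) counted apart, and
everything else — IUPAC ambiguity codes including `S` (G/C), gap symbols —
in a residual class. The conventions, fixed once and applied everywhere:

* **Denominator.** GC% = 100·(G+C)/(A+C+G+T) over unambiguous bases only.
  `N`, ambiguity codes and gaps never enter numerator or denominator. This
  makes the partition identity exact (below) and matches the most common
  assembly-GC convention; public databases do not always state theirs, so
  GC values quoted from them may differ in the second digit.
* **Masking dialect.** Lowercase = repeat (soft-masking, as in Ensembl
  "sm" dumps, which include low-complexity regions); uppercase `N` =
  assembly gap. Hard-masked input (N-for-repeat) is not supported; a fully
  unmasked input triggers a warning rather than an error.
* **RNA-alphabet entries.** `U`/`u` count as `T`/`t` of the same case; some
  consensus libraries contain RNA-alphabet records.
* **Precision.** GC is carried at full double precision internally; the
  report writers round GC to one decimal and coefficients to three.

`partition_genome()` satisfies, whenever both fractions are defined,

$$ c_\mathrm{rep}\,\mathrm{GC_{REP}} + c_\mathrm{nonrep}\,\mathrm{GC_{NONREP}}
   = (c_\mathrm{rep}+c_\mathrm{nonrep})\,\mathrm{GC_G} $$

with \(c\) the counted bases of each fraction; the test suite checks this to
1e-9 relative tolerance and checks all tallies against an independent
per-character oracle.

```{r toy}
partition_genome("aattGGCC")
```

## Isochore bands

The classical band limits are approximate and leave one-point gaps
(36 to 37, 40 to 41, 45 to 46, 52 to 53). Classification must be a total,
monotone function, so `isochore_band()` closes the gaps with half-open
intervals — sub-L1 [0,34), L1 [34,37), L2 [37,41), H1 [41,46), H2 [46,53),
H3 [53,100] — and exposes the five boundaries as an argument for users who
prefer a different closure.

## TE taxonomy

Headers follow the `name#Class/Superfamily` dialect of FishTEDB and
Repbase-derived libraries. The class map (`default_te_classes()`) assigns
`LINE/ SINE/ LTR/ DIRS/ Retroposon/ Penelope` to Class I and `DNA/ RC` to
Class II; Helitrons (`RC/Helitron`) are Class II and Penelope elements
Class I by mechanism, both reassignable through the map. Simple repeats,
low-complexity sequence, satellites, structural RNAs and artefacts are
non-TE and excluded from every TE statistic. Composite superfamily names
collapse to their leading token (`CMC-EnSpm` to CMC, `TcMar-Tc1` to TcMar);
the raw string is always retained. Unparseable headers are kept as
`unknown`/`Unknown`: they contribute to overall GC_TE but to neither class
value, a choice made here because discarding them would silently shrink the
consensus pool while assigning them to a class would be a guess.

**Copy-number weighting.** GC_TE is computed from consensus sequences, each
family once. Consensi approximate elements at insertion time, so this
statistic is deliberately independent of where copies sit in the genome and
how often they occur; a mobilome-weighted GC is a distinct quantity and out
of scope here.

**Cross-species aggregation.** Two defensible conventions exist for pooling
group GC over species: summing base counts (each consensus base equal) or
averaging per-species GC values (each species equal). They differ whenever
species contribute unequal library sizes, and published group-level figures
rarely say which was used. `pool_groups_across_species()` therefore always
reports both (`gc_pooled`, `gc_mean_of_species`), with pooled bases as the
headline column.

## Cross-species statistics

`analysis_suite()` runs six fixed analyses (size vs TE%, size vs GC with
and without salmonids, assembly size vs GC, GC_TE vs GC_G, GC_REP vs
GC_NONREP) over pairwise-complete observations — no imputation, so each
analysis has its own n, mirroring how heterogeneous public compilations
behave. Both Pearson and Spearman are computed; Spearman is reported first
because genome size is heavy-tailed across fish. For small untied samples
the Spearman p-value comes from the exact permutation null distribution;
the suite verifies it against full enumeration of all n! permutations. No
phylogenetic correction (PIC/PGLS) and no multiple-testing adjustment are
applied; coefficients are reported raw and documented as such.

Salmonids carry a lineage-specific extra whole-genome duplication and
extremely amplified, GC-rich rRNA arrays; `apply_filters()` implements
their exclusion (and a teleost-only restriction) with a per-species
exclusion log so every reported n is auditable.

## The synthetic study panel

`generate_panel()` produces the reference conditions on which the pipeline
is validated: by default 30 species, assembly sizes uniform on 1–3 Mb.
The megabase scale is a deliberately scaled-down stand-in for real fish
genomes (hundreds of Mb to several Gb): binomial sampling noise on a GC
percentage falls off as \(1/\sqrt{\text{length}}\), so composition
statistics stabilise well below real genome sizes, and 30 × ~2 Mb keeps a
complete simulate-then-analyse round trip under a minute. Planted
structure, chosen to echo the direction and rough magnitude of the trends
reported for real fish panels:

| parameter | default | meaning |
|---|---|---|
| `te_intercept`, `te_slope` | 10, +8 %/Mb | TE% rises with genome size |
| `gc_intercept`, `gc_slope` | 48, −3 %/Mb | genomic GC falls with size |
| `noise_sd` | 1 (GC points) | scatter around both relations |
| `class1_gc_offset` | +6 pp | Class I pooled GC above Class II |
| `group_profile` | DIRS 53.8 … CMC 35.8 | group GC ordering (DIRS richest, CMC poorest, LTR > LINE) |
| `te_gc_coupling` | 0.5 | consensus GC tracks the species' background GC |
| `copy_mutation_rate` | 0.02 /base | substitutions on inserted copies |
| `salmonid_fraction` | 0.2 | species flagged salmonid |
| `salmonid_size_boost_mb`, `salmonid_gc_boost` | +1.5 Mb, +4 pp | off-trend inflation of salmonid-flagged species |

The raw group targets are shifted rigidly per class
(`adjust_group_targets()`) so the family-weighted Class I − Class II
contrast equals `class1_gc_offset` exactly; the per-species coupling shift
is symmetric across classes and cancels from the contrast. Salmonid
inflation is applied *after* the trend values are drawn, so flagged species
sit off-trend (larger and GC-richer), which is what makes their inclusion
measurably attenuate the negative size–GC correlation.

Generation details that matter for interpretation:

* **Background** is i.i.d. per base at the species' planted GC. There is no
  isochore-scale autocorrelation, so the panel validates composition and
  correlation statistics but says nothing about windowed or banding
  analyses.
* **TE copies** are drawn with replacement from the species' own library,
  substituted at `copy_mutation_rate` (each hit base becomes one of the
  other three uniformly — this drifts copy GC toward 50% by
  \(\Delta p = \tfrac{2r}{3}(1-2p)\), about +0.3 GC points at the default
  rate, which the realized truth absorbs), lowercased and spliced in at
  uniform positions; the last copy is truncated so the repetitive fraction
  matches the plant exactly. No nesting or fragmentation model: partition
  arithmetic is position-independent.
* **Truth tables** record both planted parameters and realized
  post-sampling values, together with binomial standard deviations at the
  realized sequence lengths; recovery tests use plant ± 3 SD, never an
  ad-hoc tolerance.
* **Determinism.** One scalar seed drives a fixed per-species substream
  (`species_seed()` arithmetic inside 32-bit range), so identical seeds
  give byte-identical panels, and panels are extensible without disturbing
  earlier species. Gzip output carries no timestamp, so whole output trees
  hash identically across runs.

```{r panel, eval = FALSE}
panel <- generate_panel(panel_spec(seed = 1))
suite <- analysis_suite(panel$species)
tidy(suite)
```

What passing on this panel does *not* show: robustness to real-data
features it omits — isochore structure, nested/fragmented and diverged
copies, library incompleteness, assembly artefacts, phylogenetic
non-independence of species.

## Numerical and degenerate-input choices

* A GC value with a zero denominator is `NA` with an explicit warning where
  it signals something (fully unmasked assembly, library without countable
  TE sequence) — undefined is a value, not an error.
* Fewer than 3 complete pairs is an error for a correlation; zero variance
  yields an `NA` coefficient with a warning.
* Spearman ties are handled by mid-ranks (and the exact permutation null is
  then unavailable; the asymptotic p-value is used).
* C-value (pg) to Mb conversion uses 978 Mb/pg as a configurable default;
  analyses natively accept either size scale, so the constant only serves
  cross-checks.
* Report TSVs use `.` for missing, LF endings and UTF-8 throughout;
  rounding happens only at the report layer.

## Validation problem sizes

The shipped test suite validates composition against a per-character oracle
on 1,000 random full-IUPAC sequences (lengths 0–2,000), correlation against
closed-form and rank oracles on 200 random panels (n = 5–12) with exhaustive
n! permutation enumeration for n ≤ 7, and parameter recovery plus the four
qualitative correlation claims on the default 30-species panel at a fixed
seed; determinism is checked by hashing two complete `full_run()` output
trees on a reduced 6-species panel. These sizes were chosen so the whole
suite validates every claim the package makes while remaining quick enough
to run on every change.

## Known limitations

* Consensus-level GC only; no mobilome (copy-number-weighted) GC.
* No windowed GC profiles, banding emulation or chromosome-level isochore
  mapping; no GC-biased gene conversion or recombination modelling.
* No masking is ever produced — soft-masked input is consumed as given
  (outside the simulator), and annotation quality is inherited from it.
* Species are treated as independent observations; with strong phylogenetic
  signal the reported p-values overstate certainty.
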