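---
title: "Methods: parthenogenesis inference from microsatellite panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parthenogenesis inference from microsatellite panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parthenotrace)
```

## The inference problem

Captive female bamboo sharks lay egg cases in pairs roughly every 6–7 days
through a 2–3 month season, fertilising them from sperm stored in the
oviducal gland — for up to ~4 months after a single insemination. A small
fraction of eggs instead develops by facultative parthenogenesis. Given a
codominant microsatellite panel (allele calls as integer fragment lengths)
for dams, candidate sires, and offspring, plus an egg-by-egg oviposition
log, the package answers three questions:

* Which offspring are parthenotes, which are sexually sired, and by whom?
* How many distinct females, at minimum, must have produced an observed
  set of parthenotes whose dams were not sampled?
* What are the per-female and cohort reproductive rates, with
  parthenotes separated from insemination success?

## Classification model

The genetic signature modelled is **terminal-fusion automixis**: the ovum
fuses with its meiotic sister product, so the offspring carries two copies
of a single maternal allele at every locus — genome-wide homozygosity for
maternal alleles, with no paternal contribution. The per-locus evidence
(`locus_parthenote_consistent()`) is therefore:

* `hom_maternal` — offspring homozygous, allele present in the dam's known
  alleles (a dam slot whose allele is unknown is a *wildcard* and matches
  anything; this is essential when the dam is itself reconstructed);
* `non_maternal_allele` — the offspring demonstrably carries an allele the
  dam lacks;
* `missing` — failed locus; `het` — anything else.

Verdicts: all scored loci `hom_maternal` gives `PARTHENOTE` when at most
`max_missing` loci failed and `CONSISTENT_UNCONFIRMED` otherwise; a
genotype explainable by dam + (optional) sire with at most `tolerance`
exception loci is `SEXUAL`; more unexplained loci give `MISMATCH`.

**Why `max_missing = 1` by default.** A strict rule ("confirmed only with
all loci scored") conflicts with how such data are actually read: a single
failed PCR in an otherwise fully homozygous-maternal 9-locus profile leaves
a false-confirmation probability below $10^{-4}$ for any realistic allele
frequencies, and the reference dataset's confirmed parthenote set includes
exactly such a profile (P9, one failed locus) while withholding
confirmation from P8, which has four failed loci and only five scored. One
tolerated dropout reproduces both calls; users wanting the strict rule set
`max_missing = 0`.

Two deliberate simplifications: central-fusion automixis (which retains
heterozygosity) is *not* modelled — a heterozygous-but-all-maternal profile
is classified `SEXUAL`, since the homozygosity rule cannot see central
fusion and pretending otherwise would overstate the classifier's power; and
genotyping error beyond the integer `tolerance` / `max_missing` knobs
(no likelihood model, no allele-frequency weighting) is out of scope.

Paternity (`assign_paternity()`) is by exclusion counting only: a candidate
sire is excluded at a locus when the offspring's non-maternal allele(s)
cannot be drawn from his known alleles; candidates are ranked by exclusion
count with lexicographic tie-break. Because a parthenote's alleles are all
maternal, a parthenote never excludes any sire — which is why the
`PARTHENOTE` verdict takes precedence in reporting.

## Minimum-dam estimation

Each homozygous parthenote pins at most one maternal allele per locus, so a
set of parthenotes is compatible with a single (diploid) dam **iff at every
locus the union of their known alleles has size ≤ 2**. A direct consequence
worth stating: *no two* fully homozygous parthenotes can ever be
incompatible — each contributes one allele per locus, so pairwise unions
never exceed two. Incompatibility first appears in triples. (Pairwise
bounds are therefore trivial on such inputs; they only bite when
consistent-unconfirmed heterozygous profiles are included.)

`min_mothers()` finds the minimum number of compatible blocks by exact
search: iterative deepening on the number of blocks $k$ starting from a
greedy pairwise-incompatibility lower bound, with depth-first placement of
each parthenote into existing blocks (restricted-growth order) or a new
block while fewer than $k$ exist, pruning on the running per-locus unions.
The first complete assignment found is the smallest restricted-growth
assignment **in input order**, which makes results deterministic and, for
the reference data read in their natural order, reproduces the published
grouping. Exact search is guaranteed up to `exact_limit = 20` individuals;
beyond that a greedy first-fit merge runs with a warning and reports an
upper bound. (Study-scale inputs are tiny; correctness comes first.)

Missing offspring loci contribute no alleles (wildcards). Reconstruction
(`reconstruct_dam()`) reports the per-locus allele union, flagging a
wildcard slot when fewer than two alleles are pinned; a reconstructed dam
prints as e.g. `289/-`. The reference dataset's published reconstruction of
one dam excludes its unconfirmed member (P8), whose fifth scored locus
would pin a second allele; the package reconstructs both ways (the
unconfirmed member changes one locus of one dam and never the minimum
of four).

## Reproductive metrics: conventions

* **Wind cases** (yolkless egg cases) are excluded from every denominator.
  In the reference outcome table the printed "egg cases laid" and the
  denominators implied by the printed percentages disagree for several
  females; the fixture records both (`n_laid`, `n_eggs`) and all
  percentages validate against `n_eggs`.
* **Fertility** = `100 · n_fertile / n_eggs`, **hatchability** =
  `100 · n_hatched / n_eggs`, both **AI-adjusted**: parthenote-flagged eggs
  are excluded from the numerators by default. One reference row (female
  307) prints a fertility that *includes* its two parthenotes; the
  `include_parthenotes = TRUE` raw mode reproduces it, and the discrepancy
  is documented rather than silently matched.
* **Fertility duration** = last − first AI-fertile lay day: 121 − 14 = 107
  days for the longest-storing female. A female with exactly one fertile
  egg has duration 0 (the reference table prints 1, an inclusive count);
  with no fertile eggs the duration is undefined (`NA`).
* **Rounding**: percentages are rounded once, at reporting, to one decimal,
  ties away from zero (`round_half_up()`); pooled cohort rates are computed
  from summed counts, never by averaging percentages.
* **Incidence**: observed = confirmed (+ unconfirmed, by default — the
  conservative-inclusion convention used for P8) over total non-wind eggs;
  the maximum variant adds all ungenotyped developed eggs to the numerator;
  a third rate uses developed eggs as denominator.

## Synthetic-data generator: the stated world

Defaults encode the study conditions rather than tunable knobs:

| parameter | default | why |
|---|---|---|
| panel | 9 loci × 6 equifrequent alleles | study panel size; false-positive parthenote call $(1/6)^9 < 10^{-6}$ per sexual offspring. No published allele frequencies exist; synthetic and labelled as such. |
| `pair_interval_days` | 6–7 | natural egg-pair cadence |
| `season_length_days` | 105 | the habitat monitoring window; individual females in the recovery experiments draw personal 60–90-day cycles (the "2–3 month" laying cycle), giving ≈1000 non-wind eggs per 48-female season |
| `wind_rate` | 0.1 | ≈ the wind fraction implied by the outcome table (39/403) |
| `initial_fertility` | 0.6 | peak per-egg fertility of successful trials |
| `fertilization_decay` | 0.99/day | geometric stand-in for sperm-storage decay; the study shows a peak-then-decline with fertile eggs to day 121 but no functional form — geometric is the simplest monotone choice and is confined to this module |
| `parthenote_rate` | 0.011 | the observed 1.1% habitat incidence |
| `hatch_given_fertile` | 0.85 | 97 hatchlings / 114 fertile eggs |

Automixis is simulated as terminal fusion only (pick one maternal allele,
duplicate). Genotyping noise: each locus fails wholesale with
`locus_failure_rate`, otherwise each allele drops to a half-missing slot
with `allele_dropout_rate`. All generators take an explicit `seed` and are
bitwise-reproducible; seeded calls restore the caller's RNG stream.

**What a green test does and does not establish.** The generator emulates
Hardy–Weinberg genotypes, Mendelian segregation, genome-wide automictic
homozygosity, independent per-locus dropout, and memoryless fertilisation
decay. Real data violate several of these: loci may be linked or
sex-linked (all are treated as autosomal), allele frequencies are neither
equifrequent nor known, dropout is allele-size-biased, females suspend
laying unpredictably, and fertility peaks ~4 weeks post-insemination
before declining rather than decaying from day 0. Green synthetic tests
therefore establish correctness of the *inference machinery under its own
assumptions*, not field performance of the panel.

## Numerical and degenerate-input policy

* Allele pairs are normalised ascending with missing slots last; genotype
  comparisons never depend on input order. Accepted missing tokens on
  input: `-`, typographic minus/en-dash, `.`, empty; always written `-`.
* `min_mothers(list())` returns 0 dams; a singleton group is always
  compatible; `reconstruct_dam()` on an empty or incompatible group errors.
* Classification is total: all-missing offspring profiles fall to
  `CONSISTENT_UNCONFIRMED` (no evidence either way).
* Zero-egg denominators signal errors (`incidence()`) or return `NA`
  (per-female percentages for females whose every egg was wind).
* Genepop export codes alleles 001…999 by ascending fragment length per
  locus (000 = missing) and refuses panels exceeding the 3-digit space;
  the allele→code map is emitted alongside for lossless round-trips.

## Known limitations

* Likelihood-based parentage (LOD scores, CERVUS/COLONY-style), sibship
  reconstruction, and probabilistic dam assignment are non-goals.
* The minimum-dam count is a lower bound by construction; equally minimal
  partitions exist and the tie-break (input order) picks one
  deterministically rather than enumerating all.
* Per-offspring paternity of the study's sexually-sired offspring and the
  inseminated-cohort parthenogenesis rate (0.71%) are not reproducible
  from published data (genotypes/denominators unprinted) and are exercised
  on synthetic data only.
* The morphometrics fixture is synthetic per-cell data constructed to match
  the published component means exactly; its higher moments are arbitrary.
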