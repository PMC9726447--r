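---
title: "Painting hybrid subgenomes from uniquely shared alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Painting hybrid subgenomes from uniquely shared alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridpaint)
```

## The problem

An allopolyploid hybrid such as lager yeast carries a subgenome inherited
from a wild parent species. If several diverged populations of that parent
exist, the subgenome is usually not a clean copy of any one of them: it is a
mosaic, because the founding parent(s) carried standing variation and the
populations have continued to diverge since. `hybridpaint` decomposes such a
subgenome into population-labelled blocks using only diagnostic alleles —
alleles carried by the hybrid query and by exactly one candidate source
population. It is a deterministic, auditable alternative to probabilistic
local-ancestry models, appropriate when the candidate populations are few,
well separated, and represented by sequenced strains in the same joint
genotyping run.

## Model and assumptions

The classification unit is one biallelic SNP from a multi-sample VCF. A
*population scheme* names the query, and per population an *assignment* set
(strains whose alleles can vouch for the population) and an *exclusion* set
(strains in which a diagnostic allele must be absent). Keeping the two sets
separate mirrors how such panels are built in practice: one well-assembled
strain per population anchors assignment, while every available strain of
the *other* populations serves as an exclusion filter.

At a site, let $Q$ be the allele set of the query. Population $P_i$
qualifies iff

$$\exists a \in Q:\; a \in \mathrm{assign}(P_i)\ \wedge\ \forall j \ne i,\;
a \notin \mathrm{exclude}(P_j).$$

Exactly one qualifying population assigns the site; two or more (possible
only via *different* alleles of a heterozygous query) yield
`shared_by_multiple`; none yields `shared_by_none`. A missing query call is
`query_missing`; a population whose representatives are all missing makes
the site unusable (`reps_missing`) because its exclusion test cannot be
evaluated. Precedence is `query_missing` > `reps_missing` > the shared
counts.

Two modelling choices deserve emphasis:

* **Allele symmetry.** Evidence is "shares an allele", not "shares the ALT
  call". When variants are called against an assembly belonging to one of
  the candidate populations, that population's diagnostic alleles largely
  *are* the REF alleles, so an ALT-only reading would blind the method to
  one population. The literal ALT-presence reading remains available as
  `alt_presence_only = TRUE` in `classify_sites()`.
* **Uniqueness is absolute.** An allele present in two populations'
  exclusion sets vouches for neither. Drift-shared and ancestral alleles
  therefore fall out of the analysis instead of being force-assigned.

## From sites to blocks

Isolated diagnostic sites are noisy (genotyping error, gene conversion), so
blocks require at least `min_support = 2` consecutive sites assigned to the
same population. "Consecutive" is evaluated among *assigned* sites:
unassigned sites are transparent and do not interrupt a run, but a site
assigned to a different population — even a singleton — breaks it. The
rendering convention that motivated this (isolated discordant ticks drawn
offset inside long blocks) treats such sites as genuine interruptions;
`unassigned_breaks_runs = TRUE` flips the transparency choice.

Raw blocks span their outermost supporting sites. Expansion draws the border
between adjacent blocks at the integer midpoint between the facing
outermost sites, $\lfloor (l + f)/2 \rfloor$ in 1-based coordinates, with
the boundary base going to the left block; the first and last blocks extend
to the chromosome ends. This is exactly the per-base nearest-outermost-site
rule with left-wins ties, and a property test asserts equality against that
brute force. Internally all blocks are 0-based half-open (BED convention);
VCF positions stay 1-based at the parsing boundary — the conversion of a raw
block's outermost sites $[f..l]$ is $[f-1, l)$.

A chromosome with no qualifying blocks becomes one explicit `UNASSIGNED`
block. Additionally, a run of at least `desert_min_run = 10` consecutive
`query_missing` sites is treated as a no-call desert: it becomes an
`UNASSIGNED` pseudo-block that participates in midpoint expansion (capping
the expansion of its neighbours) and splits any population run it
interrupts. Without this rule, two blocks flanking a large unsequenced or
filtered-out region would silently annex it; with it, assigned totals can be
honestly smaller than the genome. The threshold of 10 sites is a
compromise — at the default simulated site density (one site per 200 bp) it
corresponds to roughly 2 kb of consecutive no-calls — and is configurable.

Percentages are reported over *assigned* bp, not genome length: the
quantity of interest is the relative contribution of each source population
to the interpretable fraction of the subgenome. `ancestry_summary()` checks
`assigned + unassigned = genome` and `summarize_blocks()` refuses
non-tiling input.

## Filter cascade

The painter consumes analysis-ready SNPs produced by `filter_variants()`,
in a pinned order: genotype masking, then SNP-cluster removal, then
multiallelic, missingness and SNP-only exclusion.

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 15 | genotypes with DP < 15 are masked (strict) |
| `min_gq` | 40 | genotypes with GQ < 40 are masked (strict) |
| `cluster_size` / `cluster_window` | 5 / 20 bp | ≥ 5 SNPs whose inclusive span ≤ 20 bp are all removed |
| `max_missing_fraction` | 0.30 | sites with missing fraction > 0.30 removed (boundary survives) |
| `biallelic_only`, `snps_only` | TRUE | multiallelic sites and indels removed |

Masking precedes missingness exclusion because a depth- or quality-failed
genotype *is* a missing observation: a site riddled with low-quality calls
should die by the missingness rule, not survive with pseudo-confident
genotypes. Genotypes whose DP or GQ annotation is absent are left as called,
matching the behaviour of annotation-driven hard filtering, where an absent
annotation cannot fail a threshold. The cluster rule uses the inclusive span
semantics of cluster-window filtering (`pos_last − pos_first + 1 ≤ window`)
and removes every SNP of every qualifying window. The cascade is idempotent
and degenerates to the identity when all thresholds are disabled; both are
property-tested, as is the report's conservation identity (input − site
removals = output).

## RRHS

`generate_alignments()` emits pseudo-haplotype SNP alignments in which each
heterozygous genotype is independently resolved to one allele with
probability 1/2 per sample per site — no within-chromosome phasing, matching
the site-wise sampling of the published RRHS procedure. Missing genotypes
emit `N`, the standard ambiguity code accepted by downstream tree tools.
Each strain contributes one resolved row per iteration. Iteration $i$ uses
an RNG substream seeded from `(seed, i)`, so a run is byte-reproducible and
any single alignment can be regenerated in isolation
(`subset = i`). Tree search itself (e.g. RAxML under GTRGAMMA) is
deliberately out of scope: the alignments are the interface to it.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the painter relies
on, not yeast biology: $k$ populations (default 3, two strains each, labels
Tibet / Ireland / NorthCarolina) genotyped at SNP sites placed by a Poisson
process (default one site per 200 bp on a single 500-kb chromosome — large
enough for ~10 tracts with hundreds of diagnostic sites each, small enough
to simulate in seconds). A fraction of sites (default 0.8) carries an ALT
allele private to one population; the rest carry an ALT shared by two
populations. Within-strain heterozygosity (default 0.01, reflecting the
near-homozygous diploids such panels contain) adds realistic low-level
noise. The hybrid query is a mosaic: each truth tract copies the genotypes
of one randomly chosen strain of its source population. Missingness and
genotype error (both default 0; switched on explicitly where a test needs
them) apply to all samples, since joint-call noise is not specific to the
query. DP and GQ are constants above the filter thresholds unless
`degrade = TRUE` injects sub-threshold values to exercise the cascade.

What the generator does **not** emulate — coalescent genealogies, linkage
within populations, recombination-rate variation, indel/multiallelic
realism, reference bias — bounds what green tests mean: they demonstrate
correct rule arithmetic and robust parameter recovery under idealized site
patterns, not performance on real panels, where diagnostic-site density and
population separation must be assessed per dataset.

## Numerical and degenerate-input choices

* Midpoints use integer floor; ties go to the left block (deterministic and
  equal to the per-base oracle).
* Sorting follows the genome index, never lexicographic chromosome names.
* Diploid parsing is fixed: haploid GT promotes to homozygous, ploidy > 2 is
  an error, any `.` allele makes the whole call missing.
* Empty outputs are legal but explicit: an empty filter result is flagged in
  the report; a chromosome without blocks paints as one `UNASSIGNED` block;
  an empty alignment is an error.
* `run_pipeline()` writes a manifest of MD5 checksums; identical config and
  seed reproduce identical manifests.

## Validation summary

The test suite asserts, among others: exact reproduction of the published
per-population percentage arithmetic for the two lager lineages (37.69 /
56.09 / 6.21 and 42.28 / 51.93 / 5.78, averaging to 40 / 54 / 6); equality
of `expand_blocks()` with the per-base brute force on 1000+ random
chromosomes; every filter boundary (DP 14/15, GQ 39/40, 5-in-20 clusters,
30/40% missingness); RRHS determinism and the binomial band around 1/2 at
heterozygous sites; and end-to-end recovery of 10-tract mosaic proportions
within 2 percentage points noise-free and 5 points under 1% genotype error
with 5% missingness across 10 seeds. `scripts/acceptance.R` recomputes these
quantities from scratch against the installed package.

## Known limitations

* Two sites are enough for a block; a pair of tightly linked convergent
  sites can seed a short spurious block. Raising `min_support` trades
  sensitivity for specificity (assigned bp is monotonically non-increasing
  in it, property-tested).
* The method has no uncertainty model: block borders are point estimates
  quantized to inter-site midpoints, so border error is of the order of one
  inter-site gap per junction.
* Populations must be represented in the joint call; the scheme cannot
  express an unsampled ghost population, whose material will surface as
  `shared_by_none` sites and unassigned regions.
* With more than a few candidate populations the uniqueness requirement
  becomes conservative: as exclusion sets grow, fewer alleles stay
  diagnostic.
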