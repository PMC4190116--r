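---
title: "Identifying mixed pollen samples by two-marker DNA barcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying mixed pollen samples by two-marker DNA barcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pollenID)
```

## The problem

A pollen pellet collected by honeybees is a mixture of pollen from many
plant species. DNA barcoding identifies its components by amplifying two
short plastid regions — the coding gene *rbcL* and the non-coding
*trnH-psbA* intergenic spacer — from the pooled DNA, cloning the mixed PCR
product, and sequencing on the order of 100 individual clones per sample.
Each cloned sequence is then compared against a curated reference database
of the local flora, and the sample's plant composition is read off the
matches. *rbcL* amplifies almost universally but often cannot separate
congeneric species; *trnH-psbA* is more variable and resolves most species,
which is why the two markers are used together and reconciled.

pollenID implements the full computational side of this design: the
reference-database model, clone dereplication into MOTUs (molecular
operational taxonomic units), percent-identity matching with a 99%
threshold, two-marker reconciliation, community summaries, and
species-accumulation curves — plus a simulator that generates reference
databases and clone libraries with the statistical structure the analysis
assumes, so everything is testable without any sequence data.

## Percent identity and its semantics

The matching statistic is the percent identity of a semi-global
(free-end-gap) Needleman–Wunsch alignment under match +1, mismatch −1,
gap −2 per column (gap opening and extension are equal, so the gap penalty
is linear). Identity is BLAST-like: matching columns divided by all
alignment columns except end-gap columns. Internal gap columns count
against identity; free end gaps mean an exact-but-shorter clone still
scores 100%, which is the behaviour the threshold rule needs for amplicons
with differently trimmed ends.

```{r identity}
aln <- global_align("ACGTACGT", "ACGAACGT")
aln$matches
percent_identity("ACGTACGT", "ACGAACGT")
```

Three numerical choices matter:

* **Determinism.** Traceback ties are broken in a fixed order (diagonal
  over up over left; among equal-scoring end cells the larger row, then
  column, index wins), and each pair is aligned in lexicographic order with
  the gapped strings swapped back. The second rule exists because
  co-optimal alignments would otherwise make the reported identity depend
  on argument order; with it, identity is exactly symmetric.
* **Coverage and the band.** For unrelated sequences the score-optimal
  free-end alignment can be a short, nearly perfect overlap — the local
  analog of a tiny 100%-identity BLAST HSP. The pipeline therefore runs its
  high-volume comparisons in a diagonal band (half-width 25 columns plus
  the length difference; `band` in `pipeline_config()`). Within the band
  the result is exactly the full optimum whenever the optimal path stays
  near the diagonal — always true for the substitution-dominated variation
  this analysis deals in — while unrelated pairs, denied the trivial
  corner overlaps, report the low identities they deserve. The public
  `global_align()`/`percent_identity()` default to the full, unbanded DP.
* **IUPAC codes.** A column matches iff the two symbols' base sets
  intersect (`N` matches everything); a gap never matches.

The aligner is validated against an independent recursive-enumeration
oracle on short sequences and against closed-form Hamming expectations on
substitution-derived pairs (see `tests/testthat/`).

## MOTUs: dereplication before matching

Clone libraries contain reads with one or two substitutions per clone.
Reads are grouped by single-linkage clustering: two reads link iff their
**end-to-end (global)** alignment has at most `motu_max_mismatches = 2`
mismatch columns and no gap run longer than that. Global rather than
free-end alignment is used for linkage deliberately: under free end gaps,
two unrelated reads can "agree" on a short perfect overlap and would
single-link entire libraries. The radius of 2 matches the observed clone
error scale; with radius 0 the operation degenerates to exact
dereplication. Single linkage can chain beyond the radius — that is
accepted and documented behaviour, not a bug.

Each MOTU's representative is its most frequent exact sequence (ties to
the lexicographically smallest), and the consensus is the column-wise
majority with ties resolved toward the representative, so neither depends
on input order. When clone errors strike near-random positions, as in the
simulator, reads of one template are often 3–4 substitutions apart and a
species fragments into several MOTUs; this inflates MOTU counts relative
to libraries whose errors recur at hotspot positions, but leaves taxon
calls untouched, because every fragment still matches its species at
≥ 99%.

## The 99% rule and two-marker reconciliation

For each MOTU consensus, one hit per reference species is computed and
ranked (identity descending, species ascending). Hits at or above
`threshold_pct = 99` qualify — the comparison uses the unrounded identity;
the one-decimal rendering in reports is display only. The call logic is:

* no qualifying hit → **unidentifiable** (and flagged for an external
  database lookup);
* one qualifying species → **species** call;
* several qualifying congeners → **genus** call ("*Acer* sp.");
* qualifying hits in several genera → **ambiguous**, with the full hit
  list retained.

A species call requires uniqueness among *all* qualifying hits, not just
the top hit: a 100% match demoted by a congener at 99.6% is exactly how
*rbcL*'s weak congeneric resolution manifests, and the genus-level call is
the honest answer there.

Reconciliation of the two markers is by specificity first (species beats
genus beats ambiguous beats unidentifiable); at equal specificity
*trnH-psbA* wins (configurable), encoding its higher species-level
resolution. Two species-level calls that disagree are flagged as a
conflict and reported, never silently merged. At the community level the
same precedence is applied genus-wise within each (site, sampling) cell: a
genus-level call is absorbed by a species-level call of the same genus in
that cell, which is what turns "*Prunella* sp. (rbcL) + *Prunella
grandiflora* (trnH-psbA)" into one species row.

## Community summaries

`summarize_reports()` pools the per-marker reports into a long composition
table and a presence/absence matrix (taxa × site-by-sampling cells;
presence iff either marker detected the taxon; unidentifiable and
ambiguous MOTUs excluded). Richness per site, shared taxa between sites,
persistence classes (in how many of the three samplings a taxon appears),
status counts and genus counts all derive from that matrix. The package
ships a transcribed reference community table (52 taxa × 3 sites × 3
samplings, with status, pollination mode and flowering period) as a pinned
fixture; `community_summary(pollen_survey_fixture())` reproduces its statistics
exactly, and the test suite asserts them.

## Accumulation curves

Whether ~300 clones per site suffice is assessed with individual-based
accumulation curves, clones as individuals, pooling a site's three
sampling dates (pooling removes phenology effects from the depth
question). Two estimators are provided: randomized resampling
(`accumulation_permutation()`, default 1,000 iterations, seeded) and the
closed-form hypergeometric expectation
E[S(n)] = Σᵢ (1 − C(N−Nᵢ, n)/C(N, n)) (`accumulation_analytic()`), with
binomial coefficients in log space so N = 300 is nowhere near overflow.
The analytic form is the oracle for the permutation estimator in the
tests; vegan's `rarefy()` cross-checks the analytic form. Unidentifiable
MOTUs are real sequences of unseen taxa, so by default each contributes a
distinct pseudo-taxon; `include_unidentified = FALSE` drops them, since
it is genuinely unclear whether such clusters should count as taxa and
the choice visibly moves the curve's tail when contaminants are present.

## The simulator and what it does (not) emulate

`generate_reference_set()` draws, per genus and marker, an ancestor
sequence uniformly over {A, C, G, T}, then derives each species from its
genus ancestor with a per-species divergence drawn from
`congener_divergence` (default 0.2–1% per site). Congeners therefore sit
in the ~98–99.6% identity band — spanning both sides of the threshold, so
genus-level demotion and clean species calls both occur — while distinct
genera are unrelated sequences far below it. Defaults mirror the study
conditions: 693 species, marker lengths 627 and 634 nt, 100 clones per
mixture, 1–2 substitutions per clone (exact counts, positions drawn
without replacement), mixtures of 12–18 species per sample whose two
markers share one composition (both are amplified from the same pooled
DNA). Remaining free choices, documented here as the package's own:
250 genera (a realistic flora-wide congener density), status probabilities
0.80/0.15/0.05 for common/rare/alien, Dirichlet(1) relative abundances
within a mixture, and site pools of ~18–24 species (matching observed
site-level richness of ~20–30). Contaminant clones are uniform random
sequences rejected until below 99% identity to every reference — by
construction of the acceptance surface itself, so "contaminants are always
unidentifiable" is a property the pipeline must and does reproduce.

The simulator does **not** emulate: chimeras, PCR abundance bias, indel
sequencing errors (the error model is substitutions only), error hotspots
(real clone errors recur at the same positions; uniform positions fragment
MOTUs more, as noted above), or any relationship between clone counts and
true pollen abundance beyond multinomial sampling. Passing tests
therefore demonstrate correctness of the analysis under this generative
model, not robustness to every artefact of real clone libraries.

## Problem sizes and determinism

The test suite and the acceptance script run the full-scale configuration:
a 693-species, two-marker database; 3 sites × 3 dates × 2 markers = 18
libraries of 100 clones; 5% contaminants for the recovery checks and a
contaminant-free site for the asymptote check; 1,000 permutation
iterations for the rarefaction comparison. Oracle comparisons use 200
random pairs (length ≤ 12) and 50 random read sets (≤ 30 reads). Every
random step takes an explicit seed, and identical configuration plus seeds
give byte-identical outputs end to end.

## Known limitations

* The identity of a free-end alignment is reported on the score-optimal
  alignment; between unrelated sequences that value is coverage-dependent
  (see the band discussion above).
* Single-linkage chaining can merge congeners sharing intermediate reads;
  at the study's divergences this never crosses genera.
* Genus-level absorption assumes one species per genus per cell resolves
  the genus; with two resolved congeners in one cell, clones of the
  genus-level MOTU remain under "Genus sp.".
* The pseudogene screen is a reading-frame and internal-stop check in a
  stated frame; it is a flag, not a classifier, and is undefined for the
  non-coding spacer.
```
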