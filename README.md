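# pollenID

DNA-barcoding identification of mixed pollen samples.

Honeybee pollen pellets are mixtures of pollen from many plants. Their
composition can be read molecularly: amplify two plastid barcode regions —
the coding gene *rbcL* and the non-coding *trnH-psbA* spacer — from the
pooled DNA, clone the mixed PCR product, sequence ~100 clones per sample,
and match every cloned sequence against a reference database of the local
flora. pollenID implements that analysis end to end, for beekeeping
product traceability, melissopalynology, and plant–pollinator studies:

* **Reference database** model and FASTA + TSV I/O for a two-marker local
  flora (species, genus, status common/rare/alien, accession), with an
  *rbcL* pseudogene screen (reading-frame and internal-stop flags).
* **Alignment and identity**: semi-global Needleman–Wunsch (free end gaps,
  match +1 / mismatch −1 / gap −2, IUPAC-aware, deterministic traceback)
  with BLAST-like percent identity
  `identity = matches / (columns − end-gap columns)`.
* **MOTU dereplication**: single-linkage clustering of clone reads (radius
  ≤ 2 mismatch columns, end-to-end alignment) with majority-rule consensus.
* **Taxonomic assignment**: hits at identity ≥ 99% qualify; a unique
  qualifying species gives a species call, several congeners a genus call
  ("*Acer* sp."), several genera an ambiguous call, none — "unidentifiable"
  (flagged for external lookup). The two markers are reconciled by
  specificity, ties to *trnH-psbA*.
* **Community summaries**: site-by-sampling presence/absence matrix,
  richness, shared taxa, persistence classes, status and genus counts;
  a transcribed 52-taxon reference community table ships as a fixture.
* **Accumulation curves**: individual-based rarefaction by randomized
  resampling (1,000 iterations) and the hypergeometric closed form
  E[S(n)] = Σᵢ (1 − C(N−Nᵢ, n)/C(N, n)).
* **Simulator**: reference sets with nearly identical congeners
  (99–99.6% band) and unrelated genera, clone libraries with exact 1–2
  substitutions per clone, off-database contaminants, and full multi-site
  study scenarios — all seeded and deterministic.

## Worked example

```r
library(pollenID)

# simulate a small two-marker flora and one pollen mixture
cfg <- simulation_config(n_species = 40, n_genera = 15,
                         seq_len_rbcl = 627, seq_len_trnh = 634, seed = 7)
db <- generate_reference_set(cfg)

mix <- mixture_spec(site = "Ortanella", date = "2011-05-20",
                    composition = c("Genus002 species002" = 0.35,
                                    "Genus002 species021" = 0.25,
                                    "Genus003 species003" = 0.25,
                                    "Genus005 species005" = 0.15),
                    n_clones = 60, subs_per_clone = c(1, 2))
lib <- generate_clone_library(db, mix, marker = "rbcL", seed = 11)

report <- assign_clone_library(lib, db, pipeline_config())
report[, c("motu_id", "n_clones", "call_level", "call_name",
           "best_identity_pct")][1:5, ]
#>   motu_id n_clones call_level           call_name best_identity_pct
#> 1 MOTU001       12    species Genus002 species002         100.00000
#> 2 MOTU002        7    species Genus003 species003         100.00000
#> 3 MOTU003        4      genus        Genus002 sp.         100.00000
#> 4 MOTU004        3    species Genus005 species005         100.00000
#> 5 MOTU005        1    species Genus002 species002          99.68102
```

Each row is one MOTU (a cluster of near-identical clones). `MOTU001` is a
clean species call at 100% identity; `MOTU003` is demoted to the genus
because a second congener also qualifies at ≥ 99%; `MOTU005` is a single
clone carrying two substitutions (identity 625/627 = 99.7%), still safely
above the threshold. Clone counts always sum to the library size.

The packaged reference community table and its summary statistics:

```r
s <- community_summary(pollen_survey_fixture())
s$total_taxa
#> [1] 52
s$richness
#>     Cornisella      Ortanella Alpe Moncodeno
#>             21             31             23
```

52 taxa across three sites; 21, 31 and 23 taxa detected per site over the
three sampling dates.

A thin command-line wrapper over the same functions is installed at
`inst/cli/pollenid.R` with subcommands `simulate`, `assign`, `summarize`
and `rarefy`, e.g.
`Rscript <pkg>/cli/pollenid.R summarize --fixture survey`.

## Vignette

`vignettes/pollen-identification.Rmd` documents the model and its
assumptions: the identity definition and its banding, the MOTU linkage
rule, the threshold and reconciliation semantics, what the simulator does
and does not emulate, and known limitations.
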