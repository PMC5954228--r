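# fiscog

Comparative-genomics pipeline for distilling a **fungus-insect symbiotic
core gene (FISCoG) toolbox**: the gene families shared by
insect-associated fungi — gut commensals (e.g. Harpellales) and
entomopathogens alike — but absent from free-living relatives. The
package is aimed at comparative genomicists who want the whole screen
(similarity search → ortholog clustering → core-set algebra →
negative-control subtraction) as tested, scriptable R functions, together
with the supporting computations such studies lean on: supermatrix
preparation, allele-frequency-spectrum ploidy inference, genome-match
identity aggregation and assembly statistics. A synthetic-data module
generates proteomes and read pileups with known ground truth, so every
stage is verifiable without downloading real assemblies.

## The method

Given per-taxon protein sets grouped into guilds (commensals, two
pathogen groups, free-living controls):

1. **Similarity**: all-vs-all Smith-Waterman (affine gaps, BLOSUM62) with
   Karlin-Altschul E-values, E = K·m·n·e^(−λS); hits kept at E ≤ 1e-5 in
   the 12-column BLAST tabular layout (import/export supported, so
   externally computed tables drop in).
2. **Orthology**: reciprocal best hits (ranked by E-value, then bit
   score) assembled into families, and independently Markov clustering
   (MCL, inflation 2) of the graph weighted by −log10(E); per-taxon
   representatives are the members with maximal total connectivity.
3. **Core sets**: a family is core to a guild when present in at least
   N−k of its N taxa (defaults 3-of-9, 2-of-6, 0-of-3 tolerances).
4. **The screen**: candidate toolbox = commensal core families linked by
   representative hits into *both* pathogen cores; subtract every
   candidate with any control-proteome hit at E < 1e-5; survivors are the
   symbiosis-specific core, with per-taxon enrichment counts for heat
   maps.
5. **Ploidy**: per-site read counts are filtered (coverage ≥ 10, alt
   reads ≥ 2, alt fraction ≥ 0.2, exact binomial P < 0.05 vs the error
   rate), binned into an integer allele-frequency spectrum over 10–90%,
   and called diploid when ≥ 50% of the mass sits in the 40–60% window.

See `vignettes/fiscog-methods.Rmd` for the full model description,
parameter rationale and limitations.

## Worked example

```r
library(fiscog)

# Simulate the four-guild study design: 9 commensals, 6 + 3 pathogens,
# 4 free-living controls; 300 background families shared by everyone,
# 8 planted symbiosis-core families absent from controls.
design <- fiscog_design(seed = 42)
sim <- simulate_proteomes(design)
guild <- function(g) sim$proteomes[sim$taxa$taxon[sim$taxa$guild == g]]

res <- fiscog_pipeline(guild("commensal"), guild("pathogenA"),
                       guild("pathogenB"), guild("control"))
res$report
#> Symbiotic core gene report
#>   candidates (3-way intersection): 308
#>   removed by negative controls:    300
#>   surviving symbiosis-specific:    8
```

All 308 commensal core families are shared with both pathogen groups
(they are candidates); the 300 background families have homologs in the
control proteomes and are subtracted; exactly the 8 planted
symbiosis-core families survive. `res$enrichment` holds the
family-by-taxon counts behind an enrichment heat map (all zeros in
control columns, by construction of survival).

Ploidy inference from a simulated diploid pileup:

```r
pd <- pileup_design(ploidy = 2, n_sites = 50000, coverage_mean = 30,
                    heterozygosity = 0.005, seed = 7)
sites <- call_variants(simulate_pileup(pd))
sp <- allele_frequency_spectrum(sites[sites$accepted, ])
classify_ploidy(sp)
#> $call
#> [1] "diploid"
#> $mass_fraction
#> [1] 0.7383966
#> $n_sites
#> [1] 237
```

237 accepted heterozygous sites with 74% of the spectrum mass in the
40–60% window — the 50% peak of a disomic genome. A haploid design under
the same settings yields a near-empty spectrum and a non-diploid call.

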