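---
title: "Methods: distilling a fungus-insect symbiotic core gene toolbox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distilling a fungus-insect symbiotic core gene toolbox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

Fungi associated with insects span a spectrum from harmless gut commensals
(such as the Harpellales, obligate symbionts of aquatic insect larvae) to
entomopathogens that kill their hosts. A natural comparative-genomics
question is whether these ecologically disparate symbionts share a small
set of gene families that free-living relatives lack — a *fungus-insect
symbiotic core gene* (FISCoG) toolbox. `fiscog` implements that screen as
a reusable, fully testable pipeline:

1. **Similarity evidence** (`all_vs_all()`): every cross-taxon protein
   pair is aligned with a full Smith-Waterman/Gotoh affine-gap kernel and
   scored with Karlin-Altschul statistics; pairs with E-value at or below
   the working threshold (1e-5) become hits in the 12-column BLAST
   tabular layout.
2. **Ortholog structure** (`reciprocal_best_hits()`, `mcl_cluster()`):
   hits are condensed into families either by reciprocal best hits
   assembled into connected components, or by Markov clustering of the
   graph whose edges are weighted by `-log10` of the best pairwise
   E-value. Each family then receives per-taxon representatives chosen by
   total connectivity within the family.
3. **Core-set algebra** (`shared_genes()`, `fiscog_identify()`): per
   guild, the core is the set of families present in at least
   \(N - k\) of its \(N\) taxa (defaults: up to 3 of 9 commensals, up to
   2 of 6 group-A pathogens, and no group-B pathogens missing). The
   candidate toolbox is the intersection of the three symbiont cores,
   taken between family representatives linked by hits at E ≤ 1e-5; any
   candidate whose representative hits a free-living control proteome at
   E < 1e-5 is subtracted. Survivors are the symbiosis-specific core.
4. **Supporting computations**: supermatrix preparation (gap-fraction
   trimming, the 50-column length filter, concatenation with partition
   bookkeeping), allele-frequency-spectrum ploidy inference from per-site
   read counts, genome-match identity aggregation with the 100-kb
   close-pair rule, assembly statistics and the 25-Mb integer-multiple
   genome-size classification associated with whole-genome duplication.

# The similarity model

Scores use BLOSUM62 over the 20 standard residues with `X` scored 0
against everything, and affine gaps costing `gap_open + k * gap_extend`
for a length-`k` gap (defaults 11 and 1, the usual BLASTP settings). The
dynamic program is exhaustive — no seeding or banding — because the
pipeline targets desk-scale inputs where full DP over every pair is
affordable (the C++ kernel scores roughly 10^5 short pairs per second).

E-values use the Karlin-Altschul form \(E = K m n e^{-\lambda S}\) with
the conventional gapped-BLOSUM62 parameters \(K = 0.041\),
\(\lambda = 0.267\). These are not BLAST-bit-exact statistics and are not
meant to be: downstream logic consumes only the ordering of hits and the
1e-5 threshold. E-values are floored at 1e-200 before the `-log10`
transform so graph weights stay finite, capping edge weights at 200.

An important practical consequence of honest E-value calibration: at
threshold \(t\), unrelated sequence pairs produce chance hits at a rate
near \(t\) per pair. We measured about 3.5 chance hits per million random
length-50 pairs at E ≤ 1e-5 with these settings. A screen that compares
millions of pairs therefore sees a handful of spurious weak edges
(weights barely above 5, against ~100-200 for true homologs); the Markov
clustering step absorbs them, and the control-subtraction step is exposed
to only a few thousand representative-versus-control comparisons, so the
planted-recovery experiment below recovers the planted families exactly
in the overwhelming majority of seeds. This is a property of any
correctly calibrated threshold screen, not an implementation artifact.

# Markov clustering

`mcl_cluster()` implements the standard MCL update: self-loops with
weight equal to each node's maximum incident weight (1 for isolated
nodes), column normalisation, then alternating expansion (matrix
squaring) and inflation (entrywise power, default 2 — the `mcl` program's
convention — then renormalisation) until the largest entry change drops
below `1e-6` or 100 iterations pass. Clusters are read off as connected
components of the converged matrix's support, where entries below `1e-8`
count as zero; without such a floor the "nonzero pattern" of a
floating-point iterate is ill-defined. Random-walk flow cannot cross
connected components, so the iteration runs per component — identical
results to whole-graph iteration (the test suite checks this against an
independent whole-graph dense reference) at cost linear in component
size. All orderings (cluster IDs, tie-breaks in representative selection)
are lexicographic, so results do not depend on input order.

# The synthetic study design

`fiscog_design()` generates the study-shaped simulation: 9 commensal, 6
pathogen-A, 3 pathogen-B and 4 free-living control taxa; 300 background
families present in every guild including controls; 8 planted
symbiosis-core families present in every symbiont taxon and absent from
all controls. Per family an ancestral protein is drawn uniformly over the
20 residues; each carrying taxon receives an independently diverged copy
on a star phylogeny (binomial substitutions at rate 0.1 per site), and
paralog copies diverge further at rate 0.05. Defaults were chosen once,
before freezing, by two empirical requirements: same-family sequences
must always cross-match at E < 1e-5 (at 50 residues and 0.1 per-branch
divergence, true-pair scores sit far above the threshold), and unrelated
families must essentially never match (see the chance-hit rate above;
shorter proteins make the Karlin-Altschul formula slightly conservative,
which is the safe direction). Copy-number maps allow planting
lineage-specific paralog expansions to mimic post-duplication copy
retention.

What the simulator does *not* emulate: real domain architecture,
composition bias, indels, gene fusion/fission, annotation noise, or
phylogenetic correlation between taxa (divergence is star-shaped).
Passing tests therefore demonstrate the correctness of the set algebra,
clustering and thresholding machinery on data with known truth — not that
the biological screen is robust to annotation artifacts in real
proteomes.

The pileup simulator draws per-site coverage from a Poisson (mean 30 by
default, floored at 1). In a diploid, a site is heterozygous with the
design heterozygosity and its alternate count is Binomial(coverage, 1/2)
— symmetric sequencing error leaves the expected allele split at 1/2 —
while homozygous and haploid sites draw alternate reads only from the
error rate (default 1% per read).

# Variant calling and the ploidy rule

Site acceptance mirrors a conventional pileup SNP caller: coverage ≥ 10,
alternate reads ≥ 2, alternate fraction ≥ 0.20, and an exact one-sided
binomial test of the alternate count against the error rate at P < 0.05.
The named thresholds (min-coverage 10, P 0.05) are the analysis's stated
settings; the remaining two follow common caller conventions. The
significance test is a plain exact binomial rather than any specific
caller's internal statistic — it expresses the same contract and is
independently verifiable by direct tail summation.

Accepted sites are binned by alternate-allele percent, rounded half-up
(46.5 becomes 47; banker's rounding would shift bins between platforms),
over the 10-90% interval. The ploidy call is `"diploid"` when at least
half of the spectrum mass falls in the 40-60% window and the spectrum
holds at least 100 sites; `"haploid"` when sites suffice but the peak
mass does not. With fewer than 100 sites the call is `"indeterminate"`:
at realistic error rates a haploid genome yields an essentially empty
spectrum (about 0.2 accepted sites per 50 kb at 30x coverage in our
simulations), so "haploid or indeterminate" is the expected non-diploid
outcome and is how we score haploid truth in the recovery experiment. At
the default simulation scale (50,000 sites, heterozygosity 0.005,
coverage 30) diploids yield ~250 accepted sites with ~74% of mass in the
peak window, and classification accuracy in 100 + 100 replicates is 100%.

# Numerical and boundary choices

* "Best hit" ranks by lowest E-value, then highest bit score, then
  lexicographic subject ID, making reciprocal best hits deterministic.
* Cross-guild sharing uses E ≤ 1e-5 (the working cutoff); negative-control
  subtraction uses strict E < 1e-5. Both thresholds are configurable
  independently.
* The alignment length filter keeps blocks of ≥ 50 columns (a 49-column
  alignment is discarded); the close-pair rule is strict (exactly 100,000
  matched bases is not flagged); the scaffold filter is strict (> 1,000
  bp); aligned bases sum reference match lengths without overlap merging;
  summary identity is length-weighted by default with a plain-mean
  option.
* GC content is computed over retained (> 1 kb) scaffolds with ambiguous
  bases excluded from the denominator.
* Genome-size multiples round half-up with a minimum multiple of 1.

# Problem sizes

The shipped experiments run at: the full four-guild design (22 taxa,
~6,700 proteins of 50 residues, ~12 million cross-taxon alignments —
about 80 seconds on one core), 100 + 100 pileup replicates of 50,000
sites, and oracle suites at 20-30 nodes/pairs. These sizes were chosen so
the whole pipeline is comfortable on a laptop core while keeping every
stage's statistics meaningful.

# Known limitations

* The aligner reports one optimal alignment; co-optimal alignments are
  resolved deterministically but arbitrarily.
* Karlin-Altschul parameters are fixed per scoring scheme, not estimated
  per composition; E-values are honest for the simulator's uniform
  composition but only indicative for strongly biased real proteins.
* Multi-taxon RBH families use single-linkage components of pairwise
  pairs — the weakest defensible assembly rule; the MCL route is the
  primary clustering path.
* The ploidy model is strictly biallelic; multi-allelic sites and
  mapping artifacts are out of scope.
* Assembly statistics and match aggregation consume standard FASTA and
  coordinate tables; alignment itself (nucmer-style) is not reimplemented.
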