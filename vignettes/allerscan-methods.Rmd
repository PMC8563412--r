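---
title: "Methods: saturation-mutagenesis PhIP-seq epitope mapping with allerscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saturation-mutagenesis PhIP-seq epitope mapping with allerscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allerscan)
```

# The measurement

Phage immunoprecipitation sequencing (PhIP-seq) profiles the antibody
repertoire of a serum sample against a programmable peptide library: each
phage displays one peptide, serum antibodies are mixed with the library,
IgE or IgG is immunoprecipitated, and the bound phage are identified by
short-read sequencing. `allerscan` implements the complete computational
side of an allergen-focused variant of this assay, in which the library
contains 20-mer tiles stepped every 10 residues along a panel of allergen
proteins, plus a *saturation-mutagenesis* layer: every tile position
substituted with each of the 19 alternative amino acids. The wild-type
tiles measure *which* peptides a serum recognizes; the mutant layer
resolves *how* they are recognized, because substitutions at residues
contacted by the antibody deplete binding.

The package covers five stages, each usable on its own:

1. **Library design** (`design_library()`, `reverse_translate()`,
   `assemble_oligos()`): tiling, saturation, codon-optimized reverse
   translation with restriction-site exclusion and unique 50-nt 5'
   prefixes, and fixed cloning adaptors.
2. **Quantification** (`count_reads()`, `build_null()`, `zscore()`):
   from reads (or count tables) to enrichment Z-scores against a binned,
   trimmed mock-IP null, replicate averaging and reactivity calls.
3. **Footprints** (`wildtype_estimate()`, `relative_enrichment()`,
   `critical_residues()`, `substitution_profile()`): per-(sample, tile)
   substitution-effect matrices and critical-residue calls.
4. **Repertoire analytics** (`breadth()`, `seroprevalence()`,
   `jaccard()`, `footprint_correlation()`, `dominant_footprint()`,
   `preexisting_fold_change()`, `overlap_categories()`).
5. **Simulation** (`simulate_cohort()`, `simulate_ip()`,
   `simulate_footprint_panel()`): a fully ground-truthed generator so
   every stage is testable without any sequencing data.

# Library design

Tiles are 20-mers every 10 residues (`window`, `step`). When the step
grid leaves a gap before the C-terminus, one extra tile anchored at the
C-terminus is appended so that no residue is uncovered; proteins shorter
than one window become a single full-length tile, and saturation then
uses the actual tile length. These two rules are design choices: the
construction we reproduce states the grid but not the tail handling, and
full coverage is the evident intent. A strict-grid mode
(`cterm_anchor = FALSE`) is available for matching libraries built
without the anchor.

Reverse translation starts from the most-preferred codon for every
residue (E. coli K-12 ranking, since the library is expressed in
E. coli) and then repairs the encoding with deterministic synonymous
swaps — single swaps ordered from the 5' end before pairs — until two
constraints hold:

* no EcoRI (`GAATTC`) or XhoI (`CTCGAG`) site occurs in the insert or
  across an adaptor-insert junction. These are the enzymes that cut the
  amplicon during cloning; the 5' adaptor itself deliberately contains
  the EcoRI site, so adaptor-internal occurrences are the cloning sites
  and are not violations;
* the first 50 nt of every insert are unique across the library, so
  that sequencing reads can be assigned by exact prefix match with no
  aligner (`count_reads()` exploits exactly this guarantee).

Peptides are processed in lexicographic id order, which makes collision
resolution reproducible run-to-run regardless of input order. The two
adaptors, `GGAATTCCGCTGCGT` and `CAGGGAAGAGCTCGA`, are fixed constants
of the construction.

# The binned mock-IP null and Z-scores

A mock IP (no serum) measures what the sequencer returns for unbound
library background. Because expected read counts vary over orders of
magnitude with library abundance, a single global null is useless;
instead peptides of similar input abundance are grouped into
equal-occupancy bins (default 300 members, the last bin may be smaller)
and each peptide is scored against its own bin:

$$Z_{ps} = \frac{c_{ps} - \mu_{b(p)}}{\sigma_{b(p)}}$$

where $\mu_b$ and $\sigma_b$ are the mean and standard deviation of the
middle 90% of the bin members' mock counts (5% trimmed from each tail,
`ceiling(0.05 n)` values per end). Reactivity is called at
replicate-averaged $Z > 3.5$, strictly.

Three numerical choices matter here and are worth stating explicitly:

* **Binning reference.** The binning abundance estimate must be
  independent of the counts the moments are measured on; otherwise bin
  members are selected for tightly clustered values and the null spread
  collapses far below what an independent IP of the same peptides shows.
  `build_null()` therefore bins on an input-library sequencing run (the
  deep library QC run; `input_counts`) when one is available — this is
  also how the binning is described in the method line we follow
  ("abundance in the input library") — and falls back to splitting the
  mock replicates into a binning half and a moment half. With a single
  mock replicate and no input run the estimate degenerates and a message
  warns that the null spread may be optimistic.
* **Trimmed-sd consistency.** The standard deviation of the middle 90%
  of a distribution understates the full spread by a factor of ~0.789
  (normal reference). Left uncorrected, a nominal $Z > 3.5$ rule is an
  effective 2.8-sigma rule, and the resulting ~0.5%-per-peptide
  persistent false-call rate measurably contaminates small epitope sets
  (we observed it diluting longitudinal fold-change estimates). By
  default the trimmed sd is divided by the truncation consistency
  factor computed from the realized trim fraction — the same logic as
  the 1.4826 in a MAD — so Z is on a true-sigma scale;
  `sd_correction = FALSE` restores the literal uncorrected formula.
* **Depth scaling.** Samples are put on the mock scale by
  median-of-ratios scaling over well-measured peptides (default),
  which corrects sequencing depth *and* the compositional depression of
  unbound peptides when bound phage consume a visible share of a
  fixed read budget; plain total-depth scaling (`"total"`) and no
  scaling (`"none"`) are provided. Zero-variance bins get a 1-read sd
  floor.

# Footprints and critical residues

The enrichment unit for footprint work is the dimensionless fold-change
of a peptide's (depth-scaled) counts over its expected mock abundance.
The reference is the peptide's own averaged mock count
(`ref = "peptide"`): every mutant is a distinct library member, so a
bin-level reference would inject the within-bin abundance scatter into
every ratio as persistent noise — in focused high-coverage experiments
this was enough to corrupt critical-residue calls, while the per-peptide
reference is near-exact there. The bin-mean reference (`ref = "bin"`)
remains available for low-coverage full-library screens, where it
denoises the reference instead. Counts are floored at 0.5 reads so
log-ratios stay finite.

The wild-type tile's own enrichment is one noisy measurement, so the
wild-type level is estimated as the mean of the wild-type value and the
top half (top `ceiling(k/2)` of the `k` available) of its alanine-mutant
enrichments — alanine substitutions are mostly tolerated outside the
binding interface. Positions whose wild-type residue *is* alanine simply
contribute no alanine mutant. Each mutant's enrichment divided by this
estimate is the relative-to-wild-type enrichment `rel`; heatmaps plot
`-log10(1/rel)` (identically `log10(rel)`, asserted in the tests), and a
position is *critical* when the median of its 19 mutant enrichments
falls strictly below 40% of the wild-type estimate.

Per-protein substitution profiles average the per-position mean
depletion `mean(1 - rel)` over tiles whose wild-type Z strictly exceeds
5, averaging where gated tiles overlap; replicates are analyzed
individually. Footprints from different samples are compared as
flattened vectors of defined display cells on their shared cells;
subjects with pairwise Pearson r > 0.75 share a footprint, footprint
groups are connected components of that graph (deterministic and
order-free, unlike clique-based grouping), and the dominant footprint is
the largest component with lexicographic tie-breaking.

# Repertoire analytics

Genetic and splice variants of one allergen would count the same epitope
repeatedly, so set-level statistics use one canonical variant per
allergen family — the lowest-numbered id, overridable. On the resulting
epitope sets the package computes breadth (count of reactive canonical
wild-type tiles), cohort seroprevalence with a strict >30% public rule,
IgE/IgG Jaccard overlap and exclusive/shared fractions, and longitudinal
change for pre-existing epitopes (Z > 3.5 at baseline): per-peptide
`log2(Z_post/Z_pre)` with Z floored at 0.1, summarized as mean ± SEM.
Fold changes are computed over canonical wild-type tiles — the same
epitope universe as breadth — not over mutant peptides.

# What the simulator emulates

`sim_config()` defaults are the study conditions of the cohort the
package is built around, fixed up front:

| parameter | default | what it encodes |
|---|---|---|
| `reads_per_sample` | 2e6 | per-sample sequencing depth |
| `replicates` | 2 | technical IP replicates |
| `enrichment_fold` | 100 | fold enrichment of a bound wild-type peptide |
| `attenuation` | 10 | binding loss of mutants at critical positions |
| `n_critical` | 5 | critical positions per epitope footprint |
| `abundance_sdlog` | 2.0 | log-normal library spread: `2*pnorm(log(10)/2)-1` = 75% of members within one log10 of the median |
| `abundance_trunc` | 1.8 | smooth truncation (log10) of the abundance tails |
| `n_allergic`, `n_control` | 15, 30 | cohort sizes |
| `public_prevalence` | 0.3–0.9 | planted public-epitope prevalences |
| `private_rate` | 8 | Poisson mean of private IgE epitopes per subject |
| `igg_given_ige` | 0.5 | P(a week-0 IgE epitope is also an IgG epitope) |
| `ige_attenuation`, `igg_boost` | 0.5, 4 | post-OIT enrichment shifts |
| `igg_diversification` | 8 | newly acquired IgG epitopes after OIT |
| `igg_diversify_from_ige` | 0.7 | P(a new IgG epitope revisits an IgE specificity) |
| `sigma_rep` | 0.1 | log-normal per-replicate efficiency jitter |
| `input_coverage` | 60 | fold coverage of the input-library QC run |

With `private_rate = 8` and ten public epitopes at mean prevalence 0.6,
mean IgE breadth comes out near 14 and week-0 IgG breadth (half of IgE)
near 7, matching the pre-treatment repertoire sizes of the emulated
cohort; diversification takes week-52 IgG to ~15. The abundance
truncation exists because an unbounded sdlog-2 log-normal would leave
~10% of members undetectable at the 60-fold QC coverage, contradicting
the near-complete (99.3%) library recovery the distribution is supposed
to emulate; the 75%-within-one-log calibration is unaffected.

Reads are one multinomial draw per replicate at fixed depth, with
sampling weights `abundance x fold`; folds from multiple specificities
on one tile add (independent antibody clones capture distinct phage —
the simplest defensible combination rule). Mock IPs are the no-epitope
special case. Replicate variation beyond resampling comes only from the
log-normal efficiency jitter.

**Two regimes, one deliberate scope choice.** In a saturation library a
single bound epitope drags its whole 381-member mutant family along, so
at realistic breadths the bound phage dominate the fixed read budget and
multinomial renormalization distorts all count-level quantities —
ratio-based footprint statistics cancel this, Z-level repertoire
statistics do not. `simulate_cohort()` therefore models wild-type-level
reactivity over the full library background (`mutant_binding = FALSE`,
bound mass ~3% of reads), the regime in which planted folds are realized
as measured; mutant binding is simulated fully in focused per-tile
panels (`simulate_footprint_panel()`, `simulate_ip()`), the regime used
for footprint questions. The flag restores full mutant binding in cohort
mode if wanted.

What the generator does *not* emulate: PCR amplification bias, phage
growth competition, antibody competition/saturation chemistry,
conformational epitopes, and real sequence composition (proteins are
uniform-random). Passing recovery tests therefore demonstrates that the
estimators invert the generating model at realistic depths and effect
sizes — not that the thresholds are optimal for any particular real
dataset.

# Problem sizes and verification

The test-suite and acceptance-script simulations use a default synthetic
proteome of 8 allergen families (two with a second sequence variant,
exercising variant de-duplication), lengths 80–250 aa, giving ~170
wild-type tiles and ~65,000 peptides with mutants — about 40% of the
scale of the real peanut library, chosen to keep a full cohort run
around half a minute. Focused footprint panels use a single 100-aa
protein. The acceptance script (`scripts/acceptance.R`) recomputes, from
a fresh simulation at the given seed: breadth and its OIT shift,
epitope-call recall, pre-existing-epitope log2 fold changes, Jaccard
overlaps, seroprevalence recovery, mock false-call rate, replicate QC
correlation, critical-residue sensitivity/specificity, dominant
footprint size, within-subject IgE/IgG footprint similarity, and a
library-design constraint audit.

Key invariants asserted in the suite: binned-null Z-scores agree
elementwise (1e-12) with an independent brute-force reimplementation;
saturation yields exactly `19 x length` Hamming-1 mutants; every
designed insert translates back exactly, avoids the two restriction
motifs including junctions, and has a unique 50-nt prefix; Jaccard and
seroprevalence respect their bounds and strict thresholds; footprint
grouping is order-invariant and matches a union-find oracle.

# Known limitations

* With a single mock replicate and no input-library run, the null
  spread is estimated from the binning counts themselves and is
  optimistic; use at least two mocks or provide the QC run.
* The binned null inherits heavy-tailed miscalibration where per-bin
  abundance heterogeneity is large (very small libraries, extreme
  abundance tails); expect a ~0.1–0.5% per-peptide false-call rate at
  Z > 3.5 rather than the Gaussian nominal rate.
* Fold-change recovery interprets Z as proportional to `fold - 1`;
  this holds when the bound mass fraction is small and degrades as a
  sample's read budget saturates with bound phage.
* `count_reads()` is exact-match by design; reads with errors in the
  first 50 nt are counted as unmatched rather than rescued.
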