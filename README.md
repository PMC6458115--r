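# satellitome

Satellite DNA discovery, cataloguing and W-chromosome enrichment analysis
from unassembled short reads.

## The problem

Satellite DNAs (satDNAs) are noncoding sequences repeated head-to-tail in
long tandem arrays. In species with female-heterogametic (ZZ/ZW) sex
chromosomes, the female-limited W chromosome accumulates satellite
families that are rare or absent in males, so comparing a female (ZW) and
a male (ZZ) sequencing library family-by-family pinpoints W-linked
repeats without any genome assembly. This package implements that
comparative workflow at desk scale, for researchers studying
sex-chromosome differentiation, and for anyone who needs satellite
discovery, abundance quantification or repeat landscapes from raw reads:

- **simulate** — paired ZW/ZZ genomes with planted tandem arrays of known
  monomer, copy number, divergence and linkage, plus an error-bearing
  2x250 bp read simulator and a machine-readable truth table, so every
  downstream stage is testable without sequencing data;
- **discover** — an iterative mining loop: sample reads, cluster them by
  shared canonical k-mers, detect tandem periodicity by lag self-match,
  derive monomer consensuses, mask the pool and repeat until no new
  satellite appears (low-abundance families surface in later rounds once
  abundant ones are masked);
- **catalog** — a three-level hierarchy (variant / family / superfamily
  at >95% / >80% / >40% identity) built on circular, strand-aware
  sequence identity, with `<Prefix>SatNNN-RUL` names ranked by female
  abundance;
- **quantify** — equal-size subsampling of the two libraries, best-hit
  local alignment of reads to the catalog, per-family abundance
  (aligned nucleotides / library nucleotides), Kimura 2-parameter
  divergence, repeat landscapes, the subtractive female-minus-male
  landscape, and F/M ratio ranking of W candidates;
- **monomer-net** — harvesting of complete, phased monomers from reads,
  haplotype collapse with per-sex counts, singleton removal and
  abundance-aware minimum spanning trees (GraphML/DOT export);
- **sexing** — two non-invasive sex diagnosis calculators: quick-FISH
  interphase spot counting (2 spots = ZZ male, 3 = ZW female) and qPCR
  delta-Ct relative quantification of a W-linked satellite against a
  single-copy reference, plus the Mann-Whitney U (exact by enumeration
  for small samples), Shapiro-Wilk and Kruskal-Wallis tests used around
  them.

## The statistics at the core

For a satellite family *f* with abundance $A_F(f)$ in the female library
and $A_M(f)$ in the male library (each the fraction of library
nucleotides aligning to the family consensus),

$$\mathrm{F/M}(f) = A_F(f) / A_M(f),$$

with families absent in the male flagged (they sort above every finite
ratio). Large F/M ratios indicate W-chromosome accumulation. Divergence
of each aligned read segment from the consensus uses the Kimura
2-parameter distance

$$K = -\tfrac{1}{2}\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\,\big],$$

where $P$ and $Q$ are the transition and transversion proportions.
Binning each hit's abundance contribution by its $K$ gives the repeat
landscape; the per-bin female-minus-male difference is the subtractive
landscape that highlights divergence classes over-represented in the
female genome. The qPCR calculator uses $\mathrm{RQ} = 2^{-\Delta C_t}$
with $\Delta C_t = \overline{C_t}^{\,target} - \overline{C_t}^{\,ref}$.

## Worked example

The bundled candidate table carries the published per-library abundances
(percent of library nucleotides) of the top W-candidate families of a
characiform fish with a ZZ/ZW system:

```r
library(satellitome)
tab <- candidate_families()
sel <- tab[match(c("MmaSat009-53", "MmaSat097-39", "MmaSat155-71"),
                 tab$family), ]
data.frame(family = sel$family,
           fm = fm_ratio(sel$abundance_female,
                         ifelse(is.na(sel$abundance_male), 0,
                                sel$abundance_male)))
#>         family        fm
#> 1 MmaSat009-53     1.834
#> 2 MmaSat097-39    88.909
#> 3 MmaSat155-71       Inf
```

MmaSat009 is only mildly female-enriched (it has autosomal copies as
well as a W cluster), MmaSat097 is ~89-fold enriched (a W-specific
band — the family used for quick-FISH sexing), and MmaSat155 is absent
from the male library altogether (`Inf` = the absent-in-male flag).

The same quantities on fully synthetic data, where the truth is known:

```r
set.seed(11)
specs <- list(
  family_spec("satA", random_dna(60), copies_female = 120,
              copies_male = 120, n_arrays = 2,
              per_copy_substitution_rate = 0.02),
  family_spec("satW", random_dna(70), copies_female = 60, copies_male = 0,
              n_arrays = 2, per_copy_substitution_rate = 0.02,
              linkage = "W"))
g <- plant_satellites(specs, 200000, seed = 11)
sim <- simulate_reads(g, read_sim_config(n_read_pairs = 3000, seed = 12))
res <- abundance_table(sim$female, sim$male,
                       setNames(g$monomers, names(g$monomers)))
res$table[, c("family_id", "abundance_female", "abundance_male",
              "divergence_female", "fm_ratio")]
#>      family_id abundance_female abundance_male divergence_female fm_ratio
#> satW      satW           0.0211         0.0000              2.19      Inf
#> satA      satA           0.0325         0.0355              2.02    0.915
```

The autosomal family comes back at F/M near 1 with its planted ~2%
divergence, and the W-linked family is flagged absent-in-male; both
abundances match the planted truth (`g$truth`) within read-sampling
noise. `run_pipeline(default_config(seed = 1), out_dir = "out")` runs
the whole chain — simulate, discover, catalog, quantify, monomer
network — and writes the catalog FASTA, abundance and landscape tables,
ranked candidates, MST graphs and a seeded run manifest.

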