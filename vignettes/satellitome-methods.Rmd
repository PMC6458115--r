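---
title: "Methods: satellite discovery, W-linkage quantification and sexing"
author: "satellitome authors"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models
and procedures implemented, the parameters that matter and their
defaults, what the synthetic data generator does and does not emulate,
the numerical choices, and the known limits of each stage.

## The comparative design

In a ZZ/ZW species the W chromosome is confined to females, so any
satellite family clustered on the W contributes nucleotides to a female
(ZW) sequencing library but not — or much less — to a male (ZZ) one.
The package's central statistic is therefore the per-family F/M ratio:
the family's abundance (aligned nucleotides over library nucleotides) in
an equal-size sample of the female library divided by the same quantity
in the male library. Autosomal families sit near 1, Z-linked families
near 0.5 (one dose in females, two in males), and W-linked families far
above 1 or, when absent from the male sample, at the absent-in-male flag
(`Inf`), which sorts above every finite ratio. Equal-size subsampling of
the two libraries (`subsample_equal`, default: the size of the smaller
library) is what makes the two abundances comparable; without it the
deeper library would dominate every ratio.

## Synthetic data: what it emulates and what it does not

`plant_satellites()` builds one background sequence per sex
(i.i.d. uniform nucleotides) and inserts head-to-tail tandem arrays at
uniform random non-overlapping positions. Each planted copy is mutated
independently: substitutions at the family's per-copy rate with a
transition:transversion ratio of 2 (so planted divergence is recoverable
by the Kimura 2-parameter estimator), indels off by default so the truth
table's nucleotide bookkeeping stays exact. The truth table records
post-mutation array coordinates (0-based, half-open) and the exact
planted fractions. `simulate_reads()` samples fragments uniformly
(normal insert length, default 500 +/- 25 nt), reverse-complements the
second mate, applies uniform substitution errors (default 0.001/base)
and emits constant-Q30 qualities; quality trimming is exercised in tests
by injecting low-quality tails rather than by a full error model.

Deliberately not modeled: realistic Illumina error profiles, PCR
duplicates, GC bias, chimeric reads, chromosome structure (each "genome"
is a sequence list; linkage is a label, which is sufficient because the
downstream mathematics only consumes per-library nucleotide fractions),
and unequal per-sex coverage (available by configuring different
`n_read_pairs`, but the quantify stage subsamples to equal size anyway).
Consequently, passing tests demonstrate the correctness of the
algorithms under clean sampling assumptions — not robustness to the
artifacts of real libraries.

Two facts about this design matter when reading test tolerances. First,
read pairs are sampled as fragments, so the two mates of a
satellite-spanning fragment are correlated and the effective sample size
for an abundance estimate is the number of fragments, not reads; the
binomial bounds in the tests use fragment counts. Second, at roughly 1x
coverage and above, background reads overlap each other and share
k-mers, which is why satellite triage in clustering cannot rely on
connectivity alone (next section).

## Discovery loop

`run_discovery_loop()` joins the two libraries and iterates four steps.

1. **Sampling.** Round 1 draws `round0_n` reads per library; round 2
   doubles the draw; later rounds keep it constant. Sampling is uniform
   without replacement and seeded per round.
2. **Clustering** (`cluster_reads`). Reads are nodes; an edge joins two
   reads sharing at least `min_kmer_share` (default 0.2) of the smaller
   of their canonical k-mer sets (k = 13; canonical = lexicographic
   minimum of a k-mer and its reverse complement, which makes the graph
   strand-symmetric). Connected components of at least
   `min_cluster_size` (default 5) reads are candidate satellites. Reads
   whose k-mers are essentially private cannot form qualifying edges and
   are excluded before the quadratic step. A component is kept only if
   the median relative k-mer diversity of its reads is at most 0.85: a
   read made of tandem copies carries roughly one monomer's worth of
   distinct k-mers (well under half its length), whereas overlapping
   single-copy reads carry nearly maximal diversity. This quantitative
   triage replaces the visual "spherical or ring-shaped" cluster
   inspection of graph-based repeat explorers, which is not reproducible
   programmatically, and it is also what keeps coverage-induced
   background components from wasting consensus work.
3. **Tandem detection** (`detect_tandem_period`). The cluster consensus
   (majority vote over members locally aligned to the cluster medoid;
   the medoid maximizes the size-normalized in-cluster k-mer share so
   that array-edge reads with background tails are not chosen) is
   scanned for the smallest lag at which at least `min_match_fraction`
   (default 0.7) of positions match themselves shifted; among lags
   within 10% of that candidate the best-matching one wins, guarding
   against off-by-one lags under noise. The monomer consensus is the
   column majority over lag phases. Periods up to half the consensus
   length are detectable, so with 250 nt reads the practical monomer
   ceiling for discovery is ~125 nt; longer monomers must come in via a
   user catalog.
4. **Masking** (`mask_reads`). Reads aligning to any discovered monomer
   (tiled to circular completeness, either strand) at >= 0.8 identity
   over at least half the read are removed from the pool, and the loop
   repeats until a round contributes no novel monomer (novel = below
   0.8 circular identity to every known one) or `max_rounds` is hit.

The sample-doubling plus masking dynamic is what lets rare families
surface late: a family at ~0.3% of nucleotides usually misses the
round-1 cluster-size floor but clears it once the sample doubles, which
is the desk-scale analogue of low-copy W-linked satellites appearing
only in later mining iterations.

## Circular identity and the catalog

Tandem monomers are circular and strandless, so sequence identity must
be rotation- and strand-invariant. `circular_identity()` aligns the
shorter sequence globally against every rotation of the longer one, on
both strands, with free end gaps in the partner; identity is matches
over alignment length, where the length also charges the part of the
partner the alignment leaves uncovered. Charging the uncovered length is
deliberate: a 17-nt monomer fitted snugly inside a 60-nt monomer is not
"90% identical" to it — the repeat units are incompatible — and without
that term the 40% superfamily threshold would merge families of wildly
different repeat unit lengths. The explicit rotation scan is exact but
cubic in length; beyond 400 nt a single fit alignment against the
doubled partner replaces it (a close approximation that can only differ
when an alignment profitably spans more than one period).

A caveat stated rather than hidden: for random monomers in the 30-90 nt
range, the maximum over all rotations and strands of a gapped alignment
identity has a chance baseline near 0.4-0.5. The >40% superfamily tier
is therefore only weakly discriminative at these lengths — it reliably
separates families with incompatible repeat unit lengths, which is the
useful signal it carries — while the >80% family tier and >95% variant
tier sit far above chance and drive all downstream conclusions.

`group_hierarchy()` takes single-linkage connected components of the
pairwise identity graph at the three thresholds; because an edge above a
higher threshold is also above every lower one, the three partitions
nest by construction. `assign_names()` ranks families by decreasing
female abundance and names them `<prefix>SatNNN-RUL` (rank zero-padded
to 3 digits, configurable), with ties broken by male abundance and then
lexicographically so names are deterministic under input permutation.

## Quantification

`align_to_catalog()` gives each read its single best-scoring local
alignment to any catalog variant (either strand, variants tiled so
alignments cross copy junctions); unaligned flanks long enough to host
another hit are re-aligned, so hits never overlap and abundance is never
double-counted — this is the best-hit resolution a masking-based
annotator applies. Hits need >= 20 aligned bases at >= 0.7 identity.
Abundance is aligned nucleotides over total library nucleotides: the
library-fraction reading of abundance, chosen (and documented here)
because the alternative read-count denominator makes families of
different monomer length incomparable; a read-count interpretation can
be recovered from the hit tables if needed. Substitutions in each hit
are classified as transitions (A/G, C/T) or transversions, giving per-hit
proportions P and Q and the Kimura 2-parameter distance
K = -0.5 ln[(1-2P-Q) sqrt(1-2Q)]; arguments outside the log domain
return NA (saturation) rather than a fabricated value. Family divergence
is the aligned-nt-weighted mean of per-hit K, in percent, computed
read-versus-consensus (as masking annotators do) rather than all-pairs
among copies. Landscapes accumulate each hit's abundance contribution
into 1%-wide divergence bins (width configurable), so bins sum exactly
to family abundance; the subtractive landscape is the per-bin
female-minus-male difference and may be negative.

## Monomer networks

`harvest_monomers()` aligns each read (both strands) to the family
consensus tiled head-to-tail and excises every complete monomer copy —
an alignment segment spanning one full consensus period strictly inside
the read — oriented to the consensus strand and projected onto consensus
coordinates (per consensus position the aligned read base, `-` for a
deletion; read insertions dropped). This star alignment to the consensus
stands in for a full multiple alignment of all monomers; it is an
approximation that reads every monomer through the consensus's
coordinate frame, adequate at the low intra-family divergences involved,
and it guarantees that rotations never create artificial haplotypes
because every monomer is phased to consensus position 0. Haplotypes are
exact-sequence groups over the projections with per-sex counts pooled
across libraries before filtering; a singleton is a haplotype seen once
across both libraries combined. `build_mst()` runs Kruskal's algorithm
over Hamming distances (gaps a fifth state) with deterministic,
abundance-aware tie-breaking: among equal-weight edges, the edge whose
endpoints carry the higher total count is added first, then the higher
minimum count, then lexicographic node order — the tie-break style of
goeBURST-type haplotype network tools. Tie-breaking only selects among
co-optimal trees; minimal total weight is guaranteed regardless, and the
tests verify it against exhaustive spanning-tree enumeration.

## Sexing calculators

The quick-FISH caller consumes per-cell spot counts from a two-probe
design (an autosomal control locus giving two signals plus a W-specific
locus giving a third in females). Cells with counts other than 2 or 3
are treated as dropout/overlap: excluded from the denominator but
reported. A specimen is called when at least `majority` (default 0.8) of
informative cells agree; the default is set below the ~90% expected
signal rate of real preparations so that true specimens classify, and at
least `min_cells = 20` informative cells are required. The qPCR
calculator computes dCt = mean target Ct - mean reference Ct,
RQ = efficiency^(-dCt) with efficiency defaulting to 2 (100%
amplification efficiency; exposed as a parameter), SEM propagated as the
root-sum-square of the two channel SEMs. Replicates whose within-channel
range exceeds 0.5 cycles are deemed inconsistent and the record is
rejected — a common-practice threshold, stated here because no standard
exists. Sex calls compare RQ of the W-linked target to a threshold,
derived when calibration specimens of both known sexes are supplied as
the geometric midpoint of the two groups' RQ geometric means.

The accompanying statistics are two-sided throughout. Mann-Whitney U is
implemented in full: midranks, U = min(U_a, U_b), and for
n_a + n_b <= 12 an exact p by enumerating all group assignments of the
pooled observations (P(U <= u_obs); the min-U statistic is inherently
two-sided), otherwise a normal approximation with tie correction and
continuity correction. Shapiro-Wilk and Kruskal-Wallis delegate to the
vetted routines in `stats` behind validating wrappers.

## Numerical choices and degenerate inputs

Alignment scoring is deliberately simple — match +1, mismatch -2,
gap -3, linear — because every decision downstream is made on identity
computed from the traceback, not on the raw score. Local alignments clip
terminal mismatches, so a substitution at the first or last base of a
read is invisible to divergence counting; at 250 nt this bias is
negligible. Empty read sets, empty hit lists, empty catalogs, zero read
pairs and single-haplotype networks all return well-formed empty or
singleton objects rather than errors, except where emptiness makes an
operation meaningless (an empty library has no defined abundance
denominator). K-mer sizes are capped at 15 so codes fit
32-bit integers. Stage seeds derive from the master seed as
`(seed + 7919 * stage) mod (2^31 - 1)`, keeping every derived seed a
valid 32-bit integer and letting any stage be re-run independently.

## Problem sizes used in the checks

The test and acceptance simulations run at desk scale, chosen so the
statistical assertions have adequate power under fragment-level binomial
noise: abundance recovery plants five families at 1.2-3.0% of a 1 Mb
genome per sex and sequences 20,000 read pairs per sex (at these
fractions the 15% relative-error band is about two standard deviations
of fragment sampling); discovery convergence plants five families at
0.3-2.5% of 400 kb and samples 1000 reads per library in round one,
twenty replicate simulations; the rare 0.3% family is deliberately
placed so round-1 samples often miss it and the doubled round-2 sample
recovers it. Published-scale quantities that depend on the real
sequencing libraries (hundreds of families, genome-wide satellite
fractions, exact monomer counts) are outside what synthetic data can
reproduce and are represented by these property-level checks instead.

## Known limitations

- Discovery is limited to monomers shorter than half the consensus
  contig length (~read length); very long monomers (up to the 2000 nt
  the catalog supports) are quantifiable but not discoverable from
  250 nt reads.
- The greedy anchor consensus is not an assembler; contigs never exceed
  read length, which is fine for periodicity detection but means the
  catalog consensus of a family is its monomer, not a higher-order
  array structure. Higher-order repeat detection is out of scope.
- The star alignment behind haplotype distances slightly compresses
  distances between haplotypes that share an indel relative to the
  consensus.
- The superfamily tier carries limited signal at short monomer lengths,
  as discussed above.
- The sexing calculators validate on synthetic spot/Ct data; their
  field reliability depends on probe and primer behavior that no
  simulation here models.
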