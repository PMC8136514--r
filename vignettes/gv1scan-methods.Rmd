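---
title: "From backcross to broken splice site: the gv1scan methods"
author: "gv1scan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From backcross to broken splice site: the gv1scan methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gv1scan)
```

# The scientific problem

Inbred mouse strains differ in whether they present murine leukemia virus
(MLV) envelope glycoprotein on the cell surface (the classical G~IX~
antigen). The controlling locus maps to a Krüppel-associated-box zinc
finger protein (KRAB-ZFP) cluster on chromosome 13 — a region so
repetitive and structurally variable between strains that every standard
analysis step needs care. `gv1scan` implements the computational chain
used to dissect such a locus:

1. **Backcross linkage mapping** places the trait between two
   microsatellite markers and interpolates a physical peak position.
2. **Windowed read-depth-ratio profiling** reveals copy-number variation
   (CNV) in the candidate region and clusters strains into lineage
   groups by the median absolute error (MAE) between profiles.
3. **Assembly-versus-reference comparison** of BAC clone sequences from
   an alternate haplotype exposes duplicated and unique sequence, and
   end-overlap scaffolding reassembles the clones.
4. **Splice-acceptor classification** against the consensus N[C/T]AG↓G
   explains why a duplicated gene copy can be non-functional.
5. **ERV expression analysis** quantifies the de-repression of MLV
   subclasses when the silencer is absent.

Every stage consumes either standard text formats (bedGraph, BED, FASTA,
PAF, TSV) or the output of the package's synthetic-data generators, so
the whole chain runs and is tested without any external download.

# Linkage mapping

In an N2 backcross every informative animal is heterozygous (`H`) or
homozygous (`B`) at each marker, so the recombination fraction between a
marker and a fully penetrant binary trait is directly countable. For a
marker with $N$ informative animals and $R$ phenotype–genotype
disagreements (phase chosen per marker to make $R \le N/2$, because
linkage phase is not known a priori), the package scores

$$\hat r = R/N, \qquad
\mathrm{LOD} = (N-R)\log_{10} 2(1-\hat r) + R\log_{10} 2\hat r ,$$

the log~10~ likelihood ratio of the binomial recombination model at
$\hat r$ against free recombination ($r = 0.5$). Inside the $R$ term
$\hat r$ is floored at $1/(2N)$ so the score stays finite; at $R = 0$
that term vanishes and the familiar $N \log_{10} 2$ results (about 30.1
at $N = 100$).

The physical peak is interpolated between the two markers flanking the
maximum-LOD marker by scaling genetic to physical distance:

$$\mathrm{peak} = \mathrm{pos}_A +
\frac{d_A}{d_A + d_B}\,(\mathrm{pos}_B - \mathrm{pos}_A),$$

with $d_A$, $d_B$ obtained from the flanking markers' recombination
fractions through Haldane's inverse map $d = -50\ln(1-2r)$. Haldane's
function (memoryless crossovers) is used consistently in the simulator
and the scan; whether a Kosambi-style map would fit real mouse data
better is irrelevant here because the same function generates and
analyses the synthetic meioses, and the interpolation itself is agnostic
to the distance measure (units cancel in the ratio).

The phenotype is treated as a binary trait with a penetrance parameter:
the recorded phenotype equals the trait-locus genotype with probability
`penetrance` (default 0.95), flipped symmetrically in both genotype
classes otherwise. Phenotype misclassification inflates all marker
$\hat r$ estimates additively, which shifts LOD magnitudes but largely
cancels in the *comparison* between markers — the property the peak
interpolation relies on.

```{r linkage-demo}
map <- gv1MarkerMap()
bc <- simBackcross(map, traitPosCm = approx(map$posMb, map$posCm, 66.58)$y,
                   nAnimals = 1108, penetrance = 0.95, seed = 1)
linkageScan(bc)
```

The simulated study conditions are nine markers spanning 13:63–68 Mb at
0.5 cM/Mb (the mouse genome-average recombination rate) and 1,108
animals. Under these conditions the interpolated peak lands within one
marker interval (0.625 Mb) of the true trait position in well over 95 %
of seeds — the property the test suite asserts over 100 replicates.

# Depth-ratio CNV profiling

Depth profiles are windowed counts on a fixed grid (default 10 kb — the
precision at which CNV boundaries in this region are usually quoted).
The per-window ratio of strain $s$ against reference $r$ is

$$\rho_i = \frac{(c_i + p)/L_s}{(r_i + p)/L_r},$$

with pseudocount $p = 0.5$ keeping deleted windows finite and library
sizes $L$ normalizing coverage. Its expectation is $\mathrm{CN}/2$ for a
diploid reference. Two numerical points deserve mention:

* **Library sizes are genome-scale totals.** If $L$ were the sum of
  counts over the profiled region alone, a megabase-scale deletion
  (20 % of the region) would inflate every other window's ratio by
  25 % and push diploid windows across a state boundary. Real
  sequencing libraries are genome-wide, so the simulator supplies the
  expected diploid total; the reader defaults to column sums only when
  nothing better is known.
* **The ratio of two noisy counts is slightly biased upward** (by a
  factor $\approx 1 + 1/\mu$ for Poisson counts of mean $\mu$). At
  WGS-like window depths this is percent-level and irrelevant to state
  calling; the test that checks the $\mathrm{CN}/2$ expectation against
  Monte-Carlo error therefore uses deep coverage where the bias is
  negligible.

Segmentation median-filters the ratio track (width 5 windows), maps
windows to states at the midpoints between copy-number expectations
(0.25, 0.75, 1.25, 1.75), merges runs, and reports non-diploid calls at
least 5 windows long — suppressing single-window noise while keeping
every span the analysis cares about (the shortest reported deletion is
81 windows). A median filter preserves ideal step edges exactly, so on
noise-free input boundary error is zero and the tests assert the
worst-case bound of half the filter width.

```{r cnv-demo}
dps <- simDepthProfiles(gv1StrainPanel(), simConfig(seed = 1), "B6J")
segmentRatio(depthRatio(dps))[, c("strain", "state", "spanKb")]
```

Strain distance is the **median** absolute error between ratio
profiles. The acronym MAE usually reads "mean", but the figure legend
this measure re-implements spells out *median*; the conventional mean is
available via `fun = "mean"`. The median has a consequence worth
understanding: two strains must differ in **more than half** of their
windows for the distance to rise above the noise floor. The synthetic
strain panel therefore gives the non-C57 lineage an alternate
chromosomal conformation spanning most of the region (gains and losses
over ~93 % of windows) plus small private variants — which is also the
biological picture the profiling suggested: not scattered small CNVs,
but a different haplotype of independent subspecies origin. Clustering
is agglomerative (average linkage by default, robust to the block-CNV
structure) on the symmetric zero-diagonal MAE matrix, and `hclust`'s
deterministic merge order makes results reproducible; flat groups come
from cutting the tree at $k = 2$ for the lineage split.

# Assembly comparison and scaffolding

Alignment segments arrive as PAF-like records (precomputed or
simulated; the package does not align). The dotplot filter keeps
segments of query span ≥ 1 kb and identity ≥ 98 % (inclusive).
Duplicated reference sequence is detected as windows overlapped by ≥ 2
distinct segments; unique query sequence is the per-query complement of
segment coverage. Both reduce to interval arithmetic on half-open
coordinates and are tested against brute-force oracles.

Vector removal merges hit intervals, excises them, and keeps fragments
≥ 500 bp (shorter remnants are vector-adjacent junk in practice).

Scaffolding joins clones whose ends overlap: for every clone pair and
relative orientation the longest suffix–prefix overlap ≥ 1 kb at ≥ 99 %
identity is found by anchoring an exact match of the leading bases of
the candidate prefix (24 bp seed) and verifying identity over the full
overlap. Joins are applied greedily, longest overlap first with
ties broken by clone name; each clone end is used at most once and
cycle-closing joins are skipped, so scaffolds are simple paths and the
scaffold count equals the number of connected components of the overlap
graph. The anchor-based detection assumes the first bases of a true
overlap match exactly — appropriate for the high-accuracy consensus
sequences being joined, and exact for the engineered overlaps the
generator produces. The criteria used for the original BAC joining are
not on record; these defaults are declared, not reconstructed.

# Splice-acceptor classification

The consensus mammalian 3′ splice acceptor is scored over exactly five
positions — N[C/T]AG↓G: four intronic bases (anything, pyrimidine, A,
G) and the first exonic base (G). No branch-point or polypyrimidine
scoring is attempted, and no splice-strength model: the question the
classifier answers is categorical (does the canonical acceptor exist at
all?), which is also how variant-effect predictors treat
splice-acceptor disruptions ("high" impact). Minus-strand sites are
reverse-complemented before scoring, making classification strand
symmetric, which the tests verify exhaustively over all 1,024 5-mers.
`N` in input matches only the consensus N slot, and IUPAC codes other
than N are rejected outright — silent degenerate matching would mask
data problems. The figure this mirrors shows the broken bases only
graphically, so the synthetic sites break the consensus at two defined,
representative positions (the pyrimidine and the exonic G) rather than
asserting unprinted base identities.

```{r splice-demo}
sites <- simAcceptorSites(seed = 1)
compareAcceptors(sites$reference, sites$broken_pyrimidine)
```

# ERV expression analysis

The regulated/unregulated call follows the published rule — *q* < 0.01
and |log2FC| > 1 — but the study's actual differential-expression
machinery is not described in the main text. Rather than wrap an
external DE package, `gv1scan` defines a self-contained permutation
test so the rule is exercised end to end: the statistic is the
difference of group means of $\log_2(\mathrm{CPM}+1)$ (the +1 offset
handles fully silenced loci), its null distribution comes from sample
relabelings — exhaustive when $\binom{n}{n_A}$ does not exceed the
permutation budget, otherwise 10,000 random relabelings with the
add-one correction $p = (b+1)/(n+1)$ — and *q* is Benjamini–Hochberg
across loci. This is a declared substitute, not a reconstruction.

A hard arithmetic fact follows: with three samples per group there are
only $\binom{6}{3} = 20$ relabelings, and because the two-sided
statistic ties each relabeling with its complement, the smallest
attainable *p* is 0.1. **No locus can reach q < 0.01 in an exhaustive
3 vs 3 permutation test**, whatever its fold change. The package
reports this honestly (the 3 vs 3 design is enumerated exhaustively and
its *p* floor is asserted in the tests); power of the q < 0.01 rule is
demonstrated at six per group, where the floor is 2/924 and strong
fold-8 signals are flagged reliably. The published analysis evidently
used a parametric DE method, which buys significance at n = 3 by
modelling assumptions instead of permutations.

Subclass summaries average **linear** folds $2^{\log_2 FC}$
arithmetically (a geometric-mean alternative is a flag away, and
whether to average all loci of a subclass or only the significant ones
is an explicit argument, since the published "average upregulation"
does not say). Simulated at the study conditions — ~50 MLV loci, folds
of 14.5 for pMLV and 5.3 for xMLV — the summaries recover the planted
folds within Monte-Carlo error at large n. As with depth profiles,
per-sample library sizes are transcriptome-scale (~10^6^) so that
strong ERV induction does not deflate the CPMs of unchanged loci
(composition bias); `normalizeCpm` on a bare matrix still gives
columns summing to exactly 10^6^.

PBS stratification compares per-locus log2 fold changes between tRNA
primer-binding-site classes with a rank-based test (Wilcoxon for two
classes, Kruskal–Wallis beyond); "no stratification" is the expected
outcome and is reported at p ≥ 0.05. qRT-PCR support implements
$2^{-\Delta Ct}$ against a reference gene, with targets at the 40-cycle
cap reported as negligible-or-absent (relative expression 0, flagged).

# What the synthetic data do and do not show

The generators reproduce the *statistical structure* the analysis
assumes: Haldane meioses over a real-scale marker map; Poisson or
negative-binomial window counts (variance $\mu + \alpha\mu^2$;
$\alpha = 0$ degrades to Poisson) with CN/2 expectations; engineered
deletions/duplications at the published coordinates; consensus and
broken acceptor contexts; exact engineered clone overlaps;
negative-binomial two-group counts with subclass-specific folds.
They do **not** reproduce mappability and GC artefacts of real depth
data, sequencing error in clone consensus sequences, linkage-map
inflation from genotyping error, or the correlation structure of real
ERV expression. Passing tests therefore demonstrate that the
*algorithms* are correct and well calibrated under their stated models,
not that the biological values would be recovered from the deposited
raw data — several published quantities (the 2494× BAC coverage, the
exact 14.5×/5.3× folds, the real peak at 13:66.58 Mb) depend on
unavailable raw or supplementary material and are targeted only through
property-based substitutes at matched problem sizes.

Problem sizes used throughout the tests and the acceptance script are
the study's own where stated (1,108 animals × 9 markers; ~400 windows
of 10 kb over 4 Mb; ~50 ERV loci; 3 mice per group, with larger n only
where an estimate's Monte-Carlo error or a p-value floor demands it;
15 clones in 8 components) and 100-seed replication for every
stochastic recovery rate.

# Degenerate inputs and tie-breaking

* Markers with all genotypes missing raise; constant phenotypes return
  LOD 0 with a flag rather than an error, so a scan over many markers
  survives a degenerate one.
* `interpolatePeak` refuses $d_A + d_B = 0$; a maximum-LOD marker at
  either end of the map places the peak at that marker.
* Window grids must match exactly between profiles; the first
  mismatching window is named in the error.
* The last partial window at a region end is dropped, never padded —
  equal-width windows keep ratios comparable.
* Greedy scaffolding breaks overlap-length ties by clone name;
  `hclust` merge order resolves clustering ties; both make reruns
  byte-identical.
* All generators take explicit integer seeds, and the pipeline derives
  per-stage seeds from one master seed.

# Known limitations

* Interval mapping (EM over positions between markers) is not
  implemented; the peak comes from single-marker statistics plus
  interpolation. The second, unlinked locus of the original cross is
  not modelled.
* Segmentation is threshold-based on a median-filtered track; no HMM or
  CBS. For the block CNVs at issue this is exact; for noisy, short, or
  mosaic CNVs it would not be.
* No GC/mappability correction of depth, by design — upstream of this
  package.
* The permutation DE test cannot reach q < 0.01 at 3 vs 3 (see above);
  that is a property of exact inference at tiny n, stated rather than
  papered over.
* Scaffolding assumes clean consensus sequences; it is not a
  general-purpose overlap-layout assembler.
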