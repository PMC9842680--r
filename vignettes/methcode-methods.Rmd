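---
title: "Models and methods behind methcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methcode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcode)
```

# Scope

`methcode` implements a comparative DNA methylation analysis stack for
reduced representation bisulfite sequencing (RRBS) that does not require
reference genomes. The pipeline runs from raw (simulated or real) reads to
species-level statistics: in silico restriction digest, reference-free
consensus fragment construction, methylation calling, coverage-based
quality flags, methylation erosion statistics, sequence-composition models
of genome-wide methylation with phylogenetic correction, k-mer classifiers
of locus-level methylation state with cross-species transfer, tissue
differential methylation with motif enrichment, and gene-centric promoter
methylation in a shared human-ortholog space. A synthetic data generator
covers every stage, so the full stack is testable without external data.

This vignette records the models, the tunable parameters, and the design
choices that were genuinely open, in the package's own words.

# The synthetic data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed once and used throughout the test suite.

**Species trees.** `simulate_tree()` draws a pure-birth (Yule) tree, which
is ultrametric by construction; taxonomic group labels come from an
average-linkage cut of the cophenetic distances. Branch lengths are in
expected-substitution units with birth rate 1.

**Genomes.** `simulate_genome()` produces an i.i.d. background at a target
GC content (default 0.40, a typical vertebrate value) with optional
planted features: CpG islands as 300 bp blocks whose token mixture yields
GC near 0.66 and a high CpG observed/expected ratio; tandem 9-mer repeat
runs (used to emulate repeat expansions in "inverted" species); and
non-overlapping gene intervals with strand. Islands and repeats replace
sequence and never overlap each other.

**The planted methylation code.** `planted_code()` assigns each 3-mer a
weight (centred Gaussian, default SD 60) and each locus a base methylation
probability `plogis(intercept + sum(w * f))` with `f` the locus's 3-mer
frequency vector. Because 3-mer frequencies of a 100-300 bp fragment vary
on the order of 0.01, the default weight SD spreads the fragment logits
over roughly ±3, giving the strongly bimodal fragment-level methylation
landscape seen in vertebrate RRBS data. Inverted species use sign-flipped
weights. An `mc_methylome` then adds, on the logit scale, tissue offsets
(SD 2) and individual offsets (SD 1) for randomly chosen effect fragments
(10% each by default), plus fragment-by-sample noise (SD 0.5). A per-CpG
jitter (SD 0.03, probability scale) decorrelates CpGs within a fragment
slightly.

**Reads.** `simulate_rrbs_reads()` emits single-end, directional reads:
the plus-strand prefix and the reverse complement of the suffix of each
digest fragment, `read_length` = 50 bp, Poisson `mean_coverage` (default
20) per fragment end. Converted libraries apply bisulfite chemistry per
cytosine: an unmethylated C reads T with probability `conversion_rate`
(default 0.99, typical RRBS efficiency) and a methylated C reads T with
probability `over_conversion` (default 0.005). CpG cytosines use the
planted fragment probability; other cytosines a non-CpG level (default
0.01, doubled in brain samples to emulate the elevated non-CpG methylation
of neural tissue). Two fixed 200 bp spike-in controls (one treated as
fully methylated, one as fully unmethylated) are mixed in at 0.1% — the
concentration used for RRBS conversion controls — and support conversion-
rate estimation. One unconverted library per species is emitted without
any conversion. CpG context is determined within the 50 bp read template;
a C in the last template position therefore has no recorded context and is
excluded from CpG statistics, a deliberate simplification. The same seed
and configuration give byte-identical FASTQ output.

The generator emulates restriction-site structure, bimodal
sequence-driven methylation, tissue/individual variance components,
conversion noise, and spike-ins. It does **not** emulate PCR duplicates,
quality-score decay, indels, polymorphism between individuals, or genome
assembly artifacts; pipeline performance on those aspects of real data is
out of the tests' reach.

`simulate_callset()` is a shortcut that draws per-CpG binomial counts
directly from the true methylome, bypassing reads; the statistical modules
are tested on both paths, while read-level properties (consensus recovery,
conversion-rate estimation) always use the full read simulator.

# In silico digest

`find_restriction_sites()` locates MspI (`CCGG`) and TaqI (`TCGA`) sites
(via `Biostrings::matchPattern`; N never matches). The cut is placed after
the first base of each site (C^CGG, T^CGA), matching the enzymes'
cleavage chemistry; the fragments between consecutive cuts — terminal
fragments included — are size-selected to 50-1000 bp (inclusive bounds),
and the first and last 50 bp of each retained fragment become the read
intervals. `element_coverage()` counts a CpG as covered iff it lies inside
any read interval; an element class with no CpGs yields a missing
fraction, not zero. All coordinates in the package are 0-based half-open;
promoters are TSS − 1000 bp to TSS + 500 bp on the gene's strand.
`concat_scaffolds()` reproduces the pseudo-chromosome construction
(round-robin into 20 chromosomes, 100 Ns between scaffolds) with an exact
bidirectional coordinate map.

# Reference-free consensus and calling

Reads from all samples are pooled and grouped into stacks by their
C-to-T-collapsed key; keys within Hamming distance 1 are merged in a
single pass (pigeonhole on the two key halves finds all candidate pairs),
the larger stack absorbing the smaller with deterministic tie-breaks, so
the construction is independent of read input order. Stacks below depth 5
are dropped as noise. The stack key is the consensus backbone over
{A, G, T}; at each backbone T a genomic cytosine is called iff the
unconverted members show C at frequency ≥ `tau_unconv` (0.5 — unconverted
evidence is authoritative) or the converted members show C at frequency ≥
`tau_meth` (0.1 — a cytosine visible through conversion is genuinely
methylatable rather than a sequencing error). Fragments are
single-stranded references: reads from the two strands form separate
stacks and CpG calls are not strand-merged, mirroring the reference-free
setting where strand pairing is unknown.

Calling assigns each sample's reads to fragments by collapsed-key lookup
(Hamming-1 rescue); at a consensus cytosine a read C counts methylated, a
read T unmethylated, and any other base is ignored. Per-read CpG state
vectors are retained for the erosion statistics. Contamination filtering
removes reads that align, bisulfite-aware and ungapped, to a decoy set at
a mismatch rate ≤ 0.1.

On a simulated 1 Mb genome at coverage 20 with perfect conversion, more
than 99% of consensus fragments equal a true fragment read verbatim and
per-CpG calls sit within three binomial standard errors of the planted
probabilities (the acceptance suite recomputes this).

# Methylation metrics and erosion

Aggregation is unweighted at every level — cytosine → fragment → sample →
species — and fragment methylation bins use `[0, 0.2)`, `[0.2, 0.8]`,
`(0.8, 1]` on fragments with at least 10 reads. The proportion of
discordant reads (PDR) classifies every read with ≥ 4 valid CpG
measurements, after discarding the first and last CpG on the read as
unreliable; a CpG's PDR is the discordant fraction of valid reads covering
it, and sample/species values are unweighted means. Under the null model
in which each of n CpGs on a read is independently methylated with
probability m,

$$\mathrm{E[PDR]}(m) = 1 - m^n - (1-m)^n,$$

which vanishes at m = 0 and 1, is symmetric about m = 0.5, and for n = 4
reaches its maximum 0.875 at 50% methylation — the analytic reference
curve for erosion analyses (`expected_pdr()`), reported by
`scripts/acceptance.R`.

# Sequence features and genome-wide models

K-mer spectra pool positions across fragments (per-fragment averaging is
not used; pooling weights long fragments proportionally to their
information content) and only fragments covered by the unconverted library
enter sequence analyses, since only those have fully recovered cytosines.
CpG islands follow the Gardiner-Garden (GC ≥ 0.50, obs/exp ≥ 0.6) and
Takai-Jones (0.55 / 0.65) criteria over 50 bp windows sliding by 1 bp
("stretches of 50 bp" is ambiguous; a non-overlapping step is available
via `step = 50`). K-mers are counted on the given strand only.

Genome-wide methylation is modelled as a function of these features by
ordinary least squares with the Wherry adjustment
$1-(1-R^2)(n-1)/(n-p-1)$ (the n − p − 1 denominator variant), Gaussian
AIC counting the variance parameter, and by phylogenetic GLS with
Brownian-motion covariance from the species tree (`nlme::gls` +
`ape::corBrownian`); on a star tree the GLS estimates coincide with OLS to
numerical precision, which the tests assert. Trees without branch lengths
receive unit lengths. Stepwise selection is the classic bidirectional
greedy AIC search from the intercept-only model with bootstrap stability
(percentage of resamples selecting each feature). Note that greedy AIC
with 64 candidates is liberal: under pure noise it still admits roughly a
dozen features per run, so stability scores separate planted from decoy
features by ranking rather than by an absolute threshold. Per-3-mer tests
are Bonferroni-adjusted across the 64 features.

# The locus-level methylation code

Fragments are discretized to `low` (< 20% in all samples) or `high`
(> 80% in all samples) at mean coverage strictly above 10 reads; a lenient
variant labels `low` on any sample. Class-balanced train/test sets of
2000 sequences (1000 per class, both classes shrunk together when one is
limiting) feed a linear SVM on k-mer frequency vectors — the primal form
of a spectrum-kernel SVM, fitted through a precomputed kernel
(`kernlab::ksvm`) with explicit weight extraction so every k-mer has an
interpretable, logo-ready weight. The frequency vectors are unit-norm
(cosine) scaled: with raw frequencies (vector norm around 0.1) the hinge
loss saturates inside the standard C grid {0.01, 0.1, 1, 10} and even a
perfectly separable motif problem is not learned; cosine scaling — the
normalized spectrum kernel — restores separability at C near 1 while
leaving the weight interpretation intact. Grid search covers C in
{0.01, 0.1, 1, 10} and k in 1..10 with stratified 10-fold
cross-validation maximizing AUC (ties prefer the smaller k, then the
smaller C). AUC uses the rank statistic with midranks, so
AUC(w) + AUC(−w) = 1 exactly.

Cross-species transfer trains in one species and tests, without
retraining, in another (features recomputed at the model's k); a species
is *inverted* when the mean off-diagonal AUC of its test column is
strictly below 0.45 (the column mean is used; the train-row mean is the
noted alternative). Differential 3-mer weights between a focal species and
its group use Wilcoxon tests with the top 10 reported, and the 9-mer
repeat analysis contrasts the frequency of tripled 3-mers between high-
and low-methylation fragments — the mechanism by which methylated repeat
expansions produce inversion in the simulator and, by hypothesis, in real
genomes.

# Tissue differential methylation

Variance decomposition computes, per eligible species (≥ 2 individuals,
≥ 2 tissues, a shared tissue, ≥ 50% CpG overlap between samples), the
mean squared Pearson correlation of fragment methylation between
same-tissue/different-individual pairs (tissue R²) and
same-individual/different-tissue pairs (individual R²); pairs sharing
fewer than 100 fragments are skipped (configurable).

Per-CpG tests between heart and liver are moderated t-tests: the pooled
two-group variance is shrunk toward an inverse-chi-square prior whose
scale s₀² and degrees of freedom d₀ are fitted across CpGs by moment
matching on log variances, giving
$s^2_{\mathrm{post}} = (d_0 s_0^2 + d s^2)/(d_0 + d)$ and a t statistic
with d + d₀ degrees of freedom; the implementation is the package's own
and is cross-checked in the tests against `limma::squeezeVar`. Fragment
p-values combine the per-CpG p-values by Fisher's statistic referred to a
scaled chi-square whose moments are corrected for the average within-
fragment correlation (Brown's method with the Kost-McDermott polynomial);
plain Fisher is available. Selection uses the combined-rank rule: ranks by
p-value, |relative difference| (denominator: the mean of the two tissue
means) and |absolute difference| are aggregated by their maximum
(configurable to the sum), and up to 500 fragments per direction passing
p < 0.05 and coverage ≥ 2 in both tissues are selected, ties broken by
fragment id.

Motif enrichment scans sequences with log-odds matrices against a 0-order
background estimated from all input; the hit threshold is the smallest
score whose *exact* null exceedance probability (dynamic programming over
the score distribution, scores held at a fixed 10⁻³ resolution so the DP
is exact for the matrix actually scanned) is at most 10⁻⁴ per window;
sequence-level hits feed a one-sided Fisher exact test, BH-adjusted across
motifs and directions. Note the resolution of the null: motifs shorter
than 7 bp cannot reach a 10⁻⁴ window probability and therefore can never
produce hits at the default threshold. Transcription factor activity
combines significant enrichments with methyl-binding preference and
expression (> 1 in heart or liver), requiring at least 10 significant
enrichments per species before any call is made.

# Gene-centric analyses

Cross-mapping aligns consensus fragments to candidate genomes with an
ungapped 11-mer-seeded search on both strands; the best placement must
satisfy a mismatch rate ≤ 0.2 and ties between equally good placements
leave the fragment unmapped rather than randomly placed. Gene profiles
average calls in 100 bp bins across ±5000 bp flanks and 200 bp bins in
the body; for the meta-gene average the variable body bins are rescaled
onto 20 relative positions. Promoter methylation is the mean over 50 bins
of 50 bp spanning 2500 bp upstream of the TSS, strand-aware; bins without
data are skipped, not imputed. The promoter matrix re-keys genes to human
orthologs through the two NCBI dictionaries, averaging source genes that
share an ortholog and keeping missingness explicit.

For the joint embedding the rows are correlated on pairwise-complete
observations (iteratively dropping the worst row until no correlation is
undefined), connected into a k-nearest-neighbour graph (20 neighbours for
samples, 15 for genes), laid out in 2-D by force-directed placement and
clustered by Leiden community detection at resolution 0.06. This is a
deliberate design choice: the contract is a neighbourhood-graph embedding
with communities, and the kNN-graph + force-directed layout delivers it
with the graph machinery already underlying the clustering; parameters
specific to other embedding algorithms (minimum distance, spread) have no
analogue here and are not exposed. The scrambled control permutes the
non-missing values over the non-missing positions, preserving the
missingness mask exactly.

Species-held-out classification predicts a binary sample property from
promoter methylation with a bagged ensemble of `rpart` trees; surrogate
splits route missing values natively, so no imputation is performed. Genes
must cover ≥ 60% of samples and samples ≥ 12% of genes; train and test
never share a species; repetitions with a one-class test set are redrawn;
and the scrambled control runs the identical procedure on the permuted
matrix.

# Numerical conventions and degenerate inputs

* Coordinates: 0-based half-open everywhere; BED native, GFF converted on
  read.
* Ties: consensus tie-breaks by fixed base order A < C < G < T; stack
  merging by depth then lexicographic key; grid search by smaller k then
  smaller C; DMR selection by fragment id.
* Ratios with empty denominators are missing (`NA`), never zero: empty
  element classes, fragments with no covered cytosines, obs/exp without
  C or G.
* p-values of exactly 0 are clipped to 1e-300 before log-combination,
  with a warning.
* Seeds: every stochastic routine takes a seed and restores the caller's
  RNG state, so the pipeline is reproducible end to end.

# Problem sizes in the test suite

The validation suite generates its data at desk scale, chosen as the
smallest sizes at which the statistical properties under test are stable:
a 1 Mb genome at coverage 20 for the reference-free round trip; 1000
random 10 kb sequences for the digest oracle; balanced sets of a few
hundred to 2000 sequences for the classifier checks (100 seeds for the
permutation null, 100 replicates of an 8-species panel for inversion
detection); a 64-leaf tree with 100 Brownian replicates for the
phylogenetic regression; 5000 fragments for the type-I-error check of the
differential stack; and 40 species for the held-out promoter classifier.

# Known limitations

* The aligner used for decoy filtering and cross-mapping is ungapped;
  indels are out of scope at 50 bp read length.
* Consensus construction is a simplified reimplementation of the
  reference-free contract (collapsed-key stacks, single merge pass); it
  does not reproduce any external tool's internal heuristics.
* Greedy AIC stepwise selection over many candidates overfits under the
  null; interpret stability scores comparatively.
* The sliding-window island criteria are sensitive to the window step;
  the default step of 1 bp is the most permissive reading.
* Non-CpG methylation is simulated as a uniform per-tissue level, not as
  a sequence-dependent signal; tests of the brain excess therefore only
  exercise the statistics, not a biological mechanism.
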