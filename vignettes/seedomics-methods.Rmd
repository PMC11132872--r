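---
title: "Models and methods behind seedomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind seedomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seedomics` dissects the shared genetic architecture of two correlated
quantitative traits from population genotypes and seed transcriptomes.
This vignette explains the models, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where the
methodology left room.

## The mixed-model association layer

Every association scan — trait GWAS, per-gene eQTL scans, and module
eigengene GWAS — uses one engine: for a phenotype $y$ and a variant
dosage $x$,

$$ y = \mu + x\beta + g + \varepsilon,\qquad
   g \sim N(0, \sigma^2_g A_{\mathrm{LOCO}}),\quad
   \varepsilon \sim N(0, \sigma^2_e I), $$

where $A_{\mathrm{LOCO}}$ is the standardized-dosage genomic relationship
matrix built from every chromosome except the tested variant's
(leave-one-chromosome-out), which prevents the tested signal from being
absorbed into the polygenic term. Variance components are estimated once
per chromosome by REML on the null model: the GRM is eigendecomposed,
the restricted likelihood is a one-dimensional function of the variance
ratio $\delta = \sigma^2_e/\sigma^2_g$ on that basis, and it is profiled
by golden-section search over $\log\delta \in [-10, 12]$ (tolerance
1e-8). Each variant is then tested by generalized least squares at the
fitted components, vectorized over all variants of a chromosome; p-values
are Wald $\chi^2_1$. Fitting components once per chromosome rather than
per variant is the behaviour of the standard MLM-association tools; a
`per_variant_reml` flag re-estimates them per variant, in which case an
identity GRM reproduces ordinary least squares exactly (this is an
oracle equivalence the test suite checks at 1e-6 relative tolerance).

Non-positive-definite GRMs (inevitable when accessions outnumber
retained variants) are ridge-regularized by `|min eigenvalue| + 1e-6`
with a logged message. Monomorphic variants are flagged and carry `NA`
statistics. Missing dosages are mean-imputed everywhere (PCA, GRM, GLS):
imputation to the variant mean preserves allele frequencies and
contributes zero deviation to relationship estimates.

The genome-wide threshold is an effective-test Bonferroni correction:
per chromosome, non-overlapping windows of 200 variants are
eigendecomposed and the number of leading eigenvalues reaching 99.5% of
the trace is summed (a simpleM-style count). The cited methodology used
a dedicated tool for this; only the resulting threshold is consumed
downstream, so an eigenvalue-based count with the same contract stands
behind the same interface.

Result clumping is the greedy PLINK procedure: the most significant
unassigned variant with $p \le p_1$ seeds a locus and absorbs unassigned
variants with $p \le p_2$ (default 0.01) within 500 kb and $r^2 \ge 0.5$;
ties on $p$ break deterministically by (chromosome, position).

## Bivariate REML genetic correlation

The two-trait model stacks both phenotypes with genetic and residual
covariance matrices $V_g, V_e$ (2×2) and a shared GRM. On the GRM
eigenbasis the covariance of each rotated observation pair is the block
$d_i V_g + V_e$, so the exact restricted likelihood costs $O(n)$ per
evaluation. It is maximised over log-Cholesky parameters of $V_g$ and
$V_e$ (Nelder–Mead then BFGS, three starts: an even split of the
phenotypic covariance and two extreme splits, keeping the best optimum —
the duplicated-trait boundary case $r_g = 1$ otherwise traps a single
start). The reported
$r_g = V_{g,12}/\sqrt{V_{g,11} V_{g,22}}$ gets a standard error from the
inverse numerical Hessian by the delta method. This is the same
estimator as average-information REML iterations, maximised by a
quasi-Newton optimizer instead; at these sample sizes (hundreds of
accessions) it is robust to the variance-boundary cases that AI updates
handle awkwardly.

## eQTL mapping, classification, hotspots

Expression is filtered (TPM $\ge$ 5 in at least 5% of accessions;
95th/5th percentile ratio $\ge$ 2, a zero 5th percentile passing) and
each gene quantile-normalised to $\Phi^{-1}((\mathrm{rank}-0.5)/n)$ with
average ranks for ties, then scanned with the engine above. The calling
chain per gene: keep $p < 10^{-4}$; clump at $r^2$ 0.2 within 250 kb;
retain leads with $p < 1/m$ ($m$ = variant count) and at least 2 LD
proxies; merge a gene's leads that sit in one LD block, represented by
the most significant lead. Two readings of the proxy rule ("more than
two LD proxies") exist; the default is $\ge 2$ non-lead clump members,
with `strict_proxies = TRUE` for the literal $> 2$. Block membership for
merging is decided by the pairwise D′ confidence-interval criterion
between the leads themselves (strong LD: CI lower bound $\ge$ 0.70 and
upper $\ge$ 0.98, within 5 Mb) — equivalent in effect to asking whether
a full block detection would place them together, and far cheaper than
computing genome-wide blocks per gene. The full Gabriel-style block
scan, with EM haplotype-frequency estimation on unphased genotype pairs
and a likelihood-profile CI on a 0.01-spaced D′ grid, is exported
separately (`detectLDBlocks`) and validated on planted high-LD segments.

Local vs distal classification measures the distance from the lead to
the gene span (zero inside the span, otherwise the gap to the nearer
edge); same chromosome and distance $\le$ 1 Mb, boundary inclusive, is
local. A TSS-distance mode is available.

Hotspots: 1 Mb windows sliding by 100 kb count *distinct* distal eGenes
whose lead falls in the window. The null relocates every distal lead
uniformly within its chromosome (per-chromosome counts preserved, eGene
links kept), records the genome-wide maximum window count per
permutation, and takes the $1-\alpha$ empirical quantile
(`sorted[⌈(1−α)n⌉]`, so a brute-force recomputation with the same seed
matches exactly). Windows must *strictly* exceed the threshold —
a count equal to the threshold does not pass — and overlapping flagged
windows are merged into one hotspot (the merge is a package choice; the
flagged-window set is also returned unmerged). The same
max-statistic permutation logic, with random gene sets in place of
shuffled positions, powers the module-level distal-regulation test.

Open-chromatin enrichment relocates OCR intervals uniformly per
chromosome with lengths preserved, retrying up to 10 times to avoid
overlap among relocated intervals before accepting; the empirical
p-value uses the add-one estimator $(1 + \#\{null \ge obs\})/(B+1)$.

## ICA coexpression modules

The centered, per-gene standardized expression matrix (genes ×
accessions) is decomposed by fastICA with the logcosh contrast and
symmetric decorrelation, treating genes as observations of independent
component weights — the right orientation for module discovery, where a
component's gene-weight vector is sparse (non-Gaussian) and its mixing
row is the per-accession eigengene. The component count is the smallest
number of principal components explaining 70% of the variance
(`var_cutoff`). Each of `n_runs = 15` restarts iterates the fixed point
to convergence (tolerance 1e-4, up to 200 iterations), re-initializing
up to `max_iter = 10` times if it fails to stabilize. Components are
matched across runs to the first run by absolute gene-weight
correlation (greedy on the correlation matrix), sign-aligned, and
averaged **only over runs matching at $|r| \ge 0.8$** — averaging in
unconverged restarts demonstrably corrupts converged components — with
the unfiltered mean matched $|r|$ reported as a per-component stability
index. Signs are fixed so weight skewness is positive; membership is
$|w| > 2$ SD of that component's weights (the source study reports
module sizes but not its membership rule; 2 SD is a documented default,
not an inference). Eigen-expression is the least-squares factor profile
given the averaged weights, standardized.

Submodule partition builds a gene graph with edges where Spearman
$\rho \ge$ `corr_min` (0.3) weighted by $\rho$, and runs Louvain at
resolution 1 with a fixed seed; communities under 5 genes merge into the
community with the strongest mean edge weight to them. Edges use
*positive* correlations by default: submodules in seed coexpression
modules are sign-coherent (one negatively, others positively
trait-correlated), and absolute-value edges would glue anti-correlated
groups into one community. An `use_abs` flag restores |ρ| connectivity.

Promoter motif enrichment scans 2 kb strand-aware promoters with
log-odds PWMs on both strands; a promoter is a hit when its best score
reaches the threshold whose exact per-position tail probability under
the 0-order background is $\le 10^{-4}$, computed by discretized
dynamic-programming convolution of the score distribution (scores
rounded at 0.01 resolution). Enrichment is a one-sided hypergeometric
of hit-bearing promoters, module against the background universe (which
should contain the module), BH-corrected across motifs. Promoters
shorter than the motif count as no-hits.

## TWAS

Genes pass a cis-heritability gate: single-component REML on the
cis-variant GRM (gene span ± 500 kb, at least 30 cis variants) with a
likelihood-ratio test against $h^2 = 0$ using the boundary-corrected
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ mixture; the null likelihood is the
analytic $\delta \to \infty$ limit of the alternative, so the LRT is
never negative. Expression weights come from four models on standardized
cis dosages — top1 (the most significant variant's marginal
coefficient), BLUP (ridge with $\lambda = m\hat\delta$ from the cis
REML), lasso and elastic net (mixing 0.5, penalty by internal CV) — each
scored by 5-fold cross-validated $R^2 = 1 - SSE/SST$ with folds shared
across models; the best model is refit on all data, and genes where no
model predicts (all cv $R^2 \le 0$) are dropped. The Bayesian sparse LMM
variant of the weight ensemble is deliberately omitted: lasso/enet cover
the sparse architectures, and model selection by cv $R^2$ keeps the
ensemble's contract.

The association statistic is
$z = w^\top z_{\mathrm{gwas}} / \sqrt{w^\top R w}$ with $R$ the LD
correlation of the weighted variants in the reference genotypes. $R$ is
ridge-regularized as $\mathrm{cov2cor}(R + 0.1 I)$ — rescaling to unit
diagonal keeps the single-indicator case exact (a top1 gene reproduces
its variant's GWAS z), which a bare ridge would break. Candidates
require $|Z| \ge 3$; when an eGWAS Z is supplied the rule is applied
jointly by default, per the source methodology's phrasing, with a flag
for the alternative reading.

## Selection scans and haplotype spectra

Windowed diversity is the unbiased per-site heterozygosity
$2p(1-p)\,n/(n-1)$ (allele count $n$) summed per window and divided by
the full window length — the convention of the standard windowed-π
tools — not by callable sites. π-ratio scans exclude 0/0 windows, cap
$x/0$ at the largest finite ratio (flagged), and set the sweep threshold
at the top-`top_frac` genome-wide quantile by sort-and-index, so the
threshold is exactly reproducible. F_ST is Weir–Cockerham: per-site
variance components $a, b, c$ aggregated per window as
$\sum a / \sum(a+b+c)$, negative aggregates reported as computed.
Haplotype spectra concatenate alleles at the defining variants into two
phase-free pseudo-haplotypes per accession (one carries the alternate
allele where dosage $\ge 1$, the other where dosage $= 2$); frequencies
are phase-invariant, and in the near-homozygous panels the generator
produces the two pseudo-haplotypes almost always coincide. Accessions
missing any defining genotype leave that panel's denominator.

## The synthetic-data generator

The generator is the package's validation instrument: every statistical
structure the analysis assumes is planted with known parameters and
recorded in a `TruthTable`.

* **Population structure**: Balding–Nichols allele frequencies around
  ancestral frequencies drawn above `maf_floor`, for `n_subpops`
  subpopulations at `target_fst`. Both the ancestral and the
  subpopulation frequencies are spatially autocorrelated along the
  chromosome (Gaussian copula through the Beta marginals, decay twice
  `ld_decay_bp`): without that, independently drawn marginal frequencies
  bound the achievable r² between linked variants and the LD-dependent
  machinery (clump proxies, blocks) has nothing to work with.
* **LD**: haplotypes threshold a latent AR(1) Gaussian process whose
  autocorrelation decays as $\exp(-d/\texttt{ld\_decay\_bp})$. The
  default decay scale (300 kb) and density (~33 variants/Mb over 5 × 30
  Mb chromosomes) give nearby-variant r² around 0.4–0.5 and 2–5 clump
  proxies per signal — chosen once for a selfing crop with long LD and
  for the proxy-retention rules to be exercised at desk scale, not
  inferred from any particular data set.
* **Inbreeding**: accessions carry two copies of one founder haplotype
  (dosage = 2 × haplotype) with a small residual per-genotype
  heterozygosity (`het_rate` 0.5%). The 2%-heterozygote site filter only
  makes sense for a selfing panel; an outbred generator would see almost
  every site dropped.
* **Expression**: log-scale sum of a gene baseline (8% of genes set low
  to exercise the TPM filter), planted local-eQTL effects at variants
  with MAF ≥ 0.15 within 100 kb of the TSS (common variants, so the
  proxy rule is tested rather than defeated), hotspot-regulator effects
  on ≥ `genes_per_hotspot` genes all > 1 Mb away, skewed (non-Gaussian)
  module latent factors, and Gaussian noise — exponentiated to
  pseudo-TPM.
* **Trait architecture**: per-variant effects for the two traits are
  bivariate normal with correlation `trait_rg` (default 0.39, the kind
  of positive seed-weight/oil correlation the motivating system shows);
  genetic values are scaled to `trait_h2` (0.7, 0.5) and yearly
  environmental noise added, with BLUEs as the per-accession means. When
  a `TruthTable` is supplied, hotspot regulators receive major same-sign
  effects on both traits with a fixed variance share (effect
  $9/\mathrm{sd}(x)$, about a fifth of the genetic variance — a major
  pleiotropic domestication locus), and a few local eGenes are promoted
  to expression-mediated trait genes (effect $4.5/\mathrm{sd}(x)$
  aligned with the expression effect), recorded as mediators for TWAS
  scoring. Note the realized total $r_g$ then exceeds the polygenic
  `trait_rg`, since the planted major loci are fully shared.
* **Panels**: wild/landrace/cultivar panels share one variant set with
  increasing Balding–Nichols divergence (F = 0.02/0.10/0.15); in one
  region the wild panel's minor-allele haplotype is swept to target
  frequencies (0.3/0.8/0.95), with the replacement rate calibrated
  against each panel's baseline carrier frequency so realized
  frequencies hit their targets in expectation, and flanking diversity
  collapses in the later panels.

What the generator does **not** emulate: sequencing reads and genotype
likelihood errors beyond the GQ/DP injection, indels and multiallelic
realism (the VCF fixtures are biallelic SNPs; multiallelic splitting is
tested on hand-written records), demographic history (no drift
trajectories, bottlenecks or migration), dominance and epistasis,
expression count noise (pseudo-TPM is lognormal, not a count model), and
batch structure. Passing parameter-recovery tests therefore shows the
estimators are correct under their assumptions, not that real data meet
those assumptions.

## Problem sizes and reproducibility

The validation suite runs studies of 300 accessions × 3,000 variants ×
300 genes (recovery of planted local eQTLs, hotspots, dual-trait
modules and TWAS mediators), 400 × 1,500–2,000 for genetic-correlation
recovery, and 200-accession panels for the sweep scans — sizes chosen so
the whole suite completes in minutes on one CPU while leaving each test
adequately powered. All generator output is a pure function of the
configuration including its seed; permutation nulls take explicit seeds
and their thresholds are reproduced exactly by brute-force replay, which
the tests do. The pipeline derives per-stage seeds from the global seed
by a stable hash so stages are independently reproducible.

## Known limitations

* The per-chromosome (rather than per-variant) variance components make
  the usual MLM approximation; the exact mode exists but is slow.
* D′ confidence intervals use a likelihood profile over a 0.01 grid;
  very small samples can make the CI bounds grid-coarse.
* The eQTL lead-merging step tests strong LD between leads directly
  instead of embedding them in full Gabriel blocks; leads bridged only
  through intermediate markers are not merged.
* `bivariateGREML` constrains estimates through the Cholesky
  parametrization, so $|r_g| \le 1$ by construction; boundary solutions
  show up as near-singular Hessians and a missing standard error rather
  than as constraint violations.
* Motif scanning assumes a 0-order background; promoters with strong
  composition bias will mis-calibrate the hit threshold.
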