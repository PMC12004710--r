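---
title: "Models and methods of the nmibcGenomics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the nmibcGenomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models the package implements, the
parameters that matter and their defaults, the design decisions taken where
the methodology is genuinely open, what the synthetic-cohort generator does
and does not emulate, and the package's known limitations. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

# The data model

A cohort binds five validated tables — somatic mutations (MAF-like),
allele-specific copy-number segments (ASCAT-style), purity/ploidy profiles,
clinical records, and gene-role annotations — plus an optional expression
count matrix, into an `NmibcCohort` S4 object. Coordinates are 1-based,
fully closed intervals for both mutations and segments (the ASCAT
convention). The normal copy number is fixed at 2 for autosomes; sex
chromosomes are retained at ingest but excluded from mutation timing and
wGII by default (`include_sex`/analysis flags override). Unknown
consequence strings map to `"other"` with a warning rather than an error,
because upstream annotators disagree on vocabulary and a hard failure would
discard otherwise valid rows.

# Temporal dissection of mutations

For a mutation with variant allele fraction $f$ in a tumor of purity
$\rho$ on a segment of total copy number $CN_t$, the mutation copy number
is

$$ c = f \cdot \frac{\rho\,CN_t + 2(1-\rho)}{\rho}, \qquad
   m = \mathrm{round}(c) \text{ clipped to } [1, \text{major}], \qquad
   \mathrm{CCF} = \frac{c}{m}. $$

The 95% CI on CCF is the exact Clopper–Pearson binomial interval on $f$
(from the alt/ref read counts) pushed through the same linear map; the
exact binomial interval was chosen because published cohort analyses of
this kind rarely name their CI procedure and the exact interval is
assumption-free at WES depths. A
mutation is **clonal** when the uncapped CI overlaps 1 (equivalently, its
upper bound reaches 1), **subclonal** otherwise. Reported CCFs are capped
at 1; clonality always uses the uncapped interval. Depth below 8 reads
sets a wide-CI flag.

**Early/late.** Subclonal mutations are late. Clonal mutations on segments
with major allele $\geq 2$ are *early* iff the mutation copy number
exceeds 1, and here the integer multiplicity $m$ — not the continuous
estimate $c$ — carries the decision: for a true single-copy mutation $c$ is
centred exactly on the boundary value 1, so a rule on the continuous
estimate degenerates to a read-noise coin flip, whereas $m$ is the natural
estimator of the discrete quantity ("on how many copies does the mutation
sit") that the early/late logic refers to. Clonal mutations on major
$< 2$ regions default to *early*: in cohorts of this type the early+late
totals essentially exhaust all mutations, implying un-amplifiable clonal
events were kept with the early clonal class; `strict_timing = TRUE`
labels them `untimeable` instead. Mutations with no covering segment or
with total copy number 0 are `untimeable` and counted.

**Early enrichment.** Per gene with at least 3 timed mutations, the early
ratio is compared with ratios of equally sized draws from the cohort's
timed non-gene mutations; $p = (1 + \#\{\text{perm} \geq \text{obs}\}) /
(n_{perm}+1)$ with BH adjustment across tested genes. The permutation seed
is mandatory.

# Genome instability

* **wGD method 1:** length-weighted genome fraction with major allele
  $\geq 2$; wGD iff $\geq$ 50%.
* **wGD method 2:** each autosomal arm is summarized by its
  length-weighted modal (major, minor) state; wGD iff arms with modal
  major $\geq 2$ cover $\geq$ 50% of the autosomal arm length *and* ploidy
  exceeds 2.5. The published probability model this stands in for is
  under-specified; the ploidy gate bounds false positives from
  arm-level 2+0 states in diploid genomes.
* A sample is **wGD** only when both methods agree (the AND rule).
* **wGII:** length-weighted fraction of the autosomal genome whose total
  copy number differs from the rounded ploidy; **CIN** iff wGII > 0.2.
  Whether the source methodology counts total-CN or allele-specific
  aberrations is unstated; total-CN is the default, `allele_aware = TRUE`
  switches to the balanced allele-specific comparison. wGII is invariant
  to splitting segments, which the tests assert.
* **TMB:** nonsynonymous mutations (missense, nonsense, splice, indel) per
  megabase of exome (`exome_size_mb`, default 30 for real cohorts; the toy
  cohorts use their actual coding footprint).
* **Hypermutation:** samples are ranked by TMB in descending order and the
  gap to the next sample computed; the cut sits at the maximal gap within
  the top quartile of ranks, and samples above it are flagged. Restricting
  to the top quartile prevents a mid-distribution gap from flagging half
  the cohort; a zero maximal gap flags nobody.

# Mutational signatures

Spectra use the 96 pyrimidine-centred trinucleotide channels in the
conventional order (six substitution classes, 5' then 3' flank). Exposure
fitting is maximum-likelihood EM for a multinomial mixture with the
catalog's signature columns as fixed components; iteration stops when the
relative log-likelihood change falls below $10^{-8}$ (cap 10,000
iterations), and the log-likelihood is non-decreasing at every step
(asserted in tests). A signature is **present** when it accounts for at
least 10 mutations (counts rounded half-up) and at least 5% of the
sample's total. Early and late spectra are fitted separately with the same
rule.

De novo extraction replaces a hierarchical Dirichlet process sampler with
Brunet KL-NMF over the cohort spectra plus cosine matching of each
component to the catalog: the published signatures are ultimately reported
as catalog (COSMIC) entities, and the HDP machinery is orthogonal to that
end point. The bundled catalog is **synthetic** — four 96-channel vectors
imitating the channel concentrations of SBS2 (APOBEC C>T at tCw), SBS5
(flat, clock-like), SBS13 (APOBEC C>G) and SBS22 (aristolochic acid T>A) —
so that no external download is required; real COSMIC v3.3 TSVs are read
by the same `readSignatureCatalog()`.

**APOBEC enrichment.** Per sample, over C>T and C>G SNVs at cytosines
(G-reference mutations reverse-complemented):
$E = (\text{mut}_{tCw}/\text{mut}_C) \,/\,
(\text{ctx}_{tCw}/\text{ctx}_C)$, where the context counts come from the
reference sequence in ±20 nt windows around each mutated cytosine, with
motifs counted on both strands and with overlaps. Reference windows (not
sample consensus) are used — the sample consensus is unavailable from a
mutation table alone. Significance per sample is Fisher's exact test on
the 2×2 table, BH across samples; the APOBEC load is
$\text{mut}_{tCw} \cdot \max(0, (E-1)/E)$ and samples split into
none (q ≥ 0.05) / low / high at the median load of the significant
samples. The exact published three-level binning is unstated; this
quantization is the package's own and is labelled in the output.

# Selection (dN/dS)

Opportunities are enumerated per gene: every possible single-base change
of the in-frame CDS is classified against the genetic code and weighted by
a rate model of 6 pyrimidine substitution types × CpG flag — a deliberate
simplification of full 192-rate covariate models, sufficient for the
timing odds-ratio logic at toy scale and estimated from synonymous sites
(uniform by default; strata with no observations keep rate 1 after
rescaling to mean 1). dN/dS for a class is
$(n_c/L_c)/(n_s/L_s)$; conditional on the total count the class count is
binomial, so the exact Clopper–Pearson interval on the binomial
probability transforms into the CI for the ratio of Poisson rates. Zero
synonymous counts flag the estimate unstable rather than silently
producing an infinite CI. The point-mutation class combines missense,
nonsense and splice; the toy gene models are single-exon, so splice
opportunities are zero there and the combined class reduces to
missense+nonsense. q-values are BH within each stratum.

The timing odds ratio is $\mathrm{OR} = \omega_{early}/\omega_{late}$ with
early-favored iff OR > 2 and late-favored iff OR < 0.5; ORs are reported
for scopes reaching q < 0.1 in either stratum, and an unstable late
estimate makes the OR not evaluable. Pathway estimates pool member-gene
counts and opportunities before estimation, so a one-gene pathway equals
that gene's estimate exactly.

# Recurrent CNAs (GISTIC-like)

Segments become events when $|\log_2(CN/\text{ploidy})| \geq 0.25$ (CN 0
capped at $\log_2(0.5/\text{ploidy})$); abutting same-direction runs merge;
arms with qualifying coverage $\geq 0.75$ of their length yield broad
(arm-level) events and the rest are focal. Recurrence significance scores
each genomic bin (default 10 kb) as the sum of event amplitudes over
samples, against a null that circularly shifts each sample's amplitude
track along the concatenated genome — per-sample event counts, sizes and
amplitudes are preserved exactly. Empirical p per bin and direction, BH
within direction, q < 0.1 significant. The semi-parametric background and
peel-off of the original tool are not reproduced; outputs are labelled
GISTIC-like and locus lists will differ from GISTIC2.

# Event dependencies (DISCOVER-like)

The binary event matrix joins driver-gene mutation flags (restricted to
the driver catalog), significant focal/broad CNA indicators, signature
presence and the wGD/CIN/hypermutation/APOBEC flags, then drops events
below 10% cohort frequency (or constant). The null for pair testing
preserves both margins exactly: curveball trades (burn-in 10× the number
of 1-entries, then `n_perm` sampled matrices) — the same null concept as
the analytic Poisson-binomial background it stands in for, with per-sample
event loads respected. One-sided empirical p in each direction; the
reported direction is the sign of observed-minus-expected overlap and BH
runs within direction (the one- vs two-sided FDR pooling is unstated in
the source methodology). Early→late ordering interactions use Fisher's
exact test on the 2×2 of early × late presence, with the raw OR reported
as infinite when a cell is zero and the Haldane–Anscombe (+0.5) corrected
OR alongside.

# NMF subtyping

The subtyping matrix is the frequency-filtered event matrix plus the
significant CNA indicators, deduplicated by name. Factorization is Brunet
KL-NMF (multiplicative updates, relative KL tolerance $10^{-6}$, cap 5,000
iterations, best of ≥ 30 restarts; the objective is non-increasing per
iteration and asserted). Samples are assigned by the argmax of their
coefficient column *after* rescaling rows of H by the basis column sums —
assignment must not depend on the arbitrary scale split between W and H —
with ties to the lowest factor index.

**Rank selection.** For each candidate rank the restart-consensus matrix
and its cophenetic correlation are computed. On binary event matrices the
consensus is frequently near-perfect for several *nested* partitions at
once — merging two related groups is exactly as reproducible as splitting
them — so the cophenetic maximum alone reduces to third-decimal noise. A
rank is therefore *supported* when the KL reconstruction-error curve has a
genuine elbow there (the error drop gained by its last factor is at least
1.7× the drop the next factor would add) and its consensus is stable
(cophenetic ≥ 0.95); the largest supported rank — the finest resolution
the error curve supports — is selected, falling back to the cophenetic
maximum (ties to the smaller rank) when no rank is supported, with a
structureless-matrix warning when no rank reaches cophenetic 0.9. The
elbow margin 1.7 is a design constant: on structureless matrices
consecutive error drops decay smoothly with ratios near 1.2–1.5, while a
resolved block of samples adds a distinctly larger drop.

Subtype characterization is one-vs-rest Fisher's exact test per binary
feature with BH within feature family, and a Kruskal–Wallis rank-sum
comparison of TMB across subtypes; subtypes smaller than 3 samples are
flagged but reported.

# Expression scoring

Counts are normalized by median-of-ratios (DESeq-style size factors,
deterministic). The subtype marker ranker is a one-vs-rest Wilcoxon
rank-sum test with a shrunken log2 fold change
($\log_2((\mu_{in}+c)/(\mu_{out}+c))$, $c = 5$): top 30 genes by BH
adjusted p, split into up/down sets by fold-change sign. This deliberately
stands in for a negative-binomial DE fit — DE machinery is off-the-shelf
and not this package's contribution — and externally computed DE tables
can be substituted. Gene-set scores are rank-based single-sample
enrichment (ssGSEA-style weighted running sum, exponent 0.25 on
within-sample ranks), linearly rescaled to [−1, 1] across the cohort;
being rank-based they are invariant to any monotone within-sample
transform, which the tests assert. The subtype score is the up-set score
minus the down-set score (exactly antisymmetric under swapping the sets)
and is dichotomized at the cohort median for survival validation. Bundled
marker panels (basal, luminal, p53, stroma, inflammation, claudin-low,
immune checkpoint, interferon, BCG response) are short canonical gene
lists and fully configurable; the BCG-response panel in particular is a
representative immune-effector list, not the published proprietary
signature.

# Clinical statistics

The two-cohort comparison applies the two-sided Fisher exact test (sum of
hypergeometric probabilities ≤ the observed table's — the convention of
standard statistical software, stated here because two-sided conventions
differ) per gene with BH adjustment and an adjusted-p < 0.1 significance
cutoff; the bundled count table carries the published European (n = 127)
vs Chinese (n = 58) Ta-stage counts, whose adjusted values were computed
from unrounded p-values. Cox, Kaplan–Meier/log-rank and logistic models
delegate to the survival package and `stats::glm`; variance inflation
factors are computed directly from the definition ($1/(1-R^2)$ of each
column on the others) and any multivariable Cox model with a VIF ≥ 5 is
rejected with the offending variables named.

# The synthetic-cohort generator

The generator's defaults are the study conditions the tests and the
acceptance script run under: 10 samples per archetype; purity uniform on
[0.2, 0.9]; negative-binomial depth (mean 150, size 8, WES-like
overdispersion); one subclone per sample with CCF uniform on [0.15, 0.6]
carrying 25% of mutations; expected burdens 600/80/120/200 for the
AA-like / FGFR3-HRAS / FGFR3-chr9del / GI archetypes (the AA-like burden
is ≥ 5× the FGFR3/HRAS burden, reflecting AA-driven hypermutation);
archetype signature mixtures over the bundled catalog (AA-like 65% SBS22;
the others APOBEC/clock mixtures, with the chr9del SBS22 share kept below
the presence rule so SBS22 presence stays confined to the AA-like class,
as reported cohorts show). Copy-number archetypes: flat 1+1; chr9 p+q loss
(1+0) with a frequent focal CDKN2A deep deletion; and a tetraploid 2+2
baseline with random arm states plus focal E2F3/CCND1 amplifications and
an RB1 deep deletion. Read counts are binomial around
$m\rho\,\mathrm{CCF}/(\rho CN_t + 2(1-\rho))$; trinucleotide contexts are
drawn from the mixture and placed at matching positions of a deterministic
toy genome (10 chromosomes, 1 Mb total, GC 0.45, p-arm = first 40%);
consequences come from the actual codon change of ~150 planted single-exon
genes read in frame. Driver events are planted per archetype at fixed
per-gene probabilities chosen to echo the published cohort frequencies
(e.g. FGFR3 dominating both FGFR3 subtypes, PIK3CA ≈ 19% cohort-wide,
LATS1/CDKN1A/ZFP36L1 in the hypermutated class); these are
order-of-magnitude design choices exposed in the config, not claims about
any real cohort. Expression counts are negative-binomial with planted
per-archetype marker genes and panel-linked effects; recurrence outcomes
are exponential with configurable log hazard ratios (default: log 2 for
CIN). Every emitted mutation has exactly one truth row, and identical
seeds give bitwise-identical emitted files.

**What the generator does not emulate:** chromatin/replication-timing
covariates of mutation rate, indel signatures, multi-region or multifocal
sampling, subclonal copy number, transcription-strand bias, germline
contamination, and realistic linkage between expression and genotype
beyond the planted effects. Passing tests therefore demonstrate that the
estimators recover the model they assume — not that the model captures
every property of real tumors.

# Numerical choices and degenerate inputs

Permutation p-values always use the add-one form, so their floor is
$1/(n_{perm}+1)$ — q-values near a threshold need enough permutations.
EM and NMF guard divisions with $10^{-12}$-scale epsilons; NMF inputs must
be non-negative and EM of an all-zero spectrum returns zero exposures with
nothing present. Gene-set scores of a set equal to the whole matrix are
constant by definition and returned as exact zeros. Fisher tables with a
zero cell report an infinite raw OR plus the corrected one. CN-0 segments
cap the log ratio at $\log_2(0.5/\text{ploidy})$. All seeds derive from a
single user seed through a fixed linear-congruential child-seed map kept
below $2^{31}$.

# Problem sizes used by the tests

The bundled suites run at the scale the generator's defaults define: 40
samples for timing/subtyping recovery, 50 samples per class for wGD
separation, 5,000 mutations × 100 replicates for dN/dS calibration, 500
samples for the Cox hazard-ratio recovery, and 200 replicates of 50 × 20
matrices for the dependency type-I check. These sizes were chosen so that
each property is measured with comfortable statistical margin on a single
CPU.

# Limitations

Upstream read alignment, variant calling, ASCAT itself, expression
quantification and the original MutSigCV/dndscv/GISTIC2/DISCOVER/GSVA
implementations are out of scope; the built-in stand-ins share each
method's null concept but will not reproduce those tools' outputs
numerically. The bundled signature catalog is synthetic. Cohort-specific
published results (subtype memberships, specific enrichment ORs, hazard
ratios) depend on non-public patient data and are not reproduction
targets; the package's claims are the exact published cross-cohort
comparison plus recovery of planted truth under the stated generator.
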