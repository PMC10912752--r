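---
title: "Models and methods behind tmzscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tmzscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmzscreen)
library(dplyr)
```

`tmzscreen` implements the computational backbone of a temozolomide (TMZ)
chemoresistance study in glioblastoma: statistics for a DNA-damage-response
(DDR) focused pooled CRISPR dropout screen, a somatic-variant filter chain
feeding 96-trinucleotide mutation catalogs and signature refitting, and a
patient-cohort model relating proliferation-adjusted RAD18 expression to
Signature-11 hypermutation. A synthetic-data module generates every input
with retained ground truth, so the full pipeline runs — and every claim in
this vignette is testable — without any external download.

## The screen model

A dropout screen transduces a pooled sgRNA library (by default 504 DDR
genes x 10 guides plus 1000 non-targeting controls, matching the screened
library's composition), grows cells for 20 population doublings with TMZ or
DMSO, and sequences the integrated cassettes at PD0 and PD20. Guide counts
are normalized per sample to a fixed total (counts-per-10-million;
`normalize_counts()`); every downstream statistic is a ratio or contrast,
so it does not depend on this constant.

Per guide and replicate the dropout signal is
$r = \log_2\frac{n_{20} + c}{n_{0} + c}$ with pseudocount $c = 1$ guarding
guides that fall to zero. Gene ranking uses SigmaFC (SUMLFC): the sum over
a gene's guides of their replicate-mean $r$. Its significance comes from a
permutation null: `B` resamples of the same number of guides drawn without
replacement from the non-targeting-control pool, scored identically, with
the +1-corrected two-sided empirical p-value — the attainable minimum is
$1/(B+1)$, never zero.

For the treatment contrast, each gene gets a two-sample statistic

$$Z_g = \frac{X_g}{S_g},\qquad
X_g = \bar r_{\mathrm{TMZ}} - \bar r_{\mathrm{DMSO}},\qquad
S_g = \sqrt{\frac{s^2_{\mathrm{TMZ}}}{n_{\mathrm{TMZ}}} +
            \frac{s^2_{\mathrm{DMSO}}}{n_{\mathrm{DMSO}}}},$$

and pathways combine member genes as

$$Z_P = \frac{\sum_{g\in P} X_g}{\sqrt{\sum_{g\in P} S_g^2}}.$$

We read $S_g$ as the standard error of the difference in means (Welch
form). That reading is forced by the pathway combination: only if $S_g^2$
estimates $\mathrm{Var}(X_g)$ does $Z_P$ have unit variance — and hence a
standard normal null distribution — for pathways of any size. A pooled-sd
reading would leave $Z_P$ miscalibrated by a factor depending on group
sizes. Observations enter as guide x replicate units by default
(`pooling = "observations"`); collapsing replicates to one mean per guide
first is available (`pooling = "guide_means"`) because the upstream
protocol does not pin this down.

The pathway dropout heatmap statistics are separate and simpler: a paired
t-test of $\log_{10}$ counts (PD20 vs PD0 over the pathway's
guide x replicate pairs) and the log2 fold change of pooled counts. Two
conventions for degenerate inputs: all-zero paired differences give p = 1;
zero variance with nonzero mean gives p = 0 with a warning.

### What the screen generator emulates

`sim_screen_counts()` draws PD0 abundances log-normal (sd 0.25) around
uniform — real libraries are skewed, and this stresses the normalization —
then negative-binomial counts with variance $\mu + \alpha\mu^2$
($\alpha = 0.05$ by default, 0 giving Poisson). The PD20 expectation of a
guide is its PD0 expectation times $2^{\beta + \eta}$, where $\beta$ is the
gene's selection coefficient in that (genotype, treatment) arm and $\eta$
is guide-level noise (sd 0.2) shared across replicate screens.

One design choice deserves emphasis: $\eta$ attaches only to guides of
genes with a nonzero $\beta$ in that arm. It models guide-to-guide
variability *of the selection effect*, not a free-floating perturbation.
The alternative — noise on every targeting guide — would make null
targeting guides heavier-tailed than the control pool by construction, so
permutation p-values could not be uniform under the null and $Z_P$ could
not be standard normal; with the chosen semantics both calibration
properties hold and are verified in the test suite. Each
(genotype, treatment, replicate) arm carries its own PD0 sample; whether
PD0 was split before or after treatment assignment is not determined by the
protocol, and the metadata schema supports either.

Default depth is 5e6 reads per sample (several-hundred-fold representation
of the ~6000-guide library); calibration tests run at 1e6, where the
injected-effect recovery and null-uniformity properties already hold
comfortably.

Guide quantification from reads (`count_guides()`) uses exact spacer
matching between the universal flanks — fuzzy alignment is deliberately
out of scope, with a one-mismatch mode behind `max_mismatch = 1`. Exact
matching makes the mapped fraction under a per-base error rate $e$ exactly
binomial, $(1-e)^{L}$ with $L$ the error-sensitive length, which the tests
exploit.

## Mutation catalogs and signatures

The somatic filter chain keeps a record iff caller FILTER is PASS, variant
allele fraction $\ge$ 10%, depth $\ge$ 10x, supporting reads $\ge$ 3, indel
length $\le$ 10 bp, the (chrom, pos, ref, alt) tuple is not a known
polymorphism, and the variant start lies in an exon interval (BED 0-based
half-open against the 1-based VCF position). All thresholds are inclusive
at the stated boundary; the indel rule removes strictly-greater-than-10.
Filters are a conjunction — order affects only the per-filter removal
tally (first failing test, in the order above), never the surviving set.

Catalog construction canonicalizes every SNV to the pyrimidine convention
(purine-reference records are reverse-complemented, context included) and
counts by the 96 canonical contexts (six classes x 16 flank pairs,
COSMIC-v2 ordering). Pattern I is the C>T count, attributed to O6-methyl
guanine mispairing with thymine; Pattern II is the sum of the other five
classes, attributed to N7-methyl guanine and N3-methyl adenine; the two
always sum to the total.

Signature exposures solve non-negative least squares per sample,
$\min_{e \ge 0} \lVert m - S e \rVert_2$, via the Lawson–Hanson active-set
method (`pracma::lsqnonneg`), reported in mutation counts rather than
proportions. Tests validate the solver against an exhaustive grid-search
oracle for $K \le 3$ and against multinomial resampling at 10,000
mutations (recovery within ±0.03 of true proportions). Hypermutation is
the strict rule: more than 500 mutations attributed to the
Signature-11-like profile; exactly 500 is not hypermutant.

Because no external signature file can be assumed, the package bundles a
synthetic five-signature matrix built in code: a Signature-11-like profile
(C>T concentrated at non-CpG contexts with an unequal 5' base preference —
the footprint of alkylating agents, whose G:C>A:T transitions avoid CpG),
a CpG-deamination clock, a flat profile, a C>A-heavy and a T>C-heavy
profile. These are stand-ins with the right structure for testing
refitting, not estimates of the COSMIC signatures; `read_signatures_tsv()`
accepts any COSMIC-v2-layout matrix for real analyses.

Group contrasts of exposures use pairwise mean differences with pooled
within-group variance and studentized-range (Tukey HSD / Tukey–Kramer)
adjusted p-values, computed from `ptukey` with $N - k$ error df. For two
groups this reduces exactly to the pooled two-sided t-test (the
$q = |t|\sqrt{2}$ identity), which the tests assert to 1e-10, alongside a
Monte-Carlo check that the familywise error at $\alpha = 0.05$ stays in
[0.03, 0.07] for three null groups.

### Catalog generator calibration

Each of the eight arms (RAD18+/+ or −/− x MLH1+/+ or −/− x TMZ or DMSO)
yields clones whose de novo SNV totals are negative binomial
($\alpha = 0.05$) around basal-plus-induced means. The induced means in
MMR-proficient cells are the reported cell-line values — 396 (RAD18+/+)
and 378 (RAD18−/−) — and the remaining calibration follows the reported
qualitative ordering: basal means 100/200/600/900 for
WT / RAD18−/− / MLH1−/− / double knockout (MMR loss dominates basal
mutability, RAD18 loss raises it moderately), induced 420 for
RAD18+/+ MLH1−/− and ~0 for the double knockout (TMZ adds nothing when
both error-prone routes are disabled). Signature mixtures give DMSO arms
background processes only; TMZ arms gain the Signature-11-like component,
larger in the RAD18-null MMR-proficient arm (0.65 vs 0.40), reproducing
the ~2-fold Signature-11 excess that motivates the error-free-bypass
interpretation. A separate primary-lesion spectrum (70% N7mG, 25% N3mA,
5% O6mG) is exposed by `sim_lesions()`.

Emitted variant records carry depth/VAF/supporting-read fields that pass
the default filter chain, and contexts attached directly; with
`sim_context_reference()` the records are instead placed at genuine loci
of a synthetic chromosome so the FASTA-lookup path of `build_catalog()`
can be exercised and shown equivalent to the attached-context path.

## The cohort model

Proliferation is scored per sample as the mean of within-cohort z-scored
expression over a cell-cycle gene set. This is a deliberate simplification
of kernel-based single-sample enrichment: the downstream adjustment needs
only a monotone proliferation proxy, the mean-z score is transparent and
affine-invariant, and a precomputed score column can be supplied instead.
RAD18 expression is adjusted by ordinary least squares
(`expression ~ proliferation`); the residuals — expression unexplained by
proliferation — are the adjusted values, orthogonal to the score and
summing to zero (checked at 1e-9). Samples are stratified at the empirical
1/3 and 2/3 quantiles (type-7 linear interpolation; ties share a label;
all-equal inputs become all-medium with a warning). Hypermutation is then
modeled as

`glm(hypermutant ~ adjusted + mgmt_low, family = binomial("logit"))`

with Wald standard errors and two-sided normal p-values. MGMT enters as a
binary low/high indicator by default (the published stratification), with
a continuous mode available; POLE-mutant samples are excluded before
modelling when flagged. All samples enter the model with their continuous
adjusted expression — the tertiles are display strata, since the source
analysis does not state that medium samples were dropped. Separation is
detected (|coefficient| > 15 after convergence) and reported as an error
naming the covariate rather than returning meaningless Wald statistics.

The cohort generator draws proliferation standard normal and sets RAD18 to
$\rho \cdot \mathrm{prolif} + \sqrt{1-\rho^2}\,\varepsilon$, so the
population correlation is exactly $\rho$ (default 0.75, the reported
value). Hypermutation is Bernoulli on the logit scale with defaults
$\beta_0 = -2$, $\beta_{\mathrm{RAD18}} = -1.5$,
$\beta_{\mathrm{MGMT,low}} = +2$ — effect directions from the reported
associations, magnitudes chosen once to give a realistic hypermutant
fraction (~20-25%) at the default cohort size of 72 (back-solved from the
reported correlation test: r = 0.75 reaches p ~ 1e-14 near that n).
Signature-11 counts are drawn consistently with the strict >500 rule on
both sides of the boundary.

## Numerical conventions and problem sizes

* Degenerate inputs: zero-variance gene contrasts error unless the mean
  difference is also zero (then $Z_g = 0$); the permutation p floor
  $1/(B+1)$ is attained; all-zero samples abort normalization by name.
* `B = 10000` permutations by default; every generator takes an explicit
  seed and is byte-reproducible given one.
* The test suite runs calibration checks at reduced but adequate sizes:
  null screens at depth 1e6, 200 clones per arm for the induced-SNV
  calibration, 2000 draws for the $Z_P$ normality, type-I and familywise
  error checks, 100,000 draws for the lesion spectrum. One caveat
  discovered during design: resampling many pathways from a *single*
  realized screen shares that screen's random global normalization offset
  across draws, so distributional checks of $Z_P$ draw pathways across 20
  independent null screens instead.

## What passing tests do and do not show

The generators emulate library skew, counting noise, overdispersion,
signature mixtures and logistic cohort structure — but not PCR duplicates,
sequencing error beyond uniform substitutions, clonal phylogenies, guide
off-target activity, or batch structure in cohorts. Parameter-recovery
results on synthetic data therefore demonstrate the statistics are
implemented correctly and calibrated under their stated assumptions, not
that those assumptions hold in any particular real screen or cohort.
Exposure refitting inherits the usual caveat of signature analysis:
attribution is only as identifiable as the signature matrix is
well-conditioned.

## A worked end-to-end pass

```{r example, eval = FALSE}
# screen: simulate, quantify, test
lib <- sim_library(seed = 1)
eff <- effect_spec(tidyr::crossing(
  gene = c("MLH1", "MSH2", "MSH6", "PMS1", "PMS2"),
  genotype = c("WT", "KO"), treatment = "TMZ") |> mutate(effect = 2))
counts <- sim_screen_counts(lib, screen_design(), eff, seed = 2) |>
  normalize_counts()
genes <- screen_gene_table(counts, B = 10000, seed = 3)
pathways <- pathway_zstat(gene_zstat(guide_lfc(counts)),
                          default_pathway_map())

# mutagenesis: catalogs, exposures, group contrasts
clones <- sim_mutation_catalogs(seed = 4)
exposures <- fit_exposures(build_catalog(clones$variants))
flags <- classify_hypermutation(exposures)

# cohort: adjust, stratify, fit
cohort <- sim_cohort(seed = 5)$cohort
fit <- cohort_analysis(cohort)
tidy(fit$fit)
```
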