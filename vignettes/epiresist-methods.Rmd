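---
title: "Methods: prioritizing epigenetically silenced platinum-resistance biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prioritizing epigenetically silenced platinum-resistance biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiresist)
library(dplyr)
```

## The scientific problem

Ovarian carcinomas that initially respond to platinum chemotherapy often
relapse as resistant disease. One resistance mechanism is epigenetic: tumor
suppressors or drug-response genes acquire promoter CpG-island
hypermethylation, lose expression, and can be reactivated by demethylating
agents (5-Aza-dC) combined with HDAC inhibition (TSA). epiresist implements
a complete desk-scale discovery pipeline for such genes: it calls
differential methylation from bisulfite counts, locates CpG islands,
classifies the genomic zone of each methylated position, screens expression
and drug-induced re-expression, intersects the evidence layers into a
candidate funnel and a cross-study contrast matrix, and quantifies the
downstream validation read-outs a lab would collect (qMSP percent
methylation, dose–response IC50, survival stratified by methylation).

Because the matched multi-omics data of a real study cannot be bundled with
a package, every stage is exercised against a synthetic study with planted
ground truth. The generator is a first-class, tested module: the package's
statistical guarantees are statements about that generator, not about any
particular clinical cohort.

## Differential methylation from bisulfite counts

For each CpG (destranded, counts pooled at the forward-strand C) with
methylated count $m$ and unmethylated count $u$, the methylation level is
the beta value $\beta = m/(m+u)$, computed only where coverage $m+u$ is
*strictly greater* than the coverage cutoff (5X by default, 10X in the
matrix schemes — "greater than" is taken literally, so a coverage of
exactly 5 is dropped).

A CpG is differentially methylated between sensitive (S) and resistant (R)
phenotypes when it satisfies every inequality of a named threshold scheme
*and* is significant at the scheme's false-discovery level. Four schemes
are shipped (`dm_scheme()`):

| scheme | bounds | coverage |
|---|---|---|
| `initial` | $\beta_R > 0.7$, $\beta_S < 0.3$ | > 5X |
| `readjusted` | $\beta_S < 0.2$, $\Delta\beta > 0.4$ | > 5X |
| `matrix_a` | $\beta_R > 0.4$, $\beta_S < 0.23$ | > 10X |
| `matrix_b` | $\beta_S < 0.16$, $\Delta\beta \ge 0.14$ | > 10X |

The `readjusted` scheme is deliberately formalized as $\beta_S < 0.2$ AND
$(\beta_R - \beta_S) > 0.4$ with *no* separate $\beta_R$ floor: the prose
definition it formalizes ("a level of 0.2 in S and a difference greater
than 0.4 in R") does not state one, and adding one would only re-exclude
moderately methylated resistant positions the readjustment was meant to
keep.

Significance uses a two-sided Fisher's exact test on the 2×2 count table
per CpG, with Benjamini–Hochberg adjustment across all coverage-passing
CpGs. This is an explicit, transparent stand-in for the beta-binomial
machinery of dedicated WGBS callers (methylKit and relatives): with a
single pooled library per phenotype — replicates are pooled by count
summation before testing — Fisher's exact test is the exact conditional
test of the same 2×2 table those tools start from. The implementation
enumerates the hypergeometric support directly (`dhyper`) for speed and is
cross-checked against `stats::fisher.test()` in the test suite. Whether
FDR filtering precedes or follows the beta-threshold filter is
order-independent, so both are applied jointly.

## CpG-island detection and genomic zones

Islands are detected with the Takai–Jones criteria: GC $\ge$ 55%,
observed/expected CpG ratio $\ge$ 0.65, length $\ge$ 500 bp, where
$$\mathrm{O/E} = \frac{N_{CpG} \cdot L}{N_C \cdot N_G}.$$
The criterion is sometimes printed as "Obs/Exp ≥ 65"; this package reads it
as the ratio 0.65, the Takai–Jones convention. The original scanners were
interactive web tools; the local algorithm is: slide a 200-bp window at
1-bp steps, mark windows meeting the GC and O/E bounds, require windows to
be free of soft-masked (lowercase) bases — masking stands in for
RepeatMasker removal of ALU-like repeats, which can mimic islands — then
union qualifying windows into runs and trim each run to its longest
sub-interval (leftmost on ties) whose full span still meets all three
criteria. Every reported island therefore re-satisfies the criteria on its
own sequence, an invariant the tests recompute from raw character counts.
On sequences of a few kilobases the scanner is verified against an
exhaustive brute-force enumeration of all qualifying intervals.

Positions are classified into zones with precedence
alpha > beta (shore > shelf) > gamma:

* **alpha** — promoter: within 2000 bp upstream to 500 bp downstream of a
  TSS, in gene orientation. One of the formalized approaches quantifies the
  promoter exactly this way; the other speaks only of "typical promoter
  areas", so the −2000/+500 window is adopted globally.
* **beta** — shore (0–2 kb) and shelf (2–4 kb) measured 5′ upstream of an
  island start, on the strand of the island's assigned gene. The upstream-
  only definition is kept deliberately; symmetric shores exist in other
  annotation traditions but are not what this pipeline formalizes.
* **gamma** — gene body.

Coordinates are 1-based closed internally (the Bioconductor convention);
BED output is 0-based half-open, and the conversion lives in exactly one
place.

## Expression screening

Array-style log2 intensities are compared with a per-gene unpaired Welch
t-test and BH adjustment (`differential_expression()`); genes are
differential at $q \le 0.05$. This replaces limma's moderated variance
with the plain unpaired t-test the moderation refines; the substitution is
isolated behind the result interface and its cost is visible in the power
analysis below. Duplicate probes for one gene are collapsed to the
max-variance probe (the convention when a study reports only that
duplicates "were eliminated"). Count data go through the standard RNA-seq
preprocessing pair: genes with CPM < 1 in fewer than 6 samples are
discarded, and TMM normalization factors (30% M-trim, 5% A-trim,
precision-weighted, geometric mean 1) are computed by an in-package
implementation of the published recipe, cross-checked against
edgeR::calcNormFactors in the tests.

Re-expression after 5-Aza-dC/TSA treatment (`detect_reexpression()`) calls
genes with RT−R log2 fold change $\ge \log_2 2$ at $q \le 0.05$. The
2-fold default is a package choice: the study this pipeline formalizes
reports re-expressed gene counts without stating its cutoff, and reported
validation fold changes (70–270×) sit far above any reasonable threshold,
so the screen errs permissive. Relative expression by qRT-PCR uses the
comparative threshold-cycle method $2^{-\Delta\Delta Ct}$ against an
endogenous control and a calibrator sample.

## qMSP, pharmacology, survival

With simultaneous methylated (M) and unmethylated (U) probes and
amplification efficiency $E$ (default 2.0, perfect doubling, configurable
per probe), the fraction of methylated molecules is
$$\mathrm{percent} = 100\cdot\frac{E^{-Ct_M}}{E^{-Ct_M} + E^{-Ct_U}},$$
which is 50% at equal Cts for any $E$ and exactly 0/100 when one channel
is undetected. Whether a study's percentages derive from a standard curve
instead is usually unstated; this closed-form two-channel model is the
documented stand-in. A sample is MSP-positive when its percentage is
*strictly above* 29.74%, the lowest quantitative value observed to
coincide with a positive qualitative MSP call; fold changes between
phenotypes are plain ratios and reactivation-induced demethylation is
reported in absolute percentage points (consistent with reading "13–15%
less methylation" off paired bar values).

Viability is normalized to the untreated (dose 0) control as 100% survival.
IC50 is the linear interpolation of the mean viability curve at its first
(lowest-dose) 50% crossing — chosen over a 4-parameter logistic fit for
transparency on the 6-dose designs this targets; on a dense logistic curve
the interpolation lands within 2% of the analytic midpoint (tested). The
resistance index is IC50(resistant)/IC50(sensitive), reported raw and
rounded to 2 decimals.

Survival uses the Kaplan–Meier product-limit estimator and the two-group
log-rank test (backed by the survival package; hand-computed product-limit
and $O\!-\!E/V$ oracles in the tests), with deaths processed before
censorings at tied times. Patients are stratified by the qualitative MSP
call when present, else by the qMSP percentage against the 29.74%
threshold — the qualitative assay is the primary measure and the threshold
itself was derived from it, hence the precedence. Both OS and PFS
endpoints are supported through a column selector.

## Cohort selection, funnel, contrast matrix

Two selection presets (`cohort_criteria()`): **approach1** requires
platinum treatment, death within 1100 days and expression data;
**approach2** requires platinum treatment, expression (RNA-seq) and
methylation (450K) data and relapse within 6 months, encoded as 183 days.
"Death within 1100 days" means event = death AND OS ≤ 1100.

The funnel (`run_funnel()`) intersects, in order: in-vitro DE genes →
cohort-supported genes → re-expressed genes → genes with a promoter CpG
island → differentially methylated genes, reporting each stage's size and
its nearest-integer percentage of the previous stage. "Supported by every
selected patient" is not fully algorithmic in the source study; it is
implemented as cohort-level tumor-vs-control DE plus a per-patient
direction-consistency requirement (fraction configurable, default 1.0 =
all selected patients), with the per-patient direction read from the sign
of the patient's log2 CPM deviation from the mean control profile.

The contrast matrix (`evaluate_contrasts()`) evaluates 24 named
intersections of the five evidence layers, shipped as a YAML catalogue in
three groups mirroring the three methodology families (WGBS + array +
cohort; 450K + RNA-seq + cohort; all layers), with direction filters such
as hypermethylated-and-inhibited or hypomethylated-and-overexpressed
applied before intersection. The catalogue reconstructs the *structure* of
the original 24 cross-studies, whose exact compositions live in
supplementary material not distributed here; users can supply their own
YAML. Candidates with more than 10 DM CpG positions (strict, "more than")
can be kept with `filter_min_positions()`, and `rank_candidates()` orders
genes by contrast recurrence, then DM-CpG count, then max $|\Delta\beta|$,
then gene id — a deterministic total order.

## The synthetic study

`sim_config()` defines the study conditions; defaults are chosen once, as
what a study of this kind typically reports, and are not tuned per
analysis:

* **Genome** — 1 chromosome × 2 Mb, 200 non-overlapping genes (2.4 kb
  bodies, alternating strands), CpG-depleted ~40%-GC background (85% of
  background CpGs broken by a C→T transition, mimicking germline CpG
  decay), an 800-bp island-grade sequence planted across the promoter of
  every silenced gene and of half the remaining genes (so the
  promoter-island filter is a real filter), plus two lowercase decoy
  islands per chromosome that a masking-aware scanner must skip.
* **Methylation** — coverage ~ Poisson(30); methylated counts ~
  Binomial(coverage, p) with p = 0.1 background, 0.8 over planted regions
  in R, and 0.65 × 0.8 = 0.52 in RT (partial demethylation after
  reactivation; the RT fraction is configurable).
* **Expression** — cell-line design: log2 intensities, Gaussian noise
  sd 0.25, 5 replicates per phenotype; planted genes −2 log2 units in R
  and +3 in RT. Five replicates is the design point at which the plain
  Welch t-test retains ≥ 90% sensitivity for 2-fold effects after BH
  correction at this noise level — the moderated-variance refinement this
  package deliberately omits is what buys smaller designs. Cohort design:
  Poisson counts, lognormal library-size variation (sd 0.2 on the log),
  one tumor per patient plus 10 normal controls, planted genes silenced
  4-fold in every tumor (tumor-intrinsic silencing).
* **Cohort** — 60 patients, 50% platinum-resistant; resistant patients
  carry the planted methylation with probability 0.85 (0.10 for
  sensitive), qMSP percentages drawn from U(40, 95) for methylated and
  U(0, 25) for unmethylated patients; exponential OS (baseline median 900
  days) and PFS (median 300 days) with the hazard multiplied by 3 for
  methylated patients, administratively censored at 5 years.

Distributions (Poisson coverage, binomial methylation, Gaussian
log-expression, exponential survival) are the minimal standard models for
each data type. One integer seed reproduces every artifact byte for byte;
each generator derives its own sub-seed, so artifacts can be regenerated
independently and in any order.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: read-level errors and incomplete
bisulfite conversion, copy-number and SNP effects on counts,
correlated methylation along reads, array probe biases and batch effects,
non-exponential survival, and informative censoring. Recovery statistics
on this generator measure the pipeline's internal consistency, not
clinical performance.

## Problem sizes and verification

The package's own checks run at desk scale: island-scanner oracles on
≤ 5 kb sequences, DM-caller oracle on 10⁴ CpGs, full-pipeline recovery
over 20 seeds of the default 200-gene study (sensitivity and precision of
planted-gene recovery, and how often the top-ranked candidate is planted),
DM call-rate calibration on 20 null-generator seeds, log-rank null
uniformity over 200 cohort draws and power at hazard ratio 4 with 200
patients over 30 draws. `scripts/acceptance.R` recomputes the headline
numbers from scratch at these sizes and writes them as JSON.

## Known limitations

* The per-CpG Fisher test ignores biological replicate variance; with
  true replicates a beta-binomial caller is preferable.
* Welch t on 5 replicates is less efficient than moderated-variance
  methods; small designs will lose sensitivity.
* The island trimmer returns one maximal sub-interval per run; a run
  containing two disjoint qualifying islands separated by a sub-500-bp dip
  that still scans as qualifying windows is reported as its longest
  qualifying stretch only.
* Linear-interpolation IC50 is undefined when the curve does not cross
  50% and ignores curve shape between doses.
* No Cox regression or multivariable adjustment; survival comparisons are
  two-group log-rank only.
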