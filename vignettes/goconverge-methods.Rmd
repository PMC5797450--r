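---
title: "Testing genomic functional convergence with goconverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing genomic functional convergence with goconverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goconverge)
```

## The question and the model

Convergently evolved syndromes — plant carnivory being the motivating case —
are expected to leave a genomic signature not in shared sequence but in
shared *function*: if a lifestyle demands digestive enzymes and nutrient
transporters, genomes of taxa that adopted it should be enriched for genes
annotated with those functions, whatever their ancestry. `goconverge`
operationalises this as follows.

A *reference set* fixes, a priori, the functions hypothesised to belong to
the syndrome, each identified with one or more Gene Ontology (GO) codes.
The packaged set (`carnivory_reference()`) holds 36 carnivory-associated
functions spanning 39 codes; entries with several codes treat them as
aliases (equivalent or deprecated forms of the best-matching current term),
and matching is by literal code only — no propagation through the GO graph.
That choice keeps the statistic interpretable (each function is exactly the
set of genes annotated with its codes) at the cost of missing genes
annotated only at coarser or finer ontology levels.

Each taxon contributes a gene-to-GO table, either curated (annotations
shipped with the genome record, extracted from GenBank flat files) or
mapped (annotations transferred to predicted proteins by sequence
similarity). For taxon $i$ and function $f$ the *representation* is

$$r_{if} = 1000 \cdot \frac{\#\{\text{genes of } i \text{ carrying a code of } f\}}{\#\{\text{genes of } i \text{ with} \geq 1 \text{ GO code}\}},$$

genes per thousand function-assigned genes. A gene counts at most once per
function but may count for several functions, and the syndrome total is the
*sum* of the per-function values. The sum convention (rather than counting
distinct syndrome genes) is what makes the total recomputable from
calibrated per-function values and makes share decompositions
(`function_shares()`) additive; the alternative reading is available by
scoring distinct genes directly from the annotation table if ever needed.

## Cross-method calibration

Curated and mapped annotation differ systematically in their tendency to
detect particular functions. The pipeline corrects this with per-function
factors estimated from one taxon annotated by both routes:
$a_f = r^{\text{curated}}_f / r^{\text{mapped}}_f$, computed on the
per-thousand proportions. Mapped profiles are multiplied by $a_f$ and their
totals recomputed. When either route detects zero instances of $f$ the
factor is undefined (a "nullset" function, flagged symmetrically for zeros
on either side); undefined functions pass through unadjusted by default
(`zero_undefined = FALSE` in `apply_adjustment()`) and are excluded from
testing, which we prefer to silently zeroing data. Applying a taxon's own
factors to its own mapped profile reproduces its curated profile exactly —
the self-calibration identity the test suite checks to $10^{-12}$.

## Inference

Two designs are run over the tested functions plus the syndrome total:

* **Group level** (`run_analysis_1()`): one upper-tailed two-sample t-test
  per criterion, carnivorous vs control. The default is the Welch
  (unequal-variance) form: the per-mille values of the two classes have no
  reason to share a variance, and the pooled form is kept only as an option
  (`var_equal = TRUE`).
* **Taxon level** (`run_analysis_2()`): each carnivorous taxon's value is
  Z-tested against a normal reference located at the *median* of the
  control values with scale equal to their sample (n−1) standard deviation.
  The median guards the location against a single aberrant control genome;
  the n−1 scale is a choice the original design left unstated, made
  explicit here.

Each family of tests (the group family; each taxon's family) is corrected
with Storey q-values. $\pi_0$, the estimated fraction of true nulls, is
estimated by default with the closed-form bootstrap of Storey, Taylor &
Siegmund over the grid $\lambda = 0.05, 0.10, \ldots, 0.95$: across the
five published test families this package set out to reproduce, the
bootstrap's $\pi_0$ matches the values implied by the published q/p ratios
essentially exactly in three families (0.343, 0.747, 0.968), while the
spline-smoother estimator does not come close for any of them — so the
bootstrap is the default and `"smoother"` and `"fixed"` are options.
Estimates outside $(0,1]$ are clamped to 1 (warned about, and logged by
`run_pipeline()`); families smaller than `min_m = 10` fall back to
$\pi_0 = 1$, i.e. Benjamini–Hochberg, because a handful of p-values cannot
support a stable $\pi_0$ estimate. Ties in p share their maximum rank, so q
is monotone in p. With $\pi_0$ fixed at 1 the procedure is exactly BH; the
suite verifies this against `stats::p.adjust` on a thousand random
families.

Significance is coded in six strict bins — NS ($q>0.10$), "." ($<0.10$),
"*" ($<0.05$), "**" ($<0.01$), "***" ($<0.001$), "****" ($<0.0001$) — with
boundary values falling in the less significant bin, and
`compare_significance()` counts level changes between the raw and
calibrated analyses (the adjusted-vs-raw change accounting).

### Which functions are tested

A reference entry enters testing when it was detected in at least one taxon
and its adjustment factor is defined. With the packaged 36-entry set this
is what reduces the tested battery to the two dozen functions a real study
reports; `exclusion_report()` makes the dropped entries and their reasons
explicit rather than silent.

### Power, and two honest caveats

`power_effect_size()` gives the known-variance normal-approximation effect
size $d = (z_{1-\alpha} + z_{1-\beta})\sqrt{1/n_1 + 1/n_2}$; for the 6-vs-4
design at $\alpha = 0.05$ it returns 1.06 control-SDs at 50% power and 2.12
at 95%. Two approximations deserve flagging:

* The *actual* Welch t-test at those shifts has lower power than the
  normal approximation suggests (noncentral-t with ≈6.6 degrees of freedom:
  about 0.43 and 0.90 rather than 0.50 and 0.95). The suite therefore
  validates the formula by simulating the known-variance group comparison
  it describes, and this gap should be kept in mind when reading the
  formula as a statement about the t-test battery.
* The taxon-level Z-test treats the control median and SD as known. With
  only six controls they are estimates, so the plug-in test's true type-I
  error exceeds its nominal level; the suite's null-calibration check draws
  the null value from the reference distribution actually used, which
  isolates the p-value computation from this design limitation.

## The synthetic-data generator

No genome downloads are needed to exercise the pipeline: `generate_taxa()`
draws annotated gene sets with exactly the structure the analysis assumes.
Per taxon, each gene is "assigned" (gets ≥1 GO code) with probability
`assigned_fraction`; assigned genes carry each reference function's code
with probability `baseline_rate` × a per-(taxon, function) lognormal jitter
(`taxon_noise_sd`, log scale) × the function's `enrichment` multiplier in
carnivorous taxa; mapped-method taxa further scale detection by
`method_bias`. Filler codes from a synthetic pool (`GO:8xxxxxx`, outside
the reference set) give assigned genes realistic multi-code annotations and
make unique-GO summaries non-trivial. A dual-annotated calibration taxon is
materialised as two views of the *same* latent gene set, the mapped view
thinned per function — which is what makes bias recovery
(`compute_adjustment()` estimating $1/b_f$) a clean consistency check.

Defaults are fixed at the study conditions the design mirrors: 6 control
and 4 carnivorous taxa, 30,000 genes per taxon (the study genomes range
from ~18k to ~89k genes), `assigned_fraction = 0.5` (observed %Results run
from 23% to 97%), `baseline_rate = 0.001` so the syndrome total sits near
3.6% of assigned genes (observed totals: 2.4–5.0%), and
`taxon_noise_sd = 0.25`, giving the ~25% between-taxon coefficient of
variation that makes control ranges overlap the way real genomes do. The
lognormal jitter produces strictly positive, right-skewed between-taxon
variation — the shape the median/SD reference framing presumes; the closed
form `expected_profile()` holds the jitter at its median. What the
generator does **not** emulate: GO-graph structure, correlated functions,
gene-length or assembly-quality artefacts, and phylogenetic
non-independence of taxa. Tests passing on synthetic data therefore
validate the pipeline's arithmetic and statistical behaviour, not the
biological robustness of any particular real-data conclusion.

For test-budget reasons the suite runs the generator at 1,500–30,000 genes
per taxon and Monte-Carlo checks at a few thousand replicates; these sizes
were chosen so every documented bound (binomial 4σ envelopes, ±0.01 on the
null rejection rate, ±0.05 on power recovery) is comfortably inside the
check's own sampling noise.

## Numerical and degenerate-input choices

* Per-mille values are kept at full precision; rounding (statistics to 2
  decimals, p and q to 3 significant figures) happens only in
  `format_test_table()` at report time.
* An empty annotation table summarises to zeros with %Results defined as 0;
  a taxon with no assigned genes has no profile (error), and an all-zero
  profile has no share decomposition (error).
* Reference distributions require ≥2 controls that are not all equal
  (zero scale is an error, not an Inf).
* A profile can be adjusted once; a second `apply_adjustment()` is a state
  error rather than a silent double-correction.
* Deposited profile tables are read back with their `Total` column as
  deposited — the total is itself a tested criterion, so reproduction mode
  must not re-derive it.

## Reproduction mode and its limits

`load_profile_table()` consumes a deposited per-taxon representation table
(taxa × function abbreviations, genes per thousand, plus `Total` and
`Class`) so that published profile data can be re-analysed without the
original annotation files. The original study's deposited supplemental
tables are not redistributable with this package, and printed
medians/SDs/statistics under-determine them, so the package's exact-number
reproduction of that dataset is limited to what the printed report tables
themselves contain — notably the five p-value families, whose published
q-values the default Storey layer reproduces.
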