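---
title: "Models and methods: duplex melting thermodynamics and seed-mediated off-target analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscreen)
```

# Scope

Chemically modified siRNAs — for example duplexes carrying 2'-modified
nucleosides in the guide-strand seed region — are characterized along two
axes: how the modification changes duplex hybridization thermodynamics, and
how it changes seed-mediated (miRNA-like) off-target repression of
transcripts whose 3'UTRs contain the seed complement. `seedscreen`
implements both analysis arms plus a fully seeded synthetic-data generator
so that every stage can be validated end to end against known truth.

# The two-state melting model

A non-self-complementary duplex A·B with both strands at equal
concentration is treated as a two-state equilibrium
A + B &#8652; AB with association constant
$K(T) = \exp\!\left(-\Delta G^\circ(T)/RT\right)$,
$\Delta G^\circ(T) = \Delta H^\circ - T\Delta S^\circ$ (association-signed,
so both $\Delta H^\circ$ and $\Delta S^\circ$ are negative for a stable
duplex). With $C_t$ the **total** single-strand concentration (both strands
summed), mass action gives $K (C_t/2 - x)^2 = x$ for the duplex
concentration $x$, and the duplex fraction $\alpha = 2x/C_t$
(`two_state_fraction()`). At the melting temperature, defined by
$\alpha = 1/2$, this reduces to $K(T_m) = 4/C_t$, i.e.

$$\frac{1}{T_m} = \frac{R\,\ln(C_t/4) + \Delta S^\circ}{\Delta H^\circ},$$

the linear concentration dependence that `predict_tm()` inverts and
`vant_hoff_fit()` exploits: ordinary least squares of $1/T_m$ on
$\log_{10}(C_t/4)$ yields $\Delta H^\circ = R\ln 10/\mathrm{slope}$ and
$\Delta S^\circ = \mathrm{intercept}\cdot\Delta H^\circ$. We work in cal
units internally ($R = 1.987204$ cal mol$^{-1}$K$^{-1}$, slope constant
$R\ln 10 = 4.5757$) and report $\Delta H^\circ$, $\Delta G^\circ$ in
kcal/mol and $\Delta S^\circ$ in cal/(mol K), the units in which such
parameters are conventionally tabulated. `gibbs_free_energy()` evaluates
$\Delta G^\circ = \Delta H^\circ - T\Delta S^\circ$; note that some
published method sections print this relation with a plus sign, but the
minus sign is the thermodynamic identity and is what reproduces tabulated
$\Delta G^\circ_{37}$ values from their own $\Delta H^\circ, \Delta
S^\circ$ — we implement the minus sign.

Two readings of a quoted concentration series exist in the literature: "3,
6, 9, 12 uM for each strand" can mean a per-strand quantity (total
$C_t$ = 6, 12, 18, 24 uM) or an already-total one. The generators default
to the per-strand reading; `read_melting_curves(ct_mode = "total")`
preserves the alternative. Only non-self-complementary duplexes are
supported — the $C_t/4$ factor assumes them.

## Tm extraction and the inflection bias

`extract_tm()` offers two estimators:

* `"derivative"` (default): cubic smoothing spline (smoothing parameter by
  generalized cross-validation) followed by the temperature of maximum
  first derivative on a 2001-point grid with quadratic peak refinement.
  This is the classic "inflection point of the sigmoid" reading of a UV
  melting trace.
* `"two_state_fit"`: nonlinear least squares (Levenberg–Marquardt) of the
  full dual-baseline model
  $A(T) = \alpha(T)\,(m_{ds}T + b_{ds}) + (1-\alpha(T))\,(m_{ss}T+b_{ss})$,
  parameterized directly by $(T_m, \Delta H^\circ)$ at the curve's $C_t$.

These do not estimate the same quantity. For a **bimolecular** melt the
inflection of $\alpha(T)$ does not fall at $\alpha = 1/2$: at parameters
typical of an 11-mer RNA duplex ($\Delta H^\circ \approx -119$ kcal/mol,
$C_t = 6$ uM) the maximum of $|d\alpha/dT|$ sits at $\alpha \approx 0.42$,
about 0.8 °C above the $\alpha = 1/2$ temperature. The derivative method
therefore carries a small systematic offset relative to the van't Hoff
$T_m$; the two-state fit recovers the $\alpha = 1/2$ temperature to
better than 0.2 °C on noiseless curves. Our tests assert each method
against its own truth (an analytic-inflection oracle for the derivative
method), and the demo pipeline feeds the van't Hoff regression from
`"two_state_fit"` estimates. A curve whose derivative maximum lands at the
grid boundary, or whose absorbance is flat, raises a "no transition
detected" error rather than returning a boundary artifact.

## Sugar pucker from J-couplings

The ribose C3'-endo (north, A-form-like) population is estimated from the
H1'–H2' three-bond coupling by the empirical two-state relation
C3'-endo(%) = 100 − 10·J(Hz), clamped to [0, 100] with a flag when
clamping occurs (`c3_endo_percent()`). The map is affine and monotone
non-increasing in J; it is an NMR-derived population estimate, not a
structure determination.

# Seed matching

The seed region is guide positions 2–8 from the 5' end (a 7-mer);
`extract_seed()` also supports the 1–8 octamer used when reporter inserts
are designed around the "8 nt seed-containing" window. The target-side
motif is the reverse complement of the seed, written 5'→3', and a
transcript is **seed-matched (SM)** when its 3'UTR contains at least one
occurrence (`classify_utr_set()`; multiplicity is reported but does not
affect the label). Defaults follow the seven-nucleotide seed definition;
`mode = "8mer"` is the stricter variant. Matching is exact and literal:
overlapping occurrences count, T/U and case are normalized, ambiguity
codes (N, ...) never match, and UTRs are scanned on the given mRNA strand
only. Scanning is delegated to `Biostrings` pattern matching and verified
in the test suite against a naive per-position oracle.

`design_reporter_inserts()` produces the two luciferase readout inserts:
the complete-match (CM) insert — the full guide complement, an on-target
cleavage readout — and the SM insert, three tandem seed-complement
octamers separated by short random spacers, rejection-sampled so the
insert contains exactly the designed number of seed sites and shares no
complementary run of ≥ 6 nt with the non-seed guide region.

# Off-target expression analysis

The microarray arm filters features on the standard one-color QC flags
(`ControlType = 0`, `gIsPosAndSignif = 1`, `gIsFeatNonUnifOL = 0`,
`gIsWellAboveBG = 1`, `gIsSaturated = 0`, `gIsFeatPopnOL = 0`) and, when
an annotation column is present, to curated `NM_` transcripts
(`apply_flag_filter()`). The RNA-seq arm excludes transcripts with TPM
below 10 in the reference (mock) sample — rows at exactly the threshold
are kept (`filter_low_tpm()`; "any"/"all" sample modes are available since
the reference sample is a design choice, with mock as the default).
Columns are then quantile-normalized (`quantile_normalize()`, computed by
`limma::normalizeQuantiles` with tie averaging).

Per-transcript effects are summarized as
$\log_2\!\frac{\text{treated}+\varepsilon}{\text{mock}+\varepsilon}$
against the MA abscissa $\tfrac12(\log_{10}(\text{treated}+\varepsilon) +
\log_{10}(\text{mock}+\varepsilon))$, with pseudocount $\varepsilon = 1$
by default ($\varepsilon = 0$ is allowed for strictly positive tables; the
exact floor applied to array signals before log transformation is a
convention, so it is exposed as a parameter). One mock and one treated
column per condition is the default design — fold changes come from single
columns, matching the single-array-per-condition layout such experiments
typically use.

`offtarget_report()` joins fold changes to SM labels, excludes the
on-target transcript(s) from both groups when given (they are plotted
separately, not tested), and compares the SM and non-SM log2 fold-change
distributions: group means, ECDFs, and a two-sided Wilcoxon rank-sum
p-value. No multiple-testing correction is applied — one test per siRNA is
reported. An input with no SM transcripts yields a warning-carrying result
with an undefined p-value rather than an error.

## The rank-sum test

`wilcoxon_rank_sum()` is implemented in the package: exact enumeration of
the null rank-sum distribution by the classic dynamic-programming
recurrence when the smaller group has ≤ 10 observations, the data are
tie-free and the pooled size is ≤ 200 (the DP is quadratic in pooled
size); otherwise the normal approximation with tie and continuity
corrections. The two-sided exact p is $2\min(P(W\le w), P(W\ge w))$
capped at 1. The implementation is cross-checked in the tests against
`stats::wilcox.test`, which agrees to numerical precision in both
regimes. The worst-case disagreement between the exact and approximate
p-value over all rank configurations is 0.011 at 8-vs-8 and falls below
0.01 once either group reaches 10 — an intrinsic property of the normal
approximation, relevant when interpreting borderline p-values from very
small groups.

# The synthetic-data generator

The generator exists so each analysis stage has an input with known truth;
its defaults are the study conditions the analyses are designed for:

* **Melting curves** (`gen_melting_curves()`): two-state $\alpha(T)$ at
  $\Delta H^\circ = -118.8$ kcal/mol, $\Delta S^\circ = -350.9$
  cal/(mol K) (an unmodified 11-mer RNA duplex), $C_t$ = 6, 12, 18, 24 uM,
  a 15–90 °C grid in 0.5 °C steps, linear baselines with the single-strand
  line above the duplex line (A260 hyperchromicity; defaults
  ss = 0.0004/°C + 1.00, ds = 0.0002/°C + 0.80 au) and Gaussian absorbance
  noise (0.002 au — a typical spectrophotometer residual). Zero-noise
  curves equal the analytic model exactly, so generator and analyzer are
  inverses up to floating point.
* **UTR sets** (`gen_utr_set()`): i.i.d. backgrounds at 42% GC and lengths
  150–1500 nt (AT-rich, in the range of typical human 3'UTRs),
  rejection-sampled until motif-free; exactly
  `round(n * planted_fraction)` transcripts then receive the seed
  complement at a uniform random offset. This guarantees clean truth
  labels: a naive substring search over the emitted FASTA reproduces the
  truth table exactly. Default planted fraction 0.15, of the order of the
  SM fraction seen on genome-wide arrays for a typical seed.
* **Expression tables** (`gen_expression_table()`): mock signal
  $\log_2$-normal (mean 8, sd 2), treated = mock shifted by −2 log2 on the
  on-target transcript (knockdown to 25%, the level typically achieved at
  high siRNA dose), by −0.5 log2 on SM transcripts (a strong seed effect),
  plus per-transcript log2 noise of sd 0.3. The microarray platform emits
  the six QC-flag columns (all passing; a `fail_fraction` knob flips rows
  to control features to exercise the filter) and `NM_` annotations; the
  RNA-seq platform emits TPM-like columns without flags.
* **Assay tables** (`gen_assay_tables()`): Renilla/firefly pairs and
  target/reference Ct values with known fold changes, so
  `relative_luc_activity()` and `ddct_fold_change()` recover the truth
  exactly at zero noise.

One integer seed drives everything; per-curve and per-transcript child
streams are derived deterministically from it, so outputs are
byte-identical across runs and stable under subsetting.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: probe-level microarray structure (background
subtraction, spatial detrending, probe–gene multiplicity), read-level
RNA-seq sampling (only TPM-level tables are produced), correlated
expression noise between transcripts, UTR sequence composition beyond
i.i.d. bases (no repeats, no conservation structure), and biological
off-target mechanisms beyond exact seed complementarity (no seed-pairing
stability weighting, no 3' supplementary pairing). Synthetic SM counts
validate the scanning machinery, not any particular genome's SM census,
which depends on the UTR annotation set used.

# Numerical choices

* Duplex fraction: closed-form root $\alpha = b/(b + 1 + \sqrt{2b+1})$
  with $b = K C_t$, evaluated via the conjugate form to avoid
  cancellation, and by its asymptotic expansion when $\ln b > 500$ to
  avoid overflow. Verified against bisection to 1e-9.
* Temperatures are handled in °C at the interfaces and Kelvin internally
  (K = °C + 273.15).
* The van't Hoff regression is unweighted OLS; with four concentrations,
  weighting schemes are not identifiable and are not offered.
* $\Delta T_m$ is reported at one decimal place, the precision of the
  tables it is compared against; the reference is the matched unmodified
  (or matched modified, for mismatch series) duplex.
* Exact Wilcoxon enumeration refuses pooled sizes above 1000; `auto`
  switches to the approximation far earlier (see above).
* Degenerate inputs error early and specifically: constant absorbance,
  boundary transitions, singular concentration designs, empty rank-sum
  groups, missing QC columns (named in the error), malformed FASTA (first
  offending line number).

# Demonstration pipeline and problem sizes

`run_demo()` chains the stages — simulate → classify → QC/normalize →
off-target comparison → melt simulation → van't Hoff fit — under a
validated configuration (unknown keys are rejected before any stage
runs) and writes the MA table, ECDF tables, JSON summary, FASTA, curve
CSV and a manifest (package version, seed, config MD5). Reruns with the
same configuration are byte-identical.

Test and demonstration problem sizes are chosen to exercise the
statistics at study-like scale while keeping the suite quick: the power
and type-I properties use 150 SM vs 5000 non-SM transcripts (the order of
a filtered genome-wide array), with 500 replicates for the null rejection
rate; scanning properties use 1000 random UTR/motif pairs; the noisy-Tm
property uses 200 replicate curves at 0.002 au noise.

# Known limitations

Single mock/treated columns mean no within-condition variance estimate —
the rank-sum test compares transcripts, not replicates, exactly as the
corresponding array analyses do. The melting model is strictly two-state
and salt-uncorrected; nearest-neighbor sequence-based predictions and
multi-state or self-complementary melts are out of scope. Seed
classification is exact complementarity only — no thermodynamic seed
scoring, conservation weighting, or TargetScan-style context features.
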