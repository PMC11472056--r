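# seedscreen

Quantitative analysis of chemically modified siRNA duplexes along the two
axes that matter for therapeutic siRNA design:

1. **Hybridization thermodynamics** — how a sugar modification changes
   duplex stability: melting-temperature (Tm) extraction from UV melting
   curves, van't Hoff estimation of ΔH°/ΔS° from the concentration
   dependence of Tm, Gibbs free energies, ΔTm tables, and ribose
   sugar-pucker populations from ¹H-NMR J-couplings.
2. **Seed-mediated off-target repression** — how the modification changes
   miRNA-like silencing of transcripts whose 3'UTRs contain the
   seed complement: seed extraction and 3'UTR scanning, microarray QC /
   RNA-seq TPM filtering, quantile normalization, MA summaries, and
   Wilcoxon rank-sum comparison of seed-matched (SM) vs non-SM log2
   fold-change distributions.

A fully seeded synthetic-data generator produces every input — melting
curves, UTR sets with planted seed matches, expression tables with
seed-dependent knockdown, luciferase/qPCR assay tables — with truth
labels, so the whole pipeline is testable end to end. It is aimed at
nucleic-acid chemists and computational biologists who characterize
modified siRNAs.

## The models in brief

A non-self-complementary duplex is treated as a two-state equilibrium
A + B ⇌ AB. With C_t the total single-strand concentration, the duplex
fraction α solves K(T)(C_t/2 − x)² = x, α = 2x/C_t, and α = ½ at the
melting temperature, giving

    1/Tm = (R ln(C_t/4) + ΔS°) / ΔH°,

so ΔH° and ΔS° follow from an ordinary least-squares fit of 1/Tm against
log₁₀(C_t/4) across a concentration series, and
ΔG°(T) = ΔH° − TΔS°. Sugar pucker uses the empirical two-state estimate
C3'-endo(%) = 100 − 10·J₁'₋₂'(Hz).

The seed region is guide-strand positions 2–8 from the 5' end; a
transcript is seed-matched when its 3'UTR contains the reverse complement
of the seed. SM and non-SM log2 fold-change distributions (treated vs
mock) are compared with a two-sided Wilcoxon rank-sum test (exact
enumeration for small groups, normal approximation with tie/continuity
corrections otherwise).

See the methods vignette (`vignettes/seed-offtarget-methods.Rmd`) for
assumptions, parameter defaults, and numerical choices.

## Worked example

```r
library(seedscreen)

# --- thermodynamics: recover ΔH°/ΔS° from a Tm concentration series ---
cts <- c(6, 12, 18, 24) * 1e-6          # total strand conc, mol/L
tms <- vapply(cts, function(ct) predict_tm(-118.8, -350.9, ct)$tm_K,
              numeric(1))
vant_hoff_fit(cts, tms)
#> Van't Hoff fit of 1/Tm vs log10(Ct/4)
#>   dH  =   -118.8 kcal/mol
#>   dS  =   -350.9 cal/(mol K)
#>   dG(37 C) = -10.0 kcal/mol
#>   n = 4 concentrations, R^2 = 1.000000

c3_endo_percent(8.8)$c3_endo_percent    # pucker from J(1'-2') = 8.8 Hz
#> [1] 12
delta_tm(58.6, 66.2)                    # modified vs unmodified duplex
#> [1] -7.6

# --- end-to-end synthetic off-target screen ---
res <- run_demo(list(n_transcripts = 300,
                     utr_length_range = c(100L, 400L), seed = 7),
                out_dir = "demo_out")
res$report
#> Seed-dependent off-target comparison (SM vs non-SM)
#>   n_sm = 44, n_other = 249
#>   mean log2FC: SM -0.4340, other 0.0850
#>   Wilcoxon rank-sum (normal_approx): W = 2366.5, p = 2.46e-15
res$thermo
#> Van't Hoff fit of 1/Tm vs log10(Ct/4)
#>   dH  =   -120.3 kcal/mol
#>   dS  =   -355.5 cal/(mol K)
#>   dG(37 C) = -10.0 kcal/mol
#>   n = 4 concentrations, R^2 = 0.999707
```

Reading the output: the first fit inverts analytically generated Tm
values, so the generating parameters come back exactly (R² = 1). The demo
simulates a 300-transcript screen in which 15% of UTRs carry the planted
seed complement and SM transcripts receive a −0.5 log2 knockdown on top
of 0.3 log2 noise: the SM group mean (−0.43 after quantile normalization
and pseudocount handling) is clearly below the non-SM mean, and the
rank-sum test detects the seed-dependent shift (p ≈ 2×10⁻¹⁵). The second
thermodynamic fit runs on simulated noisy melting curves (0.002 au), so
the recovered ΔH° lands near, not exactly on, the generating −118.8
kcal/mol. `demo_out/` contains the MA table, ECDF tables, summary JSON,
FASTA, melting-curve CSV and a run manifest; reruns with the same config
and seed are byte-identical.

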