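# Synthetic-data generators.
#
# Every input the analysis stages consume can be simulated with truth
# labels: two-state melting curves with linear baselines and Gaussian
# absorbance noise, 3'UTR sets with a controlled fraction of planted
# seed-complement motifs over rejection-sampled motif-free background,
# expression tables with a log-scale knockdown applied to the on-target
# transcript and a smaller shift applied to seed-matched transcripts, and
# luciferase / qPCR assay tables with known fold changes.

#' Specification for simulated melting curves
#'
#' Defaults mirror a UV-melting concentration series: strands at 3, 6, 9 and
#' 12 uM each (total single-strand concentration Ct = 6, 12, 18, 24 uM), a
#' 15-90 C grid in 0.5 C steps, and linear duplex/single-strand baselines
#' with the single-strand line above the duplex line (A260 hyperchromicity).
#'
#' @param dH_kcal_per_mol association enthalpy (negative)
#' @param dS_cal_per_mol_K association entropy (negative)
#' @param conc_series_M total single-strand concentrations, mol/L
#' @param temp_grid_C strictly increasing temperature grid, degrees C
#' @param baseline_ds,baseline_ss `c(slope, intercept)` of the duplex and
#'   single-strand absorbance baselines (au per degree C, au)
#' @param noise_sd_au Gaussian absorbance noise SD, au
#' @param seed integer RNG seed
#' @return object of class `melt_sim_spec`
#' @export
melt_sim_spec <- function(dH_kcal_per_mol = -118.8,
                          dS_cal_per_mol_K = -350.9,
                          conc_series_M = c(6, 12, 18, 24) * 1e-6,
                          temp_grid_C = seq(15, 90, by = 0.5),
                          baseline_ds = c(2e-4, 0.80),
                          baseline_ss = c(4e-4, 1.00),
                          noise_sd_au = 0.002,
                          seed = 1L) {
  vals <- c(dH_kcal_per_mol, dS_cal_per_mol_K, conc_series_M, temp_grid_C,
            baseline_ds, baseline_ss, noise_sd_au)
  if (!all(is.finite(vals))) stop("non-finite simulation parameters")
  if (any(conc_series_M <= 0)) stop("concentrations must be > 0")
  if (any(diff(temp_grid_C) <= 0)) {
    stop("temp_grid_C must be strictly increasing")
  }
  if (noise_sd_au < 0) stop("noise_sd_au must be >= 0")
  ds <- baseline_ds[1L] * temp_grid_C + baseline_ds[2L]
  ss <- baseline_ss[1L] * temp_grid_C + baseline_ss[2L]
  if (any(ss <= ds)) {
    stop("single-strand baseline must lie above the duplex baseline ",
         "over the whole grid (hyperchromicity)")
  }
  structure(
    list(dH_kcal_per_mol = dH_kcal_per_mol,
         dS_cal_per_mol_K = dS_cal_per_mol_K,
         conc_series_M = conc_series_M,
         temp_grid_C = temp_grid_C,
         baseline_ds = baseline_ds,
         baseline_ss = baseline_ss,
         noise_sd_au = noise_sd_au,
         seed = as.integer(seed)),
    class = "melt_sim_spec"
  )
}

#' Simulate a concentration series of UV melting curves
#'
#' One curve per concentration: `A(T) = alpha(T) ds(T) + (1 - alpha(T)) ss(T)
#' + noise`, where alpha is the two-state duplex fraction
#' ([two_state_fraction]) at that curve's Ct. Each curve's noise comes from
#' a child RNG stream derived from the spec seed, so single curves are
#' reproducible independent of the series.
#'
#' @param spec a [melt_sim_spec]
#' @return list of [melting_curve]; each carries the generating parameters
#'   in its `sim_params` attribute
#' @export
gen_melting_curves <- function(spec) {
  stopifnot(inherits(spec, "melt_sim_spec"))
  tK <- spec$temp_grid_C + KELVIN0
  ds <- spec$baseline_ds[1L] * spec$temp_grid_C + spec$baseline_ds[2L]
  ss <- spec$baseline_ss[1L] * spec$temp_grid_C + spec$baseline_ss[2L]
  lapply(seq_along(spec$conc_series_M), function(i) {
    ct <- spec$conc_series_M[i]
    a <- two_state_fraction(spec$dH_kcal_per_mol, spec$dS_cal_per_mol_K,
                            ct, tK)
    noise <- if (spec$noise_sd_au > 0) {
      with_seed(child_seed(spec$seed, i),
                stats::rnorm(length(tK), 0, spec$noise_sd_au))
    } else 0
    curve <- melting_curve(spec$temp_grid_C, a * ds + (1 - a) * ss + noise,
                           ct, label = sprintf("curve%02d_Ct=%.3g", i, ct))
    attr(curve, "sim_params") <- list(dH = spec$dH_kcal_per_mol,
                                      dS = spec$dS_cal_per_mol_K,
                                      Ct = ct, seed = spec$seed)
    curve
  })
}

#' Write melting curves to CSV with a JSON concentration sidecar
#'
#' @param curves list of [melting_curve]
#' @param path output CSV path (columns `temperature_C`, `absorbance`,
#'   `curve_id`); per-curve concentrations go to `<path>.json`
#' @return invisibly, the CSV path
#' @export
write_melting_curves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cu) {
    data.frame(temperature_C = cu$temperature_C,
               absorbance = cu$absorbance_au,
               curve_id = cu$label, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  ct <- lapply(curves, function(cu) cu$total_strand_conc_M)
  names(ct) <- vapply(curves, function(cu) cu$label, "")
  jsonlite::write_json(ct, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Specification for a simulated 3'UTR set
#'
#' Backgrounds are i.i.d. bases at the given GC fraction, rejection-sampled
#' until motif-free; exactly `round(n_transcripts * planted_fraction)`
#' transcripts then receive the seed-complement motif at a uniform random
#' offset. Default lengths and composition approximate human 3'UTRs
#' (AT-rich, a few hundred to a couple of thousand nt).
#'
#' @param n_transcripts number of transcripts
#' @param motif target-side seed-match sequence (7 or 8 nt, RNA)
#' @param utr_length_range min/max UTR length, nt
#' @param gc_fraction background GC content
#' @param planted_fraction fraction of transcripts receiving >= 1 motif
#' @param on_target_id id of the transcript designated as the siRNA's
#'   full-match target (default: the first transcript)
#' @param seed integer RNG seed
#' @return object of class `transcriptome_sim_spec`
#' @export
transcriptome_sim_spec <- function(n_transcripts = 1000L,
                                   motif,
                                   utr_length_range = c(150L, 1500L),
                                   gc_fraction = 0.42,
                                   planted_fraction = 0.15,
                                   on_target_id = NULL,
                                   seed = 1L) {
  motif <- normalize_rna(motif)
  if (!nchar(motif) %in% c(7L, 8L)) stop("motif length must be 7 or 8")
  bad <- setdiff(strsplit(motif, "")[[1L]], RNA_BASES)
  if (length(bad)) {
    stop("motif alphabet must be A/C/G/U(T): bad characters ",
         paste(unique(bad), collapse = ", "))
  }
  if (planted_fraction < 0 || planted_fraction > 1) {
    stop("planted_fraction must be in [0, 1]")
  }
  if (utr_length_range[1L] < nchar(motif)) {
    stop("UTR lengths must be >= motif length")
  }
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stop("gc_fraction must be in (0, 1)")
  }
  n <- as.integer(n_transcripts)
  if (n < 1L) stop("need >= 1 transcript")
  ids <- sprintf("TX%04d", seq_len(n))
  if (is.null(on_target_id)) on_target_id <- ids[1L]
  if (!on_target_id %in% ids) stop("on_target_id not among transcript ids")
  structure(
    list(n_transcripts = n, motif = motif,
         utr_length_range = as.integer(utr_length_range),
         gc_fraction = gc_fraction, planted_fraction = planted_fraction,
         on_target_id = on_target_id, ids = ids, seed = as.integer(seed)),
    class = "transcriptome_sim_spec"
  )
}

#' Simulate a 3'UTR set with planted seed-complement motifs
#'
#' @param spec a [transcriptome_sim_spec]
#' @return list with `$sequences` (named character vector, RNA) and
#'   `$truth` (data.frame: `transcript_id`, `is_sm`, `n_planted_motifs`,
#'   `is_on_target`); a naive substring search over the sequences
#'   reproduces `is_sm` exactly
#' @export
gen_utr_set <- function(spec) {
  stopifnot(inherits(spec, "transcriptome_sim_spec"))
  n <- spec$n_transcripts
  n_plant <- round(n * spec$planted_fraction)
  motif <- spec$motif
  m <- nchar(motif)
  planted_idx <- with_seed(child_seed(spec$seed, 0L),
                           sample.int(n, n_plant))
  planted <- logical(n)
  planted[planted_idx] <- TRUE
  seqs <- vapply(seq_len(n), function(i) {
    with_seed(child_seed(spec$seed, i), {
      len <- sample(seq.int(spec$utr_length_range[1L],
                            spec$utr_length_range[2L]), 1L)
      repeat {
        s <- random_rna(len, spec$gc_fraction)
        if (length(scan_sequence(s, motif)) == 0L) break
      }
      if (planted[i]) {
        off <- sample.int(len - m + 1L, 1L)
        substr(s, off, off + m - 1L) <- motif
      }
      s
    })
  }, "")
  names(seqs) <- spec$ids
  counts <- vapply(seqs, function(s) length(scan_sequence(s, motif)), 0L)
  truth <- data.frame(
    transcript_id = spec$ids,
    is_sm = counts >= 1L,
    n_planted_motifs = as.integer(counts),
    is_on_target = spec$ids == spec$on_target_id,
    stringsAsFactors = FALSE
  )
  list(sequences = seqs, truth = truth)
}

#' Write a UTR set as 60-column wrapped FASTA
#'
#' @param sequences named character vector of sequences
#' @param path output path
#' @return invisibly, the path
#' @export
write_utr_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

MICROARRAY_FLAGS <- c(ControlType = 0L, gIsPosAndSignif = 1L,
                      gIsFeatNonUnifOL = 0L, gIsWellAboveBG = 1L,
                      gIsSaturated = 0L, gIsFeatPopnOL = 0L)

#' Specification for a simulated expression experiment
#'
#' Mock expression is log2-normal; the treated sample is the mock shifted on
#' the log2 scale by the on-target knockdown for the designated target, by
#' the seed-match effect for SM transcripts, and by zero otherwise, plus
#' per-transcript Gaussian noise. `platform = "microarray"` adds the six
#' QC-flag columns and a `SystematicName` annotation; `fail_fraction` flips
#' a random subset of rows to failing flags to exercise the QC filter.
#'
#' @param baseline_log2_mean,baseline_log2_sd log2-scale mock expression
#'   distribution
#' @param on_target_log2fc log2 fold change applied to the on-target
#'   transcript (default -2, i.e. knockdown to 25 percent)
#' @param sm_log2fc log2 fold change applied to seed-matched transcripts
#' @param noise_log2_sd per-transcript measurement noise SD (log2)
#' @param platform `"microarray"` or `"rnaseq"`
#' @param fail_fraction fraction of rows given failing QC flags
#'   (microarray only)
#' @param seed integer RNG seed
#' @return object of class `expression_sim_spec`
#' @export
expression_sim_spec <- function(baseline_log2_mean = 8,
                                baseline_log2_sd = 2,
                                on_target_log2fc = -2,
                                sm_log2fc = -0.5,
                                noise_log2_sd = 0.3,
                                platform = c("microarray", "rnaseq"),
                                fail_fraction = 0,
                                seed = 1L) {
  platform <- match.arg(platform)
  if (noise_log2_sd < 0) stop("noise_log2_sd must be >= 0")
  if (baseline_log2_sd < 0) stop("baseline_log2_sd must be >= 0")
  if (fail_fraction < 0 || fail_fraction > 1) {
    stop("fail_fraction must be in [0, 1]")
  }
  structure(
    list(baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         on_target_log2fc = on_target_log2fc,
         sm_log2fc = sm_log2fc,
         noise_log2_sd = noise_log2_sd,
         platform = platform,
         fail_fraction = fail_fraction,
         seed = as.integer(seed)),
    class = "expression_sim_spec"
  )
}

#' Simulate a mock/treated expression table with seed-dependent knockdown
#'
#' @param truth truth table from [gen_utr_set] (`transcript_id`, `is_sm`,
#'   `is_on_target`)
#' @param spec an [expression_sim_spec]
#' @return list with `$table` (data.frame: `transcript_id`, annotation and
#'   flag columns for microarray, then `mock` and `treated` sample columns)
#'   and `$truth` (input truth plus `true_log2fc` and `qc_pass`)
#' @export
gen_expression_table <- function(truth, spec) {
  stopifnot(inherits(spec, "expression_sim_spec"), is.data.frame(truth))
  if (nrow(truth) == 0L) stop("truth table is empty")
  n <- nrow(truth)
  true_fc <- ifelse(truth$is_on_target, spec$on_target_log2fc,
                    ifelse(truth$is_sm, spec$sm_log2fc, 0))
  sim <- with_seed(spec$seed, {
    mock_log2 <- stats::rnorm(n, spec$baseline_log2_mean,
                              spec$baseline_log2_sd)
    noise <- if (spec$noise_log2_sd > 0) {
      stats::rnorm(n, 0, spec$noise_log2_sd)
    } else 0
    n_fail <- round(n * spec$fail_fraction)
    fail_idx <- if (n_fail > 0) sample.int(n, n_fail) else integer(0)
    list(mock_log2 = mock_log2, noise = noise, fail_idx = fail_idx)
  })
  mock <- 2^sim$mock_log2
  treated <- 2^(sim$mock_log2 + true_fc + sim$noise)
  qc_pass <- rep(TRUE, n)
  tab <- data.frame(transcript_id = truth$transcript_id,
                    stringsAsFactors = FALSE)
  if (spec$platform == "microarray") {
    tab$SystematicName <- sprintf("NM_%06d", seq_len(n))
    for (fl in names(MICROARRAY_FLAGS)) {
      tab[[fl]] <- rep(MICROARRAY_FLAGS[[fl]], n)
    }
    if (length(sim$fail_idx)) {
      # failing rows are marked as control features
      tab$ControlType[sim$fail_idx] <- 1L
      qc_pass[sim$fail_idx] <- FALSE
    }
  }
  tab$mock <- mock
  tab$treated <- treated
  attr(tab, "platform") <- spec$platform
  truth$true_log2fc <- true_fc
  truth$qc_pass <- qc_pass
  list(table = tab, truth = truth)
}

#' Simulate luciferase and qPCR assay tables with known fold changes
#'
#' Each condition has a true expression fold change relative to the mock /
#' control. The luciferase table carries Renilla/firefly pairs whose ratio,
#' normalized to the control condition, recovers the fold change; the Ct
#' table carries target and reference (GAPDH-like) cycle thresholds whose
#' delta-delta-Ct recovers it too. Noise is Gaussian on log-scale readings
#' (luciferase) and on Ct cycles (qPCR).
#'
#' @param effects named numeric vector of true fold changes per condition
#'   (1 = no change); a `siCont` control with effect 1 is prepended
#' @param noise SD of the Gaussian noise (log-luciferase units / Ct cycles)
#' @param seed integer RNG seed
#' @return list with `$luciferase` (condition, renilla, firefly),
#'   `$ct` (condition, ct_target_sample, ct_ref_sample, ct_target_mock,
#'   ct_ref_mock) and `$truth` (condition, fold_change, ddct)
#' @export
gen_assay_tables <- function(effects = c(siRNA_A = 0.25, siRNA_B = 0.5),
                             noise = 0, seed = 1L) {
  if (is.null(names(effects)) || any(!nzchar(names(effects)))) {
    stop("effects must be a named vector of per-condition fold changes")
  }
  if (any(effects <= 0)) stop("fold changes must be > 0")
  if (noise < 0) stop("noise must be >= 0")
  eff <- c(siCont = 1, effects)
  k <- length(eff)
  base_firefly <- 1000
  base_ratio <- 0.8
  ct_ref0 <- 15
  ct_target0 <- 20
  out <- with_seed(seed, {
    e_luc <- if (noise > 0) matrix(stats::rnorm(2 * k, 0, noise), k) else
      matrix(0, k, 2)
    e_ct <- if (noise > 0) matrix(stats::rnorm(4 * k, 0, noise), k) else
      matrix(0, k, 4)
    list(e_luc = e_luc, e_ct = e_ct)
  })
  firefly <- base_firefly * exp(out$e_luc[, 1L])
  renilla <- firefly * base_ratio * eff * exp(out$e_luc[, 2L])
  luc <- data.frame(condition = names(eff), renilla = renilla,
                    firefly = firefly, stringsAsFactors = FALSE,
                    row.names = NULL)
  ct <- data.frame(
    condition = names(eff),
    ct_target_sample = ct_target0 - log2(eff) + out$e_ct[, 1L],
    ct_ref_sample = ct_ref0 + out$e_ct[, 2L],
    ct_target_mock = ct_target0 + out$e_ct[, 3L],
    ct_ref_mock = ct_ref0 + out$e_ct[, 4L],
    stringsAsFactors = FALSE, row.names = NULL
  )
  truth <- data.frame(condition = names(eff), fold_change = unname(eff),
                      ddct = -log2(unname(eff)), stringsAsFactors = FALSE)
  list(luciferase = luc, ct = ct, truth = truth)
}
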