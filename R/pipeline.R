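# End-to-end synthetic demonstration: simulate -> seed-scan -> off-target
# comparison -> thermodynamic fit, with a validated configuration and a
# run manifest for reproducibility.

DEMO_CONFIG_DEFAULTS <- list(
  guide = "UGAUCGUAGCAGUCAUGCUAU",
  n_transcripts = 1000L,
  planted_fraction = 0.15,
  utr_length_range = c(150L, 1500L),
  gc_fraction = 0.42,
  on_target_log2fc = -2,
  sm_log2fc = -0.5,
  noise_log2_sd = 0.3,
  platform = "microarray",
  fail_fraction = 0.02,
  dH_kcal_per_mol = -118.8,
  dS_cal_per_mol_K = -350.9,
  conc_series_M = c(6, 12, 18, 24) * 1e-6,
  melt_noise_sd_au = 0.002,
  seed = 1L
)

#' Validate a demo run configuration
#'
#' Fills defaults and rejects unknown keys, so misspelled parameters fail
#' before any stage runs.
#'
#' @param config named list of overrides for the demo configuration
#' @return the completed configuration list
#' @export
validate_run_config <- function(config = list()) {
  if (!is.list(config)) stop("config must be a list")
  unknown <- setdiff(names(config), names(DEMO_CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(DEMO_CONFIG_DEFAULTS, config)
  if (!out$platform %in% c("microarray", "rnaseq")) {
    stop("config error in 'platform': must be microarray or rnaseq")
  }
  for (key in c("n_transcripts", "seed")) {
    if (!is.numeric(out[[key]]) || length(out[[key]]) != 1L) {
      stop("config error in '", key, "': must be a single number")
    }
  }
  out
}

#' Run the end-to-end synthetic off-target demonstration
#'
#' Executes the whole pipeline on simulated data: generates a 3'UTR set
#' with planted seed matches for the configured guide, an expression table
#' with seed-dependent knockdown, and a melting-curve concentration series;
#' then classifies the UTRs, runs the QC filter (microarray) or TPM filter
#' (RNA-seq), quantile normalization, the SM/non-SM off-target comparison,
#' Tm extraction per curve and the van't Hoff fit. All artifacts plus a
#' `manifest.json` (package version, seed, config hash) are written under
#' `out_dir`; outputs are byte-reproducible for a fixed config.
#'
#' @param config named list of overrides, validated by
#'   [validate_run_config]
#' @param out_dir writable output directory
#' @return invisibly, a list with the `offtarget_report`, the
#'   `vant_hoff_fit`, the classification, truth tables and artifact paths
#' @export
run_demo <- function(config = list(), out_dir = tempfile("seedscreen_demo")) {
  cfg <- validate_run_config(config)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }

  guide <- guide_strand(cfg$guide, name = "demo_guide")
  motif <- extract_seed(guide)

  utr_spec <- transcriptome_sim_spec(
    n_transcripts = cfg$n_transcripts, motif = motif$target_match,
    utr_length_range = cfg$utr_length_range, gc_fraction = cfg$gc_fraction,
    planted_fraction = cfg$planted_fraction, seed = child_seed(cfg$seed, 1L)
  )
  utrs <- gen_utr_set(utr_spec)
  fasta_path <- file.path(out_dir, "utrs.fasta")
  write_utr_fasta(utrs$sequences, fasta_path)

  expr_spec <- expression_sim_spec(
    on_target_log2fc = cfg$on_target_log2fc, sm_log2fc = cfg$sm_log2fc,
    noise_log2_sd = cfg$noise_log2_sd, platform = cfg$platform,
    fail_fraction = cfg$fail_fraction, seed = child_seed(cfg$seed, 2L)
  )
  expr <- gen_expression_table(utrs$truth, expr_spec)

  cls <- classify_utr_set(fasta_path, guide)

  tab <- expr$table
  if (cfg$platform == "microarray") {
    tab <- apply_flag_filter(tab, qc_criteria())
  } else {
    tab <- filter_low_tpm(tab, threshold = 10, reference_sample = "mock")
  }
  tab <- quantile_normalize(tab, c("mock", "treated"))
  report <- offtarget_report(tab, cls, on_target = utr_spec$on_target_id)
  report_paths <- write_offtarget_report(report, out_dir)

  melt_spec <- melt_sim_spec(
    dH_kcal_per_mol = cfg$dH_kcal_per_mol,
    dS_cal_per_mol_K = cfg$dS_cal_per_mol_K,
    conc_series_M = cfg$conc_series_M,
    noise_sd_au = cfg$melt_noise_sd_au,
    seed = child_seed(cfg$seed, 3L)
  )
  curves <- gen_melting_curves(melt_spec)
  curves_path <- file.path(out_dir, "melting_curves.csv")
  write_melting_curves(curves, curves_path)
  tms <- vapply(curves,
                function(cu) extract_tm(cu, "two_state_fit")$tm_C, 0)
  thermo <- vant_hoff_fit(cfg$conc_series_M, tms + KELVIN0)
  thermo_path <- file.path(out_dir, "thermo_fit.json")
  jsonlite::write_json(
    list(dH_kcal_per_mol = thermo$dH_kcal_per_mol,
         dS_cal_per_mol_K = thermo$dS_cal_per_mol_K,
         dG37_kcal_per_mol = thermo$dG37_kcal_per_mol,
         r_squared = thermo$r_squared,
         tm_C = tms, conc_series_M = cfg$conc_series_M),
    thermo_path, auto_unbox = TRUE, digits = NA
  )

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "seedscreen",
    version = as.character(utils::packageVersion("seedscreen")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = c("simulate", "seed-scan", "offtarget", "fit-thermo")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(
    report = report,
    thermo = thermo,
    classification = cls,
    truth = expr$truth,
    config = cfg,
    paths = c(fasta = fasta_path, curves = curves_path,
              thermo = thermo_path, manifest = manifest_path,
              config = cfg_path, report_paths)
  ))
}
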