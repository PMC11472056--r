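# Seed-dependent off-target expression analysis.
#
# QC filtering of microarray feature flags, low-TPM filtering for RNA-seq,
# quantile normalization, per-transcript log2 fold changes with MA
# coordinates, and comparison of seed-matched (SM) versus non-SM fold-change
# distributions by Wilcoxon rank-sum test with ECDF summaries. Plus the two
# small assay quantifications: relative luciferase activity and the
# delta-delta-Ct method.

#' Default microarray QC criteria
#'
#' Feature-level flag values a probe must carry to be kept, matching the
#' standard one-color Agilent Feature Extraction flags, plus a systematic-
#' name prefix restricting to curated mRNA (RefSeq NM_) annotations.
#'
#' @param ControlType,gIsPosAndSignif,gIsFeatNonUnifOL,gIsWellAboveBG,gIsSaturated,gIsFeatPopnOL
#'   required flag values
#' @param systematic_name_prefix required annotation prefix, or `NULL` to
#'   skip the annotation filter
#' @return named list of class `qc_criteria`
#' @export
qc_criteria <- function(ControlType = 0L, gIsPosAndSignif = 1L,
                        gIsFeatNonUnifOL = 0L, gIsWellAboveBG = 1L,
                        gIsSaturated = 0L, gIsFeatPopnOL = 0L,
                        systematic_name_prefix = "NM_") {
  structure(
    list(flags = c(ControlType = ControlType,
                   gIsPosAndSignif = gIsPosAndSignif,
                   gIsFeatNonUnifOL = gIsFeatNonUnifOL,
                   gIsWellAboveBG = gIsWellAboveBG,
                   gIsSaturated = gIsSaturated,
                   gIsFeatPopnOL = gIsFeatPopnOL),
         systematic_name_prefix = systematic_name_prefix),
    class = "qc_criteria"
  )
}

#' Filter an expression table on microarray QC flags
#'
#' Keeps only rows whose flag columns equal the required values and (when a
#' `SystematicName` column is present and a prefix is configured) whose
#' annotation starts with the required prefix. Removal counts per criterion
#' are attached as the `removed` attribute.
#'
#' @param table expression data.frame containing the flag columns
#' @param criteria a [qc_criteria]
#' @return the filtered data.frame
#' @export
apply_flag_filter <- function(table, criteria = qc_criteria()) {
  stopifnot(is.data.frame(table), inherits(criteria, "qc_criteria"))
  keep <- rep(TRUE, nrow(table))
  removed <- integer(0)
  for (fl in names(criteria$flags)) {
    if (!fl %in% names(table)) {
      stop("missing QC flag column: ", fl)
    }
    ok <- table[[fl]] == criteria$flags[[fl]]
    removed[fl] <- sum(keep & !ok)
    keep <- keep & ok
  }
  pre <- criteria$systematic_name_prefix
  if (!is.null(pre) && "SystematicName" %in% names(table)) {
    ok <- startsWith(as.character(table$SystematicName), pre)
    removed["SystematicName"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "platform") <- attr(table, "platform")
  attr(out, "removed") <- removed
  out
}

#' Exclude low-abundance RNA-seq transcripts
#'
#' Removes rows whose reference-sample TPM is below the threshold (rows at
#' exactly the threshold are kept).
#'
#' @param table expression data.frame
#' @param threshold minimum TPM to keep (default 10)
#' @param reference_sample name of the column the threshold is applied to;
#'   `mode = "any"`/`"all"` instead applies it across the given sample
#'   columns
#' @param mode `"reference"` (default), `"any"` (keep if any sample passes)
#'   or `"all"` (keep only if all pass)
#' @param sample_cols sample columns for `"any"`/`"all"` modes
#' @return the filtered data.frame
#' @export
filter_low_tpm <- function(table, threshold = 10, reference_sample = "mock",
                           mode = c("reference", "any", "all"),
                           sample_cols = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(table))
  keep <- if (mode == "reference") {
    if (!reference_sample %in% names(table)) {
      stop("unknown reference sample column: ", reference_sample)
    }
    table[[reference_sample]] >= threshold
  } else {
    if (is.null(sample_cols)) stop("sample_cols required for mode ", mode)
    m <- as.matrix(table[, sample_cols, drop = FALSE])
    if (mode == "any") apply(m >= threshold, 1L, any)
    else apply(m >= threshold, 1L, all)
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "platform") <- attr(table, "platform")
  out
}

#' Quantile-normalize sample columns of an expression table
#'
#' Forces the named sample columns to share one distribution: values at the
#' same rank across columns are replaced by their cross-column mean, ties
#' receiving the average of the tied ranks' reference values. Column-wise
#' rank order is preserved. (Computation via [limma::normalizeQuantiles].)
#'
#' @param table expression data.frame
#' @param sample_cols names of >= 2 sample columns
#' @return the data.frame with those columns normalized
#' @export
quantile_normalize <- function(table, sample_cols = c("mock", "treated")) {
  stopifnot(is.data.frame(table))
  if (length(sample_cols) < 2L) stop("need >= 2 sample columns")
  if (!all(sample_cols %in% names(table))) {
    stop("missing sample columns: ",
         paste(setdiff(sample_cols, names(table)), collapse = ", "))
  }
  m <- as.matrix(table[, sample_cols, drop = FALSE])
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("expression values must be finite and >= 0")
  }
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  for (j in seq_along(sample_cols)) table[[sample_cols[j]]] <- norm[, j]
  table
}

#' Per-transcript log2 fold changes with MA coordinates
#'
#' `log2fc = log2((treated + pc) / (mock + pc))`; the MA abscissa is the
#' mean of `log10(value + pc)` over the two samples. A zero pseudocount is
#' allowed only when all values are strictly positive.
#'
#' @param table expression data.frame
#' @param treated,mock sample column names
#' @param pseudocount additive offset before the log transforms (default 1)
#' @return data.frame: `transcript_id`, `log2fc`, `avg_log_intensity`
#' @export
compute_fold_changes <- function(table, treated = "treated", mock = "mock",
                                 pseudocount = 1.0) {
  stopifnot(is.data.frame(table))
  for (col in c(treated, mock)) {
    if (!col %in% names(table)) stop("missing sample column: ", col)
  }
  tv <- table[[treated]]; mv <- table[[mock]]
  if (any(tv < 0) || any(mv < 0)) stop("negative expression values")
  if (pseudocount == 0 && (any(tv == 0) || any(mv == 0))) {
    stop("zero values need a positive pseudocount")
  }
  data.frame(
    transcript_id = table$transcript_id,
    log2fc = log2((tv + pseudocount) / (mv + pseudocount)),
    avg_log_intensity = (log10(tv + pseudocount) +
                           log10(mv + pseudocount)) / 2,
    stringsAsFactors = FALSE
  )
}

# Exact null distribution of the rank sum of group A: number of size-n1
# subsets of ranks 1..n achieving each sum, by the classic DP recurrence.
rank_sum_null_counts <- function(n1, n) {
  w_max <- sum(seq.int(n - n1 + 1L, n))
  counts <- matrix(0, nrow = n1 + 1L, ncol = w_max + 1L)
  counts[1L, 1L] <- 1
  for (i in seq_len(n)) {
    kmax <- min(i, n1)
    for (k in seq.int(kmax, 1L)) {
      src <- counts[k, seq_len(w_max + 1L - i)]
      counts[k + 1L, seq.int(i + 1L, w_max + 1L)] <-
        counts[k + 1L, seq.int(i + 1L, w_max + 1L)] + src
    }
  }
  counts[n1 + 1L, ]  # index w+1 holds #subsets with rank sum w
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sided Mann-Whitney/Wilcoxon test. `mode = "auto"` uses exact
#' enumeration of the null rank-sum distribution when the smaller group has
#' at most 10 observations, there are no ties, and the pooled size is at
#' most 200; otherwise the normal approximation with tie and continuity
#' corrections. The exact enumeration is a dynamic program over subset
#' rank-sum counts, independent of [stats::wilcox.test].
#'
#' @param values_a,values_b numeric samples (e.g. SM and non-SM log2 fold
#'   changes)
#' @param mode `"auto"`, `"exact"` or `"normal"`
#' @return list: `n_a`, `n_b`, `W` (rank sum of sample a), `U_a`, `U_b`,
#'   `z_value` (normal mode), `p_two_sided`, `method`
#' @export
wilcoxon_rank_sum <- function(values_a, values_b,
                              mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  if (any(!is.finite(c(a, b)))) stop("non-finite values")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  ties <- anyDuplicated(pooled) > 0L
  W <- sum(r[seq_len(n1)])
  U_a <- W - n1 * (n1 + 1) / 2
  U_b <- n1 * n2 - U_a
  if (mode == "exact" || (mode == "auto" && !ties &&
                          min(n1, n2) <= 10L && n <= 200L)) {
    if (ties) stop("exact mode requires tie-free data")
    if (n > 1000L) stop("exact enumeration impractical for pooled n > 1000")
    counts <- rank_sum_null_counts(n1, n)
    total <- sum(counts)
    p_le <- sum(counts[seq_len(W + 1L)]) / total
    p_ge <- sum(counts[seq.int(W + 1L, length(counts))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    z <- NA_real_
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      z <- 0
      p <- 1
    } else {
      z <- (U_a - mu - sign(U_a - mu) * 0.5) / sqrt(sigma2)
      if (abs(U_a - mu) <= 0.5) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  list(n_a = n1, n_b = n2, W = W, U_a = U_a, U_b = U_b,
       z_value = z, p_two_sided = p, method = method)
}

#' Empirical cumulative distribution curve
#'
#' Right-continuous step ECDF: the cumulative fraction at each distinct
#' sorted value.
#'
#' @param values nonempty numeric vector
#' @return object of class `ecdf_curve`: `$values` (sorted distinct),
#'   `$fractions` (nondecreasing, ending at 1)
#' @export
ecdf_curve <- function(values) {
  v <- as.numeric(values)
  if (length(v) == 0L) stop("empty input")
  if (any(!is.finite(v))) stop("non-finite values")
  xs <- sort(unique(v))
  f <- stats::ecdf(v)
  structure(list(values = xs, fractions = f(xs)), class = "ecdf_curve")
}

#' @export
print.ecdf_curve <- function(x, ...) {
  cat(sprintf("ECDF over %d distinct values in [%g, %g]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Compare SM and non-SM fold-change distributions
#'
#' Joins per-transcript fold changes to seed-match labels, optionally
#' excludes the on-target transcript(s) from both groups, and summarizes
#' the seed-dependent off-target shift: group mean log2 fold changes, the
#' two ECDFs, and the two-sided Wilcoxon rank-sum p-value. If no SM
#' transcript is present the comparison fields are `NA` and a warning is
#' recorded on the result.
#'
#' @param table expression data.frame (already QC-filtered/normalized as
#'   appropriate)
#' @param classification a [classify_utr_set] result, or a data.frame with
#'   `transcript_id` and `is_sm`
#' @param treated,mock sample column names
#' @param on_target id(s) of on-target transcript(s) to exclude, or `NULL`
#' @param pseudocount passed to [compute_fold_changes]
#' @param wilcoxon_mode passed to [wilcoxon_rank_sum]
#' @return object of class `offtarget_report`: `$comparison` (n_sm,
#'   n_other, statistic, z, p, method, group means), `$ma` (MA table with
#'   `is_sm`), `$ecdf_sm`, `$ecdf_other`, `$warnings`
#' @export
offtarget_report <- function(table, classification, treated = "treated",
                             mock = "mock", on_target = NULL,
                             pseudocount = 1.0, wilcoxon_mode = "auto") {
  cls <- if (inherits(classification, "seed_classification")) {
    classification$classification
  } else {
    classification
  }
  stopifnot(is.data.frame(cls), all(c("transcript_id", "is_sm") %in%
                                      names(cls)))
  fc <- compute_fold_changes(table, treated, mock, pseudocount)
  ma <- merge(fc, cls[, c("transcript_id", "is_sm")], by = "transcript_id",
              sort = FALSE)
  if (nrow(ma) == 0L) stop("classification covers no transcript in table")
  ma$is_on_target <- ma$transcript_id %in% on_target
  grp <- ma[!ma$is_on_target, , drop = FALSE]
  sm <- grp$log2fc[grp$is_sm]
  other <- grp$log2fc[!grp$is_sm]
  warnings <- character(0)
  if (length(sm) == 0L || length(other) == 0L) {
    warnings <- c(warnings,
                  "a comparison group is empty: p-value undefined")
    comparison <- list(n_sm = length(sm), n_other = length(other),
                       W = NA_real_, U_sm = NA_real_, U_other = NA_real_,
                       z_value = NA_real_, p_two_sided = NA_real_,
                       method = NA_character_,
                       mean_log2fc_sm = if (length(sm)) mean(sm) else
                         NA_real_,
                       mean_log2fc_other = if (length(other)) mean(other)
                       else NA_real_)
    ec_sm <- if (length(sm)) ecdf_curve(sm) else NULL
    ec_other <- if (length(other)) ecdf_curve(other) else NULL
  } else {
    wt <- wilcoxon_rank_sum(sm, other, mode = wilcoxon_mode)
    comparison <- list(n_sm = wt$n_a, n_other = wt$n_b, W = wt$W,
                       U_sm = wt$U_a, U_other = wt$U_b,
                       z_value = wt$z_value, p_two_sided = wt$p_two_sided,
                       method = wt$method,
                       mean_log2fc_sm = mean(sm),
                       mean_log2fc_other = mean(other))
    ec_sm <- ecdf_curve(sm)
    ec_other <- ecdf_curve(other)
  }
  structure(
    list(comparison = comparison, ma = ma, ecdf_sm = ec_sm,
         ecdf_other = ec_other, warnings = warnings),
    class = "offtarget_report"
  )
}

#' @export
print.offtarget_report <- function(x, ...) {
  cmp <- x$comparison
  cat("Seed-dependent off-target comparison (SM vs non-SM)\n")
  cat(sprintf("  n_sm = %d, n_other = %d\n", cmp$n_sm, cmp$n_other))
  cat(sprintf("  mean log2FC: SM %.4f, other %.4f\n",
              cmp$mean_log2fc_sm, cmp$mean_log2fc_other))
  if (is.finite(cmp$p_two_sided)) {
    cat(sprintf("  Wilcoxon rank-sum (%s): W = %.1f, p = %.3g\n",
                cmp$method, cmp$W, cmp$p_two_sided))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Plot an off-target report
#'
#' Two base-graphics panels: the MA plot (SM transcripts dark, on-target in
#' red) and the SM / non-SM cumulative distributions.
#'
#' @param x an [offtarget_report]
#' @param ... passed to [plot]
#' @return invisibly, `x`
#' @export
plot.offtarget_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  ma <- x$ma
  col <- ifelse(ma$is_on_target, "red",
                ifelse(ma$is_sm, "navy", "lightblue3"))
  graphics::plot(ma$avg_log_intensity, ma$log2fc, col = col, pch = 20,
                 xlab = "average log10 signal", ylab = "log2 fold change",
                 main = "MA plot", ...)
  graphics::abline(h = 0, lty = 2)
  if (!is.null(x$ecdf_sm) && !is.null(x$ecdf_other)) {
    rng <- range(c(x$ecdf_sm$values, x$ecdf_other$values))
    graphics::plot(x$ecdf_other$values, x$ecdf_other$fractions, type = "s",
                   col = "black", xlim = rng, ylim = c(0, 1),
                   xlab = "log2 fold change", ylab = "cumulative fraction",
                   main = "Cumulative distributions")
    graphics::lines(x$ecdf_sm$values, x$ecdf_sm$fractions, type = "s",
                    col = "red")
    graphics::legend("topleft", legend = c("SM", "non-SM"),
                     col = c("red", "black"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Write an off-target report to disk
#'
#' Emits `ma.tsv` (transcript_id, log2fc, avg_log_intensity, is_sm),
#' `ecdf_sm.tsv`, `ecdf_other.tsv` and `summary.json` (counts, statistic,
#' p-value, group means) under `dir`.
#'
#' @param x an [offtarget_report]
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_offtarget_report <- function(x, dir) {
  stopifnot(inherits(x, "offtarget_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  ma_path <- file.path(dir, "ma.tsv")
  utils::write.table(
    x$ma[, c("transcript_id", "log2fc", "avg_log_intensity", "is_sm")],
    ma_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  paths <- c(paths, ma_path)
  for (side in c("sm", "other")) {
    ec <- x[[paste0("ecdf_", side)]]
    if (is.null(ec)) next
    p <- file.path(dir, sprintf("ecdf_%s.tsv", side))
    utils::write.table(
      data.frame(log2fc = ec$values, cumulative_fraction = ec$fractions),
      p, sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths <- c(paths, p)
  }
  sj <- file.path(dir, "summary.json")
  jsonlite::write_json(c(x$comparison, list(warnings = x$warnings)), sj,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, sj))
}

#' Relative luciferase activity
#'
#' `100 * (renilla / firefly) / control_ratio` percent, where
#' `control_ratio` is the Renilla/firefly ratio of the control siRNA
#' condition (defined as 100 percent activity).
#'
#' @param renilla,firefly raw luminescence readings (firefly > 0)
#' @param control_ratio control-condition Renilla/firefly ratio (> 0)
#' @return percent activity, vectorized over wells
#' @export
relative_luc_activity <- function(renilla, firefly, control_ratio) {
  if (any(firefly <= 0)) stop("firefly readings must be > 0")
  if (any(control_ratio <= 0)) stop("control ratio must be > 0")
  100 * (renilla / firefly) / control_ratio
}

#' Fold change by the delta-delta-Ct method
#'
#' `2^-ddCt` with `ddCt = (Ct_target_sample - Ct_ref_sample) -
#' (Ct_target_mock - Ct_ref_mock)`; the reference gene (e.g. GAPDH)
#' normalizes loading, the mock sample normalizes the condition.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_mock,ct_ref_mock finite
#'   cycle-threshold values
#' @return expression fold change relative to mock
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_mock, ct_ref_mock) {
  vals <- c(ct_target_sample, ct_ref_sample, ct_target_mock, ct_ref_mock)
  if (any(!is.finite(vals))) stop("non-finite Ct values")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_mock - ct_ref_mock)
  2^(-ddct)
}
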