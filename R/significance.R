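#' Two-sided Wilcoxon rank-sum test of patient vs background deltas
#'
#' Exact enumeration is used when both samples have at most 12 values and
#' no ties; otherwise the normal approximation with continuity and tie
#' correction.  Small patient samples (< 10) trigger a warning, not an
#' abort: with too few samples the rank-sum test cannot reach significance
#' even for large effects.
#'
#' @param patient_deltas,background_deltas Numeric vectors (>= 1 value
#'   each).
#' @return Two-sided p-value.
#' @export
ranksum_test <- function(patient_deltas, background_deltas) {
  if (length(patient_deltas) == 0L || length(background_deltas) == 0L)
    stop("both samples must be non-empty")
  if (length(patient_deltas) < 10L)
    warning("fewer than 10 patient values; the rank-sum test may lack power")
  use_exact <- length(patient_deltas) <= 12L && length(background_deltas) <= 12L &&
    !any(duplicated(c(patient_deltas, background_deltas)))
  suppressWarnings(
    stats::wilcox.test(patient_deltas, background_deltas,
                       alternative = "two.sided", exact = use_exact,
                       correct = TRUE)$p.value)
}

#' Bonferroni correction
#' @param raw_pvals Numeric vector of raw p-values.
#' @param n_tests Number of tests corrected for (defaults to
#'   `length(raw_pvals)`; must be at least that).
#' @return `pmin(1, raw_pvals * n_tests)`.
#' @export
bonferroni <- function(raw_pvals, n_tests = length(raw_pvals)) {
  if (n_tests < length(raw_pvals)) stop("n_tests must cover all p-values")
  pmin(1, raw_pvals * n_tests)
}

#' Per-patient effect size against the background distribution
#'
#' The log10-scaled fraction of background delta-dbA values at least as
#' extreme as the observed patient delta, where "as extreme" means same
#' sign and at least the magnitude.  Add-one smoothing keeps the log
#' finite: `f = (1 + n_extreme) / (1 + n_background)`.  More negative
#' values mean larger effects; `delta = 0` returns 0 by convention (no
#' effect).
#'
#' @param patient_delta Scalar aggregated delta-dbA for one patient.
#' @param background_deltas Numeric vector of background deltas (non-empty).
#' @return `log10(f)`, in `[-log10(n_background + 1), 0]`.
#' @export
effect_size <- function(patient_delta, background_deltas) {
  if (length(background_deltas) == 0L) stop("background deltas must be non-empty")
  if (patient_delta == 0) return(0)
  n_extreme <- sum(abs(background_deltas) >= abs(patient_delta) &
                     sign(background_deltas) == sign(patient_delta))
  log10((1 + n_extreme) / (1 + length(background_deltas)))
}

#' Significance report for one mutation block
#'
#' For every TF with background deltas available, compares the patients'
#' aggregated delta-dbA values against the background alternates' values
#' with the two-sided rank-sum test, applies Bonferroni correction over
#' the number of TFs tested, classifies the direction by the sign of the
#' mean patient delta (positive = binding-site creation, negative =
#' destruction), and computes the per-(patient, TF) effect-size matrix
#' for heatmap rendering.
#'
#' @param delta_set A `delta_set` from [compute_block_deltas()].
#' @param background_deltas Background alternates x TFs matrix (the
#'   `deltas` element of [compute_background_deltas()]).
#' @param alpha Corrected-p significance threshold.  Default 0.001, a
#'   stringent preset for large cohorts; 0.05 is the documented preset
#'   for small cohorts.
#' @return A `significance_report`: list with `block_id`, `table`
#'   (columns `tf`, `raw_p`, `corrected_p`, `direction`, `mean_delta`,
#'   `significant`, sorted by corrected then raw p), `significant_tfs`,
#'   `effect_sizes` (TF x patient matrix) and `alpha`.
#' @export
summarize_block <- function(delta_set, background_deltas, alpha = 0.001) {
  tfs <- delta_set$tf_ids
  have_bg <- tfs %in% colnames(background_deltas)
  if (any(!have_bg)) {
    warning("no background deltas for TF(s): ",
            paste(tfs[!have_bg], collapse = ", "), "; excluded")
    tfs <- tfs[have_bg]
  }
  if (length(tfs) == 0L) stop("no TF has both patient and background deltas")
  rows <- lapply(tfs, function(tf) {
    x <- delta_set$patient_deltas[, tf]
    y <- background_deltas[, tf]
    data.frame(tf = tf,
               raw_p = ranksum_test(x, y),
               direction = if (mean(x) >= 0) "positive" else "negative",
               mean_delta = mean(x), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$corrected_p <- bonferroni(tab$raw_p, length(tfs))
  tab$significant <- tab$corrected_p < alpha
  tab <- tab[, c("tf", "raw_p", "corrected_p", "direction", "mean_delta",
                 "significant")]
  tab <- tab[order(tab$corrected_p, tab$raw_p, tab$tf), , drop = FALSE]
  rownames(tab) <- NULL
  eff <- sapply(tfs, function(tf)
    vapply(delta_set$patient_deltas[, tf], effect_size, numeric(1L),
           background_deltas = background_deltas[, tf]))
  eff <- matrix(eff, ncol = length(tfs),
                dimnames = list(delta_set$patient_ids, tfs))
  structure(list(block_id = delta_set$block_id, table = tab,
                 significant_tfs = tab$tf[tab$significant],
                 effect_sizes = t(eff), alpha = alpha),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat("<significance_report> block ", x$block_id, ": ",
      nrow(x$table), " TF(s) tested, ", length(x$significant_tfs),
      " significant at corrected p < ", x$alpha, "\n", sep = "")
  if (length(x$significant_tfs) > 0L)
    print(head(x$table[x$table$significant, ], 20L))
  invisible(x)
}

#' Write a significance report (and its effect-size matrix) as TSV
#' @param report A `significance_report`.
#' @param path Output TSV for the per-TF table.
#' @param effects_path Optional output TSV for the TF x patient
#'   effect-size matrix.
#' @export
write_report <- function(report, path, effects_path = NULL) {
  write.table(report$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(effects_path)) {
    df <- data.frame(tf = rownames(report$effect_sizes), report$effect_sizes,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, effects_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Effect-size heatmap of significant TFs
#'
#' Renders the per-patient effect sizes of the significant TFs, signed by
#' direction: increased binding in orange (positive), reduced binding in
#' blue (negative); darker cells mean larger effects.
#'
#' @param report A `significance_report`.
#' @param delta_set The matching `delta_set` (for per-patient signs).
#' @param file Optional output image path.
#' @export
plot_effect_heatmap <- function(report, delta_set, file = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_effect_heatmap requires the pheatmap package")
  tfs <- report$significant_tfs
  if (length(tfs) == 0L) stop("no significant TFs to plot")
  m <- report$effect_sizes[tfs, , drop = FALSE]
  signs <- sign(delta_set$patient_deltas[, tfs, drop = FALSE])
  m <- -m * t(signs)  # positive = creation (orange), negative = destruction (blue)
  pal <- grDevices::colorRampPalette(c("#1f5fbf", "white", "#e08214"))(101)
  pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                     color = pal, filename = file %||% NA)
  invisible(m)
}

#' Background-saturation curve
#'
#' Re-runs the block significance call using only the first `n` background
#' blocks for each `n` in `grid`, and reports
#' `Y(n) = |significant(n) intersect significant(full)| / |significant(full)|`,
#' the fraction of the full-background significant TFs already discovered
#' with `n` blocks.  `Y(full_n) = 1` by construction.
#'
#' @param delta_set A `delta_set`.
#' @param background A [compute_background_deltas()] result (with
#'   `block_index`), computed from the full background set.
#' @param grid Increasing vector of background-block counts to evaluate.
#' @param alpha Corrected-p threshold passed to [summarize_block()].
#' @return Data frame with columns `n` and `Y`; `Y` is all `NA` (with a
#'   message) when the full set finds no significant TFs.
#' @export
background_saturation <- function(delta_set, background, grid, alpha = 0.001) {
  full_n <- max(background$block_index)
  stopifnot(all(grid >= 1), all(grid <= full_n))
  sig_at <- function(n) {
    keep <- background$block_index <= n
    rep <- summarize_block(delta_set, background$deltas[keep, , drop = FALSE],
                           alpha = alpha)
    rep$significant_tfs
  }
  full_sig <- sig_at(full_n)
  if (length(full_sig) == 0L) {
    message("no significant TFs with the full background set; curve undefined")
    return(data.frame(n = grid, Y = NA_real_))
  }
  Y <- vapply(grid, function(n)
    length(intersect(sig_at(n), full_sig)) / length(full_sig), numeric(1L))
  data.frame(n = grid, Y = Y)
}
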