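#' Write the combined study report
#'
#' Writes deterministic CSV tables (and optionally bar-with-error-bar
#' figures) for the three assays: DRS group summaries of both browning
#' indices, MSI group summaries per band, qPCR fold changes, and the
#' group-comparison statistics. Empty or `NULL` inputs yield header-only
#' tables.
#'
#' @param drs_summary data.frame with a `metric` column stacked over
#'   [summarize_groups()] outputs for `ratio` and `slope` (or `NULL`).
#' @param msi_summary `summary` element of [quantify_msi()] (or `NULL`).
#' @param qpcr_results [summarize_expression()] output (or `NULL`).
#' @param comparisons data.frame of pairwise comparisons with columns
#'   `assay, metric, group1, group2, p_adj, stars` (or `NULL`).
#' @param out_dir output directory, created if needed.
#' @param figures also write PNG bar charts.
#' @return Invisibly, character vector of the files written.
#' @export
render_report <- function(drs_summary = NULL, msi_summary = NULL,
                          qpcr_results = NULL, comparisons = NULL,
                          out_dir, figures = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_fmt("cannot create output directory: %s", out_dir)

  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  tables <- list(
    drs_group_summary.csv = drs_summary %||%
      empty(c("metric", "group", "tissue", "day", "mean", "se", "n")),
    msi_group_summary.csv = msi_summary %||%
      empty(c("band", "group", "tissue", "day", "mean", "se", "n")),
    qpcr_fold_changes.csv = qpcr_results %||%
      empty(c("gene", "tissue", "day", "group", "fold", "log2_fold",
              "se_log2", "se_fold", "n")),
    group_comparisons.csv = comparisons %||%
      empty(c("assay", "metric", "group1", "group2", "p_adj", "stars"))
  )
  written <- character()
  for (fname in names(tables)) {
    path <- file.path(out_dir, fname)
    utils::write.csv(tables[[fname]], path, row.names = FALSE)
    written <- c(written, path)
  }

  if (figures) {
    if (!is.null(drs_summary) && nrow(drs_summary)) {
      for (metric in unique(drs_summary$metric)) {
        sub <- display_cells(drs_summary[drs_summary$metric == metric, ])
        path <- file.path(out_dir, paste0("drs_", metric, ".png"))
        bar_with_se(sub, main = paste("DRS", metric),
                    ylab = if (metric == "ratio") "R(680)/R(550)"
                           else "slope (per 100 nm)", path = path)
        written <- c(written, path)
      }
    }
    if (!is.null(msi_summary) && nrow(msi_summary)) {
      for (b in unique(msi_summary$band)) {
        sub <- display_cells(msi_summary[msi_summary$band == b, ])
        path <- file.path(out_dir, sprintf("msi_%snm.png", b))
        bar_with_se(sub, main = sprintf("MSI ROI mean, %s nm", b),
                    ylab = "mean ROI intensity (8-bit)", path = path)
        written <- c(written, path)
      }
    }
    if (!is.null(qpcr_results) && nrow(qpcr_results)) {
      for (gene in unique(qpcr_results$gene)) {
        sub <- qpcr_results[qpcr_results$gene == gene & qpcr_results$group != "C", ]
        if (!nrow(sub)) next
        plot_df <- data.frame(label = sprintf("%s d%s", sub$tissue, sub$day),
                              mean = sub$fold, se = sub$se_fold)
        path <- file.path(out_dir, paste0("qpcr_", gene, ".png"))
        bar_with_se(plot_df, main = paste(gene, "relative expression"),
                    ylab = "fold change vs control", path = path)
        written <- c(written, path)
      }
    }
  }
  invisible(written)
}

# Reduce a group summary to the displayed cells: pooled controls plus
# per-day treated cells, in browning order.
display_cells <- function(summary_df) {
  ctrl <- summary_df[summary_df$group == "C" & summary_df$day == "4+7", ]
  trt <- summary_df[summary_df$group == "Tr", ]
  lab <- function(d) sprintf("%s %s%s", d$group, d$tissue,
                             ifelse(d$day == "4+7", "", paste0(" d", d$day)))
  out <- rbind(
    data.frame(label = lab(ctrl), mean = ctrl$mean, se = ctrl$se),
    data.frame(label = lab(trt), mean = trt$mean, se = trt$se))
  order_hint <- c("C WAT", "Tr WAT d4", "Tr WAT d7", "C BAT", "Tr BAT d4", "Tr BAT d7")
  out[order(match(out$label, order_hint)), , drop = FALSE]
}

bar_with_se <- function(df, main, ylab, path) {
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  upper <- df$mean + ifelse(is.na(df$se), 0, df$se)
  mids <- graphics::barplot(df$mean, names.arg = df$label, main = main,
                            ylab = ylab, ylim = c(0, max(upper) * 1.15),
                            las = 2, col = "grey80")
  ok <- !is.na(df$se) & df$se > 0
  if (any(ok)) {
    graphics::arrows(mids[ok], df$mean[ok] - df$se[ok],
                     mids[ok], df$mean[ok] + df$se[ok],
                     angle = 90, code = 3, length = 0.05)
  }
}
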