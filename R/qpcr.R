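#' Reference-gene-normalized Ct differences
#'
#' Averages technical replicates (arithmetic mean of Ct per sample and
#' gene), then computes `dCt = Ct_target - Ct_reference` for every target
#' gene of every sample.
#'
#' @param ct_table data.frame with columns `sample_id, group, tissue, day,
#'   gene, ct`.
#' @param reference_gene housekeeping gene (default beta-actin, "ACTB").
#' @return data.frame `sample_id, group, tissue, day, gene, delta_ct` for
#'   the target genes.
#' @export
delta_ct <- function(ct_table, reference_gene = "ACTB") {
  need <- c("sample_id", "group", "tissue", "day", "gene", "ct")
  missing <- setdiff(need, names(ct_table))
  if (length(missing)) stop_fmt("Ct table lacks column(s): %s",
                                paste(missing, collapse = ", "))
  # technical replicates: arithmetic mean of Ct per (sample, gene)
  agg <- stats::aggregate(ct ~ sample_id + group + tissue + day + gene,
                          data = ct_table, FUN = mean)
  ref <- agg[agg$gene == reference_gene, ]
  targets <- agg[agg$gene != reference_gene, ]
  if (nrow(targets) == 0L) stop_fmt("no target genes besides '%s'", reference_gene)
  ref_ct <- ref$ct[match(targets$sample_id, ref$sample_id)]
  if (any(is.na(ref_ct))) {
    bad <- unique(targets$sample_id[is.na(ref_ct)])
    stop_fmt("reference gene '%s' not measured for sample(s): %s",
             reference_gene, paste(bad, collapse = ", "))
  }
  data.frame(sample_id = targets$sample_id, group = targets$group,
             tissue = targets$tissue, day = targets$day, gene = targets$gene,
             delta_ct = targets$ct - ref_ct, stringsAsFactors = FALSE)
}

#' Relative expression fold changes (2^-ddCt)
#'
#' For each (gene, tissue, day) cell: `ddCt_i = dCt_i - mean(dCt over the
#' control group)`, per-sample fold `2^-ddCt_i`, and the reported fold is
#' the geometric mean over the group (folds are log-scale quantities).
#' The control group's fold is 1 by construction. Uncertainty is
#' propagated in log2 space (`se_log2 = sd(ddCt)/sqrt(n)`); a linear-scale
#' SE via the delta method is reported alongside.
#'
#' @param dct output of [delta_ct()].
#' @param control_group control group label (default "C").
#' @return data.frame `gene, tissue, day, group, fold, log2_fold, se_log2,
#'   se_fold, n`.
#' @export
fold_change <- function(dct, control_group = "C") {
  cells <- unique(dct[c("gene", "tissue", "day")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- dct$gene == cells$gene[i] & dct$tissue == cells$tissue[i] &
      dct$day == cells$day[i]
    sub <- dct[sel, ]
    ctrl <- sub$delta_ct[sub$group == control_group]
    if (!length(ctrl)) {
      stop_fmt("no control ('%s') samples for %s / %s day %s",
               control_group, cells$gene[i], cells$tissue[i], cells$day[i])
    }
    ctrl_mean <- mean(ctrl)
    for (grp in unique(sub$group)) {
      ddct <- sub$delta_ct[sub$group == grp] - ctrl_mean
      n <- length(ddct)
      log2_fold <- -mean(ddct)
      se_log2 <- if (n > 1L) stats::sd(ddct) / sqrt(n) else NA_real_
      fold <- 2^log2_fold
      rows[[length(rows) + 1L]] <- data.frame(
        gene = cells$gene[i], tissue = cells$tissue[i], day = cells$day[i],
        group = grp, fold = fold, log2_fold = log2_fold, se_log2 = se_log2,
        se_fold = fold * log(2) * se_log2, n = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$gene, out$tissue, out$day, out$group), , drop = FALSE]
}

#' Full relative-expression analysis of a Ct table
#'
#' Runs [delta_ct()] and [fold_change()] for the requested genes.
#'
#' @param ct_table Ct table data.frame (see [delta_ct()]).
#' @param reference_gene housekeeping gene.
#' @param control_group control group label.
#' @param genes target genes to analyse (default: all non-reference genes).
#' @return data.frame of fold changes, see [fold_change()].
#' @export
summarize_expression <- function(ct_table, reference_gene = "ACTB",
                                 control_group = "C", genes = NULL) {
  dct <- delta_ct(ct_table, reference_gene)
  if (!is.null(genes)) {
    unknown <- setdiff(genes, unique(dct$gene))
    if (length(unknown)) stop_fmt("gene(s) not in table: %s",
                                  paste(unknown, collapse = ", "))
    dct <- dct[dct$gene %in% genes, ]
  }
  fold_change(dct, control_group)
}
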