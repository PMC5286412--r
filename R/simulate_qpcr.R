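#' Default fold-change calibration for marker genes
#'
#' Treated-vs-control fold changes in WAT for the two classical browning
#' markers: UCP1 rises ~11.7-fold at day 4 and ~39-fold at day 7;
#' PGC-1a rises ~3.3-fold and ~10-fold.
#'
#' @return data.frame with columns `gene, tissue, day, fold`.
#' @export
default_fold_map <- function() {
  data.frame(
    gene = c("UCP1", "UCP1", "PGC1a", "PGC1a"),
    tissue = "WAT",
    day = c(4L, 7L, 4L, 7L),
    fold = c(11.7, 39, 3.3, 10),
    stringsAsFactors = FALSE
  )
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' For every (tissue, day) cell of the fold map, `n_mice` control and
#' `n_mice` treated animals are generated. The reference gene amplifies at
#' a fixed Ct for every sample, target genes at a fixed control baseline,
#' and treated samples are shifted down by `log2(fold)` cycles — so a
#' noise-free table analysed with [summarize_expression()] returns the
#' fold map exactly.
#'
#' @param fold_map data.frame `gene, tissue, day, fold` (folds > 0);
#'   default [default_fold_map()].
#' @param n_mice animals per group per cell (>= 2).
#' @param ct_sd Gaussian Ct noise in cycles, applied to every measurement.
#' @param seed RNG seed (`NULL` = current stream).
#' @param reference_gene reference (housekeeping) gene name.
#' @param reference_ct reference-gene Ct level (cycles).
#' @param base_ct control-group target-gene Ct level (cycles).
#' @return data.frame Ct table (`sample_id, group, tissue, day, gene, ct`).
#' @export
simulate_ct_table <- function(fold_map = default_fold_map(), n_mice = 8,
                              ct_sd = 0.15, seed = NULL,
                              reference_gene = "ACTB",
                              reference_ct = 18, base_ct = 26) {
  if (any(!is.finite(fold_map$fold)) || any(fold_map$fold <= 0)) {
    stop_fmt("all fold values must be positive and finite")
  }
  if (n_mice < 2) stop_fmt("'n_mice' must be >= 2")

  with_seed(seed, {
    rows <- list()
    cells <- unique(fold_map[c("tissue", "day")])
    for (ci in seq_len(nrow(cells))) {
      tissue <- cells$tissue[ci]; day <- cells$day[ci]
      genes <- fold_map$gene[fold_map$tissue == tissue & fold_map$day == day]
      for (grp in c("C", "Tr")) {
        for (i in seq_len(n_mice)) {
          sid <- sprintf("%s_%s_d%d_m%d", grp, tissue, day, i)
          for (gene in genes) {
            fold <- fold_map$fold[fold_map$gene == gene &
                                    fold_map$tissue == tissue &
                                    fold_map$day == day]
            ct <- base_ct - (if (grp == "Tr") log2(fold) else 0) +
              stats::rnorm(1L, 0, ct_sd)
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = sid, group = grp, tissue = tissue, day = day,
              gene = gene, ct = ct, stringsAsFactors = FALSE)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, group = grp, tissue = tissue, day = day,
            gene = reference_gene, ct = reference_ct + stats::rnorm(1L, 0, ct_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
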