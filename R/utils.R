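`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tissue class labels
#'
#' The six phantom classes: control and treated (beta3-agonist) white and
#' brown adipose tissue, treated tissue at day 4 or 7 post induction.
#' Control classes pool both sacrifice days.
#'
#' @return Character vector of the six class labels.
#' @export
class_labels <- function() {
  c("C_WAT", "TrWAT_d4", "TrWAT_d7", "C_BAT", "TrBAT_d4", "TrBAT_d7")
}

#' Parse a class label into its experimental factors
#'
#' @param label one of [class_labels()].
#' @return list with `group` ("C"/"Tr"), `tissue` ("WAT"/"BAT") and `day`
#'   (4, 7, or `NA` for controls, which pool days).
#' @export
parse_class_label <- function(label) {
  if (!label %in% class_labels()) {
    stop("unknown class label: ", label, call. = FALSE)
  }
  group <- if (startsWith(label, "Tr")) "Tr" else "C"
  tissue <- if (grepl("WAT", label, fixed = TRUE)) "WAT" else "BAT"
  day <- if (grepl("_d4$", label)) 4L else if (grepl("_d7$", label)) 7L else NA_integer_
  list(group = group, tissue = tissue, day = day)
}

#' Analysis cell for a sample
#'
#' Maps (group, tissue, day) metadata back to the reporting cell used for
#' group comparisons: treated samples keep their day, control samples pool
#' days (the reporting convention for control tissue).
#'
#' @param group "C" or "Tr".
#' @param tissue "WAT" or "BAT".
#' @param day 4 or 7 (ignored for controls).
#' @return A class label string.
#' @export
analysis_cell <- function(group, tissue, day) {
  ifelse(group == "C",
         paste0("C_", tissue),
         paste0("Tr", tissue, "_d", day))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`
# (NULL seed = use the current RNG stream untouched).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Derive a sub-stream seed from a master seed
#'
#' Deterministic splitting of one master seed into per-sample / per-stage
#' seeds, kept inside the 32-bit integer range.
#'
#' @param master integer master seed, or `NULL` (returns `NULL`).
#' @param stream non-negative integer stream index.
#' @return An integer seed, or `NULL` if `master` is `NULL`.
#' @export
derive_seed <- function(master, stream) {
  if (is.null(master)) return(NULL)
  as.integer((as.numeric(master) * 7919 + as.numeric(stream) * 104729) %% 2147483647)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
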