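#' Score a benchmark of labeled SNV-sequence pairs
#'
#' Benchmark inputs are an SNV centered in a fixed-length sequence (50-nt
#' flanks, 101 nt in total by default); both difference statistics are
#' computed for each pair at half-window `w`. Folding is global since the
#' inputs fit in one window.
#'
#' @param pairs data.frame with `pair_id`, `sequence`, `snv_pos` (0-based,
#'   the center), `ref`, `alt`, `label` (`"ribosnitch"`/`"non_ribosnitch"`).
#' @param w Half-window; must not exceed the flank length.
#' @param config A [fold_config()].
#' @return `pairs` with `mean_diff` and `euc_diff` appended.
#' @export
score_benchmark <- function(pairs, w, config = fold_config()) {
  flank <- (nchar(pairs$sequence[1L]) - 1L) %/% 2L
  if (w > flank) stop("w exceeds flank length (", flank, ")")
  bad <- substr(pairs$sequence, pairs$snv_pos + 1L, pairs$snv_pos + 1L) != pairs$ref
  if (any(bad)) stop("sequence center does not match ref for pair ",
                     pairs$pair_id[which(bad)[1L]])
  if (any(pairs$ref == pairs$alt)) stop("pair with alt equal to ref")
  sc <- lapply(seq_len(nrow(pairs)), function(i) {
    score_mutation(pairs$sequence[i], pairs$snv_pos[i], pairs$alt[i],
                   config, w)
  })
  pairs$mean_diff <- vapply(sc, `[[`, numeric(1), "mean_diff")
  pairs$euc_diff <- vapply(sc, `[[`, numeric(1), "euc_diff")
  pairs
}

#' ROC curve and AUC for a score
#'
#' Rank-based AUC (ties averaged), equivalent to the Mann-Whitney
#' statistic; computed with pROC. Higher scores must indicate the positive
#' (riboSNitch) class.
#'
#' @param scores Numeric vector.
#' @param labels Vector with both `"ribosnitch"` and `"non_ribosnitch"`
#'   present (or a logical/0-1 vector, `TRUE`/1 = positive).
#' @return List with `auc` and a `curve` data.frame (`fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  pos <- normalize_labels(labels)
  if (length(unique(pos)) < 2L) stop("need both classes in labels")
  r <- pROC::roc(response = pos, predictor = scores, levels = c(FALSE, TRUE),
                 direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)),
       curve = data.frame(fpr = rev(1 - r$specificities),
                          tpr = rev(r$sensitivities)))
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  lab <- as.character(labels)
  if (!all(lab %in% c("ribosnitch", "non_ribosnitch")))
    stop("labels must be ribosnitch/non_ribosnitch")
  lab == "ribosnitch"
}

#' AUC of the dual-statistic intersection ranking
#'
#' Combines MeanDiff and EucDiff into one ranking mirroring the dual-tail
#' intersection call: each pair's combined score is the minimum of its two
#' within-cohort ranks (rank 1 = lowest score), so a pair ranks high only if
#' it is high in both statistics.
#'
#' @param mean_scores,euc_scores Numeric vectors.
#' @inheritParams roc_auc
#' @return List with `auc`, `curve` and the `combined` score vector.
#' @export
intersection_auc <- function(mean_scores, euc_scores, labels) {
  combined <- pmin(rank(mean_scores, ties.method = "average"),
                   rank(euc_scores, ties.method = "average"))
  out <- roc_auc(combined, labels)
  out$combined <- combined
  out
}

#' AUC table over a window sweep
#'
#' Scores a benchmark at several half-windows and reports the AUC of each
#' statistic and of their intersection ranking per window.
#'
#' @param pairs Benchmark data.frame (see [score_benchmark()]).
#' @param windows Half-window values, e.g. `c(2, 5, 10, 15, 20, 25, 50)`.
#' @param config A [fold_config()].
#' @return data.frame with `w`, `auc_meandiff`, `auc_eucdiff`,
#'   `auc_intersection`.
#' @export
benchmark_window_sweep <- function(pairs, windows = c(2L, 5L, 10L, 15L, 20L,
                                                      25L, 50L),
                                   config = fold_config()) {
  rows <- lapply(windows, function(w) {
    sc <- score_benchmark(pairs, w, config)
    data.frame(w = w,
               auc_meandiff = roc_auc(sc$mean_diff, sc$label)$auc,
               auc_eucdiff = roc_auc(sc$euc_diff, sc$label)$auc,
               auc_intersection = intersection_auc(sc$mean_diff, sc$euc_diff,
                                                   sc$label)$auc)
  })
  do.call(rbind, rows)
}
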