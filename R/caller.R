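#' Empirical tail cutoffs for riboSNitch calling
#'
#' Computes the score thresholds delimiting the top and bottom tails of the
#' MeanDiff and EucDiff distributions of a cohort. Quantiles use linear
#' interpolation of order statistics (type 7).
#'
#' @param scores data.frame with `mean_diff` and `euc_diff` columns.
#' @param top_fraction,bottom_fraction Tail fractions in (0, 0.5); the
#'   defaults give the 2.5\% dual-tail convention. 0.05/0.10/0.20 reproduce
#'   the relaxed-cutoff variants.
#' @param cohort_label Provenance label stored with the cutoffs.
#' @return An object of class `tail_cutoffs` with fields `mean_top`,
#'   `mean_bottom`, `euc_top`, `euc_bottom`, the fractions, the label and
#'   `n_scores`.
#' @export
compute_cutoffs <- function(scores, top_fraction = 0.025,
                            bottom_fraction = 0.025,
                            cohort_label = "cohort") {
  if (NROW(scores) == 0L) stop("no scores")
  if (top_fraction <= 0 || top_fraction >= 0.5 ||
      bottom_fraction <= 0 || bottom_fraction >= 0.5)
    stop("tail fractions must lie in (0, 0.5)")
  structure(list(
    top_fraction = top_fraction, bottom_fraction = bottom_fraction,
    mean_top = unname(quantile(scores$mean_diff, 1 - top_fraction, type = 7)),
    mean_bottom = unname(quantile(scores$mean_diff, bottom_fraction, type = 7)),
    euc_top = unname(quantile(scores$euc_diff, 1 - top_fraction, type = 7)),
    euc_bottom = unname(quantile(scores$euc_diff, bottom_fraction, type = 7)),
    cohort_label = cohort_label, n_scores = NROW(scores)),
    class = "tail_cutoffs")
}

#' @export
print.tail_cutoffs <- function(x, ...) {
  cat(sprintf(paste0("tail_cutoffs [%s] n=%d top=%g bottom=%g\n",
                     "  MeanDiff: <=%.6g | >=%.6g\n  EucDiff:  <=%.6g | >=%.6g\n"),
              x$cohort_label, x$n_scores, x$top_fraction, x$bottom_fraction,
              x$mean_bottom, x$mean_top, x$euc_bottom, x$euc_top))
  invisible(x)
}

#' Call riboSNitches by dual-tail intersection
#'
#' A mutation is a `ribosnitch` iff both its MeanDiff and its EucDiff reach
#' the top-tail thresholds, a `non_ribosnitch` iff both sit at or below the
#' bottom-tail thresholds, and `intermediate` otherwise. Ties at a threshold
#' are included in the tail. If the thresholds fail to separate (degenerate
#' score distributions where a score would satisfy both rules), the label is
#' `intermediate`.
#'
#' @param scores data.frame with `mean_diff` and `euc_diff`.
#' @param cutoffs A `tail_cutoffs`, either computed on this cohort
#'   ([compute_cutoffs()]) or imported from another cohort (e.g. calling a
#'   clinical dataset with germline-cohort thresholds).
#' @return Factor with levels `ribosnitch`, `intermediate`,
#'   `non_ribosnitch`, one per row of `scores`.
#' @export
call_ribosnitches <- function(scores, cutoffs) {
  if (!inherits(cutoffs, "tail_cutoffs")) stop("cutoffs must be tail_cutoffs")
  n <- NROW(scores)
  top <- scores$mean_diff >= cutoffs$mean_top &
    scores$euc_diff >= cutoffs$euc_top
  bottom <- scores$mean_diff <= cutoffs$mean_bottom &
    scores$euc_diff <= cutoffs$euc_bottom
  lab <- rep("intermediate", n)
  lab[top & !bottom] <- "ribosnitch"
  lab[bottom & !top] <- "non_ribosnitch"
  factor(lab, levels = c("ribosnitch", "intermediate", "non_ribosnitch"))
}

#' Serialize tail cutoffs to a key-value text file
#'
#' @param cutoffs A `tail_cutoffs`.
#' @param path Output file.
#' @export
write_cutoffs <- function(cutoffs, path) {
  flds <- c("cohort_label", "top_fraction", "bottom_fraction", "mean_top",
            "mean_bottom", "euc_top", "euc_bottom", "n_scores")
  writeLines(paste(flds, vapply(cutoffs[flds], function(v)
    format(v, digits = 17), character(1)), sep = "\t"), path)
}

#' Read tail cutoffs written by [write_cutoffs()]
#'
#' @param path Input file.
#' @return A `tail_cutoffs`.
#' @export
read_cutoffs <- function(path) {
  kv <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  vals <- setNames(kv[[2]], kv[[1]])
  need <- c("mean_top", "mean_bottom", "euc_top", "euc_bottom")
  if (!all(need %in% names(vals))) stop("missing thresholds in ", path)
  structure(list(
    top_fraction = as.numeric(vals[["top_fraction"]]),
    bottom_fraction = as.numeric(vals[["bottom_fraction"]]),
    mean_top = as.numeric(vals[["mean_top"]]),
    mean_bottom = as.numeric(vals[["mean_bottom"]]),
    euc_top = as.numeric(vals[["euc_top"]]),
    euc_bottom = as.numeric(vals[["euc_bottom"]]),
    cohort_label = vals[["cohort_label"]],
    n_scores = as.integer(vals[["n_scores"]])),
    class = "tail_cutoffs")
}
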