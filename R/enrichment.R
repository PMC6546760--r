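#' One-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric tail probability for the table
#' `rbind(c(a, b), c(c, d))`, in the requested direction for the top-left
#' cell. Degenerate tables (an empty margin) return p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts; first row is the
#'   observed group (`a` = riboSNitches, `b` = the rest), second row the
#'   comparison group.
#' @param direction `"greater"` (enrichment of `a`) or `"less"` (depletion).
#' @return p-value in (0, 1].
#' @export
fisher_one_sided <- function(a, b, c, d, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative counts")
  if (any(cells != round(cells))) stop("counts must be integers")
  tab <- matrix(as.integer(round(cells)), nrow = 2, byrow = TRUE)
  if (sum(tab) == 0L || any(rowSums(tab) == 0L) || all(colSums(tab) == 0L))
    return(1)
  stats::fisher.test(tab, alternative = direction)$p.value
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at
#' 1 and invariant to input order.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return q-values in the same order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

haldane_or <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Test elements for riboSNitch enrichment and depletion
#'
#' For every element, compares the observed riboSNitch contingency
#' `[obs_ribo, obs_total - obs_ribo]` with the simulated expectation
#' `[exp_ribo, exp_total - exp_ribo]` by one-sided Fisher's exact tests in
#' both directions. BH correction is applied within each element class and
#' direction separately. Elements present in only one of the two inputs are
#' flagged and excluded.
#'
#' @param observed data.frame with `element_id`, `element_class`
#'   (`5UTR`/`3UTR`/`lncRNA`), `obs_ribo`, `obs_total`.
#' @param expected data.frame with `element_id`, `exp_ribo`, `exp_total`
#'   (e.g. `per_element` from [expected_ribo_count()]).
#' @param q_cutoffs Cutoffs at which a direction call is reported.
#' @return data.frame with counts, Haldane-corrected odds ratio,
#'   `p_enriched`, `p_depleted`, `q_enriched`, `q_depleted` and a
#'   `call_q<cutoff>` column per cutoff (`"enriched"`, `"depleted"` or
#'   `"none"`). Attribute `excluded` lists unmatched element ids.
#' @export
test_elements <- function(observed, expected,
                          q_cutoffs = c(0.05, 0.1, 0.2)) {
  only_obs <- setdiff(observed$element_id, expected$element_id)
  only_exp <- setdiff(expected$element_id, observed$element_id)
  if (length(only_obs))
    warning("elements without expectation excluded: ",
            paste(only_obs, collapse = ","))
  m <- merge(observed, expected[, c("element_id", "exp_ribo", "exp_total")],
             by = "element_id")
  if (nrow(m) == 0L) stop("no elements shared between observed and expected")
  m$odds_ratio <- mapply(haldane_or, m$obs_ribo, m$obs_total - m$obs_ribo,
                         m$exp_ribo, m$exp_total - m$exp_ribo)
  m$p_enriched <- mapply(function(a, b, c, d) fisher_one_sided(a, b, c, d, "greater"),
                         m$obs_ribo, m$obs_total - m$obs_ribo,
                         m$exp_ribo, m$exp_total - m$exp_ribo)
  m$p_depleted <- mapply(function(a, b, c, d) fisher_one_sided(a, b, c, d, "less"),
                         m$obs_ribo, m$obs_total - m$obs_ribo,
                         m$exp_ribo, m$exp_total - m$exp_ribo)
  m$q_enriched <- NA_real_; m$q_depleted <- NA_real_
  for (cl in unique(m$element_class)) {
    sel <- m$element_class == cl
    m$q_enriched[sel] <- bh_adjust(m$p_enriched[sel])
    m$q_depleted[sel] <- bh_adjust(m$p_depleted[sel])
  }
  for (qc in q_cutoffs) {
    call <- rep("none", nrow(m))
    call[m$q_enriched < qc] <- "enriched"
    call[m$q_depleted < qc & m$q_enriched >= qc] <- "depleted"
    m[[sprintf("call_q%g", qc)]] <- call
  }
  attr(m, "excluded") <- list(observed_only = only_obs,
                              expected_only = only_exp)
  m
}

#' Cancer-specificity test for one element
#'
#' One-sided Fisher's exact test comparing the riboSNitch fraction of an
#' element between a somatic and a germline cohort, each called with its own
#' cohort cutoffs. An element is cancer-specific when p is strictly below
#' `1e-3`.
#'
#' @param ribo_cancer,total_cancer Somatic riboSNitch / total counts.
#' @param ribo_germline,total_germline Germline counts.
#' @param direction `"greater"` tests excess riboSNitch fraction in cancer
#'   (enriched elements); use `"less"` for depleted elements.
#' @param p_threshold Specificity threshold (strict inequality).
#' @return List with `p` and logical `is_specific`.
#' @export
cancer_specific_test <- function(ribo_cancer, total_cancer, ribo_germline,
                                 total_germline,
                                 direction = c("greater", "less"),
                                 p_threshold = 1e-3) {
  direction <- match.arg(direction)
  if (total_cancer == 0 || total_germline == 0)
    return(list(p = 1, is_specific = FALSE))
  p <- fisher_one_sided(ribo_cancer, total_cancer - ribo_cancer,
                        ribo_germline, total_germline - ribo_germline,
                        direction)
  list(p = p, is_specific = p < p_threshold)
}

#' Binding-site overlap enrichment of riboSNitches
#'
#' Tests whether riboSNitches fall inside (padded) binding-site intervals
#' more often than non-riboSNitches: one-sided Fisher's exact test on the
#' 2x2 table label x containment.
#'
#' @param calls data.frame with genomic `chrom`, 1-based `pos` and a `label`
#'   column containing `"ribosnitch"` / `"non_ribosnitch"` (intermediate
#'   rows are ignored).
#' @param features Binding sites: `GRanges`, or data.frame with `chrom`,
#'   `start`, `end` (0-based half-open, BED semantics).
#' @param pad Padding in nt added to both sides of every feature
#'   (default 20).
#' @param direction `"greater"` tests enrichment of riboSNitches inside
#'   features.
#' @return List with `odds_ratio`, `p` and the 2x2 `table`.
#' @export
feature_overlap_enrichment <- function(calls, features, pad = 20L,
                                       direction = c("greater", "less")) {
  direction <- match.arg(direction)
  lab <- as.character(calls$label)
  keep <- lab %in% c("ribosnitch", "non_ribosnitch")
  calls <- calls[keep, , drop = FALSE]; lab <- lab[keep]
  if (nrow(calls) == 0L) stop("no labeled mutations")
  if (is.data.frame(features)) {
    features <- GenomicRanges::GRanges(
      features$chrom,
      IRanges::IRanges(start = features$start + 1L, end = features$end))
  }
  padded <- GenomicRanges::resize(features,
                                  GenomicRanges::width(features) + 2L * pad,
                                  fix = "center")
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$pos, width = 1L))
  inside <- GenomicRanges::countOverlaps(gr, padded, ignore.strand = TRUE) > 0L
  a <- sum(lab == "ribosnitch" & inside)
  b <- sum(lab == "ribosnitch" & !inside)
  c <- sum(lab == "non_ribosnitch" & inside)
  d <- sum(lab == "non_ribosnitch" & !inside)
  list(odds_ratio = haldane_or(a, b, c, d),
       p = fisher_one_sided(a, b, c, d, direction),
       table = matrix(c(a, b, c, d), 2, byrow = TRUE,
                      dimnames = list(c("ribosnitch", "non_ribosnitch"),
                                      c("inside", "outside"))))
}
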