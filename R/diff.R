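#' Windowed mean absolute difference between pairedness profiles
#'
#' \deqn{MeanDiff_k = \sum_{i=k-w}^{k+w} |BPP_{ref,i} - BPP_{alt,i}| / (2w+1)}
#' The window is clipped at sequence ends and the sum is divided by the
#' number of positions actually covered (`effective_positions`), so the
#' statistic remains an average for mutations near transcript ends.
#'
#' @param bpp_ref,bpp_alt Numeric pairedness vectors of equal length (or
#'   `pairedness_profile` objects).
#' @param k 0-based mutation position.
#' @param w Half-window in nt (`w = 0` reduces to the single-site
#'   difference).
#' @return Non-negative scalar in \[0, 1\].
#' @export
mean_diff <- function(bpp_ref, bpp_alt, k, w) {
  v <- diff_window(bpp_ref, bpp_alt, k, w)
  mean(abs(v))
}

#' Windowed Euclidean difference between pairedness profiles
#'
#' \deqn{EucDiff_k = \sqrt{\sum_{i=k-w}^{k+w} (BPP_{ref,i} - BPP_{alt,i})^2}}
#' with the same end-clipping as [mean_diff()].
#'
#' @inheritParams mean_diff
#' @return Non-negative scalar, at most `sqrt(effective_positions)`.
#' @export
euc_diff <- function(bpp_ref, bpp_alt, k, w) {
  v <- diff_window(bpp_ref, bpp_alt, k, w)
  sqrt(sum(v^2))
}

diff_window <- function(bpp_ref, bpp_alt, k, w) {
  if (inherits(bpp_ref, "pairedness_profile")) bpp_ref <- bpp_ref$bpp
  if (inherits(bpp_alt, "pairedness_profile")) bpp_alt <- bpp_alt$bpp
  n <- length(bpp_ref)
  if (length(bpp_alt) != n) stop("profile length mismatch")
  if (k < 0 || k >= n) stop("k out of range")
  if (w < 0) stop("w must be >= 0")
  idx <- max(0L, k - w):min(n - 1L, k + w)
  bpp_ref[idx + 1L] - bpp_alt[idx + 1L]
}

effective_positions <- function(n, k, w) {
  min(n - 1L, k + w) - max(0L, k - w) + 1L
}

#' Score one mapped mutation
#'
#' Folds the reference and the mutated mature sequence under an identical
#' configuration and evaluates both difference statistics around the
#' mutation site. When the sequence exceeds the folding window, only the
#' sliding windows containing the mutated base can contribute a non-zero
#' profile difference, so the computation is restricted to those windows
#' (normalizing by the full per-position window coverage); this is exactly
#' equal to differencing two full window-averaged profiles.
#'
#' @param transcript_seq Mature reference sequence.
#' @param k 0-based mutation position in the mature sequence.
#' @param alt_t Alternative base on the transcript strand.
#' @param config A [fold_config()].
#' @param w Half-window for the difference statistics.
#' @param ref_profile Optional precomputed reference profile (reused across
#'   mutations on one transcript when the sequence fits in one window).
#' @return One-row data.frame: `k`, `w`, `effective_positions`, `mean_diff`,
#'   `euc_diff`.
#' @export
score_mutation <- function(transcript_seq, k, alt_t, config = fold_config(),
                           w = 25L, ref_profile = NULL) {
  n <- nchar(transcript_seq)
  if (substr(transcript_seq, k + 1L, k + 1L) == toupper(alt_t))
    stop("not a variant: base at k already equals alt")
  if (config$backend == "internal" && n > config$window_W) {
    d <- local_diff_vector(transcript_seq, k, alt_t, config, w)
  } else {
    if (is.null(ref_profile))
      ref_profile <- pairedness_profile(transcript_seq, config)
    alt_profile <- pairedness_profile(mutate_sequence(transcript_seq, k, alt_t),
                                      config)
    d <- diff_window(ref_profile, alt_profile, k, w)
  }
  data.frame(k = k, w = w, effective_positions = length(d),
             mean_diff = mean(abs(d)), euc_diff = sqrt(sum(d^2)))
}

# Difference restricted to fold windows containing k (others cancel exactly).
local_diff_vector <- function(transcript_seq, k, alt_t, config, w) {
  s_ref <- encode_seq(transcript_seq)
  n <- length(s_ref)
  W <- config$window_W
  s_alt <- s_ref
  s_alt[k + 1L] <- BASE_CODE[[toupper(alt_t)]]
  lo <- max(0L, k - w); hi <- min(n - 1L, k + w)
  acc <- numeric(hi - lo + 1L)
  starts <- max(0L, k - W + 1L):min(n - W, k)         # 0-based window starts
  for (st in starts) {
    idx <- (st + 1L):(st + W)
    dwin <- .fold_bpp_cpp(s_ref[idx], config$min_hairpin, config$max_span_L,
                          config$pair_weight, config$stack_bonus) -
            .fold_bpp_cpp(s_alt[idx], config$min_hairpin, config$max_span_L,
                          config$pair_weight, config$stack_bonus)
    ov <- intersect(lo:hi, st:(st + W - 1L))
    if (length(ov))
      acc[ov - lo + 1L] <- acc[ov - lo + 1L] + dwin[ov - st + 1L]
  }
  # total coverage counts every window, contributing or not
  cov <- vapply(lo:hi, function(i) {
    min(i, n - W) - max(0L, i - W + 1L) + 1L
  }, numeric(1))
  acc / cov
}

#' Score a table of mapped mutations
#'
#' Batch wrapper around [score_mutation()]: scores every exonic mapped
#' mutation of one transcript against its mature sequence, reusing the
#' reference fold.
#'
#' @param mapped data.frame from [map_mutations()] (one transcript).
#' @param transcript_seq The transcript's mature sequence.
#' @inheritParams score_mutation
#' @return `mapped` with `w`, `effective_positions`, `mean_diff`,
#'   `euc_diff` columns appended; intronic rows are dropped.
#' @export
score_mutations <- function(mapped, transcript_seq, config = fold_config(),
                            w = 25L) {
  ex <- mapped[!is.na(mapped$k), , drop = FALSE]
  if (nrow(ex) == 0L) return(cbind(ex, w = numeric(0),
                                   effective_positions = numeric(0),
                                   mean_diff = numeric(0), euc_diff = numeric(0)))
  ref_profile <- if (nchar(transcript_seq) <= config$window_W &&
                     config$backend == "internal")
    pairedness_profile(transcript_seq, config) else NULL
  sc <- do.call(rbind, lapply(seq_len(nrow(ex)), function(i) {
    score_mutation(transcript_seq, ex$k[i], ex$alt_t[i], config, w,
                   ref_profile = ref_profile)
  }))
  ex$w <- sc$w
  ex$effective_positions <- sc$effective_positions
  ex$mean_diff <- sc$mean_diff
  ex$euc_diff <- sc$euc_diff
  ex
}
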