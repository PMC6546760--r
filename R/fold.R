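#' Folding configuration
#'
#' Parameters controlling the base-pair-probability backend. The internal
#' backend is a pair-weight partition function over all pseudoknot-free
#' structures with canonical pairs (A-T, G-C, G-T): every admissible pair
#' contributes a constant Boltzmann weight (`pair_weight`), optionally with a
#' stacking bonus for helix continuation (`pair_weight_model = "stack"`).
#' It is deliberately not a nearest-neighbour thermodynamic model: it is
#' exactly verifiable against exhaustive structure enumeration
#' ([enumerate_structures()]), which makes the whole scoring pipeline
#' testable at desk scale. For thermodynamic numbers use the
#' `"rnaplfold"` backend, which shells out to (or parses the output of)
#' RNAplfold.
#'
#' @param window_W Local folding window length in nt. Sequences longer than
#'   `window_W` are folded in all sliding windows of this length and
#'   per-position pairedness is averaged over covering windows; shorter
#'   sequences are folded globally. Default 200.
#' @param max_span_L Maximal base-pair span, counted as `j - i + 1` for a
#'   pair `(i, j)`. Defaults to `window_W`.
#' @param min_hairpin Minimal number of unpaired bases closed by a pair
#'   (hairpin loop size). Default 3.
#' @param pair_weight Multiplicative weight per base pair in the internal
#'   model. Default 2: pairing is favoured over the open chain without
#'   freezing the ensemble.
#' @param pair_weight_model `"uniform"` (constant weight per pair) or
#'   `"stack"` (additional `stack_bonus` for a pair whose immediate inner
#'   neighbour is also paired).
#' @param stack_bonus Helix-continuation bonus for the `"stack"` model.
#' @param backend `"internal"` or `"rnaplfold"`.
#' @return An object of class `fold_config`.
#' @export
fold_config <- function(window_W = 200L, max_span_L = window_W,
                        min_hairpin = 3L, pair_weight = 2,
                        pair_weight_model = c("uniform", "stack"),
                        stack_bonus = 2, backend = c("internal", "rnaplfold")) {
  pair_weight_model <- match.arg(pair_weight_model)
  backend <- match.arg(backend)
  window_W <- as.integer(window_W)
  max_span_L <- as.integer(max_span_L)
  if (window_W < 1L) stop("window_W must be >= 1")
  if (max_span_L < 1L || max_span_L > window_W)
    stop("require 1 <= max_span_L <= window_W")
  if (min_hairpin < 0L) stop("min_hairpin must be >= 0")
  if (pair_weight <= 0) stop("pair_weight must be positive")
  structure(list(window_W = window_W, max_span_L = max_span_L,
                 min_hairpin = as.integer(min_hairpin),
                 pair_weight = pair_weight,
                 pair_weight_model = pair_weight_model,
                 stack_bonus = if (pair_weight_model == "stack") stack_bonus else 1,
                 backend = backend),
            class = "fold_config")
}

#' @export
print.fold_config <- function(x, ...) {
  cat("fold_config: W=", x$window_W, " L=", x$max_span_L,
      " min_hairpin=", x$min_hairpin, " w=", x$pair_weight,
      " model=", x$pair_weight_model, " backend=", x$backend, "\n", sep = "")
  invisible(x)
}

BASE_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L, U = 3L)

encode_seq <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  code <- BASE_CODE[chars]
  if (anyNA(code)) stop("sequence contains non-ACGTN characters: ",
                        paste(unique(chars[is.na(code)]), collapse = ","))
  unname(code)
}

#' Per-position pairedness profile
#'
#' Computes, for every position of a sequence, the probability that it is
#' base-paired in the structure ensemble. For sequences longer than the
#' folding window `window_W`, each sliding window of length `window_W` is
#' folded independently and a position's value is the average over all
#' windows covering it (edge positions are covered by fewer windows and are
#' averaged over those only).
#'
#' @param sequence Nucleotide string over A/C/G/T/N (U accepted as T).
#' @param config A [fold_config()]. For `backend = "rnaplfold"` the RNAplfold
#'   executable must be on the PATH; see [read_plfold_lunp()] to ingest
#'   precomputed output instead.
#' @param sequence_id Identifier stored in the returned profile.
#' @return An object of class `pairedness_profile`: a list with
#'   `sequence_id`, `bpp` (numeric vector in \[0,1\]) and the config used.
#' @export
pairedness_profile <- function(sequence, config = fold_config(),
                               sequence_id = "seq") {
  if (!inherits(config, "fold_config")) stop("config must be a fold_config")
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop("sequence must be a non-empty string")
  bpp <- switch(config$backend,
    internal = bpp_internal(sequence, config),
    rnaplfold = bpp_rnaplfold(sequence, config),
    stop("unknown backend: ", config$backend))
  new_profile(sequence_id, bpp, config)
}

new_profile <- function(sequence_id, bpp, config) {
  stopifnot(all(bpp >= -1e-12), all(bpp <= 1 + 1e-12))
  structure(list(sequence_id = sequence_id,
                 bpp = pmin(pmax(bpp, 0), 1),
                 config = config),
            class = "pairedness_profile")
}

bpp_internal <- function(sequence, config) {
  s <- encode_seq(sequence)
  n <- length(s)
  W <- config$window_W
  if (n <= W) {
    return(.fold_bpp_cpp(s, config$min_hairpin, min(config$max_span_L, n),
                         config$pair_weight, config$stack_bonus))
  }
  acc <- numeric(n)
  cov <- numeric(n)
  for (start in 1:(n - W + 1L)) {
    idx <- start:(start + W - 1L)
    acc[idx] <- acc[idx] + .fold_bpp_cpp(s[idx], config$min_hairpin,
                                         config$max_span_L,
                                         config$pair_weight, config$stack_bonus)
    cov[idx] <- cov[idx] + 1
  }
  acc / cov
}

#' Substitute a single base
#'
#' @param sequence Nucleotide string.
#' @param k 0-based position to mutate.
#' @param alt Replacement base; must differ from the current base.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(sequence, k, alt) {
  n <- nchar(sequence)
  if (k < 0 || k >= n) stop("k out of range")
  alt <- toupper(alt)
  if (substr(sequence, k + 1L, k + 1L) == alt) stop("not a variant: base at k already equals alt")
  substr(sequence, k + 1L, k + 1L) <- alt
  sequence
}

#' Enumerate all secondary structures (verification oracle)
#'
#' Exhaustively lists every pseudoknot-free structure of a short sequence
#' under the same pairing rules as the internal backend, with its Boltzmann
#' weight. Intended as an independent oracle for the partition-function
#' recursions; guarded to short sequences.
#'
#' @param sequence Nucleotide string, at most 20 nt.
#' @param config A [fold_config()]; `window_W`/`max_span_L` larger than the
#'   sequence mean an unconstrained span.
#' @return A list with `structures` (list of integer matrices, one row per
#'   pair, 0-based columns i, j), `weights` (numeric), and `Z` (their sum).
#' @export
enumerate_structures <- function(sequence, config = fold_config()) {
  s <- encode_seq(sequence)
  n <- length(s)
  if (n > 20L) stop("enumeration guarded to sequences of length <= 20")
  mh <- config$min_hairpin
  span <- min(config$max_span_L, n)
  ok <- function(i, j) {
    (j - i - 1L) >= mh && (j - i + 1L) <= span && pairable_codes(s[i + 1L], s[j + 1L])
  }
  # structures on [i, j] (0-based inclusive); returns list of pair matrices
  enum <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2)))
    out <- enum(i + 1L, j)                      # i unpaired
    for (k in seq.int(i + 1L, j)) {
      if (!ok(i, k)) next
      left <- enum(i + 1L, k - 1L)
      right <- enum(k + 1L, j)
      for (a in left) for (b in right) {
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
      }
    }
    out
  }
  structures <- enum(0L, n - 1L)
  weights <- vapply(structures, function(m) {
    np <- nrow(m)
    w <- config$pair_weight ^ np
    if (config$stack_bonus != 1 && np > 1L) {
      key <- paste(m[, 1], m[, 2])
      nstack <- sum(paste(m[, 1] + 1L, m[, 2] - 1L) %in% key)
      w <- w * config$stack_bonus ^ nstack
    }
    w
  }, numeric(1))
  list(structures = structures, weights = weights, Z = sum(weights))
}

pairable_codes <- function(a, b) {
  if (a > b) { t <- a; a <- b; b <- t }
  (a == 0L && b == 3L) || (a == 1L && b == 2L) || (a == 2L && b == 3L)
}

#' Pair frequencies from exhaustive enumeration
#'
#' Boltzmann-weighted probability that each position is paired, derived from
#' [enumerate_structures()]. Independent of the partition-function recursion.
#'
#' @inheritParams enumerate_structures
#' @return Numeric vector of per-position pairedness.
#' @export
enumeration_bpp <- function(sequence, config = fold_config()) {
  en <- enumerate_structures(sequence, config)
  n <- nchar(sequence)
  acc <- numeric(n)
  for (idx in seq_along(en$structures)) {
    m <- en$structures[[idx]]
    if (nrow(m) == 0L) next
    pos <- c(m[, 1], m[, 2]) + 1L
    acc[pos] <- acc[pos] + en$weights[idx]
  }
  acc / en$Z
}

#' Parse RNAplfold unpaired-probability output
#'
#' Reads the `_lunp` text format produced by `RNAplfold -u`, and returns the
#' pairedness profile `1 - P(unpaired)` taken from the u = 1 column.
#'
#' @param path Path to a `_lunp` file.
#' @param sequence_id Identifier stored in the profile.
#' @return A `pairedness_profile`.
#' @export
read_plfold_lunp <- function(path, sequence_id = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data rows in ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  pos <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 1L)))
  p_unp <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  bad <- is.na(pos) | is.na(p_unp) | p_unp < 0 | p_unp > 1
  if (any(bad)) stop("malformed _lunp rows: ", paste(which(bad), collapse = ","))
  if (!identical(pos, seq_along(pos))) stop("positions not contiguous from 1")
  new_profile(sequence_id, 1 - p_unp, fold_config(backend = "rnaplfold",
                                                  window_W = max(200L, length(pos))))
}

bpp_rnaplfold <- function(sequence, config) {
  exe <- Sys.which("RNAplfold")
  if (!nzchar(exe)) stop("RNAplfold not found on PATH")
  dir <- tempfile("plfold")
  dir.create(dir)
  old <- setwd(dir); on.exit({ setwd(old); unlink(dir, recursive = TRUE) })
  writeLines(c(">q", sequence), "in.fa")
  status <- system2(exe, c("-W", config$window_W, "-L", config$max_span_L,
                           "-u", "1"), stdin = "in.fa", stdout = FALSE,
                    stderr = FALSE)
  if (status != 0L) stop("RNAplfold failed with status ", status)
  read_plfold_lunp("q_lunp", sequence_id = "q")$bpp
}
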