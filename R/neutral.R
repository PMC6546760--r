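#' Build the 96-category neutral mutation profile from intronic mutations
#'
#' Intronic mutations are taken as selectively neutral; their strand-collapsed
#' substitution class counts define the background substitution process.
#' `"frequency"` normalization divides the 96 class counts by their total;
#' `"per_context_rate"` divides each class count by the number of intronic
#' occurrences of that class's trinucleotide context.
#'
#' @param intronic_mutations data.frame of mapped mutations (rows with
#'   `region == "intron"` and a non-`NA` `subst_class96`); other rows are
#'   ignored with a warning.
#' @param intronic_context_counts 32-vector of intronic trinucleotide context
#'   occurrence counts (required for `per_context_rate`), e.g. from
#'   [intron_composition()].
#' @param normalization `"frequency"` or `"per_context_rate"`.
#' @param source_cohort Provenance label.
#' @return Object of class `mutation_profile`: list with `rate` (96-vector,
#'   named by [subst_class_labels()]), `counts`, `normalization`,
#'   `source_cohort`.
#' @export
build_profile <- function(intronic_mutations, intronic_context_counts = NULL,
                          normalization = c("frequency", "per_context_rate"),
                          source_cohort = "cohort") {
  normalization <- match.arg(normalization)
  keep <- !is.na(intronic_mutations$subst_class96)
  if ("region" %in% names(intronic_mutations)) {
    nonint <- intronic_mutations$region != "intron"
    if (any(nonint, na.rm = TRUE)) {
      warning("dropping ", sum(nonint, na.rm = TRUE), " non-intronic rows")
      keep <- keep & !nonint
    }
  }
  cls <- intronic_mutations$subst_class96[keep]
  counts <- tabulate(cls + 1L, nbins = 96L)
  if (sum(counts) == 0L) stop("no classified intronic mutations")
  if (normalization == "frequency") {
    rate <- counts / sum(counts)
  } else {
    if (is.null(intronic_context_counts))
      stop("per_context_rate needs intronic_context_counts")
    ctx <- as.numeric(intronic_context_counts)
    if (length(ctx) != 32L) stop("intronic_context_counts must have length 32")
    ctx96 <- ctx[context_of_class96(0:95) + 1L]
    if (any(counts > 0 & ctx96 == 0))
      stop("observed mutation class with zero context count")
    rate <- ifelse(ctx96 > 0, counts / ctx96, 0)
  }
  structure(list(rate = setNames(rate, subst_class_labels()),
                 counts = setNames(counts, subst_class_labels()),
                 normalization = normalization,
                 source_cohort = source_cohort),
            class = "mutation_profile")
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("mutation_profile [%s] %s, %d mutations, %d/96 classes seen\n",
              x$source_cohort, x$normalization, sum(x$counts),
              sum(x$counts > 0)))
  invisible(x)
}

#' 32-category trinucleotide composition of a sequence
#'
#' Slides a 3-mer window over the sequence, strand-collapses each context to
#' a pyrimidine center and counts occurrences per class. 3-mers containing N
#' are skipped. For an N-free sequence of length L the counts sum to L - 2.
#'
#' @param sequence Nucleotide string, length >= 3.
#' @return Integer 32-vector named by [context_class_labels()].
#' @export
transcript_composition <- function(sequence) {
  n <- nchar(sequence)
  if (n < 3L) stop("sequence shorter than 3 nt")
  s <- toupper(sequence)
  tri <- substring(s, 1:(n - 2L), 3:n)
  classify_context(tri)
}

classify_context <- function(tri) {
  counts <- integer(32L)
  ok <- !grepl("[^ACGT]", tri)
  tri <- tri[ok]
  if (length(tri)) {
    mid <- substr(tri, 2, 2)
    flip <- mid %in% c("A", "G")
    tri[flip] <- revcomp(tri[flip])
    c_idx <- match(substr(tri, 2, 2), c("C", "T")) - 1L
    f_idx <- match(substr(tri, 1, 1), BASES) - 1L
    t_idx <- match(substr(tri, 3, 3), BASES) - 1L
    cls <- c_idx * 16L + f_idx * 4L + t_idx
    counts <- tabulate(cls + 1L, nbins = 32L)
  }
  setNames(as.integer(counts), context_class_labels())
}

#' Intronic trinucleotide composition of a transcript
#'
#' Counts strand-collapsed 3-mer contexts over the transcript's intron
#' sequences (gaps between consecutive exons). Collapse makes the counts
#' strand-invariant, so genome-strand sequence is used directly.
#'
#' @param transcript A [transcript()].
#' @param genome Named character vector from [read_genome()].
#' @return Integer 32-vector (all zero for single-exon transcripts).
#' @export
intron_composition <- function(transcript, genome) {
  ex <- transcript$exons
  if (nrow(ex) < 2L)
    return(setNames(integer(32L), context_class_labels()))
  chrom <- chrom_seq(genome, transcript$chrom)
  total <- integer(32L)
  for (i in seq_len(nrow(ex) - 1L)) {
    lo <- ex[i, 2]; hi <- ex[i + 1L, 1]           # 0-based half-open gap
    if (hi - lo >= 3L)
      total <- total + classify_context(
        substring(chrom, (lo + 1L):(hi - 2L), (lo + 3L):hi))
  }
  setNames(as.integer(total), context_class_labels())
}

#' Recalibrate the neutral profile to a transcript's composition
#'
#' The probability of drawing substitution class c on this transcript is
#' proportional to `rate[c] * composition[context(c)]`: the background
#' substitution propensity weighted by how often the class's trinucleotide
#' context occurs in the sequence. Classes whose context is absent get
#' probability zero.
#'
#' @param profile A [build_profile()] result.
#' @param composition 32-vector from [transcript_composition()].
#' @return Numeric 96-vector summing to 1.
#' @export
recalibrate_profile <- function(profile, composition) {
  if (!inherits(profile, "mutation_profile")) stop("need a mutation_profile")
  comp <- as.numeric(composition)
  if (length(comp) != 32L) stop("composition must have length 32")
  p <- profile$rate * comp[context_of_class96(0:95) + 1L]
  tot <- sum(p)
  if (tot <= 0) stop("transcript incompatible with profile (all-zero product)")
  setNames(p / tot, subst_class_labels())
}

#' Simulate a neutral mutation cohort on a transcript
#'
#' Each simulated mutation draws a substitution class from `distribution`,
#' then a uniform position among the sequence sites whose strand-collapsed
#' trinucleotide context matches that class, then applies the class's
#' alternative allele (complemented back when the site's center is a
#' purine). Sites may be restricted to a mature-coordinate interval
#' (element simulation). Reproducible under `set.seed()`.
#'
#' @param sequence Mature transcript sequence.
#' @param distribution 96-vector of class probabilities from
#'   [recalibrate_profile()] (renormalized over classes with at least one
#'   matching site in the chosen interval).
#' @param n Number of mutations to draw.
#' @param interval Optional 0-based half-open `c(start, end)` restriction on
#'   mutated positions.
#' @return data.frame with 0-based `k`, `ref_t`, `alt_t`, `subst_class96`.
#' @export
simulate_mutations <- function(sequence, distribution, n,
                               interval = NULL) {
  L <- nchar(sequence)
  pos1 <- 2:(L - 1L)                              # 1-based centers with context
  if (!is.null(interval))
    pos1 <- pos1[pos1 - 1L >= interval[1] & pos1 - 1L < interval[2]]
  if (length(pos1) == 0L) stop("no eligible sites in interval")
  tri <- substring(sequence, pos1 - 1L, pos1 + 1L)
  ok <- !grepl("[^ACGT]", tri)
  pos1 <- pos1[ok]; tri <- tri[ok]
  if (length(pos1) == 0L) stop("no eligible N-free sites")
  mid <- substr(tri, 2, 2)
  flip <- mid %in% c("A", "G")
  ctri <- tri; ctri[flip] <- revcomp(tri[flip])
  cls32 <- (match(substr(ctri, 2, 2), c("C", "T")) - 1L) * 16L +
    (match(substr(ctri, 1, 1), BASES) - 1L) * 4L +
    (match(substr(ctri, 3, 3), BASES) - 1L)
  sites_by_ctx <- split(seq_along(pos1), cls32)

  p <- as.numeric(distribution)
  ctx96 <- context_of_class96(0:95)
  p[!(as.character(ctx96) %in% names(sites_by_ctx))] <- 0
  if (sum(p) <= 0) stop("distribution has no support on eligible sites")
  p <- p / sum(p)

  cls_draw <- sample.int(96L, n, replace = TRUE, prob = p) - 1L
  alt_coll <- alt_of_class96(cls_draw)
  out_k <- integer(n); out_ref <- character(n); out_alt <- character(n)
  for (i in seq_len(n)) {
    cand <- sites_by_ctx[[as.character(ctx96[cls_draw[i] + 1L])]]
    j <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    out_k[i] <- pos1[j] - 1L                      # 0-based
    out_ref[i] <- mid[j]
    out_alt[i] <- if (flip[j]) COMP[[alt_coll[i]]] else alt_coll[i]
  }
  data.frame(k = out_k, ref_t = out_ref, alt_t = out_alt,
             subst_class96 = cls_draw, stringsAsFactors = FALSE)
}

#' Score a simulated cohort and count expected riboSNitches
#'
#' Pools simulated scores, derives tail cutoffs on the pooled simulated
#' distribution (the simulated cohort is calibrated against itself, not
#' against the observed cohort) and counts riboSNitch calls per element and
#' in total.
#'
#' @param simulated_scores data.frame of scores with an `element_id` column.
#' @param top_fraction,bottom_fraction Tail fractions (see
#'   [compute_cutoffs()]).
#' @return List with `cutoffs`, `calls`, `per_element` (data.frame
#'   `element_id`, `exp_ribo`, `exp_total`), `expected_ribo`,
#'   `expected_total`.
#' @export
expected_ribo_count <- function(simulated_scores, top_fraction = 0.025,
                                bottom_fraction = 0.025) {
  cutoffs <- compute_cutoffs(simulated_scores, top_fraction, bottom_fraction,
                             cohort_label = "simulated")
  calls <- call_ribosnitches(simulated_scores, cutoffs)
  ribo <- calls == "ribosnitch"
  per <- data.frame(
    element_id = names(split(ribo, simulated_scores$element_id)),
    exp_ribo = as.integer(vapply(split(ribo, simulated_scores$element_id),
                                 sum, numeric(1))),
    exp_total = as.integer(table(simulated_scores$element_id)[
      names(split(ribo, simulated_scores$element_id))]),
    stringsAsFactors = FALSE, row.names = NULL)
  list(cutoffs = cutoffs, calls = calls, per_element = per,
       expected_ribo = sum(ribo), expected_total = length(ribo))
}
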