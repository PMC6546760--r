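# Independent oracles and small builders shared across the test files.
# Every oracle here is written from the definition, never by calling the
# package routine it is meant to check.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# the folding/diff configuration used for fixture-scale studies
study_config <- function() {
  fold_config(max_span_L = 50L, pair_weight_model = "stack", stack_bonus = 8)
}

# literal-loop re-implementations of the windowed difference statistics
meandiff_literal <- function(r, a, k, w) {
  tot <- 0; m <- 0L
  for (i in (k - w):(k + w)) {
    if (i >= 0 && i < length(r)) { tot <- tot + abs(r[i + 1] - a[i + 1]); m <- m + 1L }
  }
  tot / m
}

eucdiff_literal <- function(r, a, k, w) {
  tot <- 0
  for (i in (k - w):(k + w)) {
    if (i >= 0 && i < length(r)) tot <- tot + (r[i + 1] - a[i + 1])^2
  }
  sqrt(tot)
}

# one-sided Fisher p by explicit enumeration of all tables with the
# observed margins, using binomial coefficients only
fisher_brute <- function(a, b, c, d, direction = "greater") {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  weight <- choose(r1, xs) * choose(r2, c1 - xs)
  prob <- weight / sum(weight)
  if (direction == "greater") sum(prob[xs >= a]) else sum(prob[xs <= a])
}

# BH step-up from the definition
bh_literal <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- running
  }
  q
}

# AUC by exhaustive pairwise comparison (Mann-Whitney definition)
auc_brute <- function(scores, positive) {
  p <- scores[positive]; n <- scores[!positive]
  mean(outer(p, n, function(x, y) (x > y) + 0.5 * (x == y)))
}

# a small two-exon plus/minus-strand transcript over an explicit genome
tiny_genome <- function(seq, chrom = "chrT") setNames(seq, chrom)

tiny_transcript <- function(exons, strand = "+", biotype = "protein_coding",
                            id = "T1", gene = "GX", regions = NULL, ...) {
  transcript(transcript_id = id, gene_id = gene, gene_name = gene,
             biotype = biotype, chrom = "chrT", strand = strand,
             exons = exons, regions = regions, ...)
}
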