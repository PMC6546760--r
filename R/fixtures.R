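#' @title Synthetic fixtures: genomes, annotation, benchmarks, cohorts
#' @description Generates every input the pipeline consumes, deterministically
#'   from a seed: a toy multi-gene genome with GENCODE-style annotation, a
#'   hairpin SNV benchmark, and somatic/germline mutation cohorts drawn from
#'   a chosen 96-class neutral profile with planted riboSNitch-enriched or
#'   -depleted elements.
#' @name fixtures
NULL

# base sampling helpers -------------------------------------------------------

sample_seq <- function(n, probs) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# near-inert background: mostly A/C (a C>A substitution there neither breaks
# nor creates a canonical pair) with sparse G/T giving a weak, unstacked
# pairing background, so neutral scores form a continuum instead of a point
# mass at zero
inert_seq <- function(n) sample_seq(n, c(A = .46, C = .46, G = .04, T = .04))

# all-four-letter background used outside mature sequences (introns, gaps)
weak_seq <- function(n) sample_seq(n, c(A = .3, C = .3, G = .2, T = .2))

# G-C stem hairpin: every stem base sits in a C-centered (strand-collapsed)
# context, so a C>A-dominated neutral process keeps hitting the helix.
# Mixed (non-repetitive) arms prevent register sliding: a single broken
# pair cannot be absorbed by shifting the helix.
gc_hairpin <- function(stem = 7L, loop = 4L) {
  arm <- substr(strrep("GGCGCCG", 3L), 1L, stem)   # aperiodic, runs <= 2
  paste0(arm, sample_seq(loop, c(A = .5, C = .5)), revcomp(arm))
}

# A-T stem hairpin: no stem base is C/G-centered, so the same neutral
# process never touches the helix, while a deliberate stem substitution
# still collapses it
at_hairpin <- function(stem = 7L, loop = 4L) {
  arm <- substr(strrep("TTATAAT", 3L), 1L, stem)
  paste0(arm, strrep("C", loop), revcomp(arm))
}

# element sequences by selective role ------------------------------------------
# The roles differ only in how the element's structure intersects the
# neutral substitution spectrum:
#   null:     inert A/C sequence -> neutral mutations are structurally silent
#   enriched: A-T helices in inert flanks -> neutral expectation stays ~0,
#             but stem-breaking candidate mutations exist for planting
#   depleted: G-C helices in inert flanks -> the neutral process constantly
#             breaks them, producing a high expected riboSNitch fraction
element_seq <- function(len, role) {
  if (role %in% c("enriched", "depleted")) {
    # depleted elements carry one extra helix: most of their C/G sites are
    # stem sites, so the neutral process keeps a high expected fraction
    hp <- if (role == "enriched") c(at_hairpin(), at_hairpin())
      else c(gc_hairpin(loop = 3L), gc_hairpin(loop = 3L),
             gc_hairpin(loop = 3L))
    flank_len <- len - sum(nchar(hp))
    sizes <- diff(round(seq(0, flank_len, length.out = length(hp) + 2L)))
    # enriched flanks are strictly A/C: a C>A substitution there is exactly
    # silent, so the whole neutral expectation of the element stays ~0
    flank_gen <- if (role == "enriched")
      function(n) sample_seq(n, c(A = .5, C = .5)) else inert_seq
    parts <- character(2L * length(hp) + 1L)
    parts[seq(1L, length(parts), by = 2L)] <-
      vapply(sizes, function(n) flank_gen(n), character(1))
    parts[seq(2L, length(parts), by = 2L)] <- hp
    paste(parts, collapse = "")
  } else {
    inert_seq(len)
  }
}

#' Default 96-class neutral profile for fixtures
#'
#' A single-signature substitution spectrum: all mass on the 16 C>A
#' transversion classes, uniform over flanks (a stylized version of cohorts
#' dominated by one mutational signature, as in tobacco-associated
#' tumours). The interaction of this spectrum with element base composition
#' is what gives the fixture elements their distinct neutral expectations.
#'
#' @return Numeric 96-vector summing to 1, named by [subst_class_labels()].
#' @export
default_fixture_profile <- function() {
  w <- numeric(96)
  w[0:95 %/% 16L == 0L] <- 1 / 16   # C>A block
  setNames(w, subst_class_labels())
}

#' Wrap a raw 96-vector as a mutation profile
#'
#' @param rate Non-negative 96-vector (normalized to sum 1).
#' @param source_cohort Provenance label.
#' @return A `mutation_profile` in frequency normalization.
#' @export
as_mutation_profile <- function(rate, source_cohort = "specified") {
  rate <- as.numeric(rate)
  if (length(rate) != 96L || any(rate < 0) || sum(rate) <= 0)
    stop("rate must be a non-negative 96-vector")
  structure(list(rate = setNames(rate / sum(rate), subst_class_labels()),
                 counts = setNames(integer(96), subst_class_labels()),
                 normalization = "frequency", source_cohort = source_cohort),
            class = "mutation_profile")
}

#' Fixture specification
#'
#' Bundles the parameters of the synthetic study: genome layout, element
#' sizes, the neutral substitution profile, cohort sizes and the planted
#' selection effects. The defaults are the package's reference study
#' conditions used throughout the tests.
#'
#' @param seed Integer seed; fully determines all fixture output.
#' @param n_pc_genes,n_lnc_genes Number of protein-coding / lncRNA genes.
#' @param utr_length,cds_length,lnc_length Element sizes in nt.
#' @param intron_length_range Range to draw intron lengths from.
#' @param plus_strand_prob Probability a gene sits on the + strand.
#' @param profile_96 Neutral substitution profile (96-vector).
#' @param n_mut_per_element Observed mutations drawn per unplanted element.
#' @param n_mut_planted Observed mutations per planted element.
#' @param n_intronic Intronic mutations per cohort.
#' @param planted data.frame with `slot` (`"pc_5utr"`, `"pc_3utr"`,
#'   `"lnc"`), `effect` (`"enriched"`/`"depleted"`) and `fold_effect`
#'   (target ratio of observed to expected riboSNitch fraction; > 1
#'   enriched, < 1 depleted). Slots are assigned to distinct genes in
#'   order.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_pc_genes = 14L, n_lnc_genes = 6L,
                         utr_length = 80L, cds_length = 30L,
                         lnc_length = 130L,
                         intron_length_range = c(80L, 150L),
                         plus_strand_prob = 0.5,
                         profile_96 = default_fixture_profile(),
                         n_mut_per_element = 35L, n_mut_planted = 30L,
                         n_intronic = 400L,
                         planted = data.frame(
                           slot = c("pc_5utr", "pc_3utr", "pc_3utr", "lnc"),
                           effect = c("enriched", "enriched", "depleted",
                                      "depleted"),
                           fold_effect = c(10, 10, 0.1, 0.1),
                           stringsAsFactors = FALSE)) {
  if (!is.null(planted) && nrow(planted)) {
    stopifnot(all(planted$effect %in% c("enriched", "depleted")),
              all((planted$fold_effect > 1) == (planted$effect == "enriched")))
  }
  structure(list(seed = as.integer(seed), n_pc_genes = n_pc_genes,
                 n_lnc_genes = n_lnc_genes, utr_length = utr_length,
                 cds_length = cds_length, lnc_length = lnc_length,
                 intron_length_range = intron_length_range,
                 plus_strand_prob = plus_strand_prob,
                 profile_96 = profile_96,
                 n_mut_per_element = n_mut_per_element,
                 n_mut_planted = n_mut_planted, n_intronic = n_intronic,
                 planted = planted),
            class = "fixture_spec")
}

#' Generate a toy genome and annotation
#'
#' Lays the genes of a [fixture_spec()] on one synthetic chromosome with
#' intergenic gaps, both strands, two-exon transcripts, UTR/CDS
#' sub-annotation and GENCODE-style isoform metadata. The first two
#' protein-coding genes carry decoy isoforms with strictly worse priority
#' keys (APPRIS rank, CCDS, level, length) so principal-transcript selection
#' is exercised; planted element roles are assigned to dedicated genes.
#'
#' @param spec A [fixture_spec()].
#' @return List with `genome` (named character vector), `transcripts` (all
#'   isoforms), `elements` (data.frame: `element_id`, `gene_id`,
#'   `transcript_id`, `element_class`, `start`, `end` in mature
#'   coordinates, `role`, `fold_effect`), and `spec`.
#' @export
make_genome_and_annotation <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  roles <- assign_roles(spec)
  transcripts <- list()
  elements <- list()
  segs <- character(0)
  cursor <- 0L
  chrom <- "chrS1"
  gap <- function() weak_seq(150L)

  for (g in seq_len(nrow(roles))) {
    segs <- c(segs, gap()); cursor <- cursor + 150L
    r <- roles[g, ]
    strand <- if (runif(1) < spec$plus_strand_prob) "+" else "-"
    if (r$type == "pc") {
      u5 <- element_seq(spec$utr_length, r$role_5utr)
      cds <- inert_seq(spec$cds_length)   # keeps mature-sequence neighbourhoods inert
      u3 <- element_seq(spec$utr_length, r$role_3utr)
      mature <- paste0(u5, cds, u3)
      L <- nchar(mature)
      split <- spec$utr_length + spec$cds_length %/% 2L
      ilen <- sample(spec$intron_length_range[1]:spec$intron_length_range[2], 1L)
      intr <- weak_seq(ilen)
      layout_seq <- paste0(substr(mature, 1, split), intr,
                           substr(mature, split + 1L, L))
      Lg <- L + ilen
      ex_fwd <- rbind(c(0L, split), c(split + ilen, Lg))
      regions <- data.frame(
        region = c("5UTR", "CDS", "3UTR"),
        start = c(0L, spec$utr_length, spec$utr_length + spec$cds_length),
        end = c(spec$utr_length, spec$utr_length + spec$cds_length, L),
        stringsAsFactors = FALSE)
    } else {
      mature <- element_seq(spec$lnc_length, r$role_lnc)
      L <- nchar(mature)
      split <- L %/% 2L
      ilen <- sample(spec$intron_length_range[1]:spec$intron_length_range[2], 1L)
      intr <- weak_seq(ilen)
      layout_seq <- paste0(substr(mature, 1, split), intr,
                           substr(mature, split + 1L, L))
      Lg <- L + ilen
      ex_fwd <- rbind(c(0L, split), c(split + ilen, Lg))
      regions <- NULL
    }
    if (strand == "+") {
      gseq <- layout_seq
      exons <- ex_fwd + cursor
    } else {
      gseq <- revcomp(layout_seq)
      exons <- cbind(Lg - ex_fwd[, 2], Lg - ex_fwd[, 1]) + cursor
    }
    gene_id <- sprintf("G%03d", g)
    tid <- paste0(gene_id, ".T1")
    tr <- transcript(
      transcript_id = tid, gene_id = gene_id, gene_name = gene_id,
      biotype = if (r$type == "pc") "protein_coding" else "lncRNA",
      chrom = chrom, strand = strand, exons = exons,
      appris_rank = if (r$type == "pc") 1L else NA_integer_,
      has_ccds = r$type == "pc",
      transcript_level = if (r$type == "pc") 1L else 2L,
      regions = regions)
    transcripts[[tid]] <- tr
    transcripts <- c(transcripts, decoy_isoforms(tr, g))
    elements[[length(elements) + 1L]] <- element_rows(tr, r)
    segs <- c(segs, gseq); cursor <- cursor + Lg
  }
  segs <- c(segs, gap())
  genome <- setNames(paste(segs, collapse = ""), chrom)
  el <- do.call(rbind, elements)
  rownames(el) <- NULL
  list(genome = genome, transcripts = transcripts, elements = el, spec = spec)
}

# distribute planted slots over distinct genes, remaining elements are null
assign_roles <- function(spec) {
  n <- spec$n_pc_genes + spec$n_lnc_genes
  type <- c(rep("pc", spec$n_pc_genes), rep("lnc", spec$n_lnc_genes))
  roles <- data.frame(type = type, role_5utr = "null", role_3utr = "null",
                      role_lnc = "null", fe_5utr = NA_real_,
                      fe_3utr = NA_real_, fe_lnc = NA_real_,
                      stringsAsFactors = FALSE)
  pl <- spec$planted
  if (is.null(pl) || nrow(pl) == 0L) return(roles)
  next_pc <- 3L   # genes 1-2 reserved for decoy-isoform exercises
  next_lnc <- spec$n_pc_genes + 1L
  for (i in seq_len(nrow(pl))) {
    if (pl$slot[i] == "lnc") {
      stopifnot(next_lnc <= n)
      roles$role_lnc[next_lnc] <- pl$effect[i]
      roles$fe_lnc[next_lnc] <- pl$fold_effect[i]
      next_lnc <- next_lnc + 1L
    } else {
      stopifnot(next_pc <= spec$n_pc_genes)
      col <- if (pl$slot[i] == "pc_5utr") "role_5utr" else "role_3utr"
      fcol <- if (pl$slot[i] == "pc_5utr") "fe_5utr" else "fe_3utr"
      roles[[col]][next_pc] <- pl$effect[i]
      roles[[fcol]][next_pc] <- pl$fold_effect[i]
      next_pc <- next_pc + 1L
    }
  }
  roles
}

element_rows <- function(tr, r) {
  if (tr$biotype == "protein_coding") {
    reg <- tr$regions
    u5 <- reg[reg$region == "5UTR", ]
    u3 <- reg[reg$region == "3UTR", ]
    data.frame(
      element_id = paste0(tr$gene_name, ":", c("5UTR", "3UTR")),
      gene_id = tr$gene_id, transcript_id = tr$transcript_id,
      element_class = c("5UTR", "3UTR"),
      start = c(u5$start, u3$start), end = c(u5$end, u3$end),
      role = c(r$role_5utr, r$role_3utr),
      fold_effect = c(r$fe_5utr, r$fe_3utr), stringsAsFactors = FALSE)
  } else {
    data.frame(element_id = paste0(tr$gene_name, ":lncRNA"),
               gene_id = tr$gene_id, transcript_id = tr$transcript_id,
               element_class = "lncRNA", start = 0L, end = tr$mature_length,
               role = r$role_lnc, fold_effect = r$fe_lnc,
               stringsAsFactors = FALSE)
  }
}

# genes 1 and 2 get inferior isoforms so every priority key can decide
decoy_isoforms <- function(tr, gene_index) {
  if (!gene_index %in% c(1L, 2L) || tr$biotype != "protein_coding")
    return(list())
  shorten <- function(exons, by) {
    ex <- exons
    if (tr$strand == "+") ex[nrow(ex), 2] <- ex[nrow(ex), 2] - by
    else ex[1L, 1] <- ex[1L, 1] + by
    ex
  }
  if (gene_index == 1L) {
    # distinct APPRIS ranks decide; third isoform lacks APPRIS entirely
    d1 <- transcript(paste0(tr$gene_id, ".T2"), tr$gene_id, tr$gene_name,
                     tr$biotype, tr$chrom, tr$strand, shorten(tr$exons, 20L),
                     appris_rank = 2L, has_ccds = TRUE, transcript_level = 1L)
    d2 <- transcript(paste0(tr$gene_id, ".T3"), tr$gene_id, tr$gene_name,
                     tr$biotype, tr$chrom, tr$strand, shorten(tr$exons, 40L),
                     appris_rank = NA_integer_, has_ccds = TRUE,
                     transcript_level = 1L)
    setNames(list(d1, d2), c(d1$transcript_id, d2$transcript_id))
  } else {
    # equal APPRIS: CCDS then level then length decide
    d1 <- transcript(paste0(tr$gene_id, ".T2"), tr$gene_id, tr$gene_name,
                     tr$biotype, tr$chrom, tr$strand, shorten(tr$exons, 20L),
                     appris_rank = 1L, has_ccds = FALSE,
                     transcript_level = 1L)
    d2 <- transcript(paste0(tr$gene_id, ".T3"), tr$gene_id, tr$gene_name,
                     tr$biotype, tr$chrom, tr$strand, shorten(tr$exons, 40L),
                     appris_rank = 1L, has_ccds = TRUE,
                     transcript_level = 2L)
    setNames(list(d1, d2), c(d1$transcript_id, d2$transcript_id))
  }
}

# ---- file emission ----------------------------------------------------------

#' Write fixture genome and annotation to FASTA + GTF
#'
#' @param fix Result of [make_genome_and_annotation()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`fasta`, `gtf`).
#' @export
write_fixture_files <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(fix$genome), fasta)
  gtf <- file.path(dir, "annotation.gtf")
  write_gtf(fix$transcripts, gtf)
  invisible(list(fasta = fasta, gtf = gtf))
}

#' Write transcripts as a GENCODE-style GTF
#'
#' @param transcripts List of [transcript()] objects.
#' @param path Output file.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (tr in transcripts) {
    gt <- switch(tr$biotype, protein_coding = "protein_coding",
                 lncRNA = "lncRNA", "misc_RNA")
    attrs <- sprintf(paste0('gene_id "%s"; transcript_id "%s"; ',
                            'gene_type "%s"; gene_name "%s"; level %d;'),
                     tr$gene_id, tr$transcript_id, gt, tr$gene_name,
                     ifelse(is.na(tr$transcript_level), 3L,
                            tr$transcript_level))
    if (!is.na(tr$appris_rank))
      attrs <- paste0(attrs, sprintf(' tag "appris_principal_%d";',
                                     tr$appris_rank))
    if (tr$has_ccds) attrs <- paste0(attrs, ' tag "CCDS";')
    row <- function(feature, start0, end0) {
      sprintf("%s\tfixture\t%s\t%d\t%d\t.\t%s\t.\t%s", tr$chrom, feature,
              start0 + 1L, end0, tr$strand, attrs)
    }
    lines <- c(lines, row("transcript", min(tr$exons[, 1]), max(tr$exons[, 2])))
    for (i in seq_len(nrow(tr$exons)))
      lines <- c(lines, row("exon", tr$exons[i, 1], tr$exons[i, 2]))
    if (!is.null(tr$regions)) {
      feat_of <- c(`5UTR` = "five_prime_utr", CDS = "CDS",
                   `3UTR` = "three_prime_utr")
      for (i in seq_len(nrow(tr$regions))) {
        gi <- genomic_intervals(tr, tr$regions$start[i], tr$regions$end[i])
        for (j in seq_len(nrow(gi)))
          lines <- c(lines, row(feat_of[[tr$regions$region[i]]],
                                gi[j, 1], gi[j, 2]))
      }
    }
  }
  writeLines(lines, path)
}

# ---- hairpin benchmark ------------------------------------------------------

#' Generate a hairpin SNV benchmark
#'
#' Labeled SNV-sequence pairs in the standard benchmark geometry: the SNV
#' centered in a fixed-length sequence with low-structure flanks (101 nt by
#' default). The embedded hairpin has a fixed aperiodic G/C stem inside
#' A-dominant flanks, so the helix is the only substantially stacked
#' structure and every interior stem position is firmly paired. Positives
#' break an interior stem pair (G/C to A); negatives substitute a loop A by
#' C, which leaves the helix intact (the non-riboSNitch contract).
#'
#' @param n_pairs Total pairs (half positive, half negative).
#' @param stem_len,loop_len Hairpin geometry; `stem_len >= 4`,
#'   `loop_len >= 3`.
#' @param flank Flank length on each side of the SNV (sequence length is
#'   `2 * flank + 1`).
#' @param seed Integer seed.
#' @return data.frame of benchmark pairs: `pair_id`, `sequence`, `snv_pos`
#'   (0-based center), `ref`, `alt`, `label`.
#' @export
make_hairpin_benchmark <- function(n_pairs = 500L, stem_len = 7L,
                                   loop_len = 5L, flank = 50L, seed = 1L) {
  stopifnot(stem_len >= 4L, loop_len >= 3L)
  set.seed(seed)
  n_pos <- n_pairs %/% 2L
  hp_len <- 2L * stem_len + loop_len
  total <- 2L * flank + 1L
  rows <- lapply(seq_len(n_pairs), function(i) {
    positive <- i <= n_pos
    # choose the mutated hairpin position: stem base (positive) or loop
    # base (negative); build the sequence so that position sits at center
    arm <- substr(strrep("GCCGCGG", 3L), 1L, stem_len)
    hp <- paste0(arm, strrep("A", loop_len), revcomp(arm))
    if (positive) {
      side <- sample(c("left", "right"), 1L)
      off <- sample.int(stem_len - 2L, 1L)            # interior arm position
      hp_off <- if (side == "left") off else stem_len + loop_len + off
    } else {
      hp_off <- stem_len + sample.int(loop_len, 1L) - 1L
    }
    ref <- substr(hp, hp_off + 1L, hp_off + 1L)
    # G/C -> A breaks the pair; loop A -> C cannot break anything
    alt <- if (positive) "A" else "C"
    left_len <- flank - hp_off
    right_len <- total - left_len - hp_len
    fl <- function(n) sample_seq(n, c(A = .85, C = .15))
    seqc <- paste0(fl(left_len), hp, fl(right_len))
    data.frame(pair_id = sprintf("P%04d", i), sequence = seqc,
               snv_pos = flank, ref = ref, alt = alt,
               label = if (positive) "ribosnitch" else "non_ribosnitch",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  stopifnot(all(nchar(out$sequence) == total),
            all(substr(out$sequence, flank + 1L, flank + 1L) == out$ref))
  out
}

# ---- mutation cohorts -------------------------------------------------------

# neutral element draws mapped back to genomic records
neutral_element_records <- function(tr, mature, el, profile, n, cohort,
                                    samples) {
  dist <- recalibrate_profile(
    profile, transcript_composition(substr(mature, el$start + 1L, el$end)))
  sim <- simulate_mutations(mature, dist, n, interval = c(el$start, el$end))
  to_genomic_records(tr, sim$k, sim$ref_t, sim$alt_t, cohort, samples)
}

to_genomic_records <- function(tr, k, ref_t, alt_t, cohort, samples) {
  if (length(k) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      sample_id = character(0), cohort = character(0),
                      stringsAsFactors = FALSE))
  g <- vapply(k, function(x) genomic_position(tr, x), integer(1))
  flipped <- tr$strand == "-"
  data.frame(chrom = tr$chrom, pos = g + 1L,
             ref = if (flipped) unname(COMP[ref_t]) else ref_t,
             alt = if (flipped) unname(COMP[alt_t]) else alt_t,
             sample_id = sample(samples, length(k), replace = TRUE),
             cohort = cohort, stringsAsFactors = FALSE)
}

# candidate pool for planting: every interior element site with a
# pair-breaking substitution heuristic, scored with the pipeline's scorer
planted_candidates <- function(tr, mature, el, config, w) {
  ks <- seq.int(max(1L, el$start), min(nchar(mature) - 2L, el$end - 1L))
  refs <- substring(mature, ks + 1L, ks + 1L)
  alts <- c(A = "C", C = "A", G = "A", T = "C")[refs]
  pool <- data.frame(k = ks, ref_t = refs, alt_t = unname(alts),
                     stringsAsFactors = FALSE)
  prof <- if (nchar(mature) <= config$window_W)
    pairedness_profile(mature, config) else NULL
  sc <- do.call(rbind, lapply(seq_len(nrow(pool)), function(i) {
    score_mutation(mature, pool$k[i], pool$alt_t[i], config, w,
                   ref_profile = prof)
  }))
  pool$mean_diff <- sc$mean_diff
  pool$euc_diff <- sc$euc_diff
  pool$joint_rank <- pmin(rank(pool$mean_diff), rank(pool$euc_diff))
  pool
}

#' Generate somatic and germline mutation cohorts
#'
#' Draws intronic and element (5'UTR/3'UTR/lncRNA) mutations from the
#' fixture's neutral 96-class profile. In the somatic cohort, planted
#' elements deviate from neutrality: enriched elements take a portion of
#' their mutations from the top of a pair-breaking candidate pool ranked by
#' the pipeline's own scorer (by construction this tests recovery of the
#' planted signal, not biology), depleted elements take all of theirs from
#' the bottom of that pool. The germline cohort is entirely neutral, so
#' planted effects are somatic-specific.
#'
#' @param fix Result of [make_genome_and_annotation()].
#' @param config Folding configuration used for planting scores (should
#'   match the scan configuration).
#' @param w Half-window for planting scores.
#' @return List with `somatic` and `germline` mutation data.frames
#'   (`chrom`, `pos`, `ref`, `alt`, `sample_id`, `cohort`) and the
#'   `elements` table.
#' @export
make_mutation_cohort <- function(fix, config = fold_config(max_span_L = 50L,
                                                           pair_weight_model = "stack",
                                                           stack_bonus = 8),
                                 w = 15L) {
  spec <- fix$spec
  set.seed(spec$seed + 1000L)
  profile <- as_mutation_profile(spec$profile_96, "fixture")
  samples_som <- sprintf("TCx%02d", 1:25)
  samples_ger <- sprintf("NORM%02d", 1:25)
  principals <- principal_transcripts(fix$transcripts)
  matures <- lapply(principals, extract_mature_sequence, genome = fix$genome)

  somatic <- list(); germline <- list()
  for (i in seq_len(nrow(fix$elements))) {
    el <- fix$elements[i, ]
    tr <- principals[[el$gene_id]]
    mature <- matures[[el$gene_id]]
    germline[[length(germline) + 1L]] <- neutral_element_records(
      tr, mature, el, profile, spec$n_mut_per_element, "germline",
      samples_ger)
    if (el$role == "null") {
      somatic[[length(somatic) + 1L]] <- neutral_element_records(
        tr, mature, el, profile, spec$n_mut_per_element, "somatic",
        samples_som)
    } else {
      pool <- planted_candidates(tr, mature, el, config, w)
      n_obs <- spec$n_mut_planted
      if (el$role == "enriched") {
        # plant several times the nominal-tail target: the cohort-level
        # cutoffs land inside the planted block, so the realized riboSNitch
        # fraction is cutoff-limited, not planting-limited
        n_plant <- min(nrow(pool),
                       ceiling(min(1, 4 * el$fold_effect * 0.025) * n_obs))
        top <- pool[order(-pool$joint_rank), ][seq_len(n_plant), ]
        rest <- neutral_element_records(tr, mature, el, profile,
                                        n_obs - n_plant, "somatic",
                                        samples_som)
        somatic[[length(somatic) + 1L]] <- rbind(
          to_genomic_records(tr, top$k, top$ref_t, top$alt_t, "somatic",
                             samples_som), rest)
      } else {
        bottom <- pool[order(pool$joint_rank), ][seq_len(min(nrow(pool),
                                                             n_obs)), ]
        somatic[[length(somatic) + 1L]] <- to_genomic_records(
          tr, bottom$k, bottom$ref_t, bottom$alt_t, "somatic", samples_som)
      }
    }
  }
  somatic[[length(somatic) + 1L]] <- intronic_records(
    principals, fix$genome, profile, spec$n_intronic, "somatic", samples_som)
  germline[[length(germline) + 1L]] <- intronic_records(
    principals, fix$genome, profile, spec$n_intronic, "germline",
    samples_ger)
  list(somatic = do.call(rbind, somatic),
       germline = do.call(rbind, germline), elements = fix$elements)
}

# neutral intronic mutations across all multi-exon principal transcripts
intronic_records <- function(principals, genome, profile, n, cohort,
                             samples) {
  pieces <- list()
  for (tr in principals) {
    ex <- tr$exons
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      lo <- ex[i, 2]; hi <- ex[i + 1L, 1]
      if (hi - lo >= 10L)
        pieces[[length(pieces) + 1L]] <-
          list(chrom = tr$chrom, lo = lo,
               seq = substr(chrom_seq(genome, tr$chrom), lo + 1L, hi))
    }
  }
  if (length(pieces) == 0L) stop("no introns in fixture")
  sizes <- vapply(pieces, function(p) nchar(p$seq), numeric(1))
  draw <- tabulate(sample.int(length(pieces), n, replace = TRUE,
                              prob = sizes), nbins = length(pieces))
  recs <- list()
  for (j in seq_along(pieces)) {
    if (draw[j] == 0L) next
    p <- pieces[[j]]
    dist <- recalibrate_profile(profile, transcript_composition(p$seq))
    sim <- simulate_mutations(p$seq, dist, draw[j])
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = p$chrom, pos = p$lo + sim$k + 1L, ref = sim$ref_t,
      alt = sim$alt_t, sample_id = sample(samples, draw[j], replace = TRUE),
      cohort = cohort, stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}
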