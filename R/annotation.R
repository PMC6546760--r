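#' @title Transcript annotation, principal isoforms and mutation mapping
#' @description Helpers to read GENCODE-style annotation, pick one principal
#'   transcript per gene, extract mature (spliced) sequences and project SNVs
#'   onto mature-transcript coordinates with their trinucleotide context.
#' @name annotation
NULL

# ---- coordinate conventions -------------------------------------------------
# Genomic inputs are 1-based (VCF); all internal intervals are 0-based
# half-open; the mature-transcript coordinate k is 0-based.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMP[strsplit(toupper(s), "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a transcript object
#'
#' @param transcript_id,gene_id,gene_name Identifiers.
#' @param biotype One of `"protein_coding"`, `"lncRNA"`, `"other"`.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Integer matrix with columns `start`, `end`: 0-based half-open
#'   genomic intervals, non-overlapping, sorted by genomic start.
#' @param appris_rank APPRIS principal-isoform rank 1--5, or `NA`.
#' @param has_ccds Logical: transcript carries a CCDS id.
#' @param transcript_level Annotation level 1--3, or `NA`.
#' @param regions Optional data.frame (`region`, `start`, `end`) partitioning
#'   mature coordinates into `5UTR`/`CDS`/`3UTR` (0-based half-open).
#' @return An object of class `transcript`.
#' @export
transcript <- function(transcript_id, gene_id, gene_name = gene_id,
                       biotype = c("protein_coding", "lncRNA", "other"),
                       chrom, strand, exons, appris_rank = NA_integer_,
                       has_ccds = FALSE, transcript_level = NA_integer_,
                       regions = NULL) {
  biotype <- match.arg(biotype)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("transcript needs at least one exon")
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) stop("empty or inverted exon interval")
  if (nrow(exons) > 1L && any(exons[-1L, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons")
  mature_length <- sum(exons[, 2] - exons[, 1])
  if (!is.null(regions)) {
    stopifnot(all(c("region", "start", "end") %in% names(regions)))
    if (any(regions$start < 0L) || any(regions$end > mature_length))
      stop("region outside mature coordinates")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 gene_name = gene_name, biotype = biotype, chrom = chrom,
                 strand = strand, exons = exons,
                 appris_rank = as.integer(appris_rank),
                 has_ccds = isTRUE(has_ccds),
                 transcript_level = as.integer(transcript_level),
                 mature_length = mature_length, regions = regions),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("transcript %s (%s, %s) %s%s %d exon(s), mature %d nt\n",
              x$transcript_id, x$gene_name, x$biotype, x$chrom, x$strand,
              nrow(x$exons), x$mature_length))
  invisible(x)
}

#' Select the principal transcript of a gene
#'
#' Ranks isoforms by APPRIS rank (lower wins, missing ranks after 5), then
#' CCDS membership, then annotation level (lower wins, missing last), then
#' mature length (longer wins), with a deterministic final tie-break on the
#' lexicographically smallest transcript id.
#'
#' @param transcripts_of_gene Non-empty list of [transcript()] objects
#'   sharing one `gene_id`.
#' @return The single principal [transcript()].
#' @export
select_principal_transcript <- function(transcripts_of_gene) {
  if (length(transcripts_of_gene) == 0L) stop("no transcripts")
  gids <- unique(vapply(transcripts_of_gene, `[[`, character(1), "gene_id"))
  if (length(gids) != 1L) stop("transcripts from multiple genes: ",
                               paste(gids, collapse = ","))
  key <- function(t) {
    c(ifelse(is.na(t$appris_rank), 6L, t$appris_rank),
      ifelse(t$has_ccds, 0L, 1L),
      ifelse(is.na(t$transcript_level), 4L, t$transcript_level),
      -t$mature_length)
  }
  keys <- t(vapply(transcripts_of_gene, key, integer(4)))
  ids <- vapply(transcripts_of_gene, `[[`, character(1), "transcript_id")
  ord <- order(keys[, 1], keys[, 2], keys[, 3], keys[, 4], ids)
  transcripts_of_gene[[ord[1L]]]
}

#' One principal transcript per gene
#'
#' @param transcripts List of [transcript()] objects (any number of genes).
#' @return Named list of principal transcripts, one per `gene_id`.
#' @export
principal_transcripts <- function(transcripts) {
  gid <- vapply(transcripts, `[[`, character(1), "gene_id")
  lapply(split(transcripts, gid), select_principal_transcript)
}

# ---- genome access ----------------------------------------------------------

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase chromosome sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

chrom_seq <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  genome[[chrom]]
}

#' Extract the mature (spliced) transcript sequence
#'
#' Exon sequences are concatenated 5' to 3' on the transcript strand;
#' minus-strand transcripts are reverse-complemented. The DNA alphabet is
#' kept throughout (T, never U).
#'
#' @param transcript A [transcript()].
#' @param genome Named character vector as from [read_genome()].
#' @return Uppercase nucleotide string of length `mature_length`.
#' @export
extract_mature_sequence <- function(transcript, genome) {
  chrom <- chrom_seq(genome, transcript$chrom)
  if (any(transcript$exons[, 2] > nchar(chrom)))
    stop("exon outside chromosome bounds")
  parts <- apply(transcript$exons, 1L, function(e) {
    substr(chrom, e[1] + 1L, e[2])
  })
  s <- toupper(paste(parts, collapse = ""))
  if (!grepl("^[ACGTN]*$", s)) stop("non-ACGTN base in mature sequence")
  if (transcript$strand == "-") s <- revcomp(s)
  s
}

# ---- mutations --------------------------------------------------------------

#' Read single-nucleotide variants
#'
#' Accepts either a 5-column TSV (`chrom`, `pos`, `ref`, `alt`, `sample`;
#' header optional) or a VCF. Multi-allelic VCF rows are split into biallelic
#' records; anything that is not a single-base substitution is dropped.
#'
#' @param path Input file.
#' @param cohort Cohort label stored with every record.
#' @return data.frame with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `sample_id`, `cohort`.
#' @export
read_snvs <- function(path, cohort = "cohort") {
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    recs <- lapply(fields, function(f) {
      alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
      data.frame(chrom = f[1], pos = as.integer(f[2]), ref = toupper(f[4]),
                 alt = toupper(alts),
                 sample_id = if (f[3] %in% c(".", "")) "sample" else f[3],
                 stringsAsFactors = FALSE)
    })
    m <- do.call(rbind, recs)
  } else {
    has_header <- grepl("chrom", first, ignore.case = TRUE)
    m <- read.table(path, sep = "\t", header = has_header,
                    stringsAsFactors = FALSE)
    if (!has_header) {
      if (ncol(m) < 5L) stop("mutation TSV needs 5 columns")
      names(m)[1:5] <- c("chrom", "pos", "ref", "alt", "sample_id")
    } else {
      names(m)[names(m) %in% c("sample", "sample_name")] <- "sample_id"
      need <- c("chrom", "pos", "ref", "alt", "sample_id")
      if (!all(need %in% names(m)))
        stop("mutation TSV missing columns: ",
             paste(setdiff(need, names(m)), collapse = ","))
    }
    m <- m[, c("chrom", "pos", "ref", "alt", "sample_id")]
    m$chrom <- as.character(m$chrom)
    m$pos <- as.integer(m$pos)
    m$ref <- toupper(m$ref); m$alt <- toupper(m$alt)
  }
  keep <- nchar(m$ref) == 1L & nchar(m$alt) == 1L &
    m$ref %in% c("A", "C", "G", "T") & m$alt %in% c("A", "C", "G", "T") &
    m$ref != m$alt
  m <- m[keep, , drop = FALSE]
  m$cohort <- cohort
  rownames(m) <- NULL
  m
}

#' Remove mutations falling in blacklist regions
#'
#' @param mutations data.frame with `chrom` and 1-based `pos`.
#' @param blacklist A `GRanges` (e.g. from `rtracklayer::import` of a BED
#'   file) or a data.frame with `chrom`, `start`, `end` in 0-based half-open
#'   coordinates. Empty blacklist returns the input unchanged.
#' @return The retained mutations, input order preserved.
#' @export
filter_blacklist <- function(mutations, blacklist) {
  if (is.null(blacklist) || length(blacklist) == 0L || NROW(blacklist) == 0L)
    return(mutations)
  if (is.data.frame(blacklist)) {
    blacklist <- GenomicRanges::GRanges(
      blacklist$chrom,
      IRanges::IRanges(start = blacklist$start + 1L, end = blacklist$end))
  }
  gr <- GenomicRanges::GRanges(mutations$chrom,
                               IRanges::IRanges(mutations$pos, width = 1L))
  hits <- GenomicRanges::countOverlaps(gr, blacklist, ignore.strand = TRUE)
  mutations[hits == 0L, , drop = FALSE]
}

# ---- trinucleotide classification -------------------------------------------

SUB_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' Labels of the 96 substitution classes
#'
#' Strand-collapsed substitution classes in COSMIC-style order: 6 pyrimidine
#' substitution types x 4 5'-flanks x 4 3'-flanks, e.g. `"A[C>T]A"`.
#' Class index `i` (0-based) has type `i %/% 16`, 5' flank `(i %% 16) %/% 4`
#' and 3' flank `i %% 4`.
#'
#' @return Character vector of length 96.
#' @export
subst_class_labels <- function() {
  out <- character(96)
  for (s in 0:5) for (f in 0:3) for (t in 0:3) {
    out[s * 16 + f * 4 + t + 1] <-
      paste0(BASES[f + 1], "[", SUB_TYPES[s + 1], "]", BASES[t + 1])
  }
  out
}

#' Labels of the 32 trinucleotide composition classes
#'
#' Strand-collapsed trinucleotide contexts: center base C or T x 16 flank
#' combinations, e.g. `"ACA"`. Class index `i` (0-based) has center
#' `i %/% 16` (0 = C, 1 = T), 5' flank `(i %% 16) %/% 4`, 3' flank `i %% 4`.
#'
#' @return Character vector of length 32.
#' @export
context_class_labels <- function() {
  out <- character(32)
  for (ct in 0:1) for (f in 0:3) for (t in 0:3) {
    out[ct * 16 + f * 4 + t + 1] <-
      paste0(BASES[f + 1], c("C", "T")[ct + 1], BASES[t + 1])
  }
  out
}

#' Classify a substitution into the 96/32 trinucleotide categories
#'
#' When the reference base is a purine, the trinucleotide and both alleles
#' are reverse-complemented first, collapsing strands so every class has a
#' pyrimidine (C/T) center. Vectorized.
#'
#' @param tri_context 3-mers of the transcript (or genome) sequence centered
#'   on the mutated base.
#' @param ref,alt Alleles on the same strand as `tri_context`.
#' @return data.frame with 0-based `subst_class96`, `tri_class32` and the
#'   collapsed `label`. Contexts containing N yield `NA` classes.
#' @export
classify_substitution <- function(tri_context, ref, alt) {
  tri_context <- toupper(tri_context)
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(length(ref) == length(tri_context),
            length(alt) == length(tri_context))
  mid <- substr(tri_context, 2, 2)
  bad_mid <- nchar(tri_context) != 3L | mid != ref
  if (any(bad_mid & !is.na(tri_context)))
    stop("tri_context center must equal ref")
  if (any(ref == alt)) stop("ref equals alt")
  flip <- ref %in% c("A", "G")
  tri <- tri_context
  tri[flip] <- revcomp(tri_context[flip])
  r <- ref; a <- alt
  r[flip] <- COMP[ref[flip]]
  a[flip] <- COMP[alt[flip]]
  five <- substr(tri, 1, 1); three <- substr(tri, 3, 3)
  sub_idx <- match(paste0(r, ">", a), SUB_TYPES) - 1L
  f_idx <- match(five, BASES) - 1L
  t_idx <- match(three, BASES) - 1L
  c_idx <- match(r, c("C", "T")) - 1L
  ok <- !is.na(sub_idx) & !is.na(f_idx) & !is.na(t_idx)
  s96 <- ifelse(ok, sub_idx * 16L + f_idx * 4L + t_idx, NA_integer_)
  s32 <- ifelse(ok, c_idx * 16L + f_idx * 4L + t_idx, NA_integer_)
  data.frame(subst_class96 = as.integer(s96), tri_class32 = as.integer(s32),
             label = ifelse(ok, subst_class_labels()[s96 + 1L], NA_character_),
             stringsAsFactors = FALSE)
}

# tri class (0-31) of the context of a 96-class
context_of_class96 <- function(class96) {
  center <- ifelse(class96 %/% 16L < 3L, 0L, 1L)  # C for first 3 types
  center * 16L + class96 %% 16L
}

# alt base (on collapsed strand) implied by a 96-class
alt_of_class96 <- function(class96) {
  alts <- vapply(strsplit(SUB_TYPES, ">", fixed = TRUE), `[`, character(1), 2L)
  alts[class96 %/% 16L + 1L]
}

# ---- mapping ----------------------------------------------------------------

# mature-coordinate k for 0-based genomic position g, or NA
mature_position <- function(tr, g) {
  ex <- tr$exons
  cum <- c(0L, cumsum(ex[, 2] - ex[, 1]))
  hit <- which(g >= ex[, 1] & g < ex[, 2])
  if (length(hit) == 0L) return(NA_integer_)
  k_plus <- cum[hit] + (g - ex[hit, 1])
  if (tr$strand == "+") k_plus else tr$mature_length - 1L - k_plus
}

# inverse of mature_position: 0-based genomic position of mature coordinate k
genomic_position <- function(tr, k) {
  if (k < 0L || k >= tr$mature_length) stop("k outside mature transcript")
  k_plus <- if (tr$strand == "+") k else tr$mature_length - 1L - k
  ex <- tr$exons
  cum <- c(0L, cumsum(ex[, 2] - ex[, 1]))
  e <- findInterval(k_plus, cum, rightmost.closed = FALSE)
  ex[e, 1] + (k_plus - cum[e])
}

# project a 0-based half-open mature interval onto genomic intervals
genomic_intervals <- function(tr, mstart, mend) {
  g <- vapply(mstart:(mend - 1L), function(k) genomic_position(tr, k),
              integer(1))
  g <- sort(g)
  brk <- c(0L, which(diff(g) != 1L), length(g))
  do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    c(start = g[brk[i] + 1L], end = g[brk[i + 1L]] + 1L)
  }))
}

region_of_k <- function(tr, k) {
  if (tr$biotype == "lncRNA") return("lncRNA")
  if (is.null(tr$regions)) return(if (tr$biotype == "protein_coding") "CDS" else "other")
  hit <- which(k >= tr$regions$start & k < tr$regions$end)
  if (length(hit) == 0L) "CDS" else tr$regions$region[hit[1L]]
}

#' Map SNVs onto a mature transcript
#'
#' Projects each record onto mature-transcript coordinates. Exonic records
#' get a 0-based mature position `k`, strand-corrected alleles, the
#' trinucleotide context of the mature sequence at `k` and the 96/32 class
#' indices. Records between the transcript's first and last exon but outside
#' every exon are kept as intronic (no `k`; context taken from the genome,
#' which after strand collapse is strand-invariant). Records outside the
#' transcript span are dropped.
#'
#' @param mutations data.frame from [read_snvs()] (columns `chrom`, `pos`,
#'   `ref`, `alt`, `sample_id`, `cohort`).
#' @param tr A [transcript()].
#' @param genome Named character vector from [read_genome()].
#' @param mature Optional precomputed mature sequence (speeds up batch use).
#' @return data.frame of mapped mutations with columns `chrom`, `pos`,
#'   `ref`, `alt`, `sample_id`, `cohort`, `transcript_id`, `k`, `ref_t`,
#'   `alt_t`, `tri_context`, `region`, `subst_class96`, `tri_class32`.
#'   Mutations whose reference allele contradicts the genome raise an error.
#' @export
map_mutations <- function(mutations, tr, genome,
                          mature = extract_mature_sequence(tr, genome)) {
  on_chrom <- mutations$chrom == tr$chrom
  span_lo <- min(tr$exons[, 1]); span_hi <- max(tr$exons[, 2])
  g <- mutations$pos - 1L
  inside <- on_chrom & g >= span_lo & g < span_hi
  m <- mutations[inside, , drop = FALSE]
  if (nrow(m) == 0L) return(empty_mapped())
  chrom <- chrom_seq(genome, tr$chrom)
  gpos <- m$pos - 1L
  genome_base <- toupper(substring(chrom, m$pos, m$pos))
  mismatch <- genome_base != m$ref & genome_base != "N"
  if (any(mismatch))
    stop("reference mismatch at ", tr$chrom, ":", m$pos[mismatch][1L],
         " (genome ", genome_base[mismatch][1L], ", record ",
         m$ref[mismatch][1L], ")")
  k <- vapply(gpos, function(gg) mature_position(tr, gg), integer(1))
  exonic <- !is.na(k)

  out <- m
  out$transcript_id <- tr$transcript_id
  out$k <- k
  out$ref_t <- NA_character_; out$alt_t <- NA_character_
  out$tri_context <- NA_character_
  out$region <- NA_character_
  out$subst_class96 <- NA_integer_; out$tri_class32 <- NA_integer_

  if (any(exonic)) {
    kk <- k[exonic]
    flipped <- tr$strand == "-"
    out$ref_t[exonic] <- if (flipped) COMP[m$ref[exonic]] else m$ref[exonic]
    out$alt_t[exonic] <- if (flipped) COMP[m$alt[exonic]] else m$alt[exonic]
    interior <- kk >= 1L & kk <= tr$mature_length - 2L
    ctx <- rep(NA_character_, sum(exonic))
    ctx[interior] <- substring(mature, kk[interior], kk[interior] + 2L)
    out$tri_context[exonic] <- ctx
    out$region[exonic] <- vapply(kk, function(x) region_of_k(tr, x), character(1))
    usable <- which(exonic)[interior & !grepl("N", ctx)]
    if (length(usable)) {
      cl <- classify_substitution(out$tri_context[usable],
                                  out$ref_t[usable], out$alt_t[usable])
      out$subst_class96[usable] <- cl$subst_class96
      out$tri_class32[usable] <- cl$tri_class32
    }
  }
  if (any(!exonic)) {
    idx <- which(!exonic)
    out$region[idx] <- "intron"
    p <- m$pos[idx]
    ctx <- toupper(substring(chrom, p - 1L, p + 1L))
    ctx[p - 1L < 1L | p + 1L > nchar(chrom)] <- NA_character_
    out$tri_context[idx] <- ctx
    out$ref_t[idx] <- m$ref[idx]   # intronic context kept on genome strand;
    out$alt_t[idx] <- m$alt[idx]   # classification is strand-collapsed anyway
    usable <- idx[!is.na(ctx) & !grepl("N", ctx)]
    if (length(usable)) {
      cl <- classify_substitution(out$tri_context[usable],
                                  out$ref_t[usable], out$alt_t[usable])
      out$subst_class96[usable] <- cl$subst_class96
      out$tri_class32[usable] <- cl$tri_class32
    }
  }
  rownames(out) <- NULL
  out
}

empty_mapped <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), sample_id = character(0),
             cohort = character(0), transcript_id = character(0),
             k = integer(0), ref_t = character(0), alt_t = character(0),
             tri_context = character(0), region = character(0),
             subst_class96 = integer(0), tri_class32 = integer(0),
             stringsAsFactors = FALSE)
}

# ---- GTF reading ------------------------------------------------------------

#' Read transcripts from a GENCODE-style GTF
#'
#' Builds [transcript()] objects from `exon` features, with isoform-priority
#' metadata taken from GENCODE-style attributes: `tag "appris_principal"` /
#' `"appris_principal_N"` (APPRIS rank), `tag "CCDS"` or a `ccdsid`
#' attribute, and `level`. UTR/CDS sub-annotation is taken from
#' `five_prime_utr`/`three_prime_utr`/`CDS` features when present and
#' converted to mature coordinates. `gene_type` values other than
#' `protein_coding`/`lncRNA` map to biotype `"other"` (GENCODE v19's
#' `lincRNA` and `processed_transcript` with lncRNA semantics are accepted
#' as lncRNA).
#'
#' @param path GTF file.
#' @return List of [transcript()] objects.
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  get_col <- function(nm) if (nm %in% names(md)) md[[nm]] else NULL
  type <- as.character(md$type)
  tid <- as.character(md$transcript_id)
  keep <- type %in% c("exon", "CDS", "five_prime_utr", "three_prime_utr", "UTR") &
    !is.na(tid)
  gr <- gr[keep]; md <- S4Vectors::mcols(gr)
  type <- as.character(md$type); tid <- as.character(md$transcript_id)

  # rtracklayer keeps only the last of GENCODE's repeated `tag` attributes;
  # recover the full tag set from the raw attribute strings
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  raw_tid <- ifelse(grepl('transcript_id "', raw, fixed = TRUE),
                    sub('.*transcript_id "([^"]+)".*', "\\1", raw),
                    NA_character_)
  raw_tags <- regmatches(raw, gregexpr('tag "([^"]+)"', raw))
  tags_by_tid <- lapply(
    split(raw_tags, raw_tid),
    function(x) unique(sub('tag "([^"]+)"', "\\1", unlist(x))))
  lvl_col <- get_col("level")
  tsl_col <- get_col("transcript_support_level")
  ccds_col <- get_col("ccdsid")

  out <- list()
  for (id in unique(tid)) {
    sel <- which(tid == id)
    ex <- sel[type[sel] == "exon"]
    if (length(ex) == 0L) next
    first <- ex[1L]
    exons <- cbind(GenomicRanges::start(gr)[ex] - 1L, GenomicRanges::end(gr)[ex])
    gene_type <- as.character(md$gene_type[first])
    biotype <- if (identical(gene_type, "protein_coding")) "protein_coding"
      else if (gene_type %in% c("lncRNA", "lincRNA", "antisense",
                                "processed_transcript")) "lncRNA"
      else "other"
    tags <- tags_by_tid[[id]]
    if (is.null(tags)) tags <- character(0)
    appris <- NA_integer_
    ap <- grep("^appris_principal", tags, value = TRUE)
    if (length(ap)) {
      num <- suppressWarnings(as.integer(sub("^appris_principal_?", "", ap[1L])))
      appris <- if (is.na(num)) 1L else num
    }
    has_ccds <- "CCDS" %in% tags ||
      (!is.null(ccds_col) && any(!is.na(ccds_col[sel])))
    level <- NA_integer_
    if (!is.null(lvl_col)) {
      v <- suppressWarnings(as.integer(as.character(lvl_col[first])))
      if (!is.na(v)) level <- v
    }
    if (is.na(level) && !is.null(tsl_col)) {
      v <- suppressWarnings(as.integer(as.character(tsl_col[first])))
      if (!is.na(v)) level <- v
    }
    tr <- transcript(
      transcript_id = id,
      gene_id = as.character(md$gene_id[first]),
      gene_name = if ("gene_name" %in% names(md) && !is.na(md$gene_name[first]))
        as.character(md$gene_name[first]) else as.character(md$gene_id[first]),
      biotype = biotype,
      chrom = as.character(GenomicRanges::seqnames(gr)[first]),
      strand = as.character(GenomicRanges::strand(gr)[first]),
      exons = exons, appris_rank = appris, has_ccds = has_ccds,
      transcript_level = level)
    sub <- sel[type[sel] %in% c("CDS", "five_prime_utr", "three_prime_utr")]
    if (length(sub)) {
      regs <- lapply(sub, function(i) {
        lo <- GenomicRanges::start(gr)[i] - 1L; hi <- GenomicRanges::end(gr)[i]
        k1 <- mature_position(tr, lo); k2 <- mature_position(tr, hi - 1L)
        if (is.na(k1) || is.na(k2)) return(NULL)
        lab <- switch(type[i], CDS = "CDS", five_prime_utr = "5UTR",
                      three_prime_utr = "3UTR", "CDS")
        data.frame(region = lab, start = min(k1, k2), end = max(k1, k2) + 1L,
                   stringsAsFactors = FALSE)
      })
      regs <- do.call(rbind, regs[!vapply(regs, is.null, logical(1))])
      if (!is.null(regs) && nrow(regs)) {
        regs <- merge_regions(regs)
        tr$regions <- regs
      }
    }
    out[[id]] <- tr
  }
  out
}

merge_regions <- function(regs) {
  regs <- regs[order(regs$region, regs$start), , drop = FALSE]
  out <- list()
  for (lab in unique(regs$region)) {
    r <- regs[regs$region == lab, , drop = FALSE]
    cur_s <- r$start[1L]; cur_e <- r$end[1L]
    for (i in seq_len(nrow(r))[-1L]) {
      if (r$start[i] <= cur_e) cur_e <- max(cur_e, r$end[i])
      else { out[[length(out) + 1L]] <- data.frame(region = lab, start = cur_s,
                                                   end = cur_e); cur_s <- r$start[i]; cur_e <- r$end[i] }
    }
    out[[length(out) + 1L]] <- data.frame(region = lab, start = cur_s, end = cur_e)
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}
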