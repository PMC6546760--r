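test_that("principal transcript selection follows the 4-key priority", {
  mk <- function(id, appris, ccds, level, len) {
    tiny_transcript(cbind(0L, len), id = id, appris_rank = appris,
                    has_ccds = ccds, transcript_level = level)
  }
  # APPRIS rank decides first
  expect_equal(select_principal_transcript(
    list(mk("a", 2L, TRUE, 1L, 500L), mk("b", 1L, FALSE, 3L, 100L))
  )$transcript_id, "b")
  # missing APPRIS ranks after all present ranks
  expect_equal(select_principal_transcript(
    list(mk("a", NA, TRUE, 1L, 900L), mk("b", 5L, FALSE, 3L, 100L))
  )$transcript_id, "b")
  # CCDS breaks APPRIS ties
  expect_equal(select_principal_transcript(
    list(mk("a", 1L, FALSE, 1L, 900L), mk("b", 1L, TRUE, 3L, 100L))
  )$transcript_id, "b")
  # level breaks CCDS ties
  expect_equal(select_principal_transcript(
    list(mk("a", 1L, TRUE, 2L, 900L), mk("b", 1L, TRUE, 1L, 100L))
  )$transcript_id, "b")
  # length last: the 1200-nt isoform wins over 900 nt
  expect_equal(select_principal_transcript(
    list(mk("a", 1L, TRUE, 1L, 900L), mk("b", 1L, TRUE, 1L, 1200L))
  )$transcript_id, "b")
  # identity on a single transcript; error on none
  single <- mk("only", 1L, TRUE, 1L, 50L)
  expect_identical(select_principal_transcript(list(single)), single)
  expect_error(select_principal_transcript(list()), "no transcripts")
})

test_that("selection is a total order: permutations never change the winner", {
  set.seed(41)
  for (rep in 1:20) {
    trs <- lapply(1:5, function(i) {
      tiny_transcript(cbind(0L, sample(50:500, 1)),
                      id = sprintf("t%d", i),
                      appris_rank = sample(c(NA, 1:5), 1),
                      has_ccds = sample(c(TRUE, FALSE), 1),
                      transcript_level = sample(c(NA, 1:3), 1))
    })
    picked <- select_principal_transcript(trs)$transcript_id
    for (p in 1:5) {
      expect_equal(
        select_principal_transcript(sample(trs))$transcript_id, picked)
    }
  }
})

test_that("mature sequence extraction splices and strand-corrects", {
  g <- tiny_genome("ACGTGG")
  expect_equal(extract_mature_sequence(
    tiny_transcript(cbind(0L, 4L)), g), "ACGT")
  # minus strand: reverse complement of the asymmetric exon
  g2 <- tiny_genome("AAGTGG")
  expect_equal(extract_mature_sequence(
    tiny_transcript(cbind(0L, 4L), strand = "-"), g2), "ACTT")
  # two-exon splice
  g3 <- tiny_genome("ACGTTGGA")
  expect_equal(extract_mature_sequence(
    tiny_transcript(rbind(c(0L, 3L), c(5L, 8L))), g3), "ACGGGA")
  # exon beyond the chromosome is an error
  expect_error(extract_mature_sequence(
    tiny_transcript(cbind(0L, 10L)), g), "chromosome")
})

test_that("blacklist filtering respects half-open interval semantics", {
  muts <- data.frame(chrom = "chrT", pos = c(100L, 100L, 250L),
                     ref = "C", alt = "A", sample_id = "s", cohort = "c")
  # [99,101) contains 0-based 99 -> removed
  bl <- data.frame(chrom = "chrT", start = 99L, end = 101L)
  expect_equal(nrow(filter_blacklist(muts[1, ], bl)), 0L)
  # [100,200) does not contain 0-based 99 -> retained
  bl2 <- data.frame(chrom = "chrT", start = 100L, end = 200L)
  expect_equal(nrow(filter_blacklist(muts[2, ], bl2)), 1L)
  # empty blacklist is the identity; order preserved
  expect_identical(filter_blacklist(muts, NULL), muts)
  expect_equal(filter_blacklist(muts, bl)$pos, 250L)
})

test_that("substitution classification collapses strands consistently", {
  a <- classify_substitution("ACA", "C", "T")
  expect_equal(a$label, "A[C>T]A")
  # reverse complement gives the identical class
  b <- classify_substitution("TGT", "G", "A")
  expect_equal(b$subst_class96, a$subst_class96)
  expect_equal(b$tri_class32, a$tri_class32)
  # full enumeration: exactly 96 substitution and 32 context classes
  ctx <- expand.grid(f = c("A", "C", "G", "T"), m = c("A", "C", "G", "T"),
                     t = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                     stringsAsFactors = FALSE)
  ctx <- ctx[ctx$m != ctx$alt, ]
  cl <- classify_substitution(paste0(ctx$f, ctx$m, ctx$t), ctx$m, ctx$alt)
  expect_equal(length(unique(cl$subst_class96)), 96L)
  expect_equal(length(unique(cl$tri_class32)), 32L)
  expect_false(anyNA(cl$subst_class96))
  # involution property on random substitutions
  set.seed(7)
  for (i in 1:50) {
    tri <- rand_seq(3)
    ref <- substr(tri, 2, 2)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    rc <- function(s) ribosnitch:::revcomp(s)
    x <- classify_substitution(tri, ref, alt)
    y <- classify_substitution(rc(tri), rc(ref), rc(alt))
    expect_equal(x$subst_class96, y$subst_class96)
  }
  # N context yields NA classes, not an error
  expect_true(is.na(classify_substitution("ANA", "N", "C")$subst_class96))
})

test_that("mutation mapping round-trips through mature coordinates", {
  set.seed(11)
  for (strand in c("+", "-")) for (rep in 1:10) {
    gseq <- rand_seq(60)
    tr <- tiny_transcript(rbind(c(5L, 20L), c(30L, 50L)), strand = strand)
    g <- tiny_genome(gseq)
    mature <- extract_mature_sequence(tr, g)
    pos <- sample(c(6:20, 31:50), 5)   # 1-based exonic positions
    ref <- substring(gseq, pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    muts <- data.frame(chrom = "chrT", pos = pos, ref = ref, alt = alt,
                       sample_id = "s", cohort = "c")
    mapped <- map_mutations(muts, tr, g)
    expect_equal(nrow(mapped), 5L)
    # transcript base at k equals the strand-corrected ref
    expect_equal(substring(mature, mapped$k + 1, mapped$k + 1), mapped$ref_t)
    # genomic round trip
    back <- vapply(mapped$k, function(k) ribosnitch:::genomic_position(tr, k),
                   integer(1))
    expect_equal(back + 1L, mapped$pos)
  }
})

test_that("mapping separates exonic, intronic and external records", {
  gseq <- paste0("AAAA", "ACGTACGTAC", "TTTTTTT", "GGCCGGCC", "AAAA")
  #              0-3    4-13 exon1     14-20 in  21-28 ex2   29-32
  tr <- tiny_transcript(rbind(c(4L, 14L), c(21L, 29L)))
  g <- tiny_genome(gseq)
  ref_at <- function(p) substring(gseq, p, p)
  mk <- function(p) data.frame(chrom = "chrT", pos = p, ref = ref_at(p),
                               alt = if (ref_at(p) == "T") "A" else "T",
                               sample_id = "s", cohort = "c")
  # third base of exon 1 (1-based genomic 7) -> k = 2
  m <- map_mutations(mk(7L), tr, g)
  expect_equal(m$k, 2L)
  expect_false(m$region == "intron")
  # intronic position keeps the record without k
  m2 <- map_mutations(mk(16L), tr, g)
  expect_equal(m2$region, "intron")
  expect_true(is.na(m2$k))
  # outside the transcript span -> dropped
  m3 <- map_mutations(mk(2L), tr, g)
  expect_equal(nrow(m3), 0L)
  # minus strand: k = L - 1 - offset for a single-exon transcript
  trm <- tiny_transcript(cbind(4L, 14L), strand = "-")
  m4 <- map_mutations(mk(7L), trm, g)
  expect_equal(m4$k, 10L - 1L - 2L)
  expect_equal(m4$ref_t, unname(ribosnitch:::COMP[ref_at(7L)]))
  # reference mismatch is an error
  bad <- data.frame(chrom = "chrT", pos = 7L,
                    ref = setdiff(c("A", "C", "G", "T"), ref_at(7L))[1],
                    alt = "T", sample_id = "s", cohort = "c")
  bad$alt <- setdiff(c("A", "C", "G", "T"), c(bad$ref, ref_at(7L)))[1]
  expect_error(map_mutations(bad, tr, g), "reference mismatch")
})

test_that("SNV reading handles TSV and multiallelic VCF", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt\tsample",
               "chr1\t10\tC\tA\ts1",
               "chr1\t11\tCT\tC\ts1",     # indel dropped
               "chr1\t12\tG\tG\ts1"),     # non-variant dropped
             tsv)
  m <- read_snvs(tsv, cohort = "x")
  expect_equal(nrow(m), 1L)
  expect_equal(m$cohort, "x")

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t20\trs1\tA\tC,G\t.\tPASS\t.",
               "chr1\t21\t.\tT\tTTA\t.\tPASS\t."), vcf)
  v <- read_snvs(vcf)
  expect_equal(nrow(v), 2L)       # multiallelic split, indel dropped
  expect_setequal(v$alt, c("C", "G"))
  expect_equal(unique(v$sample_id), "rs1")
})
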