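test_that("fixture generation is seed-deterministic", {
  a <- make_genome_and_annotation(fixture_spec(seed = 9))
  b <- make_genome_and_annotation(fixture_spec(seed = 9))
  expect_identical(a$genome, b$genome)
  expect_identical(a$elements, b$elements)
  expect_identical(lapply(a$transcripts, `[[`, "exons"),
                   lapply(b$transcripts, `[[`, "exons"))
  c2 <- make_genome_and_annotation(fixture_spec(seed = 10))
  expect_false(identical(a$genome, c2$genome))
  # file emission is byte-identical too
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture_files(a, d1); write_fixture_files(b, d2)
  expect_identical(readLines(file.path(d1, "annotation.gtf")),
                   readLines(file.path(d2, "annotation.gtf")))
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
})

test_that("generated transcripts satisfy the annotation invariants", {
  fix <- make_genome_and_annotation(fixture_spec(seed = 12))
  for (tr in fix$transcripts) {
    ex <- tr$exons
    expect_true(all(ex[, 2] > ex[, 1]))
    if (nrow(ex) > 1) expect_true(all(ex[-1, 1] >= ex[-nrow(ex), 2]))
    expect_equal(tr$mature_length, sum(ex[, 2] - ex[, 1]))
    mature <- extract_mature_sequence(tr, fix$genome)
    expect_equal(nchar(mature), tr$mature_length)
    if (!is.null(tr$regions)) {
      expect_true(all(tr$regions$start >= 0))
      expect_true(all(tr$regions$end <= tr$mature_length))
    }
  }
  # both strands and both biotypes appear
  strands <- vapply(fix$transcripts, `[[`, character(1), "strand")
  biotypes <- vapply(fix$transcripts, `[[`, character(1), "biotype")
  expect_setequal(unique(strands), c("+", "-"))
  expect_true(all(c("protein_coding", "lncRNA") %in% biotypes))
})

test_that("decoy isoforms exercise every priority key", {
  fix <- make_genome_and_annotation(fixture_spec(seed = 13))
  ids <- vapply(fix$transcripts, `[[`, character(1), "gene_id")
  g1 <- fix$transcripts[ids == "G001"]
  expect_gte(length(g1), 3L)
  keys <- lapply(g1, function(t) list(t$appris_rank, t$has_ccds,
                                      t$transcript_level, t$mature_length))
  expect_equal(length(unique(keys)), length(keys))
  # selection picks the intended principal
  expect_equal(select_principal_transcript(g1)$transcript_id, "G001.T1")
  g2 <- fix$transcripts[ids == "G002"]
  expect_equal(select_principal_transcript(g2)$transcript_id, "G002.T1")
})

test_that("GTF/FASTA round trip preserves the annotation", {
  fix <- make_genome_and_annotation(fixture_spec(seed = 14))
  dir <- tempfile()
  paths <- write_fixture_files(fix, dir)
  genome2 <- read_genome(paths$fasta)
  expect_identical(unname(genome2), unname(fix$genome))
  back <- read_transcripts(paths$gtf)
  expect_setequal(names(back), names(fix$transcripts))
  for (id in names(fix$transcripts)) {
    orig <- fix$transcripts[[id]]
    got <- back[[id]]
    expect_equal(got$exons, orig$exons, ignore_attr = TRUE)
    expect_equal(got$strand, orig$strand)
    expect_equal(got$biotype, orig$biotype)
    expect_equal(got$appris_rank, orig$appris_rank)
    expect_equal(got$has_ccds, orig$has_ccds)
    expect_equal(got$transcript_level, orig$transcript_level)
    if (!is.null(orig$regions)) {
      expect_equal(got$regions[order(got$regions$start), ],
                   orig$regions[order(orig$regions$start), ],
                   ignore_attr = TRUE)
    }
    # identical mature sequence through either representation
    expect_equal(extract_mature_sequence(got, genome2),
                 extract_mature_sequence(orig, fix$genome))
  }
})

test_that("hairpin benchmark pairs have the stated geometry", {
  pairs <- make_hairpin_benchmark(40, stem_len = 7, loop_len = 5, seed = 15)
  expect_equal(nrow(pairs), 40L)
  expect_true(all(nchar(pairs$sequence) == 101L))
  expect_true(all(pairs$snv_pos == 50L))
  expect_true(all(substr(pairs$sequence, 51, 51) == pairs$ref))
  expect_true(all(pairs$ref != pairs$alt))
  expect_equal(sum(pairs$label == "ribosnitch"), 20L)
  # negatives always substitute an inert loop A by C
  expect_true(all(pairs$ref[pairs$label == "non_ribosnitch"] == "A"))
  expect_true(all(pairs$alt[pairs$label == "non_ribosnitch"] == "C"))
  # positives always hit the G/C stem
  expect_true(all(pairs$ref[pairs$label == "ribosnitch"] %in% c("G", "C")))
  expect_identical(pairs, make_hairpin_benchmark(40, stem_len = 7,
                                                 loop_len = 5, seed = 15))
})

test_that("mutation cohorts carry planted somatic effects only", {
  fix <- make_genome_and_annotation(fixture_spec(seed = 16))
  coh <- make_mutation_cohort(fix, study_config(), w = 15L)
  expect_identical(coh$somatic,
                   make_mutation_cohort(fix, study_config(), w = 15L)$somatic)
  for (m in list(coh$somatic, coh$germline)) {
    expect_true(all(m$ref %in% c("A", "C", "G", "T")))
    expect_true(all(m$ref != m$alt))
    # every record matches the genome reference
    expect_equal(substring(fix$genome[[1]], m$pos, m$pos), m$ref)
  }
  expect_setequal(unique(coh$somatic$cohort), "somatic")
  expect_setequal(unique(coh$germline$cohort), "germline")
  # intronic mutations present in both cohorts (needed for the profile)
  pr <- principal_transcripts(fix$transcripts)
  count_intronic <- function(m) {
    n <- 0L
    for (tr in pr) {
      mm <- map_mutations(m, tr, fix$genome)
      n <- n + sum(mm$region == "intron", na.rm = TRUE)
    }
    n
  }
  expect_gt(count_intronic(coh$somatic), 100L)
  expect_gt(count_intronic(coh$germline), 100L)
})

test_that("intronic draws recover the fixture profile", {
  fix <- make_genome_and_annotation(fixture_spec(seed = 17, n_intronic = 2000L))
  coh <- make_mutation_cohort(fix, study_config(), w = 15L)
  pr <- principal_transcripts(fix$transcripts)
  intr <- list()
  for (tr in pr) {
    mm <- map_mutations(coh$somatic, tr, fix$genome)
    intr[[length(intr) + 1L]] <- mm[mm$region == "intron" & !is.na(mm$region), ]
  }
  intr <- do.call(rbind, intr)
  est <- build_profile(intr)
  target <- default_fixture_profile()
  tv <- sum(abs(est$rate - target)) / 2
  # draws are recalibrated by intron composition, so frequencies deviate
  # from the flat target by the context weighting; the bound is loose
  expect_lt(tv, 0.25)
  # every observed class belongs to the C>A signature block
  expect_true(all(which(est$rate > 0) <= 16))
})
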