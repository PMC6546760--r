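#' Map and score a mutation cohort over principal transcripts
#'
#' Selects one principal transcript per gene, maps the cohort onto each,
#' separates intronic from exonic records and scores every exonic mutation's
#' structural impact. Mutations overlapping several genes' principal
#' transcripts are assigned to every one of them.
#'
#' @param genome Named character vector from [read_genome()].
#' @param transcripts List of [transcript()] objects (all isoforms).
#' @param mutations data.frame from [read_snvs()] (or a fixture cohort).
#' @param config A [fold_config()].
#' @param w Half-window for the difference statistics.
#' @param blacklist Optional blacklist passed to [filter_blacklist()].
#' @return List with `scores` (exonic mapped mutations with `mean_diff`,
#'   `euc_diff`, `element_id` where applicable), `intronic` (mapped
#'   intronic records), `principals`, `matures`.
#' @export
score_cohort <- function(genome, transcripts, mutations,
                         config = fold_config(), w = 200L,
                         blacklist = NULL) {
  if (!is.null(blacklist)) mutations <- filter_blacklist(mutations, blacklist)
  principals <- principal_transcripts(transcripts)
  matures <- lapply(principals, extract_mature_sequence, genome = genome)
  scores <- list(); intronic <- list()
  for (gid in names(principals)) {
    tr <- principals[[gid]]
    mapped <- map_mutations(mutations, tr, genome, mature = matures[[gid]])
    if (nrow(mapped) == 0L) next
    intr <- mapped[mapped$region == "intron" & !is.na(mapped$region), ,
                   drop = FALSE]
    if (nrow(intr)) intronic[[length(intronic) + 1L]] <- intr
    ex <- mapped[!is.na(mapped$k), , drop = FALSE]
    if (nrow(ex))
      scores[[length(scores) + 1L]] <- score_mutations(ex, matures[[gid]],
                                                       config, w)
  }
  scores <- if (length(scores)) do.call(rbind, scores) else NULL
  intronic <- if (length(intronic)) do.call(rbind, intronic) else
    empty_mapped()
  if (!is.null(scores)) {
    scores$element_id <- ifelse(
      scores$region %in% c("5UTR", "3UTR", "lncRNA"),
      paste0(vapply(scores$transcript_id, function(t)
        transcripts[[t]]$gene_name, character(1)),
        ":", scores$region), NA_character_)
  }
  list(scores = scores, intronic = intronic, principals = principals,
       matures = matures)
}

#' Full riboSNitch element scan
#'
#' End-to-end analysis of a somatic cohort: scores structural disruption of
#' every exonic mutation, calls riboSNitches by dual-tail intersection,
#' builds the intronic neutral profile, simulates a neutral cohort per
#' element (recalibrated to element trinucleotide composition), derives the
#' expected riboSNitch counts from the pooled simulated distribution, and
#' tests each element for enrichment and depletion with one-sided Fisher's
#' exact tests under BH control per element class. With a germline cohort,
#' elements are additionally tested for cancer specificity (strictly
#' p < 1e-3, in the element's own direction).
#'
#' @param genome,transcripts Annotation inputs (see [score_cohort()]).
#' @param somatic Somatic mutation data.frame.
#' @param germline Optional germline mutation data.frame.
#' @param config A [fold_config()].
#' @param w Half-window for MeanDiff/EucDiff.
#' @param top_fraction,bottom_fraction Dual-tail fractions (default 2.5%;
#'   0.05/0.10/0.20 give the relaxed variants).
#' @param n_sims Simulated mutations per element (the neutral expectation;
#'   1000 reproduces the reference protocol, smaller values trade
#'   resolution for speed).
#' @param seed Seed for the simulation draws.
#' @param blacklist Optional blacklist intervals.
#' @return List of class `element_scan` with `results` (per-element tests),
#'   `cutoffs` (observed somatic), `sim_cutoffs`, `profile`, `scores`
#'   (somatic, with `call` column), `germline_scores`, `n_sims`, `seed`.
#' @export
element_scan <- function(genome, transcripts, somatic, germline = NULL,
                         config = fold_config(), w = 200L,
                         top_fraction = 0.025, bottom_fraction = 0.025,
                         n_sims = 1000L, seed = 1L, blacklist = NULL) {
  som <- score_cohort(genome, transcripts, somatic, config, w, blacklist)
  if (is.null(som$scores)) stop("no scorable somatic mutations")
  if (nrow(som$intronic) == 0L) stop("no intronic mutations for the profile")
  profile <- build_profile(som$intronic, normalization = "frequency",
                           source_cohort = unique(somatic$cohort)[1L])
  cutoffs <- compute_cutoffs(som$scores, top_fraction, bottom_fraction,
                             cohort_label = "somatic")
  som$scores$call <- call_ribosnitches(som$scores, cutoffs)

  elem_scores <- som$scores[!is.na(som$scores$element_id), , drop = FALSE]
  if (nrow(elem_scores) == 0L) stop("no element mutations")
  observed <- aggregate_calls(elem_scores)

  set.seed(seed)
  sims <- simulate_elements(som, profile, observed$element_id, config, w,
                            n_sims)
  expected <- expected_ribo_count(sims, top_fraction, bottom_fraction)

  results <- test_elements(observed, expected$per_element)

  germ_scores <- NULL
  if (!is.null(germline)) {
    ger <- score_cohort(genome, transcripts, germline, config, w, blacklist)
    if (!is.null(ger$scores)) {
      g_cutoffs <- compute_cutoffs(ger$scores, top_fraction, bottom_fraction,
                                   cohort_label = "germline")
      ger$scores$call <- call_ribosnitches(ger$scores, g_cutoffs)
      germ_scores <- ger$scores
      g_elem <- ger$scores[!is.na(ger$scores$element_id), , drop = FALSE]
      g_obs <- aggregate_calls(g_elem)
      names(g_obs)[names(g_obs) == "obs_ribo"] <- "germ_ribo"
      names(g_obs)[names(g_obs) == "obs_total"] <- "germ_total"
      results <- merge(results,
                       g_obs[, c("element_id", "germ_ribo", "germ_total")],
                       by = "element_id", all.x = TRUE)
      results$germ_ribo[is.na(results$germ_ribo)] <- 0L
      results$germ_total[is.na(results$germ_total)] <- 0L
      cs <- mapply(function(rc, tc, rg, tg, pe, pd) {
        dir <- if (pe <= pd) "greater" else "less"
        unlist(cancer_specific_test(rc, tc, rg, tg, dir))
      }, results$obs_ribo, results$obs_total, results$germ_ribo,
         results$germ_total, results$p_enriched, results$p_depleted)
      results$cancer_specific_p <- as.numeric(cs["p", ])
      results$cancer_specific <- as.logical(cs["is_specific", ])
    }
  }
  structure(list(results = results, cutoffs = cutoffs,
                 sim_cutoffs = expected$cutoffs, profile = profile,
                 scores = som$scores, germline_scores = germ_scores,
                 n_sims = n_sims, seed = seed),
            class = "element_scan")
}

aggregate_calls <- function(elem_scores) {
  ribo <- elem_scores$call == "ribosnitch"
  ids <- sort(unique(elem_scores$element_id))
  data.frame(
    element_id = ids,
    element_class = vapply(ids, function(i)
      elem_scores$region[match(i, elem_scores$element_id)], character(1)),
    obs_ribo = vapply(ids, function(i)
      sum(ribo[elem_scores$element_id == i]), numeric(1)),
    obs_total = vapply(ids, function(i)
      sum(elem_scores$element_id == i), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

simulate_elements <- function(som, profile, element_ids, config, w, n_sims) {
  out <- list()
  for (eid in element_ids) {
    gname <- sub(":[^:]*$", "", eid)
    region <- sub("^.*:", "", eid)
    gid <- NULL
    for (g in names(som$principals))
      if (som$principals[[g]]$gene_name == gname) { gid <- g; break }
    if (is.null(gid)) next
    tr <- som$principals[[gid]]
    mature <- som$matures[[gid]]
    interval <- if (region == "lncRNA") c(0L, tr$mature_length) else {
      reg <- tr$regions[tr$regions$region == region, ]
      c(reg$start[1L], reg$end[1L])
    }
    dist <- recalibrate_profile(
      profile,
      transcript_composition(substr(mature, interval[1] + 1L, interval[2])))
    sim <- simulate_mutations(mature, dist, n_sims, interval = interval)
    ref_profile <- if (nchar(mature) <= config$window_W &&
                       config$backend == "internal")
      pairedness_profile(mature, config) else NULL
    sc <- do.call(rbind, lapply(seq_len(nrow(sim)), function(i) {
      score_mutation(mature, sim$k[i], sim$alt_t[i], config, w,
                     ref_profile = ref_profile)
    }))
    sc$element_id <- eid
    out[[length(out) + 1L]] <- sc
  }
  do.call(rbind, out)
}

#' @export
print.element_scan <- function(x, ...) {
  r <- x$results
  cat(sprintf("element_scan: %d elements, %d somatic scores, n_sims=%d\n",
              nrow(r), nrow(x$scores), x$n_sims))
  cat(sprintf("  enriched (q<0.05): %d, depleted (q<0.05): %d\n",
              sum(r$q_enriched < 0.05), sum(r$q_depleted < 0.05)))
  if ("cancer_specific" %in% names(r))
    cat(sprintf("  cancer-specific (p<1e-3): %d\n",
                sum(r$cancer_specific, na.rm = TRUE)))
  invisible(x)
}

#' Write scores or results as TSV
#'
#' @param x data.frame.
#' @param path Output file.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
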