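#' Run the full TBE annotation and evolution pipeline
#'
#' Stages in order: (optional) genome simulation, six-frame translated
#' search, element assembly, TIR/TSD detection, family clustering,
#' integrity profiling, pairwise dN/dS with the purifying-selection test,
#' and track-enrichment context. With a `synth_config` the run is fully
#' self-contained and deterministic for a given seed.
#'
#' @param cfg A [synth_config()] (used when `genome` is NULL).
#' @param genome Optional genome (`DNAStringSet` or FASTA path).
#' @param queries Optional named protein queries (`orf42`, `orf22`,
#'   `orf57`); required with a user genome.
#' @param mds,satellite Optional annotation tracks (`GRanges`).
#' @param scheme A [scoring_scheme()].
#' @param acfg An [annotate_config()].
#' @param max_pairs Cap on sampled pairs per group for the similarity and
#'   dN/dS tables.
#' @param out_dir Optional output directory for artifacts (FASTA, GFF3,
#'   TSV, JSON summary).
#' @return A list of class `tbe_report`: the annotation, integrity calls,
#'   report tables (distribution, similarity, TIR features, integrity
#'   prevalence, dN/dS summary, enrichment), stage record counts, and the
#'   simulation truth when simulated.
#' @export
run_pipeline <- function(cfg = synth_config(), genome = NULL,
                         queries = NULL, mds = NULL, satellite = NULL,
                         scheme = scoring_scheme(),
                         acfg = annotate_config(), max_pairs = 10,
                         out_dir = NULL) {
  sim <- NULL
  if (is.null(genome)) {
    sim <- simulate_genome(cfg)
    genome <- sim$genome
    queries <- sim$queries
    mds <- sim$mds
    satellite <- sim$satellite
  } else {
    if (is.character(genome)) genome <- read_genome(genome)
    if (is.null(queries)) stop("queries are required with a user genome")
  }
  set.seed(cfg$seed + 1L)
  counts <- list(contigs = length(genome))

  hits <- search_protein(queries, genome, scheme)
  counts$hits <- nrow(hits)

  ann <- assemble_elements(hits, acfg)
  ann <- flag_context(ann, genome, acfg)
  counts$elements <- nrow(ann$elements)
  counts$complete <- sum(ann$elements$completeness == "complete")

  fams <- tryCatch(cluster_families(ann, genome),
                   error = function(e) NULL)
  if (!is.null(fams)) ann <- apply_families(ann, fams)
  counts$families <- if (is.null(fams)) 0L else
    length(unique(stats::na.omit(fams$membership)))

  # pass 1 with the global queries seeds per-family consensus proteins;
  # pass 2 with those refines CDS spans and integrity calls
  integ1 <- integrity_scan(ann, genome, queries)
  famq <- family_consensus_queries(integ1, queries, ann, genome)
  integ <- integrity_scan(ann, genome, famq)
  ann <- refine_orf_coords(ann, integ)
  counts$cds_alignments <- nrow(integ)

  ann <- detect_tir(ann, genome)
  ann <- call_tsd(ann, genome)

  # dN/dS per family x role, stratified by that gene's own integrity
  alns <- attr(integ, "alignments")
  regions <- attr(integ, "regions")
  est_all <- list()
  drop_tally <- c(low_coverage = 0L)
  for (fam in sort(unique(stats::na.omit(integ$family)))) {
    for (role in tbe_roles) {
      w <- which(integ$family == fam & integ$role == role &
                   integ$coverage >= 0.5)
      if (length(w) < 2) next
      drop_tally["low_coverage"] <- drop_tally["low_coverage"] +
        sum(integ$family == fam & integ$role == role &
              integ$coverage < 0.5, na.rm = TRUE)
      keys <- paste0(integ$element_id[w], ".", integ$role[w])
      cds <- vapply(keys, function(k) {
        repair_sequence(alns[[k]], regions[[k]])
      }, character(1))
      names(cds) <- integ$element_id[w]
      degen <- integ$has_premature_stop[w] | integ$has_frameshift[w]
      prs <- t(utils::combn(names(cds), 2))
      if (nrow(prs) > max_pairs) {
        prs <- prs[sample.int(nrow(prs), max_pairs), , drop = FALSE]
      }
      est <- ng86_pairs(cds, prs)
      da <- degen[match(est$id_a, names(cds))]
      db <- degen[match(est$id_b, names(cds))]
      est$group <- paste0(fam, ".", role, ".",
                          ifelse(da | db, "degenerate", "intact"))
      est$family <- fam
      est$role <- role
      est_all[[paste(fam, role)]] <- est
    }
  }
  est_all <- if (length(est_all)) do.call(rbind, est_all) else NULL
  omega_tab <- if (!is.null(est_all)) omega_distribution(est_all) else NULL
  neut <- NULL
  if (!is.null(est_all)) {
    v <- est_all[est_all$valid, ]
    if (nrow(v) && sum(v$Sd + v$Nd) >= 1) {
      neut <- neutrality_test(sum(v$S), sum(v$N), sum(v$Sd), sum(v$Nd))
    }
  }

  # report tables
  t1 <- element_table(ann, track = mds)
  prot <- list()
  grp <- list()
  for (role in tbe_roles) {
    w <- which(!is.na(integ$family) & integ$role == role &
                 integ$coverage >= 0.5)
    for (i in w) {
      key <- paste0(integ$element_id[i], ".", role)
      cdsr <- repair_sequence(alns[[key]], regions[[key]])
      prot[[paste0(role, ".", integ$element_id[i])]] <-
        gsub("\\*", "X", translate_cds(cdsr))
      grp[[paste0(role, ".", integ$element_id[i])]] <-
        paste0(integ$family[i], ".", role)
    }
  }
  t2 <- if (length(prot) >= 2) {
    pairwise_protein_similarity(unlist(prot), unlist(grp),
                                max_pairs = max_pairs)
  } else NULL
  dstats <- distance_stats(ann)
  t3 <- list()
  for (fam in sort(unique(stats::na.omit(ann$elements$family)))) {
    tirs <- tir_sequences(ann, genome, family = fam)
    cons <- if (length(tirs)) tir_consensus(tirs) else NULL
    tsds <- ann$elements$tsd[!is.na(ann$elements$family) &
                               ann$elements$family == fam]
    tsds <- tsds[!is.na(tsds)]
    t3[[fam]] <- list(
      family = fam,
      tir_consensus = if (!is.null(cons)) cons$consensus[1L] else NA,
      n_tir = length(tirs),
      telomeric = if (length(tirs))
        scan_telomeric(cons$consensus[1L])$status else NA,
      tsd_mode = if (length(tsds)) names(sort(table(tsds),
                                              decreasing = TRUE))[1L] else NA,
      distances = dstats[dstats$family == fam, ])
  }
  t4 <- integrity_table(integ)
  enr <- NULL
  if (!is.null(mds) && length(mds) && nrow(ann$elements)) {
    comp <- ann$elements$completeness == "complete"
    sub <- ann
    sub$elements <- ann$elements[comp, , drop = FALSE]
    enr <- enrichment_near_track(sub, mds, genome)
  }
  report <- structure(list(
    annotation = ann, integrity = integ, estimates = est_all,
    tables = list(distribution = t1, similarity = t2, tir_features = t3,
                  integrity = t4, omega = omega_tab, enrichment = enr,
                  neutrality = neut),
    counts = counts, dropped = drop_tally, seed = cfg$seed,
    truth = if (is.null(sim)) NULL else sim$truth,
    truth_orfs = if (is.null(sim)) NULL else sim$truth_orfs,
    queries = queries), class = "tbe_report")
  if (!is.null(out_dir)) write_report(report, genome, out_dir)
  report
}

write_report <- function(report, genome, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(genome, file.path(out_dir, "genome.fa"))
  write_gff3(report$annotation, file.path(out_dir, "elements.gff3"))
  utils::write.table(report$annotation$elements,
                     file.path(out_dir, "elements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$integrity, file.path(out_dir, "integrity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$estimates)) {
    utils::write.table(report$estimates, file.path(out_dir, "dnds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(counts = report$counts, seed = report$seed,
                  dropped = as.list(report$dropped))
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.tbe_report <- function(x, ...) {
  cat("TBE pipeline report\n")
  cat("  contigs:", x$counts$contigs, " hits:", x$counts$hits,
      " elements:", x$counts$elements,
      " (complete:", x$counts$complete, ")\n")
  cat("  families:", x$counts$families, "\n")
  if (!is.null(x$tables$omega)) {
    cat("  dN/dS groups:\n")
    print(x$tables$omega[, c("group", "n", "median")])
  }
  invisible(x)
}

#' Score a pipeline run against simulation ground truth
#'
#' @param report A `tbe_report` from a simulated run (or a
#'   `tbe_annotation`).
#' @param truth,truth_orfs Ground-truth tables from [simulate_genome()]
#'   (taken from the report when omitted).
#' @return List scorecard: complete-element recall and precision, median
#'   ORF-envelope boundary error (bp), family Rand index over matched
#'   complete elements, and TSD accuracy.
#' @export
compare_to_truth <- function(report, truth = NULL, truth_orfs = NULL) {
  ann <- if (is(report, "tbe_annotation")) report else report$annotation
  if (is.null(truth)) truth <- report$truth
  if (is.null(truth_orfs)) truth_orfs <- report$truth_orfs
  stopifnot(!is.null(truth))
  el <- ann$elements
  if (length(setdiff(unique(el$contig), unique(truth$contig))) &&
      nrow(el)) {
    # called contigs must exist in truth's namespace
    extra <- setdiff(unique(el$contig), unique(truth$contig))
    # contigs without implants legitimately produce no elements; only a
    # disjoint namespace is an error
    if (!length(intersect(unique(el$contig), unique(truth$contig)))) {
      stop("annotation and truth share no contigs: ", extra[1L])
    }
  }
  tc <- truth[truth$completeness == "complete", , drop = FALSE]
  called <- el[el$completeness == "complete", , drop = FALSE]
  match_of <- rep(NA_integer_, nrow(called))
  for (i in seq_len(nrow(called))) {
    w <- which(tc$contig == called$contig[i] &
                 pmin(tc$end, called$end[i]) -
                   pmax(tc$start, called$start[i]) + 1 >=
                 0.5 * (called$end[i] - called$start[i] + 1))
    if (length(w)) match_of[i] <- w[1L]
  }
  recall <- length(unique(stats::na.omit(match_of))) / max(nrow(tc), 1L)
  precision <- mean(!is.na(match_of))
  boundary <- NA_real_
  fam_rand <- NA_real_
  tsd_acc <- NA_real_
  ok <- !is.na(match_of)
  if (any(ok) && !is.null(truth_orfs)) {
    errs <- numeric(0)
    for (i in which(ok)) {
      ot <- truth_orfs[truth_orfs$copy_id == tc$copy_id[match_of[i]], ]
      if (!nrow(ot)) next
      errs <- c(errs, abs(called$env_start[i] - min(ot$start)),
                abs(called$env_end[i] - max(ot$end)))
    }
    boundary <- stats::median(errs)
  }
  if (any(ok)) {
    tf <- tc$family[match_of[ok]]
    cf <- called$family[ok]
    keep <- !is.na(cf)
    if (sum(keep) >= 2) fam_rand <- rand_index(tf[keep], cf[keep])
    if ("tsd" %in% names(called)) {
      tsd_acc <- mean(called$tsd[ok] == tc$tsd[match_of[ok]],
                      na.rm = TRUE)
    }
  }
  list(n_truth_complete = nrow(tc), n_called_complete = nrow(called),
       recall = recall, precision = precision,
       boundary_error_bp = boundary, family_rand_index = fam_rand,
       tsd_accuracy = tsd_acc)
}
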