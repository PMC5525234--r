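# End-to-end orchestration: qc -> map -> conserve -> constriction ->
# classify -> pairwise -> operon, with TSV/JSON reports and a run manifest.

#' Run the full FNT analysis pipeline
#'
#' Executes every stage on a FASTA input and writes one report per stage
#' plus a run manifest (package version, parameters, input digests). All
#' randomness is seeded, and reports are written with fixed formatting, so
#' two runs with identical inputs and configuration are byte-identical.
#'
#' @param fasta Path to the input protein FASTA.
#' @param out_dir Output directory (created if needed).
#' @param features Optional genome feature table path (GFF3 or TSV); when
#'   absent the operon stage is skipped with a logged notice.
#' @param reference Optional reference annotation path (default bundled).
#' @param species_tsv Optional sidecar TSV with id/species columns.
#' @param min_length,min_segment_coverage,redundancy_threshold QC
#'   thresholds (see [qc_filter()], [cluster_redundancy()]).
#' @param outlier_k Z-score threshold for [flag_unusual()].
#' @param margin_min Classification margin (see [classify()]).
#' @param conservation_positions Reference positions for the conservation
#'   report (default: every segment position).
#' @param run_pairwise Compute the group identity/similarity matrix
#'   (quadratic in cohort size; disable for very large runs).
#' @param seed Integer seed.
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with every stage result and the report paths.
#' @export
fnt_run_all <- function(fasta, out_dir, features = NULL, reference = NULL,
                        species_tsv = NULL, min_length = 150,
                        min_segment_coverage = 0.5,
                        redundancy_threshold = 0.98, outlier_k = 2.5,
                        margin_min = 0.25, conservation_positions = NULL,
                        run_pairwise = TRUE, seed = 1, verbose = TRUE) {
  log_msg <- function(...) if (verbose) message("[fntscan] ", ...)
  if (!file.exists(fasta)) stop("input FASTA not found: ", fasta, call. = FALSE)
  if (!is.null(features) && !file.exists(features)) {
    stop("feature table not found: ", features, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  frame <- load_reference(reference)
  paths <- character(0)

  log_msg("reading ", fasta)
  records <- read_protein_fasta(fasta, species_tsv)

  log_msg("redundancy reduction at ", redundancy_threshold * 100, "% identity")
  red <- cluster_redundancy(records, threshold = redundancy_threshold)
  records2 <- records[records$id %in% red$kept, , drop = FALSE]

  log_msg("QC + mapping of ", nrow(records2), " sequences")
  qc <- qc_filter(records2, frame, min_length = min_length,
                  min_segment_coverage = min_segment_coverage)
  qc$discarded <- rbind(red$discarded, qc$discarded)
  paths["qc"] <- file.path(out_dir, "qc_report.tsv")
  write_qc_report(qc, paths["qc"])
  mapset <- qc$maps
  if (length(mapset) == 0L) stop("no sequences survived QC", call. = FALSE)
  paths["maps"] <- file.path(out_dir, "maps.tsv")
  write_maps_tsv(mapset, paths["maps"])

  log_msg("conservation profile")
  if (is.null(conservation_positions)) {
    conservation_positions <- segment_positions(frame)
  }
  cons <- conservation_table(mapset, conservation_positions)
  paths["conservation"] <- file.path(out_dir, "conservation.tsv")
  write_tsv0(cons, paths["conservation"])

  log_msg("subfamily classification")
  cls <- classify_cohort(mapset, margin_min = margin_min)
  paths["classification"] <- file.path(out_dir, "classification.tsv")
  write_tsv0(cls, paths["classification"])

  log_msg("constriction-site scoring")
  scores <- score_sites_cohort(mapset)
  grouping <- cls$label[match(scores$sequence_id, cls$id)]
  scores <- suppressWarnings(
    flag_unusual(scores, grouping = grouping, k = outlier_k))
  paths["constriction"] <- file.path(out_dir, "constriction.tsv")
  write_tsv0(scores, paths["constriction"])

  gm <- NULL
  if (run_pairwise) {
    classified <- cls$label != "unclassified"
    tab <- table(cls$label[classified])
    ok_groups <- names(tab)[tab >= 2L]
    sel <- classified & cls$label %in% ok_groups
    if (sum(sel) >= 2L) {
      log_msg("pairwise identity/similarity over ", sum(sel), " sequences")
      gm <- group_average_matrix(map_set(mapset[sel], frame),
                                 cls$label[sel])
      paths["pairwise"] <- file.path(out_dir, "pairwise_identity.tsv")
      paths["pairwise_json"] <- file.path(out_dir, "pairwise.json")
      write_group_matrix(gm, paths["pairwise"], paths["pairwise_json"])
    } else {
      log_msg("pairwise stage skipped: fewer than two classified sequences")
    }
  }

  op <- NULL
  if (!is.null(features)) {
    log_msg("operon support scan")
    feat <- read_features(features)
    loci <- intersect(vapply(mapset, `[[`, "", "id"), feat$locus_tag)
    op <- operon_support_table(feat, loci)
    op$subfamily <- cls$label[match(op$fnt_locus, cls$id)]
    paths["operons"] <- file.path(out_dir, "operons.tsv")
    write_tsv0(op, paths["operons"])
  } else {
    log_msg("operon stage skipped: no feature table supplied")
  }

  paths["manifest"] <- file.path(out_dir, "manifest.txt")
  inputs <- c(fasta = fasta, features = features)
  digests <- tools::md5sum(unlist(inputs))
  manifest <- c(
    paste0("fntscan version: ", as.character(utils::packageVersion("fntscan"))),
    paste0("reference: ", frame$name),
    sprintf("input %s: %s md5=%s", names(inputs), unlist(inputs), digests),
    sprintf("parameters: min_length=%d min_segment_coverage=%g redundancy_threshold=%g outlier_k=%g margin_min=%g seed=%d",
            min_length, min_segment_coverage, redundancy_threshold,
            outlier_k, margin_min, seed),
    sprintf("sequences: input=%d kept=%d discarded=%d", nrow(records),
            length(qc$kept), nrow(qc$discarded)),
    sprintf("reports: %s", paste(basename(paths), collapse = ", ")))
  writeLines(manifest, paths["manifest"])

  log_msg("done: ", length(paths), " files in ", out_dir)
  invisible(list(frame = frame, qc = qc, mapset = mapset,
                 conservation = cons, classification = cls,
                 constriction = scores, pairwise = gm, operons = op,
                 paths = paths))
}
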