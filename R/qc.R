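# Sequence quality control: length filter, mapping-coverage completeness
# check, and greedy redundancy reduction with a species-retention rule.

#' Length and segment-coverage quality filter
#'
#' Discards sequences shorter than `min_length` (an FNT channel needs six
#' transmembrane segments, so very short records cannot be complete), then
#' aligns the remainder to the reference and discards records in which any
#' of the ten segments has mapped coverage below `min_segment_coverage`
#' (the mapping-coverage reinterpretation of a missing-TM check) or that
#' cannot be aligned at all.
#'
#' @param records Data frame with columns `id`, `sequence`, optional
#'   `species`.
#' @param frame Reference frame.
#' @param min_length Minimum sequence length (residues).
#' @param min_segment_coverage Minimum per-segment mapped fraction.
#' @param ... Passed to [align_to_reference()].
#' @return An object of class `fnt_qc`: list with `kept` (character ids),
#'   `discarded` (data frame id, reason), and `maps` (an `fnt_mapset` of
#'   the kept records).
#' @export
qc_filter <- function(records, frame, min_length = 150,
                      min_segment_coverage = 0.5, ...) {
  if (nrow(records) == 0L) stop("no records supplied", call. = FALSE)
  species <- if ("species" %in% names(records)) records$species
             else rep(NA_character_, nrow(records))
  kept <- character(0)
  maps <- list()
  disc_id <- character(0); disc_reason <- character(0)
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    if (nchar(records$sequence[i]) < min_length) {
      disc_id <- c(disc_id, id); disc_reason <- c(disc_reason, "too_short")
      next
    }
    m <- tryCatch(
      align_to_reference(records$sequence[i], frame, id = id,
                         species = species[i], ...),
      fnt_unalignable = function(e) NULL)
    if (is.null(m)) {
      disc_id <- c(disc_id, id); disc_reason <- c(disc_reason, "unalignable")
      next
    }
    if (any(m$coverage < min_segment_coverage)) {
      disc_id <- c(disc_id, id); disc_reason <- c(disc_reason, "missing_segment")
      next
    }
    kept <- c(kept, id)
    maps[[length(maps) + 1L]] <- m
  }
  structure(list(kept = kept,
                 discarded = data.frame(id = disc_id, reason = disc_reason,
                                        stringsAsFactors = FALSE),
                 maps = map_set(maps, frame)),
            class = "fnt_qc")
}

#' Greedy redundancy reduction at an identity threshold
#'
#' CD-HIT-style greedy clustering: records are sorted by descending length
#' (ties by id), each record joins the first representative with percent
#' identity at or above `threshold`, and non-representatives are discarded
#' as redundant -- unless their species label differs from the
#' representative's, in which case they are retained.
#'
#' @param records Data frame with columns `id`, `sequence`, optional
#'   `species`.
#' @param threshold Identity threshold as a fraction (default 0.98).
#' @param ... Passed to the pairwise identity computation.
#' @return An `fnt_qc` object (`maps` empty; this stage is sequence-only).
#' @export
cluster_redundancy <- function(records, threshold = 0.98, ...) {
  species <- if ("species" %in% names(records)) records$species
             else rep(NA_character_, nrow(records))
  ord <- order(-nchar(records$sequence), records$id)
  reps <- integer(0)
  kept <- character(0)
  disc_id <- character(0)
  for (i in ord) {
    hit <- 0L
    for (r in reps) {
      idp <- sequence_identity(records$sequence[r], records$sequence[i], ...)
      if (idp >= threshold * 100) { hit <- r; break }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      kept <- c(kept, records$id[i])
    } else if (!is.na(species[i]) && !is.na(species[hit]) &&
               species[i] != species[hit]) {
      kept <- c(kept, records$id[i])  # same cluster, different species: retain
    } else {
      disc_id <- c(disc_id, records$id[i])
    }
  }
  structure(list(kept = kept,
                 discarded = if (length(disc_id))
                   data.frame(id = disc_id, reason = "redundant",
                              stringsAsFactors = FALSE)
                 else data.frame(id = character(0), reason = character(0),
                                 stringsAsFactors = FALSE),
                 maps = NULL),
            class = "fnt_qc")
}

#' @export
print.fnt_qc <- function(x, ...) {
  cat(sprintf("fnt_qc: %d kept, %d discarded", length(x$kept),
              nrow(x$discarded)))
  if (nrow(x$discarded) > 0L) {
    tab <- table(x$discarded$reason)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param qc An `fnt_qc` object.
#' @param path Output path.
#' @export
write_qc_report <- function(qc, path) {
  df <- rbind(
    data.frame(id = qc$kept, status = "kept", reason = NA_character_,
               stringsAsFactors = FALSE),
    if (nrow(qc$discarded) > 0L)
      data.frame(id = qc$discarded$id, status = "discarded",
                 reason = qc$discarded$reason, stringsAsFactors = FALSE))
  write_tsv0(df, path)
}
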