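# Position-wise conservation statistics over mapped sequence sets:
# individual-residue frequencies, character-class (group) conservation,
# and loop/termini length statistics.

#' Default residue-class registry
#'
#' Character classes used for group conservation. `small_weakly_polar`
#' (G, A, S, T, C) is the class whose joint conservation marks tight
#' helix-helix packing positions; the remaining classes support
#' hydrophobic/hydrophilic/aromatic/charge character scans. The exact
#' membership of broad classes like "hydrophilic" is a documented
#' convention, not a family-specific result; override by passing your own
#' named list wherever a `classes` argument appears.
#'
#' @return Named list of character vectors of one-letter residue codes.
#' @export
residue_classes <- function() {
  list(
    small_weakly_polar = c("G", "A", "S", "T", "C"),
    aromatic           = c("F", "Y", "W"),
    hydrophobic        = c("A", "V", "L", "I", "M", "F", "C", "W"),
    acidic             = c("D", "E"),
    basic              = c("K", "R"),
    hydrophilic        = c("N", "Q", "S", "T", "H", "D", "E", "K", "R"))
}

#' Conservation profile of one reference position
#'
#' Counts residues over the non-gap observations of a column; gaps are
#' excluded from the denominator (percentages are over the channels that
#' possess the position). An all-gap column is reported as missing
#' (`n_effective = 0`, percentages `NA`), not as 0%.
#'
#' @param mapset An `fnt_mapset`.
#' @param position Reference position (31-275).
#' @param classes Residue-class registry (see [residue_classes()]).
#' @param top_min Individual frequency at or above which a residue is listed
#'   in `top_residues`.
#' @return List with `position`, `segment`, `n_effective`, `counts` (named,
#'   descending), `freqs`, `top_residues`, `class_percentages`.
#' @export
column_profile <- function(mapset, position, classes = residue_classes(),
                           top_min = 0.1) {
  stopifnot(length(mapset) > 0L)
  col <- residue_matrix(mapset, position)[, 1L]
  col <- col[!is.na(col)]
  frame <- attr(mapset, "frame")
  seg <- segment_of(frame, position)
  if (length(col) == 0L) {
    return(list(position = position, segment = seg, n_effective = 0L,
                counts = integer(0), freqs = numeric(0),
                top_residues = character(0),
                class_percentages = setNames(rep(NA_real_, length(classes)),
                                             names(classes))))
  }
  counts <- sort(table(col), decreasing = TRUE)
  counts <- setNames(as.integer(counts), names(counts))
  freqs <- counts / length(col)
  cls <- vapply(classes, function(members) {
    100 * sum(freqs[names(freqs) %in% members])
  }, numeric(1L))
  list(position = position, segment = seg, n_effective = length(col),
       counts = counts, freqs = freqs,
       top_residues = names(freqs)[freqs >= top_min],
       class_percentages = cls)
}

# "G(95), C, S" style cell: residues by descending frequency; percentage in
# brackets for residues at or above `pct_show`.
format_top_residues <- function(freqs, list_min = 0.05, pct_show = 0.30) {
  freqs <- freqs[freqs >= list_min]
  if (length(freqs) == 0L) return("")
  lab <- names(freqs)
  show <- freqs >= pct_show
  lab[show] <- sprintf("%s(%.0f)", lab[show], 100 * freqs[show])
  paste(lab, collapse = ", ")
}

#' Conservation table over reference positions
#'
#' One row per position: segment, effective count, top residues (descending
#' frequency, percentages of the frequent residues in brackets), the
#' percentage of the most frequent residue, and one column per residue
#' class. Percentages are reported to one decimal place.
#'
#' @inheritParams column_profile
#' @param positions Integer vector of reference positions (31-275); an empty
#'   vector yields an empty table.
#' @return Data frame keyed by `position`.
#' @export
conservation_table <- function(mapset, positions,
                               classes = residue_classes()) {
  cols <- c("position", "segment", "n_effective", "top_residues",
            "top_pct", names(classes))
  if (length(positions) == 0L) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$segment <- character(0); out$top_residues <- character(0)
    return(out)
  }
  rows <- lapply(positions, function(p) {
    pr <- column_profile(mapset, p, classes)
    df <- data.frame(
      position = p, segment = pr$segment, n_effective = pr$n_effective,
      top_residues = format_top_residues(pr$freqs),
      top_pct = if (pr$n_effective > 0L) round(100 * pr$freqs[1L], 1)
                else NA_real_,
      stringsAsFactors = FALSE)
    for (nm in names(classes)) {
      df[[nm]] <- round(pr$class_percentages[[nm]], 1)
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Loop and termini length statistics per group
#'
#' Measures, per mapped sequence, the number of query residues before the
#' first mapped position of TM1 (N-terminus), between consecutive
#' transmembrane segments separated in the reference numbering (loops A-E:
#' TM1/TM2a, TM2b/TM3, TM3/TM4, TM4/TM5a, TM5b/TM6), and after the last
#' mapped position of TM6 (C-terminus), then summarises mean, SD and n per
#' group. Sequences in which a flanking segment is entirely unmapped
#' contribute `NA` for the affected regions; groups with no members are
#' omitted with a warning.
#'
#' @param mapset An `fnt_mapset`.
#' @param group_labels Character vector of group labels, one per sequence.
#' @return Data frame: group, region, n, mean_length, sd_length.
#' @export
region_length_stats <- function(mapset, group_labels) {
  stopifnot(length(group_labels) == length(mapset))
  frame <- attr(mapset, "frame")
  seg <- frame$segments
  gapped <- which(seg$start[-1L] > seg$end[-nrow(seg)] + 1L)
  loop_names <- setNames(LETTERS[seq_along(gapped)], gapped)

  region_lengths <- function(m) {
    first_idx <- function(i) {
      v <- m$map[as.character(seg$start[i]:seg$end[i])]
      v <- v[!is.na(v)]
      if (length(v)) v[1L] else NA_integer_
    }
    last_idx <- function(i) {
      v <- m$map[as.character(seg$start[i]:seg$end[i])]
      v <- v[!is.na(v)]
      if (length(v)) v[length(v)] else NA_integer_
    }
    out <- c(Nterm = first_idx(1L) - 1L)
    for (k in seq_along(gapped)) {
      i <- gapped[k]
      out[paste0("loop", loop_names[k])] <- first_idx(i + 1L) - last_idx(i) - 1L
    }
    c(out, Cterm = nchar(m$sequence) - last_idx(nrow(seg)))
  }

  region_names <- c("Nterm", paste0("loop", loop_names), "Cterm")
  lens <- t(vapply(mapset, region_lengths,
                   setNames(numeric(2L + length(gapped)), region_names)))
  groups <- unique(group_labels)
  empty <- setdiff(groups, group_labels)
  if (length(empty)) warning("group(s) with no members omitted: ",
                             paste(empty, collapse = ", "), call. = FALSE)
  rows <- list()
  for (g in groups) {
    sub <- lens[group_labels == g, , drop = FALSE]
    for (region in colnames(lens)) {
      v <- sub[, region]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, region = region, n = length(v),
        mean_length = if (length(v)) mean(v) else NA_real_,
        sd_length = if (length(v) > 1L) sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
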