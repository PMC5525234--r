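# Constriction-site scoring: cumulative hydropathy index (CHI) and
# cumulative van der Waals volume (CVV), per-sequence site extraction, and
# outlier flagging.

#' Cumulative hydropathy index (CHI)
#'
#' Sum of Kyte-Doolittle hydropathy values over the residues of a
#' constriction site. Higher values mean a more hydrophobic site. The
#' canonical central constriction F,F,H,A scores +4.2; an all-isoleucine
#' four-residue site would score +18.0, the hydrophobic extreme.
#'
#' @param residues Residue string (or character vector of one-letter
#'   codes); must be non-empty standard residues, no gaps.
#' @param scales Scale set from [fnt_scales()].
#' @return The CHI value (dimensionless).
#' @examples
#' chi("FFHA")  # 4.2
#' chi("YFQS")  # -2.8
#' @export
chi <- function(residues, scales = fnt_scales()) {
  sum(scale_value("hydropathy", split_site(residues), scales))
}

#' Cumulative van der Waals volume (CVV)
#'
#' Sum of Creighton per-residue van der Waals volumes over the residues of
#' a constriction site, in cubic Angstrom. Higher values mean a more
#' occluded (narrower) site.
#'
#' @inheritParams chi
#' @return The CVV value in cubic Angstrom.
#' @examples
#' cvv("FFHA")   # 455
#' cvv("YLFNI")  # 620
#' @export
cvv <- function(residues, scales = fnt_scales()) {
  sum(scale_value("volume", split_site(residues), scales))
}

split_site <- function(residues) {
  res <- if (length(residues) == 1L) strsplit(residues, "", fixed = TRUE)[[1L]]
         else as.character(residues)
  if (length(res) == 0L) stop("empty residue string", call. = FALSE)
  if (any(res == "-")) stop("gap symbol '-' in residue string", call. = FALSE)
  res
}

#' Score the constriction sites of a mapped sequence
#'
#' Extracts the central constriction, closed-state slit and open-state slit
#' residues and computes CHI and CVV for each complete (gap-free) site.
#' Incompleteness is data, not failure: gapped sites carry
#' `complete = FALSE` and `NA` scores.
#'
#' @param mapped An `fnt_map`.
#' @param frame Reference frame.
#' @param scales Scale set from [fnt_scales()].
#' @return Data frame with one row per site: `sequence_id`, `site`,
#'   `state`, `residues`, `chi`, `cvv`, `complete`.
#' @export
score_sites <- function(mapped, frame, scales = fnt_scales()) {
  defs <- list(c("central", "na"), c("slit", "closed"), c("slit", "open"))
  rows <- lapply(defs, function(d) {
    res <- extract_region(mapped, site_positions(frame, d[1L], d[2L]))
    complete <- !grepl("-", res, fixed = TRUE)
    data.frame(sequence_id = mapped$id, site = d[1L], state = d[2L],
               residues = res,
               chi = if (complete) chi(res, scales) else NA_real_,
               cvv = if (complete) cvv(res, scales) else NA_real_,
               complete = complete, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score the constriction sites of every sequence in a map set
#'
#' @param mapset An `fnt_mapset`.
#' @param scales Scale set.
#' @return Row-bound [score_sites()] results.
#' @export
score_sites_cohort <- function(mapset, scales = fnt_scales()) {
  frame <- attr(mapset, "frame")
  out <- do.call(rbind, lapply(mapset, score_sites, frame = frame,
                               scales = scales))
  rownames(out) <- NULL
  out
}

#' Flag sequences with unusual constriction sites
#'
#' Within each (site, state, group) stratum with at least `min_group`
#' complete scores, flags entries whose CHI or CVV deviates from the
#' stratum distribution: z-score method flags `|x - mean| / sd >= k` (a
#' zero-spread stratum flags nothing); percentile method flags values
#' outside the `[p, 100 - p]` percentile band (note duplication of entries
#' shifts percentile bounds). Undersized strata are skipped with a warning.
#' The input is not modified; flags are returned on a copy.
#'
#' @param scores Data frame from [score_sites_cohort()].
#' @param grouping Optional character vector of group labels, one per row
#'   of `scores` (e.g. subfamily); default puts everything in one group.
#' @param method `"zscore"` or `"percentile"`.
#' @param k Z-score threshold (default 2.5).
#' @param p Percentile (in percent) for the percentile method (default 1).
#' @param min_group Minimum complete scores per stratum (default 10).
#' @return `scores` with an added `flags` column (comma-joined subset of
#'   `low_chi`, `high_chi`, `low_cvv`, `high_cvv`; empty when unflagged).
#' @export
flag_unusual <- function(scores, grouping = NULL,
                         method = c("zscore", "percentile"),
                         k = 2.5, p = 1, min_group = 10) {
  method <- match.arg(method)
  if (is.null(grouping)) grouping <- rep("all", nrow(scores))
  stopifnot(length(grouping) == nrow(scores))
  out <- scores
  out$flags <- ""
  strata <- split(seq_len(nrow(scores)),
                  list(scores$site, scores$state, grouping), drop = TRUE)
  for (idx in strata) {
    idx <- idx[scores$complete[idx]]
    if (length(idx) < min_group) {
      if (length(idx) > 0L)
        warning("stratum with ", length(idx),
                " complete scores skipped (need >= ", min_group, ")",
                call. = FALSE)
      next
    }
    for (metric in c("chi", "cvv")) {
      x <- scores[[metric]][idx]
      if (method == "zscore") {
        s <- sd(x)
        if (is.na(s) || s == 0) next
        z <- (x - mean(x)) / s
        lo <- z <= -k; hi <- z >= k
      } else {
        b <- quantile(x, c(p, 100 - p) / 100, names = FALSE, type = 7)
        lo <- x < b[1L]; hi <- x > b[2L]
      }
      add <- function(rows, flag) {
        cur <- out$flags[rows]
        out$flags[rows] <<- ifelse(nzchar(cur), paste(cur, flag, sep = ","),
                                   flag)
      }
      if (any(lo)) add(idx[lo], paste0("low_", metric))
      if (any(hi)) add(idx[hi], paste0("high_", metric))
    }
  }
  out
}

#' Typical constriction-site residues per subfamily
#'
#' Reference metadata for report annotation (not thresholds): the typical
#' residue strings of each prokaryotic subfamily at the central
#' constriction and the cytoplasmic slit in both states, with their CHI/CVV
#' values computed from the package scales.
#'
#' @return Data frame: subfamily, site, state, residues, chi, cvv.
#' @export
typical_constrictions <- function() {
  rows <- list(
    # central constriction
    c("FocA", "central", "na", "FFHA"), c("FdhC", "central", "na", "FFHA"),
    c("NirC-alpha", "central", "na", "FFHV"),
    c("NirC-beta", "central", "na", "FFHA"),
    c("NirC-gamma", "central", "na", "FFHA"),
    c("HSC", "central", "na", "FFHA"),
    c("YfdC-alpha", "central", "na", "YIHV"),
    c("YfdC-beta", "central", "na", "FLHL"),
    # slit, closed state
    c("FocA", "slit", "closed", "LLTV"), c("FdhC", "slit", "closed", "LLTV"),
    c("NirC-alpha", "slit", "closed", "FLTV"),
    c("NirC-beta", "slit", "closed", "LLTV"),
    c("NirC-gamma", "slit", "closed", "LLTV"),
    c("HSC", "slit", "closed", "LLTV"),
    c("YfdC-alpha", "slit", "closed", "FLTI"),
    c("YfdC-beta", "slit", "closed", "FLTM"),
    # slit, open state
    c("FocA", "slit", "open", "LLFNV"), c("FdhC", "slit", "open", "LLINV"),
    c("NirC-alpha", "slit", "open", "FLLNV"),
    c("NirC-beta", "slit", "open", "LLFNV"),
    c("NirC-gamma", "slit", "open", "LLLNV"),
    c("HSC", "slit", "open", "LLFNV"),
    c("YfdC-alpha", "slit", "open", "FLFGI"),
    c("YfdC-beta", "slit", "open", "FLFGM"))
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(subfamily = r[1L], site = r[2L], state = r[3L],
               residues = r[4L], chi = chi(r[4L]), cvv = cvv(r[4L]),
               stringsAsFactors = FALSE)
  }))
  out
}

#' Format a CHI value for reports
#'
#' Positive values carry an explicit `+` prefix, matching the field's
#' reporting convention.
#'
#' @param x Numeric CHI values.
#' @return Character vector like `"+4.2"`, `"-2.8"`.
#' @export
format_chi <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%+.1f", x))
}
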