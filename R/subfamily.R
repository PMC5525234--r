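# Subfamily assignment from diagnostic-position profiles. This classifier
# encodes the published subfamily-diagnostic residue conservation as
# position-specific profiles; it deliberately replaces (and does not
# reproduce) phylogenetic tree inference.

.SUBFAMILIES <- c("FocA", "FdhC", "NirC-alpha", "NirC-beta", "NirC-gamma",
                  "HSC", "YfdC-alpha", "YfdC-beta")

# Diagnostic table: per position, per subfamily, "residues|weight" with the
# stated aggregate conservation fraction; NA where the subfamily shows no
# specific conservation at that position.
.DIAGNOSTIC_TABLE <- list(
  #        FocA          FdhC          NirC-a        NirC-b       NirC-g          HSC           YfdC-a         YfdC-b
  `202` = c("F|1.000",   "F|0.996",    "F|1.000",    "F|1.000",   "F|1.000",      "F|1.000",    "VIM|0.997",   "IMLV|1.000"),
  `212` = c("A|1.000",   "A|0.934",    "V|1.000",    "A|1.000",   "A|0.827",      "A|1.000",    "V|0.715",     "VIL|0.735"),
  `79`  = c("LVI|0.990", "LI|0.934",   "FY|0.981",   "L|1.000",   "L|0.994",      "LVI|0.960",  "FY|1.000",    "F|0.735"),
  `90`  = c("F|1.000",   "VLI|0.863",  "VL|0.909",   "FY|1.000",  NA,             "F|0.917",    "FY|0.997",    "F|1.000"),
  `172` = c("N|1.000",   "N|0.996",    "N|1.000",    "N|1.000",   "N|0.994",      "N|0.964",    "G|0.997",     "G|0.990"),
  `86`  = c("G|0.993",   "G|1.000",    "G|0.919",    "G|1.000",   "NQ|0.760",     "GS|0.956",   "RHD|0.812",   "RHK|0.755"),
  `92`  = c("S|1.000",   "GS|1.000",   "G|0.990",    "G|1.000",   "SG|1.000",     "GSA|1.000",  "E|1.000",     "E|0.902"),
  `93`  = c("TS|1.000",  "N|0.913",    "V|0.848",    "H|0.987",   "N|0.955",      "N|0.889",    "N|0.931",     NA),
  `100` = c("KR|0.799",  "ASG|0.996",  "ASG|0.995",  "GA|1.000",  "GAS|1.000",    "GSAT|0.972", "P|0.751",     NA),
  `208` = c("E|1.000",   "Q|0.830",    "E|1.000",    "E|1.000",   "E|0.994",      "ED|0.968",   "AST|0.756",   NA),
  `34`  = c("TAS|0.943", "LMIV|0.788", NA,           "F|1.000",   "YF|0.989",     "FY|0.988",   "LI|0.939",    "LIVM|0.941"),
  `37`  = c("LM|0.812",  "L|0.830",    "RK|0.952",   "GSA|0.962", "RK|0.989",     NA,           "SA|0.964",    "TS|0.971"),
  `113` = c("N|0.772",   "N|0.909",    "N|0.743",    "VI|0.962",  "VLIM|0.994",   NA,           "LVIM|0.856",  "LIV|0.990"),
  `167` = c("L|1.000",   "S|0.751",    "KR|0.948",   "KR|1.000",  "RKED|0.983",   "RK|0.956",   NA,            NA),
  `254` = c("N|1.000",   "N|0.979",    "N|1.000",    "N|1.000",   "NQ|0.726",     "N|0.893",    "FY|0.961",    "FW|0.745"))

#' Built-in subfamily diagnostic profiles
#'
#' The eight prokaryotic FNT subfamily profiles, transcribed from the
#' published subfamily-specific conservation table: per diagnostic
#' reference position, the allowed residue set and its stated aggregate
#' conservation fraction as weight. Positions where a subfamily shows no
#' specific conservation are omitted from that profile.
#'
#' @return Named list of `fnt_profile` objects (name, `diagnostics` data
#'   frame with columns position/residues/weight, `source`).
#' @examples
#' p <- builtin_profiles()
#' p[["YfdC-alpha"]]$diagnostics  # position 172: G, weight 0.997
#' @export
builtin_profiles <- function() {
  out <- lapply(seq_along(.SUBFAMILIES), function(si) {
    pos <- integer(0); res <- character(0); wt <- numeric(0)
    for (p in names(.DIAGNOSTIC_TABLE)) {
      cell <- .DIAGNOSTIC_TABLE[[p]][si]
      if (is.na(cell)) next
      parts <- strsplit(cell, "|", fixed = TRUE)[[1L]]
      pos <- c(pos, as.integer(p))
      res <- c(res, parts[1L])
      wt <- c(wt, as.numeric(parts[2L]))
    }
    ord <- order(pos)
    structure(list(name = .SUBFAMILIES[si],
                   diagnostics = data.frame(position = pos[ord],
                                            residues = res[ord],
                                            weight = wt[ord],
                                            stringsAsFactors = FALSE),
                   source = "paper_table"),
              class = "fnt_profile")
  })
  setNames(out, .SUBFAMILIES)
}

#' @export
print.fnt_profile <- function(x, ...) {
  cat(sprintf("fnt_profile '%s' (%s): %d diagnostic positions\n",
              x$name, x$source, nrow(x$diagnostics)))
  invisible(x)
}

#' Score a mapped sequence against a subfamily profile
#'
#' Weighted fraction of diagnostic positions whose residue falls in the
#' profile's allowed set: matched positions contribute their weight,
#' gapped positions subtract `gap_penalty_factor * weight` (missing
#' evidence is weaker than contradicting evidence), and the total is
#' normalised by the sum of weights, so a full match scores 1.
#'
#' @param mapped An `fnt_map`.
#' @param profile An `fnt_profile`.
#' @param gap_penalty_factor Penalty factor for gapped diagnostic
#'   positions (default 0.5).
#' @return Normalised score in `[-gap_penalty_factor, 1]`.
#' @export
score_sequence <- function(mapped, profile, gap_penalty_factor = 0.5) {
  d <- profile$diagnostics
  res <- strsplit(extract_region(mapped, d$position), "", fixed = TRUE)[[1L]]
  allowed <- strsplit(d$residues, "", fixed = TRUE)
  hit <- mapply(function(r, set) r %in% set, res, allowed)
  gap <- res == "-"
  sum(d$weight * hit - gap_penalty_factor * d$weight * gap) / sum(d$weight)
}

#' Classify a mapped sequence into an FNT subfamily
#'
#' Computes, for every profile, both the normalised score (see
#' [score_sequence()]) and the raw matched evidence (the unnormalised
#' weighted sum). Profiles are ranked by raw evidence: because some
#' subfamilies show no specific conservation at positions that are
#' diagnostic for others, their claimed position sets can be nested (a
#' YfdC-alpha sequence satisfies every YfdC-beta diagnostic), and the
#' normalised score then ties; the total matched evidence resolves such
#' nesting in favour of the more specific profile. When the margin between
#' the best and second-best evidence is below `margin_min` the sequence is
#' `"unclassified"`. Ties break deterministically by profile name order.
#'
#' @param mapped An `fnt_map`.
#' @param profiles List of `fnt_profile` objects (at least two).
#' @param margin_min Minimum best-minus-second evidence margin (in weight
#'   units; one fully-conserved diagnostic contributes ~1).
#' @param ... Passed to [score_sequence()].
#' @return List: `label`, `score` (normalised score of the winning
#'   profile), `margin` (evidence margin), `scores` and `evidence` (named
#'   vectors over profiles).
#' @export
classify <- function(mapped, profiles = builtin_profiles(),
                     margin_min = 0.25, ...) {
  stopifnot(length(profiles) >= 2L)
  scores <- vapply(profiles, score_sequence, numeric(1L), mapped = mapped, ...)
  evidence <- vapply(profiles, function(p) {
    sum(p$diagnostics$weight) * scores[[p$name]]
  }, numeric(1L))
  names(evidence) <- names(profiles)
  ord <- order(-evidence, names(evidence))
  margin <- evidence[ord[1L]] - evidence[ord[2L]]
  label <- if (margin < margin_min) "unclassified" else names(evidence)[ord[1L]]
  list(label = label, score = unname(scores[ord[1L]]),
       margin = unname(margin), scores = scores, evidence = evidence)
}

#' Classify every sequence in a map set
#'
#' @param mapset An `fnt_mapset`.
#' @param ... Passed to [classify()].
#' @return Data frame: `id`, `label`, `score`, `margin`.
#' @export
classify_cohort <- function(mapset, ...) {
  rows <- lapply(mapset, function(m) {
    cl <- classify(m, ...)
    data.frame(id = m$id, label = cl$label, score = cl$score,
               margin = cl$margin, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read/write subfamily profiles as TSV
#'
#' The serialisation is one row per diagnostic position: `subfamily`,
#' `position`, `residues` (concatenated one-letter codes), `weight`.
#'
#' @param profiles Named list of `fnt_profile` objects.
#' @param path TSV path.
#' @return `read_profiles_tsv` returns a named list of `fnt_profile`.
#' @export
write_profiles_tsv <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    cbind(subfamily = p$name, p$diagnostics)
  })
  write_tsv0(do.call(rbind, rows), path)
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(residues = "character"))
  out <- lapply(split(tab, tab$subfamily), function(d) {
    d <- d[order(d$position), ]
    structure(list(name = d$subfamily[1L],
                   diagnostics = data.frame(position = d$position,
                                            residues = d$residues,
                                            weight = d$weight,
                                            stringsAsFactors = FALSE),
                   source = "learned"),
              class = "fnt_profile")
  })
  out[order(names(out))]
}

#' Learn subfamily profiles from a labelled map set
#'
#' Builds profiles at the given positions from the conservation module:
#' per group and position, the allowed set collects residues by descending
#' frequency until their joint frequency reaches `min_freq`; that joint
#' frequency becomes the weight. Positions whose top residue is below
#' `min_top` are omitted (no specific conservation).
#'
#' @param mapset An `fnt_mapset`.
#' @param labels Group labels, one per sequence.
#' @param positions Candidate diagnostic positions.
#' @param min_freq Target joint frequency of the allowed set.
#' @param min_top Minimum frequency of the top residue for inclusion.
#' @return Named list of `fnt_profile` objects with `source = "learned"`.
#' @export
learn_profiles <- function(mapset, labels, positions, min_freq = 0.9,
                           min_top = 0.5) {
  frame <- attr(mapset, "frame")
  out <- lapply(sort(unique(labels)), function(g) {
    sub <- map_set(mapset[labels == g], frame)
    pos <- integer(0); res <- character(0); wt <- numeric(0)
    for (p in positions) {
      pr <- column_profile(sub, p)
      if (pr$n_effective == 0L || pr$freqs[1L] < min_top) next
      cum <- cumsum(pr$freqs)
      take <- seq_len(which(cum >= min_freq)[1L])
      pos <- c(pos, p)
      res <- c(res, paste(names(pr$freqs)[take], collapse = ""))
      wt <- c(wt, cum[take[length(take)]])
    }
    structure(list(name = g,
                   diagnostics = data.frame(position = pos, residues = res,
                                            weight = unname(wt),
                                            stringsAsFactors = FALSE),
                   source = "learned"),
              class = "fnt_profile")
  })
  setNames(out, sort(unique(labels)))
}
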