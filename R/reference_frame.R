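# The reference coordinate system: FocA (PDB 3KCU) residue numbering,
# transmembrane segment bounds, and the two constriction-site definitions.

.SEGMENT_NAMES <- c("TM1", "TM2a", "OMEGA", "TM2b", "TM3",
                    "TM4", "TM5a", "S", "TM5b", "TM6")
.FRAME_SPAN <- c(31L, 275L)

#' Load a reference frame annotation
#'
#' Reads a reference-frame annotation file: the reference sequence (with its
#' numbering offset), the ten transmembrane/loop segment bounds, the
#' constriction-site position sets, and the residues asserted to occupy
#' specific reference positions. The bundled default uses FocA/3KCU
#' numbering with a synthetic reference sequence that satisfies every
#' asserted residue (see `inst/extdata/fnt_reference.txt` for the schema).
#'
#' All invariants are checked: exactly ten segments named
#' TM1, TM2a, OMEGA, TM2b, TM3, TM4, TM5a, S, TM5b, TM6, strictly ascending
#' and non-overlapping; constriction positions inside declared segments; the
#' sequence spanning at least positions 31-275 and agreeing with every
#' asserted residue.
#'
#' @param path Path to an annotation file; `NULL` loads the bundled default.
#' @return An object of class `fnt_frame`.
#' @examples
#' frame <- load_reference()
#' frame$segments
#' site_positions(frame, "central")
#' @export
load_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fnt_reference.txt", package = "fntscan",
                        mustWork = TRUE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(fields, `[[`, "", 1L)

  kv <- function(k, default = NULL) {
    i <- which(key == k)
    if (length(i) == 0L) {
      if (is.null(default)) stop("reference annotation: missing key '", k, "'",
                                 call. = FALSE)
      return(default)
    }
    fields[[i[1L]]][2L]
  }
  name <- kv("name", "reference")
  offset <- as.integer(kv("offset", "1"))
  sequence <- toupper(kv("sequence"))

  seg_rows <- fields[key == "segment"]
  segments <- data.frame(
    name  = vapply(seg_rows, `[[`, "", 2L),
    start = as.integer(vapply(seg_rows, `[[`, "", 3L)),
    end   = as.integer(vapply(seg_rows, `[[`, "", 4L)),
    stringsAsFactors = FALSE)

  site_rows <- fields[key == "site"]
  sites <- list()
  for (r in site_rows) {
    sites[[paste(r[[2L]], r[[3L]], sep = "_")]] <-
      as.integer(strsplit(r[[4L]], ",", fixed = TRUE)[[1L]])
  }

  res_rows <- fields[key == "residue"]
  known <- setNames(vapply(res_rows, `[[`, "", 3L),
                    vapply(res_rows, `[[`, "", 2L))

  frame <- structure(
    list(name = name, sequence = sequence, offset = offset,
         segments = segments, sites = sites, known_residues = known),
    class = "fnt_frame")
  validate_frame(frame)
  frame
}

validate_frame <- function(frame) {
  seg <- frame$segments
  missing <- setdiff(.SEGMENT_NAMES, seg$name)
  if (length(missing) > 0L) {
    stop("reference frame: missing segment(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(seg) != 10L || any(seg$name != .SEGMENT_NAMES)) {
    stop("reference frame: expected exactly the 10 segments ",
         paste(.SEGMENT_NAMES, collapse = ", "), " in order", call. = FALSE)
  }
  if (any(seg$start > seg$end)) {
    stop("reference frame: segment with start > end: ",
         seg$name[seg$start > seg$end][1L], call. = FALSE)
  }
  if (any(seg$start[-1L] <= seg$end[-nrow(seg)])) {
    i <- which(seg$start[-1L] <= seg$end[-nrow(seg)])[1L]
    stop("reference frame: segments ", seg$name[i], " and ", seg$name[i + 1L],
         " overlap or are out of order", call. = FALSE)
  }
  for (nm in c("central_na", "slit_closed", "slit_open")) {
    pos <- frame$sites[[nm]]
    if (is.null(pos)) stop("reference frame: missing site definition ", nm,
                           call. = FALSE)
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("reference frame: site ", nm, " positions must be strictly ascending",
           call. = FALSE)
    }
    out <- pos[!vapply(pos, function(p) any(p >= seg$start & p <= seg$end), TRUE)]
    if (length(out) > 0L) {
      stop("reference frame: site ", nm, " position(s) outside segments: ",
           paste(out, collapse = ", "), call. = FALSE)
    }
  }
  last <- frame$offset + nchar(frame$sequence) - 1L
  if (frame$offset > .FRAME_SPAN[1L] || last < .FRAME_SPAN[2L]) {
    stop("reference frame: sequence must span positions ", .FRAME_SPAN[1L],
         "-", .FRAME_SPAN[2L], call. = FALSE)
  }
  if (length(frame$known_residues) > 0L) {
    pos <- as.integer(names(frame$known_residues))
    got <- ref_residue(frame, pos)
    bad <- which(got != unname(frame$known_residues))
    if (length(bad) > 0L) {
      stop("reference frame: sequence conflicts with asserted residue at ",
           "position ", pos[bad[1L]], " (sequence has '", got[bad[1L]],
           "', asserted '", frame$known_residues[bad[1L]], "')", call. = FALSE)
    }
  }
  invisible(frame)
}

#' Constriction-site positions
#'
#' @param frame An `fnt_frame`.
#' @param site `"central"` or `"slit"`.
#' @param state `"na"` (central), or `"closed"` / `"open"` (slit).
#' @return Integer vector of reference positions in ascending
#'   primary-sequence order.
#' @examples
#' frame <- load_reference()
#' site_positions(frame, "slit", "open")  # 79, 89, 90, 172, 175
#' @export
site_positions <- function(frame, site = c("central", "slit"),
                           state = c("na", "closed", "open")) {
  site <- match.arg(site)
  state <- match.arg(state)
  if (site == "central" && state != "na") {
    stop("site 'central' has no state; use state = \"na\"", call. = FALSE)
  }
  if (site == "slit" && state == "na") {
    stop("site 'slit' requires state \"closed\" or \"open\"", call. = FALSE)
  }
  frame$sites[[paste(site, state, sep = "_")]]
}

#' Residues of the reference sequence at given positions
#'
#' @param frame An `fnt_frame`.
#' @param positions Integer vector of reference positions.
#' @return Character vector of one-letter residues.
#' @export
ref_residue <- function(frame, positions) {
  idx <- positions - frame$offset + 1L
  if (any(idx < 1L | idx > nchar(frame$sequence))) {
    stop("position(s) outside the reference sequence", call. = FALSE)
  }
  substring(frame$sequence, idx, idx)
}

#' Segment containing each reference position
#'
#' @param frame An `fnt_frame`.
#' @param positions Integer vector of reference positions.
#' @return Character vector of segment names, `NA` for inter-segment
#'   positions.
#' @export
segment_of <- function(frame, positions) {
  seg <- frame$segments
  vapply(positions, function(p) {
    i <- which(p >= seg$start & p <= seg$end)
    if (length(i) == 0L) NA_character_ else seg$name[i]
  }, character(1L))
}

# All reference positions lying inside a declared segment.
segment_positions <- function(frame) {
  seg <- frame$segments
  unlist(lapply(seq_len(nrow(seg)), function(i) seg$start[i]:seg$end[i]),
         use.names = FALSE)
}

#' @export
print.fnt_frame <- function(x, ...) {
  cat("FNT reference frame:", x$name, "\n")
  cat(sprintf("  sequence: %d residues (positions %d-%d)\n",
              nchar(x$sequence), x$offset, x$offset + nchar(x$sequence) - 1L))
  cat("  segments:",
      paste(sprintf("%s %d-%d", x$segments$name, x$segments$start,
                    x$segments$end), collapse = ", "), "\n")
  cat("  central constriction:", paste(x$sites$central_na, collapse = ","),
      "| slit closed:", paste(x$sites$slit_closed, collapse = ","),
      "| slit open:", paste(x$sites$slit_open, collapse = ","), "\n")
  invisible(x)
}
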