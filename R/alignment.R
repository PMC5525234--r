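# Position mapping: global affine-gap alignment of a query protein to the
# reference frame, with gap opening discouraged inside the transmembrane
# segments, yielding a monotone map in reference numbering.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")
.ALPHABET <- c(.AA20, "X")  # X = any ambiguity code; scores at the floor

.subst_cache <- new.env(parent = emptyenv())

# 21x21 substitution matrix over .ALPHABET. Ambiguity code X scores at the
# matrix floor against everything, so it is tolerated but never favoured.
substitution_matrix <- function(name = "BLOSUM62") {
  key <- name
  if (!is.null(.subst_cache[[key]])) return(.subst_cache[[key]])
  data_env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = data_env)
  full <- data_env[[name]]
  floor_score <- min(full[.AA20, .AA20])
  m <- matrix(floor_score, 21L, 21L, dimnames = list(.ALPHABET, .ALPHABET))
  m[.AA20, .AA20] <- full[.AA20, .AA20]
  .subst_cache[[key]] <- m
  m
}

# Encode a residue string as indices into .ALPHABET; ambiguity codes
# (B, Z, U, J, O, *) collapse to X. Errors on anything else (gaps included).
encode_protein <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  chars[chars %in% c("B", "Z", "U", "J", "O", "*")] <- "X"
  code <- match(chars, .ALPHABET)
  if (anyNA(code)) {
    stop("invalid residue symbol(s) in sequence: ",
         paste(unique(chars[is.na(code)]), collapse = ", "), call. = FALSE)
  }
  code
}

# Gap-open multipliers along the reference: `mult` inside segments, 1 in
# loops/termini. Deletions use the multiplier of the deleted position;
# insertions are inflated whenever both flanking reference positions lie
# inside segments (including the junctions of numbering-contiguous
# segments such as TM2a|OMEGA|TM2b, where no loop exists to absorb them).
gap_multipliers <- function(frame, mult) {
  n <- nchar(frame$sequence)
  pos <- frame$offset + seq_len(n) - 1L
  seg <- segment_of(frame, pos)
  del <- ifelse(is.na(seg), 1, mult)
  ins <- c(1, ifelse(!is.na(seg[-n]) & !is.na(seg[-1L]), mult, 1), 1)
  list(del = as.numeric(del), ins = as.numeric(ins[seq_len(n + 1L)]))
}

#' Align a query protein to the reference frame
#'
#' Global alignment with affine gaps and free end gaps (query and reference
#' termini are not penalised). Gap opening inside the reference
#' transmembrane/loop segments costs `segment_gap_multiplier` times the base
#' penalty, implementing the structural constraint that indels fall in the
#' inter-segment loops. Traceback ties prefer an aligned pair over a gap in
#' the query over a gap in the reference, so maps are deterministic.
#'
#' @param sequence Query protein sequence (one-letter codes; ambiguity codes
#'   such as X are tolerated but never matched favourably).
#' @param frame Reference frame from [load_reference()].
#' @param id,species Identifier and optional species label carried on the
#'   result.
#' @param gap_open,gap_extend Base affine gap penalties (positive).
#' @param segment_gap_multiplier Gap-open inflation factor inside segments.
#' @param matrix Substitution matrix name from Biostrings (default BLOSUM62).
#' @param min_score Score floor; alignments scoring below it raise an error
#'   of class `fnt_unalignable`.
#' @return An object of class `fnt_map`: the query sequence plus a monotone
#'   map from every reference position 31-275 to a query index (`NA` = gap)
#'   and per-segment coverage fractions.
#' @examples
#' frame <- load_reference()
#' m <- align_to_reference(frame$sequence, frame, id = "ref")
#' extract_region(m, site_positions(frame, "central"))  # "FFHA"
#' @export
align_to_reference <- function(sequence, frame, id = "query", species = NA_character_,
                               gap_open = 11, gap_extend = 1,
                               segment_gap_multiplier = 3,
                               matrix = "BLOSUM62", min_score = 60) {
  if (!nzchar(sequence)) stop("empty query sequence", call. = FALSE)
  ref_code <- encode_protein(frame$sequence)
  qry_code <- encode_protein(sequence)
  mults <- gap_multipliers(frame, segment_gap_multiplier)
  res <- align_affine_cpp(ref_code, qry_code, substitution_matrix(matrix),
                          gap_open, gap_extend, mults$del, mults$ins)
  if (res$score < min_score) {
    stop(structure(
      class = c("fnt_unalignable", "error", "condition"),
      list(message = sprintf("sequence '%s' is unalignable (score %.1f < floor %.1f)",
                             id, res$score, min_score),
           call = NULL)))
  }
  span <- .FRAME_SPAN[1L]:.FRAME_SPAN[2L]
  full <- res$map
  full[full == 0L] <- NA_integer_
  map <- setNames(full[span - frame$offset + 1L], span)
  seg <- frame$segments
  coverage <- setNames(vapply(seq_len(nrow(seg)), function(i) {
    p <- seg$start[i]:seg$end[i]
    mean(!is.na(map[as.character(p)]))
  }, numeric(1L)), seg$name)
  structure(list(id = id, species = species, sequence = sequence,
                 score = res$score, map = map, coverage = coverage),
            class = "fnt_map")
}

#' @export
print.fnt_map <- function(x, ...) {
  cat(sprintf("fnt_map '%s': %d residues, score %.1f, %d/%d reference positions mapped\n",
              x$id, nchar(x$sequence), x$score, sum(!is.na(x$map)), length(x$map)))
  cov <- paste(sprintf("%s %.2f", names(x$coverage), x$coverage), collapse = ", ")
  cat("  segment coverage:", cov, "\n")
  invisible(x)
}

#' Extract residues at reference positions from a mapped sequence
#'
#' @param mapped An `fnt_map`.
#' @param positions Reference positions (within 31-275), in the order wanted.
#' @return Single residue string; gapped positions yield `-`.
#' @export
extract_region <- function(mapped, positions) {
  if (any(positions < .FRAME_SPAN[1L] | positions > .FRAME_SPAN[2L])) {
    stop("position(s) outside the reference frame span ",
         .FRAME_SPAN[1L], "-", .FRAME_SPAN[2L], call. = FALSE)
  }
  idx <- mapped$map[as.character(positions)]
  out <- rep("-", length(positions))
  ok <- which(!is.na(idx))
  if (length(ok)) out[ok] <- substring(mapped$sequence, idx[ok], idx[ok])
  paste(out, collapse = "")
}

#' Align a set of sequences to the reference
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `species` (as returned by [read_protein_fasta()] or
#'   [generate_cohort()]).
#' @param frame Reference frame.
#' @param ... Passed to [align_to_reference()].
#' @return An `fnt_mapset`: a list of `fnt_map` objects with the frame
#'   attached as an attribute. Unalignable sequences are dropped with a
#'   warning.
#' @export
align_cohort <- function(records, frame, ...) {
  species <- if ("species" %in% names(records)) records$species
             else rep(NA_character_, nrow(records))
  maps <- vector("list", nrow(records))
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    m <- tryCatch(
      align_to_reference(records$sequence[i], frame, id = records$id[i],
                         species = species[i], ...),
      fnt_unalignable = function(e) NULL)
    if (!is.null(m)) { maps[[i]] <- m; keep[i] <- TRUE }
  }
  if (!all(keep)) {
    warning(sum(!keep), " unalignable sequence(s) dropped", call. = FALSE)
  }
  map_set(maps[keep], frame)
}

#' Bundle mapped sequences into a map set
#'
#' @param maps List of `fnt_map` objects.
#' @param frame The shared reference frame.
#' @return An `fnt_mapset`.
#' @export
map_set <- function(maps, frame) {
  structure(maps, frame = frame, class = "fnt_mapset")
}

#' @export
print.fnt_mapset <- function(x, ...) {
  cat(sprintf("fnt_mapset: %d mapped sequences on frame '%s'\n",
              length(x), attr(x, "frame")$name))
  invisible(x)
}

#' Residue matrix of a map set
#'
#' @param mapset An `fnt_mapset`.
#' @param positions Reference positions (default: the full 31-275 span).
#' @return Character matrix, sequences x positions; `NA` where gapped.
#' @export
residue_matrix <- function(mapset, positions = NULL) {
  if (is.null(positions)) positions <- .FRAME_SPAN[1L]:.FRAME_SPAN[2L]
  key <- as.character(positions)
  out <- matrix(NA_character_, length(mapset), length(positions),
                dimnames = list(vapply(mapset, `[[`, "", "id"), key))
  for (i in seq_along(mapset)) {
    m <- mapset[[i]]
    idx <- m$map[key]
    ok <- which(!is.na(idx))
    if (length(ok)) out[i, ok] <- substring(m$sequence, idx[ok], idx[ok])
  }
  out
}

# Percent identity between two full sequences (no frame): free end-gap
# affine alignment, matches divided by the shorter length (CD-HIT style).
sequence_identity <- function(a, b, gap_open = 11, gap_extend = 1,
                              matrix = "BLOSUM62") {
  ca <- encode_protein(a); cb <- encode_protein(b)
  ones <- rep(1, length(ca))
  res <- align_affine_cpp(ca, cb, substitution_matrix(matrix),
                          gap_open, gap_extend, ones, c(1, ones))
  aligned <- which(res$map > 0L)
  matches <- sum(ca[aligned] == cb[res$map[aligned]])
  100 * matches / min(length(ca), length(cb))
}
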