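# Operon-based functional support: scan the gene neighborhood of an FNT
# gene for partner metabolic enzymes (same transcriptional strand, within a
# gene window) and derive the implied subfamily support.

#' Default partner-enzyme keyword registry
#'
#' Maps partner classes to keyword/gene-symbol sets matched
#' (case-insensitively, as substrings) against neighbour `product` and
#' `locus_tag` annotations. User-extensible: pass a modified copy to
#' [assign_operon_support()].
#'
#' @return Named list of character vectors.
#' @export
operon_keywords <- function() {
  list(
    pfl    = c("pyruvate formate lyase", "formate acetyltransferase",
               "pflA", "pflB"),
    fdh    = c("formate dehydrogenase", "fdhA", "fdhB"),
    nirBD  = c("nitrite reductase", "nirB", "nirD"),
    asrABC = c("sulfite reductase", "asrA", "asrB", "asrC"))
}

.IMPLIED_SUPPORT <- c(pfl = "FocA-formate", fdh = "FdhC-formate",
                      nirBD = "NirC-nitrite", asrABC = "HSC-hydrosulphide",
                      none = "none")

validate_features <- function(features) {
  need <- c("contig", "start", "end", "strand", "locus_tag", "product")
  missing <- setdiff(need, names(features))
  if (length(missing) > 0L) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(features$start > features$end)) {
    stop("feature with start > end", call. = FALSE)
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  invisible(features)
}

#' Read a genome feature table
#'
#' Accepts GFF3 (CDS features; `locus_tag` and `product` attributes, read
#' via rtracklayer) or a simple 6-column TSV dialect with header
#' `contig, start, end, strand, locus_tag, product`. Coordinates are
#' 1-based inclusive in both dialects.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return Data frame with the six canonical columns.
#' @export
read_features <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    md <- S4Vectors::mcols(gr)
    get_attr <- function(nm, fallback) {
      if (nm %in% names(md)) as.character(md[[nm]]) else fallback
    }
    features <- data.frame(
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      locus_tag = get_attr("locus_tag",
                           get_attr("ID", rep(NA_character_, length(gr)))),
      product = get_attr("product", rep("", length(gr))),
      stringsAsFactors = FALSE)
  } else {
    features <- read.delim(path, stringsAsFactors = FALSE)
  }
  features$product[is.na(features$product)] <- ""
  validate_features(features)
}

#' Write a feature table
#'
#' @param features Canonical 6-column feature data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"gff3"`.
#' @export
write_features <- function(features, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  validate_features(features)
  if (format == "tsv") {
    write_tsv0(features, path)
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = features$contig,
      ranges = IRanges::IRanges(features$start, features$end),
      strand = features$strand)
    gr$type <- "CDS"
    gr$source <- "fntscan"
    gr$phase <- 0L
    gr$locus_tag <- features$locus_tag
    gr$product <- features$product
    gr$ID <- features$locus_tag
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Scan the gene neighborhood of an FNT locus
#'
#' Features are sorted by (contig, start); up to `window` genes on each
#' side of the FNT gene on the same contig are taken, then filtered to the
#' FNT gene's strand when `same_strand`. Gene distance is signed in the
#' FNT gene's transcription direction: positive = downstream.
#'
#' @param features Canonical feature data frame.
#' @param fnt_locus Locus tag of the FNT gene.
#' @param window Number of genes each side (default 3).
#' @param same_strand Keep only same-strand neighbours (default TRUE).
#' @return Neighbour features with an added signed `gene_distance` column,
#'   ordered by `|gene_distance|` then downstream-first. The FNT feature
#'   itself is carried in attribute `fnt`.
#' @export
scan_neighborhood <- function(features, fnt_locus, window = 3,
                              same_strand = TRUE) {
  validate_features(features)
  features <- features[order(features$contig, features$start,
                             features$locus_tag), , drop = FALSE]
  hit <- which(features$locus_tag == fnt_locus)
  if (length(hit) == 0L) {
    stop("locus not found in feature table: ", fnt_locus, call. = FALSE)
  }
  hit <- hit[1L]
  fnt <- features[hit, , drop = FALSE]
  same_contig <- which(features$contig == fnt$contig)
  k <- match(hit, same_contig)
  lo <- max(1L, k - window); hi <- min(length(same_contig), k + window)
  nb_idx <- same_contig[setdiff(lo:hi, k)]
  nb <- features[nb_idx, , drop = FALSE]
  offset <- match(nb_idx, same_contig) - k  # + = higher coordinate
  nb$gene_distance <- if (fnt$strand == "+") offset else -offset
  if (same_strand) nb <- nb[nb$strand == fnt$strand, , drop = FALSE]
  nb <- nb[order(abs(nb$gene_distance), -sign(nb$gene_distance)), ,
           drop = FALSE]
  rownames(nb) <- NULL
  attr(nb, "fnt") <- fnt
  nb
}

#' Assign operon-based functional support from a neighborhood
#'
#' The nearest neighbour (smallest absolute gene distance; equidistant
#' ties go downstream) whose `product` or `locus_tag` matches a registry
#' keyword determines the partner class and the implied subfamily support;
#' `none` otherwise.
#'
#' @param neighbors Output of [scan_neighborhood()].
#' @param registry Keyword registry (see [operon_keywords()]).
#' @return One-row data frame: `fnt_locus`, `partner_class`,
#'   `partner_locus`, `gene_distance`, `implied_support`.
#' @export
assign_operon_support <- function(neighbors, registry = operon_keywords()) {
  fnt <- attr(neighbors, "fnt")
  fnt_locus <- if (!is.null(fnt)) fnt$locus_tag else NA_character_
  match_class <- function(text) {
    text <- tolower(text)
    for (cls in names(registry)) {
      if (any(vapply(tolower(registry[[cls]]),
                     function(k) grepl(k, text, fixed = TRUE), TRUE))) {
        return(cls)
      }
    }
    NA_character_
  }
  # neighbors come ordered nearest-first, downstream preferred on ties
  for (i in seq_len(nrow(neighbors))) {
    cls <- match_class(paste(neighbors$product[i], neighbors$locus_tag[i]))
    if (!is.na(cls)) {
      return(data.frame(fnt_locus = fnt_locus, partner_class = cls,
                        partner_locus = neighbors$locus_tag[i],
                        gene_distance = neighbors$gene_distance[i],
                        implied_support = unname(.IMPLIED_SUPPORT[cls]),
                        stringsAsFactors = FALSE))
    }
  }
  data.frame(fnt_locus = fnt_locus, partner_class = "none",
             partner_locus = NA_character_, gene_distance = NA_integer_,
             implied_support = "none", stringsAsFactors = FALSE)
}

#' Operon support for a set of FNT loci
#'
#' @param features Canonical feature data frame.
#' @param fnt_loci Character vector of FNT locus tags.
#' @param window,same_strand Passed to [scan_neighborhood()].
#' @param registry Passed to [assign_operon_support()].
#' @return Row-bound support table, one row per locus.
#' @export
operon_support_table <- function(features, fnt_loci, window = 3,
                                 same_strand = TRUE,
                                 registry = operon_keywords()) {
  rows <- lapply(fnt_loci, function(loc) {
    nb <- scan_neighborhood(features, loc, window, same_strand)
    assign_operon_support(nb, registry)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
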