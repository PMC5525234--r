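# FASTA input and small TSV helpers.

#' Read protein sequences from FASTA
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA via Biostrings. Species
#' labels are taken from a UniProt-style `OS=` token in the header if
#' present, or from a sidecar TSV with columns `id` and `species`.
#'
#' @param path FASTA file path.
#' @param species_tsv Optional TSV path with columns `id`, `species`.
#' @return Data frame with columns `id`, `species`, `sequence`.
#' @export
read_protein_fasta <- function(path, species_tsv = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  id <- vapply(strsplit(headers, "\\s+"), `[[`, "", 1L)
  species <- rep(NA_character_, length(aa))
  has_os <- grepl("OS=", headers, fixed = TRUE)
  species[has_os] <- sub("^.*OS=(.*?)(\\s+[A-Z]{2}=.*)?$", "\\1", headers[has_os])
  if (!is.null(species_tsv)) {
    tab <- read.delim(species_tsv, stringsAsFactors = FALSE)
    species <- tab$species[match(id, tab$id)]
  }
  data.frame(id = id, species = species, sequence = as.character(aa),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Deterministic TSV writer: fixed separators, no quoting, unix newlines.
write_tsv0 <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.4f", x)
    out[is.na(x)] <- "NA"
    out
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a map set to TSV
#'
#' One row per (sequence, reference position): id, reference_position,
#' query_index, residue.
#'
#' @param mapset An `fnt_mapset`.
#' @param path Output TSV path.
#' @export
write_maps_tsv <- function(mapset, path) {
  rows <- lapply(mapset, function(m) {
    pos <- as.integer(names(m$map))
    idx <- unname(m$map)
    resi <- rep(NA_character_, length(idx))
    ok <- which(!is.na(idx))
    if (length(ok)) resi[ok] <- substring(m$sequence, idx[ok], idx[ok])
    data.frame(id = m$id, reference_position = pos, query_index = idx,
               residue = resi, stringsAsFactors = FALSE)
  })
  write_tsv0(do.call(rbind, rows), path)
}
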