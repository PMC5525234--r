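# Amino-acid scales used by the constriction-site scores.

.KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Creighton per-residue van der Waals volumes, in cubic Angstrom.
.VDW_VOLUME <- c(
  A =  67, R = 148, N =  96, D =  91, C =  86,
  Q = 114, E = 109, G =  48, H = 118, I = 124,
  L = 124, K = 135, M = 124, F = 135, P =  90,
  S =  73, T =  93, W = 163, Y = 141, V = 105)

#' Amino-acid scales for constriction-site scoring
#'
#' Returns the two per-residue scales used throughout the package: the
#' Kyte-Doolittle hydropathy scale (dimensionless; positive = hydrophobic)
#' and the Creighton van der Waals volumes (cubic Angstrom). Each covers
#' exactly the 20 standard residues.
#'
#' @return A list with components `hydropathy` and `vdw_volume`, each a named
#'   numeric vector over the 20 standard one-letter codes.
#' @examples
#' s <- fnt_scales()
#' s$hydropathy[["I"]]   # 4.5, the most hydrophobic residue
#' s$vdw_volume[["G"]]   # 48, the smallest residue
#' @export
fnt_scales <- function() {
  list(hydropathy = .KD_HYDROPATHY, vdw_volume = .VDW_VOLUME)
}

#' Look up a scale value for a residue
#'
#' @param kind `"hydropathy"` or `"volume"`.
#' @param residue One-letter residue code (case-insensitive). May be a
#'   vector; all elements must be standard residues.
#' @param scales Scale set, as returned by [fnt_scales()].
#' @return Numeric vector of scale values (volume in cubic Angstrom).
#' @examples
#' scale_value("hydropathy", "I")  # 4.5
#' scale_value("volume", c("F", "F", "H", "Y"))  # sums to 529
#' @export
scale_value <- function(kind = c("hydropathy", "volume"), residue,
                        scales = fnt_scales()) {
  kind <- match.arg(kind)
  tab <- if (kind == "hydropathy") scales$hydropathy else scales$vdw_volume
  res <- toupper(as.character(residue))
  bad <- res[!res %in% names(tab)]
  if (length(bad) > 0L) {
    stop("non-standard residue code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  unname(tab[res])
}
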