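# Pairwise identity/similarity over the transmembrane + Omega + S regions,
# and intra/inter-subgroup average matrices.

#' Pairwise identity and similarity of two mapped sequences
#'
#' Computed over the reference positions of the ten segments where BOTH
#' sequences have a mapped (non-gap) residue: identity = matches over the
#' shared positions; similarity additionally counts substitutions with a
#' positive substitution-matrix score (standard convention; the matrix is
#' configurable). This confines the comparison to the transmembrane helices
#' and the Omega/S loops without penalising coverage differences twice.
#'
#' @param a,b `fnt_map` objects on the same frame.
#' @param frame Reference frame.
#' @param matrix Substitution matrix name (default BLOSUM62).
#' @return Named numeric vector `c(identity =, similarity =, n_shared =)`
#'   in percent; identity/similarity are `NA` (with zero `n_shared`) when
#'   the sequences share no covered segment positions.
#' @export
pairwise_identity_similarity <- function(a, b, frame, matrix = "BLOSUM62") {
  pos <- as.character(segment_positions(frame))
  ia <- a$map[pos]; ib <- b$map[pos]
  ok <- !is.na(ia) & !is.na(ib)
  n <- sum(ok)
  if (n == 0L) {
    return(c(identity = NA_real_, similarity = NA_real_, n_shared = 0))
  }
  ra <- substring(a$sequence, ia[ok], ia[ok])
  rb <- substring(b$sequence, ib[ok], ib[ok])
  m <- substitution_matrix(matrix)
  ra[!ra %in% rownames(m)] <- "X"
  rb[!rb %in% rownames(m)] <- "X"
  matches <- ra == rb
  positive <- m[cbind(ra, rb)] > 0
  c(identity = 100 * sum(matches) / n,
    similarity = 100 * sum(matches | positive) / n,
    n_shared = n)
}

#' Intra- and inter-group average identity/similarity matrix
#'
#' Diagonal entries are means over all unordered within-group pairs;
#' off-diagonal entries are means over all cross pairs. Groups with fewer
#' than two members get a missing diagonal.
#'
#' @param mapset An `fnt_mapset`.
#' @param labels Character vector of group labels, one per sequence.
#' @param matrix Substitution matrix name.
#' @return An object of class `fnt_groupmatrix`: list with `labels`,
#'   symmetric `identity`, `similarity` and `n_pairs` matrices.
#' @export
group_average_matrix <- function(mapset, labels, matrix = "BLOSUM62") {
  stopifnot(length(labels) == length(mapset))
  frame <- attr(mapset, "frame")
  groups <- sort(unique(labels))
  g <- length(groups)
  idm <- simm <- matrix(NA_real_, g, g, dimnames = list(groups, groups))
  npm <- matrix(0, g, g, dimnames = list(groups, groups))
  idx_by <- split(seq_along(mapset), factor(labels, levels = groups))
  n <- length(mapset)
  # all unordered pairs once
  pair_id <- matrix(NA_real_, n, n)
  pair_sim <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- pairwise_identity_similarity(mapset[[i]], mapset[[j]], frame,
                                        matrix)
      pair_id[i, j] <- v[["identity"]]
      pair_sim[i, j] <- v[["similarity"]]
    }
  }
  for (gi in seq_len(g)) {
    for (gj in gi:g) {
      a <- idx_by[[gi]]; b <- idx_by[[gj]]
      if (gi == gj) {
        if (length(a) < 2L) next
        cmb <- utils::combn(a, 2L)
        iv <- pair_id[cbind(cmb[1L, ], cmb[2L, ])]
        sv <- pair_sim[cbind(cmb[1L, ], cmb[2L, ])]
      } else {
        grid <- expand.grid(a = a, b = b)
        lo <- pmin(grid$a, grid$b); hi <- pmax(grid$a, grid$b)
        iv <- pair_id[cbind(lo, hi)]
        sv <- pair_sim[cbind(lo, hi)]
      }
      idm[gi, gj] <- idm[gj, gi] <- mean(iv, na.rm = TRUE)
      simm[gi, gj] <- simm[gj, gi] <- mean(sv, na.rm = TRUE)
      npm[gi, gj] <- npm[gj, gi] <- length(iv)
    }
  }
  structure(list(labels = groups, identity = idm, similarity = simm,
                 n_pairs = npm),
            class = "fnt_groupmatrix")
}

#' @export
print.fnt_groupmatrix <- function(x, digits = 0, ...) {
  cat("Average pairwise identity (similarity), %:\n")
  g <- length(x$labels)
  disp <- matrix("", g, g, dimnames = list(x$labels, x$labels))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    disp[i, j] <- if (is.na(x$identity[i, j])) "-" else
      sprintf("%.*f (%.*f)", digits, x$identity[i, j], digits,
              x$similarity[i, j])
  }
  print(disp, quote = FALSE)
  invisible(x)
}

#' Write a group matrix as TSV and JSON
#'
#' The TSV mirrors the familiar "identity (similarity)" cell layout; the
#' JSON carries the raw matrices.
#'
#' @param gm An `fnt_groupmatrix`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_group_matrix <- function(gm, tsv_path = NULL, json_path = NULL) {
  g <- length(gm$labels)
  if (!is.null(tsv_path)) {
    disp <- matrix("-", g, g)
    for (i in seq_len(g)) for (j in seq_len(g)) {
      if (!is.na(gm$identity[i, j])) {
        disp[i, j] <- sprintf("%.1f (%.1f)", gm$identity[i, j],
                              gm$similarity[i, j])
      }
    }
    df <- data.frame(group = gm$labels, disp, stringsAsFactors = FALSE)
    names(df) <- c("group", gm$labels)
    write_tsv0(df, tsv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(labels = gm$labels, identity = gm$identity,
           similarity = gm$similarity, n_pairs = gm$n_pairs),
      json_path, digits = NA, na = "null", matrix = "rowmajor")
  }
  invisible(gm)
}
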