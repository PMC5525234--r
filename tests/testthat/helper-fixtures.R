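# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

ref_frame <- function() fixture("frame", load_reference())

ref_map <- function() {
  fixture("ref_map", {
    frame <- ref_frame()
    align_to_reference(frame$sequence, frame, id = "ref")
  })
}

all_subfamilies <- c("FocA", "FdhC", "NirC-alpha", "NirC-beta", "NirC-gamma",
                     "HSC", "YfdC-alpha", "YfdC-beta")

# Small mapped cohort (6 per subfamily, seed 7) shared across test files.
small_cohort <- function() {
  fixture("small_cohort", {
    cfg <- generator_config(counts = setNames(rep(6L, 8), all_subfamilies),
                            seed = 7)
    cohort <- generate_cohort(cfg)
    mapset <- align_cohort(cohort$records, ref_frame())
    labels <- cohort$truth$subfamily[match(vapply(mapset, `[[`, "", "id"),
                                           cohort$truth$id)]
    list(config = cfg, cohort = cohort, mapset = mapset, labels = labels)
  })
}

# Build an fnt_map directly from an explicit residue string over positions
# 31-275 (gap symbol '-'), bypassing the aligner; for targeted conservation
# and pairwise tests.
manual_map <- function(residues_31_275, id = "manual") {
  stopifnot(nchar(residues_31_275) == 245L)
  chars <- strsplit(residues_31_275, "", fixed = TRUE)[[1L]]
  seqstr <- paste(chars[chars != "-"], collapse = "")
  map <- rep(NA_integer_, 245L)
  map[chars != "-"] <- seq_len(sum(chars != "-"))
  names(map) <- as.character(31:275)
  frame <- ref_frame()
  seg <- frame$segments
  coverage <- setNames(vapply(seq_len(nrow(seg)), function(i) {
    mean(!is.na(map[as.character(seg$start[i]:seg$end[i])]))
  }, numeric(1L)), seg$name)
  structure(list(id = id, species = NA_character_, sequence = seqstr,
                 score = NA_real_, map = map, coverage = coverage),
            class = "fnt_map")
}

# A residue string over 31-275 equal to the reference, with substitutions
# given as a named vector position -> residue ('-' to gap a position).
ref_string_with <- function(subs = character(0)) {
  frame <- ref_frame()
  chars <- ref_residue(frame, 31:275)
  if (length(subs)) chars[match(as.integer(names(subs)), 31:275)] <- subs
  paste(chars, collapse = "")
}

# Independent brute-force affine-gap DP oracle (score only): free end gaps,
# position-specific gap-open multipliers on the first sequence's axis.
# Written as plain Gotoh matrices in R, independent of the compiled kernel.
oracle_align_score <- function(a, b, submat, gap_open, gap_ext,
                               mult_del = rep(1, nchar(a)),
                               mult_ins = rep(1, nchar(a) + 1L)) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -Inf
  M <- matrix(NEG, n + 1L, m + 1L)
  D <- matrix(NEG, n + 1L, m + 1L)
  I <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  D[2:(n + 1L), 1] <- 0
  I[1, 2:(m + 1L)] <- 0
  for (i in 2:(n + 1L)) {
    od <- gap_open * mult_del[i - 1L] + gap_ext
    for (j in 2:(m + 1L)) {
      s <- submat[av[i - 1L], bv[j - 1L]]
      M[i, j] <- s + max(M[i - 1L, j - 1L], D[i - 1L, j - 1L],
                         I[i - 1L, j - 1L])
      D[i, j] <- max(M[i - 1L, j] - od, D[i - 1L, j] - gap_ext,
                     I[i - 1L, j] - od)
      oi <- gap_open * mult_ins[i] + gap_ext
      I[i, j] <- max(M[i, j - 1L] - oi, D[i, j - 1L] - oi,
                     I[i, j - 1L] - gap_ext)
    }
  }
  best <- max(M[n + 1L, ], D[n + 1L, ], I[n + 1L, ],
              M[, m + 1L], D[, m + 1L], I[, m + 1L])
  best
}

random_protein <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}
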