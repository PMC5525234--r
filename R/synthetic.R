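# Synthetic FNT cohort generator: sequence cohorts with known subfamily
# structure, conservation levels, loop-length variation and genome feature
# tables -- the ground-truthed test substrate for every other module.

.LOOP_REGIONS <- c("Nterm", "loopA", "loopB", "loopC", "loopD", "loopE",
                   "Cterm")

#' Default loop/termini length model
#'
#' Mean and SD of the N-terminus, the five inter-segment loops (A: TM1/TM2a,
#' B: TM2b/TM3, C: TM3/TM4, D: TM4/TM5a, E: TM5b/TM6) and the C-terminus,
#' per subfamily. The defaults emulate the reported qualitative pattern:
#' YfdC subfamilies carry the longest N-termini (40-55 residues vs 25-32
#' elsewhere), NirC-alpha has the shortest loop A and the longest loop C,
#' FocA an uncharacteristically long loop E, and FocA/YfdC-alpha the
#' longest C-termini.
#'
#' @return Data frame: region, subfamily, mean, sd.
#' @export
default_loop_model <- function() {
  means <- rbind(
    Nterm = c(28, 30, 25, 30, 27, 32, 50, 45),
    loopA = c(7, 7, 3, 7, 7, 7, 8, 8),
    loopB = c(5, 5, 5, 5, 5, 5, 5, 5),
    loopC = c(20, 20, 30, 20, 20, 20, 22, 22),
    loopD = c(3, 3, 3, 3, 3, 3, 3, 3),
    loopE = c(22, 10, 10, 10, 10, 10, 12, 12),
    Cterm = c(25, 10, 8, 10, 10, 10, 25, 12))
  sds <- c(Nterm = 5, loopA = 2, loopB = 1, loopC = 3, loopD = 1,
           loopE = 3, Cterm = 4)
  colnames(means) <- .SUBFAMILIES
  out <- expand.grid(region = rownames(means), subfamily = .SUBFAMILIES,
                     stringsAsFactors = FALSE)
  out$mean <- means[cbind(out$region, out$subfamily)]
  out$sd <- sds[out$region]
  out
}

#' Default FNT-gene / partner-enzyme map for the generator
#'
#' Which partner-enzyme class accompanies operon-supported genes of each
#' subfamily. The uncharacterized YfdC subfamilies have no known partner
#' (consistent with the absence of genetic linkage reported for them), so
#' they are never selected for operon placement under the default map.
#'
#' @return Named character vector, `NA` = no partner class.
#' @export
default_partner_map <- function() {
  c(FocA = "pfl", FdhC = "fdh", `NirC-alpha` = "nirBD",
    `NirC-beta` = "nirBD", `NirC-gamma` = "nirBD", HSC = "asrABC",
    `YfdC-alpha` = NA, `YfdC-beta` = NA)
}

#' Generator configuration
#'
#' Validated configuration for [generate_cohort()]. The default subfamily
#' counts reproduce the reported prokaryotic cohort composition (1723
#' classified sequences; YfdC-alpha largest with 361, NirC-beta smallest
#' with 79); the default mutation rate, diagnostic fidelity and operon
#' fraction are the study-like conditions used throughout the package's
#' validation (10% background substitution, 99% fidelity at constrained
#' positions, 15% operon support).
#'
#' @param counts Named integer vector, sequences per subfamily.
#' @param mutation_rate Per-position substitution probability at
#'   unconstrained positions (uniform over the 19 alternatives).
#' @param diagnostic_fidelity Probability that a constrained position
#'   (subfamily diagnostic or family-wide near-invariant) emits its
#'   consensus residue; otherwise it emits uniformly from outside its
#'   allowed set.
#' @param loop_length_model Data frame as [default_loop_model()].
#' @param operon_fraction Fraction of FNT genes given a partner enzyme in
#'   the generated feature tables.
#' @param partner_map Named vector as [default_partner_map()].
#' @param seed Integer seed; all draws flow from one generator stream, so a
#'   fixed seed gives byte-identical output.
#' @return A `fnt_generator_config` list.
#' @export
generator_config <- function(counts = NULL, mutation_rate = 0.1,
                             diagnostic_fidelity = 0.99,
                             loop_length_model = default_loop_model(),
                             operon_fraction = 0.15,
                             partner_map = default_partner_map(),
                             seed = 42) {
  if (is.null(counts)) {
    counts <- c(FocA = 280, FdhC = 250, `NirC-alpha` = 200, `NirC-beta` = 79,
                `NirC-gamma` = 180, HSC = 160, `YfdC-alpha` = 361,
                `YfdC-beta` = 213)
  }
  stopifnot(all(names(counts) %in% .SUBFAMILIES), all(counts >= 0),
            mutation_rate >= 0, mutation_rate <= 1,
            diagnostic_fidelity >= 0, diagnostic_fidelity <= 1,
            operon_fraction >= 0, operon_fraction <= 1)
  structure(list(counts = counts, mutation_rate = mutation_rate,
                 diagnostic_fidelity = diagnostic_fidelity,
                 loop_length_model = loop_length_model,
                 operon_fraction = operon_fraction,
                 partner_map = partner_map, seed = as.integer(seed)),
            class = "fnt_generator_config")
}

# Allowed residue set per constrained position for a subfamily: the
# family-wide asserted residues (near-invariant positions), overridden by
# the subfamily's diagnostic sets.
constrained_sets <- function(subfamily, frame, profiles) {
  sets <- as.list(frame$known_residues)
  d <- profiles[[subfamily]]$diagnostics
  for (i in seq_len(nrow(d))) {
    sets[[as.character(d$position[i])]] <-
      strsplit(d$residues[i], "", fixed = TRUE)[[1L]]
  }
  sets
}

# Deterministic draws isolated from (and restoring) the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.LOOP_ALPHABET <- c("G", "S", "N", "P", "D", "E")
.HYDRO_ALPHABET <- c("L", "A", "V", "I", "F", "M", "W", "G")

#' Build a subfamily consensus sequence
#'
#' Assembles a full-length consensus spanning the reference frame:
#' constrained positions (diagnostics and family-wide near-invariants) take
#' the first residue of their allowed set, remaining transmembrane
#' positions are filled with hydrophobic residues and loop positions from
#' the loop alphabet (G,S,N,P,D,E), deterministically from seed 0 offset by
#' the subfamily index so that distinct subfamilies diverge at
#' unconstrained positions (keeping inter-subfamily identity in the
#' realistic 25-35% range while intra-subfamily identity stays high).
#' Loop/termini lengths are the rounded means of the length model.
#'
#' @param subfamily Subfamily name.
#' @param frame Reference frame.
#' @param profiles Profiles from [builtin_profiles()].
#' @param loop_length_model Data frame as [default_loop_model()].
#' @return The consensus residue string, with attributes `core` (named
#'   residue vector over the segment positions) and `loops` (named list of
#'   region strings).
#' @export
build_consensus <- function(subfamily, frame, profiles = builtin_profiles(),
                            loop_length_model = default_loop_model()) {
  if (!subfamily %in% names(profiles)) {
    stop("unknown subfamily: ", subfamily, call. = FALSE)
  }
  si <- match(subfamily, .SUBFAMILIES)
  sets <- constrained_sets(subfamily, frame, profiles)
  segpos <- segment_positions(frame)
  refres <- ref_residue(frame, segpos)
  core <- with_seed(0L + si, {
    vapply(seq_along(segpos), function(k) {
      key <- as.character(segpos[k])
      if (!is.null(sets[[key]])) return(sets[[key]][1L])
      # homolog-like transmembrane fill: keep the reference residue with
      # probability 0.35, otherwise a random hydrophobic residue, so that
      # consensus-to-reference similarity matches what real subfamily
      # members show in the membrane (structure-anchored mapping stays
      # realistic while subfamilies still diverge from one another)
      if (runif(1L) < 0.35) refres[k] else sample(.HYDRO_ALPHABET, 1L)
    }, character(1L))
  })
  names(core) <- as.character(segpos)
  llm <- loop_length_model[loop_length_model$subfamily == subfamily, ]
  lens <- setNames(round(llm$mean), llm$region)
  loops <- with_seed(100L + si, {
    setNames(lapply(.LOOP_REGIONS, function(r) {
      paste(sample(.LOOP_ALPHABET, max(0L, lens[[r]]), replace = TRUE),
            collapse = "")
    }), .LOOP_REGIONS)
  })
  seq <- assemble_sequence(core, loops, frame)
  attr(seq, "core") <- core
  attr(seq, "loops") <- loops
  seq
}

# Join N-terminus, segment blocks and loops into a sequence string. Segment
# blocks contiguous in reference numbering (TM2a+OMEGA+TM2b; TM5a+S+TM5b)
# are emitted as one block; loops A-E fill the numbering gaps.
assemble_sequence <- function(core, loops, frame) {
  seg <- frame$segments
  blocks <- character(0)
  loop_i <- 0L
  for (i in seq_len(nrow(seg))) {
    if (i > 1L && seg$start[i] > seg$end[i - 1L] + 1L) {
      loop_i <- loop_i + 1L
      blocks <- c(blocks, loops[[paste0("loop", LETTERS[loop_i])]])
    }
    blocks <- c(blocks,
                paste(core[as.character(seg$start[i]:seg$end[i])],
                      collapse = ""))
  }
  paste0(loops$Nterm, paste(blocks, collapse = ""), loops$Cterm)
}

#' Generate a synthetic FNT cohort with ground truth
#'
#' Per sequence: the subfamily consensus core is re-emitted position by
#' position (constrained positions emit their consensus residue with
#' probability `diagnostic_fidelity`, otherwise uniformly from outside
#' their allowed set;
#' unconstrained positions substituted with probability `mutation_rate`,
#' uniformly over the 19 alternatives), loop/termini lengths are drawn from
#' the length model (contents from the consensus loop, resized and
#' mutated), and indels are thereby confined to loops and termini --
#' transmembrane blocks are never gapped. The emitted FASTA ids encode
#' nothing about the label; the label lives only in the ground truth.
#' Operon placement for `round(operon_fraction * n)` genes is drawn among
#' the subfamilies with a partner class.
#'
#' @param config A [generator_config()].
#' @param frame Reference frame.
#' @param profiles Profiles from [builtin_profiles()].
#' @return List with `records` (data frame id, species, sequence) and
#'   `truth` (data frame id, subfamily, constriction residue strings,
#'   region lengths, operon placement).
#' @export
generate_cohort <- function(config = generator_config(),
                            frame = load_reference(),
                            profiles = builtin_profiles()) {
  stopifnot(inherits(config, "fnt_generator_config"))
  counts <- config$counts[config$counts > 0]
  n_total <- sum(counts)
  if (n_total == 0L) {
    empty <- data.frame(id = character(0), species = character(0),
                        sequence = character(0), stringsAsFactors = FALSE)
    return(list(records = empty, truth = data.frame(id = character(0))))
  }
  consensi <- lapply(setNames(names(counts), names(counts)), build_consensus,
                     frame = frame, profiles = profiles,
                     loop_length_model = config$loop_length_model)
  sets_by_sub <- lapply(setNames(names(counts), names(counts)),
                        constrained_sets, frame = frame, profiles = profiles)
  segpos_chr <- as.character(segment_positions(frame))
  site_chr <- lapply(list(central = site_positions(frame, "central"),
                          slit_closed = site_positions(frame, "slit", "closed"),
                          slit_open = site_positions(frame, "slit", "open")),
                     as.character)

  with_seed(config$seed, {
    rows <- vector("list", n_total)
    k <- 0L
    for (sub in names(counts)) {
      cons <- consensi[[sub]]
      core <- attr(cons, "core")
      loops <- attr(cons, "loops")
      sets <- sets_by_sub[[sub]]
      constrained <- names(core) %in% names(sets)
      llm <- config$loop_length_model[
        config$loop_length_model$subfamily == sub, ]
      lmean <- setNames(llm$mean, llm$region)
      lsd <- setNames(llm$sd, llm$region)
      for (r in seq_len(counts[[sub]])) {
        k <- k + 1L
        emitted <- core
        u <- runif(length(core))
        for (i in which(constrained)) {
          allowed <- sets[[names(core)[i]]]
          if (u[i] < config$diagnostic_fidelity) {
            emitted[i] <- allowed[1L]  # consensus residue of the allowed set
          } else {
            emitted[i] <- sample(setdiff(.AA20, allowed), 1L)
          }
        }
        mut <- which(!constrained & u < config$mutation_rate)
        for (i in mut) {
          emitted[i] <- sample(setdiff(.AA20, core[i]), 1L)
        }
        drawn <- list()
        lens <- integer(0)
        for (region in .LOOP_REGIONS) {
          len <- max(0L, as.integer(round(rnorm(1L, lmean[[region]],
                                                lsd[[region]]))))
          base <- strsplit(loops[[region]], "", fixed = TRUE)[[1L]]
          s <- if (len <= length(base)) base[seq_len(len)]
               else c(base, .LOOP_ALPHABET[
                 ((length(base) + seq_len(len - length(base)) - 1L) %%
                    length(.LOOP_ALPHABET)) + 1L])
          if (config$mutation_rate > 0 && len > 0L) {
            mu <- which(runif(len) < config$mutation_rate)
            for (i in mu) s[i] <- sample(setdiff(.AA20, s[i]), 1L)
          }
          drawn[[region]] <- paste(s, collapse = "")
          lens[region] <- len
        }
        rows[[k]] <- list(
          subfamily = sub,
          sequence = assemble_sequence(emitted, drawn, frame),
          central = paste(emitted[site_chr$central], collapse = ""),
          slit_closed = paste(emitted[site_chr$slit_closed], collapse = ""),
          slit_open = paste(emitted[site_chr$slit_open], collapse = ""),
          lens = lens)
      }
    }
    ord <- sample.int(n_total)
    rows <- rows[ord]
    ids <- sprintf("FNT%04d", seq_len(n_total))
    species <- sprintf("Synthomonas sp. S%04d", seq_len(n_total))

    truth <- data.frame(
      id = ids,
      subfamily = vapply(rows, `[[`, "", "subfamily"),
      central = vapply(rows, `[[`, "", "central"),
      slit_closed = vapply(rows, `[[`, "", "slit_closed"),
      slit_open = vapply(rows, `[[`, "", "slit_open"),
      stringsAsFactors = FALSE)
    for (region in .LOOP_REGIONS) {
      truth[[paste0("len_", region)]] <-
        vapply(rows, function(x) x$lens[[region]], integer(1L))
    }

    # operon placement among subfamilies with a partner class
    truth$partner_class <- "none"
    truth$gene_distance <- NA_integer_
    eligible <- which(!is.na(config$partner_map[truth$subfamily]))
    n_op <- round(config$operon_fraction * n_total)
    if (n_op > length(eligible)) {
      warning("operon_fraction demands ", n_op, " supported genes but only ",
              length(eligible), " belong to partnered subfamilies; capping",
              call. = FALSE)
      n_op <- length(eligible)
    }
    sel <- if (n_op > 0L) sort(sample(eligible, n_op)) else integer(0)
    truth$partner_class[sel] <-
      unname(config$partner_map[truth$subfamily[sel]])
    truth$gene_distance[sel] <-
      sample(1:3, length(sel), replace = TRUE) *
      sample(c(-1L, 1L), length(sel), replace = TRUE)

    list(records = data.frame(
           id = ids, species = species,
           sequence = vapply(rows, `[[`, "", "sequence"),
           stringsAsFactors = FALSE),
         truth = truth)
  })
}

.FILLER_PRODUCTS <- c("hypothetical protein", "DNA-binding response regulator",
                      "ABC transporter permease", "ribosomal protein L3",
                      "tRNA ligase", "cell division protein FtsZ")
.PARTNER_PRODUCTS <- c(pfl = "pyruvate formate lyase",
                       fdh = "formate dehydrogenase alpha subunit",
                       nirBD = "nitrite reductase large subunit",
                       asrABC = "anaerobic sulfite reductase subunit A")

#' Generate genome feature tables realising the cohort's operon placement
#'
#' One contig per sequence, each carrying the FNT CDS (locus tag = the
#' sequence id) flanked by filler genes; sequences selected for operon
#' support in the ground truth get a partner-enzyme CDS at the recorded
#' signed gene distance on the same strand.
#'
#' @param truth Ground-truth data frame from [generate_cohort()].
#' @param config The same [generator_config()].
#' @return Canonical 6-column feature data frame.
#' @export
generate_feature_table <- function(truth, config) {
  with_seed(config$seed + 1L, {
    rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      id <- truth$id[i]
      strand <- sample(c("+", "-"), 1L)
      n_genes <- 7L
      fnt_pos <- 4L
      lens <- sample(900:1500, n_genes, replace = TRUE)
      gaps <- sample(50:200, n_genes, replace = TRUE)
      starts <- cumsum(c(1L, (lens + gaps)[-n_genes]))
      ends <- starts + lens - 1L
      strands <- sample(c("+", "-"), n_genes, replace = TRUE)
      strands[fnt_pos] <- strand
      products <- sample(.FILLER_PRODUCTS, n_genes, replace = TRUE)
      products[fnt_pos] <- "FNT family anion channel"
      tags <- sprintf("%s_g%d", id, seq_len(n_genes))
      tags[fnt_pos] <- id
      if (truth$partner_class[i] != "none") {
        d <- truth$gene_distance[i]
        off <- if (strand == "+") d else -d  # downstream = transcription dir
        p <- fnt_pos + off
        strands[p] <- strand
        products[p] <- .PARTNER_PRODUCTS[[truth$partner_class[i]]]
      }
      rows[[i]] <- data.frame(
        contig = paste0("ctg_", id), start = starts, end = ends,
        strand = strands, locus_tag = tags, product = products,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Write a generated cohort to disk
#'
#' Emits standard FASTA (species carried as a UniProt-style `OS=` token),
#' the ground-truth TSV, and -- when a feature table is supplied -- GFF3
#' and TSV feature files.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param features Optional feature table from [generate_feature_table()].
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir, features = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "cohort.fasta"),
             truth = file.path(dir, "ground_truth.tsv"))
  aa <- Biostrings::AAStringSet(setNames(cohort$records$sequence,
                                         sprintf("%s OS=%s",
                                                 cohort$records$id,
                                                 cohort$records$species)))
  Biostrings::writeXStringSet(aa, paths[["fasta"]])
  write_tsv0(cohort$truth, paths[["truth"]])
  if (!is.null(features)) {
    paths[["features_tsv"]] <- file.path(dir, "features.tsv")
    paths[["features_gff3"]] <- file.path(dir, "features.gff3")
    write_features(features, paths[["features_tsv"]], "tsv")
    write_features(features, paths[["features_gff3"]], "gff3")
  }
  invisible(paths)
}
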