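# Seeded synthetic-data generator. Emulates the statistical structure the
# model assumes: proteins of 50-500 residues, a roughly 5.5:1
# non-site:site residue imbalance, and labels determined by local sequence
# context (a planted motif whose central residue is the positive class).
# Together with synth_feature_source() this makes the whole pipeline
# testable with no external databases.

# PSI-BLAST matrix column order (differs from the package's alphabet order).
PSIBLAST_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]

#' Synthetic corpus configuration
#'
#' @param n_proteins Number of proteins.
#' @param len_range Inclusive protein length range.
#' @param motif Planted residue motif; its central residue is labeled a
#'   site. `NULL` gives the motif-free negative control in which labels
#'   are drawn independently of sequence (an unlearnable task).
#' @param composition Named background residue probabilities over the
#'   20-letter alphabet, or `NULL` for uniform.
#' @param ratio Target non-site:site residue ratio (default 5.5, the
#'   imbalance of the published corpus).
#' @param sigma Feature noise level forwarded to [synth_feature_source()].
#' @param site_index Which residue of a planted occurrence carries the
#'   site label (1-based within the motif). The default is the motif's
#'   central residue; `site_index = 1` places the whole motif inside the
#'   window's central K-mer under the default `w = 7`, `k = 3` geometry,
#'   making the label a function of that K-mer alone.
#' @param seed Seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 200L, len_range = c(50L, 500L),
                         motif = "KDY", composition = NULL, ratio = 5.5,
                         sigma = 0, site_index = NULL, seed = 1L) {
  stopifnot(n_proteins >= 1L, length(len_range) == 2L,
            len_range[1L] >= 1L, len_range[1L] <= len_range[2L],
            ratio > 0, sigma >= 0)
  if (!is.null(motif)) {
    stopifnot(is.character(motif), nchar(motif) >= 1L)
    if (!all(strsplit(motif, "")[[1L]] %in% AA_ALPHABET)) {
      stop("motif must use the canonical residue alphabet", call. = FALSE)
    }
    if (nchar(motif) > len_range[1L]) {
      stop("motif longer than the minimum protein length", call. = FALSE)
    }
  }
  if (!is.null(composition)) {
    stopifnot(all(names(composition) %in% AA_ALPHABET), all(composition >= 0),
              sum(composition) > 0)
  }
  if (is.null(site_index)) {
    site_index <- if (is.null(motif)) 1L else (nchar(motif) + 1L) %/% 2L
  }
  site_index <- as.integer(site_index)
  if (!is.null(motif) && (site_index < 1L || site_index > nchar(motif))) {
    stop("site_index must lie within the motif", call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 len_range = as.integer(len_range), motif = motif,
                 composition = composition, ratio = ratio, sigma = sigma,
                 site_index = site_index, seed = as.integer(seed)),
            class = "synth_config")
}

# All start positions (1-based) where `motif` occurs in `chars`.
motif_occurrences <- function(chars, motif_chars) {
  L <- length(chars)
  mlen <- length(motif_chars)
  if (L < mlen) return(integer(0))
  starts <- seq_len(L - mlen + 1L)
  hits <- vapply(starts, function(s) {
    all(chars[s:(s + mlen - 1L)] == motif_chars)
  }, logical(1L))
  starts[hits]
}

generate_one_protein <- function(L, cfg, comp_probs) {
  mlen <- if (is.null(cfg$motif)) 0L else nchar(cfg$motif)
  if (is.null(cfg$motif)) {
    chars <- sample(AA_ALPHABET, L, replace = TRUE, prob = comp_probs)
    labels <- stats::rbinom(L, 1L, 1 / (1 + cfg$ratio))
    return(list(chars = chars, labels = labels, plants = integer(0)))
  }
  motif_chars <- strsplit(cfg$motif, "")[[1L]]
  n_plant <- max(0L, round(L / (1 + cfg$ratio)))
  if (n_plant * mlen > L) {
    stop("infeasible motif/length combination: ", n_plant, " plants of ",
         mlen, " residues do not fit in length ", L, call. = FALSE)
  }
  # Non-overlapping plant starts: rejection-sample a few times.
  plants <- NULL
  for (try in 1:50) {
    avail <- seq_len(L - mlen + 1L)
    chosen <- integer(0)
    while (length(chosen) < n_plant && length(avail) > 0L) {
      s <- if (length(avail) == 1L) avail else sample(avail, 1L)
      chosen <- c(chosen, s)
      avail <- avail[abs(avail - s) >= mlen]
    }
    if (length(chosen) == n_plant) { plants <- sort(chosen); break }
  }
  if (is.null(plants)) {
    stop("could not place ", n_plant, " non-overlapping motifs in length ",
         L, call. = FALSE)
  }
  chars <- sample(AA_ALPHABET, L, replace = TRUE, prob = comp_probs)
  planted_pos <- unlist(lapply(plants, function(s) s:(s + mlen - 1L)))
  for (s in plants) chars[s:(s + mlen - 1L)] <- motif_chars
  # Destroy accidental (unplanted) occurrences so the label is an exact
  # function of the local window.
  for (iter in 1:200) {
    occ <- setdiff(motif_occurrences(chars, motif_chars), plants)
    if (length(occ) == 0L) break
    s <- occ[1L]
    span <- s:(s + mlen - 1L)
    mutable <- setdiff(span, planted_pos)
    if (length(mutable) == 0L) {
      # Overlap pattern fully inside plants cannot occur for non-overlapping
      # plants unless the motif is self-overlapping at distance >= mlen,
      # which setdiff(.., plants) already excludes.
      stop("internal error: accidental motif occurrence inside plants",
           call. = FALSE)
    }
    pos <- mutable[1L]
    current <- chars[pos]
    chars[pos] <- sample(setdiff(AA_ALPHABET, current), 1L)
  }
  if (length(setdiff(motif_occurrences(chars, motif_chars), plants)) > 0L) {
    stop("could not remove accidental motif occurrences", call. = FALSE)
  }
  labels <- integer(L)
  centers <- plants + cfg$site_index - 1L
  labels[centers] <- 1L
  list(chars = chars, labels = labels, plants = plants)
}

#' Generate a labeled synthetic protein corpus
#'
#' Sequences are drawn from the background composition; the motif is
#' planted at seeded non-overlapping positions at a rate chosen so the
#' realized non-site:site ratio matches the target; accidental motif
#' occurrences in the background are mutated away, so a residue is labeled
#' 1 exactly when it is the central residue of a planted occurrence. Each
#' record carries its ground-truth plant positions in the `"plants"`
#' attribute.
#'
#' @param cfg A [synth_config()].
#' @return List of labeled [protein_record]s.
#' @export
generate_proteins <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  comp_probs <- if (is.null(cfg$composition)) {
    rep(1 / 20, 20L)
  } else {
    p <- stats::setNames(numeric(20L), AA_ALPHABET)
    p[names(cfg$composition)] <- cfg$composition
    p / sum(p)
  }
  with_rng_seed(cfg$seed, {
    lapply(seq_len(cfg$n_proteins), function(i) {
      L <- if (cfg$len_range[1L] == cfg$len_range[2L]) cfg$len_range[1L] else
        sample(cfg$len_range[1L]:cfg$len_range[2L], 1L)
      g <- generate_one_protein(L, cfg, comp_probs)
      rec <- protein_record(sprintf("synth%04d", i),
                            paste(g$chars, collapse = ""), g$labels)
      attr(rec, "plants") <- g$plants
      rec
    })
  })
}

#' Realized non-site:site ratio of a labeled corpus
#' @param records Labeled [protein_record]s.
#' @return Scalar ratio of negative to positive residues.
#' @export
realized_ratio <- function(records) {
  labs <- unlist(lapply(records, `[[`, "labels"))
  sum(labs == 0L) / sum(labs == 1L)
}

# ---- fixture writers (the exact dialects the readers parse) ----

#' Write protein records to a FASTA file
#' @param records List of [protein_record]s.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  lines <- unlist(lapply(records, function(r) {
    starts <- seq(1L, nchar(r$sequence), by = width)
    c(paste0(">", r$id),
      vapply(starts, function(s) substr(r$sequence, s, s + width - 1L),
             character(1L)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write residue labels as two-column text
#' @param records Labeled [protein_record]s.
#' @param path Output path.
#' @export
write_labels <- function(records, path) {
  lines <- vapply(records, function(r) {
    paste(r$id, paste(r$labels, collapse = ""))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write a raw log-odds matrix in the PSI-BLAST ASCII PSSM dialect
#'
#' @param raw L x 20 raw (unsquashed) log-odds matrix whose columns follow
#'   the PSI-BLAST residue order `ARNDCQEGHILKMFPSTWYV`.
#' @param sequence Residue string of length L.
#' @param path Output path.
#' @export
write_pssm <- function(raw, sequence, path) {
  L <- nchar(sequence)
  stopifnot(nrow(raw) == L, ncol(raw) == 20L)
  chars <- strsplit(sequence, "")[[1L]]
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%10s", PSIBLAST_ORDER), collapse = ""))
  )
  body <- vapply(seq_len(L), function(i) {
    paste0(sprintf("%5d %s", i, chars[i]),
           paste(sprintf(" %9.4f", raw[i, ]), collapse = ""))
  }, character(1L))
  writeLines(c(lines, body, "", "                      K         Lambda"), path)
  invisible(path)
}

#' Write secondary-structure states in the classic DSSP text dialect
#'
#' Residues with `NA` state are omitted from the data section (that is how
#' missing assignments appear in real DSSP output); `"other"` is written as
#' the blank (coil) code.
#'
#' @param states Character vector of states aligned to the sequence
#'   (`G,H,I,B,E,T,S`, `"other"`, or `NA`).
#' @param record The [protein_record] the states belong to.
#' @param path Output path.
#' @export
write_dssp <- function(states, record, path) {
  L <- nchar(record$sequence)
  stopifnot(length(states) == L)
  chars <- strsplit(record$sequence, "")[[1L]]
  lines <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    paste0("  ", L, "  1  0  0  0  TOTAL NUMBER OF RESIDUES"),
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"
  )
  serial <- 0L
  body <- character(0)
  for (i in seq_len(L)) {
    if (is.na(states[i])) next
    serial <- serial + 1L
    code <- if (states[i] %in% SS_STATES[1:7]) states[i] else " "
    body <- c(body, sprintf("%5d%5d A %s  %s", serial, i, chars[i], code))
  }
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a per-residue embedding table
#' @param emb L x E numeric matrix.
#' @param path Output path.
#' @export
write_embedding <- function(emb, path) {
  utils::write.table(format(emb, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a complete synthetic dataset as on-disk fixtures
#'
#' Emits `sequences.fasta`, `labels.txt` and per-protein `pssm/`, `dssp/`
#' and `emb/` files in exactly the dialects the readers parse, so a
#' file-based run reproduces a synthetic one.
#'
#' @param records Labeled [protein_record]s.
#' @param dir Output directory (created if needed).
#' @param source A [synth_feature_source()] supplying the feature draws.
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(records, dir,
                                    source = synth_feature_source()) {
  for (d in file.path(dir, c("", "pssm", "dssp", "emb"))) {
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }
  write_fasta(records, file.path(dir, "sequences.fasta"))
  write_labels(records, file.path(dir, "labels.txt"))
  perm <- match(PSIBLAST_ORDER, AA_ALPHABET)
  for (r in records) {
    prot_seed <- string_seed(r$id, source$seed)
    raw <- with_rng_seed(prot_seed, synth_pssm_raw(r, source))
    write_pssm(raw[, perm, drop = FALSE], r$sequence,
               file.path(dir, "pssm", paste0(r$id, ".pssm")))
    ss <- with_rng_seed(prot_seed + 1L, synth_ss_states(r, source))
    write_dssp(ss, r, file.path(dir, "dssp", paste0(r$id, ".dssp")))
    emb <- get_embedding(hash_embedding_provider(source$embed_dim,
                                                 source$seed), r)
    write_embedding(emb, file.path(dir, "emb", paste0(r$id, ".tsv")))
  }
  invisible(dir)
}
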