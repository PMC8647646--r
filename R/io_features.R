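#' @useDynLib hanppis, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical residue alphabet; column order is fixed across the package.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Eight explicit secondary-structure states plus the catch-all "other"
# bucket used for coil/blank assignments.
SS_STATES <- c("G", "H", "I", "B", "E", "T", "S", "other")

# Kyte-Doolittle hydropathy scale (free energy of water -> organic-solvent
# transfer, dimensionless as tabulated).
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Construct a protein record
#'
#' A `protein_record` couples a sequence identifier, its residue string and
#' (optionally) a per-residue 0/1 interaction-site label vector.
#'
#' @param id Sequence identifier.
#' @param sequence Residue string (canonical 20-letter alphabet plus
#'   nonstandard codes such as X, B, Z, U, O).
#' @param labels Optional integer vector of 0/1 site labels, one per residue.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, labels = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) {
    stop("protein record '", id, "' has an empty sequence", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nchar(sequence)) {
      stop("labels for '", id, "' have length ", length(labels),
           " but the sequence has ", nchar(sequence), " residues",
           call. = FALSE)
    }
    if (!all(labels %in% c(0L, 1L))) {
      stop("labels for '", id, "' contain values outside {0,1}", call. = FALSE)
    }
  }
  structure(list(id = id, sequence = sequence, labels = labels),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, ": ", nchar(x$sequence), " residues",
      if (!is.null(x$labels)) paste0(", ", sum(x$labels), " site(s)"), "\n",
      sep = "")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Wrapped sequence lines are concatenated; record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_record] objects (no labels attached).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(list())
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  empty <- which(nchar(seqs) == 0L)
  if (length(empty) > 0L) {
    stop("FASTA record '", ids[empty[1L]], "' has an empty sequence",
         call. = FALSE)
  }
  unname(Map(protein_record, ids, seqs))
}

#' Read per-protein residue labels
#'
#' Parses a two-column whitespace-delimited text file: protein id, then a
#' string of 0/1 characters (one per residue).
#'
#' @param path Path to the label file.
#' @return A named list of integer 0/1 vectors, one per protein id.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L) {
      stop("malformed label line (expected 'id 0/1-string'): ", ln,
           call. = FALSE)
    }
    id <- parts[1L]
    bits <- strsplit(parts[2L], "")[[1L]]
    if (!all(bits %in% c("0", "1"))) {
      stop("label string for '", id, "' contains characters outside {0,1}",
           call. = FALSE)
    }
    if (!is.null(out[[id]])) stop("duplicate label id: ", id, call. = FALSE)
    out[[id]] <- as.integer(bits)
  }
  out
}

#' One-hot encode a residue
#'
#' The 20 canonical residues (order `ACDEFGHIKLMNPQRSTVWY`) map to indicator
#' vectors; any other character (X, B, Z, gaps, ...) maps to the all-zero
#' vector.
#'
#' @param residue Single character.
#' @return Numeric vector of length 20.
#' @export
one_hot_encode <- function(residue) {
  stopifnot(is.character(residue), length(residue) == 1L, nchar(residue) == 1L)
  v <- numeric(20L)
  i <- match(residue, AA_ALPHABET)
  if (!is.na(i)) v[i] <- 1
  v
}

# Vectorised one-hot over a sequence string -> L x 20 matrix.
one_hot_matrix <- function(sequence) {
  chars <- strsplit(sequence, "")[[1L]]
  idx <- match(chars, AA_ALPHABET)
  m <- matrix(0, nrow = length(chars), ncol = 20L)
  ok <- which(!is.na(idx))
  m[cbind(ok, idx[ok])] <- 1
  m
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` dialect (two header lines, one data row per
#' residue carrying the position, the residue and 20 integer log-odds
#' scores, then trailing statistics). Each raw log-odds value `x` is mapped
#' through the logistic function `1/(1+exp(-x))` so entries lie in (0,1);
#' set `scale = FALSE` to keep the raw integers.
#'
#' @param path Path to the PSSM file.
#' @param expected_length Number of residues the matrix must cover.
#' @param scale Apply the logistic squashing (default `TRUE`).
#' @return Numeric matrix with `expected_length` rows and 20 columns, in
#'   PSI-BLAST column order.
#' @export
parse_pssm <- function(path, expected_length, scale = TRUE) {
  if (!file.exists(path)) stop("PSSM file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # Data rows start with an integer position followed by a residue letter.
  is_data <- grepl("^\\s*\\d+\\s+[A-Za-z]", lines)
  rows <- lines[is_data]
  if (length(rows) == 0L) stop("no PSSM data rows in ", path, call. = FALSE)
  parsed <- lapply(rows, function(ln) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) < 22L) {
      stop("malformed PSSM row (fewer than 22 fields): ", ln, call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts[3:22]))
    if (anyNA(vals)) stop("non-numeric log-odds in PSSM row: ", ln, call. = FALSE)
    vals
  })
  m <- do.call(rbind, parsed)
  if (nrow(m) != expected_length) {
    stop("PSSM in ", path, " has ", nrow(m), " rows but ", expected_length,
         " residues were expected", call. = FALSE)
  }
  if (scale) m <- 1 / (1 + exp(-m))
  dimnames(m) <- NULL
  m
}

#' Encode a secondary-structure state as a 9-dimensional vector
#'
#' The first eight dimensions one-hot encode the DSSP states G (3_10-helix),
#' H (alpha-helix), I (pi-helix), B (isolated bridge), E (extended sheet),
#' T (turn), S (bend) and a catch-all "other" bucket (DSSP blank/coil codes
#' land here). The ninth dimension flags whether any structural state was
#' available; residues absent from the DSSP output get the all-zero vector.
#'
#' @param state Single state character, `"other"`, or `NA` for absent.
#' @return Numeric vector of length 9.
#' @export
encode_secondary_structure <- function(state) {
  v <- numeric(9L)
  if (length(state) != 1L || is.na(state)) return(v)
  state <- as.character(state)
  i <- match(state, SS_STATES)
  if (is.na(i)) i <- 8L  # blanks and unrecognised codes -> "other"
  v[i] <- 1
  v[9L] <- 1
  v
}

#' Parse a DSSP output file and align states to a protein sequence
#'
#' Reads the classic DSSP text dialect: data rows follow the line whose
#' header starts with `#  RESIDUE`; the residue number sits in columns 6-10
#' and the single-character structure code in column 17. Chain-break rows
#' (residue `!`) are skipped. Residues with no DSSP row are reported as
#' `NA` (no structural information).
#'
#' @param path Path to the DSSP file.
#' @param record A [protein_record]; states are aligned to its residues.
#' @return Character vector of length `nchar(record$sequence)`; entries are
#'   state codes, `"other"` for blank assignments, or `NA` when absent.
#' @export
parse_dssp <- function(path, record) {
  if (!file.exists(path)) stop("DSSP file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (length(hdr) == 0L) {
    stop("no '#  RESIDUE' header line in DSSP file ", path, call. = FALSE)
  }
  data <- lines[seq.int(hdr[1L] + 1L, length.out = length(lines) - hdr[1L])]
  data <- data[nzchar(trimws(data))]
  if (length(data) == 0L) stop("DSSP file ", path, " has no data rows", call. = FALSE)
  L <- nchar(record$sequence)
  states <- rep(NA_character_, L)
  for (ln in data) {
    aa <- substr(ln, 14L, 14L)
    if (aa == "!") next  # chain break
    num <- suppressWarnings(as.integer(trimws(substr(ln, 6L, 10L))))
    if (is.na(num)) next  # rows with no sequential residue number
    if (num < 1L || num > L) {
      stop("DSSP row for residue ", num, " is outside 1..", L,
           " for protein '", record$id, "'", call. = FALSE)
    }
    code <- substr(ln, 17L, 17L)
    states[num] <- if (code %in% SS_STATES[1:7]) code else "other"
  }
  states
}

#' Kyte-Doolittle hydropathy of a residue
#'
#' Nonstandard or unknown residues map to 0 (neutral). Alternative scales
#' can be supplied as a named numeric vector.
#'
#' @param residue Single character.
#' @param scale Named numeric lookup; defaults to the Kyte-Doolittle table.
#' @return Scalar hydropathy value.
#' @export
hydropathy <- function(residue, scale = KYTE_DOOLITTLE) {
  stopifnot(is.character(residue), length(residue) == 1L, nchar(residue) == 1L)
  v <- scale[residue]
  if (is.na(v)) 0 else unname(v)
}

#' Relative position of a residue within its protein
#'
#' Divides the 1-based position by the protein length so the feature lies
#' in (0, 1].
#'
#' @param position 1-based residue index.
#' @param length Protein length.
#' @return Scalar in (0, 1].
#' @export
position_feature <- function(position, length) {
  stopifnot(length >= 1L)
  if (position < 1L || position > length) {
    stop("position ", position, " out of range 1..", length, call. = FALSE)
  }
  position / length
}

#' Deterministic hash-based embedding provider
#'
#' Stands in for a pre-trained protein language model when no precomputed
#' embedding files are available: each residue character is expanded into
#' `dim` pseudo-random values in [-1, 1] by an integer hash of
#' (character, seed, column), so the provider is a pure function of its
#' inputs and needs no stored model.
#'
#' @param dim Embedding dimension (default 1024).
#' @param seed Integer hash seed.
#' @return An embedding provider usable with [get_embedding()].
#' @export
hash_embedding_provider <- function(dim = 1024L, seed = 1L) {
  stopifnot(dim >= 1L)
  structure(list(kind = "hash", dim = as.integer(dim), seed = as.integer(seed)),
            class = "han_embedding_provider")
}

#' File-backed embedding provider
#'
#' Serves precomputed per-residue embeddings from one whitespace-delimited
#' L x E table per protein, named `<id>.tsv` under `dir`.
#'
#' @param dir Directory of per-protein embedding tables.
#' @param dim Embedding dimension the tables must have.
#' @return An embedding provider usable with [get_embedding()].
#' @export
file_embedding_provider <- function(dir, dim = 1024L) {
  stopifnot(dir.exists(dir))
  structure(list(kind = "file", dir = dir, dim = as.integer(dim)),
            class = "han_embedding_provider")
}

# Deterministic integer hash -> value in [-1, 1]. Pure double arithmetic;
# all intermediates stay far below 2^53 so results are exact and portable.
hash_unit_values <- function(char_code, seed, n) {
  j <- seq_len(n)
  h <- (char_code * 2654435.0 + seed * 40503.0 + j * 9973.0) %% 2147483647
  h <- (h * 16807) %% 2147483647
  h <- (h * 16807) %% 2147483647
  2 * (h / 2147483646) - 1
}

#' Per-residue embedding matrix for a protein
#'
#' @param provider Provider from [hash_embedding_provider()] or
#'   [file_embedding_provider()].
#' @param record A [protein_record].
#' @return Numeric matrix with one row per residue and `provider$dim` columns.
#' @export
get_embedding <- function(provider, record) {
  stopifnot(inherits(provider, "han_embedding_provider"))
  L <- nchar(record$sequence)
  if (L == 0L) stop("empty sequence", call. = FALSE)
  if (provider$kind == "hash") {
    chars <- strsplit(record$sequence, "")[[1L]]
    codes <- utf8ToInt(record$sequence)
    uniq <- unique(codes)
    rows <- vapply(uniq, hash_unit_values, numeric(provider$dim),
                   seed = provider$seed, n = provider$dim)
    # vapply gives dim x n_uniq; index columns by residue then transpose
    t(rows[, match(codes, uniq), drop = FALSE])
  } else {
    path <- file.path(provider$dir, paste0(record$id, ".tsv"))
    if (!file.exists(path)) {
      stop("no embedding table for protein '", record$id, "' at ", path,
           call. = FALSE)
    }
    m <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != L) {
      stop("embedding for '", record$id, "' has ", nrow(m),
           " rows but the sequence has ", L, " residues", call. = FALSE)
    }
    if (ncol(m) != provider$dim) {
      stop("embedding for '", record$id, "' has ", ncol(m),
           " columns; expected ", provider$dim, call. = FALSE)
    }
    m
  }
}

#' Assemble per-residue feature bundles
#'
#' Combines the six feature blocks for each residue of a protein: one-hot
#' identity, PSSM row, 9-dimensional secondary-structure encoding,
#' hydropathy, relative sequence position and the raw embedding row
#' (projection to the fused width happens inside the model).
#'
#' @param record A [protein_record].
#' @param pssm L x 20 matrix from [parse_pssm()] (or a synthetic source).
#' @param ss_states Character vector of length L from [parse_dssp()].
#' @param embedding L x E matrix from [get_embedding()].
#' @return A list of `residue_feature_bundle` objects, one per residue.
#' @export
assemble_bundles <- function(record, pssm, ss_states, embedding) {
  L <- nchar(record$sequence)
  if (nrow(pssm) != L) stop("pssm has ", nrow(pssm), " rows, expected ", L, call. = FALSE)
  if (length(ss_states) != L) stop("ss_states has length ", length(ss_states), ", expected ", L, call. = FALSE)
  if (nrow(embedding) != L) stop("embedding has ", nrow(embedding), " rows, expected ", L, call. = FALSE)
  chars <- strsplit(record$sequence, "")[[1L]]
  lapply(seq_len(L), function(i) {
    structure(list(
      one_hot    = one_hot_encode(chars[i]),
      pssm       = pssm[i, ],
      ss9        = encode_secondary_structure(ss_states[i]),
      hydropathy = hydropathy(chars[i]),
      rel_pos    = position_feature(i, L),
      embedding  = embedding[i, ]
    ), class = "residue_feature_bundle")
  })
}
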