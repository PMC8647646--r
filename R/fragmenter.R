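# Fragmenter: labeled proteins -> per-residue training samples. Each
# residue of a (truncated) protein yields one fragment: an odd-length
# window of residue feature vectors centred on it, zero-padded at the
# sequence ends, segmented into consecutive non-overlapping K-mers.

#' Truncate a protein record to a maximum length
#'
#' @param record A [protein_record].
#' @param max_len Maximum retained length (default 500).
#' @return The record with sequence and labels cut to the first `max_len`
#'   residues; shorter records are returned unchanged.
#' @export
truncate_record <- function(record, max_len = 500L) {
  stopifnot(max_len >= 1L)
  L <- nchar(record$sequence)
  if (L <= max_len) return(record)
  protein_record(record$id, substr(record$sequence, 1L, max_len),
                 if (!is.null(record$labels)) record$labels[seq_len(max_len)])
}

# Zero feature bundle used to pad windows at sequence boundaries.
zero_bundle <- function(embed_dim) {
  structure(list(
    one_hot = numeric(20L), pssm = numeric(20L), ss9 = numeric(9L),
    hydropathy = 0, rel_pos = 0, embedding = numeric(embed_dim)
  ), class = "residue_feature_bundle")
}

#' Extract the sliding window centred on one residue
#'
#' Positions falling outside the protein are filled with zero-feature pads,
#' marked 0 in the pad mask and shown as `-` in the window string.
#'
#' @param bundles List of `residue_feature_bundle` from [assemble_bundles()].
#' @param residues Residue string of the (truncated) protein.
#' @param labels Integer 0/1 label vector, or `NULL` for unlabeled proteins.
#' @param center 0-based index of the target residue.
#' @param w Odd window length (default 7).
#' @param protein_id Identifier recorded on the fragment.
#' @return An object of class `han_fragment` with fields `protein_id`,
#'   `center`, `window_bundles`, `pad_mask`, `label` and `window_residues`.
#' @export
extract_window <- function(bundles, residues, labels, center, w = 7L,
                           protein_id = "") {
  w <- as.integer(w)
  if (w %% 2L == 0L) stop("window length w must be odd, got ", w, call. = FALSE)
  L <- length(bundles)
  stopifnot(nchar(residues) == L)
  if (center < 0L || center >= L) {
    stop("center ", center, " out of range 0..", L - 1L, call. = FALSE)
  }
  half <- (w - 1L) %/% 2L
  idx <- (center - half):(center + half)
  inside <- idx >= 0L & idx < L
  embed_dim <- length(bundles[[1L]]$embedding)
  window_bundles <- lapply(seq_len(w), function(i) {
    if (inside[i]) bundles[[idx[i] + 1L]] else zero_bundle(embed_dim)
  })
  chars <- rep("-", w)
  chars[inside] <- strsplit(residues, "")[[1L]][idx[inside] + 1L]
  structure(list(
    protein_id      = protein_id,
    center          = as.integer(center),
    window_bundles  = window_bundles,
    pad_mask        = as.integer(inside),
    label           = if (!is.null(labels)) as.integer(labels[center + 1L]) else NA_integer_,
    window_residues = paste(chars, collapse = "")
  ), class = "han_fragment")
}

#' @export
print.han_fragment <- function(x, ...) {
  cat("<han_fragment> ", x$protein_id, " center=", x$center,
      " window=", x$window_residues, " label=", x$label, "\n", sep = "")
  invisible(x)
}

#' K-mer chunk sizes for a window
#'
#' @param w Window length.
#' @param k K-mer size.
#' @return Integer vector of chunk sizes: all `k` except a possibly shorter
#'   final chunk.
#' @export
kmer_sizes <- function(w, k) {
  w <- as.integer(w); k <- as.integer(k)
  if (k < 1L || k > w) stop("k must lie in 1..w, got k=", k, ", w=", w, call. = FALSE)
  n_full <- w %/% k
  rem <- w %% k
  sizes <- rep(k, n_full)
  if (rem > 0L) sizes <- c(sizes, rem)
  sizes
}

#' Segment a fragment's window into K-mers
#'
#' Chunks are consecutive and non-overlapping; all have length `k` except a
#' possibly shorter final chunk. Their concatenation reproduces the window.
#'
#' @param fragment A `han_fragment` from [extract_window()].
#' @param k K-mer size (default 3).
#' @return An object of class `kmer_segmentation` with fields `k`, `sizes`,
#'   `indices` (1-based window positions per K-mer) and `kmers` (residue
#'   substrings, pads shown as `-`).
#' @export
segment_kmers <- function(fragment, k = 3L) {
  stopifnot(inherits(fragment, "han_fragment"))
  w <- length(fragment$pad_mask)
  sizes <- kmer_sizes(w, k)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  indices <- Map(seq.int, starts, ends)
  kmers <- vapply(indices, function(ix) {
    substr(fragment$window_residues, ix[1L], ix[length(ix)])
  }, character(1L))
  structure(list(k = as.integer(k), sizes = sizes,
                 indices = indices, kmers = kmers),
            class = "kmer_segmentation")
}

#' Build a protein-level train/test dataset of fragments
#'
#' Proteins are truncated to `config$max_len`, featurized once each, then
#' shuffled with `config$seed` and split at the protein level: the first
#' `ceiling(split * N)` shuffled proteins form the training partition. Every
#' residue of every truncated protein becomes one fragment.
#'
#' @param records List of labeled [protein_record]s.
#' @param feature_source Source from [synth_feature_source()] or
#'   [file_feature_source()].
#' @param config A [han_config()].
#' @return An object of class `han_dataset` holding per-protein feature
#'   matrices and a fragment table with a `split` column.
#' @export
build_dataset <- function(records, feature_source, config = han_config()) {
  stopifnot(length(records) > 0L)
  no_labels <- vapply(records, function(r) is.null(r$labels), logical(1L))
  if (any(no_labels)) {
    stop("record(s) without labels: ",
         paste(vapply(records[no_labels], `[[`, "", "id"), collapse = ", "),
         call. = FALSE)
  }
  records <- lapply(records, truncate_record, max_len = config$max_len)
  n <- length(records)
  order_idx <- with_rng_seed(config$seed, sample.int(n))
  n_train <- ceiling(config$split * n)
  train_idx <- sort(order_idx[seq_len(n_train)])
  test_idx <- sort(setdiff(seq_len(n), train_idx))

  feats <- lapply(records, function(r) {
    bind_blocks(featurize(feature_source, r), config$blocks)
  })

  frag_tabs <- lapply(seq_len(n), function(i) {
    L <- nchar(records[[i]]$sequence)
    data.frame(protein = i, center = seq_len(L) - 1L,
               label = records[[i]]$labels)
  })
  fragments <- do.call(rbind, frag_tabs)
  fragments$split <- ifelse(fragments$protein %in% train_idx, "train", "test")

  structure(list(
    records = records,
    features = feats,
    fragments = fragments,
    train_proteins = train_idx,
    test_proteins = test_idx,
    config = config,
    seed = config$seed
  ), class = "han_dataset")
}

#' @export
print.han_dataset <- function(x, ...) {
  cat("<han_dataset> ", length(x$records), " proteins (",
      length(x$train_proteins), " train / ", length(x$test_proteins),
      " test), ", nrow(x$fragments), " fragments, ",
      sum(x$fragments$label), " positive\n", sep = "")
  invisible(x)
}

# Window matrices (fixed part, embedding part, pad mask) for one fragment
# of a dataset; used by the R reference forward pass and `explain`.
fragment_matrices <- function(dataset, protein, center) {
  f <- dataset$features[[protein]]
  L <- nrow(f$fixed)
  w <- dataset$config$w
  half <- (w - 1L) %/% 2L
  idx <- (center - half):(center + half)
  inside <- idx >= 0L & idx < L
  fixed <- matrix(0, nrow = w, ncol = ncol(f$fixed))
  fixed[inside, ] <- f$fixed[idx[inside] + 1L, , drop = FALSE]
  emb <- NULL
  if (!is.null(f$emb)) {
    emb <- matrix(0, nrow = w, ncol = ncol(f$emb))
    emb[inside, ] <- f$emb[idx[inside] + 1L, , drop = FALSE]
  }
  list(fixed = fixed, emb = emb, mask = as.integer(inside))
}
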