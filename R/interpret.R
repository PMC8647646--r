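# Interpretability: extract the two-level attention distributions the
# model produced for a chosen residue and export them as TSV (optionally
# rendered as bar charts mirroring the K-mer / residue attention plots).

#' Attention report for one residue
#'
#' Runs a forward pass on the window centred at `position` and repackages
#' the attention trace with residue annotations: which K-mers the window
#' splits into, how much K-mer-level attention each receives, and how the
#' residue-level attention distributes inside each K-mer.
#'
#' @param model A `han_model` (or `han_params`).
#' @param record A [protein_record].
#' @param feature_source Feature source used to featurize the protein.
#' @param position 1-based residue position (within the truncated protein).
#' @return An object of class `attention_report` with fields `protein_id`,
#'   `position`, `target_residue`, `window`, `kmers`, `kmer_weights`,
#'   `residue_weights` and `p_site`.
#' @export
explain_attention <- function(model, record, feature_source, position) {
  params <- if (inherits(model, "han_model")) model$params else model
  stopifnot(inherits(params, "han_params"))
  cfg <- params$config
  record <- truncate_record(record, cfg$max_len)
  L <- nchar(record$sequence)
  if (position < 1L || position > L) {
    stop("position ", position, " out of range 1..", L,
         " (after truncation)", call. = FALSE)
  }
  feats <- bind_blocks(featurize(feature_source, record), cfg$blocks)
  pseudo <- structure(list(records = list(record), features = list(feats),
                           config = cfg), class = "han_dataset")
  center <- position - 1L
  fm <- fragment_matrices(pseudo, 1L, center)
  out <- cpp_han_batch(params$theta, shapes_for_cpp(params$shapes),
                       cfg_for_cpp(params), list(fm$fixed),
                       list(if (is.null(fm$emb)) matrix(0, 0, 0) else fm$emb),
                       list(fm$mask), -1L, FALSE, TRUE)
  half <- (cfg$w - 1L) %/% 2L
  idx <- (center - half):(center + half)
  chars <- rep("-", cfg$w)
  inside <- idx >= 0L & idx < L
  chars[inside] <- strsplit(record$sequence, "")[[1L]][idx[inside] + 1L]
  window <- paste(chars, collapse = "")
  sizes <- kmer_sizes(cfg$w, cfg$k)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  kmers <- vapply(seq_along(sizes), function(j) {
    substr(window, starts[j], ends[j])
  }, character(1L))
  trace <- out$traces[[1L]]
  structure(list(
    protein_id = record$id,
    position = as.integer(position),
    target_residue = substr(record$sequence, position, position),
    window = window,
    kmers = kmers,
    kmer_weights = as.numeric(trace$kmer_weights),
    residue_weights = lapply(trace$residue_weights, as.numeric),
    p_site = out$probs[1L, 2L]
  ), class = "attention_report")
}

#' @export
print.attention_report <- function(x, ...) {
  cat("<attention_report> ", x$protein_id, " position ", x$position,
      " (", x$target_residue, "), window ", x$window,
      sprintf(", p(site) = %.3f\n", x$p_site), sep = "")
  for (j in seq_along(x$kmers)) {
    cat(sprintf("  K-mer %d %-8s weight %.4f | residues: %s\n",
                j, paste0("'", x$kmers[j], "'"), x$kmer_weights[j],
                paste(sprintf("%.4f", x$residue_weights[[j]]),
                      collapse = " ")))
  }
  invisible(x)
}

#' Mean K-mer-level attention over a dataset partition
#'
#' Averages the K-mer-level attention distribution over fragments,
#' optionally restricted to positive (site) fragments — the population
#' version of the single-sample attention bar plots. For motif-planted
#' synthetic data the central (motif-bearing) K-mer is expected to
#' dominate.
#'
#' @param model A `han_model` (or `han_params`).
#' @param dataset A `han_dataset`.
#' @param partition `"test"` (default) or `"train"`.
#' @param which `"positive"` (default), `"negative"` or `"all"` fragments.
#' @return List with `kmer_weights` (mean weight per K-mer slot),
#'   `residue_weights` (mean residue-level weight per window position,
#'   averaged within the K-mer it belongs to) and `n` fragments used.
#' @export
mean_attention <- function(model, dataset, partition = "test",
                           which = c("positive", "negative", "all")) {
  which <- match.arg(which)
  params <- if (inherits(model, "han_model")) model$params else model
  stopifnot(inherits(params, "han_params"), inherits(dataset, "han_dataset"))
  tab <- dataset$fragments[dataset$fragments$split == partition, , drop = FALSE]
  if (which == "positive") tab <- tab[tab$label == 1L, , drop = FALSE]
  if (which == "negative") tab <- tab[tab$label == 0L, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no fragments selected", call. = FALSE)
  shp <- shapes_for_cpp(params$shapes)
  ccfg <- cfg_for_cpp(params)
  cfg <- params$config
  sizes <- kmer_sizes(cfg$w, cfg$k)
  m <- length(sizes)
  ksum <- numeric(m)
  rsum <- numeric(cfg$w)
  csum <- numeric(cfg$w)
  n <- nrow(tab)
  chunk <- 256L
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n)
    wnd <- slice_windows(dataset, tab[sel, , drop = FALSE])
    out <- cpp_han_batch(params$theta, shp, ccfg, wnd$fixed, wnd$emb,
                         wnd$mask, rep(-1L, length(sel)), FALSE, TRUE)
    for (tr in out$traces) {
      kw <- as.numeric(tr$kmer_weights)
      rw <- unlist(lapply(tr$residue_weights, as.numeric))
      ksum <- ksum + kw
      rsum <- rsum + rw
      csum <- csum + rep(kw, sizes) * rw  # joint weight over window positions
    }
  }
  list(kmer_weights = ksum / n, residue_weights = rsum / n,
       combined_weights = csum / n, n = n)
}

#' Export an attention report as TSV
#'
#' One data row per attention unit: the K-mer-level weights first, then
#' each K-mer's residue-level weights. Columns: `level` ("kmer" or
#' "residue"), `kmer_index`, `window_position` (NA for K-mer rows), `unit`
#' (the K-mer string or residue character) and `weight`.
#'
#' @param report An `attention_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_attention <- function(report, path) {
  stopifnot(inherits(report, "attention_report"))
  rows <- list()
  for (j in seq_along(report$kmers)) {
    rows[[length(rows) + 1L]] <- data.frame(
      level = "kmer", kmer_index = j, window_position = NA_integer_,
      unit = report$kmers[j], weight = report$kmer_weights[j])
  }
  pos <- 0L
  for (j in seq_along(report$residue_weights)) {
    wts <- report$residue_weights[[j]]
    for (t in seq_along(wts)) {
      pos <- pos + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        level = "residue", kmer_index = j, window_position = pos,
        unit = substr(report$window, pos, pos), weight = wts[t])
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(level = character(0), kmer_index = integer(0),
               window_position = integer(0), unit = character(0),
               weight = numeric(0))
  }
  tab$weight <- sprintf("%.6f", tab$weight)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
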