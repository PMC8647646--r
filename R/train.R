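# Training loop: seeded mini-batches of window fragments, class-weighted
# cross-entropy, Adam updates, per-epoch validation F1 with best-model
# selection and optional early stopping.

# Window matrices for a set of fragment-table rows, ready for the
# compiled backend.
slice_windows <- function(dataset, rows) {
  n <- nrow(rows)
  fixed <- vector("list", n)
  emb <- vector("list", n)
  msk <- vector("list", n)
  empty <- matrix(0, 0L, 0L)
  for (i in seq_len(n)) {
    fm <- fragment_matrices(dataset, rows$protein[i], rows$center[i])
    fixed[[i]] <- fm$fixed
    emb[[i]] <- if (is.null(fm$emb)) empty else fm$emb
    msk[[i]] <- fm$mask
  }
  list(fixed = fixed, emb = emb, mask = msk)
}

# Forward pass over fragment-table rows; returns site probabilities.
forward_rows <- function(dataset, rows, params, chunk = 512L) {
  shp <- shapes_for_cpp(params$shapes)
  cfg <- cfg_for_cpp(params)
  n <- nrow(rows)
  p_site <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n)
    wnd <- slice_windows(dataset, rows[sel, , drop = FALSE])
    out <- cpp_han_batch(params$theta, shp, cfg, wnd$fixed, wnd$emb,
                         wnd$mask, rep(-1L, length(sel)), FALSE, FALSE)
    p_site[sel] <- out$probs[, 2L]
  }
  p_site
}

#' Train the hierarchical attention network
#'
#' Initializes parameters from the seeded Glorot scheme, then iterates
#' seeded shuffled mini-batches of the training fragments, applying the
#' class-weighted cross-entropy loss and Adam updates. A protein-level
#' slice of the training partition (fraction `config$val_fraction`) is
#' held out for validation; the parameters with the best validation F1
#' are returned. Training stops early after `config$patience` epochs
#' without improvement.
#'
#' @param dataset A `han_dataset` from [build_dataset()].
#' @param config A [han_config()] (defaults to the dataset's own).
#' @param quiet Suppress per-epoch progress messages.
#' @return An object of class `han_model`: list with `params` (best),
#'   `final_params`, `history` (data frame of epoch, train_loss, val_f1)
#'   and `config`.
#' @export
han_train <- function(dataset, config = dataset$config, quiet = TRUE) {
  stopifnot(inherits(dataset, "han_dataset"))
  train_tab <- dataset$fragments[dataset$fragments$split == "train", , drop = FALSE]
  if (nrow(train_tab) == 0L) stop("training partition is empty", call. = FALSE)

  # Protein-level validation carve-out from the training partition.
  tp <- dataset$train_proteins
  n_val <- floor(config$val_fraction * length(tp))
  val_prot <- if (n_val >= 1L && length(tp) > n_val) {
    with_rng_seed(config$seed + 1L, sample(tp, n_val))
  } else integer(0)
  fit_tab <- train_tab[!(train_tab$protein %in% val_prot), , drop = FALSE]
  val_tab <- train_tab[train_tab$protein %in% val_prot, , drop = FALSE]
  if (nrow(fit_tab) == 0L) {  # degenerate: too few proteins to carve out
    fit_tab <- train_tab
    val_tab <- train_tab
  }
  if (nrow(val_tab) == 0L) val_tab <- fit_tab

  params <- han_init(config)
  shp <- shapes_for_cpp(params$shapes)
  ccfg <- cfg_for_cpp(params)
  state <- adam_init(length(params$theta))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_f1 = numeric(0))
  if (config$epochs == 0L) {
    return(structure(list(params = params, final_params = params,
                          history = history, config = config),
                     class = "han_model"))
  }

  best_theta <- params$theta
  best_f1 <- -Inf
  stale <- 0L
  n_fit <- nrow(fit_tab)
  theta <- params$theta

  for (epoch in seq_len(config$epochs)) {
    ord <- with_rng_seed(config$seed + 1000L + epoch, sample.int(n_fit))
    loss_sum <- 0
    loss_n <- 0L
    for (start in seq(1L, n_fit, by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1L, n_fit)]
      rows <- fit_tab[sel, , drop = FALSE]
      wnd <- slice_windows(dataset, rows)
      out <- cpp_han_batch(theta, shp, ccfg, wnd$fixed, wnd$emb, wnd$mask,
                           as.integer(rows$label), TRUE, FALSE)
      nb <- out$n_labeled
      step <- adam_step(theta, out$grad / nb, state,
                        alpha = config$lr, beta1 = config$beta1,
                        beta2 = config$beta2, eps = config$eps)
      theta <- step$theta
      state <- step$state
      loss_sum <- loss_sum + out$loss_sum
      loss_n <- loss_n + nb
    }
    params$theta <- theta
    val_p <- forward_rows(dataset, val_tab, params)
    val_m <- classification_metrics(
      confusion_counts(val_tab$label, val_p, config$threshold), quiet = TRUE)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = loss_sum / loss_n, val_f1 = val_m$f1))
    if (!quiet) {
      message(sprintf("epoch %d: train loss %.4f, val F1 %.4f",
                      epoch, loss_sum / loss_n, val_m$f1))
    }
    if (val_m$f1 > best_f1 + 1e-12) {
      best_f1 <- val_m$f1
      best_theta <- theta
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (is.finite(config$patience) && stale >= config$patience) break
    }
  }

  best <- params
  best$theta <- best_theta
  final <- params
  final$theta <- theta
  structure(list(params = best, final_params = final, history = history,
                 config = config),
            class = "han_model")
}

#' @export
print.han_model <- function(x, ...) {
  cat("<han_model> trained ", nrow(x$history), " epoch(s); best val F1 ",
      if (nrow(x$history)) sprintf("%.4f", max(x$history$val_f1)) else "NA",
      "\n", sep = "")
  invisible(x)
}

#' Predict site probabilities for every residue of a protein
#'
#' The record is truncated to `config$max_len`, featurized with the given
#' source, and one forward pass is run per residue.
#'
#' @param model A `han_model` from [han_train()] (or a bare `han_params`).
#' @param record A [protein_record].
#' @param feature_source Source from [synth_feature_source()] or
#'   [file_feature_source()].
#' @return Numeric vector of site probabilities, one per (truncated)
#'   residue.
#' @export
predict_sites <- function(model, record, feature_source) {
  params <- if (inherits(model, "han_model")) model$params else model
  stopifnot(inherits(params, "han_params"))
  cfg <- params$config
  if (nchar(record$sequence) == 0L) stop("empty sequence", call. = FALSE)
  record <- truncate_record(record, cfg$max_len)
  L <- nchar(record$sequence)
  feats <- bind_blocks(featurize(feature_source, record), cfg$blocks)
  pseudo <- structure(list(
    records = list(record), features = list(feats),
    config = cfg
  ), class = "han_dataset")
  rows <- data.frame(protein = 1L, center = seq_len(L) - 1L)
  forward_rows(pseudo, rows, params)
}

#' Save a trained model as a JSON checkpoint
#'
#' The checkpoint is a versioned plain-text archive: configuration, the
#' parameter shape table and the flat parameter vector at full precision.
#'
#' @param model A `han_model`.
#' @param path Output path.
#' @export
save_han_model <- function(model, path) {
  stopifnot(inherits(model, "han_model"))
  payload <- list(
    format = "hanppis-checkpoint",
    version = 1L,
    config = unclass(model$config),
    shapes = model$params$shapes,
    theta = model$params$theta,
    history = model$history
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_han_model()]
#' @param path Checkpoint path.
#' @return A `han_model`.
#' @export
load_han_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "hanppis-checkpoint")) {
    stop("not a hanppis checkpoint: ", path, call. = FALSE)
  }
  config <- do.call(han_config, payload$config[
    setdiff(names(payload$config), character(0))])
  params <- structure(list(theta = as.numeric(payload$theta),
                           shapes = as.data.frame(payload$shapes),
                           config = config),
                      class = "han_params")
  expected <- han_param_shapes(config)
  if (!isTRUE(all.equal(expected[c("name", "nrow", "ncol", "offset")],
                        params$shapes[c("name", "nrow", "ncol", "offset")],
                        check.attributes = FALSE))) {
    stop("checkpoint shape table does not match its configuration",
         call. = FALSE)
  }
  history <- if (!is.null(payload$history) && length(payload$history)) {
    as.data.frame(payload$history)
  } else {
    data.frame(epoch = integer(0), train_loss = numeric(0), val_f1 = numeric(0))
  }
  structure(list(params = params, final_params = params,
                 history = history, config = config),
            class = "han_model")
}
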