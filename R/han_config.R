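#' Model and training configuration
#'
#' Collects every tunable of the hierarchical attention model and its
#' training loop. Defaults reproduce the published setting: window length
#' 7, maximum protein length 500, batch size 3, 86 hidden units in both
#' Bi-GRU levels, a 50-unit embedding projection, and a positive-class
#' sample weight of 7.
#'
#' @param w Odd sliding-window length.
#' @param k K-mer size for segmenting windows (non-overlapping chunks).
#' @param max_len Proteins longer than this are truncated.
#' @param batch_size Mini-batch size.
#' @param hidden Hidden units per GRU direction at both levels.
#' @param proj Output width of the embedding projection layer.
#' @param attn Width of both attention projections.
#' @param embed_dim Raw embedding dimension coming from the provider.
#' @param blocks Feature blocks to include (subset of
#'   `c("one_hot","pssm","ss9","hydropathy","rel_pos","embedding")`).
#' @param pos_weight Loss weight on positive (site) samples.
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation-F1
#'   improvement); `Inf` disables early stopping.
#' @param val_fraction Fraction of training proteins held out for
#'   validation-based model selection.
#' @param split Train fraction of the protein-level train/test split.
#' @param threshold Probability threshold for calling a residue a site.
#' @param seed Seed controlling the split, initialization and batching.
#' @param clip Probability clipping bound keeping the log-loss finite.
#' @param cell Recurrent cell type; only `"gru"` is implemented.
#' @return An object of class `han_config`.
#' @export
han_config <- function(w = 7L, k = 3L, max_len = 500L, batch_size = 3L,
                       hidden = 86L, proj = 50L, attn = 50L,
                       embed_dim = 1024L, blocks = BLOCK_NAMES,
                       pos_weight = 7, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, epochs = 10L,
                       patience = 3L, val_fraction = 0.1, split = 0.8,
                       threshold = 0.5, seed = 42L, clip = 1e-7,
                       cell = "gru") {
  w <- as.integer(w); k <- as.integer(k)
  if (w < 1L || w %% 2L == 0L) stop("w must be a positive odd integer", call. = FALSE)
  if (k < 1L || k > w) stop("k must lie in 1..w", call. = FALSE)
  if (!identical(cell, "gru")) {
    stop("only the GRU recurrent cell is implemented (cell = \"gru\")",
         call. = FALSE)
  }
  unknown <- setdiff(blocks, BLOCK_NAMES)
  if (length(unknown) > 0L) {
    stop("unknown feature block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c("max_len", "batch_size", "hidden", "proj", "attn",
               "embed_dim", "pos_weight", "lr", "beta1", "beta2", "eps",
               "epochs", "val_fraction", "split", "threshold", "clip")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      stop(nm, " must be a non-negative scalar", call. = FALSE)
    }
  }
  if (split <= 0 || split > 1) stop("split must lie in (0, 1]", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)", call. = FALSE)
  structure(list(
    w = w, k = k, max_len = as.integer(max_len),
    batch_size = as.integer(batch_size), hidden = as.integer(hidden),
    proj = as.integer(proj), attn = as.integer(attn),
    embed_dim = as.integer(embed_dim), blocks = blocks,
    pos_weight = pos_weight, lr = lr, beta1 = beta1, beta2 = beta2,
    eps = eps, epochs = as.integer(epochs), patience = patience,
    val_fraction = val_fraction, split = split, threshold = threshold,
    seed = as.integer(seed), clip = clip, cell = cell
  ), class = "han_config")
}

#' @export
print.han_config <- function(x, ...) {
  cat("<han_config> w=", x$w, " k=", x$k, " max_len=", x$max_len,
      " batch=", x$batch_size, " hidden=", x$hidden, " proj=", x$proj,
      " pos_weight=", x$pos_weight, " epochs=", x$epochs,
      " seed=", x$seed, "\n  blocks: ", paste(x$blocks, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a configuration to a YAML file
#' @param config A [han_config()].
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "han_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration from a YAML file
#' @param path Path written by [write_config()].
#' @return A [han_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(han_config, vals)
}

# Input width of the level-1 GRU: fixed blocks plus the projected embedding.
fused_dim <- function(config) {
  fixed_width(config$blocks) +
    if ("embedding" %in% config$blocks) config$proj else 0L
}

#' Parameter shape table
#'
#' Lays out every trainable tensor of the model in a fixed order inside one
#' flat parameter vector: embedding projection (when the embedding block is
#' used), the forward and backward GRU gate weights of both levels, both
#' attention heads, and the softmax output layer.
#'
#' @param config A [han_config()].
#' @return Data frame with columns `name`, `nrow`, `ncol`, `offset`
#'   (0-based position in the flat vector).
#' @export
han_param_shapes <- function(config) {
  u <- config$hidden; a <- config$attn; P <- config$proj
  use_emb <- "embedding" %in% config$blocks
  din1 <- fused_dim(config)
  din2 <- 2L * u
  rows <- list()
  add <- function(name, nr, nc) {
    rows[[length(rows) + 1L]] <<- data.frame(name = name, nrow = nr, ncol = nc)
  }
  if (use_emb) {
    add("W_proj", P, config$embed_dim)
    add("b_proj", P, 1L)
  }
  for (lvl in 1:2) {
    din <- if (lvl == 1L) din1 else din2
    for (dir in c("f", "b")) {
      for (g in c("z", "r", "h")) {
        tag <- paste0(g, lvl, dir)
        add(paste0("W_", tag), u, din)
        add(paste0("U_", tag), u, u)
        add(paste0("b_", tag), u, 1L)
      }
    }
    add(paste0("W_a", lvl), a, 2L * u)
    add(paste0("b_a", lvl), a, 1L)
    add(paste0("u_ctx", lvl), a, 1L)
  }
  add("W_out", 2L, 2L * u)
  add("b_out", 2L, 1L)
  tab <- do.call(rbind, rows)
  sizes <- tab$nrow * tab$ncol
  tab$offset <- cumsum(c(0L, sizes[-length(sizes)]))
  tab
}

#' Initialize model parameters
#'
#' Weight matrices get seeded Glorot-style uniform draws on
#' `[-sqrt(6/(fan_in+fan_out)), +sqrt(6/(fan_in+fan_out))]`; biases start
#' at zero; attention context vectors are drawn like a width-1 weight.
#'
#' @param config A [han_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return An object of class `han_params` holding the flat parameter
#'   vector, the shape table and the configuration.
#' @export
han_init <- function(config = han_config(), seed = config$seed) {
  shapes <- han_param_shapes(config)
  total <- sum(shapes$nrow * shapes$ncol)
  theta <- numeric(total)
  with_rng_seed(seed, {
    for (i in seq_len(nrow(shapes))) {
      nr <- shapes$nrow[i]; nc <- shapes$ncol[i]
      n <- nr * nc
      span <- shapes$offset[i] + seq_len(n)
      if (startsWith(shapes$name[i], "b_")) {
        theta[span] <- 0
      } else {
        lim <- sqrt(6 / (nr + nc))
        theta[span] <- stats::runif(n, -lim, lim)
      }
    }
  })
  structure(list(theta = theta, shapes = shapes, config = config),
            class = "han_params")
}

#' @export
print.han_params <- function(x, ...) {
  cat("<han_params> ", length(x$theta), " parameters in ",
      nrow(x$shapes), " tensors (hidden=", x$config$hidden,
      ", proj=", x$config$proj, ")\n", sep = "")
  invisible(x)
}

#' Unpack the flat parameter vector into named matrices
#' @param params A `han_params` object.
#' @return Named list of numeric matrices.
#' @export
han_unflatten <- function(params) {
  stopifnot(inherits(params, "han_params"))
  sh <- params$shapes
  out <- vector("list", nrow(sh))
  names(out) <- sh$name
  for (i in seq_len(nrow(sh))) {
    n <- sh$nrow[i] * sh$ncol[i]
    out[[i]] <- matrix(params$theta[sh$offset[i] + seq_len(n)],
                       nrow = sh$nrow[i], ncol = sh$ncol[i])
  }
  out
}

#' Pack named matrices back into a flat parameter vector
#' @param mats Named list as produced by [han_unflatten()].
#' @param shapes Shape table from [han_param_shapes()].
#' @return Numeric vector.
#' @export
han_flatten <- function(mats, shapes) {
  theta <- numeric(sum(shapes$nrow * shapes$ncol))
  for (i in seq_len(nrow(shapes))) {
    m <- mats[[shapes$name[i]]]
    stopifnot(nrow(m) == shapes$nrow[i], ncol(m) == shapes$ncol[i])
    theta[shapes$offset[i] + seq_len(length(m))] <- as.numeric(m)
  }
  theta
}
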