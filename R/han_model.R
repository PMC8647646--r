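# The hierarchical attention network. The documented functions below are
# the reference (pure R) implementations of each layer; training and batch
# prediction run the same computation through the compiled backend (see
# src/), and the two paths are cross-checked against each other in the
# test suite.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Project a raw embedding vector to the fused width
#'
#' A trained affine map followed by a rectifier, reducing the
#' provider-dimensional embedding (default 1024) to `proj` dimensions
#' (default 50) before fusion with the other five blocks.
#'
#' @param e Raw embedding vector of length E.
#' @param W_proj P x E weight matrix.
#' @param b_proj Length-P bias.
#' @return Length-P numeric vector.
#' @export
project_embedding <- function(e, W_proj, b_proj) {
  if (ncol(W_proj) != length(e)) {
    stop("W_proj has ", ncol(W_proj), " columns but the embedding has length ",
         length(e), call. = FALSE)
  }
  relu(as.numeric(W_proj %*% e + b_proj))
}

#' Fuse a residue feature bundle into the model input vector
#'
#' Concatenates the blocks in fixed order (one-hot, PSSM, secondary
#' structure, hydropathy, relative position, projected embedding). With
#' every block present and the default 50-unit projection the fused vector
#' has 20+20+9+1+1+50 = 101 dimensions.
#'
#' @param bundle A `residue_feature_bundle` from [assemble_bundles()].
#' @param params A `han_params` object (supplies the projection weights).
#' @return Numeric vector of length `fixed_width(blocks) + proj`.
#' @export
fuse <- function(bundle, params) {
  stopifnot(inherits(bundle, "residue_feature_bundle"),
            inherits(params, "han_params"))
  blocks <- params$config$blocks
  fixed_names <- intersect(names(FIXED_BLOCK_WIDTHS), blocks)
  parts <- lapply(fixed_names, function(b) as.numeric(bundle[[b]]))
  if ("embedding" %in% blocks) {
    mats <- han_unflatten(params)
    parts <- c(parts, list(project_embedding(bundle$embedding,
                                             mats$W_proj,
                                             as.numeric(mats$b_proj))))
  }
  unlist(parts, use.names = FALSE)
}

# Single-direction GRU over the rows of X; masked rows copy the previous
# hidden state. Gate params: list(Wz, Uz, bz, Wr, Ur, br, Wh, Uh, bh).
gru_run <- function(X, p, mask) {
  T_ <- nrow(X)
  u <- nrow(p$Wz)
  H <- matrix(0, nrow = T_, ncol = u)
  h <- numeric(u)
  for (t in seq_len(T_)) {
    if (mask[t] == 0L) {
      H[t, ] <- h
      next
    }
    x <- X[t, ]
    z <- sigmoid(as.numeric(p$Wz %*% x + p$Uz %*% h + p$bz))
    r <- sigmoid(as.numeric(p$Wr %*% x + p$Ur %*% h + p$br))
    hc <- tanh(as.numeric(p$Wh %*% x + p$Uh %*% (r * h) + p$bh))
    h <- (1 - z) * h + z * hc
    H[t, ] <- h
  }
  H
}

#' Bidirectional GRU encoding
#'
#' Runs the standard GRU recurrence (update gate `z`, reset gate `r`,
#' candidate state `tanh`) over the rows of `X` in both directions and
#' concatenates the per-position hidden states. Masked positions carry the
#' previous hidden state through unchanged.
#'
#' @param X T x d input matrix (rows are positions).
#' @param gru_params List with elements `fwd` and `bwd`, each a list of
#'   gate weights `Wz, Uz, bz, Wr, Ur, br, Wh, Uh, bh`.
#' @param mask Optional 0/1 vector of length T (default all 1).
#' @return T x 2u matrix `[forward | backward]`.
#' @export
bigru_encode <- function(X, gru_params, mask = NULL) {
  X <- as.matrix(X)
  T_ <- nrow(X)
  stopifnot(T_ >= 1L)
  if (is.null(mask)) mask <- rep(1L, T_)
  stopifnot(length(mask) == T_)
  Hf <- gru_run(X, gru_params$fwd, mask)
  rev_idx <- rev(seq_len(T_))
  Hb <- gru_run(X[rev_idx, , drop = FALSE], gru_params$bwd, mask[rev_idx])
  cbind(Hf, Hb[rev_idx, , drop = FALSE])
}

#' Attention pooling over encoder states
#'
#' Scores each row of `H` against a learned context vector through a tanh
#' projection (`s_t = u_ctx' tanh(W_a h_t + b_a)`), masks padded positions
#' to `-Inf`, applies a softmax, and returns the weighted sum of the rows
#' together with the weights.
#'
#' @param H T x d matrix of encoder states.
#' @param W_a a x d attention projection.
#' @param b_a Length-a bias.
#' @param u_ctx Length-a context vector.
#' @param mask Optional 0/1 vector of length T; at least one position must
#'   be unmasked.
#' @return List with `v` (length-d pooled vector) and `alpha` (length-T
#'   weights summing to 1, padded positions exactly 0).
#' @export
attention_pool <- function(H, W_a, b_a, u_ctx, mask = NULL) {
  H <- as.matrix(H)
  T_ <- nrow(H)
  stopifnot(T_ >= 1L)
  if (is.null(mask)) mask <- rep(1L, T_)
  if (all(mask == 0L)) stop("attention_pool: all positions are masked", call. = FALSE)
  s <- vapply(seq_len(T_), function(t) {
    sum(u_ctx * tanh(as.numeric(W_a %*% H[t, ] + b_a)))
  }, numeric(1L))
  s[mask == 0L] <- -Inf
  alpha <- softmax(s)
  alpha[mask == 0L] <- 0  # exact zeros for pads
  v <- as.numeric(crossprod(H, alpha))
  list(v = v, alpha = alpha)
}

# Assemble level-specific GRU parameter lists from the unflattened tensors.
gru_level_params <- function(mats, level) {
  pick <- function(dir) {
    list(Wz = mats[[paste0("W_z", level, dir)]],
         Uz = mats[[paste0("U_z", level, dir)]],
         bz = as.numeric(mats[[paste0("b_z", level, dir)]]),
         Wr = mats[[paste0("W_r", level, dir)]],
         Ur = mats[[paste0("U_r", level, dir)]],
         br = as.numeric(mats[[paste0("b_r", level, dir)]]),
         Wh = mats[[paste0("W_h", level, dir)]],
         Uh = mats[[paste0("U_h", level, dir)]],
         bh = as.numeric(mats[[paste0("b_h", level, dir)]]))
  }
  list(fwd = pick("f"), bwd = pick("b"))
}

# Window matrices (fixed, embedding, mask) from a standalone han_fragment.
fragment_to_matrices <- function(fragment, blocks) {
  w <- length(fragment$pad_mask)
  fixed_names <- intersect(names(FIXED_BLOCK_WIDTHS), blocks)
  fixed <- do.call(rbind, lapply(fragment$window_bundles, function(b) {
    unlist(lapply(fixed_names, function(nm) as.numeric(b[[nm]])),
           use.names = FALSE)
  }))
  if (is.null(fixed)) fixed <- matrix(0, w, 0L)
  emb <- if ("embedding" %in% blocks) {
    do.call(rbind, lapply(fragment$window_bundles,
                          function(b) as.numeric(b$embedding)))
  } else NULL
  list(fixed = fixed, emb = emb, mask = fragment$pad_mask)
}

# Pure-R reference forward pass over window matrices. Returns the class
# probabilities and the two-level attention trace. The compiled backend
# implements the identical computation; tests assert their agreement.
han_forward_ref <- function(fixed, emb, mask, params) {
  cfg <- params$config
  mats <- han_unflatten(params)
  w <- nrow(fixed)
  use_emb <- "embedding" %in% cfg$blocks
  din <- fused_dim(cfg)
  X <- matrix(0, nrow = w, ncol = din)
  for (t in seq_len(w)) {
    if (mask[t] == 0L) next
    row <- as.numeric(fixed[t, ])
    if (use_emb) {
      row <- c(row, project_embedding(emb[t, ], mats$W_proj,
                                      as.numeric(mats$b_proj)))
    }
    X[t, ] <- row
  }
  sizes <- kmer_sizes(w, cfg$k)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  g1 <- gru_level_params(mats, 1L)
  g2 <- gru_level_params(mats, 2L)
  m <- length(sizes)
  V <- matrix(0, nrow = m, ncol = 2L * cfg$hidden)
  kmer_mask <- integer(m)
  residue_weights <- vector("list", m)
  for (j in seq_len(m)) {
    ix <- starts[j]:ends[j]
    sub_mask <- mask[ix]
    if (all(sub_mask == 0L)) {
      residue_weights[[j]] <- numeric(length(ix))
      next
    }
    kmer_mask[j] <- 1L
    Hj <- bigru_encode(X[ix, , drop = FALSE], g1, sub_mask)
    pooled <- attention_pool(Hj, mats$W_a1, as.numeric(mats$b_a1),
                             as.numeric(mats$u_ctx1), sub_mask)
    V[j, ] <- pooled$v
    residue_weights[[j]] <- pooled$alpha
  }
  G <- bigru_encode(V, g2, kmer_mask)
  pooled2 <- attention_pool(G, mats$W_a2, as.numeric(mats$b_a2),
                            as.numeric(mats$u_ctx2), kmer_mask)
  logits <- as.numeric(mats$W_out %*% pooled2$v + as.numeric(mats$b_out))
  p <- softmax(logits)
  list(p = p,
       trace = list(kmer_weights = pooled2$alpha,
                    residue_weights = residue_weights))
}

#' Forward pass of the hierarchical attention network
#'
#' Fuses the window's residue features, encodes each K-mer with the
#' residue-level Bi-GRU and attention pooling, encodes the resulting K-mer
#' vectors with the K-mer-level Bi-GRU and attention pooling, and maps the
#' pooled fragment vector through an affine layer and softmax. K-mers made
#' entirely of padding are skipped and receive zero attention.
#'
#' @param fragment A `han_fragment` from [extract_window()].
#' @param params A `han_params` object.
#' @return List with `p` (probabilities over non-site/site, summing to 1)
#'   and `trace` (list with `kmer_weights` and per-K-mer
#'   `residue_weights`).
#' @export
han_forward <- function(fragment, params) {
  stopifnot(inherits(fragment, "han_fragment"),
            inherits(params, "han_params"))
  cfg <- params$config
  if (length(fragment$pad_mask) != cfg$w) {
    stop("fragment window length ", length(fragment$pad_mask),
         " does not match config w = ", cfg$w, call. = FALSE)
  }
  m <- fragment_to_matrices(fragment, cfg$blocks)
  out <- cpp_han_batch(params$theta, shapes_for_cpp(params$shapes),
                       cfg_for_cpp(params), list(m$fixed),
                       if (is.null(m$emb)) list(matrix(0, 0, 0)) else list(m$emb),
                       list(m$mask), -1L, FALSE, TRUE)
  list(p = as.numeric(out$probs[1L, ]),
       trace = list(kmer_weights = as.numeric(out$traces[[1L]]$kmer_weights),
                    residue_weights = lapply(out$traces[[1L]]$residue_weights,
                                             as.numeric)))
}

# Marshal shapes/config for the compiled backend.
shapes_for_cpp <- function(shapes) {
  list(name = shapes$name, nrow = as.integer(shapes$nrow),
       ncol = as.integer(shapes$ncol), offset = as.integer(shapes$offset))
}

cfg_for_cpp <- function(params) {
  cfg <- params$config
  use_emb <- "embedding" %in% cfg$blocks
  list(w = cfg$w, k = cfg$k, u = cfg$hidden, a = cfg$attn,
       P = cfg$proj, E = if (use_emb) cfg$embed_dim else 0L,
       d_fixed = as.integer(fixed_width(cfg$blocks)),
       use_emb = use_emb, w_pos = cfg$pos_weight, clip = cfg$clip)
}

#' Class-weighted binary cross-entropy
#'
#' The mean cross-entropy over samples, with positive samples weighted by
#' `w_pos` to counter the roughly 1:5.5 site/non-site imbalance (the
#' published setting weights them about 1:7). With `w_pos = 1` this is the
#' plain unweighted cross-entropy. Probabilities are clipped to
#' `[clip, 1 - clip]` so the loss stays finite.
#'
#' @param y Integer 0/1 labels.
#' @param p_site Predicted site probabilities.
#' @param w_pos Positive-class weight (default 7).
#' @param clip Clipping bound (default 1e-7).
#' @return Scalar loss.
#' @export
weighted_bce_loss <- function(y, p_site, w_pos = 7, clip = 1e-7) {
  if (length(y) != length(p_site)) {
    stop("y and p_site have different lengths", call. = FALSE)
  }
  p <- pmin(pmax(p_site, clip), 1 - clip)
  cw <- ifelse(y == 1L, w_pos, 1)
  -mean(cw * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Initialize Adam optimizer state
#' @param n_params Number of parameters.
#' @return List with zeroed first/second moment vectors and step counter.
#' @export
adam_init <- function(n_params) {
  list(m = numeric(n_params), v = numeric(n_params), t = 0L)
}

#' One Adam update step
#'
#' Exponential moving averages of the gradient and squared gradient with
#' bias correction, then `theta <- theta - alpha * m_hat / (sqrt(v_hat) + eps)`.
#'
#' @param theta Flat parameter vector.
#' @param grad Gradient of the loss at `theta`.
#' @param state Optimizer state from [adam_init()].
#' @param alpha Learning rate.
#' @param beta1,beta2 Moment decay rates.
#' @param eps Numerical-stability constant.
#' @return List with updated `theta` and `state`.
#' @export
adam_step <- function(theta, grad, state, alpha = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  stopifnot(length(theta) == length(grad),
            length(state$m) == length(theta))
  t <- state$t + 1L
  m <- beta1 * state$m + (1 - beta1) * grad
  v <- beta2 * state$v + (1 - beta2) * grad^2
  m_hat <- m / (1 - beta1^t)
  v_hat <- v / (1 - beta2^t)
  theta <- theta - alpha * m_hat / (sqrt(v_hat) + eps)
  list(theta = theta, state = list(m = m, v = v, t = t))
}
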