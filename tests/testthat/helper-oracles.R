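# Independent oracles and small fixture builders shared across tests.

# Tiny network configuration used wherever full-size tensors are not the
# point; keeps the suite fast without changing any model semantics.
tiny_config <- function(...) {
  defaults <- list(hidden = 8L, proj = 4L, attn = 6L, embed_dim = 16L,
                   epochs = 2L, seed = 7L)
  do.call(han_config, utils::modifyList(defaults, list(...)))
}

tiny_corpus <- function(n = 8L, len = 20L, seed = 7L, sigma = 0.2) {
  recs <- generate_proteins(synth_config(n_proteins = n,
                                         len_range = c(len, len),
                                         seed = seed))
  src <- synth_feature_source(sigma = sigma, seed = seed, embed_dim = 16L)
  list(records = recs, source = src)
}

# Independent scalar-loop re-implementation of the class-weighted
# cross-entropy (deliberately different style from the vectorized one).
oracle_bce <- function(y, p, w_pos, clip = 1e-7) {
  total <- 0
  for (i in seq_along(y)) {
    pi <- min(max(p[i], clip), 1 - clip)
    ci <- if (y[i] == 1) w_pos else 1
    total <- total + ci * (y[i] * log(pi) + (1 - y[i]) * log(1 - pi))
  }
  -total / length(y)
}

# Independent per-coordinate Adam implementation (explicit loops, scalar
# state), used to cross-check the vectorized optimizer.
oracle_adam_run <- function(theta0, grads_list, alpha, beta1, beta2, eps) {
  n <- length(theta0)
  theta <- theta0
  m <- numeric(n)
  v <- numeric(n)
  for (t in seq_along(grads_list)) {
    g <- grads_list[[t]]
    for (i in seq_len(n)) {
      m[i] <- beta1 * m[i] + (1 - beta1) * g[i]
      v[i] <- beta2 * v[i] + (1 - beta2) * g[i]^2
      mh <- m[i] / (1 - beta1^t)
      vh <- v[i] / (1 - beta2^t)
      theta[i] <- theta[i] - alpha * mh / (sqrt(vh) + eps)
    }
  }
  theta
}

# Brute-force confusion recount oracle over raw (label, call) pairs.
oracle_confusion <- function(y, calls) {
  tp <- 0; fp <- 0; tn <- 0; fn <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1 && calls[i] == 1) tp <- tp + 1
    else if (y[i] == 0 && calls[i] == 1) fp <- fp + 1
    else if (y[i] == 0 && calls[i] == 0) tn <- tn + 1
    else fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Random window matrices + mask for forward fuzzing (direct backend calls).
random_window <- function(cfg, rng_pad = TRUE) {
  w <- cfg$w
  d_fixed <- sum(c(one_hot = 20L, pssm = 20L, ss9 = 9L, hydropathy = 1L,
                   rel_pos = 1L)[setdiff(cfg$blocks, "embedding")])
  fixed <- matrix(stats::runif(w * d_fixed, -1, 1), nrow = w)
  emb <- if ("embedding" %in% cfg$blocks) {
    matrix(stats::runif(w * cfg$embed_dim, -1, 1), nrow = w)
  } else matrix(0, 0, 0)
  mask <- rep(1L, w)
  if (rng_pad && stats::runif(1) < 0.5) {
    # sequence-boundary style padding: a run of pads at one or both ends
    npad_l <- sample(0:((w - 1L) %/% 2L), 1L)
    npad_r <- sample(0:((w - 1L) %/% 2L), 1L)
    if (npad_l > 0) mask[seq_len(npad_l)] <- 0L
    if (npad_r > 0) mask[w - seq_len(npad_r) + 1L] <- 0L
  }
  fixed[mask == 0L, ] <- 0
  if (length(emb)) emb[mask == 0L, ] <- 0
  list(fixed = fixed, emb = emb, mask = mask)
}

# Direct call into the compiled batch kernel (used by fuzz/gradient tests).
han_batch_raw <- function(params, windows, labels, want_grad = FALSE,
                          want_trace = FALSE) {
  hanppis:::cpp_han_batch(
    params$theta, hanppis:::shapes_for_cpp(params$shapes),
    hanppis:::cfg_for_cpp(params),
    lapply(windows, `[[`, "fixed"), lapply(windows, `[[`, "emb"),
    lapply(windows, `[[`, "mask"), as.integer(labels), want_grad, want_trace)
}
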