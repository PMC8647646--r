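test_that("embedding projection is an affine map with rectifier", {
  e <- c(1, -2, 3, 0.5, -1)
  W0 <- matrix(0, 3, 5)
  expect_equal(project_embedding(e, W0, rep(0, 3)), rep(0, 3))
  cfg <- han_config()
  params <- han_init(cfg, seed = 1L)
  mats <- han_unflatten(params)
  out <- project_embedding(runif(1024, -1, 1), mats$W_proj,
                           as.numeric(mats$b_proj))
  expect_length(out, 50L)
  expect_true(all(out >= 0))  # rectifier
  # identity-like square weights pass non-negative inputs through
  I5 <- diag(5)
  expect_equal(project_embedding(abs(e), I5, rep(0, 5)), abs(e))
  expect_error(project_embedding(e[1:4], I5, rep(0, 5)), "columns")
})

test_that("fusion concatenates the six blocks to the published 101 width", {
  rec <- protein_record("p1", "RDAKDYA")
  bundles <- assemble_bundles(rec, matrix(0.5, 7, 20),
                              rep("H", 7), matrix(0.1, 7, 1024))
  cfg <- han_config()  # P = 50, all blocks
  params <- han_init(cfg, seed = 2L)
  v <- fuse(bundles[[4]], params)
  expect_length(v, 101L)
  expect_equal(v[1:20], one_hot_encode("K"))
  expect_equal(v[21:40], rep(0.5, 20))
  expect_equal(v[41:49], encode_secondary_structure("H"))
  expect_equal(v[50], hydropathy("K"))
  expect_equal(v[51], 4 / 7)

  cfg10 <- han_config(proj = 10L)
  expect_length(fuse(bundles[[1]], han_init(cfg10, seed = 2L)), 61L)

  # dropping the embedding removes the projection entirely
  cfg_noemb <- han_config(blocks = setdiff(hanppis:::BLOCK_NAMES, "embedding"))
  expect_length(fuse(bundles[[1]], han_init(cfg_noemb, seed = 2L)), 51L)
})

test_that("Bi-GRU encoding has the right shape and zero fixed point", {
  u <- 4L
  din <- 3L
  zerop <- function() list(Wz = matrix(0, u, din), Uz = matrix(0, u, u),
                           bz = rep(0, u), Wr = matrix(0, u, din),
                           Ur = matrix(0, u, u), br = rep(0, u),
                           Wh = matrix(0, u, din), Uh = matrix(0, u, u),
                           bh = rep(0, u))
  gp <- list(fwd = zerop(), bwd = zerop())
  H <- bigru_encode(matrix(rnorm(3), 1, 3), gp)
  expect_equal(dim(H), c(1L, 2L * u))
  expect_equal(as.numeric(H), rep(0, 2 * u))  # tanh(0)*sigmoid(0) with h0=0

  # with default hidden = 86 the encoder output width is 172
  cfg <- tiny_config(hidden = 86L)
  mats <- han_unflatten(han_init(cfg, seed = 3L))
  g1 <- hanppis:::gru_level_params(mats, 1L)
  X <- matrix(rnorm(5 * hanppis:::fused_dim(cfg)), nrow = 5)
  expect_equal(ncol(bigru_encode(X, g1)), 172L)
})

test_that("reversing the input swaps the roles of the two GRU directions", {
  u <- 5L; din <- 4L; T_ <- 6L
  set.seed(42)
  mk <- function() list(Wz = matrix(rnorm(u * din, sd = 0.3), u, din),
                        Uz = matrix(rnorm(u * u, sd = 0.3), u, u),
                        bz = rnorm(u, sd = 0.1),
                        Wr = matrix(rnorm(u * din, sd = 0.3), u, din),
                        Ur = matrix(rnorm(u * u, sd = 0.3), u, u),
                        br = rnorm(u, sd = 0.1),
                        Wh = matrix(rnorm(u * din, sd = 0.3), u, din),
                        Uh = matrix(rnorm(u * u, sd = 0.3), u, u),
                        bh = rnorm(u, sd = 0.1))
  shared <- mk()
  gp <- list(fwd = shared, bwd = shared)  # shared weights expose the symmetry
  X <- matrix(rnorm(T_ * din), T_, din)
  H <- bigru_encode(X, gp)
  Hrev <- bigru_encode(X[T_:1, , drop = FALSE], gp)
  expect_equal(Hrev[T_:1, (u + 1):(2 * u)], H[, 1:u], tolerance = 1e-12)
  expect_equal(Hrev[T_:1, 1:u], H[, (u + 1):(2 * u)], tolerance = 1e-12)
})

test_that("attention pooling normalizes, masks pads and is permutation-equivariant", {
  a <- 3L; d <- 4L
  set.seed(9)
  Wa <- matrix(rnorm(a * d), a, d)
  ba <- rnorm(a)
  uc <- rnorm(a)

  one <- attention_pool(matrix(rnorm(d), 1, d), Wa, ba, uc)
  expect_equal(one$alpha, 1)

  H4 <- matrix(rep(rnorm(d), each = 4), 4, d)
  same <- attention_pool(H4, Wa, ba, uc)
  expect_equal(same$alpha, rep(0.25, 4))

  H <- matrix(rnorm(6 * d), 6, d)
  pooled <- attention_pool(H, Wa, ba, uc)
  expect_equal(sum(pooled$alpha), 1, tolerance = 1e-12)
  expect_true(all(pooled$alpha >= 0))
  expect_equal(pooled$v, as.numeric(crossprod(H, pooled$alpha)))

  # masked positions get exactly zero weight
  mask <- c(1L, 0L, 1L, 1L, 0L, 1L)
  masked <- attention_pool(H, Wa, ba, uc, mask)
  expect_identical(masked$alpha[c(2, 5)], c(0, 0))
  expect_equal(sum(masked$alpha), 1, tolerance = 1e-12)
  expect_error(attention_pool(H, Wa, ba, uc, rep(0L, 6)), "all positions")

  # permuting rows permutes the weights identically and keeps v unchanged
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  permuted <- attention_pool(H[perm, ], Wa, ba, uc)
  expect_equal(permuted$alpha, pooled$alpha[perm], tolerance = 1e-12)
  expect_equal(permuted$v, pooled$v, tolerance = 1e-12)
})

test_that("forward pass yields a probability simplex and a structured trace", {
  corpus <- tiny_corpus(n = 2L, len = 12L, seed = 13L)
  cfg <- tiny_config(seed = 13L)
  ds <- build_dataset(corpus$records, corpus$source, cfg)
  params <- han_init(cfg)
  rec <- ds$records[[1]]
  feats <- featurize(corpus$source, rec)
  bundles <- assemble_bundles(rec, feats$pssm,
                              rep(NA_character_, 12L), feats$embedding)
  fr <- extract_window(bundles, rec$sequence, rec$labels, 5L, cfg$w)
  out <- han_forward(fr, params)
  expect_length(out$p, 2L)
  expect_true(all(out$p >= 0))
  expect_equal(sum(out$p), 1, tolerance = 1e-12)
  expect_length(out$trace$kmer_weights, 3L)
  expect_equal(lengths(out$trace$residue_weights), c(3L, 3L, 1L))
  expect_equal(sum(out$trace$kmer_weights), 1, tolerance = 1e-9)

  # boundary fragment: padded positions carry exactly zero residue weight,
  # and a fully padded K-mer carries zero K-mer weight
  fr0 <- extract_window(bundles, rec$sequence, rec$labels, 0L, cfg$w)
  out0 <- han_forward(fr0, params)
  expect_identical(out0$trace$residue_weights[[1]], c(0, 0, 0))
  expect_identical(out0$trace$kmer_weights[1], 0)
  expect_equal(sum(out0$trace$kmer_weights), 1, tolerance = 1e-9)
  expect_equal(sum(out0$p), 1, tolerance = 1e-12)
})

test_that("compiled forward agrees with the pure-R reference", {
  for (seed in c(3L, 4L)) {
    cfg <- han_config(hidden = 6L, proj = 3L, attn = 5L, embed_dim = 9L,
                      seed = seed, k = sample(c(2L, 3L, 4L), 1L))
    params <- han_init(cfg)
    corpus <- tiny_corpus(n = 2L, len = 15L, seed = seed)
    src <- synth_feature_source(sigma = 0.4, seed = seed, embed_dim = 9L)
    ds <- build_dataset(corpus$records, src, cfg)
    for (center in c(0L, 4L, 14L)) {
      fm <- hanppis:::fragment_matrices(ds, 1L, center)
      ref <- hanppis:::han_forward_ref(fm$fixed, fm$emb, fm$mask, params)
      out <- han_batch_raw(params, list(fm), -1L, want_trace = TRUE)
      expect_equal(as.numeric(out$probs), ref$p, tolerance = 1e-12)
      expect_equal(as.numeric(out$traces[[1]]$kmer_weights),
                   ref$trace$kmer_weights, tolerance = 1e-12)
      expect_equal(unlist(lapply(out$traces[[1]]$residue_weights, as.numeric)),
                   unlist(ref$trace$residue_weights), tolerance = 1e-12)
    }
  }
  # and with the embedding block ablated
  cfg_ne <- han_config(hidden = 5L, attn = 4L, seed = 5L,
                       blocks = setdiff(hanppis:::BLOCK_NAMES, "embedding"))
  params <- han_init(cfg_ne)
  corpus <- tiny_corpus(n = 1L, len = 10L, seed = 5L)
  ds <- build_dataset(corpus$records, corpus$source, cfg_ne)
  fm <- hanppis:::fragment_matrices(ds, 1L, 3L)
  ref <- hanppis:::han_forward_ref(fm$fixed, NULL, fm$mask, params)
  out <- han_batch_raw(params, list(list(fixed = fm$fixed,
                                         emb = matrix(0, 0, 0),
                                         mask = fm$mask)), -1L)
  expect_equal(as.numeric(out$probs), ref$p, tolerance = 1e-12)
})

test_that("weighted cross-entropy reproduces its closed forms", {
  expect_lt(weighted_bce_loss(1L, 1 - 1e-7, w_pos = 5), 1e-6)
  expect_equal(weighted_bce_loss(c(0L, 1L), c(0.5, 0.5), w_pos = 1),
               log(2), tolerance = 1e-12)
  expect_equal(weighted_bce_loss(1L, 0.5, w_pos = 7), 7 * log(2),
               tolerance = 1e-12)
  expect_error(weighted_bce_loss(c(0L, 1L), 0.5), "different lengths")
  # w_pos = 1 equals the plain unweighted formula from an independent
  # scalar-loop implementation, on random inputs
  set.seed(31)
  for (rep in 1:5) {
    y <- rbinom(20, 1, 0.3)
    p <- runif(20, 0.01, 0.99)
    expect_equal(weighted_bce_loss(y, p, w_pos = 1),
                 oracle_bce(y, p, w_pos = 1), tolerance = 1e-12)
    expect_equal(weighted_bce_loss(y, p, w_pos = 7),
                 oracle_bce(y, p, w_pos = 7), tolerance = 1e-12)
  }
})

test_that("Adam matches the printed update rule and a reference run", {
  st <- adam_init(3L)
  up <- adam_step(rep(1, 3), rep(0, 3), st)
  expect_equal(up$theta, rep(1, 3))  # zero gradient moves nothing
  # scalar first step: bias corrections cancel, theta' ~ 1 - alpha
  up1 <- adam_step(1, 1, adam_init(1L), alpha = 0.1)
  expect_equal(up1$theta, 1 - 0.1 * 1 / (1 + 1e-8), tolerance = 1e-12)
  expect_error(adam_step(1, 1, adam_init(1L), alpha = 0), "positive")

  # 100 random steps against the independent per-coordinate oracle
  set.seed(17)
  n <- 7L
  theta0 <- rnorm(n)
  grads <- lapply(1:100, function(i) rnorm(n))
  th <- theta0
  st <- adam_init(n)
  for (g in grads) {
    up <- adam_step(th, g, st, alpha = 0.01)
    th <- up$theta
    st <- up$state
  }
  expect_equal(th, oracle_adam_run(theta0, grads, 0.01, 0.9, 0.999, 1e-8),
               tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  cfg <- han_config(hidden = 3L, proj = 2L, attn = 3L, embed_dim = 5L,
                    seed = 23L)
  params <- han_init(cfg)
  set.seed(23)
  windows <- lapply(1:4, function(i) random_window(cfg))
  labels <- c(1L, 0L, 0L, 1L)
  out <- han_batch_raw(params, windows, labels, want_grad = TRUE)
  g <- out$grad
  lossfn <- function(th) {
    p2 <- params
    p2$theta <- th
    han_batch_raw(p2, windows, labels)$loss_sum
  }
  eps <- 1e-5
  idx <- sort(sample(seq_along(params$theta), 150L))
  fd <- vapply(idx, function(i) {
    tp <- params$theta; tp[i] <- tp[i] + eps
    tm <- params$theta; tm[i] <- tm[i] - eps
    (lossfn(tp) - lossfn(tm)) / (2 * eps)
  }, numeric(1))
  rel <- abs(fd - g[idx]) / pmax(abs(fd), abs(g[idx]), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("parameter flattening round-trips through the shape table", {
  cfg <- tiny_config()
  params <- han_init(cfg)
  mats <- han_unflatten(params)
  expect_equal(han_flatten(mats, params$shapes), params$theta)
  expect_equal(dim(mats$W_out), c(2L, 2L * cfg$hidden))
  expect_equal(dim(mats$W_proj), c(cfg$proj, cfg$embed_dim))
  expect_equal(dim(mats$W_a1), c(cfg$attn, 2L * cfg$hidden))
  # biases start at zero, weights within the Glorot bound
  expect_true(all(as.numeric(mats$b_z1f) == 0))
  lim <- sqrt(6 / sum(dim(mats$W_z1f)))
  expect_true(all(abs(mats$W_z1f) <= lim))
})
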