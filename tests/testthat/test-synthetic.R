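test_that("generator is deterministic and labels follow the planted motif", {
  cfg <- synth_config(n_proteins = 15L, len_range = c(40L, 80L), seed = 11L)
  recs1 <- generate_proteins(cfg)
  recs2 <- generate_proteins(cfg)
  expect_identical(recs1, recs2)

  motif_chars <- strsplit(cfg$motif, "")[[1]]
  for (r in recs1) {
    chars <- strsplit(r$sequence, "")[[1]]
    plants <- attr(r, "plants")
    occ <- hanppis:::motif_occurrences(chars, motif_chars)
    # every occurrence is a plant: the label is an exact function of context
    expect_identical(occ, plants)
    centers <- plants + (length(motif_chars) - 1L) %/% 2L
    expected <- integer(length(chars))
    expected[centers] <- 1L
    expect_equal(r$labels, expected)
  }
})

test_that("label rule example: planted KDY centers the middle residue", {
  # motif "KDY" planted at positions 4-6 of a length-7 protein labels
  # exactly position 5 (the central 'D' of the occurrence)
  chars <- strsplit("RDAKDYA", "")[[1]]
  occ <- hanppis:::motif_occurrences(chars, c("K", "D", "Y"))
  expect_equal(occ, 4L)
  center <- occ + 1L
  labels <- integer(7)
  labels[center] <- 1L
  expect_equal(labels, c(0L, 0L, 0L, 0L, 1L, 0L, 0L))
})

test_that("realized class imbalance tracks the 5.5:1 target within 20%", {
  recs <- generate_proteins(synth_config(n_proteins = 40L,
                                         len_range = c(50L, 120L),
                                         ratio = 5.5, seed = 2L))
  r <- realized_ratio(recs)
  expect_gte(r, 4.4)
  expect_lte(r, 6.6)
})

test_that("motif-free mode yields context-independent labels at the target rate", {
  cfg <- synth_config(n_proteins = 30L, len_range = c(60L, 60L),
                      motif = NULL, seed = 4L)
  recs <- generate_proteins(cfg)
  r <- realized_ratio(recs)
  expect_gt(r, 3.5)
  expect_lt(r, 8.5)
})

test_that("infeasible motif/length combinations are rejected", {
  expect_error(synth_config(motif = "KDYKDYKDY", len_range = c(5L, 50L)),
               "longer than the minimum")
  # lengths so short the required plant count cannot fit
  expect_error(
    generate_proteins(synth_config(n_proteins = 1L, motif = "ACDEFGHIKL",
                                   len_range = c(12L, 12L), ratio = 0.1,
                                   seed = 1L)),
    "infeasible|could not place")
})

test_that("synthetic feature source is pure and shape-consistent", {
  recs <- generate_proteins(synth_config(n_proteins = 3L,
                                         len_range = c(20L, 30L), seed = 6L))
  src <- synth_feature_source(sigma = 0, seed = 6L, embed_dim = 12L)
  f1 <- featurize(src, recs[[1]])
  f2 <- featurize(src, recs[[1]])
  expect_identical(f1, f2)
  L <- nchar(recs[[1]]$sequence)
  expect_equal(nrow(f1$one_hot), L)
  expect_equal(dim(f1$pssm), c(L, 20L))
  expect_equal(dim(f1$ss9), c(L, 9L))
  expect_equal(dim(f1$embedding), c(L, 12L))
  # sigma = 0: the PSSM row is the logistic of a scaled one-hot, maximal at
  # the true residue column (0.5 elsewhere)
  chars <- strsplit(recs[[1]]$sequence, "")[[1]]
  for (i in c(1L, L %/% 2L, L)) {
    col <- match(chars[i], hanppis:::AA_ALPHABET)
    expect_equal(which.max(f1$pssm[i, ]), col)
    expect_equal(f1$pssm[i, -col], rep(0.5, 19), tolerance = 1e-12)
  }
  # noise changes values but not shape or determinism
  srcn <- synth_feature_source(sigma = 0.5, seed = 6L, embed_dim = 12L)
  g1 <- featurize(srcn, recs[[1]])
  expect_identical(g1, featurize(srcn, recs[[1]]))
  expect_false(identical(g1$pssm, f1$pssm))
})

test_that("written fixtures round-trip through the file readers", {
  recs <- generate_proteins(synth_config(n_proteins = 3L,
                                         len_range = c(15L, 25L), seed = 8L))
  src <- synth_feature_source(sigma = 0.3, seed = 8L, embed_dim = 10L)
  d <- withr::local_tempdir()
  write_synthetic_dataset(recs, d, src)

  # FASTA + labels round trip
  back <- read_fasta(file.path(d, "sequences.fasta"))
  expect_equal(vapply(back, `[[`, "", "sequence"),
               vapply(recs, `[[`, "", "sequence"))
  labs <- read_labels(file.path(d, "labels.txt"))
  expect_equal(labs[[recs[[2]]$id]], recs[[2]]$labels)

  # file-backed featurization agrees with the in-memory synthetic source
  # (PSSM columns permuted into PSI-BLAST order on disk)
  fsrc <- file_feature_source(pssm_dir = file.path(d, "pssm"),
                              dssp_dir = file.path(d, "dssp"),
                              emb_dir = file.path(d, "emb"),
                              embed_dim = 10L, seed = 8L, sigma = 0.3)
  perm <- match(hanppis:::PSIBLAST_ORDER, hanppis:::AA_ALPHABET)
  for (r in recs) {
    mem <- featurize(src, r)
    fil <- featurize(fsrc, r)
    expect_equal(fil$pssm, mem$pssm[, perm], tolerance = 1e-4)
    expect_equal(fil$embedding, mem$embedding, tolerance = 1e-12)
    # states match where present (absent rows are all-zero in both)
    expect_equal(fil$ss9, mem$ss9)
    expect_identical(fil$one_hot, mem$one_hot)
  }
})

test_that("file source falls back to synthetic features for missing proteins", {
  recs <- generate_proteins(synth_config(n_proteins = 2L,
                                         len_range = c(12L, 12L), seed = 9L))
  d <- withr::local_tempdir()
  src <- synth_feature_source(sigma = 0, seed = 9L, embed_dim = 8L)
  write_synthetic_dataset(recs[1], d, src)  # only the first protein on disk
  fsrc <- file_feature_source(pssm_dir = file.path(d, "pssm"),
                              dssp_dir = file.path(d, "dssp"),
                              emb_dir = file.path(d, "emb"),
                              embed_dim = 8L, seed = 9L, sigma = 0)
  # protein 2 has no files: featurization still succeeds, deterministically
  f <- featurize(fsrc, recs[[2]])
  expect_identical(f, featurize(fsrc, recs[[2]]))
  expect_equal(f$pssm, featurize(src, recs[[2]])$pssm)
})
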