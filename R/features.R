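# Feature sources: objects that turn a protein_record into the six raw
# feature blocks, either from files on disk (PSI-BLAST PSSM, DSSP,
# embedding tables) or from the deterministic synthetic provider. Both
# kinds are pure: the same record always yields the same blocks.

BLOCK_NAMES <- c("one_hot", "pssm", "ss9", "hydropathy", "rel_pos", "embedding")

# Widths of the five fixed (non-embedding) blocks.
FIXED_BLOCK_WIDTHS <- c(one_hot = 20L, pssm = 20L, ss9 = 9L,
                        hydropathy = 1L, rel_pos = 1L)

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Small deterministic string hash onto 1..2^31-2, for deriving per-protein
# seeds from a base seed and a protein id.
string_seed <- function(id, base_seed) {
  codes <- utf8ToInt(id)
  h <- (base_seed %% 2147483647) + 1
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h + 1)
}

ss9_matrix <- function(states) {
  m <- t(vapply(states, encode_secondary_structure, numeric(9L)))
  dimnames(m) <- NULL
  m
}

#' Synthetic feature source
#'
#' Emulates the outputs of PSI-BLAST, DSSP and a pre-trained embedding model
#' for proteins with no external data: the PSSM is the logistic transform of
#' a scaled one-hot log-odds pattern plus Gaussian noise of standard
#' deviation `sigma`; secondary-structure states are drawn from a seeded
#' per-residue categorical (including occasional "absent" rows); embeddings
#' come from the deterministic hash provider. All draws are keyed on
#' (`seed`, protein id), so the source is a pure function of the record.
#'
#' @param sigma Standard deviation of the Gaussian noise added to the raw
#'   PSSM log-odds before the logistic squashing.
#' @param seed Base seed.
#' @param embed_dim Embedding dimension.
#' @param pssm_scale Raw log-odds magnitude assigned to the true residue
#'   column before squashing.
#' @param p_ss_absent Probability that a residue has no structure state.
#' @return A feature source usable with [featurize()] and [build_dataset()].
#' @export
synth_feature_source <- function(sigma = 0, seed = 1L, embed_dim = 1024L,
                                 pssm_scale = 4, p_ss_absent = 0.05) {
  stopifnot(sigma >= 0)
  structure(list(kind = "synthetic", sigma = sigma, seed = as.integer(seed),
                 embed_dim = as.integer(embed_dim), pssm_scale = pssm_scale,
                 p_ss_absent = p_ss_absent),
            class = "han_feature_source")
}

#' File-backed feature source with synthetic fallback
#'
#' Looks for `<id>.pssm` (PSI-BLAST ASCII dialect), `<id>.dssp` (classic
#' DSSP text) and `<id>.tsv` (whitespace-delimited L x E embedding table)
#' under the respective directories. Any directory given as `NULL`, and any
#' individual protein whose file is missing, falls back to the deterministic
#' synthetic provider so pipelines run with partial inputs.
#'
#' @param pssm_dir,dssp_dir,emb_dir Directories of per-protein files, or
#'   `NULL` to use the synthetic provider for that block.
#' @param embed_dim Embedding dimension.
#' @param seed Seed for the synthetic fallbacks.
#' @param sigma Noise level for fallback PSSMs.
#' @return A feature source usable with [featurize()] and [build_dataset()].
#' @export
file_feature_source <- function(pssm_dir = NULL, dssp_dir = NULL,
                                emb_dir = NULL, embed_dim = 1024L,
                                seed = 1L, sigma = 0) {
  for (d in c(pssm_dir, dssp_dir, emb_dir)) {
    if (!is.null(d) && !dir.exists(d)) stop("directory not found: ", d, call. = FALSE)
  }
  structure(list(kind = "file", pssm_dir = pssm_dir, dssp_dir = dssp_dir,
                 emb_dir = emb_dir, embed_dim = as.integer(embed_dim),
                 seed = as.integer(seed), sigma = sigma,
                 pssm_scale = 4, p_ss_absent = 0.05),
            class = "han_feature_source")
}

synth_pssm_raw <- function(record, source) {
  m <- one_hot_matrix(record$sequence) * source$pssm_scale
  if (source$sigma > 0) {
    m <- m + matrix(stats::rnorm(length(m), sd = source$sigma),
                    nrow = nrow(m))
  }
  m
}

synth_ss_states <- function(record, source) {
  L <- nchar(record$sequence)
  pool <- c(SS_STATES, NA_character_)
  probs <- c(rep((1 - source$p_ss_absent) / 8, 8), source$p_ss_absent)
  sample(pool, L, replace = TRUE, prob = probs)
}

#' Compute the six raw feature blocks for one protein
#'
#' @param source A feature source from [synth_feature_source()] or
#'   [file_feature_source()].
#' @param record A [protein_record].
#' @return Named list of matrices `one_hot` (L x 20), `pssm` (L x 20),
#'   `ss9` (L x 9), `hydropathy` (L x 1), `rel_pos` (L x 1) and
#'   `embedding` (L x E).
#' @export
featurize <- function(source, record) {
  stopifnot(inherits(source, "han_feature_source"))
  if (source$kind == "zeroed") {
    feat <- featurize(source$inner, record)
    feat[[source$drop]][] <- 0
    return(feat)
  }
  L <- nchar(record$sequence)
  chars <- strsplit(record$sequence, "")[[1L]]
  prot_seed <- string_seed(record$id, source$seed)

  pssm <- NULL
  ss <- NULL
  if (source$kind == "file") {
    if (!is.null(source$pssm_dir)) {
      p <- file.path(source$pssm_dir, paste0(record$id, ".pssm"))
      if (file.exists(p)) pssm <- parse_pssm(p, L)
    }
    if (!is.null(source$dssp_dir)) {
      p <- file.path(source$dssp_dir, paste0(record$id, ".dssp"))
      if (file.exists(p)) ss <- parse_dssp(p, record)
    }
  }
  if (is.null(pssm)) {
    raw <- with_rng_seed(prot_seed, synth_pssm_raw(record, source))
    pssm <- 1 / (1 + exp(-raw))
  }
  if (is.null(ss)) {
    ss <- with_rng_seed(prot_seed + 1L, synth_ss_states(record, source))
  }

  emb_provider <- if (source$kind == "file" && !is.null(source$emb_dir) &&
                      file.exists(file.path(source$emb_dir,
                                            paste0(record$id, ".tsv")))) {
    file_embedding_provider(source$emb_dir, source$embed_dim)
  } else {
    hash_embedding_provider(source$embed_dim, source$seed)
  }

  list(
    one_hot    = one_hot_matrix(record$sequence),
    pssm       = pssm,
    ss9        = ss9_matrix(ss),
    hydropathy = matrix(vapply(chars, hydropathy, numeric(1L)), ncol = 1L),
    rel_pos    = matrix(seq_len(L) / L, ncol = 1L),
    embedding  = get_embedding(emb_provider, record)
  )
}

# Bind the requested blocks into the model's inputs: a fixed matrix
# (everything except the embedding, in canonical block order) and the raw
# embedding matrix (NULL when the embedding block is dropped).
bind_blocks <- function(feat, blocks = BLOCK_NAMES) {
  unknown <- setdiff(blocks, BLOCK_NAMES)
  if (length(unknown) > 0L) {
    stop("unknown feature block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fixed_names <- intersect(names(FIXED_BLOCK_WIDTHS), blocks)
  fixed <- if (length(fixed_names) > 0L) {
    do.call(cbind, feat[fixed_names])
  } else {
    matrix(0, nrow = nrow(feat$one_hot), ncol = 0L)
  }
  dimnames(fixed) <- NULL
  emb <- if ("embedding" %in% blocks) feat$embedding else NULL
  list(fixed = fixed, emb = emb)
}

# Width of the fixed part for a given block selection.
fixed_width <- function(blocks = BLOCK_NAMES) {
  sum(FIXED_BLOCK_WIDTHS[intersect(names(FIXED_BLOCK_WIDTHS), blocks)])
}
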