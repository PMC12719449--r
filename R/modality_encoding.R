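#' Per-modality embedding matrix over a node-id index
#'
#' Container aligning an `n x d_embed` real matrix with an ordered node-id
#' index; `missing_mask` marks exactly the rows that were produced by
#' imputation rather than by an encoder.
#'
#' @param modality_name Modality label (e.g. `"sequence"`).
#' @param index Character vector of node ids, one per matrix row.
#' @param matrix Numeric matrix, `length(index)` rows.
#' @param missing_mask Logical vector, one flag per row.
#' @return An object of class `modality_matrix`.
#' @export
modality_matrix <- function(modality_name, index, matrix,
                            missing_mask = rep(FALSE, length(index))) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(index)) {
    stop_mmkge("mmkge_shape_error",
               "matrix has %d rows but index has %d ids",
               nrow(matrix), length(index))
  }
  if (length(missing_mask) != length(index)) {
    stop_mmkge("mmkge_shape_error", "missing_mask length mismatch")
  }
  if (any(!is.finite(matrix))) {
    stop_mmkge("mmkge_data_error",
               "modality matrix \"%s\" contains non-finite values",
               modality_name)
  }
  rownames(matrix) <- index
  structure(list(modality = modality_name, index = as.character(index),
                 matrix = matrix, missing_mask = as.logical(missing_mask)),
            class = "modality_matrix")
}

#' @export
print.modality_matrix <- function(x, ...) {
  cat(sprintf("<modality_matrix> \"%s\": %d x %d (%d imputed)\n",
              x$modality, nrow(x$matrix), ncol(x$matrix),
              sum(x$missing_mask)))
  invisible(x)
}

hash_bucket_vector <- function(tokens, counts, d_embed) {
  v <- numeric(d_embed)
  for (i in seq_along(tokens)) {
    b <- string_hash(tokens[i]) %% d_embed + 1
    v[b] <- v[b] + counts[i]
  }
  l2_normalize(v)
}

#' Encode a residue sequence by hashed k-mer counts
#'
#' Counts all overlapping k-mers, hashes each into one of `d_embed` buckets
#' with a fixed polynomial hash, and L2-normalizes the bucket counts. A
#' deterministic, trainable-state-free stand-in for a frozen sequence
#' language model: identical strings always map to identical vectors.
#'
#' @param sequence Character scalar over the residue alphabet.
#' @param k K-mer length (>= 1; sequence must be at least k long).
#' @param d_embed Output dimension (default 768).
#' @return Numeric vector of length `d_embed` with unit L2 norm.
#' @export
encode_sequence_kmer <- function(sequence, k = 3L, d_embed = 768L) {
  if (k < 1) stop_mmkge("mmkge_config_error", "k must be >= 1")
  n <- nchar(sequence)
  if (is.na(sequence) || n < k) {
    stop_mmkge("mmkge_data_error",
               "sequence of length %d is shorter than k = %d", n, k)
  }
  kmers <- substring(sequence, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  tab <- table(kmers)
  hash_bucket_vector(names(tab), as.numeric(tab), d_embed)
}

#' Encode free text by hashed bag-of-words
#'
#' Lowercases, splits on whitespace, hashes tokens into `d_embed` buckets,
#' term-frequency weights, L2-normalizes. Deterministic; token order is
#' irrelevant (bag-of-words).
#'
#' @param text Non-empty character scalar.
#' @param d_embed Output dimension (default 768).
#' @return Numeric vector of length `d_embed` with unit L2 norm.
#' @export
encode_text_hash <- function(text, d_embed = 768L) {
  if (is.na(text) || !nzchar(trimws(text))) {
    stop_mmkge("mmkge_data_error", "cannot encode empty text")
  }
  tokens <- strsplit(tolower(trimws(text)), "\\s+")[[1]]
  tab <- table(tokens)
  hash_bucket_vector(names(tab), as.numeric(tab), d_embed)
}

#' Deterministic random imputation for a missing attribute
#'
#' Draws the replacement embedding from `N(0, 1/d_embed)` using a seed
#' derived from `(global_seed, node_id, modality)`, so a given node always
#' receives the same imputed vector across runs and epochs.
#'
#' @param node_id Node identifier.
#' @param d_embed Output dimension.
#' @param global_seed Integer seed shared by the run.
#' @param modality Modality name entering the seed derivation.
#' @return Numeric vector of length `d_embed`.
#' @export
impute_missing <- function(node_id, d_embed = 768L, global_seed = 1L,
                           modality = "") {
  s <- derive_seed(global_seed, "impute", node_id, modality)
  with_seed(s, rnorm(d_embed, mean = 0, sd = 1 / sqrt(d_embed)))
}

#' Load a precomputed (external) embedding matrix
#'
#' Adapter for per-modality embeddings computed elsewhere (e.g. frozen
#' language-model outputs): a whitespace/tab-delimited dense matrix file plus
#' a newline-delimited node-id index file.
#'
#' @param matrix_path Path to the dense matrix (one row per node, no header).
#' @param index_path Path to the node-id index (one id per line).
#' @param modality_name Label recorded on the result.
#' @return A [modality_matrix()].
#' @export
load_external_embeddings <- function(matrix_path, index_path, modality_name) {
  ids <- readLines(index_path)
  ids <- ids[nzchar(ids)]
  m <- as.matrix(read.delim(matrix_path, header = FALSE, sep = "",
                            colClasses = "numeric"))
  dimnames(m) <- NULL
  if (nrow(m) != length(ids)) {
    stop_mmkge("mmkge_shape_error",
               "matrix has %d rows but index lists %d ids", nrow(m),
               length(ids))
  }
  modality_matrix(modality_name, ids, m)
}

# Which encoder serves a raw attribute of a given modality.
encode_raw <- function(raw, modality, d_embed, k_seq = 3L, k_ngram = 2L) {
  switch(modality,
         sequence = encode_sequence_kmer(raw, k = k_seq, d_embed = d_embed),
         smiles = encode_sequence_kmer(raw, k = k_ngram, d_embed = d_embed),
         description = encode_text_hash(raw, d_embed = d_embed),
         encode_text_hash(raw, d_embed = d_embed))
}

#' Encode all modalities of a knowledge graph
#'
#' Builds one [modality_matrix()] per modality over every node: present
#' attributes go through the hashing encoders (k-mers for sequences,
#' character n-grams for SMILES, bag-of-words for descriptions); absent
#' attributes are imputed by [impute_missing()] and flagged in the missing
#' mask. All matrices share the node-id index and the output dimension.
#'
#' @param kg A [knowledge_graph()].
#' @param d_embed Common embedding dimension (default 768).
#' @param seed Global seed driving imputation.
#' @param k_seq K-mer length for sequences (default 3).
#' @param k_ngram Character n-gram length for SMILES strings (default 2).
#' @return Named list of [modality_matrix()] objects.
#' @export
encode_kg_modalities <- function(kg, d_embed = 768L, seed = 1L,
                                 k_seq = 3L, k_ngram = 2L) {
  ids <- kg$nodes$node_id
  out <- list()
  for (m in kg$modalities) {
    raw <- kg$nodes[[m]]
    mat <- matrix(0, length(ids), d_embed)
    miss <- is.na(raw)
    for (i in seq_along(ids)) {
      mat[i, ] <- if (miss[i]) {
        impute_missing(ids[i], d_embed, seed, m)
      } else {
        encode_raw(raw[i], m, d_embed, k_seq, k_ngram)
      }
    }
    out[[m]] <- modality_matrix(m, ids, mat, miss)
  }
  out
}

#' Write a modality matrix as a dense TSV plus an id index
#'
#' @param mm A [modality_matrix()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.index`.
#' @return `prefix`, invisibly.
#' @export
write_modality_matrix <- function(mm, prefix) {
  utils::write.table(mm$matrix, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(mm$index, paste0(prefix, ".index"))
  invisible(prefix)
}
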