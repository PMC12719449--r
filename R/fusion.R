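#' Elementwise mean fusion of modality vectors
#'
#' @param xs List of M numeric vectors of equal dimension.
#' @return The elementwise mean vector.
#' @export
fuse_mean <- function(xs) {
  if (length(xs) < 1) stop_mmkge("mmkge_config_error", "need at least one vector")
  d <- unique(vapply(xs, length, 0L))
  if (length(d) != 1) {
    stop_mmkge("mmkge_shape_error", "modality vectors have differing dims")
  }
  colMeans(do.call(rbind, xs))
}

#' Parameters for attention fusion
#'
#' One projection matrix per modality mapping its input dimension into the
#' common space, plus the query vector that scores projected embeddings.
#' Parameters are Glorot-initialized (query standard normal) and frozen: the
#' fusion stage feeds downstream learners as a fixed featurizer.
#'
#' @param d_in Integer vector of per-modality input dimensions (named by
#'   modality, optionally).
#' @param D Common output dimension.
#' @param seed Integer seed.
#' @return An object of class `attention_fusion_params` with fields
#'   `projections` (list of `D x d_i` matrices) and `query` (length `D`).
#' @export
attention_fusion_params <- function(d_in, D = 128L, seed = 1L) {
  with_seed(seed, {
    projections <- lapply(d_in, function(d) t(glorot(d, D)))
    query <- rnorm(D) / sqrt(D)
    structure(list(projections = projections, query = query, D = D),
              class = "attention_fusion_params")
  })
}

#' Attention fusion of modality vectors
#'
#' Projects each modality vector `x_i` into the common space,
#' `h_i = W_i x_i`, scores it against the query, `alpha = softmax(q' h_i)`,
#' and returns the attention-weighted sum `sum_i alpha_i h_i`. With
#' `final_mean = TRUE` the weighted sum is additionally scaled by `1/M` (the
#' balanced-integration convention; the scale is absorbed by downstream
#' linear layers).
#'
#' @param xs List of M modality vectors (dims matching the projections).
#' @param params An [attention_fusion_params()].
#' @param final_mean Scale the weighted sum by `1/M` (default `FALSE` at the
#'   single-vector level; the matrix-level [fuse_nodes()] defaults it on).
#' @return List with `h` (fused vector) and `weights` (the attention
#'   simplex, summing to 1 exactly).
#' @export
fuse_attention <- function(xs, params, final_mean = FALSE) {
  M <- length(xs)
  if (M < 1) stop_mmkge("mmkge_config_error", "need at least one vector")
  if (any(!vapply(xs, function(x) all(is.finite(x)), TRUE))) {
    stop_mmkge("mmkge_data_error", "non-finite modality vector")
  }
  H <- vapply(seq_len(M),
              function(i) as.numeric(params$projections[[i]] %*% xs[[i]]),
              numeric(params$D))
  scores <- as.numeric(params$query %*% H)
  w <- exp(scores - logsumexp(scores))
  w <- w / sum(w)
  h <- as.numeric(H %*% w)
  if (final_mean) h <- h / M
  list(h = h, weights = w)
}

#' Parameters for relation-guided dual adaptive fusion (ReDAF)
#'
#' A gate vector scores `tanh`-squashed modality vectors; a per-relation
#' temperature (through a sigmoid, so in `(0, 1)`) sharpens or flattens the
#' resulting softmax weights. A global fallback temperature serves fusion
#' performed outside any single relation context (e.g. contrastive
#' pre-training).
#'
#' @param D Common vector dimension.
#' @param relations Character vector of relation labels receiving their own
#'   temperature.
#' @param zeta0 Global fallback temperature (raw scale, pre-sigmoid); set to
#'   `NA` to require an explicit relation.
#' @param seed Integer seed for the gate vector.
#' @return An object of class `redaf_params` with `gate_vector`,
#'   `relation_temperatures`, `zeta0`.
#' @export
redaf_params <- function(D = 128L, relations = character(), zeta0 = 0,
                         seed = 1L) {
  with_seed(seed, {
    structure(list(
      gate_vector = rnorm(D) / sqrt(D),
      relation_temperatures = setNames(rnorm(length(relations), 0, 0.1),
                                       relations),
      zeta0 = zeta0, D = D
    ), class = "redaf_params")
  })
}

#' ReDAF fusion of modality vectors
#'
#' Scores each modality as the inner product of the gate vector with the
#' `tanh` of the modality vector, divided by the sigmoid-squashed relational
#' temperature; weights are the softmax of the scores and the output is the
#' weight-averaged sum `sum_m omega_m v_m`. The elementwise gate-times-tanh
#' product is reduced to a scalar by summation, the only reduction under
#' which the softmax over modalities is well-defined.
#'
#' @param xs List of M modality vectors, all of dimension `params$D`.
#' @param params A [redaf_params()].
#' @param relation Optional relation label selecting a temperature; when
#'   absent the global fallback is used.
#' @param final_mean Scale the weighted sum by `1/M` (default `FALSE`).
#' @return List with `h` (fused vector) and `weights` (simplex over
#'   modalities).
#' @export
fuse_redaf <- function(xs, params, relation = NULL, final_mean = FALSE) {
  M <- length(xs)
  if (M < 1) stop_mmkge("mmkge_config_error", "need at least one vector")
  zeta <- if (is.null(relation)) {
    params$zeta0
  } else if (relation %in% names(params$relation_temperatures)) {
    params$relation_temperatures[[relation]]
  } else {
    params$zeta0
  }
  if (is.null(zeta) || is.na(zeta)) {
    stop_mmkge("mmkge_config_error",
               "relation \"%s\" has no temperature and no fallback configured",
               if (is.null(relation)) "<none>" else relation)
  }
  temp <- sigmoid(zeta)
  scores <- vapply(xs, function(v) sum(params$gate_vector * tanh(v)), 0) / temp
  w <- exp(scores - logsumexp(scores))
  w <- w / sum(w)
  h <- colSums(do.call(rbind, xs) * w)
  if (final_mean) h <- h / M
  list(h = h, weights = w)
}

#' Fuse per-modality embedding matrices into unified node embeddings
#'
#' Combines the modality matrices of a graph into one embedding per node.
#' `method = "none"` averages the modality vectors elementwise (staying in
#' the encoder dimension); `"attention"` and `"redaf"` first project each
#' modality into `dim` with frozen random projections, then weight
#' modalities per node. With `final_mean = TRUE` (default) weighted sums are
#' scaled by `1/M`.
#'
#' @param modality_mats Named list of [modality_matrix()] objects sharing
#'   one node-id index.
#' @param method `"none"`, `"attention"`, or `"redaf"`.
#' @param dim Common fusion dimension for the weighted methods (default
#'   128).
#' @param final_mean Apply the `1/M` scaling after the weighted sum.
#' @param relations Relation labels handed to [redaf_params()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `fused_embeddings`: `index`, `matrix`
#'   (`n x dim` or `n x d_embed` for `"none"`), `weights` (`n x M`),
#'   `method`, `params`.
#' @export
fuse_nodes <- function(modality_mats, method = c("none", "attention", "redaf"),
                       dim = 128L, final_mean = TRUE,
                       relations = character(), seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(modality_mats) >= 1)
  index <- modality_mats[[1]]$index
  for (mm in modality_mats) stopifnot(identical(mm$index, index))
  M <- length(modality_mats)
  Xs <- lapply(modality_mats, `[[`, "matrix")

  if (method == "none") {
    fused <- Reduce(`+`, Xs) / M
    return(structure(list(index = index, matrix = fused,
                          weights = matrix(1 / M, length(index), M),
                          method = method, params = NULL),
                     class = "fused_embeddings"))
  }

  d_in <- vapply(Xs, ncol, 0L)
  if (method == "attention") {
    params <- attention_fusion_params(d_in, D = dim, seed = seed)
    H <- lapply(seq_len(M), function(m) Xs[[m]] %*% t(params$projections[[m]]))
    scores <- vapply(H, function(Hm) as.numeric(Hm %*% params$query),
                     numeric(length(index)))
  } else {
    proj_seed <- derive_seed(seed, "redaf_proj")
    projections <- with_seed(proj_seed,
                             lapply(d_in, function(d) t(glorot(d, dim))))
    params <- redaf_params(D = dim, relations = relations, seed = seed)
    params$projections <- projections
    H <- lapply(seq_len(M), function(m) Xs[[m]] %*% t(projections[[m]]))
    temp <- sigmoid(params$zeta0)
    scores <- vapply(H, function(Hm) as.numeric(tanh(Hm) %*%
                                                  params$gate_vector) / temp,
                     numeric(length(index)))
  }
  scores <- matrix(scores, nrow = length(index))
  W <- softmax_rows(scores)
  fused <- matrix(0, length(index), dim)
  for (m in seq_len(M)) fused <- fused + W[, m] * H[[m]]
  if (final_mean) fused <- fused / M
  rownames(fused) <- index
  structure(list(index = index, matrix = fused, weights = W, method = method,
                 params = params),
            class = "fused_embeddings")
}

#' @export
print.fused_embeddings <- function(x, ...) {
  cat(sprintf("<fused_embeddings> %d nodes x %d dims (method: %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$method))
  invisible(x)
}
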