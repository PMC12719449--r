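#' DistMult triple score
#'
#' Bilinear-diagonal score `sum_d h_d r_d t_d`; the predicted probability of
#' the triple is the sigmoid of the score. Symmetric in head and tail by
#' construction.
#'
#' @param h_vec,r_vec,t_vec Numeric vectors of equal dimension.
#' @return Scalar score.
#' @export
distmult_score <- function(h_vec, r_vec, t_vec) {
  if (length(h_vec) != length(r_vec) || length(r_vec) != length(t_vec)) {
    stop_mmkge("mmkge_shape_error", "entity/relation vector dims differ")
  }
  # (h * t) * r: the entity product first, so head/tail symmetry holds
  # bit-exactly, not just up to floating-point reassociation
  sum(h_vec * t_vec * r_vec)
}

#' Parameters for a two-layer relational graph convolutional encoder
#'
#' Relation-specific weights use basis decomposition
#' (`W_r = sum_b a_rb B_b`, `bases = min(|R|, 4)` by default) plus a
#' self-loop transform per layer; a relation embedding table for DistMult
#' scoring is carried alongside.
#'
#' @param relations Character vector of relation labels.
#' @param d_in Input feature dimension.
#' @param hidden,d_out Hidden and output widths (defaults 128).
#' @param n_bases Number of basis matrices (default `min(|R|, 4)`).
#' @param seed Integer seed.
#' @return A named list of parameter arrays of class `rgcn_params`, with
#'   attributes `relations` and `dims`.
#' @export
rgcn_params <- function(relations, d_in, hidden = 128L, d_out = 128L,
                        n_bases = NULL, seed = 1L) {
  nr <- length(relations)
  if (is.null(n_bases)) n_bases <- min(nr, 4L)
  params <- with_seed(seed, {
    B1 <- array(0, c(d_in, hidden, n_bases))
    B2 <- array(0, c(hidden, d_out, n_bases))
    for (b in seq_len(n_bases)) {
      B1[, , b] <- glorot(d_in, hidden)
      B2[, , b] <- glorot(hidden, d_out)
    }
    list(
      B1 = B1, C1 = matrix(rnorm(nr * n_bases, 0, 1 / sqrt(n_bases)),
                           nr, n_bases),
      W01 = glorot(d_in, hidden), bias1 = numeric(hidden),
      B2 = B2, C2 = matrix(rnorm(nr * n_bases, 0, 1 / sqrt(n_bases)),
                           nr, n_bases),
      W02 = glorot(hidden, d_out), bias2 = numeric(d_out),
      Z_rel = matrix(rnorm(nr * d_out, 0, 1 / sqrt(d_out)), nr, d_out,
                     dimnames = list(relations, NULL))
    )
  })
  structure(params, class = "rgcn_params", relations = relations,
            dims = c(d_in = d_in, hidden = hidden, d_out = d_out,
                     n_bases = n_bases))
}

# Per-relation mean-normalized adjacency over the undirected view of the
# subgraph (messages flow both ways through one W_r).
relation_adjacencies <- function(kg, relations) {
  idx <- setNames(seq_len(n_nodes(kg)), kg$nodes$node_id)
  out <- list()
  for (r in relations) {
    tr <- kg$triples[kg$triples$relation == r, ]
    if (nrow(tr) == 0) { out[[r]] <- NULL; next }
    i <- c(idx[tr$head], idx[tr$tail])
    j <- c(idx[tr$tail], idx[tr$head])
    A <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(n_nodes(kg), n_nodes(kg)))
    A@x <- pmin(A@x, 1)
    deg <- Matrix::rowSums(A)
    out[[r]] <- Matrix::Diagonal(n_nodes(kg), 1 / pmax(deg, 1)) %*% A
  }
  out
}

rgcn_layer_forward <- function(Ar_list, H, B, C, W0, bias, relations) {
  P <- sweep(H %*% W0, 2, bias, `+`)
  Ms <- list()
  for (r in names(Ar_list)) {
    ri <- match(r, relations)
    M <- as.matrix(Ar_list[[r]] %*% H)
    W_r <- matrix(0, dim(B)[1], dim(B)[2])
    for (b in seq_len(dim(B)[3])) W_r <- W_r + C[ri, b] * B[, , b]
    P <- P + M %*% W_r
    Ms[[r]] <- M
  }
  list(P = P, Ms = Ms, H = H)
}

rgcn_layer_backward <- function(cache, dP, Ar_list, B, C, W0, relations) {
  dW0 <- crossprod(cache$H, dP)
  dbias <- colSums(dP)
  dH <- dP %*% t(W0)
  dB <- B * 0
  dC <- C * 0
  for (r in names(Ar_list)) {
    ri <- match(r, relations)
    M <- cache$Ms[[r]]
    dW_r <- crossprod(M, dP)
    for (b in seq_len(dim(B)[3])) {
      dC[ri, b] <- sum(dW_r * B[, , b])
      dB[, , b] <- dB[, , b] + C[ri, b] * dW_r
    }
    W_r <- matrix(0, dim(B)[1], dim(B)[2])
    for (b in seq_len(dim(B)[3])) W_r <- W_r + C[ri, b] * B[, , b]
    dH <- dH + as.matrix(Matrix::t(Ar_list[[r]]) %*% (dP %*% t(W_r)))
  }
  list(dH = dH, dB = dB, dC = dC, dW0 = dW0, dbias = dbias)
}

rgcn_forward_full <- function(Ar_list, X, params, dropout = 0,
                              training = FALSE, seed = 1L) {
  relations <- attr(params, "relations")
  l1 <- rgcn_layer_forward(Ar_list, X, params$B1, params$C1, params$W01,
                           params$bias1, relations)
  H1 <- relu(l1$P)
  mask <- NULL
  if (training && dropout > 0) {
    mask <- with_seed(seed, matrix(runif(length(H1)) >= dropout, nrow(H1)))
    H1 <- H1 * mask / (1 - dropout)
  }
  l2 <- rgcn_layer_forward(Ar_list, H1, params$B2, params$C2, params$W02,
                           params$bias2, relations)
  list(Z = l2$P, cache = list(l1 = l1, l2 = l2, mask = mask,
                              dropout = dropout, Ar_list = Ar_list))
}

rgcn_backward_full <- function(cache, dZ, params) {
  relations <- attr(params, "relations")
  b2 <- rgcn_layer_backward(cache$l2, dZ, cache$Ar_list, params$B2,
                            params$C2, params$W02, relations)
  dH1 <- b2$dH
  if (!is.null(cache$mask)) dH1 <- dH1 * cache$mask / (1 - cache$dropout)
  dP1 <- dH1 * (cache$l1$P > 0)  # P1 cached pre-activation
  b1 <- rgcn_layer_backward(cache$l1, dP1, cache$Ar_list, params$B1,
                            params$C1, params$W01, relations)
  list(B1 = b1$dB, C1 = b1$dC, W01 = b1$dW0, bias1 = b1$dbias,
       B2 = b2$dB, C2 = b2$dC, W02 = b2$dW0, bias2 = b2$dbias)
}

#' Encode a (sub)graph with the relational graph convolutional encoder
#'
#' Two rounds of per-relation mean-aggregated message passing with a
#' self-loop transform per layer, rectifier between layers, dropout in
#' training mode only.
#'
#' @param subgraph A [knowledge_graph()] view; every relation occurring in
#'   it must be known to the parameter table.
#' @param X_init `n x d_in` initial node features aligned to
#'   `subgraph$nodes`.
#' @param params An [rgcn_params()].
#' @param dropout Dropout rate for training mode.
#' @param training Apply dropout stochastically.
#' @param seed Seed for the dropout mask.
#' @return `n x d_out` embedding matrix (row names = node ids).
#' @export
rgcn_encode <- function(subgraph, X_init, params, dropout = 0,
                        training = FALSE, seed = 1L) {
  relations <- attr(params, "relations")
  unknown <- setdiff(unique(subgraph$triples$relation), relations)
  if (length(unknown)) {
    stop_mmkge("mmkge_integrity_error", "unseen relation label(s): %s",
               paste(unknown, collapse = ", "))
  }
  Ar <- relation_adjacencies(subgraph, relations)
  Z <- rgcn_forward_full(Ar, X_init, params, dropout, training, seed)$Z
  rownames(Z) <- subgraph$nodes$node_id
  Z
}

#' Link-prediction training loss: BCE plus weighted L2 regularization
#'
#' `L = L_BCE + alpha * L_reg` with
#' `L_BCE = -(1/N) sum [y log p + (1-y) log(1-p)]` and
#' `L_reg = lambda (||X||^2 + ||Z||^2)`, where `X` are the encoded entity
#' embeddings and `Z` the relation embedding table. Probabilities are
#' clamped away from 0/1 before the log.
#'
#' @param probs Predicted probabilities in `(0, 1)`.
#' @param labels 0/1 labels.
#' @param Z_nodes Encoded entity embedding matrix.
#' @param Z_rel Relation embedding table.
#' @param alpha Weight of the regularization term (default 0.01).
#' @param lam Inner regularization weight lambda (default 0.01).
#' @return Scalar loss.
#' @export
kge_loss <- function(probs, labels, Z_nodes, Z_rel, alpha = 0.01,
                     lam = 0.01) {
  if (!all(labels %in% c(0, 1))) {
    stop_mmkge("mmkge_data_error", "labels must be 0/1")
  }
  p <- clamp_prob(probs)
  bce <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  reg <- lam * (sum(Z_nodes^2) + sum(Z_rel^2))
  bce + alpha * reg
}

#' Configuration for link-predictor training
#'
#' Defaults are the package's standard recipe: Adam at learning rate 0.001
#' with cosine annealing and 200 warm-up steps, batch size 128 triples, 100
#' epochs, dropout 0.2, gradient clipping at norm 1.0, early-stopping
#' patience 3 on validation loss, random-walk subgraph sampling (walk
#' length 10) per epoch, 1:1 training negatives, both regularization
#' weights 0.01.
#'
#' @param epochs,lr,batch_size,hidden,dim,dropout Optimization and
#'   architecture knobs.
#' @param n_bases Relation-basis count (`NULL` = `min(|R|, 4)`).
#' @param walk_length,walk_roots Random-walk sampler parameters.
#' @param ratio_k Training negatives per positive.
#' @param neg_mode Training-negative sampling mode: `"unfiltered"`
#'   (default, cheap) or `"filtered"` (recommended for dense graphs, where
#'   uniform corruptions frequently hit true edges).
#' @param alpha,lambda Regularization weights.
#' @param warmup,grad_clip,patience Optimizer schedule knobs.
#' @param seed Integer seed.
#' @return A list of class `kge_config`.
#' @export
kge_config <- function(epochs = 100L, lr = 0.001, batch_size = 128L,
                       hidden = 128L, dim = 128L, dropout = 0.2,
                       n_bases = NULL, walk_length = 10L, walk_roots = 100L,
                       ratio_k = 1L, neg_mode = "unfiltered",
                       alpha = 0.01, lambda = 0.01,
                       warmup = 200L, grad_clip = 1.0, patience = 3L,
                       seed = 1L) {
  structure(as.list(environment()), class = "kge_config")
}

triple_indices <- function(triples, node_ids, relations) {
  list(h = match(triples$head, node_ids),
       t = match(triples$tail, node_ids),
       r = match(triples$relation, relations))
}

#' Train an RGCN + DistMult link predictor
#'
#' Message passing runs over the training partition only (validation and
#' test triples never enter the encoder's graph). Each epoch draws a
#' random-walk subgraph of the training graph, resamples type-constrained
#' negatives among its positives, and takes Adam steps on batches of
#' triples; validation loss on fixed, filtered negatives selects the
#' checkpoint that is returned (lowest validation loss, early stopping on
#' patience). Deterministic given the config seed.
#'
#' @param kg The full [knowledge_graph()] (supplies nodes and types).
#' @param split An `edge_split` of `kg`'s triples.
#' @param X_init Initial node feature matrix with row names or rows aligned
#'   to `kg$nodes` (from fusion, contrastive pre-training, or random).
#' @param config A [kge_config()].
#' @return An object of class `link_predictor`: `params`, `relations`,
#'   `graph` (the training message graph), `X_init`, `history`
#'   (train/valid loss per epoch), `best_epoch`, `config`.
#' @export
train_link_predictor <- function(kg, split, X_init, config = kge_config()) {
  if (!is.null(rownames(X_init))) {
    X_init <- X_init[match(kg$nodes$node_id, rownames(X_init)), ,
                     drop = FALSE]
  }
  if (nrow(X_init) != n_nodes(kg)) {
    stop_mmkge("mmkge_shape_error",
               "X_init rows (%d) do not match node count (%d)",
               nrow(X_init), n_nodes(kg))
  }
  kg_train <- knowledge_graph(kg$nodes, split$train,
                              modalities = kg$modalities)
  kg_train$relations <- kg$relations
  params <- rgcn_params(kg$relations, ncol(X_init), config$hidden,
                        config$dim, config$n_bases,
                        seed = derive_seed(config$seed, "rgcn"))
  meta <- attributes(params)
  opt <- adam_init(params)

  valid_lab <- sample_negatives(kg, split$valid, ratio_k = config$ratio_k,
                                mode = "filtered",
                                seed = derive_seed(split$seed, "valid_negs"))
  vt <- triple_indices(valid_lab, kg$nodes$node_id, kg$relations)

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        valid_loss = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  step <- 0L
  total_steps <- NULL  # horizon set from the first epoch's batch count
  Ar_full <- relation_adjacencies(kg_train, kg$relations)

  restore_attrs <- function(p) { attributes(p) <- meta; p }

  for (epoch in seq_len(config$epochs)) {
    es <- derive_seed(config$seed, "epoch", epoch)
    sub <- random_walk_subgraph(kg_train, config$walk_length,
                                config$walk_roots, seed = es)
    sub$relations <- kg$relations
    sub_ids <- sub$nodes$node_id
    Xs <- X_init[match(sub_ids, kg$nodes$node_id), , drop = FALSE]
    if (nrow(sub$triples) == 0) next
    # in filtered mode the reference positive set is the FULL graph (not
    # just the training partition): a filtered negative must not occur
    # anywhere in the known triple set
    filt <- sub
    if (config$neg_mode == "filtered") {
      keep_full <- kg$triples$head %in% sub_ids & kg$triples$tail %in% sub_ids
      filt$triples <- kg$triples[keep_full, , drop = FALSE]
    }
    labeled <- sample_negatives(filt, sub$triples, ratio_k = config$ratio_k,
                                mode = config$neg_mode,
                                seed = derive_seed(es, "negs"))
    perm <- with_seed(derive_seed(es, "shuffle"),
                      sample.int(nrow(labeled)))
    labeled <- labeled[perm, ]
    ti <- triple_indices(labeled, sub_ids, kg$relations)
    Ar_sub <- relation_adjacencies(sub, kg$relations)

    n_batch <- ceiling(nrow(labeled) / config$batch_size)
    if (is.null(total_steps)) total_steps <- config$epochs * n_batch
    ep_loss <- 0
    for (bi in seq_len(n_batch)) {
      rows <- ((bi - 1L) * config$batch_size + 1L):
        min(bi * config$batch_size, nrow(labeled))
      fw <- rgcn_forward_full(Ar_sub, Xs, params, config$dropout, TRUE,
                              seed = derive_seed(es, "dropout", bi))
      Z <- fw$Z
      h <- ti$h[rows]; t <- ti$t[rows]; r <- ti$r[rows]
      y <- labeled$label[rows]
      scores <- rowSums(Z[h, , drop = FALSE] * Z[t, , drop = FALSE] *
                          params$Z_rel[r, , drop = FALSE])
      p <- clamp_prob(sigmoid(scores))
      N <- length(rows)
      bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
      ep_loss <- ep_loss + bce * N

      g <- (p - y) / N   # d bce / d score
      Rm <- params$Z_rel[r, , drop = FALSE]
      Hm <- Z[h, , drop = FALSE]
      Tm <- Z[t, , drop = FALSE]
      dZ <- scatter_rows(g * Rm * Tm, h, nrow(Z)) +
        scatter_rows(g * Hm * Rm, t, nrow(Z))
      dR <- scatter_rows(g * Hm * Tm, r, nrow(params$Z_rel))
      # the L2 penalty is on whole embedding tables; distribute it across
      # the epoch's batches so one epoch minimizes BCE + alpha*L_reg in
      # aggregate (applying it in full every step overwhelms the batch-mean
      # BCE gradient near the origin and stabilizes the collapsed solution)
      rs <- 2 * config$alpha * config$lambda / n_batch
      dZ <- dZ + rs * Z
      dR <- dR + rs * params$Z_rel
      grads <- rgcn_backward_full(fw$cache, dZ, params)
      grads$Z_rel <- dR
      step <- step + 1L
      lr <- lr_schedule(config$lr, step, total_steps, config$warmup)
      upd <- adam_step(params, grads, opt, lr, clip_norm = config$grad_clip)
      params <- restore_attrs(upd$params)
      opt <- upd$state
    }

    Zf <- rgcn_forward_full(Ar_full, X_init, params)$Z
    vscores <- rowSums(Zf[vt$h, , drop = FALSE] * Zf[vt$t, , drop = FALSE] *
                         params$Z_rel[vt$r, , drop = FALSE])
    # validation tracks predictive BCE only; the L2 penalty is a training
    # term and would otherwise mask improvements as embedding norms grow
    vloss <- kge_loss(sigmoid(vscores), valid_lab$label, Zf, params$Z_rel,
                      alpha = 0, lam = config$lambda)
    train_reg <- config$lambda * (sum(Zf^2) + sum(params$Z_rel^2))
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = ep_loss / nrow(labeled) +
                                  config$alpha * train_reg,
                                valid_loss = vloss))
    if (vloss < best$loss - 1e-9) {
      best <- list(loss = vloss, params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  final <- if (best$epoch > 0) best$params else params
  structure(list(params = restore_attrs(final), relations = kg$relations,
                 graph = kg_train, X_init = X_init, history = history,
                 best_epoch = best$epoch, config = config),
            class = "link_predictor")
}

#' @export
print.link_predictor <- function(x, ...) {
  cat(sprintf(paste0("<link_predictor> %d relations, dim %d, %d epoch(s)",
                     " trained (best %d)\n"),
              length(x$relations), ncol(x$params$Z_rel),
              nrow(x$history), x$best_epoch))
  invisible(x)
}

#' Score triples with a trained link predictor
#'
#' Encodes the model's training message graph (or a supplied graph) in
#' evaluation mode and returns DistMult sigmoid probabilities for the given
#' triples.
#'
#' @param model A [train_link_predictor()] result.
#' @param triples Data frame `head,relation,tail`.
#' @param graph Optional [knowledge_graph()] supplying message-passing
#'   edges (default: the training graph stored in the model).
#' @return Numeric vector of probabilities.
#' @export
predict_links <- function(model, triples, graph = NULL) {
  g <- if (is.null(graph)) model$graph else graph
  Z <- rgcn_encode(g, model$X_init, model$params)
  ti <- triple_indices(triples, g$nodes$node_id, model$relations)
  if (anyNA(unlist(ti))) {
    stop_mmkge("mmkge_integrity_error",
               "triple references a node or relation unknown to the model")
  }
  scores <- rowSums(Z[ti$h, , drop = FALSE] * Z[ti$t, , drop = FALSE] *
                      model$params$Z_rel[ti$r, , drop = FALSE])
  unname(sigmoid(scores))
}

#' Save a link predictor as a plain-text checkpoint directory
#'
#' Parameter arrays are written as TSVs (basis tensors one slice per file)
#' together with a JSON manifest (dimensions, relations, config, training
#' history) and the training message graph and initial features needed to
#' reload and score.
#'
#' @param model A [train_link_predictor()] result.
#' @param dir Checkpoint directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_link_predictor <- function(model, dir) {
  dir.create(file.path(dir, "params"), showWarnings = FALSE, recursive = TRUE)
  p <- model$params
  dims <- attr(p, "dims")
  wr <- function(m, nm) utils::write.table(
    m, file.path(dir, "params", paste0(nm, ".tsv")), sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (nm in c("C1", "W01", "C2", "W02", "Z_rel")) wr(p[[nm]], nm)
  for (nm in c("bias1", "bias2")) wr(matrix(p[[nm]], nrow = 1), nm)
  for (b in seq_len(dims["n_bases"])) {
    wr(p$B1[, , b], paste0("B1_", b))
    wr(p$B2[, , b], paste0("B2_", b))
  }
  write_modality_matrix(modality_matrix("X_init", model$graph$nodes$node_id,
                                        model$X_init),
                        file.path(dir, "X_init"))
  write.csv(model$graph$nodes, file.path(dir, "graph_nodes.csv"),
            row.names = FALSE, na = "")
  write.csv(model$graph$triples, file.path(dir, "graph_edges.csv"),
            row.names = FALSE)
  write.csv(model$history, file.path(dir, "history.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(relations = model$relations, dims = as.list(dims),
         best_epoch = model$best_epoch,
         config = unclass(model$config)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a link predictor from a checkpoint directory
#'
#' @param dir Directory written by [save_link_predictor()].
#' @return A `link_predictor`.
#' @export
load_link_predictor <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  dims <- unlist(man$dims)
  rd <- function(nm) as.matrix(read.delim(
    file.path(dir, "params", paste0(nm, ".tsv")), header = FALSE))
  p <- list()
  for (nm in c("C1", "W01", "C2", "W02", "Z_rel")) {
    p[[nm]] <- unname(rd(nm))
  }
  p$bias1 <- as.numeric(rd("bias1"))
  p$bias2 <- as.numeric(rd("bias2"))
  p$B1 <- array(0, c(dims["d_in"], dims["hidden"], dims["n_bases"]))
  p$B2 <- array(0, c(dims["hidden"], dims["d_out"], dims["n_bases"]))
  for (b in seq_len(dims["n_bases"])) {
    p$B1[, , b] <- rd(paste0("B1_", b))
    p$B2[, , b] <- rd(paste0("B2_", b))
  }
  rownames(p$Z_rel) <- man$relations
  params <- structure(p, class = "rgcn_params", relations = man$relations,
                      dims = dims)
  X <- load_external_embeddings(file.path(dir, "X_init.tsv"),
                                file.path(dir, "X_init.index"), "X_init")
  graph <- load_knowledge_graph(file.path(dir, "graph_nodes.csv"),
                                file.path(dir, "graph_edges.csv"))
  graph$relations <- man$relations
  Xm <- X$matrix[match(graph$nodes$node_id, X$index), , drop = FALSE]
  rownames(Xm) <- graph$nodes$node_id
  cfg <- man$config
  class(cfg) <- "kge_config"
  structure(list(params = params, relations = man$relations, graph = graph,
                 X_init = Xm,
                 history = read.csv(file.path(dir, "history.csv")),
                 best_epoch = man$best_epoch, config = cfg),
            class = "link_predictor")
}

#' Simulate a knowledge graph from a planted DistMult model
#'
#' Entities and relations receive standard-normal embedding vectors; every
#' ordered entity pair and relation becomes an edge with probability
#' `sigmoid(score)` of the planted DistMult score. Used for parameter
#' recovery checks: a trained model should rank held-out edges above
#' non-edges.
#'
#' @param n_entities,n_relations,dim Model size (defaults 80 / 3 / 16).
#' @param seed Integer seed.
#' @return A list with `kg` (a [knowledge_graph()] of type `other` nodes),
#'   `entity_vectors`, `relation_vectors`.
#' @export
simulate_distmult_kg <- function(n_entities = 80L, n_relations = 3L,
                                 dim = 16L, seed = 1L) {
  with_seed(seed, {
    ids <- sprintf("e%03d", seq_len(n_entities))
    rels <- sprintf("rel%d", seq_len(n_relations))
    Ent <- matrix(rnorm(n_entities * dim), n_entities, dim,
                  dimnames = list(ids, NULL))
    Rel <- matrix(rnorm(n_relations * dim), n_relations, dim,
                  dimnames = list(rels, NULL))
    triples <- list()
    for (r in seq_len(n_relations)) {
      S <- (Ent * matrix(Rel[r, ], n_entities, dim, byrow = TRUE)) %*% t(Ent)
      diag(S) <- -Inf
      keep <- matrix(runif(length(S)), nrow(S)) < sigmoid(S)
      idx <- which(keep, arr.ind = TRUE)
      triples[[r]] <- data.frame(head = ids[idx[, 1]], relation = rels[r],
                                 tail = ids[idx[, 2]],
                                 stringsAsFactors = FALSE)
    }
    nodes <- data.frame(node_id = ids, node_type = "other",
                        subtype = NA_character_, stringsAsFactors = FALSE)
    list(kg = knowledge_graph(nodes, do.call(rbind, triples)),
         entity_vectors = Ent, relation_vectors = Rel)
  })
}
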