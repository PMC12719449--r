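#' A (possibly augmented) view of a graph
#'
#' Feature matrix plus an undirected edge index, with augmentation
#' provenance. Masked feature rows are exactly zeroed; dropped edges are a
#' subset of the original edge set.
#'
#' @param X Numeric `n x d` feature matrix.
#' @param edges Integer `m x 2` matrix of node indices (one row per
#'   undirected edge).
#' @param provenance List recording `(feature_mask_rate, edge_drop_rate,
#'   seed)` for augmented views.
#' @return An object of class `graph_view`.
#' @export
graph_view <- function(X, edges, provenance = list()) {
  edges <- matrix(as.integer(edges), ncol = 2)
  structure(list(X = as.matrix(X), edges = edges, provenance = provenance),
            class = "graph_view")
}

# Homogeneous projection of a knowledge graph: relation labels dropped,
# duplicate/reciprocal edges collapsed.
kg_graph_view <- function(kg, X) {
  idx <- setNames(seq_len(n_nodes(kg)), kg$nodes$node_id)
  h <- idx[kg$triples$head]
  t <- idx[kg$triples$tail]
  lo <- pmin(h, t)
  hi <- pmax(h, t)
  keep <- !duplicated(paste(lo, hi)) & lo != hi
  graph_view(X, cbind(lo[keep], hi[keep]))
}

#' Random masking / edge-removal augmentation
#'
#' Zeroes each node's feature row independently with probability
#' `feature_mask_rate` and removes each edge independently with probability
#' `edge_drop_rate`. Deterministic given `seed`.
#'
#' @param view_in A [graph_view()].
#' @param feature_mask_rate,edge_drop_rate Rates in `[0, 1)`.
#' @param seed Integer seed.
#' @return An augmented [graph_view()].
#' @export
augment_graph <- function(view_in, feature_mask_rate = 0.2,
                          edge_drop_rate = 0.2, seed = 1L) {
  if (feature_mask_rate >= 1 || edge_drop_rate >= 1 ||
      feature_mask_rate < 0 || edge_drop_rate < 0) {
    stop_mmkge("mmkge_config_error", "augmentation rates must be in [0, 1)")
  }
  with_seed(seed, {
    X <- view_in$X
    if (feature_mask_rate > 0) {
      masked <- runif(nrow(X)) < feature_mask_rate
      X[masked, ] <- 0
    }
    edges <- view_in$edges
    if (edge_drop_rate > 0 && nrow(edges) > 0) {
      edges <- edges[runif(nrow(edges)) >= edge_drop_rate, , drop = FALSE]
    }
    graph_view(X, edges, provenance = list(
      feature_mask_rate = feature_mask_rate,
      edge_drop_rate = edge_drop_rate, seed = seed))
  })
}

#' Feature corruption by row shuffling (the standard DGI corruption)
#'
#' Permutes the rows of the feature matrix across nodes while keeping the
#' graph fixed; the multiset of feature rows (hence every column sum) is
#' preserved exactly.
#'
#' @param X Numeric feature matrix with at least 2 rows.
#' @param seed Integer seed.
#' @return The row-permuted matrix.
#' @export
corrupt_features <- function(X, seed = 1L) {
  stopifnot(nrow(X) >= 2)
  with_seed(seed, X[sample.int(nrow(X)), , drop = FALSE])
}

# Symmetrically normalized adjacency with self-loops:
# D^{-1/2} (A + I) D^{-1/2}, as a sparse Matrix.
gcn_normalize <- function(edges, n) {
  i <- c(edges[, 1], edges[, 2], seq_len(n))
  j <- c(edges[, 2], edges[, 1], seq_len(n))
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n),
                            use.last.ij = FALSE)
  A@x <- pmin(A@x, 1)  # collapse duplicate edges
  deg <- Matrix::rowSums(A)
  Dinv <- Matrix::Diagonal(n, 1 / sqrt(pmax(deg, 1e-12)))
  Dinv %*% A %*% Dinv
}

# ---- two-layer GCN encoder with manual backprop ------------------------------

gcn_init <- function(d_in, hidden = 128L, d_out = 128L, seed = 1L,
                     init = c("glorot", "zeros")) {
  init <- match.arg(init)
  with_seed(seed, {
    if (init == "zeros") {
      list(W1 = matrix(0, d_in, hidden), b1 = numeric(hidden),
           W2 = matrix(0, hidden, d_out), b2 = numeric(d_out))
    } else {
      list(W1 = glorot(d_in, hidden), b1 = numeric(hidden),
           W2 = glorot(hidden, d_out), b2 = numeric(d_out))
    }
  })
}

gcn_forward <- function(Ahat, X, params, dropout = 0, training = FALSE,
                        seed = 1L) {
  A1 <- as.matrix(Ahat %*% X)
  P1 <- sweep(A1 %*% params$W1, 2, params$b1, `+`)
  H1 <- relu(P1)
  mask <- NULL
  if (training && dropout > 0) {
    mask <- with_seed(seed, matrix(runif(length(H1)) >= dropout, nrow(H1)))
    H1 <- H1 * mask / (1 - dropout)
  }
  A2 <- as.matrix(Ahat %*% H1)
  Z <- sweep(A2 %*% params$W2, 2, params$b2, `+`)
  list(Z = Z, cache = list(Ahat = Ahat, A1 = A1, P1 = P1, A2 = A2,
                           mask = mask, dropout = dropout))
}

gcn_backward <- function(cache, dZ, params) {
  dW2 <- crossprod(cache$A2, dZ)
  db2 <- colSums(dZ)
  dA2 <- dZ %*% t(params$W2)
  dH1 <- as.matrix(cache$Ahat %*% dA2)  # Ahat is symmetric
  if (!is.null(cache$mask)) dH1 <- dH1 * cache$mask / (1 - cache$dropout)
  dP1 <- dH1 * (cache$P1 > 0)
  dW1 <- crossprod(cache$A1, dP1)
  db1 <- colSums(dP1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

# Numerically stable log(1 + exp(x)).
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# ---- DGI ---------------------------------------------------------------------

dgi_loss_grad <- function(Z_real, Z_corrupt, W_D) {
  n <- nrow(Z_real)
  if (nrow(Z_corrupt) != n) {
    stop_mmkge("mmkge_shape_error", "real/corrupt row counts differ")
  }
  s <- sigmoid(colMeans(Z_real))
  ws <- as.numeric(W_D %*% s)
  lp <- as.numeric(Z_real %*% ws)
  ln <- as.numeric(Z_corrupt %*% ws)
  loss <- (sum(softplus(-lp)) + sum(softplus(ln))) / (2 * n)
  glp <- (sigmoid(lp) - 1) / (2 * n)
  gln <- sigmoid(ln) / (2 * n)
  dZ_real <- outer(glp, ws)
  dZ_cor <- outer(gln, ws)
  dws <- as.numeric(crossprod(Z_real, glp) + crossprod(Z_corrupt, gln))
  dW <- outer(dws, s)
  ds <- as.numeric(crossprod(W_D, dws))
  dm <- ds * s * (1 - s)
  dZ_real <- dZ_real + matrix(dm / n, n, length(dm), byrow = TRUE)
  list(loss = loss, dZ_real = dZ_real, dZ_corrupt = dZ_cor, dW = dW)
}

#' Deep-graph-infomax loss
#'
#' Binary cross-entropy of a bilinear discriminator
#' `D(h, s) = sigmoid(h' W s)` between node embeddings and the graph summary
#' `s = sigmoid(mean(Z_real))`, with real patches labeled 1 and corrupted
#' patches 0, averaged over the `2n` terms.
#'
#' @param Z_real,Z_corrupt `n x d` embedding matrices from the clean and
#'   corrupted passes.
#' @param W_D `d x d` discriminator bilinear matrix (default identity).
#' @return Scalar loss (>= 0).
#' @export
dgi_loss <- function(Z_real, Z_corrupt, W_D = diag(ncol(Z_real))) {
  dgi_loss_grad(Z_real, Z_corrupt, W_D)$loss
}

# ---- GGD (edge-reconstruction BCE) -------------------------------------------

ggd_loss_grad <- function(Z, pos_edges, neg_edges) {
  if (is.null(pos_edges) || nrow(pos_edges) == 0) {
    stop_mmkge("mmkge_config_error", "pos_edges must be non-empty")
  }
  score <- function(E) rowSums(Z[E[, 1], , drop = FALSE] *
                                 Z[E[, 2], , drop = FALSE])
  yp <- score(pos_edges)
  loss <- sum(softplus(-yp))
  dZ <- Z * 0
  gp <- sigmoid(yp) - 1
  dZ <- dZ + scatter_rows(gp * Z[pos_edges[, 2], , drop = FALSE],
                          pos_edges[, 1], nrow(Z))
  dZ <- dZ + scatter_rows(gp * Z[pos_edges[, 1], , drop = FALSE],
                          pos_edges[, 2], nrow(Z))
  if (!is.null(neg_edges) && nrow(neg_edges) > 0) {
    yn <- score(neg_edges)
    loss <- loss + sum(softplus(yn))
    gn <- sigmoid(yn)
    dZ <- dZ + scatter_rows(gn * Z[neg_edges[, 2], , drop = FALSE],
                            neg_edges[, 1], nrow(Z))
    dZ <- dZ + scatter_rows(gn * Z[neg_edges[, 1], , drop = FALSE],
                            neg_edges[, 2], nrow(Z))
  }
  list(loss = loss, dZ = dZ)
}

#' Group-discrimination edge-reconstruction loss
#'
#' Edge-logit discrimination: logits `y_ij = z_i' z_j` for node pairs, with
#' binary cross-entropy summed over positive (observed) edges against
#' sampled non-edges:
#' `L = -sum_pos log sigmoid(y) - sum_neg log(1 - sigmoid(y))`.
#'
#' @param Z `n x d` node embedding matrix.
#' @param pos_edges Integer `m x 2` matrix of observed edges (non-empty).
#' @param neg_edges Integer matrix of sampled non-edges (by convention the
#'   same number as positives).
#' @return Scalar loss (a sum, >= 0).
#' @export
ggd_loss <- function(Z, pos_edges, neg_edges) {
  ggd_loss_grad(Z, pos_edges, neg_edges)$loss
}

# Uniform non-edges: sampled pairs (i, j), i != j, rejected if present in the
# undirected edge set. Deterministic given seed.
sample_non_edges <- function(edges, n, m, seed = 1L) {
  keys <- c(paste(edges[, 1], edges[, 2]), paste(edges[, 2], edges[, 1]))
  with_seed(seed, {
    out <- matrix(0L, m, 2)
    got <- 0L
    while (got < m) {
      i <- sample.int(n, 1L); j <- sample.int(n, 1L)
      if (i != j && !(paste(i, j) %in% keys)) {
        got <- got + 1L
        out[got, ] <- c(i, j)
      }
    }
    out
  })
}

# ---- GRACE -------------------------------------------------------------------

projector_init <- function(d, seed = 1L) {
  with_seed(seed, list(V1 = glorot(d, d), c1 = numeric(d),
                       V2 = glorot(d, d), c2 = numeric(d)))
}

projector_forward <- function(Z, proj) {
  P1 <- sweep(Z %*% proj$V1, 2, proj$c1, `+`)
  H <- relu(P1)
  U <- sweep(H %*% proj$V2, 2, proj$c2, `+`)
  list(U = U, cache = list(Z = Z, P1 = P1, H = H))
}

projector_backward <- function(cache, dU, proj) {
  dV2 <- crossprod(cache$H, dU)
  dc2 <- colSums(dU)
  dH <- dU %*% t(proj$V2)
  dP1 <- dH * (cache$P1 > 0)
  dV1 <- crossprod(cache$Z, dP1)
  dc1 <- colSums(dP1)
  dZ <- dP1 %*% t(proj$V1)
  list(grads = list(V1 = dV1, c1 = dc1, V2 = dV2, c2 = dc2), dZ = dZ)
}

# InfoNCE on projected views. By default the denominator runs over
# inter-view pairs only; `full_negatives` adds the intra-view terms
# (canonical formulation).
grace_loss_grad <- function(U, V, tau, full_negatives = FALSE) {
  n <- nrow(U)
  if (n == 1) {
    return(list(loss = 0, dU = U * 0, dV = V * 0))
  }
  S <- (U %*% t(V)) / tau
  if (!full_negatives) {
    P <- softmax_rows(S)
    loss <- sum(apply(S, 1, logsumexp) - diag(S))
    G <- P
    diag(G) <- diag(G) - 1
    dU <- (G %*% V) / tau
    dV <- (t(G) %*% U) / tau
  } else {
    Sintra <- (U %*% t(U)) / tau
    loss <- 0
    dU <- U * 0
    dV <- V * 0
    for (i in seq_len(n)) {
      logits <- c(S[i, ], Sintra[i, -i])
      lse <- logsumexp(logits)
      loss <- loss + (lse - S[i, i])
      p <- exp(logits - lse)
      g_inter <- p[seq_len(n)]
      g_inter[i] <- g_inter[i] - 1
      dU[i, ] <- dU[i, ] + as.numeric(g_inter %*% V) / tau
      dV <- dV + outer(g_inter, U[i, ]) / tau
      g_intra <- p[-seq_len(n)]
      others <- setdiff(seq_len(n), i)
      dU[i, ] <- dU[i, ] + as.numeric(g_intra %*% U[others, , drop = FALSE]) / tau
      dU[others, ] <- dU[others, ] + outer(g_intra, U[i, ]) / tau
    }
  }
  list(loss = loss, dU = dU, dV = dV)
}

#' Two-view InfoNCE (GRACE) loss
#'
#' Temperature-scaled softmax contrast between corresponding nodes of two
#' augmented views after a shared two-layer projector:
#' `L = -sum_i log exp(P(z1_i)' P(z2_i)/tau) / sum_j exp(P(z1_i)' P(z2_j)/tau)`.
#' The denominator runs over inter-view pairs only; intra-view negatives are
#' available via `full_negatives = TRUE`, and a symmetrized variant
#' (averaging both directions) via `symmetric = TRUE`.
#'
#' @param Z1,Z2 `n x d` view embeddings (equal `n`).
#' @param tau Temperature (> 0, default 0.5).
#' @param projector Optional projector parameters (see internals); `NULL`
#'   means identity.
#' @param full_negatives Include intra-view negatives.
#' @param symmetric Average the 1->2 and 2->1 losses.
#' @return Scalar loss (0 when `n = 1`).
#' @export
grace_loss <- function(Z1, Z2, tau = 0.5, projector = NULL,
                       full_negatives = FALSE, symmetric = FALSE) {
  if (tau <= 0) stop_mmkge("mmkge_config_error", "tau must be > 0")
  if (nrow(Z1) != nrow(Z2)) {
    stop_mmkge("mmkge_shape_error", "view embeddings differ in row count")
  }
  U <- if (is.null(projector)) Z1 else projector_forward(Z1, projector)$U
  V <- if (is.null(projector)) Z2 else projector_forward(Z2, projector)$U
  l12 <- grace_loss_grad(U, V, tau, full_negatives)$loss
  if (!symmetric) return(l12)
  l21 <- grace_loss_grad(V, U, tau, full_negatives)$loss
  (l12 + l21) / 2
}

#' Configuration for graph-contrastive pre-training
#'
#' Defaults follow the package's standard training recipe: Adam at learning
#' rate 0.001 with cosine annealing and 200 warm-up steps, 100 epochs,
#' 2-layer GCN with hidden width 128, dropout 0.2, gradient clipping at norm
#' 1.0, early-stopping patience 3; masking/edge-drop rates 0.2 and GRACE
#' temperature 0.5.
#'
#' @param epochs,lr,hidden,dim,dropout,feature_mask_rate,edge_drop_rate,tau
#'   Training hyperparameters.
#' @param grace_full_negatives,grace_symmetric GRACE variants.
#' @param warmup,grad_clip,patience Optimizer schedule knobs.
#' @param per_node_type Run contrastive refinement separately on each node
#'   type's induced subgraph (default whole-graph).
#' @param init Encoder initialization (`"glorot"` or `"zeros"`).
#' @param seed Integer seed.
#' @return A list of class `gcl_config`.
#' @export
gcl_config <- function(epochs = 100L, lr = 0.001, hidden = 128L, dim = 128L,
                       dropout = 0.2, feature_mask_rate = 0.2,
                       edge_drop_rate = 0.2, tau = 0.5,
                       grace_full_negatives = FALSE, grace_symmetric = FALSE,
                       warmup = 5L, grad_clip = 1.0, patience = 3L,
                       per_node_type = FALSE, init = "glorot", seed = 1L) {
  structure(as.list(environment()), class = "gcl_config")
}

#' Self-supervised refinement of fused node embeddings
#'
#' Trains a two-layer GCN encoder on the homogeneous (untyped) projection of
#' the knowledge graph with one of three contrastive objectives — `"dgi"`
#' (patch-vs-summary discrimination), `"ggd"` (edge-reconstruction BCE), or
#' `"grace"` (two-view InfoNCE) — using random feature-masking and
#' edge-removal augmentation. Returns the encoder output for all nodes under
#' the best-loss parameters, plus the per-epoch training log. Deterministic
#' given the config seed.
#'
#' @param kg A [knowledge_graph()].
#' @param fused A [fused_embeddings()] (or any object with `index` and
#'   `matrix`) supplying input features aligned to `kg`.
#' @param objective `"dgi"`, `"ggd"`, or `"grace"`.
#' @param config A [gcl_config()].
#' @return An object of class `gcl_result`: `embeddings` (`n x dim` matrix,
#'   row names = node ids), `log` (per-epoch loss), `objective`, `params`.
#' @export
pretrain_gcl <- function(kg, fused, objective = c("dgi", "ggd", "grace"),
                         config = gcl_config()) {
  objective <- match.arg(objective)
  X <- fused$matrix[match(kg$nodes$node_id, fused$index), , drop = FALSE]

  if (isTRUE(config$per_node_type)) {
    Z <- matrix(0, n_nodes(kg), config$dim)
    logs <- list()
    for (ty in unique(kg$nodes$node_type)) {
      sel <- kg$nodes$node_type == ty
      ids <- kg$nodes$node_id[sel]
      keep <- kg$triples$head %in% ids & kg$triples$tail %in% ids
      sub <- knowledge_graph(kg$nodes[sel, , drop = FALSE],
                             kg$triples[keep, , drop = FALSE],
                             modalities = kg$modalities)
      cfg <- config
      cfg$per_node_type <- FALSE
      res <- pretrain_gcl(sub, list(index = ids,
                                    matrix = X[sel, , drop = FALSE]),
                          objective, cfg)
      Z[sel, ] <- res$embeddings
      logs[[ty]] <- res$log
    }
    rownames(Z) <- kg$nodes$node_id
    return(structure(list(embeddings = Z, log = logs, objective = objective,
                          params = NULL), class = "gcl_result"))
  }

  view0 <- kg_graph_view(kg, X)
  n <- nrow(X)
  Ahat0 <- gcn_normalize(view0$edges, n)
  params <- gcn_init(ncol(X), config$hidden, config$dim,
                     seed = derive_seed(config$seed, "gcn"),
                     init = config$init)
  if (objective == "dgi") {
    params$W_D <- with_seed(derive_seed(config$seed, "disc"),
                            if (config$init == "zeros")
                              diag(config$dim) else
                                glorot(config$dim, config$dim))
  }
  if (objective == "grace") {
    proj <- projector_init(config$dim, derive_seed(config$seed, "proj"))
    params <- c(params, proj)
  }
  gcn_names <- c("W1", "b1", "W2", "b2")
  opt <- adam_init(params)
  log <- numeric(0)
  best <- list(loss = Inf, params = params)
  stall <- 0L

  for (epoch in seq_len(config$epochs)) {
    es <- function(tag) derive_seed(config$seed, "epoch", epoch, tag)
    track_scale <- 1
    if (objective == "grace") {
      v1 <- augment_graph(view0, config$feature_mask_rate,
                          config$edge_drop_rate, es("view1"))
      v2 <- augment_graph(view0, config$feature_mask_rate,
                          config$edge_drop_rate, es("view2"))
      A1 <- gcn_normalize(v1$edges, n)
      A2 <- gcn_normalize(v2$edges, n)
      f1 <- gcn_forward(A1, v1$X, params, config$dropout, TRUE, es("do1"))
      f2 <- gcn_forward(A2, v2$X, params, config$dropout, TRUE, es("do2"))
      proj <- params[c("V1", "c1", "V2", "c2")]
      p1 <- projector_forward(f1$Z, proj)
      p2 <- projector_forward(f2$Z, proj)
      lg <- grace_loss_grad(p1$U, p2$U, config$tau,
                            config$grace_full_negatives)
      loss <- lg$loss
      dU <- lg$dU; dV <- lg$dV
      if (isTRUE(config$grace_symmetric)) {
        lg2 <- grace_loss_grad(p2$U, p1$U, config$tau,
                               config$grace_full_negatives)
        loss <- (loss + lg2$loss) / 2
        dU <- (dU + lg2$dV) / 2
        dV <- (dV + lg2$dU) / 2
      }
      pb1 <- projector_backward(p1$cache, dU, proj)
      pb2 <- projector_backward(p2$cache, dV, proj)
      g1 <- gcn_backward(f1$cache, pb1$dZ, params)
      g2 <- gcn_backward(f2$cache, pb2$dZ, params)
      grads <- setNames(lapply(gcn_names, function(nm) g1[[nm]] + g2[[nm]]),
                        gcn_names)
      for (nm in c("V1", "c1", "V2", "c2")) {
        grads[[nm]] <- pb1$grads[[nm]] + pb2$grads[[nm]]
      }
    } else if (objective == "dgi") {
      v <- augment_graph(view0, config$feature_mask_rate,
                         config$edge_drop_rate, es("view"))
      Ah <- gcn_normalize(v$edges, n)
      Xc <- corrupt_features(v$X, es("corrupt"))
      fr <- gcn_forward(Ah, v$X, params, config$dropout, TRUE, es("do1"))
      fc <- gcn_forward(Ah, Xc, params, config$dropout, TRUE, es("do2"))
      lg <- dgi_loss_grad(fr$Z, fc$Z, params$W_D)
      loss <- lg$loss
      gr <- gcn_backward(fr$cache, lg$dZ_real, params)
      gc_ <- gcn_backward(fc$cache, lg$dZ_corrupt, params)
      grads <- setNames(lapply(gcn_names, function(nm) gr[[nm]] + gc_[[nm]]),
                        gcn_names)
      grads$W_D <- lg$dW
    } else {
      v <- augment_graph(view0, config$feature_mask_rate,
                         config$edge_drop_rate, es("view"))
      Ah <- gcn_normalize(v$edges, n)
      f <- gcn_forward(Ah, v$X, params, config$dropout, TRUE, es("do"))
      neg <- sample_non_edges(view0$edges, n, max(1L, nrow(v$edges)),
                              es("neg"))
      lg <- ggd_loss_grad(f$Z, v$edges, neg)
      loss <- lg$loss
      # the objective is a sum over a stochastic number of edge terms;
      # improvements are tracked on the per-term mean
      track_scale <- nrow(v$edges) + nrow(neg)
      grads <- gcn_backward(f$cache, lg$dZ, params)
    }

    lr <- lr_schedule(config$lr, epoch, config$epochs, config$warmup)
    upd <- adam_step(params, grads, opt, lr, clip_norm = config$grad_clip)
    params <- upd$params
    opt <- upd$state
    log <- c(log, loss)
    if (loss / track_scale < best$loss - 1e-9) {
      best <- list(loss = loss / track_scale, params = params)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  final <- if (is.finite(best$loss)) best$params else params
  Z <- gcn_forward(Ahat0, X, final, dropout = 0, training = FALSE)$Z
  rownames(Z) <- kg$nodes$node_id
  structure(list(embeddings = Z, log = log, objective = objective,
                 params = final),
            class = "gcl_result")
}

#' @export
print.gcl_result <- function(x, ...) {
  nl <- if (is.list(x$log)) sum(lengths(x$log)) else length(x$log)
  cat(sprintf("<gcl_result> %s: %d x %d embeddings, %d epoch(s) logged\n",
              x$objective, nrow(x$embeddings), ncol(x$embeddings), nl))
  invisible(x)
}
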