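make_view <- function(n = 12, d = 6, m = 20, seed = 1) {
  set.seed(seed)
  edges <- unique(cbind(sample.int(n, m, TRUE), sample.int(n, m, TRUE)))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  graph_view(matrix(rnorm(n * d), n, d), edges)
}

test_that("augmentation masks features, drops edges, and is reproducible", {
  v <- make_view()
  # zero rates are the identity
  v0 <- augment_graph(v, 0, 0, seed = 1)
  expect_equal(v0$X, v$X)
  expect_equal(v0$edges, v$edges)

  a <- augment_graph(v, 0.4, 0.3, seed = 2)
  # masked rows are exactly zeroed, dropped edges are a subset
  zeroed <- rowSums(a$X != 0) == 0
  expect_true(all(a$X[zeroed, ] == 0))
  expect_true(all(paste(a$edges[, 1], a$edges[, 2]) %in%
                    paste(v$edges[, 1], v$edges[, 2])))
  # deterministic given seed
  expect_identical(augment_graph(v, 0.4, 0.3, seed = 2), a)
  expect_error(augment_graph(v, 1, 0), class = "mmkge_config_error")

  # surviving-edge fraction matches the binomial oracle over 50 seeds
  rate <- 0.3
  m <- nrow(v$edges)
  surv <- vapply(1:50, function(s) {
    nrow(augment_graph(v, 0, rate, seed = s)$edges) / m
  }, 0)
  se <- sqrt(rate * (1 - rate) / (m * 50))
  expect_lt(abs(mean(surv) - (1 - rate)), 3 * se)
})

test_that("feature corruption is a row permutation", {
  X <- matrix(rnorm(10 * 4), 10, 4)
  Xc <- corrupt_features(X, seed = 3)
  # multiset of rows preserved
  expect_equal(X[do.call(order, as.data.frame(X)), ],
               Xc[do.call(order, as.data.frame(Xc)), ])
  # column sums exactly preserved
  expect_identical(colSums(X), colSums(Xc))
  # n = 2 reproducible
  X2 <- matrix(1:4, 2, 2)
  expect_identical(corrupt_features(X2, seed = 5),
                   corrupt_features(X2, seed = 5))
})

test_that("DGI loss has its closed forms and limits", {
  # zero embeddings: all discriminator logits 0, loss = ln 2
  Z0 <- matrix(0, 5, 4)
  expect_equal(dgi_loss(Z0, Z0), log(2))

  # n = 1 hand-set case against the scalar oracle
  h <- c(0.5, -1, 2)
  hc <- c(-0.3, 0.8, 0.1)
  s <- 1 / (1 + exp(-h))  # readout of the single real patch
  oracle <- -0.5 * (log(1 / (1 + exp(-sum(h * s)))) +
                      log(1 - 1 / (1 + exp(sum(-hc * s)))))
  expect_equal(dgi_loss(matrix(h, 1), matrix(hc, 1), diag(3)), oracle)

  # perfect discrimination drives the loss toward 0
  Zr <- matrix(50, 3, 2)
  Zc <- matrix(-50, 3, 2)
  expect_lt(dgi_loss(Zr, Zc), 1e-6)
  expect_error(dgi_loss(matrix(0, 3, 2), matrix(0, 2, 2)),
               class = "mmkge_shape_error")
})

test_that("GGD loss matches the edge-logit BCE closed forms", {
  # all-zero embeddings: every term is ln 2, and the loss is a sum
  Z0 <- matrix(0, 4, 2)
  pos <- rbind(c(1, 2), c(3, 4))
  neg <- rbind(c(1, 3))
  expect_equal(ggd_loss(Z0, pos, neg), 3 * log(2))

  # one positive edge with z_i = z_j = (2, 0): -log sigmoid(4)
  Z <- rbind(c(2, 0), c(2, 0))
  expect_equal(ggd_loss(Z, matrix(c(1, 2), 1), matrix(numeric(0), 0, 2)),
               log(1 + exp(-4)))

  # scaling down aligned embeddings with orthogonal negatives is
  # monotone nondecreasing in loss (dense sweep oracle)
  Zt <- rbind(c(2, 0), c(2, 0), c(0, 1))
  losses <- vapply(seq(1, 0, length.out = 25), function(cc) {
    ggd_loss(cc * Zt, matrix(c(1, 2), 1), matrix(c(1, 3), 1))
  }, 0)
  expect_true(all(diff(losses) >= -1e-12))
  expect_error(ggd_loss(Z0, matrix(numeric(0), 0, 2), neg),
               class = "mmkge_config_error")
})

test_that("GRACE loss matches its closed forms", {
  # singleton view: softmax over one pair, loss 0
  expect_equal(grace_loss(matrix(1:3, 1), matrix(4:6, 1)), 0)

  # n = 2, tau = 1, identity projector, orthonormal rows
  Z <- rbind(c(1, 0), c(0, 1))
  expect_equal(grace_loss(Z, Z, tau = 1), 2 * log(1 + exp(-1)))

  # infinite temperature flattens the softmax: loss -> n log n
  Zr <- matrix(rnorm(8), 4, 2)
  expect_equal(grace_loss(Zr, Zr, tau = 1e9), 4 * log(4), tolerance = 1e-6)

  # the canonical full-negative variant is at least as large
  expect_gte(grace_loss(Z, Z, tau = 1, full_negatives = TRUE),
             grace_loss(Z, Z, tau = 1))
  expect_error(grace_loss(Z, Z, tau = 0), class = "mmkge_config_error")
})

test_that("losses are nonnegative and finite on random inputs", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    Z1 <- matrix(rnorm(n * 3) * 10^sample(-1:2, 1), n, 3)
    Z2 <- matrix(rnorm(n * 3), n, 3)
    for (l in c(dgi_loss(Z1, Z2),
                ggd_loss(Z1, matrix(c(1, 2), 1), matrix(c(2, 1), 1)),
                grace_loss(Z1, Z2, tau = 0.5))) {
      expect_true(is.finite(l))
      expect_gte(l, 0)
    }
  }
})

test_that("zero-initialized encoders start at the chance-level loss", {
  fix <- small_fixture()
  kg <- fix$kg
  enc <- encode_kg_modalities(kg, d_embed = 64, seed = 1)
  fused <- fuse_nodes(enc, "none", seed = 1)
  base <- gcl_config(epochs = 1, dim = 32, hidden = 32, init = "zeros",
                     feature_mask_rate = 0, edge_drop_rate = 0, seed = 1)
  # DGI at chance: ln 2
  expect_equal(pretrain_gcl(kg, fused, "dgi", base)$log[1], log(2))
  # GGD: (|pos| + |neg|) * ln 2 with |neg| = |pos| undirected edges
  m <- nrow(mmkge:::kg_graph_view(kg, fused$matrix)$edges)
  expect_equal(pretrain_gcl(kg, fused, "ggd", base)$log[1], 2 * m * log(2))
  # GRACE on identical zero views: n log n
  expect_equal(pretrain_gcl(kg, fused, "grace", base)$log[1],
               nrow(kg$nodes) * log(nrow(kg$nodes)))
})

test_that("contrastive pre-training reduces its objective", {
  fix <- small_fixture()
  enc <- encode_kg_modalities(fix$kg, d_embed = 64, seed = 1)
  fused <- fuse_nodes(enc, "none", seed = 1)
  for (obj in c("dgi", "ggd", "grace")) {
    for (s in 1:3) {
      # generous patience so a noisy first augmented epoch cannot end the
      # run before the warm-up completes
      res <- pretrain_gcl(fix$kg, fused, obj,
                          gcl_config(epochs = 40, dim = 32, hidden = 32,
                                     patience = 10, seed = s))
      expect_lt(min(res$log), res$log[1])
    }
  }
})

test_that("epochs = 0 returns the untrained encoder output with the right shape", {
  fix <- small_fixture()
  enc <- encode_kg_modalities(fix$kg, d_embed = 64, seed = 1)
  fused <- fuse_nodes(enc, "none", seed = 1)
  res <- pretrain_gcl(fix$kg, fused, "grace",
                      gcl_config(epochs = 0, dim = 128, hidden = 64))
  expect_equal(dim(res$embeddings), c(nrow(fix$kg$nodes), 128L))
  expect_length(res$log, 0)
  expect_error(pretrain_gcl(fix$kg, fused, "unknown"), regexp = "arg")
})

test_that("refinement raises within-block agreement over the input", {
  gains <- sapply(c("dgi", "ggd", "grace"), function(obj) {
    mean(vapply(1:5, function(s) {
      fix <- small_fixture(seed = s)
      enc <- encode_kg_modalities(fix$kg, d_embed = 64, seed = s)
      fused <- fuse_nodes(enc, "none", seed = s)
      res <- pretrain_gcl(fix$kg, fused, obj,
                          gcl_config(epochs = 40, dim = 32, hidden = 32,
                                     seed = s))
      blocks <- fix$blocks[fix$kg$nodes$node_id]
      group_cosine(res$embeddings, blocks)["within"] -
        group_cosine(fused$matrix, blocks)["within"]
    }, 0))
  })
  expect_true(all(gains > 0))
})

test_that("per-node-type refinement keeps nodes in place", {
  fix <- small_fixture()
  enc <- encode_kg_modalities(fix$kg, d_embed = 64, seed = 1)
  fused <- fuse_nodes(enc, "none", seed = 1)
  res <- pretrain_gcl(fix$kg, fused, "grace",
                      gcl_config(epochs = 5, dim = 32, hidden = 32,
                                 per_node_type = TRUE, seed = 1))
  expect_equal(rownames(res$embeddings), fix$kg$nodes$node_id)
  expect_equal(dim(res$embeddings), c(nrow(fix$kg$nodes), 32L))
})
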