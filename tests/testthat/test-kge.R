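test_that("DistMult scoring is the bilinear-diagonal sum and is symmetric", {
  expect_equal(distmult_score(c(1, 2), c(1, 1), c(1, 1)), 3)
  expect_equal(distmult_score(c(1, 2), c(0, 0), c(5, -1)), 0)
  expect_error(distmult_score(1:2, 1:3, 1:2), class = "mmkge_shape_error")
  # head/tail symmetry holds bit-exactly for random vectors
  set.seed(2)
  for (i in 1:25) {
    h <- rnorm(8); r <- rnorm(8); t <- rnorm(8)
    expect_identical(distmult_score(h, r, t), distmult_score(t, r, h))
  }
})

test_that("the relational encoder matches a dense matrix oracle", {
  nodes <- data.frame(node_id = c("n1", "n2", "n3"), node_type = "other",
                      subtype = NA_character_)
  tr <- data.frame(head = c("n1", "n2"), relation = "r1",
                   tail = c("n2", "n3"))
  kg <- knowledge_graph(nodes, tr)
  set.seed(6)
  X <- matrix(rnorm(3 * 4), 3, 4)
  params <- rgcn_params("r1", d_in = 4, hidden = 2, d_out = 2,
                        n_bases = 1, seed = 9)

  # independent dense-arithmetic oracle
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  An <- A / rowSums(A)
  W_r1 <- params$C1[1, 1] * params$B1[, , 1]
  H1 <- pmax(An %*% X %*% W_r1 +
               sweep(X %*% params$W01, 2, params$bias1, `+`), 0)
  W_r2 <- params$C2[1, 1] * params$B2[, , 1]
  Zo <- An %*% H1 %*% W_r2 + sweep(H1 %*% params$W02, 2, params$bias2, `+`)

  Z <- rgcn_encode(kg, X, params)
  expect_equal(unname(Z), unname(as.matrix(Zo)))

  # unseen relation label is rejected
  tr2 <- tr; tr2$relation <- "r2"
  kg2 <- knowledge_graph(nodes, tr2)
  expect_error(rgcn_encode(kg2, X, params), class = "mmkge_integrity_error")
})

test_that("an edgeless graph reduces to the self-loop transform", {
  nodes <- data.frame(node_id = c("a", "b"), node_type = "other",
                      subtype = NA_character_)
  ref <- knowledge_graph(nodes, data.frame(head = "a", relation = "r1",
                                           tail = "b"))
  params <- rgcn_params("r1", d_in = 3, hidden = 2, d_out = 2, seed = 4)
  empty <- ref
  empty$triples <- ref$triples[0, ]
  X <- matrix(rnorm(6), 2, 3)
  H1 <- pmax(sweep(X %*% params$W01, 2, params$bias1, `+`), 0)
  expect_equal(unname(rgcn_encode(empty, X, params)),
               unname(sweep(H1 %*% params$W02, 2, params$bias2, `+`)))
})

test_that("the encoder is permutation-equivariant", {
  fix <- small_fixture()
  kg <- fix$kg
  set.seed(3)
  X <- matrix(rnorm(nrow(kg$nodes) * 8), ncol = 8)
  params <- rgcn_params(kg$relations, 8, hidden = 4, d_out = 4, seed = 5)
  Z <- rgcn_encode(kg, X, params)
  perm <- sample.int(nrow(kg$nodes))
  kg_p <- kg
  kg_p$nodes <- kg$nodes[perm, ]
  Zp <- rgcn_encode(kg_p, X[perm, , drop = FALSE], params)
  expect_equal(unname(Zp), unname(Z[perm, , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("the training loss matches its closed forms", {
  z <- matrix(0, 1, 2)
  expect_equal(kge_loss(c(0.5, 0.5), c(1, 0), z, z), log(2))
  expect_lt(kge_loss(c(1 - 1e-9, 1e-9), c(1, 0), z, z), 1e-5)
  # unit-norm single entity and relation rows add alpha*lambda*2
  e1 <- matrix(c(1, 0), 1, 2)
  expect_equal(kge_loss(c(0.5, 0.5), c(1, 0), e1, e1),
               log(2) + 0.01 * 0.01 * 2)
  expect_error(kge_loss(0.5, 2, z, z), class = "mmkge_data_error")
})

test_that("training improves validation loss on the synthetic fixture", {
  fix <- small_fixture()
  kg <- fix$kg
  sp <- split_edges(kg, seed = 7)
  set.seed(7)
  X <- matrix(rnorm(nrow(kg$nodes) * 32, 0, 1 / sqrt(32)), ncol = 32)
  rownames(X) <- kg$nodes$node_id
  m <- train_link_predictor(kg, sp, X,
                            kge_config(epochs = 10, lr = 0.003, hidden = 32,
                                       dim = 32, walk_roots = 60, seed = 7))
  expect_lt(min(m$history$valid_loss), m$history$valid_loss[1])
  expect_equal(m$best_epoch, which.min(m$history$valid_loss))

  # DistMult symmetry carries over to the trained model
  te <- sp$test[1:5, ]
  swapped <- data.frame(head = te$tail, relation = te$relation,
                        tail = te$head)
  expect_identical(predict_links(m, te), predict_links(m, swapped))

  # checkpoints round-trip through the plain-text format
  dir <- withr::local_tempdir()
  save_link_predictor(m, dir)
  m2 <- load_link_predictor(dir)
  expect_equal(predict_links(m2, te), predict_links(m, te))
})

test_that("an untrained model scores at chance", {
  fix <- small_fixture()
  sp <- split_edges(fix$kg, seed = 1)
  set.seed(1)
  X <- matrix(rnorm(nrow(fix$kg$nodes) * 16, 0, 0.25), ncol = 16)
  rownames(X) <- fix$kg$nodes$node_id
  m0 <- train_link_predictor(fix$kg, sp, X,
                             kge_config(epochs = 0, hidden = 16, dim = 16))
  expect_equal(m0$best_epoch, 0L)
  ev <- evaluate_link_predictor(m0, sp, ratio_k = 1, seed = 5)
  # AP of an uninformed ranking concentrates near the positive fraction
  expect_gt(ev$ap, 0.3)
  expect_lt(ev$ap, 0.75)
})

test_that("early stopping triggers after patience non-improving epochs", {
  fix <- small_fixture()
  sp <- split_edges(fix$kg, seed = 2)
  set.seed(2)
  X <- matrix(rnorm(nrow(fix$kg$nodes) * 16, 0, 0.25), ncol = 16)
  rownames(X) <- fix$kg$nodes$node_id
  m <- train_link_predictor(fix$kg, sp, X,
                            kge_config(epochs = 20, lr = 0, hidden = 16,
                                       dim = 16, patience = 3, seed = 3))
  # epoch 1 sets the best; 3 identical epochs then stop
  expect_equal(nrow(m$history), 4L)
})

test_that("stronger regularization shrinks the relation embeddings", {
  fix <- small_fixture()
  sp <- split_edges(fix$kg, seed = 4)
  set.seed(4)
  X <- matrix(rnorm(nrow(fix$kg$nodes) * 16, 0, 0.25), ncol = 16)
  rownames(X) <- fix$kg$nodes$node_id
  norms <- vapply(c(0.01, 5), function(a) {
    m <- train_link_predictor(fix$kg, sp, X,
                              kge_config(epochs = 8, lr = 0.003,
                                         hidden = 16, dim = 16,
                                         alpha = a, seed = 6))
    sqrt(sum(m$params$Z_rel^2))
  }, 0)
  expect_lt(norms[2], norms[1])
})
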