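test_that("average precision agrees with brute-force enumeration", {
  # worked example: labels (1,0,1,0) by descending score
  expect_equal(average_precision(c(4, 3, 2, 1), c(1, 0, 1, 0)),
               (1 + 2 / 3) / 2)
  # perfect ranking
  expect_equal(average_precision(c(9, 8, 1, 0), c(1, 1, 0, 0)), 1)
  expect_error(average_precision(1:3, c(0, 0, 0)),
               class = "mmkge_undefined_metric_error")

  # oracle equivalence on ALL labelings of up to 8 ranked items
  for (n in 1:8) {
    scores <- rev(seq_len(n))  # distinct, descending
    for (bits in seq_len(2^n - 1)) {
      labels <- as.integer(intToBits(bits)[seq_len(n)])
      expect_equal(average_precision(scores, labels),
                   ap_bruteforce(scores, labels))
    }
  }

  # tie handling is pinned: stable original order breaks ties
  expect_equal(average_precision(c(1, 1, 1), c(1, 0, 1)),
               ap_bruteforce(c(3, 2, 1), c(1, 0, 1)))
})

test_that("random scores give chance-level AP near the positive fraction", {
  set.seed(123)
  n_pos <- 30
  for (k in c(1, 3, 5, 10)) {
    labels <- c(rep(1, n_pos), rep(0, k * n_pos))
    aps <- vapply(1:200, function(i) {
      average_precision(runif(length(labels)), labels)
    }, 0)
    se <- sd(aps) / sqrt(length(aps))
    # the permutation null has a closed-form mean (see helper), which
    # approaches the positive fraction 1/(1+k) from above as n_pos grows
    null_mean <- ap_null_mean(n_pos, k * n_pos)
    expect_lt(abs(mean(aps) - null_mean), 3 * se)
    expect_lt(abs(null_mean - 1 / (1 + k)), 0.04)
  }
})

test_that("F1 matches the confusion-matrix oracle", {
  expect_equal(f1_at_threshold(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  # predict-all-positive at 1:1: P = 0.5, R = 1
  expect_equal(f1_at_threshold(rep(0.9, 4), c(1, 1, 0, 0)), 2 / 3)
  # 2 TP, 1 FP, 1 FN
  expect_equal(f1_at_threshold(c(0.9, 0.8, 0.7, 0.2), c(1, 1, 0, 1)), 2 / 3)
  # all-negative predictions give 0, not NaN
  expect_equal(f1_at_threshold(rep(0.1, 4), c(1, 1, 0, 0)), 0)
  expect_error(f1_at_threshold(c(0.2, 0.9), c(1, 1)),
               class = "mmkge_undefined_metric_error")
  # threshold is exposed
  expect_equal(f1_at_threshold(c(0.4, 0.3, 0.1, 0.05), c(1, 1, 0, 0),
                               threshold = 0.2), 1)
})

test_that("per-relation precision is bookkept per relation", {
  fix <- small_fixture()
  sp <- split_edges(fix$kg, seed = 3)
  set.seed(3)
  X <- matrix(rnorm(nrow(fix$kg$nodes) * 16, 0, 0.25), ncol = 16)
  rownames(X) <- fix$kg$nodes$node_id
  m0 <- train_link_predictor(fix$kg, sp, X,
                             kge_config(epochs = 0, hidden = 16, dim = 16))
  tab <- per_relation_precision(m0, sp, ratio_k = 10, seed = 2)
  expect_identical(tab$relation, sort(m0$relations))
  # row counts sum to the evaluated split's positive count
  expect_equal(sum(tab$n_pos), nrow(sp$test))
  expect_true(all(tab$precision[!tab$flagged] >= 0 &
                    tab$precision[!tab$flagged] <= 1))
  # relation with zero positives is flagged, not dropped
  sp2 <- sp
  sp2$test <- sp$test[sp$test$relation != "drug_disease", ]
  tab2 <- per_relation_precision(m0, sp2, ratio_k = 2, seed = 2)
  expect_true(tab2$flagged[tab2$relation == "drug_disease"])
  expect_equal(nrow(tab2), length(m0$relations))
})

test_that("a one-cell benchmark grid yields one reproducible row", {
  fix <- small_fixture()
  cfg <- benchmark_config(init_regimes = "random", fusions = "none",
                          gcl_objectives = "grace", ratios = 1L,
                          seeds = 1L, dim = 16L,
                          kge = kge_config(epochs = 2, hidden = 16,
                                           dim = 16))
  rep1 <- run_benchmark(fix$kg, cfg)
  expect_equal(nrow(rep1$summary), 1L)
  expect_length(rep1$errors, 0)
  expect_true(rep1$summary$ap >= 0 && rep1$summary$ap <= 1)

  # identical config + seeds give a byte-identical CSV
  rep2 <- run_benchmark(fix$kg, cfg)
  d <- withr::local_tempdir()
  write_eval_report(rep1, file.path(d, "a.csv"))
  write_eval_report(rep2, file.path(d, "b.csv"))
  expect_identical(readLines(file.path(d, "a.csv")),
                   readLines(file.path(d, "b.csv")))
  expect_error(benchmark_config(init_regimes = character()),
               class = "mmkge_config_error")
})

test_that("embedding export round-trips and labels protein interactors", {
  fix <- small_fixture()
  kg <- fix$kg
  set.seed(5)
  Z <- matrix(rnorm(nrow(kg$nodes) * 8), ncol = 8)
  rownames(Z) <- kg$nodes$node_id
  d <- withr::local_tempdir()
  drugs <- kg$nodes$node_id[kg$nodes$node_type == "drug"]
  protein <- kg$nodes$node_id[kg$nodes$node_type == "gene_protein"][1]
  export_embeddings(Z, file.path(d, "emb"), node_filter = drugs,
                    kg = kg, protein = protein)

  back <- load_external_embeddings(file.path(d, "emb.tsv"),
                                   file.path(d, "emb.index"), "embedding")
  expect_equal(length(back$index), length(drugs))
  expect_equal(unname(back$matrix), unname(Z[back$index, , drop = FALSE]))

  lab <- read.delim(file.path(d, "emb.labels.tsv"),
                    stringsAsFactors = FALSE)
  tr <- kg$triples
  partners <- unique(c(tr$head[tr$tail == protein],
                       tr$tail[tr$head == protein]))
  expect_setequal(lab$node_id[lab$interacts == 1],
                  intersect(drugs, partners))
  expect_error(export_embeddings(Z, file.path(d, "x"),
                                 node_filter = character()),
               class = "mmkge_config_error")
})
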