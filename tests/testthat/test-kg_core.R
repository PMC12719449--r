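test_that("loading validates tables and tracks missing attributes", {
  tt <- toy_tables()
  kg <- load_knowledge_graph(tt$nodes, tt$edges)
  expect_s3_class(kg, "knowledge_graph")
  expect_equal(nrow(kg$nodes), 3L)
  expect_equal(nrow(kg$triples), 2L)
  expect_setequal(kg$relations, c("drug_protein", "disease_protein"))
  # empty cells are missing attributes, not empty strings
  expect_true(is.na(kg$nodes$description[kg$nodes$node_id == "d1"]))
  expect_false(is.na(kg$nodes$smiles[kg$nodes$node_id == "d1"]))

  # dangling edge reference names the offending id
  bad <- read.csv(tt$edges, stringsAsFactors = FALSE)
  bad <- rbind(bad, data.frame(head = "d1", relation = "drug_protein",
                               tail = "X9"))
  bp <- file.path(tt$dir, "bad_edges.csv")
  write.csv(bad, bp, row.names = FALSE)
  expect_error(load_knowledge_graph(tt$nodes, bp), "X9",
               class = "mmkge_integrity_error")

  # missing mandatory column is a schema error
  nt <- read.csv(tt$nodes, stringsAsFactors = FALSE)
  nt$node_type <- NULL
  np <- file.path(tt$dir, "bad_nodes.csv")
  write.csv(nt, np, row.names = FALSE)
  expect_error(load_knowledge_graph(np, tt$edges),
               class = "mmkge_schema_error")
})

test_that("schema remapping accepts PrimeKG-style column names", {
  tt <- toy_tables()
  et <- read.csv(tt$edges, stringsAsFactors = FALSE)
  names(et) <- c("x_index", "relation", "y_index")
  ep <- file.path(tt$dir, "edges_pk.csv")
  write.csv(et, ep, row.names = FALSE)
  kg <- load_knowledge_graph(tt$nodes, ep,
                             kg_schema(head = "x_index", tail = "y_index"))
  expect_equal(nrow(kg$triples), 2L)
})

test_that("split sizes follow the floor-remainder convention exactly", {
  expect_equal(unname(split_sizes(3527861)), c(2116717, 705572, 705572))
  expect_equal(unname(split_sizes(42012)), c(25208, 8402, 8402))
  expect_equal(unname(split_sizes(10)), c(6, 2, 2))
})

test_that("edge splits are disjoint, exhaustive and size-exact", {
  kg <- toy_kg()
  sp <- split_edges(kg, seed = 3)
  all_rows <- rbind(sp$train, sp$valid, sp$test)
  key <- function(d) sort(paste(d$head, d$relation, d$tail))
  expect_equal(key(all_rows), key(kg$triples))
  expect_equal(nrow(sp$valid), floor(0.2 * nrow(kg$triples)))
  expect_equal(nrow(sp$test), floor(0.2 * nrow(kg$triples)))
  # deterministic given seed
  sp2 <- split_edges(kg, seed = 3)
  expect_identical(sp$train, sp2$train)
  expect_error(split_edges(kg$triples[1:2, ]),
               class = "mmkge_degenerate_split_error")

  # property: sizes add up for random totals across orders of magnitude
  set.seed(11)
  for (n in c(3, 4, 5, sample.int(1e6, 25))) {
    s <- split_sizes(n)
    expect_equal(sum(s), n)
    expect_equal(unname(s[2:3]), rep(floor(0.2 * n), 2))
  }
})

test_that("edge split round-trips through its on-disk form", {
  kg <- toy_kg()
  sp <- split_edges(kg, seed = 5)
  dir <- withr::local_tempdir()
  write_edge_split(sp, dir)
  tr <- read.delim(file.path(dir, "train.tsv"), stringsAsFactors = FALSE)
  expect_equal(nrow(tr), nrow(sp$train))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 5)
  expect_equal(man$counts$train, nrow(sp$train))
})

test_that("negative sampling honors counts, types and the filter", {
  kg <- toy_kg()
  pos <- kg$triples[1:4, ]
  lab <- sample_negatives(kg, pos, ratio_k = 1, seed = 1)
  expect_equal(nrow(lab), 8L)
  expect_equal(sum(lab$label), 4L)
  lab5 <- sample_negatives(kg, pos, ratio_k = 5, seed = 1)
  expect_equal(nrow(lab5), 24L)
  expect_equal(sum(lab5$label == 0), 20L)

  # type constraint: corrupted heads stay drugs, tails stay proteins
  type_of <- setNames(kg$nodes$node_type, kg$nodes$node_id)
  negs <- lab5[lab5$label == 0, ]
  expect_true(all(type_of[negs$head] == "drug"))
  expect_true(all(type_of[negs$tail] == "gene_protein"))

  # filtered mode never returns a known positive (exhaustive, many seeds)
  pos_keys <- paste(kg$triples$head, kg$triples$relation, kg$triples$tail)
  for (s in 1:20) {
    f <- sample_negatives(kg, kg$triples, ratio_k = 2, mode = "filtered",
                          seed = s)
    neg_keys <- paste(f$head, f$relation, f$tail)[f$label == 0]
    expect_length(intersect(neg_keys, pos_keys), 0)
  }

  # determinism
  expect_identical(sample_negatives(kg, pos, 3, seed = 9),
                   sample_negatives(kg, pos, 3, seed = 9))
})

test_that("filtered sampling on a complete bipartite graph is infeasible", {
  nodes <- data.frame(node_id = c("d1", "d2", "g1", "g2"),
                      node_type = c("drug", "drug", "gene_protein",
                                    "gene_protein"),
                      subtype = NA_character_)
  tr <- expand.grid(head = c("d1", "d2"), tail = c("g1", "g2"),
                    stringsAsFactors = FALSE)
  tr$relation <- "drug_protein"
  kg <- knowledge_graph(nodes, tr[, c("head", "relation", "tail")])
  expect_error(sample_negatives(kg, kg$triples, 1, mode = "filtered",
                                seed = 1),
               class = "mmkge_sampling_infeasible_error")
})

test_that("random-walk subgraphs are induced, contained and reproducible", {
  # a single-edge graph: the only possible walk visits both endpoints
  nodes <- data.frame(node_id = c("a", "b"), node_type = "other",
                      subtype = NA_character_)
  tr <- data.frame(head = "a", relation = "r", tail = "b")
  kg1 <- knowledge_graph(nodes, tr)
  sub1 <- random_walk_subgraph(kg1, walk_length = 1, num_roots = 1, seed = 1)
  expect_setequal(sub1$nodes$node_id, c("a", "b"))
  expect_equal(nrow(sub1$triples), 1L)

  kg <- toy_kg()
  # rooting every node with long walks covers a connected graph
  sub <- random_walk_subgraph(kg, walk_length = 30,
                              num_roots = nrow(kg$nodes), seed = 2)
  expect_setequal(sub$nodes$node_id, kg$nodes$node_id)
  expect_equal(nrow(sub$triples), nrow(kg$triples))

  # containment: nodes subset of V, triples = E restricted to the node set
  sub2 <- random_walk_subgraph(kg, walk_length = 2, num_roots = 2, seed = 4)
  expect_true(all(sub2$nodes$node_id %in% kg$nodes$node_id))
  keep <- kg$triples$head %in% sub2$nodes$node_id &
    kg$triples$tail %in% sub2$nodes$node_id
  expect_equal(nrow(sub2$triples), sum(keep))

  # byte-identical under a repeated seed
  expect_identical(random_walk_subgraph(kg, 5, 3, seed = 7),
                   random_walk_subgraph(kg, 5, 3, seed = 7))
  expect_error(random_walk_subgraph(kg, 0, 1, seed = 1),
               class = "mmkge_config_error")
})
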