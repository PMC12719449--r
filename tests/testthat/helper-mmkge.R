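# Small deterministic fixtures shared across test files.

# Exact expectation of average precision under a uniformly random ranking
# of n_pos positives among n_pos + n_neg items: conditioning on a positive
# at rank r, the other positives are hypergeometric over the preceding
# ranks, giving E[AP] = (H_N + (P-1)(N - H_N)/(N-1)) / N. This converges to
# the positive fraction but carries a positive O(1/P) finite-sample bias.
ap_null_mean <- function(n_pos, n_neg) {
  N <- n_pos + n_neg
  H <- sum(1 / seq_len(N))
  (H + (n_pos - 1) * (N - H) / (N - 1)) / N
}

# Three-node, two-edge toy graph with one missing description.
toy_tables <- function(dir = withr::local_tempdir(.local_envir =
                                                    parent.frame())) {
  nodes <- data.frame(
    node_id = c("g1", "d1", "s1"),
    node_type = c("gene_protein", "drug", "disease"),
    subtype = c("protein_coding", "small_molecule", "disease"),
    sequence = c("MKTAYIAKQR", "", ""),
    smiles = c("", "CCO", ""),
    description = c("kinase involved in signaling", "", "chronic syndrome"),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(head = c("d1", "s1"),
                      relation = c("drug_protein", "disease_protein"),
                      tail = c("g1", "g1"), stringsAsFactors = FALSE)
  np <- file.path(dir, "nodes.csv")
  ep <- file.path(dir, "edges.csv")
  write.csv(nodes, np, row.names = FALSE)
  write.csv(edges, ep, row.names = FALSE)
  list(nodes = np, edges = ep, dir = dir)
}

# In-memory toy knowledge graph (no I/O).
toy_kg <- function(n_per_type = 6L) {
  ids <- c(sprintf("g%d", seq_len(n_per_type)),
           sprintf("d%d", seq_len(n_per_type)))
  nodes <- data.frame(
    node_id = ids,
    node_type = rep(c("gene_protein", "drug"), each = n_per_type),
    subtype = NA_character_, stringsAsFactors = FALSE)
  set.seed(42)
  heads <- sprintf("d%d", sample.int(n_per_type, 3 * n_per_type, TRUE))
  tails <- sprintf("g%d", sample.int(n_per_type, 3 * n_per_type, TRUE))
  tr <- unique(data.frame(head = heads, relation = "drug_protein",
                          tail = tails, stringsAsFactors = FALSE))
  knowledge_graph(nodes, tr)
}

# Small synthetic fixture used where the full default one is too slow.
small_fixture <- function(seed = 7L) {
  synthetic_knowledge_graph(synthetic_kg_config(
    n_nodes_per_type = c(gene_protein = 24L, drug = 16L, disease = 12L),
    n_blocks = 2L, missing_rate = 0.1, seed = seed))
}

# Independent average-precision oracle: walks the precision-recall curve
# rank by rank (step interpolation), entirely separate from the package's
# implementation.
ap_bruteforce <- function(scores, labels) {
  ord <- order(-scores)
  y <- labels[ord]
  n_pos <- sum(y)
  ap <- 0
  prev_rec <- 0
  for (k in seq_along(y)) {
    tp <- sum(y[seq_len(k)])
    ap <- ap + (tp / k) * (tp / n_pos - prev_rec)
    prev_rec <- tp / n_pos
  }
  ap
}

# Mean cosine similarity between rows of Z within / across a grouping.
group_cosine <- function(Z, groups) {
  Zn <- Z / pmax(sqrt(rowSums(Z^2)), 1e-12)
  S <- Zn %*% t(Zn)
  same <- outer(groups, groups, `==`)
  diag(same) <- NA
  c(within = mean(S[same & !is.na(same)]),
    across = mean(S[!same & !is.na(same)]))
}
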