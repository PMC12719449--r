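#' Configuration for the synthetic multimodal knowledge-graph generator
#'
#' The generator plants a latent block structure: every node receives a
#' uniform block label, edges form with probability `p_in` within a block and
#' `p_out` across blocks (per relation), and modality strings are emitted
#' from block-biased distributions so that attribute signal and graph signal
#' are correlated. Defaults are the package's standard fixture: three node
#' types (60 gene/protein, 40 drug, 30 disease), 3 blocks, four relations
#' mirroring drug-protein / protein-protein / drug-disease / disease-protein
#' interactions with `p_in = 0.3`, `p_out = 0.02`, 10% of nodes with all
#' attributes missing, seed 7.
#'
#' @param n_nodes_per_type Named integer vector, nodes per node type.
#' @param n_blocks Number of latent communities.
#' @param relation_specs Data frame with columns
#'   `relation,head_type,tail_type,p_in,p_out`. For every relation
#'   `0 <= p_out < p_in <= 1` must hold (the planted signal).
#' @param missing_rate Fraction of nodes with all modalities masked, in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `synthetic_kg_config`.
#' @export
synthetic_kg_config <- function(
    n_nodes_per_type = c(gene_protein = 60L, drug = 40L, disease = 30L),
    n_blocks = 3L,
    relation_specs = data.frame(
      relation = c("drug_protein", "protein_protein",
                   "drug_disease", "disease_protein"),
      head_type = c("drug", "gene_protein", "drug", "disease"),
      tail_type = c("gene_protein", "gene_protein", "disease", "gene_protein"),
      p_in = 0.3, p_out = 0.02,
      stringsAsFactors = FALSE),
    missing_rate = 0.1,
    seed = 7L) {
  if (any(relation_specs$p_in > 1) || any(relation_specs$p_out < 0) ||
      any(relation_specs$p_out >= relation_specs$p_in)) {
    stop_mmkge("mmkge_config_error",
               "every relation needs 0 <= p_out < p_in <= 1")
  }
  if (any(n_nodes_per_type < n_blocks)) {
    stop_mmkge("mmkge_config_error",
               "each node type needs at least n_blocks nodes")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_mmkge("mmkge_config_error", "missing_rate must be in [0, 1)")
  }
  bad <- setdiff(unique(c(relation_specs$head_type, relation_specs$tail_type)),
                 names(n_nodes_per_type))
  if (length(bad)) {
    stop_mmkge("mmkge_config_error",
               "relation endpoint type(s) without nodes: %s",
               paste(bad, collapse = ", "))
  }
  structure(list(n_nodes_per_type = n_nodes_per_type,
                 n_blocks = as.integer(n_blocks),
                 relation_specs = relation_specs,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_kg_config")
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT_ALPHABET <- c("A", "C", "G", "T")
SMILES_FRAGMENTS <- c("C", "CC", "N", "O", "c1ccccc1", "C(=O)O", "Cl", "F",
                      "S", "C(N)", "OC", "c1ccncc1")
DESC_VOCAB <- c("protein", "receptor", "binding", "inhibitor", "pathway",
                "signaling", "membrane", "enzyme", "kinase", "agonist",
                "chronic", "acute", "syndrome", "treatment", "molecule")

# Block-biased categorical draw: a block-specific slice of the alphabet takes
# `bias` of the probability mass, the rest is uniform.
block_biased_sample <- function(alphabet, block, n_blocks, len, bias = 0.6) {
  sz <- max(1L, length(alphabet) %/% n_blocks)
  fav_start <- ((block - 1L) * sz) %% length(alphabet)
  fav <- alphabet[(fav_start + seq_len(sz) - 1L) %% length(alphabet) + 1L]
  p <- rep((1 - bias) / length(alphabet), length(alphabet))
  p[match(fav, alphabet)] <- p[match(fav, alphabet)] + bias / length(fav)
  sample(alphabet, len, replace = TRUE, prob = p)
}

block_sequence <- function(alphabet, block, n_blocks, len) {
  paste(block_biased_sample(alphabet, block, n_blocks, len), collapse = "")
}

block_description <- function(block, n_blocks, n_tokens = 12L) {
  kw <- paste0("blk", block, "_", c("marker", "feature", "signature"))
  pool <- c(kw, DESC_VOCAB)
  p <- c(rep(0.6 / length(kw), length(kw)),
         rep(0.4 / length(DESC_VOCAB), length(DESC_VOCAB)))
  paste(sample(pool, n_tokens, replace = TRUE, prob = p), collapse = " ")
}

#' Generate a synthetic multimodal knowledge graph with planted blocks
#'
#' Emits a node table and an edge table in the exact dialect consumed by
#' [load_knowledge_graph()] / [knowledge_graph()], plus the latent block
#' assignment (for oracle tests only; the pipeline never reads it).
#' Within-type relations draw each unordered node pair at most once (no
#' reciprocal duplicates); cross-type relations draw each ordered
#' head-to-tail pair once. Deterministic given the config seed.
#'
#' @param config A [synthetic_kg_config()].
#' @return A list with `nodes` (data frame), `edges` (data frame
#'   `head,relation,tail`), and `blocks` (named integer vector).
#' @export
generate_synthetic_kg <- function(config = synthetic_kg_config()) {
  stopifnot(inherits(config, "synthetic_kg_config"))
  with_seed(config$seed, {
    types <- rep(names(config$n_nodes_per_type), config$n_nodes_per_type)
    ids <- unlist(lapply(names(config$n_nodes_per_type), function(ty) {
      sprintf("%s_%03d", ty, seq_len(config$n_nodes_per_type[[ty]]))
    }))
    n <- length(ids)
    blocks <- sample.int(config$n_blocks, n, replace = TRUE)
    names(blocks) <- ids

    subtype <- character(n)
    sequence <- rep(NA_character_, n)
    smiles <- rep(NA_character_, n)
    description <- rep(NA_character_, n)
    for (i in seq_len(n)) {
      b <- blocks[i]
      if (types[i] == "gene_protein") {
        subtype[i] <- sample(c("protein_coding", "non_coding"), 1L,
                             prob = c(0.8, 0.2))
        alpha <- if (subtype[i] == "protein_coding") AA_ALPHABET else NT_ALPHABET
        sequence[i] <- block_sequence(alpha, b, config$n_blocks,
                                      60L + sample.int(20L, 1L))
        description[i] <- block_description(b, config$n_blocks)
      } else if (types[i] == "drug") {
        subtype[i] <- sample(c("small_molecule", "antibody"), 1L,
                             prob = c(0.85, 0.15))
        if (subtype[i] == "antibody") {
          sequence[i] <- block_sequence(AA_ALPHABET, b, config$n_blocks, 60L)
        } else {
          smiles[i] <- paste(block_biased_sample(SMILES_FRAGMENTS, b,
                                                 config$n_blocks,
                                                 8L + sample.int(6L, 1L)),
                             collapse = "")
        }
        description[i] <- block_description(b, config$n_blocks)
      } else {
        subtype[i] <- types[i]
        description[i] <- block_description(b, config$n_blocks)
      }
    }

    if (config$missing_rate > 0) {
      n_miss <- floor(config$missing_rate * n)
      if (n_miss > 0) {
        miss <- sample.int(n, n_miss)
        sequence[miss] <- NA_character_
        smiles[miss] <- NA_character_
        description[miss] <- NA_character_
      }
    }

    nodes <- data.frame(node_id = ids, node_type = types, subtype = subtype,
                        sequence = sequence, smiles = smiles,
                        description = description, stringsAsFactors = FALSE)

    edges <- list()
    for (j in seq_len(nrow(config$relation_specs))) {
      spec <- config$relation_specs[j, ]
      hs <- ids[types == spec$head_type]
      ts <- ids[types == spec$tail_type]
      if (spec$head_type == spec$tail_type) {
        pairs <- t(utils::combn(hs, 2L))
      } else {
        pairs <- as.matrix(expand.grid(hs, ts, stringsAsFactors = FALSE))
      }
      same_block <- blocks[pairs[, 1L]] == blocks[pairs[, 2L]]
      p <- ifelse(same_block, spec$p_in, spec$p_out)
      keep <- runif(nrow(pairs)) < p
      if (any(keep)) {
        edges[[spec$relation]] <- data.frame(head = pairs[keep, 1L],
                                             relation = spec$relation,
                                             tail = pairs[keep, 2L],
                                             stringsAsFactors = FALSE)
      }
    }
    edges <- do.call(rbind, c(edges, list(make.row.names = FALSE)))
    list(nodes = nodes, edges = edges, blocks = blocks)
  })
}

#' Write a synthetic knowledge graph to disk
#'
#' Writes `nodes.csv` and `edges.csv` (the loader's canonical dialect) and
#' the block assignment as a sidecar `blocks.tsv` intended only for oracle
#' checks — the pipeline never reads it.
#'
#' @param sim Result of [generate_synthetic_kg()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_kg <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(sim$nodes, file.path(dir, "nodes.csv"), row.names = FALSE,
            na = "")
  write.csv(sim$edges, file.path(dir, "edges.csv"), row.names = FALSE)
  utils::write.table(
    data.frame(node_id = names(sim$blocks), block = as.integer(sim$blocks)),
    file.path(dir, "blocks.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Synthetic knowledge graph as a loaded object
#'
#' Convenience wrapper: generate and wrap into a [knowledge_graph()].
#'
#' @param config A [synthetic_kg_config()].
#' @return A list with `kg` (the [knowledge_graph()]) and `blocks`.
#' @export
synthetic_knowledge_graph <- function(config = synthetic_kg_config()) {
  sim <- generate_synthetic_kg(config)
  list(kg = knowledge_graph(sim$nodes, sim$edges), blocks = sim$blocks)
}
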