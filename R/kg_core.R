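#' Column schema for knowledge-graph tables
#'
#' Maps the columns of a node table and an edge table onto the roles the
#' loader expects. The defaults match the canonical dialect
#' (`node_id,node_type,subtype,sequence,smiles,description` and
#' `head,relation,tail`); PrimeKG-style edge tables can be read with
#' `kg_schema(head = "x_index", tail = "y_index")`.
#'
#' @param id,type,subtype Node-table column names for the node identifier,
#'   node type and subtype.
#' @param modalities Named character vector mapping modality names to
#'   node-table columns holding the raw attribute strings.
#' @param head,relation,tail Edge-table column names.
#' @return An object of class `kg_schema`.
#' @export
kg_schema <- function(id = "node_id", type = "node_type", subtype = "subtype",
                      modalities = c(sequence = "sequence", smiles = "smiles",
                                     description = "description"),
                      head = "head", relation = "relation", tail = "tail") {
  structure(list(id = id, type = type, subtype = subtype,
                 modalities = modalities,
                 head = head, relation = relation, tail = tail),
            class = "kg_schema")
}

NODE_TYPES <- c("gene_protein", "drug", "disease", "other")

#' Construct a heterogeneous knowledge graph
#'
#' A knowledge graph is a set of typed nodes, an ordered set of relation
#' labels, a list of directed `(head, relation, tail)` triples, and a partial
#' attribute map attaching raw modality strings (sequence, SMILES,
#' description) to nodes. Attributes are stored as columns of the node table;
#' `NA` marks a missing attribute.
#'
#' @param nodes Data frame with columns `node_id`, `node_type`, `subtype` and
#'   one column per modality (may be `NA`).
#' @param triples Data frame with columns `head`, `relation`, `tail`.
#' @param modalities Character vector of modality column names present in
#'   `nodes` (defaults to the intersection with the canonical three).
#' @return An object of class `knowledge_graph` with fields `nodes`,
#'   `triples`, `relations` and `modalities`.
#' @export
knowledge_graph <- function(nodes, triples,
                            modalities = intersect(
                              c("sequence", "smiles", "description"),
                              names(nodes))) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  triples <- as.data.frame(triples, stringsAsFactors = FALSE)
  need_n <- c("node_id", "node_type")
  if (!all(need_n %in% names(nodes))) {
    stop_mmkge("mmkge_schema_error", "node table lacks column(s): %s",
               paste(setdiff(need_n, names(nodes)), collapse = ", "))
  }
  need_e <- c("head", "relation", "tail")
  if (!all(need_e %in% names(triples))) {
    stop_mmkge("mmkge_schema_error", "edge table lacks column(s): %s",
               paste(setdiff(need_e, names(triples)), collapse = ", "))
  }
  if (!("subtype" %in% names(nodes))) nodes$subtype <- NA_character_
  nodes$node_id <- as.character(nodes$node_id)
  if (anyDuplicated(nodes$node_id)) {
    stop_mmkge("mmkge_integrity_error", "duplicate node ids: %s",
               paste(unique(nodes$node_id[duplicated(nodes$node_id)]),
                     collapse = ", "))
  }
  bad_type <- setdiff(unique(nodes$node_type), NODE_TYPES)
  if (length(bad_type)) {
    stop_mmkge("mmkge_schema_error", "unknown node type(s): %s",
               paste(bad_type, collapse = ", "))
  }
  for (m in modalities) {
    v <- nodes[[m]]
    v[!is.na(v) & !nzchar(trimws(v))] <- NA_character_
    nodes[[m]] <- as.character(v)
  }
  triples$head <- as.character(triples$head)
  triples$tail <- as.character(triples$tail)
  triples$relation <- as.character(triples$relation)
  known <- triples$head %in% nodes$node_id & triples$tail %in% nodes$node_id
  if (!all(known)) {
    i <- which(!known)[1L]
    missing_id <- setdiff(c(triples$head[i], triples$tail[i]), nodes$node_id)[1L]
    stop_mmkge("mmkge_integrity_error",
               "edge row %d references unknown node id \"%s\"", i, missing_id)
  }
  structure(list(
    nodes = nodes[, unique(c("node_id", "node_type", "subtype", modalities))],
    triples = triples[, c("head", "relation", "tail")],
    relations = unique(triples$relation),
    modalities = modalities
  ), class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d nodes (%s), %d triples, %d relations\n",
              nrow(x$nodes),
              paste(sprintf("%s: %d", names(table(x$nodes$node_type)),
                            table(x$nodes$node_type)), collapse = ", "),
              nrow(x$triples), length(x$relations)))
  invisible(x)
}

n_nodes <- function(kg) nrow(kg$nodes)
n_edges <- function(kg) nrow(kg$triples)

read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE,
           colClasses = "character", check.names = FALSE)
}

#' Load a knowledge graph from node and edge tables
#'
#' Reads CSV/TSV tables (delimiter chosen by file extension), applies the
#' column schema, and validates referential integrity: every edge endpoint
#' must exist in the node table. Empty modality cells become missing
#' attributes.
#'
#' @param node_table_path,edge_table_path Paths to the node and edge tables.
#' @param schema A [kg_schema()].
#' @return A [knowledge_graph()].
#' @export
load_knowledge_graph <- function(node_table_path, edge_table_path,
                                 schema = kg_schema()) {
  nt <- read_table_auto(node_table_path)
  et <- read_table_auto(edge_table_path)
  need <- c(schema$id, schema$type)
  if (!all(need %in% names(nt))) {
    stop_mmkge("mmkge_schema_error",
               "node table %s lacks mandatory column(s): %s", node_table_path,
               paste(setdiff(need, names(nt)), collapse = ", "))
  }
  need_e <- c(schema$head, schema$relation, schema$tail)
  if (!all(need_e %in% names(et))) {
    stop_mmkge("mmkge_schema_error",
               "edge table %s lacks mandatory column(s): %s", edge_table_path,
               paste(setdiff(need_e, names(et)), collapse = ", "))
  }
  nodes <- data.frame(node_id = nt[[schema$id]],
                      node_type = nt[[schema$type]],
                      stringsAsFactors = FALSE)
  nodes$subtype <- if (schema$subtype %in% names(nt)) {
    nt[[schema$subtype]]
  } else {
    NA_character_
  }
  present <- schema$modalities[schema$modalities %in% names(nt)]
  for (m in names(present)) {
    v <- nt[[present[[m]]]]
    v[!nzchar(trimws(v))] <- NA_character_
    nodes[[m]] <- v
  }
  triples <- data.frame(head = et[[schema$head]],
                        relation = et[[schema$relation]],
                        tail = et[[schema$tail]],
                        stringsAsFactors = FALSE)
  knowledge_graph(nodes, triples, modalities = names(present))
}

#' Deterministic train/valid/test sizes for an edge split
#'
#' Validation and test sizes are `floor(ratio * n)`; the remainder goes to
#' train. This floor-remainder convention is the one under which the split
#' sizes are fully determined by the total and the ratios.
#'
#' @param n_edges Total number of triples.
#' @param ratios Length-3 numeric vector of train/valid/test fractions
#'   (must be positive, summing to 1).
#' @return Named integer-valued vector `c(train=, valid=, test=)`.
#' @export
split_sizes <- function(n_edges, ratios = c(0.6, 0.2, 0.2)) {
  stopifnot(length(ratios) == 3)
  if (any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-8) {
    stop_mmkge("mmkge_config_error", "split ratios must be positive and sum to 1")
  }
  n_valid <- floor(ratios[2] * n_edges)
  n_test <- floor(ratios[3] * n_edges)
  c(train = n_edges - n_valid - n_test, valid = n_valid, test = n_test)
}

#' Randomly split triples into train/valid/test partitions
#'
#' Applies a uniform random permutation and cuts it into partitions sized by
#' [split_sizes()]. Partitions are disjoint and their union is the original
#' triple multiset. Deterministic given `seed`.
#'
#' @param kg A [knowledge_graph()], or a data frame of triples with columns
#'   `head`, `relation`, `tail`.
#' @param ratios Train/valid/test fractions (positive, sum to 1).
#' @param seed Integer seed.
#' @return An object of class `edge_split` with data frames `train`, `valid`,
#'   `test`, plus `ratios`, `seed` and `sizes`.
#' @export
split_edges <- function(kg, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  triples <- if (inherits(kg, "knowledge_graph")) kg$triples else
    as.data.frame(kg, stringsAsFactors = FALSE)
  n <- nrow(triples)
  if (n < 3) {
    stop_mmkge("mmkge_degenerate_split_error",
               "cannot split %d triple(s) into three non-empty partitions", n)
  }
  sizes <- split_sizes(n, ratios)
  perm <- with_seed(seed, sample.int(n))
  idx_train <- perm[seq_len(sizes["train"])]
  idx_valid <- perm[sizes["train"] + seq_len(sizes["valid"])]
  idx_test <- perm[sizes["train"] + sizes["valid"] + seq_len(sizes["test"])]
  structure(list(
    train = triples[idx_train, , drop = FALSE],
    valid = triples[idx_valid, , drop = FALSE],
    test = triples[idx_test, , drop = FALSE],
    ratios = ratios, seed = as.integer(seed), sizes = sizes
  ), class = "edge_split")
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf("<edge_split> train %d / valid %d / test %d (seed %d)\n",
              x$sizes["train"], x$sizes["valid"], x$sizes["test"], x$seed))
  invisible(x)
}

#' Persist an edge split as TSVs plus a JSON manifest
#'
#' @param split An `edge_split`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_edge_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in c("train", "valid", "test")) {
    utils::write.table(split[[p]], file.path(dir, paste0(p, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(seed = split$seed, ratios = split$ratios,
                   counts = as.list(setNames(as.integer(split$sizes),
                                             names(split$sizes))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Observed type signature of each relation: which node types appear as heads
# and as tails. Used to type-constrain corruption.
relation_signatures <- function(kg) {
  type_of <- setNames(kg$nodes$node_type, kg$nodes$node_id)
  out <- list()
  for (r in kg$relations) {
    tr <- kg$triples[kg$triples$relation == r, ]
    out[[r]] <- list(head_types = unique(type_of[tr$head]),
                     tail_types = unique(type_of[tr$tail]))
  }
  out
}

#' Sample corrupted (negative) triples for link prediction
#'
#' Each positive triple receives `ratio_k` corruptions obtained by replacing
#' its head or tail with a uniformly sampled node whose type is compatible
#' with the relation's observed type signature. The replacement never equals
#' the original node; in `filtered` mode a corruption is additionally rejected
#' if it occurs anywhere in the graph's positive triple set. Positives are
#' labeled 1, negatives 0. Deterministic given `seed`.
#'
#' @param kg A [knowledge_graph()] (supplies node types and, in filtered
#'   mode, the full positive set).
#' @param positives Data frame of positive triples (`head,relation,tail`).
#' @param ratio_k Number of negatives per positive (>= 1).
#' @param mode `"unfiltered"` (default, cheap, for training) or `"filtered"`
#'   (for evaluation).
#' @param corruption Which slot to corrupt: `"both"` (head or tail with equal
#'   probability), `"head"`, or `"tail"`.
#' @param seed Integer seed.
#' @return Data frame `head,relation,tail,label` with
#'   `(1 + ratio_k) * nrow(positives)` rows.
#' @export
sample_negatives <- function(kg, positives, ratio_k = 1L,
                             mode = c("unfiltered", "filtered"),
                             corruption = c("both", "head", "tail"),
                             seed = 1L) {
  mode <- match.arg(mode)
  corruption <- match.arg(corruption)
  if (ratio_k < 1) stop_mmkge("mmkge_config_error", "ratio_k must be >= 1")
  positives <- as.data.frame(positives, stringsAsFactors = FALSE)
  unknown <- setdiff(unique(positives$relation), kg$relations)
  if (length(unknown)) {
    stop_mmkge("mmkge_integrity_error", "unknown relation \"%s\"", unknown[1])
  }
  sigs <- relation_signatures(kg)
  nodes_by_type <- split(kg$nodes$node_id, kg$nodes$node_type)
  pos_keys <- if (mode == "filtered") {
    paste(kg$triples$head, kg$triples$relation, kg$triples$tail, sep = "\r")
  } else {
    character(0)
  }
  negs <- with_seed(seed, {
    # each positive in turn contributes ratio_k corruptions
    idx <- rep(seq_len(nrow(positives)), each = ratio_k)
    h <- positives$head[idx]
    r <- positives$relation[idx]
    t <- positives$tail[idx]
    m <- length(idx)
    slot_head <- switch(corruption,
                        head = rep(TRUE, m),
                        tail = rep(FALSE, m),
                        both = runif(m) < 0.5)
    cand <- character(m)
    for (rl in unique(r)) {
      sig <- sigs[[rl]]
      for (sh in unique(slot_head[r == rl])) {
        rows <- which(r == rl & slot_head == sh)
        pool <- unique(unlist(nodes_by_type[
          if (sh) sig$head_types else sig$tail_types
        ], use.names = FALSE))
        orig <- if (sh) h[rows] else t[rows]
        x <- pool[sample.int(length(pool), length(rows), replace = TRUE)]
        bad <- x == orig
        if (mode == "filtered") {
          key <- if (sh) paste(x, rl, t[rows], sep = "\r") else
            paste(h[rows], rl, x, sep = "\r")
          bad <- bad | key %in% pos_keys
        }
        tries <- 0L
        while (any(bad) && tries < 50L) {
          nb <- sum(bad)
          x[bad] <- pool[sample.int(length(pool), nb, replace = TRUE)]
          bad <- x == orig
          if (mode == "filtered") {
            key <- if (sh) paste(x, rl, t[rows], sep = "\r") else
              paste(h[rows], rl, x, sep = "\r")
            bad <- bad | key %in% pos_keys
          }
          tries <- tries + 1L
        }
        # retries exhausted: enumerate candidates exactly per offending row
        for (q in which(bad)) {
          keys <- if (sh) paste(pool, rl, t[rows[q]], sep = "\r") else
            paste(h[rows[q]], rl, pool, sep = "\r")
          ok <- pool != orig[q]
          if (mode == "filtered") ok <- ok & !(keys %in% pos_keys)
          if (!any(ok)) {
            stop_mmkge("mmkge_sampling_infeasible_error",
                       paste0("no admissible corruption for triple ",
                              "(%s, %s, %s): compatible pool exhausted"),
                       h[rows[q]], rl, t[rows[q]])
          }
          left <- pool[ok]
          x[q] <- left[sample.int(length(left), 1L)]
        }
        cand[rows] <- x
      }
    }
    data.frame(head = ifelse(slot_head, cand, h), relation = r,
               tail = ifelse(slot_head, t, cand), stringsAsFactors = FALSE)
  })
  rbind(cbind(positives[, c("head", "relation", "tail")], label = 1L),
        cbind(negs, label = 0L))
}

# Undirected adjacency list over node indices (1..n), ignoring relation labels.
adjacency_list <- function(kg) {
  idx <- setNames(seq_len(n_nodes(kg)), kg$nodes$node_id)
  h <- idx[kg$triples$head]
  t <- idx[kg$triples$tail]
  adj <- vector("list", n_nodes(kg))
  both <- split(c(t, h), c(h, t))
  for (nm in names(both)) adj[[as.integer(nm)]] <- unname(both[[nm]])
  adj
}

#' Random-walk node-induced subgraph (GraphSAINT-style sampler)
#'
#' Samples `num_roots` root nodes uniformly without replacement, runs a
#' `walk_length`-step random walk from each over the undirected view of the
#' graph (relation labels ignored during walking), and returns the subgraph
#' induced on the union of visited nodes, retaining all triples among them.
#' Deterministic given `seed`.
#'
#' @param kg A [knowledge_graph()].
#' @param walk_length Steps per walk (>= 1).
#' @param num_roots Number of walk roots (>= 1; capped at the node count).
#' @param seed Integer seed.
#' @return A [knowledge_graph()] on the visited nodes, with the root node ids
#'   in attribute `"roots"`.
#' @export
random_walk_subgraph <- function(kg, walk_length = 10L, num_roots = 100L,
                                 seed = 1L) {
  if (n_nodes(kg) == 0L) stop_mmkge("mmkge_config_error", "empty graph")
  if (walk_length < 1 || num_roots < 1) {
    stop_mmkge("mmkge_config_error", "walk_length and num_roots must be >= 1")
  }
  adj <- adjacency_list(kg)
  n <- n_nodes(kg)
  visited <- with_seed(seed, {
    roots <- sample.int(n, min(num_roots, n))
    seen <- logical(n)
    seen[roots] <- TRUE
    for (v0 in roots) {
      v <- v0
      for (s in seq_len(walk_length)) {
        nb <- adj[[v]]
        if (length(nb) == 0L) break
        v <- nb[sample.int(length(nb), 1L)]
        seen[v] <- TRUE
      }
    }
    list(seen = seen, roots = roots)
  })
  ids <- kg$nodes$node_id[visited$seen]
  keep <- kg$triples$head %in% ids & kg$triples$tail %in% ids
  sub <- knowledge_graph(kg$nodes[visited$seen, , drop = FALSE],
                         kg$triples[keep, , drop = FALSE],
                         modalities = kg$modalities)
  # relations must keep the parent ordering even if some are absent here
  sub$relations <- intersect(kg$relations, sub$relations)
  attr(sub, "roots") <- kg$nodes$node_id[visited$roots]
  sub
}
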