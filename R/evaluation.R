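#' Average precision of a ranking
#'
#' Step-interpolated average precision over the descending-score ranking:
#' `AP = sum_k P@k * (R@k - R@k-1)`, summing precision at every rank that
#' holds a positive. Ties are broken by stable original order (the earlier
#' item keeps the better rank).
#'
#' @param scores Numeric scores (higher = more confident positive).
#' @param labels 0/1 labels, at least one positive.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop_mmkge("mmkge_shape_error", "scores/labels length mismatch")
  }
  if (sum(labels == 1) == 0) {
    stop_mmkge("mmkge_undefined_metric_error",
               "average precision undefined without positives")
  }
  ord <- order(-scores)  # stable: ties keep original order
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

#' F1 score at a probability threshold
#'
#' `F1 = 2PR / (P + R)` with predictions `score >= threshold`; returns 0
#' when precision and recall are both zero.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels containing both classes.
#' @param threshold Decision threshold (default 0.5).
#' @return F1 in `[0, 1]`.
#' @export
f1_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (length(unique(labels)) < 2) {
    stop_mmkge("mmkge_undefined_metric_error",
               "F1 undefined for single-class labels")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (tp == 0 && (fp == 0 || fn == 0) && (tp + fp + fn) == 0) return(0)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# Full positive set of a split (for filtered evaluation sampling).
split_full_kg <- function(model, split) {
  kg_full <- model$graph
  kg_full$triples <- rbind(split$train, split$valid, split$test)
  kg_full$relations <- model$relations
  kg_full
}

#' Evaluate a link predictor on a positive triple set
#'
#' Scores the positives together with `ratio_k` filtered negatives per
#' positive and reports average precision and F1 at 0.5.
#'
#' @param model A [train_link_predictor()] result.
#' @param split The `edge_split` the model was trained on (supplies the
#'   full positive set for filtering).
#' @param partition Which partition to evaluate (default `"test"`).
#' @param ratio_k Negatives per positive.
#' @param seed Seed fixing the evaluation negatives.
#' @return List with `ap`, `f1`, `scores`, `labels`.
#' @export
evaluate_link_predictor <- function(model, split, partition = "test",
                                    ratio_k = 1L, seed = NULL) {
  if (is.null(seed)) seed <- derive_seed(split$seed, "eval_negs", ratio_k)
  kg_full <- split_full_kg(model, split)
  labeled <- sample_negatives(kg_full, split[[partition]], ratio_k,
                              mode = "filtered", seed = seed)
  probs <- predict_links(model, labeled)
  list(ap = average_precision(probs, labeled$label),
       f1 = f1_at_threshold(probs, labeled$label),
       scores = probs, labels = labeled$label)
}

#' Per-relation precision table
#'
#' For every relation of the model: precision at threshold 0.5 over that
#' relation's positives in the evaluated partition plus `ratio_k` filtered
#' negatives sampled per relation, along with the positive-edge count.
#' Relations with zero positives are flagged, not dropped. Rows are sorted
#' by relation label.
#'
#' @param model A [train_link_predictor()] result.
#' @param split The `edge_split` the model was trained on.
#' @param ratio_k Negatives per positive (default 10).
#' @param partition Partition to evaluate (default `"test"`).
#' @param seed Seed fixing the negatives.
#' @return Data frame `relation, precision, n_pos, flagged`.
#' @export
per_relation_precision <- function(model, split, ratio_k = 10L,
                                   partition = "test", seed = NULL) {
  if (is.null(seed)) seed <- derive_seed(split$seed, "relprec", ratio_k)
  kg_full <- split_full_kg(model, split)
  pos <- split[[partition]]
  rels <- sort(model$relations)
  rows <- lapply(rels, function(r) {
    pr <- pos[pos$relation == r, , drop = FALSE]
    if (nrow(pr) == 0) {
      return(data.frame(relation = r, precision = NA_real_, n_pos = 0L,
                        flagged = TRUE))
    }
    labeled <- sample_negatives(kg_full, pr, ratio_k, mode = "filtered",
                                seed = derive_seed(seed, r))
    p <- predict_links(model, labeled)
    pred <- p >= 0.5
    prec <- if (!any(pred)) 0 else
      sum(pred & labeled$label == 1) / sum(pred)
    data.frame(relation = r, precision = prec, n_pos = nrow(pr),
               flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' Configuration for the benchmark grid
#'
#' Enumerates initialization regimes (`random`: random features; `direct`:
#' fused encoder output; `gcl`: contrastively refined), fusion methods, GCL
#' objectives and negative-sampling ratios. All cells share the same edge
#' split and the same evaluation negatives per ratio (controlled
#' comparison).
#'
#' @param init_regimes,fusions,gcl_objectives,ratios Grid axes.
#' @param seeds Integer vector of replicate seeds.
#' @param d_embed Encoder output dimension (default 768).
#' @param dim Fusion / embedding dimension (default 128).
#' @param split_seed Seed of the shared edge split.
#' @param gcl Baseline [gcl_config()] (seed overridden per replicate).
#' @param kge Baseline [kge_config()] (seed and ratio overridden per cell).
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(init_regimes = c("random", "direct", "gcl"),
                             fusions = c("none", "attention", "redaf"),
                             gcl_objectives = c("dgi", "ggd", "grace"),
                             ratios = c(1L, 3L, 5L),
                             seeds = c(1L, 2L, 3L),
                             d_embed = 768L, dim = 128L, split_seed = 1L,
                             gcl = gcl_config(), kge = kge_config()) {
  if (length(init_regimes) == 0 || length(ratios) == 0 ||
      length(seeds) == 0) {
    stop_mmkge("mmkge_config_error", "benchmark grid is empty")
  }
  structure(as.list(environment()), class = "benchmark_config")
}

#' Run the initialization/fusion/objective benchmark grid
#'
#' Trains and evaluates a link predictor for every grid cell with shared
#' split and evaluation seeds; any cell failure is recorded and the run
#' continues. Returns per-cell rows and the seed-averaged summary.
#'
#' @param kg A [knowledge_graph()].
#' @param config A [benchmark_config()].
#' @return An object of class `eval_report`: `rows` (per seed),
#'   `summary` (seed-averaged, columns `init,fusion,gcl,ratio,ap,f1`),
#'   `errors`, `split_seed`.
#' @export
run_benchmark <- function(kg, config = benchmark_config()) {
  split <- split_edges(kg, seed = config$split_seed)
  rows <- list()
  errors <- list()

  for (s in config$seeds) {
    # initialization regimes -> named list of feature matrices + grid labels
    feats <- list()
    if ("random" %in% config$init_regimes) {
      X <- with_seed(derive_seed(s, "random_init"),
                     matrix(rnorm(n_nodes(kg) * config$dim,
                                  0, 1 / sqrt(config$dim)),
                            n_nodes(kg), config$dim))
      rownames(X) <- kg$nodes$node_id
      feats[["random|-|-"]] <- X
    }
    if (any(c("direct", "gcl") %in% config$init_regimes)) {
      enc <- encode_kg_modalities(kg, d_embed = config$d_embed, seed = s)
      for (fu in config$fusions) {
        fused <- fuse_nodes(enc, method = fu, dim = config$dim,
                            relations = kg$relations,
                            seed = derive_seed(s, "fusion", fu))
        if ("direct" %in% config$init_regimes) {
          feats[[paste("direct", fu, "-", sep = "|")]] <- fused$matrix
        }
        if ("gcl" %in% config$init_regimes) {
          for (obj in config$gcl_objectives) {
            cfg <- config$gcl
            cfg$seed <- derive_seed(s, "gcl", fu, obj)
            res <- pretrain_gcl(kg, fused, obj, cfg)
            feats[[paste("gcl", fu, obj, sep = "|")]] <- res$embeddings
          }
        }
      }
    }

    for (nm in names(feats)) {
      lab <- strsplit(nm, "|", fixed = TRUE)[[1]]
      for (k in config$ratios) {
        cell <- sprintf("%s ratio 1:%d seed %d", nm, k, s)
        out <- tryCatch({
          kcfg <- config$kge
          kcfg$ratio_k <- as.integer(k)
          kcfg$seed <- derive_seed(s, "kge", nm, k)
          model <- train_link_predictor(kg, split, feats[[nm]], kcfg)
          ev <- evaluate_link_predictor(model, split, ratio_k = k)
          data.frame(init = lab[1], fusion = lab[2], gcl = lab[3],
                     ratio = k, seed = s, ap = ev$ap, f1 = ev$f1)
        }, error = function(e) e)
        if (inherits(out, "error")) {
          errors[[cell]] <- conditionMessage(out)
        } else {
          rows[[cell]] <- out
        }
      }
    }
  }

  rows <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  summary <- stats::aggregate(cbind(ap, f1) ~ init + fusion + gcl + ratio,
                              data = rows, FUN = mean)
  summary <- summary[order(summary$init, summary$fusion, summary$gcl,
                           summary$ratio), ]
  structure(list(rows = rows, summary = summary, errors = errors,
                 split_seed = config$split_seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$summary, row.names = FALSE)
  if (length(x$errors)) {
    cat(sprintf("%d cell(s) failed: %s\n", length(x$errors),
                paste(names(x$errors), collapse = "; ")))
  }
  invisible(x)
}

#' Write an evaluation report to CSV
#'
#' Seed-averaged summary with columns exactly
#' `init,fusion,gcl,ratio,ap,f1`.
#'
#' @param report An `eval_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  write.csv(report$summary[, c("init", "fusion", "gcl", "ratio", "ap", "f1")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export node embeddings for latent-space inspection
#'
#' Dumps an embedding matrix restricted to a node filter in the modality
#' matrix dialect (dense TSV plus newline-delimited id index). Optionally
#' writes an interaction-label sidecar marking which exported drugs are
#' adjacent to a chosen protein through drug-protein relations, for
#' external 2-D projection and plotting.
#'
#' @param x A `gcl_result`, `link_predictor`, [fused_embeddings()], or a
#'   numeric matrix with node-id row names.
#' @param prefix Output path prefix (`<prefix>.tsv`, `<prefix>.index`, and
#'   optionally `<prefix>.labels.tsv`).
#' @param node_filter Character vector of node ids to export (default all).
#' @param kg Knowledge graph used for the interaction sidecar.
#' @param protein Node id whose interactors get label 1 in the sidecar.
#' @return The exported [modality_matrix()], invisibly.
#' @export
export_embeddings <- function(x, prefix, node_filter = NULL, kg = NULL,
                              protein = NULL) {
  Z <- if (inherits(x, "gcl_result")) x$embeddings
  else if (inherits(x, "link_predictor")) rgcn_encode(x$graph, x$X_init,
                                                      x$params)
  else if (inherits(x, "fused_embeddings")) x$matrix
  else as.matrix(x)
  if (is.null(rownames(Z))) {
    stop_mmkge("mmkge_data_error", "embedding matrix lacks node-id row names")
  }
  ids <- rownames(Z)
  if (!is.null(node_filter)) ids <- intersect(ids, node_filter)
  if (length(ids) == 0) {
    stop_mmkge("mmkge_config_error", "node filter selects no nodes")
  }
  mm <- modality_matrix("embedding", ids, Z[ids, , drop = FALSE])
  write_modality_matrix(mm, prefix)
  if (!is.null(kg) && !is.null(protein)) {
    tr <- kg$triples
    type_of <- setNames(kg$nodes$node_type, kg$nodes$node_id)
    dp <- tr[(tr$head == protein & type_of[tr$tail] == "drug") |
               (tr$tail == protein & type_of[tr$head] == "drug"), ]
    partners <- unique(c(dp$head, dp$tail))
    utils::write.table(
      data.frame(node_id = ids,
                 interacts = as.integer(ids %in% partners)),
      paste0(prefix, ".labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(mm)
}
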