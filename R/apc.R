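# Automatic phenotype classification: marker-keyed cluster features, an
# incremental training store, bagged-forest lineage classification, and
# rule-based refinement of diagnostic subsets within each lineage.

#' Cluster feature table
#'
#' One row per cluster.  The layout is determined by the tube's normalized
#' marker list sorted lexicographically -- per-marker transformed median and
#' ordinal five-level code -- followed by the cluster's fraction of cleaned
#' events and its FSC-A/SSC-A medians normalized by the sample's 95th
#' percentiles.  Keying features by marker name (not detector or
#' fluorochrome) is what lets a model transfer across reagent or color
#' scheme changes.
#'
#' @param clusters a `cg_clusters`.
#' @param tube the `cg_tube` the sample was matched to.
#' @return numeric matrix, rows = clusters.
#' @export
featurize <- function(clusters, tube) {
  stopifnot(inherits(clusters, "cg_clusters"))
  markers <- sort(tube$channels$marker_norm)
  miss <- setdiff(markers, clusters$markers)
  if (length(miss))
    cg_stop("cg_feature_error", "cluster set lacks tube marker(s): %s",
            paste(miss, collapse = ", "))
  extra <- setdiff(clusters$markers, markers)
  if (length(extra))
    cg_stop("cg_feature_error", "cluster set has marker(s) absent from tube: %s",
            paste(extra, collapse = ", "))
  K <- nrow(clusters$clusters)
  med <- clusters$medians[, markers, drop = FALSE]
  lvl <- clusters$codes[, markers, drop = FALSE]
  X <- matrix(0, K, 2 * length(markers) + 3)
  X[, seq(1, by = 2, length.out = length(markers))] <- med
  X[, seq(2, by = 2, length.out = length(markers))] <- lvl
  X[, 2 * length(markers) + 1] <- clusters$clusters$frac
  X[, 2 * length(markers) + 2] <- clusters$clusters$fsc_med / clusters$scatter_q95["fsc"]
  X[, 2 * length(markers) + 3] <- clusters$clusters$ssc_med / clusters$scatter_q95["ssc"]
  colnames(X) <- c(rbind(paste0("med_", markers), paste0("lvl_", markers)),
                   "frac", "fsc_med", "ssc_med")
  rownames(X) <- clusters$clusters$id
  X
}

#' Create an empty training store
#'
#' The store is append-only: labeled cluster features accumulate per tube
#' and earlier entries are never mutated, so incremental training is
#' append-and-retrain and fully reproducible.
#'
#' @param panel a `cg_panel`; fixes the per-tube label vocabulary
#'   (lineages plus configured non-lymphocyte labels).
#' @return a `cg_store`.
#' @export
new_store <- function(panel) {
  vocab <- lapply(names(panel$tubes), function(tb) lineage_labels(panel, tb))
  names(vocab) <- names(panel$tubes)
  structure(list(
    entries = lapply(vocab, function(...) list(features = NULL, labels = character(0),
                                               case_id = character(0),
                                               timestamp = character(0))),
    vocab = vocab
  ), class = "cg_store")
}

#' Append labeled clusters to a training store
#'
#' @param store a `cg_store`.
#' @param tube tube name.
#' @param features a [featurize()] matrix.
#' @param labels character labels, one per feature row, drawn from the
#'   tube's vocabulary.
#' @param case_id identifier of the contributing case.
#' @return the grown store (prior entries untouched).
#' @export
update_store <- function(store, tube, features, labels, case_id = "case") {
  stopifnot(inherits(store, "cg_store"))
  if (!tube %in% names(store$vocab))
    cg_stop("cg_vocab_error", "unknown tube '%s'", tube)
  bad <- setdiff(unique(labels), store$vocab[[tube]])
  if (length(bad))
    cg_stop("cg_vocab_error", "label(s) not in the '%s' vocabulary: %s",
            tube, paste(bad, collapse = ", "))
  stopifnot(nrow(features) == length(labels))
  e <- store$entries[[tube]]
  if (!is.null(e$features) && !identical(colnames(e$features), colnames(features)))
    cg_stop("cg_feature_error", "feature layout differs from stored entries")
  rownames(features) <- NULL
  e$features <- rbind(e$features, features)
  e$labels <- c(e$labels, as.character(labels))
  e$case_id <- c(e$case_id, rep(case_id, length(labels)))
  e$timestamp <- c(e$timestamp, rep(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                    length(labels)))
  store$entries[[tube]] <- e
  store
}

#' Number of stored examples per tube
#' @param store a `cg_store`.
#' @return named integer vector.
#' @export
store_size <- function(store) {
  vapply(store$entries, function(e) length(e$labels), 1L)
}

#' Save / load a training store
#'
#' Stores round-trip losslessly through a single JSON file.
#' @param store a `cg_store`.
#' @param path file path.
#' @return `save_store`: the path, invisibly; `load_store`: the store.
#' @export
save_store <- function(store, path) {
  doc <- list(vocab = store$vocab,
              entries = lapply(store$entries, function(e) list(
                feature_names = colnames(e$features),
                features = if (is.null(e$features)) list() else
                  apply(e$features, 1, function(r) as.list(unname(r)), simplify = FALSE),
                labels = e$labels, case_id = e$case_id, timestamp = e$timestamp)))
  cg_write_json(doc, path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  doc <- cg_read_json(path)
  entries <- lapply(doc$entries, function(e) {
    feats <- NULL
    if (length(e$features)) {
      feats <- do.call(rbind, lapply(e$features, function(r) as.numeric(unlist(r))))
      colnames(feats) <- unlist(e$feature_names)
    }
    list(features = feats, labels = as.character(unlist(e$labels)),
         case_id = as.character(unlist(e$case_id)),
         timestamp = as.character(unlist(e$timestamp)))
  })
  structure(list(entries = entries,
                 vocab = lapply(doc$vocab, function(v) as.character(unlist(v)))),
            class = "cg_store")
}

#' Train the per-tube cluster classifier
#'
#' Fits a bagged random forest on the tube's stored labeled cluster
#' features.  Requires at least two labels with at least five examples
#' each; the out-of-bag accuracy is recorded on the model.
#'
#' @param store a `cg_store`.
#' @param tube tube name.
#' @param n_trees forest size (default 200).
#' @param seed RNG seed; `(store, seed)` reproduces the model exactly.
#' @return a `cg_apc_model`.
#' @export
train_classifier <- function(store, tube, n_trees = 200, seed = 1) {
  e <- store$entries[[tube]]
  if (is.null(e) || length(e$labels) == 0)
    cg_stop("cg_training_error", "no training examples for tube '%s'", tube)
  counts <- table(e$labels)
  deficient <- names(counts)[counts < 5]
  if (length(counts) < 2 || length(deficient))
    cg_stop("cg_training_error",
            "need >= 2 labels with >= 5 examples each%s",
            if (length(deficient))
              paste0("; deficient: ", paste(deficient, collapse = ", "))
            else "")
  forest <- cg_forest(e$features, e$labels, n_trees = n_trees, seed = seed)
  structure(list(tube = tube, forest = forest, vocab = store$vocab[[tube]],
                 n_train = length(e$labels), seed = seed,
                 oob_accuracy = forest$oob_accuracy,
                 version = as.character(utils::packageVersion("cytogate"))),
            class = "cg_apc_model")
}

#' Classify clusters into lineages
#'
#' Majority vote over the forest; clusters whose top vote fraction falls
#' below `low_confidence` are flagged for manual review.
#'
#' @param model a `cg_apc_model`.
#' @param features a [featurize()] matrix (may have zero rows).
#' @param low_confidence review-flag threshold on the top probability
#'   (default 0.7).
#' @return data frame: `cluster`, `label`, `probability`,
#'   `low_confidence`.
#' @export
classify_clusters <- function(model, features, low_confidence = 0.7) {
  stopifnot(inherits(model, "cg_apc_model"))
  if (nrow(features) == 0)
    return(data.frame(cluster = integer(0), label = character(0),
                      probability = numeric(0), low_confidence = logical(0)))
  prob <- predict(model$forest, features)
  top <- max.col(prob, ties.method = "first")
  data.frame(
    cluster = as.integer(rownames(features)),
    label = model$forest$labels[top],
    probability = prob[cbind(seq_len(nrow(prob)), top)],
    low_confidence = prob[cbind(seq_len(nrow(prob)), top)] < low_confidence
  )
}

predicates_hold <- function(code, predicates) {
  for (p in predicates) {
    v <- code[[p$marker]]
    if (is.null(v) || is.na(v))
      cg_stop("cg_taxonomy_error", "predicate references marker '%s' absent from tube",
              p$marker)
    if (v < p$min || v > p$max) return(FALSE)
  }
  TRUE
}

#' Refine lineage labels into diagnostic subsets
#'
#' Events inherit their cluster's lineage; within each lineage the tube's
#' taxonomy is walked top-down, assigning the first primary child whose
#' marker-level predicates hold on the cluster's phenotype code (so the
#' deepest label per event is unique and subset counts roll up exactly).
#' Secondary subsets (crossing marker axes such as light chains) are
#' recorded as additional memberships without affecting the partition.
#'
#' @param clusters a `cg_clusters`.
#' @param lineages a [classify_clusters()] data frame (or a character
#'   vector of per-cluster lineage labels).
#' @param tube the `cg_tube`.
#' @param panel the `cg_panel` carrying the taxonomy.
#' @return a `cg_labels` object (per-event cluster ids plus per-cluster
#'   label paths).
#' @export
refine_subsets <- function(clusters, lineages, tube, panel) {
  stopifnot(inherits(clusters, "cg_clusters"))
  if (is.data.frame(lineages)) {
    lab <- lineages$label[order(lineages$cluster)]
    prob <- lineages$probability[order(lineages$cluster)]
    lowc <- lineages$low_confidence[order(lineages$cluster)]
  } else {
    lab <- as.character(lineages)
    prob <- rep(NA_real_, length(lab))
    lowc <- rep(FALSE, length(lab))
  }
  K <- nrow(clusters$clusters)
  stopifnot(length(lab) == K)
  nodes <- tube_taxonomy(panel, tube$name)
  node_names <- vapply(nodes, `[[`, "", "name")

  paths <- vector("list", K)
  secondary <- vector("list", K)
  deepest <- character(K)
  for (c in seq_len(K)) {
    code <- as.list(clusters$codes[c, ])
    if (!(lab[c] %in% node_names)) {           # non-lymphocyte label
      paths[[c]] <- lab[c]
      secondary[[c]] <- character(0)
      deepest[c] <- lab[c]
      next
    }
    path <- c("lymphocytes", lab[c])
    cur <- lab[c]
    repeat {
      kids <- tax_children(nodes, cur, primary_only = TRUE)
      nxt <- NULL
      for (kid in kids)
        if (length(kid$predicates) && predicates_hold(code, kid$predicates)) {
          nxt <- kid$name; break
        }
      if (is.null(nxt)) break
      path <- c(path, nxt)
      cur <- nxt
    }
    sec <- character(0)
    for (nd in nodes)
      if (nd$secondary && nd$parent %in% path &&
          predicates_hold(code, nd$predicates))
        sec <- c(sec, nd$name)
    paths[[c]] <- path
    secondary[[c]] <- sec
    deepest[c] <- cur
  }

  structure(list(
    cluster_id = clusters$assignment,
    clusters = data.frame(id = seq_len(K), lineage = lab, deepest = deepest,
                          probability = prob, low_confidence = lowc,
                          size = clusters$clusters$size),
    paths = paths,
    secondary = secondary,
    tube = tube$name
  ), class = "cg_labels")
}
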