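# Bagged random-forest classifier: CART trees on bootstrap resamples with
# per-node random feature subsets (Gini impurity), majority vote across
# trees, and out-of-bag accuracy.  Authored here because no tree/ensemble
# package is assumed at runtime; the training sets (cluster feature tables)
# are small, so plain R recursion is adequate.

gini_best_split <- function(x, y, n_classes) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)
  cut_ok <- which(xs[-n] < xs[-1])
  if (length(cut_ok) == 0) return(NULL)
  counts <- matrix(0L, n, n_classes)
  counts[cbind(seq_len(n), ys)] <- 1L
  cum <- apply(counts, 2, cumsum)
  nl <- seq_len(n)
  tot <- cum[n, ]
  gl <- 1 - rowSums(cum^2) / nl^2
  cr <- sweep(-cum, 2, tot, `+`)
  nr <- n - nl
  gr <- 1 - rowSums(cr^2) / pmax(nr, 1L)^2
  score <- (nl * gl + nr * gr) / n
  i <- cut_ok[which.min(score[cut_ok])]
  list(threshold = (xs[i] + xs[i + 1]) / 2, score = score[i])
}

grow_tree <- function(X, y, mtry, min_n, n_classes) {
  nodes <- list()
  build <- function(idx) {
    yy <- y[idx]
    counts <- tabulate(yy, n_classes)
    pred <- which.max(counts)
    node_id <- length(nodes) + 1L
    nodes[[node_id]] <<- list(feature = NA_integer_, threshold = NA_real_,
                              left = NA_integer_, right = NA_integer_,
                              pred = pred)
    if (length(idx) < min_n || max(counts) == length(idx)) return(node_id)
    feats <- sample.int(ncol(X), mtry)
    best <- NULL; best_f <- NA_integer_
    for (f in feats) {
      sp <- gini_best_split(X[idx, f], yy, n_classes)
      if (!is.null(sp) && (is.null(best) || sp$score < best$score)) {
        best <- sp; best_f <- f
      }
    }
    if (is.null(best)) return(node_id)
    go_left <- X[idx, best_f] <= best$threshold
    l <- build(idx[go_left])
    r <- build(idx[!go_left])
    nodes[[node_id]] <<- list(feature = best_f, threshold = best$threshold,
                              left = l, right = r, pred = pred)
    node_id
  }
  build(seq_along(y))
  data.frame(feature = vapply(nodes, `[[`, 1L, "feature"),
             threshold = vapply(nodes, `[[`, 1, "threshold"),
             left = vapply(nodes, `[[`, 1L, "left"),
             right = vapply(nodes, `[[`, 1L, "right"),
             pred = vapply(nodes, `[[`, 1L, "pred"))
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  pos <- rep(1L, n)
  repeat {
    feat <- tree$feature[pos]
    inner <- !is.na(feat)
    if (!any(inner)) break
    ii <- which(inner)
    go_left <- X[cbind(ii, feat[ii])] <= tree$threshold[pos[ii]]
    pos[ii] <- ifelse(go_left, tree$left[pos[ii]], tree$right[pos[ii]])
  }
  tree$pred[pos]
}

#' Train a bagged random forest
#'
#' @param X numeric feature matrix (rows = examples).
#' @param y character or factor labels.
#' @param n_trees number of bootstrap trees (default 200).
#' @param mtry features tried per split (default `floor(sqrt(ncol(X)))`).
#' @param min_n minimum node size to attempt a split (default 2).
#' @param seed RNG seed; the same `(X, y, seed)` gives an identical model.
#' @return a `cg_forest` with trees, label vocabulary and out-of-bag
#'   accuracy.
#' @export
cg_forest <- function(X, y, n_trees = 200, mtry = NULL, min_n = 2, seed = 1) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  labels <- sort(unique(as.character(y)))
  yi <- match(as.character(y), labels)
  L <- length(labels)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  n <- nrow(X)
  oob_votes <- matrix(0L, n, L)
  trees <- vector("list", n_trees)
  with_seed(seed, {
    for (t in seq_len(n_trees)) {
      boot <- sample.int(n, n, replace = TRUE)
      trees[[t]] <- grow_tree(X[boot, , drop = FALSE], yi[boot], mtry, min_n, L)
      oob <- setdiff(seq_len(n), boot)
      if (length(oob)) {
        pred <- predict_tree(trees[[t]], X[oob, , drop = FALSE])
        oob_votes[cbind(oob, pred)] <- oob_votes[cbind(oob, pred)] + 1L
      }
    }
  })
  voted <- rowSums(oob_votes) > 0
  oob_pred <- max.col(oob_votes[voted, , drop = FALSE], ties.method = "first")
  structure(list(
    trees = trees, labels = labels, mtry = mtry, n_trees = n_trees,
    min_n = min_n, seed = seed,
    feature_names = colnames(X), n_train = n,
    oob_accuracy = mean(oob_pred == yi[voted])
  ), class = "cg_forest")
}

#' Forest class probabilities
#'
#' @param object a `cg_forest`.
#' @param X feature matrix with the model's feature layout.
#' @param ... unused.
#' @return matrix (rows = examples) of per-label vote fractions; rows sum
#'   to 1.
#' @export
predict.cg_forest <- function(object, X, ...) {
  stopifnot(is.matrix(X))
  if (!is.null(object$feature_names) &&
      !identical(colnames(X), object$feature_names))
    cg_stop("cg_feature_error", "feature layout does not match the trained model")
  votes <- matrix(0L, nrow(X), length(object$labels))
  if (nrow(X) > 0)
    for (tree in object$trees) {
      pred <- predict_tree(tree, X)
      votes[cbind(seq_len(nrow(X)), pred)] <- votes[cbind(seq_len(nrow(X)), pred)] + 1L
    }
  prob <- votes / object$n_trees
  colnames(prob) <- object$labels
  prob
}
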