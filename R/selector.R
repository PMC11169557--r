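# Model-family recommendation from (dataset size, scaffold diversity):
# the published-style rule heuristic, and a greedy tree-sums meta-classifier
# (an additive ensemble of shallow decision trees grown greedily across
# trees, in the FIGS family) learned from benchmark winners.

.families <- c("TRANSFORMER", "CLASSICAL", "FSLC")

#' Rule-based model-family recommendation
#'
#' The size/diversity heuristic: below \code{small} molecules the few-shot
#' classifier dominates; between \code{small} and \code{large} molecules the
#' middle zone goes to a pre-trained transformer when diversity is at or
#' above \code{div_cut} and to a classical model otherwise; above
#' \code{large} molecules classical models win.
#'
#' @param n_molecules dataset size.
#' @param div scaffold diversity score in [0, 1).
#' @param small,large zone boundaries (defaults 50 and 240; the zones are
#'   n < small, small <= n <= large, n > large).
#' @param div_cut middle-zone diversity cut (default 0.5).
#' @return a \code{recommendation}: list with \code{family},
#'   \code{rule_fired}, \code{rationale}.
#' @export
#' @examples
#' recommend_rule(18, 0.3)$family   # FSLC
#' recommend_rule(100, 0.8)$family  # TRANSFORMER
#' recommend_rule(2969, 0.52)$family  # CLASSICAL
recommend_rule <- function(n_molecules, div, small = 50, large = 240,
                           div_cut = 0.5) {
  stopifnot(n_molecules >= 1, div >= 0, div < 1, small < large)
  if (n_molecules < small) {
    fam <- "FSLC"; rule <- sprintf("n < %d", small)
    why <- "few-shot classifiers dominate on very small datasets"
  } else if (n_molecules > large) {
    fam <- "CLASSICAL"; rule <- sprintf("n > %d", large)
    why <- "classical fingerprint models win once data is plentiful"
  } else if (div >= div_cut) {
    fam <- "TRANSFORMER"
    rule <- sprintf("%d <= n <= %d and div >= %.2f", small, large, div_cut)
    why <- "mid-size diverse sets favor pre-trained transformers"
  } else {
    fam <- "CLASSICAL"
    rule <- sprintf("%d <= n <= %d and div < %.2f", small, large, div_cut)
    why <- "mid-size homogeneous sets stay with classical models"
  }
  structure(list(family = fam, rule_fired = rule, rationale = why),
            class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("recommend %s (%s): %s\n", x$family, x$rule_fired,
              x$rationale))
  invisible(x)
}

#' Label benchmark winners
#'
#' Adds a \code{winner} column: the family whose decision metric is highest
#' per row; exact ties break toward CLASSICAL.
#'
#' @param table data.frame with columns \code{dataset_id},
#'   \code{n_molecules}, \code{div} and one numeric metric column per
#'   family (named by family).
#' @param families which columns to compare (default: all family columns
#'   present).
#' @return the table with a \code{winner} column.
#' @export
label_winners <- function(table, families = intersect(.families,
                                                      names(table))) {
  if (length(families) < 2)
    stop("need metric columns for at least two families", call. = FALSE)
  scores <- as.matrix(table[, families, drop = FALSE])
  if (any(!is.finite(scores)))
    stop("non-finite family metrics", call. = FALSE)
  table$winner <- apply(scores, 1, function(r) {
    top <- families[r == max(r)]
    if ("CLASSICAL" %in% top) "CLASSICAL" else top[1]
  })
  table
}

# ---- greedy tree sums -----------------------------------------------------
# Trees are stored as a data.frame of nodes: id, feature (NA = leaf),
# threshold, left, right, and one value column per class. Prediction is the
# softmax of the summed leaf vectors across trees.

new_leaf_tree <- function(n_classes) {
  data.frame(id = 1L, feature = NA_integer_, threshold = NA_real_,
             left = NA_integer_, right = NA_integer_, depth = 0L,
             matrix(0, 1, n_classes,
                    dimnames = list(NULL, paste0("v", seq_len(n_classes)))))
}

tree_leaf_of <- function(tree, X) {
  vapply(seq_len(nrow(X)), function(i) {
    node <- 1L
    repeat {
      row <- tree[tree$id == node, ]
      if (is.na(row$feature)) return(node)
      node <- if (X[i, row$feature] <= row$threshold) row$left else row$right
    }
  }, integer(1))
}

tree_predict_raw <- function(tree, X, n_classes) {
  leaves <- tree_leaf_of(tree, X)
  vals <- as.matrix(tree[, paste0("v", seq_len(n_classes)), drop = FALSE])
  vals[match(leaves, tree$id), , drop = FALSE]
}

# best split of the points `idx` on residual matrix R: squared-error
# impurity; ties broken by lowest feature index then lowest threshold
best_split <- function(X, R, idx, min_leaf) {
  parent_sse <- sum(sweep(R[idx, , drop = FALSE], 2,
                          colMeans(R[idx, , drop = FALSE]))^2)
  best <- list(gain = 0)
  for (j in seq_len(ncol(X))) {
    v <- X[idx, j]
    cuts <- sort(unique(v))
    if (length(cuts) < 2) next
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (th in mids) {
      li <- idx[v <= th]; ri <- idx[v > th]
      if (length(li) < min_leaf || length(ri) < min_leaf) next
      sse <- sum(sweep(R[li, , drop = FALSE], 2,
                       colMeans(R[li, , drop = FALSE]))^2) +
             sum(sweep(R[ri, , drop = FALSE], 2,
                       colMeans(R[ri, , drop = FALSE]))^2)
      gain <- parent_sse - sse
      if (gain > best$gain + 1e-12) best <- list(gain = gain, feature = j,
                                                 threshold = th)
    }
  }
  best
}

#' Fit a greedy tree-sums meta-classifier
#'
#' An additive ensemble of at most \code{max_trees} shallow decision trees
#' fit greedily: at every step each current leaf of each tree (and the root
#' of a potential new tree) is evaluated for its best split of the one-hot
#' residuals (class indicators minus the other trees' summed predictions),
#' and the single split with the largest squared-error impurity reduction is
#' committed. Fitting stops when no split improves or limits are reached.
#' Class probabilities are the softmax of the summed leaf vectors.
#'
#' @param X numeric feature matrix (columns, e.g., dataset size and
#'   diversity) or data.frame.
#' @param y class labels (e.g. winning family names).
#' @param max_trees maximum number of trees (default 3).
#' @param max_depth maximum tree depth.
#' @param min_leaf minimum points per leaf.
#' @return a \code{tree_sum_model}.
#' @export
figs_fit <- function(X, y, max_trees = 3, max_depth = 4, min_leaf = 5) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  classes <- sort(unique(as.character(y)))
  n <- nrow(X); C <- length(classes)
  feature_names <- colnames(X)
  if (C == 1) {
    warning("single-class labels: returning a constant predictor",
            call. = FALSE)
    tree <- new_leaf_tree(1)
    tree$v1 <- 1
    return(structure(list(trees = list(tree), classes = classes,
                          max_trees = max_trees,
                          feature_names = feature_names),
                     class = "tree_sum_model"))
  }
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), match(y, classes))] <- 1
  vcols <- paste0("v", seq_len(C))
  trees <- list()
  repeat {
    # predictions of every current tree
    preds <- lapply(trees, function(tr) tree_predict_raw(tr, X, C))
    total <- Reduce(`+`, preds, matrix(0, n, C))
    candidates <- list()
    for (t in seq_along(trees)) {
      R <- Y - (total - preds[[t]])
      tr <- trees[[t]]
      for (leaf in tr$id[is.na(tr$feature)]) {
        if (tr$depth[tr$id == leaf] >= max_depth) next
        idx <- which(tree_leaf_of(tr, X) == leaf)
        if (length(idx) < 2 * min_leaf) next
        sp <- best_split(X, R, idx, min_leaf)
        if (sp$gain > 0)
          candidates[[length(candidates) + 1]] <-
            c(sp, list(tree = t, leaf = leaf, idx = list(idx)))
      }
    }
    if (length(trees) < max_trees) {
      R <- Y - total
      sp <- best_split(X, R, seq_len(n), min_leaf)
      if (sp$gain > 0)
        candidates[[length(candidates) + 1]] <-
          c(sp, list(tree = 0, leaf = 1L, idx = list(seq_len(n))))
    }
    if (length(candidates) == 0) break
    gains <- vapply(candidates, `[[`, numeric(1), "gain")
    feats <- vapply(candidates, `[[`, numeric(1), "feature")
    ths <- vapply(candidates, `[[`, numeric(1), "threshold")
    ord <- order(-gains, feats, ths)
    ch <- candidates[[ord[1]]]
    if (ch$tree == 0) {
      trees[[length(trees) + 1]] <- new_leaf_tree(C)
      ch$tree <- length(trees)
    }
    tr <- trees[[ch$tree]]
    row <- which(tr$id == ch$leaf)
    nid <- max(tr$id)
    tr$feature[row] <- ch$feature
    tr$threshold[row] <- ch$threshold
    tr$left[row] <- nid + 1L
    tr$right[row] <- nid + 2L
    kid <- tr[rep(row, 2), ]
    kid$id <- c(nid + 1L, nid + 2L)
    kid$feature <- NA_integer_; kid$threshold <- NA_real_
    kid$left <- NA_integer_; kid$right <- NA_integer_
    kid$depth <- tr$depth[row] + 1L
    tr <- rbind(tr, kid)
    trees[[ch$tree]] <- tr
    # refit all leaf values of this tree against its residuals
    preds_other <- Reduce(`+`, lapply(trees[-ch$tree], function(t2)
      tree_predict_raw(t2, X, C)), matrix(0, n, C))
    R <- Y - preds_other
    leaves <- tree_leaf_of(tr, X)
    for (leaf in tr$id[is.na(tr$feature)]) {
      idx <- which(leaves == leaf)
      tr[tr$id == leaf, vcols] <-
        if (length(idx) > 0) colMeans(R[idx, , drop = FALSE]) else 0
    }
    trees[[ch$tree]] <- tr
  }
  if (length(trees) == 0) {
    tree <- new_leaf_tree(C)
    tree[, vcols] <- colMeans(Y)
    trees <- list(tree)
  }
  structure(list(trees = trees, classes = classes, max_trees = max_trees,
                 feature_names = feature_names),
            class = "tree_sum_model")
}

#' @export
print.tree_sum_model <- function(x, ...) {
  cat(sprintf("<tree_sum_model> %d tree(s), classes: %s\n",
              length(x$trees), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict with a tree-sums model
#'
#' @param model a \code{tree_sum_model}.
#' @param X feature matrix or data.frame (same columns as at fit time).
#' @return list with \code{probs} (rows sum to 1), \code{family}
#'   (argmax class per row).
#' @export
figs_predict <- function(model, X) {
  stopifnot(inherits(model, "tree_sum_model"))
  X <- as.matrix(X)
  C <- length(model$classes)
  raw <- Reduce(`+`, lapply(model$trees, function(tr)
    tree_predict_raw(tr, X, C)), matrix(0, nrow(X), C))
  probs <- row_softmax(raw)
  dimnames(probs) <- list(NULL, model$classes)
  list(probs = probs, family = model$classes[max.col(probs,
                                                     ties.method = "first")])
}

#' Serialize / restore a tree-sums model as JSON
#' @param model a \code{tree_sum_model}.
#' @param path JSON file path.
#' @return \code{figs_write}: path invisibly; \code{figs_read}: the model.
#' @export
figs_write <- function(model, path) {
  obj <- list(classes = model$classes, max_trees = model$max_trees,
              feature_names = model$feature_names,
              trees = lapply(model$trees, function(tr)
                lapply(as.list(tr), unname)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname figs_write
#' @export
figs_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  trees <- lapply(obj$trees, function(tr) {
    tr <- lapply(tr, function(col)
      unlist(lapply(col, function(v) if (is.null(v)) NA else v)))
    df <- as.data.frame(tr, stringsAsFactors = FALSE)
    for (col in c("id", "feature", "left", "right", "depth"))
      df[[col]] <- as.integer(df[[col]])
    for (col in setdiff(names(df), c("id", "feature", "left", "right",
                                     "depth", "threshold")))
      df[[col]] <- as.numeric(df[[col]])
    df$threshold <- as.numeric(df$threshold)
    df
  })
  structure(list(trees = trees, classes = as.character(obj$classes),
                 max_trees = obj$max_trees,
                 feature_names = obj$feature_names),
            class = "tree_sum_model")
}

#' Benchmark model families across a task collection
#'
#' Computes, per dataset: size, diversity, and one metric per requested
#' family (FSLC: mean episodic ROC AUC of a supplied model; CLASSICAL:
#' nested-CV ROC AUC or R^2; TRANSFORMER: metric of imported external
#' scores). Also returns the pairwise Pearson correlations among metrics,
#' metric differences, size and diversity.
#'
#' @param tasks list of \code{molecule_dataset}s.
#' @param families subset of \code{c("FSLC", "CLASSICAL", "TRANSFORMER")}.
#' @param fslc_model trained [fslc_init()] model (required for FSLC).
#' @param shot a [shot_config()] for FSLC evaluation.
#' @param n_resamples episodes per task for FSLC.
#' @param baseline a [baseline_config()] for CLASSICAL.
#' @param external named list (by dataset id) of [import_external_scores()]
#'   results (required for TRANSFORMER).
#' @param seed RNG seed.
#' @return list with \code{table} (winner-labelable data.frame) and
#'   \code{correlations} (matrix).
#' @export
run_benchmark <- function(tasks, families = c("FSLC", "CLASSICAL"),
                          fslc_model = NULL, shot = shot_config(5, 5),
                          n_resamples = 50,
                          baseline = baseline_config(), external = NULL,
                          seed = 1) {
  families <- match.arg(families, .families, several.ok = TRUE)
  if ("FSLC" %in% families && is.null(fslc_model))
    stop("FSLC requested without a model", call. = FALSE)
  if ("TRANSFORMER" %in% families && is.null(external))
    stop("TRANSFORMER requested without imported scores", call. = FALSE)
  rows <- lapply(tasks, function(ds) {
    prof <- scaffold_profile(ds)
    out <- data.frame(dataset_id = dataset_id(ds), n_molecules = nrow(ds),
                      div = prof$div)
    kind <- task_kind(ds)
    if ("FSLC" %in% families) {
      r <- fslc_evaluate(fslc_model, list(ds), list(shot),
                         n_resamples = n_resamples,
                         seed = derive_seed(seed, nrow(ds)))
      out$FSLC <- unname(r[[1]]$mean["rocauc"])
    }
    if ("CLASSICAL" %in% families) {
      cv <- nested_cv(ds, baseline)
      out$CLASSICAL <- unname(if (kind == "classification")
        cv$aggregate$mean["rocauc"] else cv$aggregate$mean["r2"])
    }
    if ("TRANSFORMER" %in% families) {
      ex <- external[[dataset_id(ds)]]
      if (is.null(ex)) stop("no external scores for ", dataset_id(ds),
                            call. = FALSE)
      out$TRANSFORMER <- if (kind == "classification")
        roc_auc(unname(ex$scores), ds$activity_class) else
        r_squared(ds$activity, unname(ex$scores))
    }
    out
  })
  table <- do.call(rbind, rows)
  num <- table[, c("n_molecules", "div", families), drop = FALSE]
  if (length(families) == 2)
    num$metric_diff <- table[[families[1]]] - table[[families[2]]]
  correlations <- suppressWarnings(stats::cor(as.matrix(num)))
  list(table = table, correlations = correlations)
}
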