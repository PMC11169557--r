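# Shared fixtures, built in code. Heavier objects (synthetic task families,
# trained models) are cached per test run in an environment so several test
# files can reuse them without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# a small curated-looking CSV on disk
write_toy_csv <- function(rows = c("Cc1ccccc1,100,nM",
                                   "CCO,1,uM",
                                   "c1ccncc1,50,nM"),
                          header = "smiles,value,unit") {
  path <- tempfile(fileext = ".csv")
  writeLines(c(header, rows), path)
  path
}

# an alkane-only dataset: cheap to build, no scaffolds needed
alkane_dataset <- function(n, with_classes = FALSE, seed = 1) {
  smiles <- vapply(seq_len(n), function(k) strrep("C", k + 1), character(1))
  act <- 5 + (seq_len(n) %% 5)
  molecule_dataset(
    smiles, activity = act,
    activity_class = if (with_classes) rep_len(c(1L, 0L), n) else NULL,
    dataset_id = "alkanes",
    task_kind = if (with_classes) "classification" else "regression")
}

# a separable synthetic task family (shared across fewshot/baseline tests)
toy_family <- function() {
  fixture("toy_family", function() {
    tpl <- synth_spec(120, equal_counts(120, 24), noise_rate = 0, seed = 1)
    synth_tasks(6, tpl, family_seed = 11, min_per_class = 25)
  })
}

# random scaffold-count multisets for diversity property tests
random_multiset <- function(max_s = 30, max_count = 20) {
  S <- sample.int(max_s, 1)
  stats::setNames(sample.int(max_count, S, replace = TRUE),
                  paste0("s", seq_len(S)))
}

# independent CART oracle: plain recursive partitioning with squared-error
# impurity on one-hot labels, same limits as the tree-sums fitter
cart_oracle_predict <- function(X, y, Xnew, max_depth = 4, min_leaf = 5) {
  classes <- sort(unique(as.character(y)))
  Y <- matrix(0, nrow(X), length(classes))
  Y[cbind(seq_len(nrow(X)), match(y, classes))] <- 1
  grow <- function(idx, depth) {
    leaf_val <- colMeans(Y[idx, , drop = FALSE])
    if (depth >= max_depth || length(idx) < 2 * min_leaf)
      return(list(leaf = TRUE, value = leaf_val))
    parent <- sum(sweep(Y[idx, , drop = FALSE], 2,
                        colMeans(Y[idx, , drop = FALSE]))^2)
    best <- NULL; best_gain <- 0
    for (j in seq_len(ncol(X))) {
      v <- sort(unique(X[idx, j]))
      if (length(v) < 2) next
      for (th in (v[-1] + v[-length(v)]) / 2) {
        li <- idx[X[idx, j] <= th]; ri <- idx[X[idx, j] > th]
        if (length(li) < min_leaf || length(ri) < min_leaf) next
        sse <- sum(sweep(Y[li, , drop = FALSE], 2,
                         colMeans(Y[li, , drop = FALSE]))^2) +
               sum(sweep(Y[ri, , drop = FALSE], 2,
                         colMeans(Y[ri, , drop = FALSE]))^2)
        gain <- parent - sse
        if (gain > best_gain + 1e-12) {
          best_gain <- gain; best <- list(j = j, th = th, li = li, ri = ri)
        }
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, value = leaf_val))
    list(leaf = FALSE, j = best$j, th = best$th,
         left = grow(best$li, depth + 1), right = grow(best$ri, depth + 1))
  }
  root <- grow(seq_len(nrow(X)), 0)
  classify <- function(node, x) {
    if (node$leaf) return(node$value)
    if (x[node$j] <= node$th) classify(node$left, x) else
      classify(node$right, x)
  }
  t(vapply(seq_len(nrow(Xnew)), function(i) classify(root, Xnew[i, ]),
           numeric(length(classes))))
}
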