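test_that("the size/diversity rule fires the documented zones", {
  expect_equal(recommend_rule(18, 0.2)$family, "FSLC")
  expect_equal(recommend_rule(18, 0.9)$family, "FSLC")
  expect_equal(recommend_rule(100, 0.8)$family, "TRANSFORMER")
  expect_equal(recommend_rule(100, 0.3)$family, "CLASSICAL")
  expect_equal(recommend_rule(2969, 0.52)$family, "CLASSICAL")
  # boundary inclusivity: 50 and 240 belong to the middle zone
  expect_equal(recommend_rule(49, 0.9)$family, "FSLC")
  expect_equal(recommend_rule(50, 0.9)$family, "TRANSFORMER")
  expect_equal(recommend_rule(240, 0.9)$family, "TRANSFORMER")
  expect_equal(recommend_rule(241, 0.9)$family, "CLASSICAL")
})

test_that("the rule is piecewise constant with breaks only at thresholds", {
  fams <- vapply(1:500, function(n) recommend_rule(n, 0.7)$family, "")
  breaks <- which(fams[-1] != fams[-500]) + 1
  expect_equal(breaks, c(50, 241))
  fams_low <- vapply(1:500, function(n) recommend_rule(n, 0.2)$family, "")
  expect_equal(which(fams_low[-1] != fams_low[-500]) + 1, 50)
})

test_that("winner labelling is an argmax with ties to CLASSICAL", {
  tab <- data.frame(dataset_id = c("a", "b", "c"), n_molecules = 1:3,
                    div = c(0.1, 0.2, 0.3),
                    FSLC = c(0.70, 0.60, 0.55),
                    CLASSICAL = c(0.60, 0.60, 0.60))
  lw <- label_winners(tab)
  expect_equal(lw$winner, c("FSLC", "CLASSICAL", "CLASSICAL"))
  perm <- label_winners(tab[c(3, 1, 2), ])
  expect_equal(perm$winner[order(perm$dataset_id)],
               lw$winner[order(lw$dataset_id)])
  expect_error(label_winners(tab[, 1:4]), "two families")
})

test_that("single-class labels yield a constant predictor with a warning", {
  X <- matrix(runif(40), 20, 2)
  expect_warning(m <- figs_fit(X, rep("FSLC", 20)), "single-class")
  p <- figs_predict(m, X)
  expect_true(all(p$family == "FSLC"))
  expect_equal(unname(p$probs[1, ]), 1)
})

test_that("tree sums with one tree equal an independent CART", {
  set.seed(71)
  for (rep in seq_len(20)) {
    n <- sample(30:60, 1)
    X <- cbind(runif(n, 0, 500), runif(n))
    y <- ifelse(X[, 1] < 150, "A", ifelse(X[, 2] > 0.5, "B", "C"))
    # random label noise so trees are non-trivial
    flip <- runif(n) < 0.1
    y[flip] <- sample(c("A", "B", "C"), sum(flip), replace = TRUE)
    m <- figs_fit(X, y, max_trees = 1, max_depth = 3, min_leaf = 4)
    got <- figs_predict(m, X)$probs
    oracle <- cart_oracle_predict(X, y, X, max_depth = 3, min_leaf = 4)
    # with a single tree the summed leaf values are the leaf class means;
    # compare pre-softmax structure through the induced partition
    raw <- goldilocks:::tree_predict_raw(m$trees[[1]], X,
                                         length(m$classes))
    expect_equal(unname(raw), unname(oracle), tolerance = 1e-12)
  }
})

test_that("tree sums recover planted rule thresholds from labeled grids", {
  set.seed(101)
  grid <- expand.grid(n_molecules = seq(5, 500, length.out = 40),
                      div = seq(0.02, 0.95, length.out = 40))
  y <- mapply(function(n, d) recommend_rule(n, d)$family,
              grid$n_molecules, grid$div)
  tr <- sample(nrow(grid), 1200)
  m <- figs_fit(grid[tr, ], y[tr], max_trees = 3, max_depth = 4,
                min_leaf = 5)
  pred <- figs_predict(m, grid[-tr, ])$family
  expect_gte(mean(pred == y[-tr]), 0.95)
  # learned thresholds on dataset size sit near the planted 50 and 240
  ths <- unlist(lapply(m$trees, function(tr2)
    tr2$threshold[!is.na(tr2$feature) & tr2$feature == 1]))
  expect_true(any(abs(ths - 50) / 50 <= 0.2))
  expect_true(any(abs(ths - 240) / 240 <= 0.2))
})

test_that("selector predictions are normalized and serialize bit-exactly", {
  set.seed(3)
  X <- cbind(runif(200, 0, 500), runif(200))
  y <- ifelse(X[, 1] < 100, "FSLC", "CLASSICAL")
  m <- figs_fit(X, y)
  Xnew <- cbind(runif(1000, 0, 500), runif(1000))
  p <- figs_predict(m, Xnew)
  expect_equal(unname(rowSums(p$probs)), rep(1, 1000), tolerance = 1e-9)
  path <- tempfile(fileext = ".json")
  figs_write(m, path)
  m2 <- figs_read(path)
  p2 <- figs_predict(m2, Xnew)
  expect_identical(p$probs, p2$probs)
  expect_identical(p$family, p2$family)
})

test_that("benchmarks tabulate per-family metrics and their correlations", {
  tasks <- toy_family()[1:4]
  m <- fslc_init(n_bits = 2048, hidden = c(64, 32), K = 1, radius = 5,
                 seed = 1)
  bench <- fixture("bench_small", function()
    run_benchmark(tasks, families = c("FSLC", "CLASSICAL"),
                  fslc_model = m, shot = shot_config(5, 5),
                  n_resamples = 10,
                  baseline = baseline_config(
                    outer_folds = 3, inner_folds = 2,
                    hyper_grid = data.frame(cost = 10, gamma = NA)),
                  seed = 1))
  expect_equal(nrow(bench$table), 4)
  expect_true(all(c("FSLC", "CLASSICAL", "div") %in% names(bench$table)))
  expect_equal(bench$correlations["div", "div"], 1)
  lw <- label_winners(bench$table)
  expect_true(all(lw$winner %in% c("FSLC", "CLASSICAL")))
  expect_error(run_benchmark(tasks, families = "TRANSFORMER"),
               "without imported scores")
})
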