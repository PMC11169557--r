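# small grids/folds keep the SVM fit counts manageable in the suite; the
# pipeline under test (nested selection, calibration, pooling) is identical
small_grid <- expand.grid(cost = c(1, 10), gamma = NA)

test_that("nested CV partitions records exactly once per outer fold", {
  ds <- toy_family()[[1]]
  for (seed in c(1, 2, 3)) {
    cv <- nested_cv(ds, baseline_config(outer_folds = 3, inner_folds = 2,
                                        hyper_grid = small_grid,
                                        seed = seed, fp_bits = 256))
    expect_equal(sort(cv$predictions$row), seq_len(nrow(ds)))
    expect_equal(length(unique(cv$predictions$fold)), 3)
  }
})

test_that("SVC separates a noise-free planted rule and not permuted labels", {
  ds <- fixture("svc_sep_ds", function()
    synth_dataset(synth_spec(300, equal_counts(300, 30), noise_rate = 0,
                             seed = 41), dataset_id = "sep"))
  cv <- nested_cv(ds, baseline_config(outer_folds = 3, inner_folds = 2,
                                      hyper_grid = small_grid, seed = 1))
  expect_gte(unname(cv$aggregate$mean["rocauc"]), 0.9)

  perm <- molecule_dataset(ds$smiles,
                           activity_class = sample(ds$activity_class),
                           task_kind = "classification",
                           keys = ds$structure_key)
  cvp <- nested_cv(perm, baseline_config(outer_folds = 3, inner_folds = 2,
                                         hyper_grid = small_grid, seed = 1))
  expect_lt(abs(unname(cvp$aggregate$mean["rocauc"]) - 0.5), 0.1)
})

test_that("tiny class counts produce a fold-construction error with advice", {
  tiny <- molecule_dataset(c("CC", "CCC", "CCCC", "CCCCC"),
                           activity_class = c(1L, 0L, 0L, 0L),
                           task_kind = "classification")
  expect_error(nested_cv(tiny, baseline_config(outer_folds = 5)),
               "reduce outer_folds")
})

test_that("SVR recovers noise-free synthetic regression", {
  ds <- fixture("svr_reg_ds", function()
    synth_dataset(synth_spec(240, equal_counts(240, 24), noise_rate = 0,
                             seed = 43, task_kind = "regression",
                             sigma = 0.05), dataset_id = "reg"))
  cv <- nested_cv(ds, baseline_config(outer_folds = 3, inner_folds = 2,
                                      hyper_grid = expand.grid(
                                        cost = c(10, 100), gamma = NA),
                                      seed = 1))
  expect_equal(cv$algorithm, "svr")
  expect_gte(unname(cv$aggregate$mean["r2"]), 0.8)
})

test_that("SVR predictive power degrades as planted diversity grows", {
  # scaffold-driven labels: once every scaffold is unique, held-out scaffolds
  # are unseen and regression collapses
  r2s <- fixture("svr_div_curve", function() {
    svals <- c(4, 8, 15, 25, 40, 60, 100, 150)
    vapply(seq_along(svals), function(i) {
      S <- svals[i]
      ds <- synth_dataset(synth_spec(150, equal_counts(150, S),
                                     label_rule = "scaffold",
                                     noise_rate = 0, seed = 50 + i,
                                     task_kind = "regression",
                                     sigma = 0.05),
                          dataset_id = paste0("div", S))
      cv <- nested_cv(ds, baseline_config(
        algorithm = "svr", outer_folds = 3, inner_folds = 2,
        hyper_grid = data.frame(cost = 10, gamma = NA), seed = 1))
      unname(cv$aggregate$mean["r2"])
    }, numeric(1))
  })
  expect_lte(cor(seq_along(r2s), r2s, method = "spearman"), -0.5)
})

test_that("final fits memorize separable data and predict deterministically", {
  ds <- fixture("svc_sep_ds", function()
    synth_dataset(synth_spec(300, equal_counts(300, 30), noise_rate = 0,
                             seed = 41), dataset_id = "sep"))
  cfg <- baseline_config(outer_folds = 3, inner_folds = 2,
                         hyper_grid = small_grid, seed = 1)
  h <- fixture("svc_final", function() fit_final(ds, cfg))
  some <- c(which(ds$activity_class == 1)[1:5],
            which(ds$activity_class == 0)[1:5])
  s <- predict_baseline(h, ds$smiles[some])
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(mean(s[1:5]), mean(s[6:10]))
  expect_equal(predict_baseline(h, ds$smiles[some]), s)
  expect_error(predict_baseline(h, "not_a_smiles"), "unparseable")
})

test_that("external scores are matched by key with coverage accounting", {
  ds <- alkane_dataset(6, with_classes = TRUE)
  path <- tempfile(fileext = ".csv")
  scores <- c(0.9, 0.2, 0.8, 0.3, 0.7, 0.1)
  write.csv(data.frame(structure_key = ds$structure_key, score = scores),
            path, row.names = FALSE)
  ex <- import_external_scores(path, ds)
  expect_equal(ex$coverage, 1.0)
  # metrics on the imported scores equal direct hand evaluation
  rep_ <- metric_report(ds$activity_class, unname(ex$scores))
  expect_equal(rep_$rocauc, roc_auc(scores, ds$activity_class))
  expect_equal(rep_$rocauc, 1.0)  # scores were built to separate classes

  write.csv(data.frame(structure_key = c(ds$structure_key[-1], "ALIEN"),
                       score = scores), path, row.names = FALSE)
  expect_warning(ex2 <- import_external_scores(path, ds), "no dataset")
  expect_equal(ex2$coverage, 5 / 6)
  expect_error(suppressWarnings(import_external_scores(path, ds,
                                                       strict = TRUE)),
               "coverage")
})
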