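test_that("CSV parsing keeps valid rows, rejects or skips invalid ones", {
  path <- write_toy_csv()
  ds <- read_bioactivity(path)
  expect_s3_class(ds, "molecule_dataset")
  expect_equal(nrow(ds), 3)
  expect_equal(ds$activity, c(7, 6, -log10(5e-8)), tolerance = 1e-12)

  bad <- write_toy_csv(rows = c("Cc1ccccc1,100,nM", "not_a_smiles,1,uM"))
  expect_error(read_bioactivity(bad, strict = TRUE), "row")
  expect_warning(ds2 <- read_bioactivity(bad), "skipped")
  expect_equal(nrow(ds2), 1)

  expect_error(read_bioactivity(write_toy_csv(header = "structure,value,unit")),
               "missing required column")
  # same file parsed twice -> identical
  expect_identical(read_bioactivity(path), read_bioactivity(path))
})

test_that(".smi files and salt-stripping standardization are supported", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("Cc1ccccc1 mol1", "CCO mol2"), smi)
  ds <- read_bioactivity(smi)
  expect_equal(nrow(ds), 2)
  expect_true(all(is.na(ds$activity)))

  expect_equal(standardize_smiles("CC(=O)[O-].[Na+]"),
               canonical_smiles("CC(=O)[O-]"))
  expect_error(standardize_smiles("CC.O", reject_multicomponent = TRUE),
               "multi-component")
})

test_that("unit conversion to -log[M] matches hand values and is monotone", {
  expect_identical(to_neg_log_molar(100, "nM"), 7)
  expect_identical(to_neg_log_molar(1, "M"), 0)
  expect_equal(to_neg_log_molar(50, "nM"), 7.30103, tolerance = 1e-6)
  expect_equal(to_neg_log_molar(1, "uM"), to_neg_log_molar(1, "µM"))
  expect_equal(to_neg_log_molar(1, "NM"), 9)  # case-insensitive
  expect_error(to_neg_log_molar(-1, "nM"), "positive")
  expect_error(to_neg_log_molar(1, "parsec"), "unrecognized")

  set.seed(1)
  conc <- sort(10^runif(20, -9, 0))
  vals <- to_neg_log_molar(conc, "M")
  expect_true(all(diff(vals) < 0))
  expect_true(all(abs(vals + log10(conc)) < 1e-12))
})

test_that("duplicate averaging is a mean on the -log[M] scale and idempotent", {
  ds <- molecule_dataset(c("CC", "CC", "CCC"), activity = c(6, 8, 5),
                         keys = c("k1", "k1", "k2"))
  dd <- dedupe_average(ds)
  expect_equal(nrow(dd), 2)
  expect_equal(dd$activity, c(7, 5))
  expect_equal(dd$smiles[1], "CC")

  ds3 <- molecule_dataset(rep("CC", 3), activity = c(6, 7, 8),
                          keys = rep("k", 3))
  expect_equal(dedupe_average(ds3)$activity, 7)

  nodup <- alkane_dataset(5)
  expect_equal(dedupe_average(nodup)$activity, nodup$activity)
  expect_identical(dedupe_average(dedupe_average(ds)), dedupe_average(ds))

  ds$activity[2] <- NA
  expect_error(dedupe_average(ds), "activity")
})

test_that("binarization at 100 nM uses the inclusive -log[M] >= 7 boundary", {
  ds <- molecule_dataset(c("CC", "CCC", "CCCC"),
                         activity = c(7.5, 7.0, 6.9))
  b <- binarize(ds, threshold_molar = 1e-7)
  expect_equal(b$activity_class, c(1L, 1L, 0L))
  expect_equal(task_kind(b), "classification")
  # actives + inactives = n
  expect_equal(sum(b$activity_class == 1) + sum(b$activity_class == 0),
               nrow(b))
  ds$activity[1] <- NA
  expect_error(binarize(ds, 1e-7), "activity")
})

test_that("dataset filtering enforces 'fewer than' minima exactly", {
  d19 <- alkane_dataset(19)
  d20 <- alkane_dataset(20)
  expect_length(filter_datasets(list(d19, d20), min_total = 20,
                                quiet = TRUE), 1)
  expect_identical(filter_datasets(list(d20), min_total = 20,
                                   quiet = TRUE)[[1]], d20)

  # 25 records but only 19 actives
  cls <- c(rep(1L, 19), rep(0L, 6))
  d25 <- molecule_dataset(vapply(1:25, function(k) strrep("C", k + 1), ""),
                          activity_class = cls,
                          task_kind = "classification")
  expect_length(filter_datasets(list(d25), min_total = 20,
                                min_per_class = 20, quiet = TRUE), 0)
  expect_error(filter_datasets(list(alkane_dataset(30)), min_total = 20,
                               min_per_class = 5, quiet = TRUE),
               "non-classification")
})

test_that("splits hit the rounded fraction targets and partition the data", {
  ds <- alkane_dataset(100)
  parts <- split_dataset(ds, c(0.70, 0.05, 0.25), seed = 3)
  expect_equal(vapply(parts, nrow, numeric(1)), c(70, 5, 25))

  p2 <- split_dataset(ds, c(0.70, 0.05, 0.25), seed = 3)
  expect_identical(lapply(parts, `[[`, "smiles"),
                   lapply(p2, `[[`, "smiles"))

  ds37 <- alkane_dataset(37)
  for (seed in 1:100) {
    p <- split_dataset(ds37, c(0.70, 0.15, 0.15), seed = seed)
    keys <- unlist(lapply(p, `[[`, "structure_key"))
    expect_length(keys, 37)
    expect_false(anyDuplicated(keys) > 0)
  }
  expect_error(split_dataset(ds, c(0.5, 0.4)), "sum to 1")
})

test_that("stratified splits keep class proportions within one count", {
  ds <- alkane_dataset(10, with_classes = TRUE)
  for (seed in 1:25) {
    p <- split_dataset(ds, c(0.7, 0.15, 0.15), stratified = TRUE,
                       seed = seed)
    for (part in Filter(Negate(is.null), p)) {
      n1 <- sum(part$activity_class == 1)
      n0 <- sum(part$activity_class == 0)
      expect_lte(abs(n1 - n0), 1)
    }
  }
})

test_that("fingerprints are canonical-structure invariants of fixed length", {
  fp <- fingerprint_matrix(c("c1ccccc1", "C1=CC=CC=C1", "CC"),
                           radius = 3, n_bits = 1024)
  expect_equal(dim(fp), c(3, 1024))
  expect_identical(fp[1, ], fp[2, ])
  # no shared circular environments between benzene and ethane
  expect_equal(tanimoto(fp[1, ], fp[3, ]), 0)
  expect_equal(ncol(fingerprint_matrix("CCO", kind = "maccs")), 166)
  expect_equal(ncol(fingerprint_matrix("CCO", radius = 5, n_bits = 2048)),
               2048)
  expect_error(fingerprint_matrix("xx1"), "unparseable")
})

test_that("Murcko scaffolds strip substituents and are idempotent", {
  expect_identical(murcko_scaffold("CC"), "")
  expect_identical(murcko_scaffold("c1ccccc1"),
                   canonical_smiles("c1ccccc1"))
  expect_identical(murcko_scaffold("Cc1ccccc1"),
                   canonical_smiles("c1ccccc1"))
  # whole acyclic side chains go; atoms double-bonded to the framework stay
  expect_identical(murcko_scaffold("CC(=O)c1ccccc1"),
                   canonical_smiles("c1ccccc1"))
  expect_identical(murcko_scaffold("C=C1CCCCC1"),
                   canonical_smiles("C=C1CCCCC1"))
  scafs <- murcko_scaffold(c("CCOc1ccc(CNC(=O)c2ccncc2)cc1",
                             "Clc1ccc2[nH]ccc2c1", "CCC(C)CO"))
  again <- vapply(scafs, function(s)
    if (nzchar(s)) murcko_scaffold(s) else "", character(1), USE.NAMES = FALSE)
  expect_identical(again, scafs)
})

test_that("max Tanimoto equals the brute-force pairwise maximum", {
  ref <- c("Cc1ccccc1", "CCO", "c1ccncc1", "CCCC", "c1ccc2ccccc2c1")
  expect_equal(max_tanimoto("CCO", ref), 1.0)
  expect_error(max_tanimoto("CCO", character(0)), "empty")

  fps <- fingerprint_matrix(c("CCNc1ccccc1", ref), kind = "maccs")
  brute <- max(vapply(seq_along(ref), function(i) {
    a <- fps[1, ]; b <- fps[i + 1, ]
    sum(a == 1 & b == 1) / sum(a == 1 | b == 1)
  }, numeric(1)))
  expect_equal(max_tanimoto("CCNc1ccccc1", ref), brute, tolerance = 1e-12)
})
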