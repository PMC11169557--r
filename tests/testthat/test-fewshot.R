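# A tiny deterministic model for unit-level checks
tiny_model <- function(K = 2, n_bits = 8, hidden = c(6, 4), seed = 5) {
  m <- fslc_init(n_bits = n_bits, hidden = hidden, K = K, radius = 2,
                 seed = seed)
  set.seed(seed + 1)
  m$par$gate_q <- matrix(rnorm(max(K, 1) * hidden[2]), max(K, 1), hidden[2])
  m$par$gate_s <- matrix(rnorm(max(K, 1) * hidden[2]), max(K, 1), hidden[2])
  m
}

test_that("episode sampling is exact, disjoint and seeded", {
  task <- list(fp = matrix(0, 60, 8),
               labels = rep(c(1L, 0L), c(25, 35)), id = "t")
  cfg <- shot_config(10, 10)
  expect_identical(cfg$label, "10-10")
  for (r in 1:50) {
    epi <- sample_episode(task, cfg, seed = r)
    expect_length(epi$support_idx, 20)
    expect_length(epi$query_idx, 20)
    expect_equal(sum(epi$support_labels == 1), 10)
    expect_equal(sum(epi$query_labels == 0), 10)
    expect_length(intersect(epi$support_idx, epi$query_idx), 0)
  }
  expect_identical(sample_episode(task, cfg, seed = 4),
                   sample_episode(task, cfg, seed = 4))
  expect_equal(length(sample_episode(task, shot_config(1, 1),
                                     seed = 1)$support_idx), 2)
  no_actives <- list(fp = matrix(0, 30, 8), labels = rep(0L, 30), id = "na")
  expect_error(sample_episode(no_actives, cfg, seed = 1), "actives")
})

test_that("embedding has the contracted shape and hand-checkable values", {
  m <- tiny_model()
  X <- matrix(rbinom(5 * 8, 1, 0.5), 5, 8)
  E <- fslc_embed(m, X)
  expect_equal(dim(E), c(5, 4))
  expect_identical(E, fslc_embed(m, X))
  expect_error(fslc_embed(m, matrix(0, 2, 9)), "does not match")

  # 2-bit toy with hand-set weights: relu(relu(x W1 + b1) W2 + b2)
  mm <- fslc_init(n_bits = 2, hidden = c(2, 2), K = 0, seed = 1)
  mm$par$W1 <- matrix(c(1, 0, 0, -1), 2, 2)
  mm$par$b1 <- c(0, 0.5)
  mm$par$W2 <- matrix(c(2, 1, 0, 1), 2, 2)
  mm$par$b2 <- c(-1, 0)
  x <- matrix(c(1, 1), 1, 2)
  h1 <- pmax(c(1, -0.5), 0)           # = (1, 0)
  expected <- pmax(c(h1 %*% matrix(c(2, 1, 0, 1), 2, 2)) + c(-1, 0), 0)
  expect_equal(drop(fslc_embed(mm, x)), expected)  # = (1, 0)
})

test_that("refinement: K = 0 is the identity, degenerate attention fixes", {
  m <- tiny_model(K = 0)
  S <- matrix(rnorm(12), 3, 4); Q <- matrix(rnorm(8), 2, 4)
  r <- fslc_refine(m, S, Q, K = 0)
  expect_identical(r$support, S)
  expect_identical(r$query, Q)

  # all support embeddings identical: every attention read-out is that row
  m2 <- tiny_model(K = 3)
  srow <- rnorm(4)
  S2 <- matrix(srow, 5, 4, byrow = TRUE)
  r2 <- fslc_refine(m2, S2, Q)
  # support stays at its own fixed point: g*s + (1-g)*s = s
  expect_equal(r2$support, S2, tolerance = 1e-12)
  # each query moves toward srow by the gate schedule, exactly
  gq <- lapply(1:3, function(t) 1 / (1 + exp(-m2$par$gate_q[t, ])))
  qexp <- Q
  for (t in 1:3)
    qexp <- sweep(qexp, 2, gq[[t]], "*") +
      matrix(srow, nrow(Q), 4, byrow = TRUE) *
      matrix(1 - gq[[t]], nrow(Q), 4, byrow = TRUE)
  expect_equal(r2$query, qexp, tolerance = 1e-12)
  expect_error(fslc_refine(m2, S, Q[, 1:3, drop = FALSE]), "dimension")
})

test_that("refinement matches a step-by-step manual unrolling", {
  m <- tiny_model(K = 2)
  S <- matrix(rnorm(8), 2, 4); Q <- matrix(rnorm(4), 1, 4)
  got <- fslc_refine(m, S, Q)
  # independent re-execution with plain loops
  sm <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  Sc <- S; Qc <- Q
  for (t in 1:2) {
    gq <- 1 / (1 + exp(-m$par$gate_q[t, ]))
    gs <- 1 / (1 + exp(-m$par$gate_s[t, ]))
    Rq <- matrix(0, nrow(Qc), 4); Rs <- matrix(0, nrow(Sc), 4)
    for (i in seq_len(nrow(Qc))) {
      w <- sm(as.numeric(Sc %*% Qc[i, ]) / 2)   # sqrt(d) = 2
      Rq[i, ] <- colSums(Sc * w)
    }
    for (i in seq_len(nrow(Sc))) {
      w <- sm(as.numeric(Sc %*% Sc[i, ]) / 2)
      Rs[i, ] <- colSums(Sc * w)
    }
    Qn <- Qc; Sn <- Sc
    for (j in 1:4) {
      Qn[, j] <- gq[j] * Qc[, j] + (1 - gq[j]) * Rq[, j]
      Sn[, j] <- gs[j] * Sc[, j] + (1 - gs[j]) * Rs[, j]
    }
    Qc <- Qn; Sc <- Sn
  }
  expect_equal(got$query, Qc, tolerance = 1e-12)
  expect_equal(got$support, Sc, tolerance = 1e-12)
})

test_that("prototypes are class means", {
  one <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  p <- class_prototypes(one, c(0, 1))
  expect_equal(unname(p["0", ]), c(1, 2))
  expect_equal(unname(p["1", ]), c(3, 4))
  two <- matrix(c(0, 0, 2, 2, 5, 5, 7, 7), 4, 2, byrow = TRUE)
  p2 <- class_prototypes(two, c(0, 0, 1, 1))
  expect_equal(unname(p2["0", ]), c(1, 1))
  three <- matrix(c(0, 0, 1, 0, 2, 3, 9, 9), 4, 2, byrow = TRUE)
  expect_equal(unname(class_prototypes(three, c(1, 1, 1, 0))["1", ]),
               c(1, 1))
  expect_error(class_prototypes(one, c(1, 1)), "both classes")
})

test_that("query probabilities are softmax of negative squared distances", {
  protos <- rbind("0" = c(0, 0), "1" = c(2, 0))
  eq <- classify_queries(matrix(c(1, 5), 1, 2), protos)
  expect_equal(unname(eq[1, ]), c(0.5, 0.5))

  at0 <- classify_queries(matrix(c(0, 0), 1, 2),
                          rbind("0" = c(0, 0), "1" = c(50, 0)))
  expect_gt(at0[1, "0"], 1 - 1e-10)

  # distances 1 and 2 -> p = e^-1 / (e^-1 + e^-4)
  p <- classify_queries(matrix(c(1, 0), 1, 2),
                        rbind("0" = c(0, 0), "1" = c(3, 0)))
  expect_equal(unname(p[1, "0"]), exp(-1) / (exp(-1) + exp(-4)),
               tolerance = 1e-12)

  set.seed(2)
  Q <- matrix(rnorm(40), 20, 2)
  pr <- classify_queries(Q, protos)
  expect_equal(unname(rowSums(pr)), rep(1, 20), tolerance = 1e-9)
  # translation invariance of Euclidean distances
  shift <- matrix(c(3, -2), 20, 2, byrow = TRUE)
  pr2 <- classify_queries(Q + shift, protos + rep(c(3, -2), each = 2))
  expect_equal(pr, pr2, tolerance = 1e-9)
})

test_that("with one support point per class, classification is nearest
           neighbor", {
  set.seed(8)
  S <- matrix(rnorm(8), 2, 4)
  protos <- class_prototypes(S, c(0, 1))
  Q <- matrix(rnorm(40), 10, 4)
  p <- classify_queries(Q, protos)
  nn <- apply(Q, 1, function(q) {
    d <- c(sum((q - S[1, ])^2), sum((q - S[2, ])^2))
    c(0, 1)[which.min(d)]
  })
  expect_equal(as.integer(p[, "1"] > 0.5), nn)
})

test_that("analytic gradients match finite differences", {
  m <- tiny_model(K = 2, n_bits = 10, hidden = c(7, 5), seed = 11)
  set.seed(12)
  Xs <- matrix(rbinom(60, 1, 0.4), 6, 10); ys <- c(1, 1, 1, 0, 0, 0)
  Xq <- matrix(rbinom(40, 1, 0.4), 4, 10); yq <- c(1, 0, 1, 0)
  g <- goldilocks:::episode_grad(m$par, 2, Xs, ys, Xq, yq)
  expect_true(is.finite(g$loss) && g$loss >= 0)
  eps <- 1e-6
  for (nm in names(g$grads)) {
    idx <- sample(length(m$par[[nm]]), min(6, length(m$par[[nm]])))
    for (i in idx) {
      pp <- m$par; pp[[nm]][i] <- pp[[nm]][i] + eps
      l1 <- goldilocks:::episode_grad(pp, 2, Xs, ys, Xq, yq)$loss
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      l0 <- goldilocks:::episode_grad(pp, 2, Xs, ys, Xq, yq)$loss
      num <- (l1 - l0) / (2 * eps)
      expect_equal(g$grads[[nm]][i], num, tolerance = 5e-3)
    }
  }
})

test_that("training is deterministic and drives the loss down", {
  tasks <- toy_family()[1:3]
  tensors <- fixture("toy_tensors_small", function()
    lapply(tasks, task_tensor, radius = 2, n_bits = 256))
  run <- function() fslc_train(tensors, parse_shot_configs("5-5"),
                               max_episodes = 60, seed = 21,
                               n_bits = 256, hidden = c(64, 32), K = 2,
                               radius = 2)
  m1 <- run(); m2 <- run()
  expect_identical(m1$par, m2$par)
  h <- attr(m1, "loss_history")
  expect_true(all(is.finite(h)) && all(h >= 0))
  expect_lt(mean(tail(h, 15)), mean(head(h, 15)))
})

test_that("a trained model separates held-out episodes well", {
  tasks <- toy_family()
  m <- fixture("toy_trained", function()
    fslc_train(lapply(tasks[1:4], task_tensor, radius = 2, n_bits = 1024),
               parse_shot_configs("5-5"), max_episodes = 400, seed = 2,
               n_bits = 1024, hidden = c(256, 64), K = 3, radius = 2))
  heldout <- lapply(tasks[5:6], task_tensor, radius = 2, n_bits = 1024)
  ev <- fslc_evaluate(m, heldout, parse_shot_configs("5-5"),
                      n_resamples = 100, seed = 3)
  expect_gte(unname(ev[["5-5"]]$mean["rocauc"]), 0.75)
})

test_that("evaluation: chance scorers score 0.5, oracles score 1", {
  tasks <- toy_family()[5]
  tensors <- fixture("toy_tensor_eval", function()
    lapply(tasks, task_tensor, radius = 2, n_bits = 256))
  flat <- fslc_evaluate(NULL, tensors, parse_shot_configs("5-5"),
                        n_resamples = 30, seed = 4,
                        scorer = function(sfp, sl, qfp)
                          rep(0.5, nrow(qfp)))
  expect_equal(unname(flat[["5-5"]]$mean["rocauc"]), 0.5)

  # oracle: look each query up in the task and answer its true label
  tt <- tensors[[1]]
  oracle <- function(sfp, sl, qfp) {
    apply(qfp, 1, function(q)
      tt$labels[which(colSums(abs(t(tt$fp) - q)) == 0)[1]])
  }
  perf <- fslc_evaluate(NULL, tensors, parse_shot_configs("5-5"),
                        n_resamples = 30, seed = 4, scorer = oracle)
  expect_equal(unname(perf[["5-5"]]$mean), rep(1, 5), tolerance = 1e-12)
})

test_that("resampled means are stable across resample counts", {
  tasks <- toy_family()[5:6]
  tensors <- fixture("toy_tensor_eval2", function()
    lapply(tasks, task_tensor, radius = 2, n_bits = 256))
  m <- fslc_init(n_bits = 256, hidden = c(64, 32), K = 1, radius = 2,
                 seed = 6)
  small <- fslc_evaluate(m, tensors, parse_shot_configs("5-5"),
                         n_resamples = 50, seed = 8)
  large <- fslc_evaluate(m, tensors, parse_shot_configs("5-5"),
                         n_resamples = 500, seed = 9)
  se <- large[["5-5"]]$sd["rocauc"] / sqrt(2) + 1e-3
  expect_lt(abs(small[["5-5"]]$mean["rocauc"] -
                large[["5-5"]]$mean["rocauc"]), 3 * se + 0.05)
})

test_that("model serialization round-trips predictions exactly", {
  m <- tiny_model(K = 2)
  path <- tempfile(fileext = ".json")
  fslc_write(m, path)
  m2 <- fslc_read(path)
  set.seed(3)
  sfp <- matrix(rbinom(32, 1, 0.5), 4, 8)
  qfp <- matrix(rbinom(16, 1, 0.5), 2, 8)
  expect_equal(fslc_predict(m2, sfp, c(1, 1, 0, 0), qfp),
               fslc_predict(m, sfp, c(1, 1, 0, 0), qfp), tolerance = 1e-12)
})
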