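# Episodic few-shot prototypical classifier over molecular fingerprints.
#
# Architecture: a feed-forward embedding network g' maps fingerprints to an
# embedding space; an attention-refinement module g (a gated recurrence in
# the IterRefLSTM family) jointly refines support and query embeddings for K
# iterations; class prototypes are the mean refined support embeddings and
# queries are classified by softmax over negative squared Euclidean
# distances. Training is episodic: sample a support/query draw from a random
# task, compute the query negative log-likelihood, and update all parameters
# with Adam. Gradients are computed analytically (verified against finite
# differences in the test suite).

#' Support/query composition of an episode
#'
#' @param support_actives,support_inactives molecules per class in the
#'   support set.
#' @param query_actives,query_inactives molecules per class in the query
#'   set; default mirrors the support composition.
#' @return a \code{shot_config} with a label like \code{"10-10"} derived
#'   from the support composition.
#' @export
#' @examples
#' shot_config(1, 10)
shot_config <- function(support_actives, support_inactives,
                        query_actives = support_actives,
                        query_inactives = support_inactives) {
  stopifnot(support_actives >= 1, support_inactives >= 1,
            query_actives >= 1, query_inactives >= 1)
  structure(list(support_actives = as.integer(support_actives),
                 support_inactives = as.integer(support_inactives),
                 query_actives = as.integer(query_actives),
                 query_inactives = as.integer(query_inactives),
                 label = paste0(support_actives, "-", support_inactives)),
            class = "shot_config")
}

#' Parse "a-i" shot labels into configurations
#' @param labels character vector like \code{c("10-10", "1-5")}.
#' @return list of [shot_config()]s.
#' @export
parse_shot_configs <- function(labels) {
  lapply(strsplit(labels, "-", fixed = TRUE), function(p) {
    stopifnot(length(p) == 2)
    shot_config(as.integer(p[1]), as.integer(p[2]))
  })
}

#' Standard episodic training compositions
#'
#' The six support/query compositions used to probe stability of the
#' few-shot classifier under class imbalance at micro-data sizes.
#' @return list of [shot_config()]s: 10-10, 5-10, 1-10, 5-5, 1-5, 1-1.
#' @export
default_shot_configs <- function() {
  parse_shot_configs(c("10-10", "5-10", "1-10", "5-5", "1-5", "1-1"))
}

#' Fingerprint tensor for episodic work
#'
#' Computes the few-shot descriptor block of a dataset once: circular
#' fingerprints (default 2048 bits, radius 5) plus labels.
#'
#' @param dataset a classification \code{molecule_dataset}.
#' @param radius,n_bits circular fingerprint parameters.
#' @return list with \code{fp} (matrix), \code{labels} (0/1), \code{id}.
#' @export
task_tensor <- function(dataset, radius = 5, n_bits = 2048) {
  stopifnot(inherits(dataset, "molecule_dataset"),
            task_kind(dataset) == "classification")
  list(fp = fingerprint_matrix(dataset$smiles, "circular",
                               radius = radius, n_bits = n_bits),
       labels = dataset$activity_class,
       id = dataset_id(dataset))
}

#' Sample a support/query episode from a task
#'
#' Uniform sampling without replacement; support and query are disjoint and
#' match the configuration exactly.
#'
#' @param task a \code{molecule_dataset} or a [task_tensor()].
#' @param config a [shot_config()].
#' @param seed optional seed (omit to draw from the current RNG stream).
#' @return list with \code{support_idx}, \code{query_idx},
#'   \code{support_labels}, \code{query_labels}, \code{config},
#'   \code{task_id}.
#' @export
sample_episode <- function(task, config, seed = NULL) {
  labels <- if (inherits(task, "molecule_dataset")) task$activity_class
    else task$labels
  id <- if (inherits(task, "molecule_dataset")) dataset_id(task) else task$id
  if (anyNA(labels)) stop("task must be binarized", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  pos <- which(labels == 1); neg <- which(labels == 0)
  need_pos <- config$support_actives + config$query_actives
  need_neg <- config$support_inactives + config$query_inactives
  if (length(pos) < need_pos)
    stop(sprintf("task %s has %d actives but the episode needs %d",
                 id, length(pos), need_pos), call. = FALSE)
  if (length(neg) < need_neg)
    stop(sprintf("task %s has %d inactives but the episode needs %d",
                 id, length(neg), need_neg), call. = FALSE)
  pos_draw <- pos[sample.int(length(pos), need_pos)]
  neg_draw <- neg[sample.int(length(neg), need_neg)]
  sup <- c(pos_draw[seq_len(config$support_actives)],
           neg_draw[seq_len(config$support_inactives)])
  qry <- c(pos_draw[config$support_actives + seq_len(config$query_actives)],
           neg_draw[config$support_inactives +
                      seq_len(config$query_inactives)])
  list(support_idx = sup, query_idx = qry,
       support_labels = labels[sup], query_labels = labels[qry],
       config = config, task_id = id)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

row_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Initialize a few-shot classifier
#'
#' @param n_bits fingerprint length fed to the embedding network.
#' @param hidden sizes of the two embedding layers; the second is the
#'   embedding dimension.
#' @param K refinement iterations (0 disables refinement, leaving a plain
#'   prototypical network).
#' @param radius circular fingerprint radius the model expects.
#' @param seed weight initialization seed.
#' @return an \code{fslc_model}.
#' @export
fslc_init <- function(n_bits = 2048, hidden = c(512, 128), K = 3,
                      radius = 5, seed = 1) {
  stopifnot(length(hidden) == 2, K >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  d <- hidden[2]
  par <- list(
    W1 = matrix(stats::rnorm(n_bits * hidden[1], 0, sqrt(2 / n_bits)),
                n_bits, hidden[1]),
    b1 = numeric(hidden[1]),
    W2 = matrix(stats::rnorm(hidden[1] * d, 0, sqrt(2 / hidden[1])),
                hidden[1], d),
    b2 = numeric(d),
    # gate logits start at 2 (sigmoid ~ 0.88): refinement begins as a gentle
    # perturbation of the raw embeddings
    gate_q = matrix(2, max(K, 1), d),
    gate_s = matrix(2, max(K, 1), d)
  )
  structure(list(par = par, n_bits = n_bits, hidden = hidden, K = K,
                 radius = radius, seed = seed, trained_episodes = 0L),
            class = "fslc_model")
}

#' @export
print.fslc_model <- function(x, ...) {
  cat(sprintf(
    "<fslc_model> %d-bit fp (radius %d) -> %d -> %d, K = %d (%d episodes trained)\n",
    x$n_bits, x$radius, x$hidden[1], x$hidden[2], x$K, x$trained_episodes))
  invisible(x)
}

#' Embed fingerprints
#'
#' Two rectified-linear layers; one embedding row per input row.
#'
#' @param model an \code{fslc_model}.
#' @param fp fingerprint matrix (rows = molecules, \code{model$n_bits}
#'   columns).
#' @return embedding matrix (rows x embedding dim).
#' @export
fslc_embed <- function(model, fp) {
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  if (ncol(fp) != model$n_bits)
    stop("fingerprint length ", ncol(fp), " does not match model input ",
         model$n_bits, call. = FALSE)
  f <- embed_forward(model$par, fp)
  f$H2
}

embed_forward <- function(par, X) {
  A1 <- sweep(X %*% par$W1, 2, par$b1, "+")
  H1 <- pmax(A1, 0)
  A2 <- sweep(H1 %*% par$W2, 2, par$b2, "+")
  H2 <- pmax(A2, 0)
  list(X = X, H1 = H1, H2 = H2)
}

embed_backward <- function(par, cache, dH2) {
  dA2 <- dH2 * (cache$H2 > 0)
  dW2 <- crossprod(cache$H1, dA2)
  db2 <- colSums(dA2)
  dH1 <- tcrossprod(dA2, par$W2)
  dA1 <- dH1 * (cache$H1 > 0)
  dW1 <- crossprod(cache$X, dA1)
  db1 <- colSums(dA1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Jointly refine support and query embeddings
#'
#' K iterations of the gated attention recurrence: queries attend over the
#' support set, the support attends over itself (scaled dot-product
#' attention), and each embedding is updated as a sigmoid-gated convex
#' combination of its current state and its attention read-out, with
#' per-iteration learned gate vectors. K = 0 returns the inputs unchanged.
#'
#' @param model an \code{fslc_model}.
#' @param support_emb,query_emb embedding matrices of equal width.
#' @param K iterations; defaults to the model's K.
#' @return list with refined \code{support} and \code{query} matrices.
#' @export
fslc_refine <- function(model, support_emb, query_emb, K = model$K) {
  if (ncol(support_emb) != ncol(query_emb))
    stop("support and query embeddings must have equal dimension",
         call. = FALSE)
  r <- refine_forward(model$par, support_emb, query_emb, K)
  list(support = r$S, query = r$Q)
}

refine_forward <- function(par, S, Q, K) {
  caches <- vector("list", K)
  d <- ncol(S)
  sq <- 1 / sqrt(d)
  for (t in seq_len(K)) {
    Pq <- row_softmax(tcrossprod(Q, S) * sq)
    Rq <- Pq %*% S
    Ps <- row_softmax(tcrossprod(S, S) * sq)
    Rs <- Ps %*% S
    gq <- sigmoid(par$gate_q[t, ])
    gs <- sigmoid(par$gate_s[t, ])
    caches[[t]] <- list(S = S, Q = Q, Pq = Pq, Rq = Rq, Ps = Ps, Rs = Rs,
                        gq = gq, gs = gs)
    Q <- sweep(Q, 2, gq, "*") + sweep(Rq, 2, 1 - gq, "*")
    S <- sweep(S, 2, gs, "*") + sweep(Rs, 2, 1 - gs, "*")
  }
  list(S = S, Q = Q, caches = caches)
}

refine_backward <- function(par, caches, GS, GQ, K) {
  d_gate_q <- matrix(0, nrow(par$gate_q), ncol(par$gate_q))
  d_gate_s <- matrix(0, nrow(par$gate_s), ncol(par$gate_s))
  sq <- if (K > 0) 1 / sqrt(ncol(caches[[1]]$S)) else 1
  for (t in rev(seq_len(K))) {
    cc <- caches[[t]]
    dgq <- colSums(GQ * (cc$Q - cc$Rq))
    d_gate_q[t, ] <- dgq * cc$gq * (1 - cc$gq)
    dgs <- colSums(GS * (cc$S - cc$Rs))
    d_gate_s[t, ] <- dgs * cc$gs * (1 - cc$gs)
    GRq <- sweep(GQ, 2, 1 - cc$gq, "*")
    GRs <- sweep(GS, 2, 1 - cc$gs, "*")
    GQc <- sweep(GQ, 2, cc$gq, "*")
    GSc <- sweep(GS, 2, cc$gs, "*")
    # Rq = Pq S with Pq = softmax(Q S' / sqrt(d))
    dPq <- tcrossprod(GRq, cc$S)
    GSc <- GSc + crossprod(cc$Pq, GRq)
    dZq <- cc$Pq * (dPq - rowSums(dPq * cc$Pq))
    GQc <- GQc + dZq %*% cc$S * sq
    GSc <- GSc + crossprod(dZq, cc$Q) * sq
    # Rs = Ps S with Ps = softmax(S S' / sqrt(d))
    dPs <- tcrossprod(GRs, cc$S)
    GSc <- GSc + crossprod(cc$Ps, GRs)
    dZs <- cc$Ps * (dPs - rowSums(dPs * cc$Ps))
    GSc <- GSc + dZs %*% cc$S * sq + crossprod(dZs, cc$S) * sq
    GQ <- GQc
    GS <- GSc
  }
  list(GS = GS, GQ = GQ, gate_q = d_gate_q, gate_s = d_gate_s)
}

#' Class prototypes from support embeddings
#'
#' @param support_emb embedding matrix.
#' @param labels 0/1 support labels (one per row; both classes required).
#' @return matrix with rows \code{"0"} and \code{"1"}, the per-class means.
#' @export
class_prototypes <- function(support_emb, labels) {
  stopifnot(nrow(support_emb) == length(labels))
  if (!all(0:1 %in% labels))
    stop("both classes need at least one support point", call. = FALSE)
  rbind("0" = colMeans(support_emb[labels == 0, , drop = FALSE]),
        "1" = colMeans(support_emb[labels == 1, , drop = FALSE]))
}

#' Classify query embeddings against prototypes
#'
#' Class probability proportional to exp(-squared Euclidean distance) to
#' each prototype; rows sum to 1.
#'
#' @param query_emb embedding matrix.
#' @param protos prototype matrix from [class_prototypes()].
#' @return matrix of probabilities with columns \code{"0"} and \code{"1"}.
#' @export
classify_queries <- function(query_emb, protos) {
  stopifnot(nrow(protos) == 2)
  D2 <- outer(rowSums(query_emb^2), rep(1, 2)) -
    2 * tcrossprod(query_emb, protos) +
    outer(rep(1, nrow(query_emb)), rowSums(protos^2))
  p <- row_softmax(-D2)
  colnames(p) <- rownames(protos)
  p
}

# full forward pass + loss + gradients for one episode
episode_grad <- function(par, K, Xs, ys, Xq, yq) {
  X <- rbind(Xs, Xq)
  emb <- embed_forward(par, X)
  ns <- nrow(Xs)
  S0 <- emb$H2[seq_len(ns), , drop = FALSE]
  Q0 <- emb$H2[-seq_len(ns), , drop = FALSE]
  ref <- refine_forward(par, S0, Q0, K)
  S <- ref$S; Q <- ref$Q
  n0 <- sum(ys == 0); n1 <- sum(ys == 1)
  protos <- class_prototypes(S, ys)
  D2 <- outer(rowSums(Q^2), rep(1, 2)) - 2 * tcrossprod(Q, protos) +
    outer(rep(1, nrow(Q)), rowSums(protos^2))
  Z <- -D2
  Zs <- Z - apply(Z, 1, max)
  logp <- Zs - log(rowSums(exp(Zs)))
  nq <- nrow(Q)
  yi <- yq + 1L
  loss <- -mean(logp[cbind(seq_len(nq), yi)])
  P <- exp(logp)
  Y <- matrix(0, nq, 2); Y[cbind(seq_len(nq), yi)] <- 1
  dZ <- (P - Y) / nq
  dD2 <- -dZ
  # d/dQ ||q-c||^2 = 2(q-c); d/dc = -2(q-c)
  GQ <- 2 * (Q * rowSums(dD2) - dD2 %*% protos)
  GC <- -2 * (crossprod(dD2, Q) - protos * colSums(dD2))
  GS <- matrix(0, nrow(S), ncol(S))
  GS[ys == 0, ] <- matrix(GC[1, ] / n0, n0, ncol(S), byrow = TRUE)
  GS[ys == 1, ] <- matrix(GC[2, ] / n1, n1, ncol(S), byrow = TRUE)
  rb <- refine_backward(par, ref$caches, GS, GQ, K)
  dH2 <- rbind(rb$GS, rb$GQ)
  eb <- embed_backward(par, emb, dH2)
  grads <- c(eb, list(gate_q = rb$gate_q, gate_s = rb$gate_s))
  list(loss = loss, grads = grads, probs = P)
}

# global-norm gradient clipping: micro-episodes (one support active) have
# very high gradient variance and destabilize mixed-composition training
clip_grads <- function(grads, max_norm = 5) {
  norm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(norm) && norm > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / norm))
  grads
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

#' Train the few-shot classifier episodically
#'
#' Per episode: draw a task and a shot configuration (cycling through
#' \code{configs} by default), sample a support/query episode, embed,
#' refine, build prototypes, classify the query set, and update all
#' parameters with Adam on the negative log-likelihood. Training stops when
#' the moving average (window 50) of the episode loss falls below
#' \code{loss_tol} or after \code{max_episodes}.
#'
#' @param train_tasks list of classification \code{molecule_dataset}s (or
#'   [task_tensor()]s).
#' @param configs list of [shot_config()]s; defaults to the six standard
#'   compositions.
#' @param val_tasks optional validation tasks; if given, the model with the
#'   best validation ROC AUC (checked every \code{val_every} episodes) is
#'   returned.
#' @param max_episodes episode cap.
#' @param lr Adam learning rate.
#' @param loss_tol moving-average loss stopping tolerance.
#' @param seed seed governing initialization and episode sampling.
#' @param model optionally continue training an existing model.
#' @param val_every validation cadence in episodes.
#' @param clip global gradient-norm clip (micro-episodes with one support
#'   active otherwise destabilize mixed-composition training).
#' @param ... passed to [fslc_init()] (\code{n_bits}, \code{hidden},
#'   \code{K}, \code{radius}).
#' @return a trained \code{fslc_model} (with a \code{loss_history}
#'   attribute).
#' @export
fslc_train <- function(train_tasks, configs = default_shot_configs(),
                       val_tasks = NULL, max_episodes = 2000, lr = 1e-3,
                       loss_tol = 1e-6, seed = 1, model = NULL,
                       val_every = 250, clip = 5, ...) {
  stopifnot(length(train_tasks) >= 1)
  if (inherits(configs, "shot_config")) configs <- list(configs)
  if (is.null(model)) model <- fslc_init(seed = seed, ...)
  tensors <- lapply(train_tasks, function(tk)
    if (inherits(tk, "molecule_dataset"))
      task_tensor(tk, radius = model$radius, n_bits = model$n_bits) else tk)
  # keep only tasks that support every config
  feasible <- function(tt, cf)
    sum(tt$labels == 1) >= cf$support_actives + cf$query_actives &&
    sum(tt$labels == 0) >= cf$support_inactives + cf$query_inactives
  ok <- vapply(tensors, function(tt)
    all(vapply(configs, function(cf) feasible(tt, cf), logical(1))),
    logical(1))
  if (!any(ok))
    stop("no training task supports the requested shot configurations",
         call. = FALSE)
  tensors <- tensors[ok]
  par <- model$par
  state <- list(t = 0,
                m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 7))
  losses <- numeric(0)
  best <- list(score = -Inf, par = par)
  window <- 50
  for (ep in seq_len(max_episodes)) {
    cf <- configs[[(ep - 1) %% length(configs) + 1]]
    tt <- tensors[[sample.int(length(tensors), 1)]]
    epi <- sample_episode(tt, cf)
    g <- episode_grad(par, model$K,
                      tt$fp[epi$support_idx, , drop = FALSE],
                      epi$support_labels,
                      tt$fp[epi$query_idx, , drop = FALSE],
                      epi$query_labels)
    st <- adam_step(par, clip_grads(g$grads, max_norm = clip), state, lr)
    par <- st$par; state <- st$state
    losses <- c(losses, g$loss)
    if (length(losses) >= window &&
        mean(utils::tail(losses, window)) < loss_tol) break
    if (!is.null(val_tasks) && ep %% val_every == 0) {
      m <- model; m$par <- par
      sc <- fslc_evaluate(m, val_tasks, configs, n_resamples = 20,
                          seed = derive_seed(seed, 100 + ep))
      v <- mean(vapply(sc, function(r) r$mean["rocauc"], numeric(1)))
      if (v > best$score) best <- list(score = v, par = par)
    }
  }
  if (!is.null(val_tasks) && best$score > -Inf) par <- best$par
  model$par <- par
  model$trained_episodes <- model$trained_episodes + length(losses)
  attr(model, "loss_history") <- losses
  model
}

#' Score query molecules with a trained model
#'
#' @param model an \code{fslc_model}.
#' @param support_fp,support_labels support fingerprints and 0/1 labels.
#' @param query_fp query fingerprints.
#' @return numeric vector of P(active) per query.
#' @export
fslc_predict <- function(model, support_fp, support_labels, query_fp) {
  ns <- nrow(support_fp)
  emb <- fslc_embed(model, rbind(support_fp, query_fp))
  S <- emb[seq_len(ns), , drop = FALSE]
  Q <- emb[-seq_len(ns), , drop = FALSE]
  ref <- refine_forward(model$par, S, Q, model$K)
  p <- classify_queries(ref$Q, class_prototypes(ref$S, support_labels))
  unname(p[, "1"])
}

#' Evaluate a model by repeated episodic resampling
#'
#' For each task and shot configuration, \code{n_resamples} episodes are
#' drawn, the query sets scored, and per-episode metrics (ROC AUC, average
#' precision, F1, Cohen's kappa, MCC) averaged within each task; the report
#' gives the mean and standard deviation of the per-task averages across
#' tasks.
#'
#' @param model an \code{fslc_model} (or any scorer via
#'   \code{scorer}: a \code{function(support_fp, support_labels, query_fp)}
#'   returning P(active), enabling baseline comparisons under the identical
#'   protocol).
#' @param test_tasks list of classification datasets or [task_tensor()]s.
#' @param configs list of [shot_config()]s.
#' @param n_resamples episodes per task and configuration.
#' @param seed RNG seed.
#' @param scorer optional replacement scoring function.
#' @return named list (one entry per config label) of lists with
#'   \code{mean}, \code{sd} (named metric vectors across tasks) and
#'   \code{per_task} (matrix tasks x metrics).
#' @export
fslc_evaluate <- function(model, test_tasks, configs = default_shot_configs(),
                          n_resamples = 1000, seed = 1, scorer = NULL) {
  if (inherits(configs, "shot_config")) configs <- list(configs)
  tensors <- lapply(test_tasks, function(tk)
    if (inherits(tk, "molecule_dataset"))
      task_tensor(tk,
                  radius = if (is.null(model)) 5 else model$radius,
                  n_bits = if (is.null(model)) 2048 else model$n_bits)
    else tk)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  metric_names <- c("rocauc", "avg_precision", "f1", "ck", "mcc")
  # with a fixed model the embedding of each molecule is constant, so embed
  # every task once and let episodes index rows
  emb_cache <- if (is.null(scorer))
    lapply(tensors, function(tt) fslc_embed(model, tt$fp)) else NULL
  out <- list()
  for (cf in configs) {
    per_task <- matrix(NA_real_, length(tensors), length(metric_names),
                       dimnames = list(vapply(tensors, `[[`, "", "id"),
                                       metric_names))
    for (ti in seq_along(tensors)) {
      tt <- tensors[[ti]]
      acc <- matrix(NA_real_, n_resamples, length(metric_names))
      for (r in seq_len(n_resamples)) {
        epi <- sample_episode(tt, cf)
        if (is.null(scorer)) {
          E <- emb_cache[[ti]]
          ref <- refine_forward(model$par,
                                E[epi$support_idx, , drop = FALSE],
                                E[epi$query_idx, , drop = FALSE], model$K)
          scores <- unname(classify_queries(
            ref$Q, class_prototypes(ref$S, epi$support_labels))[, "1"])
        } else {
          scores <- scorer(tt$fp[epi$support_idx, , drop = FALSE],
                           epi$support_labels,
                           tt$fp[epi$query_idx, , drop = FALSE])
        }
        rep_ <- metric_report(epi$query_labels, scores)
        acc[r, ] <- unlist(rep_[metric_names])
      }
      per_task[ti, ] <- colMeans(acc)
    }
    out[[cf$label]] <- list(mean = colMeans(per_task),
                            sd = apply(per_task, 2, stats::sd),
                            per_task = per_task)
  }
  out
}

#' Serialize / restore a few-shot model as JSON
#'
#' @param model an \code{fslc_model}.
#' @param path JSON file path.
#' @return \code{fslc_write}: the path, invisibly; \code{fslc_read}: the
#'   model.
#' @export
fslc_write <- function(model, path) {
  obj <- list(n_bits = model$n_bits, hidden = model$hidden, K = model$K,
              radius = model$radius, seed = model$seed,
              trained_episodes = model$trained_episodes,
              par = lapply(model$par, function(p)
                if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
                else list(dim = NULL, data = as.vector(p))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname fslc_write
#' @export
fslc_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- lapply(obj$par, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2)
      matrix(p$data, p$dim[1], p$dim[2]) else as.numeric(p$data)
  })
  structure(list(par = par, n_bits = obj$n_bits, hidden = obj$hidden,
                 K = obj$K, radius = obj$radius, seed = obj$seed,
                 trained_episodes = obj$trained_episodes),
            class = "fslc_model")
}
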