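# Classical fingerprint models under nested cross-validation, plus an
# import interface for externally produced prediction scores (e.g. from a
# fine-tuned sequence model). Model fitting is delegated to e1071 (libsvm),
# randomForest, class::knn and stats::glm; the nested-CV orchestration,
# hyperparameter selection, score calibration and metrics are package code.

default_hyper_grid <- function(algorithm) {
  switch(algorithm,
         svc = ,
         svr = expand.grid(cost = c(0.1, 1, 10, 100),
                           gamma = c(NA, 0.01, 0.001)),  # NA = 1/p default
         knn = data.frame(k = c(1, 3, 5, 7)),
         rf = data.frame(ntree = c(200)),
         logistic = data.frame(dummy = 1))
}

#' Configuration for a classical baseline
#'
#' @param algorithm one of \code{"svc"}, \code{"svr"}, \code{"knn"},
#'   \code{"rf"}, \code{"logistic"}; defaults to SVC for classification
#'   tasks and SVR for regression.
#' @param fp_radius,fp_bits circular-fingerprint parameters (default ECFP6:
#'   radius 3, 1024 bits).
#' @param outer_folds,inner_folds nested cross-validation fold counts.
#' @param hyper_grid data.frame of hyperparameter combinations to search in
#'   the inner loop; defaults per algorithm (radial-basis SVM with
#'   C in {0.1, 1, 10, 100} and gamma in {1/p, 0.01, 0.001}).
#' @param seed RNG seed.
#' @return a \code{baseline_config}.
#' @export
baseline_config <- function(algorithm = NULL, fp_radius = 3, fp_bits = 1024,
                            outer_folds = 5, inner_folds = 5,
                            hyper_grid = NULL, seed = 1) {
  if (!is.null(algorithm))
    algorithm <- match.arg(algorithm, c("svc", "svr", "knn", "rf",
                                        "logistic"))
  stopifnot(outer_folds >= 2, inner_folds >= 2)
  structure(list(algorithm = algorithm, fp_radius = fp_radius,
                 fp_bits = fp_bits, outer_folds = outer_folds,
                 inner_folds = inner_folds, hyper_grid = hyper_grid,
                 seed = as.integer(seed)),
            class = "baseline_config")
}

resolve_algorithm <- function(config, kind) {
  if (!is.null(config$algorithm)) return(config$algorithm)
  if (kind == "classification") "svc" else "svr"
}

# stratified fold assignment: shuffled round-robin within each class keeps
# fold class counts within one of each other
make_folds <- function(y, k, stratified) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[sample_vec(idx)] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

fit_algo <- function(algorithm, X, y, hyper, kind) {
  if (kind == "classification") {
    yf <- factor(y, levels = c(0, 1))
    switch(algorithm,
      svc = {
        gamma <- if (is.na(hyper$gamma)) 1 / ncol(X) else hyper$gamma
        e1071::svm(X, yf, kernel = "radial", cost = hyper$cost,
                   gamma = gamma, scale = FALSE)
      },
      knn = list(knn = TRUE, X = X, y = yf, k = hyper$k),
      rf = randomForest::randomForest(X, yf, ntree = hyper$ntree),
      logistic = suppressWarnings(
        stats::glm.fit(cbind(1, X), y, family = stats::binomial())),
      stop("algorithm ", algorithm, " is not a classifier", call. = FALSE))
  } else {
    switch(algorithm,
      svr = {
        gamma <- if (is.na(hyper$gamma)) 1 / ncol(X) else hyper$gamma
        e1071::svm(X, y, kernel = "radial", cost = hyper$cost,
                   gamma = gamma, scale = FALSE, type = "eps-regression")
      },
      knn = list(knn = TRUE, reg = TRUE, X = X, y = y, k = hyper$k),
      rf = randomForest::randomForest(X, y, ntree = hyper$ntree),
      stop("algorithm ", algorithm, " is not a regressor", call. = FALSE))
  }
}

# classification: numeric score increasing with P(active); regression:
# predicted -log[M]
predict_algo <- function(algorithm, model, X, kind) {
  if (kind == "regression") {
    if (is.list(model) && isTRUE(model$knn)) {
      d <- as.matrix(stats::dist(rbind(model$X, X)))
      nt <- nrow(model$X)
      return(vapply(seq_len(nrow(X)), function(i) {
        nn <- order(d[nt + i, seq_len(nt)])[seq_len(model$k)]
        mean(model$y[nn])
      }, numeric(1)))
    }
    return(unname(stats::predict(model, X)))
  }
  switch(algorithm,
    svc = {
      p <- stats::predict(model, X, decision.values = TRUE)
      dvm <- attr(p, "decision.values")
      dv <- unname(drop(dvm))
      # libsvm orients decision values toward the first class in the column
      # label; flip so larger = more active (class "1")
      lev <- strsplit(colnames(dvm)[1], "/")[[1]]
      if (lev[1] == "1") dv else -dv
    },
    knn = {
      pr <- class::knn(model$X, X, model$y, k = model$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    rf = unname(stats::predict(model, X, type = "prob")[, "1"]),
    logistic = {
      eta <- drop(cbind(1, X) %*% model$coefficients)
      eta[is.na(eta)] <- 0
      1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
    })
}

eval_fold <- function(labels, scores, kind) {
  if (kind == "classification") {
    if (length(unique(labels)) < 2)
      return(c(rocauc = NA, avg_precision = NA, f1 = NA, ck = NA, mcc = NA,
               r2 = NA))
    r <- metric_report(labels, scores,
                       threshold = if (all(scores >= 0 & scores <= 1))
                         0.5 else 0)
    c(unlist(r[c("rocauc", "avg_precision", "f1", "ck", "mcc")]), r2 = NA)
  } else {
    c(rocauc = NA, avg_precision = NA, f1 = NA, ck = NA, mcc = NA,
      r2 = r_squared(labels, scores))
  }
}

#' Nested cross-validation of a classical fingerprint model
#'
#' Outer folds (stratified for classification) estimate generalization;
#' inner folds select hyperparameters from the grid by mean ROC AUC
#' (classification) or R^2 (regression). For classification a logistic
#' calibration is fit on the inner-fold decision values of each outer
#' training set and applied to the outer test scores, so reported scores
#' are probabilities.
#'
#' @param dataset a curated \code{molecule_dataset}.
#' @param config a [baseline_config()].
#' @return a \code{cv_result}: list with \code{per_fold} (metric matrix),
#'   \code{aggregate} (mean and sd), \code{chosen} (hyperparameters per
#'   fold), \code{predictions} (data.frame with row, fold, label/truth,
#'   score), \code{kind}, \code{algorithm}.
#' @export
nested_cv <- function(dataset, config = baseline_config()) {
  stopifnot(inherits(dataset, "molecule_dataset"),
            inherits(config, "baseline_config"))
  kind <- task_kind(dataset)
  algorithm <- resolve_algorithm(config, kind)
  grid <- config$hyper_grid
  if (is.null(grid)) grid <- default_hyper_grid(algorithm)
  y <- if (kind == "classification") dataset$activity_class else
    dataset$activity
  if (kind == "classification" &&
      min(table(y)) < config$outer_folds)
    stop("too few records per class for ", config$outer_folds,
         "-fold stratified CV; reduce outer_folds", call. = FALSE)
  X <- fingerprint_matrix(dataset$smiles, "circular",
                          radius = config$fp_radius, n_bits = config$fp_bits)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  outer <- make_folds(y, config$outer_folds, kind == "classification")
  per_fold <- NULL
  chosen <- list()
  preds <- data.frame()
  for (f in seq_len(config$outer_folds)) {
    tr <- which(outer != f); te <- which(outer == f)
    inner <- make_folds(y[tr], config$inner_folds, kind == "classification")
    inner_score <- vapply(seq_len(nrow(grid)), function(h) {
      sc <- vapply(seq_len(config$inner_folds), function(g) {
        itr <- tr[inner != g]; ite <- tr[inner == g]
        if (kind == "classification" && length(unique(y[ite])) < 2)
          return(NA_real_)
        m <- fit_algo(algorithm, X[itr, , drop = FALSE], y[itr],
                      grid[h, , drop = FALSE], kind)
        s <- predict_algo(algorithm, m, X[ite, , drop = FALSE], kind)
        if (kind == "classification") roc_auc(s, y[ite]) else
          r_squared(y[ite], s)
      }, numeric(1))
      mean(sc, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(inner_score)
    chosen[[f]] <- grid[best, , drop = FALSE]
    m <- fit_algo(algorithm, X[tr, , drop = FALSE], y[tr],
                  grid[best, , drop = FALSE], kind)
    s_te <- predict_algo(algorithm, m, X[te, , drop = FALSE], kind)
    if (kind == "classification" && algorithm == "svc") {
      # logistic calibration on the inner-fold decision values
      cal_s <- unlist(lapply(seq_len(config$inner_folds), function(g) {
        itr <- tr[inner != g]; ite <- tr[inner == g]
        mi <- fit_algo(algorithm, X[itr, , drop = FALSE], y[itr],
                       grid[best, , drop = FALSE], kind)
        stats::setNames(predict_algo(algorithm, mi,
                                     X[ite, , drop = FALSE], kind), ite)
      }))
      cal_y <- y[as.integer(names(cal_s))]
      cal <- suppressWarnings(stats::glm(cal_y ~ cal_s,
                                         family = stats::binomial()))
      s_te <- unname(stats::predict(cal, data.frame(cal_s = s_te),
                                    type = "response"))
    }
    per_fold <- rbind(per_fold, eval_fold(y[te], s_te, kind))
    preds <- rbind(preds, data.frame(row = te, fold = f, truth = y[te],
                                     score = s_te))
  }
  rownames(per_fold) <- paste0("fold", seq_len(config$outer_folds))
  structure(list(
    per_fold = per_fold,
    aggregate = list(mean = colMeans(per_fold, na.rm = TRUE),
                     sd = apply(per_fold, 2, stats::sd, na.rm = TRUE)),
    chosen = chosen, predictions = preds, kind = kind,
    algorithm = algorithm, config = config), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %s, %d outer folds\n", x$algorithm, x$kind,
              nrow(x$per_fold)))
  m <- x$aggregate$mean; s <- x$aggregate$sd
  keep <- !is.na(m)
  cat(paste(sprintf("  %s: %.3f +/- %.3f", names(m)[keep], m[keep],
                    s[keep]), collapse = "\n"), "\n")
  invisible(x)
}

#' Fit a final model on the full dataset
#'
#' Runs [nested_cv()] (or accepts its result), picks the modal
#' hyperparameters across outer folds, refits on all data, and fits a
#' calibration map on cross-validated scores so classification predictions
#' land in [0, 1].
#'
#' @param dataset a curated \code{molecule_dataset}.
#' @param config a [baseline_config()].
#' @param cv optional precomputed \code{cv_result}.
#' @return a \code{baseline_predictor} handle for [predict_baseline()].
#' @export
fit_final <- function(dataset, config = baseline_config(), cv = NULL) {
  if (is.null(cv)) cv <- nested_cv(dataset, config)
  kind <- cv$kind
  algorithm <- cv$algorithm
  tab <- table(vapply(cv$chosen, function(h)
    paste(unlist(h), collapse = "|"), character(1)))
  modal <- names(tab)[which.max(tab)]
  hyper <- cv$chosen[[which(vapply(cv$chosen, function(h)
    paste(unlist(h), collapse = "|"), character(1)) == modal)[1]]]
  y <- if (kind == "classification") dataset$activity_class else
    dataset$activity
  X <- fingerprint_matrix(dataset$smiles, "circular",
                          radius = config$fp_radius, n_bits = config$fp_bits)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  model <- fit_algo(algorithm, X, y, hyper, kind)
  cal <- NULL
  if (kind == "classification" && algorithm == "svc") {
    s <- cv$predictions$score[order(cv$predictions$row)]
    cal <- suppressWarnings(stats::glm(y ~ s, family = stats::binomial(),
                                       data = data.frame(y = y, s = s)))
  }
  structure(list(model = model, algorithm = algorithm, kind = kind,
                 hyper = hyper, calibration = cal, config = config),
            class = "baseline_predictor")
}

#' Predict with a fitted baseline
#'
#' @param handle a \code{baseline_predictor} from [fit_final()].
#' @param smiles character vector of SMILES.
#' @return scores: P(active) in [0, 1] for classification, -log[M] for
#'   regression.
#' @export
predict_baseline <- function(handle, smiles) {
  stopifnot(inherits(handle, "baseline_predictor"))
  X <- fingerprint_matrix(smiles, "circular",
                          radius = handle$config$fp_radius,
                          n_bits = handle$config$fp_bits)
  s <- predict_algo(handle$algorithm, handle$model, X, handle$kind)
  if (!is.null(handle$calibration))
    s <- unname(stats::predict(handle$calibration, data.frame(s = s),
                               type = "response"))
  s
}

#' Episode scorer wrapping an SVC, for protocol-matched comparisons
#'
#' Returns a \code{function(support_fp, support_labels, query_fp)} that
#' fits a radial-basis SVC on the support set of each episode and scores
#' the queries, for use as the \code{scorer} argument of
#' [fslc_evaluate()]. By default the queries are scored by the predicted
#' class (0/1), matching the reporting convention of classification
#' pipelines that compute every metric, ROC AUC included, from hard label
#' predictions - which is why an SVC shown a single support active sits at
#' chance. Set \code{hard = FALSE} for continuous decision-value scores.
#' Degenerate fits fall back to chance.
#'
#' @param cost,gamma fallback SVM hyperparameters (gamma NA = 1/p), used
#'   when selection is off or the support set is too small to fold.
#' @param hard score queries by predicted class instead of decision value.
#' @param select per-episode hyperparameter selection: when each support
#'   class has at least 3 members, the default grid is searched by 3-fold
#'   CV accuracy, mirroring the nested hyperparameter optimization used
#'   for the full-size baselines.
#' @return a scoring closure.
#' @export
svc_episode_scorer <- function(cost = 1, gamma = NA, hard = TRUE,
                               select = TRUE) {
  grid <- default_hyper_grid("svc")
  function(support_fp, support_labels, query_fp) {
    tryCatch({
      hyper <- data.frame(cost = cost, gamma = gamma)
      if (select && min(table(support_labels)) >= 3) {
        folds <- make_folds(support_labels, 3, stratified = TRUE)
        acc <- vapply(seq_len(nrow(grid)), function(h) {
          mean(vapply(1:3, function(f) {
            tr <- folds != f
            m <- fit_algo("svc", support_fp[tr, , drop = FALSE],
                          support_labels[tr], grid[h, , drop = FALSE],
                          "classification")
            mean(as.integer(as.character(
              stats::predict(m, support_fp[!tr, , drop = FALSE]))) ==
                support_labels[!tr])
          }, numeric(1)))
        }, numeric(1))
        hyper <- grid[which.max(acc), , drop = FALSE]
      }
      m <- fit_algo("svc", support_fp, support_labels, hyper,
                    "classification")
      if (hard) {
        as.numeric(as.character(stats::predict(m, query_fp)))
      } else {
        s <- predict_algo("svc", m, query_fp, "classification")
        1 / (1 + exp(-s))
      }
    }, error = function(e) rep(0.5, nrow(query_fp)))
  }
}

#' Select episodic SVC hyperparameters for a task
#'
#' Mirrors per-dataset nested hyperparameter optimization at episodic
#' scale: draws \code{n_episodes} support sets at the given composition,
#' scores every grid combination by 3-fold cross-validated ROC AUC on the
#' support molecules only, and returns the combination with the best
#' average. The choice is then held fixed across evaluation resamples
#' (query sets are never touched).
#'
#' @param task a classification \code{molecule_dataset} or [task_tensor()].
#' @param config a [shot_config()]; per-class support counts must be >= 3
#'   so the support folds contain both classes.
#' @param grid hyperparameter data.frame (default: the standard SVC grid).
#' @param n_episodes selection episodes to average over.
#' @param seed RNG seed.
#' @return one-row data.frame with \code{cost} and \code{gamma}.
#' @export
episodic_svc_hypers <- function(task, config, grid = default_hyper_grid("svc"),
                                n_episodes = 20, seed = 1) {
  tt <- if (inherits(task, "molecule_dataset")) task_tensor(task) else task
  if (min(config$support_actives, config$support_inactives) < 3)
    stop("support composition too small for inner folds; use the scorer's ",
         "fallback hyperparameters instead", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  score <- matrix(NA_real_, n_episodes, nrow(grid))
  for (e in seq_len(n_episodes)) {
    epi <- sample_episode(tt, config)
    sfp <- tt$fp[epi$support_idx, , drop = FALSE]
    sl <- epi$support_labels
    folds <- make_folds(sl, 3, stratified = TRUE)
    for (h in seq_len(nrow(grid))) {
      aucs <- vapply(1:3, function(f) {
        tr <- folds != f
        if (length(unique(sl[!tr])) < 2) return(NA_real_)
        m <- fit_algo("svc", sfp[tr, , drop = FALSE], sl[tr],
                      grid[h, , drop = FALSE], "classification")
        roc_auc(predict_algo("svc", m, sfp[!tr, , drop = FALSE],
                             "classification"), sl[!tr])
      }, numeric(1))
      score[e, h] <- mean(aucs, na.rm = TRUE)
    }
  }
  grid[which.max(colMeans(score, na.rm = TRUE)), , drop = FALSE]
}

#' Import externally produced prediction scores
#'
#' Reads a CSV of per-molecule scores (columns \code{structure_key} or
#' \code{smiles}, and \code{score}) standing in for predictions of an
#' external model, and matches them against a dataset.
#'
#' @param path CSV path.
#' @param dataset the \code{molecule_dataset} the scores refer to.
#' @param strict error unless every dataset molecule is covered.
#' @return an \code{external_scores} list: \code{scores} (named by
#'   structure key, NA where missing), \code{coverage} fraction,
#'   \code{provenance}.
#' @export
import_external_scores <- function(path, dataset, strict = FALSE) {
  stopifnot(inherits(dataset, "molecule_dataset"))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"score" %in% names(tab))
    stop("score column required in ", path, call. = FALSE)
  keys <- if ("structure_key" %in% names(tab)) tab$structure_key
    else if ("smiles" %in% names(tab)) structure_key(tab$smiles)
    else stop("need a structure_key or smiles column in ", path,
              call. = FALSE)
  if (any(!is.finite(tab$score)))
    stop("non-finite scores in ", path, call. = FALSE)
  m <- match(dataset$structure_key, keys)
  scores <- stats::setNames(tab$score[m], dataset$structure_key)
  coverage <- mean(!is.na(m))
  alien <- setdiff(keys, dataset$structure_key)
  if (length(alien) > 0)
    warning(length(alien), " score record(s) match no dataset molecule",
            call. = FALSE)
  if (strict && coverage < 1)
    stop(sprintf("score coverage %.3f < 1 with strict matching", coverage),
         call. = FALSE)
  structure(list(scores = scores, coverage = coverage,
                 provenance = path), class = "external_scores")
}
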