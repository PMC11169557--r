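# Curation of single-target bioactivity datasets: reading, standardization,
# unit conversion to -log[M], deduplication, binarization, filtering, splits.

#' Construct a molecule dataset
#'
#' A \code{molecule_dataset} is a data.frame with one row per molecule
#' (columns \code{smiles}, \code{structure_key}, \code{activity},
#' \code{activity_class}, \code{source_value}, \code{source_unit}) plus
#' attributes \code{dataset_id}, \code{task_kind} and (optionally)
#' \code{threshold_molar}.
#'
#' @param smiles character vector of parseable SMILES.
#' @param activity potency in -log[M] (optional, NA allowed).
#' @param activity_class binary 0/1 labels (optional).
#' @param source_value,source_unit raw reported numbers and units (optional).
#' @param dataset_id identifier string.
#' @param task_kind \code{"regression"} or \code{"classification"}.
#' @param threshold_molar molar activity threshold, if binarized.
#' @param keys precomputed structure keys (computed from SMILES if NULL).
#' @return an object of class \code{molecule_dataset}.
#' @export
molecule_dataset <- function(smiles, activity = NULL, activity_class = NULL,
                             source_value = NULL, source_unit = NULL,
                             dataset_id = "dataset",
                             task_kind = c("regression", "classification"),
                             threshold_molar = NULL, keys = NULL) {
  task_kind <- match.arg(task_kind)
  n <- length(smiles)
  if (n == 0) stop("empty dataset: no molecules", call. = FALSE)
  if (is.null(keys)) keys <- structure_key(smiles)
  if (anyNA(keys)) stop("unparseable SMILES in dataset", call. = FALSE)
  act <- if (is.null(activity)) rep(NA_real_, n) else as.numeric(activity)
  if (any(!is.na(act) & !is.finite(act)))
    stop("activity values must be finite", call. = FALSE)
  cls <- if (is.null(activity_class)) rep(NA_integer_, n) else
    as.integer(activity_class)
  if (any(!is.na(cls) & !cls %in% c(0L, 1L)))
    stop("activity_class must be 0 or 1", call. = FALSE)
  if (task_kind == "classification" && anyNA(cls))
    stop("classification datasets need activity_class for every record",
         call. = FALSE)
  df <- data.frame(
    smiles = smiles,
    structure_key = keys,
    activity = act,
    activity_class = cls,
    source_value = if (is.null(source_value)) NA_real_ else source_value,
    source_unit = if (is.null(source_unit)) NA_character_ else source_unit,
    stringsAsFactors = FALSE
  )
  structure(df, class = c("molecule_dataset", "data.frame"),
            dataset_id = dataset_id, task_kind = task_kind,
            threshold_molar = threshold_molar)
}

#' @export
print.molecule_dataset <- function(x, ...) {
  cat(sprintf("<molecule_dataset '%s'> %d molecules, task: %s\n",
              attr(x, "dataset_id"), nrow(x), attr(x, "task_kind")))
  if (attr(x, "task_kind") == "classification")
    cat(sprintf("  actives: %d, inactives: %d\n",
                sum(x$activity_class == 1), sum(x$activity_class == 0)))
  invisible(x)
}

#' Dataset identifier, task kind
#' @param dataset a \code{molecule_dataset}.
#' @return a string.
#' @export
dataset_id <- function(dataset) attr(dataset, "dataset_id")

#' @rdname dataset_id
#' @export
task_kind <- function(dataset) attr(dataset, "task_kind")

unit_multiplier <- function(unit) {
  u <- tolower(trimws(unit))
  u[u == "µm"] <- "um"
  mult <- c(m = 1, mm = 1e-3, um = 1e-6, nm = 1e-9)
  out <- unname(mult[u])
  if (anyNA(out))
    stop("unrecognized concentration unit(s): ",
         paste(unique(unit[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Convert a concentration to -log[M]
#'
#' Potencies are standardized to the negative decadic logarithm of molar
#' concentration (the pIC50-style scale): 100 nM becomes exactly 7.
#'
#' @param value positive concentration value(s).
#' @param unit unit token(s): M, mM, uM (or the micro sign), nM;
#'   case-insensitive. Recycled against \code{value}.
#' @return numeric vector of -log10(molar) values.
#' @export
#' @examples
#' to_neg_log_molar(100, "nM")  # 7
to_neg_log_molar <- function(value, unit) {
  if (any(!is.finite(value) | value <= 0))
    stop("concentration values must be positive and finite", call. = FALSE)
  -log10(value * unit_multiplier(unit))
}

#' Standardize SMILES (salt stripping hook)
#'
#' Default standardization: keep the largest organic fragment of
#' multi-component records (salt stripping). This is the package's
#' replacement for heavyweight proprietary cleaning pipelines; pass any
#' function \code{character -> character} as the \code{standardize} argument
#' of [read_bioactivity()] to substitute your own.
#'
#' @param smiles character vector of parseable SMILES.
#' @param reject_multicomponent error on multi-fragment records instead of
#'   stripping.
#' @return standardized canonical SMILES.
#' @export
standardize_smiles <- function(smiles, reject_multicomponent = FALSE) {
  can <- canonical_smiles(smiles)
  multi <- grepl(".", can, fixed = TRUE)
  if (any(multi) && reject_multicomponent)
    stop("multi-component record(s) at position(s): ",
         paste(utils::head(which(multi), 5), collapse = ", "), call. = FALSE)
  for (i in which(multi)) {
    frags <- strsplit(can[i], ".", fixed = TRUE)[[1]]
    # heavy-atom count per fragment decides the "largest organic" fragment;
    # organic = contains carbon
    nheavy <- vapply(frags, function(f) {
      sdf <- smiles_to_sdfset(f)
      nrow(ChemmineR::atomblock(sdf[[1]]))
    }, numeric(1))
    has_c <- grepl("c", frags, ignore.case = TRUE)
    cand <- if (any(has_c)) frags[has_c] else frags
    nh <- nheavy[match(cand, frags)]
    can[i] <- cand[which.max(nh)]
  }
  canonical_smiles(can)
}

#' Read a single-target bioactivity dataset
#'
#' Reads a CSV (header required; configurable column names) or a .smi file
#' (whitespace-separated SMILES plus optional identifier). Rows with
#' unparseable SMILES abort the read when \code{strict}, otherwise they are
#' skipped with a warning. Row order is preserved.
#'
#' @param path file path (.csv or .smi).
#' @param column_map named character vector mapping roles to column names;
#'   defaults \code{c(smiles = "smiles", value = "value", unit = "unit")}.
#'   Set \code{value}/\code{unit} to NA for structure-only files.
#' @param strict abort on invalid SMILES rows.
#' @param standardize NULL, or a function applied to the SMILES column before
#'   validation (see [standardize_smiles()]).
#' @param dataset_id identifier; defaults to the file name.
#' @return a \code{molecule_dataset} with activities in -log[M] when value
#'   and unit columns are present.
#' @export
read_bioactivity <- function(path,
                             column_map = c(smiles = "smiles",
                                            value = "value", unit = "unit"),
                             strict = FALSE, standardize = NULL,
                             dataset_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("smiles", "id")[1:2],
                             fill = TRUE)
    smiles <- tab[[1]]
    value <- NULL; unit <- NULL
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
    need <- column_map[!is.na(column_map)]
    missing_cols <- setdiff(unname(need["smiles"]), names(tab))
    if (length(missing_cols) > 0)
      stop("missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    smiles <- tab[[need[["smiles"]]]]
    has_act <- all(c("value", "unit") %in% names(need)) &&
      all(need[c("value", "unit")] %in% names(tab))
    if (all(c("value", "unit") %in% names(need)) && !has_act)
      stop("missing required column(s): ",
           paste(setdiff(unname(need[c("value", "unit")]), names(tab)),
                 collapse = ", "), call. = FALSE)
    value <- if (has_act) tab[[need[["value"]]]] else NULL
    unit <- if (has_act) tab[[need[["unit"]]]] else NULL
  }
  if (!is.null(standardize)) smiles <- standardize(smiles)
  ok <- is_valid_smiles(smiles)
  if (!all(ok)) {
    if (strict)
      stop("invalid SMILES at row(s): ",
           paste(utils::head(which(!ok), 10), collapse = ", "), call. = FALSE)
    warning(sum(!ok), " row(s) with invalid SMILES skipped (rows ",
            paste(utils::head(which(!ok), 10), collapse = ", "), ")",
            call. = FALSE)
  }
  if (!any(ok)) stop("no valid rows in ", path, call. = FALSE)
  activity <- NULL
  if (!is.null(value)) activity <- to_neg_log_molar(value[ok], unit[ok])
  molecule_dataset(smiles[ok], activity = activity,
                   source_value = if (is.null(value)) NULL else value[ok],
                   source_unit = if (is.null(unit)) NULL else unit[ok],
                   dataset_id = dataset_id)
}

#' Average duplicate molecules by structure key
#'
#' Collapses records sharing a structure key to a single record whose
#' activity is the arithmetic mean of the duplicates' activities on the
#' -log[M] scale; the first-seen SMILES is retained and first-seen order is
#' preserved. Idempotent.
#'
#' @param dataset a \code{molecule_dataset} whose records all carry
#'   activities.
#' @return a deduplicated \code{molecule_dataset}.
#' @export
dedupe_average <- function(dataset) {
  stopifnot(inherits(dataset, "molecule_dataset"))
  if (anyNA(dataset$activity))
    stop("dedupe_average requires an activity for every record",
         call. = FALSE)
  keys <- dataset$structure_key
  first <- !duplicated(keys)
  mean_by_key <- tapply(dataset$activity, keys, mean)
  out <- dataset[first, , drop = FALSE]
  out$activity <- unname(mean_by_key[out$structure_key])
  molecule_dataset(out$smiles, activity = out$activity,
                   source_value = out$source_value,
                   source_unit = out$source_unit,
                   dataset_id = dataset_id(dataset), keys = out$structure_key)
}

#' Binarize activities at a molar threshold
#'
#' A molecule is active (class 1) when its potency is at or below the
#' threshold concentration, i.e. when its -log[M] activity is >= the
#' threshold's -log[M] value (100 nM corresponds to 7; the boundary is
#' inclusive on the active side).
#'
#' @param dataset a \code{molecule_dataset} with activities in -log[M].
#' @param threshold_molar threshold concentration in mol/L (e.g. 1e-7 for
#'   100 nM).
#' @return a classification \code{molecule_dataset}.
#' @export
#' @examples
#' \dontrun{binarize(ds, threshold_molar = 1e-7)}
binarize <- function(dataset, threshold_molar) {
  stopifnot(inherits(dataset, "molecule_dataset"), threshold_molar > 0)
  if (anyNA(dataset$activity))
    stop("binarize requires an activity for every record", call. = FALSE)
  cut <- -log10(threshold_molar)
  molecule_dataset(dataset$smiles, activity = dataset$activity,
                   activity_class = as.integer(dataset$activity >= cut),
                   source_value = dataset$source_value,
                   source_unit = dataset$source_unit,
                   dataset_id = dataset_id(dataset),
                   task_kind = "classification",
                   threshold_molar = threshold_molar,
                   keys = dataset$structure_key)
}

#' Filter a collection of datasets by size minima
#'
#' Retains datasets with at least \code{min_total} records and, when
#' \code{min_per_class} is set, at least that many records in each class.
#' Order is preserved; removals are reported via message.
#'
#' @param collection list of \code{molecule_dataset}s.
#' @param min_total minimum total record count ("fewer than" is removed, so
#'   a dataset of exactly \code{min_total} is retained).
#' @param min_per_class minimum per-class count, or NULL to skip.
#' @param quiet suppress the removal message.
#' @return filtered list.
#' @export
filter_datasets <- function(collection, min_total = 20,
                            min_per_class = NULL, quiet = FALSE) {
  stopifnot(is.list(collection))
  keep <- vapply(collection, function(ds) {
    stopifnot(inherits(ds, "molecule_dataset"))
    if (nrow(ds) < min_total) return(FALSE)
    if (!is.null(min_per_class)) {
      if (task_kind(ds) != "classification")
        stop("min_per_class set on a non-classification dataset: ",
             dataset_id(ds), call. = FALSE)
      if (sum(ds$activity_class == 1) < min_per_class ||
          sum(ds$activity_class == 0) < min_per_class) return(FALSE)
    }
    TRUE
  }, logical(1))
  if (!quiet && any(!keep))
    message(sum(!keep), " dataset(s) removed by size filter: ",
            paste(vapply(collection[!keep], dataset_id, character(1)),
                  collapse = ", "))
  collection[keep]
}

# floor the fraction targets and give the remainder to the largest fraction
partition_sizes <- function(n, fractions) {
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[which.max(fractions)] <- sizes[which.max(fractions)] + rem
  sizes
}

#' Split a dataset into partitions
#'
#' Random, optionally stratified, split into \code{length(fractions)}
#' partitions. Partition sizes are the floored fraction targets with the
#' remainder assigned to the largest fraction (n = 100 at 70/5/25 gives
#' exactly 70/5/25). Stratified splits apply the same rule within each class,
#' keeping class proportions within one count per class. Reproducible by
#' seed.
#'
#' @param dataset a \code{molecule_dataset}.
#' @param fractions non-negative fractions summing to 1.
#' @param stratified stratify by activity_class.
#' @param seed integer RNG seed.
#' @return list of \code{molecule_dataset} partitions (empty partitions stay
#'   in place as zero-row data frames are not allowed, a partition of size 0
#'   is returned as NULL).
#' @export
split_dataset <- function(dataset, fractions = c(0.70, 0.15, 0.15),
                          stratified = FALSE, seed = 1) {
  stopifnot(inherits(dataset, "molecule_dataset"))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  if (any(fractions < 0)) stop("fractions must be non-negative", call. = FALSE)
  n <- nrow(dataset)
  assign_part <- function(idx) {
    sizes <- partition_sizes(length(idx), fractions)
    perm <- sample_vec(idx)
    split(perm, rep.int(seq_along(sizes), sizes))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (stratified) {
    if (anyNA(dataset$activity_class))
      stop("stratified split requires activity_class", call. = FALSE)
    parts_by_class <- lapply(split(seq_len(n), dataset$activity_class),
                             assign_part)
    members <- lapply(as.character(seq_along(fractions)), function(k) {
      sort(unlist(lapply(parts_by_class, function(p) p[[k]]), use.names = FALSE))
    })
  } else {
    p <- assign_part(seq_len(n))
    members <- lapply(as.character(seq_along(fractions)), function(k) {
      sort(p[[k]])
    })
  }
  lapply(seq_along(members), function(k) {
    idx <- members[[k]]
    if (length(idx) == 0) return(NULL)
    subset_dataset(dataset, idx,
                   id = paste0(dataset_id(dataset), "_part", k))
  })
}

subset_dataset <- function(dataset, idx, id = dataset_id(dataset)) {
  molecule_dataset(dataset$smiles[idx],
                   activity = dataset$activity[idx],
                   activity_class = if (anyNA(dataset$activity_class[idx]))
                     NULL else dataset$activity_class[idx],
                   source_value = dataset$source_value[idx],
                   source_unit = dataset$source_unit[idx],
                   dataset_id = id,
                   task_kind = if (anyNA(dataset$activity_class[idx]))
                     "regression" else task_kind(dataset),
                   threshold_molar = attr(dataset, "threshold_molar"),
                   keys = dataset$structure_key[idx])
}

#' Write a curated dataset to CSV
#'
#' Columns: smiles, structure_key, neg_log_m, class.
#'
#' @param dataset a \code{molecule_dataset}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "molecule_dataset"))
  utils::write.csv(
    data.frame(smiles = dataset$smiles,
               structure_key = dataset$structure_key,
               neg_log_m = dataset$activity,
               class = dataset$activity_class),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a dataset written by [write_dataset()]
#' @param path CSV path with columns smiles, structure_key, neg_log_m, class.
#' @param dataset_id identifier; defaults to file name.
#' @return a \code{molecule_dataset}.
#' @export
read_dataset <- function(path, dataset_id = NULL) {
  if (is.null(dataset_id))
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  cls <- if ("class" %in% names(tab) && !anyNA(tab$class))
    tab$class else NULL
  molecule_dataset(tab$smiles,
                   activity = if ("neg_log_m" %in% names(tab))
                     tab$neg_log_m else NULL,
                   activity_class = cls,
                   dataset_id = dataset_id,
                   task_kind = if (is.null(cls)) "regression" else
                     "classification",
                   keys = if ("structure_key" %in% names(tab))
                     tab$structure_key else NULL)
}

# sample from the elements of x (never from 1:x when x is scalar)
sample_vec <- function(x, k = length(x)) x[sample.int(length(x), k)]

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
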