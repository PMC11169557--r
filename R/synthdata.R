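# Synthetic single-target datasets with controlled size, scaffold diversity,
# planted activity rules, and label noise. The generator emulates curated
# ChEMBL-style sets: 10-5000 molecules, activities in -log[M], binarizable
# at 100 nM / 1 uM, scaffold diversity tunable across the range seen in real
# kinase sets, and families of related tasks for episodic training.
#
# Exact diversity control is the point: every molecule is a ring scaffold
# from a fixed library decorated with acyclic substituents only, so its
# Bemis-Murcko scaffold equals its source scaffold by construction and the
# measured CSFP diversity of a generated dataset equals the closed-form
# diversity of the requested scaffold counts.

# ring systems used to enumerate the scaffold library; each starts with a
# carbon atom so that prefixing an acyclic substituent string is a valid
# substitution ("C" + "c1ccccc1" -> toluene)
.ring_systems <- c(
  "c1ccccc1",            # benzene (library head)
  "c1ccncc1", "c1ccccn1", "c1cncnc1", "c1cnccn1", "c1ccnnc1",
  "c1ccsc1", "c1ccoc1", "c1cc[nH]c1", "c1ncc[nH]1", "c1nccs1", "c1ncco1",
  "C1CCCCC1", "C1CCCC1", "C1CCNCC1", "C1CNCCN1", "C1COCCN1", "C1CCOC1",
  "c1ccc2ccccc2c1", "c1ccc2ncccc2c1", "c1ccc2[nH]ccc2c1", "C1CCC2CCCCC2C1"
)

# two-ring scaffolds: ringB (closure digits shifted) + linker + ringA
.ring_linkers <- c("", "C", "CC", "O", "N", "C(=O)N")

# substituent grammar: functional head written as a prefix string + linear
# alkyl spacer; all acyclic, so scaffolds are preserved exactly
.substituent_groups <- c(
  methyl = "C", ethyl = "CC", fluoro = "F", chloro = "Cl", bromo = "Br",
  methoxy = "CO", hydroxy = "O", amino = "N", nitro = "O=[N+]([O-])",
  cyano = "N#C", trifluoromethyl = "FC(F)(F)", carboxamide = "NC(=O)"
)
# heads considered polar: default planted-activity pharmacophores
.polar_groups <- c("hydroxy", "amino", "nitro", "cyano", "carboxamide",
                   "methoxy")

.goldilocks_cache <- new.env(parent = emptyenv())

# shift ring-closure digits 1,2 -> 3,4 so two ring systems can be
# concatenated in one SMILES
shift_closures <- function(s) {
  chartr("12", "34", s)
}

scaffold_candidates <- function() {
  singles <- .ring_systems
  doubles <- as.vector(t(outer(
    seq_along(.ring_systems), seq_along(.ring_systems),
    Vectorize(function(i, j) paste0(shift_closures(.ring_systems[j]), "LNK",
                                    .ring_systems[i]))
  )))
  out <- singles
  for (lnk in .ring_linkers)
    out <- c(out, sub("LNK", lnk, doubles, fixed = TRUE))
  out
}

# derive a stream of sub-seeds below 2^31 from one integer seed
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483629)
}

#' Deterministic library of decoration-ready scaffolds
#'
#' Enumerates ring systems and linked ring pairs, canonicalizes them, and
#' keeps those that are fixed points of [murcko_scaffold()] and accept an
#' acyclic substituent by string prefixing. The library order is fixed
#' (benzene first); the first \code{S} entries are returned unless
#' \code{shuffle} is set, in which case entries after the first are permuted
#' by \code{seed}.
#'
#' @param S number of scaffolds requested (library capacity is > 500).
#' @param seed permutation seed, used only when \code{shuffle = TRUE}.
#' @param shuffle permute the library tail before taking \code{S}.
#' @return character vector of S distinct canonical scaffold SMILES.
#' @export
make_scaffold_library <- function(S, seed = 1, shuffle = FALSE) {
  stopifnot(S >= 1)
  if (S > length(scaffold_candidates()))
    stop("requested ", S, " scaffolds but library capacity is at most ",
         length(scaffold_candidates()), call. = FALSE)
  have <- .goldilocks_cache$scaffolds
  if (is.null(have)) have <- character(0)
  if (length(have) < max(S, 64)) {
    cands <- scaffold_candidates()
    pos <- .goldilocks_cache$scaffold_pos
    if (is.null(pos)) pos <- 0L
    while (length(have) < max(S, 64) && pos < length(cands)) {
      take <- cands[(pos + 1):min(pos + 256, length(cands))]
      pos <- pos + length(take)
      can <- canonical_smiles(take)
      can <- can[!is.na(can)]
      can <- setdiff(unique(can), have)
      if (length(can) > 0) {
        fixed <- murcko_scaffold(can) == can
        decoratable <- is_valid_smiles(paste0("C", can)) &
          vapply(can, function(s) {
            m <- tryCatch(murcko_scaffold(paste0("C", s)),
                          error = function(e) NA_character_)
            identical(m, s)
          }, logical(1))
        have <- c(have, can[fixed & decoratable])
      }
    }
    .goldilocks_cache$scaffolds <- have
    .goldilocks_cache$scaffold_pos <- pos
    if (length(have) < S)
      stop("requested ", S, " scaffolds but library capacity is ",
           length(have), call. = FALSE)
  }
  out <- have
  if (shuffle && S > 1) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    out <- c(out[1], sample(out[-1]))
  }
  out[seq_len(S)]
}

# substituent strings in a deterministic order; extended on demand with
# longer linear spacers so any per-scaffold count is reachable
substituent_strings <- function(k) {
  combos <- character(0)
  grp <- character(0)
  len <- 0
  while (length(combos) < k) {
    s <- paste0(.substituent_groups, strrep("C", len))
    new <- !(s %in% combos)
    combos <- c(combos, s[new])
    grp <- c(grp, names(.substituent_groups)[new])
    len <- len + 1
  }
  data.frame(sub = combos, group = grp, stringsAsFactors = FALSE)
}

#' Specification for a synthetic dataset
#'
#' @param n_molecules total molecules (>= 2).
#' @param scaffold_counts positive integers summing to \code{n_molecules};
#'   one entry per scaffold class. See [equal_counts()] / [zipf_counts()].
#' @param active_fraction target fraction of actives in (0, 1).
#' @param label_rule \code{"substructure"} (activity = presence of a planted
#'   polar substituent head; the default, so fingerprints carry the signal),
#'   \code{"scaffold"} (activity = membership of an active scaffold subset)
#'   or \code{"latent"} (activity = thresholded latent linear score over
#'   substituent and scaffold features).
#' @param noise_rate independent label-flip probability in [0, 0.5).
#' @param seed integer RNG seed.
#' @param task_kind \code{"classification"} or \code{"regression"}.
#' @param sigma regression noise sd in log units (activities are a base
#'   potency plus a rule effect plus Gaussian noise, clipped to [3, 10]
#'   -log[M]).
#' @param active_groups substituent head names counted as active under the
#'   substructure rule (default: the polar heads).
#' @return a \code{synth_spec} list.
#' @export
synth_spec <- function(n_molecules, scaffold_counts,
                       active_fraction = 0.5,
                       label_rule = c("substructure", "scaffold", "latent"),
                       noise_rate = 0, seed = 1,
                       task_kind = c("classification", "regression"),
                       sigma = 0.3, active_groups = .polar_groups) {
  label_rule <- match.arg(label_rule)
  task_kind <- match.arg(task_kind)
  stopifnot(n_molecules >= 2, all(scaffold_counts >= 1),
            sum(scaffold_counts) == n_molecules,
            active_fraction > 0, active_fraction < 1,
            noise_rate >= 0, noise_rate < 0.5)
  structure(list(n_molecules = n_molecules,
                 scaffold_counts = as.integer(scaffold_counts),
                 active_fraction = active_fraction,
                 label_rule = label_rule, noise_rate = noise_rate,
                 seed = as.integer(seed), task_kind = task_kind,
                 sigma = sigma, active_groups = active_groups),
            class = "synth_spec")
}

#' Equal and Zipf-distributed scaffold count vectors
#'
#' \code{equal_counts(n, S)} spreads n molecules as evenly as possible over S
#' scaffolds (exactly equal when S divides n, giving closed-form diversity
#' (S-1)/S); \code{zipf_counts(n, S, alpha)} makes count of scaffold k
#' proportional to k^-alpha, emulating the skewed scaffold frequencies of
#' real datasets.
#'
#' @param n total molecules.
#' @param S number of scaffolds.
#' @param alpha Zipf exponent (> 0).
#' @return integer vector of length S summing to n.
#' @export
equal_counts <- function(n, S) {
  stopifnot(S >= 1, n >= S)
  counts <- rep(n %/% S, S)
  extra <- n - sum(counts)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  as.integer(counts)
}

#' @rdname equal_counts
#' @export
zipf_counts <- function(n, S, alpha = 1) {
  stopifnot(S >= 1, n >= S, alpha > 0)
  w <- (seq_len(S))^(-alpha)
  counts <- pmax(1L, floor(n * w / sum(w)))
  # distribute the remainder to the largest-weight scaffolds
  i <- 1
  while (sum(counts) < n) {
    counts[i] <- counts[i] + 1L
    i <- i %% S + 1
  }
  while (sum(counts) > n) {
    j <- which(counts > 1)
    counts[j[length(j)]] <- counts[j[length(j)]] - 1L
  }
  as.integer(counts)
}

#' Closed-form diversity of a scaffold count vector
#'
#' The diversity the CSFP of a generated dataset will realize, computed
#' directly from the planned counts.
#'
#' @param counts positive integer scaffold counts.
#' @return the div score in [0, 1).
#' @export
planned_div <- function(counts) {
  names(counts) <- as.character(seq_along(counts))
  div_score(csfp_points(counts))$div
}

#' Generate a synthetic dataset
#'
#' For scaffold i, \code{scaffold_counts[i]} distinct molecules are built by
#' prefixing acyclic substituents from the fragment grammar; labels follow
#' the planted rule and are then flipped independently with probability
#' \code{noise_rate}. Activities are generated on the -log[M] scale
#' (actives near 100 nM-10 nM potency, inactives micromolar).
#'
#' @param spec a [synth_spec()].
#' @param dataset_id identifier for the result.
#' @param scaffolds optional explicit scaffold SMILES (defaults to the
#'   deterministic library head).
#' @return a \code{molecule_dataset}; the planted truth (pre-noise labels,
#'   substituent heads, scaffold index) is attached as attribute
#'   \code{"planted"}.
#' @export
#' @examples
#' \dontrun{ds <- synth_dataset(synth_spec(40, equal_counts(40, 4)))}
synth_dataset <- function(spec, dataset_id = "synthetic",
                          scaffolds = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  S <- length(spec$scaffold_counts)
  if (is.null(scaffolds)) scaffolds <- make_scaffold_library(S)
  stopifnot(length(scaffolds) == S)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_molecules
  max_count <- max(spec$scaffold_counts)
  # each scaffold draws from per-class pools without replacement, so size the
  # grammar so either class pool alone can cover the largest scaffold
  grammar <- substituent_strings(2 * max_count + 48)
  polar <- grammar$group %in% spec$active_groups
  n_active_target <- round(spec$active_fraction * n)
  if (n_active_target < 1 || n_active_target > n - 1)
    stop("active_fraction infeasible at this dataset size", call. = FALSE)

  # per-molecule plan: scaffold index + rule-dependent decoration
  scaf_idx <- rep(seq_len(S), spec$scaffold_counts)
  labels_true <- integer(n)
  sub_rows <- integer(n)

  if (spec$label_rule == "substructure") {
    # exact active composition: choose which molecules are active, then give
    # actives polar heads and inactives apolar heads, without replacement
    # within each scaffold so structures stay distinct
    act <- sample(n, n_active_target)
    labels_true[act] <- 1L
    for (s in seq_len(S)) {
      rows <- which(scaf_idx == s)
      pool_a <- sample(which(polar)); pool_i <- sample(which(!polar))
      for (r in rows) {
        if (labels_true[r] == 1L) {
          if (length(pool_a) == 0) pool_a <- sample(which(polar))
          sub_rows[r] <- pool_a[1]; pool_a <- pool_a[-1]
        } else {
          if (length(pool_i) == 0) pool_i <- sample(which(!polar))
          sub_rows[r] <- pool_i[1]; pool_i <- pool_i[-1]
        }
      }
    }
  } else {
    for (s in seq_len(S)) {
      rows <- which(scaf_idx == s)
      pool <- sample(nrow(grammar))
      sub_rows[rows] <- pool[seq_along(rows)]
    }
    if (spec$label_rule == "scaffold") {
      ord <- order(-spec$scaffold_counts)
      cum <- cumsum(spec$scaffold_counts[ord])
      k <- which(cum >= n_active_target)[1]
      active_scafs <- ord[seq_len(k)]
      got <- cum[k]
      if (got == n || k == S)
        stop("active_fraction infeasible under the scaffold rule for ",
             "these scaffold counts", call. = FALSE)
      labels_true <- as.integer(scaf_idx %in% active_scafs)
    } else { # latent linear score
      g <- match(grammar$group[sub_rows], names(.substituent_groups))
      w_g <- stats::rnorm(length(.substituent_groups))
      w_s <- stats::rnorm(8)
      score <- w_g[g] + 0.3 * nchar(grammar$sub[sub_rows]) +
        w_s[(scaf_idx %% 8) + 1]
      cut <- stats::quantile(score, 1 - spec$active_fraction, type = 1)
      labels_true <- as.integer(score > cut)
      if (sum(labels_true) == 0)
        labels_true[which.max(score)] <- 1L
    }
  }

  smiles <- paste0(grammar$sub[sub_rows], scaffolds[scaf_idx])
  ok <- is_valid_smiles(smiles)
  if (!all(ok))
    stop("internal: generated invalid SMILES for scaffold(s) ",
         paste(unique(scaf_idx[!ok]), collapse = ", "), call. = FALSE)

  flips <- stats::runif(n) < spec$noise_rate
  labels <- as.integer(xor(labels_true == 1L, flips))

  base <- ifelse(labels == 1L, 7.5, 5.5)
  activity <- pmin(10, pmax(3, base + stats::rnorm(n, 0, spec$sigma)))
  if (spec$task_kind == "regression")
    activity <- pmin(10, pmax(3, 5.0 + 2.5 * labels_true +
                                stats::rnorm(n, 0, spec$sigma)))

  ds <- molecule_dataset(
    smiles, activity = activity,
    activity_class = if (spec$task_kind == "classification") labels else NULL,
    dataset_id = dataset_id, task_kind = spec$task_kind,
    keys = canonical_smiles(smiles))
  attr(ds, "planted") <- data.frame(
    scaffold = scaffolds[scaf_idx], scaffold_index = scaf_idx,
    group = grammar$group[sub_rows], label_true = labels_true,
    flipped = flips)
  attr(ds, "spec") <- spec
  ds
}

#' Generate a family of related synthetic tasks
#'
#' Tasks share the fragment grammar and scaffold library (a shared embedding
#' space) but each gets its own planted substructure rule (a distinct subset
#' of substituent heads counts as active), so labels generalize across tasks
#' only through the structure-activity signal, not through any shared label.
#'
#' @param n_tasks number of tasks (>= 1).
#' @param template a [synth_spec()] used for every task (its seed is
#'   re-derived per task from \code{family_seed}).
#' @param family_seed integer seed for the collection.
#' @param min_per_class if set, each task is guaranteed at least this many
#'   actives and inactives after label noise (the generator redraws noise a
#'   bounded number of times; infeasible minima error out).
#' @return list of \code{molecule_dataset}s with distinct dataset ids.
#' @export
synth_tasks <- function(n_tasks, template, family_seed = 1,
                        min_per_class = NULL) {
  stopifnot(n_tasks >= 1, inherits(template, "synth_spec"))
  S <- length(template$scaffold_counts)
  scaffolds <- make_scaffold_library(S)
  heads <- names(.substituent_groups)
  lapply(seq_len(n_tasks), function(t) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(family_seed, t))
    # per-task planted rule: half of the substituent heads, drawn per task
    active_groups <- sample(heads, length(heads) %/% 2)
    for (try in 1:50) {
      sp <- template
      sp$seed <- derive_seed(family_seed, 1000 + t * 53 + try)
      sp$active_groups <- active_groups
      ds <- synth_dataset(synth_spec(
        sp$n_molecules, sp$scaffold_counts, sp$active_fraction,
        sp$label_rule, sp$noise_rate, sp$seed, sp$task_kind, sp$sigma,
        active_groups),
        dataset_id = sprintf("task%02d", t), scaffolds = scaffolds)
      if (is.null(min_per_class)) return(ds)
      n1 <- sum(ds$activity_class == 1); n0 <- sum(ds$activity_class == 0)
      if (n1 >= min_per_class && n0 >= min_per_class) return(ds)
    }
    stop("could not satisfy min_per_class = ", min_per_class,
         " for task ", t, " under this template", call. = FALSE)
  })
}
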