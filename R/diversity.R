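# Scaffold diversity: cumulative scaffold frequency plot (CSFP), its AUC,
# and the diversity score div = 2(1 - AUC).
#
# The CSFP sorts scaffolds from most to least frequent and plots the
# cumulative fraction of molecules covered against the cumulative fraction
# of scaffolds used. A single-scaffold set covers everything immediately
# (the curve encloses the whole unit square, div = 0); an all-unique set
# follows the diagonal (div -> 1 as n grows). The AUC uses the upper-step
# convention - the curve jumps to its level at the left edge of each
# scaffold's interval - which is the only rectangle rule reproducing both
# printed limits exactly.

#' CSFP curve points from scaffold counts
#'
#' Scaffolds are sorted by descending count (ties broken lexicographically by
#' scaffold SMILES purely for reproducible output; the AUC is invariant to
#' tie order). Point i is (i/S, cumulative molecule fraction of the top-i
#' scaffolds).
#'
#' @param counts named vector (or table) of positive scaffold counts; the
#'   empty scaffold "" is a valid name.
#' @return data.frame with columns \code{x} (scaffold fraction) and \code{y}
#'   (molecule fraction), S rows, ending at (1, 1).
#' @export
#' @examples
#' csfp_points(c(A = 2, B = 1, C = 1))
csfp_points <- function(counts) {
  counts <- unclass(counts)
  if (length(counts) == 0) stop("empty scaffold counts", call. = FALSE)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("scaffold counts must be positive integers", call. = FALSE)
  nm <- names(counts)
  if (is.null(nm)) nm <- as.character(seq_along(counts))
  ord <- order(-counts, nm)
  sorted <- counts[ord]
  S <- length(sorted)
  n <- sum(sorted)
  data.frame(x = seq_len(S) / S, y = unname(cumsum(sorted) / n),
             row.names = NULL)
}

#' CSFP AUC and diversity score
#'
#' AUC is the upper-step rectangle sum \eqn{\sum_i y_i (x_i - x_{i-1})} with
#' \eqn{x_0 = 0}; the diversity score is \eqn{div = 2(1 - AUC)}. One scaffold
#' gives div = 0 exactly; S equally frequent scaffolds give (S-1)/S; n
#' all-unique scaffolds give (n-1)/n, approaching 1.
#'
#' @param curve data.frame of CSFP points as from [csfp_points()].
#' @return list with elements \code{auc} and \code{div}.
#' @export
#' @examples
#' div_score(csfp_points(c(A = 2, B = 1, C = 1)))  # div = 0.5
div_score <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("x", "y") %in% names(curve)))
  x <- curve$x; y <- curve$y
  if (is.unsorted(x, strictly = TRUE) || is.unsorted(y))
    stop("CSFP curve must be monotone non-decreasing", call. = FALSE)
  if (abs(x[length(x)] - 1) > 1e-9 || abs(y[length(y)] - 1) > 1e-9)
    stop("CSFP curve must end at (1, 1)", call. = FALSE)
  auc <- sum(y * diff(c(0, x)))
  list(auc = auc, div = 2 * (1 - auc))
}

#' Scaffold profile of a dataset
#'
#' Extracts the Bemis-Murcko scaffold of every molecule, builds the CSFP
#' and computes the diversity score. Acyclic molecules all share the single
#' empty scaffold class.
#'
#' @param dataset a \code{molecule_dataset} or a character vector of SMILES.
#' @return an object of class \code{scaffold_profile}: list with
#'   \code{counts} (named scaffold counts), \code{n}, \code{S},
#'   \code{curve}, \code{auc}, \code{div}.
#' @export
#' @examples
#' \dontrun{scaffold_profile(c("Cc1ccccc1", "CCc1ccccc1", "c1ccncc1"))}
scaffold_profile <- function(dataset) {
  smiles <- if (inherits(dataset, "molecule_dataset")) dataset$smiles
    else dataset
  if (length(smiles) == 0) stop("empty dataset", call. = FALSE)
  scaf <- murcko_scaffold(smiles)
  counts <- table(scaf)
  counts <- stats::setNames(as.integer(counts), names(counts))
  curve <- csfp_points(counts)
  sc <- div_score(curve)
  structure(list(counts = counts, n = length(smiles), S = length(counts),
                 curve = curve, auc = sc$auc, div = sc$div),
            class = "scaffold_profile")
}

#' @export
print.scaffold_profile <- function(x, ...) {
  cat(sprintf("<scaffold_profile> n = %d, S = %d, AUC = %.4f, div = %.4f\n",
              x$n, x$S, x$auc, x$div))
  invisible(x)
}

#' Plot a CSFP curve
#'
#' Fraction of scaffolds (most frequent first) on the x axis vs fraction of
#' molecules covered on the y axis, drawn as the upper step curve used for
#' the AUC; the diagonal marks the all-unique limit.
#'
#' @param profile a \code{scaffold_profile}.
#' @param ... passed to \code{plot}.
#' @return the profile, invisibly.
#' @export
plot_csfp <- function(profile, ...) {
  stopifnot(inherits(profile, "scaffold_profile"))
  x <- c(0, profile$curve$x)
  y <- c(profile$curve$y[1], profile$curve$y)
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Fraction of scaffolds",
                 ylab = "Fraction of molecules",
                 main = sprintf("CSFP (div = %.3f)", profile$div), ...)
  graphics::lines(x, y, type = "s", lwd = 2, col = "steelblue")
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(profile)
}
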