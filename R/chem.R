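# Low-level chemistry: canonicalization, structure keys, fingerprints,
# Bemis-Murcko scaffolds. All structure perception is delegated to
# ChemmineR/ChemmineOB (OpenBabel); only the scaffold pruning logic is local.

# OpenBabel prints perception warnings to stderr; they are harmless noise for
# batch conversion, so wrap calls and keep R-level errors informative.
ob_convert <- function(from, to, text) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(from, to, text)),
    error = function(e) stop("structure toolkit conversion failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  out
}

# Split multi-record SMILES-like output ("smiles\ttitle" lines) into a vector.
ob_lines <- function(out) {
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- sub("\t.*$", "", lines)
  lines <- sub("[[:space:]]+$", "", lines)
  lines[nzchar(lines)]
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the toolkit's canonical form. Invalid SMILES yield
#' \code{NA} (the conversion engine stops at the first bad record, so a batch
#' failure triggers a per-record retry to locate the culprits).
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES, \code{NA} where unparseable.
#' @export
#' @examples
#' canonical_smiles(c("C1=CC=CC=C1", "c1ccccc1"))
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  batch <- ob_lines(ob_convert("SMI", "CAN",
                               paste0(paste(smiles[ok], collapse = "\n"), "\n")))
  if (length(batch) == sum(ok)) {
    out[ok] <- batch
  } else {
    # at least one record failed to parse; resolve one by one
    for (i in which(ok)) {
      res <- ob_lines(ob_convert("SMI", "CAN", paste0(smiles[i], "\n")))
      if (length(res) == 1) out[i] <- res
    }
  }
  out
}

#' Test whether SMILES strings are parseable
#'
#' @param smiles character vector of SMILES.
#' @return logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

#' Structure keys for deduplication
#'
#' Returns the standard InChIKey for each structure; where the toolkit cannot
#' produce one the canonical SMILES is used as the key instead, so every
#' parseable structure always gets a deterministic key.
#'
#' @param smiles character vector of parseable SMILES.
#' @return character vector of keys (\code{NA} for unparseable input).
#' @export
structure_key <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  can <- canonical_smiles(smiles)
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(can)
  if (!any(ok)) return(out)
  keys <- tryCatch(
    ob_lines(ob_convert("SMI", "INCHIKEY",
                        paste0(paste(can[ok], collapse = "\n"), "\n"))),
    error = function(e) character(0)
  )
  if (length(keys) == sum(ok)) out[ok] <- keys else out[ok] <- can[ok]
  out
}

smiles_to_sdfset <- function(smiles) {
  stopifnot(all(is_valid_smiles(smiles)))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  if (length(sdf) != length(smiles))
    stop("internal: SDF conversion dropped records", call. = FALSE)
  suppressWarnings(ChemmineR::cid(sdf) <- paste0("M", seq_along(smiles)))
  sdf
}

#' Molecular fingerprints as a bit matrix
#'
#' Circular (ECFP-style, via the toolkit's ECFP0-ECFP10 families, folded to
#' the requested length) or structural-key (MACCS, 166 keys) fingerprints.
#' Identical canonical structures give identical bit rows.
#'
#' @param smiles character vector of parseable SMILES.
#' @param kind \code{"circular"} or \code{"maccs"}.
#' @param radius circular radius (0-5); ignored for MACCS.
#' @param n_bits folded length for circular fingerprints (power of two,
#'   <= 4096); ignored for MACCS (always 166).
#' @return integer 0/1 matrix with one row per molecule.
#' @export
#' @examples
#' fp <- fingerprint_matrix(c("c1ccccc1", "CCO"), radius = 3, n_bits = 1024)
#' dim(fp)
fingerprint_matrix <- function(smiles, kind = c("circular", "maccs"),
                               radius = 3, n_bits = 1024) {
  kind <- match.arg(kind)
  if (length(smiles) == 0) stop("no molecules to fingerprint", call. = FALSE)
  bad <- !is_valid_smiles(smiles)
  if (any(bad))
    stop("unparseable SMILES at position(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  if (kind == "circular") {
    if (!radius %in% 0:5)
      stop("circular radius must be an integer in 0..5", call. = FALSE)
    if (!n_bits %in% 2^(4:12))
      stop("n_bits must be a power of two between 16 and 4096", call. = FALSE)
    m <- ob_fingerprints(smiles, sprintf("ECFP%d", 2 * radius))
    # the toolkit emits 4096-bit circular fingerprints; fold by OR-ing halves
    while (ncol(m) > n_bits) {
      half <- ncol(m) / 2
      m <- (m[, 1:half, drop = FALSE] | m[, half + 1:half, drop = FALSE]) * 1L
    }
  } else {
    m <- ob_fingerprints(smiles, "MACCS")[, 1:166, drop = FALSE]
  }
  rownames(m) <- NULL
  m
}

# fingerprints via the toolkit's command-line interface in a subprocess
# (the in-process fingerprint bindings do not release their C++ buffers,
# which matters for episodic workloads that fingerprint many tasks)
ob_fingerprints <- function(smiles, fptype) {
  smi <- tempfile(fileext = ".smi")
  on.exit(unlink(smi), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), smi)
  out <- suppressWarnings(
    system2("obabel", c(shQuote(smi), "-ofps", "-xf", fptype),
            stdout = TRUE, stderr = FALSE))
  lines <- out[!startsWith(out, "#") & nzchar(out)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  idx <- as.integer(vapply(parts, `[`, "", 2))
  hex <- vapply(parts, `[`, "", 1)
  if (length(idx) != length(smiles) || anyNA(idx))
    stop("fingerprint generation failed for ",
         length(smiles) - sum(!is.na(idx)), " molecule(s)", call. = FALSE)
  # hex nibble -> 4 bits lookup (a fixed bijection; bit order is internal)
  lut <- t(vapply(0:15, function(v)
    as.integer(intToBits(v)[4:1]), integer(4)))
  rownames(lut) <- c(0:9, letters[1:6])
  m <- matrix(0L, length(smiles), nchar(hex[1]) * 4L)
  for (k in seq_along(idx)) {
    nib <- strsplit(tolower(hex[k]), "")[[1]]
    m[idx[k], ] <- as.vector(t(lut[nib, , drop = FALSE]))
  }
  m
}

#' Tanimoto similarity between fingerprint bit vectors
#'
#' @param a,b 0/1 integer vectors of equal length.
#' @return similarity in [0, 1]; 0 when both vectors are empty.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(0)
  inter / uni
}

#' Maximal Tanimoto similarity of a query against a reference set
#'
#' Uses MACCS structural keys by default, the convention for reporting how
#' close a hit sits to a training set.
#'
#' @param query single SMILES.
#' @param reference character vector of reference SMILES (or a
#'   \code{molecule_dataset}).
#' @param kind fingerprint kind passed to [fingerprint_matrix()].
#' @param radius,n_bits circular-fingerprint parameters, if used.
#' @return maximum pairwise Tanimoto similarity in [0, 1].
#' @export
max_tanimoto <- function(query, reference, kind = "maccs",
                         radius = 3, n_bits = 1024) {
  if (inherits(reference, "molecule_dataset")) reference <- reference$smiles
  if (length(reference) == 0) stop("reference set is empty", call. = FALSE)
  stopifnot(length(query) == 1)
  fps <- fingerprint_matrix(c(query, reference), kind = kind,
                            radius = radius, n_bits = n_bits)
  q <- fps[1, ]
  max(vapply(seq_len(length(reference)),
             function(i) tanimoto(q, fps[i + 1, ]), numeric(1)))
}

# --- Bemis-Murcko scaffolds ------------------------------------------------

# Framework atoms = 2-core of the heavy-atom graph (iterated removal of
# degree-1 atoms leaves exactly the ring systems plus inter-ring linkers),
# plus any atom attached to that core by a bond of order >= 2 (retains
# exocyclic =O / =N etc., the convention of standard toolkits).
murcko_atom_set <- function(n_atoms, bonds) {
  if (n_atoms == 0 || nrow(bonds) == 0) return(integer(0))
  alive <- rep(TRUE, n_atoms)
  repeat {
    deg <- integer(n_atoms)
    keep_bond <- alive[bonds[, 1]] & alive[bonds[, 2]]
    if (any(keep_bond)) {
      tab <- tabulate(c(bonds[keep_bond, 1], bonds[keep_bond, 2]), n_atoms)
      deg <- tab
    }
    drop <- alive & deg <= 1
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  core <- which(alive)
  if (length(core) == 0) return(integer(0))
  # re-attach multiply-bonded appendages (single pass)
  extra <- integer(0)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds[k, 1]; b <- bonds[k, 2]; ord <- bonds[k, 3]
    if (ord >= 2) {
      if (a %in% core && !(b %in% core)) extra <- c(extra, b)
      if (b %in% core && !(a %in% core)) extra <- c(extra, a)
    }
  }
  sort(unique(c(core, extra)))
}

# Minimal V2000 molblock for a pruned subgraph; coordinates are carried over
# from the parsed structure (canonical SMILES output ignores them anyway).
subgraph_molblock <- function(atoms, bonds, keep) {
  idx <- match(seq_len(nrow(atoms)), keep)
  kb <- bonds[bonds[, 1] %in% keep & bonds[, 2] %in% keep, , drop = FALSE]
  elem <- sub("_.*$", "", rownames(atoms)[keep])
  lines <- c(
    "", " goldilocks scaffold", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            length(keep), nrow(kb)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            atoms[keep, 1], atoms[keep, 2], 0, elem),
    if (nrow(kb) > 0)
      sprintf("%3d%3d%3d  0  0  0  0",
              idx[kb[, 1]], idx[kb[, 2]], kb[, 3]),
    "M  END", "$$$$"
  )
  paste(lines, collapse = "\n")
}

#' Bemis-Murcko scaffold of each molecule
#'
#' The scaffold is the ring systems plus the linkers connecting them, with
#' acyclic substituents removed; atoms double- or triple-bonded to the
#' framework (e.g. exocyclic carbonyl oxygens) are retained. Acyclic
#' molecules yield the empty scaffold \code{""}. Output SMILES are canonical,
#' so the function is idempotent on its own output.
#'
#' @param smiles character vector of parseable SMILES.
#' @return character vector of canonical scaffold SMILES ("" if no ring).
#' @export
#' @examples
#' murcko_scaffold(c("CC", "Cc1ccccc1"))
murcko_scaffold <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  bad <- !is_valid_smiles(smiles)
  if (any(bad))
    stop("unparseable SMILES at position(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  sdf <- smiles_to_sdfset(smiles)
  out <- character(length(smiles))
  blocks <- character(0)
  block_of <- integer(0)
  for (i in seq_along(smiles)) {
    mol <- sdf[[i]]
    atoms <- ChemmineR::atomblock(mol)
    bonds <- ChemmineR::bondblock(mol)
    bonds <- matrix(as.numeric(bonds), ncol = ncol(bonds))
    keep <- murcko_atom_set(nrow(atoms), bonds)
    if (length(keep) == 0) {
      out[i] <- ""
    } else {
      blocks <- c(blocks, subgraph_molblock(atoms, bonds, keep))
      block_of <- c(block_of, i)
    }
  }
  if (length(blocks) > 0) {
    res <- ob_lines(ob_convert("SDF", "CAN",
                               paste0(paste(blocks, collapse = "\n"), "\n")))
    if (length(res) != length(blocks))
      stop("scaffold canonicalization dropped records", call. = FALSE)
    out[block_of] <- res
  }
  out
}
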