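#' Construct a fingerprint set
#'
#' A set of binary molecular fingerprints: one row per compound, one column
#' per bit.  Every fingerprint must have at least one set bit (an all-zero
#' fingerprint makes Tanimoto similarity 0/0-undefined and is rejected
#' rather than silently scored).
#'
#' @param bits logical or 0/1 numeric matrix, compounds in rows.
#' @param ids compound identifiers; default taken from row names.
#' @return a `fingerprint_set` object (logical matrix with compound row
#'   names).
#' @export
fingerprint_set <- function(bits, ids = rownames(bits)) {
  if (!is.matrix(bits)) stop("'bits' must be a matrix", call. = FALSE)
  if (is.numeric(bits)) {
    if (any(is.na(bits)) || !all(bits %in% c(0, 1))) {
      stop("fingerprint cells must all be 0 or 1", call. = FALSE)
    }
    bits <- bits > 0
  }
  if (!is.logical(bits) || any(is.na(bits))) {
    stop("'bits' must be a logical or 0/1 matrix", call. = FALSE)
  }
  if (is.null(ids)) ids <- sprintf("cpd%04d", seq_len(nrow(bits)))
  if (length(ids) != nrow(bits) || anyDuplicated(ids)) {
    stop("ids must be unique, one per fingerprint", call. = FALSE)
  }
  if (any(rowSums(bits) == 0L)) {
    stop("every fingerprint must have at least one set bit", call. = FALSE)
  }
  rownames(bits) <- ids
  class(bits) <- c("fingerprint_set", "matrix", "array")
  bits
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat("Fingerprint set:", nrow(x), "compounds x", ncol(x), "bits",
      sprintf("(mean set bits %.1f)\n", mean(rowSums(unclass(x)))))
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over the set bits of two binary
#' fingerprints of equal length.
#'
#' @param a,b logical or 0/1 vectors of the same length, each with at least
#'   one set bit.
#' @return similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 2/4
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) {
    stop("fingerprints must have the same length", call. = FALSE)
  }
  if (!any(a) || !any(b)) {
    stop("fingerprints must each have at least one set bit", call. = FALSE)
  }
  sum(a & b) / sum(a | b)
}

#' Structural diversity of a compound set
#'
#' The diversity metric `d = 1 - mean pairwise Tanimoto similarity` over all
#' unordered pairs of distinct compounds (self-pairs excluded).  Values near
#' 0 indicate a structurally homogeneous set; values near 1 indicate highly
#' diverse chemistry.  The pairwise mean is computed by bit-matrix cross
#' products, equivalent to (but much faster than) the double loop over
#' pairs.
#'
#' @param fps a `fingerprint_set` with n >= 2 compounds.
#' @param exclude_ids optional compound ids to drop before computing (e.g.
#'   to measure the diversity of a collection with one taxon removed).  At
#'   least 2 compounds must remain.
#' @return a `chem_diversity` list: `d`, `n`, `n_pairs`, `mean_similarity`.
#' @export
chem_diversity <- function(fps, exclude_ids = NULL) {
  stopifnot(inherits(fps, "fingerprint_set"))
  if (!is.null(exclude_ids)) {
    unknown <- setdiff(exclude_ids, rownames(fps))
    if (length(unknown)) {
      stop("unknown compound id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    keep <- !(rownames(fps) %in% exclude_ids)
    if (sum(keep) < 2L) {
      stop("fewer than 2 compounds remain after exclusion", call. = FALSE)
    }
    fps <- fingerprint_set(unclass(fps)[keep, , drop = FALSE])
  }
  n <- nrow(fps)
  if (n < 2L) stop("diversity needs at least 2 compounds", call. = FALSE)
  X <- matrix(as.integer(unclass(fps)), nrow = n)
  inter <- tcrossprod(X)
  sz <- rowSums(X)
  uni <- outer(sz, sz, "+") - inter
  sim <- inter / uni
  ut <- upper.tri(sim)
  mean_sim <- mean(sim[ut])
  structure(
    list(d = 1 - mean_sim, n = n, n_pairs = n * (n - 1) / 2,
         mean_similarity = mean_sim),
    class = "chem_diversity"
  )
}

#' @export
print.chem_diversity <- function(x, ...) {
  cat(sprintf("Chemical diversity d = %.3f (n = %d compounds, %d pairs, mean Tanimoto %.3f)\n",
              x$d, x$n, x$n_pairs, x$mean_similarity))
  invisible(x)
}

#' Read fingerprints from TSV
#'
#' Two-column tab-separated input `compound_id, fingerprint`, where the
#' fingerprint is either a 0/1 bitstring (`"01101..."`) or a hexadecimal
#' string (`"9a0f..."`, 4 bits per character, most significant bit first).
#' All fingerprints must decode to the same length.
#'
#' @param path input TSV with a header row.
#' @param format `"auto"` (default; hex if any character outside 0/1),
#'   `"bits"`, or `"hex"`.
#' @return a `fingerprint_set`.
#' @export
read_fingerprints <- function(path, format = c("auto", "bits", "hex")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("fingerprint file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L || nrow(df) == 0L) {
    stop("expected columns compound_id, fingerprint", call. = FALSE)
  }
  fp <- trimws(df[[2]])
  if (format == "auto") {
    format <- if (all(grepl("^[01]+$", fp))) "bits" else "hex"
  }
  rows <- lapply(fp, decode_fp, format = format)
  len <- unique(vapply(rows, length, integer(1)))
  if (length(len) != 1L) {
    stop("fingerprints decode to differing lengths: ",
         paste(len, collapse = ", "), call. = FALSE)
  }
  bits <- do.call(rbind, rows)
  fingerprint_set(bits, ids = df[[1]])
}

decode_fp <- function(s, format) {
  if (format == "bits") {
    if (!grepl("^[01]+$", s)) stop("invalid bitstring: ", s, call. = FALSE)
    return(strsplit(s, "")[[1]] == "1")
  }
  if (!grepl("^[0-9a-fA-F]+$", s)) stop("invalid hex string: ", s,
                                        call. = FALSE)
  nib <- strtoi(strsplit(tolower(s), "")[[1]], base = 16L)
  # vapply gives a 4 x n matrix (one column per nibble, msb first);
  # column-major flattening restores the original bit order
  as.logical(vapply(nib, function(v) bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L,
                    logical(4)))
}

#' Write a diversity result as JSON
#'
#' @param x a `chem_diversity` result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diversity <- function(x, path) {
  stopifnot(inherits(x, "chem_diversity"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fingerprints from SMILES strings (optional adapter)
#'
#' Converts SMILES to atom-pair-derived binary fingerprints via the
#' ChemmineR package (a Suggests dependency; the diversity metric itself is
#' fingerprint-agnostic and this adapter is deliberately swappable).  Very
#' small molecules can map to an all-zero fingerprint under the common
#' atom-pair dictionary; those are rejected by [fingerprint_set()] rather
#' than silently scored.
#'
#' @param smiles character vector of SMILES, optionally named with compound
#'   ids.
#' @param bits fingerprint length (default 1024).
#' @return a `fingerprint_set`.
#' @export
fingerprints_from_smiles <- function(smiles, bits = 1024) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("the SMILES adapter needs the ChemmineR package", call. = FALSE)
  }
  if (is.null(names(smiles))) {
    names(smiles) <- sprintf("cpd%04d", seq_along(smiles))
  }
  sdf <- ChemmineR::smiles2sdf(smiles)
  # resolve the atom-pair dictionary explicitly so the adapter also works
  # when ChemmineR is loaded but not attached
  env <- new.env(parent = emptyenv())
  utils::data("apfp", package = "ChemmineR", envir = env)
  descnames <- as.character(env$apfp$AP)[seq_len(bits)]
  m <- ChemmineR::desc2fp(ChemmineR::sdf2ap(sdf), descnames = descnames,
                          type = "matrix")
  fingerprint_set(m > 0, ids = names(smiles))
}
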