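#' Read a BiG-SCAPE-style BGC clustering table
#'
#' Parses a tab-separated clustering table assigning each biosynthetic gene
#' cluster (BGC) to a gene cluster family (GCF).  The default dialect matches
#' the `*_clustering_c*.tsv` files emitted by BiG-SCAPE: columns
#' `#BGC Name` and `Family Number`, with the `#`-prefixed header tolerated.
#'
#' Rows with a missing or empty BGC or family identifier are dropped with a
#' warning reporting how many were rejected.
#'
#' @param path path to the clustering TSV.
#' @param dialect named list mapping logical columns to file columns:
#'   `bgc_col` (default `"#BGC Name"`) and `family_col`
#'   (default `"Family Number"`).  Column matching falls back to the same
#'   names without a leading `#`.
#' @return a data.frame with columns `bgc_id` and `gcf_id`, one row per BGC.
#' @seealso [read_bgc_map()] to attach genome/species metadata,
#'   [build_incidence()] for the downstream incidence matrix.
#' @export
read_clustering_table <- function(path,
                                  dialect = list(bgc_col = "#BGC Name",
                                                 family_col = "Family Number")) {
  if (!file.exists(path)) {
    stop("clustering table not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "", check.names = FALSE,
                          colClasses = "character",
                          blank.lines.skip = TRUE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("no parseable rows in clustering table: ", path, call. = FALSE)
  }
  find_col <- function(wanted) {
    hit <- match(wanted, names(df))
    if (is.na(hit)) hit <- match(sub("^#", "", wanted), names(df))
    if (is.na(hit)) hit <- match(paste0("#", wanted), names(df))
    hit
  }
  bi <- find_col(dialect$bgc_col %||% "#BGC Name")
  fi <- find_col(dialect$family_col %||% "Family Number")
  if (is.na(bi) || is.na(fi)) {
    stop("clustering table is missing the configured columns (",
         dialect$bgc_col, ", ", dialect$family_col, "); found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(bgc_id = trimws(df[[bi]]), gcf_id = trimws(df[[fi]]),
                    stringsAsFactors = FALSE)
  bad <- is.na(out$bgc_id) | out$bgc_id == "" | is.na(out$gcf_id) |
    out$gcf_id == ""
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing BGC or family identifier dropped",
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0L) {
    stop("no valid rows in clustering table: ", path,
         " (first offending line: 2)", call. = FALSE)
  }
  if (anyDuplicated(out$bgc_id)) {
    stop("duplicate bgc_id values in clustering table", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a BGC-to-genome sidecar map
#'
#' Reads the tab-separated sidecar table that maps each BGC to its genome and
#' species, with optional BGC class and contig-edge annotations.  Expected
#' columns: `bgc_id`, `genome_id`, `species_id`, and optionally `class` (or
#' `bgc_class`) and `contig_edge` (logical, or 0/1).
#'
#' @param path path to the map TSV.
#' @return a data.frame with columns `bgc_id`, `genome_id`, `species_id`,
#'   `bgc_class` (NA when absent) and `contig_edge` (NA when absent).
#' @export
read_bgc_map <- function(path) {
  if (!file.exists(path)) stop("BGC map not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  need <- c("bgc_id", "genome_id", "species_id")
  if (!all(need %in% names(df))) {
    stop("BGC map must have columns bgc_id, genome_id, species_id",
         call. = FALSE)
  }
  cls <- if ("bgc_class" %in% names(df)) df$bgc_class
         else if ("class" %in% names(df)) df$class
         else NA_character_
  edge <- if ("contig_edge" %in% names(df)) {
    tolower(trimws(df$contig_edge)) %in% c("true", "t", "1", "yes")
  } else NA
  data.frame(bgc_id = df$bgc_id, genome_id = df$genome_id,
             species_id = df$species_id, bgc_class = cls, contig_edge = edge,
             stringsAsFactors = FALSE)
}

#' Assemble BGC records from a clustering table and a genome map
#'
#' Joins the GCF assignments to the genome/species metadata, yielding one
#' record per BGC — the substrate for [build_incidence()].
#'
#' @param clustering data.frame from [read_clustering_table()] (or any frame
#'   with `bgc_id`, `gcf_id`).
#' @param map data.frame from [read_bgc_map()].  BGCs absent from the map are
#'   an error: every BGC must be attributable to a sampling unit.
#' @return a `bgc_records` data.frame with columns `bgc_id`, `genome_id`,
#'   `species_id`, `gcf_id`, `bgc_class`, `contig_edge`.
#' @export
bgc_records <- function(clustering, map) {
  stopifnot(is.data.frame(clustering), is.data.frame(map))
  idx <- match(clustering$bgc_id, map$bgc_id)
  if (anyNA(idx)) {
    stop(sum(is.na(idx)), " BGC(s) in the clustering table have no entry ",
         "in the genome map", call. = FALSE)
  }
  out <- data.frame(
    bgc_id = clustering$bgc_id,
    genome_id = map$genome_id[idx],
    species_id = map$species_id[idx],
    gcf_id = clustering$gcf_id,
    bgc_class = map$bgc_class[idx],
    contig_edge = map$contig_edge[idx],
    stringsAsFactors = FALSE
  )
  validate_bgc_records(out)
}

validate_bgc_records <- function(records) {
  need <- c("bgc_id", "genome_id", "species_id", "gcf_id")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop("records must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) stop("records is empty", call. = FALSE)
  if (anyDuplicated(records$bgc_id)) {
    stop("bgc_id values must be unique", call. = FALSE)
  }
  if (any(records$gcf_id == "" | is.na(records$gcf_id))) {
    stop("gcf_id must be non-empty for every record", call. = FALSE)
  }
  if (any(records$species_id == "" | is.na(records$species_id))) {
    stop("species_id must be non-empty for every record", call. = FALSE)
  }
  if (!"bgc_class" %in% names(records)) records$bgc_class <- NA_character_
  if (!"contig_edge" %in% names(records)) records$contig_edge <- NA
  class(records) <- c("bgc_records", "data.frame")
  records
}

#' Filter BGC records
#'
#' The only built-in filter is optional removal of contig-edge BGCs (clusters
#' truncated at an assembly contig boundary, a standard quality flag in
#' antiSMASH output).  With `drop_contig_edge = FALSE` the input is returned
#' unchanged; records with an NA edge flag are always kept.
#'
#' @param records a `bgc_records` data.frame.
#' @param drop_contig_edge drop records whose `contig_edge` flag is TRUE?
#' @return the filtered `bgc_records` data.frame.
#' @export
filter_bgcs <- function(records, drop_contig_edge = FALSE) {
  records <- validate_bgc_records(records)
  if (!drop_contig_edge) return(records)
  keep <- !(records$contig_edge %in% TRUE)
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("all records removed by contig-edge filter",
                            call. = FALSE)
  rownames(out) <- NULL
  validate_bgc_records(out)
}

#' Build a species-by-GCF incidence matrix
#'
#' Collapses BGC records to presence/absence: cell (u, g) is 1 iff at least
#' one BGC of GCF g occurs in sampling unit u.  Multiple BGC copies of the
#' same family within a unit count once — richness estimation downstream is
#' incidence-based, not abundance-based.
#'
#' When `unit_level = "species"` and several genomes share a species, only the
#' lexicographically smallest `genome_id` is kept (deterministic
#' deduplication); the dropped genomes are reported in a message.
#'
#' @param records a `bgc_records` data.frame.
#' @param unit_level `"species"` (default) or `"genome"`: what constitutes a
#'   sampling unit.
#' @return an `incidence_matrix`: an integer 0/1 matrix with sampling units as
#'   rows (dimnames `units`) and GCFs as columns.
#' @export
build_incidence <- function(records, unit_level = c("species", "genome")) {
  unit_level <- match.arg(unit_level)
  records <- validate_bgc_records(records)
  if (unit_level == "species") {
    per_species <- split(records$genome_id, records$species_id)
    multi <- vapply(per_species, function(g) length(unique(g)) > 1L, logical(1))
    if (any(multi)) {
      keep_genome <- vapply(per_species, function(g) min(sort(unique(g))),
                            character(1))
      dropped <- unique(records$genome_id[
        records$genome_id != keep_genome[records$species_id]])
      message("multiple genomes per species; kept lexicographically ",
              "smallest, dropped: ", paste(dropped, collapse = ", "))
      records <- records[records$genome_id ==
                           keep_genome[records$species_id], , drop = FALSE]
    }
    unit <- records$species_id
  } else {
    unit <- records$genome_id
  }
  tab <- table(unit, records$gcf_id)
  mat <- matrix(as.integer(tab > 0), nrow = nrow(tab),
                dimnames = list(rownames(tab), colnames(tab)))
  incidence_matrix(mat)
}

#' Construct and validate an incidence matrix
#'
#' @param mat a numeric/logical matrix of 0/1 cells with unit row names and
#'   GCF column names.
#' @return the validated `incidence_matrix` object.
#' @export
incidence_matrix <- function(mat) {
  if (!is.matrix(mat)) stop("'mat' must be a matrix", call. = FALSE)
  storage.mode(mat) <- "integer"
  if (any(is.na(mat)) || !all(mat %in% c(0L, 1L))) {
    stop("incidence cells must all be 0 or 1", call. = FALSE)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("incidence matrix needs unit row names and GCF column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    stop("duplicate unit or GCF identifiers", call. = FALSE)
  }
  if (any(colSums(mat) == 0L)) {
    stop("every GCF column must contain at least one presence", call. = FALSE)
  }
  class(mat) <- c("incidence_matrix", "matrix", "array")
  mat
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("Incidence matrix:", nrow(x), "sampling units x", ncol(x), "GCFs\n")
  cat("  total presences:", sum(x),
      "| singleton GCFs:", sum(colSums(x) == 1L), "\n")
  invisible(x)
}

#' Write / read an incidence matrix as TSV
#'
#' Plain-text interchange format: first column `species_id`, remaining
#' columns one per GCF, cells 0/1.
#'
#' @param x an `incidence_matrix`.
#' @param path output (input) file path.
#' @return `write_incidence` returns `path` invisibly; `read_incidence`
#'   returns an `incidence_matrix`.
#' @export
write_incidence <- function(x, path) {
  stopifnot(inherits(x, "incidence_matrix"))
  df <- data.frame(species_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_incidence
#' @export
read_incidence <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  incidence_matrix(mat)
}

#' Summarize a BGC dataset
#'
#' Headline counts of a genome-mining survey: BGC and GCF totals, mean BGCs
#' per sampling unit, the singleton fraction (GCFs present in exactly one
#' unit — the raw material of undetected-richness estimation), and a tally of
#' BGC class labels.
#'
#' @param records the `bgc_records` the matrix was built from.
#' @param matrix the corresponding `incidence_matrix`.
#' @return a `dataset_summary` list with fields `n_bgcs`, `n_gcfs`, `n_units`,
#'   `mean_bgcs_per_unit`, `singleton_count`, `singleton_fraction`,
#'   `gcf_bgc_ratio`, `class_tally`.
#' @export
summarize_dataset <- function(records, matrix) {
  records <- validate_bgc_records(records)
  stopifnot(inherits(matrix, "incidence_matrix"))
  occ <- colSums(matrix)
  out <- list(
    n_bgcs = nrow(records),
    n_gcfs = length(unique(records$gcf_id)),
    n_units = nrow(matrix),
    mean_bgcs_per_unit = nrow(records) / nrow(matrix),
    singleton_count = sum(occ == 1L),
    singleton_fraction = sum(occ == 1L) / ncol(matrix),
    gcf_bgc_ratio = length(unique(records$gcf_id)) / nrow(records),
    class_tally = if (all(is.na(records$bgc_class))) integer(0) else
      table(records$bgc_class, useNA = "no")
  )
  class(out) <- "dataset_summary"
  out
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("BGC dataset summary\n")
  cat(sprintf("  BGCs: %d   GCFs: %d   sampling units: %d\n",
              x$n_bgcs, x$n_gcfs, x$n_units))
  cat(sprintf("  mean BGCs per unit: %.1f\n", x$mean_bgcs_per_unit))
  cat(sprintf("  singleton GCFs: %d (%.1f%%)   GCF:BGC ratio: %.3f\n",
              x$singleton_count, 100 * x$singleton_fraction, x$gcf_bgc_ratio))
  if (length(x$class_tally)) {
    cat("  classes:", paste(names(x$class_tally), x$class_tally,
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
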