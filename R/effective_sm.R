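#' Construct a BGC-SM link table
#'
#' A bipartite table of experimentally validated links between biosynthetic
#' gene clusters and the secondary metabolites they produce (the shape of a
#' flattened MIBiG export).  Duplicate (bgc_id, sm_id) pairs are collapsed
#' with a warning; every BGC and every SM must appear in at least one link.
#'
#' @param links data.frame with columns `bgc_id` and `sm_id` (additional
#'   columns such as `smiles` are carried along).
#' @return a `bgc_sm_table` data.frame.
#' @export
bgc_sm_table <- function(links) {
  if (!is.data.frame(links) || !all(c("bgc_id", "sm_id") %in% names(links))) {
    stop("links must be a data.frame with columns bgc_id, sm_id",
         call. = FALSE)
  }
  if (nrow(links) == 0L) stop("link table is empty", call. = FALSE)
  bad <- is.na(links$bgc_id) | links$bgc_id == "" |
    is.na(links$sm_id) | links$sm_id == ""
  if (any(bad)) {
    stop("bgc_id and sm_id must be non-empty in every link", call. = FALSE)
  }
  key <- paste(links$bgc_id, links$sm_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate BGC-SM pair(s) collapsed",
            call. = FALSE)
    links <- links[!duplicated(key), , drop = FALSE]
  }
  rownames(links) <- NULL
  class(links) <- c("bgc_sm_table", "data.frame")
  links
}

#' Read a BGC-SM link table from TSV or JSON
#'
#' TSV: tab-separated with header `bgc_id, sm_id[, smiles]`.  JSON: an array
#' of objects with the same fields.
#'
#' @param path input file; format chosen by extension (`.json` vs anything
#'   else = TSV).
#' @return a `bgc_sm_table`.
#' @export
read_bgc_sm_table <- function(path) {
  if (!file.exists(path)) stop("link table not found: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, sep = "\t", header = TRUE,
                      colClasses = "character", check.names = FALSE)
  }
  bgc_sm_table(df)
}

#' Per-SM multiplicity
#'
#' For each secondary metabolite, the number of distinct BGCs linked to it —
#' the sharing count `k_s` that drives the down-weighting in
#' [effective_sm()].
#'
#' @param table a `bgc_sm_table`.
#' @return named integer vector, one entry per distinct `sm_id`, each >= 1.
#' @export
sm_multiplicity <- function(table) {
  stopifnot(inherits(table, "bgc_sm_table"))
  tab <- base::table(table$sm_id)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Effective number of SMs per BGC
#'
#' A metabolite produced by several gene clusters should not be counted in
#' full for each of them.  Each SM shared by `k` BGCs contributes `1/k` to
#' every linked BGC, so a BGC's effective SM count is
#' \deqn{\mathrm{eff}(b) = \sum_{s \in SM(b)} 1 / k_s.}
#' This is one concrete reading of "down-weighting shared SMs" — the simplest
#' scheme with the clean accounting identity that the effective counts sum to
#' the number of distinct SMs, so the mean equals
#' `n_distinct_sms / n_bgcs` exactly.  Treat the scheme as an interpretation:
#' other down-weightings are conceivable, and this one is chosen for its
#' transparency.
#'
#' @param table a `bgc_sm_table`.
#' @return an `effective_sm` list: `per_bgc` (named numeric), `mean_effective`,
#'   `n_bgcs`, `n_distinct_sms`.
#' @export
effective_sm <- function(table) {
  stopifnot(inherits(table, "bgc_sm_table"))
  if (nrow(table) == 0L) stop("link table is empty", call. = FALSE)
  k <- sm_multiplicity(table)
  w <- 1 / k[table$sm_id]
  per_bgc <- tapply(w, table$bgc_id, sum)
  per_bgc <- stats::setNames(as.numeric(per_bgc), names(per_bgc))
  structure(
    list(per_bgc = per_bgc,
         mean_effective = mean(per_bgc),
         n_bgcs = length(per_bgc),
         n_distinct_sms = length(k)),
    class = "effective_sm"
  )
}

#' @export
print.effective_sm <- function(x, ...) {
  cat(sprintf(
    "Effective SMs per BGC: %.2f (mean over %d BGCs, %d distinct SMs)\n",
    x$mean_effective, x$n_bgcs, x$n_distinct_sms))
  invisible(x)
}
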