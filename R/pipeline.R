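#' Run configuration
#'
#' Flat named-list configuration shared by the `run_*` pipeline stages.  Only
#' the fields a stage uses need to be present; `out_dir` and (for stochastic
#' stages) `seed` are always required.  Configurations round-trip losslessly
#' through JSON via [read_run_config()] / [write_run_config()].
#'
#' @param ... named fields, e.g. `clustering`, `bgc_map`, `incidence`,
#'   `bgc_sm`, `fingerprints` (input paths); `unit_level`,
#'   `drop_contig_edge`; `t_max`, `n_target`, `n_boot`, `seed`;
#'   `bgcs_per_species`, `n_species`, `sms_per_bgc`; `out_dir`.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (is.null(cfg$out_dir)) stop("'out_dir' is required", call. = FALSE)
  if (length(cfg) && (is.null(names(cfg)) || any(names(cfg) == ""))) {
    stop("all config fields must be named", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

load_records <- function(cfg) {
  if (is.null(cfg$clustering) || is.null(cfg$bgc_map)) {
    stop("config needs 'clustering' and 'bgc_map' input paths",
         call. = FALSE)
  }
  clust <- read_clustering_table(cfg$clustering)
  map <- read_bgc_map(cfg$bgc_map)
  recs <- bgc_records(clust, map)
  filter_bgcs(recs, drop_contig_edge = isTRUE(cfg$drop_contig_edge))
}

stage_log <- function(cfg, stage) {
  ver <- as.character(utils::packageVersion("smprospect"))
  hash <- sum(utf8ToInt(paste(
    names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                       character(1)),
    collapse = ";")))
  message(sprintf("[smprospect %s] stage=%s config_hash=%d seed=%s",
                  ver, stage, hash,
                  if (is.null(cfg$seed)) "none" else cfg$seed))
}

#' Pipeline stage: dataset summary
#'
#' Reads the clustering table and BGC map named in the config, builds the
#' incidence matrix, and writes `summary.json` and `incidence.tsv` to
#' `out_dir`.
#'
#' @param cfg a `run_config` with `clustering`, `bgc_map`, `out_dir` and
#'   optionally `unit_level`, `drop_contig_edge`.
#' @return the `dataset_summary`, invisibly.
#' @export
run_summarize <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage_log(cfg, "summarize")
  recs <- load_records(cfg)
  mat <- build_incidence(recs, unit_level = cfg$unit_level %||% "species")
  sm <- summarize_dataset(recs, mat)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- unclass(sm)
  out$class_tally <- as.list(out$class_tally)
  jsonlite::write_json(out, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_incidence(mat, file.path(cfg$out_dir, "incidence.tsv"))
  invisible(sm)
}

#' Pipeline stage: rarefaction/extrapolation curve
#'
#' Fits [gcf_rarefaction()] to the incidence matrix named in the config (or
#' built from the clustering inputs) and writes `curve.tsv` and
#' `richness.json` to `out_dir`.
#'
#' @param cfg a `run_config` with `incidence` (or `clustering` + `bgc_map`),
#'   `seed`, `out_dir`, and optionally `t_max`, `n_boot`, `n_target`.
#' @return the `gcf_rarefaction` fit, invisibly.
#' @export
run_rarefaction <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$seed)) stop("'seed' is required for the bootstrap",
                              call. = FALSE)
  stage_log(cfg, "rarefy")
  mat <- if (!is.null(cfg$incidence)) {
    read_incidence(cfg$incidence)
  } else {
    build_incidence(load_records(cfg),
                    unit_level = cfg$unit_level %||% "species")
  }
  fit <- gcf_rarefaction(mat, t_max = cfg$t_max,
                         n_boot = cfg$n_boot %||% 200, seed = cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_curve(fit, file.path(cfg$out_dir, "curve.tsv"))
  rep <- fit$estimate
  if (!is.null(cfg$n_target)) {
    rep <- richness_at(mat, cfg$n_target, n_boot = cfg$n_boot %||% 200,
                       seed = cfg$seed)
  }
  jsonlite::write_json(unclass(rep),
                       file.path(cfg$out_dir, "richness.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}

#' Pipeline stage: effective SMs per BGC
#'
#' @param cfg a `run_config` with `bgc_sm` (link-table path) and `out_dir`.
#' @return the `effective_sm` result, invisibly.
#' @export
run_effective_sm <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage_log(cfg, "effective-sm")
  if (is.null(cfg$bgc_sm)) stop("config needs 'bgc_sm'", call. = FALSE)
  res <- effective_sm(read_bgc_sm_table(cfg$bgc_sm))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- unclass(res)
  out$per_bgc <- as.list(out$per_bgc)
  jsonlite::write_json(out, file.path(cfg$out_dir, "effective_sm.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Pipeline stage: projection grid
#'
#' @param cfg a `run_config` with `out_dir` and optionally
#'   `bgcs_per_species` (vector), `n_species`, `sms_per_bgc`, and `ratio`
#'   (string `"n_gcfs/n_bgcs"`, or omit for the two built-in ratios).
#' @return the `projection_grid`, invisibly.
#' @export
run_project <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage_log(cfg, "project")
  ratios <- if (is.null(cfg$ratio)) default_ratios() else {
    parts <- as.numeric(strsplit(cfg$ratio, "/")[[1]])
    if (length(parts) != 2L || anyNA(parts)) {
      stop("'ratio' must look like \"4463/6972\"", call. = FALSE)
    }
    list(discovery_ratio(parts[1], parts[2], cfg$ratio))
  }
  grid <- scenario_grid(B_set = cfg$bgcs_per_species %||% c(30, 40, 50),
                        n_species = cfg$n_species %||% 85000,
                        ratios = ratios,
                        sms_per_bgc = cfg$sms_per_bgc %||% 1.57)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(grid, file.path(cfg$out_dir, "projection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(grid, file.path(cfg$out_dir, "projection.json"),
                       digits = NA, dataframe = "rows")
  invisible(grid)
}

#' Pipeline stage: structural diversity
#'
#' @param cfg a `run_config` with `fingerprints` (TSV path), `out_dir`, and
#'   optionally `exclude_ids`.
#' @return the `chem_diversity` result, invisibly.
#' @export
run_diversity <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage_log(cfg, "diversity")
  if (is.null(cfg$fingerprints)) stop("config needs 'fingerprints'",
                                      call. = FALSE)
  fps <- read_fingerprints(cfg$fingerprints)
  res <- chem_diversity(fps, exclude_ids = cfg$exclude_ids)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_diversity(res, file.path(cfg$out_dir, "diversity.json"))
  invisible(res)
}

#' Pipeline stage: simulate a full synthetic dataset
#'
#' Generates incidence, BGC-SM, and fingerprint inputs with the default
#' calibration and writes them (plus ground truth) to `out_dir`.
#'
#' @param cfg a `run_config` with `seed`, `out_dir`, and optionally
#'   `n_units`, `s_true`.
#' @return the ground-truth list, invisibly.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$seed)) stop("'seed' is required", call. = FALSE)
  stage_log(cfg, "simulate")
  sim <- gen_incidence(incidence_model(n_units = cfg$n_units %||% 135,
                                       s_true = cfg$s_true %||% 4463,
                                       seed = cfg$seed))
  sm_sim <- gen_bgc_sm_table(seed = cfg$seed + 1L)
  fp_sim <- gen_fingerprints(n_families = 8, per_family = 12,
                             seed = cfg$seed + 2L)
  write_synthetic(cfg$out_dir, sim, sm_sim, fp_sim)
  invisible(list(incidence = sim$ground_truth,
                 bgc_sm = sm_sim$ground_truth,
                 fingerprints = fp_sim$ground_truth))
}
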