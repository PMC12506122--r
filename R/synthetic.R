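#' Synthetic incidence model
#'
#' Parameters of the generator that emulates the statistical structure of a
#' genome-mining survey: a pool of `s_true` gene cluster families whose
#' occupancy counts (number of species carrying each family) follow a
#' truncated Zipf distribution on `{1..n_units}`, with within-genome BGC
#' duplication adding Poisson-distributed extra copies per presence.
#'
#' The defaults are calibrated to the observed structure of a 135-genome
#' *Aspergillus* survey: `occupancy_alpha` is chosen so that the expected
#' singleton fraction is 3,607/4,463 (about 80.8% of families in exactly one
#' species), and `duplication_rate` so that the expected GCF:BGC count ratio
#' is 4,463/6,972 (about 0.640), which together imply about 51.6 BGCs per
#' species at the default pool size.
#'
#' @param n_units number of sampling units (species), T.
#' @param s_true number of gene cluster families in the pool.
#' @param occupancy_alpha Zipf decay exponent for occupancy counts; default
#'   calibrated via [calibrate_occupancy()].
#' @param duplication_rate Poisson mean of extra same-family BGC copies per
#'   presence; default calibrated via [calibrate_duplication()].
#' @param seed integer seed (required: the generator is stochastic).
#' @return an `incidence_model` list.
#' @export
incidence_model <- function(n_units = 135,
                            s_true = 4463,
                            occupancy_alpha = NULL,
                            duplication_rate = NULL,
                            seed) {
  n_units <- stopifnot_count(n_units, "n_units", min = 2)
  s_true <- stopifnot_count(s_true, "s_true", min = 1)
  if (is.null(occupancy_alpha)) {
    occupancy_alpha <- calibrate_occupancy(n_units, 3607 / 4463)
  }
  if (is.null(duplication_rate)) {
    duplication_rate <- calibrate_duplication(n_units, occupancy_alpha,
                                              4463 / 6972)
  }
  if (occupancy_alpha <= 0) stop("occupancy_alpha must be > 0", call. = FALSE)
  if (duplication_rate < 0) stop("duplication_rate must be >= 0",
                                 call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  structure(
    list(n_units = n_units, s_true = s_true,
         occupancy_alpha = occupancy_alpha,
         duplication_rate = duplication_rate,
         seed = as.integer(seed)),
    class = "incidence_model"
  )
}

# Truncated-Zipf pmf on {1..T}: P(Y = k) proportional to k^(-alpha).
zipf_pmf <- function(alpha, T) {
  w <- (1:T)^(-alpha)
  w / sum(w)
}

#' Calibrate the occupancy exponent to a singleton fraction
#'
#' Finds the Zipf exponent `alpha` such that the probability of a family
#' occupying exactly one unit, `P(Y = 1) = 1 / sum(k^-alpha)`, matches the
#' target singleton fraction.  `P(Y = 1)` is monotone increasing in `alpha`,
#' so a simple bisection converges; targets outside the attainable range
#' `(1/T, 1)` raise an error naming the feasible interval.
#'
#' @param T number of sampling units.
#' @param target_singleton_fraction target `P(Y = 1)`, in (0, 1).
#' @param tol convergence tolerance on the fraction (default 1e-3).
#' @return the calibrated exponent alpha.
#' @export
calibrate_occupancy <- function(T, target_singleton_fraction, tol = 1e-3) {
  T <- stopifnot_count(T, "T", min = 2)
  target <- stopifnot_prob(target_singleton_fraction,
                           "target_singleton_fraction")
  p1 <- function(a) zipf_pmf(a, T)[1]
  lo <- 1e-6; hi <- 60
  if (target <= p1(lo) || target >= p1(hi)) {
    stop(sprintf(
      "target singleton fraction %.4f unattainable for T = %d; feasible range (%.4f, %.4f)",
      target, T, p1(lo), p1(hi)), call. = FALSE)
  }
  root <- stats::uniroot(function(a) p1(a) - target, c(lo, hi),
                         tol = 1e-10)$root
  if (abs(p1(root) - target) > tol) {
    stop("occupancy calibration did not converge", call. = FALSE)
  }
  root
}

#' Calibrate the duplication rate to a GCF:BGC count ratio
#'
#' With occupancy exponent `alpha`, a family occupies on average
#' `E[Y]` units and contributes `E[Y] * (1 + lambda)` BGC records, so the
#' expected GCF:BGC ratio is `1 / (E[Y] * (1 + lambda))`.  Solving for the
#' Poisson duplication mean gives
#' `lambda = 1 / (ratio * E[Y]) - 1`.  A target ratio above `1 / E[Y]`
#' (which would need fewer than one record per presence) is an error.
#'
#' @param T number of sampling units.
#' @param alpha occupancy exponent.
#' @param target_ratio target ratio of family count to BGC count, in (0, 1].
#' @return the calibrated Poisson mean lambda (>= 0).
#' @export
calibrate_duplication <- function(T, alpha, target_ratio) {
  stopifnot_prob(target_ratio, "target_ratio")
  if (target_ratio == 0) stop("target_ratio must be > 0", call. = FALSE)
  pmf <- zipf_pmf(alpha, T)
  ey <- sum((1:T) * pmf)
  lambda <- 1 / (target_ratio * ey) - 1
  if (lambda < 0) {
    stop(sprintf(
      "target ratio %.3f exceeds the maximum %.3f attainable at alpha = %.3f (duplication cannot be negative)",
      target_ratio, 1 / ey, alpha), call. = FALSE)
  }
  lambda
}

#' Generate synthetic BGC records and their incidence matrix
#'
#' For each of the `s_true` families, an occupancy count is drawn from the
#' truncated Zipf distribution, the occupied species are chosen uniformly
#' without replacement, and each presence is expanded into `1 + Poisson(
#' duplication_rate)` BGC records (same family, same species).  All
#' randomness flows from the model seed, so identical models produce
#' identical output.  Ground-truth bookkeeping records everything a test
#' needs to verify downstream code exactly.
#'
#' Every family in the pool occupies at least one unit, so with the full
#' matrix `S_obs = s_true`; subsampling units (e.g. taking the first rows,
#' or [rarefy_incidence()]) is the way to study partial detection.
#'
#' @param model an `incidence_model`.
#' @return a list with `records` (a `bgc_records` data.frame), `matrix` (the
#'   `incidence_matrix`), and `ground_truth` (list: `s_true`, `S_obs`, `Q1`,
#'   `Q2`, `Y`, `n_bgcs`, `singleton_fraction`, `gcf_bgc_ratio`,
#'   `mean_bgcs_per_unit`).
#' @export
gen_incidence <- function(model) {
  stopifnot(inherits(model, "incidence_model"))
  T <- model$n_units; S <- model$s_true
  with_seed(model$seed, {
    pmf <- zipf_pmf(model$occupancy_alpha, T)
    Y <- sample.int(T, S, replace = TRUE, prob = pmf)
    units <- lapply(Y, function(y) sort(sample.int(T, y)))
    gcf <- rep(seq_len(S), Y)
    unit <- unlist(units)
    copies <- 1L + stats::rpois(length(unit), model$duplication_rate)
    gcf_all <- rep(gcf, copies)
    unit_all <- rep(unit, copies)
    n_bgcs <- length(gcf_all)
    records <- data.frame(
      bgc_id = sprintf("BGC%06d", seq_len(n_bgcs)),
      genome_id = sprintf("G%03d", unit_all),
      species_id = sprintf("S%03d", unit_all),
      gcf_id = sprintf("GCF%05d", gcf_all),
      bgc_class = NA_character_,
      contig_edge = NA,
      stringsAsFactors = FALSE
    )
    records <- validate_bgc_records(records)
    # all T units must appear as rows even if some drew no BGC (possible
    # only for tiny pools); build the matrix directly from presences
    mat <- matrix(0L, nrow = T, ncol = S,
                  dimnames = list(sprintf("S%03d", seq_len(T)),
                                  sprintf("GCF%05d", seq_len(S))))
    mat[cbind(unit, gcf)] <- 1L
    mat <- mat[rowSums(mat) >= 0L, colSums(mat) > 0L, drop = FALSE]
    matrix <- incidence_matrix(mat)
    gt <- list(
      s_true = S, S_obs = ncol(matrix),
      Q1 = sum(Y == 1L), Q2 = sum(Y == 2L), Y = Y,
      n_bgcs = n_bgcs,
      singleton_fraction = mean(Y == 1L),
      gcf_bgc_ratio = S / n_bgcs,
      mean_bgcs_per_unit = n_bgcs / T
    )
    list(records = records, matrix = matrix, ground_truth = gt)
  })
}

#' Generate a synthetic BGC-SM link table
#'
#' Each BGC is linked to at least one secondary metabolite; the number of
#' links per BGC is `1 + Poisson(mean_sms_per_bgc - 1)`.  Each link reuses an
#' already-assigned SM with probability `sharing_prob` (drawn uniformly from
#' the current pool, avoiding duplicate pairs) and otherwise mints a novel
#' SM.  Ground truth records the realized per-SM multiplicities, so the
#' down-weighting identity of [effective_sm()] can be checked exactly.
#'
#' @param n_bgcs number of BGCs (default 158, the size of a typical curated
#'   *Aspergillus* link set).
#' @param mean_sms_per_bgc expected SM links per BGC (>= 1; default 1.8).
#' @param sharing_prob probability a link reuses an existing SM (default
#'   0.15).
#' @param seed integer seed.
#' @return a list with `table` (a `bgc_sm_table`) and `ground_truth` (list:
#'   `n_bgcs`, `n_links`, `n_distinct_sms`, `multiplicity` named vector).
#' @export
gen_bgc_sm_table <- function(n_bgcs = 158, mean_sms_per_bgc = 1.8,
                             sharing_prob = 0.15, seed) {
  n_bgcs <- stopifnot_count(n_bgcs, "n_bgcs", min = 1)
  stopifnot_prob(sharing_prob, "sharing_prob")
  if (mean_sms_per_bgc < 1) stop("mean_sms_per_bgc must be >= 1",
                                 call. = FALSE)
  with_seed(seed, {
    n_links_per_bgc <- 1L + stats::rpois(n_bgcs, mean_sms_per_bgc - 1)
    bgc <- character(0); sm <- character(0)
    pool <- character(0); next_sm <- 1L
    for (b in seq_len(n_bgcs)) {
      bid <- sprintf("BGC%04d", b)
      mine <- character(0)
      for (l in seq_len(n_links_per_bgc[b])) {
        reuse <- length(pool) > 0L && stats::runif(1) < sharing_prob
        cand <- setdiff(pool, mine)
        if (reuse && length(cand) > 0L) {
          sid <- cand[sample.int(length(cand), 1L)]
        } else {
          sid <- sprintf("SM%05d", next_sm)
          next_sm <- next_sm + 1L
          pool <- c(pool, sid)
        }
        mine <- c(mine, sid)
      }
      bgc <- c(bgc, rep(bid, length(mine)))
      sm <- c(sm, mine)
    }
    tab <- bgc_sm_table(data.frame(bgc_id = bgc, sm_id = sm,
                                   stringsAsFactors = FALSE))
    mult <- sm_multiplicity(tab)
    list(table = tab,
         ground_truth = list(n_bgcs = n_bgcs, n_links = nrow(tab),
                             n_distinct_sms = length(mult),
                             multiplicity = mult))
  })
}

#' Generate a structured synthetic fingerprint set
#'
#' Emulates chemical families: the bit space is partitioned into disjoint
#' family cores plus a shared noise region.  Each compound carries its whole
#' family core and a number of private noise bits controlled by
#' `within_family_overlap`: at overlap 1 members equal their core exactly
#' (within-family Tanimoto 1), and lower overlap adds
#' `round(core_bits * (1 - overlap) / max(overlap, 0.05))` private bits,
#' diluting within-family similarity while leaving between-family similarity
#' near zero.
#'
#' @param n_families number of chemical families.
#' @param per_family compounds per family.
#' @param bits_per_fp fingerprint length; must fit the disjoint cores plus a
#'   noise region.
#' @param within_family_overlap in (0, 1]: fraction of a member's bits that
#'   come from its family core.
#' @param core_bits bits per family core (default 24).
#' @param seed integer seed.
#' @return a list with `fps` (a `fingerprint_set`) and `ground_truth` (list:
#'   `family` membership vector, `core_bits`, `private_bits`).
#' @export
gen_fingerprints <- function(n_families, per_family, bits_per_fp = 512,
                             within_family_overlap = 0.8, core_bits = 24,
                             seed) {
  n_families <- stopifnot_count(n_families, "n_families", min = 1)
  per_family <- stopifnot_count(per_family, "per_family", min = 1)
  ov <- stopifnot_prob(within_family_overlap, "within_family_overlap")
  if (ov == 0) stop("within_family_overlap must be > 0", call. = FALSE)
  n_private <- round((1 - ov) / max(ov, 0.05) * core_bits)
  need <- n_families * core_bits
  noise_lo <- need + 1L
  if (bits_per_fp < need + max(n_private, 1L)) {
    stop("bits_per_fp too small for ", n_families, " disjoint cores of ",
         core_bits, " bits plus a noise region", call. = FALSE)
  }
  with_seed(seed, {
    n <- n_families * per_family
    bits <- matrix(FALSE, nrow = n, ncol = bits_per_fp)
    fam <- rep(seq_len(n_families), each = per_family)
    for (i in seq_len(n)) {
      core <- ((fam[i] - 1L) * core_bits + 1L):(fam[i] * core_bits)
      bits[i, core] <- TRUE
      if (n_private > 0L) {
        noise <- sample(noise_lo:bits_per_fp, n_private)
        bits[i, noise] <- TRUE
      }
    }
    fps <- fingerprint_set(bits, ids = sprintf("F%02d_C%03d", fam,
                                               stats::ave(fam, fam,
                                                          FUN = seq_along)))
    list(fps = fps,
         ground_truth = list(family = fam, core_bits = core_bits,
                             private_bits = n_private))
  })
}

#' Write synthetic inputs to a directory
#'
#' Emits the plain-text dialects the readers consume — a BiG-SCAPE-style
#' clustering TSV, the BGC map sidecar, the incidence TSV, a BGC-SM link
#' TSV, a fingerprint TSV — plus `ground_truth.json`, enabling full
#' write-then-read round-trip checks.
#'
#' @param dir output directory (created if missing).
#' @param sim result of [gen_incidence()].
#' @param sm_sim optional result of [gen_bgc_sm_table()].
#' @param fp_sim optional result of [gen_fingerprints()].
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(dir, sim, sm_sim = NULL, fp_sim = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- sim$records
  clust <- data.frame(`#BGC Name` = rec$bgc_id,
                      `Family Number` = rec$gcf_id,
                      check.names = FALSE)
  utils::write.table(clust, file.path(dir, "clustering.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  map <- rec[, c("bgc_id", "genome_id", "species_id")]
  utils::write.table(map, file.path(dir, "bgc_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_incidence(sim$matrix, file.path(dir, "incidence.tsv"))
  gt <- list(incidence = sim$ground_truth)
  if (!is.null(sm_sim)) {
    utils::write.table(sm_sim$table[, c("bgc_id", "sm_id")],
                       file.path(dir, "bgc_sm.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gt$bgc_sm <- sm_sim$ground_truth
  }
  if (!is.null(fp_sim)) {
    fpm <- unclass(fp_sim$fps)
    df <- data.frame(compound_id = rownames(fpm),
                     fingerprint = apply(fpm, 1L, function(r)
                       paste(as.integer(r), collapse = "")),
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, "fingerprints.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gt$fingerprints <- fp_sim$ground_truth[c("core_bits", "private_bits")]
  }
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
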