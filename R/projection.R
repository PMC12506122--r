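#' Discovery ratio
#'
#' The fraction of BGCs that are the first observed instance of their gene
#' cluster family, carried as an exact count pair (numerator GCFs,
#' denominator BGCs) — never as a rounded percentage, because projections
#' built from a rounded ratio do not reproduce count-level arithmetic.
#'
#' @param n_gcfs number of GCFs (numerator).
#' @param n_bgcs number of BGCs (denominator, >= n_gcfs).
#' @param label free-text provenance label for reports.
#' @return a `discovery_ratio` object.
#' @examples
#' discovery_ratio(4463, 6972, "Aspergillus")   # prints as 64%
#' discovery_ratio(9808, 28696, "Pezizomycotina")  # prints as 34.2%
#' @export
discovery_ratio <- function(n_gcfs, n_bgcs, label = "") {
  n_gcfs <- stopifnot_count(n_gcfs, "n_gcfs", min = 1)
  n_bgcs <- stopifnot_count(n_bgcs, "n_bgcs", min = 1)
  if (n_gcfs > n_bgcs) stop("n_gcfs must not exceed n_bgcs", call. = FALSE)
  structure(
    list(n_gcfs = n_gcfs, n_bgcs = n_bgcs, value = n_gcfs / n_bgcs,
         label = label),
    class = "discovery_ratio"
  )
}

#' Format a discovery ratio as a percentage
#'
#' One-decimal percentage with a trailing `.0` dropped (64.0% prints as
#' "64%", 34.17...% as "34.2%").
#'
#' @param x a `discovery_ratio`.
#' @param ... unused.
#' @return character scalar such as `"64%"`.
#' @export
format.discovery_ratio <- function(x, ...) {
  pct <- round_half_away(100 * x$value, 1)
  if (pct == round_half_away(pct)) {
    sprintf("%d%%", as.integer(round_half_away(pct)))
  } else {
    sprintf("%.1f%%", pct)
  }
}

#' @export
print.discovery_ratio <- function(x, ...) {
  cat(sprintf("Discovery ratio %s: %d/%d = %s\n",
              if (nzchar(x$label)) paste0("(", x$label, ")") else "",
              x$n_gcfs, x$n_bgcs, format(x)))
  invisible(x)
}

#' Derived BGC count from a genome survey
#'
#' Total BGCs implied by a survey's genome count and mean BGCs per genome,
#' rounded half away from zero (e.g. 721 genomes x 39.8 BGCs/genome = 28,696).
#'
#' @param n_genomes number of genomes surveyed.
#' @param mean_bgcs mean BGCs per genome.
#' @return integer count.
#' @export
derived_bgc_count <- function(n_genomes, mean_bgcs) {
  stopifnot(n_genomes > 0, mean_bgcs > 0)
  as.integer(round_half_away(n_genomes * mean_bgcs))
}

#' Projected SM count from a GCF count
#'
#' Multiplies a GCF count by the effective SMs-per-BGC multiplier and rounds
#' half away from zero.
#'
#' @param n_gcfs GCF count (may be fractional if an unrounded intermediate).
#' @param m effective SMs per BGC (default 1.57).
#' @return integer SM count.
#' @export
sm_from_gcf <- function(n_gcfs, m = 1.57) {
  stopifnot(n_gcfs > 0, m > 0)
  round_half_away(n_gcfs * m)
}

#' Build a projection scenario
#'
#' @param bgcs_per_species assumed BGCs per species (B).
#' @param n_species number of species projected over (N).
#' @param ratio a `discovery_ratio` (r).
#' @param sms_per_bgc effective SMs per BGC (m, default 1.57).
#' @return a `projection_scenario` list.
#' @export
projection_scenario <- function(bgcs_per_species, n_species, ratio,
                                sms_per_bgc = 1.57) {
  stopifnot(inherits(ratio, "discovery_ratio"),
            bgcs_per_species > 0, n_species > 0, sms_per_bgc > 0)
  structure(
    list(B = bgcs_per_species, N = n_species, ratio = ratio,
         m = sms_per_bgc),
    class = "projection_scenario"
  )
}

#' Project GCF and SM counts for one scenario
#'
#' The projection chain `B x N x r x m` evaluated in full precision:
#' total BGCs = B*N, projected GCFs = B*N*r, projected SMs = B*N*r*m.
#' Rounding (half away from zero) is applied only to the display values, and
#' the displayed SM count is derived from the *unrounded* GCF intermediate —
#' rounding the GCF count first can be off by one.
#'
#' @param scenario a `projection_scenario`.
#' @return a `projection_result` list: `total_bgcs`, `gcfs_exact`,
#'   `sms_exact`, `gcfs_display`, `sms_display`, plus the scenario.
#' @export
project_sms <- function(scenario) {
  stopifnot(inherits(scenario, "projection_scenario"))
  total_bgcs <- scenario$B * scenario$N
  gcfs_exact <- total_bgcs * scenario$ratio$n_gcfs / scenario$ratio$n_bgcs
  sms_exact <- gcfs_exact * scenario$m
  structure(
    list(scenario = scenario,
         total_bgcs = total_bgcs,
         gcfs_exact = gcfs_exact,
         sms_exact = sms_exact,
         gcfs_display = round_half_away(gcfs_exact),
         sms_display = round_half_away(sms_exact)),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf(
    "Projection: B = %g BGCs/species, N = %s species, r = %s, m = %g\n",
    x$scenario$B, format(x$scenario$N, big.mark = ","),
    format(x$scenario$ratio), x$scenario$m))
  cat(sprintf("  total BGCs: %s   GCFs: %s   SMs: %s\n",
              format(x$total_bgcs, big.mark = ",", scientific = FALSE),
              format(x$gcfs_display, big.mark = ",", scientific = FALSE),
              format(x$sms_display, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Scenario grid of GCF and SM projections
#'
#' Crosses a set of BGCs-per-species values with one or more discovery
#' ratios at a fixed species count and SM multiplier, yielding one projection
#' per combination.  With the defaults (B in 30/40/50, N = 85,000,
#' the Aspergillus-derived ratio 4,463/6,972 and the Pezizomycotina-derived
#' ratio 9,808/28,696, m = 1.57) this is the full published projection table
#' for filamentous fungi.
#'
#' @param B_set numeric vector of BGCs-per-species scenarios.
#' @param n_species species count N.
#' @param ratios list of `discovery_ratio` objects.
#' @param sms_per_bgc multiplier m.
#' @return a `projection_grid` data.frame with one row per (ratio, B):
#'   columns `ratio_label`, `ratio_pct`, `B`, `N`, `total_bgcs`,
#'   `gcfs_exact`, `sms_exact`, `gcfs`, `sms`.
#' @examples
#' scenario_grid()
#' @export
scenario_grid <- function(B_set = c(30, 40, 50),
                          n_species = 85000,
                          ratios = default_ratios(),
                          sms_per_bgc = 1.57) {
  stopifnot(length(B_set) >= 1, length(ratios) >= 1)
  if (inherits(ratios, "discovery_ratio")) ratios <- list(ratios)
  rows <- list()
  for (r in ratios) {
    for (B in B_set) {
      res <- project_sms(projection_scenario(B, n_species, r, sms_per_bgc))
      rows[[length(rows) + 1L]] <- data.frame(
        ratio_label = r$label, ratio_pct = format(r), B = B, N = n_species,
        total_bgcs = res$total_bgcs,
        gcfs_exact = res$gcfs_exact, sms_exact = res$sms_exact,
        gcfs = res$gcfs_display, sms = res$sms_display,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("projection_grid", "data.frame")
  out
}

#' Default discovery ratios
#'
#' The two published count pairs behind the projection table: 4,463 GCFs from
#' 6,972 BGCs across 135 *Aspergillus* genomes, and 9,808 GCFs from 28,696
#' BGCs across 721 Pezizomycotina genomes (the Robey et al. survey: 721
#' genomes averaging 39.8 BGCs each).
#'
#' @return a list of two `discovery_ratio` objects.
#' @export
default_ratios <- function() {
  list(
    aspergillus = discovery_ratio(4463, 6972, "135 Aspergillus genomes"),
    pezizomycotina = discovery_ratio(9808, derived_bgc_count(721, 39.8),
                                     "721 Pezizomycotina genomes")
  )
}

#' @export
print.projection_grid <- function(x, ...) {
  cat("GCF / SM projection grid\n")
  df <- x
  class(df) <- "data.frame"
  show <- df[, c("ratio_pct", "B", "N", "total_bgcs", "gcfs", "sms")]
  show$total_bgcs <- format(show$total_bgcs, big.mark = ",")
  show$gcfs <- format(show$gcfs, big.mark = ",")
  show$sms <- format(show$sms, big.mark = ",")
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}
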