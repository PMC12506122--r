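test_that("occupancy calibration hits the target singleton probability", {
  a <- calibrate_occupancy(135, 3607 / 4463)
  pmf <- smprospect:::zipf_pmf(a, 135)
  expect_equal(pmf[1], 3607 / 4463, tolerance = 1e-3)
  # monotonicity: a higher singleton target needs faster decay
  expect_gt(calibrate_occupancy(135, 0.9), a)
  # T = 2 with a target just below 1 forces a very large exponent
  expect_gt(calibrate_occupancy(2, 0.999), 9)
  # a singleton fraction below 1/T is unattainable
  expect_error(calibrate_occupancy(4, 0.2), "unattainable")
})

test_that("duplication calibration inverts the expected GCF:BGC ratio", {
  a <- calibrate_occupancy(135, 3607 / 4463)
  lam <- calibrate_duplication(135, a, 4463 / 6972)
  expect_gte(lam, 0)
  pmf <- smprospect:::zipf_pmf(a, 135)
  ey <- sum((1:135) * pmf)
  expect_equal(1 / (ey * (1 + lam)), 4463 / 6972, tolerance = 1e-12)
  expect_error(calibrate_duplication(135, a, 0.99), "exceeds")
})

test_that("generated incidence is a pure function of model and seed", {
  mod <- incidence_model(n_units = 20, s_true = 60, seed = 31)
  a <- gen_incidence(mod)
  b <- gen_incidence(mod)
  expect_identical(a$records, b$records)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- gen_incidence(incidence_model(n_units = 20, s_true = 60, seed = 32))
  expect_false(identical(a$records, c$records))
})

test_that("without duplication every presence is exactly one BGC record", {
  mod <- incidence_model(n_units = 15, s_true = 40, duplication_rate = 0,
                         seed = 41)
  sim <- gen_incidence(mod)
  gt <- sim$ground_truth
  expect_equal(gt$n_bgcs, sum(gt$Y))
  expect_equal(nrow(sim$records), sum(gt$Y))
  expect_equal(sum(sim$matrix), sum(gt$Y))
})

test_that("ground-truth bookkeeping matches what the pipeline recomputes", {
  sim <- gen_incidence(incidence_model(n_units = 25, s_true = 80, seed = 51))
  gt <- sim$ground_truth
  f <- incidence_freqs(sim$matrix)
  expect_equal(f$S_obs, gt$S_obs)
  expect_equal(f$Q1, gt$Q1)
  expect_equal(f$Q2, gt$Q2)
  expect_equal(sort(f$Y), sort(as.integer(gt$Y)))
  m2 <- build_incidence(sim$records)
  expect_equal(sum(m2), sum(sim$matrix))
  s <- summarize_dataset(sim$records, m2)
  expect_equal(s$n_bgcs, gt$n_bgcs)
  expect_equal(s$gcf_bgc_ratio, gt$gcf_bgc_ratio)
})

test_that("synthetic BGC-SM tables honour their sharing regime", {
  # no sharing: every link mints a fresh SM, so the down-weighted mean
  # equals the plain links-per-BGC mean
  ns <- gen_bgc_sm_table(n_bgcs = 40, mean_sms_per_bgc = 1.6,
                         sharing_prob = 0, seed = 61)
  r <- effective_sm(ns$table)
  expect_equal(r$mean_effective, nrow(ns$table) / 40)
  expect_true(all(sm_multiplicity(ns$table) == 1L))

  # total sharing with single-SM BGCs: everyone shares one compound
  all_shared <- gen_bgc_sm_table(n_bgcs = 25, mean_sms_per_bgc = 1,
                                 sharing_prob = 1, seed = 62)
  r2 <- effective_sm(all_shared$table)
  expect_equal(r2$n_distinct_sms, 1L)
  expect_equal(r2$mean_effective, 1 / 25)

  # intermediate sharing: ground truth multiplicities are what the
  # analysis recomputes, and the distinct/total identity holds
  mid <- gen_bgc_sm_table(n_bgcs = 60, mean_sms_per_bgc = 1.8,
                          sharing_prob = 0.3, seed = 63)
  expect_identical(sm_multiplicity(mid$table),
                   mid$ground_truth$multiplicity)
  r3 <- effective_sm(mid$table)
  expect_equal(r3$mean_effective,
               mid$ground_truth$n_distinct_sms / 60, tolerance = 1e-12)
})

test_that("synthetic fingerprints separate families as configured", {
  one <- gen_fingerprints(n_families = 1, per_family = 8,
                          within_family_overlap = 1, seed = 71)
  expect_equal(chem_diversity(one$fps)$d, 0)

  # disjoint cores, full overlap: d grows with the number of families
  ds <- vapply(c(2, 4, 8), function(k) {
    chem_diversity(gen_fingerprints(n_families = k, per_family = 6,
                                    within_family_overlap = 1,
                                    seed = 72)$fps)$d
  }, numeric(1))
  expect_true(all(diff(ds) > 0))

  # reproducibility
  x <- gen_fingerprints(3, 5, within_family_overlap = 0.7, seed = 73)
  y <- gen_fingerprints(3, 5, within_family_overlap = 0.7, seed = 73)
  expect_identical(unclass(x$fps), unclass(y$fps))

  # within-family similarity exceeds between-family similarity
  sim <- gen_fingerprints(3, 6, within_family_overlap = 0.7, seed = 74)
  fam <- sim$ground_truth$family
  bits <- unclass(sim$fps)
  within <- between <- c()
  for (i in 1:17) for (j in (i + 1):18) {
    s <- tanimoto(bits[i, ], bits[j, ])
    if (fam[i] == fam[j]) within <- c(within, s) else between <- c(between, s)
  }
  expect_gt(mean(within), mean(between))
})

test_that("emitted files re-read to the recorded ground truth", {
  dir <- withr::local_tempdir()
  sim <- gen_incidence(incidence_model(n_units = 12, s_true = 30, seed = 81))
  sm_sim <- gen_bgc_sm_table(n_bgcs = 20, seed = 82)
  fp_sim <- gen_fingerprints(2, 5, seed = 83)
  write_synthetic(dir, sim, sm_sim, fp_sim)

  clust <- read_clustering_table(file.path(dir, "clustering.tsv"))
  recs <- bgc_records(clust, read_bgc_map(file.path(dir, "bgc_map.tsv")))
  expect_equal(recs$bgc_id, sim$records$bgc_id)
  expect_equal(recs$gcf_id, sim$records$gcf_id)
  expect_equal(recs$species_id, sim$records$species_id)

  m <- read_incidence(file.path(dir, "incidence.tsv"))
  expect_equal(unclass(m), unclass(sim$matrix))

  tab <- read_bgc_sm_table(file.path(dir, "bgc_sm.tsv"))
  expect_identical(sm_multiplicity(tab),
                   sm_sim$ground_truth$multiplicity)

  fps <- read_fingerprints(file.path(dir, "fingerprints.tsv"))
  expect_equal(unname(unclass(fps)), unname(unclass(fp_sim$fps)))

  gt <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_equal(gt$incidence$S_obs, sim$ground_truth$S_obs)
  expect_equal(gt$incidence$n_bgcs, sim$ground_truth$n_bgcs)
})

test_that("model construction validates its parameters", {
  expect_error(incidence_model(n_units = 1, seed = 1), ">= 2")
  expect_error(incidence_model(n_units = 10, s_true = 30,
                               duplication_rate = -0.5, seed = 1), ">= 0")
  expect_error(incidence_model(n_units = 10, s_true = 30), "seed")
})
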