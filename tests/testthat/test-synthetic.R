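test_that("cohort_spec validates dimensions and builds labelled metadata", {
  spec <- cohort_spec(n_reference = 6, n_patients = 2,
                      n_regions_left = 24, n_regions_right = 24,
                      n_timepoints = 80)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(nrow(spec$meta), 48)
  expect_setequal(unique(spec$meta$hemisphere), c("L", "R"))
  expect_true(all(table(spec$meta$region_id) == 1))
  expect_true(all(dysconn_networks() %in% spec$meta$network))
  expect_true(all(diag(spec$base_covariance$L) == 1))
  ev <- eigen(spec$base_covariance$L, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(cohort_spec(n_regions_left = 8, n_regions_right = 8),
               "at least 20 regions")
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- cohort_spec(n_reference = 3, n_patients = 2,
                      n_regions_left = 20, n_regions_right = 20,
                      n_timepoints = 60)
  eff <- planted_effect("default-mode", 0.4, 0.5)
  a <- generate_cohort(spec, eff, seed = 42)
  b <- generate_cohort(spec, eff, seed = 42)
  expect_identical(a$reference, b$reference)
  expect_identical(a$patients, b$patients)
  expect_identical(a$covariates, b$covariates)
  c2 <- generate_cohort(spec, eff, seed = 43)
  expect_false(identical(a$patients, c2$patients))
})

test_that("without effects patients and reference share the population", {
  spec <- cohort_spec(n_reference = 2, n_patients = 2,
                      n_regions_left = 20, n_regions_right = 20,
                      n_timepoints = 60, subject_sd = 0)
  st <- generate_cohort(spec, effects = list(), seed = 1)
  expect_equal(st$target_cov$patients[[1]]$baseline$L,
               st$target_cov$reference[[1]]$L)
  expect_equal(st$target_cov$patients[[1]]$followup$R,
               spec$base_covariance$R)
})

test_that("full attenuation restores the unshifted covariance exactly", {
  spec <- cohort_spec(n_reference = 1, n_patients = 1,
                      n_regions_left = 20, n_regions_right = 20,
                      n_timepoints = 60, subject_sd = 0)
  eff <- planted_effect("default-mode", 0.5, attenuation = 1.0)
  st <- generate_cohort(spec, eff, seed = 2)
  expect_equal(st$target_cov$patients[[1]]$followup$L,
               spec$base_covariance$L)
  expect_false(isTRUE(all.equal(st$target_cov$patients[[1]]$baseline$L,
                                spec$base_covariance$L)))
})

test_that("planted shift is recovered in sample Fisher-z (50-seed mean)", {
  # 0.5 Fisher-z shift on explicit default-mode pairs at 300 timepoints;
  # the across-seed mean of the sample z on target connections must sit
  # at base + 0.5 up to Monte-Carlo error
  spec <- cohort_spec(n_reference = 1, n_patients = 1,
                      n_regions_left = 30, n_regions_right = 30,
                      n_timepoints = 300, subject_sd = 0)
  dmn <- spec$meta$region_id[spec$meta$network == "default-mode" &
                               spec$meta$hemisphere == "L"]
  pairs <- t(combn(dmn[1:5], 2))
  eff <- planted_effect(pairs, baseline_shift = 0.5, attenuation = 0.6)
  ids_l <- spec$meta$region_id[spec$meta$hemisphere == "L"]
  base_z <- mean(atanh(spec$base_covariance$L[ids_l, ids_l][pairs]))
  shifts <- vapply(1:50, function(s) {
    st <- generate_cohort(spec, eff, seed = 100 + s)
    z <- fisher_z_connectivity(st$patients[[1]]$baseline, spec$meta)$L
    mean(z[pairs]) - base_z
  }, numeric(1))
  expect_lt(abs(mean(shifts) - 0.5), 0.03)
})

test_that("empirical correlation converges to the subject target", {
  spec <- cohort_spec(n_reference = 1, n_patients = 1,
                      n_regions_left = 20, n_regions_right = 20,
                      n_timepoints = 5000)
  st <- generate_cohort(spec, planted_effect("default-mode", 0.4, 0.5),
                        seed = 8)
  idx <- which(spec$meta$hemisphere == "L")
  emp <- cor(st$patients[[1]]$baseline[, spec$meta$region_id[idx]])
  tgt <- st$target_cov$patients[[1]]$baseline$L
  expect_lt(max(abs(emp - tgt)), 0.05)
})

test_that("connections outside the target keep the base population", {
  spec <- cohort_spec(n_reference = 1, n_patients = 1,
                      n_regions_left = 20, n_regions_right = 20,
                      n_timepoints = 60, subject_sd = 0)
  eff <- planted_effect("default-mode", 0.5, 0.3)
  st <- generate_cohort(spec, eff, seed = 3)
  tgt <- st$target_cov$patients[[1]]$baseline$L
  base <- spec$base_covariance$L
  ids <- spec$meta$region_id[spec$meta$hemisphere == "L"]
  dmn <- ids %in% spec$meta$region_id[spec$meta$network == "default-mode"]
  untouched <- !dmn
  expect_equal(tgt[untouched, untouched], base[untouched, untouched])
})

test_that("invalid effects are rejected", {
  spec <- cohort_spec(n_reference = 1, n_patients = 1,
                      n_regions_left = 20, n_regions_right = 20,
                      n_timepoints = 60)
  expect_error(planted_effect("default-mode", 0.5, 1.5), "attenuation")
  cross <- cbind("L001", "R001")
  expect_error(
    generate_cohort(spec, planted_effect(cross, 0.5, 0.5), seed = 1),
    "within one hemisphere")
  expect_error(
    generate_cohort(spec, planted_effect("no-such-network", 0.5, 0.5),
                    seed = 1),
    "unknown network")
})

test_that("expression generator couples only the planted set", {
  coords <- random_coords(40)
  map <- setNames(smooth_field(coords), rownames(coords))
  es <- expression_spec(n_genes = 400, set_size = 30, coupling = 0,
                        noise_sd = 1)
  ex <- generate_expression(es, map, seed = 5)
  rho <- suppressWarnings(cor(map, ex$expression, method = "spearman"))
  planted <- colnames(ex$expression) %in% es$gene_sets$Oli
  expect_lt(abs(mean(abs(rho[planted])) - mean(abs(rho[!planted]))), 0.05)

  es1 <- expression_spec(n_genes = 400, set_size = 30, coupling = 1,
                         noise_sd = 0)
  ex1 <- generate_expression(es1, map, seed = 6)
  rho1 <- suppressWarnings(
    cor(map, ex1$expression[, es1$gene_sets$Oli], method = "spearman"))
  expect_equal(as.numeric(rho1), rep(1, 30), tolerance = 1e-12)

  expect_error(expression_spec(coupling = 1.2), "coupling")
})

test_that("coupled-gene correlation matches the closed-form level", {
  # coupling 0.6, noise SD 1: population Pearson = 0.6/sqrt(0.36 + 1);
  # for a bivariate Gaussian the Spearman analogue is
  # (6/pi) asin(rho/2); checked as a 50-seed Monte-Carlo mean
  coords <- random_coords(100, seed = 78)
  map <- setNames(smooth_field(coords), rownames(coords))
  es <- expression_spec(n_genes = 220, set_size = 20, coupling = 0.6,
                        noise_sd = 1)
  rho_pop <- 0.6 / sqrt(0.36 + 1)
  rho_sp <- (6 / pi) * asin(rho_pop / 2)
  means <- vapply(1:50, function(s) {
    ex <- generate_expression(es, map, seed = 300 + s)
    mean(cor(map, ex$expression[, es$gene_sets$Oli], method = "spearman"))
  }, numeric(1))
  expect_lt(abs(mean(means) - rho_sp), 0.03)
})

test_that("clinical changes follow the planted network coupling", {
  fx <- planted_fixture()
  meta <- fx$spec$meta
  n <- fx$spec$n_patients
  regions <- meta$region_id
  set.seed(9)
  chg <- matrix(rnorm(n * length(regions)), n,
                dimnames = list(fx$study$covariates$subject, regions))

  # zero strength: independent of the deviation changes (mean absolute
  # correlation over 25 noise draws stays at the n = 12 null level)
  dmn_mean <- rowMeans(chg[, meta$region_id[meta$network == "default-mode"]])
  cors <- vapply(1:25, function(s) {
    clin0 <- generate_clinical(chg, meta,
                               coupling = list(GAF = list(
                                 target = "default-mode", strength = 0)),
                               noise_sd = 1, seed = 10 + s)
    cor(clin0$GAF, dmn_mean)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.2)

  # noise-free monotone coupling: rank correlation exactly 1
  clin1 <- generate_clinical(chg, meta,
                             coupling = list(GAF = list(
                               target = "default-mode", strength = 2)),
                             noise_sd = 0, seed = 12)
  expect_equal(cor(clin1$GAF, dmn_mean, method = "spearman"), 1)

  expect_error(
    generate_clinical(chg, meta, coupling = list(XYZ = list(
      target = "visual", strength = 1)), seed = 1),
    "unknown score")
})
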