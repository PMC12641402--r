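test_that("BH q-values match the brute-force step-up oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  expect_identical(fdr_bh(numeric(0)), numeric(0))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    q <- fdr_bh(p)
    expect_lt(max(abs(q - bh_brute(p))), 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("BH significance calls agree with the oracle on 1000 vectors", {
  set.seed(7)
  agree <- vapply(1:1000, function(i) {
    p <- runif(sample(2:25, 1))
    q <- fdr_bh(p)
    qo <- bh_brute(p)
    max(abs(q - qo)) < 1e-12 && identical(q < 0.05, qo < 0.05)
  }, logical(1))
  expect_true(all(agree))
})

test_that("the mixed model recovers a planted session shift", {
  set.seed(8)
  hits <- vapply(1:50, function(i) {
    tab <- sim_dci_table(12, 0.5, 1, delta = -0.8)
    fit <- fit_dci_lmm(tab)
    abs(fit$session_estimate - (-0.8)) < 2 * fit$session_se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null session p-values are uniform (KS oracle)", {
  set.seed(9)
  p <- vapply(1:200, function(i) {
    fit_dci_lmm(sim_dci_table(10, 0.5, 1, delta = 0))$session_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("a constant response gives a zero session effect", {
  tab <- sim_dci_table(6, 0, 0, delta = 0)
  tab$dci <- 3
  fit <- suppressWarnings(fit_dci_lmm(tab))
  expect_equal(fit$session_estimate, 0, tolerance = 1e-10)
  expect_equal(fit$var_intercept + fit$var_residual, 0, tolerance = 1e-12)
})

test_that("zero random-intercept variance reproduces ordinary least squares", {
  # in this balanced design the session estimate coincides with OLS
  # whatever the variance split, and exactly so when the random
  # intercept collapses to zero
  set.seed(10)
  tab <- sim_dci_table(20, 0, 1, delta = -0.5)
  fit <- fit_dci_lmm(tab)
  ols <- lm(dci ~ session + hemisphere, data = tab)
  expect_equal(fit$session_estimate,
               unname(coef(ols)["sessionfollowup"]), tolerance = 1e-6)
})

test_that("battery assembles all scopes once with monotone q >= p", {
  fx <- planted_fixture()
  tab <- dci_longitudinal_table(fx$conn$patients, fx$norm,
                                fx$study$covariates, fx$seeds)
  expect_equal(sort(unique(tab$scope)), sort(names(fx$seeds)))
  expect_equal(nrow(tab), 12 * 2 * 2 * 13)
  bat <- with_cache("battery", dci_battery(tab))
  expect_equal(nrow(bat$results), 13)
  expect_true(all(bat$results$q >= bat$results$p - 1e-15))
  expect_equal(bat$results$q, fdr_bh(bat$results$p))
})

test_that("post hoc d uses the model SD and flips under label swap", {
  fx <- planted_fixture()
  tab <- dci_longitudinal_table(fx$conn$patients, fx$norm,
                                fx$study$covariates,
                                fx$seeds["default-mode"])
  fit <- fit_dci_lmm(tab, outcome = "default-mode")
  ph <- posthoc_session(fit)
  # the planted attenuation reduces the DCI: negative d
  expect_lt(ph$cohen_d, -1)
  expect_equal(ph$cohen_d,
               ph$estimate / sqrt(fit$var_intercept + fit$var_residual))
  expect_true(ph$ci95[1] <= ph$cohen_d && ph$cohen_d <= ph$ci95[2])

  swapped <- tab
  swapped$session <- factor(
    ifelse(tab$session == "baseline", "followup", "baseline"),
    levels = c("baseline", "followup"))
  ph2 <- posthoc_session(fit_dci_lmm(swapped, outcome = "default-mode"))
  expect_equal(ph2$cohen_d, -ph$cohen_d, tolerance = 1e-8)
  expect_equal(ph2$ci95, -rev(ph$ci95), tolerance = 1e-8)
})

test_that("session-effect map finds planted reductions where they live", {
  fx <- planted_fixture()
  dcc <- study_dcc(fx$conn$patients, fx$norm)
  sem <- session_effect_map(dcc$baseline, dcc$followup,
                            fx$study$covariates)
  meta <- fx$spec$meta
  top <- sem$region[order(-sem$reduction_stat)][1:12]  # top decile
  frac_dmn_top <- mean(meta$network[match(top, meta$region_id)] ==
                         "default-mode")
  base_rate <- mean(meta$network == "default-mode")
  expect_gte(frac_dmn_top / base_rate, 3)

  # single-region oracle: direct refit of the same paired model
  rg <- meta$region_id[1]
  direct <- lmerTest::lmer(
    dcc ~ session + age + sex + cpz + trainings + group + (1 | subject),
    data = data.frame(
      dcc = c(dcc$baseline[, rg], dcc$followup[, rg]),
      session = factor(rep(c("baseline", "followup"),
                           each = nrow(dcc$baseline)),
                       levels = c("baseline", "followup")),
      fx$study$covariates[match(rep(rownames(dcc$baseline), 2),
                                fx$study$covariates$subject), -1],
      subject = rep(rownames(dcc$baseline), 2)))
  tstat <- coef(summary(direct))["sessionfollowup", "t value"]
  expect_equal(sem$statistic[sem$region == rg], tstat, tolerance = 1e-6)
})

test_that("rank-deficient session-effect designs are reported", {
  fx <- planted_fixture()
  dcc <- study_dcc(fx$conn$patients, fx$norm)
  cv <- fx$study$covariates
  cv$trainings <- cv$age  # alias two columns
  expect_error(session_effect_map(dcc$baseline, dcc$followup, cv),
               "aliased")
})

test_that("clinical regression matches the closed-form OLS oracle", {
  set.seed(11)
  n <- 6
  subs <- sprintf("s%d", 1:n)
  chg <- matrix(rnorm(n), n, 1, dimnames = list(subs, "r1"))
  cov <- data.frame(subject = subs, age = rnorm(n),
                    sex = factor(rep(c("F", "M"), 3)), cpz = rnorm(n))
  clin <- data.frame(subject = subs, GAF = rnorm(n))
  res <- voxelwise_clinical_regression(chg, clin, cov)
  X <- cbind(1, chg[, 1], cov$age, cov$sex == "M", cov$cpz)
  beta <- solve(t(X) %*% X, t(X) %*% clin$GAF)
  expect_equal(res$beta, beta[2], tolerance = 1e-10)

  # noise-free coupling: planted strength recovered exactly
  clin2 <- data.frame(subject = subs, PANSS = 2.25 * chg[, 1])
  res2 <- suppressWarnings(
    voxelwise_clinical_regression(chg, clin2, cov))
  expect_equal(res2$beta, 2.25, tolerance = 1e-10)
  expect_equal(res2$beta_thresholded, 2.25, tolerance = 1e-10)

  expect_error(voxelwise_clinical_regression(chg[1:4, , drop = FALSE],
                                             clin[1:4, ], cov[1:4, ]),
               "more subjects")
})

test_that("session-effect map is centred when nothing was planted", {
  spec <- cohort_spec(n_reference = 12, n_patients = 8,
                      n_regions_left = 20, n_regions_right = 20,
                      n_timepoints = 150)
  st <- generate_cohort(spec, seed = 61)
  conn <- study_connectivity(st)
  norm <- fit_reference_norm(conn$reference)
  dcc <- study_dcc(conn$patients, norm)
  sem <- session_effect_map(dcc$baseline, dcc$followup, st$covariates)
  expect_lt(abs(mean(sem$statistic, na.rm = TRUE)), 0.3)
  expect_gt(mean(sem$p > 0.05, na.rm = TRUE), 0.8)
})

test_that("mixed clinical coupling concentrates beta in its network", {
  fx <- planted_fixture()
  dcc <- study_dcc(fx$conn$patients, fx$norm)
  chg <- dcc_change_map(dcc$baseline, dcc$followup)
  meta <- fx$spec$meta
  clin <- generate_clinical(chg, meta,
                            coupling = list(
                              GAF = list(target = "default-mode",
                                         strength = 2),
                              PANSS = list(target = "somatomotor",
                                           strength = 1.5)),
                            noise_sd = 0.3, seed = 62)
  vr <- voxelwise_clinical_regression(chg, clin, fx$study$covariates)
  dmn <- meta$region_id[meta$network == "default-mode"]
  gaf <- vr[vr$outcome == "GAF", ]
  expect_gt(mean(gaf$beta[gaf$region %in% dmn]),
            mean(gaf$beta[!gaf$region %in% dmn]))
  # per-region OLS oracle on one coupled region
  rg <- dmn[1]
  d <- data.frame(y = clin$GAF, x = chg[, rg],
                  fx$study$covariates[match(rownames(chg),
                                            fx$study$covariates$subject),
                                      c("age", "sex", "cpz")])
  ora <- coef(summary(lm(y ~ x + age + sex + cpz, data = d)))["x", ]
  expect_equal(gaf$beta[gaf$region == rg], unname(ora["Estimate"]),
               tolerance = 1e-10)
})
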