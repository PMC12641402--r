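#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' as used across the battery of mixed-model outcomes.
#'
#' @param pvals Numeric vector of p-values in \eqn{[0, 1]}.
#' @return Vector of q-values, same length and order; empty in, empty out.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_bh <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

# Build the fixed-effects formula, dropping covariates without variation
# (a single-group cohort would otherwise make the design rank deficient).
lmm_formula <- function(df, response = "dci") {
  covs <- c("session", "age", "sex", "cpz", "trainings", "group",
            "hemisphere")
  covs <- covs[covs %in% names(df)]
  keep <- vapply(covs, function(v) length(unique(df[[v]])) > 1, logical(1))
  dropped <- covs[!keep]
  f <- stats::as.formula(paste(
    response, "~", paste(c(covs[keep], "(1 | subject)"), collapse = " + ")))
  attr(f, "dropped") <- dropped
  f
}

#' Random-intercept mixed model for one DCI outcome
#'
#' Fits, by restricted maximum likelihood, the repeated-measures model
#' with session, age, sex, CPZ equivalents, achieved trainings, group and
#' hemisphere as fixed effects and a per-participant random intercept:
#' \deqn{DCI_{ijk} = \beta_0 + \sum_n \beta_n X_{ijk,n} + \gamma_i +
#'   \epsilon_{ijk}}
#' for subject \eqn{i}, session \eqn{j}, hemisphere \eqn{k}. The p-value
#' of the session effect uses Satterthwaite degrees of freedom. Covariates
#' without variation in the data are dropped from the design (recorded in
#' the result).
#'
#' @param df Data frame with columns `dci`, `session` (factor, baseline
#'   first), `subject`, and any of `age`, `sex`, `cpz`, `trainings`,
#'   `group`, `hemisphere`. One scope at a time.
#' @param outcome Label stored in the result.
#' @return An object of class `dci_lmm`: list with the fitted model
#'   (`fit`), the fixed-effect table (`coefficients`), `session_estimate`,
#'   `session_se`, `session_df`, `session_p`, variance components
#'   (`var_intercept`, `var_residual`), `singular` flag and `dropped`
#'   covariates. A constant response short-circuits to a zero session
#'   effect with zero variances and `session_p = 1` (`fit` is `NULL`).
#' @export
fit_dci_lmm <- function(df, outcome = "dci") {
  stopifnot(is.data.frame(df), "dci" %in% names(df),
            "session" %in% names(df), "subject" %in% names(df))
  if (length(unique(df$subject)) < 3) stop("too few subjects for the LMM")
  if (stats::var(df$dci) == 0) {
    # a constant outcome carries no evidence: zero effect, zero variances
    co <- matrix(c(df$dci[1], rep(0, 4)), 1, 5,
                 dimnames = list("(Intercept)",
                                 c("Estimate", "Std. Error", "df",
                                   "t value", "Pr(>|t|)")))
    return(structure(list(
      fit = NULL, outcome = outcome, coefficients = co,
      session_estimate = 0, session_se = 0, session_df = NA_real_,
      session_p = 1, var_intercept = 0, var_residual = 0,
      singular = TRUE, dropped = character(0)
    ), class = "dci_lmm"))
  }
  f <- lmm_formula(df)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(f, data = df, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = lme4::.makeCC(
                       action = "ignore", tol = 1e-4)))))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  co <- stats::coef(summary(fit))
  srow <- grep("^session", rownames(co))
  if (length(srow) != 1) stop("session effect not estimable")
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_int <- vc$vcov[vc$grp == "subject"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  structure(list(
    fit = fit, outcome = outcome, coefficients = co,
    session_estimate = co[srow, "Estimate"],
    session_se = co[srow, "Std. Error"],
    session_df = co[srow, "df"],
    session_p = co[srow, "Pr(>|t|)"],
    var_intercept = var_int, var_residual = var_res,
    singular = singular, dropped = attr(f, "dropped")
  ), class = "dci_lmm")
}

#' Fit the full battery of DCI mixed models with FDR correction
#'
#' Runs [fit_dci_lmm()] once per scope of a longitudinal DCI table (by
#' default the 13 scopes: whole brain, eight networks, four seed scopes)
#' and corrects the session p-values across the battery by
#' Benjamini-Hochberg FDR.
#'
#' @param table Output of [dci_longitudinal_table()].
#' @return List with `results` (data frame: `scope`, `estimate`, `se`,
#'   `df`, `p`, `q`, `singular`) and `fits` (named list of `dci_lmm`
#'   objects).
#' @export
dci_battery <- function(table) {
  scopes <- unique(table$scope)
  fits <- lapply(scopes, function(sc) {
    fit_dci_lmm(table[table$scope == sc, , drop = FALSE], outcome = sc)
  })
  names(fits) <- scopes
  results <- data.frame(
    scope = scopes,
    estimate = vapply(fits, `[[`, numeric(1), "session_estimate"),
    se = vapply(fits, `[[`, numeric(1), "session_se"),
    df = vapply(fits, `[[`, numeric(1), "session_df"),
    p = vapply(fits, `[[`, numeric(1), "session_p"),
    singular = vapply(fits, `[[`, logical(1), "singular"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  results$q <- fdr_bh(results$p)
  list(results = results, fits = fits)
}

#' Tukey post hoc session contrast as Cohen's d
#'
#' Computes the marginal-mean contrast follow-up minus baseline from a
#' fitted DCI mixed model with Tukey adjustment (degenerate for the single
#' two-level comparison), and expresses it as Cohen's d using the
#' model-based total SD \eqn{\sqrt{\sigma^2_{\gamma} + \sigma^2_\epsilon}}
#' (random-intercept plus residual variance). A DCI that is lower at
#' follow-up therefore gives a negative d. The 95% confidence interval maps
#' the contrast's t interval onto the d scale.
#'
#' @param fit A `dci_lmm` object.
#' @return An object of class `posthoc_result`: list with `outcome`,
#'   `contrast`, `estimate`, `se`, `df`, `p_tukey`, `cohen_d`, `ci95`
#'   (length 2) and `standardiser`.
#' @export
posthoc_session <- function(fit) {
  stopifnot(inherits(fit, "dci_lmm"))
  total_var <- fit$var_intercept + fit$var_residual
  if (total_var <= 0) stop("total variance is zero; d undefined")
  emm <- emmeans::emmeans(fit$fit, "session", lmer.df = "satterthwaite")
  ctr <- summary(emmeans::contrast(emm, "revpairwise", adjust = "tukey"),
                 infer = c(TRUE, TRUE))
  sdv <- sqrt(total_var)
  est <- ctr$estimate[1]
  se <- ctr$SE[1]
  dfree <- ctr$df[1]
  half <- stats::qt(0.975, dfree) * se
  structure(list(
    outcome = fit$outcome,
    contrast = as.character(ctr$contrast[1]),
    estimate = est, se = se, df = dfree,
    p_tukey = ctr$p.value[1],
    cohen_d = est / sdv,
    ci95 = c((est - half) / sdv, (est + half) / sdv),
    standardiser = "sqrt(random-intercept variance + residual variance)"
  ), class = "posthoc_result")
}

#' Region-wise session-effect map
#'
#' Fits, per region, a repeated-measures model of the regional DCC on
#' session, age, sex, CPZ equivalents, trainings and group with a
#' per-subject random intercept, and returns the session statistic map.
#' `reduction_stat` negates the follow-up-minus-baseline t-value so that
#' positive values mark regions whose dysconnectivity fell — the map that
#' feeds the transcriptomic analysis.
#'
#' @param baseline,followup Subjects-by-regions DCC matrices.
#' @param covariates Data frame with `subject`, `age`, `sex`, `cpz`,
#'   `trainings`, `group`.
#' @return Data frame: `region`, `statistic` (session t), `p`,
#'   `reduction_stat`.
#' @export
session_effect_map <- function(baseline, followup, covariates) {
  stopifnot(identical(dimnames(baseline), dimnames(followup)))
  subs <- rownames(baseline)
  miss <- setdiff(subs, covariates$subject)
  if (length(miss)) stop("covariates missing for: ",
                         paste(miss, collapse = ", "))
  cv <- covariates[match(subs, covariates$subject), , drop = FALSE]
  long0 <- data.frame(
    subject = rep(subs, 2),
    session = factor(rep(c("baseline", "followup"), each = length(subs)),
                     levels = c("baseline", "followup")),
    rbind(cv[setdiff(names(cv), "subject")],
          cv[setdiff(names(cv), "subject")]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  check_full_rank(long0)
  out <- lapply(colnames(baseline), function(rg) {
    long0$dcc <- c(baseline[, rg], followup[, rg])
    f <- lmm_formula(long0, response = "dcc")
    fitr <- suppressMessages(suppressWarnings(
      lmerTest::lmer(f, data = long0, REML = TRUE,
                     control = lme4::lmerControl(
                       check.conv.singular = lme4::.makeCC(
                         action = "ignore", tol = 1e-4)))))
    co <- stats::coef(summary(fitr))
    srow <- grep("^session", rownames(co))
    data.frame(region = rg, statistic = co[srow, "t value"],
               p = co[srow, "Pr(>|t|)"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$reduction_stat <- -out$statistic
  rownames(out) <- NULL
  out
}

check_full_rank <- function(df) {
  covs <- intersect(c("session", "age", "sex", "cpz", "trainings", "group"),
                    names(df))
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(covs, collapse = "+"))), df)
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    aliased <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop("design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  invisible(TRUE)
}

#' Region-wise regression of clinical change on DCC change
#'
#' For every region and clinical outcome, fits ordinary least squares of
#' the subject-level clinical change score (positive = improvement) on the
#' region's DCC change (positive = reduction), controlling for age, sex
#' and CPZ equivalents. Returns the regression weight and p-value per
#' region, plus the weight thresholded at an unadjusted p < 0.05 — a
#' deliberately descriptive map; set `fdr = TRUE` for a
#' Benjamini-Hochberg-thresholded variant.
#'
#' @param changes Subjects-by-regions matrix of DCC change
#'   (positive = reduction), e.g. [dcc_change_map()] output.
#' @param clinical Data frame with `subject` and one column per outcome
#'   (any of `GAF`, `PANSS`, `cognition`).
#' @param covariates Data frame with `subject`, `age`, `sex`, `cpz`.
#' @param p_threshold Threshold for the descriptive beta map.
#' @param fdr Apply BH correction across regions before thresholding.
#' @return Data frame: `outcome`, `region`, `beta`, `p`, `beta_thresholded`
#'   (`NA` where not below threshold).
#' @export
voxelwise_clinical_regression <- function(changes, clinical, covariates,
                                          p_threshold = 0.05, fdr = FALSE) {
  stopifnot(is.matrix(changes))
  outcomes <- intersect(c("GAF", "PANSS", "cognition"), names(clinical))
  if (!length(outcomes)) stop("clinical table has no recognised outcomes")
  df <- merge(clinical, covariates[, c("subject", "age", "sex", "cpz")],
              by = "subject", sort = FALSE)
  df <- df[match(rownames(changes), df$subject), , drop = FALSE]
  if (anyNA(df$subject)) stop("clinical/covariate rows missing for subjects")
  n <- nrow(df)
  if (n <= 3 + 2) stop("need more subjects than covariates + 2")
  res <- list()
  for (oc in outcomes) {
    y <- df[[oc]]
    for (rg in colnames(changes)) {
      dat <- data.frame(y = y, x = changes[, rg], age = df$age,
                        sex = df$sex, cpz = df$cpz)
      fit <- stats::lm(y ~ x + age + sex + cpz, data = dat)
      co <- stats::coef(summary(fit))
      res[[length(res) + 1]] <- data.frame(
        outcome = oc, region = rg, beta = co["x", "Estimate"],
        p = co["x", "Pr(>|t|)"], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, res)
  res$beta_thresholded <- NA_real_
  for (oc in outcomes) {
    idx <- which(res$outcome == oc)
    pv <- if (fdr) fdr_bh(res$p[idx]) else res$p[idx]
    keep <- idx[pv < p_threshold]
    res$beta_thresholded[keep] <- res$beta[keep]
  }
  rownames(res) <- NULL
  res
}
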