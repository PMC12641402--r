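#' Fit the healthy reference norm
#'
#' Estimates, per hemisphere and per connection, the mean and standard
#' deviation of Fisher-z connectivity across the reference cohort. A
#' connection of a new subject is later classified as dysconnected when its
#' Fisher-z value deviates from the reference mean by more than
#' `threshold_k` reference SDs (two-sided).
#'
#' With a finite reference cohort the naive `k`-SD rule flags slightly more
#' than the nominal Gaussian fraction \eqn{2\Phi(-k)}, because both the
#' mean and the SD are estimated. When `calibrate = TRUE` (default) the
#' stored threshold is widened to
#' \eqn{k_{\mathrm{eff}} = \sqrt{1 + 1/n}\; t^{-1}_{n-1}(\Phi(k))}, which
#' makes the expected flag rate of a held-out subject from the reference
#' population exactly \eqn{2\Phi(-k)} under Gaussian deviations; as
#' \eqn{n \to \infty}, \eqn{k_{\mathrm{eff}} \to k}.
#'
#' @param ref_mats List over reference subjects; each element a list with
#'   `L` and `R` Fisher-z matrices (as from [fisher_z_connectivity()]),
#'   identical region order across subjects.
#' @param threshold_k Nominal deviation threshold in reference SDs
#'   (default 2).
#' @param sd_floor Connections whose reference SD falls below this floor
#'   get the floor instead (default 1e-6), keeping the rule defined for
#'   degenerate reference sets.
#' @param calibrate Apply the finite-reference threshold calibration
#'   described above (default `TRUE`).
#' @return An object of class `reference_norm`: per hemisphere `mu` and
#'   `sigma` matrices, plus `threshold_k`, `threshold_k_eff`, `sd_floor`,
#'   `n_reference`, `calibrated`.
#' @examples
#' mats <- replicate(12, {
#'   z <- matrix(rnorm(16, sd = 0.1), 4, 4); z <- (z + t(z)) / 2; diag(z) <- 0
#'   dimnames(z) <- list(paste0("L", 1:4), paste0("L", 1:4))
#'   list(L = z, R = `dimnames<-`(z, list(paste0("R", 1:4), paste0("R", 1:4))))
#' }, simplify = FALSE)
#' norm <- fit_reference_norm(mats)
#' norm$threshold_k_eff
#' @export
fit_reference_norm <- function(ref_mats, threshold_k = 2, sd_floor = 1e-6,
                               calibrate = TRUE) {
  stopifnot(length(ref_mats) >= 2, threshold_k > 0, sd_floor > 0)
  n <- length(ref_mats)
  out <- list()
  for (h in c("L", "R")) {
    ids <- colnames(ref_mats[[1]][[h]])
    bad <- which(!vapply(ref_mats, function(m) {
      identical(colnames(m[[h]]), ids)
    }, logical(1)))
    if (length(bad)) {
      stop("reference subjects with mismatched region sets (hemisphere ",
           h, "): ", paste(bad, collapse = ", "))
    }
    stack <- vapply(ref_mats, function(m) m[[h]], ref_mats[[1]][[h]])
    mu <- apply(stack, c(1, 2), mean)
    sigma <- apply(stack, c(1, 2), stats::sd)
    sigma[sigma < sd_floor] <- sd_floor
    dimnames(mu) <- dimnames(sigma) <- dimnames(ref_mats[[1]][[h]])
    out[[h]] <- list(mu = mu, sigma = sigma)
  }
  k_eff <- if (calibrate) {
    sqrt(1 + 1 / n) * stats::qt(stats::pnorm(threshold_k), df = n - 1)
  } else {
    threshold_k
  }
  structure(c(out, list(threshold_k = threshold_k,
                        threshold_k_eff = k_eff,
                        sd_floor = sd_floor, n_reference = n,
                        calibrated = calibrate)),
            class = "reference_norm")
}

#' Classify dysconnected connections for one subject
#'
#' Flags every within-hemisphere connection whose Fisher-z value deviates
#' from the reference mean by more than the norm's (calibrated) threshold
#' times the reference SD. The diagonal is never flagged.
#'
#' @param z Symmetric Fisher-z matrix for one hemisphere.
#' @param norm A [fit_reference_norm()] object.
#' @param hemisphere `"L"` or `"R"`.
#' @return Symmetric logical matrix, same dimnames as `z`.
#' @export
dysconnection_mask <- function(z, norm, hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(inherits(norm, "reference_norm"))
  ref <- norm[[hemisphere]]
  if (!identical(dim(z), dim(ref$mu)) ||
      !identical(colnames(z), colnames(ref$mu))) {
    stop("matrix and norm must share region order (hemisphere ",
         hemisphere, ")")
  }
  mask <- abs(z - ref$mu) > norm$threshold_k_eff * ref$sigma
  diag(mask) <- FALSE
  mask
}

#' Dysconnectivity count (DCC) per region
#'
#' Counts, for every region, the incident flagged connections of a
#' symmetric dysconnection mask (each flagged pair contributes once to each
#' of its two endpoint regions).
#'
#' @param mask Symmetric logical (or 0/1) region-by-region matrix.
#' @return Named non-negative integer vector over regions.
#' @export
dcc_map <- function(mask) {
  mask <- as.matrix(mask)
  if (!isSymmetric(unname(mask * 1))) {
    stop("dysconnection mask must be symmetric")
  }
  rs <- rowSums(mask != 0)
  storage.mode(rs) <- "integer"
  rs
}

#' Whole-brain dysconnectivity index for one hemisphere
#'
#' The sum of a hemisphere's regional DCC values normalised by the number
#' of regions in that hemisphere.
#'
#' @param dcc Named integer vector from [dcc_map()].
#' @param n_regions Hemisphere size used as the normaliser; defaults to
#'   `length(dcc)`.
#' @return A single non-negative number.
#' @examples
#' whole_brain_dci(c(a = 2L, b = 1L, c = 1L), n_regions = 3)
#' @export
whole_brain_dci <- function(dcc, n_regions = length(dcc)) {
  stopifnot(n_regions > 0)
  if (n_regions < length(dcc)) stop("n_regions smaller than the DCC map")
  sum(dcc) / n_regions
}

#' Define a seed scope for the specific DCI
#'
#' @param name Scope label (e.g. `"default-mode"` or
#'   `"thalamus:middle-frontal"`).
#' @param regions_a,regions_b Character vectors of region ids; use
#'   `regions_b = regions_a` (the default) for a within-network scope.
#' @return An object of class `seed_definition`.
#' @export
seed_definition <- function(name, regions_a, regions_b = regions_a) {
  stopifnot(length(regions_a) >= 1, length(regions_b) >= 1)
  structure(list(name = name, regions_a = unique(as.character(regions_a)),
                 regions_b = unique(as.character(regions_b))),
            class = "seed_definition")
}

#' Specific DCI within a seed scope
#'
#' Restricts the dysconnection mask to connections with one end in
#' `regions_a` and the other in `regions_b`, counts the restricted DCC over
#' the scope's regions, and normalises by the number of scope regions
#' present in the hemisphere. With both region sets equal to the whole
#' hemisphere this reproduces the whole-brain DCI.
#'
#' @param z Fisher-z matrix for one hemisphere.
#' @param norm A [fit_reference_norm()] object.
#' @param hemisphere `"L"` or `"R"`.
#' @param seed A [seed_definition()].
#' @return A single non-negative number.
#' @export
specific_dci <- function(z, norm, hemisphere, seed) {
  stopifnot(inherits(seed, "seed_definition"))
  mask <- dysconnection_mask(z, norm, hemisphere)
  ids <- colnames(mask)
  a <- intersect(seed$regions_a, ids)
  b <- intersect(seed$regions_b, ids)
  if (!length(a) || !length(b)) {
    stop("seed '", seed$name, "' has no regions in hemisphere ", hemisphere)
  }
  sel <- matrix(FALSE, nrow(mask), ncol(mask), dimnames = dimnames(mask))
  sel[a, b] <- TRUE
  sel[b, a] <- TRUE
  diag(sel) <- FALSE
  if (!any(sel)) {
    stop("seed '", seed$name, "' yields an empty connection set")
  }
  restricted <- mask & sel
  scope <- union(a, b)
  sum(restricted[scope, , drop = FALSE]) / length(scope)
}

#' Longitudinal DCC change map, standardised across participants
#'
#' Standardises every region's DCC across all participants (pooling both
#' sessions) and returns, per subject and region, the standardised baseline
#' value minus the standardised follow-up value, so that
#' \emph{positive change = reduction in dysconnectivity}.
#'
#' @param baseline,followup Subjects-by-regions numeric matrices of DCC
#'   values with matching dimnames.
#' @param pool_sessions Standardise over both sessions pooled (default)
#'   or per session.
#' @return Subjects-by-regions matrix; `attr(, "convention")` records the
#'   sign convention. Regions with zero pooled SD yield 0 change.
#' @examples
#' b <- matrix(c(4, 2, 6, 2), 2, 2, dimnames = list(c("s1", "s2"), c("r1", "r2")))
#' f <- matrix(c(1, 1, 5, 3), 2, 2, dimnames = dimnames(b))
#' dcc_change_map(b, f)
#' @export
dcc_change_map <- function(baseline, followup, pool_sessions = TRUE) {
  stopifnot(is.matrix(baseline), is.matrix(followup))
  if (!identical(dimnames(baseline), dimnames(followup))) {
    stop("baseline and followup must cover the same subjects and regions")
  }
  if (pool_sessions) {
    pooled <- rbind(baseline, followup)
    mu <- colMeans(pooled)
    sdv <- apply(pooled, 2, stats::sd)
    sdv[sdv == 0] <- 1
    zb <- sweep(sweep(baseline, 2, mu), 2, sdv, "/")
    zf <- sweep(sweep(followup, 2, mu), 2, sdv, "/")
  } else {
    std <- function(m) {
      sdv <- apply(m, 2, stats::sd)
      sdv[sdv == 0] <- 1
      sweep(sweep(m, 2, colMeans(m)), 2, sdv, "/")
    }
    zb <- std(baseline)
    zf <- std(followup)
  }
  out <- zb - zf
  attr(out, "convention") <- "positive = reduction in dysconnectivity"
  out
}

#' Connectivity matrices for every subject of a synthetic study
#'
#' Convenience wrapper running [fisher_z_connectivity()] (optionally after
#' [preprocess_bold()]) over the reference and patient series of a
#' [generate_cohort()] study.
#'
#' @param study A `synthetic_study`.
#' @param preprocess Apply the standard cleaning first (default `FALSE`:
#'   the generator's frames are already stationary and exchangeable).
#' @return List with `reference` (list over subjects) and `patients`
#'   (per subject, per session), each element a list of `L`/`R` Fisher-z
#'   matrices.
#' @export
study_connectivity <- function(study, preprocess = FALSE) {
  stopifnot(inherits(study, "synthetic_study"))
  meta <- study$spec$meta
  conn <- function(ts) {
    if (preprocess) {
      ts <- preprocess_bold(ts, tr_seconds = study$spec$tr_seconds)
    }
    fisher_z_connectivity(ts, meta)
  }
  list(
    reference = lapply(study$reference, conn),
    patients = lapply(study$patients, function(p) lapply(p, conn))
  )
}

#' The thirteen default dysconnectivity scopes
#'
#' Whole brain, the eight canonical networks, and four seed scopes:
#' thalamus to middle frontal gyrus, thalamus to somatomotor network,
#' hippocampal formation to prefrontal cortex, and within the hippocampal
#' formation.
#'
#' @param meta Region metadata with `region_id` and `network` columns.
#' @return Named list of [seed_definition()]s (the whole-brain scope is a
#'   seed over all regions).
#' @export
default_seed_definitions <- function(meta) {
  by_net <- function(nets) meta$region_id[meta$network %in% nets]
  networks <- c("visual", "somatomotor", "limbic", "frontoparietal",
                "default-mode", "dorsal-attention", "salience",
                "subcortical")
  seeds <- list(
    `whole-brain` = seed_definition("whole-brain", meta$region_id)
  )
  for (nw in networks) {
    seeds[[nw]] <- seed_definition(nw, by_net(nw))
  }
  seeds[["thalamus:middle-frontal"]] <-
    seed_definition("thalamus:middle-frontal", by_net("thalamus"),
                    by_net("middle-frontal"))
  seeds[["thalamus:somatomotor"]] <-
    seed_definition("thalamus:somatomotor", by_net("thalamus"),
                    by_net("somatomotor"))
  seeds[["hippocampal-formation:prefrontal"]] <-
    seed_definition("hippocampal-formation:prefrontal",
                    by_net("hippocampal-formation"), by_net("prefrontal"))
  seeds[["hippocampal-formation"]] <-
    seed_definition("hippocampal-formation", by_net("hippocampal-formation"))
  seeds
}

#' Assemble the longitudinal DCI table for the mixed-model battery
#'
#' Scores every patient session against the reference norm and produces a
#' tidy table of DCI values per subject, session, hemisphere and scope,
#' joined with the patient covariates.
#'
#' @param patient_mats `patients` element of [study_connectivity()].
#' @param norm A [fit_reference_norm()] object.
#' @param covariates Data frame with `subject`, `age`, `sex`, `cpz`,
#'   `trainings`, `group`.
#' @param seeds Named list of [seed_definition()]s; defaults must be
#'   supplied by the caller via [default_seed_definitions()].
#' @return Data frame with columns `subject`, `session`, `hemisphere`,
#'   `scope`, `dci` plus the covariates; `session` and `hemisphere` are
#'   factors with baseline / left as reference levels.
#' @export
dci_longitudinal_table <- function(patient_mats, norm, covariates, seeds) {
  rows <- list()
  for (id in names(patient_mats)) {
    for (sess in names(patient_mats[[id]])) {
      for (h in c("L", "R")) {
        z <- patient_mats[[id]][[sess]][[h]]
        for (sc in names(seeds)) {
          dci <- specific_dci(z, norm, h, seeds[[sc]])
          rows[[length(rows) + 1]] <- data.frame(
            subject = id, session = sess, hemisphere = h, scope = sc,
            dci = dci, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$session <- factor(out$session, levels = c("baseline", "followup"))
  out$hemisphere <- factor(out$hemisphere, levels = c("L", "R"))
  merge(out, covariates, by = "subject", sort = FALSE)
}

#' Per-region DCC tables for both sessions
#'
#' @param patient_mats `patients` element of [study_connectivity()].
#' @param norm A [fit_reference_norm()] object.
#' @return List with `baseline` and `followup` subjects-by-regions DCC
#'   matrices (columns ordered left then right hemisphere).
#' @export
study_dcc <- function(patient_mats, norm) {
  one <- function(id, sess) {
    m <- patient_mats[[id]][[sess]]
    unlist(lapply(c("L", "R"), function(h) {
      dcc_map(dysconnection_mask(m[[h]], norm, h))
    }))
  }
  ids <- names(patient_mats)
  out <- lapply(c(baseline = "baseline", followup = "followup"),
                function(sess) {
    t(vapply(ids, one, numeric(length(one(ids[1], sess))), sess = sess))
  })
  out
}
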