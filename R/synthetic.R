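#' Canonical network labels used by the synthetic cohort
#'
#' Eight large-scale resting-state networks plus four region groups
#' (hippocampal formation, prefrontal cortex, thalamus, middle frontal
#' gyrus) that together define the thirteen dysconnectivity scopes the
#' longitudinal battery analyses (whole brain, eight networks, four
#' region-pair or within-region seeds).
#'
#' @return Character vector of twelve labels.
#' @export
dysconn_networks <- function() {
  c("visual", "somatomotor", "limbic", "frontoparietal", "default-mode",
    "dorsal-attention", "salience", "subcortical",
    "hippocampal-formation", "prefrontal", "thalamus", "middle-frontal")
}

#' Specify a synthetic two-hemisphere cohort
#'
#' Describes the dimensions and the generative connectivity structure of a
#' synthetic study: a healthy reference cohort and a patient cohort measured
#' at baseline and follow-up. Regions are split into left and right
#' hemispheres, each region carries one network label and a 3-D coordinate,
#' and the population connectivity of each hemisphere is a block
#' correlation matrix with stronger within-network than between-network
#' coupling. Individual subjects deviate from this population matrix by a
#' smooth, trait-like perturbation whose typical per-connection magnitude on
#' the Fisher-z scale is `subject_sd` (see Details).
#'
#' @details Between-subject heterogeneity is generated as
#' `cov2cor((I + E) %*% S %*% t(I + E))` with `E` a matrix of independent
#' Gaussian entries, which guarantees a valid correlation matrix for every
#' subject. The entry scale of `E` is chosen so that the standard deviation
#' of the induced per-connection deviation is approximately `subject_sd`;
#' the reference norm later estimates the realised per-connection spread
#' empirically, so only the order of magnitude matters. The perturbation is
#' drawn once per subject and held fixed across sessions, making individual
#' connectomes stable traits on which session effects are planted; when the
#' two hemispheres have equal size the perturbation is also shared between
#' them, emulating the dominantly homotopic (bilaterally symmetric)
#' organisation of individual connectivity deviations — and keeping a
#' single per-subject random intercept a correctly specified model for the
#' resulting DCI tables.
#'
#' @param n_reference Number of healthy reference subjects.
#' @param n_patients Number of patients (each measured at baseline and
#'   follow-up).
#' @param n_regions_left,n_regions_right Regions per hemisphere. Their sum
#'   must be at least 20.
#' @param n_timepoints Frames per acquisition.
#' @param tr_seconds Repetition time in seconds.
#' @param networks Character vector of network labels cycled over regions
#'   within each hemisphere.
#' @param r_within,r_between Population correlation within / between
#'   networks used to build the default block covariance.
#' @param subject_sd Typical between-subject SD of a connection on the
#'   Fisher-z scale (0 disables heterogeneity).
#' @param noise_sd Standard deviation of each region's signal. The scale is
#'   shared across regions so correlations are unaffected.
#' @param base_covariance Optional list with elements `L` and `R`: custom
#'   population correlation matrices (unit diagonal, positive definite).
#' @param meta Optional region metadata data frame overriding the generated
#'   one; must have columns `region_id`, `hemisphere`, `network`,
#'   `x`, `y`, `z`, `parcel_id`.
#'
#' @return An object of class `cohort_spec`: a list with the arguments
#'   above plus `meta` (region metadata) and `base_covariance`.
#' @examples
#' spec <- cohort_spec(n_reference = 10, n_patients = 4,
#'                     n_regions_left = 24, n_regions_right = 24,
#'                     n_timepoints = 120)
#' table(spec$meta$network, spec$meta$hemisphere)
#' @export
cohort_spec <- function(n_reference = 40, n_patients = 12,
                        n_regions_left = 60, n_regions_right = 60,
                        n_timepoints = 300, tr_seconds = 2,
                        networks = dysconn_networks(),
                        r_within = 0.35, r_between = 0.10,
                        subject_sd = 0.1, noise_sd = 1,
                        base_covariance = NULL, meta = NULL) {
  stopifnot(n_reference >= 1, n_patients >= 0,
            n_timepoints >= 2, tr_seconds > 0,
            subject_sd >= 0, noise_sd > 0)
  if (n_regions_left + n_regions_right < 20) {
    stop("at least 20 regions are required across the two hemispheres")
  }
  if (is.null(meta)) {
    meta <- build_region_meta(n_regions_left, n_regions_right, networks)
  } else {
    required <- c("region_id", "hemisphere", "network", "x", "y", "z",
                  "parcel_id")
    missing <- setdiff(required, names(meta))
    if (length(missing)) {
      stop("meta is missing columns: ", paste(missing, collapse = ", "))
    }
  }
  spec <- structure(list(
    n_reference = n_reference, n_patients = n_patients,
    n_regions_left = n_regions_left, n_regions_right = n_regions_right,
    n_timepoints = n_timepoints, tr_seconds = tr_seconds,
    subject_sd = subject_sd, noise_sd = noise_sd,
    meta = meta
  ), class = "cohort_spec")
  if (is.null(base_covariance)) {
    base_covariance <- lapply(split_regions(meta), function(idx) {
      S <- block_correlation(meta$network[idx], r_within, r_between)
      dimnames(S) <- list(meta$region_id[idx], meta$region_id[idx])
      S
    })
  }
  for (h in c("L", "R")) {
    S <- base_covariance[[h]]
    if (!isSymmetric(unname(S)) || any(abs(diag(S) - 1) > 1e-8)) {
      stop("base covariance for hemisphere ", h,
           " must be symmetric with unit diagonal")
    }
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("base covariance for hemisphere ", h,
           " is not positive definite")
    }
  }
  spec$base_covariance <- base_covariance
  spec
}

# Relative region shares of the twelve labels, mirroring the strongly
# unequal footprint of resting-state networks on the cortex (default-mode
# largest, sensory networks next, focal region groups smallest).
network_shares <- function(networks) {
  shares <- c("visual" = 8, "somatomotor" = 8, "limbic" = 4,
              "frontoparietal" = 6, "default-mode" = 10,
              "dorsal-attention" = 5, "salience" = 5, "subcortical" = 4,
              "hippocampal-formation" = 2, "prefrontal" = 4,
              "thalamus" = 2, "middle-frontal" = 2)
  out <- shares[networks]
  out[is.na(out)] <- 1
  names(out) <- networks
  out
}

# Region metadata: ids, hemisphere, network label, coordinates, parcel.
# Networks are laid out at separate spatial centroids (mirrored across
# hemispheres) so that network-level statistical maps are spatially smooth,
# which the variogram-surrogate machinery downstream relies on. Region
# counts per network follow network_shares(), scaled to the hemisphere
# size with every network kept non-empty.
build_region_meta <- function(n_left, n_right, networks) {
  centroids <- network_centroids(length(networks))
  one_hemi <- function(n, hemi) {
    if (n < length(networks)) {
      net <- networks[seq_len(n)]
    } else {
      shares <- network_shares(networks)
      counts <- pmax(1, floor(shares / sum(shares) * n))
      # distribute the remainder by largest fractional share
      while (sum(counts) < n) {
        frac <- shares / sum(shares) * n - counts
        counts[which.max(frac)] <- counts[which.max(frac)] + 1
      }
      while (sum(counts) > n) {
        over <- which(counts > 1)
        counts[over[which.max(counts[over])]] <-
          counts[over[which.max(counts[over])]] - 1
      }
      net <- rep(networks, times = counts)
    }
    idx_in_net <- stats::ave(seq_len(n), net, FUN = seq_along)
    offs <- region_offsets(max(idx_in_net))
    ci <- match(net, networks)
    x <- centroids[ci, 1] + offs[idx_in_net, 1]
    x <- if (hemi == "L") -abs(x + 40) else abs(x + 40)
    data.frame(
      region_id = sprintf("%s%03d", hemi, seq_len(n)),
      hemisphere = hemi,
      network = net,
      x = x,
      y = centroids[ci, 2] + offs[idx_in_net, 2],
      z = centroids[ci, 3] + offs[idx_in_net, 3],
      parcel_id = sprintf("%s%03d", hemi, seq_len(n)),
      stringsAsFactors = FALSE
    )
  }
  rbind(one_hemi(n_left, "L"), one_hemi(n_right, "R"))
}

network_centroids <- function(k) {
  g <- expand.grid(x = c(0, 28), y = seq(-70, 70, length.out = 3),
                   z = c(10, 52))
  as.matrix(g[rep_len(seq_len(nrow(g)), k), , drop = FALSE])
}

region_offsets <- function(k) {
  g <- as.matrix(expand.grid(dx = c(-6, 0, 6), dy = c(-6, 0, 6),
                             dz = c(-6, 0, 6)))
  g[rep_len(seq_len(nrow(g)), k), , drop = FALSE]
}

split_regions <- function(meta) {
  list(L = which(meta$hemisphere == "L"), R = which(meta$hemisphere == "R"))
}

block_correlation <- function(network, r_within, r_between) {
  same <- outer(network, network, "==")
  S <- ifelse(same, r_within, r_between)
  diag(S) <- 1
  S
}

#' Describe a planted dysconnectivity effect
#'
#' Defines a ground-truth perturbation of patient connectivity: an additive
#' shift on the Fisher-z scale applied to a set of within-hemisphere
#' connections at baseline, of which a fraction `attenuation` is removed at
#' follow-up. `attenuation = 1` restores the unshifted connectome;
#' `attenuation = 0` leaves the effect untouched.
#'
#' @param target Either a network label or a two-column matrix/data frame
#'   of region-id pairs; each pair must lie within one hemisphere.
#' @param baseline_shift Additive Fisher-z shift at baseline (magnitude).
#' @param attenuation Fraction of the shift removed at follow-up, in
#'   \eqn{[0, 1]}.
#' @param direction `"hyper"` (connectivity pushed up) or `"hypo"`
#'   (pushed down).
#' @param scope For a network target: `"within"` (default) shifts the
#'   connections joining two regions of the network; `"incident"` shifts
#'   every within-hemisphere connection with at least one endpoint in the
#'   network. Large incident shifts can violate correlation geometry (a
#'   few regions cannot all correlate strongly with many mutually weak
#'   ones) and will trigger logged positive-definiteness repairs; keep
#'   incident shifts small. Ignored for an explicit pair target.
#' @return An object of class `planted_effect`.
#' @examples
#' planted_effect("default-mode", baseline_shift = 0.5, attenuation = 0.6)
#' @export
planted_effect <- function(target, baseline_shift, attenuation,
                           direction = c("hyper", "hypo"),
                           scope = c("within", "incident")) {
  direction <- match.arg(direction)
  scope <- match.arg(scope)
  stopifnot(is.numeric(baseline_shift), length(baseline_shift) == 1)
  if (!is.numeric(attenuation) || attenuation < 0 || attenuation > 1) {
    stop("attenuation must lie in [0, 1]")
  }
  structure(list(target = target, baseline_shift = abs(baseline_shift),
                 attenuation = attenuation, direction = direction,
                 scope = scope),
            class = "planted_effect")
}

# Resolve an effect's target to a data frame of within-hemisphere
# region-id pairs.
resolve_effect_connections <- function(effect, meta) {
  tgt <- effect$target
  if (is.character(tgt) && length(tgt) == 1) {
    if (!tgt %in% meta$network) {
      stop("unknown network label in planted effect: ", tgt)
    }
    pairs <- do.call(rbind, lapply(c("L", "R"), function(h) {
      in_h <- meta$hemisphere == h
      ids <- meta$region_id[in_h & meta$network == tgt]
      if (!length(ids)) return(NULL)
      if (identical(effect$scope, "within")) {
        if (length(ids) < 2) return(NULL)
        cmb <- utils::combn(ids, 2)
        return(data.frame(region_a = cmb[1, ], region_b = cmb[2, ],
                          hemisphere = h, stringsAsFactors = FALSE))
      }
      all_ids <- meta$region_id[in_h]
      cmb <- utils::combn(all_ids, 2)
      keep <- cmb[1, ] %in% ids | cmb[2, ] %in% ids
      data.frame(region_a = cmb[1, keep], region_b = cmb[2, keep],
                 hemisphere = h, stringsAsFactors = FALSE)
    }))
  } else {
    tgt <- as.data.frame(tgt, stringsAsFactors = FALSE)
    if (ncol(tgt) < 2) stop("explicit target must have two columns")
    ha <- meta$hemisphere[match(tgt[[1]], meta$region_id)]
    hb <- meta$hemisphere[match(tgt[[2]], meta$region_id)]
    if (anyNA(ha) || anyNA(hb)) stop("unknown region id in planted effect")
    if (any(ha != hb)) {
      stop("planted connections must lie within one hemisphere")
    }
    pairs <- data.frame(region_a = tgt[[1]], region_b = tgt[[2]],
                        hemisphere = ha, stringsAsFactors = FALSE)
  }
  if (is.null(pairs) || !nrow(pairs)) {
    stop("planted effect resolves to no connections")
  }
  pairs
}

#' Generate a synthetic reference + patient study
#'
#' Draws a healthy reference cohort and a patient cohort (baseline and
#' follow-up sessions) of region-by-time BOLD-like series. Each hemisphere's
#' series are stationary Gaussian with a subject-specific target correlation
#' matrix: the population block structure of `spec`, perturbed by a stable
#' per-subject deviation (see [cohort_spec()]), and — for patients — with
#' every planted connection's Fisher-z shifted by the effect's
#' `baseline_shift` at baseline and by `baseline_shift * (1 - attenuation)`
#' at follow-up. Shifts are applied on the Fisher-z scale and mapped back
#' through `tanh`, so shifted correlations are always valid; if a shifted
#' matrix loses positive definiteness it is repaired by eigenvalue clipping
#' and the repair is recorded in the returned `log`.
#'
#' Frames are drawn independently (no temporal autocorrelation) so that the
#' connectivity of the generated series has a closed-form target; pass the
#' result through [preprocess_bold()] if a filtered pipeline is being
#' exercised.
#'
#' @param spec A [cohort_spec()].
#' @param effects A [planted_effect()] or list of them. Empty list: patients
#'   and reference share the same generative distribution.
#' @param seed Integer seed; identical `(spec, effects, seed)` give
#'   bit-identical output.
#' @return An object of class `synthetic_study`: list with elements
#'   `spec`, `effects`, `reference` (list of timepoints-by-regions
#'   matrices), `patients` (per subject, list with `baseline` and
#'   `followup` matrices), `covariates` (per patient: `age`, `sex`, `cpz`,
#'   `trainings`, `group`), `truth` (resolved planted connections),
#'   `target_cov` (per subject and session, the exact target correlation
#'   matrices) and `log` (character vector of repair notes).
#' @examples
#' spec <- cohort_spec(n_reference = 6, n_patients = 2,
#'                     n_regions_left = 24, n_regions_right = 24,
#'                     n_timepoints = 80)
#' study <- generate_cohort(spec, planted_effect("default-mode", 0.5, 0.6),
#'                          seed = 1)
#' dim(study$patients[[1]]$baseline)
#' @export
generate_cohort <- function(spec, effects = list(), seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (inherits(effects, "planted_effect")) effects <- list(effects)
  if (!all(vapply(effects, inherits, logical(1), "planted_effect"))) {
    stop("effects must be planted_effect objects")
  }
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(as.integer(seed))

  meta <- spec$meta
  hemi_idx <- split_regions(meta)
  truth <- lapply(effects, function(e) {
    cbind(resolve_effect_connections(e, meta),
          shift = ifelse(e$direction == "hyper", 1, -1) * e$baseline_shift,
          attenuation = e$attenuation)
  })
  log_lines <- character(0)

  tau <- lapply(spec$base_covariance, function(S) {
    if (spec$subject_sd == 0) return(0)
    # first-order entry scale, then a fixed-point correction for the
    # shrinkage that cov2cor's diagonal renormalisation (E[diag] grows by
    # tau^2 * n) applies to the deviations
    n <- nrow(S)
    base <- spec$subject_sd / sqrt(2 * mean(diag(S %*% S)))
    tau <- base
    for (i in 1:3) tau <- base * (1 + tau^2 * n)
    tau
  })

  # One deviation matrix per subject, shared by both hemispheres when the
  # dimensions allow it: individual connectivity deviations are modelled
  # as bilaterally symmetric (homotopic) traits, so the subject random
  # intercept of the longitudinal model captures them fully
  share_hemis <- spec$n_regions_left == spec$n_regions_right
  draw_subject_E <- function() {
    if (spec$subject_sd == 0) return(NULL)
    if (share_hemis) {
      n <- spec$n_regions_left
      list(L = matrix(stats::rnorm(n * n, sd = tau[["L"]]), n, n))
    } else {
      lapply(c(L = "L", R = "R"), function(h) {
        n <- nrow(spec$base_covariance[[h]])
        matrix(stats::rnorm(n * n, sd = tau[[h]]), n, n)
      })
    }
  }
  subject_cov <- function(h, E) {
    S <- spec$base_covariance[[h]]
    if (is.null(E)) return(S)
    Eh <- if (share_hemis) E$L else E[[h]]
    M <- diag(nrow(S)) + Eh
    stats::cov2cor(M %*% S %*% t(M))
  }

  draw_series <- function(S) {
    n <- nrow(S)
    L <- chol(S)
    matrix(stats::rnorm(spec$n_timepoints * n), spec$n_timepoints, n) %*%
      L * spec$noise_sd
  }

  # patient covariates (drawn first so cohort sizes do not reorder them)
  covariates <- if (spec$n_patients > 0) {
    data.frame(
      subject = sprintf("sub%02d", seq_len(spec$n_patients)),
      age = sample(22:55, spec$n_patients, replace = TRUE),
      sex = factor(sample(c("F", "M"), spec$n_patients, replace = TRUE),
                   levels = c("F", "M")),
      cpz = round(stats::rlnorm(spec$n_patients, log(300), 0.5)),
      trainings = stats::rpois(spec$n_patients, 35),
      group = factor(rep_len(c("AET", "FSBT"), spec$n_patients),
                     levels = c("AET", "FSBT")),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(subject = character(0))
  }

  bind_hemis <- function(mats) {
    out <- cbind(mats$L, mats$R)
    colnames(out) <- c(meta$region_id[hemi_idx$L], meta$region_id[hemi_idx$R])
    out
  }

  reference <- vector("list", spec$n_reference)
  ref_cov <- vector("list", spec$n_reference)
  for (s in seq_len(spec$n_reference)) {
    E <- draw_subject_E()
    covs <- list(L = subject_cov("L", E), R = subject_cov("R", E))
    reference[[s]] <- bind_hemis(lapply(covs, draw_series))
    ref_cov[[s]] <- covs
  }

  patients <- list()
  pat_cov <- list()
  for (s in seq_len(spec$n_patients)) {
    id <- covariates$subject[s]
    E <- draw_subject_E()
    base_covs <- list(L = subject_cov("L", E), R = subject_cov("R", E))
    sess_cov <- list()
    sess_ts <- list()
    for (sess in c("baseline", "followup")) {
      covs <- base_covs
      for (h in c("L", "R")) {
        covs[[h]] <- apply_shifts_one(covs[[h]], h, truth, effects,
                                      sess, meta, hemi_idx,
                                      function(line) {
                                        log_lines <<- c(log_lines, line)
                                      }, id)
      }
      sess_cov[[sess]] <- covs
      sess_ts[[sess]] <- bind_hemis(lapply(covs, draw_series))
    }
    patients[[id]] <- sess_ts
    pat_cov[[id]] <- sess_cov
  }

  if (length(log_lines)) {
    message(length(log_lines), " covariance repair(s) applied; see $log")
  }
  structure(list(
    spec = spec, effects = effects, reference = reference,
    patients = patients, covariates = covariates,
    truth = truth,
    target_cov = list(reference = ref_cov, patients = pat_cov),
    log = log_lines
  ), class = "synthetic_study")
}

# Apply every planted effect to one hemisphere's matrix for one session.
apply_shifts_one <- function(S, h, truth, effects, session, meta, hemi_idx,
                             log_fun, subject_id) {
  ids <- meta$region_id[hemi_idx[[h]]]
  touched <- FALSE
  for (k in seq_along(truth)) {
    tr <- truth[[k]]
    scale <- if (session == "baseline") 1 else 1 - effects[[k]]$attenuation
    if (scale == 0) next
    rows <- which(tr$hemisphere == h)
    for (r in rows) {
      i <- match(tr$region_a[r], ids)
      j <- match(tr$region_b[r], ids)
      r0 <- S[i, j]
      if (abs(r0) >= 1) stop("shifted correlation outside (-1, 1)")
      S[i, j] <- S[j, i] <- tanh(atanh(r0) + tr$shift[r] * scale)
      touched <- TRUE
    }
  }
  if (touched) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) {
      S2 <- near_pd_correlation(S)
      log_fun(paste0("nearest-PD repair (", subject_id, ", ", session,
                     ", hemisphere ", h, "): min eigenvalue ",
                     signif(min(ev), 3), " clipped"))
      S <- S2
    }
  }
  S
}

# Eigenvalue clipping at 1e-8 followed by rescaling to unit diagonal.
near_pd_correlation <- function(S, floor = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  out <- e$vectors %*% (vals * t(e$vectors))
  stats::cov2cor(out)
}

#' Specify synthetic parcel-level gene expression
#'
#' Describes a parcel-by-gene expression matrix in which the genes of one
#' annotated cell-type set co-vary spatially with a target map while all
#' other genes are pure noise. Default gene sets mimic cell-type
#' annotations from single-nucleus studies: excitatory (Ex) and inhibitory
#' (In) neurons, astrocytes (Ast), oligodendrocytes (Oli), oligodendrocyte
#' precursor cells (OPC), microglia (Mic), endothelial cells (End),
#' pericytes (Per) and cerebellar variants (OPC_Cer, Ast_Cer).
#'
#' @param n_genes Total number of genes.
#' @param gene_sets Named list of gene-id vectors; `NULL` builds disjoint
#'   default sets of `set_size` genes each for the ten cell types.
#' @param planted_set Name of the set coupled to the target map.
#' @param coupling Spatial coupling strength in \eqn{[-1, 1]}: planted genes
#'   equal `coupling * standardised(map) + noise`.
#' @param noise_sd Noise SD for every gene.
#' @param set_size Genes per default set.
#' @return An object of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 2000, gene_sets = NULL,
                            planted_set = "Oli", coupling = 0.5,
                            noise_sd = 1, set_size = 150) {
  if (!is.numeric(coupling) || abs(coupling) > 1) {
    stop("coupling must lie in [-1, 1]")
  }
  stopifnot(noise_sd >= 0, n_genes >= 1)
  if (is.null(gene_sets)) {
    types <- c("Ex", "In", "Ast", "Oli", "OPC", "Mic", "End", "Per",
               "OPC_Cer", "Ast_Cer")
    if (n_genes < length(types) * set_size) {
      stop("n_genes too small for the default gene sets")
    }
    gene_sets <- lapply(setNames(types, types), function(tp) {
      sprintf("%s_%03d", tp, seq_len(set_size))
    })
  }
  if (any(!lengths(gene_sets))) stop("every gene set must be non-empty")
  if (!planted_set %in% names(gene_sets)) {
    stop("planted_set must name one of the gene sets")
  }
  structure(list(n_genes = n_genes, gene_sets = gene_sets,
                 planted_set = planted_set, coupling = coupling,
                 noise_sd = noise_sd),
            class = "expression_spec")
}

#' Generate parcel-by-gene expression with a planted spatial coupling
#'
#' Genes in the planted set equal `coupling * standardised(target_map)`
#' plus Gaussian noise; all other genes (set members or unannotated
#' filler) are pure noise. Stands in for donor-averaged atlas expression
#' parcellated to the analysis atlas.
#'
#' @param spec An [expression_spec()].
#' @param target_map Named numeric vector (names = parcel ids, length
#'   at least 20): the spatial map the planted set tracks.
#' @param seed Integer seed.
#' @return List with `expression` (parcels-by-genes matrix, dimnames set)
#'   and `gene_sets` (named list as in `spec`).
#' @examples
#' map <- setNames(rnorm(30), paste0("p", 1:30))
#' ex <- generate_expression(expression_spec(n_genes = 600, set_size = 40),
#'                           map, seed = 1)
#' dim(ex$expression)
#' @export
generate_expression <- function(spec, target_map, seed) {
  stopifnot(inherits(spec, "expression_spec"))
  if (length(target_map) < 20) {
    stop("target_map must cover at least 20 parcels")
  }
  if (is.null(names(target_map))) {
    names(target_map) <- sprintf("parcel%03d", seq_along(target_map))
  }
  set.seed(as.integer(seed))
  p <- length(target_map)
  set_genes <- unique(unlist(spec$gene_sets))
  n_fill <- spec$n_genes - length(set_genes)
  if (n_fill < 0) {
    stop("n_genes smaller than the number of annotated genes")
  }
  genes <- c(set_genes,
             if (n_fill > 0) sprintf("NONE_%04d", seq_len(n_fill)))
  expr <- matrix(stats::rnorm(p * length(genes), sd = spec$noise_sd),
                 nrow = p, dimnames = list(names(target_map), genes))
  planted <- spec$gene_sets[[spec$planted_set]]
  std_map <- as.numeric(scale(target_map))
  expr[, planted] <- expr[, planted] + spec$coupling * std_map
  list(expression = expr, gene_sets = spec$gene_sets)
}

#' Generate clinical change scores coupled to regional deviation change
#'
#' Builds per-subject change scores for the three clinical outcomes (GAF,
#' PANSS total, cognition composite) as weighted sums of each subject's
#' realised regional dysconnectivity change plus noise. All three change
#' scores follow the convention \emph{positive = improvement}; for GAF and
#' cognition that corresponds to follow-up minus baseline of the raw scale,
#' for PANSS to baseline minus follow-up.
#'
#' @param changes Subjects-by-regions numeric matrix of deviation change
#'   (positive = reduction in dysconnectivity), e.g. from
#'   [dcc_change_map()]; rownames are subject ids, colnames region ids.
#' @param meta Region metadata (for resolving network targets).
#' @param coupling Named list over scores (`GAF`, `PANSS`, `cognition`).
#'   Each element is a list with `target` (network label or vector of
#'   region ids) and `strength` (real). Scores without an entry are pure
#'   noise.
#' @param noise_sd Noise SD added to every score change.
#' @param seed Integer seed.
#' @return Data frame with columns `subject`, `GAF`, `PANSS`, `cognition`
#'   (all change scores, positive = improvement).
#' @export
generate_clinical <- function(changes, meta, coupling = list(),
                              noise_sd = 1, seed) {
  stopifnot(is.matrix(changes))
  set.seed(as.integer(seed))
  scores <- c("GAF", "PANSS", "cognition")
  bad <- setdiff(names(coupling), scores)
  if (length(bad)) stop("unknown score name(s): ", paste(bad, collapse = ", "))
  n <- nrow(changes)
  out <- data.frame(subject = rownames(changes), stringsAsFactors = FALSE)
  for (sc in scores) {
    signal <- numeric(n)
    cp <- coupling[[sc]]
    if (!is.null(cp)) {
      regions <- resolve_region_target(cp$target, meta)
      regions <- intersect(regions, colnames(changes))
      if (!length(regions)) stop("coupling target has no regions in changes")
      signal <- cp$strength *
        rowMeans(changes[, regions, drop = FALSE])
    }
    out[[sc]] <- signal + stats::rnorm(n, sd = noise_sd)
  }
  attr(out, "convention") <- "positive = improvement"
  out
}

resolve_region_target <- function(target, meta) {
  if (is.character(target) && length(target) == 1 &&
      target %in% meta$network) {
    return(meta$region_id[meta$network == target])
  }
  if (all(target %in% meta$region_id)) return(as.character(target))
  stop("coupling target must be a network label or region ids")
}
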