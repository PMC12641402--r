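# Shared fixtures and independent oracles for the test suite.

# Cache expensive fixtures across test files within one run.
.fixture_env <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Desk-scale study with the planted default-mode effect (baseline +0.5
# Fisher-z on within-network connections, 60% attenuated at follow-up),
# plus its connectivity, reference norm and seed scopes.
planted_fixture <- function() {
  with_cache("planted", {
    spec <- cohort_spec()
    eff <- planted_effect("default-mode", baseline_shift = 0.5,
                          attenuation = 0.6)
    study <- suppressMessages(generate_cohort(spec, effects = eff,
                                              seed = 1000))
    conn <- study_connectivity(study)
    norm <- fit_reference_norm(conn$reference, threshold_k = 2)
    list(spec = spec, effect = eff, study = study, conn = conn,
         norm = norm, seeds = default_seed_definitions(spec$meta))
  })
}

# Brute-force Benjamini-Hochberg step-up: for the hypothesis of rank r,
# q = min over j >= r of n * p_(j) / j, capped at 1. Written as literal
# loops, independent of stats::p.adjust.
bh_brute <- function(p) {
  n <- length(p)
  if (!n) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(n)
  for (r in seq_len(n)) {
    best <- Inf
    for (j in r:n) best <- min(best, n * ps[j] / j)
    q_sorted[r] <- min(1, best)
  }
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

# Brute-force weighted KS enrichment score: walk the full ranked list.
es_brute <- function(scores, in_set) {
  scores <- unname(scores)
  n <- length(scores)
  m <- sum(in_set)
  nr <- sum(abs(scores[in_set]))
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (in_set[i]) abs(scores[i]) / nr else -1 / (n - m)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Small longitudinal table with a known session effect, for mixed-model
# parameter-recovery checks.
sim_dci_table <- function(n_sub, sd_int, sd_res, delta,
                          hemis = c("L", "R")) {
  g <- rnorm(n_sub, 0, sd_int)
  rows <- expand.grid(subject = seq_len(n_sub),
                      session = c("baseline", "followup"),
                      hemisphere = hemis, stringsAsFactors = FALSE)
  rows$session <- factor(rows$session, levels = c("baseline", "followup"))
  rows$dci <- 5 + g[rows$subject] +
    ifelse(rows$session == "followup", delta, 0) +
    rnorm(nrow(rows), 0, sd_res)
  rows$subject <- sprintf("s%02d", rows$subject)
  rows
}

# Random smooth scalar field over given coordinates (linear gradient in a
# random direction plus white noise).
smooth_field <- function(coords, noise_sd = 0.45) {
  d <- rnorm(3)
  d <- d / sqrt(sum(d^2))
  f <- as.numeric(coords %*% d)
  f / sd(f) + rnorm(nrow(coords), 0, noise_sd)
}

random_coords <- function(p, seed = 77) {
  set.seed(seed)
  coords <- cbind(runif(p, 0, 100), runif(p, 0, 100), runif(p, 0, 100))
  rownames(coords) <- sprintf("p%03d", seq_len(p))
  coords
}

# Symmetric Fisher-z matrix helper for hand-built fixtures.
sym_z <- function(n, ids, fill = 0) {
  z <- matrix(fill, n, n, dimnames = list(ids, ids))
  diag(z) <- 0
  z
}
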