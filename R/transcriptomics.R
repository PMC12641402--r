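#' Parcellate a region-level map
#'
#' Averages region values within parcels and computes parcel centroids as
#' the mean of member-region coordinates. Parcels with no assigned region
#' are excluded with a warning.
#'
#' @param values Named numeric vector over regions.
#' @param assignment Named character vector mapping region id to parcel id
#'   (names = region ids); every region in `values` must be assigned.
#' @param coords Optional regions-by-3 coordinate matrix with region ids as
#'   rownames; when given, parcel centroids are returned.
#' @return An object of class `parcel_map`: list with `value` (named
#'   numeric over parcels) and `coords` (parcels-by-3 matrix or `NULL`).
#' @examples
#' v <- c(r1 = 1, r2 = 2, r3 = 3, r4 = 4)
#' a <- c(r1 = "A", r2 = "A", r3 = "B", r4 = "B")
#' parcellate(v, a)$value
#' @export
parcellate <- function(values, assignment, coords = NULL) {
  if (is.null(names(values))) stop("values must be named by region id")
  parc <- assignment[names(values)]
  if (anyNA(parc)) {
    stop("regions without parcel assignment: ",
         paste(names(values)[is.na(parc)], collapse = ", "))
  }
  empty <- setdiff(unique(assignment), parc)
  if (length(empty)) {
    warning("parcel(s) with no member regions excluded: ",
            paste(empty, collapse = ", "))
  }
  value <- tapply(values, parc, mean)
  value <- stats::setNames(as.numeric(value), names(value))
  centroid <- NULL
  if (!is.null(coords)) {
    coords <- as.matrix(coords[names(values), , drop = FALSE])
    centroid <- apply(coords, 2, function(cc) tapply(cc, parc, mean))
    centroid <- centroid[names(value), , drop = FALSE]
  }
  structure(list(value = value, coords = centroid), class = "parcel_map")
}

# Empirical variogram over precomputed pair bins:
# gamma(bin) = 0.5 * mean over pairs in bin of (x_i - x_j)^2.
pair_bins <- function(dists, n_bins) {
  n <- nrow(dists)
  ut <- which(upper.tri(dists))
  d <- dists[ut]
  breaks <- stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1))
  breaks[1] <- -Inf
  bin <- cut(d, breaks = unique(breaks), labels = FALSE)
  i <- row(dists)[ut]
  j <- col(dists)[ut]
  list(i = i, j = j, bin = bin, n_bins = max(bin))
}

variogram_from_bins <- function(x, pb) {
  sq <- 0.5 * (x[pb$i] - x[pb$j])^2
  as.numeric(tapply(sq, pb$bin, mean))
}

#' Variogram-matched spatial surrogate maps
#'
#' Generates randomised versions of a parcellated map that preserve its
#' value distribution exactly and approximate its spatial autocorrelation.
#' Each surrogate permutes the map, smooths the permuted values with
#' distance-decaying exponential kernels over a ladder of candidate
#' scales, keeps the scale whose empirical variogram is closest (least
#' squares over distance bins) to that of the original map, and finally
#' rank-remaps the smoothed values onto the original value multiset.
#'
#' @param map A [parcellate()] result with coordinates, or a named numeric
#'   vector plus `coords`.
#' @param n Number of surrogates (100 or more for inferential use).
#' @param seed Integer seed; surrogates are deterministic given the seed.
#' @param coords Parcels-by-3 coordinate matrix (ignored when `map` is a
#'   `parcel_map` carrying its own).
#' @param n_scales Number of candidate kernel scales (distance quantiles).
#' @param n_bins Distance bins for the variogram match.
#' @return An object of class `surrogate_ensemble`: list with `maps`
#'   (n-by-parcels matrix, each row one surrogate), `scales` (chosen scale
#'   per surrogate) and the generator parameters.
#' @export
variogram_surrogates <- function(map, n, seed, coords = NULL,
                                 n_scales = 8, n_bins = 10) {
  if (inherits(map, "parcel_map")) {
    coords <- map$coords
    values <- map$value
  } else {
    values <- map
  }
  if (is.null(coords)) stop("parcel coordinates are required")
  if (stats::sd(values) == 0) {
    stop("variogram undefined for a constant map")
  }
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  p <- length(values)
  dists <- as.matrix(stats::dist(coords))
  pb <- pair_bins(dists, n_bins)
  target <- variogram_from_bins(values, pb)
  scales <- stats::quantile(dists[upper.tri(dists)],
                            probs = seq(0.05, 0.95, length.out = n_scales))
  # row-normalised smoothing weights per candidate scale; scale index 0
  # (no smoothing, pure permutation) is always a candidate
  kernels <- lapply(scales, function(sc) {
    W <- exp(-dists / sc)
    W / rowSums(W)
  })
  sorted_vals <- sort(values)
  maps <- matrix(NA_real_, n, p, dimnames = list(NULL, names(values)))
  chosen <- numeric(n)
  for (s in seq_len(n)) {
    perm <- values[sample.int(p)]
    cand <- c(list(perm), lapply(kernels, function(W) {
      as.numeric(W %*% perm)
    }))
    sse <- vapply(cand, function(x) {
      remapped <- remap_ranks(x, sorted_vals)
      sum((variogram_from_bins(remapped, pb) - target)^2)
    }, numeric(1))
    best <- which.min(sse)
    maps[s, ] <- remap_ranks(cand[[best]], sorted_vals)
    chosen[s] <- if (best == 1) 0 else scales[best - 1]
  }
  structure(list(maps = maps, scales = chosen,
                 candidate_scales = as.numeric(scales),
                 n_bins = n_bins, seed = seed),
            class = "surrogate_ensemble")
}

# Replace x by the original value multiset, preserving x's ranks.
# Ties broken by first occurrence so the output multiset is exact.
remap_ranks <- function(x, sorted_vals) {
  out <- numeric(length(x))
  out[order(x)] <- sorted_vals
  out
}

#' Spearman map-gene correlations with spatial-null p-values
#'
#' Correlates a parcellated map with every gene's expression profile
#' (Spearman) and derives a two-sided p-value per gene from the
#' variogram-matched surrogate ensemble: the proportion of surrogates whose
#' absolute correlation with the gene reaches the observed one, with a +1
#' correction so that p is never zero.
#'
#' @param map A [parcellate()] result or named numeric vector over parcels.
#' @param expression Parcels-by-genes matrix (rownames = parcel ids,
#'   colnames = gene ids).
#' @param surrogates A [variogram_surrogates()] ensemble built from `map`.
#' @return An object of class `gene_correlation`: data frame with `gene`,
#'   `rho`, `p_spatial`; genes with zero expression variance get `NA` in
#'   both columns.
#' @export
spatial_gene_correlation <- function(map, expression, surrogates) {
  values <- if (inherits(map, "parcel_map")) map$value else map
  stopifnot(inherits(surrogates, "surrogate_ensemble"))
  expression <- as.matrix(expression)
  if (!is.null(rownames(expression)) && !is.null(names(values))) {
    if (!setequal(rownames(expression), names(values))) {
      stop("map and expression must cover the same parcels")
    }
    expression <- expression[names(values), , drop = FALSE]
  }
  if (nrow(expression) != length(values)) {
    stop("map and expression must cover the same parcels")
  }
  degenerate <- apply(expression, 2, stats::sd) == 0
  rk_expr <- apply(expression, 2, rank)
  rk_map <- rank(values)
  # zero-variance genes are reported as NA below; silence cor's warning
  rho <- as.numeric(suppressWarnings(stats::cor(rk_map, rk_expr)))
  rk_surr <- t(apply(surrogates$maps, 1, rank))
  rho_surr <- suppressWarnings(
    stats::cor(t(rk_surr), rk_expr))  # n_surr x n_genes
  n_surr <- nrow(surrogates$maps)
  exceed <- colSums(abs(rho_surr) >= rep(abs(rho), each = n_surr))
  p <- (1 + exceed) / (n_surr + 1)
  rho[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  if (any(degenerate)) {
    message(sum(degenerate), " gene(s) with zero variance reported as NA")
  }
  structure(data.frame(gene = colnames(expression), rho = rho,
                       p_spatial = p, stringsAsFactors = FALSE),
            class = c("gene_correlation", "data.frame"))
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score.
# w_abs: |ranking score| in ranked order; pos: sorted positions of the
# set's genes in the ranked list. Returns ES and the hit index at which
# the extremum is attained.
gsea_es <- function(w_abs, pos, n_total) {
  m <- length(pos)
  nr <- sum(w_abs[pos])
  if (nr == 0) {
    # all hit weights zero: running sum only decreases between hits
    return(list(es = 0, peak = 1L))
  }
  hit_cum <- cumsum(w_abs[pos]) / nr
  miss_after <- (pos - seq_len(m)) / (n_total - m)
  miss_before <- (pos - 1 - (seq_len(m) - 1)) / (n_total - m)
  top <- hit_cum - miss_after        # running sum just after each hit
  bottom <- c(0, hit_cum[-m]) - miss_before  # just before each hit
  i_max <- which.max(top)
  i_min <- which.min(bottom)
  if (top[i_max] >= -bottom[i_min]) {
    list(es = top[i_max], peak = i_max)
  } else {
    list(es = bottom[i_min], peak = i_min)
  }
}

#' Pre-ranked gene-set enrichment over cell-type annotations
#'
#' Ranks genes by their map correlation (descending) and computes, per
#' gene set, the weighted Kolmogorov-Smirnov enrichment score (weight
#' exponent 1: hits advance the running sum by their absolute ranking
#' score, misses retreat it by 1/(N - m)). The null distribution draws
#' random gene sets of the same size (gene-label permutation, the
#' convention for a pre-ranked list where sample permutation is
#' impossible). The normalised enrichment score divides ES by the mean
#' absolute null ES of matching sign; positive NES marks sets whose genes
#' concentrate where the map is most positive — with a dysconnectivity
#' \emph{reduction} map, sets whose expression is higher where
#' dysconnectivity fell.
#'
#' @param corr A [spatial_gene_correlation()] result, or a named numeric
#'   vector of per-gene ranking scores.
#' @param gene_sets Named list of gene-id vectors; each must intersect the
#'   ranked list and be smaller than it.
#' @param n_perm Gene-label permutations for the null (default 1000).
#' @param seed Integer seed.
#' @param fdr_method `"permutation"`: the signed-NES permutation FDR of
#'   pre-ranked enrichment; `"BH"`: Benjamini-Hochberg over nominal
#'   p-values.
#' @return An object of class `enrichment_result`: data frame with `set`,
#'   `size`, `es`, `nes`, `p_nominal`, `q`, `hit_proportion` (fraction of
#'   set genes in the leading edge), ordered by decreasing `nes`.
#' @export
gsea_cell_types <- function(corr, gene_sets, n_perm = 1000, seed,
                            fdr_method = c("permutation", "BH")) {
  fdr_method <- match.arg(fdr_method)
  if (inherits(corr, "gene_correlation") || is.data.frame(corr)) {
    scores <- stats::setNames(corr$rho, corr$gene)
  } else {
    scores <- corr
  }
  scores <- scores[!is.na(scores)]
  if (is.null(names(scores))) stop("ranking scores must be named by gene")
  set.seed(as.integer(seed))
  ord <- order(scores, decreasing = TRUE)
  ranked <- scores[ord]
  w_abs <- abs(ranked)
  n_total <- length(ranked)
  idx_of <- stats::setNames(seq_len(n_total), names(ranked))

  sizes <- integer(0)
  obs <- list()
  for (nm in names(gene_sets)) {
    pos <- sort(unname(idx_of[intersect(gene_sets[[nm]], names(ranked))]))
    if (!length(pos)) {
      stop("gene set '", nm, "' does not intersect the ranked list")
    }
    if (length(pos) >= n_total) {
      stop("gene set '", nm, "' is as large as the ranked list")
    }
    es <- gsea_es(w_abs, pos, n_total)
    obs[[nm]] <- list(pos = pos, es = es$es, peak = es$peak,
                      m = length(pos))
    sizes <- union(sizes, length(pos))
  }

  # null ES per unique set size (gene-label permutation = random positions)
  null_es <- lapply(stats::setNames(sizes, sizes), function(m) {
    vapply(seq_len(n_perm), function(b) {
      pos <- sort(sample.int(n_total, m))
      gsea_es(w_abs, pos, n_total)$es
    }, numeric(1))
  })

  norm_es <- function(es, null) {
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    denom <- mean(abs(same))
    if (!length(same) || denom == 0) return(NA_real_)
    es / denom
  }

  rows <- lapply(names(obs), function(nm) {
    o <- obs[[nm]]
    null <- null_es[[as.character(o$m)]]
    same <- if (o$es >= 0) null[null >= 0] else null[null < 0]
    p <- (1 + sum(abs(same) >= abs(o$es))) / (1 + length(same))
    hit_prop <- if (o$es >= 0) o$peak / o$m else (o$m - o$peak + 1) / o$m
    data.frame(set = nm, size = o$m, es = o$es,
               nes = norm_es(o$es, null), p_nominal = p,
               hit_proportion = hit_prop, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)

  if (fdr_method == "BH") {
    res$q <- fdr_bh(res$p_nominal)
  } else {
    # signed-NES permutation FDR: compare each observed NES with the
    # pooled null NES distribution of matching sign
    null_nes <- unlist(lapply(names(null_es), function(msz) {
      null <- null_es[[msz]]
      vapply(null, norm_es, numeric(1), null = null)
    }), use.names = FALSE)
    null_nes <- null_nes[is.finite(null_nes)]
    # add-one smoothing in both tail fractions: the null ES distribution
    # can be strongly sign-asymmetric (a few heavy ranking scores at one
    # end), leaving very few same-sign null draws; without smoothing the
    # numerator collapses to an over-confident zero
    res$q <- vapply(seq_len(nrow(res)), function(i) {
      nes <- res$nes[i]
      if (!is.finite(nes)) return(NA_real_)
      if (nes >= 0) {
        nn <- null_nes[null_nes >= 0]
        oo <- res$nes[res$nes >= 0]
        num <- (1 + sum(nn >= nes)) / (1 + length(nn))
        den <- (1 + sum(oo >= nes)) / (1 + length(oo))
      } else {
        nn <- null_nes[null_nes < 0]
        oo <- res$nes[res$nes < 0]
        num <- (1 + sum(nn <= nes)) / (1 + length(nn))
        den <- (1 + sum(oo <= nes)) / (1 + length(oo))
      }
      min(1, num / den)
    }, numeric(1))
  }
  res <- res[order(-res$nes), ]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"))
}
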