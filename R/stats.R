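# Statistical machinery: mean-shift clustering with k-NN bandwidth
# estimation, hierarchical outlier ranking, correlation/KS/FDR wrappers,
# position-occupancy binning, and list-intersection significance.

#' k-nearest-neighbour bandwidth estimate
#'
#' Mean over points of the distance to each point's
#' \eqn{\lceil q n \rceil}-th nearest neighbour (self excluded, capped
#' at n - 1). Stated explicitly so results do not depend on any
#' particular library's internals; scales linearly with the data.
#'
#' @param points numeric matrix, one row per item.
#' @param quantile neighbour quantile q in (0, 1].
#' @return bandwidth (scalar > 0).
#' @export
estimate_bandwidth <- function(points, quantile = 0.3) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  if (quantile <= 0 || quantile > 1) stop("quantile must lie in (0, 1]")
  k <- min(max(1L, ceiling(quantile * n)), n - 1L)
  dmat <- as.matrix(stats::dist(points))
  kd <- apply(dmat, 1L, function(d) sort(d[-which.min(d)])[k])
  # (drop the zero self-distance, then take the k-th smallest)
  bw <- mean(kd)
  if (bw == 0) {
    stop("estimated bandwidth is 0 (identical points); supply a positive ",
         "bandwidth explicitly")
  }
  bw
}

#' Flat-kernel mean-shift clustering
#'
#' Every point is a seed; each seed is shifted to the mean of the
#' points within `bandwidth` of it until the displacement falls below
#' `1e-5 * bandwidth` (at most `max_iter` sweeps, warning on
#' non-convergence). Converged modes are merged greedily in order of
#' decreasing support (points within bandwidth), discarding modes
#' within `bandwidth` of an already-kept mode; items are labeled by the
#' nearest kept mode. Deterministic: no random seeding or binning.
#'
#' @param points numeric matrix, one row per item.
#' @param bandwidth kernel radius (> 0).
#' @param max_iter iteration cap per seed (default 300).
#' @return object of class `mean_shift_result`: `labels` (dense cluster
#'   ids from 1, named by rownames), `centers` (modes), `bandwidth`,
#'   `n_clusters`.
#' @export
mean_shift <- function(points, bandwidth, max_iter = 300L) {
  points <- as.matrix(points)
  if (bandwidth <= 0) stop("bandwidth must be positive")
  n <- nrow(points)
  modes <- points
  for (s in seq_len(n)) {
    x <- points[s, ]
    for (it in seq_len(max_iter)) {
      d2 <- colSums((t(points) - x)^2)
      within <- d2 <= bandwidth^2
      nx <- colMeans(points[within, , drop = FALSE])
      if (sqrt(sum((nx - x)^2)) < 1e-5 * bandwidth) {
        x <- nx
        break
      }
      x <- nx
      if (it == max_iter) {
        warning("mean-shift seed ", s, " did not converge in ", max_iter,
                " iterations")
      }
    }
    modes[s, ] <- x
  }
  support <- vapply(seq_len(n), function(s) {
    sum(colSums((t(points) - modes[s, ])^2) <= bandwidth^2)
  }, 1L)
  ord <- order(-support, seq_len(n))  # ties: first seed wins, deterministic
  kept <- integer(0)
  for (s in ord) {
    if (length(kept) == 0L ||
        min(sqrt(colSums((t(modes[kept, , drop = FALSE]) - modes[s, ])^2))) >
        bandwidth) {
      kept <- c(kept, s)
    }
  }
  centers <- modes[kept, , drop = FALSE]
  labels <- apply(points, 1L, function(x) {
    which.min(colSums((t(centers) - x)^2))
  })
  names(labels) <- rownames(points)
  rownames(centers) <- NULL
  structure(
    list(labels = labels, centers = centers, bandwidth = bandwidth,
         n_clusters = nrow(centers)),
    class = "mean_shift_result"
  )
}

#' @export
print.mean_shift_result <- function(x, ...) {
  cat(sprintf("<mean_shift_result> %d clusters at bandwidth %.4g; sizes %s\n",
              x$n_clusters, x$bandwidth,
              paste(tabulate(x$labels, x$n_clusters), collapse = ", ")))
  invisible(x)
}

#' Rank items by distance to all others (hierarchical view)
#'
#' Items ranked by their mean Euclidean distance to every other item
#' (stable order on ties), together with the average-linkage
#' agglomeration of the same distances for dendrogram inspection.
#'
#' @param points numeric matrix, one row per item.
#' @return list with `ranking` (data frame: item, mean_dist, rank,
#'   ordered by decreasing mean distance) and `hclust` (the
#'   average-linkage tree).
#' @export
rank_outliers_hierarchical <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  d <- stats::dist(points)
  dm <- as.matrix(d)
  mean_dist <- rowSums(dm) / (nrow(dm) - 1L)
  items <- if (is.null(rownames(points))) as.character(seq_len(nrow(points)))
  else rownames(points)
  ord <- order(-mean_dist, seq_along(mean_dist))
  ranking <- data.frame(item = items[ord], mean_dist = mean_dist[ord],
                        rank = rank(-mean_dist, ties.method = "min")[ord],
                        stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  list(ranking = ranking, hclust = stats::hclust(d, method = "average"))
}

#' Pearson correlation with two-sided p-value
#' @param x,y numeric vectors (n >= 3, nonzero variance).
#' @return list with `R` and `p` (t-approximation, two-sided).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(R = unname(ct$estimate), p = ct$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#' @param a,b numeric samples.
#' @return list with `statistic` (sup CDF difference) and `p`
#'   (asymptotic, two-sided).
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                        exact = FALSE))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Benjamini-Hochberg step-up at level q
#' @param pvalues named numeric vector of p-values in [0, 1].
#' @param q false discovery rate (default 0.05).
#' @return list with `rejected` (named logical), `adjusted` (BH-adjusted
#'   p-values), `q`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(rejected = adj <= q, adjusted = adj, q = q)
}

#' Position-occupancy vector over a sequence universe
#'
#' Counts list positions into `n_bins` equal-width bins over
#' `[1, universe]`: bin i covers `[universe/n * (i-1), universe/n * i)`.
#'
#' @param positions integer positions in `[1, universe]`.
#' @param n_bins number of bins (default 10).
#' @param universe universe length (default 306, a two-chain dimer of
#'   153-residue subunits).
#' @return integer vector of bin counts (sums to `length(positions)`).
#' @export
binned_position_occupancy <- function(positions, n_bins = 10L,
                                      universe = 306L) {
  if (length(positions) > 0 &&
      (min(positions) < 1 || max(positions) > universe)) {
    stop("positions out of [1, ", universe, "]")
  }
  width <- universe / n_bins
  bin <- pmin(floor(positions / width) + 1L, n_bins)
  tabulate(bin, nbins = n_bins)
}

#' Correlation of two position lists via binned occupancy
#'
#' Builds the occupancy vector of each list and reports the Pearson
#' correlation between them. Positions on a second chain should be
#' offset into the dimer range first (see [dimer_position()]).
#'
#' @param list_a,list_b integer position vectors.
#' @inheritParams binned_position_occupancy
#' @return list with `R`, `p`, and the two occupancy vectors `v_a`,
#'   `v_b`.
#' @export
binned_position_correlation <- function(list_a, list_b, n_bins = 10L,
                                        universe = 306L) {
  va <- binned_position_occupancy(list_a, n_bins, universe)
  vb <- binned_position_occupancy(list_b, n_bins, universe)
  pr <- pearson(va, vb)
  list(R = pr$R, p = pr$p, v_a = va, v_b = vb)
}

#' Map per-chain positions into the dimer position range
#'
#' Chain A keeps its numbering; each later chain is offset by the
#' subunit length, so a 153-residue homodimer spans 1..306.
#'
#' @param chain chain id vector.
#' @param resno residue number vector.
#' @param chains ordered chain ids of the dimer (default `c("A", "F")`).
#' @param subunit_length residues per subunit (default 153).
#' @return integer dimer positions.
#' @export
dimer_position <- function(chain, resno, chains = c("A", "F"),
                           subunit_length = 153L) {
  idx <- match(chain, chains)
  if (anyNA(idx)) {
    stop("unknown chains: ", paste(unique(chain[is.na(idx)]), collapse = ", "))
  }
  as.integer(resno + (idx - 1L) * subunit_length)
}

#' Significance of the intersection of two position lists
#'
#' Hypergeometric upper-tail (enrichment) probability of an overlap at
#' least as large as observed, drawing `|B|` positions from a universe
#' containing `|A|` marked ones.
#'
#' @param list_a,list_b position vectors (deduplicated internally).
#' @param universe_size number of positions in the universe.
#' @return list with `overlap` (sorted common positions) and `p`.
#' @export
intersection_test <- function(list_a, list_b, universe_size) {
  if (universe_size < 1) stop("empty universe")
  a <- unique(list_a)
  b <- unique(list_b)
  if (length(a) > universe_size || length(b) > universe_size) {
    stop("list larger than universe")
  }
  ov <- sort(intersect(a, b))
  p <- stats::phyper(length(ov) - 1L, length(a), universe_size - length(a),
                     length(b), lower.tail = FALSE)
  list(overlap = ov, p = p)
}
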