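# Destructive hydrogen-bond detection: per-variant deviations D^m from the
# wild type, per-bond contributions xi, the 9-bin contribution histogram
# (table H) with its S-bar summary, cluster-based variant selection, and
# tail thresholding of mean contributions.

#' Per-variant deviations and per-bond contributions
#'
#' For each variant m, the deviation from the wild type is
#' \eqn{D^m = \sqrt{\sum_i (SEA_i^m - SEA_i^{WT})^2}} over the union
#' bond set, and the contribution of bond j is
#' \eqn{\xi_j^m = (SEA_j^m - SEA_j^{WT})^2 / (D^m)^2}. Contributions of
#' a variant sum to 1 whenever \eqn{D^m > 0}; a variant identical to
#' the wild type gets a zero xi row and is flagged.
#'
#' @param sea a `sea_table`.
#' @param wt_id wild-type column (defaults to the table's designation).
#' @return object of class `contribution_set`: `D` (named vector over
#'   variants), `xi` (bonds x variants matrix), `zero_deviation`
#'   (logical flags), and `present` (bonds x variants logical matrix:
#'   bond seen in the variant or the WT, used by the histogram's
#'   present-bonds counting policy).
#' @export
compute_deviations <- function(sea, wt_id = sea$wt_id) {
  vals <- sea$values
  if (!wt_id %in% colnames(vals)) stop("wt_id ", wt_id, " not in table")
  variants <- setdiff(colnames(vals), wt_id)
  if (length(variants) == 0L) stop("table holds no variants besides the WT")
  wt <- vals[, wt_id]
  diff2 <- (vals[, variants, drop = FALSE] - wt)^2
  D <- sqrt(colSums(diff2))
  xi <- diff2
  for (m in variants) {
    xi[, m] <- if (D[[m]] > 0) diff2[, m] / D[[m]]^2 else 0
  }
  if (any(D == 0)) {
    warning("variants identical to the WT (zero deviation): ",
            paste(variants[D == 0], collapse = ", "))
  }
  present <- vals[, variants, drop = FALSE] > 0 | wt > 0
  structure(
    list(D = D, xi = xi, zero_deviation = D == 0, present = present,
         wt_id = wt_id),
    class = "contribution_set"
  )
}

#' @export
print.contribution_set <- function(x, ...) {
  cat(sprintf("<contribution_set> %d bonds x %d variants, D in [%.3g, %.3g]\n",
              nrow(x$xi), ncol(x$xi), min(x$D), max(x$D)))
  invisible(x)
}

#' Contribution histogram (table H)
#'
#' One row per variant, 9 cells: cell i counts the variant's bonds with
#' contribution \eqn{\xi \in [0.1 (i-1), 0.1 i)} for i = 1..8; the
#' ninth cell closes at 1.0 inclusive ([0.8, 1.0]). Which bonds are
#' counted is set by the counting policy: `"variant_present_bonds"`
#' (default) counts bonds observed in the variant or the wild type,
#' `"union_bonds"` counts the whole bond universe.
#'
#' @param contrib a `contribution_set`.
#' @param counting_policy see above.
#' @return object of class `h_table`: `counts` (variants x 9 matrix)
#'   and `s_bar` (per-variant mean of cells 2..9).
#' @export
build_h_table <- function(contrib,
                          counting_policy = c("variant_present_bonds",
                                              "union_bonds")) {
  counting_policy <- match.arg(counting_policy)
  variants <- colnames(contrib$xi)
  counts <- matrix(0L, nrow = length(variants), ncol = 9L,
                   dimnames = list(variants, paste0("H", 1:9)))
  for (m in variants) {
    xi <- contrib$xi[, m]
    if (counting_policy == "variant_present_bonds") {
      xi <- xi[contrib$present[, m]]
    }
    # [0.8, 1.0] closes bin 9; the epsilon guards exact bin edges
    # (e.g. xi = 0.1) against floating-point representation error
    bin <- pmin(floor(xi * 10 + 1e-9) + 1L, 9L)
    counts[m, ] <- tabulate(bin, nbins = 9L)
  }
  structure(
    list(counts = counts, s_bar = rowMeans(counts[, 2:9, drop = FALSE]),
         counting_policy = counting_policy),
    class = "h_table"
  )
}

#' Mean high-contribution count S-bar for one variant
#'
#' \eqn{\bar{S}_H = (1/8) \sum_{i=2}^{9} H_m[i]}: the average cell
#' count beyond the first bin, tracking bonds that contribute more than
#' 10 percent of the variant's squared deviation.
#'
#' @param h an `h_table`.
#' @param variant variant id.
#' @return scalar S-bar.
#' @export
mean_sh <- function(h, variant) {
  if (!variant %in% rownames(h$counts)) stop("unknown variant ", variant)
  unname(h$s_bar[variant])
}

#' Select variants with high-contribution bonds
#'
#' Mean-shift clusters the rows of table H (bandwidth from the k-NN
#' quantile estimator unless given) and returns the union of variants
#' in clusters whose mean S-bar is positive, i.e. clusters whose
#' members carry bonds contributing more than 10 percent each. With a
#' single cluster the selection is empty (warned): no variant stands
#' out.
#'
#' @param h an `h_table`.
#' @param bandwidth mean-shift bandwidth; estimated if NULL.
#' @return character vector of selected variant ids (possibly empty),
#'   with the clustering attached as attribute `clustering`.
#' @export
select_high_contribution_variants <- function(h, bandwidth = NULL) {
  if (nrow(h$counts) < 2L) stop("need at least 2 variants to cluster")
  pts <- h$counts
  storage.mode(pts) <- "double"
  if (is.null(bandwidth)) {
    bandwidth <- tryCatch(estimate_bandwidth(pts), error = function(e) 0)
  }
  cl <- if (bandwidth > 0) mean_shift(pts, bandwidth) else {
    # identical rows: a single degenerate cluster
    structure(list(labels = stats::setNames(rep(1L, nrow(pts)),
                                            rownames(pts)),
                   centers = pts[1L, , drop = FALSE], bandwidth = 0,
                   n_clusters = 1L), class = "mean_shift_result")
  }
  if (cl$n_clusters == 1L) {
    warning("H-table clustering found a single cluster; empty selection")
    out <- character(0)
  } else {
    cl_sbar <- tapply(h$s_bar, cl$labels, mean)
    keep <- as.integer(names(cl_sbar)[cl_sbar > 0])
    out <- rownames(pts)[cl$labels %in% keep]
  }
  attr(out, "clustering") <- cl
  out
}

#' Detect destructive bonds from mean contributions
#'
#' Averages contributions over the selected variants,
#' \eqn{\bar{\xi}_j = |S|^{-1} \sum_{m \in S} \xi_j^m}, and thresholds
#' at the rightmost `tail` of the \eqn{\bar{\xi}} distribution: the
#' empirical (1 - tail) quantile (linear interpolation) over bonds with
#' \eqn{\bar{\xi} > 0} (the mass of unaffected bonds at zero is
#' excluded from the quantile base). Bonds at or above the threshold
#' are destructive. The explained fraction is the mean over selected
#' variants of the summed contributions of the destructive bonds.
#'
#' @param contrib a `contribution_set`.
#' @param selected non-empty character vector of variant ids.
#' @param tail tail fraction (default 0.05); 0 yields an empty set.
#' @return object of class `destructive_result`: `selected_variants`,
#'   `xi_bar`, `threshold`, `destructive_bonds` (keys ordered by
#'   decreasing xi-bar), `explained_fraction`.
#' @export
detect_destructive <- function(contrib, selected, tail = 0.05) {
  if (length(selected) == 0L) stop("empty variant selection")
  if (!all(selected %in% colnames(contrib$xi))) {
    stop("unknown variants: ",
         paste(setdiff(selected, colnames(contrib$xi)), collapse = ", "))
  }
  if (tail < 0 || tail >= 1) stop("tail must lie in [0, 1)")
  xi_bar <- rowMeans(contrib$xi[, selected, drop = FALSE])
  if (tail == 0) {
    res <- list(selected_variants = selected, xi_bar = xi_bar,
                threshold = Inf, destructive_bonds = character(0),
                explained_fraction = 0)
    return(structure(res, class = "destructive_result"))
  }
  base <- xi_bar[xi_bar > 0]
  if (length(base) == 0L) stop("all mean contributions are zero")
  threshold <- unname(stats::quantile(base, 1 - tail, type = 7))
  destructive <- names(xi_bar)[xi_bar >= threshold]
  destructive <- destructive[order(-xi_bar[destructive])]
  explained <- mean(colSums(contrib$xi[destructive, selected, drop = FALSE]))
  structure(
    list(selected_variants = selected, xi_bar = xi_bar,
         threshold = threshold, destructive_bonds = destructive,
         explained_fraction = explained),
    class = "destructive_result"
  )
}

#' @export
print.destructive_result <- function(x, ...) {
  cat(sprintf(
    "<destructive_result> %d bonds >= %.4g over %d variants; explained fraction %.2f\n",
    length(x$destructive_bonds), x$threshold, length(x$selected_variants),
    x$explained_fraction))
  invisible(x)
}

#' Residues participating in a set of hydrogen bonds
#'
#' Extracts the unique (chain, residue) participants of the given bond
#' keys and cross-tags each position against the annotation roles.
#'
#' @param bonds character vector of bond keys ([hbond_key()] format).
#' @param annotations named list of position vectors (default the SOD1
#'   annotation set, [sod1_residue_annotations()]).
#' @return data frame with `chain`, `resno` and `roles` (comma-joined
#'   annotation names); opaque keys yield a partial result with a
#'   warning.
#' @export
residues_of_bonds <- function(bonds, annotations = sod1_residue_annotations()) {
  parsed <- parse_hbond_key(bonds)
  if (any(!parsed$parsed)) {
    warning(sum(!parsed$parsed), " opaque bond labels skipped")
    parsed <- parsed[parsed$parsed, , drop = FALSE]
  }
  res <- unique(rbind(
    data.frame(chain = parsed$don_chain, resno = parsed$don_resno,
               stringsAsFactors = FALSE),
    data.frame(chain = parsed$acc_chain, resno = parsed$acc_resno,
               stringsAsFactors = FALSE)
  ))
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  res$roles <- vapply(res$resno, function(p) {
    paste(names(annotations)[vapply(annotations, function(v) p %in% v, TRUE)],
          collapse = ",")
  }, character(1))
  res
}
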