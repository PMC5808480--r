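# ANM mechanical stiffness: pairwise effective spring constants from the
# mode spectrum, per-residue summaries, tail extraction, widest-path
# impulse transmission, and site-set mean stiffness.

#' Pairwise mechanical stiffness from normal modes
#'
#' Uniaxial-extension formulation: for nodes i, j with equilibrium
#' separation direction \eqn{\hat{n}_{ij}}, the compliance is
#' \eqn{c_{ij} = \sum_k \lambda_k^{-1} [(u_k(j) - u_k(i)) \cdot
#' \hat{n}_{ij}]^2} summed over non-trivial modes, and the effective
#' spring constant is \eqn{\kappa_{ij} = 1 / c_{ij}} (units of the
#' network's gamma). Pairs whose compliance underflows `rigid_tol` are
#' fully rigid at the model's resolution: their kappa is stored as an
#' `Inf` sentinel, flagged, and excluded from downstream means and
#' quantiles.
#'
#' @param modes a `mode_set` (carries eigenpairs, node coordinates and
#'   metadata).
#' @param modes_used number of non-trivial modes to sum; default all.
#' @param rigid_tol compliance underflow threshold (default 1e-12).
#' @return object of class `stiffness_matrix`: `kappa` (symmetric, NA
#'   diagonal), `rigid` (logical flag matrix), `nodes`, `coords`,
#'   `modes_used`.
#' @export
pairwise_stiffness <- function(modes, modes_used = NULL, rigid_tol = 1e-12) {
  xyz <- modes$coords
  n <- nrow(xyz)
  if (n < 2L) stop("need at least 2 nodes")
  if (is.null(modes_used)) modes_used <- length(modes$values)
  if (modes_used < 1L || modes_used > length(modes$values)) {
    stop("modes_used must lie in 1..", length(modes$values))
  }
  dx <- outer(xyz[, 1L], xyz[, 1L], "-")
  dy <- outer(xyz[, 2L], xyz[, 2L], "-")
  dz <- outer(xyz[, 3L], xyz[, 3L], "-")
  dd <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(dd[upper.tri(dd)] < 1e-6)) stop("coincident nodes in model")
  diag(dd) <- 1  # avoid 0/0; diagonal is masked below
  nx <- dx / dd; ny <- dy / dd; nz <- dz / dd
  compliance <- matrix(0, n, n)
  for (k in seq_len(modes_used)) {
    u <- matrix(modes$vectors[, k], ncol = 3L, byrow = TRUE)
    # proj[i, j] = (u(i) - u(j)) . n_ij ; squared, so orientation-safe
    proj <- outer(u[, 1L], u[, 1L], "-") * nx +
      outer(u[, 2L], u[, 2L], "-") * ny +
      outer(u[, 3L], u[, 3L], "-") * nz
    compliance <- compliance + proj^2 / modes$values[k]
  }
  rigid <- compliance < rigid_tol
  kappa <- 1 / compliance
  kappa[rigid] <- Inf
  diag(kappa) <- NA_real_
  diag(rigid) <- FALSE
  labels <- node_labels(modes$nodes)
  dimnames(kappa) <- list(labels, labels)
  dimnames(rigid) <- dimnames(kappa)
  structure(
    list(kappa = kappa, rigid = rigid, nodes = modes$nodes, coords = xyz,
         modes_used = modes_used, structure_id = modes$structure_id),
    class = "stiffness_matrix"
  )
}

node_labels <- function(nodes) {
  ifelse(nodes$is_metal,
         paste0(toupper(nodes$name), ":", nodes$chain),
         paste0(nodes$resno, nodes$insert, ".", nodes$chain))
}

#' @export
print.stiffness_matrix <- function(x, ...) {
  fin <- x$kappa[upper.tri(x$kappa)]
  fin <- fin[is.finite(fin)]
  cat(sprintf(
    "<stiffness_matrix> %s: %d nodes, %d modes; kappa median %.3g (%d rigid pairs)\n",
    x$structure_id, nrow(x$kappa), x$modes_used, stats::median(fin),
    sum(x$rigid) / 2L))
  invisible(x)
}

#' Mean stiffness per residue
#'
#' Row mean of kappa over partner residues: all residues by default, or
#' same-chain partners only. Metal nodes and infinite (rigid) sentinels
#' are excluded from the partner set; the divisor is the actual partner
#' count.
#'
#' @param m a `stiffness_matrix`.
#' @param scope `"all"` or `"same_chain"`.
#' @return named numeric vector over residue nodes (metal nodes are not
#'   summarized).
#' @export
mean_stiffness <- function(m, scope = c("all", "same_chain")) {
  scope <- match.arg(scope)
  res_idx <- which(!m$nodes$is_metal)
  if (length(res_idx) == 0L) stop("no residue nodes in scope")
  out <- numeric(length(res_idx))
  names(out) <- rownames(m$kappa)[res_idx]
  n_dropped <- 0L
  for (t in seq_along(res_idx)) {
    i <- res_idx[t]
    partners <- setdiff(res_idx, i)
    if (scope == "same_chain") {
      partners <- partners[m$nodes$chain[partners] == m$nodes$chain[i]]
    }
    v <- m$kappa[i, partners]
    n_dropped <- n_dropped + sum(!is.finite(v))
    out[t] <- mean(v[is.finite(v)])
  }
  if (n_dropped > 0L) {
    message(n_dropped, " rigid-pair sentinels excluded from mean stiffness")
  }
  out
}

#' Stiffness profile from a named site node
#'
#' The kappa row of a single node, typically a metal ion: for a copper
#' node, the profile \eqn{\kappa_{Cu,i}} over residues.
#'
#' @param m a `stiffness_matrix`.
#' @param site node label, e.g. `"CU:A"` (see rownames of `m$kappa`).
#' @return named numeric vector over all other nodes.
#' @export
site_stiffness_profile <- function(m, site) {
  if (!site %in% rownames(m$kappa)) {
    metals <- rownames(m$kappa)[m$nodes$is_metal]
    stop("site node '", site, "' not in model; metal nodes available: ",
         if (length(metals)) paste(metals, collapse = ", ") else "(none)")
  }
  prof <- m$kappa[site, ]
  prof[names(prof) != site & !is.na(prof)]
}

#' Keys in the rightmost tail of a value distribution
#'
#' Keys whose value is at or above the empirical (1 - fraction)
#' quantile (linear interpolation). Ties at the threshold are all
#' included. Non-finite values are excluded from the quantile base.
#'
#' @param values named numeric vector.
#' @param fraction tail fraction in (0, 1).
#' @return character vector of keys, ordered by decreasing value.
#' @export
top_tail <- function(values, fraction) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  v <- values[is.finite(values)]
  thr <- unname(stats::quantile(v, 1 - fraction, type = 7))
  keys <- names(v)[v >= thr]
  keys[order(-v[keys])]
}

#' Widest transmission path between two nodes
#'
#' Operationalizes a "chain of spatially close residues transmitting a
#' mechanical impulse": on the contact graph (node pairs within
#' `contact_cutoff`), the path from source to sink maximizing the
#' minimum edge stiffness, found on the maximum spanning tree (whose
#' unique source-sink path is a widest path).
#'
#' @param m a `stiffness_matrix`.
#' @param source,sink node labels.
#' @param contact_cutoff contact distance, Angstrom (default 8).
#' @return character vector of node labels from source to sink, with
#'   attribute `bottleneck` (the minimum kappa along the path).
#' @export
transmission_path <- function(m, source, sink, contact_cutoff = 8) {
  labels <- rownames(m$kappa)
  for (s in c(source, sink)) {
    if (!s %in% labels) stop("node '", s, "' not in model")
  }
  dmat <- as.matrix(stats::dist(m$coords))
  contact <- dmat <= contact_cutoff & upper.tri(dmat)
  pairs <- which(contact, arr.ind = TRUE)
  w <- m$kappa[pairs]
  w[!is.finite(w)] <- max(m$kappa[is.finite(m$kappa)]) * 2  # rigid = widest
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  igraph::E(g)$kappa <- w
  if (igraph::components(g)$no > 1L ||
      igraph::vcount(g) < nrow(m$kappa)) {
    stop("contact graph disconnected at cutoff ", contact_cutoff)
  }
  mst <- igraph::mst(g, weights = -w)  # maximum spanning tree
  vp <- igraph::shortest_paths(mst, from = match(source, labels),
                               to = match(sink, labels), weights = NA,
                               output = "both")
  path_nodes <- as.integer(vp$vpath[[1L]])
  out <- labels[path_nodes]
  attr(out, "bottleneck") <- min(igraph::E(mst)$kappa[
    as.integer(vp$epath[[1L]])])
  out
}

#' Mean stiffness between a position and an important-site set
#'
#' \eqn{\bar{\kappa}_{m c} = |C|^{-1} \sum_{i \in C} \kappa_{m, c_i}}
#' between a (mutated) position and a reference set of structurally
#' important positions. Returns the raw sample as well, for
#' distributional comparison (e.g. Kolmogorov-Smirnov against all
#' pairwise kappa).
#'
#' @param m a `stiffness_matrix`.
#' @param position node label of the query position.
#' @param important character vector of node labels (must not contain
#'   `position`).
#' @return list with `mean` and `sample` (named kappa values).
#' @export
site_mean_stiffness <- function(m, position, important) {
  if (length(important) == 0L) stop("empty important set")
  if (position %in% important) {
    stop("position ", position, " overlaps the important set")
  }
  labels <- rownames(m$kappa)
  missing <- setdiff(c(position, important), labels)
  if (length(missing) > 0L) {
    stop("nodes not in model: ", paste(missing, collapse = ", "))
  }
  sample <- m$kappa[position, important]
  list(mean = mean(sample[is.finite(sample)]), sample = sample)
}

#' Write a structure with a stiffness profile in the B-factor column
#'
#' Every atom of a residue gets its residue's profile value (0 for
#' residues absent from the profile), so the structure can be colored
#' by stiffness in any molecular viewer.
#'
#' @param structure an `enstab_structure`.
#' @param profile named vector over node labels (`"resno.chain"`).
#' @param path output PDB path.
#' @export
write_stiffness_pdb <- function(structure, profile, path) {
  at <- structure$atoms
  lab <- paste0(at$resno, at$insert, ".", at$chain)
  b <- ifelse(lab %in% names(profile), profile[lab], 0)
  b[!is.finite(b)] <- 0
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(at))) {
    rec <- if (isTRUE(at$hetatm[i])) "HETATM" else "ATOM  "
    name_fmt <- if (nchar(at$name[i]) < 4L && nchar(at$element[i]) == 1L) {
      sprintf(" %-3s", at$name[i])
    } else sprintf("%-4s", at$name[i])
    writeLines(sprintf(
      "%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, i, name_fmt, at$resname[i], at$chain[i], at$resno[i],
      ifelse(at$insert[i] == "", " ", at$insert[i]),
      at$x[i], at$y[i], at$z[i], 1, b[i], at$element[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}
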