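# Anisotropic elastic-network models: Hessian assembly, normal modes,
# mode collectivity, DQ-sweep conformer ensembles, eigenvector comparison.

#' Ensemble generation configuration
#'
#' Parameters of the elastic-network ensemble stage. Defaults reproduce
#' the standard low-frequency sweep: 5 modes, perturbation grid
#' -100..100 in steps of 20 (11 conformers per mode, 55 per structure),
#' 8 Angstrom interaction cutoff.
#'
#' @param n_modes number of non-trivial modes used for conformers.
#' @param dq_min,dq_max,dq_step perturbation grid (dimensionless DQ
#'   units; dq = +/-100 maps to `amplitude_scale` Angstrom of maximum
#'   nodal displacement).
#' @param cutoff spring cutoff distance, Angstrom.
#' @param gamma uniform spring constant (arbitrary units; stiffness is
#'   reported in units of `gamma`).
#' @param node_policy which atoms become network nodes: `"heavy_atoms"`
#'   (hydrogens ride with their bonded heavy atom), `"calpha"` (one node
#'   per residue plus metal ions; all residue atoms ride with the CA),
#'   or `"all_atoms"`.
#' @param amplitude_scale Angstrom of maximum nodal displacement at
#'   |dq| = 100.
#' @param nrbl accepted for config-file compatibility with rotation-
#'   translation-block solvers and ignored (modes are computed by exact
#'   diagonalization).
#' @return a validated list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_modes = 5L, dq_min = -100, dq_max = 100,
                            dq_step = 20, cutoff = 8, gamma = 1,
                            node_policy = c("heavy_atoms", "calpha",
                                            "all_atoms"),
                            amplitude_scale = 2.0, nrbl = NULL) {
  node_policy <- match.arg(node_policy)
  if (!(dq_min < dq_max)) stop("dq_min must be < dq_max")
  if (dq_step <= 0) stop("dq_step must be positive")
  nsteps <- (dq_max - dq_min) / dq_step
  if (abs(nsteps - round(nsteps)) > 1e-9) {
    stop("(dq_max - dq_min) must be a multiple of dq_step")
  }
  if (cutoff <= 0) stop("cutoff must be positive")
  if (n_modes < 1L) stop("n_modes must be >= 1")
  structure(
    list(n_modes = as.integer(n_modes), dq_min = dq_min, dq_max = dq_max,
         dq_step = dq_step, cutoff = cutoff, gamma = gamma,
         node_policy = node_policy, amplitude_scale = amplitude_scale),
    class = "ensemble_config"
  )
}

#' @export
print.ensemble_config <- function(x, ...) {
  cat(sprintf(
    "<ensemble_config> %d modes, dq %g..%g step %g, cutoff %g A, nodes %s, amplitude %g A\n",
    x$n_modes, x$dq_min, x$dq_max, x$dq_step, x$cutoff, x$node_policy,
    x$amplitude_scale))
  invisible(x)
}

#' dq grid of a configuration
#' @param config an `ensemble_config`.
#' @return numeric vector of dq values.
#' @export
dq_values <- function(config) {
  seq(config$dq_min, config$dq_max, by = config$dq_step)
}

# Map atoms to network nodes under a node policy. Returns list(
#   node_atoms: atom-row indices of the nodes,
#   atom_node:  for every atom, the node index it rides with).
select_nodes <- function(structure, node_policy) {
  at <- structure$atoms
  xyz <- coords(structure)
  if (node_policy == "all_atoms") {
    return(list(node_atoms = seq_len(nrow(at)), atom_node = seq_len(nrow(at))))
  }
  if (node_policy == "heavy_atoms") {
    node_atoms <- which(!at$is_hydrogen)
    atom_node <- integer(nrow(at))
    atom_node[node_atoms] <- seq_along(node_atoms)
    hyd <- which(at$is_hydrogen)
    if (length(hyd) > 0L) {
      heavy_xyz <- xyz[node_atoms, , drop = FALSE]
      for (h in hyd) {
        d2 <- colSums((t(heavy_xyz) - xyz[h, ])^2)
        atom_node[h] <- which.min(d2)  # bonded heavy atom is the nearest
      }
    }
    return(list(node_atoms = node_atoms, atom_node = atom_node))
  }
  # calpha: one node per residue at CA, plus each metal ion as its own node
  is_node <- (at$name == "CA" & !at$is_metal & !at$is_hydrogen) | at$is_metal
  node_atoms <- which(is_node)
  if (length(node_atoms) < 2L) stop("fewer than 2 CA/metal nodes")
  rkey <- paste(at$chain, at$resno, at$insert)
  node_of_res <- stats::setNames(seq_along(node_atoms)[!at$is_metal[node_atoms]],
                                 rkey[node_atoms[!at$is_metal[node_atoms]]])
  atom_node <- node_of_res[rkey]
  atom_node[node_atoms] <- seq_along(node_atoms)  # metals ride with themselves
  if (anyNA(atom_node)) {
    stop("residues without CA node: ",
         paste(unique(rkey[is.na(atom_node)]), collapse = ", "))
  }
  list(node_atoms = node_atoms, atom_node = unname(atom_node))
}

#' Build an anisotropic elastic-network model
#'
#' Nodes are selected by the configured node policy; every node pair
#' within the cutoff is connected by a Hookean spring of constant
#' `gamma`. The 3N x 3N Hessian carries the standard anisotropic
#' blocks: for a connected pair (i, j) the off-diagonal 3x3 block is
#' \eqn{-(\gamma / R_{ij}^2) (R_{ij} \otimes R_{ij})}, and diagonal
#' blocks are minus the sum of the row's off-diagonal blocks.
#'
#' @param structure an `enstab_structure`.
#' @param config an [ensemble_config()].
#' @return object of class `elastic_model`: node coordinates, the spring
#'   list, the Hessian, and the atom-to-node map.
#' @export
build_elastic_model <- function(structure, config = ensemble_config()) {
  sel <- select_nodes(structure, config$node_policy)
  xyz <- coords(structure)[sel$node_atoms, , drop = FALSE]
  n <- nrow(xyz)
  if (n < 2L) stop("need at least 2 network nodes")
  dmat <- as.matrix(stats::dist(xyz))
  adj <- dmat <= config$cutoff & upper.tri(dmat)
  pairs <- which(adj, arr.ind = TRUE)
  if (nrow(pairs) == 0L) {
    stop("elastic network disconnected at cutoff ", config$cutoff,
         ": no node pair within range (", n, " isolated nodes)")
  }
  comp <- igraph::components(igraph::graph_from_edgelist(pairs, directed = FALSE))
  if (comp$no > 1L || length(comp$membership) < n) {
    sizes <- if (length(comp$membership) < n) {
      c(comp$csize, rep(1L, n - length(comp$membership)))
    } else comp$csize
    stop("elastic network disconnected at cutoff ", config$cutoff, ": ",
         length(sizes), " components of sizes ",
         paste(sort(sizes, decreasing = TRUE), collapse = ", "))
  }
  hess <- matrix(0, 3L * n, 3L * n)
  gam <- config$gamma
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    rij <- xyz[j, ] - xyz[i, ]
    blk <- -(gam / sum(rij^2)) * tcrossprod(rij)
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    jj <- (3L * (j - 1L) + 1L):(3L * j)
    hess[ii, jj] <- hess[ii, jj] + blk
    hess[jj, ii] <- hess[jj, ii] + blk
    hess[ii, ii] <- hess[ii, ii] - blk
    hess[jj, jj] <- hess[jj, jj] - blk
  }
  at <- structure$atoms[sel$node_atoms, , drop = FALSE]
  nodes <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      name = at$name, is_metal = at$is_metal,
                      stringsAsFactors = FALSE)
  structure(
    list(coords = xyz, springs = data.frame(i = pairs[, 1L], j = pairs[, 2L],
                                            dist = dmat[pairs]),
         gamma = gam, hessian = hess, nodes = nodes,
         node_atoms = sel$node_atoms, atom_node = sel$atom_node,
         structure_id = structure$id),
    class = "elastic_model"
  )
}

#' Mode collectivity
#'
#' Entropy-based measure of how many nodes a mode displaces
#' appreciably: \eqn{\kappa = N^{-1} \exp(-\sum_i p_i \ln p_i)} where
#' \eqn{p_i} is the normalized squared displacement magnitude of node
#' i. 1 for a perfectly collective mode, 1/N for a single-node mode.
#'
#' @param mode 3N eigenvector.
#' @return collectivity in (0, 1].
#' @export
collectivity <- function(mode) {
  if (all(mode == 0)) stop("zero mode vector")
  m <- matrix(mode, ncol = 3L, byrow = TRUE)
  p <- rowSums(m^2)
  p <- p / sum(p)
  nz <- p > 0
  exp(-sum(p[nz] * log(p[nz]))) / length(p)
}

#' Normal modes of an elastic model
#'
#' Exact diagonalization of the Hessian. The six near-zero rigid-body
#' modes are excluded from the non-trivial set; non-trivial modes are
#' returned in ascending eigenvalue order, each with its collectivity.
#'
#' @param model an `elastic_model`.
#' @param n_nontrivial minimum number of non-trivial modes required
#'   (error if fewer are available). All non-trivial modes are stored.
#' @param zero_tol eigenvalues below `zero_tol * max(eigenvalue)` count
#'   as rigid-body modes.
#' @param allow_degenerate permit more than 6 near-zero modes (needed
#'   for deliberately degenerate geometries such as collinear chains);
#'   by default such geometries raise an error.
#' @return object of class `mode_set` with `values`, `vectors`
#'   (orthonormal columns), `collectivity`, `n_zero` and node metadata.
#' @export
compute_modes <- function(model, n_nontrivial = NULL, zero_tol = 1e-8,
                          allow_degenerate = FALSE) {
  eig <- eigen(model$hessian, symmetric = TRUE)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_along(eig$values)), drop = FALSE]
  lam_max <- max(vals)
  n_zero <- sum(vals < zero_tol * lam_max)
  if (n_zero > 6L && !allow_degenerate) {
    stop(n_zero, " near-zero modes (expected 6): disconnected network or ",
         "degenerate geometry")
  }
  if (n_zero >= length(vals)) stop("no non-trivial modes")
  keep <- seq.int(n_zero + 1L, length(vals))
  if (!is.null(n_nontrivial) && length(keep) < n_nontrivial) {
    stop("only ", length(keep), " non-trivial modes available, need ",
         n_nontrivial)
  }
  vectors <- vecs[, keep, drop = FALSE]
  structure(
    list(values = vals[keep], vectors = vectors,
         collectivity = apply(vectors, 2L, collectivity),
         n_zero = n_zero, nodes = model$nodes, coords = model$coords,
         gamma = model$gamma, structure_id = model$structure_id),
    class = "mode_set"
  )
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf(
    "<mode_set> %s: %d non-trivial modes (%d rigid-body excluded), lambda_1 = %.4g\n",
    x$structure_id, length(x$values), x$n_zero, x$values[1L]))
  invisible(x)
}

# Indices (into the non-trivial set) of the n modes with highest
# collectivity; ties broken toward lower frequency.
select_collective_modes <- function(modes, n) {
  if (length(modes$values) < n) {
    stop("only ", length(modes$values), " non-trivial modes, need ", n)
  }
  ord <- order(-modes$collectivity, seq_along(modes$values))
  sort(ord[seq_len(n)])
}

#' Generate a conformer ensemble along low-frequency modes
#'
#' Selects the `n_modes` non-trivial modes of highest collectivity and
#' displaces the structure along each over the dq grid. Each eigenvector
#' is rescaled so its largest nodal displacement is 1; a conformer at
#' perturbation dq then displaces that node by
#' `(dq/100) * amplitude_scale` Angstrom. Atoms that are not network
#' nodes (hydrogens, or side-chain atoms under the calpha policy) move
#' rigidly with the node they are attached to. The dq = 0 conformer of
#' every mode is the parent structure.
#'
#' @param structure the parent `enstab_structure`.
#' @param modes its `mode_set` (from [compute_modes()]).
#' @param config an [ensemble_config()].
#' @param model the `elastic_model` the modes came from (for the
#'   atom-to-node map); rebuilt from `structure` if omitted.
#' @return object of class `conformer_ensemble`: the parent id, a list
#'   of conformer structures, and a label table (mode rank, mode index,
#'   dq).
#' @export
generate_conformers <- function(structure, modes, config = ensemble_config(),
                                model = NULL) {
  if (is.null(model)) model <- build_elastic_model(structure, config)
  sel <- select_collective_modes(modes, config$n_modes)
  dqs <- dq_values(config)
  xyz0 <- coords(structure)
  conformers <- vector("list", length(sel) * length(dqs))
  labels <- data.frame(mode_rank = integer(0), mode_index = integer(0),
                       dq = numeric(0))
  k <- 0L
  for (r in seq_along(sel)) {
    u <- matrix(modes$vectors[, sel[r]], ncol = 3L, byrow = TRUE)
    u <- u / max(sqrt(rowSums(u^2)))          # unit maximum nodal displacement
    disp_atoms <- u[model$atom_node, , drop = FALSE]
    for (dq in dqs) {
      k <- k + 1L
      s <- set_coords(structure, xyz0 + (dq / 100) * config$amplitude_scale *
                        disp_atoms)
      s$id <- sprintf("%s|m%d|dq%+d", structure$id, sel[r], as.integer(dq))
      conformers[[k]] <- s
      labels[k, ] <- list(r, sel[r], dq)
    }
  }
  structure(
    list(parent_id = structure$id, conformers = conformers, labels = labels),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %s: %d conformers (%d modes x %d dq)\n",
              x$parent_id, length(x$conformers),
              length(unique(x$labels$mode_index)),
              length(unique(x$labels$dq))))
  invisible(x)
}

#' Correlate eigenvectors of two mode sets
#'
#' Validation of ensemble comparability across structures: for each of
#' the first k non-trivial modes (matched by rank), the absolute Pearson
#' correlation between the flattened eigenvector components. Absolute
#' value because eigenvector sign is a gauge freedom.
#'
#' @param modes_a,modes_b mode sets over equal-size networks with a
#'   common node ordering.
#' @param k number of mode pairs to compare.
#' @return numeric vector of k correlations in [0, 1].
#' @export
mode_correlation <- function(modes_a, modes_b, k = 5L) {
  if (nrow(modes_a$vectors) != nrow(modes_b$vectors)) {
    stop("mode sets come from networks of different size")
  }
  if (length(modes_a$values) < k || length(modes_b$values) < k) {
    stop("fewer than ", k, " non-trivial modes available")
  }
  vapply(seq_len(k), function(i) {
    abs(stats::cor(modes_a$vectors[, i], modes_b$vectors[, i]))
  }, numeric(1))
}
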