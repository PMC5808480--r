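# Shared fixtures and independent oracles used across the suite.

# A tiny hand-made structure: `n` atoms at given coordinates, all CA.
toy_atoms <- function(xyz, chain = "A", element = "C", name = "CA") {
  n <- nrow(xyz)
  as_structure(data.frame(
    serial = seq_len(n), name = name, element = element, resname = "GLY",
    resno = seq_len(n), insert = "", chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    hetatm = FALSE, stringsAsFactors = FALSE
  ), id = "toy")
}

# Random densely connected point cloud: N points uniform in a compact
# box (side ~3 n^(1/3)), resampled until no two points are closer than
# 2 A and the contact graph at 8 A is connected. Dense generic packing
# avoids the floppy transverse modes of tree-like spring topologies.
random_connected_coords <- function(n, cutoff = 8, spread = 3) {
  side <- spread * n^(1 / 3)
  repeat {
    xyz <- matrix(stats::runif(3 * n, 0, side), n, 3)
    d <- as.matrix(stats::dist(xyz))
    if (min(d[upper.tri(d)]) < 2) next
    adj <- d <= cutoff
    reach <- adj[1, ]
    for (k in seq_len(n)) reach <- reach | colSums(adj[reach, , drop = FALSE]) > 0
    if (all(reach)) return(xyz)
  }
}

elastic_from_coords <- function(xyz, cutoff = 8, gamma = 1) {
  build_elastic_model(toy_atoms(xyz), ensemble_config(cutoff = cutoff,
                                                      gamma = gamma,
                                                      node_policy = "calpha"))
}

# Independent Kabsch superposition (SVD), used as the oracle against
# the bio3d-backed implementation.
kabsch_rmsd_oracle <- function(xa, xb) {
  ca <- colMeans(xa); cb <- colMeans(xb)
  a <- sweep(xa, 2, ca); b <- sweep(xb, 2, cb)
  s <- svd(t(b) %*% a)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- a %*% t(r)  # rotate a onto b? keep consistent: rotate b onto a
  r2 <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  bf <- b %*% r2
  sqrt(mean(rowSums((a - bf)^2)))
}

# Pseudo-inverse force-response stiffness oracle: solve H x = f with
# paired unit forces along the pair axis, project out rigid modes,
# kappa = 1 / (n . (x_j - x_i)).
pinv_stiffness_oracle <- function(hessian, xyz, i, j) {
  n <- nrow(xyz)
  nij <- xyz[j, ] - xyz[i, ]
  nij <- nij / sqrt(sum(nij^2))
  f <- numeric(3 * n)
  f[(3 * (j - 1) + 1):(3 * j)] <- nij
  f[(3 * (i - 1) + 1):(3 * i)] <- -nij
  hp <- MASS::ginv(hessian)
  x <- hp %*% f
  xi <- x[(3 * (i - 1) + 1):(3 * i)]
  xj <- x[(3 * (j - 1) + 1):(3 * j)]
  1 / sum(nij * (xj - xi))
}

# A small protonated N-H ... O=C probe with controllable geometry.
hbond_probe <- function(no_dist = 2.9, angle = 170) {
  # donor N at origin, H along +x; acceptor O placed so that the
  # N-H-O angle at H equals `angle` and |N-O| = no_dist
  nh <- 1.0
  ang <- angle * pi / 180
  # O position: from H, direction making angle `ang` with H->N
  # vector; choose in xy-plane
  hn <- c(-1, 0, 0)
  dir <- c(cos(ang) * hn[1] - sin(ang) * hn[2],
           sin(ang) * hn[1] + cos(ang) * hn[2], 0)
  # distance H-O solving |N-O| = no_dist with N = (0,0,0), H = (1,0,0)*nh
  # parametrize O = H + t*dir, find t > 0 with |O| = no_dist
  h <- c(nh, 0, 0)
  tt <- stats::uniroot(function(t) sqrt(sum((h + t * dir)^2)) - no_dist,
                       c(0.1, 6))$root
  o <- h + tt * dir
  as_structure(data.frame(
    serial = 1:4,
    name = c("N", "H", "C", "O"),
    element = c("N", "H", "C", "O"),
    resname = "GLY", resno = c(1L, 1L, 5L, 5L), insert = "",
    chain = "A",
    x = c(0, h[1], o[1] + 1.2, o[1]),
    y = c(0, h[2], o[2], o[2]),
    z = c(0, h[3], o[3], o[3]),
    hetatm = FALSE, stringsAsFactors = FALSE
  ), id = "probe")
}

# Direct brute-force two-sample KS statistic.
ks_stat_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- vapply(grid, function(g) mean(a <= g), 1)
  fb <- vapply(grid, function(g) mean(b <= g), 1)
  max(abs(fa - fb))
}

# All simple paths between two vertices on a small graph; returns the
# best bottleneck value (widest-path oracle).
widest_path_oracle <- function(edges, weights, from, to, n) {
  wmat <- matrix(-Inf, n, n)
  for (e in seq_len(nrow(edges))) {
    wmat[edges[e, 1], edges[e, 2]] <- weights[e]
    wmat[edges[e, 2], edges[e, 1]] <- weights[e]
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  paths <- igraph::all_simple_paths(g, from, to)
  best <- -Inf
  for (p in paths) {
    v <- as.integer(p)
    best <- max(best, min(wmat[cbind(v[-length(v)], v[-1])]))
  }
  best
}
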