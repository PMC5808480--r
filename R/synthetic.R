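# Synthetic inputs for every stage: idealized backbone structures built
# from internal coordinates, locally perturbed variants, stability tables
# with planted shifted bonds, and survival tables with a planted linear
# stiffness dependence.

# Run an expression under a fixed RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Place atom D given A-B-C with bond |CD|, angle B-C-D (deg) and
# dihedral A-B-C-D (deg): natural extension reference frame.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

pracma_cross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

# Backbone dihedral tables per geometry.
backbone_dihedrals <- function(n_res, geometry) {
  if (geometry == "helix") {
    # dihedrals chosen so the ideal i -> i+4 amide-carbonyl geometry
    # (N..O ~2.86 A, N-H..O ~162 deg) clears the default bond criteria
    return(data.frame(phi = rep(-62.0, n_res), psi = rep(-47.0, n_res)))
  }
  # antiparallel beta strand
  data.frame(phi = rep(-139, n_res), psi = rep(135, n_res))
}

# Rotation taking unit vector d onto unit vector z (Rodrigues).
rotation_onto <- function(d, z) {
  v <- pracma_cross(d, z)
  s2 <- sum(v^2)
  if (s2 < 1e-12) return(diag(3) * sign(sum(d * z)))
  vx <- matrix(c(0, -v[3L], v[2L], v[3L], 0, -v[1L], -v[2L], v[1L], 0),
               3L, 3L, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - sum(d * z)) / s2)
}

build_backbone_chain <- function(n_res, geometry, chain_id) {
  if (geometry == "sheet_hairpin") {
    return(build_hairpin_chain(n_res, chain_id))
  }
  dih <- backbone_dihedrals(n_res, geometry)
  # ideal backbone internal coordinates (lengths A, angles deg)
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_c_o <- 1.231
  b_n_h <- 1.01
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7
  a_ca_c_o <- 120.5; a_c_n_h <- 119.3
  N <- matrix(NA_real_, n_res, 3L)
  CA <- N; C <- N; O <- N; H <- N
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(b_n_ca, 0, 0)
  ang <- a_n_ca_c * pi / 180
  C[1L, ] <- CA[1L, ] + b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                           b_c_n, a_ca_c_n, dih$psi[i - 1L])
      CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                            b_n_ca, a_c_n_ca, 180)      # omega trans
      C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                           b_ca_c, a_n_ca_c, dih$phi[i])
      # amide H in the peptide plane, trans to the carbonyl O
      H[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                           b_n_h, a_c_n_h, 0)
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], b_c_o, a_ca_c_o,
                         dih$psi[i] + 180)
  }
  H[1L, ] <- place_atom(C[1L, ], CA[1L, ], N[1L, ], b_n_h, 114, 180)
  rows <- list()
  for (i in seq_len(n_res)) {
    rows[[i]] <- data.frame(
      name = c("N", "H", "CA", "C", "O"),
      element = c("N", "H", "C", "C", "O"),
      resname = "GLY", resno = i, insert = "", chain = chain_id,
      x = c(N[i, 1L], H[i, 1L], CA[i, 1L], C[i, 1L], O[i, 1L]),
      y = c(N[i, 2L], H[i, 2L], CA[i, 2L], C[i, 2L], O[i, 2L]),
      z = c(N[i, 3L], H[i, 3L], CA[i, 3L], C[i, 3L], O[i, 3L]),
      hetatm = FALSE, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# Two antiparallel beta strands at sheet geometry. The second strand is
# the first rotated 180 degrees about the sheet normal's perpendicular
# and offset laterally; the placement (spin 170 deg, offset 4.65 /
# -2.9 A) was chosen once to maximize the inter-strand amide-carbonyl
# rung count at the default bond criteria (~n/2 - 2 bonds). The two
# strands share a chain id and contiguous numbering; they are joined
# elastically (by the distance cutoff), not covalently.
build_hairpin_chain <- function(n_res, chain_id) {
  n1 <- ceiling(n_res / 2)
  n2 <- n_res - n1
  base <- build_backbone_chain(n1, "strand", chain_id)
  xyz <- as.matrix(base[, c("x", "y", "z")])
  ca <- xyz[base$name == "CA", , drop = FALSE]
  d <- ca[n1, ] - ca[1L, ]
  r <- rotation_onto(d / sqrt(sum(d^2)), c(0, 0, 1))
  x1 <- xyz %*% t(r)
  x1 <- sweep(x1, 2L, colMeans(x1))
  s1 <- base
  s1$x <- x1[, 1L]; s1$y <- x1[, 2L]; s1$z <- x1[, 3L]
  if (n2 == 0L) return(s1)
  th <- 170 * pi / 180
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3L, 3L, byrow = TRUE)
  keep <- base$resno <= n2
  x2 <- x1[keep, , drop = FALSE] %*% t(diag(c(-1, 1, -1))) %*% t(rz)
  x2 <- sweep(x2, 2L, c(0, 4.65, -2.9), "+")
  s2 <- base[keep, , drop = FALSE]
  s2$resno <- s2$resno + n1
  s2$x <- x2[, 1L]; s2$y <- x2[, 2L]; s2$z <- x2[, 3L]
  rbind(s1, s2)
}

#' Specification of a synthetic toy structure
#'
#' @param n_res_per_chain residues per chain (>= 4).
#' @param n_chains number of chains (default 2; ids A, B, C, ...).
#' @param geometry `"helix"` or `"sheet_hairpin"`.
#' @param metal_sites list of `list(chain =, residues =, element =)`
#'   entries; each metal is placed at the centroid of the CA atoms of
#'   its coordinating residues (element defaults to `"CU"`).
#' @param seed integer seed (the backbone build is deterministic; the
#'   seed is recorded and used by downstream perturbations).
#' @return list of class `toy_spec`.
#' @export
toy_spec <- function(n_res_per_chain = 12L, n_chains = 2L,
                     geometry = c("helix", "sheet_hairpin"),
                     metal_sites = list(), seed = 1L) {
  geometry <- match.arg(geometry)
  if (n_res_per_chain < 4L) stop("n_res_per_chain must be >= 4")
  structure(
    list(n_res_per_chain = as.integer(n_res_per_chain),
         n_chains = as.integer(n_chains), geometry = geometry,
         metal_sites = metal_sites, seed = as.integer(seed)),
    class = "toy_spec"
  )
}

#' Build a synthetic backbone structure
#'
#' Chains are ideal backbones (N, H, CA, C, O per residue) built from
#' standard internal coordinates: an alpha-helix (phi/psi -62/-47,
#' giving the i -> i+4 amide-carbonyl bonds) or a beta-hairpin. For
#' multi-chain specs, successive chains are copies rotated 180 degrees
#' and packed side by side with an interface gap under the elastic
#' cutoff, so the dimer network is connected. Metal atoms are placed at
#' the centroid of their coordinating residues' CA positions (nudged
#' off any clash). Fully deterministic for a fixed spec.
#'
#' @param spec a [toy_spec()].
#' @return an `enstab_structure` with id `"toy_<geometry><n>x<chains>"`.
#' @export
make_toy_structure <- function(spec = toy_spec()) {
  base <- build_backbone_chain(spec$n_res_per_chain, spec$geometry, "A")
  chains <- list(base)
  if (spec$n_chains > 1L) {
    xyz <- as.matrix(base[, c("x", "y", "z")])
    rot <- xyz %*% diag(c(-1, -1, 1))          # 180 deg about z
    # pack successive chains along x so the nearest inter-chain atom
    # pair sits at ~4.6 A: inside the elastic cutoff (connected dimer
    # network) but outside clash range
    min_cross <- function(a, b) {
      m <- Inf
      for (i in seq_len(nrow(a))) {
        m <- min(m, min(colSums((t(b) - a[i, ])^2)))
      }
      sqrt(m)
    }
    gap_at <- function(t) {
      shifted <- rot
      shifted[, 1L] <- shifted[, 1L] + t
      min_cross(xyz, shifted)
    }
    tt <- max(xyz[, 1L]) - min(rot[, 1L]) - 5
    while (gap_at(tt) < 4.6) tt <- tt + 0.1
    while (gap_at(tt - 0.1) >= 4.6) tt <- tt - 0.1
    prev_shift <- 0
    for (c_i in 2:spec$n_chains) {
      prev_shift <- prev_shift + tt
      cp <- base
      cp$chain <- LETTERS[c_i]
      shifted <- if (c_i %% 2L == 0L) rot else xyz
      cp$x <- shifted[, 1L] + prev_shift
      cp$y <- shifted[, 2L]; cp$z <- shifted[, 3L]
      chains[[c_i]] <- cp
    }
  }
  atoms <- do.call(rbind, chains)
  for (ms in spec$metal_sites) {
    el <- toupper(if (is.null(ms$element)) "CU" else ms$element)
    ca <- atoms$name == "CA" & atoms$chain == ms$chain &
      atoms$resno %in% ms$residues
    if (!any(ca)) {
      stop("metal site on chain ", ms$chain, " has no coordinating residues")
    }
    pos <- colMeans(atoms[ca, c("x", "y", "z")])
    xyz_all <- as.matrix(atoms[, c("x", "y", "z")])
    dmin <- sqrt(min(colSums((t(xyz_all) - pos)^2)))
    if (dmin < 1.5) pos <- pos + (1.5 - dmin) * c(0, 0, 1)  # nudge off clash
    atoms <- rbind(atoms, data.frame(
      name = el, element = el, resname = el,
      resno = max(atoms$resno[atoms$chain == ms$chain]) + 100L,
      insert = "", chain = ms$chain,
      x = pos[1L], y = pos[2L], z = pos[3L], hetatm = TRUE,
      stringsAsFactors = FALSE
    ))
  }
  # group atoms by chain (metals next to their chain) so the stored
  # order matches chain-block PDB layout
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain))), ,
                 drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  as_structure(atoms, id = sprintf("toy_%s%dx%d", spec$geometry,
                                   spec$n_res_per_chain, spec$n_chains))
}

#' Perturb selected residues of a structure
#'
#' Gaussian coordinate noise (sd `sigma` Angstrom, per axis) applied to
#' every atom of the listed residues; all other atoms are untouched. A
#' deterministic stand-in for structurally relaxed point variants.
#'
#' @param structure parent `enstab_structure`.
#' @param positions residue numbers to perturb (all chains, unless
#'   given as `"resno.chain"` labels).
#' @param sigma noise level, Angstrom.
#' @param seed integer seed.
#' @param id identifier for the variant (default derived from parent).
#' @return a perturbed `enstab_structure`.
#' @export
make_variant <- function(structure, positions, sigma, seed,
                         id = NULL) {
  at <- structure$atoms
  if (length(positions) == 0L) {
    warning("no positions to perturb; returning an identical copy")
    sel <- logical(nrow(at))
  } else if (is.character(positions)) {
    sel <- paste0(at$resno, ".", at$chain) %in% positions
  } else {
    sel <- at$resno %in% positions
  }
  if (length(positions) > 0L && !any(sel)) {
    stop("no atoms at positions ", paste(positions, collapse = ", "))
  }
  out <- structure
  if (any(sel) && sigma > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(3L * sum(sel), 0, sigma),
                                    ncol = 3L))
    out$atoms$x[sel] <- at$x[sel] + noise[, 1L]
    out$atoms$y[sel] <- at$y[sel] + noise[, 2L]
    out$atoms$z[sel] <- at$z[sel] + noise[, 3L]
  }
  out$id <- if (is.null(id)) {
    sprintf("%s_var%s_s%d", structure$id,
            paste(utils::head(positions, 3L), collapse = "-"), seed)
  } else id
  out
}

#' Specification for a directly generated stability table
#'
#' @param n_bonds number of bond rows.
#' @param n_variants number of variant columns (plus one WT column).
#' @param planted_bonds number (or indices) of bonds whose occupancy is
#'   shifted in the planted variants.
#' @param planted_variants number (or indices) of variants carrying the
#'   shift.
#' @param delta occupancy shift in (0, 1].
#' @param background_sigma sd of the background occupancy noise (warned
#'   if `delta <= 2 * background_sigma`: shift not clearly detectable).
#' @param n_conformers grid denominator (default 55; all values are
#'   multiples of 1/55).
#' @param seed integer seed.
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(n_bonds = 200L, n_variants = 9L, planted_bonds = 5L,
                       planted_variants = NULL, delta = 0.4,
                       background_sigma = 0.02, n_conformers = 55L,
                       seed = 1L) {
  if (delta <= 0 || delta > 1) stop("delta must lie in (0, 1]")
  if (length(planted_bonds) == 1L && planted_bonds > n_bonds) {
    stop("more planted bonds than bonds")
  }
  if (delta <= 2 * background_sigma) {
    warning("delta <= 2 * background_sigma: planted shift may be ",
            "indistinguishable from noise")
  }
  if (is.null(planted_variants)) planted_variants <- n_variants
  structure(
    list(n_bonds = as.integer(n_bonds), n_variants = as.integer(n_variants),
         planted_bonds = planted_bonds, planted_variants = planted_variants,
         delta = delta, background_sigma = background_sigma,
         n_conformers = as.integer(n_conformers), seed = as.integer(seed)),
    class = "plant_spec"
  )
}

#' Simulate a SEA table with planted shifted bonds
#'
#' The WT column is drawn uniformly from the occupancy grid
#' (multiples of `1/n_conformers`); every variant entry is the WT value
#' plus grid-rounded Gaussian noise (sd `background_sigma`). For the
#' planted (bond, variant) pairs, the occupancy is additionally shifted
#' by `delta` away from its WT value (downward when the WT occupancy is
#' at least 0.5, upward otherwise), then clipped to [0, 1]. The ground
#' truth is returned next to the table, never embedded in it.
#'
#' @param plant a [plant_spec()].
#' @return list with `sea` (a `sea_table`, WT column `"WT"`) and
#'   `truth` (planted bond keys and variant ids).
#' @export
simulate_sea_table <- function(plant = plant_spec()) {
  grid <- function(x) {
    pmin(1, pmax(0, round(x * plant$n_conformers) / plant$n_conformers))
  }
  with_seed(plant$seed, {
    nb <- plant$n_bonds
    nv <- plant$n_variants
    bonds <- sprintf("bond_%03d", seq_len(nb))
    variants <- sprintf("VAR%02d", seq_len(nv))
    pb <- if (length(plant$planted_bonds) == 1L) {
      sample.int(nb, plant$planted_bonds)
    } else plant$planted_bonds
    pv <- if (length(plant$planted_variants) == 1L) {
      seq_len(plant$planted_variants)
    } else plant$planted_variants
    wt <- sample.int(plant$n_conformers + 1L, nb, replace = TRUE) - 1L
    wt <- wt / plant$n_conformers
    vals <- matrix(0, nb, nv + 1L,
                   dimnames = list(bonds, c("WT", variants)))
    vals[, "WT"] <- wt
    for (v in seq_len(nv)) {
      x <- wt + stats::rnorm(nb, 0, plant$background_sigma)
      if (v %in% pv) {
        shift <- ifelse(wt[pb] >= 0.5, -plant$delta, plant$delta)
        x[pb] <- wt[pb] + shift
      }
      vals[, v + 1L] <- grid(x)
    }
    list(
      sea = new_sea_table(vals, "WT",
                          stats::setNames(rep(plant$n_conformers, nv + 1L),
                                          colnames(vals))),
      truth = list(planted_bonds = bonds[sort(pb)],
                   planted_variants = variants[sort(pv)],
                   delta = plant$delta, seed = plant$seed)
    )
  })
}

#' Simulate survival times from a stiffness profile
#'
#' Linear model with Gaussian noise:
#' \eqn{s_m = a + b \kappa_m + \epsilon}, \eqn{\epsilon \sim N(0,
#' \sigma^2)}, truncated below at 0.1 years.
#'
#' @param stiffness named numeric vector (variant -> stiffness value).
#' @param a intercept, years.
#' @param b slope, years per stiffness unit.
#' @param sigma noise sd, years.
#' @param seed integer seed.
#' @return list with `table` (data frame `mutation`, `years`) and
#'   `truth` (the generating parameters).
#' @export
simulate_survival <- function(stiffness, a, b, sigma, seed = 1L) {
  if (length(stiffness) < 3L) stop("need at least 3 variants")
  years <- with_seed(seed, {
    pmax(0.1, a + b * stiffness + stats::rnorm(length(stiffness), 0, sigma))
  })
  list(
    table = data.frame(mutation = names(stiffness), years = unname(years),
                       stringsAsFactors = FALSE),
    truth = list(a = a, b = b, sigma = sigma, seed = seed)
  )
}
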