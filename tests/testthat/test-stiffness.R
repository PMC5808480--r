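stiffness_of <- function(xyz, cutoff = 8, allow_degenerate = FALSE,
                         gamma = 1) {
  m <- elastic_from_coords(xyz, cutoff = cutoff, gamma = gamma)
  pairwise_stiffness(compute_modes(m, allow_degenerate = allow_degenerate))
}

test_that("a single spring has effective stiffness gamma", {
  xyz <- matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)
  k <- stiffness_of(xyz, allow_degenerate = TRUE)  # 2 nodes: 5 rigid modes
  expect_equal(k$kappa[1, 2], 1, tolerance = 1e-9)
  k3 <- stiffness_of(xyz, allow_degenerate = TRUE, gamma = 3)
  expect_equal(k3$kappa[1, 2], 3, tolerance = 1e-9)
})

test_that("collinear chains follow the series-spring law", {
  # nearest-neighbour springs only: end-to-end kappa = gamma / (n - 1)
  for (n in c(3, 5, 8)) {
    xyz <- cbind(3.5 * (seq_len(n) - 1), 0, 0)
    k <- stiffness_of(xyz, cutoff = 4, allow_degenerate = TRUE)
    expect_equal(k$kappa[1, n], 1 / (n - 1), tolerance = 1e-9)
  }
})

test_that("mode-sum stiffness equals the pseudo-inverse force oracle", {
  withr::local_seed(19)
  for (rep in 1:50) {
    xyz <- random_connected_coords(sample(6:12, 1))
    model <- elastic_from_coords(xyz)
    k <- pairwise_stiffness(compute_modes(model))
    n <- nrow(xyz)
    pairs <- matrix(c(1, n, sample.int(n, 2)), 2, 2, byrow = TRUE)
    for (p in 1:2) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      if (i == j) next
      oracle <- pinv_stiffness_oracle(model$hessian, xyz, i, j)
      expect_equal(k$kappa[i, j], oracle, tolerance = 1e-6)
    }
    # symmetry
    expect_equal(k$kappa, t(k$kappa), tolerance = 1e-9)
  }
})

test_that("adding a spring never decreases any pairwise stiffness", {
  withr::local_seed(23)
  for (rep in 1:20) {
    xyz <- random_connected_coords(8)
    m <- elastic_from_coords(xyz)
    k0 <- pairwise_stiffness(compute_modes(m))$kappa
    # augment: connect the currently farthest pair with an extra spring
    d <- as.matrix(stats::dist(xyz))
    far <- which(d == max(d), arr.ind = TRUE)[1, ]
    i <- far[1]; j <- far[2]
    rij <- xyz[j, ] - xyz[i, ]
    blk <- -(1 / sum(rij^2)) * tcrossprod(rij)
    h2 <- m$hessian
    ii <- (3 * (i - 1) + 1):(3 * i); jj <- (3 * (j - 1) + 1):(3 * j)
    h2[ii, jj] <- h2[ii, jj] + blk
    h2[jj, ii] <- h2[jj, ii] + blk
    h2[ii, ii] <- h2[ii, ii] - blk
    h2[jj, jj] <- h2[jj, jj] - blk
    m2 <- m
    m2$hessian <- h2
    k1 <- pairwise_stiffness(compute_modes(m2))$kappa
    off <- upper.tri(k0)
    expect_true(all(k1[off] >= k0[off] * (1 - 1e-9)))
  }
})

test_that("mode truncation only stiffens (dropped compliance is positive)", {
  withr::local_seed(29)
  xyz <- random_connected_coords(10)
  modes <- compute_modes(elastic_from_coords(xyz))
  k_all <- pairwise_stiffness(modes)$kappa
  k_few <- pairwise_stiffness(modes, modes_used = 5)$kappa
  off <- upper.tri(k_all)
  expect_true(all(k_few[off] >= k_all[off] * (1 - 1e-9)))
})

test_that("mean stiffness equals hand-computed row means over finite partners", {
  xyz <- matrix(c(0, 0, 0, 4, 0, 0, 0, 4.5, 0, 2, 2, 3.5), 4, 3,
                byrow = TRUE)
  k <- stiffness_of(xyz)
  kb <- mean_stiffness(k)
  for (i in 1:4) {
    v <- k$kappa[i, -i]
    expect_equal(unname(kb[i]), mean(v[is.finite(v)]), tolerance = 1e-12)
  }
})

test_that("a symmetric dimer gives chain-symmetric summaries", {
  s <- make_toy_structure(toy_spec(n_res_per_chain = 10, n_chains = 2))
  model <- build_elastic_model(s, ensemble_config(node_policy = "calpha"))
  k <- pairwise_stiffness(compute_modes(model))
  kb <- mean_stiffness(k)
  a <- kb[grepl("\\.A$", names(kb))]
  b <- kb[grepl("\\.B$", names(kb))]
  expect_equal(unname(a), unname(b), tolerance = 1e-6)
})

test_that("site profiles require an existing node and respond to coupling", {
  # a metal within the cutoff of a single residue couples maximally to it
  at <- data.frame(
    serial = 1:5,
    name = c("CA", "CA", "CA", "CA", "CU"),
    element = c("C", "C", "C", "C", "CU"),
    resname = c(rep("GLY", 4), "CU"), resno = c(1:4, 101L), insert = "",
    chain = "A",
    x = c(0, 5, 10, 15, -4), y = c(0, 2, 0, 2, 0), z = 0,
    hetatm = c(rep(FALSE, 4), TRUE), stringsAsFactors = FALSE
  )
  s <- as_structure(at, "metal_toy")
  model <- build_elastic_model(s, ensemble_config(cutoff = 6,
                                                  node_policy = "calpha"))
  k <- pairwise_stiffness(compute_modes(model, allow_degenerate = TRUE))
  expect_error(site_stiffness_profile(k, "FE:A"), "CU:A")
  prof <- site_stiffness_profile(k, "CU:A")
  expect_false("CU:A" %in% names(prof))
  fin <- prof[is.finite(prof)]
  expect_equal(names(which.max(fin)), "1.A")
})

test_that("tail extraction follows order statistics with tie inclusion", {
  v <- stats::setNames(as.numeric(1:1000), sprintf("k%04d", 1:1000))
  expect_setequal(top_tail(v, 0.005), sprintf("k%04d", 996:1000))
  # as the fraction approaches 1 the threshold slides to the minimum
  expect_gte(length(top_tail(v, 0.999)), 999L)
  expect_length(top_tail(stats::setNames(rep(2, 7), letters[1:7]), 0.5), 7L)
  vt <- stats::setNames(c(1, 2, 3, 3), c("a", "b", "c", "d"))
  expect_setequal(top_tail(vt, 0.26), c("c", "d"))  # ties both included
  expect_error(top_tail(v, 0), "fraction")
})

test_that("the transmission path is the widest path on the contact graph", {
  # linear chain: the unique path is the chain itself
  xyz <- cbind(3.5 * (0:4), 0, 0)
  k <- stiffness_of(xyz, cutoff = 4, allow_degenerate = TRUE)
  lab <- rownames(k$kappa)
  p <- transmission_path(k, lab[1], lab[5], contact_cutoff = 4)
  expect_equal(as.character(p), lab)
  # reversal gives the reverse sequence
  p_rev <- transmission_path(k, lab[5], lab[1], contact_cutoff = 4)
  expect_equal(as.character(p_rev), rev(lab))
})

test_that("widest paths match brute-force enumeration on random toys", {
  withr::local_seed(37)
  for (rep in 1:10) {
    xyz <- random_connected_coords(8)
    model <- elastic_from_coords(xyz)
    k <- pairwise_stiffness(compute_modes(model))
    dmat <- as.matrix(stats::dist(xyz))
    contact <- dmat <= 8 & upper.tri(dmat)
    pairs <- which(contact, arr.ind = TRUE)
    w <- k$kappa[pairs]
    fin <- is.finite(w)
    p <- transmission_path(k, rownames(k$kappa)[1], rownames(k$kappa)[8])
    oracle <- widest_path_oracle(pairs[fin, , drop = FALSE], w[fin], 1, 8, 8)
    expect_equal(attr(p, "bottleneck"), oracle, tolerance = 1e-9)
  }
})

test_that("site mean stiffness averages the sample it returns", {
  xyz <- matrix(c(0, 0, 0, 4, 0, 0, 0, 4.5, 0, 2, 2, 3.5, 4, 4, 2), 5, 3,
                byrow = TRUE)
  k <- stiffness_of(xyz)
  lab <- rownames(k$kappa)
  r <- site_mean_stiffness(k, lab[1], lab[2:4])
  expect_length(r$sample, 3L)
  expect_equal(r$mean, mean(r$sample), tolerance = 1e-12)
  expect_error(site_mean_stiffness(k, lab[1], lab[1:3]), "overlap")
  # degenerate single-element set
  r1 <- site_mean_stiffness(k, lab[1], lab[2])
  expect_equal(r1$mean, unname(k$kappa[lab[1], lab[2]]))
})

test_that("stiffness profiles can be exported as B-factors", {
  s <- make_toy_structure(toy_spec(n_res_per_chain = 6, n_chains = 1))
  model <- build_elastic_model(s, ensemble_config(node_policy = "calpha"))
  k <- pairwise_stiffness(compute_modes(model))
  kb <- mean_stiffness(k)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_stiffness_pdb(s, kb, tmp)
  lines <- readLines(tmp)
  b <- as.numeric(substr(lines[grepl("^ATOM", lines)], 61, 66))
  expect_true(all(is.finite(b)))
  expect_gt(max(b), 0)
})
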