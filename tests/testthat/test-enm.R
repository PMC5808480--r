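test_that("ensemble configuration validates its grid", {
  expect_error(ensemble_config(dq_min = 10, dq_max = -10), "dq_min")
  expect_error(ensemble_config(dq_step = -1), "dq_step")
  expect_error(ensemble_config(dq_min = 0, dq_max = 10, dq_step = 3),
               "multiple")
  expect_equal(dq_values(ensemble_config()), seq(-100, 100, 20))
})

test_that("a single spring gives the textbook rank-1 Hessian", {
  xyz <- matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)
  m <- elastic_from_coords(xyz)
  expect_equal(nrow(m$springs), 1L)
  ev <- eigen(m$hessian, symmetric = TRUE)$values
  expect_equal(sum(ev > 1e-10), 1L)           # rank 1
  expect_equal(max(ev), 2, tolerance = 1e-12) # 2*gamma for the stretch pair
})

test_that("nodes beyond the cutoff leave the network disconnected", {
  xyz <- matrix(c(0, 0, 0, 9, 0, 0), 2, 3, byrow = TRUE)
  expect_error(elastic_from_coords(xyz, cutoff = 8), "disconnected")
})

test_that("Hessian row-block sums vanish (translational invariance)", {
  withr::local_seed(42)
  xyz <- random_connected_coords(10)
  m <- elastic_from_coords(xyz)
  n <- nrow(xyz)
  for (i in seq_len(n)) {
    ii <- (3 * (i - 1) + 1):(3 * i)
    blocksum <- matrix(0, 3, 3)
    for (j in seq_len(n)) {
      jj <- (3 * (j - 1) + 1):(3 * j)
      blocksum <- blocksum + m$hessian[ii, jj]
    }
    expect_equal(blocksum, matrix(0, 3, 3), tolerance = 1e-10)
  }
  # spring blocks match the ANM closed form
  s <- m$springs[1, ]
  rij <- xyz[s$j, ] - xyz[s$i, ]
  blk <- -(1 / sum(rij^2)) * tcrossprod(rij)
  ii <- (3 * (s$i - 1) + 1):(3 * s$i)
  jj <- (3 * (s$j - 1) + 1):(3 * s$j)
  expect_equal(m$hessian[ii, jj], blk, tolerance = 1e-12)
})

test_that("Hessian is PSD with exactly 6 rigid-body modes on random toys", {
  withr::local_seed(7)
  for (rep in 1:100) {
    xyz <- random_connected_coords(sample(4:12, 1))
    m <- elastic_from_coords(xyz)
    ev <- eigen(m$hessian, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
    expect_equal(sum(ev < 1e-8 * max(ev)), 6L)
  }
})

test_that("mode eigenvalues match an independent solver on a toy chain", {
  # a 2-spring chain is floppy beyond its rigid-body modes (transverse
  # pivots carry no ANM energy), so degenerate geometry is permitted
  xyz <- matrix(c(0, 0, 0, 3.8, 0.4, 0, 7.4, 0, 0.6), 3, 3, byrow = TRUE)
  m <- elastic_from_coords(xyz, cutoff = 4)
  modes <- compute_modes(m, allow_degenerate = TRUE)
  oracle <- sort(eigen(m$hessian, symmetric = TRUE)$values)
  expect_equal(modes$values, oracle[oracle > 1e-8 * max(oracle)],
               tolerance = 1e-10)
  v <- modes$vectors
  expect_equal(t(v) %*% v, diag(ncol(v)), tolerance = 1e-8)
  expect_error(compute_modes(m), "degenerate")
})

test_that("translating the structure leaves eigenvalues unchanged", {
  withr::local_seed(3)
  xyz <- random_connected_coords(8)
  v1 <- compute_modes(elastic_from_coords(xyz))$values
  v2 <- compute_modes(elastic_from_coords(sweep(xyz, 2, c(12, -5, 3),
                                                "+")))$values
  expect_equal(v1, v2, tolerance = 1e-8 * max(v1))
})

test_that("collectivity matches its closed forms", {
  n <- 8
  uniform <- rep(1 / sqrt(3 * n), 3 * n)
  expect_equal(collectivity(uniform), 1, tolerance = 1e-12)
  point <- c(1, rep(0, 3 * n - 1))
  expect_equal(collectivity(point), 1 / n, tolerance = 1e-12)
  # N = 4 with p = (1/2, 1/2, 0, 0): kappa = exp(ln 2) / 4 = 0.5
  v <- c(sqrt(0.5), 0, 0, sqrt(0.5), 0, 0, rep(0, 6))
  expect_equal(collectivity(v), 0.5, tolerance = 1e-12)
  expect_error(collectivity(rep(0, 12)), "zero")
})

test_that("ensemble size follows the dq grid and dq = 0 reproduces the parent", {
  s <- make_toy_structure(toy_spec(n_res_per_chain = 8, n_chains = 1))
  cfg <- ensemble_config()
  model <- build_elastic_model(s, cfg)
  modes <- compute_modes(model, cfg$n_modes)
  ens <- generate_conformers(s, modes, cfg, model = model)
  expect_length(ens$conformers, 55L)
  zero <- which(ens$labels$dq == 0)
  expect_length(zero, 5L)
  for (k in zero) expect_equal(coords(ens$conformers[[k]]), coords(s))

  cfg2 <- ensemble_config(n_modes = 3, dq_min = -30, dq_max = 30,
                          dq_step = 15)
  ens2 <- generate_conformers(s, modes, cfg2, model = model)
  expect_length(ens2$conformers, 3 * 5)
})

test_that("ensemble size is n_modes x n_dq for arbitrary valid configs", {
  s <- make_toy_structure(toy_spec(n_res_per_chain = 6, n_chains = 1))
  model <- build_elastic_model(s, ensemble_config())
  modes <- compute_modes(model)
  withr::local_seed(5)
  for (rep in 1:5) {
    nm <- sample(1:4, 1)
    step <- sample(c(10, 20, 25, 50), 1)
    cfg <- ensemble_config(n_modes = nm, dq_min = -100, dq_max = 100,
                           dq_step = step)
    ens <- generate_conformers(s, modes, cfg, model = model)
    expect_length(ens$conformers, nm * (200 / step + 1))
  }
})

test_that("displacement at |dq| = 100 equals the amplitude scale", {
  s <- make_toy_structure(toy_spec(n_res_per_chain = 8, n_chains = 1))
  cfg <- ensemble_config(amplitude_scale = 2.0)
  model <- build_elastic_model(s, cfg)
  modes <- compute_modes(model, cfg$n_modes)
  ens <- generate_conformers(s, modes, cfg, model = model)
  ext <- which(ens$labels$dq == 100)
  for (k in ext) {
    disp <- sqrt(rowSums((coords(ens$conformers[[k]]) - coords(s))^2))
    expect_equal(max(disp), 2.0, tolerance = 1e-9)
  }
})

test_that("mode correlations are 1 for identical models and gauge-invariant", {
  s <- make_toy_structure(toy_spec(n_res_per_chain = 8, n_chains = 1))
  model <- build_elastic_model(s, ensemble_config())
  modes <- compute_modes(model, 5)
  expect_equal(mode_correlation(modes, modes, 5), rep(1, 5))
  flipped <- modes
  flipped$vectors <- -flipped$vectors
  expect_equal(mode_correlation(modes, flipped, 5), rep(1, 5))
})

test_that("a small perturbation leaves the first mode highly correlated", {
  s <- make_toy_structure(toy_spec(n_res_per_chain = 10, n_chains = 1))
  v <- make_variant(s, positions = 5, sigma = 0.1, seed = 21)
  ma <- compute_modes(build_elastic_model(s, ensemble_config()))
  mb <- compute_modes(build_elastic_model(v, ensemble_config()))
  r <- mode_correlation(ma, mb, 1)
  expect_gt(r[1], 0.9)
  expect_lte(r[1], 1)
})
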