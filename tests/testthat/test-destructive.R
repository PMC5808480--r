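make_sea <- function(values, wt = "WT") {
  n_conf <- stats::setNames(rep(55L, ncol(values)), colnames(values))
  enstab:::new_sea_table(values, wt, n_conf)
}

test_that("deviations follow the Euclidean formula with normalized contributions", {
  # single-bond difference of 0.5: D = 0.5 and that bond takes all of it
  v <- matrix(c(0.5, 0.2, 1.0, 0.2), 2, 2,
              dimnames = list(c("b1", "b2"), c("WT", "M")))
  cs <- compute_deviations(make_sea(v))
  expect_equal(unname(cs$D["M"]), 0.5)
  expect_equal(unname(cs$xi[, "M"]), c(1, 0))

  # 3-4-5: deviations (0.3, 0.4) give D = 0.5, xi = (0.36, 0.64)
  v2 <- matrix(c(0.5, 0.5, 0.8, 0.9), 2, 2,
               dimnames = list(c("b1", "b2"), c("WT", "M")))
  cs2 <- compute_deviations(make_sea(v2))
  expect_equal(unname(cs2$D["M"]), 0.5)
  expect_equal(unname(cs2$xi[, "M"]), c(0.36, 0.64))
})

test_that("contributions sum to 1 and D matches a brute-force recomputation", {
  withr::local_seed(13)
  for (rep in 1:20) {
    vals <- matrix(round(runif(50 * 4) * 55) / 55, 50, 4,
                   dimnames = list(sprintf("b%02d", 1:50),
                                   c("WT", "M1", "M2", "M3")))
    cs <- compute_deviations(make_sea(vals))
    for (m in c("M1", "M2", "M3")) {
      d_oracle <- 0
      for (i in 1:50) d_oracle <- d_oracle + (vals[i, m] - vals[i, "WT"])^2
      expect_equal(unname(cs$D[m]), sqrt(d_oracle), tolerance = 1e-12)
      if (cs$D[m] > 0) {
        expect_equal(sum(cs$xi[, m]), 1, tolerance = 1e-9)
      }
    }
    # xi is zero exactly where the variant matches the WT
    same <- vals[, "M1"] == vals[, "WT"]
    expect_true(all(cs$xi[same, "M1"] == 0))
  }
})

test_that("variants identical to the WT are flagged, not NaN", {
  v <- matrix(c(0.5, 0.2, 0.5, 0.2, 0.9, 0.2), 2, 3,
              dimnames = list(c("b1", "b2"), c("WT", "SAME", "DIFF")))
  expect_warning(cs <- compute_deviations(make_sea(v)), "SAME")
  expect_true(cs$zero_deviation["SAME"])
  expect_false(any(is.nan(cs$xi)))
  expect_equal(unname(cs$xi[, "SAME"]), c(0, 0))
})

test_that("a single-structure table is rejected", {
  v <- matrix(c(0.5, 0.2), 2, 1, dimnames = list(c("b1", "b2"), "WT"))
  expect_error(compute_deviations(make_sea(v)), "no variants")
})

test_that("the contribution histogram bins correctly, including closures", {
  v <- matrix(c(0.5, 0.5, 0.8, 0.9), 2, 2,
              dimnames = list(c("b1", "b2"), c("WT", "M")))
  cs <- compute_deviations(make_sea(v))
  h <- build_h_table(cs)
  # xi = (0.36, 0.64) fall in bins 4 and 7
  expect_equal(unname(h$counts["M", ]), c(0, 0, 0, 1, 0, 0, 1, 0, 0))

  # xi = 0.95 goes in bin 9 ([0.8, 1.0] closure), xi = 0.05 in bin 1
  cs2 <- cs
  cs2$xi[, "M"] <- c(0.95, 0.05)
  cs2$present[, "M"] <- TRUE
  h2 <- build_h_table(cs2)
  expect_equal(unname(h2$counts["M", c(1, 9)]), c(1, 1))

  # row sums equal the number of counted bonds under both policies
  pl <- simulate_sea_table(plant_spec(n_bonds = 120, n_variants = 5,
                                      seed = 8))
  cs3 <- compute_deviations(pl$sea)
  h_union <- build_h_table(cs3, "union_bonds")
  expect_equal(unname(rowSums(h_union$counts)),
               rep(nrow(pl$sea$values), 5))
  h_pres <- build_h_table(cs3, "variant_present_bonds")
  expect_equal(unname(rowSums(h_pres$counts)),
               unname(colSums(cs3$present)))
})

test_that("S-bar averages histogram cells 2..9", {
  counts <- matrix(0L, 1, 9, dimnames = list("M", paste0("H", 1:9)))
  counts[1, 1] <- 920L
  counts[1, 2] <- 6L
  h <- structure(list(counts = counts,
                      s_bar = rowMeans(counts[, 2:9, drop = FALSE]),
                      counting_policy = "union_bonds"), class = "h_table")
  expect_equal(mean_sh(h, "M"), 0.75)
  expect_error(mean_sh(h, "XX"), "unknown")
  # all-zero tail means S-bar 0
  counts0 <- counts
  counts0[1, 2] <- 0L
  h0 <- structure(list(counts = counts0,
                       s_bar = rowMeans(counts0[, 2:9, drop = FALSE]),
                       counting_policy = "union_bonds"), class = "h_table")
  expect_equal(mean_sh(h0, "M"), 0)
})

test_that("variant selection keeps clusters with positive mean S-bar", {
  # 26 variants with flat histograms, 9 with heavy tails
  withr::local_seed(31)
  flat <- t(replicate(26, c(200 + sample(0:3, 1), rep(0, 8))))
  tail <- t(replicate(9, c(190, sample(3:6, 1), sample(1:3, 1),
                           rep(0, 6))))
  counts <- rbind(flat, tail)
  rownames(counts) <- c(sprintf("flat%02d", 1:26), sprintf("hot%02d", 1:9))
  h <- structure(list(counts = counts,
                      s_bar = rowMeans(counts[, 2:9, drop = FALSE]),
                      counting_policy = "union_bonds"), class = "h_table")
  sel <- select_high_contribution_variants(h)
  expect_setequal(sel, sprintf("hot%02d", 1:9))

  # identical rows collapse to one cluster and select nothing
  h1 <- structure(list(counts = flat[rep(1, 8), , drop = FALSE] * 0 + 100,
                       s_bar = rep(0, 8),
                       counting_policy = "union_bonds"), class = "h_table")
  rownames(h1$counts) <- sprintf("v%d", 1:8)
  expect_warning(sel1 <- select_high_contribution_variants(h1), "single")
  expect_length(sel1, 0)
})

test_that("planted high-contribution bonds land in the 5% tail exactly", {
  withr::local_seed(77)
  n <- 100
  xi_bar <- runif(n, 0.001, 0.005)
  planted <- sample.int(n, 5)
  xi_bar[planted] <- xi_bar[planted] * 10
  xi <- matrix(xi_bar, n, 3,
               dimnames = list(sprintf("b%03d", 1:n), c("A", "B", "C")))
  xi <- sweep(xi, 2, colSums(xi), "/")
  cs <- structure(list(D = c(A = 1, B = 1, C = 1), xi = xi,
                       zero_deviation = c(A = FALSE, B = FALSE, C = FALSE),
                       present = xi > -1, wt_id = "WT"),
                  class = "contribution_set")
  res <- detect_destructive(cs, c("A", "B", "C"), tail = 0.05)
  expect_setequal(res$destructive_bonds, sprintf("b%03d", sort(planted)))
  expect_true(res$explained_fraction > 0 && res$explained_fraction <= 1)

  # tail = 0 yields the degenerate empty result
  res0 <- detect_destructive(cs, c("A", "B", "C"), tail = 0)
  expect_length(res0$destructive_bonds, 0)
  expect_equal(res0$explained_fraction, 0)
})

test_that("shrinking the tail never grows the destructive set", {
  pl <- simulate_sea_table(plant_spec(n_bonds = 150, n_variants = 6,
                                      seed = 10))
  cs <- compute_deviations(pl$sea)
  sel <- colnames(cs$xi)
  sizes <- vapply(c(0.2, 0.1, 0.05, 0.02, 0.01), function(tl) {
    length(detect_destructive(cs, sel, tl)$destructive_bonds)
  }, 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("every planted destructive bond is detected across seeds", {
  # planted share (5 of 200) is under the 5% tail, so the detected set
  # must contain all planted bonds; its total size tracks the tail of
  # the positive xi-bar distribution
  for (seed in 1:20) {
    pl <- simulate_sea_table(plant_spec(n_bonds = 200, n_variants = 9,
                                        planted_bonds = 5, delta = 0.4,
                                        background_sigma = 0.02,
                                        seed = seed))
    cs <- compute_deviations(pl$sea)
    res <- detect_destructive(cs, pl$truth$planted_variants, tail = 0.05)
    expect_true(all(pl$truth$planted_bonds %in% res$destructive_bonds))
    n_pos <- sum(res$xi_bar > 0)
    expect_lte(length(res$destructive_bonds), ceiling(0.05 * n_pos) + 1L)
    # planted bonds dominate the ranking
    expect_setequal(utils::head(res$destructive_bonds, 5),
                    pl$truth$planted_bonds)
  }
})

test_that("pipeline from exported TSV equals the in-memory pipeline bit-exactly", {
  pl <- simulate_sea_table(plant_spec(n_bonds = 80, n_variants = 5, seed = 3))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_sea_table(pl$sea, tmp)
  back <- read_stability_table(tmp, "WT")
  a <- compute_deviations(pl$sea)
  b <- compute_deviations(back)
  expect_identical(a$D, b$D)
  expect_identical(a$xi, b$xi)
  ra <- detect_destructive(a, colnames(a$xi), 0.05)
  rb <- detect_destructive(b, colnames(b$xi), 0.05)
  expect_identical(ra$destructive_bonds, rb$destructive_bonds)
  expect_identical(ra$threshold, rb$threshold)
})

test_that("bond residues are extracted with annotation roles and chain tags", {
  keys <- c("A:10:N|H->A:14:O", "A:46:N|H->F:113:O")
  res <- residues_of_bonds(keys)
  expect_setequal(paste(res$chain, res$resno),
                  c("A 10", "A 14", "A 46", "F 113"))
  expect_match(res$roles[res$resno == 46], "copper_site")
  expect_match(res$roles[res$resno == 113], "dimer_interface")
  expect_warning(res2 <- residues_of_bonds(c(keys, "opaque-label")),
                 "opaque")
  expect_equal(nrow(res2), 4L)
})
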