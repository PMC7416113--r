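test_that("IPL depth scaling maps the borders to 0 and 10 linearly", {
  cloud <- tibble::tibble(x_um = c(0, 1, 2, 3), y_um = c(50, 70, 60, 75),
                          z_um = 0, is_soma = c(TRUE, FALSE, FALSE, FALSE))
  sc <- scale_ipl_depth(cloud, ipl_inner = 50, ipl_outer = 70)
  expect_equal(sc$y_ipl, c(0, 10, 5, 12.5))  # beyond the INL border -> > 10
  expect_error(scale_ipl_depth(cloud, 50, 50), class = "chromarg_invalid_argument")
})

test_that("morphological summaries match hand values and the O(n^3) hull oracle", {
  # unit square in xz with equal depth everywhere
  sq <- tibble::tibble(x_um = c(0, 0, 1, 1, 0), y_um = 2, z_um = c(0, 0, 0, 1, 1),
                       is_soma = c(TRUE, rep(FALSE, 4)))
  sq$y_ipl <- 5
  s <- summarize_morphology(sq)
  expect_equal(s$xz_area, 1)
  expect_equal(s$y_span, 0)
  expect_equal(s$num_pts, 4L)
  # collinear points span zero area
  lin <- tibble::tibble(x_um = 1:5, y_um = 1:5, z_um = 2 * (1:5) + 1,
                        is_soma = c(TRUE, rep(FALSE, 4)), y_ipl = 1:5)
  expect_equal(summarize_morphology(lin)$xz_area, 0)
  # random clouds against the brute-force hull oracle
  withr::with_seed(11, {
    for (rep in 1:8) {
      n <- sample(4:12, 1)
      x <- rnorm(n) * 10
      z <- rnorm(n) * 10
      expect_equal(convex_hull_area(x, z), hull_area_oracle(x, z),
                   tolerance = 1e-9)
    }
  })
  # rigid xz translation and point order leave summaries unchanged
  withr::with_seed(12, {
    cl <- make_morph_cloud(morph_gen_config(n_points = 50, seed = 3))
  })
  s1 <- summarize_morphology(cl)
  cl2 <- cl
  cl2$x_um <- cl2$x_um + 100
  cl2$z_um <- cl2$z_um - 40
  expect_equal(summarize_morphology(cl2), s1)
  cl3 <- cl[c(1, sample(2:nrow(cl))), ]
  expect_equal(summarize_morphology(cl3), s1)
})

test_that("summary standardization z-scores each column with n-1 SD", {
  tbl <- tibble::tibble(y_span = c(1, 3), y_mean = c(2, 8), num_pts = c(10, 30))
  std <- standardize_stats(tbl)
  # two-cell table: values are +/- 1/sqrt(2) under the n-1 convention
  expect_equal(std$y_span, c(-1, 1) / sqrt(2))
  expect_equal(std$y_mean, c(-1, 1) / sqrt(2))
  withr::with_seed(13, {
    big <- tibble::tibble(y_span = rnorm(20, 5), y_mean = runif(20),
                          num_pts = rpois(20, 50) + 1)
  })
  sb <- standardize_stats(big)
  for (cn in c("y_span", "y_mean", "num_pts")) {
    expect_lt(abs(mean(sb[[cn]])), 1e-9)
    expect_equal(sd(sb[[cn]]), 1, tolerance = 1e-9)
  }
  # affine rescaling of a column beforehand changes nothing
  big2 <- big
  big2$y_span <- big$y_span * 7 - 2
  expect_equal(standardize_stats(big2)$y_span, sb$y_span, tolerance = 1e-12)
  big3 <- big
  big3$y_mean <- 1
  expect_error(standardize_stats(big3), class = "chromarg_degenerate")
})

test_that("hierarchical clustering splits blobs, bounds the CCC, and is deterministic", {
  withr::with_seed(14, {
    blob <- rbind(matrix(rnorm(30 * 2, 0), 30),
                  matrix(rnorm(30 * 2, 20), 30))
  })
  tbl <- tibble::as_tibble(as.data.frame(blob))
  hc <- hier_cluster(tbl, c("V1", "V2"), 2)
  expect_equal(adjusted_rand(hc$labels, rep(1:2, each = 30)), 1)
  expect_true(hc$ccc >= -1 && hc$ccc <= 1)
  hc2 <- hier_cluster(tbl, c("V1", "V2"), 2)
  expect_identical(hc$labels, hc2$labels)
  expect_identical(hc$ccc, hc2$ccc)
  expect_error(hier_cluster(tbl, c("V1", "V2"), 100),
               class = "chromarg_invalid_argument")
  # an exactly ultrametric configuration: CCC = 1, against the naive
  # cophenetic oracle
  um <- tibble::tibble(V1 = c(0, 1, 10, 11, 30, 31) * 1.0, V2 = 0)
  hcu <- hier_cluster(um, c("V1", "V2"), 2)
  expect_equal(hcu$ccc,
               cor(cophenetic_oracle(hcu$tree), dist(as.matrix(um), "manhattan")),
               tolerance = 1e-12)
  # oracle agrees with stats::cophenetic everywhere
  expect_equal(as.vector(cophenetic_oracle(hc$tree)),
               as.vector(cophenetic(hc$tree)), tolerance = 1e-12)
})


test_that("two-stage clustering yields 18 - 2 + 9 = 25 clusters and pure planted types", {
  pop <- morph_population(n_per = 33, seed = 100)
  tbl <- summarize_morph_population(pop$clouds)
  ts <- two_stage_cluster(tbl, stage1_k = 18, split_spec = c(6, 3),
                          min_members = 4)
  expect_equal(ts$n_total_clusters, 25L)
  expect_lte(ts$presented_k, 25L)
  expect_true(all(abs(c(ts$ccc_stage1, ts$ccc_splits)) <= 1))
  # each planted type is majority-pure in some final cluster
  lab <- ts$labels$final
  for (ti in 1:4) {
    best_purity <- max(vapply(split(pop$type == ti, lab), mean, numeric(1)))
    expect_gt(best_purity, 0.5)
  }
  # labels are conserved: every cell gets a final label
  expect_equal(length(lab), nrow(tbl))
  # min_members = 1 presents everything
  ts1 <- two_stage_cluster(tbl, stage1_k = 18, split_spec = c(6, 3),
                           min_members = 1)
  expect_equal(ts1$presented_k, ts1$n_total_clusters)
  expect_equal(nrow(glance(ts)), 1)
  expect_error(two_stage_cluster(tbl, stage1_k = 18,
                                 split_spec = c(`99` = 3)),
               class = "chromarg_invalid_argument")
})

test_that("dendritic tilt obeys its spherical-coordinate definition", {
  mk <- function(offset) {
    tibble::tibble(x_um = c(0, offset[1]), y_um = c(0, offset[2]),
                   z_um = c(0, offset[3]), is_soma = c(TRUE, FALSE))
  }
  # CoM straight above the soma: theta = 0
  up <- compute_tilt(mk(c(0, 7, 0)))
  expect_equal(up$theta, 0)
  expect_equal(up$r, 7)
  # CoM at the soma's own depth: theta = pi/2
  side <- compute_tilt(mk(c(4, 0, 0)))
  expect_equal(side$theta, pi / 2)
  # phi along +x vs -x differ by exactly pi
  expect_equal(abs(compute_tilt(mk(c(-4, 0, 0)))$phi - side$phi), pi)
  # CoM at the soma: undefined tilt
  und <- compute_tilt(mk(c(0, 0, 0)))
  expect_false(und$defined)
  expect_true(is.nan(und$theta))
  # planted phi recovered within 10 degrees at >= 200 points
  errs <- vapply(1:6, function(i) {
    phi <- i
    cl <- make_morph_cloud(morph_gen_config(n_points = 200, tilt_r = 10,
                                            tilt_theta = pi / 4, tilt_phi = phi,
                                            seed = 60 + i))
    d <- abs(compute_tilt(cl)$phi - (phi %% (2 * pi)))
    min(d, 2 * pi - d)
  }, numeric(1))
  expect_lt(mean(errs) * 180 / pi, 10)
})

test_that("the KS test matches its definition on degenerate and shifted samples", {
  a <- c(1, 2, 3, 4, 5)
  same <- ks_two_sample(a, a)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  disj <- ks_two_sample(a, a + 100)
  expect_equal(disj$D, 1)
  # invariance under common monotone transforms
  withr::with_seed(15, {
    x <- rnorm(40); y <- rnorm(40, 1)
  })
  r1 <- ks_two_sample(x, y)
  r2 <- ks_two_sample(exp(x), exp(y))
  expect_equal(r1$D, r2$D)
  expect_equal(r1$p, r2$p)
  expect_error(ks_two_sample(numeric(0), a), class = "chromarg_invalid_argument")
})

test_that("the Kuiper test is rotation invariant and minimal on identical samples", {
  withr::with_seed(16, {
    a <- runif(50, 0, 2 * pi)
    b <- runif(50, 0, 2 * pi)
  })
  r0 <- kuiper_two_sample(a, b)
  r_rot <- kuiper_two_sample(a + 1.23, b + 1.23)
  expect_equal(r_rot$V, r0$V, tolerance = 1e-12)
  expect_equal(r_rot$p, r0$p, tolerance = 1e-12)
  same <- kuiper_two_sample(a, a)
  expect_equal(same$p, 1)
  expect_lte(same$V, 1 / 50 + 1e-12)
  # opposite von Mises populations are detected decisively
  withr::with_seed(17, {
    va <- rvonmises(60, 0, 2)
    vb <- rvonmises(60, pi, 2)
  })
  expect_lt(kuiper_two_sample(va, vb)$p, 0.01)
})

test_that("group-level tilt comparison reports KS for r/theta and Kuiper for phi", {
  withr::with_seed(18, {
    tilts <- tibble::tibble(
      r_um = c(rnorm(30, 10), rnorm(30, 14)),
      theta_rad = abs(c(rnorm(30, 0.4, 0.1), rnorm(30, 0.4, 0.1))),
      phi_rad = c(rvonmises(30, 0, 2), rvonmises(30, pi, 2)),
      region = rep(c("SZ", "N"), each = 30)
    )
  })
  cmp <- compare_tilt_groups(tilts)
  expect_equal(cmp$test, c("ks", "ks", "kuiper"))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  # r differs, theta does not, phi differs: mirrored in the p-values
  expect_lt(cmp$p_value[cmp$variable == "r"], 0.05)
  expect_gt(cmp$p_value[cmp$variable == "theta"], 0.05)
  expect_lt(cmp$p_value[cmp$variable == "phi"], 0.05)
})
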