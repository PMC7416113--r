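# Independent oracles and shared fixtures for the test suite.

# von Mises sampler by rejection from the uniform (exact; used only to
# generate circular test data)
rvonmises <- function(n, mu, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    cand <- runif(2 * n, 0, 2 * pi)
    acc <- runif(2 * n) < exp(kappa * (cos(cand - mu) - 1))
    out <- c(out, cand[acc])
  }
  (out[seq_len(n)]) %% (2 * pi)
}

# O(n^3) convex-hull area oracle: an edge (i, j) is a hull edge iff all
# other points lie on one side; shoelace over the ordered hull
hull_area_oracle <- function(x, z) {
  pts <- unique(cbind(x, z))
  n <- nrow(pts)
  if (n < 3L) return(0)
  on_hull <- rep(FALSE, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    cr <- (pts[, 1] - pts[i, 1]) * (pts[j, 2] - pts[i, 2]) -
      (pts[, 2] - pts[i, 2]) * (pts[j, 1] - pts[i, 1])
    if (all(cr <= 1e-12) || all(cr >= -1e-12)) {
      on_hull[i] <- TRUE
      on_hull[j] <- TRUE
    }
  }
  hp <- pts[on_hull, , drop = FALSE]
  if (nrow(hp) < 3L) return(0)
  ctr <- colMeans(hp)
  ord <- order(atan2(hp[, 2] - ctr[2], hp[, 1] - ctr[1]))
  hp <- hp[ord, , drop = FALSE]
  m <- nrow(hp)
  abs(sum(hp[, 1] * hp[c(2:m, 1), 2] - hp[c(2:m, 1), 1] * hp[, 2])) / 2
}

# naive cophenetic distance oracle from an hclust tree
cophenetic_oracle <- function(tree) {
  n <- nrow(tree$merge) + 1L
  co <- matrix(0, n, n)
  groups <- vector("list", nrow(tree$merge))
  for (s in seq_len(nrow(tree$merge))) {
    a <- tree$merge[s, 1]; b <- tree$merge[s, 2]
    ga <- if (a < 0) -a else groups[[a]]
    gb <- if (b < 0) -b else groups[[b]]
    for (i in ga) for (j in gb) co[i, j] <- co[j, i] <- tree$height[s]
    groups[[s]] <- c(ga, gb)
  }
  as.dist(co)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# well-separated Gaussian blobs for clustering tests
make_blobs <- function(n = 300, d = 5, k = 3, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(k * d), k, d)
    centers <- centers / sqrt(rowSums(centers^2)) * sep
    lab <- sample.int(k, n, TRUE)
    list(x = centers[lab, , drop = FALSE] + matrix(rnorm(n * d), n, d),
         labels = lab)
  })
}

# shared small simulated population (built once per test run)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      stim <- noise_stimulus(duration_s = 120, seed = 101)
      cfg <- sim_config(n_rois = 12, seed = 101, duration = 120)
      pop <- make_population(cfg, default_cluster_spec(3), stim = stim)
      kt <- estimate_population_kernels(pop, stim)
      cache <<- list(stim = stim, cfg = cfg, pop = pop, kernels = kt)
    }
    cache
  }
})

# planted four-type morphology population (narrow-On, narrow-Off,
# diffuse, sparse)
morph_population <- function(n_per = 33, seed = 100) {
  # four planted types: narrow-On, narrow-Off, diffuse, sparse
  specs <- list(
    list(y_mean = 2, y_span = 1, n = 320, xz = 12),
    list(y_mean = 8, y_span = 1, n = 300, xz = 12),
    list(y_mean = 5, y_span = 7, n = 310, xz = 20),
    list(y_mean = 5, y_span = 3, n = 60, xz = 8)
  )
  clouds <- list()
  type <- integer(0)
  for (ti in seq_along(specs)) {
    sp <- specs[[ti]]
    for (i in seq_len(n_per)) {
      cfg <- morph_gen_config(
        n_points = sp$n + (seed + i) %% 11 + ti, y_mean = sp$y_mean,
        y_span = sp$y_span, tilt_r = 6, tilt_theta = pi / 8,
        tilt_phi = 0.5, xz_spread = sp$xz, seed = seed + 37 * ti + i
      )
      clouds[[length(clouds) + 1L]] <- make_morph_cloud(cfg)
      type <- c(type, ti)
    }
  }
  list(clouds = clouds, type = type)
}

# writer for synthetic deposited-format CSV fixtures
write_deposited_fixture <- function(dir, n_roi = 3, kernel_len = 649,
                                    chirp_len = 2499) {
  withr::with_seed(20, {
    rows <- tidyr::expand_grid(roi_id = seq_len(n_roi),
                               channel = channel_order())
    km <- matrix(rnorm(nrow(rows) * kernel_len), nrow(rows))
    kt <- cbind(rows, as.data.frame(km))
    cm <- matrix(rnorm(n_roi * chirp_len), n_roi)
    ct <- cbind(data.frame(roi_id = seq_len(n_roi)), as.data.frame(cm))
  })
  kp <- file.path(dir, "kernels.csv")
  cp <- file.path(dir, "chirps.csv")
  write.csv(kt, kp, row.names = FALSE)
  write.csv(ct, cp, row.names = FALSE)
  list(kernels = kp, chirps = cp)
}
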