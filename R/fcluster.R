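#' Kernel-quality filter for clustering
#'
#' Keeps ROIs whose clustering quality — the maximum over the four
#' colours of the normalized kernel's standard deviation — reaches
#' `quality_threshold` (default 5). This gate is separate from the 10-SD
#' peak-to-peak responsiveness gate used for ternary classification.
#'
#' @param kernel_tbl Output of [estimate_population_kernels()].
#' @param quality_threshold Minimum `quality_sd_max` (default 5).
#' @return The filtered tibble; errors with class
#'   `chromarg_empty_dataset` if nothing survives.
#' @export
qc_filter <- function(kernel_tbl, quality_threshold = 5) {
  out <- dplyr::filter(kernel_tbl, .data$quality_sd_max >= quality_threshold)
  if (nrow(out) == 0L) {
    abort("no ROI passes the kernel-quality threshold",
          class = "chromarg_empty_dataset")
  }
  out
}

#' Assemble the ROIs x time feature matrix from kernel sets
#'
#' @param kernel_tbl A tibble with a `kernel_set` list-column.
#' @return Numeric matrix, one row per ROI, 4 x 649 columns ordered by
#'   colour block (R, G, B, UV).
#' @export
kernel_feature_matrix <- function(kernel_tbl) {
  t(vapply(kernel_tbl$kernel_set,
           function(ks) as.numeric(ks$kernels),
           numeric(4L * 649L)))
}

block_index <- function(n_cols, n_blocks = 4L) {
  per <- n_cols / n_blocks
  if (per != floor(per)) abort_invalid("columns do not split into 4 equal colour blocks.")
  rep(seq_len(n_blocks), each = per)
}

#' Scale each colour block to unit pooled SD
#'
#' Divides each colour's block of the feature matrix by a single scalar:
#' the standard deviation pooled over all ROIs and time points of that
#' block. This gives each colour even weighting (red and green kernels
#' tend to have larger amplitudes than blue and UV).
#'
#' @param x Feature matrix (ROIs x 4 concatenated colour blocks).
#' @return The scaled matrix, with attribute `block_sd`.
#' @export
scale_per_color <- function(x) {
  if (nrow(x) < 2L) abort_invalid("need at least 2 ROIs to scale.")
  blocks <- block_index(ncol(x))
  sds <- numeric(4)
  for (b in 1:4) {
    v <- sd(as.vector(x[, blocks == b]))
    if (!is.finite(v) || v == 0) {
      abort("zero-variance colour block: scaling degenerate",
            class = "chromarg_degenerate")
    }
    x[, blocks == b] <- x[, blocks == b] / v
    sds[b] <- v
  }
  attr(x, "block_sd") <- setNames(sds, channel_order())
  x
}

#' Per-colour PCA retaining >= 99% variance
#'
#' Mean-centred PCA applied to each colour block separately; for each
#' block the smallest number of leading components whose cumulative
#' explained variance reaches `var_target` is retained, and the four
#' score matrices are concatenated in channel order R, G, B, UV.
#'
#' @param x Scaled feature matrix from [scale_per_color()].
#' @param var_target Variance fraction to retain (default 0.99;
#'   `1.0` keeps every component with nonzero variance).
#' @return A list of class `color_pca`: `scores` (ROIs x total
#'   components), `n_components` (per colour), `pca` (the four `prcomp`
#'   fits).
#' @export
pca_per_color <- function(x, var_target = 0.99) {
  if (nrow(x) < 2L) abort_invalid("need at least 2 ROIs for PCA.")
  blocks <- block_index(ncol(x))
  fits <- vector("list", 4)
  scores <- vector("list", 4)
  n_comp <- integer(4)
  for (b in 1:4) {
    p <- prcomp(x[, blocks == b], center = TRUE, scale. = FALSE)
    var_frac <- p$sdev^2 / sum(p$sdev^2)
    nonzero <- p$sdev > p$sdev[1] * 1e-9
    nc <- if (var_target >= 1) {
      sum(nonzero)
    } else {
      which(cumsum(var_frac) >= var_target)[1]
    }
    fits[[b]] <- p
    n_comp[b] <- nc
    scores[[b]] <- p$x[, seq_len(nc), drop = FALSE]
  }
  structure(
    list(scores = do.call(cbind, scores),
         n_components = setNames(n_comp, channel_order()),
         pca = setNames(fits, channel_order())),
    class = "color_pca"
  )
}

covariance_structures <- function() {
  c("shared_diag", "unshared_diag", "shared_full", "unshared_full")
}

gmm_n_params <- function(k, d, structure) {
  cov_p <- switch(structure,
    shared_diag = d,
    unshared_diag = k * d,
    shared_full = d * (d + 1) / 2,
    unshared_full = k * d * (d + 1) / 2,
    abort_invalid("unknown covariance structure")
  )
  k * d + (k - 1) + cov_p
}

# k-means++ seeding followed by a short Lloyd refinement; returns hard
# responsibilities (n x k).
gmm_init_z <- function(x, k, seed) {
  n <- nrow(x)
  withr::with_seed(seed, {
    centers <- matrix(0, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1), ]
    if (k > 1) {
      d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
      for (j in 2:k) {
        prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[j, ] <- x[sample.int(n, 1, prob = prob), ]
        d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
      }
    }
    assign <- tryCatch(
      suppressWarnings(kmeans(x, centers = centers, iter.max = 20,
                              algorithm = "Lloyd")$cluster),
      error = function(e) {
        d2 <- vapply(seq_len(k), function(j)
          rowSums(sweep(x, 2, centers[j, ])^2), numeric(n))
        max.col(-d2)
      }
    )
  })
  z <- matrix(0, n, k)
  z[cbind(seq_len(n), assign)] <- 1
  z
}

# one EM fit; returns loglik = -Inf with converged = FALSE on failure
# (a component emptying out, a singular covariance, or a non-finite
# likelihood all count as failure, as in reference mixture fitters)
fit_gmm <- function(x, k, structure, reg = 1e-5, max_iter = 1e4,
                    tol = 1e-6, seed = 1L, init_z = NULL) {
  n <- nrow(x); d <- ncol(x)
  z <- init_z %||% gmm_init_z(x, k, seed)
  x2 <- x^2
  tx <- t(x)
  ll_old <- -Inf
  converged <- FALSE
  pi_k <- mu <- covs <- NULL
  fail <- function(iter) list(loglik = -Inf, converged = FALSE,
                              n_iter = iter, k = k, structure = structure)
  for (iter in seq_len(max_iter)) {
    nk <- colSums(z)
    if (any(nk < 1)) return(fail(iter))
    pi_k <- nk / n
    mu <- crossprod(z, x) / nk                       # k x d
    logdens <- matrix(0, n, k)
    if (structure %in% c("shared_diag", "unshared_diag")) {
      vars <- crossprod(z, x2) / nk - mu^2           # k x d
      if (structure == "shared_diag") {
        v <- colSums(vars * nk) / n + reg
        vars <- matrix(v, k, d, byrow = TRUE)
      } else {
        vars <- pmax(vars, 0) + reg
      }
      # -0.5 * (x - mu)^2 / v, expanded to avoid per-component sweeps
      logdens <- -0.5 * (x2 %*% t(1 / vars) - 2 * (x %*% t(mu / vars))) -
        matrix(0.5 * (rowSums(mu^2 / vars) + rowSums(log(2 * pi * vars))),
               n, k, byrow = TRUE)
      covs <- vars
    } else {
      sig <- vector("list", k)
      for (j in seq_len(k)) {
        sig[[j]] <- crossprod(x * z[, j], x) / nk[j] - tcrossprod(mu[j, ])
      }
      if (structure == "shared_full") {
        pooled <- Reduce(`+`, purrr::map2(sig, nk, `*`)) / n +
          diag(reg, d)
        sig <- rep(list(pooled), k)
      } else {
        sig <- lapply(sig, function(s) s + diag(reg, d))
      }
      ok <- TRUE
      ch <- NULL
      hx <- NULL
      for (j in seq_len(k)) {
        if (structure != "shared_full" || is.null(ch)) {
          ch <- tryCatch(chol(sig[[j]]), error = function(e) NULL)
          if (is.null(ch)) { ok <- FALSE; break }
          hx <- backsolve(ch, tx, transpose = TRUE)      # d x n
        }
        hmu <- backsolve(ch, mu[j, ], transpose = TRUE)
        mahal <- colSums(hx^2) - 2 * as.numeric(crossprod(hmu, hx)) +
          sum(hmu^2)
        logdens[, j] <- -0.5 * (mahal + 2 * sum(log(diag(ch))) +
                                  d * log(2 * pi))
      }
      if (!ok) return(fail(iter))
      covs <- sig
    }
    lw <- sweep(logdens, 2, log(pi_k), `+`)
    mx <- lw[cbind(seq_len(n), max.col(lw, ties.method = "first"))]
    lse <- mx + log(rowSums(exp(lw - mx)))
    ll <- sum(lse)
    if (!is.finite(ll)) return(fail(iter))
    z <- exp(lw - lse)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  assign <- max.col(z, ties.method = "first")
  list(loglik = ll_old, converged = converged, n_iter = iter,
       k = k, structure = structure, weights = pi_k, means = mu,
       covariances = covs, responsibilities = z, assignments = assign)
}

#' Gaussian-mixture sweep with BIC model selection
#'
#' Fits mixtures with 1 to `k_max` components under four covariance
#' structures (shared-diagonal, unshared-diagonal, shared-full,
#' unshared-full). Each (k, structure) cell is fit `replicates` times
#' with different k-means++-seeded initial values (replicate r uses seed
#' `seed + r`) and the replicate with the largest log-likelihood kept.
#' Covariances carry a ridge regularization of `reg` to stay positive
#' definite. BIC is `-2 logL + p log(n)` with `p` counted per structure;
#' non-converged fits are recorded, not fatal.
#'
#' @param features Numeric matrix (ROIs x features), e.g. the scores of
#'   [pca_per_color()].
#' @param k_max Largest component count (default 20; the full protocol
#'   uses 100).
#' @param covariance_set Subset of [covariance_structures()].
#' @param replicates Initializations per cell (default 20).
#' @param reg Covariance ridge (default 1e-5).
#' @param max_iter EM iteration cap (default 1e4).
#' @param seed Base seed; the sweep is reproducible given it.
#' @return A list of class `gmm_sweep`: `bic_table` (tibble with `k`,
#'   `structure`, `loglik`, `n_params`, `bic`, `converged`, `n_failed`),
#'   `models` (best fit per cell), `n`, `d`.
#' @export
gmm_sweep <- function(features, k_max = 20, covariance_set = covariance_structures(),
                      replicates = 20, reg = 1e-5, max_iter = 1e4, seed = 1L) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n <= k_max) abort_invalid("need more rows than `k_max`.")
  covariance_set <- match.arg(covariance_set, covariance_structures(),
                              several.ok = TRUE)
  cells <- tidyr::expand_grid(structure = covariance_set, k = seq_len(k_max))
  models <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    k <- cells$k[i]
    st <- cells$structure[i]
    n_rep <- if (k == 1L) 1L else replicates
    best <- NULL
    n_failed <- 0L
    # replicates are screened at a loose tolerance; the best one is then
    # polished to full tolerance from its own responsibilities, which
    # cannot decrease its log-likelihood
    for (r in seq_len(n_rep)) {
      fit <- fit_gmm(x, k, st, reg = reg, max_iter = max_iter,
                     seed = seed + r, tol = 1e-4)
      if (!is.finite(fit$loglik)) {
        n_failed <- n_failed + 1L
        next
      }
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (!is.null(best)) {
      polished <- fit_gmm(x, k, st, reg = reg, max_iter = max_iter,
                          seed = seed, init_z = best$responsibilities)
      if (is.finite(polished$loglik) && polished$loglik >= best$loglik) {
        best <- polished
      }
    }
    if (is.null(best)) {
      rows[[i]] <- tibble::tibble(k = k, structure = st, loglik = -Inf,
                                  n_params = gmm_n_params(k, ncol(x), st),
                                  bic = Inf, converged = FALSE,
                                  n_failed = n_failed)
      next
    }
    p <- gmm_n_params(k, ncol(x), st)
    rows[[i]] <- tibble::tibble(k = k, structure = st, loglik = best$loglik,
                                n_params = p,
                                bic = -2 * best$loglik + p * log(n),
                                converged = best$converged,
                                n_failed = n_failed)
    models[[i]] <- best
  }
  structure(
    list(bic_table = dplyr::bind_rows(rows), models = models,
         cells = cells, n = n, d = ncol(x), seed = seed),
    class = "gmm_sweep"
  )
}

#' Select the model from a sweep
#'
#' In `"bic"` mode the cell minimizing BIC wins; ties break toward
#' smaller `k`, then toward the simpler covariance structure in the
#' order shared-diagonal, unshared-diagonal, shared-full, unshared-full.
#' `"fixed_k"` mode returns the requested (k, covariance) cell — the
#' fallback used when BIC does not give a clean clustering.
#'
#' @param sweep A `gmm_sweep`.
#' @param mode `"bic"` or `"fixed_k"`.
#' @param fixed_k,fixed_covariance The cell to return in fixed mode.
#' @return The chosen fit (list with `assignments`, `loglik`, ...), with
#'   `bic` added.
#' @export
select_model <- function(sweep, mode = c("bic", "fixed_k"),
                         fixed_k = NULL, fixed_covariance = "unshared_diag") {
  mode <- match.arg(mode)
  tab <- sweep$bic_table
  if (mode == "bic") {
    ord <- order(tab$bic, tab$k,
                 match(tab$structure, covariance_structures()))
    i <- ord[1]
  } else {
    if (is.null(fixed_k)) abort_invalid("`fixed_k` required in fixed_k mode.")
    i <- which(tab$k == fixed_k & tab$structure == fixed_covariance)
    if (length(i) != 1L || is.null(sweep$models[[i]])) {
      abort_invalid("requested (k, covariance) cell is not in the sweep.")
    }
  }
  model <- sweep$models[[i]]
  model$bic <- tab$bic[i]
  model
}

#' Drop undersized clusters and re-index by size
#'
#' Clusters with fewer than `min_members` members are removed; their
#' ROIs become unassigned (`NA`). Surviving clusters are renumbered 1, 2,
#' ... in decreasing size.
#'
#' @param model A fit from [select_model()].
#' @param min_members Minimum cluster size (the full protocol uses 10
#'   for dendritic/IPL datasets and 5 for somatic/GCL datasets).
#' @return A list of class `cluster_set`: `cluster` (integer or `NA` per
#'   ROI), `sizes`, `n_unassigned`, `k`.
#' @export
finalize_clusters <- function(model, min_members = 10) {
  a <- model$assignments
  sizes <- table(a)
  keep <- as.integer(names(sizes))[sizes >= min_members]
  relabel <- rep(NA_integer_, max(a))
  keep <- keep[order(-sizes[as.character(keep)])]
  relabel[keep] <- seq_along(keep)
  cluster <- relabel[a]
  structure(
    list(cluster = cluster,
         sizes = if (length(keep)) table(cluster) else table(integer(0)),
         n_unassigned = sum(is.na(cluster)), k = length(keep)),
    class = "cluster_set"
  )
}

#' Per-cluster mean response profiles
#'
#' Pointwise mean and SD of the member kernels per cluster (and of the
#' chirp responses when provided), plus max-scaled mean kernels.
#'
#' @param clusters A `cluster_set` aligned with `kernel_tbl` rows.
#' @param kernel_tbl The clustered kernel tibble.
#' @param chirps Optional list of per-ROI chirp vectors (2,499 samples).
#' @return A tibble with one row per (cluster, channel): `cluster`,
#'   `n_members`, `channel`, list-columns `mean`, `sd`, `mean_scaled`
#'   (mean divided by its max absolute value), and `chirp_mean`/
#'   `chirp_sd` when chirps are given.
#' @export
cluster_profiles <- function(clusters, kernel_tbl, chirps = NULL) {
  ks <- kernel_tbl$kernel_set
  rows <- list()
  for (cl in seq_len(clusters$k)) {
    members <- which(!is.na(clusters$cluster) & clusters$cluster == cl)
    if (length(members) == 0L) next
    chirp_mean <- chirp_sd <- NULL
    if (!is.null(chirps)) {
      cm <- do.call(cbind, chirps[members])
      chirp_mean <- rowMeans(cm)
      chirp_sd <- apply(cm, 1, sd)
      if (length(members) == 1L) chirp_sd <- numeric(length(chirp_mean))
    }
    for (ch in 1:4) {
      m <- vapply(members, function(i) ks[[i]]$kernels[, ch], numeric(649))
      m <- matrix(m, nrow = 649)
      mu <- rowMeans(m)
      s <- if (ncol(m) > 1) apply(m, 1, sd) else numeric(649)
      scl <- if (max(abs(mu)) > 0) mu / max(abs(mu)) else mu
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cluster = cl, n_members = length(members),
        channel = channel_order()[ch],
        mean = list(mu), sd = list(s), mean_scaled = list(scl),
        chirp_mean = if (ch == 1L && !is.null(chirp_mean)) list(chirp_mean) else list(NULL),
        chirp_sd = if (ch == 1L && !is.null(chirp_sd)) list(chirp_sd) else list(NULL)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Functional clustering of a kernel population (one call)
#'
#' Chains the full protocol: quality filter at 5, per-colour scaling,
#' per-colour >= 99%-variance PCA, the GMM/BIC sweep, model selection,
#' and the minimum-member filter.
#'
#' @param kernel_tbl Output of [estimate_population_kernels()].
#' @param quality_threshold Clustering QC gate (default 5).
#' @param k_max,replicates,reg,max_iter,seed Passed to [gmm_sweep()].
#' @param covariance_set Structures to sweep.
#' @param mode,fixed_k,fixed_covariance Passed to [select_model()].
#' @param min_members Passed to [finalize_clusters()].
#' @param var_target Passed to [pca_per_color()].
#' @return A list of class `functional_clustering`: `rois` (the filtered
#'   tibble with a `cluster` column), `sweep`, `model`, `clusters`,
#'   `pca`, `n_in`, `n_passed`.
#' @export
cluster_functional <- function(kernel_tbl, quality_threshold = 5,
                               k_max = 20, covariance_set = covariance_structures(),
                               replicates = 20, reg = 1e-5, max_iter = 1e4,
                               seed = 1L, mode = "bic", fixed_k = NULL,
                               fixed_covariance = "unshared_diag",
                               min_members = 10, var_target = 0.99) {
  passed <- qc_filter(kernel_tbl, quality_threshold)
  feats <- kernel_feature_matrix(passed)
  scaled <- scale_per_color(feats)
  pca <- pca_per_color(scaled, var_target = var_target)
  sweep <- gmm_sweep(pca$scores, k_max = k_max,
                     covariance_set = covariance_set,
                     replicates = replicates, reg = reg,
                     max_iter = max_iter, seed = seed)
  model <- select_model(sweep, mode = mode, fixed_k = fixed_k,
                        fixed_covariance = fixed_covariance)
  clusters <- finalize_clusters(model, min_members = min_members)
  passed$cluster <- clusters$cluster
  structure(
    list(rois = passed, sweep = sweep, model = model, clusters = clusters,
         pca = pca, n_in = nrow(kernel_tbl), n_passed = nrow(passed)),
    class = "functional_clustering"
  )
}

#' Tidy a GMM sweep into its BIC table
#'
#' @param x A `gmm_sweep`.
#' @param ... Unused.
#' @return The BIC tibble (`k`, `structure`, `loglik`, `n_params`,
#'   `bic`, `converged`, `n_failed`).
#' @export
tidy.gmm_sweep <- function(x, ...) x$bic_table

#' One-row summary of a GMM sweep
#'
#' @param x A `gmm_sweep`.
#' @param ... Unused.
#' @return Tibble with the BIC-optimal `k`, `structure`, `bic`,
#'   `loglik`, and problem size.
#' @export
glance.gmm_sweep <- function(x, ...) {
  tab <- x$bic_table
  i <- order(tab$bic, tab$k, match(tab$structure, covariance_structures()))[1]
  tibble::tibble(k_best = tab$k[i], structure_best = tab$structure[i],
                 bic_min = tab$bic[i], loglik = tab$loglik[i],
                 n = x$n, d = x$d)
}

#' Plot BIC curves of a sweep
#'
#' @param object A `gmm_sweep`.
#' @param ... Unused.
#' @return A ggplot of BIC versus component count, one line per
#'   covariance structure.
#' @export
autoplot.gmm_sweep <- function(object, ...) {
  ggplot2::ggplot(object$bic_table,
                  ggplot2::aes(x = .data$k, y = .data$bic,
                               colour = .data$structure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "number of mixture components", y = "BIC") +
    ggplot2::theme_minimal()
}

#' Tidy a functional clustering result
#'
#' @param x A `functional_clustering`.
#' @param ... Unused.
#' @return Tibble with `roi_id` and `cluster` (NA = unassigned).
#' @export
tidy.functional_clustering <- function(x, ...) {
  tibble::tibble(roi_id = x$rois$roi_id, cluster = x$rois$cluster)
}

#' One-row summary of a functional clustering
#'
#' @param x A `functional_clustering`.
#' @param ... Unused.
#' @return Tibble with counts in/out of QC, selected k before and after
#'   the member filter, and the winning covariance structure.
#' @export
glance.functional_clustering <- function(x, ...) {
  tibble::tibble(
    n_in = x$n_in, n_passed = x$n_passed,
    k_selected = x$model$k, structure = x$model$structure,
    k_final = x$clusters$k, n_unassigned = x$clusters$n_unassigned,
    bic = x$model$bic
  )
}
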