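#' Rescale raw depth coordinates to IPL units
#'
#' Linear map sending the GCL-side IPL border to 0 and the INL-side
#' border to 10; processes beyond the borders map outside `[0, 10]`.
#' x and z are unchanged.
#'
#' @param cloud A tibble with columns `x_um`, `y_um`, `z_um`, `is_soma`.
#' @param ipl_inner y coordinate of the GCL-side (inner) IPL border.
#' @param ipl_outer y coordinate of the INL-side (outer) IPL border.
#' @return The cloud with a `y_ipl` column, classed `morph_cloud`.
#' @export
scale_ipl_depth <- function(cloud, ipl_inner, ipl_outer) {
  if (ipl_inner == ipl_outer) abort_invalid("degenerate IPL borders.")
  cloud$y_ipl <- (cloud$y_um - ipl_inner) / (ipl_outer - ipl_inner) * 10
  if (!inherits(cloud, "morph_cloud")) {
    class(cloud) <- c("morph_cloud", class(cloud))
  }
  cloud
}

#' Convex-hull area of a planar point set
#'
#' @param x,z Coordinates in micrometres.
#' @return Hull area in um^2 (0 for fewer than 3 non-collinear points).
#' @export
convex_hull_area <- function(x, z) {
  pts <- unique(cbind(x, z))
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hz <- pts[h, 2]
  n <- length(h)
  if (n < 3L) return(0)
  abs(sum(hx * hz[c(2:n, 1)] - hx[c(2:n, 1)] * hz)) / 2
}

#' Morphological summary statistics of a point cloud
#'
#' The four per-cell statistics: `y_span` (stratification width,
#' max - min of the IPL-scaled depth), `y_mean` (mean depth), `num_pts`
#' (dendritic point count), and `xz_area` (convex-hull area of the
#' dendritic tree in the tangential plane, um^2). The soma is excluded
#' throughout.
#'
#' @param cloud A `morph_cloud` (needs `y_ipl`; see [scale_ipl_depth()]).
#' @return A one-row tibble: `y_span`, `y_mean`, `num_pts`, `xz_area`.
#' @export
summarize_morphology <- function(cloud) {
  d <- cloud[!cloud$is_soma, ]
  if (nrow(d) < 1L) abort_invalid("cloud has no dendritic points.")
  if (is.null(d$y_ipl)) abort_invalid("cloud lacks `y_ipl`; run scale_ipl_depth().")
  tibble::tibble(
    y_span = max(d$y_ipl) - min(d$y_ipl),
    y_mean = mean(d$y_ipl),
    num_pts = nrow(d),
    xz_area = convex_hull_area(d$x_um, d$z_um)
  )
}

#' Summarize a list of point clouds
#'
#' @param clouds A (possibly named) list of `morph_cloud`s.
#' @return A tibble with `cell_id`, `region` and the four summary
#'   statistics per cloud.
#' @export
summarize_morph_population <- function(clouds) {
  ids <- names(clouds) %||% as.character(seq_along(clouds))
  purrr::map2_dfr(clouds, ids, function(cl, id) {
    dplyr::bind_cols(
      tibble::tibble(cell_id = id,
                     region = attr(cl, "region") %||% NA_character_),
      summarize_morphology(cl)
    )
  })
}

#' Standardize summary-statistic columns
#'
#' Z-scores each named column (mean 0, SD 1, n - 1 denominator) so every
#' statistic is equally weighted by the clustering distance.
#'
#' @param tbl A data frame of per-cell summaries.
#' @param columns Character vector of columns to standardize.
#' @return The table with the named columns standardized.
#' @export
standardize_stats <- function(tbl, columns = c("y_span", "y_mean", "num_pts")) {
  if (nrow(tbl) < 2L) abort_invalid("need at least 2 cells.")
  for (cn in columns) {
    v <- tbl[[cn]]
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("column `%s` has zero variance", cn),
            class = "chromarg_degenerate")
    }
    tbl[[cn]] <- (v - mean(v)) / s
  }
  tbl
}

#' Agglomerative clustering with cophenetic validation
#'
#' City-block (Manhattan) distances with average linkage, cut to
#' `n_clusters`; the cophenetic correlation coefficient (CCC) — the
#' correlation between tree-implied and original pairwise distances, in
#' `[-1, 1]` — measures how faithfully the tree represents the data.
#'
#' @param tbl Data frame of (already standardized) features.
#' @param columns Feature columns to use.
#' @param n_clusters Number of clusters to cut to.
#' @param metric Distance metric (default `"manhattan"`, i.e. city
#'   block).
#' @param linkage Linkage method (default `"average"`).
#' @return A list of class `hier_clustering`: `labels`, `ccc`, `tree`.
#' @export
hier_cluster <- function(tbl, columns, n_clusters, metric = "manhattan",
                         linkage = "average") {
  x <- as.matrix(tbl[, columns, drop = FALSE])
  if (n_clusters > nrow(x)) abort_invalid("`n_clusters` exceeds the number of cells.")
  d <- dist(x, method = metric)
  tree <- hclust(d, method = linkage)
  labels <- cutree(tree, k = n_clusters)
  ccc <- if (nrow(x) > 2L) cor(cophenetic(tree), d) else NA_real_
  structure(list(labels = labels, ccc = ccc, tree = tree),
            class = "hier_clustering")
}

#' Two-stage hierarchical morphology clustering
#'
#' Stage 1 clusters all cells on the standardized (`y_span`, `y_mean`,
#' `num_pts`) triplet into `stage1_k` clusters. The stage-1 clusters
#' named in `split_spec` (by default the two largest, split into 6 and 3
#' subclusters) are then re-clustered on `y_span` alone, giving
#' `stage1_k - length(split_spec) + sum(split_spec)` clusters in total
#' (25 with the defaults). Clusters below `min_members` are excluded
#' from the presentation set but their labels are retained.
#'
#' @param tbl Per-cell summaries (raw; standardized internally).
#' @param stage1_k Stage-1 cluster count (default 18).
#' @param split_spec Named integer vector `c(<stage1 id> = <n_sub>, ...)`
#'   or an unnamed vector (default `c(6, 3)`) applied to the largest
#'   stage-1 clusters in size order.
#' @param min_members Presentation-set minimum (default 4).
#' @return A list of class `morph_clustering`: `labels` (tibble with
#'   `stage1`, `final`, `presented`), `ccc_stage1`, `ccc_splits`,
#'   `n_total_clusters`, `presented_k`, `trees`.
#' @export
two_stage_cluster <- function(tbl, stage1_k = 18, split_spec = c(6, 3),
                              min_members = 4) {
  std <- standardize_stats(tbl, c("y_span", "y_mean", "num_pts"))
  s1 <- hier_cluster(std, c("y_span", "y_mean", "num_pts"), stage1_k)
  sizes <- sort(table(s1$labels), decreasing = TRUE)
  if (is.null(names(split_spec))) {
    if (length(split_spec) > length(sizes)) {
      abort_invalid("more splits requested than stage-1 clusters.")
    }
    split_spec <- setNames(as.integer(split_spec),
                           names(sizes)[seq_along(split_spec)])
  }
  targets <- as.integer(names(split_spec))
  if (!all(targets %in% s1$labels)) {
    abort_invalid("split target absent from the stage-1 clustering.")
  }
  final <- as.integer(s1$labels)
  next_id <- stage1_k
  ccc_splits <- numeric(0)
  trees <- list(stage1 = s1$tree)
  for (j in seq_along(targets)) {
    members <- which(s1$labels == targets[j])
    n_sub <- split_spec[[j]]
    if (length(members) < n_sub) {
      abort_invalid(sprintf(
        "stage-1 cluster %d has %d members, cannot split into %d",
        targets[j], length(members), n_sub))
    }
    sub <- hier_cluster(std[members, ], "y_span", n_sub)
    final[members] <- next_id + as.integer(sub$labels)
    next_id <- next_id + n_sub
    ccc_splits <- c(ccc_splits, sub$ccc)
    trees[[paste0("split_", targets[j])]] <- sub$tree
  }
  # relabel to consecutive ids
  final <- match(final, sort(unique(final)))
  fsizes <- table(final)
  presented_ids <- as.integer(names(fsizes))[fsizes >= min_members]
  labels <- tibble::tibble(
    stage1 = as.integer(s1$labels), final = final,
    presented = final %in% presented_ids
  )
  structure(
    list(labels = labels, ccc_stage1 = s1$ccc, ccc_splits = ccc_splits,
         n_total_clusters = length(unique(final)),
         presented_k = length(presented_ids), trees = trees),
    class = "morph_clustering"
  )
}

#' Dendritic tilt in soma-centred spherical coordinates
#'
#' Translates the soma to the origin, takes the centre of mass of the
#' dendritic points (mean x, y, z; soma excluded), and converts to
#' spherical coordinates with the polar angle measured from the +y axis
#' (the axis perpendicular to the retinal plane — the y and z roles are
#' swapped relative to the usual convention): `r` the CoM distance (um),
#' `theta` in `[0, pi]` the tilt strength (0 = no tilt; pi/2 = CoM at
#' the soma's own depth), `phi = atan2(z, x)` in `[0, 2*pi)` the tilt
#' direction.
#'
#' @param cloud A `morph_cloud` containing exactly one soma row.
#' @return A list of class `tilt_coordinates`: `r`, `theta`, `phi`,
#'   `defined` (`FALSE`, with `NaN` angles, when the CoM coincides with
#'   the soma).
#' @export
compute_tilt <- function(cloud) {
  soma <- cloud[cloud$is_soma, ]
  dend <- cloud[!cloud$is_soma, ]
  if (nrow(soma) != 1L) abort_invalid("cloud must contain exactly one soma point.")
  if (nrow(dend) < 1L) abort_invalid("cloud has no dendritic points.")
  v <- unname(c(mean(dend$x_um) - soma$x_um,
                mean(dend$y_um) - soma$y_um,
                mean(dend$z_um) - soma$z_um))
  r <- sqrt(sum(v^2))
  if (r == 0) {
    return(structure(list(r = 0, theta = NaN, phi = NaN, defined = FALSE),
                     class = "tilt_coordinates"))
  }
  theta <- acos(pmin(pmax(v[2] / r, -1), 1))
  phi <- atan2(v[3], v[1]) %% (2 * pi)
  structure(list(r = r, theta = theta, phi = phi, defined = TRUE),
            class = "tilt_coordinates")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Supremum difference of the two empirical CDFs with the asymptotic
#' p-value; used for the linear tilt variables r and theta.
#'
#' @param a,b Numeric samples.
#' @return A list: `D`, `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) abort_invalid("both samples must be non-empty.")
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' Two-sample Kuiper test for circular data
#'
#' The Kuiper statistic `V = D+ + D-` (maximum positive plus maximum
#' negative deviation between the two empirical CDFs) is invariant to a
#' common rotation of both samples, making it the appropriate
#' two-sample test for the 2*pi-periodic tilt direction phi. The
#' p-value uses the standard asymptotic series with Stephens'
#' finite-sample correction of the argument.
#'
#' @param angles_a,angles_b Samples of angles in radians (any range;
#'   reduced mod 2*pi).
#' @return A list: `V`, `p`, `ne` (effective sample size).
#' @export
kuiper_two_sample <- function(angles_a, angles_b) {
  if (length(angles_a) < 1L || length(angles_b) < 1L) {
    abort_invalid("both samples must be non-empty.")
  }
  a <- angles_a %% (2 * pi)
  b <- angles_b %% (2 * pi)
  n1 <- length(a); n2 <- length(b)
  pooled <- sort(unique(c(a, b)))
  fa <- vapply(pooled, function(t) mean(a <= t), numeric(1))
  fb <- vapply(pooled, function(t) mean(b <= t), numeric(1))
  diffs <- fa - fb
  v <- max(diffs, 0) + max(-diffs, 0)
  ne <- n1 * n2 / (n1 + n2)
  lam <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * v
  p <- if (lam < 0.4) {
    1
  } else {
    j <- 1:100
    min(1, max(0, 2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))))
  }
  list(V = v, p = p, ne = ne)
}

#' Compare tilt distributions between two regions
#'
#' Runs the KS test on r and theta and the Kuiper test on phi between
#' two groups of cells (e.g. strike zone versus nasal).
#'
#' @param tilts A tibble with columns `r_um`, `theta_rad`, `phi_rad`
#'   and a grouping column.
#' @param group Name of the grouping column (two levels).
#' @return A tibble with one row per variable: `variable`, `test`,
#'   `statistic`, `p_value`.
#' @export
compare_tilt_groups <- function(tilts, group = "region") {
  g <- factor(tilts[[group]])
  if (nlevels(g) != 2L) abort_invalid("grouping column must have exactly two levels.")
  a <- tilts[g == levels(g)[1], ]
  b <- tilts[g == levels(g)[2], ]
  ks_r <- ks_two_sample(a$r_um, b$r_um)
  ks_t <- ks_two_sample(a$theta_rad, b$theta_rad)
  ku <- kuiper_two_sample(a$phi_rad, b$phi_rad)
  tibble::tibble(
    variable = c("r", "theta", "phi"),
    test = c("ks", "ks", "kuiper"),
    statistic = c(ks_r$D, ks_t$D, ku$V),
    p_value = c(ks_r$p, ks_t$p, ku$p)
  )
}

#' Tidy a morphology clustering
#'
#' @param x A `morph_clustering`.
#' @param ... Unused.
#' @return The per-cell label tibble (`stage1`, `final`, `presented`).
#' @export
tidy.morph_clustering <- function(x, ...) x$labels

#' One-row summary of a morphology clustering
#'
#' @param x A `morph_clustering`.
#' @param ... Unused.
#' @return Tibble with total/presented cluster counts and CCCs.
#' @export
glance.morph_clustering <- function(x, ...) {
  tibble::tibble(
    n_total_clusters = x$n_total_clusters,
    presented_k = x$presented_k,
    ccc_stage1 = x$ccc_stage1,
    ccc_split_1 = x$ccc_splits[1] %||% NA_real_,
    ccc_split_2 = x$ccc_splits[2] %||% NA_real_
  )
}
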