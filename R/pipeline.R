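#' Default pipeline configuration
#'
#' A single nested list drives the whole synthetic pipeline; every run
#' echoes its resolved configuration and seed into the run directory.
#' Thresholds carry their canonical defaults: 0.7 SD event detection,
#' 10 SD ternary responsiveness, 5 clustering QC, 8 x 20 Eye-IPL bins.
#'
#' @param seed Master seed; all stage randomness derives from it.
#' @return A nested list of parameter blocks.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_rois = 60L, duration = 258, event_rate_scale = 8,
                    indicator_decay = 0.4, noise_sd = 0.2,
                    trace_rate = 15.625, n_clusters = 3L),
    kernels = list(threshold_sd = 0.7),
    classify = list(ternary_threshold = 10),
    maps = list(smooth = TRUE),
    cluster_functional = list(quality_threshold = 5, k_max = 8L,
                              replicates = 5L, min_members = 10L,
                              mode = "bic", fixed_k = NULL,
                              fixed_covariance = "unshared_diag"),
    report = list(digits = 3L)
  )
}

check_config_keys <- function(config, template, path = "") {
  extra <- setdiff(names(config), names(template))
  if (length(extra) > 0L) {
    abort(sprintf("unknown config key%s: %s",
                  if (length(extra) > 1) "s" else "",
                  paste0(path, extra, collapse = ", ")),
          class = "chromarg_config_error")
  }
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      if (!is.list(config[[nm]])) {
        abort(sprintf("config key `%s%s` must be a block", path, nm),
              class = "chromarg_config_error")
      }
      check_config_keys(config[[nm]], template[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(config, template) {
  for (nm in names(config)) {
    template[[nm]] <- if (is.list(template[[nm]]) && is.list(config[[nm]])) {
      merge_config(config[[nm]], template[[nm]])
    } else {
      config[[nm]]
    }
  }
  template
}

#' Run the synthetic pipeline end to end
#'
#' Executes the stages in dependency order — simulate, kernels,
#' classify, maps, cluster-functional, report — writing each stage's
#' tidy CSV output, the resolved configuration (YAML) and a JSON
#' manifest (files, seeds, filter counts, package version) into
#' `out_dir`. Identical configurations produce byte-identical numeric
#' outputs. Unknown configuration keys abort before any computation.
#'
#' @param config A (possibly partial) configuration list merged over
#'   [default_pipeline_config()], or a path to a YAML file of one.
#' @param out_dir Run directory (created if missing).
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("chromarg_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  template <- default_pipeline_config()
  check_config_keys(config, template)
  cfg <- merge_config(config, template)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files[[name]] <<- path
    path
  }

  # stage 1: simulate
  sim <- cfg$simulate
  scfg <- sim_config(n_rois = sim$n_rois, seed = cfg$seed,
                     event_rate_scale = sim$event_rate_scale,
                     indicator_decay = sim$indicator_decay,
                     noise_sd = sim$noise_sd, trace_rate = sim$trace_rate,
                     duration = sim$duration)
  stim <- noise_stimulus(duration_s = sim$duration, seed = cfg$seed)
  pop <- make_population(scfg, default_cluster_spec(sim$n_clusters), stim = stim)
  emit(as.data.frame(stim), "stimulus.csv")
  emit(dplyr::select(pop, "roi_id", "true_cluster", "compartment",
                     "eye_pos", "ipl_depth"),
       "population.csv")

  # stage 2: kernels
  kt <- estimate_population_kernels(pop, stim,
                                    threshold_sd = cfg$kernels$threshold_sd)
  emit(dplyr::select(kt, "roi_id", "quality", "quality_sd_max", "n_events"),
       "kernels.csv")

  # stage 3: classify
  cls <- classify_rois(kt, threshold = cfg$classify$ternary_threshold)
  cls$centroid_hz <- purrr::map_dbl(cls$kernel_set, function(ks) {
    resp <- which(ks$quality >= cfg$classify$ternary_threshold)
    if (length(resp) == 0L) return(NA_real_)
    spectral_centroid(ks$kernels[, resp[which.max(ks$quality[resp])]])
  })
  emit(dplyr::select(cls, "roi_id", "ternary_index", "category",
                     "crossing_pair", "n_sign_changes",
                     "dominant_polarity", "centroid_hz"),
       "classified.csv")

  # stage 4: maps
  cls$polarity <- cls$dominant_polarity
  m_ooi <- ooi_map(cls)
  if (isTRUE(cfg$maps$smooth)) m_ooi <- smooth_map(m_ooi)
  emit(tidy(m_ooi), "ooi_map.csv")

  # stage 5: functional clustering
  fc_cfg <- cfg$cluster_functional
  fc <- tryCatch(
    cluster_functional(kt, quality_threshold = fc_cfg$quality_threshold,
                       k_max = fc_cfg$k_max, replicates = fc_cfg$replicates,
                       seed = cfg$seed, mode = fc_cfg$mode,
                       fixed_k = fc_cfg$fixed_k,
                       fixed_covariance = fc_cfg$fixed_covariance,
                       min_members = fc_cfg$min_members),
    chromarg_empty_dataset = function(e) NULL
  )
  if (!is.null(fc)) {
    emit(tidy(fc), "cluster_assignments.csv")
    emit(tidy(fc$sweep), "bic_table.csv")
  }

  # stage 6: report
  n_responsive <- sum(cls$quality >= cfg$classify$ternary_threshold)
  report <- list(
    n_rois = nrow(pop),
    n_pass_ternary_gate = n_responsive,
    pct_pass_ternary_gate = round(100 * n_responsive / nrow(pop),
                                  cfg$report$digits),
    n_pass_clustering_qc = if (is.null(fc)) 0L else fc$n_passed,
    k_selected = if (is.null(fc)) NA else fc$model$k,
    k_final = if (is.null(fc)) NA else fc$clusters$k,
    category_counts = as.list(table(cls$category))
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  files[["report.json"]] <- report_path

  yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("chromarg")),
    seed = cfg$seed,
    stages = c("simulate", "kernels", "classify", "maps",
               "cluster_functional", "report"),
    outputs = as.list(vapply(files, basename, character(1))),
    md5 = as.list(tools::md5sum(unlist(files)))
  )
  names(manifest$md5) <- basename(names(manifest$md5))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(out_dir = out_dir, manifest = manifest, config = cfg,
                 population = pop, kernels = kt, classified = cls,
                 ooi_map = m_ooi, functional = fc, report = report))
}

#' Import deposited population kernel and chirp tables
#'
#' Reads flat CSV exports of the deposited data: a kernel table with
#' columns `roi_id`, `channel`, then 649 value columns (one row per ROI
#' and colour, dt = 2 ms starting at -973.5 ms), and optionally a chirp
#' table with `roi_id` plus 2,499 value columns (dt = 1 ms). Every row
#' is validated against the canonical grid; rows of the wrong length
#' are reported with their index.
#'
#' @param kernels_csv Path to the kernel CSV.
#' @param chirps_csv Optional path to the chirp CSV.
#' @return A list: `kernels` (tibble with `roi_id` and a `kernel_set`
#'   list-column carrying the deposited waveforms; qualities recomputed
#'   from the stored z-scored kernels) and `chirps` (list of numeric
#'   vectors by ROI, or `NULL`).
#' @export
import_deposited <- function(kernels_csv, chirps_csv = NULL) {
  kt <- read.csv(kernels_csv, check.names = FALSE)
  meta_cols <- c("roi_id", "channel")
  if (!all(meta_cols %in% names(kt))) {
    abort("kernel table must carry `roi_id` and `channel` columns",
          class = "chromarg_format_error")
  }
  vals <- as.matrix(kt[, setdiff(names(kt), meta_cols), drop = FALSE])
  if (ncol(vals) != 649L) {
    abort(sprintf("kernel rows have %d samples; the canonical grid has 649",
                  ncol(vals)),
          class = "chromarg_format_error")
  }
  bad <- which(rowSums(!is.finite(vals)) > 0)
  if (length(bad) > 0L) {
    abort(sprintf("non-finite kernel values in row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "chromarg_format_error")
  }
  rois <- unique(kt$roi_id)
  sets <- purrr::map(rois, function(id) {
    sub <- kt$roi_id == id
    chans <- kt$channel[sub]
    if (!setequal(chans, channel_order())) {
      abort(sprintf("ROI %s does not carry exactly one row per channel", id),
            class = "chromarg_format_error")
    }
    k <- t(vals[sub, , drop = FALSE][match(channel_order(), chans), ])
    colnames(k) <- channel_order()
    ks <- list(kernels = k, lag_s = lag_grid(),
               quality = apply(k, 2, function(v) max(v) - min(v)),
               quality_sd = apply(k, 2, sd),
               polarity = apply(k, 2, function(v) {
                 tryCatch(classify_polarity(v),
                          chromarg_degenerate = function(e) NA_character_)
               }),
               n_events = NA_integer_)
    class(ks) <- "kernel_set"
    ks
  })
  kernels <- tibble::tibble(
    roi_id = rois, kernel_set = sets,
    quality = purrr::map_dbl(sets, ~ max(.x$quality)),
    quality_sd_max = purrr::map_dbl(sets, ~ max(.x$quality_sd))
  )
  chirps <- NULL
  if (!is.null(chirps_csv)) {
    ct <- read.csv(chirps_csv, check.names = FALSE)
    if (!"roi_id" %in% names(ct)) {
      abort("chirp table must carry a `roi_id` column",
            class = "chromarg_format_error")
    }
    cv <- as.matrix(ct[, setdiff(names(ct), "roi_id"), drop = FALSE])
    if (ncol(cv) != 2499L) {
      abort(sprintf("chirp rows have %d samples; the canonical window has 2499",
                    ncol(cv)),
            class = "chromarg_format_error")
    }
    chirps <- setNames(asplit(cv, 1), ct$roi_id)
  }
  list(kernels = kernels, chirps = chirps)
}
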