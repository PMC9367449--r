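# End-to-end batch pipeline: merge -> QC -> endpoints -> stats
# (-> EC50, -> PCA/clustering), with every artefact written to disk and the
# fully-resolved configuration echoed alongside for provenance.

#' Pipeline run configuration
#'
#' @param groups Named list, one entry per treatment group:
#'   `list(dir = "path/to/per-cell/files", concentration_uM = NA)`. The
#'   concentration field feeds the dose-response stage; leave NA for
#'   non-dose groups.
#' @param um_per_px Pixel calibration (required; see [recording_meta()]).
#' @param fps,duration_s Recording parameters.
#' @param control Name of the control group (burst threshold reference,
#'   post-hoc reference, dose-response 100%).
#' @param min_coverage,min_frames QC thresholds (see [filter_tracks()]).
#' @param max_gap_frames Gap policy for kinematics (see [step_series()]).
#' @param ec50_endpoint Endpoint column for the dose-response stage, or
#'   `NULL` to skip it; requires `concentration_uM` on at least 3 groups.
#' @param cluster_k Number of clusters to cut the column tree into when the
#'   multivariate stage runs (needs at least 3 groups).
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(groups, um_per_px, fps = 30, duration_s = 10,
                       control = names(groups)[1],
                       min_coverage = 0.85, min_frames = 30,
                       max_gap_frames = 5,
                       ec50_endpoint = NULL, cluster_k = 3,
                       out_dir = "ciliotrack_out") {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  if (!control %in% names(groups)) abort("`control` must name one of the groups.")
  for (g in names(groups)) {
    if (is.null(groups[[g]]$dir)) abort(sprintf("Group '%s' has no `dir`.", g))
  }
  structure(
    list(
      groups = groups, um_per_px = um_per_px, fps = fps, duration_s = duration_s,
      control = control, min_coverage = min_coverage, min_frames = min_frames,
      max_gap_frames = max_gap_frames, ec50_endpoint = ec50_endpoint,
      cluster_k = cluster_k, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file with the fields of `run_config()`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$groups <- lapply(cfg$groups, function(g) {
    g$concentration_uM <- g$concentration_uM %||% NA_real_
    g
  })
  do.call(run_config, cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full locomotion pipeline
#'
#' For every group: merge the per-cell tracker exports, QC-filter, and
#' compute the six endpoints against the control group's pooled burst
#' threshold. Then compare all endpoints across groups, and — when
#' configured — fit the dose-response curve and run the PCA/clustering
#' stage. All tables are written as CSV (plus JSON for the QC report and
#' EC50 fit, plain Newick for the trees) under `cfg$out_dir`; rerunning on
#' identical inputs reproduces identical files.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory results
#'   (`endpoints`, `summaries`, `stats`, `qc`, `ec50`, `multivariate`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  sets <- list()
  qcs <- list()
  for (g in names(cfg$groups)) {
    meta <- recording_meta(
      fps = cfg$fps, duration_s = cfg$duration_s,
      um_per_px = cfg$um_per_px, recording_id = g
    )
    merged <- stage(paste0("merge:", g), merge_tracks(cfg$groups[[g]]$dir, meta, group_label = g))
    filtered <- stage(paste0("qc:", g), filter_tracks(
      merged,
      min_coverage = cfg$min_coverage, min_frames = cfg$min_frames
    ))
    sets[[g]] <- filtered
    qcs[[g]] <- qc_report(filtered)
  }

  # burst threshold: pooled Q3 of the control group's step speeds
  control_steps <- stage("burst-threshold", step_series(
    sets[[cfg$control]],
    max_gap_frames = cfg$max_gap_frames
  ))
  thr <- burst_threshold(pooled_speeds(control_steps))

  endpoints <- purrr::map(names(sets), function(g) {
    stage(paste0("endpoints:", g), compute_endpoints(
      sets[[g]],
      group_label = g,
      max_gap_frames = cfg$max_gap_frames,
      burst_threshold_um_s = thr
    ))
  }) |> dplyr::bind_rows()

  summaries <- summarize_endpoints(endpoints)
  stats_tbl <- if (length(sets) >= 2) {
    stage("compare", compare_endpoints(endpoints, control = cfg$control))
  } else {
    NULL
  }

  combined <- dplyr::bind_rows(purrr::map(names(sets), function(g) {
    dplyr::mutate(tibble::as_tibble(sets[[g]]), group = g)
  }))
  readr::write_csv(combined, file.path(cfg$out_dir, "combined.csv"), progress = FALSE)
  jsonlite::write_json(
    purrr::map(qcs, function(q) {
      list(n_input = q$n_input, n_kept = q$n_kept, n_dropped = q$n_dropped,
           drop_reasons = q$drop_reasons)
    }),
    file.path(cfg$out_dir, "qc_report.json"),
    auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(endpoints, file.path(cfg$out_dir, "endpoints.csv"), progress = FALSE)
  readr::write_csv(summaries, file.path(cfg$out_dir, "endpoint_summaries.csv"), progress = FALSE)
  if (!is.null(stats_tbl)) {
    readr::write_csv(stats_tbl, file.path(cfg$out_dir, "group_stats.csv"), progress = FALSE)
  }

  # per-cell polylines over valid frames, for trajectory plots
  traj_plot <- combined |>
    dplyr::filter(.data$valid) |>
    dplyr::select("group", "cell_id", "frame", "x_um", "y_um")
  readr::write_csv(traj_plot, file.path(cfg$out_dir, "trajectory_plot.csv"), progress = FALSE)

  ec50 <- NULL
  if (!is.null(cfg$ec50_endpoint)) {
    conc <- purrr::map_dbl(cfg$groups, ~ .x$concentration_uM %||% NA_real_)
    dosed <- names(conc)[is.finite(conc)]
    if (length(unique(conc[is.finite(conc) & conc > 0])) >= 3 && cfg$control %in% names(sets)) {
      ctrl_vals <- endpoints[[cfg$ec50_endpoint]][endpoints$group == cfg$control]
      dr <- endpoints |>
        dplyr::filter(.data$group %in% dosed) |>
        dplyr::mutate(
          concentration_uM = conc[.data$group],
          response_pct = normalize_to_control(.data[[cfg$ec50_endpoint]], ctrl_vals)
        )
      ec50 <- stage("ec50", fit_dose_response(dr, "concentration_uM", "response_pct"))
      write_dose_response_json(ec50, file.path(cfg$out_dir, "ec50_fit.json"))
      if (!is.null(ec50$curve)) {
        readr::write_csv(ec50$curve, file.path(cfg$out_dir, "ec50_curve.csv"), progress = FALSE)
      }
    }
  }

  multivariate <- NULL
  if (length(sets) >= 3) {
    m <- behavior_matrix(endpoints)
    clus <- stage("cluster", cluster_heatmap(m))
    pca <- stage("pca", pca_svd(clus$scaled))
    readr::write_csv(
      as_tibble(pca$scores, rownames = "group"),
      file.path(cfg$out_dir, "pca_scores.csv"), progress = FALSE
    )
    readr::write_csv(
      as_tibble(pca$loadings, rownames = "endpoint"),
      file.path(cfg$out_dir, "pca_loadings.csv"), progress = FALSE
    )
    readr::write_csv(
      as_tibble(clus$heatmap_values, rownames = "endpoint"),
      file.path(cfg$out_dir, "heatmap_matrix.csv"), progress = FALSE
    )
    writeLines(hclust_to_newick(clus$col_tree), file.path(cfg$out_dir, "col_tree.nwk"))
    writeLines(hclust_to_newick(clus$row_tree), file.path(cfg$out_dir, "row_tree.nwk"))
    multivariate <- list(matrix = m, clustering = clus, pca = pca,
                         clusters = cut_cluster(clus, k = min(cfg$cluster_k, ncol(m))))
  }

  # provenance: resolved config + its hash + package version
  cfg_yaml <- file.path(cfg$out_dir, "run_config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_yaml)
  writeLines(
    c(
      sprintf("ciliotrack %s", as.character(utils::packageVersion("ciliotrack"))),
      sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("config_md5 %s", unname(tools::md5sum(cfg_yaml))),
      sprintf("burst_threshold_um_s %.10g", thr)
    ),
    file.path(cfg$out_dir, "run_log.txt")
  )

  invisible(list(
    endpoints = endpoints, summaries = summaries, stats = stats_tbl,
    qc = qcs, ec50 = ec50, multivariate = multivariate,
    burst_threshold_um_s = thr
  ))
}

#' Trajectory overview plot
#'
#' Per-cell swimming paths over the recording window, the standard visual
#' sanity check of a tracking run.
#'
#' @param trajectories Long trajectory tibble.
#' @param max_cells Cap on the number of cells drawn.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, max_cells = 100) {
  ids <- unique(trajectories$cell_id)
  if (length(ids) > max_cells) ids <- ids[seq_len(max_cells)]
  df <- trajectories |>
    dplyr::filter(.data$valid, .data$cell_id %in% ids)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$y_um, group = .data$cell_id)) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
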