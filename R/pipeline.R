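# End-to-end orchestration: generate/load -> segment -> measure ->
# associate -> cluster -> stats, with a validated declarative config and a
# JSON run manifest for reproducibility.

.default_run_config <- function() {
  list(
    input_dir = NULL,
    out_dir = NULL,
    mode = "rodent-3d",
    seed = 42L,
    frangi = list(scales = c(1, 2, 3, 4, 5), gamma_fraction = 0.4,
                  alpha = 0.5, beta = 0.5),
    segmentation = list(soma_min_area = 60, threshold_method = "otsu",
                        single_cell_min_size = 2000, igg_threshold = 25,
                        igg_min_area = 5),
    morphometrics = list(prune_um = 1, enabled = TRUE),
    vam = list(attach_distance = NULL),
    clustering = list(enabled = TRUE, k = 4, n_neighbors = 15,
                      min_dist = 0.1, seed = 42L),
    stats = list(enabled = TRUE, response = "vam_frequency")
  )
}

#' Validate and normalize a pipeline run configuration
#'
#' Fills all defaults, rejects unknown keys (no silent ignoring) and checks
#' ranges. `config` may be a YAML file path or a nested list with the same
#' structure.
#'
#' @param config path to a YAML config file, or a list.
#' @return the normalized configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- .default_run_config()
  errs <- character()
  check_keys <- function(x, ref, path) {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown))
      errs <<- c(errs, paste0("unknown key", if (length(unknown) > 1) "s",
                              ": ", paste0(path, unknown, collapse = ", ")))
  }
  check_keys(config, defaults, "")
  for (blk in c("frangi", "segmentation", "morphometrics", "vam",
                "clustering", "stats")) {
    if (!is.null(config[[blk]])) {
      if (!is.list(config[[blk]])) {
        errs <- c(errs, paste0(blk, " must be a block of key/value pairs"))
      } else check_keys(config[[blk]], defaults[[blk]], paste0(blk, "."))
    }
  }
  cfg <- modifyList(defaults, config)
  if (!cfg$mode %in% c("rodent-3d", "human-2d"))
    errs <- c(errs, "mode must be rodent-3d or human-2d")
  if (!(cfg$frangi$gamma_fraction > 0 && cfg$frangi$gamma_fraction <= 1))
    errs <- c(errs, "frangi.gamma_fraction out of range (0, 1]")
  if (any(cfg$frangi$scales <= 0))
    errs <- c(errs, "frangi.scales must be positive")
  if (cfg$segmentation$soma_min_area <= 0)
    errs <- c(errs, "segmentation.soma_min_area must be positive")
  if (cfg$clustering$k < 1) errs <- c(errs, "clustering.k must be >= 1")
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  cfg
}

#' Run the full quantification pipeline on a dataset
#'
#' Expects the dataset layout written by [simulate_dataset()] (an
#' `index.csv` with `group`, `fov_id`, `tiff`, plus per-FOV TIFFs with JSON
#' sidecars). Per field of view: vessel segmentation, soma detection, IgG
#' quantification, VAM classification; optionally single-cell morphometrics
#' and morphology clustering; finally Welch tests on the per-FOV summaries
#' between groups. Writes `fov_summary.csv`, `cells.csv`,
#' `cluster_labels.csv`, `stats.csv` and `run_manifest.json` into
#' `out_dir`.
#'
#' @param config configuration accepted by [validate_config()]; must set
#'   `input_dir` and `out_dir`.
#' @return list with the report tables (`fov_summary`, `cells`, `clusters`,
#'   `stats`) and the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  if (is.null(cfg$input_dir) || is.null(cfg$out_dir))
    stop("config must set input_dir and out_dir")
  index_path <- file.path(cfg$input_dir, "index.csv")
  if (!file.exists(index_path)) stop("no index.csv under ", cfg$input_dir)
  index <- read.csv(index_path, stringsAsFactors = FALSE)
  if (anyDuplicated(index$fov_id)) stop("duplicate FOV ids in index")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  seg_par <- do.call(segmentation_params, cfg$segmentation)
  fr_par <- do.call(frangi_params, cfg$frangi)

  fov_rows <- list(); cell_rows <- list()
  for (i in seq_len(nrow(index))) {
    fov_id <- index$fov_id[i]
    vol <- withCallingHandlers(
      read_fov_tiff(index$tiff[i]),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(fov_id, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    res <- tryCatch(
      .process_fov(vol, cfg, seg_par, fr_par, fov_id),
      error = function(e) stop("stage failure in FOV ", fov_id, ": ",
                               conditionMessage(e)))
    warnings_log <- c(warnings_log, res$warnings)
    row <- cbind(data.frame(group = index$group[i], fov_id = fov_id),
                 res$summary)
    fov_rows[[i]] <- row
    if (nrow(res$cells)) {
      res$cells$group <- index$group[i]
      res$cells$fov_id <- fov_id
      cell_rows[[length(cell_rows) + 1L]] <- res$cells
    }
  }
  fov_summary <- do.call(rbind, fov_rows)
  cells <- if (length(cell_rows)) do.call(rbind, cell_rows) else data.frame()

  clusters <- data.frame()
  if (isTRUE(cfg$clustering$enabled) && nrow(cells) >= max(cfg$clustering$k, 5)) {
    cl <- tryCatch(
      cluster_morphologies(cells, k = cfg$clustering$k, by = "group",
                           seed = cfg$clustering$seed),
      error = function(e) {
        warnings_log <<- c(warnings_log,
                           paste0("clustering skipped: ", conditionMessage(e)))
        NULL
      })
    if (!is.null(cl)) {
      clusters <- data.frame(fov_id = cells$fov_id, cell_id = cells$cell_id,
                             group = cells$group, cluster = cl$labels,
                             umap1 = cl$embedding[, 1], umap2 = cl$embedding[, 2])
    }
  } else if (isTRUE(cfg$clustering$enabled)) {
    warnings_log <- c(warnings_log,
                      "too few cells for clustering; stage skipped")
  }

  stats_tab <- data.frame()
  if (isTRUE(cfg$stats$enabled) && length(unique(fov_summary$group)) >= 2) {
    groups <- unique(fov_summary$group)
    pairs <- utils::combn(groups, 2)
    out <- list()
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      for (resp in c("vam_frequency", "igg_percent", "microglia_per_mm2")) {
        x <- fov_summary[[resp]][fov_summary$group == g1]
        y <- fov_summary[[resp]][fov_summary$group == g2]
        res <- tryCatch(welch_t(x, y), error = function(e) NULL)
        if (!is.null(res)) {
          res$response <- resp
          res$comparison <- paste(g1, "vs", g2)
          out[[length(out) + 1L]] <- res
        }
      }
    }
    if (length(out)) stats_tab <- do.call(rbind, out)
  }

  paths <- c(fov_summary = file.path(cfg$out_dir, "fov_summary.csv"),
             cells = file.path(cfg$out_dir, "cells.csv"),
             clusters = file.path(cfg$out_dir, "cluster_labels.csv"),
             stats = file.path(cfg$out_dir, "stats.csv"))
  write.csv(fov_summary, paths["fov_summary"], row.names = FALSE)
  write.csv(cells, paths["cells"], row.names = FALSE)
  write.csv(clusters, paths["clusters"], row.names = FALSE)
  write.csv(stats_tab, paths["stats"], row.names = FALSE)
  manifest <- list(config = cfg[setdiff(names(cfg), c("input_dir", "out_dir"))],
                   n_fov = nrow(index),
                   outputs = as.list(setNames(unname(tools::md5sum(paths)),
                                              names(paths))),
                   warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fov_summary = fov_summary, cells = cells,
                 clusters = clusters, stats = stats_tab,
                 manifest = manifest))
}

# single-FOV stage chain
.process_fov <- function(vol, cfg, seg_par, fr_par, fov_id) {
  warns <- character()
  wcap <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, paste0(fov_id, ": ", conditionMessage(w)))
    invokeRestart("muffleWarning")
  })
  vs <- vol$voxel_size
  vseg <- wcap(segment_vessels(vol, fr_par))
  somata <- wcap(segment_somata(vol, params = seg_par))
  igg_pct <- if (!is.null(vol$channels$igg))
    wcap(quantify_igg(vol, params = seg_par)) else NA_real_
  vam <- wcap(classify_vam(somata$labels, vseg$mask, vs,
                           attach_distance = cfg$vam$attach_distance))
  vsum <- vam_summary(vam, vol$dim, vs)
  cells_tab <- data.frame()
  if (isTRUE(cfg$morphometrics$enabled) && somata$n_somata > 0) {
    mode <- if (cfg$mode == "human-2d") "human-2d" else "rodent-3d"
    cells <- wcap(extract_single_cells(vol, somata$labels, params = seg_par,
                                       mode = mode))
    if (length(cells)) {
      n_touch <- sum(vapply(cells, function(cl) isTRUE(cl$touching), logical(1)))
      if (n_touch > 0)
        warns <- c(warns, paste0(fov_id, ": ", n_touch,
                                 " touching cells excluded"))
      cells_tab <- wcap(morphology_table(cells, vs,
                                         prune_um = cfg$morphometrics$prune_um))
      if (nrow(cells_tab)) {
        cells_tab$is_vam <- vam$is_vam[match(cells_tab$cell_id, vam$cell_id)]
      }
    }
  }
  summary <- cbind(vsum,
                   data.frame(igg_percent = igg_pct,
                              soma_count = somata$n_somata,
                              mean_soma_area_um2 =
                                if (somata$n_somata) mean(somata$somata$area_um2)
                                else NA_real_,
                              vessel_low = vseg$thresholds$low,
                              vessel_high = vseg$thresholds$high))
  list(summary = summary, cells = cells_tab, warnings = warns)
}
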