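# Composition of complete synthetic fields of view and datasets.

#' Simulate one synthetic field of view
#'
#' Runs [generate_vessels()], [generate_microglia()] and
#' [generate_leakage()], composes the three channels with the background
#' level, and applies acquisition noise with per-channel derived seeds. All
#' ground truth is returned alongside.
#'
#' @param config a [fov_config()].
#' @param fov_id identifier recorded in the truth tables.
#' @return list: `volume` (an [image_volume()] with channels `iba1`,
#'   `vessel`, `igg`), `clean` (noise-free channels), `truth` (vessels,
#'   cells, leakage ground truth).
#' @export
simulate_fov <- function(config, fov_id = "fov1") {
  stopifnot(inherits(config, "fov_config"))
  ves <- generate_vessels(config)
  mic <- generate_microglia(config, ves$truth, fov_id = fov_id)
  igg <- generate_leakage(config, ves$truth)
  bg <- config$background
  clean <- list(iba1 = mic$channel + bg,
                vessel = ves$channel + bg,
                igg = igg$channel + bg * 0.8) # keep baseline below threshold
  noisy <- list(
    iba1 = add_noise(clean$iba1, config$noise$sigma, config$noise$poisson,
                     .derive_seed(config$seed, 101L)),
    vessel = add_noise(clean$vessel, config$noise$sigma, config$noise$poisson,
                       .derive_seed(config$seed, 102L)),
    igg = add_noise(clean$igg, config$noise$sigma, config$noise$poisson,
                    .derive_seed(config$seed, 103L)))
  vs <- config$voxel_size
  if (config$shape[3] == 1L) {
    noisy <- lapply(noisy, function(a) array(a, dim = config$shape[1:2]))
    clean <- lapply(clean, function(a) array(a, dim = config$shape[1:2]))
    vs <- vs[1:2]
  }
  truth <- list(vessels = ves$truth, cells = mic$truth,
                true_leakage_fraction = igg$true_leakage_fraction,
                fov_id = fov_id)
  list(volume = image_volume(noisy, vs), clean = clean, truth = truth)
}

#' Simulate a multi-FOV dataset and write it to disk
#'
#' Per-FOV RNG streams derive from the master seed and the FOV index, so a
#' dataset is reproducible as a whole and per FOV. Writes one multi-channel
#' TIFF per FOV (with JSON sidecar), per-vessel/per-cell truth CSVs and a
#' JSON run manifest holding the full configuration.
#'
#' @param out_dir output directory (created if needed).
#' @param groups named list: for each experimental group, a list with
#'   `n_fov` and optional [fov_config()] overrides (e.g.
#'   `list(control = list(n_fov = 4, vam_fraction = 0.1))`).
#' @param base_config baseline [fov_config()]; per-group overrides are
#'   applied on top.
#' @param seed master seed.
#' @return data frame index of the dataset (group, fov_id, tiff path),
#'   invisibly; files under `out_dir`.
#' @export
simulate_dataset <- function(out_dir, groups, base_config = fov_config(),
                             seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  index <- list(); truth_cells <- list(); truth_fov <- list()
  fov_counter <- 0L
  for (g in names(groups)) {
    spec <- groups[[g]]
    n_fov <- spec$n_fov %||% 1L
    overrides <- spec[setdiff(names(spec), "n_fov")]
    for (i in seq_len(n_fov)) {
      fov_counter <- fov_counter + 1L
      cfg_args <- modifyList(unclass(base_config), overrides)
      cfg_args$seed <- .derive_seed(seed, fov_counter)
      cfg <- do.call(fov_config, cfg_args)
      fov_id <- sprintf("%s_fov%02d", g, i)
      sim <- simulate_fov(cfg, fov_id = fov_id)
      tiff_path <- file.path(out_dir, paste0(fov_id, ".tif"))
      write_fov_tiff(sim$volume, tiff_path)
      index[[fov_counter]] <- data.frame(group = g, fov_id = fov_id,
                                         tiff = tiff_path)
      cells <- sim$truth$cells$cells
      if (!is.null(cells) && nrow(cells)) {
        cells$group <- g; cells$fov_id <- fov_id
        truth_cells[[length(truth_cells) + 1L]] <- cells
      }
      truth_fov[[fov_counter]] <- data.frame(
        group = g, fov_id = fov_id,
        n_cells = if (is.null(cells)) 0L else nrow(cells),
        n_vam_planted = if (is.null(cells)) 0L else sum(cells$is_vam),
        true_leakage_fraction = sim$truth$true_leakage_fraction)
    }
  }
  index <- do.call(rbind, index)
  write.csv(index, file.path(out_dir, "index.csv"), row.names = FALSE)
  if (length(truth_cells))
    write.csv(do.call(rbind, truth_cells),
              file.path(out_dir, "truth_cells.csv"), row.names = FALSE)
  write.csv(do.call(rbind, truth_fov),
            file.path(out_dir, "truth_fov.csv"), row.names = FALSE)
  manifest <- list(seed = seed,
                   base_config = unclass(base_config),
                   groups = groups,
                   created = "synthetic dataset manifest")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(index)
}
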