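## Config-driven batch orchestration: seeded synthetic-data generation,
## per-image fractal-dimension runs, per-drop colour quantification and the
## statistics stage, each writing plain CSV so a whole study is
## reproducible from one YAML file and one seed.  A resolved copy of the
## config is written next to the outputs for provenance, and identical
## config + seed give byte-identical output trees.

pipeline_schema <- list(
  top = c("version", "seed", "output_dir", "simulate", "fd", "colour", "stats"),
  simulate = c("mycelium", "drops", "fractals"),
  mycelium = c("name", "medium", "timepoint", "n_images", "params"),
  drop_scene = c("name", "medium", "width_px", "height_px", "drops",
                 "red_rgb", "medium_rgb", "bg_rgb", "noise_sd"),
  fractal = c("name", "kind", "size_px", "level", "density"),
  fd = c("sizes", "kuwahara", "threshold", "mask_fill", "min_edge_contrast"),
  kuwahara = c("variant", "window", "n_orientations"),
  threshold = c("name", "fixed_value"),
  colour = c("min_particle_px", "threshold", "min_class_separation"),
  stats = c("fd_response", "colour_response")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown config key(s) in %s: %s", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
}

#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent list) with a
#' versioned schema; unknown keys anywhere are rejected before any
#' computation. Sections: `simulate` (mycelium groups, drop scenes,
#' fractal fixtures), `fd` (box-size series, Kuwahara and threshold
#' settings), `colour`, `stats`. `seed` and `output_dir` are required.
#'
#' @param config path to a YAML file, or a list.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  check_keys(config, pipeline_schema$top, "top level")
  if (is.null(config$version) || config$version != 1)
    stop("config version must be 1", call. = FALSE)
  if (is.null(config$seed) || is.null(config$output_dir))
    stop("config requires `seed` and `output_dir`", call. = FALSE)
  sim <- config$simulate %||% list()
  check_keys(sim, pipeline_schema$simulate, "simulate")
  for (g in sim$mycelium %||% list())
    check_keys(g, pipeline_schema$mycelium, "simulate.mycelium entry")
  for (g in sim$drops %||% list())
    check_keys(g, pipeline_schema$drop_scene, "simulate.drops entry")
  for (g in sim$fractals %||% list())
    check_keys(g, pipeline_schema$fractal, "simulate.fractals entry")
  check_keys(config$fd %||% list(), pipeline_schema$fd, "fd")
  check_keys(config$fd$kuwahara %||% list(), pipeline_schema$kuwahara,
             "fd.kuwahara")
  check_keys(config$fd$threshold %||% list(), pipeline_schema$threshold,
             "fd.threshold")
  check_keys(config$colour %||% list(), pipeline_schema$colour, "colour")
  check_keys(config$colour$threshold %||% list(), pipeline_schema$threshold,
             "colour.threshold")
  check_keys(config$stats %||% list(), pipeline_schema$stats, "stats")
  config$seed <- as.integer(config$seed)
  class(config) <- c("pipeline_config", class(config))
  config
}

# deterministic sub-seed stream derived from the master seed
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 7919 + counter * 104729) %% 2147483562 + 1)
}

fd_cfg_from_config <- function(config) {
  fd <- config$fd %||% list()
  kw <- fd$kuwahara %||% list()
  th <- fd$threshold %||% list()
  list(
    kuwahara = kuwahara_config(variant = kw$variant %||% "linear",
                               window = kw$window %||% 5L,
                               n_orientations = kw$n_orientations %||% 8L),
    threshold = threshold_method(name = th$name %||% "isodata",
                                 fixed_value = th$fixed_value),
    series = box_size_series(fd$sizes %||% c(3L, 6L, 12L, 24L, 48L, 96L,
                                             192L, 384L)),
    mask_fill = fd$mask_fill %||% 0L,
    min_edge_contrast = fd$min_edge_contrast %||% 128
  )
}

write_csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
}

#' Generate the synthetic inputs described by a config
#'
#' Writes, under `output_dir`: one grayscale PNG + skeleton-mask PNG + JSON
#' sidecar per simulated mycelium image, one RGB PNG + JSON sidecar (drop
#' polygons and ground-truth red fractions) per drop scene, one mask PNG +
#' sidecar (theoretical dimension) per fractal fixture, and manifest CSVs.
#' Re-running with the same config and seed reproduces every file.
#'
#' @param config a [pipeline_config()] (or path / list coercible to one).
#' @return invisibly, a list of manifest data frames.
#' @export
pipeline_simulate <- function(config) {
  cfg <- pipeline_config(config)
  out <- cfg$output_dir
  dir.create(file.path(out, "images"), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out, "config_resolved.yaml"))
  counter <- 0L
  myc_rows <- list()
  for (g in cfg$simulate$mycelium %||% list()) {
    for (i in seq_len(g$n_images %||% 1L)) {
      counter <- counter + 1L
      seed_i <- derive_seed(cfg$seed, counter)
      args <- g$params %||% list()
      args$seed <- seed_i
      p <- do.call(mycelium_params, args)
      sim <- simulate_mycelium(p)
      id <- sprintf("%s_%02d", g$name, i)
      img_file <- file.path("images", paste0(id, ".png"))
      write_image(sim$image, file.path(out, img_file))
      write_image(255 * (sim$skeleton + 0),
                  file.path(out, "images", paste0(id, "_skeleton.png")))
      jsonlite::write_json(list(image_id = id, params = unclass(p),
                                skeleton_px = sum(sim$skeleton)),
                           file.path(out, "images", paste0(id, ".json")),
                           auto_unbox = TRUE, digits = NA)
      myc_rows[[length(myc_rows) + 1L]] <-
        data.frame(image_id = id, file = img_file,
                   medium = g$medium %||% NA_character_,
                   timepoint = g$timepoint %||% NA,
                   replicate = i, seed = seed_i)
    }
  }
  drop_rows <- list()
  for (g in cfg$simulate$drops %||% list()) {
    counter <- counter + 1L
    seed_i <- derive_seed(cfg$seed, counter)
    drops <- lapply(g$drops, function(d) d[c("cx", "cy", "r", "red_fraction")])
    p <- drop_scene_params(width_px = g$width_px, height_px = g$height_px,
                           drops = drops,
                           red_rgb = unlist(g$red_rgb %||% c(180L, 30L, 40L)),
                           medium_rgb = unlist(g$medium_rgb %||% c(210L, 200L, 150L)),
                           bg_rgb = unlist(g$bg_rgb %||% c(245L, 245L, 245L)),
                           noise_sd = g$noise_sd %||% 4, seed = seed_i)
    scene <- render_drop_scene(p)
    id <- g$name
    img_file <- file.path("images", paste0(id, ".png"))
    write_image(scene$image, file.path(out, img_file))
    rois <- lapply(g$drops, function(d)
      circle_polygon(d$cx, d$cy, d$r))
    write_roi_json(list(polygons = rois),
                   file.path(out, "images", paste0(id, ".roi.json")))
    jsonlite::write_json(list(scene_id = id, truth = scene$truth,
                              seed = seed_i),
                         file.path(out, "images", paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    medium <- g$medium %||% rep(NA_character_, length(g$drops))
    drop_rows[[length(drop_rows) + 1L]] <-
      data.frame(scene_id = id, file = img_file,
                 drop_id = seq_along(g$drops),
                 medium = unlist(medium),
                 true_red_fraction = scene$truth$true_red_fraction,
                 seed = seed_i)
  }
  frac_rows <- list()
  for (g in cfg$simulate$fractals %||% list()) {
    counter <- counter + 1L
    fx <- render_fractal(g$kind, size_px = g$size_px, level = g$level,
                         density = g$density,
                         seed = if (identical(g$kind, "random_dust"))
                           derive_seed(cfg$seed, counter) else NULL)
    id <- g$name
    img_file <- file.path("images", paste0(id, ".png"))
    write_image(255 * (fx$mask + 0), file.path(out, img_file))
    jsonlite::write_json(list(fixture_id = id, kind = g$kind,
                              dimension = fx$dimension),
                         file.path(out, "images", paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    frac_rows[[length(frac_rows) + 1L]] <-
      data.frame(fixture_id = id, file = img_file, kind = g$kind,
                 dimension = fx$dimension)
  }
  manifests <- list(mycelium = do.call(rbind, myc_rows),
                    drops = do.call(rbind, drop_rows),
                    fractals = do.call(rbind, frac_rows))
  if (!is.null(manifests$mycelium))
    write_csv_stable(manifests$mycelium, file.path(out, "manifest_mycelium.csv"))
  if (!is.null(manifests$drops))
    write_csv_stable(manifests$drops, file.path(out, "manifest_drops.csv"))
  if (!is.null(manifests$fractals))
    write_csv_stable(manifests$fractals, file.path(out, "manifest_fractals.csv"))
  invisible(manifests)
}

#' Run the fractal-dimension stage over a generated image set
#'
#' Reads `manifest_mycelium.csv` under the config's `output_dir`, applies
#' the full treatment ([fd_pipeline()]) to each image (using a
#' `<image>.roi.json` sidecar if present) and writes one row per image to
#' `fd.csv`. A failing image is recorded with a flag and the run
#' continues.
#'
#' @param config a [pipeline_config()].
#' @return the fd table, invisibly.
#' @export
pipeline_fd <- function(config) {
  cfg <- pipeline_config(config)
  out <- cfg$output_dir
  man <- utils::read.csv(file.path(out, "manifest_mycelium.csv"))
  fdc <- fd_cfg_from_config(cfg)
  rows <- lapply(seq_len(nrow(man)), function(i) {
    img_path <- file.path(out, man$file[i])
    roi_path <- sub("\\.png$", ".roi.json", img_path)
    res <- tryCatch({
      img <- read_image(img_path)
      rois <- if (file.exists(roi_path)) {
        rj <- read_roi_json(roi_path)
        list(rect = if (length(rj$rects)) rj$rects[[1L]],
             polygons = rj$polygons)
      }
      fd_pipeline(img, rois, fdc)
    }, error = function(e) {
      structure(list(fd = NA_real_, intercept = NA_real_,
                     r_squared = NA_real_, sizes_used = integer(0),
                     counts_used = integer(0), flags = paste0("error: ",
                     conditionMessage(e))), class = "fd_estimate")
    })
    data.frame(image_id = man$image_id[i], medium = man$medium[i],
               timepoint = man$timepoint[i], replicate = man$replicate[i],
               sizes = paste(res$sizes_used, collapse = ";"),
               counts = paste(res$counts_used, collapse = ";"),
               fd = res$fd, intercept = res$intercept,
               r_squared = res$r_squared,
               flags = paste(res$flags, collapse = ";"))
  })
  fd_tab <- do.call(rbind, rows)
  write_csv_stable(fd_tab, file.path(out, "fd.csv"))
  invisible(fd_tab)
}

#' Run the colour-quantification stage over generated drop scenes
#'
#' Reads `manifest_drops.csv`, quantifies percent red per drop through
#' [quantify_red_in_drops()] with the drop polygons of each scene's ROI
#' sidecar, and writes `colour.csv`.
#'
#' @param config a [pipeline_config()].
#' @return the colour table, invisibly.
#' @export
pipeline_colour <- function(config) {
  cfg <- pipeline_config(config)
  out <- cfg$output_dir
  man <- utils::read.csv(file.path(out, "manifest_drops.csv"))
  col_cfg <- cfg$colour %||% list()
  th <- col_cfg$threshold %||% list()
  tm <- threshold_method(name = th$name %||% "huang",
                         fixed_value = th$fixed_value)
  rows <- lapply(unique(man$scene_id), function(sid) {
    scene_rows <- man[man$scene_id == sid, ]
    img <- read_image(file.path(out, scene_rows$file[1L]))
    rois <- read_roi_json(file.path(out, sub("\\.png$", ".roi.json",
                                             scene_rows$file[1L])))$polygons
    q <- quantify_red_in_drops(img, rois,
                               min_particle_px = col_cfg$min_particle_px %||% 0L,
                               threshold = tm,
                               min_class_separation =
                                 col_cfg$min_class_separation %||% 16)
    cbind(scene_id = sid, q,
          medium = scene_rows$medium[match(q$drop_id, scene_rows$drop_id)],
          true_red_fraction = scene_rows$true_red_fraction[
            match(q$drop_id, scene_rows$drop_id)])
  })
  col_tab <- do.call(rbind, rows)
  write_csv_stable(col_tab, file.path(out, "colour.csv"))
  invisible(col_tab)
}

#' Run the statistics stage on the fd and colour tables
#'
#' For the fd table: a two-way ANOVA (medium x timepoint, Type II) with
#' Tukey contrasts when both factors vary; a one-way ANOVA with Tukey
#' contrasts when only the medium varies; a Welch t test when the medium
#' has exactly two levels. For the colour table: a one-way ANOVA of
#' percent red over media plus Tukey contrasts. Results are written as
#' tidy CSVs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of the result tables.
#' @export
pipeline_stats <- function(config) {
  cfg <- pipeline_config(config)
  out <- cfg$output_dir
  results <- list()
  fd_path <- file.path(out, "fd.csv")
  if (file.exists(fd_path)) {
    fd_tab <- utils::read.csv(fd_path)
    fd_tab <- fd_tab[is.finite(fd_tab$fd), ]
    n_med <- length(unique(fd_tab$medium))
    n_tp <- length(unique(fd_tab$timepoint))
    if (n_med >= 2L && n_tp >= 2L) {
      results$fd_anova <- two_way_anova(fd_tab, "fd", "medium", "timepoint")
      results$fd_tukey <- rbind(
        tukey_hsd(fd_tab, "factor_a", "fd", "medium", "timepoint"),
        tukey_hsd(fd_tab, "factor_b", "fd", "medium", "timepoint"))
    } else if (n_med == 2L) {
      g <- split(fd_tab$fd, fd_tab$medium)
      w <- welch_t_test(g[[1L]], g[[2L]])
      results$fd_welch <- data.frame(group_a = names(g)[1L],
                                     group_b = names(g)[2L],
                                     statistic = w$statistic, df = w$df,
                                     p_value = w$p_value, mean_a = w$mean_a,
                                     sd_a = w$sd_a, n_a = w$n_a,
                                     mean_b = w$mean_b, sd_b = w$sd_b,
                                     n_b = w$n_b)
    } else if (n_med > 2L) {
      results$fd_anova <- one_way_anova(fd_tab, "fd", "medium")
      results$fd_tukey <- tukey_hsd(fd_tab, "factor_a", "fd", "medium")
    }
  }
  col_path <- file.path(out, "colour.csv")
  if (file.exists(col_path)) {
    col_tab <- utils::read.csv(col_path)
    col_tab <- col_tab[!col_tab$excluded, ]
    # an F test needs >= 2 levels and residual df (>= 2 drops per medium)
    if (length(unique(col_tab$medium)) >= 2L &&
        min(table(col_tab$medium)) >= 2L) {
      results$colour_anova <- one_way_anova(col_tab, "percent_red", "medium")
      results$colour_tukey <- tukey_hsd(col_tab, "factor_a", "percent_red",
                                        "medium")
    }
  }
  for (nm in names(results))
    write_csv_stable(as.data.frame(results[[nm]]),
                     file.path(out, paste0("stats_", nm, ".csv")))
  invisible(results)
}

#' Run the whole pipeline
#'
#' `simulate`, then `fd`, then `colour`, then `stats`. With a fixed config
#' and seed the output tree is byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the list of stats tables.
#' @export
pipeline_all <- function(config) {
  cfg <- pipeline_config(config)
  pipeline_simulate(cfg)
  if (length(cfg$simulate$mycelium %||% list()) > 0L) pipeline_fd(cfg)
  if (length(cfg$simulate$drops %||% list()) > 0L) pipeline_colour(cfg)
  pipeline_stats(cfg)
}
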