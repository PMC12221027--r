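#' Pipeline configuration
#'
#' Bundles the analysis constants: snapshot windows, thresholds, the
#' moving-average window, aggregator and step pattern. Defaults follow
#' the study design: five 20-year snapshot windows across the
#' 400 BCE - 400 CE analysis span, a strict 20 % trim, a 70 % climate
#' similarity threshold and more than 5 dated samples for record
#' selection, and the Rabiner-Juang VI-c step pattern.
#'
#' @param snapshot_starts first astronomical years of the snapshot
#'   windows (ordered, non-overlapping).
#' @param window_length snapshot window length, years.
#' @param trim_threshold hybrid trim threshold in [0, 1].
#' @param similarity_threshold record-selection similarity threshold.
#' @param min_dates strict minimum dated samples within the window.
#' @param ma_window moving-average window for the annual series, years.
#' @param aggregator hybrid aggregator (`"mean"`, `"min"`,
#'   `"count-fraction"`).
#' @param pattern step-pattern name for the proxy validation.
#' @param precip_method delta-method precipitation mode (`"additive"` or
#'   `"ratio"`).
#' @param n_crops number of synthetic crops.
#' @param analysis_window `c(first, last)` years of the validation
#'   window (default: the five-snapshot study span).
#' @param site optional fine-grid `c(row, col)` reference site for the
#'   similarity map (default: domain centre).
#' @return validated list of class `ps_config`.
#' @export
pipeline_config <- function(snapshot_starts = c(-309L, -9L, 100L, 240L, 340L),
                            window_length = 20L,
                            trim_threshold = 0.20,
                            similarity_threshold = 0.70,
                            min_dates = 5L,
                            ma_window = 20L,
                            aggregator = "mean",
                            pattern = "rj6c",
                            precip_method = "additive",
                            n_crops = 6L,
                            analysis_window = c(-399L, 400L),
                            site = NULL) {
  snapshot_starts <- as.integer(snapshot_starts)
  if (is.unsorted(snapshot_starts, strictly = TRUE))
    stop("snapshot windows must be ordered")
  if (length(snapshot_starts) > 1L &&
        any(diff(snapshot_starts) < window_length))
    stop("snapshot windows must not overlap")
  for (th in c(trim_threshold, similarity_threshold))
    if (th < 0 || th > 1) stop("thresholds must lie in [0, 1]")
  structure(list(snapshot_starts = snapshot_starts,
                 window_length = as.integer(window_length),
                 trim_threshold = trim_threshold,
                 similarity_threshold = similarity_threshold,
                 min_dates = as.integer(min_dates),
                 ma_window = as.integer(ma_window),
                 aggregator = aggregator, pattern = pattern,
                 precip_method = precip_method,
                 n_crops = as.integer(n_crops),
                 analysis_window = as.integer(analysis_window),
                 site = site),
            class = "ps_config")
}

safe_label <- function(x) gsub("[^A-Za-z0-9.-]+", "_", x)

pipeline_stages <- c("simulate", "downscale", "similarity", "suitability",
                     "hybrid", "variability", "validate")

#' Run the full analysis pipeline on a synthetic world
#'
#' Executes, in order, any subset of: `simulate` (terrain, soil, climate
#' cube, reference climatology, proxies, crops), `downscale` (snapshot
#' means, delta downscaling, annual phase series), `similarity`,
#' `suitability` (per crop and snapshot), `hybrid` (trim + combine +
#' class shares and changes), `variability` (CV and binary-change maps)
#' and `validate` (proxy DTW comparison). Every product is written under
#' `out_dir`; stages not run in the same call re-load their inputs from
#' those files, so subcommands can be run in isolation. A JSON manifest
#' with MD5 digests of every output ties the run together; identical
#' seed and configuration reproduce identical digests.
#'
#' @param spec `ps_world_spec`.
#' @param config `ps_config`.
#' @param out_dir output directory (created if missing).
#' @param stages character subset of the stage names, in any order.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(spec, config = pipeline_config(),
                         out_dir, stages = pipeline_stages) {
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  outputs <- character(0)
  pth <- function(...) file.path(out_dir, paste0(...))
  emit <- function(path) outputs <<- c(outputs, path)
  labels <- vapply(config$snapshot_starts,
                   window_label, "", config$window_length)

  need <- function(what) {
    if (!is.null(st[[what]])) return(st[[what]])
    st[[what]] <- switch(
      what,
      terrain = { g <- read_grids_nc(pth("terrain.nc"))
        structure(c(g, list(geom = attr(g, "geom"))), class = "ps_terrain") },
      soil = { g <- read_grids_nc(pth("soil.nc"))
        structure(c(g, list(geom = attr(g, "geom"))), class = "ps_soil") },
      cube = read_cube_nc(pth("cube.nc")),
      reference = read_climatology_nc(pth("reference.nc")),
      crops = read_crops_yaml(pth("crops.yaml")),
      proxies = read_proxy_csv(pth("proxies.csv")),
      similarity = { g <- read_grids_nc(pth("similarity.nc"))
        structure(list(values = g$similarity, site = config$site,
                       geom = attr(g, "geom")), class = "ps_similarity") },
      snapshots = lapply(labels, function(lb)
        read_climatology_nc(pth("downscaled_", safe_label(lb), ".nc"))),
      suitability = lapply(labels, function(lb) {
        g <- read_grids_nc(pth("suitability_", safe_label(lb), ".nc"))
        lapply(names(g), function(nm)
          structure(list(values = g[[nm]],
                         classes = normalize_classify(g[[nm]]),
                         crop = nm, snapshot = lb, geom = attr(g, "geom")),
                    class = "ps_suitability"))
      }),
      hybrids = lapply(labels, function(lb) {
        g <- read_grids_nc(pth("hybrid_", safe_label(lb), ".nc"))
        structure(list(values = g$value,
                       classes = normalize_classify(g$value),
                       n_crops = g$n_crops, aggregator = config$aggregator,
                       threshold = config$trim_threshold, snapshot = lb,
                       geom = attr(g, "geom")), class = "ps_hybrid")
      }),
      stop("internal: unknown input ", what))
    st[[what]]
  }

  if ("simulate" %in% stages) {
    st$terrain <- generate_terrain(spec)
    st$soil <- generate_soil(spec, st$terrain)
    wc <- generate_climate(spec, st$terrain, config$snapshot_starts,
                           config$window_length)
    st$cube <- wc$cube; st$reference <- wc$reference; st$truth <- wc$truth
    st$crops <- generate_crops(config$n_crops, spec$seed)
    st$proxies <- generate_proxy(spec, st$cube)
    emit(write_grids_nc(st$terrain[c("elevation", "slope", "twi", "wind",
                                     "solar")],
                        st$terrain$geom, pth("terrain.nc")))
    emit(write_grids_nc(st$soil[c("sand", "silt", "clay", "ph")],
                        st$soil$geom, pth("soil.nc")))
    emit(write_cube_nc(st$cube, pth("cube.nc")))
    emit(write_climatology_nc(st$reference, pth("reference.nc")))
    for (lb in names(st$truth))
      emit(write_climatology_nc(st$truth[[lb]],
                                pth("truth_", safe_label(lb), ".nc")))
    emit(write_crops_yaml(st$crops, pth("crops.yaml")))
    emit(write_proxy_csv(st$proxies, pth("proxies.csv")))
  }

  if ("downscale" %in% stages) {
    cube <- need("cube"); reference <- need("reference")
    baseline_start <- cube$years[length(cube$years)] -
      config$window_length + 1L
    baseline <- snapshot_mean(cube, baseline_start, config$window_length,
                              label = "baseline")
    st$snapshots <- lapply(config$snapshot_starts, function(s) {
      snap <- snapshot_mean(cube, s, config$window_length)
      delta_downscale(snap, baseline, reference, config$precip_method)
    })
    for (k in seq_along(labels))
      emit(write_climatology_nc(st$snapshots[[k]],
                                pth("downscaled_", safe_label(labels[k]),
                                    ".nc")))
    ## annual regional series with 20-year moving average, z-scores, phases
    region <- cbind(row = rep(seq_len(cube$geom$nrow), cube$geom$ncol),
                    col = rep(seq_len(cube$geom$ncol), each = cube$geom$nrow))
    ann <- annual_aggregate(cube, region)
    aw <- config$analysis_window
    ann <- ann[ann$year >= aw[1] & ann$year <= aw[2], ]
    ann$temperature_smoothed <- moving_average(ann$temperature,
                                               config$ma_window)
    ann$precipitation_smoothed <- moving_average(ann$precipitation,
                                                 config$ma_window)
    ann$temperature_z <- zscore(ann$temperature_smoothed)
    ann$precipitation_z <- zscore(ann$precipitation_smoothed)
    ann$phase <- as.character(classify_phase(ann$temperature_z,
                                             ann$precipitation_z))
    data.table::fwrite(ann, pth("annual_phases.csv"))
    emit(pth("annual_phases.csv"))
  }

  if ("similarity" %in% stages) {
    reference <- need("reference")
    site <- config$site %||% c(reference$geom$nrow %/% 2L + 1L,
                               reference$geom$ncol %/% 2L + 1L)
    st$similarity <- similarity_index(reference, site)
    emit(write_grids_nc(list(similarity = st$similarity$values),
                        st$similarity$geom, pth("similarity.nc")))
  }

  if ("suitability" %in% stages) {
    crops <- need("crops"); snaps <- need("snapshots")
    statics <- static_grids(need("terrain"), need("soil"))
    st$suitability <- lapply(snaps, function(snap)
      lapply(crops, function(cr) crop_suitability(snap, statics, cr)))
    for (k in seq_along(labels)) {
      maps <- st$suitability[[k]]
      vals <- lapply(maps, function(m) m$values)
      names(vals) <- vapply(maps, function(m) m$crop, "")
      emit(write_grids_nc(vals, maps[[1]]$geom,
                          pth("suitability_", safe_label(labels[k]), ".nc")))
    }
  }

  if ("hybrid" %in% stages) {
    suits <- need("suitability")
    st$hybrids <- lapply(suits, function(maps)
      hybrid_combine(maps, config$aggregator, config$trim_threshold))
    shares <- list(); changes <- list()
    for (k in seq_along(labels)) {
      hy <- st$hybrids[[k]]
      emit(write_grids_nc(list(value = hy$values,
                               class = hy$classes * 1.0,
                               n_crops = hy$n_crops * 1.0),
                          hy$geom, pth("hybrid_", safe_label(labels[k]),
                                       ".nc")))
      per_crop <- lapply(suits[[k]], function(m)
        class_area_shares(m$classes))
      names(per_crop) <- vapply(suits[[k]], function(m) m$crop, "")
      per_crop$hybrid <- class_area_shares(hy$classes)
      shares[[labels[k]]] <- per_crop
    }
    share_df <- do.call(rbind, lapply(names(shares), function(lb)
      do.call(rbind, lapply(names(shares[[lb]]), function(cr)
        data.frame(snapshot = lb, crop = cr, class = suitability_classes(),
                   share = as.numeric(shares[[lb]][[cr]]))))))
    data.table::fwrite(share_df, pth("class_shares.csv"))
    emit(pth("class_shares.csv"))
    if (length(labels) > 1L) {
      chg <- do.call(rbind, lapply(2:length(labels), function(k)
        do.call(rbind, lapply(names(shares[[k]]), function(cr)
          data.frame(from = labels[k - 1], to = labels[k], crop = cr,
                     class = suitability_classes(),
                     change_pt = as.numeric(
                       class_change(shares[[k - 1]][[cr]],
                                    shares[[k]][[cr]])))))))
      data.table::fwrite(chg, pth("class_changes.csv"))
      emit(pth("class_changes.csv"))
    }
  }

  if ("variability" %in% stages) {
    hybrids <- need("hybrids"); snaps <- need("snapshots")
    hyvals <- lapply(hybrids, function(h) h$values)
    binaries <- lapply(hybrids, function(h)
      binarize_hybrid(h, config$trim_threshold))
    ann_t <- lapply(snaps, function(s) apply(s$temperature, c(1, 2), mean))
    ann_p <- lapply(snaps, function(s) apply(s$precipitation, c(1, 2), sum))
    emit(write_grids_nc(list(
      hybrid_cv = cv_across_snapshots(hyvals),
      change_count = binary_change_sum(binaries) * 1.0,
      temperature_cv = cv_across_snapshots(ann_t),
      precipitation_cv = cv_across_snapshots(ann_p)),
      hybrids[[1]]$geom, pth("variability.nc")))
  }

  if ("validate" %in% stages) {
    report <- compare_simulation_proxy(
      need("cube"), need("proxies"), need("similarity"),
      pattern = config$pattern, window = config$analysis_window,
      min_similarity = config$similarity_threshold,
      min_dates = config$min_dates)
    st$report <- report
    rj <- list(records_used = as.list(report$records_used),
               n_years = report$n_years,
               phase_agreement = report$phase_agreement)
    for (v in c("temperature", "precipitation"))
      rj[[v]] <- report[[v]][c("distance", "normalized_distance",
                               "rescaled_distance", "median_path_offset")]
    jsonlite::write_json(rj, pth("validation_report.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(pth("validation_report.json"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("paleosuit")),
    r_version = R.version.string,
    seed = spec$seed,
    spec = unclass(spec),
    config = unclass(config),
    stages = stages,
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = as.list(tools::md5sum(sort(unique(outputs)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
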