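#' Run the full analysis pipeline
#'
#' Executes the stages in order: Argos reading, speed/distance/angle
#' pre-filtering, CTCRW state-space fitting and 6-hourly path prediction,
#' movement-persistence estimation, persistence segmentation into
#' migration phases, current attachment and speed correction, calving
#' detection on the southbound leg, and the bioenergetic budget over the
#' migration window (departure from the first transit segment to the end
#' of the last one). When a depth grid is supplied, least-cost routes
#' between the mean feeding and breeding positions (direct and via the
#' stopover means) are computed as well.
#'
#' All intermediate artifacts are written to `out_dir` and listed, with
#' MD5 hashes, in `manifest.json`; a rerun with identical inputs and
#' configuration reproduces identical hashes.
#'
#' @param argos Path to an Argos CSV or an [argos_obs] data frame.
#' @param config A [run_config()].
#' @param currents Optional path to a grid CSV or a [gridded_field].
#' @param depth Optional path to a depth CSV or a [depth_grid].
#' @param out_dir Output directory (created if needed).
#' @param require_currents Fail (rather than fall back to a zero-current
#'   ocean) when no current field is supplied.
#' @return List with `track`, `phases`, `calving`, `budget`, `routes`
#'   (or NULL), `manifest`.
#' @export
run_pipeline <- function(argos, config = run_config(), currents = NULL,
                         depth = NULL, out_dir = tempfile("pipeline"),
                         require_currents = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    cat(jsonlite::toJSON(list(stage = name, status = "ok",
                              time = format(Sys.time(), tz = "UTC")),
                         auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
    res
  }
  obs <- stage("read_argos", function()
    if (is.character(argos)) read_argos(argos) else argos)
  filt <- stage("prefilter", function()
    sda_filter(obs, filter_settings(vmax = config$vmax)))
  write_track_csv <- function(d, f) {
    p <- file.path(out_dir, f)
    dd <- d
    dd$timestamp <- format(dd$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
    utils::write.csv(dd, p, row.names = FALSE, quote = FALSE, na = "")
    p
  }
  write_track_csv(filt$kept, "filtered.csv")
  fit <- stage("ssm_fit", function()
    fit_crw(filt$kept, center = config$projection_center))
  track <- stage("ssm_predict", function()
    predict_path(fit, config$interval_hours))
  mpm <- stage("persistence", function() estimate_persistence(track))
  track$gamma <- mpm$gamma
  seg <- stage("segmentation", function() detect_migration_phases(track))
  phases <- seg$phases
  track$segment <- rep(seq_len(nrow(phases)),
                       phases$end_index - phases$start_index + 1)
  field <- stage("read_currents", function() {
    if (is.null(currents)) {
      if (require_currents) stop("no current field supplied")
      NULL
    } else if (is.character(currents)) read_gridded_field(currents)
    else currents
  })
  track <- stage("currents", function()
    attach_currents(track, field, config$resting_threshold))
  transit <- which(phases$label == "transit")
  win <- NULL
  if (length(transit)) {
    win <- c(phases$start[transit[1]],
             phases$end[transit[length(transit)]])
  }
  calving <- stage("calving", function() {
    res <- phases[phases$label == "residence", , drop = FALSE]
    if (!length(transit) || !nrow(res)) return(NULL)
    breeding <- res[which.min(vapply(seq_len(nrow(res)), function(r)
      mean(track$lat[res$start_index[r]:res$end_index[r]]), numeric(1))), ]
    south <- track[phases$start_index[transit[1]]:breeding$start_index, ,
                   drop = FALSE]
    south <- south[south$segment %in% transit, , drop = FALSE]
    if (nrow(south) < 16) return(NULL)
    detect_calving(south)
  })
  bud <- stage("energetics", function()
    budget(track, window = win, params = config$energetics,
           resting_threshold = config$resting_threshold))
  routes <- stage("routes", function() {
    if (is.null(depth)) return(NULL)
    grid <- if (is.character(depth)) read_depth_grid(depth) else depth
    res <- phases[phases$label == "residence", , drop = FALSE]
    if (nrow(res) < 2) return(NULL)
    meanpos <- function(r) c(mean(track$lon[r$start_index:r$end_index]),
                             mean(track$lat[r$start_index:r$end_index]))
    feeding <- meanpos(res[1, ])
    ib <- which.min(vapply(seq_len(nrow(res)), function(r)
      meanpos(res[r, ])[2], numeric(1)))
    breeding <- meanpos(res[ib, ])
    direct <- least_cost_path(feeding, breeding, grid)
    via <- NULL
    # stopovers: residences visited between leaving the feeding ground and
    # reaching the breeding ground
    stopovers <- which(res$segment > res$segment[1] &
                         res$segment < res$segment[ib])
    if (length(stopovers)) {
      pts <- c(list(feeding), lapply(stopovers, function(r)
        meanpos(res[r, ])), list(breeding))
      legs <- lapply(seq_len(length(pts) - 1), function(k)
        least_cost_path(pts[[k]], pts[[k + 1]], grid))
      via <- list(length_km = sum(vapply(legs, `[[`, numeric(1),
                                         "length_km")),
                  vertices = do.call(rbind, lapply(legs, `[[`, "vertices")))
      class(via) <- "route_path"
    }
    list(direct = direct, via = via,
         comparison = route_comparison(track, direct, via))
  })
  write_track(track, file.path(out_dir, "track.csv"), "csv")
  write_track(track, file.path(out_dir, "track.geojson"), "geojson")
  pcsv <- phases
  pcsv$start <- format(pcsv$start, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  pcsv$end <- format(pcsv$end, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(pcsv, file.path(out_dir, "phases.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(calving = if (!is.null(calving))
      list(change_detected = calving$change_detected,
           breakpoint_time = format(calving$breakpoint_time,
                                    "%Y-%m-%d %H:%M:%S", tz = "UTC"),
           median_pre = calving$median_pre,
           median_post = calving$median_post,
           speed_source = calving$speed_source),
      budget = as.data.frame(bud)),
    file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  utils::write.csv(as.data.frame(bud), file.path(out_dir, "budget.csv"),
                   row.names = FALSE)
  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(
    list(interval_hours = config$interval_hours, vmax = config$vmax,
         resting_threshold = config$resting_threshold,
         projection_center = config$projection_center,
         seed = config$seed,
         energetics = unclass(config$energetics)),
    cfg_json, auto_unbox = TRUE, digits = NA)
  files <- c("filtered.csv", "track.csv", "track.geojson", "phases.csv",
             "results.json", "budget.csv", "config.json")
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_json)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cetatrack")),
    files = lapply(files, function(f)
      list(name = f,
           md5 = unname(tools::md5sum(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(track = track, fit = fit, phases = phases, calving = calving,
       budget = bud, routes = routes, manifest = manifest,
       filter_report = filt$report, out_dir = out_dir)
}

#' Read a relocation-series CSV (reconstructed-path summaries)
#'
#' Reads the per-relocation series distributed as supplementary data with
#' single-whale tracking studies: date-time, current-corrected swim speed
#' (m/s), movement persistence, and distance between consecutive
#' relocations. Column names are matched case-insensitively on the
#' prefixes `date`/`time`, `speed`, `persist`/`gamma`/`g`, `dist`.
#'
#' @param path CSV path.
#' @return Data frame: `timestamp`, `speed`, `gamma`, `distance_m`.
#' @export
read_relocations <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = ",",
                         stringsAsFactors = FALSE)
  nm <- .squash(names(d))
  pick <- function(pats) {
    for (p in pats) { hit <- grep(p, nm); if (length(hit)) return(hit[1]) }
    NA_integer_
  }
  it <- pick(c("^datetime", "^date", "^time"))
  is <- pick(c("speed"))
  ig <- pick(c("persist", "gamma", "^g$"))
  id <- pick(c("dist"))
  if (is.na(it) || is.na(is))
    stop("need date-time and speed columns in relocation series")
  out <- data.frame(timestamp = .parse_utc(d[[it]]),
                    speed = as.numeric(d[[is]]),
                    gamma = if (!is.na(ig)) as.numeric(d[[ig]]) else NA_real_,
                    distance_m = if (!is.na(id)) as.numeric(d[[id]])
                                 else NA_real_)
  out[order(out$timestamp), , drop = FALSE]
}

#' Energetic replay of a relocation series
#'
#' Recomputes the bioenergetic budget directly from a relocation series
#' ([read_relocations()]): per-step cost of transport from the cubic drag
#' law at each recorded swim speed held over the step duration, per-step
#' maintenance accrual, cumulative distance (recorded distances when
#' present, otherwise speed x duration), and the median transiting speed.
#'
#' @param reloc Data frame from [read_relocations()].
#' @param window Optional POSIXct length-2 window (start, end].
#' @param params A [bioenergetic_params()] object.
#' @param resting_threshold m/s, default 0.5.
#' @return List: `days`, `e_cot_mj`, `maintenance_mj`, `e_total_mj`,
#'   `distance_km`, `median_speed`, `median_speed_transiting`.
#' @export
replay_budget <- function(reloc, window = NULL,
                          params = bioenergetic_params(),
                          resting_threshold = 0.5) {
  if (is.null(window)) window <- range(reloc$timestamp)
  r <- reloc[reloc$timestamp >= window[1] & reloc$timestamp < window[2], ,
             drop = FALSE]
  if (nrow(r) < 2) stop("window not covered by relocation series")
  dt <- c(diff(as.numeric(r$timestamp)), NA)
  dt[is.na(dt)] <- median(dt, na.rm = TRUE)
  ok <- !is.na(r$speed)
  e_cot <- sum(cot_power(r$speed[ok], params) * dt[ok]) / 1e6
  days <- sum(dt) / 86400
  maint <- bmr_daily(params) * days
  dist_km <- if (!all(is.na(r$distance_m)))
    sum(r$distance_m, na.rm = TRUE) / 1000
  else sum(r$speed[ok] * dt[ok]) / 1000
  transiting <- r$speed[ok][r$speed[ok] > resting_threshold]
  list(days = days, e_cot_mj = e_cot, maintenance_mj = maint,
       e_total_mj = e_cot + maint, distance_km = dist_km,
       median_speed = median(r$speed, na.rm = TRUE),
       median_speed_transiting = median(transiting))
}
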