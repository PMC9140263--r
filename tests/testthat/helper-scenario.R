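# One full paper-scale end-to-end run, computed once per test session and
# shared by the tests that need it (the CTCRW fit dominates the cost).
.e2e_env <- new.env(parent = emptyenv())

e2e_run <- function(seed = 42L) {
  key <- paste0("s", seed)
  if (!is.null(.e2e_env[[key]])) return(.e2e_env[[key]])
  spec <- paper_like_scenario(seed = seed)
  tr <- simulate_truth(spec)
  obs <- observe_argos(tr, spec)
  filt <- sda_filter(obs)
  fit <- fit_crw(filt$kept, center = spec$projection_center)
  path <- predict_path(fit, 6)
  mpm <- estimate_persistence(path)
  path$gamma <- mpm$gamma
  path <- attach_currents(path, NULL)
  seg <- detect_migration_phases(path)
  ph <- seg$phases
  path$segment <- rep(seq_len(nrow(ph)), ph$end_index - ph$start_index + 1)
  tri <- which(ph$label == "transit")
  res <- ph[ph$label == "residence", , drop = FALSE]
  ib <- which.min(vapply(seq_len(nrow(res)), function(r)
    mean(path$lat[res$start_index[r]:res$end_index[r]]), numeric(1)))
  south <- path[ph$start_index[tri[1]]:res$start_index[ib], , drop = FALSE]
  south <- south[south$segment %in% tri, , drop = FALSE]
  calving <- detect_calving(south)
  win <- c(ph$start[tri[1]], ph$end[tri[length(tri)]])
  bud <- budget(path, win)
  inw <- tr$timestamp >= win[1] & tr$timestamp < win[2]
  vtrue <- tr$speed_true[inw]
  ecot_true <- sum(cot_power(vtrue[!is.na(vtrue)]) * 21600) / 1e6
  # step-row offset between the prediction grid (starts at first fix) and
  # the truth grid (starts at deployment)
  off <- as.numeric(difftime(path$timestamp[1], tr$timestamp[1],
                             units = "hours")) / 6
  true_bp <- cumsum(c(120, 28, 60, 244, 64, 284)) - off
  true_calving_time <- tr$timestamp[120 + 28 + 60 + 96]
  out <- list(spec = spec, truth = tr, obs = obs, filt = filt, fit = fit,
              path = path, mpm = mpm, seg = seg, calving = calving,
              window = win, budget = bud, ecot_true = ecot_true,
              true_bp = true_bp, true_calving_time = true_calving_time)
  .e2e_env[[key]] <- out
  out
}
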