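# End-to-end orchestration with a validated flat configuration.

#' Default pipeline configuration
#'
#' All analysis thresholds with their standard defaults: 80 ms decoding
#' windows on a 5 ms stride, validity gates m < 10 cm / delta < 20 cm /
#' speed < 5 cm/s, acceptance gates duration > 100 ms and dispersion >
#' 12 cm, ripple events at 2 SD / 15 ms with 50 ms merging, bursts at 3 SD /
#' 50 ms without merging, 2 cm bins, 8 cm field smoothing, 10 cm barrier
#' kernel, and 100-shuffle nulls. `synthetic` holds the generator
#' parameters.
#'
#' @return named list
#' @export
default_config <- function() {
  list(
    tau = 0.08, stride = 0.005,
    speed_max = 5, m_max = 10, delta_max = 20,
    min_duration = 0.1, min_dispersion = 12,
    run_threshold = 10,
    ripple_threshold_z = 2, ripple_min_dur = 0.015, ripple_merge_gap = 0.05,
    burst_threshold_z = 3, burst_min_dur = 0.05,
    bin_cm = 2, map_sd_cm = 8, barrier_sd_cm = 10,
    n_shuffle = 100, n_snippets = 100, n_field_null = 100,
    alpha = 0.05,
    synthetic = synthetic_config()
  )
}

check_config <- function(config) {
  ref <- default_config()
  extra <- setdiff(names(config), names(ref))
  if (length(extra)) stop("unknown config keys: ",
                          paste(extra, collapse = ", "))
  out <- utils::modifyList(ref, config)
  extra2 <- setdiff(names(out$synthetic), names(synthetic_config()))
  if (length(extra2)) stop("unknown synthetic config keys: ",
                           paste(extra2, collapse = ", "))
  out
}

#' Run the full pipeline on a synthetic (or provided) session
#'
#' simulate -> behavioral segmentation -> rate maps & place cells ->
#' decoding of stopping periods -> replay detection -> ripple/burst event
#' detection and replay labeling -> ripple field with circular-shuffle
#' nulls. Deterministic given (config, seed).
#'
#' @param config configuration list (defaults filled in from
#'   [default_config()]; unknown keys rejected)
#' @param seed session seed
#' @param bundle optional existing session bundle (skips simulation)
#' @param out_dir optional output directory for CSV summaries
#' @return list with the session bundle, place-cell table, replay table,
#'   event tables, per-replay labels, ripple field, field statistics and
#'   null p-values
#' @export
run_all <- function(config = list(), seed = 1, bundle = NULL,
                    out_dir = NULL) {
  config <- check_config(config)
  if (is.null(bundle)) bundle <- make_session(seed, config$synthetic)
  pos <- bundle$positions
  env <- bundle$env
  stopping <- detect_stopping(pos, config$speed_max)
  t_range <- c(pos$t[1], pos$t[nrow(pos)])

  maps <- lapply(bundle$spikes, compute_rate_map, pos = pos, env = env,
                 run_threshold = config$run_threshold,
                 sd_cm = config$map_sd_cm)
  occ_p <- occupancy_prob(maps[[1]])
  cell_stats <- data.frame(
    cell = names(maps),
    mean_rate = vapply(maps, function(m)
      sum(m$smoothed[m$valid] * occ_p[m$valid]), numeric(1)),
    si = vapply(maps, function(m)
      tryCatch(spatial_information(m$smoothed, occ_p),
               error = function(e) 0), numeric(1)))
  cell_stats$place_cell <- classify_place_cells(cell_stats$mean_rate,
                                                cell_stats$si)
  pc <- cell_stats$cell[cell_stats$place_cell]
  decoder <- build_decoder(maps, pc, env)
  post <- decode_session(bundle$spikes, decoder, t_range,
                         intervals = stopping,
                         tau = config$tau, stride = config$stride)
  replays <- detect_replays(post, pos, decoder,
                            min_duration = config$min_duration,
                            min_dispersion = config$min_dispersion,
                            n_shuffle = config$n_shuffle,
                            alpha = config$alpha, seed = seed)
  paths <- attr(replays, "paths")
  accepted <- replays[replays$accepted, , drop = FALSE]

  rip_mean <- ripple_power(bundle$lfp, bundle$fs_lfp, stopping)
  rip_tet <- ripple_power(bundle$lfp, bundle$fs_lfp, stopping,
                          average = FALSE)
  sdens <- spike_density(bundle$spikes, t_range, stopping)
  ripple_events <- detect_events(rip_mean, config$ripple_threshold_z,
                                 config$ripple_min_dur,
                                 config$ripple_merge_gap)
  tet_events <- lapply(rip_tet, detect_events,
                       threshold_z = config$ripple_threshold_z,
                       min_duration = config$ripple_min_dur,
                       merge_gap = config$ripple_merge_gap)
  burst_events <- detect_events(sdens, config$burst_threshold_z,
                                config$burst_min_dur, merge_gap = NULL)
  labels <- NULL
  if (nrow(accepted)) {
    labels <- do.call(rbind, lapply(seq_len(nrow(accepted)), function(i) {
      lb <- label_replay(accepted[i, ], ripple_events, burst_events,
                         rip_mean, sdens, stopping, accepted,
                         n_snippets = config$n_snippets,
                         seed = seed + i)
      data.frame(replay = i, has_ripple = lb$has_ripple,
                 has_burst = lb$has_burst, class = lb$class,
                 n_tetrodes = count_detecting_tetrodes(accepted[i, ],
                                                       tet_events))
    }))
  }
  field <- NULL; field_si <- NA_real_; si_null <- NULL; stab <- NA_real_
  if (length(paths) >= 2) {
    field <- compute_event_field(paths, rip_mean, env,
                                 sd_cm = config$map_sd_cm)
    field_si <- event_field_si(field)
    si_null <- field_null(paths, rip_mean, env, "si",
                          n = config$n_field_null,
                          seed = substream(seed, "shuffle"))
    stab <- split_half_stability(paths, env = env, series = rip_mean)
  }
  res <- list(bundle = bundle, stopping = stopping,
              cell_stats = cell_stats, decoder_cells = pc,
              replays = replays, paths = paths, labels = labels,
              ripple_events = ripple_events, burst_events = burst_events,
              tetrode_events = tet_events,
              ripple_field = field, ripple_field_si = field_si,
              ripple_field_si_p = if (is.null(si_null)) NA_real_ else si_null$p,
              split_half = stab, config = config, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(replays, file.path(out_dir, "replays.csv"),
                     row.names = FALSE)
    if (!is.null(labels))
      utils::write.csv(labels, file.path(out_dir, "replay_labels.csv"),
                       row.names = FALSE)
    utils::write.csv(cell_stats, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(ripple_events, file.path(out_dir, "ripple_events.csv"),
                     row.names = FALSE)
    utils::write.csv(burst_events, file.path(out_dir, "burst_events.csv"),
                     row.names = FALSE)
    summ <- data.frame(n_place_cells = length(pc),
                       n_replays = nrow(accepted),
                       ripple_field_si = field_si,
                       ripple_field_si_p = res$ripple_field_si_p,
                       split_half = stab)
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(config[setdiff(names(config), "synthetic")],
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
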