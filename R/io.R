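# Plain-text session bundle: a directory of delimited-text tables plus JSON
# headers. Layout:
#   header.json      arena/bins/barriers/wells, sample rates, seed
#   positions.csv    t, x, y, speed, speed2
#   spikes.csv       cell, t (one row per spike)
#   cells.csv        cell, tetrode
#   lfp.csv          one column per tetrode, rows at fs_lfp
#   ground_truth.json  (optional) fields, replays with paths, zones

#' Write a session bundle to a directory of text files
#'
#' @param bundle a session bundle from [make_session()]
#' @param dir output directory (created if missing)
#' @param include_lfp write the (large) LFP table (default TRUE)
#' @return `dir`, invisibly
#' @export
write_session_bundle <- function(bundle, dir, include_lfp = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  env <- bundle$env
  header <- list(arena_cm = env$arena_cm, bin_cm = env$bin_cm,
                 barrier_slots = env$barriers$slot,
                 home_well_index = env$home_well_index,
                 fs_pos = attr(bundle$positions, "fs"),
                 fs_lfp = bundle$fs_lfp,
                 duration_s = bundle$duration_s, seed = bundle$seed)
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(bundle$positions),
                   file.path(dir, "positions.csv"), row.names = FALSE)
  sp <- data.frame(
    cell = rep(names(bundle$spikes), lengths(bundle$spikes)),
    t = unlist(bundle$spikes, use.names = FALSE))
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(bundle$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  if (include_lfp && !is.null(bundle$lfp)) {
    lf <- as.data.frame(bundle$lfp)
    names(lf) <- paste0("t", seq_len(ncol(lf)))
    utils::write.csv(lf, file.path(dir, "lfp.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$ground_truth)) {
    gt <- bundle$ground_truth
    jsonlite::write_json(
      list(true_replays = gt$true_replays,
           ripple_zones = gt$ripple_zones,
           ripple_times = gt$ripple_times,
           design_fraction_rippleless = gt$design_fraction_rippleless,
           cell_fields = gt$cell_fields,
           replay_paths = lapply(gt$replay_paths, function(p)
             p[, c("t", "x", "y")])),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param dir bundle directory
#' @return a session bundle list
#' @export
read_session_bundle <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "header.json"),
                                simplifyVector = TRUE)
  env <- make_environment(arena_cm = header$arena_cm,
                          bin_cm = header$bin_cm,
                          barrier_slot_ids = header$barrier_slots,
                          home_well_index = header$home_well_index)
  posdf <- utils::read.csv(file.path(dir, "positions.csv"))
  pos <- position_series(posdf$t, posdf$x, posdf$y, posdf$speed,
                         posdf$speed2, fs = header$fs_pos)
  sp <- utils::read.csv(file.path(dir, "spikes.csv"),
                        stringsAsFactors = FALSE)
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  spikes <- stats::setNames(
    lapply(cells$cell, function(cn) sort(sp$t[sp$cell == cn])), cells$cell)
  lfp <- NULL
  if (file.exists(file.path(dir, "lfp.csv")))
    lfp <- as.matrix(utils::read.csv(file.path(dir, "lfp.csv")))
  gt <- NULL
  if (file.exists(file.path(dir, "ground_truth.json"))) {
    gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                              simplifyVector = TRUE)
    gt$replay_paths <- lapply(gt$replay_paths, as.data.frame)
  }
  list(positions = pos, spikes = spikes, cells = cells, lfp = lfp,
       fs_lfp = header$fs_lfp, env = env, ground_truth = gt,
       duration_s = header$duration_s, seed = header$seed)
}
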