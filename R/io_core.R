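#' Session data model and on-disk round trip
#'
#' A session bundle collects everything downstream analyses consume: tracked
#' head pose, sorted spike trains, LFP channels, maze geometry, and metadata.
#' All time axes share one clock with t = 0 at session start.
#'
#' @name io_core
NULL

#' Construct a pose series
#'
#' @param t sample times [s], strictly increasing, uniform rate.
#' @param pos n x 3 position matrix [cm].
#' @param quat n x 4 quaternion matrix, scalar-first (w, x, y, z). Norms
#'   deviating from 1 by more than 1e-3 are renormalized; by more than 1e-2
#'   raise an error.
#' @param valid logical mask of valid (non-occluded) samples.
#' @return object of class `pose_series`.
#' @export
pose_series <- function(t, pos, quat, valid = NULL) {
  pos <- as.matrix(pos); quat <- as.matrix(quat)
  stopifnot(length(t) == nrow(pos), nrow(pos) == nrow(quat), ncol(pos) == 3,
            ncol(quat) == 4)
  if (any(diff(t) <= 0)) stop("clock error: time axis not strictly increasing")
  if (is.null(valid)) valid <- rep(TRUE, length(t))
  nv <- quat_norm(quat[valid, , drop = FALSE])
  if (any(abs(nv - 1) > 1e-2)) stop("invalid quaternion: norm deviates > 1e-2")
  if (any(abs(nv - 1) > 1e-3))
    quat[valid, ] <- quat_normalize(quat[valid, , drop = FALSE])
  fs <- 1 / stats::median(diff(t))
  structure(list(t = as.numeric(t), pos = unname(pos), quat = unname(quat),
                 valid = as.logical(valid), fs = fs),
            class = "pose_series")
}

#' Construct a unit profile
#' @param unit_id identifier.
#' @param times sorted spike times [s].
#' @param channel recording channel (optional).
#' @export
unit_profile <- function(unit_id, times, channel = NA_integer_) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = FALSE)) times <- sort(times)
  structure(list(unit_id = unit_id, times = times, channel = channel,
                 n = length(times), mean_rate = NA_real_,
                 burst_index = NA_real_, putative_type = "unclassified"),
            class = "unit_profile")
}

#' Construct an LFP series
#' @param samples signal [uV].
#' @param fs sampling rate [Hz].
#' @param channel_id channel label.
#' @param t0 time of the first sample [s].
#' @param artifact_mask logical, TRUE where the sample is rejected.
#' @export
lfp_series <- function(samples, fs, channel_id = "lfp1", t0 = 0,
                       artifact_mask = NULL) {
  structure(list(samples = as.numeric(samples), fs = fs,
                 channel_id = channel_id, t0 = t0,
                 artifact_mask = artifact_mask %||% rep(FALSE, length(samples))),
            class = "lfp_series")
}

#' Assemble and validate a session bundle
#'
#' @param session_id identifier string.
#' @param tracking a `pose_series`.
#' @param units list of `unit_profile`s.
#' @param lfp list of `lfp_series` (may be empty).
#' @param maze a `maze_model`.
#' @param meta named list of metadata.
#' @return object of class `session_bundle`.
#' @export
session_bundle <- function(session_id, tracking, units = list(), lfp = list(),
                           maze = maze_model(), meta = list()) {
  stopifnot(inherits(tracking, "pose_series"), inherits(maze, "maze_model"))
  dur <- max(tracking$t) + 1 / tracking$fs
  for (u in units) {
    if (length(u$times) && (min(u$times) < 0 || max(u$times) > dur))
      stop("spike times outside [0, session_duration] for unit ", u$unit_id)
  }
  structure(list(session_id = session_id, tracking = tracking, units = units,
                 lfp = lfp, maze = maze, duration = dur, meta = meta),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle '%s': %.1f s, %d units, %d LFP channel(s), %d place bins>\n",
              x$session_id, x$duration, length(x$units), length(x$lfp),
              n_place_bins(x$maze)))
  invisible(x)
}

#' Write a session bundle to a directory
#'
#' Layout: `tracking.csv` (t,x,y,z,qw,qx,qy,qz), `spikes.csv` (unit_id,t),
#' `units.csv`, one float32 stream + JSON sidecar per LFP channel,
#' `maze.json`, `meta.json`, and a `manifest.json` with MD5 checksums.
#' Identical inputs give bit-identical files.
#'
#' @param bundle a `session_bundle`.
#' @param path output directory (created if absent).
#' @return the manifest (invisibly): data frame of file names and checksums.
#' @export
write_session <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tr <- bundle$tracking
  trk <- data.frame(t = tr$t, x = tr$pos[, 1], y = tr$pos[, 2], z = tr$pos[, 3],
                    qw = tr$quat[, 1], qx = tr$quat[, 2], qy = tr$quat[, 3],
                    qz = tr$quat[, 4])
  trk[!tr$valid, -1] <- NA
  utils::write.csv(format(trk, digits = 15, trim = TRUE, scientific = FALSE),
                   file.path(path, "tracking.csv"), row.names = FALSE, quote = FALSE)
  sp <- do.call(rbind, lapply(bundle$units, function(u)
    if (length(u$times)) data.frame(unit_id = u$unit_id, t = u$times) else NULL))
  if (is.null(sp)) sp <- data.frame(unit_id = character(), t = numeric())
  utils::write.csv(format(sp, digits = 15, trim = TRUE, scientific = FALSE),
                   file.path(path, "spikes.csv"), row.names = FALSE, quote = FALSE)
  um <- data.frame(unit_id = vapply(bundle$units, `[[`, "", "unit_id"),
                   channel = vapply(bundle$units, function(u) as.integer(u$channel %||% NA), 1L),
                   n_spikes = vapply(bundle$units, `[[`, 1L, "n"))
  utils::write.csv(um, file.path(path, "units.csv"), row.names = FALSE, quote = FALSE)
  for (ch in bundle$lfp) {
    con <- file(file.path(path, paste0("lfp_", ch$channel_id, ".f32")), "wb")
    writeBin(as.numeric(ch$samples), con, size = 4, endian = "little")
    close(con)
    jsonlite::write_json(list(fs_hz = ch$fs, channel_id = ch$channel_id, t0 = ch$t0),
                         file.path(path, paste0("lfp_", ch$channel_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  mz <- bundle$maze
  jsonlite::write_json(list(extent = mz$extent, n_floors = mz$n_floors,
                            floor_heights = mz$floor_heights,
                            reward_ports = mz$reward_ports,
                            place_grid = mz$place_grid,
                            view_bin_cm = mz$view_bin_cm),
                       file.path(path, "maze.json"), digits = NA)
  jsonlite::write_json(c(list(session_id = bundle$session_id), bundle$meta),
                       file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  files <- sort(setdiff(list.files(path), "manifest.json"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(path, files))))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"))
  invisible(manifest)
}

#' Load a session bundle from a directory
#'
#' Counterpart of [write_session()]; validates quaternions and clock
#' monotonicity on the way in.
#'
#' @param path session directory.
#' @return a `session_bundle`.
#' @export
load_session <- function(path) {
  need <- c("tracking.csv", "spikes.csv", "units.csv", "maze.json", "meta.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("incomplete session: missing ", paste(missing, collapse = ", "))
  trk <- utils::read.csv(file.path(path, "tracking.csv"))
  valid <- stats::complete.cases(trk[, -1])
  q <- as.matrix(trk[, c("qw", "qx", "qy", "qz")])
  if (any(!valid))
    q[!valid, ] <- matrix(rep(c(1, 0, 0, 0), sum(!valid)), ncol = 4, byrow = TRUE)
  p <- as.matrix(trk[, c("x", "y", "z")]); p[!valid, ] <- 0
  tracking <- pose_series(trk$t, p, q, valid)
  sp <- utils::read.csv(file.path(path, "spikes.csv"),
                        colClasses = c("character", "numeric"))
  um <- utils::read.csv(file.path(path, "units.csv"), colClasses = c("character", "integer", "integer"))
  units <- lapply(seq_len(nrow(um)), function(i)
    unit_profile(um$unit_id[i], sp$t[sp$unit_id == um$unit_id[i]], um$channel[i]))
  lfp_json <- list.files(path, pattern = "^lfp_.*\\.json$", full.names = TRUE)
  lfp <- lapply(lfp_json, function(jf) {
    side <- jsonlite::read_json(jf, simplifyVector = TRUE)
    bf <- sub("\\.json$", ".f32", jf)
    n <- file.size(bf) / 4
    con <- file(bf, "rb")
    x <- readBin(con, numeric(), n = n, size = 4, endian = "little")
    close(con)
    lfp_series(x, side$fs_hz, side$channel_id, side$t0)
  })
  mj <- jsonlite::read_json(file.path(path, "maze.json"), simplifyVector = TRUE)
  maze <- maze_model(extent = mj$extent, n_floors = mj$n_floors,
                     floor_heights = mj$floor_heights,
                     reward_ports = matrix(unlist(mj$reward_ports),
                                           ncol = 3,
                                           byrow = !is.matrix(mj$reward_ports)),
                     place_grid = mj$place_grid, view_bin_cm = mj$view_bin_cm)
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  session_bundle(meta$session_id, tracking, units, lfp, maze,
                 meta[setdiff(names(meta), "session_id")])
}
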