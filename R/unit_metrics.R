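#' Unit quality control, burst index, and putative cell typing
#'
#' The burst index compares the measured inter-spike-interval (ISI)
#' distribution in the 2-40 ms range against the ISI density of a Poisson
#' process with the unit's whole-session mean rate; both are normalized to
#' unit mass over 2-40 ms, then summed over 2-20 ms:
#' BI = (sum_meas - sum_pred) / (sum_meas + sum_pred), bounded in [-1, 1].
#' Putative pyramidal vs interneuron labels come from 2-means clustering on
#' standardized (BI, mean rate); the higher-rate cluster is the interneuron
#' one (fast-spiking).
#'
#' @name unit_metrics
NULL

#' Quality-control a set of units
#'
#' Drops units with fewer than `min_spikes` spikes, then resolves duplicate
#' pairs: if two units share more than `overlap_frac` of spike times at 1 ms
#' resolution (fraction of the smaller train), only the higher-count unit is
#' kept (stand-in for signal-to-noise when waveforms are absent).
#'
#' @param units list of `unit_profile`s.
#' @param session_duration session length [s].
#' @param min_spikes spike-count floor (default 100).
#' @param overlap_frac duplicate threshold (default 0.5).
#' @return list with `kept` (unit list) and `rejected` (data frame
#'   `unit_id`, `reason`).
#' @export
qc_units <- function(units, session_duration, min_spikes = 100,
                     overlap_frac = 0.5) {
  rejected <- data.frame(unit_id = character(), reason = character())
  n <- vapply(units, `[[`, 1L, "n")
  low <- n < min_spikes
  for (u in units[low])
    rejected <- rbind(rejected, data.frame(unit_id = u$unit_id, reason = "too_few_spikes"))
  units <- units[!low]
  if (length(units) >= 2) {
    bins <- lapply(units, function(u) unique(floor(u$times * 1000)))
    drop <- rep(FALSE, length(units))
    for (i in seq_along(units)[-1]) {
      for (j in seq_len(i - 1L)) {
        if (drop[j]) next
        shared <- length(intersect(bins[[i]], bins[[j]]))
        if (shared / min(length(bins[[i]]), length(bins[[j]])) > overlap_frac) {
          victim <- if (units[[i]]$n >= units[[j]]$n) j else i
          drop[victim] <- TRUE
        }
      }
    }
    for (u in units[drop])
      rejected <- rbind(rejected, data.frame(unit_id = u$unit_id, reason = "duplicate"))
    units <- units[!drop]
  }
  list(kept = units, rejected = rejected)
}

#' Burst index of a spike train
#'
#' @param train a `unit_profile` (or list with `times`).
#' @param duration session duration [s] for the mean rate.
#' @param range_ms ISI histogram range (default 2-40 ms, 1 ms bins).
#' @param sum_ms summation range for the index (default 2-20 ms).
#' @param predicted "integrated" (bin-integrated exponential mass, default)
#'   or "center" (density evaluated at bin centers).
#' @return the input profile with `mean_rate`, `burst_index`,
#'   `isi_measured`, `isi_predicted` filled in; `burst_index` is NA (with a
#'   flag) when no ISI falls in the range.
#' @export
burst_index <- function(train, duration, range_ms = c(2, 40),
                        sum_ms = c(2, 20), predicted = "integrated") {
  times <- train$times
  if (length(times) < 2) stop("need at least 2 spikes")
  lambda <- length(times) / duration
  edges_ms <- seq(range_ms[1], range_ms[2], by = 1)
  isi_ms <- diff(times) * 1000
  meas <- as.numeric(table(cut(isi_ms, edges_ms, right = FALSE)))
  edges_s <- edges_ms / 1000
  pred <- if (predicted == "integrated") {
    exp(-lambda * edges_s[-length(edges_s)]) - exp(-lambda * edges_s[-1])
  } else {
    centers <- (edges_s[-1] + edges_s[-length(edges_s)]) / 2
    lambda * exp(-lambda * centers)
  }
  if (sum(meas) == 0) {
    train$mean_rate <- lambda
    train$burst_index <- NA_real_
    train$bi_flag <- "no_isis_in_range"
    return(train)
  }
  meas <- meas / sum(meas)
  pred <- pred / sum(pred)
  burst_bins <- edges_ms[-length(edges_ms)] < sum_ms[2] &
    edges_ms[-length(edges_ms)] >= sum_ms[1]
  sm <- sum(meas[burst_bins]); sp <- sum(pred[burst_bins])
  train$mean_rate <- lambda
  train$isi_measured <- meas
  train$isi_predicted <- pred
  train$burst_index <- (sm - sp) / (sm + sp)
  train
}

#' Classify putative pyramidal cells and interneurons
#'
#' 2-means on per-feature standardized (burst index, mean rate), multi-start
#' and seeded; the cluster with the higher mean firing rate is labeled
#' "interneuron", the other "pyramidal". Degenerate feature sets (zero
#' variance / empty cluster) leave all units "unclassified" with a warning.
#'
#' @param profiles list of `unit_profile`s with `burst_index` and
#'   `mean_rate` computed.
#' @param seed RNG seed for the k-means restarts.
#' @return list with `profiles` (labels filled in) and `summary` (data frame
#'   of cluster means and sizes).
#' @export
classify_cell_types <- function(profiles, seed = 1) {
  ok <- vapply(profiles, function(p) is.finite(p$burst_index) && is.finite(p$mean_rate),
               logical(1))
  if (sum(ok) < 2) stop("need at least 2 units with defined burst index")
  feats <- cbind(bi = vapply(profiles[ok], `[[`, 1, "burst_index"),
                 rate = vapply(profiles[ok], `[[`, 1, "mean_rate"))
  sds <- apply(feats, 2, stats::sd)
  if (any(sds == 0)) {
    warning("degenerate clustering: zero-variance feature")
    for (i in seq_along(profiles)) profiles[[i]]$putative_type <- "unclassified"
    return(list(profiles = profiles, summary = NULL))
  }
  z <- scale(feats)
  km <- local_seed(seed, stats::kmeans(z, centers = 2, nstart = 25))
  if (any(km$size == 0)) {
    warning("degenerate clustering: empty cluster")
    for (i in seq_along(profiles)) profiles[[i]]$putative_type <- "unclassified"
    return(list(profiles = profiles, summary = NULL))
  }
  rate_by_cluster <- tapply(feats[, "rate"], km$cluster, mean)
  int_cluster <- as.integer(names(which.max(rate_by_cluster)))
  labels <- ifelse(km$cluster == int_cluster, "interneuron", "pyramidal")
  j <- 1L
  for (i in seq_along(profiles)) {
    if (ok[i]) { profiles[[i]]$putative_type <- labels[j]; j <- j + 1L }
    else profiles[[i]]$putative_type <- "unclassified"
  }
  summary <- data.frame(cluster = c("pyramidal", "interneuron"),
                        mean_rate = c(rate_by_cluster[-int_cluster][1], rate_by_cluster[as.character(int_cluster)]),
                        mean_bi = c(tapply(feats[, "bi"], km$cluster, mean)[-int_cluster][1],
                                    tapply(feats[, "bi"], km$cluster, mean)[as.character(int_cluster)]),
                        n = c(km$size[-int_cluster][1], km$size[int_cluster]))
  list(profiles = profiles, summary = summary)
}

#' Summarize units as a table
#' @param profiles list of `unit_profile`s.
#' @return data frame `unit_id,n_spikes,mean_rate_hz,burst_index,putative_type`.
#' @export
unit_table <- function(profiles) {
  data.frame(unit_id = vapply(profiles, `[[`, "", "unit_id"),
             n_spikes = vapply(profiles, `[[`, 1L, "n"),
             mean_rate_hz = vapply(profiles, `[[`, 1, "mean_rate"),
             burst_index = vapply(profiles, `[[`, 1, "burst_index"),
             putative_type = vapply(profiles, `[[`, "", "putative_type"))
}
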