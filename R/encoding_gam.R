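#' Mixed-selectivity encoding with Poisson GAMs
#'
#' Single-unit spike counts in tracking-locked frames are modeled as
#' y ~ Poisson(exp(beta0 + sum_r f_r(x_r))) with penalized-spline smooths
#' f_r (mgcv P-splines; cyclic splines for circular angles). Goodness of fit
#' is the explained deviance ED = 1 - D_fitted / D_null, with the deviances
#' computed from the saturated, fitted and mean-rate log-likelihoods.
#' Variables enter by nested forward selection gated on circular-shift
#' shuffle nulls.
#'
#' Variable groups: pyramidal-type models draw from \{place, view, hd\},
#' interneuron-type models from \{ahv, ts\}. A multi-dimensional variable
#' (place = x,y,z; view = u,v; hd = yaw,pitch,roll) enters as additive
#' per-dimension smooths treated as one unit for selection.
#'
#' @name encoding_gam
NULL

#' Build an encoding design for one unit
#'
#' Frames are tracking-locked (default 1/60 s); frames with missing
#' tracking are dropped from target and predictors alike.
#'
#' @param bundle a `session_bundle`.
#' @param unit a `unit_profile`.
#' @param cfg an [analysis_config()].
#' @param kin optional precomputed [compute_kinematics()] frame.
#' @param view optional precomputed [project_view()] frame.
#' @param frame_ms frame width; multiples of the tracking frame are formed
#'   by decimating the tracking grid.
#' @return list of class `encoding_design`: `y` (counts per frame), `vars`
#'   (named list of per-variable data frames), `frame_s`, `t`.
#' @export
build_design <- function(bundle, unit, cfg = analysis_config(), kin = NULL,
                         view = NULL, frame_ms = NULL) {
  pose <- bundle$tracking
  kin <- kin %||% compute_kinematics(pose, cfg)
  view <- view %||% project_view(pose, bundle$maze)
  frame_ms <- frame_ms %||% cfg$gam_frame_ms
  step <- max(1L, round(frame_ms / 1000 * pose$fs))
  idx <- seq(1L, length(pose$t) - step, by = step)
  frame_s <- step / pose$fs
  t0 <- pose$t[idx]
  y <- findInterval(t0 + frame_s, unit$times) - findInterval(t0, unit$times)
  # pose/view at the frame midpoint; kinematics averaged over the frame
  # (sampling at the frame edge aliases the locomotion/stop structure)
  mid <- pmin(idx + step %/% 2L, length(pose$t))
  frame_mean <- function(x) {
    if (step == 1L) return(x[pmin(idx, length(x))])
    cs <- cumsum(ifelse(is.finite(x), x, 0))
    nn <- cumsum(is.finite(x))
    hi <- pmin(idx + step - 1L, length(x))
    tot <- cs[hi] - cs[idx] + ifelse(is.finite(x[idx]), x[idx], 0)
    cnt <- nn[hi] - nn[idx] + is.finite(x[idx])
    ifelse(cnt > 0, tot / cnt, NA_real_)
  }
  kidx <- mid
  yaw <- atan2(2 * (pose$quat[, 1] * pose$quat[, 4] + pose$quat[, 2] * pose$quat[, 3]),
               1 - 2 * (pose$quat[, 3]^2 + pose$quat[, 4]^2)) * 180 / pi
  fwd <- quat_rotate(pose$quat, c(1, 0, 0))
  pitch <- asin(pmin(pmax(fwd[, 3], -1), 1)) * 180 / pi
  side <- quat_rotate(pose$quat, c(0, 1, 0))
  roll <- asin(pmin(pmax(side[, 3], -1), 1)) * 180 / pi
  vars <- list(
    place = data.frame(px = pose$pos[mid, 1], py = pose$pos[mid, 2],
                       pz = pose$pos[mid, 3]),
    view = {
      g <- view_global_coords(bundle$maze, view$face, view$u, view$v)
      data.frame(vu = g$gu[mid], vv = g$gv[mid])
    },
    hd = data.frame(yaw = yaw[mid], pitch = pitch[mid], roll = roll[mid]),
    ahv = data.frame(ahv = frame_mean(kin$ahv)),
    ts = data.frame(ts = frame_mean(kin$ts))
  )
  ok <- pose$valid[mid]
  for (v in vars) ok <- ok & stats::complete.cases(v)
  vars <- lapply(vars, function(v) v[ok, , drop = FALSE])
  structure(list(y = y[ok], vars = vars, frame_s = frame_s, t = t0[ok]),
            class = "encoding_design")
}

gam_formula <- function(variables, design, k = 10) {
  terms <- character(0)
  for (v in variables) {
    cols <- names(design$vars[[v]])
    for (cn in cols) {
      bs <- if (v == "hd" && cn %in% c("yaw", "roll")) "cc" else "ps"
      # the unwrapped view perimeter axis spans ~3x the other domains
      kk <- if (cn == "vu") min(24L, 2L * k) else k
      terms <- c(terms, sprintf("s(%s, bs = '%s', k = %d)", cn, bs, kk))
    }
  }
  stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
}

#' Fit a Poisson GAM for a variable set
#'
#' @param design an `encoding_design`.
#' @param variables character vector from
#'   \{"place", "view", "hd", "ahv", "ts"\}; at least one.
#' @param cfg an [analysis_config()].
#' @param data optional replacement data frame (internal, for shuffles).
#' @return list of class `gam_fit`: `model` (mgcv fit), `mu` (fitted means),
#'   `ed`, `d_fitted`, `d_null`, `converged`, `variables`.
#' @export
fit_poisson_gam <- function(design, variables, cfg = analysis_config(),
                            data = NULL, sp = NULL) {
  stopifnot(length(variables) >= 1)
  df <- data %||% do.call(cbind, unname(design$vars[variables]))
  df$y <- design$y
  fml <- gam_formula(variables, design, cfg$gam_basis_k)
  fit <- mgcv::gam(fml, family = stats::poisson(), data = df,
                   method = "GCV.Cp", sp = sp)
  mu <- as.numeric(stats::fitted(fit))
  ed <- explained_deviance(design$y, mu, cfg$ed_formula)
  structure(list(model = fit, mu = mu, ed = ed$ed, d_fitted = ed$d_fitted,
                 d_null = ed$d_null, converged = fit$converged,
                 variables = variables),
            class = "gam_fit")
}

#' Explained deviance of a Poisson fit
#'
#' D_fitted = 2 * sum(y log(y/mu) - (y - mu)) (saturated-vs-fitted);
#' D_null uses the constant mean-rate model. The conventional form
#' ED = 1 - D_fitted / D_null is the default; `formula = "printed"` gives
#' the complementary ratio D_fitted / D_null.
#'
#' @param y observed counts.
#' @param mu fitted means.
#' @param formula "conventional" or "printed".
#' @return list `ed`, `d_fitted`, `d_null`.
#' @export
explained_deviance <- function(y, mu, formula = "conventional") {
  d_fitted <- poisson_deviance(y, mu)
  ybar <- mean(y)
  if (ybar == 0) stop("undefined: constant zero target")
  d_null <- poisson_deviance(y, rep(ybar, length(y)))
  ed <- if (formula == "printed") d_fitted / d_null else 1 - d_fitted / d_null
  list(ed = ed, d_fitted = d_fitted, d_null = d_null)
}

circshift_vec <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) return(x)
  c(x[(k + 1):n], x[1:k])
}

circshift_df <- function(df, k) as.data.frame(lapply(df, circshift_vec, k = k))

#' Shuffle-gated nested forward selection
#'
#' At each iteration every remaining variable is added to the selected set
#' and fit. The null for first-order models circularly shifts the target
#' (spike counts); for higher orders it shifts the candidate predictor only,
#' leaving the target and already-selected predictors intact. A candidate
#' is significant when its real ED exceeds the Bonferroni-corrected 95th
#' percentile of its null EDs; among significant candidates the one with
#' the highest normalized ED (real - mean shuffle) wins. Selection stops
#' when no candidate passes.
#'
#' @param design an `encoding_design`.
#' @param model_family "pyramidal" (place, view, hd) or "interneuron"
#'   (ahv, ts), or a character vector of candidate variables.
#' @param cfg an [analysis_config()]; `gam_n_shuffle` (default 100) and
#'   `gam_alpha` (0.05) control the gate.
#' @param seed RNG seed for the shifts.
#' @return list of class `selection_trace`: `selected`, `iterations` (per
#'   iteration: candidate EDs, null percentiles, accepted variable, stop
#'   reason), `final_fit` (a `gam_fit` or NULL).
#' @export
forward_select <- function(design, model_family = "pyramidal",
                           cfg = analysis_config(), seed = 1) {
  candidates <- if (length(model_family) > 1) model_family
  else switch(model_family,
              pyramidal = c("place", "view", "hd"),
              interneuron = c("ahv", "ts"),
              model_family)
  selected <- character(0)
  iterations <- list()
  final_fit <- NULL
  n <- length(design$y)
  n_sh <- cfg$gam_n_shuffle
  min_shift <- max(2L, round(n * 0.05))
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    alpha_corr <- cfg$gam_alpha / length(remaining)
    q <- 1 - alpha_corr
    rows <- list()
    for (v in remaining) {
      fit <- fit_poisson_gam(design, c(selected, v), cfg)
      shifts <- local_seed(child_seed(seed, paste0(length(selected), v)),
                           sample(seq(min_shift, n - min_shift), n_sh, replace = n_sh > n))
      # null fits reuse the real fit's smoothing parameters (no GCV search)
      sp_fix <- fit$model$sp
      null_ed <- vapply(shifts, function(k) {
        if (!length(selected)) {
          d2 <- design; d2$y <- circshift_vec(design$y, k)
          fit_poisson_gam(d2, v, cfg, sp = sp_fix)$ed
        } else {
          df <- do.call(cbind, unname(design$vars[c(selected, v)]))
          shift_cols <- names(design$vars[[v]])
          df[shift_cols] <- lapply(df[shift_cols], circshift_vec, k = k)
          fit_poisson_gam(design, c(selected, v), cfg, data = df, sp = sp_fix)$ed
        }
      }, numeric(1))
      rows[[v]] <- list(variable = v, ed = fit$ed,
                        null_q = stats::quantile(null_ed, q, names = FALSE),
                        null_mean = mean(null_ed),
                        norm_ed = fit$ed - mean(null_ed),
                        significant = fit$ed > stats::quantile(null_ed, q, names = FALSE),
                        fit = fit)
    }
    sig <- Filter(function(r) r$significant, rows)
    if (!length(sig)) {
      iterations[[length(iterations) + 1L]] <-
        list(candidates = rows, accepted = NA_character_, stop = "no significant candidate")
      break
    }
    best <- sig[[which.max(vapply(sig, `[[`, 1, "norm_ed"))]]
    selected <- c(selected, best$variable)
    final_fit <- best$fit
    iterations[[length(iterations) + 1L]] <-
      list(candidates = rows, accepted = best$variable, stop = NA_character_)
  }
  structure(list(selected = selected, iterations = iterations,
                 final_fit = final_fit),
            class = "selection_trace")
}

#' Cross-validated prediction score of the winning model
#'
#' The session is split into `cv_folds` contiguous equal-time folds; for
#' each fold the model is refit on the rest and the held-out rate
#' predicted. Per-fold R^2 is the squared Pearson correlation between
#' predicted rate and real counts; the final R^2 averages folds, and an
#' F-test (regression F on the mean R^2 with held-out df) at alpha = 0.05
#' labels the unit "encoding".
#'
#' @param design an `encoding_design`.
#' @param variables selected variable set (non-empty).
#' @param cfg an [analysis_config()].
#' @return list: `r2` (mean over folds), `per_fold`, `f_p`, `encoding`.
#' @export
evaluate_prediction <- function(design, variables, cfg = analysis_config()) {
  stopifnot(length(variables) >= 1)
  n <- length(design$y)
  folds <- cfg$cv_folds
  fold_id <- ceiling(seq_len(n) / n * folds)
  r2 <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (sum(design$y[!tr]) == 0) next  # fold without spikes: skipped
    d_tr <- design
    d_tr$y <- design$y[tr]
    d_tr$vars <- lapply(design$vars, function(v) v[tr, , drop = FALSE])
    fit <- fit_poisson_gam(d_tr, variables, cfg)
    newdata <- do.call(cbind, unname(lapply(design$vars[variables],
                                            function(v) v[!tr, , drop = FALSE])))
    pred <- as.numeric(stats::predict(fit$model, newdata = newdata,
                                      type = "response"))
    if (stats::sd(pred) == 0 || stats::sd(design$y[!tr]) == 0) next
    r2[f] <- stats::cor(pred, design$y[!tr])^2
  }
  used <- which(is.finite(r2))
  if (!length(used)) return(list(r2 = NA_real_, per_fold = r2, f_p = NA_real_,
                                 encoding = FALSE))
  r2m <- mean(r2[used])
  m <- floor(n / folds)  # held-out frames per fold
  fstat <- r2m / max(1 - r2m, .Machine$double.eps) * (m - 2)
  f_p <- stats::pf(fstat, 1, m - 2, lower.tail = FALSE)
  list(r2 = r2m, per_fold = r2, f_p = f_p, encoding = f_p < cfg$cv_alpha)
}
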