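#' Pseudo-population place decoding
#'
#' Decodes coarse place (4 of 6 floor-half bins) from per-unit firing rates
#' integrated over 200 ms windows centered on head "fixations" (AHV below
#' 200 deg/s), with a linear one-vs-one SVM, balanced-subsample repeats and
#' fivefold cross-validation. Ensembles are built greedily (seed unit =
#' best single-unit decoder, then best n+1 extension) and compared against
#' random combinations; performance vs ensemble size is summarized with a
#' Naka-Rushton fit.
#'
#' @name place_decoding
NULL

#' Extract fixation trials for decoding
#'
#' Candidate centers are local minima of AHV inside sub-threshold runs,
#' spaced at least one window apart. Each trial carries the per-unit rate
#' over the 200 ms window and the floor-half place class at its center. The
#' 4 retained classes (of 6) are those with the highest trial counts.
#'
#' @param bundle a `session_bundle`.
#' @param kin data frame from [compute_kinematics()].
#' @param cfg an [analysis_config()].
#' @param units optional subset of unit profiles (default all in bundle).
#' @return list of class `trial_set`: `rates` (trials x units), `labels`,
#'   `t_center`, `classes` (the 4 retained class ids), `class_counts`.
#' @export
extract_trials <- function(bundle, kin, cfg = analysis_config(), units = NULL) {
  units <- units %||% bundle$units
  half_w <- cfg$decoder_window_ms / 2000
  spacing <- cfg$decoder_spacing_ms / 1000
  ahv <- kin$ahv
  low <- !is.na(ahv) & ahv < cfg$decoder_low_ahv
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  centers <- numeric(0)
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    tt <- kin$t[idx]; vv <- ahv[idx]
    if (tt[length(tt)] - tt[1] < 2 * half_w) next
    # local minima, then greedy spacing enforcement (deepest first)
    n <- length(vv)
    if (n < 3) next
    is_min <- c(FALSE, vv[2:(n - 1)] <= vv[1:(n - 2)] & vv[2:(n - 1)] <= vv[3:n], FALSE)
    cand <- idx[is_min]
    cand <- cand[order(ahv[cand])]
    chosen <- numeric(0)
    for (ci in cand) {
      tc <- kin$t[ci]
      if (!length(chosen) || all(abs(tc - chosen) >= spacing + 2 * half_w))
        chosen <- c(chosen, tc)
    }
    centers <- c(centers, chosen)
  }
  centers <- sort(centers)
  centers <- centers[centers - half_w >= 0 & centers + half_w <= bundle$duration]
  # global non-overlap pass (candidates from adjacent runs can collide)
  if (length(centers) > 1) {
    keep <- centers[1]
    for (tc in centers[-1])
      if (tc - keep[length(keep)] >= 2 * half_w + spacing) keep <- c(keep, tc)
    centers <- keep
  }
  if (!length(centers)) {
    warning("insufficient sampling: no usable low-AHV trials")
    return(structure(list(rates = matrix(0, 0, length(units)),
                          labels = integer(0), t_center = numeric(0),
                          classes = integer(0), class_counts = integer(0)),
                     class = "trial_set"))
  }
  pose <- bundle$tracking
  pos_idx <- spike_sample_index(centers, pose$t, 1 / pose$fs)
  labels <- floor_half_bin(bundle$maze, pose$pos[pos_idx, , drop = FALSE])
  rates <- vapply(units, function(u) {
    cnt <- findInterval(centers + half_w, u$times) -
      findInterval(centers - half_w, u$times)
    cnt / (2 * half_w)
  }, numeric(length(centers)))
  if (is.null(dim(rates))) rates <- matrix(rates, nrow = length(centers))
  colnames(rates) <- vapply(units, `[[`, "", "unit_id")
  counts <- table(labels)
  keep_classes <- as.integer(names(sort(counts, decreasing = TRUE)))[seq_len(min(4, length(counts)))]
  sel <- labels %in% keep_classes
  cc <- as.integer(counts[as.character(keep_classes)])
  if (length(keep_classes) < 4 || any(cc < cfg$decoder_min_trials))
    warning("insufficient sampling: fewer than 4 classes with ",
            cfg$decoder_min_trials, " trials")
  structure(list(rates = rates[sel, , drop = FALSE], labels = labels[sel],
                 t_center = centers[sel], classes = sort(keep_classes),
                 class_counts = cc),
            class = "trial_set")
}

#' Train and cross-validate the place decoder
#'
#' Per repeat: every class is subsampled to the minimum class count, split
#' into stratified folds, features z-scored on the training folds only, a
#' linear one-vs-one SVM fit, and fold accuracies averaged. Reported
#' accuracy is the mean over repeats (never the best).
#'
#' @param trials a `trial_set`.
#' @param members unit ids (or column indices) to use as features.
#' @param cfg an [analysis_config()].
#' @param seed RNG seed.
#' @param repeats,folds override the config counts (test-scale hooks).
#' @param shuffle_labels permute labels uniformly at random (chance floor).
#' @return list: `accuracy` (mean over repeats), `sd`, `ci` (95%, normal),
#'   `per_repeat`, `confusion` (summed over repeats/folds).
#' @export
train_decoder <- function(trials, members = NULL, cfg = analysis_config(),
                          seed = 1, repeats = NULL, folds = NULL,
                          shuffle_labels = FALSE) {
  members <- members %||% colnames(trials$rates)
  X_all <- trials$rates[, members, drop = FALSE]
  y_all <- trials$labels
  repeats <- repeats %||% cfg$decoder_repeats
  folds <- folds %||% cfg$decoder_folds
  cls <- sort(unique(y_all))
  conf <- matrix(0, length(cls), length(cls),
                 dimnames = list(as.character(cls), as.character(cls)))
  per_repeat <- local_seed(seed, {
    vapply(seq_len(repeats), function(rep_i) {
      # a fresh label permutation per repeat: the mean over repeats then
      # estimates the chance level rather than one permutation's quirk
      if (shuffle_labels) y_all <- sample(y_all)
      m <- min(table(y_all))
      keep <- unlist(lapply(cls, function(cl) sample(which(y_all == cl), m)))
      X <- X_all[keep, , drop = FALSE]; y <- y_all[keep]
      fold_id <- unlist(lapply(cls, function(cl)
        sample(rep_len(seq_len(folds), m))))
      accs <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        mu <- colMeans(X[tr, , drop = FALSE])
        sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
        sdv[sdv == 0] <- 1
        Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
        Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
        fit <- svm_ovo_train(Xtr, y[tr], cfg$decoder_C)
        pred <- svm_ovo_predict(fit, Xte)
        for (i in seq_along(pred))
          conf[as.character(y[!tr][i]), as.character(pred[i])] <<-
            conf[as.character(y[!tr][i]), as.character(pred[i])] + 1
        mean(pred == y[!tr])
      }, numeric(1))
      mean(accs)
    }, numeric(1))
  })
  se <- stats::sd(per_repeat) / sqrt(repeats)
  list(accuracy = mean(per_repeat), sd = stats::sd(per_repeat),
       ci = mean(per_repeat) + c(-1.96, 1.96) * se,
       per_repeat = per_repeat, confusion = conf)
}

#' Greedy ensemble construction
#'
#' Iteration 1 trains one decoder per pool unit; the best unit seeds the
#' ensemble. Each later iteration tries all single-unit extensions and
#' keeps the best, until `max_size` or until improvement over the last 3
#' sizes falls below `ensemble_tol`. Ties break toward the lower unit
#' index.
#'
#' @param trials a `trial_set`.
#' @param pool candidate unit ids.
#' @param cfg an [analysis_config()].
#' @param max_size maximum ensemble size (default `cfg$ensemble_max_size`).
#' @param seed RNG seed.
#' @param repeats,folds decoder overrides passed through.
#' @return list of class `ensemble_curve`: `members` (in selection order),
#'   `accuracy` per size, `ci` matrix, `variant`.
#' @export
build_greedy_ensemble <- function(trials, pool = NULL, cfg = analysis_config(),
                                  max_size = NULL, seed = 1,
                                  repeats = NULL, folds = NULL) {
  pool <- pool %||% colnames(trials$rates)
  max_size <- max_size %||% cfg$ensemble_max_size
  members <- character(0)
  acc <- numeric(0); ci <- NULL
  remaining <- pool
  for (size in seq_len(min(max_size, length(pool)))) {
    evals <- lapply(remaining, function(u)
      train_decoder(trials, c(members, u), cfg,
                    seed = child_seed(seed, paste0("s", size)),
                    repeats = repeats, folds = folds))
    accs <- vapply(evals, `[[`, 1, "accuracy")
    best <- which.max(accs)  # first max = lowest index tie-break
    members <- c(members, remaining[best])
    acc <- c(acc, accs[best])
    ci <- rbind(ci, evals[[best]]$ci)
    remaining <- setdiff(remaining, remaining[best])
    if (size > 3 && (acc[size] - acc[size - 3]) < cfg$ensemble_tol) break
    if (!length(remaining)) break
  }
  structure(list(members = members, accuracy = acc, ci = ci,
                 variant = "greedy"), class = "ensemble_curve")
}

#' Random-combination ensemble control
#'
#' Accuracy distribution of `n_combos` unique random subsets of `size`
#' units from the pool.
#'
#' @param trials a `trial_set`.
#' @param pool candidate unit ids.
#' @param size ensemble size.
#' @param n_combos number of random combinations (default 100).
#' @param cfg an [analysis_config()].
#' @param seed RNG seed.
#' @param repeats,folds decoder overrides passed through.
#' @return list: `accuracies`, `mean`, `ci` (95% normal over combos),
#'   `combos`.
#' @export
random_ensembles <- function(trials, pool, size, n_combos = NULL,
                             cfg = analysis_config(), seed = 1,
                             repeats = NULL, folds = NULL) {
  n_combos <- n_combos %||% cfg$random_n_combos
  if (length(pool) < size) stop("pool smaller than ensemble size")
  max_unique <- choose(length(pool), size)
  n_combos <- min(n_combos, max_unique)
  combos <- local_seed(seed, {
    seen <- character(0); out <- list()
    while (length(out) < n_combos) {
      cb <- sort(sample(pool, size))
      key <- paste(cb, collapse = "|")
      if (!key %in% seen) { seen <- c(seen, key); out[[length(out) + 1L]] <- cb }
    }
    out
  })
  accs <- vapply(seq_along(combos), function(i)
    train_decoder(trials, combos[[i]], cfg, seed = child_seed(seed, paste0("c", i)),
                  repeats = repeats, folds = folds)$accuracy,
    numeric(1))
  se <- stats::sd(accs) / sqrt(length(accs))
  list(accuracies = accs, mean = mean(accs),
       ci = mean(accs) + c(-1.96, 1.96) * se, combos = combos)
}

#' Naka-Rushton fit to an ensemble performance curve
#'
#' @param curve an `ensemble_curve`.
#' @param seed RNG seed for the fitter restarts.
#' @return a `naka_rushton_fit`; the saturating accuracy is
#'   `par["r_max"] + par["b"]`.
#' @export
curve_fit_performance <- function(curve, seed = 1) {
  if (length(curve$accuracy) < 4) stop("need at least 4 ensemble sizes")
  fit_naka_rushton(seq_along(curve$accuracy), curve$accuracy, seed = seed)
}
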