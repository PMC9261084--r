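# Clinical classification from sense-of-agency performance: per-participant
# psychometric slopes (self-attribution proportion vs alteration level, per
# aspect), nearest-group-centroid assignment by Euclidean distance in the
# 2-D slope space, leave-p-out resampling with optional trial subsampling,
# a label-permutation null, and the robustness grid.

CELL_LEVELS <- c("none0", "temporal1", "temporal2", "temporal3",
                 "spatial1", "spatial2", "spatial3")
# OLS slope of proportion on level 0..3: sum((x - 1.5) * y) / sum((x - 1.5)^2)
SLOPE_W <- c(-1.5, -0.5, 0.5, 1.5) / 5

trial_cell <- function(trials) {
  match(paste0(trials$aspect, trials$magnitude_level), CELL_LEVELS)
}

#' Per-magnitude self-attribution proportions
#'
#' Proportion of "identical" responses at each alteration level 0..3 for one
#' aspect. Level 0 is the shared unaltered pool (there is a single pool of
#' unaltered trials, used by both aspects).
#'
#' @param trials one participant's retained trials.
#' @param aspect `"temporal"` or `"spatial"`.
#' @return numeric vector of 4 proportions, ordered by level.
#' @export
per_magnitude_proportions <- function(trials, aspect) {
  aspect <- match.arg(aspect, c("temporal", "spatial"))
  resp <- trials$response_identical
  if (anyNA(resp)) stop("trials with missing responses must be excluded first",
                        call. = FALSE)
  props <- numeric(4)
  for (lvl in 0:3) {
    sel <- if (lvl == 0) trials$magnitude_level == 0L
           else trials$aspect == aspect & trials$magnitude_level == lvl
    if (!any(sel)) {
      stop("no trials at ", aspect, " level ", lvl, call. = FALSE)
    }
    props[lvl + 1] <- mean(resp[sel])
  }
  props
}

#' Least-squares slope of a 4-point psychometric profile
#'
#' Ordinary least-squares line of self-attribution proportion on alteration
#' level (0, 1, 2, 3).
#'
#' @param proportions numeric vector of 4 proportions.
#' @return named numeric vector `c(slope, intercept)`.
#' @export
fit_slope <- function(proportions) {
  stopifnot(length(proportions) == 4, all(is.finite(proportions)))
  slope <- sum(SLOPE_W * proportions)
  c(slope = slope, intercept = mean(proportions) - slope * 1.5)
}

#' Per-participant slope features
#'
#' The classifier's feature vector: the temporal and spatial psychometric
#' slopes fitted to the per-level self-attribution proportions (intercepts
#' are recorded for diagnostics but not used by the classifier).
#'
#' @param data a [soa_dataset()] (apply [apply_exclusions()] first).
#' @param trial_pool `"whole_experiment"` or `"first_block"` (block 1 only).
#' @return data.frame of class `soa_slopes`: `participant_id`, `group`,
#'   `slope_temporal`, `slope_spatial`, `intercept_temporal`,
#'   `intercept_spatial`, `n_trials_used`.
#' @export
slope_features <- function(data, trial_pool = "whole_experiment") {
  stopifnot(inherits(data, "soa_dataset"))
  trial_pool <- match.arg(trial_pool, c("whole_experiment", "first_block"))
  trials <- data$trials[!is.na(data$trials$response_identical), , drop = FALSE]
  if (trial_pool == "first_block") trials <- trials[trials$block == 1L, , drop = FALSE]
  rows <- lapply(unique(trials$participant_id), function(pid) {
    tt <- trials[trials$participant_id == pid, , drop = FALSE]
    ft <- fit_slope(per_magnitude_proportions(tt, "temporal"))
    fs <- fit_slope(per_magnitude_proportions(tt, "spatial"))
    data.frame(participant_id = pid, group = tt$group[1],
               slope_temporal = ft[["slope"]], slope_spatial = fs[["slope"]],
               intercept_temporal = ft[["intercept"]],
               intercept_spatial = fs[["intercept"]],
               n_trials_used = nrow(tt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("soa_slopes", "data.frame")
  out
}

#' Assign a participant to the nearest group centroid
#'
#' Euclidean distance in the (temporal slope, spatial slope) plane; the
#' participant is assigned to the group with the nearer mean slope vector.
#' Exact ties are resolved by `tie_rule` (default: assign control) with a
#' warning.
#'
#' @param features length-2 numeric (temporal, spatial slopes).
#' @param centroid_control,centroid_psychosis length-2 numeric centroids.
#' @param tie_rule group assigned on an exact tie.
#' @return `"control"` or `"psychosis"`.
#' @export
classify_participant <- function(features, centroid_control, centroid_psychosis,
                                 tie_rule = c("control", "psychosis")) {
  tie_rule <- match.arg(tie_rule)
  if (!all(is.finite(c(features, centroid_control, centroid_psychosis)))) {
    stop("non-finite features or centroids", call. = FALSE)
  }
  dc <- sum((features - centroid_control)^2)
  dp <- sum((features - centroid_psychosis)^2)
  if (dc == dp) {
    warning("exact centroid tie; assigning ", tie_rule, call. = FALSE)
    return(tie_rule)
  }
  if (dc < dp) "control" else "psychosis"
}

derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Draw n trials without replacement from one participant's pool until every
# aspect x level cell is represented; returns c(slope_temporal, slope_spatial).
subsample_slopes <- function(cell, resp, n, max_resample = 100L) {
  nT <- length(cell)
  for (attempt in seq_len(max_resample)) {
    idx <- sample.int(nT, n)
    cells <- cell[idx]
    tn <- tabulate(cells, 7L)
    if (any(tn == 0L)) next
    ty <- tabulate(cells[resp[idx]], 7L)
    props <- ty / tn
    return(c(sum(SLOPE_W * props[c(1L, 2L, 3L, 4L)]),
             sum(SLOPE_W * props[c(1L, 5L, 6L, 7L)])))
  }
  stop("could not draw ", n, " trials covering every aspect x level cell in ",
       max_resample, " attempts", call. = FALSE)
}

classifier_engine <- function(data, leave_out_fraction, n_iterations,
                              n_trials_sampled, trial_pool, seed, tie_rule,
                              subsample_retained, permute_labels,
                              max_resample = 100L) {
  stopifnot(inherits(data, "soa_dataset"))
  trial_pool <- match.arg(trial_pool, c("whole_experiment", "first_block"))
  tie_rule <- match.arg(tie_rule, c("control", "psychosis"))
  stopifnot(leave_out_fraction > 0, leave_out_fraction < 1, n_iterations >= 1)
  subsampling <- !identical(n_trials_sampled, "all")
  if (subsampling) {
    n_trials_sampled <- as.integer(n_trials_sampled)
    stopifnot(n_trials_sampled >= 7)
    if (trial_pool == "first_block" && n_trials_sampled > 48) {
      stop("first_block pool caps n_trials_sampled at 48", call. = FALSE)
    }
  }

  trials <- data$trials[!is.na(data$trials$response_identical), , drop = FALSE]
  pool <- if (trial_pool == "first_block")
    trials[trials$block == 1L, , drop = FALSE] else trials

  # sorted for invariance to trial row order
  ids <- sort(unique(trials$participant_id))
  grp <- data$participants$group[match(ids, data$participants$participant_id)]
  n_c <- sum(grp == "control"); n_p <- sum(grp == "psychosis")
  if (n_c < 2 || n_p < 2) stop("need at least two participants per group",
                               call. = FALSE)
  k_c <- max(1L, round(leave_out_fraction * n_c))
  k_p <- max(1L, round(leave_out_fraction * n_p))
  if (k_c >= n_c || k_p >= n_p) {
    stop("leave_out_fraction leaves no retained participants", call. = FALSE)
  }

  # centroid features: full retained trials, whole experiment
  full_sf <- slope_features(data)
  Ffull <- as.matrix(full_sf[match(ids, full_sf$participant_id),
                             c("slope_temporal", "slope_spatial")])
  # test features when no subsampling: every trial in the chosen pool
  Fpool <- if (trial_pool == "whole_experiment") Ffull else {
    pf <- slope_features(data, trial_pool = "first_block")
    as.matrix(pf[match(ids, pf$participant_id),
                 c("slope_temporal", "slope_spatial")])
  }
  pool_cell <- pool_resp <- vector("list", length(ids))
  if (subsampling) {
    for (i in seq_along(ids)) {
      pt <- pool[pool$participant_id == ids[i], , drop = FALSE]
      if (nrow(pt) < n_trials_sampled) {
        stop("participant ", ids[i], " has only ", nrow(pt),
             " trials in the ", trial_pool, " pool", call. = FALSE)
      }
      pool_cell[[i]] <- trial_cell(pt)
      pool_resp[[i]] <- pt$response_identical
    }
  }

  seeds <- derive_seeds(seed, 2L)
  # participant stream: leave-out draws (and label permutations for the null)
  set.seed(seeds[1])
  idx_c <- which(grp == "control"); idx_p <- which(grp == "psychosis")
  iter_sets <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    g <- if (permute_labels) sample(grp) else grp
    ic <- which(g == "control"); ip <- which(g == "psychosis")
    iter_sets[[it]] <- list(g = g,
                            out_c = ic[sample.int(length(ic), k_c)],
                            out_p = ip[sample.int(length(ip), k_p)])
  }
  # trial stream: subsampling draws
  set.seed(seeds[2])

  acc <- sens <- spec <- numeric(n_iterations)
  n_out <- n_correct <- n_as_psych <- integer(length(ids))
  n_ties <- 0L
  for (it in seq_len(n_iterations)) {
    st <- iter_sets[[it]]
    g <- st$g
    out <- c(st$out_c, st$out_p)
    retained <- setdiff(seq_along(ids), out)
    rc <- retained[g[retained] == "control"]
    rp <- retained[g[retained] == "psychosis"]
    if (subsampling && subsample_retained) {
      cen_c <- colMeans(t(vapply(rc, function(i)
        subsample_slopes(pool_cell[[i]], pool_resp[[i]], n_trials_sampled,
                         max_resample), numeric(2))))
      cen_p <- colMeans(t(vapply(rp, function(i)
        subsample_slopes(pool_cell[[i]], pool_resp[[i]], n_trials_sampled,
                         max_resample), numeric(2))))
    } else {
      cen_c <- colMeans(Ffull[rc, , drop = FALSE])
      cen_p <- colMeans(Ffull[rp, , drop = FALSE])
    }
    correct <- logical(length(out))
    is_psych <- g[out] == "psychosis"
    for (j in seq_along(out)) {
      i <- out[j]
      f <- if (subsampling)
        subsample_slopes(pool_cell[[i]], pool_resp[[i]], n_trials_sampled,
                         max_resample)
      else Fpool[i, ]
      dc <- sum((f - cen_c)^2); dp <- sum((f - cen_p)^2)
      lab <- if (dc == dp) { n_ties <- n_ties + 1L; tie_rule }
             else if (dc < dp) "control" else "psychosis"
      correct[j] <- lab == g[i]
      n_out[i] <- n_out[i] + 1L
      n_correct[i] <- n_correct[i] + (lab == g[i])
      n_as_psych[i] <- n_as_psych[i] + (lab == "psychosis")
    }
    acc[it] <- mean(correct)
    sens[it] <- mean(correct[is_psych])
    spec[it] <- mean(correct[!is_psych])
  }
  if (n_ties > 0) warning(n_ties, " exact centroid tie(s) resolved to '",
                          tie_rule, "'", call. = FALSE)
  per_participant <- data.frame(
    participant_id = ids, group = grp, n_left_out = n_out,
    freq_correct = ifelse(n_out > 0, n_correct / n_out, NA_real_),
    freq_classified_psychosis = ifelse(n_out > 0, n_as_psych / n_out, NA_real_),
    stringsAsFactors = FALSE)
  structure(list(
    accuracy = acc, sensitivity = sens, specificity = spec,
    summary = data.frame(
      metric = c("accuracy", "sensitivity", "specificity"),
      mean = c(mean(acc), mean(sens), mean(spec)),
      sd = c(stats::sd(acc), stats::sd(sens), stats::sd(spec)),
      ci_lo = c(stats::quantile(acc, 0.025), stats::quantile(sens, 0.025),
                stats::quantile(spec, 0.025)),
      ci_hi = c(stats::quantile(acc, 0.975), stats::quantile(sens, 0.975),
                stats::quantile(spec, 0.975)),
      row.names = NULL),
    per_participant = per_participant,
    config = list(leave_out_fraction = leave_out_fraction,
                  n_iterations = n_iterations,
                  n_trials_sampled = if (subsampling) n_trials_sampled else "all",
                  trial_pool = trial_pool, seed = seed, tie_rule = tie_rule,
                  subsample_retained = subsample_retained,
                  permuted_labels = permute_labels)
  ), class = "soa_classifier")
}

#' Leave-p-out nearest-centroid classification
#'
#' On each of `n_iterations` resampling iterations the same fraction of
#' participants is left out of each group; the retained participants'
#' mean (temporal, spatial) slope vectors form the two group centroids, and
#' each left-out participant is assigned to the group with the nearer
#' centroid. Left-out participants' slopes are computed either from all
#' their retained trials (`n_trials_sampled = "all"`) or from a random
#' subset of `n_trials_sampled` trials drawn without replacement from
#' `trial_pool` (the whole session or only block 1); a draw leaving any
#' aspect-by-level cell empty is rejected and retried. Centroids always use
#' the retained participants' full trial sets unless
#' `subsample_retained = TRUE`.
#'
#' Two independent seeded random-number streams drive participant selection
#' and trial subsampling, so classifier runs with different trial
#' configurations share identical leave-out sequences for a given seed.
#'
#' @param data a [soa_dataset()] (apply [apply_exclusions()] first).
#' @param leave_out_fraction fraction of each group left out per iteration.
#' @param n_iterations number of resampling iterations (study value 10000).
#' @param n_trials_sampled `"all"` or an integer number of trials drawn for
#'   each left-out participant.
#' @param trial_pool `"whole_experiment"` or `"first_block"` (caps
#'   `n_trials_sampled` at 48).
#' @param seed integer seed.
#' @param tie_rule group assigned on an exact centroid tie.
#' @param subsample_retained also subsample the retained participants'
#'   trials when computing centroids (default `FALSE`).
#' @return object of class `soa_classifier` with per-iteration `accuracy`,
#'   `sensitivity` (psychosis correctly classified) and `specificity`
#'   (controls correctly classified), a `summary` table with means and 95%
#'   percentile intervals, and per-participant classification frequencies.
#' @export
run_classifier <- function(data, leave_out_fraction = 0.2,
                           n_iterations = 10000L, n_trials_sampled = "all",
                           trial_pool = "whole_experiment", seed = 1,
                           tie_rule = "control", subsample_retained = FALSE) {
  classifier_engine(data, leave_out_fraction, n_iterations, n_trials_sampled,
                    trial_pool, seed, tie_rule, subsample_retained,
                    permute_labels = FALSE)
}

#' Permutation null distribution of classifier accuracy
#'
#' Repeats the leave-p-out procedure after randomly permuting group labels
#' (group sizes preserved) before each iteration's centroid computation.
#' The resulting accuracy distribution is the chance reference against
#' which the true-label accuracies are compared (see [ks_two_sample()]).
#'
#' @inheritParams run_classifier
#' @return object of class `soa_classifier` (with
#'   `config$permuted_labels = TRUE`).
#' @export
permutation_null <- function(data, leave_out_fraction = 0.2,
                             n_iterations = 10000L, n_trials_sampled = "all",
                             trial_pool = "whole_experiment", seed = 1,
                             tie_rule = "control", subsample_retained = FALSE) {
  classifier_engine(data, leave_out_fraction, n_iterations, n_trials_sampled,
                    trial_pool, seed, tie_rule, subsample_retained,
                    permute_labels = TRUE)
}

#' @export
print.soa_classifier <- function(x, ...) {
  cat(sprintf("%s nearest-centroid classifier (%d iterations, leave-out %.0f%%, trials: %s, pool: %s)\n",
              if (x$config$permuted_labels) "Permuted-label" else "Leave-p-out",
              x$config$n_iterations, 100 * x$config$leave_out_fraction,
              as.character(x$config$n_trials_sampled), x$config$trial_pool))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.1f%%  (95%% interval %.1f%%-%.1f%%)\n",
                s$metric[i], 100 * s$mean[i], 100 * s$ci_lo[i], 100 * s$ci_hi[i]))
  }
  invisible(x)
}

#' @export
summary.soa_classifier <- function(object, ...) {
  print(object)
  cat("\nMost often misclassified participants:\n")
  pp <- object$per_participant
  pp <- pp[order(pp$freq_correct), ]
  print(utils::head(pp, 5), row.names = FALSE)
  invisible(object$summary)
}

#' Robustness grid of classifier accuracy
#'
#' Mean classifier accuracy over a grid of trial-subsample sizes and
#' leave-out fractions, the robustness analysis of the classifier.
#'
#' @inheritParams run_classifier
#' @param n_trials vector of trial counts (`240` is treated as `"all"` for
#'   the whole-experiment pool, `48` as `"all"` for the first-block pool).
#' @param leave_out vector of leave-out fractions.
#' @return data.frame of class `soa_classifier_grid` with columns
#'   `n_trials`, `leave_out`, `accuracy`, `sensitivity`, `specificity`.
#' @export
classifier_grid <- function(data, n_trials = c(240, 120, 48, 24),
                            leave_out = c(0.2, 0.5, 0.8),
                            trial_pool = "whole_experiment",
                            n_iterations = 1000L, seed = 1,
                            subsample_retained = FALSE) {
  trial_pool <- match.arg(trial_pool, c("whole_experiment", "first_block"))
  pool_size <- if (trial_pool == "first_block") 48L else 240L
  rows <- list()
  for (fo in leave_out) {
    for (nt in n_trials) {
      nts <- if (nt >= pool_size) "all" else nt
      res <- classifier_engine(data, fo, n_iterations, nts, trial_pool, seed,
                               tie_rule = "control",
                               subsample_retained = subsample_retained,
                               permute_labels = FALSE)
      s <- res$summary
      rows[[length(rows) + 1L]] <- data.frame(
        n_trials = nt, leave_out = fo,
        accuracy = s$mean[s$metric == "accuracy"],
        sensitivity = s$mean[s$metric == "sensitivity"],
        specificity = s$mean[s$metric == "specificity"])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("soa_classifier_grid", "data.frame")
  out
}

#' @export
print.soa_classifier_grid <- function(x, ...) {
  cat("Classifier accuracy grid (mean accuracy)\n")
  m <- stats::xtabs(accuracy ~ n_trials + leave_out, data = x)
  print(round(m[order(-as.numeric(rownames(m))), , drop = FALSE], 3))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs, with the
#' asymptotic two-sided p-value; used to compare the true-label classifier
#' accuracy distribution with its permutation null.
#'
#' @param x,y numeric samples.
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}
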