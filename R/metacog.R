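# Type-2 (metacognition) analysis: Goodman-Kruskal gamma rank correlation
# between trial-level confidence and the correctness of the agency judgment,
# per participant and at the group level.

#' Goodman-Kruskal gamma between confidence and accuracy
#'
#' Over all unordered trial pairs, a pair is concordant when the more
#' confident trial is also the correct one and discordant when the more
#' confident trial is the incorrect one; pairs tied on confidence or on
#' accuracy are excluded. Gamma is `(C - D) / (C + D)`, ranging from -1 to 1
#' with 0 meaning confidence carries no information about accuracy.
#'
#' When all retained trials are correct (or all incorrect), or confidence is
#' constant, no pair is informative and gamma is undefined: an error of
#' class `soameta_undefined_gamma` is signalled carrying the cause, and the
#' caller decides whether to exclude the participant.
#'
#' @param confidence numeric vector of confidence ratings.
#' @param accuracy logical vector of judgment correctness, same length.
#' @return list with `gamma`, `n_concordant`, `n_discordant`, `n_pairs_used`.
#' @export
gk_gamma <- function(confidence, accuracy) {
  stopifnot(length(confidence) == length(accuracy))
  keep <- !is.na(confidence) & !is.na(accuracy)
  confidence <- confidence[keep]
  accuracy <- as.logical(accuracy[keep])
  if (length(confidence) < 2) {
    stop(errorCondition("gamma undefined: fewer than two usable trials",
                        class = c("soameta_undefined_gamma", "error")))
  }
  conf_correct <- confidence[accuracy]
  conf_wrong <- confidence[!accuracy]
  if (length(conf_correct) == 0 || length(conf_wrong) == 0) {
    stop(errorCondition(
      "gamma undefined: accuracy has no contrast (all correct or all incorrect)",
      class = c("soameta_undefined_gamma", "error")))
  }
  # pairs within an accuracy class are tied on accuracy, hence dropped;
  # across classes, count strict confidence orderings
  cmp <- outer(conf_correct, conf_wrong, "-")
  C <- sum(cmp > 0)
  D <- sum(cmp < 0)
  if (C + D == 0) {
    stop(errorCondition(
      "gamma undefined: confidence is tied across all informative pairs",
      class = c("soameta_undefined_gamma", "error")))
  }
  list(gamma = (C - D) / (C + D), n_concordant = C, n_discordant = D,
       n_pairs_used = C + D)
}

#' Per-participant metacognition summary
#'
#' Computes Goodman-Kruskal gamma per participant from retained trials with
#' both a response and a confidence rating, pooling both aspects and all
#' magnitudes (the study's statistic). With `by_aspect = TRUE`, per-aspect
#' rows restrict altered trials to one aspect while sharing the unaltered
#' pool. Participants with undefined gamma get `NA` and a warning.
#'
#' @param data a [soa_dataset()] (apply [apply_exclusions()] first).
#' @param by_aspect logical; additionally return per-aspect rows.
#' @return data.frame of class `soa_gamma`: `participant_id`, `group`,
#'   `aspect`, `gamma`, `n_concordant`, `n_discordant`, `n_pairs_used`.
#' @export
gamma_summary <- function(data, by_aspect = FALSE) {
  stopifnot(inherits(data, "soa_dataset"))
  trials <- data$trials
  trials <- trials[!is.na(trials$response_identical) &
                     !is.na(trials$confidence), , drop = FALSE]
  trials$accuracy <- label_accuracy(trials)
  aspects <- if (by_aspect) c("pooled", "temporal", "spatial") else "pooled"
  rows <- list()
  undefined <- character(0)
  for (pid in unique(trials$participant_id)) {
    tt <- trials[trials$participant_id == pid, , drop = FALSE]
    for (a in aspects) {
      sub <- if (a == "pooled") tt
             else tt[tt$aspect %in% c("none", a), , drop = FALSE]
      g <- tryCatch(gk_gamma(sub$confidence, sub$accuracy),
                    soameta_undefined_gamma = function(e) NULL)
      if (is.null(g)) {
        undefined <- c(undefined, paste0(pid, "/", a))
        g <- list(gamma = NA_real_, n_concordant = NA_integer_,
                  n_discordant = NA_integer_, n_pairs_used = NA_integer_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, group = tt$group[1], aspect = a,
        gamma = g$gamma, n_concordant = g$n_concordant,
        n_discordant = g$n_discordant, n_pairs_used = g$n_pairs_used,
        stringsAsFactors = FALSE)
    }
  }
  if (length(undefined)) {
    warning("gamma undefined for: ", paste(undefined, collapse = ", "),
            "; excluded from group tests", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("soa_gamma", "data.frame")
  out
}

#' Group-level tests of metacognitive performance
#'
#' Between-group Welch comparison of per-participant gamma values plus a
#' one-sample t-test of each group's gamma distribution against zero (zero
#' meaning no confidence-accuracy association). Undefined gammas are
#' excluded.
#'
#' @param gammas either a `soa_gamma` data.frame (pooled rows are used) or a
#'   numeric vector for the control group.
#' @param gammas_psychosis numeric vector for the psychosis group when
#'   `gammas` is a vector.
#' @return object of class `soa_gamma_tests`: `between` (a
#'   [group_compare()] result) and `one_sample` (per-group
#'   [one_sample_test()] results).
#' @export
gamma_group_tests <- function(gammas, gammas_psychosis = NULL) {
  if (inherits(gammas, "soa_gamma")) {
    pooled <- gammas[gammas$aspect == "pooled", , drop = FALSE]
    gc <- pooled$gamma[pooled$group == "control"]
    gp <- pooled$gamma[pooled$group == "psychosis"]
  } else {
    gc <- gammas
    gp <- gammas_psychosis
  }
  structure(list(
    between = group_compare(gc, gp),
    one_sample = list(control = one_sample_test(gc),
                      psychosis = one_sample_test(gp))
  ), class = "soa_gamma_tests")
}

#' @export
print.soa_gamma_tests <- function(x, ...) {
  cat("Metacognition (Goodman-Kruskal gamma)\n")
  cat("Between groups: ")
  print(x$between)
  for (g in names(x$one_sample)) {
    cat(sprintf("%s vs 0: ", g))
    print(x$one_sample[[g]])
  }
  invisible(x)
}
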