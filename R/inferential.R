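# Inferential stage: BIC-compared mixed-effects model ladders for the
# agency judgments (logistic) and confidence ratings (linear), and Pearson
# correlations between task measures and clinical scales.

# delta-BIC evidence grades for the lower-BIC model
bic_grade <- function(delta) {
  cut(delta, breaks = c(-Inf, 2, 6, 10, Inf),
      labels = c("weak", "positive", "strong", "very strong"), right = FALSE)
}

model_frame <- function(data, need_confidence = FALSE) {
  tr <- data$trials[!is.na(data$trials$response_identical), , drop = FALSE]
  if (need_confidence) tr <- tr[!is.na(tr$confidence), , drop = FALSE]
  df <- data.frame(
    pid = factor(tr$participant_id),
    self = as.integer(tr$response_identical),
    confidence = tr$confidence,
    magnitude = tr$magnitude_level,
    mag_c = tr$magnitude_level - 1.5,
    group = factor(tr$group, levels = c("control", "psychosis")),
    # centred group contrast: the magnitude term is then the cross-group
    # average slope and the interaction the control-minus-psychosis slope
    # difference, matching the sign conventions of the reported statistics
    group_c = ifelse(tr$group == "control", 0.5, -0.5),
    # centered aspect contrast; 0 on the shared unaltered trials, so the
    # aspect effect is identified from altered trials only
    aspect_c = ifelse(tr$aspect == "spatial", 0.5,
                      ifelse(tr$aspect == "temporal", -0.5, 0)),
    stringsAsFactors = FALSE)
  df$accuracy <- as.integer(label_accuracy(tr))
  df
}

fit_ladder <- function(df, formulas, fitter) {
  fits <- vector("list", length(formulas))
  msgs <- character(length(formulas))
  for (i in seq_along(formulas)) {
    fits[[i]] <- tryCatch(
      withCallingHandlers(
        fitter(stats::as.formula(formulas[[i]]), df),
        warning = function(w) {
          msgs[i] <<- paste(msgs[i], conditionMessage(w))
          invokeRestart("muffleWarning")
        },
        message = function(m) {
          msgs[i] <<- paste(msgs[i], trimws(conditionMessage(m)))
          invokeRestart("muffleMessage")
        }),
      error = function(e) {
        msgs[i] <<- conditionMessage(e)
        NULL
      })
  }
  if (all(vapply(fits, is.null, TRUE))) {
    stop("no model in the ladder could be fitted", call. = FALSE)
  }
  bics <- vapply(fits, function(f) if (is.null(f)) NA_real_ else stats::BIC(f),
                 numeric(1))
  singular <- vapply(fits, function(f) !is.null(f) && lme4::isSingular(f), TRUE)
  tab <- data.frame(model = names(formulas),
                    formula = unlist(formulas),
                    BIC = bics,
                    delta_bic = bics - min(bics, na.rm = TRUE),
                    converged = !is.na(bics),
                    singular_fit = singular,
                    note = trimws(msgs),
                    stringsAsFactors = FALSE)
  win <- which.min(bics)
  coefs <- as.data.frame(stats::coef(summary(fits[[win]])))
  est <- coefs[, 1]; se <- coefs[, 2]
  ci <- stats::qnorm(0.975) * se
  coefs$ci_lo <- est - ci
  coefs$ci_hi <- est + ci
  coefs$term <- rownames(coefs)
  rownames(coefs) <- NULL
  runner <- sort(tab$delta_bic[tab$model != tab$model[win]])[1]
  structure(list(table = tab[order(tab$delta_bic), ],
                 winner = names(formulas)[win],
                 winner_fit = fits[[win]],
                 coefficients = coefs,
                 evidence = as.character(bic_grade(runner))),
            class = "soa_model_comparison")
}

#' @export
print.soa_model_comparison <- function(x, digits = 3, ...) {
  cat("Mixed-model comparison (BIC)\n")
  tab <- x$table
  tab$formula <- NULL
  print(tab, row.names = FALSE, digits = digits)
  cat(sprintf("\nWinner: %s (%s evidence over runner-up)\n", x$winner, x$evidence))
  cat("Coefficients:\n")
  print(x$coefficients, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Logistic mixed-model ladder for agency judgments
#'
#' Compares, by BIC, logistic mixed-effects regressions of the trial-level
#' self-attribution response on centred alteration magnitude (ordinal levels
#' 0-3), a centred group contrast (control +1/2, psychosis -1/2), their
#' interaction, and a centred aspect contrast with its interactions. All
#' models carry per-participant random intercept, magnitude and aspect
#' slopes (diagonal). Delta-BIC values of 2-6, 6-10 and >10 are graded
#' as positive, strong and very strong evidence. The winner's coefficients
#' are reported with Wald z statistics and 95% CIs. Models that fail to
#' converge are recorded and the ladder continues.
#'
#' @param data a [soa_dataset()] (apply [apply_exclusions()] first).
#' @param nAGQ integer passed to [lme4::glmer()]; `0` uses the fast
#'   penalized-likelihood approximation (the package default for
#'   simulation-scale work), `1` the Laplace approximation.
#' @return object of class `soa_model_comparison`: BIC table with
#'   `delta_bic`, the winning model, its coefficient table and the evidence
#'   grade over the runner-up.
#' @export
fit_soa_ladder <- function(data, nAGQ = 0) {
  df <- model_frame(data)
  if (nlevels(droplevels(df$group)) < 2) stop("need both groups", call. = FALSE)
  # every candidate carries the same random structure: per-participant
  # intercept, magnitude slope and aspect slope (diagonal); without the
  # aspect slope, individual differences in temporal vs spatial sensitivity
  # masquerade as a spurious fixed aspect effect
  formulas <- list(
    magnitude = "self ~ mag_c + (1 + mag_c + aspect_c || pid)",
    magnitude_group = "self ~ mag_c + group_c + (1 + mag_c + aspect_c || pid)",
    magnitude_x_group = "self ~ mag_c * group_c + (1 + mag_c + aspect_c || pid)",
    magnitude_x_group_aspect = paste(
      "self ~ mag_c * group_c + aspect_c + aspect_c:mag_c + aspect_c:group_c",
      "+ (1 + mag_c + aspect_c || pid)"))
  fitter <- function(f, d) {
    lme4::glmer(f, data = d, family = stats::binomial(), nAGQ = nAGQ,
                control = lme4::glmerControl(calc.derivs = FALSE))
  }
  fit_ladder(df, formulas, fitter)
}

#' Linear mixed-model ladder for confidence ratings
#'
#' Compares, by BIC (maximum likelihood), linear mixed-effects regressions
#' of trial-level confidence on an orthogonal quadratic expansion of
#' alteration magnitude (confidence is high at the extremes of no alteration
#' and maximal alteration), judgment accuracy (1 = correct), group, and
#' their interactions up to the full three-way model. All models carry a
#' per-participant random intercept and random magnitude slope. The winning
#' model is refitted with Satterthwaite degrees of freedom for the
#' coefficient table.
#'
#' @param data a [soa_dataset()] (apply [apply_exclusions()] first).
#' @return object of class `soa_model_comparison`.
#' @export
fit_confidence_ladder <- function(data) {
  df <- model_frame(data, need_confidence = TRUE)
  formulas <- list(
    intercept_only = "confidence ~ 1 + (1 + mag_c | pid)",
    magnitude = "confidence ~ poly(magnitude, 2) + (1 + mag_c | pid)",
    magnitude_x_accuracy =
      "confidence ~ poly(magnitude, 2) * accuracy + (1 + mag_c | pid)",
    magnitude_x_accuracy_group =
      "confidence ~ poly(magnitude, 2) * accuracy + group_c + (1 + mag_c | pid)",
    full_three_way =
      "confidence ~ poly(magnitude, 2) * accuracy * group_c + (1 + mag_c | pid)")
  fitter <- function(f, d) {
    lmerTest::lmer(f, data = d, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE))
  }
  fit_ladder(df, formulas, fitter)
}

#' Per-participant summary of all derived measures
#'
#' Convenience join of the signal-detection ([sdt_summary()]),
#' metacognition ([gamma_summary()]) and psychometric-slope
#' ([slope_features()]) summaries with the clinical scores.
#'
#' @param data a [soa_dataset()] (apply [apply_exclusions()] first).
#' @return data.frame, one row per participant.
#' @export
participant_summary <- function(data) {
  sdt <- sdt_summary(data)
  gam <- suppressWarnings(gamma_summary(data))
  slp <- slope_features(data)
  out <- merge(sdt[sdt$aspect == "pooled",
                   c("participant_id", "group", "H", "FA", "d_prime", "criterion_c")],
               gam[gam$aspect == "pooled", c("participant_id", "gamma")],
               by = "participant_id")
  out <- merge(out, slp[c("participant_id", "slope_temporal", "slope_spatial")],
               by = "participant_id")
  merge(out, data$participants[setdiff(PARTICIPANT_COLUMNS, "group")],
        by = "participant_id")
}

#' Pearson correlations between task measures and clinical scales
#'
#' Correlates per-participant sensitivity (d'), bias (criterion) and
#' metacognition (gamma) with the group-appropriate clinical scales: PANSS
#' subscales for the psychosis group, SPQ-B subscales for controls.
#' P-values are two-sided and uncorrected; a Holm-adjusted column is added
#' for convenience. Cells with a constant vector or fewer than 3 complete
#' pairs are flagged with `NA`.
#'
#' @param data a [soa_dataset()] with clinical scores (apply
#'   [apply_exclusions()] first).
#' @param measures which task measures to correlate.
#' @return data.frame of class `soa_correlations`: `group`, `scale`,
#'   `measure`, `r`, `p`, `n`, `p_holm`.
#' @export
clinical_correlations <- function(data,
                                  measures = c("d_prime", "criterion_c", "gamma")) {
  ps <- participant_summary(data)
  scales <- list(
    control = c("spqb_cogper", "spqb_inter", "spqb_disorg", "spqb_total"),
    psychosis = c("panss_positive", "panss_negative", "panss_general",
                  "panss_total"))
  rows <- list()
  for (g in names(scales)) {
    sub <- ps[ps$group == g, , drop = FALSE]
    for (sc in scales[[g]]) {
      for (m in measures) {
        ok <- stats::complete.cases(sub[[sc]], sub[[m]])
        n <- sum(ok)
        if (n < 3 || stats::sd(sub[[sc]][ok]) == 0 || stats::sd(sub[[m]][ok]) == 0) {
          r <- NA_real_; p <- NA_real_
        } else {
          ct <- stats::cor.test(sub[[sc]][ok], sub[[m]][ok], method = "pearson")
          r <- unname(ct$estimate); p <- ct$p.value
        }
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, scale = sc, measure = m, r = r, p = p, n = n,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_holm <- NA_real_
  out$p_holm[!is.na(out$p)] <- stats::p.adjust(out$p[!is.na(out$p)], "holm")
  class(out) <- c("soa_correlations", "data.frame")
  out
}

#' @export
print.soa_correlations <- function(x, digits = 2, ...) {
  cat("Correlations between task measures and clinical scales (Pearson r)\n")
  wide <- stats::reshape(as.data.frame(x)[c("group", "scale", "measure", "r")],
                         idvar = c("group", "scale"), timevar = "measure",
                         direction = "wide")
  names(wide) <- sub("^r\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = digits)
  cat("(two-sided p-values uncorrected; see $p and $p_holm)\n")
  invisible(x)
}
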