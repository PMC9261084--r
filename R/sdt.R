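# Signal-detection analysis of agency judgments: hit / false-alarm rates
# (signal = unaltered movement, "identical" = yes), d-prime and criterion,
# per-participant summaries and Welch group comparisons.

#' Hit and false-alarm rates for one participant
#'
#' Signal trials are the unaltered movements; a hit is an "identical"
#' response on an unaltered trial and a false alarm is an "identical"
#' response on an altered trial, pooling both aspects and all alteration
#' magnitudes. Rates are corrected by the log-linear rule
#' `(count + 0.5) / (n + 1)`, applied uniformly to every participant, so
#' they lie strictly inside (0, 1).
#'
#' @param trials one participant's retained trials (non-missing responses).
#' @return list with `H`, `FA`, `n_signal`, `n_noise`.
#' @export
compute_rates <- function(trials) {
  resp <- trials$response_identical
  if (anyNA(resp)) stop("trials with missing responses must be excluded first",
                        call. = FALSE)
  altered <- is_altered(trials)
  n_signal <- sum(!altered)
  n_noise <- sum(altered)
  if (n_signal == 0 || n_noise == 0) {
    stop("participant needs at least one unaltered and one altered trial",
         call. = FALSE)
  }
  list(H = (sum(resp & !altered) + 0.5) / (n_signal + 1),
       FA = (sum(resp & altered) + 0.5) / (n_noise + 1),
       n_signal = n_signal, n_noise = n_noise)
}

#' Sensitivity and bias from hit and false-alarm rates
#'
#' Equal-variance signal detection: `d' = z(H) - z(FA)` and
#' `c = -(z(H) + z(FA)) / 2`, `z` the standard-normal quantile. Under the
#' signal = unaltered convention a negative criterion means a bias toward
#' claiming agency ("identical") regardless of the evidence.
#'
#' @param H,FA rates strictly inside (0, 1); apply [compute_rates()]'s
#'   correction first if counts are extreme.
#' @return list with `d_prime` and `criterion_c`.
#' @export
dprime_criterion <- function(H, FA) {
  if (any(c(H, FA) <= 0) || any(c(H, FA) >= 1)) {
    stop("H and FA must lie strictly in (0, 1); apply the log-linear ",
         "correction first", call. = FALSE)
  }
  zH <- stats::qnorm(H)
  zFA <- stats::qnorm(FA)
  list(d_prime = zH - zFA, criterion_c = -(zH + zFA) / 2)
}

#' Per-participant signal-detection summary
#'
#' Computes corrected hit / false-alarm rates, d' and criterion for every
#' participant, pooled across aspects and magnitudes (the study's statistic).
#' With `by_aspect = TRUE` altered trials are restricted to one aspect at a
#' time while the shared unaltered pool supplies the signal trials.
#'
#' @param data a [soa_dataset()] (apply [apply_exclusions()] first).
#' @param by_aspect logical; additionally return per-aspect rows.
#' @return data.frame of class `soa_sdt` with one row per participant (and
#'   per aspect if requested): `participant_id`, `group`, `aspect`,
#'   `n_signal`, `n_noise`, `H`, `FA`, `d_prime`, `criterion_c`.
#' @export
sdt_summary <- function(data, by_aspect = FALSE) {
  stopifnot(inherits(data, "soa_dataset"))
  trials <- data$trials[!is.na(data$trials$response_identical), , drop = FALSE]
  aspects <- if (by_aspect) c("pooled", "temporal", "spatial") else "pooled"
  rows <- list()
  for (pid in unique(trials$participant_id)) {
    tt <- trials[trials$participant_id == pid, , drop = FALSE]
    for (a in aspects) {
      sub <- if (a == "pooled") tt
             else tt[tt$aspect %in% c("none", a), , drop = FALSE]
      r <- compute_rates(sub)
      s <- dprime_criterion(r$H, r$FA)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, group = tt$group[1], aspect = a,
        n_signal = r$n_signal, n_noise = r$n_noise, H = r$H, FA = r$FA,
        d_prime = s$d_prime, criterion_c = s$criterion_c,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("soa_sdt", "data.frame")
  out
}

#' Welch two-sample comparison with Cohen's d
#'
#' Unequal-variance (Welch) t-test with Welch-Satterthwaite degrees of
#' freedom and a pooled-SD Cohen's d, the study's group-difference statistic
#' for d', criterion and gamma.
#'
#' @param values_control,values_psychosis numeric vectors (NA dropped).
#' @param labels group labels used in printing.
#' @return object of class `soa_group_test`: `t`, `df`, `p`, `cohens_d`,
#'   `group_means`, `group_ns`.
#' @export
group_compare <- function(values_control, values_psychosis,
                          labels = c("control", "psychosis")) {
  x <- values_control[!is.na(values_control)]
  y <- values_psychosis[!is.na(values_psychosis)]
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least two values per group", call. = FALSE)
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) != mean(y)) stop("zero variance in both groups", call. = FALSE)
    tt <- list(statistic = c(t = 0), parameter = c(df = length(x) + length(y) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
  }
  sp <- sqrt(((length(x) - 1) * vx + (length(y) - 1) * vy) /
               (length(x) + length(y) - 2))
  d <- if (sp > 0) (mean(x) - mean(y)) / sp else 0
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohens_d = d,
                 group_means = stats::setNames(c(mean(x), mean(y)), labels),
                 group_ns = stats::setNames(c(length(x), length(y)), labels)),
            class = "soa_group_test")
}

#' One-sample t-test against zero with Cohen's d
#'
#' @param values numeric vector (NA dropped).
#' @param mu null value (default 0).
#' @return object of class `soa_group_test` with `group_means` holding the
#'   sample mean.
#' @export
one_sample_test <- function(values, mu = 0) {
  x <- values[!is.na(values)]
  if (length(x) < 2) stop("need at least two values", call. = FALSE)
  tt <- stats::t.test(x, mu = mu)
  d <- if (stats::sd(x) > 0) (mean(x) - mu) / stats::sd(x) else 0
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohens_d = d,
                 group_means = c(mean = mean(x)),
                 group_ns = c(n = length(x))),
            class = "soa_group_test")
}

#' @export
print.soa_group_test <- function(x, ...) {
  cat(sprintf("t(%.1f) = %.3f, p = %.4g, Cohen's d = %.2f\n",
              x$df, x$t, x$p, x$cohens_d))
  means <- paste(sprintf("%s = %.3f (n = %d)", names(x$group_means),
                         x$group_means, x$group_ns), collapse = ", ")
  cat(" ", means, "\n")
  invisible(x)
}
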