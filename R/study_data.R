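# Canonical trial-level data model for the virtual-hand agency task:
# construction and validation of datasets, CSV readers/writers, the
# pre-registered trial exclusion step and accuracy labelling.

TRIAL_COLUMNS <- c(
  "participant_id", "group", "block", "trial_index", "aspect",
  "magnitude_level", "magnitude_value", "response_identical", "confidence",
  "excluded", "exclusion_reason"
)

PARTICIPANT_COLUMNS <- c(
  "participant_id", "group",
  "panss_positive", "panss_negative", "panss_general", "panss_total",
  "spqb_cogper", "spqb_inter", "spqb_disorg", "spqb_total"
)

GROUPS <- c("control", "psychosis")
ASPECTS <- c("temporal", "spatial", "none")
EXCLUSION_REASONS <- c("none", "no_movement", "camera_malfunction", "no_response")

# Physical alteration magnitudes per ordinal level 1..3
MAGNITUDE_VALUES <- list(temporal = c(100, 200, 300), spatial = c(6, 10, 14))

#' Construct a study dataset
#'
#' Bundles a validated trial table and a participant table (with clinical
#' scores) into a single object used by every analysis stage. Trials are one
#' row per experimental trial; participants are one row per person, carrying
#' PANSS subscales for the psychosis group and SPQ-B subscales for controls.
#'
#' @param trials data.frame with columns `participant_id`, `group`, `block`,
#'   `trial_index`, `aspect`, `magnitude_level`, `magnitude_value`,
#'   `response_identical`, `confidence`, `excluded`, `exclusion_reason`.
#' @param participants data.frame with `participant_id`, `group` and clinical
#'   score columns (`panss_*`, `spqb_*`); if `NULL`, inferred from `trials`
#'   with all clinical scores missing.
#' @param provenance named list of free-form metadata (seeds, parameter
#'   digests) carried along with the data.
#' @param validate logical; run full invariant validation (default `TRUE`).
#' @return An object of class `soa_dataset`: a list with elements `trials`,
#'   `participants` and `provenance`.
#' @seealso [read_trials()], [apply_exclusions()], [build_cohort()]
#' @export
soa_dataset <- function(trials, participants = NULL, provenance = list(),
                        validate = TRUE) {
  trials <- as.data.frame(trials)
  if (is.null(participants)) {
    idx <- !duplicated(trials$participant_id)
    participants <- data.frame(
      participant_id = trials$participant_id[idx],
      group = trials$group[idx],
      stringsAsFactors = FALSE
    )
  }
  participants <- as.data.frame(participants)
  for (col in setdiff(PARTICIPANT_COLUMNS, names(participants))) {
    participants[[col]] <- NA_real_
  }
  participants <- participants[PARTICIPANT_COLUMNS]
  obj <- structure(
    list(trials = trials, participants = participants, provenance = provenance),
    class = "soa_dataset"
  )
  if (validate) validate_dataset(obj)
  obj
}

#' @export
print.soa_dataset <- function(x, ...) {
  n_trials <- nrow(x$trials)
  n_part <- nrow(x$participants)
  tab <- table(x$participants$group)
  cat("Sense-of-agency study dataset\n")
  cat(sprintf("  %d trials, %d participants (%s)\n", n_trials, n_part,
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  n_excl <- sum(x$trials$excluded)
  cat(sprintf("  excluded trials: %d (%.1f%%)\n", n_excl,
              if (n_trials > 0) 100 * n_excl / n_trials else 0))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.soa_dataset <- function(object, ...) {
  print(object)
  cat("\nTrials per participant:\n")
  print(summary(as.integer(table(object$trials$participant_id))))
  invisible(object)
}

is_altered <- function(trials) trials$magnitude_level > 0L

fmt_rows <- function(rows) {
  if (length(rows) > 12) {
    paste0(paste(utils::head(rows, 12), collapse = ", "), ", ... (",
           length(rows), " rows)")
  } else {
    paste(rows, collapse = ", ")
  }
}

#' Validate a trial table against the task schema
#'
#' Checks column presence, enum membership, value ranges and the structural
#' invariants linking alteration level, aspect and physical magnitude
#' (temporal levels are 100/200/300 ms delays, spatial levels 6/10/14 degree
#' deviations, level 0 is the unaltered condition with aspect `"none"`).
#' Violations raise an error naming the offending rows.
#'
#' @param trials data.frame of trials (see [soa_dataset()]).
#' @return `trials`, invisibly, if valid.
#' @export
validate_trials <- function(trials) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows)) problems <<- c(problems, paste0(what, " at row(s) ", fmt_rows(rows)))
  }
  bad(!trials$group %in% GROUPS, "unknown group")
  bad(!trials$aspect %in% ASPECTS, "unknown aspect")
  bad(!trials$exclusion_reason %in% EXCLUSION_REASONS, "unknown exclusion_reason")
  bad(is.na(trials$block) | trials$block < 1 | trials$block > 5, "block outside 1..5")
  bad(is.na(trials$trial_index) | trials$trial_index < 1, "trial_index < 1")
  bad(is.na(trials$magnitude_level) | trials$magnitude_level < 0 |
        trials$magnitude_level > 3, "magnitude_level outside 0..3")
  bad(!is.na(trials$confidence) &
        (trials$confidence < -3 | trials$confidence > 3),
      "confidence outside [-3, 3]")
  # level 0 <=> aspect none <=> magnitude_value 0 (the unaltered condition)
  lvl0 <- trials$magnitude_level == 0L
  bad(lvl0 & (trials$aspect != "none" | trials$magnitude_value != 0),
      "unaltered trial with nonzero aspect/magnitude")
  bad(!lvl0 & trials$aspect == "none", "altered trial with aspect 'none'")
  for (a in c("temporal", "spatial")) {
    sel <- !lvl0 & trials$aspect == a
    expect_val <- MAGNITUDE_VALUES[[a]][trials$magnitude_level[sel]]
    bad_rows <- which(sel)[!is.na(expect_val) & trials$magnitude_value[sel] != expect_val]
    if (length(bad_rows)) {
      problems <- c(problems, paste0("magnitude_value inconsistent with ", a,
                                     " level at row(s) ", fmt_rows(bad_rows)))
    }
  }
  bad(xor(trials$excluded, trials$exclusion_reason != "none"),
      "excluded flag inconsistent with exclusion_reason")
  if (length(problems)) {
    stop("invalid trial table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(trials)
}

validate_dataset <- function(data) {
  stopifnot(inherits(data, "soa_dataset"))
  validate_trials(data$trials)
  orphan <- setdiff(unique(data$trials$participant_id),
                    data$participants$participant_id)
  if (length(orphan)) {
    stop("trials reference participant(s) absent from the participant table: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  dup <- vapply(split(data$trials$trial_index, data$trials$participant_id),
                anyDuplicated, 0L)
  if (any(dup > 0)) {
    stop("duplicated trial_index within participant(s): ",
         paste(names(dup)[dup > 0], collapse = ", "), call. = FALSE)
  }
  invisible(data)
}

#' Read a trial table (and optionally participants) from CSV
#'
#' Reads the flat trial-level CSV schema: header row, booleans written as
#' `true`/`false`, missing values as empty cells. Rows are validated against
#' the task invariants; violations are reported with row numbers.
#'
#' @param path path to the trial CSV file.
#' @param participants optional path to a participant/clinical-scores CSV.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return A [soa_dataset()].
#' @export
read_trials <- function(path, participants = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("trial file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_bool <- function(x, col) {
    out <- rep(NA, length(x))
    out[!is.na(x) & tolower(x) == "true"] <- TRUE
    out[!is.na(x) & tolower(x) == "false"] <- FALSE
    bad <- which(!is.na(x) & !tolower(x) %in% c("true", "false"))
    if (length(bad)) stop("column '", col, "' has non-boolean value(s) at row(s) ",
                          fmt_rows(bad), call. = FALSE)
    as.logical(out)
  }
  trials <- data.frame(
    participant_id = raw$participant_id,
    group = raw$group,
    block = as.integer(raw$block),
    trial_index = as.integer(raw$trial_index),
    aspect = raw$aspect,
    magnitude_level = as.integer(raw$magnitude_level),
    magnitude_value = as.numeric(raw$magnitude_value),
    response_identical = parse_bool(raw$response_identical, "response_identical"),
    confidence = as.numeric(raw$confidence),
    excluded = parse_bool(raw$excluded, "excluded"),
    exclusion_reason = raw$exclusion_reason,
    stringsAsFactors = FALSE
  )
  ptab <- NULL
  if (!is.null(participants)) ptab <- read_participants(participants)
  soa_dataset(trials, ptab, provenance = list(source = path))
}

#' Read a participant table with clinical scores
#'
#' @param path CSV with `participant_id`, `group` and clinical score columns
#'   (`panss_positive`, `panss_negative`, `panss_general`, `panss_total`,
#'   `spqb_cogper`, `spqb_inter`, `spqb_disorg`, `spqb_total`).
#' @return data.frame in canonical column order.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (!all(c("participant_id", "group") %in% names(p))) {
    stop("participant file must have participant_id and group columns",
         call. = FALSE)
  }
  for (col in setdiff(PARTICIPANT_COLUMNS, names(p))) p[[col]] <- NA_real_
  p[PARTICIPANT_COLUMNS]
}

#' Write a dataset's trial (and participant) tables to CSV
#'
#' Inverse of [read_trials()]: booleans as `true`/`false`, missing values as
#' empty cells, canonical column order. Reading the written file back yields
#' a field-identical dataset.
#'
#' @param data a [soa_dataset()].
#' @param path output path for the trial CSV.
#' @param participants optional output path for the participant CSV.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path, participants = NULL) {
  stopifnot(inherits(data, "soa_dataset"))
  out <- data$trials[TRIAL_COLUMNS]
  for (col in c("response_identical", "excluded")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         ifelse(out[[col]], "true", "false"))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  if (!is.null(participants)) {
    utils::write.csv(data$participants, participants, row.names = FALSE,
                     na = "", quote = FALSE)
  }
  invisible(path)
}

#' Apply the pre-registered trial exclusions
#'
#' Removes trials flagged for exclusion (no movement made, camera
#' malfunction, no response given) and reports per-group exclusion
#' fractions. Optionally drops whole participants named on an explicit
#' exclusion list (participant-level criteria live in the study
#' pre-registration, so they are supplied as a list rather than recomputed).
#' The operation is idempotent.
#'
#' @param data a [soa_dataset()].
#' @param exclude_participants character vector of participant ids to drop
#'   entirely (default none).
#' @return list with `data` (the filtered dataset) and `report` (class
#'   `soa_exclusion_report`: per-group totals, excluded counts, fractions
#'   and a reason breakdown).
#' @export
apply_exclusions <- function(data, exclude_participants = character(0)) {
  stopifnot(inherits(data, "soa_dataset"))
  trials <- data$trials
  participants <- data$participants
  if (length(exclude_participants)) {
    trials <- trials[!trials$participant_id %in% exclude_participants, , drop = FALSE]
    participants <- participants[
      !participants$participant_id %in% exclude_participants, , drop = FALSE]
  }
  report <- lapply(GROUPS, function(g) {
    sub <- trials[trials$group == g, , drop = FALSE]
    reasons <- table(factor(sub$exclusion_reason[sub$excluded],
                            levels = setdiff(EXCLUSION_REASONS, "none")))
    list(n_total = nrow(sub),
         n_excluded = sum(sub$excluded),
         fraction = if (nrow(sub) > 0) sum(sub$excluded) / nrow(sub) else NA_real_,
         by_reason = as.list(reasons))
  })
  names(report) <- GROUPS
  kept <- trials[!trials$excluded, , drop = FALSE]
  if (nrow(kept) == 0) warning("all trials excluded; empty dataset returned")
  out <- soa_dataset(kept, participants, provenance = data$provenance,
                     validate = FALSE)
  structure(list(data = out,
                 report = structure(report, class = "soa_exclusion_report")),
            class = "soa_exclusions")
}

#' @export
print.soa_exclusion_report <- function(x, ...) {
  cat("Trial exclusions by group\n")
  for (g in names(x)) {
    cat(sprintf("  %-9s %d / %d trials excluded (%.1f%%)\n", g,
                x[[g]]$n_excluded, x[[g]]$n_total, 100 * x[[g]]$fraction))
  }
  invisible(x)
}

#' Label each trial's agency judgment as correct or incorrect
#'
#' A judgment is correct when the participant answered "identical" on an
#' unaltered trial, or "not identical" on an altered trial. Accuracy is the
#' basis of the type-2 (metacognition) analyses.
#'
#' @param trials data.frame of retained trials with non-missing
#'   `response_identical`.
#' @return logical vector, one element per row of `trials`.
#' @export
label_accuracy <- function(trials) {
  resp <- trials$response_identical
  if (anyNA(resp)) {
    stop("response_identical is missing for ", sum(is.na(resp)),
         " trial(s); such trials should have been excluded", call. = FALSE)
  }
  altered <- is_altered(trials)
  (resp & !altered) | (!resp & altered)
}
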