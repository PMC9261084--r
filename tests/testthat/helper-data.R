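# Shared fixtures, all generated in code.

# A minimal hand-built trial table for one participant: n0 unaltered trials
# plus n_per trials at each aspect x level, in canonical schema.
make_trials <- function(participant_id = "C01", group = "control",
                        n0 = 4, n_per = 2,
                        response = TRUE, confidence = 0) {
  rows <- list()
  add <- function(aspect, level, k) {
    mv <- if (level == 0) 0 else soameta:::MAGNITUDE_VALUES[[aspect]][level]
    data.frame(aspect = if (level == 0) "none" else aspect,
               magnitude_level = level, magnitude_value = mv,
               n = k, stringsAsFactors = FALSE)
  }
  cond <- rbind(add("none", 0, n0),
                do.call(rbind, lapply(1:3, function(l) add("temporal", l, n_per))),
                do.call(rbind, lapply(1:3, function(l) add("spatial", l, n_per))))
  cond <- cond[rep(seq_len(nrow(cond)), cond$n), c("aspect", "magnitude_level",
                                                   "magnitude_value")]
  n <- nrow(cond)
  data.frame(
    participant_id = participant_id, group = group,
    block = rep_len(1:5, n), trial_index = seq_len(n),
    aspect = cond$aspect, magnitude_level = cond$magnitude_level,
    magnitude_value = cond$magnitude_value,
    response_identical = rep_len(response, n),
    confidence = rep_len(confidence, n),
    excluded = FALSE, exclusion_reason = "none",
    stringsAsFactors = FALSE, row.names = NULL)
}

# Memoized small default cohort shared within a test file.
local({
  cache <- new.env(parent = emptyenv())
  default_cohort <<- function(seed = 1) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- apply_exclusions(build_cohort(seed = seed))$data
    }
    cache[[key]]
  }
})

# Generative parameters scaled down to n participants per group.
small_params <- function(n_control = 10, n_psychosis = n_control,
                         modify = identity) {
  cfg <- jsonlite::read_json(
    system.file("extdata", "default_generative_params.json",
                package = "soameta"), simplifyVector = TRUE)
  cfg$control$n_participants <- n_control
  cfg$psychosis$n_participants <- n_psychosis
  cfg <- modify(cfg)
  gen_params(cfg$control, cfg$psychosis)
}

# Brute-force Goodman-Kruskal gamma: literal enumeration of all unordered
# pairs, comparing both variables generically. Independent of the package's
# split-by-accuracy implementation.
bruteforce_gamma <- function(confidence, accuracy) {
  n <- length(confidence)
  C <- 0L; D <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- confidence[i] - confidence[j]
      dy <- accuracy[i] - accuracy[j]
      if (dx != 0 && dy != 0) {
        if (sign(dx) == sign(dy)) C <- C + 1L else D <- D + 1L
      }
    }
  }
  if (C + D == 0) return(NULL)
  list(gamma = (C - D) / (C + D), n_concordant = C, n_discordant = D)
}
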