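session_csv_columns <- c("participant_id", "group", "index", "onset_s",
                         "orientation_deg", "contrast", "duration_s", "role",
                         "test_type", "response")

#' Write a cohort to a session CSV and sidecar files
#'
#' Writes one row per stimulus event (all participants in a single
#' `sessions.csv`, orientations and probabilities to 6 significant digits),
#' the participant profiles to `profiles.json`, and a small `manifest.json`
#' recording the seed, a content hash of the session file, the package
#' version and elapsed time.
#'
#' @param cohort A cohort from [generate_cohort()] (or the same structure).
#' @param dir Output directory (created if missing).
#' @param seed Optional seed to record in the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_sessions <- function(cohort, dir, seed = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    ev <- s$events
    data.frame(
      participant_id = s$profile$participant_id, group = s$profile$group,
      index = ev$index, onset_s = signif(ev$onset, 6),
      orientation_deg = signif(ev$orientation, 6), contrast = ev$contrast,
      duration_s = ev$duration, role = ev$role, test_type = ev$test_type,
      response = ev$response, stringsAsFactors = FALSE
    )
  })
  csv_path <- file.path(dir, "sessions.csv")
  write.csv(do.call(rbind, rows), csv_path, row.names = FALSE, na = "")
  profiles <- lapply(cohort, function(s) unclass(s$profile))
  names(profiles) <- vapply(cohort, function(s) s$profile$participant_id, "")
  jsonlite::write_json(profiles, file.path(dir, "profiles.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(packageVersion("serialdep")),
    seed = seed, sessions_md5 = unname(tools::md5sum(csv_path)),
    n_participants = length(cohort),
    files = c("sessions.csv", "profiles.json"),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort from a session CSV and profile sidecar
#'
#' Validates the session dialect: required columns, per-participant event
#' ordering with strictly increasing onsets, responses only on test rows and
#' test types only on tests. An empty file yields an empty cohort with a
#' warning.
#'
#' @param path Directory containing `sessions.csv` and `profiles.json`, or a
#'   path to the CSV itself (with the sidecar alongside).
#' @return A cohort: list of `list(profile, events)`, class `cohort`.
#' @export
read_sessions <- function(path) {
  csv_path <- if (dir.exists(path)) file.path(path, "sessions.csv") else path
  prof_path <- file.path(dirname(csv_path), "profiles.json")
  if (!file.exists(csv_path)) stop("no session file at ", csv_path)
  df <- read.csv(csv_path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty session file: returning empty cohort")
    return(structure(list(), class = "cohort"))
  }
  missing <- setdiff(session_csv_columns, names(df))
  if (length(missing))
    stop("session CSV is missing columns: ", paste(missing, collapse = ", "))
  bad <- which(df$role == "adaptor" & !is.na(df$response))
  if (length(bad))
    stop("response on adaptor row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- which((df$role == "test") != (df$test_type != "none"))
  if (length(bad))
    stop("role/test_type mismatch on row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  profiles <- jsonlite::fromJSON(prof_path, simplifyVector = TRUE)
  cohort <- lapply(unique(df$participant_id), function(id) {
    sub <- df[df$participant_id == id, ]
    sub <- sub[order(sub$index), ]
    if (is.unsorted(sub$onset_s, strictly = TRUE))
      stop("non-monotone onsets for participant ", id)
    pr <- profiles[[id]]
    if (is.null(pr)) stop("no profile for participant ", id)
    prof <- participant_profile(
      participant_id = pr$participant_id, group = pr$group, c0 = pr$c0,
      k_high = pr$k_high, k_low = pr$k_low, mu_ref = pr$mu_ref,
      kappa_ref = pr$kappa_ref, low_contrast = pr$low_contrast,
      high_contrast = pr$high_contrast
    )
    events <- data.frame(
      index = sub$index, onset = sub$onset_s,
      orientation = sub$orientation_deg, contrast = sub$contrast,
      duration = sub$duration_s, role = sub$role, test_type = sub$test_type,
      response = sub$response, stringsAsFactors = FALSE
    )
    list(profile = prof, events = events)
  })
  structure(cohort, class = "cohort")
}

#' Read a design/cohort configuration from JSON
#'
#' The config has a `design` block (any [session_design()] fields), a
#' `cohort` block (`n_per_group`), a `ranges` block (sampling-range
#' overrides) and a `seed`.
#'
#' @param path Path to a JSON file.
#' @return List with `design` (a `session_design`), `n_per_group`, `ranges`,
#'   `seed`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  design <- do.call(session_design, as.list(cfg$design))
  n_per_group <- if (is.null(cfg$cohort$n_per_group))
    c(A = 8L, B = 8L, C = 8L) else unlist(cfg$cohort$n_per_group)
  list(design = design, n_per_group = n_per_group,
       ranges = if (is.null(cfg$ranges)) list() else as.list(cfg$ranges),
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

#' Write a design/cohort configuration to JSON
#'
#' @param config List as returned by [read_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  out <- list(design = unclass(config$design),
              cohort = list(n_per_group = as.list(config$n_per_group)),
              ranges = config$ranges, seed = config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# minimal deterministic hand-built stream used by the toy fixtures
toy_stream <- function(profile, orientations, test_at, design = session_design()) {
  n <- length(orientations)
  is_test <- seq_len(n) %in% test_at
  step <- design$duration + design$isi + ifelse(is_test, design$response_pause, 0)
  tt <- rep("none", n)
  tt[test_at] <- ifelse(orientations[test_at] >= profile$c0, "HC+", "HC-")
  data.frame(
    index = 0:(n - 1L), onset = c(0, cumsum(step)[-n]),
    orientation = orientations, contrast = profile$high_contrast,
    duration = design$duration, role = ifelse(is_test, "test", "adaptor"),
    test_type = tt, response = NA_integer_, stringsAsFactors = FALSE
  )
}

#' Deterministic test fixtures
#'
#' Small scenarios with precomputed expected values, for test suites:
#' `"toy-20-trials"` (20 hand-built events, 4 tests, responses filled),
#' `"groupB-mini"` / `"groupC-mini"` (one 240-stimulus session of the given
#' group), and `"null-model"` (tests at the baseline midpoint, where the
#' zero-weight linear model predicts exactly 0.5, so the NLL equals
#' `R ln 2`). Identical name and seed give identical fixtures.
#'
#' @param name Scenario label.
#' @param seed Integer seed.
#' @return List with `cohort` (list of `list(profile, events)`) and
#'   `expected` (named list of oracle values for the scenario).
#' @export
make_fixture <- function(name = c("toy-20-trials", "groupB-mini",
                                  "groupC-mini", "null-model"), seed = 1L) {
  name <- match.arg(name)
  mini <- session_design(n_stimuli = 240L)
  if (name %in% c("groupB-mini", "groupC-mini")) {
    grp <- if (name == "groupB-mini") "B" else "C"
    prof <- sample_participant(grp, mini, seed = seed)
    ev <- generate_session(prof, mini, seed = seed + 1L)
    return(list(cohort = list(list(profile = prof, events = ev)),
                expected = list(n_events = 240L, n_tests = 40L)))
  }
  prof <- participant_profile("T01", "A", c0 = 0, k_high = 0.8, k_low = 0.4,
                              mu_ref = 0, kappa_ref = 50)
  if (name == "toy-20-trials") {
    ori <- withr::with_seed(seed, round(rnorm(20, 0, 5), 2))
    test_at <- c(5L, 10L, 15L, 20L)
    ori[test_at] <- c(3, -3, 3, -3)
    ev <- toy_stream(prof, ori, test_at)
    ev <- simulate_responses(ev, sequential_predict(ev, prof,
                                                    default_linear_params()),
                             seed = seed + 1L)
    return(list(cohort = list(list(profile = prof, events = ev)),
                expected = list(n_events = 20L, n_tests = 4L)))
  }
  # null-model: all tests exactly at c0; zero-weight linear NLL = R ln 2
  ori <- withr::with_seed(seed, round(rnorm(24, 0, 3), 2))
  test_at <- c(6L, 12L, 18L, 24L)
  ori[test_at] <- prof$c0
  ev <- toy_stream(prof, ori, test_at)
  ev$response[test_at] <- withr::with_seed(seed + 1L, rbinom(4, 1, 0.5))
  list(cohort = list(list(profile = prof, events = ev)),
       expected = list(n_events = 24L, n_tests = 4L,
                       null_nll = 4 * log(2)))
}
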