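#' Measure specifications for the emotionality score
#'
#' Defines which behavioral measures enter the composite score, the test
#' each belongs to, and the sign applied so that a larger signed z-score
#' always means greater emotionality: anxio-depressive behavior shows as
#' *less* open-arm activity in the elevated plus maze, a *longer* latency to
#' feed in novelty-suppressed feeding, and *less* grooming in the splash
#' test. Home-cage food consumption is an appetite control, not a score
#' component, and is deliberately absent.
#'
#' @return Tibble with columns `test`, `measure`, `direction` (+1 or -1).
#' @export
measure_specs <- function() {
  tibble(
    test      = c("EPM", "EPM", "NSF", "ST"),
    measure   = c("open_arm_time", "open_arm_entries",
                  "latency_to_feed", "grooming_duration"),
    direction = c(-1, -1, 1, -1)
  )
}

#' Control-group reference statistics for z-scoring
#'
#' Computes, for each measure, the mean and sample (n-1) standard deviation
#' of the designated control group at one session. These are the mu and
#' sigma of the z transformation; they are always estimated from control
#' animals of the same session only, so each behavioral round is
#' standardized internally.
#'
#' @param data Long behavioral table with columns `animal`, `group`,
#'   `session`, `measure`, `value`.
#' @param control_group Label of the control arm (the vehicle group).
#' @param session Session label the reference belongs to.
#' @param specs Measure table, see [measure_specs()].
#' @return Tibble `measure`, `mu`, `sigma`, `n_control`, `session`.
#' @export
reference_stats <- function(data, control_group, session,
                            specs = measure_specs()) {
  check_columns(data, c("animal", "group", "session", "measure", "value"),
                "behavior data")
  if (!control_group %in% data$group) {
    stop_schema(sprintf("control group '%s' not present in data",
                        control_group))
  }
  ses <- session
  ref <- data %>%
    filter(.data$group == control_group, .data$session == ses,
           .data$measure %in% specs$measure, !is.na(.data$value)) %>%
    group_by(.data$measure) %>%
    summarise(mu = mean(.data$value), sigma = sd(.data$value),
              n_control = n_distinct(.data$animal), .groups = "drop")
  missing <- setdiff(specs$measure, ref$measure)
  if (length(missing) > 0) {
    stop_stat(sprintf("control group has no values for measure(s): %s",
                      paste(missing, collapse = ", ")))
  }
  if (any(ref$n_control < 2)) {
    stop_stat(sprintf(
      "control group needs >= 2 animals per measure (violated for: %s)",
      paste(ref$measure[ref$n_control < 2], collapse = ", ")
    ))
  }
  degen <- ref$measure[!is.na(ref$sigma) & ref$sigma == 0]
  if (length(degen) > 0) {
    stop_stat(sprintf(
      "degenerate reference: zero control-group variance for measure(s): %s",
      paste(degen, collapse = ", ")
    ))
  }
  ref$session <- ses
  ref
}

#' Signed z-score of an observation against a control reference
#'
#' `direction * (x - mu) / sigma`: how many control-group standard
#' deviations an observation lies from the control mean, signed so that
#' positive always means more anxio-depressive. Missing observations
#' propagate as `NA`, never as zero.
#'
#' @param x Observed value(s).
#' @param mu,sigma Control-group mean and SD (sigma > 0).
#' @param direction +1 or -1, see [measure_specs()].
#' @return Numeric vector of signed z-scores.
#' @export
#' @examples
#' zscore(300, mu = 180, sigma = 60, direction = 1) # latency 2 SD above: +2
zscore <- function(x, mu, sigma, direction = 1) {
  if (any(!is.na(sigma) & sigma <= 0)) {
    stop_stat("`sigma` must be > 0 for z-scoring")
  }
  if (!all(direction %in% c(-1, 1))) {
    stop_config("`direction` must be +1 or -1")
  }
  direction * (x - mu) / sigma
}

#' Composite behavioral emotionality scores
#'
#' For every animal and session, z-scores each measure against the
#' control-group reference of that session, averages the signed z-scores
#' within each test, then averages the per-test values across tests so the
#' three assays carry equal weight regardless of how many measures each
#' contributes. Right-censored feeding latencies enter at the cap value
#' (their rows keep `censored = TRUE` upstream); missing single measures are
#' dropped from the within-test mean, and an animal missing an entire test
#' gets a composite over the remaining tests plus a warning.
#'
#' @inheritParams reference_stats
#' @param sessions Sessions to score (default: all present).
#' @return Tibble with one row per animal x session: `animal`, `group`,
#'   `session`, one `z_<test>` column per test, and `emotionality` (the
#'   composite mean of available per-test z values).
#' @export
emotionality_scores <- function(data, specs = measure_specs(),
                                control_group = "Veh/Veh",
                                sessions = NULL) {
  check_columns(data, c("animal", "group", "session", "measure", "value"),
                "behavior data")
  if (is.null(sessions)) sessions <- unique(data$session)

  scored <- purrr::map_dfr(sessions, function(ses) {
    ref <- reference_stats(data, control_group, ses, specs)
    data %>%
      filter(.data$session == ses, .data$measure %in% specs$measure) %>%
      select(-dplyr::any_of("test")) %>%
      inner_join(specs, by = "measure") %>%
      inner_join(ref[, c("measure", "mu", "sigma")], by = "measure") %>%
      mutate(z = zscore(.data$value, .data$mu, .data$sigma,
                        .data$direction)) %>%
      group_by(.data$animal, .data$group, .data$session, .data$test) %>%
      summarise(z_test = mean(.data$z, na.rm = TRUE), .groups = "drop")
  })
  scored$z_test[is.nan(scored$z_test)] <- NA_real_

  n_tests <- length(unique(specs$test))
  incomplete <- scored %>%
    group_by(.data$animal, .data$session) %>%
    summarise(n_ok = sum(!is.na(.data$z_test)), n_have = n(),
              .groups = "drop") %>%
    filter(.data$n_ok < n_tests)
  if (nrow(incomplete) > 0) {
    warn(sprintf(
      "%d animal-session(s) missing an entire test; composite averaged over remaining tests (e.g. %s at %s)",
      nrow(incomplete), incomplete$animal[1], incomplete$session[1]
    ))
  }

  scored %>%
    group_by(.data$animal, .data$group, .data$session) %>%
    summarise(emotionality = mean(.data$z_test, na.rm = TRUE),
              .groups = "drop") %>%
    left_join(
      tidyr::pivot_wider(scored, names_from = "test", values_from = "z_test",
                         names_prefix = "z_"),
      by = c("animal", "group", "session")
    ) %>%
    select("animal", "group", "session", dplyr::starts_with("z_"),
           "emotionality") %>%
    arrange(.data$session, .data$group, .data$animal)
}
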