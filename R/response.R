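#' Classify treated animals as responders or non-responders
#'
#' Response is defined per animal from the individual change in composite
#' emotionality score between a baseline and a follow-up session:
#' `percent_reduction = 100 * (baseline - followup) / baseline`. An animal
#' is a responder when the reduction reaches the threshold (>= convention,
#' matching the clinical ">= 50% improvement" criterion), a non-responder
#' otherwise. Percent change of a signed score is unstable near zero, so
#' animals whose baseline does not exceed `baseline_floor` are reported as
#' `indeterminate` rather than forced into either class. Animals missing
#' either session are listed in the `excluded` attribute, never silently
#' dropped.
#'
#' @param scores Output of [emotionality_scores()] (needs `animal`,
#'   `session`, `emotionality`; `group` is carried through if present).
#' @param baseline_session,followup_session Session labels compared.
#' @param threshold_pct Percent-reduction threshold (default 50).
#' @param baseline_floor Minimum baseline score (composite-z units) for a
#'   determinate call (default 0.1).
#' @return Tibble of class `responder_calls`: `animal`, (`group`,)
#'   `score_baseline`, `score_followup`, `percent_reduction`, `call`
#'   (responder / non_responder / indeterminate), with attribute
#'   `excluded` (animals lacking a session). Summaries via
#'   [glance.responder_calls()] and [response_rate()].
#' @export
#' @examples
#' scores <- tibble::tibble(
#'   animal = rep(c("m1", "m2"), each = 2),
#'   session = rep(c("W5", "W10"), 2),
#'   emotionality = c(2.0, 0.8, 2.0, 1.2)
#' )
#' classify_responders(scores)
classify_responders <- function(scores,
                                baseline_session = "W5",
                                followup_session = "W10",
                                threshold_pct = 50,
                                baseline_floor = 0.1) {
  check_columns(scores, c("animal", "session", "emotionality"), "scores")
  check_number(threshold_pct, "threshold_pct", lower = 0, upper = 100,
               open_lower = TRUE)
  for (ses in c(baseline_session, followup_session)) {
    if (!ses %in% scores$session) {
      stop_schema(sprintf("session '%s' not present in scores", ses))
    }
  }
  has_group <- "group" %in% names(scores)
  keys <- if (has_group) c("animal", "group") else "animal"

  wide <- scores %>%
    filter(.data$session %in% c(baseline_session, followup_session)) %>%
    mutate(.which = ifelse(.data$session == baseline_session,
                           "score_baseline", "score_followup")) %>%
    select(dplyr::all_of(keys), ".which", "emotionality") %>%
    tidyr::pivot_wider(names_from = ".which", values_from = "emotionality")
  if (!"score_baseline" %in% names(wide)) wide$score_baseline <- NA_real_
  if (!"score_followup" %in% names(wide)) wide$score_followup <- NA_real_

  excluded <- wide %>%
    filter(is.na(.data$score_baseline) | is.na(.data$score_followup))
  if (nrow(excluded) > 0) {
    warn(sprintf("%d animal(s) missing a session; see attr(., 'excluded')",
                 nrow(excluded)))
  }

  calls <- wide %>%
    anti_join(excluded, by = "animal") %>%
    mutate(
      percent_reduction = 100 * (.data$score_baseline - .data$score_followup) /
        .data$score_baseline,
      call = dplyr::case_when(
        .data$score_baseline <= baseline_floor ~ "indeterminate",
        .data$percent_reduction >= threshold_pct ~ "responder",
        TRUE ~ "non_responder"
      ),
      percent_reduction = ifelse(.data$call == "indeterminate",
                                 NA_real_, .data$percent_reduction)
    ) %>%
    arrange(.data$animal)

  structure(calls,
            excluded = excluded,
            threshold_pct = threshold_pct,
            baseline_floor = baseline_floor,
            class = c("responder_calls", class(calls)))
}

#' Response rate among determinate calls
#'
#' Fraction of responders among animals with a determinate call
#' (responders / (responders + non-responders)); indeterminate animals are
#' excluded from the denominator with a note.
#'
#' @param calls A `responder_calls` table from [classify_responders()].
#' @return A single fraction in \[0, 1\].
#' @export
#' @examples
#' # 18 responders of 25 treated animals -> 0.72
response_rate <- function(calls) {
  check_columns(calls, "call", "responder calls")
  n_ind <- sum(calls$call == "indeterminate")
  det <- calls$call[calls$call != "indeterminate"]
  if (length(det) == 0) {
    stop_stat("no determinate responder calls; cannot compute a rate")
  }
  if (n_ind > 0) {
    inform(sprintf("%d indeterminate call(s) excluded from the denominator",
                   n_ind))
  }
  sum(det == "responder") / length(det)
}

#' Summarise a responder classification
#'
#' @param x A `responder_calls` table.
#' @param ... Unused.
#' @return One-row tibble: counts per call, exclusions, and the response
#'   rate over determinate calls (`NA` when there are none).
#' @method glance responder_calls
#' @export
glance.responder_calls <- function(x, ...) {
  n_r <- sum(x$call == "responder")
  n_nr <- sum(x$call == "non_responder")
  tibble(
    n_responder = n_r,
    n_non_responder = n_nr,
    n_indeterminate = sum(x$call == "indeterminate"),
    n_excluded = nrow(attr(x, "excluded") %||% tibble()),
    threshold_pct = attr(x, "threshold_pct"),
    response_rate = if (n_r + n_nr > 0) n_r / (n_r + n_nr) else NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
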