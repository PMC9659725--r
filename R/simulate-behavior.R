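#' Baseline distributions of the behavioral test battery
#'
#' Internal table of the measures produced by the three-test battery
#' (elevated plus maze, novelty-suppressed feeding, splash test) with the
#' vehicle-arm baseline parameters used by [simulate_behavior_cohort()].
#' Open-arm time and grooming duration are Gaussian (seconds, clamped to the
#' test duration), open-arm entries are Poisson counts, and the latency to
#' feed is log-normal and right-censored at the test window.
#'
#' @return A tibble with one row per measure: `test`, `measure`, `family`
#'   (gaussian / poisson / lognormal), `baseline`, `sd` (Gaussian SD in
#'   measurement units, or log-scale SD for the latency), and `max`
#'   (physical upper bound in the same units).
#' @export
behavior_measures <- function() {
  tibble(
    test     = c("EPM", "EPM", "NSF", "ST"),
    measure  = c("open_arm_time", "open_arm_entries",
                 "latency_to_feed", "grooming_duration"),
    family   = c("gaussian", "poisson", "lognormal", "gaussian"),
    baseline = c(60, 10, 150, 80),
    sd       = c(20, sqrt(10), 0.45, 25),
    max      = c(300, Inf, 600, 300)
  )
}

# raw-measure sign of an anxiogenic (emotionality-raising) shift
anxiogenic_sign <- function(measure) {
  ifelse(measure == "latency_to_feed", 1, -1)
}

#' Default planted group effects for a corticosterone / fluoxetine / ECS cohort
#'
#' Effect sizes, in vehicle-SD units on each raw measure, that reproduce the
#' qualitative structure of a chronic-corticosterone study: corticosterone
#' raises the latency to feed and lowers open-arm activity and grooming at
#' both sessions; fluoxetine largely reverses those shifts by the follow-up
#' session in the treated arm, while the arm destined for electroconvulsive
#' stimulation remains shifted (non-responders) until a final session.
#'
#' @param severity Multiplier applied to every planted shift (default 1).
#' @return A tibble with columns `group`, `session`, `measure`, `shift`
#'   (signed, in vehicle-SD units of the raw measure).
#' @export
default_group_effects <- function(severity = 1) {
  base <- tibble(
    measure = c("open_arm_time", "open_arm_entries",
                "latency_to_feed", "grooming_duration"),
    shift   = c(-1.5, -1.2, 1.5, -1.0)
  )
  # per-arm, per-session attenuation of the corticosterone phenotype
  scale <- tibble(
    group = rep(c("Cort/Veh", "Cort/Flx", "Cort/Flx-NR-ECS"), each = 3),
    session = rep(c("W5", "W10", "W12"), times = 3),
    k = c(1, 1, 1,      # untreated corticosterone arm stays shifted
          1, 0.3, 0.3,  # fluoxetine arm improves by W10
          1, 1, 0.25)   # non-responder arm improves only after ECS (W12)
  )
  tidyr::crossing(scale, base) %>%
    mutate(shift = severity * .data$k * .data$shift) %>%
    select("group", "session", "measure", "shift")
}

#' Configure a synthetic behavioral cohort
#'
#' @param n_per_group Named integer vector, animals per treatment arm
#'   (each >= 2). Names are the arm labels.
#' @param group_effects Tibble with columns `group`, `measure`, `shift` and
#'   optionally `session` (missing or `NA` = all sessions): planted mean
#'   shifts in vehicle-SD units of the raw measure. Groups must be a subset
#'   of `names(n_per_group)`.
#' @param sessions Character vector of session labels to simulate.
#' @param nsf_max_latency Feeding-test window in seconds; latencies at or
#'   above it are right-censored at this value (default 600 s = 10 min).
#' @param measure_noise_sd Optional named numeric overriding the per-measure
#'   noise SD of [behavior_measures()] (log-scale SD for the latency).
#' @param trait_sd SD of a per-animal latent susceptibility (in SD units,
#'   shared across measures and sessions); gives animals stable individual
#'   differences so that percent-change response classification is
#'   meaningful. Set 0 to disable.
#' @param seed Integer seed; identical configurations yield identical data.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c("Veh/Veh" = 12, "Cort/Veh" = 12,
                                          "Cort/Flx" = 25,
                                          "Cort/Flx-NR-ECS" = 8),
                          group_effects = default_group_effects(),
                          sessions = c("W5", "W10"),
                          nsf_max_latency = 600,
                          measure_noise_sd = NULL,
                          trait_sd = 0.5,
                          seed = 1L) {
  if (is.null(names(n_per_group)) || any(names(n_per_group) == "")) {
    stop_config("`n_per_group` must be a named vector of arm sizes")
  }
  if (any(n_per_group < 2)) {
    stop_config("every arm needs n_per_group >= 2")
  }
  check_number(nsf_max_latency, "nsf_max_latency", lower = 0, open_lower = TRUE)
  check_number(trait_sd, "trait_sd", lower = 0)
  check_columns(group_effects, c("group", "measure", "shift"), "group_effects")
  bad <- setdiff(unique(group_effects$group), names(n_per_group))
  if (length(bad) > 0) {
    stop_config(sprintf(
      "group_effects refers to unknown group(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  bad_m <- setdiff(unique(group_effects$measure), behavior_measures()$measure)
  if (length(bad_m) > 0) {
    stop_config(sprintf(
      "group_effects refers to unknown measure(s): %s",
      paste(bad_m, collapse = ", ")
    ))
  }
  if (!is.null(measure_noise_sd)) {
    if (any(measure_noise_sd <= 0)) stop_config("noise SDs must be > 0")
  }
  structure(
    list(
      n_per_group = n_per_group, group_effects = group_effects,
      sessions = sessions, nsf_max_latency = nsf_max_latency,
      measure_noise_sd = measure_noise_sd, trait_sd = trait_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Simulate a behavioral cohort with planted group effects
#'
#' Draws one observation per animal x session x measure for the three-test
#' battery. Continuous measures are Gaussian around a shifted mean and
#' clamped to the test duration; entry counts are Poisson; feeding latencies
#' are log-normal and right-censored at the test window (`censored = TRUE`,
#' value set to the cap). Shifts are applied on the scale of vehicle SDs
#' (log-scale SDs for the latency), in the direction stated by the effect
#' table; the latent per-animal trait acts in the anxiogenic direction on
#' every measure.
#'
#' @param config A [cohort_config()].
#' @return A tibble (long format): `animal`, `group`, `session`, `test`,
#'   `measure`, `value`, `censored`.
#' @export
#' @examples
#' cfg <- cohort_config(n_per_group = c("Veh/Veh" = 4, "Cort/Veh" = 4),
#'                      group_effects = default_group_effects()[
#'                        default_group_effects()$group == "Cort/Veh", ],
#'                      seed = 42)
#' simulate_behavior_cohort(cfg)
simulate_behavior_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  meas <- behavior_measures()
  if (!is.null(config$measure_noise_sd)) {
    idx <- match(names(config$measure_noise_sd), meas$measure)
    if (anyNA(idx)) stop_config("measure_noise_sd names unknown measure(s)")
    meas$sd[idx] <- unname(config$measure_noise_sd)
  }
  meas$max[meas$measure == "latency_to_feed"] <- config$nsf_max_latency

  groups <- names(config$n_per_group)
  animals <- tibble(
    group = rep(groups, times = config$n_per_group),
    animal = sprintf(
      "%s_%02d",
      gsub("[^A-Za-z0-9]+", ".", rep(groups, times = config$n_per_group)),
      unlist(lapply(config$n_per_group, seq_len))
    )
  )

  eff <- config$group_effects
  if (!"session" %in% names(eff)) eff$session <- NA_character_

  withr::with_seed(config$seed, {
    animals$trait <- rnorm(nrow(animals), 0, config$trait_sd)

    grid <- tidyr::crossing(animals, session = config$sessions) %>%
      tidyr::crossing(meas)

    eff_all <- eff %>% filter(is.na(.data$session)) %>% select(-"session")
    eff_ses <- eff %>% filter(!is.na(.data$session))
    grid <- grid %>%
      left_join(eff_ses, by = c("group", "session", "measure")) %>%
      left_join(eff_all, by = c("group", "measure"),
                suffix = c("", "_all")) %>%
      mutate(
        shift = dplyr::coalesce(.data$shift, .data$shift_all, 0),
        total_shift = .data$shift + anxiogenic_sign(.data$measure) * .data$trait
      )

    n <- nrow(grid)
    value <- numeric(n)
    g <- grid$family == "gaussian"
    value[g] <- rnorm(sum(g),
                      grid$baseline[g] + grid$total_shift[g] * grid$sd[g],
                      grid$sd[g])
    p <- grid$family == "poisson"
    lam <- pmax(0.05, grid$baseline[p] + grid$total_shift[p] * grid$sd[p])
    value[p] <- rpois(sum(p), lam)
    l <- grid$family == "lognormal"
    value[l] <- rlnorm(sum(l),
                       log(grid$baseline[l]) + grid$total_shift[l] * grid$sd[l],
                       grid$sd[l])

    grid$value <- value
    grid %>%
      mutate(
        censored = .data$family == "lognormal" & .data$value >= .data$max,
        value = pmin(pmax(.data$value, 0), .data$max)
      ) %>%
      arrange(.data$session, .data$group, .data$animal,
              .data$test, .data$measure) %>%
      select("animal", "group", "session", "test", "measure",
             "value", "censored")
  })
}
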