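validate_latency <- function(data) {
  check_columns(data, c("latency", "censored", "group"), "latency data")
  if (nrow(data) == 0) stop_schema("latency data is empty")
  if (any(is.na(data$latency)) || any(data$latency <= 0)) {
    stop_schema("latencies must be positive and non-missing")
  }
  data
}

#' Kaplan-Meier estimate of the latency-to-feed survival curve
#'
#' Product-limit estimator of the fraction of animals that have not yet
#' eaten by time t in the novelty-suppressed-feeding test, per group.
#' Animals that never feed within the test window are right-censored at the
#' cap and never counted as events. Thin wrapper over
#' [survival::survfit()] returning a tidy step table.
#'
#' @param data Tibble with columns `latency` (seconds, > 0), `censored`
#'   (logical, `TRUE` = did not eat), `group`.
#' @return Tibble of class `ecsig_km`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` — one row per observed time per
#'   group, plus the implicit start at `time = 0`, `survival = 1`.
#' @export
km_estimate <- function(data) {
  data <- validate_latency(data)
  fit <- survival::survfit(
    survival::Surv(latency, !censored) ~ group,
    data = data
  )
  smry <- summary(fit, censored = TRUE)
  grp <- if (is.null(smry$strata)) {
    rep(as.character(data$group[1]), length(smry$time))
  } else {
    sub("^group=", "", as.character(smry$strata))
  }
  out <- tibble(
    group = grp,
    time = smry$time,
    n_risk = smry$n.risk,
    n_event = smry$n.event,
    n_censor = smry$n.censor,
    survival = smry$surv
  )
  start <- out %>%
    group_by(.data$group) %>%
    summarise(time = 0, n_risk = max(.data$n_risk), n_event = 0L,
              n_censor = 0L, survival = 1, .groups = "drop")
  out <- bind_rows(start, out) %>% arrange(.data$group, .data$time)
  class(out) <- c("ecsig_km", class(out))
  out
}

#' Mantel-Cox log-rank test on censored latencies
#'
#' Compares latency distributions between groups with the standard
#' observed-minus-expected statistic accumulated over ordered event times
#' (hypergeometric variance, standard tie handling), chi-square with
#' k - 1 degrees of freedom. Wraps [survival::survdiff()].
#'
#' @inheritParams km_estimate
#' @return Object of class `ecsig_test_report`; see [tidy.ecsig_test_report()].
#' @export
logrank_test <- function(data) {
  data <- validate_latency(data)
  if (length(unique(data$group)) < 2) {
    stop_stat("log-rank test needs at least two groups")
  }
  if (sum(!data$censored) == 0) {
    stop_stat("log-rank test needs at least one event (uncensored latency)")
  }
  sd_fit <- survival::survdiff(
    survival::Surv(latency, !censored) ~ group,
    data = data
  )
  df <- length(sd_fit$n) - 1
  structure(
    list(
      test = "Mantel-Cox log-rank",
      statistic = unname(sd_fit$chisq),
      df = df,
      p_value = pchisq(sd_fit$chisq, df, lower.tail = FALSE),
      n = sum(sd_fit$n),
      groups = sub("^group=", "", names(sd_fit$n))
    ),
    class = "ecsig_test_report"
  )
}

#' Normality-gated location test for behavioral measures
#'
#' Implements the analysis policy used for the behavioral endpoints:
#' Shapiro-Wilk normality is checked per group at `gate_alpha`; if every
#' group looks normal the parametric route is taken (Student t-test for two
#' groups, one-way ANOVA with Fisher's LSD post-hoc for more), otherwise
#' the non-parametric route (Mann-Whitney, or Kruskal-Wallis with Dunn's
#' post-hoc). Post-hoc p-values are unadjusted. The gate decision and the
#' per-group normality p-values are part of the report.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding the measure and the arm.
#' @param gate_alpha Significance level of the normality gate (default 0.05).
#' @return Object of class `ecsig_gated_test` with elements `path`
#'   (`"parametric"` / `"nonparametric"`), `normality` (per-group tibble),
#'   `test`, `statistic`, `df`, `p_value`, and `posthoc` (tibble of pairwise
#'   comparisons, `NULL` for two groups). `tidy()` returns the post-hoc
#'   table, `glance()` the omnibus row.
#' @export
gated_location_test <- function(data, value, group, gate_alpha = 0.05) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v)
  v <- v[keep]; g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2) stop_stat("need at least two groups")
  ns <- table(g)
  if (any(ns < 3)) {
    stop_stat(sprintf(
      "normality gate needs >= 3 values per group (violated for: %s)",
      paste(names(ns)[ns < 3], collapse = ", ")
    ))
  }

  normality <- tibble(
    group = levels(g),
    n = as.integer(ns),
    shapiro_p = vapply(levels(g), function(gr) {
      x <- v[g == gr]
      if (length(unique(x)) == 1) 0 else shapiro.test(x)$p.value
    }, numeric(1))
  )
  parametric <- all(normality$shapiro_p > gate_alpha)

  posthoc <- NULL
  if (k == 2) {
    if (parametric) {
      tt <- t.test(v ~ g, var.equal = TRUE)
      res <- list(test = "Student t-test",
                  statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p_value = tt$p.value)
    } else {
      wt <- suppressWarnings(wilcox.test(v ~ g, exact = FALSE))
      res <- list(test = "Mann-Whitney U",
                  statistic = unname(wt$statistic),
                  df = NA_real_, p_value = wt$p.value)
    }
  } else {
    if (parametric) {
      fit <- aov(v ~ g)
      tab <- summary(fit)[[1]]
      res <- list(test = "one-way ANOVA",
                  statistic = tab[["F value"]][1],
                  df = tab[["Df"]][1], p_value = tab[["Pr(>F)"]][1])
      posthoc <- fisher_lsd(v, g)
    } else {
      kw <- kruskal.test(v ~ g)
      res <- list(test = "Kruskal-Wallis",
                  statistic = unname(kw$statistic),
                  df = unname(kw$parameter), p_value = kw$p.value)
      posthoc <- dunn_posthoc(v, g)
    }
  }

  structure(
    c(list(path = if (parametric) "parametric" else "nonparametric",
           gate_alpha = gate_alpha, normality = normality),
      res, list(posthoc = posthoc)),
    class = "ecsig_gated_test"
  )
}

# Fisher's least-significant-difference post-hoc: pairwise t statistics with
# the pooled ANOVA error variance, unadjusted p-values.
fisher_lsd <- function(v, g) {
  k <- nlevels(g)
  ns <- tapply(v, g, length)
  means <- tapply(v, g, mean)
  mse <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / (length(v) - k)
  df <- length(v) - k
  pairs <- combn(levels(g), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
    tstat <- (means[[a]] - means[[b]]) / se
    tibble(group1 = a, group2 = b, statistic = tstat, df = df,
           p_value = 2 * pt(-abs(tstat), df))
  })
}

# Dunn's rank-based post-hoc after Kruskal-Wallis, with tie correction,
# unadjusted two-sided normal p-values.
dunn_posthoc <- function(v, g) {
  N <- length(v)
  r <- rank(v)
  rbar <- tapply(r, g, mean)
  ns <- tapply(v, g, length)
  ties <- table(v)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- combn(levels(g), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    tibble(group1 = a, group2 = b, statistic = z, df = NA_real_,
           p_value = 2 * pnorm(-abs(z)))
  })
}
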