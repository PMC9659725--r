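test_that("product-limit estimate matches closed forms without censoring", {
  d <- tibble::tibble(latency = c(50, 100, 200, 400),
                      censored = FALSE, group = "A")
  km <- km_estimate(d)
  steps <- km[km$time > 0, ]
  expect_equal(steps$survival, c(3, 2, 1, 0) / 4)
  # all censored: survival stays at 1
  dc <- tibble::tibble(latency = 600, censored = TRUE,
                       group = "A")[rep(1, 4), ]
  kmc <- km_estimate(dc)
  expect_true(all(kmc$survival == 1))
})

test_that("mixed toy set reproduces the hand product-limit computation", {
  d <- tibble::tibble(latency = c(100, 600, 300),
                      censored = c(FALSE, TRUE, FALSE), group = "A")
  km <- km_estimate(d)
  expect_equal(km$survival[km$time == 100], 2 / 3)
  expect_equal(km$survival[km$time == 300], 1 / 3)
  # independent recomputation over a random censored sample
  set.seed(9)
  lat <- pmin(round(rlnorm(40, 5, 0.6)), 600)
  d2 <- tibble::tibble(latency = lat, censored = lat >= 600, group = "G")
  km2 <- km_estimate(d2)
  orc <- oracle_km(d2$latency, !d2$censored)
  got <- km2[km2$n_event > 0, ]
  expect_equal(got$time, orc$time)
  expect_equal(got$survival, orc$surv, tolerance = 1e-12)
})

test_that("KM output is row-order invariant, monotone, and in [0, 1]", {
  d <- toy_latency()
  k1 <- km_estimate(d)
  k2 <- km_estimate(d[sample(nrow(d)), ])
  expect_equal(as.data.frame(k1), as.data.frame(k2))
  for (g in unique(k1$group)) {
    s <- k1$survival[k1$group == g]
    expect_true(all(diff(s) <= 0))
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("log-rank matches the brute-force hypergeometric oracle", {
  d <- toy_latency()
  res <- logrank_test(d)
  orc <- oracle_logrank(d$latency, !d$censored, d$group)
  expect_equal(res$statistic, orc$chisq, tolerance = 1e-10)
  expect_equal(res$p_value, orc$p, tolerance = 1e-10)
  # label symmetry
  flipped <- d |> dplyr::mutate(group = ifelse(group == "A", "B", "A"))
  expect_equal(logrank_test(flipped)$p_value, res$p_value)
  # several random censored instances
  set.seed(13)
  for (i in 1:5) {
    lat <- pmin(round(rlnorm(30, 5, 0.5)) + 1, 600)
    d3 <- tibble::tibble(latency = lat, censored = lat >= 600,
                         group = rep(c("A", "B"), 15))
    expect_equal(logrank_test(d3)$statistic,
                 oracle_logrank(d3$latency, !d3$censored, d3$group)$chisq,
                 tolerance = 1e-8)
  }
})

test_that("identical groups give a null log-rank and degenerate inputs error", {
  same <- tibble::tibble(latency = rep(c(100, 200, 300), 2),
                         censored = FALSE,
                         group = rep(c("A", "B"), each = 3))
  res <- logrank_test(same)
  expect_lt(res$statistic, 1e-10)
  expect_gt(res$p_value, 0.99)
  allc <- tibble::tibble(latency = 600, censored = TRUE,
                         group = c("A", "B"))
  expect_error(logrank_test(allc), class = "ecsig_stat_error")
  expect_error(
    km_estimate(tibble::tibble(latency = numeric(), censored = logical(),
                               group = character())),
    class = "ecsig_schema_error"
  )
})

test_that("the normality gate picks the parametric path for normal data", {
  set.seed(7)
  d <- tibble::tibble(v = c(rnorm(20), rnorm(20, 1)),
                      g = rep(c("a", "b"), each = 20))
  res <- gated_location_test(d, v, g)
  expect_equal(res$path, "parametric")
  expect_equal(res$test, "Student t-test")
  ref <- t.test(v ~ g, data = d, var.equal = TRUE)
  expect_equal(res$p_value, ref$p.value)
})

test_that("skewed data routes to the non-parametric path", {
  set.seed(8)
  d <- tibble::tibble(v = c(rexp(20)^3, rexp(20)^3 + 0.2),
                      g = rep(c("a", "b"), each = 20))
  res <- gated_location_test(d, v, g)
  expect_equal(res$path, "nonparametric")
  expect_equal(res$test, "Mann-Whitney U")
})

test_that("identical groups are a null result on either path", {
  x <- c(1.2, 3.4, 2.2, 4.8, 2.9, 3.3)
  d <- tibble::tibble(v = rep(x, 2), g = rep(c("a", "b"), each = 6))
  res <- gated_location_test(d, v, g)
  expect_gt(res$p_value, 0.99)
})

test_that("k-group paths run ANOVA + LSD or Kruskal-Wallis + Dunn", {
  set.seed(10)
  d <- tibble::tibble(v = c(rnorm(12), rnorm(12, 2), rnorm(12)),
                      g = rep(c("a", "b", "c"), each = 12))
  res <- gated_location_test(d, v, g)
  expect_equal(res$test, "one-way ANOVA")
  ref <- summary(aov(v ~ g, data = d))[[1]]
  expect_equal(res$p_value, ref[["Pr(>F)"]][1])
  ph <- tidy(res)
  expect_equal(nrow(ph), 3)
  expect_lt(ph$p_value[ph$group1 == "a" & ph$group2 == "b"], 0.05)

  dsk <- tibble::tibble(v = c(rexp(12)^3, rexp(12)^3, rexp(12)^3 + 9),
                        g = rep(c("a", "b", "c"), each = 12))
  res2 <- gated_location_test(dsk, v, g)
  expect_equal(res2$test, "Kruskal-Wallis")
  ref2 <- kruskal.test(v ~ g, data = dsk)
  expect_equal(res2$p_value, ref2$p.value)
  ph2 <- tidy(res2)
  expect_true(all(c("statistic", "p_value") %in% names(ph2)))
  # Dunn z for a vs c against direct rank computation
  r <- rank(dsk$v); N <- length(r)
  rbar <- tapply(r, dsk$g, mean)
  se <- sqrt((N * (N + 1) / 12) * (1 / 12 + 1 / 12))
  z_ac <- (rbar[["a"]] - rbar[["c"]]) / se
  expect_equal(ph2$statistic[ph2$group1 == "a" & ph2$group2 == "c"], z_ac,
               tolerance = 1e-10)
  expect_error(
    gated_location_test(
      tibble::tibble(v = c(1, 2, 3, 4), g = c("a", "a", "a", "b")),
      v, g
    ),
    class = "ecsig_stat_error"
  )
})
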