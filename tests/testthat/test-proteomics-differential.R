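two_group_matrix <- function(rows) {
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("P%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("S%d", seq_len(ncol(m)))
  m
}
grp6 <- rep(c("g1", "g2"), each = 3)

test_that("constant counts give zero deviance and p = 1", {
  m <- two_group_matrix(list(c(7, 7, 7, 7, 7, 7)))
  res <- poisson_group_test(m, grp6, offset = FALSE)
  expect_equal(res$deviance, 0)
  expect_equal(res$p_value, 1)
})

test_that("two-group deviance matches the closed-form profile-likelihood oracle", {
  cases <- list(
    c(10, 10, 10, 20, 20, 20),
    c(3, 5, 4, 9, 12, 8),
    c(0, 1, 0, 6, 4, 7),
    c(15, 11, 13, 14, 12, 16)
  )
  m <- two_group_matrix(cases)
  res <- poisson_group_test(m, grp6, offset = FALSE)
  for (i in seq_along(cases)) {
    orc <- oracle_poisson_lrt2(cases[[i]], grp6)
    expect_equal(res$deviance[i], orc$stat, tolerance = 1e-8)
    expect_equal(res$p_value[i], orc$p, tolerance = 1e-8)
  }
})

test_that("all-zero proteins are untestable, never p = 1", {
  m <- two_group_matrix(list(rep(0, 6), c(1, 2, 1, 5, 6, 4)))
  res <- poisson_group_test(m, grp6, offset = FALSE)
  expect_true(res$untestable[1])
  expect_true(is.na(res$p_value[1]))
  expect_false(res$untestable[2])
})

test_that("three-level designs use k - 1 degrees of freedom", {
  m <- two_group_matrix(list(c(10, 12, 9, 22, 18, 20, 9, 11, 10)))
  colnames(m) <- sprintf("S%d", 1:9)
  res <- poisson_group_test(m, rep(c("a", "b", "c"), each = 3),
                            offset = FALSE)
  expect_equal(res$df, 2)
  y <- m[1, ]
  g <- rep(c("a", "b", "c"), each = 3)
  mu1 <- ave(y, g); mu0 <- mean(y)
  stat <- 2 * sum(y * log(mu1 / mu0))
  expect_equal(res$deviance, stat, tolerance = 1e-8)
})

test_that("the library-size offset absorbs depth differences", {
  # same composition, double depth in group 2: offset model sees no effect
  m <- two_group_matrix(list(c(10, 10, 10, 20, 20, 20),
                             c(30, 30, 30, 60, 60, 60)))
  res_off <- poisson_group_test(m, grp6, offset = TRUE)
  expect_equal(res_off$deviance, rep(0, 2), tolerance = 1e-10)
  res_raw <- poisson_group_test(m, grp6, offset = FALSE)
  expect_true(all(res_raw$deviance > 1))
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(16)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("BH is permutation-invariant, monotone, and >= raw p", {
  set.seed(17)
  p <- runif(30)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  perm <- sample(30)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  # NA propagation keeps the family size at the non-missing count
  p_na <- c(0.01, NA, 0.02)
  adj_na <- bh_adjust(p_na)
  expect_true(is.na(adj_na[2]))
  expect_equal(adj_na[c(1, 3)], oracle_bh(c(0.01, 0.02)))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "ecsig_schema_error")
})

test_that("pairwise contrasts call direction by the sign of the mean difference", {
  m <- two_group_matrix(list(c(10, 11, 9, 21, 20, 19),
                             c(20, 21, 19, 10, 11, 9)))
  ct <- pairwise_contrasts(m, grp6)
  expect_equal(ct$contrast, rep("g2 vs g1", 2))
  expect_equal(ct$direction, c("up", "down"))
  ref <- t.test(c(21, 20, 19), c(10, 11, 9), var.equal = TRUE)
  expect_equal(ct$p_value[1], ref$p.value)
  # zero variance in both groups: untestable
  m2 <- two_group_matrix(list(c(5, 5, 5, 5, 5, 5)))
  ct2 <- pairwise_contrasts(m2, grp6)
  expect_true(is.na(ct2$p_value))
  expect_true(is.na(ct2$direction))
})

test_that("contrast summaries recover a planted up/down split", {
  cfg <- proteome_sim_config(n_proteins = 40, n_samples_per_group = 4,
                             groups = c("ref", "alt"), baseline_rate = 20,
                             frac_de = 0.25, prop_down = 0.4,
                             fold_change = 6, seed = 18)
  sim <- simulate_spectral_counts(cfg)
  ct <- pairwise_contrasts(sim$counts, sim$samples)
  smry <- contrast_summary(ct)
  expect_equal(smry$n_tested, 40)
  planted_down <- sum(sim$truth$direction == "down", na.rm = TRUE)
  planted_up <- sum(sim$truth$direction == "up", na.rm = TRUE)
  expect_gte(smry$n_down, planted_down - 1)
  expect_gte(smry$n_up, planted_up - 1)
  # directions agree with truth for every significant planted protein
  joined <- dplyr::inner_join(ct, sim$truth, by = "protein") |>
    dplyr::filter(significant, is_de)
  expect_true(all(joined$direction.x == joined$direction.y))
})

test_that("identical groups stay near the nominal false-positive rate", {
  cfg <- proteome_sim_config(n_proteins = 400, groups = c("a", "b"),
                             baseline_rate = 15, frac_de = 0,
                             library_size_variation = c(1, 1), seed = 19)
  sim <- simulate_spectral_counts(cfg)
  ct <- pairwise_contrasts(sim$counts, sim$samples)
  fp <- mean(ct$significant, na.rm = TRUE)
  expect_lt(fp, 0.1)
})

test_that("strong planted effects are recovered with controlled FDR over seeds", {
  run_once <- function(s) {
    sim <- simulate_spectral_counts(proteome_sim_config(
      n_proteins = 100, n_samples_per_group = 3, groups = c("ref", "alt"),
      baseline_rate = 10, frac_de = 0.1, fold_change = 4, seed = s
    ))
    dt <- poisson_group_test(sim$counts, sim$samples)
    dt$p_adj <- bh_adjust(dt$p_value)
    hits <- dt$protein[!is.na(dt$p_adj) & dt$p_adj < 0.05]
    planted <- sim$truth$protein[sim$truth$is_de]
    c(sens = mean(planted %in% hits),
      fdr = if (length(hits) > 0) mean(!hits %in% planted) else 0)
  }
  res <- vapply(300 + 1:20, run_once, numeric(2))
  expect_gte(mean(res["sens", ]), 0.9)
  expect_lte(mean(res["fdr", ]), 0.1)
})
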