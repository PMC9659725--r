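#' Per-protein Poisson regression test of a group effect
#'
#' Fits, for each protein row, a Poisson log-linear regression of spectral
#' counts on the sample group and compares it to the intercept-only model
#' with a likelihood-ratio (deviance) test, chi-square with k - 1 degrees
#' of freedom. An optional library-size offset absorbs depth differences
#' between runs (on by default; disable to fit the literal unnormalised
#' model). The default size factors are median-of-ratios against the
#' geometric-mean reference profile, which stays anchored on the
#' non-differential majority even when many proteins shift in one
#' direction; `offset_method = "total"` uses log total spectra per sample
#' instead, which is simpler but biased when the differential signal is
#' asymmetric. Rows with all-zero counts are reported as untestable
#' (`NA` p-value), not as p = 1.
#'
#' @param counts Integer matrix, proteins x samples (dimnames required).
#' @param sample_groups Sample annotation: tibble (`sample`, `group`),
#'   named vector, or factor aligned with `colnames(counts)`.
#' @param offset Use a library-size offset (default `TRUE`).
#' @param offset_method `"median_ratio"` (default) or `"total"`.
#' @return Tibble: `protein`, `deviance` (LRT statistic), `df`, `p_value`,
#'   `untestable`. Adjust with [bh_adjust()].
#' @export
poisson_group_test <- function(counts, sample_groups, offset = TRUE,
                               offset_method = c("median_ratio", "total")) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_schema("`counts` needs row (protein) and column (sample) names")
  }
  offset_method <- match.arg(offset_method)
  grp <- sample_group_factor(counts, sample_groups)
  k <- nlevels(grp)
  if (k < 2 || any(table(grp) < 2)) {
    stop_stat("need >= 2 groups with >= 2 samples each")
  }
  off <- if (!offset) {
    rep(0, ncol(counts))
  } else if (offset_method == "median_ratio") {
    log(size_factors(counts))
  } else {
    log(colSums(counts))
  }
  if (offset && any(!is.finite(off))) {
    stop_stat("offset undefined: some samples have zero total counts")
  }

  res <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    y <- counts[i, ]
    if (all(y == 0)) {
      return(tibble(protein = rownames(counts)[i], deviance = NA_real_,
                    df = k - 1, p_value = NA_real_, untestable = TRUE))
    }
    fit1 <- glm(y ~ grp, family = poisson(), offset = off)
    fit0 <- glm(y ~ 1, family = poisson(), offset = off)
    dev <- max(0, fit0$deviance - fit1$deviance)
    tibble(protein = rownames(counts)[i], deviance = dev, df = k - 1,
           p_value = pchisq(dev, k - 1, lower.tail = FALSE),
           untestable = FALSE)
  })
  res
}

#' Median-of-ratios library size factors
#'
#' For each sample, the median ratio of its counts to the geometric-mean
#' reference profile over proteins observed in every sample. Robust to a
#' minority of differential proteins; falls back to relative column totals
#' when no protein is observed everywhere.
#'
#' @param counts Integer matrix, proteins x samples.
#' @return Positive numeric vector, one size factor per sample.
#' @export
size_factors <- function(counts) {
  pos <- counts[apply(counts, 1, function(r) all(r > 0)), , drop = FALSE]
  if (nrow(pos) == 0) {
    warn("no protein observed in every sample; using relative column totals")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  geo <- exp(rowMeans(log(pos)))
  apply(pos, 2, function(col) stats::median(col / geo))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement (via
#' [stats::p.adjust()]). Missing values propagate as missing and do not
#' count toward the family size, so untestable proteins can be excluded
#' from the family simply by passing their p-values as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NA` allowed.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_schema("`p` must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop_schema(sprintf("p-values outside [0, 1] at position(s): %s",
                        paste(which(bad), collapse = ", ")))
  }
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Pairwise two-sample contrasts with direction calls
#'
#' For each protein and each ordered contrast `alt vs ref`, runs a
#' two-sample Student t-test (equal variances) on the counts and flags
#' significance at `alpha`. The direction (`up` = higher mean in the `alt`
#' group) is reported only for significant proteins. Comparisons with zero
#' variance in both groups are untestable (`NA` p). A square-root
#' variance-stabilising transform is available behind a flag; the default
#' tests the raw counts.
#'
#' @inheritParams poisson_group_test
#' @param contrasts List of length-2 character vectors `c(alt, ref)`;
#'   default: every later group level against every earlier one.
#' @param alpha Significance level for the direction call (default 0.05).
#' @param sqrt_transform Test `sqrt(counts)` instead of raw counts.
#' @return Tibble: `protein`, `contrast` (`"alt vs ref"`), `mean_alt`,
#'   `mean_ref`, `statistic`, `p_value`, `significant`, `direction`.
#' @export
pairwise_contrasts <- function(counts, sample_groups, contrasts = NULL,
                               alpha = 0.05, sqrt_transform = FALSE) {
  grp <- sample_group_factor(counts, sample_groups)
  lv <- levels(grp)
  if (is.null(contrasts)) {
    pairs <- combn(lv, 2, simplify = FALSE)
    contrasts <- lapply(pairs, function(p) c(p[2], p[1]))  # later vs earlier
  }
  for (ct in contrasts) {
    if (length(ct) != 2 || !all(ct %in% lv)) {
      stop_schema("each contrast must be c(alt, ref) using known group labels")
    }
  }
  x <- if (sqrt_transform) sqrt(counts) else counts

  purrr::map_dfr(contrasts, function(ct) {
    alt <- ct[1]; ref <- ct[2]
    ia <- grp == alt; ir <- grp == ref
    purrr::map_dfr(seq_len(nrow(x)), function(i) {
      a <- x[i, ia]; r <- x[i, ir]
      ma <- mean(a); mr <- mean(r)
      if (var(a) == 0 && var(r) == 0) {
        stat <- NA_real_; p <- NA_real_
      } else {
        tt <- t.test(a, r, var.equal = TRUE)
        stat <- unname(tt$statistic); p <- tt$p.value
      }
      sig <- !is.na(p) && p < alpha
      tibble(
        protein = rownames(x)[i],
        contrast = paste(alt, "vs", ref),
        mean_alt = ma, mean_ref = mr,
        statistic = stat, p_value = p,
        significant = sig,
        direction = if (sig) {
          if (ma > mr) "up" else "down"
        } else NA_character_
      )
    })
  })
}

#' Tally significant proteins per contrast
#'
#' @param contrast_tbl Output of [pairwise_contrasts()].
#' @return Tibble per contrast: `n_tested`, `n_significant`, `n_up`,
#'   `n_down`, `n_untestable`.
#' @export
contrast_summary <- function(contrast_tbl) {
  check_columns(contrast_tbl, c("contrast", "p_value", "significant",
                                "direction"), "contrast table")
  contrast_tbl %>%
    group_by(.data$contrast) %>%
    summarise(
      n_tested = sum(!is.na(.data$p_value)),
      n_significant = sum(.data$significant, na.rm = TRUE),
      n_up = sum(.data$direction == "up", na.rm = TRUE),
      n_down = sum(.data$direction == "down", na.rm = TRUE),
      n_untestable = sum(is.na(.data$p_value)),
      .groups = "drop"
    )
}
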