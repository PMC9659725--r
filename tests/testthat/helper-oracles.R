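# Independent brute-force oracles. Each reimplements a computation from
# first principles, deliberately sharing no code with the package, so the
# package routes can be checked against step-by-step recomputation.

# Benjamini-Hochberg step-up, literal definition: sort ascending, multiply
# p_(i) by m/i, enforce monotonicity from the largest rank down, cap at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Product-limit estimator by hand: S(t) = prod over event times u <= t of
# (1 - d_u / n_u). Returns the step function evaluated just after each
# distinct event time.
oracle_km <- function(time, event) {
  times <- sort(unique(time[event]))
  n <- length(time)
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    at_risk <- sum(time >= times[i])
    d <- sum(time == times[i] & event)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = times, surv = surv)
}

# Two-group Mantel-Cox log-rank by summing hypergeometric moments at each
# distinct event time.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  times <- sort(unique(time[event]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    n1 <- sum(time >= t & g == 1)
    n2 <- sum(time >= t & g == 2)
    nt <- n1 + n2
    d1 <- sum(time == t & event & g == 1)
    dt <- sum(time == t & event)
    O1 <- O1 + d1
    E1 <- E1 + dt * n1 / nt
    if (nt > 1) {
      V <- V + dt * (n1 / nt) * (n2 / nt) * (nt - dt) / (nt - 1)
    }
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Closed-form two-group Poisson likelihood-ratio statistic: with group MLEs
# ybar_g and pooled MLE ybar, the deviance difference is
# 2 * sum_i y_i * log(mu1_i / mu0_i) (0 log 0 = 0).
oracle_poisson_lrt2 <- function(y, group) {
  g <- as.integer(factor(group))
  mu1 <- ave(y, g)
  mu0 <- mean(y)
  terms <- ifelse(y == 0, 0, y * log(mu1 / mu0))
  stat <- 2 * sum(terms)
  list(stat = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# Union-find partition of proteins connected through shared peptides.
oracle_components <- function(map) {
  prots <- sort(unique(map$protein))
  parent <- stats::setNames(prots, prots)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[[max(ra, rb)]] <<- min(ra, rb)
  }
  for (pep in unique(map$peptide)) {
    members <- map$protein[map$peptide == pep]
    if (length(members) > 1) {
      for (i in 2:length(members)) union2(members[1], members[i])
    }
  }
  vapply(prots, find, character(1))
}

# Literal application of the three identification rules.
oracle_filter <- function(psm, pep_max = 0.01, min_pep = 2, prot_max = 1e-4) {
  rows <- do.call(rbind, lapply(seq_len(nrow(psm)), function(i) {
    data.frame(peptide = psm$peptide[i], evalue = psm$evalue[i],
               protein = strsplit(psm$proteins[i], ";")[[1]])
  }))
  rows <- unique(rows)
  rows <- rows[rows$evalue < pep_max, ]
  retained <- character(0)
  for (pr in unique(rows$protein)) {
    sub <- unique(rows[rows$protein == pr, c("peptide", "evalue")])
    if (nrow(sub) >= min_pep && prod(sub$evalue) < prot_max) {
      retained <- c(retained, pr)
    }
  }
  sort(retained)
}

# Brute-force UPGMA on a distance matrix: repeatedly merge the closest pair
# (lowest indices on ties); inter-cluster distance = arithmetic mean over
# all cross pairs of the original distances.
oracle_upgma_heights <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  cluster_dist <- function(a, b) mean(D[a, b])
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- cluster_dist(clusters[[i]], clusters[[j]])
        if (d < bd - 1e-12) {
          bd <- d; best <- c(i, j)
        }
      }
    }
    heights <- c(heights, bd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  sort(heights)
}

# Small latency fixture used across the survival tests.
toy_latency <- function() {
  tibble::tibble(
    latency = c(100, 600, 300, 150, 200, 600),
    censored = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    group = rep(c("A", "B"), each = 3)
  )
}
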