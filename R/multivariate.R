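#' Center each protein row at zero
#'
#' Subtracts the row mean from every row, so an entry is positive where a
#' sample lies above that protein's average abundance (the red/blue
#' convention of the expression heatmap). Constant rows become all-zero.
#'
#' @param m Numeric matrix (proteins x samples).
#' @return Matrix of the same shape with zero row means.
#' @export
center_rows <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop_schema("`m` must be numeric matrix")
  m - rowMeans(m)
}

#' Euclidean / UPGMA biclustering of an abundance matrix
#'
#' Row-centers the matrix, then runs average-linkage (unweighted pair-group
#' arithmetic mean) agglomeration on Euclidean distances independently over
#' the protein rows and the sample columns — the two trees ordering an
#' expression heatmap. Merge heights of average linkage are non-decreasing;
#' ties resolve deterministically (lowest index first).
#'
#' @param m Numeric matrix with >= 2 rows and >= 2 columns, dimnames set.
#' @param center Row-center before clustering (default `TRUE`).
#' @return Object of class `ecsig_bicluster`: `rows` and `cols` (`hclust`
#'   objects), `centered` (the matrix used). `tidy()` gives the merge
#'   tables; [export_linkage()] writes Newick + TSV.
#' @export
upgma_bicluster <- function(m, center = TRUE) {
  if (!is.matrix(m) || nrow(m) < 2 || ncol(m) < 2) {
    stop_stat("biclustering needs a matrix with >= 2 rows and >= 2 columns")
  }
  cm <- if (center) center_rows(m) else m
  structure(
    list(
      rows = hclust(dist(cm), method = "average"),
      cols = hclust(dist(t(cm)), method = "average"),
      centered = cm,
      metric = "euclidean", method = "average"
    ),
    class = "ecsig_bicluster"
  )
}

#' Export linkage trees as Newick and merge tables
#'
#' @param x An `ecsig_bicluster`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written: `rows.nwk`, `cols.nwk`,
#'   `rows_merges.tsv`, `cols_merges.tsv`.
#' @export
export_linkage <- function(x, dir) {
  stopifnot(inherits(x, "ecsig_bicluster"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (dim in c("rows", "cols")) {
    hc <- x[[dim]]
    nwk <- file.path(dir, paste0(dim, ".nwk"))
    ape::write.tree(ape::as.phylo(hc), file = nwk)
    tsv <- file.path(dir, paste0(dim, "_merges.tsv"))
    readr::write_tsv(hclust_merges(hc, dim), tsv)
    paths <- c(paths, nwk, tsv)
  }
  invisible(paths)
}

hclust_merges <- function(hc, dimension) {
  tibble(
    dimension = dimension,
    step = seq_len(nrow(hc$merge)),
    left = hc$merge[, 1], right = hc$merge[, 2],
    height = hc$height
  )
}

#' Tidy the merge sequences of a biclustering
#'
#' @param x An `ecsig_bicluster`.
#' @param ... Unused.
#' @return Tibble over both dimensions: `dimension`, `step`, `left`,
#'   `right` (negative = leaf index, positive = earlier merge), `height`.
#' @method tidy ecsig_bicluster
#' @export
tidy.ecsig_bicluster <- function(x, ...) {
  bind_rows(hclust_merges(x$rows, "rows"), hclust_merges(x$cols, "cols"))
}

#' PCA of samples with per-group bivariate-normal density summaries
#'
#' Ordinary principal component analysis of the samples in protein-abundance
#' space (per-protein centering; unit-variance scaling optional and off by
#' default), followed by per-group summaries of the first two score
#' dimensions — the 2-D mean vector and covariance matrix that parametrise
#' the bivariate-normal density ellipse drawn for each group. The sign of
#' each component is fixed so its largest-magnitude loading is positive,
#' making scores reproducible across platforms.
#'
#' @param m Numeric matrix, proteins x samples (>= 2 proteins,
#'   >= 3 samples).
#' @param groups Sample annotation (tibble `sample`/`group`, named vector,
#'   or vector aligned with columns).
#' @param scale Divide each protein by its SD before the decomposition.
#' @return Object of class `ecsig_pca`: `scores` (tibble `sample`, `group`,
#'   `PC1`, ...), `loadings` (tibble `protein`, `PC1`, ...),
#'   `var_explained` (fractions), `ellipses` (per group: `mean_pc1`,
#'   `mean_pc2`, `var_pc1`, `var_pc2`, `cov_pc12`, `n`), plus `rotation`,
#'   `center`, `sdev` for reconstruction. See [density_draws()] for
#'   simulated draws from the group densities.
#' @export
pca_with_group_densities <- function(m, groups, scale = FALSE) {
  if (!is.matrix(m) || nrow(m) < 2) stop_stat("PCA needs >= 2 proteins")
  if (ncol(m) < 3) stop_stat("PCA needs >= 3 samples")
  grp <- sample_group_factor(m, groups)

  pr <- prcomp(t(m), center = TRUE, scale. = scale)
  # deterministic sign: largest-|loading| entry of each PC made positive
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  ve <- pr$sdev^2 / sum(pr$sdev^2)

  scores <- as_tibble(pr$x, rownames = "sample") %>%
    mutate(group = as.character(grp[match(.data$sample, colnames(m))]),
           .after = "sample")

  pc12 <- pr$x[, seq_len(min(2, ncol(pr$x))), drop = FALSE]
  if (ncol(pc12) == 1) pc12 <- cbind(pc12, PC2 = 0)
  ellipses <- purrr::map_dfr(levels(grp), function(gl) {
    s <- pc12[grp == gl, , drop = FALSE]
    cv <- if (nrow(s) >= 2) cov(s) else matrix(NA_real_, 2, 2)
    tibble(group = gl, n = nrow(s),
           mean_pc1 = mean(s[, 1]), mean_pc2 = mean(s[, 2]),
           var_pc1 = cv[1, 1], var_pc2 = cv[2, 2], cov_pc12 = cv[1, 2])
  })

  structure(
    list(scores = scores,
         loadings = as_tibble(pr$rotation, rownames = "protein"),
         var_explained = ve,
         ellipses = ellipses,
         rotation = pr$rotation, center = pr$center, sdev = pr$sdev,
         scale = pr$scale),
    class = "ecsig_pca"
  )
}

#' Simulate draws from the per-group bivariate-normal score densities
#'
#' Samples (PC1, PC2) points from each group's fitted bivariate normal —
#' the simulated-density rendering of the score plot. Groups whose
#' covariance is undefined (single sample) are skipped.
#'
#' @param pca An `ecsig_pca`.
#' @param n Draws per group.
#' @param seed Integer seed.
#' @return Tibble: `group`, `PC1`, `PC2`.
#' @export
density_draws <- function(pca, n = 500, seed = 1L) {
  stopifnot(inherits(pca, "ecsig_pca"))
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(pca$ellipses)), function(i) {
      e <- pca$ellipses[i, ]
      if (is.na(e$var_pc1)) return(tibble())
      sigma <- matrix(c(e$var_pc1, e$cov_pc12, e$cov_pc12, e$var_pc2), 2, 2)
      d <- MASS::mvrnorm(n, mu = c(e$mean_pc1, e$mean_pc2), Sigma = sigma)
      tibble(group = e$group, PC1 = d[, 1], PC2 = d[, 2])
    })
  })
}

#' @method tidy ecsig_pca
#' @export
tidy.ecsig_pca <- function(x, ...) x$scores

#' @method glance ecsig_pca
#' @export
glance.ecsig_pca <- function(x, ...) {
  tibble(
    n_components = length(x$var_explained),
    var_pc1 = x$var_explained[1],
    var_pc2 = if (length(x$var_explained) >= 2) x$var_explained[2] else NA_real_
  )
}
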