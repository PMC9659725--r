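#' Configure an end-to-end pipeline run
#'
#' Bundles every tunable of the behavioral and proteomic stages with the
#' input locations and the seed. Inputs may be TSV paths or in-memory
#' objects; anything left `NULL` is simulated from the package's synthetic
#' generators under `seed`, which gives a self-contained, fully
#' reproducible demo run.
#'
#' @param behavior Long behavioral table (tibble) or TSV path; `NULL` to
#'   simulate a default cohort.
#' @param psm Peptide table (tibble) or TSV path; `NULL` to simulate a
#'   small table with known peptide sharing.
#' @param counts Protein x sample count matrix (or TSV path, first column =
#'   protein); `NULL` to simulate spectral counts with planted effects.
#' @param sample_groups Sample annotation for `counts` (required when
#'   `counts` is supplied).
#' @param control_group Control arm label for z-scoring.
#' @param treated_groups Arms classified for response; default: every
#'   non-control arm.
#' @param baseline_session,followup_session Sessions compared for response.
#' @param threshold_pct Responder threshold, percent reduction in (0, 100].
#' @param baseline_floor See [classify_responders()].
#' @param alpha Significance level in (0, 1).
#' @param bh Apply Benjamini-Hochberg adjustment to the per-protein group
#'   test family (default `TRUE`).
#' @param offset Library-size offset in the Poisson model (default `TRUE`).
#' @param proteome_config Optional [proteome_sim_config()] for the
#'   simulated count matrix.
#' @param seed Integer master seed for every simulated input.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(behavior = NULL, psm = NULL, counts = NULL,
                            sample_groups = NULL,
                            control_group = "Veh/Veh",
                            treated_groups = NULL,
                            baseline_session = "W5",
                            followup_session = "W10",
                            threshold_pct = 50,
                            baseline_floor = 0.1,
                            alpha = 0.05,
                            bh = TRUE,
                            offset = TRUE,
                            proteome_config = NULL,
                            seed = 1L) {
  check_number(threshold_pct, "threshold_pct", lower = 0, upper = 100,
               open_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  if (!is.null(counts) && is.null(sample_groups) && !is.character(counts)) {
    stop_schema("`sample_groups` is required when `counts` is supplied")
  }
  structure(
    list(behavior = behavior, psm = psm, counts = counts,
         sample_groups = sample_groups, control_group = control_group,
         treated_groups = treated_groups,
         baseline_session = baseline_session,
         followup_session = followup_session,
         threshold_pct = threshold_pct, baseline_floor = baseline_floor,
         alpha = alpha, bh = bh, offset = offset,
         proteome_config = proteome_config, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

read_tsv_quiet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

load_behavior <- function(config) {
  b <- config$behavior
  if (is.null(b)) {
    return(simulate_behavior_cohort(cohort_config(seed = config$seed)))
  }
  if (is.character(b)) b <- read_tsv_quiet(b)
  check_columns(b, c("animal", "group", "session", "test", "measure",
                     "value"), "behavior input")
  if (!"censored" %in% names(b)) b$censored <- FALSE
  b
}

load_counts <- function(config) {
  cm <- config$counts
  if (is.null(cm)) {
    pc <- config$proteome_config %||%
      proteome_sim_config(n_proteins = 60, n_samples_per_group = 3,
                          baseline_rate = 10, frac_de = 0.2,
                          prop_down = 0.25, fold_change = 4,
                          seed = config$seed)
    sim <- simulate_spectral_counts(pc)
    return(list(counts = sim$counts, samples = sim$samples,
                truth = sim$truth))
  }
  if (is.character(cm)) {
    tab <- read_tsv_quiet(cm)
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab[[1]]
    cm <- m
  }
  sg <- config$sample_groups
  if (is.null(sg)) stop_schema("`sample_groups` missing for supplied counts")
  if (is.character(sg) && length(sg) == 1 && file.exists(sg)) {
    sg <- read_tsv_quiet(sg)
  }
  list(counts = cm, samples = sg, truth = NULL)
}

write_stage <- function(x, dir, name) {
  readr::write_tsv(x, file.path(dir, name))
  name
}

#' Run the full behavioral + proteomic pipeline
#'
#' Executes every stage in order — emotionality scoring, responder
#' classification, behavioral inference (normality-gated location tests per
#' measure; Kaplan-Meier and log-rank on the feeding latency), proteomic
#' identification filtering / grouping / count assembly, per-protein
#' Poisson differential tests with BH adjustment, pairwise direction calls,
#' and UPGMA biclustering + PCA of the significant proteins — writing each
#' result as TSV into `out_dir` together with a JSON manifest and a log.
#' Identical configuration and seed give byte-identical outputs; on error
#' the partially written directory is removed (when this call created it).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; may exist but is overwritten).
#' @return Invisibly, a list of class `ecsig_run` with the in-memory
#'   results and the file names written.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  run <- function() {
    files <- character(0)
    res <- list()

    # ---- behavioral arm ----
    behavior <- load_behavior(config)
    if (!config$control_group %in% behavior$group) {
      stop_schema(sprintf(
        "control_group: '%s' not found among behavior groups (%s)",
        config$control_group,
        paste(unique(behavior$group), collapse = ", ")
      ))
    }
    note("behavior: %d rows, %d animals, %d group(s)",
         nrow(behavior), n_distinct(behavior$animal),
         n_distinct(behavior$group))
    files <- c(files, write_stage(behavior, out_dir, "behavior.tsv"))

    scores <- emotionality_scores(behavior,
                                  control_group = config$control_group)
    res$scores <- scores
    files <- c(files, write_stage(scores, out_dir, "scores.tsv"))

    treated <- config$treated_groups %||%
      setdiff(unique(behavior$group), config$control_group)
    calls <- classify_responders(
      scores %>% filter(.data$group %in% treated),
      baseline_session = config$baseline_session,
      followup_session = config$followup_session,
      threshold_pct = config$threshold_pct,
      baseline_floor = config$baseline_floor
    )
    res$responders <- calls
    files <- c(files, write_stage(as_tibble(calls), out_dir,
                                  "responders.tsv"))
    files <- c(files, write_stage(glance(calls), out_dir,
                                  "responder_summary.tsv"))
    note("response: %d responder(s), %d non-responder(s), %d indeterminate",
         sum(calls$call == "responder"), sum(calls$call == "non_responder"),
         sum(calls$call == "indeterminate"))

    # per-measure location tests at follow-up (latency handled by KM below)
    follow <- behavior %>% filter(.data$session == config$followup_session)
    meas <- setdiff(unique(follow$measure), "latency_to_feed")
    reports <- purrr::map_dfr(meas, function(m) {
      d <- follow %>% filter(.data$measure == m)
      out <- tryCatch(
        glance(gated_location_test(d, value, group)),
        ecsig_stat_error = function(e) {
          note("location test skipped for %s: %s", m, conditionMessage(e))
          NULL
        }
      )
      if (!is.null(out)) mutate(out, measure = m, .before = 1) else NULL
    })
    res$behavior_tests <- reports
    files <- c(files, write_stage(reports, out_dir, "behavior_tests.tsv"))

    nsf <- follow %>%
      filter(.data$measure == "latency_to_feed") %>%
      mutate(latency = .data$value) %>%
      select("animal", "group", "latency", "censored")
    if (nrow(nsf) > 0) {
      km <- km_estimate(nsf)
      res$km <- km
      files <- c(files, write_stage(as_tibble(km), out_dir,
                                    "km_curves.tsv"))
      lr <- tryCatch(logrank_test(nsf), ecsig_stat_error = function(e) {
        note("log-rank skipped: %s", conditionMessage(e)); NULL
      })
      if (!is.null(lr)) {
        res$logrank <- lr
        files <- c(files, write_stage(tidy(lr), out_dir,
                                      "nsf_logrank.tsv"))
      }
    }

    # ---- proteomic arm: identification on the PSM table ----
    psm <- config$psm
    if (is.null(psm)) {
      psm <- simulate_psm_table(
        n_proteins = 6,
        ambiguity_spec = tibble(
          peptide = c("SHAREDPEPK", "SHAREDPEPR"),
          proteins = c("PROT001;PROT002", "PROT002;PROT003")
        ),
        seed = config$seed
      )
    } else if (is.character(psm)) {
      psm <- read_tsv_quiet(psm)
    }
    filt <- filter_identifications(psm)
    groups <- group_proteins(filt)
    res$protein_groups <- groups
    files <- c(files, write_stage(filt$proteins, out_dir,
                                  "protein_evidence.tsv"))
    files <- c(files, write_stage(groups, out_dir, "protein_groups.tsv"))
    note("identification: %d/%d protein(s) retained, %d group(s)",
         sum(filt$proteins$retained), nrow(filt$proteins),
         n_distinct(groups$group))
    if (nrow(groups) > 0) {
      psm_counts <- withCallingHandlers(
        assemble_counts(groups, filt$peptides),
        warning = function(w) {
          note("assembly: %s", conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
      files <- c(files, write_stage(
        as_tibble(psm_counts, rownames = "protein"),
        out_dir, "psm_counts.tsv"
      ))
    }

    # ---- differential abundance on the quantitative matrix ----
    quant <- load_counts(config)
    files <- c(files, write_stage(
      as_tibble(quant$counts, rownames = "protein"), out_dir, "counts.tsv"
    ))
    if (!is.null(quant$truth)) {
      files <- c(files, write_stage(quant$truth, out_dir, "truth.tsv"))
    }
    dt <- poisson_group_test(quant$counts, quant$samples,
                             offset = config$offset)
    dt$p_adjusted <- if (config$bh) bh_adjust(dt$p_value) else dt$p_value
    res$differential <- dt
    files <- c(files, write_stage(dt, out_dir, "differential.tsv"))

    ct <- pairwise_contrasts(quant$counts, quant$samples,
                             alpha = config$alpha)
    res$contrasts <- ct
    files <- c(files, write_stage(ct, out_dir, "contrasts.tsv"))
    files <- c(files, write_stage(contrast_summary(ct), out_dir,
                                  "contrast_summary.tsv"))

    sig <- dt$protein[!is.na(dt$p_adjusted) &
                        dt$p_adjusted < config$alpha]
    note("differential: %d significant protein(s) at alpha = %g (%s)",
         length(sig), config$alpha,
         if (config$bh) "BH-adjusted" else "raw p")

    # ---- multivariate summary of the significant set ----
    if (length(sig) >= 2 && ncol(quant$counts) >= 3) {
      sub <- quant$counts[sig, , drop = FALSE]
      bic <- upgma_bicluster(sub)
      res$bicluster <- bic
      export_linkage(bic, file.path(out_dir, "linkage"))
      files <- c(files, file.path("linkage", c("rows.nwk", "cols.nwk",
                                               "rows_merges.tsv",
                                               "cols_merges.tsv")))
      pca <- pca_with_group_densities(sub, quant$samples)
      res$pca <- pca
      files <- c(files, write_stage(pca$scores, out_dir, "pca_scores.tsv"))
      files <- c(files, write_stage(
        tibble(component = paste0("PC", seq_along(pca$var_explained)),
               var_explained = pca$var_explained),
        out_dir, "pca_variance.tsv"
      ))
      files <- c(files, write_stage(pca$ellipses, out_dir,
                                    "pca_ellipses.tsv"))
    } else {
      note("multivariate stage skipped: %d significant protein(s)",
           length(sig))
    }

    # ---- manifest + log ----
    manifest <- list(
      package = "ecsig",
      version = as.character(utils::packageVersion("ecsig")),
      seed = config$seed,
      config = purrr::map(
        config[setdiff(names(config),
                       c("behavior", "psm", "counts", "sample_groups",
                         "proteome_config"))],
        identity
      ),
      inputs = list(
        behavior = input_label(config$behavior),
        psm = input_label(config$psm),
        counts = input_label(config$counts)
      ),
      files = sort(files)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "log.txt"))

    res$files <- c(sort(files), "manifest.json", "log.txt")
    res$out_dir <- out_dir
    class(res) <- "ecsig_run"
    invisible(res)
  }

  tryCatch(
    suppressMessages(run()),
    error = function(e) {
      if (created) unlink(out_dir, recursive = TRUE)
      abort(sprintf("pipeline failed: %s", conditionMessage(e)),
            class = class(e)[1], parent = e)
    }
  )
}

input_label <- function(x) {
  if (is.null(x)) "simulated" else if (is.character(x)) x else "in-memory"
}
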