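#' Configure a synthetic spectral-count experiment
#'
#' Counts are Poisson with rate = `baseline_rate` x per-sample library factor
#' x fold effect; a fraction `frac_de` of proteins carries a planted
#' multiplicative group effect in the affected group (`fold_change` for
#' up-regulated proteins, `1 / fold_change` for the down-regulated fraction
#' `prop_down`). Library factors are drawn log-uniformly inside
#' `library_size_variation` to emulate run-to-run depth differences.
#'
#' @param n_proteins Number of protein rows.
#' @param n_samples_per_group Samples (animals) per group.
#' @param groups Group labels, in order; `affected_group` defaults to the
#'   last one.
#' @param affected_group Group whose samples receive the planted effects.
#' @param baseline_rate Mean spectral count per protein per sample (> 0).
#' @param frac_de Fraction of proteins with a planted effect, in \[0, 1\].
#' @param prop_down Fraction of the planted proteins that are down- rather
#'   than up-regulated.
#' @param fold_change Multiplicative effect (> 0) on the Poisson rate.
#' @param library_size_variation Length-2 range of per-sample multiplicative
#'   depth factors.
#' @param seed Integer seed.
#' @return An object of class `proteome_sim_config`.
#' @export
proteome_sim_config <- function(n_proteins = 100,
                                n_samples_per_group = 3,
                                groups = c("Cort/Veh", "Flx-NR", "Flx-NR-ECS"),
                                affected_group = groups[length(groups)],
                                baseline_rate = 10,
                                frac_de = 0.1,
                                prop_down = 0,
                                fold_change = 4,
                                library_size_variation = c(0.8, 1.25),
                                seed = 1L) {
  check_number(n_proteins, "n_proteins", lower = 1)
  check_number(n_samples_per_group, "n_samples_per_group", lower = 1)
  check_number(baseline_rate, "baseline_rate", lower = 0, open_lower = TRUE)
  check_number(frac_de, "frac_de", lower = 0, upper = 1)
  check_number(prop_down, "prop_down", lower = 0, upper = 1)
  check_number(fold_change, "fold_change", lower = 0, open_lower = TRUE)
  if (length(library_size_variation) != 2 ||
      any(library_size_variation <= 0) ||
      diff(library_size_variation) < 0) {
    stop_config("`library_size_variation` must be an increasing positive pair")
  }
  if (!affected_group %in% groups) {
    stop_config("`affected_group` is not one of `groups`")
  }
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      n_samples_per_group = as.integer(n_samples_per_group),
      groups = groups, affected_group = affected_group,
      baseline_rate = baseline_rate, frac_de = frac_de,
      prop_down = prop_down, fold_change = fold_change,
      library_size_variation = library_size_variation,
      seed = as.integer(seed)
    ),
    class = "proteome_sim_config"
  )
}

#' Simulate a spectral-count matrix with known ground truth
#'
#' @param config A [proteome_sim_config()].
#' @return A list of class `sc_sim`:
#'   \describe{
#'     \item{counts}{integer matrix, proteins x samples, with dimnames.}
#'     \item{samples}{tibble `sample`, `group`, `lib_factor`.}
#'     \item{truth}{tibble `protein`, `is_de`, `direction` (`"up"`/`"down"`,
#'       `NA` for null proteins), `fold` (rate multiplier in the affected
#'       group).}
#'   }
#' @export
simulate_spectral_counts <- function(config) {
  stopifnot(inherits(config, "proteome_sim_config"))
  withr::with_seed(config$seed, {
    proteins <- sprintf("PROT%04d", seq_len(config$n_proteins))
    samples <- tibble(
      group = rep(config$groups, each = config$n_samples_per_group),
      sample = sprintf(
        "%s_%d",
        gsub("[^A-Za-z0-9]+", ".",
             rep(config$groups, each = config$n_samples_per_group)),
        rep(seq_len(config$n_samples_per_group), times = length(config$groups))
      )
    )
    lsv <- config$library_size_variation
    samples$lib_factor <- exp(runif(nrow(samples), log(lsv[1]), log(lsv[2])))

    n_de <- round(config$frac_de * config$n_proteins)
    n_down <- round(config$prop_down * n_de)
    de_idx <- if (n_de > 0) sample.int(config$n_proteins, n_de) else integer(0)
    down_idx <- if (n_down > 0) de_idx[seq_len(n_down)] else integer(0)

    fold <- rep(1, config$n_proteins)
    fold[de_idx] <- config$fold_change
    fold[down_idx] <- 1 / config$fold_change

    truth <- tibble(
      protein = proteins,
      is_de = seq_len(config$n_proteins) %in% de_idx,
      direction = dplyr::case_when(
        seq_len(config$n_proteins) %in% down_idx ~ "down",
        seq_len(config$n_proteins) %in% de_idx ~ "up",
        TRUE ~ NA_character_
      ),
      fold = fold
    )

    affected <- samples$group == config$affected_group
    rate <- outer(rep(config$baseline_rate, config$n_proteins),
                  samples$lib_factor)
    rate[, affected] <- rate[, affected] * fold

    counts <- matrix(
      rpois(length(rate), as.vector(rate)),
      nrow = config$n_proteins,
      dimnames = list(proteins, samples$sample)
    )
    structure(
      list(counts = counts, samples = samples[, c("sample", "group",
                                                  "lib_factor")],
           truth = truth),
      class = "sc_sim"
    )
  })
}

#' Simulate a peptide-spectrum-match table with controlled peptide sharing
#'
#' Generates per-protein specific peptides plus, optionally, peptides shared
#' between proteins according to `ambiguity_spec`, with E-values drawn
#' log-uniformly across a range spanning the usual identification
#' thresholds, and Poisson per-sample spectrum counts. This feeds the
#' identification filter and the shared-peptide grouping stages with a known
#' ambiguity structure.
#'
#' @param n_proteins Number of protein accessions (`PROT001`, ...).
#' @param ambiguity_spec Optional tibble with columns `peptide` (label) and
#'   `proteins` (semicolon-separated accessions sharing that peptide).
#'   Duplicate peptide labels with conflicting protein sets are a
#'   configuration error.
#' @param n_samples Number of samples with spectrum counts.
#' @param peptides_per_protein Specific peptides generated per protein.
#' @param evalue_range Range of peptide E-values (log-uniform draw).
#' @param mean_spectra Mean per-sample spectrum count of a peptide.
#' @param seed Integer seed.
#' @return Tibble with columns `peptide`, `evalue`, `proteins`
#'   (semicolon-separated accessions), `sample`, `spectra`.
#' @export
simulate_psm_table <- function(n_proteins,
                               ambiguity_spec = NULL,
                               n_samples = 6,
                               peptides_per_protein = 4,
                               evalue_range = c(1e-6, 0.05),
                               mean_spectra = 3,
                               seed = 1L) {
  check_number(n_proteins, "n_proteins", lower = 1)
  proteins <- sprintf("PROT%03d", seq_len(n_proteins))
  if (!is.null(ambiguity_spec)) {
    check_columns(ambiguity_spec, c("peptide", "proteins"), "ambiguity_spec")
    dup <- ambiguity_spec %>%
      distinct(.data$peptide, .data$proteins) %>%
      count(.data$peptide) %>%
      filter(.data$n > 1)
    if (nrow(dup) > 0) {
      stop_config(sprintf(
        "ambiguity_spec lists peptide(s) with conflicting protein sets: %s",
        paste(dup$peptide, collapse = ", ")
      ))
    }
    ambiguity_spec <- distinct(ambiguity_spec, .data$peptide, .data$proteins)
    mapped <- unlist(strsplit(ambiguity_spec$proteins, ";", fixed = TRUE))
    bad <- setdiff(trimws(mapped), proteins)
    if (length(bad) > 0) {
      stop_config(sprintf("ambiguity_spec names unknown accession(s): %s",
                          paste(unique(bad), collapse = ", ")))
    }
  }

  withr::with_seed(seed, {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
    random_peptide <- function(n) {
      vapply(seq_len(n), function(i) {
        paste0(paste(sample(aa, sample(8:14, 1), replace = TRUE),
                     collapse = ""), "K")
      }, character(1))
    }
    specific <- tibble(
      proteins = rep(proteins, each = peptides_per_protein),
      peptide = random_peptide(n_proteins * peptides_per_protein)
    )
    peps <- bind_rows(
      specific,
      if (!is.null(ambiguity_spec)) {
        tibble(proteins = gsub("\\s+", "", ambiguity_spec$proteins),
               peptide = ambiguity_spec$peptide)
      }
    )
    peps$evalue <- exp(runif(nrow(peps),
                             log(evalue_range[1]), log(evalue_range[2])))
    tidyr::crossing(peps, sample = sprintf("S%02d", seq_len(n_samples))) %>%
      mutate(spectra = rpois(dplyr::n(), mean_spectra)) %>%
      select("peptide", "evalue", "proteins", "sample", "spectra") %>%
      arrange(.data$peptide, .data$sample)
  })
}
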