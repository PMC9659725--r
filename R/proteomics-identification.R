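# Identification-level processing of a post-search peptide table:
# E-value filtering, shared-peptide protein grouping, spectral-count
# assembly. The input is the flat PSM/peptide table a search pipeline
# exports: peptide, evalue, proteins (semicolon-separated accessions),
# sample, spectra.

normalise_psm <- function(psms) {
  check_columns(psms, c("peptide", "evalue", "proteins"), "peptide table")
  if (any(is.na(psms$evalue)) || any(psms$evalue <= 0)) {
    stop_schema("peptide E-values must be positive and non-missing")
  }
  if (!"sample" %in% names(psms)) psms$sample <- "S01"
  if (!"spectra" %in% names(psms)) psms$spectra <- 1L
  if (any(psms$spectra < 0) || any(psms$spectra != floor(psms$spectra))) {
    stop_schema("spectrum counts must be non-negative integers")
  }
  long <- psms %>%
    mutate(proteins = gsub("\\s+", "", .data$proteins)) %>%
    mutate(protein = strsplit(.data$proteins, ";", fixed = TRUE)) %>%
    tidyr::unnest("protein") %>%
    select("peptide", "evalue", "protein", "sample", "spectra")
  if (any(long$protein == "")) stop_schema("empty protein accession found")

  # one E-value per peptide sequence; conflicting reports collapse to the min
  ev <- long %>% distinct(.data$peptide, .data$evalue)
  if (anyDuplicated(ev$peptide)) {
    warn("peptides reported with multiple E-values; keeping the minimum")
    long <- long %>%
      group_by(.data$peptide) %>%
      mutate(evalue = min(.data$evalue)) %>%
      ungroup()
  }
  dup <- anyDuplicated(long[, c("peptide", "protein", "sample")])
  if (dup) {
    warn("duplicate (peptide, protein, sample) rows collapsed (spectra summed)")
    long <- long %>%
      group_by(.data$peptide, .data$evalue, .data$protein, .data$sample) %>%
      summarise(spectra = sum(.data$spectra), .groups = "drop")
  }
  long
}

#' Filter peptide identifications and protein evidence
#'
#' Applies the three identification rules in order: (1) peptides with
#' E-value >= 0.01 are discarded; (2) each protein must keep at least two
#' distinct peptides; (3) the protein E-value — the product of its unique
#' retained peptides' E-values — must be below 1e-4. Proteins failing
#' either protein-level rule are removed together with peptide-to-protein
#' mappings that pointed only at them. The filter is idempotent and
#' independent of row order.
#'
#' @param psms Peptide table: `peptide`, `evalue`, `proteins`
#'   (semicolon-separated accessions); optional `sample`, `spectra`.
#' @param peptide_evalue_max Peptide E-value cutoff (strict `<`, default 0.01).
#' @param min_peptides Minimum distinct retained peptides per protein
#'   (default 2).
#' @param protein_evalue_max Protein E-value cutoff (strict `<`, default 1e-4).
#' @return List of class `id_filter`:
#'   \describe{
#'     \item{peptides}{long tibble of retained peptide-protein-sample rows
#'       (`peptide`, `evalue`, `protein`, `sample`, `spectra`), restricted
#'       to retained proteins.}
#'     \item{proteins}{evidence tibble: `protein`, `n_peptides`,
#'       `evalue_product`, `retained`.}
#'   }
#' @export
filter_identifications <- function(psms,
                                   peptide_evalue_max = 0.01,
                                   min_peptides = 2,
                                   protein_evalue_max = 1e-4) {
  long <- normalise_psm(psms)
  kept <- long %>% filter(.data$evalue < peptide_evalue_max)

  evidence <- kept %>%
    distinct(.data$protein, .data$peptide, .data$evalue) %>%
    group_by(.data$protein) %>%
    summarise(n_peptides = n_distinct(.data$peptide),
              evalue_product = prod(.data$evalue[!duplicated(.data$peptide)]),
              .groups = "drop") %>%
    mutate(retained = .data$n_peptides >= min_peptides &
             .data$evalue_product < protein_evalue_max)

  # proteins seen only before peptide filtering: zero retained peptides
  dropped_all <- setdiff(unique(long$protein), evidence$protein)
  if (length(dropped_all) > 0) {
    evidence <- bind_rows(
      evidence,
      tibble(protein = dropped_all, n_peptides = 0L,
             evalue_product = NA_real_, retained = FALSE)
    )
  }
  evidence <- arrange(evidence, .data$protein)

  retained_prot <- evidence$protein[evidence$retained]
  peptides <- kept %>% filter(.data$protein %in% retained_prot)

  structure(list(peptides = peptides, proteins = evidence),
            class = "id_filter")
}

#' Group proteins by shared peptides and call subgroups
#'
#' Two retained proteins sharing at least one retained peptide belong to
#' the same group; groups are the connected components of the bipartite
#' protein-peptide graph projected onto proteins (so sharing is
#' transitive). Within a group, a member with at least one peptide specific
#' to it (mapped to no other retained protein) is a subgroup — one subgroup
#' represents one distinguishable protein. Group ids are the
#' lexicographically smallest member accession, which makes them
#' deterministic.
#'
#' @param x An `id_filter` from [filter_identifications()], or a long
#'   tibble with columns `peptide`, `protein` (already filtered).
#' @return Tibble: `protein`, `group`, `is_subgroup`, `n_specific`
#'   (specific peptides), `n_peptides`; attribute `peptide_map` holds the
#'   per-peptide assignment (`peptide`, `protein`, `specific`).
#' @export
group_proteins <- function(x) {
  map <- if (inherits(x, "id_filter")) x$peptides else x
  check_columns(map, c("peptide", "protein"), "peptide-protein map")
  map <- distinct(map, .data$peptide, .data$protein)
  if (nrow(map) == 0) {
    out <- tibble(protein = character(), group = character(),
                  is_subgroup = logical(), n_specific = integer(),
                  n_peptides = integer())
    attr(out, "peptide_map") <- tibble(peptide = character(),
                                       protein = character(),
                                       specific = logical())
    return(out)
  }

  g <- igraph::graph_from_data_frame(
    tibble(from = paste0("pep:", map$peptide),
           to = paste0("prot:", map$protein)),
    directed = FALSE
  )
  comp <- igraph::components(g)$membership
  prot_names <- sub("^prot:", "", names(comp)[startsWith(names(comp), "prot:")])
  prot_comp <- comp[startsWith(names(comp), "prot:")]

  membership <- tibble(protein = prot_names, comp = unname(prot_comp)) %>%
    group_by(.data$comp) %>%
    mutate(group = min(.data$protein)) %>%
    ungroup() %>%
    select(-"comp")

  specific_map <- map %>%
    group_by(.data$peptide) %>%
    mutate(specific = n_distinct(.data$protein) == 1) %>%
    ungroup()

  out <- map %>%
    left_join(specific_map[, c("peptide", "protein", "specific")],
              by = c("peptide", "protein")) %>%
    group_by(.data$protein) %>%
    summarise(n_specific = sum(.data$specific),
              n_peptides = n(), .groups = "drop") %>%
    left_join(membership, by = "protein") %>%
    mutate(is_subgroup = .data$n_specific >= 1) %>%
    select("protein", "group", "is_subgroup", "n_specific", "n_peptides") %>%
    arrange(.data$group, .data$protein)

  attr(out, "peptide_map") <- specific_map
  out
}

#' Assemble a spectral-count matrix from grouped identifications
#'
#' Sums, per sample, the spectrum counts of the peptides assigned to each
#' subgroup. A peptide specific to one protein is counted for that
#' protein's subgroup row; a peptide shared between several proteins is
#' never attributed to any subgroup (spectral counts must not be
#' double-counted) and is accumulated instead on a group-level row named
#' `<group>/shared`. Samples with zero total spectra are dropped with a
#' warning.
#'
#' @param groups Output of [group_proteins()].
#' @param peptides Long retained peptide table (`peptide`, `protein`,
#'   `sample`, `spectra`), e.g. `filter_identifications(...)$peptides`.
#' @return Integer matrix, rows = subgroups (accession) plus any
#'   `<group>/shared` rows, columns = samples.
#' @export
assemble_counts <- function(groups, peptides) {
  check_columns(peptides, c("peptide", "protein", "sample", "spectra"),
                "peptide table")
  pm <- attr(groups, "peptide_map")
  if (is.null(pm)) stop_schema("`groups` must come from group_proteins()")

  # one row per peptide x sample, with its assignment target
  assignment <- pm %>%
    left_join(groups[, c("protein", "group")], by = "protein") %>%
    group_by(.data$peptide) %>%
    summarise(
      target = if (dplyr::first(.data$specific)) {
        dplyr::first(.data$protein)
      } else {
        paste0(dplyr::first(.data$group), "/shared")
      },
      .groups = "drop"
    )

  per_sample <- peptides %>%
    distinct(.data$peptide, .data$sample, .data$spectra) %>%
    inner_join(assignment, by = "peptide") %>%
    group_by(.data$target, .data$sample) %>%
    summarise(spectra = sum(.data$spectra), .groups = "drop")

  subgroup_rows <- sort(groups$protein[groups$is_subgroup])
  shared_rows <- sort(unique(
    assignment$target[grepl("/shared$", assignment$target)]
  ))
  rows <- c(subgroup_rows, shared_rows)
  samples <- sort(unique(peptides$sample))

  m <- matrix(0L, nrow = length(rows), ncol = length(samples),
              dimnames = list(rows, samples))
  idx <- cbind(match(per_sample$target, rows),
               match(per_sample$sample, samples))
  keep <- !is.na(idx[, 1])
  m[idx[keep, , drop = FALSE]] <- as.integer(per_sample$spectra[keep])

  empty <- colSums(m) == 0
  if (any(empty)) {
    warn(sprintf("dropping sample(s) with zero total spectra: %s",
                 paste(colnames(m)[empty], collapse = ", ")))
    m <- m[, !empty, drop = FALSE]
  }
  m
}
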