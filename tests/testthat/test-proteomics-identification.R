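psm_row <- function(peptide, evalue, proteins, sample = "S1", spectra = 1L) {
  tibble::tibble(peptide = peptide, evalue = evalue, proteins = proteins,
                 sample = sample, spectra = spectra)
}

test_that("the three identification rules are applied in order", {
  psm <- dplyr::bind_rows(
    psm_row(c("p1", "p2"), c(1e-3, 1e-3), "KEEP"),     # product 1e-6 < 1e-4
    psm_row("p3", 1e-9, "ONEPEP"),                     # one peptide only
    psm_row(c("p4", "p5"), c(5e-3, 5e-2), "LOSTPEP"),  # p5 fails E < 0.01
    psm_row(c("p6", "p7"), c(5e-3, 5e-3), "WEAK")      # product 2.5e-5 ok
  )
  res <- filter_identifications(psm)
  ev <- res$proteins
  expect_true(ev$retained[ev$protein == "KEEP"])
  expect_equal(ev$evalue_product[ev$protein == "KEEP"], 1e-6)
  expect_false(ev$retained[ev$protein == "ONEPEP"])
  expect_false(ev$retained[ev$protein == "LOSTPEP"])
  expect_equal(ev$n_peptides[ev$protein == "LOSTPEP"], 1L)
  expect_true(ev$retained[ev$protein == "WEAK"])
  # peptides mapping only to removed proteins disappear from the output
  expect_false(any(res$peptides$protein %in% c("ONEPEP", "LOSTPEP")))
})

test_that("a borderline product fails the strict < 1e-4 cutoff", {
  psm <- psm_row(c("q1", "q2"), c(1e-2 / 2, 4e-2 / 1), "X")  # q2 >= 0.01
  res <- filter_identifications(psm)
  expect_false(res$proteins$retained[1])
  # product exactly at the threshold is rejected
  psm2 <- psm_row(c("r1", "r2"), c(1e-2, 1e-2), "Y")  # both at the peptide cap
  expect_false(filter_identifications(psm2)$proteins$retained[1])
  psm3 <- psm_row(c("s1", "s2"), c(9.9e-3, 9.9e-3), "Z")  # product 9.8e-5
  expect_true(filter_identifications(psm3)$proteins$retained[1])
})

test_that("filtering is idempotent, order-independent, and collapses duplicates", {
  psm <- simulate_psm_table(6, seed = 14, evalue_range = c(1e-6, 0.05))
  r1 <- filter_identifications(psm)
  r2 <- filter_identifications(psm[sample(nrow(psm)), ])
  expect_equal(dplyr::arrange(r1$proteins, protein),
               dplyr::arrange(r2$proteins, protein))
  # re-filtering the retained table changes nothing
  again <- filter_identifications(
    r1$peptides |>
      dplyr::rename(proteins = protein)
  )
  expect_setequal(again$proteins$protein[again$proteins$retained],
                  r1$proteins$protein[r1$proteins$retained])
  dup <- dplyr::bind_rows(psm, psm[1, ])
  expect_warning(filter_identifications(dup), "collapsed")
})

test_that("grouping merges shared peptides transitively into components", {
  # A,B share pep1; C disjoint -> {A,B}, {C}
  map <- tibble::tibble(
    peptide = c("pep1", "pep1", "pepA", "pepB", "pepC1", "pepC2"),
    protein = c("A", "B", "A", "B", "C", "C")
  )
  g <- group_proteins(map)
  expect_equal(g$group[g$protein == "A"], "A")
  expect_equal(g$group[g$protein == "B"], "A")
  expect_equal(g$group[g$protein == "C"], "C")
  # transitivity: A-B via p1, B-C via p2 -> one group
  map2 <- tibble::tibble(
    peptide = c("p1", "p1", "p2", "p2", "pa", "pb", "pc"),
    protein = c("A", "B", "B", "C", "A", "B", "C")
  )
  g2 <- group_proteins(map2)
  expect_equal(unique(g2$group), "A")
  expect_equal(nrow(g2), 3)
})

test_that("subgroups require a specific peptide; shared-only members get none", {
  # A has specific p3; B only shares
  map <- tibble::tibble(
    peptide = c("p1", "p1", "p3"),
    protein = c("A", "B", "A")
  )
  g <- group_proteins(map)
  expect_true(g$is_subgroup[g$protein == "A"])
  expect_false(g$is_subgroup[g$protein == "B"])
  # two proteins sharing all peptides: one group, no subgroups
  map2 <- tibble::tibble(peptide = rep(c("x1", "x2"), each = 2),
                         protein = rep(c("A", "B"), 2))
  g2 <- group_proteins(map2)
  expect_equal(unique(g2$group), "A")
  expect_false(any(g2$is_subgroup))
  # disjoint peptide sets: one group per protein, each its own subgroup
  map3 <- tibble::tibble(peptide = c("y1", "y2"), protein = c("A", "B"))
  g3 <- group_proteins(map3)
  expect_equal(g3$group, c("A", "B"))
  expect_true(all(g3$is_subgroup))
})

test_that("grouping equals a union-find oracle on random bipartite maps", {
  set.seed(15)
  for (i in 1:25) {
    n_prot <- sample(3:10, 1)
    n_pep <- sample(3:12, 1)
    map <- tibble::tibble(
      peptide = sprintf("pep%02d", sample(n_pep, n_pep * 2, replace = TRUE)),
      protein = sprintf("PR%02d", sample(n_prot, n_pep * 2, replace = TRUE))
    ) |> dplyr::distinct()
    g <- group_proteins(map)
    orc <- oracle_components(map)
    expect_equal(stats::setNames(g$group, g$protein), orc[g$protein])
  }
})

test_that("counts sum per subgroup; shared peptides go to a group-level row", {
  psm <- dplyr::bind_rows(
    psm_row(c("a1", "a2"), 1e-4, "A", "S1", c(3L, 2L)),
    psm_row(c("a1", "a2"), 1e-4, "A", "S2", c(1L, 1L)),
    psm_row(c("b1", "b2"), 1e-4, "B", "S1", c(4L, 1L)),
    psm_row(c("b1", "b2"), 1e-4, "B", "S2", c(2L, 2L)),
    psm_row("sh", 1e-4, "A;B", "S1", 5L),
    psm_row("sh", 1e-4, "A;B", "S2", 7L)
  )
  filt <- filter_identifications(psm)
  grp <- group_proteins(filt)
  m <- assemble_counts(grp, filt$peptides)
  expect_equal(m["A", "S1"], 5L)  # 3 + 2, shared excluded
  expect_equal(m["B", "S1"], 5L)
  expect_equal(m["A/shared", "S1"], 5L)
  expect_equal(m["A/shared", "S2"], 7L)
  expect_equal(sort(rownames(m)), c("A", "A/shared", "B"))
})

test_that("samples with zero total spectra are dropped with a warning", {
  psm <- dplyr::bind_rows(
    psm_row(c("a1", "a2"), 1e-4, "A", "S1", c(3L, 2L)),
    psm_row(c("a1", "a2"), 1e-4, "A", "S2", c(0L, 0L))
  )
  filt <- filter_identifications(psm)
  grp <- group_proteins(filt)
  expect_warning(m <- assemble_counts(grp, filt$peptides), "zero total")
  expect_equal(colnames(m), "S1")
})
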