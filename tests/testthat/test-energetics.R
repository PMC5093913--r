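# a three-heavy-atom chain whose bend angle distinguishes geometries under
# heavy-atom deduplication
bent_chain <- function(bend, e) {
  th <- bend * pi / 180
  conformer(
    data.frame(
      element = c("N", "C", "O"),
      x = c(0, 1.4, 1.4 + 1.4 * cos(th)),
      y = c(0, 0, 1.4 * sin(th)),
      z = 0
    ),
    energy = e, meta = list(system = "chain")
  )
}

test_that("hierarchies sort, deduplicate and convert units", {
  ens <- ensemble_tbl(
    list(bent_chain(0, -9.5), bent_chain(60, -10.0), bent_chain(120, -9.5)),
    system = "w"
  )
  h <- build_hierarchy(ens)
  expect_equal(h$entries$rank, 0:2)
  expect_equal(h$entries$rel_ev, c(0, 0.5, 0.5))
  expect_equal(h$entries$rel_kjmol, c(0, 0.5, 0.5) * 96.485, tolerance = 1e-9)
  expect_equal(h$n_merged, 0)
  # an exact duplicate geometry is merged into the lower-energy copy
  dup <- bent_chain(60, -9.7)
  ens2 <- dplyr::bind_rows(ens, ensemble_tbl(list(dup), system = "w"))
  ens2$frame <- seq_len(nrow(ens2)) - 1L
  h2 <- build_hierarchy(ens2)
  expect_equal(nrow(h2$entries), 3)
  expect_equal(h2$n_merged, 1)
  expect_equal(h2$entries$energy[1], -10.0) # global minimum survives dedup
  expect_error(build_hierarchy(ens[0, ]), class = "pepc_error_energetics")
})

test_that("conformer counting respects the energy window", {
  ens <- ensemble_tbl(
    list(bent_chain(0, -10), bent_chain(60, -9.6), bent_chain(120, -9.0)),
    system = "w"
  )
  h <- build_hierarchy(ens)
  expect_equal(count_conformers(h), 3)
  expect_equal(count_conformers(h, 0), 1)
  expect_equal(count_conformers(h, 0.5), 2)
  expect_error(count_conformers(h, -1), class = "pepc_error_energetics")
})

test_that("binding energy arithmetic, sign convention and linearity hold", {
  expect_equal(binding_energy(-10, -4, -5), 1)
  expect_equal(binding_energy(-9, -4, -5), 0)
  d <- 0.37
  expect_equal(
    binding_energy(-10 + d, -4, -5),
    binding_energy(-10, -4, -5) - d
  )
  # unit round trip
  e <- 1.234567
  expect_equal(e * 96.485 / 96.485, e, tolerance = 1e-12)
})

test_that("affinity ranking and ion ordering sort strongest first with tie flags", {
  tr <- trend_table(tibble::tibble(
    ligand = rep(c("A", "B", "C"), each = 2),
    ion = rep(c("Ca", "Ba"), 3),
    e_bind = c(3, 2.0, 1, 0.5, 2, 2.0)
  ))
  r <- affinity_ranking(tr, "Ca")
  expect_equal(r$ligand, c("A", "C", "B"))
  ties <- trend_table(tibble::tibble(
    ligand = c("A", "B"), ion = "Ca", e_bind = c(1, 1)
  ))
  rt <- affinity_ranking(ties, "Ca")
  expect_equal(rt$ligand, c("A", "B")) # lexicographic tie break
  expect_true(all(rt$tied))
  io <- ion_ordering(tr, "A")
  expect_equal(io$ion, c("Ca", "Ba"))
  expect_error(ion_ordering(tr, "Z"), class = "pepc_error_energetics")
  expect_error(affinity_ranking(tr, "Hg"), class = "pepc_error_energetics")
})

test_that("rank concordance reproduces exact and brute-force Kendall values", {
  a <- c(A = 1, B = 2, C = 3, D = 4)
  expect_equal(rank_concordance(a, a)$tau, 1)
  expect_equal(rank_concordance(a, a)$max_abs_diff, 0)
  b <- setNames(rev(unname(a)), names(a))
  expect_equal(rank_concordance(a, b)$tau, -1)
  # 5-item case with a tie against the O(n^2) pair-enumeration oracle
  x <- c(A = 1.2, B = 3.4, C = 3.4, D = 0.1, E = 2.2)
  y <- c(A = 2.0, B = 1.0, C = 4.0, D = 0.5, E = 2.2)
  expect_equal(
    rank_concordance(x, y)$tau,
    oracle_kendall(unname(x), unname(y[names(x)])),
    tolerance = 1e-12
  )
  expect_error(rank_concordance(x, y[1:3]), class = "pepc_error_energetics")
  expect_error(rank_concordance(x[1], y[1]), class = "pepc_error_energetics")
})

test_that("contraction reports compare bare and complexed conformer counts", {
  bare <- tibble::tibble(system = c("a", "b"), n = c(10L, 6L))
  ion <- tibble::tibble(system = c("a", "b", "c"), n = c(4L, 3L, 2L))
  rep <- contraction_report(bare, ion)
  expect_equal(rep$ratio[rep$system == "a"], 0.4)
  expect_true(all(rep$n_ion <= rep$n_bare))
  expect_equal(attr(rep, "totals")$n_bare, 16)
  expect_equal(attr(rep, "unmatched")$ion_only, "c")
  expect_error(
    contraction_report(bare, tibble::tibble(system = "z", n = 1L)),
    class = "pepc_error_energetics"
  )
})
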