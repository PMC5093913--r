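test_that("free amino-acid conformers classify into the three backbone types", {
  tpl <- ala_free_template()
  t2 <- build_peptide(tpl, t_coo = 180, t_oh = 0, t_hn = 60)
  expect_equal(classify_free_amino_acid(t2, t2$meta$topology)$label, "typeII")
  t1 <- build_peptide(tpl, t_coo = 0, t_oh = 180, t_hn = 0)
  expect_equal(classify_free_amino_acid(t1, t1$meta$topology)$label, "typeI")
  zw <- build_peptide(tpl, t_coo = 0, backbone_form = "zwitterion", t_hn = 0)
  cl <- classify_free_amino_acid(zw, zw$meta$topology)
  expect_equal(cl$label, "zwitterionic")
  expect_true(length(cl$evidence) > 0)
  none <- build_peptide(tpl, t_coo = 90, t_oh = 180, t_hn = 150)
  expect_equal(classify_free_amino_acid(none, none$meta$topology)$label, "other")
})

test_that("cation-bound amino acids split into salt-bridge and charge-solvated", {
  tpl <- ala_free_template()
  zw <- build_peptide(tpl, t_coo = 0, backbone_form = "zwitterion", t_hn = 0)
  sb <- place_ion(zw, "carboxylate", "Ca", 2.3)
  expect_equal(
    classify_ion_amino_acid(sb, sb$meta$topology, sb$meta$ion_index)$label,
    "salt_bridge"
  )
  nt <- build_peptide(tpl, t_coo = 0, t_oh = 180, t_hn = 150)
  cs <- place_ion(nt, "amine_carbonyl", "Ca", 2.4)
  expect_equal(
    classify_ion_amino_acid(cs, cs$meta$topology, cs$meta$ion_index)$label,
    "charge_solvated"
  )
  far <- place_ion(zw, "amine_carbonyl", "Ca", 6.0)
  expect_equal(
    classify_ion_amino_acid(far, far$meta$topology, far$meta$ion_index)$label,
    "other"
  )
  # a non-cation index is rejected
  expect_error(
    classify_ion_amino_acid(sb, sb$meta$topology, 1),
    class = "pepc_error_classify"
  )
})

test_that("dipeptides classify into C5 and the two C7 mirror forms", {
  tpl <- ala_capped_template()
  c5 <- build_peptide(tpl, phi = -158, psi = 162)
  expect_equal(classify_dipeptide(c5, c5$meta$topology)$label, "C5")
  c7eq <- build_peptide(tpl, phi = -83, psi = 66, t_cb = 150)
  expect_equal(classify_dipeptide(c7eq, c7eq$meta$topology)$label, "C7eq")
  c7ax <- build_peptide(tpl, phi = 83, psi = -66, t_cb = -60)
  expect_equal(classify_dipeptide(c7ax, c7ax$meta$topology)$label, "C7ax")
  oth <- build_peptide(tpl, phi = -60, psi = 140)
  expect_equal(classify_dipeptide(oth, oth$meta$topology)$label, "other")
})

test_that("cation-closed iC7 rings classify with the expected quadrants", {
  tpl <- ala_capped_template()
  ax <- place_ion(build_peptide(tpl, phi = 60, psi = 40, t_cb = -90),
    "carbonyl_bridge", "Ca", 2.3
  )
  cl_ax <- classify_dipeptide_ion(ax, ax$meta$topology, ax$meta$ion_index)
  expect_equal(cl_ax$label, "iC7ax")
  expect_equal(quadrant(60, 40)$quadrant, "I")
  eq <- place_ion(build_peptide(tpl, phi = -60, psi = -40, t_cb = -150),
    "carbonyl_bridge", "Ca", 2.3
  )
  cl_eq <- classify_dipeptide_ion(eq, eq$meta$topology, eq$meta$ion_index)
  expect_equal(cl_eq$label, "iC7eq")
  expect_equal(quadrant(-60, -40)$quadrant, "III")
  # cation away from the backbone oxygens
  far <- place_ion(build_peptide(tpl, phi = -60, psi = 140),
    "carbonyl_bridge", "Ca", 5.5
  )
  expect_equal(
    classify_dipeptide_ion(far, far$meta$topology, far$meta$ion_index)$label,
    "other"
  )
  # no side chain: the ax/eq identity is undefined
  gly <- place_ion(
    build_peptide(residue_template("gly", "capped", 0, "none"),
      phi = 60, psi = 40
    ),
    "carbonyl_bridge", "Ca", 2.3
  )
  expect_equal(
    classify_dipeptide_ion(gly, gly$meta$topology, gly$meta$ion_index)$label,
    "other"
  )
})

test_that("Ramachandran quadrants follow the sign convention with boundary flags", {
  expect_equal(quadrant(-83, 66)$quadrant, "II")
  expect_equal(quadrant(60, 45)$quadrant, "I")
  q3 <- quadrant(-170, -160)
  expect_equal(q3$quadrant, "III")
  expect_false(q3$boundary)
  qb <- quadrant(180, 10)
  expect_true(qb$boundary)
  # vectorised
  qq <- quadrant(c(10, -10, -10, 10), c(10, 10, -10, -10))
  expect_equal(qq$quadrant, c("I", "II", "III", "IV"))
})

test_that("classification is total and deterministic on generated ensembles", {
  suite <- generate_labeled_ensembles(seed = 11, panel = suite_panel()[c(2, 4), ])
  a <- classify_conformers(suite$ensembles)
  b <- classify_conformers(suite$ensembles)
  expect_false(any(is.na(a$class)))
  expect_true(all(a$class %in% pepcation:::PEPC_CLASSES))
  expect_identical(a$class, b$class)
})

test_that("rotamer tables bin chi angles and weight by Boltzmann factors", {
  tpl <- residue_template("ser", "capped", 1, "hydroxyl")
  mk <- function(chi, e) {
    cf <- build_peptide(tpl, phi = -83, psi = 66, chis = chi)
    cf$energy <- e
    cf
  }
  # a single conformer occupies its bin with frequency 1
  one <- ensemble_tbl(list(mk(60, -1)), system = "s1")
  rt1 <- derive_rotamer_table(one)
  expect_equal(rt1$frequency, 1)
  expect_equal(rt1$chi_bin, "g+")
  # two degenerate conformers in different bins split 50/50
  two <- ensemble_tbl(list(mk(60, -1), mk(-60, -1)), system = "s2")
  rt2 <- derive_rotamer_table(two)
  expect_equal(sort(rt2$frequency), c(0.5, 0.5))
  # 0.1 eV split at 300 K reproduces the closed-form Boltzmann ratio
  three <- ensemble_tbl(list(mk(60, -1), mk(180, -0.9)), system = "s3")
  rt3 <- derive_rotamer_table(three, temperature_k = 300)
  w <- exp(-0.1 / (8.617333262e-5 * 300))
  expect_equal(
    rt3$frequency[rt3$chi_bin == "t"], w / (1 + w),
    tolerance = 1e-9
  )
  expect_equal(sum(rt3$frequency), 1, tolerance = 1e-9)
  # empty window errors
  expect_error(
    derive_rotamer_table(three, energy_window_ev = -1),
    class = "pepc_error_classify"
  )
})
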