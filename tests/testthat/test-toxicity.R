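test_that("ion reference table reproduces the packaged literature values", {
  expect_equal(ion_reference("Ca")$shannon_radius_pm, 100)
  expect_equal(ion_reference("Pb")$shannon_radius_pm, 98)
  expect_equal(ion_reference("Pb")$hydration_enthalpy_kJ_mol, -1479.9)
  expect_equal(ion_reference("Ca")$hydration_enthalpy_kJ_mol, -1592.4)
  ba <- ion_reference("Ba")
  expect_equal(ba$chloride_ld50_low_mg_kg, 100)
  expect_equal(ba$chloride_ld50_high_mg_kg, 300)
  expect_equal(ion_reference("Ca")$chloride_ld50_low_mg_kg, 2301)
  expect_equal(ion_reference("Sr")$chloride_ld50_low_mg_kg, 1253)
  expect_equal(ion_reference("Pb")$chloride_ld50_low_mg_kg, 1947)
  expect_equal(ion_reference("Cd")$chloride_ld50_low_mg_kg, 107)
  expect_equal(ion_reference("Hg")$chloride_ld50_low_mg_kg, 47)
  expect_error(ion_reference("Na"), class = "pepc_error_toxicity")
  # every record carries a citation
  tbl <- ion_reference_table()
  expect_true(all(nzchar(tbl$citation)))
})

test_that("toxicity correlation is anti-monotone for constructed input", {
  # perfectly anti-monotone binding means against the real LD50 ordering
  ld <- vapply(
    c("Ca", "Ba", "Sr", "Cd", "Pb"),
    function(i) {
      r <- ion_reference(i)
      sqrt(r$chloride_ld50_low_mg_kg * r$chloride_ld50_high_mg_kg)
    },
    double(1)
  )
  means <- setNames(-rank(ld), names(ld)) # stronger binding <-> lower LD50
  tc <- toxicity_correlation(means)
  expect_equal(tc$tau, -1)
  expect_error(
    toxicity_correlation(means[1:3], exclusions = c("Ca")),
    class = "pepc_error_toxicity"
  )
})

test_that("leave-one-out flags the discordant ion regardless of input order", {
  # constructed input: five ions anti-monotone, Ba planted discordantly
  means <- c(Sr = 1.0, Ca = 1.5, Pb = 1.5, Cd = 3.0, Hg = 4.0, Ba = 0.2)
  tc <- toxicity_correlation(means)
  expect_equal(tc$outlier, "Ba")
  perm <- sample(names(means))
  tc2 <- toxicity_correlation(means[perm])
  expect_equal(tc2$outlier, "Ba")
  expect_equal(tc2$tau, tc$tau, tolerance = 1e-12)
  # leave-one-out taus match the brute-force pair enumeration
  ld <- tc$table$ld50[match(tc$table$ion, tc$table$ion)]
  for (k in seq_len(nrow(tc$table))) {
    keep <- tc$table$ion != tc$table$ion[k]
    expect_equal(
      tc$table$loo_tau[k],
      oracle_kendall(tc$table$e_bind[keep], tc$table$ld50[keep]),
      tolerance = 1e-12
    )
  }
})
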