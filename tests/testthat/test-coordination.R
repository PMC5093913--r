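ion_probe <- function(dists, elements) {
  n <- length(dists)
  conformer(data.frame(
    element = c("Ca", elements),
    x = c(0, dists), y = 0, z = 0
  ))
}

test_that("coordination shells collect N/O/S ligands inside the cutoff", {
  cf <- ion_probe(c(2.3), "O")
  sh <- coordination_shell(cf, 1, cutoff = 3.0)
  expect_equal(nrow(sh), 1)
  expect_equal(sh$element, "O")
  cf2 <- ion_probe(c(2.3, 2.9, 3.5), c("O", "N", "S"))
  sh2 <- coordination_shell(cf2, 1, cutoff = 3.0)
  expect_equal(sh2$element, c("O", "N"))
  expect_equal(sh2$distance, c(2.3, 2.9))
  expect_warning(coordination_shell(ion_probe(5, "O"), 1, cutoff = 3.0), "empty")
  # equals an exhaustive distance scan on a built complex
  big <- place_ion(
    build_peptide(residue_template("asn", "capped", 1, "amide"),
      phi = 60, psi = 40, t_cb = -90
    ),
    "carbonyl_bridge", "Cd", 2.25
  )
  sh3 <- coordination_shell(big, big$meta$ion_index, cutoff = 3.2)
  el <- big$atoms$element
  xyz <- coords(big)
  want <- integer(0)
  for (j in which(el %in% c("N", "O", "S"))) {
    if (sqrt(sum((xyz[j, ] - xyz[big$meta$ion_index, ])^2)) <= 3.2) {
      want <- c(want, j)
    }
  }
  expect_setequal(sh3$atom, want)
})

test_that("cation-O histograms conserve counts and report the median", {
  mk <- function(d) {
    conformer(data.frame(element = c("Ca", "O"), x = c(0, d), y = 0, z = 0))
  }
  h <- cation_o_histogram(list(mk(2.2), mk(2.3), mk(2.4)), bin_width = 0.1)
  expect_equal(sum(h$counts), 3)
  expect_equal(h$median, 2.3)
  # counts conserved under a different bin width
  h2 <- cation_o_histogram(list(mk(2.2), mk(2.3), mk(2.4)), bin_width = 0.02)
  expect_equal(sum(h2$counts), 3)
  expect_equal(h2$median, h$median)
  expect_error(cation_o_histogram(list()), class = "pepc_error_coordination")
  expect_error(
    cation_o_histogram(list(water_conformer())),
    class = "pepc_error_coordination"
  )
})

test_that("mode counting separates unimodal from bimodal distance pools", {
  set.seed(7)
  uni <- stats::rnorm(200, mean = 2.3, sd = 0.04)
  expect_equal(count_modes(uni, bandwidth = 0.08), 1)
  bi <- c(stats::rnorm(100, 2.0, 0.04), stats::rnorm(100, 2.6, 0.04))
  expect_equal(count_modes(bi, bandwidth = 0.1), 2)
  expect_equal(count_modes(2.25, bandwidth = 0.08), 1)
  expect_error(count_modes(uni, bandwidth = 0), class = "pepc_error_coordination")
  # monotone non-increasing in bandwidth
  for (bw in list(c(0.05, 0.1), c(0.1, 0.2), c(0.2, 0.4))) {
    expect_gte(count_modes(bi, bw[1]), count_modes(bi, bw[2]))
    expect_gte(count_modes(uni, bw[1]), count_modes(uni, bw[2]))
  }
})

test_that("median-shift reports compare two ions' distance pools", {
  mk <- function(ds) {
    lapply(ds, function(d) {
      conformer(data.frame(element = c("Ca", "O"), x = c(0, d), y = 0, z = 0))
    })
  }
  ha <- cation_o_histogram(mk(c(2.28, 2.30, 2.32)))
  hb <- cation_o_histogram(mk(c(2.63, 2.65, 2.67)))
  rep <- median_shift_report(ha, hb)
  expect_gt(rep$median_shift, 0)
  expect_equal(median_shift_report(ha, ha)$median_shift, 0)
  expect_equal(rep$modes_a, 1)
})
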