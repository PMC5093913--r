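test_that("the builder realises requested torsions without clashes", {
  tpl <- residue_template("glu", "capped", 2, "carboxylate")
  cf <- build_peptide(tpl, phi = -150, psi = 150, chis = c(65, -170))
  tor <- backbone_torsions(cf, cf$meta$topology)
  expect_equal(tor$phi, -150, tolerance = 1e-6)
  expect_equal(tor$psi, 150, tolerance = 1e-6)
  expect_equal(tor$chi[[1]], c(65, -170), tolerance = 1e-6)
  # no nonbonded pair below the clash threshold
  dm <- as.matrix(dist(coords(cf)))
  adj <- pepcation:::bond_matrix(cf)
  expect_true(all(dm[!adj & upper.tri(dm)] >= 0.7))
  # a Gly-like template has no side chain and no chi torsions
  gly <- residue_template("gly", "free", 0, "none")
  cfg <- build_peptide(gly, t_coo = 0)
  expect_true(is.na(cfg$meta$topology$CB))
  expect_length(cfg$meta$topology$chi, 0)
  expect_error(
    build_peptide(tpl, phi = 270, psi = 0),
    class = "pepc_error_builder"
  )
})

test_that("cation placement honours site geometry and distances", {
  tpl <- ala_capped_template()
  cf <- place_ion(build_peptide(tpl, phi = 60, psi = 40, t_cb = -90),
    "carbonyl_bridge", "Ca", 2.3
  )
  topo <- cf$meta$topology
  xyz <- coords(cf)
  ii <- cf$meta$ion_index
  d1 <- sqrt(sum((xyz[ii, ] - xyz[topo$O_prev, ])^2))
  d2 <- sqrt(sum((xyz[ii, ] - xyz[topo$O, ])^2))
  expect_true(d1 >= 2.25 && d1 <= 2.35)
  expect_true(d2 >= 2.25 && d2 <= 2.35)
  # asymmetric bridge
  hg <- place_ion(build_peptide(tpl, phi = 60, psi = 40, t_cb = -90),
    "carbonyl_bridge", "Hg", 2.0,
    distance2 = 2.6
  )
  xh <- coords(hg)
  expect_equal(sqrt(sum((xh[hg$meta$ion_index, ] - xh[topo$O_prev, ])^2)), 2.0,
    tolerance = 1e-6
  )
  expect_equal(sqrt(sum((xh[hg$meta$ion_index, ] - xh[topo$O, ])^2)), 2.6,
    tolerance = 1e-6
  )
  # carboxylate site on a zwitterion classifies as salt bridge
  zw <- build_peptide(ala_free_template(), t_coo = 0, backbone_form = "zwitterion")
  sb <- place_ion(zw, "carboxylate", "Ca", 2.3)
  expect_equal(
    classify_ion_amino_acid(sb, sb$meta$topology, sb$meta$ion_index)$label,
    "salt_bridge"
  )
  # thiol side-chain site: nearest ligand is sulfur
  cys <- build_peptide(residue_template("cys", "free", 1, "thiol"), t_coo = 0)
  sc <- place_ion(cys, "side_chain", "Hg", 2.4)
  shell <- coordination_shell(sc, sc$meta$ion_index, cutoff = 3.0)
  expect_equal(shell$element[1], "S")
  expect_error(
    place_ion(build_peptide(residue_template("gly", "free", 0, "none"), t_coo = 0),
      "side_chain", "Ca", 2.3
    ),
    class = "pepc_error_builder"
  )
})

test_that("toy energies are physical: monotone Coulomb, zero baseline, pairwise sum", {
  two <- function(r) {
    conformer(
      data.frame(element = c("N", "O"), x = c(0, r), y = 0, z = 0, charge = c(1, -1))
    )
  }
  p <- toy_energy_params()
  expect_lt(toy_energy(two(3), p), toy_energy(two(4), p))
  # an isolated atom has zero energy
  lone <- structure(
    list(
      atoms = tibble::tibble(element = "Ca", x = 0, y = 0, z = 0, charge = 2),
      energy = NA_real_, meta = list()
    ),
    class = "pepc_conformer"
  )
  expect_equal(toy_energy(lone, p), 0)
  expect_equal(toy_ion_energy("Ca"), 0)
  # energy difference between fixed structures matches the hand-summed
  # screened-Coulomb difference (no bonds, no H, no ions involved)
  mk <- function(r13) {
    conformer(data.frame(
      element = c("N", "O", "N"),
      x = c(0, 3.0, r13), y = c(0, 0, 2.5), z = 0,
      charge = c(0.5, -0.5, 0.3)
    ))
  }
  hand <- function(cf) {
    xyz <- coords(cf)
    q <- cf$atoms$charge
    el <- cf$atoms$element
    s <- 0
    for (i in 1:2) {
      for (j in (i + 1):3) {
        r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        s <- s + 14.3996 * q[i] * q[j] / (p$eps_mol * r)
        sig <- (p$lj_sigma[[el[i]]] + p$lj_sigma[[el[j]]]) / 2
        s <- s + 4 * p$lj_eps * ((sig / r)^12 - (sig / r)^6)
      }
    }
    s
  }
  a <- mk(5.0)
  b <- mk(6.0)
  expect_equal(
    toy_energy(a, p) - toy_energy(b, p),
    hand(a) - hand(b),
    tolerance = 1e-9
  )
  # rigid-motion invariance
  tplc <- residue_template("ser", "capped", 1, "hydroxyl")
  cf <- build_peptide(tplc, phi = -83, psi = 66)
  expect_equal(toy_energy(cf, p), toy_energy(transform_conformer(cf), p),
    tolerance = 1e-9
  )
  # untyped atoms are rejected
  bad <- water_conformer()
  expect_error(toy_energy(bad, p), "charge", class = "pepc_error_toy")
})

test_that("basin hopping is deterministic and finds both analytic wells", {
  # 1-torsion toy potential with wells at +90 and -90 degrees
  f <- function(t) cos(2 * t * pi / 180)
  r1 <- basin_hop(f, 1, n_steps = 60, step_deg = 90, seed = 5)
  r2 <- basin_hop(f, 1, n_steps = 60, step_deg = 90, seed = 5)
  expect_identical(r1, r2)
  wells <- sort(vapply(r1$torsions, function(t) round(abs(t)), double(1)))
  expect_true(any(abs(unlist(r1$torsions) - 90) < 2) &&
    any(abs(unlist(r1$torsions) + 90) < 2))
  expect_equal(min(r1$energy), -1, tolerance = 1e-6)
  # a single step yields a single minimum
  one <- basin_hop(f, 1, n_steps = 1, seed = 3)
  expect_equal(nrow(one), 1)
  # the full conformer search is seed-reproducible
  tpl <- ala_free_template()
  s1 <- basin_hop_search(tpl, n_steps = 5, seed = 9)
  s2 <- basin_hop_search(tpl, n_steps = 5, seed = 9)
  expect_equal(s1$energy, s2$energy, tolerance = 1e-12)
})

test_that("generated suites are reproducible and carry complete ground truth", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  panel <- suite_panel()[c(1, 5), ]
  generate_benchmark_suite(21, d1, panel = panel)
  generate_benchmark_suite(21, d2, panel = panel)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 0)
  for (f in f1) {
    expect_identical(
      readLines(file.path(d1, f)),
      readLines(file.path(d2, f)),
      info = f
    )
  }
  back <- read_benchmark_suite(d1)
  expect_equal(nrow(back$index), 2 * 2 * 7)
  expect_false(any(is.na(back$ensembles$label)))
  # labels read back from disk are recovered by the classifier
  cls <- classify_conformers(back$ensembles)
  expect_equal(cls$class, cls$label)
})

test_that("suite-wide invariants hold for multiple seeds", {
  panel <- suite_panel()[c(2, 5, 7), ] # one zwit, one typeII, one cationic ligand
  for (seed in c(31, 32)) {
    suite <- generate_labeled_ensembles(seed, panel = panel)
    # every ion ensemble is strictly smaller than its bare counterpart
    idx <- suite$index
    for (k in which(idx$complexation != "none")) {
      bare_n <- idx$n_conformers[
        idx$ligand == idx$ligand[k] & idx$backbone == idx$backbone[k] &
          idx$complexation == "none"
      ]
      expect_lt(idx$n_conformers[k], bare_n)
    }
    # toy binding energies ordered Ba < Sr < Ca = Pb < Cd < Hg per system
    rec <- binding_records(suite$ensembles)
    for (key in unique(paste(rec$ligand, rec$backbone))) {
      sub <- rec[paste(rec$ligand, rec$backbone) == key, ]
      v <- setNames(sub$e_bind, sub$ion)
      expect_lt(v[["Ba"]], v[["Sr"]])
      expect_lt(v[["Sr"]], v[["Ca"]])
      expect_equal(v[["Ca"]], v[["Pb"]], tolerance = 1e-12)
      expect_lt(v[["Ca"]], v[["Cd"]])
      expect_lt(v[["Cd"]], v[["Hg"]])
    }
  }
})
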