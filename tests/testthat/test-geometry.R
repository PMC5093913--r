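test_that("dihedral reproduces canonical and oracle values", {
  # planar cis and trans
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 1, 0)), 0)
  expect_equal(abs(dihedral(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, -1, 0))), 180)
  # +60 degree case against the numeric cross-product oracle
  p <- list(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(cos(pi / 3), sin(pi / 3), 1))
  expect_equal(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]), 60, tolerance = 1e-9)
  expect_equal(
    dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
    oracle_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
    tolerance = 1e-9
  )
  expect_error(
    dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
    "undefined", class = "pepc_error_geometry"
  )
  expect_error(
    dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
    "undefined", class = "pepc_error_geometry"
  )
})

test_that("dihedral agrees with the oracle and is rigid-motion invariant", {
  set.seed(42)
  for (rep in 1:25) {
    pts <- lapply(1:4, function(i) stats::rnorm(3))
    d0 <- tryCatch(dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
      error = function(e) NULL
    )
    if (is.null(d0)) next
    expect_equal(d0, oracle_dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
      tolerance = 1e-9
    )
    R <- rot_xyz(stats::runif(1, 0, pi), stats::runif(1, 0, pi), stats::runif(1, 0, pi))
    sh <- stats::rnorm(3)
    moved <- lapply(pts, function(p) as.numeric(R %*% p + sh))
    expect_equal(
      dihedral(moved[[1]], moved[[2]], moved[[3]], moved[[4]]), d0,
      tolerance = 1e-9
    )
  }
})

test_that("builder-requested backbone torsions are measured back exactly", {
  tpl <- ala_capped_template()
  cf <- build_peptide(tpl, phi = -150, psi = 150)
  tor <- backbone_torsions(cf, cf$meta$topology)
  expect_equal(tor$phi, -150, tolerance = 1e-6)
  expect_equal(tor$psi, 150, tolerance = 1e-6)
  # free amino acid: no acetyl cap, phi undefined
  cf_free <- build_peptide(ala_free_template(), t_coo = 0)
  tor_free <- backbone_torsions(cf_free, cf_free$meta$topology)
  expect_true(is.na(tor_free$phi))
  # chi list length matches template torsion count
  tpl3 <- residue_template("lys", "capped", 3, "ammonium")
  cf3 <- build_peptide(tpl3, phi = -83, psi = 66, chis = c(170, 60, -60))
  tor3 <- backbone_torsions(cf3, cf3$meta$topology)
  expect_length(tor3$chi[[1]], 3)
  expect_equal(tor3$chi[[1]], c(170, 60, -60), tolerance = 1e-6)
  expect_error(
    backbone_torsions(cf3, list(N = 1, CA = 2, C = 99, N_next = 98)),
    class = "pepc_error_topology"
  )
})

test_that("hydrogen-bond detection matches the exhaustive oracle", {
  # hand-built N-H...O geometries
  good <- conformer(data.frame(
    element = c("N", "H", "O", "C"),
    x = c(0, 1.01, 3.0, 3.5),
    y = c(0, 0, 0, 1),
    z = c(0, 0, 0, 0)
  ))
  hb <- detect_hbonds(good)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor, 1)
  expect_equal(hb$acceptor, 3)
  # bent to 90 degrees: rejected
  bent <- conformer(data.frame(
    element = c("N", "H", "O", "C"),
    x = c(0, 1.01, 1.01, 3.5),
    y = c(0, 0, 2.0, 1),
    z = c(0, 0, 0, 0)
  ))
  expect_equal(nrow(detect_hbonds(bent)), 0)
  # every bond on builder structures equals the exhaustive triple loop
  crits <- list(hbond_criteria(), c5_criteria(), hbond_criteria(3.0, 4.0, 100))
  tpl <- residue_template("ser", "capped", 1, "hydroxyl")
  structs <- list(
    build_peptide(ala_capped_template(), phi = -83, psi = 66),
    build_peptide(ala_capped_template(), phi = -158, psi = 162),
    build_peptide(tpl, phi = -83, psi = 66, chis = 60),
    build_peptide(ala_free_template(), t_coo = 180, t_oh = 0)
  )
  for (cf in structs) {
    for (cr in crits) {
      got <- detect_hbonds(cf, cr)
      want <- oracle_hbonds(cf, cr)
      key <- function(d) {
        if (is.null(d) || nrow(d) == 0) {
          return(character(0))
        }
        sort(paste(d$donor, d$hydrogen, d$acceptor))
      }
      expect_identical(key(got), key(want))
    }
  }
})

test_that("proton assignment finds nearest heavy atoms, shared and orphan flags", {
  cf <- conformer(data.frame(
    element = c("N", "O", "H"),
    x = c(0, 2.6, 1.0), y = 0, z = 0
  ))
  pr <- assign_protons(cf)
  expect_equal(pr$heavy, 1)
  expect_equal(pr$status, "assigned")
  # shared proton: two heavy atoms within the band
  cf2 <- conformer(data.frame(
    element = c("O", "N", "H"),
    x = c(0, 2.45, 1.20), y = 0, z = 0
  ))
  pr2 <- assign_protons(cf2, shared_band = 0.1)
  expect_equal(pr2$status, "shared")
  # orphan
  cf3 <- conformer(data.frame(
    element = c("O", "H"), x = c(0, 3), y = 0, z = 0
  ))
  expect_equal(assign_protons(cf3)$status, "orphan")
  # equals exhaustive nearest-neighbour scan on a built structure
  big <- build_peptide(residue_template("lys", "free", 3, "ammonium"), t_coo = 0)
  pr4 <- assign_protons(big)
  el <- big$atoms$element
  xyz <- coords(big)
  heavy <- which(el != "H")
  for (k in seq_len(nrow(pr4))) {
    h <- pr4$hydrogen[k]
    dd <- sqrt(colSums((t(xyz[heavy, ]) - xyz[h, ])^2))
    expect_equal(pr4$heavy[k], heavy[which.min(dd)])
    expect_equal(pr4$distance[k], min(dd), tolerance = 1e-12)
  }
})

test_that("pseudocycle tracing counts 5- and 7-membered rings", {
  tpl <- ala_capped_template()
  # C5: residue N-H donating to its own carbonyl O
  c5 <- build_peptide(tpl, phi = -158, psi = 162)
  topo <- c5$meta$topology
  hb <- detect_hbonds(c5, c5_criteria())
  row <- hb[hb$donor == topo$N & hb$acceptor == topo$O, ]
  ring5 <- find_pseudocycle(c5, list(
    donor = row$donor, hydrogen = row$hydrogen, acceptor = row$acceptor
  ))
  expect_equal(ring5$size, 5)
  # C7: terminal amide N-H donating to the acetyl O
  c7 <- build_peptide(tpl, phi = -83, psi = 66)
  hb7 <- detect_hbonds(c7)
  row7 <- hb7[hb7$donor == topo$N_next & hb7$acceptor == topo$O_prev, ]
  ring7 <- find_pseudocycle(c7, list(
    donor = row7$donor, hydrogen = row7$hydrogen, acceptor = row7$acceptor
  ))
  expect_equal(ring7$size, 7)
  expect_equal(ring7$closure_type, "hydrogen_bond")
  # cation closing the same ring between the two backbone oxygens
  ic7 <- place_ion(build_peptide(tpl, phi = 60, psi = 40, t_cb = -90),
    "carbonyl_bridge", "Ca", 2.3
  )
  ring_i <- find_pseudocycle(ic7, list(
    cation = ic7$meta$ion_index, o1 = topo$O_prev, o2 = topo$O
  ))
  expect_equal(ring_i$size, 7)
  expect_equal(ring_i$closure_type, "cation_bridge")
  # disconnected end points
  frag <- conformer(data.frame(
    element = c("N", "H", "O"), x = c(0, 1.0, 10), y = 0, z = 0
  ))
  expect_error(
    find_pseudocycle(frag, list(donor = 1, hydrogen = 2, acceptor = 3)),
    "no ring", class = "pepc_error_geometry"
  )
})

test_that("side-chain orientation splits axial and equatorial at 45 degrees", {
  # constructed ring in the xy-plane, CA in the ring, CB placed at a known
  # angle to the normal
  ring_at <- function(theta_deg) {
    th <- theta_deg * pi / 180
    ring <- data.frame(
      element = rep("C", 6),
      x = cos(seq(0, 5) * pi / 3), y = sin(seq(0, 5) * pi / 3), z = 0
    )
    cb <- c(1 + 1.5 * sin(th), 0, 1.5 * cos(th))
    conformer(rbind(ring, data.frame(element = "C", x = cb[1], y = cb[2], z = cb[3])))
  }
  expect_equal(
    side_chain_orientation(ring_at(0), 1:6, ca_index = 1, cb_index = 7)$orientation,
    "axial"
  )
  expect_equal(
    side_chain_orientation(ring_at(90), 1:6, ca_index = 1, cb_index = 7)$orientation,
    "equatorial"
  )
  expect_equal(
    side_chain_orientation(ring_at(44), 1:6, ca_index = 1, cb_index = 7)$orientation,
    "axial"
  )
  expect_equal(
    side_chain_orientation(ring_at(46), 1:6, ca_index = 1, cb_index = 7)$orientation,
    "equatorial"
  )
  expect_error(
    side_chain_orientation(ring_at(10), 1:6, ca_index = 1, cb_index = NA),
    "no side chain", class = "pepc_error_geometry"
  )
})

test_that("Kabsch RMSD is zero under rigid motion and matches the grid oracle", {
  tpl <- ala_capped_template()
  a <- build_peptide(tpl, phi = -83, psi = 66)
  expect_equal(kabsch_rmsd(a, a), 0, tolerance = 1e-12)
  moved <- transform_conformer(a)
  expect_lt(kabsch_rmsd(a, moved), 1e-9)
  # symmetry
  b <- build_peptide(tpl, phi = -70, psi = 80)
  expect_equal(kabsch_rmsd(a, b), kabsch_rmsd(b, a), tolerance = 1e-12)
  expect_error(kabsch_rmsd(a, water_conformer()), class = "pepc_error_geometry")
  # 4-atom displaced-atom case vs brute-force rotation grid
  A <- matrix(c(
    0, 0, 0,
    1.5, 0, 0,
    0, 1.5, 0,
    0, 0, 1.5
  ), ncol = 3, byrow = TRUE)
  B <- A
  B[4, ] <- B[4, ] + c(0.6, 0.6, 0.5) # ~1 A displacement
  ca <- conformer(data.frame(element = rep("C", 4), x = A[, 1], y = A[, 2], z = A[, 3]))
  cb <- conformer(data.frame(element = rep("C", 4), x = B[, 1], y = B[, 2], z = B[, 3]))
  expect_equal(kabsch_rmsd(ca, cb), oracle_rmsd_grid(A, B), tolerance = 1e-3)
})
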