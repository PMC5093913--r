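# Conformer classification into the backbone structure taxonomy:
# free amino acids -> type I / type II / zwitterionic,
# amino acid + cation -> salt-bridge / charge-solvated,
# dipeptides -> C5 / C7ax / C7eq,
# dipeptide + cation -> iC7ax / iC7eq,
# with "other" as the catch-all.

PEPC_CLASSES <- c(
  "typeI", "typeII", "zwitterionic", "charge_solvated", "salt_bridge",
  "C5", "C7ax", "C7eq", "iC7ax", "iC7eq", "other"
)

backbone_class <- function(label, evidence = list()) {
  stopifnot(label %in% PEPC_CLASSES)
  structure(list(label = label, evidence = evidence), class = "pepc_class")
}

#' @export
print.pepc_class <- function(x, ...) {
  ev <- if (length(x$evidence) == 0) {
    ""
  } else {
    paste0(
      " [", paste(names(x$evidence), unlist(lapply(x$evidence, format)),
        sep = "=", collapse = ", "
      ), "]"
    )
  }
  cat("<pepc_class> ", x$label, ev, "\n", sep = "")
  invisible(x)
}

# Per-ion coordination distance cutoff: Shannon radius + oxygen radius proxy
# (1.52 A) + slack.
coordination_cutoff <- function(ion, slack = 0.4) {
  ref <- ion_reference(ion)
  ref$shannon_radius_pm / 100 + 1.52 + slack
}

# Hydrogens currently sitting on the atom `idx` according to the proton map.
protons_on <- function(protons, idx) {
  protons$hydrogen[protons$heavy == idx & protons$status != "orphan"]
}

#' Classify a free (uncapped, uncomplexed) amino acid conformer
#'
#' Decision rule driven by proton assignment and hydrogen bonding: a
#' deprotonated carboxylate (no H on either carboxyl O) means zwitterionic;
#' a carboxyl O-H donating to the backbone N means type II; a neutral
#' carboxyl with the backbone N-H donating to the carbonyl O means type I;
#' anything else is "other". A side-chain N-H donor to the carboxylate (the
#' Arg-style guanidino zwitterion) also counts as zwitterionic, recorded in
#' the evidence.
#'
#' @param conf A `pepc_conformer`.
#' @param topology Topology map with `N`, `CA`, `C`, `O_carbonyl`,
#'   `O_hydroxyl` (the two carboxyl oxygens) and optionally `side_donors`
#'   (indices of side-chain donor heavy atoms).
#' @param criteria Hydrogen-bond criteria, see [hbond_criteria()].
#' @return A `pepc_class` object.
#' @export
classify_free_amino_acid <- function(conf, topology, criteria = hbond_criteria()) {
  for (r in c("N", "CA", "C", "O_carbonyl", "O_hydroxyl")) {
    if (is.null(topology[[r]]) || is.na(topology[[r]])) {
      abort(paste0("topology lacks backbone atom '", r, "'"),
        class = "pepc_error_topology"
      )
    }
  }
  n_bb <- topology$N
  o_c <- topology$O_carbonyl
  o_h <- topology$O_hydroxyl
  protons <- assign_protons(conf)
  hbonds <- detect_hbonds(conf, criteria)
  h_on_oc <- protons_on(protons, o_c)
  h_on_oh <- protons_on(protons, o_h)
  carboxyl_h <- c(h_on_oh, h_on_oc)

  if (length(carboxyl_h) == 0) {
    ev <- list(carboxylate = TRUE, n_protons_on_N = length(protons_on(protons, n_bb)))
    side <- topology$side_donors %||% integer(0)
    sb <- hbonds[hbonds$donor %in% side & hbonds$acceptor %in% c(o_c, o_h), ]
    if (nrow(sb) > 0) ev$side_chain_donor <- sb$donor[1]
    return(backbone_class("zwitterionic", ev))
  }
  # neutral carboxyl: which motif?
  oh_to_n <- hbonds[hbonds$hydrogen %in% carboxyl_h & hbonds$acceptor == n_bb, ]
  if (nrow(oh_to_n) > 0) {
    return(backbone_class("typeII", list(
      d_ha = oh_to_n$d_ha[1], angle_dha = oh_to_n$angle_dha[1],
      donor_O = oh_to_n$donor[1]
    )))
  }
  # the type I N-H...O=C contact closes the same bent five-membered ring as
  # C5 in dipeptides, so it is screened with the relaxed five-ring criteria
  hbonds5 <- detect_hbonds(conf, c5_criteria())
  free_o <- setdiff(c(o_c, o_h), protons$heavy[protons$hydrogen %in% carboxyl_h])
  nh_to_o <- hbonds5[hbonds5$donor == n_bb & hbonds5$acceptor %in% free_o, ]
  if (nrow(nh_to_o) > 0) {
    return(backbone_class("typeI", list(
      d_ha = nh_to_o$d_ha[1], angle_dha = nh_to_o$angle_dha[1],
      acceptor_O = nh_to_o$acceptor[1]
    )))
  }
  backbone_class("other", list(reason = "no class-defining contact"))
}

#' Classify an amino acid + cation conformer
#'
#' Salt-bridge: zwitterionic backbone (deprotonated carboxylate) with the
#' cation within its coordination cutoff of at least one carboxylate oxygen.
#' Charge-solvated: neutral backbone with the cation coordinating the
#' backbone N and at least one oxygen. Anything else is "other".
#'
#' @inheritParams classify_free_amino_acid
#' @param ion_index Index of the cation atom.
#' @param slack Additive slack on the coordination cutoff, Angstrom.
#' @return A `pepc_class` object.
#' @export
classify_ion_amino_acid <- function(conf, topology, ion_index,
                                    criteria = hbond_criteria(), slack = 0.4) {
  el <- conf$atoms$element
  if (!is_cation_element(el[ion_index])) {
    abort(paste0("atom ", ion_index, " (", el[ion_index], ") is not a registered cation"),
      class = "pepc_error_classify"
    )
  }
  xyz <- coords(conf)
  cutoff <- coordination_cutoff(el[ion_index], slack)
  n_bb <- topology$N
  o_c <- topology$O_carbonyl
  o_h <- topology$O_hydroxyl
  protons <- assign_protons(conf)
  carboxyl_h <- c(protons_on(protons, o_h), protons_on(protons, o_c))
  d_oc <- dist_pair(xyz, ion_index, o_c)
  d_oh <- dist_pair(xyz, ion_index, o_h)
  d_n <- dist_pair(xyz, ion_index, n_bb)
  zwitterionic <- length(carboxyl_h) == 0
  ev <- list(
    d_ion_Oc = d_oc, d_ion_Oh = d_oh, d_ion_N = d_n, cutoff = cutoff
  )
  if (zwitterionic && (d_oc <= cutoff || d_oh <= cutoff)) {
    return(backbone_class("salt_bridge", ev))
  }
  if (!zwitterionic && d_n <= cutoff && (d_oc <= cutoff || d_oh <= cutoff)) {
    return(backbone_class("charge_solvated", ev))
  }
  backbone_class("other", c(ev, list(reason = "cation not at a class-defining site")))
}

#' Relaxed criteria for the long C5 contact
#'
#' The five-membered C5 pseudocycle has an intrinsically long, bent
#' N-H...O contact, so its detection uses a longer distance bound and a
#' shallower angle bound than ordinary hydrogen bonds.
#'
#' @inheritParams hbond_criteria
#' @export
c5_criteria <- function(max_d_ha = 2.7, max_d_da = 3.5, min_angle = 95) {
  hbond_criteria(max_d_ha, max_d_da, min_angle)
}

#' Classify a bare dipeptide conformer
#'
#' Looks for the hydrogen-bonded pseudocycles that define the two dominant
#' dipeptide motifs: a 5-membered ring (C5) and a 7-membered ring (C7, split
#' into axial/equatorial by side-chain orientation). If both are present the
#' shorter H...A contact wins.
#'
#' @inheritParams classify_free_amino_acid
#' @param topology Capped topology map: `C_prev`, `N`, `CA`, `C`, `O`,
#'   `O_prev` (acetyl O), `N_next`, `CB` (NA for Gly), `chi`.
#' @param c5 Criteria used for C5 detection, see [c5_criteria()].
#' @return A `pepc_class` object.
#' @export
classify_dipeptide <- function(conf, topology, criteria = hbond_criteria(),
                               c5 = c5_criteria()) {
  for (r in c("C_prev", "N", "CA", "C", "O", "O_prev", "N_next")) {
    if (is.null(topology[[r]]) || is.na(topology[[r]])) {
      abort(paste0("topology lacks capped backbone atom '", r, "'"),
        class = "pepc_error_topology"
      )
    }
  }
  hb <- detect_hbonds(conf, c5) # superset: c5 criteria are the looser ones
  # the motifs are defined on the backbone: C5 closes N-H...O=C within the
  # residue, C7 closes the terminal amide N-H...acetyl O ring
  hb <- hb[(hb$donor == topology$N & hb$acceptor == topology$O) |
    (hb$donor == topology$N_next & hb$acceptor == topology$O_prev), ]
  candidates <- list()
  for (k in seq_len(nrow(hb))) {
    ring <- tryCatch(
      find_pseudocycle(conf, list(
        donor = hb$donor[k], hydrogen = hb$hydrogen[k], acceptor = hb$acceptor[k]
      )),
      error = function(e) NULL
    )
    if (is.null(ring)) next
    if (ring$size == 5 && hb$d_ha[k] <= c5$max_d_ha) {
      candidates[[length(candidates) + 1L]] <- list(kind = "C5", d = hb$d_ha[k], ring = ring)
    }
    if (ring$size == 7 && hb$d_ha[k] <= criteria$max_d_ha &&
      hb$angle_dha[k] >= criteria$min_angle) {
      candidates[[length(candidates) + 1L]] <- list(kind = "C7", d = hb$d_ha[k], ring = ring)
    }
  }
  if (length(candidates) == 0) {
    return(backbone_class("other", list(reason = "no C5/C7 pseudocycle")))
  }
  best <- candidates[[which.min(vapply(candidates, `[[`, double(1), "d"))]]
  if (best$kind == "C5") {
    return(backbone_class("C5", list(d_ha = best$d, ring_size = 5)))
  }
  ori <- tryCatch(
    side_chain_orientation(conf, best$ring, topology$CA, topology$CB),
    error = function(e) NULL
  )
  if (is.null(ori)) {
    # no CB (Gly): the ax/eq distinction is undefined
    return(backbone_class("other", list(
      reason = "C7 ring without side chain", ring_size = 7
    )))
  }
  lab <- if (ori$orientation == "axial") "C7ax" else "C7eq"
  backbone_class(lab, list(d_ha = best$d, ring_size = 7, theta = ori$theta))
}

#' Classify a dipeptide + cation conformer
#'
#' The iC7 motif: the cation bridges the acetyl oxygen and the residue
#' carbonyl oxygen, closing the otherwise incomplete 7-membered pseudocycle;
#' axial vs equatorial is measured on the cation-closed ring.
#'
#' @inheritParams classify_dipeptide
#' @inheritParams classify_ion_amino_acid
#' @return A `pepc_class` object.
#' @export
classify_dipeptide_ion <- function(conf, topology, ion_index, slack = 0.4) {
  el <- conf$atoms$element
  if (!is_cation_element(el[ion_index])) {
    abort(paste0("atom ", ion_index, " (", el[ion_index], ") is not a registered cation"),
      class = "pepc_error_classify"
    )
  }
  xyz <- coords(conf)
  cutoff <- coordination_cutoff(el[ion_index], slack)
  o_prev <- topology$O_prev
  o_res <- topology$O
  d1 <- dist_pair(xyz, ion_index, o_prev)
  d2 <- dist_pair(xyz, ion_index, o_res)
  ev <- list(d_ion_Oacetyl = d1, d_ion_Ocarbonyl = d2, cutoff = cutoff)
  if (d1 > cutoff || d2 > cutoff) {
    return(backbone_class("other", c(ev, list(reason = "cation does not bridge backbone oxygens"))))
  }
  ring <- find_pseudocycle(conf, list(cation = ion_index, o1 = o_prev, o2 = o_res))
  ori <- tryCatch(
    side_chain_orientation(conf, ring, topology$CA, topology$CB),
    error = function(e) NULL
  )
  if (is.null(ori)) {
    return(backbone_class("other", c(ev, list(
      reason = "cation-closed ring without side chain", ring_size = ring$size
    ))))
  }
  lab <- if (ori$orientation == "axial") "iC7ax" else "iC7eq"
  backbone_class(lab, c(ev, list(ring_size = ring$size, theta = ori$theta)))
}

#' Ramachandran quadrant of a (phi, psi) pair
#'
#' Quadrant I: phi>0, psi>0; II: phi<0, psi>0; III: phi<0, psi<0;
#' IV: phi>0, psi<0. Values exactly on a boundary (0 or +-180) are flagged
#' and resolved clockwise in the Ramachandran plane: phi = 0 counts as
#' positive, phi = +-180 as negative, psi = 0 as negative, psi = +-180 as
#' positive.
#'
#' @param phi,psi Torsion angles in degrees, in (-180, 180]. Vectorised.
#' @return A tibble with columns `quadrant` ("I".."IV") and `boundary`
#'   (logical flag).
#' @examples
#' quadrant(-83, 66) # II
#' @export
quadrant <- function(phi, psi) {
  on_edge <- function(a) a == 0 | abs(a) == 180
  boundary <- on_edge(phi) | on_edge(psi)
  phi_pos <- ifelse(phi == 0, TRUE, ifelse(abs(phi) == 180, FALSE, phi > 0))
  psi_pos <- ifelse(psi == 0, FALSE, ifelse(abs(psi) == 180, TRUE, psi > 0))
  q <- ifelse(phi_pos & psi_pos, "I",
    ifelse(!phi_pos & psi_pos, "II",
      ifelse(!phi_pos & !psi_pos, "III", "IV")
    )
  )
  tibble(quadrant = q, boundary = boundary)
}

chi_bin_one <- function(chi) {
  if (chi > 0 && chi <= 120) {
    "g+"
  } else if (chi > 120 || chi <= -120) {
    "t"
  } else {
    "g-"
  }
}

#' Derive a rotamer table from classified ensembles
#'
#' Bins every side-chain torsion into g+ (0, 120], t (120, 180] U (-180,
#' -120] and g- (-120, 0], counts conformers inside the energy window and
#' attaches Boltzmann weights computed from relative energies.
#'
#' @param ensembles An ensemble tibble whose conformers carry topology
#'   metadata (as produced by the synthetic generator), or a tibble with
#'   columns `system`, `energy` and a `chi` list-column.
#' @param energy_window_ev Width of the energy window above the per-system
#'   minimum, eV.
#' @param temperature_k Temperature for the Boltzmann weights, K.
#' @return A tibble: `system`, `chi_bin` (comma-joined bin tuple), `count`,
#'   `frequency` (Boltzmann-weighted, summing to 1 per system).
#' @export
derive_rotamer_table <- function(ensembles, energy_window_ev = Inf,
                                 temperature_k = 300) {
  if (!"chi" %in% names(ensembles)) {
    ensembles <- dplyr::mutate(
      ensembles,
      chi = purrr::map(.data$conformer, function(cf) {
        topo <- cf$meta$topology
        if (is.null(topo)) {
          abort("conformers carry no topology metadata; supply a `chi` column",
            class = "pepc_error_classify"
          )
        }
        backbone_torsions(cf, topo)$chi[[1]]
      })
    )
  }
  out <- ensembles |>
    dplyr::group_by(.data$system) |>
    dplyr::mutate(rel_e = .data$energy - min(.data$energy)) |>
    dplyr::filter(.data$rel_e <= energy_window_ev) |>
    dplyr::ungroup()
  if (nrow(out) == 0) {
    abort("energy window contains no conformers", class = "pepc_error_classify")
  }
  out$chi_bin <- vapply(out$chi, function(ch) {
    if (length(ch) == 0) {
      return("-")
    }
    paste(vapply(ch, chi_bin_one, character(1)), collapse = ",")
  }, character(1))
  out |>
    dplyr::group_by(.data$system) |>
    dplyr::mutate(w = exp(-.data$rel_e / (KB_EV * temperature_k))) |>
    dplyr::group_by(.data$system, .data$chi_bin) |>
    dplyr::summarise(count = dplyr::n(), weight = sum(.data$w), .groups = "drop_last") |>
    dplyr::mutate(frequency = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup() |>
    dplyr::select("system", "chi_bin", "count", "frequency")
}

#' Classify every conformer of an ensemble table
#'
#' Dispatches to the free/capped, bare/complexed classifier appropriate for
#' each system. The system descriptor and topology are taken from each
#' conformer's metadata (`meta$descriptor`, `meta$topology`, `meta$ion_index`)
#' as written by the synthetic generator, or supplied via `descriptors`.
#'
#' @param ensembles An ensemble tibble.
#' @param descriptors Optional tibble with columns `system`, `backbone`,
#'   `complexation` overriding conformer metadata.
#' @param criteria,c5 Hydrogen-bond criteria.
#' @param slack Coordination cutoff slack, Angstrom.
#' @return The input tibble with columns `class`, `phi`, `psi`, `quadrant`,
#'   `boundary` and an `evidence` list-column added.
#' @export
classify_conformers <- function(ensembles, descriptors = NULL,
                                criteria = hbond_criteria(), c5 = c5_criteria(),
                                slack = 0.4) {
  desc_for <- function(cf, sys) {
    if (!is.null(descriptors)) {
      row <- descriptors[descriptors$system == sys, ]
      if (nrow(row) == 0) {
        abort(paste0("no descriptor for system '", sys, "'"), class = "pepc_error_classify")
      }
      list(backbone = row$backbone[1], complexation = row$complexation[1])
    } else {
      d <- cf$meta$descriptor
      if (is.null(d)) {
        abort("conformer metadata lacks a system descriptor", class = "pepc_error_classify")
      }
      d
    }
  }
  rows <- purrr::pmap(
    list(ensembles$conformer, ensembles$system),
    function(cf, sys) {
      topo <- cf$meta$topology
      if (is.null(topo)) {
        abort("conformer metadata lacks a topology map", class = "pepc_error_classify")
      }
      d <- desc_for(cf, sys)
      ion <- cf$meta$ion_index %||% which(is_cation_element(cf$atoms$element))[1]
      cl <- if (d$backbone == "free" && d$complexation == "none") {
        classify_free_amino_acid(cf, topo, criteria)
      } else if (d$backbone == "free") {
        classify_ion_amino_acid(cf, topo, ion, criteria, slack)
      } else if (d$complexation == "none") {
        classify_dipeptide(cf, topo, criteria, c5)
      } else {
        classify_dipeptide_ion(cf, topo, ion, slack)
      }
      tor <- backbone_torsions(cf, topo)
      tibble(
        class = cl$label, phi = tor$phi, psi = tor$psi,
        evidence = list(cl$evidence)
      )
    }
  )
  out <- dplyr::bind_cols(ensembles, dplyr::bind_rows(rows))
  qq <- quadrant(out$phi, out$psi)
  out$quadrant <- ifelse(is.na(out$phi) | is.na(out$psi), NA_character_, qq$quadrant)
  out$boundary <- ifelse(is.na(out$phi) | is.na(out$psi), NA, qq$boundary)
  out
}
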