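# Internal-coordinate construction of simplified amino-acid and dipeptide
# models (NeRF-style sequential placement), plus cation placement.
#
# The models are polar-hydrogen surrogates: heavy atoms plus the hydrogens
# on N/O/S donors. Side chains are simplified chains of 0-3 carbons ending
# in a chemically typed terminal group; classes, not element-exact residues,
# are what the generator keeps faithful.

deg2rad <- function(x) x * pi / 180

# Next-atom placement: X is bonded to `c` with bond length `bond`, angle
# X-c-b = `angle` and dihedral(a, b, c, X) = `torsion` (degrees).
place_nerf <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# ---------------------------------------------------------------------------
# Side-chain terminal groups. Each entry is a function(tip, prev, prev2,
# atoms-accumulator) returning new rows; charges are toy partial charges.

TERMINAL_TYPES <- c(
  "methyl", "carboxylate", "carboxylic_acid", "amine", "ammonium", "thiol",
  "imidazole_like", "guanidino_like", "aromatic_like", "hydroxyl", "amide",
  "none"
)

#' Define a simplified residue template
#'
#' @param name Ligand name (lower case, used in system ids).
#' @param backbone `"free"` or `"capped"`.
#' @param n_chain Number of side-chain carbons (0 = no side chain, Gly-like;
#'   1 = CB only).
#' @param terminal Terminal group type, one of
#'   methyl/carboxylate/carboxylic_acid/amine/ammonium/thiol/imidazole_like/
#'   guanidino_like/aromatic_like/hydroxyl/amide/none.
#' @param side_charge Formal charge carried by the side chain (-1, 0, +1),
#'   implied by the terminal type; recorded for bookkeeping.
#' @return A list of class `pepc_template`.
#' @export
residue_template <- function(name, backbone = c("free", "capped"),
                             n_chain = 1, terminal = "none") {
  backbone <- match.arg(backbone)
  if (!terminal %in% TERMINAL_TYPES) {
    abort(paste0("unknown terminal type '", terminal, "'"), class = "pepc_error_template")
  }
  if (n_chain == 0 && terminal != "none") {
    abort("a terminal group needs at least one chain atom", class = "pepc_error_template")
  }
  side_charge <- switch(terminal,
    carboxylate = -1L,
    ammonium = 1L,
    guanidino_like = 1L,
    0L
  )
  n_chi <- if (n_chain == 0) 0L else if (terminal %in% c("none", "methyl")) {
    n_chain - 1L
  } else {
    n_chain
  }
  structure(
    list(
      name = name, backbone = backbone, n_chain = n_chain,
      terminal = terminal, side_charge = side_charge, n_chi = as.integer(n_chi)
    ),
    class = "pepc_template"
  )
}

# internal: one atom row (plain list; a single tibble is built at the end)
atom_row <- function(name, element, pos, charge) {
  list(
    name = name, element = element,
    x = pos[1], y = pos[2], z = pos[3], charge = charge
  )
}

# flatten nested lists of atom rows into one tibble
bind_atom_rows <- function(rows) {
  flat <- list()
  walk <- function(x) {
    if (is.null(x) || length(x) == 0) {
      return(invisible(NULL))
    }
    if (!is.null(x$name) && !is.list(x$name)) {
      flat[[length(flat) + 1L]] <<- x
    } else {
      for (e in x) walk(e)
    }
  }
  walk(rows)
  tibble(
    name = vapply(flat, `[[`, character(1), "name"),
    element = vapply(flat, `[[`, character(1), "element"),
    x = vapply(flat, `[[`, double(1), "x"),
    y = vapply(flat, `[[`, double(1), "y"),
    z = vapply(flat, `[[`, double(1), "z"),
    charge = vapply(flat, `[[`, double(1), "charge")
  )
}

# Build side chain onto CA. `frame` = list(a, b, c) positions used for the
# first chain torsion (chi1 = dihedral(N, CA, CB->) convention via NeRF
# frames). Returns list(rows, chi_quads, tip_index_offset).
build_side_chain <- function(template, ca, n, c_prev_frame, chis, idx0, t_cb = 122) {
  rows <- list()
  quads <- list()
  if (template$n_chain == 0) {
    return(list(rows = list(), chi = list(), tip = NA_integer_))
  }
  # CB off CA; the improper torsion t_cb positions the side chain relative
  # to the backbone (axial vs equatorial territory for ring conformers)
  cb <- place_nerf(c_prev_frame, n, ca, 1.53, 110, t_cb)
  rows[[1]] <- atom_row("CB", "C", cb, 0)
  chain_pos <- list(cb)
  prev2 <- n
  prev1 <- ca
  # chain carbons beyond CB, rotated by chi1, chi2, ...
  if (template$n_chain > 1) {
    for (k in 2:template$n_chain) {
      chi <- chis[k - 1]
      newp <- place_nerf(prev2, prev1, chain_pos[[k - 1]], 1.53, 112, chi)
      rows[[k]] <- atom_row(paste0("C", k + 1), "C", newp, 0)
      prev2 <- prev1
      prev1 <- chain_pos[[k - 1]]
      chain_pos[[k]] <- newp
    }
  }
  tip <- chain_pos[[template$n_chain]]
  tip_i <- idx0 + template$n_chain - 1L
  # frame atoms for the terminal torsion
  fa <- prev2
  fb <- prev1
  n_used <- if (template$terminal %in% c("none", "methyl")) {
    template$n_chain - 1L
  } else {
    template$n_chain
  }
  chi_t <- if (n_used >= template$n_chain && template$n_chain <= length(chis)) {
    chis[template$n_chain]
  } else {
    180
  }
  term <- switch(template$terminal,
    none = list(),
    methyl = list(),
    hydroxyl = {
      o <- place_nerf(fa, fb, tip, 1.42, 109, chi_t)
      h <- place_nerf(fb, tip, o, 0.97, 107, 180)
      list(
        atom_row("OT", "O", o, -0.45),
        atom_row("HOT", "H", h, 0.40)
      )
    },
    thiol = {
      s <- place_nerf(fa, fb, tip, 1.81, 109, chi_t)
      h <- place_nerf(fb, tip, s, 1.34, 96, 180)
      list(
        atom_row("ST", "S", s, -0.25),
        atom_row("HST", "H", h, 0.15)
      )
    },
    carboxylate = {
      cg <- place_nerf(fa, fb, tip, 1.52, 112, chi_t)
      o1 <- place_nerf(fb, tip, cg, 1.26, 118, 0)
      o2 <- place_nerf(fb, tip, cg, 1.26, 118, 180)
      list(
        atom_row("CT", "C", cg, 0.30),
        atom_row("OT1", "O", o1, -0.65),
        atom_row("OT2", "O", o2, -0.65)
      )
    },
    carboxylic_acid = {
      cg <- place_nerf(fa, fb, tip, 1.52, 112, chi_t)
      o1 <- place_nerf(fb, tip, cg, 1.23, 121, 0)
      o2 <- place_nerf(fb, tip, cg, 1.32, 113, 180)
      h <- place_nerf(tip, cg, o2, 0.98, 107, 180)
      list(
        atom_row("CT", "C", cg, 0.45),
        atom_row("OT1", "O", o1, -0.45),
        atom_row("OT2", "O", o2, -0.40),
        atom_row("HOT", "H", h, 0.40)
      )
    },
    amine = {
      nz <- place_nerf(fa, fb, tip, 1.47, 110, chi_t)
      h1 <- place_nerf(fb, tip, nz, 1.01, 109, 60)
      h2 <- place_nerf(fb, tip, nz, 1.01, 109, 300)
      list(
        atom_row("NT", "N", nz, -0.60),
        atom_row("HNT1", "H", h1, 0.30),
        atom_row("HNT2", "H", h2, 0.30)
      )
    },
    ammonium = {
      nz <- place_nerf(fa, fb, tip, 1.47, 110, chi_t)
      hs <- lapply(c(60, 180, 300), function(t) place_nerf(fb, tip, nz, 1.01, 109, t))
      list(
        atom_row("NT", "N", nz, -0.20),
        atom_row("HNT1", "H", hs[[1]], 0.40),
        atom_row("HNT2", "H", hs[[2]], 0.40),
        atom_row("HNT3", "H", hs[[3]], 0.40)
      )
    },
    guanidino_like = {
      ne <- place_nerf(fa, fb, tip, 1.46, 112, chi_t)
      cz <- place_nerf(fb, tip, ne, 1.33, 124, 180)
      nh1 <- place_nerf(tip, ne, cz, 1.33, 120, 0)
      nh2 <- place_nerf(tip, ne, cz, 1.33, 120, 180)
      hne <- place_nerf(fb, tip, ne, 1.01, 118, 0)
      hh1 <- place_nerf(ne, cz, nh1, 1.01, 120, 180)
      hh2 <- place_nerf(ne, cz, nh2, 1.01, 120, 180)
      list(
        atom_row("NE", "N", ne, -0.30),
        atom_row("CZ", "C", cz, 0.75),
        atom_row("NH1", "N", nh1, -0.25),
        atom_row("NH2", "N", nh2, -0.25),
        atom_row("HNE", "H", hne, 0.35),
        atom_row("HH1", "H", hh1, 0.35),
        atom_row("HH2", "H", hh2, 0.35)
      )
    },
    imidazole_like = {
      nd <- place_nerf(fa, fb, tip, 1.49, 110, chi_t)
      ce <- place_nerf(fb, tip, nd, 1.32, 108, 180)
      ne <- place_nerf(tip, nd, ce, 1.32, 110, 0)
      hne <- place_nerf(nd, ce, ne, 1.01, 125, 180)
      list(
        atom_row("ND", "N", nd, -0.30),
        atom_row("CE", "C", ce, 0.30),
        atom_row("NE", "N", ne, -0.40),
        atom_row("HNE", "H", hne, 0.40)
      )
    },
    aromatic_like = {
      c1 <- place_nerf(fa, fb, tip, 1.50, 113, chi_t)
      c2 <- place_nerf(fb, tip, c1, 1.39, 120, 90)
      c3 <- place_nerf(fb, tip, c1, 1.39, 120, 270)
      list(
        atom_row("CR1", "C", c1, 0),
        atom_row("CR2", "C", c2, 0),
        atom_row("CR3", "C", c3, 0)
      )
    },
    amide = {
      cg <- place_nerf(fa, fb, tip, 1.52, 112, chi_t)
      o <- place_nerf(fb, tip, cg, 1.23, 121, 0)
      nd <- place_nerf(fb, tip, cg, 1.32, 116, 180)
      h1 <- place_nerf(tip, cg, nd, 1.01, 119, 0)
      h2 <- place_nerf(tip, cg, nd, 1.01, 119, 180)
      list(
        atom_row("CT", "C", cg, 0.45),
        atom_row("OT", "O", o, -0.50),
        atom_row("NDT", "N", nd, -0.60),
        atom_row("HND1", "H", h1, 0.35),
        atom_row("HND2", "H", h2, 0.35)
      )
    }
  )
  # chi quadruples in 1-based final indexing are attached by the caller
  list(rows = c(rows, list(term)), tip = tip_i)
}

#' Build a simplified peptide model at requested torsions
#'
#' Realises the template as Cartesian coordinates by sequential
#' internal-to-Cartesian placement. For capped templates `phi`/`psi` are the
#' backbone torsions; for free templates the carboxyl orientation `t_coo`
#' (dihedral N-CA-C-O_carbonyl) plays the backbone role and `phi` is absent.
#' The measured torsions reproduce the requested ones to builder precision.
#'
#' @param template A `pepc_template`.
#' @param phi,psi Backbone torsions, degrees in (-180, 180] (capped only).
#' @param chis Numeric vector of side-chain torsions (length `n_chi`).
#' @param t_coo Carboxyl orientation for free templates, degrees.
#' @param backbone_form `"neutral"` or `"zwitterion"` (free templates).
#' @param t_oh Carboxyl O-H torsion (dihedral CA-C-O_h-H): 0 points the
#'   proton towards the backbone N, 180 away (free neutral only).
#' @param t_hn Orientation of the first amino H (dihedral C-CA... frame),
#'   degrees.
#' @param t_cb Side-chain placement (improper) torsion of CB about CA,
#'   degrees; controls axial vs equatorial side-chain orientation.
#' @param min_nonbonded Clash threshold: any nonbonded pair closer than this
#'   (Angstrom) is an error.
#' @return A `pepc_conformer` with toy charges in `atoms$charge` and the
#'   topology map in `meta$topology`.
#' @export
build_peptide <- function(template, phi = NULL, psi = NULL, chis = NULL,
                          t_coo = 0, backbone_form = c("neutral", "zwitterion"),
                          t_oh = 180, t_hn = 60, t_cb = 122,
                          min_nonbonded = 0.7) {
  backbone_form <- match.arg(backbone_form)
  chis <- chis %||% rep(180, template$n_chi)
  chk_angle <- function(a, what) {
    if (is.null(a)) {
      return(invisible(NULL))
    }
    if (any(a <= -180 | a > 180)) {
      abort(paste0(what, " must lie in (-180, 180]"), class = "pepc_error_builder")
    }
  }
  chk_angle(phi, "phi")
  chk_angle(psi, "psi")
  chk_angle(chis, "chi")
  chk_angle(t_coo, "t_coo")
  if (length(chis) != template$n_chi) {
    abort(
      paste0("template has ", template$n_chi, " chi torsions, got ", length(chis)),
      class = "pepc_error_builder"
    )
  }
  if (template$backbone == "capped") {
    out <- build_capped(template, phi, psi, chis, t_cb, min_nonbonded)
  } else {
    out <- build_free(template, t_coo, chis, backbone_form, t_oh, t_hn, t_cb,
      min_nonbonded)
  }
  out
}

# gas-phase proton-transfer penalty carried by the zwitterionic protomer
ZWIT_SELF_EV <- 0.15

build_free <- function(template, t_coo, chis, backbone_form, t_oh, t_hn, t_cb,
                       min_nonbonded) {
  zwit <- backbone_form == "zwitterion"
  n <- c(0, 0, 0)
  ca <- c(1.47, 0, 0)
  th <- deg2rad(111)
  cc <- ca + 1.52 * c(-cos(th), sin(th), 0)
  q_n <- if (zwit) -0.30 else -0.50
  q_c <- if (zwit) 0.60 else 0.55
  q_oc <- if (zwit) -0.80 else -0.50
  q_oh <- if (zwit) -0.80 else -0.45
  q_hn <- if (zwit) 0.33 else 0.25
  rows <- list(
    atom_row("N", "N", n, q_n),
    atom_row("CA", "C", ca, 0.10),
    atom_row("C", "C", cc, q_c)
  )
  o_c <- place_nerf(n, ca, cc, 1.24, 121, t_coo)
  o_h <- place_nerf(n, ca, cc, if (zwit) 1.26 else 1.31, 113, wrap_angle(t_coo + 180))
  rows <- c(rows, list(
    atom_row("OC", "O", o_c, q_oc),
    atom_row("OH", "O", o_h, q_oh)
  ))
  idx_side0 <- 6L
  side <- build_side_chain(template, ca, n, cc, chis, idx_side0, t_cb)
  rows <- c(rows, side$rows)
  # amino hydrogens
  hn_tors <- if (zwit) c(t_hn, t_hn + 120, t_hn - 120) else c(t_hn, t_hn + 120)
  for (k in seq_along(hn_tors)) {
    h <- place_nerf(cc, ca, n, 1.01, 109, wrap_angle(hn_tors[k]))
    rows <- c(rows, list(atom_row(paste0("HN", k), "H", h, q_hn)))
  }
  if (!zwit) {
    ho <- place_nerf(ca, cc, o_h, 0.98, 107, t_oh)
    rows <- c(rows, list(atom_row("HO", "H", ho, 0.40)))
  }
  atoms <- bind_atom_rows(rows)
  topo <- list(
    N = 1L, CA = 2L, C = 3L, O_carbonyl = 4L, O_hydroxyl = 5L,
    CB = if (template$n_chain > 0) idx_side0 else NA_integer_,
    chi = free_chi_quads(template, idx_side0),
    side_donors = side_donor_indices(template, idx_side0)
  )
  finish_build(atoms, topo, template, min_nonbonded,
    self_energy = if (zwit) ZWIT_SELF_EV else 0
  )
}

build_capped <- function(template, phi, psi, chis, t_cb, min_nonbonded) {
  if (is.null(phi) || is.null(psi)) {
    abort("capped templates need phi and psi", class = "pepc_error_builder")
  }
  cay <- c(0, 0, 0)
  cy <- c(1.51, 0, 0)
  # third atom in the xy-plane at the CAY-CY-N angle
  nn <- cy + 1.34 * c(cos(deg2rad(180 - 115)), sin(deg2rad(180 - 115)), 0)
  oy <- place_nerf(nn, cay, cy, 1.23, 121, 180)
  ca <- place_nerf(cay, cy, nn, 1.46, 122, 180)
  cc <- place_nerf(cy, nn, ca, 1.52, 111, phi)
  oo <- place_nerf(nn, ca, cc, 1.24, 121, wrap_angle(psi + 180))
  nt <- place_nerf(nn, ca, cc, 1.34, 115, psi)
  cmt <- place_nerf(ca, cc, nt, 1.46, 121, 180)
  hn <- place_nerf(cay, cy, nn, 1.01, 119, 0)
  hnt <- place_nerf(ca, cc, nt, 1.01, 119, 0)
  rows <- list(
    atom_row("CAY", "C", cay, 0.00),
    atom_row("CY", "C", cy, 0.50),
    atom_row("N", "N", nn, -0.45),
    atom_row("OY", "O", oy, -0.50),
    atom_row("CA", "C", ca, 0.10),
    atom_row("C", "C", cc, 0.50),
    atom_row("O", "O", oo, -0.50),
    atom_row("NT", "N", nt, -0.45),
    atom_row("CMT", "C", cmt, 0.10),
    atom_row("HN", "H", hn, 0.30),
    atom_row("HNT", "H", hnt, 0.30)
  )
  idx_side0 <- 12L
  side <- build_side_chain(template, ca, nn, cy, chis, idx_side0, t_cb)
  rows <- c(rows, side$rows)
  atoms <- bind_atom_rows(rows)
  topo <- list(
    C_prev = 2L, N = 3L, O_prev = 4L, CA = 5L, C = 6L, O = 7L, N_next = 8L,
    CB = if (template$n_chain > 0) idx_side0 else NA_integer_,
    chi = capped_chi_quads(template, idx_side0),
    side_donors = side_donor_indices(template, idx_side0)
  )
  finish_build(atoms, topo, template, min_nonbonded)
}

# chi torsion atom quadruples for the topology map
free_chi_quads <- function(template, i0) chi_quads(template, i0, n_idx = 1L, ca_idx = 2L)
capped_chi_quads <- function(template, i0) chi_quads(template, i0, n_idx = 3L, ca_idx = 5L)

chi_quads <- function(template, i0, n_idx, ca_idx) {
  if (template$n_chi == 0) {
    return(list())
  }
  chain <- c(n_idx, ca_idx, seq.int(i0, i0 + template$n_chain - 1L))
  extra_tip <- if (!template$terminal %in% c("none", "methyl")) {
    i0 + template$n_chain # first terminal heavy atom follows the chain
  } else {
    NULL
  }
  full <- c(chain, extra_tip)
  lapply(seq_len(template$n_chi), function(k) full[k:(k + 3)])
}

# heavy side-chain donor atoms (carry H) for evidence reporting
side_donor_indices <- function(template, i0) {
  if (template$n_chain == 0) {
    return(integer(0))
  }
  base <- i0 + template$n_chain
  switch(template$terminal,
    hydroxyl = base,
    thiol = base,
    carboxylic_acid = base + 2L,
    amine = base,
    ammonium = base,
    guanidino_like = c(base, base + 2L, base + 3L),
    imidazole_like = base + 2L,
    amide = base + 2L,
    integer(0)
  )
}

finish_build <- function(atoms, topo, template, min_nonbonded, self_energy = 0) {
  cf <- conformer(atoms[, c("element", "x", "y", "z", "charge")],
    energy = NA_real_,
    meta = list(
      topology = topo, template = template$name, atom_names = atoms$name,
      self_energy = self_energy
    )
  )
  # steric check over nonbonded pairs
  adj <- bond_matrix(cf)
  dm <- as.matrix(stats::dist(coords(cf)))
  bad <- dm < min_nonbonded & !adj & upper.tri(dm)
  if (any(bad)) {
    abort("clash: nonbonded atoms closer than threshold after placement",
      class = "pepc_error_builder"
    )
  }
  cf
}

#' Place a cation at a binding site
#'
#' Puts the ion on the bisector of the site's ligating atoms at the
#' requested mean ligand distance (or at the two requested distances for an
#' asymmetric bridge), on the side facing away from the molecule.
#'
#' @param conf A `pepc_conformer` with topology metadata.
#' @param site One of `"carbonyl_bridge"` (acetyl O + residue carbonyl O),
#'   `"carboxylate"` (the two carboxyl O), `"amine_carbonyl"` (backbone N +
#'   carbonyl O), `"side_chain"` (terminal heavy atom).
#' @param ion Element symbol of the divalent cation.
#' @param distance Mean cation-ligand distance, Angstrom.
#' @param distance2 Optional second distance: the bridge becomes asymmetric
#'   with the first ligand at `distance` and the second at `distance2`.
#' @return A new `pepc_conformer` with the ion appended (`meta$ion_index`).
#' @export
place_ion <- function(conf, site, ion, distance, distance2 = NULL) {
  if (!is_cation_element(ion)) {
    abort(paste0("'", ion, "' is not a registered cation"), class = "pepc_error_builder")
  }
  topo <- conf$meta$topology
  xyz <- coords(conf)
  pair <- switch(site,
    carbonyl_bridge = {
      if (is.null(topo$O_prev)) {
        abort("carbonyl_bridge needs a capped backbone", class = "pepc_error_builder")
      }
      c(topo$O_prev, topo$O)
    },
    carboxylate = {
      if (is.null(topo$O_carbonyl)) {
        abort("carboxylate site needs a free backbone", class = "pepc_error_builder")
      }
      c(topo$O_carbonyl, topo$O_hydroxyl)
    },
    amine_carbonyl = {
      if (is.null(topo$O_carbonyl)) {
        abort("amine_carbonyl site needs a free backbone", class = "pepc_error_builder")
      }
      c(topo$N, topo$O_carbonyl)
    },
    side_chain = NULL,
    abort(paste0("unknown site '", site, "'"), class = "pepc_error_builder")
  )
  if (is.null(pair)) {
    # single-atom site: terminal heavy atom, placed radially outwards
    donors <- topo$side_donors
    tip <- if (length(donors) > 0) donors[1] else topo$CB
    if (is.na(tip)) {
      abort("side_chain site needs a side chain", class = "pepc_error_builder")
    }
    ctr <- colMeans(xyz)
    dir <- unit(xyz[tip, ] - ctr)
    pos <- xyz[tip, ] + distance * dir
  } else {
    p <- xyz[pair[1], ]
    q <- xyz[pair[2], ]
    sep <- vnorm(q - p)
    d1 <- distance
    d2 <- distance2 %||% distance
    if (sep >= d1 + d2) {
      abort("site atoms too far apart for the requested distances",
        class = "pepc_error_builder"
      )
    }
    ctr <- colMeans(xyz)
    axis <- unit(q - p)
    mid_dir <- (p + q) / 2 - ctr
    perp <- mid_dir - sum(mid_dir * axis) * axis
    if (vnorm(perp) < 1e-6) {
      perp <- cross3(axis, c(0, 0, 1))
      if (vnorm(perp) < 1e-6) perp <- cross3(axis, c(0, 1, 0))
    }
    perp <- unit(perp)
    xloc <- (sep^2 + d1^2 - d2^2) / (2 * sep)
    h2 <- d1^2 - xloc^2
    if (h2 < 0) {
      abort("requested bridge distances are inconsistent with the site geometry",
        class = "pepc_error_builder"
      )
    }
    pos <- p + xloc * axis + sqrt(h2) * perp
  }
  atoms <- dplyr::bind_rows(
    conf$atoms,
    tibble(element = ion, x = pos[1], y = pos[2], z = pos[3], charge = 2)
  )
  meta <- conf$meta
  meta$ion_index <- nrow(atoms)
  conformer(atoms, energy = conf$energy, meta = meta)
}
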