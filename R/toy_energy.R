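# Toy interaction energy: screened Coulomb + Lennard-Jones + a geometric
# hydrogen-bond well + per-ion coordination terms. A deliberately simple,
# deterministic stand-in for the first-principles total energies the
# analysis operates on; only the statistical structure (class ordering, ion
# ordering, contraction) is meant to be faithful.

#' Toy energy model parameters
#'
#' @param eps_r Dielectric screening of Coulomb pairs involving a cation.
#' @param eps_mol Dielectric screening of molecule-internal Coulomb pairs
#'   (stronger, so that class-defining hydrogen bonds rather than long-range
#'   conformational electrostatics set the energy ordering).
#' @param e_hb Named hydrogen-bond well depths by donor element (eV),
#'   modulated by a floored squared-cosine of the D-H-A angle.
#' @param hb_d0,hb_w Centre and width of the Gaussian H...A distance well,
#'   Angstrom.
#' @param hb_side_scale Scale applied to wells donated by side-chain donors
#'   (the simplified side chains should not out-compete the backbone
#'   motifs the taxonomy is built on).
#' @param lj_eps Lennard-Jones well depth for molecular atoms, eV.
#' @param base_well Depth of the Gaussian cation-O coordination well every
#'   ion carries at its preferred contact distance, eV.
#' @param ions Per-ion list: `charge`, `radius` (toy effective radius,
#'   Angstrom; Shannon-ordered Ca < Sr < Ba), `contact` (preferred
#'   cation-O distance), `bonus` (extra coordination well depth, eV),
#'   `hg_like` (two-short-ligand term switch), and for the Hg-like ion
#'   `short_contact` / `short_bonus`.
#' @return A parameter list of class `pepc_toyparams`.
#' @export
toy_energy_params <- function(eps_r = 4, eps_mol = 10,
                              e_hb = c(O = 1.1, N = 1.1, S = 0.5),
                              hb_d0 = 1.85, hb_w = 0.35, hb_side_scale = 0.4,
                              lj_eps = 0.005, base_well = 0.8, ions = NULL) {
  ions <- ions %||% list(
    Ca = list(charge = 2, radius = 1.00, contact = 2.30, bonus = 0, hg_like = FALSE),
    Sr = list(charge = 2, radius = 1.18, contact = 2.48, bonus = 0, hg_like = FALSE),
    Ba = list(charge = 2, radius = 1.35, contact = 2.65, bonus = 0, hg_like = FALSE),
    Cd = list(charge = 2, radius = 0.95, contact = 2.25, bonus = 0.3, hg_like = FALSE),
    # toy Pb is parameterised identically to Ca: the mimicry condition
    Pb = list(charge = 2, radius = 1.00, contact = 2.30, bonus = 0, hg_like = FALSE),
    Hg = list(
      charge = 2, radius = 1.02, contact = 2.30, bonus = 0.3, hg_like = TRUE,
      short_contact = 2.00, short_bonus = 2.8, long_contact = 2.60
    )
  )
  if (!(ions$Ca$radius < ions$Sr$radius && ions$Sr$radius < ions$Ba$radius)) {
    abort("toy ion radii must be ordered Ca < Sr < Ba", class = "pepc_error_toy")
  }
  structure(
    list(
      eps_r = eps_r, eps_mol = eps_mol, e_hb = e_hb, hb_d0 = hb_d0, hb_w = hb_w,
      hb_side_scale = hb_side_scale, lj_eps = lj_eps, base_well = base_well,
      lj_sigma = c(H = 2.0, C = 3.4, N = 3.2, O = 3.0, S = 3.6),
      ions = ions
    ),
    class = "pepc_toyparams"
  )
}

# pairs within 2 bonds of each other (1-2 and 1-3 neighbours)
bonded_within <- function(adj, k = 2) {
  m <- adj
  reach <- adj
  for (i in seq_len(k - 1)) {
    m <- (m %*% adj) > 0
    reach <- reach | m
  }
  diag(reach) <- FALSE
  reach
}

#' Toy total energy of a conformer
#'
#' Screened Coulomb over all atom pairs separated by more than two bonds,
#' Lennard-Jones for the same pairs, an angle-modulated Gaussian
#' hydrogen-bond well, and per-ion coordination terms (a Gaussian well at
#' the ion's preferred cation-O contact distance; for the Hg-like ion an
#' additional deep short-range well applied to its two nearest oxygens).
#' Translation and rotation invariant; an isolated atom has energy zero.
#'
#' @param conf A `pepc_conformer` whose atoms carry a `charge` column.
#' @param params A `pepc_toyparams` list.
#' @return Energy in eV.
#' @export
toy_energy <- function(conf, params = toy_energy_params()) {
  atoms <- conf$atoms
  if (nrow(atoms) == 1) {
    return(0)
  }
  if (!"charge" %in% names(atoms) || any(is.na(atoms$charge))) {
    abort("untyped atom: all atoms need a toy partial charge", class = "pepc_error_toy")
  }
  el <- atoms$element
  xyz <- coords(conf)
  dm <- as.matrix(stats::dist(xyz))
  adj <- bond_matrix(conf)
  excl <- bonded_within(adj, 2)
  q <- atoms$charge
  is_ion <- is_cation_element(el)

  pair_mask <- upper.tri(dm) & !excl
  e_coul <- 0
  e_lj <- 0
  idx <- which(pair_mask, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    r <- dm[pair_mask]
    qq <- q[idx[, 1]] * q[idx[, 2]]
    ion_involved <- is_ion[idx[, 1]] | is_ion[idx[, 2]]
    eps <- ifelse(ion_involved, params$eps_r, params$eps_mol)
    e_coul <- sum(COULOMB_EV_A * qq / (eps * r))
    # LJ acts between heavy atoms only (polar-hydrogen convention: H sterics
    # are handled by the builder's clash threshold, and H-bond contacts must
    # not sit on a repulsive wall); ion pairs use the preferred contact
    # distance as the minimum position
    sig_of <- function(i) {
      if (is_ion[i]) NA_real_ else params$lj_sigma[[el[i]]] %||% 3.4
    }
    s1 <- vapply(idx[, 1], sig_of, double(1))
    s2 <- vapply(idx[, 2], sig_of, double(1))
    sig <- (s1 + s2) / 2
    ion_pair <- is.na(s1) | is.na(s2)
    if (any(ion_pair)) {
      ion_el <- ifelse(is.na(s1), el[idx[, 1]], el[idx[, 2]])[ion_pair]
      contact <- vapply(ion_el, function(e) {
        p <- params$ions[[e]]
        if (is.null(p)) abort(paste0("no toy parameters for ion ", e), class = "pepc_error_toy")
        p$contact
      }, double(1))
      sig[ion_pair] <- contact / 2^(1 / 6)
    }
    h_pair <- el[idx[, 1]] == "H" | el[idx[, 2]] == "H"
    sr6 <- (sig / r)^6
    e_lj <- sum((4 * params$lj_eps * (sr6^2 - sr6))[!h_pair])
  }

  # hydrogen-bond wells on geometrically detected contacts
  e_hb <- 0
  hb <- detect_hbonds(conf, hbond_criteria(
    max_d_ha = params$hb_d0 + 3 * params$hb_w, max_d_da = 4.5, min_angle = 91
  ))
  if (nrow(hb) > 0) {
    depth <- params$e_hb[el[hb$donor]]
    depth[is.na(depth)] <- 0
    side <- conf$meta$topology$side_donors %||% integer(0)
    depth[hb$donor %in% side] <- depth[hb$donor %in% side] * params$hb_side_scale
    fang <- 0.25 + 0.75 * cos(deg2rad(hb$angle_dha))^2
    fdist <- exp(-((hb$d_ha - params$hb_d0) / params$hb_w)^2)
    e_hb <- -sum(depth * fang * fdist)
  }

  # ion coordination wells
  e_ion <- 0
  for (i in which(is_ion)) {
    p <- params$ions[[el[i]]]
    if (is.null(p)) {
      abort(paste0("no toy parameters for ion ", el[i]), class = "pepc_error_toy")
    }
    o_idx <- which(el == "O")
    if (length(o_idx) == 0) next
    r <- dm[i, o_idx]
    near <- r <= 3.5
    depth <- params$base_well + p$bonus
    e_ion <- e_ion - depth * sum(exp(-((r[near] - p$contact) / 0.30)^2))
    if (isTRUE(p$hg_like) && any(near)) {
      # the Hg-like covalency surrogate: one deep short-range well pulling
      # the nearest oxygen in closer than the ionic contact
      nearest <- which.min(r)
      e_ion <- e_ion - p$short_bonus *
        exp(-((r[nearest] - p$short_contact) / 0.30)^2)
    }
  }
  # protomer self-energy (e.g. the proton-transfer penalty that makes the
  # gas-phase zwitterion compete with, rather than dominate, the neutral
  # forms); recorded by the builder
  e_self <- conf$meta$self_energy %||% 0
  e_coul + e_lj + e_hb + e_ion + e_self
}

#' Reference energy of an isolated ion in the toy model
#'
#' By construction zero: the toy energy contains only interatomic terms.
#'
#' @param ion Element symbol.
#' @param params Toy parameters (checked for the ion's presence).
#' @return 0 (eV).
#' @export
toy_ion_energy <- function(ion, params = toy_energy_params()) {
  if (is.null(params$ions[[ion]])) {
    abort(paste0("no toy parameters for ion ", ion), class = "pepc_error_toy")
  }
  0
}
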