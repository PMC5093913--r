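# Low-level geometric measurements on conformers.

vnorm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("zero-length vector", class = "pepc_error_geometry")
  v / n
}

dist_pair <- function(xyz, i, j) vnorm(xyz[i, ] - xyz[j, ])

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention; result in degrees in the interval (-180, 180].
#' Invariant under rigid rotation and translation.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Dihedral angle in degrees.
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(cos(pi / 3), sin(pi / 3), 1))
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9) {
    abort("undefined dihedral: coincident consecutive points",
      class = "pepc_error_geometry"
    )
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    abort("undefined dihedral: collinear consecutive points",
      class = "pepc_error_geometry"
    )
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * unit(b2))
  ang <- atan2(y, x) * 180 / pi
  wrap_angle(ang)
}

# Wrap an angle in degrees into (-180, 180].
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(abs(a + 180) < 1e-12, 180, a)
}

angle_deg <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Backbone and side-chain torsion angles
#'
#' Computes phi (C'prev-N-CA-C), psi (N-CA-C-Nnext) and the chi torsions
#' named by the topology map. Atoms absent from the topology (e.g. no acetyl
#' cap on a free amino acid) yield `NA` angles rather than errors.
#'
#' @param conf A `pepc_conformer`.
#' @param topology Named list of 1-based atom indices with entries `N`, `CA`,
#'   `C`, optionally `C_prev` (acetyl carbonyl C), `N_next` (amide N) and
#'   `chi`, a list of 4-long index vectors for the side-chain torsions.
#' @return A one-row tibble with `phi`, `psi` (degrees) and a list-column
#'   `chi` of side-chain torsions.
#' @export
backbone_torsions <- function(conf, topology) {
  xyz <- coords(conf)
  idx_ok <- function(i) {
    !is.null(i) && length(i) == 1 && !is.na(i)
  }
  check_range <- function(i) {
    if (any(i < 1 | i > nrow(xyz))) {
      abort("topology references out-of-range atom index",
        class = "pepc_error_topology"
      )
    }
    i
  }
  tors <- function(ii) {
    ii <- check_range(ii)
    dihedral(xyz[ii[1], ], xyz[ii[2], ], xyz[ii[3], ], xyz[ii[4], ])
  }
  for (r in c("N", "CA", "C")) {
    if (!idx_ok(topology[[r]])) {
      abort(paste0("topology lacks backbone atom '", r, "'"),
        class = "pepc_error_topology"
      )
    }
  }
  phi <- if (idx_ok(topology$C_prev)) {
    tors(c(topology$C_prev, topology$N, topology$CA, topology$C))
  } else {
    NA_real_
  }
  psi <- if (idx_ok(topology$N_next)) {
    tors(c(topology$N, topology$CA, topology$C, topology$N_next))
  } else {
    NA_real_
  }
  chis <- lapply(topology$chi %||% list(), tors)
  tibble(phi = phi, psi = psi, chi = list(unlist(chis) %||% double(0)))
}

#' Default geometric hydrogen-bond criteria
#'
#' @param max_d_ha Maximum H...acceptor distance, Angstrom.
#' @param max_d_da Maximum donor...acceptor distance, Angstrom.
#' @param min_angle Minimum donor-H-acceptor angle, degrees.
#' @return A named list of criteria.
#' @export
hbond_criteria <- function(max_d_ha = 2.5, max_d_da = 3.5, min_angle = 120) {
  list(max_d_ha = max_d_ha, max_d_da = max_d_da, min_angle = min_angle)
}

HB_ELEMENTS <- c("N", "O", "S")

# Covalent bond test by element-pair distance cutoff.
covalent_cutoff_pair <- function(el1, el2, scale = 1.25) {
  r1 <- COVALENT_RADII[el1]
  r2 <- COVALENT_RADII[el2]
  unname((r1 + r2) * scale)
}

# Adjacency matrix of covalent bonds. Cations are never bonded.
bond_matrix <- function(conf, scale = 1.25) {
  el <- conf$atoms$element
  xyz <- coords(conf)
  n <- nrow(xyz)
  dm <- as.matrix(stats::dist(xyz))
  rc <- COVALENT_RADII[el]
  rc[is.na(rc)] <- 0 # metals etc: no covalent bonds
  cut <- outer(rc, rc, "+") * scale
  adj <- dm > 0 & dm <= cut & outer(rc > 0, rc > 0, "&")
  diag(adj) <- FALSE
  adj
}

#' Detect intramolecular hydrogen bonds
#'
#' Geometric criteria: donor and acceptor are N/O/S, the hydrogen is
#' covalently attached to the donor, and the H...A distance, D...A distance
#' and D-H-A angle all satisfy the given thresholds.
#'
#' @param conf A `pepc_conformer`.
#' @param criteria A list from [hbond_criteria()].
#' @return Tibble with one row per bond: `donor`, `hydrogen`, `acceptor`
#'   (atom indices), `d_ha`, `d_da` (Angstrom), `angle_dha` (degrees),
#'   sorted by `d_ha`. Zero rows when none found.
#' @export
detect_hbonds <- function(conf, criteria = hbond_criteria()) {
  el <- conf$atoms$element
  xyz <- coords(conf)
  adj <- bond_matrix(conf)
  h_idx <- which(el == "H")
  acceptors_all <- which(el %in% HB_ELEMENTS)
  donor <- integer()
  hydrogen <- integer()
  acceptor <- integer()
  d_ha <- double()
  d_da <- double()
  angle_dha <- double()
  for (h in h_idx) {
    donors <- unname(which(adj[h, ] & el %in% HB_ELEMENTS))
    if (length(donors) == 0) next
    # the covalent partner: nearest bonded heavy atom
    dd <- sqrt(colSums((t(xyz[donors, , drop = FALSE]) - xyz[h, ])^2))
    d <- donors[which.min(dd)]
    acc <- setdiff(acceptors_all, d)
    if (length(acc) == 0) next
    r_ha <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[h, ])^2))
    keep <- r_ha <= criteria$max_d_ha
    acc <- acc[keep]
    r_ha <- r_ha[keep]
    if (length(acc) == 0) next
    r_da <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[d, ])^2))
    keep <- r_da <= criteria$max_d_da
    acc <- acc[keep]
    r_ha <- r_ha[keep]
    r_da <- r_da[keep]
    if (length(acc) == 0) next
    ang <- vapply(seq_along(acc), function(k) {
      angle_deg(xyz[d, ], xyz[h, ], xyz[acc[k], ])
    }, double(1))
    keep <- ang >= criteria$min_angle
    if (!any(keep)) next
    donor <- c(donor, rep(d, sum(keep)))
    hydrogen <- c(hydrogen, rep(h, sum(keep)))
    acceptor <- c(acceptor, acc[keep])
    d_ha <- c(d_ha, r_ha[keep])
    d_da <- c(d_da, r_da[keep])
    angle_dha <- c(angle_dha, ang[keep])
  }
  out <- tibble(
    donor = donor, hydrogen = hydrogen, acceptor = acceptor,
    d_ha = d_ha, d_da = d_da, angle_dha = angle_dha
  )
  out[order(out$d_ha), ]
}

#' Assign each hydrogen to its nearest heavy atom
#'
#' Protonation-state bookkeeping: every H is attached to the nearest heavy
#' atom within `covalent_cutoff`; when the two nearest heavy atoms lie within
#' `shared_band` of each other the proton is flagged `"shared"` (the
#' shared-proton situation between carboxyl O and amino N); an H with no
#' heavy atom within the cutoff is flagged `"orphan"`.
#'
#' @param conf A `pepc_conformer`.
#' @param covalent_cutoff Maximum assignment distance, Angstrom.
#' @param shared_band Distance-difference band for the `"shared"` flag.
#' @return Tibble: `hydrogen`, `heavy`, `heavy_element`, `distance`,
#'   `second`, `second_distance`, `status` (assigned/shared/orphan).
#' @export
assign_protons <- function(conf, covalent_cutoff = 1.3, shared_band = 0.15) {
  el <- conf$atoms$element
  xyz <- coords(conf)
  h_idx <- which(el == "H")
  if (length(h_idx) == 0) {
    abort("conformer contains no hydrogen", class = "pepc_error_geometry")
  }
  heavy <- which(el != "H" & !is_cation_element(el))
  hvy_xyz <- t(xyz[heavy, , drop = FALSE])
  nearest <- integer(length(h_idx))
  d1 <- double(length(h_idx))
  second <- rep(NA_integer_, length(h_idx))
  d2 <- rep(NA_real_, length(h_idx))
  for (k in seq_along(h_idx)) {
    dd <- sqrt(colSums((hvy_xyz - xyz[h_idx[k], ])^2))
    o <- order(dd)
    nearest[k] <- heavy[o[1]]
    d1[k] <- dd[o[1]]
    if (length(o) > 1) {
      second[k] <- heavy[o[2]]
      d2[k] <- dd[o[2]]
    }
  }
  status <- ifelse(d1 > covalent_cutoff, "orphan",
    ifelse(!is.na(d2) & (d2 - d1) <= shared_band, "shared", "assigned")
  )
  tibble(
    hydrogen = h_idx, heavy = nearest, heavy_element = el[nearest],
    distance = d1, second = second, second_distance = d2, status = status
  )
}

#' Trace a hydrogen-bonded or cation-closed pseudocycle
#'
#' Follows the covalent path between the closure end points and counts ring
#' members as heavy atoms on the path plus the closing hydrogen or cation
#' (the convention behind the C5/C7/iC7 names).
#'
#' @param conf A `pepc_conformer`.
#' @param closure For a hydrogen bond: `list(donor=, hydrogen=, acceptor=)`;
#'   for a cation bridge: `list(cation=, o1=, o2=)` (1-based indices).
#' @return A list of class `pepc_pseudocycle`: `members` (heavy-atom indices
#'   along the ring), `closing` (H or cation index), `closure_type`
#'   (`"hydrogen_bond"` or `"cation_bridge"`), `size`.
#' @export
find_pseudocycle <- function(conf, closure) {
  el <- conf$atoms$element
  adj <- bond_matrix(conf)
  # path search over heavy atoms only
  heavy <- which(el != "H" & !is_cation_element(el))
  if (!is.null(closure$cation)) {
    from <- closure$o1
    to <- closure$o2
    closing <- closure$cation
    ctype <- "cation_bridge"
    if (!is_cation_element(el[closing])) {
      abort("closure$cation is not a registered cation element",
        class = "pepc_error_geometry"
      )
    }
  } else {
    from <- closure$donor
    to <- closure$acceptor
    closing <- closure$hydrogen
    ctype <- "hydrogen_bond"
  }
  sub <- adj[heavy, heavy, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  vi <- match(from, heavy)
  vj <- match(to, heavy)
  if (is.na(vi) || is.na(vj)) {
    abort("closure end points must be heavy non-cation atoms",
      class = "pepc_error_geometry"
    )
  }
  sp <- suppressWarnings(igraph::shortest_paths(g, from = vi, to = vj)$vpath[[1]])
  if (length(sp) == 0) {
    abort("no ring: closure end points are not covalently connected",
      class = "pepc_error_geometry"
    )
  }
  members <- heavy[as.integer(sp)]
  structure(
    list(
      members = members, closing = closing,
      closure_type = ctype, size = length(members) + 1L
    ),
    class = "pepc_pseudocycle"
  )
}

#' @export
print.pepc_pseudocycle <- function(x, ...) {
  cat(
    "<pepc_pseudocycle> size ", x$size, " (", x$closure_type, "), members ",
    paste(x$members, collapse = "-"), " + ", x$closing, "\n",
    sep = ""
  )
  invisible(x)
}

#' Axial or equatorial side-chain orientation
#'
#' Fits a least-squares plane to the pseudocycle members (including the
#' closing atom) and measures the angle between the CA->CB vector and the
#' plane normal; below 45 degrees the side chain is axial, otherwise
#' equatorial.
#'
#' @param conf A `pepc_conformer`.
#' @param pseudocycle A `pepc_pseudocycle` (or an integer vector of ring
#'   member indices).
#' @param ca_index,cb_index Indices of CA and CB.
#' @param threshold Axial/equatorial split angle, degrees.
#' @return A list: `orientation` (`"axial"`/`"equatorial"`), `theta`
#'   (degrees to the normal).
#' @export
side_chain_orientation <- function(conf, pseudocycle, ca_index, cb_index,
                                   threshold = 45) {
  if (is.null(cb_index) || length(cb_index) == 0 || is.na(cb_index)) {
    abort("no side chain: CB is absent (Gly)", class = "pepc_error_geometry")
  }
  members <- if (inherits(pseudocycle, "pepc_pseudocycle")) {
    c(pseudocycle$members, pseudocycle$closing)
  } else {
    pseudocycle
  }
  if (length(members) < 4) {
    abort("pseudocycle must have at least 4 members", class = "pepc_error_geometry")
  }
  xyz <- coords(conf)
  ring <- xyz[members, , drop = FALSE]
  ctr <- colMeans(ring)
  sv <- svd(sweep(ring, 2, ctr))
  normal <- sv$v[, 3]
  v <- xyz[cb_index, ] - xyz[ca_index, ]
  costh <- abs(sum(unit(v) * unit(normal)))
  theta <- acos(pmin(1, costh)) * 180 / pi
  list(
    orientation = if (theta < threshold) "axial" else "equatorial",
    theta = theta
  )
}

#' Minimal RMSD after optimal superposition (Kabsch)
#'
#' Least-squares superposition over proper rotations and translation.
#'
#' @param conf_a,conf_b Conformers with identical element sequences.
#' @param heavy_only Drop hydrogens before superposing?
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(conf_a, conf_b, heavy_only = FALSE) {
  ea <- conf_a$atoms$element
  eb <- conf_b$atoms$element
  if (length(ea) != length(eb) || !all(ea == eb)) {
    abort("conformers differ in atoms; cannot superpose", class = "pepc_error_geometry")
  }
  keep <- if (heavy_only) which(ea != "H") else seq_along(ea)
  A <- coords(conf_a)[keep, , drop = FALSE]
  B <- coords(conf_b)[keep, , drop = FALSE]
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  diffs <- B - A %*% t(R)
  sqrt(sum(diffs^2) / nrow(A))
}
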