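# Independent brute-force oracles and small fixture builders used across the
# test files. The oracles deliberately use the dumbest correct algorithm.

# exhaustive triple-loop hydrogen-bond search
oracle_hbonds <- function(conf, criteria) {
  el <- conf$atoms$element
  xyz <- coords(conf)
  n <- nrow(xyz)
  dd <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  ang <- function(i, j, k) {
    v1 <- xyz[i, ] - xyz[j, ]
    v2 <- xyz[k, ] - xyz[j, ]
    acos(min(1, max(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }
  # covalent H attachment: nearest N/O/S within the covalent cutoff
  res <- NULL
  for (h in seq_len(n)) {
    if (el[h] != "H") next
    best_d <- Inf
    donor <- NA
    for (d in seq_len(n)) {
      if (!(el[d] %in% c("N", "O", "S"))) next
      r <- dd(h, d)
      if (r < best_d && r <= 1.25 * (0.31 + pepcation:::COVALENT_RADII[el[d]])) {
        best_d <- r
        donor <- d
      }
    }
    if (is.na(donor)) next
    for (a in seq_len(n)) {
      if (a == donor || !(el[a] %in% c("N", "O", "S"))) next
      if (dd(h, a) > criteria$max_d_ha) next
      if (dd(donor, a) > criteria$max_d_da) next
      if (ang(donor, h, a) < criteria$min_angle) next
      res <- rbind(res, data.frame(donor = donor, hydrogen = h, acceptor = a))
    }
  }
  res
}

# numeric cross-product dihedral oracle
oracle_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(a, b) {
    c(
      a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1]
    )
  }
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cr(n1, n2) * b2 / sqrt(sum(b2^2)))
  atan2(y, x) * 180 / pi
}

rot_xyz <- function(a, b, c) {
  rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  rz <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
  rz %*% ry %*% rx
}

# hierarchical grid search over proper rotations (after centering); returns
# the minimal RMSD found
oracle_rmsd_grid <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  rmsd_at <- function(ang) {
    R <- rot_xyz(ang[1], ang[2], ang[3])
    sqrt(sum((B - A %*% t(R))^2) / nrow(A))
  }
  centre <- c(0, 0, 0)
  width <- pi
  best <- Inf
  best_ang <- centre
  for (pass in 1:5) {
    grid <- seq(-width, width, length.out = 9)
    for (a in centre[1] + grid) {
      for (b in centre[2] + grid / 2) {
        for (cc in centre[3] + grid) {
          v <- rmsd_at(c(a, b, cc))
          if (v < best) {
            best <- v
            best_ang <- c(a, b, cc)
          }
        }
      }
    }
    centre <- best_ang
    width <- width / 4
  }
  best
}

# O(n^2) Kendall tau-b with tie correction
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j])
      dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) {
        # joint tie: counted in neither correction term
      } else if (dx == 0) {
        tx <- tx + 1
      } else if (dy == 0) {
        ty <- ty + 1
      } else if (dx == dy) {
        conc <- conc + 1
      } else {
        disc <- disc + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# a rigid rotation + translation applied to a conformer
transform_conformer <- function(conf, angles = c(0.3, 1.1, -0.7), shift = c(1, -2, 3)) {
  R <- rot_xyz(angles[1], angles[2], angles[3])
  xyz <- coords(conf) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  at <- conf$atoms
  at$x <- xyz[, 1]
  at$y <- xyz[, 2]
  at$z <- xyz[, 3]
  conformer(at, energy = conf$energy, meta = conf$meta)
}

# small fixed fixtures
water_conformer <- function() {
  conformer(
    data.frame(
      element = c("O", "H", "H"),
      x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = c(0, 0, 0)
    ),
    energy = -1.0, meta = list(system = "water")
  )
}

ala_free_template <- function() residue_template("ala", "free", 1, "none")
ala_capped_template <- function() residue_template("ala", "capped", 1, "none")
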