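# Torsional basin-hopping: Monte-Carlo perturbation of the torsion vector,
# local minimisation on the (toy) potential, Metropolis acceptance on the
# minimised energies, and angular deduplication of the minima found.

wrap_torsions <- function(t) wrap_angle(t)

# circular distance between torsion vectors, degrees
torsion_distance <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  max(d)
}

#' Basin-hopping over an arbitrary torsional objective
#'
#' The generic engine: repeatedly perturb the torsion vector, locally
#' minimise the objective, accept or reject on the minimised energy
#' (Metropolis), and collect distinct minima.
#'
#' @param objective Function mapping a numeric torsion vector (degrees) to
#'   an energy (eV); may return `Inf` for infeasible geometries.
#' @param n_torsions Dimension of the torsion vector.
#' @param n_steps Number of basin-hopping steps (>= 1).
#' @param step_deg Scale of the uniform torsion perturbation, degrees.
#' @param seed RNG seed (required: runs are reproducible by construction).
#' @param temperature_ev Metropolis temperature for accepting uphill moves.
#' @param dedup_deg Minima closer than this (max circular torsion
#'   difference) are considered the same basin.
#' @param start Optional starting torsions; random otherwise.
#' @return A tibble of distinct minima: `energy` and a `torsions`
#'   list-column, sorted by energy.
#' @export
basin_hop <- function(objective, n_torsions, n_steps = 100, step_deg = 60,
                      seed = 1, temperature_ev = 0.2, dedup_deg = 20,
                      start = NULL) {
  if (n_steps < 1) abort("n_steps must be >= 1", class = "pepc_error_basinhop")
  with_pepc_seed(seed, {
    cur <- start %||% stats::runif(n_torsions, -180, 180)
    minimize <- function(t0) {
      if (n_torsions == 1) {
        # gradient descent from t0 keeps the hop inside the nearest basin
        op <- optim(t0, function(t) objective(wrap_torsions(t)),
          method = "BFGS", control = list(reltol = 1e-10)
        )
      } else {
        op <- optim(t0, function(t) objective(wrap_torsions(t)),
          method = "Nelder-Mead", control = list(maxit = 400, reltol = 1e-8)
        )
      }
      list(par = wrap_torsions(op$par), value = op$value)
    }
    m <- minimize(cur)
    cur <- m$par
    cur_e <- m$value
    minima <- list(list(par = cur, e = cur_e))
    for (step in seq_len(n_steps - 1)) {
      cand <- wrap_torsions(cur + stats::runif(n_torsions, -step_deg, step_deg))
      mc <- minimize(cand)
      if (is.finite(mc$value)) {
        known <- any(vapply(minima, function(mm) {
          torsion_distance(mm$par, mc$par) < dedup_deg
        }, logical(1)))
        if (!known) minima[[length(minima) + 1L]] <- list(par = mc$par, e = mc$value)
        if (mc$value <= cur_e ||
          stats::runif(1) < exp(-(mc$value - cur_e) / temperature_ev)) {
          cur <- mc$par
          cur_e <- mc$value
        }
      }
    }
    es <- vapply(minima, `[[`, double(1), "e")
    ord <- order(es)
    tibble(
      energy = es[ord],
      torsions = lapply(minima[ord], `[[`, "par")
    )
  })
}

#' Basin-hopping conformer search on the toy potential
#'
#' Searches the torsion space of a template (phi/psi and side-chain chis for
#' capped templates; carboxyl orientation and chis for free ones) on the toy
#' energy surface, optionally with a cation placed at a binding site before
#' each evaluation.
#'
#' @param template A `pepc_template`.
#' @param params Toy energy parameters.
#' @param n_steps,step_deg,seed,temperature_ev,dedup_deg See [basin_hop()].
#' @param ion_site Optional list `list(site =, ion =, distance =)` passed to
#'   [place_ion()] for every evaluated geometry.
#' @return An ensemble tibble of the distinct minima found, energies from
#'   [toy_energy()], torsions in each conformer's metadata.
#' @export
basin_hop_search <- function(template, params = toy_energy_params(),
                             n_steps = 100, step_deg = 60, seed = 1,
                             temperature_ev = 0.2, dedup_deg = 20,
                             ion_site = NULL) {
  n_bb <- if (template$backbone == "capped") 2L else 1L
  n_t <- n_bb + template$n_chi
  build_at <- function(t) {
    if (template$backbone == "capped") {
      build_peptide(template,
        phi = t[1], psi = t[2],
        chis = if (template$n_chi > 0) t[-(1:2)] else NULL
      )
    } else {
      build_peptide(template,
        t_coo = t[1],
        chis = if (template$n_chi > 0) t[-1] else NULL
      )
    }
  }
  objective <- function(t) {
    cf <- tryCatch(build_at(t), error = function(e) NULL)
    if (is.null(cf)) {
      return(Inf)
    }
    if (!is.null(ion_site)) {
      cf <- tryCatch(
        place_ion(cf, ion_site$site, ion_site$ion, ion_site$distance),
        error = function(e) NULL
      )
      if (is.null(cf)) {
        return(Inf)
      }
    }
    toy_energy(cf, params)
  }
  minima <- basin_hop(objective, n_t,
    n_steps = n_steps, step_deg = step_deg,
    seed = seed, temperature_ev = temperature_ev, dedup_deg = dedup_deg
  )
  confs <- purrr::map2(minima$torsions, minima$energy, function(t, e) {
    cf <- build_at(t)
    if (!is.null(ion_site)) {
      cf <- place_ion(cf, ion_site$site, ion_site$ion, ion_site$distance)
    }
    cf$energy <- e
    cf$meta$torsions <- t
    cf
  })
  sys <- paste0(template$name, "_", template$backbone, "_",
    if (is.null(ion_site)) "none" else ion_site$ion)
  ensemble_tbl(confs, system = sys)
}
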