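# Labeled synthetic benchmark suite.
#
# For a panel of simplified ligands the generator emits, per backbone type
# and complexation state, a conformer ensemble whose members are built from
# class templates (so every conformer carries a constructive ground-truth
# label), with toy-model energies arranged so that the designated class is
# the global minimum, ion ensembles are smaller than bare ones, and the
# cross-ion binding-energy and coordination-distance structure mirrors the
# trends the analysis is meant to recover.

#' The default benchmark ligand panel
#'
#' Ten simplified ligands covering the terminal-group chemistry of the
#' proteinogenic side chains (none/methyl, hydroxyl, thiol, carboxylate,
#' ammonium, guanidino, amide, aromatic), with the designated global-minimum
#' class for each backbone/complexation combination.
#'
#' @return A tibble: `ligand`, `n_chain`, `terminal`, `free_gm`,
#'   `free_ion_gm`, `capped_gm`, `capped_ion_gm`.
#' @export
suite_panel <- function() {
  tibble::tribble(
    ~ligand, ~n_chain, ~terminal, ~free_gm, ~free_ion_gm, ~capped_gm, ~capped_ion_gm,
    "gly", 0L, "none", "typeII", "salt_bridge", "C5", "other",
    "ala", 1L, "none", "zwitterionic", "salt_bridge", "C7eq", "iC7eq",
    "ser", 1L, "hydroxyl", "typeII", "charge_solvated", "C7eq", "iC7ax",
    "cys", 1L, "thiol", "typeI", "salt_bridge", "C7ax", "iC7ax",
    "asp", 1L, "carboxylate", "typeII", "salt_bridge", "C7ax", "iC7ax",
    "glu", 2L, "carboxylate", "zwitterionic", "salt_bridge", "C7eq", "iC7ax",
    "lys", 3L, "ammonium", "zwitterionic", "salt_bridge", "C7ax", "iC7eq",
    "arg", 2L, "guanidino_like", "zwitterionic", "salt_bridge", "C7ax", "iC7eq",
    "asn", 1L, "amide", "typeII", "charge_solvated", "C7eq", "iC7ax",
    "phe", 1L, "aromatic_like", "typeI", "salt_bridge", "C5", "iC7ax"
  )
}

# Build-parameter constants for the free-backbone class templates.
FREE_CLASS_PARAMS <- list(
  typeII = list(
    opt = list(t_coo = 180, t_oh = 0, t_hn = 60, form = "neutral"),
    strained = list(t_coo = 160, t_oh = 0, t_hn = 60, form = "neutral"),
    tvar = c(-15, 15)
  ),
  typeI = list(
    opt = list(t_coo = 0, t_oh = 180, t_hn = 0, form = "neutral"),
    strained = list(t_coo = 25, t_oh = 180, t_hn = 15, form = "neutral"),
    tvar = c(-20, 20)
  ),
  zwitterionic = list(
    opt = list(t_coo = 0, t_oh = NA, t_hn = 0, form = "zwitterion"),
    strained = list(t_coo = 60, t_oh = NA, t_hn = 150, form = "zwitterion"),
    tvar = c(-60, 60)
  ),
  other = list(
    candidates = list(
      list(t_coo = 90, t_oh = 180, t_hn = 150, form = "neutral"),
      list(t_coo = -45, t_oh = 180, t_hn = 150, form = "neutral"),
      list(t_coo = 30, t_oh = 180, t_hn = 150, form = "neutral"),
      list(t_coo = -85, t_oh = 180, t_hn = 150, form = "neutral"),
      list(t_coo = 60, t_oh = 180, t_hn = 150, form = "neutral")
    )
  )
)

# Capped-backbone class templates: phi, psi, CB improper.
CAPPED_CLASS_PARAMS <- list(
  C5 = list(opt = c(-158, 162, 122), var = list(c(-150, 148, 122), c(-166, 174, 122))),
  C7eq = list(opt = c(-83, 66, 150), strained = c(-79, 76, 150)),
  C7ax = list(opt = c(83, -66, -60), strained = c(79, -76, -60)),
  iC7ax = list(opt = c(60, 40, -90)),
  iC7eq = list(opt = c(-60, -40, -150)),
  other = list(candidates = list(
    c(-60, 140, 122), c(60, -140, 122), c(-100, 150, 122),
    c(100, -150, 122), c(-130, 100, 122)
  ))
)

# Which non-designated free classes appear (strained) in an ensemble: only
# those whose strained form stays clearly above the designated class.
FREE_COMPANIONS <- list(
  typeII = c("typeI", "zwitterionic"),
  zwitterionic = c("typeI"),
  typeI = c("zwitterionic")
)

# one set of torsion/distance jitters; shared across ions for complexes
draw_jitter <- function(jitter_deg, jitter_dist, n_chi) {
  list(
    bb1 = stats::runif(1, -jitter_deg, jitter_deg),
    bb2 = stats::runif(1, -jitter_deg, jitter_deg),
    cb = stats::runif(1, -jitter_deg, jitter_deg),
    chi = if (n_chi > 0) stats::runif(n_chi, -jitter_deg, jitter_deg) else numeric(0),
    d = stats::runif(1, -jitter_dist, jitter_dist)
  )
}

CHI_BIN_CENTRES <- c(180, 60, -60)

# deterministic per-ligand side-chain placement for complexes: the chi
# tuple (over the first two torsions) that keeps the side-chain tip
# farthest from the cation, so the binding site stays a pure backbone motif
select_ion_chis <- function(tpl, build_opt, params) {
  if (tpl$n_chi == 0) {
    return(NULL)
  }
  cand1 <- CHI_BIN_CENTRES
  cand2 <- if (tpl$n_chi >= 2) CHI_BIN_CENTRES else NA
  scored <- list()
  for (c1 in cand1) {
    for (c2 in cand2) {
      ch <- rep(180, tpl$n_chi)
      ch[1] <- c1
      if (!is.na(c2)) ch[2] <- c2
      cf <- tryCatch(build_opt(ch), error = function(e) NULL)
      if (is.null(cf)) next
      ion <- cf$meta$ion_index
      xyz <- coords(cf)
      side <- setdiff(
        seq_len(nrow(xyz)),
        c(unlist(cf$meta$topology[c(
          "N", "CA", "C", "O_carbonyl", "O_hydroxyl",
          "C_prev", "O_prev", "O", "N_next"
        )]), ion)
      )
      side <- side[cf$atoms$element[side] != "H"]
      if (length(side) == 0) next
      scored[[length(scored) + 1L]] <- list(
        ch = ch,
        d = min(sqrt(colSums((t(xyz[side, , drop = FALSE]) - xyz[ion, ])^2))),
        e = toy_energy(cf, params)
      )
    }
  }
  if (length(scored) == 0) {
    return(rep(180, tpl$n_chi))
  }
  # rule out strained (clashing) placements, then push the side chain as far
  # from the cation as possible
  es <- vapply(scored, `[[`, double(1), "e")
  ok <- which(es <= min(es) + 2)
  ds <- vapply(scored[ok], `[[`, double(1), "d")
  scored[[ok[which.max(ds)]]]$ch
}

# deterministic per-ligand side-chain placement: the chi tuple (over the
# first two torsions) that minimises the designated-class template energy
select_base_chis <- function(tpl, build_opt, params) {
  if (tpl$n_chi == 0) {
    return(NULL)
  }
  cand1 <- CHI_BIN_CENTRES
  cand2 <- if (tpl$n_chi >= 2) CHI_BIN_CENTRES else NA
  best <- NULL
  best_e <- Inf
  for (c1 in cand1) {
    for (c2 in cand2) {
      ch <- rep(180, tpl$n_chi)
      ch[1] <- c1
      if (!is.na(c2)) ch[2] <- c2
      e <- tryCatch(
        toy_energy(build_opt(ch), params),
        error = function(e) Inf
      )
      if (e < best_e) {
        best_e <- e
        best <- ch
      }
    }
  }
  best %||% rep(180, tpl$n_chi)
}

# chi variants: rotate chi1 into the two bins the base does not occupy
chi_variants <- function(base_chis) {
  if (is.null(base_chis)) {
    return(list())
  }
  vals <- setdiff(CHI_BIN_CENTRES, base_chis[1])
  lapply(vals, function(v) {
    ch <- base_chis
    ch[1] <- v
    ch
  })
}

# recipes: each row one conformer to build; `chis` NULL means base
free_bare_recipes <- function(gm_class, base_chis, others, has_cb = TRUE) {
  p <- FREE_CLASS_PARAMS
  rec <- list()
  add <- function(truth, pars, chis = NULL, t_cb = NULL) {
    rec[[length(rec) + 1L]] <<- list(truth = truth, pars = pars, chis = chis, t_cb = t_cb)
  }
  add(gm_class, p[[gm_class]]$opt)
  if (has_cb) add(gm_class, p[[gm_class]]$opt, t_cb = -122)
  for (tv in p[[gm_class]]$tvar) {
    pv <- p[[gm_class]]$opt
    pv$t_coo <- wrap_angle(pv$t_coo + tv)
    add(gm_class, pv)
  }
  for (oc in FREE_COMPANIONS[[gm_class]]) {
    add(oc, p[[oc]]$strained)
  }
  for (pars in others) add("other", pars)
  for (ch in chi_variants(base_chis)) add(gm_class, p[[gm_class]]$opt, chis = ch)
  rec
}

free_ion_recipes <- function(gm_class, base_chis, include_cs = TRUE) {
  p <- FREE_CLASS_PARAMS
  rec <- list()
  add <- function(truth, pars, site, doff = 0, far = FALSE, chis = NULL) {
    rec[[length(rec) + 1L]] <<- list(
      truth = truth, pars = pars, site = site, doff = doff, far = far, chis = chis
    )
  }
  cs_pars <- list(t_coo = 0, t_oh = 180, t_hn = 150, form = "neutral")
  if (gm_class == "salt_bridge") {
    add("salt_bridge", p$zwitterionic$opt, "carboxylate")
    add("salt_bridge", p$zwitterionic$opt, "carboxylate", doff = 0.30)
    if (include_cs) add("charge_solvated", cs_pars, "amine_carbonyl", doff = 0.25)
    add("other", p$zwitterionic$opt, "amine_carbonyl", far = TRUE)
    ch <- chi_variants(base_chis)
    if (length(ch) > 0) add("salt_bridge", p$zwitterionic$opt, "carboxylate", chis = ch[[1]])
  } else {
    add("charge_solvated", cs_pars, "amine_carbonyl")
    add("charge_solvated", cs_pars, "amine_carbonyl", doff = 0.30)
    add("other", cs_pars, "amine_carbonyl", far = TRUE)
    ch <- chi_variants(base_chis)
    if (length(ch) > 0) add("charge_solvated", cs_pars, "amine_carbonyl", chis = ch[[1]])
  }
  rec
}

capped_bare_recipes <- function(gm_class, base_chis, others) {
  p <- CAPPED_CLASS_PARAMS
  rec <- list()
  add <- function(truth, tors, chis = NULL) {
    rec[[length(rec) + 1L]] <<- list(truth = truth, tors = tors, chis = chis)
  }
  add(gm_class, p[[gm_class]]$opt)
  if (gm_class == "C5") {
    for (v in p$C5$var) add("C5", v)
  } else {
    s <- p[[gm_class]]$strained
    add(gm_class, (p[[gm_class]]$opt + s) / 2)
    # the weakly bound extended form is present but never competitive
    add("C5", p$C5$var[[1]])
  }
  for (t in others) add("other", t)
  for (ch in chi_variants(base_chis)) add(gm_class, p[[gm_class]]$opt, chis = ch)
  rec
}

capped_ion_recipes <- function(gm_class, base_chis) {
  p <- CAPPED_CLASS_PARAMS
  rec <- list()
  add <- function(truth, tors, doff = 0, far = FALSE, chis = NULL) {
    rec[[length(rec) + 1L]] <<- list(
      truth = truth, tors = tors, doff = doff, far = far, chis = chis
    )
  }
  base <- if (gm_class == "other") "iC7ax" else gm_class
  truth0 <- gm_class
  add(truth0, p[[base]]$opt)
  add(truth0, p[[base]]$opt, doff = 0.30)
  add("other", p$other$candidates[[1]], far = TRUE)
  ch <- chi_variants(base_chis)
  if (length(ch) > 0) add(truth0, p[[base]]$opt, chis = ch[[1]])
  rec
}

jittered_chis <- function(ch, jit) {
  if (is.null(ch)) {
    return(NULL)
  }
  wrap_angle(ch + jit$chi[seq_along(ch)])
}

realize_free <- function(tpl, recipe, jit, base_chis) {
  ch <- recipe$chis %||% base_chis
  p <- recipe$pars
  build_peptide(tpl,
    t_coo = wrap_angle(p$t_coo + jit$bb1),
    chis = jittered_chis(ch, jit),
    backbone_form = p$form,
    t_oh = if (is.na(p$t_oh)) 180 else p$t_oh,
    t_hn = p$t_hn, t_cb = wrap_angle((recipe$t_cb %||% 122) + jit$cb)
  )
}

realize_capped <- function(tpl, recipe, jit, base_chis) {
  ch <- recipe$chis %||% base_chis
  t <- recipe$tors
  build_peptide(tpl,
    phi = wrap_angle(t[1] + jit$bb1),
    psi = wrap_angle(t[2] + jit$bb2),
    chis = jittered_chis(ch, jit),
    t_cb = wrap_angle(t[3] + jit$cb)
  )
}

attach_ion <- function(cf, ion, site, doff, far, jit, params) {
  pion <- params$ions[[ion]]
  if (far) {
    return(place_ion(cf, site, ion, 6.0))
  }
  if (isTRUE(pion$hg_like) && site %in% c("carbonyl_bridge", "carboxylate")) {
    place_ion(cf, site, ion,
      distance = pion$short_contact + doff + jit$d,
      distance2 = (pion$long_contact %||% pion$contact) + doff + jit$d
    )
  } else if (isTRUE(pion$hg_like) && site == "amine_carbonyl") {
    # nitrogen kept at the ionic contact, the oxygen pulled in short
    place_ion(cf, site, ion,
      distance = pion$contact + doff + jit$d,
      distance2 = pion$short_contact + doff + jit$d
    )
  } else {
    place_ion(cf, site, ion, pion$contact + doff + jit$d)
  }
}

# Choose filler "other" conformers for one system: candidates are kept only
# if they classify "other" and sit comfortably above the designated-class
# optimum (margin in eV); the two highest-margin survivors are used.
select_other_templates <- function(build_fn, classify_fn, energy_fn,
                                   e_designated, candidates,
                                   margin = 0.25, n_keep = 2) {
  scored <- list()
  for (cand in candidates) {
    cf <- tryCatch(build_fn(cand), error = function(e) NULL)
    if (is.null(cf)) next
    if (classify_fn(cf) != "other") next
    e <- energy_fn(cf)
    scored[[length(scored) + 1L]] <- list(pars = cand, e = e)
  }
  if (length(scored) == 0) {
    return(list())
  }
  es <- vapply(scored, `[[`, double(1), "e")
  ok <- which(es >= e_designated + margin)
  pick <- if (length(ok) >= n_keep) {
    ok[seq_len(n_keep)] # candidate order encodes geometric spacing
  } else {
    order(-es)[seq_len(min(n_keep, length(es)))]
  }
  lapply(scored[pick], `[[`, "pars")
}

#' Generate the labeled benchmark ensembles in memory
#'
#' Emits, for every panel ligand, backbone type and complexation state, an
#' ensemble of conformers built from class templates with small seeded
#' torsion jitter. Complexed conformers reuse the bare ligand geometry draws
#' across all six ions (the ion is substituted and re-placed at its own
#' preferred distance), which makes the Ca-like and Pb-like series exactly
#' identical by construction.
#'
#' @param seed Integer RNG seed; the suite is deterministic given the seed.
#' @param panel Ligand panel, see [suite_panel()].
#' @param params Toy energy parameters.
#' @param jitter_deg Torsion jitter half-width, degrees.
#' @param jitter_dist Ion-placement distance jitter half-width, Angstrom.
#' @return A list: `ensembles` (ensemble tibble with ground-truth `label`,
#'   ligand/backbone/complexation columns) and `index` (per-system tibble
#'   with the intended global-minimum class and conformer count).
#' @export
generate_labeled_ensembles <- function(seed, panel = suite_panel(),
                                       params = toy_energy_params(),
                                       jitter_deg = 4, jitter_dist = 0.02) {
  with_pepc_seed(seed, {
    all_rows <- list()
    idx_rows <- list()
    for (li in seq_len(nrow(panel))) {
      lig <- panel[li, ]
      for (backbone in c("free", "capped")) {
        tpl <- residue_template(lig$ligand, backbone, lig$n_chain, lig$terminal)
        gm_bare <- if (backbone == "free") lig$free_gm else lig$capped_gm
        gm_ion <- if (backbone == "free") lig$free_ion_gm else lig$capped_ion_gm
        # deterministic side-chain base placement for this ligand/backbone
        base_chis <- select_base_chis(tpl, function(ch) {
          if (backbone == "free") {
            pars <- FREE_CLASS_PARAMS[[gm_bare]]$opt
            build_peptide(tpl,
              t_coo = pars$t_coo, chis = ch, backbone_form = pars$form,
              t_oh = if (is.na(pars$t_oh)) 180 else pars$t_oh, t_hn = pars$t_hn
            )
          } else {
            t <- CAPPED_CLASS_PARAMS[[if (gm_bare == "other") "C5" else gm_bare]]$opt
            build_peptide(tpl, phi = t[1], psi = t[2], chis = ch, t_cb = t[3])
          }
        }, params)
        # --- bare ensemble; filler "other" templates are screened against
        # the designated optimum so they never compete for the minimum
        build_bare <- function(pars) {
          if (backbone == "free") {
            build_peptide(tpl,
              t_coo = pars$t_coo, chis = base_chis, backbone_form = pars$form,
              t_oh = if (is.na(pars$t_oh)) 180 else pars$t_oh, t_hn = pars$t_hn
            )
          } else {
            build_peptide(tpl,
              phi = pars[1], psi = pars[2], chis = base_chis, t_cb = pars[3]
            )
          }
        }
        classify_bare <- function(cf) {
          if (backbone == "free") {
            classify_free_amino_acid(cf, cf$meta$topology)$label
          } else {
            classify_dipeptide(cf, cf$meta$topology)$label
          }
        }
        e_opt <- toy_energy(build_bare(
          if (backbone == "free") {
            FREE_CLASS_PARAMS[[gm_bare]]$opt
          } else {
            CAPPED_CLASS_PARAMS[[gm_bare]]$opt
          }
        ), params)
        others <- select_other_templates(
          build_bare, classify_bare, function(cf) toy_energy(cf, params),
          e_opt,
          if (backbone == "free") {
            FREE_CLASS_PARAMS$other$candidates
          } else {
            CAPPED_CLASS_PARAMS$other$candidates
          }
        )
        recipes <- if (backbone == "free") {
          free_bare_recipes(gm_bare, base_chis, others, has_cb = tpl$n_chain > 0)
        } else {
          capped_bare_recipes(gm_bare, base_chis, others)
        }
        sys <- paste0(lig$ligand, "_", backbone, "_none")
        confs <- list()
        labs <- character()
        for (r in recipes) {
          jit <- draw_jitter(jitter_deg, jitter_dist, tpl$n_chi)
          cf <- if (backbone == "free") {
            realize_free(tpl, r, jit, base_chis)
          } else {
            realize_capped(tpl, r, jit, base_chis)
          }
          cf$meta$descriptor <- list(
            ligand = lig$ligand, backbone = backbone, complexation = "none"
          )
          cf$meta$system <- sys
          cf$energy <- toy_energy(cf, params)
          confs[[length(confs) + 1L]] <- cf
          labs <- c(labs, r$truth)
        }
        all_rows[[length(all_rows) + 1L]] <- dplyr::mutate(
          ensemble_tbl(confs, sys, labs),
          ligand = lig$ligand, backbone = backbone, complexation = "none"
        )
        idx_rows[[length(idx_rows) + 1L]] <- tibble(
          system = sys, ligand = lig$ligand, backbone = backbone,
          complexation = "none", intended_gm = gm_bare, n_conformers = length(confs)
        )
        # --- ion ensembles: shared ligand-geometry draws across ions;
        # the side-chain base placement is re-selected with a reference ion
        # present so that charged tips rotate away from the binding site
        base_chis_ion <- select_ion_chis(tpl, function(ch) {
          if (backbone == "free") {
            pars <- if (gm_ion == "charge_solvated") {
              list(t_coo = 0, t_oh = 180, t_hn = 150, form = "neutral")
            } else {
              FREE_CLASS_PARAMS$zwitterionic$opt
            }
            cf <- build_peptide(tpl,
              t_coo = pars$t_coo, chis = ch, backbone_form = pars$form,
              t_oh = if (is.na(pars$t_oh)) 180 else pars$t_oh, t_hn = pars$t_hn
            )
            site <- if (gm_ion == "charge_solvated") "amine_carbonyl" else "carboxylate"
            place_ion(cf, site, "Ca", params$ions$Ca$contact)
          } else {
            t <- CAPPED_CLASS_PARAMS[[if (gm_ion == "other") "iC7ax" else gm_ion]]$opt
            cf <- build_peptide(tpl, phi = t[1], psi = t[2], chis = ch, t_cb = t[3])
            place_ion(cf, "carbonyl_bridge", "Ca", params$ions$Ca$contact)
          }
        }, params)
        ion_recipes <- if (backbone == "free") {
          free_ion_recipes(gm_ion, base_chis_ion, include_cs = tpl$n_chain > 0)
        } else {
          capped_ion_recipes(gm_ion, base_chis_ion)
        }
        jits <- lapply(ion_recipes, function(r) {
          draw_jitter(jitter_deg, jitter_dist, tpl$n_chi)
        })
        for (ion in PEPC_IONS) {
          sysi <- paste0(lig$ligand, "_", backbone, "_", ion)
          confs <- list()
          labs <- character()
          for (k in seq_along(ion_recipes)) {
            r <- ion_recipes[[k]]
            cf <- if (backbone == "free") {
              realize_free(tpl, r, jits[[k]], base_chis_ion)
            } else {
              realize_capped(tpl, r, jits[[k]], base_chis_ion)
            }
            site <- if (backbone == "free") r$site else "carbonyl_bridge"
            cf <- attach_ion(cf, ion, site, r$doff, r$far, jits[[k]], params)
            cf$meta$descriptor <- list(
              ligand = lig$ligand, backbone = backbone, complexation = ion
            )
            cf$meta$system <- sysi
            cf$energy <- toy_energy(cf, params)
            confs[[length(confs) + 1L]] <- cf
            labs <- c(labs, r$truth)
          }
          all_rows[[length(all_rows) + 1L]] <- dplyr::mutate(
            ensemble_tbl(confs, sysi, labs),
            ligand = lig$ligand, backbone = backbone, complexation = ion
          )
          idx_rows[[length(idx_rows) + 1L]] <- tibble(
            system = sysi, ligand = lig$ligand, backbone = backbone,
            complexation = ion, intended_gm = gm_ion, n_conformers = length(confs)
          )
        }
      }
    }
    list(
      ensembles = dplyr::bind_rows(all_rows),
      index = dplyr::bind_rows(idx_rows)
    )
  })
}

#' Write the benchmark suite to disk
#'
#' One directory per system: `ensemble.extxyz` (geometries, energies and
#' ground-truth labels), `labels.json` (labels, intended global-minimum
#' class, topology map, descriptor) and `manifest.yaml` (descriptor + seed).
#' Output is byte-identical for a fixed seed.
#'
#' @inheritParams generate_labeled_ensembles
#' @param out_dir Output directory (created if needed).
#' @return The suite index tibble, invisibly.
#' @export
generate_benchmark_suite <- function(seed, out_dir, panel = suite_panel(),
                                     params = toy_energy_params()) {
  suite <- generate_labeled_ensembles(seed, panel = panel, params = params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (sys in unique(suite$ensembles$system)) {
    sub <- suite$ensembles[suite$ensembles$system == sys, ]
    d <- file.path(out_dir, sys)
    dir.create(d, showWarnings = FALSE)
    write_extxyz(sub, file.path(d, "ensemble.extxyz"))
    cf1 <- sub$conformer[[1]]
    info <- suite$index[suite$index$system == sys, ]
    jsonlite::write_json(
      list(
        system = sys,
        labels = sub$label,
        intended_gm = info$intended_gm,
        descriptor = cf1$meta$descriptor,
        topology = cf1$meta$topology,
        ion_index = cf1$meta$ion_index %||% NA,
        seed = seed
      ),
      file.path(d, "labels.json"),
      auto_unbox = TRUE, null = "null", na = "null", digits = NA
    )
    yaml::write_yaml(
      list(
        system = sys, ligand = info$ligand, backbone = info$backbone,
        complexation = info$complexation, seed = seed,
        n_conformers = info$n_conformers
      ),
      file.path(d, "manifest.yaml")
    )
  }
  jsonlite::write_json(suite$index, file.path(out_dir, "index.json"),
    dataframe = "rows", digits = NA
  )
  invisible(suite$index)
}

#' Read a benchmark suite from disk
#'
#' Restores the ensembles written by [generate_benchmark_suite()], including
#' topology and descriptor metadata, into the ensemble-tibble form the
#' classification and energetics functions consume.
#'
#' @param dir Suite directory.
#' @return A list: `ensembles`, `index`, as in
#'   [generate_labeled_ensembles()].
#' @export
read_benchmark_suite <- function(dir) {
  if (!dir.exists(dir)) {
    abort(paste0("no such suite directory: ", dir), class = "pepc_error_io")
  }
  sysdirs <- list.dirs(dir, recursive = FALSE)
  rows <- list()
  idx <- list()
  for (d in sysdirs) {
    lab <- jsonlite::read_json(file.path(d, "labels.json"), simplifyVector = TRUE)
    ens <- read_extxyz(file.path(d, "ensemble.extxyz"))
    topo <- lab$topology
    topo$chi <- if (is.matrix(topo$chi)) {
      lapply(seq_len(nrow(topo$chi)), function(r) as.integer(topo$chi[r, ]))
    } else {
      lapply(topo$chi, as.integer)
    }
    for (nm in c("N", "CA", "C", "O_carbonyl", "O_hydroxyl", "C_prev", "O_prev", "O", "N_next", "CB")) {
      if (!is.null(topo[[nm]])) topo[[nm]] <- as.integer(topo[[nm]])
    }
    topo$side_donors <- as.integer(topo$side_donors)
    ens$conformer <- lapply(ens$conformer, function(cf) {
      cf$meta$topology <- topo
      cf$meta$descriptor <- as.list(lab$descriptor)
      ii <- lab$ion_index
      if (!is.null(ii) && length(ii) == 1 && !is.na(ii)) {
        cf$meta$ion_index <- as.integer(ii)
      }
      cf
    })
    ens$label <- lab$labels
    ens$ligand <- lab$descriptor$ligand
    ens$backbone <- lab$descriptor$backbone
    ens$complexation <- lab$descriptor$complexation
    rows[[length(rows) + 1L]] <- ens
    idx[[length(idx) + 1L]] <- tibble(
      system = lab$system, ligand = lab$descriptor$ligand,
      backbone = lab$descriptor$backbone,
      complexation = lab$descriptor$complexation,
      intended_gm = lab$intended_gm, n_conformers = nrow(ens)
    )
  }
  list(ensembles = dplyr::bind_rows(rows), index = dplyr::bind_rows(idx))
}
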