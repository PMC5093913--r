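# Energy hierarchies, binding energies and cross-ion trend statistics.

#' Build a deduplicated, energy-sorted conformational hierarchy
#'
#' Conformers are sorted by total energy; any conformer within
#' `dedup_threshold` heavy-atom RMSD of a lower-energy one is merged into it
#' (the lowest-energy representative is kept). Relative energies are
#' reported in eV and kJ/mol.
#'
#' @param ensemble An ensemble tibble for a single system.
#' @param dedup_threshold Heavy-atom RMSD merge threshold, Angstrom.
#' @return An object of class `pepc_hierarchy`: list with `system`, `entries`
#'   (tibble: `frame`, `energy`, `rel_ev`, `rel_kjmol`, `rank`),
#'   `n_merged`, `dedup_threshold`.
#' @export
build_hierarchy <- function(ensemble, dedup_threshold = 0.3) {
  if (!is.data.frame(ensemble) || nrow(ensemble) == 0) {
    abort("empty ensemble", class = "pepc_error_energetics")
  }
  if (length(unique(ensemble$system)) != 1) {
    abort("`ensemble` must contain a single system", class = "pepc_error_energetics")
  }
  if (any(is.na(ensemble$energy))) {
    abort("all conformers need energies", class = "pepc_error_energetics")
  }
  ord <- order(ensemble$energy)
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (j in kept) {
      r <- kabsch_rmsd(ensemble$conformer[[i]], ensemble$conformer[[j]],
        heavy_only = TRUE
      )
      if (r < dedup_threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, i)
  }
  e <- ensemble$energy[kept]
  entries <- tibble(
    frame = ensemble$frame[kept],
    energy = e,
    rel_ev = e - e[1],
    rel_kjmol = (e - e[1]) * EV_TO_KJMOL,
    rank = seq_along(kept) - 1L
  )
  structure(
    list(
      system = ensemble$system[1],
      entries = entries,
      n_input = nrow(ensemble),
      n_merged = nrow(ensemble) - length(kept),
      dedup_threshold = dedup_threshold
    ),
    class = "pepc_hierarchy"
  )
}

#' @export
print.pepc_hierarchy <- function(x, ...) {
  cat(
    "<pepc_hierarchy> ", x$system, ": ", nrow(x$entries), " conformers (",
    x$n_merged, " merged at ", x$dedup_threshold, " A), span ",
    sprintf("%.3f", max(x$entries$rel_ev)), " eV\n",
    sep = ""
  )
  invisible(x)
}

#' Count conformers within an energy window
#'
#' @param hierarchy A `pepc_hierarchy`.
#' @param window_ev Window above the global minimum, eV (`Inf` counts all).
#' @return Integer count.
#' @export
count_conformers <- function(hierarchy, window_ev = Inf) {
  stopifnot(inherits(hierarchy, "pepc_hierarchy"))
  if (window_ev < 0) abort("window must be >= 0", class = "pepc_error_energetics")
  sum(hierarchy$entries$rel_ev <= window_ev)
}

#' Cation binding energy from constituent minima
#'
#' `E_bind = (E_ligand_min + E_ion) - E_complex_min`; a positive value means
#' the bound complex lies below the separated constituents (favourable
#' binding), so larger is stronger.
#'
#' @param e_complex_min,e_ligand_min,e_ion Total energies, eV (global minima
#'   for complex and ligand; bare-ion reference for the ion). Vectorised.
#' @return Binding energy in eV.
#' @examples
#' binding_energy(-10, -4, -5) # 1 eV
#' @export
binding_energy <- function(e_complex_min, e_ligand_min, e_ion) {
  (e_ligand_min + e_ion) - e_complex_min
}

#' Assemble a ligand x ion binding-energy trend table
#'
#' @param records A tibble with columns `ligand`, `ion`, `e_bind` (eV) and
#'   optionally `gm_class` (class of the complex global minimum).
#' @return An object of class `pepc_trend` wrapping the long table and the
#'   ligand x ion matrix.
#' @export
trend_table <- function(records) {
  needed <- c("ligand", "ion", "e_bind")
  if (!all(needed %in% names(records))) {
    abort("`records` needs columns ligand, ion, e_bind", class = "pepc_error_energetics")
  }
  if (anyDuplicated(records[, c("ligand", "ion")]) > 0) {
    abort("duplicate (ligand, ion) entries", class = "pepc_error_energetics")
  }
  wide <- tidyr::pivot_wider(
    records[, c("ligand", "ion", "e_bind")],
    names_from = "ion", values_from = "e_bind"
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$ligand
  structure(
    list(records = as_tibble(records), matrix = m),
    class = "pepc_trend"
  )
}

#' @export
print.pepc_trend <- function(x, ...) {
  cat(
    "<pepc_trend> ", nrow(x$matrix), " ligands x ", ncol(x$matrix),
    " ions (e_bind, eV)\n",
    sep = ""
  )
  print(round(x$matrix, 3))
  invisible(x)
}

#' Rank ligands by affinity for one ion
#'
#' Descending binding energy, i.e. strongest binder first (the x-axis
#' ordering of the per-ion affinity plots). Ties are broken
#' lexicographically and flagged.
#'
#' @param trend A `pepc_trend`.
#' @param ion Ion column to rank by.
#' @return Tibble: `ligand`, `e_bind`, `rank`, `tied`.
#' @export
affinity_ranking <- function(trend, ion) {
  stopifnot(inherits(trend, "pepc_trend"))
  if (!ion %in% colnames(trend$matrix)) {
    abort(paste0("ion '", ion, "' not in trend table"), class = "pepc_error_energetics")
  }
  v <- trend$matrix[, ion]
  if (any(is.na(v))) {
    abort(
      paste0(
        "missing e_bind for ", ion, ": ",
        paste(rownames(trend$matrix)[is.na(v)], collapse = ", ")
      ),
      class = "pepc_error_energetics"
    )
  }
  ord <- order(-v, names(v))
  tibble(
    ligand = names(v)[ord],
    e_bind = unname(v[ord]),
    rank = seq_along(v),
    tied = duplicated(v[ord]) | duplicated(v[ord], fromLast = TRUE)
  )
}

#' Rank ions by affinity for one ligand
#'
#' @param trend A `pepc_trend`.
#' @param ligand Ligand row to rank.
#' @return Tibble: `ion`, `e_bind`, `rank`, `tied` (strongest first).
#' @export
ion_ordering <- function(trend, ligand) {
  stopifnot(inherits(trend, "pepc_trend"))
  if (!ligand %in% rownames(trend$matrix)) {
    abort(paste0("ligand '", ligand, "' not in trend table"),
      class = "pepc_error_energetics"
    )
  }
  v <- trend$matrix[ligand, ]
  if (any(is.na(v))) {
    abort(
      paste0(
        "missing e_bind for ", ligand, ": ",
        paste(colnames(trend$matrix)[is.na(v)], collapse = ", ")
      ),
      class = "pepc_error_energetics"
    )
  }
  ord <- order(-v, names(v))
  tibble(
    ion = names(v)[ord],
    e_bind = unname(v[ord]),
    rank = seq_along(v),
    tied = duplicated(v[ord]) | duplicated(v[ord], fromLast = TRUE)
  )
}

#' Rank concordance between two binding-energy series
#'
#' Kendall tau-b (tie-corrected) between the two series over a shared ligand
#' set, plus the largest absolute binding-energy deviation — the statistic
#' behind the Ca/Pb mimicry comparison.
#'
#' @param series_a,series_b Named numeric vectors (names = ligands), or two
#'   ion column names together with `trend`.
#' @param trend Optional `pepc_trend` supplying the columns.
#' @return A list: `tau`, `max_abs_diff`, `n`.
#' @export
rank_concordance <- function(series_a, series_b, trend = NULL) {
  if (!is.null(trend)) {
    series_a <- trend$matrix[, series_a]
    series_b <- trend$matrix[, series_b]
  }
  if (is.null(names(series_a)) || is.null(names(series_b))) {
    abort("series must be named by ligand", class = "pepc_error_energetics")
  }
  if (!setequal(names(series_a), names(series_b))) {
    abort("ligand sets differ between the two series", class = "pepc_error_energetics")
  }
  if (length(series_a) < 2) {
    abort("need at least 2 ligands", class = "pepc_error_energetics")
  }
  b <- series_b[names(series_a)]
  tau <- cor(series_a, b, method = "kendall")
  list(
    tau = unname(tau),
    max_abs_diff = max(abs(series_a - b)),
    n = length(series_a)
  )
}

#' Conformer-count contraction upon cation binding
#'
#' Compares per-system conformer counts without and with a bound cation.
#'
#' @param bare_counts,ion_counts Tibbles with columns `system` (or `ligand`)
#'   and `n`, or named lists of `pepc_hierarchy` objects.
#' @return A tibble `system`, `n_bare`, `n_ion`, `ratio`, with aggregate
#'   totals in attribute `"totals"`. Unmatched systems are reported in
#'   attribute `"unmatched"`.
#' @export
contraction_report <- function(bare_counts, ion_counts) {
  as_counts <- function(x) {
    if (is.data.frame(x)) {
      nm <- if ("system" %in% names(x)) "system" else "ligand"
      tibble(system = x[[nm]], n = x$n)
    } else {
      tibble(
        system = vapply(x, `[[`, character(1), "system"),
        n = vapply(x, function(h) nrow(h$entries), integer(1))
      )
    }
  }
  b <- as_counts(bare_counts)
  i <- as_counts(ion_counts)
  common <- intersect(b$system, i$system)
  if (length(common) == 0) {
    abort("no matching systems between bare and ion sets", class = "pepc_error_energetics")
  }
  out <- tibble(
    system = common,
    n_bare = b$n[match(common, b$system)],
    n_ion = i$n[match(common, i$system)]
  )
  out$ratio <- out$n_ion / out$n_bare
  attr(out, "totals") <- tibble(
    n_bare = sum(out$n_bare), n_ion = sum(out$n_ion),
    ratio = sum(out$n_ion) / sum(out$n_bare)
  )
  attr(out, "unmatched") <- list(
    bare_only = setdiff(b$system, common),
    ion_only = setdiff(i$system, common)
  )
  out
}
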