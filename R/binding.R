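# Assembling binding records and trend statistics from classified ensembles.

#' Per-system global minima of an ensemble table
#'
#' @param ensembles An ensemble tibble with (at least) `system` and `energy`;
#'   classification columns are carried through when present.
#' @return One row per system: the lowest-energy conformer.
#' @export
global_minima <- function(ensembles) {
  ensembles |>
    dplyr::group_by(.data$system) |>
    dplyr::slice_min(.data$energy, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Binding records for every (ligand, backbone, ion) system
#'
#' Combines per-system global-minimum energies into binding energies
#' `E_bind = (E_ligand_min + E_ion) - E_complex_min` against the matching
#' bare system. When a `protomer` column is present the bare reference must
#' share the complex's protomer.
#'
#' @param ensembles A classified ensemble tibble with `ligand`, `backbone`,
#'   `complexation` columns (as produced by the suite generator or
#'   [read_benchmark_suite()]).
#' @param e_ion Bare-ion reference energy, eV (0 in the toy model).
#' @return A tibble: `ligand`, `backbone`, `ion`, `e_bind`, `gm_class` (when
#'   classification columns are present).
#' @export
binding_records <- function(ensembles, e_ion = 0) {
  needed <- c("ligand", "backbone", "complexation", "energy")
  if (!all(needed %in% names(ensembles))) {
    abort("ensembles need ligand/backbone/complexation/energy columns",
      class = "pepc_error_energetics"
    )
  }
  has_prot <- "protomer" %in% names(ensembles)
  key_of <- function(d) {
    paste(d$ligand, if (has_prot) d$protomer else "", d$backbone)
  }
  gm <- global_minima(ensembles)
  bare <- gm[gm$complexation == "none", ]
  cx <- gm[gm$complexation != "none", ]
  idx <- match(key_of(cx), key_of(bare))
  if (any(is.na(idx))) {
    abort(
      paste0(
        "no matching bare reference (same ligand/protomer/backbone) for: ",
        paste(unique(cx$system[is.na(idx)]), collapse = ", ")
      ),
      class = "pepc_error_energetics"
    )
  }
  out <- tibble(
    ligand = cx$ligand,
    backbone = cx$backbone,
    ion = cx$complexation,
    e_bind = binding_energy(cx$energy, bare$energy[idx], e_ion)
  )
  if ("class" %in% names(cx)) out$gm_class <- cx$class
  out
}

#' Build the full trend analysis from binding records
#'
#' @param records Output of [binding_records()] (one backbone type, or pass
#'   `backbone` to filter).
#' @param backbone Optional filter (`"free"` or `"capped"`).
#' @return A `pepc_trend` whose ligand ids combine ligand and backbone when
#'   both backbones are present.
#' @export
binding_trend <- function(records, backbone = NULL) {
  if (!is.null(backbone)) {
    records <- records[records$backbone == backbone, ]
  }
  lig <- if (length(unique(records$backbone)) > 1) {
    paste(records$ligand, records$backbone, sep = "/")
  } else {
    records$ligand
  }
  trend_table(tibble(
    ligand = lig, ion = records$ion, e_bind = records$e_bind,
    gm_class = records$gm_class %||% NA_character_
  ))
}

#' Validate externally deposited dataset counts
#'
#' Opt-in check against a locally downloaded copy of the full
#' first-principles conformer database (not shipped with the package): reads
#' the per-system ensembles from `dir` (extended-XYZ files, one per system)
#' and reports total and per-filter conformer counts for comparison with the
#' published figures.
#'
#' @param dir Directory of extended-XYZ ensembles.
#' @return A tibble of per-system conformer counts with a `total` attribute.
#' @export
validate_external_counts <- function(dir) {
  files <- list.files(dir, pattern = "\\.(xyz|extxyz)$", full.names = TRUE)
  if (length(files) == 0) {
    abort(paste0("no extended-XYZ files under ", dir), class = "pepc_error_io")
  }
  rows <- lapply(files, function(f) {
    ens <- read_extxyz(f)
    dplyr::count(ens, .data$system, name = "n")
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "total") <- sum(out$n)
  out
}
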