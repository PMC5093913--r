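#' Create a conformer object
#'
#' A conformer is one molecular geometry with an optional total energy and
#' free-form provenance metadata. The atom table is a tibble so conformers
#' compose naturally with dplyr verbs.
#'
#' @param atoms A data frame with columns `element` (chemical symbol), `x`,
#'   `y`, `z` (Cartesian coordinates, Angstrom). An optional `charge` column
#'   carries toy-model partial charges.
#' @param energy Total energy in eV, or `NA` when unknown.
#' @param meta Named list of provenance fields (source file, frame index,
#'   system id, ...).
#' @return An object of class `pepc_conformer`: a list with elements `atoms`
#'   (tibble), `energy` (double) and `meta` (list).
#' @examples
#' conformer(data.frame(
#'   element = c("O", "H", "H"),
#'   x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0
#' ), energy = -2081.0)
#' @export
conformer <- function(atoms, energy = NA_real_, meta = list()) {
  atoms <- as_tibble(atoms)
  required <- c("element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("`atoms` lacks column(s): ", paste(missing_cols, collapse = ", ")),
      class = "pepc_error_conformer"
    )
  }
  if (nrow(atoms) < 2) {
    abort("a conformer needs at least 2 atoms", class = "pepc_error_conformer")
  }
  bad <- setdiff(unique(atoms$element), PEPC_ELEMENTS)
  if (length(bad) > 0) {
    abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")),
      class = "pepc_error_conformer"
    )
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    abort("atom coordinates must be finite", class = "pepc_error_conformer")
  }
  if (length(energy) != 1) {
    abort("`energy` must be a single value", class = "pepc_error_conformer")
  }
  if (!is.na(energy) && !is.finite(energy)) {
    abort("`energy` must be finite or NA", class = "pepc_error_conformer")
  }
  structure(
    list(atoms = atoms, energy = as.double(energy), meta = meta),
    class = "pepc_conformer"
  )
}

#' @export
print.pepc_conformer <- function(x, ...) {
  cat(
    "<pepc_conformer> ", nrow(x$atoms), " atoms",
    if (is.na(x$energy)) ", energy NA" else sprintf(", energy %.6f eV", x$energy),
    "\n",
    sep = ""
  )
  if (!is.null(x$meta$system)) cat("  system: ", x$meta$system, "\n", sep = "")
  invisible(x)
}

#' Coordinate matrix of a conformer
#'
#' @param conf A `pepc_conformer`.
#' @return An n x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @export
coords <- function(conf) {
  stopifnot(inherits(conf, "pepc_conformer"))
  m <- as.matrix(conf$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Number of atoms in a conformer
#' @param conf A `pepc_conformer`.
#' @return Integer atom count.
#' @export
n_atoms <- function(conf) nrow(conf$atoms)

#' Assemble conformers into an ensemble table
#'
#' The tidy container used throughout the package: one row per conformer with
#' the conformer object held in a list-column. All conformers of one system
#' must share the same element multiset (they are alternative geometries of
#' the same molecule).
#'
#' @param conformers List of `pepc_conformer` objects.
#' @param system Character system id(s), recycled to the number of conformers.
#' @param label Optional ground-truth or assigned class labels.
#' @return A tibble with columns `system`, `frame`, `energy`, `label`,
#'   `conformer` (list-column).
#' @export
ensemble_tbl <- function(conformers, system, label = NA_character_) {
  if (length(conformers) == 0) {
    abort("empty ensemble", class = "pepc_error_ensemble")
  }
  ok <- vapply(conformers, inherits, logical(1), what = "pepc_conformer")
  if (!all(ok)) {
    abort("all elements must be pepc_conformer objects", class = "pepc_error_ensemble")
  }
  tbl <- tibble(
    system = rep_len(as.character(system), length(conformers)),
    frame = seq_along(conformers) - 1L,
    energy = vapply(conformers, function(cf) cf$energy, double(1)),
    label = rep_len(as.character(label), length(conformers)),
    conformer = conformers
  )
  tbl <- tbl |>
    dplyr::group_by(.data$system) |>
    dplyr::mutate(frame = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
  validate_ensemble_tbl(tbl)
  tbl
}

validate_ensemble_tbl <- function(tbl) {
  split_tbl <- split(tbl$conformer, tbl$system)
  for (sys in names(split_tbl)) {
    sigs <- vapply(split_tbl[[sys]], function(cf) {
      paste(sort(cf$atoms$element), collapse = "")
    }, character(1))
    if (length(unique(sigs)) > 1) {
      abort(
        paste0("system '", sys, "': conformers differ in element composition"),
        class = "pepc_error_ensemble"
      )
    }
  }
  invisible(tbl)
}
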