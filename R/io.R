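# Conformer file I/O.
#
# Multi-frame extended XYZ: per frame an atom-count line, a comment line with
# whitespace-separated key=value tokens (at least `energy=` in eV and
# `system=`; `label=` optional), then one `element x y z` line per atom.
# A small single-structure geometry dialect (`atom  x y z  element`) is also
# supported for importing externally relaxed structures.

parse_kv_line <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  kv <- strsplit(toks, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), character(1))
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  as.list(vals)
}

#' Read a multi-frame extended-XYZ conformer file
#'
#' Each frame becomes one conformer; frames are grouped into ensembles by
#' their `system` id. Energies are read from the `energy=` token on the
#' comment line (eV).
#'
#' @param path Path to an extended-XYZ file.
#' @return An ensemble tibble (see [ensemble_tbl()]): columns `system`,
#'   `frame`, `energy`, `label`, `conformer`.
#' @export
read_extxyz <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "pepc_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) {
    abort(paste0("empty file: ", path), class = "pepc_error_parse")
  }
  confs <- list()
  systems <- character()
  labels <- character()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1 ||
      !grepl("^\\s*[0-9]+\\s*$", lines[i])) {
      abort(paste0("line ", i, ": malformed atom count"),
        class = "pepc_error_parse"
      )
    }
    if (i + 1L + nat > length(lines)) {
      abort(paste0("line ", i, ": frame truncated (", nat, " atoms declared)"),
        class = "pepc_error_parse"
      )
    }
    kv <- parse_kv_line(lines[i + 1L])
    if (is.null(kv$energy)) {
      abort(paste0("line ", i + 1L, ": missing energy key"),
        class = "pepc_error_parse"
      )
    }
    energy <- suppressWarnings(as.double(kv$energy))
    if (is.na(energy)) {
      abort(paste0("line ", i + 1L, ": unreadable energy '", kv$energy, "'"),
        class = "pepc_error_parse"
      )
    }
    if (is.null(kv$system)) {
      abort(paste0("line ", i + 1L, ": missing system key"),
        class = "pepc_error_parse"
      )
    }
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    fields <- strsplit(trimws(atom_lines), "\\s+")
    nf <- vapply(fields, length, integer(1))
    if (any(nf < 4)) {
      abort(paste0("line ", i + 1L + which(nf < 4)[1], ": malformed atom line"),
        class = "pepc_error_parse"
      )
    }
    el <- vapply(fields, `[[`, character(1), 1)
    badel <- which(!(el %in% PEPC_ELEMENTS))
    if (length(badel) > 0) {
      abort(
        paste0("line ", i + 1L + badel[1], ": unknown element '", el[badel[1]], "'"),
        class = "pepc_error_parse"
      )
    }
    xyz <- vapply(fields, function(f) as.double(f[2:4]), double(3))
    if (!all(is.finite(xyz))) {
      abort(paste0("line ", i, ": non-numeric coordinate in frame"),
        class = "pepc_error_parse"
      )
    }
    atoms <- tibble(element = el, x = xyz[1, ], y = xyz[2, ], z = xyz[3, ])
    meta <- c(
      list(source = path, source_frame = frame, system = kv$system),
      kv[setdiff(names(kv), c("energy", "system", "label"))]
    )
    confs[[length(confs) + 1L]] <- conformer(atoms, energy = energy, meta = meta)
    systems <- c(systems, kv$system)
    labels <- c(labels, kv$label %||% NA_character_)
    i <- i + 2L + nat
    frame <- frame + 1L
  }
  ord <- order(match(systems, unique(systems)))
  ensemble_tbl(confs[ord], system = systems[ord], label = labels[ord])
}

#' Write ensembles to a multi-frame extended-XYZ file
#'
#' Output is bit-stable for fixed input (fixed numeric formats, no
#' timestamps) and read back losslessly by [read_extxyz()] (coordinates to
#' 1e-6 Angstrom, energies to printed precision).
#'
#' @param ensembles An ensemble tibble (see [ensemble_tbl()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(ensembles, path) {
  if (!is.data.frame(ensembles) || nrow(ensembles) == 0) {
    abort("`ensembles` must be a non-empty ensemble tibble", class = "pepc_error_io")
  }
  validate_ensemble_tbl(ensembles)
  out <- character()
  for (k in seq_len(nrow(ensembles))) {
    cf <- ensembles$conformer[[k]]
    if (is.na(cf$energy)) {
      abort("cannot write a conformer without an energy", class = "pepc_error_io")
    }
    hdr <- sprintf(
      "energy=%.10f system=%s", cf$energy, ensembles$system[k]
    )
    if (!is.na(ensembles$label[k])) {
      hdr <- paste0(hdr, " label=", ensembles$label[k])
    }
    body <- sprintf(
      "%-2s %14.8f %14.8f %14.8f",
      cf$atoms$element, cf$atoms$x, cf$atoms$y, cf$atoms$z
    )
    out <- c(out, as.character(nrow(cf$atoms)), hdr, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Read a single-structure quantum-chemistry geometry file
#'
#' Accepts the plain geometry dialect with lines `atom  x y z  element`
#' (Angstrom) and `#` comments. Periodic inputs (lattice keywords) are
#' rejected. The returned conformer has no energy.
#'
#' @param path Path to the geometry file.
#' @param energy Optional total energy (eV) supplied alongside the geometry.
#' @return A `pepc_conformer` with `energy = NA` unless provided.
#' @export
read_qc_geometry <- function(path, energy = NA_real_) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "pepc_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0("empty geometry file: ", path), class = "pepc_error_parse")
  }
  fields <- strsplit(trimws(lines), "\\s+")
  key <- vapply(fields, `[[`, character(1), 1)
  if (any(key %in% c("lattice_vector", "lattice", "cell"))) {
    abort("periodic input unsupported", class = "pepc_error_parse")
  }
  bad <- which(key != "atom")
  if (length(bad) > 0) {
    abort(paste0("line ", bad[1], ": unknown keyword '", key[bad[1]], "'"),
      class = "pepc_error_parse"
    )
  }
  nf <- vapply(fields, length, integer(1))
  if (any(nf != 5)) {
    abort("atom lines must be `atom  x y z  element`", class = "pepc_error_parse")
  }
  xyz <- vapply(fields, function(f) as.double(f[2:4]), double(3))
  el <- vapply(fields, `[[`, character(1), 5)
  conformer(
    tibble(element = el, x = xyz[1, ], y = xyz[2, ], z = xyz[3, ]),
    energy = energy,
    meta = list(source = path)
  )
}
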