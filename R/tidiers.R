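# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an energy hierarchy
#'
#' @param x A `pepc_hierarchy`.
#' @param ... Unused.
#' @return One row per retained conformer: `system`, `frame`, `energy`,
#'   `rel_ev`, `rel_kjmol`, `rank`.
#' @export
tidy.pepc_hierarchy <- function(x, ...) {
  dplyr::mutate(x$entries, system = x$system, .before = 1)
}

#' @rdname tidy.pepc_hierarchy
#' @export
glance.pepc_hierarchy <- function(x, ...) {
  tibble(
    system = x$system,
    n_conformers = nrow(x$entries),
    n_merged = x$n_merged,
    span_ev = max(x$entries$rel_ev),
    dedup_threshold = x$dedup_threshold
  )
}

#' Tidy a binding-energy trend table
#'
#' @param x A `pepc_trend`.
#' @param ... Unused.
#' @return Long tibble: `ligand`, `ion`, `e_bind` (+ `gm_class` if present).
#' @export
tidy.pepc_trend <- function(x, ...) {
  as_tibble(x$records)
}

#' @rdname tidy.pepc_trend
#' @export
glance.pepc_trend <- function(x, ...) {
  rc <- if (all(c("Ca", "Pb") %in% colnames(x$matrix))) {
    rank_concordance("Ca", "Pb", trend = x)
  } else {
    list(tau = NA_real_, max_abs_diff = NA_real_)
  }
  tibble(
    n_ligands = nrow(x$matrix),
    n_ions = ncol(x$matrix),
    e_bind_min = min(x$matrix, na.rm = TRUE),
    e_bind_max = max(x$matrix, na.rm = TRUE),
    tau_ca_pb = rc$tau,
    max_abs_diff_ca_pb = rc$max_abs_diff
  )
}

#' Tidy a toxicity correlation report
#'
#' @param x A `pepc_toxcor`.
#' @param ... Unused.
#' @return The per-ion table with leave-one-out taus.
#' @export
tidy.pepc_toxcor <- function(x, ...) x$table

#' @rdname tidy.pepc_toxcor
#' @export
glance.pepc_toxcor <- function(x, ...) {
  tibble(tau = x$tau, n = x$n, outlier = x$outlier)
}

#' Tidy a distance histogram
#'
#' @param x A `pepc_disthist`.
#' @param ... Unused.
#' @return One row per bin: `bin_lo`, `bin_hi`, `count`.
#' @export
tidy.pepc_disthist <- function(x, ...) {
  tibble(
    bin_lo = head(x$breaks, -1),
    bin_hi = tail(x$breaks, -1),
    count = x$counts
  )
}

#' @rdname tidy.pepc_disthist
#' @export
glance.pepc_disthist <- function(x, ...) {
  tibble(
    n = length(x$distances),
    median = x$median,
    modes = count_modes(x)
  )
}
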