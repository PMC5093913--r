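# Packaged literature reference values for the six divalent cations
# (Shannon octahedral radii, standard hydration enthalpies, acute oral LD50
# of the chloride salts) and the binding-trend / toxicity correlation.

ion_reference_cache <- new.env(parent = emptyenv())

#' Reference table for the divalent cations
#'
#' Ships the literature values used throughout the analysis: Shannon ionic
#' radius (octahedral, pm), standard hydration enthalpy (kJ/mol) and the
#' chloride-salt median lethal dose (mg/kg, as an interval; a point value
#' has equal low and high). Each row carries its citation string.
#'
#' @param path Optional CSV overriding the packaged table (same columns).
#' @return A tibble with one row per ion.
#' @export
ion_reference_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(ion_reference_cache$tbl)) {
      return(ion_reference_cache$tbl)
    }
    path <- system.file("extdata", "ion_reference.csv", package = "pepcation")
    tbl <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
    ion_reference_cache$tbl <- tbl
    return(tbl)
  }
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Look up one ion's reference record
#'
#' @param ion One of Ca, Ba, Sr, Cd, Pb, Hg.
#' @param table Reference table, defaulting to the packaged one.
#' @return A one-row tibble with `ion`, `shannon_radius_pm`,
#'   `hydration_enthalpy_kJ_mol`, `chloride_ld50_low_mg_kg`,
#'   `chloride_ld50_high_mg_kg`, `citation`.
#' @examples
#' ion_reference("Ca")$shannon_radius_pm # 100
#' @export
ion_reference <- function(ion, table = ion_reference_table()) {
  row <- table[table$ion == ion, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown ion '", ion, "'"), class = "pepc_error_toxicity")
  }
  if (row$shannon_radius_pm <= 0 || row$chloride_ld50_low_mg_kg <= 0 ||
    row$chloride_ld50_low_mg_kg > row$chloride_ld50_high_mg_kg) {
    abort("invalid reference record", class = "pepc_error_toxicity")
  }
  row
}

# Point LD50 used in correlations: geometric mean of the interval.
ld50_point <- function(ref_row) {
  sqrt(ref_row$chloride_ld50_low_mg_kg * ref_row$chloride_ld50_high_mg_kg)
}

#' Correlate binding-energy trends with acute toxicity
#'
#' Kendall tau between per-ion mean binding energies and chloride-salt LD50
#' values (stronger binding is expected to pair with lower LD50, i.e. a
#' negative tau), together with a leave-one-out scan that flags the ion
#' whose removal most increases |tau| — the rank outlier. Interval LD50
#' values enter as their geometric mean. Ties in the leave-one-out gain are
#' broken by the larger per-ion rank discrepancy between the two orderings,
#' then alphabetically.
#'
#' @param binding_means A tibble with columns `ion` and `e_bind` (mean
#'   binding energy per ion, eV), or a named numeric vector.
#' @param ld50_table Reference table (defaults to the packaged one).
#' @param exclusions Ions to drop before correlating.
#' @return Object of class `pepc_toxcor`: list with `tau`, `n`, `table`
#'   (per-ion values), `loo` (leave-one-out taus), `outlier`.
#' @export
toxicity_correlation <- function(binding_means, ld50_table = ion_reference_table(),
                                 exclusions = character()) {
  if (is.data.frame(binding_means)) {
    v <- setNames(binding_means$e_bind, binding_means$ion)
  } else {
    v <- binding_means
  }
  v <- v[setdiff(names(v), exclusions)]
  if (length(v) < 3) {
    abort("need at least 3 ions after exclusions", class = "pepc_error_toxicity")
  }
  ld50 <- vapply(names(v), function(i) ld50_point(ion_reference(i, ld50_table)), double(1))
  tau <- unname(cor(v, ld50, method = "kendall"))
  loo <- vapply(names(v), function(drop) {
    keep <- setdiff(names(v), drop)
    unname(cor(v[keep], ld50[keep], method = "kendall"))
  }, double(1))
  gain <- abs(loo) - abs(tau)
  # rank discrepancy between binding order and inverse-toxicity order
  rb <- rank(v)
  rl <- rank(-ld50)
  disc <- abs(rb - rl)
  ord <- order(-gain, -disc, names(v))
  outlier <- names(v)[ord[1]]
  structure(
    list(
      tau = tau,
      n = length(v),
      table = tibble(
        ion = names(v), e_bind = unname(v), ld50 = unname(ld50),
        loo_tau = unname(loo), loo_gain = unname(gain),
        rank_discrepancy = unname(disc)
      ),
      outlier = outlier
    ),
    class = "pepc_toxcor"
  )
}

#' @export
print.pepc_toxcor <- function(x, ...) {
  cat(
    "<pepc_toxcor> Kendall tau = ", sprintf("%.3f", x$tau), " over ", x$n,
    " ions; leave-one-out outlier: ", x$outlier, "\n",
    sep = ""
  )
  print(x$table)
  invisible(x)
}
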