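# System taxonomy: 20 proteinogenic side chains x 2 backbone types
# (free termini or acetyl/amino-methyl capped) x 7 complexation states
# (bare or one of six divalent cations) = 280 systems at the default
# protomer level.

PEPC_SIDE_CHAINS <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"
)

# Side chains with an alternative protonation state considered alongside the
# default form (Arg/ArgH, Lys/LysH, His/HisH, Asp/AspH, Glu/GluH).
PEPC_PROTOMER_REGISTRY <- c(
  Arg = "protonated", Lys = "protonated", His = "protonated",
  Asp = "protonated", Glu = "protonated"
)

PEPC_BACKBONES <- c("capped", "free")
PEPC_COMPLEXATIONS <- c("none", sort(PEPC_IONS))

#' Enumerate the molecular systems of the study
#'
#' Builds the full cross product of 20 side chains, 2 backbone types and 7
#' complexation states (bare + six divalent cations), 280 systems in all.
#' With `include_protomers = TRUE` one alternative protonation state is added
#' for each registry entry (Arg, Lys, His, Asp, Glu) in every
#' backbone/complexation combination.
#'
#' @param include_protomers Add the registered alternative protomers?
#' @param protomer_registry Named character vector mapping side chain to the
#'   alternative protomer label; defaults to the five standard pairs.
#' @return A tibble with columns `side_chain`, `protomer`, `backbone`,
#'   `complexation` and a composed `system` id, sorted lexicographically.
#' @examples
#' nrow(enumerate_systems()) # 280
#' @export
enumerate_systems <- function(include_protomers = FALSE,
                              protomer_registry = PEPC_PROTOMER_REGISTRY) {
  base <- tidyr::expand_grid(
    side_chain = PEPC_SIDE_CHAINS,
    protomer = "default",
    backbone = PEPC_BACKBONES,
    complexation = PEPC_COMPLEXATIONS
  )
  out <- base
  if (isTRUE(include_protomers)) {
    extra <- tidyr::expand_grid(
      side_chain = names(protomer_registry),
      backbone = PEPC_BACKBONES,
      complexation = PEPC_COMPLEXATIONS
    )
    extra$protomer <- unname(protomer_registry[extra$side_chain])
    out <- dplyr::bind_rows(base, extra[, names(base)])
  }
  out <- dplyr::arrange(
    out, .data$side_chain, .data$protomer, .data$backbone, .data$complexation
  )
  out$system <- system_id(out$side_chain, out$protomer, out$backbone, out$complexation)
  out
}

#' Compose or parse system ids
#'
#' A system id is `<side_chain>[H]_<backbone>_<complexation>`, e.g.
#' `Glu_free_Ca` or `LysH_capped_none` for the protonated Lys protomer.
#'
#' @param side_chain,protomer,backbone,complexation Descriptor fields.
#' @return `system_id()` a character vector of ids; `parse_system_id()` a
#'   tibble of descriptor fields.
#' @export
system_id <- function(side_chain, protomer, backbone, complexation) {
  tag <- ifelse(protomer == "protonated", "H",
    ifelse(protomer == "deprotonated", "m", "")
  )
  paste0(side_chain, tag, "_", backbone, "_", complexation)
}

#' @rdname system_id
#' @param id Character vector of system ids.
#' @export
parse_system_id <- function(id) {
  parts <- strsplit(id, "_", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3
  if (any(bad)) {
    abort(paste0("malformed system id: ", paste(id[bad], collapse = ", ")),
      class = "pepc_error_system"
    )
  }
  sc_raw <- vapply(parts, `[[`, character(1), 1)
  protomer <- rep("default", length(id))
  side_chain <- sc_raw
  protomer[grepl("H$", sc_raw) & !(sc_raw %in% PEPC_SIDE_CHAINS)] <- "protonated"
  protomer[grepl("m$", sc_raw)] <- "deprotonated"
  side_chain[protomer != "default"] <-
    sub("[Hm]$", "", sc_raw[protomer != "default"])
  tibble(
    system = id,
    side_chain = side_chain,
    protomer = protomer,
    backbone = vapply(parts, `[[`, character(1), 2),
    complexation = vapply(parts, `[[`, character(1), 3)
  )
}
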