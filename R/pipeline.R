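# End-to-end orchestration: configuration, the full analysis chain over a
# benchmark suite, and report assembly.

PIPELINE_SCHEMA <- list(
  input_dir = "character", output_dir = "character", seed = "numeric",
  ions = "character",
  hbond = c("max_d_ha", "max_d_da", "min_angle"),
  c5 = c("max_d_ha", "max_d_da", "min_angle"),
  coordination_slack = "numeric",
  dedup_threshold = "numeric",
  histogram = c("bin_width", "range_min", "range_max", "bandwidth"),
  toxicity_exclusions = "character"
)

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected before any computation; every threshold has an
#' explicit value in the validated object, so the run log never contains
#' silent defaults.
#'
#' @param input_dir Benchmark-suite directory ([generate_benchmark_suite()]).
#' @param output_dir Report directory.
#' @param seed RNG seed recorded with the run.
#' @param ... Overrides: `ions`, `hbond` (list), `c5` (list),
#'   `coordination_slack`, `dedup_threshold`, `histogram` (list),
#'   `toxicity_exclusions`.
#' @param config_file Optional YAML file supplying the same fields; explicit
#'   arguments win over the file.
#' @return A validated `pepc_config` list with a `hash` field.
#' @export
pipeline_config <- function(input_dir, output_dir, seed = 1, ...,
                            config_file = NULL) {
  base <- list(
    input_dir = input_dir, output_dir = output_dir, seed = seed,
    ions = PEPC_IONS,
    hbond = hbond_criteria(),
    c5 = c5_criteria(),
    coordination_slack = 0.4,
    dedup_threshold = 0.3,
    histogram = list(bin_width = 0.05, range_min = 1.8, range_max = 3.6, bandwidth = 0.08),
    toxicity_exclusions = character(0)
  )
  from_file <- if (!is.null(config_file)) {
    yaml::read_yaml(config_file)
  } else {
    list()
  }
  overrides <- list(...)
  cfg <- utils::modifyList(utils::modifyList(base, from_file), overrides)
  unknown <- setdiff(names(cfg), names(PIPELINE_SCHEMA))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
      class = "pepc_error_config"
    )
  }
  for (nm in c("hbond", "c5", "histogram")) {
    bad <- setdiff(names(cfg[[nm]]), PIPELINE_SCHEMA[[nm]])
    if (length(bad) > 0) {
      abort(paste0("unknown key(s) in config$", nm, ": ", paste(bad, collapse = ", ")),
        class = "pepc_error_config"
      )
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    abort("config$seed must be a single number", class = "pepc_error_config")
  }
  # fingerprint of the analysis parameters (the report destination does not
  # change what is computed)
  fp <- cfg[sort(setdiff(names(cfg), "output_dir"))]
  cfg$hash <- rlang::hash(fp)
  structure(cfg, class = "pepc_config")
}

write_csv_stable <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) if (is.list(df[[nm]])) df[[nm]] <- NULL
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' read suite -> classify -> hierarchies -> binding -> trends ->
#' coordination -> toxicity. Deterministic for fixed inputs and seed; every
#' report file carries the configuration hash.
#'
#' @param config A `pepc_config` from [pipeline_config()].
#' @return Invisibly, a `pepc_report` list: the classification table,
#'   hierarchy summaries, trend object, histograms, toxicity report and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pepc_config")) {
    abort("config must come from pipeline_config()", class = "pepc_error_config")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
        class = "pepc_error_stage", parent = e
      )
    })
  }
  suite <- stage("read", read_benchmark_suite(config$input_dir))
  cls <- stage("classify", classify_conformers(
    suite$ensembles,
    criteria = do.call(hbond_criteria, config$hbond),
    c5 = do.call(hbond_criteria, config$c5),
    slack = config$coordination_slack
  ))
  hiers <- stage("hierarchy", {
    lapply(split(cls, cls$system), build_hierarchy,
      dedup_threshold = config$dedup_threshold
    )
  })
  hier_tbl <- dplyr::bind_rows(lapply(hiers, function(h) {
    tibble(
      system = h$system, n_conformers = nrow(h$entries),
      n_merged = h$n_merged, span_ev = max(h$entries$rel_ev)
    )
  }))
  records <- stage("bind", binding_records(cls))
  records <- records[records$ion %in% config$ions, ]
  trend <- stage("trends", binding_trend(records))
  taus <- ion_tau_matrix(trend)
  gm_cx <- global_minima(cls[cls$complexation != "none", ])
  hists <- stage("coordination", {
    out <- list()
    for (ion in intersect(config$ions, unique(gm_cx$complexation))) {
      out[[ion]] <- cation_o_histogram(
        gm_cx[gm_cx$complexation == ion, ],
        bin_width = config$histogram$bin_width,
        range = c(config$histogram$range_min, config$histogram$range_max)
      )
    }
    out
  })
  tox <- stage("toxicity", {
    means <- records |>
      dplyr::group_by(.data$ion) |>
      dplyr::summarise(e_bind = mean(.data$e_bind), .groups = "drop")
    toxicity_correlation(means, exclusions = config$toxicity_exclusions)
  })

  # ---- report bundle
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(df, file) {
    p <- file.path(config$output_dir, file)
    write_csv_stable(df, p)
    paths[[length(paths) + 1L]] <<- p
    p
  }
  cls_out <- cls[, c(
    "system", "frame", "energy", "label", "class", "phi", "psi",
    "quadrant", "boundary"
  )]
  emit(cls_out, "classification.csv")
  emit(hier_tbl, "hierarchies.csv")
  emit(records, "binding_records.csv")
  wide <- as.data.frame(trend$matrix)
  wide <- cbind(ligand = rownames(trend$matrix), wide)
  emit(wide, "binding_matrix_eV.csv")
  wide_kj <- wide
  wide_kj[, -1] <- wide_kj[, -1] * EV_TO_KJMOL
  emit(wide_kj, "binding_matrix_kJmol.csv")
  for (ion in names(hists)) {
    h <- hists[[ion]]
    emit(
      tibble(
        bin_lo = head(h$breaks, -1), bin_hi = tail(h$breaks, -1),
        count = h$counts
      ),
      paste0("histogram_", ion, ".csv")
    )
  }
  emit(tox$table, "toxicity.csv")
  trend_json <- list(
    config_hash = config$hash,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("pepcation")),
    affinity_ranking = lapply(
      setNames(colnames(trend$matrix), colnames(trend$matrix)),
      function(i) affinity_ranking(trend, i)$ligand
    ),
    ion_tau = taus,
    histogram_medians = lapply(hists, function(h) h$median),
    histogram_modes = lapply(hists, function(h) {
      count_modes(h, config$histogram$bandwidth)
    }),
    toxicity_tau = tox$tau,
    toxicity_outlier = tox$outlier
  )
  pj <- file.path(config$output_dir, "trends.json")
  jsonlite::write_json(trend_json, pj, auto_unbox = TRUE, digits = NA)
  paths[[length(paths) + 1L]] <- pj
  log <- c(
    paste0("pepcation ", utils::packageVersion("pepcation")),
    paste0("config_hash: ", config$hash),
    paste0("seed: ", config$seed),
    paste0("input_dir: ", config$input_dir),
    yaml::as.yaml(unclass(config)[setdiff(names(config), "hash")])
  )
  writeLines(log, file.path(config$output_dir, "run_log.txt"))
  invisible(structure(
    list(
      classification = cls, hierarchies = hier_tbl, records = records,
      trend = trend, histograms = hists, toxicity = tox,
      config = config, paths = unlist(paths)
    ),
    class = "pepc_report"
  ))
}

# pairwise Kendall tau between ion columns of a trend table
ion_tau_matrix <- function(trend) {
  ions <- colnames(trend$matrix)
  out <- list()
  for (i in seq_along(ions)) {
    for (j in seq_along(ions)) {
      if (i < j) {
        rc <- rank_concordance(ions[i], ions[j], trend = trend)
        out[[paste0(ions[i], "_", ions[j])]] <- list(
          tau = rc$tau, max_abs_diff_ev = rc$max_abs_diff
        )
      }
    }
  }
  out
}

#' Generate a benchmark suite from the command line or scripts
#'
#' Thin wrapper over [generate_benchmark_suite()].
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return The suite index tibble, invisibly.
#' @export
run_synth <- function(seed, out_dir) {
  if (missing(out_dir) || is.null(out_dir)) {
    abort("out_dir is required", class = "pepc_error_config")
  }
  generate_benchmark_suite(seed, out_dir)
}
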