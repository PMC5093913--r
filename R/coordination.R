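# Cation coordination shells and cation-oxygen distance diagnostics.

#' Extract the coordination shell of a cation
#'
#' All N/O/S atoms within `cutoff` of the ion, sorted by distance.
#'
#' @param conf A `pepc_conformer`.
#' @param ion_index Index of the cation atom.
#' @param cutoff Shell cutoff, Angstrom.
#' @return Tibble: `atom`, `element`, `distance`, sorted ascending, with the
#'   cutoff in attribute `"cutoff"`. Empty (with a warning) when nothing is
#'   inside the cutoff.
#' @export
coordination_shell <- function(conf, ion_index, cutoff = 3.0) {
  el <- conf$atoms$element
  if (ion_index < 1 || ion_index > length(el)) {
    abort("ion_index out of range", class = "pepc_error_coordination")
  }
  xyz <- coords(conf)
  lig <- which(el %in% HB_ELEMENTS)
  dd <- vapply(lig, function(j) dist_pair(xyz, ion_index, j), double(1))
  keep <- dd <= cutoff
  out <- tibble(atom = lig[keep], element = el[lig][keep], distance = dd[keep])
  out <- dplyr::arrange(out, .data$distance)
  if (nrow(out) == 0) {
    warn(paste0("empty coordination shell within ", cutoff, " A"))
  }
  attr(out, "cutoff") <- cutoff
  out
}

#' Pooled cation-oxygen distance histogram
#'
#' Pools all cation-O distances up to the histogram range limit over the
#' supplied conformers (typically the per-system global minima) and bins
#' them on a fixed grid.
#'
#' @param conformers A list of `pepc_conformer`s each containing exactly one
#'   cation, or an ensemble tibble.
#' @param bin_width Bin width, Angstrom.
#' @param range Histogram range, Angstrom.
#' @return Object of class `pepc_disthist`: list with `distances`, `breaks`,
#'   `counts`, `median`, `bin_width`.
#' @export
cation_o_histogram <- function(conformers, bin_width = 0.05, range = c(1.8, 3.6)) {
  if (is.data.frame(conformers)) conformers <- conformers$conformer
  if (length(conformers) == 0) {
    abort("empty conformer pool", class = "pepc_error_coordination")
  }
  pool <- unlist(lapply(conformers, function(cf) {
    el <- cf$atoms$element
    ion <- which(is_cation_element(el))
    if (length(ion) != 1) {
      abort("each conformer must contain exactly one cation",
        class = "pepc_error_coordination"
      )
    }
    xyz <- coords(cf)
    o <- which(el == "O")
    dd <- vapply(o, function(j) dist_pair(xyz, ion, j), double(1))
    dd[dd >= range[1] & dd <= range[2]]
  }))
  if (length(pool) == 0) {
    abort("no cation-O distances inside the histogram range",
      class = "pepc_error_coordination"
    )
  }
  breaks <- seq(range[1], range[2], by = bin_width)
  if (max(breaks) < range[2]) breaks <- c(breaks, max(breaks) + bin_width)
  counts <- graphics::hist(pool, breaks = breaks, plot = FALSE)$counts
  structure(
    list(
      distances = sort(pool), breaks = breaks, counts = counts,
      median = median(pool), bin_width = bin_width
    ),
    class = "pepc_disthist"
  )
}

#' @export
print.pepc_disthist <- function(x, ...) {
  cat(
    "<pepc_disthist> ", length(x$distances), " distances, median ",
    sprintf("%.3f", x$median), " A, ", length(x$counts), " bins\n",
    sep = ""
  )
  invisible(x)
}

#' Count modes of a distance distribution
#'
#' Number of local maxima of the Gaussian-kernel smoothed density, after
#' merging maxima that lie within one bandwidth of each other and dropping
#' low-prominence maxima (below a fraction of the tallest peak). Used for
#' the one-peak vs multi-modal contrast between ions.
#'
#' @param hist A `pepc_disthist`, or a numeric vector of distances.
#' @param bandwidth Gaussian kernel bandwidth, Angstrom.
#' @param min_height Minimum height of a countable maximum, as a fraction of
#'   the highest density value.
#' @return Integer mode count (>= 1 for non-empty input).
#' @export
count_modes <- function(hist, bandwidth = 0.08, min_height = 0.15) {
  if (bandwidth <= 0) {
    abort("bandwidth must be positive", class = "pepc_error_coordination")
  }
  xs <- if (inherits(hist, "pepc_disthist")) hist$distances else as.numeric(hist)
  if (length(xs) == 0) {
    abort("empty distance set", class = "pepc_error_coordination")
  }
  if (length(xs) == 1 || max(xs) - min(xs) < 1e-12) {
    return(1L)
  }
  d <- density(xs, bw = bandwidth, n = 2048, cut = 4)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  locmax <- locmax[y[locmax] >= min_height * max(y)]
  if (length(locmax) == 0) {
    return(1L)
  }
  # merge maxima closer than one bandwidth, strongest representative kept
  pos <- d$x[locmax]
  o <- order(pos)
  pos <- pos[o]
  merged <- 1L
  last <- pos[1]
  for (p in pos[-1]) {
    if (p - last >= bandwidth) {
      merged <- merged + 1L
      last <- p
    }
  }
  merged
}

#' Median-shift report between two distance distributions
#'
#' @param hist_a,hist_b `pepc_disthist` objects (e.g. two ions).
#' @param bandwidth Bandwidth used for the mode counts, Angstrom.
#' @param min_height Prominence threshold passed to [count_modes()].
#' @return One-row tibble: medians, their difference (b - a), and both mode
#'   counts.
#' @export
median_shift_report <- function(hist_a, hist_b, bandwidth = 0.08,
                                min_height = 0.15) {
  stopifnot(inherits(hist_a, "pepc_disthist"), inherits(hist_b, "pepc_disthist"))
  tibble(
    median_a = hist_a$median,
    median_b = hist_b$median,
    median_shift = hist_b$median - hist_a$median,
    modes_a = count_modes(hist_a, bandwidth, min_height),
    modes_b = count_modes(hist_b, bandwidth, min_height)
  )
}
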