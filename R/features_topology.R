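# Barcode-derived topological feature counts.

#' Filter barcodes by lifespan and bin deaths
#'
#' Bars with lifespan (`death - birth`) below `lifespan_cutoff` are dropped
#' as noise; infinite bars are counted separately and never binned; the
#' remaining finite deaths are histogrammed into `(lower, upper]` bins over
#' `death_bins`.
#'
#' @param bars a `plaff_barcodes`, or a single `data.frame(birth, death)`.
#' @param lifespan_cutoff minimum lifespan in Angstrom (default 0.1).
#' @param death_bins strictly increasing bin edges in Angstrom.
#' @return For a barcode set: a list per dimension; each entry has
#'   `bin_counts` (length `length(death_bins) - 1`), `n_infinite`,
#'   `n_kept`, `n_removed`.
#' @export
filter_and_bin_barcodes <- function(bars, lifespan_cutoff = 0.1,
                                    death_bins = 0:12) {
  stopifnot(all(diff(death_bins) > 0))
  one <- function(df) {
    life <- df$death - df$birth
    kept <- df[life >= lifespan_cutoff, , drop = FALSE]
    inf <- is.infinite(kept$death)
    finite_deaths <- kept$death[!inf]
    counts <- if (length(finite_deaths)) {
      as.numeric(table(cut(finite_deaths, breaks = death_bins,
                           right = TRUE, include.lowest = FALSE)))
    } else numeric(length(death_bins) - 1L)
    list(bin_counts = counts, n_infinite = sum(inf),
         n_kept = nrow(kept), n_removed = nrow(df) - nrow(kept))
  }
  if (is.data.frame(bars)) return(one(bars))
  stopifnot(inherits(bars, "plaff_barcodes"))
  lapply(bars, one)
}

#' Element-pair topological feature block
#'
#' For every ordered element pair the bipartite modified-distance Rips
#' filtration is built and its persistence barcodes are reduced to counts:
#' per homology dimension, binned finite-death counts plus the number of
#' infinite bars. On a bipartite complex the 1-cycles never die (no
#' triangles can form), so dimension-1 signal lives in the infinite-bar
#' count and in births, while dimension-0 deaths record cross-partner
#' contact scales.
#'
#' @param region a `plaff_interface`.
#' @param element_list elements considered per side.
#' @param dims homology dimensions (default `0:1`).
#' @param lifespan_cutoff,death_bins see [filter_and_bin_barcodes()].
#' @param max_filtration Rips cap in Angstrom.
#' @return Object of class `plaff_topo_block` with named `values` and a
#'   `layout` data.frame.
#' @export
topological_feature_block <- function(region,
                                      element_list = c("C", "N", "O", "S"),
                                      dims = 0:1,
                                      lifespan_cutoff = 0.1,
                                      death_bins = 2:12,
                                      max_filtration = 12.0) {
  stopifnot(inherits(region, "plaff_interface"))
  nb <- length(death_bins) - 1L
  vals <- numeric(0)
  for (ea in element_list) for (eb in element_list) {
    ia <- which(region$atoms_a$element == ea)
    ib <- which(region$atoms_b$element == eb)
    if (length(ia) == 0L || length(ib) == 0L) {
      cell_bars <- NULL
    } else {
      dm <- modified_distance_matrix(region, ia, ib)
      fc <- build_rips_filtration(dm, max_dim = max(dims),
                                  max_filtration = max_filtration)
      cell_bars <- filter_and_bin_barcodes(compute_barcodes(fc),
                                           lifespan_cutoff, death_bins)
    }
    for (p in dims) {
      key <- as.character(p)
      cell <- if (!is.null(cell_bars) && key %in% names(cell_bars)) {
        c(cell_bars[[key]]$bin_counts, cell_bars[[key]]$n_infinite)
      } else numeric(nb + 1L)
      names(cell) <- sprintf("%s.%s|p%d|%s", ea, eb, p,
                             c(sprintf("death_b%g", death_bins[-1L]), "inf"))
      vals <- c(vals, cell)
    }
  }
  structure(list(values = vals, element_list = element_list, dims = dims,
                 death_bins = death_bins, lifespan_cutoff = lifespan_cutoff),
            class = "plaff_topo_block")
}

#' @export
print.plaff_topo_block <- function(x, ...) {
  cat("Topological block: ", length(x$values), " counts over ",
      length(x$element_list)^2, " element pairs\n", sep = "")
  invisible(x)
}
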