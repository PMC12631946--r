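# Persistent Laplacians and binned eigenvalue statistics.

# oriented (real) boundary matrix between explicit simplex index sets;
# rows/cols are indices into fc, orientation from ascending vertex order
.real_boundary <- function(fc, rows, cols) {
  rowpos <- stats::setNames(seq_along(rows),
                            vapply(fc$simplices[rows], .skey, ""))
  m <- matrix(0, length(rows), length(cols))
  for (jj in seq_along(cols)) {
    s <- fc$simplices[[cols[jj]]]
    for (i in seq_along(s)) {
      m[rowpos[[.skey(s[-i])]], jj] <- (-1)^(i - 1L)
    }
  }
  m
}

#' Persistent Laplacian of a filtration pair
#'
#' For the nested pair of sublevel complexes `K = K_x` and `L = K_y`
#' (`x <= y`), builds the `p`-persistent Laplacian on the `p`-simplices of
#' `K`: the down part is the usual `t(B_p) %*% B_p` over `K` (zero for
#' `p = 0`), and the up part acts through the subspace of `(p+1)`-chains of
#' `L` whose boundary stays inside `K`. Two equivalent constructions are
#' provided: the Schur complement of the up-Laplacian of `L` over the
#' `p`-simplices outside `K` (default), and an explicit orthonormal basis of
#' the constrained chain subspace; they agree to numerical precision and are
#' cross-checked in the test suite. At `x = y` and `p = 0` the matrix is the
#' graph Laplacian of the 1-skeleton at `x`.
#'
#' The number of (near-)zero eigenvalues -- the harmonic spectrum -- equals
#' the persistent Betti number of the pair; the positive part of the
#' spectrum carries the geometric signal that plain persistence discards.
#'
#' @param fc a `plaff_filtration`.
#' @param p homology dimension of the operator.
#' @param x,y filtration thresholds with `x <= y` (defaults to the diagonal
#'   pair `y = x`).
#' @param method `"schur"` or `"nullspace"`.
#' @return Object of class `plaff_plap`: `matrix`, `up`, `down`,
#'   `p`, `x`, `y`, `simplices` (indices of the `p`-simplices of `K_x`).
#' @export
persistent_laplacian <- function(fc, p, x, y = x,
                                 method = c("schur", "nullspace")) {
  method <- match.arg(method)
  stopifnot(inherits(fc, "plaff_filtration"))
  if (x > y) stop("x must be <= y")
  sx_p <- sublevel_indices(fc, x, p)
  npx <- length(sx_p)
  if (npx == 0L) {
    return(structure(list(matrix = matrix(0, 0, 0), up = matrix(0, 0, 0),
                          down = matrix(0, 0, 0), p = p, x = x, y = y,
                          simplices = integer()), class = "plaff_plap"))
  }

  # down part over K_x
  if (p == 0L) {
    down <- matrix(0, npx, npx)
  } else {
    sx_pm1 <- sublevel_indices(fc, x, p - 1L)
    bp <- .real_boundary(fc, sx_pm1, sx_p)
    down <- crossprod(bp)  # t(B) %*% B
  }

  # up part through C_{p+1}^{L,K}
  sy_p <- sublevel_indices(fc, y, p)
  sy_p1 <- sublevel_indices(fc, y, p + 1L)
  if (length(sy_p1) == 0L) {
    up <- matrix(0, npx, npx)
  } else {
    b <- .real_boundary(fc, sy_p, sy_p1)
    in_k <- sy_p %in% sx_p
    bi <- b[in_k, , drop = FALSE]
    bj <- b[!in_k, , drop = FALSE]
    if (nrow(bj) == 0L) {
      up <- tcrossprod(bi)
    } else if (method == "schur") {
      l <- tcrossprod(b)  # up-Laplacian of L over all p-simplices of L
      lii <- l[in_k, in_k, drop = FALSE]
      lij <- l[in_k, !in_k, drop = FALSE]
      ljj <- l[!in_k, !in_k, drop = FALSE]
      up <- lii - lij %*% MASS::ginv(ljj) %*% t(lij)
    } else {
      # explicit orthonormal basis of {c : boundary of c has no component
      # outside K}
      sv <- svd(bj, nu = 0, nv = ncol(bj))
      dvals <- c(sv$d, rep(0, ncol(bj) - length(sv$d)))
      tol <- max(dim(bj)) * max(dvals, 0) * .Machine$double.eps * 100
      z <- sv$v[, dvals <= tol, drop = FALSE]
      d <- bi %*% z
      up <- tcrossprod(d)
    }
  }

  # reorder up to K_x simplex order (rows of bi follow sy_p order restricted
  # to K_x, which equals sx_p order since both are filtration-sorted)
  m <- up + down
  asym <- max(abs(m - t(m)), 0)
  if (asym > 1e-9) stop("internal: persistent Laplacian asymmetric by ", asym)
  m <- (m + t(m)) / 2
  structure(list(matrix = m, up = (up + t(up)) / 2, down = down,
                 p = p, x = x, y = y, simplices = sx_p),
            class = "plaff_plap")
}

#' @export
print.plaff_plap <- function(x, ...) {
  cat("Persistent Laplacian p=", x$p, " pair (", x$x, ", ", x$y, "): ",
      nrow(x$matrix), "x", ncol(x$matrix), "\n", sep = "")
  invisible(x)
}

#' Eigen-spectrum of a persistent Laplacian
#'
#' Full symmetric eigendecomposition; eigenvalues within `-zero_tol` of zero
#' are clipped to 0 and those below `zero_tol` counted as harmonic. The
#' default tolerance scales with the largest eigenvalue,
#' `1e-8 * max(1, lambda_max)`.
#'
#' @param pl a `plaff_plap` or a symmetric numeric matrix.
#' @param zero_tol threshold separating harmonic (zero) from significant
#'   eigenvalues; `NULL` for the scaled default.
#' @return Object of class `plaff_spectrum`: `eigenvalues` (ascending),
#'   `zero_tol`, `harmonic_multiplicity`.
#' @export
spectrum <- function(pl, zero_tol = NULL) {
  m <- if (inherits(pl, "plaff_plap")) pl$matrix else as.matrix(pl)
  if (length(m) && max(abs(m - t(m))) > 1e-9) {
    stop("matrix asymmetry exceeds 1e-9")
  }
  ev <- if (nrow(m) == 0L) numeric() else
    sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (is.null(zero_tol)) zero_tol <- 1e-8 * max(1, if (length(ev)) max(ev) else 0)
  ev[ev < 0 & ev > -zero_tol] <- 0
  ev[ev < 0] <- 0  # PSD by construction; residual negatives are roundoff
  structure(list(eigenvalues = ev, zero_tol = zero_tol,
                 harmonic_multiplicity = sum(ev < zero_tol)),
            class = "plaff_spectrum")
}

#' @export
print.plaff_spectrum <- function(x, ...) {
  cat("Spectrum: ", length(x$eigenvalues), " eigenvalues, harmonic ",
      x$harmonic_multiplicity, "\n", sep = "")
  invisible(x)
}

#' Eight summary statistics of an eigen-spectrum
#'
#' In fixed order: sum, minimum over eigenvalues above the zero tolerance
#' (0 when none), maximum, mean, population standard deviation, population
#' variance, sum of squares, and the count of significant (above-tolerance)
#' eigenvalues. Sum/max/mean/sd/var/sumsq run over *all* eigenvalues
#' including the harmonic zeros; an empty spectrum yields all zeros. Set
#' `min_over_positive = FALSE` for the raw minimum.
#'
#' @param es a `plaff_spectrum`, or a numeric vector of eigenvalues.
#' @param zero_tol used when `es` is a bare numeric vector.
#' @param min_over_positive restrict the "min" slot to significant
#'   eigenvalues (default; the raw minimum is almost always a trivial 0).
#' @return Named numeric vector of length 8.
#' @export
eigen_statistics <- function(es, zero_tol = NULL, min_over_positive = TRUE) {
  if (!inherits(es, "plaff_spectrum")) {
    es <- spectrum(diag(as.numeric(es), nrow = length(es)), zero_tol = zero_tol)
  }
  ev <- es$eigenvalues
  nm <- c("sum", "min", "max", "mean", "sd", "var", "sumsq", "n_sig")
  if (length(ev) == 0L) return(stats::setNames(numeric(8L), nm))
  pos <- ev[ev > es$zero_tol]
  mn <- if (min_over_positive) { if (length(pos)) min(pos) else 0 } else min(ev)
  mu <- mean(ev)
  v <- mean((ev - mu)^2)  # population variance
  stats::setNames(
    c(sum(ev), mn, max(ev), mu, sqrt(v), v, sum(ev^2), length(pos)), nm)
}

#' Binned persistent-Laplacian features of an interface
#'
#' For every ordered element pair (one element from partner A, one from
#' partner B) the bipartite modified-distance matrix is built, and at each
#' bin threshold `t` the persistent Laplacian at the pair `(t, t + delta)`
#' is formed for each dimension in `p_list`; its eigenvalues are summarised
#' by [eigen_statistics()]. Pairs with no atoms on either side give all-zero
#' cells. Layout order: element pairs row-major over `element_list`, then
#' bins ascending, then `p`, then the 8 statistics.
#'
#' @param region a `plaff_interface`.
#' @param element_list elements considered on each side.
#' @param bins increasing upper distance thresholds in Angstrom.
#' @param p_list Laplacian dimensions (default 0; dimension 1 is available
#'   but costs more).
#' @param delta offset of the second filtration threshold; 0 gives the
#'   diagonal (instantaneous) Laplacian at each bin, positive values the
#'   genuinely persistent operator `(t, t + delta)`.
#' @param zero_tol passed to [spectrum()].
#' @return Object of class `plaff_spectral_block`: named `values` vector of
#'   length `pairs * bins * dims * 8` and a `layout` data.frame.
#' @export
binned_spectral_features <- function(region,
                                     element_list = c("C", "N", "O", "S"),
                                     bins = 2:12, p_list = 0L, delta = 0,
                                     zero_tol = NULL) {
  stopifnot(inherits(region, "plaff_interface"),
            all(diff(bins) > 0), delta >= 0)
  stat_names <- c("sum", "min", "max", "mean", "sd", "var", "sumsq", "n_sig")
  vals <- numeric(0)
  layout <- list()
  for (ea in element_list) for (eb in element_list) {
    ia <- which(region$atoms_a$element == ea)
    ib <- which(region$atoms_b$element == eb)
    pair_empty <- length(ia) == 0L || length(ib) == 0L
    dm <- if (!pair_empty) {
      suppressWarnings(modified_distance_matrix(region, ia, ib))
    } else NULL
    fc <- NULL
    if (!pair_empty && any(p_list > 0L)) {
      fc <- build_rips_filtration(dm, max_dim = max(p_list) + 1L,
                                  max_filtration = max(bins) + delta)
    }
    for (t in bins) for (p in p_list) {
      cell <- if (pair_empty) {
        stats::setNames(numeric(8L), stat_names)
      } else if (p == 0L && delta == 0) {
        # fast path: diagonal dimension-0 operator is the graph Laplacian
        eigen_statistics(spectrum(.graph_laplacian_at(dm, t),
                                  zero_tol = zero_tol))
      } else {
        pl <- persistent_laplacian(fc, p, t, t + delta)
        eigen_statistics(spectrum(pl, zero_tol = zero_tol))
      }
      names(cell) <- sprintf("%s.%s|b%g|p%d|%s", ea, eb, t, p, stat_names)
      vals <- c(vals, cell)
      layout[[length(layout) + 1L]] <- data.frame(
        pair = paste0(ea, ".", eb), bin = t, p = p, empty = pair_empty)
    }
  }
  structure(list(values = vals, layout = do.call(rbind, layout),
                 bins = bins, element_list = element_list, p_list = p_list,
                 delta = delta),
            class = "plaff_spectral_block")
}

# graph Laplacian of the cross-distance graph thresholded at t
.graph_laplacian_at <- function(dm, t) {
  adj <- is.finite(dm$values) & dm$values <= t + 1e-12
  diag(adj) <- FALSE
  l <- -1 * adj
  diag(l) <- rowSums(adj)
  l
}

#' @export
print.plaff_spectral_block <- function(x, ...) {
  cat("Spectral feature block: ", length(x$values), " values (",
      length(x$element_list)^2, " element pairs x ", length(x$bins),
      " bins x ", length(x$p_list), " dims x 8)\n", sep = "")
  invisible(x)
}

#' Write a feature block as tab-separated text with a layout sidecar
#'
#' @param block a `plaff_spectral_block` or any named numeric vector.
#' @param path output TSV path; the layout manifest goes to
#'   `paste0(path, ".manifest.json")`.
#' @export
write_feature_block <- function(block, path) {
  vals <- if (is.list(block) && !is.null(block$values)) block$values else block
  df <- data.frame(feature = names(vals), value = as.numeric(vals))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- if (is.list(block) && !is.null(block$layout)) block$layout else
    data.frame(feature = names(vals))
  jsonlite::write_json(meta, paste0(path, ".manifest.json"), dataframe = "rows")
  invisible(path)
}
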