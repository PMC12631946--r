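# Filtered simplicial complexes: bipartite modified-distance Rips and
# Euclidean alpha filtrations.

#' Modified cross-partner distance matrix
#'
#' Builds the distance matrix that restricts topology to intermolecular
#' contacts: the entry for two atoms in the *same* partner is `+Inf`, while
#' cross-partner entries are the Euclidean distance in Angstrom. Any simplex
#' that would require an intra-partner edge therefore never enters a Rips
#' filtration built from this matrix, so its 1-skeleton is bipartite between
#' the two partners at every threshold.
#'
#' @param region a `plaff_interface` from [extract_interface()].
#' @param subset_a,subset_b atom selections per side: `NULL` (all atoms), an
#'   element symbol (e.g. `"C"`), a residue key from the residue grouping, or
#'   an integer index vector into `atoms_a`/`atoms_b`.
#' @return An object of class `plaff_distmat`: `values` (symmetric matrix
#'   with `Inf` sentinels, zero diagonal), `labels` (per-row partner, element
#'   and residue), `n_a`, `n_b`.
#' @export
modified_distance_matrix <- function(region, subset_a = NULL, subset_b = NULL) {
  stopifnot(inherits(region, "plaff_interface"))
  ia <- .resolve_subset(region, "A", subset_a)
  ib <- .resolve_subset(region, "B", subset_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    warning("degenerate distance matrix: empty atom subset on side ",
            if (length(ia) == 0L) "A" else "B")
  }
  a <- region$atoms_a[ia, , drop = FALSE]
  b <- region$atoms_b[ib, , drop = FALSE]
  n <- nrow(a) + nrow(b)
  values <- matrix(Inf, n, n)
  if (nrow(a) > 0L && nrow(b) > 0L) {
    d <- cross_distances(a, b)
    values[seq_len(nrow(a)), nrow(a) + seq_len(nrow(b))] <- d
    values[nrow(a) + seq_len(nrow(b)), seq_len(nrow(a))] <- t(d)
  }
  diag(values) <- 0
  labels <- data.frame(
    partner = rep(c("A", "B"), c(nrow(a), nrow(b))),
    element = c(a$element, b$element),
    residue = c(paste(a$chain, a$resno, a$resname, sep = ":"),
                paste(b$chain, b$resno, b$resname, sep = ":")),
    stringsAsFactors = FALSE
  )
  structure(list(values = values, labels = labels,
                 n_a = nrow(a), n_b = nrow(b)),
            class = "plaff_distmat")
}

.resolve_subset <- function(region, side, subset) {
  atoms <- if (side == "A") region$atoms_a else region$atoms_b
  if (is.null(subset)) return(seq_len(nrow(atoms)))
  if (is.numeric(subset)) {
    stopifnot(all(subset >= 1L), all(subset <= nrow(atoms)))
    return(as.integer(subset))
  }
  if (is.character(subset) && length(subset) >= 1L) {
    g <- region$groupings
    if (all(subset %in% names(g$element[[side]]))) {
      return(sort(unlist(g$element[[side]][subset], use.names = FALSE)))
    }
    if (all(subset %in% names(g$residue[[side]]))) {
      return(sort(unlist(g$residue[[side]][subset], use.names = FALSE)))
    }
    # element symbols outside the grouping list still select atoms
    return(which(atoms$element %in% subset))
  }
  stop("cannot interpret atom subset for side ", side)
}

#' @export
print.plaff_distmat <- function(x, ...) {
  fin <- sum(is.finite(x$values[upper.tri(x$values)]))
  cat("Modified distance matrix: ", x$n_a, "+", x$n_b, " atoms, ",
      fin, " finite cross entries\n", sep = "")
  invisible(x)
}

.new_filtration <- function(simplices, dims, values, n_vertices,
                            max_dimension, max_filtration) {
  ord <- order(values, dims, seq_along(values))
  structure(list(
    simplices = simplices[ord],
    dim = dims[ord],
    value = values[ord],
    n_vertices = n_vertices,
    max_dimension = max_dimension,
    max_filtration = max_filtration
  ), class = "plaff_filtration")
}

#' Vietoris-Rips filtration from a distance matrix
#'
#' Vertices enter at filtration value 0; a `k`-simplex enters when all its
#' pairwise distances do, at the maximum pairwise entry. Entries of `Inf`
#' (the intra-partner sentinel of [modified_distance_matrix()]) never produce
#' simplices, so on a modified distance matrix only vertices and
#' cross-partner edges (and bipartite higher cells, of which there are none)
#' appear.
#'
#' @param dm a `plaff_distmat`, or a plain symmetric numeric matrix.
#' @param max_dim highest simplex dimension to enumerate (default 2, giving
#'   H0/H1; values above 3 are refused unless `allow_high_dim = TRUE`).
#' @param max_filtration upper bound on filtration values in Angstrom;
#'   simplices above it are not built.
#' @param allow_high_dim override the `max_dim > 3` guard.
#' @return An object of class `plaff_filtration`: parallel lists/vectors
#'   `simplices` (integer vertex tuples, ascending), `dim`, `value`, sorted
#'   by (value, dimension) so faces always precede cofaces.
#' @export
build_rips_filtration <- function(dm, max_dim = 2L, max_filtration = 12.0,
                                  allow_high_dim = FALSE) {
  values <- if (inherits(dm, "plaff_distmat")) dm$values else as.matrix(dm)
  stopifnot(nrow(values) == ncol(values), max_dim >= 0L, max_filtration > 0)
  if (max_dim > 3L && !allow_high_dim) {
    stop("max_dim > 3 refused (combinatorial blow-up); ",
         "set allow_high_dim = TRUE to override")
  }
  n <- nrow(values)
  simplices <- as.list(seq_len(n))
  dims <- rep(0L, n)
  vals <- rep(0, n)

  if (max_dim >= 1L && n >= 2L) {
    adj <- is.finite(values) & values <= max_filtration
    diag(adj) <- FALSE
    ut <- which(upper.tri(values) & adj, arr.ind = TRUE)
    if (nrow(ut)) {
      edges <- lapply(seq_len(nrow(ut)), function(k) c(ut[k, 1L], ut[k, 2L]))
      simplices <- c(simplices, edges)
      dims <- c(dims, rep(1L, nrow(ut)))
      vals <- c(vals, values[ut])
    }
    if (max_dim >= 2L) {
      higher <- .rips_cliques(values, adj, max_dim)
      simplices <- c(simplices, higher$simplices)
      dims <- c(dims, higher$dims)
      vals <- c(vals, higher$vals)
    }
  }
  .new_filtration(simplices, dims, vals, n, max_dim, max_filtration)
}

# enumerate triangles (and tetrahedra for max_dim >= 3) as cliques of the
# threshold graph; filtration value = max pairwise distance
.rips_cliques <- function(values, adj, max_dim) {
  n <- nrow(adj)
  simplices <- list(); dims <- integer(); vals <- numeric()
  nbr <- lapply(seq_len(n), function(i) which(adj[i, ] & seq_len(n) > i))
  for (i in seq_len(n)) {
    for (j in nbr[[i]]) {
      common <- intersect(nbr[[i]], nbr[[j]])
      for (k in common) {
        simplices[[length(simplices) + 1L]] <- c(i, j, k)
        dims <- c(dims, 2L)
        vals <- c(vals, max(values[i, j], values[i, k], values[j, k]))
        if (max_dim >= 3L) {
          common2 <- intersect(common, nbr[[k]])
          for (l in common2[common2 > k]) {
            simplices[[length(simplices) + 1L]] <- c(i, j, k, l)
            dims <- c(dims, 3L)
            vals <- c(vals, max(values[i, j], values[i, k], values[i, l],
                                values[j, k], values[j, l], values[k, l]))
          }
        }
      }
    }
  }
  list(simplices = simplices, dims = dims, vals = vals)
}

#' @export
print.plaff_filtration <- function(x, ...) {
  tab <- table(factor(x$dim, levels = 0:max(x$dim, 0)))
  cat("Filtration: ", length(x$simplices), " simplices (",
      paste(sprintf("%d of dim %s", tab, names(tab)), collapse = ", "),
      "), max value ", format(max(x$value)), "\n", sep = "")
  invisible(x)
}

#' Alpha filtration of a Euclidean point cloud
#'
#' Builds the Delaunay triangulation of the points (2-D or 3-D) and assigns
#' each simplex the filtration value `max(De/2)` over its edges, where `De`
#' is the Euclidean edge length; values are propagated so every face enters
#' no later than its cofaces. At the maximal filtration value the complex
#' equals the full Delaunay triangulation. Coplanar 3-D input falls back to a
#' planar triangulation with a warning. The Delaunay step is an exhaustive
#' empty-circumsphere test, intended for the modest point counts of
#' interface patches.
#'
#' @param points numeric matrix, one point per row (2 or 3 columns).
#' @return A `plaff_filtration`.
#' @export
build_alpha_filtration <- function(points) {
  points <- rbind(points)
  n <- nrow(points)
  if (n < 2L) {
    return(.new_filtration(as.list(seq_len(max(n, 0L))), rep(0L, n),
                           rep(0, n), n, 0L, Inf))
  }
  d <- ncol(points)
  stopifnot(d %in% c(2L, 3L))
  if (d == 3L) {
    # rank of the centered cloud decides degeneracy
    sv <- svd(scale(points, scale = FALSE))$d
    if (n < 4L || sv[3L] < 1e-9 * max(sv[1L], 1)) {
      warning("coplanar 3-D input: falling back to 2-D triangulation")
      basis <- svd(scale(points, scale = FALSE))$v[, 1:2, drop = FALSE]
      points <- scale(points, scale = FALSE) %*% basis
      d <- 2L
    }
  }
  top <- if (d == 2L) .delaunay2d(points) else .delaunay3d(points)

  # collect all faces of the top-dimensional simplices
  keys <- new.env(parent = emptyenv())
  add <- function(s) {
    k <- paste(s, collapse = "-")
    if (is.null(keys[[k]])) keys[[k]] <- s
  }
  for (s in top) {
    m <- length(s)
    for (sz in seq_len(m)) {
      cmb <- utils::combn(s, sz)
      for (ci in seq_len(ncol(cmb))) add(sort(cmb[, ci]))
    }
  }
  for (v in seq_len(n)) add(v)  # isolated vertices (degenerate inputs)

  simplices <- as.list(mget(ls(keys), envir = keys))
  names(simplices) <- NULL
  dims <- vapply(simplices, length, integer(1)) - 1L
  edge_val <- function(s) {
    if (length(s) == 1L) return(0)
    pr <- utils::combn(s, 2L)
    max(vapply(seq_len(ncol(pr)), function(k) {
      sqrt(sum((points[pr[1L, k], ] - points[pr[2L, k], ])^2)) / 2
    }, numeric(1)))
  }
  vals <- vapply(simplices, edge_val, numeric(1))
  .new_filtration(simplices, dims, vals, n, max(dims), max(vals))
}

# exhaustive empty-circumcircle Delaunay; returns list of vertex triples
.delaunay2d <- function(p, tol = 1e-9) {
  n <- nrow(p)
  out <- list()
  if (n < 3L) return(out)
  cmb <- utils::combn(n, 3L)
  for (k in seq_len(ncol(cmb))) {
    tri <- cmb[, k]
    cc <- .circumcircle2d(p[tri, , drop = FALSE])
    if (is.null(cc)) next  # collinear
    dd <- sqrt(rowSums((p - matrix(cc$center, n, 2, byrow = TRUE))^2))
    if (all(dd[-tri] >= cc$radius - tol)) out[[length(out) + 1L]] <- tri
  }
  out
}

.delaunay3d <- function(p, tol = 1e-9) {
  n <- nrow(p)
  out <- list()
  if (n < 4L) return(out)
  cmb <- utils::combn(n, 4L)
  for (k in seq_len(ncol(cmb))) {
    tet <- cmb[, k]
    cs <- .circumsphere3d(p[tet, , drop = FALSE])
    if (is.null(cs)) next  # degenerate tetrahedron
    dd <- sqrt(rowSums((p - matrix(cs$center, n, 3, byrow = TRUE))^2))
    if (all(dd[-tet] >= cs$radius - tol)) out[[length(out) + 1L]] <- tet
  }
  out
}

.circumcircle2d <- function(q) {
  a <- 2 * (q[2:3, ] - q[rep(1L, 2L), ])
  if (abs(det(a)) < 1e-12) return(NULL)
  b <- rowSums(q[2:3, ]^2) - sum(q[1L, ]^2)
  ctr <- solve(a, b)
  list(center = ctr, radius = sqrt(sum((q[1L, ] - ctr)^2)))
}

.circumsphere3d <- function(q) {
  a <- 2 * (q[2:4, ] - q[rep(1L, 3L), ])
  if (abs(det(a)) < 1e-12) return(NULL)
  b <- rowSums(q[2:4, ]^2) - sum(q[1L, ]^2)
  ctr <- solve(a, b)
  list(center = ctr, radius = sqrt(sum((q[1L, ] - ctr)^2)))
}

#' Write a filtration as a plain-text simplex list
#'
#' Three tab-separated columns: space-separated vertex ids, dimension,
#' filtration value. Intended for debugging and for comparison against
#' independent constructions.
#'
#' @param fc a `plaff_filtration`.
#' @param path output file path.
#' @export
export_filtration <- function(fc, path) {
  stopifnot(inherits(fc, "plaff_filtration"))
  df <- data.frame(
    vertices = vapply(fc$simplices, paste, character(1), collapse = " "),
    dim = fc$dim,
    value = fc$value
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# indices (into fc order) of simplices present in the sublevel complex at x
sublevel_indices <- function(fc, x, p = NULL) {
  keep <- fc$value <= x + 1e-12
  if (!is.null(p)) keep <- keep & fc$dim == p
  which(keep)
}
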