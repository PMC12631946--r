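# Persistence by boundary-matrix reduction over Z2, with an independent
# rank-based oracle used for cross-checking.

# key for simplex lookup tables
.skey <- function(v) paste(v, collapse = "-")

# map from simplex key to position in filtration order
.simplex_index <- function(fc) {
  env <- new.env(parent = emptyenv(), size = length(fc$simplices))
  for (i in seq_along(fc$simplices)) env[[.skey(fc$simplices[[i]])]] <- i
  env
}

#' Boundary matrix of a filtration at one dimension
#'
#' Column `j` holds the boundary of the `j`-th `p`-simplex (in filtration
#' order) expressed over the `(p-1)`-simplices. Over `Z2` entries are 0/1;
#' over the reals they are the orientation signs `(-1)^i` induced by the
#' global ascending vertex order, as needed for Laplacians. In either
#' convention composing successive boundary maps gives zero.
#'
#' @param fc a `plaff_filtration`.
#' @param p simplex dimension of the columns (`1 <= p <= max dimension`).
#' @param coefficients `"Z2"` or `"real"`.
#' @return A list of class `plaff_boundary`: `matrix`, `row_simplices`,
#'   `col_simplices` (indices into the filtration), `p`, `coefficients`.
#' @export
boundary_matrix <- function(fc, p, coefficients = c("Z2", "real")) {
  coefficients <- match.arg(coefficients)
  stopifnot(inherits(fc, "plaff_filtration"))
  if (p < 1L || p > max(fc$dim)) stop("p = ", p, " out of range for this filtration")
  rows <- which(fc$dim == p - 1L)
  cols <- which(fc$dim == p)
  idx <- .simplex_index(fc)
  rowpos <- stats::setNames(seq_along(rows), vapply(fc$simplices[rows], .skey, ""))
  m <- matrix(0, length(rows), length(cols))
  for (jj in seq_along(cols)) {
    s <- fc$simplices[[cols[jj]]]
    for (i in seq_along(s)) {
      face <- s[-i]
      ri <- rowpos[[.skey(face)]]
      m[ri, jj] <- if (coefficients == "real") (-1)^(i - 1L) else 1
    }
  }
  structure(list(matrix = m, row_simplices = rows, col_simplices = cols,
                 p = p, coefficients = coefficients),
            class = "plaff_boundary")
}

#' Persistence barcodes by column reduction
#'
#' Standard persistence pairing over Z2: columns of the global boundary
#' matrix are reduced in filtration order; a column that reduces to zero
#' creates a class, a surviving lowest entry kills the class created by that
#' row. Zero-length bars are discarded; classes alive at the end of the
#' filtration get death `Inf`.
#'
#' @param fc a `plaff_filtration` (sorted so faces precede cofaces, as
#'   produced by the constructors here).
#' @param max_p highest homology dimension reported (default: filtration
#'   dimension minus nothing, i.e. all available).
#' @return Object of class `plaff_barcodes`: a list with one
#'   `data.frame(birth, death)` per dimension `0..max_p`, named `"0"`,
#'   `"1"`, ...
#' @export
compute_barcodes <- function(fc, max_p = NULL) {
  stopifnot(inherits(fc, "plaff_filtration"))
  if (is.null(max_p)) max_p <- max(fc$dim)
  n <- length(fc$simplices)
  idx <- .simplex_index(fc)

  # reduced columns stored as sorted integer vectors of row (simplex) indices
  low_owner <- integer(n)            # low row -> column that owns it
  destroyed <- logical(n)
  births <- list()
  for (d in 0:max_p) births[[d + 1L]] <- list(b = numeric(), dth = numeric())

  cols <- vector("list", n)
  for (j in seq_len(n)) {
    s <- fc$simplices[[j]]
    if (length(s) == 1L) next  # vertices have empty boundary
    col <- sort(vapply(seq_along(s), function(i) idx[[.skey(s[-i])]], integer(1)))
    repeat {
      if (length(col) == 0L) break
      lw <- col[length(col)]
      owner <- low_owner[lw]
      if (owner == 0L) break
      # Z2 addition = symmetric difference
      oc <- cols[[owner]]
      col <- sort(c(setdiff(col, oc), setdiff(oc, col)))
    }
    if (length(col) == 0L) next  # j creates a class
    lw <- col[length(col)]
    cols[[j]] <- col
    low_owner[lw] <- j
    destroyed[lw] <- TRUE
    pd <- fc$dim[lw]
    if (pd <= max_p) {
      b <- fc$value[lw]; dth <- fc$value[j]
      if (dth > b) {  # zero-length bars discarded
        births[[pd + 1L]]$b <- c(births[[pd + 1L]]$b, b)
        births[[pd + 1L]]$dth <- c(births[[pd + 1L]]$dth, dth)
      }
    }
  }
  # unpaired creators: simplices that are not destroyers and never killed
  is_destroyer <- !vapply(cols, is.null, logical(1))
  for (j in seq_len(n)) {
    if (is_destroyer[j] || destroyed[j]) next
    pd <- fc$dim[j]
    if (pd <= max_p) {
      births[[pd + 1L]]$b <- c(births[[pd + 1L]]$b, fc$value[j])
      births[[pd + 1L]]$dth <- c(births[[pd + 1L]]$dth, Inf)
    }
  }
  out <- lapply(births, function(bb) {
    df <- data.frame(birth = bb$b, death = bb$dth)
    df[order(df$birth, df$death), , drop = FALSE]
  })
  names(out) <- as.character(0:max_p)
  structure(out, class = "plaff_barcodes")
}

#' @export
print.plaff_barcodes <- function(x, ...) {
  for (d in names(x)) {
    df <- x[[d]]
    inf <- sum(is.infinite(df$death))
    cat("H", d, ": ", nrow(df), " bars (", inf, " infinite)\n", sep = "")
  }
  invisible(x)
}

#' Persistent Betti number from barcodes
#'
#' Counts intervals with `birth <= x` and `death > y`: the rank of the map
#' `Hp(Kx) -> Hp(Ky)` induced by inclusion.
#'
#' @param fc a `plaff_filtration` or a precomputed `plaff_barcodes`.
#' @param p homology dimension.
#' @param x,y filtration pair, `x <= y`.
#' @export
persistent_betti <- function(fc, p, x, y = x) {
  stopifnot(x <= y)
  bars <- if (inherits(fc, "plaff_barcodes")) fc else compute_barcodes(fc)
  key <- as.character(p)
  if (!key %in% names(bars)) return(0L)
  df <- bars[[key]]
  sum(df$birth <= x + 1e-12 & df$death > y + 1e-12)
}

#' Write barcodes as three-column text
#'
#' Columns `dim`, `birth`, `death`; infinite deaths written as `inf`.
#' @param bars a `plaff_barcodes`.
#' @param path output path.
#' @export
export_barcodes <- function(bars, path) {
  stopifnot(inherits(bars, "plaff_barcodes"))
  rows <- do.call(rbind, lapply(names(bars), function(d) {
    df <- bars[[d]]
    if (nrow(df) == 0L) return(NULL)
    data.frame(dim = as.integer(d), birth = df$birth,
               death = ifelse(is.infinite(df$death), "inf",
                              format(df$death)))
  }))
  if (is.null(rows)) rows <- data.frame(dim = integer(), birth = numeric(),
                                        death = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- independent Z2 rank oracle -------------------------------------------
## Used to cross-check the reduction algorithm: persistent Betti numbers are
## recomputed from explicit cycle/boundary subspaces and Z2 Gaussian
## elimination, sharing no code with compute_barcodes().

# rank of a 0/1 matrix over Z2 by Gaussian elimination
z2_rank <- function(m) {
  if (length(m) == 0L) return(0L)
  m <- (m %% 2) != 0
  r <- 0L
  nr <- nrow(m); nc <- ncol(m)
  for (col in seq_len(nc)) {
    piv <- which(m[, col] & seq_len(nr) > r)
    if (length(piv) == 0L) next
    piv <- piv[1L]
    r <- r + 1L
    if (piv != r) m[c(piv, r), ] <- m[c(r, piv), ]
    hit <- which(m[, col]); hit <- hit[hit != r]
    if (length(hit)) m[hit, ] <- xor(m[hit, , drop = FALSE],
                                     matrix(m[r, ], length(hit), nc, byrow = TRUE))
  }
  r
}

# null-space basis (columns) of a 0/1 matrix over Z2
z2_nullspace <- function(m) {
  nc <- ncol(m)
  if (nc == 0L) return(matrix(0, 0, 0))
  if (nrow(m) == 0L) return(diag(1, nc))
  m <- (m %% 2) != 0
  nr <- nrow(m)
  pivots <- integer(0)
  r <- 0L
  for (col in seq_len(nc)) {
    piv <- which(m[, col] & seq_len(nr) > r)
    if (length(piv) == 0L) next
    piv <- piv[1L]; r <- r + 1L
    if (piv != r) m[c(piv, r), ] <- m[c(r, piv), ]
    hit <- which(m[, col]); hit <- hit[hit != r]
    if (length(hit)) m[hit, ] <- xor(m[hit, , drop = FALSE],
                                     matrix(m[r, ], length(hit), nc, byrow = TRUE))
    pivots <- c(pivots, col)
  }
  free <- setdiff(seq_len(nc), pivots)
  if (length(free) == 0L) return(matrix(0, nc, 0))
  # m is in reduced row-echelon form: row i reads x[pivots[i]] + sum over
  # free columns c of m[i,c] x[c] = 0, so setting one free variable to 1
  # fixes every pivot variable directly
  basis <- matrix(0, nc, length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    v <- numeric(nc); v[f] <- 1
    for (i in seq_along(pivots)) v[pivots[i]] <- as.numeric(m[i, f])
    basis[, k] <- v
  }
  basis
}

# boundary matrix of the p-simplices of the sublevel complex at threshold x,
# over Z2, rows = (p-1)-simplices at x (built independently of boundary_matrix)
.z2_boundary_at <- function(fc, p, x) {
  cols <- sublevel_indices(fc, x, p)
  rows <- sublevel_indices(fc, x, p - 1L)
  rowpos <- stats::setNames(seq_along(rows),
                            vapply(fc$simplices[rows], .skey, ""))
  m <- matrix(0, length(rows), length(cols))
  if (p >= 1L) {
    for (jj in seq_along(cols)) {
      s <- fc$simplices[[cols[jj]]]
      for (i in seq_along(s)) m[rowpos[[.skey(s[-i])]], jj] <- 1
    }
  }
  list(m = m, rows = rows, cols = cols)
}

# persistent Betti number from explicit subspace ranks:
#   beta_p(x,y) = dim Z_p(K_x) - dim( Z_p(K_x) /\ B_p(K_y) )
# with dim(Z /\ B) = dim Z + dim B - rank [Z | B] after embedding Z_p(K_x)
# into the p-chain coordinates of K_y.
persistent_betti_z2rank <- function(fc, p, x, y = x) {
  stopifnot(x <= y)
  bx <- .z2_boundary_at(fc, p, x)
  if (length(bx$cols) == 0L) return(0L)
  # cycles at x
  if (p == 0L) {
    z_basis <- diag(1, length(bx$cols))  # all 0-chains are cycles
  } else {
    z_basis <- z2_nullspace(bx$m)
  }
  dim_z <- ncol(z_basis)
  if (dim_z == 0L) return(0L)
  # boundaries at y, in K_y p-chain coordinates
  by <- .z2_boundary_at(fc, p + 1L, y)
  cols_y <- sublevel_indices(fc, y, p)
  # embed x-cycles into y coordinates
  pos_in_y <- match(bx$cols, cols_y)
  z_in_y <- matrix(0, length(cols_y), dim_z)
  z_in_y[pos_in_y, ] <- z_basis
  if (length(by$cols) == 0L) return(dim_z)
  bmat <- matrix(0, length(cols_y), length(by$cols))
  # rows of by$m are the p-simplices at y in the same order as cols_y
  stopifnot(identical(by$rows, cols_y))
  bmat <- by$m
  dim_b <- z2_rank(bmat)
  dim_sum <- z2_rank(cbind(z_in_y, bmat))
  inter <- dim_z + dim_b - dim_sum
  dim_z - inter
}
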