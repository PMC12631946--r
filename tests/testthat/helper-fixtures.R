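# shared fixtures and independent mini-oracles used across test files

# minimal two-atom PDB text (chains A and B, 5 A apart on x)
two_atom_pdb <- function(d = 5) {
  generate_fixture_complex("two-atom", cross_distance = d)$pdb
}

# unit-square Euclidean distance matrix
square_dist <- function() {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  as.matrix(dist(pts))
}

# random Euclidean Rips filtration on <= n points
random_filtration <- function(n = 7, max_dim = 2, dim_space = 3,
                              frac = 0.8) {
  pts <- matrix(stats::rnorm(n * dim_space), n, dim_space)
  d <- as.matrix(dist(pts))
  build_rips_filtration(d, max_dim = max_dim,
                        max_filtration = stats::quantile(d[upper.tri(d)],
                                                         frac))
}

# random bipartite modified-distance filtration
random_bipartite_filtration <- function(na = 3, nb = 4, max_dim = 2) {
  xa <- matrix(stats::rnorm(na * 3, sd = 2), na, 3)
  xb <- matrix(stats::rnorm(nb * 3, sd = 2), nb, 3)
  n <- na + nb
  values <- matrix(Inf, n, n)
  cr <- plaff:::cross_distances(xa, xb)
  values[seq_len(na), na + seq_len(nb)] <- cr
  values[na + seq_len(nb), seq_len(na)] <- t(cr)
  diag(values) <- 0
  build_rips_filtration(values, max_dim = max_dim,
                        max_filtration = max(cr) * 1.1)
}

# independent brute-force Rips construction: enumerate all vertex subsets
brute_force_rips <- function(dvals, max_dim, max_filtration) {
  n <- nrow(dvals)
  out <- list()
  for (k in 0:max_dim) {
    cmb <- utils::combn(n, k + 1L)
    for (ci in seq_len(ncol(cmb))) {
      s <- cmb[, ci]
      if (k == 0L) {
        out[[length(out) + 1L]] <- list(s = s, value = 0)
      } else {
        pr <- utils::combn(s, 2L)
        dd <- dvals[t(pr)]
        if (all(is.finite(dd)) && all(dd <= max_filtration)) {
          out[[length(out) + 1L]] <- list(s = s, value = max(dd))
        }
      }
    }
  }
  out
}

# canonical multiset representation of a filtration for comparison
filtration_signature <- function(fc) {
  sig <- vapply(seq_along(fc$simplices), function(i) {
    paste(paste(fc$simplices[[i]], collapse = "."),
          signif(fc$value[i], 10), sep = "@")
  }, "")
  sort(sig)
}

# brute-force affine-gap global alignment score: enumerates every alignment
# as a move sequence (D diagonal, U gap in b, L gap in a) and scores it
# directly; independent of the Gotoh implementation, viable for tiny inputs
brute_force_nw_score <- function(a, b, sub, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  enumerate <- function(i, j) {
    if (i == 0L && j == 0L) return(list(character(0)))
    out <- list()
    if (i > 0L && j > 0L) {
      out <- c(out, lapply(enumerate(i - 1L, j - 1L), function(p) c(p, "D")))
    }
    if (i > 0L) out <- c(out, lapply(enumerate(i - 1L, j),
                                     function(p) c(p, "U")))
    if (j > 0L) out <- c(out, lapply(enumerate(i, j - 1L),
                                     function(p) c(p, "L")))
    out
  }
  score_one <- function(moves) {
    i <- 0L; j <- 0L; s <- 0; prev <- ""
    for (m in moves) {
      if (m == "D") {
        i <- i + 1L; j <- j + 1L
        s <- s + sub[av[i], bv[j]]
      } else {
        if (m == "U") i <- i + 1L else j <- j + 1L
        s <- s - ext - if (m == prev) 0 else open
      }
      prev <- m
    }
    s
  }
  max(vapply(enumerate(length(av), length(bv)), score_one, numeric(1)))
}
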