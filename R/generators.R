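# Synthetic fixtures: toy PDB complexes with analytically known interface
# topology, and feature/label datasets with a known generating function.

.pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                           element, occ = 1.00) {
  name_f <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_f, resname, chain, resno, xyz[1L], xyz[2L], xyz[3L],
          occ, 0, toupper(element))
}

.pdb_from_atoms <- function(df) {
  lines <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    lines[i] <- .pdb_atom_line(i, df$name[i], df$resname[i], df$chain[i],
                               df$resno[i], c(df$x[i], df$y[i], df$z[i]),
                               df$element[i])
  }
  paste(c(lines, "END"), collapse = "\n")
}

#' Generate a toy two-chain complex with known interface topology
#'
#' Emits PDB text for a small constructed dimer together with a manifest of
#' exact quantities derived from the construction geometry: atom counts,
#' the distinct cross-partner distances, interface sizes at given cutoffs,
#' and -- for the lattice/ring/two-atom templates -- the expected H0/H1
#' persistence intervals of the bipartite modified-distance Rips filtration
#' (on a bipartite complex no triangle can form, so 1-cycles never die and
#' are listed with death `Inf`).
#'
#' Templates:
#' \describe{
#'   \item{`two-atom`}{one atom per chain at `cross_distance` Angstrom.}
#'   \item{`bipartite-lattice`}{a 2x2 square of atoms per chain, the chains
#'     stacked `spacing` apart; H0 merges happen at `spacing` and at the
#'     face diagonal.}
#'   \item{`ring-motif`}{six atoms alternating A/B on a circle of radius
#'     `ring_radius`; the hexagon closes into one 1-cycle at the side
#'     length (= radius) and three more at the diameter.}
#'   \item{`two-helix`}{two idealised alpha-helix backbones (N/CA/C/O) with
#'     parallel axes `separation` apart; the manifest carries brute-force
#'     interface sizes instead of barcodes.}
#' }
#'
#' @param template template name.
#' @param seed seed for the optional coordinate jitter.
#' @param cross_distance two-atom separation (Angstrom).
#' @param spacing lattice inter-chain spacing.
#' @param ring_radius ring radius.
#' @param n_res residues per helix.
#' @param separation helix axis separation.
#' @param jitter Gaussian coordinate noise (default 0: byte-identical
#'   output for any seed).
#' @return List: `pdb` (text), `manifest` (named list of known quantities).
#' @export
generate_fixture_complex <- function(template = c("two-atom",
                                                  "bipartite-lattice",
                                                  "ring-motif", "two-helix"),
                                     seed = 1L, cross_distance = 5,
                                     spacing = 3, ring_radius = 4,
                                     n_res = 8L, separation = 9,
                                     jitter = 0) {
  template <- match.arg(template)
  atoms <- switch(
    template,
    "two-atom" = data.frame(
      name = "CA", resname = "GLY", chain = c("A", "B"), resno = 1L,
      x = c(0, cross_distance), y = 0, z = 0, element = "C",
      stringsAsFactors = FALSE),
    "bipartite-lattice" = {
      xy <- expand.grid(x = c(0, spacing), y = c(0, spacing))
      data.frame(name = "CA", resname = "GLY",
                 chain = rep(c("A", "B"), each = 4L),
                 resno = rep(1:4, 2L),
                 x = rep(xy$x, 2L), y = rep(xy$y, 2L),
                 z = rep(c(0, spacing), each = 4L), element = "C",
                 stringsAsFactors = FALSE)
    },
    "ring-motif" = {
      ang <- (0:5) * pi / 3
      data.frame(name = "CA", resname = "GLY",
                 chain = rep(c("A", "B"), 3L),
                 resno = rep(1:3, each = 2L),
                 x = ring_radius * cos(ang), y = ring_radius * sin(ang),
                 z = 0, element = "C", stringsAsFactors = FALSE)
    },
    "two-helix" = {
      helix <- function(chain, x_offset) {
        res <- lapply(seq_len(n_res), function(i) {
          th <- (i - 1L) * 100 * pi / 180
          base <- c(x_offset + 2.3 * cos(th), 2.3 * sin(th), (i - 1L) * 1.5)
          data.frame(
            name = c("N", "CA", "C", "O"),
            resname = "ALA", chain = chain, resno = i,
            x = base[1L] + c(-0.5, 0, 0.5, 0.6),
            y = base[2L] + c(0.4, 0, -0.4, -1.2),
            z = base[3L] + c(-0.5, 0, 0.5, 0.7),
            element = c("N", "C", "C", "O"), stringsAsFactors = FALSE)
        })
        do.call(rbind, res)
      }
      rbind(helix("A", 0), helix("B", separation))
    })

  if (jitter > 0) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, jitter)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, jitter)
  }

  a_idx <- atoms$chain == "A"
  cross <- cross_distances(cbind(atoms$x, atoms$y, atoms$z)[a_idx, , drop = FALSE],
                           cbind(atoms$x, atoms$y, atoms$z)[!a_idx, , drop = FALSE])
  manifest <- list(
    template = template,
    n_atoms = nrow(atoms),
    n_atoms_a = sum(a_idx), n_atoms_b = sum(!a_idx),
    cross_distances = sort(unique(round(as.numeric(cross), 6))),
    min_cross_distance = min(cross),
    interface_size = function(cutoff) {
      list(a = sum(apply(cross, 1L, min) <= cutoff),
           b = sum(apply(cross, 2L, min) <= cutoff))
    }
  )
  if (jitter == 0) {
    manifest$barcodes <- switch(
      template,
      "two-atom" = list(
        h0 = data.frame(birth = c(0, 0), death = c(cross_distance, Inf)),
        h1 = data.frame(birth = numeric(), death = numeric())),
      "bipartite-lattice" = {
        d1 <- spacing; d2 <- spacing * sqrt(2)
        list(h0 = data.frame(birth = 0,
                             death = c(rep(d1, 4L), rep(d2, 3L), Inf)),
             h1 = data.frame(birth = c(rep(d2, 5L),
                                       rep(spacing * sqrt(3), 4L)),
                             death = Inf))
      },
      "ring-motif" = {
        side <- ring_radius  # hexagon side equals radius
        list(h0 = data.frame(birth = 0, death = c(rep(side, 5L), Inf)),
             h1 = data.frame(birth = c(side, rep(2 * ring_radius, 3L)),
                             death = Inf))
      },
      "two-helix" = NULL)
  }
  list(pdb = .pdb_from_atoms(atoms), manifest = manifest)
}

.save_seed <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed",
                                               envir = globalenv())
  } else assign(".Random.seed", old, globalenv())
}

#' Synthetic feature/label dataset with a known generating function
#'
#' Draws grouped feature vectors and labels
#' `y = f(x) + N(0, noise_sd^2)` for a documented sparse nonlinear `f`
#' (linear terms, one interaction, one sinusoid, one quadratic), on a
#' binding-free-energy-like scale around -9 kcal/mol. Records carry parent
#' ids, with several "mutant" rows per parent whose features are correlated
#' within the group, so grouped splits are meaningful. The generating
#' function is returned for recovery scoring.
#'
#' @param n number of records (>= 10).
#' @param noise_sd label noise standard deviation, kcal/mol.
#' @param seed integer seed.
#' @param n_features feature dimension (>= 8).
#' @param group_size average records per parent group.
#' @return List: `X` (matrix with column names), `y`, `records`
#'   (`structure_id`, `parent_id`, `is_mutant`), `f` (the noiseless map on
#'   a feature matrix), `noise_sd`.
#' @export
generate_synthetic_dataset <- function(n, noise_sd = 0.5, seed = 1L,
                                       n_features = 40L, group_size = 8L) {
  stopifnot(n >= 10L, n_features >= 8L)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)

  n_groups <- max(2L, ceiling(n / group_size))
  grp <- sort(rep_len(seq_len(n_groups), n))
  # group-level feature centres: mutants of one parent stay similar
  centres <- matrix(stats::rnorm(n_groups * n_features, 0, 0.8),
                    n_groups, n_features)
  X <- centres[grp, , drop = FALSE] +
    matrix(stats::rnorm(n * n_features, 0, 0.6), n, n_features)
  colnames(X) <- sprintf("f%02d", seq_len(n_features))

  f <- function(X) {
    -9 + 1.6 * X[, 1L] - 1.2 * X[, 2L] + 0.8 * X[, 3L] +
      0.9 * X[, 4L] * X[, 5L] + 0.8 * sin(pi * X[, 6L] / 2) +
      0.5 * (X[, 7L]^2 - 1)
  }
  y <- f(X) + stats::rnorm(n, 0, noise_sd)

  records <- data.frame(
    structure_id = sprintf("S%05d", seq_len(n)),
    parent_id = sprintf("G%04d", grp),
    is_mutant = duplicated(grp),
    stringsAsFactors = FALSE)
  list(X = X, y = y, records = records, f = f, noise_sd = noise_sd,
       seed = seed)
}
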