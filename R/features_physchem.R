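# Physicochemical descriptors: interaction energies, solvent accessible and
# buried surface area, and the 74-slot auxiliary block.

#' Cross-partner pairwise interaction energy
#'
#' Sums Coulomb (`k q_i q_j / (eps r_ij)`, `k = 332.0637`
#' kcal*Angstrom/(mol*e^2)) or Lennard-Jones
#' (`4 eps_ij [(sigma_ij/r)^12 - (sigma_ij/r)^6]`, Lorentz-Berthelot mixing)
#' energies over all cross-partner atom pairs; same-partner pairs contribute
#' nothing. Distances below the clash floor are clamped to it with a
#' warning. The result carries a decomposition by the element of the focal
#' partner's atom.
#'
#' @param pair a `plaff_partner_pair` (or a list with `partner_a`,
#'   `partner_b` atom tables).
#' @param model `"coulomb"` or `"lennard_jones"`.
#' @param params for Coulomb: `charges_a`, `charges_b` (e units; default
#'   [assign_default_charges()]) and `dielectric` (default 1); for LJ:
#'   `epsilon`, `sigma` named per-element vectors (bundled defaults).
#' @param focal which partner's atom elements index the decomposition.
#' @param clash_floor minimum distance in Angstrom (default 0.5).
#' @return List: `total` (kcal/mol), `by_element` (named over C/N/O/S plus
#'   `other`), `model`.
#' @export
pairwise_interaction_energy <- function(pair,
                                        model = c("coulomb", "lennard_jones"),
                                        params = list(), focal = "A",
                                        clash_floor = 0.5) {
  model <- match.arg(model)
  a <- pair$partner_a; b <- pair$partner_b
  stopifnot(nrow(a) > 0L, nrow(b) > 0L)
  r <- cross_distances(a, b)
  if (any(r < clash_floor)) {
    warning(sum(r < clash_floor), " atom pair(s) below the ", clash_floor,
            " A clash floor; distances clamped")
    r[r < clash_floor] <- clash_floor
  }
  if (model == "coulomb") {
    qa <- params$charges_a %||% assign_default_charges(a)
    qb <- params$charges_b %||% assign_default_charges(b)
    if (length(qa) != nrow(a) || length(qb) != nrow(b)) {
      stop("charge vectors must match atom counts")
    }
    eps <- params$dielectric %||% 1
    emat <- COULOMB_K * outer(qa, qb) / (eps * r)
  } else {
    epsl <- params$epsilon %||% LJ_EPSILON
    sigl <- params$sigma %||% LJ_SIGMA
    miss <- setdiff(unique(c(a$element, b$element)), names(epsl))
    if (length(miss)) {
      stop("missing Lennard-Jones parameters for element(s): ",
           paste(miss, collapse = ", "), " (first atom serial ",
           c(a$serial, b$serial)[c(a$element, b$element) %in% miss][1L], ")")
    }
    sij <- outer(sigl[a$element], sigl[b$element], "+") / 2
    eij <- sqrt(outer(epsl[a$element], epsl[b$element]))
    sr6 <- (sij / r)^6
    emat <- 4 * eij * (sr6^2 - sr6)
  }
  foc_el <- if (focal == "A") a$element else b$element
  margin <- if (focal == "A") rowSums(emat) else colSums(emat)
  grp <- ifelse(foc_el %in% c("C", "N", "O", "S"), foc_el, "other")
  by_el <- vapply(c("C", "N", "O", "S", "other"),
                  function(e) sum(margin[grp == e]), numeric(1))
  list(total = sum(emat), by_element = by_el, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic golden-angle (Fibonacci) lattice on the unit sphere
.sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom ASA by sphere sampling: each atom's solvent sphere (van der
#' Waals radius + probe) is covered with a deterministic golden-angle point
#' lattice and a point counts as accessible when it lies outside every
#' neighbouring atom's solvent sphere.
#'
#' @param atoms atom table.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points sample points per atom (>= 100).
#' @param radii named per-element van der Waals radii; bundled Bondi values
#'   by default. Unknown elements fall back to `default_radius` with a
#'   warning.
#' @param default_radius fallback radius, Angstrom.
#' @return Numeric vector of per-atom areas in Angstrom^2.
#' @export
solvent_accessible_area <- function(atoms, probe = 1.4, n_points = 960L,
                                    radii = VDW_RADII, default_radius = 1.7) {
  stopifnot(n_points >= 100L)
  n <- nrow(atoms)
  if (n == 0L) return(numeric(0))
  rv <- radii[atoms$element]
  if (anyNA(rv)) {
    warning("unknown vdW radius for element(s) ",
            paste(unique(atoms$element[is.na(rv)]), collapse = ", "),
            "; using ", default_radius, " A")
    rv[is.na(rv)] <- default_radius
  }
  rs <- rv + probe  # solvent sphere radii
  xyz <- .xyz(atoms)
  pts <- .sphere_lattice(n_points)
  out <- numeric(n)
  d <- if (n > 1L) cross_distances(xyz, xyz) else matrix(0, 1, 1)
  for (i in seq_len(n)) {
    nbr <- which(d[i, ] < rs[i] + rs & seq_len(n) != i)
    if (length(nbr) == 0L) {
      out[i] <- 4 * pi * rs[i]^2
      next
    }
    sp <- pts * rs[i] + matrix(xyz[i, ], n_points, 3L, byrow = TRUE)
    free <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(free)) break
      dj2 <- (sp[free, 1L] - xyz[j, 1L])^2 + (sp[free, 2L] - xyz[j, 2L])^2 +
        (sp[free, 3L] - xyz[j, 3L])^2
      free[free] <- dj2 > rs[j]^2
    }
    out[i] <- 4 * pi * rs[i]^2 * sum(free) / n_points
  }
  out
}

#' Buried surface area on complex formation
#'
#' `BSA = ASA(A alone) + ASA(B alone) - ASA(complex)`; the per-partner split
#' is each side's own loss of accessible area.
#'
#' @param pair a `plaff_partner_pair`.
#' @inheritParams solvent_accessible_area
#' @return List: `total`, `a`, `b` (Angstrom^2), plus per-atom losses
#'   `per_atom_a`, `per_atom_b`.
#' @export
buried_surface_area <- function(pair, probe = 1.4, n_points = 960L) {
  a <- pair$partner_a; b <- pair$partner_b
  asa_a <- solvent_accessible_area(a, probe, n_points)
  asa_b <- solvent_accessible_area(b, probe, n_points)
  both <- rbind(a, b)
  asa_ab <- solvent_accessible_area(both, probe, n_points)
  loss_a <- asa_a - asa_ab[seq_len(nrow(a))]
  loss_b <- asa_b - asa_ab[nrow(a) + seq_len(nrow(b))]
  list(total = sum(loss_a) + sum(loss_b), a = sum(loss_a), b = sum(loss_b),
       per_atom_a = loss_a, per_atom_b = loss_b)
}

# Debye-screened cross-partner Coulomb energy: the bundled surrogate for the
# Poisson-Boltzmann slots (dielectric 80, kappa for 150 mM ionic strength,
# Debye length ~7.9 A at 298 K)
screened_coulomb_energy <- function(pair, dielectric = 80, kappa = 0.127,
                                    charges_a = NULL, charges_b = NULL,
                                    clash_floor = 0.5) {
  a <- pair$partner_a; b <- pair$partner_b
  qa <- charges_a %||% assign_default_charges(a)
  qb <- charges_b %||% assign_default_charges(b)
  r <- cross_distances(a, b)
  r[r < clash_floor] <- clash_floor
  screened <- COULOMB_K * outer(qa, qb) * exp(-kappa * r) / (dielectric * r)
  unscreened <- COULOMB_K * outer(qa, qb) / (dielectric * r)
  list(binding = sum(screened), solvation = sum(screened - unscreened))
}

#' Names of the 74 auxiliary slots
#' @return Character vector of length 74, the per-partner schema.
#' @export
auxiliary_schema <- function() {
  c(paste0("count_", AA3),
    paste0("asa_", AA3),
    paste0("asa_", c("total", "C", "N", "O", "S")),
    paste0("bsa_", c("total", "C", "N", "O", "S")),
    c("charge_net", "charge_pos", "charge_neg", "charge_mean_abs"),
    paste0("coulomb_", c("C", "N", "O", "S")),
    paste0("lj_", c("C", "N", "O", "S")),
    c("pb_binding", "pb_solvation"),
    c("n_interface_atoms", "n_surface_atoms"),
    c("asa_hydrophobic", "asa_hydrophilic"),
    paste0("crossdist_", c("min", "mean", "max")),
    c("n_salt_bridges", "n_hbond_donors", "n_hbond_acceptors"))
}

#' Assemble the 74-slot auxiliary physicochemical block for one partner
#'
#' Fills the fixed per-partner schema (see [auxiliary_schema()]): interface
#' residue-type counts, per-residue-type and per-element accessible surface
#' area, buried surface area, charge statistics, cross-partner Coulomb and
#' Lennard-Jones energies decomposed by the focal partner's elements, two
#' electrostatics slots (precomputed Poisson-Boltzmann values if supplied,
#' otherwise the bundled Debye-screened Coulomb surrogate), atom counts,
#' hydrophobic/hydrophilic area split, cross-distance statistics, and
#' contact counts (salt bridges, hydrogen-bond donors/acceptors by simple
#' geometric criteria). A slot whose subroutine fails is filled with 0 and
#' recorded in the `audit` attribute -- never silently absent.
#'
#' @param pair a `plaff_partner_pair`.
#' @param partner `"A"` or `"B"`.
#' @param pb_values optional `list(binding=, solvation=)` of precomputed
#'   Poisson-Boltzmann energies (kcal/mol).
#' @param region optional precomputed `plaff_interface`; extracted at
#'   `cutoff_r` otherwise.
#' @param cutoff_r interface cutoff used when `region` is missing.
#' @param n_points sphere-sampling resolution for the area slots.
#' @param charges optional per-atom charge list `list(a=, b=)`.
#' @return Object of class `plaff_aux_block`: numeric `values` of length
#'   74 named by the schema, `partner`, and an `audit` character vector of
#'   zero-filled slots.
#' @export
assemble_auxiliary_block <- function(pair, partner = c("A", "B"),
                                     pb_values = NULL, region = NULL,
                                     cutoff_r = 10.0, n_points = 240L,
                                     charges = NULL) {
  partner <- match.arg(partner)
  if (is.null(region)) region <- extract_interface(pair, cutoff_r)
  schema <- auxiliary_schema()
  v <- stats::setNames(numeric(length(schema)), schema)
  audit <- character(0)
  fill <- function(vals, slot_names) {
    v[slot_names] <<- vals
  }
  try_fill <- function(expr, slots) {
    res <- tryCatch(expr, error = function(e) {
      audit <<- c(audit, paste0(paste(slots, collapse = ","), ": ",
                                conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) fill(res, slots)
  }

  mine <- if (partner == "A") region$atoms_a else region$atoms_b
  other <- if (partner == "A") region$atoms_b else region$atoms_a
  full_mine <- if (partner == "A") pair$partner_a else pair$partner_b

  # residue composition over interface residues of this partner
  try_fill({
    res_keys <- paste(mine$chain, mine$resno, mine$icode, mine$resname,
                      sep = ":")
    rn <- mine$resname[!duplicated(res_keys)]
    as.numeric(table(factor(rn, levels = AA3)))
  }, paste0("count_", AA3))

  asa_mine <- tryCatch(solvent_accessible_area(mine, n_points = n_points),
                       error = function(e) { audit <<- c(audit, "asa"); NULL })
  if (!is.null(asa_mine)) {
    fill(vapply(AA3, function(r) sum(asa_mine[mine$resname == r]), 0),
         paste0("asa_", AA3))
    fill(c(sum(asa_mine),
           vapply(c("C", "N", "O", "S"),
                  function(e) sum(asa_mine[mine$element == e]), 0)),
         paste0("asa_", c("total", "C", "N", "O", "S")))
    fill(c(sum(asa_mine[mine$element %in% c("C", "S")]),
           sum(asa_mine[!mine$element %in% c("C", "S")])),
         c("asa_hydrophobic", "asa_hydrophilic"))
    fill(c(nrow(mine), sum(asa_mine > 0.1)),
         c("n_interface_atoms", "n_surface_atoms"))
  }

  # buried area of this partner's interface atoms
  try_fill({
    asa_complex <- solvent_accessible_area(rbind(mine, other),
                                           n_points = n_points)
    loss <- asa_mine - asa_complex[seq_len(nrow(mine))]
    c(sum(loss),
      vapply(c("C", "N", "O", "S"),
             function(e) sum(loss[mine$element == e]), 0))
  }, paste0("bsa_", c("total", "C", "N", "O", "S")))

  q_mine <- if (!is.null(charges)) {
    if (partner == "A") charges$a else charges$b
  } else assign_default_charges(mine)
  q_other <- if (!is.null(charges)) {
    if (partner == "A") charges$b else charges$a
  } else assign_default_charges(other)
  try_fill(c(sum(q_mine), sum(q_mine[q_mine > 0]), sum(q_mine[q_mine < 0]),
             mean(abs(q_mine))),
           c("charge_net", "charge_pos", "charge_neg", "charge_mean_abs"))

  iface_pair <- structure(list(partner_a = mine, partner_b = other),
                          class = "plaff_partner_pair")
  # the interface sub-pair is oriented mine->other, so the focal side is "A"
  try_fill({
    e <- suppressWarnings(pairwise_interaction_energy(
      iface_pair, "coulomb",
      params = list(charges_a = q_mine, charges_b = q_other), focal = "A"))
    e$by_element[c("C", "N", "O", "S")]
  }, paste0("coulomb_", c("C", "N", "O", "S")))
  try_fill({
    e <- suppressWarnings(pairwise_interaction_energy(iface_pair,
                                                      "lennard_jones",
                                                      focal = "A"))
    e$by_element[c("C", "N", "O", "S")]
  }, paste0("lj_", c("C", "N", "O", "S")))

  if (!is.null(pb_values)) {
    fill(c(pb_values$binding, pb_values$solvation),
         c("pb_binding", "pb_solvation"))
  } else {
    try_fill({
      pb <- screened_coulomb_energy(iface_pair, charges_a = q_mine,
                                    charges_b = q_other)
      c(pb$binding, pb$solvation)
    }, c("pb_binding", "pb_solvation"))
  }

  try_fill({
    d <- cross_distances(mine, other)
    c(min(d), mean(d), max(d))
  }, paste0("crossdist_", c("min", "mean", "max")))

  try_fill({
    d <- cross_distances(mine, other)
    sb <- sum(outer(q_mine, q_other) < -0.2 & d <= 4.0)
    don <- sum(mine$element == "N" &
                 apply(d[, other$element %in% c("N", "O"), drop = FALSE], 1L,
                       function(z) any(z <= 3.5)))
    acc <- sum(mine$element == "O" &
                 apply(d[, other$element %in% c("N", "O"), drop = FALSE], 1L,
                       function(z) any(z <= 3.5)))
    c(sb, don, acc)
  }, c("n_salt_bridges", "n_hbond_donors", "n_hbond_acceptors"))

  structure(list(values = v, partner = partner, audit = audit,
                 schema_version = "v1"),
            class = "plaff_aux_block")
}

#' @export
print.plaff_aux_block <- function(x, ...) {
  cat("Auxiliary block, partner ", x$partner, ": ", length(x$values),
      " slots", if (length(x$audit)) paste0(" (", length(x$audit),
                                            " zero-filled, see $audit)"),
      "\n", sep = "")
  invisible(x)
}
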