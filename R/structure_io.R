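# Structure input: PDB parsing, partner assignment, interface extraction.

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Parse a PDB-format structure into an atom table
#'
#' Reads `ATOM`/`HETATM` records from PDB text and returns one row per atom.
#' Multi-model (NMR-style) files are handled through `model_index`; alternate
#' locations are resolved to the conformer with the highest occupancy (ties
#' keep the first in file order); water molecules are dropped unless
#' `keep_waters = TRUE`.
#'
#' @param pdb_text character; either a single string containing the PDB file
#'   or a character vector of lines.
#' @param model_index which `MODEL` block to read (1-based). Files without
#'   `MODEL` records are treated as a single model.
#' @param keep_waters keep water residues (`HOH`/`WAT`/`DOD`)? Default drops
#'   them.
#' @return A `data.frame` with one row per atom: `serial`, `name`, `altloc`,
#'   `element`, `resname`, `chain`, `resno`, `icode`, `x`, `y`, `z`,
#'   `occupancy`, `is_hetero`, `line` (source line number).
#' @examples
#' txt <- paste(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
#'   sep = "\n")
#' parse_structure(txt)
#' @export
parse_structure <- function(pdb_text, model_index = 1L, keep_waters = FALSE) {
  stopifnot(is.character(pdb_text), length(pdb_text) >= 1L)
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE)) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1L]]
  } else pdb_text

  rec <- substr(lines, 1L, 6L)
  model_of <- integer(length(lines))
  cur <- 0L
  seen_model <- FALSE
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      cur <- cur + 1L
      seen_model <- TRUE
    }
    model_of[i] <- max(cur, 1L)
  }
  n_models <- max(model_of)
  if (!seen_model) n_models <- 1L
  if (model_index < 1L || model_index > n_models) {
    stop("model_index ", model_index, " out of range: structure has ",
         n_models, " model(s)")
  }

  is_atom <- (rec == "ATOM  " | rec == "HETATM") & model_of == model_index
  idx <- which(is_atom)
  if (length(idx) == 0L) stop("empty structure: no ATOM/HETATM records in model ",
                              model_index)
  al <- lines[idx]
  # pad short lines so fixed-column extraction is safe
  al <- formatC(al, width = max(80L, max(nchar(al))), flag = "-")

  num_field <- function(txt, what, lineno) {
    v <- suppressWarnings(as.numeric(trimws(txt)))
    bad <- which(is.na(v) & nzchar(trimws(txt)))
    bad2 <- which(!nzchar(trimws(txt)))
    bad <- sort(c(bad, bad2))
    if (length(bad)) {
      stop("malformed ", what, " field at line ", lineno[bad[1L]],
           ": '", trimws(txt[bad[1L]]), "'")
    }
    v
  }

  x <- num_field(substr(al, 31L, 38L), "x coordinate", idx)
  y <- num_field(substr(al, 39L, 46L), "y coordinate", idx)
  z <- num_field(substr(al, 47L, 54L), "z coordinate", idx)
  occ_txt <- trimws(substr(al, 55L, 60L))
  occ <- suppressWarnings(as.numeric(occ_txt))
  occ[is.na(occ)] <- 1.0

  name <- trimws(substr(al, 13L, 16L))
  element <- trimws(substr(al, 77L, 78L))
  # element-field/atom-name reconciliation: fall back to the name when the
  # element columns are blank or unparseable
  fallback <- .element_from_name(substr(al, 13L, 16L))
  blank <- !grepl("^[A-Za-z]{1,2}$", element)
  element[blank] <- fallback[blank]
  element <- .normalize_element(element)

  atoms <- data.frame(
    serial    = suppressWarnings(as.integer(trimws(substr(al, 7L, 11L)))),
    name      = name,
    altloc    = substr(al, 17L, 17L),
    element   = element,
    resname   = trimws(substr(al, 18L, 20L)),
    chain     = substr(al, 22L, 22L),
    resno     = suppressWarnings(as.integer(trimws(substr(al, 23L, 26L)))),
    icode     = substr(al, 27L, 27L),
    x = x, y = y, z = z,
    occupancy = occ,
    is_hetero = rec[idx] == "HETATM",
    line      = idx,
    stringsAsFactors = FALSE
  )
  if (!keep_waters) atoms <- atoms[!(atoms$resname %in% WATER_RESIDUES), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("empty structure after water removal")

  atoms <- .resolve_altloc(atoms)
  rownames(atoms) <- NULL
  atoms
}

# highest-occupancy altloc wins; ties resolved by file order
.resolve_altloc <- function(atoms) {
  has_alt <- atoms$altloc != " " & atoms$altloc != ""
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt])) {
    rows <- which(key == k)
    if (length(rows) < 2L) next
    best <- rows[which.max(atoms$occupancy[rows])]  # which.max: first of ties
    keep[setdiff(rows, best)] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

.element_from_name <- function(name4) {
  # columns 13-14 hold the element for two-letter symbols (e.g. "FE", "ZN");
  # a blank column 13 means a one-letter element in column 14
  two <- trimws(substr(name4, 1L, 2L))
  out <- character(length(name4))
  is_two <- grepl("^[A-Za-z]{2}$", two) &
    toupper(two) %in% c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "CA",
                        "BR", "SE", "NI", "CO", "CD", "HG")
  out[is_two] <- two[is_two]
  rest <- !is_two
  stripped <- gsub("[^A-Za-z]", "", trimws(name4[rest]))
  out[rest] <- substr(stripped, 1L, 1L)
  out
}

.normalize_element <- function(el) {
  el <- toupper(trimws(el))
  n2 <- nchar(el) == 2L
  el[n2] <- paste0(substr(el[n2], 1L, 1L), tolower(substr(el[n2], 2L, 2L)))
  el
}

.xyz <- function(atoms) cbind(atoms$x, atoms$y, atoms$z)

# all-pairs Euclidean cross distances (rows of a vs rows of b)
cross_distances <- function(xa, xb) {
  if (is.data.frame(xa)) xa <- .xyz(xa)
  if (is.data.frame(xb)) xb <- .xyz(xb)
  xa <- rbind(xa); xb <- rbind(xb)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Assign binding partners A and B
#'
#' Splits the chains of a parsed complex into two binding partners. Chains
#' with no atom within the contact threshold of the opposite partner are
#' dropped as nonbinding; when the remaining chains form several disjoint
#' interfaces, the primary (most inclusive) one -- the chain-contact-graph
#' component with the most cross-partner atom pairs within the threshold --
#' is retained. Ties go to the component with more atoms, then to
#' lexicographic chain order.
#'
#' @param atoms atom table from [parse_structure()].
#' @param spec `list(A = <chain ids>, B = <chain ids>)`, or `NULL` to assign
#'   automatically (only possible for exactly two chains).
#' @param cutoff_r contact threshold in Angstrom used both for the
#'   nonbinding-chain test and for ranking disjoint interfaces.
#' @param source_id identifier carried on the result.
#' @return An object of class `plaff_partner_pair`: a list with `partner_a`,
#'   `partner_b` (atom tables), `chain_map`, `source_id`, `cutoff_r`.
#' @export
assign_partners <- function(atoms, spec = NULL, cutoff_r = 10.0,
                            source_id = "complex") {
  chains <- unique(atoms$chain)
  if (is.null(spec)) {
    if (length(chains) != 2L) {
      stop("automatic partner assignment needs exactly two chains; found ",
           length(chains), " -- provide spec = list(A = ..., B = ...)")
    }
    spec <- list(A = chains[1L], B = chains[2L])
  }
  stopifnot(is.list(spec), !is.null(spec$A), !is.null(spec$B))
  unknown <- setdiff(c(spec$A, spec$B), chains)
  if (length(unknown)) {
    stop("unknown chain id(s) in partner spec: ", paste(unknown, collapse = ", "))
  }
  if (length(intersect(spec$A, spec$B))) stop("partner chain sets overlap")

  a_atoms <- atoms[atoms$chain %in% spec$A, , drop = FALSE]
  b_atoms <- atoms[atoms$chain %in% spec$B, , drop = FALSE]
  if (nrow(a_atoms) == 0L || nrow(b_atoms) == 0L) stop("a partner has no atoms")

  # chain-level cross-contact pair counts within cutoff_r
  pairs_ab <- matrix(0, length(spec$A), length(spec$B),
                     dimnames = list(spec$A, spec$B))
  for (ca in spec$A) {
    xa <- a_atoms[a_atoms$chain == ca, , drop = FALSE]
    for (cb in spec$B) {
      xb <- b_atoms[b_atoms$chain == cb, , drop = FALSE]
      pairs_ab[ca, cb] <- sum(cross_distances(xa, xb) <= cutoff_r)
    }
  }

  # nonbinding chains are ignored
  keep_a <- rownames(pairs_ab)[rowSums(pairs_ab) > 0]
  keep_b <- colnames(pairs_ab)[colSums(pairs_ab) > 0]
  if (length(keep_a) == 0L || length(keep_b) == 0L) {
    stop("no interface: all chains are nonbinding at cutoff_r = ", cutoff_r)
  }
  pairs_ab <- pairs_ab[keep_a, keep_b, drop = FALSE]

  # connected components of the chain contact graph; keep the primary one
  comp <- .contact_components(pairs_ab)
  if (length(comp) > 1L) {
    score <- vapply(comp, function(cp) sum(pairs_ab[cp$A, cp$B, drop = FALSE]),
                    numeric(1))
    natoms <- vapply(comp, function(cp) {
      sum(atoms$chain %in% c(cp$A, cp$B))
    }, numeric(1))
    lex <- vapply(comp, function(cp) paste(sort(c(cp$A, cp$B)), collapse = ""),
                  character(1))
    ord <- order(-score, -natoms, lex)
    comp <- comp[ord]
  }
  prim <- comp[[1L]]

  structure(list(
    partner_a = atoms[atoms$chain %in% prim$A, , drop = FALSE],
    partner_b = atoms[atoms$chain %in% prim$B, , drop = FALSE],
    chain_map = list(A = prim$A, B = prim$B),
    source_id = source_id,
    cutoff_r  = cutoff_r
  ), class = "plaff_partner_pair")
}

.contact_components <- function(pairs_ab) {
  an <- rownames(pairs_ab); bn <- colnames(pairs_ab)
  nodes <- c(paste0("A:", an), paste0("B:", bn))
  parent <- seq_along(nodes); names(parent) <- nodes
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(an)) for (j in seq_along(bn)) {
    if (pairs_ab[i, j] > 0) {
      ri <- find(i); rj <- find(length(an) + j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  lapply(unique(roots), function(r) {
    members <- nodes[roots == r]
    list(A = sub("^A:", "", members[startsWith(members, "A:")]),
         B = sub("^B:", "", members[startsWith(members, "B:")]))
  })
}

#' @export
print.plaff_partner_pair <- function(x, ...) {
  cat("Partner pair <", x$source_id, ">\n", sep = "")
  cat("  A: chains", paste(x$chain_map$A, collapse = ","),
      "-", nrow(x$partner_a), "atoms\n")
  cat("  B: chains", paste(x$chain_map$B, collapse = ","),
      "-", nrow(x$partner_b), "atoms\n")
  invisible(x)
}

#' Extract the binding interface region
#'
#' Retains every atom of partner A within `cutoff_r` Angstrom of some atom of
#' partner B, and symmetrically, and groups the retained atoms by element
#' (over `element_list`) and by residue. Hydrogens are excluded by default:
#' crystal structures typically lack them and the topological features are
#' defined on heavy atoms.
#'
#' @param pair a `plaff_partner_pair`.
#' @param cutoff_r interface cutoff in Angstrom (> 0).
#' @param element_list elements that receive element-specific groupings.
#' @param include_hydrogens retain H atoms in the region?
#' @return An object of class `plaff_interface`: `atoms_a`, `atoms_b`,
#'   `cutoff_r`, and `groupings$element` / `groupings$residue`, each a list
#'   with per-side index lists into `atoms_a`/`atoms_b`.
#' @export
extract_interface <- function(pair, cutoff_r = 10.0,
                              element_list = c("C", "N", "O", "S"),
                              include_hydrogens = FALSE) {
  stopifnot(inherits(pair, "plaff_partner_pair"), cutoff_r > 0)
  a <- pair$partner_a; b <- pair$partner_b
  if (!include_hydrogens) {
    a <- a[a$element != "H", , drop = FALSE]
    b <- b[b$element != "H", , drop = FALSE]
  }
  if (nrow(a) == 0L || nrow(b) == 0L) {
    warning("empty interface: a partner has no (heavy) atoms")
    return(.empty_interface(cutoff_r))
  }
  d <- cross_distances(a, b)
  keep_a <- apply(d, 1L, min) <= cutoff_r
  keep_b <- apply(d, 2L, min) <= cutoff_r
  if (!any(keep_a) || !any(keep_b)) {
    warning("empty interface at cutoff_r = ", cutoff_r)
    return(.empty_interface(cutoff_r))
  }
  atoms_a <- a[keep_a, , drop = FALSE]; rownames(atoms_a) <- NULL
  atoms_b <- b[keep_b, , drop = FALSE]; rownames(atoms_b) <- NULL

  group_side <- function(atoms) {
    el <- lapply(stats::setNames(element_list, element_list),
                 function(e) which(atoms$element == e))
    rk <- paste(atoms$chain, atoms$resno, trimws(atoms$icode), atoms$resname,
                sep = ":")
    rs <- split(seq_len(nrow(atoms)), rk)
    list(element = el, residue = rs)
  }
  ga <- group_side(atoms_a); gb <- group_side(atoms_b)

  structure(list(
    atoms_a = atoms_a, atoms_b = atoms_b, cutoff_r = cutoff_r,
    element_list = element_list,
    groupings = list(
      element = list(A = ga$element, B = gb$element),
      residue = list(A = ga$residue, B = gb$residue)
    )
  ), class = "plaff_interface")
}

.empty_interface <- function(cutoff_r) {
  empty <- data.frame(serial = integer(), name = character(),
                      altloc = character(), element = character(),
                      resname = character(), chain = character(),
                      resno = integer(), icode = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      occupancy = numeric(), is_hetero = logical(),
                      line = integer(), stringsAsFactors = FALSE)
  structure(list(atoms_a = empty, atoms_b = empty, cutoff_r = cutoff_r,
                 element_list = character(),
                 groupings = list(element = list(A = list(), B = list()),
                                  residue = list(A = list(), B = list()))),
            class = "plaff_interface")
}

#' @export
print.plaff_interface <- function(x, ...) {
  cat("Interface region (cutoff ", x$cutoff_r, " A): ",
      nrow(x$atoms_a), " A-side / ", nrow(x$atoms_b), " B-side atoms\n",
      sep = "")
  invisible(x)
}
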