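test_that("PDB parsing echoes coordinates, elements and hetero flags", {
  txt <- paste(
    "ATOM      1  N   ALA A   1       0.000   1.500  -2.250  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "HETATM    3 ZN    ZN B  90       3.000   3.000   3.000  1.00  0.00          ZN",
    sep = "\n")
  atoms <- parse_structure(txt)
  expect_equal(nrow(atoms), 3L)
  expect_equal(atoms$x, c(0, 1.458, 3))
  expect_equal(atoms$y[1], 1.5)
  expect_equal(atoms$z[1], -2.25)
  expect_equal(atoms$element, c("N", "C", "Zn"))
  expect_equal(atoms$is_hetero, c(FALSE, FALSE, TRUE))
  expect_equal(atoms$chain, c("A", "A", "B"))
})

test_that("altloc resolves to highest occupancy, first on ties", {
  txt <- paste(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CB AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    sep = "\n")
  atoms <- parse_structure(txt)
  expect_equal(nrow(atoms), 2L)
  expect_equal(atoms$x[atoms$name == "CA"], 0)    # occupancy 0.6 wins
  expect_equal(atoms$x[atoms$name == "CB"], 1)    # tie: first in file
})

test_that("model selection, water removal and error reporting behave", {
  txt <- paste(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       9.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    sep = "\n")
  expect_equal(parse_structure(txt, model_index = 1)$x, 0)
  expect_equal(parse_structure(txt, model_index = 2)$x, 9)
  expect_error(parse_structure(txt, model_index = 3), "out of range")

  wat <- paste(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A 100       1.000   0.000   0.000  1.00  0.00           O",
    sep = "\n")
  expect_equal(nrow(parse_structure(wat)), 1L)
  expect_equal(nrow(parse_structure(wat, keep_waters = TRUE)), 2L)

  bad <- "ATOM      1  CA  GLY A   1       x.xxx   0.000   0.000  1.00  0.00           C"
  expect_error(parse_structure(bad), "line 1")
})

test_that("fixture complexes parse back to the generator's manifest counts", {
  for (tpl in c("two-atom", "bipartite-lattice", "ring-motif", "two-helix")) {
    fx <- generate_fixture_complex(tpl)
    atoms <- parse_structure(fx$pdb)
    expect_equal(nrow(atoms), fx$manifest$n_atoms, info = tpl)
    expect_equal(sum(atoms$chain == "A"), fx$manifest$n_atoms_a, info = tpl)
  }
})

test_that("partner assignment drops nonbinding chains and flags unknown ids", {
  fx <- generate_fixture_complex("two-helix")
  atoms <- parse_structure(fx$pdb)
  pair <- assign_partners(atoms, list(A = "A", B = "B"))
  expect_s3_class(pair, "plaff_partner_pair")
  expect_equal(nrow(pair$partner_a), fx$manifest$n_atoms_a)
  expect_error(assign_partners(atoms, list(A = "A", B = "Z")),
               "unknown chain")

  # a far-away chain C in partner A is nonbinding and dropped
  farc <- atoms[atoms$chain == "A", ]
  farc$chain <- "C"
  farc$x <- farc$x + 500
  all3 <- rbind(atoms, farc)
  pair2 <- assign_partners(all3, list(A = c("A", "C"), B = "B"))
  expect_equal(pair2$chain_map$A, "A")
  # every chain nonbinding -> no interface
  solo <- rbind(atoms[atoms$chain == "A", ], farc)
  expect_error(assign_partners(solo, list(A = "A", B = "C")), "no interface")
})

test_that("primary interface keeps the component with most contact pairs", {
  # two disjoint interfaces: A-B tight 3x3 block; C-D tiny 1-atom contact
  mk <- function(chain, base, n) {
    data.frame(serial = 1:n, name = "CA", altloc = " ", element = "C",
               resname = "GLY", chain = chain, resno = 1:n, icode = " ",
               x = base[1] + seq_len(n), y = base[2], z = base[3],
               occupancy = 1, is_hetero = FALSE, line = 1:n,
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(mk("A", c(0, 0, 0), 5), mk("B", c(0, 3, 0), 5),
                 mk("C", c(500, 0, 0), 1), mk("D", c(500, 3, 0), 1))
  pair <- assign_partners(atoms, list(A = c("A", "C"), B = c("B", "D")),
                          cutoff_r = 6)
  expect_equal(pair$chain_map$A, "A")
  expect_equal(pair$chain_map$B, "B")
  # brute-force check that A-B really has the most cross pairs
  d_ab <- plaff:::cross_distances(atoms[atoms$chain == "A", ],
                                  atoms[atoms$chain == "B", ])
  d_cd <- plaff:::cross_distances(atoms[atoms$chain == "C", ],
                                  atoms[atoms$chain == "D", ])
  expect_gt(sum(d_ab <= 6), sum(d_cd <= 6))
})

test_that("interface extraction matches a brute-force scan and is monotone", {
  fx <- generate_fixture_complex("two-helix")
  atoms <- parse_structure(fx$pdb)
  pair <- assign_partners(atoms, list(A = "A", B = "B"))
  a <- pair$partner_a; b <- pair$partner_b
  d <- plaff:::cross_distances(a, b)
  prev_a <- 0L
  for (cutoff in c(4, 6, 8, 10)) {
    region <- extract_interface(pair, cutoff)
    expect_equal(nrow(region$atoms_a), sum(apply(d, 1, min) <= cutoff))
    expect_equal(nrow(region$atoms_b), sum(apply(d, 2, min) <= cutoff))
    expect_gte(nrow(region$atoms_a), prev_a)   # monotone in cutoff
    prev_a <- nrow(region$atoms_a)
  }
})

test_that("interface extraction is symmetric under partner swap", {
  fx <- generate_fixture_complex("two-helix")
  atoms <- parse_structure(fx$pdb)
  p1 <- assign_partners(atoms, list(A = "A", B = "B"))
  p2 <- assign_partners(atoms, list(A = "B", B = "A"))
  r1 <- extract_interface(p1, 8)
  r2 <- extract_interface(p2, 8)
  expect_equal(r1$atoms_a$serial, r2$atoms_b$serial)
  expect_equal(r1$atoms_b$serial, r2$atoms_a$serial)
  d1 <- sort(plaff:::cross_distances(r1$atoms_a, r1$atoms_b))
  d2 <- sort(plaff:::cross_distances(r2$atoms_a, r2$atoms_b))
  expect_equal(d1, d2)
})

test_that("element groupings cover exactly the listed elements", {
  fx <- generate_fixture_complex("two-helix")
  pair <- assign_partners(parse_structure(fx$pdb), list(A = "A", B = "B"))
  region <- extract_interface(pair, 10, element_list = c("C", "N", "O", "S"))
  for (side in c("A", "B")) {
    atoms <- if (side == "A") region$atoms_a else region$atoms_b
    idx <- sort(unname(unlist(region$groupings$element[[side]])))
    expect_equal(idx, which(atoms$element %in% c("C", "N", "O", "S")))
    # residue groupings partition all retained atoms
    ridx <- sort(unname(unlist(region$groupings$residue[[side]])))
    expect_equal(ridx, seq_len(nrow(atoms)))
  }
})

test_that("tiny cutoffs give an empty interface with a warning", {
  pair <- assign_partners(parse_structure(two_atom_pdb(5)),
                          list(A = "A", B = "B"))
  expect_warning(region <- extract_interface(pair, 4), "empty")
  expect_equal(nrow(region$atoms_a), 0L)
  region10 <- extract_interface(pair, 10)
  expect_equal(nrow(region10$atoms_a), 1L)
  expect_equal(nrow(region10$atoms_b), 1L)
})
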