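helix_pair <- function() {
  fx <- generate_fixture_complex("two-helix")
  assign_partners(parse_structure(fx$pdb), list(A = "A", B = "B"))
}

test_that("barcode filtering drops short bars and bins finite deaths", {
  bars <- data.frame(birth = c(0, 0, 0, 0.3),
                     death = c(1.2, 2.5, 2.7, 0.35))
  out <- filter_and_bin_barcodes(bars, lifespan_cutoff = 0.1,
                                 death_bins = c(0, 2, 3))
  expect_equal(out$bin_counts, c(1, 2))
  expect_equal(out$n_removed, 1L)           # the (0.3, 0.35) bar
  expect_equal(out$n_infinite, 0L)

  inf_bars <- data.frame(birth = c(0, 0), death = c(Inf, 0.05))
  out2 <- filter_and_bin_barcodes(inf_bars, 0.1, c(0, 5))
  expect_equal(out2$n_infinite, 1L)
  expect_equal(out2$bin_counts, 0)          # infinite bars never binned
})

test_that("random barcode sets histogram exactly like a brute-force count", {
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    b <- runif(n, 0, 2)
    d <- b + rexp(n, 1)
    bars <- data.frame(birth = b, death = d)
    edges <- sort(runif(4, 0, 6))
    out <- filter_and_bin_barcodes(bars, 0.2, edges)
    keep <- (d - b) >= 0.2
    manual <- vapply(seq_len(length(edges) - 1), function(k) {
      sum(keep & d > edges[k] & d <= edges[k + 1])
    }, numeric(1))
    expect_equal(out$bin_counts, manual)
  }
})

test_that("Coulomb energy reproduces the unit-charge constant", {
  mk <- function(chain, x) data.frame(
    serial = 1L, name = "X", altloc = " ", element = "C", resname = "GLY",
    chain = chain, resno = 1L, icode = " ", x = x, y = 0, z = 0,
    occupancy = 1, is_hetero = FALSE, line = 1L, stringsAsFactors = FALSE)
  pair <- structure(list(partner_a = mk("A", 0), partner_b = mk("B", 1)),
                    class = "plaff_partner_pair")
  e <- pairwise_interaction_energy(pair, "coulomb",
                                   params = list(charges_a = 1, charges_b = 1,
                                                 dielectric = 1))
  expect_equal(e$total, 332.0637, tolerance = 1e-7)
  # same-partner pairs contribute nothing: doubling an A atom far away
  pair2 <- structure(list(partner_a = rbind(mk("A", 0), mk("A", 100)),
                          partner_b = mk("B", 1)),
                     class = "plaff_partner_pair")
  e2 <- pairwise_interaction_energy(pair2, "coulomb",
                                    params = list(charges_a = c(1, 0),
                                                  charges_b = 1,
                                                  dielectric = 1))
  expect_equal(e2$total, e$total, tolerance = 1e-7)
})

test_that("Lennard-Jones has its analytic zero and minimum", {
  sig <- plaff:::LJ_SIGMA[["C"]]; eps <- plaff:::LJ_EPSILON[["C"]]
  mk <- function(chain, x) data.frame(
    serial = 1L, name = "X", altloc = " ", element = "C", resname = "GLY",
    chain = chain, resno = 1L, icode = " ", x = x, y = 0, z = 0,
    occupancy = 1, is_hetero = FALSE, line = 1L, stringsAsFactors = FALSE)
  at_r <- function(r) {
    pair <- structure(list(partner_a = mk("A", 0), partner_b = mk("B", r)),
                      class = "plaff_partner_pair")
    suppressWarnings(pairwise_interaction_energy(pair, "lennard_jones"))$total
  }
  expect_equal(at_r(sig), 0, tolerance = 1e-10)
  expect_equal(at_r(2^(1 / 6) * sig), -eps, tolerance = 1e-10)
  expect_warning(
    structure(list(partner_a = mk("A", 0), partner_b = mk("B", 0.1)),
              class = "plaff_partner_pair") |>
      pairwise_interaction_energy("lennard_jones"),
    "clash")
})

test_that("isolated-sphere ASA matches the analytic area", {
  atom <- data.frame(serial = 1L, name = "X", altloc = " ", element = "C",
                     resname = "GLY", chain = "A", resno = 1L, icode = " ",
                     x = 0, y = 0, z = 0, occupancy = 1, is_hetero = FALSE,
                     line = 1L, stringsAsFactors = FALSE)
  asa <- solvent_accessible_area(atom, probe = 1.4, n_points = 960)
  expect_equal(asa, 4 * pi * 3.1^2, tolerance = 1e-6)   # lattice is exact here
})

test_that("occlusion reduces area and convergence holds on a toy trimer", {
  mk <- function(x) data.frame(serial = 1L, name = "X", altloc = " ",
                               element = "C", resname = "GLY", chain = "A",
                               resno = 1L, icode = " ", x = x, y = 0, z = 0,
                               occupancy = 1, is_hetero = FALSE, line = 1L,
                               stringsAsFactors = FALSE)
  two <- rbind(mk(0), mk(0.01))   # nearly coincident spheres
  asa2 <- sum(solvent_accessible_area(two, n_points = 480))
  expect_lt(asa2, 2 * 4 * pi * 3.1^2 * 0.55)
  trimer <- rbind(mk(0), mk(2.2), mk(4.4))
  lo <- solvent_accessible_area(trimer, n_points = 960)
  hi <- solvent_accessible_area(trimer, n_points = 9600)
  expect_equal(sum(lo), sum(hi), tolerance = 0.02)   # within 2 percent
})

test_that("buried surface area is near zero for distant partners, else >= 0", {
  pair_far <- assign_partners(parse_structure(two_atom_pdb(100)),
                              list(A = "A", B = "B"), cutoff_r = 200)
  bsa <- buried_surface_area(pair_far, n_points = 480)
  expect_equal(bsa$total, 0, tolerance = 1e-9)
  bsa2 <- buried_surface_area(helix_pair(), n_points = 240)
  expect_gte(bsa2$total, -1e-6)
  expect_gt(bsa2$total, 10)    # helices at 9 A really bury surface
})

test_that("auxiliary block has 74 schema-named slots with consistent counts", {
  pair <- helix_pair()
  region <- extract_interface(pair, 10)
  blk <- assemble_auxiliary_block(pair, "A", region = region,
                                  n_points = 240)
  expect_length(blk$values, 74L)
  expect_equal(names(blk$values), auxiliary_schema())
  expect_length(blk$audit, 0L)
  # residue-composition slots sum to the interface residue count
  rk <- paste(region$atoms_a$chain, region$atoms_a$resno,
              region$atoms_a$icode, region$atoms_a$resname)
  expect_equal(sum(blk$values[paste0("count_", plaff:::AA3)]),
               length(unique(rk)))
  expect_equal(blk$values[["n_interface_atoms"]], nrow(region$atoms_a))
  # ASA/BSA slots are non-negative
  expect_true(all(blk$values[grep("^asa_|^bsa_", names(blk$values))] >= -1e-6))
})

test_that("uncharged toys zero the charge statistics", {
  pair <- helix_pair()
  blk <- assemble_auxiliary_block(pair, "A", n_points = 240,
                                  charges = list(
                                    a = numeric(sum(pair$partner_a$element != "H")),
                                    b = numeric(sum(pair$partner_b$element != "H"))))
  expect_equal(unname(blk$values[c("charge_net", "charge_pos", "charge_neg",
                                   "charge_mean_abs")]), rep(0, 4))
  expect_equal(unname(blk$values[paste0("coulomb_",
                                        c("C", "N", "O", "S"))]), rep(0, 4))
})

test_that("embedding block pools to 3840 with the stub embedder", {
  emb <- assemble_embedding_block(stub_embedder(), "ACDEF", "KLMNP")
  expect_length(emb$values, 3840L)
  expect_equal(unname(emb$values), rep(1, 3840))
})

test_that("chunked embedding equals unchunked for a residue-local embedder", {
  e <- stub_embedder(16, kind = "hash")
  seq_long <- paste(rep("ACDEFGHIKL", 30), collapse = "")  # 300 residues
  full <- e(seq_long)
  blk <- assemble_embedding_block(e, seq_long, "AC", max_len = 150)
  expect_equal(unname(blk$values[1:16]), unname(colMeans(full)),
               tolerance = 1e-12)
})

test_that("pooled segments equal brute-force means for random embeddings", {
  set.seed(73)
  w <- 8L
  tabA <- matrix(rnorm(5 * w), 5, w)
  tabB <- matrix(rnorm(3 * w), 3, w)
  embedder <- function(seq) if (nchar(seq) == 5) tabA else tabB
  blk <- assemble_embedding_block(embedder, "AAAAA", "CCC")
  expect_equal(unname(blk$values),
               unname(c(colMeans(tabA), colMeans(tabB),
                        colMeans(rbind(tabA, tabB)))), tolerance = 1e-12)
})

test_that("embedder failure propagates instead of silently zeroing", {
  boom <- function(seq) stop("embedder offline")
  expect_error(assemble_embedding_block(boom, "ACD", "KLM"), "offline")
})

test_that("the manifest covers the vector contiguously and masks line up", {
  pair <- helix_pair()
  fv <- complex_features(pair, bins = c(4, 6, 8),
                         embedder = stub_embedder(32), label = -8.5)
  m <- fv$manifest
  expect_equal(m$start[1], 1L)
  expect_equal(m$end[nrow(m)], length(fv$values))
  expect_true(all(m$start[-1] == head(m$end, -1) + 1))   # no gaps
  expect_length(feature_mask(fv, "auxiliary"), 148L)
  expect_length(feature_mask(fv, "esm"), 3 * 32L)
  expect_setequal(feature_mask(fv, "all"), seq_along(fv$values))
  expect_equal(fv$label, -8.5)
})

test_that("feature vectors are invariant to rigid motion of the complex", {
  fx <- generate_fixture_complex("two-helix")
  atoms <- parse_structure(fx$pdb)
  build_fv <- function(a) {
    pair <- assign_partners(a, list(A = "A", B = "B"))
    region <- extract_interface(pair, 10)
    aux <- assemble_auxiliary_block(pair, "A", region = region,
                                    n_points = 240)$values
    list(exact = c(topological_feature_block(region,
                                             death_bins = c(2, 6, 10),
                                             max_filtration = 10)$values,
                   binned_spectral_features(region, bins = c(4, 8))$values,
                   aux[grep("coulomb|lj_|charge|count_|crossdist|n_",
                            names(aux))]),
         sampled = aux[grep("^asa|^bsa", names(aux))])
  }
  v0 <- build_fv(atoms)
  # rotate 40 degrees about z and translate
  th <- 40 * pi / 180
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% rot
  atoms2 <- atoms
  atoms2$x <- xyz[, 1] + 11.3; atoms2$y <- xyz[, 2] - 4.2
  atoms2$z <- xyz[, 3] + 0.7
  v1 <- build_fv(atoms2)
  # distance-based blocks are rigid-motion invariant to numerical precision
  expect_equal(v0$exact, v1$exact, tolerance = 1e-6)
  # sphere-sampled area slots vary only at the lattice resolution
  expect_equal(v0$sampled, v1$sampled, tolerance = 0.02)
})

test_that("swapping partner labels swaps the per-partner blocks", {
  fx <- generate_fixture_complex("two-helix")
  atoms <- parse_structure(fx$pdb)
  p_ab <- assign_partners(atoms, list(A = "A", B = "B"))
  p_ba <- assign_partners(atoms, list(A = "B", B = "A"))
  aux_a1 <- assemble_auxiliary_block(p_ab, "A", n_points = 240)
  aux_b2 <- assemble_auxiliary_block(p_ba, "B", n_points = 240)
  expect_equal(aux_a1$values, aux_b2$values, tolerance = 1e-9)
  e <- stub_embedder(8, "hash")
  emb1 <- assemble_embedding_block(e, chain_sequence(p_ab$partner_a),
                                   chain_sequence(p_ab$partner_b))
  emb2 <- assemble_embedding_block(e, chain_sequence(p_ba$partner_a),
                                   chain_sequence(p_ba$partner_b))
  expect_equal(unname(emb1$values[1:8]), unname(emb2$values[9:16]))
  expect_equal(unname(emb1$values[17:24]), unname(emb2$values[17:24]))
})

test_that("feature blocks write as TSV with a manifest sidecar", {
  pair <- helix_pair()
  region <- extract_interface(pair, 10)
  blk <- binned_spectral_features(region, bins = c(4, 8))
  path <- tempfile(fileext = ".tsv")
  write_feature_block(blk, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), length(blk$values))
  expect_true(file.exists(paste0(path, ".manifest.json")))
})
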