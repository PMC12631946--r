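test_that("affinity conversion follows RT ln K and passes dG through", {
  expect_equal(affinity_to_dg(1, "Kd", "M"), 0)
  expect_equal(affinity_to_dg(1, "Kd", "nM"),
               1.98720425e-3 * 298.15 * log(1e-9), tolerance = 1e-12)
  expect_equal(affinity_to_dg(1, "Kd", "nM"), -12.28, tolerance = 1e-2)
  expect_equal(affinity_to_dg(-7.5, "dG", "kcal/mol"), -7.5)
  expect_equal(affinity_to_dg(-31.38, "dG", "kJ/mol"), -31.38 / 4.184)
  expect_equal(affinity_to_dg(5, "Ki", "uM"),
               affinity_to_dg(5, "Kd", "uM"))       # Ki treated as Kd
  expect_error(affinity_to_dg(-1, "Kd", "M"), "positive")
  expect_error(affinity_to_dg(1, "Kd", "parsec"), "unknown")
})

toy_records <- function() {
  data.frame(
    structure_id = c("1abc", "1abc", "2xyz", "3pqr", "3pqr", "4bad"),
    affinity_value = c(1, 100, 5, -8, -9, 2),
    affinity_type = c("Kd", "Kd", "IC50", "dG", "dG", "Kd"),
    unit = c("nM", "nM", "nM", "kcal/mol", "kcal/mol", "uM"),
    is_mutant = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    parent_id = c("1abc", "1abc", "2xyz", "3pqr", "3pqr", "missing"),
    mutation = c("", "", "", "", "", "A:L45A"),
    stringsAsFactors = FALSE)
}

test_that("curation drops bad types and orphans, averages replicates on dG", {
  out <- curate_records(toy_records())
  expect_equal(sort(unique(out$kept$structure_id)), c("1abc", "3pqr"))
  expect_equal(nrow(out$kept), 2L)
  expect_true("dropped_type" %in% out$audit$code)
  expect_true("dropped_orphan_mutant" %in% out$audit$code)
  dg1 <- affinity_to_dg(1, "Kd", "nM"); dg2 <- affinity_to_dg(100, "Kd", "nM")
  expect_equal(out$kept$dg[out$kept$structure_id == "1abc"],
               mean(c(dg1, dg2)))
  expect_equal(out$kept$dg[out$kept$structure_id == "3pqr"], -8.5)
})

test_that("curation is idempotent", {
  once <- curate_records(toy_records())$kept
  twice <- curate_records(once)$kept
  expect_equal(twice$dg, once$dg)
  expect_equal(twice$structure_id, once$structure_id)
})

test_that("range-valued affinities keep the boundary estimate or drop", {
  rec <- data.frame(structure_id = "9rng", affinity_value = NA_real_,
                    affinity_type = "Kd", unit = "nM", range_bound = 50,
                    stringsAsFactors = FALSE)
  kept <- curate_records(rec, keep_range_bounds = TRUE)$kept
  expect_equal(kept$affinity_value, 50)
  dropped <- curate_records(rec, keep_range_bounds = FALSE)
  expect_equal(nrow(dropped$kept), 0L)
  expect_true("dropped_range" %in% dropped$audit$code)
})

test_that("identity on trivial pairs is exact", {
  expect_equal(nw_identity("ACDEFGHIKL", "ACDEFGHIKL"), 100)
  expect_equal(nw_identity("AAAA", "GGGG"), 0)
  expect_equal(nw_identity("ACDF", "ACEF"), 75)
})

test_that("Gotoh scores equal brute-force enumeration on tiny sequences", {
  sub <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  set.seed(79)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:8) {
    a <- paste(sample(aas, sample(2:4, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:4, 1), replace = TRUE), collapse = "")
    got <- nw_identity(a, b, details = TRUE)
    expect_equal(got$score, brute_force_nw_score(a, b, sub),
                 info = paste(a, b))
  }
})

test_that("Gotoh scores match Biostrings pairwiseAlignment", {
  set.seed(83)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:5) {
    a <- paste(sample(aas, 12, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 15, replace = TRUE), collapse = "")
    got <- nw_identity(a, b, details = TRUE)
    pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 0.5)
    expect_equal(got$score, Biostrings::score(pa), info = paste(a, b))
  }
})

test_that("identity is symmetric, bounded, and maps odd symbols to X", {
  set.seed(89)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:5) {
    a <- paste(sample(aas, 10, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 13, replace = TRUE), collapse = "")
    i1 <- nw_identity(a, b); i2 <- nw_identity(b, a)
    expect_equal(i1, i2)
    expect_gte(i1, 0); expect_lte(i1, 100)
  }
  expect_warning(nw_identity("AC1D", "ACD"), "mapped to X")
})

test_that("identity audit flags duplicates and passes unrelated chains", {
  set.seed(97)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  s1 <- paste(sample(aas, 200, replace = TRUE), collapse = "")
  s2 <- paste(sample(aas, 200, replace = TRUE), collapse = "")
  rep_ok <- identity_audit(c(H = s1, L = s2), threshold = 25)
  expect_true(rep_ok$pass)
  rep_dup <- identity_audit(c(H = s1, H2 = s1), threshold = 25)
  expect_false(rep_dup$pass)
  expect_equal(rep_dup$violations$identity, 100)
  expect_true(identity_audit(c(a = s1, b = s1), threshold = 100)$pass)
})

test_that("grouped splits never separate a mutant from its parent", {
  rec <- data.frame(
    structure_id = c("wt1", paste0("wt1_m", 1:5), paste0("wt", 2:11)),
    parent_id = c(rep("wt1", 6), paste0("wt", 2:11)),
    is_mutant = c(FALSE, rep(TRUE, 5), rep(FALSE, 10)),
    stringsAsFactors = FALSE)
  for (seed in 1:5) {
    plan <- grouped_splits(rec, k = 4, mode = "grouped_kfold", seed = seed)
    fold_of <- integer(nrow(rec))
    for (fi in seq_along(plan$folds)) fold_of[plan$folds[[fi]]] <- fi
    for (g in unique(rec$parent_id)) {
      expect_length(unique(fold_of[rec$parent_id == g]), 1L)
    }
    expect_setequal(unlist(plan$folds), seq_len(nrow(rec)))
  }
})

test_that("leave-one-protein-out gives one fold per group; kfold checks k", {
  rec <- data.frame(structure_id = paste0("wt", 1:10),
                    parent_id = paste0("wt", 1:10),
                    stringsAsFactors = FALSE)
  lopo <- grouped_splits(rec, mode = "leave_one_protein_out", seed = 2)
  expect_length(lopo$folds, 10L)
  expect_true(all(lengths(lopo$folds) == 1L))
  ten <- grouped_splits(rec, k = 10, mode = "grouped_kfold", seed = 2)
  expect_true(all(lengths(ten$folds) == 1L))
  expect_error(grouped_splits(rec, k = 11, mode = "grouped_kfold"),
               "exceeds")
})

test_that("split plans are seed-reproducible and JSON-serialisable", {
  rec <- data.frame(structure_id = paste0("s", 1:20),
                    parent_id = paste0("g", rep(1:7, length.out = 20)),
                    stringsAsFactors = FALSE)
  p1 <- grouped_splits(rec, k = 3, seed = 42)
  p2 <- grouped_splits(rec, k = 3, seed = 42)
  expect_identical(p1$folds, p2$folds)
  path <- tempfile(fileext = ".json")
  write_split_plan(p1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$mode, "grouped_kfold")
  expect_equal(sort(as.integer(unlist(back$folds))), 1:20)
})

test_that("fixture generation is byte-identical across calls", {
  f1 <- generate_fixture_complex("ring-motif", seed = 1)
  f2 <- generate_fixture_complex("ring-motif", seed = 99)  # seed unused at jitter 0
  expect_identical(f1$pdb, f2$pdb)
  expect_error(generate_fixture_complex("no-such-template"), "arg")
})

test_that("fixture manifests predict the bipartite Rips barcodes", {
  for (tpl in c("two-atom", "bipartite-lattice", "ring-motif")) {
    fx <- generate_fixture_complex(tpl)
    pair <- assign_partners(parse_structure(fx$pdb), list(A = "A", B = "B"))
    region <- extract_interface(pair, 20)
    fc <- build_rips_filtration(modified_distance_matrix(region), 2, 15)
    bars <- compute_barcodes(fc)
    man <- fx$manifest$barcodes
    expect_equal(sort(bars[["0"]]$death), sort(man$h0$death),
                 tolerance = 1e-3, info = tpl)
    expect_equal(sort(bars[["1"]]$birth), sort(man$h1$birth),
                 tolerance = 1e-3, info = tpl)
    if (nrow(man$h1)) expect_true(all(is.infinite(bars[["1"]]$death)))
  }
})

test_that("synthetic labels follow the documented generating function", {
  ds0 <- generate_synthetic_dataset(200, noise_sd = 0, seed = 5)
  expect_equal(ds0$y, ds0$f(ds0$X), tolerance = 1e-12)
  dsa <- generate_synthetic_dataset(500, noise_sd = 0.5, seed = 6)
  dsb <- generate_synthetic_dataset(500, noise_sd = 0.5, seed = 6)
  expect_identical(dsa$X, dsb$X)
  expect_identical(dsa$y, dsb$y)
})

test_that("label variance decomposes into signal plus noise", {
  ds <- generate_synthetic_dataset(5000, noise_sd = 0.5, seed = 8)
  expect_equal(stats::sd(ds$y),
               sqrt(stats::var(ds$f(ds$X)) + 0.25), tolerance = 0.05)
})
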