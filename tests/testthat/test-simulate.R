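small_cfg <- function(seed = 101, ...) {
  simulation_config(
    n_species = 6, accessions_per_species = 3,
    loci = data.frame(name = c("nuc", "pla"), length = c(400L, 400L),
                      genome = c("nuclear", "plastid")),
    inter_divergence = c(nuc = 0.15, pla = 0.05),
    intra_divergence = c(nuc = 0.002, pla = 0),
    capture_pairs = list(c("species_01", "species_02")),
    seed = seed, ...)
}

test_that("configuration validation catches inconsistent setups", {
  expect_error(simulation_config(n_species = 6, seed = 1,
                                 capture_pairs = list(c("species_01", "nope")),
                                 loci = default_loci()),
               "unknown species")
  expect_error(simulation_config(n_species = 6, loci = default_loci()),
               "seed")
  expect_error(simulation_config(n_species = 6, seed = 1, kappa = 0),
               "kappa")
  expect_error(
    simulation_config(n_species = 2, seed = 1,
                      missing_loci = list(species_01 = default_loci()$name)),
    "no locus at all")
})

test_that("default configuration mirrors a field-study accession structure", {
  cfg <- simulation_config(seed = 3)
  expect_equal(cfg$n_species, 36L)
  expect_equal(sum(cfg$accessions_per_species), 292L)
  expect_equal(sum(cfg$accessions_per_species == 1L), 3L)
  expect_equal(nrow(cfg$loci), 5L)
  expect_equal(sum(cfg$loci$genome == "plastid"), 4L)
})

test_that("zero branch divergence copies the parent exactly", {
  p <- random_seq(300)
  expect_identical(evolve_sequence(p, 0, kappa = 2), p)
})

test_that("very large kappa makes essentially all changes transitions", {
  set.seed(13)
  p <- random_seq(10000)
  child <- evolve_sequence(p, 0.1, kappa = 1e6)
  cnt <- count_site_patterns(p, child)
  expect_gt(cnt$n_transitions, 0)
  expect_equal(cnt$n_transversions, 0)
})

test_that("realized ts:tv ratios recover kappa within sampling error", {
  set.seed(14)
  kappa <- 2
  d <- 0.05
  # expected ts:tv proportions from the exact site-change probabilities at
  # this branch length (slightly below kappa/2 because of multiple hits)
  p <- random_seq(50000)
  child <- evolve_sequence(p, d, kappa)
  cnt <- count_site_patterns(p, child)
  ratio <- cnt$n_transitions / cnt$n_transversions
  # binomial sampling band around kappa/2, wide enough for 5 sd
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.35)
})

test_that("estimated K2P distance recovers the branch divergence (200 reps)", {
  set.seed(15)
  d <- 0.05
  reps <- 200
  est <- replicate(reps, {
    p <- random_seq(1000)
    as.numeric(k2p_distance(count_site_patterns(p, evolve_sequence(p, d, 2))))
  })
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - d), 3 * se)
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_genus(small_cfg(77))
  s2 <- simulate_genus(small_cfg(77))
  expect_identical(s1$dataset$loci, s2$dataset$loci)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_genus(small_cfg(78))
  expect_false(identical(s1$dataset$loci, s3$dataset$loci))
})

test_that("capture pairs share plastid founders but not nuclear ones", {
  sim <- simulate_genus(small_cfg(21))
  ds <- sim$dataset
  # plastid accessions of the capture pair are byte-identical (intra = 0)
  pla <- ds$loci$pla$sequences
  expect_equal(unname(pla[["species_01_acc01"]]),
               unname(pla[["species_02_acc01"]]))
  tp <- sim$truth$unresolved$pla
  expect_true("species_01|species_02" %in% canon_pairs(tp))
  expect_false("species_01|species_02" %in% canon_pairs(sim$truth$unresolved$nuc))
})

test_that("all-zero divergences collapse every sequence onto the ancestor", {
  cfg <- simulation_config(
    n_species = 4, accessions_per_species = 2,
    loci = data.frame(name = "L", length = 120L, genome = "plastid"),
    inter_divergence = c(L = 0), intra_divergence = c(L = 0),
    capture_pairs = list(), seed = 5)
  sim <- simulate_genus(cfg)
  expect_equal(length(unique(sim$dataset$loci$L$sequences)), 1L)
  rep <- analyze_dataset(sim$dataset)
  expect_equal(rep$loci$L$resolution$percent, 0)
  expect_equal(nrow(sim$truth$unresolved$L), choose(4, 2))
})

test_that("with zero intra noise the analysis recovers the ground truth exactly", {
  cfg <- simulation_config(
    n_species = 10, accessions_per_species = 2,
    loci = data.frame(name = c("nuc", "p1", "p2"),
                      length = c(500L, 500L, 500L),
                      genome = c("nuclear", "plastid", "plastid")),
    inter_divergence = c(nuc = 0.15, p1 = 0.05, p2 = 0.05),
    intra_divergence = c(nuc = 0, p1 = 0, p2 = 0),
    capture_pairs = list(c("species_03", "species_07")),
    seed = 31)
  sim <- simulate_genus(cfg)
  rep <- analyze_dataset(sim$dataset,
                         combos = list(c("p1", "p2"), c("nuc", "p1")))
  for (lc in c("nuc", "p1", "p2")) {
    expect_identical(canon_pairs(rep$loci[[lc]]$resolution$unresolved_pairs),
                     canon_pairs(truth_unresolved(sim$truth, lc)))
  }
  expect_identical(canon_pairs(rep$combinations[["p1+p2"]]$resolution$unresolved_pairs),
                   canon_pairs(truth_unresolved(sim$truth, c("p1", "p2"))))
  expect_identical(canon_pairs(rep$combinations[["nuc+p1"]]$resolution$unresolved_pairs),
                   canon_pairs(truth_unresolved(sim$truth, c("nuc", "p1"))))
})

test_that("missing loci are omitted from alignments and combination scopes", {
  cfg <- simulation_config(
    n_species = 5, accessions_per_species = 2,
    loci = data.frame(name = c("L1", "L2"), length = c(200L, 200L),
                      genome = c("plastid", "plastid")),
    inter_divergence = c(L1 = 0.05, L2 = 0.05),
    intra_divergence = c(L1 = 0, L2 = 0),
    capture_pairs = list(),
    missing_loci = list(species_05 = "L2"),
    seed = 44)
  sim <- simulate_genus(cfg)
  expect_false(any(grepl("species_05",
                         names(sim$dataset$loci$L2$sequences))))
  prof <- build_species_profiles(sim$dataset)
  cmb <- combine_loci(prof, c("L1", "L2"), sim$dataset)
  expect_equal(sort(cmb$species), sprintf("species_%02d", 1:4))
})

test_that("simulation writes a complete, re-readable file set", {
  sim <- simulate_genus(small_cfg(55))
  dir <- tempfile()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("nuc.fasta", "pla.fasta", "sample_sheet.tsv", "truth.json",
           "config.json")))))
  ds2 <- barcode_dataset(
    list(read_alignment(file.path(dir, "nuc.fasta"), "nuc"),
         read_alignment(file.path(dir, "pla.fasta"), "pla")),
    read_sample_sheet(file.path(dir, "sample_sheet.tsv")))
  expect_identical(ds2$loci$nuc$sequences, sim$dataset$loci$nuc$sequences)
})
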