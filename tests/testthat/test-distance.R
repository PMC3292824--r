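test_that("site-pattern counting matches a naive per-site oracle on random pairs", {
  set.seed(42)
  for (i in 1:60) {
    len <- sample(20:120, 1)
    a <- random_seq(len, p_missing = 0.15)
    b <- random_seq(len, p_missing = 0.15)
    got <- count_site_patterns(a, b)
    want <- naive_site_counts(a, b)
    expect_equal(got$n_compared, want$n_compared)
    expect_equal(got$n_transitions, want$n_transitions)
    expect_equal(got$n_transversions, want$n_transversions)
  }
})

test_that("site-pattern counting basics: identity, single transition, length check", {
  idc <- count_site_patterns("ACGTACGT", "ACGTACGT")
  expect_equal(unlist(idc[c("n_compared", "n_transitions", "n_transversions")]),
               c(n_compared = 8L, n_transitions = 0L, n_transversions = 0L))
  one <- count_site_patterns("AG", "GG")
  expect_equal(one$n_transitions, 1L)
  expect_equal(one$n_transversions, 0L)
  expect_error(count_site_patterns("ACG", "AC"), "length")
})

test_that("complete deletion uses a fixed dataset-wide column mask", {
  seqs <- c(s1 = "ACGTA", s2 = "ACGT-", s3 = "ACGTC")
  dm <- pairwise_distance_matrix(seqs, deletion = "complete")
  # column 5 has a gap in s2, so s1 vs s3 also ignores it
  expect_equal(dm$d["s1", "s3"], 0)
  dp <- pairwise_distance_matrix(seqs, deletion = "pairwise")
  expect_gt(dp$d["s1", "s3"], 0)
})

test_that("K2P closed form: worked values, JC limit at Q = 2P, saturation", {
  expect_equal(k2p_distance(site_counts(100, 0, 0)), 0)
  expect_equal(k2p_distance(site_counts(100, 10, 5)), 0.17018, tolerance = 1e-4)
  # Q = 2P collapses to Jukes-Cantor with p = P + Q
  d <- k2p_distance(site_counts(100, 5, 10))
  expect_equal(d, -0.75 * log(1 - 4 * 0.15 / 3), tolerance = 1e-12)
  expect_equal(d, 0.16735, tolerance = 1e-4)
  sat <- k2p_distance(site_counts(10, 6, 0))  # 1 - 2P = -0.2
  expect_true(is.na(sat))
  expect_equal(attr(sat, "reason"), "saturated")
  emp <- k2p_distance(site_counts(0, 0, 0))
  expect_true(is.na(emp))
  expect_equal(attr(emp, "reason"), "empty overlap")
})

test_that("K2P equals the independent closed form over many random site counts", {
  set.seed(7)
  n_cases <- 10000
  n <- sample(50:2000, n_cases, replace = TRUE)
  ts <- floor(n * runif(n_cases, 0, 0.35))
  tv <- floor((n - ts) * runif(n_cases, 0, 0.3))
  got <- mapply(function(nn, s, v) k2p_distance(site_counts(nn, s, v)),
                n, ts, tv)
  want <- mapply(k2p_closed_form, n, ts, tv)
  expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
})

test_that("p-distance arithmetic and the p <= K2P dominance property", {
  expect_equal(p_distance(site_counts(100, 0, 0)), 0)
  expect_equal(p_distance(site_counts(100, 10, 5)), 0.15)
  set.seed(8)
  for (i in 1:500) {
    n <- sample(30:500, 1)
    ts <- sample(0:floor(n * 0.3), 1)
    tv <- sample(0:floor((n - ts) * 0.25), 1)
    k <- k2p_distance(site_counts(n, ts, tv))
    p <- p_distance(site_counts(n, ts, tv))
    if (!is.na(k)) {
      expect_gte(k, p)
      if (ts + tv == 0) expect_equal(k, p)
    }
  }
})

test_that("K2P is strictly increasing in transitions and transversions", {
  base <- k2p_distance(site_counts(1000, 50, 30))
  expect_gt(k2p_distance(site_counts(1000, 51, 30)), base)
  expect_gt(k2p_distance(site_counts(1000, 50, 31)), base)
})

test_that("distance matrices are symmetric, zero-diagonal, and match ape's K80", {
  skip_if_not_installed("ape")
  set.seed(21)
  for (rep_i in 1:5) {
    n_taxa <- 8
    len <- 300
    anc <- random_seq(len)
    seqs <- setNames(
      replicate(n_taxa, evolve_sequence(anc, runif(1, 0.02, 0.15), 2)),
      paste0("t", 1:n_taxa))
    # sprinkle missing data so pairwise deletion is exercised
    seqs <- vapply(seqs, function(s) {
      v <- strsplit(s, "")[[1]]
      v[sample(len, 10)] <- sample(c("-", "N"), 10, replace = TRUE)
      paste(v, collapse = "")
    }, character(1))
    dm <- pairwise_distance_matrix(seqs, model = "k2p",
                                   deletion = "pairwise")
    expect_true(isSymmetric(dm$d))
    expect_equal(unname(diag(dm$d)), rep(0, n_taxa))
    chars <- do.call(rbind, strsplit(tolower(seqs), ""))
    rownames(chars) <- names(seqs)
    ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(chars), model = "K80",
                                   pairwise.deletion = TRUE))
    ref <- ref[rownames(dm$d), colnames(dm$d)]
    # undefined entries (saturated/empty overlap) must coincide with ape's
    # non-finite results; defined entries must agree numerically
    expect_equal(is.na(dm$d) & !diag(n_taxa), !is.finite(ref) & !diag(n_taxa),
                 ignore_attr = TRUE)
    ok <- !is.na(dm$d)
    expect_equal(dm$d[ok], ref[ok], tolerance = 1e-10)
  }
})

test_that("matrix computation equals element-wise recomputation", {
  set.seed(33)
  seqs <- setNames(replicate(6, random_seq(150, p_missing = 0.1)),
                   paste0("t", 1:6))
  dm <- pairwise_distance_matrix(seqs)
  for (i in 1:5) for (j in (i + 1):6) {
    v <- k2p_distance(count_site_patterns(seqs[[i]], seqs[[j]]))
    expect_equal(dm$d[i, j], as.numeric(v))
  }
})

test_that("saturated pairs are flagged undefined, not zeroed", {
  seqs <- c(s1 = strrep("A", 10), s2 = strrep("G", 10), s3 = strrep("A", 10))
  dm <- pairwise_distance_matrix(seqs)
  expect_true(dm$undefined["s1", "s2"])
  expect_true(is.na(dm$d["s1", "s2"]))
  expect_false(dm$undefined["s1", "s3"])
  expect_equal(dm$d["s1", "s3"], 0)
})

test_that("intra-specific summaries use accessions, exclude singletons", {
  ds <- toy_dataset()
  s <- intra_specific_summary(ds$loci$locA, locus_species(ds, "locA"))
  expect_equal(sort(names(s$per_species)), c("X", "Y"))  # Z is a singleton
  expect_equal(s$intra_max, 0)
  expect_equal(s$n_species, 2L)
  # a divergent conspecific pair raises the maximum
  aln <- locus_alignment("L", c(x1 = "ACGTACGTAC", x2 = "ACGTACGTAT",
                                y1 = "ACGTACGTAC"))
  sp <- c(x1 = "X", x2 = "X", y1 = "Y")
  s2 <- intra_specific_summary(aln, sp)
  expect_equal(s2$per_species$X,
               as.numeric(k2p_distance(count_site_patterns(
                 "ACGTACGTAC", "ACGTACGTAT"))))
  expect_warning(
    intra_specific_summary(locus_alignment("L", c(a = "ACGT", b = "ACGT")),
                           c(a = "A", b = "B")),
    "no multi-accession")
})

test_that("inter-specific summaries: single transition pair and degenerate cases", {
  reps <- c(spA = paste0(strrep("A", 99), "A"),
            spB = paste0(strrep("A", 99), "G"))
  res <- inter_specific_matrix(reps)
  # closed form at P = 0.01, Q = 0: -0.5 * log(1 - 0.02) = 0.0101014
  expect_equal(res$mean, -0.5 * log(0.98), tolerance = 1e-12)
  same <- inter_specific_matrix(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGT"))
  expect_equal(same$mean, 0)
  expect_equal(same$range, c(0, 0))
  expect_error(inter_specific_matrix(c(only = "ACGT")), "two species")
})
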