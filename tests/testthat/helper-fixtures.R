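# Shared fixtures built in code.

write_fasta_tmp <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# random aligned sequence with optional missing/gap characters
random_seq <- function(len, p_missing = 0) {
  pool <- c("A", "C", "G", "T")
  s <- sample(pool, len, replace = TRUE)
  if (p_missing > 0) {
    miss <- runif(len) < p_missing
    s[miss] <- sample(c("-", "N", "?", "R", "Y"), sum(miss), replace = TRUE)
  }
  paste(s, collapse = "")
}

# a tiny hand-built two-locus, three-species dataset
toy_dataset <- function() {
  locA <- locus_alignment("locA", c(
    a1 = "ACGTACGTAC", a2 = "ACGTACGTAC",   # species X, identical
    b1 = "ACGTACGTAT", b2 = "ACGTACGTAT",   # species Y
    c1 = "AAAAACGTAC"))                     # species Z, singleton
  locB <- locus_alignment("locB", c(
    a1 = "GGGGCCCC", a2 = "GGGGCCCC",
    b1 = "GGGGCCCC", b2 = "GGGGCCCC",       # X and Y identical at locB
    c1 = "GGGGCCTT"))
  sheet <- data.frame(
    accession_id = rep(c("a1", "a2", "b1", "b2", "c1"), 2),
    species_label = rep(c("X", "X", "Y", "Y", "Z"), 2),
    locus_name = rep(c("locA", "locB"), each = 5),
    source_tag = "self", stringsAsFactors = FALSE)
  barcode_dataset(list(locA, locB), sheet)
}

# independent naive per-site counting oracle
naive_site_counts <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  purine <- c("A", "G")
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(av)) {
    x <- av[i]; y <- bv[i]
    if (!x %in% c("A", "C", "G", "T") || !y %in% c("A", "C", "G", "T")) next
    n <- n + 1L
    if (x == y) next
    if ((x %in% purine) == (y %in% purine)) ts <- ts + 1L else tv <- tv + 1L
  }
  list(n_compared = n, n_transitions = ts, n_transversions = tv)
}

# high-precision closed-form K2P, written independently of the package path
k2p_closed_form <- function(n, ts, tv) {
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log1p(-(2 * P + Q)) - 0.25 * log1p(-2 * Q)
}

canon_pairs <- function(m) {
  if (nrow(m) == 0) return(character(0))
  sort(apply(m, 1, function(r) paste(sort(r), collapse = "|")))
}
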