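## Pairwise site-pattern counting and evolutionary distances.
##
## Only unambiguous bases {A,C,G,T} are ever compared. Under pairwise
## deletion, sites are dropped per pair; under complete deletion the set of
## usable columns is fixed for the whole sequence set before any pair is
## compared. Transitions are A<->G and C<->T; everything else is a
## transversion.

# transition partner by code: A(1)<->G(3), C(2)<->T(4)
.TS_PARTNER <- c(3L, 4L, 1L, 2L)

#' Count compared sites, transitions and transversions for one pair
#'
#' @param a,b Aligned sequences of equal length: character strings or
#'   integer-encoded vectors (A=1, C=2, G=3, T=4, NA = missing).
#' @param deletion `"pairwise"` (default) or `"complete"`. Complete deletion
#'   requires `keep_sites`, the dataset-wide usable-column mask.
#' @param keep_sites Logical vector of columns retained under complete
#'   deletion; ignored for pairwise deletion.
#' @return A `site_counts` object: list with `n_compared`, `n_transitions`,
#'   `n_transversions`. `n_compared = 0` marks an empty overlap.
#' @examples
#' count_site_patterns("AG", "GG")  # one transition over two sites
#' @export
count_site_patterns <- function(a, b, deletion = c("pairwise", "complete"),
                                keep_sites = NULL) {
  deletion <- match.arg(deletion)
  if (is.character(a)) a <- encode_sequence(a)
  if (is.character(b)) b <- encode_sequence(b)
  if (length(a) != length(b))
    stop("aligned sequences differ in length (", length(a), " vs ",
         length(b), ")")
  ok <- !is.na(a) & !is.na(b)
  if (deletion == "complete") {
    if (is.null(keep_sites))
      stop("complete deletion requires a precomputed 'keep_sites' mask")
    ok <- ok & keep_sites
  }
  d <- ok & a != b
  ts <- sum(d & (b == .TS_PARTNER[a]), na.rm = TRUE)
  tot <- sum(d)
  site_counts(sum(ok), ts, tot - ts)
}

#' Construct a site-pattern count triple
#'
#' @param n_compared Number of sites compared.
#' @param n_transitions Transition differences among them.
#' @param n_transversions Transversion differences among them.
#' @return A `site_counts` object.
#' @export
site_counts <- function(n_compared, n_transitions, n_transversions) {
  if (any(c(n_compared, n_transitions, n_transversions) < 0))
    stop("site counts must be non-negative")
  if (n_transitions + n_transversions > n_compared)
    stop("differences exceed compared sites")
  structure(list(n_compared = as.integer(n_compared),
                 n_transitions = as.integer(n_transitions),
                 n_transversions = as.integer(n_transversions)),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat("sites compared:", x$n_compared, " transitions:", x$n_transitions,
      " transversions:", x$n_transversions, "\n")
  invisible(x)
}

#' Kimura-2-parameter distance from site counts
#'
#' Computes d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q) with
#' P = transitions / compared sites and Q = transversions / compared sites.
#' The distance is undefined ("saturated") when either log argument is
#' non-positive, and undefined with reason `"empty overlap"` when no site
#' could be compared; both cases return `NA` with attributes
#' `undefined = TRUE` and `reason`.
#'
#' @param c A `site_counts` object (or a list with the same fields).
#' @return Distance in substitutions/site (`numeric(1)`), or `NA` with
#'   attributes `undefined` and `reason`.
#' @examples
#' k2p_distance(site_counts(100, 10, 5))  # ~0.17018
#' @export
k2p_distance <- function(c) {
  if (c$n_compared == 0L)
    return(structure(NA_real_, undefined = TRUE, reason = "empty overlap"))
  P <- c$n_transitions / c$n_compared
  Q <- c$n_transversions / c$n_compared
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(structure(NA_real_, undefined = TRUE, reason = "saturated"))
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' p-distance (proportion of differing sites)
#'
#' @inheritParams k2p_distance
#' @return Proportion of compared sites that differ, or `NA` (empty
#'   overlap).
#' @export
p_distance <- function(c) {
  if (c$n_compared == 0L)
    return(structure(NA_real_, undefined = TRUE, reason = "empty overlap"))
  (c$n_transitions + c$n_transversions) / c$n_compared
}

#' Jukes-Cantor distance from site counts
#'
#' d = -3/4 log(1 - 4p/3) with p the p-distance; undefined when
#' 1 - 4p/3 <= 0.
#'
#' @inheritParams k2p_distance
#' @return Distance in substitutions/site, or `NA` with reason.
#' @export
jc_distance <- function(c) {
  p <- p_distance(c)
  if (is.na(p)) return(p)
  w <- 1 - 4 * p / 3
  if (w <= 0)
    return(structure(NA_real_, undefined = TRUE, reason = "saturated"))
  -0.75 * log(w)
}

.dist_fun <- function(model) {
  switch(model, k2p = k2p_distance, p = p_distance, jc = jc_distance,
         stop("unknown model: ", model))
}

#' Pairwise distance matrix over a set of aligned sequences
#'
#' Computes all unordered pairwise distances under the chosen model and
#' deletion policy. Undefined pairs (saturated or empty overlap) are `NA`
#' in the matrix and flagged in `undefined`, never silently zeroed.
#'
#' @param x A `locus_alignment`, or a named character vector of equal-length
#'   aligned sequences (e.g. species representatives).
#' @param model `"k2p"` (default), `"p"` or `"jc"`.
#' @param deletion `"pairwise"` (default) or `"complete"`. Under complete
#'   deletion, every column containing a gap/missing/ambiguous character in
#'   any sequence of `x` is excluded for all pairs.
#' @return A `barcode_dist`: list with `labels`, `d` (symmetric numeric
#'   matrix, zero diagonal, `NA` where undefined), `undefined` (logical
#'   matrix), `model`, `deletion`, `n_sites`.
#' @export
pairwise_distance_matrix <- function(x, model = c("k2p", "p", "jc"),
                                     deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  seqs <- if (inherits(x, "locus_alignment")) x$sequences else x
  if (length(seqs) < 2L) stop("need at least two sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  enc <- encode_alignment(seqs)
  n <- nrow(enc)
  keep <- NULL
  if (deletion == "complete") keep <- colSums(is.na(enc)) == 0L
  fn <- .dist_fun(model)
  d <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  undef <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      cnt <- count_site_patterns(enc[i, ], enc[j, ], deletion = deletion,
                                 keep_sites = keep)
      val <- fn(cnt)
      if (is.na(val)) {
        undef[i, j] <- undef[j, i] <- TRUE
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- val
      }
    }
  }
  structure(list(labels = rownames(enc), d = d, undefined = undef,
                 model = model, deletion = deletion, n_sites = ncol(enc)),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  cat("Pairwise ", toupper(x$model), " distances (", x$deletion,
      " deletion): ", length(x$labels), " taxa, ", x$n_sites, " sites",
      sep = "")
  nu <- sum(x$undefined[upper.tri(x$undefined)])
  if (nu) cat(", ", nu, " undefined pair(s)", sep = "")
  cat("\n")
  invisible(x)
}

#' Write a distance matrix as TSV or PHYLIP square matrix
#'
#' Undefined entries are written as `NA`; distances are rounded to four
#' decimals for reporting.
#'
#' @param dm A `barcode_dist`.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  m <- round(dm$d, 4)
  if (format == "tsv") {
    df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(formatC(rownames(m)[i], width = -10),
                       paste(ifelse(is.na(m[i, ]), "NA",
                                    formatC(m[i, ], format = "f", digits = 4)),
                             collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Intra-specific distance summary for one locus
#'
#' Computes, for every species represented by at least two accessions, all
#' within-species pairwise distances at accession level, and the locus-wide
#' maximum intra-specific distance. Singleton species contribute nothing;
#' if no species has two accessions the maximum is defined as 0, with a
#' warning.
#'
#' @param aln A `locus_alignment`.
#' @param species Named character vector accession -> species label (e.g.
#'   from [locus_species()]), covering every accession in `aln`.
#' @inheritParams pairwise_distance_matrix
#' @return List with `locus`, `per_species` (named list of numeric distance
#'   vectors), `intra_max`, `intra_range` (c(min, max)), `n_species`
#'   (species with >= 2 accessions), `n_undefined` (intra pairs with
#'   undefined distance, excluded from the summaries).
#' @export
intra_specific_summary <- function(aln, species, model = "k2p",
                                   deletion = "pairwise") {
  stopifnot(inherits(aln, "locus_alignment"))
  ids <- names(aln$sequences)
  miss <- setdiff(ids, names(species))
  if (length(miss))
    stop("no species label for accession(s): ", paste(miss, collapse = ", "))
  sp <- species[ids]
  enc <- encode_alignment(aln$sequences)
  keep <- if (deletion == "complete") colSums(is.na(enc)) == 0L else NULL
  fn <- .dist_fun(model)
  multi <- names(which(table(sp) >= 2L))
  n_undef <- 0L
  per <- lapply(multi, function(s) {
    rows <- which(sp == s)
    out <- numeric(0)
    for (i in seq_len(length(rows) - 1L)) {
      for (j in seq.int(i + 1L, length(rows))) {
        v <- fn(count_site_patterns(enc[rows[i], ], enc[rows[j], ],
                                    deletion = deletion, keep_sites = keep))
        if (is.na(v)) n_undef <<- n_undef + 1L else out <- c(out, v)
      }
    }
    out
  })
  names(per) <- multi
  all_d <- unlist(per, use.names = FALSE)
  if (length(all_d) == 0L) {
    warning("locus '", aln$locus,
            "': no multi-accession species; intra-specific maximum set to 0",
            call. = FALSE)
    intra_max <- 0
    intra_range <- c(0, 0)
  } else {
    intra_max <- max(all_d)
    intra_range <- range(all_d)
  }
  list(locus = aln$locus, per_species = per, intra_max = intra_max,
       intra_range = intra_range, n_species = length(multi),
       n_undefined = n_undef)
}

#' Inter-specific distances between species representatives
#'
#' One representative sequence per species; returns the full pairwise
#' matrix plus the mean and range over all unordered species pairs
#' (undefined pairs excluded from mean/range and counted).
#'
#' @param representatives Named character vector species -> representative
#'   sequence (equal lengths).
#' @inheritParams pairwise_distance_matrix
#' @return List with `matrix` (a `barcode_dist`), `mean`, `range`,
#'   `n_species`, `n_pairs`, `n_undefined`.
#' @export
inter_specific_matrix <- function(representatives, model = "k2p",
                                  deletion = "pairwise") {
  if (length(representatives) < 2L)
    stop("need at least two species representatives")
  dm <- pairwise_distance_matrix(representatives, model = model,
                                 deletion = deletion)
  up <- upper.tri(dm$d)
  vals <- dm$d[up]
  n_undef <- sum(is.na(vals))
  vals <- vals[!is.na(vals)]
  list(matrix = dm,
       mean = if (length(vals)) mean(vals) else NA_real_,
       range = if (length(vals)) range(vals) else c(NA_real_, NA_real_),
       n_species = length(representatives),
       n_pairs = sum(up),
       n_undefined = n_undef)
}
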