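## Majority-rule consensus representatives, one per species per locus.
## Ties among top-count bases become the minimal IUPAC code covering the
## tied set; those codes are later skipped (pairwise deletion) in distance
## computations, so tie-breaking is deterministic, order-invariant and
## conservative.

# IUPAC code for each non-empty subset of {A,C,G,T}, keyed by sorted paste
.IUPAC <- c("A" = "A", "C" = "C", "G" = "G", "T" = "T",
            "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W",
            "GT" = "K", "AC" = "M", "CGT" = "B", "AGT" = "D",
            "ACT" = "H", "ACG" = "V", "ACGT" = "N")

#' Majority-rule consensus of one species' accessions at one locus
#'
#' Per alignment column: the strict-majority base among A/C/G/T wins; a gap
#' (`-`) wins only when gaps are the strict majority of the column's
#' non-missing characters; ties among the most frequent bases yield the
#' minimal IUPAC code covering the tied bases; missing characters (`N`,
#' `?`, ambiguity codes) are ignored unless the whole column is missing, in
#' which case the consensus is `N`.
#'
#' @param records Named character vector of equal-length aligned sequences
#'   (the accessions of one species at one locus).
#' @return The consensus sequence (character string of the same length).
#' @examples
#' consensus_representative(c(a1 = "AAG", a2 = "AAT", a3 = "GAT"))
#' @export
consensus_representative <- function(records) {
  if (length(records) == 0L) stop("no records to take a consensus of")
  lens <- nchar(records)
  if (length(unique(lens)) != 1L)
    stop("records have unequal aligned lengths")
  if (length(records) == 1L) return(unname(records[[1L]]))
  chars <- vapply(records, function(s) strsplit(s, "", fixed = TRUE)[[1L]],
                  character(lens[1L]))
  # chars: sites x records
  if (lens[1L] == 1L) chars <- matrix(chars, nrow = 1L)
  apply_col <- function(col) {
    base_n <- vapply(.BASES, function(b) sum(col == b), integer(1))
    gap_n <- sum(col == "-")
    informative <- sum(base_n) + gap_n
    if (informative == 0L) return("N")
    if (gap_n * 2L > informative) return("-")
    if (sum(base_n) == 0L) return("-")  # only gaps among informative chars
    top <- max(base_n)
    winners <- .BASES[base_n == top]
    if (length(winners) == 1L) return(winners)
    .IUPAC[[paste(sort(winners), collapse = "")]]
  }
  paste(apply(chars, 1L, apply_col), collapse = "")
}

#' Build per-species consensus profiles across all loci
#'
#' One representative sequence per species per locus where the species has
#' at least one accession; species lacking a locus simply have no
#' representative for it. Intra-specific statistics always use the
#' accession-level sequences; representatives feed only the inter-specific
#' matrices.
#'
#' @param ds A `barcode_dataset`.
#' @return A `species_profiles` object: named list (by species) of lists
#'   with `representatives` (named character vector by locus) and
#'   `n_accessions` (named integer vector by locus).
#' @export
build_species_profiles <- function(ds) {
  stopifnot(inherits(ds, "barcode_dataset"))
  species_all <- sort(unique(ds$sheet$species_label))
  profiles <- lapply(species_all, function(s) {
    reps <- character(0)
    nacc <- integer(0)
    for (lc in names(ds$loci)) {
      sp <- locus_species(ds, lc)
      ids <- names(sp)[sp == s]
      if (length(ids) == 0L) next
      reps[[lc]] <- consensus_representative(ds$loci[[lc]]$sequences[ids])
      nacc[[lc]] <- length(ids)
    }
    list(species = s, representatives = reps, n_accessions = nacc)
  })
  names(profiles) <- species_all
  structure(profiles, class = "species_profiles")
}

#' @export
print.species_profiles <- function(x, ...) {
  cat("Species profiles:", length(x), "species\n")
  invisible(x)
}

#' Extract one locus' representatives from species profiles
#'
#' @param profiles A `species_profiles` object.
#' @param locus Locus name.
#' @return Named character vector species -> representative sequence
#'   (species without the locus omitted).
#' @export
locus_representatives <- function(profiles, locus) {
  out <- vapply(profiles, function(p) {
    if (locus %in% names(p$representatives)) p$representatives[[locus]]
    else NA_character_
  }, character(1))
  out[!is.na(out)]
}

#' Write species representatives as multi-FASTA
#'
#' @param profiles A `species_profiles` object.
#' @param locus Locus name.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_representatives <- function(profiles, locus, path) {
  reps <- locus_representatives(profiles, locus)
  seqinr::write.fasta(as.list(reps), names = names(reps), file.out = path,
                      nbchar = 80)
  invisible(path)
}
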