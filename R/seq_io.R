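#' @keywords internal
"_PACKAGE"

## Characters treated as missing for distance purposes: gaps, hard missing,
## and IUPAC ambiguity codes (consensus ties produce these; their comparison
## is undefined under the substitution models used here).
.BASES <- c("A", "C", "G", "T")
.MISSING <- c("-", "N", "?", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
.ALLOWED <- c(.BASES, .MISSING)

#' Read an aligned multi-FASTA file for one locus
#'
#' Parses an aligned multi-FASTA file into a `locus_alignment`. The first
#' whitespace-delimited token of each header is taken as the accession id;
#' the remainder of the header is ignored. Sequences are uppercased and `U`
#' is mapped to `T`; gaps (`-`) and missing/ambiguity characters are
#' preserved.
#'
#' @param path Path to an aligned multi-FASTA file.
#' @param locus_name Name of the locus the file contains.
#' @return A `locus_alignment`: list with elements `locus` (name),
#'   `sequences` (named character vector, one aligned sequence per
#'   accession) and `length` (alignment columns).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a1 voucher X", "ACGT", ">a2", "ACGA"), f)
#' aln <- read_alignment(f, "matK")
#' aln$length
#' @export
read_alignment <- function(path, locus_name) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                             as.string = TRUE)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(vapply(recs, as.character, character(1)))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  names(seqs) <- ids
  locus_alignment(locus_name, seqs)
}

#' Construct a locus alignment from named sequences
#'
#' @param locus_name Locus name.
#' @param sequences Named character vector of equal-length aligned sequences
#'   (names are accession ids).
#' @return A `locus_alignment` object.
#' @export
locus_alignment <- function(locus_name, sequences) {
  if (length(sequences) < 1L) stop("alignment for locus '", locus_name,
                                   "' has no records")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every record needs a non-empty accession id")
  if (anyDuplicated(ids))
    stop("duplicate accession ids in locus '", locus_name, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- nchar(sequences)
  if (any(lens == 0L)) stop("empty sequence for accession ",
                            paste(ids[lens == 0L], collapse = ", "))
  if (length(unique(lens)) != 1L) {
    tab <- paste0(ids, " (", lens, " bp)")
    stop("unequal aligned lengths in locus '", locus_name, "': ",
         paste(tab, collapse = ", "))
  }
  bad <- vapply(sequences,
                function(s) any(!strsplit(s, "", fixed = TRUE)[[1]] %in% .ALLOWED),
                logical(1))
  if (any(bad))
    stop("invalid characters in accession(s): ",
         paste(ids[bad], collapse = ", "))
  structure(list(locus = locus_name,
                 sequences = sequences,
                 length = unname(lens[1L])),
            class = "locus_alignment")
}

#' Write a locus alignment as multi-FASTA
#'
#' @param aln A `locus_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "locus_alignment"))
  seqinr::write.fasta(as.list(aln$sequences), names = names(aln$sequences),
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("Locus alignment '", x$locus, "': ", length(x$sequences),
      " accessions, ", x$length, " aligned sites\n", sep = "")
  invisible(x)
}

#' Read an accession sample sheet
#'
#' The sample sheet maps accessions to species and loci. It is a TSV with
#' header columns `accession_id`, `species_label`, `locus_name`,
#' `source_tag` (values `self` or `genbank`); one row per (accession,
#' locus). Whitespace is trimmed; duplicate (accession, locus) rows and
#' empty species labels are rejected.
#'
#' @param path Path to the TSV sheet.
#' @return A validated `data.frame` (class `sample_sheet`).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", strip.white = TRUE)
  sample_sheet(df)
}

#' Validate a sample-sheet data frame
#'
#' @param df data.frame with columns `accession_id`, `species_label`,
#'   `locus_name`, `source_tag`.
#' @return The validated sheet with class `sample_sheet` prepended.
#' @export
sample_sheet <- function(df) {
  req <- c("accession_id", "species_label", "locus_name", "source_tag")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("sample sheet missing required column(s): ",
         paste(miss, collapse = ", "))
  df <- df[, req, drop = FALSE]
  for (cl in req) df[[cl]] <- trimws(as.character(df[[cl]]))
  if (any(!nzchar(df$accession_id))) stop("empty accession_id in sheet")
  if (any(!nzchar(df$species_label)))
    stop("empty species_label for accession(s): ",
         paste(df$accession_id[!nzchar(df$species_label)], collapse = ", "))
  if (any(!nzchar(df$locus_name))) stop("empty locus_name in sheet")
  bad <- !df$source_tag %in% c("self", "genbank")
  if (any(bad))
    stop("source_tag must be 'self' or 'genbank'; offending rows: ",
         paste(which(bad), collapse = ", "))
  key <- paste(df$accession_id, df$locus_name, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (accession, locus) rows: ",
         paste(unique(paste0(df$accession_id[duplicated(key)], "/",
                             df$locus_name[duplicated(key)])), collapse = ", "))
  sp <- tapply(df$species_label, df$accession_id,
               function(x) length(unique(x)))
  if (any(sp > 1L))
    stop("accession(s) mapped to more than one species: ",
         paste(names(sp)[sp > 1L], collapse = ", "))
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a synonym map
#'
#' Two-column TSV (`alias`, `canonical`) used to merge species labels that
#' are taxonomic synonyms before analysis.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping alias to canonical label.
#' @export
read_synonym_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2L) stop("synonym map needs two columns (alias, canonical)")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Assemble a multi-locus barcode dataset
#'
#' Binds per-locus alignments to a sample sheet (and an optional synonym
#' map, applied to species labels at load time) into the validated dataset
#' the downstream analysis consumes.
#'
#' @param loci Named list of `locus_alignment` objects (names must equal the
#'   `locus` fields) or an unnamed list (names taken from the objects).
#' @param sheet A `sample_sheet` (or data.frame coercible to one).
#' @param synonyms Optional named character vector alias -> canonical label.
#' @return A `barcode_dataset`.
#' @export
barcode_dataset <- function(loci, sheet, synonyms = NULL) {
  if (length(loci) == 0L) stop("dataset has no loci")
  if (!all(vapply(loci, inherits, logical(1), "locus_alignment")))
    stop("all elements of 'loci' must be locus_alignment objects")
  nm <- vapply(loci, function(a) a$locus, character(1))
  names(loci) <- nm
  if (anyDuplicated(nm)) stop("duplicate locus names")
  if (!inherits(sheet, "sample_sheet")) sheet <- sample_sheet(sheet)
  if (!is.null(synonyms) && length(synonyms)) {
    hit <- sheet$species_label %in% names(synonyms)
    sheet$species_label[hit] <- unname(synonyms[sheet$species_label[hit]])
  }
  ds <- structure(list(loci = loci, sheet = sheet,
                       synonyms = synonyms %||% character(0)),
                  class = "barcode_dataset")
  validate_dataset(ds)  # errors propagate; warnings surface
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a barcode dataset
#'
#' Cross-checks every aligned record against the sample sheet and
#' summarises, per locus, the accession, species and singleton-species
#' counts (species represented by exactly one accession are excluded from
#' intra-specific statistics downstream).
#'
#' @param ds A `barcode_dataset`.
#' @return A `data.frame` (class `validation_report`) with one row per
#'   locus: `locus`, `n_accessions`, `n_species`, `n_singleton_species`,
#'   `n_multi_species`. Accessions listed in the sheet without a sequence
#'   are reported as warnings; aligned records absent from the sheet are an
#'   error.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "barcode_dataset"))
  if (length(ds$loci) == 0L) stop("dataset has no loci")
  sheet <- ds$sheet
  out <- lapply(names(ds$loci), function(lc) {
    aln <- ds$loci[[lc]]
    rows <- sheet[sheet$locus_name == lc, , drop = FALSE]
    ids <- names(aln$sequences)
    missing_in_sheet <- setdiff(ids, rows$accession_id)
    if (length(missing_in_sheet))
      stop("locus '", lc, "': aligned accession(s) absent from sample sheet: ",
           paste(missing_in_sheet, collapse = ", "))
    orphan <- setdiff(rows$accession_id, ids)
    if (length(orphan))
      warning("locus '", lc, "': sheet lists accession(s) with no sequence: ",
              paste(orphan, collapse = ", "), call. = FALSE)
    sp <- rows$species_label[match(ids, rows$accession_id)]
    tab <- table(sp)
    data.frame(locus = lc,
               n_accessions = length(ids),
               n_species = length(tab),
               n_singleton_species = sum(tab == 1L),
               n_multi_species = sum(tab >= 2L),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, out)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' Species labels of the accessions in one locus
#'
#' @param ds A `barcode_dataset`.
#' @param locus Locus name.
#' @return Named character vector: accession id -> species label, in
#'   alignment order.
#' @export
locus_species <- function(ds, locus) {
  aln <- ds$loci[[locus]]
  if (is.null(aln)) stop("unknown locus: ", locus)
  rows <- ds$sheet[ds$sheet$locus_name == locus, , drop = FALSE]
  sp <- rows$species_label[match(names(aln$sequences), rows$accession_id)]
  stats::setNames(sp, names(aln$sequences))
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat("Barcode dataset:", length(x$loci), "locus/loci,",
      length(unique(x$sheet$species_label)), "species,",
      length(unique(x$sheet$accession_id)), "accessions\n")
  print(validate_dataset(x))
  invisible(x)
}

# Integer-encode an aligned sequence: A=1 C=2 G=3 T=4, everything else NA
# (gaps, N, ?, IUPAC ambiguity codes -- all skipped under pairwise deletion).
encode_sequence <- function(s) {
  match(strsplit(s, "", fixed = TRUE)[[1L]], .BASES)
}

# rows = accessions, cols = sites
encode_alignment <- function(seqs) {
  m <- t(vapply(seqs, encode_sequence, integer(nchar(seqs[[1L]]))))
  rownames(m) <- names(seqs)
  m
}
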