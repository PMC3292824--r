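## Report rendering and pipeline orchestration. Rendering is a pure
## function of the report bundle: distances at 4 decimals, percentages at
## 2, so re-rendering the same bundle is byte-identical.

.fmt_d <- function(x) {
  ifelse(is.na(x), "NA", formatC(round_half_up(x, 4), format = "f",
                                 digits = 4))
}

.fmt_range <- function(r) paste0(.fmt_d(r[1]), " - ", .fmt_d(r[2]))

#' Tabulate per-locus divergence summaries
#'
#' One row per locus: species counts used for intra- and inter-specific
#' statistics, the intra-specific distance range, and the mean and range
#' of inter-specific distances between species representatives.
#'
#' @param report A `barcode_report` from [analyze_dataset()].
#' @return data.frame.
#' @export
divergence_table <- function(report) {
  rows <- lapply(report$loci, function(l) {
    dv <- l$divergence
    data.frame(locus = dv$locus,
               n_species_intra = dv$n_species_intra,
               intra_range = .fmt_range(dv$intra_range),
               intra_max = round_half_up(dv$intra_max, 4),
               n_species_inter = dv$n_species_inter,
               inter_mean = round_half_up(dv$inter_mean, 4),
               inter_range = .fmt_range(dv$inter_range),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.resolution_row <- function(res) {
  data.frame(scope = res$scope_id,
             n_species_analyzed_A = res$A,
             n_unresolved_pairs = res$n_unresolved_pairs,
             n_species_unresolved_B = res$B,
             n_species_discriminated_C = res$C,
             tau = round_half_up(res$tau %||% 0, 4),
             percent_resolution = sprintf("%.2f", res$percent),
             stringsAsFactors = FALSE)
}

#' Tabulate per-locus resolution results
#'
#' Mirrors the classic per-locus layout: species analyzed (A), unresolved
#' pair count, species involved in unresolved pairs (B), species
#' discriminated (C = A - B), and percent resolution.
#'
#' @param report A `barcode_report`.
#' @return data.frame.
#' @export
resolution_table <- function(report) {
  out <- do.call(rbind, lapply(report$loci,
                               function(l) .resolution_row(l$resolution)))
  rownames(out) <- NULL
  out
}

#' Tabulate per-combination resolution results
#'
#' @param report A `barcode_report`.
#' @return data.frame (header-only when no combinations were analyzed).
#' @export
combination_table <- function(report) {
  if (length(report$combinations) == 0L) {
    return(data.frame(scope = character(0),
                      n_species_analyzed_A = integer(0),
                      n_unresolved_pairs = integer(0),
                      n_species_unresolved_B = integer(0),
                      n_species_discriminated_C = integer(0),
                      tau = numeric(0),
                      percent_resolution = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(report$combinations,
                               function(l) .resolution_row(l$resolution)))
  rownames(out) <- NULL
  out
}

#' List all unresolved species pairs across scopes
#'
#' @param report A `barcode_report`.
#' @return data.frame with columns `scope`, `species_1`, `species_2`.
#' @export
unresolved_pairs_table <- function(report) {
  collect <- function(items) {
    do.call(rbind, lapply(items, function(l) {
      p <- l$resolution$unresolved_pairs
      if (nrow(p) == 0L) return(NULL)
      data.frame(scope = l$resolution$scope_id, species_1 = p[, 1L],
                 species_2 = p[, 2L], stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(collect(report$loci), collect(report$combinations))
  if (is.null(out))
    out <- data.frame(scope = character(0), species_1 = character(0),
                      species_2 = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Render a report bundle to TSV and JSON files
#'
#' Writes `divergence.tsv` (intra/inter summaries), `resolution.tsv`
#' (per-locus), `combos.tsv` (per-combination), `unresolved_pairs.tsv`,
#' `scope_percent.tsv` (every scope's percent, the data behind a
#' resolution-by-scope figure) and `bundle.json`.
#'
#' @param report A `barcode_report`.
#' @param dir Output directory (created if absent).
#' @return Character vector of the written paths, invisibly.
#' @export
render_reports <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(wt(divergence_table(report), "divergence.tsv"),
             wt(resolution_table(report), "resolution.tsv"),
             wt(combination_table(report), "combos.tsv"),
             wt(unresolved_pairs_table(report), "unresolved_pairs.tsv"))
  sc <- rbind(resolution_table(report)[, c("scope", "percent_resolution")],
              combination_table(report)[, c("scope", "percent_resolution")])
  paths <- c(paths, wt(sc, "scope_percent.tsv"))
  bundle <- report_bundle(report)
  pj <- file.path(dir, "bundle.json")
  jsonlite::write_json(bundle, pj, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, pj))
}

#' Convert a report to a plain-list bundle (JSON-ready)
#'
#' @param report A `barcode_report`.
#' @return Nested list mirroring the report, with pair matrices as
#'   two-column data frames.
#' @export
report_bundle <- function(report) {
  scope_list <- function(l) {
    res <- l$resolution
    out <- list(scope = res$scope_id, A = res$A, B = res$B, C = res$C,
                percent = res$percent, tau = res$tau %||% 0,
                n_unresolved_pairs = res$n_unresolved_pairs,
                unresolved_pairs = as.data.frame(res$unresolved_pairs,
                                                 stringsAsFactors = FALSE))
    if (!is.null(l$divergence)) {
      dv <- l$divergence
      out$divergence <- list(
        n_species_intra = dv$n_species_intra %||% NULL,
        intra_max = dv$intra_max %||% NULL,
        intra_range = dv$intra_range %||% NULL,
        n_species_inter = dv$n_species_inter,
        inter_mean = dv$inter_mean,
        inter_range = dv$inter_range)
    }
    out
  }
  list(meta = report$meta,
       loci = lapply(report$loci, scope_list),
       combinations = lapply(report$combinations, scope_list))
}

#' Run the full pipeline from files to rendered reports
#'
#' Reads the per-locus alignments and sample sheet, validates the dataset,
#' builds consensus profiles, computes distances and resolution for every
#' locus and requested combination, and renders the report files.
#'
#' @param alignments Named character vector locus -> FASTA path, or a
#'   `barcode_dataset` (in which case `sheet`/`synonyms` are ignored).
#' @param sheet Path to the sample-sheet TSV.
#' @param synonyms Optional path to a synonym-map TSV.
#' @param combos List of combinations (`combination_spec`s or character
#'   vectors), or the string `"all-subsets"` to enumerate every subset of
#'   up to `k` loci.
#' @param k Maximum subset size for `"all-subsets"`.
#' @param model,deletion Passed to [analyze_dataset()].
#' @param out_dir Output directory for rendered reports; `NULL` skips
#'   rendering.
#' @param verbose Log per-stage counts to stderr.
#' @return The `barcode_report`, invisibly.
#' @export
run_pipeline <- function(alignments, sheet = NULL, synonyms = NULL,
                         combos = list(), k = NULL, model = "k2p",
                         deletion = "pairwise", out_dir = NULL,
                         verbose = TRUE) {
  log <- function(...) if (verbose) message("[barcodegap] ", ...)
  if (inherits(alignments, "barcode_dataset")) {
    ds <- alignments
  } else {
    if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
      stop("alignment paths must be named by locus")
    loci <- lapply(names(alignments), function(lc)
      read_alignment(alignments[[lc]], lc))
    sh <- read_sample_sheet(sheet)
    syn <- if (!is.null(synonyms)) read_synonym_map(synonyms) else NULL
    ds <- barcode_dataset(loci, sh, syn)
  }
  rep0 <- validate_dataset(ds)
  log("validated: ", nrow(rep0), " loci, ",
      length(unique(ds$sheet$species_label)), " species, ",
      length(unique(ds$sheet$accession_id)), " accessions")
  if (identical(combos, "all-subsets")) {
    combos <- all_subset_combinations(names(ds$loci),
                                      k %||% length(ds$loci))
  } else {
    combos <- lapply(combos, function(cs)
      if (is.character(cs)) combination_spec(cs) else cs)
    for (cs in combos) {
      bad <- setdiff(cs$member_loci, names(ds$loci))
      if (length(bad))
        stop("combination requests unknown locus/loci: ",
             paste(bad, collapse = ", "))
    }
  }
  log("analyzing ", nrow(rep0), " locus scope(s) and ", length(combos),
      " combination scope(s)")
  report <- analyze_dataset(ds, combos = combos, model = model,
                            deletion = deletion)
  if (!is.null(out_dir)) {
    render_reports(report, out_dir)
    log("reports written to ", out_dir)
  }
  invisible(report)
}
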