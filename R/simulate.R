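## Ground-truthed simulator of congeneric multi-locus barcode datasets.
##
## Species sit on a star phylogeny: every founding haplotype evolves
## independently from a common ancestor along a branch of length
## inter_divergence/2, so the expected pairwise divergence between any two
## founders is inter_divergence (distances are additive in expectation).
## Conspecific accessions likewise evolve from their founder along branches
## of intra_divergence/2. Evolution is substitution-only (sequences are
## born aligned) and per-site changes are drawn from the exact K2P
## transition-probability matrix for the branch length, so distance
## recovery is unbiased at moderate divergence. Designated plastid-capture
## pairs copy their plastid founders verbatim, emulating species that share
## identical chloroplast haplotypes while remaining distinct at the nuclear
## locus.

#' Simulator configuration for a congeneric genus
#'
#' Defaults emulate a field study of a horticulturally traded orchid genus:
#' 36 species sampled as 292 accessions (three species as singletons, the
#' rest with 8-9 accessions each), four plastid loci plus the nuclear ITS,
#' per-locus expected inter-specific divergences at the magnitudes typical
#' of congeneric plastid barcodes (0.004-0.013 substitutions/site) versus
#' ITS (~0.17), near-zero plastid intra-specific divergence, and one
#' species pair sharing identical plastid haplotypes.
#'
#' @param n_species Number of species.
#' @param accessions_per_species Integer (same for all species) or named
#'   integer vector per species; `NULL` uses the default field-study
#'   pattern (25 species x 9, 8 x 8, 3 singletons = 292 accessions).
#' @param loci data.frame with columns `name`, `length` (bp) and `genome`
#'   (`"nuclear"` or `"plastid"`).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param inter_divergence Named numeric: expected substitutions/site
#'   between any two species' founding haplotypes, per locus.
#' @param intra_divergence Named numeric: expected substitutions/site
#'   between conspecific accessions, per locus.
#' @param capture_pairs List of length-2 character vectors: species pairs
#'   whose plastid founding haplotypes are copied verbatim from the first
#'   member to the second.
#' @param missing_loci Named list species -> character vector of loci that
#'   species lacks entirely.
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(n_species = 36,
                              accessions_per_species = NULL,
                              loci = default_loci(),
                              kappa = 2,
                              inter_divergence = c(ITS = 0.1714,
                                                   matK = 0.0126,
                                                   rbcL = 0.0061,
                                                   rpoB = 0.0077,
                                                   rpoC1 = 0.0042),
                              intra_divergence = c(ITS = 0.003,
                                                   matK = 0.0005,
                                                   rbcL = 0, rpoB = 0,
                                                   rpoC1 = 0),
                              capture_pairs = list(c("species_01",
                                                     "species_02")),
                              missing_loci = list(),
                              seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (n_species < 2L) stop("need at least two species")
  if (kappa <= 0) stop("kappa must be > 0")
  species <- sprintf("species_%02d", seq_len(n_species))
  if (is.null(accessions_per_species)) {
    n_multi <- max(n_species - 3L, 0L)
    acc <- rep(1L, n_species)
    if (n_multi > 0L)
      acc[seq_len(n_multi)] <- rep(c(9L, 8L), c(ceiling(n_multi * 25 / 33),
                                                n_multi))[seq_len(n_multi)]
    accessions_per_species <- stats::setNames(acc, species)
  } else if (length(accessions_per_species) == 1L &&
             is.null(names(accessions_per_species))) {
    accessions_per_species <- stats::setNames(
      rep(as.integer(accessions_per_species), n_species), species)
  } else {
    bad <- setdiff(names(accessions_per_species), species)
    if (length(bad)) stop("unknown species in accession map: ",
                          paste(bad, collapse = ", "))
    full <- stats::setNames(rep(1L, n_species), species)
    full[names(accessions_per_species)] <-
      as.integer(accessions_per_species)
    accessions_per_species <- full
  }
  if (any(accessions_per_species < 1L))
    stop("every species needs >= 1 accession")
  stopifnot(is.data.frame(loci),
            all(c("name", "length", "genome") %in% names(loci)),
            all(loci$genome %in% c("nuclear", "plastid")),
            all(loci$length >= 1))
  for (v in list(inter_divergence, intra_divergence)) {
    miss <- setdiff(loci$name, names(v))
    if (length(miss)) stop("divergence missing for locus/loci: ",
                           paste(miss, collapse = ", "))
    if (any(v < 0)) stop("divergences must be >= 0")
  }
  for (cp in capture_pairs) {
    if (length(cp) != 2L || any(!cp %in% species))
      stop("capture pair references unknown species: ",
           paste(cp, collapse = "/"))
  }
  bad_sp <- setdiff(names(missing_loci), species)
  if (length(bad_sp)) stop("missing_loci references unknown species: ",
                           paste(bad_sp, collapse = ", "))
  for (s in names(missing_loci)) {
    bad <- setdiff(missing_loci[[s]], loci$name)
    if (length(bad)) stop("missing_loci references unknown locus: ",
                          paste(bad, collapse = ", "))
    if (length(setdiff(loci$name, missing_loci[[s]])) == 0L)
      stop("species ", s, " would have no locus at all")
  }
  structure(list(n_species = as.integer(n_species),
                 species = species,
                 accessions_per_species = accessions_per_species,
                 loci = loci, kappa = kappa,
                 inter_divergence = inter_divergence,
                 intra_divergence = intra_divergence,
                 capture_pairs = capture_pairs,
                 missing_loci = missing_loci,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default locus panel for the simulator
#'
#' @return data.frame of the five-locus panel (nuclear ITS plus the four
#'   plastid barcoding loci) with typical amplicon lengths.
#' @export
default_loci <- function() {
  data.frame(name = c("ITS", "matK", "rbcL", "rpoB", "rpoC1"),
             length = c(700L, 800L, 600L, 500L, 520L),
             genome = c("nuclear", rep("plastid", 4L)),
             stringsAsFactors = FALSE)
}

# Exact K80 per-site transition probabilities for a branch of expected
# length d (substitutions/site) with ts/tv rate ratio kappa.
# Returns c(p_same, p_transition, p_each_transversion).
.k2p_site_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)           # beta * t
  at <- kappa * bt                # alpha * t
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts   = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv   = 0.25 - 0.25 * e1)      # each of the two transversion targets
}

# transversion targets by code: A->C/T, C->A/G, G->C/T, T->A/G
.TV1 <- c(2L, 1L, 2L, 1L)
.TV2 <- c(4L, 3L, 4L, 3L)

# parent/child as integer codes 1..4
.evolve_int <- function(parent, d, kappa) {
  if (d == 0) return(parent)
  pr <- .k2p_site_probs(d, kappa)
  u <- stats::runif(length(parent))
  child <- parent
  is_ts <- u >= pr[["same"]] & u < pr[["same"]] + pr[["ts"]]
  is_tv1 <- u >= pr[["same"]] + pr[["ts"]] &
    u < pr[["same"]] + pr[["ts"]] + pr[["tv"]]
  is_tv2 <- u >= pr[["same"]] + pr[["ts"]] + pr[["tv"]]
  child[is_ts] <- .TS_PARTNER[parent[is_ts]]
  child[is_tv1] <- .TV1[parent[is_tv1]]
  child[is_tv2] <- .TV2[parent[is_tv2]]
  child
}

#' Evolve a sequence along a branch under the K2P process
#'
#' Each site mutates independently according to the exact
#' Kimura-2-parameter transition-probability matrix for the branch length,
#' with transition:per-transversion probabilities in ratio kappa:1 (total
#' transversion weight 2). The expected K2P distance between parent and
#' child equals `branch_divergence`.
#'
#' @param parent Character string over A/C/G/T.
#' @param branch_divergence Expected substitutions/site along the branch
#'   (>= 0).
#' @param kappa Transition/transversion rate ratio.
#' @return The child sequence (character string).
#' @export
evolve_sequence <- function(parent, branch_divergence, kappa = 2) {
  stopifnot(branch_divergence >= 0, kappa > 0)
  enc <- encode_sequence(parent)
  if (anyNA(enc)) stop("parent sequence must contain only A/C/G/T")
  paste(.BASES[.evolve_int(enc, branch_divergence, kappa)], collapse = "")
}

#' Simulate a congeneric multi-locus barcode dataset with ground truth
#'
#' Generates founding haplotypes per species per locus on a star phylogeny,
#' copies plastid founders verbatim within capture pairs, evolves
#' accessions from the founders, assembles the loci and sample sheet into a
#' validated `barcode_dataset`, and records the ground truth: for each
#' locus, the exact set of species pairs whose founding haplotypes are
#' identical (the pairs that must stay unresolved when intra-specific noise
#' is zero).
#'
#' @param cfg A `simulation_config`.
#' @return A `genus_simulation`: list with `dataset` (`barcode_dataset`),
#'   `truth` (see [truth_unresolved()]) and `config`.
#' @export
simulate_genus <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  species <- cfg$species
  founders <- list()   # locus -> matrix species x sites (int codes)
  for (li in seq_len(nrow(cfg$loci))) {
    lc <- cfg$loci$name[li]
    len <- cfg$loci$length[li]
    ancestor <- sample.int(4L, len, replace = TRUE)
    half <- cfg$inter_divergence[[lc]] / 2
    m <- t(vapply(species, function(s) .evolve_int(ancestor, half,
                                                   cfg$kappa),
                  integer(len)))
    rownames(m) <- species
    if (cfg$loci$genome[li] == "plastid") {
      for (cp in cfg$capture_pairs) m[cp[2L], ] <- m[cp[1L], ]
    }
    founders[[lc]] <- m
  }
  # ground truth: founder pairs with identical haplotypes, per locus
  truth_pairs <- lapply(founders, function(m) {
    out <- list()
    for (i in seq_len(nrow(m) - 1L)) {
      for (j in seq.int(i + 1L, nrow(m))) {
        if (all(m[i, ] == m[j, ]))
          out[[length(out) + 1L]] <- c(rownames(m)[i], rownames(m)[j])
      }
    }
    .as_pair_matrix(out)
  })
  # accessions
  aln_list <- list()
  sheet_rows <- list()
  for (li in seq_len(nrow(cfg$loci))) {
    lc <- cfg$loci$name[li]
    half_intra <- cfg$intra_divergence[[lc]] / 2
    seqs <- character(0)
    for (s in species) {
      if (lc %in% (cfg$missing_loci[[s]] %||% character(0))) next
      n_acc <- cfg$accessions_per_species[[s]]
      for (k in seq_len(n_acc)) {
        id <- sprintf("%s_acc%02d", s, k)
        child <- .evolve_int(founders[[lc]][s, ], half_intra, cfg$kappa)
        seqs[[id]] <- paste(.BASES[child], collapse = "")
        sheet_rows[[length(sheet_rows) + 1L]] <-
          data.frame(accession_id = id, species_label = s,
                     locus_name = lc, source_tag = "self",
                     stringsAsFactors = FALSE)
      }
    }
    aln_list[[lc]] <- locus_alignment(lc, seqs)
  }
  sheet <- sample_sheet(do.call(rbind, sheet_rows))
  ds <- barcode_dataset(aln_list, sheet)
  truth <- list(unresolved = truth_pairs,
                loci = cfg$loci,
                species = species,
                missing_loci = cfg$missing_loci)
  structure(list(dataset = ds, truth = truth, config = cfg),
            class = "genus_simulation")
}

#' @export
print.genus_simulation <- function(x, ...) {
  cat("Simulated genus: ", x$config$n_species, " species, ",
      nrow(x$config$loci), " loci, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Expected unresolved pairs for a locus or combination, from ground truth
#'
#' A species pair stays unresolved under a zero-threshold scope iff its
#' founding haplotypes are identical at every member locus (the
#' concatenated distance pools site counts, so it is zero iff zero in all
#' members). Species lacking any member locus are outside the scope and
#' excluded.
#'
#' @param truth The `truth` element of a `genus_simulation`.
#' @param members Character vector of member loci.
#' @return Two-column character matrix of expected unresolved species
#'   pairs (canonical order).
#' @export
truth_unresolved <- function(truth, members) {
  stopifnot(all(members %in% names(truth$unresolved)))
  in_scope <- vapply(truth$species, function(s)
    !any(members %in% (truth$missing_loci[[s]] %||% character(0))),
    logical(1))
  scope_sp <- truth$species[in_scope]
  sets <- lapply(truth$unresolved[members], function(m)
    paste(m[, 1L], m[, 2L], sep = "\r"))
  common <- Reduce(intersect, sets)
  if (length(common) == 0L) return(.as_pair_matrix(list()))
  parts <- strsplit(common, "\r", fixed = TRUE)
  keep <- vapply(parts, function(p) all(p %in% scope_sp), logical(1))
  .as_pair_matrix(parts[keep])
}

#' Write a simulated dataset to disk
#'
#' Emits one aligned multi-FASTA per locus, the sample sheet TSV, the
#' ground-truth unresolved pairs as JSON and an echo of the configuration.
#'
#' @param sim A `genus_simulation`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "genus_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lc in names(sim$dataset$loci))
    write_alignment(sim$dataset$loci[[lc]],
                    file.path(dir, paste0(lc, ".fasta")))
  utils::write.table(sim$dataset$sheet,
                     file.path(dir, "sample_sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_json <- lapply(sim$truth$unresolved, function(m)
    apply(m, 1L, function(r) paste(r, collapse = " / ")))
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  cfg <- sim$config
  cfg_echo <- list(n_species = cfg$n_species,
                   accessions_per_species =
                     as.list(cfg$accessions_per_species),
                   loci = cfg$loci, kappa = cfg$kappa,
                   inter_divergence = as.list(cfg$inter_divergence),
                   intra_divergence = as.list(cfg$intra_divergence),
                   capture_pairs = cfg$capture_pairs,
                   missing_loci = cfg$missing_loci, seed = cfg$seed)
  jsonlite::write_json(cfg_echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
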