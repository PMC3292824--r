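## The core statistic: threshold-based pair discrimination and percent
## species resolution, per locus and per multi-locus concatenation.
##
## Two species are distinct when their inter-specific distance is strictly
## greater than the scope's maximum intra-specific distance (tau). With
## tau = 0 this reduces to counting species pairs with a zero distance
## estimate. Percent resolution = (A - B) * 100 / A, where A is the number
## of species analyzed and B the number of distinct species involved in at
## least one unresolved pair.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages and distances
#' here use conventional half-up rounding (80.555... -> 80.56).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Scope threshold: maximum intra-specific distance
#'
#' @param intra An intra-specific summary from [intra_specific_summary()]
#'   (or any list with an `intra_max` element), or a bare numeric vector of
#'   intra-specific distances.
#' @return `tau`, the maximum intra-specific distance (0 when no
#'   intra-specific pair exists).
#' @export
locus_threshold <- function(intra) {
  if (is.numeric(intra))
    return(if (length(intra)) max(intra) else 0)
  stopifnot(is.list(intra), !is.null(intra$intra_max))
  intra$intra_max
}

#' Discriminate one species pair against a threshold
#'
#' Resolved iff the inter-specific distance is strictly greater than
#' `tau`. A saturated (undefined, log argument <= 0) distance implies
#' divergence far beyond any plausible threshold and is treated as
#' resolved, with a warning.
#'
#' @param d_inter Inter-specific distance (substitutions/site); may be `NA`
#'   if `saturated` is `TRUE`.
#' @param tau Scope threshold (maximum intra-specific distance).
#' @param saturated Logical: is the pair's distance undefined by
#'   saturation?
#' @return `"resolved"` or `"unresolved"`.
#' @examples
#' discriminate_pair(0.0172, 0.0101)  # resolved
#' discriminate_pair(0, 0)            # unresolved
#' @export
discriminate_pair <- function(d_inter, tau, saturated = FALSE) {
  stopifnot(tau >= 0)
  if (saturated || (!is.na(d_inter) && is.infinite(d_inter))) {
    warning("saturated pair treated as resolved", call. = FALSE)
    return("resolved")
  }
  if (is.na(d_inter)) stop("undefined, non-saturated distance")
  if (d_inter > tau) "resolved" else "unresolved"
}

#' Percent species resolution from an unresolved-pair list
#'
#' B is the number of distinct species appearing in at least one unresolved
#' pair (a species in several pairs is counted once); the statistic is
#' (A - B) * 100 / A, reported half-up to two decimals.
#'
#' @param A Total number of species analyzed in the scope.
#' @param unresolved_pairs Unresolved species pairs: a two-column
#'   matrix/data.frame or a list of length-2 character vectors; may be
#'   empty.
#' @param species Optional character vector of the A species labels; when
#'   given, pairs referencing unknown species are an error.
#' @param scope_id Identifier of the locus or combination (for reporting).
#' @return A `resolution_result`: list with `scope_id`, `A`, `B`,
#'   `C = A - B`, `percent` (2 decimals), `unresolved_pairs` (two-column
#'   character matrix), `n_unresolved_pairs`.
#' @examples
#' resolution_percent(36, list())                    # 100
#' resolution_percent(36, list(c("s1", "s2"), c("s1", "s3")))  # 91.67
#' @export
resolution_percent <- function(A, unresolved_pairs, species = NULL,
                               scope_id = NA_character_) {
  stopifnot(A >= 1)
  pairs <- .as_pair_matrix(unresolved_pairs)
  members <- unique(as.vector(pairs))
  if (!is.null(species)) {
    unknown <- setdiff(members, species)
    if (length(unknown))
      stop("unresolved pair references unknown species: ",
           paste(unknown, collapse = ", "))
    if (length(species) != A)
      stop("species list length does not match A")
  }
  B <- length(members)
  if (B > A) stop("more unresolved species than species analyzed")
  structure(list(scope_id = scope_id,
                 A = as.integer(A),
                 B = as.integer(B),
                 C = as.integer(A - B),
                 percent = round_half_up((A - B) * 100 / A, 2),
                 unresolved_pairs = pairs,
                 n_unresolved_pairs = nrow(pairs)),
            class = "resolution_result")
}

.as_pair_matrix <- function(pairs) {
  if (is.null(pairs) || (is.list(pairs) && length(pairs) == 0L) ||
      (is.matrix(pairs) && nrow(pairs) == 0L) || length(pairs) == 0L) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("species_1", "species_2"))))
  }
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (is.list(pairs)) {
    if (any(lengths(pairs) != 2L)) stop("each pair must have two species")
    pairs <- do.call(rbind, lapply(pairs, as.character))
  }
  if (!is.matrix(pairs) || ncol(pairs) != 2L)
    stop("unresolved pairs must form a two-column structure")
  if (any(pairs[, 1] == pairs[, 2]))
    stop("a species cannot pair with itself")
  # canonical order within pair and across rows, for determinism
  swap <- pairs[, 1] > pairs[, 2]
  pairs[swap, ] <- pairs[swap, c(2, 1), drop = FALSE]
  pairs <- unique(pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE])
  dimnames(pairs) <- list(NULL, c("species_1", "species_2"))
  pairs
}

#' @export
print.resolution_result <- function(x, ...) {
  cat("Scope ", x$scope_id, ": A = ", x$A, ", unresolved pairs = ",
      x$n_unresolved_pairs, ", B = ", x$B, ", C = ", x$C,
      ", resolution = ", sprintf("%.2f%%", x$percent), "\n", sep = "")
  invisible(x)
}

#' Specify a multi-locus combination
#'
#' @param member_loci Character vector of distinct locus names (order is
#'   the concatenation order).
#' @param id Scope identifier; defaults to the members joined with `+`.
#' @return A `combination_spec`.
#' @export
combination_spec <- function(member_loci, id = NULL) {
  if (length(member_loci) < 1L) stop("a combination needs >= 1 locus")
  if (anyDuplicated(member_loci)) stop("combination members must be distinct")
  structure(list(member_loci = member_loci,
                 id = id %||% paste(member_loci, collapse = "+")),
            class = "combination_spec")
}

#' All locus subsets up to a given size
#'
#' Enumerates every non-empty subset of `loci` with at most `k` members as
#' `combination_spec`s (4 loci, k = 4 gives 15 scopes: 4 singles, 6 pairs,
#' 4 triples, 1 quadruple).
#'
#' @param loci Character vector of locus names.
#' @param k Maximum subset size (defaults to all loci).
#' @return List of `combination_spec`s.
#' @export
all_subset_combinations <- function(loci, k = length(loci)) {
  if (k > length(loci)) stop("k exceeds the number of loci")
  out <- list()
  for (m in seq_len(k)) {
    cmb <- utils::combn(loci, m, simplify = FALSE)
    out <- c(out, lapply(cmb, combination_spec))
  }
  out
}

#' Concatenate loci into a combination scope
#'
#' The species set of a combination is the intersection of species having a
#' representative for every member locus; its representatives are the
#' per-locus representatives concatenated in member order. The
#' combination's intra-specific distances (hence its tau) are computed on
#' concatenated accession-level sequences, restricted to accessions
#' sequenced for all member loci; the concatenated distance is therefore
#' the model distance on pooled site counts, exactly as if the concatenated
#' alignment were analysed directly.
#'
#' @param profiles A `species_profiles` object.
#' @param spec A `combination_spec` (or character vector of loci).
#' @param ds The `barcode_dataset` (accession-level data for intra
#'   statistics).
#' @return List with `scope_id`, `member_loci`, `species`,
#'   `representatives` (named character vector), `intra_alignment` (a
#'   `locus_alignment` of concatenated accession sequences, or NULL if no
#'   accession spans all members), `intra_species` (accession -> species).
#' @export
combine_loci <- function(profiles, spec, ds) {
  if (is.character(spec)) spec <- combination_spec(spec)
  stopifnot(inherits(spec, "combination_spec"),
            inherits(ds, "barcode_dataset"))
  absent <- setdiff(spec$member_loci, names(ds$loci))
  if (length(absent))
    stop("combination references unknown locus/loci: ",
         paste(absent, collapse = ", "))
  keep <- vapply(profiles, function(p)
    all(spec$member_loci %in% names(p$representatives)), logical(1))
  sp_set <- names(profiles)[keep]
  if (length(sp_set) == 0L)
    stop("no species has all member loci: ", spec$id)
  reps <- vapply(sp_set, function(s)
    paste(profiles[[s]]$representatives[spec$member_loci], collapse = ""),
    character(1))
  # accession-level concatenation for intra statistics
  per_locus_ids <- lapply(spec$member_loci, function(lc)
    names(ds$loci[[lc]]$sequences))
  acc <- Reduce(intersect, per_locus_ids)
  intra_aln <- NULL
  intra_sp <- character(0)
  if (length(acc)) {
    cat_seqs <- vapply(acc, function(a)
      paste(vapply(spec$member_loci,
                   function(lc) ds$loci[[lc]]$sequences[[a]], character(1)),
            collapse = ""), character(1))
    sheet <- ds$sheet[ds$sheet$locus_name == spec$member_loci[1L], ,
                      drop = FALSE]
    intra_sp <- stats::setNames(
      sheet$species_label[match(acc, sheet$accession_id)], acc)
    keep_acc <- intra_sp %in% sp_set
    if (any(keep_acc)) {
      intra_aln <- locus_alignment(spec$id, cat_seqs[keep_acc])
      intra_sp <- intra_sp[keep_acc]
    }
  }
  list(scope_id = spec$id, member_loci = spec$member_loci,
       species = sp_set, representatives = reps,
       intra_alignment = intra_aln, intra_species = intra_sp)
}

# Resolve one scope given representatives and a tau.
.resolve_scope <- function(representatives, tau, scope_id, model, deletion) {
  inter <- inter_specific_matrix(representatives, model = model,
                                 deletion = deletion)
  dm <- inter$matrix
  n <- length(dm$labels)
  pairs <- list()
  n_sat <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (dm$undefined[i, j]) { n_sat <- n_sat + 1L; next }  # resolved
      if (dm$d[i, j] <= tau)
        pairs[[length(pairs) + 1L]] <- c(dm$labels[i], dm$labels[j])
    }
  }
  if (n_sat > 0L)
    warning(scope_id, ": ", n_sat,
            " saturated species pair(s) treated as resolved", call. = FALSE)
  res <- resolution_percent(n, pairs, species = dm$labels,
                            scope_id = scope_id)
  res$tau <- tau
  res$n_saturated_pairs <- n_sat
  list(resolution = res, inter = inter)
}

#' Run the full discrimination analysis on a dataset
#'
#' For every locus: intra-specific summary (accession level, species with
#' at least two accessions), the tau threshold, the inter-specific
#' representative matrix and the resolution result. For every requested
#' combination: the concatenated scope, its concatenated-intra tau and the
#' resolution result.
#'
#' @param ds A `barcode_dataset`.
#' @param combos List of `combination_spec`s (or character vectors of
#'   loci); default none.
#' @inheritParams pairwise_distance_matrix
#' @return A `barcode_report`: list with `loci` (per locus: `divergence`
#'   summary, `resolution`), `combinations` (per combo: `resolution`,
#'   `divergence`), `meta` (model, deletion policy).
#' @export
analyze_dataset <- function(ds, combos = list(), model = "k2p",
                            deletion = "pairwise") {
  stopifnot(inherits(ds, "barcode_dataset"))
  validate_dataset(ds)
  profiles <- build_species_profiles(ds)
  loci_out <- list()
  for (lc in names(ds$loci)) {
    sp <- locus_species(ds, lc)
    intra <- intra_specific_summary(ds$loci[[lc]], sp, model = model,
                                    deletion = deletion)
    tau <- locus_threshold(intra)
    reps <- locus_representatives(profiles, lc)
    sc <- .resolve_scope(reps, tau, lc, model, deletion)
    loci_out[[lc]] <- list(
      divergence = list(locus = lc,
                        n_species_intra = intra$n_species,
                        intra_max = intra$intra_max,
                        intra_range = intra$intra_range,
                        n_species_inter = sc$inter$n_species,
                        inter_mean = sc$inter$mean,
                        inter_range = sc$inter$range,
                        n_undefined = sc$inter$n_undefined),
      intra = intra,
      resolution = sc$resolution)
  }
  combos <- lapply(combos, function(cs)
    if (is.character(cs)) combination_spec(cs) else cs)
  combos_out <- list()
  for (cs in combos) {
    cmb <- combine_loci(profiles, cs, ds)
    if (length(cmb$species) < 2L)
      stop("combination ", cmb$scope_id, " has fewer than two species")
    tau <- 0
    if (!is.null(cmb$intra_alignment) &&
        length(cmb$intra_species) >= 2L &&
        any(table(cmb$intra_species) >= 2L)) {
      intra <- intra_specific_summary(cmb$intra_alignment, cmb$intra_species,
                                      model = model, deletion = deletion)
      tau <- locus_threshold(intra)
    }
    sc <- .resolve_scope(cmb$representatives, tau, cmb$scope_id, model,
                         deletion)
    combos_out[[cmb$scope_id]] <- list(
      divergence = list(locus = cmb$scope_id,
                        n_species_inter = sc$inter$n_species,
                        inter_mean = sc$inter$mean,
                        inter_range = sc$inter$range,
                        n_undefined = sc$inter$n_undefined),
      resolution = sc$resolution)
  }
  structure(list(loci = loci_out, combinations = combos_out,
                 meta = list(model = model, deletion = deletion,
                             n_loci = length(ds$loci))),
            class = "barcode_report")
}

#' @export
print.barcode_report <- function(x, ...) {
  cat("Barcode discrimination report (", toupper(x$meta$model), ", ",
      x$meta$deletion, " deletion)\n", sep = "")
  for (lc in names(x$loci)) print(x$loci[[lc]]$resolution)
  for (cb in names(x$combinations)) print(x$combinations[[cb]]$resolution)
  invisible(x)
}

#' Construct a species-pair list with given pair and species counts
#'
#' Builds a deterministic list of `n_pairs` distinct unordered species
#' pairs whose species union has exactly `n_species_union` members --
#' useful for replaying published per-locus tallies (pairs with zero
#' distance, species involved) through [resolution_percent()] without the
#' underlying sequences. When `n_pairs >= n_species_union - 1` the graph is
#' a star plus extra edges; otherwise it is a forest (one chain plus
#' single-edge components), which requires `2 * n_pairs >=
#' n_species_union`.
#'
#' @param n_pairs Number of pairs (>= 0).
#' @param n_species_union Number of distinct species across the pairs.
#' @param labels Optional character vector supplying at least
#'   `n_species_union` species labels; defaults to `sp001`, `sp002`, ...
#' @return Two-column character matrix of pairs.
#' @examples
#' p <- pair_list_with_counts(5, 7)   # e.g. a 5-pair, 7-species tally
#' resolution_percent(36, p)$percent  # 80.56
#' @export
pair_list_with_counts <- function(n_pairs, n_species_union, labels = NULL) {
  stopifnot(n_pairs >= 0, n_species_union >= 0)
  if (n_pairs == 0L) {
    if (n_species_union != 0L)
      stop("zero pairs cannot cover any species")
    return(.as_pair_matrix(list()))
  }
  if (n_species_union < 2L) stop("pairs need at least two species")
  if (is.null(labels)) labels <- sprintf("sp%03d", seq_len(n_species_union))
  if (length(labels) < n_species_union) stop("not enough labels")
  s <- labels[seq_len(n_species_union)]
  pairs <- list()
  if (n_pairs >= n_species_union - 1L) {
    for (i in seq.int(2L, n_species_union))
      pairs[[length(pairs) + 1L]] <- c(s[1L], s[i])
    extra_needed <- n_pairs - (n_species_union - 1L)
    if (extra_needed > 0L) {
      cand <- utils::combn(s[-1L], 2L, simplify = FALSE)
      if (length(cand) < extra_needed)
        stop("n_pairs exceeds the maximum for this species union")
      pairs <- c(pairs, cand[seq_len(extra_needed)])
    }
  } else {
    # forest: one chain plus single-edge components
    k <- n_species_union - n_pairs          # number of components
    if (n_pairs < k)
      stop("too few pairs to cover ", n_species_union, " species")
    chain_edges <- n_pairs - (k - 1L)        # chain covers chain_edges + 1
    idx <- 1L
    for (i in seq_len(chain_edges)) {
      pairs[[length(pairs) + 1L]] <- c(s[idx], s[idx + 1L])
      idx <- idx + 1L
    }
    idx <- idx + 1L
    for (i in seq_len(k - 1L)) {
      pairs[[length(pairs) + 1L]] <- c(s[idx], s[idx + 1L])
      idx <- idx + 2L
    }
  }
  .as_pair_matrix(pairs)
}
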