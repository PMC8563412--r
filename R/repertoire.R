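#' Canonical variant per allergen family
#'
#' Genetic and splice variants of one allergen carry near-identical
#' peptides; counting them all would count the same epitope repeatedly.
#' The canonical variant of each family is the one with the
#' lexicographically smallest `protein_id` (e.g. `"Ara h 2.01"`).
#'
#' @param library peptide annotation table.
#' @param override named character vector `family -> protein_id` forcing a
#'   choice.
#' @return character vector of canonical protein ids, named by family.
#' @export
canonical_variants <- function(library, override = NULL) {
  fam <- split(library$parent, library$family)
  canon <- vapply(fam, function(p) sort(unique(p))[1], character(1))
  if (!is.null(override)) canon[names(override)] <- override
  canon
}

#' Reactive epitope set of one sample column
#'
#' Wild-type tiles from canonical variants whose replicate-averaged
#' Z-score strictly exceeds the threshold.
#'
#' @param z_avg replicate-averaged Z matrix.
#' @param column column of `z_avg` (a `subject|isotype|timepoint` key).
#' @param library peptide annotation.
#' @param threshold reactivity cutoff (default 3.5).
#' @param override passed to [canonical_variants()].
#' @return character vector of reactive wild-type tile ids.
#' @export
epitope_set <- function(z_avg, column, library, threshold = 3.5,
                        override = NULL) {
  canon <- canonical_variants(library, override)
  wt <- library[library$is_wildtype & library$parent %in% canon, ,
                drop = FALSE]
  ids <- intersect(wt$peptide_id, rownames(z_avg))
  ids[z_avg[ids, column] > threshold]
}

#' Repertoire breadth
#'
#' Number of variant-deduplicated wild-type peptides recognized by a
#' sample at mean Z > threshold.
#'
#' @inheritParams epitope_set
#' @return integer count.
#' @export
breadth <- function(z_avg, column, library, threshold = 3.5,
                    override = NULL) {
  length(epitope_set(z_avg, column, library, threshold, override))
}

#' Seroprevalence of a peptide across a cohort
#'
#' Fraction of subjects (columns) whose mean Z-score for the tile strictly
#' exceeds the reactivity threshold. A peptide is "public" when recognized
#' by strictly more than `public_threshold` (default 30%) of the cohort,
#' otherwise "private".
#'
#' @param z_avg replicate-averaged Z matrix.
#' @param tile_id wild-type peptide id (row of `z_avg`).
#' @param columns cohort columns of `z_avg` (one per subject).
#' @param threshold reactivity cutoff.
#' @return fraction in [0, 1].
#' @export
seroprevalence <- function(z_avg, tile_id, columns, threshold = 3.5) {
  mean(z_avg[tile_id, columns] > threshold)
}

#' @rdname seroprevalence
#' @param prevalence a seroprevalence fraction.
#' @param public_threshold public/private cutoff (strict `>`).
#' @export
classify_public <- function(prevalence, public_threshold = 0.30) {
  prevalence > public_threshold
}

#' Jaccard index between two epitope sets
#'
#' `|A n B| / |A u B|`; 0 when both sets are empty (convention).
#'
#' @param a,b character vectors of epitope (tile) ids.
#' @return value in [0, 1].
#' @export
jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(0)
  length(intersect(a, b)) / length(u)
}

#' Flatten a footprint into a comparable vector
#'
#' Defined (substitution, position) cells of the `display` (default) or
#' `rel` matrix, named `"res@pos"`, so vectors from different samples can
#' be matched cell-by-cell.
#'
#' @param fp a [relative_enrichment()] footprint.
#' @param use `"display"` or `"rel"`.
#' @return named numeric vector.
#' @export
footprint_vector <- function(fp, use = c("display", "rel")) {
  use <- match.arg(use)
  m <- fp[[use]]
  idx <- which(!is.na(m), arr.ind = TRUE)
  setNames(m[idx], paste0(rownames(m)[idx[, 1]], "@", idx[, 2]))
}

#' Pairwise Pearson correlation between footprints
#'
#' Correlates footprint vectors on their shared defined cells. Pairs with
#' fewer than `min_shared` shared cells, or with a constant vector, are
#' reported as `NA`.
#'
#' @param vectors named list of [footprint_vector()]s (names = subjects).
#' @param min_shared minimum shared cells per pair (default 10).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
footprint_correlation <- function(vectors, min_shared = 10L) {
  n <- length(vectors)
  if (n < 2L) stop("need at least two footprint vectors")
  nm <- names(vectors)
  r <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  diag(r) <- 1
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- intersect(names(vectors[[i]]), names(vectors[[j]]))
    if (length(shared) < min_shared) next
    x <- vectors[[i]][shared]
    y <- vectors[[j]][shared]
    if (sd(x) == 0 || sd(y) == 0) next
    r[i, j] <- r[j, i] <- cor(x, y)
  }
  r
}

#' Shared and dominant footprints
#'
#' Two subjects share a footprint when their pairwise Pearson correlation
#' strictly exceeds `threshold` (0.75). Footprint groups are the connected
#' components of the resulting sharing graph; the dominant footprint is
#' the largest group (ties broken by the group containing the
#' lexicographically smallest member).
#'
#' @param corr symmetric correlation matrix ([footprint_correlation()]).
#' @param threshold sharing cutoff (strict `>`).
#' @return list: `membership` (group index per subject), `dominant`
#'   (members of the dominant group), `dominant_size`, `n_groups`.
#' @export
dominant_footprint <- function(corr, threshold = 0.75) {
  nm <- rownames(corr)
  adj <- !is.na(corr) & corr > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  member <- setNames(comp$membership, nm)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(b) sort(nm[member == b])[1], character(1))
    best <- best[order(firsts)][1]
  }
  list(membership = member, dominant = sort(nm[member == best]),
       dominant_size = max(sizes), n_groups = comp$no)
}

#' Within-subject IgE/IgG footprint similarity
#'
#' Pearson correlation between a subject's two isotype footprints for the
#' same tile (typically week-0 IgE vs week-52 IgG) on shared defined
#' cells; pairs with `r > threshold` are flagged highly similar.
#'
#' @param v_ige,v_igg [footprint_vector()]s for the same (subject, tile).
#' @param threshold similarity flag cutoff (0.75).
#' @param min_shared minimum shared cells.
#' @return list: `r`, `similar` flag, `n_shared` (both NA-safe).
#' @export
ige_igg_similarity <- function(v_ige, v_igg, threshold = 0.75,
                               min_shared = 10L) {
  shared <- intersect(names(v_ige), names(v_igg))
  if (length(shared) < min_shared ||
      sd(v_ige[shared]) == 0 || sd(v_igg[shared]) == 0)
    return(list(r = NA_real_, similar = NA, n_shared = length(shared)))
  r <- cor(v_ige[shared], v_igg[shared])
  list(r = r, similar = r > threshold, n_shared = length(shared))
}

#' Longitudinal fold change of pre-existing epitopes
#'
#' For peptides reactive at baseline (Z > `threshold` at week 0), the
#' per-peptide `log2(Z_post / Z_pre)` with Z floored at `floor_z` before
#' the ratio; returns the mean and its standard error.
#'
#' @param z_pre,z_post named Z vectors (or matrix columns) for the same
#'   subject/isotype at the two timepoints.
#' @param threshold baseline reactivity cutoff (default 3.5).
#' @param floor_z floor applied to Z before the log-ratio (default 0.1).
#' @return list: `mean_log2fc`, `sem`, `n`, `log2fc` (per peptide).
#' @export
preexisting_fold_change <- function(z_pre, z_post, threshold = 3.5,
                                    floor_z = 0.1) {
  pre <- which(z_pre > threshold)
  if (!length(pre))
    return(list(mean_log2fc = NA_real_, sem = NA_real_, n = 0L,
                log2fc = numeric()))
  fc <- log2(pmax(z_post[pre], floor_z) / pmax(z_pre[pre], floor_z))
  list(mean_log2fc = mean(fc),
       sem = if (length(fc) > 1L) sd(fc) / sqrt(length(fc)) else NA_real_,
       n = length(fc), log2fc = fc)
}

#' IgE-only / IgG-only / shared epitope fractions
#'
#' Partition of the union of a subject's IgE and IgG epitope sets into the
#' exclusively-IgE, exclusively-IgG, and shared fractions (summing to 1).
#'
#' @param set_ige,set_igg epitope id vectors.
#' @return named numeric vector (`ige_only`, `igg_only`, `shared`), or
#'   NAs when both sets are empty.
#' @export
overlap_categories <- function(set_ige, set_igg) {
  u <- union(set_ige, set_igg)
  if (!length(u))
    return(c(ige_only = NA_real_, igg_only = NA_real_, shared = NA_real_))
  both <- intersect(set_ige, set_igg)
  c(ige_only = length(setdiff(set_ige, set_igg)) / length(u),
    igg_only = length(setdiff(set_igg, set_ige)) / length(u),
    shared = length(both) / length(u))
}
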