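#' Collect wild-type and mutant enrichments for one tile in one sample
#'
#' Gathers the fold-change enrichment of a wild-type tile and of all its
#' saturation mutants from an enrichment matrix, arranged as a 20
#' (substituted residue) x tile-length matrix with `NA` at each position's
#' wild-type residue and at unobserved mutants.
#'
#' @param enr peptide x sample enrichment matrix ([enrichment()]).
#' @param library peptide annotation (wild-type + mutants).
#' @param tile_id peptide id of the wild-type tile.
#' @param sample column of `enr` to use.
#' @param wt_z optional wild-type Z-score carried along for gating.
#' @return object of class `enrichment_set`.
#' @export
enrichment_set <- function(enr, library, tile_id, sample, wt_z = NA_real_) {
  wt <- library[library$peptide_id == tile_id, , drop = FALSE]
  if (nrow(wt) != 1L || !wt$is_wildtype)
    stop("tile_id must name one wild-type record: ", tile_id)
  muts <- library[!library$is_wildtype & library$parent == wt$parent &
                    library$start == wt$start & library$end == wt$end, ,
                  drop = FALSE]
  len <- nchar(wt$aa_seq)
  mm <- matrix(NA_real_, 20L, len, dimnames = list(AA20, NULL))
  if (nrow(muts))
    mm[cbind(match(muts$mut_residue, AA20), muts$mut_position)] <-
      enr[muts$peptide_id, sample]
  structure(list(tile_id = tile_id, sample = sample,
                 parent = wt$parent, start = wt$start, end = wt$end,
                 wt_seq = wt$aa_seq,
                 wt_enrichment = unname(enr[tile_id, sample]),
                 mutant_enrichment = mm, wt_zscore = wt_z),
            class = "enrichment_set")
}

#' Adjusted wild-type enrichment estimate
#'
#' The wild-type peptide's own enrichment is a noisy single measurement;
#' a more robust estimate is the mean of the wild-type value and the top
#' 50% (top `ceiling(k/2)` of the k available) alanine-mutant enrichments,
#' alanine substitutions being mostly tolerated at non-critical positions.
#' Positions whose wild-type residue is alanine contribute no alanine
#' mutant; with no alanine mutants at all the wild-type value is returned
#' unchanged.
#'
#' @param set an [enrichment_set()].
#' @return scalar estimate of the tile's true enrichment.
#' @export
wildtype_estimate <- function(set) {
  ala <- set$mutant_enrichment["A", ]
  ala <- ala[!is.na(ala)]
  if (!length(ala)) return(set$wt_enrichment)
  top <- sort(ala, decreasing = TRUE)[seq_len(ceiling(length(ala) / 2))]
  mean(c(set$wt_enrichment, top))
}

#' Relative-to-wild-type enrichment footprint
#'
#' Divides each mutant's enrichment by the adjusted wild-type estimate to
#' give the relative-to-wild-type enrichment `rel`; values below 1 mean the
#' substitution disrupts antibody binding. The display transform
#' `-log10(1 / rel)` (= `log10(rel)`) is what footprint heatmaps plot.
#' Critical residues are called per [critical_residues()].
#'
#' @param set an [enrichment_set()].
#' @param critical_fraction threshold for the critical-residue call.
#' @return object of class `footprint`: `rel` and `display` matrices
#'   (20 x tile length, `NA` at wild-type/unobserved cells), per-position
#'   `critical` logical, `wt_estimate`, and provenance fields; `NULL` (with
#'   a warning) when the wild-type estimate is not positive.
#' @export
relative_enrichment <- function(set, critical_fraction = 0.40) {
  est <- wildtype_estimate(set)
  if (!is.finite(est) || est <= 0) {
    warning("non-positive wild-type estimate for ", set$tile_id,
            " in ", set$sample, "; footprint unavailable")
    return(NULL)
  }
  rel <- set$mutant_enrichment / est
  fp <- structure(list(tile_id = set$tile_id, sample = set$sample,
                       parent = set$parent, start = set$start,
                       end = set$end, wt_seq = set$wt_seq,
                       rel = rel, display = log10(rel),
                       wt_estimate = est, wt_zscore = set$wt_zscore),
                  class = "footprint")
  fp$critical <- critical_residues(fp, critical_fraction)
  fp
}

#' Critical-residue calls for a footprint
#'
#' A position is critical for antibody binding when the median enrichment
#' of its mutants is strictly below `fraction` (default 40%) of the
#' wild-type estimate, i.e. `median(rel) < fraction`. Positions with no
#' observed mutants are `NA` and excluded downstream.
#'
#' @param fp a [relative_enrichment()] footprint.
#' @param fraction critical cutoff on the median relative enrichment.
#' @return logical vector, one element per tile position.
#' @export
critical_residues <- function(fp, fraction = 0.40) {
  apply(fp$rel, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA)
    median(col) < fraction
  })
}

#' Per-residue substitution profile across a protein
#'
#' Summarizes substitution effects along a protein: at each tile position
#' the score is the mean depletion of the mutants relative to the
#' wild-type estimate, `mean(1 - rel)` (0 = substitutions tolerated, -> 1 =
#' fully disruptive). Only tiles whose wild-type Z-score strictly exceeds
#' `z_gate` (default 5) contribute; where gated tiles overlap, their
#' per-residue scores are averaged. Replicates are analyzed individually.
#'
#' @param footprints list of [relative_enrichment()] footprints from one
#'   sample/replicate (entries with `wt_zscore` at or below the gate are
#'   dropped).
#' @param z_gate wild-type Z-score gate (strict `>`).
#' @return data.frame: `parent`, `position` (1-based residue in the
#'   protein), `score`, `n_tiles` contributing.
#' @export
substitution_profile <- function(footprints, z_gate = 5.0) {
  footprints <- Filter(function(fp) !is.null(fp) && is.finite(fp$wt_zscore)
                       && fp$wt_zscore > z_gate, footprints)
  if (!length(footprints))
    return(data.frame(parent = character(), position = integer(),
                      score = numeric(), n_tiles = integer(),
                      stringsAsFactors = FALSE))
  per_tile <- lapply(footprints, function(fp) {
    sc <- apply(fp$rel, 2L, function(col) {
      col <- col[!is.na(col)]
      if (!length(col)) return(NA_real_)
      mean(1 - col)
    })
    data.frame(parent = fp$parent,
               position = fp$start + seq_along(sc) - 1L,
               score = sc, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_tile)
  all <- all[!is.na(all$score), , drop = FALSE]
  agg <- aggregate(score ~ parent + position, data = all, FUN = mean)
  n <- aggregate(score ~ parent + position, data = all, FUN = length)
  agg$n_tiles <- n$score
  agg[order(agg$parent, agg$position), , drop = FALSE]
}

#' Export footprints as a tidy table
#'
#' One row per defined (substitution, position) cell: sample, tile,
#' position, wild-type residue, substitution, `rel`, `display`, and the
#' position's critical call.
#'
#' @param footprints list of [relative_enrichment()] footprints.
#' @return data.frame suitable for TSV export.
#' @export
footprint_table <- function(footprints) {
  rows <- lapply(Filter(Negate(is.null), footprints), function(fp) {
    idx <- which(!is.na(fp$rel), arr.ind = TRUE)
    data.frame(sample = fp$sample, tile_id = fp$tile_id,
               position = idx[, 2],
               wt_residue = substring(fp$wt_seq, idx[, 2], idx[, 2]),
               substitution = AA20[idx[, 1]],
               rel = fp$rel[idx], display = fp$display[idx],
               critical = fp$critical[idx[, 2]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
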