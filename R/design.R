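AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Allergen protein set
#'
#' Builds a validated table of allergen proteins for library design. Each
#' protein carries a unique `protein_id` (e.g. `"Ara h 2.02"`) and a
#' `family_id` shared by genetic/splice variants of the same allergen
#' (e.g. `"Ara h 2"`), used later for variant de-duplication.
#'
#' @param protein_id character vector of unique protein identifiers.
#' @param sequence amino-acid sequences (single-letter, canonical 20 only).
#' @param family_id allergen family per protein; defaults to `protein_id`
#'   stripped of a trailing `".NN"` variant suffix.
#' @return data.frame with columns `protein_id`, `family_id`, `sequence`.
#' @export
allergen_proteins <- function(protein_id, sequence, family_id = NULL) {
  protein_id <- as.character(protein_id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(protein_id))
    stop("protein_id values must be unique")
  if (length(sequence) != length(protein_id))
    stop("protein_id and sequence lengths differ")
  if (is.null(family_id))
    family_id <- sub("\\.[0-9]+$", "", protein_id)
  for (i in seq_along(sequence)) {
    if (nchar(sequence[i]) < 1L)
      stop("empty sequence for protein ", protein_id[i])
    bad <- which(!strsplit(sequence[i], "")[[1]] %in% AA20)
    if (length(bad))
      stop("non-canonical residue in ", protein_id[i],
           " at position ", bad[1])
  }
  data.frame(protein_id = protein_id, family_id = as.character(family_id),
             sequence = sequence, stringsAsFactors = FALSE)
}

#' Read allergen proteins from FASTA
#'
#' FASTA headers become `protein_id`; family ids are derived by stripping a
#' trailing variant suffix (`"Ara h 2.02"` -> `"Ara h 2"`).
#'
#' @param path FASTA file of amino-acid sequences.
#' @inheritParams allergen_proteins
#' @export
read_proteins <- function(path, family_id = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  allergen_proteins(names(aa), as.character(aa), family_id = family_id)
}

pep_id <- function(protein_id, start, end, mut_position = NA, mut_residue = NA) {
  base <- paste0(gsub("[[:space:]]+", "_", protein_id), "_", start, "-", end)
  n <- max(length(base), length(mut_position), length(mut_residue))
  base <- rep_len(base, n)
  mut_position <- rep_len(mut_position, n)
  mut_residue <- rep_len(mut_residue, n)
  ifelse(is.na(mut_position), paste0(base, "_wt"),
         paste0(base, "_p", mut_position, mut_residue))
}

new_peptide_records <- function(parent, family, start, end, aa_seq,
                                is_wildtype, mut_position = NA_integer_,
                                mut_residue = NA_character_) {
  data.frame(
    peptide_id = pep_id(parent, start, end, mut_position, mut_residue),
    parent = parent, family = family,
    start = as.integer(start), end = as.integer(end),
    is_wildtype = is_wildtype,
    mut_position = as.integer(mut_position),
    mut_residue = as.character(mut_residue),
    aa_seq = aa_seq, stringsAsFactors = FALSE)
}

#' Tile a protein into overlapping peptide windows
#'
#' Produces wild-type 20-mer tiles every `step` residues. When the last
#' canonical tile stops short of the C-terminus an extra tile anchored at
#' the C-terminus is appended (disable with `cterm_anchor = FALSE`), so
#' every residue is covered. Proteins shorter than `window` yield a single
#' full-length tile.
#'
#' @param protein one-row data.frame as from [allergen_proteins()].
#' @param window tile length in residues (default 20).
#' @param step offset between successive tile starts (default 10).
#' @param cterm_anchor append a C-terminus-anchored tile when the grid
#'   leaves a gap at the tail.
#' @return data.frame of wild-type peptide records.
#' @export
tile_protein <- function(protein, window = 20L, step = 10L,
                         cterm_anchor = TRUE) {
  stopifnot(window >= 1L, step >= 1L, nrow(protein) == 1L)
  seq <- protein$sequence
  L <- nchar(seq)
  if (L < 1L) stop("empty sequence for protein ", protein$protein_id)
  if (L <= window) {
    starts <- 1L
    window_i <- L
  } else {
    starts <- seq.int(1L, L - window + 1L, by = step)
    if (cterm_anchor && max(starts) + window - 1L < L)
      starts <- c(starts, L - window + 1L)
    window_i <- window
  }
  starts <- unique(starts)
  ends <- pmin(starts + window_i - 1L, L)
  new_peptide_records(
    parent = protein$protein_id, family = protein$family_id,
    start = starts, end = ends,
    aa_seq = substring(seq, starts, ends),
    is_wildtype = TRUE)
}

#' Saturation mutagenesis of a wild-type tile
#'
#' Emits every single-residue substitution of the tile: each position is
#' replaced by each of the 19 amino acids other than the wild-type residue,
#' giving `19 * nchar(aa_seq)` mutants at Hamming distance 1.
#'
#' @param tile one-row wild-type peptide record from [tile_protein()].
#' @return data.frame of mutant peptide records.
#' @export
saturate <- function(tile) {
  stopifnot(nrow(tile) == 1L)
  if (!isTRUE(tile$is_wildtype))
    stop("saturate() expects a wild-type tile: ", tile$peptide_id)
  aa <- strsplit(tile$aa_seq, "")[[1]]
  len <- length(aa)
  pos <- rep(seq_len(len), each = 19L)
  res <- unlist(lapply(aa, function(w) setdiff(AA20, w)), use.names = FALSE)
  mut_seq <- vapply(seq_along(pos), function(i) {
    v <- aa
    v[pos[i]] <- res[i]
    paste(v, collapse = "")
  }, character(1))
  new_peptide_records(
    parent = tile$parent, family = tile$family,
    start = tile$start, end = tile$end,
    aa_seq = mut_seq, is_wildtype = FALSE,
    mut_position = pos, mut_residue = res)
}

#' Design the complete tiling + saturation library
#'
#' Tiles every protein and, optionally, saturates each wild-type tile with
#' all single-residue mutants. One 20-mer tile yields 380 mutants, 381
#' peptides including the wild-type.
#'
#' @param proteins data.frame from [allergen_proteins()] / [read_proteins()].
#' @param mutants include saturation mutants (default TRUE).
#' @inheritParams tile_protein
#' @return data.frame of peptide records (annotation table).
#' @export
design_library <- function(proteins, window = 20L, step = 10L,
                           cterm_anchor = TRUE, mutants = TRUE) {
  tiles <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i)
    tile_protein(proteins[i, , drop = FALSE], window, step, cterm_anchor)))
  if (!mutants) return(tiles)
  muts <- do.call(rbind, lapply(seq_len(nrow(tiles)), function(i)
    saturate(tiles[i, , drop = FALSE])))
  rbind(tiles, muts)
}
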