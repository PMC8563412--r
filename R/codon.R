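# Rank-ordered preferred codons for E. coli K-12, highest usage first.
ECOLI_CODONS <- list(
  A = c("GCG", "GCC", "GCA", "GCT"),
  R = c("CGT", "CGC", "CGG", "CGA", "AGA", "AGG"),
  N = c("AAC", "AAT"),
  D = c("GAT", "GAC"),
  C = c("TGC", "TGT"),
  Q = c("CAG", "CAA"),
  E = c("GAA", "GAG"),
  G = c("GGC", "GGT", "GGG", "GGA"),
  H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  L = c("CTG", "TTA", "TTG", "CTT", "CTC", "CTA"),
  K = c("AAA", "AAG"),
  M = "ATG",
  F = c("TTT", "TTC"),
  P = c("CCG", "CCA", "CCT", "CCC"),
  S = c("AGC", "TCT", "TCC", "AGT", "TCA", "TCG"),
  T = c("ACC", "ACA", "ACG", "ACT"),
  W = "TGG",
  Y = c("TAT", "TAC"),
  V = c("GTG", "GTT", "GTC", "GTA"))

#' Codon policy for reverse translation
#'
#' Bundles the organism codon preference, the restriction motifs that must
#' not occur in the insert (EcoRI `GAATTC` and XhoI `CTCGAG` by default, the
#' two enzymes that cut the amplicon during cloning), the fixed 5'/3'
#' adaptors, and the length of the 5' prefix that must be unique across the
#' library so reads can be assigned unambiguously.
#'
#' @param codon_table named list, residue -> ranked character vector of
#'   synonymous codons (most preferred first). Default: E. coli K-12.
#' @param forbidden_motifs nucleotide motifs excluded from inserts and
#'   adaptor-insert junctions.
#' @param adaptor_5p,adaptor_3p fixed adaptor sequences.
#' @param unique_prefix_len length of the unique 5' prefix (default 50).
#' @return object of class `codon_policy`.
#' @export
codon_policy <- function(codon_table = ECOLI_CODONS,
                         forbidden_motifs = c("GAATTC", "CTCGAG"),
                         adaptor_5p = "GGAATTCCGCTGCGT",
                         adaptor_3p = "CAGGGAAGAGCTCGA",
                         unique_prefix_len = 50L) {
  stopifnot(all(AA20 %in% names(codon_table)))
  if (any(vapply(codon_table, length, 1L) < 1L))
    stop("every residue needs at least one codon")
  structure(list(codon_table = codon_table,
                 forbidden_motifs = toupper(forbidden_motifs),
                 adaptor_5p = toupper(adaptor_5p),
                 adaptor_3p = toupper(adaptor_3p),
                 unique_prefix_len = as.integer(unique_prefix_len)),
            class = "codon_policy")
}

#' Translate DNA to protein
#'
#' Thin wrapper over the standard genetic code for in-frame, stop-free
#' coding sequences as produced by [reverse_translate()].
#'
#' @param nt character vector of nucleotide sequences (length multiple of 3).
#' @return character vector of amino-acid sequences.
#' @export
translate_dna <- function(nt) {
  vapply(nt, function(s) {
    n <- nchar(s)
    if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Motif violations in adaptor_5p + nt + adaptor_3p, ignoring occurrences
# that lie entirely inside an adaptor (those are the cloning sites).
motif_violation <- function(nt, policy) {
  oligo <- paste0(policy$adaptor_5p, nt, policy$adaptor_3p)
  lo <- nchar(policy$adaptor_5p)        # insert spans lo+1 .. lo+nchar(nt)
  hi <- lo + nchar(nt)
  for (m in policy$forbidden_motifs) {
    hits <- gregexpr(m, oligo, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (p in hits) {                   # occurrence spans p .. p+nchar(m)-1
      if (p + nchar(m) - 1L > lo && p <= hi) return(TRUE)
    }
  }
  FALSE
}

# Candidate codon-choice vectors: base (all top-rank), then all single
# swaps ordered by (position from 5' end, codon rank), then double swaps.
# Deterministic; returns the first nt passing motif + prefix constraints.
resolve_nt <- function(aa, policy, used_prefixes, budget = 50000L) {
  res <- strsplit(aa, "")[[1]]
  tabs <- policy$codon_table[res]
  nalt <- vapply(tabs, length, 1L)
  plen <- policy$unique_prefix_len

  build <- function(choice) paste(mapply(function(t, k) t[k], tabs, choice),
                                  collapse = "")
  ok <- function(nt) {
    if (motif_violation(nt, policy)) return(FALSE)
    !exists(substr(nt, 1L, plen), envir = used_prefixes, inherits = FALSE)
  }

  tried <- 0L
  base <- rep(1L, length(res))
  nt <- build(base)
  if (ok(nt)) return(nt)

  swaps <- which(nalt > 1L)
  for (i in swaps) {
    for (k in 2:nalt[i]) {
      tried <- tried + 1L
      if (tried > budget) break
      ch <- base; ch[i] <- k
      nt <- build(ch)
      if (ok(nt)) return(nt)
    }
  }
  for (i in swaps) for (j in swaps[swaps > i]) {
    for (ki in 2:nalt[i]) for (kj in 2:nalt[j]) {
      tried <- tried + 1L
      if (tried > budget)
        stop("synonymous-swap budget exhausted for peptide ", aa)
      ch <- base; ch[i] <- ki; ch[j] <- kj
      nt <- build(ch)
      if (ok(nt)) return(nt)
    }
  }
  stop("could not satisfy motif/uniqueness constraints for peptide ", aa)
}

#' Reverse translation with constraint repair
#'
#' Encodes each peptide with the most-preferred codons, then repairs the
#' encoding by deterministic synonymous swaps (explored from the 5' end,
#' least-disruptive single swaps before pairs) until the insert (i) carries
#' no forbidden motif, including across the adaptor junctions, and (ii) has
#' a 5' prefix of `unique_prefix_len` nt distinct from every other library
#' member, so sequencing reads map unambiguously by exact prefix match.
#' Peptides are processed in lexicographic `peptide_id` order so collisions
#' resolve identically across runs; output row order is preserved.
#'
#' @param peptides peptide annotation data.frame with `peptide_id`, `aa_seq`.
#' @param policy a [codon_policy()].
#' @param seed unused placeholder for interface stability; the procedure is
#'   fully deterministic.
#' @return `peptides` with an `nt_seq` column added.
#' @export
reverse_translate <- function(peptides, policy = codon_policy(), seed = 0L) {
  stopifnot(inherits(policy, "codon_policy"))
  if (anyDuplicated(peptides$peptide_id))
    stop("duplicate peptide_id in library")
  ord <- order(peptides$peptide_id, method = "radix")
  used <- new.env(parent = emptyenv())
  nt <- character(nrow(peptides))
  for (i in ord) {
    s <- resolve_nt(peptides$aa_seq[i], policy, used)
    assign(substr(s, 1L, policy$unique_prefix_len), TRUE, envir = used)
    nt[i] <- s
  }
  peptides$nt_seq <- nt
  peptides
}

#' Add adaptors to encoded peptides
#'
#' `oligo_seq = adaptor_5p + nt_seq + adaptor_3p` for every record.
#'
#' @inheritParams reverse_translate
#' @export
assemble_oligos <- function(peptides, policy = codon_policy()) {
  if (is.null(peptides$nt_seq) || anyNA(peptides$nt_seq))
    stop("nt_seq missing; run reverse_translate() first")
  peptides$oligo_seq <- paste0(policy$adaptor_5p, peptides$nt_seq,
                               policy$adaptor_3p)
  peptides
}
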