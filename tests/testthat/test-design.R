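test_that("tiling produces the expected windows", {
  set.seed(40)
  p40 <- allergen_proteins("P.01", random_aa(1, 40))
  t40 <- tile_protein(p40)
  expect_equal(nrow(t40), 3L)
  expect_equal(t40$start, c(1L, 11L, 21L))
  expect_equal(t40$end, c(20L, 30L, 40L))

  p20 <- allergen_proteins("P.01", random_aa(1, 20))
  t20 <- tile_protein(p20)
  expect_equal(nrow(t20), 1L)
  expect_equal(c(t20$start, t20$end), c(1L, 20L))

  # C-terminal anchor: last canonical tile [21-40] misses residues 41-45
  p45 <- allergen_proteins("P.01", random_aa(1, 45))
  t45 <- tile_protein(p45)
  expect_equal(nrow(t45), 4L)
  expect_equal(t45$start, c(1L, 11L, 21L, 26L))
  expect_equal(t45$end[4], 45L)
  expect_equal(nrow(tile_protein(p45, cterm_anchor = FALSE)), 3L)

  # short protein: one full-length tile
  p12 <- allergen_proteins("P.01", random_aa(1, 12))
  t12 <- tile_protein(p12)
  expect_equal(nrow(t12), 1L)
  expect_equal(nchar(t12$aa_seq), 12L)
})

test_that("tiling matches a brute-force window enumerator", {
  set.seed(41)
  for (len in sample(20:400, 25)) {
    p <- allergen_proteins("X.01", random_aa(1, len))
    tiles <- tile_protein(p)
    expect_equal(tiles$start, oracle_tile_starts(len), info = len)
    # full coverage and count formula
    covered <- rep(FALSE, len)
    for (i in seq_len(nrow(tiles)))
      covered[tiles$start[i]:tiles$end[i]] <- TRUE
    expect_true(all(covered))
    base_n <- floor((len - 20) / 10) + 1
    expect_true(nrow(tiles) %in% c(base_n, base_n + 1))
  }
})

test_that("invalid protein input is rejected with position info", {
  expect_error(allergen_proteins("P.01", ""), "empty")
  expect_error(allergen_proteins("P.01", "ACDEFGHIKLMNPQRSTVWX"),
               "position 20")
  expect_error(allergen_proteins(c("P.01", "P.01"), c("ACDE", "ACDE")),
               "unique")
})

test_that("saturation emits all and only Hamming-1 mutants", {
  set.seed(42)
  p <- allergen_proteins("P.01", random_aa(1, 20))
  tile <- tile_protein(p)
  muts <- saturate(tile)
  expect_equal(nrow(muts), 380L)
  expect_false(any(duplicated(muts$peptide_id)))
  expect_false(any(duplicated(paste(muts$mut_position, muts$mut_residue))))
  wt <- strsplit(tile$aa_seq, "")[[1]]
  hd <- vapply(muts$aa_seq, function(m)
    sum(strsplit(m, "")[[1]] != wt), integer(1))
  expect_true(all(hd == 1L))
  # mutated residue is at the declared position and differs from wild type
  at <- substring(muts$aa_seq, muts$mut_position, muts$mut_position)
  expect_equal(at, muts$mut_residue)
  expect_true(all(at != wt[muts$mut_position]))
  expect_error(saturate(muts[1, ]), "wild-type")
})

test_that("library size follows 381 peptides per 20-mer tile", {
  set.seed(43)
  p <- allergen_proteins("P.01", random_aa(1, 50))
  lib <- design_library(p)
  n_tiles <- length(oracle_tile_starts(50))
  expect_equal(nrow(lib), n_tiles * 381L)
  expect_equal(sum(lib$is_wildtype), n_tiles)
  # short tiles saturate with their actual length
  p9 <- allergen_proteins("S.01", random_aa(1, 9))
  lib9 <- design_library(p9)
  expect_equal(nrow(lib9), 1L + 9L * 19L)
})

test_that("reverse translation round-trips and resolves duplicates", {
  set.seed(44)
  # two protein variants sharing a tile sequence force a prefix collision
  shared <- random_aa(1, 40)
  p <- allergen_proteins(c("V.01", "V.02"), c(shared, shared), c("V", "V"))
  lib <- design_library(p, mutants = FALSE)
  expect_true(any(duplicated(lib$aa_seq)))
  lib <- reverse_translate(lib)
  expect_equal(nchar(lib$nt_seq), rep(60L, nrow(lib)))
  expect_equal(translate_dna(lib$nt_seq), lib$aa_seq)
  # cross-check translation with an independent implementation
  expect_equal(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(lib$nt_seq))), lib$aa_seq)
  prefixes <- substr(lib$nt_seq, 1, 50)
  expect_false(any(duplicated(prefixes)))
  # determinism
  lib2 <- reverse_translate(design_library(p, mutants = FALSE))
  expect_identical(lib$nt_seq, lib2$nt_seq)
})

test_that("forbidden motifs are removed from inserts and junctions", {
  # E followed by F encodes GAA-TTC = an EcoRI site under top-rank codons
  p <- allergen_proteins("M.01", "AAAAAAAAAEFAAAAAAAAA")
  lib <- reverse_translate(design_library(p, mutants = FALSE))
  pol <- codon_policy()
  for (nt in lib$nt_seq) {
    oligo <- paste0(pol$adaptor_5p, nt, pol$adaptor_3p)
    lo <- nchar(pol$adaptor_5p); hi <- lo + nchar(nt)
    for (m in c("GAATTC", "CTCGAG")) {
      hits <- gregexpr(m, oligo, fixed = TRUE)[[1]]
      hits <- hits[hits > 0]
      # any occurrence must lie entirely inside an adaptor
      expect_true(all(hits + nchar(m) - 1 <= lo | hits > hi))
    }
    expect_equal(translate_dna(nt), "AAAAAAAAAEFAAAAAAAAA")
  }
})

test_that("oligo assembly adds the exact adaptors", {
  set.seed(45)
  p <- allergen_proteins("P.01", random_aa(1, 20))
  lib <- assemble_oligos(reverse_translate(design_library(p)))
  expect_true(all(startsWith(lib$oligo_seq, "GGAATTCCGCTGCGT")))
  expect_true(all(endsWith(lib$oligo_seq, "CAGGGAAGAGCTCGA")))
  expect_equal(nchar(lib$oligo_seq), rep(90L, nrow(lib)))
  # strip adaptors, translate: recovers the peptide
  core <- substr(lib$oligo_seq, 16, 75)
  expect_equal(translate_dna(core), lib$aa_seq)
  expect_error(assemble_oligos(design_library(p)), "nt_seq")
})

test_that("library files round-trip losslessly", {
  set.seed(46)
  p <- allergen_proteins(c("Ara h 2.01", "Ara h 2.02"),
                         random_aa(2, 35), c("Ara h 2", "Ara h 2"))
  lib <- assemble_oligos(reverse_translate(design_library(p)))
  dir <- withr::local_tempdir()
  write_library(lib, dir)
  back <- read_library(dir)
  expect_equal(back$peptide_id, lib$peptide_id)
  expect_equal(back$aa_seq, lib$aa_seq)
  expect_equal(back$oligo_seq, lib$oligo_seq)
  expect_equal(back$mut_position, lib$mut_position)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "library_oligos.fasta"))
  expect_equal(names(fa), lib$peptide_id)
  expect_equal(length(fa), nrow(back))
})
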