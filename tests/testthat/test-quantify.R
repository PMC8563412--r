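make_null <- function(ids, bin, bin_mean, bin_sd, mock_mean = NULL) {
  # hand-assembled null for formula-level tests
  structure(list(bin = setNames(bin, ids), bin_mean = bin_mean,
                 bin_sd = bin_sd, n_members = tabulate(bin),
                 mock_mean = if (is.null(mock_mean))
                   setNames(bin_mean[bin], ids) else mock_mean,
                 mock_depth = sum(bin_mean[bin]),
                 bin_size = max(tabulate(bin)), trim = 0.05, sd_floor = 1,
                 sd_correction = TRUE),
            class = "binned_null")
}

test_that("reads are assigned by exact 50-nt prefix match", {
  set.seed(50)
  p <- allergen_proteins("P.01", random_aa(1, 30))
  lib <- reverse_translate(design_library(p, mutants = FALSE))
  r1 <- substr(lib$nt_seq[1], 1, 50)
  mism <- r1
  substr(mism, 25, 25) <- setdiff(c("A", "C", "G", "T"),
                                  substr(r1, 25, 25))[1]
  res <- suppressWarnings(count_reads(c(r1, r1, mism, "ACGT"), lib))
  expect_equal(unname(res$counts[lib$peptide_id[1], 1]), 2L)
  expect_equal(unname(res$unmatched), 2L)
  expect_equal(sum(res$counts) + sum(res$unmatched), 4L)
  expect_warning(count_reads(c(r1, "ACGT"), lib), "shorter")
})

test_that("counting a sampled FASTQ recovers the sampling tally", {
  set.seed(7)
  p <- allergen_proteins("P.01", random_aa(1, 60))
  lib <- reverse_translate(design_library(p, mutants = FALSE))
  draw <- sample(nrow(lib), 10000, replace = TRUE,
                 prob = runif(nrow(lib)))
  reads <- substr(lib$nt_seq[draw], 1, 50)
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(paste0("@r", seq_along(reads), "\n", reads, "\n+\n",
                    strrep("I", 50)), fq)
  res <- count_reads(fq, lib)
  expect_equal(unname(res$counts[, 1]),
               unname(tabulate(draw, nbins = nrow(lib))))
  expect_equal(unname(res$unmatched), 0L)
})

test_that("binning partitions the library by mock abundance", {
  set.seed(11)
  ids <- sprintf("p%04d", 1:900)
  mock <- matrix(rpois(1800, rep(exp(runif(900, 0, 6)), 2)), ncol = 2,
                 dimnames = list(ids, c("m1", "m2")))
  null <- build_null(mock, bin_size = 300)
  expect_equal(unname(null$n_members), c(300L, 300L, 300L))
  expect_equal(sort(unique(null$bin)), 1:3)
  # contiguity: every bin-1 abundance <= every bin-3 abundance (half A)
  estA <- mock[, 1]
  expect_lte(max(estA[null$bin == 1]), min(estA[null$bin == 3]))
})

test_that("constant bins get the sd floor", {
  ids <- sprintf("p%03d", 1:60)
  mock <- matrix(50, nrow = 60, ncol = 2, dimnames = list(ids, NULL))
  expect_message(null <- build_null(mock, bin_size = 30), "floored")
  expect_equal(unname(null$bin_mean), c(50, 50))
  expect_equal(unname(null$bin_sd), c(1, 1))
})

test_that("Z-score formula is exact against a hand-built null", {
  ids <- c("a", "b", "c")
  null <- make_null(ids, c(1L, 1L, 2L), bin_mean = c(10, 100),
                    bin_sd = c(2, 10))
  counts <- matrix(c(10, 14, 100), ncol = 1,
                   dimnames = list(ids, "s1"))
  z <- zscore(counts, null, depth_normalize = "none")
  expect_equal(unname(z[, 1]), c(0, 2, 0))   # mean -> 0; mean + 2 sd -> 2
  bad <- matrix(1, 1, 1, dimnames = list("zzz", "s1"))
  expect_error(zscore(bad, null, depth_normalize = "none"), "zzz")
})

test_that("zscore is permutation-equivariant and monotone in counts", {
  set.seed(13)
  ids <- sprintf("p%03d", 1:120)
  mock <- matrix(rpois(240, 60), ncol = 2, dimnames = list(ids, NULL))
  counts <- matrix(rpois(120, 60), ncol = 1, dimnames = list(ids, "s"))
  null <- build_null(mock, bin_size = 40)
  z <- zscore(counts, null, depth_normalize = "none")
  perm <- sample(ids)
  z_perm <- zscore(counts[perm, , drop = FALSE], null,
                   depth_normalize = "none")
  expect_equal(z_perm[ids, ], z[ids, ])
  # same peptide, higher count -> higher z
  counts2 <- counts + 5
  z2 <- zscore(counts2, null, depth_normalize = "none")
  expect_true(all(z2 > z))
})

test_that("replicate averaging returns means and QC correlations", {
  ids <- c("a", "b")
  z <- matrix(c(2, 1, 4, 3, 5, 5), nrow = 2,
              dimnames = list(ids, c("s1_r1", "s1_r2", "m1")))
  ss <- sample_sheet(c("s1_r1", "s1_r2", "m1"),
                     c("S1", "S1", NA), c("IgE", "IgE", "mock"),
                     c("week0", "week0", "none"), c(1, 2, 1),
                     c("allergic", "allergic", "mock"))
  avg <- average_replicates(z, ss)
  expect_equal(unname(avg$z[, "S1|IgE|week0"]), c(3, 2))  # (2+4)/2, (1+3)/2
  expect_equal(avg$replicate_cor$pearson_r, 1)            # affine replicas
  # identical replicates return the input
  z2 <- z; z2[, 2] <- z2[, 1]
  avg2 <- average_replicates(z2, ss)
  expect_equal(unname(avg2$z[, 1]), unname(z[, 1]))
})

test_that("hit calling uses a strict threshold", {
  z <- matrix(c(3.5, 3.6, -1), ncol = 1,
              dimnames = list(c("a", "b", "c"), "S1|IgE|week0"))
  hits <- call_hits(z)
  expect_equal(hits$peptide_id, "b")
  expect_equal(nrow(call_hits(z, threshold = 5)), 0L)
})

test_that("mock samples z-scored on their own null centre near zero", {
  set.seed(17)
  cfg <- tiny_config(seed = 17)
  sim <- simulate_library(cfg)
  mock <- simulate_ip(sim, cfg, n_rep = 2)
  colnames(mock) <- c("m1", "m2")
  null <- build_null(mock)
  # the column whose counts parameterized the bin moments must centre at
  # zero bin by bin (the binning column is subject to selection and is
  # checked only in aggregate)
  z2 <- zscore(mock[, 2, drop = FALSE], null)
  for (b in unique(null$bin)) {
    tm <- allerscan:::trimmed_moments(as.vector(z2[null$bin == b, ]))
    expect_lt(abs(tm[["mean"]]), 0.1)
  }
  z <- zscore(mock, null)
  expect_lt(abs(median(z)), 0.25)
})
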