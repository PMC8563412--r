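# Hand-built enrichment sets: a 4-residue tile "KEAF" (position 3 is
# alanine, so only 3 alanine mutants exist).
mini_set <- function(wt_enr, mut_fill, ala = NULL) {
  mm <- matrix(NA_real_, 20, 4,
               dimnames = list(c("A","C","D","E","F","G","H","I","K","L",
                                 "M","N","P","Q","R","S","T","V","W","Y"),
                               NULL))
  wt <- c("K", "E", "A", "F")
  for (pos in 1:4) {
    others <- setdiff(rownames(mm), wt[pos])
    mm[others, pos] <- mut_fill
  }
  if (!is.null(ala)) mm["A", c(1, 2, 4)] <- ala
  structure(list(tile_id = "T_1-4_wt", sample = "s1", parent = "T",
                 start = 1L, end = 4L, wt_seq = "KEAF",
                 wt_enrichment = wt_enr, mutant_enrichment = mm,
                 wt_zscore = 10), class = "enrichment_set")
}

test_that("wild-type estimate averages wt with top half of alanine mutants", {
  # wt = 10, alanine mutants {2, 4, 6, 8} -> top 2 are {8, 6} -> mean = 8
  s <- mini_set(10, 1)
  s$mutant_enrichment["A", c(1, 2, 4)] <- c(2, 4, 6)
  s$mutant_enrichment["A", 2] <- 8   # now {2, 8, 6}: top 2 = {8, 6}
  expect_equal(wildtype_estimate(s), mean(c(10, 8, 6)))
  # no alanine mutants available -> wt unchanged
  s2 <- mini_set(7, 1)
  s2$mutant_enrichment["A", ] <- NA
  expect_equal(wildtype_estimate(s2), 7)
  # constant case
  s3 <- mini_set(5, 5, ala = 5)
  expect_equal(wildtype_estimate(s3), 5)
  # scale equivariance
  s4 <- mini_set(10, 3, ala = c(2, 9, 4))
  est <- wildtype_estimate(s4)
  s4$wt_enrichment <- s4$wt_enrichment * 3
  s4$mutant_enrichment <- s4$mutant_enrichment * 3
  expect_equal(wildtype_estimate(s4), 3 * est)
})

test_that("relative enrichment and its display transform", {
  s <- mini_set(10, 10, ala = 10)   # estimate = 10
  fp <- relative_enrichment(s)
  expect_equal(fp$wt_estimate, 10)
  expect_equal(unname(fp$rel["C", 1]), 1)
  expect_equal(unname(fp$display["C", 1]), 0)
  s$mutant_enrichment["C", 1] <- 1   # wt_est / 10
  fp <- relative_enrichment(s)
  expect_equal(unname(fp$rel["C", 1]), 0.1)
  expect_equal(unname(fp$display["C", 1]), -1)
  # display identically equals log10(rel) wherever defined
  expect_equal(fp$display[!is.na(fp$rel)], log10(fp$rel[!is.na(fp$rel)]))
  # non-positive estimate -> no footprint
  s$wt_enrichment <- 0
  s$mutant_enrichment[] <- ifelse(is.na(s$mutant_enrichment), NA, 0)
  expect_warning(fp0 <- relative_enrichment(s), "unavailable")
  expect_null(fp0)
})

test_that("critical residues use a strict 40% median rule", {
  s <- mini_set(10, 1, ala = 10)    # estimate 10, mutants at rel 0.1
  fp <- relative_enrichment(s)
  expect_true(all(fp$critical[c(1, 2, 4)]))
  # position 3: mutants include the high alanine? no - ala is at 1,2,4;
  # position 3 mutants are all 1 -> critical too
  expect_true(fp$critical[3])
  s2 <- mini_set(10, 10, ala = 10)  # mutants equal wt -> not critical
  expect_false(any(relative_enrichment(s2)$critical))
  # median exactly at 0.40 x estimate -> NOT critical (strict less-than)
  s3 <- mini_set(10, 4, ala = 10)
  fp3 <- relative_enrichment(s3)
  expect_equal(unname(median(fp3$rel[, 1], na.rm = TRUE)), 0.4)
  expect_false(fp3$critical[1])
  s4 <- mini_set(10, 3.99, ala = 10)
  expect_true(relative_enrichment(s4)$critical[1])
})

test_that("substitution profile scores, gates and overlap-averages", {
  s <- mini_set(10, 10, ala = 10)
  fp_flat <- relative_enrichment(s)      # all rel = 1 -> score 0
  prof <- substitution_profile(list(fp_flat), z_gate = 5)
  expect_true(all(abs(prof$score) < 1e-12))
  s2 <- mini_set(10, 1e-6, ala = 1e-6)   # rel -> 0 => score -> 1
  fp_dep <- relative_enrichment(s2)
  prof2 <- substitution_profile(list(fp_dep))
  expect_true(all(prof2$score > 0.99))
  # tile below the Z gate contributes nothing
  fp_low <- fp_dep; fp_low$wt_zscore <- 4.9
  expect_equal(nrow(substitution_profile(list(fp_low))), 0L)
  # overlapping gated tiles: per-tile scores 0.2 and 0.6 average to 0.4
  mk <- function(start, relval) {
    fp <- fp_flat
    fp$start <- start
    fp$rel[!is.na(fp$rel)] <- 1 - relval
    fp
  }
  prof3 <- substitution_profile(list(mk(1, 0.2), mk(3, 0.6)))
  ov <- prof3$score[prof3$position %in% 3:4]
  expect_equal(ov, rep(0.4, 2))
  expect_equal(prof3$score[prof3$position %in% 1:2], rep(0.2, 2))
  expect_equal(prof3$score[prof3$position %in% 5:6], rep(0.6, 2))
})

test_that("substitution score is antitone in mutant enrichment", {
  set.seed(23)
  s <- mini_set(10, 1, ala = c(8, 9, 10))
  free <- !is.na(s$mutant_enrichment) & row(s$mutant_enrichment) != 1
  s$mutant_enrichment[free] <- runif(sum(free), 0.5, 12)
  base <- substitution_profile(list(relative_enrichment(s)))
  for (k in 1:5) {
    idx <- which(!is.na(s$mutant_enrichment) &
                   row(s$mutant_enrichment) != 1)  # keep alanine fixed
    pick <- sample(idx, 1)
    s2 <- s
    s2$mutant_enrichment[pick] <- s2$mutant_enrichment[pick] * 2
    prof2 <- substitution_profile(list(relative_enrichment(s2)))
    expect_true(all(prof2$score <= base$score + 1e-12))
  }
})

test_that("planted critical positions are recovered from simulated counts", {
  cs <- list(P1 = c(3L, 8L, 15L))
  pan <- simulate_footprint_panel(
    sim_config(seed = 29, n_families = 1, n_variant_families = 0,
               protein_length = c(60L, 60L), n_public = 1), cs)
  fp <- pan$footprints$P1
  expect_equal(which(fp$critical), c(3L, 8L, 15L))
  # enrichment_set round trip: mutant map excludes the wild-type residue
  es <- enrichment_set(pan$enrichment, pan$sim$library, pan$tile, "P1_r1")
  wt <- strsplit(es$wt_seq, "")[[1]]
  for (pos in seq_along(wt))
    expect_true(is.na(es$mutant_enrichment[wt[pos], pos]))
})

test_that("footprint tables export one row per defined cell", {
  s <- mini_set(10, 2, ala = c(4, 6, 8))
  fp <- relative_enrichment(s)
  tab <- footprint_table(list(fp))
  expect_equal(nrow(tab), sum(!is.na(fp$rel)))
  expect_setequal(unique(tab$wt_residue), c("K", "E", "A", "F"))
  expect_true(all(tab$substitution != tab$wt_residue))
})
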