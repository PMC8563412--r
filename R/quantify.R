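#' Assign reads to library members by unique 5' prefix
#'
#' Library inserts are designed so their first `unique_prefix_len`
#' nucleotides are unique ([reverse_translate()]), so reads are assigned by
#' exact match of their leading prefix against the library; no aligner is
#' needed. Reads shorter than the prefix, or not matching any member, are
#' tallied as unmatched.
#'
#' @param reads character vector of read sequences, a named list of such
#'   vectors (one element per sample), or a FASTQ/FASTA file path.
#' @param library annotation with `peptide_id` and `nt_seq` columns.
#' @param prefix_len prefix length (default 50).
#' @return list: `counts` (peptide x sample integer matrix), `unmatched`
#'   (per-sample count), satisfying colSums(counts) + unmatched = reads.
#' @export
count_reads <- function(reads, library, prefix_len = 50L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  if (!is.list(reads)) reads <- list(sample1 = reads)
  prefixes <- substr(library$nt_seq, 1L, prefix_len)
  if (anyDuplicated(prefixes)) stop("library prefixes are not unique")
  counts <- matrix(0L, nrow(library), length(reads),
                   dimnames = list(library$peptide_id, names(reads)))
  unmatched <- integer(length(reads))
  names(unmatched) <- names(reads)
  for (s in seq_along(reads)) {
    r <- reads[[s]]
    short <- nchar(r) < prefix_len
    if (any(short))
      warning(sum(short), " reads shorter than the ", prefix_len,
              "-nt prefix counted as unmatched")
    idx <- match(substr(r[!short], 1L, prefix_len), prefixes)
    tab <- tabulate(idx[!is.na(idx)], nbins = nrow(library))
    counts[, s] <- tab
    unmatched[s] <- length(r) - sum(tab)
  }
  list(counts = counts, unmatched = unmatched)
}

trimmed_moments <- function(x, trim = 0.05, sd_correction = TRUE) {
  x <- sort(x)
  k <- ceiling(trim * length(x))
  mid <- if (length(x) > 2L * k) x[(k + 1L):(length(x) - k)] else x
  s <- if (length(mid) > 1L) sd(mid) else 0
  if (sd_correction && k > 0L && length(x) > 2L * k) {
    # The sd of the middle (1 - 2t) of a normal understates the full sd;
    # divide by the truncation consistency factor so Z is on a true-sigma
    # scale (t taken as the trim fraction actually realized).
    t_eff <- k / length(x)
    z_t <- qnorm(1 - t_eff)
    s <- s / sqrt(1 - 2 * z_t * dnorm(z_t) / (1 - 2 * t_eff))
  }
  c(mean = mean(mid), sd = s)
}

#' Build the binned mock-IP null distribution
#'
#' Mock (no-serum) IP counts measure baseline library abundance. Peptides
#' are sorted by mean mock abundance and partitioned into contiguous
#' equal-occupancy bins; within each bin the mean and standard deviation of
#' the middle 90% of member counts (top and bottom `trim` removed from each
#' tail) define the null against which sample counts are Z-scored. Multiple
#' mock replicates are averaged per peptide before binning. Bins whose
#' trimmed counts are constant get their standard deviation floored at
#' `sd_floor` reads.
#'
#' @param mock_counts a [count_table()] of mock samples only, or a peptide x
#'   replicate matrix of mock counts.
#' @param bin_size target peptides per bin (default 300; last bin may be
#'   smaller).
#' @param trim fraction trimmed from each tail (default 0.05);
#'   `ceiling(trim * n)` values are dropped per end.
#' @param sd_floor minimum allowed bin standard deviation in reads.
#' @param sd_correction divide each bin's trimmed sd by the normal
#'   truncation consistency factor (~0.789 at 5% trim) so the Z scale is
#'   in true null standard deviations (default TRUE); `FALSE` keeps the
#'   raw middle-90% sd.
#' @param input_counts optional per-peptide counts (vector or peptide x
#'   run matrix) from sequencing the input library itself, e.g. a deep
#'   QC run. When given, peptides are binned by this independent
#'   abundance estimate and the null moments use all mock replicates;
#'   without it the mock replicates are split into a binning half and a
#'   moment half.
#' @return object of class `binned_null`: `bin` (peptide -> bin index),
#'   `bin_mean`, `bin_sd`, `n_members`, `mock_mean` (per-peptide averaged
#'   mock counts), `mock_depth`, plus the parameters.
#' @export
build_null <- function(mock_counts, bin_size = 300L, trim = 0.05,
                       sd_floor = 1, sd_correction = TRUE,
                       input_counts = NULL) {
  m <- if (inherits(mock_counts, "count_table")) {
    keep <- mock_counts$samples$isotype == "mock"
    if (!any(keep)) stop("no mock samples in count table")
    mock_counts$counts[, mock_counts$samples$sample_id[keep], drop = FALSE]
  } else as.matrix(mock_counts)
  if (bin_size < 20L) stop("bin_size must be >= 20")
  mock_mean <- rowMeans(m)
  n <- length(mock_mean)
  # The binning abundance estimate must be independent of the counts the
  # moments are measured on: binning and measuring on the same counts
  # selects bin members for tightly clustered values and collapses the
  # null spread below what an independent IP of the same peptides shows.
  # Preferred reference: an input-library sequencing run (deep QC run);
  # fallback: split the mock replicates into a binning half and a moment
  # half.
  if (!is.null(input_counts)) {
    ic <- as.matrix(input_counts)
    if (nrow(ic) != n) stop("input_counts does not match the peptide set")
    if (!is.null(rownames(ic))) ic <- ic[rownames(m), , drop = FALSE]
    bin_on <- rowMeans(ic)
    half_b <- seq_len(ncol(m))
  } else {
    if (ncol(m) >= 2L) {
      half_a <- seq(1L, ncol(m), by = 2L)
      half_b <- setdiff(seq_len(ncol(m)), half_a)
    } else {
      message("single mock replicate and no input counts: null spread ",
              "is estimated from the binning counts themselves and may ",
              "be optimistic")
      half_a <- half_b <- 1L
    }
    bin_on <- rowMeans(m[, half_a, drop = FALSE])
  }
  ord <- order(bin_on, rownames(m), method = "radix")
  bin <- integer(n)
  bin[ord] <- (seq_len(n) - 1L) %/% bin_size + 1L
  nbin <- max(bin)
  mom <- vapply(seq_len(nbin), function(b)
    trimmed_moments(as.vector(m[bin == b, half_b, drop = FALSE]), trim,
                    sd_correction),
    numeric(2))
  bin_sd <- pmax(mom["sd", ], sd_floor)
  if (any(mom["sd", ] < sd_floor))
    message(sum(mom["sd", ] < sd_floor),
            " bins had near-zero trimmed variance; sd floored at ",
            sd_floor, " read(s)")
  structure(list(bin = setNames(bin, rownames(m)),
                 bin_mean = mom["mean", ], bin_sd = bin_sd,
                 n_members = tabulate(bin, nbin),
                 mock_mean = mock_mean, mock_depth = sum(mock_mean),
                 bin_size = bin_size, trim = trim, sd_floor = sd_floor,
                 sd_correction = sd_correction),
            class = "binned_null")
}

#' @export
print.binned_null <- function(x, ...) {
  cat(sprintf("binned_null: %d peptides in %d bins (target size %d, trim %g)\n",
              length(x$bin), length(x$bin_mean), x$bin_size, x$trim))
  invisible(x)
}

# Depth scaling of sample counts onto the mock reference scale.
# "ratio" (median-of-ratios against the mock mean over well-measured
# peptides) corrects sequencing depth AND the compositional depression of
# background counts that a large bound-phage fraction causes; "total"
# matches total depth only; "none" leaves raw counts.
depth_scale <- function(counts, null,
                        method = c("ratio", "total", "none"),
                        min_ref = 10) {
  method <- match.arg(method)
  if (method == "none") return(counts)
  if (method == "ratio") {
    ref <- null$mock_mean
    idx <- which(ref >= min_ref)
    if (length(idx) >= 200L) {
      s <- apply(counts[idx, , drop = FALSE] / ref[idx], 2L, median)
      if (all(s > 0)) return(sweep(counts, 2L, s, "/"))
    }
    # too few well-measured reference peptides: fall back to total depth
  }
  depths <- colSums(counts)
  sweep(counts, 2L, ifelse(depths > 0, null$mock_depth / depths, 1), "*")
}

norm_method <- function(depth_normalize) {
  if (is.logical(depth_normalize))
    if (depth_normalize) "ratio" else "none"
  else match.arg(depth_normalize, c("ratio", "total", "none"))
}

#' Enrichment Z-scores against the binned mock null
#'
#' For peptide p in sample s, `Z = (counts[p, s] - mean_b) / sd_b` where
#' `mean_b` / `sd_b` are the trimmed moments of p's mock-abundance bin. By
#' default each sample's counts are first put on the mock scale by
#' median-of-ratios scaling (`"ratio"`), which corrects both sequencing
#' depth and the compositional depression of unbound peptides when bound
#' phage consume a visible share of the reads; `"total"` scales to the
#' mock total depth only and `"none"`/`FALSE` applies the formula to raw
#' counts.
#'
#' @param counts a [count_table()] or a peptide x sample matrix.
#' @param null a [binned_null()] covering every peptide in `counts`.
#' @param depth_normalize `"ratio"` (default, `TRUE`), `"total"`, or
#'   `"none"` (`FALSE`).
#' @return matrix of Z-scores, same dimnames as the counts.
#' @export
zscore <- function(counts, null, depth_normalize = "ratio") {
  m <- if (inherits(counts, "count_table")) counts$counts else
    as.matrix(counts)
  missing <- setdiff(rownames(m), names(null$bin))
  if (length(missing))
    stop("peptide absent from null: ", missing[1])
  m <- depth_scale(m, null, norm_method(depth_normalize))
  b <- null$bin[rownames(m)]
  (m - null$bin_mean[b]) / null$bin_sd[b]
}

#' Fold-change enrichment over the mock expectation
#'
#' Counts divided by the peptide's expected mock abundance, after depth
#' scaling. This dimensionless fold-change is the "enrichment" unit
#' consumed by the footprint analysis; counts are floored at
#' `floor_reads` so downstream log-ratios stay finite. The reference is
#' the peptide's own averaged mock count (`ref = "peptide"`, default),
#' which is near-exact whenever per-peptide mock coverage is deep;
#' `ref = "bin"` divides by the trimmed mean of the peptide's
#' mock-abundance bin instead, which denoises the reference in
#' low-coverage full-library screens at the cost of absorbing the
#' within-bin abundance scatter into every ratio.
#'
#' @inheritParams zscore
#' @param floor_reads floor (in reads, post-scaling) applied to counts
#'   and to the reference before the ratio (default 0.5).
#' @param ref `"peptide"` (own mock counts) or `"bin"` (bin trimmed mean).
#' @return matrix of fold-change enrichments (> 0).
#' @export
enrichment <- function(counts, null, depth_normalize = "ratio",
                       floor_reads = 0.5, ref = c("peptide", "bin")) {
  ref <- match.arg(ref)
  m <- if (inherits(counts, "count_table")) counts$counts else
    as.matrix(counts)
  m <- depth_scale(m, null, norm_method(depth_normalize))
  denom <- if (ref == "peptide") null$mock_mean[rownames(m)] else
    null$bin_mean[null$bin[rownames(m)]]
  pmax(m, floor_reads) / pmax(denom, floor_reads)
}

rep_key <- function(ss) paste(ss$subject_id, ss$isotype, ss$timepoint,
                              sep = "|")

#' Average Z-scores over technical replicates
#'
#' Collapses replicate columns to one column per (subject, isotype,
#' timepoint) by the arithmetic mean, and reports the Pearson correlation
#' between the first two replicates of each group as sequencing QC
#' (routinely > 0.95 in well-behaved libraries).
#'
#' @param z peptide x sample Z-score matrix (columns = sample ids).
#' @param samples [sample_sheet()] describing the columns; mocks excluded.
#' @return list: `z` (peptide x group matrix, columns
#'   `subject|isotype|timepoint`), `samples` (one row per group),
#'   `replicate_cor` (data.frame with per-group Pearson r, NA for
#'   single-replicate groups).
#' @export
average_replicates <- function(z, samples) {
  ss <- samples[samples$isotype != "mock", , drop = FALSE]
  z <- z[, ss$sample_id, drop = FALSE]
  key <- rep_key(ss)
  groups <- unique(key)
  zavg <- vapply(groups, function(g)
    rowMeans(z[, key == g, drop = FALSE]), numeric(nrow(z)))
  dimnames(zavg) <- list(rownames(z), groups)
  rc <- vapply(groups, function(g) {
    cols <- which(key == g)
    if (length(cols) < 2L) return(NA_real_)
    cor(z[, cols[1]], z[, cols[2]])
  }, numeric(1))
  meta <- ss[!duplicated(key), c("subject_id", "isotype", "timepoint",
                                 "group")]
  meta$column <- groups
  rownames(meta) <- NULL
  list(z = zavg, samples = meta,
       replicate_cor = data.frame(column = groups, pearson_r = unname(rc),
                                  stringsAsFactors = FALSE))
}

#' Call reactive peptides
#'
#' A peptide is reactive in a sample when its replicate-averaged Z-score
#' strictly exceeds the threshold (default 3.5).
#'
#' @param z_avg replicate-averaged Z matrix ([average_replicates()]`$z`).
#' @param threshold reactivity cutoff (strict `>`).
#' @return data.frame of (`column`, `peptide_id`, `z`) hit pairs.
#' @export
call_hits <- function(z_avg, threshold = 3.5) {
  idx <- which(z_avg > threshold, arr.ind = TRUE)
  data.frame(column = colnames(z_avg)[idx[, 2]],
             peptide_id = rownames(z_avg)[idx[, 1]],
             z = z_avg[idx], stringsAsFactors = FALSE)
}
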