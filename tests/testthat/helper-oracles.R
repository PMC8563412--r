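# Independent brute-force reimplementations used as oracles. These are
# deliberately written as plain loops, separate from the package code.

# Binned-null Z-scores: sort peptides by the abundance estimated from the
# odd-numbered mock replicates, chunk into bins, take trimmed moments of
# the even-numbered replicates' pooled counts per bin, and z-score.
oracle_zscore <- function(mock, samples, bin_size = 300, trim = 0.05,
                          sd_correction = TRUE, sd_floor = 1,
                          depth = "none", input = NULL) {
  nm <- ncol(mock)
  if (!is.null(input)) {
    est <- input
    b_cols <- seq_len(nm)
  } else if (nm >= 2) {
    a_cols <- seq(1, nm, by = 2)
    b_cols <- setdiff(seq_len(nm), a_cols)
    est <- rowMeans(mock[, a_cols, drop = FALSE])
  } else {
    b_cols <- 1L
    est <- mock[, 1]
  }
  mock_mean <- rowMeans(mock)

  sm <- samples
  if (depth == "ratio") {
    ref <- which(mock_mean >= 10)
    if (length(ref) >= 200) {
      for (j in seq_len(ncol(sm))) {
        sj <- median(samples[ref, j] / mock_mean[ref])
        sm[, j] <- samples[, j] / sj
      }
    } else depth <- "total"
  }
  if (depth == "total") {
    for (j in seq_len(ncol(sm)))
      sm[, j] <- samples[, j] * sum(mock_mean) / sum(samples[, j])
  }

  ord <- order(est, rownames(mock), method = "radix")
  z <- matrix(NA_real_, nrow(samples), ncol(samples),
              dimnames = dimnames(samples))
  start <- 1
  while (start <= length(ord)) {
    idx <- ord[start:min(start + bin_size - 1, length(ord))]
    vals <- sort(as.numeric(mock[idx, b_cols]))
    k <- ceiling(trim * length(vals))
    if (length(vals) > 2 * k) {
      mid <- vals[(k + 1):(length(vals) - k)]
      s <- sd(mid)
      if (sd_correction && k > 0) {
        t_eff <- k / length(vals)
        zt <- qnorm(1 - t_eff)
        s <- s / sqrt(1 - 2 * zt * dnorm(zt) / (1 - 2 * t_eff))
      }
    } else {
      mid <- vals
      s <- if (length(mid) > 1) sd(mid) else 0
    }
    mu <- mean(mid)
    s <- max(s, sd_floor)
    for (j in seq_len(ncol(sm))) z[idx, j] <- (sm[idx, j] - mu) / s
    start <- start + bin_size
  }
  z
}

# Connected components by label propagation, independent of igraph.
oracle_components <- function(adj) {
  n <- nrow(adj)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && adj[i, j] && lab[j] != lab[i]) {
        m <- min(lab[i], lab[j])
        lab[lab == lab[i] | lab == lab[j]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# Brute-force window enumeration for tiling.
oracle_tile_starts <- function(len, window = 20, step = 10,
                               cterm_anchor = TRUE) {
  if (len <= window) return(1L)
  starts <- c()
  s <- 1L
  while (s + window - 1L <= len) { starts <- c(starts, s); s <- s + step }
  if (cterm_anchor && max(starts) + window - 1L < len)
    starts <- c(starts, len - window + 1L)
  unique(starts)
}

random_aa <- function(n, len) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  vapply(seq_len(n), function(i)
    paste(sample(aa, len, replace = TRUE), collapse = ""), character(1))
}

# Small fast simulation config for unit tests.
tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_families = 2L, n_variant_families = 1L,
             protein_length = c(60L, 80L), n_allergic = 3L, n_control = 2L,
             n_public = 3L, private_rate = 2, reads_per_sample = 5e5,
             igg_diversification = 2L, ...)
}
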