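#' Simulation configuration
#'
#' Defaults emulate the study conditions of a saturation-mutagenesis
#' PhIP-seq screen of an allergic oral-immunotherapy (OIT) cohort: 15
#' allergic subjects sampled pre (week 0) and post (week 52) OIT for IgE
#' and IgG, 30 non-allergic controls (IgG only), 2 technical replicates
#' per IP sequenced to 2 million reads, a log-normal library abundance
#' with ~75% of mass within one log10 of the median (`sdlog = 2`),
#' 100-fold enrichment of bound wild-type peptides, 10-fold attenuation of
#' mutants at critical footprint positions, public epitopes planted at
#' 30-90% prevalence plus private epitopes per subject, and OIT shifts
#' (IgE enrichment halved, IgG quadrupled, 8 newly acquired IgG epitopes).
#'
#' @param seed integer RNG seed; every simulated quantity is a
#'   deterministic function of it.
#' @param ... overrides for any listed default.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # library
    n_families = 8L,           # allergen families
    n_variant_families = 2L,   # families carrying a second variant
    protein_length = c(80L, 250L),
    window = 20L, step = 10L,
    include_mutants = TRUE,
    abundance_sdlog = 2.0,     # ~75% of mass within one log10 of median
    abundance_trunc = 1.8,     # truncate abundance at +/- this many log10
    # sequencing
    reads_per_sample = 2e6, replicates = 2L, n_mock = 2L,
    input_coverage = 60,       # fold coverage of the input-library QC run
    sigma_rep = 0.1,           # per-replicate efficiency jitter (log-normal sd)
    # cohort
    n_allergic = 15L, n_control = 30L,
    n_public = 10L,
    public_prevalence = NULL,  # default: seq(0.3, 0.9) over public epitopes
    private_rate = 8,          # Poisson mean private IgE epitopes / subject
    igg_given_ige = 0.5,       # P(IgE epitope also in week-0 IgG set)
    control_epitope_rate = 0,  # mean epitopes per control subject
    # footprints
    n_critical = 5L,           # critical positions per epitope
    enrichment_fold = 100,
    attenuation = 10,          # fold reduction of mutants at critical sites
    deviant_rate = 0.2,        # P(subject carries a private deviant footprint)
    igg_coupling = 0.9,        # P(IgG inherits the subject's IgE footprint)
    mutant_binding = FALSE,    # cohort IPs: enrich mutant peptides too
    # OIT effects (week 52)
    oit = TRUE,
    ige_attenuation = 0.5, igg_boost = 4, igg_diversification = 8L,
    igg_diversify_from_ige = 0.7)  # P(new IgG epitope taken from IgE set)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown sim_config fields: ",
                        paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  if (is.null(cfg$public_prevalence))
    cfg$public_prevalence <- seq(0.3, 0.9, length.out = cfg$n_public)
  stopifnot(all(cfg$public_prevalence >= 0 & cfg$public_prevalence <= 1),
            cfg$enrichment_fold >= 1, cfg$attenuation >= 1)
  class(cfg) <- "sim_config"
  cfg
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

#' Simulate a peptide library and its abundance distribution
#'
#' Generates random allergen proteins (some families with two variants, to
#' exercise variant de-duplication), designs the tiling + saturation
#' library at amino-acid level, and draws a log-normal abundance for every
#' peptide, normalized to probabilities. At the default `sdlog = 2`,
#' `2*pnorm(log(10)/2) - 1` = 75% of peptides lie within one log10 of the
#' median abundance, emulating an evenly distributed cloned library.
#'
#' @param config a [sim_config()].
#' @param proteins optional [allergen_proteins()] table; generated from the
#'   seed when omitted.
#' @param set_seed seed the RNG from `config$seed` (default TRUE).
#' @return list: `library` (annotation), `abundance` (named probability
#'   vector), `proteins`.
#' @export
simulate_library <- function(config = sim_config(), proteins = NULL,
                             set_seed = TRUE) {
  if (set_seed) set.seed(config$seed)
  if (is.null(proteins)) {
    nf <- config$n_families
    fam <- sprintf("AllerSim %d", seq_len(nf))
    len_range <- seq(config$protein_length[1], config$protein_length[2])
    lens <- len_range[sample.int(length(len_range), nf, replace = TRUE)]
    ids <- paste0(fam, ".01")
    seqs <- vapply(lens, random_protein, character(1))
    fam_all <- fam
    vf <- head(seq_len(nf), config$n_variant_families)
    for (i in vf) {
      # second variant: same length, a few substitutions
      v <- strsplit(seqs[i], "")[[1]]
      at <- sample(length(v), max(1L, length(v) %/% 25L))
      v[at] <- vapply(v[at], function(a) sample(setdiff(AA20, a), 1L),
                      character(1))
      ids <- c(ids, paste0(fam[i], ".02"))
      seqs <- c(seqs, paste(v, collapse = ""))
      fam_all <- c(fam_all, fam[i])
    }
    proteins <- allergen_proteins(ids, seqs, fam_all)
  }
  lib <- design_library(proteins, window = config$window,
                        step = config$step,
                        mutants = config$include_mutants)
  # Truncated log-normal abundance: sdlog 2 puts ~75% of members within
  # one log10 of the median; the smooth +/- abundance_trunc truncation
  # bounds the tails so that essentially every member is detectable at
  # the ~60x coverage used for library QC, as a well-cloned pool is.
  n_pep <- nrow(lib)
  sdl <- config$abundance_sdlog
  if (sdl > 0) {
    tq <- pnorm(c(-1, 1) * config$abundance_trunc * log(10) / sdl)
    ab <- exp(qnorm(runif(n_pep, tq[1], tq[2])) * sdl)
  } else ab <- rep(1, n_pep)
  ab <- ab / sum(ab)
  names(ab) <- lib$peptide_id
  list(library = lib, abundance = ab, proteins = proteins)
}

# Per-peptide sampling-weight multipliers for one IP. Folds from multiple
# antibody specificities on the same tile combine additively (independent
# clones capture distinct phage). With mutant_binding = FALSE only the
# wild-type tiles are enriched, keeping the bound fraction of the read
# budget small so planted folds survive multinomial renormalization.
ip_fold_vector <- function(library, epitope_folds, critical, attenuation,
                           mutant_binding = TRUE) {
  fold <- rep(1, nrow(library))
  if (!length(epitope_folds)) return(fold)
  tiles <- names(epitope_folds)
  wt <- match(tiles, library$peptide_id)
  if (anyNA(wt)) stop("unknown epitope tile: ", tiles[which(is.na(wt))[1]])
  for (k in seq_along(tiles)) {
    f <- epitope_folds[k]
    fold[wt[k]] <- fold[wt[k]] + (f - 1)
    if (!mutant_binding) next
    mut <- which(!library$is_wildtype &
                   library$parent == library$parent[wt[k]] &
                   library$start == library$start[wt[k]])
    crit <- critical[[tiles[k]]]
    at_crit <- library$mut_position[mut] %in% crit
    f_mut <- ifelse(at_crit, f / attenuation, f)
    fold[mut] <- fold[mut] + (f_mut - 1)
  }
  fold
}

#' Simulate one IP reaction (replicate read counts)
#'
#' Sampling weights are `abundance * fold`, where fold is
#' `enrichment_fold` for bound wild-type peptides, `enrichment_fold /
#' attenuation` for their mutants at critical footprint positions, and 1
#' elsewhere; read counts are one multinomial draw of `reads_per_sample`
#' per replicate (so each column sums exactly to the sequencing depth).
#' Replicate-to-replicate variation beyond resampling comes from an
#' optional log-normal per-peptide efficiency jitter (`sigma_rep`). A mock
#' IP is the special case of no epitopes.
#'
#' @param sim a [simulate_library()] result.
#' @param config a [sim_config()].
#' @param epitope_folds named numeric vector, wild-type tile id ->
#'   enrichment fold (empty for a mock IP).
#' @param critical named list, tile id -> integer critical positions.
#' @param n_rep number of replicate draws.
#' @return integer matrix, peptide x replicate.
#' @export
simulate_ip <- function(sim, config = sim_config(), epitope_folds = numeric(),
                        critical = list(), n_rep = config$replicates,
                        mutant_binding = TRUE) {
  fold <- ip_fold_vector(sim$library, epitope_folds, critical,
                         config$attenuation, mutant_binding)
  w <- sim$abundance * fold
  n <- length(w)
  out <- matrix(0L, n, n_rep, dimnames = list(sim$library$peptide_id, NULL))
  for (r in seq_len(n_rep)) {
    wr <- if (config$sigma_rep > 0)
      w * rlnorm(n, 0, config$sigma_rep) else w
    out[, r] <- rmultinom(1L, size = config$reads_per_sample,
                          prob = wr)[, 1]
  }
  out
}

#' Simulate sequencing of the input library itself
#'
#' The QC run that measures library composition directly (no IP): one
#' multinomial draw over the library abundances at `input_coverage`-fold
#' mean coverage. Used as the independent binning reference for
#' [build_null()].
#'
#' @param sim a [simulate_library()] result.
#' @param config a [sim_config()].
#' @return named integer vector of input-library counts.
#' @export
simulate_input <- function(sim, config = sim_config()) {
  reads <- round(config$input_coverage * length(sim$abundance))
  setNames(rmultinom(1L, reads, sim$abundance)[, 1],
           sim$library$peptide_id)
}

sample_critical <- function(len, n_critical, exclude = integer()) {
  pool <- setdiff(seq_len(len), exclude)
  sort(sample(pool, min(n_critical, length(pool))))
}

#' Simulate a complete cohort experiment with ground truth
#'
#' Emits week-0 and (if `oit`) week-52 IgE/IgG replicate IPs for every
#' allergic subject, single-timepoint IgG for controls, mock IPs, and the
#' generating ground truth. Public epitopes are planted on canonical
#' wild-type tiles at the configured prevalences; each subject adds
#' Poisson-many private epitopes. Every epitope carries a cohort-level
#' critical-position footprint which a subject deviates from with
#' probability `deviant_rate`; week-0 IgG epitope sets subsample the IgE
#' sets and IgG inherits the subject's IgE footprint with probability
#' `igg_coupling`. Under OIT, week-52 IgE enrichment is scaled by
#' `ige_attenuation`, IgG by `igg_boost`, and `igg_diversification` newly
#' recognized IgG epitopes are added per subject.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `library`, `abundance`, `proteins`,
#'   `counts` (a [count_table()]), `truth` (epitope sets, critical
#'   positions, footprint deviants, per-sample fold tables), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  sim <- simulate_library(config, set_seed = FALSE)
  input <- simulate_input(sim, config)
  lib <- sim$library
  canon <- canonical_variants(lib)
  cand <- lib$peptide_id[lib$is_wildtype & lib$parent %in% canon]
  tile_len <- setNames(nchar(lib$aa_seq[match(cand, lib$peptide_id)]), cand)
  if (length(cand) < config$n_public + 5L)
    stop("library too small for the configured number of public epitopes")

  public <- sample(cand, config$n_public)
  prevalence <- setNames(config$public_prevalence, public)
  cohort_critical <- lapply(tile_len, sample_critical,
                            n_critical = config$n_critical)

  subjects <- sprintf("S%02d", seq_len(config$n_allergic))
  controls <- sprintf("C%02d", seq_len(config$n_control))
  timepoints <- if (config$oit) c("week0", "week52") else "week0"

  f0 <- config$enrichment_fold
  truth <- list(public = public, prevalence = prevalence,
                cohort_critical = cohort_critical,
                epitopes = list(), critical = list(), deviant = list(),
                # expected measured Z-ratio under the generating model:
                # Z is proportional to (fold - 1) for a planted peptide
                log2fc = c(
                  IgE = log2((f0 * config$ige_attenuation - 1) / (f0 - 1)),
                  IgG = log2((f0 * config$igg_boost - 1) / (f0 - 1))))
  cols <- list(); meta <- list()

  add_sample <- function(sid, subj, iso, tp, grp, folds, crit) {
    m <- simulate_ip(sim, config, folds, crit,
                     mutant_binding = config$mutant_binding)
    colnames(m) <- paste0(sid, "_r", seq_len(ncol(m)))
    for (r in seq_len(ncol(m))) {
      cols[[length(cols) + 1L]] <<- m[, r]
      meta[[length(meta) + 1L]] <<- data.frame(
        sample_id = colnames(m)[r], subject_id = subj, isotype = iso,
        timepoint = tp, replicate = r, group = grp,
        stringsAsFactors = FALSE)
    }
  }

  for (s in subjects) {
    carried <- public[rbinom(length(public), 1L, prevalence) == 1L]
    private <- sample(setdiff(cand, public),
                      min(rpois(1L, config$private_rate),
                          length(cand) - length(public)))
    ige <- c(carried, private)
    igg <- ige[runif(length(ige)) < config$igg_given_ige]

    crit_ige <- lapply(setNames(ige, ige), function(t) {
      if (runif(1) < config$deviant_rate)
        sample_critical(tile_len[t], config$n_critical,
                        exclude = cohort_critical[[t]])
      else cohort_critical[[t]]
    })
    crit_igg <- lapply(setNames(igg, igg), function(t) {
      if (runif(1) < config$igg_coupling) crit_ige[[t]]
      else sample_critical(tile_len[t], config$n_critical)
    })

    truth$epitopes[[s]] <- list(
      IgE = list(week0 = ige, week52 = if (config$oit) ige),
      IgG = list(week0 = igg))
    truth$critical[[s]] <- list(IgE = crit_ige, IgG = crit_igg)
    truth$deviant[[s]] <- vapply(ige, function(t)
      !identical(crit_ige[[t]], cohort_critical[[t]]), logical(1))

    add_sample(paste0(s, "_IgE_week0"), s, "IgE", "week0", "allergic",
               setNames(rep(f0, length(ige)), ige), crit_ige)
    add_sample(paste0(s, "_IgG_week0"), s, "IgG", "week0", "allergic",
               setNames(rep(f0, length(igg)), igg), crit_igg)

    if (config$oit) {
      # newly acquired IgG epitopes preferentially revisit the subject's
      # pre-existing IgE specificities (OIT-induced IgG tracks IgE)
      n_div <- min(config$igg_diversification, length(cand) - length(igg))
      pool_ige <- setdiff(ige, igg)
      n_from_ige <- min(rbinom(1L, n_div, config$igg_diversify_from_ige),
                        length(pool_ige))
      pool_rest <- setdiff(cand, c(igg, pool_ige))
      new_igg <- c(sample(pool_ige, n_from_ige),
                   sample(pool_rest, n_div - n_from_ige))
      igg52 <- c(igg, new_igg)
      crit_igg52 <- crit_igg
      for (t in new_igg)
        crit_igg52[[t]] <- if (t %in% ige && runif(1) < config$igg_coupling)
          crit_ige[[t]] else cohort_critical[[t]]
      truth$epitopes[[s]]$IgG$week52 <- igg52
      truth$critical[[s]]$IgG52 <- crit_igg52

      add_sample(paste0(s, "_IgE_week52"), s, "IgE", "week52", "allergic",
                 setNames(rep(f0 * config$ige_attenuation, length(ige)),
                          ige), crit_ige)
      add_sample(paste0(s, "_IgG_week52"), s, "IgG", "week52", "allergic",
                 setNames(rep(f0 * config$igg_boost, length(igg52)), igg52),
                 crit_igg52)
    }
  }

  for (s in controls) {
    n_ep <- if (config$control_epitope_rate > 0)
      rpois(1L, config$control_epitope_rate) else 0L
    eps <- if (n_ep > 0) sample(cand, min(n_ep, length(cand))) else character()
    truth$epitopes[[s]] <- list(IgG = list(week0 = eps))
    add_sample(paste0(s, "_IgG_week0"), s, "IgG", "week0", "non_allergic",
               setNames(rep(config$enrichment_fold, length(eps)), eps),
               lapply(setNames(eps, eps), function(t)
                 cohort_critical[[t]]))
  }

  mocks <- simulate_ip(sim, config, n_rep = config$n_mock)
  for (r in seq_len(config$n_mock)) {
    cols[[length(cols) + 1L]] <- mocks[, r]
    meta[[length(meta) + 1L]] <- data.frame(
      sample_id = paste0("mock_r", r), subject_id = NA_character_,
      isotype = "mock", timepoint = "none", replicate = r, group = "mock",
      stringsAsFactors = FALSE)
  }

  counts <- do.call(cbind, cols)
  rownames(counts) <- lib$peptide_id
  meta <- do.call(rbind, meta)
  colnames(counts) <- meta$sample_id
  ss <- sample_sheet(meta$sample_id, meta$subject_id, meta$isotype,
                     meta$timepoint, meta$replicate, meta$group)
  structure(list(library = lib, abundance = sim$abundance,
                 proteins = sim$proteins,
                 counts = count_table(counts, ss),
                 input_counts = input,
                 truth = truth, config = config),
            class = "sim_cohort")
}

#' Simulate a focused footprint panel for one epitope tile
#'
#' High-resolution footprint questions (critical-residue recovery, shared
#' vs deviant footprints, IgE/IgG footprint similarity) are simulated on a
#' small library with mutant binding fully modeled: every subject's IP
#' enriches one planted epitope tile, with its mutants attenuated at that
#' subject's critical positions. Subjects with `NULL` in `critical_sets`
#' get the shared (first) footprint.
#'
#' @param config a [sim_config()] (a small `n_families` keeps this fast).
#' @param critical_sets named list, subject -> integer critical positions
#'   for the planted tile.
#' @param tile_index which canonical wild-type tile to plant (default 1).
#' @param n_rep replicates per subject IP.
#' @return list: `sim` (library), `tile` (planted tile id), `counts`
#'   (peptide x (subject x replicate) matrix, plus mock columns
#'   `mock_r*`), `critical_sets`, `null` ([build_null()]), `enrichment`,
#'   `z`, and `footprints` (subject -> [relative_enrichment()] footprint
#'   from replicate 1).
#' @export
simulate_footprint_panel <- function(config, critical_sets,
                                     tile_index = 1L, n_rep = 2L) {
  set.seed(config$seed)
  sim <- simulate_library(config, set_seed = FALSE)
  canon <- canonical_variants(sim$library)
  cand <- sim$library$peptide_id[sim$library$is_wildtype &
                                   sim$library$parent %in% canon]
  tile <- cand[tile_index]
  subjects <- names(critical_sets)
  cols <- list()
  for (s in subjects) {
    m <- simulate_ip(sim, config,
                     setNames(config$enrichment_fold, tile),
                     setNames(list(critical_sets[[s]]), tile),
                     n_rep = n_rep)
    colnames(m) <- paste0(s, "_r", seq_len(n_rep))
    cols[[s]] <- m
  }
  mocks <- simulate_ip(sim, config, n_rep = config$n_mock)
  colnames(mocks) <- paste0("mock_r", seq_len(config$n_mock))
  input <- simulate_input(sim, config)
  counts <- do.call(cbind, c(cols, list(mocks)))
  null <- build_null(mocks, input_counts = input)
  enr <- enrichment(counts, null)
  z <- zscore(counts, null)
  fps <- lapply(setNames(subjects, subjects), function(s)
    relative_enrichment(enrichment_set(enr, sim$library, tile,
                                       paste0(s, "_r1"),
                                       wt_z = z[tile, paste0(s, "_r1")])))
  list(sim = sim, tile = tile, counts = counts,
       critical_sets = critical_sets, null = null, input_counts = input,
       enrichment = enr, z = z, footprints = fps)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d peptides, %d samples (%d allergic, %d control subjects)\n",
    nrow(x$counts$counts), ncol(x$counts$counts),
    x$config$n_allergic, x$config$n_control))
  invisible(x)
}
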