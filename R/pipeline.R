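#' Run configuration
#'
#' All pipeline tunables with their defaults: tiling window/step, null
#' binning, the Z > 3.5 reactivity threshold, the Z > 5 footprint gate,
#' the 40% critical-residue fraction, the 30% public-epitope threshold and
#' the 0.75 footprint-sharing threshold. Serialized (with an md5 hash)
#' into every output directory for provenance.
#'
#' @param ... overrides for any default.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(window = 20L, step = 10L, cterm_anchor = TRUE,
              bin_size = 300L, trim = 0.05, sd_correction = TRUE,
              depth_normalize = "ratio",
              hit_threshold = 3.5, z_gate = 5.0, critical_fraction = 0.40,
              public_threshold = 0.30, share_threshold = 0.75,
              unique_prefix_len = 50L, seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown run_config fields: ",
                        paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  stopifnot(cfg$hit_threshold > 0, cfg$trim >= 0, cfg$trim < 0.5,
            cfg$critical_fraction > 0, cfg$critical_fraction < 1,
            cfg$public_threshold >= 0, cfg$public_threshold <= 1,
            cfg$share_threshold >= -1, cfg$share_threshold <= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Quantify a count table end-to-end
#'
#' Builds the binned mock null from the table's mock columns, Z-scores all
#' serum samples, averages replicates, and calls reactive peptides.
#'
#' @param ct a [count_table()] containing mock columns.
#' @param config a [run_config()].
#' @param input_counts optional input-library sequencing counts used as
#'   the binning reference (see [build_null()]).
#' @return list: `null`, `z` (per replicate), `z_avg`, `samples` (one row
#'   per averaged column), `replicate_cor`, `hits`, `enrichment`.
#' @export
analyze_counts <- function(ct, config = run_config(),
                           input_counts = NULL) {
  null <- build_null(ct, bin_size = config$bin_size, trim = config$trim,
                     sd_correction = config$sd_correction,
                     input_counts = input_counts)
  z <- zscore(ct, null, depth_normalize = config$depth_normalize)
  avg <- average_replicates(z, ct$samples)
  list(null = null, z = z, z_avg = avg$z, samples = avg$samples,
       replicate_cor = avg$replicate_cor,
       hits = call_hits(avg$z, config$hit_threshold),
       enrichment = enrichment(ct, null,
                               depth_normalize = config$depth_normalize))
}

#' Footprints for a set of tiles in one sample column
#'
#' Builds [relative_enrichment()] footprints for the given wild-type tiles
#' from an enrichment matrix, attaching each tile's Z-score from `z` for
#' downstream gating.
#'
#' @param enr peptide x sample enrichment matrix.
#' @param library peptide annotation.
#' @param sample column of `enr` (and of `z`).
#' @param tiles wild-type tile ids (default: all in the library).
#' @param z matrix of Z-scores aligned with `enr` columns (optional).
#' @param critical_fraction passed to [relative_enrichment()].
#' @return named list of footprints (NULL entries dropped).
#' @export
sample_footprints <- function(enr, library, sample, tiles = NULL, z = NULL,
                              critical_fraction = 0.40) {
  if (is.null(tiles))
    tiles <- library$peptide_id[library$is_wildtype]
  fps <- lapply(setNames(tiles, tiles), function(t) {
    wz <- if (!is.null(z)) unname(z[t, sample]) else NA_real_
    relative_enrichment(enrichment_set(enr, library, t, sample, wt_z = wz),
                        critical_fraction)
  })
  Filter(Negate(is.null), fps)
}

#' Run the full pipeline on a simulated or provided experiment
#'
#' Quantifies counts against the mock null, computes per-sample epitope
#' sets and repertoire summaries (breadth, seroprevalence/public calls,
#' IgE-IgG Jaccard and overlap categories, pre-existing-epitope fold
#' changes across timepoints), and writes all result TSVs plus the config
#' (and its hash) to `out_dir`. Stages run in order and abort naming the
#' failing stage.
#'
#' @param ct a [count_table()] with mock columns.
#' @param library peptide annotation for `ct`.
#' @param config a [run_config()].
#' @param out_dir output directory (created); omit to skip writing.
#' @param input_counts optional input-library sequencing counts (binning
#'   reference, see [build_null()]).
#' @return list: `quant` ([analyze_counts()] result), `epitopes` (per
#'   column), `breadth`, `seroprevalence`, `jaccard`, `overlap`,
#'   `fold_change` data.frames.
#' @export
run_pipeline <- function(ct, library, config = run_config(),
                         out_dir = NULL, input_counts = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  quant <- stage("quantify", analyze_counts(ct, config, input_counts))
  zavg <- quant$z_avg
  meta <- quant$samples

  eps <- stage("epitopes", lapply(setNames(meta$column, meta$column),
                                  function(cl) epitope_set(
                                    zavg, cl, library,
                                    config$hit_threshold)))
  breadth_df <- data.frame(meta[, c("subject_id", "isotype", "timepoint")],
                           column = meta$column,
                           breadth = lengths(eps)[meta$column],
                           stringsAsFactors = FALSE)

  sero <- stage("seroprevalence", {
    canon <- canonical_variants(library)
    wt <- intersect(library$peptide_id[library$is_wildtype &
                                         library$parent %in% canon],
                    rownames(zavg))
    out <- list()
    for (iso in setdiff(unique(meta$isotype), "mock"))
      for (tp in unique(meta$timepoint[meta$isotype == iso])) {
        cls <- meta$column[meta$isotype == iso & meta$timepoint == tp &
                             meta$group == "allergic"]
        if (length(cls) < 1L) next
        prev <- vapply(wt, function(t)
          seroprevalence(zavg, t, cls, config$hit_threshold), numeric(1))
        out[[paste(iso, tp)]] <- data.frame(
          peptide_id = wt, isotype = iso, timepoint = tp,
          seroprevalence = unname(prev),
          public = classify_public(prev, config$public_threshold),
          stringsAsFactors = FALSE)
      }
    do.call(rbind, out)
  })

  jac <- stage("jaccard", {
    out <- list()
    for (s in unique(meta$subject_id[meta$group == "allergic"]))
      for (tp in unique(meta$timepoint[meta$subject_id == s])) {
        kE <- paste(s, "IgE", tp, sep = "|")
        kG <- paste(s, "IgG", tp, sep = "|")
        if (!kE %in% names(eps) || !kG %in% names(eps)) next
        oc <- overlap_categories(eps[[kE]], eps[[kG]])
        out[[paste(s, tp)]] <- data.frame(
          subject_id = s, timepoint = tp,
          jaccard = jaccard(eps[[kE]], eps[[kG]]),
          ige_only = oc[["ige_only"]], igg_only = oc[["igg_only"]],
          shared = oc[["shared"]], stringsAsFactors = FALSE)
      }
    do.call(rbind, out)
  })

  fc <- stage("fold_change", {
    tps <- unique(meta$timepoint)
    canon <- canonical_variants(library)
    wt <- intersect(library$peptide_id[library$is_wildtype &
                                         library$parent %in% canon],
                    rownames(zavg))
    if (length(tps) < 2L) NULL else {
      out <- list()
      for (s in unique(meta$subject_id[meta$group == "allergic"]))
        for (iso in c("IgE", "IgG")) {
          k0 <- paste(s, iso, tps[1], sep = "|")
          k1 <- paste(s, iso, tps[2], sep = "|")
          if (!all(c(k0, k1) %in% colnames(zavg))) next
          r <- preexisting_fold_change(zavg[wt, k0], zavg[wt, k1],
                                       config$hit_threshold)
          out[[paste(s, iso)]] <- data.frame(
            subject_id = s, isotype = iso, mean_log2fc = r$mean_log2fc,
            sem = r$sem, n = r$n, stringsAsFactors = FALSE)
        }
      do.call(rbind, out)
    }
  })

  res <- list(quant = quant, epitopes = eps, breadth = breadth_df,
              seroprevalence = sero, jaccard = jac, fold_change = fc,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_plain <- unclass(config)
    yaml::write_yaml(cfg_plain, file.path(out_dir, "run_config.yaml"))
    write_zscores(zavg, file.path(out_dir, "zscores_avg.tsv"), cfg_plain)
    write_tsv_hdr(breadth_df, file.path(out_dir, "breadth.tsv"), cfg_plain)
    if (!is.null(sero))
      write_tsv_hdr(sero, file.path(out_dir, "seroprevalence.tsv"),
                    cfg_plain)
    if (!is.null(jac))
      write_tsv_hdr(jac, file.path(out_dir, "jaccard.tsv"), cfg_plain)
    if (!is.null(fc))
      write_tsv_hdr(fc, file.path(out_dir, "fold_change.tsv"), cfg_plain)
    write_tsv_hdr(quant$replicate_cor,
                  file.path(out_dir, "replicate_qc.tsv"), cfg_plain)
  }
  res
}
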