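ANNOT_COLS <- c("peptide_id", "parent", "family", "start", "end",
                "is_wildtype", "mut_position", "mut_residue", "aa_seq")

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

write_tsv_hdr <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  hash <- if (is.null(config)) "none" else config_hash(config)
  writeLines(sprintf("# allerscan config=%s", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_hdr <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write the peptide library to disk
#'
#' Writes (a) the annotation TSV (fixed column set) and (b) an oligo FASTA
#' whose headers are the peptide ids. Both round-trip losslessly through
#' [read_library()].
#'
#' @param peptides completed peptide records (with `oligo_seq` if the FASTA
#'   is wanted).
#' @param dir output directory, created if needed.
#' @param config optional config list recorded as a hash in file headers.
#' @return invisibly, the paths written.
#' @export
write_library <- function(peptides, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann_path <- file.path(dir, "library_annotation.tsv")
  write_tsv_hdr(peptides[, intersect(c(ANNOT_COLS, "nt_seq"),
                                     names(peptides))], ann_path, config)
  paths <- ann_path
  if (!is.null(peptides$oligo_seq)) {
    fa_path <- file.path(dir, "library_oligos.fasta")
    oligos <- Biostrings::DNAStringSet(peptides$oligo_seq)
    names(oligos) <- peptides$peptide_id
    Biostrings::writeXStringSet(oligos, fa_path, width = 200L)
    paths <- c(paths, fa_path)
  }
  invisible(paths)
}

#' Read a peptide library written by [write_library()]
#'
#' @param dir directory containing `library_annotation.tsv` and, optionally,
#'   `library_oligos.fasta`.
#' @return peptide annotation data.frame (with `oligo_seq` if present).
#' @export
read_library <- function(dir) {
  ann <- read_tsv_hdr(file.path(dir, "library_annotation.tsv"))
  ann$mut_residue <- as.character(ann$mut_residue)
  ann$mut_residue[ann$is_wildtype] <- NA_character_
  fa_path <- file.path(dir, "library_oligos.fasta")
  if (file.exists(fa_path)) {
    oligos <- Biostrings::readDNAStringSet(fa_path)
    ann$oligo_seq <- as.character(oligos)[match(ann$peptide_id,
                                                names(oligos))]
  }
  ann
}

#' Sample sheet constructor
#'
#' One row per sequenced IP reaction. Mock reactions (no serum) are flagged
#' by `isotype = "mock"` and carry no subject.
#'
#' @param sample_id unique sample identifiers.
#' @param subject_id subject per sample (`NA` for mocks).
#' @param isotype `"IgE"`, `"IgG"` or `"mock"`.
#' @param timepoint label, e.g. `"week0"` / `"week52"`.
#' @param replicate integer replicate index (>= 1).
#' @param group `"allergic"`, `"non_allergic"` or `"mock"`.
#' @export
sample_sheet <- function(sample_id, subject_id, isotype, timepoint,
                         replicate, group) {
  ss <- data.frame(sample_id = as.character(sample_id),
                   subject_id = as.character(subject_id),
                   isotype = as.character(isotype),
                   timepoint = as.character(timepoint),
                   replicate = as.integer(replicate),
                   group = as.character(group),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(ss$sample_id)) stop("sample_id must be unique")
  key <- with(ss, paste(subject_id, isotype, timepoint, replicate))
  if (anyDuplicated(key[ss$isotype != "mock"]))
    stop("(subject, isotype, timepoint, replicate) must be unique")
  if (any(ss$isotype == "mock" & !is.na(ss$subject_id)))
    stop("mock samples must not carry a subject")
  ss
}

#' Assemble a count table
#'
#' Peptide x sample matrix of raw read counts plus its sample sheet.
#'
#' @param counts non-negative integer matrix, rownames = peptide ids,
#'   colnames = sample ids.
#' @param samples [sample_sheet()] covering every column.
#' @return object of class `count_table` (list: `counts`, `samples`).
#' @export
count_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (is.null(rownames(counts))) stop("counts needs peptide rownames")
  if (!identical(sort(colnames(counts)), sort(samples$sample_id)))
    stop("count columns and sample sheet disagree")
  counts <- counts[, samples$sample_id, drop = FALSE]
  structure(list(counts = counts, samples = samples),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d peptides x %d samples (%d mock)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$isotype == "mock")))
  invisible(x)
}

#' Write / read count tables and sample sheets
#'
#' Counts are written as TSV with peptides as rows (`peptide_id` key
#' column) and one column per sample; the sample sheet as CSV.
#'
#' @param ct a [count_table()].
#' @param dir output directory.
#' @param config optional config recorded in headers.
#' @export
write_counts <- function(ct, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(peptide_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_hdr(df, file.path(dir, "counts.tsv"), config)
  write.csv(ct$samples, file.path(dir, "sample_sheet.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_counts
#' @export
read_counts <- function(dir) {
  df <- read_tsv_hdr(file.path(dir, "counts.tsv"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$peptide_id
  ss <- read.csv(file.path(dir, "sample_sheet.csv"),
                 stringsAsFactors = FALSE)
  ss$subject_id <- as.character(ss$subject_id)
  count_table(m, ss)
}

#' Write a Z-score matrix as TSV keyed by peptide id
#'
#' @param z matrix with peptide rownames.
#' @param path output file.
#' @param config optional config recorded in the header.
#' @export
write_zscores <- function(z, path, config = NULL) {
  df <- data.frame(peptide_id = rownames(z), z, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_hdr(df, path, config)
}

#' @rdname write_zscores
#' @export
read_zscores <- function(path) {
  df <- read_tsv_hdr(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$peptide_id
  m
}
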