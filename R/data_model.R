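## Core containers and transforms shared by every pipeline stage.
##
## Matrices are always probe x sample; `samples` is a data.frame sample
## sheet; `controls` is a long table of control-probe intensities.  The
## dataset carries a `processing` character vector recording which
## corrections have been applied (provenance).

#' Construct a methylation dataset
#'
#' Bundles the methylated/unmethylated intensity matrices, per-probe bead
#' counts, control-probe intensities and the sample sheet into a validated
#' container.  All matrices are probe x sample and must share dimnames.
#'
#' @param meth,unmeth Non-negative numeric matrices (probe x sample) of
#'   methylated / unmethylated fluorescence intensities.
#' @param beads Non-negative integer matrix of bead counts, same shape.
#' @param controls Data frame of control-probe intensities with columns
#'   `control_type` (one of `"bisulfite"`, `"negative"`, `"norm_grn"`,
#'   `"norm_red"`), `channel` (`"green"` or `"red"`), `probe_id`, and one
#'   numeric column per sample (intensities).
#' @param samples Sample sheet data frame; see [validate_sample_sheet()].
#' @param processing Character vector of processing-stage tags already
#'   applied (e.g. `"background_corrected"`). Defaults to none.
#' @return An object of class `MethylationDataset`.
#' @export
methylation_dataset <- function(meth, unmeth, beads, controls, samples,
                                processing = character()) {
  ds <- structure(
    list(meth = meth, unmeth = unmeth, beads = beads,
         controls = controls, samples = samples,
         probes = rownames(meth), processing = processing),
    class = "MethylationDataset")
  validate_dataset(ds)
  ds
}

#' Validate a methylation dataset
#'
#' Checks shared probe/sample ordering across assays, non-negativity of
#' intensities, and a one-to-one match between matrix columns and sample
#' sheet rows.  Errors name the offending sample IDs.
#'
#' @param ds A `MethylationDataset`.
#' @return `ds`, invisibly, if valid.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "MethylationDataset"))
  for (nm in c("meth", "unmeth", "beads")) {
    m <- ds[[nm]]
    if (!is.matrix(m)) stop("'", nm, "' must be a matrix")
    if (!identical(dim(m), dim(ds$meth)))
      stop("'", nm, "' dimensions differ from 'meth'")
    if (!identical(rownames(m), rownames(ds$meth)) ||
        !identical(colnames(m), colnames(ds$meth)))
      stop("'", nm, "' dimnames differ from 'meth'")
    if (any(m < 0)) stop("negative values in '", nm, "'")
  }
  validate_sample_sheet(ds$samples)
  mat_ids <- colnames(ds$meth)
  sheet_ids <- ds$samples$sample_id
  missing_in_sheet <- setdiff(mat_ids, sheet_ids)
  missing_in_mat <- setdiff(sheet_ids, mat_ids)
  if (length(missing_in_sheet) || length(missing_in_mat))
    stop("sample ID mismatch between matrices and sample sheet; ",
         "missing from sheet: [",
         paste(missing_in_sheet, collapse = ", "),
         "]; missing from matrices: [",
         paste(missing_in_mat, collapse = ", "), "]")
  ctrl <- ds$controls
  need <- c("control_type", "channel", "probe_id")
  if (!all(need %in% names(ctrl)))
    stop("controls table must have columns ",
         paste(need, collapse = ", "))
  if (!all(mat_ids %in% names(ctrl)))
    stop("controls table lacks intensity columns for samples: ",
         paste(setdiff(mat_ids, names(ctrl)), collapse = ", "))
  bad_type <- setdiff(unique(ctrl$control_type),
                      c("bisulfite", "negative", "norm_grn", "norm_red"))
  if (length(bad_type))
    stop("unknown control_type: ", paste(bad_type, collapse = ", "))
  invisible(ds)
}

#' Validate a sample sheet
#'
#' Required columns: `sample_id`, `subject_id`, `tissue` (blood/csf),
#' `collection_day`, `plate`, `chip`, `row` (1-6), `column` (1-2),
#' `replicate_group`, `trait`, `age`, `sex`, `is_control_sample`,
#' `control_level`.  Enforces unique (plate, chip, row, column) positions
#' and that technical replicates share subject, tissue and day.
#'
#' @param s Sample sheet data frame.
#' @return `s`, invisibly, if valid.
#' @export
validate_sample_sheet <- function(s) {
  need <- c("sample_id", "subject_id", "tissue", "collection_day",
            "plate", "chip", "row", "column", "replicate_group",
            "trait", "age", "sex", "is_control_sample", "control_level")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(s$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!all(s$tissue %in% c("blood", "csf")))
    stop("tissue must be 'blood' or 'csf'")
  if (!all(s$row %in% 1:6) || !all(s$column %in% 1:2))
    stop("row must be in 1..6 and column in 1..2")
  pos <- paste(s$plate, s$chip, s$row, s$column)
  if (anyDuplicated(pos))
    stop("duplicate (plate, chip, row, column) position: ",
         pos[duplicated(pos)][1])
  lv <- s$control_level[s$is_control_sample]
  if (length(lv) && !all(lv %in% c(0, 0.30, 0.70, 1.0)))
    stop("control_level must be one of 0, 0.30, 0.70, 1.0")
  rg <- s$replicate_group[!is.na(s$replicate_group)]
  for (g in unique(rg)) {
    members <- s[!is.na(s$replicate_group) & s$replicate_group == g, ]
    if (length(unique(members$subject_id)) > 1 ||
        length(unique(members$tissue)) > 1 ||
        length(unique(members$collection_day)) > 1)
      stop("replicate_group '", g,
           "' members differ in subject/tissue/day")
  }
  invisible(s)
}

#' Validate a probe annotation table
#'
#' Columns: `probe_id`, `design_type` (I-green / I-red / II),
#' `chromosome`, `region` (island / shore / shelf / open_sea),
#' `orientation` (TSS / 5'UTR / first_exon / body / 3'UTR / intergenic),
#' `snp_overlap`, `cross_reactive` (logical flags).
#'
#' @param a Annotation data frame.
#' @return `a`, invisibly, if valid.
#' @export
validate_annotation <- function(a) {
  need <- c("probe_id", "design_type", "chromosome", "region",
            "orientation", "snp_overlap", "cross_reactive")
  miss <- setdiff(need, names(a))
  if (length(miss))
    stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (!all(a$design_type %in% c("I-green", "I-red", "II")))
    stop("design_type must be I-green, I-red or II")
  if (!all(a$region %in% c("island", "shore", "shelf", "open_sea")))
    stop("region category out of range")
  if (!all(a$orientation %in% c("TSS", "5'UTR", "first_exon", "body",
                                "3'UTR", "intergenic")))
    stop("orientation category out of range")
  if (anyDuplicated(a$probe_id)) stop("duplicate probe_id in annotation")
  invisible(a)
}

#' @export
print.MethylationDataset <- function(x, ...) {
  cat("MethylationDataset:", nrow(x$meth), "probes x",
      ncol(x$meth), "samples\n")
  cat("  tissues:", paste(sort(unique(x$samples$tissue)), collapse = ", "),
      "\n")
  cat("  control probes:", nrow(x$controls), "\n")
  cat("  processing:",
      if (length(x$processing)) paste(x$processing, collapse = " -> ")
      else "raw", "\n")
  invisible(x)
}

#' Beta-values from channel intensities
#'
#' Beta = meth / (meth + unmeth + offset), the standard Illumina
#' definition of percent methylation; the offset regularizes low-intensity
#' probes.  Works elementwise on vectors or matrices.
#'
#' @param meth,unmeth Non-negative intensities (same shape).
#' @param offset Positive regularizing constant, default 100.
#' @return Beta-values in `[0, 1)`, same shape as the inputs.
#' @export
beta_from_intensities <- function(meth, unmeth, offset = 100) {
  if (any(meth < 0) || any(unmeth < 0))
    stop("negative intensities are not allowed")
  if (offset <= 0) stop("offset must be > 0")
  meth / (meth + unmeth + offset)
}

#' M-values from beta-values
#'
#' M = log2(beta / (1 - beta)).  Betas are clipped to
#' `[eps, 1 - eps]` first so the transform stays finite for degenerate
#' fully (un)methylated values.
#'
#' @param beta Beta-values in `[0, 1]`.
#' @param eps Clipping bound, default `1e-6`.
#' @return M-values, same shape as `beta`.
#' @export
m_from_beta <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Beta-values from M-values (inverse logit2)
#'
#' @param m M-values.
#' @return Beta-values in `(0, 1)`.
#' @export
beta_from_m <- function(m) {
  2^m / (1 + 2^m)
}

#' Beta and M matrices for a dataset
#'
#' @param ds A `MethylationDataset`.
#' @param offset Beta offset, see [beta_from_intensities()].
#' @return List with `beta` and `m` matrices (probe x sample) and a
#'   `provenance` tag copied from the dataset's processing history.
#' @export
dataset_beta <- function(ds, offset = 100) {
  beta <- beta_from_intensities(ds$meth, ds$unmeth, offset = offset)
  list(beta = beta, m = m_from_beta(beta),
       provenance = if (length(ds$processing))
         paste(ds$processing, collapse = "+") else "raw")
}

## ---- readers / writers -------------------------------------------------

write_matrix_tsv <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a dataset to a directory of plain-text files
#'
#' Emits `meth.tsv`, `unmeth.tsv`, `beads.tsv` (probe x sample TSV with a
#' leading `probe_id` column), `controls.tsv` and `samples.csv`.  With
#' `gzip = TRUE` the matrices are gzip-compressed (`.tsv.gz`).
#'
#' @param ds A `MethylationDataset`.
#' @param dir Output directory (created if absent).
#' @param gzip Compress the matrix files?
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, gzip = FALSE) {
  validate_dataset(ds)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (gzip) ".tsv.gz" else ".tsv"
  write_matrix_tsv(ds$meth, file.path(dir, paste0("meth", ext)))
  write_matrix_tsv(ds$unmeth, file.path(dir, paste0("unmeth", ext)))
  write_matrix_tsv(ds$beads, file.path(dir, paste0("beads", ext)))
  write.table(ds$controls, file.path(dir, "controls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.csv(ds$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  writeLines(ds$processing, file.path(dir, "processing.txt"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the dataset files.
#' @return A validated `MethylationDataset`.
#' @export
read_dataset <- function(dir) {
  pick <- function(stem) {
    for (ext in c(".tsv", ".tsv.gz")) {
      p <- file.path(dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
    stop("no file '", stem, ".tsv[.gz]' in ", dir)
  }
  samples <- read.csv(file.path(dir, "samples.csv"),
                      stringsAsFactors = FALSE)
  samples$replicate_group <- as.character(samples$replicate_group)
  controls <- read.delim(file.path(dir, "controls.tsv"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  proc_path <- file.path(dir, "processing.txt")
  processing <- if (file.exists(proc_path)) readLines(proc_path)
                else character()
  methylation_dataset(
    meth = read_matrix_tsv(pick("meth")),
    unmeth = read_matrix_tsv(pick("unmeth")),
    beads = read_matrix_tsv(pick("beads")),
    controls = controls, samples = samples, processing = processing)
}

#' Write / read a probe annotation table (TSV)
#'
#' @param a Annotation data frame.
#' @param path TSV path.
#' @return `path` (write) or the annotation data frame (read).
#' @export
write_annotation <- function(a, path) {
  validate_annotation(a)
  write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  a <- read.delim(path, stringsAsFactors = FALSE)
  a$snp_overlap <- as.logical(a$snp_overlap)
  a$cross_reactive <- as.logical(a$cross_reactive)
  validate_annotation(a)
  a
}
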