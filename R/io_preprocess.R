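#' Compute a methylation beta value from probe intensities
#'
#' Converts methylated/unmethylated fluorescence intensities into a
#' methylation fraction using the standard Infinium estimator
#' \deqn{\beta = \max(M,0) / [\max(M,0) + \max(U,0) + 100]}
#' where the offset of 100 stabilises the ratio at low total intensity.
#' Negative intensities (possible after background correction) clamp to zero.
#'
#' @param meth_signal Numeric vector of methylated-allele intensities.
#' @param unmeth_signal Numeric vector of unmethylated-allele intensities.
#' @return Numeric vector of beta values in `[0, 1)`.
#' @examples
#' beta_from_intensities(900, 100)   # 0.8181...
#' beta_from_intensities(-50, 200)   # 0
#' @export
beta_from_intensities <- function(meth_signal, unmeth_signal) {
  if (!is.numeric(meth_signal) || !is.numeric(unmeth_signal)) {
    stop("intensities must be numeric", call. = FALSE)
  }
  m <- pmax(meth_signal, 0)
  u <- pmax(unmeth_signal, 0)
  m / (m + u + 100)
}

#' Logit2-transform beta values to M values
#'
#' M values, \eqn{\log_2(\beta / (1 - \beta))}, stabilise the variance of
#' methylation fractions and are the preferred scale for linear modelling.
#' Betas are clipped to `[epsilon, 1 - epsilon]` so boundary values stay
#' finite.
#'
#' @param beta Numeric vector or matrix of methylation fractions in `[0, 1]`.
#'   `NA` values are propagated.
#' @param epsilon Clip bound, `0 < epsilon < 0.5`. Default `1e-6`.
#' @return M values with the same shape (and dimnames) as `beta`.
#' @export
beta_to_mvalue <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(beta)) stop("beta must be numeric", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon <= 0 || epsilon >= 0.5) {
    stop("epsilon must be a single value in (0, 0.5)", call. = FALSE)
  }
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) {
    stop("beta values outside [0, 1] at ", sum(bad), " position(s)",
         call. = FALSE)
  }
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  out <- log2(b / (1 - b))
  if (!is.null(dim(beta))) {
    dim(out) <- dim(beta)
    dimnames(out) <- dimnames(beta)
  }
  out
}

#' Inverse of [beta_to_mvalue()]
#'
#' @param m Numeric vector or matrix of M values (log2 units).
#' @return Beta values in `(0, 1)`.
#' @export
mvalue_to_beta <- function(m) {
  out <- 2^m / (1 + 2^m)
  if (!is.null(dim(m))) {
    dim(out) <- dim(m)
    dimnames(out) <- dimnames(m)
  }
  out
}

# split semicolon-joined mask strings into a list of character vectors
.split_masks <- function(masks) {
  masks[is.na(masks)] <- ""
  strsplit(masks, ";", fixed = TRUE)
}

.check_beta_matrix <- function(bm) {
  if (!is.matrix(bm) || !is.numeric(bm)) {
    stop("beta matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(bm)) || is.null(colnames(bm))) {
    stop("beta matrix must carry probe rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(bm))) stop("duplicate probe ids", call. = FALSE)
  if (anyDuplicated(colnames(bm))) stop("duplicate sample ids", call. = FALSE)
  rng <- range(bm, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("beta values outside [0, 1]", call. = FALSE)
  }
  invisible(bm)
}

#' Filter probes by annotation masks
#'
#' Removes probes carrying any of the requested exclusion flags. When
#' `"sex_chromosome"` is among `exclude_flags`, probes annotated to the X or Y
#' chromosome are removed whether or not they carry an explicit mask. Probe
#' order of the retained set is preserved, so the operation is idempotent.
#'
#' @param bm Beta matrix (probes x samples) with probe rownames.
#' @param ann Probe annotation `data.frame` with columns `probe_id`,
#'   `chromosome` and `masks` (semicolon-joined flag strings; `""` or `NA`
#'   means unmasked).
#' @param exclude_flags Character vector of mask names to exclude, e.g.
#'   `c("sex_chromosome", "cross_reactive", "snp_overlap")`.
#' @return The beta matrix restricted to retained probes.
#' @export
filter_probes <- function(bm, ann,
                          exclude_flags = c("sex_chromosome",
                                            "cross_reactive",
                                            "snp_overlap")) {
  probes <- rownames(bm)
  missing <- setdiff(probes, ann$probe_id)
  if (length(missing) > 0) {
    stop("probes lacking annotation: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ..." else "", call. = FALSE)
  }
  if (length(exclude_flags) == 0) return(bm)
  ann <- ann[match(probes, ann$probe_id), , drop = FALSE]
  flag_list <- .split_masks(as.character(ann$masks))
  drop <- vapply(flag_list, function(f) any(f %in% exclude_flags), logical(1))
  if ("sex_chromosome" %in% exclude_flags) {
    drop <- drop | ann$chromosome %in% c("X", "Y", "chrX", "chrY")
  }
  bm[!drop, , drop = FALSE]
}

#' Select the most variable probes
#'
#' Ranks probes by their across-sample variance of beta values (the scale on
#' which deconvolution operates) and keeps the top `count`. Ties are broken by
#' probe id in lexicographic order so the selection is deterministic.
#'
#' @param bm Beta matrix (probes x samples).
#' @param count Number of probes to keep; when `count >= nrow(bm)` the input
#'   is returned unchanged.
#' @return Beta matrix restricted to the selected probes, ordered by
#'   decreasing variance.
#' @export
select_most_variable <- function(bm, count) {
  if (ncol(bm) < 2) {
    stop("variance requires at least 2 samples", call. = FALSE)
  }
  if (!is.numeric(count) || length(count) != 1 || count < 1) {
    stop("count must be a positive integer", call. = FALSE)
  }
  if (count >= nrow(bm)) return(bm)
  n <- ncol(bm)
  mu <- rowMeans(bm)
  v <- rowSums((bm - mu)^2) / (n - 1)
  ord <- order(-v, rownames(bm), method = "radix")
  bm[ord[seq_len(count)], , drop = FALSE]
}

.island_levels <- c("island", "shore", "shelf", "open_sea")
.gene_region_levels <- c("promoter", "exon", "intron", "intergenic")

.check_annotation <- function(ann) {
  req <- c("probe_id", "chromosome", "position", "island_relation",
           "gene_region", "masks")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0) {
    stop("annotation missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ann$probe_id)) {
    stop("duplicate probe_id in annotation", call. = FALSE)
  }
  bad_isl <- !ann$island_relation %in% .island_levels
  if (any(bad_isl)) {
    stop("unknown island_relation values: ",
         paste(unique(ann$island_relation[bad_isl]), collapse = ", "),
         call. = FALSE)
  }
  bad_gr <- !ann$gene_region %in% .gene_region_levels
  if (any(bad_gr)) {
    stop("unknown gene_region values: ",
         paste(unique(ann$gene_region[bad_gr]), collapse = ", "),
         call. = FALSE)
  }
  invisible(ann)
}

.check_sample_sheet <- function(sheet) {
  if (!all(c("sample_id", "age") %in% names(sheet))) {
    stop("sample sheet requires sample_id and age columns", call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  if (any(!is.na(sheet$age) & sheet$age <= 0)) {
    stop("age must be positive", call. = FALSE)
  }
  invisible(sheet)
}

#' Read a beta matrix from TSV
#'
#' Expects a header row, a first column named `probe_id`, and one column per
#' sample.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (probes x samples) with dimnames.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id") {
    stop("first column of a beta matrix file must be 'probe_id'",
         call. = FALSE)
  }
  bm <- as.matrix(df[, -1, drop = FALSE])
  rownames(bm) <- df$probe_id
  storage.mode(bm) <- "double"
  bad <- which(!is.na(bm) & (bm < 0 | bm > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s'",
                 rownames(bm)[bad[1, 1]], colnames(bm)[bad[1, 2]]),
         call. = FALSE)
  }
  .check_beta_matrix(bm)
}

#' Write a beta matrix to TSV
#' @param bm Beta matrix (probes x samples).
#' @param path Output path.
#' @export
write_beta_matrix <- function(bm, path) {
  df <- data.frame(probe_id = rownames(bm), bm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#' @param path Path to the TSV file; requires `sample_id` and `age` columns.
#' @return `data.frame` with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_sample_sheet(sheet)
  sheet
}

#' Write a sample sheet to TSV
#' @param sheet Sample sheet `data.frame`.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probe annotation from TSV
#' @param path Path to the TSV file with columns `probe_id`, `chromosome`,
#'   `position`, `island_relation`, `gene_region`, optional `gene_symbol`,
#'   and `masks` (semicolon-joined flags).
#' @return Annotation `data.frame`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(masks = "character"))
  ann$masks[is.na(ann$masks)] <- ""
  .check_annotation(ann)
  ann
}

#' Write probe annotation to TSV
#' @param ann Annotation `data.frame`.
#' @param path Output path.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load and cross-validate a dataset bundle
#'
#' Reads a beta matrix, sample sheet and probe annotation, and checks that the
#' three agree: every beta column has a sample-sheet row and vice versa, and
#' every probe has an annotation record. The sample sheet is reordered to the
#' beta matrix column order.
#'
#' @param beta_path,sample_path,annotation_path TSV file paths (see the
#'   corresponding `read_*` functions for dialects).
#' @return A list with elements `beta`, `sheet`, `annotation`.
#' @export
load_dataset <- function(beta_path, sample_path, annotation_path) {
  bm <- read_beta_matrix(beta_path)
  sheet <- read_sample_sheet(sample_path)
  ann <- read_annotation(annotation_path)

  only_beta <- setdiff(colnames(bm), sheet$sample_id)
  only_sheet <- setdiff(sheet$sample_id, colnames(bm))
  if (length(only_beta) > 0 || length(only_sheet) > 0) {
    stop("sample id mismatch; only in beta matrix: [",
         paste(only_beta, collapse = ", "), "]; only in sample sheet: [",
         paste(only_sheet, collapse = ", "), "]", call. = FALSE)
  }
  missing_ann <- setdiff(rownames(bm), ann$probe_id)
  if (length(missing_ann) > 0) {
    stop("probes lacking annotation: ",
         paste(utils::head(missing_ann, 10), collapse = ", "), call. = FALSE)
  }
  sheet <- sheet[match(colnames(bm), sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  list(beta = bm, sheet = sheet, annotation = ann)
}

#' Drop probes with any missing beta values
#'
#' Deconvolution and per-CpG modelling require complete data; probes with any
#' missing entry are removed (with a message reporting how many).
#'
#' @param bm Beta matrix.
#' @return Beta matrix restricted to complete probes.
#' @export
drop_incomplete_probes <- function(bm) {
  keep <- rowSums(is.na(bm)) == 0
  if (any(!keep)) {
    message(sum(!keep), " probe(s) with missing values dropped")
  }
  bm[keep, , drop = FALSE]
}
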