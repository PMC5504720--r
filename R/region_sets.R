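#' Construct a region set
#'
#' A region set is a labelled collection of genomic intervals (e.g. histone
#' mark peaks or transcription-factor binding sites) used for overlap
#' enrichment. Intervals follow the BED convention: 0-based, half-open
#' `[start, end)`.
#'
#' @param label Non-empty set label.
#' @param intervals `data.frame` with columns `chromosome`, `start`, `end`.
#' @return An object of class `region_set`.
#' @export
region_set <- function(label, intervals) {
  if (!is.character(label) || length(label) != 1 || !nzchar(label)) {
    stop("label must be a non-empty string", call. = FALSE)
  }
  req <- c("chromosome", "start", "end")
  if (!all(req %in% names(intervals))) {
    stop("intervals need columns chromosome, start, end", call. = FALSE)
  }
  intervals <- intervals[, req, drop = FALSE]
  if (nrow(intervals) > 0 && any(intervals$start >= intervals$end)) {
    stop("intervals must satisfy start < end", call. = FALSE)
  }
  structure(list(label = label, intervals = intervals), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set '", x$label, "': ", nrow(x$intervals), " interval(s)\n",
      sep = "")
  invisible(x)
}

#' Read region sets from a BED file
#'
#' BED3+name input; intervals are grouped into one region set per distinct
#' value of the name column. Files without a name column yield a single set
#' labelled after the file.
#'
#' @param path Path to a BED file.
#' @return A named list of [region_set()] objects.
#' @export
read_region_sets <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm))) {
    nm <- rep(sub("\\.bed$", "", basename(path)), nrow(df))
  }
  parts <- split(df, nm)
  mapply(function(d, label) region_set(label, d),
         parts, names(parts), SIMPLIFY = FALSE)
}

#' Write region sets to a BED file
#'
#' Emits BED3+name with one row per interval; the name column carries the set
#' label so [read_region_sets()] round-trips.
#'
#' @param sets A list of [region_set()] objects (or a single one).
#' @param path Output path.
#' @export
write_region_sets <- function(sets, path) {
  if (inherits(sets, "region_set")) sets <- list(sets)
  rows <- do.call(rbind, lapply(sets, function(rs) {
    if (nrow(rs$intervals) == 0) return(NULL)
    data.frame(rs$intervals, name = rs$label, stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(
    rows$chromosome,
    IRanges::IRanges(start = rows$start + 1L, end = rows$end),
    name = rows$name
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
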