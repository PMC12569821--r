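# Plain-text table readers and writers for the rearrangement workflow.
# Internal coordinates are 1-based closed; BED/BEDPE exports are 0-based
# half-open per the BED convention.

#' Read a marker table TSV
#'
#' @param path TSV with header chrom, pos, allele_p1, allele_p2, depth_p1,
#'   depth_p2.
#' @return validated marker data.frame.
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) stop("marker table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  .validate_marker_track(df)
  df
}

#' Write a marker table TSV
#' @param track marker data.frame.
#' @param path output path.
#' @export
write_marker_table <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a junction table TSV
#'
#' @param path TSV with header chrom_a, pos_a, strand_a, chrom_b, pos_b,
#'   strand_b, flank_a, flank_b, support.
#' @return junction data.frame.
#' @export
read_junction_table <- function(path) {
  if (!file.exists(path)) stop("junction table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom_a", "pos_a", "strand_a", "chrom_b", "pos_b", "strand_b")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("junction table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!is.null(df$support) && any(df$support < 1)) {
    stop("junction support must be >= 1")
  }
  for (col in intersect(c("flank_a", "flank_b"), names(df))) {
    bad <- grepl("[^ACGTN]", toupper(df[[col]]))
    if (any(bad)) stop("flank sequences must be ACGTN: ", col)
  }
  df
}

#' Write a junction table TSV
#' @param junctions junction data.frame.
#' @param path output path.
#' @export
write_junction_table <- function(junctions, path) {
  write.table(junctions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chromosome-sizes TSV (chrom, size)
#' @param path two-column TSV, no header required.
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chromosome sizes not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), df[[1]])
}

#' Write a chromosome-sizes TSV
#' @param chrom_sizes named numeric vector.
#' @param path output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(names(chrom_sizes), as.numeric(chrom_sizes)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a repeats BED file
#' @param path BED3+ file (chrom, start 0-based, end exclusive, [name]).
#' @return data.frame with columns chrom, start, end and name if present.
#' @export
read_repeats_bed <- function(path) {
  if (!file.exists(path)) stop("repeats BED not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

#' Write segment events as BED (0-based half-open)
#' @param segments data.frame with chrom, start, end (1-based closed) and
#'   optionally klass.
#' @param path output path.
#' @export
write_segments_bed <- function(segments, path) {
  if (nrow(segments)) {
    bed <- data.frame(chrom = segments$chrom,
                      start = segments$start - 1,
                      end = segments$end,
                      name = if (!is.null(segments$klass)) segments$klass
                      else ".")
  } else {
    bed <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character())
  }
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write junctions as BEDPE link table
#'
#' A Circos-style link export: both breakpoints as 0-based half-open
#' single-base intervals plus class and support.
#'
#' @param junctions classified junction data.frame.
#' @param path output path.
#' @export
write_junctions_bedpe <- function(junctions, path) {
  if (nrow(junctions)) {
    bp <- data.frame(chrom1 = junctions$chrom_a,
                     start1 = junctions$pos_a - 1, end1 = junctions$pos_a,
                     chrom2 = junctions$chrom_b,
                     start2 = junctions$pos_b - 1, end2 = junctions$pos_b,
                     name = if (!is.null(junctions$klass)) junctions$klass
                     else ".",
                     score = if (!is.null(junctions$support))
                       junctions$support else 0,
                     strand1 = junctions$strand_a,
                     strand2 = junctions$strand_b)
  } else {
    bp <- data.frame(chrom1 = character(), start1 = numeric(),
                     end1 = numeric(), chrom2 = character(),
                     start2 = numeric(), end2 = numeric(),
                     name = character(), score = numeric(),
                     strand1 = character(), strand2 = character())
  }
  write.table(bp, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Serialise an isolate report to JSON
#' @param report an `isolate_report`.
#' @param path output path.
#' @export
write_isolate_report_json <- function(report, path) {
  out <- list(
    isolate_id = report$isolate_id,
    n_events = report$n_events,
    total_loh_length = report$total_loh_length,
    total_cnv_length = report$total_cnv_length,
    loh_fraction = report$loh_fraction,
    excluded = report$excluded,
    exclusion_reason = report$exclusion_reason,
    loh_segments = report$loh_segments,
    cnv_events = report$cnv_events,
    junction_events = report$junction_events)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
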