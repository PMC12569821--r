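# Candidate split-site screening: metric collection over per-variant
# predicted models, interface-area vs stability correlation, and Pareto
# ranking against the baseline construct.

#' Enumerate candidate split positions around a centre
#'
#' Split position k means the chain is divided between residues k and k+1 of
#' the parent enzyme.
#'
#' @param parent_length parent chain length in residues.
#' @param center the reference split position.
#' @param half_window candidates span `center +/- half_window` (inclusive).
#' @return ordered integer vector of `2 * half_window + 1` positions.
#' @export
enumerate_split_candidates <- function(parent_length, center, half_window = 7) {
  if (half_window < 0) stop("half_window must be >= 0")
  lo <- center - half_window; hi <- center + half_window
  if (lo < 1 || hi >= parent_length) {
    stop("candidate window [", lo, ", ", hi,
         "] leaves the valid split range [1, ", parent_length - 1, "]")
  }
  seq.int(lo, hi)
}

#' Read a variant stability table
#'
#' @param path TSV with header columns `variant_id` and `delta_g`
#'   (total Gibbs free energy of the complex, kcal/mol; externally computed).
#' @return data.frame.
#' @export
read_dg_table <- function(path) {
  if (!file.exists(path)) stop("free-energy table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "delta_g") %in% names(df))) {
    stop("free-energy table must have columns variant_id, delta_g")
  }
  if (anyDuplicated(df$variant_id)) {
    stop("duplicate variant_id in free-energy table: ",
         paste(unique(df$variant_id[duplicated(df$variant_id)]), collapse = ", "))
  }
  df
}

#' Collect screening metrics for split-site variants
#'
#' For each variant, parses its predicted complex model, computes the mean
#' per-residue confidence and the protein-DNA buried interface area, and
#' joins the externally supplied complex free energy.
#'
#' @param model_paths named character vector, `variant_id -> model file`.
#' @param dg_table data.frame with `variant_id`, `delta_g`, or a TSV path.
#' @param chains_protein,chains_dna chain ids of the two interface sides.
#' @param baseline_id variant_id of the original construct (must be present).
#' @param split_positions optional named integer vector `variant_id ->
#'   split position`; defaults to parsing trailing digits of the id.
#' @param params [sasa_params()] used for the burial computation.
#' @return A `screen_table`: data.frame (variant_id, split_position,
#'   mean_plddt, buried_area, delta_g) with attribute `baseline_id`.
#' @export
collect_metrics <- function(model_paths, dg_table, chains_protein, chains_dna,
                            baseline_id, split_positions = NULL,
                            params = sasa_params()) {
  if (length(model_paths) == 0L) stop("empty variant list")
  ids <- names(model_paths)
  if (is.null(ids) || any(!nzchar(ids))) stop("model_paths must be named by variant_id")
  if (anyDuplicated(ids)) stop("duplicate variant ids in model_paths")
  if (is.character(dg_table) && length(dg_table) == 1L) {
    dg_table <- read_dg_table(dg_table)
  }
  if (anyDuplicated(dg_table$variant_id)) {
    stop("duplicate variant_id in free-energy table")
  }
  missing_dg <- setdiff(ids, dg_table$variant_id)
  if (length(missing_dg)) {
    stop("no free-energy entry for variant(s): ",
         paste(missing_dg, collapse = ", "))
  }
  missing_model <- ids[!file.exists(model_paths)]
  if (length(missing_model)) {
    stop("missing model file for variant(s): ",
         paste(missing_model, collapse = ", "))
  }
  if (!baseline_id %in% ids) stop("baseline variant '", baseline_id,
                                  "' absent from the model set")
  if (is.null(split_positions)) {
    split_positions <- suppressWarnings(
      as.integer(sub(".*?(\\d+)$", "\\1", ids)))
    names(split_positions) <- ids
  }
  rows <- lapply(ids, function(id) {
    m <- parse_structure(model_paths[[id]])
    im <- buried_surface_area(m, chains_protein, chains_dna, params)
    data.frame(variant_id = id,
               split_position = unname(split_positions[id]),
               mean_plddt = mean_plddt(m),
               buried_area = im$buried_area,
               delta_g = dg_table$delta_g[match(id, dg_table$variant_id)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline_id") <- baseline_id
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-zero variance.
#' @return list of class `correlation_result`: `r`, `p_two_sided`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need n >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_two_sided = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, two-sided p = %.4g (n = %d)\n",
              x$r, x$p_two_sided, x$n))
  invisible(x)
}

#' Two-sided p-value for a given Pearson r and sample size
#'
#' Uses the t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param r Pearson correlation coefficient, |r| < 1.
#' @param n number of pairs, n >= 3.
#' @return two-sided p-value.
#' @export
pearson_p <- function(r, n) {
  if (abs(r) >= 1) stop("|r| must be < 1")
  if (n < 3) stop("need n >= 3")
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tval), df = n - 2)
}

#' Rank split-site variants against the baseline
#'
#' Keeps variants that strictly Pareto-dominate the baseline construct
#' (larger buried interface AND lower complex free energy), orders them by
#' descending buried area, breaking ties by ascending free energy and then
#' ascending split position; the winner is the first. An empty dominated set
#' is a valid "no improvement" outcome.
#'
#' @param table a `screen_table` from [collect_metrics()] (any data.frame
#'   with the same columns and a `baseline_id` attribute works).
#' @param baseline_id overrides the table's `baseline_id` attribute.
#' @return list of class `split_ranking`: `ranking` (variant ids in order),
#'   `winner` (id or `NA`), `baseline_id`, `no_improvement` flag.
#' @export
rank_variants <- function(table, baseline_id = attr(table, "baseline_id")) {
  if (is.null(baseline_id)) stop("baseline_id not given")
  if (sum(table$variant_id == baseline_id) != 1L) {
    stop("baseline '", baseline_id, "' must appear exactly once")
  }
  base <- table[table$variant_id == baseline_id, ]
  if (anyNA(base[c("buried_area", "delta_g")])) {
    stop("baseline variant is missing metrics")
  }
  cand <- table[table$variant_id != baseline_id, , drop = FALSE]
  dom <- cand[!is.na(cand$buried_area) & !is.na(cand$delta_g) &
                cand$buried_area > base$buried_area &
                cand$delta_g < base$delta_g, , drop = FALSE]
  ord <- order(-dom$buried_area, dom$delta_g, dom$split_position)
  dom <- dom[ord, , drop = FALSE]
  structure(list(ranking = dom$variant_id,
                 winner = if (nrow(dom)) dom$variant_id[1] else NA_character_,
                 baseline_id = baseline_id,
                 no_improvement = nrow(dom) == 0L),
            class = "split_ranking")
}

#' @export
print.split_ranking <- function(x, ...) {
  if (x$no_improvement) {
    cat("split ranking: no variant improves on baseline", x$baseline_id, "\n")
  } else {
    cat("split ranking (baseline ", x$baseline_id, "): ",
        paste(x$ranking, collapse = " > "), "\nwinner: ", x$winner, "\n",
        sep = "")
  }
  invisible(x)
}
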