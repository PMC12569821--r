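# Calling and classifying genome rearrangements in a hybrid diploid from
# per-SNP marker evidence and junction records.
#
# Event classes follow the standard taxonomy for nuclease-induced
# rearrangements: interstitial LOH = short gene conversion (SGC), LOH
# running to a chromosome end = break-induced replication (BIR),
# translocations at unique sequence = NHEJ-mediated (NMTL), translocations
# between repeats = non-allelic homologous recombination (NAHR), plus
# whole-chromosome aneuploidy from dosage.
#
# Coordinates are 1-based closed internally; BED/BEDPE exports convert to
# 0-based half-open.

.validate_marker_track <- function(track) {
  need <- c("chrom", "pos", "allele_p1", "allele_p2", "depth_p1", "depth_p2")
  miss <- setdiff(need, names(track))
  if (length(miss)) stop("marker track lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(track) == 0L) stop("empty marker track")
  if (any(track$depth_p1 < 0 | track$depth_p2 < 0)) stop("negative depths")
  if (any(track$allele_p1 == track$allele_p2)) {
    stop("parental alleles must differ at every marker")
  }
  by_chrom <- split(track$pos, track$chrom)
  bad <- names(by_chrom)[vapply(by_chrom, function(p) any(diff(p) <= 0), logical(1))]
  if (length(bad)) {
    stop("marker positions not strictly increasing on: ", paste(bad, collapse = ", "))
  }
  invisible(track)
}

#' Genotype SNP markers from allele depths
#'
#' The parental-allele fraction `f = depth_p1 / (depth_p1 + depth_p2)` is
#' banded into genotype calls: markers under the depth floor are `nocall`;
#' `f >= 1 - hom_band` is `hom_p1`; `f <= hom_band` is `hom_p2`; `f` inside
#' `het_band` is `het`; anything between the bands is `nocall`.
#'
#' @param track marker data.frame (chrom, pos, allele_p1, allele_p2,
#'   depth_p1, depth_p2), positions strictly increasing per chromosome.
#' @param min_depth minimum total depth for a call.
#' @param het_band inclusive allele-fraction interval called heterozygous.
#' @param hom_band allele-fraction margin for homozygous calls.
#' @return the track with a `genotype` column added.
#' @export
genotype_markers <- function(track, min_depth = 10,
                             het_band = c(0.25, 0.75), hom_band = 0.10) {
  .validate_marker_track(track)
  total <- track$depth_p1 + track$depth_p2
  f <- ifelse(total > 0, track$depth_p1 / total, NA_real_)
  g <- rep("nocall", nrow(track))
  callable <- total >= min_depth
  g[callable & f >= 1 - hom_band] <- "hom_p1"
  g[callable & f <= hom_band] <- "hom_p2"
  g[callable & f >= het_band[1] & f <= het_band[2] &
      f > hom_band & f < 1 - hom_band] <- "het"
  track$genotype <- g
  track
}

# Greedy left-to-right chaining of concordant hom markers for one haplotype
# on one chromosome. Opposite-hom markers always break a run; het/nocall
# markers are tolerated up to max_discordant_frac of the run. Runs span
# first to last concordant marker.
.loh_runs_one <- function(pos, genotype, hap, min_run, max_discordant_frac) {
  conc <- genotype == hap
  opp <- genotype == setdiff(c("hom_p1", "hom_p2"), hap)
  idx <- which(conc)
  runs <- list()
  if (!length(idx)) return(runs)
  cur_start <- idx[1]; cur_end <- idx[1]
  n_conc <- 1L; n_disc <- 0L
  flush <- function() {
    if (n_conc >= min_run) {
      runs[[length(runs) + 1L]] <<- list(start = pos[cur_start],
                                         end = pos[cur_end],
                                         first_i = cur_start, last_i = cur_end,
                                         n_markers = n_conc)
    }
  }
  for (k in idx[-1]) {
    if (k - cur_end > 1L) {
      between <- seq(cur_end + 1L, k - 1L)
      gap_opp <- any(opp[between])
    } else {
      between <- integer(0); gap_opp <- FALSE
    }
    gap_disc <- length(between)
    new_disc <- n_disc + gap_disc
    ok_frac <- new_disc / (n_conc + 1L + new_disc) <= max_discordant_frac
    if (!gap_opp && ok_frac) {
      n_conc <- n_conc + 1L; n_disc <- new_disc; cur_end <- k
    } else {
      flush()
      cur_start <- k; cur_end <- k; n_conc <- 1L; n_disc <- 0L
    }
  }
  flush()
  runs
}

#' Call LOH segments and classify them as SGC or BIR
#'
#' Finds maximal runs of at least `min_run` concordant homozygous markers of
#' one haplotype, tolerating interspersed het/nocall markers up to
#' `max_discordant_frac` of the run (opposite-haplotype markers always
#' terminate a run). A segment is classified BIR when it reaches a
#' chromosome end - its span comes within `end_margin` of position 1 or of
#' the chromosome length, or it contains the first or last marker of the
#' chromosome; interstitial segments are SGC.
#'
#' @param track genotyped marker track (see [genotype_markers()]).
#' @param chrom_sizes named numeric vector, chromosome -> length in bp.
#' @param min_run minimum number of concordant markers per segment.
#' @param max_discordant_frac tolerated fraction of het/nocall markers.
#' @param end_margin distance (bp) from a chromosome end within which a
#'   segment counts as telomere-reaching.
#' @return data.frame (chrom, start, end, haplotype, n_markers, klass) in
#'   genomic order; segments never overlap.
#' @export
call_loh <- function(track, chrom_sizes, min_run = 5,
                     max_discordant_frac = 0.1, end_margin = 20000) {
  if (is.null(track$genotype)) stop("track is not genotyped; run genotype_markers()")
  unknown <- setdiff(unique(track$chrom), names(chrom_sizes))
  if (length(unknown)) stop("unknown chromosome(s) in track: ",
                            paste(unknown, collapse = ", "))
  out <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    size <- chrom_sizes[[ch]]
    n <- nrow(sub)
    for (hap in c("hom_p1", "hom_p2")) {
      runs <- .loh_runs_one(sub$pos, sub$genotype, hap, min_run,
                            max_discordant_frac)
      for (r in runs) {
        telo <- r$start <= end_margin || (size - r$end) <= end_margin ||
          r$first_i == 1L || r$last_i == n
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = r$start, end = r$end,
          haplotype = sub("hom_", "", hap), n_markers = r$n_markers,
          klass = if (telo) "BIR" else "SGC", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      haplotype = character(), n_markers = integer(),
                      klass = character(), stringsAsFactors = FALSE))
  }
  seg <- do.call(rbind, out)
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Call whole-chromosome aneuploidy from marker depth
#'
#' Normalises each chromosome's median total marker depth by the genome-wide
#' median; ratios at or above `gain_ratio` are gains (trisomy in a diploid
#' sits at 1.5), at or below `loss_ratio` losses (monosomy at 0.5). Events
#' span whole chromosomes.
#'
#' @param track marker track with depths.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param gain_ratio,loss_ratio normalised-dosage thresholds.
#' @return data.frame (chrom, start, end, klass = "aneuploidy", subtype,
#'   dosage_ratio).
#' @export
call_aneuploidy <- function(track, chrom_sizes, gain_ratio = 1.25,
                            loss_ratio = 0.75) {
  .validate_marker_track(track)
  chroms <- unique(track$chrom)
  if (length(chroms) < 2L) {
    stop("aneuploidy calling needs more than one chromosome for normalisation")
  }
  total <- track$depth_p1 + track$depth_p2
  genome_med <- median(total)
  if (genome_med <= 0) stop("genome-wide median depth is zero")
  out <- list()
  for (ch in chroms) {
    ratio <- median(total[track$chrom == ch]) / genome_med
    if (ratio >= gain_ratio || ratio <= loss_ratio) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = 1, end = unname(chrom_sizes[[ch]]),
        klass = "aneuploidy",
        subtype = if (ratio >= gain_ratio) "gain" else "loss",
        dosage_ratio = ratio, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      klass = character(), subtype = character(),
                      dosage_ratio = numeric(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# 1-based position inside 0-based half-open BED intervals?
.in_bed <- function(chrom, pos, bed) {
  any(bed$chrom == chrom & bed$start < pos & pos <= bed$end)
}

#' Classify translocation junctions as NAHR or NMTL
#'
#' A junction whose breakpoints both fall inside annotated repeat intervals
#' (e.g. Ty retrotransposons) is non-allelic homologous recombination
#' (NAHR); every other junction is an NHEJ-mediated translocation (NMTL).
#' Inter- and intra-chromosomal junctions are both accepted, and every
#' junction receives exactly one class.
#'
#' @param junctions data.frame with `chrom_a`, `pos_a`, `strand_a`,
#'   `chrom_b`, `pos_b`, `strand_b` and optionally `flank_a`, `flank_b`,
#'   `support`.
#' @param repeats repeat annotation, BED-convention data.frame
#'   (`chrom`, `start` 0-based, `end` exclusive).
#' @return the junction table with a `klass` column (`"NAHR"`/`"NMTL"`).
#' @export
classify_translocations <- function(junctions, repeats) {
  if (nrow(junctions) == 0L) {
    junctions$klass <- character(0)
    return(junctions)
  }
  junctions$klass <- vapply(seq_len(nrow(junctions)), function(i) {
    in_a <- .in_bed(junctions$chrom_a[i], junctions$pos_a[i], repeats)
    in_b <- .in_bed(junctions$chrom_b[i], junctions$pos_b[i], repeats)
    if (in_a && in_b) "NAHR" else "NMTL"
  }, character(1))
  junctions
}

#' Check a breakpoint flank for the recognition motif
#'
#' Tests whether the motif (or its reverse complement) occurs overlapping
#' the junction point, searching within one motif length either side of the
#' cut. The flank string carries the junction at its midpoint: with the
#' conventional +/-20 bp flank, the cut falls between characters 20 and 21.
#'
#' @param flank_seq flank sequence (uppercase ACGTN), junction at midpoint.
#' @param motif recognition sequence, default `"GATC"`.
#' @param cut_index number of bases 5' of the junction inside `flank_seq`;
#'   defaults to half the flank length.
#' @return logical: motif present at the breakpoint.
#' @export
check_breakpoint_motif <- function(flank_seq, motif = "GATC",
                                   cut_index = NULL) {
  m <- nchar(motif)
  if (nchar(flank_seq) < m) stop("flank shorter than the motif")
  if (is.null(cut_index)) cut_index <- nchar(flank_seq) %/% 2L
  flank_seq <- toupper(flank_seq)
  pats <- unique(c(motif, reverse_complement(motif)))
  for (pat in pats) {
    starts <- gregexpr(pat, flank_seq, fixed = TRUE)[[1]]
    starts <- starts[starts > 0]
    # occurrence [s, s+m-1] must intersect the +/- m window around the cut,
    # i.e. positions [cut_index - m + 1, cut_index + m]
    if (any(starts <= cut_index + m & (starts + m - 1) >= cut_index - m + 1)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Annotate junctions with per-breakpoint motif matches
#'
#' @param junctions junction table with `flank_a`, `flank_b` columns.
#' @param motif recognition sequence.
#' @return the table with logical `motif_match_a`, `motif_match_b` columns.
#' @export
annotate_junction_motifs <- function(junctions, motif = "GATC") {
  junctions$motif_match_a <- vapply(junctions$flank_a, check_breakpoint_motif,
                                    logical(1), motif = motif, USE.NAMES = FALSE)
  junctions$motif_match_b <- vapply(junctions$flank_b, check_breakpoint_motif,
                                    logical(1), motif = motif, USE.NAMES = FALSE)
  junctions
}

.reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1
  if (ov <= 0) return(0)
  min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

#' Subtract control-strain events
#'
#' Removes segment events sharing at least `reciprocal_overlap` mutual
#' overlap with any control segment on the same chromosome, and junction
#' events whose two breakpoints both coincide with a control junction's
#' within `junction_tol`.
#'
#' @param events,control_events event data.frames as produced by the
#'   callers; segment events carry `chrom`/`start`/`end`, junction events
#'   `chrom_a`/`pos_a`/`chrom_b`/`pos_b`.
#' @param reciprocal_overlap minimum mutual overlap fraction for removal.
#' @param junction_tol breakpoint coincidence tolerance in bp.
#' @return filtered `events`.
#' @export
subtract_control <- function(events, control_events,
                             reciprocal_overlap = 0.5, junction_tol = 1000) {
  if (nrow(events) == 0L || is.null(control_events) ||
      nrow(control_events) == 0L) {
    return(events)
  }
  keep <- vapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    if (!is.null(e$start) && !is.na(e$start)) {
      for (j in seq_len(nrow(control_events))) {
        c_ <- control_events[j, ]
        if (is.null(c_$start) || is.na(c_$start)) next
        if (c_$chrom != e$chrom) next
        if (.reciprocal_overlap(e$start, e$end, c_$start, c_$end) >=
            reciprocal_overlap) {
          return(FALSE)
        }
      }
      TRUE
    } else {
      for (j in seq_len(nrow(control_events))) {
        c_ <- control_events[j, ]
        if (is.null(c_$chrom_a) || is.na(c_$chrom_a)) next
        same <- (c_$chrom_a == e$chrom_a && c_$chrom_b == e$chrom_b &&
                   abs(c_$pos_a - e$pos_a) <= junction_tol &&
                   abs(c_$pos_b - e$pos_b) <= junction_tol) ||
          (c_$chrom_a == e$chrom_b && c_$chrom_b == e$chrom_a &&
             abs(c_$pos_a - e$pos_b) <= junction_tol &&
             abs(c_$pos_b - e$pos_a) <= junction_tol)
        if (same) return(FALSE)
      }
      TRUE
    }
  }, logical(1))
  events[keep, , drop = FALSE]
}

# Merge 1-based closed intervals per chromosome; returns total length.
.merged_length <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(0)
  total <- 0
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cur_s <- sub$start[1]; cur_e <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= cur_e + 1) {
        cur_e <- max(cur_e, sub$end[i])
      } else {
        total <- total + (cur_e - cur_s + 1)
        cur_s <- sub$start[i]; cur_e <- sub$end[i]
      }
    }
    total <- total + (cur_e - cur_s + 1)
  }
  total
}

#' Build a per-isolate rearrangement report
#'
#' Combines an isolate's called events into one record with total LOH tract
#' length (merged SGC + BIR intervals) and total CNV tract length (merged
#' dosage-altered intervals from aneuploidy plus any NAHR/NMTL events that
#' carry segment coordinates). An isolate whose merged LOH covers at least
#' `exclude_loh_frac` of the marker-bearing genome is flagged excluded, the
#' operational proxy for haploidization (complete loss of heterozygosity).
#'
#' @param isolate_id isolate label.
#' @param loh_segments output of [call_loh()].
#' @param cnv_events output of [call_aneuploidy()], plus any pre-typed
#'   dosage events (e.g. large deletions) with chrom/start/end/klass.
#' @param junction_events output of [classify_translocations()] (optionally
#'   motif-annotated).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param track optional genotyped marker track; when given, the
#'   haploidization check uses the marker-bearing span instead of full
#'   chromosome lengths.
#' @param exclude_loh_frac LOH coverage fraction triggering exclusion.
#' @return An object of class `isolate_report`.
#' @export
build_isolate_report <- function(isolate_id, loh_segments, cnv_events,
                                 junction_events, chrom_sizes, track = NULL,
                                 exclude_loh_frac = 0.95) {
  total_loh <- .merged_length(loh_segments)
  cnv_seg <- if (!is.null(cnv_events) && nrow(cnv_events)) {
    cnv_events[!is.na(cnv_events$start), , drop = FALSE]
  } else {
    NULL
  }
  total_cnv <- .merged_length(cnv_seg)
  denom <- if (!is.null(track)) {
    sum(vapply(split(track$pos, track$chrom),
               function(p) max(p) - min(p) + 1, numeric(1)))
  } else {
    sum(chrom_sizes)
  }
  loh_frac <- if (denom > 0) total_loh / denom else 0
  excluded <- loh_frac >= exclude_loh_frac
  n_events <- (if (is.null(loh_segments)) 0L else nrow(loh_segments)) +
    (if (is.null(cnv_events)) 0L else nrow(cnv_events)) +
    (if (is.null(junction_events)) 0L else nrow(junction_events))
  structure(list(isolate_id = isolate_id,
                 loh_segments = loh_segments,
                 cnv_events = cnv_events,
                 junction_events = junction_events,
                 n_events = n_events,
                 total_loh_length = total_loh,
                 total_cnv_length = total_cnv,
                 loh_fraction = loh_frac,
                 excluded = excluded,
                 exclusion_reason = if (excluded)
                   "complete loss of heterozygosity" else NA_character_),
            class = "isolate_report")
}

#' @export
print.isolate_report <- function(x, ...) {
  cat(sprintf(paste0("isolate_report %s: %d events, LOH %.0f bp, CNV %.0f bp",
                     "%s\n"),
              x$isolate_id, x$n_events, x$total_loh_length,
              x$total_cnv_length,
              if (x$excluded) paste0(" [EXCLUDED: ", x$exclusion_reason, "]")
              else ""))
  invisible(x)
}

#' Count events of chosen classes in a report
#'
#' @param report an `isolate_report`.
#' @param classes event classes to count.
#' @return integer count.
#' @export
count_events <- function(report,
                         classes = c("SGC", "BIR", "NMTL", "NAHR",
                                     "aneuploidy")) {
  n <- 0L
  for (df in list(report$loh_segments, report$cnv_events,
                  report$junction_events)) {
    if (!is.null(df) && nrow(df) && "klass" %in% names(df)) {
      n <- n + sum(df$klass %in% classes)
    }
  }
  n
}
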