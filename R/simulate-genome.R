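# Hybrid-diploid genome simulation: two haplotypes at a chosen SNP
# divergence, with implanted ground-truthed rearrangement events and
# binomially sampled allele depths. Emulates the sequencing evidence of a
# two-parent fusion diploid (SK1 x S288C-like, ~0.7% SNPs) from the marker
# table level onward; no read-level simulation.

.BASES <- c("A", "C", "G", "T")

#' Simulate a two-haplotype hybrid diploid genome
#'
#' Haplotype 1 is uniform random sequence; haplotype 2 is a copy with
#' independent substitutions at the divergence rate (substituted base
#' always differs). The substituted positions are the heterozygous SNP
#' markers. Every `motif_window` of haplotype 1 is guaranteed at least one
#' occurrence of the recognition motif (windows lacking one are resampled),
#' so motif-snapped junction implanting never fails on small test genomes.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp (recycled).
#' @param divergence per-position substitution probability (default 0.007,
#'   a 0.7% SNP rate).
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @param motif recognition sequence guaranteed per window.
#' @param motif_window guarantee window size in bp.
#' @return list of class `hybrid_genome`: `hap1`, `hap2` (named character
#'   vectors of chromosome sequences), `markers` (data.frame chrom, pos,
#'   allele_p1, allele_p2), `chrom_sizes` (named numeric).
#' @export
gen_hybrid_genome <- function(n_chromosomes = 1, chrom_length = 1e6,
                              divergence = 0.007, seed = 1,
                              motif = "GATC", motif_window = 10000) {
  if (divergence <= 0 || divergence >= 1) stop("divergence must be in (0, 1)")
  set.seed(seed)
  lens <- rep_len(chrom_length, n_chromosomes)
  chrom_names <- sprintf("chr%02d", seq_len(n_chromosomes))
  hap1 <- character(n_chromosomes); hap2 <- character(n_chromosomes)
  markers <- list()
  for (c_i in seq_len(n_chromosomes)) {
    L <- lens[c_i]
    b1 <- sample(.BASES, L, replace = TRUE)
    # guarantee >= 1 motif occurrence per window
    starts <- seq(1, L, by = motif_window)
    for (ws in starts) {
      we <- min(ws + motif_window - 1, L)
      if (we - ws + 1 < nchar(motif)) next
      repeat {
        win <- paste(b1[ws:we], collapse = "")
        if (grepl(motif, win, fixed = TRUE)) break
        b1[ws:we] <- sample(.BASES, we - ws + 1, replace = TRUE)
      }
    }
    sub_pos <- which(runif(L) < divergence)
    b2 <- b1
    if (length(sub_pos)) {
      # draw a uniformly random different base at each substituted position
      shift <- sample.int(3, length(sub_pos), replace = TRUE)
      b2[sub_pos] <- .BASES[(match(b1[sub_pos], .BASES) - 1L + shift) %% 4L + 1L]
    }
    hap1[c_i] <- paste(b1, collapse = "")
    hap2[c_i] <- paste(b2, collapse = "")
    markers[[c_i]] <- data.frame(chrom = chrom_names[c_i], pos = sub_pos,
                                 allele_p1 = b1[sub_pos],
                                 allele_p2 = b2[sub_pos],
                                 stringsAsFactors = FALSE)
  }
  names(hap1) <- chrom_names; names(hap2) <- chrom_names
  structure(list(hap1 = hap1, hap2 = hap2,
                 markers = do.call(rbind, markers),
                 chrom_sizes = setNames(as.numeric(lens), chrom_names)),
            class = "hybrid_genome")
}

#' @export
print.hybrid_genome <- function(x, ...) {
  cat(sprintf("hybrid_genome: %d chromosome(s), %.0f bp, %d SNP markers (%.3f%%)\n",
              length(x$hap1), sum(x$chrom_sizes), nrow(x$markers),
              100 * nrow(x$markers) / sum(x$chrom_sizes)))
  invisible(x)
}

# Snap a position to the nearest motif occurrence on the chromosome; returns
# the breakpoint coordinate (last base 5' of the cut, with the cut falling
# immediately 5' of the motif).
.snap_to_motif <- function(seq, pos, motif) {
  occ <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  occ <- occ[occ > 0]
  if (!length(occ)) stop("no motif occurrence on chromosome")
  s <- occ[which.min(abs(occ - pos))]
  s - 1L  # junction sits between s-1 and s
}

#' Implant rearrangement events and emit marker/junction evidence
#'
#' Applies a ground-truth event list to a simulated hybrid genome and draws
#' the sequencing evidence the callers consume. SGC converts an
#' interstitial interval to one haplotype; BIR converts from an internal
#' start to the chromosome end; aneuploidy applies a whole-chromosome
#' dosage factor (1.5 gain / 0.5 loss of one haplotype); NMTL breakpoints
#' are snapped to the nearest recognition-motif occurrence, NAHR
#' breakpoints must fall inside the supplied repeat intervals. Marker
#' depths are drawn as Poisson totals (coverage x dosage) split
#' binomially by the expected haplotype fraction; junction records carry
#' the true +/-20 bp flanks.
#'
#' @param genome a `hybrid_genome`.
#' @param events list of event specs: each a list with `klass` in
#'   `c("SGC","BIR","aneuploidy","NMTL","NAHR")` and fields `chrom`,
#'   `start`, `end`, `haplotype` (`"p1"`/`"p2"`, LOH and aneuploidy),
#'   `subtype` (`"gain"`/`"loss"`, aneuploidy), or `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b` (junctions).
#' @param coverage mean sequencing depth.
#' @param seed RNG seed for the depth draws.
#' @param repeats optional repeat annotation (BED-convention data.frame)
#'   required for NAHR events.
#' @param motif recognition motif NMTL breakpoints snap to.
#' @param flank_bp flank length either side of a junction.
#' @param overdispersion optional negative-binomial size parameter for
#'   total depth (off by default: Poisson).
#' @return list of class `sim_truth`: `truth` (normalised event list),
#'   `markers` (marker table with depths), `junctions` (junction table),
#'   `chrom_sizes`.
#' @export
implant_events <- function(genome, events, coverage = 30, seed = 1,
                           repeats = NULL, motif = "GATC", flank_bp = 20,
                           overdispersion = NULL) {
  if (!inherits(genome, "hybrid_genome")) stop("not a hybrid_genome")
  set.seed(seed)
  mk <- genome$markers
  sizes <- genome$chrom_sizes
  # per-marker expected hap1 fraction and per-chromosome dosage
  frac <- rep(0.5, nrow(mk))
  dosage_of <- setNames(rep(1, length(sizes)), names(sizes))
  loh_iv <- list()
  truth <- list()
  junctions <- list()
  for (ev in events) {
    kl <- ev$klass
    if (kl %in% c("SGC", "BIR")) {
      if (!ev$chrom %in% names(sizes)) stop("unknown chromosome: ", ev$chrom)
      if (ev$start < 1 || ev$end > sizes[[ev$chrom]] || ev$start > ev$end) {
        stop("event coordinates outside the genome")
      }
      if (kl == "BIR") ev$end <- sizes[[ev$chrom]]
      for (iv in loh_iv) {
        if (iv$chrom == ev$chrom && iv$start <= ev$end && ev$start <= iv$end) {
          stop("overlapping conflicting LOH events")
        }
      }
      loh_iv[[length(loh_iv) + 1L]] <- ev
      sel <- mk$chrom == ev$chrom & mk$pos >= ev$start & mk$pos <= ev$end
      frac[sel] <- if (ev$haplotype == "p1") 1 else 0
      truth[[length(truth) + 1L]] <- data.frame(
        klass = kl, chrom = ev$chrom, start = ev$start, end = ev$end,
        haplotype = ev$haplotype, stringsAsFactors = FALSE)
    } else if (kl == "aneuploidy") {
      hap <- if (is.null(ev$haplotype)) "p1" else ev$haplotype
      if (ev$subtype == "gain") {
        dosage_of[ev$chrom] <- 1.5
        f <- if (hap == "p1") 2 / 3 else 1 / 3
      } else {
        dosage_of[ev$chrom] <- 0.5
        f <- if (hap == "p1") 0 else 1  # losing hap leaves the other
      }
      sel <- mk$chrom == ev$chrom
      frac[sel] <- f
      truth[[length(truth) + 1L]] <- data.frame(
        klass = kl, chrom = ev$chrom, start = 1,
        end = unname(sizes[[ev$chrom]]),
        haplotype = paste(ev$subtype, hap, sep = "_"),
        stringsAsFactors = FALSE)
    } else if (kl %in% c("NMTL", "NAHR")) {
      pa <- ev$pos_a; pb <- ev$pos_b
      if (kl == "NMTL") {
        pa <- .snap_to_motif(genome$hap1[[ev$chrom_a]], pa, motif)
        pb <- .snap_to_motif(genome$hap1[[ev$chrom_b]], pb, motif)
      } else {
        if (is.null(repeats)) stop("NAHR events require a repeat annotation")
        if (!.in_bed(ev$chrom_a, pa, repeats) ||
            !.in_bed(ev$chrom_b, pb, repeats)) {
          stop("NAHR breakpoints must lie inside repeat intervals")
        }
      }
      flank <- function(chrom, pos) {
        L <- sizes[[chrom]]
        substr(genome$hap1[[chrom]], max(1, pos - flank_bp + 1),
               min(L, pos + flank_bp))
      }
      junctions[[length(junctions) + 1L]] <- data.frame(
        chrom_a = ev$chrom_a, pos_a = pa, strand_a = "+",
        chrom_b = ev$chrom_b, pos_b = pb, strand_b = "+",
        flank_a = flank(ev$chrom_a, pa), flank_b = flank(ev$chrom_b, pb),
        support = max(1L, rpois(1, coverage / 2)),
        klass_truth = kl, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        klass = kl, chrom = ev$chrom_a, start = pa, end = pb,
        haplotype = NA_character_, stringsAsFactors = FALSE)
    } else {
      stop("unknown event class: ", kl)
    }
  }
  n <- nrow(mk)
  lambda <- coverage * unname(dosage_of[mk$chrom])
  total <- if (is.null(overdispersion)) {
    rpois(n, lambda)
  } else {
    rnbinom(n, size = overdispersion, mu = lambda)
  }
  d1 <- rbinom(n, total, frac)
  mk$depth_p1 <- d1
  mk$depth_p2 <- total - d1
  jdf <- if (length(junctions)) do.call(rbind, junctions) else
    data.frame(chrom_a = character(), pos_a = numeric(),
               strand_a = character(), chrom_b = character(),
               pos_b = numeric(), strand_b = character(),
               flank_a = character(), flank_b = character(),
               support = integer(), klass_truth = character(),
               stringsAsFactors = FALSE)
  tdf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(klass = character(), chrom = character(), start = numeric(),
               end = numeric(), haplotype = character(),
               stringsAsFactors = FALSE)
  structure(list(truth = tdf, markers = mk, junctions = jdf,
                 chrom_sizes = sizes),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d implanted events, %d markers, %d junctions\n",
              nrow(x$truth), nrow(x$markers), nrow(x$junctions)))
  invisible(x)
}
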