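mk_track <- function(pos, d1, d2, chrom = "chr01") {
  data.frame(chrom = chrom, pos = pos,
             allele_p1 = "A", allele_p2 = "G",
             depth_p1 = d1, depth_p2 = d2, stringsAsFactors = FALSE)
}

test_that("genotype bands behave as specified", {
  tr <- mk_track(c(100, 200, 300, 400, 500),
                 d1 = c(15, 30, 0, 4, 17),
                 d2 = c(14, 0, 25, 3, 3))
  g <- genotype_markers(tr)$genotype
  expect_equal(g, c("het", "hom_p1", "hom_p2", "nocall", "nocall"))
  # 17/20 = 0.85 sits between the het and hom bands -> nocall
})

test_that("interstitial runs are SGC and telomere-reaching runs are BIR", {
  sizes <- c(chr01 = 1e6)
  # 8 hom_p2 markers flanked by het on both sides, mid-chromosome
  pos <- seq(400000, 400000 + 13 * 1000, by = 1000)
  d1 <- c(15, 15, 15, rep(0, 8), 15, 15, 15)
  d2 <- c(14, 16, 15, rep(30, 8), 16, 15, 14)
  tr <- genotype_markers(mk_track(pos, d1, d2))
  seg <- call_loh(tr, sizes)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$klass, "SGC")
  expect_equal(seg$haplotype, "p2")
  expect_equal(seg$n_markers, 8L)
  expect_equal(seg$start, 403000)
  expect_equal(seg$end, 410000)

  # 50 hom_p1 markers running to the last marker of the chromosome
  pos2 <- c(seq(100000, 109000, by = 1000), seq(500000, 549000, by = 1000))
  d1b <- c(rep(15, 10), rep(30, 50))
  d2b <- c(rep(15, 10), rep(0, 50))
  tr2 <- genotype_markers(mk_track(pos2, d1b, d2b))
  seg2 <- call_loh(tr2, sizes)
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$klass, "BIR")

  # below min_run: no segment
  pos3 <- seq(1000, 9000, by = 1000)
  tr3 <- genotype_markers(mk_track(pos3, c(15, 15, 15, 30, 30, 30, 15, 15, 15),
                                   c(14, 15, 16, 0, 0, 0, 15, 16, 14)))
  expect_equal(nrow(call_loh(tr3, sizes)), 0L)
  expect_error(call_loh(tr3, c(chrX = 100)), "unknown chromosome")
})

test_that("LOH segments tolerate sparse discordant markers and never overlap", {
  sizes <- c(chr01 = 1e6)
  set.seed(31)
  n <- 60
  pos <- sort(sample(100000:500000, n))
  d1 <- rep(30, n); d2 <- rep(0, n)
  # sprinkle 4 discordant (het) markers inside the run (< 10%)
  het_idx <- c(10, 25, 40, 55)
  d1[het_idx] <- 15; d2[het_idx] <- 15
  tr <- genotype_markers(mk_track(pos, d1, d2))
  seg <- call_loh(tr, sizes)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_markers, n - length(het_idx))

  # property: re-scan reports and check concordant count and no overlap
  for (seed in 1:10) {
    set.seed(seed)
    n <- 80
    pos <- sort(sample(1:900000, n))
    geno_draw <- sample(c("het", "hom_p1", "hom_p2"), n, replace = TRUE,
                        prob = c(0.5, 0.3, 0.2))
    d1 <- ifelse(geno_draw == "het", 15, ifelse(geno_draw == "hom_p1", 30, 0))
    d2 <- ifelse(geno_draw == "het", 15, ifelse(geno_draw == "hom_p1", 0, 30))
    tr <- genotype_markers(mk_track(pos, d1, d2))
    seg <- call_loh(tr, sizes, min_run = 3)
    if (nrow(seg) > 1) {
      ord <- order(seg$start)
      expect_true(all(seg$start[ord][-1] > seg$end[ord][-nrow(seg)]))
    }
    if (nrow(seg)) {
      for (i in seq_len(nrow(seg))) {
        inside <- tr$pos >= seg$start[i] & tr$pos <= seg$end[i]
        conc <- sum(tr$genotype[inside] == paste0("hom_", seg$haplotype[i]))
        expect_gte(conc, 3)
        expect_equal(conc, seg$n_markers[i])
      }
    }
  }
})

test_that("aneuploidy is called from normalised chromosome dosage", {
  sizes <- c(chr01 = 1e6, chr02 = 8e5, chr03 = 1e6, chr04 = 9e5)
  mk_chrom <- function(ch, depth) {
    mk_track(seq(1000, 99000, by = 1000), depth, 0, chrom = ch)
  }
  tr <- rbind(mk_chrom("chr01", 30), mk_chrom("chr02", 30),
              mk_chrom("chr03", 45), mk_chrom("chr04", 15))
  ev <- call_aneuploidy(tr, sizes)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$subtype[ev$chrom == "chr03"], "gain")
  expect_equal(ev$subtype[ev$chrom == "chr04"], "loss")
  expect_equal(ev$end[ev$chrom == "chr03"], 1e6)

  flat <- rbind(mk_chrom("chr01", 30), mk_chrom("chr02", 30))
  expect_equal(nrow(call_aneuploidy(flat, sizes)), 0L)
  expect_error(call_aneuploidy(mk_chrom("chr01", 30), sizes),
               "more than one chromosome")
})

test_that("translocations partition into NAHR and NMTL", {
  reps <- data.frame(chrom = c("chr01", "chr02"),
                     start = c(10000, 50000), end = c(12000, 53000))
  j <- data.frame(chrom_a = c("chr01", "chr01", "chr03"),
                  pos_a = c(11000, 11000, 7000),
                  strand_a = "+",
                  chrom_b = c("chr02", "chr02", "chr02"),
                  pos_b = c(51000, 20000, 51000),
                  strand_b = "+", stringsAsFactors = FALSE)
  out <- classify_translocations(j, reps)
  expect_equal(out$klass, c("NAHR", "NMTL", "NMTL"))
  expect_true(all(out$klass %in% c("NAHR", "NMTL")))
  empty <- classify_translocations(j[0, ], reps)
  expect_equal(nrow(empty), 0L)
})

test_that("breakpoint motif search looks around the junction point", {
  # 20 bp either side, cut between positions 20 and 21, GATC right of the cut
  left <- "CCATTGCCAATTGGCCAACG"
  expect_true(check_breakpoint_motif(paste0(left, "GATCAATTGGCCAATTGGCC")))
  expect_false(check_breakpoint_motif(paste0(left, "AAAAAATTGGCCAATTGGCC")))
  # a GATC far from the cut must not count
  expect_false(check_breakpoint_motif("GATCAATTGGCCAACGCCATTGCCAATTGGCCAACGACCA"))
  # motif parameterisation: a GATC junction is no CCCGGG junction
  expect_false(check_breakpoint_motif(paste0(left, "GATCAATTGGCCAATTGGCC"),
                                      motif = "CCCGGG"))
  # reverse complement hits count (GGATCC junction probed with GGATCC rc = itself;
  # use a non-palindromic motif to see the rc path)
  expect_true(check_breakpoint_motif(paste0(left, "CCGGAATTGGCCAATTGGCC"),
                                     motif = "TTCCGG"))
  expect_error(check_breakpoint_motif("ACG", motif = "GATC"), "shorter")
})

test_that("control subtraction removes coincident events at the stated overlap", {
  ev <- data.frame(chrom = "chr01", start = c(100, 5000, 20000),
                   end = c(200, 6000, 30000), klass = "SGC",
                   stringsAsFactors = FALSE)
  ctrl <- data.frame(chrom = "chr01", start = c(100, 40000),
                     end = c(200, 50000), klass = "SGC",
                     stringsAsFactors = FALSE)
  out <- subtract_control(ev, ctrl)
  expect_equal(out$start, c(5000, 20000))

  # 60%-overlapping pair: removed at 0.5, kept at 0.7
  a <- data.frame(chrom = "chr01", start = 1, end = 1000, klass = "SGC")
  b <- data.frame(chrom = "chr01", start = 401, end = 1400, klass = "SGC")
  expect_equal(nrow(subtract_control(a, b, reciprocal_overlap = 0.5)), 0L)
  expect_equal(nrow(subtract_control(a, b, reciprocal_overlap = 0.7)), 1L)

  jev <- data.frame(chrom_a = "chr01", pos_a = 1000, strand_a = "+",
                    chrom_b = "chr02", pos_b = 9000, strand_b = "+",
                    stringsAsFactors = FALSE)
  jctrl <- data.frame(chrom_a = "chr01", pos_a = 1400, strand_a = "+",
                      chrom_b = "chr02", pos_b = 8500, strand_b = "+",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(subtract_control(jev, jctrl)), 0L)  # within 1 kb
  jctrl$pos_a <- 2500
  expect_equal(nrow(subtract_control(jev, jctrl)), 1L)
})

test_that("isolate reports sum merged tract lengths and flag haploidization", {
  sizes <- c(chr01 = 2e6, chr02 = 1e6)
  loh <- data.frame(chrom = "chr01", start = c(100001, 500001),
                    end = c(200000, 900000),
                    haplotype = "p1", n_markers = 50L,
                    klass = c("SGC", "BIR"), stringsAsFactors = FALSE)
  cnv <- data.frame(chrom = "chr02", start = 1, end = 1e6,
                    klass = "aneuploidy", subtype = "gain",
                    dosage_ratio = 1.5, stringsAsFactors = FALSE)
  rep1 <- build_isolate_report("iso1", loh, cnv, NULL, sizes)
  expect_equal(rep1$total_loh_length, 100000 + 400000)
  expect_equal(rep1$total_cnv_length, 1e6)
  expect_false(rep1$excluded)
  expect_equal(count_events(rep1), 3L)

  # overlapping LOH intervals merge before summing
  loh2 <- data.frame(chrom = "chr01", start = c(1, 50001),
                     end = c(100000, 150000), haplotype = "p1",
                     n_markers = 10L, klass = "SGC", stringsAsFactors = FALSE)
  rep2 <- build_isolate_report("iso2", loh2, NULL, NULL, sizes)
  expect_equal(rep2$total_loh_length, 150000)

  # genome-wide LOH -> excluded
  loh3 <- data.frame(chrom = c("chr01", "chr02"), start = 1,
                     end = c(2e6, 1e6), haplotype = "p1", n_markers = 100L,
                     klass = "BIR", stringsAsFactors = FALSE)
  rep3 <- build_isolate_report("iso3", loh3, NULL, NULL, sizes)
  expect_true(rep3$excluded)
  expect_equal(rep3$exclusion_reason, "complete loss of heterozygosity")
})
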