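test_that("sphere fixtures carry the requested atoms", {
  m <- gen_sphere_fixture("C", matrix(0, 1, 3))
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(unname(m$chains), "ligand")
  m2 <- gen_sphere_fixture(c("C", "N"), rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(m2$atoms$element, c("C", "N"))
})

test_that("toy complexes are deterministic per seed and plant the contact patch", {
  a <- gen_toy_complex(6, 100, seed = 8)
  b <- gen_toy_complex(6, 100, seed = 8)
  expect_identical(a, b)
  c_ <- gen_toy_complex(6, 100, seed = 9)
  expect_false(identical(a, c_))
  expect_equal(sum(a$atoms$z == 3.4), 6L)
  expect_error(gen_toy_complex(99, 100), "exceeds")
})

test_that("B-DNA duplexes have 2n nucleotides and valid base pairing", {
  s <- "ACGTACGTAC"
  m <- gen_bdna(s)
  nt_key <- unique(paste(m$atoms$chain, m$atoms$resno))
  expect_equal(length(nt_key), 2L * nchar(s))
  expect_error(gen_bdna("ACGX"), "A, C, G, T")
  # bottom strand is the reverse complement
  bot <- m$atoms[m$atoms$chain == "B" & m$atoms$name == "P", ]
  bot_seq <- paste(sub("^D", "", bot$resname[order(bot$resno)]), collapse = "")
  expect_equal(bot_seq, reverse_complement(s))
})

test_that("simulated genomes are pure functions of the seed", {
  g1 <- gen_hybrid_genome(2, 50000, seed = 5)
  g2 <- gen_hybrid_genome(2, 50000, seed = 5)
  expect_identical(g1, g2)
  g3 <- gen_hybrid_genome(2, 50000, seed = 6)
  expect_false(identical(g1$hap1, g3$hap1))
})

test_that("marker density tracks the divergence parameter", {
  g <- gen_hybrid_genome(1, 1e6, divergence = 0.007, seed = 17)
  n <- nrow(g$markers)
  sd3 <- 3 * sqrt(1e6 * 0.007 * 0.993)
  expect_gt(n, 7000 - sd3)
  expect_lt(n, 7000 + sd3)
  expect_equal(round(100 * n / 1e6, 1), 0.7)
  # markers really differ between haplotypes
  idx <- g$markers$pos[1:50]
  h1 <- strsplit(g$hap1[[1]], "")[[1]][idx]
  h2 <- strsplit(g$hap2[[1]], "")[[1]][idx]
  expect_true(all(h1 != h2))
  expect_equal(g$markers$allele_p1[1:50], h1)
})

test_that("every 10 kb window of haplotype 1 contains the motif", {
  g <- gen_hybrid_genome(1, 60000, seed = 23)
  for (ws in seq(1, 60000, by = 10000)) {
    win <- substr(g$hap1[[1]], ws, min(ws + 9999, 60000))
    expect_true(grepl("GATC", win, fixed = TRUE))
  }
})

test_that("allele depths sum to the drawn totals and events shape the fractions", {
  g <- gen_hybrid_genome(2, 80000, divergence = 0.01, seed = 3)
  ev <- list(list(klass = "SGC", chrom = "chr01", start = 20000, end = 60000,
                  haplotype = "p1"))
  st <- implant_events(g, ev, coverage = 30, seed = 4)
  mk <- st$markers
  expect_true(all(mk$depth_p1 + mk$depth_p2 >= 0))
  inside <- mk$chrom == "chr01" & mk$pos >= 20000 & mk$pos <= 60000
  expect_true(all(mk$depth_p2[inside] == 0))  # binomial at f = 1
  outside_f <- with(mk[!inside & (mk$depth_p1 + mk$depth_p2) > 0, ],
                    mean(depth_p1 / (depth_p1 + depth_p2)))
  expect_equal(outside_f, 0.5, tolerance = 0.05)
})

test_that("null event lists leave a genome-wide het track with no calls", {
  g <- gen_hybrid_genome(2, 60000, seed = 12)
  st <- implant_events(g, list(), coverage = 30, seed = 13)
  tr <- genotype_markers(st$markers)
  expect_gt(mean(tr$genotype == "het"), 0.9)
  seg <- call_loh(tr, st$chrom_sizes)
  expect_equal(nrow(seg), 0L)
  expect_equal(nrow(st$junctions), 0L)
})

test_that("NMTL junctions snap to the motif and carry it in their flanks", {
  sim <- simulate_isolate(seed = 77)
  j <- sim$sim$junctions
  nm <- j[j$klass_truth == "NMTL", ]
  expect_gte(nrow(nm), 1L)
  ann <- annotate_junction_motifs(nm)
  expect_true(all(ann$motif_match_a))
  expect_true(all(ann$motif_match_b))
  # flank carries GATC immediately 3' of the cut midpoint
  expect_equal(substr(nm$flank_a[1], 21, 24), "GATC")
})

test_that("conflicting or invalid event specs are rejected", {
  g <- gen_hybrid_genome(1, 50000, seed = 19)
  expect_error(implant_events(g, list(
    list(klass = "SGC", chrom = "chr01", start = 1000, end = 20000,
         haplotype = "p1"),
    list(klass = "SGC", chrom = "chr01", start = 15000, end = 30000,
         haplotype = "p2"))), "overlapping")
  expect_error(implant_events(g, list(
    list(klass = "SGC", chrom = "chr01", start = 1000, end = 90000,
         haplotype = "p1"))), "outside")
  expect_error(implant_events(g, list(
    list(klass = "NAHR", chrom_a = "chr01", pos_a = 100, chrom_b = "chr01",
         pos_b = 200))), "repeat")
})

test_that("implanted SGC/BIR/aneuploidy events are recovered with correct class", {
  n_rep <- 20
  n_truth <- 0; n_found <- 0; motif_ok <- TRUE
  for (seed in seq_len(n_rep)) {
    sim <- simulate_isolate(seed = seed)
    st <- sim$sim
    tr <- genotype_markers(st$markers)
    loh <- call_loh(tr, st$chrom_sizes)
    cnv <- call_aneuploidy(tr, st$chrom_sizes)
    truth <- st$truth
    for (i in seq_len(nrow(truth))) {
      tv <- truth[i, ]
      if (tv$klass %in% c("SGC", "BIR")) {
        n_truth <- n_truth + 1
        hit <- any(loh$klass == tv$klass & loh$chrom == tv$chrom &
                     vapply(seq_len(nrow(loh)), function(k) {
                       reciprocal_overlap_frac(loh$start[k], loh$end[k],
                                               tv$start, tv$end) >= 0.5
                     }, logical(1)))
        n_found <- n_found + hit
      } else if (tv$klass == "aneuploidy") {
        n_truth <- n_truth + 1
        n_found <- n_found + any(cnv$chrom == tv$chrom & cnv$subtype == "gain")
      }
    }
    ann <- annotate_junction_motifs(
      st$junctions[st$junctions$klass_truth == "NMTL", ])
    if (!all(ann$motif_match_a & ann$motif_match_b)) motif_ok <- FALSE
  }
  expect_gte(n_found / n_truth, 0.95)
  expect_true(motif_ok)
})
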