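genome2 <- tibble::tibble(contig = c("chr1", "chr2"),
                          length = c(3000000L, 2000000L))

test_that("random placement is uniform, size-preserving and deterministic", {
  region <- tibble::tibble(contig = "x", start = 0L, end = 20000L)
  g1 <- tibble::tibble(contig = "chr1", length = 1000000L)
  pl <- random_placement(region, g1, n_reps = 4000L, seed = 1)
  expect_equal(nrow(pl), 4000L)
  expect_true(all(pl$end - pl$start == 20000L))
  expect_true(all(pl$start >= 0 & pl$end <= 1000000L))
  # mean start within 3 SE of (L - len) / 2 under uniformity
  m <- (1000000 - 20000) / 2
  se <- (1000000 - 20000) / sqrt(12) / sqrt(4000)
  expect_lt(abs(mean(pl$start) - m), 3 * se)
  # determinism
  expect_identical(random_placement(region, g1, n_reps = 5L, seed = 9),
                   random_placement(region, g1, n_reps = 5L, seed = 9))
  # no mutual overlap within a replicate, and forbidden zones respected
  regions <- tibble::tibble(contig = "x", start = 0L,
                            end = rep(30000L, 6))
  forb <- tibble::tibble(contig = "chr1", start = 0L, end = 500000L)
  pl2 <- random_placement(regions, g1, forbidden = forb, n_reps = 20L,
                          seed = 2)
  expect_true(all(pl2$start >= 500000L))
  for (r in split(pl2, pl2$rep)) {
    o <- r[order(r$start), ]
    expect_true(all(o$start[-1] >= o$end[-nrow(o)]))
  }
  # infeasible totals error
  expect_error(random_placement(
    tibble::tibble(contig = "x", start = 0L, end = 2000000L), g1),
    "exceed")
})

test_that("enrichment is calibrated on random features and bounded below in p", {
  feats <- random_placement(
    tibble::tibble(contig = "x", start = 0L, end = rep(1000L, 600)),
    genome2, n_reps = 1L, seed = 10)[, c("contig", "start", "end")]
  qry <- random_placement(
    tibble::tibble(contig = "x", start = 0L, end = rep(10000L, 120)),
    genome2, n_reps = 1L, seed = 11)[, c("contig", "start", "end")]
  et <- enrichment_test(qry, feats, genome2, n_reps = 500L, seed = 12)
  expect_gt(et$fold, 0.8)
  expect_lt(et$fold, 1.2)
  expect_gt(et$p, 0.05)
  expect_equal(et$n_reps, 500L)
  # identical seed reproduces the full result
  et2 <- enrichment_test(qry, feats, genome2, n_reps = 500L, seed = 12)
  expect_identical(et$null, et2$null)
  expect_identical(tidy(et), tidy(et2))

  # a self-overlap construction on a sparse genome achieves the add-one
  # minimum p = 1 / (reps + 1)
  sparse <- feats[1:30, ]
  ets <- enrichment_test(sparse, sparse, genome2, n_reps = 400L, seed = 13)
  expect_equal(ets$observed, 30)
  expect_equal(ets$p, 1 / 401)
  expect_gt(ets$fold, 1)
  expect_true(ets$p >= 1 / (ets$n_reps + 1))
})

test_that("breakpoint segments are centered, clipped and conserve length", {
  g <- tibble::tibble(contig = "chr1", length = 100000L)
  cn <- tibble::tibble(contig = "chr1", start = c(10000L, 300L),
                       end = c(30000L, 99500L))
  bp <- breakpoint_segments(cn, g)
  expect_equal(nrow(bp), 4L)
  b1 <- bp[bp$cnvr_id == 1, ]
  expect_equal(b1$start, c(9000L, 29000L))
  expect_equal(b1$end, c(11000L, 31000L))
  b2 <- bp[bp$cnvr_id == 2, ]
  expect_equal(b2$start[b2$boundary == "start"], 0L)     # clipped left
  expect_equal(b2$end[b2$boundary == "start"], 1300L)
  expect_equal(b2$end[b2$boundary == "end"], 100000L)    # clipped right
  # n unclipped CNVRs contribute n * 4000 segment bases
  interior <- tibble::tibble(contig = "chr1",
                             start = c(10000L, 50000L), end = c(30000L, 70000L))
  bpi <- breakpoint_segments(interior, g)
  expect_equal(sum(bpi$end - bpi$start), 2L * 4000L)
})

test_that("pooled segment GC matches direct counting and saturates to the genome", {
  s <- random_masked_seq(50000L, 3, 100, seed = 50)
  seqs <- c(chr1 = s)
  seg <- tibble::tibble(contig = "chr1", start = c(1000L, 30000L),
                        end = c(3000L, 32000L))
  got <- sdcnv:::pooled_gc(seqs, seg)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  picked <- c(ch[1001:3000], ch[30001:32000])
  expect_equal(got, sum(picked %in% c("G", "C")) / sum(picked != "N"))
  # segments covering the whole genome equal the background, p ~ 1
  whole <- tibble::tibble(contig = "chr1", start = 0L, end = 50000L)
  gcc <- gc_compare(whole, seqs, n_reps = 50L, seed = 51)
  expect_equal(gcc$gc_segments, gcc$gc_background)
  expect_gt(gcc$p, 0.5)
})

test_that("GC-rich islands at breakpoints are detected as enrichment", {
  set.seed(52)
  base <- strsplit(random_masked_seq(200000L, 0, 0, seed = 52), "")[[1]]
  # engineer 60% GC islands on an otherwise ~42% genome at known spots
  spots <- c(20000L, 80000L, 140000L)
  for (at in spots) {
    island <- sample(c("G", "C", "A", "T"), 2000, replace = TRUE,
                     prob = c(0.3, 0.3, 0.2, 0.2))
    base[(at + 1):(at + 2000)] <- island
  }
  seqs <- c(chr1 = paste(base, collapse = ""))
  seg <- tibble::tibble(contig = "chr1", start = spots, end = spots + 2000L)
  gcc <- gc_compare(seg, seqs, n_reps = 200L, seed = 53)
  expect_gt(gcc$gc_segments, gcc$gc_background + 0.05)
  expect_equal(gcc$p, 1 / 201)
})

test_that("GC peaks require the 1.5-fold local excess", {
  # homogeneous sequence: no peaks
  ref <- generate_reference(c(chr1 = 100000L), gc_target = 0.42, seed = 54)
  expect_equal(nrow(detect_gc_peaks(ref$seqs)), 0L)
  # a planted 90% GC window on a 30% background: one merged peak, ratio ~ 3
  lo <- generate_reference(c(chr1 = 100000L), gc_target = 0.30, seed = 55)
  s <- lo$seqs[["chr1"]]
  set.seed(56)
  substr(s, 50001, 50500) <- paste(
    sample(c("G", "C", "A", "T"), 500, replace = TRUE,
           prob = c(0.45, 0.45, 0.05, 0.05)), collapse = "")
  pk <- detect_gc_peaks(c(chr1 = s))
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$ratio - 3), 0.4)
  expect_true(pk$peak_start >= 49700 & pk$peak_end <= 51300)
  # boundary rule is inclusive: a constructed window at exactly the fold
  # threshold is reported
  flat <- strrep("AT", 10000)                     # GC 0
  block <- paste0(strrep("AATT", 1125),           # 4500 bp at GC 0
                  strrep("GCAT", 125),            # 500 bp at GC 0.5
                  strrep("AATT", 1250))           # 5000 bp at GC 0
  seqs_b <- c(chr1 = paste0(flat, block, flat))
  pk_b <- detect_gc_peaks(seqs_b, local = 500L, background = 10000L,
                          fold = 20, step = 100L)
  # local .5 vs background .025: ratio exactly 20 -> inclusive rule reports it
  expect_equal(nrow(pk_b), 1L)
  expect_equal(pk_b$ratio, 20)
})

test_that("breakpoint-peak association hits its degenerate and constructed limits", {
  g <- tibble::tibble(contig = "chr1", length = 500000L)
  bp <- tibble::tibble(contig = "chr1",
                       start = c(10000L, 100000L, 250000L),
                       end = c(12000L, 102000L, 252000L))
  # no peaks: proportion and fold are zero
  none <- breakpoint_peak_association(bp, bp[0, ], g, n_reps = 50L, seed = 60)
  expect_equal(none$observed, 0)
  expect_equal(none$fold, 0)
  # peaks placed exactly at the breakpoint midpoints: proportion 1, minimal p
  pks <- tibble::tibble(contig = "chr1", start = bp$start + 750L,
                        end = bp$start + 1250L)
  hit <- breakpoint_peak_association(bp, pks, g, n_reps = 200L, seed = 61)
  expect_equal(hit$observed, 1)
  expect_equal(hit$p, 1 / 201)
  # peaks tiling the whole genome: null saturates, fold ~ 1
  dense <- tibble::tibble(contig = "chr1",
                          start = seq(0L, 498000L, by = 2000L))
  dense$end <- dense$start + 500L
  sat <- breakpoint_peak_association(bp, dense, g, n_reps = 100L, seed = 62)
  expect_equal(sat$observed, 1)
  expect_equal(sat$fold, 1)
})

test_that("enrichment p values are roughly uniform under the null", {
  # meta-experiment: random queries against fixed random features
  feats <- random_placement(
    tibble::tibble(contig = "x", start = 0L, end = rep(2000L, 150)),
    genome2, n_reps = 1L, seed = 70)[, c("contig", "start", "end")]
  counter_genome <- genome2
  ps <- vapply(1:60, function(i) {
    qry <- random_placement(
      tibble::tibble(contig = "x", start = 0L, end = rep(8000L, 25)),
      counter_genome, n_reps = 1L, seed = 700L + i)[, c("contig", "start", "end")]
    enrichment_test(qry, feats, counter_genome, n_reps = 120L,
                    seed = 7000L + i)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(ps > 0 & ps <= 1))
})
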