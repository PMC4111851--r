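make_placements <- function(starts, contig = "chr") {
  structure(tibble::tibble(read_id = sprintf("r%d", seq_along(starts)),
                           contig = contig, start = as.integer(starts),
                           strand = "+", n_hits = 1L),
            class = c("placement_set", class(tibble::tibble())),
            read_length = 100L)
}

test_that("read counting respects half-open window spans", {
  seqs <- c(chr = strrep("ACGT", 2500))    # 10 kb
  w <- build_windows(seqs, dialect = "original", kind = "copy",
                     units_per_window = 1000L, read_length = 100)
  # zero placements
  w0 <- count_reads(w, make_placements(integer(0)))
  expect_true(all(w0$read_count == 0L))
  # a placement exactly at a span start belongs to that window
  w1 <- count_reads(w, make_placements(c(1000L, 1999L, 2000L)))
  expect_equal(w1$read_count[1:3], c(0L, 2L, 1L))
})

test_that("read counting matches a brute-force containment scan", {
  seqs <- c(chr = random_masked_seq(30000L, 6, 150, seed = 40))
  for (kind in c("copy", "long")) {
    w <- build_windows(seqs, dialect = "enhanced", kind = kind,
                       units_per_window = if (kind == "long") 2000L else 1000L,
                       slide_units = if (kind == "long") 500L else NULL,
                       read_length = 100)
    set.seed(41)
    starts <- sample.int(30000L, 500) - 1L
    wc <- count_reads(w, make_placements(starts))
    if (kind == "copy") {
      # tiling: each placement belongs to the window owning its start unit
      owner <- findInterval(starts, w$start)
      ok <- owner >= 1 & starts < w$end[pmax(owner, 1)]
      brute <- tabulate(owner[ok], nbins = nrow(w))
      expect_equal(wc$read_count, brute)
      # count conservation for the non-overlapping kind
      expect_equal(sum(wc$read_count) + attr(wc, "dropped_placements"),
                   length(starts))
    } else {
      brute <- vapply(seq_len(nrow(w)), function(i) {
        sum(starts >= w$start[i] & starts < w$end[i])
      }, 0L)
      expect_equal(wc$read_count, brute)
    }
  }
})

test_that("GC correction factors are ratios to the global mean", {
  df <- tibble::tibble(
    contig = "chr", start = (0:39) * 1000L, end = (0:39) * 1000L + 1000L,
    n_units = 1000L, gc = rep(c(0.30, 0.50), each = 20),
    read_count = rep(c(50L, 100L), each = 20), rd_corrected = NA_real_)
  w <- sdcnv:::new_window_set(df, "copy", "enhanced", 1000L, 1000L, 100L)
  fac <- fit_gc_correction(w, min_windows = 10L)
  expect_equal(fac$factor[fac$bin == 30], 1.5)
  expect_equal(fac$factor[fac$bin == 50], 0.75)
  wc <- apply_gc_correction(w, fac)
  expect_equal(unique(wc$rd_corrected), 75)
  # a single bin leaves counts unchanged
  w1 <- sdcnv:::new_window_set(dplyr::mutate(df, gc = 0.42), "copy",
                               "enhanced", 1000L, 1000L, 100L)
  f1 <- fit_gc_correction(w1, min_windows = 10L)
  expect_equal(f1$factor, 1)
  expect_equal(apply_gc_correction(w1, f1)$rd_corrected, df$read_count * 1)
})

test_that("GC correction flattens a linear coverage bias", {
  ref <- generate_reference(c(chr1 = 1000000L), seed = 42)
  reads <- simulate_reads(ref, coverage = 8, read_length = 100, seed = 43,
                          gc_bias = function(g) 1 + (g - 0.42))
  pl <- map_reads_exact(reads, ref, 0)
  w <- count_reads(build_windows(ref, dialect = "enhanced", kind = "copy",
                                 read_length = 100), pl)
  fac <- fit_gc_correction(w)
  wc <- apply_gc_correction(w, fac)
  rel <- wc$rd_corrected / mean(wc$rd_corrected)
  slope <- coef(lm(rel ~ wc$gc))[2]
  expect_lt(abs(slope), 0.05 * 10)  # slope per unit GC; 0.05 per 1% bin scale
  raw_slope <- coef(lm(I(wc$read_count / mean(wc$read_count)) ~ wc$gc))[2]
  expect_lt(abs(slope), abs(raw_slope) / 4)
})

test_that("control statistics trim outliers and converge idempotently", {
  set.seed(44)
  depths <- c(rnorm(950, 100, 10), rnorm(50, 300, 10))
  df <- tibble::tibble(contig = "chr", start = (seq_along(depths) - 1L) * 1000L,
                       end = (seq_along(depths) - 1L) * 1000L + 1000L,
                       n_units = 1000L, gc = 0.42,
                       read_count = as.integer(depths), rd_corrected = depths)
  w <- sdcnv:::new_window_set(df, "long", "enhanced", 1000L, 1000L, 100L)
  st <- fit_control_stats(w)
  expect_lt(abs(st$mu - 100) / 100, 0.01)
  expect_lt(st$sigma, 15)
  # idempotence: refitting on the surviving control windows moves mu < 1e-6 mu
  w2 <- sdcnv:::new_window_set(df[st$control_idx, ], "long", "enhanced",
                               1000L, 1000L, 100L)
  st2 <- fit_control_stats(w2)
  expect_lt(abs(st2$mu - st$mu), 1e-6 * st$mu)

  # constant depth triggers the minimum-sigma floor
  dfc <- dplyr::mutate(df, rd_corrected = 100)
  stc <- fit_control_stats(sdcnv:::new_window_set(dfc, "long", "enhanced",
                                                  1000L, 1000L, 100L))
  expect_equal(stc$mu, 100)
  expect_equal(stc$sigma, 0.5)
  expect_error(fit_control_stats(w, min_control = 2000L), "control windows")
})

test_that("the 6-of-7 rule rejects short runs and fires on long ones", {
  mu <- 100; sigma <- 5
  base <- rep(mu, 40)
  # all at the mean: no calls
  m0 <- synthetic_model(base, mu, sigma)
  expect_equal(nrow(call_cnv(m0, "duplication")), 0L)
  # exactly 5 consecutive elevated windows: 6-of-7 unsatisfied
  d5 <- base; d5[10:14] <- mu + 10 * sigma
  expect_equal(nrow(call_cnv(synthetic_model(d5, mu, sigma), "duplication")), 0L)
  # 8 consecutive elevated windows fire, span = union of deviating windows
  d8 <- base; d8[10:17] <- mu + 10 * sigma
  calls <- call_cnv(synthetic_model(d8, mu, sigma), "duplication")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, (10L - 1L) * 1000L)
  expect_equal(calls$end, (17L - 1L) * 1000L + 5000L)
  expect_gte(calls$end - calls$start, 10000L)
  # deletions are symmetric
  dd <- base; dd[10:17] <- mu - 10 * sigma
  expect_equal(nrow(call_cnv(synthetic_model(dd, mu, sigma), "deletion")), 1L)
})

test_that("one tolerated miss inside the run is allowed", {
  mu <- 100; sigma <- 5
  d <- rep(mu, 40); d[10:16] <- mu + 10 * sigma; d[13] <- mu
  calls <- call_cnv(synthetic_model(d, mu, sigma), "duplication")
  expect_equal(nrow(calls), 1L)   # 6 of the 7 windows deviate
})

test_that("gap-artifact calls are removed", {
  mu <- 100; sigma <- 5
  d <- rep(mu, 40); d[10:17] <- mu - 10 * sigma
  gaps <- tibble::tibble(contig = "chr", start = 8000L, end = 17000L)
  calls <- call_cnv(synthetic_model(d, mu, sigma), "deletion", gaps = gaps)
  expect_equal(nrow(calls), 0L)
})

test_that("the minimal callable span under defaults is exactly 10 kb", {
  expect_equal(minimal_call_span(), 10000L)
  expect_equal(minimal_call_span(5000L, 1000L, 6L), 10000L)
})

test_that("copy number is the diploid depth ratio", {
  depths <- c(rep(100, 50), 200, 50, 0)
  df <- tibble::tibble(contig = "chr", start = (seq_along(depths) - 1L) * 1000L,
                       end = (seq_along(depths) - 1L) * 1000L + 1000L,
                       n_units = 1000L, gc = 0.42,
                       read_count = as.integer(depths), rd_corrected = depths)
  w <- sdcnv:::new_window_set(df, "copy", "enhanced", 1000L, 1000L, 100L)
  model <- list(copy = list(windows = w, stats = list(mu = 100, sigma = 5)))
  prof <- estimate_copy_number(model, "s1")
  expect_equal(prof$cn[1], 2)
  expect_equal(prof$cn[51], 4)
  expect_equal(prof$cn[52], 1)
  expect_equal(prof$cn[53], 0)
  model$copy$stats$mu <- 0
  expect_error(estimate_copy_number(model), "positive")
})
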