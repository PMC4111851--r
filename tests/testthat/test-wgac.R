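# Self-comparison at desk scale. Genomes here are small (<= 200 kb) so
# the whole anchor -> chain -> align path stays fast.

test_that("anchors are confined to the duplicated pair and capped repeats vanish", {
  ref <- generate_reference(
    c(chr1 = 120000L), seed = 80,
    sds = tibble::tibble(length = 5000L, divergence = 0))
  an <- seed_matches(ref, k = 16, max_occ = 50)
  tr <- ref$sd_truth
  in_sd <- (an$pos_a >= tr$start_a & an$pos_a < tr$end_a) |
    (an$pos_a >= tr$start_b & an$pos_a < tr$end_b)
  # a handful of coincidental k-mer collisions are expected in 120 kb of
  # random sequence; essentially all anchors come from the planted pair
  expect_gt(mean(in_sd), 0.99)
  expect_gt(nrow(an), 4000)
  # canonical ordering: (a) precedes (b)
  expect_true(all(an$pos_a < an$pos_b | an$contig_a != an$contig_b))

  # a 500-copy repeat contributes no anchors at cap 50 (any surviving
  # anchor is a coincidental collision away from the repeat track)
  ref2 <- generate_reference(
    c(chr1 = 150000L), seed = 81,
    repeats = tibble::tibble(length = 150L, copies = 500L))
  an2 <- seed_matches(ref2, k = 16, max_occ = 50)
  if (nrow(an2) > 0) {
    anc_iv <- tibble::tibble(
      contig = c(an2$contig_a, an2$contig_b),
      start = c(an2$pos_a, an2$pos_b),
      end = c(an2$pos_a, an2$pos_b) + an2$k[1])
    expect_equal(sum(overlap_bases(anc_iv, ref2$repeat_track)), 0)
    expect_lt(nrow(an2), 10)
  } else {
    expect_equal(nrow(an2), 0L)
  }
})

test_that("anchor set equals a brute-force k-mer index", {
  ref <- generate_reference(
    c(chr1 = 60000L, chr2 = 40000L), seed = 82,
    sds = tibble::tibble(length = c(2000L, 1500L), divergence = c(0, 0.02)))
  k <- 16L
  an <- seed_matches(ref, k = k, max_occ = 50)
  # brute force: index every k-mer of both strands
  tab <- list()
  for (ctg in names(ref$seqs)) {
    s <- ref$seqs[[ctg]]
    p <- 0:(nchar(s) - k)
    km <- substring(s, p + 1, p + k)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
    canon <- pmin(km, rc)
    tab[[ctg]] <- tibble::tibble(contig = ctg, pos = p, canon = canon,
                                 fwd = km <= rc)
  }
  tab <- dplyr::bind_rows(tab)
  counts <- table(tab$canon)
  tab <- tab[tab$canon %in% names(counts)[counts >= 2 & counts <= 50], ]
  brute <- dplyr::group_modify(
    dplyr::group_by(tab, canon), function(d, key) {
      ij <- utils::combn(nrow(d), 2)
      tibble::tibble(contig_a = d$contig[ij[1, ]], pos_a = d$pos[ij[1, ]],
                     contig_b = d$contig[ij[2, ]], pos_b = d$pos[ij[2, ]],
                     strand = ifelse(d$fwd[ij[1, ]] == d$fwd[ij[2, ]],
                                     "+", "-"))
    })
  brute <- dplyr::ungroup(brute)[, c("contig_a", "pos_a", "contig_b",
                                     "pos_b", "strand")]
  swap <- brute$contig_a > brute$contig_b |
    (brute$contig_a == brute$contig_b & brute$pos_a > brute$pos_b)
  tmpc <- brute$contig_a[swap]; tmpp <- brute$pos_a[swap]
  brute$contig_a[swap] <- brute$contig_b[swap]
  brute$pos_a[swap] <- brute$pos_b[swap]
  brute$contig_b[swap] <- tmpc; brute$pos_b[swap] <- tmpp
  brute <- dplyr::arrange(dplyr::distinct(brute),
                          contig_a, contig_b, strand, pos_a)
  got <- dplyr::arrange(an[, names(brute)], contig_a, contig_b, strand, pos_a)
  expect_equal(as.data.frame(got), as.data.frame(brute))
})

test_that("chained alignments recover planted duplications at their divergence", {
  ref <- generate_reference(
    c(chr1 = 150000L), seed = 83,
    sds = tibble::tibble(length = c(2000L, 5000L), divergence = c(0, 0.05)))
  al <- chain_and_align(seed_matches(ref, k = 16, max_occ = 50), ref)
  expect_equal(nrow(al), 2L)
  exact <- al[al$identity == 1, ]
  expect_equal(nrow(exact), 1L)
  expect_gte(exact$aligned_columns, 1980)  # chain ends lose < k bp per side
  expect_lte(exact$aligned_columns, 2000)
  div <- al[al$identity < 1, ]
  expect_lt(abs(div$identity - 0.95), 0.01)
  # each planted pair is covered >= 90% by its alignment
  tr <- ref$sd_truth
  for (i in seq_len(nrow(tr))) {
    pair <- tibble::tibble(
      contig = c(tr$contig_a[i], tr$contig_b[i]),
      start = c(tr$start_a[i], tr$start_b[i]),
      end = c(tr$end_a[i], tr$end_b[i]))
    cov <- sum(overlap_bases(pair, merge_alignment_intervals(al))) /
      sum(pair$end - pair$start)
    expect_gte(cov, 0.9)
  }
})

test_that("distant duplications stay separate alignments", {
  ref <- generate_reference(
    c(chr1 = 120000L), seed = 84,
    sds = tibble::tibble(length = c(2000L, 2000L), divergence = c(0, 0)))
  al <- chain_and_align(seed_matches(ref, k = 16, max_occ = 50), ref)
  expect_equal(nrow(al), 2L)
})

test_that("the SD filter applies strict length and inclusive identity rules", {
  mk <- function(len, id) tibble::tibble(
    contig_a = "c", start_a = 0L, end_a = len, contig_b = "c",
    start_b = 50000L, end_b = 50000L + len, strand = "+", length = len,
    aligned_columns = len, matches = round(id * len), identity = id)
  al <- dplyr::bind_rows(mk(900L, 0.99), mk(5000L, 0.89), mk(5000L, 0.95),
                         mk(1000L, 0.95), mk(1001L, 0.90))
  fl <- filter_wgac(al)
  expect_equal(nrow(fl), 2L)
  expect_setequal(fl$length, c(5000L, 1001L))
  expect_true(all(fl$identity >= 0.90))
})

test_that("alignment interval merging matches the bitmap union", {
  set.seed(85)
  al <- tibble::tibble(
    contig_a = "chr", start_a = sample.int(50000L, 20),
    contig_b = "chr", start_b = sample.int(50000L, 20),
    strand = "+", identity = runif(20, 0.9, 1))
  al$end_a <- al$start_a + sample.int(3000L, 20)
  al$end_b <- al$start_b + sample.int(3000L, 20)
  m <- merge_alignment_intervals(al)
  both <- tibble::tibble(contig = "chr",
                         start = c(al$start_a, al$start_b),
                         end = c(al$end_a, al$end_b))
  expect_equal(covered_bases(m), sum(oracle_bitmap(both, 60000L)))
  # disjoint intervals stay distinct
  dj <- tibble::tibble(contig_a = "chr", start_a = c(0L, 10000L),
                       end_a = c(1000L, 11000L), contig_b = "chr",
                       start_b = c(20000L, 30000L),
                       end_b = c(21000L, 31000L), strand = "+",
                       identity = 0.95)
  expect_equal(nrow(merge_alignment_intervals(dj)), 4L)
})

test_that("swapping the two sides of every anchor leaves the result unchanged", {
  ref <- generate_reference(
    c(chr1 = 100000L), seed = 86,
    sds = tibble::tibble(length = 3000L, divergence = 0.03))
  an <- seed_matches(ref, k = 16, max_occ = 50)
  swapped <- dplyr::mutate(an, tmp_c = contig_a, tmp_p = pos_a,
                           contig_a = contig_b, pos_a = pos_b,
                           contig_b = tmp_c, pos_b = tmp_p)
  swapped <- swapped[, names(an)]
  al1 <- chain_and_align(an, ref)
  # re-canonicalize the swapped anchors the same way seed_matches does
  swap <- swapped$contig_a > swapped$contig_b |
    (swapped$contig_a == swapped$contig_b & swapped$pos_a > swapped$pos_b)
  tmpc <- swapped$contig_a[swap]; tmpp <- swapped$pos_a[swap]
  swapped$contig_a[swap] <- swapped$contig_b[swap]
  swapped$pos_a[swap] <- swapped$pos_b[swap]
  swapped$contig_b[swap] <- tmpc; swapped$pos_b[swap] <- tmpp
  al2 <- chain_and_align(dplyr::arrange(swapped, contig_a, contig_b,
                                        strand, pos_a), ref)
  expect_equal(as.data.frame(al1), as.data.frame(al2))
})
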