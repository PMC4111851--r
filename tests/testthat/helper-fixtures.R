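# Shared fixtures, all built in code.

# the worked fragmentation example: a 4 kb sequence whose first 2 kb
# alternate 50 bp N and 50 bp clean blocks (starting with N), rest clean
fig6_sequence <- function(total = 4000L, fragmented = 2000L, block = 50L) {
  set.seed(4242)
  s <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
             collapse = "")
  for (b in seq(0L, fragmented - 1L, by = 2L * block)) {
    substr(s, b + 1L, b + block) <- strrep("N", block)
  }
  c(chr = s)
}

# random masked sequence for oracle tests
random_masked_seq <- function(n, n_masks, mask_len, seed) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  for (i in seq_len(n_masks)) {
    at <- sample.int(n - mask_len, 1)
    substr(s, at, at + mask_len - 1L) <- strrep("N", mask_len)
  }
  s
}

# brute-force unique-hit positions: test every offset directly
oracle_unique_hits <- function(seq, L) {
  n <- nchar(seq)
  if (n < L) return(integer(0))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  which(vapply(0:(n - L), function(p) all(ch[(p + 1):(p + L)] != "N"),
               TRUE)) - 1L
}

# random interval table on one contig
random_intervals <- function(n, contig = "chr", max_pos = 100000L,
                             max_len = 5000L, seed = 1) {
  set.seed(seed)
  start <- sample.int(max_pos - max_len, n)
  len <- sample.int(max_len, n)
  tibble::tibble(contig = contig, start = start, end = start + len)
}

# per-base bitmap of covered positions
oracle_bitmap <- function(x, max_pos) {
  bm <- logical(max_pos)
  for (i in seq_len(nrow(x))) {
    if (x$end[i] > x$start[i]) bm[(x$start[i] + 1):x$end[i]] <- TRUE
  }
  bm
}

# windows with synthetic depth for caller unit tests: `n` long windows of
# 5000 units sliding by 1000 on an unmasked coordinate system
synthetic_long_windows <- function(depths, mu = 100, start0 = 0L) {
  n <- length(depths)
  df <- tibble::tibble(
    contig = "chr", start = start0 + (seq_len(n) - 1L) * 1000L,
    end = start0 + (seq_len(n) - 1L) * 1000L + 5000L,
    n_units = 5000L, gc = 0.42, read_count = as.integer(round(depths)),
    rd_corrected = depths)
  sdcnv:::new_window_set(df, "long", "enhanced", 5000L, 1000L, 100L)
}

synthetic_model <- function(depths, mu, sigma) {
  list(long = list(windows = synthetic_long_windows(depths),
                   stats = list(mu = mu, sigma = sigma)),
       short = NULL, copy = NULL)
}
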