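# Synthetic genomes with known CNV truth: a reference with planted
# high-copy repeats (to be hard-masked), planted segmental duplications,
# assembly gaps, per-individual duplication/deletion events, and uniform
# coverage reads with optional GC bias.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, gc = 0.42) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, n, replace = TRUE, prob = p)])
}

# point-mutate a sequence at the given per-base rate; every mutated base
# becomes a different base, so Hamming distance / length ~ rate
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1), "")
  paste(ch, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# place an element of length len on a contig without overlapping `occupied`
# (a per-contig list of interval tibbles); returns list(contig, start) or
# errors with `what` in the message
place_element <- function(len, contig_lengths, occupied, what, max_try = 2000L) {
  room <- pmax(contig_lengths - len + 1, 0)
  if (sum(room) == 0) stop(sprintf("placement error for %s: no contig can hold it", what), call. = FALSE)
  for (i in seq_len(max_try)) {
    ctg <- sample(names(contig_lengths), 1, prob = room)
    start <- sample.int(room[[ctg]], 1) - 1L
    occ <- occupied[[ctg]]
    if (is.null(occ) || nrow(occ) == 0 ||
        !any(start < occ$end & (start + len) > occ$start)) {
      return(list(contig = ctg, start = start))
    }
  }
  stop(sprintf("placement error for %s: could not fit without overlap", what), call. = FALSE)
}

#' Generate a synthetic reference genome
#'
#' Builds a multi-contig random reference with planted assembly gaps (runs
#' of N), planted high-copy repeats (recorded so they can be hard-masked),
#' and planted segmental duplications (SDs) whose second copy is
#' point-mutated at a chosen divergence. All planted elements are placed
#' uniformly at random without mutual overlap.
#'
#' @param contigs Named integer vector of contig lengths in bp (>= 10 kb).
#' @param gc_target Genome-wide GC fraction in (0, 1).
#' @param repeats Data frame with columns `length`, `copies`: one row per
#'   high-copy repeat family. Every copy is recorded in the repeat track.
#' @param sds Data frame with columns `length`, `divergence` (in `[0, 0.10]`):
#'   one row per planted SD pair.
#' @param gaps Data frame with columns `length`, `n`: assembly gaps.
#' @param fragmented Data frame with columns `length`, `block`: regions of
#'   densely interspersed repeats whose hard masking fragments the
#'   mappable sequence — alternating `block`-bp masked and clean stretches
#'   (starting masked) over `length` bp, recorded in the repeat track.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   genome byte for byte.
#' @return A `ref_bundle`: list with `seqs` (named character vector of
#'   contig sequences, gaps already N), `repeat_track`, `gap_track`
#'   (interval tibbles), `sd_truth` (tibble of planted SD pairs with
#'   divergence), and `gc_target`.
#' @examples
#' ref <- generate_reference(c(chr1 = 50000), seed = 1)
#' @export
generate_reference <- function(contigs = c(chr1 = 100000L),
                               gc_target = 0.42,
                               repeats = NULL, sds = NULL, gaps = NULL,
                               fragmented = NULL, seed = NULL) {
  stopifnot(length(contigs) >= 1, !is.null(names(contigs)),
            all(contigs >= 10000), gc_target > 0, gc_target < 1)
  if (!is.null(sds) && nrow(sds) > 0 &&
      any(sds$divergence < 0 | sds$divergence > 0.10)) {
    stop("sd divergences must be in [0, 0.10]", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  contigs <- setNames(as.integer(contigs), names(contigs))

  seqs <- vapply(contigs, random_dna, "", gc = gc_target)
  occupied <- setNames(vector("list", length(contigs)), names(contigs))
  note <- function(ctg, start, end) {
    occupied[[ctg]] <<- dplyr::bind_rows(occupied[[ctg]],
                                         tibble(start = start, end = end))
  }
  plant <- function(ctg, start, piece) {
    substr(seqs[[ctg]], start + 1L, start + nchar(piece)) <<- piece
  }

  gap_track <- tibble(contig = character(), start = integer(), end = integer())
  if (!is.null(gaps)) {
    for (i in seq_len(nrow(gaps))) {
      for (j in seq_len(gaps$n[i])) {
        len <- as.integer(gaps$length[i])
        at <- place_element(len, contigs, occupied, sprintf("gap row %d", i))
        plant(at$contig, at$start, strrep("N", len))
        note(at$contig, at$start, at$start + len)
        gap_track <- dplyr::add_row(gap_track, contig = at$contig,
                                    start = at$start, end = at$start + len)
      }
    }
  }

  repeat_track <- tibble(contig = character(), start = integer(), end = integer())
  if (!is.null(fragmented)) {
    for (i in seq_len(nrow(fragmented))) {
      len <- as.integer(fragmented$length[i])
      blk <- as.integer(fragmented$block[i])
      at <- place_element(len, contigs, occupied, sprintf("fragmented row %d", i))
      note(at$contig, at$start, at$start + len)
      blocks <- seq(0L, len - 1L, by = 2L * blk)
      repeat_track <- dplyr::bind_rows(repeat_track,
        tibble(contig = at$contig, start = at$start + blocks,
               end = pmin(at$start + blocks + blk, at$start + len)))
    }
  }
  if (!is.null(repeats)) {
    for (i in seq_len(nrow(repeats))) {
      len <- as.integer(repeats$length[i])
      unit <- random_dna(len, gc_target)
      for (j in seq_len(repeats$copies[i])) {
        at <- place_element(len, contigs, occupied, sprintf("repeat row %d", i))
        plant(at$contig, at$start, unit)
        note(at$contig, at$start, at$start + len)
        repeat_track <- dplyr::add_row(repeat_track, contig = at$contig,
                                       start = at$start, end = at$start + len)
      }
    }
  }

  sd_truth <- tibble(contig_a = character(), start_a = integer(), end_a = integer(),
                     contig_b = character(), start_b = integer(), end_b = integer(),
                     divergence = double())
  if (!is.null(sds)) {
    for (i in seq_len(nrow(sds))) {
      len <- as.integer(sds$length[i])
      src <- place_element(len, contigs, occupied, sprintf("sd row %d (source)", i))
      note(src$contig, src$start, src$start + len)
      dst <- place_element(len, contigs, occupied, sprintf("sd row %d (target)", i))
      note(dst$contig, dst$start, dst$start + len)
      piece <- substr(seqs[[src$contig]], src$start + 1L, src$start + len)
      plant(dst$contig, dst$start, mutate_seq(piece, sds$divergence[i]))
      sd_truth <- dplyr::add_row(sd_truth,
        contig_a = src$contig, start_a = src$start, end_a = src$start + len,
        contig_b = dst$contig, start_b = dst$start, end_b = dst$start + len,
        divergence = sds$divergence[i])
    }
  }

  structure(list(seqs = seqs, repeat_track = repeat_track,
                 gap_track = merge_intervals(gap_track, merge_abutting = TRUE),
                 sd_truth = sd_truth, gc_target = gc_target),
            class = "ref_bundle")
}

#' @export
print.ref_bundle <- function(x, ...) {
  cat(sprintf("<ref_bundle> %d contig(s), %s bp total\n",
              length(x$seqs), format(sum(nchar(x$seqs)), big.mark = ",")))
  cat(sprintf("  repeats: %d interval(s); gaps: %d; planted SD pairs: %d\n",
              nrow(x$repeat_track), nrow(x$gap_track), nrow(x$sd_truth)))
  invisible(x)
}

#' Contig table of a reference bundle
#'
#' @param ref A `ref_bundle` (or named character vector of sequences).
#' @return Tibble with `contig` and `length` columns.
#' @export
contig_table <- function(ref) {
  seqs <- if (inherits(ref, "ref_bundle")) ref$seqs else ref
  tibble(contig = names(seqs), length = nchar(seqs))
}

#' Combined hard-mask of a reference
#'
#' The union of the repeat track and the gap track: the intervals whose
#' bases are N after hard masking.
#'
#' @param ref A `ref_bundle`.
#' @return Merged interval tibble.
#' @export
reference_mask <- function(ref) {
  merge_intervals(dplyr::bind_rows(ref$repeat_track, ref$gap_track),
                  merge_abutting = TRUE)
}

#' Hard-masked contig sequences
#'
#' Replaces every base under the repeat or gap track with N. This is the
#' substrate for mappability and window construction; read mapping uses
#' the unmasked sequence (mask filtering happens at window counting).
#'
#' @param ref A `ref_bundle`.
#' @return Named character vector of masked sequences.
#' @export
masked_seqs <- function(ref) {
  seqs <- ref$seqs
  m <- reference_mask(ref)
  for (i in seq_len(nrow(m))) {
    substr(seqs[[m$contig[i]]], m$start[i] + 1L, m$end[i]) <-
      strrep("N", m$end[i] - m$start[i])
  }
  seqs
}

#' Simulate a diploid donor individual
#'
#' Applies duplication/deletion events to two haplotype copies of the
#' reference so the donor carries `copy_number / 2` times the reference
#' dosage of each event segment. Deletions remove the segment from
#' `2 - copy_number` haplotypes; duplications append `copy_number - 2`
#' extra copies distributed round-robin over the haplotypes, in tandem
#' after the source segment or at a random dispersed position.
#'
#' @param ref A `ref_bundle`.
#' @param events Data frame with `contig`, `start`, `end`,
#'   `copy_number` (non-negative integer, != 2). Must be non-overlapping.
#' @param individual_id Sample name carried through to reads and calls.
#' @param geometry `"tandem"` (default) or `"dispersed"` placement of
#'   extra duplication copies; the read-depth signal is identical.
#' @param seed Integer seed (used only for dispersed placement).
#' @return A `donor_genome`: list with `genome` (named character vector,
#'   two haplotypes per contig), `truth` (the events, unchanged), and
#'   `individual_id`.
#' @export
simulate_individual <- function(ref, events = NULL, individual_id = "ind1",
                                geometry = c("tandem", "dispersed"),
                                seed = NULL) {
  geometry <- match.arg(geometry)
  if (!is.null(seed)) withr::local_seed(seed)
  events <- if (is.null(events) || nrow(as.data.frame(events)) == 0) {
    tibble(contig = character(), start = integer(), end = integer(),
           copy_number = integer())
  } else check_intervals(events, "events")
  lens <- setNames(nchar(ref$seqs), names(ref$seqs))
  if (nrow(events) > 0) {
    stopifnot("copy_number" %in% names(events))
    if (any(events$copy_number == 2) || any(events$copy_number < 0) ||
        any(events$copy_number != round(events$copy_number))) {
      stop("copy_number must be a non-negative integer different from 2",
           call. = FALSE)
    }
    if (any(events$end > lens[events$contig])) {
      stop("events extend beyond contig bounds", call. = FALSE)
    }
    ov <- events %>% dplyr::arrange(.data$contig, .data$start) %>%
      dplyr::group_by(.data$contig) %>%
      dplyr::mutate(clash = .data$start < dplyr::lag(.data$end, default = -1L)) %>%
      dplyr::pull(.data$clash)
    if (any(ov)) stop("events overlap within the individual", call. = FALSE)
  }

  haps <- list()
  for (ctg in names(ref$seqs)) {
    for (h in 1:2) haps[[paste0(ctg, "_h", h)]] <- ref$seqs[[ctg]]
  }
  ev <- events %>% dplyr::arrange(.data$contig, dplyr::desc(.data$start))
  for (i in seq_len(nrow(ev))) {
    ctg <- ev$contig[i]; s <- ev$start[i]; e <- ev$end[i]
    cn <- ev$copy_number[i]
    segment <- substr(ref$seqs[[ctg]], s + 1L, e)
    hap_names <- paste0(ctg, "_h", 1:2)
    if (cn < 2) {                         # remove from (2 - cn) haplotypes
      for (h in seq_len(2 - cn)) {
        hp <- hap_names[h]
        haps[[hp]] <- paste0(substr(haps[[hp]], 1, s), substr(haps[[hp]], e + 1L,
                                                              nchar(haps[[hp]])))
      }
    } else {                              # append (cn - 2) extra copies
      for (k in seq_len(cn - 2)) {
        hp <- hap_names[(k - 1) %% 2 + 1]
        at <- if (geometry == "tandem") e else
          sample.int(nchar(haps[[hp]]) - 1L, 1)
        haps[[hp]] <- paste0(substr(haps[[hp]], 1, at), segment,
                             substr(haps[[hp]], at + 1L, nchar(haps[[hp]])))
      }
    }
  }
  structure(list(genome = unlist(haps), truth = events,
                 individual_id = individual_id),
            class = "donor_genome")
}

#' Simulate uniform-coverage short reads
#'
#' Samples single-end reads of fixed length uniformly from a donor genome
#' (or directly from a reference, for the reference individual). Read
#' count is Poisson with mean `coverage * genome_length / read_length`;
#' reads containing N (assembly gaps) are rejected and resampled. An
#' optional GC bias reweights start positions by `gc_bias(gc)` of the read
#' fragment via rejection sampling.
#'
#' @param donor A `donor_genome`, `ref_bundle`, or named character vector
#'   of sequences.
#' @param coverage Mean haploid-genome coverage (> 0).
#' @param read_length Read length in bp (>= 20).
#' @param gc_bias Optional function mapping GC fraction in `[0, 1]` to a
#'   non-negative weight; `NULL` means uniform (and consumes the same
#'   random stream as a constant bias of 1).
#' @param seed Integer seed.
#' @return A `read_set` tibble with `read_id`, `seq`, and attributes
#'   `read_length`, `individual_id`, `coverage`, `seed`.
#' @export
simulate_reads <- function(donor, coverage, read_length = 100L,
                           gc_bias = NULL, seed = NULL) {
  if (!is.numeric(coverage) || coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  stopifnot(read_length >= 20)
  if (!is.null(seed)) withr::local_seed(seed)
  seqs <- if (inherits(donor, "donor_genome")) donor$genome
          else if (inherits(donor, "ref_bundle")) donor$seqs else donor
  ind <- if (inherits(donor, "donor_genome")) donor$individual_id else "reference"
  lens <- nchar(seqs)
  if (all(lens < read_length)) stop("donor shorter than read_length", call. = FALSE)
  valid <- pmax(lens - read_length + 1L, 0L)
  total <- sum(as.numeric(lens))
  n_target <- rpois(1, coverage * total / read_length)
  bmax <- if (is.null(gc_bias)) 1 else max(vapply(seq(0, 1, 0.01), gc_bias, 0))
  if (!is.null(gc_bias) && bmax <= 0) stop("gc_bias must be positive somewhere", call. = FALSE)

  out <- character(0)
  guard <- 0L
  while (length(out) < n_target && guard < 50L) {
    guard <- guard + 1L
    n_draw <- max(100L, ceiling((n_target - length(out)) * 1.3))
    ctg <- sample.int(length(seqs), n_draw, replace = TRUE, prob = valid)
    start <- floor(runif(n_draw) * valid[ctg])      # 0-based
    frag <- substring(seqs[ctg], start + 1, start + read_length)
    u <- runif(n_draw)
    keep <- !stringr::str_detect(frag, "N")
    if (!is.null(gc_bias)) {
      gc <- stringr::str_count(frag, "[GC]") / read_length
      keep <- keep & u < vapply(gc, gc_bias, 0) / bmax
    }
    frag <- frag[keep]
    rev <- runif(length(frag)) < 0.5
    if (any(rev)) frag[rev] <- revcomp(frag[rev])
    out <- c(out, frag)
  }
  out <- unname(out[seq_len(min(length(out), n_target))])
  res <- tibble(read_id = sprintf("r%07d", seq_along(out)), seq = out)
  structure(res, class = c("read_set", class(res)),
            read_length = as.integer(read_length), individual_id = ind,
            coverage = coverage, seed = seed)
}

#' Map reads to all placements with at most a given number of mismatches
#'
#' An exact multi-mapper: reports every placement of every read, on both
#' strands, with at most `max_mismatches` mismatches against the unmasked
#' reference (reference N never matches). Placements over masked bases are
#' reported too; mask filtering happens later at window counting.
#' Reverse-strand placements are recorded by their forward-strand start.
#'
#' @param reads A `read_set` (tibble with `read_id`, `seq`).
#' @param ref A `ref_bundle` or named character vector of sequences.
#' @param max_mismatches Integer in 0..2 (small by design).
#' @return A `placement_set` tibble: `read_id`, `contig`, `start`
#'   (0-based), `strand`, `n_hits` (total placements of that read).
#' @export
map_reads_exact <- function(reads, ref, max_mismatches = 0L) {
  stopifnot(max_mismatches >= 0, max_mismatches <= 2)
  seqs <- if (inherits(ref, "ref_bundle")) ref$seqs else ref
  L <- attr(reads, "read_length")
  if (is.null(L)) L <- nchar(reads$seq[1])
  hits <- cpp_map_reads(unname(seqs), reads$seq, as.integer(max_mismatches))
  res <- tibble(read_id = reads$read_id[hits$read],
                contig = names(seqs)[hits$contig],
                start = hits$start,
                strand = hits$strand) %>%
    dplyr::arrange(.data$contig, .data$start, .data$read_id, .data$strand) %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::mutate(n_hits = dplyr::n()) %>%
    dplyr::ungroup()
  structure(res, class = c("placement_set", class(res)),
            read_length = as.integer(L),
            individual_id = attr(reads, "individual_id"),
            n_reads = nrow(reads))
}
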