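# Whole-genome assembly self-comparison (WGAC) at desk scale: exact k-mer
# anchors capped at a genome-wide occurrence limit (suppressing high-copy
# repeats), banded chaining by diagonal, global alignment of each chain,
# and the >1 kb / >=90% identity SD filter.

# all k-mer anchor pairs between distinct positions; canonical strand
# handling: a position pair is "+" when both carry the same k-mer and "-"
# when one carries the reverse complement of the other
#' Exact k-mer anchor matches under an occurrence cap
#'
#' Finds all pairs of distinct genome positions sharing an exact k-mer on
#' either strand — the stand-in for high-copy-repeat removal is an
#' occurrence cap: every base covered by a k-mer whose genome-wide
#' canonical count exceeds `max_occ` is treated as repeat-masked, and any
#' k-mer touching such a base is excluded. A planted high-copy repeat
#' therefore contributes no anchors at all, boundary k-mers included.
#'
#' @param ref A `ref_bundle` or named character vector of sequences.
#' @param k K-mer size in `[12, 32]`.
#' @param max_occ Maximum genome-wide occurrences of a k-mer (>= 2).
#' @return An `anchor` tibble: `contig_a`, `pos_a`, `contig_b`, `pos_b`,
#'   `strand` (`+` same orientation, `-` reverse complement), `k`;
#'   canonicalized so that (a) <= (b) and symmetric duplicates removed.
#' @export
seed_matches <- function(ref, k = 16L, max_occ = 50L) {
  stopifnot(k >= 12, k <= 32, max_occ >= 2)
  seqs <- if (inherits(ref, "ref_bundle")) ref$seqs else ref
  pos_tab <- purrr::map_dfr(names(seqs), function(ctg) {
    s <- seqs[[ctg]]
    n <- nchar(s)
    if (n < k) return(NULL)
    p <- 0:(n - k)
    km <- substring(s, p + 1, p + k)
    ok <- !stringr::str_detect(km, "[^ACGT]")
    tibble(contig = ctg, pos = p[ok], kmer = km[ok])
  })
  if (nrow(pos_tab) == 0) return(empty_anchors(k))
  rc <- revcomp(pos_tab$kmer)
  canon_fwd <- pos_tab$kmer <= rc
  pos_tab$canon <- ifelse(canon_fwd, pos_tab$kmer, rc)
  pos_tab$orient <- ifelse(canon_fwd, "+", "-")
  counts <- table(pos_tab$canon)
  over <- pos_tab$canon %in% names(counts)[counts > max_occ]
  # bases covered by an over-cap k-mer are repeat-masked; drop every
  # k-mer that touches one (removes repeat-boundary seeds too)
  if (any(over)) {
    touches <- rep(FALSE, nrow(pos_tab))
    for (ctg in unique(pos_tab$contig[over])) {
      n <- nchar(seqs[[ctg]])
      d <- integer(n + 1L)
      po <- pos_tab$pos[over & pos_tab$contig == ctg]
      for (p in po) { d[p + 1L] <- d[p + 1L] + 1L; d[min(p + k, n) + 1L] <- d[min(p + k, n) + 1L] - 1L }
      masked <- cumsum(d[seq_len(n)]) > 0L
      cm <- c(0L, cumsum(masked))
      i <- pos_tab$contig == ctg
      q <- pos_tab$pos[i]
      touches[i] <- (cm[pmin(q + k, n) + 1L] - cm[q + 1L]) > 0L
    }
    pos_tab <- pos_tab[!touches, ]
  }
  counts <- table(pos_tab$canon)
  keep <- names(counts)[counts >= 2]
  pos_tab <- pos_tab[pos_tab$canon %in% keep, ]
  if (nrow(pos_tab) == 0) return(empty_anchors(k))
  anchors <- pos_tab %>%
    dplyr::group_by(.data$canon) %>%
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      ij <- utils::combn(n, 2)
      tibble(contig_a = d$contig[ij[1, ]], pos_a = d$pos[ij[1, ]],
             orient_a = d$orient[ij[1, ]],
             contig_b = d$contig[ij[2, ]], pos_b = d$pos[ij[2, ]],
             orient_b = d$orient[ij[2, ]])
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(strand = ifelse(.data$orient_a == .data$orient_b, "+", "-"),
                  k = as.integer(k)) %>%
    dplyr::select(-"canon", -"orient_a", -"orient_b")
  # canonical order: (contig_a, pos_a) lexicographically <= (contig_b, pos_b)
  swap <- anchors$contig_a > anchors$contig_b |
    (anchors$contig_a == anchors$contig_b & anchors$pos_a > anchors$pos_b)
  if (any(swap)) {
    tmp_c <- anchors$contig_a[swap]; tmp_p <- anchors$pos_a[swap]
    anchors$contig_a[swap] <- anchors$contig_b[swap]
    anchors$pos_a[swap] <- anchors$pos_b[swap]
    anchors$contig_b[swap] <- tmp_c
    anchors$pos_b[swap] <- tmp_p
  }
  anchors %>%
    dplyr::distinct(.data$contig_a, .data$pos_a, .data$contig_b, .data$pos_b,
                    .data$strand, .keep_all = TRUE) %>%
    dplyr::arrange(.data$contig_a, .data$contig_b, .data$strand, .data$pos_a)
}

empty_anchors <- function(k) {
  tibble(contig_a = character(), pos_a = integer(),
         contig_b = character(), pos_b = integer(),
         strand = character(), k = as.integer(k))
}

align_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                           gap_open = 4, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  matches <- Biostrings::nmatch(aln)
  list(aligned_columns = cols, matches = matches,
       identity = matches / cols)
}

#' Chain anchors and align each chain
#'
#' Groups anchors by contig pair and strand, clusters them into chains
#' whose diagonals agree within `band` bp and whose consecutive anchors
#' are at most `max_gap` bp apart, and globally aligns the two spanned
#' intervals of each chain (match +1, mismatch -1, affine gaps open -4 /
#' extend -2). Identity is computed over all alignment columns including
#' gap columns.
#'
#' @param anchors A [seed_matches()] result.
#' @param ref The same reference the anchors came from.
#' @param band Diagonal tolerance when clustering anchors in bp.
#' @param max_gap Maximum distance between consecutive chained anchors.
#' @param diag_trim After clustering, anchors farther than this from the
#'   cluster's median diagonal are discarded (indel tolerance); keeps
#'   stray same-band anchors from inflating the aligned span.
#' @param min_anchors,min_span Drop chains with fewer anchors or smaller
#'   genomic span before aligning (noise suppression).
#' @return A `pairwise_alignments` tibble: `contig_a`, `start_a`, `end_a`,
#'   `contig_b`, `start_b`, `end_b`, `strand`, `length` (min interval
#'   length), `aligned_columns`, `matches`, `identity`, `n_anchors`.
#' @export
chain_and_align <- function(anchors, ref, band = 300L, max_gap = 2000L,
                            diag_trim = 30L, min_anchors = 2L,
                            min_span = 100L) {
  seqs <- if (inherits(ref, "ref_bundle")) ref$seqs else ref
  if (nrow(anchors) == 0) return(empty_alignments())
  ksize <- anchors$k[1]
  chains <- anchors %>%
    dplyr::mutate(diag = ifelse(.data$strand == "+",
                                .data$pos_b - .data$pos_a,
                                .data$pos_a + .data$pos_b)) %>%
    dplyr::group_by(.data$contig_a, .data$contig_b, .data$strand) %>%
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$diag, d$pos_a), ]
      d$chain <- cumsum(c(1L, diff(d$diag) > band))
      d %>%
        dplyr::group_by(.data$chain) %>%
        dplyr::group_modify(function(dd, kk) {
          # trim to the dominant diagonal of the cluster
          dd <- dd[abs(dd$diag - median(dd$diag)) <= diag_trim, ]
          dd <- dd[order(dd$pos_a), ]
          dd$sub <- cumsum(c(1L, diff(dd$pos_a) > max_gap))
          dd
        }) %>%
        dplyr::ungroup()
    }) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(.data$contig_a, .data$contig_b, .data$strand,
                    .data$chain, .data$sub) %>%
    dplyr::summarise(start_a = min(.data$pos_a),
                     end_a = max(.data$pos_a) + .env$ksize,
                     start_b = min(.data$pos_b),
                     end_b = max(.data$pos_b) + .env$ksize,
                     n_anchors = dplyr::n(), .groups = "drop") %>%
    dplyr::filter(.data$n_anchors >= min_anchors,
                  pmin(.data$end_a - .data$start_a,
                       .data$end_b - .data$start_b) >= min_span)
  # self-overlapping chains (a near-diagonal match of a region with itself)
  # carry no duplication signal
  chains <- chains %>%
    dplyr::filter(!(.data$contig_a == .data$contig_b &
                      .data$start_a < .data$end_b &
                      .data$start_b < .data$end_a))
  if (nrow(chains) == 0) return(empty_alignments())
  dropped <- 0L
  out <- purrr::map_dfr(seq_len(nrow(chains)), function(i) {
    ch <- chains[i, ]
    sa <- substr(seqs[[ch$contig_a]], ch$start_a + 1L, ch$end_a)
    sb <- substr(seqs[[ch$contig_b]], ch$start_b + 1L, ch$end_b)
    if (ch$strand == "-") sb <- revcomp(sb)
    res <- tryCatch(align_identity(sa, sb), error = function(e) NULL)
    if (is.null(res)) { dropped <<- dropped + 1L; return(NULL) }
    tibble(contig_a = ch$contig_a, start_a = ch$start_a, end_a = ch$end_a,
           contig_b = ch$contig_b, start_b = ch$start_b, end_b = ch$end_b,
           strand = ch$strand,
           length = min(ch$end_a - ch$start_a, ch$end_b - ch$start_b),
           aligned_columns = res$aligned_columns, matches = res$matches,
           identity = res$identity, n_anchors = ch$n_anchors)
  })
  if (dropped > 0) warning(sprintf("%d chain(s) failed to align and were dropped",
                                   dropped))
  if (nrow(out) == 0) return(empty_alignments())
  dplyr::arrange(out, .data$contig_a, .data$start_a, .data$contig_b,
                 .data$start_b)
}

empty_alignments <- function() {
  tibble(contig_a = character(), start_a = integer(), end_a = integer(),
         contig_b = character(), start_b = integer(), end_b = integer(),
         strand = character(), length = integer(), aligned_columns = integer(),
         matches = integer(), identity = double(), n_anchors = integer())
}

#' Filter WGAC alignments by the SD definition
#'
#' Segmental duplications are stretches longer than `min_length` with
#' identity of at least `min_identity` between copies.
#'
#' @param alignments A [chain_and_align()] result.
#' @param min_length Strict lower bound on `length` in bp.
#' @param min_identity Inclusive lower bound on identity.
#' @return The filtered alignment tibble.
#' @export
filter_wgac <- function(alignments, min_length = 1000L, min_identity = 0.90) {
  alignments[alignments$length > min_length &
               alignments$identity >= min_identity, ]
}

#' Merge alignment intervals into non-overlapping SD intervals
#'
#' Takes the union of all A and B intervals of the alignments, merged
#' transitively to outermost endpoints, annotated with provenance and the
#' maximum identity observed over contributing alignments.
#'
#' @param alignments Alignment tibble.
#' @param provenance Label recorded on every merged interval.
#' @return An `sd_intervals` tibble: `contig`, `start`, `end`,
#'   `provenance` (list column of label sets), `max_identity`.
#' @export
merge_alignment_intervals <- function(alignments, provenance = "WGAC_low") {
  both <- dplyr::bind_rows(
    tibble(contig = alignments$contig_a, start = alignments$start_a,
           end = alignments$end_a, identity = alignments$identity),
    tibble(contig = alignments$contig_b, start = alignments$start_b,
           end = alignments$end_b, identity = alignments$identity))
  merge_sd_intervals(both, provenance)
}

# merge intervals carrying identity + provenance annotation
merge_sd_intervals <- function(x, provenance) {
  if (nrow(x) == 0) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  provenance = list(), max_identity = double()))
  }
  if (!"identity" %in% names(x)) x$identity <- NA_real_
  if (!"provenance" %in% names(x)) x$provenance <- list(provenance)
  merged <- merge_intervals(x)
  merged$provenance <- vector("list", nrow(merged))
  merged$max_identity <- NA_real_
  for (i in seq_len(nrow(merged))) {
    hit <- x$contig == merged$contig[i] & x$start < merged$end[i] &
      x$end > merged$start[i]
    merged$provenance[[i]] <- sort(unique(unlist(x$provenance[hit])))
    ids <- x$identity[hit]
    merged$max_identity[i] <- if (all(is.na(ids))) NA_real_ else max(ids, na.rm = TRUE)
  }
  merged
}
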