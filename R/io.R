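# File-format boundaries. FASTA/FASTQ ride through Biostrings; SAM text is
# written directly (one alignment line per placement, NH = placement
# count) and read back through Rsamtools when available. BED is 0-based
# half-open, tab-separated, extra columns appended after the first three.

#' Write sequences to FASTA
#'
#' @param x A `ref_bundle`, `donor_genome`, or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "ref_bundle")) x$seqs
          else if (inherits(x, "donor_genome")) x$genome else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads to FASTQ with dummy qualities
#'
#' @param reads A `read_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                strrep("I", nchar(reads$seq))))
  invisible(path)
}

#' Write an interval table to BED
#'
#' Coordinates are already 0-based half-open; columns after
#' `contig`, `start`, `end` are appended in order.
#'
#' @param x Interval table.
#' @param path Output path.
#' @param extra Names of additional columns to keep (default: all
#'   non-list columns).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra = NULL) {
  x <- as_tibble(x)
  keep <- c("contig", "start", "end",
            extra %||% setdiff(names(x)[!vapply(x, is.list, TRUE)],
                               c("contig", "start", "end")))
  utils::write.table(x[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED path.
#' @param col_names Names for columns beyond `contig`, `start`, `end`.
#' @return Interval tibble.
#' @export
read_bed <- function(path, col_names = NULL) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  base <- c("contig", "start", "end")
  nm <- c(base, col_names)
  if (ncol(x) > length(nm)) nm <- c(nm, paste0("V", (length(nm) + 1):ncol(x)))
  names(x) <- nm[seq_len(ncol(x))]
  as_tibble(x)
}

#' Write placements as SAM
#'
#' One alignment line per placement (multi-mapped reads appear once per
#' placement), 1-based POS per the format, NH tag carrying the read's
#' placement count. Sequence and quality are omitted (`*`) — read depth
#' uses only placement starts.
#'
#' @param placements A `placement_set`.
#' @param contigs Contig table for the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(placements, contigs, path) {
  L <- attr(placements, "read_length") %||% 100L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", contigs$contig, contigs$length), con)
  flag <- ifelse(placements$strand == "-", 16L, 0L)
  writeLines(sprintf("%s\t%d\t%s\t%d\t0\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
                     placements$read_id, flag, placements$contig,
                     placements$start + 1L, L, placements$n_hits), con)
  invisible(path)
}

#' Read placements from SAM/BAM
#'
#' Accepts every alignment line (secondary included) and converts it to a
#' placement: contig, 0-based start, strand. Requires Rsamtools.
#'
#' @param path SAM or BAM path.
#' @param read_length Read length attribute for the resulting set.
#' @return A `placement_set` tibble.
#' @export
read_sam <- function(path, read_length = 100L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading SAM requires the Rsamtools package", call. = FALSE)
  }
  bam <- if (grepl("\\.sam$", path)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  res <- tibble(read_id = b$qname, contig = as.character(b$rname),
                start = b$pos - 1L, strand = as.character(b$strand)) %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::mutate(n_hits = dplyr::n()) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(.data$contig, .data$start)
  structure(res, class = c("placement_set", class(tibble())),
            read_length = as.integer(read_length))
}

#' Write a window set to BED
#'
#' Extra columns: `n_units`, `gc`, `read_count`, `rd_corrected`.
#'
#' @param windows A `window_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path) {
  write_bed(as_tibble(windows), path,
            extra = c("n_units", "gc", "read_count", "rd_corrected"))
}

#' Write CNV calls as BED9-style records
#'
#' Name column carries the state, score the mean copy number times 100.
#'
#' @param calls A `cnv_calls` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  x <- tibble(contig = calls$contig, start = calls$start, end = calls$end,
              name = calls$state,
              score = ifelse(is.na(calls$mean_cn), 0,
                             as.integer(round(calls$mean_cn * 100))),
              strand = ".")
  write_bed(x, path)
}

#' Per-individual call summary
#'
#' Counts, total length and mean size of duplication and deletion calls
#' per individual — the per-sample summary table of a cohort run.
#'
#' @param calls A `cnv_calls` tibble.
#' @return Summary tibble.
#' @export
summarize_calls <- function(calls) {
  as_tibble(calls) %>%
    dplyr::group_by(.data$individual, .data$state) %>%
    dplyr::summarise(n = dplyr::n(),
                     total_bp = sum(.data$end - .data$start),
                     mean_bp = mean(.data$end - .data$start),
                     .groups = "drop")
}
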