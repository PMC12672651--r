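#' Load alignments from a BAM file into a flat table
#'
#' Reads the fields the pileup engine needs via [Rsamtools::scanBam()].  This
#' in-memory representation (one row per alignment record) is the working
#' currency of [filter_reads()] and [compute_pileup()]; rRNA reference spaces
#' are small enough that full materialisation is the simple, auditable choice.
#'
#' @param bam path to a BAM file (index not required).
#' @return `data.frame` with columns `qname`, `flag`, `ref_id`, `pos`,
#'   `mapq`, `cigar`, `seq` (character, as stored: DNA alphabet), `qwidth`.
#' @export
read_alignments <- function(bam) {
  if (!file.exists(bam)) dc_input_error("BAM file not found: ", bam)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "qwidth", "mapq", "cigar", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  data.frame(qname = x$qname, flag = x$flag,
             ref_id = as.character(x$rname), pos = x$pos,
             mapq = x$mapq, cigar = x$cigar,
             seq = as.character(x$seq), qwidth = x$qwidth,
             stringsAsFactors = FALSE)
}

#' Read-level filter settings
#'
#' Encodes the read selection applied before pileup: keep primary, mapped
#' alignments with adequate mapping quality whose basecalled read length falls
#' inside the per-rRNA window (inclusive bounds; 2000-3300 nt for 26S and
#' 1700-2000 nt for 18S by default, selecting near-full-length molecules).
#'
#' @param length_window named list `ref_id -> c(min, max)`.
#' @param primary_only drop secondary/supplementary alignments (default TRUE).
#' @param min_mapping_quality minimum MAPQ (default 1).
#' @return list of class `read_filter`.
#' @export
read_filter <- function(length_window = list(`18S` = c(1700, 2000),
                                             `26S` = c(2000, 3300)),
                        primary_only = TRUE, min_mapping_quality = 1L) {
  for (w in length_window)
    if (length(w) != 2L || w[1] > w[2])
      dc_input_error("length_window entries must be c(min, max) with min <= max")
  structure(list(length_window = length_window, primary_only = primary_only,
                 min_mapping_quality = min_mapping_quality),
            class = "read_filter")
}

#' Filter aligned reads before pileup
#'
#' Criteria are applied in order (unmapped/secondary, mapping quality, length
#' window); a read is attributed to the first criterion that removes it.  The
#' length test is inclusive on both bounds, so an 18S read of 1700 nt is
#' retained and one of 1699 nt is removed.
#'
#' @param alignments `data.frame` from [read_alignments()] (or a BAM path).
#' @param filter a [read_filter()].
#' @return list with `alignments` (retained rows) and `report`, a
#'   `data.frame` of per-criterion removal counts plus input/retained totals.
#' @export
filter_reads <- function(alignments, filter = read_filter()) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  stopifnot(inherits(filter, "read_filter"))
  aln <- alignments
  n_input <- nrow(aln)
  unknown <- setdiff(unique(aln$ref_id), names(filter$length_window))
  if (length(unknown) > 0L)
    dc_input_error("no length window configured for reference(s): ",
                   paste(unknown, collapse = ", "))

  bad_flag <- bitwAnd(aln$flag, 4L) > 0L
  if (isTRUE(filter$primary_only))
    bad_flag <- bad_flag | bitwAnd(aln$flag, 256L) > 0L |
      bitwAnd(aln$flag, 2048L) > 0L
  aln1 <- aln[!bad_flag, , drop = FALSE]

  bad_mapq <- is.na(aln1$mapq) | aln1$mapq < filter$min_mapping_quality
  aln2 <- aln1[!bad_mapq, , drop = FALSE]

  if (nrow(aln2) > 0L) {
    win <- do.call(rbind, filter$length_window[aln2$ref_id])
    bad_len <- aln2$qwidth < win[, 1] | aln2$qwidth > win[, 2]
  } else bad_len <- logical(0)
  aln3 <- aln2[!bad_len, , drop = FALSE]

  report <- data.frame(
    criterion = c("input", "flag", "mapq", "length", "retained"),
    n = c(n_input, sum(bad_flag), sum(bad_mapq), sum(bad_len), nrow(aln3)),
    stringsAsFactors = FALSE)
  list(alignments = aln3, report = report)
}
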