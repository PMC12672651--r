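#' Compute per-position base-composition columns from alignments
#'
#' Walks each alignment's CIGAR against the reference and tallies, for every
#' reference position, the four possible basecalls plus deletions.  The
#' conventions match the four-call base-composition model used for
#' native-vs-IVT comparison:
#' \itemize{
#'   \item `M`/`=`/`X` contribute a basecall (`T` normalised to `U`);
#'   \item `D` contributes to `nDel` and to `depth` (a read spanning a
#'     position through a deletion still overlaps it);
#'   \item `I` and `S` consume read bases only and are ignored (an insertion
#'     has no reference position);
#'   \item `N` consumes reference without contributing depth.
#' }
#' Every reference position yields a column, including zero-depth ones, so the
#' column count always equals the reference length.
#'
#' @param alignments `data.frame` from [read_alignments()] / [filter_reads()],
#'   or a BAM path.
#' @param ref an [rna_reference()]; must match the alignments' reference name
#'   and length.
#' @return Pileup `data.frame` (`ref_id`, `position`, `ref_base`, `nA`, `nC`,
#'   `nG`, `nU`, `nDel`, `depth`) with one row per reference position and
#'   `depth == nA+nC+nG+nU+nDel`.
#' @export
compute_pileup <- function(alignments, ref) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  stopifnot(inherits(ref, "rna_reference"))
  aln <- alignments[alignments$ref_id == ref$ref_id & !is.na(alignments$pos), ,
                    drop = FALSE]
  L <- ref$length
  # call codes 1..4 = A,C,G,U; 5 = deletion
  acc <- integer(5L * L)
  for (i in seq_len(nrow(aln))) {
    ops <- parse_cigar(aln$cigar[i])
    rp <- aln$pos[i]              # next reference position
    qp <- 1L                      # next read base
    bases <- chartr("T", "U", strsplit(aln$seq[i], "")[[1]])
    for (j in seq_len(nrow(ops))) {
      n <- ops$len[j]
      op <- ops$op[j]
      if (op %in% c("M", "=", "X")) {
        pos <- rp:(rp + n - 1L)
        if (pos[n] > L)
          dc_input_error("alignment exceeds reference '", ref$ref_id,
                         "' length ", L)
        code <- match(bases[qp:(qp + n - 1L)], RNA_BASES)
        ok <- !is.na(code)        # non-ACGU calls (e.g. N) carry no count
        idx <- pos[ok] + L * (code[ok] - 1L)
        acc[idx] <- acc[idx] + 1L
        rp <- rp + n; qp <- qp + n
      } else if (op == "D") {
        pos <- rp:(rp + n - 1L)
        if (pos[n] > L)
          dc_input_error("alignment exceeds reference '", ref$ref_id,
                         "' length ", L)
        acc[pos + 4L * L] <- acc[pos + 4L * L] + 1L
        rp <- rp + n
      } else if (op %in% c("I", "S")) {
        qp <- qp + n
      } else if (op == "N") {
        rp <- rp + n
      } else if (op != "H" && op != "P") {
        dc_input_error("unsupported CIGAR op '", op, "'")
      }
    }
  }
  m <- matrix(acc, nrow = L, ncol = 5)
  data.frame(ref_id = ref$ref_id, position = seq_len(L),
             ref_base = ref_bases(ref),
             nA = m[, 1], nC = m[, 2], nG = m[, 3], nU = m[, 4],
             nDel = m[, 5], depth = as.integer(rowSums(m)),
             stringsAsFactors = FALSE)
}

#' Parse a CIGAR string into op/length pairs
#' @noRd
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(data.frame(len = integer(),
                                                      op = character()))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops))
    dc_input_error("malformed CIGAR: ", cigar)
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

PILEUP_COLS <- c("ref_id", "position", "ref_base",
                 "nA", "nC", "nG", "nU", "nDel", "depth")

#' Write / read pileup columns as TSV
#'
#' Plain nine-column TSV (`ref_id`, `position`, `ref_base`, `nA`, `nC`, `nG`,
#' `nU`, `nDel`, `depth`) so every downstream stage can be re-run from disk.
#'
#' @param pileup pileup `data.frame`.
#' @param path file path.
#' @return `path` (write) or the pileup `data.frame` (read).
#' @export
write_pileup_tsv <- function(pileup, path) {
  write.table(pileup[, PILEUP_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  if (!file.exists(path)) dc_input_error("pileup TSV not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(PILEUP_COLS, names(x))
  if (length(missing) > 0L)
    dc_input_error("pileup TSV ", path, " lacks columns: ",
                   paste(missing, collapse = ", "))
  x
}
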