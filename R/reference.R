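#' Construct an rRNA reference
#'
#' A reference is one rRNA sequence over the RNA alphabet `{A,C,G,U}` with an
#' identifier used as the SAM/BAM reference name (e.g. `"18S"`, `"26S"`).
#' `T` is normalised to `U` on construction so DNA-alphabet FASTA input is
#' accepted transparently.
#'
#' @param ref_id single character label.
#' @param sequence single character string over `{A,C,G,U,T}` (case
#'   insensitive).
#' @return An object of class `rna_reference`: a list with elements `ref_id`,
#'   `sequence` (uppercase RNA alphabet) and `length`.
#' @examples
#' rna_reference("toy", "ACGUU")
#' @export
rna_reference <- function(ref_id, sequence) {
  if (!is.character(ref_id) || length(ref_id) != 1L || !nzchar(ref_id))
    dc_input_error("ref_id must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L)
    dc_input_error("sequence must be a single character string")
  seq <- chartr("T", "U", toupper(sequence))
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), RNA_BASES)
  if (length(bad) > 0L)
    dc_input_error("reference '", ref_id, "' contains non-ACGU characters: ",
                   paste(bad, collapse = ","))
  if (nchar(seq) < 1L)
    dc_input_error("reference '", ref_id, "' is empty")
  structure(list(ref_id = ref_id, sequence = seq, length = nchar(seq)),
            class = "rna_reference")
}

#' @export
print.rna_reference <- function(x, ...) {
  cat(sprintf("<rna_reference> %s (%d nt)\n", x$ref_id, x$length))
  invisible(x)
}

#' Per-position base vector of a reference
#' @noRd
ref_bases <- function(ref) strsplit(ref$sequence, "")[[1]]

#' Generate a random rRNA reference sequence
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_fraction/2` and
#' `P(A) = P(U) = (1 - gc_fraction)/2`.  Reproducible for a fixed seed.
#'
#' @param ref_id reference label.
#' @param length sequence length in nt (positive integer).
#' @param gc_fraction target G+C fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return An [rna_reference()].
#' @examples
#' make_reference("18S", 100, gc_fraction = 0.5, seed = 1)
#' @export
make_reference <- function(ref_id, length, gc_fraction = 0.5, seed = 1L) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) || length < 1)
    dc_input_error("length must be a positive integer")
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1)
    dc_input_error("gc_fraction must lie in [0, 1]")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, U = (1 - gc_fraction) / 2)
  bases <- with_seed(derive_seed(seed, ref_id, "reference"), {
    sample(RNA_BASES, size = as.integer(length), replace = TRUE, prob = p)
  })
  rna_reference(ref_id, paste(bases, collapse = ""))
}

#' Read rRNA references from a FASTA file
#'
#' Accepts RNA or DNA alphabet; `T` is normalised to `U`.
#'
#' @param path FASTA file path.
#' @return Named list of [rna_reference()] objects keyed by `ref_id`.
#' @export
read_rna_fasta <- function(path) {
  if (!file.exists(path))
    dc_input_error("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  refs <- lapply(seq_along(ss), function(i)
    rna_reference(names(ss)[i], as.character(ss[[i]])))
  setNames(refs, vapply(refs, `[[`, character(1), "ref_id"))
}

#' Write rRNA references to a FASTA file
#'
#' @param refs one [rna_reference()] or a list of them.
#' @param path output path.
#' @param alphabet `"RNA"` (default) writes `U`; `"DNA"` writes `T` (what
#'   most aligners expect).
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(refs, path, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (inherits(refs, "rna_reference")) refs <- list(refs)
  seqs <- vapply(refs, `[[`, character(1), "sequence")
  if (alphabet == "DNA") seqs <- chartr("U", "T", seqs)
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- vapply(refs, `[[`, character(1), "ref_id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
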