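#' Simulation configuration
#'
#' Parameters of the synthetic DRS read/pileup generator.  Defaults encode
#' the background statistics the detection assumes: a 2.9% average background
#' miscall level, 1% background deletions, full-length (1700-2000 nt for 18S,
#' 2000-3300 nt for 26S) read-length windows, and near-full-length 3'-anchored
#' reads.
#'
#' @param background_miscall per-read probability of a non-reference basecall
#'   at an unmodified position (default 0.029).  This is the level the
#'   per-position "highest non-reference base" estimator recovers, because of
#'   how `background_skew` distributes the mass.
#' @param background_skew share of the background miscall mass carried by the
#'   position's dominant background-miscall base (default 1: all of it).
#'   Each position is assigned one dominant miscall base (seeded, identical
#'   in the native and IVT samples, as context-driven miscalls are); the
#'   remaining mass is split evenly over the other two non-reference bases.
#'   `1/3` gives a uniform split -- under which the max-base error estimator
#'   reads about a third of the configured rate, not the rate itself.
#' @param background_deletion per-read deletion probability at an unmodified
#'   position (default 0.01).
#' @param depth reads simulated per reference.
#' @param length_window named list, `ref_id -> c(min, max)` read-length window
#'   in nt (defaults cover the 18S/26S conventions).
#' @param truncation_rate per-base geometric stop probability for 3'-anchored
#'   reads; 0 means every read is full length.  Default 1e-4 keeps most reads
#'   near full length, mirroring a length-filtered DRS library.
#' @param stoichiometry fraction of native reads carrying the modification at
#'   a planted site (default 1: every molecule modified).
#' @param seed integer master seed; all sub-streams are derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(background_miscall = 0.029, background_skew = 1,
                       background_deletion = 0.01, depth = 1000L,
                       length_window = list(`18S` = c(1700, 2000),
                                            `26S` = c(2000, 3300)),
                       truncation_rate = 1e-4, stoichiometry = 1,
                       seed = 1L) {
  if (background_skew < 1 / 3 || background_skew > 1)
    dc_input_error("background_skew must lie in [1/3, 1]")
  rates <- c(background_miscall = background_miscall,
             background_deletion = background_deletion,
             truncation_rate = truncation_rate, stoichiometry = stoichiometry)
  if (any(rates < 0) || any(rates > 1))
    dc_input_error("all rates must lie in [0, 1]")
  if (depth < 0) dc_input_error("depth must be >= 0")
  for (w in length_window)
    if (length(w) != 2L || w[1] > w[2])
      dc_input_error("length_window entries must be c(min, max) with min <= max")
  structure(list(background_miscall = background_miscall,
                 background_skew = background_skew,
                 background_deletion = background_deletion,
                 depth = as.integer(depth), length_window = length_window,
                 truncation_rate = truncation_rate,
                 stoichiometry = stoichiometry, seed = as.integer(seed)),
            class = "sim_config")
}

#' Per-position emission model
#'
#' Builds, for every reference position, the deletion probability and the
#' 4-way basecall probability vector implied by the truth set, sample kind and
#' config.  IVT ignores the truth set entirely (an in vitro transcript is
#' unmodified by construction).  At a planted site in the native sample the
#' non-reference mass is `stoichiometry * native_error_rate +
#' (1 - stoichiometry) * background_miscall`, distributed by the
#' correspondingly mixed skew.
#' @return list(del = numeric(L), prob = L x 4 matrix over A,C,G,U)
#' @noRd
emission_model <- function(ref, truth, cfg, sample_kind) {
  L <- ref$length
  bases <- ref_bases(ref)
  ridx <- match(bases, RNA_BASES)
  bg <- cfg$background_miscall
  # per-position dominant background-miscall base: drawn from its own seeded
  # stream so native and IVT share it (miscalls are sequence-context driven)
  # and neither sample's output depends on the truth set
  dom_off <- with_seed(derive_seed(cfg$seed, ref$ref_id, "background"),
                       sample.int(3L, L, replace = TRUE))
  dom_idx <- (ridx - 1L + dom_off) %% 4L + 1L   # offset 1..3: never the ref
  bg_skew <- matrix((1 - cfg$background_skew) / 2, nrow = L, ncol = 4)
  bg_skew[cbind(seq_len(L), dom_idx)] <- cfg$background_skew
  bg_skew[cbind(seq_len(L), ridx)] <- 0
  bg_skew <- bg_skew / rowSums(bg_skew)
  prob <- bg * bg_skew
  colnames(prob) <- RNA_BASES
  prob[cbind(seq_len(L), ridx)] <- 1 - bg
  del <- rep(cfg$background_deletion, L)

  if (sample_kind == "native" && !is.null(truth) && nrow(truth) > 0) {
    tr <- truth[truth$ref_id == ref$ref_id, , drop = FALSE]
    if (any(tr$position < 1 | tr$position > L))
      dc_input_error("truth position outside reference '", ref$ref_id, "'")
    if (any(bases[tr$position] != tr$ref_base))
      dc_input_error("truth ref_base does not match reference '", ref$ref_id, "'")
    s <- cfg$stoichiometry
    for (i in seq_len(nrow(tr))) {
      p <- tr$position[i]
      e_mod <- tr$native_error_rate[i]
      skew <- as.numeric(tr[i, paste0("skew_", RNA_BASES)])
      e_eff <- s * e_mod + (1 - s) * bg
      # unmodified molecules at the site keep the background miscall profile
      mass <- s * e_mod * skew + (1 - s) * bg * bg_skew[p, ]
      row <- if (e_eff > 0) mass else rep(0, 4)
      row[ridx[p]] <- 1 - e_eff
      prob[p, ] <- row
      del[p] <- s * tr$deletion_rate[i] + (1 - s) * cfg$background_deletion
    }
  }
  list(del = del, prob = prob)
}

#' Simulate per-position pileup columns directly
#'
#' Column-level counterpart of [simulate_reads()]: every position is covered
#' by exactly `cfg$depth` reads; each covering read independently emits a
#' deletion (per-site rate) or a basecall drawn from the site's emission
#' distribution.  This is the idealised generator behind the native-vs-IVT
#' stacked base-composition columns; read-length structure (3' anchoring,
#' truncation) lives only in [simulate_reads()].
#'
#' @param ref an [rna_reference()].
#' @param truth truth `data.frame` from [plant_modifications()]; ignored when
#'   `sample_kind = "ivt"`.
#' @param cfg a [sim_config()].
#' @param sample_kind `"native"` or `"ivt"`.
#' @return Pileup `data.frame`: `ref_id`, `position`, `ref_base`, `nA`, `nC`,
#'   `nG`, `nU`, `nDel`, `depth`, with `nA+nC+nG+nU+nDel == depth` per row.
#' @examples
#' ref <- make_reference("18S", 50, seed = 1)
#' truth <- plant_modifications(ref, 2, seed = 1)
#' pu <- simulate_pileup(ref, truth, sim_config(depth = 100), "native")
#' @export
simulate_pileup <- function(ref, truth, cfg, sample_kind = c("native", "ivt")) {
  sample_kind <- match.arg(sample_kind)
  stopifnot(inherits(ref, "rna_reference"), inherits(cfg, "sim_config"))
  em <- emission_model(ref, truth, cfg, sample_kind)
  L <- ref$length
  n <- cfg$depth
  counts <- with_seed(derive_seed(cfg$seed, ref$ref_id, sample_kind, "pileup"), {
    ndel <- rbinom(L, n, em$del)
    m <- matrix(0L, nrow = L, ncol = 4)
    for (p in seq_len(L)) {
      if (n - ndel[p] > 0)
        m[p, ] <- as.integer(rmultinom(1, n - ndel[p], em$prob[p, ]))
    }
    cbind(m, ndel)
  })
  data.frame(ref_id = ref$ref_id, position = seq_len(L),
             ref_base = ref_bases(ref),
             nA = counts[, 1], nC = counts[, 2], nG = counts[, 3],
             nU = counts[, 4], nDel = counts[, 5],
             depth = as.integer(rowSums(counts)), stringsAsFactors = FALSE)
}

#' Simulate an aligned DRS read set (sorted BAM + truth BED)
#'
#' Reads are 3'-anchored: each read ends at the reference 3' end and extends
#' toward the 5' end, stopping per base with probability
#' `cfg$truncation_rate` (DRS threads RNA through the pore 3'->5', so
#' truncations lose the 5' end).  Substitutions and deletions follow the same
#' per-site emission model as [simulate_pileup()]; insertions are not
#' simulated.  Output is a coordinate-sorted, indexed BAM (sequence written in
#' DNA alphabet, as aligners emit) plus the planted truth as 0-based
#' half-open BED.
#'
#' @inheritParams simulate_pileup
#' @param out_prefix path prefix; writes `<out_prefix>.bam` (+ `.bai`) and
#'   `<out_prefix>.truth.bed`.
#' @return list with elements `bam`, `bed`, `n_reads`.
#' @export
simulate_reads <- function(ref, truth, cfg, sample_kind = c("native", "ivt"),
                           out_prefix) {
  sample_kind <- match.arg(sample_kind)
  stopifnot(inherits(ref, "rna_reference"), inherits(cfg, "sim_config"))
  if (missing(out_prefix) || !nzchar(out_prefix))
    dc_input_error("out_prefix is required")
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  em <- emission_model(ref, truth, cfg, sample_kind)
  L <- ref$length
  cum <- t(apply(em$prob, 1, cumsum))

  recs <- with_seed(derive_seed(cfg$seed, ref$ref_id, sample_kind, "reads"), {
    out <- vector("list", cfg$depth)
    for (i in seq_len(cfg$depth)) {
      len <- if (cfg$truncation_rate <= 0) L else
        min(L, 1L + rgeom(1, cfg$truncation_rate))
      start <- L - len + 1L
      pos <- start:L
      deleted <- runif(len) < em$del[pos]
      # alignments cannot begin or end in a deletion: trim D runs at the edges
      keep <- which(!deleted)
      if (length(keep) == 0L) { deleted[length(deleted)] <- FALSE; keep <- len }
      first <- keep[1]; last <- keep[length(keep)]
      pos <- pos[first:last]; deleted <- deleted[first:last]
      start <- pos[1]
      u <- runif(length(pos))
      bidx <- rowSums(u > cum[pos, , drop = FALSE]) + 1L
      calls <- RNA_BASES[bidx]
      seq <- paste(chartr("U", "T", calls[!deleted]), collapse = "")
      r <- rle(deleted)
      cigar <- paste0(r$lengths, ifelse(r$values, "D", "M"), collapse = "")
      out[[i]] <- c(sprintf("read_%05d", i), "0", ref$ref_id,
                    as.character(start), "60", cigar, "*", "0", "0",
                    seq, strrep("I", nchar(seq)))
    }
    out
  })

  sam <- paste0(out_prefix, ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$ref_id, L))
  body <- vapply(recs, paste, character(1), collapse = "\t")
  writeLines(c(hdr, body), sam)
  bam <- tryCatch(
    Rsamtools::asBam(sam, destination = out_prefix, overwrite = TRUE,
                     indexDestination = TRUE),
    error = function(e) dc_input_error("failed to write BAM at ", out_prefix,
                                       ".bam: ", conditionMessage(e)))
  unlink(sam)
  bed <- paste0(out_prefix, ".truth.bed")
  tr_out <- if (sample_kind == "native" && !is.null(truth)) truth else
    data.frame(ref_id = character(), position = integer(),
               mod_type = character(), native_error_rate = numeric())
  write_truth_bed(tr_out, bed)
  list(bam = bam, bed = bed, n_reads = cfg$depth)
}
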