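#' Plant a modification truth set on a reference
#'
#' Draws `n_sites` unique positions and assigns each a modification identity
#' and a native-sample miscall model.  Pseudouridine (label `"psi"`) sites are
#' drawn only where the reference base is `U` and receive a miscall skew
#' concentrated on `C` (the characteristic DRS U-to-C signature); every other
#' site receives a skew concentrated on one randomly chosen non-reference
#' base and the unassigned label `"?"`.  One dominant miscalled base per site
#' is what modified positions show in real DRS base-composition data, and it
#' is what makes a site with miscall rate `r` measure about
#' `dominant_skew * r` under the highest-non-reference-base error statistic
#' (a symmetric skew would measure only `r/3`, hiding 25-30% sites below a
#' 10% threshold).
#'
#' @param ref an [rna_reference()].
#' @param n_sites number of sites to plant.
#' @param psi_fraction fraction of sites that are pseudouridines; the count is
#'   `round(psi_fraction * n_sites)`.
#' @param native_error_rate per-read probability of a non-reference basecall
#'   at a modified position in the native sample (single value or vector of
#'   length `n_sites`).
#' @param seed integer seed.
#' @param c_skew for psi sites, the share of miscall mass on `C`
#'   (default 0.9); the remainder is split evenly over the other two
#'   non-reference bases.
#' @param dominant_skew for non-psi sites, the share of miscall mass on the
#'   site's (randomly drawn) dominant miscall base (default 0.9).
#' @param deletion_rate per-read deletion probability at modified positions in
#'   the native sample (default 0.01, same as typical background).
#' @return A `data.frame` with one row per site: `ref_id`, `position`
#'   (1-based), `ref_base`, `mod_type` (`"psi"` or `"?"`),
#'   `native_error_rate`, `deletion_rate`, and miscall-skew columns `skew_A`,
#'   `skew_C`, `skew_G`, `skew_U` (zero on the reference base, summing to 1).
#'   Sorted by position.
#' @examples
#' ref <- make_reference("18S", 200, seed = 1)
#' plant_modifications(ref, n_sites = 5, psi_fraction = 0.4, seed = 2)
#' @export
plant_modifications <- function(ref, n_sites, psi_fraction = 0.5,
                                native_error_rate = 0.3, seed = 1L,
                                c_skew = 0.9, dominant_skew = 0.9,
                                deletion_rate = 0.01) {
  stopifnot(inherits(ref, "rna_reference"))
  if (!is.numeric(n_sites) || n_sites < 0 || n_sites != round(n_sites))
    dc_input_error("n_sites must be a non-negative integer")
  if (psi_fraction < 0 || psi_fraction > 1)
    dc_input_error("psi_fraction must lie in [0, 1]")
  if (any(native_error_rate < 0) || any(native_error_rate > 1))
    dc_input_error("native_error_rate must lie in [0, 1]")
  n_sites <- as.integer(n_sites)
  bases <- ref_bases(ref)
  n_psi <- as.integer(round(psi_fraction * n_sites))
  u_pos <- which(bases == "U")
  if (n_psi > length(u_pos))
    dc_input_error("reference '", ref$ref_id, "' has only ", length(u_pos),
                   " U positions; cannot plant ", n_psi, " psi sites")
  if (n_sites > ref$length)
    dc_input_error("n_sites exceeds reference length")

  drawn <- with_seed(derive_seed(seed, ref$ref_id, "truth"), {
    psi_pos <- if (n_psi > 0) sample(u_pos, n_psi) else integer()
    other_pool <- setdiff(seq_len(ref$length), psi_pos)
    n_other <- n_sites - n_psi
    if (n_other > length(other_pool))
      dc_input_error("not enough positions left for ", n_other, " non-psi sites")
    other_pos <- if (n_other > 0) sample(other_pool, n_other) else integer()
    list(psi = psi_pos, other = other_pos,
         dom = sample.int(3L, n_other, replace = TRUE))
  })

  position <- c(drawn$psi, drawn$other)
  mod_type <- c(rep("psi", length(drawn$psi)), rep("?", length(drawn$other)))
  dom_pick <- c(rep(NA_integer_, length(drawn$psi)), drawn$dom)
  rate <- rep_len(native_error_rate, n_sites)
  skew <- matrix(0, nrow = n_sites, ncol = 4,
                 dimnames = list(NULL, paste0("skew_", RNA_BASES)))
  rb <- bases[position]
  for (i in seq_len(n_sites)) {
    nonref <- setdiff(RNA_BASES, rb[i])
    if (mod_type[i] == "psi") {
      s <- setNames(rep((1 - c_skew) / 2, 3), nonref)
      s["C"] <- c_skew
    } else {
      s <- setNames(rep((1 - dominant_skew) / 2, 3), nonref)
      s[nonref[dom_pick[i]]] <- dominant_skew
    }
    skew[i, paste0("skew_", nonref)] <- s[nonref]
  }
  out <- data.frame(ref_id = rep(ref$ref_id, n_sites), position = position,
                    ref_base = rb, mod_type = mod_type,
                    native_error_rate = rate,
                    deletion_rate = rep_len(deletion_rate, n_sites),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(skew))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a truth set as BED
#'
#' BED uses 0-based half-open coordinates; internal positions are 1-based
#' inclusive, so a site at position `p` becomes the interval `[p-1, p)`.
#' The BED name field carries the modification label and the score field the
#' native error rate in percent (rounded to an integer as BED scores are
#' integral 0-1000).
#'
#' @param truth truth `data.frame` from [plant_modifications()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  bed <- data.frame(chrom = truth$ref_id,
                    start = truth$position - 1L,
                    end = truth$position,
                    name = truth$mod_type,
                    score = as.integer(round(truth$native_error_rate * 100)),
                    strand = rep("+", nrow(truth)))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a truth BED back into 1-based positions
#'
#' @param path BED path written by [write_truth_bed()].
#' @return `data.frame` with `ref_id`, `position` (1-based), `mod_type`,
#'   `score`.
#' @export
read_truth_bed <- function(path) {
  if (!file.exists(path)) dc_input_error("BED file not found: ", path)
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) dc_input_error("malformed BED (need >= 4 columns): ", path)
  if (any(bed[[3]] - bed[[2]] != 1L))
    dc_input_error("truth BED intervals must be single positions: ", path)
  data.frame(ref_id = as.character(bed[[1]]), position = bed[[3]],
             mod_type = as.character(bed[[4]]),
             score = if (ncol(bed) >= 5) bed[[5]] else NA_integer_,
             stringsAsFactors = FALSE)
}
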