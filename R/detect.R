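#' Detection configuration
#'
#' @param threshold_pct call threshold on delta call error, percent
#'   (default 10, roughly three times the 2.9% average background miscall
#'   level; the comparison is strict, so exactly 10.0 is not called).
#' @param min_depth minimum basecall depth required in *both* samples for a
#'   position to be callable (default 50; the binomial SE of a 10% estimate at
#'   n = 50 is about 4%, acceptable for a screen).
#' @param neighbor_window distance (nt) within which a sub-threshold position
#'   can be flagged as a neighbour effect of a supported site (default 1).
#' @param neighbor_floor_pct minimum delta for a neighbour flag (default 5,
#'   keeping plain noise unflagged); must not exceed `threshold_pct`.
#' @param psi_dominance minimum share of non-reference basecalls that must be
#'   `C` for a pseudouridine signature (default 0.5).
#' @return list of class `detect_config`.
#' @export
detect_config <- function(threshold_pct = 10, min_depth = 50L,
                          neighbor_window = 1L, neighbor_floor_pct = 5,
                          psi_dominance = 0.5) {
  if (neighbor_floor_pct < 0 || neighbor_floor_pct > threshold_pct)
    dc_input_error("need 0 <= neighbor_floor_pct <= threshold_pct")
  if (min_depth < 0 || neighbor_window < 0)
    dc_input_error("min_depth and neighbor_window must be >= 0")
  if (psi_dominance < 0 || psi_dominance > 1)
    dc_input_error("psi_dominance must lie in [0, 1]")
  structure(list(threshold_pct = threshold_pct,
                 min_depth = as.integer(min_depth),
                 neighbor_window = as.integer(neighbor_window),
                 neighbor_floor_pct = neighbor_floor_pct,
                 psi_dominance = psi_dominance),
            class = "detect_config")
}

#' Per-position basecalling error profile
#'
#' The error of a position is the percentage of basecalls on the single most
#' frequent non-reference base -- not the total mismatch rate.  Deletions are
#' excluded from both numerator and denominator (`basecall_depth` counts
#' basecalls only); a zero-basecall position has error 0 and no dominant base.
#' Ties between non-reference bases are broken in the fixed order
#' `A < C < G < U` and flagged.
#'
#' @param pileup pileup `data.frame` (see [compute_pileup()]).
#' @return `data.frame`: `ref_id`, `position`, `ref_base`, `error_pct`,
#'   `dominant_nonref` (`NA` if none), `tie_flag`, `basecall_depth`.
#' @examples
#' pu <- data.frame(ref_id = "x", position = 1, ref_base = "A",
#'                  nA = 95, nC = 5, nG = 0, nU = 0, nDel = 0, depth = 100)
#' base_error(pu)
#' @export
base_error <- function(pileup) {
  m <- as.matrix(pileup[, c("nA", "nC", "nG", "nU")])
  colnames(m) <- RNA_BASES
  bdepth <- rowSums(m)
  nonref <- m
  nonref[cbind(seq_len(nrow(m)), match(pileup$ref_base, RNA_BASES))] <- -1L
  maxc <- apply(nonref, 1, max)
  maxc[maxc < 0] <- 0            # degenerate: all mass on the reference base
  err <- ifelse(bdepth > 0, 100 * maxc / bdepth, 0)
  dom <- RNA_BASES[apply(nonref, 1, which.max)]
  dom[maxc == 0] <- NA_character_
  tie <- maxc > 0 & rowSums(nonref == maxc) > 1L
  data.frame(ref_id = pileup$ref_id, position = pileup$position,
             ref_base = pileup$ref_base, error_pct = err,
             dominant_nonref = dom, tie_flag = tie,
             basecall_depth = as.integer(bdepth), stringsAsFactors = FALSE)
}

#' Delta call error between native and IVT error profiles
#'
#' `delta_pct = error_native_pct - error_ivt_pct`, computed position-wise;
#' negative values are preserved (informative for QC, never callable).  The
#' native and IVT dominant bases are taken independently -- the identity of
#' the highest non-reference base need not match between samples.
#'
#' @param native,ivt error-profile `data.frame`s from [base_error()] over the
#'   same reference positions.
#' @return `data.frame`: `ref_id`, `position`, `ref_base`,
#'   `error_native_pct`, `error_ivt_pct`, `delta_pct`, `depth_native`,
#'   `depth_ivt`, `dominant_native`, `dominant_ivt`, `tie_native`.
#' @export
delta_call_error <- function(native, ivt) {
  if (nrow(native) != nrow(ivt) ||
      any(native$position != ivt$position) ||
      any(native$ref_id != ivt$ref_id))
    stop("native and IVT profiles must cover identical positions")
  data.frame(ref_id = native$ref_id, position = native$position,
             ref_base = native$ref_base,
             error_native_pct = native$error_pct,
             error_ivt_pct = ivt$error_pct,
             delta_pct = native$error_pct - ivt$error_pct,
             depth_native = native$basecall_depth,
             depth_ivt = ivt$basecall_depth,
             dominant_native = native$dominant_nonref,
             dominant_ivt = ivt$dominant_nonref,
             tie_native = native$tie_flag, stringsAsFactors = FALSE)
}

#' Average background miscall level from the IVT sample
#'
#' Depth-weighted mean of the per-position error over IVT positions with
#' adequate basecall depth.  On an unmodified transcript this estimates the
#' platform's background miscalling level (about 2.9% for the DRS chemistry
#' the defaults assume), which motivates the 10% call threshold (roughly
#' three times background).
#'
#' @param ivt_profile error-profile `data.frame` from [base_error()] on the
#'   IVT sample.
#' @param min_depth minimum basecall depth for a position to contribute.
#' @return single numeric, percent.
#' @export
background_error <- function(ivt_profile, min_depth = 50L) {
  if (nrow(ivt_profile) == 0L) dc_input_error("empty IVT profile")
  keep <- ivt_profile$basecall_depth >= min_depth
  if (!any(keep))
    dc_input_error("no IVT positions reach min_depth = ", min_depth)
  weighted.mean(ivt_profile$error_pct[keep],
                ivt_profile$basecall_depth[keep])
}

#' Threshold delta call errors into candidate modification calls
#'
#' A position is called iff `delta_pct` strictly exceeds the threshold and
#' both samples reach `min_depth` basecalls; positions failing the depth
#' requirement carry `excluded_reason = "low_depth"` and are never called,
#' whatever their delta.
#'
#' @param deltas `data.frame` from [delta_call_error()].
#' @param cfg a [detect_config()].
#' @return `deltas` with added columns `called`, `excluded_reason`, and
#'   placeholders `signature` (`NA`, see [classify_signature()]) and
#'   `neighbor_flag` (`FALSE`, see [flag_neighbors()]).
#' @export
call_modifications <- function(deltas, cfg = detect_config()) {
  stopifnot(inherits(cfg, "detect_config"))
  low <- deltas$depth_native < cfg$min_depth | deltas$depth_ivt < cfg$min_depth
  out <- deltas
  out$called <- deltas$delta_pct > cfg$threshold_pct & !low
  out$excluded_reason <- ifelse(low, "low_depth", NA_character_)
  out$signature <- NA_character_
  out$neighbor_flag <- FALSE
  out
}

#' Classify called positions by miscall signature
#'
#' A called position is a pseudouridine candidate (`"psi"`) iff the reference
#' base is `U`, the dominant non-reference basecall in the native sample is
#' `C`, and `C` holds at least `psi_dominance` of all non-reference basecalls
#' there -- pseudouridines are mostly read as cytidines in DRS.  Every other
#' called position gets the unassigned signature `"?"`; uncalled positions
#' keep `NA`.
#'
#' @param calls `data.frame` from [call_modifications()].
#' @param native_pileup native pileup `data.frame` covering the same
#'   positions.
#' @param cfg a [detect_config()].
#' @return `calls` with the `signature` column filled in.
#' @export
classify_signature <- function(calls, native_pileup, cfg = detect_config()) {
  idx <- match(paste(calls$ref_id, calls$position),
               paste(native_pileup$ref_id, native_pileup$position))
  if (anyNA(idx[calls$called]))
    stop("native pileup does not cover all called positions")
  m <- as.matrix(native_pileup[, c("nA", "nC", "nG", "nU")])
  colnames(m) <- RNA_BASES
  out <- calls
  for (i in which(calls$called)) {
    row <- m[idx[i], ]
    nonref_total <- sum(row) - row[calls$ref_base[i]]
    c_share <- if (nonref_total > 0) row["C"] / nonref_total else 0
    is_psi <- calls$ref_base[i] == "U" &&
      identical(calls$dominant_native[i], "C") &&
      c_share >= cfg$psi_dominance
    out$signature[i] <- if (is_psi) "psi" else "?"
  }
  out
}

#' Flag sub-threshold neighbours of supported positions
#'
#' Elevated-but-sub-threshold error flanking a modified residue points to a
#' modification in the vicinity (e.g. deltas of 9.1% and 9.9% flanking an
#' MS-supported site).  A position is flagged iff it is not called, its delta
#' lies in `(neighbor_floor_pct, threshold_pct]`, and it sits within
#' `neighbor_window` nt (distance >= 1; a position is not its own neighbour)
#' of a supported position on the same reference.
#'
#' @param calls `data.frame` from [call_modifications()].
#' @param supported_positions supported positions: integer vector (applied to
#'   all references) or `data.frame` with `ref_id`, `position`.  Typically the
#'   nanopore-called positions plus externally (cryo-EM/MS) supported ones.
#' @param cfg a [detect_config()].
#' @return `calls` with the `neighbor_flag` column filled in.
#' @export
flag_neighbors <- function(calls, supported_positions, cfg = detect_config()) {
  out <- calls
  out$neighbor_flag <- FALSE
  if (cfg$neighbor_window < 1L) return(out)
  if (is.data.frame(supported_positions)) {
    sup <- supported_positions
  } else {
    sup <- expand.grid(ref_id = unique(calls$ref_id),
                       position = as.integer(supported_positions),
                       stringsAsFactors = FALSE)
  }
  if (nrow(sup) == 0L) return(out)
  eligible <- !calls$called &
    calls$delta_pct > cfg$neighbor_floor_pct &
    calls$delta_pct <= cfg$threshold_pct
  for (i in which(eligible)) {
    d <- abs(sup$position[sup$ref_id == calls$ref_id[i]] - calls$position[i])
    out$neighbor_flag[i] <- any(d >= 1L & d <= cfg$neighbor_window)
  }
  out
}

#' Native-vs-IVT modification detection, end to end
#'
#' Convenience wrapper: error profiles for both samples, delta call errors,
#' threshold calls, pseudouridine signatures and neighbour flags in one call.
#' Supported positions for neighbour flagging default to the positions called
#' here, optionally augmented with externally supported ones.
#'
#' @param native_pileup,ivt_pileup pileup `data.frame`s over the same
#'   reference.
#' @param cfg a [detect_config()].
#' @param external_support optional positions supported by other methods
#'   (integer vector or `data.frame` with `ref_id`, `position`).
#' @return Per-position `data.frame` with errors, delta, `called`,
#'   `signature`, `neighbor_flag`, `excluded_reason`.
#' @export
detect_modifications <- function(native_pileup, ivt_pileup,
                                 cfg = detect_config(),
                                 external_support = NULL) {
  deltas <- delta_call_error(base_error(native_pileup),
                             base_error(ivt_pileup))
  calls <- call_modifications(deltas, cfg)
  calls <- classify_signature(calls, native_pileup, cfg)
  sup <- data.frame(ref_id = calls$ref_id[calls$called],
                    position = calls$position[calls$called],
                    stringsAsFactors = FALSE)
  if (!is.null(external_support)) {
    if (!is.data.frame(external_support))
      external_support <- expand.grid(ref_id = unique(calls$ref_id),
                                      position = as.integer(external_support),
                                      stringsAsFactors = FALSE)
    sup <- unique(rbind(sup, external_support[, c("ref_id", "position")]))
  }
  flag_neighbors(calls, sup, cfg)
}

#' Write called positions as BED
#'
#' One interval per called position (0-based half-open), name = signature,
#' score = `delta_pct` rounded to an integer.
#'
#' @param calls `data.frame` from [detect_modifications()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  x <- calls[calls$called, , drop = FALSE]
  bed <- data.frame(chrom = x$ref_id, start = x$position - 1L,
                    end = x$position, name = x$signature,
                    score = as.integer(round(x$delta_pct)), strand = "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
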