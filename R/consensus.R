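EVIDENCE_METHODS <- c("cryoem", "ms", "nanopore")

#' Read one per-method evidence table
#' @noRd
read_evidence_tsv <- function(x, method) {
  if (is.character(x)) {
    if (!file.exists(x)) dc_input_error("evidence TSV not found: ", x)
    x <- read.delim(x, stringsAsFactors = FALSE)
  }
  need <- c("subunit", "position")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L)
    dc_input_error(method, " evidence lacks columns: ",
                   paste(missing, collapse = ", "))
  if (!"type" %in% names(x)) x$type <- NA_character_
  if (!"plant_specific" %in% names(x)) x$plant_specific <- FALSE
  if (any(is.na(x$position)) || any(x$position != round(x$position)) ||
      any(x$position < 1))
    dc_input_error(method, " evidence has malformed positions")
  bad <- setdiff(unique(x$subunit), c("SSU", "LSU"))
  if (length(bad) > 0L)
    dc_input_error(method, " evidence has unknown subunit(s): ",
                   paste(bad, collapse = ", "))
  x$type <- ifelse(is.na(x$type) | x$type == "", NA_character_,
                   as.character(x$type))
  x$plant_specific <- !is.na(x$plant_specific) &
    as.logical(x$plant_specific)
  dup <- duplicated(x[, c("subunit", "position")])
  if (any(dup)) {
    warning(sprintf("%s evidence: %d duplicate (subunit, position) rows dropped",
                    method, sum(dup)))
    x <- x[!dup, , drop = FALSE]
  }
  x[, c("subunit", "position", "type", "plant_specific")]
}

#' Convert nanopore detection output to an evidence table
#'
#' Keeps called positions, maps `ref_id` to subunit (`18S -> SSU`,
#' `26S -> LSU` by default) and uses the miscall signature as the method's
#' type: `"psi"` where the pseudouridine signature was seen, untyped
#' otherwise.
#'
#' @param calls `data.frame` from [detect_modifications()].
#' @param subunit_map named character vector `ref_id -> subunit`.
#' @return evidence `data.frame` (`subunit`, `position`, `type`,
#'   `plant_specific`).
#' @export
calls_to_evidence <- function(calls,
                              subunit_map = c(`18S` = "SSU", `26S` = "LSU")) {
  x <- calls[calls$called, , drop = FALSE]
  unknown <- setdiff(unique(x$ref_id), names(subunit_map))
  if (length(unknown) > 0L)
    dc_input_error("no subunit mapping for reference(s): ",
                   paste(unknown, collapse = ", "))
  data.frame(subunit = unname(subunit_map[x$ref_id]), position = x$position,
             type = ifelse(x$signature == "psi", "psi", NA_character_),
             plant_specific = FALSE, stringsAsFactors = FALSE)
}

#' Merge per-method evidence into one record per position
#'
#' Each input is a TSV path or `data.frame` with columns `subunit`,
#' `position` and optional `type`, `plant_specific`.  The result has one row
#' per (subunit, position) carrying the union of method support, the type
#' reported by each method, and the OR of the plant-specific annotations.
#'
#' @param cryoem,ms,nanopore per-method evidence (path, `data.frame`, or
#'   `NULL` to omit a method).  `nanopore` may also be raw
#'   [detect_modifications()] output, converted via [calls_to_evidence()].
#' @param subunit_map passed to [calls_to_evidence()] when needed.
#' @return `data.frame`: `subunit`, `position`, `methods` (comma-joined,
#'   alphabetical), `n_methods`, `type_cryoem`, `type_ms`, `type_nanopore`,
#'   `plant_specific`; sorted by subunit (SSU first) then position.
#' @export
load_evidence <- function(cryoem = NULL, ms = NULL, nanopore = NULL,
                          subunit_map = c(`18S` = "SSU", `26S` = "LSU")) {
  if (is.data.frame(nanopore) && "called" %in% names(nanopore))
    nanopore <- calls_to_evidence(nanopore, subunit_map)
  inputs <- list(cryoem = cryoem, ms = ms, nanopore = nanopore)
  tabs <- lapply(names(inputs), function(m) {
    if (is.null(inputs[[m]])) return(NULL)
    t <- read_evidence_tsv(inputs[[m]], m)
    if (nrow(t) > 0L) t$method <- m
    t
  })
  tabs <- Filter(function(t) !is.null(t) && nrow(t) > 0L, tabs)
  if (length(tabs) == 0L)
    return(data.frame(subunit = character(), position = integer(),
                      methods = character(), n_methods = integer(),
                      type_cryoem = character(), type_ms = character(),
                      type_nanopore = character(),
                      plant_specific = logical(), stringsAsFactors = FALSE))
  long <- do.call(rbind, tabs)
  key <- paste(long$subunit, long$position)
  recs <- lapply(split(long, key), function(g) {
    ms_here <- sort(unique(g$method))
    ty <- function(m) {
      v <- g$type[g$method == m]
      if (length(v) == 0L) NA_character_ else v[1]
    }
    data.frame(subunit = g$subunit[1], position = g$position[1],
               methods = paste(ms_here, collapse = ","),
               n_methods = length(ms_here),
               type_cryoem = ty("cryoem"), type_ms = ty("ms"),
               type_nanopore = ty("nanopore"),
               plant_specific = any(g$plant_specific),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(match(out$subunit, c("SSU", "LSU")), out$position), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the at-least-two-methods consensus rule
#'
#' A position is a consensus modification iff it is supported by at least
#' `min_methods` of the three orthogonal approaches (cryo-EM density,
#' nanopore error analysis, mass spectrometry).  All positions are retained;
#' non-consensus ones are flagged `FALSE`.
#'
#' @param evidence `data.frame` from [load_evidence()].
#' @param min_methods minimum supporting methods (default 2).
#' @return `evidence` with a logical `consensus` column.
#' @export
build_consensus <- function(evidence, min_methods = 2L) {
  if (min_methods < 1L) dc_input_error("min_methods must be >= 1")
  out <- evidence
  out$consensus <- evidence$n_methods >= min_methods
  out
}

#' Read a homology map of reference positions to E. coli residues
#'
#' TSV with columns `subunit`, `position`, `ecoli_position`,
#' `ecoli_mod_type`; keys (subunit, position) must be unique.
#'
#' @param path TSV path (or a `data.frame` with those columns).
#' @return validated `data.frame`.
#' @export
read_homology_map <- function(path) {
  x <- if (is.character(path)) {
    if (!file.exists(path)) dc_input_error("homology map not found: ", path)
    read.delim(path, stringsAsFactors = FALSE)
  } else path
  need <- c("subunit", "position", "ecoli_position", "ecoli_mod_type")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L)
    dc_input_error("homology map lacks columns: ",
                   paste(missing, collapse = ", "))
  if (anyDuplicated(x[, c("subunit", "position")]))
    dc_input_error("homology map keys (subunit, position) must be unique")
  x
}

#' Assign a modification type to each consensus record
#'
#' Precedence: an experimentally determined type (cryo-EM or MS or the
#' nanopore psi signature) wins; failing that, the type of the equivalent
#' E. coli residue from the homology map; failing that `"?"` (uncharacterised,
#' typical for plant-specific sites with no bacterial equivalent).  Methods
#' reporting conflicting types degrade the record to `"?"` with a warning
#' rather than picking one arbitrarily.
#'
#' @param consensus `data.frame` from [build_consensus()].
#' @param homology_map optional map from [read_homology_map()].
#' @return `consensus` with columns `assigned_type` and `source_of_type`
#'   (`"experimental"`, `"ecoli_homology"` or `"unassigned"`).
#' @export
assign_type <- function(consensus, homology_map = NULL) {
  if (!is.null(homology_map)) homology_map <- read_homology_map(homology_map)
  out <- consensus
  out$assigned_type <- "?"
  out$source_of_type <- "unassigned"
  conflicts <- character()
  for (i in seq_len(nrow(out))) {
    tys <- unique(stats::na.omit(c(out$type_cryoem[i], out$type_ms[i],
                                   out$type_nanopore[i])))
    if (length(tys) == 1L) {
      out$assigned_type[i] <- tys
      out$source_of_type[i] <- "experimental"
    } else if (length(tys) > 1L) {
      conflicts <- c(conflicts, paste0(out$subunit[i], ":", out$position[i]))
    } else if (!is.null(homology_map)) {
      hit <- homology_map$subunit == out$subunit[i] &
        homology_map$position == out$position[i]
      if (any(hit)) {
        out$assigned_type[i] <- homology_map$ecoli_mod_type[which(hit)[1]]
        out$source_of_type[i] <- "ecoli_homology"
      }
    }
  }
  if (length(conflicts) > 0L)
    warning("conflicting experimental types at ",
            paste(conflicts, collapse = ", "), "; assigned '?'")
  out
}

#' Summary counts over a consensus table
#'
#' @param consensus `data.frame` from [build_consensus()] (after
#'   [assign_type()] if type counts are wanted).
#' @return list of `data.frame`s:
#'   \describe{
#'     \item{totals}{positions and consensus counts, by subunit and total.}
#'     \item{methods}{per-method evidence counts, by subunit and total.}
#'     \item{types}{`assigned_type` counts among consensus positions (empty
#'       if types were not assigned).}
#'     \item{plant_specific}{count of plant-specific entries, by subunit and
#'       total.}
#'   }
#'   All SSU + LSU pairs sum to their totals by construction.
#' @export
count_summary <- function(consensus) {
  by_su <- function(mask) {
    c(SSU = sum(mask & consensus$subunit == "SSU"),
      LSU = sum(mask & consensus$subunit == "LSU"),
      total = sum(mask))
  }
  n <- nrow(consensus)
  totals <- rbind(positions = by_su(rep(TRUE, n)),
                  consensus = by_su(consensus$consensus))
  totals <- data.frame(category = rownames(totals), totals,
                       row.names = NULL, stringsAsFactors = FALSE)
  has <- function(m) grepl(m, consensus$methods, fixed = TRUE)
  methods <- do.call(rbind, lapply(EVIDENCE_METHODS, function(m) by_su(has(m))))
  methods <- data.frame(method = EVIDENCE_METHODS, methods,
                        row.names = NULL, stringsAsFactors = FALSE)
  types <- if ("assigned_type" %in% names(consensus)) {
    tt <- table(consensus$assigned_type[consensus$consensus])
    data.frame(assigned_type = names(tt), n = as.integer(tt),
               stringsAsFactors = FALSE)
  } else data.frame(assigned_type = character(), n = integer())
  ps <- by_su(consensus$plant_specific)
  plant <- data.frame(category = "plant_specific", SSU = ps[["SSU"]],
                      LSU = ps[["LSU"]], total = ps[["total"]],
                      stringsAsFactors = FALSE)
  list(totals = totals, methods = methods, types = types,
       plant_specific = plant)
}
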