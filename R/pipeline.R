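#' Pipeline configuration
#'
#' Collects paths and stage parameters for [run_pipeline()].  Two modes:
#' with `simulate = TRUE` references, truth sets and native/IVT read sets are
#' generated into `out_dir`; otherwise `reference_fasta`, `native_bam` and
#' `ivt_bam` must point at existing inputs.  Evidence tables and the homology
#' map are optional; when present the consensus stage runs.
#'
#' @param out_dir output directory (created if needed).
#' @param simulate generate synthetic inputs instead of reading BAMs.
#' @param reference_fasta,native_bam,ivt_bam input paths (data mode).
#' @param cryoem_tsv,ms_tsv optional per-method evidence TSVs.
#' @param homology_tsv optional E. coli homology map TSV.
#' @param sim a [sim_config()] (simulate mode).
#' @param sim_refs simulate mode: `data.frame` with `ref_id`, `length`,
#'   `n_sites`, `psi_fraction` describing each reference to generate.
#' @param native_error_rate simulate mode: planted-site error rate(s).
#' @param detect a [detect_config()].
#' @param filter a [read_filter()].
#' @param subunit_map named vector `ref_id -> subunit` for the consensus
#'   stage.
#' @param seed master seed (overrides `sim$seed`).
#' @param plots write base-composition figures for called positions.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = FALSE,
                            reference_fasta = NULL, native_bam = NULL,
                            ivt_bam = NULL, cryoem_tsv = NULL, ms_tsv = NULL,
                            homology_tsv = NULL,
                            sim = sim_config(),
                            sim_refs = data.frame(
                              ref_id = c("18S", "26S"),
                              length = c(1800L, 3000L),
                              n_sites = c(5L, 7L),
                              psi_fraction = c(0.4, 0.5)),
                            native_error_rate = 0.3,
                            detect = detect_config(),
                            filter = read_filter(),
                            subunit_map = c(`18S` = "SSU", `26S` = "LSU"),
                            seed = 1L, plots = FALSE) {
  structure(list(out_dir = out_dir, simulate = isTRUE(simulate),
                 reference_fasta = reference_fasta, native_bam = native_bam,
                 ivt_bam = ivt_bam, cryoem_tsv = cryoem_tsv, ms_tsv = ms_tsv,
                 homology_tsv = homology_tsv, sim = sim, sim_refs = sim_refs,
                 native_error_rate = native_error_rate, detect = detect,
                 filter = filter, subunit_map = subunit_map,
                 seed = as.integer(seed), plots = isTRUE(plots)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key-value (DCF) file
#'
#' Keys mirror [pipeline_config()] arguments; unknown keys are an error.
#' Example file:
#' \preformatted{
#' out_dir: results
#' simulate: TRUE
#' depth: 500
#' seed: 7
#' threshold_pct: 10
#' }
#'
#' @param path DCF file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) dc_input_error("config file not found: ", path)
  kv <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  num <- function(k, d) if (!is.null(kv[[k]])) as.numeric(kv[[k]]) else d
  chr <- function(k, d = NULL) if (!is.null(kv[[k]])) kv[[k]] else d
  lgl <- function(k, d) if (!is.null(kv[[k]])) as.logical(kv[[k]]) else d
  known <- c("out_dir", "simulate", "reference_fasta", "native_bam",
             "ivt_bam", "cryoem_tsv", "ms_tsv", "homology_tsv", "seed",
             "depth", "background_miscall", "background_deletion",
             "truncation_rate", "threshold_pct", "min_depth",
             "neighbor_window", "neighbor_floor_pct", "psi_dominance",
             "min_mapping_quality", "native_error_rate", "plots")
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0L)
    dc_input_error("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(kv$out_dir)) dc_input_error("config must set out_dir")
  seed <- as.integer(num("seed", 1))
  pipeline_config(
    out_dir = kv$out_dir, simulate = lgl("simulate", FALSE),
    reference_fasta = chr("reference_fasta"), native_bam = chr("native_bam"),
    ivt_bam = chr("ivt_bam"), cryoem_tsv = chr("cryoem_tsv"),
    ms_tsv = chr("ms_tsv"), homology_tsv = chr("homology_tsv"),
    sim = sim_config(background_miscall = num("background_miscall", 0.029),
                     background_deletion = num("background_deletion", 0.01),
                     depth = num("depth", 1000),
                     truncation_rate = num("truncation_rate", 1e-4),
                     seed = seed),
    native_error_rate = num("native_error_rate", 0.3),
    detect = detect_config(threshold_pct = num("threshold_pct", 10),
                           min_depth = num("min_depth", 50),
                           neighbor_window = num("neighbor_window", 1),
                           neighbor_floor_pct = num("neighbor_floor_pct", 5),
                           psi_dominance = num("psi_dominance", 0.5)),
    filter = read_filter(min_mapping_quality = num("min_mapping_quality", 1)),
    seed = seed, plots = lgl("plots", FALSE))
}

#' Run the full detection pipeline
#'
#' Stages: (1) obtain inputs (simulate or load), (2) filter reads and compute
#' native/IVT pileups, (3) delta-call-error detection with signatures and
#' neighbour flags, (4) evidence consensus (if evidence tables are
#' configured), (5) summary, optional figures, and a machine-readable run
#' manifest (parameters, input checksums, package version).  Every
#' intermediate table is written as TSV under `out_dir` so each stage can be
#' re-run and audited independently.  Deterministic given inputs and seed.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage progress messages (stderr).
#' @return list with `pileups`, `deltas` (per-reference call tables),
#'   `background_pct`, `evidence`, `consensus`, `summary`, `manifest`, and
#'   `files` (paths of everything written).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message("[deltacall] ", ...)
  t0 <- Sys.time()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  inputs <- character()

  stage <- function(name, expr) {
    tryCatch(expr, deltacall_input_error = function(e) stop(e),
             error = function(e)
               stop("pipeline stage '", name, "' failed: ",
                    conditionMessage(e), call. = FALSE))
  }

  # -- stage 1: inputs ------------------------------------------------------
  if (cfg$simulate) {
    say("simulating inputs (seed ", cfg$seed, ")")
    sim <- cfg$sim; sim$seed <- cfg$seed
    refs <- list(); truths <- list(); native_bams <- c(); ivt_bams <- c()
    stage("simulate", for (i in seq_len(nrow(cfg$sim_refs))) {
      rs <- cfg$sim_refs[i, ]
      ref <- make_reference(rs$ref_id, rs$length, seed = cfg$seed)
      truth <- plant_modifications(ref, rs$n_sites, rs$psi_fraction,
                                   cfg$native_error_rate, seed = cfg$seed)
      pre <- file.path(cfg$out_dir, rs$ref_id)
      nat <- simulate_reads(ref, truth, sim, "native",
                            paste0(pre, ".native"))
      ivt <- simulate_reads(ref, NULL, sim, "ivt", paste0(pre, ".ivt"))
      refs[[rs$ref_id]] <- ref; truths[[rs$ref_id]] <- truth
      native_bams[rs$ref_id] <- nat$bam; ivt_bams[rs$ref_id] <- ivt$bam
    })
    fa <- file.path(cfg$out_dir, "references.fasta")
    write_rna_fasta(refs, fa)
    files$references <- fa
    inputs <- c(inputs, unlist(native_bams), unlist(ivt_bams))
  } else {
    for (p in c(reference = cfg$reference_fasta, native = cfg$native_bam,
                ivt = cfg$ivt_bam))
      if (is.null(p) || !file.exists(p))
        dc_input_error("missing required input: ",
                       if (is.null(p)) "unset path" else p)
    refs <- stage("load", read_rna_fasta(cfg$reference_fasta))
    native_bams <- setNames(rep(cfg$native_bam, length(refs)), names(refs))
    ivt_bams <- setNames(rep(cfg$ivt_bam, length(refs)), names(refs))
    truths <- NULL
    inputs <- c(cfg$reference_fasta, cfg$native_bam, cfg$ivt_bam)
  }

  # -- stages 2+3: pileup and detection per reference -----------------------
  filt <- cfg$filter
  missing_win <- setdiff(names(refs), names(filt$length_window))
  for (m in missing_win)     # simulated refs: accept any length up to L
    filt$length_window[[m]] <- c(1L, refs[[m]]$length)
  pileups <- list(); deltas <- list(); bg <- c()
  for (rid in names(refs)) {
    say("pileup + detect: ", rid)
    ref <- refs[[rid]]
    pu <- list()
    for (kind in c("native", "ivt")) {
      bam <- if (kind == "native") native_bams[[rid]] else ivt_bams[[rid]]
      fr <- stage("filter_reads", filter_reads(read_alignments(bam), filt))
      pu[[kind]] <- stage("pileup", compute_pileup(fr$alignments, ref))
      f <- file.path(cfg$out_dir, paste0(rid, ".", kind, ".pileup.tsv"))
      write_pileup_tsv(pu[[kind]], f)
      files[[paste0(rid, "_", kind, "_pileup")]] <- f
    }
    bg[rid] <- stage("background",
                     background_error(base_error(pu$ivt), cfg$detect$min_depth))
    det <- stage("detect", detect_modifications(pu$native, pu$ivt, cfg$detect))
    f <- file.path(cfg$out_dir, paste0(rid, ".delta.tsv"))
    write.table(det, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[paste0(rid, "_delta")]] <- f
    b <- file.path(cfg$out_dir, paste0(rid, ".calls.bed"))
    write_calls_bed(det, b)
    files[[paste0(rid, "_calls")]] <- b
    pileups[[rid]] <- pu; deltas[[rid]] <- det
    if (cfg$plots) {
      poi <- det$position[det$called]
      pf <- file.path(cfg$out_dir, paste0(rid, ".composition.png"))
      stage("plot", plot_composition(pu$native, pu$ivt, poi, pf))
      files[[paste0(rid, "_plot")]] <- pf
    }
  }

  # -- stage 4: consensus ---------------------------------------------------
  all_calls <- do.call(rbind, deltas)
  evidence <- consensus <- summary <- NULL
  if (!is.null(cfg$cryoem_tsv) || !is.null(cfg$ms_tsv)) {
    say("consensus")
    sm <- cfg$subunit_map
    for (rid in setdiff(names(refs), names(sm))) sm[rid] <- rid
    evidence <- stage("consensus",
                      load_evidence(cryoem = cfg$cryoem_tsv, ms = cfg$ms_tsv,
                                    nanopore = all_calls, subunit_map = sm))
    consensus <- build_consensus(evidence)
    consensus <- stage("assign_type", assign_type(consensus, cfg$homology_tsv))
    f <- file.path(cfg$out_dir, "consensus.tsv")
    write.table(consensus, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files$consensus <- f
    summary <- count_summary(consensus)
    f <- file.path(cfg$out_dir, "summary.tsv")
    write.table(summary$totals, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files$summary <- f
    inputs <- c(inputs, unlist(cfg[c("cryoem_tsv", "ms_tsv", "homology_tsv")]))
  }

  # -- manifest -------------------------------------------------------------
  manifest <- list(
    package = "deltacall",
    version = as.character(packageVersion("deltacall")),
    seed = cfg$seed,
    parameters = list(detect = unclass(cfg$detect), sim = unclass(cfg$sim),
                      filter = unclass(cfg$filter)),
    input_md5 = local({   # keyed by file name so manifests compare across dirs
      m <- tools::md5sum(inputs[file.exists(inputs)])
      as.list(setNames(m, basename(names(m))))
    }),
    background_error_pct = as.list(bg),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  mf <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files$manifest <- mf
  say(sprintf("done in %.1fs", as.numeric(Sys.time() - t0, units = "secs")))

  list(pileups = pileups, deltas = deltas, background_pct = bg,
       truth = truths, evidence = evidence, consensus = consensus,
       summary = summary, manifest = manifest, files = files)
}
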