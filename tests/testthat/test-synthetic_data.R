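test_that("make_reference is seed-deterministic and composition follows gc_fraction", {
  r1 <- make_reference("18S", 1800, 0.5, seed = 1)
  r2 <- make_reference("18S", 1800, 0.5, seed = 1)
  expect_identical(r1$sequence, r2$sequence)
  expect_equal(r1$length, 1800)
  expect_false(identical(r1$sequence,
                         make_reference("18S", 1800, 0.5, seed = 2)$sequence))

  au <- make_reference("au", 500, gc_fraction = 0, seed = 3)
  expect_true(all(strsplit(au$sequence, "")[[1]] %in% c("A", "U")))

  # binomial oracle: GC count within 3 sigma of n * p
  r <- make_reference("26S", 3000, 0.5, seed = 7)
  gc <- sum(strsplit(r$sequence, "")[[1]] %in% c("G", "C"))
  sigma <- sqrt(3000 * 0.5 * 0.5)
  expect_gt(gc, 1500 - 3 * sigma)
  expect_lt(gc, 1500 + 3 * sigma)

  expect_error(make_reference("x", 0, seed = 1), class = "deltacall_input_error")
  expect_error(make_reference("x", 10, gc_fraction = 2, seed = 1),
               class = "deltacall_input_error")
})

test_that("rna_reference validates and normalises its alphabet", {
  r <- rna_reference("toy", "acgtT")
  expect_identical(r$sequence, "ACGUU")
  expect_equal(r$length, 5)
  expect_error(rna_reference("toy", "ACGN"), class = "deltacall_input_error")
})

test_that("plant_modifications respects psi placement, skew and determinism", {
  ref <- make_reference("18S", 600, seed = 4)
  t0 <- plant_modifications(ref, 0, seed = 1)
  expect_equal(nrow(t0), 0)

  tr <- plant_modifications(ref, 10, psi_fraction = 0.5, seed = 9)
  tr2 <- plant_modifications(ref, 10, psi_fraction = 0.5, seed = 9)
  expect_identical(tr, tr2)
  expect_equal(anyDuplicated(tr$position), 0)
  bases <- strsplit(ref$sequence, "")[[1]]
  expect_identical(tr$ref_base, bases[tr$position])
  expect_true(all(tr$ref_base[tr$mod_type == "psi"] == "U"))
  skew <- as.matrix(tr[, paste0("skew_", c("A", "C", "G", "U"))])
  expect_equal(unname(rowSums(skew)), rep(1, 10), tolerance = 1e-9)
  # skew puts no mass on the reference base
  expect_true(all(skew[cbind(seq_len(10),
                             match(tr$ref_base, c("A", "C", "G", "U")))] == 0))
  expect_true(all(tr$skew_C[tr$mod_type == "psi"] == 0.9))
  # non-psi sites have one dominant miscall base
  nonpsi <- skew[tr$mod_type != "psi", , drop = FALSE]
  expect_true(all(apply(nonpsi, 1, max) == 0.9))

  # psi_fraction = 1 on an all-U reference
  allu <- rna_reference("u", strrep("U", 50))
  tu <- plant_modifications(allu, 5, psi_fraction = 1, seed = 1)
  expect_true(all(tu$ref_base == "U" & tu$mod_type == "psi"))
  expect_true(all(tu$skew_C == 0.9))

  # too few U positions for the requested psi count
  allg <- rna_reference("g", strrep("G", 50))
  expect_error(plant_modifications(allg, 2, psi_fraction = 1, seed = 1),
               class = "deltacall_input_error")
})

test_that("simulate_pileup columns satisfy the depth invariant and limits", {
  ref <- make_reference("18S", 400, seed = 2)
  truth <- plant_modifications(ref, 3, seed = 2)
  cfg <- sim_config(depth = 150, seed = 11)
  pu <- simulate_pileup(ref, truth, cfg, "native")
  expect_equal(nrow(pu), 400)
  expect_equal(pu$nA + pu$nC + pu$nG + pu$nU + pu$nDel, pu$depth)
  expect_true(all(pu$depth == 150))
  expect_identical(pu, simulate_pileup(ref, truth, cfg, "native"))

  # zero-noise limit: only reference calls
  clean <- sim_config(background_miscall = 0, background_deletion = 0,
                      depth = 50, seed = 1)
  pu0 <- simulate_pileup(ref, NULL, clean, "ivt")
  m <- as.matrix(pu0[, c("nA", "nC", "nG", "nU")])
  expect_true(all(m[cbind(seq_len(400),
                          match(pu0$ref_base, c("A", "C", "G", "U")))] == 50))
  expect_true(all(pu0$nDel == 0))
})

test_that("IVT pileups recover the configured background rate (binomial oracle)", {
  ref <- make_reference("x", 2000, seed = 6)
  cfg <- sim_config(background_miscall = 0.029, depth = 1000, seed = 21)
  pu <- simulate_pileup(ref, NULL, cfg, "ivt")
  prof <- base_error(pu)
  est <- mean(prof$error_pct)
  # mean of L binomial proportions at n = depth (deletions shrink n slightly;
  # the bound below ignores that second-order effect)
  se <- 100 * sqrt(0.029 * 0.971 / 1000 / 2000)
  expect_lt(abs(est - 2.9), 3 * se + 0.02)
})

test_that("a planted psi site is C-dominant at depth 1000 (multinomial oracle)", {
  allu <- rna_reference("u", strrep("U", 30))
  for (s in 1:10) {
    tr <- plant_modifications(allu, 1, psi_fraction = 1,
                              native_error_rate = 0.30, seed = s)
    pu <- simulate_pileup(allu, tr, sim_config(depth = 1000, seed = s), "native")
    row <- pu[pu$position == tr$position, ]
    expect_gt(row$nC, max(row$nA, row$nG))
  }
})

test_that("IVT simulation is independent of the truth set", {
  ref <- make_reference("x", 300, seed = 3)
  cfg <- sim_config(depth = 100, seed = 5)
  t1 <- plant_modifications(ref, 5, seed = 1)
  t2 <- plant_modifications(ref, 8, seed = 99)
  expect_identical(simulate_pileup(ref, t1, cfg, "ivt"),
                   simulate_pileup(ref, t2, cfg, "ivt"))
})

test_that("raising native_error_rate does not decrease delta at planted sites", {
  ref <- make_reference("x", 500, seed = 8)
  cfg <- sim_config(depth = 800, seed = 13)
  ivt <- simulate_pileup(ref, NULL, cfg, "ivt")
  mean_delta <- function(rate) {
    tr <- plant_modifications(ref, 6, native_error_rate = rate, seed = 17)
    pu <- simulate_pileup(ref, tr, cfg, "native")
    d <- detect_modifications(pu, ivt)
    mean(d$delta_pct[d$position %in% tr$position])
  }
  deltas <- vapply(c(0.1, 0.2, 0.3, 0.4), mean_delta, numeric(1))
  expect_true(all(diff(deltas) > 0))
})

test_that("simulate_reads writes a valid, deterministic BAM and truth BED", {
  ref <- make_reference("18S", 200, seed = 5)
  truth <- plant_modifications(ref, 3, seed = 5, deletion_rate = 0)
  cfg <- sim_config(depth = 60, truncation_rate = 0,
                    background_deletion = 0, seed = 7)
  d <- withr::local_tempdir()
  r1 <- simulate_reads(ref, truth, cfg, "native", file.path(d, "a"))
  r2 <- simulate_reads(ref, truth, cfg, "native", file.path(d, "b"))
  expect_identical(unname(tools::md5sum(r1$bam)), unname(tools::md5sum(r2$bam)))

  aln <- read_alignments(r1$bam)
  expect_equal(nrow(aln), 60)
  # truncation 0 + no deletions: every read is full length and 3'-anchored
  expect_true(all(aln$qwidth == 200))
  expect_true(all(aln$pos == 1))

  # truth BED round-trips exactly
  bed <- read_truth_bed(r1$bed)
  expect_identical(bed$position, truth$position)
  expect_identical(bed$mod_type, truth$mod_type)
})

test_that("3'-anchored truncation shortens reads from the 5' side", {
  ref <- make_reference("x", 300, seed = 5)
  cfg <- sim_config(depth = 80, truncation_rate = 0.01,
                    background_deletion = 0, seed = 3)
  d <- withr::local_tempdir()
  r <- simulate_reads(ref, NULL, cfg, "ivt", file.path(d, "t"))
  aln <- read_alignments(r$bam)
  # all reads end at the reference 3' end
  span <- vapply(seq_len(nrow(aln)), function(i) {
    ops <- sum(as.integer(regmatches(aln$cigar[i],
                                     gregexpr("[0-9]+(?=[MD])", aln$cigar[i],
                                              perl = TRUE))[[1]]))
    aln$pos[i] + ops - 1L
  }, numeric(1))
  expect_true(all(span == 300))
  expect_true(any(aln$pos > 1))  # some truncation at this rate
})

test_that("pileup from simulated reads agrees with simulate_pileup in expectation", {
  ref <- make_reference("x", 300, seed = 10)
  truth <- plant_modifications(ref, 4, native_error_rate = 0.3, seed = 10)
  cfg <- sim_config(depth = 1000, truncation_rate = 0, seed = 19)
  d <- withr::local_tempdir()
  r <- simulate_reads(ref, truth, cfg, "native", file.path(d, "x"))
  pu_reads <- compute_pileup(read_alignments(r$bam), ref)
  pu_direct <- simulate_pileup(ref, truth, cfg, "native")
  err_r <- base_error(pu_reads)$error_pct
  err_d <- base_error(pu_direct)$error_pct
  # per-position difference of two independent draws of the same model:
  # 3 standard errors of the difference, position-wise (rate-dependent)
  p <- pmax(err_r, err_d) / 100
  se_diff <- 100 * sqrt(2 * pmax(p, 0.005) * (1 - pmax(p, 0.005)) / 1000)
  expect_true(all(abs(err_r - err_d) <= 3 * se_diff + 0.5))
  # and identically on average
  expect_lt(abs(mean(err_r) - mean(err_d)), 0.1)
})
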