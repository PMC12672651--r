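pu_row <- function(ref_base, nA = 0, nC = 0, nG = 0, nU = 0, nDel = 0,
                   position = 1, ref_id = "toy") {
  data.frame(ref_id = ref_id, position = position, ref_base = ref_base,
             nA = nA, nC = nC, nG = nG, nU = nU, nDel = nDel,
             depth = nA + nC + nG + nU + nDel, stringsAsFactors = FALSE)
}

test_that("base_error computes the highest non-reference base percentage", {
  p <- base_error(pu_row("A", nA = 95, nC = 5))
  expect_equal(p$error_pct, 5.0)
  expect_identical(p$dominant_nonref, "C")
  expect_false(p$tie_flag)

  p <- base_error(pu_row("A", nA = 100))
  expect_equal(p$error_pct, 0.0)
  expect_true(is.na(p$dominant_nonref))

  # tie broken in fixed order A < C < G < U, flagged
  p <- base_error(pu_row("A", nA = 94, nC = 3, nG = 3))
  expect_equal(p$error_pct, 3.0)
  expect_identical(p$dominant_nonref, "C")
  expect_true(p$tie_flag)

  # zero basecall depth (deletions only) yields error 0
  p <- base_error(pu_row("A", nDel = 10))
  expect_equal(p$error_pct, 0)
  expect_equal(p$basecall_depth, 0)

  # deletions affect neither numerator nor denominator
  expect_equal(base_error(pu_row("A", nA = 90, nC = 10, nDel = 50))$error_pct,
               10.0)

  # invariant: scaling all counts leaves error_pct unchanged
  a <- base_error(pu_row("G", nA = 7, nC = 2, nG = 88, nU = 3))
  b <- base_error(pu_row("G", nA = 7 * 9, nC = 2 * 9, nG = 88 * 9, nU = 3 * 9))
  expect_equal(a$error_pct, b$error_pct)
})

test_that("delta_call_error preserves sign and requires matched positions", {
  mk_prof <- function(err, pos = 1) data.frame(
    ref_id = "toy", position = pos, ref_base = "A", error_pct = err,
    dominant_nonref = "C", tie_flag = FALSE, basecall_depth = 100L,
    stringsAsFactors = FALSE)
  d <- delta_call_error(mk_prof(12.4), mk_prof(2.3))
  expect_equal(d$delta_pct, 10.1)
  expect_equal(delta_call_error(mk_prof(5), mk_prof(5))$delta_pct, 0)
  expect_equal(delta_call_error(mk_prof(1), mk_prof(4))$delta_pct, -3)
  expect_error(delta_call_error(mk_prof(1, pos = 1), mk_prof(1, pos = 2)),
               "identical positions")
})

test_that("background_error is the depth-weighted mean over covered positions", {
  prof <- function(err, depth) data.frame(error_pct = err,
                                          basecall_depth = depth)
  expect_equal(background_error(prof(c(0, 0, 0), c(100, 100, 100))), 0)
  expect_equal(background_error(prof(c(2, 4), c(100, 100))), 3)
  expect_equal(background_error(prof(c(2, 4), c(300, 100))), 2.5)
  # positions under min_depth are excluded
  expect_equal(background_error(prof(c(2, 50), c(100, 10)), min_depth = 50), 2)
  expect_error(background_error(prof(numeric(), integer())),
               class = "deltacall_input_error")
  expect_error(background_error(prof(5, 10), min_depth = 50),
               class = "deltacall_input_error")
})

test_that("call_modifications applies the strict threshold and depth guard", {
  mk <- function(delta, dn = 1000, di = 1000, pos = 1) data.frame(
    ref_id = "toy", position = pos, ref_base = "U",
    error_native_pct = delta, error_ivt_pct = 0, delta_pct = delta,
    depth_native = dn, depth_ivt = di, dominant_native = "C",
    dominant_ivt = NA_character_, tie_native = FALSE, stringsAsFactors = FALSE)
  expect_false(call_modifications(mk(9.1))$called)
  expect_true(call_modifications(mk(10.1))$called)
  # strictly greater: exactly 10.0 is not called
  expect_false(call_modifications(mk(10.0))$called)
  # low depth excludes whatever the delta
  c <- call_modifications(mk(50, dn = 20))
  expect_false(c$called)
  expect_identical(c$excluded_reason, "low_depth")
  c <- call_modifications(mk(50, di = 20))
  expect_identical(c$excluded_reason, "low_depth")

  # raising the threshold never enlarges the called set
  set.seed(42)
  tab <- mk(0)[rep(1, 200), ]
  tab$position <- 1:200
  tab$delta_pct <- runif(200, -5, 30)
  prev <- NULL
  for (thr in c(5, 10, 15, 20)) {
    called <- call_modifications(tab, detect_config(threshold_pct = thr,
                                                    neighbor_floor_pct = 0))
    now <- called$position[called$called]
    if (!is.null(prev)) expect_true(all(now %in% prev))
    prev <- now
  }
})

test_that("classify_signature recognises the psi U-to-C miscall signature", {
  run <- function(ref_base, nA = 0, nC = 0, nG = 0, nU = 0, dom) {
    pu <- pu_row(ref_base, nA, nC, nG, nU)
    calls <- data.frame(ref_id = "toy", position = 1, ref_base = ref_base,
                        delta_pct = 20, called = TRUE,
                        dominant_native = dom, excluded_reason = NA_character_,
                        signature = NA_character_, neighbor_flag = FALSE,
                        stringsAsFactors = FALSE)
    classify_signature(calls, pu)$signature
  }
  # ref U, 90% of non-reference calls are C
  expect_identical(run("U", nC = 27, nA = 2, nG = 1, nU = 70, dom = "C"), "psi")
  # ref A can never be psi
  expect_identical(run("A", nC = 30, nA = 70, dom = "C"), "?")
  # ref U but dominant non-reference G
  expect_identical(run("U", nG = 25, nC = 5, nU = 70, dom = "G"), "?")
  # ref U, C dominant but below the dominance share
  expect_identical(run("U", nC = 12, nA = 10, nG = 8, nU = 70, dom = "C"), "?")
})

test_that("flag_neighbors flags sub-threshold positions near supported sites", {
  mk <- function(pos, delta) data.frame(
    ref_id = "toy", position = pos, ref_base = "A",
    error_native_pct = delta, error_ivt_pct = 0, delta_pct = delta,
    depth_native = 1000L, depth_ivt = 1000L, dominant_native = "C",
    dominant_ivt = NA_character_, tie_native = FALSE, stringsAsFactors = FALSE)
  # the worked example: deltas 9.1 and 9.9 flanking an MS-supported site
  tab <- rbind(mk(1670, 9.1), mk(1671, 2.0), mk(1672, 9.9))
  calls <- call_modifications(tab)
  expect_false(any(calls$called))
  flagged <- flag_neighbors(calls, 1671L)
  expect_equal(flagged$neighbor_flag, c(TRUE, FALSE, TRUE))

  # isolated sub-threshold position: no flag
  expect_false(flag_neighbors(call_modifications(mk(500, 9.0)), 1671L)$neighbor_flag)
  # degenerate window 0: no flags possible
  none <- flag_neighbors(calls, 1671L, detect_config(neighbor_window = 0))
  expect_false(any(none$neighbor_flag))
  # below the neighbour floor: no flag
  low <- flag_neighbors(call_modifications(rbind(mk(1670, 4.9))), 1671L)
  expect_false(any(low$neighbor_flag))
})

test_that("detection over a toy table equals the exhaustive oracle", {
  set.seed(123)
  bases <- sample(c("A", "C", "G", "U"), 50, replace = TRUE)
  native <- random_counts(bases, depth = 200, seed = 1)
  ivt <- random_counts(bases, depth = 200, seed = 2)
  # make some positions low-depth to exercise the guard
  for (col in c("nA", "nC", "nG", "nU"))
    native[48:50, col] <- native[48:50, col] %/% 10
  got <- detect_modifications(native, ivt, external_support = c(5L, 30L))
  want <- oracle_detect(native, ivt, external_support = c(5, 30))
  expect_equal(got$delta_pct, want$delta)
  expect_equal(got$called, want$called)
  expect_equal(got$signature, want$signature)
  expect_equal(got$neighbor_flag, want$neighbor)
})

test_that("no calls arise from pure background across seeds", {
  ref <- make_reference("null", 400, seed = 30)
  for (s in 1:5) {
    cfg <- sim_config(depth = 1000, seed = s)
    nat <- simulate_pileup(ref, NULL, cfg, "native")
    ivt <- simulate_pileup(ref, NULL, cfg, "ivt")
    det <- detect_modifications(nat, ivt)
    expect_equal(sum(det$called), 0, info = paste("seed", s))
  }
})
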