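test_that("generators are deterministic in the seed and sensitive to it", {
  d <- venn_design_spec(seed = 123)
  g1 <- gen_feature_tables(d)
  g2 <- gen_feature_tables(d)
  expect_identical(g1$tables, g2$tables)
  expect_identical(g1$manifest$features, g2$manifest$features)
  g3 <- gen_feature_tables(venn_design_spec(seed = 124))
  expect_false(identical(g1$tables$mz, g3$tables$mz))

  cs <- nodule_colonization_preset(seed = 9)
  expect_identical(gen_nodule_table(cs), gen_nodule_table(cs))

  p <- peptide_spec(c("Val", "Ala", "Phe"), n_term = "formyl")
  s1 <- gen_ms2_spectrum(p, jitter_ppm = 5, n_decoys = 3, seed = 7)
  s2 <- gen_ms2_spectrum(p, jitter_ppm = 5, n_decoys = 3, seed = 7)
  expect_identical(s1$peaks, s2$peaks)
})

test_that("design validation refuses jitter at or above the matching tolerance", {
  expect_error(venn_design_spec(jitter_ppm = 10, match_tol_ppm = 10),
               "jitter")
  expect_error(venn_design_spec(rt_jitter = 0.3, match_tol_rt = 0.2),
               "jitter")
  expect_error(venn_design_spec(leak_counts = c(Ag35 = 17L)), "leak")
})

test_that("every observed feature is attributable to a manifest ground truth", {
  d <- venn_design_spec(seed = 31)
  g <- gen_feature_tables(d)
  truth_mz <- g$manifest$features$mz
  for (i in seq_len(nrow(g$tables))) {
    dev <- abs(truth_mz - g$tables$mz[i]) / g$tables$mz[i] * 1e6
    expect_lte(min(dev), d$jitter_ppm + 1e-9)
  }
  # every planted feature key appears in some stage-1 set or is background
  keys <- g$manifest$features$key
  staged <- unique(unlist(g$manifest$stage1))
  background <- g$manifest$features$kind == "baseline"
  expect_setequal(keys[!background], staged)
})

test_that("replicate dropout thins presence according to the binomial tail", {
  # detection ~ Bernoulli(0.75) per replicate; present = >= 2 of 4 detections
  d <- venn_design_spec(
    unique_counts = c(Ag47 = 0L, Ag15 = 0L, Ag54 = 0L, Ag35 = 0L, SM = 0L),
    shared_counts = c("Ag47:Ag15" = 0L), leak_counts = c(Ag35 = 0L),
    baseline_count = 200L, dropout = 0.25, seed = 55)
  g <- gen_feature_tables(d)
  al <- match_features(g$tables)
  pres <- presence_calls(al, 0.5)
  frac <- length(pres[["single_SM"]]) / 200
  p_expect <- stats::pbinom(1, 4, 0.75, lower.tail = FALSE)
  se <- sqrt(p_expect * (1 - p_expect) / 200)
  expect_lt(abs(frac - p_expect), 3 * se)
})

test_that("simulated spectra plant the requested series and honest decoys", {
  p <- peptide_spec(c("Ile", "Gly", "Ala", "Leu", "Val", "Phe", "Ser",
                      "Thr"), n_term = "formyl")
  sp <- gen_ms2_spectrum(p, dropout = 0.1, n_decoys = 5, seed = 12)
  truth <- attr(sp, "truth")
  expect_true(all(truth$series == "b"))
  # decoys stay >= 3 tolerances from every true ion
  all_b <- fragment_ions(p, series = "b")$mz
  decoys <- setdiff(round(sp$peaks$mz, 6), round(truth$mz, 6))
  for (x in decoys) {
    tol <- pmax(0.002, 10e-6 * x)
    expect_true(all(abs(all_b - x) > 3 * tol))
  }
  expect_error(gen_ms2_spectrum(tyrocidine_a(), seed = 1), "cyclic")
})

test_that("dropout-degraded ladders flag gaps but never assert wrong residues", {
  set.seed(900)
  rtab <- residue_table()
  res_mass <- stats::setNames(rtab$mass, rtab$name)
  co <- 27.99491    # formyl cap
  ea <- 43.04220    # ethanolamide cap
  offsets <- c(0, co, -co, ea, -ea, co + ea, -co - ea)
  wrong <- 0
  for (i in 1:40) {
    res <- sample(rtab$name, 8, replace = TRUE)
    p <- peptide_spec(res, n_term = "formyl", c_term = "ethanolamide")
    sp <- gen_ms2_spectrum(p, dropout = 0.1, seed = 1000 + i)
    hy <- ladder_sequence(sp)
    if (!length(hy)) next
    h <- hy[[1]]
    # every cumulative-mass boundary the top hypothesis asserts must land on
    # a boundary of the true residue-mass ladder: a same-mass composite
    # reading (Gly+Gly as Asn) or a flagged gap still lands on one, whereas
    # a wrong residue call does not. Terminal-cap reinterpretations (formyl
    # vs free start, ethanolamide vs free-acid closure) shift the whole
    # ladder by the cap mass and are allowed.
    true_cum <- cumsum(res_mass[res])
    el_mass <- vapply(h$assignments, function(el) {
      if (inherits(el, "ladder_gap")) el$mass else res_mass[[el[1]]]
    }, numeric(1))
    pred_cum <- cumsum(el_mass)
    for (b in pred_cum) {
      ok <- any(vapply(offsets, function(o) {
        any(abs(true_cum - (b + o)) < 0.02)
      }, logical(1)))
      if (!ok) wrong <- wrong + 1
    }
  }
  expect_equal(wrong, 0)
})

test_that("colonization extremes behave: p = 0 never recovered, p = 1 always", {
  cs <- colonization_spec(list(
    none = list(members = "A", n_nodules = 12, p = c(A = 0),
                cfu_mean = c(A = 100)),
    all  = list(members = "A", n_nodules = 12, p = c(A = 1),
                cfu_mean = c(A = 100))), seed = 5)
  rr <- recovery_rates(gen_nodule_table(cs))
  expect_equal(rr$rate[rr$treatment == "none"], 0)
  expect_equal(rr$rate[rr$treatment == "all"], 100)
})
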