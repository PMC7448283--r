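make_table <- function(treatment, replicate, mz, rt) {
  data.frame(treatment = treatment, replicate = replicate,
             feature_id = sprintf("F%03d", seq_along(mz)), mz = mz, rt = rt,
             intensity = 1000, stringsAsFactors = FALSE)
}

test_that("identical tables align one cluster per feature; distant features split", {
  mz <- c(300.1, 800.5, 1500.9)
  t1 <- make_table("A", "r1", mz, c(2, 5, 9))
  t2 <- make_table("B", "r1", mz, c(2, 5, 9))
  al <- match_features(list(t1, t2))
  expect_equal(nrow(al$clusters), 3)
  expect_true(all(al$presence))
  # 50 ppm apart at 10 ppm tolerance: two clusters
  far <- make_table("A", "r1", c(1000.00, 1000.05), c(3, 3))
  expect_equal(nrow(match_features(far)$clusters), 2)
  expect_error(match_features(t1, mz_tol_ppm = -1), "positive")
})

test_that("sub-tolerance jitter does not change the clustering", {
  set.seed(99)
  mz <- sort(runif(40, 200, 2000))
  mz <- mz[c(TRUE, diff(mz) > 0.5)]
  rt <- runif(length(mz), 1, 20)
  t1 <- make_table("A", "r1", mz, rt)
  jit <- mz * (1 + runif(length(mz), -3e-6, 3e-6))
  t2 <- make_table("B", "r1", jit, rt)
  al <- match_features(list(t1, t2))
  expect_equal(nrow(al$clusters), length(mz))
  expect_true(all(al$clusters$n_samples == 2))
})

test_that("presence calls apply the inclusive replicate-fraction rule", {
  reps <- paste0("r", 1:4)
  # a background feature anchors all four replicates; the focal feature at
  # 500.5 is detected in only the first n_detect of them
  mk <- function(n_detect) {
    rbind(do.call(rbind, lapply(reps[seq_len(n_detect)], function(r) {
      make_table("A", r, 500.5, 5)
    })),
    do.call(rbind, lapply(reps, function(r) make_table("A", r, 900.9, 9))))
  }
  focal_present <- function(n_detect) {
    al <- match_features(mk(n_detect))
    focal <- al$clusters$cluster[abs(al$clusters$mz - 500.5) < 0.01]
    focal %in% presence_calls(al, 0.5)[["A"]]
  }
  expect_true(focal_present(4))
  expect_true(focal_present(2))   # 2/4 at 0.5 is inclusive
  expect_false(focal_present(1))  # 1/4 falls below
  expect_error(presence_calls(match_features(mk(2)), min_frac = 0), "0, 1")
})

test_that("stage rules: triple intersection minus baseline, uniqueness, exclusion", {
  design <- treatment_design(
    microbes = c("m1", "m2"), baseline = "base",
    triples = list(m1 = list(in_vitro = "iv1", single = "s1",
                             community = "comm"),
                   m2 = list(in_vitro = "iv2", single = "s2",
                             community = "comm")),
    exclusion = list(ex1 = "m2"))
  presence <- list(
    iv1 = c(1, 2, 3, 4), s1 = c(1, 2, 4, 9), comm = c(1, 2, 3, 4, 5, 9),
    iv2 = c(5, 1), s2 = c(5, 1), base = c(4), ex1 = c(2))
  s1 <- stage1_microbe_features(design, presence, "m1")
  expect_equal(s1, c(1, 2))      # 3 absent from s1; 4 is baseline; 9 not in iv1
  s2 <- stage1_microbe_features(design, presence, "m2")
  expect_equal(s2, c(1, 5))
  uni <- stage2_unique(list(m1 = s1, m2 = s2))
  expect_equal(uni$m1, 2)        # 1 is shared, in neither unique set
  expect_equal(uni$m2, 5)
  expect_length(intersect(uni$m1, uni$m2), 0)
  expect_equal(stage3_exclusion(uni$m1, presence, "ex1"), numeric(0))
  expect_equal(stage3_exclusion(c(2, 7), presence, "ex1"), 7)
  expect_error(stage1_microbe_features(design, presence, "m3"), "m3")
  expect_error(stage1_microbe_features(design, presence["iv1"], "m1"),
               "s1|comm")
})

test_that("the community-design synthetic run reproduces the planted Venn counts", {
  d <- venn_design_spec(seed = 20260921)
  g <- gen_feature_tables(d)
  rep <- venn_report(match_features(g$tables, d$match_tol_ppm,
                                    d$match_tol_rt),
                     g$design)
  counts <- rep$counts
  expect_equal(counts$stage2[match(c("Ag47", "Ag15", "Ag54", "Ag35", "SM"),
                                   counts$microbe)],
               c(0L, 4L, 5L, 16L, 37L))
  expect_equal(counts$stage3[counts$microbe == "Ag35"], 13L)
  # planted truth from the manifest, stage by stage
  for (m in d$microbes) {
    expect_equal(counts$stage1[counts$microbe == m],
                 length(g$manifest$stage1[[m]]))
    expect_equal(counts$stage2[counts$microbe == m],
                 length(g$manifest$stage2[[m]]))
  }
})

test_that("venn attribution is invariant to input row order", {
  d <- venn_design_spec(seed = 77)
  g <- gen_feature_tables(d)
  al1 <- match_features(g$tables)
  shuffled <- g$tables[sample(nrow(g$tables)), ]
  al2 <- match_features(shuffled)
  r1 <- venn_report(al1, g$design)
  r2 <- venn_report(al2, g$design)
  expect_equal(r1$counts, r2$counts)
  expect_equal(r1$sets$stage2, r2$sets$stage2)
})

test_that("stage nesting and disjointness hold on randomized designs", {
  for (seed in c(5, 6)) {
    d <- venn_design_spec(
      unique_counts = c(Ag47 = 3L, Ag15 = 7L, Ag54 = 2L, Ag35 = 9L,
                        SM = 11L),
      shared_counts = c("Ag47:Ag15" = 4L, "Ag54:Ag35" = 3L),
      leak_counts = c(Ag35 = 2L), baseline_count = 10L, seed = seed)
    g <- gen_feature_tables(d)
    rep <- venn_report(match_features(g$tables, samples = g$samples),
                       g$design)
    for (m in d$microbes) {
      expect_true(all(rep$sets$stage2[[m]] %in% rep$sets$stage1[[m]]))
      if (!is.null(rep$sets$stage3[[m]])) {
        expect_true(all(rep$sets$stage3[[m]] %in% rep$sets$stage2[[m]]))
      }
      expect_equal(length(rep$sets$stage2[[m]]),
                   length(g$manifest$stage2[[m]]))
    }
    pairs <- utils::combn(d$microbes, 2, simplify = FALSE)
    for (pr in pairs) {
      expect_length(intersect(rep$sets$stage2[[pr[1]]],
                              rep$sets$stage2[[pr[2]]]), 0)
    }
  }
})

test_that("empty stage sets give an all-zero report", {
  d <- venn_design_spec(
    unique_counts = c(Ag47 = 0L, Ag15 = 0L, Ag54 = 0L, Ag35 = 0L, SM = 0L),
    shared_counts = c("Ag47:Ag15" = 0L), leak_counts = c(Ag35 = 0L),
    baseline_count = 5L, seed = 2)
  g <- gen_feature_tables(d)
  al <- match_features(g$tables, samples = g$samples)
  rep <- venn_report(al, g$design)
  expect_true(all(rep$counts$stage1 == 0))
  expect_true(all(rep$counts$stage2 == 0))
})
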