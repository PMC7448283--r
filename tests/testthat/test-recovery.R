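# deterministic toy table builder: one row per (nodule, strain)
toy_table <- function(spec) {
  rows <- list()
  ino <- list()
  for (tr in names(spec)) {
    ino[[tr]] <- names(spec[[tr]])
    n <- length(spec[[tr]][[1]])
    for (s in names(spec[[tr]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr, nodule_id = paste0(tr, "_n", seq_len(n)),
        strain = s, cfu = spec[[tr]][[s]], stringsAsFactors = FALSE)
    }
  }
  nodule_table(do.call(rbind, rows), ino)
}

test_that("recovery rates: 0/15 is 0%, 12/12 is 100%, 10/12 is 83.3%", {
  nt <- toy_table(list(
    sole  = list(A = rep(0, 15)),
    full  = list(A = rep(5, 12)),
    most  = list(A = c(rep(8, 10), 0, 0))))
  rr <- recovery_rates(nt)
  expect_equal(rr$rate[rr$treatment == "sole"], 0)
  expect_equal(rr$n_nodules[rr$treatment == "sole"], 15)
  expect_equal(rr$rate[rr$treatment == "full"], 100)
  expect_equal(rr$rate[rr$treatment == "most"], 83.3, tolerance = 0.01)
  expect_true(all(rr$rate >= 0 & rr$rate <= 100))
  empty <- nodule_table(data.frame(treatment = character(0),
                                   nodule_id = character(0),
                                   strain = character(0),
                                   cfu = numeric(0)), list())
  expect_error(recovery_rates(empty), "empty")
})

test_that("nodule table validates strains against the inoculum", {
  bad <- data.frame(treatment = "t1", nodule_id = "n1", strain = "B",
                    cfu = 3)
  expect_error(nodule_table(bad, list(t1 = "A")), "not in inoculum")
  neg <- data.frame(treatment = "t1", nodule_id = "n1", strain = "A",
                    cfu = -1)
  expect_error(nodule_table(neg, list(t1 = "A")), "non-negative")
})

test_that("relative recovery classifies against single-accessory baselines", {
  nt <- toy_table(list(
    single_A = list(A = rep(0, 15)),
    single_B = list(B = c(rep(4, 8), rep(0, 7))),
    pair     = list(A = c(rep(2, 10), 0, 0), B = c(rep(3, 10), 0, 0))))
  rel <- relative_recovery(recovery_rates(nt),
                           c(A = "single_A", B = "single_B"))
  base_row <- rel[rel$treatment == "single_A" & rel$strain == "A", ]
  expect_equal(base_row$delta, 0)
  expect_equal(base_row$class, "zero")
  a_pair <- rel[rel$treatment == "pair" & rel$strain == "A", ]
  expect_equal(a_pair$delta, 83.3, tolerance = 0.05)
  expect_equal(a_pair$class, "positive")
  b_pair <- rel[rel$treatment == "pair" & rel$strain == "B", ]
  expect_equal(b_pair$delta, 83.3 - 53.3, tolerance = 0.05)
  expect_error(relative_recovery(recovery_rates(nt), c(A = "single_A")),
               "baseline")
})

test_that("co-occurrence counts partition the nodules of a treatment", {
  nt <- toy_table(list(
    pair = list(A = c(rep(2, 8), 1, 1, 0, 0),
                B = c(rep(3, 8), 0, 0, 0, 0))))
  co <- cooccurrence_counts(nt, "pair")
  expect_equal(sum(co$count), 12)
  expect_equal(co$count[co$subset == "A+B"], 8)
  expect_equal(co$count[co$subset == "A"], 2)
  expect_equal(co$count[co$subset == "None"], 2)
  empty <- toy_table(list(none = list(A = rep(0, 5))))
  co0 <- cooccurrence_counts(empty, "none")
  expect_equal(co0$count[co0$subset == "None"], 5)
  expect_error(cooccurrence_counts(nt, "nope"), "unknown")
})

test_that("mean CFU uses all nodules and fold changes handle zero denominators", {
  nt <- toy_table(list(
    alone = list(A = c(400, 400, 200, 120, 280)),  # mean 280
    pair  = list(A = c(100, 100, 45, 50, 50)),                 # mean 69
    dead  = list(A = rep(0, 5))))
  cs <- cfu_summary(nt)
  m <- cs$means
  expect_equal(m$mean_cfu[m$treatment == "alone"], 280)
  expect_equal(m$mean_cfu[m$treatment == "pair"], 69)
  fc <- cs$fold_changes
  drop4 <- fc[fc$treatment_a == "alone" & fc$treatment_b == "pair", ]
  expect_equal(drop4$fold, 280 / 69, tolerance = 1e-9)
  expect_equal(round(drop4$fold, 2), 4.06)
  same <- cfu_summary(toy_table(list(
    t1 = list(A = c(10, 20)), t2 = list(A = c(10, 20)))))
  expect_equal(same$fold_changes$fold, c(1, 1))
  undef <- fc[fc$treatment_b == "dead", ]
  expect_true(all(is.na(undef$fold)))
  expect_true(all(undef$note == "undefined"))
})

test_that("interaction labels: cooperation, competition and the mixed case", {
  nt <- toy_table(list(
    single_A = list(A = c(rep(280, 9), 0, 0, 0, 0, 0)),   # 64%, high CFU
    single_B = list(B = rep(0, 15)),                      # 0%
    pair     = list(A = c(rep(69, 10), 0, 0),             # 83%, CFU down
                    B = c(rep(65, 10), 0, 0)),            # 83%, up from 0
    trio     = list(A = c(rep(9, 2), rep(0, 10)),         # collapse
                    B = c(rep(6, 1), rep(0, 11)),
                    C = c(rep(18, 3), rep(0, 9)))))
  rel <- relative_recovery(recovery_rates(nt),
                           c(A = "single_A", B = "single_B",
                             C = "trio"))
  cs <- cfu_summary(nt)
  labs <- classify_interactions(
    rel, cs, pair_treatments = list(pair = c("A", "B")),
    trio_treatments = list(trio = list(pair = "pair", added = "C")))
  expect_equal(labs$label[labs$treatment == "pair"], "mixed")
  expect_equal(labs$label[labs$treatment == "trio"], "competition")
  # cooperation when abundance rises along with recovery
  nt2 <- toy_table(list(
    single_A = list(A = c(rep(20, 9), 0, 0, 0, 0, 0)),
    single_B = list(B = rep(0, 15)),
    pair     = list(A = c(rep(200, 10), 0, 0),
                    B = c(rep(65, 10), 0, 0))))
  rel2 <- relative_recovery(recovery_rates(nt2),
                            c(A = "single_A", B = "single_B"))
  labs2 <- classify_interactions(rel2, cfu_summary(nt2),
                                 pair_treatments = list(pair = c("A", "B")))
  expect_equal(labs2$label, "cooperation")
  # missing treatments degrade to a warning, not an error
  expect_warning(
    classify_interactions(rel2, cfu_summary(nt2),
                          pair_treatments = list(ghost = c("A", "B"))),
    "missing")
})

test_that("estimated rates track Bernoulli truth within 3 binomial SEs", {
  p_true <- c(A = 0.83, B = 0.4, C = 0.05)
  cs <- colonization_spec(list(
    big = list(members = names(p_true), n_nodules = 600, p = p_true,
               cfu_mean = c(A = 100, B = 50, C = 10))), seed = 424)
  rr <- recovery_rates(gen_nodule_table(cs))
  for (s in names(p_true)) {
    se <- sqrt(p_true[[s]] * (1 - p_true[[s]]) / 600) * 100
    expect_lt(abs(rr$rate[rr$strain == s] - 100 * p_true[[s]]), 3 * se)
  }
})
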