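#' Construct a nodule isolation table
#'
#' Canonical long form of a culture-based nodule assay: one row per
#' (treatment, nodule, strain-in-inoculum) with the CFU count recovered for
#' that strain from that nodule (0 = not recovered). The per-treatment
#' inoculum (the accessory strains added alongside the nodulating symbiont)
#' is carried as an attribute and validated against the rows.
#'
#' @param records data.frame with columns `treatment`, `nodule_id`, `strain`,
#'   `cfu` (non-negative integers).
#' @param inoculum Named list: treatment label -> character vector of
#'   inoculated accessory strains.
#' @return A `nodule_table` (data.frame with an `inoculum` attribute).
#' @export
nodule_table <- function(records, inoculum) {
  need <- c("treatment", "nodule_id", "strain", "cfu")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(records$cfu < 0)) stop("CFU counts must be non-negative")
  miss_t <- setdiff(unique(records$treatment), names(inoculum))
  if (length(miss_t)) stop("no inoculum defined for treatment(s): ",
                           paste(miss_t, collapse = ", "))
  for (tr in unique(records$treatment)) {
    extra <- setdiff(unique(records$strain[records$treatment == tr]),
                     c(inoculum[[tr]], "none"))
    if (length(extra)) stop("strain(s) not in inoculum of ", tr, ": ",
                            paste(extra, collapse = ", "))
  }
  structure(as.data.frame(records), inoculum = inoculum,
            class = c("nodule_table", "data.frame"))
}

#' Read a delimited nodule table
#'
#' Columns: `treatment`, `inoculum` ('+'-separated strain list),
#' `nodule_id`, `strain`, `cfu`.
#'
#' @param path File path (tab-delimited, `#` comments allowed).
#' @return A [nodule_table()].
#' @export
read_nodule_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  ino <- lapply(split(tab$inoculum, tab$treatment),
                function(x) strsplit(x[1], "+", fixed = TRUE)[[1]])
  nodule_table(tab[, c("treatment", "nodule_id", "strain", "cfu")], ino)
}

#' Recovery rates and CFU means per treatment and strain
#'
#' Recovery rate = percentage of a treatment's nodules from which the strain
#' was re-isolated (CFU at or above `threshold`, default 1). Strains in the
#' inoculum but never recovered get rate 0. Mean CFU is taken over *all*
#' nodules of the treatment, zero-count nodules included.
#'
#' @param t A [nodule_table()].
#' @param threshold Minimum CFU counting as recovered (default 1).
#' @return data.frame `treatment`, `strain`, `n_nodules`, `n_positive`,
#'   `rate` (percent), `mean_cfu`.
#' @export
recovery_rates <- function(t, threshold = 1) {
  stopifnot(inherits(t, "nodule_table"))
  if (!nrow(t)) stop("empty nodule table")
  inoculum <- attr(t, "inoculum")
  out <- list()
  for (tr in names(inoculum)) {
    sub <- t[t$treatment == tr, , drop = FALSE]
    if (!nrow(sub)) next
    nodules <- unique(sub$nodule_id)
    for (s in inoculum[[tr]]) {
      rows <- sub[sub$strain == s, , drop = FALSE]
      pos <- unique(rows$nodule_id[rows$cfu >= threshold])
      cfu_by_nodule <- vapply(nodules, function(nd) {
        v <- rows$cfu[rows$nodule_id == nd]
        if (length(v)) sum(v) else 0
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, strain = s, n_nodules = length(nodules),
        n_positive = length(pos),
        rate = 100 * length(pos) / length(nodules),
        mean_cfu = mean(cfu_by_nodule))
    }
  }
  do.call(rbind, out)
}

#' Relative recovery against single-accessory baselines
#'
#' For each (treatment, strain), the change in recovery rate relative to the
#' treatment where that strain was the sole accessory member. Changes within
#' `zero_band` percentage points are classified `"zero"`; otherwise
#' `"positive"`/`"negative"`.
#'
#' @param summary Output of [recovery_rates()].
#' @param baseline_map Named character vector: strain -> its
#'   single-accessory treatment label.
#' @param zero_band Half-width of the zero class in percentage points
#'   (default 1).
#' @return data.frame `treatment`, `strain`, `rate`, `baseline_rate`,
#'   `delta`, `class`.
#' @export
relative_recovery <- function(summary, baseline_map, zero_band = 1) {
  miss <- setdiff(unique(summary$strain), names(baseline_map))
  if (length(miss)) stop("no baseline treatment for strain(s): ",
                         paste(miss, collapse = ", "))
  base_rate <- vapply(seq_len(nrow(summary)), function(i) {
    s <- summary$strain[i]
    b <- summary$rate[summary$treatment == baseline_map[[s]] &
                        summary$strain == s]
    if (!length(b)) stop("baseline treatment ", baseline_map[[s]],
                         " missing from summary for strain ", s)
    b
  }, numeric(1))
  delta <- summary$rate - base_rate
  cls <- ifelse(abs(delta) <= zero_band, "zero",
                ifelse(delta > 0, "positive", "negative"))
  data.frame(treatment = summary$treatment, strain = summary$strain,
             rate = summary$rate, baseline_rate = base_rate, delta = delta,
             class = cls)
}

#' Co-occurrence counts of recovered strains within one treatment
#'
#' Partitions a treatment's nodules by the exact set of strains recovered
#' from each; nodules yielding nothing fall in the `"None"` class. Counts
#' always sum to the number of nodules assayed.
#'
#' @param t A [nodule_table()].
#' @param treatment Treatment label.
#' @param threshold Minimum CFU counting as recovered (default 1).
#' @return data.frame `subset` ('+'-joined sorted strain names or `"None"`),
#'   `count`.
#' @export
cooccurrence_counts <- function(t, treatment, threshold = 1) {
  stopifnot(inherits(t, "nodule_table"))
  sub <- t[t$treatment == treatment, , drop = FALSE]
  if (!nrow(sub)) stop("unknown or empty treatment: ", treatment)
  sets <- vapply(split(sub, sub$nodule_id), function(nd) {
    rec <- sort(unique(nd$strain[nd$cfu >= threshold]))
    if (!length(rec)) "None" else paste(rec, collapse = "+")
  }, character(1))
  counts <- table(sets)
  data.frame(subset = names(counts), count = as.integer(counts),
             row.names = NULL)
}

#' Mean-CFU summary with pairwise fold changes
#'
#' Per-strain mean CFU per treatment (zeros included) and, for every ordered
#' pair of treatments sharing a strain, the ratio of means. A zero
#' denominator yields `"undefined"` rather than an error.
#'
#' @param t A [nodule_table()].
#' @return List with `means` (from [recovery_rates()], columns `treatment`,
#'   `strain`, `mean_cfu`) and `fold_changes` (data.frame `strain`,
#'   `treatment_a`, `treatment_b`, `mean_a`, `mean_b`, `fold` (numeric,
#'   `NA` when undefined), `note`).
#' @export
cfu_summary <- function(t) {
  rates <- recovery_rates(t)
  means <- rates[, c("treatment", "strain", "mean_cfu")]
  fc <- list()
  for (s in unique(means$strain)) {
    trs <- means$treatment[means$strain == s]
    if (length(trs) < 2L) next
    for (a in trs) for (b in trs) {
      if (a == b) next
      ma <- means$mean_cfu[means$treatment == a & means$strain == s]
      mb <- means$mean_cfu[means$treatment == b & means$strain == s]
      fc[[length(fc) + 1L]] <- data.frame(
        strain = s, treatment_a = a, treatment_b = b, mean_a = ma,
        mean_b = mb, fold = if (mb > 0) ma / mb else NA_real_,
        note = if (mb > 0) "" else "undefined")
    }
  }
  list(means = means,
       fold_changes = if (length(fc)) do.call(rbind, fc)
                      else data.frame())
}

#' Classify pairwise in-planta interactions
#'
#' Labels microbe pairs from their relative recovery and CFU responses:
#' `"cooperation"` when both members' recovery rises above baseline in the
#' pair treatment; `"competition"` when adding a third member depresses a
#' pair member's recovery below its pair-treatment rate; `"mixed"` when the
#' recovery and mean-CFU effects disagree (recovery up, abundance down).
#'
#' @param rel A [relative_recovery()] result covering the treatments of
#'   interest.
#' @param cfu A [cfu_summary()] result.
#' @param pair_treatments Named list: treatment label -> the two member
#'   strains of that pair treatment.
#' @param trio_treatments Named list: treatment label -> list with elements
#'   `pair` (the pair-treatment label it extends) and `added` (the third
#'   strain).
#' @param zero_band Percentage points treated as no change (default 1).
#' @return data.frame `treatment`, `members`, `label`, `detail`; treatments
#'   missing from `rel` are reported with label `"missing"` rather than
#'   failing.
#' @export
classify_interactions <- function(rel, cfu, pair_treatments,
                                  trio_treatments = list(), zero_band = 1) {
  out <- list()
  for (tr in names(pair_treatments)) {
    members <- pair_treatments[[tr]]
    sub <- rel[rel$treatment == tr & rel$strain %in% members, , drop = FALSE]
    if (nrow(sub) < length(members)) {
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, members = paste(members, collapse = "+"),
        label = "missing", detail = "treatment absent from recovery summary")
      warning("pair treatment ", tr, " missing from relative recovery")
      next
    }
    both_up <- all(sub$delta > zero_band)
    any_down <- any(sub$delta < -zero_band)
    # does any member's abundance drop while its recovery rises?
    mixed <- FALSE
    if (both_up && nrow(cfu$fold_changes)) {
      for (s in members) {
        base_tr <- unique(rel$treatment[rel$strain == s &
                                          rel$treatment != tr &
                                          rel$delta == 0])
        f <- cfu$fold_changes[cfu$fold_changes$strain == s &
                                cfu$fold_changes$treatment_a == tr &
                                cfu$fold_changes$treatment_b %in% base_tr, ]
        if (nrow(f) && any(!is.na(f$fold) & f$fold < 1)) mixed <- TRUE
      }
    }
    label <- if (both_up && mixed) "mixed"
             else if (both_up) "cooperation"
             else if (any_down) "competition"
             else "neutral"
    out[[length(out) + 1L]] <- data.frame(
      treatment = tr, members = paste(members, collapse = "+"),
      label = label,
      detail = paste0("delta=", paste(round(sub$delta, 1), collapse = "/")))
  }
  for (tr in names(trio_treatments)) {
    info <- trio_treatments[[tr]]
    members <- pair_treatments[[info$pair]]
    sub <- rel[rel$treatment == tr & rel$strain %in% members, , drop = FALSE]
    pair_sub <- rel[rel$treatment == info$pair & rel$strain %in% members, ,
                    drop = FALSE]
    if (nrow(sub) < length(members) || nrow(pair_sub) < length(members)) {
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, members = paste(c(members, info$added),
                                        collapse = "+"),
        label = "missing", detail = "treatment absent from recovery summary")
      warning("trio treatment ", tr, " incomplete in relative recovery")
      next
    }
    drop <- vapply(members, function(s) {
      sub$rate[sub$strain == s] - pair_sub$rate[pair_sub$strain == s]
    }, numeric(1))
    label <- if (any(drop < -zero_band)) "competition" else "neutral"
    out[[length(out) + 1L]] <- data.frame(
      treatment = tr,
      members = paste(c(members, paste0("+", info$added)), collapse = "+"),
      label = label,
      detail = paste0("rate change vs pair=",
                      paste(round(drop, 1), collapse = "/")))
  }
  do.call(rbind, out)
}
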