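#' Align LC-MS features across samples
#'
#' Clusters features from many samples into canonical cross-sample features
#' by single linkage under a joint m/z (ppm) and retention-time (minutes)
#' tolerance: two features are linked when both |delta m/z| and |delta RT|
#' are within tolerance, and clusters are the connected components. Each
#' cluster receives a canonical id and consensus (median) m/z and RT.
#' Clusters whose internal m/z span exceeds twice the tolerance (chaining
#' through intermediates under single linkage) are flagged.
#'
#' @param tables A data.frame (or list of data.frames, row-bound) with
#'   columns `treatment`, `replicate`, `feature_id`, `mz`, `rt`, `intensity`.
#' @param mz_tol_ppm m/z tolerance in ppm (default 10).
#' @param rt_tol RT tolerance in minutes (default 0.2).
#' @param samples Optional data.frame (`treatment`, `replicate`) enumerating
#'   every acquired sample, so samples in which nothing was detected still
#'   contribute (all-absent) columns to the presence matrix; by default only
#'   samples with at least one feature are known.
#' @return A `feature_alignment`: list with `features` (input rows plus
#'   `cluster`), `clusters` (per-cluster `cluster`, `mz`, `rt`, `n_samples`,
#'   `chained` flag) and `presence` (logical matrix, cluster x sample, sample
#'   names `treatment::replicate`).
#' @export
match_features <- function(tables, mz_tol_ppm = 10, rt_tol = 0.2,
                           samples = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(tables)) stop("need at least one feature table")
  if (mz_tol_ppm <= 0 || rt_tol <= 0) stop("tolerances must be positive")
  feat <- do.call(rbind, tables)
  need <- c("treatment", "replicate", "feature_id", "mz", "rt")
  miss <- setdiff(need, names(feat))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  stopifnot(all(feat$mz > 0), all(feat$rt >= 0))

  n <- nrow(feat)
  ord <- order(feat$mz)
  feat <- feat[ord, , drop = FALSE]
  # union-find over mz-ordered features; only a bounded mz window can link
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n) {
      dm <- feat$mz[j] - feat$mz[i]
      if (dm > mz_tol_ppm * 1e-6 * feat$mz[j]) break
      if (abs(feat$rt[j] - feat$rt[i]) <= rt_tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      j <- j + 1L
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  feat$cluster <- match(roots, sort(unique(roots)))

  agg_mz <- tapply(feat$mz, feat$cluster, stats::median)
  agg_rt <- tapply(feat$rt, feat$cluster, stats::median)
  span <- tapply(feat$mz, feat$cluster, function(x) diff(range(x)))
  cl_ids <- as.integer(names(agg_mz))
  clusters <- data.frame(
    cluster = cl_ids,
    mz = as.numeric(agg_mz), rt = as.numeric(agg_rt),
    chained = as.numeric(span) > 2 * mz_tol_ppm * 1e-6 * as.numeric(agg_mz))
  # order canonical features by consensus m/z for stable reporting
  clusters <- clusters[order(clusters$mz, clusters$rt), , drop = FALSE]
  relab <- stats::setNames(seq_len(nrow(clusters)), clusters$cluster)
  clusters$cluster <- as.integer(relab[as.character(clusters$cluster)])
  feat$cluster <- as.integer(relab[as.character(feat$cluster)])
  clusters <- clusters[order(clusters$cluster), , drop = FALSE]
  rownames(clusters) <- NULL

  sample_id <- paste(feat$treatment, feat$replicate, sep = "::")
  all_ids <- sample_id
  if (!is.null(samples)) {
    all_ids <- c(all_ids, paste(samples$treatment, samples$replicate,
                                sep = "::"))
  }
  sample_cols <- sort(unique(all_ids))
  presence <- matrix(FALSE, nrow(clusters), length(sample_cols),
                     dimnames = list(clusters$cluster, sample_cols))
  presence[cbind(feat$cluster, match(sample_id, sample_cols))] <- TRUE
  clusters$n_samples <- rowSums(presence)

  structure(list(features = feat, clusters = clusters, presence = presence),
            class = "feature_alignment")
}

#' Per-treatment presence calls from an alignment
#'
#' A canonical feature is called present in a treatment when it was detected
#' in at least `min_frac` of that treatment's replicates (inclusive).
#'
#' @param alignment A [match_features()] result.
#' @param min_frac Minimum replicate detection fraction in (0, 1]
#'   (default 0.5).
#' @return Named list mapping each treatment to the integer vector of
#'   canonical feature (cluster) ids present in it.
#' @export
presence_calls <- function(alignment, min_frac = 0.5) {
  stopifnot(inherits(alignment, "feature_alignment"))
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  samples <- colnames(alignment$presence)
  treat <- sub("::.*$", "", samples)
  out <- lapply(split(seq_along(samples), treat), function(cols) {
    frac <- rowMeans(alignment$presence[, cols, drop = FALSE])
    as.integer(rownames(alignment$presence)[frac >= min_frac])
  })
  out
}

#' Define the multi-treatment attribution design
#'
#' Describes which treatments play which role for each microbe: the in vitro
#' culture, the single-inoculation nodule and the full-community nodule, plus
#' the baseline treatment (nodules carrying only the nodulating symbiont) and
#' any exclusion communities (treatments lacking a focal microbe).
#'
#' @param microbes Character vector of microbe names.
#' @param baseline Baseline treatment label.
#' @param triples Named list: per microbe a list/vector with elements
#'   `in_vitro`, `single`, `community` (treatment labels).
#' @param exclusion Named list mapping an exclusion-community treatment label
#'   to the character vector of member microbes (the focal microbe must be
#'   absent).
#' @return A `treatment_design`.
#' @export
treatment_design <- function(microbes, baseline, triples, exclusion = list()) {
  miss <- setdiff(microbes, names(triples))
  if (length(miss)) stop("no treatment triple for: ",
                         paste(miss, collapse = ", "))
  for (m in microbes) {
    if (!all(c("in_vitro", "single", "community") %in%
             names(triples[[m]]))) {
      stop("triple for ", m, " must name in_vitro, single and community")
    }
  }
  structure(list(microbes = microbes, baseline = baseline,
                 triples = triples, exclusion = exclusion),
            class = "treatment_design")
}

#' Stage 1: features attributable to one microbe
#'
#' Features present in all three of the microbe's treatments (in vitro,
#' single inoculation, full community) but absent from the baseline nodules.
#' For the nodulating symbiont itself — whose single-inoculation treatment
#' *is* the baseline — the baseline subtraction is skipped and the plain
#' triple intersection is returned.
#'
#' @param design A [treatment_design()].
#' @param presence Output of [presence_calls()].
#' @param microbe Microbe name.
#' @return Sorted integer vector of canonical feature ids (a feature set).
#' @export
stage1_microbe_features <- function(design, presence, microbe) {
  stopifnot(inherits(design, "treatment_design"))
  if (!microbe %in% design$microbes) stop("unknown microbe: ", microbe)
  tr <- design$triples[[microbe]]
  for (role in c("in_vitro", "single", "community")) {
    if (!tr[[role]] %in% names(presence)) {
      stop("treatment not in presence calls: ", tr[[role]])
    }
  }
  s <- intersect(intersect(presence[[tr$in_vitro]], presence[[tr$single]]),
                 presence[[tr$community]])
  if (!identical(tr$single, design$baseline)) {
    if (!design$baseline %in% names(presence)) {
      stop("treatment not in presence calls: ", design$baseline)
    }
    s <- setdiff(s, presence[[design$baseline]])
  }
  sort(s)
}

#' Stage 2: features unique to each microbe
#'
#' Subtracts every other microbe's stage-1 set from each microbe's stage-1
#' set; the resulting sets are pairwise disjoint by construction.
#'
#' @param stage1 Named list of stage-1 feature sets (>= 2 microbes).
#' @return Named list of unique-feature sets.
#' @export
stage2_unique <- function(stage1) {
  if (length(stage1) < 2L) stop("need stage-1 sets for at least two microbes")
  out <- lapply(names(stage1), function(m) {
    others <- unlist(stage1[setdiff(names(stage1), m)], use.names = FALSE)
    sort(setdiff(stage1[[m]], others))
  })
  stats::setNames(out, names(stage1))
}

#' Stage 3: exclusion-community filter
#'
#' Removes from a microbe's unique set any feature observed in a community
#' that did not include that microbe; what survives cannot be explained by
#' the other members or the plant.
#'
#' @param unique_set Stage-2 feature set for the focal microbe.
#' @param presence Output of [presence_calls()].
#' @param exclusion_treatments Character vector of exclusion-community
#'   treatment labels.
#' @return Sorted integer vector of retained feature ids.
#' @export
stage3_exclusion <- function(unique_set, presence, exclusion_treatments) {
  miss <- setdiff(exclusion_treatments, names(presence))
  if (length(miss)) stop("treatment not in presence calls: ",
                         paste(miss, collapse = ", "))
  seen <- unlist(presence[exclusion_treatments], use.names = FALSE)
  sort(setdiff(unique_set, seen))
}

#' Run the full nested Venn attribution and report counts
#'
#' Convenience wrapper running stages 1-3 for every microbe in the design
#' (stage 3 only where exclusion communities are defined) and asserting the
#' nesting (stage3 within stage2 within stage1) and stage-2 disjointness
#' invariants.
#'
#' @param alignment A [match_features()] result.
#' @param design A [treatment_design()].
#' @param min_frac Replicate presence fraction (default 0.5).
#' @param stage3_microbes Microbes to take through the exclusion filter
#'   (default: all, when exclusion communities are defined).
#' @return A `venn_report`: list with `counts` (data.frame microbe, stage1,
#'   stage2, stage3), `sets` (per-microbe list of the three sets) and
#'   `features` (canonical m/z and RT per feature id, ordered by m/z).
#' @export
venn_report <- function(alignment, design, min_frac = 0.5,
                        stage3_microbes = NULL) {
  presence <- presence_calls(alignment, min_frac)
  stage1 <- lapply(stats::setNames(design$microbes, design$microbes),
                   function(m) stage1_microbe_features(design, presence, m))
  stage2 <- stage2_unique(stage1)
  if (is.null(stage3_microbes)) {
    stage3_microbes <- if (length(design$exclusion)) design$microbes
                       else character(0)
  }
  stage3 <- lapply(stats::setNames(design$microbes, design$microbes),
                   function(m) {
    if (!m %in% stage3_microbes || !length(design$exclusion)) {
      return(NULL)
    }
    excl <- names(design$exclusion)[
      !vapply(design$exclusion, function(members) m %in% members,
              logical(1))]
    if (!length(excl)) return(NULL)
    stage3_exclusion(stage2[[m]], presence, excl)
  })
  for (m in design$microbes) {  # nesting invariant
    stopifnot(all(stage2[[m]] %in% stage1[[m]]))
    if (!is.null(stage3[[m]])) stopifnot(all(stage3[[m]] %in% stage2[[m]]))
  }
  pairs <- utils::combn(design$microbes, 2, simplify = FALSE)
  for (pr in pairs) {  # stage-2 disjointness invariant
    stopifnot(!length(intersect(stage2[[pr[1]]], stage2[[pr[2]]])))
  }
  counts <- data.frame(
    microbe = design$microbes,
    stage1 = vapply(stage1, length, integer(1))[design$microbes],
    stage2 = vapply(stage2, length, integer(1))[design$microbes],
    stage3 = vapply(design$microbes, function(m)
      if (is.null(stage3[[m]])) NA_integer_ else length(stage3[[m]]),
      integer(1)),
    row.names = NULL)
  structure(list(counts = counts,
                 sets = list(stage1 = stage1, stage2 = stage2,
                             stage3 = stage3),
                 features = alignment$clusters[
                   order(alignment$clusters$mz),
                   c("cluster", "mz", "rt", "chained")]),
            class = "venn_report")
}

#' @export
print.venn_report <- function(x, ...) {
  cat("Nested Venn feature attribution\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Read a delimited LC-MS feature table
#'
#' Reads one sample's feature export (columns `feature_id`, `mz`, `rt_min`,
#' `intensity`; tab- or comma-delimited) and labels it with its treatment
#' and replicate.
#'
#' @param path File path.
#' @param treatment Treatment label.
#' @param replicate Replicate id.
#' @param sep Field separator (default tab).
#' @return A data.frame in the layout [match_features()] expects.
#' @export
read_feature_table <- function(path, treatment, replicate, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("feature_id", "mz", "rt_min", "intensity")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data.frame(treatment = treatment, replicate = replicate,
             feature_id = tab$feature_id, mz = tab$mz, rt = tab$rt_min,
             intensity = tab$intensity, stringsAsFactors = FALSE)
}
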