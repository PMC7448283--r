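# Stable child-seed derivation: one global seed expands to per-stream seeds
# by hashing the stream name, so adding a generator never perturbs the
# pseudo-random stream of another. Kept below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 31 + code) %% 2147483629
  as.integer((h * 69621 + as.numeric(seed)) %% 2147483629)
}

#' Design of a synthetic multi-treatment feature-table experiment
#'
#' Describes the planted ground truth for the nested Venn pipeline: how many
#' features are unique to each microbe, how many are shared between microbe
#' pairs, how many plant/baseline features appear in every in-planta sample,
#' and how many of a focal microbe's unique features "leak" into
#' exclusion-community samples. The defaults reproduce the five-member
#' root-nodule community design: unique counts 0/4/5/16 for the four
#' accessory microbes (Paenibacillus Ag47, P. agglomerans Ag15, Pseudomonas
#' Ag54, B. brevis Ag35), 37 for the symbiont S. meliloti, and 3 of Ag35's
#' 16 features leaked into the two communities lacking Ag35 (so 13 survive
#' the exclusion filter).
#'
#' @param microbes Character vector of microbe names; the last is treated as
#'   the nodulating symbiont whose single-inoculation treatment is the
#'   baseline.
#' @param unique_counts Named integer vector of per-microbe unique features.
#' @param shared_counts Named integer vector of per-pair shared feature
#'   counts; names `"A:B"`.
#' @param baseline_count Plant-derived features present in every in-planta
#'   sample and no in vitro sample.
#' @param leak_counts Named integer vector: features from a microbe's unique
#'   set also planted into the exclusion communities lacking it.
#' @param replicates Replicates per treatment (default 4).
#' @param mz_range,rt_range Ranges for true feature coordinates (Da /
#'   minutes); default m/z 200-2000 (the acquisition scan range) and RT 1-20.
#' @param jitter_ppm Uniform per-detection m/z jitter half-width in ppm
#'   (default 5).
#' @param rt_jitter Uniform per-detection RT jitter half-width in minutes
#'   (default 0.02).
#' @param dropout Per-replicate detection dropout probability (default 0).
#' @param match_tol_ppm,match_tol_rt The downstream matching tolerances the
#'   jitter is validated against (jitter must stay below tolerance).
#' @param seed Global seed for the generator.
#' @return A `venn_design_spec`.
#' @export
venn_design_spec <- function(
    microbes = c("Ag47", "Ag15", "Ag54", "Ag35", "SM"),
    unique_counts = c(Ag47 = 0L, Ag15 = 4L, Ag54 = 5L, Ag35 = 16L,
                      SM = 37L),
    shared_counts = c("Ag47:Ag15" = 6L, "Ag15:Ag54" = 6L,
                      "Ag54:Ag35" = 6L),
    baseline_count = 25L,
    leak_counts = c(Ag35 = 3L),
    replicates = 4L,
    mz_range = c(200, 2000), rt_range = c(1, 20),
    jitter_ppm = 5, rt_jitter = 0.02, dropout = 0,
    match_tol_ppm = 10, match_tol_rt = 0.2,
    seed = 1L) {
  stopifnot(length(microbes) >= 2L,
            all(microbes %in% names(unique_counts)),
            all(unique_counts >= 0L), baseline_count >= 0L,
            all(leak_counts >= 0L), replicates >= 1L,
            dropout >= 0, dropout < 1)
  if (jitter_ppm >= match_tol_ppm) {
    stop("m/z jitter (", jitter_ppm, " ppm) must stay below the matching ",
         "tolerance (", match_tol_ppm, " ppm)")
  }
  if (rt_jitter >= match_tol_rt) {
    stop("RT jitter must stay below the RT matching tolerance")
  }
  for (nm in names(leak_counts)) {
    if (leak_counts[[nm]] > unique_counts[[nm]]) {
      stop("cannot leak more features than ", nm, " uniquely owns")
    }
  }
  structure(list(microbes = microbes, unique_counts = unique_counts,
                 shared_counts = shared_counts,
                 baseline_count = baseline_count, leak_counts = leak_counts,
                 replicates = replicates, mz_range = mz_range,
                 rt_range = rt_range, jitter_ppm = jitter_ppm,
                 rt_jitter = rt_jitter, dropout = dropout,
                 match_tol_ppm = match_tol_ppm, match_tol_rt = match_tol_rt,
                 seed = seed),
            class = "venn_design_spec")
}

#' Treatment design implied by a synthetic Venn design
#'
#' Builds the [treatment_design()] the generated tables follow: per-microbe
#' triples (`invitro_<m>`, `single_<m>`, `community`), the
#' `single_<symbiont>` baseline, and two exclusion communities lacking the
#' focal (last accessory) microbe.
#'
#' @param d A [venn_design_spec()].
#' @return A `treatment_design`.
#' @export
design_treatments <- function(d) {
  symbiont <- d$microbes[length(d$microbes)]
  accessory <- setdiff(d$microbes, symbiont)
  focal <- accessory[length(accessory)]
  baseline <- paste0("single_", symbiont)
  triples <- lapply(stats::setNames(d$microbes, d$microbes), function(m) {
    list(in_vitro = paste0("invitro_", m),
         single = paste0("single_", m),
         community = "community")
  })
  excl <- stats::setNames(
    list(setdiff(d$microbes, focal),
         c(symbiont, setdiff(accessory, focal)[seq_len(
           min(2L, length(accessory) - 1L))])),
    c(paste0("community_no_", focal),
      paste0("subcommunity_no_", focal)))
  treatment_design(d$microbes, baseline, triples, excl)
}

#' Generate synthetic feature tables with known attribution ground truth
#'
#' Plants features according to a [venn_design_spec()] and emits per-sample
#' feature tables with per-detection m/z and RT jitter and optional replicate
#' dropout, together with a manifest recording every feature's true
#' coordinates, owner and expected stage-1/2/3 memberships. True features
#' are drawn with a minimum mutual separation of four matching tolerances so
#' that sub-tolerance jitter can never merge two planted features. Fully
#' determined by the design's seed.
#'
#' @param d A [venn_design_spec()].
#' @return List with `tables` (long data.frame: `treatment`, `replicate`,
#'   `feature_id`, `mz`, `rt`, `intensity`), `design` (the matching
#'   [treatment_design()]), `samples` (every acquired treatment x replicate,
#'   for [match_features()]'s `samples` argument), and `manifest` (list:
#'   `features` data.frame with `key`, `mz`, `rt`, `owner`, `kind`,
#'   `leaked`; `stage1`, `stage2`, `stage3` named lists of true per-microbe
#'   feature keys).
#' @export
gen_feature_tables <- function(d) {
  stopifnot(inherits(d, "venn_design_spec"))
  td <- design_treatments(d)
  symbiont <- d$microbes[length(d$microbes)]
  accessory <- setdiff(d$microbes, symbiont)
  in_planta <- c(td$baseline,
                 paste0("single_", accessory), "community",
                 names(td$exclusion))

  # --- plant true features -------------------------------------------------
  set.seed(derive_seed(d$seed, "feature-coords"))
  placed_mz <- numeric(0); placed_rt <- numeric(0)
  draw_coord <- function() {
    repeat {
      mz <- stats::runif(1, d$mz_range[1], d$mz_range[2])
      rt <- stats::runif(1, d$rt_range[1], d$rt_range[2])
      clash <- abs(placed_mz - mz) <= 4 * d$match_tol_ppm * 1e-6 * mz &
        abs(placed_rt - rt) <= 4 * d$match_tol_rt
      if (!any(clash)) {
        placed_mz <<- c(placed_mz, mz); placed_rt <<- c(placed_rt, rt)
        return(c(mz, rt))
      }
    }
  }

  feats <- list()
  add_feature <- function(owner, kind, treatments, leaked = FALSE) {
    xy <- draw_coord()
    key <- sprintf("T%04d", length(feats) + 1L)
    feats[[key]] <<- list(key = key, mz = xy[1], rt = xy[2], owner = owner,
                          kind = kind, treatments = treatments,
                          leaked = leaked)
    key
  }
  member_exclusions <- function(m) {
    names(td$exclusion)[vapply(td$exclusion, function(mem) m %in% mem,
                               logical(1))]
  }

  for (i in seq_len(d$baseline_count)) {
    add_feature("plant", "baseline", in_planta)
  }
  unique_keys <- list()
  for (m in d$microbes) {
    tr <- td$triples[[m]]
    base_tr <- unique(c(tr$in_vitro, tr$single, tr$community))
    extra <- if (m == symbiont) {
      c(paste0("single_", accessory), names(td$exclusion))
    } else {
      member_exclusions(m)
    }
    n_leak <- if (m %in% names(d$leak_counts)) d$leak_counts[[m]] else 0L
    keys <- character(0)
    for (i in seq_len(d$unique_counts[[m]])) {
      leaked <- i <= n_leak
      trs <- unique(c(base_tr, extra,
                      if (leaked) setdiff(names(td$exclusion),
                                          member_exclusions(m))))
      keys <- c(keys, add_feature(m, "unique", trs, leaked = leaked))
    }
    unique_keys[[m]] <- keys
  }
  shared_keys <- list()
  for (nm in names(d$shared_counts)) {
    pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
    trs <- unique(c(unlist(lapply(pair, function(m) {
      tr <- td$triples[[m]]
      c(tr$in_vitro, tr$single, tr$community)
    }), use.names = FALSE),
    unlist(lapply(pair, member_exclusions), use.names = FALSE)))
    keys <- vapply(seq_len(d$shared_counts[[nm]]), function(i) {
      add_feature(nm, "shared", trs)
    }, character(1))
    shared_keys[[nm]] <- keys
  }

  # --- ground-truth stage memberships -------------------------------------
  stage1 <- lapply(stats::setNames(d$microbes, d$microbes), function(m) {
    shared_m <- unlist(shared_keys[vapply(names(shared_keys), function(nm)
      m %in% strsplit(nm, ":", fixed = TRUE)[[1]], logical(1))],
      use.names = FALSE)
    sort(c(unique_keys[[m]], shared_m))
  })
  stage2 <- lapply(stats::setNames(d$microbes, d$microbes),
                   function(m) sort(unique_keys[[m]]))
  stage3 <- lapply(stats::setNames(d$microbes, d$microbes), function(m) {
    excl <- setdiff(names(td$exclusion), member_exclusions(m))
    if (!length(excl)) return(NULL)
    leaked <- vapply(feats[unique_keys[[m]]], `[[`, logical(1), "leaked")
    sort(unique_keys[[m]][!leaked])
  })

  # --- emit jittered sample tables ----------------------------------------
  set.seed(derive_seed(d$seed, "feature-tables"))
  rows <- list()
  all_treatments <- unique(c(in_planta,
                             vapply(td$triples, function(tr) tr$in_vitro,
                                    character(1))))
  for (tr in sort(all_treatments)) {
    keys <- names(feats)[vapply(feats, function(f) tr %in% f$treatments,
                                logical(1))]
    for (rep_i in seq_len(d$replicates)) {
      detected <- keys[stats::runif(length(keys)) >= d$dropout]
      if (!length(detected)) next
      mz_true <- vapply(feats[detected], `[[`, numeric(1), "mz")
      rt_true <- vapply(feats[detected], `[[`, numeric(1), "rt")
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr, replicate = paste0("r", rep_i),
        feature_id = sprintf("F%04d", seq_along(detected)),
        mz = mz_true * (1 + stats::runif(length(detected), -d$jitter_ppm,
                                         d$jitter_ppm) * 1e-6),
        rt = pmax(0, rt_true + stats::runif(length(detected), -d$rt_jitter,
                                            d$rt_jitter)),
        intensity = round(stats::rlnorm(length(detected), 10, 1)),
        stringsAsFactors = FALSE)
    }
  }
  manifest_features <- do.call(rbind, lapply(feats, function(f) {
    data.frame(key = f$key, mz = f$mz, rt = f$rt, owner = f$owner,
               kind = f$kind, leaked = f$leaked, stringsAsFactors = FALSE)
  }))
  rownames(manifest_features) <- NULL
  list(tables = do.call(rbind, rows), design = td,
       samples = expand.grid(treatment = sort(all_treatments),
                             replicate = paste0("r", seq_len(d$replicates)),
                             stringsAsFactors = FALSE),
       manifest = list(features = manifest_features, stage1 = stage1,
                       stage2 = stage2, stage3 = stage3))
}

#' Simulate an MS2 spectrum from a known peptide
#'
#' Predicts the requested fragment series with [fragment_ions()], applies
#' per-peak m/z jitter and dropout, and adds decoy peaks drawn uniformly
#' over the spectrum range but at least three matching tolerances away from
#' every true ion. The precursor is the singly protonated peptide. Intended
#' as planted ground truth for the ladder sequencer.
#'
#' @param p A linear [peptide_spec()].
#' @param series Fragment series to plant (default `"b"`).
#' @param dropout Per-peak dropout probability (default 0).
#' @param jitter_ppm Uniform m/z jitter half-width in ppm (default 0).
#' @param n_decoys Number of decoy peaks (default 0).
#' @param tol_ppm,tol_floor Matching tolerance defining the decoy exclusion
#'   zone (defaults 10 ppm / 0.002 Da).
#' @param seed Seed (required for reproducibility).
#' @return A [spectrum_record()] with attribute `truth` (the planted ion
#'   table).
#' @export
gen_ms2_spectrum <- function(p, series = "b", dropout = 0, jitter_ppm = 0,
                             n_decoys = 0L, tol_ppm = 10, tol_floor = 0.002,
                             seed = 1L) {
  stopifnot(inherits(p, "peptide_spec"))
  if (p$cyclic) stop("cyclic peptides are not supported by the simulator")
  ions <- fragment_ions(p, series = series, max_charge = 1L)
  set.seed(derive_seed(seed, "ms2-spectrum"))
  keep <- stats::runif(nrow(ions)) >= dropout
  mz <- ions$mz[keep] *
    (1 + stats::runif(sum(keep), -jitter_ppm, jitter_ppm) * 1e-6)
  intensity <- stats::runif(sum(keep), 2e3, 1e4)
  mh <- adduct_mz(peptide_neutral_mass(p), adduct_spec(1L))
  if (n_decoys > 0L) {
    lo <- 100
    hi <- mh
    guard <- function(x) {
      tol <- pmax(tol_floor, tol_ppm * 1e-6 * x)
      all(abs(ions$mz - x) > 3 * tol)
    }
    decoys <- numeric(0)
    while (length(decoys) < n_decoys) {
      x <- stats::runif(1, lo, hi)
      if (guard(x)) decoys <- c(decoys, x)
    }
    mz <- c(mz, decoys)
    intensity <- c(intensity, stats::runif(n_decoys, 1e2, 1e3))
  }
  sp <- spectrum_record(mz, intensity, precursor_mz = mh, precursor_z = 1L,
                        collision_energy = "NCE 15")
  attr(sp, "truth") <- ions[keep, , drop = FALSE]
  sp
}

#' Colonization model for synthetic nodule tables
#'
#' Per treatment: the inoculated accessory strains, the number of nodules,
#' each strain's Bernoulli colonization probability, and the target mean CFU
#' per nodule (over all nodules, zeros included). CFU counts for colonized
#' nodules are log-normal with `sdlog` spread; the conditional mean is set
#' so the overall mean matches `cfu_mean`.
#'
#' @param treatments Named list; each element a list with `members`
#'   (character), `n_nodules`, `p` (named numeric per member) and `cfu_mean`
#'   (named numeric per member; ignored where `p` is 0).
#' @param sdlog Log-scale SD of the CFU distribution (default 0.5).
#' @param seed Seed.
#' @return A `colonization_spec`.
#' @export
colonization_spec <- function(treatments, sdlog = 0.5, seed = 1L) {
  for (nm in names(treatments)) {
    tr <- treatments[[nm]]
    stopifnot(all(c("members", "n_nodules", "p") %in% names(tr)),
              all(tr$p >= 0), all(tr$p <= 1), tr$n_nodules >= 1)
  }
  structure(list(treatments = treatments, sdlog = sdlog, seed = seed),
            class = "colonization_spec")
}

#' Colonization preset emulating the key nodule treatments
#'
#' Single-accessory treatments for all four accessory strains (recovery
#' probabilities 0.40 for Ag35, 0.64 for Ag47, 0 for Ag15 and Ag54; 15
#' nodules each), the cooperative Ag47+Ag54 pair (probability 10/12 each,
#' 12 nodules, mean CFU 69 for Ag47 and 65 for Ag54), and the trio with
#' Ag35 added (Ag47 0.17, Ag54 0.11). Mean CFU of 280 for Ag47 alone.
#'
#' @param seed Seed.
#' @return A [colonization_spec()].
#' @export
nodule_colonization_preset <- function(seed = 1L) {
  colonization_spec(list(
    single_Ag35 = list(members = "Ag35", n_nodules = 15,
                       p = c(Ag35 = 0.40), cfu_mean = c(Ag35 = 150)),
    single_Ag47 = list(members = "Ag47", n_nodules = 15,
                       p = c(Ag47 = 0.64), cfu_mean = c(Ag47 = 280)),
    single_Ag15 = list(members = "Ag15", n_nodules = 15,
                       p = c(Ag15 = 0), cfu_mean = c(Ag15 = 0)),
    single_Ag54 = list(members = "Ag54", n_nodules = 15,
                       p = c(Ag54 = 0), cfu_mean = c(Ag54 = 0)),
    pair_Ag47_Ag54 = list(members = c("Ag47", "Ag54"), n_nodules = 12,
                          p = c(Ag47 = 10 / 12, Ag54 = 10 / 12),
                          cfu_mean = c(Ag47 = 69, Ag54 = 65)),
    trio_Ag47_Ag54_Ag35 = list(members = c("Ag47", "Ag54", "Ag35"),
                               n_nodules = 12,
                               p = c(Ag47 = 0.17, Ag54 = 0.11,
                                     Ag35 = 0.25),
                               cfu_mean = c(Ag47 = 20, Ag54 = 10,
                                            Ag35 = 60))),
    seed = seed)
}

#' Generate a synthetic nodule isolation table
#'
#' Per nodule and strain, colonization is Bernoulli with the spec's
#' probability; colonized nodules draw a CFU count (>= 1) from the
#' log-normal CFU model, others record 0. Fully determined by the seed.
#'
#' @param cs A [colonization_spec()].
#' @return A [nodule_table()].
#' @export
gen_nodule_table <- function(cs) {
  stopifnot(inherits(cs, "colonization_spec"))
  set.seed(derive_seed(cs$seed, "nodule-table"))
  rows <- list()
  for (nm in names(cs$treatments)) {
    tr <- cs$treatments[[nm]]
    for (nd in seq_len(tr$n_nodules)) {
      for (s in tr$members) {
        p <- tr$p[[s]]
        hit <- stats::runif(1) < p
        cfu <- 0
        if (hit) {
          overall <- tr$cfu_mean[[s]]
          mu <- log(max(overall, 1) / max(p, 1e-9)) - cs$sdlog^2 / 2
          cfu <- max(1, round(stats::rlnorm(1, mu, cs$sdlog)))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = nm, nodule_id = paste0(nm, "_n", nd), strain = s,
          cfu = cfu, stringsAsFactors = FALSE)
      }
    }
  }
  nodule_table(do.call(rbind, rows),
               lapply(cs$treatments, `[[`, "members"))
}
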