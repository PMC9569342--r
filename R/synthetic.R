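#' Configuration for the synthetic LC-MS/MS dataset generator
#'
#' The defaults encode the study-like world every pipeline stage is tested
#' against: 20 halogen substitution series (12 complete H/Cl/Br/I quartets,
#' 8 lacking the iodinated member, as observed for the ilicicolin
#' scaffolds) built on halogen-free azaphilone/ilicicolin base formulas
#' from the packaged reference library, plus 200 unrelated decoy features;
#' 2 ppm mass jitter s.d. and 5% relative envelope intensity noise
#' (consistent with a Q-ToF of stated <10 ppm accuracy); 10% spurious
#' fragment peaks; retention-time increments of +0.3/+0.6/+1.0 min for
#' Cl/Br/I over the H member, encoding the H < Cl < Br < I elution order
#' with unambiguous spacing.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical output
#'   files.
#' @param n_series number of true scaffold series.
#' @param n_full how many of them include an iodinated member.
#' @param n_decoys unrelated decoy feature count.
#' @param mass_jitter_ppm m/z jitter standard deviation, ppm.
#' @param envelope_noise relative (multiplicative log-normal) envelope
#'   intensity noise.
#' @param spurious_fraction spurious fragment peaks added per spectrum, as
#'   a fraction of `n_fragments`.
#' @param n_fragments fragment peaks per scaffold spectrum.
#' @param shared_fraction fraction of fragments identical across a
#'   scaffold's analogs (halogen lost in fragmentation).
#' @param shifted_fraction fraction shifted by the halogen mass (halogen
#'   retained); the remainder is member-specific.
#' @param rt_base_range base (H member) RT range, seconds.
#' @param rt_increments named RT increments for Cl/Br/I, seconds.
#' @param rt_noise_sd RT noise s.d., seconds (below inter-halogen spacing).
#' @param conditions named map halogen -> culture condition label.
#' @param decoy_msms_fraction fraction of decoys carrying an MS/MS scan.
#' @param envelope_min_rel,envelope_max_peaks envelope emission: keep peaks
#'   above this relative abundance, at most this many.
#' @return `generator_config` list (validated).
#' @export
generator_config <- function(seed = 42L, n_series = 20L, n_full = 12L,
                             n_decoys = 200L, mass_jitter_ppm = 2,
                             envelope_noise = 0.05,
                             spurious_fraction = 0.10, n_fragments = 12L,
                             shared_fraction = 0.6, shifted_fraction = 0.3,
                             rt_base_range = c(180, 900),
                             rt_increments = c(Cl = 18, Br = 36, I = 60),
                             rt_noise_sd = 3,
                             conditions = c(H = "PDA", Cl = "NaCl",
                                            Br = "KBr", I = "KI"),
                             decoy_msms_fraction = 0.7,
                             envelope_min_rel = 0.01,
                             envelope_max_peaks = 5L) {
  cfg <- list(seed = as.integer(seed), n_series = as.integer(n_series),
              n_full = as.integer(n_full), n_decoys = as.integer(n_decoys),
              mass_jitter_ppm = mass_jitter_ppm,
              envelope_noise = envelope_noise,
              spurious_fraction = spurious_fraction,
              n_fragments = as.integer(n_fragments),
              shared_fraction = shared_fraction,
              shifted_fraction = shifted_fraction,
              rt_base_range = rt_base_range,
              rt_increments = rt_increments, rt_noise_sd = rt_noise_sd,
              conditions = conditions,
              decoy_msms_fraction = decoy_msms_fraction,
              envelope_min_rel = envelope_min_rel,
              envelope_max_peaks = as.integer(envelope_max_peaks))
  if (cfg$n_full > cfg$n_series) {
    stop("n_full cannot exceed n_series", call. = FALSE)
  }
  if (cfg$n_full > 0L && !"I" %in% names(cfg$conditions)) {
    stop("series with iodinated members require an I (KI) condition",
         call. = FALSE)
  }
  need <- c("H", "Cl", "Br")
  if (!all(need %in% names(cfg$conditions))) {
    stop("conditions must label at least H, Cl and Br members",
         call. = FALSE)
  }
  if (any(cfg$rt_increments <= 0)) {
    stop("rt_increments must be positive (H < Cl < Br < I)", call. = FALSE)
  }
  if (cfg$shared_fraction + cfg$shifted_fraction > 1) {
    stop("shared_fraction + shifted_fraction must be <= 1", call. = FALSE)
  }
  class(cfg) <- "generator_config"
  cfg
}

# halogen-free base formulas derived from the reference library (halogens
# stripped), extended with CH2 homologs to reach the requested count
.scaffold_formulas <- function(n) {
  lib <- reference_library()
  base <- unique(vapply(lib$formula[!is.na(lib$formula)], function(f) {
    fml <- .as_formula(f)
    counts <- stats::setNames(as.integer(fml), names(fml))
    for (el in c("Cl", "Br", "I")) {
      if (el %in% names(counts)) {
        counts["H"] <- counts["H"] + counts[el]
        counts <- counts[names(counts) != el]
      }
    }
    format(chem_formula(counts))
  }, character(1)))
  base <- sort(base)
  out <- character(n)
  for (k in seq_len(n)) {
    i <- (k - 1L) %% length(base) + 1L
    extra <- (k - 1L) %/% length(base)
    f <- .as_formula(base[i])
    if (extra > 0L) {
      f <- f + chem_formula(c(C = extra, H = 2L * extra))
    }
    out[k] <- format(f)
  }
  out
}

#' Generate a synthetic feature table, MGF and ground truth
#'
#' Builds the dataset described by [generator_config()]: for every
#' scaffold x halogen member the precursor is the jittered `[M+H]+` m/z of
#' the substituted formula, the MS1 envelope is its isotopologue pattern
#' under multiplicative noise, the MS/MS spectrum shares/shifts fragments
#' across the scaffold's analogs, RT follows the halogen-size ordering,
#' and the culture condition follows the halogen (Br members only in KBr,
#' I only in KI). Decoys get random CHNO(Cl/Br) formulas, envelopes and
#' unrelated spectra.
#'
#' @param cfg `generator_config`.
#' @param dir optional output directory; when given, writes
#'   `features.csv`, `spectra.mgf` and `truth.tsv` there.
#' @return list with `features` (a [feature_table()]), `truth` (data.frame:
#'   `id`, `scaffold`, `halogen`, `formula`, `condition`, `is_decoy`) and
#'   `paths` (when `dir` given).
#' @export
generate_dataset <- function(cfg = generator_config(), dir = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  halmap <- c(Cl = 1L, Br = 2L, I = 3L)  # order only
  scaffolds <- .scaffold_formulas(cfg$n_series)
  full <- rep(c(TRUE, FALSE), c(cfg$n_full, cfg$n_series - cfg$n_full))

  feats <- list(); spectra <- list(); truth <- list()
  jitter <- function(mz) mz * (1 + stats::rnorm(length(mz)) *
                                 cfg$mass_jitter_ppm * 1e-6)

  for (s in seq_len(cfg$n_series)) {
    sid <- sprintf("S%02d", s)
    base_f <- .as_formula(scaffolds[s])
    members <- c("H", "Cl", "Br", if (full[s]) "I")
    rt_base <- stats::runif(1, cfg$rt_base_range[1], cfg$rt_base_range[2])
    prec_h <- adduct_mz(base_f)
    # scaffold fragment set, below the H precursor
    frag_mz <- sort(stats::runif(cfg$n_fragments, 60,
                                 max(150, prec_h - 40)))
    frag_int <- stats::rlnorm(cfg$n_fragments, log(1e3), 0.7)
    n_shared <- floor(cfg$shared_fraction * cfg$n_fragments)
    n_shifted <- floor(cfg$shifted_fraction * cfg$n_fragments)
    kind <- rep(c("shared", "shifted", "unique"),
                c(n_shared, n_shifted,
                  cfg$n_fragments - n_shared - n_shifted))

    for (x in members) {
      fid <- paste0(sid, "_", x)
      fml <- if (x == "H") base_f else
        substitute_halogens(base_f,
                            n_cl = as.integer(x == "Cl"),
                            n_br = as.integer(x == "Br"),
                            n_i = as.integer(x == "I"))
      theo_mz <- adduct_mz(fml)
      jit <- 1 + stats::rnorm(1) * cfg$mass_jitter_ppm * 1e-6
      mz <- theo_mz * jit
      rt <- rt_base + (if (x == "H") 0 else cfg$rt_increments[[x]]) +
        stats::rnorm(1, 0, cfg$rt_noise_sd)
      rt <- max(rt, 1)
      intensity <- stats::rlnorm(1, log(1e5), 0.8)
      pat <- isotope_pattern(fml, prune = 1e-3)
      keep <- pat$abundance >= cfg$envelope_min_rel * max(pat$abundance)
      pat <- pat[keep, , drop = FALSE]
      pat <- pat[seq_len(min(nrow(pat), cfg$envelope_max_peaks)), ,
                 drop = FALSE]
      env <- cbind(mz = (pat$mass + .proton_mass) * jit,
                   intensity = pat$abundance * intensity *
                     exp(stats::rnorm(nrow(pat), 0, cfg$envelope_noise)))
      shift_x <- if (x == "H") 0 else halogen_shift(x)
      f_mz <- frag_mz + ifelse(kind == "shifted", shift_x, 0)
      uniq <- kind == "unique"
      if (any(uniq)) {
        f_mz[uniq] <- stats::runif(sum(uniq), 60, max(150, theo_mz - 40))
      }
      f_int <- frag_int * exp(stats::rnorm(cfg$n_fragments, 0, 0.2))
      n_spur <- ceiling(cfg$spurious_fraction * cfg$n_fragments)
      f_mz <- c(f_mz + stats::rnorm(cfg$n_fragments, 0, 0.003),
                stats::runif(n_spur, 60, theo_mz - 20))
      f_int <- c(f_int, stats::rlnorm(n_spur, log(200), 0.5))
      ref <- paste0(fid, "_ms2")
      spectra[[ref]] <- ms_spectrum(f_mz, f_int, mz, rt, ref)
      feats[[fid]] <- data.frame(id = fid, mz = mz, rt = rt,
                                 intensity = intensity,
                                 condition = cfg$conditions[[x]],
                                 msms_ref = ref, stringsAsFactors = FALSE)
      feats[[fid]]$envelope <- list(env)
      truth[[fid]] <- data.frame(id = fid, scaffold = sid, halogen = x,
                                 formula = format(fml),
                                 condition = cfg$conditions[[x]],
                                 is_decoy = FALSE, stringsAsFactors = FALSE)
    }
  }

  for (d in seq_len(cfg$n_decoys)) {
    fid <- sprintf("decoy_%03d", d)
    n_c <- sample(12:32, 1)
    counts <- c(C = n_c,
                H = as.integer(round(n_c * stats::runif(1, 1.1, 1.7))),
                O = sample(0:8, 1), N = sample(0:2, 1,
                                               prob = c(0.7, 0.2, 0.1)))
    if (stats::runif(1) < 0.10) counts <- c(counts, Cl = 1L)
    if (stats::runif(1) < 0.05) counts <- c(counts, Br = 1L)
    fml <- chem_formula(counts[counts > 0])
    jit <- 1 + stats::rnorm(1) * cfg$mass_jitter_ppm * 1e-6
    mz <- adduct_mz(fml) * jit
    rt <- stats::runif(1, 60, 1100)
    intensity <- stats::rlnorm(1, log(5e4), 1)
    pat <- isotope_pattern(fml, prune = 1e-3)
    keep <- pat$abundance >= cfg$envelope_min_rel * max(pat$abundance)
    pat <- pat[keep, , drop = FALSE]
    pat <- pat[seq_len(min(nrow(pat), cfg$envelope_max_peaks)), ,
               drop = FALSE]
    env <- cbind(mz = (pat$mass + .proton_mass) * jit,
                 intensity = pat$abundance * intensity *
                   exp(stats::rnorm(nrow(pat), 0, cfg$envelope_noise)))
    ref <- NA_character_
    if (stats::runif(1) < cfg$decoy_msms_fraction) {
      ref <- paste0(fid, "_ms2")
      nf <- 10L
      spectra[[ref]] <- ms_spectrum(stats::runif(nf, 60, mz - 20),
                                    stats::rlnorm(nf, log(500), 0.8),
                                    mz, rt, ref)
    }
    feats[[fid]] <- data.frame(id = fid, mz = mz, rt = rt,
                               intensity = intensity,
                               condition = sample(unname(cfg$conditions),
                                                  1),
                               msms_ref = ref, stringsAsFactors = FALSE)
    feats[[fid]]$envelope <- list(env)
    truth[[fid]] <- data.frame(id = fid, scaffold = NA_character_,
                               halogen = NA_character_,
                               formula = format(fml),
                               condition = feats[[fid]]$condition,
                               is_decoy = TRUE, stringsAsFactors = FALSE)
  }

  fdf <- do.call(rbind, feats)
  rownames(fdf) <- NULL
  ft <- feature_table(fdf[, c("id", "mz", "rt", "intensity", "condition",
                              "envelope", "msms_ref")],
                      spectra,
                      meta = list(generator_seed = cfg$seed,
                                  config = unclass(cfg)))
  tdf <- do.call(rbind, truth)
  rownames(tdf) <- NULL
  out <- list(features = ft, truth = tdf)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(features = file.path(dir, "features.csv"),
                  mgf = file.path(dir, "spectra.mgf"),
                  truth = file.path(dir, "truth.tsv"))
    write_feature_csv(ft, paths$features)
    write_mgf(ft$spectra, paths$mgf)
    utils::write.table(tdf, paths$truth, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    out$paths <- paths
  }
  out
}

#' Compare predictions against generator ground truth
#'
#' Member-level scoring: a predicted series member `(feature, halogen)` is
#' correct when the feature is a true scaffold member, its halogen label
#' matches the truth, and the predicted series is internally consistent
#' (all non-decoy members come from one true scaffold). Series-level: a
#' predicted series is correct when its member set equals a true series'
#' full member set. With zero predictions, precision is reported as 1 with
#' zero support (and a message is emitted).
#'
#' @param series list from [find_series()] (may be empty).
#' @param truth truth data.frame from [generate_dataset()].
#' @param halogen_calls optional [classify_features()] output; adds a
#'   halogen-call confusion summary.
#' @return list with `member` (precision, recall, tp, fp, fn), `series`
#'   (precision, recall) and optionally `halogen` (confusion data.frame).
#' @export
truth_compare <- function(series, truth, halogen_calls = NULL) {
  if (!all(series_table(series)$id %in% truth$id)) {
    stop("prediction references feature ids absent from truth",
         call. = FALSE)
  }
  true_members <- truth[!truth$is_decoy, , drop = FALSE]
  pred <- series_table(series)
  if (nrow(pred) == 0L) {
    message("no predicted series; precision reported as 1 with 0 support")
    member <- list(precision = 1, recall = 0, tp = 0L, fp = 0L,
                   fn = nrow(true_members))
    ser <- list(precision = 1, recall = 0)
  } else {
    tr <- truth[match(pred$id, truth$id), ]
    # per-series modal true scaffold among non-decoy members
    series_scaffold <- tapply(tr$scaffold, pred$series_id, function(sc) {
      sc <- sc[!is.na(sc)]
      if (length(sc) == 0L) NA_character_ else
        names(sort(table(sc), decreasing = TRUE))[1]
    })
    ok <- !tr$is_decoy & tr$halogen == pred$halogen &
      !is.na(tr$scaffold) &
      tr$scaffold == series_scaffold[pred$series_id]
    ok[is.na(ok)] <- FALSE
    tp <- sum(ok); fp <- nrow(pred) - tp
    fn <- nrow(true_members) - tp
    member <- list(precision = tp / nrow(pred),
                   recall = tp / nrow(true_members), tp = tp, fp = fp,
                   fn = max(fn, 0L))
    true_sets <- tapply(true_members$id, true_members$scaffold,
                        function(x) paste(sort(x), collapse = "|"))
    pred_sets <- vapply(series, function(s)
      paste(sort(unname(s$members)), collapse = "|"), character(1))
    ser <- list(precision = mean(pred_sets %in% true_sets),
                recall = mean(true_sets %in% pred_sets))
  }
  out <- list(member = member, series = ser)
  if (!is.null(halogen_calls)) {
    m <- match(halogen_calls$id, truth$id)
    true_hal <- truth$halogen[m]
    true_cl <- as.integer(!is.na(true_hal) & true_hal == "Cl")
    true_br <- as.integer(!is.na(true_hal) & true_hal == "Br")
    # decoys may genuinely contain halogens; recover from their formulas
    dec <- truth$is_decoy[m]
    if (any(dec)) {
      for (i in which(dec)) {
        f <- .as_formula(truth$formula[m[i]])
        true_cl[i] <- if ("Cl" %in% names(f)) unclass(f)[["Cl"]] else 0L
        true_br[i] <- if ("Br" %in% names(f)) unclass(f)[["Br"]] else 0L
      }
    }
    out$halogen <- data.frame(id = halogen_calls$id,
                              true_n_cl = true_cl, true_n_br = true_br,
                              pred_n_cl = halogen_calls$n_cl,
                              pred_n_br = halogen_calls$n_br,
                              status = halogen_calls$status,
                              stringsAsFactors = FALSE)
  }
  out
}
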