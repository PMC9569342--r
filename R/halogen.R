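#' Cosine similarity between an observed MS1 envelope and a theoretical
#' isotope pattern
#'
#' The observed envelope is aligned by anchoring its base (most intense)
#' peak on a theoretical peak — tolerant to upstream monoisotopic peak
#' mispicks. Because near 1:1 doublets (bromine's M/M+2) make the observed
#' base peak ambiguous under noise, every theoretical peak with at least
#' half the maximum abundance is tried as the anchor and the best-scoring
#' alignment is kept. For each alignment, theoretical isotopologue peaks
#' are slot-matched to observed peaks within `align_tol` and the score is
#' the cosine of the two abundance vectors over the union of slots (a peak
#' missing on either side contributes zero there), so it is invariant to
#' uniform intensity scaling of the observed envelope.
#'
#' @param observed 2-column matrix (`mz`, `intensity`), nonempty.
#' @param theoretical [isotope_pattern()] (or data.frame with `mass`,
#'   `abundance`).
#' @param align_tol slot match tolerance after alignment, Da.
#' @return similarity in `[0, 1]`.
#' @export
envelope_similarity <- function(observed, theoretical, align_tol = 0.01) {
  if (is.null(observed) || nrow(observed) == 0L) {
    stop("observed envelope is empty", call. = FALSE)
  }
  obs_mz <- observed[, 1]; obs_int <- observed[, 2]
  th_m <- theoretical$mass; th_a <- theoretical$abundance
  anchors <- which(th_a >= 0.5 * max(th_a))
  best <- 0
  for (anchor in anchors) {
    offset <- obs_mz[which.max(obs_int)] - th_m[anchor]
    obs_al <- obs_mz - offset
    th_slot <- vapply(th_m, function(m) {
      d <- abs(obs_al - m)
      i <- which.min(d)
      if (d[i] <= align_tol) i else NA_integer_
    }, integer(1))
    # union of slots: every theoretical peak + every unmatched observed peak
    v_obs <- numeric(length(th_slot))
    matched <- !is.na(th_slot)
    v_obs[matched] <- obs_int[th_slot[matched]]
    v_th <- th_a
    extra <- setdiff(seq_along(obs_mz), th_slot[matched])
    if (length(extra) > 0L) {
      v_obs <- c(v_obs, obs_int[extra])
      v_th <- c(v_th, rep(0, length(extra)))
    }
    den <- sqrt(sum(v_obs^2)) * sqrt(sum(v_th^2))
    score <- if (den == 0) 0 else max(0, min(1, sum(v_obs * v_th) / den))
    best <- max(best, score)
  }
  best
}

# theoretical pattern cache: classification sweeps the same candidate
# formulas across hundreds of features
.cached_pattern <- function(formula_str, prune = 1e-3, merge_tol = 0.05) {
  key <- paste0(formula_str, "|", prune, "|", merge_tol)
  if (is.null(.halonet_env$patterns)) {
    .halonet_env$patterns <- new.env(parent = emptyenv())
  }
  p <- .halonet_env$patterns[[key]]
  if (is.null(p)) {
    p <- isotope_pattern(formula_str, prune = prune, merge_tol = merge_tol)
    .halonet_env$patterns[[key]] <- p
  }
  p
}

#' Infer chlorine/bromine content from an MS1 isotope envelope
#'
#' Scores the observed envelope against theoretical isotopologue patterns
#' of the protonated ion over a candidate `(n_cl, n_br)` grid and reports
#' the best call with its margin over the runner-up. In `formula_given`
#' mode candidates are built by halogen-for-hydrogen substitution on
#' `base_formula`; in `formula_free` mode the carbon count is estimated
#' from the M+1/M ratio (`nC ~ ratio / 0.0107`) and a generic CnH(1.5n)
#' skeleton stands in. M+1 is always modeled: at C19-C23 the 13C
#' contribution (~21-25%) rivals the 37Cl M+2 and naive M+2-only rules
#' misclassify. Iodine is monoisotopic and therefore never called from an
#' envelope.
#'
#' @param envelope 2-column `mz`/`intensity` matrix (or NULL).
#' @param mode `"formula_free"` (default) or `"formula_given"`.
#' @param base_formula neutral base formula (required in formula_given
#'   mode); its existing Cl/Br are stripped before substitution.
#' @param max_cl,max_br candidate grid bounds (defaults 3 and 2).
#' @param margin_threshold calls with best-minus-runner-up margin below
#'   this are flagged ambiguous (default 0.02 cosine units).
#' @param align_tol envelope slot tolerance, Da.
#' @return one-row data.frame: `n_cl`, `n_br`, `score`, `margin`, `status`
#'   (`confident`/`ambiguous`/`no_envelope`).
#' @export
classify_halogens <- function(envelope, mode = c("formula_free",
                                                 "formula_given"),
                              base_formula = NULL, max_cl = 3L, max_br = 2L,
                              margin_threshold = 0.02, align_tol = 0.01) {
  mode <- match.arg(mode)
  empty_call <- function(status) {
    data.frame(n_cl = NA_integer_, n_br = NA_integer_, score = NA_real_,
               margin = NA_real_, status = status,
               stringsAsFactors = FALSE)
  }
  if (is.null(envelope) || nrow(envelope) == 0L) {
    return(empty_call("no_envelope"))
  }
  if (mode == "formula_given") {
    if (is.null(base_formula)) {
      stop("formula_given mode requires base_formula", call. = FALSE)
    }
    f <- .as_formula(base_formula)
    counts <- stats::setNames(as.integer(f), names(f))
    # strip any halogens already present, restoring their hydrogens
    for (el in c("Cl", "Br", "I")) {
      if (el %in% names(counts)) {
        counts["H"] <- counts["H"] + counts[el]
        counts <- counts[names(counts) != el]
      }
    }
    skeleton <- chem_formula(counts)
  } else {
    # M+1/M from the two lowest-mass peaks (the envelope ascends in m/z and
    # starts at the monoisotopic peak)
    ratio <- if (nrow(envelope) >= 2L) {
      d <- envelope[2, 1] - envelope[1, 1]
      if (d > 0.5 && d < 1.5) envelope[2, 2] / envelope[1, 2] else NA_real_
    } else NA_real_
    n_c <- if (is.na(ratio)) 20L else max(1L, round(ratio / 0.0107))
    skeleton <- chem_formula(c(C = n_c, H = max(as.integer(round(1.5 * n_c)),
                                                max_cl + max_br)))
  }

  grid <- expand.grid(n_cl = 0:max_cl, n_br = 0:max_br,
                      KEEP.OUT.ATTRS = FALSE)
  grid$score <- NA_real_
  for (k in seq_len(nrow(grid))) {
    cand <- tryCatch(
      substitute_halogens(skeleton, grid$n_cl[k], grid$n_br[k]),
      error = function(e) NULL)
    if (is.null(cand)) next
    ion <- .cached_pattern(format(cand))
    ion <- data.frame(mass = ion$mass + .proton_mass,
                      abundance = ion$abundance)
    grid$score[k] <- envelope_similarity(envelope, ion, align_tol)
  }
  grid <- grid[!is.na(grid$score), , drop = FALSE]
  if (nrow(grid) == 0L) return(empty_call("no_envelope"))
  o <- order(-grid$score, grid$n_cl + grid$n_br)
  best <- grid[o[1], ]
  margin <- if (nrow(grid) > 1L) best$score - grid$score[o[2]] else Inf
  data.frame(n_cl = best$n_cl, n_br = best$n_br, score = best$score,
             margin = margin,
             status = if (margin < margin_threshold) "ambiguous" else
               "confident",
             stringsAsFactors = FALSE)
}

#' Classify halogen content for every feature in a table
#'
#' @param ft `feature_table`.
#' @param ... passed to [classify_halogens()].
#' @return data.frame with one row per feature: `id`, `n_cl`, `n_br`,
#'   `score`, `margin`, `status`.
#' @export
classify_features <- function(ft, ...) {
  stopifnot(inherits(ft, "feature_table"))
  calls <- lapply(seq_len(nrow(ft$features)), function(k) {
    classify_halogens(ft$features$envelope[[k]], ...)
  })
  out <- do.call(rbind, calls)
  out <- cbind(data.frame(id = ft$features$id, stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}
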