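#' Detect OSMAC halogen substitution series
#'
#' Formalizes the search for H/Cl/Br/I analog sets of one scaffold: for
#' every candidate parent feature (the putative H member), partners are
#' probed at `+halogen_shift(X)` for X in Cl, Br, I within `ppm_tol`.
#' Evidence gates per member:
#' \itemize{
#'   \item a Cl (resp. Br) member with an MS1 envelope must carry a
#'     compatible halogen call (`n_cl >= 1`, resp. `n_br >= 1`);
#'   \item an I member is exempt from envelope checks (iodine is
#'     monoisotopic) but, when `require_condition`, must have been detected
#'     in the KI culture; Br members must come from the KBr culture;
#'   \item when both members own MS/MS spectra their modified cosine to the
#'     parent must reach `min_msms_cosine`;
#'   \item retention times are expected to increase with halogen size
#'     (H < Cl < Br < I); `rt_rule = "strict"` discards violating series,
#'     `"warn"` (default) keeps them flagged, `"off"` ignores RT.
#' }
#' Parents that themselves carry a confident nonzero halogen call are not
#' used as H anchors. Series are deduplicated by member-set equality and
#' ordered by parent m/z.
#'
#' @param ft `feature_table`.
#' @param ppm_tol per-measurement mass accuracy, ppm (default 5, from the
#'   instrument's stated <10 ppm accuracy). Because a substitution link
#'   compares the difference of two measured m/z values, the window applied
#'   to each pairwise shift propagates both errors:
#'   `|observed difference - shift| <= ppm_tol * 1e-6 * (mz_a + mz_b)`.
#' @param rt_rule `"warn"`, `"strict"` or `"off"`.
#' @param min_msms_cosine minimum parent-member modified cosine when both
#'   spectra exist (default 0.5).
#' @param require_condition require Br members in KBr and I members in KI
#'   cultures (default TRUE).
#' @param halogen_calls optional precomputed [classify_features()] output;
#'   computed (formula-free) when NULL.
#' @param frag_tol fragment tolerance for the cosine gate, Da.
#' @return list of `substitution_series` objects; each has `id`, `members`
#'   (named character vector halogen -> feature id, H first), `evidence`
#'   (per-member data.frame) and `rt_ordered` flag. Also see
#'   [series_table()].
#' @export
find_series <- function(ft, ppm_tol = 5, rt_rule = c("warn", "strict",
                                                     "off"),
                        min_msms_cosine = 0.5, require_condition = TRUE,
                        halogen_calls = NULL, frag_tol = 0.02) {
  stopifnot(inherits(ft, "feature_table"))
  rt_rule <- match.arg(rt_rule)
  if (ppm_tol <= 0) stop("ppm_tol must be > 0", call. = FALSE)
  f <- ft$features
  if (is.null(halogen_calls)) halogen_calls <- classify_features(ft)
  calls <- halogen_calls[match(f$id, halogen_calls$id), , drop = FALSE]
  shifts <- stats::setNames(halogen_shift(c("Cl", "Br", "I")),
                            c("Cl", "Br", "I"))
  halogen_order <- c("H", "Cl", "Br", "I")

  # preprocess spectra once for the cosine gate
  specs <- lapply(f$id, function(id) {
    s <- feature_spectrum(ft, id)
    if (is.null(s)) NULL else preprocess_spectrum(s)
  })
  names(specs) <- f$id

  series <- list()
  for (p in seq_len(nrow(f))) {
    pc <- calls[p, ]
    if (!is.na(pc$status) && pc$status == "confident" &&
        (pc$n_cl > 0L || pc$n_br > 0L)) next
    members <- c(H = f$id[p])
    evidence <- data.frame(halogen = "H", id = f$id[p], mz = f$mz[p],
                           rt = f$rt[p], ppm = 0, cosine = NA_real_,
                           n_cl = pc$n_cl, n_br = pc$n_br,
                           call_status = pc$status,
                           condition = f$condition[p],
                           stringsAsFactors = FALSE)
    for (x in c("Cl", "Br", "I")) {
      expect_mz <- f$mz[p] + shifts[[x]]
      ppm <- ppm_error(f$mz, expect_mz)
      # each of the two m/z measurements carries up to ppm_tol error, so
      # the window on their difference propagates both
      tol_da <- ppm_tol * 1e-6 * (f$mz[p] + f$mz)
      cand <- which(abs(f$mz - expect_mz) <= tol_da & f$id != f$id[p])
      if (length(cand) == 0L) next
      cand <- cand[order(abs(ppm[cand]))]
      for (q in cand) {
        qc <- calls[q, ]
        # envelope compatibility for Cl/Br members
        if (x == "Cl" && !is.na(qc$status) && qc$status != "no_envelope" &&
            qc$n_cl < 1L) next
        if (x == "Br" && !is.na(qc$status) && qc$status != "no_envelope" &&
            qc$n_br < 1L) next
        if (require_condition) {
          if (x == "Br" && f$condition[q] != "KBr") next
          if (x == "I" && f$condition[q] != "KI") next
        }
        cosine <- NA_real_
        if (!is.null(specs[[f$id[p]]]) && !is.null(specs[[f$id[q]]])) {
          cosine <- modified_cosine(specs[[f$id[p]]], specs[[f$id[q]]],
                                    frag_tol)$score
          if (cosine < min_msms_cosine) next
        }
        members[x] <- f$id[q]
        evidence <- rbind(evidence, data.frame(
          halogen = x, id = f$id[q], mz = f$mz[q], rt = f$rt[q],
          ppm = ppm[q], cosine = cosine, n_cl = qc$n_cl, n_br = qc$n_br,
          call_status = qc$status, condition = f$condition[q],
          stringsAsFactors = FALSE))
        break
      }
    }
    if (length(members) < 2L) next
    present <- intersect(halogen_order, names(members))
    rts <- evidence$rt[match(present, evidence$halogen)]
    rt_ordered <- all(diff(rts) > 0)
    if (rt_rule == "strict" && !rt_ordered) next
    series[[length(series) + 1L]] <- structure(
      list(id = NA_character_, parent_mz = f$mz[p],
           members = members[intersect(halogen_order, names(members))],
           evidence = evidence, rt_ordered = rt_ordered),
      class = "substitution_series")
  }
  # dedupe by member-set equality, keep first (ordered by parent m/z)
  if (length(series) > 0L) {
    series <- series[order(vapply(series, `[[`, numeric(1), "parent_mz"))]
    keys <- vapply(series, function(s)
      paste(sort(unname(s$members)), collapse = "|"), character(1))
    series <- series[!duplicated(keys)]
    for (k in seq_along(series)) {
      series[[k]]$id <- sprintf("series_%03d", k)
    }
  }
  series
}

#' @export
print.substitution_series <- function(x, ...) {
  cat(sprintf("<substitution_series> %s: %s (rt_ordered=%s)\n", x$id,
              paste(names(x$members), unname(x$members), sep = "=",
                    collapse = ", "), x$rt_ordered))
  invisible(x)
}

#' Flatten a series list into a one-row-per-member table
#'
#' @param series list from [find_series()].
#' @return data.frame with `series_id`, `halogen`, `id`, `mz`, `rt`, `ppm`,
#'   `cosine`, `condition`, `rt_ordered`.
#' @export
series_table <- function(series) {
  if (length(series) == 0L) {
    return(data.frame(series_id = character(), halogen = character(),
                      id = character(), mz = numeric(), rt = numeric(),
                      ppm = numeric(), cosine = numeric(),
                      condition = character(), rt_ordered = logical()))
  }
  do.call(rbind, lapply(series, function(s) {
    ev <- s$evidence
    data.frame(series_id = s$id, halogen = ev$halogen, id = ev$id,
               mz = ev$mz, rt = ev$rt, ppm = ev$ppm, cosine = ev$cosine,
               condition = ev$condition, rt_ordered = s$rt_ordered,
               stringsAsFactors = FALSE)
  }))
}

#' Cross-reference substitution series with the molecular network
#'
#' Annotates each series with the network connected component(s) of its
#' members: `"consistent"` when all MS/MS-bearing members share one
#' component, `"split"` otherwise, `"absent"` when no member is in the
#' network.
#'
#' @param series list from [find_series()].
#' @param network `igraph` network built from the same feature table.
#' @return data.frame: one row per series with member ids, shift summary,
#'   RT order flag, component verdict and condition pattern.
#' @export
series_report <- function(series, network) {
  comp <- network_components(network)
  rows <- lapply(series, function(s) {
    ids <- unname(s$members)
    in_net <- ids %in% names(comp)
    cids <- unique(comp[ids[in_net]])
    verdict <- if (!any(in_net)) "absent" else
      if (length(cids) == 1L) "consistent" else "split"
    ev <- s$evidence
    data.frame(
      series_id = s$id,
      members = paste(names(s$members), unname(s$members), sep = "=",
                      collapse = ";"),
      n_members = length(s$members),
      max_abs_ppm = max(abs(ev$ppm)),
      rt_ordered = s$rt_ordered,
      component = if (length(cids) == 1L) as.integer(cids) else NA_integer_,
      component_check = verdict,
      conditions = paste(ev$condition, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(series_id = character(), members = character(),
               n_members = integer(), max_abs_ppm = numeric(),
               rt_ordered = logical(), component = integer(),
               component_check = character(), conditions = character())
  rownames(out) <- NULL
  out
}
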