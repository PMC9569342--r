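#' Construct a feature table
#'
#' The central container of the pipeline: one row per LC-MS feature
#' (monoisotopic `[M+H]+` m/z, retention time in seconds, intensity,
#' culture condition label, MS1 isotopologue envelope) plus an optional
#' MS/MS spectrum per feature.
#'
#' @param features data.frame with columns `id` (unique), `mz`, `rt`
#'   (seconds), `intensity`, `condition` (e.g. PDA/NaCl/KBr/KI), `envelope`
#'   (list column of 2-column `mz`/`intensity` matrices, or NULL entries)
#'   and `msms_ref` (scan id into `spectra`, or NA).
#' @param spectra named list of [ms_spectrum()] keyed by scan id.
#' @param meta provenance list (source file, generator seed, ...).
#' @return `feature_table` object.
#' @export
feature_table <- function(features, spectra = list(), meta = list()) {
  req <- c("id", "mz", "rt", "intensity", "condition", "envelope",
           "msms_ref")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(features$id)) {
    stop("feature ids must be unique", call. = FALSE)
  }
  if (any(features$rt < 0, na.rm = TRUE)) {
    stop("retention times must be >= 0", call. = FALSE)
  }
  for (k in seq_len(nrow(features))) {
    env <- features$envelope[[k]]
    if (!is.null(env) && nrow(env) > 0L &&
        abs(env[1, 1] - features$mz[k]) > 0.01) {
      stop("envelope of feature ", features$id[k],
           " does not start at its monoisotopic m/z", call. = FALSE)
    }
  }
  rownames(features) <- NULL
  structure(list(features = features, spectra = spectra, meta = meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features (%d with MS/MS)\n",
              nrow(x$features), sum(!is.na(x$features$msms_ref))))
  invisible(x)
}

#' @export
length.feature_table <- function(x) nrow(x$features)

#' Fetch the MS/MS spectrum attached to a feature
#'
#' @param ft `feature_table`.
#' @param id feature id.
#' @return `ms_spectrum` or NULL. Spectra lacking their own RT inherit the
#'   feature's.
#' @export
feature_spectrum <- function(ft, id) {
  i <- match(id, ft$features$id)
  if (is.na(i)) stop("unknown feature id: ", id, call. = FALSE)
  ref <- ft$features$msms_ref[i]
  if (is.na(ref) || !ref %in% names(ft$spectra)) return(NULL)
  s <- ft$spectra[[ref]]
  if (is.na(s$rt)) s$rt <- ft$features$rt[i]
  s
}

.serialize_envelope <- function(env) {
  if (is.null(env) || nrow(env) == 0L) return("")
  paste(sprintf("%.5f:%.4f", env[, 1], env[, 2]), collapse = ";")
}

.parse_envelope <- function(txt, id = "?") {
  if (is.na(txt) || !nzchar(txt)) return(NULL)
  parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("cannot parse envelope of feature ", id, call. = FALSE)
  }
  vals <- suppressWarnings(vapply(parts, as.numeric, numeric(2)))
  if (any(is.na(vals))) {
    stop("cannot parse envelope of feature ", id, call. = FALSE)
  }
  matrix(c(vals[1, ], vals[2, ]), ncol = 2,
         dimnames = list(NULL, c("mz", "intensity")))
}

#' Read a feature table from CSV (and optionally its MGF)
#'
#' Column contract: `id,mz,rt_s,intensity,condition,envelope,msms_ref` with
#' the envelope serialized as semicolon-delimited `mz:intensity` pairs.
#'
#' @param path CSV file path.
#' @param mgf optional MGF path with the MS/MS spectra referenced by
#'   `msms_ref`.
#' @param rt_minutes set TRUE if the file stores RT in minutes (converted
#'   to seconds on input).
#' @return `feature_table`.
#' @export
read_feature_csv <- function(path, mgf = NULL, rt_minutes = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "mz", "rt_s", "intensity", "condition", "envelope",
           "msms_ref")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$id <- as.character(df$id)
  df$msms_ref <- as.character(df$msms_ref)
  df$envelope <- as.character(df$envelope)
  df$condition <- as.character(df$condition)
  env <- lapply(seq_len(nrow(df)),
                function(k) .parse_envelope(df$envelope[k], df$id[k]))
  feats <- data.frame(id = df$id, mz = df$mz,
                      rt = if (rt_minutes) df$rt_s * 60 else df$rt_s,
                      intensity = df$intensity, condition = df$condition,
                      msms_ref = ifelse(nzchar(df$msms_ref) &
                                          !is.na(df$msms_ref),
                                        df$msms_ref, NA_character_),
                      stringsAsFactors = FALSE)
  feats$envelope <- env
  spectra <- if (!is.null(mgf)) read_mgf(mgf) else list()
  feature_table(feats, spectra, meta = list(source = path))
}

#' Write a feature table to CSV
#'
#' @param ft `feature_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(ft, path) {
  f <- ft$features
  out <- data.frame(
    id = f$id,
    mz = sprintf("%.5f", f$mz),
    rt_s = sprintf("%.3f", f$rt),
    intensity = sprintf("%.4f", f$intensity),
    condition = f$condition,
    envelope = vapply(f$envelope, .serialize_envelope, character(1)),
    msms_ref = ifelse(is.na(f$msms_ref), "", f$msms_ref),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
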