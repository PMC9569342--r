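#' Read an MGF (Mascot Generic Format) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, `RTINSECONDS` and
#' `TITLE` headers; unknown headers are ignored. A record without PEPMASS is
#' skipped with a warning; malformed block nesting is an error reporting the
#' line number.
#'
#' @param path MGF file path.
#' @return named list of [ms_spectrum()] objects (names are the TITLEs).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  block <- NULL
  start_line <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "BEGIN IONS") {
      if (in_block) stop("nested BEGIN IONS at line ", i, call. = FALSE)
      in_block <- TRUE
      start_line <- i
      block <- list(mz = numeric(), intensity = numeric(),
                    pepmass = NA_real_, rt = NA_real_, title = "")
    } else if (ln == "END IONS") {
      if (!in_block) stop("END IONS without BEGIN IONS at line ", i,
                          call. = FALSE)
      in_block <- FALSE
      if (is.na(block$pepmass)) {
        warning("record starting at line ", start_line,
                " lacks PEPMASS; skipped", call. = FALSE)
      } else {
        id <- if (nzchar(block$title)) block$title else
          paste0("scan_", length(spectra) + 1L)
        spectra[[id]] <- ms_spectrum(block$mz, block$intensity,
                                     block$pepmass, block$rt, id)
      }
    } else if (in_block && nzchar(ln)) {
      if (grepl("^PEPMASS=", ln)) {
        block$pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                             "[ \t]+")[[1]][1])
      } else if (grepl("^RTINSECONDS=", ln)) {
        block$rt <- as.numeric(sub("^RTINSECONDS=", "", ln))
      } else if (grepl("^TITLE=", ln)) {
        block$title <- sub("^TITLE=", "", ln)
      } else if (grepl("^[0-9]", ln)) {
        xy <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
        block$mz <- c(block$mz, xy[1])
        block$intensity <- c(block$intensity,
                             if (length(xy) > 1) xy[2] else 0)
      }
      # other KEY=VALUE headers ignored
    }
  }
  if (in_block) stop("unterminated BEGIN IONS block starting at line ",
                     start_line, call. = FALSE)
  spectra
}

#' Write spectra to an MGF file
#'
#' Emits TITLE, PEPMASS and RTINSECONDS headers plus the peak list; round
#' trips through [read_mgf()] losslessly at the printed precision (m/z to
#' 1e-5 Da, intensities to 1e-4).
#'
#' @param spectra list of [ms_spectrum()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$id), con)
    writeLines(sprintf("PEPMASS=%.5f", s$precursor_mz), con)
    if (!is.na(s$rt)) writeLines(sprintf("RTINSECONDS=%.3f", s$rt), con)
    if (length(s$mz) > 0L) {
      writeLines(sprintf("%.5f %.4f", s$mz, s$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
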