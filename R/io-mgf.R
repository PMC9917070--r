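# Minimal Mascot Generic Format (MGF) reader/writer for MS/MS peak lists.
# The format is plain text: BEGIN IONS / END IONS blocks with TITLE, PEPMASS
# and RTINSECONDS headers followed by "m/z intensity" pairs.

#' Write spectra to an MGF file
#'
#' @param spectra List of `ba_spectrum` objects (see [ba_spectrum()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  lines <- unlist(lapply(spectra, function(s) {
    c("BEGIN IONS",
      paste0("TITLE=", s$key),
      paste0("PEPMASS=", format(s$precursor_mz, digits = 10)),
      "CHARGE=1-",
      sprintf("%.5f %.4f", s$mz, s$intensity),
      "END IONS",
      "")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' @param path MGF path.
#' @return List of `ba_spectrum` objects keyed by their TITLE lines.
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path))
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed MGF file: unbalanced BEGIN IONS/END IONS in ", path)
  }
  lapply(seq_along(starts), function(k) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    headers <- grep("=", block, fixed = TRUE, value = TRUE)
    peaks <- block[!grepl("=", block, fixed = TRUE) & nzchar(block)]
    key <- sub("^TITLE=", "", grep("^TITLE=", headers, value = TRUE)[1])
    pm <- as.numeric(sub("^PEPMASS=", "",
                         grep("^PEPMASS=", headers, value = TRUE)[1]))
    vals <- do.call(rbind, lapply(strsplit(peaks, "[ \t]+"), as.numeric))
    if (is.null(vals)) {
      return(ba_spectrum(key, pm, numeric(0), numeric(0)))
    }
    ba_spectrum(key, pm, vals[, 1], vals[, 2])
  })
}
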