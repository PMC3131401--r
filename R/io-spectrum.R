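.spectrumMetadataFields <- c("bandwidth_hz", "transmitter_frequency_mhz",
                             "reference_ppm", "echo_time_ms",
                             "repetition_time_ms", "n_averages", "role",
                             "domain", "voxel_mm")

.metadataList <- function(spectrum) {
  g <- spectrum@geometry
  list(bandwidth_hz = spectrum@bandwidth,
       transmitter_frequency_mhz = spectrum@transmitterFrequency,
       reference_ppm = spectrum@referencePpm,
       echo_time_ms = spectrum@echoTime,
       repetition_time_ms = spectrum@repetitionTime,
       n_averages = spectrum@nAverages,
       role = spectrum@role, domain = spectrum@domain,
       voxel_mm = c(g@dimX, g@dimY, g@dimZ))
}

.spectrumFromParts <- function(meta, re, im, path) {
  miss <- setdiff(.spectrumMetadataFields, names(meta))
  if (length(miss))
    stop(sprintf("spectrum file '%s' is missing mandatory metadata: %s",
                 path, paste(miss, collapse = ", ")))
  if (!length(re)) stop("empty spectrum: no samples in ", path)
  if (length(re) != length(im))
    stop("real and imaginary arrays differ in length in ", path)
  vox <- as.numeric(meta$voxel_mm)
  Spectrum(complex(real = re, imaginary = im),
           bandwidth = meta$bandwidth_hz,
           transmitterFrequency = meta$transmitter_frequency_mhz,
           referencePpm = meta$reference_ppm,
           echoTime = meta$echo_time_ms,
           repetitionTime = meta$repetition_time_ms,
           nAverages = meta$n_averages, role = meta$role,
           domain = meta$domain, geometry = .voxelFromConfig(vox))
}

#' Read a spectrum file
#'
#' Supported dialects: the package's native self-describing JSON
#' (metadata block plus parallel real/imaginary arrays), the native CSV
#' variant (commented `# key: value` header, then `real,imag` columns), and
#' a JCAMP-DX NMR-FID subset (NTUPLES, AFFN encoding). The time/frequency
#' domain flag is taken from the file header.
#'
#' @param path file to read.
#' @param dialect `"native_json"`, `"native_csv"` or `"jcamp_dx"`; by
#'   default guessed from the file extension (.json/.csv/.jdx|.dx).
#' @return a [Spectrum-class] with all metadata populated. Missing
#'   mandatory metadata and non-numeric samples are hard errors (the latter
#'   with the offending line number for CSV).
#' @export
readSpectrum <- function(path,
                         dialect = c("auto", "native_json", "native_csv",
                                     "jcamp_dx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- switch(tolower(tools::file_ext(path)),
                      json = "native_json", csv = "native_csv",
                      jdx = "jcamp_dx", dx = "jcamp_dx",
                      stop("cannot guess dialect from extension of ", path))
  }
  switch(dialect,
         native_json = .readSpectrumJson(path),
         native_csv = .readSpectrumCsv(path),
         jcamp_dx = .readSpectrumJcamp(path))
}

#' Write a spectrum file
#'
#' Inverse of [readSpectrum()]: samples are written with 17 significant
#' digits, so a read-back reproduces the object field-by-field.
#'
#' @param spectrum a [Spectrum-class].
#' @param path output file.
#' @param dialect `"native_json"`, `"native_csv"` or `"jcamp_dx"`.
#' @return the path, invisibly.
#' @export
writeSpectrum <- function(spectrum, path,
                          dialect = c("native_json", "native_csv",
                                      "jcamp_dx")) {
  stopifnot(is(spectrum, "Spectrum"))
  validObject(spectrum)
  dialect <- match.arg(dialect)
  switch(dialect,
         native_json = .writeSpectrumJson(spectrum, path),
         native_csv = .writeSpectrumCsv(spectrum, path),
         jcamp_dx = .writeSpectrumJcamp(spectrum, path))
  invisible(path)
}

.readSpectrumJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$metadata))
    stop("spectrum file '", path, "' is missing mandatory metadata: all")
  re <- obj$real; im <- obj$imag
  if (!is.numeric(re) || !is.numeric(im))
    stop("non-numeric samples in ", path)
  .spectrumFromParts(as.list(obj$metadata), re, im, path)
}

.writeSpectrumJson <- function(spectrum, path) {
  obj <- list(format = "carnotype-spectrum", version = 1L,
              metadata = .metadataList(spectrum),
              real = Re(spectrum@samples), imag = Im(spectrum@samples))
  ok <- try(jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write spectrum to ", path)
}

.readSpectrumCsv <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      key <- m[2]; val <- trimws(m[3])
      meta[[key]] <- if (key %in% c("role", "domain")) val
        else as.numeric(strsplit(val, "[,; ]+")[[1]])
    }
  }
  body <- which(!hdr)
  body <- body[nzchar(trimws(lines[body]))]
  if (length(body) && grepl("^\\s*real\\s*,\\s*imag", lines[body[1]],
                            ignore.case = TRUE))
    body <- body[-1]
  if (!length(body)) stop("empty spectrum: no samples in ", path)
  re <- numeric(length(body)); im <- numeric(length(body))
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(lines[body[i]]), ",")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2L || anyNA(vals))
      stop(sprintf("non-numeric sample at line %d of %s", body[i], path))
    re[i] <- vals[1]; im[i] <- vals[2]
  }
  .spectrumFromParts(meta, re, im, path)
}

.writeSpectrumCsv <- function(spectrum, path) {
  meta <- .metadataList(spectrum)
  hdr <- c("# carnotype-spectrum",
           vapply(names(meta), function(k) {
             v <- meta[[k]]
             val <- if (is.numeric(v))
               paste(sprintf("%.17g", v), collapse = " ") else as.character(v)
             sprintf("# %s: %s", k, val)
           }, character(1)),
           "real,imag")
  body <- sprintf("%.17g,%.17g", Re(spectrum@samples), Im(spectrum@samples))
  ok <- try(writeLines(c(hdr, body), path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write spectrum to ", path)
}
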