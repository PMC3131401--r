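# Minimal JCAMP-DX support: the NMR FID/spectrum NTUPLES subset with AFFN
# (plain decimal) data tables, two pages (real, imaginary). Compressed ASDF
# forms (SQZ/DIF/DUP) are out of scope.

.writeSpectrumJcamp <- function(spectrum, path) {
  meta <- .metadataList(spectrum)
  n <- length(spectrum@samples)
  dataType <- if (spectrum@domain == "time") "NMR FID" else "NMR SPECTRUM"
  emitTable <- function(v, sym) {
    # X++(Y..Y): leading X is the running point index
    lines <- character(0)
    per <- 6L
    for (start in seq(1L, n, by = per)) {
      end <- min(start + per - 1L, n)
      lines <- c(lines, paste(c(sprintf("%d", start - 1L),
                                sprintf("%.17g", v[start:end])),
                              collapse = " "))
    }
    c(sprintf("##PAGE=N=%d", if (sym == "R") 1L else 2L),
      sprintf("##DATA TABLE=(X++(%s..%s)), XYDATA", sym, sym), lines)
  }
  out <- c(
    "##TITLE=carnotype spectrum",
    "##JCAMP-DX=5.00",
    sprintf("##DATA TYPE=%s", dataType),
    "##DATA CLASS=NTUPLES",
    "##ORIGIN=carnotype",
    "##OWNER=carnotype",
    sprintf("##.OBSERVE FREQUENCY=%.17g", meta$transmitter_frequency_mhz),
    sprintf("##$BANDWIDTH_HZ=%.17g", meta$bandwidth_hz),
    sprintf("##$REFERENCE_PPM=%.17g", meta$reference_ppm),
    sprintf("##$ECHO_TIME_MS=%.17g", meta$echo_time_ms),
    sprintf("##$REPETITION_TIME_MS=%.17g", meta$repetition_time_ms),
    sprintf("##$N_AVERAGES=%d", meta$n_averages),
    sprintf("##$ROLE=%s", meta$role),
    sprintf("##$DOMAIN=%s", meta$domain),
    sprintf("##$VOXEL_MM=%.17g %.17g %.17g", meta$voxel_mm[1],
            meta$voxel_mm[2], meta$voxel_mm[3]),
    sprintf("##NTUPLES=%s", dataType),
    "##VAR_NAME=INDEX, SIGNAL/REAL, SIGNAL/IMAG",
    "##SYMBOL=X,R,I",
    sprintf("##VAR_DIM=%d,%d,%d", n, n, n),
    emitTable(Re(spectrum@samples), "R"),
    emitTable(Im(spectrum@samples), "I"),
    sprintf("##END NTUPLES=%s", dataType),
    "##END=")
  ok <- try(writeLines(out, path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write spectrum to ", path)
}

.readSpectrumJcamp <- function(path) {
  lines <- readLines(path)
  ldr <- grepl("^##", lines)
  records <- list()
  for (ln in lines[ldr]) {
    m <- regmatches(ln, regexec("^##([^=]*)=(.*)$", ln))[[1]]
    if (length(m) == 3L) records[[toupper(trimws(m[2]))]] <- trimws(m[3])
  }
  num <- function(label) {
    v <- records[[label]]
    if (is.null(v)) return(NULL)
    suppressWarnings(as.numeric(strsplit(v, "[ ,]+")[[1]]))
  }
  meta <- list(bandwidth_hz = num("$BANDWIDTH_HZ"),
               transmitter_frequency_mhz = num(".OBSERVE FREQUENCY"),
               reference_ppm = num("$REFERENCE_PPM"),
               echo_time_ms = num("$ECHO_TIME_MS"),
               repetition_time_ms = num("$REPETITION_TIME_MS"),
               n_averages = num("$N_AVERAGES"),
               role = records[["$ROLE"]], domain = records[["$DOMAIN"]],
               voxel_mm = num("$VOXEL_MM"))
  meta <- meta[!vapply(meta, is.null, logical(1))]

  tabStarts <- grep("^##DATA TABLE=", lines)
  if (length(tabStarts) < 2L)
    stop("JCAMP file '", path, "' lacks the two (real, imaginary) ",
         "NTUPLES data tables")
  readTable <- function(start) {
    vals <- numeric(0)
    i <- start + 1L
    while (i <= length(lines) && !grepl("^##", lines[i])) {
      if (nzchar(trimws(lines[i]))) {
        tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
        y <- suppressWarnings(as.numeric(tok[-1]))   # first token is X
        if (anyNA(y))
          stop(sprintf("non-numeric sample at line %d of %s", i, path))
        vals <- c(vals, y)
      }
      i <- i + 1L
    }
    vals
  }
  re <- readTable(tabStarts[1])
  im <- readTable(tabStarts[2])
  .spectrumFromParts(meta, re, im, path)
}
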