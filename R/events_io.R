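#' Write an event cloud to a delimited event table
#'
#' Tab-separated text with the two log-channel columns; the sample key is
#' stored in `#key:` header comments so a round trip preserves it.
#'
#' @param cloud an `event_cloud`.
#' @param path output file path.
#' @param digits significant digits written (default full precision).
#' @export
write_events <- function(cloud, path, digits = 15) {
  stopifnot(inherits(cloud, "event_cloud"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#key:treatment=%s\treplicate=%s\tday=%s",
                     cloud$treatment, cloud$replicate, cloud$day), con)
  writeLines(paste(colnames(cloud$events), collapse = "\t"), con)
  writeLines(paste(formatC(cloud$events[, 1], digits = digits, format = "g"),
                   formatC(cloud$events[, 2], digits = digits, format = "g"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read an event cloud from a delimited table or an FCS 3.0/3.1 file
#'
#' Delimited tables are the package's own round-trippable format (see
#' [write_events()]). FCS files are read-only: the two analysis channels are
#' selected by `$PnN` short names via `channels`.
#'
#' @param path input file.
#' @param format `"auto"` (sniff), `"table"` or `"fcs"`.
#' @param channels for FCS input, length-2 character vector naming the
#'   forward-scatter and DNA-fluorescence channels to extract.
#' @return an `event_cloud`.
#' @export
read_events <- function(path, format = c("auto", "table", "fcs"),
                        channels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0) stopf("empty event file: %s", path)
  if (format == "auto") {
    magic <- readBin(path, "raw", 6)
    format <- if (identical(rawToChar(magic), "FCS3.0") ||
                  identical(rawToChar(magic), "FCS3.1")) "fcs" else "table"
  }
  if (format == "fcs") return(read_events_fcs(path, channels))
  read_events_table(path)
}

read_events_table <- function(path) {
  lines <- readLines(path)
  key <- list(treatment = NA_character_, replicate = NA, day = NA_real_)
  keyline <- grep("^#key:", lines, value = TRUE)
  if (length(keyline)) {
    for (fld in strsplit(sub("^#key:", "", keyline[1]), "\t")[[1]]) {
      kv <- strsplit(fld, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2) key[[kv[1]]] <- kv[2]
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2) stopf("no event rows in %s", path)
  header <- strsplit(body[1], "\t")[[1]]
  rows <- strsplit(body[-1], "\t")
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    stopf("%s: malformed row at line ~%d (expected %d columns)",
          path, bad[1] + 1, length(header))
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))),
              ncol = length(header), byrow = TRUE,
              dimnames = list(NULL, header))
  if (any(is.na(m))) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stopf("%s: non-numeric value in event row %d", path, bad)
  }
  day <- suppressWarnings(as.numeric(key$day))
  event_cloud(m[, 1:2, drop = FALSE], treatment = key$treatment,
              replicate = key$replicate, day = day)
}

# --- minimal FCS 3.0/3.1 reader -------------------------------------------
# HEADER: 6-byte version, 4 spaces, then three pairs of 8-byte ASCII offsets
# (TEXT begin/end, DATA begin/end, ANALYSIS begin/end). TEXT is a
# delimiter-separated keyword/value list; DATA is list-mode binary, laid out
# row-major as $TOT events x $PAR parameters with $DATATYPE F (float32),
# D (float64) or I ($PnB-bit unsigned int), byte order per $BYTEORD.
read_fcs <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 58) stopf("malformed FCS header in %s (truncated)", path)
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stopf("unsupported FCS version '%s' in %s", version, path)
  off <- function(i, j) {
    s <- trimws(rawToChar(raw[i:j]))
    if (!nzchar(s)) return(NA_real_)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stopf("malformed FCS header offsets in %s", path)
    v
  }
  tb <- off(11, 18); te <- off(19, 26)
  db <- off(27, 34); de <- off(35, 42)
  if (is.na(tb) || is.na(te) || te <= tb || te + 1 > length(raw))
    stopf("malformed FCS TEXT offsets in %s", path)
  delim <- rawToChar(raw[tb + 1])
  toks <- strsplit(rawToChar(raw[(tb + 1):(te + 1)]), delim, fixed = TRUE)[[1]]
  toks <- toks[-1]                      # leading delimiter
  if (length(toks) %% 2 == 1) toks <- c(toks, "")
  kw <- toks[seq(2, length(toks), 2)]
  names(kw) <- toupper(trimws(toks[seq(1, length(toks), 2)]))
  need <- function(k) {
    if (is.na(kw[k])) stopf("FCS file %s lacks required keyword %s", path, k)
    kw[[k]]
  }
  npar <- as.integer(need("$PAR"))
  ntot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  endian <- if (grepl("^4", byteord)) "big" else "little"
  if (is.na(db) || db == 0) db <- as.numeric(need("$BEGINDATA"))
  if (is.na(de) || de == 0) de <- as.numeric(need("$ENDDATA"))
  pnames <- vapply(seq_len(npar), function(i) {
    v <- kw[sprintf("$P%dN", i)]
    if (is.na(v)) sprintf("P%d", i) else v
  }, "")
  nvals <- npar * ntot
  data <- raw[(db + 1):(de + 1)]
  vals <- switch(dtype,
    F = readBin(data, "double", nvals, size = 4, endian = endian),
    D = readBin(data, "double", nvals, size = 8, endian = endian),
    I = {
      bits <- as.integer(kw[sprintf("$P%dB", seq_len(npar))])
      if (length(unique(bits)) != 1 || !unique(bits) %in% c(16L, 32L))
        stopf("FCS integer data in %s needs uniform $PnB of 16 or 32", path)
      readBin(data, "integer", nvals, size = unique(bits) / 8,
              signed = unique(bits) > 16, endian = endian)
    },
    stopf("unsupported FCS $DATATYPE '%s' in %s", dtype, path))
  if (length(vals) < nvals)
    stopf("FCS data segment in %s shorter than $TOT x $PAR", path)
  m <- matrix(vals[seq_len(nvals)], nrow = ntot, ncol = npar, byrow = TRUE)
  colnames(m) <- pnames
  list(data = m, keywords = kw, version = version)
}

read_events_fcs <- function(path, channels) {
  fcs <- read_fcs(path)
  avail <- colnames(fcs$data)
  if (is.null(channels)) {
    if (ncol(fcs$data) == 2) channels <- avail
    else stopf("FCS file %s has channels [%s]; select two with `channels`",
               path, paste(avail, collapse = ", "))
  }
  if (length(channels) != 2 || !all(channels %in% avail))
    stopf("channels [%s] not all present in %s; available: [%s]",
          paste(channels, collapse = ", "), path,
          paste(avail, collapse = ", "))
  m <- fcs$data[, channels, drop = FALSE]
  colnames(m) <- c("logFSC", "logDNA")
  key <- list(treatment = fcs$keywords["TREATMENT"],
              replicate = fcs$keywords["REPLICATE"],
              day = suppressWarnings(as.numeric(fcs$keywords["DAY"])))
  event_cloud(m, treatment = unname(key$treatment),
              replicate = unname(key$replicate), day = unname(key$day))
}
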