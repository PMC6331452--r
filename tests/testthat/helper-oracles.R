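# Independent oracles used by unit and acceptance tests. These deliberately
# use different algorithms from the package implementation.

# Even-odd (crossing number) point-in-polygon, the classic pnpoly algorithm.
# Vectorized over points but algorithmically independent of the package's
# convex half-plane test. Boundary behavior differs; callers use points in
# general position.
pip_crossing <- function(xy, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(xy))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > xy[, 2]) != (yj > xy[, 2])) &
      (xy[, 1] < (xj - xi) * (xy[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# First-match gate assignment by per-gate crossing-number scan.
brute_assign <- function(xy, polys) {
  assign <- rep(0L, nrow(xy))
  for (i in seq_along(polys)) {
    free <- assign == 0L
    hit <- pip_crossing(xy[free, , drop = FALSE], polys[[i]])
    assign[which(free)[hit]] <- i
  }
  assign
}

brute_hill <- function(row, threshold) {
  cnt <- 0L
  for (v in row) if (v > threshold) cnt <- cnt + 1L
  cnt
}

brute_beta <- function(row_i, row_j, threshold) {
  uniq <- 0L
  for (g in names(row_i)) {
    di <- row_i[[g]] > threshold
    dj <- row_j[[g]] > threshold
    if (di != dj) uniq <- uniq + 1L
  }
  uniq
}

brute_bray <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  as.numeric(num / den)
}

# Spearman rho via explicit average ranks + the Pearson product-moment
# formula, independent of stats::cor internals.
average_ranks <- function(v) {
  o <- order(v)
  r <- numeric(length(v))
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

brute_spearman <- function(x, y) {
  rx <- average_ranks(x); ry <- average_ranks(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Random convex polygon: convex hull of points on a jittered circle.
rand_convex_poly <- function(center, radius, nv = 6) {
  ang <- sort(runif(nv, 0, 2 * pi))
  r <- radius * runif(nv, 0.6, 1)
  pts <- cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
  pts[grDevices::chull(pts), , drop = FALSE]
}

# Minimal FCS writer, built directly from the byte layout with writeBin;
# independent of the package's reader. Produces list-mode FCS 3.0.
write_fcs_fixture <- function(path, data, channels = colnames(data),
                              datatype = "F", endian = "little",
                              keywords = character()) {
  stopifnot(ncol(data) == length(channels))
  npar <- ncol(data); ntot <- nrow(data)
  size <- switch(datatype, F = 4L, D = 8L, I = 2L)
  kw <- c("$DATATYPE", datatype,
          "$MODE", "L",
          "$BYTEORD", if (endian == "little") "1,2,3,4" else "4,3,2,1",
          "$PAR", as.character(npar),
          "$TOT", as.character(ntot))
  for (i in seq_len(npar))
    kw <- c(kw, sprintf("$P%dN", i), channels[i],
            sprintf("$P%dB", i), as.character(size * 8),
            sprintf("$P%dR", i), "262144",
            sprintf("$P%dE", i), "0,0")
  kw <- c(kw, keywords)
  delim <- "/"
  text <- paste0(delim, paste(kw, collapse = delim), delim)
  header_len <- 58L
  # pad TEXT so DATA starts at a fixed offset
  text_begin <- header_len
  text_end <- text_begin + nchar(text) - 1L
  data_begin <- text_end + 1L
  nbytes <- npar * ntot * size
  data_end <- data_begin + nbytes - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end, data_begin, data_end, 0L, 0L)
  stopifnot(nchar(header) == 58)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  flat <- as.vector(t(data))
  if (datatype == "I") writeBin(as.integer(flat), con, size = size,
                                endian = endian)
  else writeBin(as.double(flat), con, size = size, endian = endian)
  invisible(path)
}
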