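#' Gate template
#'
#' An ordered collection of named convex polygon gates in log-channel
#' coordinates, applied identically to every sample of a study so that gate
#' abundances are comparable across samples and days. Events falling in
#' overlapping gates are assigned to the FIRST matching gate in template
#' order, which keeps gate counts a partition of the gated events.
#'
#' @param gates named list of polygon vertex matrices (m x 2, m >= 3), in
#'   template order.
#' @param provenance free-text note (e.g. "manual file" or "kde-detected").
#' @return an object of class `gate_template`.
#' @export
gate_template <- function(gates, provenance = "manual") {
  if (!length(gates)) stopf("a gate template needs at least one gate")
  ids <- names(gates)
  if (is.null(ids) || any(!nzchar(ids))) stopf("all gates must be named")
  if (anyDuplicated(ids))
    stopf("duplicate gate id '%s'", ids[duplicated(ids)][1])
  gates <- lapply(seq_along(gates), function(i) {
    p <- as.matrix(gates[[i]])
    if (ncol(p) != 2 || nrow(p) < 3)
      stopf("gate '%s' needs >= 3 vertices with 2 coordinates", ids[i])
    if (any(!is.finite(p))) stopf("gate '%s' has non-finite vertices", ids[i])
    storage.mode(p) <- "double"
    ensure_ccw_convex(p, ids[i])
  })
  names(gates) <- ids
  structure(list(gates = gates, provenance = provenance),
            class = "gate_template")
}

# Normalize vertex order to counter-clockwise and verify convexity
# (cross products of consecutive edges all >= 0 after orientation).
ensure_ccw_convex <- function(p, id) {
  n <- nrow(p)
  area2 <- sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])
  if (abs(area2) < 1e-300) stopf("gate '%s' is degenerate (zero area)", id)
  if (area2 < 0) p <- p[n:1, , drop = FALSE]
  nx <- p[c(2:n, 1), ]; nnx <- p[c(3:n, 1, 2), ]
  cross <- (nx[, 1] - p[, 1]) * (nnx[, 2] - nx[, 2]) -
           (nx[, 2] - p[, 2]) * (nnx[, 1] - nx[, 1])
  tol <- -1e-12 * max(abs(p))
  if (any(cross < tol)) stopf("gate '%s' is not convex", id)
  p
}

#' @export
print.gate_template <- function(x, ...) {
  cat(sprintf("<gate_template> %d gates (%s): %s\n", length(x$gates),
              x$provenance, paste(names(x$gates), collapse = ", ")))
  invisible(x)
}

# Vectorized containment test for one convex CCW polygon: a point is inside
# iff it lies on the left of (or on) every edge. Inclusive boundary, so an
# on-edge event counts for the first gate that reaches it.
points_in_convex <- function(xy, poly) {
  n <- nrow(poly)
  inside <- rep(TRUE, nrow(xy))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- poly[j, 1] - poly[i, 1]; ey <- poly[j, 2] - poly[i, 2]
    s <- ex * (xy[, 2] - poly[i, 2]) - ey * (xy[, 1] - poly[i, 1])
    inside <- inside & (s >= 0)
    if (!any(inside)) break
  }
  inside
}

#' Apply a gate template to an event cloud
#'
#' Assigns every event to the first gate (in template order) whose polygon
#' contains it, then expresses gate counts as percent of all GATED events;
#' events outside every gate are reported separately as `ungated`.
#'
#' @param cloud an `event_cloud`.
#' @param template a `gate_template`.
#' @return a one-row `data.frame` with the sample key, one percent column
#'   per gate, `ungated` (count) and `total` (count).
#' @export
apply_template <- function(cloud, template) {
  stopifnot(inherits(cloud, "event_cloud"), inherits(template, "gate_template"))
  xy <- cloud$events
  assign <- rep(0L, nrow(xy))
  unassigned <- rep(TRUE, nrow(xy))
  for (i in seq_along(template$gates)) {
    if (!any(unassigned)) break
    idx <- which(unassigned)
    hit <- points_in_convex(xy[idx, , drop = FALSE], template$gates[[i]])
    assign[idx[hit]] <- i
    unassigned[idx[hit]] <- FALSE
  }
  counts <- tabulate(assign, nbins = length(template$gates))
  gated <- sum(counts)
  if (gated == 0)
    stopf("no events in template for sample %s/%s/day %s",
          cloud$treatment, cloud$replicate, cloud$day)
  ab <- as.list(100 * counts / gated)
  names(ab) <- names(template$gates)
  cbind(data.frame(treatment = cloud$treatment,
                   replicate = cloud$replicate,
                   day = cloud$day, stringsAsFactors = FALSE),
        as.data.frame(ab, check.names = FALSE),
        data.frame(ungated = nrow(xy) - gated, total = nrow(xy)))
}

#' Build the abundance table for a set of clouds
#'
#' @param clouds list of `event_cloud` objects (e.g. from [simulate_study()]).
#' @param template a `gate_template`.
#' @return `data.frame` with columns treatment, replicate, day, one percent
#'   column per gate, ungated and total; class `abundance_table`.
#' @export
abundance_table <- function(clouds, template) {
  rows <- lapply(clouds, apply_template, template = template)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  key <- sprintf("%s/%s/%s", tab$treatment, tab$replicate, tab$day)
  if (anyDuplicated(key)) stopf("duplicate sample keys in abundance table")
  class(tab) <- c("abundance_table", "data.frame")
  tab
}

#' Gate id columns of an abundance table
#' @param table an `abundance_table` (or compatible data.frame).
#' @return character vector of gate column names.
#' @export
gate_ids <- function(table) {
  setdiff(colnames(table), c("treatment", "replicate", "day",
                             "ungated", "total"))
}

#' Default gate template for the bundled synthetic community
#'
#' One axis-aligned square gate per default subcommunity, centered on the
#' generative cluster center with half-width `halfwidth` (about 3 cluster
#' SDs, so ~99% of a cluster's events fall inside its own gate). The same
#' template ships as plain text in `inst/extdata/default_template.tsv`.
#'
#' @param specs subcommunity specs (default [default_subcommunities()]).
#' @param halfwidth half of the square side length, log-channel units.
#' @return a `gate_template`.
#' @export
default_gate_template <- function(specs = default_subcommunities(),
                                  halfwidth = 0.45) {
  gates <- lapply(specs, function(s) {
    c <- s$center; h <- halfwidth
    cbind(c[1] + c(-h, h, h, -h), c[2] + c(-h, -h, h, h))
  })
  names(gates) <- vapply(specs, `[[`, "", "id")
  gate_template(gates, provenance = "default-synthetic")
}

#' Detect gates from pooled event density peaks
#'
#' Pools events across clouds (equal per-cloud subsampling up to `cap`),
#' evaluates a 2D Gaussian kernel density on a grid, finds local maxima
#' above `min_density` (as a fraction of the global maximum) separated by at
#' least `min_separation`, and draws one convex-hull polygon per peak around
#' the grid region above `level` x peak height (split between nearby peaks
#' by proximity). Gates are ordered by peak density, ids G1..Gm. This is the
#' automated stand-in for the study practice of setting a gate whenever a
#' new subcommunity becomes apparent.
#'
#' @param clouds list of `event_cloud` objects.
#' @param bandwidth kernel bandwidth (log-channel units) for both axes.
#' @param gridsize density grid resolution per axis.
#' @param min_density minimum peak height as fraction of the maximum density.
#' @param min_separation minimum distance between peaks (log-channel units).
#' @param level level-set fraction of each peak's height for the polygon.
#' @param cap maximum events subsampled per cloud before pooling.
#' @param seed subsampling seed.
#' @return a `gate_template` with provenance `"kde-detected"`.
#' @export
detect_gates <- function(clouds, bandwidth = 0.35, gridsize = 128,
                         min_density = 0.02, min_separation = 0.35,
                         level = 0.10, cap = 5000, seed = 1L) {
  if (inherits(clouds, "event_cloud")) clouds <- list(clouds)
  if (!length(clouds)) stopf("detect_gates needs at least one cloud")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  pooled <- do.call(rbind, lapply(clouds, function(cl) {
    ev <- cl$events
    if (nrow(ev) > cap) ev[sample.int(nrow(ev), cap), , drop = FALSE] else ev
  }))
  kde <- MASS::kde2d(pooled[, 1], pooled[, 2],
                     h = c(bandwidth, bandwidth) * 4, n = gridsize,
                     lims = c(range(pooled[, 1]) + c(-2, 2) * bandwidth,
                              range(pooled[, 2]) + c(-2, 2) * bandwidth))
  z <- kde$z
  zmax <- max(z)
  nx <- nrow(z); ny <- ncol(z)
  # local maxima on the 8-neighborhood
  pad <- matrix(-Inf, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- z
  ismax <- z >= zmax * min_density
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    ismax <- ismax & (z >= pad[2:(nx + 1) + dx, 2:(ny + 1) + dy])
  }
  pk <- which(ismax, arr.ind = TRUE)
  if (nrow(pk) == 0)
    stopf("no density peaks found; relax min_density or increase bandwidth")
  peaks <- data.frame(x = kde$x[pk[, 1]], y = kde$y[pk[, 2]],
                      h = z[pk])
  peaks <- peaks[order(-peaks$h), ]
  # enforce minimum separation, keeping the higher peak
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      d <- sqrt((peaks$x[-(1:i)] - peaks$x[i])^2 +
                (peaks$y[-(1:i)] - peaks$y[i])^2)
      keep[-(1:i)][d < min_separation] <- FALSE
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  gx <- kde$x[grid$ix]; gy <- kde$y[grid$iy]; gz <- z[as.matrix(grid)]
  # nearest-peak partition of the grid, then per-peak level set + hull
  dmat <- outer(gx, peaks$x, `-`)^2 + outer(gy, peaks$y, `-`)^2
  nearest <- max.col(-dmat)
  gates <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    sel <- nearest == i & gz >= level * peaks$h[i]
    pts <- cbind(gx[sel], gy[sel])
    if (nrow(pts) < 3) {
      # fall back to a small box around the peak
      hb <- bandwidth / 2
      pts <- cbind(peaks$x[i] + c(-hb, hb, hb, -hb),
                   peaks$y[i] + c(-hb, -hb, hb, hb))
    }
    hull <- grDevices::chull(pts)
    gates[[i]] <- pts[hull, , drop = FALSE]
  }
  names(gates) <- sprintf("G%d", seq_along(gates))
  gate_template(gates, provenance = "kde-detected")
}

#' Read / write a gate template as delimited text
#'
#' One vertex per line: `gate_id<TAB>x<TAB>y`, vertices grouped and ordered
#' per gate; blank lines and `#` comments are ignored. Gate order follows
#' first appearance.
#'
#' @param path file path.
#' @return a `gate_template`.
#' @export
read_template <- function(path) {
  if (!file.exists(path)) stopf("template file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stopf("template file %s has no vertex rows", path)
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(parts) != 3)
  if (length(bad)) stopf("%s: expected 'gate x y' on line %d", path, bad[1])
  id <- vapply(parts, `[`, "", 1)
  x <- as.numeric(vapply(parts, `[`, "", 2))
  y <- as.numeric(vapply(parts, `[`, "", 3))
  if (any(is.na(x)) || any(is.na(y)))
    stopf("%s: non-numeric vertex coordinate", path)
  order_ids <- unique(id)
  runs <- rle(id)$values
  if (anyDuplicated(runs))
    stopf("%s: vertices of gate '%s' are not contiguous (duplicate id?)",
          path, runs[duplicated(runs)][1])
  gates <- lapply(order_ids, function(g) cbind(x[id == g], y[id == g]))
  names(gates) <- order_ids
  gate_template(gates, provenance = sprintf("file:%s", basename(path)))
}

#' @rdname read_template
#' @param template a `gate_template`.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "gate_template"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gate template: gate_id\tx\ty (convex polygons, CCW)", con)
  for (g in names(template$gates)) {
    p <- template$gates[[g]]
    writeLines(sprintf("%s\t%.15g\t%.15g", g, p[, 1], p[, 2]), con)
  }
  invisible(path)
}
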