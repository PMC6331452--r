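#' Dominant subcommunities of one sample
#'
#' Gates whose relative cell abundance is STRICTLY greater than the
#' dominance threshold. The study convention uses 2.9% (cytometric
#' dominance) and 0.71% (matched to the sequencing OTU threshold).
#'
#' @param row named numeric vector of gate abundances in percent, or a
#'   one-row abundance-table slice.
#' @param threshold dominance threshold in percent (> 0).
#' @return character vector of dominant gate ids.
#' @export
dominant_set <- function(row, threshold = 2.9) {
  if (!is.numeric(threshold) || threshold <= 0)
    stopf("threshold must be > 0")
  row <- as_gate_row(row)
  names(row)[row > threshold]
}

as_gate_row <- function(row) {
  if (is.data.frame(row)) {
    if (nrow(row) != 1) stopf("expected a single abundance row")
    row <- unlist(row[gate_ids(row)])
  }
  if (is.null(names(row))) names(row) <- sprintf("G%d", seq_along(row))
  if (any(row < 0)) stopf("abundances must be non-negative")
  row
}

#' Gate-based Hill alpha-diversity of order zero
#'
#' Richness of the community fingerprint: the number of dominant gates at
#' the given threshold (Hill number D_q with q = 0 over gates passing the
#' dominance filter).
#'
#' @inheritParams dominant_set
#' @return integer count in [0, number of gates].
#' @export
hill_alpha <- function(row, threshold = 2.9) {
  length(dominant_set(row, threshold))
}

#' Intra-community beta-diversity between two sampling days
#'
#' The number of subcommunities unique to either day: the cardinality of
#' the symmetric difference of the two dominant-gate sets.
#'
#' @param row_i,row_j abundance rows sharing the same gate set.
#' @inheritParams dominant_set
#' @return integer count in [0, 2 x number of gates].
#' @export
intra_beta <- function(row_i, row_j, threshold = 2.9) {
  ri <- as_gate_row(row_i); rj <- as_gate_row(row_j)
  if (!identical(names(ri), names(rj)))
    stopf("rows have mismatched gate sets")
  a <- names(ri)[ri > threshold]; b <- names(rj)[rj > threshold]
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Bray-Curtis dissimilarity between two abundance rows
#'
#' `sum(|x - y|) / sum(x + y)`, in [0, 1].
#'
#' @inheritParams intra_beta
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(row_i, row_j) {
  ri <- as_gate_row(row_i); rj <- as_gate_row(row_j)
  if (!identical(names(ri), names(rj)))
    stopf("rows have mismatched gate sets")
  tot <- sum(ri) + sum(rj)
  if (tot == 0) stopf("Bray-Curtis undefined for two all-zero rows")
  sum(abs(ri - rj)) / tot
}

#' Bray-Curtis dissimilarity matrix of an abundance table
#'
#' @param table an `abundance_table`.
#' @return a symmetric matrix with sample keys `treatment/replicate/day` as
#'   dimnames.
#' @export
bray_curtis_matrix <- function(table) {
  g <- gate_ids(table)
  m <- as.matrix(table[, g, drop = FALSE])
  rownames(m) <- sprintf("%s/%s/%s", table$treatment, table$replicate,
                         table$day)
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  d
}

#' Diversity time series (alpha and consecutive-day beta)
#'
#' Computes per-sample alpha (Hill D0) and, within each (treatment,
#' replicate), beta between day pairs: consecutive sampling days by default,
#' or every day against a fixed reference day.
#'
#' @param table an `abundance_table`.
#' @param threshold dominance threshold in percent.
#' @param beta_mode `"consecutive"` (day-to-day, default) or `"reference"`.
#' @param reference_day reference day when `beta_mode = "reference"`.
#' @return list with `alpha` (data.frame treatment/replicate/day/alpha),
#'   `beta` (treatment/replicate/day_from/day_to/beta), the threshold, and
#'   per-treatment/day replicate `mean` and sample `sd` summaries.
#' @export
diversity_series <- function(table, threshold = 2.9,
                             beta_mode = c("consecutive", "reference"),
                             reference_day = NULL) {
  beta_mode <- match.arg(beta_mode)
  g <- gate_ids(table)
  alpha <- data.frame(treatment = table$treatment,
                      replicate = table$replicate, day = table$day,
                      alpha = vapply(seq_len(nrow(table)), function(i)
                        hill_alpha(unlist(table[i, g]), threshold), 0L))
  beta <- NULL
  for (tr in unique(table$treatment)) {
    for (rp in unique(table$replicate[table$treatment == tr])) {
      sub <- table[table$treatment == tr & table$replicate == rp, ]
      sub <- sub[order(sub$day), ]
      days <- sub$day
      if (length(days) < 2) next
      if (beta_mode == "consecutive") {
        from <- days[-length(days)]; to <- days[-1]
      } else {
        ref <- reference_day %||% days[1]
        if (!ref %in% days) stopf("reference day %g not sampled", ref)
        from <- rep(ref, sum(days != ref)); to <- days[days != ref]
      }
      b <- vapply(seq_along(from), function(k)
        intra_beta(unlist(sub[sub$day == from[k], g][1, ]),
                   unlist(sub[sub$day == to[k], g][1, ]), threshold), 0L)
      beta <- rbind(beta, data.frame(treatment = tr, replicate = rp,
                                     day_from = from, day_to = to, beta = b))
    }
  }
  summ <- function(df, value) {
    ag <- aggregate(df[[value]],
                    by = list(treatment = df$treatment,
                              day = df[[if (value == "beta") "day_to" else "day"]]),
                    FUN = function(v) c(mean = mean(v), sd = sd(v)))
    data.frame(treatment = ag$treatment, day = ag$day,
               mean = ag$x[, "mean"], sd = ag$x[, "sd"])
  }
  list(alpha = alpha, beta = beta, threshold = threshold,
       alpha_summary = summ(alpha, "alpha"),
       beta_summary = if (!is.null(beta)) summ(beta, "beta"))
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS (monotone regression) with random restarts; the
#' lowest-stress configuration wins. Seeded and reproducible. An all-zero
#' dissimilarity matrix embeds trivially at the origin with stress 0.
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal.
#' @param k embedding dimension (study convention: 2).
#' @param restarts number of random restarts (>= 1).
#' @param seed RNG seed.
#' @return list with `points` (n x k), `stress` (Kruskal stress-1 in [0,1]),
#'   `metric`, `restarts`, `seed`; class `nmds_result`.
#' @export
nmds <- function(d, k = 2, restarts = 20, seed = 1L) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stopf("dissimilarity matrix must be square and symmetric")
  if (any(diag(d) != 0)) stopf("dissimilarity matrix must have zero diagonal")
  n <- nrow(d)
  if (max(d) == 0) {
    pts <- matrix(0, n, k, dimnames = list(rownames(d), NULL))
    return(structure(list(points = pts, stress = 0, metric = "bray-curtis",
                          restarts = restarts, seed = seed),
                     class = "nmds_result"))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  dd <- stats::as.dist(d)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- if (r == 1) {
      # metric-scaling start; remaining restarts are random
      cmdscale(dd, k = k)
    } else matrix(rnorm(n * k), n, k)
    if (ncol(init) < k)
      init <- cbind(init, matrix(rnorm(n * (k - ncol(init))) * 1e-4, n))
    fit <- try(vegan::monoMDS(dd, y = init, k = k, model = "global",
                              scaling = TRUE), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stopf("NMDS failed on all restarts")
  pts <- best$points
  rownames(pts) <- rownames(d)
  structure(list(points = pts, stress = best$stress,
                 metric = "bray-curtis", restarts = restarts, seed = seed),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("<nmds> %d samples in %d dims, stress %.4f (%d restarts)\n",
              nrow(x$points), ncol(x$points), x$stress, x$restarts))
  invisible(x)
}

#' Column-wise min-max normalization of an abundance table
#'
#' Scales each gate column to [0, 1] across samples for fingerprint
#' heatmap display (cybar-style table); constant columns map to 0.5.
#'
#' @param table an `abundance_table` (>= 2 rows).
#' @return a copy of the table with gate columns rescaled.
#' @export
cybar_normalize <- function(table) {
  if (nrow(table) < 2) stopf("normalization needs at least 2 rows")
  out <- table
  for (g in gate_ids(table)) {
    v <- table[[g]]
    r <- range(v)
    out[[g]] <- if (diff(r) == 0) rep(0.5, length(v)) else
      (v - r[1]) / diff(r)
  }
  out
}
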