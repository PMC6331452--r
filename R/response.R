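#' Per-gate abundance trend slope under one treatment
#'
#' Ordinary least-squares fit of gate abundance (percent) against sampling
#' day over the analysis window, excluding the day-0 inoculum by default
#' (window 4-24 d, after the adaptation). Replicates are pooled as
#' individual points (default) or averaged per day first.
#'
#' @param table an `abundance_table`.
#' @param treatment treatment label.
#' @param gate gate id.
#' @param window numeric length-2 inclusive day window; default `c(4, 24)`.
#' @param replicates `"pool"` (default) or `"average"`.
#' @param scale `"percent"` (raw percent/day, default) or `"cybar"`
#'   (slope on the min-max-normalized table; resembles the study's printed
#'   k magnitudes, whose normalization is not fully specified).
#' @return list with `k` (slope), `intercept`, `window`, `n`, `ci95`
#'   (95% confidence interval of the slope), `scale`, `replicates`.
#' @export
gate_trend <- function(table, treatment, gate, window = c(4, 24),
                       replicates = c("pool", "average"),
                       scale = c("percent", "cybar")) {
  replicates <- match.arg(replicates)
  scale <- match.arg(scale)
  if (scale == "cybar") table <- cybar_normalize(table)
  pts <- trend_points(table, treatment, gate, window, replicates)
  if (length(unique(pts$day)) < 2)
    stopf("need >= 2 distinct days in window [%g, %g] for %s/%s",
          window[1], window[2], treatment, gate)
  fit <- lm(abundance ~ day, data = pts)
  ci <- tryCatch(suppressWarnings(confint(fit)["day", ]),
                 error = function(e) c(NA_real_, NA_real_))
  list(k = unname(coef(fit)["day"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       window = window, n = nrow(pts), ci95 = unname(ci),
       scale = scale, replicates = replicates)
}

trend_points <- function(table, treatment, gate, window, replicates) {
  if (!treatment %in% table$treatment)
    stopf("treatment '%s' not in table", treatment)
  if (!gate %in% gate_ids(table)) stopf("gate '%s' not in table", gate)
  sub <- table[table$treatment == treatment &
                 table$day >= window[1] & table$day <= window[2], ]
  pts <- data.frame(day = sub$day, abundance = sub[[gate]])
  if (replicates == "average")
    pts <- aggregate(abundance ~ day, data = pts, FUN = mean)
  pts
}

#' Spearman correlation of gate abundance with exposure duration
#'
#' Rank correlation (average ranks on ties) between abundance and sampling
#' day within the trend window, replicates pooled. Correlations with
#' `|rho| >= cutoff` (default 0.4) are flagged strong; the threshold is
#' inclusive, so rho = 0.39 at cutoff 0.4 is NOT strong. A zero-variance
#' abundance series has undefined rho and is reported as not-strong with
#' status `"undefined"`.
#'
#' @inheritParams gate_trend
#' @param cutoff strong-correlation threshold on |rho|.
#' @return list with `rho`, `strong` (logical), `status`
#'   (`"ok"`/`"undefined"`), `n`, `cutoff`.
#' @export
spearman_response <- function(table, treatment, gate, cutoff = 0.4,
                              window = c(4, 24),
                              replicates = c("pool", "average")) {
  replicates <- match.arg(replicates)
  pts <- trend_points(table, treatment, gate, window, replicates)
  if (nrow(pts) < 3) stopf("need >= 3 observations for rho (%s/%s)",
                           treatment, gate)
  if (stats::var(pts$abundance) == 0 || stats::var(pts$day) == 0)
    return(list(rho = NA_real_, strong = FALSE, status = "undefined",
                n = nrow(pts), cutoff = cutoff))
  rho <- cor(pts$day, pts$abundance, method = "spearman")
  list(rho = rho, strong = abs(rho) >= cutoff, status = "ok",
       n = nrow(pts), cutoff = cutoff)
}

#' Full per-(treatment, gate) response report
#'
#' Combines trend slopes and Spearman response flags and classifies each
#' gate as a positive marker (strong positive rho and k > 0), a negative
#' marker (strong negative rho, k < 0, and initial abundance at the window
#' start above `negative_floor`), or no marker. Marker candidacy is
#' reported per treatment; treatment specificity is reported, not filtered.
#'
#' @inheritParams gate_trend
#' @inheritParams spearman_response
#' @param negative_floor minimum replicate-mean abundance (percent) at the
#'   first window day for a gate to qualify as a negative marker; guards
#'   against flagging near-empty gates whose only way is sideways.
#' @return `data.frame` (class `response_report`) with columns treatment,
#'   gate, k, intercept, rho, strong, status, marker.
#' @export
response_report <- function(table, treatments = unique(table$treatment),
                            cutoff = 0.4, window = c(4, 24),
                            replicates = c("pool", "average"),
                            negative_floor = 1) {
  replicates <- match.arg(replicates)
  gates <- gate_ids(table)
  rows <- list()
  for (tr in treatments) {
    first_day <- min(table$day[table$treatment == tr &
                                 table$day >= window[1] &
                                 table$day <= window[2]])
    for (g in gates) {
      tr_fit <- gate_trend(table, tr, g, window, replicates)
      sp <- spearman_response(table, tr, g, cutoff, window, replicates)
      init <- mean(table[[g]][table$treatment == tr &
                                table$day == first_day])
      marker <- "none"
      if (isTRUE(sp$strong) && sp$status == "ok") {
        if (sp$rho > 0 && tr_fit$k > 0) marker <- "positive"
        if (sp$rho < 0 && tr_fit$k < 0 && init >= negative_floor)
          marker <- "negative"
      }
      rows[[length(rows) + 1]] <-
        data.frame(treatment = tr, gate = g, k = tr_fit$k,
                   intercept = tr_fit$intercept, rho = sp$rho,
                   strong = sp$strong, status = sp$status,
                   initial_abundance = init, marker = marker,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "cutoff") <- cutoff
  attr(out, "window") <- window
  attr(out, "negative_floor") <- negative_floor
  attr(out, "replicates") <- replicates
  class(out) <- c("response_report", "data.frame")
  out
}

#' Marker gate sets for sorting
#'
#' @param report a `response_report`.
#' @param treatment treatment of interest.
#' @return list with character vectors `positive` and `negative` plus the
#'   supporting report rows in `detail`.
#' @export
select_marker_gates <- function(report, treatment) {
  stopifnot(inherits(report, "response_report"))
  sub <- report[report$treatment == treatment, ]
  if (!nrow(sub)) stopf("treatment '%s' not in report", treatment)
  list(positive = sub$gate[sub$marker == "positive"],
       negative = sub$gate[sub$marker == "negative"],
       detail = sub[sub$marker != "none", ])
}

#' Fold change of a gate's abundance relative to a reference treatment
#'
#' Ratio of replicate-mean abundances at one sampling day.
#'
#' @param table an `abundance_table`.
#' @param gate gate id.
#' @param treatment,reference treatment labels.
#' @param day sampling day.
#' @return list with `fold` (ratio; `Inf` when the reference mean is zero),
#'   `status` (`"ok"` or `"infinite"`), and the two means.
#' @export
fold_change <- function(table, gate, treatment, reference, day) {
  if (!gate %in% gate_ids(table)) stopf("gate '%s' not in table", gate)
  m <- function(tr) {
    v <- table[[gate]][table$treatment == tr & table$day == day]
    if (!length(v)) stopf("no rows for %s at day %g", tr, day)
    mean(v)
  }
  num <- m(treatment); den <- m(reference)
  if (den == 0)
    return(list(fold = Inf, status = "infinite", value = num,
                reference = den))
  list(fold = num / den, status = "ok", value = num, reference = den)
}
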