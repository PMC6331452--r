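#' Subcommunity specification
#'
#' Describes one Gaussian subcommunity (cluster of cells with similar optical
#' properties) on the log-scaled 2D cytometric plane (log-FSC x log-DNA
#' fluorescence), together with its abundance dynamics: a baseline relative
#' abundance at day 4 (after adaptation to batch cultivation) and a linear
#' slope in percent/day per treatment over the analysis window.
#'
#' @param id gate label, e.g. "G4".
#' @param center numeric length-2 vector, cluster center in log-channel units.
#' @param covariance 2x2 symmetric positive-definite (or exactly zero)
#'   matrix in log-channel units squared.
#' @param baseline_abundance percent of the community at day 4 (>= 0).
#' @param trajectory named numeric vector or list mapping treatment label to
#'   a linear slope in percent/day; treatments absent from the map get slope 0.
#' @return an object of class `subcommunity_spec`.
#' @export
subcommunity_spec <- function(id, center, covariance, baseline_abundance,
                              trajectory = numeric()) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stopf("subcommunity id must be a non-empty string")
  center <- as.numeric(center)
  if (length(center) != 2 || any(!is.finite(center)))
    stopf("center of '%s' must be a finite 2-vector", id)
  covariance <- as.matrix(covariance)
  if (!all(dim(covariance) == c(2, 2)) || any(!is.finite(covariance)))
    stopf("covariance of '%s' must be a finite 2x2 matrix", id)
  if (max(abs(covariance - t(covariance))) > 1e-10)
    stopf("covariance of '%s' is not symmetric", id)
  if (max(abs(covariance)) > 0) {
    ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stopf("covariance of '%s' is not positive-definite", id)
  }
  if (!is.numeric(baseline_abundance) || baseline_abundance < 0)
    stopf("baseline_abundance of '%s' must be >= 0", id)
  trajectory <- unlist(trajectory)
  if (length(trajectory) && is.null(names(trajectory)))
    stopf("trajectory of '%s' must be named by treatment", id)
  structure(list(id = id, center = center, covariance = covariance,
                 baseline_abundance = as.numeric(baseline_abundance),
                 trajectory = trajectory),
            class = "subcommunity_spec")
}

#' Study design for a replicated treatment time series
#'
#' Defaults mirror a sequenced-batch toxicant exposure study: 5 treatments
#' (negative control, low AgNP-10, EC50 AgNP-10, EC50 AgNP-30, AgNO3 positive
#' control), triplicates, sampling every 3-4 d over 24 d, and 250,000 cells
#' measured per sample.
#'
#' @param treatments character vector of treatment labels.
#' @param replicates_per_treatment replicate count per treatment.
#' @param sampling_days strictly increasing day numbers.
#' @param events_per_sample cells per 2D dot plot.
#' @param adaptation_shift named numeric: abundance change (percent) applied
#'   between day 0 and day 4 per subcommunity; day-0 abundance is the
#'   baseline minus this shift, shared across treatments (common inoculum).
#' @param noise_concentration Dirichlet concentration for the per-replicate
#'   composition perturbation; one draw per (treatment, replicate), held
#'   constant across days. `Inf` disables replicate noise.
#' @param seed integer master seed.
#' @return an object of class `study_design`.
#' @export
study_design <- function(treatments = c("Neg", "LAg10", "EC50Ag10",
                                        "EC50Ag30", "Pos"),
                         replicates_per_treatment = 3,
                         sampling_days = c(0, 4, 7, 10, 14, 17, 21, 24),
                         events_per_sample = 250000,
                         adaptation_shift = default_adaptation_shift(),
                         noise_concentration = 200,
                         seed = 1L) {
  if (!length(treatments) || anyDuplicated(treatments))
    stopf("treatments must be non-empty and unique")
  if (!is_count(replicates_per_treatment))
    stopf("replicates_per_treatment must be a positive integer")
  sampling_days <- as.numeric(sampling_days)
  if (length(sampling_days) < 1 || any(diff(sampling_days) <= 0))
    stopf("sampling days must be strictly increasing")
  if (!is_count(events_per_sample))
    stopf("events_per_sample must be a positive integer")
  adaptation_shift <- unlist(adaptation_shift)
  if (length(adaptation_shift) && is.null(names(adaptation_shift)))
    stopf("adaptation_shift must be named by subcommunity id")
  if (!is.numeric(noise_concentration) || noise_concentration <= 0)
    stopf("noise_concentration must be positive")
  structure(list(treatments = as.character(treatments),
                 replicates_per_treatment = as.integer(replicates_per_treatment),
                 sampling_days = sampling_days,
                 events_per_sample = as.integer(events_per_sample),
                 adaptation_shift = adaptation_shift,
                 noise_concentration = noise_concentration,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Default synthetic subcommunities
#'
#' Ten Gaussian subcommunities on a 4-decade log scale, emulating the
#' qualitative structure of an AgNP disturbance study: G4 and G11 rise
#' strongly under EC50 nanoparticle treatments (G4's raw slope 2.17 %/day
#' matches abundance endpoints 3.1 -> 46.5 % over 20 d before compositional
#' renormalization), G3 and G6 decline, G8-G10 dominate the controls, and
#' G1/G2/G13 are inoculum-only subcommunities removed by the adaptation
#' shift. Baseline (day-4) abundances sum to 100%.
#'
#' @return named list of [subcommunity_spec] objects.
#' @export
default_subcommunities <- function() {
  sp <- function(id, cx, cy, s, base, traj = numeric())
    subcommunity_spec(id, c(cx, cy), diag(c(s, s)^2), base, traj)
  ec <- function(k) c(EC50Ag10 = k, EC50Ag30 = k)
  specs <- list(
    sp("G1",  2.7, 3.8,  0.14,  0.6),
    sp("G2",  3.6, 2.0,  0.14,  0.5),
    sp("G3",  0.9, 2.7,  0.16, 15,   ec(-0.50)),
    sp("G4",  2.6, 1.1,  0.15,  3.1, ec( 2.17)),
    sp("G6",  1.8, 3.3,  0.16, 19,   ec(-0.75)),
    sp("G8",  0.9, 1.3,  0.15, 22,
       c(Neg = 0.25, LAg10 = 0.25, Pos = 0.20)),
    sp("G9",  2.1, 2.2,  0.16, 21,
       c(Neg = 0.15, LAg10 = 0.15, Pos = 0.15)),
    sp("G10", 3.2, 2.9,  0.15, 17,  c(Neg = 0.10, LAg10 = 0.10)),
    sp("G11", 3.5, 0.75, 0.13,  0.8, ec( 0.375)),
    sp("G13", 0.5, 3.7,  0.14,  1.0)
  )
  names(specs) <- vapply(specs, `[[`, "", "id")
  specs
}

#' Default adaptation shift paired with [default_subcommunities()]
#'
#' Models the single large community rearrangement between inoculum (day 0)
#' and the first post-transfer sampling (day 4): the inoculum dominants
#' G1, G2 and G13 collapse (a negative shift means the gate was HIGHER at
#' day 0), the batch dominants G8-G10 were scarce in the inoculum, and G4
#' only becomes dominant after the transfer.
#' @return named numeric vector of percent shifts.
#' @export
default_adaptation_shift <- function() {
  c(G13 = -20, G1 = -9, G2 = -7.5, G8 = 14, G9 = 13, G10 = 9,
    G3 = -5, G6 = -3, G4 = 2)
}

expected_abundances <- function(specs, treatment, day, adaptation_shift) {
  base <- vapply(specs, `[[`, 0, "baseline_abundance")
  ids <- names(base)
  if (day == 0) {
    shift <- adaptation_shift[ids]
    shift[is.na(shift)] <- 0
    ab <- base - shift
  } else {
    slope <- vapply(specs, function(s) {
      k <- s$trajectory[treatment]
      if (is.na(k)) 0 else as.numeric(k)
    }, 0)
    ab <- base + slope * (day - 4)
  }
  ab <- pmax(ab, 0)
  tot <- sum(ab)
  if (tot <= 0) stopf("realized abundances sum to %g at day %g (%s)",
                      tot, day, treatment)
  100 * ab / tot
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Per-replicate composition perturbation: one Dirichlet draw per
# (treatment, replicate), seeded independently of the per-day event stream.
replicate_perturbation <- function(design, specs, treatment, replicate) {
  base <- vapply(specs, `[[`, 0, "baseline_abundance")
  if (!is.finite(design$noise_concentration)) return(base)
  rs <- derive_seed(design$seed, "repnoise", treatment, replicate)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rs)
  p <- base / sum(base)
  out <- 100 * rdirichlet1(design$noise_concentration * p)
  names(out) <- names(base)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

realized_abundances <- function(design, specs, treatment, replicate, day) {
  if (!treatment %in% design$treatments)
    stopf("unknown treatment '%s'", treatment)
  base <- replicate_perturbation(design, specs, treatment, replicate)
  ids <- names(base)
  if (day == 0) {
    shift <- design$adaptation_shift[ids]
    shift[is.na(shift)] <- 0
    ab <- base - shift
  } else {
    slope <- vapply(specs, function(s) {
      k <- s$trajectory[treatment]
      if (is.na(k)) 0 else as.numeric(k)
    }, 0)
    ab <- base + slope * (day - 4)
  }
  ab <- pmax(ab, 0)
  tot <- sum(ab)
  if (tot <= 0)
    stopf("realized abundances sum to %g for %s/r%s/day %g",
          tot, treatment, replicate, day)
  100 * ab / tot
}

rmvn2 <- function(n, center, covariance) {
  if (max(abs(covariance)) == 0)
    return(matrix(rep(center, each = n), ncol = 2))
  L <- chol(covariance)
  z <- matrix(rnorm(2 * n), ncol = 2)
  sweep(z %*% L, 2, center, `+`)
}

#' Simulate one sample's event cloud
#'
#' Draws `events_per_sample` single-cell events from a Gaussian mixture over
#' the subcommunities, with mixture weights equal to the realized relative
#' abundances at the requested day. Day 0 models the shared inoculum
#' (baseline minus adaptation shift, identical in distribution across
#' treatments); from day 4 onward abundances follow
#' `baseline + slope[treatment] * (day - 4)`, clipped at zero and
#' renormalized to 100%.
#'
#' @param design a [study_design].
#' @param specs list of [subcommunity_spec] objects.
#' @param treatment,replicate,day sample key; `day` must be a sampling day.
#' @param seed optional override of the design master seed.
#' @return an `event_cloud`: list with `events` (n x 2 matrix, columns
#'   `logFSC`, `logDNA`), `labels` (ground-truth subcommunity id per event),
#'   and the sample key.
#' @export
simulate_sample <- function(design, specs, treatment, replicate, day,
                            seed = design$seed) {
  stopifnot(inherits(design, "study_design"))
  if (!all(vapply(specs, inherits, TRUE, "subcommunity_spec")))
    stopf("specs must be subcommunity_spec objects")
  if (!day %in% design$sampling_days)
    stopf("day %g is not a sampling day", day)
  if (!treatment %in% design$treatments)
    stopf("unknown treatment '%s'", treatment)
  design$seed <- as.integer(seed)
  ab <- realized_abundances(design, specs, treatment, replicate, day)
  n <- design$events_per_sample
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "events", treatment, replicate, day))
  ids <- names(ab)
  lab_idx <- sample.int(length(ids), n, replace = TRUE, prob = ab / 100)
  ev <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("logFSC", "logDNA")))
  for (i in seq_along(ids)) {
    sel <- lab_idx == i
    if (any(sel))
      ev[sel, ] <- rmvn2(sum(sel), specs[[i]]$center, specs[[i]]$covariance)
  }
  event_cloud(ev, treatment = treatment, replicate = replicate, day = day,
              labels = ids[lab_idx])
}

#' Construct an event cloud
#'
#' @param events n x 2 numeric matrix of log-scaled channel values.
#' @param treatment,replicate,day sample key.
#' @param labels optional ground-truth subcommunity label per event.
#' @return an object of class `event_cloud`.
#' @export
event_cloud <- function(events, treatment = NA_character_, replicate = NA,
                        day = NA_real_, labels = NULL) {
  events <- as.matrix(events)
  if (ncol(events) != 2) stopf("events must have exactly 2 columns")
  if (nrow(events) == 0) stopf("event cloud is empty")
  if (any(!is.finite(events))) stopf("events contain non-finite values")
  storage.mode(events) <- "double"
  if (is.null(colnames(events))) colnames(events) <- c("logFSC", "logDNA")
  if (!is.null(labels) && length(labels) != nrow(events))
    stopf("labels length must match event count")
  structure(list(events = events, treatment = treatment,
                 replicate = replicate, day = day, labels = labels),
            class = "event_cloud")
}

#' @export
print.event_cloud <- function(x, ...) {
  cat(sprintf("<event_cloud> %s / r%s / day %s: %d events%s\n",
              x$treatment, x$replicate, x$day, nrow(x$events),
              if (is.null(x$labels)) "" else " (labeled)"))
  invisible(x)
}

#' Simulate a full study
#'
#' Generates one event cloud per (treatment, replicate, sampling day). Each
#' cloud gets its own deterministic seed derived from the design's master
#' seed, so identical inputs reproduce the study byte for byte.
#'
#' @inheritParams simulate_sample
#' @return named list of `event_cloud` objects, keys
#'   `"treatment/replicate/day"`.
#' @export
simulate_study <- function(design, specs = default_subcommunities()) {
  stopifnot(inherits(design, "study_design"))
  keys <- expand.grid(day = design$sampling_days,
                      replicate = seq_len(design$replicates_per_treatment),
                      treatment = design$treatments,
                      stringsAsFactors = FALSE)
  key_str <- sprintf("%s/%d/%g", keys$treatment, keys$replicate, keys$day)
  if (anyDuplicated(key_str)) stopf("duplicate sample keys in design")
  clouds <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys)))
    clouds[[i]] <- simulate_sample(design, specs, keys$treatment[i],
                                   keys$replicate[i], keys$day[i])
  names(clouds) <- key_str
  clouds
}
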