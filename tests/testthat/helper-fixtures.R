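# Shared synthetic fixtures, all built in code at test time.

three_cluster_specs <- function(weights = c(50, 30, 20)) {
  sp <- function(id, cx, cy, s, base)
    subcommunity_spec(id, c(cx, cy), diag(c(s, s)^2), base)
  specs <- list(sp("A", 1, 1, 0.12, weights[1]),
                sp("B", 3, 1, 0.12, weights[2]),
                sp("C", 2, 3, 0.12, weights[3]))
  names(specs) <- c("A", "B", "C")
  specs
}

# Six well-separated clusters, all dominant above 2.9%.
six_cluster_specs <- function(traj = NULL) {
  centers <- rbind(c(0.7, 0.7), c(3.2, 0.7), c(0.7, 3.3),
                   c(3.2, 3.3), c(2.0, 2.0), c(0.7, 2.0))
  base <- c(25, 20, 18, 15, 12, 10)
  specs <- lapply(1:6, function(i)
    subcommunity_spec(sprintf("G%d", i), centers[i, ],
                      diag(c(0.12, 0.12)^2), base[i],
                      if (is.null(traj)) numeric() else
                        traj[[sprintf("G%d", i)]] %||% numeric()))
  names(specs) <- sprintf("G%d", 1:6)
  specs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

box_template_for <- function(specs, halfwidth = 0.45) {
  default_gate_template(specs, halfwidth = halfwidth)
}

tiny_design <- function(...) {
  study_design(treatments = c("Neg", "Tox"), replicates_per_treatment = 2,
               sampling_days = c(0, 4, 10, 17, 24),
               events_per_sample = 3000, adaptation_shift = numeric(), ...)
}

# Abundance table constructed directly (no simulation) from per-gate
# day trends; one row per replicate x day.
make_table <- function(days = c(4, 7, 10, 14, 17, 21, 24), reps = 3,
                       gates = list(G1 = function(d) 50 - 0.2 * d,
                                    G2 = function(d) 30 + 0.2 * d,
                                    G3 = function(d) 20 + 0 * d),
                       treatment = "T", noise = 0, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(replicate = seq_len(reps), day = days)
  ab <- sapply(names(gates), function(g)
    gates[[g]](rows$day) + rnorm(nrow(rows), 0, noise))
  ab <- pmax(ab, 0)
  tab <- cbind(data.frame(treatment = treatment, replicate = rows$replicate,
                          day = rows$day), as.data.frame(ab),
               data.frame(ungated = 0L,
                          total = 10000L))
  class(tab) <- c("abundance_table", "data.frame")
  tab
}

random_rows <- function(n, gates = 12, max_total = 120) {
  m <- matrix(runif(n * gates, 0, max_total / gates), n, gates)
  colnames(m) <- sprintf("G%d", seq_len(gates))
  m
}
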