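#' Pipeline configuration
#'
#' Aggregates every tunable of the fingerprint pipeline: simulation (or an
#' events directory), the gate template (file path or detection parameters),
#' dominance thresholds (2.9% and 0.71% by convention), the Spearman cutoff
#' (0.4), the trend window (4-24 d), NMDS settings and the master seed.
#' Round-trips losslessly through JSON.
#'
#' @param output_dir where `run_pipeline()` writes its TSV artifacts.
#' @param events_dir directory of event files (tables or FCS), or `NULL` to
#'   simulate in place.
#' @param simulate list passed to [study_design()] when simulating.
#' @param template_path path to a gate template file; `NULL` to detect.
#' @param detect_params list of [detect_gates()] arguments used when no
#'   template file is given.
#' @param thresholds numeric vector of dominance thresholds in percent.
#' @param rho_cutoff strong-correlation cutoff on |rho|.
#' @param trend_window inclusive day window for slopes and rho.
#' @param nmds_dims,nmds_restarts NMDS embedding dimension and restarts.
#' @param seed master seed; all stage seeds derive from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            events_dir = NULL,
                            simulate = list(),
                            template_path = NULL,
                            detect_params = list(),
                            thresholds = c(2.9, 0.71),
                            rho_cutoff = 0.4,
                            trend_window = c(4, 24),
                            nmds_dims = 2,
                            nmds_restarts = 20,
                            seed = 1L) {
  if (any(thresholds <= 0)) stopf("thresholds must be positive")
  if (rho_cutoff <= 0) stopf("rho_cutoff must be positive")
  if (length(trend_window) != 2 || diff(trend_window) <= 0)
    stopf("trend_window must be an increasing day pair")
  structure(list(output_dir = output_dir, events_dir = events_dir,
                 simulate = simulate, template_path = template_path,
                 detect_params = detect_params, thresholds = thresholds,
                 rho_cutoff = rho_cutoff, trend_window = trend_window,
                 nmds_dims = nmds_dims, nmds_restarts = nmds_restarts,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline config as JSON
#' @param path JSON file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$simulate <- as.list(x$simulate)
  x$detect_params <- as.list(x$detect_params)
  do.call(pipeline_config, x)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

log_stage <- function(fmt, ...) {
  message(sprintf("[cytofp %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full fingerprint pipeline
#'
#' Simulate (or load) event clouds, build/apply the gate template, and write
#' all downstream artifacts to `config$output_dir`: the abundance table,
#' diversity series at every configured threshold, the Bray-Curtis matrix
#' and NMDS coordinates (stress in a header comment), the response report,
#' marker gate lists, and a run manifest (seed and parameter record). Any
#' stage failure aborts with the stage name in the error.
#'
#' @param config a `pipeline_config` or path to a JSON config file.
#' @param specs subcommunity specs used when simulating (default
#'   [default_subcommunities()]).
#' @return invisibly, a list with the in-memory results bundle.
#' @export
run_pipeline <- function(config, specs = default_subcommunities()) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    log_stage("stage %s", name)
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    log_stage("stage %s done (%.1fs)", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  clouds <- stage("events", {
    if (!is.null(config$events_dir)) {
      files <- sort(list.files(config$events_dir, full.names = TRUE))
      if (!length(files)) stopf("no event files in %s", config$events_dir)
      cl <- lapply(files, read_events)
      names(cl) <- vapply(cl, function(x)
        sprintf("%s/%s/%s", x$treatment, x$replicate, x$day), "")
      cl
    } else {
      sim <- config$simulate
      sim$seed <- sim$seed %||% derive_seed(config$seed, "simulate")
      design <- do.call(study_design, sim)
      if (sum(design$sampling_days >= config$trend_window[1] &
              design$sampling_days <= config$trend_window[2]) < 2)
        stopf("trend window [%g, %g] covers < 2 sampling days",
              config$trend_window[1], config$trend_window[2])
      simulate_study(design, specs)
    }
  })

  template <- stage("template", {
    if (!is.null(config$template_path)) read_template(config$template_path)
    else {
      dp <- config$detect_params
      dp$clouds <- clouds
      dp$seed <- dp$seed %||% derive_seed(config$seed, "detect")
      do.call(detect_gates, dp)
    }
  })

  table <- stage("gating", abundance_table(clouds, template))

  diversity <- stage("diversity", lapply(config$thresholds, function(th)
    diversity_series(table, threshold = th)))
  names(diversity) <- sprintf("t%g", config$thresholds)

  bc <- stage("braycurtis", bray_curtis_matrix(table))
  ord <- stage("nmds", nmds(bc, k = config$nmds_dims,
                            restarts = config$nmds_restarts,
                            seed = derive_seed(config$seed, "nmds")))

  report <- stage("response", response_report(
    table, cutoff = config$rho_cutoff, window = config$trend_window))
  markers <- lapply(unique(table$treatment), function(tr)
    select_marker_gates(report, tr))
  names(markers) <- unique(table$treatment)

  stage("write", {
    od <- config$output_dir
    write_template(template, file.path(od, "gate_template.tsv"))
    write_tsv(table, file.path(od, "abundance_table.tsv"))
    for (nm in names(diversity)) {
      d <- diversity[[nm]]
      write_tsv(d$alpha, file.path(od, sprintf("alpha_%s.tsv", nm)),
                sprintf("alpha diversity (Hill D0), threshold %g%%",
                        d$threshold))
      write_tsv(d$beta, file.path(od, sprintf("beta_%s.tsv", nm)),
                sprintf("intra-community beta, threshold %g%%", d$threshold))
    }
    bcdf <- data.frame(sample = rownames(bc), as.data.frame(bc),
                       check.names = FALSE)
    write_tsv(bcdf, file.path(od, "bray_curtis.tsv"))
    pts <- data.frame(sample = rownames(ord$points), ord$points,
                      check.names = FALSE)
    write_tsv(pts, file.path(od, "nmds_coordinates.tsv"),
              c(sprintf("stress: %.6f", ord$stress),
                sprintf("dims: %d restarts: %d", config$nmds_dims,
                        config$nmds_restarts)))
    write_tsv(as.data.frame(report), file.path(od, "response_report.tsv"),
              c(sprintf("rho cutoff: %g", config$rho_cutoff),
                sprintf("trend window: %g-%g d", config$trend_window[1],
                        config$trend_window[2])))
    mk <- do.call(rbind, lapply(names(markers), function(tr) {
      m <- markers[[tr]]
      if (!length(m$positive) && !length(m$negative))
        return(data.frame(treatment = tr, marker = "none", gate = NA))
      rbind(
        if (length(m$positive))
          data.frame(treatment = tr, marker = "positive", gate = m$positive),
        if (length(m$negative))
          data.frame(treatment = tr, marker = "negative", gate = m$negative))
    }))
    write_tsv(mk, file.path(od, "marker_gates.tsv"))
    uc <- unclass(config)
    manifest <- list(package = "cytofp",
                     version = as.character(utils::packageVersion("cytofp")),
                     seed = config$seed,
                     config = uc[setdiff(names(uc), "output_dir")],
                     n_samples = nrow(table),
                     n_gates = length(gate_ids(table)),
                     r_version = R.version.string)
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    NULL
  })

  invisible(list(config = config, template = template, table = table,
                 diversity = diversity, bray_curtis = bc, nmds = ord,
                 report = report, markers = markers))
}

#' Summarize a results bundle
#'
#' Human-readable per-treatment digest: alpha and beta time courses
#' (replicate mean +/- SD) at each threshold, the NMDS stress, and the
#' marker gates per treatment.
#'
#' @param bundle the list returned by [run_pipeline()], or an output
#'   directory written by it.
#' @return character vector of report lines (also printed).
#' @export
summarize_results <- function(bundle) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  need <- c("table", "diversity", "nmds", "markers")
  missing <- setdiff(need, names(bundle)[!vapply(bundle, is.null, TRUE)])
  if (length(missing))
    stopf("incomplete results bundle; missing: %s",
          paste(missing, collapse = ", "))
  out <- c(sprintf("cytofp results: %d samples, %d gates, NMDS stress %.3f",
                   nrow(bundle$table), length(gate_ids(bundle$table)),
                   bundle$nmds$stress))
  for (nm in names(bundle$diversity)) {
    d <- bundle$diversity[[nm]]
    out <- c(out, sprintf("alpha diversity (threshold %g%%):", d$threshold))
    s <- d$alpha_summary
    for (tr in unique(s$treatment))
      out <- c(out, sprintf("  %-10s %s", tr,
                            paste(sprintf("d%g:%.1f+/-%.1f",
                                          s$day[s$treatment == tr],
                                          s$mean[s$treatment == tr],
                                          ifelse(is.na(s$sd[s$treatment == tr]),
                                                 0, s$sd[s$treatment == tr])),
                                  collapse = " ")))
    if (!is.null(d$beta_summary)) {
      s <- d$beta_summary
      out <- c(out, sprintf("beta diversity (threshold %g%%):", d$threshold))
      for (tr in unique(s$treatment))
        out <- c(out, sprintf("  %-10s %s", tr,
                              paste(sprintf("d%g:%.1f",
                                            s$day[s$treatment == tr],
                                            s$mean[s$treatment == tr]),
                                    collapse = " ")))
    }
  }
  out <- c(out, "marker gates:")
  for (tr in names(bundle$markers)) {
    m <- bundle$markers[[tr]]
    line <- if (!length(m$positive) && !length(m$negative))
      "no responding gates"
    else sprintf("positive: %s | negative: %s",
                 paste(m$positive, collapse = ",") ,
                 paste(m$negative, collapse = ","))
    out <- c(out, sprintf("  %-10s %s", tr, line))
  }
  cat(out, sep = "\n")
  invisible(out)
}

read_bundle <- function(dir) {
  f <- function(p) file.path(dir, p)
  need <- c("abundance_table.tsv", "nmds_coordinates.tsv",
            "marker_gates.tsv", "response_report.tsv")
  missing <- need[!file.exists(f(need))]
  if (length(missing))
    stopf("incomplete results bundle; missing: %s",
          paste(missing, collapse = ", "))
  table <- read.delim(f("abundance_table.tsv"), check.names = FALSE)
  class(table) <- c("abundance_table", "data.frame")
  stress_line <- grep("stress:", readLines(f("nmds_coordinates.tsv"), n = 2),
                      value = TRUE)
  stress <- as.numeric(sub(".*stress: *", "", stress_line[1]))
  alphas <- list.files(dir, pattern = "^alpha_.*\\.tsv$", full.names = TRUE)
  diversity <- lapply(alphas, function(p) {
    th <- as.numeric(sub("^t", "", sub("^alpha_(.*)\\.tsv$", "\\1",
                                       basename(p))))
    alpha <- read.delim(p, comment.char = "#")
    beta_p <- sub("alpha_", "beta_", p)
    beta <- if (file.exists(beta_p)) read.delim(beta_p, comment.char = "#")
    s <- aggregate(alpha$alpha, by = list(treatment = alpha$treatment,
                                          day = alpha$day),
                   FUN = function(v) c(mean = mean(v), sd = sd(v)))
    bsum <- if (!is.null(beta)) {
      b <- aggregate(beta$beta, by = list(treatment = beta$treatment,
                                          day = beta$day_to),
                     FUN = function(v) c(mean = mean(v), sd = sd(v)))
      data.frame(treatment = b$treatment, day = b$day,
                 mean = b$x[, "mean"], sd = b$x[, "sd"])
    }
    list(alpha = alpha, beta = beta, threshold = th,
         alpha_summary = data.frame(treatment = s$treatment, day = s$day,
                                    mean = s$x[, "mean"], sd = s$x[, "sd"]),
         beta_summary = bsum)
  })
  names(diversity) <- sprintf("t%g",
                              vapply(diversity, `[[`, 0, "threshold"))
  mk <- read.delim(f("marker_gates.tsv"), comment.char = "#")
  markers <- lapply(split(mk, mk$treatment), function(m)
    list(positive = m$gate[m$marker == "positive"],
         negative = m$gate[m$marker == "negative"]))
  list(table = table, diversity = diversity,
       nmds = list(stress = stress), markers = markers)
}
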