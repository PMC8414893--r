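# Pipeline orchestration: simulate -> analyze -> stats, each stage a
# function over directories of plain-text tables, deterministic given the
# seed, with a small run manifest. A thin command-line wrapper lives in
# inst/scripts/intellipheno.R.

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

write_manifest <- function(out_dir, stage, inputs, outputs, seed = NA) {
  lines <- c(
    sprintf("stage: %s", stage),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("intellipheno"))),
    sprintf("seed: %s", seed),
    "inputs:",
    sprintf("  - path: %s", inputs),
    if (length(inputs)) sprintf("    md5: %s",
                                unname(tools::md5sum(inputs[file.exists(inputs)]))),
    "outputs:",
    sprintf("  - %s", outputs))
  writeLines(lines, file.path(out_dir, sprintf("manifest_%s.yaml", stage)))
}

#' Read a simulation config file
#'
#' YAML with top-level keys `cohort` (`cages`: list of
#' `{n_nontg, n_tg}`), `seed`, and `params` (per-genotype parameter maps);
#' omitted parts fall back to the packaged defaults.
#'
#' @param path Config file path, or `NULL` for the packaged defaults.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path = NULL) {
  defaults <- yaml::read_yaml(system.file("extdata", "default_params.yaml",
                                          package = "intellipheno"))
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("I/O error: missing config '%s'", path), call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.null(user$cohort$cages)) cfg$cohort$cages <- user$cohort$cages
    if (!is.null(user$seed)) cfg$seed <- user$seed
    for (g in names(user$params))
      cfg$params[[g]][names(user$params[[g]])] <- user$params[[g]]
  }
  cages <- do.call(rbind, lapply(cfg$cohort$cages, as.data.frame))
  sim_config(cages = cages, params = cfg$params, seed = cfg$seed)
}

#' Simulate a cohort and write it to disk
#'
#' Writes the event-store directory (`store/`), the retained ground truth
#' (`ground_truth.yaml`) and a run manifest under `out_dir`.
#'
#' @param config_path YAML config (see [read_sim_config()]), or `NULL` for
#'   the packaged defaults.
#' @param out_dir Output directory.
#' @param seed Optional integer overriding the config seed.
#' @return Path of the store directory, invisibly.
#' @export
cmd_simulate <- function(config_path = NULL, out_dir, seed = NULL) {
  config <- read_sim_config(config_path)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  log_stage("simulate", "seed %d, %d cage(s), %d animals", config$seed,
            nrow(config$cages), sum(config$cages$n_nontg + config$cages$n_tg))
  res <- generate_cohort(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  store_dir <- file.path(out_dir, "store")
  write_store(res$store, store_dir)
  gt <- res$ground_truth
  gt$cages <- lapply(seq_len(nrow(gt$cages)), function(i) as.list(gt$cages[i, ]))
  gt$animals <- lapply(seq_len(nrow(gt$animals)),
                       function(i) as.list(gt$animals[i, ]))
  yaml::write_yaml(gt, file.path(out_dir, "ground_truth.yaml"))
  write_manifest(out_dir, "simulate",
                 inputs = if (is.null(config_path)) character(0) else config_path,
                 outputs = c("store", "ground_truth.yaml"), seed = config$seed)
  log_stage("simulate", "wrote %s (%d visits)", store_dir, nrow(res$store$visits))
  invisible(store_dir)
}

#' Analyze a store directory into metric tables
#'
#' Computes every phase's per-animal per-day metrics, the adaptation
#' outcomes, and a per-genotype pass summary. The ground truth is never
#' read: the only input is the store directory.
#'
#' @param store_dir Directory written by [write_store()]/[cmd_simulate()].
#' @param out_dir Output directory; receives `metrics.tsv` (long format),
#'   per-day tables `<phase>_day<k>.tsv`, `adaptation_outcomes.tsv` and
#'   `pass_summary.tsv`.
#' @return The metrics data frame, invisibly.
#' @export
cmd_analyze <- function(store_dir, out_dir) {
  store <- read_store(store_dir)
  log_stage("analyze", "store: %d animals, %d visits",
            nrow(store$animals), nrow(store$visits))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- compute_all_metrics(store)
  write_tsv <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(x) ifelse(is.na(x), "NA", fmt_num(x)))
    utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  write_tsv(metrics, "metrics.tsv")
  for (ph in unique(metrics$phase)) {
    sub <- metrics[metrics$phase == ph, ]
    for (d in sort(unique(sub$day)))
      write_tsv(sub[sub$day == d, ], sprintf("%s_day%d.tsv", ph, d))
  }
  outcomes <- pass_fail_adaptation(store)
  write_tsv(outcomes, "adaptation_outcomes.tsv")
  pass <- do.call(rbind, lapply(split(outcomes, outcomes$genotype), function(s)
    data.frame(genotype = s$genotype[1], n_started = nrow(s),
               n_passed = sum(s$passed),
               pct_passed = percent_passed(nrow(s), sum(s$passed)))))
  write_tsv(pass, "pass_summary.tsv")
  write_manifest(out_dir, "analyze",
                 inputs = file.path(store_dir, unname(STORE_FILES)),
                 outputs = c("metrics.tsv", "adaptation_outcomes.tsv",
                             "pass_summary.tsv"))
  log_stage("analyze", "wrote %s", file.path(out_dir, "metrics.tsv"))
  invisible(metrics)
}

#' Run the statistical battery on a metrics table
#'
#' For every multi-day phase metric: mixed RM-ANOVA (genotype x day) with
#' Mauchly sphericity assessment, plus Bonferroni-corrected per-day post
#' hocs when the interaction is significant. Single-window metrics
#' (avoidance counts) get a pooled two-sample t test. Metrics with fewer
#' than two complete subjects per genotype are skipped with a logged
#' reason.
#'
#' Morphometric comparisons (body weight, brain weight, brain/body ratio)
#' are appended when a measurements table is supplied: genotype-wise pooled
#' t tests, plus task-completion (complete vs incomplete) comparisons
#' within each genotype when adaptation outcomes are available in the
#' metrics (the simulator does not model weights, so this input is always
#' external).
#'
#' @param metrics_path Path to a `metrics.tsv` from [cmd_analyze()] (or the
#'   metrics data frame itself).
#' @param out_dir Output directory; receives `stats_report.tsv`.
#' @param morphometrics_path Optional path to a tab-separated table
#'   `animal_id  genotype  body_g  brain_g`.
#' @return The report data frame, invisibly.
#' @export
cmd_stats <- function(metrics_path, out_dir, morphometrics_path = NULL) {
  metrics <- if (is.data.frame(metrics_path)) metrics_path else {
    if (!file.exists(metrics_path))
      stop(sprintf("I/O error: missing metrics '%s'", metrics_path), call. = FALSE)
    utils::read.delim(metrics_path, stringsAsFactors = FALSE, na.strings = "NA")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  add <- function(phase, metric, r, extra = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      phase = phase, metric = metric, term = r$term, statistic = r$statistic,
      df1 = r$df1, df2 = if (is.na(r$df2)) NA_integer_ else r$df2, p = r$p,
      adjusted_p = r$adjusted_p, stars = sig_stars(if (!is.na(r$adjusted_p))
        r$adjusted_p else r$p), stringsAsFactors = FALSE)
  }
  for (ph in unique(metrics$phase)) {
    for (met in unique(metrics$metric[metrics$phase == ph])) {
      sub <- metrics[metrics$phase == ph & metrics$metric == met, ]
      wide <- stats::reshape(sub[, c("animal_id", "genotype", "day", "value")],
                             idvar = c("animal_id", "genotype"),
                             timevar = "day", direction = "wide")
      y <- as.matrix(wide[, -(1:2), drop = FALSE])
      rownames(y) <- wide$animal_id
      group <- wide$genotype
      n_days <- ncol(y)
      res <- tryCatch({
        if (n_days >= 2) {
          des <- rm_design(y, group)
          an <- rm_anova(des)
          mau <- mauchly_test(des)
          add(ph, met, an$between)
          add(ph, met, an$within)
          add(ph, met, an$interaction)
          add(ph, met, stat_result("mauchly", mau$W, mau$df, NA_integer_, mau$p))
          if (an$interaction$p < 0.05)
            for (r in bonferroni_posthoc(des, an$interaction$p))
              add(ph, met, r)
        } else {
          keep <- !is.na(y[, 1])
          x1 <- y[keep & group == "NonTg", 1]
          x2 <- y[keep & group == "TG", 1]
          add(ph, met, pooled_t_from_data(x1, x2))
        }
        TRUE
      }, error = function(e) {
        log_stage("stats", "skipping %s/%s: %s", ph, met, conditionMessage(e))
        FALSE
      })
    }
  }
  if (!is.null(morphometrics_path)) {
    if (!file.exists(morphometrics_path))
      stop(sprintf("I/O error: missing morphometrics '%s'", morphometrics_path),
           call. = FALSE)
    mo <- utils::read.delim(morphometrics_path, stringsAsFactors = FALSE)
    need <- c("animal_id", "genotype", "body_g", "brain_g")
    if (!all(need %in% names(mo)))
      stop("morphometrics table needs columns: animal_id genotype body_g brain_g",
           call. = FALSE)
    mo$brain_body_ratio <- mo$brain_g / mo$body_g
    for (measure in c("body_g", "brain_g", "brain_body_ratio")) {
      res <- tryCatch({
        add("morphometrics", measure,
            pooled_t_from_data(mo[[measure]][mo$genotype == "NonTg"],
                               mo[[measure]][mo$genotype == "TG"]))
        TRUE
      }, error = function(e) {
        log_stage("stats", "skipping morphometrics/%s: %s", measure,
                  conditionMessage(e))
        FALSE
      })
    }
  }
  report <- do.call(rbind, rows)
  rep_out <- report
  for (col in c("statistic", "p", "adjusted_p"))
    rep_out[[col]] <- ifelse(is.na(report[[col]]), "NA",
                             sprintf("%.6g", report[[col]]))
  utils::write.table(rep_out, file.path(out_dir, "stats_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  write_manifest(out_dir, "stats",
                 inputs = if (is.data.frame(metrics_path)) character(0)
                          else metrics_path,
                 outputs = "stats_report.tsv")
  log_stage("stats", "wrote %s (%d rows)",
            file.path(out_dir, "stats_report.tsv"), nrow(report))
  invisible(report)
}
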