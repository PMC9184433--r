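# End-to-end analysis pipeline: cohort I/O, configuration, the
# grading -> survival -> report chain, and paired system comparison.

.COHORT_COLS <- c("patient_id", "p3", "p4", "p5", "has_icidc", "age", "psa",
                  "pt_stage", "margins", "bcr_time_months", "bcr_event",
                  "met_time_months", "met_event")

#' Read and validate a cohort CSV
#'
#' Parses the per-patient cohort schema (`patient_id`, `p3`, `p4`, `p5`,
#' `has_icidc`, `age`, `psa`, `pt_stage`, `margins`, `bcr_time_months`,
#' `bcr_event`, `met_time_months`, `met_event`) and validates every row:
#' percentages in \[0, 100\] summing to 100, 0/1 flags, strictly positive
#' follow-up times. PSA may be missing (imputed later). All offending
#' rows are reported together with their file line numbers.
#'
#' @param path Path to a CSV file.
#' @return Validated data.frame; an empty file with a valid header yields
#'   an empty cohort with a warning.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.COHORT_COLS, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) {
    warning("cohort file has a header but no rows", call. = FALSE)
    return(df)
  }
  problems <- character(0)
  add <- function(rows, msg) {
    if (length(rows))
      problems <<- c(problems, paste0("line ", paste(rows + 1L, collapse = ", "),
                                      ": ", msg))
  }
  num_cols <- c("p3", "p4", "p5", "age", "bcr_time_months", "met_time_months")
  for (cc in num_cols)
    add(which(!is.finite(suppressWarnings(as.numeric(df[[cc]])))),
        paste0("non-numeric ", cc))
  for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  df$psa <- suppressWarnings(as.numeric(df$psa))
  for (cc in c("p3", "p4", "p5"))
    add(which(is.finite(df[[cc]]) & (df[[cc]] < 0 | df[[cc]] > 100)),
        paste0(cc, " outside [0, 100]"))
  s <- df$p3 + df$p4 + df$p5
  add(which(is.finite(s) & abs(s - 100) > 1e-9), "p3 + p4 + p5 != 100")
  for (cc in c("has_icidc", "margins", "bcr_event", "met_event"))
    add(which(!(df[[cc]] %in% c(0, 1))), paste0(cc, " must be 0 or 1"))
  for (cc in c("bcr_time_months", "met_time_months"))
    add(which(is.finite(df[[cc]]) & df[[cc]] <= 0),
        paste0(cc, " must be > 0"))
  if (length(problems))
    stop("invalid cohort rows:\n", paste(problems, collapse = "\n"),
         call. = FALSE)
  df
}

#' Write a cohort (or graded cohort) CSV
#'
#' @param cohort data.frame to write.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Analysis configuration
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate.
#' @param sim_config A [cohort_config()] used when `input` is `NULL`.
#' @param endpoints Character subset of `c("bcr", "met")`.
#' @param n_boot Bootstrap replicates for c-index CIs (>= 2).
#' @param seed Top-level integer seed; endpoint-level resampling seeds
#'   are derived as `seed + 7919 * k` for the k-th endpoint.
#' @param min_events Minimum events required in the lowest grade group
#'   before merging upward.
#' @param score_mode `"ordinal"` (categories 1-5 score the categorical
#'   systems) or `"linear_predictor"` (a Cox model on the dummy-coded
#'   categories is refit inside each bootstrap resample).
#' @param out_dir Directory for the report bundle, or `NULL` to keep
#'   results in memory only.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, sim_config = NULL,
                            endpoints = c("bcr", "met"),
                            n_boot = 1000L, seed = 42L, min_events = 1L,
                            score_mode = c("ordinal", "linear_predictor"),
                            out_dir = NULL) {
  score_mode <- match.arg(score_mode)
  endpoints <- match.arg(endpoints, c("bcr", "met"), several.ok = TRUE)
  if (length(endpoints) == 0) stop("endpoints must be non-empty", call. = FALSE)
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  if (is.null(input) && is.null(sim_config)) sim_config <- cohort_config()
  structure(list(input = input, sim_config = sim_config,
                 endpoints = endpoints, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), min_events = as.integer(min_events),
                 score_mode = score_mode, out_dir = out_dir),
            class = "analysis_config")
}

# Dummy-code merged grade labels against the lowest (reference) group.
.grade_dummies <- function(labels, k) {
  if (k < 2) stop("constant covariate: single grade category", call. = FALSE)
  m <- matrix(0, length(labels), k - 1,
              dimnames = list(NULL, paste0("g", 2:k)))
  for (j in 2:k) m[, j - 1] <- as.numeric(labels == j)
  m
}

# Univariate Cox on merged categories; returns a Tables-3/4-style HR
# table with the reference row first.
.hr_table <- function(time, event, merged, system) {
  k <- length(merged$group_names)
  fit <- cox_fit(time, event, .grade_dummies(merged$labels, k))
  data.frame(system = system,
             group = merged$group_names,
             hr = c(1, unname(fit$hr)),
             ci_low = c(NA, unname(fit$ci_low)),
             ci_high = c(NA, unname(fit$ci_high)),
             p = c(NA, unname(fit$p_values)),
             reference = c(TRUE, rep(FALSE, k - 1)))
}

.km_by_group <- function(time, event, merged, system) {
  do.call(rbind, lapply(seq_along(merged$group_names), function(j) {
    i <- merged$labels == j
    if (!any(event[i]))
      return(NULL)  # flat curve contributes no event-time rows
    km <- km_estimate(time[i], event[i])
    data.frame(system = system, group = merged$group_names[j],
               time = km$time, survival = km$survival, at_risk = km$n_risk)
  }))
}

#' Run the full grading-and-survival analysis
#'
#' Executes, in order: (1) median imputation of missing PSA; (2) grading
#' of every patient under Grade Group, IQ-Gleason (continuous and
#' categorical) and cGrade; (3) pairwise cross-tabulations of the three
#' categorical systems with concordance fractions; (4) per endpoint:
#' sparse-group merging, Kaplan-Meier curves and a log-rank test per
#' system, univariate Cox hazard-ratio tables against the (possibly
#' merged) lowest group, and Harrell's c with a paired bootstrap CI for
#' all four scores (the three categorical systems and the continuous
#' IQ-Gleason), sharing resamples within an endpoint so systems are
#' directly comparable; (5) if `out_dir` is set, the report bundle is
#' written (CSV tables, JSON-free plain text run log with seed, config
#' hash and package version). A failure in any stage aborts with a
#' stage-named error and leaves no partial output.
#'
#' @param config An [analysis_config()].
#' @return Object of class `analysis_report` (all tables in memory).
#' @export
run_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  cohort <- stage("input",
    if (!is.null(config$input)) read_cohort(config$input)
    else generate_cohort(config$sim_config))
  cohort <- stage("impute", {
    cohort$psa <- median_impute(cohort$psa)
    cohort
  })
  graded <- stage("grading", grade_cohort(cohort))
  crosstabs <- stage("crosstab", list(
    gg_vs_iq = cross_tabulate(graded$grade_group, graded$iq_category,
                              c("GG", "IQ")),
    gg_vs_cgrade = cross_tabulate(graded$grade_group, graded$cgrade,
                                  c("GG", "cG")),
    cgrade_vs_iq = cross_tabulate(graded$cgrade, graded$iq_category,
                                  c("cG", "IQ"))))

  systems <- c("grade_group", "iq_category", "cgrade")
  endpoints <- list()
  for (k in seq_along(config$endpoints)) {
    ep <- config$endpoints[k]
    time <- graded[[paste0(ep, "_time_months")]]
    event <- as.logical(graded[[paste0(ep, "_event")]])
    ep_seed <- config$seed + 7919L * k
    res <- list(endpoint = ep, seed = ep_seed)
    res$merged <- stage(paste0(ep, "/merge"),
      stats::setNames(lapply(systems, function(sys)
        merge_sparse_groups(graded[[sys]], event, config$min_events)),
        systems))
    res$logrank <- stage(paste0(ep, "/logrank"),
      stats::setNames(lapply(systems, function(sys)
        logrank_test(time, event, res$merged[[sys]]$labels)), systems))
    res$km <- stage(paste0(ep, "/km"),
      do.call(rbind, lapply(systems, function(sys)
        .km_by_group(time, event, res$merged[[sys]], sys))))
    res$hr_table <- stage(paste0(ep, "/cox"),
      do.call(rbind, lapply(systems, function(sys)
        .hr_table(time, event, res$merged[[sys]], sys))))
    res$cindex <- stage(paste0(ep, "/cindex"), {
      dat <- data.frame(time = time, event = event,
                        grade_group = graded$grade_group,
                        iq_category = graded$iq_category,
                        cgrade = graded$cgrade,
                        iq_continuous = graded$iq_continuous)
      scorers <- if (config$score_mode == "ordinal") {
        list(grade_group = function(d) d$grade_group,
             iq_category = function(d) d$iq_category,
             cgrade = function(d) d$cgrade,
             iq_continuous = function(d) d$iq_continuous)
      } else {
        lp_scorer <- function(col) function(d) {
          mg <- merge_sparse_groups(d[[col]], d$event, config$min_events)
          k2 <- length(mg$group_names)
          cox_fit(d$time, d$event,
                  .grade_dummies(mg$labels, k2))$linear_predictor
        }
        list(grade_group = lp_scorer("grade_group"),
             iq_category = lp_scorer("iq_category"),
             cgrade = lp_scorer("cgrade"),
             iq_continuous = function(d)
               cox_fit(d$time, d$event,
                       cbind(iq = d$iq_continuous))$linear_predictor)
      }
      boot <- .bootstrap_c_multi(dat, scorers, config$n_boot, ep_seed)
      tab <- do.call(rbind, lapply(names(scorers), function(sys) {
        ci <- stats::quantile(boot$replicates[, sys], c(0.025, 0.975),
                              names = FALSE)
        data.frame(system = sys, endpoint = ep,
                   estimate = boot$estimates[[sys]]$c,
                   ci_low = ci[1], ci_high = ci[2],
                   n_boot = config$n_boot, seed = ep_seed)
      }))
      list(table = tab, replicates = boot$replicates, seed = ep_seed)
    })
    endpoints[[ep]] <- res
  }

  report <- structure(list(config = config, cohort = cohort, graded = graded,
                           crosstabs = crosstabs, endpoints = endpoints,
                           version = as.character(utils::packageVersion("pcgrade"))),
                      class = "analysis_report")
  if (!is.null(config$out_dir))
    write_report(report, config$out_dir)
  report
}

# Serialize the report bundle as plain-text CSVs plus a run log.
# Everything is staged in a temporary directory and copied over only on
# success, so a failing stage leaves no partial output behind.
write_report <- function(report, out_dir) {
  staging <- tempfile("pcgrade_report_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(staging, name), row.names = FALSE)
  wr(report$graded, "graded.csv")
  for (nm in names(report$crosstabs)) {
    ct <- report$crosstabs[[nm]]
    m <- cbind(as.data.frame(ct$counts), Total = ct$row_totals)
    m <- rbind(m, Total = c(ct$col_totals, ct$total))
    utils::write.csv(cbind(group = rownames(m), m),
                     file.path(staging, paste0("crosstab_", nm, ".csv")),
                     row.names = FALSE)
  }
  for (ep in names(report$endpoints)) {
    res <- report$endpoints[[ep]]
    wr(res$hr_table, paste0("hr_", ep, ".csv"))
    wr(res$km, paste0("km_", ep, ".csv"))
    wr(res$cindex$table, paste0("cindex_", ep, ".csv"))
    lr <- do.call(rbind, lapply(names(res$logrank), function(sys)
      data.frame(system = sys, chisq = res$logrank[[sys]]$chisq,
                 df = res$logrank[[sys]]$df,
                 p_value = res$logrank[[sys]]$p_value)))
    wr(lr, paste0("logrank_", ep, ".csv"))
  }
  cfg_file <- file.path(staging, "config_hash.tmp")
  cfg <- unclass(report$config)
  cfg$out_dir <- NULL                # hash the analysis inputs, not paths
  saveRDS(cfg, cfg_file)             # canonical bytes for hashing only
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  writeLines(c(sprintf("pcgrade version: %s", report$version),
               sprintf("seed: %d", report$config$seed),
               sprintf("config md5: %s", hash),
               sprintf("endpoints: %s",
                       paste(report$config$endpoints, collapse = ",")),
               sprintf("n_boot: %d", report$config$n_boot),
               sprintf("score_mode: %s", report$config$score_mode)),
             file.path(staging, "run_log.txt"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- file.copy(list.files(staging, full.names = TRUE), out_dir,
                  overwrite = TRUE)
  if (!all(ok)) stop("failed to write report bundle to ", out_dir,
                     call. = FALSE)
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("pcgrade analysis report\n")
  cat(sprintf("  patients: %d; endpoints: %s; n_boot: %d; seed: %d\n",
              nrow(x$graded), paste(x$config$endpoints, collapse = ", "),
              x$config$n_boot, x$config$seed))
  for (ep in names(x$endpoints)) {
    cat(sprintf("  %s c-indices:\n", ep))
    print(x$endpoints[[ep]]$cindex$table[, c("system", "estimate",
                                             "ci_low", "ci_high")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Rank grading systems by discriminative ability
#'
#' Tabulates the bootstrap c-index of every system per endpoint, ranks
#' them, and -- because all systems within an endpoint share the same
#' bootstrap resamples -- reports the paired bootstrap distribution of
#' pairwise c-index differences with its percentile 95% interval.
#'
#' @param report An [run_analysis()] result.
#' @return List with `ranking` (data.frame system/endpoint/estimate/CI/
#'   rank) and `differences` (pairwise paired-bootstrap contrasts).
#' @export
compare_systems <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  ranking <- list(); diffs <- list()
  for (ep in names(report$endpoints)) {
    res <- report$endpoints[[ep]]
    tab <- res$cindex$table
    if (length(unique(tab$seed)) != 1)
      stop("compare_systems: mismatched resample seeds across systems",
           call. = FALSE)
    tab$rank <- rank(-tab$estimate, ties.method = "min")
    ranking[[ep]] <- tab[order(tab$rank), ]
    reps <- res$cindex$replicates
    sys <- colnames(reps)
    prs <- utils::combn(sys, 2, simplify = FALSE)
    diffs[[ep]] <- do.call(rbind, lapply(prs, function(pr) {
      d <- reps[, pr[1]] - reps[, pr[2]]
      ci <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
      data.frame(endpoint = ep, system_a = pr[1], system_b = pr[2],
                 mean_diff = mean(d), ci_low = ci[1], ci_high = ci[2])
    }))
  }
  list(ranking = do.call(rbind, ranking),
       differences = do.call(rbind, diffs))
}
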