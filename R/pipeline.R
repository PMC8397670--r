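# Pipeline orchestration: simulate -> evaluate -> cohort, driven by one
# YAML-serializable configuration. Every number in the emitted reports is
# produced by a module function (generator, DVH engine, indices, objective
# checker, cohort statistics); the reporter only arranges them.

#' Pipeline configuration
#'
#' @param prescription a [prescription()].
#' @param protocol_basis `"printed"` or `"percent"` objective thresholds,
#'   see [default_objectives()].
#' @param protocol_path optional YAML protocol overriding the default
#'   objectives (see [read_objectives_yaml()]).
#' @param rasterization `"fractional"` or `"binary"` (DICOM ingestion).
#' @param patient `"patient1"` or `"patient2"` phantom.
#' @param n_per_group plans per technique for simulation.
#' @param seed master seed.
#' @param out_dir output directory.
#' @param primary_metric uncorrected primary metric for group comparisons.
#' @param multiplicity_family metric columns entering the Holm correction;
#'   `NULL` = all metric columns.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(prescription = sbrtbench::prescription(),
                            protocol_basis = "printed",
                            protocol_path = NULL,
                            rasterization = "fractional",
                            patient = "patient1",
                            n_per_group = c(RRS = 8, MOD = 34, `3D` = 15),
                            seed = 1L,
                            out_dir = "sbrtbench-out",
                            primary_metric = "ptv_dmean_gy",
                            multiplicity_family = NULL) {
    structure(list(prescription = prescription,
                   protocol_basis = protocol_basis,
                   protocol_path = protocol_path,
                   rasterization = rasterization,
                   patient = patient,
                   n_per_group = n_per_group, seed = as.integer(seed),
                   out_dir = out_dir, primary_metric = primary_metric,
                   multiplicity_family = multiplicity_family),
              class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML path.
#' @export
write_config_yaml <- function(config, path) {
    x <- unclass(config)
    x$prescription <- unclass(x$prescription)
    x$n_per_group <- as.list(x$n_per_group)
    yaml::write_yaml(x, path)
    invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
    x <- yaml::read_yaml(path)
    rxf <- x$prescription
    rx <- prescription(rxf$n_fractions, rxf$dose_per_fraction,
                       rxf$alpha_beta, rxf$anchor)
    pipeline_config(prescription = rx, protocol_basis = x$protocol_basis,
                    protocol_path = x$protocol_path,
                    rasterization = x$rasterization, patient = x$patient,
                    n_per_group = unlist(x$n_per_group), seed = x$seed,
                    out_dir = x$out_dir, primary_metric = x$primary_metric,
                    multiplicity_family = unlist(x$multiplicity_family))
}

config_phantom <- function(config) {
    switch(config$patient,
           patient1 = phantom_patient1(),
           patient2 = phantom_patient2(),
           stop("unknown patient '", config$patient, "'"))
}

config_objectives <- function(config) {
    if (!is.null(config$protocol_path))
        read_objectives_yaml(config$protocol_path)
    else default_objectives(config$prescription, config$protocol_basis)
}

#' Simulate a cohort and write it to disk
#'
#' Generates the configured synthetic cohort, writes each plan to the
#' internal container under `<out_dir>/plans/`, and writes a
#' `manifest.csv` listing file, institution, technique, algorithm, seed
#' and an MD5 checksum. Rerunning with the same seed reproduces identical
#' files.
#'
#' @param config a [pipeline_config()].
#' @param overrides passed to [make_cohort()].
#' @return the manifest data frame, invisibly.
#' @export
cmd_simulate <- function(config = pipeline_config(), overrides = NULL) {
    dir.create(file.path(config$out_dir, "plans"), recursive = TRUE,
               showWarnings = FALSE)
    plans <- make_cohort(config$n_per_group, seed = config$seed,
                         phantom_spec = config_phantom(config),
                         overrides = overrides)
    rows <- lapply(seq_along(plans), function(i) {
        p <- plans[[i]]
        f <- file.path(config$out_dir, "plans",
                       sprintf("plan_%03d.sbp", i))
        write_plan(p, f)
        data.frame(file = f, institution_id = p$meta$institution_id,
                   technique = p$meta$technique,
                   algorithm = p$meta$algorithm,
                   seed = plan_seed(config$seed, i),
                   md5 = unname(tools::md5sum(f)), stringsAsFactors = FALSE)
    })
    manifest <- do.call(rbind, rows)
    write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
              row.names = FALSE)
    invisible(manifest)
}

#' Normalize, measure and classify a set of plans
#'
#' For each plan (paths to internal-container files, or in-memory plans):
#' normalization to the prescription first, then all DVH metrics and
#' indices, then the objective verdicts and plan disposition. Unreadable
#' plan files are logged and skipped; the summary reports them. Emits
#' `metrics.csv` (one row per plan, units in column names) and
#' `reports.json` under `out_dir` when `write_outputs` is `TRUE`.
#'
#' @param plans list of [sbrt_plan()]s or a character vector of file paths.
#' @param config a [pipeline_config()].
#' @param write_outputs write `metrics.csv` / `reports.json`?
#' @return list with `table` (the [metric_table()], disposition columns
#'   added), `reports` (per-plan objective reports), `included` (row filter)
#'   and `n_failed` (unreadable files).
#' @export
cmd_evaluate <- function(plans, config = pipeline_config(),
                         write_outputs = FALSE) {
    if (length(plans) == 0L) stop("no plans to evaluate")
    rx <- config$prescription
    objectives <- config_objectives(config)
    n_failed <- 0L
    tab_rows <- list(); reports <- list()
    for (i in seq_along(plans)) {
        p <- plans[[i]]
        if (is.character(p)) {
            p <- tryCatch(read_plan(p), error = function(e) {
                message("skipping unreadable plan '", plans[[i]], "': ",
                        conditionMessage(e))
                NULL
            })
            if (is.null(p)) { n_failed <- n_failed + 1L; next }
        }
        p <- normalize_plan(p, rx)
        reports[[length(reports) + 1L]] <- evaluate_plan(p, objectives, rx)
        tab_rows[[length(tab_rows) + 1L]] <-
            metric_table(list(p), rx, patient = config$patient)
    }
    if (length(tab_rows) == 0L) stop("no readable plans")
    table <- do.call(rbind, tab_rows)
    class(table) <- c("metric_table", "data.frame")
    table$disposition <- vapply(reports, `[[`, "", "disposition")
    table$n_minor <- vapply(reports, function(r) r$n_minor, 0L)
    included <- table$disposition == "INCLUDED"
    if (write_outputs) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        tab_out <- table
        write.csv(tab_out, file.path(config$out_dir, "metrics.csv"),
                  row.names = FALSE)
        jsonlite::write_json(
            lapply(reports, function(r)
                list(institution_id = r$institution_id,
                     technique = r$technique, algorithm = r$algorithm,
                     disposition = r$disposition, n_minor = r$n_minor,
                     results = r$results)),
            file.path(config$out_dir, "reports.json"),
            auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    list(table = table, reports = reports, included = included,
         n_failed = n_failed)
}

#' Cohort summary and group statistics
#'
#' Produces the benchmark-shaped outputs from an evaluation: the
#' median/mean/sd summary per technique over *included* plans, the
#' minor-deviation tally per objective, and the Kruskal-Wallis group
#' comparisons (per technique and per algorithm) under the selective
#' multiplicity policy. With a single group the summary is still produced
#' and the statistics are skipped with a warning.
#'
#' @param evaluation result of [cmd_evaluate()].
#' @param config a [pipeline_config()].
#' @param write_outputs write `summary.csv` / `statistics.json`?
#' @return list with `summary`, `deviations`, `stats_technique`,
#'   `stats_algorithm`, `n_included`.
#' @export
cmd_cohort <- function(evaluation, config = pipeline_config(),
                       write_outputs = FALSE) {
    tab <- evaluation$table[evaluation$included, , drop = FALSE]
    tab$disposition <- NULL; tab$n_minor <- NULL
    class(tab) <- c("metric_table", "data.frame")
    summary <- summarize_cohort(tab, "technique")
    deviations <- tally_deviations(evaluation$reports)
    fam <- config$multiplicity_family
    run_stats <- function(by) {
        if (length(unique(tab[[by]])) < 2) {
            warning("only one ", by, " group; statistics skipped")
            return(NULL)
        }
        if (nrow(tab) < 3) {
            warning("fewer than 3 included plans; ", by,
                    " statistics skipped")
            return(NULL)
        }
        compare_groups(tab, by, config$primary_metric, metrics = fam)
    }
    stats_t <- run_stats("technique")
    stats_a <- run_stats("algorithm")
    if (write_outputs) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        write.csv(summary, file.path(config$out_dir, "summary.csv"),
                  row.names = FALSE)
        as_json <- function(st) lapply(st, function(r)
            list(H = r$H, df = r$df, p = r$p, adjusted_p = r$adjusted_p,
                 significant = r$significant, policy = r$policy,
                 group_ns = r$group_ns, method = r$method))
        jsonlite::write_json(
            list(policy = "primary metric unadjusted; Holm-Bonferroni for the rest",
                 primary_metric = config$primary_metric,
                 technique = if (!is.null(stats_t)) as_json(stats_t),
                 algorithm = if (!is.null(stats_a)) as_json(stats_a)),
            file.path(config$out_dir, "statistics.json"),
            auto_unbox = TRUE, digits = NA, null = "null")
    }
    list(summary = summary, deviations = deviations,
         stats_technique = stats_t, stats_algorithm = stats_a,
         n_included = nrow(tab))
}
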