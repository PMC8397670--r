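# Tiered objective protocol: each target objective has a main comparison
# and an optional "minor deviation" fallback (either a relaxed limit, a
# relaxed metric, or both); OAR rules are hard (no minor tier). Plans
# labelled with the pencil-beam algorithm are excluded outright, and any
# VIOLATION verdict excludes the plan from cohort analysis.

#' Construct a planning objective
#'
#' @param id short label, e.g. `"PTV_coverage"`.
#' @param role structure role the metric is evaluated on, or `"PLAN"` for
#'   plan-level indices (conformity).
#' @param metric metric kind as in [dvh_metric()], or `"CI_RTOG"`.
#' @param value metric parameter (e.g. 95 for D95%).
#' @param comparator `"<"` or `">"` (strict, as printed in protocols:
#'   boundary equality fails the comparison).
#' @param limit main limit (Gy, % , ml or unitless depending on metric).
#' @param minor_metric,minor_value,minor_limit the minor-deviation tier;
#'   `NULL` for hard rules. When only the limit relaxes, repeat the metric.
#' @param report_only if `TRUE` the objective is evaluated and reported but
#'   never produces a verdict (ALARA-style objectives).
#' @return an object of class `objective`.
#' @export
objective <- function(id, role, metric, value = NULL, comparator, limit,
                      minor_metric = NULL, minor_value = NULL,
                      minor_limit = NULL, report_only = FALSE) {
    comparator <- match.arg(comparator, c("<", ">"))
    if (!is.null(minor_limit) && is.null(minor_metric)) {
        minor_metric <- metric; minor_value <- value
    }
    if (!is.null(minor_limit) && identical(minor_metric, metric) &&
        identical(minor_value, value)) {
        # same metric: the minor limit must be strictly weaker
        weaker <- if (comparator == "<") minor_limit > limit
                  else minor_limit < limit
        if (!weaker) stop("minor limit must be strictly weaker than the limit")
    }
    structure(list(id = id, role = role, metric = metric, value = value,
                   comparator = comparator, limit = limit,
                   minor_metric = minor_metric, minor_value = minor_value,
                   minor_limit = minor_limit, report_only = report_only),
              class = "objective")
}

#' The benchmark objective protocol
#'
#' The tiered target objectives and OAR constraints of the mean-ITV-dose
#' prescription protocol, for a 3 x 21.5 Gy prescription:
#' \itemize{
#'   \item PTV coverage: D95% > 45.2 Gy (70% of prescription); minor
#'     deviation if instead D90% > 45.2 Gy;
#'   \item ITV coverage: D95% > 58.1 Gy (90%); minor if D90% > 58.1 Gy;
#'   \item conformity: CI_RTOG < 1.20; minor < 1.25;
#'   \item PTV hot spot: D0.1ml < 69 Gy (107%); minor < 71 Gy (110%);
#'   \item spinal canal D0.1ml < 18 Gy (hard);
#'   \item chest wall V30Gy < 30 ml (hard);
#'   \item bilateral lungs: ALARA, report-only (mean lung doses are
#'     reported, never produce a verdict).
#' }
#' By default the thresholds are the *printed* protocol values (rounded
#' half-up to the precision the protocol was distributed with: 45.2, 58.1,
#' 69, 71 Gy); `basis = "percent"` instead derives them exactly from the
#' prescription (45.15, 58.05, 69.015, 70.95 Gy).
#'
#' @param rx a [prescription()].
#' @param basis `"printed"` (default) or `"percent"`.
#' @return list of [objective()]s, ordered as in the protocol (the order in
#'   which minor deviations are tallied).
#' @export
default_objectives <- function(rx = prescription(),
                               basis = c("printed", "percent")) {
    basis <- match.arg(basis)
    th <- if (basis == "printed") {
        c(cov = display_round(dose_at_percent(rx, 70), 1),
          itv = display_round(dose_at_percent(rx, 90), 1),
          hot = display_round(dose_at_percent(rx, 107), 0),
          hot_minor = display_round(dose_at_percent(rx, 110), 0))
    } else {
        c(cov = dose_at_percent(rx, 70), itv = dose_at_percent(rx, 90),
          hot = dose_at_percent(rx, 107), hot_minor = dose_at_percent(rx, 110))
    }
    list(
        objective("PTV_coverage", "PTV", "D_pct", 95, ">", th[["cov"]],
                  minor_metric = "D_pct", minor_value = 90,
                  minor_limit = th[["cov"]]),
        objective("ITV_coverage", "ITV", "D_pct", 95, ">", th[["itv"]],
                  minor_metric = "D_pct", minor_value = 90,
                  minor_limit = th[["itv"]]),
        objective("CI", "PLAN", "CI_RTOG", NULL, "<", 1.20,
                  minor_limit = 1.25),
        objective("D0.1ml", "PTV", "D_absvol", 0.1, "<", th[["hot"]],
                  minor_limit = th[["hot_minor"]]),
        objective("spinal_canal_D0.1ml", "SPINAL_CANAL", "D_absvol", 0.1,
                  "<", 18),
        objective("chest_wall_V30Gy", "CHEST_WALL", "V_dose_cc", 30,
                  "<", 30),
        objective("lungs_ALARA", "LUNG_IPSI", "Dmean", NULL, "<", Inf,
                  report_only = TRUE))
}

eval_objective_metric <- function(plan, role, metric, value, rx,
                                  bin_width = 0.1) {
    if (identical(metric, "CI_RTOG")) return(ci_rtog(plan))
    dvh_metric(plan, metric, value = value, role = role,
               rx_gy = rx$nominal_total, bin_width = bin_width)
}

compare <- function(x, comparator, limit) {
    if (comparator == "<") x < limit else x > limit
}

#' Evaluate a plan against the objective protocol
#'
#' Requires a normalized plan (mean ITV dose equal to the prescription's
#' nominal total) since every threshold assumes that normalization. Each
#' objective gets a verdict: `PASS` if the main comparison holds, `MINOR`
#' if it fails but the minor tier holds, `VIOLATION` otherwise; hard rules
#' have no minor tier; report-only objectives get verdict `REPORT`. Plan
#' disposition: `EXCLUDED_ALGORITHM` for pencil-beam plans,
#' `EXCLUDED_CONSTRAINT` when any verdict is `VIOLATION`, else `INCLUDED`
#' (a plan with minor deviations — even several — remains included, and
#' the report flags how many).
#'
#' @param plan a normalized [sbrt_plan()].
#' @param objectives list of [objective()]s from [default_objectives()].
#' @param rx the [prescription()].
#' @param bin_width DVH bin width, Gy.
#' @return an object of class `objective_report`: data frame of per-
#'   objective results plus fields `disposition` and `n_minor`.
#' @export
evaluate_plan <- function(plan, objectives = default_objectives(rx),
                          rx = prescription(), bin_width = 0.1) {
    if (!is_normalized(plan, rx))
        stop("plan is not normalized to the prescription (mean ITV dose = ",
             format(mean_itv_dose(plan), digits = 6), " Gy, expected ",
             rx$nominal_total, " Gy); run normalize_plan() first")
    rows <- lapply(objectives, function(ob) {
        if (!identical(ob$role, "PLAN") &&
            is.null(plan$structures[[ob$role]]))
            stop("objective '", ob$id, "' needs structure role '", ob$role,
                 "' which the plan does not contain")
        val <- eval_objective_metric(plan, ob$role, ob$metric, ob$value, rx,
                                     bin_width)
        verdict <- if (ob$report_only) "REPORT"
        else if (compare(val, ob$comparator, ob$limit)) "PASS"
        else if (!is.null(ob$minor_limit)) {
            mval <- eval_objective_metric(plan, ob$role, ob$minor_metric,
                                          ob$minor_value, rx, bin_width)
            if (compare(mval, ob$comparator, ob$minor_limit)) "MINOR"
            else "VIOLATION"
        } else "VIOLATION"
        data.frame(id = ob$id, role = ob$role, metric = ob$metric,
                   value = if (is.null(ob$value)) NA_real_ else ob$value,
                   comparator = ob$comparator, limit = ob$limit,
                   measured = val, verdict = verdict,
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    disposition <- if (plan$meta$algorithm == "PB") "EXCLUDED_ALGORITHM"
        else if (any(df$verdict == "VIOLATION")) "EXCLUDED_CONSTRAINT"
        else "INCLUDED"
    structure(list(results = df, disposition = disposition,
                   n_minor = sum(df$verdict == "MINOR"),
                   institution_id = plan$meta$institution_id,
                   technique = plan$meta$technique,
                   algorithm = plan$meta$algorithm),
              class = "objective_report")
}

#' @export
print.objective_report <- function(x, ...) {
    cat("<objective_report> ", x$institution_id, " [", x$technique, "/",
        x$algorithm, "] -> ", x$disposition,
        if (x$n_minor > 0) paste0(" (", x$n_minor, " minor deviation",
                                  if (x$n_minor > 1) "s", ")"), "\n",
        sep = "")
    df <- x$results
    df$measured <- signif(df$measured, 5)
    print(df, row.names = FALSE)
    invisible(x)
}

#' Tally minor deviations per objective per group
#'
#' Counts `MINOR` verdicts per objective, split by technique and by
#' algorithm, with a total column — the shape of a benchmark deviation
#' table. Excluded plans are not counted in the deviation columns but
#' listed in the `excluded` attribute.
#'
#' @param reports list of [evaluate_plan()] reports.
#' @param group_by `"both"` (default), `"technique"` or `"algorithm"`.
#' @return data frame, one row per objective with a minor tier; attribute
#'   `"excluded"` names the excluded plans and why.
#' @export
tally_deviations <- function(reports, group_by = c("both", "technique",
                                                   "algorithm")) {
    group_by <- match.arg(group_by)
    if (length(reports) < 1L) stop("need at least one report")
    techs <- if (group_by %in% c("both", "technique")) TECHNIQUES else NULL
    algs <- if (group_by %in% c("both", "algorithm")) ALGORITHMS else NULL
    included <- Filter(function(r) r$disposition == "INCLUDED", reports)
    ids <- unique(unlist(lapply(reports, function(r)
        r$results$id[r$results$verdict != "REPORT"])))
    tab <- data.frame(objective = ids, stringsAsFactors = FALSE)
    count_minor <- function(pred)
        vapply(ids, function(oid) sum(vapply(included, function(r)
            pred(r) && any(r$results$id == oid &
                           r$results$verdict == "MINOR"), TRUE)), 0)
    for (g in techs) tab[[g]] <- count_minor(function(r) r$technique == g)
    for (g in algs) tab[[g]] <- count_minor(function(r) r$algorithm == g)
    tab$Total <- count_minor(function(r) TRUE)
    excl <- Filter(function(r) r$disposition != "INCLUDED", reports)
    attr(tab, "excluded") <- data.frame(
        institution_id = vapply(excl, `[[`, "", "institution_id"),
        technique = vapply(excl, `[[`, "", "technique"),
        algorithm = vapply(excl, `[[`, "", "algorithm"),
        disposition = vapply(excl, `[[`, "", "disposition"),
        stringsAsFactors = FALSE)
    tab
}

#' Write / read an objective protocol as YAML
#'
#' Serializes a list of [objective()]s so other prescriptions can reuse the
#' engine.
#'
#' @param objectives list of [objective()]s.
#' @param path YAML file path.
#' @export
write_objectives_yaml <- function(objectives, path) {
    yaml::write_yaml(lapply(objectives, unclass), path)
    invisible(path)
}

#' @rdname write_objectives_yaml
#' @export
read_objectives_yaml <- function(path) {
    raw <- yaml::read_yaml(path)
    lapply(raw, function(o) do.call(objective, o))
}
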