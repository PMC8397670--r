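#' Per-plan metric table
#'
#' Computes, for each (normalized) plan, the full set of benchmark metrics:
#' ITV median dose and V90%, PTV mean/median dose, V70%, dose to the
#' hottest 0.1 ml, D2% and D98%, the RTOG and Paddick conformity indices,
#' the gradient index, mean ipsi- and contralateral lung dose and chest
#' wall V30Gy (absolute ml). One row per plan; percent-denominated columns
#' state their denominator in the column name.
#'
#' @param plans list of normalized [sbrt_plan()]s.
#' @param rx the [prescription()].
#' @param bin_width DVH bin width, Gy.
#' @param patient optional patient/phantom label recycled across rows.
#' @return data frame of class `metric_table`.
#' @export
metric_table <- function(plans, rx = prescription(), bin_width = 0.1,
                         patient = NA_character_) {
    rows <- lapply(plans, function(p) {
        met <- function(kind, value = NULL, role)
            dvh_metric(p, kind, value = value, role = role,
                       rx_gy = rx$nominal_total, bin_width = bin_width)
        vols <- isodose_volumes(p)
        data.frame(
            institution_id = p$meta$institution_id,
            technique = p$meta$technique,
            algorithm = p$meta$algorithm,
            itv_dmedian_gy = met("Dmedian", role = "ITV"),
            itv_v90pct_pct = met("V_pct", 90, role = "ITV"),
            ptv_dmean_gy = met("Dmean", role = "PTV"),
            ptv_dmedian_gy = met("Dmedian", role = "PTV"),
            ptv_v70pct_pct = met("V_pct", 70, role = "PTV"),
            ptv_d01ml_gy = met("D_absvol", 0.1, role = "PTV"),
            ptv_d2pct_gy = met("D_pct", 2, role = "PTV"),
            ptv_d98pct_gy = met("D_pct", 98, role = "PTV"),
            ci_rtog = ci_rtog(vols),
            ci_paddick = ci_paddick(vols),
            gi = gradient_index(vols),
            lung_ipsi_dmean_gy = met("Dmean", role = "LUNG_IPSI"),
            lung_contra_dmean_gy = met("Dmean", role = "LUNG_CONTRA"),
            chest_wall_v30gy_cc = met("V_dose_cc", 30, role = "CHEST_WALL"),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$patient <- rep_len(patient, nrow(out))
    class(out) <- c("metric_table", "data.frame")
    out
}

metric_columns <- function(table) {
    setdiff(names(table), c("institution_id", "technique", "algorithm",
                            "patient"))
}

#' Group summary of a metric table
#'
#' Median, mean and sample standard deviation (n-1 denominator) of every
#' metric per group — the shape of a benchmark cohort-summary table. The
#' median uses the midpoint convention for even group sizes; the standard
#' deviation of a single-plan group is reported as `NA`.
#'
#' @param table a [metric_table()].
#' @param group_by grouping column, default `"technique"`.
#' @return data frame with columns `group`, `metric`, `median`, `mean`,
#'   `sd`, `n`.
#' @export
summarize_cohort <- function(table, group_by = "technique") {
    if (!group_by %in% names(table))
        stop("unknown grouping column '", group_by, "'")
    groups <- unique(table[[group_by]])
    mets <- metric_columns(table)
    rows <- list()
    for (g in groups) {
        sub <- table[table[[group_by]] == g, , drop = FALSE]
        if (nrow(sub) == 0L) stop("empty group '", g, "'")
        for (m in mets) {
            v <- sub[[m]]
            rows[[length(rows) + 1L]] <- data.frame(
                group = g, metric = m, median = median(v), mean = mean(v),
                sd = if (length(v) > 1) sd(v) else NA_real_,
                n = length(v), stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

# midranks with tie bookkeeping
midranks <- function(x) {
    r <- rank(x, ties.method = "average")
    tie_sizes <- as.numeric(table(x))
    list(r = r, ties = tie_sizes[tie_sizes > 1])
}

#' Tie-corrected Kruskal-Wallis rank test
#'
#' From-scratch implementation of the k-sample Kruskal-Wallis test on
#' midranks with the standard tie correction:
#' `H = [12 / (N(N+1))] * sum_i n_i (rbar_i - (N+1)/2)^2 / C` with
#' `C = 1 - sum(t^3 - t) / (N^3 - N)` over tie groups of size `t`. The
#' p-value is the upper-tail chi-square probability with `k - 1` degrees of
#' freedom; for small samples (`N <= exact_max`, default off) the exact
#' permutation p-value over all assignments of the observed values to the
#' group sizes is computed instead. When all values are identical the
#' statistic is 0 and p = 1 by convention.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length; at least 2 groups, total
#'   `N >= 3`.
#' @param exact_max if the total sample size is at most this, use the exact
#'   permutation distribution (feasible up to about N = 12).
#' @return an object of class `kw_result` with fields `H`, `df`, `p`,
#'   `group_ns`, `tie_correction` and `method`.
#' @export
kruskal_wallis <- function(values, groups, exact_max = 0) {
    groups <- as.factor(groups)
    stopifnot(length(values) == length(groups))
    ok <- !is.na(values) & !is.na(groups)
    values <- values[ok]; groups <- droplevels(groups[ok])
    k <- nlevels(groups)
    N <- length(values)
    if (k < 2) stop("need at least 2 groups")
    if (N < 3) stop("need at least 3 observations")
    ns <- as.numeric(table(groups))
    if (any(ns < 1)) stop("each group needs at least one observation")
    H <- kw_statistic(values, groups)
    C <- kw_tie_correction(values)
    method <- "chi-square approximation"
    if (C == 0) {          # all values identical
        p <- 1
    } else if (N <= exact_max) {
        p <- kw_exact_p(values, groups)
        method <- "exact permutation"
    } else {
        p <- pchisq(H, df = k - 1, lower.tail = FALSE)
    }
    structure(list(H = H, df = k - 1, p = p, group_ns = ns,
                   tie_correction = C, method = method),
              class = "kw_result")
}

kw_tie_correction <- function(values) {
    N <- length(values)
    t <- as.numeric(table(values))
    1 - sum(t^3 - t) / (N^3 - N)
}

kw_statistic <- function(values, groups) {
    N <- length(values)
    r <- rank(values, ties.method = "average")
    rbar <- tapply(r, groups, mean)
    ns <- tapply(r, groups, length)
    H0 <- 12 / (N * (N + 1)) * sum(ns * (rbar - (N + 1) / 2)^2)
    C <- kw_tie_correction(values)
    if (C == 0) 0 else H0 / C
}

# exact permutation p-value: enumerate all distinct assignments of the
# observed values to the group sizes and compare H
kw_exact_p <- function(values, groups) {
    ns <- table(groups)
    H_obs <- kw_statistic(values, groups)
    n <- length(values)
    count <- c(total = 0, ge = 0)
    assign_rec <- function(remaining_idx, gi, labels) {
        if (gi == length(ns)) {
            labels[remaining_idx] <- gi
            g <- factor(labels, levels = seq_along(ns))
            H <- kw_statistic(values, g)
            count["total"] <<- count["total"] + 1
            if (H >= H_obs - 1e-12) count["ge"] <<- count["ge"] + 1
            return(invisible())
        }
        picks <- utils::combn(remaining_idx, ns[gi], simplify = FALSE)
        for (p in picks) {
            labels[p] <- gi
            assign_rec(setdiff(remaining_idx, p), gi + 1, labels)
        }
    }
    assign_rec(seq_len(n), 1, integer(n))
    unname(count["ge"] / count["total"])
}

#' @export
print.kw_result <- function(x, ...) {
    cat("Kruskal-Wallis (tie-corrected): H = ", format(x$H, digits = 5),
        ", df = ", x$df, ", p = ", format.pval(x$p, digits = 4),
        " [", x$method, "]\n", sep = "")
    if (!is.null(x$adjusted_p))
        cat("  multiplicity-adjusted p = ",
            format.pval(x$adjusted_p, digits = 4), " (", x$policy, ")\n",
            sep = "")
    invisible(x)
}

#' Selective multiplicity correction across tested metrics
#'
#' Implements the benchmark's multiplicity policy: the single primary
#' metric (the study's primary interest, mean PTV dose) is tested without
#' correction; all other metrics in the family are Holm-Bonferroni
#' adjusted. Significance is declared at 0.05.
#'
#' @param results named list of [kruskal_wallis()] results, names =
#'   metric names.
#' @param primary_metric name of the primary metric; must be present.
#' @param alpha significance level (default 0.05).
#' @return the same list with `adjusted_p`, `significant` and `policy`
#'   fields added to each element.
#' @export
multiplicity_policy <- function(results, primary_metric = "ptv_dmean_gy",
                                alpha = 0.05) {
    if (!primary_metric %in% names(results))
        stop("primary metric '", primary_metric, "' is not among the results")
    others <- setdiff(names(results), primary_metric)
    padj <- if (length(others))
        p.adjust(vapply(results[others], `[[`, 0, "p"), method = "holm")
    else numeric(0)
    for (m in names(results)) {
        if (m == primary_metric) {
            results[[m]]$adjusted_p <- results[[m]]$p
            results[[m]]$policy <- "primary: unadjusted"
        } else {
            results[[m]]$adjusted_p <- unname(padj[m])
            results[[m]]$policy <- "Holm-Bonferroni within metric family"
        }
        results[[m]]$significant <- results[[m]]$adjusted_p < alpha
    }
    results
}

#' Compare all metrics between groups
#'
#' Runs the tie-corrected Kruskal-Wallis test for every metric column of a
#' metric table between the levels of `group_by`, then applies the
#' selective multiplicity policy.
#'
#' @param table a [metric_table()].
#' @param group_by grouping column (`"technique"` or `"algorithm"`).
#' @param primary_metric the uncorrected primary metric.
#' @param metrics metric columns to test; default all. Metrics with zero
#'   spread are skipped.
#' @return named list of [kruskal_wallis()] results with adjusted p-values.
#' @export
compare_groups <- function(table, group_by = "technique",
                           primary_metric = "ptv_dmean_gy",
                           metrics = NULL) {
    if (!group_by %in% names(table))
        stop("unknown grouping column '", group_by, "'")
    if (length(unique(table[[group_by]])) < 2)
        stop("need at least 2 groups to compare")
    if (is.null(metrics)) metrics <- metric_columns(table)
    results <- list()
    for (m in metrics) {
        v <- table[[m]]
        if (all(is.na(v))) next
        results[[m]] <- kruskal_wallis(v, table[[group_by]])
    }
    multiplicity_policy(results, primary_metric)
}
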