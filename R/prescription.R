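#' Dose prescription anchored to the mean ITV dose
#'
#' The study prescription used throughout the package: `n_fractions` times
#' `dose_per_fraction` Gy, normalized so that the *mean ITV dose* equals the
#' nominal total (default 3 x 21.5 Gy = 64.5 Gy, a biologically effective
#' dose of 203 Gy_10). Anchoring the prescription to the mean ITV dose,
#' rather than to a PTV-covering isodose, is what makes dose distributions
#' comparable across delivery techniques and institutions.
#'
#' @param n_fractions number of fractions (default 3).
#' @param dose_per_fraction dose per fraction in Gy (default 21.5).
#' @param alpha_beta linear-quadratic alpha/beta ratio in Gy (default 10,
#'   the conventional tumor value; BED values are then "Gy_10").
#' @param anchor normalization anchor; only `"MEAN_ITV"` is defined.
#' @return an object of class `prescription` with the additional field
#'   `nominal_total = n_fractions * dose_per_fraction`.
#' @export
prescription <- function(n_fractions = 3, dose_per_fraction = 21.5,
                         alpha_beta = 10, anchor = "MEAN_ITV") {
    stopifnot(n_fractions > 0, dose_per_fraction > 0, alpha_beta > 0)
    anchor <- match.arg(anchor, "MEAN_ITV")
    structure(list(n_fractions = n_fractions,
                   dose_per_fraction = dose_per_fraction,
                   alpha_beta = alpha_beta, anchor = anchor,
                   nominal_total = n_fractions * dose_per_fraction),
              class = "prescription")
}

#' @export
print.prescription <- function(x, ...) {
    cat("<prescription> ", x$n_fractions, " x ", x$dose_per_fraction,
        " Gy = ", x$nominal_total, " Gy to the mean ITV dose (BED = ",
        display_round(bed(x$nominal_total, x$n_fractions, x$alpha_beta), 0),
        " Gy_", x$alpha_beta, ")\n", sep = "")
    invisible(x)
}

#' Linear-quadratic biologically effective dose
#'
#' `BED = D * (1 + (D/n) / (alpha/beta))` for a total dose `D` delivered in
#' `n` equal fractions. For the study prescription, 3 x 21.5 Gy,
#' `bed(64.5, 3, 10)` is 203.175 Gy_10, displayed as 203 Gy_10 under
#' half-up integer rounding (see [display_round()]).
#'
#' @param total_dose total physical dose in Gy.
#' @param n_fractions number of fractions.
#' @param alpha_beta alpha/beta ratio in Gy.
#' @return BED in Gy_(alpha/beta), unrounded.
#' @export
bed <- function(total_dose, n_fractions, alpha_beta) {
    stopifnot(all(total_dose >= 0), n_fractions > 0, alpha_beta > 0)
    total_dose * (1 + (total_dose / n_fractions) / alpha_beta)
}

#' Absolute dose at a percentage of the prescription
#'
#' Converts a percent-of-prescription level to Gy, unrounded:
#' `pct/100 * nominal_total`. Protocol documents print these thresholds
#' rounded half-up to one decimal (70% of 64.5 Gy = 45.15 Gy, printed
#' 45.2 Gy); use [display_round()] to reproduce the printed values.
#'
#' @param rx a [prescription()].
#' @param pct percentage of the nominal total dose, `> 0`.
#' @return dose in Gy.
#' @export
dose_at_percent <- function(rx, pct) {
    stopifnot(inherits(rx, "prescription"), all(pct > 0))
    pct / 100 * rx$nominal_total
}

#' Half-up display rounding
#'
#' Rounds half-way cases away from zero (the convention of the printed
#' protocol tables), unlike base [round()] which rounds half to even.
#' `display_round(45.15, 1)` is 45.2; `display_round(203.175, 0)` is 203.
#'
#' @param x numeric.
#' @param digits decimal places (Gy thresholds: 1; BED values: 0).
#' @export
display_round <- function(x, digits = 1) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Mean ITV dose of a plan
#' @param plan an [sbrt_plan()].
#' @return occupancy-weighted mean ITV dose, Gy.
#' @export
mean_itv_dose <- function(plan) {
    voxel_mean_dose(plan$grid, plan_structure(plan, "ITV"))
}

#' Normalize a plan to the prescription's mean ITV dose
#'
#' Multiplies the whole dose array by
#' `s = nominal_total / mean_ITV_dose(plan)` so that the voxel-exact mean
#' ITV dose equals the nominal total (64.5 Gy for the study prescription).
#' The operation is idempotent: renormalizing yields a scale factor of 1.
#' Every Gy-denominated DVH metric scales by the same factor.
#'
#' @param plan an [sbrt_plan()].
#' @param rx a [prescription()].
#' @return the plan with scaled dose; the scale factor is attached as
#'   attribute `"scale"`.
#' @export
normalize_plan <- function(plan, rx = prescription()) {
    m <- mean_itv_dose(plan)
    if (!is.finite(m) || m <= 0)
        stop("cannot normalize: mean ITV dose is ", m)
    s <- rx$nominal_total / m
    plan$grid$dose <- plan$grid$dose * s
    attr(plan, "scale") <- s
    plan
}

#' Check that a plan is normalized to the prescription
#' @param plan an [sbrt_plan()].
#' @param rx a [prescription()].
#' @param tol relative tolerance on the mean ITV dose.
#' @export
is_normalized <- function(plan, rx = prescription(), tol = 1e-6) {
    abs(mean_itv_dose(plan) / rx$nominal_total - 1) < tol
}
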