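#' Isodose volumes entering the conformity and gradient indices
#'
#' Computes, by occupancy-weighted voxel thresholding on the dose lattice
#' (no surface extraction), the four volumes the conformity/gradient
#' indices are built from:
#' \describe{
#'   \item{`piv`}{prescription-isodose volume: total volume receiving at
#'     least `ref_dose_gy` (the study uses the 70% isodose, printed as
#'     45.2 Gy).}
#'   \item{`tv`}{the PTV volume.}
#'   \item{`tv_piv`}{the PTV volume receiving at least `ref_dose_gy`.}
#'   \item{`half_piv`}{volume receiving at least `half_dose_gy` (printed
#'     22.6 Gy, i.e. half the printed reference — not recomputed from the
#'     unrounded 45.15 Gy).}
#' }
#'
#' @param plan an [sbrt_plan()].
#' @param ref_dose_gy reference (prescription-level) isodose, Gy.
#' @param half_dose_gy half-level isodose, Gy; defaults to the printed
#'   protocol value when `ref_dose_gy` is the default, otherwise to
#'   `ref_dose_gy / 2`.
#' @return an object of class `isodose_volumes` (all fields cm^3).
#' @export
isodose_volumes <- function(plan, ref_dose_gy = 45.2, half_dose_gy = NULL) {
    if (is.null(half_dose_gy))
        half_dose_gy <- if (identical(ref_dose_gy, 45.2)) 22.6 else
            ref_dose_gy / 2
    vox_cc <- voxel_volume_mm3(plan$grid) / 1000
    dose <- plan$grid$dose
    ptv <- plan_structure(plan, "PTV")$occupancy
    above <- dose >= ref_dose_gy
    structure(list(
        piv = sum(above) * vox_cc,
        tv = sum(ptv) * vox_cc,
        tv_piv = sum(ptv[above]) * vox_cc,
        half_piv = sum(dose >= half_dose_gy) * vox_cc,
        ref_dose_gy = ref_dose_gy, half_dose_gy = half_dose_gy),
        class = "isodose_volumes")
}

#' @export
print.isodose_volumes <- function(x, ...) {
    cat("<isodose_volumes> PIV(", x$ref_dose_gy, " Gy) = ",
        format(x$piv, digits = 4), " cm^3, PTV = ", format(x$tv, digits = 4),
        " cm^3, PTV&PIV = ", format(x$tv_piv, digits = 4),
        " cm^3, V(", x$half_dose_gy, " Gy) = ",
        format(x$half_piv, digits = 4), " cm^3\n", sep = "")
    invisible(x)
}

#' RTOG conformity index
#'
#' `CI_RTOG = PIV / V_PTV`: the prescription-isodose volume relative to the
#' PTV volume. Values above 1 indicate dose spilling outside the target;
#' the study protocol requires `< 1.20` (minor deviation `< 1.25`).
#'
#' @param vols an [isodose_volumes()] (or a plan, which is converted).
#' @param ... passed to [isodose_volumes()] when `vols` is a plan.
#' @export
ci_rtog <- function(vols, ...) {
    vols <- as_isodose_volumes(vols, ...)
    if (vols$tv <= 0) stop("PTV volume is zero")
    vols$piv / vols$tv
}

#' Paddick conformity index
#'
#' `CI_Paddick = TV_PIV^2 / (PIV * V_PTV)`, where `TV_PIV` is the PTV
#' volume covered by the prescription isodose. Lies in `[0, 1]`; 1 only
#' when the prescription isodose coincides with the PTV. Jointly penalizes
#' under-coverage and spillage, and satisfies the identity
#' `ci_paddick * ci_rtog = (TV_PIV / V_PTV)^2` (squared coverage fraction).
#'
#' @inheritParams ci_rtog
#' @export
ci_paddick <- function(vols, ...) {
    vols <- as_isodose_volumes(vols, ...)
    if (vols$tv <= 0) stop("PTV volume is zero")
    if (vols$piv <= 0) stop("prescription-isodose volume is zero")
    vols$tv_piv^2 / (vols$piv * vols$tv)
}

#' Gradient index
#'
#' `GI = V(half level) / V(prescription level)` (study: V(22.6 Gy) /
#' V(45.2 Gy)): how much the low-dose bath expands relative to the
#' prescription isodose. Always `>= 1`; lower is steeper falloff.
#'
#' @inheritParams ci_rtog
#' @export
gradient_index <- function(vols, ...) {
    vols <- as_isodose_volumes(vols, ...)
    if (vols$piv <= 0) stop("prescription-isodose volume is zero")
    vols$half_piv / vols$piv
}

as_isodose_volumes <- function(x, ...) {
    if (inherits(x, "isodose_volumes")) return(x)
    if (inherits(x, "sbrt_plan")) return(isodose_volumes(x, ...))
    stop("expected isodose_volumes or sbrt_plan")
}
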