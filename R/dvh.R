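#' Cumulative dose-volume histogram
#'
#' Computes the occupancy-weighted cumulative DVH of a structure: for every
#' dose level `e` on a fixed grid of bin edges (default width 0.1 Gy,
#' starting at 0), the volume in cm^3 of the structure receiving at least
#' `e`. Fractional voxel occupancies contribute their fraction of the voxel
#' volume, so the curve is exact for the voxelized structure — no dose
#' interpolation between voxels is performed.
#'
#' @param grid a [dose_grid()].
#' @param mask a [structure_mask()] on the same lattice, with positive
#'   volume.
#' @param bin_width DVH bin width in Gy (default 0.1).
#' @return an object of class `dvh_curve` with fields `edges` (Gy),
#'   `cum_volume` (cm^3, non-increasing), `total_volume` (cm^3),
#'   `bin_width`, and `structure` (the structure name).
#' @export
dvh <- function(grid, mask, bin_width = 0.1) {
    check_same_lattice(grid, mask, "dose grid and mask")
    sel <- which(mask$occupancy > 0)
    if (length(sel) == 0L) stop("structure '", mask$name, "' has zero volume")
    w <- mask$occupancy[sel] * voxel_volume_mm3(mask) / 1000
    d <- grid$dose[sel]
    total <- sum(w)
    edges <- seq(0, (floor(max(d) / bin_width) + 1) * bin_width,
                 by = bin_width)
    ord <- order(d)
    ds <- d[ord]
    W <- c(0, cumsum(w[ord]))
    # volume receiving >= e  =  total - (weight of voxels with dose < e)
    nlt <- findInterval(edges, ds, left.open = TRUE)
    cum <- total - W[nlt + 1]
    structure(list(edges = edges, cum_volume = cum, total_volume = total,
                   bin_width = bin_width, structure = mask$name,
                   max_dose = max(d)),
              class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
    cat("<dvh_curve> ", x$structure, ": ",
        format(x$total_volume, digits = 4), " cm^3, ",
        length(x$edges), " bins of ", x$bin_width, " Gy\n", sep = "")
    invisible(x)
}

#' @export
as.data.frame.dvh_curve <- function(x, ...) {
    data.frame(dose_gy = x$edges,
               volume_cc = x$cum_volume,
               volume_pct = 100 * x$cum_volume / x$total_volume)
}

#' Export a DVH curve as CSV
#'
#' Columns: dose level (Gy), cumulative volume (cm^3), cumulative volume
#' (% of structure volume).
#' @param curve a [dvh()] curve.
#' @param path output path.
#' @export
dvh_write_csv <- function(curve, path) {
    df <- as.data.frame(curve)
    names(df) <- c("dose [Gy]", "volume [cm3]", "volume [%]")
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @export
plot.dvh_curve <- function(x, ..., xlab = "Dose [Gy]",
                           ylab = "Volume [%]", type = "l") {
    graphics::plot(x$edges, 100 * x$cum_volume / x$total_volume,
                   type = type, xlab = xlab, ylab = ylab, ...)
    invisible(x)
}

# dose at which the cumulative curve reaches `target_vol` (cm^3), linearly
# interpolated between bin edges; ties broken toward the higher dose, but
# never beyond the maximum dose actually observed in the structure
curve_dose_at_volume <- function(curve, target_vol,
                                 mode = c("interp", "strict")) {
    mode <- match.arg(mode)
    cum <- curve$cum_volume
    edges <- curve$edges
    ok <- which(cum >= target_vol - 1e-12)
    if (length(ok) == 0L) return(0)
    j <- max(ok)
    if (mode == "strict" || j == length(edges)) return(edges[j])
    c0 <- cum[j]; c1 <- cum[j + 1]
    if (c0 - c1 < 1e-15) return(edges[j])
    d <- edges[j] + (c0 - target_vol) / (c0 - c1) * (edges[j + 1] - edges[j])
    if (!is.null(curve$max_dose)) min(d, curve$max_dose) else d
}

# voxel-exact weighted mean / Dx
voxel_mean_dose <- function(grid, mask) {
    w <- mask$occupancy
    sw <- sum(w)
    if (sw <= 0) stop("structure '", mask$name, "' has zero volume")
    sum(grid$dose * w) / sw
}

voxel_dx_exact <- function(grid, mask, x_pct) {
    sel <- which(mask$occupancy > 0)
    w <- mask$occupancy[sel]
    d <- grid$dose[sel]
    ord <- order(d, decreasing = TRUE)
    cw <- cumsum(w[ord])
    target <- x_pct / 100 * sum(w)
    d[ord][match(TRUE, cw >= target - 1e-12)]
}

#' DVH point metrics
#'
#' Evaluates one DVH-derived metric for a structure of a plan, or directly
#' from a precomputed [dvh()] curve. Supported kinds:
#' \describe{
#'   \item{`Dmean`}{mean structure dose, Gy. Voxel-exact (occupancy-weighted
#'     mean), never read off the binned curve, so that the normalization
#'     anchor is not quantized by the bin width.}
#'   \item{`Dmedian`}{median structure dose, Gy; voxel-exact weighted
#'     median (equals `D_pct(50)` up to one bin width).}
#'   \item{`D_pct`}{dose received by at least `value`% of the structure
#'     volume, Gy; read from the cumulative curve with linear interpolation
#'     between the bin edges (`mode = "interp"`, default) or snapped to the
#'     highest qualifying bin edge (`mode = "strict"`).}
#'   \item{`D_absvol`}{dose to the hottest `value` ml of the structure, Gy;
#'     same curve lookup with an absolute volume; ties broken toward the
#'     higher dose (conservative for maximum-dose objectives).}
#'   \item{`V_dose`}{percentage of the structure volume receiving at least
#'     `value` Gy.}
#'   \item{`V_dose_cc`}{absolute volume (cm^3) receiving at least `value`
#'     Gy.}
#'   \item{`V_pct`}{percentage of the structure volume receiving at least
#'     `value`% of the prescription dose; requires `rx_gy`.}
#' }
#'
#' @param x an [sbrt_plan()] (give `role`), or a [dvh()] curve (curve-based
#'   kinds only).
#' @param kind metric kind, see Details.
#' @param value metric parameter (percent, ml or Gy depending on `kind`).
#' @param role structure role, when `x` is a plan.
#' @param rx_gy prescription dose in Gy, needed for `V_pct`.
#' @param bin_width DVH bin width used when a curve must be built.
#' @param mode `"interp"` or `"strict"` bin handling for `D_pct`/`D_absvol`.
#' @return the metric value (Gy, % or cm^3 according to `kind`).
#' @export
dvh_metric <- function(x, kind, value = NULL, role = NULL, rx_gy = NULL,
                       bin_width = 0.1, mode = "interp") {
    kinds <- c("Dmean", "Dmedian", "D_pct", "D_absvol", "V_dose",
               "V_dose_cc", "V_pct")
    kind <- match.arg(kind, kinds)
    if (inherits(x, "sbrt_plan")) {
        if (is.null(role)) stop("role is required when x is a plan")
        mask <- plan_structure(x, role)
        grid <- x$grid
        if (kind == "Dmean") return(voxel_mean_dose(grid, mask))
        if (kind == "Dmedian") return(voxel_dx_exact(grid, mask, 50))
        curve <- dvh(grid, mask, bin_width)
    } else if (inherits(x, "dvh_curve")) {
        curve <- x
        if (kind == "Dmean")   # trapezoidal mean from the binned curve
            return(sum(diff(curve$edges) *
                       (head(curve$cum_volume, -1) +
                        tail(curve$cum_volume, -1)) / 2) / curve$total_volume)
        if (kind == "Dmedian") { kind <- "D_pct"; value <- 50 }
    } else stop("x must be an sbrt_plan or a dvh_curve")
    total <- curve$total_volume
    switch(kind,
        D_pct = {
            if (is.null(value) || value <= 0 || value > 100)
                stop("D_pct requires a percentage in (0, 100]")
            curve_dose_at_volume(curve, value / 100 * total, mode)
        },
        D_absvol = {
            if (is.null(value) || value <= 0)
                stop("D_absvol requires a positive volume in ml")
            if (value > total + 1e-9)
                stop("requested volume ", value, " ml exceeds structure volume ",
                     format(total, digits = 4), " ml")
            curve_dose_at_volume(curve, value, mode)
        },
        V_dose = 100 * curve_volume_at_dose(curve, value) / total,
        V_dose_cc = curve_volume_at_dose(curve, value),
        V_pct = {
            if (is.null(rx_gy)) stop("V_pct requires rx_gy")
            100 * curve_volume_at_dose(curve, value / 100 * rx_gy) / total
        })
}

# cumulative volume (cm^3) at an arbitrary dose level, interpolated
curve_volume_at_dose <- function(curve, d_gy) {
    if (is.null(d_gy) || d_gy < 0) stop("dose level must be >= 0")
    if (d_gy >= max(curve$edges)) return(0)
    stats::approx(curve$edges, curve$cum_volume, xout = d_gy,
                  method = "linear", rule = 2)$y
}
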