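#' @useDynLib sbrtbench, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile runif rnorm sd setNames pchisq p.adjust
#' @importFrom utils write.csv read.csv head tail
NULL

#' Structure roles recognised by the pipeline
#'
#' The canonical structure roles used throughout the package: the two targets
#' (`ITV`, `PTV`), the organs at risk of a peripheral lung lesion
#' (ipsi-/contralateral lung, chest wall, spinal canal, esophagus) and a
#' catch-all `OTHER`.
#'
#' @export
STRUCTURE_ROLES <- c("ITV", "PTV", "LUNG_IPSI", "LUNG_CONTRA",
                     "CHEST_WALL", "SPINAL_CANAL", "ESOPHAGUS", "OTHER")

#' Delivery techniques and dose-calculation algorithm classes
#'
#' `TECHNIQUES`: robotic radiosurgery (`RRS`), modulated delivery (`MOD`,
#' static IMRT or arcs) and 3D-conformal delivery (`3D`).
#' `ALGORITHMS`: Monte Carlo (`MC`), Boltzmann-transport solver (`BT`),
#' collapsed cone (`CC`), analytical anisotropic algorithm (`AAA`) and pencil
#' beam (`PB`; non-compliant for lung SBRT and excluded from cohort analysis).
#'
#' @export
TECHNIQUES <- c("RRS", "MOD", "3D")

#' @rdname TECHNIQUES
#' @export
ALGORITHMS <- c("MC", "BT", "CC", "AAA", "PB")

stop_geometry <- function(...) {
    stop(structure(class = c("sbrtbench_geometry_error", "error", "condition"),
                   list(message = paste0(...), call = sys.call(-1))))
}

stop_parse <- function(...) {
    stop(structure(class = c("sbrtbench_parse_error", "error", "condition"),
                   list(message = paste0(...), call = sys.call(-1))))
}

#' Regular 3D dose lattice
#'
#' A `dose_grid` is a regular, axis-aligned 3D lattice of absorbed dose in
#' Gy. Voxel indices are 0-based in the world-coordinate convention; a
#' voxel's dose is attributed to its centre, and world coordinates are in mm
#' in patient-axis order (x, y, z). The voxel centre of index `(i, j, k)` is
#' at `origin + c(i, j, k) * spacing`.
#'
#' @param origin numeric length-3, position of the first voxel centre (mm).
#' @param spacing numeric length-3, voxel pitch (mm), all `> 0`.
#' @param dims integer length-3, voxel counts.
#' @param dose numeric array of doses in Gy; either a 3D array with
#'   `dim == dims` or a vector of length `prod(dims)` in column-major order
#'   (x fastest). All values must be finite and `>= 0`.
#' @return an object of class `dose_grid` with fields `origin`, `spacing`,
#'   `dims` and `dose` (a 3D array).
#' @export
dose_grid <- function(origin, spacing, dims, dose) {
    origin <- as.numeric(origin); spacing <- as.numeric(spacing)
    dims <- as.integer(dims)
    if (length(origin) != 3L || length(spacing) != 3L || length(dims) != 3L)
        stop_geometry("origin, spacing and dims must have length 3")
    if (any(!is.finite(spacing)) || any(spacing <= 0))
        stop_geometry("spacing must be positive")
    if (any(dims <= 0L)) stop_geometry("dims must be positive")
    dose <- as.numeric(dose)
    if (length(dose) != prod(dims))
        stop_geometry("dose length ", length(dose),
                      " does not match dims (", prod(dims), " voxels)")
    if (any(!is.finite(dose)) || any(dose < 0))
        stop("dose values must be finite and >= 0")
    dim(dose) <- dims
    structure(list(origin = origin, spacing = spacing, dims = dims,
                   dose = dose),
              class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
    cat("<dose_grid> ", paste(x$dims, collapse = " x "),
        " voxels @ ", paste(format(x$spacing), collapse = " x "), " mm\n",
        "  dose range [", format(min(x$dose)), ", ", format(max(x$dose)),
        "] Gy\n", sep = "")
    invisible(x)
}

#' Voxel volume of a lattice, in mm^3
#' @param x a `dose_grid` or `structure_mask`.
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

#' Fractional structure mask on a dose lattice
#'
#' A `structure_mask` stores, for one anatomical structure, the fractional
#' occupancy of every voxel of the lattice it shares with its `dose_grid`
#' (1 = voxel entirely inside the structure). Fractional values arise from
#' partial-volume rasterization of planar contours.
#'
#' @param name structure label as delineated (free text).
#' @param role one of [STRUCTURE_ROLES].
#' @param occupancy numeric array in `[0, 1]`, same layout rules as the
#'   `dose` field of [dose_grid()].
#' @param origin,spacing,dims lattice geometry; must equal the geometry of
#'   the paired dose grid.
#' @return an object of class `structure_mask`.
#' @export
structure_mask <- function(name, role, occupancy, origin, spacing, dims) {
    role <- match.arg(role, STRUCTURE_ROLES)
    origin <- as.numeric(origin); spacing <- as.numeric(spacing)
    dims <- as.integer(dims)
    if (any(spacing <= 0)) stop_geometry("spacing must be positive")
    occupancy <- as.numeric(occupancy)
    if (length(occupancy) != prod(dims))
        stop_geometry("occupancy length does not match dims")
    if (any(!is.finite(occupancy)) || any(occupancy < 0) || any(occupancy > 1))
        stop("occupancy values must lie in [0, 1]")
    dim(occupancy) <- dims
    structure(list(name = name, role = role, occupancy = occupancy,
                   origin = origin, spacing = spacing, dims = dims),
              class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
    cat("<structure_mask> ", x$name, " [", x$role, "], ",
        format(volume(x), digits = 4), " cm^3\n", sep = "")
    invisible(x)
}

same_lattice <- function(a, b, tol = 1e-6) {
    all(a$dims == b$dims) &&
        all(abs(a$origin - b$origin) < tol) &&
        all(abs(a$spacing - b$spacing) < tol)
}

check_same_lattice <- function(a, b, what = "objects") {
    if (!same_lattice(a, b))
        stop_geometry(what, " are not on the same lattice")
    invisible(TRUE)
}

#' Structure volume in cm^3
#'
#' The occupancy-weighted volume of a structure: the sum of fractional voxel
#' occupancies times the voxel volume, converted from mm^3 to cm^3. This is
#' the volume convention used for all volume-denominated metrics (DVH
#' curves, isodose volumes, conformity indices).
#'
#' @param mask a [structure_mask()].
#' @return volume in cm^3.
#' @export
volume <- function(mask) UseMethod("volume")

#' @export
volume.structure_mask <- function(mask) {
    sum(mask$occupancy) * voxel_volume_mm3(mask) / 1000
}

#' Plan metadata
#'
#' @param institution_id opaque institution tag.
#' @param technique one of [TECHNIQUES].
#' @param algorithm one of [ALGORITHMS].
#' @param calc_grid_mm dose-calculation grid size, mm.
#' @param mlc_width_mm MLC leaf width in mm, or `NA` for cone-based robotic
#'   delivery.
#' @param energy_label free-text beam energy description (e.g. "6FF").
#' @return an object of class `plan_meta`.
#' @export
plan_meta <- function(institution_id, technique, algorithm,
                      calc_grid_mm = 2, mlc_width_mm = NA_real_,
                      energy_label = "6FF") {
    technique <- match.arg(technique, TECHNIQUES)
    algorithm <- match.arg(algorithm, ALGORITHMS)
    structure(list(institution_id = as.character(institution_id),
                   technique = technique, algorithm = algorithm,
                   calc_grid_mm = as.numeric(calc_grid_mm),
                   mlc_width_mm = as.numeric(mlc_width_mm),
                   energy_label = as.character(energy_label)),
              class = "plan_meta")
}

#' A treatment plan: dose grid, structure set and metadata
#'
#' The unit of analysis. A plan couples one [dose_grid()] with a set of
#' [structure_mask()]s on the same lattice, keyed by role, plus
#' [plan_meta()]. At least `ITV` and `PTV` masks are required and the ITV
#' must be contained in the PTV up to rasterization tolerance (less than 1%
#' of the ITV occupancy may fall outside the PTV).
#'
#' @param grid a [dose_grid()].
#' @param structures named list of [structure_mask()]s, names = roles.
#' @param meta a [plan_meta()].
#' @param validate set `FALSE` to skip invariant checks (internal use).
#' @return an object of class `sbrt_plan`.
#' @export
sbrt_plan <- function(grid, structures, meta, validate = TRUE) {
    stopifnot(inherits(grid, "dose_grid"), inherits(meta, "plan_meta"))
    if (is.null(names(structures)))
        names(structures) <- vapply(structures, `[[`, "", "role")
    plan <- structure(list(grid = grid, structures = structures, meta = meta),
                      class = "sbrt_plan")
    if (validate) validate_plan(plan)
    plan
}

validate_plan <- function(plan) {
    for (m in plan$structures) {
        if (!inherits(m, "structure_mask")) stop("structures must be masks")
        check_same_lattice(plan$grid, m,
                           paste0("dose grid and structure '", m$name, "'"))
    }
    for (role in c("ITV", "PTV")) {
        if (is.null(plan$structures[[role]]))
            stop("plan must contain an ", role, " mask")
        if (volume(plan$structures[[role]]) <= 0)
            stop(role, " has zero volume")
    }
    itv <- plan$structures$ITV$occupancy
    ptv <- plan$structures$PTV$occupancy
    outside <- sum(pmax(itv - ptv, 0)) / sum(itv)
    if (outside >= 0.01)
        stop_geometry("ITV is not contained in PTV (",
                      format(100 * outside, digits = 3),
                      "% of ITV occupancy outside)")
    invisible(plan)
}

#' @export
print.sbrt_plan <- function(x, ...) {
    cat("<sbrt_plan> ", x$meta$institution_id, " [", x$meta$technique, "/",
        x$meta$algorithm, "]\n", sep = "")
    print(x$grid)
    for (m in x$structures)
        cat("  ", format(m$role, width = 12), format(volume(m), digits = 4),
            "cm^3\n")
    invisible(x)
}

#' Look up a structure by role, with a helpful error
#' @param plan an [sbrt_plan()].
#' @param role one of [STRUCTURE_ROLES].
#' @export
plan_structure <- function(plan, role) {
    m <- plan$structures[[role]]
    if (is.null(m))
        stop("plan has no structure with role '", role, "'")
    m
}

#' World coordinates of all voxel centres
#'
#' @param x a `dose_grid` or `structure_mask`.
#' @return a `prod(dims) x 3` matrix of voxel-centre coordinates in mm,
#'   column-major (x fastest) voxel order.
#' @export
voxel_centers <- function(x) {
    d <- x$dims
    cx <- x$origin[1] + (seq_len(d[1]) - 1) * x$spacing[1]
    cy <- x$origin[2] + (seq_len(d[2]) - 1) * x$spacing[2]
    cz <- x$origin[3] + (seq_len(d[3]) - 1) * x$spacing[3]
    cbind(rep(cx, times = d[2] * d[3]),
          rep(rep(cy, each = d[1]), times = d[3]),
          rep(cz, each = d[1] * d[2]))
}

#' Signed distance from voxel centres to a mask boundary
#'
#' Euclidean distance in mm from every voxel centre to the boundary of the
#' voxelized structure (occupancy `>= 0.5`), negative inside the structure
#' and positive outside. Used by the synthetic dose model, which shapes dose
#' as a function of distance to the PTV surface.
#'
#' @param mask a [structure_mask()].
#' @param threshold occupancy level defining the binary structure.
#' @return numeric 3D array of signed distances (mm).
#' @export
signed_distance_mm <- function(mask, threshold = 0.5) {
    inside <- mask$occupancy >= threshold
    if (!any(inside)) stop("mask is empty at threshold ", threshold)
    d_out <- sqrt(.edt_sq(as.logical(inside), mask$dims, mask$spacing))
    d_in <- sqrt(.edt_sq(as.logical(!inside), mask$dims, mask$spacing))
    # distance to the surface rather than to the nearest voxel centre on the
    # other side: shift each one-sided distance by half a voxel step
    h <- mean(mask$spacing) / 2
    sd <- ifelse(inside, -(pmax(d_in - h, 0)), pmax(d_out - h, 0))
    dim(sd) <- mask$dims
    sd
}

#' Trilinear resampling of a dose grid onto a new lattice
#'
#' Provided for ingestion when dose and structures were exported on
#' different lattices; the analysis functions themselves never resample
#' silently. Query points outside the source grid get the dose of the
#' nearest edge voxel (clamped coordinates).
#'
#' @param grid a [dose_grid()].
#' @param origin,spacing,dims target lattice.
#' @return a [dose_grid()] on the target lattice.
#' @export
resample_trilinear <- function(grid, origin, spacing, dims) {
    dims <- as.integer(dims)
    target <- list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                   dims = dims)
    pts <- voxel_centers(target)
    # continuous source-voxel coordinates (0-based)
    u <- sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
    d <- grid$dims
    val <- numeric(nrow(u))
    u1 <- pmin(pmax(u[, 1], 0), d[1] - 1)
    u2 <- pmin(pmax(u[, 2], 0), d[2] - 1)
    u3 <- pmin(pmax(u[, 3], 0), d[3] - 1)
    i0 <- pmin(floor(u1), d[1] - 2); j0 <- pmin(floor(u2), d[2] - 2)
    k0 <- pmin(floor(u3), d[3] - 2)
    i0 <- pmax(i0, 0); j0 <- pmax(j0, 0); k0 <- pmax(k0, 0)
    fx <- u1 - i0; fy <- u2 - j0; fz <- u3 - k0
    idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
    dv <- grid$dose
    val <- (1 - fx) * (1 - fy) * (1 - fz) * dv[idx(i0,     j0,     k0)] +
           fx       * (1 - fy) * (1 - fz) * dv[idx(i0 + 1, j0,     k0)] +
           (1 - fx) * fy       * (1 - fz) * dv[idx(i0,     j0 + 1, k0)] +
           fx       * fy       * (1 - fz) * dv[idx(i0 + 1, j0 + 1, k0)] +
           (1 - fx) * (1 - fy) * fz       * dv[idx(i0,     j0,     k0 + 1)] +
           fx       * (1 - fy) * fz       * dv[idx(i0 + 1, j0,     k0 + 1)] +
           (1 - fx) * fy       * fz       * dv[idx(i0,     j0 + 1, k0 + 1)] +
           fx       * fy       * fz       * dv[idx(i0 + 1, j0 + 1, k0 + 1)]
    dose_grid(origin, spacing, dims, val)
}
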