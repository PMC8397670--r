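# Synthetic phantom patients and technique-flavored dose distributions.
#
# The generator emulates the statistical structure of a multi-institutional
# lung-SBRT planning benchmark: two peripheral-lesion phantoms (ellipsoidal
# ITV, 5 mm isotropic ITV->PTV margin, PTV ~ 23.8 / 19.4 cm^3) and a dose
# model shaped purely by the signed Euclidean distance to the PTV surface —
# a plateau with a central hotspot inside the target, a sigmoidal penumbra
# across the PTV shell, and an exponential-in-distance falloff outside.
# No beam transport is simulated: the downstream analytics only ever see the
# resulting dose field, so a falloff model is sufficient.

#' Phantom patient specification
#'
#' @param itv_semi_axes ellipsoid semi-axes of the ITV, mm.
#' @param itv_center ITV centre in world coordinates, mm.
#' @param margin_mm isotropic ITV to PTV expansion (default 5 mm).
#' @param ptv_target_cm3 optional requested PTV volume; the ITV semi-axes
#'   are scaled (shape-preserving) so the dilated PTV lands within +-5% of
#'   this volume.
#' @param origin,spacing,dims lattice geometry (defaults: 2.5 mm isotropic,
#'   64 x 54 x 54 voxels, i.e. 16 x 13.5 x 13.5 cm).
#' @param oar_layout organ-at-risk layout, see [oar_layout_default()].
#' @param name phantom label.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(itv_semi_axes = c(13.5, 12.5, 12.5),
                         itv_center = c(45, 66, 66),
                         margin_mm = 5,
                         ptv_target_cm3 = NULL,
                         origin = c(0, 0, 0), spacing = c(2.5, 2.5, 2.5),
                         dims = c(64L, 54L, 54L),
                         oar_layout = oar_layout_default(itv_center),
                         name = "phantom") {
    stopifnot(all(itv_semi_axes > 0), margin_mm >= 0, all(spacing > 0))
    structure(list(itv_semi_axes = itv_semi_axes, itv_center = itv_center,
                   margin_mm = margin_mm, ptv_target_cm3 = ptv_target_cm3,
                   origin = origin, spacing = spacing, dims = as.integer(dims),
                   oar_layout = oar_layout, name = name),
              class = "phantom_spec")
}

#' Default organ-at-risk layout for a peripheral left-sided lesion
#'
#' Parametric OAR geometry on the phantom lattice, all positions in mm:
#' ipsi- and contralateral lung boxes, a chest-wall slab (its inner face at
#' `chest_wall_x` on the lateral side of the lesion), and spinal-canal and
#' esophagus cylinders along the cranio-caudal axis.
#'
#' @param center ITV centre, mm.
#' @param chest_wall_x x position of the chest wall inner face, mm; a large
#'   negative offset from the lesion models a lesion distant from the
#'   thoracic wall.
#' @export
oar_layout_default <- function(center, chest_wall_x = center[1] - 19.5) {
    list(
        lung_ipsi = list(lo = c(chest_wall_x, 15, 5),
                         hi = c(center[1] + 50, 120, 128)),
        lung_contra = list(lo = c(center[1] + 60, 15, 5),
                           hi = c(center[1] + 110, 120, 128)),
        chest_wall = list(lo = c(chest_wall_x - 12, 10, 2.5),
                          hi = c(chest_wall_x, 125, 130)),
        spinal_canal = list(center = c(center[1] + 55, 118, 0), radius = 6,
                            axis = "z"),
        esophagus = list(center = c(center[1] + 48, 95, 0), radius = 6,
                         axis = "z"))
}

#' Preset phantoms emulating the two benchmark patients
#'
#' Two peripheral early-stage NSCLC lesions: patient 1 in the left upper
#' lobe, close to the chest wall, PTV target 23.8 cm^3; patient 2 in the
#' right lower lobe, distant from the chest wall, PTV target 19.4 cm^3.
#' Both use the 5 mm isotropic ITV to PTV margin.
#'
#' @return a `phantom_spec`.
#' @export
phantom_patient1 <- function() {
    phantom_spec(itv_semi_axes = c(13.5, 12.5, 12.5),
                 ptv_target_cm3 = 23.8, name = "patient1")
}

#' @rdname phantom_patient1
#' @export
phantom_patient2 <- function() {
    ctr <- c(45, 66, 66)
    phantom_spec(itv_semi_axes = c(12.2, 11.4, 11.4), itv_center = ctr,
                 ptv_target_cm3 = 19.4,
                 oar_layout = oar_layout_default(ctr, chest_wall_x = ctr[1] - 45),
                 name = "patient2")
}

#' Build phantom structure masks
#'
#' Rasterizes the ITV ellipsoid (fractional occupancy), derives the PTV as
#' the exact morphological dilation of the ITV by `margin_mm` (using the
#' analytic signed distance to the ellipsoid surface, with a linear
#' partial-volume ramp one voxel wide), and rasterizes the OAR layout. The
#' result is deterministic given the spec; `seed` is accepted for interface
#' symmetry with [make_dose()] but the masks do not depend on it — in the
#' benchmark, every institution plans the *same* two patients.
#'
#' @param spec a [phantom_spec()].
#' @param seed unused (masks are deterministic).
#' @return named list of [structure_mask()]s (a plan skeleton without dose),
#'   with the lattice geometry attached as attribute `"lattice"`.
#' @export
make_phantom <- function(spec, seed = NULL) {
    g <- list(origin = spec$origin, spacing = spec$spacing, dims = spec$dims)
    axes <- spec$itv_semi_axes
    if (!is.null(spec$ptv_target_cm3)) {
        m <- spec$margin_mm
        volfun <- function(s) 4 / 3 * pi * prod(s * axes + m) / 1000 -
            spec$ptv_target_cm3
        s <- stats::uniroot(volfun, c(0.2, 5))$root
        axes <- axes * s
    }
    mk <- function(name, role, occ)
        structure_mask(name, role, occ, g$origin, g$spacing, g$dims)
    h <- mean(spec$spacing)
    centers <- voxel_centers(g)
    build_targets <- function(axes) {
        itv_occ <- rasterize_ellipsoid(spec$itv_center, axes, g$origin,
                                       g$spacing, g$dims)
        itv <- mk("ITV", "ITV", itv_occ)
        if (sum(itv_occ) == 0)
            stop_geometry("ITV does not intersect the lattice")
        # exact analytic distance to the ITV surface: the PTV is the true
        # morphological dilation by the margin, with a one-voxel linear
        # partial-volume ramp at its surface
        sd_itv <- ellipsoid_signed_distance(centers, spec$itv_center, axes)
        if (spec$margin_mm == 0) {
            ptv <- mk("PTV", "PTV", itv_occ)
            sdist <- sd_itv
        } else {
            occ <- pmin(1, pmax(0, 0.5 + (spec$margin_mm - sd_itv) / h))
            ptv <- mk("PTV", "PTV", occ)
            sdist <- sd_itv - spec$margin_mm
        }
        dim(sdist) <- g$dims
        list(itv = itv, ptv = ptv, sdist = sdist)
    }
    tg <- build_targets(axes)
    if (!is.null(spec$ptv_target_cm3)) {
        # the analytic first guess ignores the corner rounding of the true
        # morphological dilation; correct the semi-axes additively (the
        # margin acts additively on every axis) until the rasterized PTV
        # volume is within 1% of the target
        for (iter in 1:4) {
            v <- volume(tg$ptv)
            if (abs(v / spec$ptv_target_cm3 - 1) < 0.01) break
            r_eq <- (3 * v * 1000 / (4 * pi))^(1 / 3)
            r_target <- (3 * spec$ptv_target_cm3 * 1000 / (4 * pi))^(1 / 3)
            axes <- axes + (r_target - r_eq)
            tg <- build_targets(axes)
        }
    }
    itv <- tg$itv; ptv <- tg$ptv
    boundary_occ <- sum(ptv$occupancy[1, , ]) + sum(ptv$occupancy[g$dims[1], , ]) +
        sum(ptv$occupancy[, 1, ]) + sum(ptv$occupancy[, g$dims[2], ]) +
        sum(ptv$occupancy[, , 1]) + sum(ptv$occupancy[, , g$dims[3]])
    if (boundary_occ > 0)
        stop_geometry("PTV touches the lattice boundary; enlarge the lattice")
    ol <- spec$oar_layout
    box <- function(b) rasterize_box(b$lo, b$hi, g$origin, g$spacing, g$dims)
    cyl <- function(b) rasterize_cylinder(b$center, b$radius, b$axis,
                                          origin = g$origin,
                                          spacing = g$spacing, dims = g$dims)
    masks <- list(
        ITV = itv, PTV = ptv,
        LUNG_IPSI = mk("Lung ipsi", "LUNG_IPSI",
                       pmax(0, box(ol$lung_ipsi) - ptv$occupancy)),
        LUNG_CONTRA = mk("Lung contra", "LUNG_CONTRA", box(ol$lung_contra)),
        CHEST_WALL = mk("Chest wall", "CHEST_WALL", box(ol$chest_wall)),
        SPINAL_CANAL = mk("Spinal canal", "SPINAL_CANAL",
                          cyl(ol$spinal_canal)),
        ESOPHAGUS = mk("Esophagus", "ESOPHAGUS", cyl(ol$esophagus)))
    attr(masks, "lattice") <- g
    attr(masks, "phantom") <- spec$name
    attr(masks, "margin_mm") <- spec$margin_mm
    # cache the signed PTV-surface distance field (mm): derived from the
    # distance-to-ITV field the PTV was dilated from, so it is continuous
    # across the PTV shell rather than quantized to the voxel pitch
    attr(masks, "sdist_ptv") <- tg$sdist
    masks
}

#' Technique dose-profile parameters
#'
#' Parameters of the distance-based dose model for one delivery-technique
#' class. The dose (before normalization) at signed PTV-surface distance
#' `s` (mm, negative inside) is `64.5 * g(s)` with
#' \itemize{
#'   \item inside the ITV (deeper than the margin): a plateau rising from 1
#'     toward `hotspot_factor` over a few mm;
#'   \item across the PTV shell (`-margin <= s < 0`): a logistic drop from
#'     the plateau toward `surface_frac`, centred at relative shell depth
#'     `shell_drop_u0` with width `shell_drop_w` — an early, sharp drop
#'     (robotic cone beams) lowers the mean PTV dose while keeping the ITV
#'     covered; a late, soft drop (3D-conformal) keeps the shell hot;
#'   \item outside: exponential falloff halving every `falloff_scale_mm`,
#'     steepening by `far_steepening` once the dose drops below 40% of the
#'     surface level (dose baths decay faster far from the target than in
#'     the penumbra), on top of a flat scatter bath of `bath_frac` of the
#'     prescription;
#'   \item `penumbra_asymmetry` elongates the falloff on the chest-wall
#'     (-x) side and shortens it medially;
#'   \item `conformity_wobble_mm` modulates the isodose radius by a smooth
#'     random directional field (drawn from the plan seed), emulating the
#'     imperfect conformity of real plans: parts of the PTV surface dip
#'     below the prescription isodose (coverage < 100%) while the isodose
#'     bulges outward elsewhere (CI_RTOG > 1);
#'   \item i.i.d. Gaussian noise of sd `noise_sd_gy` (clipped at 0 Gy).
#' }
#' The `jitter_*` fields are not used by [make_dose()] itself but by
#' [make_cohort()], which perturbs each institution's profile to emulate
#' interinstitutional planning variation.
#'
#' @param technique one of [TECHNIQUES].
#' @param hotspot_factor unitless peak-to-plateau ratio inside the ITV,
#'   `>= 1`.
#' @param surface_frac dose at the PTV surface as a fraction of the ITV
#'   plateau.
#' @param falloff_scale_mm distance (mm) over which dose halves beyond the
#'   PTV surface, `> 0`.
#' @param shell_drop_u0,shell_drop_w centre and width of the logistic dose
#'   drop across the PTV shell, in relative shell depth (0 = ITV surface,
#'   1 = PTV surface).
#' @param penumbra_asymmetry unitless directional modulation of the
#'   falloff scale.
#' @param conformity_wobble_mm amplitude (mm) of the random directional
#'   isodose-radius modulation.
#' @param noise_sd_gy Gaussian dose noise, Gy.
#' @param far_steepening factor by which the falloff steepens in the
#'   low-dose bath.
#' @param bath_frac flat scatter-dose floor as a fraction of the
#'   prescription.
#' @param jitter_falloff_rel,jitter_surface_abs,jitter_hotspot_rel,jitter_wobble_rel
#'   half-widths of the uniform per-institution perturbations applied by
#'   [make_cohort()].
#' @return an object of class `technique_profile`.
#' @export
technique_profile <- function(technique, hotspot_factor = 1.12,
                              surface_frac = 0.76, falloff_scale_mm = 11,
                              shell_drop_u0 = 0.55, shell_drop_w = 0.15,
                              penumbra_asymmetry = 0.05,
                              conformity_wobble_mm = 1.2,
                              noise_sd_gy = 0.3, far_steepening = 2.5,
                              bath_frac = 0.012,
                              jitter_falloff_rel = 0.08,
                              jitter_surface_abs = 0.008,
                              jitter_hotspot_rel = 0.015,
                              jitter_wobble_rel = 0.3) {
    technique <- match.arg(technique, TECHNIQUES)
    stopifnot(hotspot_factor >= 1, falloff_scale_mm > 0,
              surface_frac > 0, surface_frac < 1, noise_sd_gy >= 0,
              shell_drop_w > 0, conformity_wobble_mm >= 0, bath_frac >= 0)
    structure(as.list(environment()), class = "technique_profile")
}

#' Default technique profiles
#'
#' One frozen profile per delivery technique, calibrated once (see
#' `scripts/calibrate_profiles.R`) so that normalized default-profile plans
#' pass the full objective protocol and their metric distributions land in
#' realistic benchmark bands: CI_RTOG in [1.05, 1.2], gradient index in
#' [3.4, 6.7], and median mean PTV dose ordered RRS < MOD < 3D (robotic
#' plans drop the dose early in the PTV shell, 3D-conformal plans keep the
#' shell hot and spill the most dose).
#'
#' @return named list of [technique_profile()]s.
#' @export
default_profiles <- function() {
    list(
        RRS = technique_profile("RRS", hotspot_factor = 1.115,
                                surface_frac = 0.760, falloff_scale_mm = 9.5,
                                shell_drop_u0 = 0.45, shell_drop_w = 0.11,
                                penumbra_asymmetry = 0.06,
                                conformity_wobble_mm = 1.1,
                                noise_sd_gy = 0.35),
        MOD = technique_profile("MOD", hotspot_factor = 1.10,
                                surface_frac = 0.745, falloff_scale_mm = 11,
                                shell_drop_u0 = 0.50, shell_drop_w = 0.16,
                                penumbra_asymmetry = 0.04,
                                conformity_wobble_mm = 1.3,
                                noise_sd_gy = 0.30),
        `3D` = technique_profile("3D", hotspot_factor = 1.10,
                                 surface_frac = 0.737, falloff_scale_mm = 12,
                                 shell_drop_u0 = 0.58, shell_drop_w = 0.18,
                                 penumbra_asymmetry = 0.05,
                                 conformity_wobble_mm = 1.3,
                                 noise_sd_gy = 0.30))
}

# evaluate the unitless radial profile g at signed surface distance s (mm)
dose_profile_g <- function(s, profile, margin_mm = 5, asym_factor = 1) {
    h <- profile$hotspot_factor
    c0 <- profile$surface_frac
    m <- margin_mm
    g <- numeric(length(s))
    out <- s >= 0
    # dose continuity at the PTV surface: the logistic shell does not quite
    # reach c0 at u = 1, so the outside falloff starts from the same level
    shell_g <- function(u)
        c0 + (1 - c0) / (1 + exp((u - profile$shell_drop_u0) /
                                 profile$shell_drop_w))
    c_surf <- shell_g(1)
    if (any(out)) {
        if (length(asym_factor) > 1) asym_factor_o <- asym_factor[out]
        else asym_factor_o <- asym_factor
        F1 <- profile$falloff_scale_mm * asym_factor_o
        gout <- c_surf * 2^(-s[out] / F1)
        brk <- 0.4 * c_surf
        low <- gout < brk
        if (any(low)) {
            # continue below the break with a steeper halving distance
            s_brk <- F1 * log2(c_surf / brk)
            if (length(s_brk) == 1) s_brk <- rep(s_brk, sum(out))
            F2 <- F1 / profile$far_steepening
            if (length(F2) == 1) F2 <- rep(F2, sum(out))
            gout[low] <- brk * 2^(-(s[out][low] - s_brk[low]) / F2[low])
        }
        g[out] <- gout
    }
    shell <- s < 0 & s >= -m
    if (any(shell))
        g[shell] <- shell_g((s[shell] + m) / m)
    core <- s < -m
    if (any(core)) {
        g0 <- shell_g(0)   # matches the shell value at the ITV surface
        g[core] <- g0 + (1 + (h - 1) * (1 - exp(-(-s[core] - m) / 3)) - g0) *
            (1 - exp(-(-s[core] - m) / 1.5))
    }
    g + profile$bath_frac
}

#' Generate a technique-flavored synthetic dose distribution
#'
#' Evaluates the technique\'s radial dose profile (see
#' [technique_profile()]) on the signed PTV-surface distance field of the
#' phantom, modulates the isodose radii with a smooth random directional
#' wobble, and adds clipped Gaussian noise. Deterministic given
#' `(phantom, profile, seed)`. The returned plan is *not* yet normalized;
#' run [normalize_plan()] before evaluating objectives.
#'
#' @param phantom masks from [make_phantom()].
#' @param profile a [technique_profile()].
#' @param seed integer RNG seed.
#' @param meta optional [plan_meta()]; defaults to a synthetic tag with the
#'   profile\'s technique and a Monte Carlo algorithm label.
#' @return an [sbrt_plan()].
#' @export
make_dose <- function(phantom, profile, seed = 1L, meta = NULL) {
    g <- attr(phantom, "lattice")
    ptv <- phantom$PTV
    s <- attr(phantom, "sdist_ptv")
    if (is.null(s)) {
        m <- attr(phantom, "margin_mm") %||% 5
        s <- signed_distance_mm(phantom$ITV) - m
    }
    s <- as.vector(s)
    set.seed(as.integer(seed %% .Machine$integer.max))
    ctr <- mask_centroid(ptv)
    vc <- voxel_centers(ptv)
    rel <- sweep(vc, 2, ctr, "-")
    rn <- pmax(sqrt(rowSums(rel^2)), 1e-9)
    u <- rel / rn
    # smooth directional wobble of the isodose radii: a random first- plus
    # second-order directional harmonic, zero-mean over the sphere
    if (profile$conformity_wobble_mm > 0) {
        v1 <- rand_unit(); v2 <- rand_unit()
        a1 <- stats::runif(1, 0.5, 1)
        w_dir <- a1 * (u %*% v1) + (1 - a1) * (3 * (u %*% v2)^2 - 1) / 2
        s_eff <- s - profile$conformity_wobble_mm * as.vector(w_dir)
    } else s_eff <- s
    # penumbra asymmetry: slower falloff toward the chest wall (-x)
    asym <- 1 + profile$penumbra_asymmetry * pmax(-1, pmin(1, -rel[, 1] / rn))
    gg <- dose_profile_g(s_eff, profile,
                         margin_mm = attr(phantom, "margin_mm") %||% 5,
                         asym_factor = asym)
    dose <- 64.5 * gg
    if (profile$noise_sd_gy > 0)
        dose <- dose + stats::rnorm(length(dose), 0, profile$noise_sd_gy)
    dose <- pmax(dose, 0)
    grid <- dose_grid(g$origin, g$spacing, g$dims, dose)
    if (is.null(meta))
        meta <- plan_meta("synthetic", profile$technique, "MC")
    sbrt_plan(grid, phantom, meta)
}

rand_unit <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mask_centroid <- function(mask) {
    w <- as.vector(mask$occupancy)
    ctr <- voxel_centers(mask)
    colSums(ctr * w) / sum(w)
}

#' Default technique -> algorithm assignment table
#'
#' Proportions with which each dose-calculation algorithm class is used by
#' each delivery technique in a simulated submission pool: robotic units
#' calculate exclusively with Monte Carlo; modulated plans mostly with
#' Boltzmann-transport or AAA; 3D-conformal plans mostly with collapsed
#' cone; a small pencil-beam share appears in the MOD and 3D groups (and is
#' excluded downstream, as PB is non-compliant for lung SBRT).
#'
#' @return a technique x algorithm matrix of proportions (rows sum to 1).
#' @export
default_algorithm_table <- function() {
    t(cbind(RRS = c(MC = 1, BT = 0, CC = 0, AAA = 0, PB = 0),
            MOD = c(MC = 2, BT = 16, CC = 0, AAA = 15, PB = 1) / 34,
            `3D` = c(MC = 2, BT = 0, CC = 10, AAA = 0, PB = 3) / 15))
}

# largest-remainder apportionment of n among proportions p
apportion <- function(n, p) {
    q <- n * p / sum(p)
    k <- floor(q)
    rem <- n - sum(k)
    if (rem > 0) {
        extra <- order(q - k, decreasing = TRUE)[seq_len(rem)]
        k[extra] <- k[extra] + 1
    }
    k
}

# per-plan substream seed: counter-based expansion of one master seed, so
# cohorts are reproducible and independent of generation order
plan_seed <- function(master_seed, index) {
    (as.numeric(master_seed) * 100003 + 7919 * as.numeric(index)) %%
        2147483647
}

perturb_profile <- function(profile, rng_seed) {
    set.seed(as.integer(rng_seed))
    profile$falloff_scale_mm <- profile$falloff_scale_mm *
        (1 + stats::runif(1, -1, 1) * profile$jitter_falloff_rel)
    profile$surface_frac <- min(0.95, max(0.05, profile$surface_frac +
        stats::runif(1, -1, 1) * profile$jitter_surface_abs))
    profile$hotspot_factor <- max(1, profile$hotspot_factor *
        (1 + stats::runif(1, -1, 1) * profile$jitter_hotspot_rel))
    profile
}

#' Simulate a multi-institutional plan cohort
#'
#' Generates `sum(n_per_group)` synthetic plans on one phantom patient:
#' for each technique group, each "institution" gets a perturbed copy of
#' the group's profile (emulating interinstitutional planning variation)
#' and an algorithm label drawn from the technique's algorithm distribution
#' by largest-remainder apportionment. Reproducible from `seed` via
#' counter-based per-plan substreams, independent of generation order.
#'
#' @param n_per_group named integer vector of plans per technique, e.g.
#'   `c(RRS = 8, MOD = 34, "3D" = 15)`.
#' @param profiles named list of [technique_profile()]s.
#' @param seed master seed.
#' @param phantom_spec a [phantom_spec()]; default patient 1.
#' @param algorithm_table technique x algorithm proportion matrix.
#' @param overrides optional named list `plan index -> technique_profile`
#'   replacing that plan's (already perturbed) profile, e.g. to plant a
#'   protocol violation.
#' @return list of [sbrt_plan()]s with distinct `institution_id`s.
#' @export
make_cohort <- function(n_per_group = c(RRS = 8, MOD = 34, `3D` = 15),
                        profiles = default_profiles(), seed = 1L,
                        phantom_spec = phantom_patient1(),
                        algorithm_table = default_algorithm_table(),
                        overrides = NULL) {
    if (length(profiles) == 0L) stop("empty profile list")
    stopifnot(all(n_per_group >= 1))
    phantom <- make_phantom(phantom_spec)
    plans <- vector("list", sum(n_per_group))
    idx <- 0L
    for (tech in names(n_per_group)) {
        n <- n_per_group[[tech]]
        prof <- profiles[[tech]]
        if (is.null(prof)) stop("no profile for technique ", tech)
        algs <- rep(colnames(algorithm_table),
                    apportion(n, algorithm_table[tech, ]))
        for (i in seq_len(n)) {
            idx <- idx + 1L
            sub <- plan_seed(seed, idx)
            p_i <- perturb_profile(prof, sub)
            if (!is.null(overrides) && !is.null(overrides[[as.character(idx)]]))
                p_i <- overrides[[as.character(idx)]]
            meta <- plan_meta(sprintf("INST%03d", idx), tech, algs[i])
            plans[[idx]] <- make_dose(phantom, p_i, seed = sub + 1, meta = meta)
        }
    }
    plans
}
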