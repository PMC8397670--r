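# Shared fixture builders. Everything is generated in code; no binary
# fixtures are stored.

# tiny grid with explicitly chosen doses, 1 mm voxels unless stated
tiny_grid <- function(doses, dims = c(length(doses), 1L, 1L),
                      spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    dose_grid(origin, spacing, dims, doses)
}

full_mask <- function(grid, role = "PTV", name = role) {
    structure_mask(name, role, rep(1, prod(grid$dims)),
                   grid$origin, grid$spacing, grid$dims)
}

# a small phantom (ITV semi-axes ~8 mm) on a coarse lattice: fast enough
# for loops over many seeds
small_phantom_spec <- function(...) {
    # OAR layout shrunk to fit the coarse lattice (110 x 90 x 90 mm)
    layout <- list(
        lung_ipsi = list(lo = c(18, 10, 5), hi = c(74, 78, 84)),
        lung_contra = list(lo = c(84, 10, 5), hi = c(106, 78, 84)),
        chest_wall = list(lo = c(6, 5, 2.5), hi = c(18, 82, 86)),
        spinal_canal = list(center = c(80, 80, 0), radius = 5, axis = "z"),
        esophagus = list(center = c(74, 62, 0), radius = 5, axis = "z"))
    phantom_spec(itv_semi_axes = c(8, 7.5, 7.5), itv_center = c(34, 44, 44),
                 dims = c(44L, 36L, 36L), spacing = c(2.5, 2.5, 2.5),
                 oar_layout = layout, name = "small", ...)
}

small_phantom <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- make_phantom(small_phantom_spec())
        cache
    }
})

patient1_phantom <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) cache <<- make_phantom(phantom_patient1())
        cache
    }
})

# a minimal hand-built plan: uniform ITV dose `itv_gy`, PTV shell dose
# `shell_gy`, one hottest voxel `hot_gy` deep inside the ITV; geometry is a
# centred box ITV inside a box PTV on a 2 mm lattice
boxes_plan <- function(itv_gy = 64.5, shell_gy = 50, hot_gy = NULL,
                       technique = "MOD", algorithm = "MC",
                       dims = c(14L, 14L, 14L)) {
    origin <- c(0, 0, 0); spacing <- c(2, 2, 2)
    n <- prod(dims)
    idx <- arrayInd(seq_len(n), dims)
    inner <- function(pad) {
        apply(idx, 1, function(i) all(i > pad & i <= dims - pad))
    }
    itv <- as.numeric(inner(5L))   # 4^3 voxels
    ptv <- as.numeric(inner(3L))   # 8^3 voxels
    dose <- rep(0.5, n)
    dose[ptv > 0] <- shell_gy
    dose[itv > 0] <- itv_gy
    if (!is.null(hot_gy)) dose[which(itv > 0)[1]] <- hot_gy
    grid <- dose_grid(origin, spacing, dims, dose)
    masks <- list(
        ITV = structure_mask("ITV", "ITV", itv, origin, spacing, dims),
        PTV = structure_mask("PTV", "PTV", ptv, origin, spacing, dims))
    sbrt_plan(grid, masks, plan_meta("test", technique, algorithm))
}

# brute-force cumulative volume at level e (cm^3): direct weighted count
oracle_cum_volume <- function(grid, mask, e) {
    sum(mask$occupancy[grid$dose >= e]) * prod(grid$spacing) / 1000
}

# voxel-exact Dx by sorting (independent of the binned DVH path)
oracle_dx <- function(grid, mask, x_pct) {
    sel <- mask$occupancy > 0
    d <- grid$dose[sel]; w <- mask$occupancy[sel]
    ord <- order(d, decreasing = TRUE)
    cw <- cumsum(w[ord]) / sum(w)
    d[ord][which(cw >= x_pct / 100 - 1e-12)[1]]
}

# random dose grid + fractional mask for property tests
random_grid_mask <- function(n = 12L, seed = 1, max_gy = 70) {
    set.seed(seed)
    dims <- c(n, n, n)
    grid <- dose_grid(c(0, 0, 0), c(2, 2, 2), dims,
                      runif(n^3, 0, max_gy))
    occ <- runif(n^3)
    occ[runif(n^3) < 0.3] <- 0          # some empty voxels
    occ[runif(n^3) < 0.2] <- 1          # some full voxels
    mask <- structure_mask("rand", "PTV", occ, grid$origin, grid$spacing,
                           dims)
    list(grid = grid, mask = mask)
}
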