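test_that("structure volume is the occupancy-weighted voxel sum", {
    g <- tiny_grid(rep(1, 1000), dims = c(10L, 10L, 10L),
                   spacing = c(2, 2, 2))
    m <- full_mask(g)
    expect_equal(volume(m), 8)     # 1000 voxels x 8 mm^3 = 8 cm^3

    empty <- structure_mask("empty", "OTHER", rep(0, 1000), g$origin,
                            g$spacing, g$dims)
    expect_equal(volume(empty), 0)

    set.seed(7)
    occ <- runif(1000)
    frac <- structure_mask("frac", "PTV", occ, g$origin, g$spacing, g$dims)
    expect_equal(volume(frac), sum(occ) * 8 / 1000)   # direct summation
})

test_that("volume is additive over disjoint masks and translation invariant", {
    dims <- c(8L, 8L, 8L); spacing <- c(1.5, 2, 2.5)
    set.seed(11)
    occ <- runif(prod(dims))
    half <- rep(c(1, 0), length.out = prod(dims))
    m1 <- structure_mask("a", "OTHER", occ * half, c(0, 0, 0), spacing, dims)
    m2 <- structure_mask("b", "OTHER", occ * (1 - half), c(0, 0, 0),
                         spacing, dims)
    m <- structure_mask("ab", "OTHER", occ, c(0, 0, 0), spacing, dims)
    expect_equal(volume(m1) + volume(m2), volume(m))

    shifted <- structure_mask("s", "OTHER", occ, c(-53, 11, 7), spacing, dims)
    expect_equal(volume(shifted), volume(m))
})

test_that("constructors enforce the lattice and value invariants", {
    expect_error(dose_grid(c(0, 0, 0), c(1, 0, 1), c(2L, 2L, 2L), rep(1, 8)),
                 "spacing")
    expect_error(dose_grid(c(0, 0, 0), c(1, 1, 1), c(2L, 2L, 2L), rep(-1, 8)),
                 "finite and >= 0")
    expect_error(dose_grid(c(0, 0, 0), c(1, 1, 1), c(2L, 2L, 2L), rep(1, 7)),
                 "does not match dims")
    expect_error(structure_mask("m", "PTV", rep(1.2, 8), c(0, 0, 0),
                                c(1, 1, 1), c(2L, 2L, 2L)),
                 "\\[0, 1\\]")
    g <- tiny_grid(rep(1, 8), dims = c(2L, 2L, 2L))
    other <- structure_mask("m", "PTV", rep(1, 8), c(9, 9, 9), c(1, 1, 1),
                            c(2L, 2L, 2L))
    expect_error(dvh(g, other), class = "sbrtbench_geometry_error")
})

test_that("a plan requires ITV contained in PTV", {
    g <- tiny_grid(rep(1, 27), dims = c(3L, 3L, 3L))
    itv <- structure_mask("ITV", "ITV", c(rep(1, 14), rep(0, 13)),
                          g$origin, g$spacing, g$dims)
    ptv_ok <- full_mask(g, "PTV")
    expect_s3_class(sbrt_plan(g, list(ITV = itv, PTV = ptv_ok),
                              plan_meta("i", "MOD", "MC")), "sbrt_plan")
    ptv_bad <- structure_mask("PTV", "PTV", c(rep(0, 14), rep(1, 13)),
                              g$origin, g$spacing, g$dims)
    expect_error(sbrt_plan(g, list(ITV = itv, PTV = ptv_bad),
                           plan_meta("i", "MOD", "MC")),
                 "not contained")
})

test_that("rasterized sphere volume converges to the analytic volume", {
    r <- 10
    vol_at <- function(h) {
        dims <- rep(ceiling(2 * (r + 3) / h), 3)
        occ <- rasterize_ellipsoid(rep((dims[1] - 1) * h / 2, 3), rep(r, 3),
                                   c(0, 0, 0), rep(h, 3), dims)
        sum(occ) * h^3 / 1000
    }
    analytic <- 4 / 3 * pi * r^3 / 1000
    expect_lt(abs(vol_at(2) / analytic - 1), 0.02)
    expect_lt(abs(vol_at(1) / analytic - 1), 0.02)   # < 2% at 1 mm, r = 10 mm
    expect_lt(abs(vol_at(0.5) / analytic - 1), 0.005)
})

test_that("binary rasterization counts voxel centres only", {
    occ <- rasterize_ellipsoid(c(5, 5, 5), c(3, 3, 3), c(0, 0, 0),
                               c(1, 1, 1), c(11L, 11L, 11L), mode = "binary")
    expect_true(all(occ %in% c(0, 1)))
    centers <- voxel_centers(list(origin = c(0, 0, 0), spacing = c(1, 1, 1),
                                  dims = c(11L, 11L, 11L)))
    inside <- rowSums(sweep(centers, 2, c(5, 5, 5), "-")^2) <= 9
    expect_equal(as.vector(occ), as.numeric(inside))
})

test_that("trilinear resampling reproduces a linear dose field exactly", {
    dims <- c(9L, 8L, 7L)
    ctr <- voxel_centers(list(origin = c(0, 0, 0), spacing = c(2, 2, 2),
                              dims = dims))
    lin <- 1 + 0.3 * ctr[, 1] + 0.2 * ctr[, 2] + 0.1 * ctr[, 3]
    g <- dose_grid(c(0, 0, 0), c(2, 2, 2), dims, lin)
    res <- resample_trilinear(g, c(1, 1, 1), c(1.5, 1.5, 1.5), c(8L, 7L, 6L))
    ctr2 <- voxel_centers(res)
    expect_equal(as.vector(res$dose),
                 1 + 0.3 * ctr2[, 1] + 0.2 * ctr2[, 2] + 0.1 * ctr2[, 3],
                 tolerance = 1e-12)
})

test_that("signed distance is negative inside, positive outside", {
    occ <- rasterize_ellipsoid(c(10, 10, 10), c(5, 5, 5), c(0, 0, 0),
                               c(1, 1, 1), c(21L, 21L, 21L))
    m <- structure_mask("s", "PTV", occ, c(0, 0, 0), c(1, 1, 1),
                        c(21L, 21L, 21L))
    sd <- signed_distance_mm(m)
    expect_lt(sd[11, 11, 11], -3)
    expect_gt(sd[1, 1, 1], 5)
    # roughly the Euclidean distance to the sphere surface at the corner
    expect_equal(sd[1, 1, 1], sqrt(3 * 100) - 5, tolerance = 1.5)
})
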