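test_that("uniform dose gives a step DVH", {
    g <- tiny_grid(rep(10, 125), dims = c(5L, 5L, 5L), spacing = c(2, 2, 2))
    m <- full_mask(g)
    curve <- dvh(g, m)
    expect_equal(curve$total_volume, 1)
    expect_true(all(curve$cum_volume[curve$edges <= 10] == 1))
    expect_true(all(curve$cum_volume[curve$edges > 10] == 0))
})

test_that("the DVH curve equals brute-force threshold counting", {
    g <- tiny_grid(1:10)                        # 10 voxels of 1 mm^3
    m <- full_mask(g)
    curve <- dvh(g, m)
    for (i in seq_along(curve$edges))
        expect_equal(curve$cum_volume[i],
                     oracle_cum_volume(g, m, curve$edges[i]))

    # fractional occupancies
    occ <- rep(c(0.5, 1), 5)
    mf <- structure_mask("f", "PTV", occ, g$origin, g$spacing, g$dims)
    curve <- dvh(g, mf)
    for (i in seq_along(curve$edges))
        expect_equal(curve$cum_volume[i],
                     oracle_cum_volume(g, mf, curve$edges[i]))
})

test_that("random fields: binned curve matches the enumeration oracle", {
    for (seed in 1:5) {
        rg <- random_grid_mask(n = 10L, seed = seed)
        curve <- dvh(rg$grid, rg$mask)
        idx <- seq(1, length(curve$edges), by = 37)
        for (i in idx)
            expect_equal(curve$cum_volume[i],
                         oracle_cum_volume(rg$grid, rg$mask,
                                           curve$edges[i]))
    }
})

test_that("Dmean is the exact arithmetic mean; quantiles match sorting", {
    g <- tiny_grid(1:10)
    p <- sbrt_plan(g, list(ITV = full_mask(g, "ITV"),
                           PTV = full_mask(g, "PTV")),
                   plan_meta("t", "MOD", "MC"), validate = FALSE)
    expect_equal(dvh_metric(p, "Dmean", role = "PTV"), 5.5)
    expect_equal(dvh_metric(p, "Dmedian", role = "PTV"),
                 oracle_dx(g, p$structures$PTV, 50))

    for (seed in 6:9) {
        rg <- random_grid_mask(n = 10L, seed = seed)
        pl <- sbrt_plan(tiny_grid(rg$grid$dose, dims = rg$grid$dims,
                                  spacing = rg$grid$spacing),
                        list(ITV = rg$mask, PTV = rg$mask),
                        plan_meta("t", "MOD", "MC"), validate = FALSE)
        for (x in c(2, 50, 95, 98))
            expect_lt(abs(dvh_metric(pl, "D_pct", x, role = "PTV") -
                          oracle_dx(rg$grid, rg$mask, x)), 0.1 + 1e-9)
    }
})

test_that("a uniform 64.5 Gy structure hits the textbook point metrics", {
    g <- tiny_grid(rep(64.5, 64), dims = c(4L, 4L, 4L), spacing = c(2, 2, 2))
    p <- sbrt_plan(g, list(ITV = full_mask(g, "ITV"),
                           PTV = full_mask(g, "PTV")),
                   plan_meta("t", "MOD", "MC"), validate = FALSE)
    expect_equal(dvh_metric(p, "D_pct", 95, role = "ITV"), 64.5,
                 tolerance = 1e-9)
    expect_equal(dvh_metric(p, "V_dose", 58.1, role = "ITV"), 100)
    expect_equal(dvh_metric(p, "V_dose", 64.6, role = "ITV"), 0)
})

test_that("quantile monotonicity and V_dose monotonicity hold", {
    for (seed in 1:5) {
        rg <- random_grid_mask(n = 9L, seed = seed)
        pl <- sbrt_plan(rg$grid, list(ITV = rg$mask, PTV = rg$mask),
                        plan_meta("t", "MOD", "MC"), validate = FALSE)
        d98 <- dvh_metric(pl, "D_pct", 98, role = "PTV")
        dmed <- dvh_metric(pl, "Dmedian", role = "PTV")
        d2 <- dvh_metric(pl, "D_pct", 2, role = "PTV")
        expect_lte(d98, dmed + 0.1)
        expect_lte(dmed, d2 + 0.1)
        # voxel-exact median agrees with the curve median within one bin
        expect_lt(abs(dmed - dvh_metric(dvh(rg$grid, rg$mask), "Dmedian")),
                  0.1 + 1e-9)
        xs <- c(5, 25, 50, 75, 95)
        dx <- vapply(xs, function(x)
            dvh_metric(pl, "D_pct", x, role = "PTV"), 0)
        expect_true(all(diff(dx) <= 1e-12))

        curve <- dvh(rg$grid, rg$mask)
        expect_equal(dvh_metric(curve, "V_dose", 0), 100)
        vd <- vapply(seq(0, 60, by = 7.5), function(d)
            dvh_metric(curve, "V_dose", d), 0)
        expect_true(all(diff(vd) <= 1e-12))
    }
})

test_that("curve-derived mean agrees with the voxel-exact mean within half a bin", {
    for (seed in 1:5) {
        rg <- random_grid_mask(n = 10L, seed = seed)
        pl <- sbrt_plan(rg$grid, list(ITV = rg$mask, PTV = rg$mask),
                        plan_meta("t", "MOD", "MC"), validate = FALSE)
        exact <- dvh_metric(pl, "Dmean", role = "PTV")
        binned <- dvh_metric(dvh(rg$grid, rg$mask), "Dmean")
        expect_lt(abs(exact - binned), 0.05)
    }
})

test_that("strict-bin mode snaps to bin edges; interp lies within the bin", {
    rg <- random_grid_mask(n = 8L, seed = 3)
    curve <- dvh(rg$grid, rg$mask)
    d_interp <- dvh_metric(curve, "D_pct", 95)
    d_strict <- dvh_metric(curve, "D_pct", 95, mode = "strict")
    expect_lt(min(d_strict %% 0.1, 0.1 - d_strict %% 0.1), 1e-9)
    expect_gte(d_interp + 1e-12, d_strict)
    expect_lt(d_interp - d_strict, 0.1)
})

test_that("invalid metric requests error", {
    g <- tiny_grid(1:10)
    m <- full_mask(g)
    curve <- dvh(g, m)
    expect_error(dvh_metric(curve, "D_pct", 0), "\\(0, 100\\]")
    expect_error(dvh_metric(curve, "D_pct", 101), "\\(0, 100\\]")
    expect_error(dvh_metric(curve, "D_absvol", 1), "exceeds structure volume")
    expect_error(dvh_metric(curve, "V_pct", 70), "rx_gy")
    empty <- structure_mask("e", "OTHER", rep(0, 10), g$origin, g$spacing,
                            g$dims)
    expect_error(dvh(g, empty), "zero volume")
})

test_that("DVH CSV export has the documented columns", {
    g <- tiny_grid(1:10)
    f <- withr::local_tempfile(fileext = ".csv")
    dvh_write_csv(dvh(g, full_mask(g)), f)
    df <- read.csv(f, check.names = FALSE)
    expect_identical(names(df), c("dose [Gy]", "volume [cm3]", "volume [%]"))
    expect_equal(df[["volume [%]"]][1], 100)
})
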