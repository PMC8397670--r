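test_that("phantoms hit the requested PTV volumes", {
    ph1 <- patient1_phantom()
    expect_gt(volume(ph1$PTV), 22.6)
    expect_lt(volume(ph1$PTV), 25.0)
    ph2 <- make_phantom(phantom_patient2())
    expect_lt(abs(volume(ph2$PTV) / 19.4 - 1), 0.05)
    # both carry the full structure set
    expect_setequal(names(ph1), c("ITV", "PTV", "LUNG_IPSI", "LUNG_CONTRA",
                                  "CHEST_WALL", "SPINAL_CANAL", "ESOPHAGUS"))
})

test_that("a zero margin collapses PTV onto ITV", {
    spec <- small_phantom_spec(); spec$margin_mm <- 0
    ph <- make_phantom(spec)
    expect_identical(ph$PTV$occupancy, ph$ITV$occupancy)
})

test_that("a spherical ITV dilates to the analytic PTV volume", {
    spec <- phantom_spec(itv_semi_axes = c(9, 9, 9), itv_center = c(40, 40, 40),
                         dims = c(40L, 40L, 40L), spacing = c(2, 2, 2),
                         oar_layout = oar_layout_default(c(40, 40, 40)))
    ph <- make_phantom(spec)
    expect_lt(abs(volume(ph$PTV) / (4 / 3 * pi * 14^3 / 1000) - 1), 0.02)
    expect_lt(abs(volume(ph$ITV) / (4 / 3 * pi * 9^3 / 1000) - 1), 0.02)
})

test_that("a PTV reaching the lattice boundary is refused", {
    spec <- phantom_spec(itv_semi_axes = c(10, 10, 10),
                         itv_center = c(12, 30, 30),
                         dims = c(24L, 24L, 24L), spacing = c(2.5, 2.5, 2.5),
                         oar_layout = oar_layout_default(c(12, 30, 30)))
    expect_error(make_phantom(spec), class = "sbrtbench_geometry_error")
})

test_that("dose generation is deterministic in the seed", {
    ph <- small_phantom()
    p1 <- make_dose(ph, default_profiles()$MOD, seed = 99)
    p2 <- make_dose(ph, default_profiles()$MOD, seed = 99)
    expect_identical(p1$grid$dose, p2$grid$dose)
    p3 <- make_dose(ph, default_profiles()$MOD, seed = 100)
    expect_false(identical(p1$grid$dose, p3$grid$dose))
})

test_that("the noiseless uniform limit is flat inside the target", {
    prof <- technique_profile("MOD", hotspot_factor = 1,
                              surface_frac = 0.99, falloff_scale_mm = 1e6,
                              shell_drop_u0 = 0.5, shell_drop_w = 0.15,
                              conformity_wobble_mm = 0, noise_sd_gy = 0,
                              bath_frac = 0)
    p <- make_dose(small_phantom(), prof, seed = 1)
    sel <- p$structures$PTV$occupancy > 0.99
    d <- p$grid$dose[sel]
    expect_lt(diff(range(d)) / max(d), 0.011)
    # with an (almost) uniform dose everywhere there is no prescription
    # isodose surface: the conformity indices are undefined (piv = 0)
    expect_error(ci_paddick(normalize_plan(p), ref_dose_gy = 80), "zero")
})

test_that("median mean PTV dose is ordered RRS < MOD < 3D", {
    ph <- small_phantom()
    med <- sapply(c("RRS", "MOD", "3D"), function(tech) {
        median(vapply(1:10, function(i) {
            p <- normalize_plan(make_dose(ph, default_profiles()[[tech]],
                                          seed = 1000 + i))
            dvh_metric(p, "Dmean", role = "PTV")
        }, 0))
    })
    expect_lt(med["RRS"], med["MOD"])
    expect_lt(med["MOD"], med["3D"])
})

test_that("cohorts have the requested group sizes, ids and algorithms", {
    plans <- make_cohort(n_per_group = c(RRS = 1, MOD = 1, `3D` = 1),
                         seed = 5, phantom_spec = small_phantom_spec())
    expect_length(plans, 3)
    ids <- vapply(plans, function(p) p$meta$institution_id, "")
    expect_equal(anyDuplicated(ids), 0L)

    plans2 <- make_cohort(n_per_group = c(RRS = 1, MOD = 1, `3D` = 1),
                          seed = 5, phantom_spec = small_phantom_spec())
    for (i in 1:3)
        expect_identical(plans[[i]]$grid$dose, plans2[[i]]$grid$dose)

    expect_error(make_cohort(c(RRS = 1), profiles = list()), "empty profile")
})

test_that("the default 57-plan split gets the documented algorithm mix", {
    # apportionment only; no dose generation needed
    tab <- default_algorithm_table()
    alg <- unlist(mapply(function(tech, n)
        rep(colnames(tab), sbrtbench:::apportion(n, tab[tech, ])),
        c("RRS", "MOD", "3D"), c(8, 34, 15)))
    counts <- table(factor(alg, levels = ALGORITHMS))
    expect_equal(as.vector(counts), c(12, 16, 10, 15, 4))  # MC BT CC AAA PB
})

test_that("masks do not depend on the seed; dose substreams are counter-based", {
    expect_identical(make_phantom(small_phantom_spec(), seed = 1)$PTV$occupancy,
                     make_phantom(small_phantom_spec(), seed = 2)$PTV$occupancy)
    s <- vapply(1:57, function(i) sbrtbench:::plan_seed(42, i), 0)
    expect_equal(anyDuplicated(s), 0L)
    expect_true(all(s >= 0 & s < 2^31))
})
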