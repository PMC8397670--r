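test_that("group summaries use midpoint medians and n-1 sd", {
    tab <- data.frame(institution_id = letters[1:6],
                      technique = rep(c("RRS", "MOD"), each = 3),
                      algorithm = "MC", patient = "p1",
                      m1 = c(1, 2, 4, 10, 20, 60),
                      m2 = c(5, 5, 5, 7, 8, 9))
    class(tab) <- c("metric_table", "data.frame")
    s <- summarize_cohort(tab)
    g <- function(grp, met, col) s[s$group == grp & s$metric == met, col]
    expect_equal(g("RRS", "m1", "median"), 2)
    expect_equal(g("MOD", "m1", "median"), 20)
    expect_equal(g("MOD", "m1", "mean"), 30)
    expect_equal(g("RRS", "m1", "sd"), sd(c(1, 2, 4)))
    # even n: midpoint convention
    tab2 <- tab; tab2$technique <- rep(c("A", "B"), 3)
    class(tab2) <- class(tab)
    s2 <- summarize_cohort(tab2)
    expect_equal(s2[s2$group == "A" & s2$metric == "m1", "median"],
                 median(c(1, 4, 20)))
    expect_error(summarize_cohort(tab, "nonexistent"), "unknown grouping")
})

test_that("single-plan groups report absent sd", {
    tab <- data.frame(institution_id = c("a", "b"),
                      technique = c("RRS", "MOD"), algorithm = "MC",
                      patient = "p1", m1 = c(3, 4))
    class(tab) <- c("metric_table", "data.frame")
    s <- summarize_cohort(tab)
    expect_equal(s$median, s$mean)
    expect_true(all(is.na(s$sd)))
})

test_that("summaries are permutation-invariant within groups", {
    set.seed(4)
    tab <- data.frame(institution_id = as.character(1:12),
                      technique = rep(c("RRS", "MOD", "3D"), 4),
                      algorithm = "MC", patient = "p1", m1 = rnorm(12))
    class(tab) <- c("metric_table", "data.frame")
    tab_perm <- tab[sample(12), ]
    class(tab_perm) <- class(tab)
    s1 <- summarize_cohort(tab); s2 <- summarize_cohort(tab_perm)
    key <- order(s1$group); key2 <- order(s2$group)
    expect_equal(s1[key, c("median", "mean", "sd")],
                 s2[key2, c("median", "mean", "sd")],
                 ignore_attr = TRUE)
})

test_that("H matches the rank formula and the exact permutation null", {
    values <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
    groups <- rep(c("a", "b", "c"), each = 3)
    res <- kruskal_wallis(values, groups)
    # brute-force rank formula, no ties
    r <- rank(values); N <- 9
    rbar <- tapply(r, groups, mean)
    H_direct <- 12 / (N * (N + 1)) * sum(3 * (rbar - (N + 1) / 2)^2)
    expect_equal(res$H, H_direct)
    expect_equal(res$df, 2)
    expect_equal(res$tie_correction, 1)

    # chi-square p vs the full permutation distribution (9!/(3!3!3!) = 1680)
    exact <- kruskal_wallis(values, groups, exact_max = 12)
    expect_equal(exact$method, "exact permutation")
    expect_lt(abs(exact$p - res$p), 0.005 + 0.02)  # approximation quality
    # the permutation p itself is reproduced by an independent enumeration
    combos <- utils::combn(9, 3, simplify = FALSE)
    count <- 0; total <- 0
    stat <- function(assign) {
        rb <- tapply(rank(values), assign, mean)
        12 / (N * (N + 1)) * sum(3 * (rb - 5)^2)
    }
    H_obs <- stat(groups)
    for (a in combos) {
        rest <- setdiff(1:9, a)
        for (b in utils::combn(rest, 3, simplify = FALSE)) {
            lab <- integer(9); lab[a] <- 1; lab[b] <- 2
            lab[setdiff(rest, b)] <- 3
            total <- total + 1
            if (stat(lab) >= H_obs - 1e-12) count <- count + 1
        }
    }
    expect_equal(exact$p, count / total)
})

test_that("tie correction matches the closed form and the reference", {
    values <- c(1, 1, 2, 2, 2, 3, 4, 4, 5, 6, 6, 7)
    groups <- rep(c("a", "b", "c"), each = 4)
    res <- kruskal_wallis(values, groups)
    t <- c(2, 3, 2, 2)
    expect_equal(res$tie_correction, 1 - sum(t^3 - t) / (12^3 - 12))
    # independent reference implementation
    ref <- stats::kruskal.test(values, factor(groups))
    expect_equal(res$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("degenerate and invariance properties of the test", {
    # identical multisets in all groups -> H = 0
    res <- kruskal_wallis(rep(c(5, 7), 3), rep(c("a", "b", "c"), each = 2))
    expect_equal(res$H, 0)
    # all values identical -> H = 0, p = 1 by convention
    res0 <- kruskal_wallis(rep(3, 9), rep(c("a", "b", "c"), each = 3))
    expect_equal(res0$H, 0)
    expect_equal(res0$p, 1)
    # invariant under strictly monotone transformations
    set.seed(8)
    x <- rnorm(15); g <- rep(c("a", "b", "c"), 5)
    expect_equal(kruskal_wallis(x, g)$H, kruskal_wallis(exp(x), g)$H)
    expect_equal(kruskal_wallis(x, g)$H, kruskal_wallis(x^3, g)$H)
    expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
    expect_error(kruskal_wallis(1:2, c("a", "b")), "3 observations")
})

test_that("two-group H equals the squared standardized rank-sum", {
    set.seed(12)
    x <- rnorm(14); g <- rep(c("a", "b"), each = 7)
    res <- kruskal_wallis(x, g)
    r <- rank(x); N <- 14; n1 <- 7
    R1 <- sum(r[g == "a"])
    z2 <- (R1 - n1 * (N + 1) / 2)^2 /
        (n1 * (N - n1) * (N + 1) / 12)
    expect_equal(res$H, z2, tolerance = 1e-12)
})

test_that("the multiplicity policy is selective Holm", {
    mk <- function(p) structure(list(H = 1, df = 2, p = p,
                                     group_ns = c(3, 3, 3)),
                                class = "kw_result")
    res <- list(ptv_dmean_gy = mk(0.3), a = mk(0.01), b = mk(0.02),
                c = mk(0.04))
    adj <- multiplicity_policy(res, "ptv_dmean_gy")
    expect_equal(adj$ptv_dmean_gy$adjusted_p, 0.3)   # primary untouched
    expect_equal(adj$a$adjusted_p, 0.03)             # Holm step-down
    expect_equal(adj$b$adjusted_p, 0.04)
    expect_equal(adj$c$adjusted_p, 0.04)
    expect_true(all(vapply(adj, function(r) r$adjusted_p >= r$p, TRUE)))

    single <- multiplicity_policy(list(ptv_dmean_gy = mk(0.2),
                                       only = mk(0.03)), "ptv_dmean_gy")
    expect_equal(single$only$adjusted_p, 0.03)       # m = 1
    expect_error(multiplicity_policy(list(a = mk(0.1)), "ptv_dmean_gy"),
                 "primary metric")
})
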