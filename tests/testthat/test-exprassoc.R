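test_that("Pearson r and p match the direct formula and cor.test", {
    expect_equal(unname(pearsonWithP(1:10, 1:10)["r"]), 1)
    expect_equal(unname(pearsonWithP(1:10, -(1:10))["r"]), -1)
    x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 6.0, 5.5, 7.2, 8.1, 7.9)
    y <- c(0.8, 2.1, 3.3, 3.9, 5.2, 4.8, 6.6, 6.1, 7.7, 8.8)
    got <- pearsonWithP(x, y)
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t <- r * sqrt((10 - 2) / (1 - r^2))
    expect_equal(unname(got["r"]), r)
    expect_equal(unname(got["p"]), 2 * stats::pt(-abs(t), 8))
    ct <- stats::cor.test(x, y)
    expect_equal(unname(got["p"]), ct$p.value, tolerance = 1e-12)
    expect_error(pearsonWithP(rep(1, 5), 1:5), "zero variance")
    expect_error(pearsonWithP(1:2, 1:2), "at least 3")
})

test_that("correlation percentiles rank by descending signed r", {
    # 99 genes built as focal + c_i * (fixed noise): sample correlation is
    # strictly decreasing in c_i, so ranks are known exactly
    set.seed(31)
    n <- 40
    focal <- rnorm(n)
    noise <- rnorm(n)
    cs <- seq(0.1, 12, length.out = 99)
    m <- rbind(FOCAL = focal,
        t(sapply(cs, function(ci) focal + ci * noise)))
    rownames(m) <- c("FOCAL", sprintf("g%02d", 1:99))
    colnames(m) <- paste0("s", seq_len(n))
    top <- correlationPercentile(m, "FOCAL", "g01")
    expect_equal(unname(top["rank"]), 1)
    expect_equal(unname(top["percentile"]), 100 * 1 / 99)
    med <- correlationPercentile(m, "FOCAL", "g50")
    expect_equal(unname(med["rank"]), 50)
    expect_equal(unname(med["percentile"]), 100 * 50 / 99,
        tolerance = 1e-9)
    expect_error(correlationPercentile(m, "FOCAL", "FOCAL"),
        "self-correlation")
    expect_error(correlationPercentile(m, "FOCAL", "nope"), "not in matrix")
})

test_that("a strongly planted partner lands at the top percentile", {
    se <- simulateExpression(nGenes = 1000, nSamples = 60,
        planted = data.frame(gene = "SHH", r = 0.9), seed = 17)
    res <- correlationPercentile(se, "FOCAL", "SHH")
    expect_lte(unname(res["percentile"]), 1)
    expect_gt(unname(res["r"]), 0.8)
})

test_that("one-tailed Welch tests match the closed form and its mirror", {
    same <- oneTailedTTest(c(1, 2, 3), c(3, 2, 1), "a>b")
    expect_equal(unname(same["p"]), 0.5)
    a <- c(1, 2, 3); b <- c(4, 5, 6)
    got <- oneTailedTTest(a, b, "b>a")
    se <- sqrt(var(a) / 3 + var(b) / 3)
    t <- (mean(a) - mean(b)) / se
    df <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
    expect_equal(unname(got["t"]), t)
    expect_equal(unname(got["p"]), stats::pt(t, df))
    rev <- oneTailedTTest(a, b, "a>b")
    expect_equal(unname(got["p"] + rev["p"]), 1)
    expect_error(oneTailedTTest(1, c(1, 2), "a>b"), "at least 2")
})

test_that("balanced two-way ANOVA matches hand-computed sums of squares", {
    # 2x2 with 2 replicates per cell
    v <- c(10, 12, 20, 22, 13, 15, 25, 27)
    f1 <- rep(c("lo", "hi"), each = 4)
    f2 <- rep(c("ctl", "trt"), each = 2, times = 2)
    got <- twoWayAnova(v, f1, f2)
    # hand computation (balanced, so type II equals the classical ANOVA)
    g <- mean(v)
    ssA <- 4 * sum((tapply(v, f1, mean) - g)^2)
    ssB <- 4 * sum((tapply(v, f2, mean) - g)^2)
    cellm <- tapply(v, interaction(f1, f2), mean)
    ssAB <- 2 * sum((cellm - g)^2) - ssA - ssB
    ssE <- sum((v - ave(v, interaction(f1, f2)))^2)
    expect_equal(got$F[got$term == "factor1"], (ssA / 1) / (ssE / 4))
    expect_equal(got$F[got$term == "factor2"], (ssB / 1) / (ssE / 4))
    expect_equal(got$F[got$term == "interaction"], (ssAB / 1) / (ssE / 4))
    expect_error(twoWayAnova(v[1:6],
        c("a", "a", "b", "b", "a", "a"),
        c("x", "x", "x", "x", "y", "y")), "empty cell")
    expect_error(twoWayAnova(v[1:6], f1[1:6], rep("x", 6)),
        "at least 2 levels")
})

test_that("a pure factor1 effect is detected and factor2 stays null", {
    # factor1 shifts the response by 5; within-cell jitter keeps the
    # residual sum of squares non-degenerate
    v <- c(0, 0.01, 0, 0.01, 5, 5.01, 5, 5.01)
    f1 <- rep(c("a", "b"), each = 4)
    f2 <- rep(c("x", "x", "y", "y"), 2)
    got <- twoWayAnova(v, f1, f2)
    expect_lt(got$p[got$term == "factor1"], 1e-6)
    expect_gt(got$p[got$term == "factor2"], 0.1)
})

test_that("ANOVA p-values are uniform under the null", {
    set.seed(99)
    ps <- replicate(200, {
        v <- rnorm(12)
        f1 <- sample(rep(c("a", "b"), 6))
        f2 <- sample(rep(c("x", "y"), 6))
        if (any(table(f1, f2) == 0)) return(NA_real_)
        twoWayAnova(v, f1, f2)$p[1L]
    })
    ks <- suppressWarnings(stats::ks.test(ps[!is.na(ps)], "punif"))
    expect_gt(ks$p.value, 0.01)
})
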