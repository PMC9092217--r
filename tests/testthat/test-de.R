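test_that("Welch statistic matches the closed form", {
    welch_oracle <- function(x, y) {
        t <- (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
        df <- (var(x) / length(x) + var(y) / length(y))^2 /
            ((var(x) / length(x))^2 / (length(x) - 1) +
             (var(y) / length(y))^2 / (length(y) - 1))
        list(t = t, df = df, p = 2 * pt(-abs(t), df))
    }
    set.seed(5)
    for (i in 1:10) {
        x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), sd = 2)
        got <- welchTest(x, y); want <- welch_oracle(x, y)
        expect_equal(got$t, want$t, tolerance = 1e-12)
        expect_equal(got$df, want$df, tolerance = 1e-12)
        expect_equal(got$p, want$p, tolerance = 1e-12)
    }
    w <- welchTest(c(0, 1), c(10, 11))
    expect_lt(w$p, 0.05)
})

test_that("Welch degenerate contracts hold", {
    expect_equal(welchTest(c(1, 2, 3), c(3, 2, 1))$t, 0)
    expect_equal(welchTest(c(1, 2, 3), c(2, 3, 1))$p, 1)
    z <- welchTest(c(2, 2), c(2, 2))
    expect_equal(z$t, 0); expect_equal(z$p, 1)
    expect_warning(z2 <- welchTest(c(1, 1), c(2, 2)), "zero variance")
    expect_equal(z2$p, 0)
    expect_error(welchTest(1, c(1, 2)), "two values")
})

test_that("Welch reduces to Student's t under equal variance and size", {
    set.seed(6)
    for (i in 1:10) {
        x <- rnorm(8)
        y <- rnorm(8) + 1
        y <- (y - mean(y)) / sd(y) * sd(x) + mean(y)  # force equal variance
        got <- welchTest(x, y)
        student <- t.test(x, y, var.equal = TRUE)
        expect_equal(got$t, unname(student$statistic), tolerance = 1e-9)
        expect_equal(got$df, 14, tolerance = 1e-9)
        expect_equal(got$p, student$p.value, tolerance = 1e-9)
    }
})

test_that("BH critical line and step-up behave canonically", {
    expect_equal(bhCriticalValue(71, 0.20, 4), 4 / 71 * 0.2)
    expect_equal(round(bhCriticalValue(71, 0.20, 4), 3), 0.011)
    expect_equal(bhCriticalValue(37, 0.1, 37), 0.1)
    expect_equal(bhCriticalValue(10, 0.05, 1), 0.005)
    expect_error(bhCriticalValue(10, 0.05, 11), "1..m")

    expect_false(any(bhAdjust(rep(1, 5), 0.2)$rejected))
    r <- bhAdjust(c(0.001, 0.9), 0.2)
    expect_identical(r$rejected, c(TRUE, FALSE))
    expect_equal(r$threshold, 0.001)
    expect_identical(bhAdjust(numeric(0), 0.1)$rejected, logical(0))
})

test_that("BH agrees with p.adjust, rejects exactly {p <= threshold}, and is monotone in q", {
    set.seed(8)
    for (i in 1:25) {
        p <- runif(sample(1:40, 1))^sample(1:3, 1)
        for (q in c(0.05, 0.1, 0.2)) {
            r <- bhAdjust(p, q)
            expect_identical(r$rejected, p.adjust(p, "BH") <= q)
            expect_identical(r$rejected, p <= r$threshold)
        }
        expect_true(all(bhAdjust(p, 0.1)$rejected <= bhAdjust(p, 0.2)$rejected))
    }
})

test_that("two-group DE flags planted fold changes and nothing on null data", {
    g <- rep(c("AD", "CTL"), each = 28)
    set.seed(31)
    dcq <- matrix(rnorm(20 * 56, sd = 0.3), nrow = 20)
    dcq[1, g == "AD"] <- dcq[1, g == "AD"] - 2       # strong increase in AD
    nm <- make_norm(dcq, coldata = data.frame(diagnosis = g))
    de <- deAnalysis(nm, "diagnosis", testLevel = "AD")
    expect_true(de$significant[1])
    expect_equal(de$class[1], "significant")
    expect_gt(de$rq[1], 1.5)
    expect_equal(attr(de, "m"), 20L)

    # identical groups by construction: no fold-change flags, no rejections
    dcq2 <- matrix(rnorm(10 * 8, sd = 0.2), nrow = 10)
    dcq2 <- cbind(dcq2, dcq2)
    nm2 <- make_norm(dcq2, coldata = data.frame(diagnosis = rep(g[c(1, 29)],
                                                                each = 8)))
    de2 <- deAnalysis(nm2, "diagnosis")
    expect_false(any(de2$fc_flag))
    expect_false(any(de2$significant))
})

test_that("probes without enough usable values stay out of the BH family", {
    g <- rep(c("AD", "CTL"), each = 4)
    dcq <- matrix(rnorm(3 * 8), nrow = 3)
    dcq[2, g == "AD"] <- c(1, NA, NA, NA)   # one usable value in AD
    nm <- make_norm(dcq, coldata = data.frame(diagnosis = g))
    de <- deAnalysis(nm, "diagnosis")
    expect_false(de$tested[2])
    expect_equal(de$class[2], "untested")
    expect_equal(attr(de, "m"), 2L)
})

test_that("stratified two-way ANOVA recovers the design decomposition", {
    d <- design_2x2x2(7L)
    set.seed(41)
    y <- rnorm(nrow(d), sd = 0.5)
    dcq <- matrix(y, nrow = 1, dimnames = list("p001", d$sample_id))
    nm <- make_norm(dcq, coldata = d[, c("diagnosis", "sex", "apoe")])
    res <- stratifiedAnova(nm)
    a <- res$anova
    expect_setequal(unique(a$stratum), c("female", "male"))
    expect_true(all(a$df_den == 24))          # 28 samples - 4 cells
    expect_equal(nrow(res$tukey), 2 * 6)      # 4 cells -> 6 pairs per stratum

    # Tukey adjusted p is never below the unadjusted pairwise p computed
    # from the same pooled ANOVA error term
    sel <- d$sex == "female"
    cell <- interaction(d$diagnosis[sel], d$apoe[sel])
    mse <- summary(aov(y[sel] ~ cell))[[1]]["Residuals", "Mean Sq"]
    se <- sqrt(mse * (1 / 7 + 1 / 7))
    tk <- res$tukey[res$tukey$stratum == "female", ]
    praw <- 2 * pt(-abs(tk$diff) / se, df = 24)
    expect_true(all(tk$p_adj >= praw - 1e-12))
})

test_that("ANOVA degenerate and empty-cell contracts hold", {
    d <- design_2x2x2(3L)
    dcq <- matrix(0, nrow = 1, ncol = nrow(d),
                  dimnames = list("p001", d$sample_id))
    nm <- make_norm(dcq, coldata = d[, c("diagnosis", "sex", "apoe")])
    # constant input warns once per stratum
    expect_warning(expect_warning(res <- stratifiedAnova(nm),
                                  "zero variance"), "zero variance")
    expect_true(all(res$anova$p == 1))

    dcq2 <- matrix(rnorm(nrow(d)), nrow = 1,
                   dimnames = list("p001", d$sample_id))
    dcq2[1, d$sex == "female" & d$diagnosis == "AD" & d$apoe == "e3,4"] <- NA
    nm2 <- make_norm(dcq2, coldata = d[, c("diagnosis", "sex", "apoe")])
    res2 <- stratifiedAnova(nm2)
    expect_true(any(res2$skipped$stratum == "female"))
    expect_false(any(res2$anova$stratum == "female"))
    expect_true(any(res2$anova$stratum == "male"))
})

test_that("ANOVA type-I rate and planted-interaction detection behave", {
    d <- design_2x2x2(7L)
    sel <- d$sex == "female"
    dia <- d$diagnosis[sel]; apo <- d$apoe[sel]
    set.seed(51)
    reps <- 300
    rejected <- 0L
    for (r in seq_len(reps)) {
        y <- rnorm(sum(sel))
        tab <- summary(aov(y ~ dia * apo))[[1]]
        rejected <- rejected + (tab[1, "Pr(>F)"] < 0.05)
    }
    rate <- rejected / reps
    expect_lt(abs(rate - 0.05), 2.5 * sqrt(0.05 * 0.95 / reps) + 1e-9)

    # pure interaction pattern at d = 2*sigma dominates the main effects
    sgn <- ifelse((dia == "AD") == (apo == "e3,4"), 1, -1)
    wins <- 0L
    for (r in 1:100) {
        y <- sgn * 1 + rnorm(sum(sel))  # +/-d/2 with d = 2, sigma = 1
        dcq <- matrix(y, nrow = 1,
                      dimnames = list("p1", d$sample_id[sel]))
        nm <- make_norm(dcq, coldata = data.frame(
            diagnosis = dia, sex = "female", apoe = apo))
        a <- stratifiedAnova(nm)$anova
        Fs <- a$F[match(c("diagnosis", "apoe", "interaction"), a$effect)]
        wins <- wins + (which.max(Fs) == 3L)
    }
    expect_gte(wins / 100, 0.95)
})

test_that("main-effect F is reconstructed from cell summaries", {
    cells <- data.frame(g = c("a", "b"), mean = c(0, 0), sd = 1, n = 5)
    expect_equal(anovaFromCellSummaries(cells, "g")$F, 0)

    cells$mean <- c(0, 1)
    res <- anovaFromCellSummaries(cells, "g")
    expect_equal(res$F, 2.5)           # 5*(0.5^2+0.5^2) / 1
    expect_equal(res$df_num, 1L)
    expect_equal(res$df_den, 8L)

    cells$n <- c(5, 1)
    expect_error(anovaFromCellSummaries(cells, "g"), "n >= 2")

    # agreement with aov() on raw data, via exact cell summaries
    set.seed(61)
    d <- design_2x2x2(7L)
    y <- rnorm(nrow(d)) + 2 * (d$diagnosis == "AD")
    agg <- aggregate(y, d[, c("diagnosis", "sex", "apoe")],
                     function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
    cells <- data.frame(agg[, 1:3], mean = agg$x[, "mean"],
                        sd = agg$x[, "sd"], n = agg$x[, "n"])
    got <- anovaFromCellSummaries(cells, "diagnosis")
    # reference: one-way F of diagnosis with the pure within-cell error term
    fit <- aov(y ~ diagnosis + interaction(diagnosis, sex, apoe), data = d)
    ss <- summary(fit)[[1]]
    Fref <- (ss["diagnosis", "Sum Sq"] / 1) /
        (ss["Residuals", "Sum Sq"] / ss["Residuals", "Df"])
    expect_equal(got$F, Fref, tolerance = 1e-9)
    expect_equal(got$df_den, ss["Residuals", "Df"])
})

test_that("balanced two-way ANOVA sums of squares decompose exactly", {
    set.seed(71)
    d <- design_2x2x2(5L)
    sel <- d$sex == "male"
    y <- rnorm(sum(sel), sd = 0.7) + (d$diagnosis[sel] == "AD") * 0.5
    fit <- aov(y ~ diagnosis * apoe, data = d[sel, ])
    tab <- summary(fit)[[1]]
    sstot <- sum((y - mean(y))^2)
    expect_equal(sum(tab[, "Sum Sq"]), sstot, tolerance = 1e-9)
})
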