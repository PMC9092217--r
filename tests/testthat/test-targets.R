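pairs_df <- function(mirna, genes)
    data.frame(mirna_id = mirna, gene_id = genes, stringsAsFactors = FALSE)

test_that("score filtering honors each source's cutoff orientation", {
    ts <- data.frame(mirna_id = "m1", gene_id = c("g1", "g2", "g3"),
                     score = c(-0.45, -0.1, -0.3))
    kept <- filterPredictions(ts, "targetscan")
    expect_setequal(kept$gene_id, c("g1", "g3"))   # -0.3 boundary kept

    db <- data.frame(mirna_id = "m1", gene_id = c("g1", "g2", "g3"),
                     score = c(60, 59.9, 95))
    kept2 <- filterPredictions(db, "mirdb")
    expect_setequal(kept2$gene_id, c("g1", "g3"))  # 60 boundary kept
    expect_error(filterPredictions(db, "other"))
})

test_that("relaxing a threshold never shrinks the retained set", {
    set.seed(17)
    tab <- data.frame(mirna_id = sample(paste0("m", 1:3), 200, TRUE),
                      gene_id = paste0("g", 1:200),
                      score = runif(200, -2, 0))
    strict <- filterPredictions(tab, "targetscan", -0.5)
    loose <- filterPredictions(tab, "targetscan", -0.2)
    expect_true(all(paste(strict$mirna_id, strict$gene_id) %in%
                    paste(loose$mirna_id, loose$gene_id)))
})

test_that("set combination follows standard semantics", {
    a <- pairs_df("m1", c("g1", "g2"))
    b <- pairs_df("m1", c("g3", "g4", "g5"))
    expect_equal(nrow(combineTargets(a, b, "union")), 5L)
    expect_equal(nrow(combineTargets(a, b, "intersection")), 0L)
    expect_equal(combineTargets(a, a, "intersection"), a)
    expect_equal(combineTargets(a, b, "A"), a)
    expect_setequal(geneTargets(rbind(a, pairs_df("m2", "g2"))),
                    c("g1", "g2"))
})

test_that("union accounting reproduces the published two-source arithmetic", {
    acc <- unionAccounting(272, 2245, 198)
    expect_equal(acc$union, 2319)
    expect_equal(acc$unique_a, 74)
    expect_equal(acc$unique_b, 2047)
    expect_equal(unionAccounting(9, 9, 9), list(union = 9, unique_a = 0,
                                                unique_b = 0))
    expect_equal(unionAccounting(5, 7, 0)$union, 12)
    expect_error(unionAccounting(5, 7, 6), "overlap")
})

test_that("benchmarking counts the 2x2 classification over the closed universe", {
    uni <- paste0("g", 1:10)
    validated <- list(pairs = pairs_df("m1", paste0("g", 1:4)),
                      universe = uni)
    predicted <- pairs_df("m1", c("g1", "g2", "g5"))
    bm <- benchmarkStrategy(predicted, validated, mirnas = "m1")
    expect_equal(bm[, c("TP", "FP", "FN", "TN")],
                 data.frame(TP = 2L, FP = 1L, FN = 2L, TN = 5L))
    expect_equal(bm$sensitivity, 0.5)
    expect_equal(bm$specificity, 5 / 6)
    expect_equal(bm$precision, 2 / 3)
    expect_equal(bm$TP + bm$FP + bm$FN + bm$TN, 10L)

    exact <- benchmarkStrategy(validated$pairs, validated, mirnas = "m1")
    expect_equal(exact$sensitivity, 1)
    expect_equal(exact$precision, 1)

    none <- benchmarkStrategy(pairs_df(character(0), character(0)),
                              validated, mirnas = "m1")
    expect_equal(none$sensitivity, 0)
    expect_equal(none$specificity, 1)
    expect_true(is.na(none$precision))
    expect_error(benchmarkStrategy(predicted,
                                   list(pairs = validated$pairs,
                                        universe = character(0))),
                 "universe")
})

test_that("the default universe is the union of predicted and validated genes", {
    a <- pairs_df("m1", c("g1", "g2"))
    b <- pairs_df("m2", c("g2", "g3"))
    v <- pairs_df("m1", c("g3", "g9"))
    expect_equal(declareUniverse(a, b, v), c("g1", "g2", "g3", "g9"))
})

test_that("union dominates either source in sensitivity, not specificity", {
    set.seed(19)
    for (i in 1:10) {
        tt <- generateTargetTables(nMirnas = 3, nGenes = 200, seed = i)
        a <- filterPredictions(tt$targetscan, "targetscan")
        b <- filterPredictions(tt$mirdb, "mirdb")
        bm <- benchmarkAll(a, b, tt$validated,
                           mirnas = sprintf("syn-miR-%04d", 1:3))
        u <- bm[bm$strategy == "union", ]
        for (s in c("A", "B")) {
            one <- bm[bm$strategy == s, ]
            expect_gte(u$sensitivity, one$sensitivity)
            expect_lte(u$specificity, one$specificity)
        }
    }
})

test_that("strategy selection is lexicographic with auditable ties", {
    tbl <- data.frame(strategy = c("union", "A"),
                      sensitivity = c(0.9, 0.5), specificity = c(0.9, 0.5),
                      precision = c(0.9, 0.5))
    expect_equal(as.character(selectStrategy(tbl)), "union")  # dominance

    tbl2 <- data.frame(strategy = c("x", "y"),
                       sensitivity = c(0.5, 0.5), specificity = c(0.8, 0.8),
                       precision = c(0.7, 0.7))
    expect_message(pick <- selectStrategy(tbl2), "tie")
    expect_equal(as.character(pick), "x")

    # non-dominated pair follows the configured priority order
    tbl3 <- data.frame(strategy = c("sens", "prec"),
                       sensitivity = c(0.9, 0.4), specificity = c(0.5, 0.9),
                       precision = c(0.4, 0.9))
    expect_equal(as.character(selectStrategy(tbl3)), "sens")
    expect_equal(as.character(
        selectStrategy(tbl3, rule = c("precision", "sensitivity",
                                      "specificity"))), "prec")
    expect_false(is.null(attr(selectStrategy(tbl3), "table")))
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
    # universe 20, targets 5, pathway 4, overlap 3
    uni <- paste0("g", 1:20)
    targets <- paste0("g", 1:5)
    pathway <- list(P = c("g1", "g2", "g3", "g9"))
    res <- overRepresentation(targets, pathway, uni, q = 0.05)
    enum <- sum(vapply(3:4, function(k)
        choose(4, k) * choose(16, 5 - k), numeric(1))) / choose(20, 5)
    expect_equal(res$p, enum, tolerance = 1e-12)

    # pathway equal to the target set beats every competitor
    pws <- list(exact = targets, other = paste0("g", 6:10),
                mixed = paste0("g", 3:7))
    res2 <- overRepresentation(targets, pws, uni, q = 0.05)
    expect_equal(res2$pathway[1], "exact")

    # disjoint pathway is never called enriched
    res3 <- overRepresentation(targets, list(dj = paste0("g", 11:14)),
                               uni, q = 0.01)
    expect_gt(res3$p, 0.5)
    expect_false(res3$bh_rejected)

    expect_warning(
        res4 <- overRepresentation(targets, list(bad = c("g1", "nope")), uni),
        "outside the universe")
    expect_equal(nrow(res4), 0L)
})

test_that("GMT files round trip through the reader", {
    tf <- tempfile(fileext = ".gmt")
    writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), tf)
    gs <- readGmt(tf)
    expect_equal(gs$setA, c("g1", "g2", "g3"))
    expect_equal(gs$setB, c("g2", "g4"))
})
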