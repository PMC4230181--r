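test_that("mean-normalization divides by the gene mean and log2-transforms", {
  m <- matrix(c(5, 5, 5,
                1, 2, 4), 2, 3, byrow = TRUE,
              dimnames = list(c("flat", "ramp"), c("s1", "s2", "s3")))
  out <- meanNormalize(m)
  expect_equal(unname(out["flat", ]), c(0, 0, 0))
  expect_equal(unname(out["ramp", ]), log2(c(1, 2, 4) / mean(c(1, 2, 4))))
  # normalization identity: back-transformed row means are 1
  expect_equal(unname(rowMeans(2^out)), c(1, 1))
  # two-sample gene (2, 4): mean 3, so entries log2(2/3), log2(4/3) --
  # symmetric about the half-log of their product
  m2 <- matrix(c(2, 4), 1, 2, dimnames = list("g", c("a", "b")))
  out2 <- meanNormalize(m2)
  expect_equal(unname(out2[1, ]), c(log2(2 / 3), log2(4 / 3)))
  expect_equal(mean(out2[1, ]), log2(8 / 9) / 2)
  expect_error(meanNormalize(matrix(c(1, -1), 1, 2,
                                    dimnames = list("g", NULL))), "positive")
})

test_that("Spearman rs reaches the stated extremes and the hand-computed value", {
  expect_equal(spearmanRs(1:10, (1:10)^3), 1)
  expect_equal(spearmanRs(1:10, -(1:10)^3), -1)
  # rank-difference formula by hand: d = (-1, 1, -1, 1), rs = 1 - 24/60
  expect_equal(spearmanRs(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(spearmanRs(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearmanRs(1:3, 1:4), "equal length")
})

test_that("Spearman rs is invariant under strictly monotone transforms", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    r0 <- spearmanRs(x, y)
    expect_equal(spearmanRs(exp(x), y), r0)
    expect_equal(spearmanRs(x, y^3 + 2 * y), r0)
  }
})

test_that("exact permutation p-value enumerates the small-sample null", {
  expect_equal(spearmanPvalue(1, 5), 2 / 120)
  expect_equal(spearmanPvalue(-1, 5), 2 / 120)
  # rs = 0 at large n is maximally non-significant
  expect_gt(spearmanPvalue(0, 100), 0.99)
  # perfect correlation in the approximation branch stays positive
  expect_gt(spearmanPvalue(1, 50), 0)
  expect_error(spearmanPvalue(0.5, 3), ">= 4")
  expect_error(spearmanPvalue(1.5, 10), "correlation")
})

test_that("t approximation tracks the exact permutation p at n = 9", {
  set.seed(7)
  for (i in 1:25) {
    y <- sample(9)
    rs <- spearmanRs(1:9, y)
    exact <- spearmanPvalue(rs, 9)
    approx <- if (abs(rs) >= 1) .Machine$double.xmin else
      min(1, 2 * pt(-abs(rs * sqrt((9 - 2) / (1 - rs^2))), df = 7))
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("co-response queries cover the requested pairs, sorted by |rs|", {
  se <- genExpressionMatrix(12, 30, blockSizes = c(4, 4),
                            latentCorrelation = 0.8, seed = 3)
  norm <- meanNormalize(se)
  one <- coresponseQuery(norm, "gene0001", "gene0002", mode = "sGQ")
  expect_identical(nrow(one), 1L)
  genes <- sprintf("gene%04d", 1:5)
  mgq <- coresponseQuery(norm, genes, mode = "mGQ")
  expect_identical(nrow(mgq), 10L)  # k(k-1)/2 pairs for k = 5
  expect_true(all(diff(abs(mgq$rs)) <= 1e-12))
  expect_true(all(mgq$rs >= -1 & mgq$rs <= 1))
  # symmetric in the pair order
  ab <- coresponseQuery(norm, "gene0001", "gene0002", mode = "sGQ")$rs
  ba <- coresponseQuery(norm, "gene0002", "gene0001", mode = "sGQ")$rs
  expect_equal(ab, ba)
  expect_error(coresponseQuery(norm, "gene0001", "nope", mode = "sGQ"),
               "not in the expression matrix")
})

test_that("within-block co-response exceeds between-block on a structured matrix", {
  se <- genExpressionMatrix(20, 60, blockSizes = c(8, 8),
                            latentCorrelation = 0.8, noiseSd = 1, seed = 9)
  norm <- meanNormalize(se)
  b1 <- sprintf("gene%04d", 1:8)
  b2 <- sprintf("gene%04d", 9:16)
  within <- coresponseQuery(norm, b1, mode = "mGQ")
  between <- mean(abs(vapply(seq_along(b1), function(i)
    spearmanRs(SummarizedExperiment::assay(norm)[b1[i], ],
               SummarizedExperiment::assay(norm)[b2[i], ]), numeric(1))))
  expect_gt(mean(abs(within$rs)), between)
})

test_that("co-expression classes respect their thresholds and sweep monotonically", {
  expect_identical(classifyCoexpression(1), "high")
  expect_identical(classifyCoexpression(0), "low")
  expect_identical(classifyCoexpression(0.5), "intermediate")
  expect_identical(classifyCoexpression(-0.9), "intermediate")
  expect_error(classifyCoexpression(0.5, highThreshold = 0.2,
                                    lowThreshold = 0.4), "lowThreshold")
  # as the high cutoff falls, a pair can only move toward "high"
  rs <- 0.65
  lab <- vapply(seq(0.9, 0.3, by = -0.1), function(h)
    classifyCoexpression(rs, highThreshold = h, lowThreshold = 0.1),
    character(1))
  firstHigh <- match("high", lab)
  expect_true(all(lab[firstHigh:length(lab)] == "high"))
})

test_that("segment summaries aggregate mean and sd with the one-gene convention", {
  m <- matrix(c(2, 1,
                -2, 1,
                5, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  map <- data.frame(gene_id = c("g1", "g2", "g3"),
                    segment_id = c("segA", "segA", "segB"))
  out <- segmentMeanExpression(m, map, sample = "s1")
  segA <- out[out$segment_id == "segA", ]
  expect_equal(segA$mean_expression, 0)          # v and -v average to zero
  expect_equal(segA$sd_expression, sd(c(2, -2)))
  segB <- out[out$segment_id == "segB", ]
  expect_identical(segB$gene_count, 1L)
  expect_equal(segB$mean_expression, 5)
  expect_equal(segB$sd_expression, 0)            # single-gene convention
  expect_error(segmentMeanExpression(m, map[0, ]), "empty")
  expect_error(segmentMeanExpression(
    m, data.frame(gene_id = "gX", segment_id = "segA")), "absent")
})

test_that("genes map to segments by coordinate overlap", {
  segs <- genSegmentAnnotation(
    c(Chr1 = 1e6),
    data.frame(chrom = "Chr1", start = c(0, 100000),
               length = c(100000, 50000), id = c("BAC1", "BAC2")))
  genes <- GenomicRanges::GRanges("Chr1",
    IRanges::IRanges(start = c(500, 120000, 900000), width = 1000))
  names(genes) <- c("gA", "gB", "gC")
  map <- segmentMapFromRanges(genes, segs)
  expect_identical(map$gene_id, c("gA", "gB"))
  expect_identical(map$segment_id, c("BAC1", "BAC2"))
})
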