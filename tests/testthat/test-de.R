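test_that("exact-test edge cases and the directional structure hold", {
  expect_equal(acPValue(0, 0, 1e6, 1e6), 1)
  expect_equal(acTailProbs(0, 0, 1e6, 1e6)[["lower"]], 0.5, tolerance = 1e-12)

  # the statistic conditions on the first library's count, so it is
  # directional: equal counts in equal libraries are exactly symmetric, and
  # both orientations always agree on the order of magnitude of evidence
  expect_equal(acPValue(7, 7, 2e5, 2e5), acPValue(7, 7, 2e5, 2e5))
  set.seed(31)
  xs <- sample(0:100, 25L, replace = TRUE)
  ys <- sample(0:100, 25L, replace = TRUE)
  a <- acPValue(xs, ys, 1e5, 3e5)
  b <- acPValue(ys, xs, 3e5, 1e5)
  expect_true(all(abs(log10(a) - log10(b)) < 1))
  expect_error(acPValue(1.5, 2, 10, 10), "non-negative integers")
})

test_that("conditional masses are normalized and tails agree with the
           negative-binomial cross-check", {
  for (x in c(0L, 3L, 17L, 50L)) {
    # the lower tail exhausts the distribution far beyond the mode
    expect_equal(acTailProbs(x, 3000L, 2e5, 2e5)[["lower"]], 1,
                 tolerance = 1e-9)
  }
  # the conditional law of y given x is NegBinomial(x+1, n1/(n1+n2))
  for (n2 in c(1e5, 2e5)) {
    for (x in c(0L, 5L, 40L)) {
      for (y in c(0L, 7L, 60L)) {
        tails <- acTailProbs(x, y, 1e5, n2)
        expect_equal(tails[["lower"]],
                     pnbinom(y, size = x + 1, prob = 1e5 / (1e5 + n2)),
                     tolerance = 1e-10)
        expect_equal(tails[["upper"]],
                     pnbinom(y - 1, size = x + 1, prob = 1e5 / (1e5 + n2),
                             lower.tail = FALSE),
                     tolerance = 1e-10)
      }
    }
  }
  # stability at large counts: equal proportions stay non-significant
  expect_gt(acPValue(1e6L, 1e6L, 5e6, 5e6), 0.9)
})

test_that("log2 ratio uses normalized proportions with a pseudocount", {
  expect_equal(log2Ratio(10, 20, 1e6, 1e6, pseudocount = 0), 1)
  expect_equal(log2Ratio(12, 12, 1e6, 1e6, pseudocount = 0), 0)
  expect_equal(log2Ratio(0, 8, 1e6, 1e6, pseudocount = 0.5),
               4.08746284125034, tolerance = 1e-12)  # log2(8.5/0.5)
  expect_equal(log2Ratio(10, 10, 2e6, 1e6, pseudocount = 0), 1)  # size-adjusted
  expect_error(log2Ratio(0, 8, 1e6, 1e6, pseudocount = 0), "pseudocount")
})

test_that("BH q-values match the direct step-up formula", {
  expect_equal(bhFDR(0.03), 0.03)
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bhFDR(rep(0.2, 5L)), rep(0.2, 5L))
  set.seed(32)
  p <- runif(200L)^2
  expect_equal(bhFDR(p), bruteBH(p))
  expect_true(all(bhFDR(p) >= p))
  expect_error(bhFDR(c(0.5, 0)), "0, 1")
  expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
})

test_that("DE calls combine the ratio and significance thresholds", {
  n <- 5e5
  mk <- function(xs, id) computeTPM(stats::setNames(xs, paste0("g", seq_along(xs))),
                                    n, id)
  base <- c(300, 300, 100, 200, 0)
  up4 <- c(1200, 300, 100, 200, 40)   # g1 4x up, g5 0 -> 40
  a <- mk(base, "A"); b <- mk(up4, "B")
  de <- callDEGenes(a, b)
  expect_identical(de$call[1L], "up")
  expect_identical(de$call[2L], "ns")
  expect_identical(de$call[5L], "up")
  s <- summarizeDECalls(de)
  expect_identical(s$total, s$up + s$down)

  # identical libraries: nothing is called
  de0 <- callDEGenes(a, a)
  expect_identical(unique(de0$call), "ns")
  expect_true(all(de0$pValue == 1))

  # exchange antisymmetry: swapping libraries flips calls and negates ratios
  deSwap <- callDEGenes(b, a)
  expect_equal(deSwap$log2Ratio, -de$log2Ratio)
  expect_identical(deSwap$call[de$call == "up"],
                   rep("down", sum(de$call == "up")))
  expect_identical(deSwap$call[de$call == "ns"],
                   rep("ns", sum(de$call == "ns")))

  # q >= p within a comparison
  expect_true(all(de$qValue >= de$pValue - 1e-15))
})

test_that("significance modes gate on q or on p as requested", {
  n <- 5e5
  x <- stats::setNames(c(40, rep(100, 60)), paste0("g", 1:61))
  y <- stats::setNames(c(110, rep(100, 60)), paste0("g", 1:61))
  a <- computeTPM(x, n, "A"); b <- computeTPM(y, n, "B")
  pRaw <- acPValue(40, 110, n, n)
  qAdj <- callDEGenes(a, b, sigMode = "fdr")$qValue[1L]
  expect_gt(qAdj, pRaw)  # multiplicity pushes the borderline gene up
  deP <- callDEGenes(a, b, sigMode = "p", alpha = pRaw * 1.01)
  deQ <- callDEGenes(a, b, sigMode = "fdr", alpha = qAdj * 0.99)
  expect_identical(deP$call[1L], "up")
  expect_identical(deQ$call[1L], "ns")
})

test_that("mismatched gene universes are rejected with the difference listed", {
  a <- computeTPM(c(g1 = 2, g2 = 3), 100, "A")
  b <- computeTPM(c(g1 = 2, g3 = 3), 100, "B")
  expect_error(callDEGenes(a, b), "only in A: g2; only in B: g3")
  # same universe in different order is accepted
  b2 <- computeTPM(c(g2 = 30, g1 = 2), 100, "B")
  de <- callDEGenes(a, b2)
  expect_identical(de$gene, c("g1", "g2"))
  expect_identical(de$y, c(2, 30))
})
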