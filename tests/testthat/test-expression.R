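test_that("probe filtering removes rows above the missingness threshold", {
  m <- rbind(a = c(rep(NA, 5L), 1, 2, 3),       # 5/8 missing -> out
             b = c(rep(NA, 4L), 1, 2, 3, 4),    # 4/8 missing -> kept
             c = 1:8)
  out <- filterProbes(m)
  expect_identical(rownames(out), c("b", "c"))
  expect_identical(filterProbes(matrix(1:8, 2L)), matrix(1:8, 2L))
  expect_warning(filterProbes(rbind(x = c(NA, NA, NA, 1))), "all probes")
  # class-preserving on the S4 container
  em <- ExpressionMatrix(m, groups = rep(c("oe", "ctrl"), each = 4L))
  expect_s4_class(filterProbes(em), "ExpressionMatrix")
  expect_identical(rownames(filterProbes(em)), c("b", "c"))
})

test_that("quantile normalization equalizes column distributions", {
  out <- quantileNormalize(cbind(a = c(3, 1, 2), b = c(6, 4, 5)))
  expect_equal(unname(out[, "a"]), c(4.5, 2.5, 3.5))
  expect_equal(unname(out[, "b"]), c(4.5, 2.5, 3.5))
  same <- matrix(c(5, 1, 9), 3L, 4L)
  expect_equal(quantileNormalize(same), same)
  set.seed(10)
  m <- matrix(rnorm(600), ncol = 6L)
  q1 <- quantileNormalize(m)
  sorted <- apply(q1, 2L, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1L])
  expect_equal(quantileNormalize(q1), q1)        # idempotent
  expect_warning(one <- quantileNormalize(matrix(1:3)), "single-column")
  expect_equal(one, matrix(1:3))
  # independent cross-check on complete matrices
  expect_equal(unname(q1), unname(limma::normalizeQuantiles(m)),
               tolerance = 1e-12)
})

test_that("the SAM d statistic matches its closed form", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1L,
              dimnames = list("p1", NULL))
  fit <- samTwoClass(m, groups = rep(c("g1", "g2"), each = 3L),
                     s0 = 0, delta = 10)
  expect_equal(round(unname(dScores(fit)), 3), -3.674)
  # swapping which group is the minuend negates every d score
  set.seed(3)
  mm <- matrix(rnorm(200), ncol = 8L)
  g <- rep(c("A", "B"), each = 4L)
  d1 <- dScores(samTwoClass(mm, g, s0 = 0.1, delta = 10, seed = 1L))
  d2 <- dScores(samTwoClass(mm[, c(5:8, 1:4)], g, s0 = 0.1, delta = 10,
                            seed = 1L))
  expect_equal(unname(d1), -unname(d2))
})

test_that("SAM flags probes without two usable values per group", {
  m <- matrix(rnorm(40), ncol = 8L,
              dimnames = list(paste0("p", 1:5), NULL))
  m[1L, 1:3] <- NA                       # one usable value in group 1
  fit <- samTwoClass(m, rep(c("A", "B"), each = 4L), s0 = 0.05,
                     delta = 10, seed = 1L)
  expect_true("p1" %in% fit@flagged)
  expect_true(is.na(dScores(fit)[["p1"]]))
  expect_false(anyNA(dScores(fit)[-1L]))
})

test_that("SAM finds planted effects on a spiked matrix", {
  sim <- simulateExpressionMatrix(ExpressionSimParams(seed = 11L))
  fit <- samTwoClass(sim$matrix, targetFdr = 0.10, seed = 11L)
  called <- unlist(significantProbes(fit))
  truthDe <- sim$truth$probe_id[sim$truth$de]
  expect_gte(length(intersect(called, truthDe)) / length(truthDe), 0.7)
  expect_lte(fit@fdrEstimate, 0.10)
  # directions match the planted signs (group 1 = oe is the minuend)
  ups <- sim$truth$probe_id[sim$truth$direction == "up"]
  expect_gt(length(intersect(significantProbes(fit)$up, ups)),
            length(intersect(significantProbes(fit)$down, ups)))
})

test_that("fold changes and ratio normalizations follow their formulas", {
  expect_equal(log2FoldChange(8, 2), 2)
  expect_equal(log2FoldChange(4, 4), 0)
  expect_equal(log2FoldChange(2, 8), -2)
  expect_error(log2FoldChange(0, 1), "positive")
  expect_equal(perIntensity(200, 100), 100)
  expect_equal(perIntensity(100, 100), 0)
  expect_equal(perIntensity(50, 100), -50)
  expect_error(perIntensity(10, 0), "positive")
  expect_equal(luciferaseRelativeActivity(5, 2, 2.5), 1)
  expect_equal(luciferaseRelativeActivity(10, 2, 2.5), 2)
  expect_equal(luciferaseRelativeActivity(20, 4, 2.5),
               luciferaseRelativeActivity(10, 2, 2.5))
  expect_error(luciferaseRelativeActivity(1, 0, 1), "positive")
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  expect_equal(hypergeometricEnrichment(10, 5, 5, 0), 1.0)
  expect_equal(hypergeometricEnrichment(10, 5, 5, 5), 1 / 252)
  expect_error(hypergeometricEnrichment(10, 11, 5, 2), "invalid")
  for (N in c(6L, 9L, 12L)) for (K in 0:N) for (n in 0:N)
    for (k in 0:min(K, n)) {
      expect_equal(hypergeometricEnrichment(N, K, n, k),
                   enumHyperTail(N, K, n, k), tolerance = 1e-12)
    }
  # tail monotone non-increasing in k
  ps <- sapply(0:5, function(k) hypergeometricEnrichment(20, 8, 5, k))
  expect_true(all(diff(ps) <= 0))
})

test_that("relative quantification follows 2^-ddCt", {
  expect_equal(deltaDeltaCt(20, 20, 20, 20), 1)
  expect_equal(deltaDeltaCt(19, 20, 20, 20), 2)
  expect_equal(deltaDeltaCt(20, 18, 24, 19), 8)
  expect_equal(deltaDeltaCt(c(19, 21), c(20, 20), 20, 20), 1)  # averaged
  expect_error(deltaDeltaCt(NA, 1, 1, 1), "finite")
  # recovers the simulator's truth exactly at zero noise
  tab <- simulateQpcrCt(5, nReplicates = 3L, ctNoiseSd = 0, seed = 1L)
  expect_equal(rqFromCtTable(tab), 5)
})

test_that("expression matrices round trip through the TSV format", {
  sim <- simulateExpressionMatrix(ExpressionSimParams(nProbes = 30L,
                                                      naFraction = 0.1,
                                                      seed = 6L))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(sim$matrix, tmp)
  back <- readExpressionMatrix(tmp)
  expect_equal(exprsValues(back), exprsValues(sim$matrix))
  expect_equal(sampleGroups(back), sampleGroups(sim$matrix))
  tl <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# predicted targets", "geneA", "", "geneB"), tl)
  expect_equal(readTargetList(tl), c("geneA", "geneB"))
})
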