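test_that("Z-score normalisation has the closed-form behaviour", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- zscoreNormalize(m)
  expect_equal(z["a", ], c(-1.2247, 0, 1.2247), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_identical(unname(attr(z, "constantRow")), c(FALSE, TRUE))
  expect_error(zscoreNormalize(matrix(numeric(0), 0, 0)), "empty")
  # every row of a normalised fixture has mean ~0 and population SD ~1
  zf <- zscoreNormalize(SummarizedExperiment::assay(toySim(1)$proteome))
  expect_lt(max(abs(rowMeans(zf))), 1e-12)
  expect_lt(max(abs(sqrt(rowMeans((zf - rowMeans(zf))^2)) - 1)), 1e-12)
})

test_that("ANOVA F and p match a brute-force sum-of-squares oracle", {
  sim <- simulateProteome(toyNet(), seed = 7, clusterSize = 2L, nBackground = 10L)
  se <- sim$proteome[1:20, ]
  dep <- anovaBH(se)
  grp <- SummarizedExperiment::colData(se)$group
  mat <- log2(SummarizedExperiment::assay(se, "abundance"))
  for (i in seq_len(nrow(mat))) {
    ref <- ssAnova(mat[i, ], grp)
    expect_equal(dep$F[i], unname(ref["F"]), tolerance = 1e-10)
    expect_equal(dep$p[i], unname(ref["p"]), tolerance = 1e-10)
  }
})

test_that("BH step-up gives the textbook adjusted values and is monotone", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(stats::p.adjust(p, "BH"), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(stats::p.adjust(0.2, "BH"), 0.2)     # q = p when m = 1
  dep <- anovaBH(toySim(1)$proteome)
  ord <- order(dep$p)
  expect_true(all(diff(dep$q[ord]) >= -1e-12))
  expect_true(all(dep$q >= 0 & dep$q <= 1))
  expect_identical(dep$significant, dep$q < 0.05)
})

test_that("two-group ANOVA equals the squared pooled t statistic", {
  set.seed(11)
  y <- rnorm(12)
  g <- rep(c("A", "B"), each = 6)
  f <- ssAnova(y, g)[["F"]]
  tt <- stats::t.test(y ~ g, var.equal = TRUE)$statistic
  expect_equal(f, unname(tt)^2, tolerance = 1e-10)
  ft <- stats::oneway.test(y ~ factor(g), var.equal = TRUE)
  expect_equal(unname(ft$statistic), f, tolerance = 1e-10)
})

test_that("near-constant groups are never significant", {
  ab <- matrix(100 + rnorm(5 * 18, sd = 1e-6), 5, 18,
               dimnames = list(paste0("p", 1:5), colnames(toySim(1)$proteome)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = ab),
    colData = SummarizedExperiment::colData(toySim(1)$proteome))
  dep <- anovaBH(se)
  expect_false(any(dep$significant))
  expect_error(anovaBH(se[, 1:4]), "invalid design")
})

test_that("type-I error of the DEP calls is controlled on null data", {
  calls <- 0; total <- 0
  for (seed in 1:100) {
    sim <- simulateProteome(toyNet(), effect = 0, seed = seed,
                            clusterSize = 0L, nBackground = 40L)
    dep <- anovaBH(sim$proteome)
    calls <- calls + sum(dep$significant); total <- total + nrow(dep)
  }
  rate <- calls / total
  se2 <- 2 * sqrt(0.05 * 0.95 / total)
  expect_lte(rate, 0.05 + se2)
})

test_that("Tukey-Kramer selection matches the studentized-range oracle", {
  sim <- simulateProteome(toyNet(), seed = 5, clusterSize = 3L, nBackground = 5L)
  se <- sim$proteome
  reg <- tukeySelect(se, alpha = 0.05)
  grp <- SummarizedExperiment::colData(se)$group
  mat <- log2(SummarizedExperiment::assay(se, "abundance"))
  for (pr in utils::head(reg$table$protein, 15)) {
    ref <- tkP(mat[pr, ], grp, "AD_NFP", "AD_VEH")
    expect_equal(reg$table$p[reg$table$protein == pr], unname(ref),
                 tolerance = 1e-6)
  }
  expect_length(intersect(reg$upregulated, reg$downregulated), 0)
  # unequal group sizes (3, 9, 6) are accepted
  expect_equal(as.vector(table(grp)), c(3, 9, 6))
  expect_error(tukeySelect(se[, 1:12]), "unsupported design")
})

test_that("a protein with equal disease/treated means is never selected", {
  set.seed(42)
  ab <- 2^matrix(20 + rnorm(3 * 18, sd = 0.1), 3, 18)
  # protein 1: identical AD_VEH and AD_NFP means by construction
  cd <- SummarizedExperiment::colData(toySim(1)$proteome)
  dimnames(ab) <- list(paste0("p", 1:3), rownames(cd))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = ab), colData = cd)
  reg <- tukeySelect(se)
  expect_false("p1" %in% c(reg$upregulated, reg$downregulated) &&
                 abs(reg$table$diff[1]) < 1e-12)
})

test_that("presence Venn counts enumerate the seven regions", {
  v <- presenceVenn(list(A = c("a", "b"), B = c("b", "c"), C = "b"))
  expect_equal(unname(v["A&B&C"]), 1)
  expect_equal(sum(v), 3)
  ident <- presenceVenn(list(X = letters[1:4], Y = letters[1:4], Z = letters[1:4]))
  expect_equal(unname(ident["X&Y&Z"]), 4)
  expect_equal(sum(ident), 4)
  # random sets: region counts reproduce brute-force membership tabulation
  set.seed(1)
  for (rep in 1:5) {
    sets <- lapply(1:3, function(i) sample(letters, sample(5:20, 1)))
    names(sets) <- c("S1", "S2", "S3")
    v <- presenceVenn(sets)
    expect_equal(sum(v), length(unique(unlist(sets))))
    inAll <- sum(letters %in% sets$S1 & letters %in% sets$S2 & letters %in% sets$S3)
    expect_equal(unname(v["S1&S2&S3"]), inAll)
    only1 <- sum(letters %in% sets$S1 & !(letters %in% sets$S2) & !(letters %in% sets$S3))
    expect_equal(unname(v["S1"]), only1)
  }
})
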