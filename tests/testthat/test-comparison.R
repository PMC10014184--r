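test_that("exact rank-sum p-values match full enumeration", {
  # hand case: complete separation at n = (2, 2)
  res <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 2 / 6, tolerance = 1e-12)
  expect_true(res$exact)
  # all sample-size splits up to n1 + n2 <= 12, tie-free random data
  set.seed(9)
  for (n1 in 2:6) for (n2 in n1:(12 - n1)) {
    if (n2 < 2) next
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(wilcoxonRankSum(x, y)$p, enumWilcoxP(x, y),
                 tolerance = 1e-12,
                 label = sprintf("exact p at n=(%d,%d)", n1, n2))
  }
  # the study's group sizes: 5005 arrangements at n = (9, 6)
  set.seed(10)
  x <- rnorm(9); y <- rnorm(6)
  expect_equal(wilcoxonRankSum(x, y)$p, enumWilcoxP(x, y), tolerance = 1e-12)
})

test_that("rank-sum test is symmetric and handles identical samples", {
  set.seed(2)
  x <- rnorm(5); y <- rnorm(7)
  expect_equal(wilcoxonRankSum(x, y)$p, wilcoxonRankSum(y, x)$p)
  expect_equal(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(wilcoxonRankSum(1, c(1, 2)), "invalid sample")
})

test_that("restoration classification implements the median + two-test rule", {
  set.seed(4)
  wt <- rnorm(3, 1, 0.05); ad <- rnorm(9, 5, 0.05); nfp <- rnorm(6, 1, 0.05)
  res <- classifyRestoration(wt, ad, nfp)
  expect_equal(res$label, "significantly_decreased_flux_sum")
  expect_lt(res$p_ad_vs_wt, 0.05)
  expect_lt(res$p_nfp_vs_ad, 0.05)
  # mirrored pattern
  expect_equal(classifyRestoration(ad, wt, ad)$label,
               "significantly_increased_flux_sum")
  # identical groups are unchanged
  z <- rnorm(6)
  expect_equal(classifyRestoration(z, z, z)$label, "unchanged")
  # right shape but insufficient evidence: plain decreased label
  res2 <- classifyRestoration(c(1, 1.2, 0.9), c(1.3, 1.1, 1.25), c(1, 1.05, 0.95))
  expect_true(res2$label %in% c("decreased_flux_sum",
                                "significantly_decreased_flux_sum"))
})

test_that("classification is invariant to common positive rescaling", {
  set.seed(5)
  wt <- rlnorm(3); ad <- rlnorm(9, 1); nfp <- rlnorm(6)
  for (cc in c(0.01, 1, 250)) {
    expect_equal(classifyRestoration(cc * wt, cc * ad, cc * nfp)$label,
                 classifyRestoration(wt, ad, nfp)$label)
  }
})

test_that("null data rarely earns a significant restoration label", {
  # the two rank-sum tests share the disease group, so their rejections are
  # positively dependent and the naive independence product alpha^2
  # understates the truth (~0.4% at alpha = 0.05 and n = (3,9,6)); what
  # must hold is (a) the provable bound by each single test's level and
  # (b) strong suppression well below alpha
  set.seed(6)
  sig <- 0; rej1 <- 0; rej2 <- 0; n <- 0
  for (seed in 1:100) {
    for (entity in 1:40) {
      r <- classifyRestoration(rlnorm(3), rlnorm(9), rlnorm(6))
      sig <- sig + grepl("^significantly", r$label)
      rej1 <- rej1 + (r$p_ad_vs_wt < 0.05)
      rej2 <- rej2 + (r$p_nfp_vs_ad < 0.05)
      n <- n + 1
    }
  }
  expect_lte(sig / n, min(rej1, rej2) / n + 2 * sqrt(0.05 * 0.95 / n))
  expect_lte(sig / n, 0.01)
  expect_lte(rej1 / n, 0.05 + 2 * sqrt(0.05 * 0.95 / n))
  expect_lte(rej2 / n, 0.05 + 2 * sqrt(0.05 * 0.95 / n))
})

test_that("compareAll aligns entities, imputes absences and sorts by effect", {
  design <- data.frame(
    sample = c("w1", "w2", "w3", "a1", "a2", "a3", "n1", "n2", "n3"),
    group = rep(c("WT_VEH", "AD_VEH", "AD_NFP"), each = 3))
  mkFlux <- function(v) new("FluxState", fluxes = v, objective = 0,
                            status = "optimal")
  fluxes <- list(
    w1 = mkFlux(c(R = 1)), w2 = mkFlux(c(R = 1.1)), w3 = mkFlux(c(R = 0.9)),
    a1 = mkFlux(c(R = 5)), a2 = mkFlux(c(R = 5.2)), a3 = mkFlux(c(R = 4.9)),
    n1 = mkFlux(c(R = 1)), n2 = mkFlux(c(R = 1.2)), n3 = mkFlux(c(R = 0.8)))
  # metabolite M absent from every treated sample: imputed as zero + flag
  sums <- list(
    w1 = c(M = 1), w2 = c(M = 1.2), w3 = c(M = 1.1),
    a1 = c(M = 6), a2 = c(M = 6.1), a3 = c(M = 5.8),
    n1 = numeric(), n2 = numeric(), n3 = numeric())
  tab <- compareAll(fluxes, sums, design)
  expect_equal(nrow(tab), 2)              # one flux + one flux-sum entity
  m <- tab[tab$entity == "M", ]
  expect_true(m$imputed)
  expect_equal(m$median_nfp, 0)
  expect_equal(m$label, "decreased_flux_sum")
  # ordering by |median(AD) - median(NFP)| descending
  expect_equal(tab$entity, c("M", "R"))
  expect_error(compareAll(fluxes[-1], sums, design), "alignment")
})
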