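test_that("exact extraction matches the exhaustive subset oracle", {
  net <- tinyNet()
  ids <- reactions(net)$id
  cases <- list(
    c(EX_a = 0, TA = 0.2, R1 = 1, ALT = -0.5, R2 = 0, TC = 0.1, EX_c = 0),
    c(EX_a = 0, TA = -0.3, R1 = -0.2, ALT = -0.1, R2 = 0.05, TC = -0.2, EX_c = 0),
    c(EX_a = 0, TA = 0.5, R1 = -1, ALT = -0.8, R2 = 2, TC = 0.3, EX_c = 0),
    c(EX_a = 0, TA = 0.5, R1 = -0.05, ALT = -0.04, R2 = 0.01, TC = -0.3, EX_c = 0))
  for (w in cases) {
    oracle <- .oracleBest(net, w)
    got <- extractContext(net, w[ids], method = "exact")
    expect_setequal(keptReactions(got), oracle$set)
  }
})

test_that("exact extraction honours a growth task", {
  net <- tinyNet()
  ids <- reactions(net)$id
  # all conversions negative: unconstrained optimum is empty, but the
  # biomass task forces the cheapest route through
  w <- c(EX_a = 0, TA = -0.1, R1 = -0.3, ALT = -0.2, R2 = -0.1, TC = -0.1, EX_c = 0)
  oracle <- .oracleBest(net, w, requireGrowth = TRUE)
  got <- extractContext(net, w[ids], requiredTasks = list(biomass = 1e-3),
                        method = "exact")
  expect_setequal(keptReactions(got), oracle$set)
  expect_true("ALT" %in% keptReactions(got))      # cheaper of the two routes
  expect_false("R1" %in% keptReactions(got))
})

test_that("greedy and exact agree on separable fixtures", {
  net <- tinyNet()
  ids <- reactions(net)$id
  w <- c(EX_a = 0, TA = 0.5, R1 = 1, ALT = -2, R2 = 0.2, TC = 0.4, EX_c = 0)
  ex <- extractContext(net, w[ids], method = "exact")
  gr <- extractContext(net, w[ids], method = "greedy")
  expect_setequal(keptReactions(ex), keptReactions(gr))
})

test_that("all-nonnegative weights keep the full consistent network", {
  net <- toyNet()
  ids <- reactions(net)$id
  w <- stats::setNames(rep(0.5, length(ids)), ids)
  got <- extractContext(net, w, medium = defaultMedium(net), method = "greedy")
  expect_setequal(keptReactions(got), fluxConsistentSet(net, defaultMedium(net)))
})

test_that("planted design separates the context models by group", {
  net <- toyNet()
  fb <- fattyAcidBranch(net)
  core <- c("CACT", "CPT2", "BOX1", "THIO")     # interior of the branch
  sim <- toySim(1)
  expr <- sampleExpression(sim$proteome)
  med <- defaultMedium(net)
  adModel <- extractContext(net, scoreReactions(net, expr[["AD_VEH_1"]]),
                            medium = med, requiredTasks = list(biomass = 1e-3),
                            method = "greedy")
  wtModel <- extractContext(net, scoreReactions(net, expr[["WT_VEH_1"]]),
                            medium = med, requiredTasks = list(biomass = 1e-3),
                            method = "greedy")
  expect_true(all(core %in% keptReactions(adModel)))
  expect_gte(length(setdiff(fb$reactions, keptReactions(wtModel))), 1)
})

test_that("greedy extraction never returns an infeasible model", {
  net <- tinyNet()
  ids <- reactions(net)$id
  set.seed(3)
  for (rep in 1:10) {
    w <- stats::setNames(rnorm(length(ids), 0, 0.5), ids)
    got <- extractContext(net, w, method = "greedy")
    kept <- keptReactions(got)
    if (length(kept))
      expect_setequal(fluxConsistentSet(subnetwork(net, kept)), kept)
  }
})

test_that("gap-fill finds minimum-cardinality repairs", {
  net <- tinyNet()
  ids <- reactions(net)$id
  med <- c(EX_a = 10)
  # context that already grows: nothing added
  full <- new("ContextModel", parent = net, kept = ids,
              gapfilled = character(), medium = med,
              sampleId = "s", group = "g")
  expect_length(gapfilledReactions(gapfillGrowth(full)), 0)
  # delete one essential transport: exactly that single reaction is added
  ctx <- new("ContextModel", parent = net, kept = setdiff(ids, "TA"),
             gapfilled = character(), medium = med, sampleId = "s", group = "g")
  fixed <- gapfillGrowth(ctx)
  expect_identical(gapfilledReactions(fixed), "TA")
  # brute-force single-addition scan confirms minimality
  singles <- setdiff(ids, keptReactions(ctx))
  okSingles <- Filter(function(r)
    optimizeGrowth(subnetwork(net, c(keptReactions(ctx), r)), med)@objective >= 1e-3,
    singles)
  expect_identical(sort(okSingles), sort(gapfilledReactions(fixed)))
  # idempotence
  expect_identical(gapfilledReactions(gapfillGrowth(fixed)),
                   gapfilledReactions(fixed))
})

test_that("gap-fill matches the exhaustive minimal-subset oracle", {
  net <- tinyNet()
  ids <- reactions(net)$id
  med <- c(EX_a = 10)
  # remove both conversion routes and the export: oracle must find the
  # smallest repair set over all candidate subsets
  removed <- c("R1", "ALT", "TC")
  ctx <- new("ContextModel", parent = net, kept = setdiff(ids, removed),
             gapfilled = character(), medium = med, sampleId = "s", group = "g")
  fixed <- gapfillGrowth(ctx)
  oracleSize <- NA
  for (k in 1:3) {
    sets <- utils::combn(removed, k, simplify = FALSE)
    ok <- vapply(sets, function(s)
      optimizeGrowth(subnetwork(net, c(keptReactions(ctx), s)), med)@objective >=
        1e-3, logical(1))
    if (any(ok)) { oracleSize <- k; break }
  }
  expect_equal(length(gapfilledReactions(fixed)), oracleSize)
  # infeasible requirement propagates
  tiny <- new("ContextModel", parent = net, kept = "EX_a",
              gapfilled = character(), medium = med, sampleId = "s", group = "g")
  expect_error(gapfillGrowth(tiny, vMin = 1e6), "infeasible")
})
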