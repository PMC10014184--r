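test_that("expression targets scale linearly to the top-expressed reaction", {
  net <- tinyNet()
  sc <- scoreReactions(net, c(g1 = 8, g2 = 2, g3 = 4), tau = 4)
  tgt <- expressionTargets(net, sc)
  expect_equal(tgt[["R1"]], 10)          # e = max  ->  d = upper bound
  expect_equal(tgt[["ALT"]], 10 * 2 / 8)
  expect_false("R2" %in% names(tgt))     # biomass carries no target
  expect_false("TA" %in% names(tgt))     # no GPR
  expect_false(any(grepl("^EX", names(tgt))))
  scZero <- scoreReactions(net, c(g1 = 0, g2 = 0, g3 = 1e-12), tau = 1)
  scZero$expression[] <- 0
  expect_error(expressionTargets(net, scZero), "zero expression")
})

test_that("LAD recovers an attainable flux distribution with zero objective", {
  # three-reaction chain with a target of 2 on the conversion: the whole
  # chain settles at flux 2 (hand-solvable LP)
  net <- chainNet()
  fs <- ladFit(net, c(CONV = 2), medium = c(EX_s = 10), vMin = 1e-3)
  expect_equal(fs@objective, 0, tolerance = 1e-9)
  v <- fs@fluxes
  expect_equal(unname(v[c("UPT", "CONV", "OUT")]), c(2, 2, 2), tolerance = 1e-9)
  expect_equal(unname(v[["EX_s"]]), -2, tolerance = 1e-9)
  # attainable targets on the toy network: fluxes from a growth solution
  net2 <- toyNet()
  med <- defaultMedium(net2)
  ref <- optimizeGrowth(net2, med)
  rxn <- reactions(net2)
  targeted <- setdiff(rxn$id[nzchar(rxn$gpr)],
                      c(exchangeReactions(net2), biomassReaction(net2)))
  fs2 <- ladFit(net2, ref@fluxes[targeted], medium = med)
  expect_equal(fs2@objective, 0, tolerance = 1e-8)
})

test_that("LAD solutions are steady-state, within bounds and optimal", {
  net <- toyNet()
  med <- defaultMedium(net)
  sim <- toySim(1)
  sc <- scoreReactions(net, sampleExpression(sim$proteome)[["AD_VEH_2"]])
  tgt <- expressionTargets(net, sc)
  fs <- ladFit(net, tgt, medium = med)
  v <- fs@fluxes
  S <- as.matrix(stoichiometry(net))
  expect_lt(max(abs(S %*% v)), 1e-6)
  bnd <- bounds(net)
  expect_true(all(v >= bnd[, "lower"] - 1e-9 & v <= bnd[, "upper"] + 1e-9))
  expect_gte(v[[biomassReaction(net)]], 1e-3 - 1e-9)
  # no feasible point beats the returned objective (random feasible probes
  # built from growth solutions under perturbed bound boxes)
  obj <- function(v) sum(abs(v[names(tgt)] - tgt))
  expect_equal(fs@objective, obj(v), tolerance = 1e-9)
  set.seed(1)
  for (rep in 1:100) {
    probe <- .randomFeasiblePoint(net, med, seed = rep)
    expect_gte(obj(probe) + 1e-9, fs@objective)
  }
})

test_that("flux-sums satisfy the production/turnover identities", {
  # linear chain at flux 1: every interior metabolite has flux-sum 1
  net <- chainNet()
  fs <- ladFit(net, c(CONV = 1), medium = c(EX_s = 10), vMin = 1e-3)
  phi <- fluxSum(net, fs)
  expect_equal(unname(phi[c("s_c", "p_c")]), c(1, 1), tolerance = 1e-9)
  # branch point: productions 2 and 3 into one metabolite add up
  netT <- tinyNet()
  vv <- stats::setNames(c(-5, 5, 2, 3, 5, 5, 5), reactions(netT)$id)
  fsT <- new("FluxState", fluxes = vv, objective = 0, status = "optimal")
  phiT <- fluxSum(netT, fsT)
  expect_equal(phiT[["b_c"]], 5)
  # identity Phi = 0.5 * sum |S_ij v_j| on a fixture model
  net2 <- toyNet()
  med <- defaultMedium(net2)
  sim <- toySim(2)
  sc <- scoreReactions(net2, sampleExpression(sim$proteome)[["AD_VEH_1"]])
  fs2 <- ladFit(net2, expressionTargets(net2, sc), medium = med)
  phi2 <- fluxSum(net2, fs2)
  S <- as.matrix(stoichiometry(net2))
  half <- 0.5 * rowSums(abs(S * rep(fs2@fluxes, each = nrow(S))))
  expect_equal(unname(phi2), unname(half), tolerance = 1e-9)
  expect_true(all(phi2 >= 0))
  # zero (to solver tolerance) exactly for metabolites with no flux through
  # any incident reaction
  carriers <- rowSums(abs(S * rep(fs2@fluxes, each = nrow(S)))) > 1e-9
  expect_identical(unname(phi2 > 1e-9), unname(carriers))
})

test_that("a non-steady-state flux vector is rejected", {
  net <- chainNet()
  bad <- new("FluxState",
             fluxes = stats::setNames(c(0, 1, 0, 0, 0), reactions(net)$id),
             objective = 0, status = "optimal")
  expect_error(fluxSum(net, bad), "steady state")
})

test_that("scaling bounds and targets scales fluxes and flux-sums", {
  c10 <- 10
  net <- chainNet()
  rx <- net@reactions
  rx$lower <- rx$lower * c10; rx$upper <- rx$upper * c10
  attr(net, "reactions") <- rx
  fsBig <- ladFit(net, c(CONV = 2 * c10), medium = c(EX_s = 10 * c10), vMin = 1e-3)
  fsRef <- ladFit(chainNet(), c(CONV = 2), medium = c(EX_s = 10), vMin = 1e-3)
  expect_equal(fsBig@fluxes, fsRef@fluxes * c10, tolerance = 1e-8)
  expect_equal(fluxSum(net, fsBig), fluxSum(chainNet(), fsRef) * c10,
               tolerance = 1e-8)
})

test_that("the LAD objective is invariant to reaction order", {
  net <- toyNet()
  med <- defaultMedium(net)
  sim <- toySim(1)
  sc <- scoreReactions(net, sampleExpression(sim$proteome)[["WT_VEH_2"]])
  tgt <- expressionTargets(net, sc)
  fs1 <- ladFit(net, tgt, medium = med)
  perm <- rev(seq_len(nrow(reactions(net))))
  net2 <- new("MetabolicNetwork",
              metabolites = net@metabolites,
              reactions = net@reactions[perm, , drop = FALSE],
              stoichiometry = net@stoichiometry[, perm, drop = FALSE],
              biomassId = net@biomassId, exchangeIds = net@exchangeIds)
  fs2 <- ladFit(net2, tgt, medium = med)
  expect_equal(fs2@objective, fs1@objective, tolerance = 1e-9)
})
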