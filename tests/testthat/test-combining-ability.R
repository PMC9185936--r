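test_that("degrees of freedom match the balanced closed forms", {
  cfg <- scaleFreeConfig(nLines = 2, envInfested = 0, envNonInfested = 2)
  sim <- simulateTrial(cfg, seed = 2)
  an <- anovaLineByTester(sim$trial, "grain_yield", "non_infested")
  tab <- as.data.frame(an)
  df <- setNames(tab$df, tab$source)
  expect_equal(df[["line_gca"]], 1)
  expect_equal(df[["tester_gca"]], 1)
  expect_equal(df[["line_x_tester_sca"]], 1)
  expect_equal(df[["hybrid"]], 3)
  expect_equal(df[["environment"]], 1)
  expect_equal(df[["hybrid_x_env"]], 3)
  # error df closed form: df over the disjoint sources sums to N - 1
  # (the hybrid and hybrid-x-env rows aggregate their partitions)
  disjoint <- !tab$source %in% c("hybrid", "hybrid_x_env")
  expect_equal(sum(tab$df[disjoint]), nrow(records(sim$trial)[
    records(sim$trial)$condition == "non_infested" &
      records(sim$trial)$entry_role == "testcross", ]) - 1)
  expect_true(an@balanced)
})

test_that("zero SCA and zero noise give exactly zero SCA sum of squares", {
  td <- balancedTrial(cellFun = function(l, t)
    100 + 10 * (l == "L1") - 10 * (l == "L3") + 5 * (t == "T1"))
  an <- anovaLineByTester(td, "grain_yield", "non_infested")
  tab <- as.data.frame(an)
  expect_equal(tab$ss[tab$source == "line_x_tester_sca"], 0,
               tolerance = 1e-8)
})

test_that("every sequential SS equals the nested-regression oracle", {
  set.seed(77)
  for (case in 1:4) {
    l <- sample(3:6, 1); e <- sample(2:3, 1)
    lines <- paste0("L", seq_len(l))
    envs <- paste0("E", seq_len(e))
    td <- balancedTrial(lines = lines, envs = envs, reps = 2,
                        cellFun = function(l, t) rnorm(1, 100, 10),
                        envEff = setNames(rnorm(e, 0, 5), envs),
                        noiseSd = 3)
    an <- anovaLineByTester(td, "grain_yield", "non_infested")
    tab <- as.data.frame(an)
    orc <- anovaOracleSS(td)
    pick <- function(s) tab$ss[tab$source == s]
    expect_equal(pick("environment"), unname(orc$ss[["env"]]),
                 tolerance = 1e-8)
    expect_equal(pick("line_gca"), unname(orc$ss[["line"]]),
                 tolerance = 1e-8)
    expect_equal(pick("tester_gca"), unname(orc$ss[["tester"]]),
                 tolerance = 1e-8)
    expect_equal(pick("line_x_tester_sca"),
                 unname(orc$ss[["line:tester"]]), tolerance = 1e-8)
    expect_equal(pick("line_x_env"), unname(orc$ss[["env:line"]]),
                 tolerance = 1e-8)
    expect_equal(pick("tester_x_env"), unname(orc$ss[["env:tester"]]),
                 tolerance = 1e-8)
    expect_equal(pick("line_x_tester_x_env"),
                 unname(orc$ss[["env:line:tester"]]), tolerance = 1e-8)
    expect_equal(pick("error"), unname(orc$ss[["Residuals"]]),
                 tolerance = 1e-8)
    # balanced additivity of the hybrid partition
    expect_equal(pick("hybrid"),
                 pick("line_gca") + pick("tester_gca") +
                   pick("line_x_tester_sca"), tolerance = 1e-8)
  }
})

test_that("an incomplete core warns and falls back to least squares", {
  td <- balancedTrial(noiseSd = 1, cellFun = function(l, t) 100)
  rec <- records(td)
  rec$grain_yield[1] <- NA
  td2 <- TrialData(rec, trialDesign(td))
  expect_warning(an <- anovaLineByTester(td2, "grain_yield",
                                         "non_infested"),
                 "not balanced")
  expect_false(an@balanced)
})

test_that("an additive 2x2 mean table yields the textbook effects", {
  td <- balancedTrial(lines = c("L1", "L2"), envs = "E1", reps = 2,
                      cellFun = function(l, t)
                        c("L1:T1" = 10, "L1:T2" = 12, "L2:T1" = 14,
                          "L2:T2" = 16)[[paste(l, t, sep = ":")]])
  ca <- suppressMessages(
    estimateGcaSca(td, "grain_yield", "non_infested"))
  expect_equal(gcaLine(ca), c(L1 = -2, L2 = 2))
  expect_equal(gcaTester(ca), c(T1 = -1, T2 = 1))
  expect_equal(max(abs(scaEffects(ca))), 0, tolerance = 1e-12)
  expect_equal(hsgcaEffects(ca)["L1", "T1"], -2)
})

test_that("centering identities and two-tester antisymmetry always hold", {
  set.seed(13)
  for (case in 1:5) {
    l <- sample(3:8, 1)
    td <- balancedTrial(lines = paste0("L", seq_len(l)),
                        cellFun = function(l, t) rnorm(1, 100, 20),
                        noiseSd = 5)
    ca <- estimateGcaSca(td, "grain_yield", "non_infested")
    expect_equal(sum(gcaLine(ca)), 0, tolerance = 1e-9)
    expect_equal(sum(gcaTester(ca)), 0, tolerance = 1e-9)
    expect_equal(max(abs(rowSums(scaEffects(ca)))), 0, tolerance = 1e-9)
    expect_equal(max(abs(colSums(scaEffects(ca)))), 0, tolerance = 1e-9)
    expect_equal(gcaTester(ca)[[1]], -gcaTester(ca)[[2]],
                 tolerance = 1e-9)
    expect_equal(hsgcaEffects(ca),
                 sweep(scaEffects(ca), 1, -gcaLine(ca)), tolerance = 1e-9)
  }
  # degenerate all-equal data keep the identities without NaN
  td0 <- balancedTrial(cellFun = function(l, t) 100)
  ca0 <- estimateGcaSca(td0, "grain_yield", "non_infested")
  expect_equal(unname(gcaLine(ca0)), rep(0, 3))
  expect_equal(max(abs(scaEffects(ca0))), 0)
})

test_that("noise-free simulated effects are recovered exactly", {
  cfg <- scaleFreeConfig(nLines = 5, envInfested = 0, envNonInfested = 3,
                         sigma2Error = 0)
  sim <- simulateTrial(cfg, seed = 31)
  ca <- estimateGcaSca(sim$trial, "grain_yield", "non_infested")
  expect_equal(gcaLine(ca), sim$truth$gcaLine, tolerance = 1e-9)
  expect_equal(gcaTester(ca), sim$truth$gcaTester, tolerance = 1e-9)
  expect_equal(scaEffects(ca), sim$truth$sca, tolerance = 1e-9)
})

test_that("standard errors follow the Kempthorne forms and flag zero df", {
  sim <- simulateTrial(trialSimConfig(nLines = 4), seed = 15)
  an <- anovaLineByTester(sim$trial, "grain_yield", "non_infested")
  tab <- as.data.frame(an)
  mse <- tab$ms[tab$source == "error"]
  ca <- estimateGcaSca(sim$trial, "grain_yield", "non_infested")
  r <- an@nRep; e <- an@nEnv
  expect_equal(ca@seGcaLine, sqrt(mse / (r * e * 2)))
  expect_equal(ca@seGcaTester, sqrt(mse / (r * e * 4)))
  expect_equal(ca@seSca, sqrt(mse / (r * e)))
})

test_that("variance components truncate at zero and shrink h2 with noise", {
  # mean squares built so every component except the error stays constant
  # as msErr varies; MS_lt = MS_lte is the null SCA case
  mkAnova <- function(msErr) {
    ms <- c(environment = 100 * msErr, rep_in_env = 5 * msErr,
            block_in_rep_env = 2 * msErr,
            line_x_env = msErr + 14, tester_x_env = msErr + 18,
            line_x_tester_x_env = msErr + 20, error = msErr)
    ms[["line_gca"]] <- ms[["line_x_env"]] + 56          # s2_gl = 3.5
    ms[["tester_gca"]] <- ms[["tester_x_env"]] + 172     # s2_gt = 172/192
    ms[["line_x_tester_sca"]] <- ms[["line_x_tester_x_env"]]
    ms[["hybrid_x_env"]] <- msErr + 16
    ms[["hybrid"]] <- ms[["hybrid_x_env"]] + 40
    src <- c("environment", "rep_in_env", "block_in_rep_env", "hybrid",
             "line_gca", "tester_gca", "line_x_tester_sca",
             "hybrid_x_env", "line_x_env", "tester_x_env",
             "line_x_tester_x_env", "error")
    df <- c(3, 4, 96, 51, 23, 1, 23, 153, 69, 3, 69, 108)
    tab <- data.frame(source = src, df = df, ss = ms[src] * df,
                      ms = unname(ms[src]), f = NA_real_, p = NA_real_)
    new("AnovaTable", table = tab, trait = "grain_yield",
        condition = "infested", balanced = TRUE, nLines = 24L,
        nTesters = 2L, nEnv = 4L, nRep = 2L)
  }
  des <- LxTDesign(sprintf("L%02d", 1:24), c("T1", "T2"))
  vc <- suppressWarnings(estimateVarianceComponents(mkAnova(10), des))
  comp <- varianceComponents(vc)
  expect_equal(comp[["sigma2_sca"]], 0)  # MS_lt = MS_lte null case
  expect_equal(comp[["sigma2_gca_line"]], 56 / (2 * 4 * 2))
  expect_equal(comp[["sigma2_gca_tester"]], 172 / (2 * 4 * 24))
  expect_equal(comp[["sigma2_A"]],
               2 * (comp[["sigma2_gca_line"]] +
                      comp[["sigma2_gca_tester"]]))
  expect_true(comp[["h2_narrow"]] >= 0 && comp[["h2_narrow"]] <= 1)

  # a negative solution is truncated and flagged
  badTab <- as.data.frame(mkAnova(10))
  badTab$ms[badTab$source == "line_gca"] <- 1   # below MS_line_x_env
  badAn <- new("AnovaTable", table = badTab, trait = "grain_yield",
               condition = "infested", balanced = TRUE, nLines = 24L,
               nTesters = 2L, nEnv = 4L, nRep = 2L)
  vcBad <- estimateVarianceComponents(badAn, des)
  expect_equal(varianceComponents(vcBad)[["sigma2_gca_line"]], 0)
  expect_true("sigma2_gca_line" %in% vcBad@truncated)

  # increasing error variance strictly decreases h2, all else fixed
  h2 <- sapply(c(5, 10, 20, 40), function(m)
    varianceComponents(suppressWarnings(
      estimateVarianceComponents(mkAnova(m), des)))[["h2_narrow"]])
  expect_true(all(diff(h2) < 0))
})

test_that("repeatability hits its null and perfect limits", {
  tab <- data.frame(
    source = c("hybrid", "hybrid_x_env", "error"),
    df = c(51, 153, 108), ss = NA_real_,
    ms = c(40, 40, 10), f = NA_real_, p = NA_real_)
  tab$ss <- tab$ms * tab$df
  an <- new("AnovaTable", table = tab, trait = "grain_yield",
            condition = "infested", balanced = TRUE, nLines = 24L,
            nTesters = 2L, nEnv = 4L, nRep = 2L)
  des <- LxTDesign(sprintf("L%02d", 1:24), c("T1", "T2"))
  expect_equal(repeatability(an, des), 0)      # MS_h = MS_hxe

  tab$ms <- c(1000, 1e-6, 1e-6)
  tab$ss <- tab$ms * tab$df
  an2 <- new("AnovaTable", table = tab, trait = "grain_yield",
             condition = "infested", balanced = TRUE, nLines = 24L,
             nTesters = 2L, nEnv = 4L, nRep = 2L)
  expect_gt(repeatability(an2, des), 0.999)    # vanishing noise limit
})

test_that("repeatability on simulated trials matches the plug-in truth", {
  # entry-mean repeatability under known components, complete blocks
  cfg <- scaleFreeConfig(nLines = 10, envInfested = 0, envNonInfested = 3,
                         blockSize = 24)
  e <- 3; r <- 2; l <- 10; t <- 2
  # expected among-hybrid component in the crossed design: the SS over
  # entry means decomposes as t*Sum(g_i^2) + l*Sum(g_j^2) + Sum(s_ij^2),
  # with expectations sigma2*(factor df) for the centered draws
  s2h <- (t * (l - 1) * 1 + l * (t - 1) * 1 +
            (l - 1) * (t - 1) * 0.25) / (l * t - 1)
  trueR <- s2h / (s2h + 1 / (r * e))
  Rs <- sapply(1:60, function(i) {
    sim <- simulateTrial(cfg, seed = 1000 + i)
    an <- anovaLineByTester(sim$trial, "grain_yield", "non_infested")
    repeatability(an, trialDesign(sim$trial))
  })
  expect_lt(abs(mean(Rs) - trueR), 0.05)
})
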