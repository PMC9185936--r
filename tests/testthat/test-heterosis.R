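test_that("standard heterosis arithmetic and identities", {
  expect_equal(standardHeterosis(1000, 1000), 0)
  expect_equal(standardHeterosis(1210, 1000), 21)
  expect_equal(standardHeterosis(950, 1000), -5)
  expect_error(standardHeterosis(100, 0), "non-zero")
  # gain of x mirrors a loss of x
  ck <- 1234
  for (x in c(0.05, 0.2, 0.5))
    expect_equal(standardHeterosis(ck * (1 + x), ck),
                 -standardHeterosis(ck * (1 - x), ck))
})

test_that("yield loss percent and the gain flag", {
  expect_equal(as.numeric(yieldLoss(5000, 1000)), 80)
  expect_equal(as.numeric(yieldLoss(3000, 3000)), 0)
  g <- yieldLoss(2000, 2500)
  expect_lt(as.numeric(g), 0)
  expect_true(attr(g, "gain"))
  expect_error(yieldLoss(0, 100), "positive")
})

test_that("SCA+yield classifier applies its three gates", {
  sca <- rbind(A = c(300, -300), B = c(50, -50), C = c(300, -300),
               D = c(-250, 250))
  colnames(sca) <- c("T1", "T2")
  means <- rbind(A = c(5000, 4000), B = c(5000, 4000), C = c(3000, 4000),
                 D = c(4000, 5100))
  colnames(means) <- c("T1", "T2")
  ca <- new("CombiningAbility", trait = "grain_yield",
            condition = "infested",
            gcaLine = setNames(rep(0, 4), rownames(sca)),
            gcaTester = c(T1 = 0, T2 = 0), sca = sca, hsgca = sca,
            seGcaLine = 1, seGcaTester = 1, seSca = 1,
            pGcaLine = setNames(rep(NA_real_, 4), rownames(sca)),
            pGcaTester = c(T1 = NA_real_, T2 = NA_real_),
            pSca = sca * NA_real_, mse = 1, errorDf = 10)
  asg <- assignGroupsScaYield(ca, means, ckMean = 5000, lsd = 500)
  grp <- setNames(asg$group, asg$line)
  expect_equal(grp[["A"]], "HGB")          # +300 with T1, yield at ck
  expect_equal(grp[["B"]], "unassigned")   # below the 100 kg/ha threshold
  expect_equal(grp[["C"]], "unassigned")   # yield gate: ck - 2*lsd
  expect_equal(asg$reason[asg$line == "C"], "yield gate failed")
  expect_equal(grp[["D"]], "HGA")          # favourable with T2
})

test_that("hsgca equals tester-mean subtraction on balanced tables", {
  set.seed(5)
  td <- balancedTrial(lines = paste0("L", 1:3),
                      cellFun = function(l, t) rnorm(1, 100, 15),
                      noiseSd = 2)
  ca <- estimateGcaSca(td, "grain_yield", "non_infested")
  m <- testcrossMeanMatrix(td, "grain_yield", "non_infested")
  expect_equal(hsgcaEffects(ca), sweep(m, 2, colMeans(m)),
               tolerance = 1e-12)
  # all-equal yields: all HSGCA zero
  td0 <- balancedTrial(cellFun = function(l, t) 42)
  expect_equal(max(abs(hsgcaEffects(
    estimateGcaSca(td0, "grain_yield", "non_infested")))), 0)
})

test_that("HSGCA classifier sign rules and tie-breaks", {
  h <- rbind(A = c(200, -150),   # positive with T1 only -> HGB
             B = c(-100, 80),    # positive with T2 only -> HGA
             C = c(50, 200),     # both positive, min at T1 -> HGB
             D = c(-20, -300),   # both negative, min at T2 -> HGA
             E = c(NA, 100))
  colnames(h) <- c("T1", "T2")
  asg <- assignGroupsHsgca(h)
  grp <- setNames(asg$group, asg$line)
  expect_equal(unname(grp[c("A", "B", "C", "D", "E")]),
               c("HGB", "HGA", "HGB", "HGA", "unassigned"))
  expect_match(asg$reason[asg$line == "E"], "missing")

  # alternative reading: largest value decides for shared-sign pairs
  asgMax <- assignGroupsHsgca(h, tieRule = "max_value")
  grpMax <- setNames(asgMax$group, asgMax$line)
  expect_equal(unname(grpMax[c("C", "D")]), c("HGA", "HGB"))

  # dead zone turns near-zero evidence into no call
  h2 <- rbind(F = c(0.5, -0.2))
  colnames(h2) <- c("T1", "T2")
  expect_equal(assignGroupsHsgca(h2, epsilon = 1)$group, "unassigned")
})

test_that("relabeling invariance: swapping testers swaps the groups", {
  set.seed(8)
  h <- matrix(rnorm(12, 0, 100), 6, 2,
              dimnames = list(paste0("L", 1:6), c("T1", "T2")))
  a1 <- assignGroupsHsgca(h)
  swapped <- h[, 2:1]
  colnames(swapped) <- c("T1", "T2")   # roles swapped under same labels
  a2 <- assignGroupsHsgca(swapped)
  flip <- c(HGA = "HGB", HGB = "HGA", unassigned = "unassigned")
  expect_equal(unname(flip[a1$group]), a2$group)
  # line order permutation does not change per-line calls
  perm <- sample(nrow(h))
  a3 <- assignGroupsHsgca(h[perm, ])
  expect_equal(setNames(a3$group, a3$line)[a1$line],
               setNames(a1$group, a1$line))
})

test_that("consensus requires agreement among assigned calls", {
  mk <- function(line, groups)
    data.frame(line = line, method = "hsgca",
               condition = c("infested", "non_infested", "across_mtl"),
               group = groups)
  asg <- rbind(mk("A", c("HGB", "HGB", "HGB")),
               mk("B", c("HGB", "HGA", "HGB")),
               mk("C", c("HGB", "unassigned", "HGB")),
               mk("D", rep("unassigned", 3)))
  cons <- consensusGroups(asg)
  out <- setNames(cons$consensus, cons$line)
  expect_equal(unname(out[c("A", "B", "C", "D")]),
               c("HGB", "inconsistent", "HGB", "unassigned"))
  expect_equal(cons$n_assigned[cons$line == "C"], 2)
})

test_that("two-tester centering collapses the SCA sign condition", {
  sim <- simulateTrial(trialSimConfig(nLines = 6), seed = 12)
  ca <- estimateGcaSca(sim$trial, "grain_yield", "infested")
  sca <- scaEffects(ca)
  expect_equal(sca[, 1], -sca[, 2], tolerance = 1e-9)
})

test_that("heterosisTable measures every entry against the tester cross", {
  sim <- simulateTrial(trialSimConfig(nLines = 4), seed = 19)
  het <- heterosisTable(sim$trial, "grain_yield", "non_infested")
  cm <- cellMeans(sim$trial, "grain_yield", "non_infested")
  ck <- cm$mean[cm$entry == "TCROSS"]
  expect_equal(het$h_percent, 100 * (het$f1 - ck) / ck)
  expect_false("TCROSS" %in% het$entry)
})
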