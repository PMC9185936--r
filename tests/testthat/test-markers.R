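panelFromMatrix <- function(d) {
  GenotypePanel(d, chromosome = rep(1, nrow(d)),
                position = seq_len(nrow(d)))
}

test_that("QC filter removes markers per criterion and reports counts", {
  # marker 1: 3/26 missing (11.5% > 10%); marker 2: monomorphic;
  # marker 3: 30% heterozygous; marker 4: clean
  set.seed(1)
  n <- 26
  clean <- function() sample(c(0, 2), n, replace = TRUE)
  m1 <- clean(); m1[1:3] <- NA
  m2 <- rep(2, n)
  m3 <- clean(); m3[1:8] <- 1
  m4 <- clean()
  d <- rbind(M1 = m1, M2 = m2, M3 = m3, M4 = m4)
  colnames(d) <- paste0("S", 1:n)
  f <- filterMarkers(panelFromMatrix(d))
  expect_equal(rownames(f), "M4")
  rep <- qcReport(f)
  expect_equal(rep$n_failing[rep$criterion == "missing_data"], 1)
  expect_equal(rep$n_failing[rep$criterion == "major_allele_frequency"], 1)
  expect_equal(rep$n_failing[rep$criterion == "heterozygosity"], 1)
  expect_equal(rep$n_failing[rep$criterion == "retained"], 1)
  expect_error(filterMarkers(panelFromMatrix(rbind(M1 = m2))),
               "empty panel")
})

test_that("filtering is order-independent (criteria are conjunctive)", {
  sim <- simulateGenotypes(genoSimConfig(nMarkers = 300,
    qcViolations = c(missing_data = 30, major_allele_frequency = 20,
                     heterozygosity = 10)), seed = 3)
  f1 <- filterMarkers(sim$panel)
  # tightening one threshold only ever removes more markers
  f2 <- filterMarkers(sim$panel, maxMissing = 0.05)
  expect_true(all(rownames(f2) %in% rownames(f1)))
})

test_that("per-marker statistics match their closed forms", {
  # p = 0.5 marker: gene diversity 0.5, PIC 0.375
  d <- rbind(M1 = c(0, 0, 2, 2), M2 = c(2, 2, 2, 2), M3 = c(0, 1, 1, 2))
  colnames(d) <- paste0("S", 1:4)
  st <- markerSummary(panelFromMatrix(d))
  pm <- st@perMarker
  expect_equal(pm$gene_diversity[pm$marker == "M1"], 0.5)
  expect_equal(pm$pic[pm$marker == "M1"], 0.375)
  expect_equal(pm$gene_diversity[pm$marker == "M2"], 0)
  expect_equal(pm$pic[pm$marker == "M2"], 0)
  expect_equal(pm$het_obs[pm$marker == "M3"], 0.5)
})

test_that("PIC equals a brute-force Botstein evaluation panel-wide", {
  sim <- simulateGenotypes(genoSimConfig(nSamples = 20, nMarkers = 50,
    qcViolations = c(missing_data = 0, major_allele_frequency = 0,
                     heterozygosity = 0)), seed = 6)
  st <- markerSummary(sim$panel)
  pm <- st@perMarker
  d <- dosage(sim$panel)
  # independent route: explicit allele counting per marker
  for (i in seq_len(nrow(d))) {
    g <- d[i, ]
    g <- g[!is.na(g)]
    p <- (2 * sum(g == 0) + sum(g == 1)) / (2 * length(g))  # A allele
    q <- 1 - p
    picOracle <- 1 - (p^2 + q^2) - 2 * p^2 * q^2
    expect_equal(pm$pic[i], picOracle, tolerance = 1e-12)
    expect_equal(pm$gene_diversity[i], 2 * p * q, tolerance = 1e-12)
  }
  # Botstein inequality: PIC <= gene diversity <= 0.5
  expect_true(all(pm$pic <= pm$gene_diversity + 1e-12))
  expect_true(all(pm$gene_diversity <= 0.5 + 1e-12))
})

test_that("Jaccard distances match hand-enumerated bit sets", {
  # 3 samples x 4 markers, hand-countable
  d <- rbind(M1 = c(0, 2, 0), M2 = c(1, 1, 0), M3 = c(2, 2, 2),
             M4 = c(0, 0, 1))
  colnames(d) <- c("A", "B", "C")
  jd <- distanceMatrix(jaccardDistance(panelFromMatrix(d)))
  # A vs B: bits A={A}, {AB}, {B}, {A}; B={B},{AB},{B},{A}
  # inter: M1 0, M2 2, M3 1, M4 1 = 4; union: M1 2, M2 2, M3 1, M4 1 = 6
  expect_equal(jd["A", "B"], 1 - 4 / 6)
  # A vs C: inter = 1+1+1+1 = 4; union = 1+2+1+2 = 6
  expect_equal(jd["A", "C"], 1 - 4 / 6)
  expect_equal(diag(jd), c(A = 0, B = 0, C = 0))

  # identical samples at 0; opposite homozygotes at 1
  d2 <- rbind(M1 = c(0, 0, 2), M2 = c(2, 2, 0))
  colnames(d2) <- c("A", "B", "C")
  jd2 <- distanceMatrix(jaccardDistance(panelFromMatrix(d2)))
  expect_equal(jd2["A", "B"], 0)
  expect_equal(jd2["A", "C"], 1)
})

test_that("IBS distance counts shared alleles", {
  d <- rbind(M1 = c(0, 2, 1, 0), M2 = c(0, 2, 1, 0), M3 = c(0, 2, 1, 0))
  colnames(d) <- c("A", "B", "C", "D")
  id <- distanceMatrix(ibsDistance(panelFromMatrix(d)))
  expect_equal(id["A", "B"], 1)    # 0 vs 2 everywhere
  expect_equal(id["A", "C"], 0.5)  # 0 vs 1: one shared allele of two
  expect_equal(id["A", "D"], 0)    # identical
  expect_true(isSymmetric(id))
})

test_that("pairwise-complete handling flags empty pairs", {
  d <- rbind(M1 = c(0, NA), M2 = c(NA, 2))
  colnames(d) <- c("A", "B")
  expect_warning(id <- ibsDistance(panelFromMatrix(d)), "zero co-called")
  expect_true(is.na(distanceMatrix(id)["A", "B"]))
  expect_equal(pairCounts(id)["A", "B"], 0L)
})

test_that("Ward clustering recovers simulated populations exactly", {
  skip_if_not_installed("mclust")
  sim <- simulateGenotypes(genoSimConfig(nMarkers = 600, divergence = 0.45,
    qcViolations = c(missing_data = 0, major_allele_frequency = 0,
                     heterozygosity = 0)), seed = 14)
  wc <- wardCluster(ibsDistance(sim$panel), k = 2)
  expect_equal(mclust::adjustedRandIndex(wc$clusters, sim$labels), 1)
  expect_true(all(diff(wc$tree$height) >= -1e-9))  # monotone merges

  # label permutation invariance
  perm <- sample(ncol(sim$panel))
  wcP <- wardCluster(ibsDistance(sim$panel[, perm]), k = 2)
  expect_equal(mclust::adjustedRandIndex(
    wcP$clusters[colnames(sim$panel)], wc$clusters), 1)
})

test_that("two samples form a single merge", {
  d <- rbind(M1 = c(0, 2), M2 = c(0, 0))
  colnames(d) <- c("A", "B")
  wc <- wardCluster(ibsDistance(panelFromMatrix(d)), k = 2)
  expect_equal(sort(unname(wc$clusters)), c(1, 2))
})

test_that("PCA percent variance behaves as a trace decomposition", {
  sim <- simulateGenotypes(genoSimConfig(nMarkers = 300, divergence = 0.45,
    qcViolations = c(missing_data = 0, major_allele_frequency = 0,
                     heterozygosity = 0)), seed = 23)
  p <- pcaGenotypes(sim$panel)
  expect_equal(sum(p$percentVar), 100, tolerance = 1e-9)
  # PC1 separates the two populations
  r <- cor(p$scores[, 1], as.numeric(sim$labels))
  expect_gt(abs(r), 0.9)

  # two samples: PC1 carries all the nonzero variance
  d <- rbind(M1 = c(0, 2), M2 = c(0, 2), M3 = c(2, 0))
  colnames(d) <- c("A", "B")
  p2 <- pcaGenotypes(panelFromMatrix(d))
  expect_equal(p2$percentVar[1], 100, tolerance = 1e-9)
  expect_error(pcaGenotypes(panelFromMatrix(
    rbind(M1 = c(0, 0), M2 = c(2, 2)))), "zero variance")
})

test_that("silhouette selects the true k and ignores relabeling", {
  sim <- simulateGenotypes(genoSimConfig(nMarkers = 600, divergence = 0.45,
    qcViolations = c(missing_data = 0, major_allele_frequency = 0,
                     heterozygosity = 0)), seed = 31)
  dd <- ibsDistance(sim$panel)
  sil <- silhouetteK(dd)
  expect_equal(sil$k, 2)
  perm <- sample(ncol(sim$panel))
  silP <- silhouetteK(ibsDistance(sim$panel[, perm]))
  expect_equal(silP$k, sil$k)
  expect_equal(sort(silP$scores$mean_silhouette),
               sort(sil$scores$mean_silhouette), tolerance = 1e-9)
  # k >= n candidates are skipped
  small <- sim$panel[, 1:4]
  expect_message(s2 <- silhouetteK(ibsDistance(small), kRange = 2:10),
                 "skipped")
  expect_true(all(s2$scores$k < 4))
})

test_that("distance matrices are valid metrics on random panels", {
  sim <- simulateGenotypes(genoSimConfig(nMarkers = 200,
    qcViolations = c(missing_data = 10, major_allele_frequency = 5,
                     heterozygosity = 5)), seed = 40)
  for (dd in list(jaccardDistance(sim$panel), ibsDistance(sim$panel))) {
    v <- distanceMatrix(dd)
    expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
    expect_equal(v, t(v))
    expect_equal(max(abs(diag(v))), 0)
  }
})
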