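#' Derive a named sub-stream seed from a master seed
#'
#' A single integer seed drives named hierarchical streams (`"trial"`,
#' `"genotypes"`, ...) so sub-experiments are independently reproducible:
#' the stream seed is `(seed * 69069 + weighted utf8 sum of the name)`
#' modulo 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stream stream name.
#' @return an integer seed.
#' @export
streamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) %% 2147483647 * 69069 + h) %% 2147483647)
}

# draw iid effects and center so the identifiability constraints hold
# exactly; expected mean squares are unchanged because the ANOVA sums of
# squares carry the same degrees of freedom either way
.drawCentered <- function(n, sigma2, names = NULL) {
  x <- rnorm(n, 0, sqrt(sigma2))
  x <- x - mean(x)
  if (!is.null(names)) names(x) <- names
  x
}

.drawDoubleCentered <- function(rn, cn, sigma2) {
  m <- matrix(rnorm(length(rn) * length(cn), 0, sqrt(sigma2)),
              length(rn), length(cn), dimnames = list(rn, cn))
  sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
}

#' Configuration for the trial simulator
#'
#' Defaults emulate a 24-line x 2-tester factorial plus 4 check hybrids
#' (including the tester-cross) laid out as a 13 x 4 alpha-lattice with 2
#' replications, over 4 infested and 6 non-infested location-year
#' environments. Variance defaults (kg/ha squared for grain yield) are of
#' the magnitude seen in multi-environment West African testcross trials
#' with non-infested yields near 5.3 t/ha. The damage-to-yield-loss link is
#' a logistic through two calibration points so that a susceptible check
#' (damage 8) loses ~80% of its yield and the tester-cross (damage 4) ~31%.
#'
#' @param nLines,nTesters numbers of candidate lines and testers.
#' @param envInfested,envNonInfested environments per condition.
#' @param replicates replications per environment.
#' @param latticeBlocks,blockSize incomplete-block layout per replicate
#'   (`NULL` latticeBlocks = smallest feasible); entries must fit,
#'   `latticeBlocks * blockSize >= nLines*nTesters + 4`.
#' @param muYield non-infested grand mean grain yield (kg/ha); infested
#'   yields arise by applying the damage-dependent loss.
#' @param sigma2GcaLine,sigma2GcaTester,sigma2Sca genetic variances.
#' @param sigma2Env,sigma2Rep,sigma2Block design-effect variances.
#' @param sigma2LineEnv,sigma2TesterEnv,sigma2ScaEnv G x E variances.
#' @param sigma2Error plot residual variance.
#' @param damageMu,damageSd mean and sd of the latent damage score (1-9
#'   scale) for testcrosses.
#' @param damageBeta damage shift per -1000 kg/ha of line GCA (susceptible
#'   lines score higher).
#' @param countMu,countBeta,countDispersion negative-binomial emerged-
#'   parasite counts: mean `countMu * exp(countBeta * (-gca_line/1000))`,
#'   dispersion (size) `countDispersion`. The distributional form is a
#'   stand-in; field counts are only known to be overdispersed.
#' @param lossCalibration 2 x 2 matrix, each row (damage score, yield-loss
#'   fraction), defining the logistic damage-to-loss link.
#' @param checkMeans,checkDamage named non-infested yield means and damage
#'   levels for the checks `tester_cross`, `tolerant`, `susceptible`,
#'   `resistant`.
#' @return a validated config (list with class `TrialSimConfig`).
#' @export
trialSimConfig <- function(nLines = 24, nTesters = 2,
                           envInfested = 4, envNonInfested = 6,
                           replicates = 2, latticeBlocks = NULL,
                           blockSize = 4,
                           muYield = 5300,
                           sigma2GcaLine = 96000, sigma2GcaTester = 380000,
                           sigma2Sca = 49000,
                           sigma2Env = 500000, sigma2Rep = 30000,
                           sigma2Block = 20000,
                           sigma2LineEnv = 150000, sigma2TesterEnv = 60000,
                           sigma2ScaEnv = 50000,
                           sigma2Error = 1e6,
                           damageMu = 5, damageSd = 1,
                           damageBeta = 1.5,
                           countMu = 12, countBeta = 0.4,
                           countDispersion = 2,
                           lossCalibration = rbind(c(8, 0.80), c(4, 0.31)),
                           checkMeans = c(tester_cross = 5200,
                                          tolerant = 4800,
                                          susceptible = 4600,
                                          resistant = 5000),
                           checkDamage = c(tester_cross = 4.0,
                                           tolerant = 6.1,
                                           susceptible = 8.0,
                                           resistant = 4.7)) {
  cfg <- as.list(environment())
  vars <- grep("^sigma2", names(cfg), value = TRUE)
  if (any(unlist(cfg[vars]) < 0)) stop("variances must be non-negative")
  nEntries <- nLines * nTesters + length(checkMeans)
  if (is.null(cfg$latticeBlocks))
    cfg$latticeBlocks <- ceiling(nEntries / blockSize)
  if (nEntries > cfg$latticeBlocks * blockSize)
    stop("infeasible lattice: ", nEntries, " entries exceed ",
         cfg$latticeBlocks, " blocks x ", blockSize)
  stopifnot(nLines >= 2, nTesters >= 2, replicates >= 1,
            envInfested >= 1 || envNonInfested >= 1)
  class(cfg) <- c("TrialSimConfig", "list")
  cfg
}

.lossLink <- function(calib) {
  d <- calib[, 1]; l <- calib[, 2]
  b <- (stats::qlogis(l[1]) - stats::qlogis(l[2])) / (d[1] - d[2])
  a <- stats::qlogis(l[1]) - b * d[1]
  function(damage) stats::plogis(a + b * damage)
}

#' Simulate a multi-environment line x tester trial
#'
#' Plot values follow `y = mu + env + rep(env) + block + g_line + g_tester
#' + sca + line:env + tester:env + sca:env + error`; main effects and SCA
#' are drawn iid from the configured variances and centered within factor
#' (SCA double-centered), G x E draws are centered within environment, so
#' the identifiability constraints of the estimators hold exactly and the
#' expected-mean-square expectations match the restricted mixed-model
#' convention. Under infestation each plot's damage score (discretised
#' latent normal clamped to 1-9, shifted against line GCA) drives a
#' multiplicative yield loss through the calibrated logistic link, and
#' emerged-parasite counts are negative binomial with line-level
#' susceptibility tied to `-gca_line`. Checks come from fixed configured
#' means. Secondary agronomic traits (flowering, heights, aspects) are
#' generated with modest line effects so every declared trait column is
#' populated.
#'
#' The truth list records every random draw plus the implied (centered)
#' effect tables, so estimators can be audited end to end; runs with equal
#' seeds are bit-identical.
#'
#' @param cfg a [trialSimConfig()] configuration.
#' @param seed integer master seed (stream `"trial"` is derived from it).
#' @return list with `trial` (a [TrialData-class]) and `truth`.
#' @examples
#' sim <- simulateTrial(trialSimConfig(nLines = 4), seed = 42)
#' sim$trial
#' @export
simulateTrial <- function(cfg = trialSimConfig(), seed = 1) {
  stopifnot(inherits(cfg, "TrialSimConfig"))
  set.seed(streamSeed(seed, "trial"))
  lines <- sprintf("L%02d", seq_len(cfg$nLines))
  testers <- paste0("T", seq_len(cfg$nTesters))
  checkIds <- c(tester_cross = "TCROSS", tolerant = "CK-TOL",
                susceptible = "CK-SUS", resistant = "CK-RES")
  checkIds <- checkIds[names(cfg$checkMeans)]
  tcEntries <- testcrossEntries(lines, testers)
  entries <- c(tcEntries, unname(checkIds))

  envs <- list(
    infested = if (cfg$envInfested > 0)
      sprintf("INF-E%d", seq_len(cfg$envInfested)) else character(),
    non_infested = if (cfg$envNonInfested > 0)
      sprintf("NON-E%d", seq_len(cfg$envNonInfested)) else character())
  allEnvs <- unlist(envs, use.names = FALSE)

  gLine <- .drawCentered(cfg$nLines, cfg$sigma2GcaLine, lines)
  gTester <- .drawCentered(cfg$nTesters, cfg$sigma2GcaTester, testers)
  sca <- .drawDoubleCentered(lines, testers, cfg$sigma2Sca)
  envEff <- setNames(rnorm(length(allEnvs), 0, sqrt(cfg$sigma2Env)),
                     allEnvs)
  lineEnv <- sapply(allEnvs, function(e)
    .drawCentered(cfg$nLines, cfg$sigma2LineEnv, lines))
  testerEnv <- sapply(allEnvs, function(e)
    .drawCentered(cfg$nTesters, cfg$sigma2TesterEnv, testers))
  scaEnv <- lapply(setNames(allEnvs, allEnvs), function(e)
    .drawDoubleCentered(lines, testers, cfg$sigma2ScaEnv))

  loss <- .lossLink(cfg$lossCalibration)
  # modest secondary-trait parameters (line-effect sd, residual sd, mean)
  secondary <- list(
    days_anthesis = c(gsd = 1.2, esd = 1.4, mu = 58),
    days_silking = c(gsd = 1.3, esd = 1.5, mu = 60.5),
    plant_height = c(gsd = 7, esd = 11, mu = 190),
    ear_height = c(gsd = 5, esd = 7, mu = 100),
    ear_aspect = c(gsd = 0.18, esd = 0.3, mu = 2.8),
    plant_aspect = c(gsd = 0.18, esd = 0.3, mu = 2.9))
  secEff <- lapply(secondary, function(p)
    list(line = .drawCentered(cfg$nLines, p[["gsd"]]^2, lines),
         tester = .drawCentered(cfg$nTesters, (p[["gsd"]] / 2)^2, testers)))

  condTraits <- list(
    infested = c("grain_yield", "striga_damage", "striga_count",
                 "days_anthesis", "days_silking", "plant_height",
                 "ear_aspect"),
    non_infested = c("grain_yield", "days_anthesis", "days_silking",
                     "plant_height", "ear_height", "ear_aspect",
                     "plant_aspect"))
  allTraits <- unique(unlist(condTraits))

  rows <- list()
  blockDraws <- list()
  for (cond in names(envs)) {
    for (env in envs[[cond]]) {
      for (repi in seq_len(cfg$replicates)) {
        perm <- sample(entries)
        nb <- cfg$latticeBlocks
        blockIdx <- rep(seq_len(nb), each = cfg$blockSize)[
          seq_along(perm)]
        blockLab <- sprintf("B%02d", blockIdx)
        bEff <- setNames(rnorm(nb, 0, sqrt(cfg$sigma2Block)),
                         sprintf("B%02d", seq_len(nb)))
        blockDraws[[paste(env, repi, sep = "/")]] <- bEff
        repEff <- rnorm(1, 0, sqrt(cfg$sigma2Rep))
        isTC <- perm %in% tcEntries
        ln <- ifelse(isTC, sub(":.*", "", perm), NA_character_)
        ts <- ifelse(isTC, sub(".*:", "", perm), NA_character_)
        role <- ifelse(isTC, "testcross",
                       ifelse(perm == checkIds[["tester_cross"]],
                              "tester_cross", "check"))
        n <- length(perm)
        base <- cfg$muYield + envEff[[env]] + repEff + bEff[blockIdx]
        gen <- numeric(n)
        gen[isTC] <- gLine[ln[isTC]] + gTester[ts[isTC]] +
          sca[cbind(ln[isTC], ts[isTC])] +
          lineEnv[ln[isTC], env] + testerEnv[ts[isTC], env] +
          scaEnv[[env]][cbind(ln[isTC], ts[isTC])]
        ckRole <- match(perm, checkIds)           # index into check vectors
        gen[!isTC] <- cfg$checkMeans[ckRole[!isTC]] - cfg$muYield
        potential <- base + gen + rnorm(n, 0, sqrt(cfg$sigma2Error))

        df <- data.frame(environment = env, condition = cond,
                         replicate = repi, block = blockLab, entry = perm,
                         entry_role = role, line = ln, tester = ts,
                         stringsAsFactors = FALSE)
        for (tr in allTraits) df[[tr]] <- NA_real_

        if (cond == "infested") {
          latent <- numeric(n)
          latent[isTC] <- cfg$damageMu -
            cfg$damageBeta * (gLine[ln[isTC]] + gTester[ts[isTC]]) / 1000 +
            rnorm(sum(isTC), 0, cfg$damageSd)
          latent[!isTC] <- cfg$checkDamage[ckRole[!isTC]] +
            rnorm(sum(!isTC), 0, cfg$damageSd)
          dmg <- pmin(pmax(round(latent), 1), 9)
          muC <- numeric(n)
          muC[isTC] <- cfg$countMu *
            exp(cfg$countBeta * (-gLine[ln[isTC]]) / 1000)
          muC[!isTC] <- cfg$countMu *
            exp(0.3 * (cfg$checkDamage[ckRole[!isTC]] - cfg$damageMu))
          df$striga_damage <- dmg
          df$striga_count <- rnbinom(n, mu = muC,
                                     size = cfg$countDispersion)
          df$grain_yield <- pmax(potential * (1 - loss(dmg)), 0)
        } else {
          df$grain_yield <- pmax(potential, 0)
        }
        for (tr in intersect(condTraits[[cond]], names(secondary))) {
          p <- secondary[[tr]]
          eff <- numeric(n)
          eff[isTC] <- secEff[[tr]]$line[ln[isTC]] +
            secEff[[tr]]$tester[ts[isTC]]
          v <- p[["mu"]] + eff + rnorm(n, 0, p[["esd"]])
          if (tr %in% c("ear_aspect", "plant_aspect"))
            v <- pmin(pmax(round(v * 2) / 2, 1), 5)
          if (grepl("^days", tr)) v <- round(v)
          df[[tr]] <- v
        }
        rows[[length(rows) + 1]] <- df
      }
    }
  }
  rec <- do.call(rbind, rows)
  design <- LxTDesign(lines, testers, checks = unname(checkIds),
                      testerCross = checkIds[["tester_cross"]],
                      replicates = cfg$replicates, environments = envs)
  trial <- TrialData(rec, design, traits = allTraits)
  cell <- cfg$muYield + outer(gLine, gTester, "+") + sca
  truth <- list(config = cfg, seed = seed,
                gcaLine = gLine, gcaTester = gTester, sca = sca,
                envEffects = envEff, blockEffects = blockDraws,
                lineEnv = lineEnv, testerEnv = testerEnv, scaEnv = scaEnv,
                secondaryEffects = secEff,
                cellMeansNonInfested = cell,
                lossLink = loss, checkIds = checkIds)
  list(trial = trial, truth = truth)
}

#' Configuration for the SNP panel simulator
#'
#' Defaults emulate a two-ancestral-population inbred maize panel: 26
#' samples (24 candidate lines plus 2 testers, populations of 6 and 20),
#' 3,305 pre-QC biallelic markers over 10 chromosomes, residual
#' heterozygosity 0.04, 2% missing calls, and designated QC violations
#' (600 missing-data, 500 major-allele-frequency, 152 heterozygosity) so
#' that 2,053 clean markers survive the default filters by construction.
#'
#' @param nSamples number of inbred samples.
#' @param nMarkers pre-QC marker count.
#' @param popSizes integer vector of ancestral-population sizes summing to
#'   `nSamples`.
#' @param divergence Fst-like divergence in (0, 1): population allele
#'   frequencies are Balding-Nichols perturbations
#'   `Beta(p(1-F)/F, (1-p)(1-F)/F)` of the ancestral frequency.
#' @param residualHet residual heterozygous-call rate injected into the
#'   inbred genotypes.
#' @param missingRate missing-call rate for clean markers.
#' @param qcViolations named integer vector: markers forced to fail exactly
#'   one criterion each (`missing_data`, `major_allele_frequency`,
#'   `heterozygosity`).
#' @param cleanFreqRange ancestral allele-frequency range for clean markers.
#' @param nChromosomes chromosomes markers are spread over.
#' @return a validated config (list with class `GenoSimConfig`).
#' @export
genoSimConfig <- function(nSamples = 26, nMarkers = 3305,
                          popSizes = NULL, divergence = 0.25,
                          residualHet = 0.04, missingRate = 0.02,
                          qcViolations = NULL,
                          cleanFreqRange = c(0.2, 0.8),
                          nChromosomes = 10) {
  if (is.null(qcViolations))
    # default violation mix scales with the panel: at 3,305 markers it is
    # 600 missing / 500 major-AF / 152 het, leaving 2,053 clean
    qcViolations <- round(nMarkers * c(missing_data = 600,
                                       major_allele_frequency = 500,
                                       heterozygosity = 152) / 3305)
  if (is.null(popSizes))
    popSizes <- c(max(round(nSamples * 6 / 26), 1),
                  nSamples - max(round(nSamples * 6 / 26), 1))
  stopifnot(sum(popSizes) == nSamples, divergence > 0, divergence < 1,
            residualHet >= 0, residualHet <= 1,
            missingRate >= 0, missingRate <= 1,
            sum(qcViolations) <= nMarkers)
  cfg <- list(nSamples = nSamples, nMarkers = nMarkers,
              popSizes = popSizes, divergence = divergence,
              residualHet = residualHet, missingRate = missingRate,
              qcViolations = qcViolations,
              cleanFreqRange = cleanFreqRange,
              nChromosomes = nChromosomes)
  class(cfg) <- c("GenoSimConfig", "list")
  cfg
}

.simCleanMarker <- function(n, pop, cfg, maxMissing = 0.10,
                            maxMajorAF = 0.95, maxHet = 0.20) {
  F <- cfg$divergence
  for (try in 1:100) {
    p0 <- runif(1, cfg$cleanFreqRange[1], cfg$cleanFreqRange[2])
    pk <- rbeta(length(cfg$popSizes), p0 * (1 - F) / F,
                (1 - p0) * (1 - F) / F)
    g <- 2 * rbinom(n, 1, pk[pop])
    g[runif(n) < cfg$residualHet] <- 1
    g[runif(n) < cfg$missingRate] <- NA
    called <- sum(!is.na(g))
    if (called == 0) next
    pB <- sum(g, na.rm = TRUE) / (2 * called)
    if (1 - called / n > maxMissing) next
    if (max(pB, 1 - pB) > maxMajorAF) next
    if (sum(g == 1, na.rm = TRUE) / called > maxHet) next
    return(list(g = g, p0 = p0, pk = pk))
  }
  stop("could not generate a QC-clean marker; check config")
}

#' Simulate an inbred two-population SNP panel
#'
#' Ancestral allele frequencies are uniform on the configured range;
#' population frequencies arise from a Balding-Nichols perturbation with
#' the divergence parameter; inbred genotypes are drawn homozygous from the
#' population frequency, then heterozygous calls are injected at the
#' residual rate and calls dropped at the missing rate. Clean markers are
#' rejection-sampled until they pass the default QC filters, and the
#' designated violation markers are constructed to fail exactly one
#' criterion each, so the generator's QC truth is exact. True population
#' labels and per-marker QC classes are returned.
#'
#' @param cfg a [genoSimConfig()] configuration.
#' @param seed integer master seed (stream `"genotypes"`).
#' @return list with `panel` (a [GenotypePanel-class]), `labels` (true
#'   population per sample), and `truth` (per-marker QC class, ancestral
#'   and population frequencies).
#' @export
simulateGenotypes <- function(cfg = genoSimConfig(), seed = 1) {
  stopifnot(inherits(cfg, "GenoSimConfig"))
  set.seed(streamSeed(seed, "genotypes"))
  n <- cfg$nSamples
  m <- cfg$nMarkers
  pop <- rep(seq_along(cfg$popSizes), cfg$popSizes)
  samples <- c(sprintf("L%02d", seq_len(max(n - 2, 0))),
               if (n >= 2) c("T1", "T2"))[seq_len(n)]

  qcClass <- rep("clean", m)
  vio <- cfg$qcViolations
  idx <- sample(m, sum(vio))
  qcClass[idx] <- rep(names(vio), vio)

  d <- matrix(NA_real_, m, n,
              dimnames = list(sprintf("M%04d", seq_len(m)), samples))
  p0v <- numeric(m)
  pkMat <- matrix(NA_real_, m, length(cfg$popSizes))
  for (i in seq_len(m)) {
    cls <- qcClass[i]
    if (cls == "clean") {
      mk <- .simCleanMarker(n, pop, cfg)
      d[i, ] <- mk$g
    } else if (cls == "missing_data") {
      cfg0 <- cfg; cfg0$missingRate <- 0
      mk <- .simCleanMarker(n, pop, cfg0)
      g <- mk$g
      g[sample(n, ceiling(n * 0.15))] <- NA
      d[i, ] <- g
    } else if (cls == "major_allele_frequency") {
      mk <- list(p0 = 1, pk = rep(1, length(cfg$popSizes)))
      d[i, ] <- 2                       # monomorphic: p_major = 1
    } else {                            # heterozygosity violation
      repeat {
        p0 <- runif(1, 0.3, 0.7)
        g <- 2 * rbinom(n, 1, p0)
        g[sample(n, ceiling(n * 0.3))] <- 1
        pB <- sum(g) / (2 * n)
        if (max(pB, 1 - pB) <= 0.95) break
      }
      mk <- list(p0 = p0, pk = rep(p0, length(cfg$popSizes)))
      d[i, ] <- g
    }
    p0v[i] <- mk$p0
    pkMat[i, ] <- mk$pk
  }
  chrom <- sort(rep(seq_len(cfg$nChromosomes), length.out = m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(2e8, length(ix)))), use.names = FALSE)
  panel <- GenotypePanel(d, chromosome = chrom, position = pos)
  ord <- match(rownames(panel), rownames(d))
  list(panel = panel,
       labels = setNames(pop, samples),
       truth = list(config = cfg, seed = seed,
                    qcClass = qcClass[ord],
                    ancestralFreq = p0v[ord],
                    populationFreq = pkMat[ord, , drop = FALSE]))
}
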