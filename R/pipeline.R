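.configHash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  b <- utf8ToInt(s)
  sprintf("%08x",
          sum(b * (seq_along(b) %% 97 + 1)) %% 4294967291)
}

#' Assemble a pipeline run configuration
#'
#' @param trial a [TrialData-class] object, or a path to a trial CSV (then
#'   `design` is required).
#' @param design an [LxTDesign-class], needed when `trial` is a path.
#' @param genotypes a [GenotypePanel-class], or `NULL` to skip the marker
#'   stages.
#' @param outDir output directory (created if absent).
#' @param traits trait columns to analyse (default `grain_yield` plus the
#'   infestation traits when present).
#' @param conditions analysis conditions (default all three).
#' @param scaThreshold,alpha,inbreeding,tieRule,epsilon method knobs passed
#'   to the grouping and variance-component stages.
#' @param seed seed recorded in output metadata.
#' @return a validated config (list with class `RunConfig`).
#' @export
runConfig <- function(trial, design = NULL, genotypes = NULL,
                      outDir = tempfile("lxt-run-"),
                      traits = NULL,
                      conditions = c("infested", "non_infested",
                                     "across_mtl"),
                      scaThreshold = 100, alpha = 0.05, inbreeding = 1,
                      tieRule = "min_value", epsilon = 0, seed = 1) {
  stopifnot(scaThreshold >= 0, alpha > 0, alpha < 1,
            inbreeding >= 0, inbreeding <= 1)
  if (is.character(trial)) {
    if (is.null(design)) stop("design is required to read a trial CSV")
    trial <- readTrialCsv(trial, design)
  }
  cfg <- list(trial = trial, genotypes = genotypes, outDir = outDir,
              traits = traits, conditions = conditions,
              scaThreshold = scaThreshold, alpha = alpha,
              inbreeding = inbreeding, tieRule = tieRule,
              epsilon = epsilon, seed = seed)
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file names the input paths and method knobs: fields `trial_csv`,
#' `genotype_csv` + `marker_map_csv` (or `vcf`), `out_dir`, `traits`,
#' `conditions`, `sca_threshold`, `alpha`, `inbreeding`, `tie_rule`,
#' `epsilon`, `seed`, plus the design under `design:` (`lines`, `testers`,
#' `checks`, `tester_cross`, `replicates`).
#'
#' @param path YAML file path.
#' @return a [runConfig()] configuration.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$design), !is.null(y$trial_csv))
  design <- LxTDesign(lines = y$design$lines, testers = y$design$testers,
                      checks = y$design$checks %||% character(),
                      testerCross = y$design$tester_cross %||% NA_character_,
                      replicates = y$design$replicates %||% 2)
  genotypes <- NULL
  if (!is.null(y$genotype_csv))
    genotypes <- readGenotypeCsv(y$genotype_csv, y$marker_map_csv)
  else if (!is.null(y$vcf))
    genotypes <- readGenotypeVcf(y$vcf)
  runConfig(trial = y$trial_csv, design = design, genotypes = genotypes,
            outDir = y$out_dir %||% tempfile("lxt-run-"),
            traits = y$traits,
            conditions = y$conditions %||% c("infested", "non_infested",
                                             "across_mtl"),
            scaThreshold = y$sca_threshold %||% 100,
            alpha = y$alpha %||% 0.05,
            inbreeding = y$inbreeding %||% 1,
            tieRule = y$tie_rule %||% "min_value",
            epsilon = y$epsilon %||% 0,
            seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeStage <- function(df, path, seed, hash) {
  writeTrialCsv(df, path, seed = seed, configHash = hash)
}

#' Run the full analysis pipeline
#'
#' Stage order: ANOVA per trait x condition, combining-ability effects,
#' standard heterosis, heterotic grouping (both classifiers plus
#' consensus), then the marker stages (QC, diversity stats, Jaccard and IBS
#' distances, Ward dendrogram with silhouette-selected k, PCA). Each stage
#' writes a CSV (or Newick) file carrying the tool version, seed and config
#' hash, so identical config + seed reruns are byte-identical. A stage
#' failure is caught and recorded; the remaining independent stages still
#' run, and a manifest (JSON) summarises per-stage status.
#'
#' @param cfg a [runConfig()] configuration.
#' @return invisibly, a list with `status` (per-stage data.frame),
#'   `outDir`, and the in-memory stage results.
#' @export
runFullPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  # hash covers the method knobs only, so moving the output directory does
  # not change the recorded configuration fingerprint
  hash <- .configHash(cfg[setdiff(names(cfg),
                                  c("trial", "genotypes", "outDir"))])
  seed <- cfg$seed
  trial <- cfg$trial
  have <- function(cond) {
    cond == "across_mtl" || cond %in% records(trial)$condition
  }
  conds <- Filter(have, cfg$conditions)
  traits <- cfg$traits %||% intersect(
    c("grain_yield", "striga_damage", "striga_count"), traitNames(trial))
  status <- list()
  results <- list()
  note <- function(stage, state, detail = "") {
    status[[length(status) + 1]] <<- data.frame(stage = stage,
                                                status = state,
                                                detail = detail)
  }
  run <- function(stage, expr) {
    tryCatch({ res <- force(expr); note(stage, "ok"); res },
             error = function(e) {
               note(stage, "failed", conditionMessage(e))
               NULL
             })
  }

  traitCond <- function(tr, cond) {
    if (tr %in% c("striga_damage", "striga_count") && cond != "infested")
      return(FALSE)
    cond != "infested" || tr != "ear_height"
  }
  anovas <- list()
  for (tr in traits) for (cond in conds) {
    if (!traitCond(tr, cond)) next
    key <- paste(tr, cond, sep = ".")
    anovas[[key]] <- run(paste0("anova/", key), {
      an <- suppressWarnings(anovaLineByTester(trial, tr, cond))
      tab <- as.data.frame(an)
      tab$sig <- signifCodes(tab$p)
      .writeStage(tab, file.path(cfg$outDir,
                                 paste0("anova_", tr, "_", cond, ".csv")),
                  seed, hash)
      an
    })
  }
  results$anova <- anovas

  cas <- list()
  vcs <- list()
  for (tr in traits) for (cond in conds) {
    if (!traitCond(tr, cond)) next
    key <- paste(tr, cond, sep = ".")
    cas[[key]] <- run(paste0("effects/", key), {
      ca <- estimateGcaSca(trial, tr, cond)
      .writeStage(combiningAbilityTable(ca),
                  file.path(cfg$outDir,
                            paste0("effects_", tr, "_", cond, ".csv")),
                  seed, hash)
      ca
    })
    if (!is.null(anovas[[key]]))
      vcs[[key]] <- run(paste0("varcomp/", key), {
        vc <- estimateVarianceComponents(anovas[[key]], trialDesign(trial),
                                         inbreeding = cfg$inbreeding)
        df <- data.frame(component = names(varianceComponents(vc)),
                         value = as.numeric(varianceComponents(vc)))
        .writeStage(df, file.path(cfg$outDir,
                                  paste0("varcomp_", tr, "_", cond,
                                         ".csv")), seed, hash)
        vc
      })
  }
  results$effects <- cas
  results$varcomp <- vcs

  results$heterosis <- run("heterosis", {
    het <- do.call(rbind, lapply(conds, function(cond) {
      h <- heterosisTable(trial, "grain_yield", cond)
      h$condition <- cond
      h
    }))
    .writeStage(het, file.path(cfg$outDir, "heterosis.csv"), seed, hash)
    het
  })

  results$groups <- run("grouping", {
    asg <- list()
    for (cond in conds) {
      ca <- cas[[paste("grain_yield", cond, sep = ".")]]
      an <- anovas[[paste("grain_yield", cond, sep = ".")]]
      if (is.null(ca) || is.null(an)) next
      means <- testcrossMeanMatrix(trial, "grain_yield", cond)
      ckEntry <- testerCross(trialDesign(trial))
      cm <- cellMeans(trial, "grain_yield", cond)
      ckMean <- cm$mean[cm$entry == ckEntry]
      lsd <- lsdMeans(an, alpha = cfg$alpha)
      if (length(ckMean) && !is.na(ckMean))
        asg[[paste0("sca.", cond)]] <-
          assignGroupsScaYield(ca, means, ckMean, lsd,
                               scaThreshold = cfg$scaThreshold,
                               condition = cond)
      asg[[paste0("hsgca.", cond)]] <-
        assignGroupsHsgca(hsgcaEffects(ca), tieRule = cfg$tieRule,
                          epsilon = cfg$epsilon, condition = cond)
    }
    common <- c("line", "method", "condition", "group")
    flat <- do.call(rbind, lapply(asg, function(d) d[common]))
    cons <- consensusGroups(flat)
    .writeStage(flat, file.path(cfg$outDir, "groups.csv"), seed, hash)
    .writeStage(cons, file.path(cfg$outDir, "groups_consensus.csv"),
                seed, hash)
    list(assignments = asg, consensus = cons)
  })

  if (is.null(cfg$genotypes)) {
    note("markers", "skipped", "no genotypes")
  } else {
    results$markers <- run("markers", {
      filtered <- filterMarkers(cfg$genotypes)
      .writeStage(qcReport(filtered),
                  file.path(cfg$outDir, "marker_qc.csv"), seed, hash)
      st <- markerSummary(filtered)
      .writeStage(st@perMarker,
                  file.path(cfg$outDir, "marker_stats.csv"), seed, hash)
      .writeStage(st@perChromosome,
                  file.path(cfg$outDir, "marker_stats_chromosome.csv"),
                  seed, hash)
      jac <- jaccardDistance(filtered)
      ibs <- ibsDistance(filtered)
      .writeStage(as.data.frame(distanceMatrix(jac)),
                  file.path(cfg$outDir, "dist_jaccard.csv"), seed, hash)
      .writeStage(as.data.frame(distanceMatrix(ibs)),
                  file.path(cfg$outDir, "dist_ibs.csv"), seed, hash)
      sil <- silhouetteK(jac)
      wc <- wardCluster(jac, k = sil$k)
      dendrogramNewick(wc$tree,
                       file.path(cfg$outDir, "dendrogram.nwk"))
      pca <- pcaGenotypes(filtered)
      sc <- data.frame(sample = rownames(pca$scores),
                       pca$scores[, seq_len(min(5, ncol(pca$scores)))])
      .writeStage(sc, file.path(cfg$outDir, "pca_scores.csv"), seed, hash)
      list(panel = filtered, stats = st, jaccard = jac, ibs = ibs,
           silhouette = sil, cluster = wc, pca = pca)
    })
  }

  statusDf <- do.call(rbind, status)
  manifest <- list(package = "testcross",
                   version = as.character(packageVersion("testcross")),
                   seed = seed, config_hash = hash,
                   stages = statusDf)
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$status <- statusDf
  results$outDir <- cfg$outDir
  if (any(statusDf$status == "failed"))
    warning("pipeline finished with failed stage(s): ",
            paste(statusDf$stage[statusDf$status == "failed"],
                  collapse = ", "))
  invisible(results)
}
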