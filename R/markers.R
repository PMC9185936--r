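#' Construct a genotype panel
#'
#' @param dosage numeric matrix of biallelic dosage calls, markers in rows
#'   and samples in columns (0/1/2/NA). A samples x markers matrix is
#'   accepted when `markersInRows = FALSE` and transposed.
#' @param chromosome,position marker map vectors, one value per marker.
#' @param markersInRows orientation of `dosage`.
#' @return a [GenotypePanel-class] object.
#' @examples
#' d <- matrix(c(0, 2, 1, NA, 0, 0), nrow = 3,
#'             dimnames = list(paste0("M", 1:3), c("S1", "S2")))
#' GenotypePanel(d, chromosome = c(1, 1, 2), position = c(10, 20, 5))
#' @export
GenotypePanel <- function(dosage, chromosome, position,
                          markersInRows = TRUE) {
  if (!markersInRows) dosage <- t(dosage)
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("M", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("S", seq_len(ncol(dosage)))
  ord <- order(chromosome, position)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage[ord, , drop = FALSE]),
    rowData = S4Vectors::DataFrame(chromosome = chromosome[ord],
                                   position = as.integer(position[ord])))
  new("GenotypePanel", se)
}

#' Read a dosage matrix plus marker-map sidecar
#'
#' The genotype file is CSV/TSV with samples in rows and markers in columns
#' (header = marker names, first column = sample identifiers); the map file
#' has columns `marker`, `chromosome`, `position`.
#'
#' @param path genotype matrix file.
#' @param mapPath marker map file.
#' @param sep field separator (`","`; use `"\t"` for TSV).
#' @return a [GenotypePanel-class] object.
#' @export
readGenotypeCsv <- function(path, mapPath, sep = ",") {
  g <- read.csv(path, sep = sep, row.names = 1, check.names = FALSE,
                comment.char = "#")
  map <- read.csv(mapPath, sep = sep, comment.char = "#",
                  stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "chromosome", "position") %in% names(map)))
  g <- as.matrix(g)
  missingMap <- setdiff(colnames(g), map$marker)
  if (length(missingMap))
    stop("markers absent from the map: ", paste(utils::head(missingMap, 5),
                                                collapse = ", "))
  map <- map[match(colnames(g), map$marker), ]
  GenotypePanel(t(g), chromosome = map$chromosome, position = map$position)
}

#' Read biallelic SNPs from a VCF
#'
#' Multiallelic sites are rejected with a count. Requires the `vcfR`
#' package.
#'
#' @param path VCF file (plain or gzipped).
#' @return a [GenotypePanel-class] object.
#' @export
readGenotypeVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readGenotypeVcf requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi))
    message("rejected ", sum(multi), " multiallelic site(s)")
  v <- v[!multi, ]
  gt <- vcfR::extract.gt(v)
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  core <- sub(":.*", "", gt)
  dos[core %in% c("0/0", "0|0")] <- 0
  dos[core %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dos[core %in% c("1/1", "1|1")] <- 2
  fix <- vcfR::getFIX(v)
  GenotypePanel(dos, chromosome = fix[, "CHROM"],
                position = as.integer(fix[, "POS"]))
}

.markerStats <- function(d) {
  n <- ncol(d)
  called <- rowSums(!is.na(d))
  nB <- rowSums(d, na.rm = TRUE)               # B allele count
  pB <- ifelse(called > 0, nB / (2 * called), NA_real_)
  pMajor <- pmax(pB, 1 - pB)
  het <- ifelse(called > 0, rowSums(d == 1, na.rm = TRUE) / called,
                NA_real_)
  data.frame(call_rate = called / n,
             missing = 1 - called / n,
             p_major = pMajor,
             maf = 1 - pMajor,
             gene_diversity = 2 * pB * (1 - pB),
             pic = 1 - (pB^2 + (1 - pB)^2) - 2 * pB^2 * (1 - pB)^2,
             het_obs = het)
}

#' Marker QC filtering
#'
#' Retains markers with missing-data fraction `<= maxMissing`, major allele
#' frequency `<= maxMajorAF`, and observed heterozygosity `<= maxHet` (all
#' conjunctive, so the filter is order-independent). "Major allele
#' frequency" is the frequency of the more common allele (p_major), not the
#' minor-allele frequency. The QC report attributes each removed marker to
#' its first failing criterion in the order missing / major-AF /
#' heterozygosity and also tallies every failure.
#'
#' @param g a [GenotypePanel-class] object.
#' @param maxMissing maximum missing fraction (default 0.10).
#' @param maxMajorAF maximum major allele frequency (default 0.95; a
#'   monomorphic marker has p_major = 1 and is removed).
#' @param maxHet maximum observed heterozygosity (default 0.20).
#' @return the filtered panel, with the QC report in `qcReport()`.
#' @export
filterMarkers <- function(g, maxMissing = 0.10, maxMajorAF = 0.95,
                          maxHet = 0.20) {
  stopifnot(is(g, "GenotypePanel"))
  d <- dosage(g)
  st <- .markerStats(d)
  failMiss <- st$missing > maxMissing
  failMaf <- !is.na(st$p_major) & st$p_major > maxMajorAF
  failHet <- !is.na(st$het_obs) & st$het_obs > maxHet
  failMaf[is.na(st$p_major)] <- TRUE   # zero-call markers removed
  keep <- !(failMiss | failMaf | failHet)
  if (!any(keep))
    stop("all markers removed by QC: empty panel")
  first <- rep("retained", nrow(d))
  first[failHet] <- "heterozygosity"
  first[failMaf] <- "major_allele_frequency"
  first[failMiss] <- "missing_data"
  report <- data.frame(
    criterion = c("input", "missing_data", "major_allele_frequency",
                  "heterozygosity", "retained"),
    threshold = c(NA, maxMissing, maxMajorAF, maxHet, NA),
    n_failing = c(nrow(d), sum(failMiss), sum(failMaf), sum(failHet),
                  sum(keep)),
    n_first_attributed = c(nrow(d), sum(first == "missing_data"),
                           sum(first == "major_allele_frequency"),
                           sum(first == "heterozygosity"), sum(keep)))
  out <- g[keep, ]
  out <- as(out, "GenotypePanel")
  S4Vectors::metadata(out)$qc <- report
  S4Vectors::metadata(out)$qc_first_criterion <- first
  out
}

#' Per-marker, per-chromosome and panel diversity statistics
#'
#' Over non-missing calls per biallelic marker: major allele frequency,
#' gene diversity (expected heterozygosity, `1 - p^2 - q^2`), polymorphic
#' information content (`PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`, at most 0.375),
#' and observed heterozygosity. Chromosome and global summaries are
#' unweighted means; markers with zero calls are excluded from summaries.
#'
#' @param g a [GenotypePanel-class] object.
#' @return a [MarkerStats-class] object.
#' @examples
#' sim <- simulateGenotypes(genoSimConfig(nMarkers = 50), seed = 1)
#' markerSummary(sim$panel)
#' @export
markerSummary <- function(g) {
  stopifnot(is(g, "GenotypePanel"))
  if (nrow(g) < 1) stop("no markers in panel")
  st <- .markerStats(dosage(g))
  map <- markerMap(g)
  per <- cbind(map, st[, c("call_rate", "p_major", "maf", "gene_diversity",
                           "pic", "het_obs")])
  ok <- !is.na(per$p_major)
  statCols <- c("call_rate", "p_major", "maf", "gene_diversity", "pic",
                "het_obs")
  byChr <- aggregate(per[ok, statCols], by = list(chromosome =
                                                    per$chromosome[ok]),
                     FUN = mean)
  byChr$n_markers <- as.integer(table(per$chromosome[ok])[
    as.character(byChr$chromosome)])
  global <- c(colMeans(per[ok, statCols]), n_markers = sum(ok))
  new("MarkerStats", perMarker = per, perChromosome = byChr,
      global = global)
}

.pairwiseDistance <- function(d, metric) {
  n <- ncol(d)
  samples <- colnames(d)
  vals <- matrix(0, n, n, dimnames = list(samples, samples))
  counts <- matrix(0L, n, n, dimnames = list(samples, samples))
  if (metric == "jaccard") {
    hasA <- d <= 1   # allele A present (dosage 0 or 1)
    hasB <- d >= 1   # allele B present (dosage 1 or 2)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(d[, i]) & !is.na(d[, j])
      m <- sum(ok)
      counts[i, j] <- counts[j, i] <- m
      if (m == 0) {
        vals[i, j] <- vals[j, i] <- NA_real_
        next
      }
      if (metric == "jaccard") {
        inter <- sum(hasA[ok, i] & hasA[ok, j]) +
          sum(hasB[ok, i] & hasB[ok, j])
        un <- sum(hasA[ok, i] | hasA[ok, j]) +
          sum(hasB[ok, i] | hasB[ok, j])
        vals[i, j] <- vals[j, i] <- 1 - inter / un
      } else {
        shared <- sum(2 - abs(d[ok, i] - d[ok, j]))
        vals[i, j] <- vals[j, i] <- 1 - shared / (2 * m)
      }
    }
  }
  if (anyNA(vals))
    warning("sample pair(s) with zero co-called markers: missing distances")
  diag(counts) <- as.integer(colSums(!is.na(d)))
  new("GenotypeDistance", values = vals, metric = metric,
      pairCounts = counts)
}

#' Jaccard dissimilarity between samples
#'
#' Each genotype is expanded to two allele-presence bits (A present for
#' dosage 0 or 1, B present for 1 or 2); the pairwise dissimilarity is
#' `1 - |intersection| / |union|` of the bit sets over markers co-called in
#' both samples. This allele-presence convention is the dominant one for
#' SNP Jaccard, since Jaccard is undefined on raw dosages; a shared-genotype
#' alternative (`1 -` fraction of identical co-called dosages) is available
#' via `method = "genotype"`.
#'
#' @param g a [GenotypePanel-class] object with >= 2 samples.
#' @param method `"allele"` (default) or `"genotype"`.
#' @return a [GenotypeDistance-class] object.
#' @export
jaccardDistance <- function(g, method = c("allele", "genotype")) {
  method <- match.arg(method)
  stopifnot(is(g, "GenotypePanel"))
  d <- dosage(g)
  if (ncol(d) < 2) stop("need at least 2 samples")
  if (method == "allele") return(.pairwiseDistance(d, "jaccard"))
  n <- ncol(d)
  vals <- matrix(0, n, n, dimnames = list(colnames(d), colnames(d)))
  counts <- matrix(0L, n, n, dimnames = dimnames(vals))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(d[, i]) & !is.na(d[, j])
    counts[i, j] <- counts[j, i] <- sum(ok)
    vals[i, j] <- vals[j, i] <- if (!sum(ok)) NA_real_ else
      1 - sum(d[ok, i] == d[ok, j]) / sum(ok)
  }
  diag(counts) <- as.integer(colSums(!is.na(d)))
  new("GenotypeDistance", values = vals, metric = "jaccard",
      pairCounts = counts)
}

#' Identity-by-state distance between samples
#'
#' Per co-called marker the shared allele count is `2 - |dosage
#' difference|`; the distance is `1 - shared / (2 * co-called markers)`, so
#' identical samples are at 0 and opposite homozygotes at 1.
#'
#' @param g a [GenotypePanel-class] object with >= 2 samples.
#' @return a [GenotypeDistance-class] object.
#' @export
ibsDistance <- function(g) {
  stopifnot(is(g, "GenotypePanel"))
  d <- dosage(g)
  if (ncol(d) < 2) stop("need at least 2 samples")
  .pairwiseDistance(d, "ibs")
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerates under the Ward minimum-variance criterion in the `ward.D2`
#' convention (dissimilarities treated as Euclidean analogues and squared
#' inside the Lance-Williams update); the convention is recorded on the
#' result because the `ward.D`/`ward.D2` choice changes trees.
#'
#' @param d a [GenotypeDistance-class] object (complete; missing distances
#'   are an error) or a `dist`.
#' @param k optional number of flat clusters to cut; `NULL` returns the
#'   tree only.
#' @return list with `tree` (an `hclust`), `method` (`"ward.D2"`), and,
#'   when `k` is given, integer `clusters` named by sample.
#' @export
wardCluster <- function(d, k = NULL) {
  v <- if (is(d, "GenotypeDistance")) distanceMatrix(d) else as.matrix(d)
  if (anyNA(v))
    stop("distance matrix has missing values; impute or drop the affected ",
         "pairs before clustering")
  tree <- hclust(as.dist(v), method = "ward.D2")
  out <- list(tree = tree, method = "ward.D2")
  if (!is.null(k)) out$clusters <- cutree(tree, k = k)
  out
}

#' Export a dendrogram as a Newick string
#'
#' @param tree an `hclust` (e.g. `wardCluster(d)$tree`).
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogramNewick <- function(tree, path = NULL) {
  nwk <- ape::write.tree(ape::as.phylo(tree))
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Principal component analysis of a genotype panel
#'
#' Dosages are column-centered per marker (marker-mean imputation for
#' missing calls, the only imputation in the package); the percent variance
#' per axis is the eigenvalue over the trace of the sample covariance, so
#' the percentages sum to 100 over all axes. Scaling markers to unit
#' variance is off by default.
#'
#' @param g a [GenotypePanel-class] with >= 2 samples and >= 2 markers.
#' @param scale logical, scale markers to unit variance before the
#'   decomposition.
#' @return list with `scores` (samples x components), `percentVar`
#'   (numeric, summing to 100), and `sdev`.
#' @export
pcaGenotypes <- function(g, scale = FALSE) {
  stopifnot(is(g, "GenotypePanel"))
  X <- t(dosage(g))                      # samples x markers
  if (nrow(X) < 2 || ncol(X) < 2) stop("need >= 2 samples and >= 2 markers")
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  v <- apply(X, 2, var)
  if (all(v == 0 | is.na(v))) stop("constant genotype matrix: zero variance")
  if (scale) X <- X[, v > 0, drop = FALSE]
  p <- prcomp(X, center = TRUE, scale. = scale)
  pct <- 100 * p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, percentVar = pct, sdev = p$sdev)
}

#' Silhouette-based choice of the number of clusters
#'
#' Mean silhouette width over Ward (`ward.D2`) flat cuts for each candidate
#' k; the selected k is the argmax, with ties broken toward the smallest k.
#' Candidates with `k >= n` are skipped with a note.
#'
#' @param d a [GenotypeDistance-class] or `dist` (n >= 3 samples).
#' @param kRange candidate cluster numbers (default 2:10).
#' @return list with `k` (selected), `scores` (data.frame k,
#'   mean_silhouette), and `clusters` at the selected k.
#' @export
silhouetteK <- function(d, kRange = 2:10) {
  v <- if (is(d, "GenotypeDistance")) distanceMatrix(d) else as.matrix(d)
  n <- nrow(v)
  if (n < 3) stop("silhouette selection needs at least 3 samples")
  keep <- kRange[kRange < n & kRange >= 2]
  if (length(keep) < length(kRange))
    message("skipped k >= n (", n, " samples)")
  wc <- wardCluster(if (is(d, "GenotypeDistance")) d else v)
  scores <- data.frame(k = keep, mean_silhouette = NA_real_)
  for (i in seq_along(keep)) {
    cl <- cutree(wc$tree, k = keep[i])
    sil <- cluster::silhouette(cl, dmatrix = v)
    scores$mean_silhouette[i] <- mean(sil[, "sil_width"])
  }
  best <- keep[which.max(scores$mean_silhouette)]  # which.max: smallest tie
  list(k = best, scores = scores,
       clusters = cutree(wc$tree, k = best))
}
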