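#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats anova aggregate as.dist cutree hclust lm model.matrix
#'   pf prcomp pt qt rbinom rnbinom rnorm runif rbeta sd setNames var
#' @importFrom utils packageVersion read.csv write.csv write.table
NULL

.CONDITIONS <- c("infested", "non_infested")
.ANALYSIS_CONDITIONS <- c("infested", "non_infested", "across_mtl")
.ENTRY_ROLES <- c("testcross", "tester_cross", "check")
.GROUPS <- c("HGA", "HGB", "unassigned")

#' Line x tester mating design
#'
#' Describes the factorial structure of a line x tester trial: the candidate
#' lines, the testers they were crossed to, the check entries (including the
#' cross between the two testers, which serves as the standard-heterosis
#' check), and the replication/environment layout per research condition.
#'
#' @slot lines character, ordered line identifiers (l of them, l >= 2).
#' @slot testers character, ordered tester identifiers (t >= 2).
#' @slot checks character, check entry identifiers (may be empty).
#' @slot testerCross single entry identifier for the tester1 x tester2 hybrid
#'   (a member of `checks`), or `NA` when no such check exists.
#' @slot replicates integer, replications per environment.
#' @slot environments named list with elements `infested` and `non_infested`,
#'   each a character vector of environment (location-year) identifiers.
#'
#' @examples
#' LxTDesign(lines = c("L1", "L2"), testers = c("T1", "T2"),
#'           checks = "T1xT2", testerCross = "T1xT2", replicates = 2,
#'           environments = list(infested = "E1", non_infested = "E2"))
#' @export
setClass("LxTDesign", representation(
  lines = "character",
  testers = "character",
  checks = "character",
  testerCross = "character",
  replicates = "integer",
  environments = "list"
))

setValidity("LxTDesign", function(object) {
  msg <- character()
  if (length(object@lines) < 2) msg <- c(msg, "need at least 2 lines")
  if (length(object@testers) < 2) msg <- c(msg, "need at least 2 testers")
  if (anyDuplicated(c(object@lines, object@testers)))
    msg <- c(msg, "line/tester identifiers must be unique")
  tc <- object@testerCross
  if (length(tc) != 1) msg <- c(msg, "testerCross must be length 1")
  if (length(tc) == 1 && !is.na(tc) && !(tc %in% object@checks))
    msg <- c(msg, "testerCross must be one of the checks")
  if (length(tc) == 1 && !is.na(tc) &&
      tc %in% testcrossEntries(object@lines, object@testers))
    msg <- c(msg, "testerCross must be distinct from all testcross entries")
  if (length(object@replicates) != 1 || object@replicates < 1)
    msg <- c(msg, "replicates must be a single positive integer")
  bad <- setdiff(names(object@environments), .CONDITIONS)
  if (length(bad))
    msg <- c(msg, paste("unknown condition in environments:",
                        paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Plot-level trial records with their design
#'
#' One row per field plot, in long (tidy) layout: design coordinates
#' (environment, condition, replicate, incomplete block, entry, entry role,
#' line, tester) followed by one column per trait. Missing plot values are
#' `NA`, never zero; downstream estimators skip them and report effective n.
#'
#' @slot records data.frame of plot observations.
#' @slot design the [LxTDesign-class] the records belong to.
#' @slot traits character, names of the trait columns in `records`.
#' @export
setClass("TrialData", representation(
  records = "data.frame",
  design = "LxTDesign",
  traits = "character"
))

.DESIGN_COLS <- c("environment", "condition", "replicate", "block",
                  "entry", "entry_role", "line", "tester")

setValidity("TrialData", function(object) {
  rec <- object@records
  msg <- character()
  missing_cols <- setdiff(c(.DESIGN_COLS, object@traits), names(rec))
  if (length(missing_cols))
    return(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  if (!all(rec$condition %in% .CONDITIONS))
    msg <- c(msg, "condition must be 'infested' or 'non_infested'")
  if (!all(rec$entry_role %in% .ENTRY_ROLES))
    msg <- c(msg, "entry_role must be testcross, tester_cross or check")
  tcx <- rec$entry_role == "testcross"
  if (any(tcx & (is.na(rec$line) | is.na(rec$tester))))
    msg <- c(msg, "testcross rows must have non-missing line and tester")
  for (tr in intersect(object@traits, names(rec))) {
    v <- rec[[tr]]
    if (!is.numeric(v)) { msg <- c(msg, paste(tr, "is not numeric")); next }
    if (tr == "striga_damage") {
      if (any(!is.na(v) & rec$condition != "infested"))
        msg <- c(msg, "striga_damage present on non-infested plots")
      if (any(!is.na(v) & (v < 1 | v > 9)))
        msg <- c(msg, "striga_damage outside the 1-9 scale")
    }
    if (tr == "striga_count" && any(!is.na(v) & v < 0))
      msg <- c(msg, "striga_count must be non-negative")
    if (tr == "grain_yield" && any(!is.na(v) & v < 0))
      msg <- c(msg, "grain_yield must be non-negative")
    if (tr %in% c("ear_aspect", "plant_aspect", "husk_cover") &&
        any(!is.na(v) & (v < 1 | v > 5)))
      msg <- c(msg, paste(tr, "outside the 1-5 scale"))
  }
  known <- c(object@design@lines, NA_character_)
  if (any(tcx & !(rec$line %in% object@design@lines)))
    msg <- c(msg, "testcross row with line not in design")
  if (any(tcx & !(rec$tester %in% object@design@testers)))
    msg <- c(msg, "testcross row with tester not in design")
  if (length(msg)) msg else TRUE
})

#' Sequential line x tester ANOVA table
#'
#' Sources in the canonical order for a multi-environment line x tester
#' trial: Environment, Rep(Env), Block(Env x Rep), Hybrid and its partition
#' into Line (GCA), Tester (GCA) and Line x Tester (SCA), the corresponding
#' environment interactions, and Error. F ratios for the genetic terms use
#' the matching x Environment mean square when that term is fitted,
#' otherwise the error mean square.
#'
#' @slot table data.frame with columns source, df, ss, ms, f, p.
#' @slot trait,condition character scalars identifying the analysis.
#' @slot balanced logical, TRUE when the testcross core was complete and the
#'   degrees of freedom match the balanced closed forms.
#' @slot nLines,nTesters,nEnv,nRep integer design constants used.
#' @export
setClass("AnovaTable", representation(
  table = "data.frame",
  trait = "character",
  condition = "character",
  balanced = "logical",
  nLines = "integer",
  nTesters = "integer",
  nEnv = "integer",
  nRep = "integer"
))

#' Combining ability estimates for one trait x condition
#'
#' GCA effects per line and tester, SCA and HSGCA effects per line x tester
#' cell, the Kempthorne standard errors, and two-sided t-test p-values
#' against the combined-ANOVA error mean square.
#'
#' @slot trait,condition character scalars.
#' @slot gcaLine,gcaTester named numeric effect vectors (trait units).
#' @slot sca,hsgca numeric matrices, lines x testers.
#' @slot seGcaLine,seGcaTester,seSca numeric scalars (trait units).
#' @slot pGcaLine,pGcaTester numeric vectors of p-values; `pSca` a matrix.
#' @slot pSca matrix of SCA p-values.
#' @slot mse error mean square; @slot errorDf its degrees of freedom.
#' @slot errorDf degrees of freedom of the error mean square.
#' @export
setClass("CombiningAbility", representation(
  trait = "character",
  condition = "character",
  gcaLine = "numeric",
  gcaTester = "numeric",
  sca = "matrix",
  hsgca = "matrix",
  seGcaLine = "numeric",
  seGcaTester = "numeric",
  seSca = "numeric",
  pGcaLine = "numeric",
  pGcaTester = "numeric",
  pSca = "matrix",
  mse = "numeric",
  errorDf = "numeric"
))

setValidity("CombiningAbility", function(object) {
  msg <- character()
  if (!identical(dim(object@sca), dim(object@hsgca)))
    msg <- c(msg, "sca and hsgca must have identical dimensions")
  if (length(msg)) msg else TRUE
})

#' Variance components from expected mean squares
#'
#' Method-of-moments components for the line x tester mixed model, the
#' additive/dominance conversion under a configurable parental inbreeding
#' coefficient, narrow-sense heritability on an entry-mean basis, and
#' entry-mean repeatability. Negative solutions are truncated to zero and
#' flagged.
#'
#' @slot components named numeric: sigma2_gca_line, sigma2_gca_tester,
#'   sigma2_sca, sigma2_line_x_env, sigma2_tester_x_env, sigma2_sca_x_env,
#'   sigma2_error, sigma2_A, sigma2_D, h2_narrow, repeatability.
#' @slot truncated character, names of components truncated at zero.
#' @slot inbreeding parental inbreeding coefficient F in [0, 1] used.
#' @slot nEnv,nRep design constants used in the expectations.
#' @export
setClass("VarianceComponents", representation(
  components = "numeric",
  truncated = "character",
  inbreeding = "numeric",
  nEnv = "integer",
  nRep = "integer"
))

#' SNP genotype panel
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding a biallelic dosage matrix (markers in rows, samples in columns;
#' calls 0 = homozygous major/A, 1 = heterozygous, 2 = homozygous B, `NA` =
#' missing) with marker chromosome and position in `rowData`. QC reports are
#' stored in `metadata(x)$qc` by [filterMarkers()].
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (!all(d[!is.na(d)] %in% 0:2))
    return("dosage calls must be 0, 1, 2 or NA")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chromosome", "position") %in% colnames(rd)))
    return("rowData must contain 'chromosome' and 'position'")
  TRUE
})

#' Per-marker, per-chromosome and panel-wide diversity statistics
#'
#' @slot perMarker data.frame: marker, chromosome, position, call_rate,
#'   p_major, maf, gene_diversity, pic, het_obs.
#' @slot perChromosome data.frame of unweighted chromosome means.
#' @slot global named numeric of unweighted panel means.
#' @export
setClass("MarkerStats", representation(
  perMarker = "data.frame",
  perChromosome = "data.frame",
  global = "numeric"
))

#' Pairwise genetic distance matrix
#'
#' Symmetric sample x sample dissimilarity in [0, 1] with a zero diagonal,
#' plus the number of co-called markers behind each pair.
#'
#' @slot values numeric matrix of distances.
#' @slot metric "jaccard" or "ibs".
#' @slot pairCounts integer matrix of co-called marker counts.
#' @export
setClass("GenotypeDistance", representation(
  values = "matrix",
  metric = "character",
  pairCounts = "matrix"
))

setValidity("GenotypeDistance", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "distance matrix must be square")
  if (any(abs(diag(v)) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "diagonal must be zero")
  if (any(v[!is.na(v)] < -1e-12 | v[!is.na(v)] > 1 + 1e-12))
    msg <- c(msg, "distances must lie in [0, 1]")
  if (any(abs(v - t(v)) > 1e-12, na.rm = TRUE))
    msg <- c(msg, "distance matrix must be symmetric")
  if (length(msg)) msg else TRUE
})
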