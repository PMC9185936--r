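#' @describeIn LxTDesign-class the candidate line identifiers.
#' @export
setMethod("designLines", "LxTDesign", function(object) object@lines)

#' @describeIn LxTDesign-class the tester identifiers.
#' @export
setMethod("designTesters", "LxTDesign", function(object) object@testers)

#' @describeIn LxTDesign-class the check entry identifiers.
#' @export
setMethod("designChecks", "LxTDesign", function(object) object@checks)

#' @describeIn LxTDesign-class the tester1 x tester2 check entry.
#' @export
setMethod("testerCross", "LxTDesign", function(object) object@testerCross)

#' @describeIn TrialData-class the plot-level records as a data.frame.
#' @export
setMethod("records", "TrialData", function(object) object@records)

#' @describeIn TrialData-class the [LxTDesign-class] of the trial.
#' @export
setMethod("trialDesign", "TrialData", function(object) object@design)

#' @describeIn TrialData-class names of the trait columns.
#' @export
setMethod("traitNames", "TrialData", function(object) object@traits)

#' @describeIn CombiningAbility-class named vector of line GCA effects.
#' @export
setMethod("gcaLine", "CombiningAbility", function(object) object@gcaLine)

#' @describeIn CombiningAbility-class named vector of tester GCA effects.
#' @export
setMethod("gcaTester", "CombiningAbility", function(object) object@gcaTester)

#' @describeIn CombiningAbility-class lines x testers matrix of SCA effects.
#' @export
setMethod("scaEffects", "CombiningAbility", function(object) object@sca)

#' @export
setMethod("hsgcaEffects", "CombiningAbility", function(object) object@hsgca)

#' @describeIn GenotypePanel the dosage matrix (markers x samples).
#' @export
setMethod("dosage", "GenotypePanel", function(object)
  SummarizedExperiment::assay(object, "dosage"))

#' @describeIn GenotypePanel marker map (marker, chromosome, position).
#' @export
setMethod("markerMap", "GenotypePanel", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  data.frame(marker = rownames(object),
             chromosome = rd$chromosome,
             position = rd$position)
})

#' @describeIn filterMarkers retrieve the QC report stored by a previous
#'   filtering step (NULL when the panel has not been filtered).
#' @export
setMethod("qcReport", "GenotypePanel", function(object)
  S4Vectors::metadata(object)$qc)

#' @describeIn GenotypeDistance-class the full symmetric distance matrix.
#' @export
setMethod("distanceMatrix", "GenotypeDistance", function(object) object@values)

#' @describeIn GenotypeDistance-class co-called marker counts per pair.
#' @export
setMethod("pairCounts", "GenotypeDistance", function(object) object@pairCounts)

#' @describeIn VarianceComponents-class named numeric vector of components.
#' @export
setMethod("varianceComponents", "VarianceComponents",
          function(object) object@components)

#' @describeIn AnovaTable-class the ANOVA table as a data.frame.
#' @param x an [AnovaTable-class] object.
#' @param row.names,optional,... passed through (unused).
#' @export
setMethod("as.data.frame", "AnovaTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

setMethod("show", "LxTDesign", function(object) {
  cat("LxTDesign:", length(object@lines), "lines x",
      length(object@testers), "testers,",
      length(object@checks), "check(s),",
      object@replicates, "replicate(s)\n")
  for (cond in names(object@environments))
    cat("  ", cond, ": ", paste(object@environments[[cond]], collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "TrialData", function(object) {
  cat("TrialData:", nrow(object@records), "plots,",
      length(object@traits), "trait(s)\n")
  tab <- table(object@records$condition)
  cat("  conditions:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  traits:", paste(object@traits, collapse = ", "), "\n")
})

setMethod("show", "AnovaTable", function(object) {
  cat("Line x tester ANOVA -", object@trait, "/", object@condition, "\n")
  cat("  ", object@nLines, "lines x", object@nTesters, "testers,",
      object@nEnv, "environment(s) x", object@nRep, "rep(s);",
      if (object@balanced) "balanced" else "UNBALANCED", "\n")
  tab <- object@table
  tab$ss <- signif(tab$ss, 6)
  tab$ms <- signif(tab$ms, 6)
  tab$f <- signif(tab$f, 4)
  tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE)
})

setMethod("show", "CombiningAbility", function(object) {
  cat("Combining ability -", object@trait, "/", object@condition, "\n")
  cat("  GCA SE (L):", signif(object@seGcaLine, 5),
      " GCA SE (T):", signif(object@seGcaTester, 5),
      " SCA SE:", signif(object@seSca, 5), "\n")
  cat("  tester GCA:",
      paste(names(object@gcaTester), signif(object@gcaTester, 5),
            sep = "=", collapse = ", "), "\n")
  cat("  line GCA range: [", signif(min(object@gcaLine), 5), ",",
      signif(max(object@gcaLine), 5), "]\n")
})

setMethod("show", "VarianceComponents", function(object) {
  cat("Variance components (expected mean squares, F =",
      object@inbreeding, ")\n")
  print(signif(object@components, 5))
  if (length(object@truncated))
    cat("  truncated at zero:", paste(object@truncated, collapse = ", "), "\n")
})

setMethod("show", "MarkerStats", function(object) {
  cat("MarkerStats:", nrow(object@perMarker), "markers,",
      nrow(object@perChromosome), "chromosomes\n")
  print(signif(object@global, 4))
})

setMethod("show", "GenotypeDistance", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat("GenotypeDistance (", object@metric, "): ",
      nrow(object@values), " samples; range [",
      signif(min(v, na.rm = TRUE), 4), ", ",
      signif(max(v, na.rm = TRUE), 4), "]\n", sep = "")
})
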