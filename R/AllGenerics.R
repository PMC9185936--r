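#' @rdname LxTDesign-class
#' @param object an object.
#' @export
setGeneric("designLines", function(object) standardGeneric("designLines"))

#' @rdname LxTDesign-class
#' @export
setGeneric("designTesters", function(object) standardGeneric("designTesters"))

#' @rdname LxTDesign-class
#' @export
setGeneric("designChecks", function(object) standardGeneric("designChecks"))

#' @rdname LxTDesign-class
#' @export
setGeneric("testerCross", function(object) standardGeneric("testerCross"))

#' @rdname TrialData-class
#' @param object an object.
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname TrialData-class
#' @export
setGeneric("trialDesign", function(object) standardGeneric("trialDesign"))

#' @rdname TrialData-class
#' @export
setGeneric("traitNames", function(object) standardGeneric("traitNames"))

#' @rdname CombiningAbility-class
#' @param object an object.
#' @export
setGeneric("gcaLine", function(object) standardGeneric("gcaLine"))

#' @rdname CombiningAbility-class
#' @export
setGeneric("gcaTester", function(object) standardGeneric("gcaTester"))

#' @rdname CombiningAbility-class
#' @export
setGeneric("scaEffects", function(object) standardGeneric("scaEffects"))

#' Heterotic-group-specific combining ability
#'
#' HSGCA for line i with tester j is `gca_line[i] + sca[i, j]`; in balanced
#' data it equals the i x j testcross mean minus the mean of all testcrosses
#' with tester j, so it measures how a line combines with one specific
#' tester's heterotic group.
#'
#' @param object a [CombiningAbility-class] object.
#' @return numeric matrix, lines x testers, in trait units.
#' @examples
#' sim <- simulateTrial(trialSimConfig(nLines = 4), seed = 1)
#' ca <- estimateGcaSca(sim$trial, "grain_yield", "non_infested")
#' hsgcaEffects(ca)
#' @export
setGeneric("hsgcaEffects", function(object) standardGeneric("hsgcaEffects"))

#' @rdname GenotypePanel
#' @param object an object.
#' @export
setGeneric("dosage", function(object) standardGeneric("dosage"))

#' @rdname GenotypePanel
#' @export
setGeneric("markerMap", function(object) standardGeneric("markerMap"))

#' @rdname filterMarkers
#' @param object an object.
#' @export
setGeneric("qcReport", function(object) standardGeneric("qcReport"))

#' @rdname GenotypeDistance-class
#' @param object an object.
#' @export
setGeneric("distanceMatrix", function(object) standardGeneric("distanceMatrix"))

#' @rdname GenotypeDistance-class
#' @export
setGeneric("pairCounts", function(object) standardGeneric("pairCounts"))

#' @rdname VarianceComponents-class
#' @param object an object.
#' @export
setGeneric("varianceComponents",
           function(object) standardGeneric("varianceComponents"))
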