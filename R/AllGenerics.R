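#' Parameter vector of an MSC-M model
#'
#' Collects every model parameter into a single named numeric vector
#' \eqn{\Theta}: node ages as \code{tau_<label>} (internal nodes only; tip
#' ages are identically 0), population sizes as \code{theta_<label>}, and
#' migration rates as \code{M_<donor>_<recipient>}.  The same naming scheme
#' is used by [updateModelParams()], by posterior-sample tables and by
#' fixed-parameter backends, so a vector returned here can be fed back
#' unchanged.
#'
#' @param object an [MSCMModel-class].
#' @return named numeric vector.
#' @export
setGeneric("paramVector", function(object) standardGeneric("paramVector"))

#' Tip (population) labels
#' @param object a [SpeciesTree-class] or [MSCMModel-class].
#' @return character vector of tip labels in tree order.
#' @export
setGeneric("tipLabels", function(object) standardGeneric("tipLabels"))

#' Extract the species tree of a model
#' @param object an [MSCMModel-class].
#' @return the [SpeciesTree-class].
#' @export
setGeneric("guideTree", function(object) standardGeneric("guideTree"))

#' Migration events of a model
#' @param object an [MSCMModel-class].
#' @return data.frame with columns donor, recipient, rate.
#' @export
setGeneric("migrations", function(object) standardGeneric("migrations"))

#' Node ages (tau, in expected mutations per site)
#' @param object a [SpeciesTree-class] or [MSCMModel-class].
#' @param label optional label(s); default all nodes.
#' @return named numeric vector.
#' @export
setGeneric("tauOf", function(object, label) standardGeneric("tauOf"))

#' Population-size parameters (theta = 4N mu)
#' @param object a [SpeciesTree-class] or [MSCMModel-class].
#' @param label optional label(s); default all nodes.
#' @return named numeric vector.
#' @export
setGeneric("thetaOf", function(object, label) standardGeneric("thetaOf"))

#' Selected gdi value of a result
#' @param object a [GdiResult-class] or [SimEstimate-class].
#' @param definition \code{"gdiJ"} or \code{"gdiK"}.
#' @return numeric scalar.
#' @export
setGeneric("gdiValue",
  function(object, definition = c("gdiK", "gdiJ")) standardGeneric("gdiValue"))

#' Current species of a delimitation state
#' @param object a [DelimitationState-class].
#' @return named list: species label -> character vector of the original
#'   populations it contains.
#' @export
setGeneric("speciesAssignment",
  function(object) standardGeneric("speciesAssignment"))

#' Iteration log of a delimitation run
#' @param object a [DelimitationState-class].
#' @return data.frame, one row per proposal.
#' @export
setGeneric("iterationLog", function(object) standardGeneric("iterationLog"))
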