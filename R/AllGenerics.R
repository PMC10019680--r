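#' @rdname MetabolicNetwork-class
#' @param x,object a package object
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' @rdname MetabolicNetwork-class
#' @export
setGeneric("elasticityPattern", function(x) standardGeneric("elasticityPattern"))

#' @rdname MetaboliteProfiles-class
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname MetaboliteProfiles-class
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname JacobianEnsemble-class
#' @export
setGeneric("medianJacobian", function(x) standardGeneric("medianJacobian"))

#' @rdname JacobianEnsemble-class
#' @export
setGeneric("iqrJacobian", function(x) standardGeneric("iqrJacobian"))

#' @rdname JacobianEnsemble-class
#' @export
setGeneric("sparsityMask", function(x) standardGeneric("sparsityMask"))

#' @rdname DifferentialJacobian-class
#' @export
setGeneric("ranking", function(x) standardGeneric("ranking"))

#' Variable importance on projection
#'
#' @param model a fitted [LatentModel-class] of kind `"plsda"` or `"oplsda"`.
#' @return named numeric vector of VIP scores, one per metabolite; the
#'   squared scores sum to the number of metabolites.
#' @export
setGeneric("vipScores", function(model) standardGeneric("vipScores"))
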