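#' @rdname GenotypeMatrix-class
#' @param x a \linkS4class{GenotypeMatrix}
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname RiskSet-class
#' @param x a \linkS4class{RiskSet}
#' @export
setGeneric("riskSetEntries", function(x) standardGeneric("riskSetEntries"))

#' @rdname RiskSet-class
#' @export
setGeneric("riskSetAudit", function(x) standardGeneric("riskSetAudit"))

#' @rdname RiskSet-class
#' @export
setGeneric("riskSetTrait", function(x) standardGeneric("riskSetTrait"))

#' @rdname RiskSet-class
#' @export
setGeneric("riskSetApproach", function(x) standardGeneric("riskSetApproach"))

#' @rdname PrsVector-class
#' @param x a \linkS4class{PrsVector}
#' @export
setGeneric("prsScores", function(x) standardGeneric("prsScores"))

#' @rdname PrsVector-class
#' @export
setGeneric("prsAudit", function(x) standardGeneric("prsAudit"))

#' @rdname EffectMatrix-class
#' @param x an \linkS4class{EffectMatrix}
#' @export
setGeneric("effectValues", function(x) standardGeneric("effectValues"))

#' @rdname EffectMatrix-class
#' @export
setGeneric("sourceTrait", function(x) standardGeneric("sourceTrait"))
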