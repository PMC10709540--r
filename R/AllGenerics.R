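#' @rdname GeneticMap-accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname GeneticMap-accessors
#' @export
setGeneric("nTraits", function(x) standardGeneric("nTraits"))

#' @rdname GeneticMap-accessors
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' @rdname GeneticMap-accessors
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname GeneticMap-accessors
#' @export
setGeneric("markerEffects", function(x) standardGeneric("markerEffects"))

#' @rdname GeneticMap-accessors
#' @export
setGeneric("recombProb", function(x) standardGeneric("recombProb"))

#' @rdname GeneticMap-accessors
#' @export
setGeneric("mapPositions", function(x) standardGeneric("mapPositions"))

#' @rdname GeneticMap-accessors
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname GeneticMap-accessors
#' @export
setGeneric("heritability<-", function(x, value) standardGeneric("heritability<-"))

#' @rdname Population-accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname Population-accessors
#' @export
setGeneric("genome", function(x) standardGeneric("genome"))

#' @rdname Population-accessors
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))

#' @rdname Population-accessors
#' @export
setGeneric("ids", function(x) standardGeneric("ids"))

#' @rdname gebv
#' @export
setGeneric("gebv", function(pop, map, ...) standardGeneric("gebv"))
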