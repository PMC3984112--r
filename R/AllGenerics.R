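#' @export
setGeneric("formatJunction", function(x, ...) standardGeneric("formatJunction"))

#' @export
setGeneric("featuresOf", function(x, gene, ...) standardGeneric("featuresOf"))

#' @export
setGeneric("collapseBySymbol", function(x, ...) standardGeneric("collapseBySymbol"))

#' @export
setGeneric("writeRefGene", function(x, path, ...) standardGeneric("writeRefGene"))

#' @export
setGeneric("templateSequences", function(x, ...) standardGeneric("templateSequences"))
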