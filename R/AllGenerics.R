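#' @rdname CaTrace-class
#' @param x an object
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' @rdname CaTrace-class
#' @param collapse return the sequence as a single string?
#' @export
setGeneric("caSequence", function(x, collapse = FALSE)
  standardGeneric("caSequence"))

#' @rdname CaTrace-class
#' @export
setGeneric("residueIds", function(x) standardGeneric("residueIds"))

#' @rdname CaTrace-class
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname ProteinizeResult-class
#' @param x an object
#' @export
setGeneric("totalScore", function(x) standardGeneric("totalScore"))

#' @rdname ProteinizeResult-class
#' @export
setGeneric("isFeasible", function(x) standardGeneric("isFeasible"))

#' @rdname MorphResult-class
#' @param x an object
#' @export
setGeneric("morphFrames", function(x) standardGeneric("morphFrames"))

#' @rdname MorphResult-class
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))

#' @rdname ProteinLikenessReport-class
#' @param x an object
#' @export
setGeneric("isProteinLike", function(x) standardGeneric("isProteinLike"))

#' @rdname Lattice-class
#' @param x an object
#' @export
setGeneric("latticeVertices", function(x) standardGeneric("latticeVertices"))

#' @rdname Lattice-class
#' @export
setGeneric("latticeSize", function(x) standardGeneric("latticeSize"))
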