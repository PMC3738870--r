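#' Construct a CaTrace
#'
#' @param coords numeric n x 3 matrix of C-alpha coordinates (Angstrom).
#' @param sequence one-letter amino-acid codes: either a single string of
#'   length n or a character vector of n single letters. Defaults to all
#'   \code{"A"}.
#' @param chain chain identifier(s) recycled to length n.
#' @param resno residue numbers (default \code{1:n}).
#' @param insert insertion codes (default empty).
#' @param resIds optional data.frame with columns chain/resno/insert,
#'   overriding the three arguments above.
#' @return a [CaTrace-class] object.
#' @examples
#' tr <- CaTrace(cbind(seq(0, 38, by = 3.8), 0, 0))
#' nResidues(tr)
#' @export
CaTrace <- function(coords, sequence = NULL, chain = "A", resno = NULL,
                    insert = "", resIds = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (is.null(sequence)) sequence <- rep("A", n)
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  if (is.null(resIds)) {
    if (is.null(resno)) resno <- seq_len(n)
    resIds <- data.frame(chain = rep_len(as.character(chain), n),
                         resno = as.integer(resno),
                         insert = rep_len(as.character(insert), n),
                         stringsAsFactors = FALSE)
  }
  dimnames(coords) <- NULL
  new("CaTrace", coords = coords, resIds = resIds,
      sequence = as.character(sequence))
}

#' @rdname CaTrace-class
#' @export
setMethod("caCoords", "CaTrace", function(x) x@coords)

#' @rdname CaTrace-class
#' @export
setMethod("caSequence", "CaTrace", function(x, collapse = FALSE) {
  if (collapse) paste(x@sequence, collapse = "") else x@sequence
})

#' @rdname CaTrace-class
#' @export
setMethod("residueIds", "CaTrace", function(x) x@resIds)

#' @rdname CaTrace-class
#' @export
setMethod("nResidues", "CaTrace", function(x) nrow(x@coords))

#' @rdname CaTrace-class
#' @export
setMethod("length", "CaTrace", function(x) nrow(x@coords))

#' @rdname CaTrace-class
#' @param i integer or logical index of residues to keep (in order).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CaTrace", function(x, i, j, ..., drop = FALSE) {
  new("CaTrace", coords = x@coords[i, , drop = FALSE],
      resIds = x@resIds[i, , drop = FALSE],
      sequence = x@sequence[i])
})

#' Replace the coordinates of a trace, keeping residue metadata
#'
#' @param trace a [CaTrace-class].
#' @param coords replacement n x 3 matrix.
#' @return a [CaTrace-class] with the new coordinates.
#' @export
setCoords <- function(trace, coords) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  new("CaTrace", coords = coords, resIds = trace@resIds,
      sequence = trace@sequence)
}

setMethod("show", "CaTrace", function(object) {
  n <- nrow(object@coords)
  cat("CaTrace with", n, "residues\n")
  cat("  chains:", paste(unique(object@resIds$chain), collapse = ", "), "\n")
  s <- paste(object@sequence, collapse = "")
  if (nchar(s) > 50) s <- paste0(substr(s, 1, 47), "...")
  cat("  sequence:", s, "\n")
})

setMethod("show", "AlignedPair", function(object) {
  cat("AlignedPair of", nrow(object@start@coords), "aligned positions;",
      sum(object@brokenEdge), "broken edge(s)\n")
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 4))
  cat("  translation:", paste(round(object@translation, 4), collapse = " "),
      "\n")
})

setMethod("show", "Lattice", function(object) {
  cat("Lattice of", nrow(object@vertices), "vertices, edge",
      object@edgeLength, "A, density", object@density, "points/A\n")
})

setMethod("show", "ProteinizeResult", function(object) {
  if (object@feasible)
    cat("ProteinizeResult (", object@strategy, "): feasible, score ",
        format(object@totalScore), ", edge ", object@edgeLength, " A\n",
        sep = "")
  else
    cat("ProteinizeResult (", object@strategy, "): infeasible at edge ",
        object@edgeLength, " A\n", sep = "")
})

setMethod("show", "MorphResult", function(object) {
  k <- length(object@frames) - 2L
  cat("MorphResult:", k, "intermediate frame(s) +",
      "start/end,", nrow(object@frames[[1L]]@coords), "residues\n")
  cat("  strategy:", object@config@strategy, " edges used:",
      paste(unique(object@diagnostics$edgeLength), collapse = ", "), "\n")
})

setMethod("show", "ProteinLikenessReport", function(object) {
  ok <- c(equidistant = object@passEquidistant, angles = object@passAngles,
          clash = object@passClash)
  cat("ProteinLikenessReport:",
      if (all(ok)) "protein-like" else "NOT protein-like", "\n")
  cat("  ", paste(names(ok), ifelse(ok, "pass", "FAIL"), collapse = "; "),
      "\n")
  if (nrow(object@clashes))
    cat("  ", nrow(object@clashes), "clash pair(s)\n")
})

#' @rdname ProteinizeResult-class
#' @export
setMethod("totalScore", "ProteinizeResult", function(x) x@totalScore)

#' @rdname ProteinizeResult-class
#' @export
setMethod("isFeasible", "ProteinizeResult", function(x) x@feasible)

#' @rdname MorphResult-class
#' @export
setMethod("morphFrames", "MorphResult", function(x) x@frames)

#' @rdname MorphResult-class
#' @export
setMethod("diagnostics", "MorphResult", function(x) x@diagnostics)

#' @rdname ProteinLikenessReport-class
#' @export
setMethod("isProteinLike", "ProteinLikenessReport", function(x)
  x@passEquidistant && x@passAngles && x@passClash)

#' @rdname Lattice-class
#' @export
setMethod("latticeVertices", "Lattice", function(x) x@vertices)

#' @rdname Lattice-class
#' @export
setMethod("latticeSize", "Lattice", function(x) nrow(x@vertices))
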