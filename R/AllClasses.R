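#' @import methods
NULL

#' CaTrace: an ordered C-alpha trace
#'
#' Container for a protein chain reduced to its C-alpha atoms: an ordered
#' \code{n x 3} coordinate matrix (Angstrom), per-residue identifiers
#' (chain, residue number, insertion code) and the one-letter amino-acid
#' sequence. This is the sole representation of a structure used throughout
#' the package.
#'
#' @slot coords numeric matrix, one row per residue, columns x/y/z in Angstrom.
#' @slot resIds data.frame with columns \code{chain}, \code{resno},
#'   \code{insert}, one row per residue.
#' @slot sequence character vector of one-letter amino-acid codes, one per
#'   residue (\code{"X"} for non-standard residues).
#'
#' @seealso [readCaTrace()], [generateChain()], [caCoords()]
#' @export
setClass("CaTrace",
  representation(coords = "matrix", resIds = "data.frame",
                 sequence = "character"),
  validity = function(object) {
    n <- nrow(object@coords)
    if (n < 2L) return("a CaTrace needs at least 2 residues")
    if (ncol(object@coords) != 3L) return("coords must have 3 columns")
    if (!all(is.finite(object@coords))) return("coordinates must be finite")
    if (length(object@sequence) != n) return("sequence length != nrow(coords)")
    if (nrow(object@resIds) != n) return("resIds rows != nrow(coords)")
    if (!all(c("chain", "resno", "insert") %in% names(object@resIds)))
      return("resIds must have columns chain, resno, insert")
    TRUE
  })

#' AlignedPair: two equal-length traces plus gap-adjacency flags
#'
#' The output of alignment-based preprocessing: the starting and ending
#' traces restricted to aligned positions, plus flags marking where adjacent
#' alignment columns are not consecutive residues in the original starting
#' structure. Distance and angle constraints are relaxed ("free") at flagged
#' positions during proteinization.
#'
#' @slot start,end [CaTrace-class] objects of equal length \code{n}.
#' @slot brokenEdge logical of length \code{n - 1}; TRUE where positions
#'   j, j+1 are non-consecutive in the original start structure.
#' @slot brokenAngle logical of length \code{n}; TRUE where either flanking
#'   pair is non-consecutive. The two termini are TRUE by convention (no
#'   pseudo-bond angle is defined there).
#'
#' @seealso [restrictToAligned()], [preprocessPair()]
#' @export
setClass("AlignedPair",
  representation(start = "CaTrace", end = "CaTrace",
                 brokenEdge = "logical", brokenAngle = "logical"),
  validity = function(object) {
    n <- nrow(object@start@coords)
    if (nrow(object@end@coords) != n) return("start and end lengths differ")
    if (length(object@brokenEdge) != n - 1L)
      return("brokenEdge must have length n - 1")
    if (length(object@brokenAngle) != n)
      return("brokenAngle must have length n")
    if (!object@brokenAngle[1L] || !object@brokenAngle[n])
      return("brokenAngle must be TRUE at both termini")
    TRUE
  })

#' RigidTransform: a proper rotation plus translation
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric 3-vector (Angstrom).
#'
#' @seealso [kabschSuperpose()], [applyTransform()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
    if (abs(det(R) - 1) > 1e-9) return("rotation determinant must be +1")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      return("rotation must be orthonormal")
    if (length(object@translation) != 3L)
      return("translation must have length 3")
    TRUE
  })

#' Lattice: candidate vertices around one interpolated point
#'
#' An axis-aligned cubic grid of candidate C-alpha positions centered on one
#' interpolated point. Grid spacing is \code{1/density} Angstrom and the grid
#' extends \code{h = floor(edgeLength * density / 2)} steps per side along
#' each axis, so the per-axis point count is the odd number \code{2h + 1} and
#' the center is always a grid point. Vertices are ordered lexicographically
#' by (x, y, z) offset, which fixes tie-breaking downstream.
#'
#' @slot center numeric 3-vector: the interpolated point.
#' @slot vertices Q x 3 matrix of candidate positions (the center included).
#' @slot edgeLength requested cube edge, Angstrom.
#' @slot density grid points per linear Angstrom.
#'
#' @seealso [buildLattice()]
#' @export
setClass("Lattice",
  representation(center = "numeric", vertices = "matrix",
                 edgeLength = "numeric", density = "numeric"),
  validity = function(object) {
    if (length(object@center) != 3L) return("center must have length 3")
    if (ncol(object@vertices) != 3L) return("vertices must have 3 columns")
    d <- sqrt(colSums((t(object@vertices) - object@center)^2))
    if (min(d) > 1e-9) return("center must be one of the vertices")
    half <- object@edgeLength / 2 * sqrt(3)
    if (max(d) > half + 1e-9)
      return("vertices exceed half the lattice diagonal")
    TRUE
  })

#' ScoreParams: geometric constraints defining a protein-like chain
#'
#' Parameters of the three scoring terms used by the dynamic program and the
#' validator: the consecutive C-alpha distance window
#' \code{[targetDist - tol, targetDist + tol]}, the pseudo-bond angle window
#' \code{[angleLow, angleHigh]} in degrees, and the steric clash distance
#' \code{clashDist} with its soft penalty multiplier.
#'
#' @slot targetDist ideal consecutive C-alpha distance, Angstrom (3.8).
#' @slot tol distance tolerance, Angstrom (0.1).
#' @slot angleLow,angleHigh pseudo-bond angle window, degrees (70, 120).
#' @slot clashDist minimum allowed distance between non-consecutive residues,
#'   Angstrom (2.0).
#' @slot clashPenalty multiplier of the inverse-square proximity penalty (100).
#' @slot clashTrigger \code{"proximity"} (penalize vertices within
#'   \code{clashDist} of an earlier lattice center) or \code{"literal"}
#'   (penalize vertices within \code{clashDist} of their own center).
#'
#' @seealso [scoreParams()]
#' @export
setClass("ScoreParams",
  representation(targetDist = "numeric", tol = "numeric",
                 angleLow = "numeric", angleHigh = "numeric",
                 clashDist = "numeric", clashPenalty = "numeric",
                 clashTrigger = "character"),
  validity = function(object) {
    if (object@tol < 0 || object@targetDist <= 0)
      return("targetDist must be positive and tol non-negative")
    if (object@angleLow >= object@angleHigh)
      return("angleLow must be < angleHigh")
    if (object@clashDist <= 0) return("clashDist must be positive")
    if (!object@clashTrigger %in% c("proximity", "literal"))
      return("clashTrigger must be 'proximity' or 'literal'")
    TRUE
  })

#' ProteinizeResult: outcome of one lattice dynamic-programming correction
#'
#' @slot points n x 3 matrix: the corrected sequence if \code{feasible},
#'   otherwise the input points.
#' @slot totalScore summed vertex/edge/angle score of the optimal lattice
#'   path; \code{Inf} when infeasible.
#' @slot feasible logical: did a finite-score path exist?
#' @slot vertexIndex integer vector of chosen lattice vertex indices
#'   (1-based), length n when feasible.
#' @slot strategy which recurrence produced the result.
#' @slot edgeLength,density lattice parameters used.
#'
#' @seealso [proteinize()]
#' @export
setClass("ProteinizeResult",
  representation(points = "matrix", totalScore = "numeric",
                 feasible = "logical", vertexIndex = "integer",
                 strategy = "character", edgeLength = "numeric",
                 density = "numeric"),
  validity = function(object) {
    if (object@feasible && !is.finite(object@totalScore))
      return("feasible result must have a finite totalScore")
    if (object@totalScore < 0) return("totalScore must be non-negative")
    TRUE
  })

#' MorphConfig: settings for a morph run
#'
#' @slot K requested number of intermediate structures; \code{NA} means
#'   automatic (rounded largest C-alpha displacement, floored at 1).
#' @slot strategy \code{"simplified"} (default), \code{"basic"} or
#'   \code{"advanced"} dynamic-programming recurrence.
#' @slot edgeSchedule ascending lattice edge lengths tried per frame until a
#'   feasible correction is found (default 1.0, 1.5, 2.0 Angstrom).
#' @slot density lattice points per linear Angstrom (default 6).
#' @slot schedule \code{"remaining"}: each target moves a fraction
#'   1/(K - k + 2) of the current remaining gap toward the end conformation;
#'   \code{"fixed"}: targets are alpha-intermediates of the original
#'   endpoints at alpha = k/(K + 1).
#' @slot rounding rule converting the maximum displacement into K:
#'   \code{"half-away"} (round half away from zero) or \code{"truncate"}.
#' @slot params [ScoreParams-class] used for scoring and validation.
#'
#' @seealso [morphConfig()], [runMorph()]
#' @export
setClass("MorphConfig",
  representation(K = "numeric", strategy = "character",
                 edgeSchedule = "numeric", density = "numeric",
                 schedule = "character", rounding = "character",
                 params = "ScoreParams"),
  validity = function(object) {
    if (!is.na(object@K) && (object@K < 1 || object@K != round(object@K)))
      return("explicit K must be a positive integer")
    if (length(object@edgeSchedule) < 1L ||
        is.unsorted(object@edgeSchedule, strictly = TRUE))
      return("edgeSchedule must be non-empty and strictly ascending")
    if (!object@strategy %in% c("basic", "advanced", "simplified"))
      return("unknown strategy")
    if (!object@schedule %in% c("remaining", "fixed"))
      return("schedule must be 'remaining' or 'fixed'")
    if (!object@rounding %in% c("half-away", "truncate"))
      return("rounding must be 'half-away' or 'truncate'")
    TRUE
  })

#' MorphResult: a complete morph trajectory
#'
#' @slot frames list of [CaTrace-class]: the aligned start structure, the K
#'   protein-like intermediates, and the (superposed) end structure, in order.
#' @slot diagnostics data.frame with one row per intermediate frame: the
#'   lattice edge length used, the DP score, and distances of the
#'   interpolation target and corrected frame to the end structure.
#' @slot config the [MorphConfig-class] that produced the morph (K resolved).
#'
#' @seealso [runMorph()], [writeMorphPdb()]
#' @export
setClass("MorphResult",
  representation(frames = "list", diagnostics = "data.frame",
                 config = "MorphConfig"),
  validity = function(object) {
    if (length(object@frames) < 3L)
      return("a morph has at least start, one intermediate, and end")
    if (!all(vapply(object@frames, is, logical(1), "CaTrace")))
      return("frames must all be CaTrace objects")
    n <- vapply(object@frames, function(f) nrow(f@coords), integer(1))
    if (length(unique(n)) != 1L) return("frames must all have equal length")
    TRUE
  })

#' ProteinLikenessReport: validation of one trace against all three criteria
#'
#' A chain is protein-like when consecutive distances lie in
#' \code{[3.7, 3.9]} Angstrom, interior pseudo-bond angles lie in
#' \code{[70, 120]} degrees, and no two non-consecutive residues come closer
#' than 2.0 Angstrom. Positions flagged as broken (alignment gaps, termini)
#' are exempt from the distance/angle criteria but still reported.
#'
#' @slot distances consecutive distances, length n - 1, Angstrom.
#' @slot angles interior vertex angles, length n, degrees; NA at termini.
#' @slot clashes data.frame (i, j, dist) of non-consecutive pairs closer
#'   than the clash distance.
#' @slot brokenEdge,brokenAngle the exemption flags used.
#' @slot passEquidistant,passAngles,passClash per-criterion outcomes.
#' @slot params the [ScoreParams-class] checked against.
#'
#' @seealso [checkProteinLike()], [isProteinLike()]
#' @export
setClass("ProteinLikenessReport",
  representation(distances = "numeric", angles = "numeric",
                 clashes = "data.frame", brokenEdge = "logical",
                 brokenAngle = "logical", passEquidistant = "logical",
                 passAngles = "logical", passClash = "logical",
                 params = "ScoreParams"))
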