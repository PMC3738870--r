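#' Scoring parameters
#'
#' Constructs the [ScoreParams-class] holding the geometric constants that
#' define a protein-like C-alpha chain. The defaults encode what is observed
#' in real protein structures: consecutive C-alpha atoms 3.8 +/- 0.1 A apart,
#' pseudo-bond angles between 70 and 120 degrees, and no two non-consecutive
#' C-alpha atoms within 2.0 A of each other.
#'
#' @param targetDist ideal consecutive C-alpha distance (A).
#' @param tol tolerance around \code{targetDist} (A).
#' @param angleLow,angleHigh pseudo-bond angle window (degrees).
#' @param clashDist steric clash distance z (A).
#' @param clashPenalty multiplier of the soft inverse-square proximity
#'   penalty added to vertex scores near earlier lattice centers.
#' @param clashTrigger when to add the proximity penalty: \code{"proximity"}
#'   (the vertex lies within \code{clashDist} of some earlier lattice center;
#'   default) or \code{"literal"} (the vertex lies within \code{clashDist} of
#'   its \emph{own} center).
#' @return a [ScoreParams-class].
#' @export
scoreParams <- function(targetDist = 3.8, tol = 0.1, angleLow = 70,
                        angleHigh = 120, clashDist = 2.0, clashPenalty = 100,
                        clashTrigger = c("proximity", "literal")) {
  new("ScoreParams", targetDist = targetDist, tol = tol, angleLow = angleLow,
      angleHigh = angleHigh, clashDist = clashDist,
      clashPenalty = clashPenalty, clashTrigger = match.arg(clashTrigger))
}

.distWindow <- function(params)
  c(params@targetDist - params@tol, params@targetDist + params@tol)

#' Edge score: the hard consecutive-distance constraint
#'
#' Zero when the distance between \code{u} and \code{w} lies inside the
#' closed window \code{[targetDist - tol, targetDist + tol]} (3.7--3.9 A by
#' default) or when the edge is broken (an alignment gap, so no physical
#' bond); \code{Inf} otherwise.
#'
#' @param u,w 3-D points.
#' @param broken is this edge exempt (gap-adjacent)?
#' @param params a [ScoreParams-class].
#' @return 0 or \code{Inf}.
#' @export
eScore <- function(u, w, broken = FALSE, params = scoreParams()) {
  if (broken) return(0)
  d <- sqrt(sum((u - w)^2))
  w2 <- .distWindow(params)
  if (d >= w2[1L] && d <= w2[2L]) 0 else Inf
}

#' Vertex score: squared displacement plus soft proximity penalty
#'
#' The base score is the squared distance of a candidate vertex to its own
#' lattice center, so the dynamic program prefers solutions close to the
#' interpolated points. To discourage steric clashes, vertices near the
#' lattice centers of \emph{earlier} chain positions (positions 1..j-2) are
#' additionally charged \code{clashPenalty * sum(d^-2)} over those centers
#' whenever the trigger condition holds (see [scoreParams()]). A vertex
#' coinciding with an earlier center scores \code{Inf}.
#'
#' @param v candidate 3-D point.
#' @param ownCenter the lattice center of \code{v}'s own position.
#' @param earlierCenters matrix (possibly 0-row) of centers of positions
#'   1..j-2, or NULL.
#' @param params a [ScoreParams-class].
#' @return a non-negative score.
#' @export
vScore <- function(v, ownCenter, earlierCenters = NULL,
                   params = scoreParams()) {
  base <- sum((v - ownCenter)^2)
  if (is.null(earlierCenters) || NROW(earlierCenters) == 0L)
    return(base)
  earlierCenters <- matrix(earlierCenters, ncol = 3L)
  d2 <- rowSums(sweep(earlierCenters, 2L, v)^2)
  if (any(d2 == 0)) return(Inf)
  trig <- if (params@clashTrigger == "literal")
    sqrt(base) <= params@clashDist
  else
    min(sqrt(d2)) <= params@clashDist
  if (trig) base + params@clashPenalty * sum(1 / d2) else base
}

#' Pseudo-bond angle at a point
#'
#' By default returns the vertex angle at \code{p2} between the segments to
#' \code{p1} and \code{p3}, in \code{[0, 180]} degrees -- the quantity
#' checked against the 70--120 degree window. With \code{lines = TRUE} the
#' minor angle between the two \emph{lines} through (p1, p2) and (p2, p3) is
#' returned instead, in \code{[0, 90]} degrees; the two readings are
#' supplementary-folded versions of each other.
#'
#' @param p1,p2,p3 3-D points; both arms at \code{p2} must be non-degenerate.
#' @param lines return the minor line angle instead of the vertex angle?
#' @return angle in degrees.
#' @examples
#' angDeg(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))              # 90
#' angDeg(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))              # 180 (vertex)
#' angDeg(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), lines = TRUE) # 0 (lines)
#' @export
angDeg <- function(p1, p2, p3, lines = FALSE) {
  u <- p1 - p2
  w <- p3 - p2
  nu <- sqrt(sum(u^2))
  nw <- sqrt(sum(w^2))
  if (nu == 0 || nw == 0)
    stop("degenerate angle: coincident points", call. = FALSE)
  ct <- sum(u * w) / (nu * nw)
  ct <- min(1, max(-1, ct))
  ang <- acos(ct) * 180 / pi
  if (lines && ang > 90) 180 - ang else ang
}

#' Angle score: the hard pseudo-bond angle constraint
#'
#' Zero when the vertex angle at \code{p2} lies in the closed window
#' \code{[angleLow, angleHigh]} (70--120 degrees by default) or when the
#' angle position is broken (gap-adjacent); \code{Inf} otherwise.
#'
#' @param p1,p2,p3 3-D points.
#' @param broken is the angle at this position exempt?
#' @param params a [ScoreParams-class].
#' @return 0 or \code{Inf}.
#' @export
aScore <- function(p1, p2, p3, broken = FALSE, params = scoreParams()) {
  if (broken) return(0)
  ang <- angDeg(p1, p2, p3)
  if (ang >= params@angleLow && ang <= params@angleHigh) 0 else Inf
}
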