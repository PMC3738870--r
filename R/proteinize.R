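.asPoints <- function(points) {
  if (is(points, "CaTrace")) points <- caCoords(points)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  points
}

.defaultFlags <- function(n, brokenEdge, brokenAngle) {
  if (is.null(brokenEdge)) brokenEdge <- rep(FALSE, n - 1L)
  if (is.null(brokenAngle))
    brokenAngle <- c(TRUE, brokenEdge[-(n - 1L)] | brokenEdge[-1L], TRUE)
  stopifnot(length(brokenEdge) == n - 1L, length(brokenAngle) == n)
  list(edge = brokenEdge, angle = brokenAngle)
}

.wrapResult <- function(res, points, strategy, edgeLength, density) {
  feasible <- isTRUE(res$feasible)
  new("ProteinizeResult",
      points = if (feasible) res$points else points,
      totalScore = res$score, feasible = feasible,
      vertexIndex = if (feasible) as.integer(res$index) else integer(0),
      strategy = strategy, edgeLength = edgeLength, density = density)
}

#' Snap a point sequence onto the closest protein-like lattice path
#'
#' Solves the discretized optimal equidistant sequence problem: around every
#' input point a local cubic lattice of candidate positions is built, and a
#' dynamic program selects one vertex per lattice so that the resulting chain
#' satisfies the protein-likeness constraints while minimizing the summed
#' squared displacement from the input points.
#'
#' Three recurrences are available:
#' \describe{
#'   \item{basic}{consecutive-distance constraint only; exact optimum of the
#'     discretized problem in O(nQ^2).}
#'   \item{advanced}{distance, angle and proximity-penalized vertex scores,
#'     optimized exactly over (current, previous) vertex-pair states in
#'     O(nQ^3). For n = 2 no angle exists and the basic recurrence (with
#'     clash-penalized vertex scores) is used.}
#'   \item{simplified}{the default: same constraints as advanced, but the
#'     angle at each step is checked against the predecessor stored on the
#'     best path into the previous vertex, keeping the cost at O(nQ^2). Any
#'     structure it produces satisfies all constraints, but it may be
#'     suboptimal, or fail on instances the advanced recurrence can solve.}
#' }
#'
#' Edges/angles flagged as broken (alignment gaps) are exempt from the hard
#' constraints. When no finite-score path exists the result has
#' \code{isFeasible(x) == FALSE}; callers typically retry with a larger
#' lattice edge (see [runMorph()]).
#'
#' @param points n x 3 matrix or [CaTrace-class] (n >= 2).
#' @param brokenEdge,brokenAngle optional gap flags (lengths n-1 and n); by
#'   default no edge is broken and only the termini have no angle.
#' @param params a [ScoreParams-class].
#' @param strategy \code{"simplified"}, \code{"basic"} or \code{"advanced"}.
#' @param edgeLength lattice cube edge (A).
#' @param density lattice points per linear Angstrom.
#' @return a [ProteinizeResult-class].
#' @seealso [bruteForceOesp()] for the exhaustive reference implementation.
#' @examples
#' p <- cbind(c(0, 4, 8), 0, 0)   # spacing 4.0 A: slightly too long
#' res <- proteinize(p, strategy = "basic", edgeLength = 1, density = 6)
#' diff(caCoords(CaTrace(res@points))[, 1])   # back inside [3.7, 3.9]
#' @export
proteinize <- function(points, brokenEdge = NULL, brokenAngle = NULL,
                       params = scoreParams(),
                       strategy = c("simplified", "basic", "advanced"),
                       edgeLength = 1.0, density = 6) {
  strategy <- match.arg(strategy)
  points <- .asPoints(points)
  n <- nrow(points)
  stopifnot(n >= 2L)
  fl <- .defaultFlags(n, brokenEdge, brokenAngle)
  lattices <- .latticeVertexList(points, edgeLength, density)
  w <- .distWindow(params)
  literal <- params@clashTrigger == "literal"
  res <- if (strategy == "advanced" && n >= 3L) {
    oespAdvancedCpp(lattices, points, fl$edge, fl$angle, w[1L], w[2L],
                    params@angleLow, params@angleHigh, params@clashDist,
                    params@clashPenalty, TRUE, literal)
  } else if (strategy == "basic") {
    oespDpCpp(lattices, points, fl$edge, fl$angle, w[1L], w[2L],
              params@angleLow, params@angleHigh, params@clashDist,
              params@clashPenalty, FALSE, FALSE, literal)
  } else {
    # simplified, or advanced at n = 2 (no angles; clash terms vacuous)
    oespDpCpp(lattices, points, fl$edge, fl$angle, w[1L], w[2L],
              params@angleLow, params@angleHigh, params@clashDist,
              params@clashPenalty, strategy == "simplified", TRUE, literal)
  }
  .wrapResult(res, points, strategy, edgeLength, density)
}

#' @rdname proteinize
#' @param ... passed on to [proteinize()].
#' @export
proteinizeBasic <- function(points, ...)
  proteinize(points, ..., strategy = "basic")

#' @rdname proteinize
#' @export
proteinizeAdvanced <- function(points, ...)
  proteinize(points, ..., strategy = "advanced")

#' @rdname proteinize
#' @export
proteinizeSimplified <- function(points, ...)
  proteinize(points, ..., strategy = "simplified")

#' Exhaustive reference solver for the lattice correction (test oracle)
#'
#' Enumerates every possible assignment of one vertex per lattice and scores
#' each complete chain from its definition: summed vertex scores (squared
#' displacement plus optional proximity penalty), hard distance-window edge
#' scores and hard angle-window scores, via the exported [vScore()],
#' [eScore()] and [aScore()] operations. Intended as an independent oracle
#' for the dynamic-programming strategies on tiny instances; refuses
#' instances with more than \code{10^7} candidate paths.
#'
#' @inheritParams proteinize
#' @param includeAngles score angles (as the advanced/simplified strategies
#'   do)? Set FALSE to mirror the basic strategy.
#' @param includeClash add the proximity penalty to vertex scores? Defaults
#'   to \code{includeAngles}.
#' @return a [ProteinizeResult-class] with strategy \code{"brute-force"}.
#' @export
bruteForceOesp <- function(points, brokenEdge = NULL, brokenAngle = NULL,
                           params = scoreParams(), edgeLength = 1.0,
                           density = 6, includeAngles = TRUE,
                           includeClash = includeAngles) {
  points <- .asPoints(points)
  n <- nrow(points)
  stopifnot(n >= 2L)
  fl <- .defaultFlags(n, brokenEdge, brokenAngle)
  lattices <- .latticeVertexList(points, edgeLength, density)
  Q <- nrow(lattices[[1L]])
  if (Q^n > 1e7)
    stop("instance too large for exhaustive enumeration (Q^n = ", Q^n, ")",
         call. = FALSE)
  # per-lattice vertex scores, straight from the exported operation
  V <- lapply(seq_len(n), function(j) {
    earlier <- if (includeClash && j >= 3L)
      points[seq_len(j - 2L), , drop = FALSE] else NULL
    vapply(seq_len(Q), function(i)
      vScore(lattices[[j]][i, ], points[j, ], earlier, params), numeric(1))
  })
  # per-edge score matrices
  E <- lapply(seq_len(n - 1L), function(j) {
    outer(seq_len(Q), seq_len(Q), Vectorize(function(h, i)
      eScore(lattices[[j]][h, ], lattices[[j + 1L]][i, ],
             fl$edge[j], params)))
  })
  # per-interior-position angle arrays [g, h, i]: the vertex-angle window
  # evaluated directly from its definition (vectorized per middle vertex)
  A <- if (includeAngles && n >= 3L) {
    lapply(2:(n - 1L), function(j) {
      arr <- array(0, dim = c(Q, Q, Q))
      if (!fl$angle[j]) {
        Lg <- lattices[[j - 1L]]
        Lh <- lattices[[j]]
        Li <- lattices[[j + 1L]]
        for (h in seq_len(Q)) {
          Ug <- sweep(Lg, 2L, Lh[h, ])
          Ui <- sweep(Li, 2L, Lh[h, ])
          ct <- (Ug %*% t(Ui)) /
            outer(sqrt(rowSums(Ug^2)), sqrt(rowSums(Ui^2)))
          ang <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
          ang[is.na(ang)] <- Inf   # degenerate arm: unreachable anyway
          arr[, h, ] <- ifelse(ang >= params@angleLow &
                                 ang <= params@angleHigh, 0, Inf)
        }
      }
      arr
    })
  } else NULL
  idx <- as.matrix(expand.grid(rep(list(seq_len(Q)), n),
                               KEEP.OUT.ATTRS = FALSE))
  score <- rep(0, nrow(idx))
  for (j in seq_len(n)) score <- score + V[[j]][idx[, j]]
  for (j in seq_len(n - 1L))
    score <- score + E[[j]][cbind(idx[, j], idx[, j + 1L])]
  if (!is.null(A))
    for (j in 2:(n - 1L))
      score <- score + A[[j - 1L]][cbind(idx[, j - 1L], idx[, j],
                                         idx[, j + 1L])]
  best <- which.min(score)   # Inf-only => which.min on all-Inf gives first
  if (!length(best) || !is.finite(score[best])) {
    res <- list(feasible = FALSE, score = Inf)
  } else {
    path <- idx[best, ]
    pts <- t(vapply(seq_len(n), function(j) lattices[[j]][path[j], ],
                    numeric(3)))
    res <- list(feasible = TRUE, score = score[best], points = pts,
                index = as.integer(path))
  }
  .wrapResult(res, points, "brute-force", edgeLength, density)
}
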