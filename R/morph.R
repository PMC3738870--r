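#' Morph configuration
#'
#' @param K number of intermediate structures, or \code{"auto"} (default):
#'   the rounded largest C-alpha displacement between the superposed start
#'   and end conformations, floored at 1.
#' @param strategy dynamic-programming recurrence used to correct each frame;
#'   see [proteinize()]. The simplified strategy is the default.
#' @param edgeSchedule ascending lattice edges (A) retried per frame until a
#'   feasible correction is found.
#' @param density lattice points per linear Angstrom.
#' @param schedule interpolation-target rule; see [MorphConfig-class].
#' @param rounding \code{"half-away"} or \code{"truncate"} for automatic K.
#' @param params a [ScoreParams-class].
#' @return a [MorphConfig-class].
#' @export
morphConfig <- function(K = "auto", strategy = c("simplified", "basic",
                                                 "advanced"),
                        edgeSchedule = c(1.0, 1.5, 2.0), density = 6,
                        schedule = c("remaining", "fixed"),
                        rounding = c("half-away", "truncate"),
                        params = scoreParams()) {
  if (identical(K, "auto")) K <- NA_real_
  new("MorphConfig", K = as.numeric(K), strategy = match.arg(strategy),
      edgeSchedule = as.numeric(edgeSchedule), density = density,
      schedule = match.arg(schedule), rounding = match.arg(rounding),
      params = params)
}

#' Alpha-intermediate of two point sequences
#'
#' The pointwise convex combination \code{(1 - alpha) * P + alpha * Pprime}.
#'
#' @param P,Pprime n x 3 matrices or [CaTrace-class] objects of equal length.
#' @param alpha interpolation fraction in \code{[0, 1]}.
#' @return an n x 3 matrix.
#' @export
alphaIntermediate <- function(P, Pprime, alpha) {
  if (alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  P <- .asPoints(P)
  Pprime <- .asPoints(Pprime)
  if (!all(dim(P) == dim(Pprime)))
    stop("point sequences must have equal dimensions", call. = FALSE)
  (1 - alpha) * P + alpha * Pprime
}

#' Largest per-residue C-alpha displacement between two conformations
#'
#' @param start,end n x 3 matrices or [CaTrace-class] objects of equal
#'   length (already superposed).
#' @return maximum Euclidean displacement, Angstrom.
#' @export
maxDisplacement <- function(start, end) {
  a <- .asPoints(start)
  b <- .asPoints(end)
  if (!all(dim(a) == dim(b)))
    stop("point sets must have equal dimensions", call. = FALSE)
  sqrt(max(rowSums((a - b)^2)))
}

#' Automatic choice of the number of intermediate structures
#'
#' K is the rounded displacement of the largest C-alpha movement between the
#' superposed conformations (e.g. a 15.2 A maximum displacement gives
#' K = 15), floored at 1 so that a morph always has at least one
#' intermediate. This makes consecutive frames differ by roughly 1 A at the
#' fastest-moving residue.
#'
#' @inheritParams maxDisplacement
#' @param rounding \code{"half-away"} (round half away from zero; default)
#'   or \code{"truncate"}.
#' @return a positive integer.
#' @examples
#' a <- cbind(seq(0, 19, by = 3.8), 0, 0)
#' b <- a; b[3, 3] <- 15.2
#' chooseNumIntermediates(a, b)   # 15
#' @export
chooseNumIntermediates <- function(start, end,
                                   rounding = c("half-away", "truncate")) {
  rounding <- match.arg(rounding)
  d <- maxDisplacement(start, end)
  k <- if (rounding == "truncate") floor(d) else floor(d + 0.5)
  max(1L, as.integer(k))
}

#' Correct one frame, escalating the lattice edge on failure
#'
#' Runs [proteinize()] at each edge length of the schedule in turn, returning
#' the first feasible result (or the last, infeasible, attempt).
#'
#' @inheritParams proteinize
#' @param edgeSchedule ascending lattice edges to try (A).
#' @return a [ProteinizeResult-class]; check [isFeasible()].
#' @export
proteinizeRetry <- function(points, brokenEdge = NULL, brokenAngle = NULL,
                            params = scoreParams(), strategy = "simplified",
                            edgeSchedule = c(1.0, 1.5, 2.0), density = 6) {
  res <- NULL
  for (edge in edgeSchedule) {
    res <- proteinize(points, brokenEdge, brokenAngle, params,
                      strategy = strategy, edgeLength = edge,
                      density = density)
    if (isFeasible(res)) return(res)
  }
  res
}

#' Run a full morph between two preprocessed conformations
#'
#' Generates K protein-like intermediate conformations between \code{start}
#' and \code{end}. At step k the current conformation first moves toward the
#' end conformation by linear interpolation (by default a fraction
#' 1/(K - k + 2) of its remaining gap, so the interpolation targets are
#' evenly spaced along the approach), and the resulting point sequence is
#' then corrected to be protein-like by [proteinize()]. If the correction is
#' infeasible the lattice edge is enlarged along \code{edgeSchedule}; if it
#' is still infeasible at the largest edge the morph fails with an error of
#' class \code{"camorphInfeasible"} naming the frame.
#'
#' The inputs must already be aligned (equal length) and superposed -- use
#' [preprocessPair()] for raw structures, or pass an [AlignedPair-class]
#' directly as \code{start} (its gap flags then exempt alignment
#' discontinuities from the geometric constraints).
#'
#' @param start an [AlignedPair-class], or the starting [CaTrace-class] /
#'   coordinate matrix.
#' @param end the ending conformation (ignored when \code{start} is an
#'   [AlignedPair-class]).
#' @param config a [MorphConfig-class].
#' @param verbose report per-frame progress (edge length, DP score) on
#'   stderr?
#' @return a [MorphResult-class]: start frame, K intermediates, end frame,
#'   plus per-frame diagnostics.
#' @examples
#' pair <- makeMorphPair(n = 12, hingeAngle = 15, seed = 1)
#' m <- runMorph(pair$start, pair$end, morphConfig(K = 3))
#' diagnostics(m)
#' @export
runMorph <- function(start, end = NULL, config = morphConfig(),
                     verbose = FALSE) {
  if (is(start, "AlignedPair")) {
    pair <- start
    startTrace <- pair@start
    endTrace <- pair@end
    brokenEdge <- pair@brokenEdge
    brokenAngle <- pair@brokenAngle
  } else {
    startTrace <- if (is(start, "CaTrace")) start else CaTrace(start)
    endTrace <- if (is(end, "CaTrace")) end else CaTrace(end)
    if (nResidues(startTrace) != nResidues(endTrace))
      stop("start and end must have equal length (run preprocessPair first)",
           call. = FALSE)
    rid <- residueIds(startTrace)
    n <- nResidues(startTrace)
    brokenEdge <- !(rid$chain[-n] == rid$chain[-1L] &
                      rid$resno[-1L] - rid$resno[-n] == 1L)
    brokenAngle <- c(TRUE, brokenEdge[-(n - 1L)] | brokenEdge[-1L], TRUE)
  }
  startXyz <- caCoords(startTrace)
  endXyz <- caCoords(endTrace)
  K <- if (is.na(config@K))
    chooseNumIntermediates(startXyz, endXyz, config@rounding)
  else as.integer(config@K)
  frames <- vector("list", K + 2L)
  frames[[1L]] <- startTrace
  frames[[K + 2L]] <- endTrace
  diag <- data.frame(frame = seq_len(K), edgeLength = NA_real_,
                     totalScore = NA_real_, targetDistToEnd = NA_real_,
                     frameDistToEnd = NA_real_)
  current <- startXyz
  for (k in seq_len(K)) {
    target <- if (config@schedule == "fixed")
      alphaIntermediate(startXyz, endXyz, k / (K + 1))
    else
      alphaIntermediate(current, endXyz, 1 / (K - k + 2))
    res <- proteinizeRetry(target, brokenEdge, brokenAngle, config@params,
                           strategy = config@strategy,
                           edgeSchedule = config@edgeSchedule,
                           density = config@density)
    if (!isFeasible(res)) {
      cond <- structure(class = c("camorphInfeasible", "error", "condition"),
                        list(message = paste0(
                          "no protein-like correction found for frame ", k,
                          " of ", K, " even at lattice edge ",
                          max(config@edgeSchedule),
                          " A; the morph cannot be produced"),
                          call = sys.call(), frame = k))
      stop(cond)
    }
    if (verbose)
      message(sprintf("frame %d/%d: edge %.2f A, score %.6g", k, K,
                      res@edgeLength, res@totalScore))
    current <- res@points
    frames[[k + 1L]] <- setCoords(startTrace, current)
    diag$edgeLength[k] <- res@edgeLength
    diag$totalScore[k] <- res@totalScore
    diag$targetDistToEnd[k] <- rmsd(target, endXyz)
    diag$frameDistToEnd[k] <- rmsd(current, endXyz)
  }
  cfg <- config
  cfg@K <- as.numeric(K)
  new("MorphResult", frames = frames, diagnostics = diag, config = cfg)
}
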