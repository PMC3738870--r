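#' Validate a trace against all three protein-likeness criteria
#'
#' A chain is protein-like if it is (3.8, 0.1)-equidistant (all consecutive
#' C-alpha distances within [3.7, 3.9] A), (70, 120)-angle consistent (all
#' interior pseudo-bond angles within [70, 120] degrees) and 2.0-distance
#' consistent (no two non-consecutive C-alpha atoms within 2.0 A). Distances
#' and angles at broken (gap-adjacent) positions are reported but exempt
#' from the pass criteria; the clash criterion applies to every pair with
#' index separation >= 2.
#'
#' @param trace a [CaTrace-class] or n x 3 matrix.
#' @param brokenEdge,brokenAngle optional gap flags (see [proteinize()]).
#' @param params a [ScoreParams-class].
#' @return a [ProteinLikenessReport-class]; see [isProteinLike()].
#' @export
checkProteinLike <- function(trace, brokenEdge = NULL, brokenAngle = NULL,
                             params = scoreParams()) {
  xyz <- .asPoints(trace)
  n <- nrow(xyz)
  fl <- .defaultFlags(n, brokenEdge, brokenAngle)
  dists <- sqrt(rowSums((xyz[-1L, , drop = FALSE] -
                           xyz[-n, , drop = FALSE])^2))
  angles <- rep(NA_real_, n)
  if (n >= 3L)
    angles[2:(n - 1L)] <- vapply(2:(n - 1L), function(j)
      angDeg(xyz[j - 1L, ], xyz[j, ], xyz[j + 1L, ]), numeric(1))
  w <- .distWindow(params)
  passEq <- all(dists[!fl$edge] >= w[1L] & dists[!fl$edge] <= w[2L])
  checkedAngles <- angles[!fl$angle]
  passAng <- all(checkedAngles >= params@angleLow &
                   checkedAngles <= params@angleHigh)
  dm <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dm) & dm < params@clashDist, arr.ind = TRUE)
  pairs <- pairs[abs(pairs[, 1L] - pairs[, 2L]) >= 2L, , drop = FALSE]
  clashes <- data.frame(i = as.integer(pairs[, 1L]),
                        j = as.integer(pairs[, 2L]),
                        dist = dm[pairs])
  clashes <- clashes[order(clashes$i, clashes$j), , drop = FALSE]
  rownames(clashes) <- NULL
  new("ProteinLikenessReport", distances = dists, angles = angles,
      clashes = clashes, brokenEdge = fl$edge, brokenAngle = fl$angle,
      passEquidistant = passEq, passAngles = passAng,
      passClash = nrow(clashes) == 0L, params = params)
}

.reportRow <- function(report, label = NA) {
  data.frame(model = label,
             n = length(report@angles),
             minDist = min(report@distances),
             maxDist = max(report@distances),
             passEquidistant = report@passEquidistant,
             minAngle = suppressWarnings(min(report@angles, na.rm = TRUE)),
             maxAngle = suppressWarnings(max(report@angles, na.rm = TRUE)),
             passAngles = report@passAngles,
             nClashes = nrow(report@clashes),
             passClash = report@passClash,
             proteinLike = isProteinLike(report))
}

#' Per-frame protein-likeness summary of a morph
#'
#' @param x a [MorphResult-class] or list of [CaTrace-class].
#' @param brokenEdge,brokenAngle optional gap flags applied to every frame.
#' @param params a [ScoreParams-class].
#' @return a data.frame with one row per frame (morph endpoints included).
#' @export
morphReport <- function(x, brokenEdge = NULL, brokenAngle = NULL,
                        params = scoreParams()) {
  frames <- if (is(x, "MorphResult")) x@frames else x
  out <- do.call(rbind, lapply(seq_along(frames), function(m)
    .reportRow(checkProteinLike(frames[[m]], brokenEdge, brokenAngle,
                                params), m)))
  rownames(out) <- NULL
  out
}

#' RMSD trajectory profile of a morph against reference structures
#'
#' For every frame of the morph and every reference structure, computes the
#' RMSD after optimal rigid superposition of the frame onto the reference.
#' Plotted over frame index this shows how the trajectory departs from the
#' start structure, passes near intermediate references, and approaches the
#' end structure.
#'
#' @param frames a [MorphResult-class] or list of [CaTrace-class].
#' @param references a list of [CaTrace-class] (or matrices) with the same
#'   length as the frames (pre-aligned by the caller).
#' @param labels column labels, defaulting to names of \code{references} or
#'   \code{ref1, ref2, ...}.
#' @return a data.frame: column \code{frame} (0 = start, K + 1 = end) plus
#'   one RMSD column per reference.
#' @export
trajectoryRmsdProfile <- function(frames, references, labels = NULL) {
  if (is(frames, "MorphResult")) frames <- frames@frames
  if (is(references, "CaTrace") || is.matrix(references))
    references <- list(references)
  if (is.null(labels))
    labels <- if (!is.null(names(references)) && all(nzchar(names(references))))
      names(references) else paste0("ref", seq_along(references))
  n <- nResidues(frames[[1L]])
  refXyz <- lapply(references, .asPoints)
  bad <- which(vapply(refXyz, nrow, integer(1)) != n)
  if (length(bad))
    stop("reference '", labels[bad[1L]], "' has a different length (",
         nrow(refXyz[[bad[1L]]]), " vs ", n, " residues)", call. = FALSE)
  vals <- vapply(refXyz, function(ref)
    vapply(frames, function(f) kabschSuperpose(caCoords(f), ref)$rmsd,
           numeric(1)), numeric(length(frames)))
  vals <- matrix(vals, nrow = length(frames))
  out <- data.frame(frame = seq_along(frames) - 1L)
  out[labels] <- as.data.frame(vals)
  out
}
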