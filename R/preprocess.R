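#' Global (Needleman-Wunsch) alignment of two amino-acid sequences
#'
#' Aligns two sequences end-to-end, maximizing the BLOSUM62 score with affine
#' gap penalties (open 10, extend 1 by default). Near-identical inputs -- the
#' usual case when morphing two conformations of the same protein or of close
#' homologs -- are insensitive to the scoring choice; a fixed scheme is used
#' so results are deterministic.
#'
#' @param seqA,seqB amino-acid strings over the 20-letter alphabet
#'   (\code{X} tolerated).
#' @param gapOpening,gapExtension non-negative gap penalties.
#' @param substitutionMatrix name of a substitution matrix shipped with
#'   Biostrings, or a matrix.
#' @return a data.frame with one row per alignment column and integer columns
#'   \code{a}, \code{b} (1-based residue indices, NA at gaps), with the
#'   alignment score in \code{attr(, "score")}.
#' @examples
#' globalAlign("ACDEFG", "ACEFG")
#' @export
globalAlign <- function(seqA, seqB, gapOpening = 10, gapExtension = 1,
                        substitutionMatrix = "BLOSUM62") {
  if (!nzchar(seqA) || !nzchar(seqB))
    stop("sequences must be non-empty", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "global", substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension)
  gp <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1L]]
  gs <- strsplit(as.character(Biostrings::subject(pa)), "")[[1L]]
  a <- ifelse(gp == "-", NA_integer_, cumsum(gp != "-"))
  b <- ifelse(gs == "-", NA_integer_, cumsum(gs != "-"))
  out <- data.frame(a = as.integer(a), b = as.integer(b))
  attr(out, "score") <- Biostrings::score(pa)
  out
}

#' Restrict two traces to their aligned positions
#'
#' Keeps only alignment columns where both sequences have a residue, and
#' records where consecutive kept positions are not consecutive residues in
#' the \emph{original starting} structure (by residue numbering). At such
#' broken positions the distance and angle constraints are waived during
#' proteinization, since no physical bond connects them.
#'
#' @param traceA,traceB the starting and ending [CaTrace-class].
#' @param alignment output of [globalAlign()] (or any data.frame with
#'   columns \code{a}, \code{b} of indices / NA).
#' @return an [AlignedPair-class].
#' @export
restrictToAligned <- function(traceA, traceB, alignment) {
  keep <- !is.na(alignment$a) & !is.na(alignment$b)
  ia <- alignment$a[keep]
  ib <- alignment$b[keep]
  if (length(ia) < 2L)
    stop("fewer than 2 aligned residue pairs", call. = FALSE)
  if (max(ia) > nResidues(traceA) || max(ib) > nResidues(traceB))
    stop("alignment indices out of range", call. = FALSE)
  a <- traceA[ia]
  b <- traceB[ib]
  rid <- residueIds(a)
  n <- length(ia)
  consecutive <- rid$chain[-n] == rid$chain[-1L] &
    rid$resno[-1L] - rid$resno[-n] == 1L
  brokenEdge <- !consecutive
  brokenAngle <- c(TRUE, brokenEdge[-(n - 1L)] | brokenEdge[-1L], TRUE)
  new("AlignedPair", start = a, end = b, brokenEdge = brokenEdge,
      brokenAngle = brokenAngle)
}

#' Root mean square deviation between paired point sets
#'
#' Plain pointwise RMSD; no superposition is performed.
#'
#' @param a,b n x 3 matrices or [CaTrace-class] objects of equal length.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- if (is(a, "CaTrace")) caCoords(a) else as.matrix(a)
  b <- if (is(b, "CaTrace")) caCoords(b) else as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("point sets must have equal dimensions", call. = FALSE)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' \code{mobile} onto \code{target}, via singular value decomposition of the
#' covariance matrix with reflection correction.
#'
#' @param mobile,target n x 3 matrices or [CaTrace-class] objects of equal
#'   length (n >= 3).
#' @return a list with elements \code{transform} (a [RigidTransform-class]),
#'   \code{rmsd} (the minimized RMSD, Angstrom) and \code{coords} (the
#'   transformed mobile coordinates).
#' @examples
#' a <- cbind(rnorm(10), rnorm(10), rnorm(10))
#' kabschSuperpose(a, a)$rmsd   # 0
#' @export
kabschSuperpose <- function(mobile, target) {
  m <- if (is(mobile, "CaTrace")) caCoords(mobile) else as.matrix(mobile)
  t0 <- if (is(target, "CaTrace")) caCoords(target) else as.matrix(target)
  if (!all(dim(m) == dim(t0)))
    stop("point sets must have equal dimensions", call. = FALSE)
  if (nrow(m) < 3L)
    stop("superposition needs at least 3 points", call. = FALSE)
  cm <- colMeans(m)
  ct <- colMeans(t0)
  P <- sweep(m, 2L, cm)
  Q <- sweep(t0, 2L, ct)
  s <- svd(crossprod(P, Q))       # P^T Q = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(ct - R %*% cm)
  moved <- sweep(m %*% t(R), 2L, trans, `+`)
  list(transform = new("RigidTransform", rotation = R, translation = trans),
       rmsd = rmsd(moved, t0), coords = moved)
}

#' Apply a rigid transform to coordinates or a trace
#'
#' @param transform a [RigidTransform-class].
#' @param x an n x 3 matrix or a [CaTrace-class].
#' @return object of the same kind as \code{x}, transformed.
#' @export
applyTransform <- function(transform, x) {
  if (is(x, "CaTrace"))
    return(setCoords(x, applyTransform(transform, caCoords(x))))
  sweep(as.matrix(x) %*% t(transform@rotation), 2L,
        transform@translation, `+`)
}

#' Full preprocessing: align, restrict, superpose
#'
#' Runs global sequence alignment of the two traces, restricts both to the
#' aligned positions, then rigidly superposes the end structure onto the
#' start structure (Kabsch) on those positions. The returned pair is ready
#' for [runMorph()].
#'
#' @param start,end [CaTrace-class] objects.
#' @param ... passed to [globalAlign()].
#' @return a list with elements \code{pair} (the superposed
#'   [AlignedPair-class]), \code{transform} (the [RigidTransform-class]
#'   applied to \code{end}), \code{rmsd} (superposed C-alpha RMSD),
#'   \code{maxDisplacement}, and \code{alignment}.
#' @export
preprocessPair <- function(start, end, ...) {
  al <- globalAlign(caSequence(start, collapse = TRUE),
                    caSequence(end, collapse = TRUE), ...)
  pair <- restrictToAligned(start, end, al)
  fit <- kabschSuperpose(pair@end, pair@start)
  pair@end <- setCoords(pair@end, fit$coords)
  list(pair = pair, transform = fit$transform, rmsd = fit$rmsd,
       maxDisplacement = maxDisplacement(pair@start, pair@end),
       alignment = al)
}
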