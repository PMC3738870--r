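# run expr under a fixed RNG seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.unit <- function(v) v / sqrt(sum(v^2))

# any unit vector orthogonal to u
.orth <- function(u) {
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(c(u[2L] * ref[3L] - u[3L] * ref[2L],
          u[3L] * ref[1L] - u[1L] * ref[3L],
          u[1L] * ref[2L] - u[2L] * ref[1L]))
}

.cross <- function(a, b)
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])

# Rodrigues rotation matrix: angle in degrees about unit axis u
.rotationAbout <- function(u, angleDeg) {
  th <- angleDeg * pi / 180
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a random protein-like C-alpha chain
#'
#' Grows a self-avoiding chain point by point: consecutive points are placed
#' exactly \code{spacing} Angstrom apart, each pseudo-bond angle is drawn
#' uniformly from \code{angleRange}, the dihedral is free (uniform), and any
#' placement bringing the new point within \code{clashDist} of a
#' non-consecutive predecessor is rejected and redrawn. With the default
#' parameters every generated chain passes [checkProteinLike()] by
#' construction. Deterministic for a given \code{seed}.
#'
#' @param n number of residues (>= 2).
#' @param spacing consecutive C-alpha distance (A). Values outside
#'   \code{[3.7, 3.9]} deliberately produce non-protein-like chains.
#' @param angleRange pseudo-bond angle range, degrees.
#' @param clashDist minimum distance enforced between non-consecutive
#'   points (A).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param maxTries placement attempts per point before restarting the chain;
#'   20 whole-chain restarts are allowed before giving up.
#' @return a [CaTrace-class] (poly-alanine labels, chain A, residues 1..n).
#' @examples
#' ch <- generateChain(30, seed = 7)
#' isProteinLike(checkProteinLike(ch))
#' @export
generateChain <- function(n, spacing = 3.8, angleRange = c(70, 120),
                          clashDist = 2.0, seed = NULL, maxTries = 100L) {
  stopifnot(n >= 2L, spacing > 0)
  .withSeed(seed, {
    for (restart in seq_len(20L)) {
      xyz <- matrix(NA_real_, n, 3L)
      xyz[1L, ] <- c(0, 0, 0)
      xyz[2L, ] <- c(spacing, 0, 0)
      ok <- TRUE
      j <- 3L
      while (j <= n && ok) {
        placed <- FALSE
        for (try in seq_len(maxTries)) {
          theta <- stats::runif(1L, angleRange[1L], angleRange[2L])
          phi <- stats::runif(1L, 0, 360)
          u <- .unit(xyz[j - 2L, ] - xyz[j - 1L, ])
          n1 <- .orth(u)
          n2 <- .cross(u, n1)
          dir <- cos(theta * pi / 180) * u +
            sin(theta * pi / 180) *
            (cos(phi * pi / 180) * n1 + sin(phi * pi / 180) * n2)
          cand <- xyz[j - 1L, ] + spacing * dir
          prevIdx <- seq_len(j - 2L)
          d2 <- rowSums(sweep(xyz[prevIdx, , drop = FALSE], 2L, cand)^2)
          if (min(d2) >= clashDist^2) {
            xyz[j, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) ok <- FALSE
        j <- j + 1L
      }
      if (ok) return(CaTrace(xyz))
    }
    stop("rejection budget exhausted: could not grow a self-avoiding chain ",
         "with the requested geometry", call. = FALSE)
  })
}

#' Add isotropic Gaussian noise to a trace
#'
#' Emulates the geometric damage done by raw linear interpolation: each
#' coordinate receives independent N(0, sigma^2) noise. Deterministic for a
#' given \code{seed}.
#'
#' @param trace a [CaTrace-class].
#' @param sigma noise standard deviation per coordinate (A).
#' @param seed integer seed, or NULL.
#' @return a perturbed [CaTrace-class].
#' @export
perturbChain <- function(trace, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(trace)
  xyz <- caCoords(trace)
  .withSeed(seed,
    setCoords(trace, xyz + matrix(stats::rnorm(length(xyz), 0, sigma),
                                  nrow(xyz), 3L)))
}

#' Generate a hinge-motion conformation pair
#'
#' Builds one protein-like chain and produces a second conformation by
#' rigidly rotating the segment past an interior hinge residue about a
#' random axis through that residue -- emulating domain hinge motions such
#' as a chaperonin's closed-to-open transition. The rotation preserves all
#' internal geometry except the pseudo-bond angle at the hinge itself, so
#' axes are redrawn until the hinge angle stays within \code{angleRange} and
#' no steric clash is introduced.
#'
#' @inheritParams generateChain
#' @param hingePos interior residue index about which the arm rotates
#'   (default the midpoint).
#' @param hingeAngle rotation in degrees; 0 returns two identical
#'   conformations.
#' @param maxTries axis redraws allowed before giving up.
#' @return a list with protein-like [CaTrace-class] elements \code{start}
#'   and \code{end}, plus \code{hingePos} and \code{hingeAngle}.
#' @export
makeMorphPair <- function(n = 40L, hingePos = NULL, hingeAngle = 30,
                          spacing = 3.8, angleRange = c(70, 120),
                          clashDist = 2.0, seed = NULL, maxTries = 100L) {
  if (is.null(hingePos)) hingePos <- max(2L, floor(n / 2))
  if (hingePos <= 1L || hingePos >= n)
    stop("hingePos must be interior to the chain", call. = FALSE)
  .withSeed(seed, {
    start <- generateChain(n, spacing, angleRange, clashDist,
                           maxTries = maxTries)
    if (hingeAngle == 0)
      return(list(start = start, end = start, hingePos = hingePos,
                  hingeAngle = hingeAngle))
    xyz <- caCoords(start)
    pivot <- xyz[hingePos, ]
    arm <- (hingePos + 1L):n
    for (try in seq_len(maxTries)) {
      axis <- .unit(stats::rnorm(3L))
      R <- .rotationAbout(axis, hingeAngle)
      rotated <- xyz
      rotated[arm, ] <- sweep(sweep(xyz[arm, , drop = FALSE], 2L, pivot)
                              %*% t(R), 2L, pivot, `+`)
      rep2 <- checkProteinLike(rotated,
                               params = scoreParams(clashDist = clashDist))
      if (isProteinLike(rep2))
        return(list(start = start, end = setCoords(start, rotated),
                    hingePos = hingePos, hingeAngle = hingeAngle))
    }
    stop("hinge rotation kept clashing or bending the hinge angle out of ",
         "range after ", maxTries, " redraws", call. = FALSE)
  })
}
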