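#' Build the local lattice of candidate positions around one point
#'
#' Constructs an axis-aligned cubic grid centered on \code{center} with grid
#' spacing \code{1/density} Angstrom. The grid extends
#' \code{h = floor(edgeLength * density / 2)} steps per side along each axis,
#' so the per-axis point count is \code{2h + 1} (odd; the center is always a
#' grid point) and the total vertex count is \code{Q = (2h + 1)^3}. Whenever
#' \code{edgeLength * density} is an even integer this equals
#' \code{edgeLength * density + 1} points per axis spanning exactly
#' \code{edgeLength}; otherwise the largest centered sub-grid is used (e.g.
#' edge 1.5 A at density 6 gives 9 points per axis spanning 1.33 A).
#'
#' At the defaults used for morphing (density 6 points per Angstrom) the
#' vertex counts are Q = 343 at edge 1.0 A and Q = 2197 at edge 2.0 A.
#'
#' @param center numeric 3-vector, Angstrom.
#' @param edgeLength cube edge length, Angstrom.
#' @param density grid points per linear Angstrom (>= 1).
#' @return a [Lattice-class]; vertices are ordered lexicographically by
#'   (x, y, z) offset.
#' @examples
#' latticeSize(buildLattice(c(0, 0, 0), 1.0, 6))   # 343
#' @export
buildLattice <- function(center, edgeLength, density) {
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center)))
    stop("center must be a finite 3-vector", call. = FALSE)
  if (edgeLength <= 0 || density < 1)
    stop("edgeLength must be positive and density >= 1", call. = FALSE)
  h <- floor(edgeLength * density / 2 + 1e-9)
  if (h < 1L)
    stop("edgeLength * density too small: the lattice would consist of ",
         "its center only", call. = FALSE)
  off <- (-h:h) / density
  g <- expand.grid(z = off, y = off, x = off,
                   KEEP.OUT.ATTRS = FALSE)   # x slowest: lexicographic x,y,z
  vertices <- cbind(g$x + center[1L], g$y + center[2L], g$z + center[3L])
  new("Lattice", center = center, vertices = vertices,
      edgeLength = edgeLength, density = density)
}

.latticeVertexList <- function(points, edgeLength, density) {
  lapply(seq_len(nrow(points)), function(j)
    latticeVertices(buildLattice(points[j, ], edgeLength, density)))
}
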