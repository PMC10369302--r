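#' Full-array geometry constants
#'
#' Named constants of the 236,880-electrode array: electrode side and
#' separation in micrometers, the derived pitch, the number of electrodes,
#' and the sensing-area dimensions in millimeters. Two slightly different
#' printed sensing-area figures exist (5.5 x 5.9 and 5.51 x 5.91 mm); both
#' are kept, and density arithmetic uses the 5.5 x 5.9 mm figure.
#'
#' @format list with elements `electrodeSide`, `separation`, `pitch`,
#'   `nElectrodes`, `sensingAreaMm` (c(width, height)),
#'   `sensingAreaAltMm`, `nBlocks`, `electrodesPerBlock`.
#' @export
HDMEA_ARRAY <- list(
  electrodeSide = 11.22,       # um
  separation = 0.25,           # um
  pitch = 11.47,               # um, side + separation
  nElectrodes = 236880L,
  sensingAreaMm = c(5.5, 5.9),       # mm (figure caption)
  sensingAreaAltMm = c(5.51, 5.91),  # mm (system description)
  nBlocks = 14L,               # readout metadata only
  electrodesPerBlock = 33840L
)

#' Construct a rectangular electrode grid
#'
#' Electrode centers are laid out row-major on a regular lattice with the
#' given center-to-center pitch; the first electrode sits at the origin.
#'
#' @param nRows,nCols lattice dimensions (>= 1).
#' @param pitch center-to-center distance, micrometers. Default 11.47
#'   (11.22 um electrode + 0.25 um separation).
#' @param electrodeSide electrode side length, micrometers.
#' @return an [ElectrodeGrid-class]
#' @examples
#' g <- makeGrid(3, 3)
#' electrodePositions(g)
#' @export
makeGrid <- function(nRows, nCols, pitch = HDMEA_ARRAY$pitch,
                     electrodeSide = HDMEA_ARRAY$electrodeSide) {
  if (nRows < 1 || nCols < 1 || pitch <= 0 || electrodeSide <= 0 ||
      pitch < electrodeSide)
    stop("invalid geometry: need nRows, nCols >= 1 and pitch >= electrodeSide > 0")
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  idx <- seq_len(nRows * nCols) - 1L
  pos <- cbind(x = (idx %% nCols) * pitch, y = (idx %/% nCols) * pitch)
  new("ElectrodeGrid", nRows = nRows, nCols = nCols, pitch = pitch,
      electrodeSide = electrodeSide, positions = pos)
}

#' @describeIn nElectrodes grid method
#' @export
setMethod("nElectrodes", "ElectrodeGrid", function(x) x@nRows * x@nCols)

#' @describeIn electrodePositions grid method
#' @export
setMethod("electrodePositions", "ElectrodeGrid", function(x) x@positions)

setMethod("show", "ElectrodeGrid", function(object) {
  cat(sprintf("ElectrodeGrid: %d x %d electrodes, pitch %.3g um, side %.3g um\n",
              object@nRows, object@nCols, object@pitch, object@electrodeSide))
})

#' Electrode index <-> (row, col) conversion
#'
#' Row-major, 1-based: index = (row - 1) * nCols + col.
#'
#' @param grid an [ElectrodeGrid-class]
#' @param row,col lattice coordinates
#' @return `electrodeIndex`: integer index; `electrodeRowCol`: integer
#'   matrix with columns row, col.
#' @export
electrodeIndex <- function(grid, row, col) {
  if (any(row < 1 | row > grid@nRows | col < 1 | col > grid@nCols))
    stop("electrode (row, col) out of range")
  as.integer((row - 1L) * grid@nCols + col)
}

#' @rdname electrodeIndex
#' @param idx electrode index
#' @export
electrodeRowCol <- function(grid, idx) {
  checkElectrodeIndex(grid, idx)
  cbind(row = as.integer((idx - 1L) %/% grid@nCols + 1L),
        col = as.integer((idx - 1L) %% grid@nCols + 1L))
}

checkElectrodeIndex <- function(grid, idx) {
  if (any(idx < 1L | idx > nElectrodes(grid)))
    stop("electrode index out of range")
  invisible(TRUE)
}

#' Lattice neighbors of an electrode
#'
#' The (up to 8) Moore neighbors of an electrode on the lattice: corner
#' electrodes have 3, edges 5, interior 8. This 8-neighborhood is the
#' adjacency used throughout (soma merging, synchronous-firing counting,
#' neighborhood waveform similarity).
#'
#' @param grid an [ElectrodeGrid-class]
#' @param idx electrode index (1-based)
#' @return integer vector of neighbor indices
#' @export
gridNeighbors <- function(grid, idx) {
  checkElectrodeIndex(grid, idx)
  rc <- electrodeRowCol(grid, idx)
  dr <- rep(-1:1, each = 3L); dc <- rep(-1:1, times = 3L)
  keep <- !(dr == 0L & dc == 0L)
  r <- rc[1L, "row"] + dr[keep]; c <- rc[1L, "col"] + dc[keep]
  ok <- r >= 1L & r <= grid@nRows & c >= 1L & c <= grid@nCols
  electrodeIndex(grid, r[ok], c[ok])
}

#' Adjacency list for the whole grid
#'
#' @param grid an [ElectrodeGrid-class]
#' @return list of integer neighbor vectors, one per electrode
#' @export
gridAdjacency <- function(grid) {
  lapply(seq_len(nElectrodes(grid)), function(i) gridNeighbors(grid, i))
}

#' Euclidean distance between electrode centers, micrometers
#' @param grid an [ElectrodeGrid-class]
#' @param i,j electrode indices (vectorized, recycled)
#' @export
electrodeDistance <- function(grid, i, j) {
  checkElectrodeIndex(grid, i); checkElectrodeIndex(grid, j)
  p <- grid@positions
  unname(sqrt((p[i, 1L] - p[j, 1L])^2 + (p[i, 2L] - p[j, 2L])^2))
}

#' Electrode density of an array over its sensing area
#'
#' Fraction (percent) of the sensing area covered by electrode metal:
#' nElectrodes * side^2 / (width * height). With the full-array parameters
#' (236,880 electrodes of 11.22 um side over 5.5 x 5.9 mm) this is 91.9%.
#'
#' @param nElectrodes electrode count
#' @param electrodeSide electrode side, micrometers
#' @param areaMm sensing area c(width, height) in millimeters
#' @return percentage
#' @examples
#' electrodeDensity() # full array, 91.9
#' @export
electrodeDensity <- function(nElectrodes = HDMEA_ARRAY$nElectrodes,
                             electrodeSide = HDMEA_ARRAY$electrodeSide,
                             areaMm = HDMEA_ARRAY$sensingAreaMm) {
  if (nElectrodes <= 0 || electrodeSide <= 0 || any(areaMm <= 0))
    stop("invalid geometry: all arguments must be positive")
  100 * nElectrodes * (electrodeSide * 1e-3)^2 / prod(areaMm)
}

#' Region mask constructor
#'
#' @param label region name
#' @param electrodes integer electrode indices
#' @param grid optional [ElectrodeGrid-class] to validate indices against
#' @return a [RegionMask-class]
#' @export
regionMask <- function(label, electrodes, grid = NULL) {
  electrodes <- as.integer(electrodes)
  if (!is.null(grid)) checkElectrodeIndex(grid, electrodes)
  new("RegionMask", label = as.character(label), electrodes = electrodes)
}
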