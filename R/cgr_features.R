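#' Vertices of the protein chaos-game 12-gon
#'
#' The 12-sided regular polygon is inscribed in the unit circle with
#' `V1 = (1, 0)` and `Vk = (cos((k-1)*pi/6), sin((k-1)*pi/6))`.
#'
#' @param k Integer vertex index (or vector of indices) in `1..12`;
#'   `NULL` returns all twelve.
#' @return A numeric matrix with columns `x`, `y`, one row per vertex.
#' @examples
#' polygon_vertex(1)  # (1, 0)
#' polygon_vertex(7)  # (-1, 0)
#' @export
polygon_vertex <- function(k = NULL) {
  if (is.null(k)) k <- 1:12
  if (any(k < 1 | k > 12 | k != round(k))) {
    stop("vertex index must be an integer in 1..12")
  }
  theta <- (k - 1) * pi / 6
  cbind(x = cos(theta), y = sin(theta))
}

#' Vertices of the RNA chaos-game unit square
#'
#' `V1 = (0,0)`, `V2 = (1,0)`, `V3 = (1,1)`, `V4 = (0,1)`, assigned to
#' A, C, G, U respectively.
#'
#' @return A 4 x 2 numeric matrix with columns `x`, `y`.
#' @export
square_vertices <- function() {
  cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
}

#' Chaos-game trajectory of a sequence
#'
#' Each symbol pulls the current point half way towards the vertex of
#' its class: point `i` is the midpoint of point `i-1` and that vertex.
#' Proteins play on the 12-gon starting from its centre `(0, 0)`; RNA
#' plays on the unit square starting from its centre `(0.5, 0.5)`.
#'
#' @param seq A single sanitized sequence.
#' @param moltype `"protein"` or `"rna"`.
#' @param twelve_map Optional 12-group override (see
#'   [validate_twelve_map()]); proteins only.
#' @return Numeric matrix with columns `x`, `y` and one row per residue.
#' @export
cgr_trajectory <- function(seq, moltype = c("protein", "rna"),
                           twelve_map = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  moltype <- match.arg(moltype)
  symbols <- strsplit(seq, "")[[1]]
  if (length(symbols) == 0L) stop("empty sequence")
  if (moltype == "protein") {
    verts <- polygon_vertex()
    cls <- protein_group12(symbols, map = twelve_map)
    pt <- c(0, 0)
  } else {
    verts <- square_vertices()
    cls <- rna_vertex(symbols)
    pt <- c(0.5, 0.5)
  }
  out <- matrix(0, nrow = length(cls), ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  for (i in seq_along(cls)) {
    pt <- (pt + verts[cls[i], ]) / 2
    out[i, ] <- pt
  }
  out
}

#' Segment index on the 12-gon (24 segments)
#'
#' The disc is cut into 12 angular sectors of 30 degrees (sector 1
#' starts on the positive x-axis, counter-clockwise) and 2 radial bands
#' split at `radius`; segment `= 2*(sector-1) + band + 1` with the
#' inner band 0 and the outer band 1.  A point at exactly the band
#' radius is outer; an angle on a sector boundary belongs to the
#' higher sector.
#'
#' @param points Numeric matrix (or length-2 vector) of `x`, `y`.
#' @param radius Radial split, default 0.5.
#' @return Integer vector of segment indices in `1..24`.
#' @export
segment_index_24 <- function(points, radius = 0.5) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  ang <- atan2(points[, 2], points[, 1]) %% (2 * pi)
  sector <- pmin(1L + as.integer(floor(ang / (pi / 6))), 12L)
  r <- sqrt(rowSums(points^2))
  band <- as.integer(r >= radius)
  2L * (sector - 1L) + band + 1L
}

#' Segment index on the unit square (16 cells)
#'
#' A 4 x 4 grid over `[0,1]^2`: column `c = min(floor(4x), 3)`, row
#' `r = min(floor(4y), 3)`, index `= 4r + c + 1` (row-major from the
#' `(0,0)` corner); the top and right edges are clamped into the last
#' row/column.
#'
#' @param points Numeric matrix (or length-2 vector) of `x`, `y`.
#' @return Integer vector of cell indices in `1..16`.
#' @export
segment_index_16 <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  cc <- pmin(as.integer(floor(4 * points[, 1])), 3L)
  rr <- pmin(as.integer(floor(4 * points[, 2])), 3L)
  4L * rr + cc + 1L
}

.cgr_histogram <- function(idx, nbins) {
  counts <- tabulate(idx, nbins = nbins)
  structure(setNames(counts / length(idx),
                     sprintf("s%02d", seq_len(nbins))),
            counts = counts)
}

#' CGR-24 encoding of a protein sequence
#'
#' Runs the 12-gon chaos game and returns the occupancy frequencies of
#' the 24 segments (counts divided by sequence length, so the vector
#' sums to 1).
#'
#' @inheritParams cgr_trajectory
#' @return Numeric vector of length 24 with attribute `counts`.
#' @export
encode_cgr_protein <- function(seq, twelve_map = NULL) {
  traj <- cgr_trajectory(seq, "protein", twelve_map = twelve_map)
  .cgr_histogram(segment_index_24(traj), 24L)
}

#' CGR-16 encoding of an RNA sequence
#'
#' Runs the unit-square chaos game and returns the occupancy
#' frequencies of the 16 grid cells (counts divided by sequence length).
#'
#' @inheritParams cgr_trajectory
#' @return Numeric vector of length 16 with attribute `counts`.
#' @export
encode_cgr_rna <- function(seq) {
  traj <- cgr_trajectory(seq, "rna")
  .cgr_histogram(segment_index_16(traj), 16L)
}

#' Plot a chaos-game trajectory
#'
#' Convenience scatter plot of the trajectory with the geometry drawn
#' underneath; for visual inspection only.
#'
#' @inheritParams cgr_trajectory
#' @param ... Passed to [graphics::points()].
#' @return The trajectory matrix, invisibly.
#' @export
plot_cgr <- function(seq, moltype = c("protein", "rna"),
                     twelve_map = NULL, ...) {
  moltype <- match.arg(moltype)
  traj <- cgr_trajectory(seq, moltype, twelve_map = twelve_map)
  if (moltype == "protein") {
    verts <- polygon_vertex()
    graphics::plot(rbind(verts, verts[1, ]), type = "l", asp = 1,
                   xlab = "x", ylab = "y", main = "CGR-24")
  } else {
    verts <- square_vertices()
    graphics::plot(rbind(verts, verts[1, ]), type = "l", asp = 1,
                   xlab = "x", ylab = "y", main = "CGR-16")
  }
  graphics::points(traj, pch = 20, cex = 0.4, ...)
  invisible(traj)
}
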