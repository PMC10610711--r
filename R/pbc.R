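# Periodic-boundary primitives shared by every analysis stage.
# Boxes are orthorhombic only: a numeric length-3 vector of edge lengths (Angstrom).

#' Validate an orthorhombic box
#'
#' A box is a numeric vector of three strictly positive edge lengths in
#' Angstrom. Only orthorhombic cells (all angles 90 degrees) are supported;
#' triclinic input is rejected at the I/O layer.
#'
#' @param box Numeric vector of length 3, edge lengths in Angstrom.
#' @return The validated box (invisibly), as a plain numeric vector.
#' @export
check_box <- function(box) {
  if (!is.numeric(box) || length(box) != 3L || anyNA(box)) {
    stop("`box` must be a numeric vector of 3 edge lengths (Angstrom)")
  }
  if (any(box <= 0)) stop("box edge lengths must be strictly positive")
  invisible(as.numeric(box))
}

#' Minimum-image displacement between two points
#'
#' Returns the displacement `b - a` shifted by integer multiples of the box
#' edges so that each component lies in `[-L/2, L/2)`. Its Euclidean norm is
#' the minimum-image distance.
#'
#' @param a,b Numeric 3-vectors, Cartesian coordinates in Angstrom.
#' @param box Orthorhombic box (3-vector of edge lengths, Angstrom).
#' @return Numeric 3-vector, the minimum-image displacement in Angstrom.
#' @examples
#' minimum_image_displacement(c(1, 0, 0), c(9, 0, 0), c(10, 10, 10)) # (-2, 0, 0)
#' @export
minimum_image_displacement <- function(a, b, box) {
  box <- check_box(box)
  d <- as.numeric(b) - as.numeric(a)
  d - box * round(d / box)
}

# Vectorised minimum image for an n x 3 displacement matrix.
min_image_mat <- function(d, box) {
  d - rep(box, each = nrow(d)) * round(d / rep(box, each = nrow(d)))
}

# Wrap an n x 3 coordinate matrix into [0, L) per axis.
wrap_coords <- function(x, box) {
  x - rep(box, each = nrow(x)) * floor(x / rep(box, each = nrow(x)))
}

# All pairs (i < j) within `cutoff` under the minimum image convention.
# Exact O(n^2) evaluation, vectorised and chunked to bound memory; systems
# handled here are desk-scale (<= a few thousand sites) where this beats an
# interpreted cell-list loop while guaranteeing oracle equivalence.
# Returns a list(i, j, dist).
pairs_within <- function(coords, box, cutoff, chunk = 2e6) {
  box <- check_box(box)
  n <- nrow(coords)
  if (n < 2L) return(list(i = integer(0), j = integer(0), dist = numeric(0)))
  out_i <- list(); out_j <- list(); out_d <- list(); k <- 0L
  rows_per_chunk <- max(1L, floor(chunk / n))
  for (start in seq(1L, n - 1L, by = rows_per_chunk)) {
    end <- min(n - 1L, start + rows_per_chunk - 1L)
    ii <- start:end
    d2 <- matrix(0, length(ii), n)
    for (ax in 1:3) {
      da <- outer(coords[ii, ax], coords[, ax], "-")
      da <- da - box[ax] * round(da / box[ax])
      d2 <- d2 + da * da
    }
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      gi <- ii[hit[, 1L]]
      gj <- hit[, 2L]
      keep <- gi < gj
      if (any(keep)) {
        k <- k + 1L
        out_i[[k]] <- gi[keep]
        out_j[[k]] <- gj[keep]
        out_d[[k]] <- sqrt(d2[hit][keep])
      }
    }
  }
  list(i = unlist(out_i, use.names = FALSE) %||% integer(0),
       j = unlist(out_j, use.names = FALSE) %||% integer(0),
       dist = unlist(out_d, use.names = FALSE) %||% numeric(0))
}

# Cross-set pairs within cutoff: rows of `xa` against rows of `xb`.
# Returns list(i, j, dist) with i indexing xa, j indexing xb.
cross_pairs_within <- function(xa, xb, box, cutoff, chunk = 2e6) {
  box <- check_box(box)
  na <- nrow(xa); nb <- nrow(xb)
  if (na == 0L || nb == 0L) return(list(i = integer(0), j = integer(0), dist = numeric(0)))
  out <- list(); k <- 0L
  rows_per_chunk <- max(1L, floor(chunk / nb))
  for (start in seq(1L, na, by = rows_per_chunk)) {
    end <- min(na, start + rows_per_chunk - 1L)
    ii <- start:end
    d2 <- matrix(0, length(ii), nb)
    for (ax in 1:3) {
      da <- outer(xa[ii, ax], xb[, ax], "-")
      da <- da - box[ax] * round(da / box[ax])
      d2 <- d2 + da * da
    }
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      k <- k + 1L
      out[[k]] <- list(i = ii[hit[, 1L]], j = hit[, 2L], dist = sqrt(d2[hit]))
    }
  }
  if (k == 0L) return(list(i = integer(0), j = integer(0), dist = numeric(0)))
  list(i = unlist(lapply(out, `[[`, "i"), use.names = FALSE),
       j = unlist(lapply(out, `[[`, "j"), use.names = FALSE),
       dist = unlist(lapply(out, `[[`, "dist"), use.names = FALSE))
}

# Disjoint-set union-find with path halving; `n` elements, edge lists i/j.
# Returns integer component labels 1..k (renumbered by first appearance).
union_find <- function(n, i, j) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(i)) {
    ri <- find(i[e]); rj <- find(j[e])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Angle at vertex `v` between points `p` and `q` (degrees), minimum image.
pbc_angle <- function(p, v, q, box) {
  u1 <- minimum_image_displacement(v, p, box)
  u2 <- minimum_image_displacement(v, q, box)
  cosang <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a
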