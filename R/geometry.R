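# Periodic geometry under the minimum-image convention (orthorhombic boxes).

#' Minimum-image displacement
#'
#' @param d Numeric matrix (n x 3) or length-3 vector of raw displacements.
#' @param box Length-3 box edges (Angstrom).
#' @return Displacements folded to the nearest periodic image.
#' @export
min_image <- function(d, box) {
  if (is.null(dim(d))) d <- matrix(d, ncol = 3)
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

#' Wrap coordinates into the primary box [0, box)
#' @param x n x 3 coordinate matrix.
#' @param box Length-3 box edges.
#' @return Wrapped coordinate matrix.
#' @export
wrap_coords <- function(x, box) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  x - sweep(floor(sweep(x, 2, box, "/")), 2, box, "*")
}

# Squared minimum-image distances from each row of `pts` to the single point
# `centre` (length 3).
.mi_dist2_to_point <- function(pts, centre, box) {
  d <- sweep(pts, 2, centre)
  d <- min_image(d, box)
  rowSums(d * d)
}

# Brute-force pair list: all pairs (i < j) with minimum-image distance <=
# cutoff. Returns data.frame(i, j, d). Used as the oracle path and as the
# fallback when the box is too small for a cell list.
.brute_pairs <- function(x, box, cutoff) {
  n <- nrow(x)
  if (n < 2L) return(data.frame(i = integer(), j = integer(), d = numeric()))
  idx <- utils::combn(n, 2L)
  d <- min_image(x[idx[2L, ], , drop = FALSE] - x[idx[1L, ], , drop = FALSE],
                 box)
  dist <- sqrt(rowSums(d * d))
  keep <- dist <= cutoff
  data.frame(i = idx[1L, keep], j = idx[2L, keep], d = dist[keep])
}

#' Neighbor pairs within a cutoff under periodic minimum image
#'
#' Cell-list search when the box admits at least three cells per dimension,
#' otherwise brute force over all pairs. Both paths return identical pair
#' sets (this equality is a tested invariant).
#'
#' @param x n x 3 coordinate matrix (Angstrom; any image).
#' @param box Length-3 box edges.
#' @param cutoff Distance cutoff (Angstrom).
#' @param method `"auto"` (cell list when valid), `"cell"`, or `"brute"`.
#' @return `data.frame` with columns `i`, `j` (i < j) and `d` (Angstrom).
#' @export
neighbor_pairs <- function(x, box, cutoff, method = c("auto", "cell", "brute")) {
  method <- match.arg(method)
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  storage.mode(x) <- "double"
  ncell <- pmax(1L, as.integer(floor(box / cutoff)))
  cell_ok <- all(ncell >= 3L)
  if (method == "brute" || (method == "auto" && !cell_ok))
    return(.brute_pairs(x, box, cutoff))
  if (method == "cell" && !cell_ok)
    stop("box too small for a cell list at this cutoff (need >= 3 cells per ",
         "dimension); use method = 'brute'")
  xw <- wrap_coords(x, box)
  cw <- box / ncell
  ci <- floor(sweep(xw, 2, cw, "/"))
  for (dcol in 1:3) ci[, dcol] <- pmin(pmax(ci[, dcol], 0), ncell[dcol] - 1L)
  ci <- matrix(as.integer(ci), ncol = 3)
  cell_id <- ci[, 1] + ncell[1] * (ci[, 2] + ncell[2] * ci[, 3]) + 1L
  members <- split(seq_len(nrow(xw)), cell_id)
  # half-shell of neighbour-cell offsets (13) + within-cell pairs
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  lin <- offs %*% c(1, 3, 9)
  offs <- offs[lin > 0, , drop = FALSE]
  out_i <- out_j <- integer(0); out_d <- numeric(0)
  occupied <- as.integer(names(members))
  coord_of <- function(id) {
    id0 <- id - 1L
    c(id0 %% ncell[1],
      (id0 %/% ncell[1]) %% ncell[2],
      id0 %/% (ncell[1] * ncell[2]))
  }
  for (id in occupied) {
    a <- members[[as.character(id)]]
    cc <- coord_of(id)
    # within-cell pairs
    if (length(a) >= 2L) {
      p <- utils::combn(length(a), 2L)
      i1 <- a[p[1L, ]]; j1 <- a[p[2L, ]]
      dd <- min_image(xw[j1, , drop = FALSE] - xw[i1, , drop = FALSE], box)
      dist <- sqrt(rowSums(dd * dd))
      keep <- dist <= cutoff
      out_i <- c(out_i, i1[keep]); out_j <- c(out_j, j1[keep])
      out_d <- c(out_d, dist[keep])
    }
    for (k in seq_len(nrow(offs))) {
      nb <- (cc + offs[k, ]) %% ncell
      nb_id <- nb[1] + ncell[1] * (nb[2] + ncell[2] * nb[3]) + 1L
      b <- members[[as.character(nb_id)]]
      if (is.null(b)) next
      i1 <- rep(a, times = length(b))
      j1 <- rep(b, each = length(a))
      dd <- min_image(xw[j1, , drop = FALSE] - xw[i1, , drop = FALSE], box)
      dist <- sqrt(rowSums(dd * dd))
      keep <- dist <= cutoff
      i1 <- i1[keep]; j1 <- j1[keep]; dist <- dist[keep]
      sw <- i1 > j1
      tmp <- i1[sw]; i1[sw] <- j1[sw]; j1[sw] <- tmp
      out_i <- c(out_i, i1); out_j <- c(out_j, j1); out_d <- c(out_d, dist)
    }
  }
  res <- data.frame(i = out_i, j = out_j, d = out_d)
  res <- unique(res)
  res[order(res$i, res$j), , drop = FALSE]
}
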