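`%||%` <- function(a, b) if (is.null(a)) b else a

#' Otsu threshold of a numeric sample
#'
#' Two-class histogram threshold by between-class-variance maximization,
#' as used for brain extraction and for the hypo/hyper split of speckled
#' voxels. Also returns the separation strength eta-squared (maximal
#' between-class variance as a fraction of total variance), which is ~0.6
#' for a unimodal Gaussian and approaches 1 for well-separated modes.
#'
#' @param values numeric vector (non-finite values dropped).
#' @param n_bins number of histogram bins.
#' @return list with `threshold` and `eta_sq`.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("otsu_threshold: no finite values")
  rng <- range(values)
  total_var <- mean((values - mean(values))^2)
  if (diff(rng) == 0 || total_var == 0) {
    return(list(threshold = rng[1], eta_sq = 0))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  mu <- sum(w * mids)
  w0 <- cumsum(w)
  m0 <- cumsum(w * mids)
  w1 <- 1 - w0
  # between-class variance for split after each bin
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, n_bins)
  bc[valid] <- (mu * w0[valid] - m0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bc)
  list(threshold = edges[k + 1L], eta_sq = max(bc) / total_var)
}

# shift a 3D array by an integer offset, padding vacated voxels with `pad`
shift3 <- function(arr, offset, pad) {
  d <- dim(arr)
  out <- array(pad, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- offset[a]
    if (abs(o) >= d[a]) return(out)
    if (o >= 0) {
      dst[[a]] <- (1 + o):d[a]
      src[[a]] <- 1:(d[a] - o)
    } else {
      dst[[a]] <- 1:(d[a] + o)
      src[[a]] <- (1 - o):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

neighbourhood_offsets <- function(connectivity = 26L) {
  stopifnot(connectivity %in% c(6L, 26L))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  manh <- rowSums(abs(g))
  if (connectivity == 6L) g[manh == 1L, , drop = FALSE] else g[manh > 0L, , drop = FALSE]
}

dilate3 <- function(mask, connectivity = 26L, iterations = 1L) {
  offs <- neighbourhood_offsets(connectivity)
  for (it in seq_len(iterations)) {
    acc <- mask
    for (i in seq_len(nrow(offs))) {
      acc <- acc | shift3(mask, offs[i, ], FALSE)
    }
    mask <- acc
  }
  mask
}

erode3 <- function(mask, connectivity = 26L, iterations = 1L) {
  offs <- neighbourhood_offsets(connectivity)
  for (it in seq_len(iterations)) {
    acc <- mask
    for (i in seq_len(nrow(offs))) {
      acc <- acc & shift3(mask, offs[i, ], FALSE)
    }
    mask <- acc
  }
  mask
}

close3 <- function(mask, connectivity = 26L) {
  erode3(dilate3(mask, connectivity), connectivity)
}

# integer component labels (0 = background) of a logical 3D array
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  lab <- label_components_cpp(as.vector(mask), dim(mask), as.integer(connectivity))
  array(lab, dim(mask))
}

largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# fill interior cavities: background components (6-connected) not touching
# the grid boundary become foreground
fill_holes3 <- function(mask) {
  bg <- !mask
  lab <- label_components(bg, connectivity = 6L)
  d <- dim(mask)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  border <- border[border > 0L]
  holes <- bg & !(lab %in% border)
  mask | array(holes, d)
}

# local box mean over a k^3 window with half-sample reflective boundaries
box_mean3 <- function(arr, k) {
  stopifnot(k %% 2L == 1L)
  d <- dim(arr)
  r <- k %/% 2L
  reflect <- function(i, n) {
    while (any(bad <- i < 1L | i > n)) {
      i[i < 1L] <- 1L - i[i < 1L]
      i[i > n] <- 2L * n + 1L - i[i > n]
    }
    i
  }
  acc <- array(0, d)
  for (dz in -r:r) {
    iz <- reflect(seq_len(d[3]) + dz, d[3])
    for (dy in -r:r) {
      iy <- reflect(seq_len(d[2]) + dy, d[2])
      for (dx in -r:r) {
        ix <- reflect(seq_len(d[1]) + dx, d[1])
        acc <- acc + arr[ix, iy, iz]
      }
    }
  }
  acc / k^3
}

# monomial basis x^a y^b z^c (total degree <= degree) on coords scaled to
# [-1, 1]; returns the n_voxel x n_term design matrix for the given voxels
poly_basis3 <- function(dim3, degree, voxels = NULL) {
  cx <- seq(-1, 1, length.out = dim3[1])
  cy <- seq(-1, 1, length.out = dim3[2])
  cz <- seq(-1, 1, length.out = dim3[3])
  if (is.null(voxels)) {
    voxels <- as.matrix(expand.grid(seq_len(dim3[1]), seq_len(dim3[2]),
                                    seq_len(dim3[3])))
  }
  x <- cx[voxels[, 1]]
  y <- cy[voxels[, 2]]
  z <- cz[voxels[, 3]]
  pows <- expand.grid(a = 0:degree, b = 0:degree, c = 0:degree)
  pows <- pows[rowSums(pows) <= degree, , drop = FALSE]
  X <- matrix(1, nrow = length(x), ncol = nrow(pows))
  for (j in seq_len(nrow(pows))) {
    X[, j] <- x^pows$a[j] * y^pows$b[j] * z^pows$c[j]
  }
  X
}
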