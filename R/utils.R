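#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rexp rbinom sd quantile median complete.cases
#'   setNames aggregate
#' @importFrom utils head tail read.csv write.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib myxorun, .registration = TRUE
NULL

# Sentinel used for "no aggregate anywhere" boundary distances (um). Can be
# overridden per call; kept as an explicit cap rather than Inf so the value can
# participate in standardized nearest-neighbour cue vectors.
NO_AGGREGATE_DISTANCE <- 500

#' Wrap angles into (-pi, pi]
#'
#' @param x angles in radians.
#' @return wrapped angles, same shape as `x`.
#' @export
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # map -pi to +pi so the interval is (-pi, pi]
  w[w <= -pi] <- pi
  w
}

# Smallest unsigned angle between two directional angles, in [0, pi].
angle_diff <- function(a, b) abs(wrap_angle(a - b))

# Angle between two vectors given as (x, y) columns; rows are vectors.
# Returns values in [0, pi]; NA for zero-length vectors.
vector_angle <- function(u, v) {
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  d <- rowSums(u * v) / (nu * nv)
  d[nu == 0 | nv == 0] <- NA_real_
  acos(pmin(1, pmax(-1, d)))
}

# Fold a coordinate into [0, L] by reflection (triangle wave).
reflect_fold <- function(p, L) {
  q <- p %% (2 * L)
  ifelse(q > L, 2 * L - q, q)
}

# Evaluate an expression with a temporary RNG seed, restoring caller state.
with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

# Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271 + 7919 * as.integer(stream)) %% 2147483647L
}

# Centered moving average with shrinking windows at the ends.
moving_average <- function(x, w) {
  n <- length(x)
  if (n == 0 || w <= 1) return(x)
  h <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Exact k-nearest-neighbour query
#'
#' Vectorized exact search: squared Euclidean distances between query rows and
#' database rows are formed in one BLAS product, then the `k` smallest indices
#' per query are extracted. Ties at the k-th distance are broken by row order.
#'
#' @param db numeric matrix (n_db x d) of database points.
#' @param query numeric matrix (n_q x d) of query points.
#' @param k number of neighbours to return.
#' @return integer matrix (n_q x k) of row indices into `db`, ordered by
#'   increasing distance.
#' @export
knn_query <- function(db, query, k) {
  stopifnot(is.matrix(db), is.matrix(query), ncol(db) == ncol(query))
  k <- min(k, nrow(db))
  d2 <- matrix(rowSums(query^2), nrow(query), nrow(db)) +
    matrix(rowSums(db^2), nrow(query), nrow(db), byrow = TRUE) -
    2 * tcrossprod(query, db)
  knn_select(d2, as.integer(k))
}

# Label connected components with 8-connectivity. EBImage::bwlabel is
# 4-connective, so labels that touch diagonally are merged with a union-find
# pass over the label adjacency.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # pairs of labels adjacent along the two diagonal directions
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]   # down-right
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]  # up-right
  pa <- c(a1, a2); pb <- c(b1, b2)
  keep <- pa > 0 & pb > 0 & pa != pb
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (any(keep)) {
    for (j in which(keep)) {
      ra <- find(pa[j]); rb <- find(pb[j])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Boundary pixels of a labelled component: pixels of the component with at
# least one 4-neighbour outside it. Returns an index matrix (row, col).
component_boundary <- function(lab, id) {
  inside <- lab == id
  nr <- nrow(inside); nc <- ncol(inside)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- inside
  core <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  which(inside & !core, arr.ind = TRUE)
}

# Bilinear interpolation of a matrix at continuous pixel coordinates.
# (col_px, row_px) are 0-based with pixel centers at integers.
bilinear_sample <- function(m, col_px, row_px) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(col_px, 0), nc - 1)
  y <- pmin(pmax(row_px, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); x1 <- x0 + 1
  y0 <- pmin(floor(y), nr - 2); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  idx <- function(r, c) m[cbind(r + 1, c + 1)]
  idx(y0, x0) * (1 - fx) * (1 - fy) + idx(y0, x1) * fx * (1 - fy) +
    idx(y1, x0) * (1 - fx) * fy + idx(y1, x1) * fx * fy
}
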