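#' Reconstruct crystal coordinates from pairwise distances
#'
#' Sonomicrometer array localization measures inter-crystal distances, not
#' positions. `coordinates_from_distances()` embeds each frame's distance
#' matrix in 3D by classical (Torgerson) multidimensional scaling and aligns
#' every frame to the previous one by orthogonal Procrustes (rotation and, if
#' needed, reflection) so the arbitrary per-frame orientation of the embedding
#' does not flip between frames. Translation is unrecoverable from distances:
#' every returned frame is centred on its centroid.
#'
#' @param dist A single symmetric zero-diagonal distance matrix (mm), or a
#'   list of such matrices (one per frame).
#' @param time Optional vector of frame times (s); defaults to frame index
#'   times the sonomicrometry interval 0.00853 s.
#' @param tol Relative eigenvalue threshold below which the configuration is
#'   considered rank-deficient (degenerate, e.g. coplanar crystals still have
#'   rank 2 only in z).
#' @return Wide tibble `time_s, c1_x, ..., cN_z` (the dialect
#'   [analyze_geometry()] reads).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[1:8]
#' pts <- cbind(16 * cos(th), 11.2 * sin(th), -2 * cos(2 * th))
#' xyz <- coordinates_from_distances(as.matrix(dist(pts)))
#' @export
coordinates_from_distances <- function(dist, time = NULL, tol = 1e-8) {
  if (is.matrix(dist)) dist <- list(dist)
  if (!length(dist)) stop("no distance matrices supplied")
  if (is.null(time)) time <- (seq_along(dist) - 1) * SONO_DT

  prev <- NULL
  frames <- vector("list", length(dist))
  for (i in seq_along(dist)) {
    X <- classical_mds(dist[[i]], tol = tol)
    if (!is.null(prev)) X <- procrustes_align(X, prev)
    frames[[i]] <- X
    prev <- X
  }
  n <- nrow(frames[[1]])
  wide <- do.call(rbind, lapply(frames, function(X) as.vector(t(X))))
  colnames(wide) <- as.vector(t(outer(seq_len(n), c("x", "y", "z"),
                                      function(i, a) paste0("c", i, "_", a))))
  dplyr::bind_cols(tibble::tibble(time_s = time), tibble::as_tibble(wide))
}

# classical (Torgerson) MDS into exactly 3 dimensions
classical_mds <- function(D, tol = 1e-8) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 4L) stop("need at least 4 crystals for a 3D embedding")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8, check.attributes = FALSE))) {
    stop("distance matrix is not symmetric")
  }
  if (any(abs(diag(D)) > 1e-8)) stop("distance matrix diagonal must be zero")
  mds <- stats::cmdscale(D, k = 3, eig = TRUE)
  if (mds$eig[3] < tol * max(mds$eig[1], 1e-300)) {
    stop("distance matrix has embedding rank < 3 (degenerate configuration)")
  }
  X <- mds$points
  colnames(X) <- c("x", "y", "z")
  X
}

# orthogonal Procrustes (rotation + reflection allowed) of centred X onto Y
procrustes_align <- function(X, Y) {
  sv <- svd(crossprod(X, Y))
  X %*% (sv$u %*% t(sv$v))
}

#' Read a per-frame inter-crystal distance CSV
#'
#' Expects columns `time_s` and the upper triangle `d_1_2, d_1_3, ..., d_7_8`
#' (mm), and returns the list-of-matrices form plus times.
#'
#' @param path File path.
#' @return List with `time` and `dist` (list of symmetric matrices).
#' @export
read_distance_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  dcols <- grep("^d_[0-9]+_[0-9]+$", names(x), value = TRUE)
  if (!length(dcols) || !"time_s" %in% names(x)) {
    stop("expected columns `time_s` and `d_<i>_<j>`")
  }
  ij <- do.call(rbind, lapply(strsplit(sub("^d_", "", dcols), "_"), as.integer))
  n <- max(ij)
  dist <- lapply(seq_len(nrow(x)), function(r) {
    D <- matrix(0, n, n)
    D[ij] <- as.numeric(x[r, dcols])
    D[ij[, 2:1, drop = FALSE]] <- as.numeric(x[r, dcols])
    D
  })
  list(time = x$time_s, dist = dist)
}
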