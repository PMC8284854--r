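#' Segment a dynamic image into approximately-proportional clusters
#'
#' Step 1 of non-parametric residue mapping: recursive binary splitting of
#' the voxel population on correlation distance between time courses,
#' until either `S_target` segments are reached or every segment satisfies
#' the within-segment proportionality criterion (voxel curves in a segment
#' approximately proportional to the segment mean curve).  Each split is a
#' 2-means partition of the row-standardised curves, for which squared
#' Euclidean distance is equivalent to 1 - Pearson correlation.
#'
#' @param dynamic_image numeric matrix, voxels x N_T.
#' @param S_target maximum number of segments.
#' @param min_segment_size do not create segments smaller than this.
#' @param prop_tol proportionality tolerance: a segment whose mean
#'   correlation distance to its mean curve is below this is not split.
#' @param sd_floor_frac per-frame standard deviations are floored at this
#'   fraction of the segment's peak mean value (also used for segments of
#'   size 1, whose SD is otherwise undefined).
#' @return An object of class `reduced_dataset`: list with `means`
#'   (S x N_T segment mean curves), `sds` (S x N_T segment standard
#'   deviations, floored), `sizes`, `labels` (voxel -> segment) and `S`.
#' @export
segment_image <- function(dynamic_image, S_target = 100,
                          min_segment_size = 1, prop_tol = 1e-8,
                          sd_floor_frac = 0.01) {
  Z <- as.matrix(dynamic_image)
  nv <- nrow(Z)
  if (nv < 1) stop("need at least one voxel")
  if (S_target < 1) stop("S_target must be >= 1")
  if (S_target > nv) stop("S_target exceeds the number of voxels")

  # row-standardise for correlation geometry; constant rows get zero curves
  mu <- rowMeans(Z)
  sdv <- apply(Z, 1, stats::sd)
  sdv[!is.finite(sdv) | sdv < .Machine$double.eps] <- Inf
  Zs <- (Z - mu) / sdv

  seg_dist <- function(idx) {
    # mean correlation distance of member curves to the segment mean curve
    if (length(idx) < 2) return(0)
    m <- colMeans(Z[idx, , drop = FALSE])
    sm <- stats::sd(m)
    if (!is.finite(sm) || sm < .Machine$double.eps) return(0)
    ms <- (m - mean(m)) / sm
    d <- 1 - Zs[idx, , drop = FALSE] %*% ms / (ncol(Z) - 1)
    mean(pmax(d, 0))
  }

  segments <- list(seq_len(nv))
  dists <- vapply(segments, seg_dist, numeric(1))
  splittable <- rep(TRUE, 1)
  while (length(segments) < S_target) {
    cand <- which(splittable & dists > prop_tol &
                    vapply(segments, length, 1L) >= 2 * min_segment_size)
    if (length(cand) == 0) break
    k <- cand[which.max(dists[cand])]
    idx <- segments[[k]]
    if (length(idx) == 2) {          # kmeans needs k < n
      g1 <- idx[1]
      g2 <- idx[2]
    } else {
      km <- suppressWarnings(
        stats::kmeans(Zs[idx, , drop = FALSE], centers = 2, nstart = 5))
      g1 <- idx[km$cluster == 1]
      g2 <- idx[km$cluster == 2]
    }
    if (length(g1) < min_segment_size || length(g2) < min_segment_size) {
      splittable[k] <- FALSE
      next
    }
    segments[[k]] <- g1
    segments[[length(segments) + 1L]] <- g2
    dists[k] <- seg_dist(g1)
    dists[length(segments)] <- seg_dist(g2)
    splittable[k] <- TRUE
    splittable[length(segments)] <- TRUE
  }

  S <- length(segments)
  NT <- ncol(Z)
  means <- matrix(0, S, NT)
  sds <- matrix(0, S, NT)
  sizes <- integer(S)
  labels <- integer(nv)
  for (s in seq_len(S)) {
    idx <- segments[[s]]
    labels[idx] <- s
    sizes[s] <- length(idx)
    means[s, ] <- colMeans(Z[idx, , drop = FALSE])
    sd_s <- if (length(idx) > 1) apply(Z[idx, , drop = FALSE], 2, stats::sd)
            else rep(0, NT)
    floor_s <- sd_floor_frac * max(abs(means[s, ]), .Machine$double.eps)
    sds[s, ] <- pmax(sd_s, floor_s)
  }
  out <- list(means = means, sds = sds, sizes = sizes,
              labels = labels, S = S)
  class(out) <- "reduced_dataset"
  out
}

#' @export
print.reduced_dataset <- function(x, ...) {
  cat(sprintf("Reduced dataset: %d segments over %d voxels, %d frames\n",
              x$S, length(x$labels), ncol(x$means)))
  invisible(x)
}
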