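# From-scratch k-means (Lloyd's algorithm with distance-weighted greedy
# seeding and restarts), the within-cluster sum-of-squared-errors objective,
# and the elbow-point selector used to pick the number of majority clusters.

# Squared Euclidean distances between rows of X (n x d) and C (k x d).
dist2 <- function(X, C) {
  d <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  d[d < 0] <- 0
  d
}

#' Within-cluster sum of squared errors
#'
#' The clustering objective: `SSE = sum_i || x_i - c_{a(i)} ||^2`, the squared
#' Euclidean distance of every point to its assigned cluster centre, summed
#' over all points.
#'
#' @param points `n x d` numeric matrix.
#' @param centers `k x d` numeric matrix of cluster centres.
#' @param assignments integer vector of cluster indices in `1..k`, one per row
#'   of `points`.
#' @return non-negative scalar.
#' @export
sse <- function(points, centers, assignments) {
  points <- as.matrix(points)
  centers <- as.matrix(centers)
  if (ncol(points) != ncol(centers)) {
    stop("points and centers have different dimensionality")
  }
  assignments <- as.integer(assignments)
  if (length(assignments) != nrow(points)) {
    stop("one assignment per point required")
  }
  if (any(assignments < 1L | assignments > nrow(centers))) {
    stop("assignments out of range 1..k")
  }
  sum((points - centers[assignments, , drop = FALSE])^2)
}

# Distance-weighted greedy seeding: first centre uniform, each subsequent
# centre drawn with probability proportional to squared distance from the
# nearest centre already chosen (k-means++-style).
kmpp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  ci <- sample.int(n, 1L)
  centers[1L, ] <- X[ci, ]
  if (k > 1L) {
    d2 <- dist2(X, centers[1L, , drop = FALSE])[, 1L]
    for (j in 2L:k) {
      if (sum(d2) <= 0) {
        ci <- sample.int(n, 1L)  # all remaining points coincide with a centre
      } else {
        ci <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- X[ci, ]
      d2 <- pmin(d2, dist2(X, centers[j, , drop = FALSE])[, 1L])
    }
  }
  centers
}

# One Lloyd descent from given initial centres. An emptied cluster is
# reseeded at the point farthest from its assigned centre (repair event
# recorded); convergence when the largest centre displacement drops below
# tol (Euclidean, original feature scale).
lloyd <- function(X, centers, max_iter, tol) {
  k <- nrow(centers)
  n <- nrow(X)
  repairs <- 0L
  sse_history <- numeric(0)
  converged <- FALSE
  assignments <- rep(1L, n)
  for (it in seq_len(max_iter)) {
    D <- dist2(X, centers)
    assignments <- max.col(-D, ties.method = "first")
    # empty-cluster repair: reseed at the point farthest from its assigned
    # centre and move it into the empty cluster (forced, so repair always
    # makes progress even on duplicate-heavy data)
    cnt <- tabulate(assignments, nbins = k)
    if (any(cnt == 0L)) {
      dists <- D[cbind(seq_len(n), assignments)]
      for (j in which(cnt == 0L)) {
        eligible <- which(cnt[assignments] > 1L)
        if (length(eligible) == 0L) break
        far <- eligible[which.max(dists[eligible])]
        cnt[assignments[far]] <- cnt[assignments[far]] - 1L
        assignments[far] <- j
        cnt[j] <- 1L
        centers[j, ] <- X[far, ]
        dists[far] <- 0
        repairs <- repairs + 1L
      }
    }
    sse_history <- c(sse_history,
                     sum((X - centers[assignments, , drop = FALSE])^2))
    new_centers <- rowsum(X, assignments) / cnt
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  D <- dist2(X, centers)
  assignments <- max.col(-D, ties.method = "first")
  list(centers = centers, assignments = assignments,
       sse = sum(D[cbind(seq_len(n), assignments)]),
       n_iter = length(sse_history), converged = converged,
       repairs = repairs, sse_history = sse_history)
}

#' k-means clustering by restarted Lloyd iterations
#'
#' Runs Lloyd's algorithm `n_restarts` times from distance-weighted greedy
#' seeds (plus any caller-supplied initial centre sets) and keeps the solution
#' with the lowest within-cluster sum of squared errors. Deterministic given
#' `seed`.
#'
#' @param points `n x d` numeric matrix.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer seed for the seeding draws.
#' @param max_iter maximum Lloyd iterations per start.
#' @param tol convergence threshold on the largest centre displacement.
#' @param n_restarts number of random starts.
#' @param extra_inits optional list of `k x d` matrices used as additional
#'   starting centre sets.
#' @return a `cluster_model`: centers, 1-based assignments, sse, n_iter,
#'   converged flag, repair count, and per-iteration SSE history of the
#'   winning start.
#' @export
kmeans_fit <- function(points, k, seed = 1L, max_iter = 300L, tol = 1e-4,
                       n_restarts = 10L, extra_inits = NULL) {
  X <- as.matrix(points)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(X)) stop("k (", k, ") exceeds number of points (", nrow(X), ")")
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_restarts)) {
      fit <- lloyd(X, kmpp_init(X, k), max_iter, tol)
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
  })
  if (!is.null(extra_inits)) {
    for (init in extra_inits) {
      fit <- lloyd(X, as.matrix(init), max_iter, tol)
      if (fit$sse < best$sse) best <- fit
    }
  }
  structure(c(best, list(k = k)), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k=%d, sse=%.4g, %d iterations%s%s\n",
              x$k, x$sse, x$n_iter,
              if (x$converged) " (converged)" else "",
              if (x$repairs > 0) sprintf(", %d empty-cluster repairs", x$repairs) else ""))
  invisible(x)
}

#' Assign points to the nearest centre of a fitted cluster model
#' @param model a `cluster_model`.
#' @param points `m x d` matrix in the same feature space.
#' @return integer vector of 1-based cluster indices.
#' @export
assign_clusters <- function(model, points) {
  max.col(-dist2(as.matrix(points), model$centers), ties.method = "first")
}

#' Scan cluster counts and record the SSE curve
#'
#' Fits k-means for every `k` in `1..cluster_n`. For `k > 1`, the best
#' solution at `k - 1`, augmented with the point farthest from its assigned
#' centre, is supplied as one additional start; this nested seeding makes the
#' SSE curve non-increasing in `k` by construction. The elbow point is then
#' chosen with [select_elbow_k()].
#'
#' @param points `n x d` numeric matrix.
#' @param cluster_n maximum number of clusters to consider.
#' @param seed integer seed.
#' @param n_restarts random starts per `k`.
#' @return an `elbow_curve`: `k_values`, `sse_values`, `chosen_k`, and the
#'   list of fitted `cluster_model`s (one per `k`).
#' @export
elbow_scan <- function(points, cluster_n, seed = 1L, n_restarts = 10L) {
  X <- as.matrix(points)
  cluster_n <- as.integer(cluster_n)
  if (cluster_n < 1L) stop("cluster_n must be >= 1")
  if (nrow(X) < cluster_n) stop("need at least cluster_n points")
  models <- vector("list", cluster_n)
  sse_values <- numeric(cluster_n)
  for (k in seq_len(cluster_n)) {
    extra <- NULL
    if (k > 1L) {
      prev <- models[[k - 1L]]
      far <- which.max(rowSums((X - prev$centers[prev$assignments, ,
                                                 drop = FALSE])^2))
      extra <- list(rbind(prev$centers, X[far, ]))
    }
    models[[k]] <- kmeans_fit(X, k, seed = seed + k, n_restarts = n_restarts,
                              extra_inits = extra)
    sse_values[k] <- models[[k]]$sse
  }
  curve <- structure(
    list(k_values = seq_len(cluster_n), sse_values = sse_values,
         chosen_k = NA_integer_, models = models),
    class = "elbow_curve"
  )
  curve$chosen_k <- select_elbow_k(curve)
  curve
}

#' Pick the elbow point of an SSE curve
#'
#' Both axes are min-max normalized to `[0, 1]`; the chosen `k` maximizes the
#' perpendicular distance from `(k, SSE_k)` to the chord joining the first and
#' last curve points — the point where the rate of decrease in SSE slows most
#' sharply. Ties break to the smallest `k`; a length-1 or flat curve yields
#' `k = 1`. The choice is invariant to affine rescaling of the SSE axis.
#'
#' @param curve an `elbow_curve` (or a list with `k_values` and `sse_values`).
#' @return the chosen integer `k`.
#' @export
select_elbow_k <- function(curve) {
  kv <- curve$k_values
  sv <- curve$sse_values
  m <- length(kv)
  if (m == 1L) return(kv[1L])
  if (diff(range(sv)) <= 0 || diff(range(kv)) <= 0) return(kv[1L])
  x <- (kv - min(kv)) / diff(range(kv))
  y <- (sv - min(sv)) / diff(range(sv))
  # chord from (x1, y1) to (xm, ym); perpendicular distance of each point
  dx <- x[m] - x[1L]
  dy <- y[m] - y[1L]
  dist <- abs(dy * x - dx * y + dx * y[1L] - dy * x[1L]) / sqrt(dx^2 + dy^2)
  kv[which.max(dist)]  # which.max takes the first (smallest k) on ties
}

#' Export an elbow curve as a two-column CSV
#' @param curve an `elbow_curve`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_elbow_csv <- function(curve, path) {
  utils::write.csv(data.frame(k = curve$k_values, sse = curve$sse_values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Plot an elbow curve to a PNG file
#' @param curve an `elbow_curve`.
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
plot_elbow <- function(curve, path) {
  grDevices::png(path, width = 720, height = 480)
  on.exit(grDevices::dev.off())
  graphics::plot(curve$k_values, curve$sse_values, type = "b", pch = 19,
                 xlab = "k (number of clusters)", ylab = "SSE",
                 main = "Elbow curve")
  graphics::abline(v = curve$chosen_k, lty = 2, col = "red")
  graphics::mtext(sprintf("chosen k = %d", curve$chosen_k), col = "red")
  invisible(path)
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat("elbow_curve over k =", paste(range(x$k_values), collapse = ".."),
      "; chosen k =", x$chosen_k, "\n")
  invisible(x)
}
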