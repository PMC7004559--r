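#' Nearly unbiased coefficient of variation
#'
#' Small-sample-corrected CV in percent,
#' `(1 + 1/(4n)) * sd(x) / mean(x) * 100`.
#'
#' @param x positive values (n >= 2).
#' @return CV in percent.
#' @export
unbiased_cv <- function(x) {
  n <- length(x)
  if (n < 2) stop("unbiased_cv needs at least two values")
  m <- mean(x)
  if (m == 0) stop("unbiased_cv undefined for zero mean")
  (1 + 1 / (4 * n)) * stats::sd(x) / m * 100
}

## column standardisation to unit variance (constant columns left alone)
standardize_columns <- function(X) {
  s <- apply(X, 2, stats::sd)
  s[s == 0] <- 1
  sweep(X, 2, s, "/")
}

#' Fuzzy c-means clustering of patient parameter vectors
#'
#' Alternating optimisation of the fuzzy c-means objective
#' `sum_i sum_j w_ij^2 ||x_i - c_j||^2` with fuzzifier m = 2 (squared
#' memberships). Columns are scaled to unit variance by default so that
#' parameters spanning different orders of magnitude contribute comparably
#' to the Euclidean distance; raw-scale clustering is retained as an
#' option. Deterministic given `seed`; a data point coinciding with a
#' centroid receives crisp membership. The objective is nonincreasing over
#' iterations (returned as `trace`).
#'
#' @param X numeric matrix, rows = patients, columns = PK parameters.
#' @param c number of clusters, in `[2, n - 1]`.
#' @param seed RNG seed for the centroid initialisation.
#' @param tol stop when the objective decreases by less than this.
#' @param max_iter iteration cap.
#' @param standardize scale columns to unit variance before clustering?
#' @param centers optional initial centroids (on the clustering scale).
#' @return Object of class `fcm`: memberships (rows sum to 1), centroids
#'   (clustering scale), `objective`, `trace`, `V_FS`, the 2-D projection
#'   of the patients with its distance-correlation `projection_fidelity`,
#'   and the crisp `assignment`.
#' @export
fuzzy_cmeans <- function(X, c, seed = 1, tol = 1e-9, max_iter = 500,
                         standardize = TRUE, centers = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (c < 2 || c > n - 1) stop("cluster count must lie in [2, n - 1]")
  Xs <- if (standardize) standardize_columns(X) else X
  set.seed(seed)
  if (is.null(centers)) {
    centers <- Xs[sample.int(n, c), , drop = FALSE] *
      (1 + 1e-3 * matrix(stats::rnorm(c * ncol(Xs)), c))
  }
  memberships_from <- function(cent) {
    D2 <- outer(rowSums(Xs^2), rep(1, nrow(cent))) -
      2 * Xs %*% t(cent) + outer(rep(1, n), rowSums(cent^2))
    D2 <- pmax(D2, 0)
    W <- matrix(0, n, nrow(cent))
    for (i in seq_len(n)) {
      d <- D2[i, ]
      z <- d < 1e-300
      if (any(z)) W[i, ] <- z / sum(z)       # crisp on coincident centroid
      else W[i, ] <- (1 / d) / sum(1 / d)    # m = 2 membership update
    }
    W
  }
  obj <- Inf; trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    W <- memberships_from(centers)
    W2 <- W^2
    centers <- sweep(t(W2) %*% Xs, 1, colSums(W2), "/")
    D2 <- outer(rowSums(Xs^2), rep(1, c)) - 2 * Xs %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    new_obj <- sum(W2 * pmax(D2, 0))
    trace <- c(trace, new_obj)
    if (obj - new_obj < tol) { obj <- new_obj; break }
    obj <- new_obj
  }
  proj <- tryCatch(project_mds(Xs), error = function(e) NULL)
  structure(list(memberships = W, centroids = centers, c = c,
                 objective = obj, trace = trace,
                 V_FS = fukuyama_sugeno(Xs, W, centers),
                 assignment = max.col(W),
                 projection = proj$coords,
                 projection_fidelity = proj$fidelity,
                 standardize = standardize, X = X, seed = seed),
            class = "fcm")
}

#' Fukuyama-Sugeno cluster validity index
#'
#' `V_FS = sum_i sum_j w_ij^2 (||x_i - c_j||^2 - ||c_j - xbar||^2)`:
#' compactness minus separation; lower is better. In the original index
#' `xbar` is the grand mean of the data (`center = "data"`, the default);
#' `center = "centroids"` replaces it by the average of the centroids.
#' The data-mean form is used for cluster-count selection because its
#' separation reference does not move when a centroid is duplicated;
#' with the centroid average, adding clusters shifts the reference and
#' the index decreases almost monotonically in the cluster count.
#'
#' @param X data matrix (same scale as the centroids).
#' @param memberships n x c membership matrix.
#' @param centroids c x p centroid matrix.
#' @param center separation reference: `"data"` grand mean (default) or
#'   `"centroids"` average.
#' @return The index value.
#' @export
fukuyama_sugeno <- function(X, memberships, centroids,
                            center = c("data", "centroids")) {
  X <- as.matrix(X); centroids <- as.matrix(centroids)
  cbar <- switch(match.arg(center),
                 data = colMeans(X),
                 centroids = colMeans(centroids))
  n <- nrow(X); c <- nrow(centroids)
  D2 <- outer(rowSums(X^2), rep(1, c)) - 2 * X %*% t(centroids) +
    outer(rep(1, n), rowSums(centroids^2))
  sep <- colSums((t(centroids) - cbar)^2)
  sum(memberships^2 * sweep(pmax(D2, 0), 2, sep, "-"))
}

#' Select the cluster count by minimising the Fukuyama-Sugeno index
#'
#' For each candidate `c` the best of `n_restarts` seeded fuzzy c-means
#' runs (by objective) is kept and its V_FS recorded; the chosen `c*`
#' minimises V_FS, with ties broken toward the smaller count.
#'
#' @param X data matrix (patients x parameters).
#' @param c_range candidate counts, subset of `[2, n - 1]`
#'   (default the full range).
#' @param n_restarts seeded restarts per candidate.
#' @param seed base RNG seed.
#' @param ... forwarded to [fuzzy_cmeans()].
#' @return List with `c_star`, the winning `fit`, and the per-candidate
#'   `vfs` table.
#' @export
select_cluster_count <- function(X, c_range = NULL, n_restarts = 20,
                                 seed = 1, ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(c_range)) c_range <- 2:(n - 1)
  if (!length(c_range)) stop("empty cluster-count range")
  stopifnot(all(c_range >= 2), all(c_range <= n - 1))
  fits <- vector("list", length(c_range))
  vfs <- numeric(length(c_range))
  for (k in seq_along(c_range)) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      f <- fuzzy_cmeans(X, c_range[k], seed = seed + 1000 * k + r, ...)
      if (is.null(best) || f$objective < best$objective) best <- f
    }
    fits[[k]] <- best
    vfs[k] <- best$V_FS
  }
  pick <- which(vfs <= min(vfs) + 1e-12)[1]   # ties toward smaller c
  list(c_star = c_range[pick], fit = fits[[pick]],
       vfs = data.frame(c = c_range, V_FS = vfs))
}

#' Classical multidimensional scaling to two dimensions
#'
#' Projects the rows of `X` (or a distance matrix) onto a 2-D plane and
#' reports the Pearson correlation between original and embedded pairwise
#' Euclidean distances as a fidelity measure.
#'
#' @param X data matrix (>= 3 rows) or a `dist` object.
#' @return List with `coords` (n x 2) and `fidelity`.
#' @export
project_mds <- function(X) {
  d <- if (inherits(X, "dist")) X else stats::dist(as.matrix(X))
  n <- attr(d, "Size")
  if (n < 3) stop("MDS projection needs at least 3 points")
  if (max(d) == 0) stop("degenerate input: all points identical")
  coords <- stats::cmdscale(d, k = 2)
  fidelity <- stats::cor(as.vector(d), as.vector(stats::dist(coords)))
  list(coords = coords, fidelity = fidelity)
}

#' Mean within-cluster coefficient of variation
#'
#' Crisp-assigns each patient to its maximum-membership cluster, then for
#' every cluster with at least two members returns the mean over parameters
#' of the [unbiased_cv()] of the original-scale parameter values; singleton
#' clusters are skipped.
#'
#' @param X original-scale parameter matrix (patients x parameters).
#' @param fit an [fuzzy_cmeans()] result on the same patients.
#' @return Named numeric vector, one mean CV (%) per eligible cluster.
#' @export
per_cluster_cv <- function(X, fit) {
  X <- as.matrix(X)
  assign <- fit$assignment
  out <- numeric(0)
  for (j in sort(unique(assign))) {
    rows <- which(assign == j)
    if (length(rows) < 2) next
    cvs <- apply(X[rows, , drop = FALSE], 2, unbiased_cv)
    out[as.character(j)] <- mean(cvs)
  }
  out
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("Fuzzy c-means: %d clusters, %d patients, objective %.4g, V_FS %.4g\n",
              x$c, nrow(x$memberships), x$objective, x$V_FS))
  if (!is.null(x$projection_fidelity))
    cat(sprintf("  2-D projection fidelity: %.4f\n", x$projection_fidelity))
  cat("  cluster sizes (crisp):",
      paste(tabulate(x$assignment, x$c), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.fcm <- function(x, ...) {
  if (is.null(x$projection)) stop("no projection available")
  graphics::plot(x$projection, col = x$assignment, pch = 19,
                 xlab = "MDS 1", ylab = "MDS 2", ...)
  invisible(x)
}
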