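#' Least-squares monotone (isotonic) regression
#'
#' Fits a non-decreasing sequence to `x` by pool-adjacent-violators
#' (via [stats::isoreg()]). `ties` supplies rank groups for Kruskal's
#' primary approach to tied dissimilarities: within a tie group the values
#' are free to take unequal fitted values, implemented by ordering each
#' group's values ascending before pooling. The fitted values are returned
#' in the original element order and conserve the input sum.
#'
#' @param x numeric vector, ordered by dissimilarity rank.
#' @param ties optional integer vector of non-decreasing rank-group ids,
#'   same length as `x`; `NULL` means all ranks distinct.
#' @return numeric vector of fitted values, same length as `x`.
#' @export
#' @examples
#' monotone_regression(c(2, 1, 3))   # -> 1.5 1.5 3
#' monotone_regression(c(3, 2, 1))   # -> 2 2 2 (full pooling)
monotone_regression <- function(x, ties = NULL) {
  if (!length(x)) cm_abort("monotone_regression: empty input")
  if (is.null(ties)) ties <- seq_along(x)
  if (length(ties) != length(x))
    cm_abort("ties must have the same length as x")
  ord <- order(ties, x)
  fit <- stats::isoreg(x[ord])$yf
  out <- numeric(length(x))
  out[ord] <- fit
  out
}

#' Kruskal stress-1 of a configuration
#'
#' Measures how well the inter-point distances of a configuration reproduce
#' the rank order of the dissimilarities:
#' `sqrt( sum (dhat_ij - dist_ij)^2 / sum dist_ij^2 )` over pairs i < j,
#' where `dist` are Euclidean configuration distances and `dhat` is the
#' monotone regression of `dist` onto the rank order of `d` (primary tie
#' treatment). 0 means a perfect rank fit; the diagonal is excluded.
#'
#' @param d dissimilarities: `cm_dissimilarity`, `dist`, or symmetric matrix.
#' @param coordinates S x m configuration matrix.
#' @return stress-1 in \[0, 1\].
#' @export
kruskal_stress <- function(d, coordinates) {
  D <- as_dissim_matrix(d)
  X <- as.matrix(coordinates)
  if (nrow(X) != nrow(D)) cm_abort("coordinates and dissimilarities disagree in size")
  dvec <- D[lower.tri(D)]
  distvec <- as.vector(dist(X))
  denom <- sum(distvec^2)
  if (denom == 0) cm_abort("degenerate configuration: all points coincide",
                           class = "cm_computation_error")
  dhat <- fit_disparities(dvec, distvec)
  sqrt(sum((distvec - dhat)^2) / denom)
}

# monotone regression of distances onto the rank order of the
# dissimilarities; returns fitted values aligned with distvec
fit_disparities <- function(dvec, distvec) {
  ranks <- match(dvec, sort(unique(dvec)))
  ord <- order(dvec)
  fit <- monotone_regression(distvec[ord], ties = ranks[ord])
  out <- numeric(length(distvec))
  out[ord] <- fit
  out
}

#' Nonmetric multidimensional scaling with Kruskal stress-1
#'
#' Embeds the statements in `dims` dimensions so that inter-point distances
#' reproduce, as well as possible, the rank order of the dissimilarities.
#' Each optimization cycle alternates a monotone-regression update of the
#' disparities with a Guttman (iterative majorization) update of the
#' configuration; stress-1 is non-increasing across cycles within a run.
#' The first start is classical (metric) scaling of the dissimilarities --
#' deterministic and usually near-optimal -- and the remaining
#' `n_starts - 1` starts are seeded uniform random configurations guarding
#' against local minima. The lowest-stress configuration is returned,
#' canonicalized (centered, principal axis horizontal, deterministic sign
#' convention).
#'
#' @param d dissimilarities (`cm_dissimilarity`, `dist`, or symmetric matrix).
#' @param dims embedding dimension (the mapping pipeline uses 2).
#' @param seed integer seed driving all random starts.
#' @param n_starts number of starts (first is classical scaling).
#' @param max_iter maximum cycles per start.
#' @param tol stop when the per-cycle stress-1 improvement falls below this
#'   (stress-1 lives in \[0, 1\], so an absolute threshold is scale-free).
#' @return `cm_pointmap`: list with `coordinates` (S x dims, statement IDs
#'   as rownames), `stress`, `converged`, `n_iter`, `trace` (per-cycle
#'   stress of the best run) and `config` (the settings used).
#' @export
nonmetric_mds <- function(d, dims = 2, seed = 1L, n_starts = 10L,
                          max_iter = 500L, tol = 1e-6) {
  D <- as_dissim_matrix(d)
  S <- nrow(D)
  if (S < 3) cm_abort("nonmetric MDS needs at least 3 statements")
  if (!is_count(n_starts, 1L) || !is_count(max_iter, 1L) || tol <= 0)
    cm_abort("invalid MDS settings")
  dvec <- D[lower.tri(D)]

  run_one <- function(X) {
    X <- sweep(X, 2, colMeans(X))
    distvec <- as.vector(dist(X))
    if (all(distvec < 1e-12)) return(NULL)
    dhat <- fit_disparities(dvec, distvec)
    stress <- sqrt(sum((distvec - dhat)^2) / sum(distvec^2))
    trace <- stress
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      # Guttman transform for the current disparities
      DX <- matrix(0, S, S)
      DX[lower.tri(DX)] <- distvec
      DX <- DX + t(DX)
      DH <- matrix(0, S, S)
      DH[lower.tri(DH)] <- dhat
      DH <- DH + t(DH)
      B <- ifelse(DX > 0, -DH / (DX + (DX == 0)), 0)
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      Xnew <- (B %*% X) / S
      distvec_new <- as.vector(dist(Xnew))
      if (all(distvec_new < 1e-12)) break
      dhat_new <- fit_disparities(dvec, distvec_new)
      stress_new <- sqrt(sum((distvec_new - dhat_new)^2) / sum(distvec_new^2))
      if (stress_new > stress + 1e-12) { converged <- TRUE; break }
      # stress-1 is already normalized to [0, 1], so an absolute
      # improvement threshold is scale-appropriate
      improved <- (stress - stress_new) >= tol
      X <- Xnew; distvec <- distvec_new; dhat <- dhat_new; stress <- stress_new
      trace <- c(trace, stress)
      if (!improved) { converged <- TRUE; break }
    }
    list(X = X, stress = stress, trace = trace, converged = converged,
         n_iter = length(trace) - 1L)
  }

  set.seed(as.integer(seed))
  starts <- vector("list", n_starts)
  X0 <- tryCatch(cmdscale(stats::as.dist(D), k = dims), error = function(e) NULL)
  if (is.null(X0) || is.null(dim(X0)) || ncol(X0) < dims) {
    pad <- matrix(rnorm(S * dims, sd = 1e-3), S, dims)
    if (!is.null(X0) && !is.null(dim(X0)) && ncol(X0) > 0)
      pad[, seq_len(ncol(X0))] <- X0
    X0 <- pad
  }
  starts[[1]] <- X0
  for (r in seq_len(n_starts - 1L))
    starts[[r + 1L]] <- matrix(runif(S * dims, -1, 1), S, dims)

  best <- NULL
  for (X in starts) {
    res <- run_one(X)
    if (!is.null(res) && (is.null(best) || res$stress < best$stress)) best <- res
  }
  if (is.null(best))
    cm_abort("all MDS starts collapsed to a degenerate configuration",
             class = "cm_computation_error")
  if (!best$converged)
    warning(sprintf("nonmetric MDS did not converge within %d iterations (stress %.4f)",
                    max_iter, best$stress))
  # fix the arbitrary map scale (RMS point norm = 1) so the configuration,
  # like the stress, is invariant to any rescaling of the dissimilarities
  Xb <- sweep(best$X, 2, colMeans(best$X))
  coords <- canonicalize(Xb / sqrt(mean(rowSums(Xb^2))))
  ids <- attr(d, "statement_ids") %||% rownames(D) %||% seq_len(S)
  rownames(coords) <- ids
  colnames(coords) <- paste0("dim", seq_len(dims))
  structure(list(coordinates = coords,
                 stress = kruskal_stress(D, coords),
                 converged = best$converged,
                 n_iter = best$n_iter,
                 trace = best$trace,
                 config = list(seed = as.integer(seed), n_starts = n_starts,
                               max_iter = max_iter, tol = tol, dims = dims)),
            class = "cm_pointmap")
}

#' @export
print.cm_pointmap <- function(x, ...) {
  cat(sprintf("Point map: %d statements in %d-D, stress-1 = %.4f (%s, %d iterations)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Canonical orientation of a configuration
#'
#' Stress is invariant under rigid motions, so a configuration is only
#' identified up to rotation, translation and reflection. This fixes one
#' representative: center at the origin, rotate so the first principal axis
#' is horizontal, and flip each axis so the first statement with a non-zero
#' coordinate on it is positive. Pairwise distances are unchanged and the
#' map is idempotent.
#'
#' @param coordinates S x m configuration.
#' @return canonicalized configuration (dimnames preserved).
#' @export
canonicalize <- function(coordinates) {
  X <- as.matrix(coordinates)
  dn <- dimnames(X)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  Xr <- Xc %*% sv$v
  for (j in seq_len(ncol(Xr))) {
    nz <- which(abs(Xr[, j]) > 1e-9)
    if (length(nz) && Xr[nz[1], j] < 0) Xr[, j] <- -Xr[, j]
  }
  dimnames(Xr) <- dn
  Xr
}
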