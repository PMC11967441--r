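#' Row-wise z-scored stage profiles
#'
#' Standardizes each gene's stage profile to mean 0 and unit population
#' standard deviation. Rows with standard deviation below `tol` (constant
#' profiles) are masked out rather than producing NaN.
#'
#' @param stage_mat genes x stages matrix of stage-mean expression.
#' @param tol standard-deviation threshold below which a row is masked.
#' @return list with `z` (z-scored matrix, masked rows removed) and `masked`
#'   (character vector of masked gene ids).
#' @export
standardize_profiles <- function(stage_mat, tol = 1e-12) {
  stage_mat <- as.matrix(stage_mat)
  if (ncol(stage_mat) < 2) stop("need at least two stages", call. = FALSE)
  mu <- rowMeans(stage_mat)
  sdp <- sqrt(rowMeans((stage_mat - mu)^2))     # population convention
  keep <- sdp >= tol
  z <- (stage_mat[keep, , drop = FALSE] - mu[keep]) / sdp[keep]
  list(z = z, masked = rownames(stage_mat)[!keep])
}

# One fuzzy c-means run from a Dirichlet-initialized membership matrix.
.fcm_once <- function(x, c, m, tol, max_iter) {
  n <- nrow(x)
  u <- matrix(stats::rgamma(n * c, 1), n, c)
  u <- u / rowSums(u)
  obj <- numeric(0)
  for (it in seq_len(max_iter)) {
    um <- u^m
    v <- (t(um) %*% x) / colSums(um)            # centroids
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(v) +
      outer(rep(1, n), rowSums(v^2))
    d2 <- pmax(d2, 0)
    obj <- c(obj, sum(um * d2))
    u_new <- matrix(0, n, c)
    zero <- d2 < 1e-300
    has_zero <- rowSums(zero) > 0
    if (any(has_zero)) {                        # coincident point-centroid
      u_new[has_zero, ] <- zero[has_zero, , drop = FALSE] /
        rowSums(zero[has_zero, , drop = FALSE])
    }
    idx <- which(!has_zero)
    if (length(idx)) {
      w <- d2[idx, , drop = FALSE]^(-1 / (m - 1))
      u_new[idx, ] <- w / rowSums(w)
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  um <- u^m
  v <- (t(um) %*% x) / colSums(um)
  d2 <- pmax(outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(v) +
               outer(rep(1, n), rowSums(v^2)), 0)
  obj <- c(obj, sum(um * d2))
  list(u = u, centroids = v, objective = obj[length(obj)], trace = obj,
       iterations = it)
}

#' Fuzzy c-means clustering of stage trajectories
#'
#' Soft clustering of z-scored stage profiles with fuzzifier `m`: centroids
#' \eqn{v_k = \sum_i u_{ik}^m x_i / \sum_i u_{ik}^m} and memberships
#' \eqn{u_{ik} = 1 / \sum_j (d_{ik}/d_{ij})^{2/(m-1)}} (Euclidean distances)
#' alternate until the largest membership change falls below `tol`. Several
#' random Dirichlet-initialized restarts are run and the solution with the
#' lowest objective \eqn{J = \sum_{ik} u_{ik}^m d_{ik}^2} is kept.
#' Deterministic given `seed`.
#'
#' @param x genes x stages matrix (see [standardize_profiles()]).
#' @param c number of clusters (default 4, the archetype count of early ear
#'   development trajectories).
#' @param m fuzzifier > 1, default 2.
#' @param seed integer seed.
#' @param restarts random restarts, default 10.
#' @param tol convergence threshold on max membership change, default 1e-6.
#' @param max_iter iteration cap per restart, default 1000.
#' @return list of class `fuzzy_cmeans`: `membership` (genes x c, rows sum to
#'   1), `centroids` (c x stages), `cluster` (hard argmax assignment),
#'   `objective`, `trace` (non-increasing objective values of the winning
#'   restart), `m`, `seed`.
#' @export
fuzzy_cmeans <- function(x, c = 4, m = 2, seed = 1L, restarts = 10,
                         tol = 1e-6, max_iter = 1000) {
  x <- as.matrix(x)
  if (c < 1) stop("c must be at least 1", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must exceed 1", call. = FALSE)
  if (c > nrow(x)) stop("more clusters than rows", call. = FALSE)
  if (c == 1) {
    v <- matrix(colMeans(x), 1, ncol(x))
    u <- matrix(1, nrow(x), 1)
    d2 <- rowSums((x - matrix(v, nrow(x), ncol(x), byrow = TRUE))^2)
    res <- list(u = u, centroids = v, objective = sum(d2), trace = sum(d2),
                iterations = 0L)
  } else {
    set.seed(as.integer(seed))
    best <- NULL
    for (r in seq_len(restarts)) {
      run <- .fcm_once(x, c, m, tol, max_iter)
      if (is.null(best) || run$objective < best$objective) best <- run
    }
    res <- best
  }
  rownames(res$u) <- rownames(x)
  colnames(res$centroids) <- colnames(x)
  structure(list(membership = res$u, centroids = res$centroids,
                 cluster = stats::setNames(max.col(res$u), rownames(x)),
                 objective = res$objective, trace = res$trace,
                 m = m, c = c, seed = as.integer(seed)),
            class = "fuzzy_cmeans")
}

#' Score contiguous two-phase splits of the stage order
#'
#' For each contiguous split k (stages 1..k vs k+1..T), the score is the mean
#' pairwise distance between stage vectors across the phases divided by the
#' pooled mean pairwise distance within the phases (splits with no
#' within-phase pair, or a zero denominator, use the raw between-phase mean).
#' The split with the highest score is chosen; ties break toward the earlier
#' split. On ear-development stage trajectories this recovers the V6-V8 /
#' V9-V10 phase structure.
#'
#' @param stage_vectors stages x features matrix: one row per stage in stage
#'   order (e.g. per-stage columns of cluster centroids, or per-stage
#'   log-mean expression over genes).
#' @return list of class `phase_partition`: `split` (chosen k), `phase1`,
#'   `phase2` (stage names), `scores` (data.frame split/score).
#' @export
score_phase_splits <- function(stage_vectors) {
  sv <- as.matrix(stage_vectors)
  T_ <- nrow(sv)
  if (T_ < 2) stop("need at least two stages", call. = FALSE)
  D <- as.matrix(stats::dist(sv))
  scores <- numeric(T_ - 1)
  for (k in seq_len(T_ - 1)) {
    i1 <- seq_len(k); i2 <- seq(k + 1, T_)
    between <- mean(D[i1, i2, drop = FALSE])
    within <- c(if (length(i1) > 1) D[i1, i1][upper.tri(D[i1, i1])],
                if (length(i2) > 1) D[i2, i2][upper.tri(D[i2, i2])])
    scores[k] <- if (length(within) == 0 || mean(within) == 0) between
                 else between / mean(within)
  }
  k_best <- which.max(scores)          # which.max takes the earliest maximum
  stages <- rownames(sv)
  if (is.null(stages)) stages <- paste0("S", seq_len(T_))
  structure(list(split = k_best,
                 phase1 = stages[seq_len(k_best)],
                 phase2 = stages[seq(k_best + 1, T_)],
                 scores = data.frame(split = seq_len(T_ - 1), score = scores)),
            class = "phase_partition")
}
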