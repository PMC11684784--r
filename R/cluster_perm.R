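# Cluster-based permutation tests on 1-D time courses and 2-D time-time
# grids: mass-univariate t maps, thresholded at a parametric quantile,
# contiguous supra-threshold clusters scored by summed t, max-cluster
# permutation null.

# vectorized two-sample (Welch-free, pooled) t per column of a subjects x
# points matrix pair; classic independent-samples t as in mass-univariate
# sensor statistics
.t_two_sample <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(b, 2, mb)^2) / (nb - 1)
  sp <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  t <- (ma - mb) / sqrt(sp * (1 / na + 1 / nb))
  t[!is.finite(t)] <- 0
  t
}

.t_one_sample <- function(a, mu = 0) {
  n <- nrow(a)
  m <- colMeans(a)
  v <- colSums(sweep(a, 2, m)^2) / (n - 1)
  t <- (m - mu) / sqrt(v / n)
  t[!is.finite(t)] <- 0
  t
}

# connected components of a logical mask; 1-D runs or 2-D 4-neighbourhood
.find_clusters <- function(mask, grid_dim) {
  if (length(grid_dim) == 1) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    Map(function(s, e) s:e, starts[r$values], ends[r$values])
  } else {
    m <- matrix(mask, grid_dim[1], grid_dim[2])
    lab <- matrix(0L, grid_dim[1], grid_dim[2])
    cur <- 0L
    for (j in seq_len(grid_dim[2])) for (i in seq_len(grid_dim[1])) {
      if (!m[i, j] || lab[i, j] != 0L) next
      cur <- cur + 1L
      queue <- matrix(c(i, j), 1)
      while (nrow(queue) > 0) {
        q <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        if (q[1] < 1 || q[1] > grid_dim[1] || q[2] < 1 || q[2] > grid_dim[2])
          next
        if (!m[q[1], q[2]] || lab[q[1], q[2]] != 0L) next
        lab[q[1], q[2]] <- cur
        queue <- rbind(queue,
                       c(q[1] - 1L, q[2]), c(q[1] + 1L, q[2]),
                       c(q[1], q[2] - 1L), c(q[1], q[2] + 1L))
      }
    }
    if (cur == 0L) list() else split(which(lab > 0), lab[lab > 0])
  }
}

# summed-t scores of supra-threshold clusters for one t map
.cluster_sums <- function(t_map, thr, tail, grid_dim) {
  out <- list()
  if (tail %in% c("two_sided", "one_sided_pos")) {
    for (idx in .find_clusters(t_map > thr, grid_dim)) {
      out[[length(out) + 1L]] <- list(members = idx, t_sum = sum(t_map[idx]))
    }
  }
  if (tail %in% c("two_sided", "one_sided_neg")) {
    for (idx in .find_clusters(t_map < -thr, grid_dim)) {
      out[[length(out) + 1L]] <- list(members = idx, t_sum = sum(t_map[idx]))
    }
  }
  out
}

#' Cluster-based permutation t-test
#'
#' Mass-univariate t statistics over a 1-D (time) or 2-D (training time x
#' testing time) grid, thresholded at the parametric t quantile
#' `cluster_alpha` (respecting the tail); contiguous supra-threshold points
#' (time-adjacency in 1-D, 4-neighbourhood in 2-D) form clusters scored by
#' their summed t. The null distribution is the maximum cluster score (|sum|
#' for two-sided, signed for one-sided) over random group-label permutations
#' (two-sample) or sign flips (one-sample); cluster p-values use the
#' `(b + 1) / (m + 1)` estimator.
#'
#' @param scores_a subjects x points matrix (or subjects x d1 x d2 array) of
#'   the first group, or of the within-subject differences for the one-sample
#'   test.
#' @param scores_b second group, or NULL for the one-sample (sign-flip) test.
#' @param tail `"two_sided"`, `"one_sided_pos"` or `"one_sided_neg"`.
#' @param n_perm number of permutations (default 1000).
#' @param cluster_alpha cluster-forming alpha (default 0.05).
#' @param seed integer seed for the permutations.
#' @param mu null value for the one-sample test (default 0).
#' @return a `cluster_test` list: `clusters` (members, t_sum, p_perm),
#'   `t_map`, `threshold`, `null_max`, `n_permutations`, `tail`, `grid_dim`.
#' @export
cluster_perm_test <- function(scores_a, scores_b = NULL,
                              tail = c("two_sided", "one_sided_pos",
                                       "one_sided_neg"),
                              n_perm = 1000L, cluster_alpha = 0.05,
                              seed = 1L, mu = 0) {
  tail <- match.arg(tail)
  dims_a <- dim(scores_a)
  grid_dim <- if (length(dims_a) == 3) dims_a[2:3] else dims_a[2]
  flatten <- function(x) {
    if (length(dim(x)) == 3) matrix(x, dim(x)[1], prod(dim(x)[2:3])) else x
  }
  a <- flatten(scores_a)
  two_sample <- !is.null(scores_b)
  if (two_sample) {
    b <- flatten(scores_b)
    if (ncol(a) != ncol(b)) stop("grids of the two groups differ")
    if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 subjects per group")
    df <- nrow(a) + nrow(b) - 2
    t_obs <- .t_two_sample(a, b)
  } else {
    if (nrow(a) < 2) stop("need >= 2 subjects")
    df <- nrow(a) - 1
    t_obs <- .t_one_sample(a, mu)
  }
  thr <- if (tail == "two_sided") stats::qt(1 - cluster_alpha / 2, df)
         else stats::qt(1 - cluster_alpha, df)
  obs <- .cluster_sums(t_obs, thr, tail, grid_dim)
  score_of <- function(cl) {
    s <- vapply(cl, `[[`, numeric(1), "t_sum")
    if (tail == "two_sided") abs(s) else if (tail == "one_sided_pos") s else -s
  }
  if (two_sample) pool <- rbind(a, b)
  null_max <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      if (two_sample) {
        idx <- sample.int(nrow(pool))
        t_p <- .t_two_sample(pool[idx[seq_len(nrow(a))], , drop = FALSE],
                             pool[idx[-seq_len(nrow(a))], , drop = FALSE])
      } else {
        signs <- sample(c(-1, 1), nrow(a), replace = TRUE)
        t_p <- .t_one_sample((a - mu) * signs, 0)
      }
      cl <- .cluster_sums(t_p, thr, tail, grid_dim)
      if (length(cl) == 0) 0 else max(score_of(cl))
    }, numeric(1))
  })
  clusters <- lapply(obs, function(cl) {
    s <- if (tail == "two_sided") abs(cl$t_sum)
         else if (tail == "one_sided_pos") cl$t_sum else -cl$t_sum
    cl$p_perm <- (sum(null_max >= s) + 1) / (n_perm + 1)
    cl
  })
  # one-sided positive tests never report negative-sum clusters (and vice
  # versa): .cluster_sums already restricts the sign
  structure(list(clusters = clusters, t_map = t_obs, threshold = thr,
                 null_max = null_max, n_permutations = n_perm,
                 cluster_alpha = cluster_alpha, tail = tail,
                 grid_dim = grid_dim, df = df),
            class = "cluster_test")
}

#' Smallest cluster p-value (1 if no clusters)
#' @param x a `cluster_test`.
#' @export
min_cluster_p <- function(x) {
  if (length(x$clusters) == 0) return(1)
  min(vapply(x$clusters, `[[`, numeric(1), "p_perm"))
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test: %s, %d permutations, threshold |t| > %.3f>\n",
              x$tail, x$n_permutations, x$threshold))
  if (length(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (cl in x$clusters) {
      cat(sprintf("  cluster of %d points, t_sum = %.2f, p = %.4f\n",
                  length(cl$members), cl$t_sum, cl$p_perm))
    }
  }
  invisible(x)
}
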