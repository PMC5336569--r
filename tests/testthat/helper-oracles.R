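# Independent oracles used only by the tests.

# Explicit prefix-checking step-down procedure with assumed family size m:
# the i-th smallest p is flagged iff every smaller p clears its own
# threshold alpha / (m - rank + 1).
oracle_holm <- function(p, m, alpha = 0.05) {
  k <- length(p)
  ord <- order(p)
  flag <- logical(k)
  for (i in seq_len(k)) {
    ok <- TRUE
    for (j in seq_len(i)) {
      if (p[ord[j]] > alpha / (m - j + 1)) { ok <- FALSE; break }
    }
    flag[ord[i]] <- ok
  }
  flag
}

# Iterative NIPALS PLS1 first component.
oracle_nipals_pls1 <- function(X, y, iter = 200, tol = 1e-12) {
  yc <- y - mean(y)
  u <- yc
  w <- NULL
  for (i in seq_len(iter)) {
    w_new <- as.numeric(crossprod(X, u)) / sum(u^2)
    w_new <- w_new / sqrt(sum(w_new^2))
    if (!is.null(w) && sum((w_new - w)^2) < tol) { w <- w_new; break }
    w <- w_new
    t <- as.numeric(X %*% w)
    c1 <- sum(yc * t) / sum(t^2)
    u <- yc * c1
  }
  list(w = w, t = as.numeric(X %*% w))
}

# Brute-force Ward agglomeration by direct minimisation of the
# within-cluster sum-of-squares increase; heights are reported as 2 * dSS,
# the Lance-Williams value for squared-Euclidean input.
oracle_ward <- function(points, labels = rownames(points)) {
  clusters <- lapply(seq_len(nrow(points)), function(i)
    list(idx = i, members = labels[i]))
  heights <- numeric(0)
  merges <- list()
  dss <- function(a, b) {
    xa <- points[a, , drop = FALSE]; xb <- points[b, , drop = FALSE]
    ca <- colMeans(xa); cb <- colMeans(xb)
    (nrow(xa) * nrow(xb)) / (nrow(xa) + nrow(xb)) * sum((ca - cb)^2)
  }
  while (length(clusters) > 1) {
    best <- NULL; best_val <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        v <- dss(clusters[[i]]$idx, clusters[[j]]$idx)
        if (v < best_val - 1e-12) { best_val <- v; best <- c(i, j) }
      }
    }
    heights <- c(heights, 2 * best_val)
    merged <- list(
      idx = c(clusters[[best[1]]]$idx, clusters[[best[2]]]$idx),
      members = sort(c(clusters[[best[1]]]$members,
                       clusters[[best[2]]]$members)))
    merges <- c(merges, list(merged$members))
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, merges = merges)
}

# Cluster memberships formed during an hclust run, as sorted label sets.
hclust_merge_sets <- function(hc) {
  sets <- list()
  out <- list()
  for (i in seq_along(hc$height)) {
    pick <- function(v) if (v < 0) hc$labels[-v] else sets[[v]]
    sets[[i]] <- sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2])))
    out[[i]] <- sets[[i]]
  }
  out
}

# Fine grid search for the in-plane rotation angle maximizing the absolute
# correlation of cos(a) s1 + sin(a) s2 with the target.
oracle_rotation_angle <- function(s1, s2, target, step_deg = 0.01) {
  angles <- seq(-90, 90 - step_deg, by = step_deg) * pi / 180
  cors <- vapply(angles, function(a)
    abs(stats::cor(cos(a) * s1 + sin(a) * s2, target)), numeric(1))
  angles[which.max(cors)]
}
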