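# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles, without touching the code
# paths they check.

# Exhaustive greedy Ward: at every step evaluate the minimum-variance cost
# of every candidate pair; heights on the distance scale (sqrt(2 * delta-SS)).
greedy_ward_oracle <- function(x) {
  n <- nrow(x)
  members <- as.list(seq_len(n))
  ids <- -(seq_len(n))
  active <- seq_len(n)
  merges <- vector("list", n - 1)
  heights <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    best <- NULL
    bestd <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) if (i < j) {
      a <- members[[active[i]]]
      b <- members[[active[j]]]
      ma <- colMeans(x[a, , drop = FALSE])
      mb <- colMeans(x[b, , drop = FALSE])
      d <- (length(a) * length(b)) / (length(a) + length(b)) * sum((ma - mb)^2)
      if (d < bestd - 1e-12) {
        bestd <- d
        best <- c(active[i], active[j])
      }
    }
    merges[[s]] <- sort(c(ids[best[1]], ids[best[2]]))
    heights[s] <- sqrt(2 * bestd)
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    ids[best[1]] <- s
    active <- setdiff(active, best[2])
  }
  list(merges = merges, heights = heights)
}

# Facet-enumeration convex hull for small point sets: every triple whose
# plane has all points on one side is a hull facet.
brute_hull_oracle <- function(P) {
  n <- nrow(P)
  ctr <- colMeans(P)
  vol <- 0
  area <- 0
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- P[i, ]; b <- P[j, ]; c <- P[k, ]
    nrm <- cross3(b - a, c - a)
    if (sqrt(sum(nrm^2)) < 1e-12) next
    s <- P %*% nrm - sum(nrm * a)
    if (all(s <= 1e-9) || all(s >= -1e-9)) {
      area <- area + 0.5 * sqrt(sum(nrm^2))
      vol <- vol + abs(sum((a - ctr) * cross3(b - ctr, c - ctr))) / 6
    }
  }
  list(volume = vol, area = area)
}

# Point-in-hull test for the voxelized-hull oracle: a point is inside the
# hull iff every facet plane has it on the inner side.
brute_hull_contains <- function(P, q) {
  n <- nrow(P)
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- P[i, ]; b <- P[j, ]; c <- P[k, ]
    nrm <- cross3(b - a, c - a)
    if (sqrt(sum(nrm^2)) < 1e-12) next
    s <- P %*% nrm - sum(nrm * a)
    if (all(s <= 1e-9)) {
      if (sum(q * nrm) - sum(nrm * a) > 1e-9) return(FALSE)
    } else if (all(s >= -1e-9)) {
      if (sum(q * nrm) - sum(nrm * a) < -1e-9) return(FALSE)
    }
  }
  TRUE
}

# Queue-based flood fill under 26-connectivity.
flood_fill_count <- function(mask) {
  dims <- dim(mask)
  seen <- array(FALSE, dims)
  idx <- which(mask != 0, arr.ind = TRUE)
  count <- 0
  key <- function(v) paste(v, collapse = ",")
  fg <- new.env(hash = TRUE)
  for (r in seq_len(nrow(idx))) assign(key(idx[r, ]), TRUE, envir = fg)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (seen[v[1], v[2], v[3]]) next
    count <- count + 1
    queue <- list(v)
    seen[v[1], v[2], v[3]] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nb <- cur + c(dx, dy, dz)
        if (any(nb < 1) || any(nb > dims)) next
        if (!seen[nb[1], nb[2], nb[3]] &&
            exists(key(nb), envir = fg, inherits = FALSE)) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  count
}

# Silhouette and Dunn from raw pairwise distances.
silhouette_brute <- function(x, labels) {
  dm <- as.matrix(dist(x))
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(dm[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(dm[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

dunn_brute <- function(x, labels) {
  dm <- as.matrix(dist(x))
  groups <- unique(labels)
  inter <- Inf
  diam <- 0
  for (g in groups) {
    ig <- which(labels == g)
    if (length(ig) > 1) diam <- max(diam, max(dm[ig, ig]))
    for (h in setdiff(groups, g)) inter <- min(inter, min(dm[ig, labels == h]))
  }
  inter / diam
}

# Hand-written Cox partial log-likelihood for a single covariate, no ties.
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Multinomial log-likelihood (reference = first factor level) for the
# direct-maximization oracle.
multinom_loglik <- function(par, g, x) {
  levs <- levels(g)
  k <- length(levs)
  b <- matrix(par, nrow = k - 1)  # columns: intercept, slope
  eta <- cbind(0, sapply(seq_len(k - 1), function(j) b[j, 1] + b[j, 2] * x))
  ll <- 0
  for (i in seq_along(g)) {
    ll <- ll + eta[i, match(g[i], levs)] - log(sum(exp(eta[i, ])))
  }
  ll
}
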