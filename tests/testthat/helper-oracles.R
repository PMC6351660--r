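# Independent oracles used by the tests. These deliberately re-derive
# results by brute force (flood fill, enumeration, closed forms, grid
# search) and never call the implementation paths they check.

# Stack-based flood fill labeling; seeds scanned in raster (row-major)
# order so labels are numbered by first pixel, matching the canonical
# labeling contract.
oracle_flood_fill <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L)
    dc <- c(0L, -1L, 1L, 0L)
  }
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_along(dr)) {
        rr <- p[1L] + dr[k]; cc <- p[2L] + dc[k]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Exhaustive two-sample KS oracle: exact D and exact p by enumerating all
# choose(m + n, m) group assignments of the pooled sample (no ties).
oracle_ks_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  ks_stat <- function(a, b) {
    z <- sort(c(a, b))
    Fa <- vapply(z, function(t) mean(a <= t), numeric(1))
    Fb <- vapply(z, function(t) mean(b <= t), numeric(1))
    max(abs(Fa - Fb))
  }
  d_obs <- ks_stat(x, y)
  pool <- c(x, y)
  combs <- utils::combn(m + n, m)
  ds <- apply(combs, 2L, function(ix) ks_stat(pool[ix], pool[-ix]))
  list(statistic = d_obs, p_value = mean(ds >= d_obs - 1e-12))
}

# Closed-form least-squares line via the normal equations.
oracle_lsq_line <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x * x) - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# Dense grid search minimizing the linear-domain sum of squared residuals
# of the monoexponential model; s0 is profiled in closed form per t2.
oracle_grid_t2star <- function(signal_matrix, te, t2_grid) {
  best_t2 <- rep(NA_real_, nrow(signal_matrix))
  best_ssr <- rep(Inf, nrow(signal_matrix))
  for (t2 in t2_grid) {
    mdl <- exp(-te / t2)
    s0 <- (signal_matrix %*% mdl) / sum(mdl^2)
    ssr <- rowSums((signal_matrix - s0 %*% t(mdl))^2)
    upd <- ssr < best_ssr
    best_ssr[upd] <- ssr[upd]
    best_t2[upd] <- t2
  }
  best_t2
}

# Brute-force greedy co-positivity matcher: all-pairs distances, repeatedly
# take the globally smallest admissible pair (ties by raster order).
oracle_match_once <- function(from, to, radius) {
  nf <- nrow(from); nt <- nrow(to)
  matched <- rep(FALSE, nf)
  if (nf == 0L || nt == 0L) return(matched)
  free_t <- rep(TRUE, nt)
  repeat {
    best <- NULL; best_d <- Inf
    for (i in which(!matched)) for (j in which(free_t)) {
      d <- sqrt((from$x_um[i] - to$x_um[j])^2 +
                  (from$y_um[i] - to$y_um[j])^2)
      if (d <= radius && d < best_d - 1e-12) {
        best <- c(i, j); best_d <- d
      }
    }
    if (is.null(best)) break
    matched[best[1L]] <- TRUE
    free_t[best[2L]] <- FALSE
  }
  matched
}

# Disc mask on an n x n raster, center and radius in pixels.
disc_mask <- function(n, center, radius) {
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  (rr - center[1L])^2 + (cc - center[2L])^2 <= radius^2
}

# Effect factors planted in the simulated CSF1R trials (shared fixture).
trial_effects <- function() {
  jsonlite::read_json(system.file("extdata", "trial_effects.json",
                                  package = "femri"),
                      simplifyVector = TRUE)
}
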