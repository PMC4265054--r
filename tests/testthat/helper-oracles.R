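# Independent oracles used across the suite. Each is deliberately naive and
# shares no code with the implementation it checks.

# First k singular triplets by power iteration with deflation.
power_iteration_svd <- function(m, k = min(dim(m)), iters = 5000) {
  m <- unname(m)
  d <- numeric(k)
  us <- matrix(0, nrow(m), k)
  vs <- matrix(0, ncol(m), k)
  resid <- m
  for (comp in seq_len(k)) {
    set.seed(comp) # deterministic start
    v <- rnorm(ncol(m))
    v <- v / sqrt(sum(v^2))
    for (i in seq_len(iters)) {
      v_new <- crossprod(resid, resid %*% v)
      nv <- sqrt(sum(v_new^2))
      if (nv == 0) break
      v_new <- drop(v_new) / nv
      if (max(abs(v_new - v)) < 1e-14 || max(abs(v_new + v)) < 1e-14) {
        v <- v_new
        break
      }
      v <- v_new
    }
    u <- drop(resid %*% v)
    s <- sqrt(sum(u^2))
    d[comp] <- s
    if (s > 0) {
      u <- u / s
      us[, comp] <- u
      vs[, comp] <- v
      resid <- resid - s * tcrossprod(u, v)
    }
  }
  list(d = d, u = us, v = vs)
}

# orient a singular pair like the package does: largest |u| entry positive
orient_like_package <- function(u, v) {
  if (u[which.max(abs(u))] < 0) list(u = -u, v = -v) else list(u = u, v = v)
}

# Brute-force KNN imputation: literal transcription of the rule.
knn_impute_oracle <- function(values, k) {
  out <- values
  for (i in seq_len(nrow(values))) {
    miss_cols <- which(is.na(values[i, ]))
    if (length(miss_cols) == 0) next
    d <- rep(Inf, nrow(values))
    for (j in seq_len(nrow(values))) {
      if (j == i) next
      co <- which(!is.na(values[i, ]) & !is.na(values[j, ]))
      if (length(co) == 0) next
      d[j] <- sqrt(sum((values[i, co] - values[j, co])^2) / length(co))
    }
    for (cc in miss_cols) {
      cand <- which(is.finite(d) & !is.na(values[, cc]))
      if (length(cand) < k) {
        out[i, cc] <- mean(values[!is.na(values[, cc]), cc])
      } else {
        ord <- cand[order(d[cand], cand)]
        out[i, cc] <- mean(values[ord[1:k], cc])
      }
    }
  }
  out
}

# Lagrange interpolating cubic through exactly four control points; the
# reference for four-point spline evaluation (including extrapolation).
lagrange_cubic <- function(x, y, t) {
  vapply(t, function(tt) {
    sum(vapply(seq_along(x), function(i) {
      y[i] * prod((tt - x[-i]) / (x[i] - x[-i]))
    }, numeric(1)))
  }, numeric(1))
}

# Naive slot-bookkeeping simulator: per-slot loops, explicit pile variable.
slot_sim_oracle <- function(t_end, n_slots = 77, barrier = 14,
                            recovery = 25, shock_at = 0,
                            mode = c("cohort", "drain")) {
  mode <- match.arg(mode)
  slots <- rep(1 / n_slots, n_slots)
  dens <- matrix(NA_real_, t_end + 1, n_slots)
  dens[1, ] <- slots
  draining <- FALSE
  for (t in 0:(t_end - 1)) {
    blocked <- !is.null(shock_at) && t >= shock_at && t < shock_at + recovery
    if (mode == "drain" && !is.null(shock_at) && t >= shock_at + recovery) {
      draining <- slots[barrier] > 1 / n_slots + 1e-12
    } else {
      draining <- FALSE
    }
    nxt <- numeric(n_slots)
    for (s in seq_len(n_slots)) {
      dest <- if (s == n_slots) 1 else s + 1
      if (s == barrier && blocked) {
        nxt[barrier] <- nxt[barrier] + slots[s]
      } else if (s == barrier && draining) {
        pass <- min(slots[s], 1 / n_slots)
        nxt[dest] <- nxt[dest] + pass
        nxt[barrier] <- nxt[barrier] + slots[s] - pass
      } else {
        nxt[dest] <- nxt[dest] + slots[s]
      }
    }
    slots <- nxt
    dens[t + 2, ] <- slots
  }
  dens
}

# Exhaustive upper-tail hypergeometric probability by direct summation.
hyper_upper_oracle <- function(N, K, n, k) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# small random expression matrix with ids
random_expr_matrix <- function(m, n, seed = 1, pvalues = FALSE) {
  set.seed(seed)
  vals <- matrix(rnorm(m * n), m, n,
                 dimnames = list(sprintf("g%03d", 1:m), sprintf("s%03d", 1:n)))
  pv <- if (pvalues) {
    matrix(runif(m * n), m, n, dimnames = dimnames(vals))
  } else NULL
  expression_matrix(vals, pvalues = pv)
}
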