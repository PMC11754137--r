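# Shared fixtures and independent oracles, built in code at test time.

# Deterministic dense-sampling oracle for ray-pixel intersection lengths:
# stratified midpoint sampling of the segment, binned by pixel. Each
# per-pixel length estimate is within 2*L/n of the truth.
ray_sampling_oracle <- function(grid, p0, p1, n = 1e5) {
  tt <- (seq_len(n) - 0.5) / n
  x <- p0[1] + tt * (p1[1] - p0[1])
  y <- p0[2] + tt * (p1[2] - p0[2])
  L <- sqrt(sum((p1 - p0)^2))
  corner <- c(grid$origin[1] - grid$extent / 2,
              grid$origin[2] - grid$extent / 2)
  ix <- floor((x - corner[1]) / grid$spacing)
  iy <- floor((y - corner[2]) / grid$spacing)
  ok <- ix >= 0 & ix < grid$nx & iy >= 0 & iy < grid$ny
  if (!any(ok)) return(numeric(0))
  k <- ix[ok] + grid$nx * iy[ok] + 1
  cnt <- table(k)
  out <- as.numeric(cnt) * L / n
  names(out) <- names(cnt)
  out
}

# Exhaustive minimum-cost path search over a small strip under the DP cost
# model (node cost 1 - normalized envelope, transition cost w*|jump|,
# |jump| <= L). Returns the minimal cost and the lexicographically earliest
# optimal path.
dp_brute_force <- function(env, jump_limit, w) {
  M <- nrow(env)
  Wd <- ncol(env)
  node <- 1 - env / max(env)
  paths <- as.matrix(expand.grid(rep(list(seq_len(Wd)), M)))[, M:1, drop = FALSE]
  if (M > 1) {
    jumps <- abs(paths[, -1, drop = FALSE] - paths[, -M, drop = FALSE])
    feas <- apply(jumps <= jump_limit, 1, all)
    paths <- paths[feas, , drop = FALSE]
    jumps <- jumps[feas, , drop = FALSE]
    trans <- rowSums(jumps) * w
  } else {
    trans <- rep(0, nrow(paths))
  }
  nodec <- vapply(seq_len(nrow(paths)),
                  function(r) sum(node[cbind(seq_len(M), paths[r, ])]),
                  numeric(1))
  cost <- nodec + trans
  best <- min(cost)
  cand <- paths[cost <= best + 1e-12, , drop = FALSE]
  ord <- do.call(order, as.data.frame(cand))
  list(cost = best, path = cand[ord[1], ])
}

# Closed-form ridge regression solution (normal equations, dense).
ridge_oracle <- function(A, y, lambda) {
  solve(crossprod(A) + diag(2 * lambda, ncol(A)), crossprod(A, y))
}

# Small reusable geometries
small_geom <- function(M = 32) ring_array(n_elements = M)
small_scan <- function(N = 4) beacon_scan(n_positions = N)
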