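#' Inversion configuration
#'
#' Settings for the L2-regularized travel-time inversion. The objective is
#' `0.5 * ||W z - dt||^2 + lambda * ||z||^2` in the slowness deficit
#' `z = 1/v0 - 1/v`, solved by Nesterov's accelerated gradient method with
#' step size `1/L`, where `L` is the largest eigenvalue of `W'W + 2*lambda*I`
#' estimated by power iteration (fixed all-ones start vector, so runs are
#' bit-reproducible).
#'
#' @param lambda_reg regularization weight (>= 0). `NULL` (default) selects
#'   `1e-3 * L_data / K` with `L_data` the power-iteration estimate of
#'   `||W'W||` and `K` the pixel count: a small data-relative ridge whose
#'   main role is numerical conditioning; with the 200-iteration cap, early
#'   stopping provides most of the effective regularization.
#' @param max_iterations hard iteration cap (default 200).
#' @param tolerance relative objective-change stopping threshold
#'   (default 1e-10; secondary to the iteration cap).
#' @param restart logical; adaptive (gradient-based) momentum restart,
#'   which recovers a fast linear rate on well-conditioned systems
#'   (default TRUE).
#' @param power_iterations power-iteration steps for the Lipschitz estimate.
#' @return an object of class `inversion_config`.
#' @export
inversion_config <- function(lambda_reg = NULL, max_iterations = 200L,
                             tolerance = 1e-10, restart = TRUE,
                             power_iterations = 100L) {
  stopifnot(is.null(lambda_reg) || lambda_reg >= 0, max_iterations >= 1)
  structure(list(lambda_reg = lambda_reg,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, restart = isTRUE(restart),
                 power_iterations = as.integer(power_iterations)),
            class = "inversion_config")
}

# Largest-eigenvalue estimate of W'W by power iteration with a fixed
# deterministic start; falls back to the Frobenius-norm upper bound if the
# iteration degenerates.
estimate_data_lipschitz <- function(W, n_iter = 100L) {
  v <- rep(1, ncol(W))
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(n_iter)) {
    u <- as.numeric(Matrix::crossprod(W, W %*% v))
    nu <- sqrt(sum(u^2))
    if (!is.finite(nu) || nu == 0) return(sum(W@x^2))  # Frobenius bound
    lam <- nu
    v <- u / nu
  }
  lam
}

#' Solve for the slowness deficit
#'
#' Minimizes `0.5*||W z - dt||^2 + lambda*||z||^2` by Nesterov's
#' accelerated gradient method, starting from `z = 0`, with the standard
#' momentum sequence and (optionally) adaptive restart. Deterministic:
#' identical inputs give bit-identical iterates.
#'
#' @param op a [build_path_operator()] result.
#' @param delta a `"delta"` [tof_table()] (or a numeric vector of length
#'   `M*N` in beacon-major order).
#' @param cfg an [inversion_config()].
#' @return an object of class `slowness_deficit`: per-pixel deficit values
#'   `z = 1/v0 - 1/v` (s/m) on the operator's grid, with the per-iteration
#'   objective `trace`, the effective `lambda_reg` and step parameters.
#' @export
solve_deficit <- function(op, delta, cfg = inversion_config()) {
  stopifnot(inherits(op, "path_operator"))
  y <- if (inherits(delta, "tof_table")) tof_vector(delta) else as.numeric(delta)
  if (length(y) != nrow(op$W))
    stop("data vector length must equal M*N (path-operator rows)")
  W <- op$W
  if (Matrix::nnzero(W) == 0) stop("path operator is identically zero")
  L_data <- estimate_data_lipschitz(W, cfg$power_iterations)
  lambda <- if (is.null(cfg$lambda_reg)) 1e-3 * L_data / op$K else cfg$lambda_reg
  L <- (L_data + 2 * lambda) * 1.01  # small safety factor on the estimate

  objective <- function(z, Wz) 0.5 * sum((Wz - y)^2) + lambda * sum(z^2)

  K <- op$K
  z_old <- numeric(K)
  yv <- z_old
  theta <- 1
  trace <- numeric(cfg$max_iterations)
  obj_prev <- objective(z_old, numeric(length(y)))
  z <- z_old
  for (it in seq_len(cfg$max_iterations)) {
    Wy <- as.numeric(W %*% yv)
    g <- as.numeric(Matrix::crossprod(W, Wy - y)) + 2 * lambda * yv
    z <- yv - g / L
    if (cfg$restart && sum(g * (z - z_old)) > 0) {
      # momentum points uphill: restart from the last iterate
      theta <- 1
      yv <- z_old
      Wy <- as.numeric(W %*% yv)
      g <- as.numeric(Matrix::crossprod(W, Wy - y)) + 2 * lambda * yv
      z <- yv - g / L
    }
    theta_new <- (1 + sqrt(1 + 4 * theta^2)) / 2
    yv <- z + ((theta - 1) / theta_new) * (z - z_old)
    theta <- theta_new
    obj <- objective(z, as.numeric(W %*% z))
    trace[it] <- obj
    if (is.finite(obj_prev) && obj_prev > 0 &&
        abs(obj_prev - obj) < cfg$tolerance * obj_prev && it > 1) {
      trace <- trace[seq_len(it)]
      z_old <- z
      break
    }
    obj_prev <- obj
    z_old <- z
  }
  structure(list(values = matrix(z, op$grid$nx, op$grid$ny),
                 grid = op$grid, trace = trace, lambda_reg = lambda,
                 lipschitz = L, iterations = length(trace)),
            class = "slowness_deficit")
}

#' @export
print.slowness_deficit <- function(x, ...) {
  cat(sprintf("<slowness_deficit> %d x %d, %d iterations, final objective %.4g\n",
              x$grid$nx, x$grid$ny, x$iterations,
              x$trace[length(x$trace)]))
  invisible(x)
}

#' Assemble the SOS map from a slowness deficit
#'
#' Inverts `z = 1/v0 - 1/v` pixel-wise: `v = 1/(1/v0 - z)`. Deficits that
#' would drive the reconstructed speed above `2*v0` (or negative) are
#' clipped; the number of clipped pixels is reported on the result as
#' attribute `"n_clipped"`.
#'
#' @param z a [solve_deficit()] result.
#' @param v0 background speed, m/s.
#' @return an [sos_map()].
#' @export
assemble_sos <- function(z, v0) {
  stopifnot(inherits(z, "slowness_deficit"), v0 > 0)
  inv <- 1 / v0 - z$values
  floor_inv <- 0.5 / v0  # speed cap at 2*v0
  n_clip <- sum(inv < floor_inv)
  inv[inv < floor_inv] <- floor_inv
  out <- sos_map(z$grid, 1 / inv, v0)
  attr(out, "n_clipped") <- n_clip
  out
}

#' Tidy the convergence trace of a fitted deficit
#'
#' @param x a [solve_deficit()] result.
#' @param ... unused.
#' @return a tibble with columns `iteration` and `objective`.
#' @export
tidy.slowness_deficit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$trace), objective = x$trace)
}

#' One-row summary of a fitted deficit
#'
#' @param x a [solve_deficit()] result.
#' @param ... unused.
#' @return a one-row tibble: iterations, final objective, lambda, Lipschitz
#'   constant used.
#' @export
glance.slowness_deficit <- function(x, ...) {
  tibble::tibble(iterations = x$iterations,
                 objective = x$trace[length(x$trace)],
                 lambda_reg = x$lambda_reg,
                 lipschitz = x$lipschitz)
}
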