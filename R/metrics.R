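img_values <- function(x) {
  if (inherits(x, "sos_map") || inherits(x, "recon_image")) x$values
  else as.matrix(x)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10*log10(MAX^2 / MSE)` with `MAX` the dynamic range
#' (max - min) of the reference image and `MSE` the mean squared pixel
#' difference. Identical images give `Inf`.
#'
#' @param test,reference images: matrices, [sos_map()]s or
#'   [recon_image()]s of the same shape.
#' @param max_value dynamic range MAX; defaults to the reference range.
#' @return PSNR in dB.
#' @export
psnr <- function(test, reference, max_value = NULL) {
  a <- img_values(test)
  b <- img_values(reference)
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  if (is.null(max_value)) max_value <- diff(range(b))
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Structural similarity (global)
#'
#' Single-window SSIM computed from the image-wide means, variances and
#' covariance, with stabilizing constants `C1 = (0.01*MAX)^2`,
#' `C2 = (0.03*MAX)^2`. Variances use the population convention (divide by
#' the pixel count). `ssim(x, x) = 1` for any image.
#'
#' @param test,reference images of the same shape.
#' @param max_value dynamic range MAX; defaults to the reference range.
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(test, reference, max_value = NULL) {
  a <- as.numeric(img_values(test))
  b <- as.numeric(img_values(reference))
  if (length(a) != length(b)) stop("image shapes differ")
  if (is.null(max_value)) max_value <- diff(range(b))
  c1 <- (0.01 * max_value)^2
  c2 <- (0.03 * max_value)^2
  mu_a <- mean(a)
  mu_b <- mean(b)
  var_a <- mean((a - mu_a)^2)
  var_b <- mean((b - mu_b)^2)
  cov_ab <- mean((a - mu_a) * (b - mu_b))
  ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
}

#' Regional SOS statistics
#'
#' Mean, standard deviation and percent error of the reconstructed sound
#' speed inside labeled region masks, in the style of reconstruction
#' accuracy tables: `percent_error = |mean - true| / true * 100`.
#'
#' @param sos reconstructed [sos_map()].
#' @param masks named list of logical masks (`nx x ny`); defaults to the
#'   masks stored on `truth` or on `sos`.
#' @param true_speeds named numeric vector of true speeds per region (m/s);
#'   names must match `masks`.
#' @return a tibble with columns `region`, `n_pixels`, `mean`, `sd`,
#'   `true`, `percent_error`.
#' @export
region_stats <- function(sos, masks, true_speeds) {
  stopifnot(inherits(sos, "sos_map"))
  if (is.null(names(masks)) || is.null(names(true_speeds)))
    stop("masks and true_speeds must be named")
  if (any(true_speeds <= 0)) stop("true speeds must be positive")
  rows <- lapply(names(true_speeds), function(lab) {
    m <- masks[[lab]]
    if (is.null(m)) stop("no mask named '", lab, "'")
    if (!any(m)) stop("empty region mask '", lab, "'")
    v <- sos$values[m]
    mu <- mean(v)
    tv <- true_speeds[[lab]]
    tibble::tibble(region = lab, n_pixels = sum(m), mean = mu,
                   sd = stats::sd(v), true = tv,
                   percent_error = abs(mu - tv) / tv * 100)
  })
  do.call(rbind, rows)
}

#' Full image-quality report
#'
#' PSNR, SSIM and (optionally) regional statistics in one object.
#'
#' @param test,reference images of the same shape.
#' @param masks,true_speeds optional; see [region_stats()] (requires `test`
#'   to be an [sos_map()]).
#' @return a list of class `metrics_report` with elements `psnr`, `ssim`
#'   and `regional` (a tibble or NULL).
#' @export
metrics_report <- function(test, reference, masks = NULL, true_speeds = NULL) {
  regional <- if (!is.null(masks) && !is.null(true_speeds))
    region_stats(test, masks, true_speeds) else NULL
  structure(list(psnr = psnr(test, reference),
                 ssim = ssim(test, reference),
                 regional = regional),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("PSNR: %.2f dB   SSIM: %.4f\n", x$psnr, x$ssim))
  if (!is.null(x$regional)) {
    r <- x$regional
    for (i in seq_len(nrow(r))) {
      cat(sprintf("  %-12s %8.2f +- %6.2f m/s   %.2f %%\n",
                  r$region[i], r$mean[i], r$sd[i], r$percent_error[i]))
    }
  }
  invisible(x)
}
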