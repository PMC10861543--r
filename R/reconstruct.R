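# Diffusion tensor reconstruction: log-linear least-squares fit from
# >= 6 directions + b0, eigenvalue decomposition, ADC / FA maps and ROI
# statistics.

#' Fit the diffusion tensor per voxel
#'
#' Solves, voxel-wise, the log-linearized signal model
#' `log(S_i / S_0) = -b_i g_i' D g_i` by (optionally weighted) least squares
#' with design rows `(gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)`. All b = 0
#' volumes are averaged into S_0. Voxels with any non-positive signal are
#' flagged invalid.
#'
#' @param dwi A `dwi_dataset` (see [simulate_dwi()] / [read_dwi()]).
#' @param weighted Use weighted least squares with weights S_i^2 (the
#'   first-order variance propagation of log-transformed Rician-corrupted
#'   magnitudes); default plain OLS.
#' @return A `tensor_field`: list with 4-D array `D` (dims x 6, components
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s) and logical `valid` mask.
#' @export
fit_tensor <- function(dwi, weighted = FALSE) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  b <- dwi$bvals
  if (!any(b == 0)) stop("at least one b = 0 volume is required")
  dwi_idx <- which(b > 0)
  if (length(dwi_idx) < 6)
    stop("at least six diffusion-weighted volumes are required")
  g <- dwi$bvecs[dwi_idx, , drop = FALSE]
  g <- g / sqrt(rowSums(g^2))
  X <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3]) *
    b[dwi_idx]
  if (qr(X)$rank < 6)
    stop("encoding directions are rank-deficient: six non-collinear ",
         "directions are required")

  dims <- dim(dwi$volumes)[1:3]
  nvox <- prod(dims)
  vols <- matrix(dwi$volumes, nrow = nvox)
  b0 <- rowMeans(vols[, which(b == 0), drop = FALSE])
  S <- vols[, dwi_idx, drop = FALSE]
  valid <- as.vector(dwi$mask) & b0 > 0 & apply(S > 0, 1, all)

  Dmat <- matrix(NA_real_, nvox, 6)
  if (any(valid)) {
    Y <- -log(S[valid, , drop = FALSE] / b0[valid])   # rows: voxels
    if (!weighted) {
      Dmat[valid, ] <- t(qr.solve(X, t(Y)))
    } else {
      W <- S[valid, , drop = FALSE]^2
      sol <- vapply(seq_len(nrow(Y)), function(i) {
        xw <- X * W[i, ]
        solve(crossprod(X, xw), crossprod(xw, Y[i, ]))[, 1]
      }, numeric(6))
      Dmat[valid, ] <- t(sol)
    }
  }
  structure(list(D = array(Dmat, c(dims, 6)),
                 valid = array(valid, dims),
                 units = "mm^2/s"),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$valid)
  cat(sprintf("<tensor_field> %d x %d x %d grid, %d valid voxels (mm^2/s)\n",
              d[1], d[2], d[3], sum(x$valid)))
  invisible(x)
}

#' Per-voxel eigenvalues of a tensor field
#'
#' @param tf A `tensor_field`.
#' @return A 4-D array (dims x 3) of eigenvalues in descending order
#'   (mm^2/s); NA outside the valid mask.
#' @export
tensor_eigen <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  dims <- dim(tf$valid)
  Dm <- matrix(tf$D, ncol = 6)
  ev <- matrix(NA_real_, nrow(Dm), 3)
  for (i in which(as.vector(tf$valid))) {
    d <- Dm[i, ]
    M <- matrix(c(d[1], d[4], d[5],
                  d[4], d[2], d[6],
                  d[5], d[6], d[3]), 3, 3)
    ev[i, ] <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  }
  array(ev, c(dims, 3))
}

scalar_map <- function(values, kind, units, dims) {
  structure(list(values = array(values, dims), kind = kind, units = units),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<scalar_map> %s (%s): %d finite voxels, range %.4g .. %.4g\n",
              x$kind, x$units, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' ADC (mean diffusivity) map
#'
#' ADC per voxel as the mean of the three tensor eigenvalues, i.e.
#' trace(D)/3 — the trace is rotation-invariant and needs no explicit
#' decomposition. Negative noise-driven eigenvalues are retained: the trace
#' estimator is unbiased under log-linear fitting.
#'
#' @param tf A `tensor_field`.
#' @return A `scalar_map` with `kind = "ADC"` in units of 1e-3 mm^2/s, the
#'   conventional reporting scale.
#' @export
eigen_adc <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  dims <- dim(tf$valid)
  adc <- (tf$D[, , , 1] + tf$D[, , , 2] + tf$D[, , , 3]) / 3 * 1e3
  adc[!tf$valid] <- NA_real_
  scalar_map(adc, "ADC", "1e-3 mm^2/s", dims)
}

#' Fractional anisotropy map
#'
#' FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2)),
#' computed from per-voxel eigenvalues with negative eigenvalues clamped to
#' zero (the FA domain requires non-negativity), clipped to [0, 1]. An
#' all-zero tensor has undefined FA and is reported as NA.
#'
#' @param tf A `tensor_field`.
#' @return A `scalar_map` with `kind = "FA"`, unitless.
#' @export
fa_map <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  dims <- dim(tf$valid)
  ev <- matrix(tensor_eigen(tf), ncol = 3)
  ev[ev < 0] <- 0
  lbar <- rowMeans(ev)
  ss <- rowSums(ev^2)
  fa <- sqrt(1.5) * sqrt(rowSums((ev - lbar)^2)) / sqrt(ss)
  fa[ss == 0] <- NA_real_
  fa <- pmin(pmax(fa, 0), 1)
  scalar_map(fa, "FA", "", dims)
}

#' Region-of-interest statistics of a scalar map
#'
#' Mean and SD of the map over the valid voxels of each requested label.
#'
#' @param map A `scalar_map`.
#' @param region_map Integer label array matching the map grid.
#' @param labels Labels to report; default all nonzero labels present.
#' @param names Optional region names aligned with `labels`.
#' @return A data frame of class `roi_stats` with columns `region`, `label`,
#'   `n_voxels`, `mean`, `sd`, `units`.
#' @export
roi_stats <- function(map, region_map, labels = NULL, names = NULL) {
  stopifnot(inherits(map, "scalar_map"))
  region_map <- as.array(region_map)
  if (length(dim(region_map)) == 2) dim(region_map) <- c(dim(region_map), 1L)
  stopifnot(all(dim(region_map) == dim(map$values)))
  if (is.null(labels)) {
    labels <- sort(unique(as.vector(region_map)))
    labels <- labels[labels > 0]
  }
  if (is.null(names)) names <- paste0("region", labels)
  rows <- lapply(seq_along(labels), function(i) {
    v <- map$values[region_map == labels[i]]
    v <- v[is.finite(v)]
    if (length(v) == 0)
      stop(sprintf("label %d has no valid voxels", labels[i]))
    data.frame(region = names[i], label = labels[i], n_voxels = length(v),
               mean = mean(v), sd = stats::sd(v), units = map$units)
  })
  out <- do.call(rbind, rows)
  out$sd[out$n_voxels == 1] <- 0
  class(out) <- c("roi_stats", "data.frame")
  out
}
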