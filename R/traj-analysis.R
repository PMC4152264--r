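#' Center-of-mass time series of one molecule
#'
#' Extracts the per-frame center of mass of a molecule from a trajectory.
#' Because the model has no explicit per-sphere masses, the default weights
#' are proportional to sphere volume (the residue-count proxy used when the
#' spheres were sized); geometric (equal) weights are available.
#'
#' @param traj a \code{\link{BDTrajectory-class}} (unwrapped positions).
#' @param molecule molecule index, or a protein id with a single copy.
#' @param weights "volume" or "geometric".
#' @return numeric matrix (frames x 3) with a \code{times} attribute (ns).
#' @export
comTrajectory <- function(traj, molecule, weights = c("volume", "geometric")) {
  weights <- match.arg(weights)
  if (is.character(molecule)) {
    mols <- unique(traj@molecule[traj@proteinId == molecule])
    if (length(mols) == 0) stop("unknown protein id: ", molecule)
    if (length(mols) > 1) stop("protein id '", molecule,
                               "' has several copies; pass a molecule index")
    molecule <- mols
  }
  sel <- which(traj@molecule == molecule)
  if (length(sel) == 0) stop("unknown molecule: ", molecule)
  w <- if (weights == "volume") traj@radii[sel]^3 else rep(1, length(sel))
  w <- w / sum(w)
  f <- traj@frames
  com <- sapply(1:3, function(c) as.matrix(f[, sel, c, drop = FALSE][, , 1]) %*% w)
  com <- matrix(com, ncol = 3)
  attr(com, "times") <- traj@times
  com
}

.series_spacing <- function(series, spacing) {
  if (!is.null(spacing)) return(spacing)
  tm <- attr(series, "times")
  if (is.null(tm)) stop("supply `spacing` (ns) or a series with a times attribute")
  diff(tm)[1]
}

#' Multi-origin mean-squared displacement
#'
#' \eqn{MSD(\tau) = \langle |r(T+\tau) - r(T)|^2 \rangle_T} averaged over all
#' admissible (overlapping) time origins of the series.
#'
#' @param series numeric matrix (frames x d) of unwrapped positions, e.g.
#'   from \code{\link{comTrajectory}}.
#' @param spacing frame spacing, ns (taken from the series attribute when
#'   present).
#' @param maxLag largest lag in frames (default: half the series).
#' @return data.frame with \code{lag} (ns), \code{msd} (A^2) and
#'   \code{n_origins}; includes the lag-0 row (MSD = 0).
#' @export
msdMultiOrigin <- function(series, spacing = NULL, maxLag = NULL) {
  series <- as.matrix(series)
  M <- nrow(series)
  if (M < 2) stop("need at least 2 frames")
  spacing <- .series_spacing(series, spacing)
  if (is.null(maxLag)) maxLag <- max(1L, M %/% 2L)
  if (maxLag >= M) stop("maxLag exceeds the series length")
  msd <- numeric(maxLag)
  nor <- integer(maxLag)
  for (k in seq_len(maxLag)) {
    d <- series[(1 + k):M, , drop = FALSE] - series[1:(M - k), , drop = FALSE]
    msd[k] <- mean(rowSums(d^2))
    nor[k] <- M - k
  }
  data.frame(lag = c(0, seq_len(maxLag)) * spacing, msd = c(0, msd),
             n_origins = c(M, nor))
}

#' Log-log power-law fit of an MSD curve
#'
#' Ordinary least squares of \eqn{\log_{10} MSD} on \eqn{\log_{10} t} inside
#' a lag window. The slope is the scaling exponent \eqn{\alpha}
#' (\eqn{MSD \propto t^\alpha}); for normal diffusion \eqn{\alpha = 1} and
#' the intercept is \eqn{\log_{10}(6D)}.
#'
#' @param msd data.frame from \code{\link{msdMultiOrigin}}.
#' @param window numeric length-2, lag window in ns (inclusive). Default:
#'   all positive lags.
#' @return list with \code{alpha}, \code{intercept}, their standard errors,
#'   and \code{n} points used.
#' @export
fitAlpha <- function(msd, window = NULL) {
  sel <- msd$lag > 0
  if (!is.null(window)) sel <- sel & msd$lag >= window[1] & msd$lag <= window[2]
  if (sum(sel) < 3) stop("need at least 3 points in the fit window")
  if (any(msd$msd[sel] <= 0)) stop("nonpositive MSD in the fit window")
  x <- log10(msd$lag[sel])
  y <- log10(msd$msd[sel])
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine here
  list(alpha = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       alpha_se = unname(s[2, 2]), intercept_se = unname(s[1, 2]),
       n = sum(sel))
}

#' Block-averaged diffusion coefficient from the MSD intercept
#'
#' The series (after discarding an initial transient) is split into
#' contiguous blocks; each block's multi-origin MSD is fit in a lag window
#' where scaling is linear. D is read off the intercept of the log-log plot
#' with the slope constrained to 1 (\eqn{\log_{10} MSD = \log_{10}(6D) +
#' \log_{10} t}), and a free-slope \eqn{\alpha} is reported as a diagnostic:
#' if it deviates from 1 by more than \code{alphaTol} the estimate is
#' flagged (drift or unresolved subdiffusion in the window), not silently
#' accepted.
#'
#' @param series unwrapped position matrix (frames x 3), e.g. a COM series.
#' @param spacing frame spacing, ns.
#' @param discard initial time to drop, ns.
#' @param nBlocks number of blocks (default 2).
#' @param window lag window for the fit, ns (default: central decade of the
#'   available lags).
#' @param alphaTol tolerance on |alpha - 1| before flagging.
#' @return list with \code{D_um2s} (mean across blocks), \code{sd_um2s},
#'   \code{perBlock_um2s}, \code{alpha} (free-slope, pooled), \code{flagged},
#'   \code{window}.
#' @export
estimateDBlocks <- function(series, spacing = NULL, discard = 0, nBlocks = 2L,
                            window = NULL, alphaTol = 0.25) {
  series <- as.matrix(series)
  spacing <- .series_spacing(series, spacing)
  drop <- round(discard / spacing)
  if (drop >= nrow(series) - 2 * nBlocks)
    stop("series too short for the requested discard and blocks")
  series <- series[(drop + 1):nrow(series), , drop = FALSE]
  M <- nrow(series)
  bl <- floor(M / nBlocks)
  if (bl < 8) stop("series too short for ", nBlocks, " blocks")
  Db <- numeric(nBlocks)
  alphas <- numeric(nBlocks)
  for (b in seq_len(nBlocks)) {
    seg <- series[((b - 1) * bl + 1):(b * bl), , drop = FALSE]
    msd <- msdMultiOrigin(seg, spacing = spacing)
    win <- window
    if (is.null(win)) {
      lmax <- max(msd$lag)
      win <- c(lmax / 100, lmax / 10)
      if (sum(msd$lag >= win[1] & msd$lag <= win[2] & msd$lag > 0) < 3)
        win <- c(0, lmax)  # short series: use every positive lag
    }
    sel <- msd$lag >= win[1] & msd$lag <= win[2] & msd$lag > 0
    if (sum(sel) < 3) stop("fewer than 3 MSD points in the fit window")
    if (any(msd$msd[sel] <= 0)) stop("nonpositive MSD in the fit window")
    # slope-1-constrained intercept: log10(6D) = mean(log10 msd - log10 t)
    intc <- mean(log10(msd$msd[sel]) - log10(msd$lag[sel]))
    Db[b] <- 10^intc / 6                       # A^2/ns
    alphas[b] <- fitAlpha(msd, window = win)$alpha
  }
  alpha <- mean(alphas)
  list(D_um2s = A2ns_to_um2s(mean(Db)),
       sd_um2s = A2ns_to_um2s(if (nBlocks > 1) sd(Db) else 0),
       perBlock_um2s = A2ns_to_um2s(Db),
       alpha = alpha,
       flagged = abs(alpha - 1) > alphaTol,
       window = if (is.null(window)) "auto" else window)
}

#' Time-dependent diffusion coefficient D(tau) = MSD(tau) / (6 tau)
#'
#' Constant for normal diffusion; decreasing in tau during a subdiffusive
#' regime and flattening once scaling becomes linear.
#'
#' @param msd data.frame from \code{\link{msdMultiOrigin}}.
#' @return data.frame with \code{lag} (ns), \code{D_A2ns} and \code{D_um2s};
#'   the lag-0 row is dropped.
#' @export
timeDependentD <- function(msd) {
  sel <- msd$lag > 0
  D <- msd$msd[sel] / (6 * msd$lag[sel])
  data.frame(lag = msd$lag[sel], D_A2ns = D, D_um2s = A2ns_to_um2s(D))
}

#' Displacement autocorrelation function
#'
#' \eqn{C_\delta(t) = \langle \delta r(T;\delta) \cdot \delta r(T+t;\delta)
#' \rangle_T} with \eqn{\delta r(T;\delta) = r(T+\delta) - r(T)}, averaged
#' over all time origins. For independent increments (normal diffusion) it is
#' zero for \eqn{t \ge \delta}; fractional Brownian motion with exponent
#' \eqn{\alpha < 1} gives a negative value at \eqn{t = \delta}, the
#' normalized value there being \eqn{2^{\alpha - 1} - 1}.
#'
#' @param series unwrapped position matrix (frames x d).
#' @param delta increment span, ns; must be a multiple of the frame spacing.
#' @param spacing frame spacing, ns.
#' @param maxT largest separation t, ns (default \code{20 * delta} or what
#'   the series allows).
#' @return data.frame with \code{t} (ns), \code{C} (raw, A^2) and
#'   \code{C_norm} (divided by \eqn{C_\delta(0)}); attributes \code{min_norm}
#'   and \code{t_min} give the minimum normalized value over
#'   \eqn{t \ge \delta} and its location.
#' @export
displacementAutocorrelation <- function(series, delta, spacing = NULL,
                                        maxT = NULL) {
  series <- as.matrix(series)
  spacing <- .series_spacing(series, spacing)
  s <- delta / spacing
  if (abs(s - round(s)) > 1e-9)
    stop("delta must be an integer multiple of the frame spacing")
  s <- as.integer(round(s))
  M <- nrow(series)
  if (M <= s + 1) stop("series too short for this delta")
  inc <- series[(1 + s):M, , drop = FALSE] - series[1:(M - s), , drop = FALSE]
  nI <- nrow(inc)
  if (is.null(maxT)) maxT <- min(20 * delta, (nI - 2) * spacing)
  K <- min(nI - 1L, as.integer(floor(maxT / spacing)))
  C <- numeric(K + 1)
  C[1] <- mean(rowSums(inc^2))
  for (k in seq_len(K)) {
    C[k + 1] <- mean(rowSums(inc[(1 + k):nI, , drop = FALSE] *
                             inc[1:(nI - k), , drop = FALSE]))
  }
  tgrid <- (0:K) * spacing
  out <- data.frame(t = tgrid, C = C, C_norm = C / C[1])
  past <- out$t >= delta - 1e-9
  attr(out, "min_norm") <- min(out$C_norm[past])
  attr(out, "t_min") <- out$t[past][which.min(out$C_norm[past])]
  attr(out, "delta") <- delta
  out
}

#' Scaling exponent from the minimum of the normalized autocorrelation
#'
#' Inverts the fractional-Brownian-motion relation between the minimum of
#' the normalized displacement autocorrelation and the MSD exponent:
#' \eqn{\min C = 2^{\alpha - 1} - 1}, so
#' \eqn{\alpha = 1 + \log_2(1 + \min C)}.
#'
#' @param minC minimum normalized autocorrelation, in \code{[-0.5, 0]}.
#' @return alpha.
#' @export
#' @examples
#' alphaFromMinCorrelation(-0.067)  # ~0.90
alphaFromMinCorrelation <- function(minC) {
  if (any(minC < -0.5 - 1e-12) || any(minC > 1e-12))
    stop("minC must lie in [-0.5, 0]")
  1 + log2(1 + pmin(0, minC))
}

#' Gaussianity diagnostics of displacement increments
#'
#' Reports, per component, the excess kurtosis and the Kolmogorov-Smirnov
#' distance against a Gaussian with matched mean and standard deviation.
#' This is a descriptive report (no hard threshold); degenerate input
#' (zero variance) is flagged.
#'
#' @param displacements numeric vector or matrix (samples x components) of
#'   displacement increments over a fixed lag.
#' @return list with \code{kurtosis} (excess, per component), \code{ks_stat},
#'   \code{ks_p}, \code{n} and \code{degenerate}.
#' @export
gaussianityCheck <- function(displacements) {
  x <- as.matrix(displacements)
  if (nrow(x) < 100) stop("need at least 100 samples")
  k <- ncol(x)
  kurt <- ks_stat <- ks_p <- numeric(k)
  degen <- logical(k)
  for (c in seq_len(k)) {
    v <- x[, c]
    s <- sd(v)
    if (s == 0) {
      degen[c] <- TRUE
      kurt[c] <- NA_real_; ks_stat[c] <- NA_real_; ks_p[c] <- NA_real_
      next
    }
    z <- (v - mean(v)) / s
    kurt[c] <- mean(z^4) - 3
    kt <- suppressWarnings(ks.test(v, "pnorm", mean = mean(v), sd = s))
    ks_stat[c] <- unname(kt$statistic)
    ks_p[c] <- kt$p.value
  }
  list(kurtosis = kurt, ks_stat = ks_stat, ks_p = ks_p, n = nrow(x),
       degenerate = degen)
}

#' Displacement increments of a series at a fixed lag
#'
#' @param series unwrapped position matrix (frames x d).
#' @param lag lag, ns; multiple of the frame spacing.
#' @param spacing frame spacing, ns.
#' @return matrix of increments (samples x d).
#' @export
displacementIncrements <- function(series, lag, spacing = NULL) {
  series <- as.matrix(series)
  spacing <- .series_spacing(series, spacing)
  s <- as.integer(round(lag / spacing))
  if (abs(lag / spacing - s) > 1e-9 || s < 1)
    stop("lag must be a positive multiple of the frame spacing")
  M <- nrow(series)
  series[(1 + s):M, , drop = FALSE] - series[1:(M - s), , drop = FALSE]
}
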