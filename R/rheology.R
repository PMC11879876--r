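## Viscoelastic moduli from tracer MSD (generalized Stokes-Einstein) and
## from stress autocorrelation (Green-Kubo); stretched-exponential plateau
## extraction and power-law scaling analysis.

#' Mean squared displacement series
#'
#' @param t Lag times (tau_Br), strictly increasing, first lag > 0.
#' @param msd MSD values (sigma^2), non-negative.
#' @param a Tracer radius (sigma).
#' @param kT Thermal energy.
#' @export
msd_series <- function(t, msd, a = 2.5, kT = 1) {
  t <- as.numeric(t); msd <- as.numeric(msd)
  stopifnot(length(t) == length(msd), all(diff(t) > 0), all(msd >= 0), all(t > 0))
  structure(list(t = t, msd = msd, a = a, kT = kT), class = "msd_series")
}

#' Time-origin-averaged MSD of a tracer track
#'
#' Uses unwrapped coordinates; averages displacements over all starting
#' times on a log-spaced lag grid.
#'
#' @param track m x 3 matrix of unwrapped positions sampled at interval `dt`.
#' @param dt Sampling interval (tau_Br).
#' @param a Tracer radius.
#' @param kT Thermal energy.
#' @param n_lags Number of log-spaced lags (up to m/4).
#' @return An [msd_series()].
#' @export
compute_msd <- function(track, dt, a = 2.5, kT = 1, n_lags = 60) {
  track <- as.matrix(track)
  m <- nrow(track)
  if (m < 100) stop("need at least 100 track samples")
  max_lag <- floor(m / 4)
  lags <- unique(round(exp(seq(log(1), log(max_lag), length.out = n_lags))))
  msd <- vapply(lags, function(l) {
    d <- track[(l + 1):m, , drop = FALSE] - track[1:(m - l), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  msd_series(lags * dt, msd, a = a, kT = kT)
}

#' Complex moduli from an MSD by the generalized Stokes-Einstein relation
#'
#' Local power-law (logarithmic-derivative) approximation: at each lag t the
#' magnitude `|G*(1/t)| = kT / (pi a MSD(t) Gamma(1 + alpha(t)))` with
#' `alpha = d ln MSD / d ln t` (clipped to [0, 1]), split into
#' `G' = |G*| cos(pi alpha / 2)` and `G'' = |G*| sin(pi alpha / 2)`.
#' Points where MSD noise pushes the raw slope outside [-0.2, 1.2] are
#' masked.
#'
#' @param msd An [msd_series()].
#' @return A `modulus_spectrum`: `omega` (= 1/t, increasing), `g1` (G'),
#'   `g2` (G''), `alpha`, `masked`.
#' @export
gser_moduli <- function(msd) {
  stopifnot(inherits(msd, "msd_series"))
  t <- msd$t; m <- msd$msd
  if (any(m[-1] <= 0)) stop("MSD must be positive on the grid interior")
  lt <- log(t); lm <- log(m)
  k <- length(t)
  alpha_raw <- numeric(k)
  for (i in seq_len(k)) {
    lo <- max(1, i - 1); hi <- min(k, i + 1)
    alpha_raw[i] <- (lm[hi] - lm[lo]) / (lt[hi] - lt[lo])
  }
  masked <- alpha_raw < -0.2 | alpha_raw > 1.2
  alpha <- pmin(pmax(alpha_raw, 0), 1)
  gmag <- msd$kT / (pi * msd$a * m * gamma(1 + alpha))
  g1 <- gmag * cos(pi * alpha / 2)
  g2 <- gmag * sin(pi * alpha / 2)
  omega <- 1 / t
  ord <- order(omega)
  structure(list(omega = omega[ord], g1 = g1[ord], g2 = g2[ord],
                 alpha = alpha[ord], masked = masked[ord],
                 a = msd$a, kT = msd$kT),
            class = "modulus_spectrum")
}

#' @export
print.modulus_spectrum <- function(x, ...) {
  cat(sprintf("modulus_spectrum: %d frequencies in [%.3g, %.3g] 1/tau_Br\n",
              length(x$omega), min(x$omega), max(x$omega)))
  invisible(x)
}

#' Stress-relaxation modulus by the Green-Kubo relation
#'
#' `G(t) = (V / (3 kT)) * sum over the three off-diagonal pressure
#' components of the time-averaged autocorrelation <P(0) P(t)>`, with each
#' component mean-subtracted first. Lags are limited to 10% of the series
#' length so every estimate averages at least ~10 independent stretches.
#'
#' @param stress A [stress_series()].
#' @param max_lag_frac Largest lag as a fraction of the series (default 0.1).
#' @return A `relaxation_series`: `t` (lags, starting at 0) and `g`.
#' @export
green_kubo_relaxation <- function(stress, max_lag_frac = 0.1) {
  stopifnot(inherits(stress, "stress_series"))
  n <- length(stress$t)
  if (n < 100) stop("stress series too short for autocorrelation analysis")
  dt <- stats::median(diff(stress$t))
  max_lag <- floor(n * max_lag_frac)
  acf_sum <- numeric(max_lag + 1)
  for (k in 1:3) {
    p <- stress$p[, k] - mean(stress$p[, k])
    a <- stats::acf(p, lag.max = max_lag, plot = FALSE, type = "covariance",
                    demean = FALSE)
    acf_sum <- acf_sum + as.numeric(a$acf)
  }
  g <- stress$volume / (3 * stress$kT) * acf_sum
  structure(list(t = (0:max_lag) * dt, g = g,
                 volume = stress$volume, kT = stress$kT),
            class = "relaxation_series")
}

#' Stretched-exponential fit of a relaxation modulus
#'
#' Fits `g(t) = a * exp(-(t / tau)^b)` by constrained nonlinear least
#' squares. `a` is the elastic plateau, `tau` the network relaxation time
#' and `b` the stretching exponent (0 < b <= 2). Initialization: `a` from
#' the first lag, `tau` at the 1/e crossing, `b = 1`.
#'
#' @param relax A `relaxation_series` (or list with `t`, `g`).
#' @param drop_zero_lag Exclude the t = 0 point (default TRUE; the
#'   zero-lag autocorrelation carries the kinetic delta peak).
#' @return A `relaxation_fit`: `a`, `tau`, `b`, standard errors, `fitted`.
#' @export
fit_stretched_exponential <- function(relax, drop_zero_lag = TRUE) {
  t <- relax$t; g <- relax$g
  if (drop_zero_lag && length(t) > 1 && t[1] == 0) { t <- t[-1]; g <- g[-1] }
  if (length(t) < 20) stop("need at least 20 points to fit")
  n3 <- max(3, floor(length(g) / 4))
  if (mean(g[seq_len(n3)]) <= mean(g[(length(g) - n3 + 1):length(g)])) {
    stop("series does not decay overall; refusing stretched-exponential fit")
  }
  a0 <- g[1]
  below <- which(g < a0 / exp(1))
  tau0 <- if (length(below)) t[below[1]] else t[length(t)] / 2
  fit <- minpack.lm::nlsLM(g ~ a * exp(-(t / tau)^b),
                           start = list(a = a0, tau = tau0, b = 1),
                           lower = c(0, 1e-12, 1e-3), upper = c(Inf, Inf, 2),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(a = unname(cf["a"]), tau = unname(cf["tau"]), b = unname(cf["b"]),
                 se = stats::setNames(as.numeric(se), c("a", "tau", "b")),
                 fitted = stats::predict(fit), t = t, g = g),
            class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf("relaxation_fit: a = %.4g, tau = %.4g tau_Br, b = %.3f\n",
              x$a, x$tau, x$b))
  invisible(x)
}

#' Elastic plateau, crossover frequency and unbinding time
#'
#' The plateau `G'_p` is the storage modulus at the largest frequency; the
#' crossover `omega_0` is where `G' = G''` (log-linear interpolation of the
#' sign change of G' - G''), and the unbinding time is `tau_u = 1/omega_0`.
#'
#' @param spectrum A `modulus_spectrum`.
#' @return List: `plateau`, `omega0` (NA with `crossover_found = FALSE` when
#'   the spectrum does not span a crossover), `tau_u`.
#' @export
extract_plateau_crossover <- function(spectrum) {
  stopifnot(inherits(spectrum, "modulus_spectrum"))
  if (length(spectrum$omega) < 2) stop("spectrum needs at least 2 frequencies")
  keep <- !spectrum$masked
  om <- spectrum$omega[keep]; g1 <- spectrum$g1[keep]; g2 <- spectrum$g2[keep]
  plateau <- g1[which.max(om)]
  d <- g1 - g2
  sgn <- sign(d)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  # keep crossovers from liquid (G'' > G') to solid (G' > G'') with rising omega
  flip <- flip[d[flip] < 0 & d[flip + 1] > 0]
  if (!length(flip)) {
    return(list(plateau = plateau, omega0 = NA_real_, tau_u = NA_real_,
                crossover_found = FALSE))
  }
  i <- flip[length(flip)]
  lx <- log(om[i:(i + 1)])
  w0 <- exp(lx[1] + (0 - d[i]) * (lx[2] - lx[1]) / (d[i + 1] - d[i]))
  list(plateau = plateau, omega0 = w0, tau_u = 1 / w0, crossover_found = TRUE)
}

#' Log-log power-law fit, optionally piecewise at a fixed breakpoint
#'
#' @param x,y Positive data.
#' @param breakpoint Optional x value splitting the fit into two segments
#'   (e.g. the overlap volume fraction 0.056).
#' @param y_err Optional y standard errors (used as weights 1/se^2 in log
#'   space via relative errors).
#' @return A `scaling_fit`: per-segment `slope`, `slope_se`, `intercept`,
#'   plus the input points.
#' @export
fit_power_law <- function(x, y, breakpoint = NULL, y_err = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (any(x <= 0) || any(y <= 0)) stop("power-law fit needs positive data")
  seg_fit <- function(idx) {
    if (length(idx) < 3) stop("need at least 3 points per segment")
    w <- if (!is.null(y_err)) (y[idx] / y_err[idx])^2 else NULL
    fit <- stats::lm(log(y[idx]) ~ log(x[idx]), weights = w)
    cf <- summary(fit)$coefficients
    list(slope = unname(cf[2, 1]), slope_se = unname(cf[2, 2]),
         intercept = unname(cf[1, 1]), n = length(idx))
  }
  segments <- if (is.null(breakpoint)) {
    list(all = seg_fit(seq_along(x)))
  } else {
    list(below = seg_fit(which(x <= breakpoint)),
         above = seg_fit(which(x >= breakpoint)))
  }
  structure(list(segments = segments, breakpoint = breakpoint,
                 x = x, y = y, y_err = y_err),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  for (nm in names(x$segments)) {
    s <- x$segments[[nm]]
    cat(sprintf("scaling_fit [%s]: slope %.3f +/- %.3f (n = %d)\n",
                nm, s$slope, s$slope_se, s$n))
  }
  invisible(x)
}

#' Predicted elasticity scaling exponents from constituent slopes
#'
#' Combines measured log-log slopes into the model exponents for the
#' high-frequency elastic plateau versus volume fraction:
#' \itemize{
#'   \item mesh-based: `G'_p ~ N_minloop / xi^3` gives exponent
#'     `(N_minloop slope) + 3 |xi slope|`;
#'   \item link-based: `G'_p ~ N_minloop <Z>` gives exponent
#'     `(N_minloop slope) + (<Z> slope)`;
#'   \item geometric linking-valence estimate: `<Z> ~ rho <l_min>^3` gives
#'     `1 + 3 (l_min slope)`.
#' }
#' Phantom-network comparators (`rho^1` with prefactor `(f-2)/f`, and
#' `rho^{1/3}` for disordered phantom networks) are reported alongside.
#' Standard errors propagate in quadrature.
#'
#' @param nminloop_slope,xi_slope,z_slope,lmin_slope Constituent slopes;
#'   each may carry an `se` attribute or be a length-2 c(slope, se).
#' @param f Valence (default 3).
#' @return A `scaling_predictions` list.
#' @export
predict_scaling_exponents <- function(nminloop_slope = NULL, xi_slope = NULL,
                                      z_slope = NULL, lmin_slope = NULL, f = 3) {
  val <- function(s) if (length(s) >= 1) as.numeric(s[1]) else NA_real_
  se <- function(s) if (length(s) >= 2) as.numeric(s[2]) else 0
  out <- list()
  if (!is.null(nminloop_slope) && !is.null(xi_slope)) {
    out$mesh_exponent <- val(nminloop_slope) + 3 * abs(val(xi_slope))
    out$mesh_exponent_se <- sqrt(se(nminloop_slope)^2 + (3 * se(xi_slope))^2)
  }
  if (!is.null(nminloop_slope) && !is.null(z_slope)) {
    out$link_exponent <- val(nminloop_slope) + val(z_slope)
    out$link_exponent_se <- sqrt(se(nminloop_slope)^2 + se(z_slope)^2)
  }
  if (!is.null(lmin_slope)) {
    out$geometric_z_exponent <- 1 + 3 * val(lmin_slope)
    out$geometric_z_exponent_se <- 3 * se(lmin_slope)
  }
  if (!length(out)) stop("no constituent slopes supplied")
  out$phantom_exponent <- 1
  out$phantom_prefactor <- (f - 2) / f
  out$phantom_disordered_exponent <- 1 / 3
  structure(out, class = "scaling_predictions")
}

#' @export
print.scaling_predictions <- function(x, ...) {
  if (!is.null(x$mesh_exponent)) {
    cat(sprintf("mesh-based plateau exponent:    %.3f +/- %.3f\n",
                x$mesh_exponent, x$mesh_exponent_se))
  }
  if (!is.null(x$link_exponent)) {
    cat(sprintf("link-based plateau exponent:    %.3f +/- %.3f\n",
                x$link_exponent, x$link_exponent_se))
  }
  if (!is.null(x$geometric_z_exponent)) {
    cat(sprintf("geometric <Z> exponent:         %.3f +/- %.3f\n",
                x$geometric_z_exponent, x$geometric_z_exponent_se))
  }
  cat(sprintf("phantom comparators: rho^1 (prefactor %.3f), rho^(1/3)\n",
              x$phantom_prefactor))
  invisible(x)
}
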