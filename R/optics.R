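#' Instrument settings for a reflectivity measurement
#'
#' Momentum-transfer grid, constant relative resolution (FWHM), flat
#' background and overall scale factor.  Defaults are typical of a
#' time-of-flight reflectometer: 120 log-spaced points over
#' 0.008--0.30 inverse Angstrom and dQ/Q = 4 % FWHM.
#'
#' @param q_grid strictly increasing, positive Q values (Angstrom^-1).
#' @param dq_over_q constant relative resolution, FWHM (dimensionless).
#' @param background flat background added to the scaled reflectivity.
#' @param scale overall scale factor (> 0).
#' @return Object of class `nr_instrument`.
#' @export
nr_instrument <- function(q_grid = exp(seq(log(0.008), log(0.30),
                                           length.out = 120)),
                          dq_over_q = 0.04,
                          background = 1e-6,
                          scale = 1) {
  if (any(q_grid <= 0) || is.unsorted(q_grid, strictly = TRUE))
    stop("q_grid must be strictly increasing and positive", call. = FALSE)
  if (dq_over_q < 0 || background < 0 || scale <= 0)
    stop("require dq_over_q >= 0, background >= 0, scale > 0",
         call. = FALSE)
  structure(list(q_grid = q_grid, dq_over_q = dq_over_q,
                 background = background, scale = scale),
            class = "nr_instrument")
}

#' @export
print.nr_instrument <- function(x, ...) {
  cat(sprintf(
    "<instrument> %d Q points [%.4g, %.4g] A^-1, dQ/Q = %.3g FWHM, bkg %.2g, scale %.3g\n",
    length(x$q_grid), min(x$q_grid), max(x$q_grid), x$dq_over_q,
    x$background, x$scale))
  invisible(x)
}

check_profile <- function(profile, warn_roughness = TRUE) {
  lay <- profile$layers
  if (any(lay$thickness < 0))
    stop("negative layer thickness in slab profile", call. = FALSE)
  if (any(lay$roughness < 0) || profile$backing_roughness < 0)
    stop("negative roughness in slab profile", call. = FALSE)
  if (warn_roughness && nrow(lay)) {
    sig <- c(lay$roughness, profile$backing_roughness)
    # interface j sits between media j-1 and j; compare to both neighbours
    adj <- pmin(c(Inf, lay$thickness), c(lay$thickness, Inf))
    big <- sig > adj / 2 & is.finite(adj)
    if (any(big))
      warning("roughness exceeds half the adjacent layer thickness at: ",
              paste(unique(c(lay$name, "backing")[big]), collapse = ", "),
              call. = FALSE)
  }
  invisible(profile)
}

# pure-R Parratt recursion; the independent oracle for the matrix engine
parratt_r <- function(q, d, rho, sigma, rho_front, rho_back,
                      backing_roughness) {
  rhos <- c(rho_front, rho, rho_back) * 1e-6
  sig <- c(sigma, backing_roughness)
  nl <- length(d)
  k02 <- q^2 / 4
  kz <- lapply(seq_len(nl + 2), function(j) {
    arg <- k02 - 4 * pi * (rhos[j] - rhos[1])
    sqrt(as.complex(arg))
  })
  # recursion from the bottom interface upwards
  Rnext <- {
    j <- nl + 1
    den <- kz[[j]] + kz[[j + 1]]
    r <- ifelse(Mod(den) > 0, (kz[[j]] - kz[[j + 1]]) / den, 0 + 0i)
    r * exp(-2 * kz[[j]] * kz[[j + 1]] * sig[j]^2)
  }
  if (nl > 0) {
    for (j in seq(nl, 1)) {
      den <- kz[[j]] + kz[[j + 1]]
      r <- ifelse(Mod(den) > 0, (kz[[j]] - kz[[j + 1]]) / den, 0 + 0i)
      r <- r * exp(-2 * kz[[j]] * kz[[j + 1]] * sig[j]^2)
      phase <- exp(2i * kz[[j + 1]] * d[j])
      Rnext <- (r + Rnext * phase) / (1 + r * Rnext * phase)
    }
  }
  pmin(pmax(Mod(Rnext)^2, 0), 1)
}

#' Specular reflectivity of a slab profile
#'
#' Exact slab-optics reflectivity with Nevot-Croce roughness factors.
#' The default engine is the compiled Abeles characteristic-matrix
#' method; `method = "parratt"` runs an independent pure-R Parratt
#' recursion (the two agree to numerical precision and serve as mutual
#' checks).  Returns the ideal curve: no resolution smearing, scale or
#' background (see [measured_curve()]).
#'
#' @param profile a [slab_profile()].
#' @param q positive momentum transfer values (Angstrom^-1).
#' @param method `"abeles"` (compiled, default) or `"parratt"` (pure R).
#' @param warn_roughness warn when a roughness exceeds half the adjacent
#'   layer thickness (fits may transiently explore such regions).
#' @return Reflectivity in \[0, 1\] at each `q`.
#' @examples
#' # bare Si/D2O interface: total reflection below the critical edge
#' p <- slab_profile(numeric(0), numeric(0), numeric(0), 2.07, 6.38)
#' reflectivity(p, c(0.01, 0.02))
#' @export
reflectivity <- function(profile, q, method = c("abeles", "parratt"),
                         warn_roughness = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "slab_profile"))
  if (any(q <= 0)) stop("q must be positive", call. = FALSE)
  check_profile(profile, warn_roughness)
  lay <- profile$layers
  if (method == "abeles") {
    abeles_cpp(q, lay$thickness, lay$sld,
               c(lay$roughness, profile$backing_roughness),
               profile$fronting_sld, profile$backing_sld)
  } else {
    parratt_r(q, lay$thickness, lay$sld, lay$roughness,
              profile$fronting_sld, profile$backing_sld,
              profile$backing_roughness)
  }
}

# Gaussian convolution weights from sampled curve nodes: for each target
# q[i], weight the nodes qf by a Gaussian of sd sigma_rel*q[i] (FWHM
# dq_over_q*q[i]) times the local node spacing, truncated at 3 sigma and
# renormalized.  Returns the nq x nf weight matrix.
smear_weights <- function(q, qf, dq_over_q) {
  sigma_rel <- dq_over_q / (2 * sqrt(2 * log(2)))
  dqf <- diff(qf)
  w_trap <- c(dqf[1], (dqf[-length(dqf)] + dqf[-1]) / 2,
              dqf[length(dqf)]) # local spacing, trapezoid-style
  if (length(qf) == 1L) w_trap <- 1
  W <- matrix(0, length(q), length(qf))
  for (i in seq_along(q)) {
    s <- sigma_rel * q[i]
    g <- exp(-0.5 * ((qf - q[i]) / s)^2)
    g[abs(qf - q[i]) > 3 * s] <- 0
    g <- g * w_trap
    W[i, ] <- g / sum(g)
  }
  W
}

# Oversampled evaluation grid + weight matrix for constant-dQ/Q smearing.
# The log-spaced fine grid is shared by all kernel evaluations, which is
# what makes repeated smearing cheap inside a fit.
smear_setup <- function(q, dq_over_q, oversample = 4) {
  if (dq_over_q <= 0)
    return(list(q_fine = q, W = NULL))
  sigma_rel <- dq_over_q / (2 * sqrt(2 * log(2)))
  pad <- 3.2 * sigma_rel
  lo <- log(min(q) * (1 - pad))
  hi <- log(max(q) * (1 + pad))
  span0 <- log(max(q)) - log(min(q))
  nf <- ceiling(oversample * length(q) * (hi - lo) / span0)
  qf <- exp(seq(lo, hi, length.out = nf))
  list(q_fine = qf, W = smear_weights(q, qf, dq_over_q))
}

#' Resolution-smear a sampled reflectivity curve
#'
#' Gaussian smearing in Q with FWHM `dq_over_q * q` evaluated per point,
#' kernel truncated at 3 sigma and renormalized over the available
#' samples.  `dq_over_q = 0` returns the input unchanged.  The kernel is
#' applied over the samples provided, so the curve should be sampled
#' finely relative to the kernel width; [measured_curve()] oversamples
#' internally on a shared log-spaced grid before smearing.
#'
#' @param r reflectivity samples.
#' @param q their momentum-transfer values (Angstrom^-1, increasing).
#' @param dq_over_q relative resolution, FWHM.
#' @return Smeared reflectivity at the same `q`.
#' @export
smear <- function(r, q, dq_over_q) {
  if (dq_over_q < 0) stop("dq_over_q must be >= 0", call. = FALSE)
  if (dq_over_q == 0) return(r)
  stopifnot(length(r) == length(q))
  drop(smear_weights(q, q, dq_over_q) %*% r)
}

#' Model curve as the instrument records it
#'
#' `scale * smear(reflectivity) + background`: the ideal reflectivity of
#' the profile, computed on an oversampled log-spaced grid, convolved
#' with the constant-dQ/Q Gaussian resolution, scaled, and offset by the
#' flat background.
#'
#' @param profile a [slab_profile()].
#' @param instrument an [nr_instrument()].
#' @param warn_roughness see [reflectivity()].
#' @return Model curve at `instrument$q_grid`.
#' @export
measured_curve <- function(profile, instrument, warn_roughness = TRUE) {
  stopifnot(inherits(instrument, "nr_instrument"))
  sm <- smear_setup(instrument$q_grid, instrument$dq_over_q)
  r <- reflectivity(profile, sm$q_fine, warn_roughness = warn_roughness)
  rs <- if (is.null(sm$W)) r else drop(sm$W %*% r)
  instrument$scale * rs + instrument$background
}
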