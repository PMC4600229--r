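# ---- uncertainty quantification -------------------------------------------

# weighted Jacobian of the stacked model curve at the best fit: columns are
# the structural free parameters (central differences) followed by the free
# per-dataset scale/background nuisances (analytic).
fit_jacobian <- function(fit) {
  obj <- fit$objective_env
  free <- fit$free
  theta <- as.numeric(fit$theta)
  lower <- fit$bounds$lower; upper <- fit$bounds$upper
  setup <- obj$setup

  stack_fixed <- function(th) {
    # curve with nuisances held at the best-fit values
    m <- model_set_params(fit$model, stats::setNames(th, free))
    unlist(lapply(seq_along(setup), function(i) {
      s <- setup[[i]]
      p <- build_slabs(m, s$contrast)
      r <- abeles_cpp(s$qf, p$layers$thickness, p$layers$sld,
                      c(p$layers$roughness, p$backing_roughness),
                      p$fronting_sld, p$backing_sld)
      mm <- if (is.null(s$W)) r else drop(s$W %*% r)
      (fit$scale[i] * mm + fit$background[i]) / s$dr
    }))
  }

  J_struct <- vapply(seq_along(free), function(j) {
    h <- pmax(1e-5, 1e-4 * (upper[j] - lower[j]))
    thp <- theta; thp[j] <- min(theta[j] + h, upper[j])
    thm <- theta; thm[j] <- max(theta[j] - h, lower[j])
    (stack_fixed(thp) - stack_fixed(thm)) / (thp[j] - thm[j])
  }, numeric(obj$n_points))

  # analytic nuisance columns, block-diagonal per dataset
  nuis_cols <- list(); nuis_names <- character(0)
  npts <- vapply(setup, function(s) length(s$y), numeric(1))
  offsets <- cumsum(c(0, npts))
  cv <- obj$curves(fit$theta)
  for (i in seq_along(setup)) {
    idx <- (offsets[i] + 1):offsets[i + 1]
    if (fit$fit_scale) {
      col <- numeric(obj$n_points)
      col[idx] <- cv[[i]]$m / setup[[i]]$dr
      nuis_cols <- c(nuis_cols, list(col))
      nuis_names <- c(nuis_names, paste0("scale_", i))
    }
    if (fit$fit_background) {
      col <- numeric(obj$n_points)
      col[idx] <- 1 / setup[[i]]$dr
      nuis_cols <- c(nuis_cols, list(col))
      nuis_names <- c(nuis_names, paste0("background_", i))
    }
  }
  J <- cbind(J_struct, do.call(cbind, c(nuis_cols, list(deparse.level = 0))))
  colnames(J) <- c(free, nuis_names)
  J
}

boot_draws_linear <- function(fit, n_resamples) {
  J <- fit_jacobian(fit)
  # column-equilibrate before solving: parameters live on very different
  # scales (fractions vs Angstroms vs background counts)
  cn <- sqrt(colSums(J^2))
  cn[cn == 0] <- 1
  Js <- sweep(J, 2, cn, `/`)
  JtJ <- crossprod(Js)
  diag(JtJ) <- diag(JtJ) + 1e-8 # mild ridge on the equilibrated system
  res <- residuals(fit) # standardized, per dataset
  p <- length(fit$free)
  draws <- matrix(NA_real_, n_resamples, ncol(J),
                  dimnames = list(NULL, colnames(J)))
  for (k in seq_len(n_resamples)) {
    estar <- unlist(lapply(res, function(r) sample(r, length(r),
                                                   replace = TRUE)))
    delta <- solve(JtJ, crossprod(Js, estar)) / cn
    draws[k, ] <- delta
  }
  theta_full <- c(as.numeric(fit$theta),
                  as.vector(rbind(if (fit$fit_scale) fit$scale,
                                  if (fit$fit_background) fit$background)))
  draws <- sweep(draws, 2, theta_full[seq_len(ncol(J))], `+`)
  # clip structural draws into the fit bounds
  for (j in seq_len(p))
    draws[, j] <- pmin(pmax(draws[, j], fit$bounds$lower[j]),
                       fit$bounds$upper[j])
  draws
}

# full nonlinear refits per resample: Levenberg-Marquardt warm-started at
# the best fit (it converges in a few iterations on resampled data)
boot_draws_refit <- function(fit, n_resamples) {
  ft <- fitted(fit)
  res <- residuals(fit)
  p <- length(fit$free)
  draws <- matrix(NA_real_, n_resamples, p,
                  dimnames = list(NULL, fit$free))
  lower <- fit$bounds$lower; upper <- fit$bounds$upper
  th0 <- as.numeric(fit$theta)
  for (k in seq_len(n_resamples)) {
    ds <- lapply(seq_along(fit$datasets), function(i) {
      d <- fit$datasets[[i]]
      d$r <- ft[[i]] + d$dr * sample(res[[i]], length(d$dr), replace = TRUE)
      d
    })
    obj <- make_objective(ds, fit$model, fit$free, fit$instrument,
                          fit$fit_scale, fit$fit_background,
                          fit$control$oversample)
    lm <- try(suppressWarnings(minpack.lm::nls.lm(
      par = th0,
      fn = function(th) obj$resid(
        stats::setNames(pmin(pmax(th, lower), upper), fit$free)),
      control = minpack.lm::nls.lm.control(maxiter = 25))),
      silent = TRUE)
    draws[k, ] <- if (inherits(lm, "try-error")) th0
    else pmin(pmax(lm$par, lower), upper)
  }
  draws
}

posterior_draws <- function(fit, n_draws) {
  # random-walk Metropolis on the free parameters, Gaussian proposal from
  # the linearized covariance, chi^2/2 log-likelihood
  J <- fit_jacobian(fit)[, seq_along(fit$free), drop = FALSE]
  cn <- sqrt(colSums(J^2))
  cn[cn == 0] <- 1
  JtJ <- crossprod(sweep(J, 2, cn, `/`))
  diag(JtJ) <- diag(JtJ) + 1e-8
  Sigma <- solve(JtJ) / outer(cn, cn)
  L <- chol((2.4^2 / length(fit$free)) * Sigma)
  obj <- fit$objective_env
  lower <- fit$bounds$lower; upper <- fit$bounds$upper
  logpost <- function(th) {
    if (any(th < lower) || any(th > upper)) return(-Inf)
    -obj$fn(stats::setNames(th, fit$free)) / 2
  }
  nsteps <- max(2000L, 5L * n_draws)
  th <- as.numeric(fit$theta)
  lp <- logpost(th)
  keep <- matrix(NA_real_, nsteps, length(th))
  for (s in seq_len(nsteps)) {
    prop <- th + drop(rnorm(length(th)) %*% L)
    lpp <- logpost(prop)
    if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
      th <- prop; lp <- lpp
    }
    keep[s, ] <- th
  }
  idx <- round(seq(nsteps / 2, nsteps, length.out = n_draws))
  draws <- keep[idx, , drop = FALSE]
  colnames(draws) <- fit$free
  draws
}

# Profile-likelihood (MINOS-style) confidence limits: for each free
# parameter, walk outward from the optimum re-minimizing all other
# parameters (warm-chained Levenberg-Marquardt) until the objective rises
# by qchisq(level, 1), interpolating the crossing on the sqrt(dchi2)
# scale (exact for locally quadratic profiles).  Step sizes come from the
# linearized covariance.
profile_intervals <- function(fit, level = 0.95) {
  obj <- fit$objective_env
  free <- fit$free
  th <- as.numeric(fit$theta)
  f0 <- fit$objective
  lower <- fit$bounds$lower; upper <- fit$bounds$upper
  target <- stats::qchisq(level, 1)

  J <- fit_jacobian(fit)
  cn <- sqrt(colSums(J^2)); cn[cn == 0] <- 1
  JtJ <- crossprod(sweep(J, 2, cn, `/`))
  diag(JtJ) <- diag(JtJ) + 1e-8
  Sigma <- solve(JtJ) / outer(cn, cn)
  sd_lin <- sqrt(pmax(diag(Sigma)[seq_along(free)], 0))

  profile_at <- function(j, v, warm) {
    idx <- setdiff(seq_along(th), j)
    r <- try(suppressWarnings(minpack.lm::nls.lm(
      par = warm,
      fn = function(p) {
        full <- numeric(length(th))
        full[idx] <- pmin(pmax(p, lower[idx]), upper[idx])
        full[j] <- v
        obj$resid(stats::setNames(full, free))
      },
      control = minpack.lm::nls.lm.control(maxiter = 60))),
      silent = TRUE)
    if (inherits(r, "try-error")) return(list(f = Inf, p = warm))
    p <- pmin(pmax(r$par, lower[idx]), upper[idx])
    full <- numeric(length(th)); full[idx] <- p; full[j] <- v
    list(f = obj$fn(stats::setNames(full, free)), p = p)
  }

  # Walk outward, tracking the LAST downward-to-upward crossing of the
  # threshold: the likelihood-ratio confidence set can be disconnected
  # when a competing optimum lies within the threshold (the tail/core
  # trade-off has one), and the reported interval is the hull of the
  # set.  The walk stops once the profile exceeds `give_up` (well above
  # the threshold) or reaches a bound.
  one_side <- function(j, dir) {
    idx <- setdiff(seq_along(th), j)
    range_j <- upper[j] - lower[j]
    # steps grow from the linearized scale but stay small enough for the
    # warm-chained re-minimization to track the other parameters
    step <- min(max(1.2 * sd_lin[j], 2e-3 * range_j), 0.04 * range_j)
    give_up <- max(4 * target, 30)
    warm <- th[idx]
    v_prev <- th[j]; d_prev <- 0
    endpoint <- th[j]
    v <- th[j]
    for (k in 1:30) {
      v <- v + dir * step
      at_bound <- FALSE
      if (v <= lower[j]) { v <- lower[j]; at_bound <- TRUE }
      if (v >= upper[j]) { v <- upper[j]; at_bound <- TRUE }
      pr <- profile_at(j, v, warm)
      warm <- pr$p
      d <- max(pr$f - f0, 0)
      if (d <= target) {
        endpoint <- v
      } else if (d_prev <= target) {
        # upward crossing: sqrt(dchi2) is locally linear in the parameter
        w <- (sqrt(target) - sqrt(d_prev)) / (sqrt(d) - sqrt(d_prev))
        endpoint <- v_prev + (v - v_prev) * w
      }
      if (at_bound || d > give_up) break
      v_prev <- v; d_prev <- d
      step <- min(step * 1.6, 0.04 * range_j)
    }
    endpoint
  }

  iv <- data.frame(parameter = free, estimate = th,
                   low = NA_real_, high = NA_real_,
                   stringsAsFactors = FALSE)
  for (j in seq_along(free)) {
    iv$low[j] <- min(one_side(j, -1), th[j])
    iv$high[j] <- max(one_side(j, 1), th[j])
  }
  iv
}

#' Confidence limits for a co-refined fit
#'
#' Attaches 95 % intervals (and interval-bearing derived metrics) to an
#' [fsb_fit()].  The default is a residual-resampling bootstrap whose
#' resamples are re-estimated in the Gauss-Newton linearization around
#' the best fit; `refit = TRUE` performs a full Nelder-Mead refit per
#' resample, and `method = "posterior"` draws from a random-walk
#' Metropolis posterior instead.  Intervals are percentile-based and
#' reported in (low, high) form.
#'
#' @param fit an [fsb_fit()] object.
#' @param method `"bootstrap"` (default), `"profile"` (MINOS-style
#'   profile likelihood; recommended for parameters lying along the
#'   curved tail/core degeneracy, where resampling undercovers) or
#'   `"posterior"`.
#' @param n_resamples number of bootstrap resamples / posterior draws
#'   retained (must be >= 20; unused by the profile method).
#' @param seed integer seed (the profile method is deterministic).
#' @param refit bootstrap only: refit each resample by full nonlinear
#'   optimization instead of the linearized solve.
#' @param level confidence level (default 0.95).
#' @return The fit with `intervals`, `derived` and (for the sampling
#'   methods) `draws` filled in.
#' @export
fsb_confint <- function(fit, method = c("bootstrap", "profile",
                                        "posterior"),
                        n_resamples = 200, seed = fit$seed + 1L,
                        refit = FALSE, level = 0.95) {
  stopifnot(inherits(fit, "fsb_fit"))
  method <- match.arg(method)
  if (method == "profile") {
    iv <- profile_intervals(fit, level)
    interval_of <- function(p) unlist(iv[iv$parameter == p,
                                         c("low", "high")])
    dm0 <- derived_metrics(fit$model)
    derived <- data.frame(metric = names(dm0), estimate = as.numeric(dm0),
                          low = NA_real_, high = NA_real_,
                          stringsAsFactors = FALSE)
    map <- c(outer_lps_pct = "outer_f_lps", inner_pc_pct = "inner_f_pc",
             coverage_pct = "coverage")
    for (nm in names(map)) if (map[[nm]] %in% iv$parameter) {
      derived[derived$metric == nm, c("low", "high")] <-
        100 * interval_of(map[[nm]])
    }
    if ("t_core" %in% iv$parameter) {
      # total head region: core interval shifted by the protein-layer
      # thickness (widths added in quadrature when both are free)
      ci_core <- interval_of("t_core")
      extra <- if (is.null(fit$model$protein)) 0 else
        fit$model$protein$thickness
      half <- c(fit$theta[["t_core"]] - ci_core[1],
                ci_core[2] - fit$theta[["t_core"]])
      if ("protein_thickness" %in% iv$parameter) {
        ci_p <- interval_of("protein_thickness")
        half <- sqrt(half^2 + c(fit$theta[["protein_thickness"]] - ci_p[1],
                                ci_p[2] -
                                  fit$theta[["protein_thickness"]])^2)
      }
      est <- derived$estimate[derived$metric == "head_region_total"]
      derived[derived$metric == "head_region_total", c("low", "high")] <-
        c(est - half[1], est + half[2])
    }
    fit$intervals <- iv
    fit$derived <- derived
    fit$draws <- NULL
    fit$interval_method <- "profile"
    fit$n_resamples <- NA_integer_
    return(fit)
  }
  if (n_resamples < 20)
    stop("n_resamples must be at least 20", call. = FALSE)
  draws <- with_seed(seed, {
    if (method == "posterior") posterior_draws(fit, n_resamples)
    else if (refit) boot_draws_refit(fit, n_resamples)
    else boot_draws_linear(fit, n_resamples)
  })
  alpha <- (1 - level) / 2
  p <- length(fit$free)

  est_full <- c(as.numeric(fit$theta),
                if (ncol(draws) > p)
                  c(as.vector(rbind(if (fit$fit_scale) fit$scale,
                                    if (fit$fit_background) fit$background))))
  qs <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  iv <- data.frame(parameter = colnames(draws),
                   estimate = est_full[seq_len(ncol(draws))],
                   low = pmin(qs[1, ], est_full[seq_len(ncol(draws))]),
                   high = pmax(qs[2, ], est_full[seq_len(ncol(draws))]),
                   stringsAsFactors = FALSE)

  # derived metrics per draw
  dm0 <- derived_metrics(fit$model)
  dmat <- t(apply(draws[, seq_len(p), drop = FALSE], 1, function(th) {
    derived_metrics(model_set_params(fit$model,
                                     stats::setNames(th, fit$free)))
  }))
  dq <- apply(dmat, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  derived <- data.frame(metric = names(dm0), estimate = as.numeric(dm0),
                        low = pmin(dq[1, ], dm0), high = pmax(dq[2, ], dm0),
                        stringsAsFactors = FALSE)

  fit$intervals <- iv
  fit$derived <- derived
  fit$draws <- draws
  fit$interval_method <- if (method == "posterior") "posterior"
  else if (refit) "bootstrap-refit" else "bootstrap-linearized"
  fit$n_resamples <- n_resamples
  fit
}

#' @export
confint.fsb_fit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$draws) && identical(object$interval_method,
                                         "profile")) {
    iv <- object$intervals
    if (missing(parm)) parm <- iv$parameter
    out <- as.matrix(iv[match(parm, iv$parameter), c("low", "high")])
    rownames(out) <- parm
    colnames(out) <- c("2.5 %", "97.5 %")
    return(out)
  }
  if (is.null(object$draws))
    object <- fsb_confint(object, level = level)
  draws <- object$draws
  if (missing(parm)) parm <- colnames(draws)
  alpha <- (1 - level) / 2
  out <- t(apply(draws[, parm, drop = FALSE], 2, stats::quantile,
                 probs = c(alpha, 1 - alpha), names = FALSE))
  colnames(out) <- paste0(format(100 * c(alpha, 1 - alpha),
                                 trim = TRUE), " %")
  out
}
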