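# ---- fittable-parameter machinery -----------------------------------------

fsb_parameter_names <- c(
  "water_gap", "t_inner_head", "t_inner_tail", "t_outer_tail", "t_core",
  "outer_f_lps", "inner_f_pc", "coverage", "sigma_bilayer",
  "protein_thickness", "protein_fraction")

model_get_params <- function(model, names) {
  vapply(names, function(nm) switch(
    nm,
    water_gap = model$water_gap,
    t_inner_head = model$t_inner_head,
    t_inner_tail = model$t_inner_tail,
    t_outer_tail = model$t_outer_tail,
    t_core = model$t_core,
    outer_f_lps = model$outer$f_lps,
    inner_f_pc = model$inner$f_pc,
    coverage = model$coverage,
    sigma_bilayer = model$sigma_bilayer,
    protein_thickness = if (is.null(model$protein)) 0 else
      model$protein$thickness,
    protein_fraction = if (is.null(model$protein)) 0 else
      model$protein$fraction,
    stop("unknown parameter '", nm, "'", call. = FALSE)), numeric(1))
}

# fast field update; assumes values already inside bounds.  Leaflet updates
# keep the leaflet's solvent fraction and give the remainder to the other
# lipid species.
model_set_params <- function(model, theta) {
  for (nm in names(theta)) {
    v <- theta[[nm]]
    switch(nm,
      water_gap = model$water_gap <- v,
      t_inner_head = model$t_inner_head <- v,
      t_inner_tail = model$t_inner_tail <- v,
      t_outer_tail = model$t_outer_tail <- v,
      t_core = model$t_core <- v,
      outer_f_lps = {
        fs <- model$outer$f_solvent
        fpc <- max(0, 1 - v - fs)
        model$outer <- structure(list(f_lps = v, f_pc = fpc,
                                      f_solvent = 1 - v - fpc),
                                 class = "fsb_leaflet")
      },
      inner_f_pc = {
        fs <- model$inner$f_solvent
        flps <- max(0, 1 - v - fs)
        model$inner <- structure(list(f_lps = flps, f_pc = v,
                                      f_solvent = 1 - v - flps),
                                 class = "fsb_leaflet")
      },
      coverage = model$coverage <- v,
      sigma_bilayer = model$sigma_bilayer <- v,
      protein_thickness = {
        if (is.null(model$protein))
          model$protein <- list(thickness = v, fraction = 0.3,
                                material = "lactoferrin")
        else model$protein$thickness <- v
      },
      protein_fraction = {
        if (is.null(model$protein))
          model$protein <- list(thickness = 0, fraction = v,
                                material = "lactoferrin")
        else model$protein$fraction <- v
      },
      stop("unknown parameter '", nm, "'", call. = FALSE))
  }
  model
}

#' Default free parameters for a model fit
#'
#' The structural parameters refined in a paper-faithful fit: water gap,
#' tail and core thicknesses, the dominant leaflet fractions, coverage
#' and the bilayer roughness; plus the protein layer thickness and
#' volume fraction when the model carries a protein layer.  Substrate
#' and head-group parameters are held at their once-fitted values.
#'
#' @param model an [fsb_model()].
#' @return Character vector of parameter names.
#' @export
default_free <- function(model) {
  free <- c("water_gap", "t_inner_tail", "t_outer_tail", "t_core",
            "outer_f_lps", "inner_f_pc", "coverage", "sigma_bilayer")
  if (!is.null(model$protein))
    free <- c(free, "protein_thickness", "protein_fraction")
  free
}

#' Default fit bounds
#'
#' Wide physically sensible boxes for each fittable parameter
#' (thicknesses in Angstrom, fractions dimensionless).  Override
#' individual entries by passing a modified copy to [fsb_fit()].
#'
#' @param model an [fsb_model()] (used only to pick which parameters
#'   apply).
#' @param free parameter names to bound.
#' @return data.frame with columns `parameter`, `lower`, `upper`.
#' @export
default_bounds <- function(model, free = default_free(model)) {
  all <- list(
    water_gap = c(8, 25), t_inner_head = c(4, 14),
    t_inner_tail = c(10, 22), t_outer_tail = c(10, 22),
    t_core = c(20, 60),
    outer_f_lps = c(0.05, 0.88), inner_f_pc = c(0.05, 0.88),
    coverage = c(0.6, 1), sigma_bilayer = c(3, 20),
    protein_thickness = c(20, 130), protein_fraction = c(0.05, 0.7))
  b <- all[free]
  if (any(vapply(b, is.null, logical(1))))
    stop("no default bounds for: ",
         paste(free[vapply(b, is.null, logical(1))], collapse = ", "),
         call. = FALSE)
  data.frame(parameter = free,
             lower = vapply(b, `[`, numeric(1), 1),
             upper = vapply(b, `[`, numeric(1), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- objective -------------------------------------------------------------

# weighted-least-squares profile of per-dataset scale and background
profile_scale_background <- function(m, y, w, fit_scale, fit_background,
                                     scale0 = 1, bkg0 = 0) {
  if (fit_scale && fit_background) {
    swm2 <- sum(w * m * m); swm <- sum(w * m); sw <- sum(w)
    det <- swm2 * sw - swm * swm
    if (det > 0) {
      s <- (sum(w * m * y) * sw - swm * sum(w * y)) / det
      b <- (sum(w * y) - s * swm) / sw
    } else {
      s <- 1; b <- 0
    }
    if (b < 0) {
      b <- 0
      s <- sum(w * m * y) / swm2
    }
    if (!is.finite(s) || s <= 0) s <- .Machine$double.eps
  } else if (fit_scale) {
    b <- bkg0
    s <- sum(w * m * (y - b)) / sum(w * m * m)
    if (!is.finite(s) || s <= 0) s <- .Machine$double.eps
  } else if (fit_background) {
    s <- scale0
    b <- sum(w * (y - s * m)) / sum(w)
    if (b < 0) b <- 0
  } else {
    s <- scale0; b <- bkg0
  }
  c(s, b)
}

# precompute everything q-grid-dependent once, return closures used by the
# optimizer; `curves` also reports the profiled scale/background
make_objective <- function(datasets, model, free, instrument = NULL,
                           fit_scale = TRUE, fit_background = TRUE,
                           oversample = 4) {
  if (!length(datasets)) stop("empty dataset list", call. = FALSE)
  if (is.null(instrument)) instrument <- nr_instrument()
  mats <- model$materials
  rho_mat <- vapply(c("lps_core", "pc_head", "lps_tails", "dppc_tails_d"),
                    function(nm) nuclear_sld(get_material(mats, nm)),
                    numeric(1))
  setup <- lapply(datasets, function(d) {
    if (any(!is.finite(d$q)) || any(!is.finite(d$r)) || any(!is.finite(d$dr)))
      stop("non-finite values in dataset '", d$label, "'", call. = FALSE)
    dqq <- if (!is.null(d$dq) && length(d$dq))
      stats::median(d$dq / d$q) else instrument$dq_over_q
    sm <- smear_setup(d$q, dqq, oversample)
    sub <- model$substrate
    list(q = d$q, y = d$r, w = 1 / d$dr^2, dr = d$dr,
         contrast = d$contrast, qf = sm$q_fine, W = sm$W, dqq = dqq,
         # contrast-fixed pieces of the slab stack
         rho_solv = solvent_sld(d$contrast, mats),
         sub_sld = vapply(sub$material, function(nm)
           spin_sld(get_material(mats, nm), d$contrast$spin), numeric(1)),
         sub_thick = sub$thickness, sub_rough = sub$roughness,
         fronting = spin_sld(get_material(mats, "si"), d$contrast$spin))
  })
  n_eval <- 0L
  scale0 <- instrument$scale; bkg0 <- instrument$background

  # lean slab assembly; mirrors build_slabs() exactly (asserted in tests)
  fast_layers <- function(m, s) {
    rs <- s$rho_solv
    cv <- m$coverage
    mem <- function(f1, r1, f2, r2)
      cv * (f1 * r1 + f2 * r2 + (1 - f1 - f2) * rs) + (1 - cv) * rs
    inner <- m$inner; outer <- m$outer
    d <- c(s$sub_thick, m$water_gap, m$t_inner_head, m$t_inner_tail,
           m$t_outer_tail, m$t_core)
    rho <- c(s$sub_sld, rs,
             mem(inner$f_lps, rho_mat[["lps_core"]],
                 inner$f_pc, rho_mat[["pc_head"]]),
             mem(inner$f_lps, rho_mat[["lps_tails"]],
                 inner$f_pc, rho_mat[["dppc_tails_d"]]),
             mem(outer$f_lps, rho_mat[["lps_tails"]],
                 outer$f_pc, rho_mat[["dppc_tails_d"]]),
             mem(outer$f_lps, rho_mat[["lps_core"]],
                 outer$f_pc, rho_mat[["pc_head"]]))
    sig <- c(s$sub_rough, rep.int(m$sigma_bilayer, 5))
    if (!is.null(m$protein) && m$protein$thickness > 0) {
      d <- c(d, m$protein$thickness)
      rho <- c(rho, mem(m$protein$fraction,
                        nuclear_sld(get_material(mats, m$protein$material)),
                        0, 0))
      sig <- c(sig, m$sigma_bilayer)
    }
    list(d = d, rho = rho, sig = c(sig, m$sigma_bilayer))
  }

  curves <- function(theta) {
    m <- model_set_params(model, theta)
    lapply(setup, function(s) {
      lay <- fast_layers(m, s)
      r <- abeles_cpp(s$qf, lay$d, lay$rho, lay$sig, s$fronting, s$rho_solv)
      mm <- if (is.null(s$W)) r else drop(s$W %*% r)
      sb <- profile_scale_background(mm, s$y, s$w, fit_scale,
                                     fit_background, scale0, bkg0)
      list(m = mm, scale = sb[1], background = sb[2],
           fitted = sb[1] * mm + sb[2])
    })
  }
  fn <- function(theta) {
    n_eval <<- n_eval + 1L
    cv <- curves(theta)
    sum(vapply(seq_along(cv), function(i)
      sum(setup[[i]]$w * (cv[[i]]$fitted - setup[[i]]$y)^2), numeric(1)))
  }
  resid <- function(theta) {
    n_eval <<- n_eval + 1L
    cv <- curves(theta)
    unlist(lapply(seq_along(cv), function(i)
      (cv[[i]]$fitted - setup[[i]]$y) / setup[[i]]$dr))
  }
  list(fn = fn, resid = resid, curves = curves, setup = setup,
       n_eval = function() n_eval,
       n_points = sum(vapply(setup, function(s) length(s$y), numeric(1))))
}

#' Error-weighted least-squares objective
#'
#' The co-refinement objective: the sum over datasets and points of
#' `((R_model - R_obs) / dR)^2`, with one shared structure and, by
#' default, per-dataset scale and background profiled out analytically
#' as free nuisance parameters.
#'
#' @param model an [fsb_model()].
#' @param datasets a list of reflectivity datasets ([nr_dataset()]).
#' @param instrument optional [nr_instrument()] supplying the resolution
#'   when a dataset has no dQ column, and the fixed scale/background
#'   when they are not profiled.
#' @param fit_scale,fit_background profile the per-dataset scale /
#'   background (default) or hold them at the instrument values.
#' @return The objective value (>= 0).
#' @export
fsb_objective <- function(model, datasets, instrument = NULL,
                          fit_scale = TRUE, fit_background = TRUE) {
  if (inherits(datasets, "nr_dataset")) datasets <- list(datasets)
  obj <- make_objective(datasets, model, character(0), instrument,
                        fit_scale, fit_background)
  obj$fn(stats::setNames(numeric(0), character(0)))
}

# ---- optimizers ------------------------------------------------------------

# differential evolution (rand/1/bin), bounded, run inside the caller's
# seeded RNG stream
de_optimize <- function(fn, lower, upper, start, pop_size, itermax,
                        F = 0.8, CR = 0.9) {
  np <- length(lower)
  pop <- matrix(runif(pop_size * np, lower, upper), nrow = pop_size,
                byrow = TRUE)
  pop[1, ] <- start
  obj <- apply(pop, 1, fn)
  for (gen in seq_len(itermax)) {
    for (i in seq_len(pop_size)) {
      idx <- sample(seq_len(pop_size)[-i], 3)
      mut <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
      # reflect back into the box
      below <- mut < lower; mut[below] <- pmin(2 * lower[below] - mut[below],
                                               upper[below])
      above <- mut > upper; mut[above] <- pmax(2 * upper[above] - mut[above],
                                               lower[above])
      mut <- pmin(pmax(mut, lower), upper)
      cross <- runif(np) < CR
      cross[sample.int(np, 1)] <- TRUE
      trial <- ifelse(cross, mut, pop[i, ])
      fo <- fn(trial)
      if (fo <= obj[i]) {
        pop[i, ] <- trial
        obj[i] <- fo
      }
    }
  }
  list(pop = pop, obj = obj)
}

# equal-objective tie-break: prefer the lowest-roughness member (parsimony)
de_best <- function(de, free) {
  best <- min(de$obj)
  cand <- which(de$obj <= best + 1e-12)
  if (length(cand) > 1L && "sigma_bilayer" %in% free) {
    j <- match("sigma_bilayer", free)
    cand <- cand[order(de$pop[cand, j])]
  }
  de$pop[cand[1], ]
}

#' Optimizer settings for [fsb_fit()]
#'
#' @param de_popsize population of the global differential-evolution
#'   stage; default 15 times the number of free parameters.
#' @param de_itermax DE generations.
#' @param de_F,de_CR DE mutation weight and crossover rate.
#' @param nm_maxit iteration cap of each Nelder-Mead run of the local
#'   polish.
#' @param nm_reltol relative convergence tolerance of the local stage.
#' @param nm_restarts maximum number of Nelder-Mead restarts (each with
#'   a fresh simplex); the loop stops early once a restart improves the
#'   objective by less than `nm_improve` relative.
#' @param nm_improve relative improvement threshold ending the restart
#'   loop.
#' @param global run the DE stage at all (disable for warm starts very
#'   close to the optimum).
#' @param multistart when > 0, replace the DE stage with a
#'   Levenberg-Marquardt multistart screen from this many jittered
#'   copies of the start; the screen's best and the original start are
#'   both polished and the better result kept.  Suited to warm starts.
#' @param ms_jitter relative jitter of the multistart screen.
#' @param lm_polish finish with a Levenberg-Marquardt polish on the
#'   weighted residuals (pins the simplex result onto the least-squares
#'   minimum).
#' @param lm_maxiter iteration cap of the polish.
#' @param oversample reflectivity oversampling factor for resolution
#'   smearing.
#' @return List of settings.
#' @export
fsb_control <- function(de_popsize = NULL, de_itermax = 40, de_F = 0.8,
                        de_CR = 0.9, nm_maxit = 700, nm_reltol = 1e-8,
                        nm_restarts = 5, nm_improve = 1e-3,
                        global = TRUE, multistart = 0, ms_jitter = 0.35,
                        lm_polish = TRUE, lm_maxiter = 30,
                        oversample = 4) {
  list(de_popsize = de_popsize, de_itermax = de_itermax, de_F = de_F,
       de_CR = de_CR, nm_maxit = nm_maxit, nm_reltol = nm_reltol,
       nm_restarts = nm_restarts, nm_improve = nm_improve,
       global = global, multistart = multistart, ms_jitter = ms_jitter,
       lm_polish = lm_polish, lm_maxiter = lm_maxiter,
       oversample = oversample)
}

# ---- the fit ---------------------------------------------------------------

#' Co-refine one bilayer structure against multi-contrast reflectivity
#'
#' Simultaneously fits a single [fsb_model()] to several reflectivity
#' datasets measured under different contrast conditions (solvent
#' isotopic composition, neutron spin).  The structure is shared across
#' datasets; only contrast-dependent SLDs and the per-dataset scale and
#' background (profiled analytically) differ.  The search runs a
#' bounded, seeded differential-evolution global stage followed by a
#' Nelder-Mead local polish, and is bit-reproducible given `seed`.
#' Percentile confidence intervals come from a residual-resampling
#' bootstrap re-estimated in the Gauss-Newton linearization around the
#' best fit (see [fsb_confint()] for full nonlinear refits or posterior
#' sampling).
#'
#' @param datasets a list of [nr_dataset()] objects (one per contrast);
#'   two or more contrasts are recommended.
#' @param model starting [fsb_model()].
#' @param free names of the parameters to refine (see [default_free()]).
#' @param bounds data.frame of `parameter`, `lower`, `upper`; must
#'   bracket the starting values.
#' @param instrument optional [nr_instrument()] (resolution fallback and
#'   fixed scale/background).
#' @param seed integer seed controlling every stochastic step.
#' @param control optimizer settings from [fsb_control()].
#' @param intervals compute bootstrap intervals (default TRUE).
#' @param n_resamples bootstrap resamples for the intervals.
#' @param fit_scale,fit_background treat per-dataset scale / background
#'   as free nuisance parameters (default TRUE).
#' @return An object of class `fsb_fit` with components `model` (the
#'   best-fit [fsb_model()]), `theta`, `objective`, `dof`, `scale` and
#'   `background` per dataset, `intervals` (95 % limits), `derived`
#'   (asymmetry metrics and coverage with intervals), `seed`,
#'   `n_evaluations`.  Methods: `print`, `summary`, `coef`, `confint`,
#'   `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' sc <- scenario_catalog()$baseline_best
#' ds <- generate_datasets(sc, seed = 1)
#' fit <- fsb_fit(ds, model = sc$truth, seed = 1,
#'                control = fsb_control(global = FALSE))
#' fit
#' }
#' @export
fsb_fit <- function(datasets, model = fsb_model(),
                    free = default_free(model),
                    bounds = default_bounds(model, free),
                    instrument = NULL, seed = 1L,
                    control = fsb_control(), intervals = TRUE,
                    n_resamples = 200, fit_scale = TRUE,
                    fit_background = TRUE) {
  if (inherits(datasets, "nr_dataset")) datasets <- list(datasets)
  if (!length(datasets)) stop("empty dataset list", call. = FALSE)
  if (!length(free)) stop("no parameter marked free", call. = FALSE)
  # canonical dataset order: the fit and its intervals are then exactly
  # invariant to the order the caller supplies the contrasts in
  datasets <- datasets[order(vapply(datasets, function(d)
    sprintf("%08.6f_%s_%s", d$contrast$d2o_fraction, d$contrast$spin,
            d$label), character(1)))]
  bounds <- bounds[match(free, bounds$parameter), ]
  if (any(is.na(bounds$lower)))
    stop("bounds missing for some free parameters", call. = FALSE)
  lower <- bounds$lower; upper <- bounds$upper
  start <- model_get_params(model, free)
  if (any(start < lower - 1e-9) || any(start > upper + 1e-9)) {
    warning("starting values clipped into bounds", call. = FALSE)
    start <- pmin(pmax(start, lower), upper)
  }

  obj <- make_objective(datasets, model, free, instrument,
                        fit_scale, fit_background, control$oversample)
  named <- function(x) stats::setNames(x, free)
  fn <- function(theta) obj$fn(named(theta))

  res <- with_seed(seed, {
    cand <- list(start)
    if (control$multistart > 0) {
      # multistart screen: Levenberg-Marquardt from jittered copies of the
      # start; its best joins the original start as a second local-search
      # candidate (the two fail on different data realizations)
      f_scr <- Inf; th_scr <- NULL
      jit <- matrix(runif(control$multistart * length(free),
                          1 - control$ms_jitter, 1 + control$ms_jitter),
                    nrow = control$multistart)
      starts <- rbind(start, sweep(jit, 2, start, `*`))
      for (k in seq_len(nrow(starts))) {
        sk <- pmin(pmax(starts[k, ], lower), upper)
        lm <- try(suppressWarnings(minpack.lm::nls.lm(
          par = sk,
          fn = function(th) obj$resid(named(pmin(pmax(th, lower), upper))),
          control = minpack.lm::nls.lm.control(maxiter = 25))),
          silent = TRUE)
        if (!inherits(lm, "try-error")) {
          p <- pmin(pmax(lm$par, lower), upper)
          f <- fn(p)
          if (f < f_scr) { f_scr <- f; th_scr <- p }
        }
      }
      if (!is.null(th_scr)) cand <- c(cand, list(th_scr))
    } else if (isTRUE(control$global) && control$de_itermax > 0) {
      pop <- control$de_popsize
      if (is.null(pop)) pop <- max(20L, 15L * length(free))
      de <- de_optimize(fn, lower, upper, start, pop,
                        control$de_itermax, control$de_F, control$de_CR)
      cand <- list(de_best(de, free))
    }
    pen_fn <- function(th) {
      if (any(th < lower) || any(th > upper))
        return(1e15 * (1 + sum(pmax(lower - th, 0) + pmax(th - upper, 0))))
      fn(th)
    }
    # local stage: restarted Nelder-Mead (a fresh simplex per restart
    # escapes premature collapse in this many-parameter objective), run
    # from every candidate start
    f_best <- Inf
    th_best <- cand[[1]]
    conv <- 0L
    for (theta in cand) {
      f_c <- fn(theta)
      th_c <- theta
      f_prev <- Inf
      for (k in seq_len(max(1L, control$nm_restarts))) {
        nm <- stats::optim(th_c, pen_fn, method = "Nelder-Mead",
                           control = list(maxit = control$nm_maxit,
                                          reltol = control$nm_reltol))
        conv <- nm$convergence
        if (nm$value <= f_c) {
          th_c <- nm$par
          f_c <- nm$value
        }
        if (f_prev - f_c < control$nm_improve * (abs(f_c) + 1e-12))
          break
        f_prev <- f_c
      }
      if (f_c < f_best) { f_best <- f_c; th_best <- th_c }
    }
    # Levenberg-Marquardt polish on the weighted residuals: pins the
    # simplex result onto the least-squares minimum precisely and cheaply
    if (isTRUE(control$lm_polish)) {
      lm <- try(suppressWarnings(minpack.lm::nls.lm(
        par = th_best,
        fn = function(th) obj$resid(named(pmin(pmax(th, lower), upper))),
        control = minpack.lm::nls.lm.control(
          maxiter = control$lm_maxiter))),
        silent = TRUE)
      if (!inherits(lm, "try-error")) {
        th_lm <- pmin(pmax(lm$par, lower), upper)
        f_lm <- fn(th_lm)
        if (f_lm <= f_best) {
          th_best <- th_lm
          f_best <- f_lm
        }
      }
    }
    list(theta = named(th_best), value = f_best, convergence = conv)
  })

  best_model <- model_set_params(model, res$theta)
  cv <- obj$curves(res$theta)
  scales <- vapply(cv, `[[`, numeric(1), "scale")
  bkgs <- vapply(cv, `[[`, numeric(1), "background")
  labels <- vapply(datasets, function(d)
    if (!is.null(d$label) && nzchar(d$label)) d$label
    else contrast_label(d$contrast), character(1))
  names(scales) <- names(bkgs) <- labels

  n_nuis <- length(datasets) * (fit_scale + fit_background)
  fit <- structure(
    list(model = best_model, theta = res$theta, free = free,
         bounds = bounds, objective = res$value,
         dof = obj$n_points - length(free) - n_nuis,
         n_points = obj$n_points,
         scale = scales, background = bkgs,
         datasets = datasets, objective_env = obj,
         fit_scale = fit_scale, fit_background = fit_background,
         instrument = instrument, seed = as.integer(seed),
         control = control, n_evaluations = obj$n_eval(),
         convergence = res$convergence,
         intervals = NULL, derived = NULL, draws = NULL),
    class = "fsb_fit")
  if (intervals)
    fit <- fsb_confint(fit, n_resamples = n_resamples, seed = seed + 1L)
  fit$n_evaluations <- obj$n_eval()
  fit
}

derived_metrics <- function(model) {
  am <- asymmetry_metrics(model)
  c(outer_lps_pct = am$outer_lps_pct, inner_pc_pct = am$inner_pc_pct,
    coverage_pct = 100 * model$coverage,
    head_region_total = model$t_core +
      if (is.null(model$protein)) 0 else model$protein$thickness)
}

# ---- methods ---------------------------------------------------------------

#' @export
coef.fsb_fit <- function(object, ...) object$theta

#' @export
fitted.fsb_fit <- function(object, ...) {
  cv <- object$objective_env$curves(object$theta)
  lapply(cv, `[[`, "fitted")
}

#' @export
residuals.fsb_fit <- function(object, type = c("standardized", "raw"), ...) {
  type <- match.arg(type)
  ft <- fitted(object)
  lapply(seq_along(object$datasets), function(i) {
    d <- object$datasets[[i]]
    r <- d$r - ft[[i]]
    if (type == "standardized") r / d$dr else r
  })
}

#' @export
predict.fsb_fit <- function(object, ...) {
  ft <- fitted(object)
  lapply(seq_along(object$datasets), function(i) {
    d <- object$datasets[[i]]
    data.frame(q = d$q, r_obs = d$r, dr = d$dr, r_fit = ft[[i]])
  })
}

#' @export
simulate.fsb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed + 100L
  ft <- fitted(object)
  with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      lapply(seq_along(object$datasets), function(i) {
        d <- object$datasets[[i]]
        d$r <- ft[[i]] + d$dr * rnorm(length(d$dr))
        d
      })
    })
  })
}

fmt_range <- function(est, low, high, digits = 4) {
  if (is.na(low) || is.na(high))
    return(format(signif(est, digits)))
  sprintf("%s (range %s,%s)", format(signif(est, digits)),
          format(signif(low, digits)), format(signif(high, digits)))
}

#' @export
print.fsb_fit <- function(x, digits = 4, ...) {
  cat("Co-refined floating supported bilayer fit\n")
  cat(sprintf("  %d datasets, %d points, objective chi^2 = %.4g (chi^2/dof = %.3g)\n",
              length(x$datasets), x$n_points, x$objective,
              x$objective / max(x$dof, 1)))
  iv <- x$intervals
  for (nm in x$free) {
    lo <- hi <- NA_real_
    if (!is.null(iv) && nm %in% iv$parameter) {
      row <- iv[iv$parameter == nm, ]
      lo <- row$low; hi <- row$high
    }
    cat(sprintf("  %-18s %s\n", nm,
                fmt_range(x$theta[[nm]], lo, hi, digits)))
  }
  am <- asymmetry_metrics(x$model)
  cat(sprintf("  leaflets (LPS:PC)  outer %s   inner %s\n",
              am$outer_ratio, am$inner_ratio))
  cat(sprintf("  coverage %.1f %%   seed %d   %d objective evaluations\n",
              100 * x$model$coverage, x$seed, x$n_evaluations))
  invisible(x)
}

#' @export
summary.fsb_fit <- function(object, ...) {
  iv <- object$intervals
  tab <- data.frame(parameter = object$free,
                    estimate = as.numeric(object$theta),
                    low = NA_real_, high = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(iv)) {
    m <- match(tab$parameter, iv$parameter)
    tab$low <- iv$low[m]; tab$high <- iv$high[m]
  }
  out <- list(table = tab, derived = object$derived,
              asymmetry = asymmetry_metrics(object$model),
              objective = object$objective, dof = object$dof,
              scale = object$scale, background = object$background,
              seed = object$seed)
  class(out) <- "summary.fsb_fit"
  out
}

#' @export
print.summary.fsb_fit <- function(x, ...) {
  cat("Best-fit parameters (95 % limits):\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("\nLeaflet asymmetry (LPS:PC): outer %s, inner %s\n",
              x$asymmetry$outer_ratio, x$asymmetry$inner_ratio))
  if (!is.null(x$derived)) {
    cat("Derived metrics:\n")
    print(x$derived, row.names = FALSE, digits = 4)
  }
  cat(sprintf("objective %.4g on %d dof\n", x$objective, x$dof))
  invisible(x)
}

#' @export
plot.fsb_fit <- function(x, ...) {
  ft <- fitted(x)
  cols <- seq_along(x$datasets) + 1
  qr <- range(unlist(lapply(x$datasets, `[[`, "q")))
  rr <- range(unlist(lapply(x$datasets, `[[`, "r")),
              unlist(ft))
  plot(NA, xlim = qr, ylim = pmax(rr, 1e-12), log = "xy",
       xlab = expression(Q ~ (ring(A)^-1)), ylab = "R", ...)
  for (i in seq_along(x$datasets)) {
    d <- x$datasets[[i]]
    points(d$q, pmax(d$r, 1e-12), col = cols[i], pch = 16, cex = 0.4)
    lines(d$q, pmax(ft[[i]], 1e-12), col = cols[i])
  }
  legend("bottomleft", bty = "n", col = cols, lty = 1,
         legend = vapply(x$datasets, function(d)
           contrast_label(d$contrast), character(1)))
  invisible(x)
}
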