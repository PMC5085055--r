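#' Configuration of the inverse material identification
#'
#' @param c10_bounds,c01_bounds Lower/upper search bounds in MPa.
#' @param n_initial_samples Size of the initial Latin-hypercube design
#'   (drawn in log-space of the parameters, since plausible moduli span a
#'   decade).
#' @param max_fe_evaluations Budget of forward finite-element evaluations.
#' @param ga_population,ga_generations Genetic-algorithm size run on the
#'   surrogate each adaptive iteration.
#' @param merit_tolerance Stop when an FE-verified merit falls below this.
#' @param rng_seed Integer seed making the whole loop reproducible.
#' @return Object of class `inverse_config`.
#' @export
inverse_config <- function(c10_bounds = c(0.005, 2.0),
                           c01_bounds = c(0.005, 2.0),
                           n_initial_samples = 20L,
                           max_fe_evaluations = 80L,
                           ga_population = 40L,
                           ga_generations = 50L,
                           merit_tolerance = 0.005,
                           rng_seed = 1L) {
  stopifnot(all(c10_bounds > 0), all(c01_bounds > 0),
            c10_bounds[1L] < c10_bounds[2L], c01_bounds[1L] < c01_bounds[2L],
            n_initial_samples >= 1L, max_fe_evaluations >= 1L,
            ga_population >= 1L, ga_generations >= 1L, merit_tolerance > 0)
  structure(list(c10_bounds = c10_bounds, c01_bounds = c01_bounds,
                 n_initial_samples = as.integer(n_initial_samples),
                 max_fe_evaluations = as.integer(max_fe_evaluations),
                 ga_population = as.integer(ga_population),
                 ga_generations = as.integer(ga_generations),
                 merit_tolerance = merit_tolerance,
                 rng_seed = as.integer(rng_seed)),
            class = "inverse_config")
}

## ---------------------------------------------------------------------------
## Ordinary Kriging surrogate
## ---------------------------------------------------------------------------

#' Fit an ordinary Kriging (Gaussian-process) surrogate
#'
#' Interpolating ordinary Kriging with a Gaussian correlation kernel and a
#' small numerical nugget. The common correlation length is selected by
#' maximizing the concentrated log-likelihood over a fixed grid, which keeps
#' the fit deterministic. Duplicate sample locations are collapsed (keeping
#' the last value) before fitting.
#'
#' @param X Numeric matrix of sample locations (n x d).
#' @param y Responses at the samples.
#' @param nugget Diagonal regularization of the correlation matrix.
#' @return Object of class `kriging_surrogate` with a `$predict(Xnew)`
#'   function (mean prediction), `$predict_var(Xnew)` (predictive variance)
#'   and `$loo_rmse`, the leave-one-out root-mean-square prediction error.
#' @export
surrogate_fit <- function(X, y, nugget = 1e-8) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  # collapse duplicates
  key <- apply(round(X, 12L), 1L, paste, collapse = "\r")
  keep <- !duplicated(key, fromLast = TRUE)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(X)
  if (n < 6L) stop("surrogate_fit requires at least 6 distinct samples", call. = FALSE)

  if (stats::sd(y) == 0) {
    const <- y[1L]
    return(structure(list(
      predict = function(Xnew) rep(const, nrow(as.matrix(Xnew))),
      predict_var = function(Xnew) rep(0, nrow(as.matrix(Xnew))),
      loo_rmse = 0, theta = NA_real_, X = X, y = y),
      class = "kriging_surrogate"))
  }

  D2 <- as.matrix(stats::dist(X))^2
  ones <- rep(1, n)
  best <- NULL
  for (theta in 10^seq(-1.5, 0.7, length.out = 26L)) {
    R <- exp(-D2 / (2 * theta^2)) + diag(nugget, n)
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) next
    Ri_y <- backsolve(ch, forwardsolve(t(ch), y))
    Ri_1 <- backsolve(ch, forwardsolve(t(ch), ones))
    mu <- sum(Ri_y) / sum(Ri_1)
    resid <- y - mu
    Ri_r <- backsolve(ch, forwardsolve(t(ch), resid))
    s2 <- sum(resid * Ri_r) / n
    if (s2 <= 0) next
    ll <- -0.5 * (n * log(s2) + 2 * sum(log(diag(ch))))
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, theta = theta, ch = ch, mu = mu, s2 = s2,
                   Ri_r = Ri_r, Ri_1 = Ri_1)
    }
  }
  if (is.null(best)) stop("Kriging correlation matrix could not be factorized", call. = FALSE)

  theta <- best$theta
  ch <- best$ch
  mu <- best$mu
  Ri_r <- best$Ri_r

  Ri <- chol2inv(ch)
  # closed-form leave-one-out residuals of the (simple-Kriging) interpolator
  loo <- (Ri %*% (y - mu)) / diag(Ri)
  loo_rmse <- sqrt(mean(loo^2))

  cross <- function(Xnew) {
    Xnew <- as.matrix(Xnew)
    d2 <- outer(rowSums(Xnew^2), rowSums(X^2), `+`) - 2 * Xnew %*% t(X)
    k <- exp(-pmax(d2, 0) / (2 * theta^2))
    # the nugget belongs to the process covariance, so prediction at a
    # sample location reproduces the sample (interpolating Kriging)
    k[d2 < 1e-18] <- k[d2 < 1e-18] + nugget
    k
  }
  predict_mean <- function(Xnew) as.vector(mu + cross(Xnew) %*% Ri_r)
  predict_var <- function(Xnew) {
    r <- cross(Xnew)
    rRi <- r %*% Ri
    v <- best$s2 * (1 + nugget - rowSums(rRi * r) +
                    (1 - as.vector(rRi %*% rep(1, nrow(X))))^2 / sum(best$Ri_1))
    pmax(as.vector(v), 0)
  }
  structure(list(predict = predict_mean, predict_var = predict_var,
                 loo_rmse = loo_rmse, theta = theta, X = X, y = y),
            class = "kriging_surrogate")
}

#' @export
print.kriging_surrogate <- function(x, ...) {
  cat(sprintf("Kriging surrogate: %d samples, correlation length %.3g, LOO RMSE %.4g\n",
              nrow(x$X), x$theta, x$loo_rmse))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Real-coded genetic algorithm on the unit box
## ---------------------------------------------------------------------------

# minimizes fn over [0,1]^d; deterministic under the caller's RNG state
ga_minimize <- function(fn, d, pop_size = 40L, generations = 50L,
                        mutate_sd = 0.08, mutate_prob = 0.25, elite = 2L) {
  pop <- matrix(stats::runif(pop_size * d), pop_size, d)
  fit <- fn(pop)
  for (gen in seq_len(generations)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(elite)], , drop = FALSE]
    while (nrow(newpop) < pop_size) {
      # binary tournaments
      pick <- function() {
        ij <- sample.int(pop_size, 2L)
        ij[which.min(fit[ij])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      # blend crossover (BLX-0.25)
      lo <- pmin(p1, p2); hi <- pmax(p1, p2)
      spread <- 0.25 * (hi - lo)
      child <- stats::runif(d, lo - spread, hi + spread)
      mut <- stats::runif(d) < mutate_prob
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, mutate_sd)
      newpop <- rbind(newpop, pmin(pmax(child, 0), 1))
    }
    pop <- newpop
    fit <- fn(pop)
  }
  best <- which.min(fit)
  list(x = pop[best, ], value = fit[best])
}

## ---------------------------------------------------------------------------
## The inverse loop
## ---------------------------------------------------------------------------

#' Fit Mooney-Rivlin parameters to measured deformation metrics
#'
#' The adaptive inverse-identification loop: (1) evaluate the merit function
#' by full forward finite-element simulation at an initial Latin-hypercube
#' design over (C10, C01); (2) fit an ordinary Kriging surrogate of the
#' (log-transformed) merit; (3) run a genetic algorithm on the surrogate;
#' (4) verify the GA optimum by a forward FE run and add it to the sample
#' set; repeat from (2) until an FE-verified merit falls below
#' `merit_tolerance` or the FE budget is exhausted. When the GA proposes a
#' point indistinguishable from an existing sample, the highest-predictive-
#' variance candidate is evaluated instead, so the loop keeps exploring.
#' Forward solves that fail to converge are logged and penalized with a
#' large finite merit rather than aborting the fit.
#'
#' @param measured `deformation_metrics` of the measurement to fit.
#' @param geom [cornea_geometry()] of the measured cornea.
#' @param iop Intraocular pressure in mmHg.
#' @param load [airpuff_load()] used in the measurement.
#' @param cfg An [inverse_config()].
#' @param mesh Optional prebuilt mesh (otherwise the default 4 x 100 grid).
#' @return An `inverse_result`: fitted [mooney_rivlin()] parameters,
#'   achieved merit (recomputed by a final audit FE run at the fitted
#'   point), `converged` flag (achieved merit within 10x tolerance), the
#'   full evaluation log, and the surrogate leave-one-out error.
#' @export
fit_material <- function(measured, geom, iop = 15, load = airpuff_load(),
                         cfg = inverse_config(), mesh = NULL) {
  stopifnot(inherits(measured, "deformation_metrics"),
            inherits(cfg, "inverse_config"))
  if (is.null(mesh)) mesh <- build_mesh(geom)
  cache <- new.env(parent = emptyenv())

  lb <- log10(c(cfg$c10_bounds[1L], cfg$c01_bounds[1L]))
  ub <- log10(c(cfg$c10_bounds[2L], cfg$c01_bounds[2L]))
  to_params <- function(x01) 10^(lb + (ub - lb) * x01)
  penalty_merit <- 1e3

  log_pts <- list()
  fe_merit <- function(x01) {
    p <- to_params(matrix(x01, 1L))
    mat <- mooney_rivlin(p[1L], p[2L])
    m <- tryCatch({
      rec <- simulate_airpuff(geom, mat, iop = iop, load = load,
                              frames = "hc", mesh = mesh, cache = cache)
      merit(measured, compute_metrics(rec))
    }, ap_nonconvergence = function(e) penalty_merit)
    log_pts[[length(log_pts) + 1L]] <<- list(c10 = p[1L], c01 = p[2L], merit = m)
    m
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$rng_seed)

  n0 <- max(cfg$n_initial_samples, 6L)
  X <- as.matrix(lhs::randomLHS(n0, 2L))
  y <- apply(X, 1L, fe_merit)

  loo <- NA_real_
  while (min(y) > cfg$merit_tolerance && nrow(X) < cfg$max_fe_evaluations) {
    ytr <- log(pmin(y, penalty_merit) + 1e-4)
    sg <- tryCatch(surrogate_fit(X, ytr), error = function(e) NULL)
    if (is.null(sg)) break
    loo <- sg$loo_rmse
    ga <- ga_minimize(function(P) sg$predict(P), d = 2L,
                      pop_size = cfg$ga_population,
                      generations = cfg$ga_generations)
    xnew <- ga$x
    dmin <- min(sqrt(rowSums((X - matrix(xnew, nrow(X), 2L, byrow = TRUE))^2)))
    if (dmin < 1e-3) {
      # exploration fallback: maximize predictive variance over a seeded cloud
      cand <- matrix(stats::runif(1024L), 512L, 2L)
      xnew <- cand[which.max(sg$predict_var(cand)), ]
    }
    X <- rbind(X, xnew)
    y <- c(y, fe_merit(xnew))
  }

  best <- which.min(y)
  p_best <- to_params(X[best, , drop = FALSE])
  mat_best <- mooney_rivlin(p_best[1L], p_best[2L])
  # audit: recompute the merit by one final forward run at the fitted point
  achieved <- fe_merit(X[best, ])

  structure(list(
    params = mat_best,
    merit = achieved,
    converged = achieved <= 10 * cfg$merit_tolerance,
    n_fe_evaluations = length(log_pts),
    evaluations = do.call(rbind, lapply(log_pts, as.data.frame)),
    surrogate_loo_rmse = loo,
    config = cfg),
    class = "inverse_result")
}

#' @export
print.inverse_result <- function(x, ...) {
  cat(sprintf("inverse fit: C10 = %.4f MPa, C01 = %.4f MPa (equivalent E = %.4f MPa)\n",
              x$params$c10, x$params$c01, small_strain_modulus(x$params)))
  cat(sprintf("  merit %.5f, converged = %s, %d FE evaluations, surrogate LOO RMSE %.3g\n",
              x$merit, x$converged, x$n_fe_evaluations, x$surrogate_loo_rmse))
  invisible(x)
}
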