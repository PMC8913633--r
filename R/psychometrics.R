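# Rotation-nulling psychophysics: trial scheduling, simulated observers,
# cumulative-Gaussian psychometric fitting and the bias-corrected illusion
# velocity. CCW is the positive direction throughout; velocities in deg/s.

#' The rotation-velocity grid of the nulling paradigm
#'
#' An arithmetic grid inclusive of both endpoints, rounded to one decimal to
#' avoid floating-grid drift; the default spans -2.1 to +2.1 deg/s in steps
#' of 0.3 (15 velocities).
#'
#' @param vMin,vMax endpoints in deg/s.
#' @param step grid step in deg/s.
#' @return numeric vector of velocities.
#' @export
velocityGrid <- function(vMin = -2.1, vMax = 2.1, step = 0.3) {
  stopifnot(step > 0, vMax >= vMin)
  round(seq(vMin, vMax + step / 100, by = step), 1)
}

#' Build a randomized trial schedule
#'
#' Every (stimulus type, velocity) pair occurs exactly `reps` times; the
#' presentation order is a seeded random permutation, so the same seed gives
#' the same schedule.
#'
#' @param velocities rotation velocities (deg/s, CCW positive).
#' @param types stimulus variants.
#' @param reps repetitions per condition (default 30).
#' @param seed integer seed for the permutation.
#' @return data.frame with `trial_index`, `stimulus_type`,
#'   `velocity_deg_per_s`, `rep_index`.
#' @export
makeSchedule <- function(velocities = velocityGrid(),
                         types = c("original", "reversed"), reps = 30L,
                         seed = 1L) {
  grid <- expand.grid(stimulus_type = types,
                      velocity_deg_per_s = velocities,
                      rep_index = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ord <- .withSeed(seed, sample.int(nrow(grid)))
  out <- grid[ord, , drop = FALSE]
  out <- cbind(trial_index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Simulate a two-alternative observer on a schedule
#'
#' On each trial the observer responds CCW with probability
#' `(1 - lapse) * pnorm((v - mu) / sigma) + lapse / 2`, where `mu` may be a
#' single value or a named vector with one entry per stimulus type (an
#' observer whose illusion shifts the psychometric function differently for
#' the original and the reversed design).
#'
#' @param trueMu psychometric threshold(s) in deg/s.
#' @param trueSigma psychometric slope parameter (> 0).
#' @param schedule a [makeSchedule()] data.frame.
#' @param seed integer seed for the binary responses.
#' @param lapse lapse rate in `[0, 1]` (default 0).
#' @return the schedule with an added `response` column (`"CCW"`/`"CW"`).
#' @seealso [responseTable()] to aggregate responses per condition.
#' @export
simulateObserver <- function(trueMu, trueSigma, schedule, seed = 1L,
                             lapse = 0) {
  stopifnot(trueSigma > 0, lapse >= 0, lapse <= 1)
  v <- schedule$velocity_deg_per_s
  mu <- if (length(trueMu) == 1L && is.null(names(trueMu)))
    rep(trueMu, nrow(schedule))
  else {
    if (!all(schedule$stimulus_type %in% names(trueMu)))
      stop("trueMu must be named with every stimulus type", call. = FALSE)
    unname(trueMu[schedule$stimulus_type])
  }
  p <- (1 - lapse) * pnorm((v - mu) / trueSigma) + lapse / 2
  ccw <- .withSeed(seed, rbinom(nrow(schedule), 1L, p))
  out <- schedule
  out$response <- ifelse(ccw == 1L, "CCW", "CW")
  out
}

#' Aggregate trial responses per (type, velocity) condition
#'
#' @param responses a data.frame with `stimulus_type`, `velocity_deg_per_s`
#'   and `response` (`"CCW"`/`"CW"`) columns, e.g. from [simulateObserver()].
#' @return data.frame with `stimulus_type`, `velocity_deg_per_s`,
#'   `n_presented`, `n_ccw`.
#' @export
responseTable <- function(responses) {
  agg <- aggregate(cbind(n_presented = rep(1L, nrow(responses)),
                         n_ccw = responses$response == "CCW"),
                   by = list(stimulus_type = responses$stimulus_type,
                             velocity_deg_per_s = responses$velocity_deg_per_s),
                   FUN = sum)
  agg[order(agg$stimulus_type, agg$velocity_deg_per_s), , drop = FALSE]
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Least-squares fit of `P(CCW | v) = pnorm((v - mu) / sigma)` to the
#' observed CCW proportions (unweighted, on the proportions themselves).
#' Initialisation: `mu0` is the velocity whose observed proportion is
#' closest to 0.5 and `sigma0` is half the velocity span; optimisation uses
#' Levenberg–Marquardt with a fallback to Nelder–Mead. A maximum-likelihood
#' binomial fit is available via `method = "ml"`.
#'
#' The rotation-cancellation velocity — the physical rotation at which CW
#' and CCW responses are equally likely — equals the fitted `mu`.
#'
#' @param responses data.frame for a single stimulus type with columns
#'   `velocity_deg_per_s` (or `velocity`), `n_presented`, `n_ccw`.
#' @param method `"ls"` (least squares, the default) or `"ml"`.
#' @return a [PsychometricFit-class].
#' @export
fitPsychometric <- function(responses, method = c("ls", "ml")) {
  method <- match.arg(method)
  v <- responses$velocity_deg_per_s
  if (is.null(v)) v <- responses$velocity
  n <- responses$n_presented
  k <- responses$n_ccw
  if (length(unique(v)) < 3L)
    stop("need at least 3 distinct velocities to fit", call. = FALSE)
  if (any(k < 0 | k > n)) stop("n_ccw must lie in [0, n_presented]", call. = FALSE)
  p <- k / n
  if (all(p == 0) || all(p == 1))
    stop("psychometric function is not identifiable: all responses are ",
         if (all(p == 0)) "CW" else "CCW",
         "; extend the velocity range so both responses occur", call. = FALSE)

  mu0 <- v[which.min(abs(p - 0.5))]
  sigma0 <- max(diff(range(v)) / 2, 1e-3)

  if (method == "ls") {
    fit <- tryCatch({
      m <- minpack.lm::nlsLM(p ~ pnorm((v - mu) / sigma),
                             start = list(mu = mu0, sigma = sigma0),
                             lower = c(mu = -Inf, sigma = 1e-6),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      cf <- stats::coef(m)
      list(mu = unname(cf["mu"]), sigma = unname(cf["sigma"]))
    }, error = function(e) NULL)
    if (is.null(fit)) {
      obj <- function(par) sum((p - pnorm((v - par[1]) / max(par[2], 1e-6)))^2)
      op <- optim(c(mu0, sigma0), obj, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
      fit <- list(mu = op$par[1], sigma = max(op$par[2], 1e-6))
    }
  } else {
    nll <- function(par) {
      pr <- pmin(pmax(pnorm((v - par[1]) / max(par[2], 1e-6)), 1e-9), 1 - 1e-9)
      -sum(k * log(pr) + (n - k) * log(1 - pr))
    }
    op <- optim(c(mu0, sigma0), nll, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-12))
    fit <- list(mu = op$par[1], sigma = max(op$par[2], 1e-6))
  }
  fitted <- pnorm((v - fit$mu) / fit$sigma)
  new("PsychometricFit", mu = fit$mu, sigma = fit$sigma,
      rss = sum((p - fitted)^2), cancellationVelocity = fit$mu,
      data = data.frame(velocity = v, n = n, p = p, fitted = fitted))
}

#' Bias-corrected illusion velocity from an original/reversed fit pair
#'
#' Combines the rotation-cancellation velocities of the two mirrored designs
#' as `(vReversed - vOriginal) / 2` (deg/s, CCW positive): mirroring reverses
#' the illusory rotation but not the observer's response bias, so the
#' difference cancels the bias.
#'
#' @param fitOriginal,fitReversed [PsychometricFit-class] objects for the
#'   original and left-right reversed stimulus.
#' @return an [IllusionVelocity-class].
#' @export
illusionVelocity <- function(fitOriginal, fitReversed) {
  vo <- if (is(fitOriginal, "PsychometricFit"))
    fitOriginal@cancellationVelocity else as.numeric(fitOriginal)
  vr <- if (is(fitReversed, "PsychometricFit"))
    fitReversed@cancellationVelocity else as.numeric(fitReversed)
  new("IllusionVelocity", vOriginal = vo, vReversed = vr,
      combined = (vr - vo) / 2)
}

#' Export a psychometric fit as a list (suitable for JSON)
#'
#' @param fit a [PsychometricFit-class].
#' @return list with `mu`, `sigma`, `rss`, `cancellation_velocity`.
#' @export
fitAsList <- function(fit) {
  list(mu = fit@mu, sigma = fit@sigma, rss = fit@rss,
       cancellation_velocity = fit@cancellationVelocity)
}

setMethod("show", "PsychometricFit", function(object) {
  cat(sprintf("PsychometricFit: mu = %.3f deg/s, sigma = %.3f, rss = %.4g\n",
              object@mu, object@sigma, object@rss))
})

setMethod("show", "IllusionVelocity", function(object) {
  cat(sprintf("IllusionVelocity: original %.3f, reversed %.3f, combined %.3f deg/s\n",
              object@vOriginal, object@vReversed, object@combined))
})
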