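#' Build a cumulative confidence ROC
#'
#' Pools the six-point confidence levels of match (target) and nonmatch
#' (lure) trials into five cumulative (false alarm, hit) coordinates: point
#' *i* is the proportion of lures (x) and targets (y) answered at confidence
#' level *i* or more confidently "old". The sixth point, cumulating all
#' levels, is (1, 1) by construction and is excluded from fitting.
#'
#' @param records Tibble of response records with at least `trial_type`
#'   (`"match"`/`"nonmatch"`) and `level` (1..6) columns, as produced by
#'   [simulate_responses()].
#' @param direction `"old_first"` (default) cumulates from level 1,
#'   "absolutely certain old", outward — the direction in which the DPSD
#'   model equations accumulate. `"new_first"` reverses the coding first
#'   (level 6 treated as most-confident old), for data coded the other way.
#' @return A `roc_points` object: list with `points` (tibble: level, fa,
#'   hit), `n_target`, `n_lure`.
#' @examples
#' rec <- tibble::tibble(
#'   trial_type = rep(c("match", "nonmatch"), each = 6),
#'   level = c(1, 1, 2, 3, 4, 6, 3, 4, 5, 6, 6, 6)
#' )
#' build_roc(rec)$points
#' @export
build_roc <- function(records, direction = c("old_first", "new_first")) {
  direction <- match.arg(direction)
  stopifnot(all(c("trial_type", "level") %in% names(records)))
  if (!all(records$level %in% 1:6)) abort("levels must be integers in 1..6")
  lev <- records$level
  if (direction == "new_first") lev <- 7L - lev
  t_lev <- lev[records$trial_type == "match"]
  l_lev <- lev[records$trial_type == "nonmatch"]
  if (length(t_lev) == 0L || length(l_lev) == 0L) {
    abort(sprintf("need both trial types: %d match and %d nonmatch records",
                  length(t_lev), length(l_lev)))
  }
  pts <- tibble(
    level = 1:5,
    fa = map_dbl(1:5, function(i) mean(l_lev <= i)),
    hit = map_dbl(1:5, function(i) mean(t_lev <= i))
  )
  structure(list(points = pts, n_target = length(t_lev),
                 n_lure = length(l_lev)),
            class = "roc_points")
}

#' @export
print.roc_points <- function(x, ...) {
  cat(sprintf("<roc_points: %d targets, %d lures>\n", x$n_target, x$n_lure))
  print(x$points)
  invisible(x)
}

#' DPSD model prediction for one or more criteria
#'
#' Cumulative rates under the dual-process signal-detection model with lure
#' recollection fixed at 0 and unit familiarity SD:
#' `p_fa = Phi(-c)` and `p_hit = R + (1 - R) * Phi(F - c)`.
#'
#' @param R Recollection probability, in `[0, 1]`.
#' @param F Familiarity sensitivity (d-prime), `>= 0`.
#' @param c Criterion (vectorised).
#' @return Tibble with columns `c`, `fa`, `hit`.
#' @examples
#' dpsd_predict(0.3, 1.0, 0)  # fa 0.5, hit 0.3 + 0.7 * pnorm(1)
#' @export
dpsd_predict <- function(R, F, c) {
  stopifnot(R >= 0, R <= 1)
  tibble(c = c, fa = pnorm(-c), hit = R + (1 - R) * pnorm(F - c))
}

dpsd_sse <- function(R, F, crit, fa, hit) {
  sum((fa - pnorm(-crit))^2 + (hit - (R + (1 - R) * pnorm(F - crit)))^2)
}

# parameter packing: theta = (R, F, c1, d2..d5); criteria = c1 - cumsum(0,d)
unpack_criteria <- function(theta) theta[3] - cumsum(c(0, theta[4:7]))

#' Fit the DPSD model to a confidence ROC by least squares
#'
#' Estimates recollection `R`, familiarity `F` and five ordered criteria by
#' minimizing the summed squared residuals of the five ROC points in *both*
#' coordinates (abscissa and ordinate). `R` is first fitted unconstrained on
#' `[-1, 1]`; if the optimum is negative, `R` is fixed to 0 (a negative
#' recollection score has no meaning beyond zero recollection) and the model
#' refit for `F` and the criteria, with `refit_applied` flagged. `F` is
#' bounded below at 0. Criteria ordering (strict to liberal, decreasing) is
#' enforced by a monotone reparameterization (base criterion plus positive
#' decrements); optimization is bounded quasi-Newton from multiple starts,
#' with criteria initialised from the probit transform of the observed
#' false-alarm rates.
#'
#' @param roc An `roc_points` object, or a records tibble (passed through
#'   [build_roc()]).
#' @param ... Passed to [build_roc()] when `roc` is a records tibble.
#' @return A `dpsd_fit` object with elements `R`, `F`, `criteria`, `sse`,
#'   `refit_applied`, `degenerate`, `roc`, `n_target`, `n_lure`.
#' @examples
#' pts <- dpsd_predict(0.3, 1.0, c(1.2, 0.6, 0, -0.6, -1.2))
#' roc <- structure(list(points = tibble::tibble(level = 1:5, fa = pts$fa,
#'                                               hit = pts$hit),
#'                       n_target = 100, n_lure = 100), class = "roc_points")
#' fit <- fit_dpsd(roc)
#' round(c(fit$R, fit$F), 3)
#' @export
fit_dpsd <- function(roc, ...) {
  if (!inherits(roc, "roc_points")) roc <- build_roc(roc, ...)
  pts <- arrange(roc$points, .data$fa, .data$hit)
  fa <- pts$fa
  hit <- pts$hit

  degenerate <- all(abs(fa - fa[1]) < 1e-12) && all(abs(hit - hit[1]) < 1e-12)
  if (degenerate) {
    warning("degenerate ROC: all five points identical; criteria collapsed",
            call. = FALSE)
  }

  # probit start for criteria from observed FA rates, kept strictly decreasing
  n_l <- max(roc$n_lure, 10)
  fa_cl <- pmin(pmax(fa, 1 / (2 * n_l)), 1 - 1 / (2 * n_l))
  c0 <- -qnorm(fa_cl)
  d0 <- pmax(-diff(c0), 0.05)

  lower <- c(-1, 0, -6, rep(1e-6, 4))
  upper <- c(1, 8, 6, rep(8, 4))

  # analytic gradient of the two-coordinate SSE w.r.t. (R, F, c1, d2..d5)
  grad_theta <- function(theta) {
    R <- theta[1]
    F <- theta[2]
    crit <- unpack_criteria(theta)
    e_fa <- pnorm(-crit) - fa
    p_hit <- R + (1 - R) * pnorm(F - crit)
    e_hit <- p_hit - hit
    phi_c <- stats::dnorm(-crit)
    phi_f <- stats::dnorm(F - crit)
    gR <- 2 * sum(e_hit * (1 - pnorm(F - crit)))
    gF <- 2 * sum(e_hit * (1 - R) * phi_f)
    gc <- 2 * (-e_fa * phi_c - e_hit * (1 - R) * phi_f)  # d/dc_i
    # c_i = c1 - sum_{j<=i} d_j  =>  dc_i/dc1 = 1, dc_i/dd_j = -1[j <= i]
    g1 <- sum(gc)
    gd <- -rev(cumsum(rev(gc)))[-1]
    c(gR, gF, g1, gd)
  }

  fit_from <- function(start) {
    obj <- function(theta) {
      dpsd_sse(theta[1], theta[2], unpack_criteria(theta), fa, hit)
    }
    optim(start, obj, gr = grad_theta, method = "L-BFGS-B",
          lower = lower, upper = upper,
          control = list(maxit = 500, factr = 1e4))
  }
  # refit path: R fixed at 0, only (F, c1, d2..d5) free
  fit_R0 <- function(start) {
    obj <- function(th) {
      dpsd_sse(0, th[1], unpack_criteria(c(0, th)), fa, hit)
    }
    optim(start, obj, gr = function(th) grad_theta(c(0, th))[-1],
          method = "L-BFGS-B", lower = lower[-1], upper = upper[-1],
          control = list(maxit = 500, factr = 1e4))
  }

  starts <- purrr::pmap(
    expand.grid(R = c(0, 0.25, 0.5), F = c(0.5, 1.5)),
    function(R, F) c(R, F, c0[1], d0)
  )
  fits <- purrr::map(starts, fit_from)
  best <- fits[[which.min(map_dbl(fits, "value"))]]

  refit_applied <- FALSE
  if (best$par[1] < 0) {
    refit_applied <- TRUE
    fits0 <- purrr::map(c(0.5, 1.5), function(F) fit_R0(c(F, c0[1], d0)))
    b0 <- fits0[[which.min(map_dbl(fits0, "value"))]]
    best <- list(par = c(0, b0$par), value = b0$value,
                 convergence = b0$convergence)
  }

  structure(
    list(R = unname(best$par[1]), F = unname(best$par[2]),
         criteria = unname(unpack_criteria(best$par)),
         sse = best$value, refit_applied = refit_applied,
         degenerate = degenerate, convergence = best$convergence,
         roc = roc, n_target = roc$n_target, n_lure = roc$n_lure),
    class = "dpsd_fit"
  )
}

#' @export
print.dpsd_fit <- function(x, ...) {
  cat(sprintf(
    "<dpsd_fit: R = %.3f, F = %.3f, sse = %.3g%s>\n", x$R, x$F, x$sse,
    if (x$refit_applied) ", R refit to 0" else ""
  ))
  cat(" criteria:", paste(sprintf("%.3f", x$criteria), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn fit_dpsd One row per parameter (R, F, c1..c5).
#' @param x A `dpsd_fit`.
#' @exportS3Method generics::tidy
tidy.dpsd_fit <- function(x, ...) {
  tibble(term = c("R", "F", paste0("c", 1:5)),
         estimate = c(x$R, x$F, x$criteria))
}

#' @describeIn fit_dpsd One-row model summary.
#' @exportS3Method generics::glance
glance.dpsd_fit <- function(x, ...) {
  tibble(R = x$R, F = x$F, sse = x$sse, refit_applied = x$refit_applied,
         degenerate = x$degenerate, n_target = x$n_target,
         n_lure = x$n_lure)
}

#' @describeIn fit_dpsd Observed ROC points with the fitted DPSD curve.
#' @param object A `dpsd_fit`.
#' @exportS3Method ggplot2::autoplot
autoplot.dpsd_fit <- function(object, ...) {
  curve <- dpsd_predict(object$R, object$F, seq(-3, 3, length.out = 200))
  ggplot(object$roc$points, aes(x = .data$fa, y = .data$hit)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    geom_path(data = curve, colour = "steelblue") +
    geom_point(size = 2) +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "Cumulative false-alarm rate", y = "Cumulative hit rate",
         title = sprintf("DPSD fit: R = %.2f, F = %.2f", object$R, object$F)) +
    theme_minimal()
}

#' @describeIn build_roc Plot the cumulative ROC points.
#' @param object An `roc_points` object.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_points <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fa, y = .data$hit)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    geom_point(size = 2) +
    geom_path() +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "Cumulative false-alarm rate", y = "Cumulative hit rate") +
    theme_minimal()
}
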