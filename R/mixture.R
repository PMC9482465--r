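# Two-phase mixture decomposition: express an observed diffraction curve as
# a non-negative combination of theoretical gas-phase and liquid-phase basis
# curves plus a smooth polynomial background, and report the fractional
# contributions. This is the package's fitted-model object.

#' Fit gas/liquid fractional contributions to a diffraction curve
#'
#' Least squares of
#' \deqn{I_{obs}(s) \approx c_g I_{gas}(s) + c_l I_{liq}(s) + \sum_j b_j s^j}
#' over \code{s_range}, with \eqn{c_g, c_l \ge 0} (physical contributions;
#' the background coefficients are unconstrained). The comparison is done on
#' \eqn{I \times s^2} (the display/weighting convention that emphasizes the
#' discriminating liquid ring over the steep small-angle region). Reported
#' percentages are intensity fractions \eqn{100 c_i / (c_g + c_l)}; they are
#' invariant under rescaling of the observed curve. With per-molecule
#' normalized bases they equal molecular fractions.
#'
#' Non-negativity is solved exactly by enumerating the active sets of the two
#' constrained coefficients. Near-collinear bases are rejected.
#'
#' @param observed A \code{diffraction_curve} (e.g. from
#'   \code{radial_average}).
#' @param gas_basis,liquid_basis Theoretical basis \code{diffraction_curve}s.
#'   They are linearly interpolated onto the observed grid, so the grids need
#'   not match, but must cover \code{s_range}.
#' @param s_range Length-2 fit interval in inverse Angstrom (default
#'   \code{c(0.8, 8)}).
#' @param background_order Polynomial background order (default 2); use
#'   higher orders when the physical background is far from quadratic.
#' @param nonneg Enforce \eqn{c_g, c_l \ge 0} (default TRUE); FALSE gives the
#'   unconstrained diagnostic fit.
#' @param delay Optional delay label (microseconds, free text) carried into
#'   the result.
#' @param condition_limit Reject fits whose basis condition number (after
#'   projecting out the background) exceeds this.
#' @return Object of class \code{mixture_fit} with components
#'   \code{liquid_percent}, \code{gas_percent}, \code{coefficients} (named:
#'   gas, liquid, bg0..), \code{residual_rms}, \code{s_range}, \code{delay},
#'   and the fit arrays. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{fitted}, \code{residuals}, \code{predict}, \code{plot}.
#' @examples
#' s <- s_grid(8)
#' gas <- total_intensity(build_glycerol(), s)
#' liq <- diffraction_curve(s, gas$values * (1 + 0.3 * exp(-(s - 1.6)^2)))
#' obs <- diffraction_curve(s, 0.6 * gas$values + 0.4 * liq$values)
#' fit <- fit_mixture(obs, gas, liq, s_range = c(0.8, 7.5))
#' coef(fit)
#' @export
fit_mixture <- function(observed, gas_basis, liquid_basis,
                        s_range = c(0.8, 8), background_order = 2L,
                        nonneg = TRUE, delay = NA_character_,
                        condition_limit = 1e8) {
  stopifnot(inherits(observed, "diffraction_curve"),
            inherits(gas_basis, "diffraction_curve"),
            inherits(liquid_basis, "diffraction_curve"),
            length(s_range) == 2L, s_range[1L] < s_range[2L])
  sel <- observed$s >= s_range[1L] & observed$s <= s_range[2L]
  if (!any(sel)) stop("empty s_range: no observed points in the interval")
  s <- observed$s[sel]
  if (min(s) < min(gas_basis$s) - 1e-9 || max(s) > max(gas_basis$s) + 1e-9 ||
      min(s) < min(liquid_basis$s) - 1e-9 || max(s) > max(liquid_basis$s) + 1e-9)
    stop("basis curves do not cover the fit range")
  w <- s^2
  y <- observed$values[sel] * w
  g <- stats::approx(gas_basis$s, gas_basis$values, xout = s)$y * w
  l <- stats::approx(liquid_basis$s, liquid_basis$values, xout = s)$y * w
  background_order <- as.integer(background_order)
  if (background_order < 0L) stop("background_order must be >= 0")
  B <- outer(s, 0:background_order, "^") * w

  # collinearity check on the basis pair after projecting out the background
  qb <- qr.Q(qr(B))
  resid_b <- function(v) v - qb %*% crossprod(qb, v)
  gp <- resid_b(g); lp <- resid_b(l)
  sv <- svd(cbind(gp, lp))$d
  cond <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  if (cond > condition_limit)
    stop(sprintf("degenerate bases: condition number %.3g after background projection",
                 cond))

  solve_ls <- function(cols) {
    X <- cbind(cols, B)
    stats::lm.fit(X, y)$coefficients
  }
  full <- solve_ls(cbind(gas = g, liquid = l))
  cg <- unname(full[1L]); cl <- unname(full[2L]); bg <- unname(full[-(1:2)])
  if (nonneg && (cg < 0 || cl < 0)) {
    # exact active-set enumeration for two constrained coefficients
    cand <- list()
    f_g <- solve_ls(cbind(gas = g))           # liquid clamped to zero
    if (f_g[1L] >= 0) cand <- c(cand, list(c(f_g[1L], 0, f_g[-1L])))
    f_l <- solve_ls(cbind(liquid = l))        # gas clamped to zero
    if (f_l[1L] >= 0) cand <- c(cand, list(c(0, f_l[1L], f_l[-1L])))
    f_0 <- stats::lm.fit(B, y)$coefficients   # both clamped
    cand <- c(cand, list(c(0, 0, f_0)))
    rss <- vapply(cand, function(cf) {
      sum((y - cbind(g, l, B) %*% cf)^2)
    }, numeric(1L))
    cf <- cand[[which.min(rss)]]
    cg <- unname(cf[1L]); cl <- unname(cf[2L]); bg <- unname(cf[-(1:2)])
  }
  coefs <- c(gas = unname(cg), liquid = unname(cl))
  names(bg) <- paste0("bg", 0:background_order)
  yhat <- as.vector(cbind(g, l, B) %*% c(cg, cl, bg))
  res <- y - yhat
  total <- cg + cl
  liquid_percent <- if (total > 0) 100 * cl / total else NA_real_
  gas_percent <- if (total > 0) 100 * cg / total else NA_real_
  structure(list(liquid_percent = liquid_percent, gas_percent = gas_percent,
                 coefficients = c(coefs, bg), residual_rms = sqrt(mean(res^2)),
                 s_range = s_range, delay = delay, nonneg = nonneg,
                 background_order = background_order, condition = cond,
                 s = s, weights = w, y = y, fitted_values = yhat,
                 basis = cbind(gas = g, liquid = l),
                 call = match.call()),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit>%s liquid %.1f%% / gas %.1f%% (residual RMS %.4g, s in [%g, %g])\n",
              if (is.na(x$delay)) "" else sprintf(" delay %s us:", x$delay),
              x$liquid_percent, x$gas_percent, x$residual_rms,
              x$s_range[1L], x$s_range[2L]))
  invisible(x)
}

#' @export
summary.mixture_fit <- function(object, ...) {
  cat("Two-phase mixture decomposition (weighted by s^2)\n")
  if (!is.na(object$delay)) cat(sprintf("  delay: %s us\n", object$delay))
  cat(sprintf("  fit range: [%g, %g] A^-1, %d points, background order %d\n",
              object$s_range[1L], object$s_range[2L], length(object$s),
              object$background_order))
  cat(sprintf("  liquid: %.2f%%   gas: %.2f%%\n",
              object$liquid_percent, object$gas_percent))
  cat(sprintf("  raw coefficients: gas %.4g, liquid %.4g\n",
              object$coefficients[["gas"]], object$coefficients[["liquid"]]))
  cat(sprintf("  residual RMS (weighted): %.4g; basis condition %.3g\n",
              object$residual_rms, object$condition))
  invisible(object)
}

#' @export
coef.mixture_fit <- function(object, ...) object$coefficients

#' @export
fitted.mixture_fit <- function(object, ...) object$fitted_values / object$weights

#' @export
residuals.mixture_fit <- function(object, ...) {
  (object$y - object$fitted_values) / object$weights
}

#' Predict the modelled intensity on a new grid
#' @param object A \code{mixture_fit}.
#' @param s New scattering-vector values (defaults to the fit grid). Must be
#'   inside the fitted range for the background polynomial to be meaningful.
#' @param ... Unused.
#' @return Predicted intensity (unweighted, same units as the observation).
#' @export
predict.mixture_fit <- function(object, s = object$s, ...) {
  gb <- stats::approx(object$s, object$basis[, "gas"] / object$weights,
                      xout = s)$y
  lb <- stats::approx(object$s, object$basis[, "liquid"] / object$weights,
                      xout = s)$y
  bg <- as.vector(outer(s, 0:object$background_order, "^") %*%
                    object$coefficients[-(1:2)])
  object$coefficients[["gas"]] * gb + object$coefficients[["liquid"]] * lb + bg
}

#' @export
plot.mixture_fit <- function(x, ...) {
  graphics::plot(x$s, x$y, type = "p", pch = 16, cex = 0.4,
                 xlab = expression(s ~ (ring(A)^-1)),
                 ylab = expression(I %*% s^2), ...)
  graphics::lines(x$s, x$fitted_values, col = 2, lwd = 2)
  graphics::legend("topright", legend = c("observed", "fit"),
                   col = c(1, 2), lty = c(NA, 1), pch = c(16, NA), bty = "n")
  invisible(x)
}

#' Mixture decomposition across a delay series
#'
#' Applies \code{fit_mixture} to each (delay, curve) observation and
#' tabulates the results in input order. A failing row is flagged and the
#' series continues.
#'
#' @param observations Named list of \code{diffraction_curve}s (names are
#'   delay labels), or a list of \code{list(delay =, curve =)} pairs.
#' @param gas_basis,liquid_basis Basis curves passed to \code{fit_mixture}.
#' @param ... Further arguments for \code{fit_mixture}.
#' @return A data frame of class \code{mixture_series} with columns
#'   \code{delay}, \code{liquid_percent}, \code{gas_percent},
#'   \code{residual_rms}, \code{ok}, \code{message}; the fits are attached as
#'   attribute \code{"fits"}.
#' @export
delay_series <- function(observations, gas_basis, liquid_basis, ...) {
  stopifnot(length(observations) >= 1L)
  if (!is.null(names(observations)) && all(nzchar(names(observations)))) {
    delays <- names(observations)
    curves <- observations
  } else {
    delays <- vapply(observations, function(o) as.character(o$delay), character(1L))
    curves <- lapply(observations, `[[`, "curve")
  }
  fits <- vector("list", length(curves))
  rows <- vector("list", length(curves))
  for (i in seq_along(curves)) {
    res <- tryCatch(
      fit_mixture(curves[[i]], gas_basis, liquid_basis, delay = delays[i], ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(delay = delays[i], liquid_percent = NA_real_,
                              gas_percent = NA_real_, residual_rms = NA_real_,
                              ok = FALSE, message = conditionMessage(res),
                              stringsAsFactors = FALSE)
    } else {
      fits[[i]] <- res
      rows[[i]] <- data.frame(delay = delays[i],
                              liquid_percent = res$liquid_percent,
                              gas_percent = res$gas_percent,
                              residual_rms = res$residual_rms,
                              ok = TRUE, message = "",
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("mixture_series", class(out))
  out
}

#' @export
print.mixture_series <- function(x, ...) {
  cat("Delay series mixture decomposition:\n")
  print.data.frame(x[, c("delay", "liquid_percent", "gas_percent",
                         "residual_rms", "ok")],
                   row.names = FALSE, digits = 4)
  invisible(x)
}
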