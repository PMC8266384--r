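#' Min-max normalise a titration signal to fractional binding
#'
#' `(v - min) / (max - min)`: a monotone affine-invariant rescaling of raw
#' per-capillary signal values onto `[0, 1]`, interpreted as fractional
#' binding once the extremes correspond to the unbound and saturated
#' plateaus.
#'
#' @param signal numeric vector of raw measurements (at least two distinct
#'   values).
#' @return Values in `[0, 1]` spanning the full range.
#' @export
normalize_curve <- function(signal) {
  if (!all(is.finite(signal))) stop("signal must be finite")
  rng <- range(signal)
  if (diff(rng) == 0) stop("constant signal: no dynamic range to normalise")
  (signal - rng[1]) / diff(rng)
}

#' Fraction of receptor bound under receptor depletion (tight binding)
#'
#' Solves the 1:1 binding equilibrium exactly for the bound fraction when
#' the labelled-receptor concentration `R` is comparable to the dissociation
#' constant, so free-ligand depletion cannot be neglected:
#' \deqn{f = \frac{(R + L + K_d) - \sqrt{(R + L + K_d)^2 - 4RL}}{2R}.}
#' Evaluated in the rationalised form `2L / (R + L + Kd + sqrt(...))`, which
#' avoids catastrophic cancellation for small `L`.
#'
#' @param L total ligand concentration(s), same units as `Kd` (e.g. nM);
#'   non-negative.
#' @param R total labelled-receptor concentration (positive).
#' @param Kd dissociation constant (positive).
#' @return Bound fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' tight_binding_fraction(1, 1, 1)  # (3 - sqrt(5)) / 2
tight_binding_fraction <- function(L, R, Kd) {
  if (any(L < 0) || R <= 0 || Kd <= 0)
    stop("require L >= 0, R > 0, Kd > 0")
  a <- R + L + Kd
  disc <- a^2 - 4 * R * L
  2 * L / (a + sqrt(pmax(disc, 0)))
}

#' Build a binding curve from a titration table
#'
#' @param ligand_conc_nM ligand concentrations in nM (positive; a 1:1 serial
#'   dilution in the published protocol); sorted ascending on ingestion.
#' @param signal raw signal or fractional binding, matched to
#'   `ligand_conc_nM`.
#' @param receptor_conc_nM total labelled-receptor (protein, not
#'   fluorophore) concentration in nM.
#' @return A data frame of class `"binding_curve"` with attribute
#'   `receptor_conc_nM`.
#' @export
binding_curve <- function(ligand_conc_nM, signal, receptor_conc_nM) {
  stopifnot(length(ligand_conc_nM) == length(signal))
  if (any(ligand_conc_nM <= 0)) stop("ligand concentrations must be positive")
  if (length(ligand_conc_nM) < 6)
    stop("need at least 6 titration points to fit")
  if (!is.numeric(receptor_conc_nM) || receptor_conc_nM <= 0)
    stop("receptor_conc_nM must be positive")
  ord <- order(ligand_conc_nM)
  out <- data.frame(ligand_conc_nM = ligand_conc_nM[ord],
                    signal = signal[ord])
  attr(out, "receptor_conc_nM") <- receptor_conc_nM
  class(out) <- c("binding_curve", "data.frame")
  out
}

#' Simulate a serial-dilution binding curve
#'
#' Generates a 1:1 (two-fold) serial dilution from `top_nM` downwards and
#' evaluates the tight-binding bound fraction, optionally with additive
#' Gaussian noise.
#'
#' @param kd_nM,receptor_conc_nM true dissociation constant and labelled
#'   receptor concentration, nM.
#' @param top_nM highest ligand concentration.
#' @param n_points number of dilution points.
#' @param noise_sd SD of additive Gaussian noise on the fraction scale.
#' @return A [binding_curve()].
#' @export
simulate_binding_curve <- function(kd_nM, receptor_conc_nM = 83.7,
                                   top_nM = 5000, n_points = 16,
                                   noise_sd = 0) {
  conc <- top_nM / 2^(seq_len(n_points) - 1)
  y <- tight_binding_fraction(conc, receptor_conc_nM, kd_nM)
  if (noise_sd > 0) y <- y + stats::rnorm(n_points, 0, noise_sd)
  binding_curve(conc, y, receptor_conc_nM)
}

#' Fit a dissociation constant with the tight-binding quadratic model
#'
#' Non-linear least squares of the receptor-depletion bound fraction against
#' normalized signal.  By default the only free parameter is `Kd` (the data
#' are taken as fractional binding); `free_amplitude = TRUE` adds an
#' amplitude and baseline (`signal = base + amp * fraction`), a useful
#' variant because min-max normalisation pins the endpoint observations.
#' The start value is the concentration at half-maximal signal; `Kd` is
#' bounded in `[1e-3, 1e6]` nM.  The standard error comes from the
#' linearised covariance at the optimum.
#'
#' @param curve a [binding_curve()], or a data frame with columns
#'   `ligand_conc_nM` and `signal`.
#' @param receptor_conc_nM labelled-receptor concentration; defaults to the
#'   curve's attribute.
#' @param free_amplitude fit amplitude and baseline as free parameters.
#' @param normalize min-max normalise the signal before fitting (default
#'   `TRUE` unless the signal already lies in `[0, 1]`).
#' @return An object of class `"tight_binding_fit"` with fields `kd_nM`,
#'   `kd_se_nM`, `residual_sse`, `converged`, plus the underlying `nls`
#'   fit; supports `print`, `summary`, `coef`, `predict`, `residuals` and
#'   `plot`.
#' @export
fit_kd <- function(curve, receptor_conc_nM = attr(curve, "receptor_conc_nM"),
                   free_amplitude = FALSE, normalize = NULL) {
  stopifnot(is.data.frame(curve),
            all(c("ligand_conc_nM", "signal") %in% names(curve)))
  if (is.null(receptor_conc_nM) || is.na(receptor_conc_nM))
    stop("receptor_conc_nM must be supplied")
  L <- curve$ligand_conc_nM
  y <- curve$signal
  # auto-normalise only when the signal is clearly not already fractional
  # (re-normalising near-fractional noisy data would bias the endpoints)
  if (is.null(normalize)) normalize <- min(y) < -0.5 || max(y) > 1.5
  if (normalize) y <- normalize_curve(y)

  # start Kd at the concentration of half-maximal signal
  half <- (min(y) + max(y)) / 2
  kd0 <- stats::approx(y, L, xout = half, ties = mean)$y
  if (!is.finite(kd0)) kd0 <- stats::median(L)
  kd0 <- min(max(kd0, 1e-3), 1e6)

  dat <- data.frame(L = L, y = y)
  fml <- if (free_amplitude)
    y ~ base + amp * tight_binding_fraction(L, receptor_conc_nM, Kd)
  else
    y ~ tight_binding_fraction(L, receptor_conc_nM, Kd)
  start <- if (free_amplitude) list(Kd = kd0, amp = 1, base = 0)
           else list(Kd = kd0)
  lower <- if (free_amplitude) c(1e-3, 1e-6, -Inf) else 1e-3
  upper <- if (free_amplitude) c(1e6, Inf, Inf) else 1e6

  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = dat, start = start, lower = lower,
                      upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(kd_nM = NA_real_, kd_se_nM = NA_real_,
                residual_sse = NA_real_, converged = FALSE,
                diagnostics = conditionMessage(fit), fit = NULL,
                curve = dat, receptor_conc_nM = receptor_conc_nM,
                free_amplitude = free_amplitude)
    class(out) <- "tight_binding_fit"
    return(out)
  }
  sm <- summary(fit)
  info <- fit$convInfo
  out <- list(kd_nM = unname(coef(fit)["Kd"]),
              kd_se_nM = unname(sm$coefficients["Kd", "Std. Error"]),
              residual_sse = sum(stats::residuals(fit)^2),
              converged = is.null(info$isConv) || isTRUE(info$isConv),
              diagnostics = if (!is.null(info)) info$stopMessage else NULL,
              amplitude = if (free_amplitude) unname(coef(fit)["amp"]) else NULL,
              baseline = if (free_amplitude) unname(coef(fit)["base"]) else NULL,
              fit = fit, curve = dat, receptor_conc_nM = receptor_conc_nM,
              free_amplitude = free_amplitude)
  class(out) <- "tight_binding_fit"
  out
}

#' @export
print.tight_binding_fit <- function(x, ...) {
  if (!x$converged && is.na(x$kd_nM)) {
    cat("Tight-binding fit did not converge:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Tight-binding fit: Kd = %.3g +/- %.2g nM (R = %.3g nM, n = %d, SSE = %.3g)%s\n",
    x$kd_nM, x$kd_se_nM, x$receptor_conc_nM, nrow(x$curve), x$residual_sse,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
summary.tight_binding_fit <- function(object, ...) {
  if (is.null(object$fit)) return(print(object))
  summary(object$fit)
}

#' @export
coef.tight_binding_fit <- function(object, ...) {
  if (is.null(object$fit)) return(c(Kd = NA_real_))
  coef(object$fit)
}

#' @export
residuals.tight_binding_fit <- function(object, ...) {
  if (is.null(object$fit)) return(numeric(0))
  stats::residuals(object$fit)
}

#' Predicted bound fraction (or signal) at new ligand concentrations
#'
#' @param object a `"tight_binding_fit"`.
#' @param newdata optional data frame with a `ligand_conc_nM` (or `L`)
#'   column; defaults to the fitted concentrations.
#' @param ... unused.
#' @export
predict.tight_binding_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$curve$L
       else newdata$ligand_conc_nM %||% newdata$L
  f <- tight_binding_fraction(L, object$receptor_conc_nM, object$kd_nM)
  if (object$free_amplitude) object$baseline + object$amplitude * f else f
}

#' @export
plot.tight_binding_fit <- function(x, ...) {
  graphics::plot(x$curve$L, x$curve$y, log = "x",
                 xlab = "ligand (nM)", ylab = "fractional binding", ...)
  Lg <- exp(seq(log(min(x$curve$L)), log(max(x$curve$L)), length.out = 200))
  graphics::lines(Lg, predict(x, data.frame(L = Lg)))
  graphics::abline(v = x$kd_nM, lty = 3)
  invisible(x)
}
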