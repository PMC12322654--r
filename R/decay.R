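#' Kinetic trace container
#'
#' @param time_s strictly increasing times, s
#' @param signal absorbance (AU) or cis fraction
#' @param temperature a [temperature()] (metadata; no Arrhenius
#'   correction is applied inside single-trace fits)
#' @param signal_kind `"absorbance"` or `"cis_fraction"`
#' @export
kinetic_trace <- function(time_s, signal, temperature = room_temperature(),
                          signal_kind = c("absorbance", "cis_fraction")) {
  signal_kind <- match.arg(signal_kind)
  if (length(time_s) != length(signal)) stop("time and signal lengths differ")
  if (is.unsorted(time_s, strictly = TRUE))
    stop("times must be strictly increasing")
  if (length(time_s) < 4L) stop("a kinetic trace needs >= 4 points")
  structure(list(time_s = as.numeric(time_s), signal = as.numeric(signal),
                 temperature = as_temperature(temperature),
                 signal_kind = signal_kind),
            class = "kinetic_trace")
}

as_kinetic_trace <- function(x) {
  if (inherits(x, "kinetic_trace")) return(x)
  if (is.data.frame(x)) {
    sig <- if (!is.null(x$signal)) x$signal else x$absorbance
    return(kinetic_trace(x$time_s, sig))
  }
  stop("cannot interpret object as a kinetic trace")
}

mono_start <- function(t, y) {
  c0 <- min(y) - 0.05 * abs(diff(range(y)))
  z <- y - c0
  pos <- z > 0
  if (sum(pos) < 3L) return(NULL)
  fit <- stats::lm(log(z[pos]) ~ t[pos])
  k <- -unname(stats::coef(fit)[2])
  if (!is.finite(k) || k <= 0) return(NULL)
  list(a = exp(unname(stats::coef(fit)[1])), k = k, c = c0)
}

#' Fit a mono-exponential decay
#'
#' Least squares for s(t) = a * exp(-k t) + c, initialised from a
#' log-linear fit. Reports the rate, half-life, and the parameter
#' covariance matrix. For baseline-corrected signals known to decay to
#' zero (e.g. cis fractions), `fit_offset = FALSE` fixes c = 0, which
#' substantially tightens the rate estimate on noisy traces.
#'
#' @param trace a [kinetic_trace()] (or data.frame with `time_s` and
#'   `signal`/`absorbance`)
#' @param fit_offset estimate the additive baseline c (default TRUE)
#' @return a `decay_fit`: list with `model = "mono"`, `rates` (k, 1/s),
#'   `amplitudes`, `offset`, `half_lives` ([halflife()]), `sigma`,
#'   `covariance`, `aicc`, `fitted`
#' @export
fit_mono_decay <- function(trace, fit_offset = TRUE) {
  trace <- as_kinetic_trace(trace)
  t <- trace$time_s; y <- trace$signal
  if (stats::sd(y) == 0 || diff(range(y)) < 1e-12 * max(abs(y), 1))
    stop("constant trace: no decay to fit")
  st <- mono_start(t, y)
  if (is.null(st)) st <- list(a = y[1] - min(y), k = log(2) / (max(t) / 2),
                              c = min(y))
  n_par <- if (fit_offset) 3L else 2L
  fit <- tryCatch(
    if (fit_offset)
      minpack.lm::nlsLM(y ~ a * exp(-k * t) + c0,
                        start = list(a = st$a, k = st$k, c0 = st$c),
                        lower = c(-Inf, 1e-12, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    else
      minpack.lm::nlsLM(y ~ a * exp(-k * t),
                        start = list(a = st$a, k = st$k),
                        lower = c(-Inf, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("mono-exponential fit failed: ",
                             conditionMessage(e)))
  p <- stats::coef(fit)
  if (p[["k"]] <= 0) stop("fit rejected: non-positive rate")
  rss <- sum(stats::resid(fit)^2)
  new_decay_fit("mono", rates = c(k = unname(p["k"])),
                amplitudes = c(a = unname(p["a"])),
                offset = if (fit_offset) unname(p["c0"]) else 0,
                covariance = stats::vcov(fit),
                sigma = sqrt(rss / max(length(t) - n_par, 1)),
                aicc = aicc_from_rss(rss, length(t), n_par),
                fitted = stats::fitted(fit),
                temperature = trace$temperature)
}

aicc_from_rss <- function(rss, n, k_par) {
  # least-squares AIC with small-sample correction
  aic <- n * log(rss / n) + 2 * k_par
  if (n - k_par - 1 > 0) aic + 2 * k_par * (k_par + 1) / (n - k_par - 1)
  else Inf
}

new_decay_fit <- function(model, rates, amplitudes, offset, covariance,
                          sigma, aicc, fitted, temperature,
                          note = NULL) {
  structure(
    list(model = model, rates = rates, amplitudes = amplitudes,
         offset = offset,
         half_lives = lapply(rates, function(k) halflife(log(2) / k, "s")),
         covariance = covariance, sigma = sigma, aicc = aicc,
         fitted = fitted, temperature = temperature, note = note),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("%s-exponential decay fit\n", x$model))
  for (i in seq_along(x$rates))
    cat(sprintf("  k_%s = %.4g 1/s  (t1/2 = %s)\n", names(x$rates)[i],
                x$rates[i], format_halflife(x$half_lives[[i]])))
  cat(sprintf("  offset = %.4g, residual sigma = %.3g, AICc = %.2f\n",
              x$offset, x$sigma, x$aicc))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

bi_grid_start <- function(t, y) {
  # fix (k_a, k_b) on a log-spaced grid, solve amplitudes+offset linearly
  t_span <- max(t) - min(t)
  ks <- exp(seq(log(0.5 / t_span), log(200 / t_span), length.out = 25))
  best <- NULL
  for (i in seq_along(ks)) for (j in seq_len(i - 1L)) {
    ka <- ks[i]; kb <- ks[j]
    X <- cbind(exp(-ka * t), exp(-kb * t), 1)
    beta <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(beta)) next
    rss <- sum((y - X %*% beta)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(ka = ka, kb = kb, a1 = beta[1], a2 = beta[2],
                   c = beta[3], rss = rss)
  }
  best
}

#' Fit a bi-exponential decay
#'
#' Parallel two-phase model s(t) = a1 exp(-k_a t) + a2 exp(-k_b t) + c
#' with k_a > k_b by convention. Initialised by a log-spaced grid search
#' over rate pairs (amplitudes solved linearly), refined by
#' Levenberg-Marquardt. When the fitted rates are closer than
#' `ratio_min` (default 3) the phases are not distinguishable and the
#' mono-exponential fit is returned with a warning. `model = "auto"`
#' in [fit_decay()] selects between mono and bi by corrected AIC.
#'
#' @param trace a [kinetic_trace()] (>= 8 points)
#' @param ratio_min minimum distinguishable k_a/k_b ratio
#' @return a `decay_fit` with `model = "bi"` (or the mono fallback)
#' @export
fit_bi_decay <- function(trace, ratio_min = 3) {
  trace <- as_kinetic_trace(trace)
  t <- trace$time_s; y <- trace$signal
  if (length(t) < 8L) stop("a bi-exponential fit needs >= 8 points")
  st <- bi_grid_start(t, y)
  if (is.null(st)) stop("bi-exponential initialisation failed")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * exp(-ka * t) + a2 * exp(-kb * t) + c0,
      start = list(a1 = st$a1, a2 = st$a2, ka = max(st$ka, st$kb),
                   kb = min(st$ka, st$kb), c0 = st$c),
      lower = c(-Inf, -Inf, 1e-12, 1e-12, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("bi-exponential fit did not converge; falling back to mono")
    out <- fit_mono_decay(trace)
    out$note <- "bi fit fell back to mono (no convergence)"
    return(out)
  }
  p <- stats::coef(fit)
  ka <- unname(p["ka"]); kb <- unname(p["kb"])
  a1 <- unname(p["a1"]); a2 <- unname(p["a2"])
  if (ka < kb) { tmp <- ka; ka <- kb; kb <- tmp
                 tmp <- a1; a1 <- a2; a2 <- tmp }
  if (ka / kb < ratio_min) {
    warning("rates indistinguishable (k_a/k_b < ", ratio_min,
            "); falling back to mono")
    out <- fit_mono_decay(trace)
    out$note <- sprintf("bi fit fell back to mono (k_a/k_b = %.2f)", ka / kb)
    return(out)
  }
  rss <- sum(stats::resid(fit)^2)
  new_decay_fit("bi", rates = c(a = ka, b = kb),
                amplitudes = c(a1 = a1, a2 = a2),
                offset = unname(p["c0"]),
                covariance = stats::vcov(fit),
                sigma = sqrt(rss / (length(t) - 5)),
                aicc = aicc_from_rss(rss, length(t), 5L),
                fitted = stats::fitted(fit),
                temperature = trace$temperature)
}

#' Fit a decay with automatic model selection
#'
#' Fits both the mono- and (when enough points) the bi-exponential
#' model and selects by corrected AIC.
#'
#' @param trace a [kinetic_trace()]
#' @param model `"auto"`, `"mono"`, or `"bi"`
#' @return a `decay_fit`
#' @export
fit_decay <- function(trace, model = c("auto", "mono", "bi")) {
  model <- match.arg(model)
  trace <- as_kinetic_trace(trace)
  if (model == "mono") return(fit_mono_decay(trace))
  if (model == "bi") return(fit_bi_decay(trace))
  mono <- fit_mono_decay(trace)
  if (length(trace$time_s) < 8L) return(mono)
  bi <- tryCatch(suppressWarnings(fit_bi_decay(trace)),
                 error = function(e) NULL)
  if (is.null(bi) || bi$model != "bi") return(mono)
  if (bi$aicc < mono$aicc) bi else mono
}

#' Half-life and Eyring barrier from a decay fit
#'
#' Takes the slowest phase of the fit (the phase that controls the
#' long-time disappearance), converts it to a half-life, and chains into
#' [barrier_from_halflife()] at the trace temperature.
#'
#' @param fit a `decay_fit`
#' @param temp a [temperature()]; defaults to the trace temperature
#'   stored on the fit
#' @return list: `half_life` ([halflife()]), `barrier`
#'   (`barrier_estimate`), `phase_used`
#' @export
halflife_report <- function(fit, temp = NULL) {
  stopifnot(inherits(fit, "decay_fit"))
  if (is.null(temp)) temp <- fit$temperature
  k_slow <- min(fit$rates)
  phase <- names(fit$rates)[which.min(fit$rates)]
  if (fit$model == "bi")
    message("bi-exponential fit: using slow phase k_", phase)
  hl <- halflife(log(2) / k_slow, "s")
  list(half_life = hl,
       barrier = barrier_from_halflife(hl, temp),
       phase_used = phase)
}
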