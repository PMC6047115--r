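#' Growth-model evaluation
#'
#' Closed-form growth curves used throughout the workflow. All evaluators are
#' overflow-guarded: exponents are clamped so the value is finite for any
#' finite input.
#'
#' * logistic: `f(t) = L / (1 + exp(-k (t - t0)))` with upper asymptote `L`,
#'   growth rate `k` and midpoint `t0`.
#' * 4-parameter logistic (4PL): `f(t) = D + (A - D) / (1 + (t/C)^B)` with
#'   bottom/top asymptotes `A`/`D`, inflection `C` (where the curve is halfway
#'   between `A` and `D`) and hill slope `B` (either sign). Note `B` here is
#'   the curve slope, unrelated to the permutation count `B` used in the scan
#'   module.
#' * Gompertz: `f(t) = a exp(-b exp(-c t))` with asymptote `a` (`f -> a` as
#'   `t -> Inf`), displacement `b > 0` and rate `c > 0`.
#'
#' @param L,k,t0 logistic parameters.
#' @param A,B,C,D 4PL parameters (`C > 0`).
#' @param a,b,c Gompertz parameters (`b > 0`, `c > 0`).
#' @param t days after sowing; vectorized. `eval_4pl` requires `t > 0`.
#' @return numeric vector of curve values.
#' @name growth_curves
NULL

.EXP_CLAMP <- 700  # exp() overflows just above exp(709)

.safe_exp <- function(x) exp(pmin(pmax(x, -.EXP_CLAMP), .EXP_CLAMP))

#' @rdname growth_curves
#' @export
eval_logistic <- function(L, k, t0, t) {
  L / (1 + .safe_exp(-k * (t - t0)))
}

#' @rdname growth_curves
#' @export
eval_4pl <- function(A, B, C, D, t) {
  if (any(t <= 0)) stop("eval_4pl: t must be > 0 (the (t/C)^B form)", call. = FALSE)
  if (C <= 0) stop("eval_4pl: C must be > 0", call. = FALSE)
  D + (A - D) / (1 + .safe_exp(B * log(t / C)))
}

#' @rdname growth_curves
#' @export
eval_gompertz <- function(a, b, c, t) {
  a * exp(-b * .safe_exp(-c * t))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, the statistic used to
#' select among growth models fitted to the same series.
#'
#' @param observed,fitted equal-length numeric vectors (length >= 2).
#' @return unitless value in (-Inf, 1].
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2)
    stop("r_squared: need equal-length vectors of length >= 2", call. = FALSE)
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("r_squared: zero total sum of squares, R^2 undefined", call. = FALSE)
  1 - sum((observed - fitted)^2) / tss
}

.n_params <- function(model) {
  switch(model,
         logistic = 3L, gompertz = 3L, fourpl = 4L,
         as.integer(sub("^poly", "", model)) + 1L)
}

new_fit_result <- function(model, params, r2, rss, converged, n_points) {
  structure(list(model = model, params = params, r_squared = r2, rss = rss,
                 converged = converged, n_points = n_points),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> model=%s converged=%s R2=%s n=%d\n",
              x$model, x$converged,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.6f", x$r_squared)),
              x$n_points))
  print(round(x$params, 6))
  invisible(x)
}

# Data-driven initialization heuristics. The linearizations below invert each
# model exactly on noiseless data away from the asymptotes, so the optimizer
# starts close to the optimum.
.init_logistic <- function(t, y) {
  increasing <- stats::cor(t, y) >= 0
  L <- if (increasing) max(y) * 1.05 else max(y) * 1.05
  p <- pmin(pmax(y / L, 0.02), 0.98)
  fit <- stats::lm(stats::qlogis(p) ~ t)
  k <- unname(stats::coef(fit)[2])
  if (!is.finite(k) || k == 0) k <- if (increasing) 0.1 else -0.1
  t0 <- unname(-stats::coef(fit)[1] / k)
  if (!is.finite(t0)) t0 <- stats::median(t)
  c(L = L, k = k, t0 = t0)
}

.init_fourpl <- function(t, y) {
  A <- min(y); D <- max(y)
  half <- (A + D) / 2
  C <- t[which.min(abs(y - half))]
  eps <- 0.05 * (D - A) + 1e-12
  u <- (A - eps - y) / (y - (D + eps))  # = (t/C)^B under the model
  ok <- is.finite(u) & u > 0 & t > 0
  B <- NA_real_
  if (sum(ok) >= 2) {
    fit <- stats::lm(log(u[ok]) ~ log(t[ok]))
    B <- unname(stats::coef(fit)[2])
    C2 <- exp(-unname(stats::coef(fit)[1]) / B)
    if (is.finite(C2) && C2 > min(t) / 4 && C2 < max(t) * 4) C <- C2
  }
  if (!is.finite(B) || B == 0) B <- 5
  if (!is.finite(C) || C <= 0) C <- stats::median(t)
  c(A = A, B = B, C = C, D = D)
}

.init_gompertz <- function(t, y) {
  a <- max(y) * 1.05
  z <- pmin(pmax(y / a, 1e-6), 1 - 1e-6)
  w <- log(-log(z))  # = log(b) - c t
  fit <- stats::lm(w ~ t)
  cc <- -unname(stats::coef(fit)[2])
  b <- exp(unname(stats::coef(fit)[1]))
  if (!is.finite(cc) || cc <= 0) cc <- 0.05
  if (!is.finite(b) || b <= 0) b <- 5
  c(a = a, b = b, c = cc)
}

.model_fn <- function(model) {
  switch(model,
    logistic = function(p, t) eval_logistic(p[["L"]], p[["k"]], p[["t0"]], t),
    fourpl   = function(p, t) eval_4pl(p[["A"]], p[["B"]], p[["C"]], p[["D"]], t),
    gompertz = function(p, t) eval_gompertz(p[["a"]], p[["b"]], p[["c"]], t),
    stop("unknown model '", model, "'", call. = FALSE))
}

.model_bounds <- function(model, t, y) {
  switch(model,
    logistic = list(lower = c(L = -Inf, k = -Inf, t0 = -Inf),
                    upper = c(L = Inf, k = Inf, t0 = Inf)),
    fourpl   = list(lower = c(A = -Inf, B = -Inf, C = 1e-8, D = -Inf),
                    upper = c(A = Inf, B = Inf, C = Inf, D = Inf)),
    gompertz = list(lower = c(a = -Inf, b = 1e-10, c = 1e-10),
                    upper = c(a = Inf, b = Inf, c = Inf)))
}

#' Fit a non-linear growth model to one time series
#'
#' Bounded Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()]) from
#' data-driven starting values, with three deterministic multi-starts (the
#' heuristic start and two scaled variants); the converged start with lowest
#' residual sum of squares wins. The fit's `r_squared` is the model-selection
#' statistic of [r_squared()].
#'
#' @param t numeric DAS values (length >= number of parameters + 1).
#' @param y observed trait values.
#' @param model one of `"logistic"`, `"fourpl"`, `"gompertz"`.
#' @param init optional named vector of starting values overriding the
#'   heuristics.
#' @param n_starts number of multi-starts (default 3).
#' @return a `growth_fit`; `converged = FALSE` (never an error) when no start
#'   converges or the series is degenerate (constant values).
#' @export
fit_growth_model <- function(t, y, model = c("fourpl", "logistic", "gompertz"),
                             init = NULL, n_starts = 3L) {
  model <- match.arg(model)
  npar <- .n_params(model)
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(y) < npar + 1L)
    stop("fit_growth_model: need at least ", npar + 1L, " points", call. = FALSE)
  if (model == "fourpl" && any(t <= 0))
    stop("fit_growth_model: 4PL requires t > 0", call. = FALSE)
  if (stats::sd(y) == 0) {
    params <- switch(model,
                     logistic = c(L = y[1] * 2, k = 0, t0 = stats::median(t)),
                     fourpl = c(A = y[1], B = 0, C = stats::median(t), D = y[1]),
                     gompertz = c(a = y[1], b = 1e-10, c = 1e-2))
    return(new_fit_result(model, params, NA_real_, 0, FALSE, length(y)))
  }

  start0 <- if (!is.null(init)) init[names(.model_bounds(model)$lower)] else
    switch(model,
           logistic = .init_logistic(t, y),
           fourpl   = .init_fourpl(t, y),
           gompertz = .init_gompertz(t, y))
  scale_y <- diff(range(y))
  mults <- c(1, 0.7, 1.4)[seq_len(max(1L, n_starts))]
  bounds <- .model_bounds(model, t, y)
  fn <- .model_fn(model)
  resid_fn <- function(p) {
    names(p) <- names(start0)
    r <- fn(as.list(p), t) - y
    r[!is.finite(r)] <- 1e6 * scale_y
    r
  }

  best <- NULL
  for (mu in mults) {
    start <- start0
    small <- abs(start) < 1e-8
    start[!small] <- start[!small] * mu
    start[small] <- start[small] + (mu - 1) * 0.1 * scale_y
    start <- pmin(pmax(start, bounds$lower + 1e-12), bounds$upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = bounds$lower, upper = bounds$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(new_fit_result(model, start0, NA_real_, NA_real_, FALSE, length(y)))
  params <- best$fit$par
  names(params) <- names(start0)
  r2 <- r_squared(y, fn(as.list(params), t))
  new_fit_result(model, params, r2, best$rss, TRUE, length(y))
}

#' Fit an ordinary polynomial baseline to one time series
#'
#' OLS fit of `y = b0 + b1 t + ... + bn t^n` for degree 2-4, the polynomial
#' baseline against which the non-linear growth models are compared.
#'
#' @param t,y the series.
#' @param degree polynomial degree, 2-4.
#' @return a `growth_fit` with model `"poly<degree>"` and coefficients
#'   `b0..bn`.
#' @export
fit_polynomial <- function(t, y, degree = 3L) {
  degree <- as.integer(degree)
  if (degree < 2L || degree > 4L) stop("fit_polynomial: degree must be 2-4", call. = FALSE)
  if (length(y) < degree + 2L)
    stop("fit_polynomial: need at least degree + 2 points", call. = FALSE)
  fit <- stats::lm(y ~ poly(t, degree, raw = TRUE))
  if (fit$rank < degree + 1L) stop("fit_polynomial: rank-deficient design", call. = FALSE)
  coefs <- unname(stats::coef(fit))
  names(coefs) <- paste0("b", 0:degree)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) NA_real_ else r_squared(y, stats::fitted(fit))
  new_fit_result(paste0("poly", degree), coefs, r2,
                 sum(stats::residuals(fit)^2), TRUE, length(y))
}

#' Select the best growth model for a series by R-squared
#'
#' Among converged fits of the same series, returns the name of the model with
#' the highest coefficient of determination; exact ties go to the model with
#' fewer parameters, then to a fixed name order (logistic, gompertz, fourpl,
#' then polynomials by degree).
#'
#' @param fits list of `growth_fit` objects for one series.
#' @return model name (character scalar).
#' @export
select_model <- function(fits) {
  conv <- Filter(function(f) isTRUE(f$converged) && is.finite(f$r_squared), fits)
  if (length(conv) == 0) stop("select_model: no converged fits", call. = FALSE)
  order_names <- c("logistic", "gompertz", "fourpl", "poly2", "poly3", "poly4")
  r2 <- vapply(conv, `[[`, numeric(1), "r_squared")
  np <- vapply(conv, function(f) .n_params(f$model), integer(1))
  nm <- vapply(conv, `[[`, character(1), "model")
  rank_nm <- match(nm, order_names, nomatch = length(order_names) + 1L)
  ord <- order(-r2, np, rank_nm)
  nm[ord[1]]
}

#' Fit one growth model to every (line, replicate) series of a trait
#'
#' @param series long data.frame with columns line, rep, DAS, trait, value.
#' @param trait trait to fit.
#' @param model model name passed to [fit_growth_model()].
#' @return data.frame with one row per (line, rep): parameter columns,
#'   `r_squared`, `converged`, `n_points`.
#' @export
fit_trait_curves <- function(series, trait, model = "fourpl") {
  dat <- series[series$trait == trait, ]
  if (nrow(dat) == 0) stop("fit_trait_curves: no rows for trait '", trait, "'", call. = FALSE)
  keys <- unique(dat[c("line", "rep")])
  keys <- keys[order(keys$line, keys$rep), ]
  res <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    s <- dat[dat$line == keys$line[i] & dat$rep == keys$rep[i], ]
    s <- s[order(s$DAS), ]
    f <- tryCatch(fit_growth_model(s$DAS, s$value, model),
                  error = function(e) NULL)
    if (is.null(f)) {
      res[[i]] <- NULL
      next
    }
    res[[i]] <- data.frame(line = keys$line[i], rep = keys$rep[i], trait = trait,
                           model = f$model, t(f$params),
                           r_squared = f$r_squared, converged = f$converged,
                           n_points = f$n_points,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
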