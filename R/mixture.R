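#' Fit a Gaussian finite mixture to weighted observations by EM
#'
#' Models the bimodal daily water-use trajectory as an m-component Gaussian
#' mixture on the time axis. A daily curve (DAS, ml) is first converted to
#' weighted samples - each DAS is an observation weighted by that day's water
#' amount (see [curve_to_samples()]) - and the mixture
#' `h(y) = sum_k pi_k N(y; mu_k, sigma_k)` is fitted by
#' expectation-maximization: the E-step computes per-observation posterior
#' class probabilities, the M-step re-estimates `(pi_k, mu_k, sigma_k)` by
#' weighted maximum likelihood using the posteriors as weights, and iteration
#' stops when the weighted log-likelihood improves by less than `tol` or
#' `max_iter` is reached. Amplitudes are reported as
#' `lam_k = pi_k * sum(weights)` (ml, the water volume attributed to each
#' mode). Components are returned sorted by mean, making the fit invariant to
#' initial labelling.
#'
#' If a component's standard deviation collapses below `sigma_floor`
#' (default 1e-3 of the data range) it is re-seeded once; a second collapse
#' flags the fit as not converged.
#'
#' @param x numeric observations (DAS values).
#' @param w non-negative weights (default all 1); not all zero.
#' @param m number of components (>= 1).
#' @param init optional list with numeric vectors `pi`, `mu`, `sigma` of
#'   length `m`.
#' @param tol absolute log-likelihood improvement threshold (default 1e-8).
#' @param max_iter maximum EM iterations (default 500).
#' @param sigma_floor minimum allowed component s.d.
#' @return object of class `mixture_fit`: `components` (data.frame pi, mu,
#'   sigma, lam ordered by mu), `log_likelihood`, `loglik_trace`,
#'   `n_iterations`, `converged`, `posterior` (n x m matrix), `total_weight`.
#' @export
em_fit <- function(x, w = NULL, m = 2L, init = NULL,
                   tol = 1e-8, max_iter = 500L, sigma_floor = NULL) {
  if (m < 1) stop("em_fit: m must be >= 1", call. = FALSE)
  if (is.null(w)) w <- rep(1, length(x))
  if (length(w) != length(x)) stop("em_fit: weights must match x", call. = FALSE)
  if (any(w < 0)) stop("em_fit: weights must be >= 0", call. = FALSE)
  keep <- w > 0 & is.finite(x)
  x <- x[keep]; w <- w[keep]
  if (sum(w) == 0) stop("em_fit: all weights are zero", call. = FALSE)
  if (length(unique(x)) < 2L * m)
    stop("em_fit: need at least 2*m distinct support points", call. = FALSE)
  rng <- diff(range(x))
  if (is.null(sigma_floor)) sigma_floor <- 1e-3 * max(rng, .Machine$double.eps)

  if (is.null(init)) init <- .quantile_split_init(x, w, m)
  pi_k <- init$pi / sum(init$pi)
  mu_k <- init$mu
  sd_k <- pmax(init$sigma, sigma_floor)

  W <- sum(w)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  reseeded <- rep(FALSE, m)
  collapsed <- FALSE
  iter <- 0L
  post <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    dens <- vapply(seq_len(m),
                   function(k) pi_k[k] * stats::dnorm(x, mu_k[k], sd_k[k]),
                   numeric(length(x)))
    dens <- matrix(dens, ncol = m)
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(w * log(tot))
    ll_trace <- c(ll_trace, ll)
    post <- dens / tot
    if (is.finite(ll_prev) && (ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M-step: weighted ML updates using posterior-weighted observation weights
    Nk <- colSums(w * post)
    Nk[Nk < .Machine$double.xmin] <- .Machine$double.xmin
    pi_k <- Nk / W
    mu_k <- colSums(w * post * x) / Nk
    sd_k <- sqrt(colSums(w * post * (x - rep(mu_k, each = length(x)))^2) / Nk)
    low <- sd_k < sigma_floor
    if (any(low)) {
      for (k in which(low)) {
        if (reseeded[k]) { collapsed <- TRUE; next }
        reseeded[k] <- TRUE
        mu_k[k] <- .weighted_quantile(x, w, stats::runif(1, 0.2, 0.8))
        sd_k[k] <- 0.25 * rng
        pi_k[k] <- max(pi_k[k], 1 / (2 * m))
        pi_k <- pi_k / sum(pi_k)
      }
      sd_k <- pmax(sd_k, sigma_floor)
      ll_prev <- -Inf  # restart convergence check after re-seeding
    }
  }
  if (collapsed) converged <- FALSE

  ord <- order(mu_k)
  comps <- data.frame(pi = pi_k[ord], mu = mu_k[ord], sigma = sd_k[ord],
                      lam = pi_k[ord] * W)
  fit <- structure(list(
    components = comps, log_likelihood = ll_trace[length(ll_trace)],
    loglik_trace = ll_trace, n_iterations = iter, converged = converged,
    posterior = post[, ord, drop = FALSE], total_weight = W,
    backend = "em"
  ), class = "mixture_fit")
  fit
}

.weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  x[ord][which(cw >= p)[1]]
}

# Deterministic initialization: split the weighted sample at its weighted
# quantiles into m blocks and use each block's weighted moments.
.quantile_split_init <- function(x, w, m) {
  probs <- seq_len(m - 1) / m
  breaks <- c(-Inf, vapply(probs, function(p) .weighted_quantile(x, w, p), 1), Inf)
  grp <- cut(x, breaks = unique(breaks), labels = FALSE, include.lowest = TRUE)
  if (length(unique(grp)) < m) grp <- cut(rank(x, ties.method = "first"),
                                          breaks = m, labels = FALSE)
  pi0 <- mu0 <- sd0 <- numeric(m)
  for (k in seq_len(m)) {
    xi <- x[grp == k]; wi <- w[grp == k]
    pi0[k] <- sum(wi) / sum(w)
    mu0[k] <- sum(wi * xi) / sum(wi)
    sd0[k] <- sqrt(sum(wi * (xi - mu0[k])^2) / sum(wi))
  }
  sd0[!is.finite(sd0) | sd0 == 0] <- diff(range(x)) / (4 * m)
  list(pi = pi0, mu = mu0, sigma = sd0)
}

#' Convert a daily water-use curve into weighted mixture observations
#'
#' @param das numeric vector of DAS values.
#' @param amount daily water amounts (ml), used as observation weights.
#' @return list with `x` (DAS) and `w` (weights), negative amounts rejected.
#' @export
curve_to_samples <- function(das, amount) {
  if (length(das) != length(amount)) stop("curve_to_samples: length mismatch", call. = FALSE)
  if (any(amount < 0, na.rm = TRUE)) stop("curve_to_samples: negative amounts", call. = FALSE)
  keep <- is.finite(das) & is.finite(amount)
  list(x = das[keep], w = amount[keep])
}

#' Posterior class probabilities of a fitted mixture
#'
#' @param fit a `mixture_fit`.
#' @param x DAS value(s) at which to evaluate.
#' @return matrix (length(x) x m) of class probabilities, rows summing to 1.
#' @export
posterior <- function(fit, x) UseMethod("posterior")

#' @export
posterior.mixture_fit <- function(fit, x) {
  cm <- fit$components
  dens <- vapply(seq_len(nrow(cm)),
                 function(k) cm$pi[k] * stats::dnorm(x, cm$mu[k], cm$sigma[k]),
                 numeric(length(x)))
  dens <- matrix(dens, ncol = nrow(cm))
  tot <- rowSums(dens)
  zero <- tot < .Machine$double.xmin
  out <- dens / ifelse(zero, 1, tot)
  out[zero, ] <- 1 / nrow(cm)  # equidistant in the far tails
  out
}

#' Bimodal separation statistic
#'
#' `S = (mu2 - mu1) / (2 sigma1 + 2 sigma2)` for a two-component fit with
#' components ordered by mean; a unitless distance between the two water-use
#' modes.
#'
#' @param fit a two-component `mixture_fit`.
#' @return numeric S.
#' @export
bimodal_separation <- function(fit) {
  cm <- fit$components
  if (nrow(cm) != 2) stop("bimodal_separation: fit must have exactly 2 components",
                          call. = FALSE)
  (cm$mu[2] - cm$mu[1]) / (2 * cm$sigma[1] + 2 * cm$sigma[2])
}

#' Fit the two-mode water-use model to one daily curve
#'
#' Front end over the two available backends: `"em"` converts the curve to
#' weighted samples and runs [em_fit()]; `"nls"` fits the two-Gaussian sum
#' `lam1 N(t; mu1, sigma1) + lam2 N(t; mu2, sigma2)` directly to the curve by
#' bounded Levenberg-Marquardt least squares.
#'
#' @param das,amount the daily curve.
#' @param backend `"em"` or `"nls"`.
#' @param ... passed to [em_fit()] (em backend only).
#' @return a `mixture_fit` (for `"nls"`, `pi` is `lam / sum(lam)` and the
#'   posterior matrix is computed from the fitted components).
#' @export
fit_water_mixture <- function(das, amount, backend = c("em", "nls"), ...) {
  backend <- match.arg(backend)
  s <- curve_to_samples(das, amount)
  if (backend == "em") return(em_fit(s$x, s$w, m = 2L, ...))

  init <- .quantile_split_init(s$x, s$w, 2L)
  W <- sum(s$w)
  start <- list(l1 = init$pi[1] * W, m1 = init$mu[1], s1 = max(init$sigma[1], 1),
                l2 = init$pi[2] * W, m2 = init$mu[2], s2 = max(init$sigma[2], 1))
  dat <- data.frame(t = das, yv = amount)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yv ~ l1 * stats::dnorm(t, m1, s1) + l2 * stats::dnorm(t, m2, s2),
      data = dat, start = start,
      lower = c(l1 = 0, m1 = min(das), s1 = 1e-3, l2 = 0, m2 = min(das), s2 = 1e-3),
      upper = c(l1 = Inf, m1 = max(das), s1 = Inf, l2 = Inf, m2 = max(das), s2 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(components = data.frame(pi = NA, mu = NA, sigma = NA, lam = NA),
                          log_likelihood = NA_real_, loglik_trace = numeric(0),
                          n_iterations = 0L, converged = FALSE, posterior = NULL,
                          total_weight = W, backend = "nls"),
                     class = "mixture_fit"))
  }
  cf <- stats::coef(fit)
  lam <- c(cf["l1"], cf["l2"])
  ord <- order(c(cf["m1"], cf["m2"]))
  comps <- data.frame(pi = (lam / sum(lam))[ord],
                      mu = c(cf["m1"], cf["m2"])[ord],
                      sigma = c(cf["s1"], cf["s2"])[ord],
                      lam = lam[ord])
  out <- structure(list(components = comps, log_likelihood = NA_real_,
                        loglik_trace = numeric(0), n_iterations = 0L,
                        converged = TRUE, posterior = NULL, total_weight = W,
                        backend = "nls"),
                   class = "mixture_fit")
  out$posterior <- posterior(out, das)
  out
}

#' Fit the water-use mixture for every (line, replicate) series
#'
#' @param series long data.frame (line, rep, DAS, trait, value).
#' @param trait water-use trait name (default "water_amount").
#' @param backend see [fit_water_mixture()].
#' @return data.frame: line, rep, mu1, lam1, sigma1, mu2, lam2, sigma2, S,
#'   loglik, converged.
#' @export
fit_trait_mixtures <- function(series, trait = "water_amount", backend = "em") {
  dat <- series[series$trait == trait, ]
  if (nrow(dat) == 0) stop("fit_trait_mixtures: no rows for trait '", trait, "'",
                           call. = FALSE)
  keys <- unique(dat[c("line", "rep")])
  keys <- keys[order(keys$line, keys$rep), ]
  res <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    s <- dat[dat$line == keys$line[i] & dat$rep == keys$rep[i], ]
    s <- s[order(s$DAS), ]
    f <- tryCatch(fit_water_mixture(s$DAS, s$value, backend = backend),
                  error = function(e) NULL)
    if (is.null(f) || nrow(f$components) != 2 || any(is.na(f$components$mu))) {
      res[[i]] <- data.frame(line = keys$line[i], rep = keys$rep[i],
                             mu1 = NA, lam1 = NA, sigma1 = NA,
                             mu2 = NA, lam2 = NA, sigma2 = NA,
                             S = NA, loglik = NA, converged = FALSE,
                             stringsAsFactors = FALSE)
      next
    }
    cm <- f$components
    res[[i]] <- data.frame(line = keys$line[i], rep = keys$rep[i],
                           mu1 = cm$mu[1], lam1 = cm$lam[1], sigma1 = cm$sigma[1],
                           mu2 = cm$mu[2], lam2 = cm$lam[2], sigma2 = cm$sigma[2],
                           S = bimodal_separation(f),
                           loglik = f$log_likelihood, converged = f$converged,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
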