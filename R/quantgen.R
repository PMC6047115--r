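#' Genetic and environmental variance components of a replicated trait
#'
#' One-way random-effects decomposition by the method of moments: with lines
#' as the random factor, the within-line mean square estimates the
#' environmental variance `s2_e` and `(between-line MS - within-line MS) / r0`
#' estimates the genetic variance `s2_g`, where `r0` is the number of
#' replicates (or its replicate-weighted analogue
#' `(N - sum(n_i^2)/N) / (a - 1)` for unbalanced designs). Negative `s2_g`
#' estimates are truncated at 0 and flagged.
#'
#' @param values either a numeric matrix (lines x replicates, NA allowed) or a
#'   data.frame with columns `line` and `value`.
#' @return object of class `variance_components`: `s2_g`, `s2_e`, `n_lines`,
#'   `n_reps` (effective), `truncated`, `ms_between`, `ms_within`.
#' @export
variance_components <- function(values) {
  if (is.matrix(values)) {
    values <- data.frame(
      line = rep(rownames(values) %||% as.character(seq_len(nrow(values))),
                 times = ncol(values)),
      value = as.vector(values))
  }
  stopifnot(all(c("line", "value") %in% names(values)))
  values <- values[is.finite(values$value), ]
  sp <- split(values$value, values$line)
  sp <- sp[lengths(sp) > 0]
  a <- length(sp)
  n_i <- lengths(sp)
  N <- sum(n_i)
  if (a < 2) stop("variance_components: need >= 2 lines", call. = FALSE)
  if (all(n_i < 2))
    stop("variance_components: single replicate everywhere, components not separable",
         call. = FALSE)
  means <- vapply(sp, mean, numeric(1))
  grand <- sum(values$value) / N
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(sp, function(v) sum((v - mean(v))^2), numeric(1)))
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  r0 <- (N - sum(n_i^2) / N) / (a - 1)
  s2_e <- msw
  s2_g <- (msb - msw) / r0
  truncated <- s2_g < 0
  if (truncated) s2_g <- 0
  structure(list(s2_g = s2_g, s2_e = s2_e, n_lines = a, n_reps = r0,
                 truncated = truncated, ms_between = msb, ms_within = msw),
            class = "variance_components")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Broad-sense heritability from variance components
#'
#' `H^2 = s2_g / (s2_g + s2_e)`, the fraction of phenotypic variance among
#' lines attributable to genetic variance.
#'
#' @param vc a [variance_components()] object (or list with `s2_g`, `s2_e`).
#' @return unitless H^2 in \[0, 1\].
#' @export
heritability <- function(vc) {
  tot <- vc$s2_g + vc$s2_e
  if (!is.finite(tot) || tot <= 0)
    stop("heritability: zero total variance, H^2 undefined", call. = FALSE)
  vc$s2_g / tot
}

.align_pair <- function(x, y) {
  to_df <- function(v, nm) {
    if (is.matrix(v)) data.frame(
      line = rep(rownames(v) %||% as.character(seq_len(nrow(v))), times = ncol(v)),
      rep = rep(seq_len(ncol(v)), each = nrow(v)),
      value = as.vector(v))
    else { stopifnot(all(c("line", "rep", "value") %in% names(v))); v[c("line", "rep", "value")] }
  }
  dx <- to_df(x); dy <- to_df(y)
  m <- merge(dx, dy, by = c("line", "rep"), suffixes = c(".x", ".y"))
  m <- m[is.finite(m$value.x) & is.finite(m$value.y), ]
  if (nrow(m) == 0) stop("covariance_components: no aligned observations", call. = FALSE)
  m
}

#' Genetic and environmental covariance between two traits
#'
#' Sum-trait identity: `S_i(x, y) = (s2_i(x + y) - s2_i(x) - s2_i(y)) / 2` for
#' `i` in {genetic, environmental}, each variance from
#' [variance_components()]. A constant sum trait (e.g. `y = -x`) gives zero
#' variance components and hence `S_i = -s2_i(x)` exactly.
#'
#' @param x,y matched designs: matrices (lines x reps) or data.frames with
#'   columns line, rep, value.
#' @return list with `S_g`, `S_e` and the three underlying
#'   `variance_components` (`vc_x`, `vc_y`, `vc_sum`).
#' @export
covariance_components <- function(x, y) {
  m <- .align_pair(x, y)
  vc_of <- function(v) {
    d <- data.frame(line = m$line, value = v)
    # a constant trait has zero variance everywhere; short-circuit to avoid
    # spurious truncation flags on exact zeros
    variance_components(d)
  }
  vc_x <- vc_of(m$value.x)
  vc_y <- vc_of(m$value.y)
  vc_s <- vc_of(m$value.x + m$value.y)
  list(S_g = (vc_s$s2_g - vc_x$s2_g - vc_y$s2_g) / 2,
       S_e = (vc_s$s2_e - vc_x$s2_e - vc_y$s2_e) / 2,
       vc_x = vc_x, vc_y = vc_y, vc_sum = vc_s)
}

#' Genetic and environmental correlation between two traits
#'
#' Default (`denominator = "geometric"`):
#' `r_i = S_i(x, y) / sqrt(s2_i(x) s2_i(y))`, the standard product-moment
#' form. `denominator = "arithmetic"` instead divides by
#' `(s2_i(x) + s2_i(y)) / 2`, provided for comparisons with reports that use
#' the arithmetic-mean normalisation. Raw values outside \[-1, 1\] are clamped
#' and flagged; a zero component variance in either trait yields NA for that
#' component (with a flag) rather than an error, unless both traits are
#' degenerate.
#'
#' @param x,y as in [covariance_components()].
#' @param denominator `"geometric"` (default) or `"arithmetic"`.
#' @return list with `r_g`, `r_e`, `S_g`, `S_e`, `clamped` (logical 2-vector),
#'   `undefined` (logical 2-vector).
#' @export
genetic_correlation <- function(x, y, denominator = c("geometric", "arithmetic")) {
  denominator <- match.arg(denominator)
  cc <- covariance_components(x, y)
  comp_r <- function(S, v1, v2) {
    if (v1 <= 0 || v2 <= 0) return(c(r = NA_real_, clamped = 0, undefined = 1))
    den <- if (denominator == "geometric") sqrt(v1 * v2) else (v1 + v2) / 2
    r <- S / den
    cl <- 0
    if (is.finite(r) && abs(r) > 1) { r <- sign(r); cl <- 1 }
    c(r = r, clamped = cl, undefined = 0)
  }
  g <- comp_r(cc$S_g, cc$vc_x$s2_g, cc$vc_y$s2_g)
  e <- comp_r(cc$S_e, cc$vc_x$s2_e, cc$vc_y$s2_e)
  if (g[["undefined"]] == 1 && e[["undefined"]] == 1)
    stop("genetic_correlation: zero variance in both components", call. = FALSE)
  list(r_g = g[["r"]], r_e = e[["r"]], S_g = cc$S_g, S_e = cc$S_e,
       clamped = c(g = g[["clamped"]] == 1, e = e[["clamped"]] == 1),
       undefined = c(g = g[["undefined"]] == 1, e = e[["undefined"]] == 1))
}

#' Heritability table for a set of fitted parameters
#'
#' Runs [variance_components()] and [heritability()] per parameter column of a
#' fitted-parameter table (e.g. from [fit_trait_curves()]).
#'
#' @param param_table data.frame with columns line, rep, and one column per
#'   parameter; non-converged rows should be removed beforehand.
#' @param params parameter column names (default: all numeric columns other
#'   than line/rep bookkeeping).
#' @return data.frame: parameter, s2_g, s2_e, H2, n_lines, truncated.
#' @export
heritability_table <- function(param_table, params = NULL) {
  if (is.null(params)) {
    skip <- c("line", "rep", "trait", "model", "r_squared", "converged",
              "n_points", "loglik", "S")
    params <- setdiff(names(param_table)[vapply(param_table, is.numeric, TRUE)], skip)
  }
  rows <- lapply(params, function(p) {
    vc <- tryCatch(
      variance_components(data.frame(line = param_table$line,
                                     value = param_table[[p]])),
      error = function(e) NULL)
    if (is.null(vc)) return(NULL)
    h2 <- tryCatch(heritability(vc), error = function(e) NA_real_)
    data.frame(parameter = p, s2_g = vc$s2_g, s2_e = vc$s2_e, H2 = h2,
               n_lines = vc$n_lines, truncated = vc$truncated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise genetic and environmental correlation matrices
#'
#' @param param_table as in [heritability_table()].
#' @param params parameter columns to correlate.
#' @param denominator see [genetic_correlation()].
#' @return list of two matrices `r_g`, `r_e` (diagonal 1, NA where undefined).
#' @export
correlation_matrices <- function(param_table, params = NULL,
                                 denominator = "geometric") {
  if (is.null(params)) {
    skip <- c("line", "rep", "trait", "model", "r_squared", "converged",
              "n_points", "loglik", "S")
    params <- setdiff(names(param_table)[vapply(param_table, is.numeric, TRUE)], skip)
  }
  p <- length(params)
  r_g <- r_e <- matrix(NA_real_, p, p, dimnames = list(params, params))
  diag(r_g) <- diag(r_e) <- 1
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (j <= i) next
    gx <- param_table[c("line", "rep")]; gx$value <- param_table[[params[i]]]
    gy <- param_table[c("line", "rep")]; gy$value <- param_table[[params[j]]]
    r <- tryCatch(genetic_correlation(gx, gy, denominator = denominator),
                  error = function(e) NULL)
    if (is.null(r)) next
    r_g[i, j] <- r_g[j, i] <- r$r_g
    r_e[i, j] <- r_e[j, i] <- r$r_e
  }
  list(r_g = r_g, r_e = r_e)
}
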