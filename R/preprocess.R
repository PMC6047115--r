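#' Discard timepoints at which not every line was observed
#'
#' A DAS is retained only if every line in `roster` has at least one
#' observation of the trait at that DAS (imaging days on which part of the
#' population was missed are dropped wholesale).
#'
#' @param series long data.frame (line, rep, DAS, trait, value).
#' @param roster character vector of required line ids (non-empty).
#' @param trait optional single trait to assess (default: completeness is
#'   required for every trait present).
#' @return list with `series` (filtered) and `report` (list: dropped
#'   timepoints, thresholds used, record counts).
#' @export
filter_incomplete_timepoints <- function(series, roster, trait = NULL) {
  if (length(roster) == 0) stop("filter_incomplete_timepoints: empty roster", call. = FALSE)
  dat <- if (is.null(trait)) series else series[series$trait == trait, ]
  traits <- unique(dat$trait)
  all_das <- sort(unique(dat$DAS))
  complete <- vapply(all_das, function(d) {
    all(vapply(traits, function(tr) {
      seen <- unique(dat$line[dat$DAS == d & dat$trait == tr])
      all(roster %in% seen)
    }, logical(1)))
  }, logical(1))
  kept_das <- all_das[complete]
  if (length(kept_das) == 0)
    stop("filter_incomplete_timepoints: no complete timepoints", call. = FALSE)
  keep_row <- series$DAS %in% kept_das |
    (!is.null(trait) & !series$trait %in% traits)
  out <- series[keep_row, ]
  rownames(out) <- NULL
  list(series = out,
       report = list(dropped_timepoints = setdiff(all_das, kept_das),
                     n_required_lines = length(roster),
                     records_in = nrow(series), records_out = nrow(out)))
}

# Cook's distance of every observation of one series against an OLS
# polynomial-in-DAS fit (orthogonal basis for numerical stability; the hat
# matrix and residuals are basis-invariant). A perfect fit - residuals at
# rounding-noise level - yields all zero distances rather than ratios of
# noise to noise.
.cooks_for_series <- function(t, y, degree) {
  fit <- stats::lm(y ~ poly(t, degree))
  if (stats::sd(stats::residuals(fit)) <= 1e-8 * stats::sd(y))
    return(rep(0, length(y)))
  cd <- stats::cooks.distance(fit)
  cd[!is.finite(cd)] <- 0
  unname(cd)
}

#' Remove outlying observations by Cook's distance
#'
#' Per (line, replicate) series of one trait, observations whose Cook's
#' distance - computed against an ordinary least-squares fit of value on a
#' polynomial in DAS - exceeds `multiplier` times the mean distance of that
#' series are removed. Series too short to fit the polynomial are left
#' untouched (with a note in the report). At most `max_frac` of a series is
#' ever removed; when more observations exceed the threshold, only the
#' largest distances go and the series is flagged in the report.
#'
#' @param series long data.frame (line, rep, DAS, trait, value).
#' @param trait trait to clean.
#' @param multiplier threshold multiple of the mean Cook's distance
#'   (default 4; `Inf` disables removal).
#' @param degree polynomial degree of the reference regression (default 3).
#' @param max_frac maximum fraction of a series that may be removed
#'   (default 0.05).
#' @return list with `series` (cleaned, other traits untouched) and `report`
#'   (data.frame of removals: line, rep, DAS, trait, cooks_d; plus attributes
#'   `skipped_series`, `capped_series` and the thresholds used).
#' @export
remove_cooks_outliers <- function(series, trait, multiplier = 4,
                                  degree = 3L, max_frac = 0.05) {
  dat <- series[series$trait == trait, ]
  if (nrow(dat) == 0) stop("remove_cooks_outliers: no rows for trait '", trait, "'",
                           call. = FALSE)
  keys <- unique(dat[c("line", "rep")])
  removals <- list()
  skipped <- character(0)
  capped <- character(0)
  drop_idx <- integer(0)
  for (i in seq_len(nrow(keys))) {
    sel <- which(series$trait == trait &
                   series$line == keys$line[i] & series$rep == keys$rep[i])
    s <- series[sel, ]
    ord <- order(s$DAS)
    sel <- sel[ord]; s <- s[ord, ]
    if (nrow(s) < degree + 3L) {
      skipped <- c(skipped, paste0(keys$line[i], "/", keys$rep[i]))
      next
    }
    cd <- .cooks_for_series(s$DAS, s$value, degree)
    thr <- multiplier * mean(cd)
    out <- which(is.finite(thr) & cd > thr)
    if (length(out) == 0) next
    cap <- max(1L, floor(max_frac * nrow(s)))
    if (length(out) > cap) {
      capped <- c(capped, paste0(keys$line[i], "/", keys$rep[i]))
      out <- out[order(cd[out], decreasing = TRUE)[seq_len(cap)]]
    }
    removals[[length(removals) + 1L]] <- data.frame(
      line = keys$line[i], rep = keys$rep[i], DAS = s$DAS[out], trait = trait,
      cooks_d = cd[out], stringsAsFactors = FALSE)
    drop_idx <- c(drop_idx, sel[out])
  }
  cleaned <- if (length(drop_idx)) series[-drop_idx, ] else series
  rownames(cleaned) <- NULL
  report <- if (length(removals)) do.call(rbind, removals) else
    data.frame(line = character(0), rep = integer(0), DAS = integer(0),
               trait = character(0), cooks_d = numeric(0), stringsAsFactors = FALSE)
  rownames(report) <- NULL
  attr(report, "skipped_series") <- skipped
  attr(report, "capped_series") <- capped
  attr(report, "thresholds") <- list(multiplier = multiplier, degree = degree,
                                     max_frac = max_frac)
  if (length(capped))
    warning("remove_cooks_outliers: removal capped at ", max_frac, " of series for ",
            length(capped), " (line, rep) series (e.g. ",
            paste(utils::head(capped, 3), collapse = ", "),
            "); see the report's capped_series attribute", call. = FALSE)
  list(series = cleaned, report = report)
}
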