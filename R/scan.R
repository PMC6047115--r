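#' One-way ANOVA for a single marker
#'
#' Classical fixed-effects one-way ANOVA of phenotype values grouped by
#' genotype class: `F = MSB / MSW` with `df = (a - 1, N - a)`, p from the F
#' distribution. Classes with no values are dropped. Also returns the marker
#' variance explained `SSB / SST` (reported downstream as `marker_h2`).
#'
#' @param values numeric phenotype values (one per line).
#' @param groups genotype class per value (factor/character); NA values or
#'   groups are dropped.
#' @return list: `F`, `p`, `df1`, `df2`, `group_means` (named), `ssb`, `ssw`,
#'   `sst`, `h2`, `n`.
#' @export
single_marker_anova <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  g <- factor(as.character(groups[keep]))
  a <- nlevels(g)
  N <- length(values)
  if (a < 2) stop("single_marker_anova: need >= 2 non-empty classes", call. = FALSE)
  if (N - a < 1) stop("single_marker_anova: zero residual df", call. = FALSE)
  n_k <- tabulate(g)
  sums <- rowsum(values, g)
  grand <- sum(values)
  ssb <- sum(sums^2 / n_k) - grand^2 / N
  sst <- sum(values^2) - grand^2 / N
  ssw <- max(sst - ssb, 0)
  df1 <- a - 1L
  df2 <- N - a
  msb <- ssb / df1
  msw <- ssw / df2
  if (sst <= 0) {
    # constant phenotype: no variance to partition
    return(list(F = NA_real_, p = NA_real_, df1 = df1, df2 = df2,
                group_means = stats::setNames(as.vector(sums / n_k), levels(g)),
                ssb = 0, ssw = 0, sst = 0, h2 = NA_real_, n = N))
  }
  Fv <- if (msw == 0) Inf else msb / msw
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = Fv, p = p, df1 = df1, df2 = df2,
       group_means = stats::setNames(as.vector(sums / n_k), levels(g)),
       ssb = ssb, ssw = ssw, sst = sst, h2 = ssb / sst, n = N)
}

# Per-marker grouping vector for scanning. genotype grouping: observed A/B
# calls, with the heterozygous class kept only if carried by >= min_het lines;
# founder grouping: consensus founder origin (heterozygous lines excluded).
.marker_groups <- function(geno, grouping, min_het = 3L) {
  calls <- geno$genotypes
  M <- ncol(calls)
  out <- vector("list", M)
  if (grouping == "founder") {
    fo <- geno$founder_origin
    if (is.null(fo)) stop("grouping = 'founder' requires founder_origin", call. = FALSE)
    for (j in seq_len(M)) out[[j]] <- geno$founders[fo[, j]]
  } else {
    for (j in seq_len(M)) {
      gj <- calls[, j]
      if (sum(gj == "H", na.rm = TRUE) < min_het) gj[gj == "H"] <- NA
      out[[j]] <- gj
    }
  }
  names(out) <- colnames(calls)
  out
}

# Vectorized ANOVA of many phenotype columns against one fixed grouping.
# Y: n x B matrix (rows = lines in group order), g: factor without NAs.
.anova_F_matrix <- function(Y, g) {
  n_k <- tabulate(g)
  N <- nrow(Y)
  a <- nlevels(g)
  gs <- rowsum(Y, g)
  tot <- colSums(Y)
  ssb <- colSums(gs^2 / n_k) - tot^2 / N
  sst <- colSums(Y^2) - tot^2 / N
  ssw <- pmax(sst - ssb, 0)
  df1 <- a - 1L
  df2 <- N - a
  Fv <- ifelse(ssw == 0, Inf, (ssb / df1) / (ssw / df2))
  Fv[sst <= 0] <- NA_real_
  list(F = Fv, df1 = df1, df2 = df2)
}

#' Genome scan: single-marker ANOVA at every marker
#'
#' At each marker, lines are grouped by observed genotype (or by ground-truth
#' founder origin for simulated data) and tested by one-way ANOVA. Markers
#' with fewer than two non-empty classes or zero residual degrees of freedom
#' are skipped with a logged reason.
#'
#' @param geno genotype object: list with `genotypes` (line x marker matrix of
#'   "A"/"B"/"H"), `map` (marker, chr, cM, bp) and, optionally,
#'   `founder_origin` + `founders` (e.g. a [simulate_magic_rils()] population
#'   or [read_genotypes()] output).
#' @param phenotype named numeric vector of per-line values (replicates
#'   already collapsed to line means).
#' @param grouping `"genotype"` or `"founder"`.
#' @param min_het minimum lines for the heterozygous class to be kept
#'   (default 3; below it, het lines are excluded at that marker).
#' @return data.frame of class `marker_scan`: marker, chr, cM, bp, F, p,
#'   neg_log10_p, marker_h2, plus one `mean_<class>` column per class;
#'   attribute `skipped` records unsable markers.
#' @export
genome_scan <- function(geno, phenotype, grouping = c("genotype", "founder"),
                        min_het = 3L) {
  grouping <- match.arg(grouping)
  lines <- intersect(rownames(geno$genotypes), names(phenotype))
  if (length(lines) < 3) stop("genome_scan: too few lines shared by genotypes and phenotype",
                              call. = FALSE)
  ph <- phenotype[lines]
  sub <- list(genotypes = geno$genotypes[lines, , drop = FALSE],
              founder_origin = if (!is.null(geno$founder_origin))
                geno$founder_origin[lines, , drop = FALSE],
              founders = geno$founders, map = geno$map)
  grp <- .marker_groups(sub, grouping, min_het)
  map <- geno$map
  M <- nrow(map)
  class_levels <- if (grouping == "founder") geno$founders else c("A", "B", "H")
  means <- matrix(NA_real_, M, length(class_levels),
                  dimnames = list(map$marker, paste0("mean_", class_levels)))
  Fv <- p <- h2 <- rep(NA_real_, M)
  skipped <- character(0)
  n_informative <- 0L
  for (j in seq_len(M)) {
    res <- tryCatch(single_marker_anova(ph, grp[[j]]), error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, paste0(map$marker[j], ": ", conditionMessage(res)))
      next
    }
    n_informative <- n_informative + 1L
    Fv[j] <- res$F; p[j] <- res$p; h2[j] <- res$h2
    means[j, paste0("mean_", names(res$group_means))] <- res$group_means
  }
  if (n_informative < 2) stop("genome_scan: fewer than 2 informative markers", call. = FALSE)
  out <- data.frame(map, F = Fv, p = p,
                    neg_log10_p = -log10(p),
                    marker_h2 = h2,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(means))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "grouping") <- grouping
  class(out) <- c("marker_scan", "data.frame")
  out
}

#' Permutation test for genome-wide significance
#'
#' Phenotype values are shuffled across lines `B` times (jointly over all
#' markers, preserving the genotype structure); each shuffle's genome-wide
#' maximum `-log10 p` forms the null distribution. The empirical p-value is
#' `K / B` where `K` counts null maxima at least as large as the observed
#' genome-wide maximum. The RNG state is restored on exit.
#'
#' @inheritParams genome_scan
#' @param B number of shuffles (default 1000).
#' @param seed integer seed for the shuffles.
#' @return object of class `permutation_result`: `B`, `null_max_stats`,
#'   `observed_max`, `K`, `empirical_p`, `seed`.
#' @export
permutation_test <- function(geno, phenotype, B = 1000L, seed = 1L,
                             grouping = c("genotype", "founder"), min_het = 3L) {
  grouping <- match.arg(grouping)
  if (B < 1) stop("permutation_test: B must be >= 1", call. = FALSE)
  obs <- genome_scan(geno, phenotype, grouping = grouping, min_het = min_het)
  obs_max <- suppressWarnings(max(obs$neg_log10_p, na.rm = TRUE))
  if (is.na(obs_max) || obs_max == -Inf)
    stop("permutation_test: no valid observed statistic", call. = FALSE)

  lines <- intersect(rownames(geno$genotypes), names(phenotype))
  ph <- phenotype[lines]
  sub <- list(genotypes = geno$genotypes[lines, , drop = FALSE],
              founder_origin = if (!is.null(geno$founder_origin))
                geno$founder_origin[lines, , drop = FALSE],
              founders = geno$founders, map = geno$map)
  grp <- .marker_groups(sub, grouping, min_het)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  P <- matrix(NA_real_, length(ph), B)
  for (b in seq_len(B)) P[, b] <- ph[sample.int(length(ph))]

  null_max <- rep(-Inf, B)
  for (j in seq_along(grp)) {
    gj <- grp[[j]]
    ok <- !is.na(gj) & is.finite(ph)
    g <- factor(as.character(gj[ok]))
    if (nlevels(g) < 2 || sum(ok) - nlevels(g) < 1) next
    st <- .anova_F_matrix(P[ok, , drop = FALSE], g)
    # same -log10(p) transform as genome_scan, so observed and null maxima
    # are exactly comparable
    logp <- -log10(stats::pf(st$F, st$df1, st$df2, lower.tail = FALSE))
    null_max <- pmax(null_max, logp, na.rm = TRUE)
  }
  K <- sum(null_max >= obs_max)
  structure(list(B = as.integer(B), null_max_stats = null_max,
                 observed_max = obs_max, K = K, empirical_p = K / B,
                 seed = as.integer(seed)),
            class = "permutation_result")
}

#' Call QTLs from a genome scan and its permutation null
#'
#' Per chromosome, the highest-scoring marker with `-log10 p` above
#' `logp_cutoff` becomes a candidate peak; its support interval extends over
#' the contiguous run of markers within `drop` `-log10 p` units of the peak
#' (reported in bp). Further peaks on the same chromosome are called outside
#' already-claimed support regions. A call passes when `-log10 p >
#' logp_cutoff` and its permutation empirical p (fraction of null genome-wide
#' maxima at least as large) is below `alpha`.
#'
#' @param scan a [genome_scan()] result.
#' @param perm a [permutation_test()] result for the same phenotype.
#' @param logp_cutoff `-log10 p` threshold (default 4).
#' @param alpha empirical-p threshold (default 0.05).
#' @param drop support-interval drop in `-log10 p` units (default 1.5).
#' @return data.frame of class `qtl_calls` (possibly 0 rows): marker, chr, cM,
#'   bp, neg_log10_p, empirical_p, lower, upper, passes_cutoff.
#' @export
call_qtls <- function(scan, perm, logp_cutoff = 4, alpha = 0.05, drop = 1.5) {
  calls <- list()
  for (ch in unique(scan$chr)) {
    sc <- scan[scan$chr == ch, ]
    sc <- sc[order(sc$cM), ]
    logp <- sc$neg_log10_p
    avail <- is.finite(logp)
    while (any(avail & logp > logp_cutoff)) {
      cand <- which(avail & logp > logp_cutoff)
      pk <- cand[which.max(logp[cand])]
      thr <- logp[pk] - drop
      lo <- pk
      while (lo > 1 && is.finite(logp[lo - 1]) && logp[lo - 1] >= thr) lo <- lo - 1
      hi <- pk
      while (hi < nrow(sc) && is.finite(logp[hi + 1]) && logp[hi + 1] >= thr) hi <- hi + 1
      emp_p <- mean(perm$null_max_stats >= logp[pk])
      calls[[length(calls) + 1L]] <- data.frame(
        marker = sc$marker[pk], chr = ch, cM = sc$cM[pk], bp = sc$bp[pk],
        neg_log10_p = logp[pk], empirical_p = emp_p,
        lower = sc$bp[lo], upper = sc$bp[hi],
        passes_cutoff = logp[pk] > logp_cutoff && emp_p < alpha,
        stringsAsFactors = FALSE)
      avail[lo:hi] <- FALSE
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(marker = character(0), chr = character(0), cM = numeric(0),
               bp = integer(0), neg_log10_p = numeric(0), empirical_p = numeric(0),
               lower = integer(0), upper = integer(0), passes_cutoff = logical(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("qtl_calls", "data.frame")
  out
}

#' Collapse a longitudinal series to per-line means at one DAS
#' @noRd
.line_means <- function(series, trait, das = NULL) {
  dat <- series[series$trait == trait, ]
  if (!is.null(das)) dat <- dat[dat$DAS == das, ]
  tapply(dat$value, dat$line, mean)
}

#' Per-timepoint genome scans of a longitudinal trait
#'
#' Runs [genome_scan()] at every retained DAS (replicates collapsed to line
#' means) and assembles per-marker trajectories of `-log10 p` and marker
#' variance explained over time.
#'
#' @param series cleaned long data.frame (line, rep, DAS, trait, value).
#' @param geno genotype object (see [genome_scan()]).
#' @param trait trait name.
#' @param das optional subset of DAS values to scan (default: all present).
#' @inheritParams genome_scan
#' @return list of class `longitudinal_scan`: `scans` (named by DAS),
#'   `trajectory` (long data.frame DAS, marker, chr, cM, bp, neg_log10_p,
#'   marker_h2).
#' @export
longitudinal_scan <- function(series, geno, trait, das = NULL,
                              grouping = "genotype", min_het = 3L) {
  dat <- series[series$trait == trait, ]
  if (nrow(dat) == 0) stop("longitudinal_scan: no rows for trait '", trait, "'",
                           call. = FALSE)
  all_das <- sort(unique(dat$DAS))
  if (is.null(das)) das <- all_das else das <- intersect(das, all_das)
  scans <- lapply(das, function(d) {
    ph <- .line_means(dat, trait, d)
    genome_scan(geno, ph, grouping = grouping, min_het = min_het)
  })
  names(scans) <- das
  traj <- do.call(rbind, lapply(seq_along(das), function(i) {
    s <- scans[[i]]
    data.frame(DAS = das[i], marker = s$marker, chr = s$chr, cM = s$cM,
               bp = s$bp, neg_log10_p = s$neg_log10_p, marker_h2 = s$marker_h2,
               stringsAsFactors = FALSE)
  }))
  rownames(traj) <- NULL
  structure(list(scans = scans, trajectory = traj, trait = trait),
            class = "longitudinal_scan")
}

#' Genome scans of fitted curve/mixture parameters
#'
#' Treats each fitted parameter as a quantitative trait: non-converged fits
#' are dropped, replicates are averaged per line, and [genome_scan()] is run
#' per parameter.
#'
#' @param param_table data.frame with columns line, rep, `converged` and one
#'   column per parameter (from [fit_trait_curves()] or
#'   [fit_trait_mixtures()]).
#' @param geno genotype object.
#' @param params parameter columns to scan (default: numeric columns other
#'   than bookkeeping).
#' @inheritParams genome_scan
#' @return named list of `marker_scan` data.frames, one per parameter.
#' @export
parameter_scan <- function(param_table, geno, params = NULL,
                           grouping = "genotype", min_het = 3L) {
  if ("converged" %in% names(param_table))
    param_table <- param_table[param_table$converged %in% TRUE, ]
  if (nrow(param_table) == 0) stop("parameter_scan: no converged fits", call. = FALSE)
  if (is.null(params)) {
    skip <- c("rep", "r_squared", "n_points", "loglik")
    params <- setdiff(names(param_table)[vapply(param_table, is.numeric, TRUE)], skip)
  }
  out <- lapply(params, function(p) {
    ph <- tapply(param_table[[p]], param_table$line, mean, na.rm = TRUE)
    ph <- ph[is.finite(ph)]
    genome_scan(geno, ph, grouping = grouping, min_het = min_het)
  })
  names(out) <- params
  out
}

#' Per-timepoint regression of a trait on one marker
#'
#' For each DAS, ordinary least squares of the line-mean trait value on the
#' marker's allele dose (A = 0, H = 1, B = 2): the per-allele effect size, its
#' standard error and p-value form a trajectory over time.
#'
#' @param series long data.frame (line, rep, DAS, trait, value).
#' @param geno genotype object.
#' @param marker marker id (must be polymorphic among the scanned lines).
#' @param trait trait name.
#' @return data.frame: DAS, slope, se, p, n.
#' @export
marker_effect_regression <- function(series, geno, marker, trait) {
  if (!marker %in% colnames(geno$genotypes))
    stop("marker_effect_regression: unknown marker '", marker, "'", call. = FALSE)
  dat <- series[series$trait == trait, ]
  dose_all <- c(A = 0, H = 1, B = 2)[geno$genotypes[, marker]]
  names(dose_all) <- rownames(geno$genotypes)
  res <- lapply(sort(unique(dat$DAS)), function(d) {
    ph <- .line_means(dat, trait, d)
    lines <- intersect(names(ph), names(dose_all))
    y <- ph[lines]; x <- dose_all[lines]
    keep <- is.finite(y) & is.finite(x)
    y <- y[keep]; x <- x[keep]
    if (length(unique(x)) < 2)
      stop("marker_effect_regression: marker '", marker, "' is monomorphic",
           call. = FALSE)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    resid <- y - mean(y) - slope * (x - mean(x))
    df <- length(y) - 2
    se <- sqrt(sum(resid^2) / df / sxx)
    tval <- slope / se
    data.frame(DAS = d, slope = slope, se = se,
               p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
               n = length(y))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
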