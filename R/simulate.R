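#' Simulation configuration for a MAGIC RIL experiment
#'
#' Bundles every knob of the synthetic multiparental experiment: the marker
#' panel, the crossing design, the longitudinal trait models and their noise
#' structure, and the QTL effects planted on latent curve parameters.
#'
#' The defaults emulate an eight-founder MAGIC wheat population of 208
#' recombinant inbred lines (RILs) grown in two replicates and imaged daily
#' between 90 and 200 days after sowing (DAS). Area, Height and TYP.Area
#' (senescence) trajectories follow a 4-parameter logistic curve; water_amount
#' follows a two-component Gaussian curve with modes near 130 and 180 DAS.
#'
#' @param seed integer seed; all simulator randomness derives from it.
#' @param n_lines number of RILs (default 208).
#' @param n_reps replicates per line (default 2).
#' @param n_founders number of founder varieties (default 8).
#' @param n_chr number of chromosomes.
#' @param markers_per_chr markers per chromosome.
#' @param chr_length_cM genetic length of each chromosome in centimorgans.
#' @param founder_maf minimum minor-allele share among founders at each marker,
#'   in (0, 0.5]. 0.5 forces a balanced 4/4 split with 8 founders.
#' @param selfing_generations rounds of selfing after the funnel (default 5).
#' @param n_intercross extra intercross generations between the final funnel
#'   cross and selfing (default 0: the three funnel crosses are the three
#'   cycles of recombination).
#' @param timepoints integer DAS grid on which traits are observed.
#' @param qtl list of planted QTL effects; each element is a list with fields
#'   `trait`, `marker`, `param` and `effects` (numeric vector of per-founder
#'   additive effects, length `n_founders`). See [qtl_effect()].
#' @param baseline named list: per trait, named vector of true baseline curve
#'   parameters (4PL `A`,`B`,`C`,`D`; water mixture `mu1`,`lam1`,`sigma1`,
#'   `mu2`,`lam2`,`sigma2`).
#' @param genetic_sd named list: per trait, named vector of line-level genetic
#'   (polygenic) standard deviations per curve parameter. Shared by replicates.
#' @param env_sd named list: per trait, named vector of per-replicate
#'   environmental standard deviations per curve parameter.
#' @param obs_sd named vector of per-trait observation-noise standard
#'   deviations (trait units).
#' @return object of class `magic_sim_config` (a validated list).
#' @export
magic_sim_config <- function(seed = 1L,
                             n_lines = 208L,
                             n_reps = 2L,
                             n_founders = 8L,
                             n_chr = 3L,
                             markers_per_chr = 40L,
                             chr_length_cM = 150,
                             founder_maf = 0.25,
                             selfing_generations = 5L,
                             n_intercross = 0L,
                             timepoints = seq(90L, 200L, by = 4L),
                             qtl = list(),
                             baseline = NULL,
                             genetic_sd = NULL,
                             env_sd = NULL,
                             obs_sd = NULL) {
  if (n_founders < 2) stop("config error: need at least 2 founders", call. = FALSE)
  if (n_chr < 1 || markers_per_chr < 2)
    stop("config error: need >= 1 chromosome with >= 2 markers", call. = FALSE)
  if (founder_maf <= 0 || founder_maf > 0.5)
    stop("config error: founder_maf must be in (0, 0.5]", call. = FALSE)
  if (n_lines < 1 || n_reps < 1 || selfing_generations < 0 || n_intercross < 0)
    stop("config error: invalid design dimensions", call. = FALSE)
  if (length(timepoints) < 1 || any(timepoints <= 0))
    stop("config error: timepoints must be positive DAS values", call. = FALSE)

  baseline   <- .merge_defaults(baseline, .default_baseline())
  genetic_sd <- .merge_defaults(genetic_sd, .default_genetic_sd())
  env_sd     <- .merge_defaults(env_sd, .default_env_sd())
  if (is.null(obs_sd)) obs_sd <- .default_obs_sd()
  if (any(unlist(genetic_sd) < 0) || any(unlist(env_sd) < 0) || any(obs_sd < 0))
    stop("config error: standard deviations must be >= 0", call. = FALSE)
  for (q in qtl) {
    if (!all(c("trait", "marker", "param", "effects") %in% names(q)))
      stop("config error: each qtl entry needs trait, marker, param, effects",
           call. = FALSE)
    if (length(q$effects) != n_founders)
      stop("config error: qtl effects must have one entry per founder", call. = FALSE)
  }

  structure(list(
    seed = as.integer(seed), n_lines = as.integer(n_lines),
    n_reps = as.integer(n_reps), n_founders = as.integer(n_founders),
    n_chr = as.integer(n_chr), markers_per_chr = as.integer(markers_per_chr),
    chr_length_cM = chr_length_cM, founder_maf = founder_maf,
    selfing_generations = as.integer(selfing_generations),
    n_intercross = as.integer(n_intercross),
    timepoints = as.integer(timepoints), qtl = qtl,
    baseline = baseline, genetic_sd = genetic_sd, env_sd = env_sd,
    obs_sd = obs_sd
  ), class = "magic_sim_config")
}

#' Describe a planted QTL effect on a latent curve parameter
#'
#' @param trait trait name the effect acts on.
#' @param marker marker id at which the causal variant sits.
#' @param param name of the curve parameter the effect shifts.
#' @param effects numeric vector of additive effects, one per founder, in
#'   trait-parameter units. A line's genetic value gains the mean of the
#'   effects of the two founder haplotypes it carries at the marker.
#' @return list suitable for the `qtl` field of [magic_sim_config()].
#' @export
qtl_effect <- function(trait, marker, param, effects) {
  list(trait = trait, marker = marker, param = param, effects = effects)
}

.merge_defaults <- function(user, defaults) {
  if (is.null(user)) return(defaults)
  for (nm in names(user)) {
    if (is.null(defaults[[nm]])) defaults[[nm]] <- user[[nm]]
    else {
      d <- defaults[[nm]]
      d[names(user[[nm]])] <- user[[nm]]
      defaults[[nm]] <- d
    }
  }
  defaults
}

# Baselines chosen to match the scale of glasshouse wheat phenomics data:
# plant area levelling off near 8.5e4 mm^2 around 130 DAS, height near 700 mm,
# senescent (yellow) area rising late, and daily water use with modes near
# 130 and 180 DAS totalling ~12 l over the experiment.
.default_baseline <- function() list(
  Area         = c(A = 2000, B = 11,  C = 130, D = 85000),
  Height       = c(A = 100,  B = 6.5, C = 120, D = 700),
  TYP.Area     = c(A = 100,  B = 10,  C = 165, D = 30000),
  water_amount = c(mu1 = 130, lam1 = 5500, sigma1 = 10,
                   mu2 = 180, lam2 = 6500, sigma2 = 12)
)

.default_genetic_sd <- function() list(
  Area         = c(A = 300, B = 0.8, C = 4, D = 6000),
  Height       = c(A = 15,  B = 0.5, C = 4, D = 50),
  TYP.Area     = c(A = 20,  B = 0.7, C = 4, D = 2500),
  water_amount = c(mu1 = 2, lam1 = 250, sigma1 = 0.8,
                   mu2 = 2, lam2 = 250, sigma2 = 0.8)
)

.default_env_sd <- function() list(
  Area         = c(A = 300, B = 0.5, C = 3, D = 4000),
  Height       = c(A = 15,  B = 0.4, C = 3, D = 35),
  TYP.Area     = c(A = 20,  B = 0.7, C = 4, D = 2500),
  water_amount = c(mu1 = 3, lam1 = 350, sigma1 = 1.2,
                   mu2 = 3, lam2 = 350, sigma2 = 1.2)
)

.default_obs_sd <- function() c(
  Area = 1500, Height = 12, TYP.Area = 700, water_amount = 8
)

.founder_names <- function(n) {
  niab <- c("Alchemy", "Brompton", "Claire", "Hereward",
            "Rialto", "Robigus", "Soissons", "Xi19")
  if (n <= 8) niab[seq_len(n)] else c(niab, paste0("F", 9:n))[seq_len(n)]
}

#' Simulate a founder panel: marker map and founder alleles
#'
#' Lays out `n_chr` chromosomes of `markers_per_chr` biallelic markers with
#' strictly increasing cM (and proportional bp) positions, and assigns each
#' founder an allele at every marker such that the minor-allele share among
#' founders is at least `founder_maf`.
#'
#' @param config a [magic_sim_config()].
#' @return object of class `founder_panel`: list with `map` (data.frame of
#'   marker, chr, cM, bp), `alleles` (founder x marker character matrix of
#'   "A"/"B" codes) and `founders` (names).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "magic_sim_config"))
  set.seed(config$seed)
  nf <- config$n_founders
  m  <- config$markers_per_chr
  maps <- lapply(seq_len(config$n_chr), function(ch) {
    gaps <- stats::runif(m, 0.5, 1.5)
    cm <- cumsum(gaps) / sum(gaps) * config$chr_length_cM
    data.frame(
      marker = sprintf("M%d_%03d", ch, seq_len(m)),
      chr = paste0("chr", ch),
      cM = cm,
      bp = as.integer(round(cm * 1e6)) + 1L,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, maps)
  founders <- .founder_names(nf)

  k_lo <- max(1L, ceiling(config$founder_maf * nf))
  k_hi <- nf - k_lo
  if (k_hi < k_lo) stop("config error: founder_maf too high for panel size", call. = FALSE)
  alleles <- matrix("A", nrow = nf, ncol = nrow(map),
                    dimnames = list(founders, map$marker))
  for (j in seq_len(nrow(map))) {
    k <- if (k_lo == k_hi) k_lo else sample(k_lo:k_hi, 1L)
    alleles[sample.int(nf, k), j] <- "B"
  }
  structure(list(map = map, alleles = alleles, founders = founders),
            class = "founder_panel")
}

# Recombination fractions between adjacent markers under the Haldane map
# function (no interference): r = (1 - exp(-2d/100)) / 2 for d in cM.
.haldane <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# A gamete from an individual (two founder-origin haplotypes) is produced per
# chromosome by a Markov walk over marker intervals: the starting homologue is
# chosen with probability 1/2 and switches between adjacent markers with the
# Haldane recombination fraction. Exact at marker resolution under no
# interference.
.gamete <- function(h1, h2, chr_index, rec) {
  out <- integer(length(h1))
  for (ci in seq_along(chr_index)) {
    idx <- chr_index[[ci]]
    nm <- length(idx)
    start <- stats::runif(1) < 0.5
    switches <- if (nm > 1) stats::runif(nm - 1) < rec[[ci]] else logical(0)
    on_h1 <- (cumsum(c(start, switches)) %% 2) == 1
    out[idx] <- ifelse(on_h1, h1[idx], h2[idx])
  }
  out
}

.cross <- function(p1, p2, chr_index, rec) {
  list(.gamete(p1[[1]], p1[[2]], chr_index, rec),
       .gamete(p2[[1]], p2[[2]], chr_index, rec))
}

# One funnel individual: founders (in the order of `perm`) are paired and
# crossed, then the crosses are paired and crossed, until a single individual
# carries all founders. With 8 founders this is the standard 2-way -> 4-way ->
# 8-way funnel, i.e. three cycles of recombination.
.funnel_individual <- function(perm, n_markers, chr_index, rec) {
  inds <- lapply(perm, function(f) list(rep.int(f, n_markers), rep.int(f, n_markers)))
  while (length(inds) > 1) {
    nxt <- list()
    i <- 1L
    while (i + 1L <= length(inds)) {
      nxt[[length(nxt) + 1L]] <- .cross(inds[[i]], inds[[i + 1L]], chr_index, rec)
      i <- i + 2L
    }
    if (i == length(inds)) nxt[[length(nxt) + 1L]] <- inds[[i]]
    inds <- nxt
  }
  inds[[1L]]
}

#' Simulate MAGIC recombinant inbred lines from a founder panel
#'
#' Each line descends from an independent funnel (founder order randomly
#' permuted per line), optionally followed by `n_intercross` generations of
#' crossing to an independent funnel individual, then `selfing_generations`
#' rounds of selfing. Founder origin is tracked per homologue at every marker;
#' the observed genotype is the carried founders' allele ("H" where the two
#' homologues carry different alleles).
#'
#' Residual heterozygosity (fraction of markers at which the two homologues
#' descend from different founders) has expectation (1/2)^selfing_generations
#' under the default funnel design.
#'
#' @param panel a [simulate_founders()] panel.
#' @param config the same [magic_sim_config()].
#' @return object of class `ril_population`: list with `genotypes`
#'   (line x marker character matrix, "A"/"B"/"H"), `hap1`/`hap2`
#'   (line x marker integer founder indices), `founder_origin` (consensus
#'   founder index, NA where the homologues disagree), `residual_het`
#'   (per-line fraction), plus the panel's `map`, `alleles`, `founders`.
#' @export
simulate_magic_rils <- function(panel, config) {
  stopifnot(inherits(panel, "founder_panel"), inherits(config, "magic_sim_config"))
  set.seed(config$seed + 1L)
  map <- panel$map
  M <- nrow(map)
  chrs <- unique(map$chr)
  chr_index <- lapply(chrs, function(ch) which(map$chr == ch))
  rec <- lapply(chr_index, function(idx) .haldane(diff(map$cM[idx])))
  nf <- config$n_founders
  nl <- config$n_lines

  hap1 <- matrix(NA_integer_, nl, M)
  hap2 <- matrix(NA_integer_, nl, M)
  for (i in seq_len(nl)) {
    ind <- .funnel_individual(sample.int(nf), M, chr_index, rec)
    for (g in seq_len(config$n_intercross)) {
      other <- .funnel_individual(sample.int(nf), M, chr_index, rec)
      ind <- .cross(ind, other, chr_index, rec)
    }
    for (s in seq_len(config$selfing_generations)) {
      ind <- .cross(ind, ind, chr_index, rec)
    }
    hap1[i, ] <- ind[[1L]]
    hap2[i, ] <- ind[[2L]]
  }
  lines <- sprintf("RIL%03d", seq_len(nl))
  dimnames(hap1) <- dimnames(hap2) <- list(lines, map$marker)

  a1 <- matrix(panel$alleles[cbind(as.vector(hap1), rep(seq_len(M), each = nl))], nl, M)
  a2 <- matrix(panel$alleles[cbind(as.vector(hap2), rep(seq_len(M), each = nl))], nl, M)
  genotypes <- a1
  genotypes[a1 != a2] <- "H"
  dimnames(genotypes) <- list(lines, map$marker)

  origin <- hap1
  origin[hap1 != hap2] <- NA_integer_
  residual_het <- rowMeans(hap1 != hap2)
  names(residual_het) <- lines

  structure(list(
    genotypes = genotypes, hap1 = hap1, hap2 = hap2,
    founder_origin = origin, residual_het = residual_het,
    map = map, alleles = panel$alleles, founders = panel$founders,
    lines = lines
  ), class = "ril_population")
}

.trait_model <- function(trait) {
  if (trait == "water_amount") "mixture" else "fourpl"
}

.eval_trait_curve <- function(trait, params, t) {
  if (.trait_model(trait) == "mixture") {
    params[["lam1"]] * stats::dnorm(t, params[["mu1"]], params[["sigma1"]]) +
      params[["lam2"]] * stats::dnorm(t, params[["mu2"]], params[["sigma2"]])
  } else {
    eval_4pl(params[["A"]], params[["B"]], params[["C"]], params[["D"]], t)
  }
}

#' Simulate longitudinal trait observations for a RIL population
#'
#' Each line's genetic curve parameters are the trait baseline plus planted
#' QTL effects (keyed by the founder haplotypes carried at each QTL marker;
#' heterozygous positions contribute the mean of the two founder effects) plus
#' a line-level polygenic deviation. Each replicate adds an independent
#' environmental deviation to the parameters and independent Gaussian
#' observation noise to every timepoint. Negative generated values are floored
#' at 0 and counted.
#'
#' @param pop a [simulate_magic_rils()] population.
#' @param config the same [magic_sim_config()].
#' @param trait one of the configured trait names.
#' @return list with `series` (data.frame line, rep, DAS, trait, value),
#'   `truth_genetic` (per-line true genetic parameters), `truth_realized`
#'   (per line x rep realized parameters) and `n_floored`.
#' @export
simulate_trait_series <- function(pop, config, trait) {
  stopifnot(inherits(pop, "ril_population"), inherits(config, "magic_sim_config"))
  if (is.null(config$baseline[[trait]]))
    stop("config error: no baseline parameters for trait '", trait, "'", call. = FALSE)
  traits <- names(config$baseline)
  set.seed(config$seed + 10L + match(trait, traits))

  base <- config$baseline[[trait]]
  pnames <- names(base)
  gsd <- config$genetic_sd[[trait]][pnames]
  esd <- config$env_sd[[trait]][pnames]
  gsd[is.na(gsd)] <- 0
  esd[is.na(esd)] <- 0
  osd <- unname(config$obs_sd[trait])
  if (is.na(osd)) osd <- 0
  nl <- length(pop$lines)
  P <- length(pnames)

  G <- matrix(rep(base, each = nl), nl, P, dimnames = list(pop$lines, pnames))
  for (q in config$qtl) {
    if (!identical(q$trait, trait)) next
    if (!q$marker %in% colnames(pop$genotypes))
      stop("config error: qtl marker '", q$marker, "' not in panel", call. = FALSE)
    if (!q$param %in% pnames)
      stop("config error: qtl param '", q$param, "' not a parameter of ", trait, call. = FALSE)
    eff <- (q$effects[pop$hap1[, q$marker]] + q$effects[pop$hap2[, q$marker]]) / 2
    G[, q$param] <- G[, q$param] + eff
  }
  G <- G + sweep(matrix(stats::rnorm(nl * P), nl, P), 2, gsd, `*`)

  t <- config$timepoints
  nt <- length(t)
  n_floored <- 0L
  rows <- vector("list", config$n_reps)
  truth_rl <- vector("list", config$n_reps)
  for (r in seq_len(config$n_reps)) {
    R <- G + sweep(matrix(stats::rnorm(nl * P), nl, P), 2, esd, `*`)
    vals <- matrix(NA_real_, nl, nt)
    for (i in seq_len(nl)) vals[i, ] <- .eval_trait_curve(trait, R[i, ], t)
    vals <- vals + matrix(stats::rnorm(nl * nt, sd = osd), nl, nt)
    n_floored <- n_floored + sum(vals < 0)
    vals[vals < 0] <- 0
    rows[[r]] <- data.frame(
      line = rep(pop$lines, times = nt),
      rep = r,
      DAS = rep(t, each = nl),
      trait = trait,
      value = as.vector(vals),
      stringsAsFactors = FALSE
    )
    truth_rl[[r]] <- data.frame(line = pop$lines, rep = r, as.data.frame(R),
                                stringsAsFactors = FALSE, row.names = NULL)
  }
  series <- do.call(rbind, rows)
  series <- series[order(series$line, series$rep, series$DAS), ]
  rownames(series) <- NULL
  if (n_floored > 0)
    message("simulate_trait_series: floored ", n_floored, " negative values at 0")
  list(series = series,
       truth_genetic = data.frame(line = pop$lines, as.data.frame(G),
                                  stringsAsFactors = FALSE, row.names = NULL),
       truth_realized = do.call(rbind, truth_rl),
       n_floored = n_floored)
}

#' Simulate a full MAGIC experiment (genotypes + all trait series)
#'
#' Convenience wrapper running [simulate_founders()], [simulate_magic_rils()]
#' and [simulate_trait_series()] for every configured trait.
#'
#' @param config a [magic_sim_config()].
#' @param traits traits to simulate (default: all with baselines).
#' @return list with `panel`, `pop`, `series` (one combined data.frame),
#'   `truth` (per-trait list of truth tables).
#' @export
simulate_magic_experiment <- function(config, traits = names(config$baseline)) {
  panel <- simulate_founders(config)
  pop <- simulate_magic_rils(panel, config)
  sims <- lapply(traits, function(tr) simulate_trait_series(pop, config, tr))
  names(sims) <- traits
  series <- do.call(rbind, lapply(sims, `[[`, "series"))
  rownames(series) <- NULL
  list(panel = panel, pop = pop, series = series,
       truth = lapply(sims, function(s) s[c("truth_genetic", "truth_realized")]))
}
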