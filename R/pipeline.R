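#' Assemble a pipeline configuration
#'
#' Exactly one of `simulate` (a [magic_sim_config()]) or the pair
#' `genotype_file` / `phenotype_file` must be supplied. Defaults mirror the
#' study settings: B = 1000 permutations, `-log10 p` cutoff 4, alpha 0.05.
#'
#' @param out_dir output directory (created if needed).
#' @param simulate optional [magic_sim_config()] for simulate mode.
#' @param genotype_file,phenotype_file input paths for data mode.
#' @param traits traits to analyse (default: those present / configured).
#' @param seed integer master seed for the scan permutations.
#' @param permutations permutation count B.
#' @param logp_cutoff,alpha QTL-call thresholds.
#' @param grouping `"genotype"` or `"founder"` marker grouping.
#' @param scan_das optional subset of DAS values for the per-timepoint scans
#'   (default: every retained DAS).
#' @param cooks list of Cook's-distance options: `multiplier`, `degree`,
#'   `max_frac`.
#' @param mixture_backend `"em"` or `"nls"` for the water-use fit.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = NULL,
                            genotype_file = NULL, phenotype_file = NULL,
                            traits = NULL,
                            seed = 1L,
                            permutations = 1000L,
                            logp_cutoff = 4, alpha = 0.05,
                            grouping = c("genotype", "founder"),
                            scan_das = NULL,
                            cooks = list(multiplier = 4, degree = 3L, max_frac = 0.05),
                            mixture_backend = "em") {
  grouping <- match.arg(grouping)
  sim_mode <- !is.null(simulate)
  file_mode <- !is.null(genotype_file) || !is.null(phenotype_file)
  if (sim_mode == file_mode)
    stop("pipeline_config: supply exactly one of simulate or input files", call. = FALSE)
  if (file_mode && (is.null(genotype_file) || is.null(phenotype_file)))
    stop("pipeline_config: both genotype_file and phenotype_file are required", call. = FALSE)
  structure(list(out_dir = out_dir, simulate = simulate,
                 genotype_file = genotype_file, phenotype_file = phenotype_file,
                 traits = traits, seed = as.integer(seed),
                 permutations = as.integer(permutations),
                 logp_cutoff = logp_cutoff, alpha = alpha, grouping = grouping,
                 scan_das = scan_das, cooks = cooks,
                 mixture_backend = mixture_backend),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML mirrors the arguments of [pipeline_config()]; a `simulate` block
#' mirrors [magic_sim_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) do.call(magic_sim_config, y$simulate)
  args <- y[setdiff(names(y), "simulate")]
  args$simulate <- sim
  do.call(pipeline_config, args)
}

#' Run the full functional-mapping pipeline
#'
#' Stages: acquire data (simulate or read) -> validate -> clean (timepoint
#' completeness, Cook's-distance outliers) -> fit growth curves and the
#' water-use mixture -> heritability and correlation report -> per-timepoint
#' and per-parameter genome scans with permutation thresholds -> QTL call
#' list. All tables are written as CSV under `config$out_dir` together with a
#' JSON run manifest; outputs are byte-identical across runs with the same
#' configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the manifest and the in-memory stage
#'   outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("growthqtl")),
                   seed = config$seed, permutations = config$permutations,
                   grouping = config$grouping, stages = list())
  manifest_path <- file.path(config$out_dir, "manifest.json")
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "error", message = conditionMessage(e))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  # -- stage: data ----------------------------------------------------------
  sim <- NULL
  if (!is.null(config$simulate)) {
    sim <- tryCatch(simulate_magic_experiment(config$simulate),
                    error = function(e) fail("data", e))
    geno <- sim$pop
    series <- sim$series
    write_genotypes(geno, file.path(config$out_dir, "genotypes.tsv"))
    write_phenotypes(series, file.path(config$out_dir, "phenotypes.csv"))
    for (tr in names(sim$truth)) {
      utils::write.csv(sim$truth[[tr]]$truth_genetic,
                       file.path(config$out_dir, paste0("truth_", gsub("[^A-Za-z0-9]", "_", tr), ".csv")),
                       row.names = FALSE)
    }
  } else {
    geno <- tryCatch(read_genotypes(config$genotype_file), error = function(e) fail("data", e))
    series <- tryCatch(read_phenotypes(config$phenotype_file), error = function(e) fail("data", e))
  }
  traits <- config$traits %||% unique(series$trait)
  missing_traits <- setdiff(traits, unique(series$trait))
  if (length(missing_traits))
    fail("data", simpleError(paste("trait(s) not in phenotype table:",
                                   paste(missing_traits, collapse = ", "))))
  manifest$stages$data <- list(status = "ok", n_lines = nrow(geno$genotypes),
                               n_markers = ncol(geno$genotypes),
                               n_records = nrow(series), traits = traits)

  # -- stage: validate ------------------------------------------------------
  report <- validate_inputs(geno, series)
  utils::write.csv(report, file.path(config$out_dir, "validation.csv"), row.names = FALSE)
  if (any(report$severity == "fatal"))
    fail("validate", simpleError(paste(report$message[report$severity == "fatal"],
                                       collapse = "; ")))
  manifest$stages$validate <- list(status = "ok", n_warnings = sum(report$severity == "warning"))

  # -- stage: clean ---------------------------------------------------------
  roster <- intersect(rownames(geno$genotypes), unique(series$line))
  series <- series[series$line %in% roster, ]
  flt <- tryCatch(filter_incomplete_timepoints(series, roster),
                  error = function(e) fail("clean", e))
  cleaned <- flt$series
  cooks_reports <- list()
  for (tr in traits) {
    ck <- remove_cooks_outliers(cleaned, tr,
                                multiplier = config$cooks$multiplier,
                                degree = config$cooks$degree,
                                max_frac = config$cooks$max_frac)
    cleaned <- ck$series
    cooks_reports[[tr]] <- ck$report
  }
  outliers <- do.call(rbind, cooks_reports)
  rownames(outliers) <- NULL
  write_phenotypes(cleaned, file.path(config$out_dir, "phenotypes_clean.csv"))
  jsonlite::write_json(
    list(dropped_timepoints = flt$report$dropped_timepoints,
         n_outliers_removed = nrow(outliers),
         cooks = config$cooks),
    file.path(config$out_dir, "cleaning_report.json"), auto_unbox = TRUE, pretty = TRUE)
  utils::write.csv(outliers, file.path(config$out_dir, "outliers.csv"), row.names = FALSE)
  manifest$stages$clean <- list(status = "ok",
                                dropped_timepoints = flt$report$dropped_timepoints,
                                n_outliers = nrow(outliers),
                                n_records = nrow(cleaned))

  # -- stage: fit -----------------------------------------------------------
  curve_traits <- setdiff(traits, "water_amount")
  param_tables <- list()
  for (tr in curve_traits) {
    tab <- tryCatch(fit_trait_curves(cleaned, tr, model = "fourpl"),
                    error = function(e) fail("fit", e))
    param_tables[[tr]] <- tab
    utils::write.csv(tab, file.path(config$out_dir,
                                    paste0("params_", gsub("[^A-Za-z0-9]", "_", tr), ".csv")),
                     row.names = FALSE)
  }
  if ("water_amount" %in% traits) {
    tab <- tryCatch(fit_trait_mixtures(cleaned, "water_amount",
                                       backend = config$mixture_backend),
                    error = function(e) fail("fit", e))
    param_tables[["water_amount"]] <- tab
    utils::write.csv(tab, file.path(config$out_dir, "params_water_amount.csv"),
                     row.names = FALSE)
  }
  manifest$stages$fit <- list(
    status = "ok",
    n_converged = vapply(param_tables, function(x) sum(x$converged %in% TRUE), 0))

  # -- stage: quantgen ------------------------------------------------------
  herit <- list()
  for (tr in names(param_tables)) {
    tab <- param_tables[[tr]]
    tab <- tab[tab$converged %in% TRUE, ]
    if (nrow(tab) < 4) next
    h <- heritability_table(tab)
    if (is.null(h)) next
    h$trait <- tr
    herit[[tr]] <- h
    cm <- correlation_matrices(tab)
    utils::write.csv(as.data.frame(cm$r_g),
                     file.path(config$out_dir, paste0("corr_genetic_", gsub("[^A-Za-z0-9]", "_", tr), ".csv")))
    utils::write.csv(as.data.frame(cm$r_e),
                     file.path(config$out_dir, paste0("corr_environment_", gsub("[^A-Za-z0-9]", "_", tr), ".csv")))
  }
  herit_tab <- do.call(rbind, herit)
  rownames(herit_tab) <- NULL
  utils::write.csv(herit_tab, file.path(config$out_dir, "heritability.csv"), row.names = FALSE)
  manifest$stages$quantgen <- list(status = "ok", n_parameters = nrow(herit_tab))

  # -- stage: scan ----------------------------------------------------------
  all_calls <- list()
  trajs <- list()
  seed_i <- config$seed
  for (tr in traits) {
    ls <- tryCatch(longitudinal_scan(cleaned, geno, tr, das = config$scan_das,
                                     grouping = config$grouping),
                   error = function(e) fail("scan", e))
    trajs[[tr]] <- cbind(trait = tr, ls$trajectory)
    for (d in names(ls$scans)) {
      seed_i <- seed_i + 1L
      ph <- .line_means(cleaned, tr, as.numeric(d))
      perm <- permutation_test(geno, ph, B = config$permutations, seed = seed_i,
                               grouping = config$grouping)
      calls <- call_qtls(ls$scans[[d]], perm, logp_cutoff = config$logp_cutoff,
                         alpha = config$alpha)
      if (nrow(calls))
        all_calls[[length(all_calls) + 1L]] <- cbind(trait = tr, context = paste0("DAS", d), calls)
    }
  }
  for (tr in names(param_tables)) {
    pscan <- tryCatch(parameter_scan(param_tables[[tr]], geno,
                                     grouping = config$grouping),
                      error = function(e) fail("scan", e))
    for (p in names(pscan)) {
      seed_i <- seed_i + 1L
      tab <- param_tables[[tr]]
      tab <- tab[tab$converged %in% TRUE, ]
      ph <- tapply(tab[[p]], tab$line, mean, na.rm = TRUE)
      ph <- ph[is.finite(ph)]
      perm <- tryCatch(permutation_test(geno, ph, B = config$permutations,
                                        seed = seed_i, grouping = config$grouping),
                       error = function(e) NULL)
      if (is.null(perm)) next
      calls <- call_qtls(pscan[[p]], perm, logp_cutoff = config$logp_cutoff,
                         alpha = config$alpha)
      if (nrow(calls))
        all_calls[[length(all_calls) + 1L]] <- cbind(trait = tr, context = paste0("param_", p), calls)
      utils::write.csv(pscan[[p]],
                       file.path(config$out_dir,
                                 paste0("scan_", gsub("[^A-Za-z0-9]", "_", tr), "_", p, ".csv")),
                       row.names = FALSE)
    }
  }
  traj_tab <- do.call(rbind, trajs)
  rownames(traj_tab) <- NULL
  utils::write.csv(traj_tab, file.path(config$out_dir, "scan_trajectories.csv"),
                   row.names = FALSE)
  call_tab <- if (length(all_calls)) do.call(rbind, all_calls) else
    data.frame(trait = character(0), context = character(0), marker = character(0),
               chr = character(0), cM = numeric(0), bp = integer(0),
               neg_log10_p = numeric(0), empirical_p = numeric(0),
               lower = integer(0), upper = integer(0), passes_cutoff = logical(0))
  rownames(call_tab) <- NULL
  utils::write.csv(call_tab, file.path(config$out_dir, "qtl_calls.csv"), row.names = FALSE)
  manifest$stages$scan <- list(status = "ok", n_calls = nrow(call_tab),
                               n_passing = sum(call_tab$passes_cutoff))

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, genotypes = geno, series = cleaned,
                 params = param_tables, heritability = herit_tab,
                 trajectories = traj_tab, calls = call_tab))
}
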