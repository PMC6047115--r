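test_that("single-marker ANOVA matches hand-worked tables", {
  res <- single_marker_anova(c(1, 2, 3, 4, 5, 6),
                             c("a", "a", "a", "b", "b", "b"))
  expect_equal(res$F, 13.5)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)
  expect_equal(res$p, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(res$group_means, c(a = 2, b = 5))
  # equal group means, positive within-group variance: F = 0
  res0 <- single_marker_anova(c(1, 3, 1, 3), c("a", "a", "b", "b"))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  expect_error(single_marker_anova(c(1, 2), c("a", "b")), "residual df")
  expect_error(single_marker_anova(c(1, 2, 3), c("a", "a", "a")), "classes")
})

test_that("ANOVA agrees with the brute-force oracle on random configurations", {
  set.seed(101)
  for (i in 1:15) {
    k <- sample(2:5, 1)
    groups <- rep(letters[1:k], times = sample(2:8, k, replace = TRUE))
    values <- rnorm(length(groups), mean = as.integer(factor(groups)))
    res <- single_marker_anova(values, groups)
    orc <- anova_oracle(values, groups)
    expect_equal(res$F, orc$F, tolerance = 1e-10)
    expect_equal(res$p, orc$p, tolerance = 1e-10)
  }
})

test_that("F increases monotonically with a planted group effect", {
  set.seed(103)
  base <- rnorm(30)
  groups <- rep(c("a", "b", "c"), each = 10)
  Fs <- vapply(c(0, 0.5, 1, 2, 4), function(d) {
    v <- base + d * (groups == "c")
    single_marker_anova(v, groups)$F
  }, 1)
  expect_true(all(diff(Fs) > 0))
})

test_that("marker variance explained is bounded and exact in the no-noise limit", {
  set.seed(105)
  groups <- rep(c("a", "b"), each = 10)
  res <- single_marker_anova(rnorm(20) + (groups == "b"), groups)
  expect_gte(res$h2, 0)
  expect_lte(res$h2, 1)
  res1 <- single_marker_anova(c(rep(1, 10), rep(2, 10)), groups)
  expect_equal(res1$h2, 1)
})

test_that("genome scans report every informative marker with exact -log10 p", {
  geno <- toy_geno(n_lines = 60, n_markers = 8)
  set.seed(107)
  ph <- setNames(rnorm(60) + 2 * (geno$genotypes[, "mk03"] == "B"),
                 rownames(geno$genotypes))
  scan <- genome_scan(geno, ph)
  expect_s3_class(scan, "marker_scan")
  expect_equal(nrow(scan), 8)
  expect_equal(scan$neg_log10_p, -log10(scan$p))
  expect_equal(which.max(scan$F), 3)
  expect_true(all(scan$p > 0 & scan$p <= 1))
  # group means by class are plain within-class averages
  m3 <- scan[3, ]
  expect_equal(m3$mean_B, mean(ph[geno$genotypes[, "mk03"] == "B"]))
})

test_that("founder-origin grouping reproduces per-founder means", {
  cfg <- small_config(seed = 109, n_lines = 120)
  pop <- simulate_magic_rils(simulate_founders(cfg), cfg)
  set.seed(1)
  ph <- setNames(rnorm(120), pop$lines)
  scan <- genome_scan(pop, ph, grouping = "founder")
  j <- which(is.finite(scan$F))[1]
  fo <- pop$founder_origin[, scan$marker[j]]
  for (f in seq_along(pop$founders)) {
    idx <- which(fo == f)
    if (length(idx) == 0) next
    expect_equal(scan[[paste0("mean_", pop$founders[f])]][j], mean(ph[idx]))
  }
})

test_that("permutation results are deterministic and detect strong signals", {
  geno <- toy_geno(n_lines = 80, n_markers = 10, seed = 7)
  set.seed(111)
  ph <- setNames(rnorm(80, sd = 0.2) + 3 * (geno$genotypes[, "mk05"] == "B"),
                 rownames(geno$genotypes))
  p1 <- permutation_test(geno, ph, B = 60, seed = 5)
  p2 <- permutation_test(geno, ph, B = 60, seed = 5)
  expect_identical(p1$null_max_stats, p2$null_max_stats)
  expect_equal(p1$empirical_p, p1$K / p1$B)
  expect_equal(p1$empirical_p, 0)  # observed max exceeds every null max
  # constant phenotype has no valid statistic anywhere
  ph0 <- setNames(rep(1, 80), rownames(geno$genotypes))
  expect_error(permutation_test(geno, ph0, B = 10, seed = 1), "no valid")
})

test_that("QTL calling applies both cutoffs and claims support intervals", {
  geno <- toy_geno(n_lines = 100, n_markers = 12, seed = 13)
  set.seed(113)
  # null phenotype: no calls
  ph0 <- setNames(rnorm(100), rownames(geno$genotypes))
  sc0 <- genome_scan(geno, ph0)
  pm0 <- permutation_test(geno, ph0, B = 50, seed = 3)
  expect_equal(nrow(call_qtls(sc0, pm0)), 0)
  # two strong unlinked effects on different chromosomes: two passing calls
  ph2 <- setNames(rnorm(100, sd = 0.3) +
                    2 * (geno$genotypes[, "mk02"] == "B") +
                    2 * (geno$genotypes[, "mk09"] == "B"),
                  rownames(geno$genotypes))
  sc2 <- genome_scan(geno, ph2)
  pm2 <- permutation_test(geno, ph2, B = 50, seed = 3)
  calls <- call_qtls(sc2, pm2)
  passing <- calls[calls$passes_cutoff, ]
  expect_setequal(unique(passing$chr), c("chr1", "chr2"))
  for (i in seq_len(nrow(passing))) {
    expect_gte(passing$bp[i], passing$lower[i])
    expect_lte(passing$bp[i], passing$upper[i])
    expect_gt(passing$neg_log10_p[i], 4)
    expect_lt(passing$empirical_p[i], 0.05)
  }
})

test_that("a single-timepoint longitudinal scan reduces to a genome scan", {
  geno <- toy_geno(n_lines = 50, n_markers = 6, seed = 17)
  set.seed(115)
  lines <- rownames(geno$genotypes)
  series <- toy_series(lines, 1:2, 140, function(l, r, d) rnorm(1))
  ls <- longitudinal_scan(series, geno, "Area")
  expect_length(ls$scans, 1)
  ph <- tapply(series$value, series$line, mean)
  direct <- genome_scan(geno, ph)
  expect_equal(ls$scans[[1]]$F, direct$F)
  expect_equal(ls$trajectory$neg_log10_p, direct$neg_log10_p)
})

test_that("parameter scans drop non-converged fits and skip constant parameters", {
  geno <- toy_geno(n_lines = 60, n_markers = 6, seed = 19)
  lines <- rownames(geno$genotypes)
  set.seed(117)
  tab <- data.frame(line = rep(lines, each = 2), rep = rep(1:2, 60),
                    B = rnorm(120) + 2 * rep(geno$genotypes[, "mk04"] == "B", each = 2),
                    C = 130,  # constant across lines
                    converged = TRUE)
  tab$converged[1:2] <- FALSE
  scans <- parameter_scan(tab, geno, params = c("B", "C"))
  expect_named(scans, c("B", "C"))
  expect_equal(which.max(scans$B$F), 4)
  expect_true(all(is.na(scans$C$p)))  # constant phenotype: no partitionable variance
  pm <- permutation_test(geno, local({
    ph <- tapply(tab$B[tab$converged], tab$line[tab$converged], mean); ph
  }), B = 40, seed = 9)
  expect_equal(nrow(call_qtls(scans$C, pm)), 0)
})

test_that("per-timepoint marker regressions estimate the planted allele effect", {
  geno <- toy_geno(n_lines = 80, n_markers = 6, seed = 23)
  lines <- rownames(geno$genotypes)
  dose <- (geno$genotypes[, "mk02"] == "B") * 2
  set.seed(119)
  series <- toy_series(lines, 1, c(100, 150, 200), function(l, r, d) {
    asy <- eval_4pl(0, 10, 130, 100 + 25 * dose[l] / 2, d)
    asy + rnorm(1, sd = 2)
  })
  traj <- marker_effect_regression(series, geno, "mk02", "Area")
  expect_equal(nrow(traj), 3)
  # late DAS: the curve sits at its asymptote, slope ~ planted per-allele effect
  expect_equal(traj$slope[traj$DAS == 200], 12.5, tolerance = 0.15)
  expect_lt(traj$p[traj$DAS == 200], 1e-6)
  # single-timepoint call equals simple regression
  one <- series[series$DAS == 150, ]
  fit <- lm(tapply(one$value, one$line, mean)[lines] ~ dose)
  expect_equal(traj$slope[traj$DAS == 150], unname(coef(fit)[2]), tolerance = 1e-10)
  mono <- geno
  mono$genotypes[, "mk01"] <- "A"
  expect_error(marker_effect_regression(series, mono, "mk01", "Area"), "monomorphic")
})

test_that("null phenotypes give uniform permutation p-values", {
  geno <- toy_geno(n_lines = 60, n_markers = 8, seed = 29)
  set.seed(121)
  ps <- vapply(1:12, function(i) {
    ph <- setNames(rnorm(60), rownames(geno$genotypes))
    permutation_test(geno, ph, B = 60, seed = i)$empirical_p
  }, 1)
  # mean of a uniform sample of 12 lies within 3 s.e. of 0.5
  expect_lt(abs(mean(ps) - 0.5), 3 * sqrt(1 / 12) / sqrt(12))
})
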