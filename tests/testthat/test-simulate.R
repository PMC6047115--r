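test_that("the simulator is deterministic under a fixed seed", {
  cfg <- small_config(seed = 1)
  p1 <- simulate_founders(cfg); p2 <- simulate_founders(cfg)
  expect_identical(p1, p2)
  pop1 <- simulate_magic_rils(p1, cfg); pop2 <- simulate_magic_rils(p2, cfg)
  expect_identical(pop1$genotypes, pop2$genotypes)
  s1 <- simulate_trait_series(pop1, cfg, "Area")
  s2 <- simulate_trait_series(pop2, cfg, "Area")
  expect_identical(s1$series, s2$series)
})

test_that("founder panels have the configured shape and polymorphism", {
  cfg <- magic_sim_config(seed = 2, n_chr = 4, markers_per_chr = 25)
  panel <- simulate_founders(cfg)
  expect_equal(dim(panel$alleles), c(8, 100))
  expect_equal(nrow(panel$map), 100)
  for (ch in unique(panel$map$chr))
    expect_true(all(diff(panel$map$cM[panel$map$chr == ch]) > 0))
  # maf bound 0.5 with 8 founders: every marker is a balanced 4/4 split
  cfg5 <- magic_sim_config(seed = 2, founder_maf = 0.5, markers_per_chr = 30)
  panel5 <- simulate_founders(cfg5)
  counts <- apply(panel5$alleles, 2, function(a) sum(a == "B"))
  expect_true(all(counts == 4))
  expect_error(magic_sim_config(n_chr = 0), "config error")
  expect_error(magic_sim_config(founder_maf = 0.7), "config error")
})

test_that("without recombination each RIL chromosome is a single founder segment", {
  cfg <- small_config(seed = 4, n_lines = 20, chr_length_cM = 1e-9)
  panel <- simulate_founders(cfg)
  pop <- simulate_magic_rils(panel, cfg)
  for (ch in unique(pop$map$chr)) {
    idx <- which(pop$map$chr == ch)
    segs <- apply(pop$hap1[, idx, drop = FALSE], 1, function(h) length(unique(h)))
    expect_true(all(segs == 1))
  }
})

test_that("residual heterozygosity matches the selfing expectation", {
  cfg <- small_config(seed = 6, n_lines = 400)
  panel <- simulate_founders(cfg)
  pop <- simulate_magic_rils(panel, cfg)
  h <- pop$residual_het
  se <- sd(h) / sqrt(length(h))
  expect_lt(abs(mean(h) - 0.5^5), 3 * se)
})

test_that("founder-origin identity between markers decays with map distance", {
  cfg <- magic_sim_config(seed = 8, n_lines = 300, n_chr = 2, markers_per_chr = 2,
                          chr_length_cM = 1)  # chr pairs ~1 cM apart
  cfg_far <- magic_sim_config(seed = 8, n_lines = 300, n_chr = 2, markers_per_chr = 2,
                              chr_length_cM = 50)
  id_rate <- function(cfg) {
    pop <- simulate_magic_rils(simulate_founders(cfg), cfg)
    idx <- which(pop$map$chr == "chr1")
    mean(pop$hap1[, idx[1]] == pop$hap1[, idx[2]])
  }
  near <- id_rate(cfg)
  far <- id_rate(cfg_far)
  expect_gt(near, far)
  expect_gt(near, 0.9)
})

test_that("a planted founder effect shifts the asymptotic trait mean by its size", {
  delta <- 20000
  eff <- c(0, 0, 0, 0, 0, delta, 0, 0)  # carriers of founder 6 only
  cfg <- small_config(
    seed = 10, n_lines = 150,
    qtl = list(qtl_effect("Area", "M1_008", "D", eff)),
    genetic_sd = list(Area = c(A = 0, B = 0, C = 0, D = 0)),
    env_sd = list(Area = c(A = 0, B = 0, C = 0, D = 0)),
    obs_sd = c(Area = 0))
  panel <- simulate_founders(cfg)
  pop <- simulate_magic_rils(panel, cfg)
  sim <- simulate_trait_series(pop, cfg, "Area")
  carrier <- pop$founder_origin[, "M1_008"] == 6
  late <- sim$series[sim$series$DAS == max(sim$series$DAS), ]
  m_car <- mean(late$value[carrier[late$line] %in% TRUE])
  m_non <- mean(late$value[carrier[late$line] %in% FALSE])
  # at late DAS the 4PL is near its asymptote D, so the shift is ~delta
  expect_equal(m_car - m_non, delta, tolerance = 0.02)
  # construction check on the latent parameter itself
  g <- sim$truth_genetic
  expect_equal(mean(g$D[carrier %in% TRUE]) - mean(g$D[carrier %in% FALSE]),
               delta, tolerance = 1e-6)
})

test_that("a noise-free generator makes all lines identical", {
  cfg <- small_config(
    seed = 12, n_lines = 10,
    genetic_sd = list(Area = c(A = 0, B = 0, C = 0, D = 0)),
    env_sd = list(Area = c(A = 0, B = 0, C = 0, D = 0)),
    obs_sd = c(Area = 0))
  sim <- simulate_trait_series(simulate_magic_rils(simulate_founders(cfg), cfg),
                               cfg, "Area")
  sp <- split(sim$series$value, sim$series$DAS)
  expect_true(all(vapply(sp, function(v) max(v) - min(v), 1) == 0))
})

test_that("with zero genetic effects the estimated heritability is centred on zero", {
  cfg <- small_config(
    seed = 14, n_lines = 500, n_reps = 2,
    genetic_sd = list(Area = c(A = 0, B = 0, C = 0, D = 0)))
  pop <- simulate_magic_rils(simulate_founders(cfg), cfg)
  sim <- simulate_trait_series(pop, cfg, "Area")
  # decompose the realized (per-replicate) latent parameter directly
  vc <- variance_components(data.frame(line = sim$truth_realized$line,
                                       value = sim$truth_realized$B))
  h2 <- heritability(vc)
  expect_lt(abs(h2), 0.1)
})

test_that("genotype and phenotype tables round-trip through their file formats", {
  cfg <- small_config(seed = 16, n_lines = 15)
  pop <- simulate_magic_rils(simulate_founders(cfg), cfg)
  sim <- simulate_trait_series(pop, cfg, "Height")
  gfile <- withr::local_tempfile(fileext = ".tsv")
  pfile <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(pop, gfile)
  geno2 <- read_genotypes(gfile)
  expect_equal(geno2$genotypes, pop$genotypes)
  expect_equal(geno2$map$marker, pop$map$marker)
  expect_equal(geno2$map$cM, pop$map$cM, tolerance = 1e-6)
  write_phenotypes(sim$series, pfile)
  ser2 <- read_phenotypes(pfile)
  expect_equal(ser2$value, sim$series$value, tolerance = 1e-6)
  expect_equal(ser2$line, sim$series$line)
})
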