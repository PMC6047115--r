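# Small fixture builders shared across test files.

small_config <- function(seed = 1, n_lines = 60, n_chr = 2, markers_per_chr = 15,
                         timepoints = seq(90, 200, by = 8), ...) {
  magic_sim_config(seed = seed, n_lines = n_lines, n_chr = n_chr,
                   markers_per_chr = markers_per_chr, timepoints = timepoints, ...)
}

# A hand-built genotype object: two chromosomes, homozygous biallelic calls.
toy_geno <- function(n_lines = 40, n_markers = 8, seed = 42) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(n_lines))
  markers <- sprintf("mk%02d", seq_len(n_markers))
  calls <- matrix(sample(c("A", "B"), n_lines * n_markers, replace = TRUE),
                  n_lines, n_markers, dimnames = list(lines, markers))
  half <- ceiling(n_markers / 2)
  map <- data.frame(marker = markers,
                    chr = rep(c("chr1", "chr2"), c(half, n_markers - half)),
                    cM = c(seq_len(half) * 10, seq_len(n_markers - half) * 10),
                    bp = c(seq_len(half), seq_len(n_markers - half)) * 1000000L,
                    stringsAsFactors = FALSE)
  list(genotypes = calls, map = map)
}

# Long-format series from an explicit value function value_fn(line, rep, DAS)
toy_series <- function(lines, reps, das, value_fn, trait = "Area") {
  grid <- expand.grid(line = lines, rep = reps, DAS = das,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$trait <- trait
  grid$value <- mapply(value_fn, grid$line, grid$rep, grid$DAS)
  grid <- grid[order(grid$line, grid$rep, grid$DAS), ]
  rownames(grid) <- NULL
  grid
}
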