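#' Write / read a genotype table
#'
#' Plain TSV with one row per marker: `marker`, `chr`, `cM`, `bp`, then one
#' column per line carrying the allele call (A/B/H). The genetic map is
#' implicit in the cM/bp columns.
#'
#' @param geno genotype object (list with `map` and `genotypes`).
#' @param path output file.
#' @export
write_genotypes <- function(geno, path) {
  tab <- cbind(geno$map, as.data.frame(t(geno$genotypes), stringsAsFactors = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @return `read_genotypes`: list with `map` (marker, chr, cM, bp) and
#'   `genotypes` (line x marker character matrix).
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("marker", "chr", "cM", "bp")
  if (!all(need %in% names(tab)))
    stop("read_genotypes: missing columns ", paste(setdiff(need, names(tab)), collapse = ", "),
         call. = FALSE)
  map <- tab[need]
  calls <- t(as.matrix(tab[setdiff(names(tab), need)]))
  colnames(calls) <- map$marker
  list(map = map, genotypes = calls)
}

#' Write / read a long-format phenotype table
#'
#' Plain CSV with columns `line`, `rep`, `DAS`, `trait`, `value`.
#'
#' @param series long data.frame.
#' @param path file path.
#' @export
write_phenotypes <- function(series, path) {
  utils::write.csv(series[c("line", "rep", "DAS", "trait", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "rep", "DAS", "trait", "value")
  if (!all(need %in% names(tab)))
    stop("read_phenotypes: missing columns ", paste(setdiff(need, names(tab)), collapse = ", "),
         call. = FALSE)
  tab[need]
}

#' Validate genotype and phenotype inputs before analysis
#'
#' Checks line-id concordance between the two tables, the allele-code
#' alphabet, monotonicity of the genetic map within chromosomes, and
#' duplicate phenotype records. Problems are classified as `"fatal"` or
#' `"warning"`.
#'
#' @param geno genotype object (list with `map`, `genotypes`).
#' @param series phenotype long data.frame.
#' @return data.frame of class `validation_report`: severity, check, message
#'   (0 rows when everything is clean).
#' @export
validate_inputs <- function(geno, series) {
  probs <- list()
  add <- function(severity, check, message)
    probs[[length(probs) + 1L]] <<- data.frame(severity = severity, check = check,
                                               message = message,
                                               stringsAsFactors = FALSE)
  bad_alleles <- setdiff(unique(as.vector(geno$genotypes)), c("A", "B", "H", NA))
  if (length(bad_alleles))
    add("fatal", "allele_alphabet",
        paste("unknown allele codes:", paste(bad_alleles, collapse = ", ")))
  for (ch in unique(geno$map$chr)) {
    cm <- geno$map$cM[geno$map$chr == ch]
    if (any(diff(cm) <= 0))
      add("fatal", "map_monotonicity",
          paste0("cM positions not strictly increasing on ", ch))
  }
  ph_lines <- unique(series$line)
  gt_lines <- rownames(geno$genotypes)
  orphan <- setdiff(ph_lines, gt_lines)
  if (length(orphan))
    add("warning", "line_concordance",
        paste0(length(orphan), " phenotyped line(s) absent from genotype table: ",
               paste(utils::head(orphan, 5), collapse = ", ")))
  if (length(intersect(ph_lines, gt_lines)) == 0)
    add("fatal", "line_concordance", "no lines shared between tables")
  dup <- duplicated(series[c("line", "rep", "DAS", "trait")])
  if (any(dup))
    add("warning", "duplicate_records",
        paste0(sum(dup), " duplicate (line, rep, DAS, trait) record(s)"))
  out <- if (length(probs)) do.call(rbind, probs) else
    data.frame(severity = character(0), check = character(0), message = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("validation_report", "data.frame")
  out
}
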