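# Shared fixture builders.  Everything is constructed in code; the only
# files touched are tempfiles written by the round-trip tests.

toy_deg <- function(genes = c("A", "B", "C"),
                    log_ratio = seq_along(genes),
                    p = seq_along(genes) / 100,
                    p_adj = p, study_id = "toy", species = "human") {
  deg_table(genes, log_ratio, p, p_adj, study_id = study_id,
            species = species)
}

toy_matrix <- function(values, genes = NULL, samples = NULL,
                       groups = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  if (is.null(groups)) groups <- stats::setNames(rep("g", ncol(values)),
                                                 samples)
  expression_matrix(values, groups)
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Independent oracle for the weighted enrichment score: per-marker weight
# lookup, no block arithmetic shared with the implementation.
oracle_weighted_score <- function(ranked_genes, markers) {
  sum(vapply(unique(markers), function(m) {
    r <- match(m, ranked_genes)
    if (is.na(r) || r > 2000) return(0)
    for (b in 1:20) {
      if (r >= (b - 1) * 100 + 1 && r <= b * 100) return(21 - b)
    }
    0
  }, 0))
}

# Independent Pearson oracle by explicit sum formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}
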