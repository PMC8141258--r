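# Signature-score endotyping: mean-center the expression matrix per gene,
# average the centered values over each signature's genes to get a
# per-sample score, and call samples high/low against a cut-off (default
# 0).  With two signatures (e.g. Th2 and Th17) the composite high/low pair
# defines the endotype clusters.

#' Mean-center an expression matrix gene-wise
#'
#' Subtracts each gene's mean across samples, so every gene row averages
#' zero.  Idempotent and shape-preserving.  Centering requires at least
#' two samples.
#'
#' @param matrix an [expression_matrix].
#' @return the centered [expression_matrix].
#' @export
mean_center <- function(matrix) {
  if (ncol(matrix) < 2L) {
    stop("mean_center: need at least 2 samples to center")
  }
  centered <- unclass(matrix) - rowMeans(matrix)
  expression_matrix(centered, sample_groups(matrix))
}

#' Per-sample signature scores
#'
#' For each signature, the score of a sample is the mean of the centered
#' expression of the signature genes present in the matrix.  Signature
#' genes absent from the matrix are dropped silently (their count is
#' reported via `n_genes_used`); a signature whose intersection with the
#' matrix falls below `min_genes` is an error naming the missing genes.
#' Scores across samples sum to zero for every signature, a direct
#' consequence of gene-wise centering.
#'
#' @param matrix an [expression_matrix] (centered internally; passing an
#'   already-centered matrix is harmless since centering is idempotent).
#' @param signatures a [gene_set_collection], or a plain character vector
#'   treated as a single signature named `"signature"`.
#' @param min_genes minimum number of signature genes that must be present
#'   (default 1).
#' @return a `signature_scores` object: a data.frame with one row per
#'   sample and one column per signature, plus attributes `n_genes_used`
#'   (named integer) and `sample_group`.
#' @export
signature_score <- function(matrix, signatures, min_genes = 1L) {
  if (is.character(signatures)) {
    signatures <- gene_set_collection(list(signature = signatures))
  }
  centered <- mean_center(matrix)
  genes_in <- rownames(centered)
  scores <- list()
  n_used <- integer(length(signatures))
  names(n_used) <- names(signatures)
  for (nm in names(signatures)) {
    sig <- signatures[[nm]]
    found <- intersect(sig, genes_in)
    if (length(found) < min_genes) {
      stop(sprintf(
        "signature_score: signature '%s' has %d/%d genes in matrix (min %d); missing: %s",
        nm, length(found), length(sig), min_genes,
        paste(setdiff(sig, genes_in), collapse = ", ")))
    }
    scores[[nm]] <- colMeans(unclass(centered)[found, , drop = FALSE])
    n_used[nm] <- length(found)
  }
  out <- as.data.frame(scores, check.names = FALSE)
  rownames(out) <- colnames(centered)
  structure(out, n_genes_used = n_used,
            sample_group = sample_groups(matrix),
            class = c("signature_scores", "data.frame"))
}

#' Assign samples to score-sign clusters
#'
#' A sample is `"high"` for a signature iff its score strictly exceeds the
#' cut-off, else `"low"` (a score exactly at the cut-off is `"low"`; the
#' boundary side is a documented convention).  With several signatures the
#' composite label concatenates the per-signature calls as
#' `"<sig>-high/<sig>-low/..."`, so two signatures yield up to four
#' composite clusters.
#'
#' @param scores a `signature_scores` object from [signature_score()].
#' @param cutoff score threshold (default 0).
#' @return a `cluster_assignment` data.frame with per-signature call
#'   columns (`<sig>.call`) and a `label` column (the composite label; for
#'   a single signature simply `"high"`/`"low"`).
#' @export
assign_clusters <- function(scores, cutoff = 0) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1L)
  calls <- lapply(names(scores), function(nm) {
    ifelse(scores[[nm]] > cutoff, "high", "low")
  })
  names(calls) <- paste0(names(scores), ".call")
  if (ncol(scores) == 1L) {
    label <- calls[[1L]]
  } else {
    parts <- mapply(function(nm, cl) paste0(nm, "-", cl),
                    names(scores), calls, SIMPLIFY = FALSE)
    label <- do.call(paste, c(parts, sep = "/"))
  }
  out <- data.frame(sample = rownames(scores), calls, label = label,
                    stringsAsFactors = FALSE, check.names = FALSE)
  structure(out, cutoff = cutoff,
            class = c("cluster_assignment", "data.frame"))
}

#' Cluster prevalence (counts and percentages)
#'
#' Counts samples per cluster label and reports the percentage of the
#' total, both at full precision and rounded half-away-from-zero to the
#' nearest integer (the convention of printed prevalence figures such as
#' "21 out of 53 (40\%)").
#'
#' @param assignment a `cluster_assignment` from [assign_clusters()], or
#'   any character vector of labels.
#' @return data.frame with columns `label`, `count`, `percent` (exact) and
#'   `percent_rounded` (integer); counts sum to the number of samples.
#' @export
cluster_prevalence <- function(assignment) {
  labels <- if (is.data.frame(assignment)) assignment$label else
    as.character(assignment)
  if (length(labels) == 0L) stop("cluster_prevalence: no samples")
  tab <- table(labels)
  pct <- 100 * as.vector(tab) / length(labels)
  data.frame(label = names(tab),
             count = as.vector(tab),
             percent = pct,
             percent_rounded = round_half_away(pct),
             stringsAsFactors = FALSE)
}

# round() in R rounds half to even; printed prevalences use the familiar
# half-away-from-zero convention (e.g. 46.15 -> 46, 59.99 -> 60, 0.5 -> 1).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
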