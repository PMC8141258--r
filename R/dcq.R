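# Digital cell quantification (DCQ): regress a case-vs-control fold-change
# vector on a column-standardized cell-type compendium with elastic-net
# regularization (heavily ridge-leaning, alpha = 0.05), repeated over
# seeded gene subsamples and averaged.  Post-processing mirrors the
# published workflow: per-group averaging, removal of cell types whose
# group-mean quantities stay below 2.0, and a per-cell-type z-score
# transform for heat-map display.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Assemble a DCQ input from a fold-change vector and a compendium
#'
#' Restricts both to their shared genes and checks the problem is
#' well-posed: at least 10 shared genes, more genes than cell types, and
#' no constant (degenerate) compendium column on the shared genes.
#'
#' @param fold_change named numeric vector of log-scale fold changes
#'   (names = gene symbols).
#' @param compendium a [cell_compendium].
#' @return a `dcq_input` list with elements `fold_change` and `compendium`
#'   aligned on the shared genes.
#' @export
dcq_input <- function(fold_change, compendium) {
  if (is.null(names(fold_change))) stop("dcq_input: fold_change must be named")
  names(fold_change) <- normalize_symbol(names(fold_change))
  shared <- intersect(names(fold_change), rownames(compendium))
  if (length(shared) < 10L) {
    stop("dcq_input: fewer than 10 genes shared with compendium")
  }
  if (length(shared) <= ncol(compendium)) {
    stop("dcq_input: need more shared genes than cell types")
  }
  ref <- unclass(compendium)[shared, , drop = FALSE]
  sds <- apply(ref, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("dcq_input: constant compendium column(s) on shared genes: %s",
                 paste(colnames(ref)[sds == 0], collapse = ", ")))
  }
  structure(list(fold_change = fold_change[shared],
                 compendium = ref),
            class = "dcq_input")
}

#' Digital cell quantification by elastic net
#'
#' Per repeat, a seeded random half of the shared genes (fraction
#' `subsample`) is drawn without replacement and the fold-change vector is
#' regressed on the column-standardized compendium by elastic net
#' (`alpha` = L1/L2 mixing, default 0.05, ridge-leaning), following a
#' 100-step regularization path terminated at
#' `lambda_min_ratio * lambda_max`.  The coefficients at the final lambda
#' give each repeat's cell-type quantities; the reported quantity is their
#' mean across repeats.
#'
#' By default (`debias = TRUE`) each repeat's penalized fit is used only
#' to select the active cell types, and the reported coefficients are an
#' ordinary least-squares refit on that support (a relaxed elastic net).
#' This keeps the selection behaviour of the penalized path while removing
#' its heavy shrinkage, so noise-free mixtures are recovered at their true
#' magnitudes.  `debias = FALSE` reports the raw penalized coefficients.
#'
#' @param input a [dcq_input].
#' @param repeats number of subsample repeats (default 3).
#' @param lambda_min_ratio path termination ratio (default 0.2).
#' @param seed integer seed; the run is deterministic given the seed.
#' @param alpha elastic-net mixing (default 0.05).
#' @param subsample fraction of genes drawn per repeat (default 0.5).
#' @param debias refit OLS on the selected support (default `TRUE`).
#' @return a `cell_quantities` object: data.frame with columns
#'   `cell_type`, `quantity` (mean over repeats), `sd` (dispersion over
#'   repeats), plus attributes `per_repeat` (cell types x repeats matrix)
#'   and `repeats_used`.
#' @export
dcq <- function(input, repeats = 3L, lambda_min_ratio = 0.2, seed = 1L,
                alpha = 0.05, subsample = 0.5, debias = TRUE) {
  stopifnot(inherits(input, "dcq_input"), repeats >= 1L)
  X <- scale(input$compendium)
  y <- input$fold_change
  K <- ncol(X)
  G <- nrow(X)
  per_rep <- matrix(NA_real_, K, repeats,
                    dimnames = list(colnames(X), NULL))
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      idx <- sort(sample.int(G, max(K + 2L, floor(subsample * G))))
      Xr <- X[idx, , drop = FALSE]
      yr <- y[idx]
      if (stats::sd(yr) == 0) {
        # null fold-change vector: all quantities are zero by definition
        per_rep[, r] <- 0
        next
      }
      fit <- glmnet::glmnet(Xr, yr, family = "gaussian", alpha = alpha,
                            nlambda = 100L,
                            lambda.min.ratio = lambda_min_ratio,
                            standardize = FALSE)
      beta <- fit$beta[, ncol(fit$beta)]
      if (debias) {
        supp <- which(beta != 0)
        coefs <- numeric(K)
        if (length(supp) > 0L) {
          refit <- stats::lm.fit(cbind(1, Xr[, supp, drop = FALSE]), yr)
          coefs[supp] <- refit$coefficients[-1L]
          coefs[is.na(coefs)] <- 0
        }
        per_rep[, r] <- coefs
      } else {
        per_rep[, r] <- as.numeric(beta)
      }
    }
  })
  out <- data.frame(cell_type = colnames(X),
                    quantity = rowMeans(per_rep),
                    sd = apply(per_rep, 1L, stats::sd),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, per_repeat = per_rep, repeats_used = repeats,
            class = c("cell_quantities", "data.frame"))
}

#' Group-average cell quantities and filter weak cell types
#'
#' Averages each cell type's quantity within every sample group, then
#' removes cell types whose group means never reach the threshold.
#' Because DCQ quantities are signed (a negative quantity is a depleted
#' cell type), the default filter uses the maximum *absolute* group mean:
#' a cell type survives if `|mean|` >= `threshold` in at least one group.
#' `signed = TRUE` restores the literal one-sided reading (survives iff
#' some group mean >= threshold).
#'
#' @param per_sample named list mapping sample id to a `cell_quantities`
#'   object (all with identical cell types).
#' @param groups named character vector mapping every sample to a group.
#' @param threshold filter threshold (default 2.0); a group mean exactly
#'   at the threshold is retained ("below" excludes only strictly smaller
#'   values).
#' @param signed use signed group means instead of absolute values.
#' @return a `group_quantities` object: cell types x groups numeric matrix
#'   of mean quantities, filtered; attribute `removed` lists the filtered
#'   cell types, `unfiltered` holds the pre-filter matrix.
#' @export
group_average_and_filter <- function(per_sample, groups, threshold = 2.0,
                                     signed = FALSE) {
  if (length(per_sample) == 0L) stop("group_average_and_filter: no samples")
  missing <- setdiff(names(per_sample), names(groups))
  if (length(missing) > 0L) {
    stop(sprintf("group_average_and_filter: ungrouped sample(s): %s",
                 paste(missing, collapse = ", ")))
  }
  cts <- per_sample[[1L]]$cell_type
  qmat <- vapply(per_sample, function(q) {
    stopifnot(identical(q$cell_type, cts))
    q$quantity
  }, numeric(length(cts)))
  if (is.null(dim(qmat))) qmat <- matrix(qmat, nrow = length(cts))
  rownames(qmat) <- cts
  grp <- groups[names(per_sample)]
  glevels <- unique(unname(grp))
  gmeans <- vapply(glevels, function(g) {
    rowMeans(qmat[, grp == g, drop = FALSE])
  }, numeric(length(cts)))
  if (is.null(dim(gmeans))) gmeans <- matrix(gmeans, nrow = length(cts))
  dimnames(gmeans) <- list(cts, glevels)
  crit <- if (signed) apply(gmeans, 1L, max) else apply(abs(gmeans), 1L, max)
  keep <- crit >= threshold
  removed <- cts[!keep]
  out <- gmeans[keep, , drop = FALSE]
  structure(out, removed = removed, unfiltered = gmeans,
            class = c("group_quantities", "matrix", "array"))
}

#' Z-score cell quantities across groups
#'
#' Standardizes each cell type's group means to mean 0, sd 1 across
#' groups (the transform behind the published heat maps).  Cell types
#' with zero variance across groups are dropped with a warning.
#'
#' @param gq a `group_quantities` matrix (cell types x groups), >= 2
#'   groups.
#' @return numeric matrix of z-scores, same layout, constant rows removed.
#' @export
zscore_by_celltype <- function(gq) {
  gq <- unclass(gq)
  attr(gq, "removed") <- NULL
  attr(gq, "unfiltered") <- NULL
  if (ncol(gq) < 2L) stop("zscore_by_celltype: need >= 2 groups")
  sds <- apply(gq, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("zscore_by_celltype: dropped %d constant row(s): %s",
                    sum(sds == 0),
                    paste(rownames(gq)[sds == 0], collapse = ", ")))
  }
  gq <- gq[sds > 0, , drop = FALSE]
  t(scale(t(gq)))[, , drop = FALSE]
}
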