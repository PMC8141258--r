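# Cross-study correlation of DEG log-ratios: FDR-filter each study,
# harmonize gene symbols across species through an ortholog map, inner-join
# on shared genes, and compute pairwise Pearson r with a two-sided t-test
# p-value.  Cells with fewer than 3 shared genes are reported as missing
# (NA), never as zero.

#' FDR-filter a DEG table
#'
#' Retains rows with `p_adj_fdr <= alpha` (the boundary value is kept),
#' preserving row order.
#'
#' @param table a [deg_table].
#' @param alpha FDR cut-off in `(0, 1]` (default 0.05).
#' @return the filtered [deg_table]; the number of rows retained is
#'   available as attribute `n_retained`.
#' @export
filter_degs <- function(table, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("filter_degs: alpha must be in (0, 1]")
  }
  keep <- table$p_adj_fdr <= alpha
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, study_id = attr(table, "study_id"),
            species = attr(table, "species"),
            n_retained = sum(keep),
            class = class(table))
}

#' Harmonize a DEG table to a target species' symbols
#'
#' Translates gene symbols through a mouse/human ortholog map so tables
#' from different species can be joined.  A same-species call is an
#' identity pass-through.  Unmapped genes are dropped (count reported via
#' attribute `n_unmapped`); several source genes translating to one target
#' symbol are collapsed by the mean-dedup rule.
#'
#' @param table a [deg_table].
#' @param orthologs an [ortholog_map].
#' @param target_species `"human"` or `"mouse"`.
#' @return a [deg_table] carrying `target_species` symbols.
#' @export
harmonize <- function(table, orthologs, target_species = c("human", "mouse")) {
  target_species <- match.arg(target_species)
  species <- attr(table, "species")
  if (identical(species, target_species)) {
    return(table)
  }
  if (target_species == "human") {
    from <- orthologs$mouse_symbol
    to <- orthologs$human_symbol
  } else {
    from <- orthologs$human_symbol
    to <- orthologs$mouse_symbol
  }
  idx <- match(table$gene, from)
  mapped <- !is.na(idx)
  n_unmapped <- sum(!mapped)
  if (!any(mapped)) {
    stop("harmonize: no genes map to target species")
  }
  out <- suppressWarnings(deg_table(
    to[idx[mapped]],
    table$log_ratio[mapped], table$p[mapped], table$p_adj_fdr[mapped],
    study_id = attr(table, "study_id"), species = target_species))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Pearson correlation of two studies' log-ratios
#'
#' Inner-joins the two (already filtered and harmonized) tables on gene
#' symbol and computes the Pearson correlation of the paired log-ratios
#' with a two-sided t-approximation p-value.  Fewer than 3 shared genes
#' yields a missing cell (`r = NA`), not an error, so one sparse pair
#' cannot kill a whole matrix run.
#'
#' @param a,b [deg_table]s.
#' @return a one-row data.frame: `study_a`, `study_b`, `n`, `r`, `p`.
#' @export
correlate_pair <- function(a, b) {
  shared <- intersect(a$gene, b$gene)
  n <- length(shared)
  cell <- data.frame(study_a = attr(a, "study_id"),
                     study_b = attr(b, "study_id"),
                     n = n, r = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
  if (n < 3L) return(cell)
  x <- a$log_ratio[match(shared, a$gene)]
  y <- b$log_ratio[match(shared, b$gene)]
  r <- stats::cor(x, y, method = "pearson")
  if (is.na(r)) return(cell)  # zero-variance degenerate input
  cell$r <- r
  # two-sided t-approximation with n - 2 df; |r| = 1 gives p = 0
  if (abs(r) >= 1) {
    cell$p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    cell$p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  cell
}

#' All-pairs correlation matrix across studies
#'
#' Computes every unordered pair once and mirrors it into a symmetric
#' layout.  The long-format cell table (one row per unordered pair) is the
#' primary output; symmetric square matrices of r, n and p are attached
#' for heat-map rendering.
#'
#' @param tables list of [deg_table]s (filtered/harmonized upstream), at
#'   least 2; names default to each table's `study_id`.
#' @return a `correlation_matrix` object: the long data.frame of cells
#'   with attributes `r_matrix`, `n_matrix`, `p_matrix` (square, symmetric,
#'   unit/NA diagonal conventions: diag(r) = 1).
#' @export
correlation_matrix <- function(tables) {
  if (length(tables) < 2L) stop("correlation_matrix: need >= 2 tables")
  ids <- vapply(tables, function(t) attr(t, "study_id"), "")
  if (anyDuplicated(ids)) stop("correlation_matrix: duplicate study ids")
  k <- length(tables)
  cells <- list()
  rmat <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  nmat <- matrix(0L, k, k, dimnames = list(ids, ids))
  pmat <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(rmat) <- 1
  for (i in seq_len(k)) nmat[i, i] <- nrow(tables[[i]])
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      cell <- correlate_pair(tables[[i]], tables[[j]])
      cells[[length(cells) + 1L]] <- cell
      rmat[i, j] <- rmat[j, i] <- cell$r
      nmat[i, j] <- nmat[j, i] <- cell$n
      pmat[i, j] <- pmat[j, i] <- cell$p
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  structure(out, r_matrix = rmat, n_matrix = nmat, p_matrix = pmat,
            class = c("correlation_matrix", "data.frame"))
}

#' Write a correlation matrix's cell table as TSV
#' @param x a `correlation_matrix`.
#' @param path output path.
#' @export
write_correlation_matrix <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
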