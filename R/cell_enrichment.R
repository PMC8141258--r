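# Fold-change-ranked weighted overlap scoring for cell-type marker lists.
# Genes are ranked by fold change (up-regulated first), the ranking is
# truncated to 2000 genes, and a marker hitting ranks 1-100 contributes
# weight 20, ranks 101-200 weight 19, ... down to weight 1 for ranks
# 1901-2000 and 0 beyond.  A size-200 sliding window at step 100 is
# exposed separately as a diagnostic overlap profile.

#' Rank genes by fold change
#'
#' Sorts a DEG table's genes descending by `log_ratio` (or by
#' `|log_ratio|` when `absolute = TRUE`), breaking ties lexicographically
#' by symbol for cross-platform determinism, and truncates to the top
#' `top_n` genes.
#'
#' @param table a [deg_table].
#' @param top_n ranking length (default 2000 = 20 weight blocks of 100).
#' @param absolute rank by absolute fold change instead of signed.
#' @return a `ranked_gene_list`: a data.frame with columns `rank`, `gene`,
#'   `ranking_value`.
#' @export
rank_genes <- function(table, top_n = 2000L, absolute = FALSE) {
  if (top_n < 1L) stop("rank_genes: top_n must be >= 1")
  if (nrow(table) == 0L) stop("rank_genes: empty table")
  key <- if (absolute) abs(table$log_ratio) else table$log_ratio
  ord <- order(-key, table$gene, method = "radix")
  ord <- ord[seq_len(min(top_n, length(ord)))]
  structure(data.frame(rank = seq_along(ord),
                       gene = table$gene[ord],
                       ranking_value = table$log_ratio[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_gene_list", "data.frame"))
}

#' Sliding-window overlap counts
#'
#' For each window start `1, 1 + step, ...` (every start whose full
#' window fits in the ranking), counts the marker genes with ranks in
#' `[start, start + window - 1]`.  Diagnostic companion to
#' [weighted_score()]: it shows where in the ranking a cell type's markers
#' concentrate.
#'
#' @param ranked a `ranked_gene_list`.
#' @param markers character vector of marker symbols (non-empty).
#' @param window window size (default 200).
#' @param step window step (default 100, aligning windows with the
#'   100-gene weight blocks).
#' @return data.frame with columns `start`, `end`, `overlap`.
#' @export
windowed_overlap <- function(ranked, markers, window = 200L, step = 100L) {
  if (length(markers) == 0L) stop("windowed_overlap: empty marker list")
  if (window > nrow(ranked)) {
    stop("windowed_overlap: window exceeds ranking length")
  }
  markers <- unique(normalize_symbol(markers))
  is_marker <- ranked$gene %in% markers
  starts <- seq.int(1L, nrow(ranked) - window + 1L, by = step)
  overlap <- vapply(starts, function(s) {
    sum(is_marker[s:(s + window - 1L)])
  }, 0L)
  data.frame(start = starts, end = starts + window - 1L, overlap = overlap)
}

# weight of a rank: 20 for 1-100, 19 for 101-200, ..., 1 for 1901-2000,
# 0 beyond rank 2000.
rank_weight <- function(rank) {
  w <- 21L - ceiling(rank / 100)
  ifelse(rank >= 1L & rank <= 2000L, w, 0L)
}

#' Weighted marker-overlap enrichment score
#'
#' Sums, over the 20 consecutive 100-gene blocks of the ranking, the
#' block's marker overlap times its weight (block 1 = ranks 1-100 weighs
#' 20, block 2 weighs 19, ... block 20 weighs 1).  Markers beyond rank
#' 2000 contribute nothing.  Equivalently: each marker found in the
#' ranking contributes the weight of its own rank.  A ranking longer than
#' 2000 genes is truncated with a warning.
#'
#' @param ranked a `ranked_gene_list`.
#' @param markers character vector of marker symbols (non-empty;
#'   duplicates removed).
#' @return an `enrichment_score` list: `weighted_score` (non-negative
#'   integer, at most `20 * n_markers`), `n_markers`, `n_found` (markers
#'   within the 2000-gene ranking) and `block_overlaps` (length-20 integer
#'   vector of per-block marker counts).
#' @export
weighted_score <- function(ranked, markers) {
  if (length(markers) == 0L) stop("weighted_score: empty marker list")
  markers <- unique(normalize_symbol(markers))
  if (nrow(ranked) > 2000L) {
    warning("weighted_score: ranking longer than 2000 genes; truncating")
    ranked <- ranked[seq_len(2000L), , drop = FALSE]
  }
  hit_ranks <- ranked$rank[ranked$gene %in% markers]
  blocks <- tabulate(ceiling(hit_ranks / 100), nbins = 20L)
  score <- sum(blocks * (20:1))
  structure(list(weighted_score = as.integer(score),
                 n_markers = length(markers),
                 n_found = length(hit_ranks),
                 block_overlaps = blocks),
            class = "enrichment_score")
}

#' Score every cell-type marker list against one ranking
#'
#' @param ranked a `ranked_gene_list`.
#' @param collections a [gene_set_collection] of cell-type marker lists.
#' @return data.frame, one row per cell type, sorted descending by
#'   `weighted_score` (ties broken by cell-type name): columns
#'   `cell_type`, `weighted_score`, `n_markers`, `n_found`,
#'   `normalized_score` (= score / (20 * n_markers), in `[0, 1]`).
#' @export
score_all_cell_types <- function(ranked, collections) {
  if (length(collections) == 0L) {
    stop("score_all_cell_types: no cell-type lists")
  }
  rows <- lapply(names(collections), function(ct) {
    es <- weighted_score(ranked, collections[[ct]])
    data.frame(cell_type = ct,
               weighted_score = es$weighted_score,
               n_markers = es$n_markers,
               n_found = es$n_found,
               normalized_score = es$weighted_score / (20 * es$n_markers),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$weighted_score, out$cell_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
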