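# Readers/writers for the delimited-text formats the pipeline exchanges:
# DEG tables, gene-by-sample expression matrices, GMT gene sets, ortholog
# maps, cell-type compendia and PD endpoint tables.  All validation lives
# here so downstream modules can assume clean inputs.

#' Normalize gene symbols
#'
#' Symbols are matched case-insensitively throughout the pipeline: mouse
#' symbols are conventionally mixed case (`Cxcl1`) while human symbols are
#' upper case (`CXCL1`).  Normalization uppercases and strips surrounding
#' whitespace.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

# Collapse duplicate keys by the arithmetic mean of each numeric column.
# Returns the collapsed data.frame plus the number of rows merged away.
dedup_mean <- function(df, key_col, num_cols) {
  dup <- duplicated(df[[key_col]])
  n_merged <- sum(dup)
  if (n_merged == 0L) {
    return(list(df = df, n_merged = 0L))
  }
  keys <- unique(df[[key_col]])
  agg <- lapply(num_cols, function(cc) {
    as.numeric(tapply(df[[cc]], df[[key_col]], mean)[keys])
  })
  out <- data.frame(key = keys, stringsAsFactors = FALSE)
  names(out) <- key_col
  for (i in seq_along(num_cols)) out[[num_cols[i]]] <- agg[[i]]
  list(df = out, n_merged = n_merged)
}

# Sniff tab vs comma from the first line; tab wins ties (TSV is the
# pipeline's native output format).
detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return("\t")
  n_tab <- lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE)))
  n_com <- lengths(regmatches(first, gregexpr(",", first, fixed = TRUE)))
  if (n_com > n_tab) "," else "\t"
}

read_delim_file <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- detect_delim(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

## ---------------------------------------------------------------- DEGTable

#' Construct a differential-expression table
#'
#' A `deg_table` holds one study's differential-expression results: gene
#' symbol, log2 fold change (`log_ratio`), raw p-value and BH-adjusted
#' p-value (`p_adj_fdr`).  Duplicate symbols (after normalization) are
#' merged by the arithmetic mean of all numeric columns, with a warning
#' reporting how many rows were merged.
#'
#' @param genes character vector of gene symbols.
#' @param log_ratio numeric log2 fold changes.
#' @param p raw p-values in `[0, 1]`.
#' @param p_adj_fdr BH-adjusted p-values in `[0, 1]`.
#' @param study_id label identifying the study.
#' @param species `"human"` or `"mouse"`.
#' @return a `deg_table`: a data.frame with columns `gene`, `log_ratio`,
#'   `p`, `p_adj_fdr` and attributes `study_id` and `species`.
#' @export
deg_table <- function(genes, log_ratio, p, p_adj_fdr,
                      study_id = "study", species = c("human", "mouse")) {
  species <- match.arg(species)
  genes <- normalize_symbol(genes)
  if (any(genes == "" | is.na(genes))) {
    stop("deg_table: empty or missing gene symbols")
  }
  log_ratio <- as.numeric(log_ratio)
  p <- as.numeric(p)
  p_adj_fdr <- as.numeric(p_adj_fdr)
  n <- length(genes)
  if (length(log_ratio) != n || length(p) != n || length(p_adj_fdr) != n) {
    stop("deg_table: column lengths differ")
  }
  if (any(!is.finite(log_ratio))) stop("deg_table: non-finite log_ratio")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("deg_table: p-values outside [0, 1]")
  }
  if (any(is.na(p_adj_fdr)) || any(p_adj_fdr < 0 | p_adj_fdr > 1)) {
    stop("deg_table: adjusted p-values outside [0, 1]")
  }
  df <- data.frame(gene = genes, log_ratio = log_ratio, p = p,
                   p_adj_fdr = p_adj_fdr, stringsAsFactors = FALSE)
  dd <- dedup_mean(df, "gene", c("log_ratio", "p", "p_adj_fdr"))
  if (dd$n_merged > 0L) {
    warning(sprintf("deg_table [%s]: merged %d duplicate gene row(s) by mean",
                    study_id, dd$n_merged))
  }
  out <- dd$df
  rownames(out) <- NULL
  structure(out, study_id = study_id, species = species,
            n_merged = dd$n_merged,
            class = c("deg_table", "data.frame"))
}

#' Read a DEG table from delimited text
#'
#' @param path file with a header row naming at least the gene, log-ratio,
#'   raw-p and adjusted-p columns.
#' @param study_id label for the study.
#' @param species `"human"` or `"mouse"`.
#' @param columns named character vector mapping the four canonical fields
#'   to the file's column names.
#' @param sep field delimiter; `NULL` auto-detects tab vs comma.
#' @return a [deg_table].
#' @export
read_deg_table <- function(path, study_id = basename(path),
                           species = c("human", "mouse"),
                           columns = c(gene = "gene",
                                       log_ratio = "log_ratio",
                                       p = "p", p_adj_fdr = "p_adj_fdr"),
                           sep = NULL) {
  species <- match.arg(species)
  df <- read_delim_file(path, sep)
  missing <- setdiff(unname(columns), names(df))
  if (length(missing) > 0L) {
    stop(sprintf("read_deg_table: missing column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  deg_table(df[[columns[["gene"]]]], df[[columns[["log_ratio"]]]],
            df[[columns[["p"]]]], df[[columns[["p_adj_fdr"]]]],
            study_id = study_id, species = species)
}

#' Write a DEG table as TSV
#' @param x a [deg_table].
#' @param path output path.
#' @export
write_deg_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ------------------------------------------------------ GeneSetCollection

#' Construct a gene-set collection
#'
#' Named, ordered gene lists (signatures or cell-type marker sets).
#' Within-set duplicates are removed keeping first occurrence; set names
#' must be unique and sets non-empty.
#'
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions
#'   (retained for GMT round-trips).
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("gene_set_collection: sets must be named")
  }
  if (anyDuplicated(names(sets))) {
    stop("gene_set_collection: duplicate set names")
  }
  sets <- lapply(sets, function(g) unique(normalize_symbol(g)))
  if (any(lengths(sets) == 0L)) stop("gene_set_collection: empty set")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name TAB description TAB gene...`.
#'
#' @param path GMT file path.
#' @return a [gene_set_collection]; an empty file yields an empty collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(structure(list(), descriptions = character(0),
                     class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("read_gmt: line %d has fewer than 3 fields", bad[1]))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' Write a gene-set collection in GMT format
#' @param x a [gene_set_collection].
#' @param path output path.
#' @export
write_gmt <- function(x, path) {
  desc <- attr(x, "descriptions")
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, desc[[nm]], x[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

## ------------------------------------------------------- ExpressionMatrix

#' Construct an expression matrix with sample groups
#'
#' @param values numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns (colnames = sample ids).
#' @param sample_group named character vector mapping every sample id to a
#'   group label.
#' @return an `expression_matrix` (a numeric matrix with a `sample_group`
#'   attribute).
#' @export
expression_matrix <- function(values, sample_group) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression_matrix: values need gene rownames and sample colnames")
  }
  rownames(values) <- normalize_symbol(rownames(values))
  if (any(!is.finite(values))) stop("expression_matrix: non-finite values")
  if (anyDuplicated(rownames(values))) {
    dup_n <- sum(duplicated(rownames(values)))
    warning(sprintf("expression_matrix: merged %d duplicate gene row(s) by mean",
                    dup_n))
    values <- rowsum(values, rownames(values), reorder = FALSE) /
      as.vector(table(rownames(values))[unique(rownames(values))])
  }
  missing <- setdiff(colnames(values), names(sample_group))
  if (length(missing) > 0L) {
    stop(sprintf("expression_matrix: sample(s) without group: %s",
                 paste(missing, collapse = ", ")))
  }
  structure(values,
            sample_group = sample_group[colnames(values)],
            class = c("expression_matrix", "matrix", "array"))
}

#' Sample-to-group map of an expression matrix
#' @param x an [expression_matrix].
#' @return named character vector, one group label per sample.
#' @export
sample_groups <- function(x) attr(x, "sample_group")

#' Read an expression matrix and its sample-group file
#'
#' @param path delimited file, first column gene symbols, remaining columns
#'   one per sample.
#' @param groups_path two-column delimited file (sample, group) with header.
#' @param sep delimiter; `NULL` auto-detects.
#' @return an [expression_matrix].
#' @export
read_expression_matrix <- function(path, groups_path, sep = NULL) {
  df <- read_delim_file(path, sep)
  if (ncol(df) < 2L) stop("read_expression_matrix: no sample columns")
  genes <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- genes
  gf <- read_delim_file(groups_path, sep)
  groups <- stats::setNames(as.character(gf[[2L]]), as.character(gf[[1L]]))
  expression_matrix(vals, groups)
}

#' Write an expression matrix (and optionally its groups) as TSV
#' @param x an [expression_matrix].
#' @param path output path for the matrix.
#' @param groups_path optional output path for the sample-group table.
#' @export
write_expression_matrix <- function(x, path, groups_path = NULL) {
  df <- data.frame(gene = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    g <- sample_groups(x)
    utils::write.table(
      data.frame(sample = names(g), group = unname(g)),
      groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

## ----------------------------------------------------------- OrthologMap

#' Construct / read a mouse-to-human ortholog map
#'
#' Two columns, mouse then human symbol.  A mouse symbol listed with two
#' different human partners is resolved by keeping the first listing, with
#' a warning (downstream many-to-one collapses are handled by the dedup
#' rule after translation).
#'
#' @param mouse_symbol,human_symbol character vectors.
#' @return an `ortholog_map` data.frame with columns `mouse_symbol`,
#'   `human_symbol`.
#' @export
ortholog_map <- function(mouse_symbol, human_symbol) {
  mouse_symbol <- normalize_symbol(mouse_symbol)
  human_symbol <- normalize_symbol(human_symbol)
  if (any(mouse_symbol == "") || any(human_symbol == "")) {
    stop("ortholog_map: empty symbols")
  }
  dup <- duplicated(mouse_symbol)
  if (any(dup)) {
    warning(sprintf("ortholog_map: dropped %d duplicate mouse symbol row(s)",
                    sum(dup)))
  }
  structure(data.frame(mouse_symbol = mouse_symbol[!dup],
                       human_symbol = human_symbol[!dup],
                       stringsAsFactors = FALSE),
            class = c("ortholog_map", "data.frame"))
}

#' @rdname ortholog_map
#' @param path two-column delimited file (mouse, human) with header.
#' @param sep delimiter; `NULL` auto-detects.
#' @export
read_ortholog_map <- function(path, sep = NULL) {
  df <- read_delim_file(path, sep)
  if (ncol(df) < 2L) stop("read_ortholog_map: need two columns")
  ortholog_map(df[[1L]], df[[2L]])
}

## -------------------------------------------------------- CellCompendium

#' Construct a cell-type reference compendium
#'
#' @param reference numeric matrix, genes in rows, cell types in columns.
#' @return a `cell_compendium` matrix.
#' @export
cell_compendium <- function(reference) {
  reference <- as.matrix(reference)
  if (is.null(rownames(reference)) || is.null(colnames(reference))) {
    stop("cell_compendium: need gene rownames and cell-type colnames")
  }
  rownames(reference) <- normalize_symbol(rownames(reference))
  if (anyDuplicated(rownames(reference))) {
    stop("cell_compendium: duplicate gene symbols")
  }
  if (anyDuplicated(colnames(reference))) {
    stop("cell_compendium: duplicate cell-type labels")
  }
  if (any(!is.finite(reference))) stop("cell_compendium: non-finite values")
  structure(reference, class = c("cell_compendium", "matrix", "array"))
}

#' Read a cell-type compendium matrix
#' @param path delimited file, first column gene symbols, remaining columns
#'   one per cell type.
#' @param sep delimiter; `NULL` auto-detects.
#' @return a [cell_compendium].
#' @export
read_cell_compendium <- function(path, sep = NULL) {
  df <- read_delim_file(path, sep)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df[[1L]])
  cell_compendium(vals)
}

#' Write a cell-type compendium as TSV
#' @param x a [cell_compendium].
#' @param path output path.
#' @export
write_cell_compendium <- function(x, path) {
  df <- data.frame(gene = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## -------------------------------------------------------------- PDTable

#' Construct a pharmacodynamics endpoint table
#'
#' Per-animal endpoint measurements with treatment-group labels and
#' (optionally, for dosed arms) trough plasma exposures.  Group labels
#' follow the convention `negative_control`, `positive_control`, and
#' free-form treated labels (e.g. `"treated:3"`); every endpoint must have
#' at least one row in each control group.
#'
#' @param animal_id character vector.
#' @param group character vector of group labels.
#' @param endpoint character vector of endpoint labels.
#' @param value numeric endpoint values (finite).
#' @param trough_exposure numeric exposures; `NA` allowed (controls).
#' @return a `pd_table` data.frame.
#' @export
pd_table <- function(animal_id, group, endpoint, value,
                     trough_exposure = NA_real_) {
  value <- as.numeric(value)
  if (any(!is.finite(value))) stop("pd_table: non-finite endpoint values")
  df <- data.frame(animal_id = as.character(animal_id),
                   group = as.character(group),
                   endpoint = as.character(endpoint),
                   value = value,
                   trough_exposure = as.numeric(trough_exposure),
                   stringsAsFactors = FALSE)
  for (ep in unique(df$endpoint)) {
    g <- df$group[df$endpoint == ep]
    if (!("negative_control" %in% g) || !("positive_control" %in% g)) {
      stop(sprintf("pd_table: endpoint '%s' lacks a control group", ep))
    }
  }
  structure(df, class = c("pd_table", "data.frame"))
}

#' Read a PD endpoint table
#' @param path delimited file with columns `animal_id`, `group`,
#'   `endpoint`, `value` and optionally `trough_exposure`.
#' @param sep delimiter; `NULL` auto-detects.
#' @return a [pd_table].
#' @export
read_pd_table <- function(path, sep = NULL) {
  df <- read_delim_file(path, sep)
  need <- c("animal_id", "group", "endpoint", "value")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("read_pd_table: missing column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  te <- if ("trough_exposure" %in% names(df)) df$trough_exposure else NA_real_
  pd_table(df$animal_id, df$group, df$endpoint, df$value, te)
}

#' Write a PD table as TSV
#' @param x a [pd_table].
#' @param path output path.
#' @export
write_pd_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
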