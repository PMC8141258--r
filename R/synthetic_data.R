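# Seeded generators reproducing the statistical structure each pipeline
# stage assumes: multi-study DEG tables sharing a latent effect with a
# tunable between-study correlation, cohort expression matrices with a
# planted signature-high subpopulation, fold-change vectors built as known
# mixtures of a cell-type compendium, rankings with markers planted at
# chosen depths, and dose-response PD tables from a known Hill curve.
# Every generator is a pure function of its arguments (seed included).

#' Four-gene Th17 chemokine surrogate signature
#'
#' The default signature used by the cohort generator and the pipeline
#' demo: the neutrophil-recruiting chemokine panel CXCL1, CXCL2, CXCL3
#' and IL-8 that marks the Th17-high endotype in bronchial-biopsy
#' transcriptomes.
#' @export
default_th17_signature <- c("CXCL1", "CXCL2", "CXCL3", "IL8")

#' Generate correlated multi-study DEG tables
#'
#' Draws one latent per-gene effect vector and adds independent per-study
#' noise scaled so that the population Pearson correlation between any
#' two studies' log-ratios equals `rho`
#' (`noise_sd = latent_sd * sqrt((1 - rho)/rho)`; `rho = 0` drops the
#' latent component entirely).  P-values come from a z-model
#' (`z = log_ratio / se`) and adjusted p-values are Benjamini-Hochberg.
#'
#' @param seed integer seed.
#' @param n_studies number of studies (default 2).
#' @param n_genes genes per study (default 2000).
#' @param rho target pairwise correlation, in `[0, 1)` (default 0.7).
#' @param latent_sd sd of the shared latent effect (default 1).
#' @param se standard error used in the p-value z-model (default 0.25).
#' @param species species label for the tables (default `"human"`).
#' @return list of [deg_table]s with study ids `study1, study2, ...`.
#' @export
gen_deg_studies <- function(seed, n_studies = 2L, n_genes = 2000L,
                            rho = 0.7, latent_sd = 1, se = 0.25,
                            species = "human") {
  if (rho < 0 || rho >= 1) stop("gen_deg_studies: rho must be in [0, 1)")
  genes <- sprintf("G%05d", seq_len(n_genes))
  with_seed(seed, {
    if (rho > 0) {
      latent <- stats::rnorm(n_genes, 0, latent_sd)
      noise_sd <- latent_sd * sqrt((1 - rho) / rho)
    } else {
      latent <- numeric(n_genes)
      noise_sd <- latent_sd
    }
    lapply(seq_len(n_studies), function(k) {
      lr <- latent + stats::rnorm(n_genes, 0, noise_sd)
      p <- 2 * stats::pnorm(-abs(lr / se))
      deg_table(genes, lr, p, stats::p.adjust(p, method = "BH"),
                study_id = sprintf("study%d", k), species = species)
    })
  })
}

#' Generate a cohort expression matrix with a planted signature-high group
#'
#' Baseline expression is Normal(0, `noise_sd`) per gene and sample; a
#' planted fraction of samples receives `+shift` on every signature gene.
#' The ground-truth labels are returned for recovery scoring.
#'
#' @param seed integer seed.
#' @param n_samples cohort size (default 60).
#' @param planted_fraction fraction of signature-high samples (default
#'   0.4); must plant at least one sample.
#' @param shift expression shift on signature genes (default 2, i.e.
#'   2 x `noise_sd` at the default noise).
#' @param signature character vector of signature gene symbols (default:
#'   the 4-gene Th17 chemokine signature).
#' @param n_genes total genes including the signature (default 200).
#' @param noise_sd baseline noise sd (default 1).
#' @return list with `matrix` (an [expression_matrix], group label
#'   `"cohort"` for all samples) and `truth` (named `"high"`/`"low"`
#'   vector).
#' @export
gen_cohort_matrix <- function(seed, n_samples = 60L, planted_fraction = 0.4,
                              shift = 2, signature = default_th17_signature,
                              n_genes = 200L, noise_sd = 1) {
  n_planted <- floor(planted_fraction * n_samples)
  if (n_planted < 1L) {
    stop("gen_cohort_matrix: planted_fraction * n_samples < 1")
  }
  signature <- normalize_symbol(signature)
  n_bg <- n_genes - length(signature)
  if (n_bg < 0L) stop("gen_cohort_matrix: n_genes smaller than signature")
  genes <- c(signature, sprintf("BG%04d", seq_len(n_bg)))
  samples <- sprintf("S%03d", seq_len(n_samples))
  with_seed(seed, {
    vals <- matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
                   n_genes, n_samples, dimnames = list(genes, samples))
    planted <- sort(sample.int(n_samples, n_planted))
    vals[signature, planted] <- vals[signature, planted] + shift
    truth <- stats::setNames(rep("low", n_samples), samples)
    truth[planted] <- "high"
    list(matrix = expression_matrix(
           vals, stats::setNames(rep("cohort", n_samples), samples)),
         truth = truth)
  })
}

#' Generate a compendium mixture fold-change vector
#'
#' Builds a compendium with `markers_per_type` distinctive genes per cell
#' type (background Normal(0, 1), markers shifted by `marker_strength`)
#' and a fold-change vector `compendium %*% w_true + Normal(0, noise_sd)`.
#'
#' @param seed integer seed.
#' @param n_genes genes (default 500); must exceed `n_cell_types`.
#' @param n_cell_types cell types (default 10).
#' @param markers_per_type distinctive genes per type (default 30).
#' @param marker_strength marker elevation over background (default 5).
#' @param w_true true mixing weights, length `n_cell_types`; default is
#'   2-sparse: +5 on the first cell type, -3 on the second.
#' @param noise_sd additive noise on the fold changes (default 0).
#' @return list with `input` (a [dcq_input]), `w_true` (named),
#'   `compendium` (the full [cell_compendium]).
#' @export
gen_mixture_foldchange <- function(seed, n_genes = 500L, n_cell_types = 10L,
                                   markers_per_type = 30L,
                                   marker_strength = 5, w_true = NULL,
                                   noise_sd = 0) {
  if (n_genes <= n_cell_types) {
    stop("gen_mixture_foldchange: need more genes than cell types")
  }
  if (markers_per_type * n_cell_types > n_genes) {
    stop("gen_mixture_foldchange: marker blocks exceed gene count")
  }
  if (is.null(w_true)) {
    w_true <- numeric(n_cell_types)
    w_true[1L] <- 5
    w_true[2L] <- -3
  }
  stopifnot(length(w_true) == n_cell_types)
  cts <- sprintf("celltype%02d", seq_len(n_cell_types))
  genes <- sprintf("G%05d", seq_len(n_genes))
  names(w_true) <- cts
  with_seed(seed, {
    ref <- matrix(stats::rnorm(n_genes * n_cell_types), n_genes,
                  n_cell_types, dimnames = list(genes, cts))
    for (k in seq_len(n_cell_types)) {
      idx <- ((k - 1L) * markers_per_type + 1L):(k * markers_per_type)
      ref[idx, k] <- ref[idx, k] + marker_strength
    }
    # canonical scale: unit-variance reference profiles, so mixing
    # weights and fitted (standardized-scale) quantities are comparable
    ref <- ref %*% diag(1 / apply(ref, 2L, stats::sd), n_cell_types)
    dimnames(ref) <- list(genes, cts)
    comp <- cell_compendium(ref)
    fc <- as.vector(ref %*% w_true) + stats::rnorm(n_genes, 0, noise_sd)
    names(fc) <- genes
    list(input = dcq_input(fc, comp), w_true = w_true, compendium = comp)
  })
}

#' Generate a DEG table with markers planted at chosen ranks
#'
#' Fold changes are strictly decreasing in rank (rank r gets
#' `(n_genes - r) / 100`), so the fold-change ranking reproduces the
#' planted layout exactly; marker genes are placed at `marker_ranks` and
#' background genes fill the remaining ranks in seeded random order.
#'
#' @param seed integer seed.
#' @param n_genes universe size (default 2500).
#' @param marker_ranks integer ranks at which markers are planted
#'   (default `1:30`).
#' @return list with `table` (a [deg_table]), `markers` (the planted
#'   marker symbols, in rank order) and `ranks` (`marker_ranks`).
#' @export
gen_ranked_planting <- function(seed, n_genes = 2500L, marker_ranks = 1:30) {
  marker_ranks <- as.integer(marker_ranks)
  if (any(marker_ranks < 1L | marker_ranks > n_genes) ||
      anyDuplicated(marker_ranks)) {
    stop("gen_ranked_planting: marker_ranks must be distinct ranks in range")
  }
  n_mk <- length(marker_ranks)
  markers <- sprintf("MARKER%03d", seq_len(n_mk))
  background <- sprintf("BG%05d", seq_len(n_genes - n_mk))
  with_seed(seed, {
    gene_at_rank <- character(n_genes)
    gene_at_rank[marker_ranks] <- markers
    gene_at_rank[-marker_ranks] <- sample(background)
    lr <- (n_genes - seq_len(n_genes)) / 100
    p <- pmin(1, seq_len(n_genes) / n_genes)
    tab <- deg_table(gene_at_rank, lr, p, stats::p.adjust(p, method = "BH"),
                     study_id = "planted_ranking", species = "mouse")
    # restore planted order (deg_table keeps input order; ranks align)
    list(table = tab, markers = markers, ranks = marker_ranks)
  })
}

#' Generate a dose-response PD endpoint table from a known Hill truth
#'
#' Emulates an allergen-challenge efficacy design: a saline negative
#' control, a challenged vehicle positive control, and dosed arms whose
#' trough exposures follow a linear dose-exposure map.  Each endpoint has
#' a baseline (negative-control mean) and an induction (positive minus
#' negative control); a treated arm's mean is
#' `baseline + induction * (1 - f)` where `f` is the true fractional
#' inhibition from that endpoint's Hill curve at the arm's exposure.
#' Per-animal values are Normal(group mean, `cv * induction`).
#'
#' Default design: saline n = 6, challenge n = 8, dosed arms n = 8 each;
#' doses 1, 3, 10, 30 with exposure = 40 x dose (nM); endpoints IL-17
#' (EC50 120 nM), IL-22 (EC50 600 nM, a 1:5 potency shift), neutrophils
#' (tracking IL-17), and eosinophils (a Th2 endpoint the mechanism does
#' not touch, `I_max = 0`); Hill slope 1.5 throughout.
#'
#' @param seed integer seed.
#' @param doses dose levels of the treated arms.
#' @param exposure_per_dose trough exposure per unit dose (default 40).
#' @param n_neg,n_pos,n_treated group sizes (defaults 6, 8, 8).
#' @param endpoints data.frame with columns `endpoint`, `baseline`,
#'   `induction`, `imax`, `ec50`, `h` (see default).
#' @param cv per-animal noise sd as a fraction of each endpoint's
#'   induction (default 0; 0 makes percent inhibition match truth
#'   exactly).
#' @return list with `table` (a [pd_table]; treated groups labelled
#'   `"treated:<dose>"`), `truth` (the endpoint parameter table plus a
#'   dose/exposure/true-inhibition grid).
#' @export
gen_pd_table <- function(seed, doses = c(1, 3, 10, 30),
                         exposure_per_dose = 40,
                         n_neg = 6L, n_pos = 8L, n_treated = 8L,
                         endpoints = default_pd_endpoints(), cv = 0) {
  need <- c("endpoint", "baseline", "induction", "imax", "ec50", "h")
  stopifnot(all(need %in% names(endpoints)))
  exposures <- doses * exposure_per_dose
  grps <- c("negative_control", "positive_control",
            sprintf("treated:%g", doses))
  sizes <- c(n_neg, n_pos, rep(n_treated, length(doses)))
  grp_exposure <- c(NA_real_, NA_real_, exposures)
  with_seed(seed, {
    rows <- list()
    truth_grid <- list()
    for (i in seq_along(endpoints$endpoint)) {
      ep <- endpoints[i, ]
      inh_frac <- (ep$imax / 100) *
        exposures^ep$h / (ep$ec50^ep$h + exposures^ep$h)
      means <- c(ep$baseline, ep$baseline + ep$induction,
                 ep$baseline + ep$induction * (1 - inh_frac))
      for (g in seq_along(grps)) {
        n <- sizes[g]
        vals <- means[g] + stats::rnorm(n, 0, cv * abs(ep$induction))
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("%s_%s_%02d", ep$endpoint, grps[g], seq_len(n)),
          group = grps[g], endpoint = ep$endpoint, value = vals,
          trough_exposure = grp_exposure[g], stringsAsFactors = FALSE)
      }
      truth_grid[[i]] <- data.frame(
        endpoint = ep$endpoint, dose = doses, exposure = exposures,
        true_inhibition = 100 * inh_frac, stringsAsFactors = FALSE)
    }
    all_rows <- do.call(rbind, rows)
    grid <- do.call(rbind, truth_grid)
    list(table = pd_table(all_rows$animal_id, all_rows$group,
                          all_rows$endpoint, all_rows$value,
                          all_rows$trough_exposure),
         truth = list(endpoints = endpoints, grid = grid))
  })
}

#' @rdname gen_pd_table
#' @export
default_pd_endpoints <- function() {
  data.frame(
    endpoint = c("IL-17", "IL-22", "neutrophils", "eosinophils"),
    baseline = c(10, 8, 20, 30),
    induction = c(100, 60, 180, 150),
    imax = c(100, 100, 100, 0),
    ec50 = c(120, 600, 150, 120),
    h = 1.5,
    stringsAsFactors = FALSE)
}
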