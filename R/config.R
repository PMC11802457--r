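#' Pipeline configuration
#'
#' Bundles every tunable constant of the pipeline with the defaults used
#' in the hippocampal-niche aging workflow. All downstream functions take
#' individual arguments; this object is a convenient single source when
#' running the full pipeline or loading settings from YAML.
#'
#' @param scale_factor Library-size scale factor for log-normalization.
#' @param n_hvg Number of highly variable genes to select.
#' @param score_bins Expression bins for module-score control matching.
#' @param score_ctrl Control genes drawn per gene-set gene.
#' @param n_pcs_curve Principal components used for principal-curve fits.
#' @param n_temporal_clusters Fuzzy c-means cluster count on age profiles.
#' @param fuzzifier Fuzzy c-means fuzzifier m (> 1).
#' @param membership_threshold Minimum max-membership for trend-gene
#'   assignment, in (0, 1].
#' @param min_profile_sd Low-variation filter: rows of the age-profile
#'   matrix with standard deviation across age means below this value are
#'   excluded before standardization.
#' @param rf_top_features Features kept in the differentiation-model
#'   retrain.
#' @param markers_per_class Markers per lineage class fed to the
#'   differentiation model before importance filtering.
#' @param min_shared_celltypes Populations that must share a trend gene
#'   for it to enter the core aging signature.
#' @param niche_populations Cell types regarded as the main niche
#'   populations for the core aging signature.
#' @param is_threshold Module-score threshold (strict `>`) for calling
#'   inflammatory spots.
#' @param n_ens_layers Extended-neighbour rings beyond the nearest
#'   neighbours in the spot hierarchy.
#' @param n_modules Pseudotime / pseudo-spatial gene-module count.
#' @param miche_radius_um Microniche circle radius in micrometres.
#' @param miche_overlap Fractional overlap of consecutive tiling circles
#'   along the reference line (0.5 means centre spacing = radius).
#' @param train_frac Fraction of the least-populated age class used for
#'   classifier training.
#' @param cv_folds Cross-validation folds for the age classifier.
#' @param hvg_loess_span Span of the loess mean-variance trend.
#' @param seed Integer seed threaded through every stochastic step.
#' @return A named list of class `niche_config`.
#' @export
niche_config <- function(scale_factor = 10000,
                         n_hvg = 5000,
                         score_bins = 24,
                         score_ctrl = 100,
                         n_pcs_curve = 7,
                         n_temporal_clusters = 8,
                         fuzzifier = 1.25,
                         membership_threshold = 0.5,
                         min_profile_sd = 0.05,
                         rf_top_features = 100,
                         markers_per_class = 50,
                         min_shared_celltypes = 2,
                         niche_populations = c("astrocyte", "qNSC",
                                               "granule cell",
                                               "endothelial", "microglia"),
                         is_threshold = 0,
                         n_ens_layers = 2,
                         n_modules = 4,
                         miche_radius_um = 55,
                         miche_overlap = 0.5,
                         train_frac = 0.7,
                         cv_folds = 10,
                         hvg_loess_span = 0.3,
                         seed = 1L) {
  cfg <- list(
    scale_factor = scale_factor, n_hvg = n_hvg, score_bins = score_bins,
    score_ctrl = score_ctrl, n_pcs_curve = n_pcs_curve,
    n_temporal_clusters = n_temporal_clusters, fuzzifier = fuzzifier,
    membership_threshold = membership_threshold,
    min_profile_sd = min_profile_sd, rf_top_features = rf_top_features,
    markers_per_class = markers_per_class,
    min_shared_celltypes = min_shared_celltypes,
    niche_populations = niche_populations, is_threshold = is_threshold,
    n_ens_layers = n_ens_layers, n_modules = n_modules,
    miche_radius_um = miche_radius_um, miche_overlap = miche_overlap,
    train_frac = train_frac, cv_folds = cv_folds,
    hvg_loess_span = hvg_loess_span, seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "niche_config")
}

validate_config <- function(cfg) {
  pos <- c("scale_factor", "n_hvg", "score_bins", "score_ctrl",
           "n_pcs_curve", "n_temporal_clusters", "rf_top_features",
           "markers_per_class", "min_shared_celltypes", "n_ens_layers",
           "n_modules", "miche_radius_um", "train_frac", "cv_folds")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      stop(nm, " must be a positive scalar", call. = FALSE)
    }
  }
  if (cfg$fuzzifier <= 1) stop("fuzzifier must exceed 1", call. = FALSE)
  if (cfg$membership_threshold <= 0 || cfg$membership_threshold > 1) {
    stop("membership_threshold must lie in (0, 1]", call. = FALSE)
  }
  for (nm in c("train_frac", "miche_overlap")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] >= 1) {
      stop(nm, " must lie in [0, 1)", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Keys in the file override [niche_config()] defaults; unknown keys are
#' an error so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `niche_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(niche_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(niche_config, raw)
}

#' @export
print.niche_config <- function(x, ...) {
  cat("<niche_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
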