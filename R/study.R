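# Crossed-design simulation runner: builds the factor grid, pairs generating
# regimes with method families per condition type, fits every method with the
# true number of components and the true sparsity level (oracle tuning, the
# comparison protocol), and collects aligned performance measures.
#
# Condition types:
#   I   matching sparsity   - sparse-loadings data (alg1) analyzed by
#       loadings methods; sparse-weights data (alg2) by weights methods.
#   II  double sparsity     - alg3 data (loadings and weights sparse with
#       disjoint supports) analyzed by both families.
#   III mismatching sparsity- families swapped across generators; recovery
#       measured by Tucker congruence against the cross-role truth.

loadings_methods <- c("varimax", "simplimax", "spca-rsvd")
weights_methods <- c("spca", "pathspca", "gpower")

method_family <- function(method) {
  if (method %in% loadings_methods) "loadings"
  else if (method %in% weights_methods) "weights"
  else stop("unknown method: ", method)
}

#' Fit one sparse PCA method with a target sparsity level
#'
#' Dispatcher used by the simulation runner and the empirical pipeline.
#' Loadings methods (\code{"varimax"}, \code{"simplimax"}) fit ordinary PCA,
#' rotate, and threshold the rotated loadings to the target proportion;
#' \code{"spca-rsvd"}, \code{"spca"}, \code{"pathspca"}, and \code{"gpower"}
#' receive a per-component cardinality of \code{round((1 - ps) * J)}
#' nonzeros.
#'
#' @param X Numeric data matrix.
#' @param K Number of components.
#' @param method One of \code{"varimax"}, \code{"simplimax"},
#'   \code{"spca-rsvd"}, \code{"spca"}, \code{"pathspca"}, \code{"gpower"}.
#' @param ps Target proportion of zeros in the sparse matrix (ignored when
#'   \code{cardinality} is given).
#' @param cardinality Nonzeros per component, overriding \code{ps}.
#' @param n_starts Random starts for Simplimax.
#' @param seed Optional seed (Simplimax starts are stochastic).
#' @param ... Further arguments passed to the underlying fitter.
#' @return An object of class \code{"spca_model"}.  For rotation methods the
#'   thresholded loadings and the zero mask are in \code{$loadings} and
#'   \code{$zero_mask}.
#' @export
fit_sparse_pca <- function(X, K, method, ps = 0, cardinality = NULL,
                           n_starts = 10L, seed = NULL, ...) {
  X <- as.matrix(X)
  J <- ncol(X)
  if (is.null(cardinality)) cardinality <- ps_to_cardinality(ps, J)
  if (method %in% loadings_methods && method != "spca-rsvd") {
    # unit-norm score convention (T = U, P = V D): the loadings carry the
    # scale, so thresholding acts on the correlation-scaled entries and the
    # conventions match the sparse-loadings estimators and generators
    s <- truncated_svd(X, K)
    base <- list(scores = s$u, loadings = s$v %*% diag(s$d, K))
    rot <- if (method == "varimax") {
      if (K >= 2L) rotate_varimax(base$loadings, scores = base$scores, ...)
      else list(rotated_loadings = base$loadings,
                rotated_scores = base$scores, Q = diag(1))
    } else {
      m <- as.integer(round(ps * J * K))
      rotate_simplimax(base$loadings, m = m, scores = base$scores,
                       n_starts = n_starts, seed = seed, ...)
    }
    th <- threshold_to_sparsity(rot$rotated_loadings, ps)
    mod <- component_model(rot$rotated_scores, th$loadings, weights = NULL,
                           method = method,
                           extra = list(zero_mask = th$zero_mask,
                                        rotation = rot$Q))
    return(mod)
  }
  pen <- penalty_spec("cardinality", cardinality = cardinality)
  switch(method,
         "spca-rsvd" = spca_rsvd(X, K, pen, ...),
         "spca" = spca_zou(X, K, pen, ...),
         "pathspca" = pathspca(X, K, r = cardinality, ...),
         "gpower" = gpower(X, K, pen, ...),
         stop("unknown method: ", method))
}

#' Evaluate a fitted model against the planted truth
#'
#' Aligns the model's sparse matrix to the condition's sparse target over all
#' column permutations and signs (minimum SRE for matching/double sparsity,
#' maximum Tucker congruence under mismatch), then computes the performance
#' measures on the aligned model.
#'
#' @param model An \code{"spca_model"}.
#' @param dataset An \code{"spca_dataset"} from [generate_dataset()].
#' @param condition_type \code{"I"}, \code{"II"}, or \code{"III"}.
#' @return Named list: \code{sre_scores}, \code{sre_sparse} (SRE of the
#'   matrix the method sparsifies; \code{NA} under mismatch),
#'   \code{cossim_scores} and \code{cossim_crossparam} (mismatch only),
#'   \code{mr}, \code{pev}, plus the alignment used.
#' @export
evaluate_model <- function(model, dataset, condition_type = c("I", "II", "III")) {
  condition_type <- match.arg(condition_type)
  family <- method_family(model$method)
  est_sparse <- if (family == "loadings") model$loadings else model$weights
  mismatch <- condition_type == "III"
  if (mismatch) {
    truth_sparse <- if (family == "loadings") dataset$W_true else dataset$P_true
    truth_mask <- if (family == "loadings") dataset$zero_mask_W
                  else dataset$zero_mask_P
  } else {
    truth_sparse <- if (family == "loadings") dataset$P_true else dataset$W_true
    truth_mask <- if (family == "loadings") dataset$zero_mask_P
                  else dataset$zero_mask_W
  }
  if (is.null(truth_sparse))
    stop("dataset lacks the truth matrix required for this pairing")
  objective <- if (mismatch) "max-cossim" else "min-sre"
  al <- align_components(est_sparse, truth_sparse, objective = objective)
  model <- apply_alignment(model, al)
  est_sparse <- if (family == "loadings") model$loadings else model$weights
  mr_val <- if (is.null(truth_mask)) NA_real_ else mr(truth_mask, est_sparse == 0)
  out <- list(
    method = model$method,
    condition_type = condition_type,
    sre_scores = if (mismatch) NA_real_ else sre(model$scores, dataset$T_true),
    sre_sparse = if (mismatch) NA_real_ else sre(est_sparse, truth_sparse),
    cossim_scores = if (mismatch) cossim(model$scores, dataset$T_true)
                    else NA_real_,
    cossim_crossparam = if (mismatch) al$value else NA_real_,
    mr = mr_val,
    pev = pev(dataset$X, model$scores, model$loadings),
    alignment = al)
  out
}

#' Build the crossed simulation design
#'
#' Full Cartesian product of the factor grids, replicated, with a
#' deterministic per-dataset seed derived from the condition fields and the
#' master seed.
#'
#' @param grids Named list of factor levels: \code{I}, \code{J}, \code{K},
#'   \code{vaf}, \code{ps} (all non-empty numeric vectors).
#' @param reps Number of replicate datasets per condition.
#' @param regime Generating regime for every row.
#' @param master_seed Integer master seed.
#' @return Data frame with one row per dataset: \code{regime}, \code{I},
#'   \code{J}, \code{K}, \code{vaf}, \code{ps}, \code{replicate},
#'   \code{seed}.
#' @export
build_design <- function(grids, reps = 1L, regime = "alg1-sparseP",
                         master_seed = 1L) {
  needed <- c("I", "J", "K", "vaf", "ps")
  if (!all(needed %in% names(grids)))
    stop("`grids` must name levels for: ", paste(needed, collapse = ", "))
  if (any(lengths(grids[needed]) == 0L) || reps < 1L)
    stop("empty factor grid")
  g <- expand.grid(I = grids$I, J = grids$J, K = grids$K, vaf = grids$vaf,
                   ps = grids$ps, replicate = seq_len(reps),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$I, g$J, g$K, g$vaf, g$ps, g$replicate), , drop = FALSE]
  rownames(g) <- NULL
  g$regime <- regime
  g$seed <- vapply(seq_len(nrow(g)), function(i) {
    stable_seed(regime, g$I[i], g$J[i], g$K[i], g$vaf[i], g$ps[i],
                g$replicate[i], master_seed)
  }, integer(1))
  g[, c("regime", "I", "J", "K", "vaf", "ps", "replicate", "seed")]
}

default_methods <- function(condition_type, regime) {
  switch(condition_type,
         "I" = if (regime == "alg1-sparseP") loadings_methods
               else weights_methods,
         "II" = c(loadings_methods, weights_methods),
         "III" = if (regime == "alg1-sparseP") weights_methods
                 else loadings_methods)
}

#' Run all methods on one condition
#'
#' Generates the dataset for one design row, fits each method with the true
#' number of components and sparsity level (oracle tuning), and evaluates it
#' under the condition type's rules.  Method failures are recorded as
#' missing values instead of aborting.
#'
#' @param cond One row of a [build_design()] data frame (or an equivalent
#'   list with the same fields).
#' @param condition_type \code{"I"}, \code{"II"}, or \code{"III"}.
#' @param methods Methods to run; defaults to the families paired with the
#'   regime under this condition type.
#' @param oracle_tuning Use the true sparsity level (\code{FALSE} fits
#'   without sparsity, for reference runs).
#' @return Long data frame with columns \code{regime}, \code{I}, \code{J},
#'   \code{K}, \code{vaf}, \code{ps}, \code{replicate},
#'   \code{condition_type}, \code{method}, \code{metric}, \code{value}.
#' @export
run_condition <- function(cond, condition_type = c("I", "II", "III"),
                          methods = NULL, oracle_tuning = TRUE) {
  condition_type <- match.arg(condition_type)
  if (is.null(methods)) methods <- default_methods(condition_type, cond$regime)
  rows <- list()
  metrics_kept <- c("sre_sparse", "sre_scores", "cossim_crossparam",
                    "cossim_scores", "mr", "pev")
  for (method in methods) {
    family <- method_family(method)
    scenario <- if (family == "loadings") "sparse-P" else "sparse-W"
    ds <- generate_dataset(cond$regime, I = cond$I, J = cond$J, K = cond$K,
                           vaf = cond$vaf, ps = cond$ps, seed = cond$seed,
                           scenario = scenario)
    vals <- tryCatch(suppressWarnings({
      fit <- fit_sparse_pca(ds$X, K = cond$K, method = method,
                            ps = if (oracle_tuning) cond$ps else 0,
                            seed = cond$seed)
      ev <- evaluate_model(fit, ds, condition_type)
      unlist(ev[metrics_kept])
    }), error = function(e) {
      stats::setNames(rep(NA_real_, length(metrics_kept)), metrics_kept)
    })
    rows[[method]] <- data.frame(
      regime = cond$regime, I = cond$I, J = cond$J, K = cond$K,
      vaf = cond$vaf, ps = cond$ps, replicate = cond$replicate,
      condition_type = condition_type, method = method,
      metric = metrics_kept, value = as.numeric(vals[metrics_kept]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run a (reduced) crossed simulation study
#'
#' Executes [build_design()] and [run_condition()] over the configured factor
#' grids for the requested condition types and summarizes each
#' condition-method-metric cell by its median and quartiles.  Fully
#' reproducible from the configuration and master seed.
#'
#' @param config Named list with elements \code{design} (factor grids:
#'   \code{I}, \code{J}, \code{K}, \code{vaf}, \code{ps}, and
#'   \code{ps_disjoint} for the double-sparsity regime), \code{reps},
#'   \code{condition_types}, optional \code{methods}, and \code{master_seed}.
#' @param out_dir Optional directory: writes \code{results.csv} (long) and
#'   \code{summary.csv}.
#' @return List of class \code{"spca_study"} with \code{results} (long data
#'   frame) and \code{summary}.
#' @export
run_study <- function(config, out_dir = NULL) {
  design <- config$design
  reps <- config$reps %||% 1L
  types <- config$condition_types %||% c("I", "II", "III")
  master_seed <- config$master_seed %||% 1L
  ps_disjoint <- design$ps_disjoint %||% c(0.7, 0.8, 0.9)
  pieces <- list()
  for (type in types) {
    regimes <- switch(type,
                      "I" = c("alg1-sparseP", "alg2-sparseW"),
                      "II" = "alg3-double",
                      "III" = c("alg1-sparseP", "alg2-sparseW"))
    for (regime in regimes) {
      grids <- list(I = design$I, J = design$J, K = design$K,
                    vaf = design$vaf,
                    ps = if (regime == "alg3-double") ps_disjoint
                         else design$ps)
      des <- build_design(grids, reps = reps, regime = regime,
                          master_seed = master_seed)
      for (i in seq_len(nrow(des))) {
        pieces[[length(pieces) + 1L]] <-
          run_condition(des[i, ], condition_type = type,
                        methods = config$methods)
      }
    }
  }
  results <- do.call(rbind, pieces)
  rownames(results) <- NULL
  key <- c("regime", "I", "J", "K", "vaf", "ps", "condition_type",
           "method", "metric")
  agg <- stats::aggregate(
    results$value, by = results[key],
    FUN = function(v) c(median = stats::median(v, na.rm = TRUE),
                        q1 = unname(stats::quantile(v, 0.25, na.rm = TRUE)),
                        q3 = unname(stats::quantile(v, 0.75, na.rm = TRUE)),
                        n = sum(!is.na(v)), n_failed = sum(is.na(v))))
  summary_df <- cbind(agg[key], as.data.frame(agg$x))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  structure(list(results = results, summary = summary_df, config = config),
            class = "spca_study")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tune the sparsity level by the index of sparseness
#'
#' Fits the method at each sparsity proportion of a grid (mapped to a
#' per-component cardinality), computes
#' \eqn{IS = PEV_{sparse} \cdot PEV_{pca} \cdot PS}, and returns the grid
#' point maximizing it together with the full IS and PEV curves.
#'
#' @param X Numeric data matrix (centered/scaled).
#' @param K Number of components.
#' @param method Method label accepted by [fit_sparse_pca()].
#' @param ps_grid Grid of sparsity proportions in \code{[0, 1)}.
#' @param ... Passed to [fit_sparse_pca()].
#' @return List with \code{best_ps}, \code{curve} (data frame with
#'   \code{ps}, \code{pev_sparse}, \code{is}), and \code{pev_pca}.
#' @export
tune_sparsity_by_is <- function(X, K, method, ps_grid, ...) {
  if (any(ps_grid < 0 | ps_grid >= 1)) stop("`ps_grid` must lie in [0, 1)")
  base <- pca_fit(X, K)
  pev_pca <- pev(X, base$scores, base$loadings)
  pev_sparse <- rep(NA_real_, length(ps_grid))
  for (i in seq_along(ps_grid)) {
    fit <- tryCatch(fit_sparse_pca(X, K, method, ps = ps_grid[i], ...),
                    error = function(e) NULL)
    if (!is.null(fit))
      pev_sparse[i] <- pev(X, fit$scores, fit$loadings)
  }
  if (all(is.na(pev_sparse))) stop("every fit on the sparsity grid failed")
  is_curve <- pev_sparse * pev_pca * ps_grid
  best <- which.max(is_curve)
  list(best_ps = ps_grid[best],
       curve = data.frame(ps = ps_grid, pev_sparse = pev_sparse,
                          is = is_curve),
       pev_pca = pev_pca)
}
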