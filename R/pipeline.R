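#' End-to-end clustering pipeline
#'
#' Runs the whole workflow on in-memory inputs: density-tracking constraint
#' mining from the expression matrix, ontology constraint mining from
#' annotations (when an ontology is supplied), weight fusion, the
#' evolutionary clustering run, and silhouette evaluation. All stages share
#' one seed, so a given configuration reproduces exactly.
#'
#' @param expr Expression tibble (will be min-max normalized unless already
#'   flagged normalized).
#' @param k Number of clusters.
#' @param ontology Optional `ssmoc_ontology`; when `NULL`, only
#'   expression-derived constraints are used (they still pass through
#'   fusion against an empty ontology set).
#' @param annotations Annotation tibble, required with `ontology`.
#' @param s Constraints selected per individual.
#' @param theta GO action parameter, default 0.5.
#' @param hi,lo Gene-similarity thresholds for ontology constraints.
#' @param epsilon,stride,n_cl,n_ml Density-tracking parameters (see
#'   [expression_constraints()]).
#' @param seed Integer seed for the whole pipeline.
#' @param ... Further [run_config()] overrides passed to [mscc()].
#' @return List: `fit` (`mscc_fit`), `labels`, `si`, `constraints`
#'   (the fused `ssmoc_weights`), and the mined `omega` / `omega_star`
#'   sets.
#' @export
run_pipeline <- function(expr, k, ontology = NULL, annotations = NULL,
                         s = 15, theta = 0.5, hi = 0.9, lo = 0.1,
                         epsilon = 0.8, stride = 2, n_cl = NULL, n_ml = NULL,
                         seed = 1, ...) {
  if (k < 2) stop("k must be >= 2")
  if (!is.null(ontology) && is.null(annotations)) {
    stop("an ontology requires annotations")
  }
  if (!is_normalized(expr)) expr <- normalize_minmax(expr)
  extra <- list(...)
  b <- if (!is.null(extra$b)) extra$b else 10

  if (!is.null(seed)) set.seed(seed)
  model <- density_model(expr, b = b)
  omega <- expression_constraints(model, epsilon = epsilon,
                                  n_cl = n_cl, n_ml = n_ml, stride = stride)
  omega_star <- if (!is.null(ontology)) {
    sem <- term_semantics(ontology)
    go_constraints(sem, annotations, hi = hi, lo = lo,
                   genes = expr$gene_id)
  } else {
    constraint_set()
  }
  fused <- fuse_constraints(omega, omega_star, theta, expr$gene_id)
  if (s > 0 && nrow(fused$pairs) < 2 * s) {
    stop("only ", nrow(fused$pairs), " fused constraints available; ",
         "s = ", s, " needs 2s = ", 2 * s)
  }
  fit <- mscc(expr, k = k, fused = fused, s = s, seed = seed, ...)
  list(fit = fit, labels = fit$best$labels, si = fit$best$si,
       constraints = fused, omega = omega, omega_star = omega_star)
}
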