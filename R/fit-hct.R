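# Data-frame-first fitting interface and broom-style methods.

ESTIMATORS <- c("OLS", "PGLS", "RegOU")
PREDICTOR_SETS <- list(
  "none" = character(0),
  "clade" = "clade",
  "habitat" = "habitat",
  "clade+habitat" = c("habitat", "clade")
)

# Normalize a predictor-set argument ("clade+habitat", c("habitat","clade"),
# or character(0)) to its canonical label and factor vector.
resolve_predictors <- function(predictors) {
  if (length(predictors) == 1L && grepl("+", predictors, fixed = TRUE)) {
    predictors <- strsplit(predictors, "+", fixed = TRUE)[[1]]
  }
  predictors <- trimws(predictors)
  if (length(predictors) == 1L && predictors %in% c("none", "")) predictors <- character(0)
  bad <- setdiff(predictors, c("habitat", "clade"))
  if (length(bad)) {
    abort(sprintf("Unknown predictor(s): %s. Use 'habitat', 'clade', both, or 'none'.",
                  paste(bad, collapse = ", ")))
  }
  label <- if (!length(predictors)) "none"
  else if (setequal(predictors, c("habitat", "clade"))) "clade+habitat"
  else predictors
  list(label = label, factors = intersect(c("habitat", "clade"), predictors))
}

#' Fit one hematocrit ANCOVA model
#'
#' Fits `hct ~ habitat + clade` (parallel-slopes dummy coding, any subset of
#' the two factors) under one of three residual-covariance estimators:
#'
#' * `"OLS"` — identity covariance (star phylogeny);
#' * `"PGLS"` — Brownian-motion covariance on the tree;
#' * `"RegOU"` — OU-transformed covariance at `d` estimated from the data
#'   (REML by default), with the extra parameter counted in AICc.
#'
#' The tree is Pagel-lengthed if it carries no branch lengths, checked for
#' ultrametricity, and rescaled to height 1. The trait table is aligned to
#' the tree's tip order by exact species-name matching.
#'
#' @param traits Trait table (`species`, `hct`, `habitat`, `clade`).
#' @param tree An `ape::phylo` tree; required for PGLS/RegOU, optional for
#'   OLS.
#' @param predictors `"none"`, `"habitat"`, `"clade"`, or
#'   `"clade+habitat"` (equivalently a character vector of factors).
#' @param estimator One of `"OLS"`, `"PGLS"`, `"RegOU"`.
#' @param d_method Surface on which d is optimized for RegOU: `"REML"`
#'   (default, the reporting convention) or `"ML"`.
#' @return A `regou_fit` object. `tidy()` gives the coefficient table,
#'   `glance()` the one-row model summary; `partial_f_tests()` adds the
#'   factor-block F-tests.
#' @export
#' @examples
#' set.seed(1)
#' sim <- simulate_dataset(sim_config(seed = 1, n_tips = 32))
#' fit <- fit_hct(sim$traits, sim$tree, predictors = "habitat", estimator = "OLS")
#' glance(fit)
fit_hct <- function(traits, tree = NULL,
                    predictors = c("habitat", "clade"),
                    estimator = c("OLS", "PGLS", "RegOU"),
                    d_method = c("REML", "ML")) {
  estimator <- match.arg(estimator)
  d_method <- match.arg(d_method)
  pred <- resolve_predictors(predictors)
  traits <- validate_traits(traits)
  if (estimator != "OLS" || !is.null(tree)) {
    if (is.null(tree)) abort(sprintf("A tree is required for the %s estimator.", estimator))
    tree <- prepare_tree(tree)
    traits <- align_traits_to_tree(traits, tree)
  }
  X <- build_design(traits, pred$factors)
  y <- traits$hct
  fit <- switch(
    estimator,
    OLS = fit_gls(y, X, star_covariance(traits$species), estimator = "OLS"),
    PGLS = fit_gls(y, X, bm_covariance(tree), estimator = "PGLS"),
    RegOU = {
      est <- reml_estimate_d(y, X, tree, surface = d_method)
      f <- fit_gls(y, X, ou_covariance(tree, est$d_hat),
                   k_extra = 1, d = est$d_hat, estimator = "RegOU")
      f$d_profile <- est$profile
      f
    }
  )
  fit$predictors <- pred$label
  fit
}

# Ensure a tree is usable for covariance construction: Pagel lengths where
# none exist, ultrametric, height 1.
prepare_tree <- function(tree) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) tree <- assign_pagel_branch_lengths(tree)
  rescale_tree_height(tree)
}

#' @export
print.regou_fit <- function(x, ...) {
  cat(sprintf("%s fit of hct ~ %s  (n = %d, p = %d, k = %d)\n",
              x$estimator, x$predictors %||% "?", x$n, x$p, x$k))
  if (!is.na(x$d)) cat(sprintf("  OU attenuation d = %.4f\n", x$d))
  cat(sprintf("  lnML = %.2f  AIC = %.2f  AICc = %.2f\n", x$lnml, x$aic, x$aicc))
  cat(sprintf("  MSE = %.2f  SEE = %.2f  r2 = %.2f\n", x$mse, x$see, x$r2))
  print(tidy(x), n = length(x$beta))
  invisible(x)
}

#' Tidy a fitted model's coefficients
#'
#' @param x A `regou_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`
#'   (partial F on 1 and n-p df), `p.value`.
#' @export
tidy.regou_fit <- function(x, ...) {
  ft <- partial_f_tests(x)
  ft <- ft[!is.na(ft$coefficient), ]
  tibble::tibble(term = ft$term, estimate = ft$coefficient,
                 std.error = ft$se, statistic = ft$f, p.value = ft$p_value)
}

#' One-row model summary
#'
#' @param x A `regou_fit`.
#' @param ... Unused.
#' @return A tibble with `estimator`, `predictors`, `n`, `p`, `k`, `lnml`,
#'   `aic`, `aicc`, `mse`, `see`, `r2`, `d`.
#' @export
glance.regou_fit <- function(x, ...) {
  tibble::tibble(
    estimator = x$estimator, predictors = x$predictors %||% NA_character_,
    n = x$n, p = x$p, k = x$k,
    lnml = x$lnml, aic = x$aic, aicc = x$aicc,
    mse = x$mse, see = x$see, r2 = x$r2, d = x$d
  )
}
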