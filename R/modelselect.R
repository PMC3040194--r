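# Model grid, AICc ranking with Burnham-Anderson support labels, group
# means, and report rendering.

# Support bands on delta-AICc, after Burnham & Anderson's rough rules of
# thumb. The anchored edges are 2 (substantial), ~3 falling in the "weaker"
# band, and >10 (virtually none); 4-7 "considerably less" and 7-10 "little"
# fill the gap.
support_label <- function(delta) {
  dplyr::case_when(
    delta <= 2 ~ "substantial",
    delta <= 4 ~ "weaker",
    delta <= 7 ~ "considerably less",
    delta <= 10 ~ "little",
    TRUE ~ "virtually none"
  )
}

#' Fit the full model-comparison grid
#'
#' Crosses the requested predictor sets (default: none, clade, habitat,
#' clade+habitat) with the requested estimators (default OLS, PGLS, RegOU)
#' — 12 fits in the default grid — and ranks all rows by AICc. Ties are
#' broken toward fewer parameters.
#'
#' @inheritParams fit_hct
#' @param predictor_sets Character vector of predictor-set labels from
#'   `c("none", "clade", "habitat", "clade+habitat")`.
#' @param estimators Character subset of `c("OLS", "PGLS", "RegOU")`.
#' @return A `regou_grid` tibble: one row per fit with `predictors`,
#'   `estimator`, `lnml`, `aic`, `aicc`, `mse`, `see`, `r2`, `d`,
#'   `delta_aicc`, `support`, `best`, and the `regou_fit` in list-column
#'   `fit`.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1, n_tips = 24))
#' grid <- model_grid(sim$traits, sim$tree, estimators = c("OLS", "PGLS"))
#' grid[, c("predictors", "estimator", "aicc", "delta_aicc", "support")]
model_grid <- function(traits, tree,
                       predictor_sets = names(PREDICTOR_SETS),
                       estimators = ESTIMATORS,
                       d_method = c("REML", "ML")) {
  d_method <- match.arg(d_method)
  bad <- setdiff(predictor_sets, names(PREDICTOR_SETS))
  if (length(bad)) abort(sprintf("Unknown predictor set(s): %s", paste(bad, collapse = ", ")))
  bad <- setdiff(estimators, ESTIMATORS)
  if (length(bad)) abort(sprintf("Unknown estimator(s): %s", paste(bad, collapse = ", ")))
  cells <- tidyr::expand_grid(predictors = predictor_sets, estimator = estimators)
  fits <- purrr::pmap(cells, function(predictors, estimator) {
    fit_hct(traits, tree, predictors = PREDICTOR_SETS[[predictors]],
            estimator = estimator, d_method = d_method)
  })
  out <- dplyr::bind_cols(
    cells,
    purrr::map_dfr(fits, function(f) glance(f)[, c("n", "p", "k", "lnml", "aic",
                                                   "aicc", "mse", "see", "r2", "d")])
  )
  out$fit <- fits
  out$delta_aicc <- out$aicc - min(out$aicc)
  out$support <- support_label(out$delta_aicc)
  ranked <- order(out$aicc, out$k)
  out$best <- seq_len(nrow(out)) == ranked[1]
  class(out) <- c("regou_grid", class(out))
  out
}

#' @export
print.regou_grid <- function(x, ...) {
  cat(sprintf("Model comparison grid: %d fits, n = %d species\n", nrow(x), x$n[1]))
  b <- which(x$best)
  cat(sprintf("Best by AICc: %s / %s (AICc = %.2f)\n\n",
              x$estimator[b], x$predictors[b], x$aicc[b]))
  print(tibble::as_tibble(x)[, c("predictors", "estimator", "lnml", "aicc",
                                 "delta_aicc", "r2", "d", "support")], n = nrow(x))
  invisible(x)
}

#' Likelihood-ratio tests for phylogenetic signal across a grid
#'
#' For every predictor set present with both a RegOU and an OLS row,
#' computes the LRT of the OU-transform model against OLS ([lrt_signal()]).
#'
#' @param grid A `regou_grid`.
#' @return A tibble with `predictors`, `lnml_ols`, `lnml_regou`,
#'   `statistic`, `df`, `p_value`.
#' @export
grid_lrt <- function(grid) {
  stopifnot(inherits(grid, "regou_grid"))
  sets <- unique(grid$predictors)
  purrr::map_dfr(sets, function(ps) {
    ols <- grid$lnml[grid$predictors == ps & grid$estimator == "OLS"]
    rou <- grid$lnml[grid$predictors == ps & grid$estimator == "RegOU"]
    if (!length(ols) || !length(rou)) return(NULL)
    dplyr::bind_cols(tibble::tibble(predictors = ps, lnml_ols = ols, lnml_regou = rou),
                     lrt_signal(rou, ols))
  })
}

#' Group means and standard errors of hematocrit
#'
#' Simple (non-phylogenetic) arithmetic means of the per-species values,
#' grouped by habitat, clade, or their combination. The SE is the sample
#' standard deviation over `sqrt(n)`; singleton groups get `NA`.
#'
#' @param traits Trait table.
#' @param by `"habitat"`, `"clade"`, or `"clade:habitat"`.
#' @return A tibble with the grouping column(s), `n`, `mean`, `se`.
#' @export
group_means <- function(traits, by = c("habitat", "clade", "clade:habitat")) {
  by <- match.arg(by)
  traits <- validate_traits(traits)
  keys <- strsplit(by, ":", fixed = TRUE)[[1]]
  traits |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$hct),
      se = ifelse(dplyr::n() > 1, sd(.data$hct) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    )
}

# Fixed-format numeric rendering for reports: likelihood-scale quantities to
# 2 decimals, coefficients to 4, blanks (not zeros) for absent values.
fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}

#' Render deterministic report files for a grid
#'
#' Writes, under `dir`:
#' * `model_comparison.tsv` — one row per grid cell (lnML, AIC, AICc, MSE,
#'   SEE, r2, REML d, delta-AICc, support), d blank for non-OU rows;
#' * `coefficients.tsv` — the full-model coefficient/F-test table for the
#'   AICc-best estimator with both factors (when present in the grid), with
#'   a base-group footnote;
#' * `group_means_habitat.tsv`, `group_means_clade.tsv`;
#' * `lrt.tsv` — the per-predictor-set signal LRTs (when RegOU rows exist);
#' * `summary.txt` — a human-readable digest.
#'
#' Output is byte-identical across reruns on identical inputs.
#'
#' @param grid A `regou_grid`.
#' @param traits The trait table the grid was fitted to.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
render_reports <- function(grid, traits, dir) {
  stopifnot(inherits(grid, "regou_grid"))
  traits <- validate_traits(traits)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  comp <- tibble::tibble(
    model = grid$predictors, estimator = grid$estimator,
    ln_ml = fmt_num(grid$lnml, 2), aic = fmt_num(grid$aic, 2),
    aicc = fmt_num(grid$aicc, 2), mse = fmt_num(grid$mse, 2),
    see = fmt_num(grid$see, 2), r2 = fmt_num(grid$r2, 2),
    reml_d = fmt_num(grid$d, 3),
    delta_aicc = fmt_num(grid$delta_aicc, 2), support = grid$support
  )
  f <- file.path(dir, "model_comparison.tsv")
  write.table(comp, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  full_rows <- which(grid$predictors == "clade+habitat")
  if (length(full_rows)) {
    b <- full_rows[order(grid$aicc[full_rows], grid$k[full_rows])][1]
    ftab <- partial_f_tests(grid$fit[[b]])
    coef_tab <- tibble::tibble(
      term = ftab$term,
      coefficient = fmt_num(ftab$coefficient, 4), se = fmt_num(ftab$se, 3),
      f = fmt_num(ftab$f, 2),
      df = ifelse(is.na(ftab$df1), "", paste0(ftab$df1, ", ", ftab$df2)),
      p = fmt_num(ftab$p_value, 4)
    )
    f <- file.path(dir, "coefficients.tsv")
    con <- file(f, "w")
    writeLines(paste0("# estimator: ", grid$estimator[b],
                      "; base groups: Terrestrial (habitat), Colubrinae (clade)"), con)
    write.table(coef_tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    files <- c(files, f)
  }

  for (key in c("habitat", "clade")) {
    gm <- group_means(traits, key)
    gm$mean <- fmt_num(gm$mean, 2)
    gm$se <- fmt_num(gm$se, 2)
    f <- file.path(dir, paste0("group_means_", key, ".tsv"))
    write.table(gm, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }

  lrt <- grid_lrt(grid)
  if (nrow(lrt)) {
    lrt_out <- dplyr::mutate(lrt, dplyr::across(dplyr::where(is.double), ~ fmt_num(.x, 4)))
    f <- file.path(dir, "lrt.tsv")
    write.table(lrt_out, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }

  b <- which(grid$best)
  f <- file.path(dir, "summary.txt")
  writeLines(c(
    sprintf("Models fitted: %d (predictor sets x estimators), n = %d species",
            nrow(grid), grid$n[1]),
    sprintf("Preferred model by AICc: %s with %s (AICc = %s)",
            grid$estimator[b], grid$predictors[b], fmt_num(grid$aicc[b], 2)),
    "",
    paste(utils::capture.output(print(as.data.frame(comp))), collapse = "\n")
  ), f)
  files <- c(files, f)
  invisible(files)
}

#' Plot a model-comparison grid
#'
#' Dot plot of delta-AICc per predictor set and estimator; the dashed lines
#' mark the 2/4/7/10 support-band edges.
#'
#' @param object A `regou_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regou_grid <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$delta_aicc,
                               y = .data$predictors,
                               colour = .data$estimator)) +
    ggplot2::geom_vline(xintercept = c(2, 4, 7, 10), linetype = "dashed",
                        colour = "grey70") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = expression(Delta * "AICc"), y = "Predictor set",
                  colour = "Estimator") +
    ggplot2::theme_minimal()
}

#' Plot group means with standard errors
#'
#' @param traits Trait table.
#' @param by Grouping: `"habitat"` or `"clade"`.
#' @return A ggplot object (mean +/- SE, group sizes annotated).
#' @export
plot_group_means <- function(traits, by = c("habitat", "clade")) {
  by <- match.arg(by)
  gm <- group_means(traits, by)
  ggplot2::ggplot(gm, ggplot2::aes(x = .data[[by]], y = .data$mean)) +
    ggplot2::geom_col(fill = "grey80", colour = "black") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n, y = 1), vjust = 0) +
    ggplot2::labs(x = by, y = "Hematocrit (% packed cell volume)") +
    ggplot2::theme_minimal()
}
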