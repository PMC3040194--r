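test_that("design matrix follows the dummy-coding contract", {
  traits <- tibble::tibble(
    species = c("s1", "s2", "s3"),
    hct = c(27, 30, 25),
    habitat = c("Terrestrial", "Marine", "Semi-aquatic"),
    clade = c("Colubrinae", "Elapidae", "Natricinae")
  )
  X <- build_design(traits, c("habitat", "clade"))
  expect_equal(unname(X["s1", ]), c(1, 0, 0, 0, 0))  # both base levels
  expect_equal(X["s2", c("(Intercept)", "Marine", "Elapidae")], c(1, 1, 1),
               ignore_attr = TRUE)
  expect_equal(sum(X["s2", ]), 3)
  expect_equal(colnames(X)[1], "(Intercept)")
  expect_true(all(X[, -1] %in% c(0, 1)))

  expect_equal(ncol(build_design(traits, character(0))), 1)
  expect_error(
    build_design(dplyr::mutate(traits, habitat = c("Lake", "Marine", "Marine")),
                 "habitat"),
    "Unknown habitat.*Lake"
  )
})

test_that("full-factor design reaches p = 10 with every level present", {
  lv <- trait_levels()
  traits <- tibble::tibble(
    species = paste0("s", 1:28),
    hct = rep(25, 28),
    habitat = rep(lv$habitat, 7),
    clade = rep(lv$clade, each = 4)
  )
  X <- build_design(traits)
  expect_equal(ncol(X), 10)
  expect_equal(colnames(X),
               c("(Intercept)", "Semi-aquatic", "Aquatic", "Marine",
                 "Boidae", "Acrochordidae", "Viperidae", "Homalopsidae",
                 "Elapidae", "Natricinae"))
})

test_that("identity-covariance GLS reproduces the longhand one-dummy fit", {
  # hand-worked: y = (20,22,25,30,33), dummy marks the last two points;
  # normal equations give beta = (67/3, 55/6), SSE = 154.5/9
  traits <- toy_traits()
  X <- build_design(traits, "habitat")
  fit <- fit_gls(traits$hct, X)
  expect_equal(unname(fit$beta), c(67 / 3, 55 / 6), tolerance = 1e-12)
  expect_equal(fit$sse, 154.5 / 9, tolerance = 1e-12)
  expect_equal(fit$mse, 154.5 / 27, tolerance = 1e-12)
  expect_equal(unname(fit$se), sqrt((154.5 / 27) * c(1 / 3, 5 / 6)),
               tolerance = 1e-12)
  expect_equal(fit$lnml, -(5 / 2) * (log(2 * pi * (154.5 / 9) / 5) + 1),
               tolerance = 1e-12)
  expect_equal(fit$r2, 1 - (154.5 / 9) / 118, tolerance = 1e-12)
  expect_equal(fit$see, sqrt(fit$mse), tolerance = 1e-15)
})

test_that("identity-covariance GLS agrees with lm() on random data", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 30
    X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
    y <- 2 + 0.5 * X[, 2] - 1.2 * X[, 3] + rnorm(n)
    fit <- fit_gls(y, X)
    ref <- lm(y ~ X[, 2] + X[, 3])
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-9)
    expect_equal(unname(fit$se), unname(coef(summary(ref))[, 2]), tolerance = 1e-9)
    expect_equal(fit$r2, summary(ref)$r.squared, tolerance = 1e-9)
  }
})

test_that("intercept-only OLS estimates the arithmetic mean", {
  y <- c(4, 8, 15, 16, 23, 42)
  fit <- fit_gls(y, matrix(1, 6, 1, dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(fit$beta), mean(y))
  expect_equal(fit$r2, 0)
})

test_that("GLS log-likelihood matches direct numerical maximization of the MVN density", {
  set.seed(71)
  for (rep in 1:3) {
    n <- 6
    tr <- random_ultrametric(n)
    v <- unclass(ou_covariance(tr, 0.6))
    X <- cbind(1, rbinom(n, 1, 0.5))
    colnames(X) <- c("(Intercept)", "x")
    y <- drop(X %*% c(25, 4)) + drop(crossprod(chol(4 * v), rnorm(n)))
    fit <- fit_gls(y, X, v)
    # independent oracle: unprofiled MVN log-likelihood maximized over
    # (beta, log sigma2) by general-purpose descent
    neg_ll <- function(par) {
      mu <- drop(X %*% par[1:2])
      s2 <- exp(par[3])
      r <- y - mu
      0.5 * (n * log(2 * pi * s2) + determinant(v)$modulus +
               drop(r %*% solve(v, r)) / s2)
    }
    opt <- optim(c(20, 0, 0), neg_ll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    expect_equal(fit$lnml, -opt$value, tolerance = 1e-6)
    expect_equal(unname(fit$beta), opt$par[1:2], tolerance = 1e-4)
  }
})

test_that("PGLS coefficients agree with nlme::gls under Brownian correlation", {
  set.seed(81)
  sim <- simulate_dataset(sim_config(seed = 81, n_tips = 30, n_clades = 3,
                                     d_true = 1))
  fit <- fit_hct(sim$traits, sim$tree, predictors = "habitat", estimator = "PGLS")
  dat <- as.data.frame(align_traits_to_tree(sim$traits, sim$tree))
  rownames(dat) <- dat$species
  dat$habitat <- factor(dat$habitat, levels = trait_levels()$habitat)
  ref <- nlme::gls(hct ~ habitat, data = dat,
                   correlation = ape::corBrownian(1, sim$tree, form = ~species))
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
})

test_that("AICc follows its definition and refuses tiny samples", {
  ic <- aicc(-198.05, k = 5, n = 67)
  expect_equal(ic$aic, 2 * 198.05 + 10)
  expect_equal(ic$aicc, ic$aic + 60 / 61)
  big <- aicc(-100, k = 4, n = 1e7)
  expect_lt(big$aicc - big$aic, 1e-5)
  expect_error(aicc(-10, k = 5, n = 6), "n - k - 1")
})

test_that("rank-deficient designs and singular covariances fail loudly", {
  X <- cbind(`(Intercept)` = 1, a = c(0, 1, 0, 1), b = c(0, 1, 0, 1))
  expect_error(fit_gls(rnorm(4), X), "collinear.*b")
  v <- matrix(1, 3, 3)
  expect_error(fit_gls(rnorm(3), matrix(1, 3, 1, dimnames = list(NULL, "i")), v),
               "singular|positive definite")
})

test_that("partial F equals squared t for one column and matches a longhand refit", {
  traits <- toy_traits()
  X <- build_design(traits, "habitat")
  fit <- fit_gls(traits$hct, X)
  ft <- partial_f_test(fit, "Marine")
  expect_equal(ft$f, (fit$beta[["Marine"]] / fit$se[["Marine"]])^2,
               tolerance = 1e-9)
  expect_equal(ft$df1, 1)
  expect_equal(ft$df2, 3)
  # longhand: reduced model is the grand mean, SSE0 = 118
  expect_equal(ft$f, ((118 - 154.5 / 9) / 1) / ((154.5 / 9) / 3), tolerance = 1e-12)
  expect_error(partial_f_test(fit, "(Intercept)"), "intercept")
  expect_error(partial_f_test(fit, "Nope"), "Unknown")
})

test_that("factor-block F-tests drop the whole dummy block", {
  set.seed(91)
  sim <- simulate_dataset(sim_config(seed = 91, n_tips = 40, n_clades = 4))
  fit <- fit_hct(sim$traits, sim$tree, predictors = "clade+habitat",
                 estimator = "OLS")
  tab <- partial_f_tests(fit)
  hab_row <- tab[tab$term == "Habitat", ]
  q <- length(attr(fit$X, "factors")$habitat)
  expect_equal(hab_row$df1, q)
  expect_equal(hab_row$df2, fit$n - fit$p)
  # brute-force refit without the habitat dummies
  keep <- setdiff(colnames(fit$X), attr(fit$X, "factors")$habitat)
  red <- fit_gls(fit$y, fit$X[, keep, drop = FALSE], fit$V)
  f_ref <- ((red$sse - fit$sse) / q) / (fit$sse / (fit$n - fit$p))
  expect_equal(hab_row$f, f_ref, tolerance = 1e-9)
})

test_that("r2 is zero for intercept-only fits and non-decreasing in added columns", {
  set.seed(101)
  sim <- simulate_dataset(sim_config(seed = 101, n_tips = 30, n_clades = 3))
  r2 <- sapply(c("none", "habitat", "clade+habitat"), function(ps) {
    fit_hct(sim$traits, sim$tree, predictors = ps, estimator = "PGLS")$r2
  })
  expect_equal(unname(r2[["none"]]), 0)
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("REML d estimation prefers the star-ward end on iid data and is bounded", {
  set.seed(111)
  tr <- random_ultrametric(48)
  X <- matrix(1, 48, 1, dimnames = list(tr$tip.label, "(Intercept)"))
  y <- rnorm(48)
  est <- reml_estimate_d(y, X, tr)
  expect_gte(est$d_hat, 0)
  expect_lte(est$d_hat, 1)
  expect_equal(nrow(est$profile), 21)
  expect_lte(est$d_hat, 0.5)  # iid data should not look Brownian
})

test_that("signal LRT clamps at zero and reproduces the chi-square tail", {
  res <- lrt_signal(-5, -5)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # independent chi-square(1) tail via the normal distribution
  res <- lrt_signal(-100, -100 - 3.841 / 2)
  expect_equal(res$statistic, 3.841)
  expect_equal(res$p_value, 2 * (1 - pnorm(sqrt(3.841))), tolerance = 1e-12)
  expect_equal(res$p_value, 0.05, tolerance = 1e-3)
})

test_that("tidy and glance expose the fit as tibbles", {
  fit <- fit_hct(toy_traits(), predictors = "habitat", estimator = "OLS")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("(Intercept)", "Marine"))
  gl <- glance(fit)
  expect_equal(gl$k, fit$p + 1)
  expect_true(is.na(gl$d))
})
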