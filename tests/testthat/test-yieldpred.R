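# synthetic design with planted subcategory effects
synth_design <- function(n, seed, beta = numeric(49), prev = 0.15,
                         intercept = -1, conf_age = 0.2) {
  set.seed(seed)
  x <- matrix(rbinom(n * 49, 1, prev), n, 49,
              dimnames = list(NULL, sprintf("subcat_%02d", 1:49)))
  conf <- cbind(age_adult = rbinom(n, 1, 0.2), sex_male = rbinom(n, 1, 0.5),
                consent_image = rbinom(n, 1, 0.15))
  y <- rbinom(n, 1, plogis(intercept + drop(x %*% beta) + conf_age * conf[, 1]))
  structure(list(x = cbind(x, conf), y = y,
                 penalized = c(rep(TRUE, 49), rep(FALSE, 3)),
                 site_levels = "lab1"),
            class = "phenodx_design")
}

test_that("design matrix encodes penalized and confounder blocks deterministically", {
  patients <- data.frame(
    age_class = c("adult", "child", "child", "child"),
    sex = c("m", "f", "f", "m"),
    site = c("a", "b", "a", "b"),
    pedia = c(TRUE, FALSE, FALSE, TRUE),
    solved = c(1, 0, 1, 0)
  )
  subcat <- matrix(c(1, 0, 0, 0, 0, 1, 0, 0), 4, 2,
                   dimnames = list(NULL, c("s1", "s2")))
  d <- build_design(patients, subcat)
  expect_equal(colnames(d$x), c("s1", "s2", "age_adult", "sex_male", "site_b",
                                "consent_image"))
  expect_equal(sum(d$penalized), 2L)
  expect_equal(nrow(d$x), 4L)          # all-zero-indicator cases retained
  expect_equal(d$x[, "site_b"], c(0, 1, 0, 1))

  co <- simulate_cohort(sim_params(n = 100, seed = 6))
  dd <- build_design(co$patients, co$subcat)
  n_sites <- length(unique(co$patients$site))
  expect_equal(ncol(dd$x), 49 + 2 + (n_sites - 1) + 1)
})

test_that("at lambda_max no subcategory is active and confounders match the unpenalized fit", {
  d <- synth_design(500, seed = 61, beta = c(rep(1, 4), rep(0, 45)))
  m <- fit_yield_model(d, cv = FALSE)
  cf_max <- yield_coef(m, m$lambda[1])
  expect_true(all(cf_max[sprintf("subcat_%02d", 1:49)] == 0))
  conf_only <- glm(d$y ~ d$x[, 50:52], family = binomial)
  expect_equal(unname(cf_max[c("(Intercept)", "age_adult", "sex_male", "consent_image")]),
               unname(coef(conf_only)), tolerance = 1e-5)
})

test_that("the lambda = 0 fit agrees with an IRLS oracle on a well-conditioned set", {
  d <- synth_design(200, seed = 42, beta = c(1, -1, 0.5, rep(0, 46)), prev = 0.4)
  # shrink to 8 penalized columns so n = 200 is comfortably well-conditioned
  keep <- c(1:8, 50:52)
  d2 <- structure(list(x = d$x[, keep], y = d$y,
                       penalized = d$penalized[keep], site_levels = "lab1"),
                  class = "phenodx_design")
  grid <- c(exp(seq(log(0.25), log(1e-4), length.out = 60)), 0)
  m <- fit_yield_model(d2, lambda = grid, cv = FALSE)
  irls <- glm(d2$y ~ d2$x, family = binomial)  # independent IRLS solver
  expect_true(irls$converged)
  expect_equal(unname(yield_coef(m, 0)), unname(coef(irls)), tolerance = 1e-4)
})

test_that("stationarity conditions hold along the whole path and folds are stratified", {
  d <- synth_design(400, seed = 77, beta = c(rep(0.8, 5), rep(0, 44)))
  m <- fit_yield_model(d, seed = 2)
  k <- kkt_check(m, d)
  expect_lt(k$max_zero_violation, 1e-6)
  expect_lt(k$max_active_violation, 1e-6)

  foldid <- phenodx:::stratified_folds(d$y, 10, seed = 3)
  per_fold_pos <- tapply(d$y, foldid, sum)
  expect_lte(diff(range(per_fold_pos)), 1)

  # CV optimality over the grid: deviance at lambda* <= deviance at lambda_max
  cvm <- m$cv$cvm
  expect_lte(cvm[which.min(abs(m$cv$lambda - m$lambda_star))], cvm[1] + 1e-12)
})

test_that("leave-one-out cross-validation on a tiny cohort returns finite deviances", {
  d <- synth_design(30, seed = 88, beta = c(2, rep(0, 48)), prev = 0.4)
  m <- fit_yield_model(d, nfolds = 30, seed = 1)
  expect_true(all(is.finite(m$cv$cvm)))
  expect_true(is.finite(m$lambda_star))
})

test_that("a pure-noise outcome keeps the parsimonious model essentially empty", {
  hits <- vapply(1:20, function(s) {
    d <- synth_design(400, seed = 1000 + s, beta = numeric(49), conf_age = 0)
    m <- fit_yield_model(d, seed = s, rule = "1se")
    sum(yield_coef(m)[1 + 1:49] != 0) <= 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("planted 8-of-49 support is recovered with signs intact", {
  beta <- numeric(49)
  beta[1:8] <- c(rep(1, 6), -1, -1)
  f1 <- sign_ok <- numeric(10)
  for (s in 1:10) {
    d <- synth_design(2000, seed = 2000 + s, beta = beta)
    m <- fit_yield_model(d, seed = s, rule = "1se")
    cf <- yield_coef(m)[1 + 1:49]
    sel <- which(cf != 0)
    tp <- length(intersect(sel, 1:8))
    prec <- tp / max(1, length(sel))
    rec <- tp / 8
    f1[s] <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    sel_true <- intersect(sel, 1:8)
    sign_ok[s] <- mean(sign(cf[sel_true]) == sign(beta[sel_true]))
  }
  expect_gte(mean(f1), 0.8)
  expect_gte(mean(sign_ok), 0.95)
})

test_that("prediction imputes training means and is monotone in positive coefficients", {
  d <- synth_design(800, seed = 90, beta = c(rep(1.2, 4), rep(0, 45)))
  m <- fit_yield_model(d, seed = 1)
  cf <- yield_coef(m)

  # all-zero indicators with every confounder unsupplied: sigmoid(intercept + means . beta_conf)
  expect_warning(p0 <- predict_yield(m), "baseline")
  conf_names <- names(m$confounder_means)
  expect_equal(p0, plogis(cf[["(Intercept)"]] +
                            sum(cf[conf_names] * m$confounder_means)))

  pos <- names(which(cf[sprintf("subcat_%02d", 1:49)] > 0))[1]
  base <- suppressWarnings(predict_yield(m, subcat = c(x = 0)))
  boosted <- predict_yield(m, subcat = stats::setNames(1, pos))
  expect_gt(boosted, base)

  # unseen site level falls back to the training means
  p_site <- predict_yield(m, subcat = stats::setNames(1, pos), site = "never_seen")
  expect_equal(p_site, boosted)
})

test_that("predicted probability correlates positively with phenotype breadth", {
  params <- sim_params(n = 800, seed = 17)
  co <- simulate_cohort(params)
  d <- build_design(co$patients, co$subcat)
  m <- fit_yield_model(d, seed = 1)
  p <- predict(m, d$x)
  n_terms <- vapply(co$patients$terms, length, integer(1))
  expect_gt(cor(n_terms, p, method = "spearman"), 0)
})

test_that("AUC matches closed forms, the null band and an independent implementation", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), B = 0)$auc, 1)

  set.seed(5)
  sc <- rnorm(10000)
  lb <- rbinom(10000, 1, 0.4)
  a <- roc_auc(sc, lb, B = 0)$auc
  expect_gt(a, 0.48)
  expect_lt(a, 0.52)

  # binary marker: AUC = (sensitivity + specificity) / 2
  set.seed(6)
  y <- rbinom(2000, 1, 0.3)
  marker <- rbinom(2000, 1, ifelse(y == 1, 0.7, 0.2))
  sens <- mean(marker[y == 1])
  spec <- mean(1 - marker[y == 0])
  expect_equal(roc_auc(marker, y, B = 0)$auc, (sens + spec) / 2)

  skip_if_not_installed("pROC")
  sc2 <- rnorm(300) + y[1:300]
  a2 <- roc_auc(sc2, y[1:300], B = 0)$auc
  expect_equal(a2, as.numeric(pROC::auc(pROC::roc(y[1:300], sc2, quiet = TRUE))),
               tolerance = 1e-12)

  expect_error(roc_auc(1:5, rep(1, 5)), "both")

  ci <- roc_auc(sc2, y[1:300], B = 200, seed = 1)$ci
  expect_length(ci, 2)
  expect_lte(ci[1], a2)
  expect_gte(ci[2], a2)
})

test_that("single-term AUCs behave like no-information markers unless associated", {
  set.seed(7)
  n <- 5000
  y <- rbinom(n, 1, 0.32)
  tm <- cbind(
    independent = rbinom(n, 1, 0.2),
    always = rep(1, n),
    informative = rbinom(n, 1, ifelse(y == 1, 0.5, 0.1))
  )
  a <- per_term_auc(tm, y)
  expect_lt(abs(a[["independent"]] - 0.5), 0.02)
  expect_equal(a[["always"]], 0.5)
  expect_gt(a[["informative"]], 0.5)

  # closed form agrees with the rank-based AUC on a binary marker
  expect_equal(a[["informative"]], roc_auc(tm[, "informative"], y, B = 0)$auc)
})

test_that("coefficient-path export respects prevalence, starts at zero and orders by strength", {
  beta <- numeric(49)
  beta[1] <- 2    # strong
  beta[2] <- 0.5  # weak
  set.seed(55)
  x <- matrix(rbinom(1500 * 49, 1, 0.2), 1500, 49,
              dimnames = list(NULL, sprintf("subcat_%02d", 1:49)))
  x[, 3] <- rbinom(1500, 1, 0.01)  # rare feature, below the 5% threshold
  conf <- cbind(age_adult = rbinom(1500, 1, 0.2), sex_male = rbinom(1500, 1, 0.5),
                consent_image = rbinom(1500, 1, 0.15))
  y <- rbinom(1500, 1, plogis(-1 + drop(x %*% beta) + 2 * x[, 3]))
  d <- structure(list(x = cbind(x, conf), y = y,
                      penalized = c(rep(TRUE, 49), rep(FALSE, 3)),
                      site_levels = "lab1"), class = "phenodx_design")
  m <- fit_yield_model(d, seed = 1)
  paths <- export_paths(m, min_prevalence = 0.05)
  expect_false("subcat_03" %in% paths$feature)  # prevalence 1% excluded
  at_lmax <- paths[paths$lambda == max(m$lambda), ]
  expect_true(all(at_lmax$coefficient == 0))

  entry <- function(f) {
    p <- paths[paths$feature == f, ]
    max(p$lambda[p$coefficient != 0])
  }
  expect_gt(entry("subcat_01"), entry("subcat_02"))
})
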