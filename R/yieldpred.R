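#' Build the design matrix for diagnostic-yield modelling
#'
#' Encodes the penalized block (phenotype subcategory indicators) and the
#' unpenalized confounder block (age class, sex, sequencing site one-hots
#' with the first level as reference, and the image-analysis-consent flag)
#' into a single numeric matrix with a deterministic column order:
#' subcategories first (in map order), then `age_adult`, `sex_male`,
#' `site_<level>` for all non-reference levels, then `consent_image`.
#'
#' @param patients Data frame with columns `age_class` (`"adult"`/`"child"`),
#'   `sex` (`"m"`/`"f"`), `site` (factor or character), `pedia` (logical
#'   image-analysis-consent flag) and `solved` (0/1 outcome).
#' @param subcat 0/1 matrix, one row per patient, one column per phenotype
#'   subcategory (as produced by [assign_groups_matrix()]).
#' @return An object of class `phenodx_design`: list with `x` (numeric
#'   matrix), `y` (0/1 vector), `penalized` (logical per column),
#'   `site_levels` (all site levels, first = reference).
#' @export
build_design <- function(patients, subcat) {
  stopifnot(nrow(patients) == nrow(subcat))
  if (is.null(colnames(subcat))) colnames(subcat) <- paste0("subcat", seq_len(ncol(subcat)))
  site_levels <- if (is.factor(patients$site)) levels(patients$site) else sort(unique(as.character(patients$site)))
  site <- factor(as.character(patients$site), levels = site_levels)
  conf <- cbind(
    age_adult = as.numeric(patients$age_class == "adult"),
    sex_male = as.numeric(patients$sex == "m")
  )
  if (length(site_levels) > 1L) {
    oh <- sapply(site_levels[-1], function(l) as.numeric(site == l))
    colnames(oh) <- paste0("site_", site_levels[-1])
    conf <- cbind(conf, oh)
  }
  conf <- cbind(conf, consent_image = as.numeric(patients$pedia))
  x <- cbind(as.matrix(subcat), conf)
  if (anyNA(x)) stop("design matrix contains missing values")
  structure(list(
    x = x,
    y = as.numeric(patients$solved),
    penalized = c(rep(TRUE, ncol(subcat)), rep(FALSE, ncol(conf))),
    site_levels = site_levels
  ), class = "phenodx_design")
}

#' Fit the penalized logistic diagnostic-yield model
#'
#' L1-penalized logistic regression of solved status on the phenotype
#' subcategory indicators, with the confounder block left unpenalized
#' (penalty factor 0), fitted along a descending lambda grid with warm
#' starts (via glmnet). Indicator columns are not standardized, so the
#' coefficient paths retain their per-subcategory interpretation. The
#' penalty parameter is tuned by stratified k-fold cross-validation on the
#' out-of-fold binomial deviance; `rule = "min"` (default) picks the
#' deviance-minimizing lambda, `"1se"` the largest lambda within one
#' standard error of it.
#'
#' @param design A `phenodx_design` from [build_design()].
#' @param nlambda Grid length (default 100).
#' @param lambda.min.ratio Smallest lambda as a fraction of lambda_max
#'   (default 1e-3).
#' @param lambda Optional explicit descending lambda grid (overrides the two
#'   arguments above).
#' @param cv Run cross-validation to select `lambda_star` (default TRUE).
#' @param nfolds Number of CV folds (default 10); `nfolds = n` gives
#'   leave-one-out.
#' @param seed Seed for the stratified fold assignment (default 1).
#' @param rule `"min"` or `"1se"`.
#' @param thresh Convergence threshold passed to glmnet (default 1e-10;
#'   tight so that the stationarity conditions hold along the path).
#' @return An object of class `phenodx_yield_model`: list with `a0`
#'   (intercepts per lambda), `beta` (p x nlambda coefficient path),
#'   `lambda`, `penalty` (0/1 penalty factors), `pf_effective` (per-column
#'   effective penalty multiplier), `lambda_star`, `cv` (lambda, mean and sd
#'   of out-of-fold deviance, nonzero counts), `confounder_means`,
#'   `penalized` mask, `site_levels`, `prevalence` (training mean of each
#'   penalized column), `seed`, `rule`.
#' @export
fit_yield_model <- function(design, nlambda = 100, lambda.min.ratio = 1e-3,
                            lambda = NULL, cv = TRUE, nfolds = 10, seed = 1L,
                            rule = c("min", "1se"), thresh = 1e-10) {
  rule <- match.arg(rule)
  x <- design$x
  y <- design$y
  if (length(unique(y)) < 2L) stop("outcome must contain both classes")
  if (length(y) < 20L) stop("need at least 20 cases to fit the model")
  pf <- as.numeric(design$penalized)
  args <- list(x = x, y = y, family = "binomial", alpha = 1,
               penalty.factor = pf, standardize = FALSE, thresh = thresh,
               maxit = 1e6)
  if (is.null(lambda)) {
    args$nlambda <- nlambda
    args$lambda.min.ratio <- lambda.min.ratio
  } else {
    args$lambda <- lambda
  }
  fit <- do.call(glmnet::glmnet, args)

  model <- structure(list(
    a0 = fit$a0,
    beta = as.matrix(fit$beta),
    lambda = fit$lambda,
    penalty = pf,
    pf_effective = pf * length(pf) / sum(pf),
    lambda_star = NULL,
    cv = NULL,
    confounder_means = colMeans(x[, !design$penalized, drop = FALSE]),
    penalized = design$penalized,
    site_levels = design$site_levels,
    prevalence = colMeans(x[, design$penalized, drop = FALSE]),
    nobs = length(y),
    seed = as.integer(seed),
    rule = rule
  ), class = "phenodx_yield_model")

  if (cv) {
    foldid <- stratified_folds(y, nfolds, seed)
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                               penalty.factor = pf, standardize = FALSE,
                               thresh = thresh, maxit = 1e6,
                               lambda = fit$lambda, foldid = foldid,
                               type.measure = "deviance",
                               grouped = nfolds < length(y))
    model$cv <- data.frame(lambda = cvfit$lambda, cvm = cvfit$cvm,
                           cvsd = cvfit$cvsd, nzero = as.integer(cvfit$nzero))
    model$lambda_star <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  }
  model
}

#' @export
print.phenodx_yield_model <- function(x, ...) {
  cat("<phenodx_yield_model> ", sum(x$penalized), " penalized + ",
      sum(!x$penalized), " confounder columns, ", length(x$lambda),
      " lambda values", sep = "")
  if (!is.null(x$lambda_star)) {
    cat("; lambda* = ", signif(x$lambda_star, 4), " (", x$rule, " rule, ",
        coef_nonzero(x), " active subcategories)", sep = "")
  }
  cat("\n")
  invisible(x)
}

# stratified fold assignment: folds balanced within each outcome class
stratified_folds <- function(y, nfolds, seed) {
  if (nfolds > length(y)) stop("more folds than observations")
  foldid <- integer(length(y))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

# number of nonzero penalized coefficients at lambda_star
coef_nonzero <- function(model, lambda = model$lambda_star) {
  j <- which.min(abs(model$lambda - lambda))
  sum(model$beta[model$penalized, j] != 0)
}

#' Coefficients at a given lambda
#'
#' @param model A `phenodx_yield_model`.
#' @param lambda Lambda value (default the CV-selected one); the nearest
#'   grid point is used.
#' @return Named numeric vector, first element `(Intercept)`.
#' @export
yield_coef <- function(model, lambda = model$lambda_star) {
  if (is.null(lambda)) stop("no lambda given and no CV-selected lambda in the model")
  j <- which.min(abs(model$lambda - lambda))
  c("(Intercept)" = unname(model$a0[j]), model$beta[, j])
}

#' Predict the probability of a diagnostic exome result
#'
#' Inverse-logit of the linear predictor at the selected lambda. Subcategory
#' indicators can be given directly or derived from a raw term list via a
#' group map. Confounders that are not supplied are imputed with the
#' training-cohort means, so predictions remain available when only the
#' phenotype (or phenotype + age + sex) is known; an unseen site level is
#' likewise mapped to the training means.
#'
#' @param model A fitted `phenodx_yield_model` with a selected lambda.
#' @param subcat Named 0/1 vector of subcategory indicators (names matching
#'   the penalized design columns; missing names count as 0), or `NULL`
#'   together with `terms`.
#' @param terms,map,index Alternative input: raw term ids plus a
#'   `phenodx_groupmap` and `phenodx_ontology` (used when `subcat` is NULL).
#' @param age_class,sex,site,pedia Optional confounders
#'   (`"adult"`/`"child"`, `"m"`/`"f"`, site label, logical).
#' @param lambda Lambda at which to predict (default `lambda_star`).
#' @return Probability in (0, 1).
#' @export
predict_yield <- function(model, subcat = NULL, terms = NULL, map = NULL,
                          index = NULL, age_class = NULL, sex = NULL,
                          site = NULL, pedia = NULL,
                          lambda = model$lambda_star) {
  cf <- yield_coef(model, lambda)
  pen_names <- rownames(model$beta)[model$penalized]
  xpen <- stats::setNames(numeric(length(pen_names)), pen_names)
  if (is.null(subcat) && !is.null(terms)) {
    subcat <- assign_groups(terms, map, index)$subcategory
  }
  if (!is.null(subcat)) {
    known <- intersect(names(subcat), pen_names)
    xpen[known] <- as.numeric(subcat[known])
  } else if (is.null(age_class) && is.null(sex)) {
    warning("no phenotype and no covariates supplied; returning the baseline probability")
  }
  xconf <- model$confounder_means
  if (!is.null(age_class)) xconf["age_adult"] <- as.numeric(age_class == "adult")
  if (!is.null(sex)) xconf["sex_male"] <- as.numeric(sex == "m")
  if (!is.null(site)) {
    sn <- paste0("site_", model$site_levels[-1])
    if (site %in% model$site_levels) {
      xconf[sn] <- as.numeric(paste0("site_", site) == sn)
    }  # unseen site: keep training means
  }
  if (!is.null(pedia)) xconf["consent_image"] <- as.numeric(pedia)
  eta <- cf[["(Intercept)"]] + sum(cf[pen_names] * xpen) +
    sum(cf[names(xconf)] * xconf)
  1 / (1 + exp(-eta))
}

#' Predict for a design matrix
#'
#' @param object A `phenodx_yield_model`.
#' @param newx Numeric matrix with the same columns as the training design.
#' @param lambda Lambda (default `lambda_star`).
#' @param ... Unused.
#' @return Vector of probabilities.
#' @export
predict.phenodx_yield_model <- function(object, newx, lambda = object$lambda_star, ...) {
  cf <- yield_coef(object, lambda)
  eta <- cf[["(Intercept)"]] + drop(newx[, rownames(object$beta), drop = FALSE] %*%
                                      cf[rownames(object$beta)])
  1 / (1 + exp(-eta))
}

#' Area under the ROC curve with a bootstrap confidence interval
#'
#' AUC computed as the tie-corrected Mann-Whitney statistic (midranks), with
#' a case-level percentile bootstrap CI.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels 0/1 outcome labels.
#' @param B Bootstrap replicates (default 2000); `B = 0` skips the CI.
#' @param seed Bootstrap seed (default 1).
#' @param conf Confidence level (default 0.95).
#' @return List with `auc`, `ci` (length-2 vector or NULL), `n`, `B`.
#' @export
roc_auc <- function(scores, labels, B = 2000, seed = 1L, conf = 0.95) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) stop("both outcome classes must be present")
  auc <- auc_rank(scores, labels)
  ci <- NULL
  if (B > 0) {
    set.seed(seed)
    n <- length(labels)
    reps <- replicate(B, {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[i])) < 2L) NA_real_ else auc_rank(scores[i], labels[i])
    })
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(reps, c(a, 1 - a), na.rm = TRUE))
  }
  list(auc = auc, ci = ci, n = length(labels), B = B)
}

# midrank Mann-Whitney AUC
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Discriminatory AUC of each single term
#'
#' For a binary presence marker the ROC curve is a single corner and the
#' AUC has the closed form `(sensitivity + specificity) / 2`.
#'
#' @param term_matrix 0/1 matrix, patients x terms.
#' @param y 0/1 outcome vector.
#' @return Named numeric vector of per-term AUCs.
#' @export
per_term_auc <- function(term_matrix, y) {
  y <- as.numeric(y)
  sens <- colMeans(term_matrix[y == 1, , drop = FALSE])
  spec <- 1 - colMeans(term_matrix[y == 0, , drop = FALSE])
  (sens + spec) / 2
}

#' Export coefficient paths for display
#'
#' Long-format coefficient paths of penalized features that are active at
#' the selected lambda and whose training prevalence is at least
#' `min_prevalence` (matching the convention of showing only features seen
#' in at least 5% of training cases).
#'
#' @param model A fitted `phenodx_yield_model` with `lambda_star`.
#' @param min_prevalence Prevalence threshold (default 0.05).
#' @return Data frame with `feature`, `lambda`, `log_lambda`, `coefficient`.
#' @export
export_paths <- function(model, min_prevalence = 0.05) {
  if (is.null(model$lambda_star)) stop("model has no selected lambda")
  jstar <- which.min(abs(model$lambda - model$lambda_star))
  pen <- which(model$penalized)
  keep <- pen[model$prevalence >= min_prevalence & model$beta[pen, jstar] != 0]
  if (!length(keep)) {
    return(data.frame(feature = character(0), lambda = numeric(0),
                      log_lambda = numeric(0), coefficient = numeric(0)))
  }
  do.call(rbind, lapply(keep, function(j) {
    data.frame(feature = rownames(model$beta)[j], lambda = model$lambda,
               log_lambda = log(model$lambda),
               coefficient = model$beta[j, ], row.names = NULL)
  }))
}

#' Stationarity (KKT) diagnostics along the lambda path
#'
#' For the L1-penalized logistic objective `-(1/n) loglik + lambda *
#' sum_j w_j |beta_j|`, a zero penalized coefficient must satisfy
#' `|gradient_j| <= lambda * w_j` and an active one must sit at
#' `gradient_j = lambda * w_j * sign(beta_j)` (with `w_j` the effective
#' per-column penalty multiplier). Returns the largest violation over the
#' whole path, for use as a fit-quality diagnostic.
#'
#' @param model A `phenodx_yield_model`.
#' @param design The training `phenodx_design`.
#' @return List with `max_zero_violation` (excess of `|grad|` over
#'   `lambda * w` at inactive coordinates) and `max_active_violation`
#'   (deviation from the subgradient equation at active coordinates).
#' @export
kkt_check <- function(model, design) {
  x <- design$x
  y <- design$y
  n <- length(y)
  zero_v <- 0
  act_v <- 0
  for (j in seq_along(model$lambda)) {
    eta <- model$a0[j] + drop(x %*% model$beta[, j])
    p <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(x, y - p)) / n  # gradient of +(1/n) loglik
    lam_w <- model$lambda[j] * model$pf_effective
    b <- model$beta[, j]
    pen <- model$penalized
    z <- pen & b == 0
    a <- pen & b != 0
    if (any(z)) zero_v <- max(zero_v, abs(grad[z]) - lam_w[z])
    if (any(a)) act_v <- max(act_v, abs(grad[a] - lam_w[a] * sign(b[a])))
  }
  list(max_zero_violation = zero_v, max_active_violation = act_v)
}

#' Serialize a yield model to JSON
#'
#' @param model A `phenodx_yield_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_yield_model <- function(model, path) {
  obj <- list(
    lambda = model$lambda, a0 = unname(model$a0), beta = model$beta,
    penalty = model$penalty, lambda_star = model$lambda_star,
    confounder_means = as.list(model$confounder_means),
    prevalence = as.list(model$prevalence),
    site_levels = model$site_levels, seed = model$seed, rule = model$rule
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
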