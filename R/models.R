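#' Area under the ROC curve
#'
#' Mann-Whitney (rank) formulation: the probability that a randomly chosen
#' positive case outranks a randomly chosen negative case, ties counted one
#' half.  Invariant to any strictly increasing transform of the scores.
#'
#' @param probabilities Numeric scores (higher = more injury-like).
#' @param labels Class labels; the positive class is `"injury"`, `TRUE` or 1.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(probabilities, labels) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2) abort("both classes must be present")
  r <- rank(probabilities)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_label <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) return(as.integer(labels != 0))
  as.integer(as.character(labels) == "injury")
}

#' Classification metrics over probability thresholds
#'
#' Classifies a subject as injured when the predicted probability exceeds the
#' threshold and reports class-wise accuracy and the overall
#' misclassification rate at each threshold.
#'
#' @inheritParams roc_auc
#' @param thresholds Probability cutoffs in `[0, 1]`.
#' @return Tibble with `threshold`, `sensitivity` (injury accuracy),
#'   `specificity` (control accuracy), `misclassification`.
#' @export
threshold_metrics <- function(probabilities, labels,
                              thresholds = seq(0.1, 0.9, by = 0.1)) {
  y <- as_binary_label(labels)
  list_rbind(map(thresholds, function(th) {
    pred <- as.integer(probabilities > th)
    tibble(threshold = th,
           sensitivity = if (sum(y == 1) > 0) mean(pred[y == 1] == 1) else NA_real_,
           specificity = if (sum(y == 0) > 0) mean(pred[y == 0] == 0) else NA_real_,
           misclassification = mean(pred != y))
  }))
}

# Leave-one-out CV over a glmnet path; ties in lambda go to the stronger
# penalty (glmnet paths are decreasing in lambda).  rule = "1se" picks the
# strongest penalty whose mean held-out deviance is within one standard
# error of the minimum (the usual conservative CV rule).
loocv_glmnet <- function(x, y, alpha, penalty.factor = rep(1, ncol(x)),
                         rule = c("min", "1se")) {
  rule <- match.arg(rule)
  full <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                         penalty.factor = penalty.factor, standardize = FALSE)
  lambda <- full$lambda
  n <- nrow(x)
  preval <- matrix(NA_real_, n, length(lambda))
  for (i in seq_len(n)) {
    fit_i <- glmnet::glmnet(x[-i, , drop = FALSE], y[-i], family = "binomial",
                            alpha = alpha, penalty.factor = penalty.factor,
                            lambda = lambda, standardize = FALSE)
    preval[i, ] <- predict(fit_i, x[i, , drop = FALSE], s = lambda,
                           type = "response")[1, ]
  }
  p <- pmin(pmax(preval, 1e-8), 1 - 1e-8)
  dev <- -2 * (y * log(p) + (1 - y) * log(1 - p))
  cvm <- colMeans(dev)
  cvse <- apply(dev, 2, sd) / sqrt(n)
  cutoff <- if (rule == "1se") min(cvm) + cvse[which.min(cvm)] else min(cvm) + 1e-10
  best <- which(cvm <= cutoff)[1]
  list(fit = full, lambda = lambda, cvm = cvm, lambda_index = best,
       lambda_min = lambda[best], preval = preval[, best])
}

#' Adaptive-lasso logistic prediction of injury status
#'
#' Two-stage penalized logistic regression with leave-one-out
#' cross-validation.  Stage one fits a ridge logistic model (LOOCV-selected
#' penalty) on standardized terms to obtain stable initial coefficients; the
#' adaptive-lasso penalty weights `1/|beta_ridge|^gamma` then drive an
#' L1-penalized fit whose penalty is again chosen by LOOCV deviance (ties
#' broken toward the stronger penalty).  Terms shrunk to zero are dropped.
#' With `interaction_screen = TRUE` a second adaptive-lasso pass augments the
#' surviving terms with their pairwise products.  Odds ratios and Wald
#' confidence intervals come from an unpenalized refit of the survivors in
#' native units; if that refit is separated the CIs are suppressed and the
#' fit is flagged rather than failed.  The reported AUROC is computed on the
#' leave-one-out predicted probabilities, not the training fit.
#'
#' @param records Tibble with a `group` column (control/injury) and numeric
#'   feature columns; typically [summarize_entropy()] joined to covariates.
#' @param terms Character vector of predictor columns; defaults to every
#'   numeric column except `subject_id`.
#' @param gamma Adaptive-weight exponent.
#' @param interaction_screen Explore pairwise interactions of the survivors
#'   in a second pass.
#' @param lambda_rule Penalty selection: `"min"` (default) takes the
#'   deviance minimizer (ties toward the stronger penalty); `"1se"` takes
#'   the strongest penalty within one standard error of the minimum, a more
#'   conservative choice.
#' @return An `adaptive_lasso_fit`: selected terms with odds ratios,
#'   LOOCV probabilities, AUROC, threshold metrics.  Use [generics::tidy()]
#'   and [generics::glance()] on the result.
#' @export
fit_adaptive_lasso <- function(records, terms = NULL, gamma = 1,
                               interaction_screen = FALSE,
                               lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  y <- as_binary_label(records$group)
  if (min(table(y)) < 3) abort("need at least 3 subjects per class")
  if (is.null(terms)) {
    terms <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                     c("subject_id"))
  }
  X0 <- as.matrix(records[, terms, drop = FALSE])
  if (length(terms) < 2)
    abort("adaptive lasso needs at least 2 candidate terms")
  run_stage <- function(X) {
    Xs <- scale(X)
    ridge <- loocv_glmnet(Xs, y, alpha = 0)
    b <- as.numeric(coef(ridge$fit, s = ridge$lambda_min))[-1]
    w <- 1 / pmax(abs(b), 1e-8)^gamma
    lasso <- loocv_glmnet(Xs, y, alpha = 1, penalty.factor = w,
                          rule = lambda_rule)
    beta <- as.numeric(coef(lasso$fit, s = lasso$lambda_min))[-1]
    list(selected = colnames(X)[abs(beta) > 1e-10], lasso = lasso)
  }
  s1 <- run_stage(X0)
  selected <- s1$selected
  stage <- s1$lasso
  if (interaction_screen && length(selected) >= 2) {
    pairs <- utils::combn(selected, 2, simplify = FALSE)
    Xi <- do.call(cbind, map(pairs, function(pr) {
      v <- X0[, pr[1]] * X0[, pr[2]]
      matrix(v, ncol = 1, dimnames = list(NULL, paste(pr, collapse = ":")))
    }))
    s2 <- run_stage(cbind(X0[, selected, drop = FALSE], Xi))
    selected <- s2$selected
    stage <- s2$lasso
  }
  prob <- stage$preval
  auroc <- roc_auc(prob, y)
  # unpenalized refit of the survivors in native units
  main <- intersect(selected, terms)
  inter <- setdiff(selected, terms)
  separation <- FALSE
  if (length(selected) > 0) {
    dat <- as.data.frame(X0[, main, drop = FALSE])
    for (nm in inter) {
      pr <- strsplit(nm, ":", fixed = TRUE)[[1]]
      dat[[nm]] <- X0[, pr[1]] * X0[, pr[2]]
    }
    names(dat) <- make.names(names(dat))
    dat$.y <- y
    refit <- withCallingHandlers(
      glm(.y ~ ., data = dat, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      })
    sm <- summary(refit)$coefficients
    est <- sm[-1, 1]
    se <- sm[-1, 2]
    term_tbl <- tibble(term = selected,
                       estimate = unname(est),
                       odds_ratio = exp(unname(est)),
                       ci_low = if (separation) NA_real_ else exp(unname(est - 1.96 * se)),
                       ci_high = if (separation) NA_real_ else exp(unname(est + 1.96 * se)),
                       p = unname(sm[-1, 4]))
  } else {
    term_tbl <- tibble(term = character(), estimate = numeric(),
                       odds_ratio = numeric(), ci_low = numeric(),
                       ci_high = numeric(), p = numeric())
  }
  structure(list(model_kind = "adaptive_lasso",
                 selected = selected,
                 terms = term_tbl,
                 candidate_terms = terms,
                 lambda = stage$lambda_min,
                 separation = separation,
                 auroc = auroc,
                 probabilities = tibble(
                   subject_id = records$subject_id %||% as.character(seq_along(y)),
                   group = records$group, probability = prob),
                 threshold_metrics = threshold_metrics(prob, y)),
            class = "adaptive_lasso_fit")
}

#' Two-node neural classifier with mixed activations
#'
#' A deliberately tiny network for small cohorts: one hidden layer with a
#' hyperbolic-tangent node and a Gaussian radial node (`exp(-u^2)`), logistic
#' output, fit by penalized maximum likelihood (quasi-Newton with random
#' restarts).  The ridge penalty is selected by 5-fold cross-validated
#' deviance, and the reported AUROC and threshold metrics are computed on the
#' cross-validated predicted probabilities.
#'
#' @inheritParams fit_adaptive_lasso
#' @param penalty_grid Candidate L2 penalties.
#' @param folds Number of CV folds.
#' @param restarts Random restarts per fit.
#' @param seed Integer seed (fold assignment and initial weights).
#' @return A `neural_fit` with `weights`, `auroc`, `cv_probabilities`,
#'   `threshold_metrics`.
#' @export
fit_neural <- function(records, terms, penalty_grid = 10^seq(-3, 0, by = 1),
                       folds = 5, restarts = 5, seed = 1) {
  y <- as_binary_label(records$group)
  if (min(table(y)) < 2) abort("need at least 2 subjects per class")
  X <- scale(as.matrix(records[, terms, drop = FALSE]))
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)
  npar <- 2 * (p + 1) + 3
  unpack <- function(th) {
    W1 <- matrix(th[seq_len(2 * p)], nrow = 2)
    b1 <- th[2 * p + (1:2)]
    w2 <- th[2 * p + 2 + (1:2)]
    b2 <- th[npar]
    list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
  }
  forward <- function(th, X) {
    pr <- unpack(th)
    U <- X %*% t(pr$W1) + matrix(pr$b1, nrow(X), 2, byrow = TRUE)
    H <- cbind(tanh(U[, 1]), exp(-U[, 2]^2))
    plogis(H %*% pr$w2 + pr$b2)
  }
  nll <- function(th, X, y, lambda) {
    pv <- pmin(pmax(forward(th, X), 1e-10), 1 - 1e-10)
    -sum(y * log(pv) + (1 - y) * log(1 - pv)) +
      lambda * sum(th[-npar]^2)
  }
  fit_once <- function(X, y, lambda) {
    best <- NULL
    for (r in seq_len(restarts)) {
      th0 <- rnorm(npar, sd = 0.5)
      res <- tryCatch(optim(th0, nll, X = X, y = y, lambda = lambda,
                            method = "BFGS",
                            control = list(maxit = 500)),
                      error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
    }
    if (is.null(best)) abort("neural fit failed to converge in all restarts")
    best$par
  }
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  cv_dev <- numeric(length(penalty_grid))
  cv_prob <- matrix(NA_real_, n, length(penalty_grid))
  for (li in seq_along(penalty_grid)) {
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2) next
      th <- fit_once(X[tr, , drop = FALSE], y[tr], penalty_grid[li])
      cv_prob[!tr, li] <- forward(th, X[!tr, , drop = FALSE])
    }
    pv <- pmin(pmax(cv_prob[, li], 1e-10), 1 - 1e-10)
    cv_dev[li] <- mean(-2 * (y * log(pv) + (1 - y) * log(1 - pv)), na.rm = TRUE)
  }
  li <- which(cv_dev <= min(cv_dev) + 1e-10)
  li <- li[length(li)]  # ties toward the stronger penalty
  lambda <- penalty_grid[li]
  th <- fit_once(X, y, lambda)
  prob_cv <- cv_prob[, li]
  train_prob <- as.numeric(forward(th, X))
  structure(list(model_kind = "neural",
                 terms = terms,
                 weights = unpack(th),
                 penalty = lambda,
                 auroc = roc_auc(prob_cv, y),
                 train_auroc = roc_auc(train_prob, y),
                 cv_probabilities = tibble(
                   subject_id = records$subject_id %||% as.character(seq_len(n)),
                   group = records$group, probability = prob_cv),
                 train_probabilities = train_prob,
                 threshold_metrics = threshold_metrics(prob_cv, y),
                 seed = seed),
            class = "neural_fit")
}

#' @export
print.adaptive_lasso_fit <- function(x, ...) {
  cat(sprintf("<adaptive_lasso_fit> %d/%d terms selected, LOOCV AUROC = %.3f%s\n",
              length(x$selected), length(x$candidate_terms), x$auroc,
              if (x$separation) " (separated refit: CIs suppressed)" else ""))
  if (nrow(x$terms) > 0) print(x$terms)
  invisible(x)
}

#' @export
print.neural_fit <- function(x, ...) {
  cat(sprintf("<neural_fit> tanh+Gaussian 2-node network on {%s}, CV AUROC = %.3f\n",
              paste(x$terms, collapse = ", "), x$auroc))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.adaptive_lasso_fit <- function(x, ...) x$terms

#' @export
glance.adaptive_lasso_fit <- function(x, ...) {
  tibble(model_kind = "adaptive_lasso",
         n = nrow(x$probabilities),
         n_candidates = length(x$candidate_terms),
         n_selected = length(x$selected),
         lambda = x$lambda,
         separation = x$separation,
         auroc = x$auroc)
}

#' @export
tidy.neural_fit <- function(x, ...) {
  w <- x$weights
  bind_rows(
    tibble(term = rep(colnames(w$W1) %||% x$terms, each = 2),
           node = rep(c("tanh", "gaussian"), length(x$terms)),
           weight = as.numeric(w$W1)),
    tibble(term = "(bias)", node = c("tanh", "gaussian"), weight = w$b1),
    tibble(term = "(output)", node = c("tanh", "gaussian"), weight = w$w2),
    tibble(term = "(output bias)", node = NA_character_, weight = w$b2))
}

#' @export
glance.neural_fit <- function(x, ...) {
  tibble(model_kind = "neural", n = nrow(x$cv_probabilities),
         n_terms = length(x$terms), penalty = x$penalty,
         auroc = x$auroc, train_auroc = x$train_auroc)
}
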