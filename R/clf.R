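#' Elastic-net specification
#'
#' Penalized logistic regression with penalty
#' `lambda * ((1 - alpha) * ||beta||^2 / 2 + alpha * ||beta||_1)` added to
#' the negative mean log-likelihood (intercept unpenalized). The default
#' mixing parameter is 0.66. The lambda grid, when not supplied, is the
#' conventional construction: `nlambda` log-spaced values from the smallest
#' lambda that zeroes every coefficient down to
#' `lambda_min_ratio * lambda_max`, computed from the full data.
#'
#' @param alpha Elastic-net mixing parameter in \[0, 1\].
#' @param nlambda Grid size.
#' @param lambda_min_ratio Ratio of smallest to largest grid value.
#' @param standardize Standardize features internally (coefficients are
#'   returned on the original scale).
#' @param lambda Optional explicit descending grid.
#' @return Object of class `enet_spec`.
#' @export
enet_spec <- function(alpha = 0.66, nlambda = 100,
                      lambda_min_ratio = 1e-4, standardize = TRUE,
                      lambda = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (!is.null(lambda) && any(diff(lambda) >= 0)) {
    stop_labelled("enet", "lambda grid must be strictly descending")
  }
  structure(list(alpha = alpha, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio,
                 standardize = standardize, lambda = lambda),
            class = "enet_spec")
}

# Coerce labels to 0/1 with the positive class second; factors keep their
# level order, otherwise sorted unique values define the order.
.binary_y <- function(y) {
  f <- as.factor(y)
  if (nlevels(f) != 2) stop_labelled("labels", "y must have two classes")
  list(y01 = as.integer(f) - 1L, levels = levels(f))
}

.lambda_grid <- function(x, y01, spec) {
  if (!is.null(spec$lambda)) return(spec$lambda)
  fit <- suppressWarnings(
    glmnet::glmnet(.pad_single(x), y01, family = "binomial",
                   alpha = spec$alpha, nlambda = spec$nlambda,
                   lambda.min.ratio = spec$lambda_min_ratio,
                   standardize = spec$standardize))
  # extend to the full nominal grid even if the path stopped early
  lam <- fit$lambda
  if (length(lam) < spec$nlambda) {
    lam <- exp(seq(log(lam[1]), log(lam[1] * spec$lambda_min_ratio),
                   length.out = spec$nlambda))
  }
  lam
}

#' Fit elastic-net logistic regression at one penalty value
#'
#' @param x n x p numeric matrix.
#' @param y Binary labels (two-level factor or 0/1); the positive class is
#'   the second factor level.
#' @param spec An [enet_spec()].
#' @param lambda Penalty value.
#' @return List with `intercept`, `beta` (named, original scale), `lambda`,
#'   `alpha`.
#' @export
fit_enet_logistic <- function(x, y, spec = enet_spec(), lambda) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop_labelled("nonfinite", "X must be finite")
  yb <- .binary_y(y)
  if (length(unique(yb$y01)) < 2) {
    stop_labelled("labels", "both classes must be present")
  }
  sds <- apply(x, 2, stats::sd)
  dropped <- character(0)
  if (spec$standardize && any(sds == 0)) {
    dropped <- colnames(x)[sds == 0]
    warning("dropping zero-variance features: ",
            paste(dropped, collapse = ", "))
    x_fit <- x[, sds > 0, drop = FALSE]
  } else {
    x_fit <- x
  }
  # fit a descending path that terminates exactly at the requested lambda,
  # so no interpolation is involved in extracting the coefficients
  lam <- .lambda_grid(x_fit, yb$y01, spec)
  path <- c(lam[lam > lambda], lambda)
  if (length(path) == 1) path <- c(10 * lambda + 1, lambda)
  fit <- suppressWarnings(
    glmnet::glmnet(.pad_single(x_fit), yb$y01, family = "binomial",
                   alpha = spec$alpha, standardize = spec$standardize,
                   thresh = 1e-12, lambda = path))
  cf <- as.matrix(glmnet::coef.glmnet(fit, s = lambda))
  beta <- stats::setNames(numeric(ncol(x)),
                          colnames(x) %||% paste0("V", seq_len(ncol(x))))
  keep <- intersect(rownames(cf)[-1], names(beta))
  beta[keep] <- cf[keep, 1]
  list(intercept = cf[1, 1], beta = beta, lambda = lambda,
       alpha = spec$alpha, dropped = dropped)
}

# Probabilities are capped at 1e-5 (the convention of the reference
# cross-validation implementation) so a single confidently misclassified
# leave-one-out fold cannot dominate the deviance SE.
.binomial_deviance <- function(y01, p) {
  p <- pmin(pmax(p, 1e-5), 1 - 1e-5)
  -2 * (y01 * log(p) + (1 - y01) * log(1 - p))
}

# glmnet requires >= 2 columns; single-feature fits (the screened-to-one
# situation) are padded with an all-zero column whose coefficient is
# structurally zero.
.pad_single <- function(x) {
  if (ncol(x) == 1) {
    cbind(x, `.pad` = 0)
  } else {
    x
  }
}
.unpad <- function(beta) beta[names(beta) != ".pad"]

#' Leave-one-out cross-validated elastic-net logistic regression
#'
#' Each of the n folds omits one sample, fits the penalized path on the
#' remaining n - 1, and scores the held-out sample across the shared lambda
#' grid with the binomial deviance. `lambda_1se` is the largest lambda whose
#' mean cross-validated deviance is within one standard error (across
#' folds) of the minimum; out-of-fold linear-predictor scores at
#' `lambda_1se` support honest ROC estimation; the selected support comes
#' from a full-data refit at `lambda_1se`. A fold whose training labels are
#' single-class is scored by an intercept-only model (log-odds of the
#' training prevalence).
#'
#' @param x n x p numeric matrix with column names.
#' @param y Binary labels; positive class = second factor level.
#' @param spec An [enet_spec()].
#' @return Object of class `cv_enet`: lambda grid, `cvm`, `cvsd`,
#'   `lambda_min`, `lambda_1se`, `oof_scores` (link scale), `support`,
#'   `coefficients`, `y01`, `levels`.
#' @export
loocv_enet <- function(x, y, spec = enet_spec()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  yb <- .binary_y(y)
  n <- nrow(x)
  if (n < 3) stop_labelled("loocv", "need n >= 3")
  if (any(table(yb$y01) < 2)) {
    stop_labelled("loocv", "both classes need >= 2 members")
  }
  lam <- .lambda_grid(x, yb$y01, spec)
  nl <- length(lam)
  dev <- matrix(NA_real_, n, nl)
  links <- matrix(NA_real_, n, nl)
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]; yt <- yb$y01[-i]
    if (length(unique(yt)) < 2) {
      p_hat <- min(max(mean(yt), 1e-6), 1 - 1e-6)
      links[i, ] <- stats::qlogis(p_hat)
    } else {
      fit <- suppressWarnings(
        glmnet::glmnet(.pad_single(xt), yt, family = "binomial",
                       alpha = spec$alpha, lambda = lam,
                       standardize = spec$standardize))
      links[i, ] <- as.numeric(
        glmnet::predict.glmnet(fit, .pad_single(x[i, , drop = FALSE]),
                               s = lam, type = "link"))
    }
    dev[i, ] <- .binomial_deviance(yb$y01[i], stats::plogis(links[i, ]))
  }
  cvm <- colMeans(dev)
  cvsd <- apply(dev, 2, stats::sd) / sqrt(n)
  imin <- which.min(cvm)
  lambda_min <- lam[imin]
  ok <- cvm <= cvm[imin] + cvsd[imin]
  lambda_1se <- max(lam[ok])
  i1se <- which(lam == lambda_1se)[1]
  full <- fit_enet_logistic(x, y, spec, lambda_1se)
  structure(list(lambda = lam, cvm = cvm, cvsd = cvsd,
                 lambda_min = lambda_min, lambda_1se = lambda_1se,
                 oof_scores = links[, i1se],
                 support = names(full$beta)[full$beta != 0],
                 coefficients = full,
                 y01 = yb$y01, levels = yb$levels, spec = spec),
            class = "cv_enet")
}

#' @export
print.cv_enet <- function(x, ...) {
  cat(sprintf("LOOCV elastic-net logistic (alpha = %.2f, %d folds)\n",
              x$spec$alpha, length(x$oof_scores)))
  cat(sprintf("lambda_min = %.4g, lambda_1se = %.4g\n",
              x$lambda_min, x$lambda_1se))
  cat("selected support:",
      if (length(x$support)) paste(x$support, collapse = ", ")
      else "(intercept only)", "\n")
  invisible(x)
}

#' Plot the cross-validation deviance curve
#' @param x A `cv_enet`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cv_enet <- function(x, ...) {
  graphics::plot(log(x$lambda), x$cvm, type = "l",
                 xlab = "log(lambda)", ylab = "mean binomial deviance", ...)
  graphics::arrows(log(x$lambda), x$cvm - x$cvsd, log(x$lambda),
                   x$cvm + x$cvsd, length = 0.02, angle = 90, code = 3,
                   col = "grey70")
  graphics::abline(v = log(c(x$lambda_min, x$lambda_1se)),
                   lty = c(3, 2))
  invisible(x)
}

#' ROC analysis of decision scores
#'
#' AUC in the Mann-Whitney form (probability a random positive outscores a
#' random negative, ties counted 1/2), a 95% DeLong confidence interval, the
#' Youden operating point (ties resolved to the lowest threshold; a sample
#' is called positive when its score is >= the threshold), the confusion
#' counts at that point, and accuracy. Constant scores give AUC 0.5 with a
#' degenerate-CI flag.
#'
#' @param scores Numeric decision scores (higher = more positive).
#' @param labels Binary labels; positive class = second factor level.
#' @return Object of class `roc_result`.
#' @export
roc_analysis <- function(scores, labels) {
  yb <- .binary_y(labels)
  y <- yb$y01
  if (length(unique(y)) < 2) {
    stop_labelled("roc", "both classes must be present")
  }
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  degenerate <- stats::sd(scores) == 0
  if (degenerate) {
    ci <- c(0.5, 0.5)
  } else {
    roc_obj <- pROC::roc(response = y, predictor = scores,
                         levels = c(0, 1), direction = "<", quiet = TRUE)
    ci_obj <- pROC::ci.auc(roc_obj, method = "delong")
    ci <- c(ci_obj[1], ci_obj[3])
  }
  thr <- sort(unique(scores))
  best <- -Inf; youden_threshold <- thr[1]
  sens_best <- spec_best <- NA_real_
  for (t in thr) {
    pred <- as.integer(scores >= t)
    sens <- sum(pred == 1 & y == 1) / n_pos
    spc <- sum(pred == 0 & y == 0) / n_neg
    j <- sens + spc - 1
    if (j > best + 1e-12) {
      best <- j; youden_threshold <- t
      sens_best <- sens; spec_best <- spc
    }
  }
  pred <- as.integer(scores >= youden_threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  structure(list(auc = auc, ci_95 = ci,
                 youden_threshold = youden_threshold,
                 youden_index = best,
                 sensitivity = sens_best, specificity = spec_best,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 accuracy = (tp + tn) / length(y),
                 degenerate = degenerate,
                 levels = yb$levels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f)%s\n", x$auc, x$ci_95[1],
              x$ci_95[2], if (x$degenerate) " [degenerate scores]" else ""))
  cat(sprintf("Youden threshold %.4g: sens %.2f, spec %.2f, accuracy %.2f\n",
              x$youden_threshold, x$sensitivity, x$specificity,
              x$accuracy))
  cat(sprintf("confusion: TP %d, FP %d, TN %d, FN %d\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  invisible(x)
}

#' Empirical ROC points
#'
#' Sensitivity/specificity pairs over all score thresholds, for plotting and
#' for checking the Mann-Whitney AUC against the trapezoidal area.
#'
#' @param scores,labels As in [roc_analysis()].
#' @return data.frame with `threshold`, `fpr`, `tpr`, ordered for plotting.
#' @export
roc_points <- function(scores, labels) {
  yb <- .binary_y(labels)
  y <- yb$y01
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- as.integer(scores >= t)
    c(fpr = sum(pred == 1 & y == 0) / sum(y == 0),
      tpr = sum(pred == 1 & y == 1) / sum(y == 1))
  }, numeric(2)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Label-permutation null distribution of the LOOCV AUC
#'
#' Each permutation shuffles the labels, reruns the entire
#' [loocv_enet()] + [roc_analysis()] pipeline (so lambda selection happens
#' inside the permutation, with no leakage), and records the null AUC. The
#' p-value uses the add-one rule
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)`.
#'
#' @param x,y,spec As in [loocv_enet()].
#' @param n_permutations Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `permutation_null` with `observed_auc`,
#'   `null_aucs`, `p_value`, `n_permutations`, `seed`.
#' @export
permutation_auc <- function(x, y, spec = enet_spec(),
                            n_permutations = 999, seed = 1) {
  if (n_permutations < 99) {
    stop_labelled("permutation", "need n_permutations >= 99")
  }
  cv <- loocv_enet(x, y, spec)
  observed <- roc_analysis(cv$oof_scores, y)$auc
  null_aucs <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      yp <- sample(y)
      cvp <- loocv_enet(x, yp, spec)
      roc_analysis(cvp$oof_scores, yp)$auc
    }, numeric(1))
  })
  p <- (1 + sum(null_aucs >= observed)) / (1 + n_permutations)
  structure(list(observed_auc = observed, null_aucs = null_aucs,
                 p_value = p, n_permutations = n_permutations,
                 seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation test: observed AUC %.3f, null median %.3f, p = %.4g (%d permutations)\n",
              x$observed_auc, stats::median(x$null_aucs), x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Evaluate latent features as a disease classifier
#'
#' The headline classification analysis: screen latent features by Welch
#' t-test with Benjamini-Hochberg correction (keeping features with
#' q < `q_threshold`), fit the elastic-net logistic model on the screened
#' features under leave-one-out cross-validation with the lambda.1se rule,
#' and compute the out-of-fold ROC. Full-data screening mirrors the original
#' analysis and is optimistic relative to in-fold screening; set
#' `screen = "in-fold"` to re-screen inside every fold for an honest
#' evaluation.
#'
#' @param latent n x k latent matrix.
#' @param groups Binary group labels; the positive class is the second
#'   factor level.
#' @param spec An [enet_spec()].
#' @param q_threshold FDR threshold for screening.
#' @param screen `"full"` (screen once on all data), `"in-fold"`, or
#'   `"none"` (use all features).
#' @param n_permutations If > 0, also run [permutation_auc()].
#' @param seed Seed for the permutation stream.
#' @return Object of class `latent_classifier_eval` with the screening
#'   table, screened feature names, `cv` (a `cv_enet`), `roc`
#'   (a `roc_result`) and optional `permutation`.
#' @export
evaluate_latent_classifier <- function(latent, groups, spec = enet_spec(),
                                       q_threshold = 0.05,
                                       screen = c("full", "in-fold", "none"),
                                       n_permutations = 0, seed = 1) {
  screen <- match.arg(screen)
  latent <- as.matrix(latent)
  if (is.null(colnames(latent))) {
    colnames(latent) <- paste0("F", seq_len(ncol(latent)))
  }
  table <- compare_latent_features(latent, groups)
  screened <- if (screen == "none") colnames(latent)
              else table$feature[table$q_value < q_threshold]
  if (screen == "in-fold") {
    res <- .loocv_infold_screen(latent, groups, spec, q_threshold)
    cv <- res
  } else {
    if (length(screened) == 0) {
      stop_labelled("screening",
                    sprintf("no feature passes q < %g", q_threshold))
    }
    cv <- loocv_enet(latent[, screened, drop = FALSE], groups, spec)
  }
  roc <- roc_analysis(cv$oof_scores, groups)
  perm <- NULL
  if (n_permutations > 0) {
    perm <- permutation_auc(latent[, screened, drop = FALSE], groups, spec,
                            n_permutations, seed)
  }
  structure(list(screening = table, screened = screened, cv = cv,
                 roc = roc, permutation = perm, screen = screen),
            class = "latent_classifier_eval")
}

# In-fold screening: each LOOCV fold re-screens features on its own
# training data, fits on the shared full-data lambda grid, and scores the
# held-out sample at the pooled lambda_1se.
.loocv_infold_screen <- function(latent, groups, spec, q_threshold) {
  yb <- .binary_y(groups)
  n <- nrow(latent)
  lam <- .lambda_grid(latent, yb$y01, spec)
  nl <- length(lam)
  dev <- matrix(NA_real_, n, nl); links <- matrix(NA_real_, n, nl)
  for (i in seq_len(n)) {
    xt <- latent[-i, , drop = FALSE]; yt_lab <- groups[-i]
    yt <- yb$y01[-i]
    sel <- tryCatch({
      tab <- compare_latent_features(xt, yt_lab)
      tab$feature[tab$q_value < q_threshold]
    }, error = function(e) character(0))
    if (length(sel) == 0 || length(unique(yt)) < 2) {
      p_hat <- min(max(mean(yt), 1e-6), 1 - 1e-6)
      links[i, ] <- stats::qlogis(p_hat)
    } else {
      fit <- suppressWarnings(
        glmnet::glmnet(.pad_single(xt[, sel, drop = FALSE]), yt,
                       family = "binomial", alpha = spec$alpha,
                       lambda = lam, standardize = spec$standardize))
      links[i, ] <- as.numeric(
        glmnet::predict.glmnet(
          fit, .pad_single(latent[i, sel, drop = FALSE]), s = lam,
          type = "link"))
    }
    dev[i, ] <- .binomial_deviance(yb$y01[i], stats::plogis(links[i, ]))
  }
  cvm <- colMeans(dev)
  cvsd <- apply(dev, 2, stats::sd) / sqrt(n)
  imin <- which.min(cvm)
  lambda_1se <- max(lam[cvm <= cvm[imin] + cvsd[imin]])
  i1se <- which(lam == lambda_1se)[1]
  tab_full <- compare_latent_features(latent, groups)
  sel_full <- tab_full$feature[tab_full$q_value < q_threshold]
  full <- if (length(sel_full)) {
    fit_enet_logistic(latent[, sel_full, drop = FALSE], groups, spec,
                      lambda_1se)
  } else {
    NULL
  }
  structure(list(lambda = lam, cvm = cvm, cvsd = cvsd,
                 lambda_min = lam[imin], lambda_1se = lambda_1se,
                 oof_scores = links[, i1se],
                 support = if (is.null(full)) character(0)
                           else names(full$beta)[full$beta != 0],
                 coefficients = full, y01 = yb$y01, levels = yb$levels,
                 spec = spec),
            class = "cv_enet")
}

#' @export
print.latent_classifier_eval <- function(x, ...) {
  cat(sprintf("screened features (%s): %s\n", x$screen,
              paste(x$screened, collapse = ", ")))
  print(x$cv)
  print(x$roc)
  if (!is.null(x$permutation)) print(x$permutation)
  invisible(x)
}
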