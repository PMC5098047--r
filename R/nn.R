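# Function-potential models: single-feature logistic baselines and the
# 6-input / 3-tanh-hidden-node / logistic-output neural network with
# random-holdback validation.

FEATURE_NAMES <- c("ptm_count", "sasa", "conservation", "ppi", "nc", "nkc")

#' Feature matrix of a MAP table
#'
#' Extracts the six model inputs in canonical order: PTM count, SASA (0
#' when missing), conservation, PPI, neighbor count, neighbor known count.
#'
#' @param maps A `map_table` (or data.frame with the feature columns).
#' @return Numeric matrix with columns `r FEATURE_NAMES`.
#' @export
map_features <- function(maps) {
  sasa <- maps$sasa
  sasa[is.na(sasa)] <- 0
  m <- cbind(ptm_count = as.numeric(maps$ptm_count), sasa = sasa,
             conservation = maps$conservation, ppi = maps$ppi,
             nc = as.numeric(maps$nc), nkc = as.numeric(maps$nkc))
  stopifnot(all(is.finite(m)))
  m
}

#' Single-feature logistic baseline
#'
#' Maximum-likelihood univariate logistic regression (intercept + slope) of
#' the known-function label on one feature; the model's scores are its
#' fitted probabilities. Complete separation triggers a small-ridge refit
#' with a warning.
#'
#' @param x Feature values.
#' @param labels Known-function labels (both classes required).
#' @param ridge Ridge penalty used on separation (default 1e-4).
#' @return List `coef` (intercept, slope), `scores`, `roc`.
#' @export
fit_single_feature_logistic <- function(x, labels, ridge = 1e-4) {
  labels <- as.logical(labels)
  stopifnot(all(is.finite(x)))
  if (!any(labels) || all(labels)) {
    stop("single-class labels: logistic fit undefined")
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(labels ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  if (stats::var(x) == 0) {
    # constant feature: intercept-only fit, slope 0 (not separation)
    cf <- c(stats::qlogis(mean(labels)), 0)
  } else if (separated || any(!is.finite(cf))) {
    warning("complete separation detected; refitting with ridge penalty ",
            ridge)
    y <- as.numeric(labels)
    nll <- function(b) {
      eta <- b[1] + b[2] * x
      mean(log1p(exp(-(2 * y - 1) * eta))) + ridge * b[2]^2
    }
    cf <- stats::optim(c(0, 0), nll, method = "BFGS")$par
    names(cf) <- c("(Intercept)", "x")
  }
  scores <- stats::plogis(cf[1] + cf[2] * x)
  list(coef = unname(cf), scores = scores, roc = roc_auc(scores, labels))
}

#' All six single-feature logistic baselines
#'
#' @param maps A scored or unscored `map_table` with features filled.
#' @return Named list of [fit_single_feature_logistic()] results, one per
#'   feature.
#' @export
fit_feature_baselines <- function(maps) {
  fm <- map_features(maps)
  out <- lapply(colnames(fm), function(nm)
    fit_single_feature_logistic(fm[, nm], maps$known_function))
  names(out) <- colnames(fm)
  out
}

nn_unpack <- function(par, d = 6, h = 3) {
  list(W1 = matrix(par[1:(d * h)], d, h),
       b1 = par[d * h + (1:h)],
       W2 = par[d * h + h + (1:h)],
       b2 = par[d * h + 2 * h + 1])
}

nn_loss_grad <- function(par, X, y, lambda, d, h) {
  p <- nn_unpack(par, d, h)
  n <- nrow(X)
  Z1 <- sweep(X %*% p$W1, 2, p$b1, "+")
  H <- tanh(Z1)
  eta <- drop(H %*% p$W2) + p$b2
  prob <- stats::plogis(eta)
  # cross-entropy via log1p for numerical stability
  loss <- mean(log1p(exp(-(2 * y - 1) * eta))) +
    lambda * (sum(p$W1^2) + sum(p$W2^2))
  d2 <- (prob - y) / n
  gW2 <- drop(crossprod(H, d2)) + 2 * lambda * p$W2
  gb2 <- sum(d2)
  dH <- outer(d2, p$W2)
  dZ1 <- dH * (1 - H^2)
  gW1 <- crossprod(X, dZ1) + 2 * lambda * p$W1
  gb1 <- colSums(dZ1)
  list(loss = loss, grad = c(as.vector(gW1), gb1, gW2, gb2))
}

#' Train the function-potential neural network
#'
#' A fully connected network with the six MAP features feeding a single
#' hidden layer of `hidden` tanh nodes and a logistic output. Inputs are
#' standardized on the training partition; a random 33% of the data is held
#' back for validation; the L2-penalized cross-entropy is minimized by BFGS
#' from a seed-controlled small random initialization, so two runs with the
#' same seed produce bit-identical parameters.
#'
#' @param features Numeric matrix (rows = MAPs, 6 columns) as from
#'   [map_features()].
#' @param labels Known-function labels.
#' @param holdback Validation fraction (default 0.33).
#' @param seed Integer seed (required).
#' @param hidden Hidden nodes (default 3).
#' @param lambda L2 penalty (default 1e-3).
#' @param maxit BFGS iteration cap (default 500).
#' @return A `saphire_nn`: normalization, weights, training metadata, plus
#'   `roc_train`, `roc_valid`, `roc_full` and the validation indices.
#' @export
train_saphire_nn <- function(features, labels, holdback = 0.33, seed,
                             hidden = 3, lambda = 1e-3, maxit = 500) {
  if (missing(seed)) stop("a seed is required for reproducible training")
  labels <- as.logical(labels)
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 200) stop("need at least 200 samples to train the network")
  stopifnot(all(is.finite(X)), length(labels) == n)
  d <- ncol(X); h <- hidden
  set.seed(seed)
  valid_idx <- integer(0)
  for (try in 1:10) {
    valid_idx <- sort(sample.int(n, round(holdback * n)))
    tr <- setdiff(seq_len(n), valid_idx)
    if (length(unique(labels[tr])) == 2 &&
        length(unique(labels[valid_idx])) == 2) break
    if (try == 10) stop("a class is absent from a partition after 10 draws")
  }
  tr <- setdiff(seq_len(n), valid_idx)
  center <- colMeans(X[tr, , drop = FALSE])
  scale <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  y <- as.numeric(labels)
  par0 <- stats::runif(d * h + h + h + 1, -0.5, 0.5) / sqrt(d)
  fit <- stats::optim(par0,
                      fn = function(p) nn_loss_grad(p, Xs[tr, ], y[tr],
                                                    lambda, d, h)$loss,
                      gr = function(p) nn_loss_grad(p, Xs[tr, ], y[tr],
                                                    lambda, d, h)$grad,
                      method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  if (!is.finite(fit$value)) stop("non-finite training loss")
  w <- nn_unpack(fit$par, d, h)
  model <- structure(list(center = center, scale = scale,
                          W1 = w$W1, b1 = w$b1, W2 = w$W2, b2 = w$b2,
                          feature_names = colnames(X),
                          meta = list(seed = seed, holdback = holdback,
                                      lambda = lambda, hidden = h,
                                      maxit = maxit,
                                      convergence = fit$convergence,
                                      final_loss = fit$value)),
                     class = "saphire_nn")
  scores <- nn_forward(model, X)
  model$valid_idx <- valid_idx
  model$roc_train <- roc_auc(scores[tr], labels[tr])
  model$roc_valid <- roc_auc(scores[valid_idx], labels[valid_idx])
  model$roc_full <- roc_auc(scores, labels)
  model
}

#' Forward pass of the neural network
#'
#' `logistic(W2' tanh(W1' normalize(x) + b1) + b2)`, strictly inside (0, 1).
#'
#' @param model A `saphire_nn` (trained, or hand-parameterized with the
#'   same fields).
#' @param features Numeric matrix or single feature vector.
#' @return Probability vector.
#' @export
nn_forward <- function(model, features) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1)
       else as.matrix(features)
  if (!all(is.finite(X))) stop("non-finite feature input")
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  H <- tanh(sweep(Xs %*% model$W1, 2, model$b1, "+"))
  drop(stats::plogis(drop(H %*% model$W2) + model$b2))
}

#' @export
predict.saphire_nn <- function(object, newdata, ...) {
  nn_forward(object, newdata)
}

#' @export
print.saphire_nn <- function(x, ...) {
  cat(sprintf("saphire_nn: %d-%d-1 tanh network (seed %s)\n",
              length(x$center), x$meta$hidden, x$meta$seed))
  if (!is.null(x$roc_valid)) {
    cat(sprintf("  validation AUC %.3f (train %.3f, full %.3f)\n",
                x$roc_valid$auc, x$roc_train$auc, x$roc_full$auc))
  }
  invisible(x)
}

#' Serialize a trained network to JSON
#' @param model A `saphire_nn`.
#' @param path Output path.
#' @export
write_nn_model <- function(model, path) {
  jsonlite::write_json(list(center = model$center, scale = model$scale,
                            W1 = as.vector(model$W1), b1 = model$b1,
                            W2 = model$W2, b2 = model$b2,
                            feature_names = model$feature_names,
                            meta = model$meta),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a serialized network
#' @param path JSON path written by [write_nn_model()].
#' @return A `saphire_nn` usable with [nn_forward()].
#' @export
read_nn_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = as.numeric(j$center), scale = as.numeric(j$scale),
                 W1 = matrix(as.numeric(j$W1), length(j$center)),
                 b1 = as.numeric(j$b1), W2 = as.numeric(j$W2),
                 b2 = as.numeric(j$b2),
                 feature_names = j$feature_names, meta = j$meta),
            class = "saphire_nn")
}
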