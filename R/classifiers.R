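# The eight reference classifiers behind one fit/predict surface.  The
# hyperparameters fixed below are the printed study settings (AdaBoost 100
# estimators; DT gini, min split 2, min leaf 1; SVM rbf; LR l2; RF 100
# trees; MLP hidden layers (5, 2); GBDT 200 estimators); everything else
# follows the common library defaults and is echoed into the fitted object.

#' Names of the eight reference classifiers
#' @export
CLASSIFIER_NAMES <- c("adaboost", "dt", "gbdt", "lr", "nb", "rf", "svm",
                      "mlp")

#' Fit one of the eight reference classifiers
#'
#' @param x numeric matrix / data.frame of features (rows = patients).
#' @param y binary labels (0/1).
#' @param method one of `"adaboost"`, `"dt"`, `"gbdt"`, `"lr"`, `"nb"`,
#'   `"rf"`, `"svm"`, `"mlp"`.
#' @param params named list of hyperparameter overrides.
#' @param seed RNG seed for the stochastic learners.
#' @return an object of class `c("hf_classifier", "<method>")` with a
#'   [predict()] method returning class-1 probabilities.
#' @export
hf_classifier <- function(x, y, method = CLASSIFIER_NAMES, params = list(),
                          seed = 1L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  set.seed(seed)
  fit <- switch(method,
                adaboost = fit_adaboost(x, y, params),
                dt = fit_dt(x, y, params),
                gbdt = fit_gbdt(x, y, params),
                lr = fit_ridge_lr(x, y, params),
                nb = fit_gnb(x, y, params),
                rf = fit_rf(x, y, params),
                svm = fit_rbf_svm(x, y, params),
                mlp = fit_mlp(x, y, params))
  structure(c(fit, list(method = method, seed = seed,
                        feature_names = colnames(x))),
            class = c("hf_classifier", method))
}

#' @export
print.hf_classifier <- function(x, ...) {
  cat(sprintf("<hf_classifier> %s (%d features)\n", x$method,
              length(x$feature_names) %||% NA_integer_))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict heart-failure probability with a fitted classifier
#'
#' @param object an `hf_classifier`.
#' @param newdata feature matrix.
#' @param type `"prob"` (class-1 probability) or `"class"` (0/1 at the 0.5
#'   threshold).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.hf_classifier <- function(object, newdata,
                                  type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  p <- switch(object$method,
              adaboost = pred_adaboost(object, x),
              dt = predict_tree(object$tree, x),
              gbdt = pred_gbdt(object, x),
              lr = pred_ridge_lr(object, x),
              nb = pred_gnb(object, x),
              rf = pred_rf(object, x),
              svm = pred_rbf_svm(object, x),
              mlp = pred_mlp(object, x))
  p <- pmin(pmax(p, 0), 1)
  if (type == "class") as.integer(p >= 0.5) else p
}

# ---- decision tree -------------------------------------------------------

fit_dt <- function(x, y, params) {
  pr <- utils::modifyList(list(max_depth = 30L, min_split = 2L,
                               min_leaf = 1L), params)
  list(tree = build_tree(x, y, max_depth = pr$max_depth,
                         min_split = pr$min_split, min_leaf = pr$min_leaf,
                         criterion = "gini"),
       params = pr)
}

# ---- random forest -------------------------------------------------------

fit_rf <- function(x, y, params) {
  pr <- utils::modifyList(list(n_estimators = 100L, max_depth = 30L,
                               min_leaf = 1L,
                               mtry = max(1L, floor(sqrt(ncol(x))))),
                          params)
  n <- nrow(x)
  trees <- vector("list", pr$n_estimators)
  for (b in seq_len(pr$n_estimators)) {
    idx <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- build_tree(x[idx, , drop = FALSE], y[idx],
                             max_depth = pr$max_depth, min_leaf = pr$min_leaf,
                             mtry = pr$mtry, criterion = "gini")
  }
  list(trees = trees, params = pr)
}

pred_rf <- function(object, x) {
  ps <- vapply(object$trees, function(tr) predict_tree(tr, x),
               numeric(nrow(x)))
  if (is.null(dim(ps))) ps <- matrix(ps, nrow = 1L)
  rowMeans(ps)
}

# ---- AdaBoost (SAMME with depth-1 stumps) --------------------------------

fit_adaboost <- function(x, y, params) {
  pr <- utils::modifyList(list(n_estimators = 100L, learning_rate = 1.0,
                               max_depth = 1L), params)
  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(pr$n_estimators)) {
    tr <- build_tree(x, y, w = w, max_depth = pr$max_depth,
                     criterion = "gini")
    pred <- as.integer(predict_tree(tr, x) >= 0.5)
    err <- sum(w * (pred != y))
    if (err <= 0) { stumps[[m]] <- tr; alphas[m] <- 10; break }
    if (err >= 0.5) break
    a <- pr$learning_rate * log((1 - err) / err)
    stumps[[m]] <- tr; alphas[m] <- a
    w <- w * exp(a * (pred != y))
    w <- w / sum(w)
  }
  if (!length(stumps)) {            # degenerate: single majority stump
    stumps <- list(build_tree(x, y, max_depth = 0L, criterion = "gini"))
    alphas <- 1
  }
  list(stumps = stumps, alphas = alphas, params = pr)
}

pred_adaboost <- function(object, x) {
  score <- numeric(nrow(x))
  for (m in seq_along(object$stumps)) {
    pm <- 2 * as.integer(predict_tree(object$stumps[[m]], x) >= 0.5) - 1
    score <- score + object$alphas[m] * pm
  }
  stats::plogis(2 * score / sum(abs(object$alphas)))
}

# ---- gradient boosting (binomial deviance, depth-3 trees) ---------------

fit_gbdt <- function(x, y, params) {
  pr <- utils::modifyList(list(n_estimators = 200L, learning_rate = 0.1,
                               max_depth = 3L, min_leaf = 1L), params)
  n <- nrow(x)
  p0 <- mean(y)
  F0 <- log(p0 / (1 - p0))
  Fx <- rep(F0, n)
  trees <- vector("list", pr$n_estimators)
  for (m in seq_len(pr$n_estimators)) {
    p <- stats::plogis(Fx)
    r <- y - p                       # negative gradient of the deviance
    tr <- build_tree(x, r, max_depth = pr$max_depth, min_leaf = pr$min_leaf,
                     criterion = "mse")
    pl <- predict_tree(tr, x, leaf_id = TRUE)
    h <- p * (1 - p)
    num <- rowsum(r, pl$leaf); den <- rowsum(h, pl$leaf)
    gamma <- num[, 1] / pmax(den[, 1], 1e-10)
    tr <- set_leaf_values(tr, as.list(stats::setNames(gamma,
                                                      rownames(num))))
    Fx <- Fx + pr$learning_rate * predict_tree(tr, x)
    trees[[m]] <- tr
  }
  list(trees = trees, F0 = F0, params = pr)
}

pred_gbdt <- function(object, x) {
  Fx <- rep(object$F0, nrow(x))
  lr <- object$params$learning_rate
  for (tr in object$trees) Fx <- Fx + lr * predict_tree(tr, x)
  stats::plogis(Fx)
}

# ---- ridge logistic regression (IRLS, l2 penalty) ------------------------

fit_ridge_lr <- function(x, y, params) {
  pr <- utils::modifyList(list(C = 1.0, max_iter = 50L, tol = 1e-8), params)
  sc <- feature_scaler(x)
  xs <- cbind(1, scale_features(x, sc))
  lambda <- 1 / pr$C
  pen <- diag(c(0, rep(lambda, ncol(xs) - 1L)))
  beta <- numeric(ncol(xs))
  for (it in seq_len(pr$max_iter)) {
    eta <- drop(xs %*% beta)
    mu <- stats::plogis(eta)
    wv <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / wv
    H <- crossprod(xs * wv, xs) + pen
    bnew <- solve(H, crossprod(xs * wv, z))
    if (max(abs(bnew - beta)) < pr$tol) { beta <- drop(bnew); break }
    beta <- drop(bnew)
  }
  list(beta = beta, scaler = sc, params = pr)
}

pred_ridge_lr <- function(object, x) {
  xs <- cbind(1, scale_features(x, object$scaler))
  stats::plogis(drop(xs %*% object$beta))
}

feature_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(center = mu, scale = sdv)
}

scale_features <- function(x, sc) {
  sweep(sweep(x, 2, sc$center), 2, sc$scale, "/")
}

# ---- Gaussian naive Bayes ------------------------------------------------

fit_gnb <- function(x, y, params) {
  pr <- utils::modifyList(list(var_smoothing = 1e-9), params)
  eps <- pr$var_smoothing * max(apply(x, 2, stats::var), 1e-12)
  stats_by_class <- lapply(c(0L, 1L), function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    list(mu = colMeans(xi),
         var = apply(xi, 2, function(v) mean((v - mean(v))^2)) + eps,
         prior = mean(y == cl))
  })
  list(classes = stats_by_class, params = pr)
}

pred_gnb <- function(object, x) {
  ll <- vapply(object$classes, function(cs) {
    z <- sweep(x, 2, cs$mu)
    rowSums(-0.5 * (log(2 * pi * rep(1, nrow(x)) %o% cs$var) +
                      sweep(z^2, 2, cs$var, "/"))) + log(cs$prior)
  }, numeric(nrow(x)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1L)
  1 / (1 + exp(ll[, 1] - ll[, 2]))
}

# ---- rbf-kernel SVM (SMO) with Platt-scaled probabilities ----------------

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

fit_rbf_svm <- function(x, y, params) {
  pr <- utils::modifyList(list(C = 1.0, gamma = NULL, tol = 1e-3,
                               max_passes = 10L, max_iter = 2000L), params)
  sc <- feature_scaler(x)
  xs <- scale_features(x, sc)
  if (is.null(pr$gamma)) {
    v <- mean(apply(xs, 2, stats::var))
    pr$gamma <- 1 / (ncol(xs) * max(v, 1e-12))
  }
  ys <- 2 * y - 1
  n <- nrow(xs)
  K <- rbf_kernel(xs, xs, pr$gamma)
  alpha <- numeric(n); b <- 0
  passes <- 0L; iters <- 0L
  fcache <- function(i) sum(alpha * ys * K[, i]) + b
  while (passes < pr$max_passes && iters < pr$max_iter) {
    iters <- iters + 1L
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- fcache(i) - ys[i]
      if ((ys[i] * Ei < -pr$tol && alpha[i] < pr$C) ||
          (ys[i] * Ei > pr$tol && alpha[i] > 0)) {
        j <- sample(setdiff(seq_len(n), i), 1L)
        Ej <- fcache(j) - ys[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (ys[i] != ys[j]) {
          L <- max(0, alpha[j] - alpha[i]); H <- min(pr$C, pr$C + alpha[j] -
                                                       alpha[i])
        } else {
          L <- max(0, alpha[i] + alpha[j] - pr$C)
          H <- min(pr$C, alpha[i] + alpha[j])
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        alpha[j] <- min(max(aj_old - ys[j] * (Ei - Ej) / eta, L), H)
        if (abs(alpha[j] - aj_old) < 1e-5) next
        alpha[i] <- ai_old + ys[i] * ys[j] * (aj_old - alpha[j])
        b1 <- b - Ei - ys[i] * (alpha[i] - ai_old) * K[i, i] -
          ys[j] * (alpha[j] - aj_old) * K[i, j]
        b2 <- b - Ej - ys[i] * (alpha[i] - ai_old) * K[i, j] -
          ys[j] * (alpha[j] - aj_old) * K[j, j]
        b <- if (alpha[i] > 0 && alpha[i] < pr$C) b1
        else if (alpha[j] > 0 && alpha[j] < pr$C) b2 else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  sv <- which(alpha > 1e-8)
  dec <- drop(K %*% (alpha * ys)) + b
  # Platt scaling of the decision values on the training set
  platt <- suppressWarnings(stats::glm(y ~ dec,
                                       family = stats::binomial()))
  list(sv_x = xs[sv, , drop = FALSE], sv_coef = (alpha * ys)[sv], b = b,
       gamma = pr$gamma, scaler = sc, platt = stats::coef(platt),
       params = pr)
}

pred_rbf_svm <- function(object, x) {
  xs <- scale_features(x, object$scaler)
  dec <- if (nrow(object$sv_x)) {
    drop(rbf_kernel(xs, object$sv_x, object$gamma) %*% object$sv_coef) +
      object$b
  } else rep(object$b, nrow(xs))
  co <- object$platt
  if (anyNA(co)) co[is.na(co)] <- 0
  stats::plogis(co[1] + co[2] * dec)
}

# ---- multilayer perceptron, hidden layers (5, 2) -------------------------

fit_mlp <- function(x, y, params) {
  pr <- utils::modifyList(list(hidden = c(5L, 2L), lr = 1e-3, alpha = 1e-4,
                               max_iter = 400L), params)
  sc <- feature_scaler(x)
  xs <- scale_features(x, sc)
  sizes <- c(ncol(xs), pr$hidden, 1L)
  L <- length(sizes) - 1L
  W <- lapply(seq_len(L), function(l)
    matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                        sqrt(2 / sizes[l])), sizes[l], sizes[l + 1]))
  bvec <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(bvec, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; epsd <- 1e-8
  n <- nrow(xs)
  for (it in seq_len(pr$max_iter)) {
    # forward
    a <- list(xs); zs <- list()
    for (l in seq_len(L)) {
      z <- sweep(a[[l]] %*% W[[l]], 2, bvec[[l]], "+")
      zs[[l]] <- z
      a[[l + 1]] <- if (l < L) pmax(z, 0) else stats::plogis(z)
    }
    phat <- drop(a[[L + 1]])
    delta <- matrix((phat - y) / n, ncol = 1)
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in rev(seq_len(L))) {
      gW[[l]] <- crossprod(a[[l]], delta) + pr$alpha * W[[l]] / n
      gb[[l]] <- colSums(delta)
      if (l > 1L)
        delta <- (delta %*% t(W[[l]])) * (zs[[l - 1]] > 0)
    }
    for (l in seq_len(L)) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
      mhW <- mW[[l]] / (1 - b1^it); vhW <- vW[[l]] / (1 - b2^it)
      mhb <- mb[[l]] / (1 - b1^it); vhb <- vb[[l]] / (1 - b2^it)
      W[[l]] <- W[[l]] - pr$lr * mhW / (sqrt(vhW) + epsd)
      bvec[[l]] <- bvec[[l]] - pr$lr * mhb / (sqrt(vhb) + epsd)
    }
  }
  list(W = W, b = bvec, scaler = sc, params = pr)
}

pred_mlp <- function(object, x) {
  a <- scale_features(x, object$scaler)
  L <- length(object$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% object$W[[l]], 2, object$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else stats::plogis(z)
  }
  drop(a)
}
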