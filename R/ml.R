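# Binary classifier families over SASA descriptor tables.
#
# Eight families with the printed default hyperparameters: single Gini
# decision tree (min node 10, max depth 20, <= 20 candidate split bins per
# feature), bagged forest (10 trees), random forest (500 trees, 9 randomly
# preselected variables per split), Gaussian naive Bayes, radial-kernel
# SVM (least-squares formulation; cost 1, gamma 0.0125), logistic
# regression (GLM), a 2 x 80 sigmoid MLP trained by SGD (learning rate
# 0.1, momentum 0.9, dropout 0.25, at most 5000 minibatch updates), and a
# bagging ensemble of 10 such MLPs. All families weight samples inversely
# to class frequency ("by class") and expose probability-like scores for
# class 1. Descriptors are min-max normalized on the training partition
# only.

# run expr with a local, restorable RNG stream
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.ml_families <- c("tree", "bagged_forest", "random_forest", "naive_bayes",
                  "svm", "logistic_regression", "neural_net",
                  "neural_net_bagging")

#' Specify a classifier
#'
#' @param family One of `"tree"`, `"bagged_forest"`, `"random_forest"`,
#'   `"naive_bayes"`, `"svm"`, `"logistic_regression"`, `"neural_net"`,
#'   `"neural_net_bagging"`.
#' @param seed Integer seed controlling every stochastic element.
#' @param ... Hyperparameter overrides. Defaults: trees use
#'   `min_node = 10`, `max_depth = 20`, `max_bins = 20`; `bagged_forest`
#'   adds `n_trees = 10`; `random_forest` uses `n_trees = 500`, `mtry = 9`;
#'   `svm` uses `cost = 1`, `gamma = 0.0125`; `neural_net` uses
#'   `hidden = c(80, 80)`, `lr = 0.1`, `momentum = 0.9`, `dropout = 0.25`,
#'   `max_iter = 5000`, `batch_size = 64`; `neural_net_bagging` adds
#'   `n_nets = 10`.
#' @return A `model_spec`.
#' @export
model_spec <- function(family, seed = 1L, ...) {
  if (!family %in% .ml_families)
    stop("unknown model family: ", family)
  defaults <- switch(family,
    tree = list(min_node = 10, max_depth = 20, max_bins = 20),
    bagged_forest = list(min_node = 10, max_depth = 20, max_bins = 20,
                         n_trees = 10),
    random_forest = list(min_node = 10, max_depth = 20, max_bins = 20,
                         n_trees = 500, mtry = 9),
    naive_bayes = list(var_floor = 1e-9),
    svm = list(cost = 1, gamma = 0.0125),
    logistic_regression = list(),
    neural_net = list(hidden = c(80, 80), lr = 0.1, momentum = 0.9,
                      dropout = 0.25, max_iter = 5000, batch_size = 64),
    neural_net_bagging = list(hidden = c(80, 80), lr = 0.1,
                              momentum = 0.9, dropout = 0.25,
                              max_iter = 5000, batch_size = 64,
                              n_nets = 10))
  hp <- utils::modifyList(defaults, list(...))
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Stratified train/test split
#'
#' @param labels 0/1 vector (or a data.frame with a `label` column).
#' @param train_fraction Fraction in the training set (default 0.7).
#' @param seed Split seed.
#' @return List with integer index vectors `train` and `test`; per-class
#'   counts match the fraction to within one row.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  if (is.data.frame(labels)) labels <- labels$label
  stopifnot(train_fraction > 0, train_fraction < 1)
  .check_two_class(labels)
  if (min(table(labels)) < 2)
    stop("each class needs >= 2 members to split")
  train <- integer()
  .with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- which(labels == cl)
      n_tr <- floor(train_fraction * length(idx) + 0.5)
      n_tr <- min(max(n_tr, 1), length(idx) - 1)
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

.class_weights <- function(y) {
  n <- length(y)
  w <- ifelse(y == 1, n / (2 * sum(y == 1)), n / (2 * sum(y == 0)))
  w
}

.minmax_fit <- function(x) {
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  hi[hi == lo] <- lo[hi == lo] + 1
  list(lo = lo, hi = hi)
}

.minmax_apply <- function(x, mm) {
  sweep(sweep(x, 2, mm$lo, "-"), 2, mm$hi - mm$lo, "/")
}

.as_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[, vapply(x, is.numeric, TRUE), drop = FALSE]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  x
}

# ------------------------------------------------------------------ CART

.cart_fit <- function(X, y, w, min_node, max_depth, max_bins,
                      mtry = NULL) {
  nfeat <- ncol(X)
  build <- function(idx, depth) {
    wi <- w[idx]; yi <- y[idx]
    W <- sum(wi); p <- sum(wi * yi) / W
    leaf <- list(leaf = TRUE, prob = p)
    if (length(idx) < 2 * min_node || depth >= max_depth ||
        p <= 0 || p >= 1)
      return(leaf)
    feats <- if (is.null(mtry) || mtry >= nfeat) seq_len(nfeat)
             else sample(nfeat, mtry)
    best <- list(score = Inf)
    g_parent <- 2 * p * (1 - p) * W
    for (f in feats) {
      v <- X[idx, f]
      ord <- order(v)
      vs <- v[ord]; ws <- wi[ord]; ys <- yi[ord]
      cw <- cumsum(ws); cwy <- cumsum(ws * ys)
      n <- length(idx)
      k <- which(vs[-n] < vs[-1])
      k <- k[k >= min_node & (n - k) >= min_node]
      if (!length(k)) next
      if (length(k) > max_bins)
        k <- k[unique(round(seq(1, length(k), length.out = max_bins)))]
      WL <- cw[k]; YL <- cwy[k]
      WR <- W - WL; YR <- cwy[n] - YL
      pL <- YL / WL; pR <- YR / WR
      sc <- WL * 2 * pL * (1 - pL) + WR * 2 * pR * (1 - pR)
      j <- which.min(sc)
      if (sc[j] < best$score) {
        best <- list(score = sc[j], feature = f,
                     threshold = (vs[k[j]] + vs[k[j] + 1]) / 2)
      }
    }
    if (!is.finite(best$score) || g_parent - best$score <= 1e-12)
      return(leaf)
    v <- X[idx, best$feature]
    li <- idx[v <= best$threshold]; ri <- idx[v > best$threshold]
    list(leaf = FALSE, feature = best$feature,
         threshold = best$threshold, prob = p,
         left = build(li, depth + 1), right = build(ri, depth + 1))
  }
  build(seq_len(nrow(X)), 0)
}

.cart_predict <- function(tree, X) {
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) { out[idx] <<- node$prob; return() }
    v <- X[idx, node$feature]
    rec(node$left, idx[v <= node$threshold])
    rec(node$right, idx[v > node$threshold])
  }
  rec(tree, seq_len(nrow(X)))
  out
}

# ------------------------------------------------------------------- MLP

.mlp_fit <- function(X, y, w, hidden, lr, momentum, dropout, max_iter,
                     batch_size) {
  n <- nrow(X)
  sizes <- c(ncol(X), hidden, 1)
  L <- length(sizes) - 1
  Wts <- vector("list", L); Bs <- vector("list", L)
  vW <- vector("list", L); vB <- vector("list", L)
  for (l in seq_len(L)) {
    r <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    Wts[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -r, r),
                       sizes[l], sizes[l + 1])
    Bs[[l]] <- numeric(sizes[l + 1])
    vW[[l]] <- Wts[[l]] * 0; vB[[l]] <- Bs[[l]] * 0
  }
  sig <- function(z) 1 / (1 + exp(-z))
  bs <- min(batch_size, n)
  for (it in seq_len(max_iter)) {
    idx <- sample.int(n, bs, replace = bs > n)
    A <- list(X[idx, , drop = FALSE])
    masks <- vector("list", L)
    for (l in seq_len(L)) {
      z <- sweep(A[[l]] %*% Wts[[l]], 2, Bs[[l]], "+")
      a <- sig(z)
      if (l < L && dropout > 0) {
        m <- matrix(stats::runif(length(a)) >= dropout,
                    nrow(a), ncol(a)) / (1 - dropout)
        a <- a * m
        masks[[l]] <- m
      }
      A[[l + 1]] <- a
    }
    p <- A[[L + 1]][, 1]
    wi <- w[idx] / sum(w[idx])
    # weighted cross-entropy with sigmoid output: delta = p - y
    delta <- matrix((p - y[idx]) * wi, ncol = 1)
    for (l in rev(seq_len(L))) {
      gW <- crossprod(A[[l]], delta)
      gB <- colSums(delta)
      if (l > 1) {
        a <- A[[l]]
        back <- delta %*% t(Wts[[l]])
        if (!is.null(masks[[l - 1]])) back <- back * masks[[l - 1]]
        delta <- back * a * (1 - a)
      }
      vW[[l]] <- momentum * vW[[l]] - lr * gW
      vB[[l]] <- momentum * vB[[l]] - lr * gB
      Wts[[l]] <- Wts[[l]] + vW[[l]]
      Bs[[l]] <- Bs[[l]] + vB[[l]]
    }
  }
  list(W = Wts, B = Bs)
}

.mlp_predict <- function(net, X) {
  sig <- function(z) 1 / (1 + exp(-z))
  a <- X
  for (l in seq_along(net$W))
    a <- sig(sweep(a %*% net$W[[l]], 2, net$B[[l]], "+"))
  a[, 1]
}

# ----------------------------------------------------------------- fit

#' Fit a classifier on a descriptor table
#'
#' Descriptors are min-max normalized on the training data (the ranges
#' travel with the model and are applied at prediction time). Samples are
#' weighted inversely to class frequency.
#'
#' @param spec A [model_spec()].
#' @param x Descriptor matrix or data.frame (numeric columns only are
#'   used).
#' @param y 0/1 labels (both classes required).
#' @return A `fitted_model` exposing class-1 probabilities via
#'   [predict_prob()].
#' @export
fit_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "model_spec"))
  X0 <- .as_matrix(x)
  y <- as.numeric(y)
  .check_two_class(y)
  stopifnot(nrow(X0) == length(y))
  mm <- .minmax_fit(X0)
  X <- .minmax_apply(X0, mm)
  w <- .class_weights(y)
  hp <- spec$hyperparameters

  fit <- .with_seed(spec$seed, switch(spec$family,
    tree = .cart_fit(X, y, w, hp$min_node, hp$max_depth, hp$max_bins),
    bagged_forest = ,
    random_forest = {
      mtry <- if (spec$family == "random_forest")
        min(hp$mtry, ncol(X)) else NULL
      lapply(seq_len(hp$n_trees), function(b) {
        idx <- sample.int(nrow(X), replace = TRUE)
        .cart_fit(X[idx, , drop = FALSE], y[idx], w[idx],
                  hp$min_node, hp$max_depth, hp$max_bins, mtry)
      })
    },
    naive_bayes = {
      by_class <- lapply(c(0, 1), function(cl) {
        i <- y == cl
        wi <- w[i] / sum(w[i])
        mu <- colSums(X[i, , drop = FALSE] * wi)
        va <- colSums(sweep(X[i, , drop = FALSE], 2, mu)^2 * wi)
        list(mu = mu, var = pmax(va, hp$var_floor),
             logprior = log(sum(w[i]) / sum(w)))
      })
      names(by_class) <- c("c0", "c1")
      by_class
    },
    svm = {
      yy <- 2 * y - 1
      K <- .rbf_kernel(X, X, hp$gamma)
      n <- nrow(X)
      A <- rbind(c(0, rep(1, n)),
                 cbind(1, K + diag(1 / (hp$cost * w), n)))
      sol <- solve(A, c(0, yy))
      list(alpha = sol[-1], b = sol[1], sv = X, gamma = hp$gamma)
    },
    logistic_regression = {
      f <- suppressWarnings(
        stats::glm.fit(cbind(1, X), y, weights = w,
                       family = stats::binomial()))
      cf <- f$coefficients
      cf[is.na(cf)] <- 0
      cf
    },
    neural_net = .mlp_fit(X, y, w, hp$hidden, hp$lr, hp$momentum,
                          hp$dropout, hp$max_iter, hp$batch_size),
    neural_net_bagging = lapply(seq_len(hp$n_nets), function(b) {
      idx <- sample.int(nrow(X), replace = TRUE)
      .mlp_fit(X[idx, , drop = FALSE], y[idx], w[idx], hp$hidden,
               hp$lr, hp$momentum, hp$dropout, hp$max_iter,
               hp$batch_size)
    })
  ))
  structure(list(spec = spec, fit = fit, minmax = mm,
                 features = colnames(X0)),
            class = "fitted_model")
}

.rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

#' Class-1 probability-like scores of a fitted model
#'
#' @param model A `fitted_model`.
#' @param x New descriptor matrix/data.frame (same columns as training).
#' @return Numeric vector in \[0, 1\].
#' @export
predict_prob <- function(model, x) {
  stopifnot(inherits(model, "fitted_model"))
  X0 <- .as_matrix(x)
  if (!is.null(model$features) && !is.null(colnames(X0)))
    X0 <- X0[, model$features, drop = FALSE]
  X <- .minmax_apply(X0, model$minmax)
  hp <- model$spec$hyperparameters
  switch(model$spec$family,
    tree = .cart_predict(model$fit, X),
    bagged_forest = ,
    random_forest = rowMeans(vapply(model$fit, function(tr)
      .cart_predict(tr, X), numeric(nrow(X)))),
    naive_bayes = {
      ll <- vapply(model$fit, function(cl) {
        rowSums(sweep(sweep(X, 2, cl$mu)^2, 2, -1 / (2 * cl$var), "*") -
                  matrix(0.5 * log(2 * pi * cl$var), nrow(X),
                         ncol(X), byrow = TRUE)) + cl$logprior
      }, numeric(nrow(X)))
      1 / (1 + exp(ll[, 1] - ll[, 2]))
    },
    svm = {
      f <- .rbf_kernel(X, model$fit$sv, model$fit$gamma) %*%
        model$fit$alpha + model$fit$b
      stats::plogis(drop(f))
    },
    logistic_regression = stats::plogis(drop(cbind(1, X) %*% model$fit)),
    neural_net = .mlp_predict(model$fit, X),
    neural_net_bagging = rowMeans(vapply(model$fit, function(net)
      .mlp_predict(net, X), numeric(nrow(X))))
  )
}

# ------------------------------------------------------------ evaluation

#' Confusion table at a probability threshold
#'
#' @param labels 0/1 vector.
#' @param probs Class-1 probabilities.
#' @param threshold Classification threshold (default 0.5).
#' @return A `confusion_table`: list with TP, TN, FP, FN.
#' @export
confusion_table <- function(labels, probs, threshold = 0.5) {
  pred <- as.integer(probs >= threshold)
  structure(list(TP = sum(pred == 1 & labels == 1),
                 TN = sum(pred == 0 & labels == 0),
                 FP = sum(pred == 1 & labels == 0),
                 FN = sum(pred == 0 & labels == 1)),
            class = "confusion_table")
}

#' Confusion-matrix statistics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
#' concordance (accuracy) (TP+TN)/n, Youden's J = sens + spec - 1,
#' Matthews correlation coefficient, F1 (harmonic mean of precision and
#' sensitivity), and Cohen's kappa with expected agreement from the
#' marginals. Any metric with a zero denominator is reported as `NA`,
#' never as 0.
#'
#' @param ct A `confusion_table` (or list with TP, TN, FP, FN).
#' @return Named list of the eight statistics.
#' @export
confusion_metrics <- function(ct) {
  TP <- ct$TP; TN <- ct$TN; FP <- ct$FP; FN <- ct$FN
  n <- TP + TN + FP + FN
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(TP, TP + FN)
  spec <- div(TN, TN + FP)
  prec <- div(TP, TP + FP)
  conc <- div(TP + TN, n)
  j <- if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1
  mden <- prod(sqrt(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (mden > 0) (TP * TN - FP * FN) / mden else NA_real_
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  pe <- div((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN), n^2)
  kappa <- if (is.na(pe) || is.na(conc) || pe == 1) NA_real_
           else (conc - pe) / (1 - pe)
  list(sensitivity = sens, specificity = spec, precision = prec,
       concordance = conc, youden_j = j, mcc = mcc, f1 = f1,
       kappa = kappa)
}

#' Stratified k-fold cross-validation
#'
#' @param spec A [model_spec()].
#' @param x,y Training descriptors and 0/1 labels.
#' @param k Folds (default 10, stratified: class ratio preserved within
#'   one row per fold).
#' @param seed Fold-assignment seed.
#' @param threshold Probability threshold for the confusion statistics.
#' @return List with `per_fold` (data.frame: fold, auc and the eight
#'   confusion statistics), `mean` and `sd` (named vectors over metrics).
#' @export
cross_validate <- function(spec, x, y, k = 10, seed = 1L,
                           threshold = 0.5) {
  y <- as.numeric(y)
  .check_two_class(y)
  if (k > min(table(y)))
    stop("k exceeds the size of the smaller class")
  folds <- integer(length(y))
  .with_seed(seed, {
    for (cl in c(0, 1)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  rows <- lapply(seq_len(k), function(f) {
    tr <- folds != f; te <- !tr
    m <- fit_model(spec, .as_matrix(x)[tr, , drop = FALSE], y[tr])
    p <- predict_prob(m, .as_matrix(x)[te, , drop = FALSE])
    cm <- confusion_metrics(confusion_table(y[te], p, threshold))
    c(fold = f, auc = roc_auc(y[te], p), unlist(cm))
  })
  per_fold <- as.data.frame(do.call(rbind, rows))
  metrics <- setdiff(names(per_fold), "fold")
  list(per_fold = per_fold,
       mean = vapply(per_fold[metrics], mean, 0, na.rm = TRUE),
       sd = vapply(per_fold[metrics], stats::sd, 0, na.rm = TRUE))
}

#' Screening metrics from model predictions on a labeled test set
#'
#' Ranks the test rows by class-1 probability and delegates to
#' [screen_metrics()].
#'
#' @param model A `fitted_model`.
#' @param x,y Test descriptors and labels.
#' @param fractions Enrichment fractions (default 1% and 5%).
#' @param alpha BEDROC alpha.
#' @return A `screen_metrics`.
#' @export
predict_and_enrich <- function(model, x, y, fractions = c(0.01, 0.05),
                               alpha = 20) {
  p <- predict_prob(model, x)
  screen_metrics(y, p, TRUE, fractions, alpha)
}

#' Permutation importance of each descriptor
#'
#' Mean AUC drop over `n_perm` seeded permutations of each column,
#' floored at 0.
#'
#' @param model A `fitted_model`.
#' @param x,y Evaluation descriptors and labels.
#' @param n_perm Permutations per column (default 5).
#' @param seed Permutation seed.
#' @return Named numeric vector, one non-negative importance per column.
#' @export
descriptor_importance <- function(model, x, y, n_perm = 5, seed = 1L) {
  X <- .as_matrix(x)
  base <- roc_auc(y, predict_prob(model, X))
  imp <- numeric(ncol(X))
  .with_seed(seed, {
    for (j in seq_len(ncol(X))) {
      drop_j <- vapply(seq_len(n_perm), function(r) {
        Xp <- X
        Xp[, j] <- Xp[sample.int(nrow(X)), j]
        base - roc_auc(y, predict_prob(model, Xp))
      }, 0)
      imp[j] <- mean(drop_j)
    }
  })
  imp <- pmax(imp, 0)
  names(imp) <- colnames(X)
  imp
}
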