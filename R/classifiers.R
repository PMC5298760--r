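# Internal classifier wrappers shared by feature selection and spotting.
# NB and SVM go through e1071; kNN prediction is computed here because the
# package's tie-breaking rule (nearest neighbour's label decides distance and
# vote ties) must be deterministic.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fit a z-score scaler on training columns; zero-sd columns are dropped.
fit_scaler <- function(X) {
  mu <- vapply(X, mean, numeric(1))
  sd <- vapply(X, stats::sd, numeric(1))
  keep <- is.finite(sd) & sd > 0
  list(mean = mu[keep], sd = sd[keep], features = names(X)[keep])
}

apply_scaler <- function(scaler, X) {
  X <- as.matrix(X[, scaler$features, drop = FALSE])
  sweep(sweep(X, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
}

# Fit one classifier. X: data frame of feature columns; y: logical labels.
# Returns an opaque fit consumed by predict_classifier(). Distance/kernel
# methods (kNN, SVM) are fitted on z-scored features; NB on raw features.
# A single-class (or feature-free) training set yields a constant classifier.
fit_classifier <- function(kind, X, y, seed = 1L, hyper = list()) {
  X <- as.data.frame(X)
  y <- as.logical(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L || ncol(X) == 0L) {
    maj <- if (length(y) > 0) mean(y) >= 0.5 else TRUE
    return(structure(list(kind = "constant", value = maj,
                          single_class = length(unique(y)) < 2L),
                     class = "sigspot_fit"))
  }
  fit <- switch(kind,
    NB = {
      m <- e1071::naiveBayes(X, factor(y, levels = c(FALSE, TRUE)))
      # floor class-conditional sds so a feature constant within one class
      # cannot produce degenerate densities
      for (f in names(m$tables)) {
        tb <- m$tables[[f]]
        floor_sd <- max(1e-9, 1e-3 * stats::sd(X[[f]]))
        tb[, 2L] <- pmax(tb[, 2L], floor_sd)
        m$tables[[f]] <- tb
      }
      list(model = m)
    },
    kNN = {
      sc <- fit_scaler(X)
      if (length(sc$features) == 0L)
        return(fit_classifier("constant_fallback", X[, 0], y))
      list(scaler = sc, train = apply_scaler(sc, X), y = y,
           k = if (is.null(hyper$k)) 5L else as.integer(hyper$k))
    },
    SVM = {
      sc <- fit_scaler(X)
      if (length(sc$features) == 0L)
        return(fit_classifier("constant_fallback", X[, 0], y))
      Xs <- apply_scaler(sc, X)
      gamma <- if (!is.null(hyper$gamma)) hyper$gamma else {
        v <- mean((Xs - mean(Xs))^2)
        if (v > 0) 1 / (ncol(Xs) * v) else 1 / ncol(Xs)
      }
      cost <- if (is.null(hyper$cost)) 1 else hyper$cost
      m <- with_seed(seed, e1071::svm(
        Xs, factor(y, levels = c(FALSE, TRUE)), type = "C-classification",
        kernel = "radial", cost = cost, gamma = gamma, scale = FALSE))
      list(scaler = sc, model = m)
    },
    stop(sprintf("unknown classifier kind '%s'", kind)))
  structure(c(list(kind = kind, single_class = FALSE), fit),
            class = "sigspot_fit")
}

# Predict logical labels; attribute "score" carries a confidence in favour of
# TRUE (posterior for NB, vote fraction for kNN, decision value for SVM).
predict_classifier <- function(fit, X) {
  X <- as.data.frame(X)
  n <- nrow(X)
  if (n == 0L) return(structure(logical(0), score = numeric(0)))
  if (fit$kind == "constant") {
    return(structure(rep(fit$value, n), score = rep(as.numeric(fit$value), n)))
  }
  switch(fit$kind,
    NB = {
      # Gaussian log-posteriors computed directly from the fitted e1071
      # model's class-conditional tables (vectorised over rows)
      m <- fit$model
      lp <- matrix(rep(log(m$apriori / sum(m$apriori)), each = n), nrow = n)
      colnames(lp) <- names(m$apriori)
      for (f in names(m$tables)) {
        tb <- m$tables[[f]]
        for (cls in colnames(lp))
          lp[, cls] <- lp[, cls] +
            stats::dnorm(X[[f]], tb[cls, 1L], tb[cls, 2L], log = TRUE)
      }
      d <- lp[, "TRUE"] - lp[, "FALSE"]
      p <- 1 / (1 + exp(-d))
      p[!is.finite(d)] <- 0.5
      structure(p > 0.5, score = p)
    },
    kNN = {
      Xs <- apply_scaler(fit$scaler, X)
      k <- min(fit$k, nrow(fit$train))
      # squared Euclidean distance matrix (test x train), vectorised
      D <- outer(rowSums(Xs^2), rowSums(fit$train^2), "+") -
        2 * Xs %*% t(fit$train)
      votes <- integer(n)
      nearest_label <- logical(n)
      for (j in seq_len(k)) {
        # j-th nearest neighbour of every row; distance ties keep training order
        idx <- max.col(-D, ties.method = "first")
        if (j == 1L) nearest_label <- fit$y[idx]
        votes <- votes + fit$y[idx]
        D[cbind(seq_len(n), idx)] <- Inf
      }
      pred <- ifelse(votes * 2L == k, nearest_label, votes * 2L > k)
      structure(as.logical(pred), score = votes / k)
    },
    SVM = {
      Xs <- apply_scaler(fit$scaler, X)
      pr <- stats::predict(fit$model, Xs, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # orient the decision value so positive favours TRUE
      flip <- grepl("^TRUE", colnames(attr(pr, "decision.values"))[1L])
      structure(as.logical(pr), score = if (flip) dv else -dv)
    },
    stop("unknown fit kind"))
}
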