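# Quadratic discriminant analysis over the 5-D tile descriptors.
#
# The classifier is Gaussian class-conditional: per-class mean, covariance
# and empirical prior; prediction minimizes the expected 0/1 classification
# cost, which for that cost reduces to the maximum-posterior rule. Decision
# boundaries in feature space are conic sections.

#' Fit a quadratic discriminant classifier
#'
#' Estimates per-class means, covariances and empirical priors from labelled
#' feature vectors. Two covariance conventions are supported: `"per_class"`
#' (the default) divides each class's centred scatter by `N_k - 1`, the
#' textbook unbiased per-class estimate; `"total"` divides by `N - 1` (the
#' total observation count). The default is `"per_class"`: with strongly
#' imbalanced classes the total-N denominator deflates the minority-class
#' covariance by the imbalance factor and collapses its density to a needle
#' around the class mean, which destroys minority-class recall (see the
#' methods vignette).
#'
#' Singular covariances are ridge-regularized by `epsilon * I` with
#' `epsilon = 1e-6 * trace / d` (logged via a message).
#'
#' @param x numeric matrix (observations x features) or data.frame of
#'   features.
#' @param y class labels (factor or character); typically `"normal"`/`"tuft"`.
#' @param cov_mode covariance denominator convention, see above.
#' @param prior optional named prior probabilities (default: class
#'   frequencies).
#' @param cost optional K x K cost matrix `C[y, k]` (cost of predicting `y`
#'   for true class `k`); default 0/1.
#' @return object of class `oir_qda`: list with `means` (K x d), `covs`
#'   (list of d x d), `prior`, `cost`, `levels`, `cov_mode`, `n`.
#' @seealso [predict.oir_qda()]
#' @export
qda_fit <- function(x, y, cov_mode = c("per_class", "total"), prior = NULL,
                    cost = NULL) {
  cov_mode <- match.arg(cov_mode)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("non-finite features", call. = FALSE)
  y <- factor(y)
  lev <- levels(y)
  K <- length(lev)
  if (K < 2L) stop("need at least two classes", call. = FALSE)
  N <- nrow(x); d <- ncol(x)
  nk <- table(y)
  if (any(nk < 2L)) stop("every class needs at least 2 observations",
                         call. = FALSE)
  means <- matrix(NA_real_, K, d, dimnames = list(lev, colnames(x)))
  covs <- vector("list", K); names(covs) <- lev
  for (k in seq_len(K)) {
    xk <- x[y == lev[k], , drop = FALSE]
    means[k, ] <- colMeans(xk)
    cen <- sweep(xk, 2L, means[k, ])
    scatter <- crossprod(cen)
    denom <- if (cov_mode == "total") N - 1L else nrow(xk) - 1L
    S <- scatter / denom
    if (!is_pd(S)) {
      eps <- 1e-6 * sum(diag(S)) / d
      if (eps <= 0) eps <- 1e-8
      S <- S + diag(eps, d)
      message(sprintf("class '%s': singular covariance, ridge %.3g added",
                      lev[k], eps))
    }
    covs[[k]] <- (S + t(S)) / 2
  }
  if (is.null(prior)) {
    prior <- as.numeric(nk) / N
  } else {
    prior <- prior[lev] / sum(prior[lev])
  }
  names(prior) <- lev
  if (is.null(cost)) {
    cost <- matrix(1, K, K, dimnames = list(lev, lev))
    diag(cost) <- 0
  }
  structure(list(means = means, covs = covs, prior = prior, cost = cost,
                 levels = lev, cov_mode = cov_mode, n = N,
                 counts = as.integer(nk)),
            class = "oir_qda")
}

is_pd <- function(S) {
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) -1)
  all(ev > max(abs(ev)) * 1e-12) && all(ev > 0)
}

# Per-class log density of the multivariate normal, evaluated via the
# Cholesky factor (numerically stable log-space form).
qda_log_density <- function(model, x) {
  x <- matrix(x, ncol = ncol(model$means))
  K <- length(model$levels)
  out <- matrix(NA_real_, nrow(x), K, dimnames = list(NULL, model$levels))
  d <- ncol(x)
  for (k in seq_len(K)) {
    S <- model$covs[[k]]
    ch <- chol(S)
    logdet <- 2 * sum(log(diag(ch)))
    cen <- sweep(x, 2L, model$means[k, ])
    z <- backsolve(ch, t(cen), transpose = TRUE)
    maha <- colSums(z^2)
    out[, k] <- -0.5 * (d * log(2 * pi) + logdet + maha)
  }
  out
}

#' Posterior class probabilities
#'
#' `P(k | x)` proportional to the class-conditional Gaussian density times
#' the prior, normalized to sum to one; evaluated in log space so extreme
#' observations do not underflow.
#' @param model an `oir_qda` model.
#' @param x numeric vector (one observation) or matrix (rows =
#'   observations).
#' @return matrix of posteriors (rows sum to 1).
#' @export
qda_posterior <- function(model, x) {
  stopifnot(inherits(model, "oir_qda"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$means))
    stop("feature dimension mismatch", call. = FALSE)
  lp <- sweep(qda_log_density(model, x), 2L, log(model$prior), `+`)
  mx <- apply(lp, 1L, max)
  p <- exp(lp - mx)
  p / rowSums(p)
}

#' Classify observations by expected-cost minimization
#'
#' Predicts the class minimizing `sum_k P(k | x) C(y | k)`; with the default
#' 0/1 cost this is the maximum-posterior rule. Ties are broken toward
#' `"normal"` when that class exists (conservative: fewer false tufts),
#' otherwise toward the first class level.
#' @param model an `oir_qda` model.
#' @param x observation vector or matrix.
#' @return factor of predicted classes.
#' @export
qda_classify <- function(model, x) {
  post <- qda_posterior(model, x)
  expcost <- post %*% t(model$cost)   # column y: sum_k post_k * C(y|k)
  pref <- preference_order(model$levels)
  pick <- apply(expcost, 1L, function(ec) {
    cand <- which(ec <= min(ec) + 1e-12)
    cand[order(pref[cand])][1L]
  })
  factor(model$levels[pick], levels = model$levels)
}

preference_order <- function(lev) {
  pref <- seq_along(lev) + 1L
  if ("normal" %in% lev) pref[lev == "normal"] <- 0L
  pref
}

#' @export
#' @param object,x an `oir_qda` model.
#' @param newdata observations to predict.
#' @param type `"class"` for labels, `"posterior"` for probabilities.
#' @param ... unused.
#' @rdname qda_fit
predict.oir_qda <- function(object, newdata,
                            type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  if (type == "class") qda_classify(object, newdata)
  else qda_posterior(object, newdata)
}

#' @export
print.oir_qda <- function(x, ...) {
  cat(sprintf("Quadratic discriminant model (%d features, %d classes, n = %d)\n",
              ncol(x$means), length(x$levels), x$n))
  cat(sprintf("  covariance mode: %s\n", x$cov_mode))
  cat("  priors:", paste(sprintf("%s = %.3f", x$levels, x$prior),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.oir_qda <- function(object, ...) {
  cat("Class means:\n")
  print(round(object$means, 4))
  cat("\nCovariance determinants:\n")
  print(vapply(object$covs, det, numeric(1)))
  cat("\nPriors:\n")
  print(object$prior)
  invisible(object)
}

#' @export
#' @param nsim number of draws.
#' @param seed RNG seed.
#' @rdname qda_fit
simulate.oir_qda <- function(object, nsim = 1L, seed = NULL, ...) {
  draw <- function(n) {
    k <- sample(length(object$levels), n, replace = TRUE, prob = object$prior)
    d <- ncol(object$means)
    x <- matrix(NA_real_, n, d, dimnames = list(NULL, colnames(object$means)))
    for (kk in unique(k)) {
      idx <- which(k == kk)
      ch <- chol(object$covs[[kk]])
      z <- matrix(stats::rnorm(length(idx) * d), length(idx), d)
      x[idx, ] <- sweep(z %*% ch, 2L, object$means[kk, ], `+`)
    }
    data.frame(x, class = factor(object$levels[k], levels = object$levels))
  }
  if (is.null(seed)) draw(nsim) else withr::with_seed(seed, draw(nsim))
}

#' Persist / restore a QDA model as JSON
#'
#' @param model an `oir_qda` model.
#' @param path file path.
#' @return `qda_load` returns the restored model; `qda_save` returns `path`
#'   invisibly.
#' @export
qda_save <- function(model, path) {
  stopifnot(inherits(model, "oir_qda"))
  fn <- colnames(model$means)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(model$means)))
  obj <- list(levels = model$levels,
              feature_names = fn,
              cov_mode = model$cov_mode, n = model$n, counts = model$counts,
              prior = as.numeric(model$prior),
              means = unname(model$means),
              covs = lapply(model$covs, unname),
              cost = unname(model$cost))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname qda_save
#' @export
qda_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lev <- obj$levels
  means <- matrix(as.numeric(obj$means), length(lev),
                  length(obj$feature_names),
                  dimnames = list(lev, obj$feature_names))
  covs <- lapply(obj$covs, function(m) {
    m <- as.matrix(m); dimnames(m) <- NULL; m
  })
  names(covs) <- lev
  prior <- as.numeric(obj$prior); names(prior) <- lev
  cost <- as.matrix(obj$cost); dimnames(cost) <- list(lev, lev)
  structure(list(means = means, covs = covs, prior = prior, cost = cost,
                 levels = lev, cov_mode = obj$cov_mode, n = obj$n,
                 counts = obj$counts),
            class = "oir_qda")
}
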