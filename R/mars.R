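# Additive multivariate adaptive regression splines (MARS).
#
# Forward pass: greedily add reflected hinge pairs max(0, x - t) /
# max(0, t - x) with candidate knots at observed predictor values,
# stopping when the relative RSS improvement drops below `thresh` or the
# term budget is reached. Backward pass: prune basis columns one at a time,
# keeping the subset minimising the generalized cross-validation score
# GCV = (RSS/n) / (1 - C/n)^2 with effective complexity
# C = k + penalty * (k - 1) / 2 (k = columns including the intercept).
# Degree is fixed at 1: additive models, no interactions.

hinge_basis <- function(x, terms) {
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  B <- matrix(1, n, 1)
  if (nrow(terms)) {
    cols <- map(seq_len(nrow(terms)), function(i) {
      v <- x[, terms$variable[i]]
      if (terms$dir[i] > 0) pmax(0, v - terms$knot[i]) else pmax(0, terms$knot[i] - v)
    })
    B <- cbind(B, do.call(cbind, cols))
  }
  B
}

gcv_score <- function(rss, n, k, penalty) {
  C <- k + penalty * (k - 1) / 2
  if (C >= n) return(Inf)
  (rss / n) / (1 - C / n)^2
}

#' Fit an additive MARS model
#'
#' @param x Numeric matrix or data frame of predictors (one column per
#'   feature).
#' @param y Numeric response (here: per-pair log2 TE fold change).
#' @param degree Interaction degree; only 1 (additive) is supported.
#' @param penalty GCV complexity penalty per knot (default 2).
#' @param thresh Forward-pass termination: stop when the R-squared gain of
#'   the best candidate falls below this (default 0.001).
#' @param max_terms Maximum basis columns including the intercept (default
#'   `min(21, 2 * ncol(x) + 1)`).
#' @return An object of class `iso_mars`: list with `terms` (tibble:
#'   `variable`, `knot`, `dir`, `coef`), `intercept`, `r_squared`, `rss`,
#'   `gcv`, `gcv_unpruned`, `n`, `y_mean`.
#' @export
mars_fit <- function(x, y, degree = 1, penalty = 2, thresh = 0.001,
                     max_terms = NULL) {
  if (degree != 1) abort("only additive models (degree = 1) are supported")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n <= 10L) abort("need more than 10 observations")
  if (length(y) != n || anyNA(x) || anyNA(y)) abort("x/y must be complete and conformable")
  max_terms <- max_terms %||% min(21L, 2L * ncol(x) + 1L)

  ybar <- mean(y)
  tss <- sum((y - ybar)^2)
  empty <- tibble(variable = character(), knot = double(), dir = integer(),
                  coef = double())
  intercept_model <- function() {
    structure(list(terms = empty, intercept = ybar, r_squared = 0,
                   rss = tss, gcv = gcv_score(tss, n, 1, penalty),
                   gcv_unpruned = gcv_score(tss, n, 1, penalty),
                   n = n, y_mean = ybar, columns = colnames(x)),
              class = "iso_mars")
  }
  if (tss < 1e-12) return(intercept_model())

  # forward pass with orthogonalised candidate scoring
  terms <- empty
  B <- matrix(1 / sqrt(n), n, 1)    # orthonormal basis (Q)
  resid <- y - ybar
  rss <- tss
  repeat {
    if (nrow(terms) + 2L + 1L > max_terms) break
    best <- list(gain = 0)
    for (v in colnames(x)) {
      xv <- x[, v]
      knots <- sort(unique(xv))
      if (length(knots) < 2L) next
      H1 <- pmax(outer(xv, knots, "-"), 0)           # h(x - t)
      H2 <- H1 - outer(xv, knots, "-")               # h(t - x)
      R1 <- H1 - B %*% crossprod(B, H1)
      R2 <- H2 - B %*% crossprod(B, H2)
      a11 <- colSums(R1^2); a22 <- colSums(R2^2); a12 <- colSums(R1 * R2)
      b1 <- as.numeric(crossprod(R1, resid)); b2 <- as.numeric(crossprod(R2, resid))
      det <- a11 * a22 - a12^2
      scale <- pmax(a11, 1e-12) * pmax(a22, 1e-12)
      ok2 <- det > 1e-10 * scale
      gain2 <- ifelse(ok2, (b1^2 * a22 - 2 * b1 * b2 * a12 + b2^2 * a11) / det, 0)
      gain1 <- pmax(ifelse(a11 > 1e-12, b1^2 / a11, 0),
                    ifelse(a22 > 1e-12, b2^2 / a22, 0))
      gain <- pmax(gain2, gain1)
      k_best <- which.max(gain)
      if (gain[k_best] > best$gain) {
        best <- list(gain = gain[k_best], variable = v, knot = knots[k_best])
      }
    }
    if (is.null(best$variable) || best$gain / tss < thresh) break
    new_terms <- tibble(variable = best$variable, knot = best$knot,
                        dir = c(1L, -1L), coef = NA_real_)
    cand <- bind_rows(terms, new_terms)
    Bfull <- hinge_basis(x, cand)
    qrf <- qr(Bfull)
    if (qrf$rank < ncol(Bfull)) {
      # keep only the independent hinge of the pair
      for (d in c(1L, -1L)) {
        cand1 <- bind_rows(terms, new_terms[new_terms$dir == d, ])
        Bf <- hinge_basis(x, cand1)
        qf <- qr(Bf)
        if (qf$rank == ncol(Bf)) { cand <- cand1; Bfull <- Bf; qrf <- qf; break }
      }
      if (qrf$rank < ncol(Bfull)) break
    }
    fit <- qr.fitted(qrf, y)
    new_rss <- sum((y - fit)^2)
    if ((rss - new_rss) / tss < thresh) break
    terms <- cand
    rss <- new_rss
    B <- qr.Q(qrf)
    resid <- y - fit
  }

  if (!nrow(terms)) return(intercept_model())
  gcv_unpruned <- gcv_score(rss, n, nrow(terms) + 1L, penalty)

  # backward pruning
  eval_subset <- function(idx) {
    Bf <- hinge_basis(x, terms[idx, , drop = FALSE])
    f <- lm.fit(Bf, y)
    sum(f$residuals^2)
  }
  current <- seq_len(nrow(terms))
  best_sets <- list(list(idx = current, rss = rss,
                         gcv = gcv_score(rss, n, length(current) + 1L, penalty)))
  while (length(current) > 0L) {
    rss_drop <- vapply(seq_along(current), function(i)
      eval_subset(current[-i]), numeric(1))
    i_best <- which.min(rss_drop)
    current <- current[-i_best]
    best_sets[[length(best_sets) + 1L]] <- list(
      idx = current, rss = rss_drop[i_best],
      gcv = gcv_score(rss_drop[i_best], n, length(current) + 1L, penalty))
  }
  gcvs <- vapply(best_sets, `[[`, numeric(1), "gcv")
  pick <- best_sets[[which.min(gcvs)]]
  terms <- terms[pick$idx, , drop = FALSE]
  Bf <- hinge_basis(x, terms)
  f <- lm.fit(Bf, y)
  co <- f$coefficients
  co[is.na(co)] <- 0
  rss <- sum(f$residuals^2)
  if (nrow(terms)) terms$coef <- co[-1]
  structure(list(terms = terms, intercept = co[1],
                 r_squared = 1 - rss / tss, rss = rss,
                 gcv = gcv_score(rss, n, nrow(terms) + 1L, penalty),
                 gcv_unpruned = gcv_unpruned, n = n, y_mean = ybar,
                 columns = colnames(x)),
            class = "iso_mars")
}

#' @export
predict.iso_mars <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) colnames(x) <- object$columns
  missing <- setdiff(unique(object$terms$variable), colnames(x))
  if (length(missing)) abort(paste0("newdata lacks predictors: ", paste(missing, collapse = ", ")))
  B <- hinge_basis(x, object$terms)
  as.numeric(B %*% c(object$intercept, object$terms$coef))
}

#' @export
print.iso_mars <- function(x, ...) {
  cat(sprintf("Additive MARS model: %d hinge terms, R^2 = %.3f, GCV = %.4g\n",
              nrow(x$terms), x$r_squared, x$gcv))
  if (nrow(x$terms)) {
    lab <- ifelse(x$terms$dir > 0,
                  sprintf("h(%s - %.3g)", x$terms$variable, x$terms$knot),
                  sprintf("h(%.3g - %s)", x$terms$knot, x$terms$variable))
    print(tibble(term = lab, coef = x$terms$coef))
  }
  invisible(x)
}

#' Per-feature variance decomposition via single-feature and cumulative models
#'
#' Fits a MARS model per feature (group) to get individual variance
#' explained, orders features by descending individual contribution, then
#' fits models on growing feature sets to get cumulative contributions and
#' their successive differences.
#'
#' @param x Predictor matrix/data frame.
#' @param y Response.
#' @param groups Optional named list mapping a feature label to the column
#'   names it spans (e.g. all significant hexamer indicators as one
#'   feature); unlisted columns form singleton groups.
#' @param ... Passed to [mars_fit()].
#' @return Tibble: `feature`, `individual`, `cumulative`, `delta`.
#' @export
variance_decomposition <- function(x, y, groups = NULL, ...) {
  x <- as.data.frame(x)
  groups <- groups %||% setNames(as.list(names(x)), names(x))
  extra <- setdiff(names(x), unlist(groups))
  for (e in extra) groups[[e]] <- e
  if (length(groups) < 2L) abort("need at least 2 features to decompose")
  indiv <- vapply(groups, function(cols)
    mars_fit(x[, cols, drop = FALSE], y, ...)$r_squared, numeric(1))
  ord <- order(indiv, decreasing = TRUE)
  cum <- numeric(length(ord))
  sel <- character(0)
  for (i in seq_along(ord)) {
    sel <- c(sel, groups[[ord[i]]])
    cum[i] <- mars_fit(x[, sel, drop = FALSE], y, ...)$r_squared
  }
  tibble(feature = names(groups)[ord],
         individual = unname(indiv[ord]),
         cumulative = cum,
         delta = c(cum[1], diff(cum)))
}

#' Repeated k-fold cross-validated variance explained
#'
#' Random fold assignments per repeat; the held-out variance explained is
#' pooled over folds: 1 - SS_res / SS_tot with predictions collected across
#' all folds of a repeat.
#'
#' @param x Predictors, `y` response.
#' @param y Numeric response.
#' @param folds Number of folds (default 10).
#' @param repeats Number of random partitions (default 100).
#' @param seed Integer seed.
#' @param ... Passed to [mars_fit()].
#' @return Tibble with one row per repeat: `repeat_id`, `r_squared`; the
#'   mean is attached as attribute `"mean"`.
#' @export
mars_cv <- function(x, y, folds = 10, repeats = 100, seed = 1L, ...) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (folds > n) abort("more folds than observations")
  set.seed(seed)
  out <- vapply(seq_len(repeats), function(rep_i) {
    fold <- sample(rep(seq_len(folds), length.out = n))
    pred <- numeric(n)
    for (k in seq_len(folds)) {
      hold <- fold == k
      fit <- mars_fit(x[!hold, , drop = FALSE], y[!hold], ...)
      pred[hold] <- predict(fit, x[hold, , drop = FALSE])
    }
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }, numeric(1))
  res <- tibble(repeat_id = seq_len(repeats), r_squared = out)
  attr(res, "mean") <- mean(out)
  res
}
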