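#' Orthogonal projections to latent structures discriminant analysis
#'
#' Fits a two-class OPLS-DA model: the scaled data matrix is split into
#' one class-predictive latent component and `n_ortho` components
#' orthogonal to the class response. With the response encoded 0/1 and
#' centered, the predictive weight is `w = X'y / |X'y|`; each orthogonal
#' round takes the loading `p = X't / t't` of the current predictive
#' score, removes its projection on `w` (`w_o = p - (w'p / w'w) w`,
#' normalized), and deflates `X` by `t_o p_o'` with `t_o = X w_o`.
#' Because `w_o` is orthogonal to `w` (and `X'y` is invariant under the
#' deflation), every orthogonal score is exactly orthogonal to the final
#' predictive score. The predictive component is then fit on the fully
#' deflated matrix.
#'
#' Model quality: `R2Y = 1 - RSS(y)/TSS(y)` on the training response,
#' `R2X` the fraction of the scaled X sum of squares captured by the
#' predictive plus orthogonal components, and `Q2(cum) = 1 - PRESS/TSS`
#' from stratified k-fold cross-validation (the chemometrics-standard
#' 7-fold convention by default). A Q2 above 0.5 is the customary reliability bar for
#' biomarker discrimination models.
#'
#' @param x numeric matrix of feature areas, samples in rows. Scaled
#'   internally to unit variance and zero mean (training parameters are
#'   stored and reused by [predict.oplsda()]).
#' @param y two-class response: factor, character, logical or 0/1
#'   numeric. The second level is the "positive" class.
#' @param n_ortho number of orthogonal components (>= 0), or `"auto"` to
#'   pick the Q2-maximizing count in 0..3.
#' @param k cross-validation folds (default 7).
#' @param crossval compute Q2 by cross-validation (default `TRUE`).
#' @param seed seed controlling fold assignment.
#' @return an object of class `oplsda`; see Details for the components.
#'   Methods: `print`, `summary`, `coef`, `fitted`, `residuals`,
#'   `predict`, `plot`.
#' @export
oplsda <- function(x, y, n_ortho = 1L, k = 7L, crossval = TRUE, seed = 1L) {
  x <- as.matrix(x)
  enc <- encode_y(y)
  stop_if(nrow(x) != length(enc$y01), "x rows and y length differ")
  sc <- uv_scale(x)
  auto <- identical(n_ortho, "auto")
  if (auto) {
    q2s <- vapply(0:3, function(a)
      oplsda_crossval(sc$x, enc$y01, n_ortho = a, k = k, seed = seed)$q2cum,
      numeric(1))
    n_ortho <- which.max(q2s) - 1L
  }
  stop_if(!is_count(n_ortho), "n_ortho must be a non-negative integer")
  yc <- enc$y01 - mean(enc$y01)
  core <- opls_core(sc$x, yc, n_ortho)
  q2 <- if (crossval)
    oplsda_crossval(sc$x, enc$y01, n_ortho = n_ortho, k = k, seed = seed)
  else NULL
  structure(c(core, list(
    scaling = sc[c("center", "scale", "kept")],
    y_mean = mean(enc$y01), levels = enc$levels, y01 = enc$y01,
    Q2cum = q2$q2cum %||% NA_real_, cv = q2, k = k, seed = seed,
    n = nrow(x), call = match.call())), class = "oplsda")
}

encode_y <- function(y) {
  if (is.factor(y)) lev <- levels(droplevels(y))
  else lev <- sort(unique(as.vector(y)))
  stop_if(length(lev) != 2,
          "y must contain exactly 2 classes (got ", length(lev), ")")
  list(y01 = as.numeric(match(y, lev) - 1L), levels = as.character(lev))
}

# core fit on an already scaled matrix and centered response
opls_core <- function(X, yc, n_ortho) {
  w0 <- drop(crossprod(X, yc))
  nw <- sqrt(sum(w0^2))
  stop_if(nw < 1e-300, "response is orthogonal to every feature")
  w <- w0 / nw
  p_feat <- ncol(X)
  Wo <- matrix(0, p_feat, 0); Po <- matrix(0, p_feat, 0)
  To <- matrix(0, nrow(X), 0)
  Xd <- X
  for (a in seq_len(n_ortho)) {
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    wo <- p - drop(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10 * sqrt(sum(p^2))) break   # no orthogonal variation left
    wo <- wo / nwo
    to <- drop(Xd %*% wo)
    po <- drop(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  t <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t)) / sum(t^2)
  q <- sum(yc * t) / sum(t^2)
  fitted_c <- t * q
  r2y <- 1 - sum((yc - fitted_c)^2) / sum(yc^2)
  ssx <- sum(X^2)
  ss_ortho <- if (ncol(To)) sum(colSums(To^2) * colSums(Po^2)) else 0
  r2x <- (sum(t^2) * sum(p^2) + ss_ortho) / ssx
  list(weights = w, loadings = p, scores = t, y_loading = q,
       ortho_weights = Wo, ortho_loadings = Po, ortho_scores = To,
       n_ortho = ncol(To), R2X = r2x, R2Y = r2y)
}

# deflate new (scaled) data by the model's orthogonal components and
# project on the predictive weight
opls_project <- function(core, Xs) {
  To_new <- matrix(0, nrow(Xs), core$n_ortho)
  for (a in seq_len(core$n_ortho)) {
    to <- drop(Xs %*% core$ortho_weights[, a])
    Xs <- Xs - tcrossprod(to, core$ortho_loadings[, a])
    To_new[, a] <- to
  }
  list(t = drop(Xs %*% core$weights), t_ortho = To_new)
}

#' Cross-validated Q2 for an OPLS-DA model
#'
#' Stratified k-fold cross-validation on an already scaled matrix: fold
#' membership is assigned round-robin within each class after a seeded
#' shuffle, each fold's model is fit on the remaining folds (columns that
#' are constant within a training fold are dropped fold-locally), and
#' `Q2(cum) = 1 - PRESS / TSS` with PRESS summed over held-out samples.
#'
#' @param x_scaled scaled matrix (samples x features).
#' @param y01 response encoded 0/1 (or any two-class vector).
#' @param n_ortho orthogonal components of each fold model.
#' @param k folds (each must leave both classes in training).
#' @return list with `q2cum`, `press`, `tss` and the `folds` assignment.
#' @export
oplsda_crossval <- function(x_scaled, y01, n_ortho = 1L, k = 7L, seed = 1L) {
  x_scaled <- as.matrix(x_scaled)
  if (!is.numeric(y01) || !all(y01 %in% c(0, 1)))
    y01 <- encode_y(y01)$y01
  n <- length(y01)
  stop_if(k < 2, "need at least 2 folds")
  stop_if(min(table(y01)) < 2, "each class needs at least 2 samples")
  folds <- integer(n)
  with_seed(seed, {
    for (cls in unique(y01)) {
      idx <- sample(which(y01 == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  press <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    stop_if(length(unique(y01[tr])) < 2,
            "fold ", f, " leaves a single class in training; lower k")
    Xtr <- x_scaled[tr, , drop = FALSE]
    keep <- which(apply(Xtr, 2, function(col) stats::var(col) > 1e-12))
    ybar <- mean(y01[tr])
    core <- opls_core(Xtr[, keep, drop = FALSE], y01[tr] - ybar, n_ortho)
    pr <- opls_project(core, x_scaled[te, keep, drop = FALSE])
    press <- press + sum((y01[te] - (pr$t * core$y_loading + ybar))^2)
  }
  tss <- sum((y01 - mean(y01))^2)
  list(q2cum = 1 - press / tss, press = press, tss = tss, folds = folds)
}

#' Predict method for OPLS-DA models
#'
#' New samples are scaled with the training scaling parameters, deflated
#' by the model's orthogonal components, and projected on the predictive
#' weight; the class call thresholds the predicted response at 0.5.
#'
#' @param object an [oplsda] model.
#' @param newdata matrix with the training features (by column name).
#' @param ... unused.
#' @return data frame with `t_pred`, `t_ortho*` columns, `y_hat` and
#'   `class`.
#' @export
predict.oplsda <- function(object, newdata, ...) {
  Xs <- uv_apply(structure(object$scaling, class = "uv_scaling"), newdata)
  pr <- opls_project(object, Xs)
  y_hat <- pr$t * object$y_loading + object$y_mean
  out <- data.frame(t_pred = pr$t)
  if (object$n_ortho > 0) {
    to <- as.data.frame(pr$t_ortho)
    names(to) <- sprintf("t_ortho%d", seq_len(object$n_ortho))
    out <- cbind(out, to)
  }
  out$y_hat <- y_hat
  out$class <- object$levels[(y_hat > 0.5) + 1L]
  rn <- rownames(newdata)
  if (!is.null(rn) && !anyDuplicated(rn)) rownames(out) <- rn
  out
}

#' @export
fitted.oplsda <- function(object, ...)
  object$scores * object$y_loading + object$y_mean

#' @export
residuals.oplsda <- function(object, ...) object$y01 - fitted(object)

#' @export
coef.oplsda <- function(object, ...) {
  # regression vector on the scaled feature space:
  # y_hat = y_mean + Xs [prod_a (I - w_o,a p_o,a')] w q
  b <- object$weights * object$y_loading
  for (a in rev(seq_len(object$n_ortho)))
    b <- b - object$ortho_weights[, a] *
      drop(crossprod(object$ortho_loadings[, a], b))
  stats::setNames(b, object$scaling$kept)
}

#' @export
print.oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA: 1 predictive + %d orthogonal component(s), %d samples x %d features\n",
              x$n_ortho, x$n, length(x$scaling$kept)))
  cat(sprintf("  classes: %s (0) vs %s (1)\n", x$levels[1], x$levels[2]))
  cat(sprintf("  R2X = %.3f  R2Y = %.3f  Q2(cum) = %s\n", x$R2X, x$R2Y,
              if (is.na(x$Q2cum)) "not computed" else sprintf("%.3f", x$Q2cum)))
  invisible(x)
}

#' @export
summary.oplsda <- function(object, ...) {
  out <- list(
    metrics = c(R2X = object$R2X, R2Y = object$R2Y, Q2cum = object$Q2cum),
    n_ortho = object$n_ortho, n = object$n,
    p = length(object$scaling$kept), levels = object$levels,
    accuracy = mean((fitted(object) > 0.5) ==
                      (object$y01 == 1)))
  class(out) <- "summary.oplsda"
  out
}

#' @export
print.summary.oplsda <- function(x, ...) {
  cat(sprintf("OPLS-DA model summary (%d samples, %d features)\n", x$n, x$p))
  print(round(x$metrics, 4))
  cat(sprintf("orthogonal components: %d\n", x$n_ortho))
  cat(sprintf("training class accuracy: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Score plot of an OPLS-DA model
#'
#' Predictive score against the first orthogonal score (or sample index
#' when the model has no orthogonal component), with the Hotelling
#' T-squared confidence ellipse.
#'
#' @param x an [oplsda] model.
#' @param alpha ellipse significance level.
#' @param ... passed to [graphics::plot()].
#' @export
plot.oplsda <- function(x, alpha = 0.05, ...) {
  t2 <- if (x$n_ortho > 0) x$ortho_scores[, 1] else seq_along(x$scores)
  ylab <- if (x$n_ortho > 0) "t_ortho[1]" else "sample index"
  cols <- c("#1b7837", "#2166ac")[x$y01 + 1]
  graphics::plot(x$scores, t2, col = cols, pch = 19,
                 xlab = "t_pred", ylab = ylab, ...)
  if (x$n_ortho > 0) {
    el <- try(hotelling_ellipse(cbind(x$scores, t2), alpha), silent = TRUE)
    if (!inherits(el, "try-error"))
      graphics::lines(ellipse_coords(el), lty = 2, col = "grey40")
  }
  graphics::legend("topright", legend = x$levels, col = c("#1b7837", "#2166ac"),
                   pch = 19, bty = "n")
  invisible(x)
}
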