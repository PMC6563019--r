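#' Unit-variance scaling
#'
#' Mean-centers and scales every feature column to unit sample variance,
#' dropping zero-variance columns (with a message). `uv_apply()` scales
#' new data with stored training parameters, as required when projecting a
#' test set onto a trained model.
#'
#' @param x numeric matrix, samples in rows, features in columns.
#' @param tol variance below which a column counts as constant.
#' @return `uv_scale()` returns a `uv_scaling` object with elements `x`
#'   (the scaled matrix), `center`, `scale` and `kept` (column names
#'   retained); `uv_apply()` returns a scaled matrix.
#' @export
uv_scale <- function(x, tol = 1e-12) {
  x <- as.matrix(x)
  stop_if(nrow(x) < 2, "unit-variance scaling needs at least 2 samples")
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  keep <- which(sds > sqrt(tol))
  if (length(keep) < ncol(x))
    message(ncol(x) - length(keep), " zero-variance feature(s) dropped")
  stop_if(length(keep) == 0, "all features have zero variance")
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, sds[keep], `/`)
  structure(list(x = xs, center = ctr[keep], scale = sds[keep],
                 kept = colnames(x)[keep]),
            class = "uv_scaling")
}

#' @rdname uv_scale
#' @param scaling a `uv_scaling` object.
#' @param xnew new data with (at least) the training features.
#' @export
uv_apply <- function(scaling, xnew) {
  stopifnot(inherits(scaling, "uv_scaling"))
  xnew <- as.matrix(xnew)
  missing <- setdiff(scaling$kept, colnames(xnew))
  stop_if(length(missing) > 0, "features missing from new data: ",
          paste(utils::head(missing, 5), collapse = ", "),
          if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  sweep(sweep(xnew[, scaling$kept, drop = FALSE], 2, scaling$center),
        2, scaling$scale, `/`)
}

#' Principal component analysis by singular value decomposition
#'
#' Unsupervised overview of a (scaled) data matrix. Scores are the
#' projections `U %*% D`, loadings the right singular vectors, and the
#' explained-variance fractions are the squared singular values over
#' their total.
#'
#' @param x numeric matrix, samples in rows (already scaled as desired).
#' @param n_components number of components, at most `min(n-1, p)`.
#' @param center mean-center columns first (default `TRUE`).
#' @return a `glyco_pca` object: `scores`, `loadings`, `explained`,
#'   `center`.
#' @export
pca_fit <- function(x, n_components = 2L, center = TRUE) {
  x <- as.matrix(x)
  stop_if(nrow(x) < 2 || ncol(x) < 1, "degenerate input matrix")
  stop_if(n_components < 1 || n_components > min(nrow(x) - 1, ncol(x)),
          "n_components must lie in 1..min(samples-1, features)")
  ctr <- if (center) colMeans(x) else rep(0, ncol(x))
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(rownames(x), sprintf("PC%d", seq_len(n_components)))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(x), colnames(scores))
  structure(list(scores = scores, loadings = loadings,
                 explained = sv$d^2 / sum(sv$d^2), center = ctr),
            class = "glyco_pca")
}

#' @export
print.glyco_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("PCA: %d components, explained variance %s\n", k,
              paste(sprintf("%.1f%%", 100 * x$explained[seq_len(k)]),
                    collapse = " / ")))
  invisible(x)
}

#' Class-stratified train/test split
#'
#' Randomly assigns each class's study samples to a training and a test
#' set. The per-class training count is `round(fraction * class size)`
#' unless explicit `counts` are supplied (useful when a published design
#' fixes the counts outright).
#'
#' @param classes named character vector: `sample_id -> class label`
#'   (study samples only).
#' @param fraction training fraction in (0, 1); exactly 0 or 1 is
#'   rejected since both sets must hold both classes.
#' @param seed RNG seed for the selection.
#' @param counts optional named integer vector of per-class training
#'   counts overriding `fraction`.
#' @return a `split_spec`: list with `train` and `test` sample ids.
#' @export
make_split <- function(classes, fraction = 0.8, seed = 1L, counts = NULL) {
  stop_if(!is.numeric(fraction) || fraction <= 0 || fraction >= 1,
          "fraction must lie strictly inside (0, 1)")
  cls <- split(names(classes), classes)
  stop_if(any(lengths(cls) < 2), "every class needs at least 2 members")
  with_seed(seed, {
    train <- unlist(lapply(names(cls), function(g) {
      ids <- cls[[g]]
      k <- if (!is.null(counts) && g %in% names(counts)) counts[[g]]
      else round(fraction * length(ids))
      k <- max(1L, min(length(ids) - 1L, as.integer(k)))
      sample(ids, k)
    }), use.names = FALSE)
  })
  structure(list(train = sort(train),
                 test = sort(setdiff(names(classes), train))),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("Split: %d training / %d test samples\n",
              length(x$train), length(x$test)))
  invisible(x)
}

#' Hotelling T-squared confidence ellipse for a 2-D score plot
#'
#' The classical chemometric score-plot ellipse: with `n` samples and two
#' plotted score columns, the boundary is the set of points at
#' `T2 = 2 (n - 1) / (n - 2) * F(1 - alpha; 2, n - 2)` Mahalanobis
#' distance (squared) from the score centroid. For large `n` the
#' squared radius approaches the chi-squared limit `qchisq(1 - alpha, 2)`.
#'
#' @param scores numeric matrix with exactly 2 columns.
#' @param alpha significance level (default 0.05 for a 95 percent
#'   confidence ellipse).
#' @return `hotelling_ellipse()` returns a `hotelling_ellipse`: `center`,
#'   `semi_axes` (major, minor), `angle` (radians, major axis vs x),
#'   `t2crit`, `cov`; `ellipse_coords()` returns an `n_points` x 2 matrix
#'   tracing the boundary.
#' @export
hotelling_ellipse <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  stop_if(ncol(scores) != 2, "scores must have exactly 2 columns")
  n <- nrow(scores)
  stop_if(n < 3, "need at least 3 samples")
  S <- stats::cov(scores)
  eg <- eigen(S, symmetric = TRUE)
  stop_if(min(eg$values) <= 1e-12 * max(eg$values),
          "singular score covariance; ellipse undefined")
  t2crit <- 2 * (n - 1) / (n - 2) * stats::qf(1 - alpha, 2, n - 2)
  structure(list(center = colMeans(scores),
                 semi_axes = sqrt(eg$values * t2crit),
                 angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
                 alpha = alpha, t2crit = t2crit, cov = S, n = n),
            class = "hotelling_ellipse")
}

#' @rdname hotelling_ellipse
#' @param ellipse a `hotelling_ellipse`.
#' @param n_points points on the returned boundary polygon.
#' @export
ellipse_coords <- function(ellipse, n_points = 200L) {
  stopifnot(inherits(ellipse, "hotelling_ellipse"))
  th <- seq(0, 2 * pi, length.out = n_points)
  a <- ellipse$semi_axes[1]; b <- ellipse$semi_axes[2]
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  pts <- cbind(a * cos(th), b * sin(th)) %*% t(rot)
  sweep(pts, 2, ellipse$center, `+`)
}
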