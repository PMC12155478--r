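#' Autoscale a data matrix
#'
#' Centers every column to mean zero and scales it to unit sample standard
#' deviation — the conventional preprocessing for spectroscopic/metabolomic
#' matrices before PCA or PLS-DA, so each volatile contributes on an equal
#' footing regardless of its concentration scale. Columns without at least
#' two distinct values carry no information after scaling and are dropped
#' with a warning.
#'
#' @param m Numeric matrix or data frame, samples in rows, variables in
#'   columns. Censor missing cells to 0 before calling.
#' @return The autoscaled matrix, with `center` and `scale` attributes.
#' @export
autoscale <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) abort("matrix has missing values; impute censored cells to 0 first")
  keep <- apply(m, 2, function(x) length(unique(x)) >= 2)
  if (!any(keep)) abort("all columns are constant; nothing to scale")
  if (any(!keep)) {
    warn(paste0("dropping constant column(s): ",
                paste(colnames(m)[!keep] %||% which(!keep), collapse = ", ")))
    m <- m[, keep, drop = FALSE]
  }
  centers <- colMeans(m)
  scales <- apply(m, 2, stats::sd)
  out <- sweep(sweep(m, 2, centers, "-"), 2, scales, "/")
  attr(out, "center") <- centers
  attr(out, "scale") <- scales
  out
}

# flip each column so its largest-magnitude entry is positive
# (ties broken by lowest row index) -- reproducible sign convention
fix_signs <- function(v) {
  apply(v, 2, function(col) {
    i <- which.max(abs(col))  # which.max returns the first maximum
    if (col[i] < 0) -col else col
  })
}

#' Principal component analysis
#'
#' PCA of a samples × variables matrix via singular value decomposition of
#' the column-centered data. Scores are the centered data projected on the
#' loadings; explained variance fractions are the eigenvalue ratios of the
#' covariance matrix. Loading columns follow a fixed sign convention (the
#' largest-magnitude entry of each column is positive) so results are
#' reproducible; loadings are otherwise defined only up to sign.
#'
#' @param m Numeric matrix or data frame (rows = samples). Apply
#'   [autoscale()] first for unit-variance PCA.
#' @param k Number of components to keep; must not exceed the matrix rank.
#' @return An object of class `pca_model` with elements `scores` (n × k),
#'   `loadings` (p × k, orthonormal columns), `explained_variance`
#'   (fractions), `center`, and `k`.
#' @seealso [tidy.pca_model()], [autoplot.pca_model()]
#' @export
pca_fit <- function(m, k = 2) {
  m <- as.matrix(m)
  centers <- colMeans(m)
  x <- sweep(m, 2, centers, "-")
  dec <- svd(x)
  tol <- max(dim(x)) * max(dec$d) * .Machine$double.eps
  rank <- sum(dec$d > tol)
  if (k > rank) {
    abort(paste0("k = ", k, " exceeds the matrix rank (", rank, ")"))
  }
  loadings <- fix_signs(dec$v[, seq_len(k), drop = FALSE])
  rownames(loadings) <- colnames(m)
  colnames(loadings) <- paste0("PC", seq_len(k))
  scores <- x %*% loadings
  rownames(scores) <- rownames(m)
  eig <- dec$d^2
  structure(
    list(
      scores = scores,
      loadings = loadings,
      explained_variance = (eig / sum(eig))[seq_len(k)],
      center = centers,
      k = k
    ),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", nrow(x$scores), "samples,", nrow(x$loadings), "variables,",
      x$k, "components\n")
  cat("explained variance (%):",
      paste(sprintf("%.1f", 100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn pca_fit Tidy scores or loadings into a long tibble
#'   (`matrix = "scores"`, `"loadings"`, or `"eigenvalues"`).
#' @param x A `pca_model`.
#' @param matrix Which quantity to tidy.
#' @param ... Unused.
#' @method tidy pca_model
#' @export
tidy.pca_model <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- arg_match(matrix)
  if (matrix == "eigenvalues") {
    return(tibble::tibble(
      component = seq_len(x$k),
      explained_variance = x$explained_variance,
      cumulative = cumsum(x$explained_variance)
    ))
  }
  m <- x[[matrix]]
  id_col <- if (matrix == "scores") "sample" else "variable"
  out <- tibble::as_tibble(m, rownames = id_col)
  tidyr::pivot_longer(out, -dplyr::all_of(id_col),
                      names_to = "component", values_to = "value")
}

#' @method glance pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_variables = nrow(x$loadings),
    k = x$k,
    total_explained = sum(x$explained_variance)
  )
}

#' Agglomerative hierarchical clustering
#'
#' Euclidean-distance agglomeration with Ward, average, or complete
#' linkage, for sample dendrograms of volatile profiles. Ward linkage uses
#' the squared-distance Lance–Williams update (heights on the original
#' distance scale), so merging two identical rows occurs at height 0.
#'
#' @param m Numeric matrix or data frame (rows = samples, ≥ 2 rows).
#' @param metric Distance metric; only `"euclidean"`.
#' @param linkage `"ward"`, `"average"`, or `"complete"`.
#' @return An object of class `hca_tree`: `merge` (n−1 × 2, `hclust`
#'   convention), `height` (non-decreasing), `order` (leaf order),
#'   `labels`, `linkage`, and the underlying `hclust` object.
#' @export
hca_fit <- function(m, metric = "euclidean", linkage = c("ward", "average", "complete")) {
  metric <- arg_match(metric)
  linkage <- arg_match(linkage)
  m <- as.matrix(m)
  if (nrow(m) < 2) abort("need at least 2 rows to cluster")
  d <- stats::dist(m, method = metric)
  hc <- stats::hclust(d, method = switch(linkage,
    ward = "ward.D2", average = "average", complete = "complete"
  ))
  structure(
    list(merge = hc$merge, height = hc$height, order = hc$order,
         labels = hc$labels %||% rownames(m), linkage = linkage, hclust = hc),
    class = "hca_tree"
  )
}

#' @export
print.hca_tree <- function(x, ...) {
  cat("HCA tree (", x$linkage, " linkage): ", length(x$height) + 1,
      " leaves\n", sep = "")
  invisible(x)
}

#' @method tidy hca_tree
#' @export
tidy.hca_tree <- function(x, ...) {
  tibble::tibble(
    merge_a = x$merge[, 1],
    merge_b = x$merge[, 2],
    height = x$height
  )
}

# one-hot class membership matrix, columns in factor-level order
one_hot <- function(classes) {
  f <- factor(classes)
  if (nlevels(f) < 2) abort("need at least 2 classes")
  y <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  y[cbind(seq_along(f), as.integer(f))] <- 1
  y
}

#' Partial least squares–discriminant analysis via NIPALS
#'
#' Fits a PLS2 model of the (optionally autoscaled) data matrix against the
#' centered one-hot class membership matrix using the NIPALS algorithm:
#' for each component, the weight vector `w` is iterated to convergence
#' (relative change < `tol`), scores `t = X w`, X-loadings
#' `p = X't / t't`, Y-loadings `q = Y't / t't`, and both blocks are
#' deflated by the rank-one component before the next one is extracted.
#' Weight vectors are unit-norm and score vectors mutually orthogonal.
#'
#' @param x Samples × variables matrix or data frame.
#' @param classes Class label per row (factor or character); ≥ 2 classes.
#' @param n_components Number of latent components `A`; defaults to
#'   (number of classes − 1), the rank bound of the centered one-hot
#'   response.
#' @param center,scale. Column preprocessing of `x`; autoscaling
#'   (`scale. = TRUE`) is the default, matching standard chemometrics
#'   practice for concentration matrices.
#' @param tol NIPALS convergence tolerance on the weight vector (1e-10).
#' @param max_iter Maximum NIPALS iterations per component (default
#'   10000; balanced multi-class designs can have nearly tied leading
#'   covariance directions, making the power-iteration convergence slow);
#'   non-convergence is an error reporting the iteration count.
#' @return An object of class `plsda_model` with matrices `weights`
#'   (p × A), `scores` (n × A), `x_loadings` (p × A), `y_loadings`
#'   (classes × A), the `classes` factor, `vip` (named vector, see
#'   [vip_scores()]), and bookkeeping (`center`, `scale`,
#'   `explained_x_variance`).
#' @seealso [vip_scores()], [select_markers()], [autoplot.plsda_model()]
#' @export
plsda_fit <- function(x, classes, n_components = NULL, center = TRUE,
                      scale. = TRUE, tol = 1e-10, max_iter = 10000) {
  x <- as.matrix(x)
  f <- factor(classes)
  if (nrow(x) != length(f)) abort("length(classes) must match nrow(x)")
  y <- one_hot(f)
  n_components <- n_components %||% (nlevels(f) - 1L)

  centers <- if (center) colMeans(x) else rep(0, ncol(x))
  scales <- if (isTRUE(scale.)) apply(x, 2, stats::sd) else rep(1, ncol(x))
  if (any(scales == 0)) {
    abort("constant column(s) in x; drop them (see autoscale()) before fitting")
  }
  e <- sweep(sweep(x, 2, centers, "-"), 2, scales, "/")
  fmat <- sweep(y, 2, colMeans(y), "-")

  total_ssx <- sum(e^2)
  p_vars <- ncol(e)
  W <- P <- matrix(0, p_vars, n_components,
                   dimnames = list(colnames(x), paste0("LV", seq_len(n_components))))
  Tm <- matrix(0, nrow(e), n_components,
               dimnames = list(rownames(x), paste0("LV", seq_len(n_components))))
  Q <- matrix(0, ncol(y), n_components,
              dimnames = list(colnames(y), paste0("LV", seq_len(n_components))))
  expl_x <- numeric(n_components)

  for (a in seq_len(n_components)) {
    u <- fmat[, which.max(apply(fmat, 2, stats::var))]
    w <- rep(0, p_vars)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w_new <- drop(crossprod(e, u))
      nw <- sqrt(sum(w_new^2))
      if (nw < .Machine$double.eps) {
        abort(paste0("NIPALS collapsed at component ", a,
                     ": X carries no remaining covariance with the classes"))
      }
      w_new <- w_new / nw
      t_vec <- drop(e %*% w_new)
      q_vec <- drop(crossprod(fmat, t_vec)) / sum(t_vec^2)
      u <- drop(fmat %*% q_vec) / sum(q_vec^2)
      if (sqrt(sum((w_new - w)^2)) < tol) {
        w <- w_new
        converged <- TRUE
        break
      }
      w <- w_new
    }
    if (!converged) {
      abort(paste0("NIPALS did not converge for component ", a,
                   " after ", max_iter, " iterations"))
    }
    # sign convention: largest-magnitude weight entry positive
    i_max <- which.max(abs(w))
    flip <- if (w[i_max] < 0) -1 else 1
    w <- flip * w
    t_vec <- drop(e %*% w)
    p_vec <- drop(crossprod(e, t_vec)) / sum(t_vec^2)
    q_vec <- drop(crossprod(fmat, t_vec)) / sum(t_vec^2)
    e <- e - tcrossprod(t_vec, p_vec)
    fmat <- fmat - tcrossprod(t_vec, q_vec)
    W[, a] <- w
    Tm[, a] <- t_vec
    P[, a] <- p_vec
    Q[, a] <- q_vec
    expl_x[a] <- sum(t_vec^2) * sum(p_vec^2) / total_ssx
  }

  model <- structure(
    list(weights = W, scores = Tm, x_loadings = P, y_loadings = Q,
         classes = f, n_components = n_components,
         center = centers, scale = scales,
         explained_x_variance = expl_x),
    class = "plsda_model"
  )
  model$vip <- vip_scores(model)
  model
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("PLS-DA model:", nrow(x$scores), "samples,", nrow(x$weights),
      "variables,", nlevels(x$classes), "classes,", x$n_components,
      "components\n")
  cat("X variance explained (%):",
      paste(sprintf("%.1f", 100 * x$explained_x_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy plsda_model
#' @export
tidy.plsda_model <- function(x, matrix = c("vip", "scores", "weights", "x_loadings"), ...) {
  matrix <- arg_match(matrix)
  if (matrix == "vip") {
    return(tibble::tibble(compound = names(x$vip), vip = unname(x$vip)))
  }
  m <- x[[matrix]]
  id_col <- if (matrix == "scores") "sample" else "variable"
  out <- tibble::as_tibble(m, rownames = id_col)
  tidyr::pivot_longer(out, -dplyr::all_of(id_col),
                      names_to = "component", values_to = "value")
}

#' @method glance plsda_model
#' @export
glance.plsda_model <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_variables = nrow(x$weights),
    n_classes = nlevels(x$classes),
    n_components = x$n_components,
    explained_x_variance = sum(x$explained_x_variance)
  )
}

#' Variable importance in projection (VIP)
#'
#' Per-variable contribution to a PLS-DA model, pooled over all response
#' columns and latent components:
#' \deqn{VIP_j = \sqrt{p \, \frac{\sum_a SSY_a (w_{ja}/\|w_a\|)^2}{\sum_a SSY_a}},
#' \quad SSY_a = (q_a' q_a)(t_a' t_a),}
#' with p variables. The squared scores average 1
#' (\eqn{\sum_j VIP_j^2 = p}), so VIP > 1 flags variables contributing
#' more than an average share to class discrimination.
#'
#' @param model A fitted [plsda_fit()] model.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  w <- model$weights
  ssy <- colSums(model$y_loadings^2) * colSums(model$scores^2)
  if (sum(ssy) <= 0) abort("zero total explained response variance")
  wn2 <- sweep(w^2, 2, colSums(w^2), "/")
  vip <- sqrt(nrow(w) * drop(wn2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(w)
  vip
}
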