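feature_columns <- c(
  "pct_simple", "pct_complex", "pct_small", "pct_large",
  "median_mci", "median_volume", "volume_density_pct",
  "nanotunnels_per_100")

#' Assemble the morphological feature matrix
#'
#' One row per individual, the eight fixed morphological features
#' (percent simple / complex / small / large, median MCI and volume,
#' volume density, nanotunnels per 100 mitochondria), with aligned group
#' labels.
#'
#' @param summaries per-individual data.frame from [cohort_summaries()]
#'   (must contain `subject_id`, `group` and the eight feature columns).
#' @return list with `x` (numeric matrix, rownames = subject ids) and
#'   `group` (factor).
#' @export
assemble_features <- function(summaries) {
  if (anyDuplicated(summaries$subject_id))
    stop("duplicated subject_id", call. = FALSE)
  for (f in feature_columns) {
    v <- summaries[[f]]
    if (is.null(v) || anyNA(v))
      stop("missing feature: ", f, call. = FALSE)
  }
  x <- as.matrix(summaries[, feature_columns])
  rownames(x) <- summaries$subject_id
  list(x = x, group = factor(summaries$group))
}

#' PLS-DA via NIPALS
#'
#' Partial least-squares discriminant analysis: the group membership is
#' one-hot encoded and a PLS2 model is fit by the NIPALS algorithm on
#' autoscaled (centered, unit-variance) features. The algorithm is
#' deterministic for a fixed input; no randomness is involved.
#'
#' @param x numeric matrix (individuals x features) or the result of
#'   [assemble_features()].
#' @param group group labels (ignored if `x` came from
#'   [assemble_features()], which carries them).
#' @param n_components number of latent components (default 2).
#' @param scale autoscale columns (default TRUE); zero-variance columns
#'   are dropped with a warning.
#' @param max_iter,tol NIPALS iteration controls.
#' @return object of class `plsda_model`: weights `W`, X-loadings `P`,
#'   Y-loadings `Q`, scores `T`, per-component explained X- and
#'   Y-variance, column centers/scales, group centroids in score space.
#' @export
plsda_fit <- function(x, group = NULL, n_components = 2, scale = TRUE,
                      max_iter = 500, tol = 1e-10) {
  if (is.list(x) && !is.null(x$x)) { group <- x$group; x <- x$x }
  x <- as.matrix(x)
  group <- factor(group)
  if (nrow(x) != length(group)) stop("x rows must match group labels",
                                     call. = FALSE)
  if (any(table(group) < 2))
    stop("need at least 2 individuals per group", call. = FALSE)
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  if (scale && any(sdev == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(x)[sdev == 0], collapse = ", "),
            call. = FALSE)
    keep <- sdev > 0
    x <- x[, keep, drop = FALSE]
    mu <- mu[keep]; sdev <- sdev[keep]
  }
  if (!scale) sdev <- rep(1, ncol(x))
  E <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  Y <- stats::model.matrix(~ group - 1)
  colnames(Y) <- levels(group)
  Fm <- sweep(Y, 2, colMeans(Y))
  ssx_tot <- sum(E^2); ssy_tot <- sum(Fm^2)
  p <- ncol(E)
  W <- P <- matrix(0, p, n_components)
  Q <- matrix(0, ncol(Y), n_components)
  Tm <- matrix(0, nrow(E), n_components)
  ssx <- ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- Fm[, which.max(colSums(Fm^2))]
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(E, u))
      wn <- sqrt(sum(w^2))
      if (wn < 1e-12) {
        # X carries no covariance with Y (e.g. perfectly confounded
        # labels): fall back to the leading X direction, which yields a
        # zero Y-loading and zero explained Y-variance
        w <- svd(E)$v[, 1]
      } else {
        w <- w / wn
      }
      tt <- drop(E %*% w)
      q <- drop(crossprod(Fm, tt)) / sum(tt^2)
      if (sum(q^2) < 1e-15) break
      u_new <- drop(Fm %*% q) / sum(q^2)
      if (sum((u_new - u)^2) < tol * max(sum(u^2), 1e-300)) {
        u <- u_new
        break
      }
      u <- u_new
    }
    pl <- drop(crossprod(E, tt)) / sum(tt^2)
    E <- E - tcrossprod(tt, pl)
    Fhat <- tcrossprod(tt, q)
    Fm <- Fm - Fhat
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q; Tm[, a] <- tt
    ssx[a] <- sum(tcrossprod(tt, pl)^2) / ssx_tot
    ssy[a] <- sum(Fhat^2) / ssy_tot
  }
  rownames(W) <- rownames(P) <- colnames(x)
  centroids <- apply(Tm, 2, function(s) tapply(s, group, mean))
  structure(list(
    W = W, P = P, Q = Q, scores = Tm, group = group,
    center = mu, scale = sdev, features = colnames(x),
    explained_x = ssx, explained_y = ssy,
    centroids = matrix(centroids, nrow = nlevels(group),
                       dimnames = list(levels(group), NULL)),
    n_components = n_components),
    class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf(
    "<plsda_model> %d components over %d features; cumulative explained X-variance %.1f%%, Y-variance %.1f%%\n",
    x$n_components, length(x$features), 100 * sum(x$explained_x),
    100 * sum(x$explained_y)))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP: per-feature influence weighted by each component's
#' explained Y-variance,
#' `VIP_j = sqrt(p * sum_a ssy_a w_ja^2 / sum_a ssy_a)` with unit-norm
#' weight vectors. The mean squared VIP is 1 by construction (so the sum
#' of squared VIPs equals the number of features); features scoring above
#' 1 carry above-average discriminative weight.
#'
#' @param model a [plsda_fit()] model.
#' @return data.frame sorted by decreasing VIP, with `feature`, `vip`,
#'   `above_1`.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  p <- length(model$features)
  ssy <- model$explained_y
  w2 <- model$W^2
  vip <- sqrt(p * drop(w2 %*% ssy) / sum(ssy))
  out <- data.frame(feature = model$features, vip = vip,
                    above_1 = vip > 1)
  out <- out[order(-out$vip), ]
  rownames(out) <- NULL
  out
}

#' Project new individuals and call their group
#'
#' Applies the training centering/scaling, projects onto the PLS
#' components, and assigns the nearest group centroid in score space.
#'
#' @param model a [plsda_fit()] model.
#' @param newdata matrix or data.frame with the model's feature columns.
#' @return data.frame of component scores plus `predicted_group`.
#' @export
predict_group <- function(model, newdata) {
  stopifnot(inherits(model, "plsda_model"))
  if (is.data.frame(newdata)) {
    if (!all(model$features %in% names(newdata)))
      stop("newdata lacks feature column(s): ",
           paste(setdiff(model$features, names(newdata)),
                 collapse = ", "), call. = FALSE)
    newdata <- as.matrix(newdata[, model$features, drop = FALSE])
  } else {
    newdata <- as.matrix(newdata)
    if (!is.null(colnames(newdata))) {
      if (!all(model$features %in% colnames(newdata)))
        stop("newdata lacks feature column(s): ",
             paste(setdiff(model$features, colnames(newdata)),
                   collapse = ", "), call. = FALSE)
      newdata <- newdata[, model$features, drop = FALSE]
    } else if (ncol(newdata) != length(model$features)) {
      stop("newdata must have ", length(model$features), " columns",
           call. = FALSE)
    }
  }
  E <- sweep(sweep(newdata, 2, model$center), 2, model$scale, "/")
  R <- model$W %*% solve(crossprod(model$P, model$W))
  scores <- E %*% R
  d2 <- sapply(seq_len(nrow(model$centroids)), function(g)
    rowSums(sweep(scores, 2, model$centroids[g, ])^2))
  d2 <- matrix(d2, nrow = nrow(scores))
  call <- rownames(model$centroids)[apply(d2, 1, which.min)]
  out <- as.data.frame(scores)
  names(out) <- paste0("comp", seq_len(ncol(scores)))
  out$predicted_group <- call
  out
}
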