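# Dimension reduction and cross-validated linear discriminant
# classification of shape features.

#' Principal component analysis of a feature matrix
#'
#' Centered covariance-matrix PCA (no correlation scaling: elliptical
#' Fourier coefficients are commensurate after Procrustes scaling).
#'
#' @param x Numeric matrix, observations in rows (>= 3).
#' @return Object of class `pca_model`: `rotation`, `eigenvalues`
#'   (non-increasing), `var_frac` (sums to 1), `scores`, `center`.
#' @export
pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop_invalid("need at least 3 observations")
  if (all(apply(x, 2L, stats::var) == 0))
    stop_invalid("degenerate input: all columns constant")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  structure(list(rotation = p$rotation, eigenvalues = ev,
                 var_frac = ev / sum(ev), scores = p$x, center = p$center),
            class = "pca_model")
}

#' Leading principal component scores reaching a variance threshold
#'
#' Returns the scores of the smallest leading block of components whose
#' cumulative variance fraction reaches `threshold`; the component that
#' crosses the threshold is included.
#'
#' @param model A [pca()] result.
#' @param threshold Cumulative variance fraction (default 0.90).
#' @return Score matrix (n x m).
#' @export
select_components <- function(model, threshold = 0.90) {
  stopifnot(inherits(model, "pca_model"))
  cum <- cumsum(model$var_frac)
  m <- which(cum >= threshold - 1e-12)[1L]
  model$scores[, seq_len(m), drop = FALSE]
}

#' Project new observations into an existing PC space
#'
#' @param model A [pca()] result.
#' @param x New observations (matrix or vector in the original feature
#'   space).
#' @param m Number of components (default all).
#' @return Score matrix.
#' @export
pca_project <- function(model, x, m = ncol(model$rotation)) {
  x <- rbind(x)
  sweep(x, 2L, model$center) %*% model$rotation[, seq_len(m), drop = FALSE]
}

#' Fit a multi-group linear discriminant model
#'
#' Gaussian discriminant with shared (pooled within-class) covariance.
#' Class priors default to class frequencies; `"uniform"` gives equal
#' priors.  A rank-deficient pooled covariance triggers an error unless
#' `regularize = TRUE`, in which case a small ridge
#' (`1e-8 * trace / ncol`) is added with a warning.
#'
#' @param x Numeric score matrix (observations x features).
#' @param labels Class labels (factor or character).
#' @param priors `"proportional"` (default) or `"uniform"`.
#' @param regularize Allow ridge regularization of the pooled covariance.
#' @return Object of class `lda_model`: `means` (class x feature),
#'   `cov_chol` (upper-triangular factor of the pooled covariance),
#'   `priors`, `levels`, `axes` (discriminant directions), `n`.
#' @export
lda_fit <- function(x, labels, priors = c("proportional", "uniform"),
                    regularize = FALSE) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop_invalid("need at least 2 classes")
  if (any(table(labels) < 1L)) stop_invalid("empty class")
  g <- nlevels(labels); d <- ncol(x); n <- nrow(x)
  means <- do.call(rbind, lapply(levels(labels), function(l)
    colMeans(x[labels == l, , drop = FALSE])))
  rownames(means) <- levels(labels)
  sw <- matrix(0, d, d)
  for (l in levels(labels)) {
    xi <- x[labels == l, , drop = FALSE]
    if (nrow(xi) > 1L) {
      c_ <- sweep(xi, 2L, colMeans(xi))
      sw <- sw + crossprod(c_)
    }
  }
  sw <- sw / (n - g)
  ch <- try(chol(sw), silent = TRUE)
  if (inherits(ch, "try-error") || any(diag(ch) < sqrt(.Machine$double.eps) *
                                         max(diag(ch)))) {
    if (!regularize)
      stop_invalid("pooled within-class covariance is numerically ",
                   "rank-deficient; set regularize = TRUE to add a ridge")
    warning("rank-deficient pooled covariance: ridge added", call. = FALSE)
    sw <- sw + diag(1e-8 * sum(diag(sw)) / d + 1e-12, d)
    ch <- chol(sw)
  }
  pr <- if (priors == "proportional") as.numeric(table(labels)) / n
        else rep(1 / g, g)
  # discriminant axes: eigenvectors of Sw^-1 Sb (between-class scatter)
  grand <- colMeans(x)
  sb <- matrix(0, d, d)
  for (i in seq_len(g)) {
    dm <- means[i, ] - grand
    sb <- sb + sum(labels == levels(labels)[i]) * tcrossprod(dm)
  }
  w <- backsolve(ch, forwardsolve(t(ch), sb))
  ax <- Re(eigen(w)$vectors[, seq_len(min(g - 1L, d)), drop = FALSE])
  structure(list(means = means, cov_chol = ch, priors = pr,
                 levels = levels(labels), axes = ax, n = n),
            class = "lda_model")
}

#' Class posterior probabilities under a linear discriminant model
#'
#' Linear discriminant scores
#' \eqn{\delta_c(x) = x^T \Sigma^{-1}\mu_c - \tfrac12 \mu_c^T \Sigma^{-1}
#' \mu_c + \log \pi_c} converted to posteriors by a stable softmax; rows
#' sum to 1.
#'
#' @param model An [lda_fit()] result.
#' @param x Observations (matrix or vector).
#' @return Matrix of posteriors (observations x classes).
#' @export
lda_posterior <- function(model, x) {
  x <- rbind(x)
  ch <- model$cov_chol
  # delta = x Sigma^-1 mu' - 0.5 diag(mu Sigma^-1 mu') + log prior
  minv_mu <- backsolve(ch, forwardsolve(t(ch), t(model$means)))
  lin <- x %*% minv_mu
  quad <- colSums(t(model$means) * minv_mu) / 2
  delta <- sweep(lin, 2L, quad)
  delta <- sweep(delta, 2L, log(model$priors), `+`)
  delta <- delta - apply(delta, 1L, max)
  p <- exp(delta)
  p <- p / rowSums(p)
  colnames(p) <- model$levels
  p
}

#' Classify observations with a linear discriminant model
#'
#' @param model An [lda_fit()] result.
#' @param x Observations.
#' @return Factor of predicted classes (argmax posterior).
#' @export
lda_classify <- function(model, x) {
  p <- lda_posterior(model, x)
  factor(model$levels[max.col(p, ties.method = "first")],
         levels = model$levels)
}

#' Cohen's Kappa from a confusion matrix
#'
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with expected agreement from the
#' confusion-matrix marginals.
#'
#' @param confusion Square count matrix, true classes in rows.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(confusion) {
  n <- sum(confusion)
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Leave-group-out cross-validation of a linear discriminant classifier
#'
#' Repeated random splits: each repeat assigns `train_frac` of the
#' observations to a modelling subset (unstratified by default), fits
#' [lda_fit()], and evaluates the held-out subset.  A training split that
#' misses a class is redrawn (bounded retries; the count is reported).
#'
#' @param x Score matrix.
#' @param labels Class labels; every class needs >= 2 members.
#' @param repeats Number of random splits (default 200).
#' @param train_frac Modelling fraction (default 0.80).
#' @param seed Integer seed; the report is reproducible given the seed.
#' @param priors,regularize Passed to [lda_fit()].
#' @param stratified Sample the split within classes (default `FALSE`).
#' @param max_redraw Retry cap per repeat (default 100).
#' @return Object of class `cv_report`: `accuracy` (per repeat),
#'   `mean_accuracy`, `kappa` (from the pooled confusion matrix),
#'   `confusion` (pooled, true x predicted), `redraws`, `repeats`.
#' @export
lgocv <- function(x, labels, repeats = 200L, train_frac = 0.80, seed = 1L,
                  priors = "proportional", regularize = FALSE,
                  stratified = FALSE, max_redraw = 100L) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (any(table(labels) < 2L)) stop_invalid("every class needs >= 2 members")
  n <- nrow(x)
  lev <- levels(labels)
  set.seed(seed)
  conf <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  acc <- numeric(repeats)
  redraws <- 0L
  for (r in seq_len(repeats)) {
    for (try_i in seq_len(max_redraw)) {
      tr <- if (stratified) {
        unlist(lapply(lev, function(l) {
          idx <- which(labels == l)
          sample(idx, max(1L, round(train_frac * length(idx))))
        }))
      } else sample.int(n, floor(train_frac * n))
      if (length(unique(labels[tr])) == length(lev) && length(tr) < n) break
      redraws <- redraws + 1L
    }
    te <- setdiff(seq_len(n), tr)
    fit <- lda_fit(x[tr, , drop = FALSE], labels[tr], priors = priors,
                   regularize = regularize)
    pred <- lda_classify(fit, x[te, , drop = FALSE])
    truth <- factor(labels[te], levels = lev)
    acc[r] <- mean(pred == truth)
    conf <- conf + table(truth, pred)
  }
  structure(list(accuracy = acc, mean_accuracy = mean(acc),
                 kappa = cohen_kappa(conf), confusion = conf,
                 redraws = redraws, repeats = repeats),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("LGOCV: %d repeats, mean accuracy %.3f, kappa %.3f\n",
              x$repeats, x$mean_accuracy, x$kappa))
  invisible(x)
}

#' Classify unknown specimens by averaged cross-validated posteriors
#'
#' Re-fits the discriminant model on each of `repeats` random modelling
#' subsets and averages the posterior probabilities of the unknowns across
#' the fitted models.
#'
#' @param x Score matrix of the labelled sample.
#' @param labels Class labels of `x`.
#' @param unknowns Score matrix of unknowns in the same PC space.
#' @param repeats,train_frac,seed,priors,regularize,max_redraw As [lgocv()].
#' @return Data frame: one row per unknown with per-class mean posteriors,
#'   `assigned` (argmax class) and `posterior` (its mean posterior).
#' @export
classify_unknowns <- function(x, labels, unknowns, repeats = 200L,
                              train_frac = 0.80, seed = 1L,
                              priors = "proportional", regularize = FALSE,
                              max_redraw = 100L) {
  x <- as.matrix(x)
  unknowns <- rbind(unknowns)
  labels <- factor(labels)
  lev <- levels(labels)
  n <- nrow(x)
  set.seed(seed)
  acc <- matrix(0, nrow(unknowns), length(lev), dimnames = list(NULL, lev))
  for (r in seq_len(repeats)) {
    for (try_i in seq_len(max_redraw)) {
      tr <- sample.int(n, floor(train_frac * n))
      if (length(unique(labels[tr])) == length(lev)) break
    }
    fit <- lda_fit(x[tr, , drop = FALSE], labels[tr], priors = priors,
                   regularize = regularize)
    acc <- acc + lda_posterior(fit, unknowns)
  }
  p <- acc / repeats
  j <- max.col(p, ties.method = "first")
  data.frame(p, assigned = lev[j],
             posterior = p[cbind(seq_len(nrow(p)), j)],
             check.names = FALSE)
}

#' Outline shape analysis pipeline
#'
#' The full 2D pipeline: generalized Procrustes superimposition of the
#' semilandmark outlines, elliptical Fourier coefficients of the aligned
#' outlines retaining a cumulative harmonic-power fraction, then PCA with a
#' variance threshold.  Steps run in that order; no extra first-harmonic
#' normalization is applied on top of the Procrustes scaling.
#'
#' @param outlines List of k x 2 outline matrices (equal k).
#' @param power Cumulative harmonic-power threshold (default 0.99).
#' @param pc_var Cumulative PC variance threshold (default 0.90).
#' @param n_max Harmonic cap (default `floor(k/2) - 1`).
#' @return List: `aligned` ([gpa()] fit), `n_harmonics`, `coefs` (matrix of
#'   flattened coefficients), `pca` ([pca()] model), `scores` (selected PC
#'   scores).
#' @export
outline_shape_analysis <- function(outlines, power = 0.99, pc_var = 0.90,
                                   n_max = NULL) {
  aligned <- gpa(outlines)
  k <- dim(aligned$coords)[1]
  if (is.null(n_max)) n_max <- floor(k / 2) - 1L
  n_shapes <- dim(aligned$coords)[3]
  full <- lapply(seq_len(n_shapes),
                 function(i) eft(aligned$coords[, , i], n_max))
  nh <- max(vapply(full, choose_harmonics, 0L, threshold = power))
  coefs <- t(vapply(full, eft_as_vector, numeric(4L * nh), n = nh))
  model <- pca(coefs)
  list(aligned = aligned, n_harmonics = nh, coefs = coefs, pca = model,
       scores = select_components(model, pc_var))
}
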