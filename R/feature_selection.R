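# Filter feature selection: five univariate scoring methods, top-n
# selection, and MinMax scaling of the selected features to [0, 1].

#' Score features against binary labels
#'
#' Univariate filter scores, higher = more informative:
#' \describe{
#'   \item{pearson}{absolute Pearson correlation between feature and label.}
#'   \item{fscore}{Chen-Lin F-score
#'     `((m+ - m)^2 + (m- - m)^2) / (s+^2 + s-^2)` with class-wise sample
#'     variances.}
#'   \item{chi2}{Pearson chi-square statistic of the (binned feature x
#'     class) contingency table.}
#'   \item{ig}{information gain `H(Y) - H(Y | X_binned)` (log base 2).}
#'   \item{mi}{plug-in mutual information `I(X_binned; Y)` (log base 2);
#'     numerically identical to `ig` under this estimator, kept as a
#'     separate method name.}
#' }
#' Binned methods use equal-width binning with `bins` bins over each
#' feature's observed range. Constant features score 0 under every method.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Binary labels (logical, 0/1 numeric, or two-level factor).
#' @param method One of `"pearson"`, `"chi2"`, `"ig"`, `"fscore"`, `"mi"`.
#' @param bins Number of equal-width bins for the binned methods (default 5).
#' @return Numeric vector of finite scores, one per feature (named when `X`
#'   has column names).
#' @export
score_features <- function(X, y,
                           method = c("pearson", "chi2", "ig", "fscore", "mi"),
                           bins = 5L) {
  method <- match.arg(method)
  y <- as_binary_labels(y)
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  constant <- apply(X, 2, function(x) max(x) == min(x))
  scores <- switch(method,
    pearson = {
      s <- abs(suppressWarnings(stats::cor(X, y)))[, 1]
      s[is.na(s)] <- 0
      s
    },
    fscore = {
      pos <- y == 1
      m <- colMeans(X)
      mp <- colMeans(X[pos, , drop = FALSE])
      mn <- colMeans(X[!pos, , drop = FALSE])
      vp <- apply(X[pos, , drop = FALSE], 2, stats::var)
      vn <- apply(X[!pos, , drop = FALSE], 2, stats::var)
      num <- (mp - m)^2 + (mn - m)^2
      den <- vp + vn
      # a feature constant within each class but split across classes is a
      # perfect separator; give it a huge finite score instead of Inf
      ifelse(num == 0, 0, num / pmax(den, 1e-12))
    },
    chi2 = apply(X, 2, function(x) binned_stat(x, y, bins, "chi2")),
    ig = apply(X, 2, function(x) binned_stat(x, y, bins, "mi")),
    mi = apply(X, 2, function(x) binned_stat(x, y, bins, "mi"))
  )
  scores[constant] <- 0
  scores
}

as_binary_labels <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) > 2) stop("labels must be binary")
    y <- as.integer(y == levels(y)[nlevels(y)])
  } else if (is.character(y)) {
    if (!all(y %in% c("positive", "negative"))) {
      stop("character labels must be 'positive'/'negative'")
    }
    y <- as.integer(y == "positive")
  } else {
    y <- as.integer(as.logical(y))
  }
  y
}

# Chi-square statistic or mutual information of equal-width-binned x vs y.
binned_stat <- function(x, y, bins, what) {
  if (max(x) == min(x)) return(0)
  brk <- seq(min(x), max(x), length.out = bins + 1L)
  bx <- cut(x, breaks = brk, include.lowest = TRUE)
  tab <- table(bx, y)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2) return(0)
  if (what == "chi2") {
    unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
  } else {
    n <- sum(tab)
    pxy <- tab / n
    px <- rowSums(pxy); py <- colSums(pxy)
    nz <- pxy > 0
    sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
  }
}

#' Select the top-n features by score
#'
#' @param scores Numeric vector of feature scores.
#' @param n Number of features to keep (default 160). Ties are broken by
#'   ascending feature index; `n >= length(scores)` selects everything.
#' @return Integer vector of feature indices in descending score order.
#' @export
select_top <- function(scores, n = 160L) {
  if (n < 1) stop("n must be >= 1")
  n <- min(n, length(scores))
  order(-scores, seq_along(scores))[seq_len(n)]
}

#' Fit a MinMax scaler
#'
#' Records the per-feature min and max of the fitting data, so selected
#' features can be scaled to the unit interval.
#'
#' @param X Numeric matrix (samples x features), at least one row.
#' @return Object of class `minmax_scaler` with fields `min` and `max`.
#' @export
minmax_fit <- function(X) {
  if (nrow(X) < 1) stop("cannot fit a scaler on zero rows")
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max)),
            class = "minmax_scaler")
}

#' Apply a MinMax scaler
#'
#' Scales to `(x - min) / (max - min)`; features that were constant during
#' fitting map to 0, and out-of-range values are clamped to [0, 1] so unseen
#' data cannot leave the unit hypercube.
#'
#' @param params A `minmax_scaler` from [minmax_fit()].
#' @param X Numeric matrix with the same number of columns as the fit data.
#' @return Scaled matrix, same shape as `X`.
#' @export
minmax_apply <- function(params, X) {
  stopifnot(inherits(params, "minmax_scaler"))
  if (ncol(X) != length(params$min)) {
    stop("dimension mismatch: scaler fitted on ", length(params$min),
         " features, got ", ncol(X))
  }
  rng <- params$max - params$min
  scaled <- sweep(X, 2, params$min, "-")
  scaled <- sweep(scaled, 2, ifelse(rng > 0, rng, 1), "/")
  scaled[, rng == 0] <- 0
  pmin(pmax(scaled, 0), 1)
}
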