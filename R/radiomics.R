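# Sliding-window radiomics: 6 statistical + 7x22 grey-level co-occurrence +
# 4x8 Gabor features per 11 x 11 window, averaged over an ROI.

WINDOW_SIZE <- 11L
GLCM_OFFSETS <- rbind(c(-3L, -1L), c(-1L, 0L), c(0L, 1L), c(0L, 3L),
                      c(1L, -1L), c(1L, 3L), c(2L, -2L))
GLCM_STATS <- c("energy", "entropy", "dissimilarity", "contrast",
                "inverse_difference", "correlation", "homogeneity",
                "autocorrelation", "cluster_shade", "cluster_prominence",
                "maximum_probability", "sum_of_squares", "sum_average",
                "sum_variance", "sum_entropy", "difference_variance",
                "difference_entropy", "imc1", "imc2",
                "max_correlation_coefficient", "inverse_difference_normalised",
                "inverse_difference_moment_normalised")
GABOR_WAVELENGTHS <- c(2.83, 5.66, 11.31, 22.63)
GABOR_ORIENTATIONS <- (0:7) * pi / 8

.radiomics_cache <- new.env(parent = emptyenv())

#' Names of the 192 radiomics features
#'
#' 6 statistical (central grey value and raw moments of order 1-5), 154
#' co-occurrence (7 offset vectors x 22 statistics) and 32 Gabor (4
#' wavelengths x 8 orientations at pi/8 spacing) features, in the order
#' produced by \code{\link{window_features}}.
#' @return Character vector of length 192.
#' @export
feature_names <- function() {
  stat <- c("stat_centre", paste0("stat_moment", 1:5))
  glcm <- as.vector(t(outer(
    sprintf("glcm_%d_%d", GLCM_OFFSETS[, 1], GLCM_OFFSETS[, 2]),
    GLCM_STATS, paste, sep = "_")))
  gab <- as.vector(t(outer(sprintf("gabor_w%.2f", GABOR_WAVELENGTHS),
                           sprintf("o%d", 0:7), paste, sep = "_")))
  c(stat, glcm, gab)
}

# Quantise grey levels to 1..nbins over `rng` (constant input -> bin 1).
quantise_grey <- function(x, nbins, rng = range(x)) {
  if (diff(rng) <= 0) return(array(1L, dim = dim(x) %||% length(x)))
  q <- floor((x - rng[1]) / diff(rng) * nbins) + 1L
  q[q > nbins] <- nbins
  storage.mode(q) <- "integer"
  q
}

# Pair-index cache for one window size and offset set: for each offset, the
# flat (column-major) indices of valid source/target pixels.
offset_pairs <- function(win = WINDOW_SIZE) {
  key <- paste0("pairs_", win)
  if (!is.null(.radiomics_cache[[key]])) return(.radiomics_cache[[key]])
  pairs <- apply(GLCM_OFFSETS, 1, function(off) {
    dr <- off[1]; dc <- off[2]
    rc <- expand.grid(r = seq_len(win), c = seq_len(win))
    ok <- rc$r + dr >= 1 & rc$r + dr <= win & rc$c + dc >= 1 & rc$c + dc <= win
    list(i = rc$r[ok] + (rc$c[ok] - 1L) * win,
         j = (rc$r[ok] + dr) + (rc$c[ok] + dc - 1L) * win)
  }, simplify = FALSE)
  .radiomics_cache[[key]] <- pairs
  pairs
}

# Symmetrised, normalised GLCM (as a length nbins^2 vector) for quantised
# window values `q` (flat) under precomputed pair indices.
glcm_probs <- function(q, pr, nbins) {
  codes <- q[pr$i] + nbins * (q[pr$j] - 1L)
  cnt <- tabulate(codes, nbins * nbins)
  tp <- transpose_perm(nbins)
  cnt <- cnt + cnt[tp]
  cnt / sum(cnt)
}

transpose_perm <- function(nbins) {
  key <- paste0("tperm_", nbins)
  if (is.null(.radiomics_cache[[key]])) {
    t0 <- seq_len(nbins * nbins) - 1L
    .radiomics_cache[[key]] <- (t0 %/% nbins) + nbins * (t0 %% nbins) + 1L
  }
  .radiomics_cache[[key]]
}

# The 22 Haralick-family statistics for a stack of normalised symmetric
# GLCMs (columns of P, each length nbins^2). Returns 22 x ncol(P).
glcm_stats_batch <- function(P, nbins) {
  G <- ncol(P)
  lev <- seq_len(nbins)
  I <- rep(lev, times = nbins); J <- rep(lev, each = nbins)
  adiff <- abs(I - J); d2 <- (I - J)^2; s <- I + J
  cs <- function(w) colSums(P * w)
  mu <- cs(I)                       # = mu_x = mu_y by symmetry
  m2I <- cs(I^2)
  sigma2 <- m2I - mu^2
  plogp <- P * log2(P); plogp[P == 0] <- 0
  entropy <- -colSums(plogp)
  pxmat <- rowsum(P, I)             # nbins x G marginal
  pxl <- pxmat * log2(pxmat); pxl[pxmat == 0] <- 0
  HX <- -colSums(pxl)
  psum <- rowsum(P, s)              # distribution of i + j
  psl <- psum * log2(psum); psl[psum == 0] <- 0
  sum_entropy <- -colSums(psl)
  pdiff <- rowsum(P, adiff)
  pdl <- pdiff * log2(pdiff); pdl[pdiff == 0] <- 0
  diff_entropy <- -colSums(pdl)
  m1s <- cs(s); m2s <- cs(s^2); m3s <- cs(s^3); m4s <- cs(s^4)
  da <- cs(adiff); dv <- cs(adiff^2) - da^2
  autoc <- cs(I * J)
  corr <- ifelse(sigma2 > 1e-12, (autoc - mu^2) / sigma2, 0)
  hxy1 <- 2 * HX                    # -sum p log(px py) with joint support
  imc1 <- ifelse(HX > 1e-12, (entropy - hxy1) / HX, 0)
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (2 * HX - entropy))))
  mcc <- vapply(seq_len(G), function(g) {
    px <- pxmat[, g]
    use <- which(px > 0)
    if (length(use) < 2) return(0)
    Pm <- matrix(P[, g], nbins, nbins)[use, use, drop = FALSE]
    pxu <- px[use]
    Q <- (Pm / pxu) %*% t(Pm / rep(pxu, each = length(use))) # p(i,k)p(j,k)/(px_i px_k)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }, numeric(1))
  out <- rbind(
    energy = colSums(P^2),
    entropy = entropy,
    dissimilarity = da,
    contrast = cs(d2),
    inverse_difference = cs(1 / (1 + adiff)),
    correlation = corr,
    homogeneity = cs(1 / (1 + d2)),
    autocorrelation = autoc,
    cluster_shade = m3s - 6 * mu * m2s + 12 * mu^2 * m1s - 8 * mu^3,
    cluster_prominence = m4s - 8 * mu * m3s + 24 * mu^2 * m2s -
      32 * mu^3 * m1s + 16 * mu^4,
    maximum_probability = apply(P, 2, max),
    sum_of_squares = sigma2,
    sum_average = m1s,
    sum_variance = m2s - m1s^2,
    sum_entropy = sum_entropy,
    difference_variance = dv,
    difference_entropy = diff_entropy,
    imc1 = imc1,
    imc2 = imc2,
    max_correlation_coefficient = mcc,
    inverse_difference_normalised = cs(1 / (1 + adiff / nbins)),
    inverse_difference_moment_normalised = cs(1 / (1 + d2 / nbins^2)))
  rownames(out) <- GLCM_STATS
  out
}

# Gabor filter bank as complex response matrices: each filter is a 121 x 121
# complex matrix A so that A %*% as.vector(window) gives the zero-padded
# cross-correlation response at every window position. Bandwidth 1 octave,
# aspect ratio 0.5, phase 0; kernels truncated to the analysis window.
gabor_bank <- function(win = WINDOW_SIZE) {
  key <- paste0("gabor_", win)
  if (!is.null(.radiomics_cache[[key]])) return(.radiomics_cache[[key]])
  half <- (win - 1L) / 2L
  sigma_factor <- sqrt(log(2) / 2) / pi * (2^1 + 1) / (2^1 - 1) # 1-octave bandwidth
  rc <- expand.grid(r = seq_len(win), c = seq_len(win))
  bank <- list()
  for (lam in GABOR_WAVELENGTHS) {
    sigma <- sigma_factor * lam
    for (th in GABOR_ORIENTATIONS) {
      # A[out, in] = kernel value at displacement (r_in - r_out, c_in - c_out)
      dy <- outer(rc$r, rc$r, function(a, b) b - a)
      dx <- outer(rc$c, rc$c, function(a, b) b - a)
      xp <- dx * cos(th) + dy * sin(th)
      yp <- -dx * sin(th) + dy * cos(th)
      A <- exp(-(xp^2 + 0.25 * yp^2) / (2 * sigma^2)) *
        exp(1i * 2 * pi * xp / lam)
      A[abs(dy) > half | abs(dx) > half] <- 0 + 0i
      bank[[length(bank) + 1L]] <- A
    }
  }
  .radiomics_cache[[key]] <- bank
  bank
}

# Feature matrix (192 x W) for raw windows stacked as columns of `Wraw`
# (121 x W) with quantised counterpart `Wq`.
window_feature_batch <- function(Wraw, Wq, nbins) {
  win <- WINDOW_SIZE
  W <- ncol(Wraw)
  centre_idx <- (win * win + 1L) / 2L
  mom <- matrix(vapply(1:5, function(r) colMeans(Wraw^r), numeric(W)), ncol = 5)
  stat <- rbind(Wraw[centre_idx, , drop = FALSE], t(mom))
  pairs <- offset_pairs(win)
  glcm <- matrix(NA_real_, length(pairs) * length(GLCM_STATS), W)
  for (o in seq_along(pairs)) {
    P <- vapply(seq_len(W), function(w) glcm_probs(Wq[, w], pairs[[o]], nbins),
                numeric(nbins * nbins))
    P <- matrix(P, nbins * nbins, W)
    glcm[(o - 1L) * length(GLCM_STATS) + seq_along(GLCM_STATS), ] <-
      glcm_stats_batch(P, nbins)
  }
  bank <- gabor_bank(win)
  gab <- t(matrix(vapply(bank, function(A) colMeans(Mod(A %*% Wraw)), numeric(W)),
                  nrow = W))
  out <- rbind(stat, glcm, gab)
  rownames(out) <- feature_names()
  out
}

#' Radiomics features of a single 11 x 11 window
#'
#' Computes the full 192-feature vector: the central grey value and raw
#' intensity moments of order 1-5; for each of the 7 co-occurrence offset
#' vectors a symmetrised, normalised GLCM (grey levels quantised to
#' \code{nbins}) and its 22 Haralick-family statistics; and the mean
#' response magnitude of the 32-filter Gabor bank (wavelengths 2.83, 5.66,
#' 11.31, 22.63 pixels; 8 orientations at pi/8 spacing).
#'
#' @param window Numeric 11 x 11 matrix of grey values.
#' @param nbins Grey-level bins for co-occurrence (default 32).
#' @param qrange Quantisation range (default the window's own range; ROI
#'   extraction passes the whole image's range).
#' @return Named numeric vector of length 192.
#' @export
window_features <- function(window, nbins = 32L, qrange = NULL) {
  window <- as.matrix(window)
  if (!all(dim(window) == WINDOW_SIZE))
    stopf("window must be %d x %d, got %d x %d", WINDOW_SIZE, WINDOW_SIZE,
          nrow(window), ncol(window))
  q <- quantise_grey(window, nbins, qrange %||% range(window))
  out <- window_feature_batch(matrix(as.numeric(window), ncol = 1),
                              matrix(as.integer(q), ncol = 1), nbins)
  setNames(out[, 1], rownames(out))
}

#' Averaged radiomics features over an ROI
#'
#' Evaluates \code{\link{window_features}} at every ROI pixel whose 11 x 11
#' window lies fully inside the image (grey levels quantised once over the
#' whole image) and averages the per-window vectors.
#'
#' @param image Numeric matrix of grey values.
#' @param mask Binary matrix of the same shape; windows are centred on
#'   nonzero mask pixels.
#' @param nbins Grey-level bins (default 32).
#' @return Named numeric vector of length 192.
#' @export
roi_features <- function(image, mask, nbins = 32L) {
  image <- as.matrix(image); mask <- as.matrix(mask)
  if (!all(dim(image) == dim(mask))) stopf("image and mask shapes differ")
  if (!any(mask != 0)) stopf("empty ROI mask")
  win <- WINDOW_SIZE; half <- (win - 1L) %/% 2L
  ctr <- which(mask != 0, arr.ind = TRUE)
  ok <- ctr[, 1] > half & ctr[, 1] <= nrow(image) - half &
        ctr[, 2] > half & ctr[, 2] <= ncol(image) - half
  ctr <- ctr[ok, , drop = FALSE]
  if (nrow(ctr) == 0) stopf("no ROI pixel admits a full %d x %d window", win, win)
  q <- quantise_grey(image, nbins)
  Wraw <- vapply(seq_len(nrow(ctr)), function(k)
    as.numeric(image[ctr[k, 1] + (-half:half), ctr[k, 2] + (-half:half)]),
    numeric(win * win))
  Wq <- vapply(seq_len(nrow(ctr)), function(k)
    as.integer(q[ctr[k, 1] + (-half:half), ctr[k, 2] + (-half:half)]),
    integer(win * win))
  Wraw <- matrix(Wraw, win * win); Wq <- matrix(Wq, win * win)
  feats <- window_feature_batch(Wraw, Wq, nbins)
  setNames(rowMeans(feats), rownames(feats))
}

#' Per-patient features across multiple slices
#'
#' Averages \code{\link{roi_features}} over a patient's image/mask pairs.
#' @param images List of grey-value matrices.
#' @param masks List of matching ROI masks.
#' @param nbins Grey-level bins (default 32).
#' @return Named numeric vector of length 192.
#' @export
patient_features <- function(images, masks, nbins = 32L) {
  stopifnot(length(images) == length(masks), length(images) >= 1)
  rowMeans(vapply(seq_along(images),
                  function(i) roi_features(images[[i]], masks[[i]], nbins),
                  numeric(192L)))
}

#' Correlation-distance nearest-neighbour route classifier
#'
#' Stores the training matrix; prediction z-scores every feature with the
#' training mean and standard deviation (zero-variance features are dropped
#' with a warning) and assigns the label of the nearest training patient
#' under correlation distance \code{d(a, b) = 1 - Pearson(a, b)} with K = 1.
#'
#' @param X Numeric matrix, patients x features.
#' @param y Class labels (length \code{nrow(X)}).
#' @return Object of class \code{metroute_knn}.
#' @export
knn_route_classifier <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2) stopf("training data contains a single class")
  mu <- colMeans(X); sd <- apply(X, 2, stats::sd)
  drop <- sd <= 0 | is.na(sd)
  if (any(drop)) {
    warnf("dropping %d zero-variance feature(s): correlation undefined", sum(drop))
  }
  if (sum(!drop) < 2) stopf("fewer than 2 usable features")
  structure(list(X = X[, !drop, drop = FALSE], y = y, keep = which(!drop),
                 mu = mu[!drop], sd = sd[!drop]),
            class = "metroute_knn")
}

# Pearson correlations between a query vector and each row of Z.
row_cor <- function(Z, z) {
  zc <- z - mean(z)
  Zc <- Z - rowMeans(Z)
  num <- as.vector(Zc %*% zc)
  den <- sqrt(rowSums(Zc^2) * sum(zc^2))
  ifelse(den > 0, num / den, 0)
}

#' @export
predict.metroute_knn <- function(object, newdata, ...) {
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  newdata <- newdata[, object$keep, drop = FALSE]
  Zt <- scale(object$X, center = object$mu, scale = object$sd)
  Zn <- scale(newdata, center = object$mu, scale = object$sd)
  apply(Zn, 1, function(z) object$y[which.max(row_cor(Zt, z))])
}

#' Leave-one-out cross-validated accuracy of the 1-NN route classifier
#'
#' Each fold leaves one patient out, refits the classifier (re-standardising
#' on the remaining patients) and predicts the held-out label.
#'
#' @param X Numeric matrix, patients x features.
#' @param y Class labels.
#' @return Accuracy in [0, 1].
#' @export
knn_loocv <- function(X, y) {
  X <- as.matrix(X); y <- as.character(y)
  n <- nrow(X)
  if (n < 2) stopf("need >= 2 patients for LOOCV")
  if (n == 2) return(mean(y[2:1] == y))  # the only neighbour is the other patient
  s1 <- colSums(X); s2 <- colSums(X^2)
  hits <- logical(n)
  for (i in seq_len(n)) {
    mu <- (s1 - X[i, ]) / (n - 1)
    v <- (s2 - X[i, ]^2 - (n - 1) * mu^2) / (n - 2)
    sd <- sqrt(pmax(v, 0))
    keep <- sd > 1e-12
    if (sum(keep) < 2) stopf("fewer than 2 usable features in a training fold")
    Z <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], `/`)
    r <- row_cor(Z[-i, , drop = FALSE], Z[i, ])
    hits[i] <- y[-i][which.max(r)] == y[i]
  }
  mean(hits)
}

#' Recursive feature elimination with LOOCV accuracy
#'
#' Backwards elimination wrapped around the correlation-distance 1-NN
#' classifier: starting from the full feature set, each step removes the
#' feature whose removal yields the highest leave-one-out accuracy (ties
#' broken by removing the highest-index feature), recording the accuracy at
#' every subset size. The final model may keep all features when no subset
#' outperforms the full set.
#'
#' @param X Numeric matrix, patients x features (named columns recommended).
#' @param y Class labels, >= 2 patients per class.
#' @param min_size Smallest subset size to explore (default 1).
#' @return List with \code{ranking} (features, best-retained first),
#'   \code{curve} (data.frame of subset size and LOOCV accuracy),
#'   \code{best_size} and \code{best_features}.
#' @export
rfe_rank <- function(X, y, min_size = 1L) {
  X <- as.matrix(X); y <- as.character(y)
  if (length(unique(y)) < 2) stopf("RFE needs >= 2 classes")
  if (min(table(y)) < 2) stopf("RFE needs >= 2 patients per class")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  active <- seq_len(ncol(X))
  sizes <- integer(0); accs <- numeric(0)
  eliminated <- integer(0)
  while (length(active) >= max(min_size, 1L)) {
    sizes <- c(sizes, length(active))
    accs <- c(accs, knn_loocv(X[, active, drop = FALSE], y))
    if (length(active) == max(min_size, 1L) || length(active) <= 2L) break
    drop_acc <- vapply(seq_along(active), function(k)
      knn_loocv(X[, active[-k], drop = FALSE], y), numeric(1))
    k <- max(which(drop_acc == max(drop_acc)))
    eliminated <- c(eliminated, active[k])
    active <- active[-k]
  }
  ranking <- colnames(X)[c(active, rev(eliminated))]
  curve <- data.frame(size = sizes, accuracy = accs)
  best <- curve$size[which.max(curve$accuracy)]
  list(ranking = ranking, curve = curve, best_size = best,
       best_features = ranking[seq_len(best)])
}
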