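## Trainable two-class pixel classification: a filter-bank of per-channel
## optical-density features at several physical smoothing scales, fed to a
## small bagged-tree ensemble trained on user scribbles.  This mirrors the
## interactive trainable-segmentation workflow (scribble, train, inspect,
## add labels, retrain) in a deterministic, scriptable form.

# ---- image filtering ---------------------------------------------------

# shift matrix rows/cols by k with edge replication
shift_mat <- function(m, k, margin) {
  n <- dim(m)[margin]
  idx <- clamp(seq_len(n) + k, 1L, n)
  if (margin == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
}

gaussian_weights <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma_px^2))
  w / sum(w)
}

# separable Gaussian smoothing with replicate padding
smooth_gaussian <- function(m, sigma_px) {
  w <- gaussian_weights(sigma_px)
  r <- (length(w) - 1L) / 2L
  acc <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(w)) acc <- acc + w[i] * shift_mat(m, i - r - 1L, 1L)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(w)) out <- out + w[i] * shift_mat(acc, i - r - 1L, 2L)
  out
}

# central-difference gradient magnitude (per-pixel units)
gradient_magnitude <- function(m) {
  gy <- (shift_mat(m, 1L, 1L) - shift_mat(m, -1L, 1L)) / 2
  gx <- (shift_mat(m, 1L, 2L) - shift_mat(m, -1L, 2L)) / 2
  sqrt(gx^2 + gy^2)
}

# feature stack: raw OD per channel, plus smoothed OD and gradient
# magnitude per channel at each physical scale
pixel_features <- function(image, feature_scales_um) {
  od <- rgb_to_optical_density(image)
  d <- dim(od)
  feats <- list()
  for (ch in 1:3) feats[[paste0("od", ch)]] <- od[, , ch]
  for (s in feature_scales_um) {
    sigma_px <- s / image$mpp
    for (ch in 1:3) {
      sm <- smooth_gaussian(od[, , ch], sigma_px)
      feats[[sprintf("gauss%g_ch%d", s, ch)]] <- sm
      feats[[sprintf("grad%g_ch%d", s, ch)]] <- gradient_magnitude(sm)
    }
  }
  X <- vapply(feats, as.numeric, numeric(d[1] * d[2]))
  colnames(X) <- names(feats)
  X
}

# ---- minimal CART-style trees -----------------------------------------

gini_impurity <- function(n1, n) {
  p <- n1 / n
  2 * p * (1 - p)
}

# grow one tree on X (n x p), y (0/1); returns a flat node table
grow_tree <- function(X, y, mtry, max_depth, min_node, n_cuts = 16L) {
  nodes <- list()
  build <- function(idx, depth) {
    node_id <- length(nodes) + 1L
    nodes[[node_id]] <<- list()  # reserve slot
    n <- length(idx)
    n1 <- sum(y[idx])
    make_leaf <- function() {
      nodes[[node_id]] <<- list(leaf = TRUE, pred = as.integer(n1 * 2L > n))
      node_id
    }
    if (depth >= max_depth || n < 2L * min_node || n1 == 0L || n1 == n)
      return(make_leaf())
    feats <- sample.int(ncol(X), mtry)
    best <- list(gain = 0)
    imp0 <- gini_impurity(n1, n)
    for (f in feats) {
      xv <- X[idx, f]
      qs <- unique(stats::quantile(xv, probs = seq_len(n_cuts) / (n_cuts + 1),
                                   names = FALSE, type = 1))
      for (t in qs) {
        left <- xv <= t
        nl <- sum(left)
        if (nl < min_node || n - nl < min_node) next
        n1l <- sum(y[idx][left])
        gain <- imp0 -
          (nl / n) * gini_impurity(n1l, nl) -
          ((n - nl) / n) * gini_impurity(n1 - n1l, n - nl)
        if (gain > best$gain + 1e-12)
          best <- list(gain = gain, feat = f, thr = t, left = left)
      }
    }
    if (best$gain <= 0) return(make_leaf())
    l_id <- build(idx[best$left], depth + 1L)
    r_id <- build(idx[!best$left], depth + 1L)
    nodes[[node_id]] <<- list(leaf = FALSE, feat = best$feat, thr = best$thr,
                              left = l_id, right = r_id)
    node_id
  }
  build(seq_along(y), 0L)
  nodes
}

predict_tree <- function(nodes, X) {
  cur <- rep(1L, nrow(X))
  out <- integer(nrow(X))
  done <- rep(FALSE, nrow(X))
  while (!all(done)) {
    for (id in unique(cur[!done])) {
      nd <- nodes[[id]]
      sel <- !done & cur == id
      if (nd$leaf) {
        out[sel] <- nd$pred
        done[sel] <- TRUE
      } else {
        goleft <- sel & X[, nd$feat] <= nd$thr
        cur[goleft] <- nd$left
        cur[sel & !goleft] <- nd$right
      }
    }
  }
  out
}

# ---- public classifier API --------------------------------------------

validate_scribbles <- function(scribbles, dims) {
  if (!is.data.frame(scribbles) ||
      !all(c("row", "col", "class") %in% names(scribbles)))
    stop2("scribbles must be a data.frame with columns row, col, class")
  if (!all(scribbles$class %in% c("tumor", "stroma")))
    stop2("scribble classes must be 'tumor' or 'stroma'")
  if (nrow(scribbles) > 0 &&
      (any(scribbles$row < 1L) || any(scribbles$row > dims[1]) ||
       any(scribbles$col < 1L) || any(scribbles$col > dims[2])))
    stop2("scribble pixels fall outside the image")
  scribbles
}

#' Train a two-class pixel classifier from labelled scribbles
#'
#' Fits a bagged ensemble of depth-limited decision trees on the scribble
#' pixels, using raw optical density plus Gaussian-smoothed OD and
#' gradient-magnitude features at the requested physical scales.  The fit
#' is deterministic for a given `seed`; prediction involves no
#' randomness.
#'
#' @param image A [calibrated_image] the scribbles refer to.
#' @param scribbles data.frame with columns `row`, `col` (1-based pixel
#'   indices) and `class` (`"tumor"` or `"stroma"`).  Both classes must
#'   be present.
#' @param feature_scales_um Physical smoothing scales in microns.
#' @param n_trees Ensemble size (odd recommended so majority votes cannot
#'   tie).
#' @param max_depth,min_node Tree growth limits.
#' @param seed RNG seed for bagging.
#' @return An object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(image, scribbles,
                                   feature_scales_um = c(0.5, 1, 2, 4),
                                   n_trees = 25L, max_depth = 8L,
                                   min_node = 5L, seed = 0L) {
  stopifnot(inherits(image, "calibrated_image"))
  scribbles <- validate_scribbles(scribbles, dim(image))
  for (cls in c("tumor", "stroma"))
    if (!any(scribbles$class == cls))
      stop2("no scribble pixels for class '", cls, "'")
  if (length(feature_scales_um) < 1L) stop2("need at least one scale")

  X_all <- pixel_features(image, feature_scales_um)
  h <- dim(image)[1]
  pix <- (scribbles$col - 1L) * h + scribbles$row
  X <- X_all[pix, , drop = FALSE]
  y <- as.integer(scribbles$class == "tumor")
  mtry <- max(1L, ceiling(sqrt(ncol(X))))
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(b) {
    boot <- sample.int(length(y), replace = TRUE)
    grow_tree(X[boot, , drop = FALSE], y[boot], mtry, max_depth, min_node)
  }))
  structure(list(feature_scales = feature_scales_um,
                 trees = trees,
                 class_labels = c("tumor", "stroma"),
                 scribbles = scribbles[c("row", "col", "class")],
                 image = image,
                 n_trees = n_trees, max_depth = max_depth,
                 min_node = min_node, seed = seed,
                 trained = TRUE),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(paste0("<pixel_classifier> %d trees, scales {%s} um, ",
                     "%d scribble pixels\n"),
              x$n_trees, paste(x$feature_scales, collapse = ", "),
              nrow(x$scribbles)))
  invisible(x)
}

#' Refine a trained classifier with additional scribbles
#'
#' Retrains on the de-duplicated union of the original and the new
#' scribbles (same training image, scales and seed).  Empty or fully
#' duplicated additions leave the model unchanged.
#'
#' @param classifier A trained [train_pixel_classifier()] result.
#' @param additional_scribbles data.frame like the training scribbles.
#' @return A retrained `pixel_classifier`.
#' @export
refine_classifier <- function(classifier, additional_scribbles) {
  if (!inherits(classifier, "pixel_classifier") || !isTRUE(classifier$trained))
    stop2("'classifier' is not a trained pixel_classifier")
  additional_scribbles <- validate_scribbles(additional_scribbles,
                                             dim(classifier$image))
  merged <- unique(rbind(classifier$scribbles,
                         additional_scribbles[c("row", "col", "class")]))
  if (nrow(merged) == nrow(classifier$scribbles)) return(classifier)
  train_pixel_classifier(classifier$image, merged,
                         feature_scales_um = classifier$feature_scales,
                         n_trees = classifier$n_trees,
                         max_depth = classifier$max_depth,
                         min_node = classifier$min_node,
                         seed = classifier$seed)
}

#' Predict a tumor mask for a calibrated image
#'
#' @param classifier A trained `pixel_classifier`.
#' @param image A [calibrated_image]; defaults to the training image.
#' @return A [tumor_mask] with one label per pixel.
#' @export
predict_mask <- function(classifier, image = classifier$image) {
  if (!inherits(classifier, "pixel_classifier") || !isTRUE(classifier$trained))
    stop2("classifier is untrained")
  stopifnot(inherits(image, "calibrated_image"))
  X <- pixel_features(image, classifier$feature_scales)
  votes <- integer(nrow(X))
  for (tr in classifier$trees) votes <- votes + predict_tree(tr, X)
  lab <- as.integer(votes * 2L > classifier$n_trees)
  tumor_mask(matrix(lab, nrow = dim(image)[1]), image$mpp)
}
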