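# Shared fixtures: small phantoms are cached per test run so each is
# generated once.

.fixture_cache <- new.env(parent = emptyenv())

# small phantom: 160 x 100 px at 16 um/px (2.54 x 1.58 mm)
small_phantom <- function(inner = 0.9, front = 0.3, noise_sd = 4, seed = 5) {
  key <- paste("small", inner, front, noise_sd, seed, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_phantom(phantom_config(
      image_size_px = c(160, 100), mpp = 16,
      inner_target_fraction = inner, front_target_fraction = front,
      noise_sd = noise_sd, seed = seed))
  .fixture_cache[[key]]
}

# default-size noise-free phantom used by the end-to-end checks
clean_phantom <- function(seed = 7) {
  key <- paste("clean", seed, sep = "_")
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_phantom(phantom_config(
      noise_sd = 0, seed = seed))
  .fixture_cache[[key]]
}

# random scribbles drawn from the phantom truth mask
truth_scribbles <- function(phantom, n_per_class = 200, seed = 99) {
  truth <- phantom$truth$tumor_mask$values
  h <- nrow(truth)
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    pick <- function(value, cls) {
      idx <- sample(which(truth == value), n_per_class)
      data.frame(row = (idx - 1) %% h + 1, col = (idx - 1) %/% h + 1,
                 class = cls)
    }
    rbind(pick(1L, "tumor"), pick(0L, "stroma"))
  })
}

# brute-force oracle: distance from pixel centres to a polyline,
# unsigned, scalar loops over segments
brute_distance <- function(nrow_px, ncol_px, mpp, vertices) {
  out <- matrix(Inf, nrow_px, ncol_px)
  for (r in seq_len(nrow_px)) for (cc in seq_len(ncol_px)) {
    q <- c((cc - 1) * mpp, (r - 1) * mpp)
    for (i in seq_len(nrow(vertices) - 1)) {
      p1 <- vertices[i, ]; p2 <- vertices[i + 1, ]
      v <- p2 - p1
      t <- sum((q - p1) * v) / sum(v * v)
      t <- min(max(t, 0), 1)
      out[r, cc] <- min(out[r, cc], sqrt(sum((q - p1 - t * v)^2)))
    }
  }
  out
}

# brute-force oracle for select_fields: direct loops over the stride
# grid, pixel-by-pixel sums, explicit border strips
brute_select_fields <- function(mask, band, k = 3,
                                field_dims_um = c(1150, 680),
                                stride_um = 50, margin_um = 20) {
  mpp <- mask$mpp
  m <- mask$values
  ext_x <- (ncol(m) - 1) * mpp
  ext_y <- (nrow(m) - 1) * mpp
  rows_for <- function(a, b) {
    lo <- max(1, ceiling(a / mpp - 1e-9) + 1)
    hi <- min(nrow(m), floor(b / mpp + 1e-9) + 1)
    if (lo > hi) integer() else lo:hi
  }
  cols_for <- function(a, b) {
    lo <- max(1, ceiling(a / mpp - 1e-9) + 1)
    hi <- min(ncol(m), floor(b / mpp + 1e-9) + 1)
    if (lo > hi) integer() else lo:hi
  }
  cand <- list()
  dims_list <- list(field_dims_um, rev(field_dims_um))
  for (o in seq_along(dims_list)) {
    w <- dims_list[[o]][1]; h <- dims_list[[o]][2]
    if (w > ext_x || h > ext_y) next
    for (y in seq(0, ext_y - h, by = stride_um)) {
      for (x in seq(0, ext_x - w, by = stride_um)) {
        cr <- round((y + h / 2) / mpp) + 1
        cc <- round((x + w / 2) / mpp) + 1
        if (band$values[cr, cc] != 1L) next
        rr <- rows_for(y, y + h); cl <- cols_for(x, x + w)
        sub <- m[rr, cl, drop = FALSE]
        mrow <- max(0, floor(margin_um / mpp + 1e-9))
        strip <- function(s) sum(s) > 0
        ok <- strip(sub[seq_len(min(nrow(sub), 1 + mrow)), , drop = FALSE]) &&
          strip(sub[seq(max(1, nrow(sub) - mrow), nrow(sub)), , drop = FALSE]) &&
          strip(sub[, seq_len(min(ncol(sub), 1 + mrow)), drop = FALSE]) &&
          strip(sub[, seq(max(1, ncol(sub) - mrow), ncol(sub)), drop = FALSE])
        if (!ok) next
        cand[[length(cand) + 1L]] <- data.frame(
          x = x, y = y, w = w, h = h, fraction = mean(sub))
      }
    }
  }
  cand <- do.call(rbind, cand)
  cand[order(cand$fraction)[seq_len(min(k, nrow(cand)))], , drop = FALSE]
}

# truth-mask tumor fraction inside a field box (same pixel convention)
truth_fraction_in_box <- function(truth_mask, box) {
  mpp <- truth_mask$mpp
  m <- truth_mask$values
  rr <- (max(1, ceiling(box$y / mpp - 1e-9) + 1)):
    (min(nrow(m), floor((box$y + box$height_um) / mpp + 1e-9) + 1))
  cl <- (max(1, ceiling(box$x / mpp - 1e-9) + 1)):
    (min(ncol(m), floor((box$x + box$width_um) / mpp + 1e-9) + 1))
  mean(m[rr, cl])
}
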