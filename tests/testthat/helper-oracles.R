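# Independent oracles and fixtures used across the test suite. These
# deliberately re-derive expected results by different algorithmic routes
# (vectorized R instead of C++ loops, flood fill instead of component
# labeling, direct convolution instead of separable passes).

# exhaustive multilevel-Otsu oracle: vectorized full-grid scan over all
# ordered cut tuples of a 256-bin histogram, lexicographically-first argmax
otsu_bruteforce <- function(values, k) {
  B <- 256L
  bin <- pmin(pmax(ceiling(values * B), 1L), B)
  counts <- tabulate(bin, nbins = B)
  w <- c(0, cumsum(counts))
  m <- c(0, cumsum(counts * seq_len(B)))
  mu <- m[B + 1L] / w[B + 1L]
  seg <- function(a, b) {
    wv <- w[b + 1L] - w[a + 1L]
    d <- ifelse(wv > 0, (m[b + 1L] - m[a + 1L]) / wv - mu, 0)
    ifelse(wv > 0, wv * d * d, 0)
  }
  if (k == 1L) {
    t1 <- 1:(B - 1L)
    v <- seg(0L, t1) + seg(t1, B)
    return(t1[which.max(v)] / B)
  }
  if (k == 2L) {
    best <- -1; bt <- NULL
    for (t1 in 1:(B - 2L)) {
      t2 <- (t1 + 1L):(B - 1L)
      v <- seg(0L, t1) + seg(t1, t2) + seg(t2, B)
      i <- which.max(v)
      if (v[i] > best) { best <- v[i]; bt <- c(t1, t2[i]) }
    }
    return(bt / B)
  }
  best <- -1; bt <- NULL
  t2g <- 2:(B - 2L)
  t3g <- 3:(B - 1L)
  # rows indexed by t3, columns by t2: column-major which.max scans t2
  # ascending then t3 ascending, i.e. lexicographic (t2, t3)
  s23 <- outer(t3g, t2g, function(t3, t2) seg(t2, t3))
  s3e <- matrix(seg(t3g, B), length(t3g), length(t2g))
  valid <- outer(t3g, t2g, ">")
  for (t1 in 1:(B - 3L)) {
    s1 <- seg(0L, t1)
    s12 <- matrix(seg(t1, t2g), length(t3g), length(t2g), byrow = TRUE)
    v <- s1 + s12 + s23 + s3e
    ok <- valid & matrix(t2g > t1, length(t3g), length(t2g), byrow = TRUE)
    v[!ok] <- -Inf
    i <- which.max(v)
    if (v[i] > best) {
      best <- v[i]
      r <- ((i - 1L) %% length(t3g)) + 1L
      cl <- ((i - 1L) %/% length(t3g)) + 1L
      bt <- c(t1, t2g[cl], t3g[r])
    }
  }
  bt / B
}

# textbook single-threshold Otsu: direct scan of w0*w1*(mu0-mu1)^2
single_otsu_textbook <- function(values) {
  B <- 256L
  bin <- pmin(pmax(ceiling(values * B), 1L), B)
  counts <- tabulate(bin, nbins = B)
  p <- counts / sum(counts)
  mu_bins <- seq_len(B)
  best <- -1; bt <- NA
  for (t in 1:(B - 1L)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:t] * mu_bins[1:t]) / w0
    mu1 <- sum(p[(t + 1):B] * mu_bins[(t + 1):B]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; bt <- t }
  }
  bt / B
}

# holes oracle: iterative 4-connected flood fill of background from the
# border; holes are the unreached background pixels
holes_floodfill_oracle <- function(mask) {
  bg <- !(mask > 0)
  reach <- matrix(FALSE, nrow(bg), ncol(bg))
  reach[1, ] <- bg[1, ]; reach[nrow(bg), ] <- bg[nrow(bg), ]
  reach[, 1] <- reach[, 1] | bg[, 1]; reach[, ncol(bg)] <- reach[, ncol(bg)] | bg[, ncol(bg)]
  shift0 <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
    cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    grown <- reach |
      (bg & (shift0(reach, 1, 0) | shift0(reach, -1, 0) |
             shift0(reach, 0, 1) | shift0(reach, 0, -1)))
    if (identical(grown, reach)) break
    reach <- grown
  }
  bg & !reach
}

# direct (non-separable) 2-D convolution with mirror boundary
conv2_bruteforce <- function(image, kernel) {
  r <- (nrow(kernel) - 1L) / 2L
  nr <- nrow(image); nc <- ncol(image)
  reflect <- function(i, n) ifelse(i < 1L, 2L - i, ifelse(i > n, 2L * n - i, i))
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (di in -r:r) for (dj in -r:r) {
        acc <- acc + kernel[di + r + 1L, dj + r + 1L] *
          image[reflect(i + di, nr), reflect(j + dj, nc)]
      }
      out[i, j] <- acc
    }
  }
  out
}

# analytic disk mask
make_disk_mask <- function(n, radius, center = c((n + 1) / 2, (n + 1) / 2)) {
  rr <- outer(seq_len(n) - center[1], rep(1, n))
  cc <- outer(rep(1, n), seq_len(n) - center[2])
  sqrt(rr^2 + cc^2) <= radius
}

# dumbbell: two overlapping disks of radius 12 whose centers are 20 apart
make_dumbbell_mask <- function() {
  n <- 64
  make_disk_mask(n, 12, c(32, 22)) | make_disk_mask(n, 12, c(32, 42))
}

# optimal one-to-one matching count by exhaustive assignment enumeration
optimal_match_count <- function(iou, min_overlap = 0.5) {
  iou[iou < min_overlap] <- 0
  np <- nrow(iou); ng <- ncol(iou)
  if (np == 0 || ng == 0) return(0L)
  best <- 0L
  recurse <- function(p, used_g, count) {
    if (count + (np - p + 1L) <= best) return()
    if (p > np) { best <<- max(best, count); return() }
    recurse(p + 1L, used_g, count)  # leave p unmatched
    for (g in seq_len(ng)) {
      if (!used_g[g] && iou[p, g] > 0) {
        used_g[g] <- TRUE
        recurse(p + 1L, used_g, count + 1L)
        used_g[g] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, ng), 0L)
  best
}

# pairwise IoU matrix between two label maps
iou_matrix <- function(pred, gt) {
  np <- max(pred, 0L); ng <- max(gt, 0L)
  out <- matrix(0, np, ng)
  if (np == 0 || ng == 0) return(out)
  ap <- tabulate(pred[pred > 0L], nbins = np)
  ag <- tabulate(gt[gt > 0L], nbins = ng)
  for (p in seq_len(np)) for (g in seq_len(ng)) {
    inter <- sum(pred == p & gt == g)
    if (inter > 0) out[p, g] <- inter / (ap[p] + ag[g] - inter)
  }
  out
}

# compact scene parameters for fast pipeline-mechanics tests (not the
# default study conditions)
small_scene_params <- function(n_cells = 6L) {
  scene_params(height = 256L, width = 256L, n_cells = n_cells,
               radius_range = c(16, 24))
}

# mock constant classifier usable in place of the SVM inside a filter model
constant_classifier <- function(value) {
  structure(list(value = value), class = "constant_classifier")
}
# registered in the global environment so stats::predict can dispatch to it
assign("predict.constant_classifier",
       function(object, newdata, ...)
         factor(rep(object$value, nrow(newdata)), levels = c("0", "1")),
       envir = globalenv())

mock_filter_model <- function(value) {
  fn <- hmacell:::feature_names()
  structure(list(svm = constant_classifier(value),
                 center = stats::setNames(rep(0, length(fn)), fn),
                 scale = stats::setNames(rep(1, length(fn)), fn),
                 features = fn,
                 meta = list(seed = 0L, n_samples = 0L)),
            class = "hma_filter_model")
}
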