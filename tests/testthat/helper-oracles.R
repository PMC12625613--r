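# Independent oracles and small mask builders used across test files.

# Naive exhaustive Otsu: tries every distinct value as the cut, computing the
# between-class variance directly from the two groups. O(n^2); independent of
# the cumulative-sum implementation in the package.
oracle_otsu_mask <- function(img) {
  v <- as.numeric(img)
  u <- sort(unique(v))
  best <- -Inf
  best_cut <- u[1]
  for (t in u[-length(u)]) {
    lo <- v[v <= t]
    hi <- v[v > t]
    w0 <- length(lo) / length(v)
    w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) {
      best <- bcv
      best_cut <- t
    }
  }
  matrix(as.integer(img > best_cut), nrow(img), ncol(img))
}

# Filled disk mask on an n x n canvas.
disk_mask <- function(n, center, radius) {
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  m <- matrix(0L, n, n)
  m[(g$r - center[1])^2 + (g$c - center[2])^2 <= radius^2] <- 1L
  m
}

# Label image built from ground-truth nucleus disks (exact geometry, no
# imaging): nucleus i painted with label i.
truth_nuclei_labels <- function(truth, n) {
  lab <- matrix(0L, n, n)
  for (i in seq_len(nrow(truth$nuclei))) {
    g <- truth$nuclei[i, ]
    rr <- max(1, floor(g$row - g$radius)):min(n, ceiling(g$row + g$radius))
    cc <- max(1, floor(g$col - g$radius)):min(n, ceiling(g$col + g$radius))
    d2 <- outer((rr - g$row)^2, rep(1, length(cc))) +
      outer(rep(1, length(rr)), (cc - g$col)^2)
    sub <- lab[rr, cc, drop = FALSE]
    sub[d2 <= g$radius^2] <- i
    lab[rr, cc] <- sub
  }
  lab
}

# Small-field generator settings that keep unit tests fast; any synth_params
# argument can be overridden.
small_params <- function(...) {
  defaults <- list(image_size = 320, n_nuclei = 20, n_myotubes = 2,
                   tube_width = 20, tube_length = 160, true_fi = 0.4)
  do.call(synth_params, utils::modifyList(defaults, list(...)))
}
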