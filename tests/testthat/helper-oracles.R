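## Independent brute-force oracles and small fixture builders. These
## deliberately avoid the package's internal code paths: plain loops and
## base-R tabulations only.

## per-pixel maximum by explicit looping
oracleMaxProject <- function(stack) {
  d <- dim(stack)
  out <- matrix(-Inf, d[2], d[3])
  for (z in seq_len(d[1]))
    for (y in seq_len(d[2]))
      for (x in seq_len(d[3]))
        if (stack[z, y, x] > out[y, x]) out[y, x] <- stack[z, y, x]
  out
}

## exhaustive between-class-variance maximization on the quantized
## histogram, computed from the class definitions directly
oracleOtsu <- function(values, classes, bins = 256L) {
  v <- pmin(pmax(as.numeric(values), 0), 1)
  idx <- pmin(floor(v * bins) + 1, bins)
  counts <- tabulate(idx, bins)
  n <- sum(counts)
  mids <- (seq_len(bins) - 0.5) / bins
  bcv <- function(cuts) {   # cuts: upper bin of each lower class
    edges <- c(0, cuts, bins)
    tot_mu <- sum(counts * mids) / n
    s <- 0
    for (k in seq_len(length(edges) - 1)) {
      b <- (edges[k] + 1):edges[k + 1]
      wk <- sum(counts[b]) / n
      if (wk > 0) {
        muk <- sum(counts[b] * mids[b]) / sum(counts[b])
        s <- s + wk * (muk - tot_mu)^2
      }
    }
    s
  }
  if (classes == 2L) {
    best <- 1; best_v <- -Inf
    for (t in 1:(bins - 1)) {
      v2 <- bcv(t)
      if (v2 > best_v + 1e-15) { best_v <- v2; best <- t }
    }
    out <- best / bins
  } else {
    best <- c(1, 2); best_v <- -Inf
    for (i in 1:(bins - 2)) for (j in (i + 1):(bins - 1)) {
      v3 <- bcv(c(i, j))
      if (v3 > best_v + 1e-15) { best_v <- v3; best <- c(i, j) }
    }
    out <- best / bins
  }
  attr(out, "between_variance") <- best_v
  out
}

## mutual information from an explicitly built joint table
oracleMI <- function(a, b, bins = 64L) {
  qz <- function(p) {
    r <- range(p)
    if (diff(r) == 0) return(matrix(1L, nrow(p), ncol(p)))
    matrix(pmin(floor((p - r[1]) / diff(r) * bins) + 1, bins),
           nrow(p), ncol(p))
  }
  qa <- qz(a); qb <- qz(b)
  tab <- table(factor(qa, 1:bins), factor(qb, 1:bins))
  jm <- tab / sum(tab)
  pa <- rowSums(jm); pb <- colSums(jm)
  s <- 0
  for (i in 1:bins) for (j in 1:bins)
    if (jm[i, j] > 0)
      s <- s + jm[i, j] * log(jm[i, j] / (pa[i] * pb[j]))
  as.numeric(s)
}

## exhaustive MI surface over integer shifts of b, scored like the
## implementation on the fixed central window (same pixel count for every
## candidate) with the same tie rule (smaller magnitude, then
## lexicographic), but computed through the independent oracleMI
oracleMIArgmax <- function(a, b, radius, bins = 64L) {
  H <- nrow(a); W <- ncol(a)
  ys <- (1 + radius):(H - radius); xs <- (1 + radius):(W - radius)
  ## quantization must be over the full plane, as the implementation does
  qz <- function(p) {
    r <- range(p)
    matrix(pmin(floor((p - r[1]) / diff(r) * bins) + 1, bins),
           nrow(p), ncol(p))
  }
  qa <- qz(a); qb <- qz(b)
  miq <- function(u, v) {
    tab <- table(factor(u, 1:bins), factor(v, 1:bins))
    jm <- tab / sum(tab)
    pa <- rowSums(jm); pb <- colSums(jm)
    s <- 0
    for (i in 1:bins) for (j in 1:bins)
      if (jm[i, j] > 0) s <- s + jm[i, j] * log(jm[i, j] / (pa[i] * pb[j]))
    as.numeric(s)
  }
  cand <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  cand <- cand[order(cand$dy^2 + cand$dx^2, cand$dy, cand$dx), ]
  best <- c(0L, 0L); best_mi <- -Inf
  for (k in seq_len(nrow(cand))) {
    dy <- cand$dy[k]; dx <- cand$dx[k]
    mi <- miq(qa[ys, xs], qb[ys - dy, xs - dx])
    if (mi > best_mi + 1e-12) { best_mi <- mi; best <- c(dy, dx) }
  }
  best
}

## single-pass brute-force re-implementation of both QC rules
oracleQCSurvivors <- function(records, min_fields = 5L) {
  a <- records$map2_area
  mu <- mean(a); s <- sd(a)
  kept <- records[a >= mu - s & a <= mu + s, , drop = FALSE]
  key <- paste(kept$plate_id, kept$well)
  counts <- table(key)
  good_wells <- names(counts)[counts >= min_fields]
  kept[paste(kept$plate_id, kept$well) %in% good_wells, , drop = FALSE]
}

## additive Gaussian spot, independent of the package's renderer
drawSpot <- function(img, cy, cx, d, amp = 1) {
  sigma <- d / 2.355
  for (y in seq_len(nrow(img))) for (x in seq_len(ncol(img))) {
    r2 <- (y - cy)^2 + (x - cx)^2
    if (r2 < (4 * sigma)^2)
      img[y, x] <- img[y, x] + amp * exp(-r2 / (2 * sigma^2))
  }
  img
}

drawDisk <- function(img, cy, cx, d, amp = 1) {
  r <- d / 2
  for (y in seq_len(nrow(img))) for (x in seq_len(ncol(img)))
    if ((y - cy)^2 + (x - cx)^2 <= r^2) img[y, x] <- amp
  img
}

## compact field spec used across image tests (nuclei scaled to fit the
## small frames)
tinySpec <- function(seed, shape = c(96L, 96L), on = 15L, off = 5L,
                     nn = 2L, na = 1L, slices = 5L, segments = 4L) {
  fieldSpec(image_shape = shape, n_slices = slices,
            n_neurite_segments = segments, n_on_puncta = on,
            n_off_puncta = off, n_neuronal_nuclei = nn,
            n_astrocyte_nuclei = na,
            neuronal_nucleus_diameter = 20, astrocyte_nucleus_diameter = 18,
            seed = as.integer(seed))
}

## mid-size spec for recovery runs
fieldSpec160 <- function(seed, on = 40L) {
  fieldSpec(image_shape = c(160L, 160L), n_slices = 5L,
            n_on_puncta = as.integer(on), n_off_puncta = 12L,
            n_neuronal_nuclei = 3L, n_astrocyte_nuclei = 2L,
            neuronal_nucleus_diameter = 22, astrocyte_nucleus_diameter = 24,
            seed = as.integer(seed))
}

## screen layouts: n plates x 16 triplicate conditions each
screenLayouts <- function(n_plates, batch_id = "batch1", prefix = "c") {
  lapply(seq_len(n_plates), function(i)
    plateLayout96(sprintf("P%02d", i), batch_id = batch_id,
                  treatments = sprintf("%s%02d_%02d", prefix, 1:16, i)))
}
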