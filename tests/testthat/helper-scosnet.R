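# Shared fixtures and independent oracles for the test suite.

ORG <- c("lung", "heart", "cord")

# small backbone for cheap model tests (16x16 inputs work at depth 2/3)
tiny_backbone <- function(depth = 2L, bf = 2L) backbone_config(depth, bf)

# a random binary mask with at least one foreground pixel
random_mask <- function(h, w, p = 0.3) {
  repeat {
    m <- matrix(as.integer(runif(h * w) < p), h, w)
    if (sum(m) > 0) return(m)
  }
}

# ---- independent brute-force surface-distance oracle -----------------------
# Everything below is written from first principles (plain double loops over
# pixels), deliberately sharing no code with the package implementation.

oracle_contour <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] == 0) next
    edge <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > h || jj < 1 || jj > w || mask[ii, jj] == 0)
        edge <- TRUE
    }
    if (edge) out[i, j] <- 1L
  }
  out
}

oracle_pooled <- function(X, Y) {
  cx <- which(oracle_contour(X) == 1, arr.ind = TRUE)
  cy <- which(oracle_contour(Y) == 1, arr.ind = TRUE)
  dmin <- function(a, B) {
    best <- Inf
    for (k in seq_len(nrow(B))) {
      d <- sqrt(sum((a - B[k, ])^2))
      if (d < best) best <- d
    }
    best
  }
  dxy <- apply(cx, 1, dmin, B = cy)
  dyx <- apply(cy, 1, dmin, B = cx)
  list(xy = dxy, yx = dyx, nX = nrow(cx), nY = nrow(cy))
}

oracle_max_hd <- function(X, Y) {
  if (sum(X) == 0) return(Inf)
  d <- oracle_pooled(X, Y)
  max(c(d$xy, d$yx))
}

oracle_hd95 <- function(X, Y) {
  if (sum(X) == 0) return(Inf)
  d <- oracle_pooled(X, Y)
  v <- sort(c(d$xy, d$yx))
  n <- length(v)
  h <- (n - 1) * 0.95 + 1  # linear interpolation between order statistics
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
}

oracle_asd <- function(X, Y) {
  if (sum(X) == 0) return(Inf)
  d <- oracle_pooled(X, Y)
  (sum(d$xy) + sum(d$yx)) / (d$nX + d$nY)
}

# ---- cached desk-scale study for the acceptance tests ----------------------
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(.study_cache$study)) {
    cfg <- experiment_config(settings = c("STL", "SCOS", "SCOS_aug"),
                             seeds = c(1L, 2L, 3L))
    .study_cache$study <- run_study(cfg)
  }
  .study_cache$study
}
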