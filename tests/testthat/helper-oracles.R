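# Independent oracles used across tests. These deliberately share no code
# with the package internals: scalar loops and stack-based searches instead
# of vectorised frontiers.

# Brute-force percentage-of-max region: given a peak voxel, collect every
# voxel >= frac * peak that is 26-connected to the peak, via a stack of
# coordinate triples.
oracle_flood <- function(values, peak, frac = 0.41, excl = NULL) {
  dims <- dim(values)
  thr <- frac * values[peak[1], peak[2], peak[3]]
  inr <- function(x, y, z) x >= 1 && x <= dims[1] && y >= 1 &&
    y <= dims[2] && z >= 1 && z <= dims[3]
  ok <- function(x, y, z) values[x, y, z] >= thr &&
    (is.null(excl) || !excl[x, y, z])
  seen <- array(FALSE, dims)
  stack <- list(peak)
  seen[peak[1], peak[2], peak[3]] <- TRUE
  out <- list()
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    out[[length(out) + 1]] <- v
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x <- v[1] + dx; y <- v[2] + dy; z <- v[3] + dz
      if (inr(x, y, z) && !seen[x, y, z] && ok(x, y, z)) {
        seen[x, y, z] <- TRUE
        stack[[length(stack) + 1]] <- c(x, y, z)
      }
    }
  }
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Exhaustive 26-connected component count of a logical mask, scalar BFS.
oracle_components <- function(mask) {
  dims <- dim(mask)
  seen <- array(FALSE, dims)
  comps <- list()
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2]))
    for (x in seq_len(dims[1])) {
      if (!mask[x, y, z] || seen[x, y, z]) next
      stack <- list(c(x, y, z))
      seen[x, y, z] <- TRUE
      comp <- list()
      while (length(stack)) {
        v <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        comp[[length(comp) + 1]] <- v
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          xx <- v[1] + dx; yy <- v[2] + dy; zz <- v[3] + dz
          if (xx >= 1 && xx <= dims[1] && yy >= 1 && yy <= dims[2] &&
              zz >= 1 && zz <= dims[3] && mask[xx, yy, zz] &&
              !seen[xx, yy, zz]) {
            seen[xx, yy, zz] <- TRUE
            stack[[length(stack) + 1]] <- c(xx, yy, zz)
          }
        }
      }
      comps[[length(comps) + 1]] <- do.call(rbind, comp)
    }
  comps
}

# Random multi-blob SUV volume for oracle-equivalence tests: a few
# Gaussian foci on a noisy background, deterministic per seed.
random_blob_volume <- function(seed, shape = c(32, 32, 32),
                               spacing = c(2, 2, 2)) {
  set.seed(seed)
  v <- array(stats::runif(prod(shape), 0, 0.4), shape)
  k <- sample(1:3, 1)
  for (i in seq_len(k)) {
    ctr <- sapply(shape, function(s) sample(seq(6, s - 5), 1))
    sig <- stats::runif(1, 3, 8)
    peak <- stats::runif(1, 4, 12)
    dx2 <- ((seq_len(shape[1]) - ctr[1]) * spacing[1])^2
    dy2 <- ((seq_len(shape[2]) - ctr[2]) * spacing[2])^2
    dz2 <- ((seq_len(shape[3]) - ctr[3]) * spacing[3])^2
    v <- pmax(v, peak * exp(-outer(outer(dx2, dy2, `+`), dz2, `+`) /
                              (2 * sig^2)))
  }
  dim(v) <- shape
  pet_volume(v, spacing, units = "suv")
}

# Exhaustive Youden search over observed cut-offs with the marker >=
# cut-off orientation; scalar re-computation of sens/spec per cut-off.
oracle_youden <- function(marker, event) {
  cuts <- sort(unique(marker))
  best <- NULL
  for (cc in cuts) {
    tp <- sum(marker >= cc & event == 1)
    fn <- sum(marker < cc & event == 1)
    tn <- sum(marker < cc & event == 0)
    fp <- sum(marker >= cc & event == 0)
    J <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (is.null(best) || J > best$J + 1e-12)
      best <- list(cutoff = cc, J = J)
  }
  best
}

# Breslow partial log-likelihood for a single covariate, scalar loops,
# no shared code with the fitter.
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      rs <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[rs])))
    }
  }
  ll
}

# Convenience: lesion fixture built directly (bypassing segmentation) for
# metric-only tests.
mk_lesion <- function(voxels, values, spacing, peak_suv = max(values),
                      organ = "other", id = NA_integer_) {
  voxels <- matrix(as.integer(voxels), ncol = 3)
  mtapet:::new_lesion(voxels = voxels, values = values,
                      peak_voxel = voxels[which.max(values), ],
                      peak_suv = peak_suv, threshold = min(values),
                      spacing = spacing, organ = organ, id = id)
}
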