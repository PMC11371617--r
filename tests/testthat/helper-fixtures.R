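# shared fixture builders; everything is generated in code at test time

utc <- function(x) as.POSIXct(x, tz = "UTC")

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# tiny deterministic day grid: D days x T slots, values day*100 + slot
toy_grid <- function(D = 4L, Tn = 10L, step = 86400 / Tn) {
  vals <- outer(seq_len(D) * 100, seq_len(Tn), `+`)
  binimpute:::new_daygrid(as.Date("2023-06-01") + seq_len(D) - 1L,
                          (seq_len(Tn) - 1L) * step, step, vals,
                          matrix(FALSE, D, Tn))
}

# random matrix with ~frac missing, every column kept non-empty
random_masked_matrix <- function(D, Tn, frac = 0.1, seed = 1L,
                                 correlated = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(D * Tn, 50, 5), D, Tn)
  if (correlated && Tn > 1L) {
    X <- X + rnorm(D, 0, 4)            # shared row effect -> correlation
  }
  n_miss <- max(1L, round(frac * D * Tn))
  idx <- sample(D * Tn, n_miss)
  X[idx] <- NA
  empty <- colSums(!is.na(X)) == 0L
  X[1L, empty] <- rnorm(sum(empty), 50, 5)
  X
}

# independent brute-force kNN oracle (plain loops, no shared code path)
knn_oracle <- function(X, k) {
  D <- nrow(X); Tw <- ncol(X)
  out <- X
  for (d in seq_len(D)) {
    mis <- which(is.na(X[d, ]))
    if (!length(mis)) next
    dist_to <- rep(Inf, D)
    for (o in seq_len(D)) {
      if (o == d) next
      s <- 0; nc <- 0L
      for (t in seq_len(Tw)) {
        if (!is.na(X[d, t]) && !is.na(X[o, t])) {
          s <- s + (X[d, t] - X[o, t])^2
          nc <- nc + 1L
        }
      }
      if (nc > 0L) dist_to[o] <- sqrt(Tw / nc * s)
    }
    ord <- order(dist_to)
    ord <- ord[is.finite(dist_to[ord]) & ord != d]
    for (j in mis) {
      donors <- ord[!is.na(X[ord, j])]
      out[d, j] <- if (length(donors)) {
        mean(X[head(donors, k), j])
      } else {
        mean(X[, j], na.rm = TRUE)
      }
    }
  }
  out
}
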