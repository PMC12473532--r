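# Independent brute-force oracles: scalar loops and textbook formulas, kept
# deliberately separate from the implementation paths they check.

oracle_spatial_mean <- function(frame, rows, cols) {
  out <- numeric(3)
  for (ch in 1:3) {
    acc <- 0; n <- 0
    for (i in rows) for (j in cols) { acc <- acc + frame[i, j, ch]; n <- n + 1 }
    out[ch] <- acc / n
  }
  out
}

oracle_chrominance <- function(R, G, B) {
  xs <- numeric(length(R)); ys <- numeric(length(R))
  for (i in seq_along(R)) {
    xs[i] <- 3 * R[i] - 2 * G[i]
    ys[i] <- 1.5 * R[i] + G[i] - 1.5 * B[i]
  }
  list(xs = xs, ys = ys)
}

oracle_majority <- function(labels, n_required) {
  last <- labels[(length(labels) - n_required + 1):length(labels)]
  counts <- sapply(unique(last), function(l) sum(last == l))
  max(counts)
}

oracle_classify_cosine <- function(v, mat, labels) {
  best <- -Inf; lab <- NA
  for (j in seq_len(nrow(mat))) {
    p <- mat[j, ]
    sim <- sum(v * p) / (sqrt(sum(v^2)) * sqrt(sum(p^2)))
    if (sim > best) { best <- sim; lab <- labels[j] }
  }
  list(label = lab, similarity = best)
}

oracle_classify_euclidean <- function(v, mat, labels) {
  best <- Inf; lab <- NA
  for (j in seq_len(nrow(mat))) {
    d <- sqrt(sum((v - mat[j, ])^2))
    if (d < best) { best <- d; lab <- labels[j] }
  }
  list(label = lab, distance = best)
}

oracle_agreement <- function(e, r) {
  n <- length(e)
  d <- numeric(n); ad <- numeric(n)
  for (i in seq_len(n)) { d[i] <- e[i] - r[i]; ad[i] <- abs(d[i]) }
  bias <- sum(d) / n
  ssd <- 0
  for (i in seq_len(n)) ssd <- ssd + (d[i] - bias)^2
  sdd <- sqrt(ssd / (n - 1))
  me <- sum(e) / n; mr <- sum(r) / n
  num <- 0; de <- 0; dr <- 0
  for (i in seq_len(n)) {
    num <- num + (e[i] - me) * (r[i] - mr)
    de <- de + (e[i] - me)^2
    dr <- dr + (r[i] - mr)^2
  }
  list(mae = sum(ad) / n, bias = bias, sd_diff = sdd,
       loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
       pearson = num / sqrt(de * dr))
}

# A clean scene (no noise, no drift) at a given heart rate, for recovery tests.
clean_scene <- function(bpm, duration_s = 10, ...) {
  scene_config(duration_s = duration_s, hr_hz = bpm / 60,
               noise_sd = 0, drift_amp = 0, ...)
}
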