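# Independent oracles used across the suite. These are deliberately naive
# (scalar loops, exhaustive sweeps) and share no code with the implementation
# paths they check.

# Scalar-by-scalar softmax of one vector.
oracle_softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# Nested-loop evaluation of the scale-attention refinement
# refined_i = gate * sum_j phi_ij %*% F_j + F_i on channels-first features.
oracle_sam <- function(phi, f, gate) {
  C <- dim(f)[1]; H <- dim(f)[2]; W <- dim(f)[3]
  out <- array(0, dim(f))
  for (a in seq_len(C)) {
    for (h in seq_len(H)) {
      for (w in seq_len(W)) {
        acc <- 0
        for (b in seq_len(C)) acc <- acc + phi[a, b] * f[b, h, w]
        out[a, h, w] <- gate * acc + f[a, h, w]
      }
    }
  }
  out
}

# Exhaustive threshold sweep: FAR/FRR at every candidate threshold by
# counting, then the crossing interpolated segment-by-segment with scalar
# arithmetic.
oracle_eer <- function(genuine, impostor) {
  cand <- c(-Inf, sort(unique(c(genuine, impostor))), Inf)
  far <- frr <- numeric(length(cand))
  for (i in seq_along(cand)) {
    far[i] <- sum(impostor >= cand[i]) / length(impostor)
    frr[i] <- sum(genuine < cand[i]) / length(genuine)
  }
  d <- far - frr
  for (i in seq_along(cand)) {
    if (d[i] == 0) return(far[i])
    if (d[i] < 0) {
      a <- d[i - 1] / (d[i - 1] - d[i])
      return(far[i - 1] + a * (far[i] - far[i - 1]))
    }
  }
  stop("no crossing")
}

# Exhaustive best-accuracy sweep.
oracle_accuracy <- function(genuine, impostor) {
  cand <- c(sort(unique(c(genuine, impostor))), Inf)
  best <- 0
  for (t in cand) {
    acc <- (sum(genuine >= t) + sum(impostor < t)) /
      (length(genuine) + length(impostor))
    best <- max(best, acc)
  }
  best
}

# Tiny network configuration used by the training/gradient tests.
tiny_net_config <- function(n_classes = 4L, attention = "sa") {
  network_config(n_classes = n_classes, input_size = 16L, stem_channels = 8L,
                 stage_widths = c(8L, 8L), blocks_per_stage = c(1L, 1L),
                 attention = attention, groups = c(1L, 2L, 4L, 8L))
}

tiny_run_config <- function(...) {
  run_config(input_size = 32L, stem_channels = 8L,
             stage_widths = c(8L, 16L), blocks_per_stage = c(1L, 1L),
             groups = c(1L, 2L, 4L, 8L),
             classes_per_batch = 6L, samples_per_class = 2L, ...)
}

tiny_synth <- function(n_classes = 6L, samples = 4L, size = 32L, seed = 5L) {
  synth_config(n_classes = n_classes, samples_per_class = samples,
               height = size, width = size, seed = seed)
}
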