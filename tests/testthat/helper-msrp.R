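# Independent brute-force recurrence matrix: double loop over all state
# pairs, no shared code with the package's vectorized path. Sums
# accumulate term by term in double precision (not base::sum's extended
# accumulator) so agreement with the package can be checked exactly.
brute_force_rp <- function(states, norm) {
  states <- unclass(states)
  n <- nrow(states)
  m <- ncol(states)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- states[i, ] - states[j, ]
    acc <- 0
    for (k in seq_len(m)) {
      acc <- switch(norm,
                    l1 = acc + abs(d[k]),
                    l2 = ,
                    l2sq = acc + d[k]^2,
                    linf = max(acc, abs(d[k])))
    }
    out[i, j] <- if (norm == "l2") sqrt(acc) else acc
  }
  out
}

# Tiny linearly separable two-class image set: bright top half vs bright
# bottom half, plus mild noise.
toy_image_set <- function(n_per_class = 10, side = 8, seed = 1) {
  set.seed(seed)
  imgs <- array(0, c(side, side, 2 * n_per_class))
  h <- side %/% 2
  for (i in seq_len(n_per_class)) {
    imgs[seq_len(h), , i] <- 1
    imgs[(h + 1):side, , n_per_class + i] <- 1
  }
  imgs <- imgs + array(stats::rnorm(side * side * 2 * n_per_class, sd = 0.1),
                       dim(imgs))
  list(images = imgs, labels = rep(1:2, each = n_per_class))
}

fast_cfg <- function(epochs = 30, seed = 1, batch_size = 8, n_repeats = 1)
  train_config(learning_rate = 1e-3, epochs = epochs, batch_size = batch_size,
               n_repeats = n_repeats, seed = seed)
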