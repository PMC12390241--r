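# Independent optimization oracle for the L1-wavelet objective: plain
# proximal gradient (ISTA, no momentum, no restarts) built from the exported
# transforms, run far past convergence.

toy_objective <- function(x, y, m, lam) {
  r <- (image_to_kspace(x) - y) * m
  wr <- dwt2(Re(x), 4); wi <- dwt2(Im(x), 4)
  0.5 * sum(Mod(r)^2) + lam * sum(sqrt(wr^2 + wi^2))
}

ista_oracle <- function(x0, y, m, lam, iters = 4000) {
  n <- nrow(x0)
  x <- x0
  for (k in seq_len(iters)) {
    g <- kspace_to_image((image_to_kspace(x) - y) * m)
    v <- x - g
    wr <- dwt2(Re(v), 4); wi <- dwt2(Im(v), 4)
    a <- sqrt(wr^2 + wi^2)
    sh <- ifelse(a > lam, 1 - lam / a, 0)
    x <- matrix(complex(real = idwt2(wr * sh, 4),
                        imaginary = idwt2(wi * sh, 4)), n, n)
  }
  x
}
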