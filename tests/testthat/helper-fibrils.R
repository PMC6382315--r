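# Shared fixtures and independent oracles, built in code at test time.

straight_rod <- function(L = 600, heading = 0, origin = c(0, 0)) {
  build_polyline(L, origin = origin, heading = heading)
}

# A reproducible irregular test chain with a few kinks.
zigzag_chain <- function() {
  build_polyline(c(150, 200, 120, 130),
                 kink_angles = c(65, 30, 110),
                 signs = c(1L, -1L, 1L))
}

sign_population <- function(n, n_k, p) {
  lapply(seq_len(n), function(i) sample_signs(n_k, p))
}

# Independent oracle for <|sum s_i|>: enumerate every sign SEQUENCE (not
# agreement pattern) with its Markov-chain probability.
markov_sign_sum_oracle <- function(n_k, p) {
  seqs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_k)))
  tot <- 0
  for (r in seq_len(nrow(seqs))) {
    s <- seqs[r, ]
    pr <- 0.5
    if (n_k > 1)
      for (i in 2:n_k) pr <- pr * if (s[i] == s[i - 1]) p else 1 - p
    tot <- tot + pr * abs(sum(s))
  }
  tot
}

# Vectorized proper-intersection test for segment pairs (a1-a2 vs b1-b2);
# collinear contacts have measure zero under the random placements used.
segments_cross <- function(a1, a2, b1, b2) {
  cr <- function(o, p, q) {
    (p[, 1] - o[, 1]) * (q[, 2] - o[, 2]) -
      (p[, 2] - o[, 2]) * (q[, 1] - o[, 1])
  }
  d1 <- cr(b1, b2, a1)
  d2 <- cr(b1, b2, a2)
  d3 <- cr(a1, a2, b1)
  d4 <- cr(a1, a2, b2)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

# Monte-Carlo excluded area of two thin rods of length L at isotropic
# relative orientation: area of the COM box times the overlap probability.
mc_excluded_area <- function(L, n = 2e5) {
  phi <- runif(n, 0, pi)
  cx <- runif(n, -L, L)
  cy <- runif(n, -L, L)
  a1 <- cbind(rep(-L / 2, n), 0)
  a2 <- cbind(rep(L / 2, n), 0)
  dx <- (L / 2) * cos(phi)
  dy <- (L / 2) * sin(phi)
  hit <- segments_cross(a1, a2, cbind(cx - dx, cy - dy),
                        cbind(cx + dx, cy + dy))
  mean(hit) * (2 * L)^2
}
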