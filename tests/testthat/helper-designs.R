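# Shared fixtures: the complementary design pair used throughout, and
# counts built from a known prevalence via the forward model.

d_ecwm1 <- ecwm_design(0.256, "ECWM1")
d_ecwm2 <- ecwm_design(0.744, "ECWM2")

# counts whose observed option-A proportion equals the model's expectation
# at prevalence pi (n_a may be fractional by construction)
counts_at <- function(pi, design, n) {
  response_counts(lambda_expected(pi, design) * n, n)
}

# independent brute-force oracle for the option-A probability: enumerate
# the four branches of the crosswise tree (carrier x randomiser) and sum
lambda_tree <- function(pi, p) {
  pi * p +               # carrier, randomiser "Yes": answers match -> A
    (1 - pi) * (1 - p)   # non-carrier, randomiser "No": answers match -> A
}

# independent grid-search maximiser of the joint two-group binomial
# log-likelihood over the whole admissible prevalence interval (both group
# option-A probabilities inside (0,1); the maximiser may fall outside
# [0,1]): coarse pass at step 1e-4, then an exhaustive fine grid at step
# 1e-7 around the coarse winner (the log-likelihood is concave in pi, so
# the refinement cannot miss the maximiser)
pool_grid_oracle <- function(lh1, n1, p1, lh2, n2, p2) {
  ll <- function(pi) {
    l1 <- (1 - p1) + (2 * p1 - 1) * pi
    l2 <- (1 - p2) + (2 * p2 - 1) * pi
    term <- function(lh, l) {
      out <- rep(-Inf, length(l))
      ok <- l > 0 & l < 1
      xlogy <- function(x, y) if (x == 0) rep(0, length(y)) else x * log(y)
      out[ok] <- xlogy(lh, l[ok]) + xlogy(1 - lh, 1 - l[ok])
      out
    }
    n1 * term(lh1, l1) + n2 * term(lh2, l2)
  }
  eps <- 1e-9
  bnd <- function(p) sort(c((eps - (1 - p)) / (2 * p - 1),
                            ((1 - eps) - (1 - p)) / (2 * p - 1)))
  b1 <- bnd(p1); b2 <- bnd(p2)
  lo <- max(b1[1], b2[1]); hi <- min(b1[2], b2[2])
  g1 <- seq(lo, hi, by = 1e-4)
  best <- g1[which.max(ll(g1))]
  g2 <- seq(max(lo, best - 2e-4), min(hi, best + 2e-4), by = 1e-7)
  g2[which.max(ll(g2))]
}
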