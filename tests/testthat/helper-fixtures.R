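# Shared fixtures, all generated in code.

# A small hand-checkable grid: 3 rt x 4 dt with known values.
tiny_grid <- function() {
  chromatogram_grid(
    rt_axis = c(1, 2, 3),
    dt_axis = c(10, 20, 30, 40),
    intensity = matrix(
      c(
        1, 5, 3, 0,
        2, 8, 1, 4,
        0, 6, 7, 2
      ),
      nrow = 3, byrow = TRUE
    )
  )
}

# Down-scaled cohort design: small grid, few peaks; fast enough for unit
# tests while exercising every generator code path.
small_design <- function(n_per_class = c(term = 4, preterm = 6), seed = 42,
                         noise_sd = 0.5, ...) {
  rt <- seq(0, 100, length.out = 30)
  dt <- seq(6, 10, length.out = 200)
  peaks <- with_test_seed(seed, lapply(1:8, function(i) {
    peak_spec(
      rt_center = runif(1, 20, 80), dt_center = runif(1, 7, 9.5),
      rt_sigma = runif(1, 2, 5), dt_sigma = runif(1, 0.05, 0.15),
      amplitude = runif(1, 5, 15)
    )
  }))
  cohort_design(
    n_per_class = n_per_class, peaks = peaks,
    rip_spec = peak_spec(0, 6.5, 1, 0.03, 30),
    noise_sd = noise_sd, baseline_drift = 0.002,
    rt_axis = rt, dt_axis = dt, seed = seed, ...
  )
}

small_crop <- function() crop_window(10, 90, 6.8, 9.8)

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Brute-force oracle: two-sided exact rank-sum p by enumeration of all
# C(m+n, m) rank assignments (independent of the DP in the package).
enum_ranksum_p <- function(x, y) {
  m <- length(x)
  n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, function(idx) sum(idx) - m * (m + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Brute-force AUC oracle: pair counting with half credit for ties.
pair_auc <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Factorial-based Fisher oracle: enumerate all 2x2 tables with the observed
# margins, exact table probabilities from log-factorials.
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  c2 <- b + d
  n <- r1 + r2
  lp <- function(a2) {
    b2 <- r1 - a2
    c2_ <- c1 - a2
    d2 <- r2 - c2_
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(c2 + 1) -
      lgamma(n + 1) - lgamma(a2 + 1) - lgamma(b2 + 1) - lgamma(c2_ + 1) - lgamma(d2 + 1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  logs <- vapply(support, lp, numeric(1))
  probs <- exp(logs)
  sum(probs[probs <= exp(lp(a)) * (1 + 1e-7)])
}
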