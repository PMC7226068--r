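# Programmatic fixtures shared across tests.

ball_mask <- function(r, n = 2 * r + 5, spacing = c(1, 1, 1)) {
  ctr <- (n + 1) / 2
  axs <- lapply(spacing, function(s) ((1:n) - ctr) * s)
  d2 <- outer(outer(axs[[1]]^2, axs[[2]]^2, `+`), axs[[3]]^2, `+`)
  d2 <= r^2
}

ellipsoid_mask <- function(radii, n = 33) {
  ctr <- (n + 1) / 2
  ax <- (1:n) - ctr
  d2 <- outer(outer((ax / radii[1])^2, (ax / radii[2])^2, `+`),
              (ax / radii[3])^2, `+`)
  d2 <= 1
}

# 4x4x1 two-level checkerboard volume (values 0/100) with full mask
checkerboard_4x4 <- function() {
  v <- array(0, c(4, 4, 1))
  for (x in 1:4) for (y in 1:4) v[x, y, 1] <- ((x + y) %% 2) * 100
  list(intensities = v, mask = array(TRUE, c(4, 4, 1)))
}

random_volume <- function(n = 8, seed = 1, n_levels = NULL) {
  set.seed(seed)
  v <- array(rnorm(n^3, 50, 30), c(n, n, n))
  if (!is.null(n_levels)) {
    v <- array(sample(seq_len(n_levels), n^3, replace = TRUE) * 10,
               c(n, n, n))
  }
  mask <- array(runif(n^3) < 0.7, c(n, n, n))
  if (!any(mask)) mask[1, 1, 1] <- TRUE
  list(intensities = v, mask = mask)
}

small_cohort <- function(n = 8, seed = 5, ...) {
  generate_cohort(cohort_spec(n_patients = n, seed = seed, ...))
}

# two-group exponential survival with a planted hazard ratio
planted_hr_outcomes <- function(n_per_group, hr, base_rate = 0.02,
                                cens_rate = 0.005, seed = 1) {
  set.seed(seed)
  group <- rep(c(0, 1), each = n_per_group)
  t_ev <- rexp(2 * n_per_group, rate = base_rate * hr^group)
  t_cn <- rexp(2 * n_per_group, rate = cens_rate)
  list(
    scores = group + rnorm(2 * n_per_group, sd = 0.01),
    outcomes = data.frame(time = pmin(t_ev, t_cn),
                          event = as.integer(t_ev <= t_cn)),
    group = group
  )
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
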