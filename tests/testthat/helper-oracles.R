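# Brute-force maximization of sum_j p_j * BinCDF(m; n, p_j) over the
# probability simplex: a dense grid (plus local refinement) independent of
# the structured-candidate ridge search used by conservative_p_value().
brute_force_sup <- function(n, c, m, grid_step = 0.004) {
  obj <- function(P) rowSums(P * pbinom(m, n, P))
  if (c == 2L) {
    p1 <- seq(0, 1, by = 1e-4)
    v <- obj(cbind(p1, 1 - p1))
    b <- p1[which.max(v)]
    p1f <- seq(max(0, b - 2e-4), min(1, b + 2e-4), length.out = 4001)
    max(v, obj(cbind(p1f, 1 - p1f)))
  } else if (c == 3L) {
    s <- seq(0, 1, by = grid_step)
    g <- expand.grid(p1 = s, p2 = s)
    g <- g[g$p1 + g$p2 <= 1, ]
    v <- obj(cbind(g$p1, g$p2, pmax(0, 1 - g$p1 - g$p2)))
    best <- max(v)
    neg <- function(x) {
      if (any(x < 0) || sum(x) > 1) return(0)
      p <- c(x, 1 - sum(x))
      -sum(p * pbinom(m, n, p))
    }
    for (i in order(v, decreasing = TRUE)[1:20]) {
      o <- optim(c(g$p1[i], g$p2[i]), neg, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 3000))
      best <- max(best, -o$value)
    }
    best
  } else stop("brute force oracle implemented for c in {2, 3}")
}

# Per-cohort subsample of a simulated training table.
subsample_training <- function(td, scheme, s, seed) {
  idx <- unlist(lapply(split(seq_len(nrow(td)), td$condition), function(i)
    i[subsample_cohort(td$length[i], scheme, s, seed = seed)]))
  td[idx, , drop = FALSE]
}

# The two frozen synthetic populations used in the sampling-design and
# covariate-transfer studies (see the methods vignette for rationale).
lesson1_config <- function(seed, n_per_cohort = 100L, n_eval_per_cohort = 0L) {
  growth_sim_config(
    cohort_ages = seq(12, 96, by = 12),
    n_per_cohort = n_per_cohort,
    mean_curve = list(family = "logistic", asymptote = 16, rate = 0.07,
                      inflection = 36),
    individual_sd = 0.05, measurement_sd = 1.0,
    n_eval_per_cohort = n_eval_per_cohort, seed = seed)
}

lesson3_config <- function(seed, group_shift = 1, n_per_cohort = 1000L,
                           n_eval_per_cohort = 0L) {
  growth_sim_config(
    cohort_ages = seq(12, 96, by = 12),
    n_per_cohort = n_per_cohort,
    mean_curve = list(family = "rise_then_fall", asymptote = 16,
                      rate = 0.0032, decline_onset = 78,
                      decline_rate = 0.0012),
    individual_sd = 0.05, measurement_sd = 1.0,
    group_shift = group_shift,
    n_eval_per_cohort = n_eval_per_cohort, seed = seed)
}
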