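#' Configure a synthetic larval-growth training experiment
#'
#' Specifies the stochastic structure of a cohort rearing experiment: cohorts
#' of known age, a unimodal mean growth curve, multiplicative individual
#' heterogeneity in growth rate, measurement noise, and stage (instar)
#' determined by developmental progress with jittered stage boundaries.
#'
#' The heterogeneity is multiplicative on the developmental clock: each
#' individual carries a lognormal rate multiplier, and its size and stage
#' are read off the mean curve at \code{age * multiplier * group_shift}.
#' This is the simplest structure under which selecting the largest
#' individuals of a cohort selects intrinsically fast developers, the
#' mechanism by which size-biased training samples break inverse prediction.
#'
#' @param cohort_ages sampled ages in hours, strictly increasing.
#' @param n_per_cohort individuals reared per cohort.
#' @param mean_curve list with \code{family} and parameters.
#'   \code{"logistic"}: \code{asymptote} (mm), \code{rate} (per h),
#'   \code{inflection} (h) — a saturating rise.  \code{"rise_then_fall"}:
#'   \code{asymptote} (peak size, mm), \code{decline_onset} (peak age, h),
#'   \code{rate} and \code{decline_rate} (curvatures, mm/h^2) — a quadratic
#'   spline rising to the peak and falling after it (post-feeding
#'   shrinkage), floored at 0; equal curvatures give an exact quadratic.
#' @param individual_sd sd of the lognormal growth-rate multiplier
#'   (0 = identical individuals).
#' @param measurement_sd measurement noise sd, mm.
#' @param stage_boundaries increasing developmental-age thresholds (h)
#'   separating successive stages (length s - 1 for s stages).
#' @param stage_labels labels of the s stages; default instar1..instarS.
#' @param boundary_jitter_sd per-individual jitter sd (h) on each boundary.
#' @param width_scale width is simulated as \code{width_scale} times the
#'   mean curve at the same developmental age, with its own noise.
#' @param group_shift growth-rate multiplier applied to the whole
#'   population, for covariate (e.g. diet) experiments; default 1.
#' @param n_eval_per_cohort held-out evaluation individuals per cohort.
#' @param seed integer seed; mandatory, the experiment is fully reproducible.
#' @return validated config of class \code{"growth_sim_config"}.
#' @export
growth_sim_config <- function(cohort_ages = seq(12, 96, by = 12),
                              n_per_cohort = 100L,
                              mean_curve = list(family = "logistic",
                                                asymptote = 16, rate = 0.07,
                                                inflection = 36),
                              individual_sd = 0.05,
                              measurement_sd = 1.0,
                              stage_boundaries = c(18, 36, 90, 200),
                              stage_labels = c("instar1", "instar2",
                                               "instar3", "pupa", "adult"),
                              boundary_jitter_sd = 3,
                              width_scale = 0.22,
                              group_shift = 1,
                              n_eval_per_cohort = 0L,
                              seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("'seed' is mandatory", call. = FALSE)
  stopifnot(length(cohort_ages) >= 1L, all(cohort_ages > 0),
            !is.unsorted(cohort_ages, strictly = TRUE),
            n_per_cohort >= 1, individual_sd >= 0, measurement_sd >= 0,
            boundary_jitter_sd >= 0, width_scale > 0, group_shift > 0,
            n_eval_per_cohort >= 0,
            !is.unsorted(stage_boundaries, strictly = TRUE))
  mean_curve$family <- match.arg(mean_curve$family,
                                 c("logistic", "rise_then_fall"))
  need <- if (mean_curve$family == "logistic")
    c("asymptote", "rate", "inflection")
  else c("asymptote", "rate", "decline_onset", "decline_rate")
  if (!all(need %in% names(mean_curve)))
    stop("mean_curve needs: ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(stage_labels))
    stage_labels <- paste0("instar", seq_len(length(stage_boundaries) + 1L))
  if (length(stage_labels) != length(stage_boundaries) + 1L)
    stop("need one more stage label than boundaries", call. = FALSE)
  structure(list(cohort_ages = as.numeric(cohort_ages),
                 n_per_cohort = as.integer(n_per_cohort),
                 mean_curve = mean_curve,
                 individual_sd = individual_sd,
                 measurement_sd = measurement_sd,
                 stage_boundaries = as.numeric(stage_boundaries),
                 stage_labels = as.character(stage_labels),
                 boundary_jitter_sd = boundary_jitter_sd,
                 width_scale = width_scale, group_shift = group_shift,
                 n_eval_per_cohort = as.integer(n_eval_per_cohort),
                 seed = as.integer(seed)),
            class = "growth_sim_config")
}

#' Mean growth curve of a simulation config
#'
#' @param config a [growth_sim_config()].
#' @param age developmental age(s), hours.
#' @return mean length (mm) at each age.
#' @export
mean_growth_curve <- function(config, age) {
  mc <- config$mean_curve
  if (mc$family == "logistic") {
    mc$asymptote / (1 + exp(-mc$rate * (age - mc$inflection)))
  } else {
    dev <- age - mc$decline_onset
    curv <- ifelse(dev <= 0, mc$rate, mc$decline_rate)
    pmax(mc$asymptote - curv * dev^2, 0)
  }
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

simulate_growth_individuals <- function(config, n_per_cohort, id_prefix) {
  ages <- rep(config$cohort_ages, each = n_per_cohort)
  n <- length(ages)
  mult <- exp(rnorm(n, 0, config$individual_sd))
  dev_age <- ages * mult * config$group_shift
  len <- mean_growth_curve(config, dev_age) + rnorm(n, 0, config$measurement_sd)
  wid <- config$width_scale *
    (mean_growth_curve(config, dev_age) +
       rnorm(n, 0, config$measurement_sd))
  clipped <- sum(len < 0) + sum(wid < 0)
  if (clipped > 0)
    message(clipped, " negative simulated measurement(s) clipped at 0")
  len <- pmax(len, 0); wid <- pmax(wid, 0)
  nb <- length(config$stage_boundaries)
  bounds <- matrix(rep(config$stage_boundaries, each = n), n, nb) +
    matrix(rnorm(n * nb, 0, config$boundary_jitter_sd), n, nb)
  stage_idx <- rowSums(dev_age > bounds) + 1L
  data.frame(specimen_id = paste0(id_prefix, seq_len(n)),
             condition = ages, length = len, width = wid,
             stage = config$stage_labels[stage_idx],
             rate_multiplier = mult,
             stringsAsFactors = FALSE)
}

#' Simulate a larval-growth training experiment
#'
#' Draws the full rearing experiment described by a [growth_sim_config()]:
#' per individual a lognormal rate multiplier, length and width read off the
#' mean curve at the individual's developmental age plus Gaussian
#' measurement noise, and an instar assigned from jittered stage boundaries
#' on the developmental-age axis.  Negative simulated measurements are
#' clipped at 0 with a message.  The same seed always reproduces the same
#' tables (Mersenne-Twister, inversion normals).
#'
#' @param config a [growth_sim_config()].
#' @return list with \code{training} and (if requested) \code{evaluation}
#'   data frames, columns \code{specimen_id}, \code{condition} (true age,
#'   h), \code{length}, \code{width} (mm), \code{stage}, and the latent
#'   \code{rate_multiplier}; plus \code{config}.
#' @export
simulate_growth_cohorts <- function(config) {
  stopifnot(inherits(config, "growth_sim_config"))
  with_seed(config$seed, {
    training <- simulate_growth_individuals(config, config$n_per_cohort, "td_")
    evaluation <- if (config$n_eval_per_cohort > 0L)
      simulate_growth_individuals(config, config$n_eval_per_cohort, "ev_")
  })
  list(training = training, evaluation = evaluation, config = config)
}

#' Configure a synthetic carrion-succession experiment
#'
#' Each species occupies a carcass over a stochastic window: its onset and
#' departure days are independent normal draws (redrawn jointly if the
#' departure precedes the onset), and it is scored present at an observation
#' time falling inside the window.  With s species scored present/absent
#' the categorical response scheme has \code{c = 2^s} categories.
#'
#' @param species named list; each element a list with \code{onset_mean},
#'   \code{onset_sd}, \code{departure_mean}, \code{departure_sd} (days).
#' @param n_carcasses number of experimental carcasses.
#' @param observation_times observation days, strictly increasing.
#' @param seed integer seed; mandatory.
#' @return validated config of class \code{"succession_sim_config"}.
#' @export
succession_sim_config <- function(species, n_carcasses = 20L,
                                  observation_times = 1:14, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("'seed' is mandatory", call. = FALSE)
  stopifnot(length(species) >= 1L, n_carcasses >= 1,
            !is.unsorted(observation_times, strictly = TRUE))
  if (is.null(names(species)))
    names(species) <- paste0("sp", seq_along(species))
  for (sp in species) {
    if (!all(c("onset_mean", "onset_sd", "departure_mean", "departure_sd")
             %in% names(sp)))
      stop("each species needs onset_mean/sd and departure_mean/sd",
           call. = FALSE)
    if (sp$onset_sd < 0 || sp$departure_sd < 0 ||
        sp$departure_mean <= sp$onset_mean)
      stop("degenerate occupancy window", call. = FALSE)
  }
  structure(list(species = species, n_carcasses = as.integer(n_carcasses),
                 observation_times = as.numeric(observation_times),
                 seed = as.integer(seed)),
            class = "succession_sim_config")
}

#' Simulate presence/absence succession data
#'
#' @param config a [succession_sim_config()].
#' @return list with \code{observations} (long data frame: one row per
#'   carcass per observation time, one 0/1 column per species, and
#'   \code{category}, the concatenated presence pattern), \code{scheme}
#'   (the full \code{2^s}-category [category_scheme()]), and \code{config}.
#' @export
simulate_succession <- function(config) {
  stopifnot(inherits(config, "succession_sim_config"))
  s <- length(config$species)
  nm <- names(config$species)
  with_seed(config$seed, {
    windows <- lapply(config$species, function(sp) {
      on <- rnorm(config$n_carcasses, sp$onset_mean, sp$onset_sd)
      off <- rnorm(config$n_carcasses, sp$departure_mean, sp$departure_sd)
      bad <- which(off < on)
      while (length(bad)) {
        on[bad] <- rnorm(length(bad), sp$onset_mean, sp$onset_sd)
        off[bad] <- rnorm(length(bad), sp$departure_mean, sp$departure_sd)
        bad <- bad[off[bad] < on[bad]]
      }
      cbind(onset = on, departure = off)
    })
  })
  grid <- expand.grid(carcass_id = seq_len(config$n_carcasses),
                      time = config$observation_times)
  pres <- sapply(seq_len(s), function(j) {
    w <- windows[[j]]
    as.integer(w[grid$carcass_id, "onset"] <= grid$time &
                 grid$time <= w[grid$carcass_id, "departure"])
  })
  pres <- matrix(pres, ncol = s, dimnames = list(NULL, nm))
  ord <- order(grid$time, grid$carcass_id)
  obs <- data.frame(carcass_id = paste0("carcass_", grid$carcass_id),
                    time = grid$time, pres, check.names = FALSE,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(obs) <- NULL
  obs$category <- apply(obs[, nm, drop = FALSE], 1L, paste, collapse = "")
  all_patterns <- apply(as.matrix(expand.grid(rep(list(0:1), s))), 1L,
                        paste, collapse = "")
  list(observations = obs,
       scheme = category_scheme(sort(all_patterns)),
       config = config)
}
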