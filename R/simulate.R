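#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the CAP pipeline assumes:
#' Markov-switching latent brain states with fixed z-scaled spatial patterns
#' (two anti-correlated pattern pairs `I+/I-`, `II+/II-` plus an extra state
#' `III`), subject-specific transition structure (trait variance on
#' self-transition logits), day-specific perturbations (state variance), a
#' subgroup C possessing the extra state, FD spike processes, and behavioral
#' variables driven by latent neural factors.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param n_parcels Number of parcels (default 64).
#' @param n_runs Runs per day (default 2).
#' @param frames_per_run Frames per run (default 200).
#' @param tr Seconds per frame (default 0.72).
#' @param p_stay Baseline self-transition probability of each state
#'   (default 0.8, i.e. expected dwell time 5 frames).
#' @param trait_sd SD of the per-subject, per-state self-transition logit
#'   effect: the between-subject (trait) variance dial (default 0.8, so
#'   between-subject occupancy spread dominates within-day sampling error of
#'   FO at the default run lengths).
#' @param day_sd SD of the per-day perturbation of the same logits: the
#'   within-subject (state) variance dial (default 0.25).
#' @param frac_subgroup_C Fraction of subjects whose chains include the extra
#'   state III (default 0.3); the remainder is split into subgroups A and B.
#' @param subgroup_shift Logit shift separating subgroup B's state
#'   persistence from subgroup A's (default 0.7), so the neural feature space
#'   has recoverable subgroup structure beyond the presence of state III.
#' @param snr Pattern amplitude over unit noise SD (default 1).
#' @param extra_state_snr Amplitude multiplier for the extra state III
#'   relative to `snr` (default 0.5): the extra state is expressed more
#'   weakly than the base states, so its detectability in a split depends on
#'   how many subgroup-C subjects the split contains.
#' @param fd_baseline,fd_sd Mean and SD of the low-motion FD floor in mm
#'   (defaults 0.15 and 0.05).
#' @param fd_spike_rate Per-frame probability of a motion spike (default 0.02).
#' @param fd_spike_magnitude Mean magnitude added to FD during a spike, mm
#'   (default 0.8, i.e. above the 0.5 mm scrubbing threshold).
#' @param n_behavior Number of behavioral variables (default 40).
#' @param n_latent Number of latent neural factors driving behavior (default 3).
#' @param behavior_noise_sd Noise SD added to each behavioral variable
#'   (default 1).
#' @param behavior_effect Scale of the factor-to-behavior loadings (default 1).
#' @param n_rt Number of behavioral variables emitted as positive
#'   reaction-time-like measures (default 5).
#' @param sex_effect SD of per-variable sex loadings (default 0.5).
#' @param seed Master seed; every random draw derives from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 20L, n_parcels = 64L, n_runs = 2L,
                       frames_per_run = 200L, tr = 0.72,
                       p_stay = 0.8, trait_sd = 0.8, day_sd = 0.25,
                       frac_subgroup_C = 0.3, subgroup_shift = 0.7,
                       snr = 1, extra_state_snr = 0.5,
                       fd_baseline = 0.15, fd_sd = 0.05,
                       fd_spike_rate = 0.02, fd_spike_magnitude = 0.8,
                       n_behavior = 40L, n_latent = 3L,
                       behavior_noise_sd = 1, behavior_effect = 1,
                       n_rt = 5L, sex_effect = 0.5,
                       seed = 1L) {
  stopifnot_scalar_number(p_stay, "p_stay", 0, 1)
  stopifnot_scalar_number(frac_subgroup_C, "frac_subgroup_C", 0, 1)
  stopifnot_scalar_number(fd_spike_rate, "fd_spike_rate", 0, 1)
  if (snr < 0) abort("`snr` must be >= 0")
  if (trait_sd < 0 || day_sd < 0) abort("`trait_sd` and `day_sd` must be >= 0")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Stationary distribution of a row-stochastic transition matrix
#'
#' @param transition K x K row-stochastic matrix.
#' @return Numeric vector of stationary probabilities (sums to 1).
#' @export
stationary_distribution <- function(transition) {
  check_stochastic(transition)
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

check_stochastic <- function(transition, tol = 1e-8) {
  if (!is.matrix(transition) || nrow(transition) != ncol(transition)) {
    abort("`transition` must be a square matrix")
  }
  if (any(transition < -tol) || any(abs(rowSums(transition) - 1) > tol)) {
    abort("`transition` rows must be non-negative and sum to 1")
  }
  invisible(transition)
}

#' Sample a latent state sequence from a Markov chain
#'
#' The first state is drawn from the chain's stationary distribution, so the
#' sequence is stationary from frame one and the expected fractional
#' occupancy of state `i` equals its stationary probability; the expected
#' dwell time of state `i` is `1 / (1 - transition[i, i])`.
#'
#' @param transition K x K row-stochastic matrix.
#' @param n_frames Sequence length (>= 1).
#' @param seed Optional seed.
#'
#' @return Integer vector of state labels in `1:K`.
#' @export
sample_state_sequence <- function(transition, n_frames, seed = NULL) {
  check_stochastic(transition)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) abort("`n_frames` must be >= 1")
  k <- nrow(transition)
  with_seed_(seed, {
    out <- integer(n_frames)
    out[1] <- sample.int(k, 1L, prob = stationary_distribution(transition))
    if (n_frames > 1L) {
      for (t in 2:n_frames) {
        out[t] <- sample.int(k, 1L, prob = transition[out[t - 1L], ])
      }
    }
    out
  })
}

#' Render BOLD-like frames from a state sequence
#'
#' Frame `t` is `snr * patterns[state_t, ] + e_t` with `e_t` i.i.d. standard
#' Gaussian per parcel.
#'
#' @param states Integer label sequence indexing rows of `patterns`.
#' @param patterns K x P matrix of spatial patterns.
#' @param snr Pattern amplitude relative to unit noise; either a scalar or
#'   one value per state (row of `patterns`).
#' @param seed Optional seed.
#'
#' @return frames x parcels numeric matrix.
#' @export
render_frames <- function(states, patterns, snr = 1, seed = NULL) {
  states <- as.integer(states)
  if (any(states < 1L | states > nrow(patterns))) {
    abort("`states` contains labels outside 1:nrow(patterns)")
  }
  amp <- rep_len(snr, nrow(patterns))
  with_seed_(seed, {
    noise <- matrix(rnorm(length(states) * ncol(patterns)),
                    nrow = length(states))
    amp[states] * patterns[states, , drop = FALSE] + noise
  })
}

# Two anti-correlated pairs plus one extra state, all z-scaled across parcels.
make_patterns <- function(n_parcels, seed) {
  with_seed_(seed, {
    zrow <- function() as.numeric(scale(rnorm(n_parcels)))
    ip <- zrow(); iip <- zrow(); iii <- zrow()
    p <- rbind(ip, -ip, iip, -iip, iii)
    rownames(p) <- c("I+", "I-", "II+", "II-", "III")
    p
  })
}

# Per subject-day transition matrix from baseline + trait + day logit effects.
build_transition <- function(state_idx, base_logit, trait_eff, day_eff) {
  k <- length(state_idx)
  p_self <- plogis(base_logit + trait_eff[state_idx] + day_eff[state_idx])
  t_mat <- matrix(0, k, k)
  for (i in seq_len(k)) {
    t_mat[i, ] <- (1 - p_self[i]) / (k - 1)
    t_mat[i, i] <- p_self[i]
  }
  t_mat
}

fd_series <- function(n, cfg, seed) {
  with_seed_(seed, {
    base <- abs(rnorm(n, cfg$fd_baseline, cfg$fd_sd))
    spikes <- rbinom(n, 1L, cfg$fd_spike_rate) *
      abs(rnorm(n, cfg$fd_spike_magnitude, 0.1))
    base + spikes
  })
}

#' Generate a full synthetic cohort with ground truth
#'
#' Subjects are partitioned into subgroups A, B and C. Subgroup C's chains
#' include the extra state III; A and B use the four base states only, and
#' differ by a persistence shift (`subgroup_shift`) on the self-transition
#' logits. Each subject receives per-state trait effects
#' `~ Normal(0, trait_sd)`; each day perturbs them by `~ Normal(0, day_sd)`.
#' FD is a low-motion floor plus Bernoulli-placed spikes. The full generating
#' truth (patterns, transition matrices, stationary distributions, state
#' sequences, subgroup labels) is returned for parameter-recovery tests.
#'
#' @param config A [sim_config()].
#'
#' @return List with elements `cohort` ([cap_cohort()]), `ground_truth`,
#'   `behavior` (tibble) and `behavior_meta` (tibble).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 6L)
  patterns <- make_patterns(cfg$n_parcels, seeds[1])
  state_labels <- rownames(patterns)

  ids <- sprintf("S%03d", seq_len(cfg$n_subjects))
  n_c <- round(cfg$frac_subgroup_C * cfg$n_subjects)
  n_b <- floor((cfg$n_subjects - n_c) / 2)
  subgroup <- with_seed_(seeds[2], sample(c(
    rep("C", n_c), rep("B", n_b), rep("A", cfg$n_subjects - n_c - n_b)
  )))
  names(subgroup) <- ids

  base_logit <- qlogis(cfg$p_stay)
  subj_seeds <- derive_seeds(seeds[3], cfg$n_subjects)

  series <- list()
  transitions <- list()
  stationary <- list()
  sequences <- list()
  for (s in seq_along(ids)) {
    id <- ids[s]
    state_idx <- if (subgroup[id] == "C") 1:5 else 1:4
    k <- length(state_idx)
    sseeds <- derive_seeds(subj_seeds[s], 4L + 2L * 2L * cfg$n_runs)
    trait_eff <- with_seed_(sseeds[1], rnorm(5, 0, cfg$trait_sd)) +
      if (subgroup[id] == "B") cfg$subgroup_shift else 0
    run_seed_i <- 4L
    for (day in 1:2) {
      day_eff <- with_seed_(sseeds[1 + day], rnorm(5, 0, cfg$day_sd))
      t_mat <- build_transition(state_idx, base_logit, trait_eff, day_eff)
      transitions[[paste(id, day, sep = ".")]] <- t_mat
      stationary[[paste(id, day, sep = ".")]] <-
        setNames(stationary_distribution(t_mat), state_labels[state_idx])
      run_states <- list(); run_data <- list(); run_fd <- list()
      for (r in seq_len(cfg$n_runs)) {
        run_seed_i <- run_seed_i + 1L
        rs <- derive_seeds(sseeds[run_seed_i], 3L)
        st_local <- sample_state_sequence(t_mat, cfg$frames_per_run, rs[1])
        st <- state_idx[st_local]
        run_states[[r]] <- st
        run_data[[r]] <- render_frames(
          st, patterns, cfg$snr * c(1, 1, 1, 1, cfg$extra_state_snr), rs[2])
        run_fd[[r]] <- fd_series(cfg$frames_per_run, cfg, rs[3])
      }
      ends <- cumsum(lengths(run_states))
      ts <- parcel_ts(
        subject_id = id, day = day,
        data = do.call(rbind, run_data),
        runs = tibble::tibble(run = seq_len(cfg$n_runs),
                              start = c(1L, head(ends, -1L) + 1L), end = ends),
        fd = unlist(run_fd), tr = cfg$tr
      )
      series[[length(series) + 1L]] <- ts
      sequences[[paste(id, day, sep = ".")]] <- unlist(run_states)
    }
  }

  covariates <- with_seed_(seeds[4], tibble::tibble(
    subject_id = ids,
    age = sample(22:36, cfg$n_subjects, replace = TRUE),
    sex = sample(c("F", "M"), cfg$n_subjects, replace = TRUE)
  ))

  ground_truth <- list(
    patterns = patterns,
    state_labels = state_labels,
    transition_matrices = transitions,
    stationary = stationary,
    state_sequences = sequences,
    subgroup = subgroup,
    config = cfg,
    seeds = seeds
  )

  beh <- generate_behavior(ground_truth, covariates, cfg, seed = seeds[5])
  ground_truth$behavioral_loadings <- beh$loadings
  ground_truth$latent_factors <- beh$factors

  list(
    cohort = cap_cohort(series, covariates),
    ground_truth = ground_truth,
    behavior = beh$table,
    behavior_meta = beh$meta
  )
}

#' Generate behavioral variables from latent neural factors
#'
#' Latent factors are per-subject summaries of the generating chains
#' (averaged over days): the stationary-occupancy contrast between CAP-I and
#' CAP-II states, overall state persistence (mean self-transition
#' probability), and the stationary occupancy of state III. Each behavioral
#' variable is a linear combination of the first `n_latent` factors plus
#' Gaussian noise and a per-variable sex loading; the last `n_rt` variables
#' are emitted as positive reaction-time-like measures (larger latent score
#' means a faster, i.e. smaller, RT) to exercise the 1/RT transform.
#'
#' @param ground_truth Ground-truth list from [generate_cohort()].
#' @param covariates Tibble with `subject_id`, `age`, `sex`.
#' @param config The [sim_config()].
#' @param seed Seed.
#'
#' @return List with `table` (tibble, `subject_id` + variables), `meta`
#'   (variable, domain, is_rt), `loadings`, `factors`.
#' @export
generate_behavior <- function(ground_truth, covariates, config, seed = NULL) {
  cfg <- config
  if (cfg$n_behavior < cfg$n_latent) {
    abort("`n_behavior` must be >= `n_latent`")
  }
  ids <- covariates$subject_id
  fac <- t(vapply(ids, function(id) {
    pis <- lapply(1:2, function(d) {
      pi_d <- ground_truth$stationary[[paste(id, d, sep = ".")]]
      full <- setNames(numeric(5), ground_truth$state_labels)
      full[names(pi_d)] <- pi_d
      full
    })
    pi_avg <- (pis[[1]] + pis[[2]]) / 2
    t_diag <- mean(vapply(1:2, function(d) {
      mean(diag(ground_truth$transition_matrices[[paste(id, d, sep = ".")]]))
    }, 1))
    c(cap1_vs_cap2 = unname(pi_avg["I+"] + pi_avg["I-"] - pi_avg["II+"] - pi_avg["II-"]),
      persistence = t_diag,
      cap3_occupancy = unname(pi_avg["III"]))
  }, numeric(3)))
  fac <- scale(fac)
  fac[is.nan(fac)] <- 0  # degenerate when a factor is constant (e.g. no C subjects)
  fac <- fac[, seq_len(cfg$n_latent), drop = FALSE]

  with_seed_(seed, {
    loadings <- matrix(rnorm(cfg$n_behavior * cfg$n_latent, 0, cfg$behavior_effect),
                       nrow = cfg$n_behavior)
    sex_load <- rnorm(cfg$n_behavior, 0, cfg$sex_effect)
    raw <- fac %*% t(loadings) +
      outer(as.numeric(covariates$sex == "M"), sex_load) +
      matrix(rnorm(length(ids) * cfg$n_behavior, 0, cfg$behavior_noise_sd),
             nrow = length(ids))
    vars <- sprintf("v%03d", seq_len(cfg$n_behavior))
    is_rt <- seq_len(cfg$n_behavior) > cfg$n_behavior - cfg$n_rt
    # RT-like variables: positive, decreasing in the latent score
    raw[, is_rt] <- exp(1 - 0.5 * raw[, is_rt, drop = FALSE])
    tab <- tibble::as_tibble(raw, .name_repair = "minimal")
    names(tab) <- vars
    tab <- dplyr::bind_cols(tibble::tibble(subject_id = ids), tab)
    meta <- tibble::tibble(
      variable = vars,
      domain = ifelse(is_rt, "task_rt",
                      rep(c("cognition", "emotion", "substance_use"),
                          length.out = cfg$n_behavior)),
      is_rt = is_rt
    )
    list(table = tab, meta = meta, loadings = loadings, factors = fac)
  })
}
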