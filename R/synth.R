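#' Directed hierarchical ground-truth coupling matrix
#'
#' Builds a block-structured coupling matrix emulating a staged, hierarchically
#' organised processing stream: every sampled link from level `k` to level
#' `k + 1` has weight `ff_strength`, its reverse link `ff_strength * fb_ratio`,
#' and within-level links (if any) `lateral_strength`. Feedforward always
#' dominates feedback (`fb_ratio < 1`), which is the directed structure the
#' fitting pipeline is expected to recover. The sparsity pattern (which
#' between-level pairs carry a link) is drawn with probability `p_link` under
#' the given seed, so the same spec reproduces the same matrix.
#'
#' @param level_sizes integer vector of nodes per hierarchy level (>= 2
#'   levels).
#' @param ff_strength feedforward coupling weight (> 0).
#' @param fb_ratio feedback/feedforward ratio in `[0, 1)`.
#' @param lateral_strength within-level coupling weight (default 0: strictly
#'   between-level structure).
#' @param p_link probability that a between-level (or within-level) pair
#'   carries a link.
#' @param seed RNG seed for the sparsity pattern.
#' @return A [coupling_matrix()] with node ids `n01, n02, ...` ordered by
#'   level, and the level assignment attached as attribute `"levels"`.
#' @export
make_ground_truth <- function(level_sizes = c(5, 5, 5, 5), ff_strength = 0.05,
                              fb_ratio = 0.3, lateral_strength = 0,
                              p_link = 0.5, seed = 1) {
  if (length(level_sizes) < 2) stop("need at least 2 levels", call. = FALSE)
  if (!is.numeric(ff_strength) || ff_strength <= 0)
    stop("`ff_strength` must be > 0", call. = FALSE)
  if (fb_ratio < 0 || fb_ratio >= 1)
    stop("`fb_ratio` must be in [0, 1)", call. = FALSE)
  if (lateral_strength < 0)
    stop("`lateral_strength` must be >= 0", call. = FALSE)
  set.seed(seed)
  n <- sum(level_sizes)
  lev <- rep(seq_along(level_sizes), level_sizes)
  C <- matrix(0, n, n)
  for (k in seq_len(length(level_sizes) - 1)) {
    senders <- which(lev == k)
    receivers <- which(lev == k + 1)
    for (j in senders) for (i in receivers) {
      if (runif(1) < p_link) {
        C[i, j] <- ff_strength             # forward j -> i
        C[j, i] <- ff_strength * fb_ratio  # reverse i -> j
      }
    }
    # every region receives input: guarantee at least one forward in-link
    # per receiver (a node with no inputs would sit at its bare local decay,
    # dynamically unlike any cortical region)
    for (i in receivers) {
      if (all(C[i, senders] == 0)) {
        j <- senders[sample.int(length(senders), 1)]
        C[i, j] <- ff_strength
        C[j, i] <- ff_strength * fb_ratio
      }
    }
    # ... and at least one forward out-link per sender, so that with
    # fb_ratio > 0 every sender also receives feedback input
    for (j in senders) {
      if (all(C[receivers, j] == 0)) {
        i <- receivers[sample.int(length(receivers), 1)]
        C[i, j] <- ff_strength
        C[j, i] <- ff_strength * fb_ratio
      }
    }
  }
  if (lateral_strength > 0) {
    for (k in seq_along(level_sizes)) {
      nodes <- which(lev == k)
      for (j in nodes) for (i in nodes) {
        if (i != j && runif(1) < p_link) C[i, j] <- lateral_strength
      }
    }
  }
  out <- coupling_matrix(C)
  attr(out, "levels") <- lev
  out
}

#' Contrast between two hierarchy levels of a ground-truth network
#'
#' Convenience builder for testing directionality recovery: the contrast pools
#' coupling from all nodes of `from_level` to all nodes of `to_level`.
#'
#' @param c_true a [make_ground_truth()] matrix (carries the `"levels"`
#'   attribute).
#' @param from_level,to_level hierarchy levels (sender, receiver).
#' @return A [directional_contrast()].
#' @export
level_contrast <- function(c_true, from_level = 1, to_level = 2) {
  lev <- attr(c_true, "levels")
  if (is.null(lev)) stop("`c_true` has no level attribute", call. = FALSE)
  ids <- rownames(c_true)
  directional_contrast(
    paste0("level ", from_level, " -> level ", to_level),
    ids[lev == from_level], ids[lev == to_level]
  )
}

#' Cohort generation settings
#'
#' @param n_participants cohort size (default 21).
#' @param n_trials independent trials averaged into each participant's
#'   evoked-style series (default 8, one per stimulus block).
#' @param samples_per_trial samples per trial (default 2700, i.e. 2.7 s at
#'   1 kHz).
#' @param dt sampling interval in seconds (default 1 ms).
#' @param participant_jitter relative SD of the multiplicative lognormal
#'   jitter applied per participant to `a`, `f` and the nonzero coupling
#'   entries (default 0.1).
#' @param seed base seed; per-participant seeds are derived deterministically
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 21, n_trials = 8,
                        samples_per_trial = 2700, dt = 1e-3,
                        participant_jitter = 0.1, seed = 1) {
  if (n_participants < 1 || n_trials < 1 || samples_per_trial < 1)
    stop("counts must be >= 1", call. = FALSE)
  if (participant_jitter < 0) stop("`participant_jitter` must be >= 0",
                                   call. = FALSE)
  structure(list(n_participants = as.integer(n_participants),
                 n_trials = as.integer(n_trials),
                 samples_per_trial = as.integer(samples_per_trial), dt = dt,
                 participant_jitter = participant_jitter, seed = seed),
            class = "cohort_spec")
}

# internal: mean-one lognormal factors with relative SD `jit`
lognormal_factors <- function(k, jit) {
  if (jit == 0) return(rep(1, k))
  sdlog <- sqrt(log(1 + jit^2))
  exp(rnorm(k, -sdlog^2 / 2, sdlog))
}

#' Generate a multi-participant evoked-style cohort
#'
#' For each participant, the node parameters `a`, `f` and the nonzero coupling
#' entries are jittered multiplicatively (mean-one lognormal, relative SD
#' `participant_jitter`), `n_trials` independent noisy runs of the jittered
#' system are simulated, and the trials are averaged into one evoked-style
#' series. All randomness derives deterministically from `(spec$seed,
#' participant index)`. A jitter draw that destabilises the linearised system
#' is resampled up to 10 times.
#'
#' @param c_true ground-truth [coupling_matrix()].
#' @param params an [oscillator_params()] shared across the cohort (before
#'   jitter).
#' @param spec a [cohort_spec()].
#' @return List of [region_ts()] (one per participant) with the per-participant
#'   jittered systems attached as attribute `"participants"` (each a list with
#'   `params` and `C`).
#' @export
generate_cohort <- function(c_true, params, spec = cohort_spec()) {
  check_conforming(params, c_true)
  set.seed(spec$seed)
  participant_seeds <- sample.int(.Machine$integer.max - 1, spec$n_participants)
  burn <- round(2 / spec$dt)
  systems <- vector("list", spec$n_participants)
  cohort <- vector("list", spec$n_participants)
  for (p in seq_len(spec$n_participants)) {
    set.seed(participant_seeds[p])
    ok <- FALSE
    for (try in 1:10) {
      fa <- lognormal_factors(params$n, spec$participant_jitter)
      ff <- lognormal_factors(params$n, spec$participant_jitter)
      fc_jit <- matrix(lognormal_factors(params$n^2, spec$participant_jitter),
                       params$n, params$n)
      p_p <- oscillator_params(a = params$a * fa, f = params$f * ff,
                               G = params$G, beta = params$beta,
                               region_ids = params$region_ids)
      C_p <- coupling_matrix(unclass(c_true) * fc_jit, params$region_ids)
      sys <- build_jacobian(p_p, C_p)
      max_re <- max(Re(eigen(sys$jacobian, only.values = TRUE)$values))
      if (max_re <= -1e-6) { ok <- TRUE; break }
    }
    if (!ok) stop("participant ", p,
                  ": jitter destabilised the system 10 times in a row",
                  call. = FALSE)
    trial_seeds <- sample.int(.Machine$integer.max - 1, spec$n_trials)
    acc <- matrix(0, spec$samples_per_trial, params$n)
    for (tr in seq_len(spec$n_trials)) {
      ts <- simulate_hopf(p_p, C_p,
                          sim_config(dt = spec$dt,
                                     n_steps = burn + spec$samples_per_trial,
                                     burn_in = burn, seed = trial_seeds[tr]))
      acc <- acc + ts$values
    }
    cohort[[p]] <- region_ts(acc / spec$n_trials, dt = spec$dt,
                             region_ids = params$region_ids)
    systems[[p]] <- list(params = p_p, C = C_p)
  }
  attr(cohort, "participants") <- systems
  attr(cohort, "spec") <- spec
  cohort
}

#' Two task conditions with boosted sub-pathways
#'
#' Emulates a two-condition design at the network level: condition A multiplies
#' the coupling of the links in `pathway_a` by `boost`, condition B those in
#' `pathway_b`. Both cohorts share the same per-participant jitters and trial
#' noise (identical derived seeds), so they differ only in the boosted links.
#'
#' @inheritParams generate_cohort
#' @param pathway_a,pathway_b two-column matrices or data frames of links
#'   (`from` = sender, `to` = receiver) given as region ids; must not overlap.
#' @param boost multiplicative boost (> 1).
#' @return List with elements `condition_a` and `condition_b`, each a cohort
#'   as returned by [generate_cohort()].
#' @export
two_condition_cohort <- function(c_true, params, spec, pathway_a, pathway_b,
                                 boost) {
  if (!is.numeric(boost) || boost <= 1)
    stop("`boost` must be > 1 (no contrast otherwise)", call. = FALSE)
  norm_path <- function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2) stop("pathways must have two columns (from, to)",
                           call. = FALSE)
    p
  }
  pa <- norm_path(pathway_a); pb <- norm_path(pathway_b)
  key <- function(p) paste(p[, 1], p[, 2], sep = "->")
  if (length(intersect(key(pa), key(pb))) > 0)
    stop("boosted pathways overlap: ",
         paste(intersect(key(pa), key(pb)), collapse = ", "), call. = FALSE)
  boost_links <- function(C, path) {
    ids <- rownames(C)
    for (r in seq_len(nrow(path))) {
      j <- match(path[r, 1], ids); i <- match(path[r, 2], ids)
      if (is.na(i) || is.na(j))
        stop("pathway link ", path[r, 1], "->", path[r, 2],
             " not resolvable", call. = FALSE)
      C[i, j] <- C[i, j] * boost
    }
    C
  }
  lv <- attr(c_true, "levels")
  ca <- boost_links(unclass(c_true), pa)
  cb <- boost_links(unclass(c_true), pb)
  mk <- function(v) { m <- coupling_matrix(v, rownames(c_true))
                      attr(m, "levels") <- lv; m }
  list(condition_a = generate_cohort(mk(ca), params, spec),
       condition_b = generate_cohort(mk(cb), params, spec))
}
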