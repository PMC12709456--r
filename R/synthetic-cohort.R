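# Synthetic multi-site cohort generation.
#
# Ground-truth directed networks with a planted layered hierarchy are
# symmetrized group-by-group (flattening) to emulate the progressive loss
# of directed, stratified architecture across disease stages; per-subject
# BOLD-like signals come from the stochastic Stuart-Landau (Hopf) model
# run on each subject's coupling. Biomarkers and cognition are linear in
# the subject's hierarchy summaries, and multi-site additive and
# multiplicative effects can be planted on any feature table.

#' Generate a directed network with a planted layered hierarchy
#'
#' Nodes are assigned to \code{n_layers} rank-ordered layers. Edges between
#' consecutive layers run predominantly downward (weight
#' \code{feedforward_weight}); reverse edges carry \code{feedback_weight}.
#' Within the chosen density, edge presence is Bernoulli.
#'
#' @param n_regions number of nodes (>= 2).
#' @param n_layers number of hierarchy layers (<= n_regions).
#' @param feedforward_weight,feedback_weight nonnegative edge weights.
#' @param density probability in (0, 1] that an eligible edge is present.
#' @param weight_jitter half-width of the uniform multiplicative jitter
#'   applied to edge weights (0 keeps weights exact).
#' @param seed integer seed; all randomness keyed to it.
#' @return list of class \code{ground_truth_network} with elements
#'   \code{coupling}, \code{planted_levels} and \code{layer_assignment}.
#' @export
generate_hierarchical_coupling <- function(n_regions, n_layers,
                                           feedforward_weight = 1,
                                           feedback_weight = 0.2,
                                           density = 0.8,
                                           weight_jitter = 0.2, seed = 1) {
  if (n_regions < 2) stop("need at least 2 regions")
  if (n_layers > n_regions) stop("n_layers cannot exceed n_regions")
  if (feedforward_weight < 0 || feedback_weight < 0) stop("weights must be >= 0")
  if (feedforward_weight == 0 && feedback_weight == 0)
    stop("all-zero weights give no graph")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  set.seed(seed)
  layer <- sort(rep_len(seq_len(n_layers), n_regions))
  C <- matrix(0, n_regions, n_regions)
  repeat {
    for (m in seq_len(n_regions)) {
      for (n in seq_len(n_regions)) {
        if (m == n) next
        dl <- layer[n] - layer[m]
        if (dl == 1 && runif(1) <= density) C[m, n] <- feedforward_weight
        if (dl == -1 && feedback_weight > 0 && runif(1) <= density / 2)
          C[m, n] <- feedback_weight
      }
    }
    # jitter weights for non-degenerate spectra, keep signs
    if (weight_jitter > 0)
      C <- C * matrix(runif(n_regions^2, 1 - weight_jitter,
                            1 + weight_jitter), n_regions)
    if (max(weak_components(C)) == 1) break
    C[] <- 0  # resample until weakly connected (certain at density 1)
  }
  structure(list(coupling = C,
                 planted_levels = max(layer) - layer,
                 layer_assignment = layer),
            class = "ground_truth_network")
}

#' Simulate BOLD-like signals from the stochastic Hopf model
#'
#' Euler-Maruyama integration of coupled Stuart-Landau oscillators
#' \eqn{dz_j = [(a_j + i\omega_j) z_j - |z_j|^2 z_j
#'   + \sum_m C_{mj}(z_m - z_j)] dt + \sigma dW_j}
#' with independent noise on the real and imaginary components; the real
#' part is recorded every TR after a discarded burn-in.
#'
#' @param C coupling matrix (\code{C[m, n]} = influence of m over n).
#' @param params [hopf_params()] object.
#' @param n_timepoints number of recorded volumes.
#' @param TR repetition time in seconds.
#' @param dt integration step (s); must satisfy \code{dt <= TR / 10}.
#' @param burn_in seconds of initial transient to discard.
#' @param seed integer seed.
#' @return regions x n_timepoints matrix of real-valued signals.
#' @export
simulate_hopf_bold <- function(C, params, n_timepoints, TR = 3, dt = 0.1,
                               burn_in = 60, seed = 1) {
  C <- check_coupling(C)
  n <- nrow(C)
  if (length(params$a) != n) stop("params dimension mismatch")
  if (dt > TR / 10) stop("dt must be <= TR / 10")
  set.seed(seed)
  steps_per_tr <- round(TR / dt)
  burn_steps <- round(burn_in / dt)
  n_steps <- burn_steps + n_timepoints * steps_per_tr
  lam <- params$a + 1i * params$omega
  tC <- t(C)
  d_in <- colSums(C)
  sn <- params$sigma * sqrt(dt)
  z <- complex(real = rep(0, n), imaginary = rep(0, n))
  out <- matrix(NA_real_, n, n_timepoints)
  rec <- 0L
  for (s in seq_len(n_steps)) {
    coupling_term <- as.vector(tC %*% z) - d_in * z
    z <- z + dt * (lam * z - Mod(z)^2 * z + coupling_term) +
      sn * complex(real = rnorm(n), imaginary = rnorm(n))
    if (any(!is.finite(Re(z)) | !is.finite(Im(z))))
      stop("trajectory diverged at step ", s,
           "; reduce dt or check that all a < 0")
    if (s > burn_steps && (s - burn_steps) %% steps_per_tr == 0) {
      rec <- rec + 1L
      out[, rec] <- Re(z)
    }
  }
  out
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study geometry the pipeline targets: 3-second TR,
#' 197 recorded volumes per subject, four diagnostic groups whose coupling
#' matrices are progressively symmetrized (hierarchy flattening), and
#' multi-site additive/multiplicative effects on derived feature tables.
#'
#' @param n_regions number of regions.
#' @param n_subjects_per_group integer vector of length 4 (groups HCneg,
#'   HCpos, MCIpos, ADpos).
#' @param n_sites number of acquisition sites.
#' @param flattening_per_group symmetrization fraction lambda in \[0, 1\]
#'   per group; subject coupling is
#'   \code{(1 - lambda) C_true + lambda (C_true + t(C_true)) / 2}.
#' @param TR,n_timepoints acquisition geometry.
#' @param coupling_scale global scale applied to the ground-truth coupling;
#'   the default places the simulated signals in a realistic resting-state
#'   synchrony regime (median FC well below saturation).
#' @param noise_sd subject-level multiplicative jitter on coupling weights.
#' @param biomarker_effect_sizes named list of linear slopes tying amyloid,
#'   tau, grey-matter volume and cognition to the subject's hierarchy
#'   summaries, plus residual noise SDs.
#' @param site_shift_sd,site_scale_range site effect hyperparameters
#'   (additive SD; multiplicative uniform range).
#' @param seed integer seed.
#' @return list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_regions = 20,
                          n_subjects_per_group = c(10, 10, 10, 10),
                          n_sites = 3,
                          flattening_per_group = c(0, 0.2, 0.4, 0.7),
                          TR = 3, n_timepoints = 197,
                          coupling_scale = 0.1,
                          noise_sd = 0.05,
                          biomarker_effect_sizes = list(
                            amyloid = -60, tau = -0.8, gmv = 2500,
                            cognition = 8, noise_frac = 0.3),
                          site_shift_sd = 1, site_scale_range = c(0.8, 1.2),
                          seed = 1) {
  if (length(n_subjects_per_group) != 4) stop("need 4 group sizes")
  if (any(flattening_per_group < 0 | flattening_per_group > 1))
    stop("flattening must be in [0, 1]")
  if (n_timepoints < 150)
    warning("n_timepoints below the 150-volume inclusion rule")
  structure(as.list(environment()), class = "cohort_config")
}

#' Plant additive and multiplicative site effects on a feature table
#'
#' For site i and feature v the planted value is
#' \eqn{\gamma_{iv} + \delta_{iv} x} with \eqn{\gamma \sim N(0, shift\_sd)}
#' and \eqn{\delta \sim U(scale\_range)}. Ground-truth gamma/delta are
#' attached as attributes for recovery tests.
#'
#' @param X subjects x features numeric matrix.
#' @param site per-subject site labels.
#' @param shift_sd additive effect SD.
#' @param scale_range length-2 positive range of multiplicative effects.
#' @param seed integer seed.
#' @return matrix like \code{X} with attributes \code{gamma} and
#'   \code{delta} (sites x features).
#' @export
plant_site_effects <- function(X, site, shift_sd = 1,
                               scale_range = c(0.8, 1.2), seed = 1) {
  X <- as.matrix(X)
  if (length(site) != nrow(X)) stop("site labels must match rows of X")
  if (any(scale_range <= 0)) stop("scale_range must exclude 0")
  set.seed(seed)
  sites <- sort(unique(as.character(site)))
  p <- ncol(X)
  gam <- matrix(rnorm(length(sites) * p, 0, shift_sd), length(sites), p,
                dimnames = list(sites, colnames(X)))
  del <- matrix(runif(length(sites) * p, scale_range[1], scale_range[2]),
                length(sites), p, dimnames = list(sites, colnames(X)))
  out <- X
  for (s in sites) {
    rows <- which(as.character(site) == s)
    out[rows, ] <- sweep(sweep(X[rows, , drop = FALSE], 2, del[s, ], "*"),
                         2, gam[s, ], "+")
  }
  attr(out, "gamma") <- gam
  attr(out, "delta") <- del
  out
}

#' Generate a complete synthetic multi-site cohort
#'
#' One ground-truth hierarchical network is flattened per group, jittered
#' per subject, simulated through the Hopf model, and used to derive
#' metadata, ATN-like biomarkers and cognition tables tied linearly to the
#' subject's true directedness and trophic levels.
#'
#' @param config a [cohort_config()] object.
#' @return list of class \code{cohort_bundle} with elements
#'   \code{timeseries} (list of regions x timepoints matrices),
#'   \code{metadata}, \code{coupling_true} (per-subject), \code{network},
#'   \code{biomarkers} (list amyloid/tau/gmv; subjects x regions),
#'   \code{cognition}, \code{truth} (generative parameters incl. per-subject
#'   directedness and trophic levels), and \code{config}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  groups <- c("HCneg", "HCpos", "MCIpos", "ADpos")
  nsub <- sum(config$n_subjects_per_group)
  if (any(config$n_subjects_per_group < 1)) stop("empty group in config")
  net <- generate_hierarchical_coupling(config$n_regions,
                                        n_layers = min(5, config$n_regions),
                                        seed = config$seed + 101)
  C_true <- net$coupling * config$coupling_scale
  C_sym <- (C_true + t(C_true)) / 2
  params <- hopf_params(a = rep(-0.02, config$n_regions),
                        omega = 2 * pi * runif(config$n_regions, 0.01, 0.08),
                        sigma = 0.01)

  group <- rep(groups, times = config$n_subjects_per_group)
  subject <- sprintf("sub-%03d", seq_len(nsub))
  site <- paste0("site", 1 + (seq_len(nsub) - 1) %% config$n_sites)
  age <- round(runif(nsub, 60, 90), 1)
  gender <- sample(c("F", "M"), nsub, replace = TRUE)
  education <- round(runif(nsub, 8, 20))
  apoe4 <- rbinom(nsub, 1, c(0.2, 0.4, 0.55, 0.7)[match(group, groups)])

  couplings <- vector("list", nsub)
  tslist <- vector("list", nsub)
  true_dir <- numeric(nsub)
  true_h <- matrix(NA_real_, nsub, config$n_regions)
  for (i in seq_len(nsub)) {
    lam <- config$flattening_per_group[match(group[i], groups)]
    Ci <- (1 - lam) * C_true + lam * C_sym
    if (config$noise_sd > 0)
      Ci <- Ci * matrix(pmax(0, 1 + rnorm(config$n_regions^2, 0,
                                          config$noise_sd)),
                        config$n_regions)
    diag(Ci) <- 0
    couplings[[i]] <- Ci
    true_dir[i] <- directedness(Ci)
    true_h[i, ] <- trophic_levels(Ci)
    tslist[[i]] <- simulate_hopf_bold(Ci, params, config$n_timepoints,
                                      TR = config$TR,
                                      seed = config$seed + 1000 + i)
  }
  names(tslist) <- names(couplings) <- subject

  es <- config$biomarker_effect_sizes
  noise <- function(scale) rnorm(nsub, 0, abs(scale) * es$noise_frac)
  # regional biomarkers: amyloid/tau load increases as directedness falls
  # (centered at the healthy group's level); GMV tracks regional hierarchy.
  dir_c <- true_dir - max(true_dir)
  amyloid_suvr <- 1.1 + pmin(2, pmax(0, (-dir_c) * 1.2 + rnorm(nsub, 0, 0.08)))
  amyloid <- outer(amyloid_suvr, runif(config$n_regions, 0.85, 1.15)) +
    matrix(rnorm(nsub * config$n_regions, 0, 0.05), nsub)
  tau <- 1.15 + outer(-dir_c * abs(es$tau), runif(config$n_regions, 0.8, 1.2)) +
    matrix(rnorm(nsub * config$n_regions, 0, 0.05 * abs(es$tau) + 1e-3), nsub)
  gmv <- 5000 + es$gmv * (true_h / max(1e-9, max(true_h))) -
    20 * (age - 75) +
    matrix(rnorm(nsub * config$n_regions, 0, abs(es$gmv) * es$noise_frac / 10),
           nsub)
  colnames(amyloid) <- colnames(tau) <- colnames(gmv) <-
    paste0("R", seq_len(config$n_regions))
  rownames(amyloid) <- rownames(tau) <- rownames(gmv) <- subject

  # cognition declines as the hierarchy flattens
  cognition <- data.frame(
    subject = subject,
    mmse = pmin(30, 30 + es$cognition * dir_c + noise(es$cognition)),
    adas13 = pmax(0, 10 - 3 * es$cognition * dir_c + noise(3 * es$cognition)),
    cdr_sb = pmax(0, -1.2 * es$cognition * dir_c + noise(es$cognition) / 4),
    moca = pmin(30, 28 + es$cognition * dir_c + noise(es$cognition)))

  metadata <- data.frame(subject, group = factor(group, levels = groups),
                         age, gender, education, site, apoe4)
  network_map <- rep_len(c("VN", "SMN", "DAN", "SAN", "LN", "CN", "DMN"),
                         config$n_regions)

  structure(list(timeseries = tslist, metadata = metadata,
                 coupling_true = couplings,
                 biomarkers = list(amyloid = amyloid, tau = tau, gmv = gmv),
                 cognition = cognition,
                 network_map = network_map,
                 truth = list(network = net, hopf = params,
                              directedness = true_dir, trophic = true_h,
                              amyloid_suvr = amyloid_suvr),
                 config = config),
            class = "cohort_bundle")
}

#' Write a cohort bundle to a directory of TSV files
#'
#' @param bundle a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(file.path(dir, "coupling_true"), recursive = TRUE,
             showWarnings = FALSE)
  for (s in names(bundle$timeseries)) {
    write_timeseries(bundle$timeseries[[s]],
                     file.path(dir, paste0(s, ".tsv")))
    write_matrix_tsv(bundle$coupling_true[[s]],
                     file.path(dir, "coupling_true", paste0(s, ".tsv")))
  }
  write.table(bundle$metadata, file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in names(bundle$biomarkers))
    write.table(data.frame(subject = rownames(bundle$biomarkers[[m]]),
                           bundle$biomarkers[[m]], check.names = FALSE),
                file.path(dir, paste0("biomarkers_", m, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$cognition, file.path(dir, "cognition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
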