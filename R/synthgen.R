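#' Simulation configuration
#'
#' Bundles every ground-truth parameter of the synthetic cohort: signal
#' model settings for the three EEG paradigms and the clinical trajectory
#' model. Defaults are the study conditions of the analysis: a 52-subject
#' cohort, 1000 Hz sampling, 9 Hz low-alpha oscillation, LDAEP slope
#' 1.55 uV/10 dB, MMN amplitude -2.97 uV, HAM-D baseline 26.13 +/- 6.80,
#' and group-dependent decline so that week-8 scores land near 4.9 (low
#' FAA group) and 12.0 (high FAA group).
#'
#' @param seed integer master seed; every generated array is a pure
#'   function of the config including this seed.
#' @param n_subjects cohort size (>= 8).
#' @param sampling_rate Hz.
#' @param montage ordered channel labels; must contain [default_montage()].
#' @param resting_duration seconds of resting EEG (>= 70 recommended so 30
#'   clean 2.048-s epochs survive rejection).
#' @param alpha_asym_target named vector (f5f6, f7f8), asymmetry index in
#'   the open interval (-100, 100) injected into the resting signal.
#' @param alpha_center_freq Hz in [8, 10).
#' @param alpha_power baseline alpha band power per channel, uV^2.
#' @param ldaep_slope_true uV per 10 dB.
#' @param n1_base,p2_base component amplitudes (uV) at the 80 dB reference.
#' @param mmn_amp_true mean deviant-minus-standard amplitude over
#'   130-280 ms, uV (negative for a genuine MMN).
#' @param trial_counts list: `ldaep` trials per intensity, `mmn` total
#'   oddball stimuli.
#' @param mmn_deviant_prob deviant probability in the oddball sequence.
#' @param isi_ldaep interstimulus interval range, seconds (uniform).
#' @param isi_mmn fixed oddball interstimulus interval, seconds.
#' @param noise_sd broadband pink-noise standard deviation, uV.
#' @param clinical list of clinical-model parameters; see Details.
#'
#' @details The clinical block holds: HAM-D baseline mean/sd (`hamd0_mean`,
#' `hamd0_sd`), age, HAM-A and CORE distributions, `p_female`,
#' `p_vortioxetine`, biomarker cohort distributions (`faa_f5f6`,
#' `faa_f7f8`, `ldaep`, `mmn` as c(mean, sd)), `core_faa_r` (latent-scale
#' correlation of CORE with true F7/F8 FAA before censoring at 0), the
#' per-group week-8 remaining fraction of baseline HAM-D, drawn lognormal
#' (`traj_frac8` = per-group medians, `traj_frac8_sigma` = log-scale sds,
#' named low/high; identical settings for both groups give a null cohort
#' with no group-by-week interaction), and per-week measurement noise
#' `week_noise_sd`.
#'
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_subjects = 52L,
                       sampling_rate = 1000,
                       montage = default_montage(),
                       resting_duration = 75,
                       alpha_asym_target = c(f5f6 = 0.03, f7f8 = -1.73),
                       alpha_center_freq = 9,
                       alpha_power = 5,
                       ldaep_slope_true = 1.55,
                       n1_base = 2.5, p2_base = 3.5,
                       mmn_amp_true = -2.97,
                       trial_counts = list(ldaep = 40L, mmn = 750L),
                       mmn_deviant_prob = 0.10,
                       isi_ldaep = c(0.5, 0.9),
                       isi_mmn = 0.5,
                       noise_sd = 2,
                       clinical = list()) {
  cl <- utils::modifyList(list(
    hamd0_mean = 26.13, hamd0_sd = 6.80,
    age_mean = 45.87, age_sd = 11.69,
    hama0_mean = 25.13, hama0_sd = 6.02,
    core_mean = 4.35, core_sd = 5.98,
    p_female = 48 / 52, p_vortioxetine = 0.5,
    faa_f5f6 = c(0.03, 14.13), faa_f7f8 = c(-1.73, 15.81),
    ldaep = c(1.55, 2.85), mmn = c(-2.97, 1.34),
    core_faa_r = 0.34,
    traj_frac8 = c(low = 0.17, high = 0.29),
    traj_frac8_sigma = c(low = 0.55, high = 0.80),
    week_noise_sd = 1.5), clinical)
  cfg <- structure(
    list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
         sampling_rate = sampling_rate, montage = montage,
         resting_duration = resting_duration,
         alpha_asym_target = alpha_asym_target,
         alpha_center_freq = alpha_center_freq,
         alpha_power = alpha_power,
         ldaep_slope_true = ldaep_slope_true,
         n1_base = n1_base, p2_base = p2_base,
         mmn_amp_true = mmn_amp_true,
         trial_counts = trial_counts,
         mmn_deviant_prob = mmn_deviant_prob,
         isi_ldaep = isi_ldaep, isi_mmn = isi_mmn,
         noise_sd = noise_sd, clinical = cl),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!all(default_montage() %in% cfg$montage))
    stop("montage must contain the required channel set: ",
         paste(setdiff(default_montage(), cfg$montage), collapse = ", "))
  if (any(abs(cfg$alpha_asym_target) >= 100))
    stop("alpha_asym_target must lie in the open interval (-100, 100)")
  if (cfg$alpha_center_freq < 8 || cfg$alpha_center_freq >= 10)
    stop("alpha_center_freq must lie in [8, 10) Hz")
  if (any(unlist(cfg$trial_counts) <= 0))
    stop("trial counts must be positive")
  if (cfg$mmn_deviant_prob <= 0 || cfg$mmn_deviant_prob >= 1)
    stop("mmn_deviant_prob must lie in (0, 1)")
  if (cfg$n_subjects < 1) stop("n_subjects must be positive")
  invisible(cfg)
}

# Deterministic sub-seed per subject and paradigm so recordings are
# independent draws but byte-identical across runs of the same config.
sub_seed <- function(cfg, subject_id, stream) {
  codes <- c(resting = 1L, ldaep = 2L, mmn = 3L, clinical = 4L)
  id <- if (is.character(subject_id))
    sum(utf8ToInt(subject_id)) else as.integer(subject_id)
  (as.integer(cfg$seed) * 10007L + id * 131L + codes[[stream]]) %%
    2147483000L
}

# Pink (1/f amplitude) noise via frequency-domain shaping, scaled to
# standard deviation `sd`. One independent trace per row. Generated at a
# highly composite FFT length and truncated, for speed.
pink_noise <- function(n_channels, n_samples, sd = 1) {
  n <- stats::nextn(n_samples, c(2, 3, 5))
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)                             # symmetric frequency index
  shape <- ifelse(f == 0, 0, 1 / sqrt(f))
  out <- matrix(0, n_channels, n_samples)
  for (ch in seq_len(n_channels)) {
    X <- stats::fft(stats::rnorm(n))
    y <- Re(stats::fft(X * shape, inverse = TRUE))[seq_len(n_samples)] / n
    out[ch, ] <- y / stats::sd(y) * sd
  }
  out
}

gauss_bump <- function(t_ms, center_ms, sd_ms) {
  exp(-0.5 * ((t_ms - center_ms) / sd_ms)^2)
}

#' Generate a resting-state EEG recording with a known alpha asymmetry
#'
#' Signal model: pink (1/f) background noise per channel plus a narrowband
#' alpha oscillation at `alpha_center_freq`. For each asymmetry pair the
#' left/right alpha powers are set so that
#' (P_left - P_right) / (P_left + P_right) x 100 equals the injected
#' asymmetry target; all other channels carry the baseline alpha power.
#'
#' @param cfg a [sim_config()].
#' @param subject_id subject identifier (also seeds the noise stream).
#' @param asym named vector overriding `cfg$alpha_asym_target`
#'   (per-subject truth in cohort simulations).
#' @return An [recording()] with paradigm "resting"; the injected truth is
#'   stored in `meta$truth`.
#' @export
gen_resting_eeg <- function(cfg, subject_id = 1L,
                            asym = cfg$alpha_asym_target) {
  validate_sim_config(cfg)
  epoch_s <- 2.048
  min_dur <- 30 * epoch_s
  if (cfg$resting_duration < min_dur)
    stop(sprintf(paste0("resting_duration %.3f s cannot yield 30 epochs of ",
                        "%.3f s; minimum is %.2f s"),
                 cfg$resting_duration, epoch_s, min_dur))
  if (any(abs(asym) >= 100))
    stop("asymmetry target must lie in (-100, 100)")
  fs <- cfg$sampling_rate
  n <- round(cfg$resting_duration * fs)
  chans <- cfg$montage
  set.seed(sub_seed(cfg, subject_id, "resting"))
  dat <- pink_noise(length(chans), n, sd = cfg$noise_sd)

  t <- (seq_len(n) - 1) / fs
  pairs <- faa_pairs()
  amp_for <- function(power) sqrt(2 * power)     # sinusoid power a^2/2
  alpha_pow <- rep(cfg$alpha_power, length(chans))
  names(alpha_pow) <- chans
  for (p in names(pairs)) {
    a <- if (p %in% names(asym)) asym[[p]] else 0
    rho <- (100 + a) / (100 - a)                  # P_left / P_right
    alpha_pow[pairs[[p]][1]] <- cfg$alpha_power * sqrt(rho)
    alpha_pow[pairs[[p]][2]] <- cfg$alpha_power / sqrt(rho)
  }
  phase <- stats::runif(length(chans), 0, 2 * pi)
  for (i in seq_along(chans)) {
    dat[i, ] <- dat[i, ] + amp_for(alpha_pow[i]) *
      sin(2 * pi * cfg$alpha_center_freq * t + phase[i])
  }
  recording(dat, chans, fs, paradigm = "resting",
            subject_id = as.character(subject_id),
            meta = list(truth = list(alpha_asym = asym,
                                     alpha_power = alpha_pow)))
}

# Fixed scalp projection of the auditory evoked response relative to Cz.
auditory_topography <- function(channels) {
  w <- rep(0.5, length(channels))
  names(w) <- channels
  w[names(w) %in% c("C3", "Cz", "C4")] <- 1.0
  w[names(w) %in% c("FC3", "FCz", "FC4")] <- 0.9
  w[names(w) %in% c("F3", "Fz", "F4")] <- 0.7
  w
}

#' Generate an intensity-series (LDAEP) auditory ERP recording
#'
#' Tones at 60/70/80/90/100 dB SPL in randomized order, interstimulus
#' interval uniform on `isi_ldaep`. Each tone evokes an N1 (negative
#' Gaussian, 100 ms, sd 20 ms) and a P2 (positive Gaussian, 200 ms,
#' sd 30 ms) at Cz whose peak-to-peak amplitude is
#' `n1_base + p2_base + slope x (intensity - 80)/10`, scaled across the
#' scalp by a fixed topography, on pink background noise.
#'
#' @param cfg a [sim_config()].
#' @param subject_id subject identifier.
#' @param slope true LDAEP slope, uV per 10 dB (default from cfg).
#' @param exact if TRUE, omit the noise (exact linear check).
#' @return A [recording()] with paradigm "ldaep" and event codes
#'   "60".."100".
#' @export
gen_ldaep_recording <- function(cfg, subject_id = 1L,
                                slope = cfg$ldaep_slope_true,
                                exact = FALSE) {
  validate_sim_config(cfg)
  fs <- cfg$sampling_rate
  n_per <- as.integer(cfg$trial_counts$ldaep)
  if (n_per <= 0) stop("trial count for ldaep must be positive")
  intensities <- c(60, 70, 80, 90, 100)
  set.seed(sub_seed(cfg, subject_id, "ldaep"))
  order_codes <- sample(rep(intensities, each = n_per))
  isi <- stats::runif(length(order_codes), cfg$isi_ldaep[1], cfg$isi_ldaep[2])
  onsets_s <- 1 + cumsum(c(0, isi[-length(isi)]))
  n <- ceiling((onsets_s[length(onsets_s)] + 1.5) * fs)
  chans <- cfg$montage
  dat <- if (exact) matrix(0, length(chans), n) else
    pink_noise(length(chans), n, sd = cfg$noise_sd)
  topo <- auditory_topography(chans)

  # evoked template on a 0..500 ms support, unit-split between N1 and P2
  t_ms <- seq(0, 500, by = 1000 / fs)
  base_total <- cfg$n1_base + cfg$p2_base
  n1_frac <- cfg$n1_base / base_total
  shape <- function(total) {
    -total * n1_frac * gauss_bump(t_ms, 100, 20) +
      total * (1 - n1_frac) * gauss_bump(t_ms, 200, 30)
  }
  events <- data.frame(sample = round(onsets_s * fs) + 1L,
                       code = as.character(order_codes))
  for (k in seq_len(nrow(events))) {
    tot <- base_total + slope * (order_codes[k] - 80) / 10
    wav <- shape(tot)
    idx <- events$sample[k] + seq_along(wav) - 1L
    dat[, idx] <- dat[, idx] + outer(topo, wav)
  }
  recording(dat, chans, fs, paradigm = "ldaep", events = events,
            subject_id = as.character(subject_id),
            meta = list(truth = list(ldaep_slope = slope,
                                     n1_base = cfg$n1_base,
                                     p2_base = cfg$p2_base)))
}

#' Generate an auditory oddball (MMN) recording
#'
#' 750 stimuli by default, deviants at 10% probability in randomized
#' order, fixed interstimulus interval. Every stimulus evokes the standard
#' N1/P2 response; deviants additionally carry a negative Gaussian
#' component (205 ms, sd 40 ms) at the nine frontocentral sites, scaled so
#' that its mean over the 130-280 ms window equals `amp` exactly.
#'
#' @param cfg a [sim_config()].
#' @param subject_id subject identifier.
#' @param amp true MMN amplitude, uV (mean over 130-280 ms; negative for a
#'   genuine MMN). Default from cfg.
#' @param exact if TRUE, omit the noise.
#' @return A [recording()] with paradigm "mmn" and event codes
#'   "standard"/"deviant".
#' @export
gen_mmn_recording <- function(cfg, subject_id = 1L,
                              amp = cfg$mmn_amp_true,
                              exact = FALSE) {
  validate_sim_config(cfg)
  fs <- cfg$sampling_rate
  n_stim <- as.integer(cfg$trial_counts$mmn)
  n_dev <- max(1L, round(n_stim * cfg$mmn_deviant_prob))
  set.seed(sub_seed(cfg, subject_id, "mmn"))
  is_dev <- rep(FALSE, n_stim)
  is_dev[sample.int(n_stim, n_dev)] <- TRUE
  onsets_s <- 1 + (seq_len(n_stim) - 1) * cfg$isi_mmn
  n <- ceiling((onsets_s[n_stim] + 1.2) * fs)
  chans <- cfg$montage
  dat <- if (exact) matrix(0, length(chans), n) else
    pink_noise(length(chans), n, sd = cfg$noise_sd)
  topo <- auditory_topography(chans)

  t_ms <- seq(0, 500, by = 1000 / fs)
  std_wav <- -cfg$n1_base * gauss_bump(t_ms, 100, 20) +
    cfg$p2_base * gauss_bump(t_ms, 200, 30)
  # scale the deviant extra component so its mean over [130, 280] ms is amp
  bump <- gauss_bump(t_ms, 205, 40)
  win <- t_ms >= 130 & t_ms <= 280
  mmn_wav <- bump * (amp / mean(bump[win]))
  sites <- chans %in% mmn_sites()

  events <- data.frame(sample = round(onsets_s * fs) + 1L,
                       code = ifelse(is_dev, "deviant", "standard"))
  for (k in seq_len(n_stim)) {
    idx <- events$sample[k] + seq_along(t_ms) - 1L
    dat[, idx] <- dat[, idx] + outer(topo, std_wav)
    if (is_dev[k])
      dat[sites, idx] <- dat[sites, idx] +
        matrix(mmn_wav, sum(sites), length(mmn_wav), byrow = TRUE)
  }
  recording(dat, chans, fs, paradigm = "mmn", events = events,
            subject_id = as.character(subject_id),
            meta = list(truth = list(mmn_amp = amp)))
}

#' Generate a synthetic clinical cohort with ground truth
#'
#' Draws per-subject true biomarker values (FAA pairs, LDAEP slope, MMN
#' amplitude) from the cohort distributions, assigns low/high groups by
#' the median of true F5/F6 FAA, and generates HAM-D trajectories at weeks
#' 0/2/4/8 where the fraction of the baseline score remaining at week 8
#' depends on group (geometric interpolation in between, rounded,
#' truncated at 0). CORE is a censored, rounded Gaussian correlated with
#' true F7/F8 FAA at the configured latent level. Sex and medication are
#' two-level categorical covariates.
#'
#' @param cfg a [sim_config()] with `n_subjects >= 8`.
#' @return list with `clinical` (data.frame, one row per subject) and
#'   `truth` (data.frame of generator ground truth per subject).
#' @export
gen_clinical_cohort <- function(cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_subjects
  if (n < 8) stop("n_subjects must be at least 8")
  cl <- cfg$clinical
  set.seed(sub_seed(cfg, 0L, "clinical"))

  rtrunc <- function(n, mean, sd, lo = -Inf, hi = Inf)
    pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))

  faa_f5f6 <- stats::rnorm(n, cl$faa_f5f6[1], cl$faa_f5f6[2])
  z_faa <- stats::rnorm(n)
  faa_f7f8 <- cl$faa_f7f8[1] + cl$faa_f7f8[2] * z_faa
  ldaep_true <- stats::rnorm(n, cl$ldaep[1], cl$ldaep[2])
  mmn_true <- stats::rnorm(n, cl$mmn[1], cl$mmn[2])

  r <- cl$core_faa_r
  core_lat <- cl$core_mean + cl$core_sd *
    (r * z_faa + sqrt(1 - r^2) * stats::rnorm(n))
  core <- as.integer(round(pmax(0, pmin(54, core_lat))))

  grp <- ifelse(faa_f5f6 <= stats::median(faa_f5f6), "low", "high")
  hamd0 <- as.integer(round(rtrunc(n, cl$hamd0_mean, cl$hamd0_sd, lo = 8)))
  # remaining fraction of baseline at week 8: lognormal (right-skewed,
  # like observed end-of-trial score distributions), median per group
  frac8 <- pmin(1.2, stats::rlnorm(n, log(cl$traj_frac8[grp]),
                                   cl$traj_frac8_sigma[grp]))
  weeks <- c(0, 2, 4, 8)
  hamd <- sapply(weeks, function(w) {
    if (w == 0) return(hamd0)
    mu <- hamd0 * frac8^(w / 8)
    as.integer(round(pmax(0, mu + stats::rnorm(n, 0, cl$week_noise_sd))))
  })
  colnames(hamd) <- paste0("hamd_w", weeks)

  hama0 <- as.integer(round(rtrunc(n, cl$hama0_mean, cl$hama0_sd, lo = 0)))
  hama8 <- as.integer(round(pmax(0, hama0 * frac8^0.8 +
                                   stats::rnorm(n, 0, cl$week_noise_sd))))
  clinical <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = round(rtrunc(n, cl$age_mean, cl$age_sd, lo = 18, hi = 65), 1),
    sex = ifelse(stats::runif(n) < cl$p_female, "female", "male"),
    medication = ifelse(stats::runif(n) < cl$p_vortioxetine,
                        "vortioxetine", "escitalopram"),
    hamd, hama_w0 = hama0, hama_w8 = hama8, core = core,
    stringsAsFactors = FALSE)

  truth <- data.frame(
    subject_id = clinical$subject_id,
    faa_f5f6_true = faa_f5f6, faa_f7f8_true = faa_f7f8,
    ldaep_true = ldaep_true, mmn_true = mmn_true,
    group_true = grp, frac8_true = frac8,
    stringsAsFactors = FALSE)
  list(clinical = clinical, truth = truth)
}
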