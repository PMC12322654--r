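#' Synthetic compound profiles for ensemble generation
#'
#' A `compound_profile` encodes the mechanisms the generator emulates:
#' the circular spread of the ring torsions phi (bulky ortho
#' substituents make the C-N rotation nearly free), the spread of the
#' central torsion psi, a base excitation energy per isomer, a
#' planarity coupling beta (planar rings delocalise the pi* orbital and
#' red-shift the excitation), a `para_weight` multiplier emulating the
#' resonance enhancement by electron-withdrawing para groups, and
#' Gaussian energy noise standing in for all other nuclear degrees of
#' freedom.
#'
#' Three presets ship with the package:
#' \describe{
#'   \item{`"azobenzene_like"`}{planar, rigid parent: small phi spread,
#'     `para_weight = 1`. Little planarity variance, so the
#'     energy-planarity correlation is weak.}
#'   \item{`"dfdc_like"`}{tetra-ortho-halogenated pattern: twisted mean
#'     phi with a large spread, `para_weight = 1`.}
#'   \item{`"dfdc_ester_like"`}{the same twisted scaffold with an
#'     electron-poor para substituent: `para_weight > 1`, strengthening
#'     the energy-planarity coupling.}
#' }
#'
#' @param name profile name
#' @param isomer `"trans"` or `"cis"`
#' @param phi_mean_deg,phi_sd_deg mean magnitude and circular (wrapped
#'   normal) spread of the ring torsions, degrees
#' @param psi_mean_deg,psi_sd_deg central torsion mean and spread,
#'   degrees (trans ~ 180, cis ~ 10)
#' @param E0_eV base vertical excitation energy, eV
#' @param beta_eV planarity coupling, eV (energy lowering per unit
#'   mean ring planarity |cos phi|)
#' @param gamma_eV central-torsion coupling, eV
#' @param para_weight electron-withdrawing para multiplier (>= 1)
#' @param noise_sd_eV residual energy noise, eV
#' @param f_mean,f_sd oscillator-strength mean and spread (truncated at
#'   0)
#' @return a `compound_profile` list
#' @export
compound_profile <- function(name, isomer = c("trans", "cis"),
                             phi_mean_deg, phi_sd_deg,
                             psi_mean_deg, psi_sd_deg,
                             E0_eV, beta_eV, gamma_eV = 0.05,
                             para_weight = 1, noise_sd_eV = 0.05,
                             f_mean = 0.05, f_sd = 0.01) {
  isomer <- match.arg(isomer)
  if (phi_sd_deg <= 0 || psi_sd_deg <= 0) stop("angular spreads must be > 0")
  if (E0_eV <= 0) stop("base excitation energy must be > 0")
  if (para_weight < 0) stop("para_weight must be >= 0")
  structure(
    list(name = name, isomer = isomer,
         phi_mean_deg = phi_mean_deg, phi_sd_deg = phi_sd_deg,
         psi_mean_deg = psi_mean_deg, psi_sd_deg = psi_sd_deg,
         E0_eV = E0_eV, beta_eV = beta_eV, gamma_eV = gamma_eV,
         para_weight = para_weight, noise_sd_eV = noise_sd_eV,
         f_mean = f_mean, f_sd = f_sd),
    class = "compound_profile"
  )
}

#' @rdname compound_profile
#' @param preset one of `"azobenzene_like"`, `"dfdc_like"`,
#'   `"dfdc_ester_like"`
#' @export
profile_preset <- function(preset = c("azobenzene_like", "dfdc_like",
                                      "dfdc_ester_like"),
                           isomer = c("trans", "cis")) {
  preset <- match.arg(preset)
  isomer <- match.arg(isomer)
  psi_mean <- if (isomer == "trans") 180 else 10
  base <- switch(preset,
    azobenzene_like = list(phi_mean = 0, phi_sd = 12, E0 = 2.73,
                           beta = 0.15, pw = 1),
    dfdc_like       = list(phi_mean = 30, phi_sd = 35, E0 = 2.72,
                           beta = 0.15, pw = 1),
    dfdc_ester_like = list(phi_mean = 30, phi_sd = 35, E0 = 2.62,
                           beta = 0.15, pw = 1.8))
  E0 <- if (isomer == "trans") base$E0 else base$E0 + 0.25
  compound_profile(name = preset, isomer = isomer,
                   phi_mean_deg = base$phi_mean, phi_sd_deg = base$phi_sd,
                   psi_mean_deg = psi_mean, psi_sd_deg = 8,
                   E0_eV = E0, beta_eV = base$beta,
                   para_weight = base$pw)
}

wrap_deg <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# wrapped-normal sample in degrees
rwrapnorm_deg <- function(n, mean_deg, sd_deg) {
  wrap_deg(stats::rnorm(n, mean_deg, sd_deg))
}

# NeRF-style internal-coordinate placement: position of D bonded to C,
# with angle D-C-B = ang_deg and torsion dihedral(A,B,C,D) = tor_deg in
# the same IUPAC sign convention as dihedral().
place_atom <- function(A, B, C, r, ang_deg, tor_deg) {
  ang <- ang_deg * pi / 180
  tor <- -tor_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-r * cos(ang), r * sin(ang) * cos(tor), r * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Idealized 24-atom azobenzene scaffold (C12H10N2) with the requested
# psi (C1-N1=N2-C1') and phi (C_ortho-C_ipso-N=N) torsions imposed.
# Bond lengths: N=N 1.25, C-N 1.42, C-C(ring) 1.39, C-H 1.08 Angstrom;
# all sp2 angles 120 deg. Atom order: N1 N2 | ring A C1..C6 | ring B
# C1'..C6' | ring A H2..H6 | ring B H2'..H6'.
build_azo_frame <- function(psi_deg, phi1_deg, phi2_deg, frame_index = 1L) {
  rNN <- 1.25; rCN <- 1.42; rCC <- 1.39; rCH <- 1.08
  xyz <- matrix(NA_real_, nrow = 24, ncol = 3)
  sym <- c("N", "N", rep("C", 12), rep("H", 10))
  xyz[1, ] <- c(0, 0, 0)                       # N1
  xyz[2, ] <- c(rNN, 0, 0)                     # N2
  # C1 (ipso A) bonded to N1, angle C1-N1-N2 = 120; fixed reference plane
  xyz[3, ] <- c(-rCN * cos(pi / 3), rCN * sin(pi / 3), 0)
  # C1' (ipso B) bonded to N2: torsion C1'-N2-N1-C1 = psi
  xyz[9, ] <- place_atom(xyz[3, ], xyz[1, ], xyz[2, ], rCN, 120, psi_deg)
  ring <- function(ipso, n_att, n_far, phi) {
    # ortho carbon: torsion C_ortho-C_ipso-N-N = phi
    idx <- numeric(6); idx[1] <- ipso
    c2 <- place_atom(n_far, n_att, xyz[ipso, ], rCC, 120, phi)
    # remaining ring atoms planar: torsions along the ring
    c3 <- place_atom(n_att, xyz[ipso, ], c2, rCC, 120, 180)
    c4 <- place_atom(xyz[ipso, ], c2, c3, rCC, 120, 0)
    c5 <- place_atom(c2, c3, c4, rCC, 120, 0)
    c6 <- place_atom(c3, c4, c5, rCC, 120, 0)
    rbind(c2, c3, c4, c5, c6)
  }
  ringA <- ring(3, xyz[1, ], xyz[2, ], phi1_deg)
  xyz[4:8, ] <- ringA
  ringB <- ring(9, xyz[2, ], xyz[1, ], phi2_deg)
  xyz[10:14, ] <- ringB
  # hydrogens on C2..C6 of each ring, in-plane, pointing outward
  h_on <- function(ca, cb, cc) place_atom(ca, cb, cc, rCH, 120, 180)
  ringA_all <- rbind(xyz[3, ], ringA)
  ringB_all <- rbind(xyz[9, ], ringB)
  for (i in 2:6) {
    prev2 <- ringA_all[((i - 3) %% 6) + 1, ]
    prev1 <- ringA_all[((i - 2) %% 6) + 1, ]
    xyz[13 + i, ] <- h_on(prev2, prev1, ringA_all[i, ])
    prev2b <- ringB_all[((i - 3) %% 6) + 1, ]
    prev1b <- ringB_all[((i - 2) %% 6) + 1, ]
    xyz[18 + i, ] <- h_on(prev2b, prev1b, ringB_all[i, ])
  }
  list(symbols = sym, coords = xyz,
       comment = sprintf("frame %d psi %.3f phi1 %.3f phi2 %.3f",
                         frame_index, psi_deg, phi1_deg, phi2_deg),
       frame_index = frame_index)
}

#' Dihedral specs matching the synthetic azobenzene scaffold atom order
#'
#' @return named list of [dihedral_spec()] (`psi`, `phi1`, `phi2`) for
#'   frames built by [gen_ensemble()]
#' @export
azo_scaffold_specs <- function() {
  list(
    psi  = dihedral_spec(c(3, 1, 2, 9), "psi"),
    phi1 = dihedral_spec(c(4, 3, 1, 2), "phi1"),
    phi2 = dihedral_spec(c(10, 9, 2, 1), "phi2")
  )
}

#' Generate a synthetic conformer ensemble with planted structure
#'
#' Emulates a thermally sampled molecular-dynamics ensemble with
#' per-snapshot vertical excitations: torsions psi/phi1/phi2 are drawn
#' from wrapped-normal distributions (the sign of the phi mean is
#' randomised per snapshot, mimicking the two symmetry-equivalent twist
#' directions), a 24-atom azobenzene scaffold is built from an
#' internal-coordinate template with those torsions imposed, and the
#' excitation energy follows the planted model
#' E = E0 - beta * para_weight * planarity - gamma * |cos psi| + noise,
#' with planarity = (|cos phi1| + |cos phi2|)/2. Oscillator strengths
#' are normal, truncated at 0. The emitted table carries the true
#' torsions so feature extraction from the geometries can be
#' cross-validated against them.
#'
#' @param profile a [compound_profile()] or preset name
#' @param n ensemble size (the study-scale default is 6000)
#' @param seed RNG seed; every output is deterministic given
#'   (profile, n, seed)
#' @param build_frames also build XYZ geometries (set `FALSE` when only
#'   the excitation table is needed)
#' @return list: `records` (data.frame `frame`, `isomer`, `energy_eV`,
#'   `osc_strength`, `psi_deg`, `phi1_deg`, `phi2_deg`, `cos_psi`,
#'   `abs_cos_phi1`, `abs_cos_phi2`, `planarity`), `frames` (list of
#'   XYZ frames or `NULL`), `profile`
#' @export
gen_ensemble <- function(profile, n = 6000, seed = 1, build_frames = TRUE) {
  if (is.character(profile)) profile <- profile_preset(profile)
  stopifnot(inherits(profile, "compound_profile"))
  if (n < 1) stop("ensemble size must be >= 1")
  set.seed(seed)
  p <- profile
  sgn1 <- sample(c(-1, 1), n, replace = TRUE)
  sgn2 <- sample(c(-1, 1), n, replace = TRUE)
  phi1 <- rwrapnorm_deg(n, sgn1 * p$phi_mean_deg, p$phi_sd_deg)
  phi2 <- rwrapnorm_deg(n, sgn2 * p$phi_mean_deg, p$phi_sd_deg)
  psi  <- rwrapnorm_deg(n, p$psi_mean_deg, p$psi_sd_deg)
  planarity <- (abs(cos(phi1 * pi / 180)) + abs(cos(phi2 * pi / 180))) / 2
  energy <- p$E0_eV - p$beta_eV * p$para_weight * planarity -
    p$gamma_eV * abs(cos(psi * pi / 180)) +
    stats::rnorm(n, 0, p$noise_sd_eV)
  f <- pmax(stats::rnorm(n, p$f_mean, p$f_sd), 0)
  records <- data.frame(
    frame = seq_len(n), isomer = p$isomer, energy_eV = energy,
    osc_strength = f, psi_deg = psi, phi1_deg = phi1, phi2_deg = phi2,
    cos_psi = cos(psi * pi / 180),
    abs_cos_phi1 = abs(cos(phi1 * pi / 180)),
    abs_cos_phi2 = abs(cos(phi2 * pi / 180)),
    planarity = planarity)
  frames <- NULL
  if (build_frames)
    frames <- lapply(seq_len(n), function(i)
      build_azo_frame(psi[i], phi1[i], phi2[i], frame_index = i))
  list(records = records, frames = frames, profile = profile)
}

#' Generate a synthetic kinetic trace with known ground truth
#'
#' Exact model curve plus seeded Gaussian noise. Kinds:
#' \describe{
#'   \item{`"mono"`}{`params = list(k, a, c)`: a exp(-k t) + c}
#'   \item{`"bi"`}{`params = list(ka, kb, a1, a2, c)`; the default
#'     preset uses half-lives of 20 min (fast phase) and 160 min (slow
#'     phase), the canonical two-step degradation pattern}
#'   \item{`"photoswitch"`}{`params = list(model, x0)` with a
#'     [photokinetic_model()]: noisy [simulate_photoswitching()]
#'     cis-fraction output under continuous light}
#' }
#'
#' @param kind trace kind
#' @param params model parameters (see above); `NULL` picks the preset
#' @param times sample times, s
#' @param noise_sd Gaussian noise SD on the signal
#' @param seed RNG seed
#' @param temperature metadata [temperature()]
#' @return a [kinetic_trace()] with attribute `"truth"` holding the
#'   generating parameters
#' @export
gen_trace <- function(kind = c("mono", "bi", "photoswitch"), params = NULL,
                      times = NULL, noise_sd = 0, seed = 1,
                      temperature = room_temperature()) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "mono") {
    if (is.null(params)) params <- list(k = log(2) / (3.16 * 3600), a = 1, c = 0)
    if (is.null(times)) times <- seq(0, 3 * log(2) / params$k, length.out = 50)
    y <- params$a * exp(-params$k * times) + params$c
  } else if (kind == "bi") {
    if (is.null(params))
      params <- list(ka = log(2) / (20 * 60), kb = log(2) / (160 * 60),
                     a1 = 0.5, a2 = 0.5, c = 0.05)
    if (is.null(times)) times <- seq(0, 6 * log(2) / params$kb, by = 120)
    y <- params$a1 * exp(-params$ka * times) +
         params$a2 * exp(-params$kb * times) + params$c
  } else {
    if (is.null(params) || is.null(params$model))
      stop("photoswitch kind needs params$model (a photokinetic_model)")
    x0 <- if (is.null(params$x0)) 0 else params$x0
    if (is.null(times)) times <- seq(0, 3600, by = 60)
    sched <- data.frame(duration_s = max(times), light = TRUE)
    sim <- simulate_photoswitching(params$model, sched, x0 = x0,
                                   dt = max(times) / 400)
    y <- stats::approx(sim$time_s, sim$cis_fraction, xout = times)$y
  }
  y_noisy <- y + stats::rnorm(length(times), 0, noise_sd)
  tr <- kinetic_trace(times, y_noisy, temperature = temperature,
                      signal_kind = if (kind == "photoswitch") "cis_fraction"
                                    else "absorbance")
  attr(tr, "truth") <- params
  tr
}

#' Generate a synthetic "experimental" UV-vis spectrum
#'
#' Takes a computed ensemble spectrum, applies a systematic energy
#' shift, converts to the wavelength domain, scales to absorbance, adds
#' seeded baseline noise, and attaches Beer-Lambert metadata (default:
#' 500 uM, 1 cm). Used to exercise the shift-calibration workflow with
#' a known planted shift.
#'
#' @param spec an `ensemble_spectrum`
#' @param shift_eV planted systematic shift, eV
#' @param scale amplitude scale to absorbance units
#' @param baseline_sd additive Gaussian noise SD, AU
#' @param noise_frac multiplicative noise SD (fraction of signal)
#' @param seed RNG seed
#' @param concentration_M,path_cm Beer-Lambert metadata
#' @return an [experimental_spectrum()] with attribute `"truth"`
#' @export
gen_experimental_spectrum <- function(spec, shift_eV = 0, scale = 1,
                                      baseline_sd = 0, noise_frac = 0,
                                      seed = 1, concentration_M = 5e-4,
                                      path_cm = 1) {
  set.seed(seed)
  shifted <- spec
  shifted$shift_eV <- spec$shift_eV + shift_eV
  tr <- to_wavelength(shifted)
  a <- tr$intensity * scale
  if (noise_frac > 0) a <- a * (1 + stats::rnorm(length(a), 0, noise_frac))
  if (baseline_sd > 0) a <- a + stats::rnorm(length(a), 0, baseline_sd)
  out <- experimental_spectrum(tr$wavelength_nm, a,
                               concentration_M = concentration_M,
                               path_cm = path_cm)
  attr(out, "truth") <- list(shift_eV = shift_eV, scale = scale)
  out
}

#' Generate a synthetic quantum-yield experiment
#'
#' Simulates the full irradiation experiment the quantum-yield
#' estimator consumes: the two-state model is integrated under
#' continuous light, the cis fraction is converted to absorbance at the
#' analysis wavelength via the two pure-isomer absorbances, noise is
#' added, and NMR anchor ratios are sampled at the given times.
#'
#' @param model a [photokinetic_model()] holding the true phi_tc
#' @param times absorbance sampling times, s
#' @param anchor_times NMR anchor times, s
#' @param A_trans,A_cis pure-isomer absorbances at the analysis
#'   wavelength
#' @param noise_sd absorbance noise SD (default 0.002 AU)
#' @param seed RNG seed
#' @return list: `trace` (data.frame `time_s`, `absorbance`), `anchors`
#'   (data.frame `time_s`, `cis_fraction`), `truth`
#' @export
gen_qy_experiment <- function(model, times = seq(0, 14400, by = 60),
                              anchor_times = c(0, 3600, 7200, 14400),
                              A_trans = 0.20, A_cis = 0.35,
                              noise_sd = 0.002, seed = 1) {
  stopifnot(inherits(model, "photokinetic_model"))
  set.seed(seed)
  sched <- data.frame(duration_s = max(times), light = TRUE)
  sim <- simulate_photoswitching(model, sched, x0 = 0,
                                 dt = max(times) / 1000)
  x_at <- function(tt) stats::approx(sim$time_s, sim$cis_fraction, xout = tt)$y
  x <- x_at(times)
  absorbance <- A_trans + (A_cis - A_trans) * x +
    stats::rnorm(length(times), 0, noise_sd)
  anchors <- data.frame(time_s = anchor_times,
                        cis_fraction = x_at(anchor_times))
  list(trace = data.frame(time_s = times, absorbance = absorbance),
       anchors = anchors,
       truth = list(phi_tc = model$phi_tc, A_trans = A_trans, A_cis = A_cis))
}
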