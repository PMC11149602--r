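#' Synthetic 4D dynamic phantoms
#'
#' Desk-scale stand-ins for whole-body dynamic FDG acquisitions: a
#' bolus-like arterial input, rectangular/ellipsoidal "organs" with known
#' ground-truth residues (compartmental or not), frame-averaged forward
#' signals, and multiplicatively structured skewed noise
#' sigma_e * psi_i * phi_j * eps with eps drawn from a standardised shifted
#' gamma.  All phantom data are synthetic; they emulate acquisition
#' structure, not anatomy or scanner physics.
#'
#' @name phantom
NULL

#' Bolus arterial input function
#'
#' Gamma-variate bolus plus a two-exponential washout tail, zero before the
#' injection time.  With zero tail amplitudes the curve is a pure
#' gamma-variate with peak at \code{t0_s + shape * scale_s}.
#'
#' @param schedule a \code{frame_schedule} (sets the sample support).
#' @param peak_kBq_ml bolus peak height.
#' @param t0_s injection time, seconds.
#' @param shape,scale_s gamma-variate shape and scale (peak at shape*scale).
#' @param tail_amps,tail_rates_per_min two-exponential tail amplitudes
#'   (kBq/mL) and rates (1/min).
#' @param dt_s sample spacing of the returned curve.
#' @return an \code{input_function}.
#' @export
make_aif <- function(schedule, peak_kBq_ml = 50, t0_s = 15, shape = 4,
                     scale_s = 4, tail_amps = c(6, 3),
                     tail_rates_per_min = c(0.12, 0.01), dt_s = 1) {
  if (shape <= 0 || scale_s <= 0) stop("gamma-variate parameters must be positive")
  if (any(tail_amps < 0)) stop("tail amplitudes must be non-negative")
  t <- seq(0, schedule$end_s[schedule$J], by = dt_s)
  u <- pmax(t - t0_s, 0)
  tp <- shape * scale_s
  g <- ifelse(u > 0, (u / tp)^shape * exp(shape * (1 - u / tp)), 0)
  ramp <- (1 - exp(-u / tp))^2          # smooth onset of the washout tail
  tail <- ramp * (tail_amps[1] * exp(-tail_rates_per_min[1] * u / 60) +
                  tail_amps[2] * exp(-tail_rates_per_min[2] * u / 60))
  input_function(t, peak_kBq_ml * g + tail)
}

# simple geometric organ masks on an (nx, ny, nz) grid
.box_mask <- function(dim, lo, hi) {
  a <- array(FALSE, dim)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  a
}

#' Named phantom presets
#'
#' \describe{
#'   \item{twocomp}{three organs with two-compartment ground-truth residues
#'     (vascular triangle + biexponential), all within the span of a 2C
#'     model.}
#'   \item{mixed}{liver/kidney-like organs with non-exponential residues
#'     (linear-decay distribution phases) that a 2C model cannot represent.}
#'   \item{flat}{constant residues (pure trapping, Patlak-like):
#'     V_b = V_d = 0 everywhere.}
#' }
#'
#' @param name preset name.
#' @param dim grid dimensions (default 32 x 32 x 48 to give a usable axial
#'   direction; acceptance phantoms use smaller cubes).
#' @param T_end_s residue support end (should match the schedule).
#' @return a \code{phantom_spec} list: organs (name, mask, residue,
#'   delay_s), noise defaults, dim.
#' @export
standard_phantoms <- function(name = c("twocomp", "mixed", "flat"),
                              dim = c(32, 32, 48), T_end_s = 3900) {
  name <- match.arg(name)
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  third <- floor(nz / 3)
  m1 <- .box_mask(dim, c(2, 2, 2), c(floor(nx / 2), ny - 1, third))
  m2 <- .box_mask(dim, c(2, 2, third + 2), c(nx - 1, floor(ny / 2), 2 * third))
  m3 <- .box_mask(dim, c(floor(nx / 2) + 1, floor(ny / 2) + 1, 2 * third + 1),
                  c(nx - 1, ny - 1, nz - 1))
  masks <- list(m1, m2, m3)
  # ensure disjoint (construction keeps them disjoint by z-bands except m1/m2 overlap guard)
  masks[[2]][masks[[1]]] <- FALSE
  masks[[3]][masks[[1]] | masks[[2]]] <- FALSE

  organs <- switch(name,
    twocomp = list(
      list(name = "gm",    mask = masks[[1]], delay_s = 2,
           residue = residue_2c(twoc_params(0.60, 0.9, 0.06, 0, 0.05), 15, T_end_s)),
      list(name = "liver", mask = masks[[2]], delay_s = 8,
           residue = residue_2c(twoc_params(0.50, 0.55, 0.005, 0, 0.09), 15, T_end_s)),
      list(name = "tumor", mask = masks[[3]], delay_s = 4,
           residue = residue_2c(twoc_params(0.30, 0.35, 0.08, 0, 0.08), 15, T_end_s))),
    mixed = list(
      list(name = "liver", mask = masks[[1]], delay_s = 8,
           residue = .linear_decay_residue(Vb = 0.09, K_d = 0.5, tau_min = 3.2,
                                           K_i = 0.003, T_end_s = T_end_s)),
      list(name = "kidney", mask = masks[[2]], delay_s = 4,
           residue = .linear_decay_residue(Vb = 0.25, K_d = 0.5, tau_min = 5,
                                           K_i = 0.005, T_end_s = T_end_s)),
      list(name = "tumor", mask = masks[[3]], delay_s = 6,
           residue = residue_2c(twoc_params(0.30, 0.35, 0.08, 0, 0.08), 15, T_end_s))),
    flat = list(
      list(name = "gm",    mask = masks[[1]], delay_s = 0,
           residue = .flat_residue(0.03, T_end_s)),
      list(name = "liver", mask = masks[[2]], delay_s = 0,
           residue = .flat_residue(0.01, T_end_s)),
      list(name = "tumor", mask = masks[[3]], delay_s = 0,
           residue = .flat_residue(0.05, T_end_s))))

  structure(list(name = name, dim = dim, organs = organs,
                 noise = list(sigma_e = 0.4, skewness = 1.5,
                              psi_axial_amp = 0.5, phi_mode = "counts"),
                 T_end_s = T_end_s),
            class = "phantom_spec")
}

# non-compartmental ground truth: triangle vascular part + linear-decay
# distribution phase (not a sum of two exponentials) + trapped plateau
.linear_decay_residue <- function(Vb, K_d, tau_min, K_i, T_end_s, t_star_s = 15) {
  g <- sort(unique(c(seq(0, t_star_s, length.out = 16),
                     exp(seq(log(t_star_s), log(T_end_s), length.out = 50)),
                     T_end_s)))
  tri <- 2 * Vb / (t_star_s / 60) * pmax(1 - g / t_star_s, 0)
  dist <- K_d * pmax(1 - (g / 60) / tau_min, 0)
  residue(g, tri + dist + K_i, tol = 1e-6)
}

.flat_residue <- function(K_i, T_end_s) {
  residue(c(0, T_end_s), c(K_i, K_i))
}

#' Simulate a dynamic phantom image with ground truth
#'
#' Noiseless voxel curves are the frame-averaged convolutions of each
#' organ's residue with its delayed AIF; noise is added per Eq.-3-style
#' structure: \code{sigma_e * psi_i * phi_j * eps_ij} with standardised
#' shifted-gamma eps (mean 0, variance 1, configurable skewness), a
#' U-shaped axial psi profile and a 1/sqrt(duration x decay) phi profile
#' (both normalised as in the DGP).
#'
#' @param spec a \code{phantom_spec}.
#' @param schedule a \code{frame_schedule}.
#' @param aif an \code{input_function} (default \code{make_aif(schedule)}).
#' @param sigma_e overall noise scale, kBq/mL (0 = noiseless); default from
#'   the \code{phantom_spec}.
#' @param skewness noise skewness (shifted gamma).
#' @param seed RNG seed.
#' @return list: \code{image} (\code{dynamic_image}, mask = union of
#'   organs), \code{truth} (per-organ kinetic parameters and maps),
#'   \code{organ_labels} (3D int array), \code{aif}, \code{psi},
#'   \code{phi}, \code{noiseless} (J x N matrix).
#' @export
simulate_image <- function(spec, schedule, aif = make_aif(schedule),
                           sigma_e = spec$noise$sigma_e,
                           skewness = spec$noise$skewness, seed = 1) {
  J <- schedule$J
  dim3 <- spec$dim
  labels <- array(0L, dim3)
  for (oi in seq_along(spec$organs)) {
    if (any(labels[spec$organs[[oi]]$mask] != 0L)) stop("organs overlap")
    labels[spec$organs[[oi]]$mask] <- oi
  }
  mask <- labels > 0L
  fg <- fine_grid(schedule, dt = 1)
  tpos <- fg$s
  curves <- vapply(spec$organs, function(org) {
    cp <- eval_input(aif, fg$t - org$delay_s)
    rf <- eval_residue(org$residue, tpos) / 60
    frame_average_indexed(conv_causal(rf, cp, fg$dt), fg$bins)
  }, numeric(J))
  curves <- matrix(curves, nrow = J)

  vox_lab <- labels[mask]
  N <- sum(mask)
  noiseless <- curves[, vox_lab, drop = FALSE]

  zidx <- arrayInd(which(mask), dim3)[, 3]
  mid <- (1 + dim3[3]) / 2
  half <- max(dim3[3] - mid, 1)
  psi <- 1 + spec$noise$psi_axial_amp * ((zidx - mid) / half)^2
  psi <- psi / sqrt(mean(psi^2))
  w <- fit_weights(schedule)
  phi <- 1 / sqrt(w / max(w))
  phi <- phi / sqrt(sum(w / sum(w) * phi^2))

  set.seed(seed)
  Z <- noiseless
  if (sigma_e > 0) {
    eps <- matrix(.std_skew_gamma(J * N, skewness), J, N)
    Z <- noiseless + sigma_e * sweep(sweep(eps, 2, psi, "*"), 1, phi, "*")
  }
  img_data <- array(0, c(dim3, J))
  flat <- matrix(img_data, prod(dim3), J)
  flat[as.vector(mask), ] <- t(Z)
  image <- dynamic_image(array(flat, c(dim3, J)), schedule, mask = mask)

  truth_params <- lapply(spec$organs, function(org) {
    kinetic_params(decompose_residue(org$residue, 15, schedule$end_s[J]))
  })
  truth_maps <- lapply(c("V_b", "V_d", "K_d", "K_i", "MTT", "Ext"), function(pn) {
    v <- vapply(truth_params, function(p) {
      val <- p[[pn]]
      if (is.null(val) || is.na(val)) NA_real_ else val
    }, numeric(1))
    map_from_vector(v[vox_lab], image)
  })
  names(truth_maps) <- c("V_b", "V_d", "K_d", "K_i", "MTT", "Ext")

  list(image = image, truth = list(params = truth_params, maps = truth_maps),
       organ_labels = labels, aif = aif, psi = psi, phi = phi,
       noiseless = noiseless, organ_curves = curves,
       organ_delays = vapply(spec$organs, `[[`, numeric(1), "delay_s"))
}

# standardised shifted gamma: mean 0, variance 1, skewness s (s = 0 falls
# back to gaussian)
.std_skew_gamma <- function(n, s) {
  if (abs(s) < 1e-8) return(stats::rnorm(n))
  shape <- 4 / s^2
  (stats::rgamma(n, shape = shape, rate = 1) - shape) / sqrt(shape) * sign(s)
}

#' Write a simulated phantom to disk
#'
#' Writes dyn.nii.gz, organs.nii.gz, truth maps, frames.csv and aif.csv to
#' a directory.
#'
#' @param sim output of \code{\link{simulate_image}}.
#' @param schedule the schedule used.
#' @param dir output directory (created).
#' @export
write_phantom <- function(sim, schedule, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti(sim$image$data, file.path(dir, "dyn.nii.gz"),
              voxel_size_mm = sim$image$voxel_size_mm)
  write_nifti(array(as.numeric(sim$organ_labels), dim(sim$organ_labels)),
              file.path(dir, "organs.nii.gz"),
              voxel_size_mm = sim$image$voxel_size_mm)
  for (pn in names(sim$truth$maps)) {
    m <- sim$truth$maps[[pn]]
    m[is.na(m)] <- 0
    write_nifti(m, file.path(dir, sprintf("truth_%s.nii.gz", pn)),
                voxel_size_mm = sim$image$voxel_size_mm)
  }
  write_schedule(schedule, file.path(dir, "frames.csv"))
  write_aif(sim$aif, file.path(dir, "aif.csv"))
  invisible(dir)
}
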