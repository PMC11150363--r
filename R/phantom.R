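#' Parameters of the age-encoded phantom generator
#'
#' The generator renders brain-like 3D phantoms whose morphology encodes the
#' two structural signatures of brain aging the literature emphasises:
#' ventricular enlargement and loss of overall tissue volume.  Each phantom is
#' a concentric ellipsoidal structure: zero background, a bright outer
#' "skull/scalp" shell, an interior "brain" compartment whose overall size
#' depends on sex, and a central low-intensity "ventricle" ellipsoid whose
#' radius grows linearly with age.  Optional additive noise and a smooth
#' multiplicative bias field emulate scanner artifacts.
#'
#' @param shape integer length-3 target grid; `c(32, 32, 16)` is the desk-test
#'   scale, `c(64, 64, 32)` mirrors the deployment input grid.
#' @param ventricle_base_radius ventricle semi-axis in voxels (along the
#'   largest grid axis) at age 0; `NULL` scales the reference value (1.5
#'   voxels on a 32-voxel axis) to the grid, keeping geometry
#'   resolution-independent.
#' @param ventricle_growth ventricle radius growth in voxels per year of age;
#'   `NULL` scales the reference value (0.07 voxels/year on a 32-voxel axis)
#'   to the grid.
#' @param shell_intensity,brain_intensity,ventricle_intensity intensity levels
#'   of the three compartments (arbitrary units, all positive).
#' @param sex_scale fractional whole-brain volume difference between the sexes
#'   (male brains rendered larger by `sex_scale/2`, female smaller by the same).
#' @param noise_sd additive zero-mean Gaussian noise level.
#' @param bias_amplitude log-scale standard deviation of the multiplicative
#'   smooth bias field (an exponentiated random quadratic; 0 disables it).
#' @param ad_delta_mean,ad_delta_sd mean and sd (years) of the accelerated-aging
#'   offset added to the rendered (not recorded) age of AD subjects.
#' @param max_age largest age (years) the geometry must accommodate; the
#'   constructor verifies the ventricle stays inside the brain up to this age.
#' @param scan_interval years between repeated scans of one subject.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(32, 32, 16),
                           ventricle_base_radius = NULL,
                           ventricle_growth = NULL,
                           shell_intensity = 1.0,
                           brain_intensity = 0.6,
                           ventricle_intensity = 0.15,
                           sex_scale = 0.08,
                           noise_sd = 0.02,
                           bias_amplitude = 0,
                           ad_delta_mean = 5,
                           ad_delta_sd = 2,
                           max_age = 120,
                           scan_interval = 1.0) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  if (is.null(ventricle_base_radius)) ventricle_base_radius <- 1.5 / 32 * max(shape)
  if (is.null(ventricle_growth)) ventricle_growth <- 0.07 / 32 * max(shape)
  if (ventricle_base_radius <= 0 || ventricle_growth < 0 ||
      any(c(shell_intensity, brain_intensity, ventricle_intensity) <= 0)) {
    stop("radii and intensities must be positive")
  }
  if (sex_scale < 0 || sex_scale >= 1) stop("sex_scale must be in [0, 1)")
  p <- structure(list(shape = shape,
                      ventricle_base_radius = ventricle_base_radius,
                      ventricle_growth = ventricle_growth,
                      shell_intensity = shell_intensity,
                      brain_intensity = brain_intensity,
                      ventricle_intensity = ventricle_intensity,
                      sex_scale = sex_scale,
                      noise_sd = noise_sd,
                      bias_amplitude = bias_amplitude,
                      ad_delta_mean = ad_delta_mean,
                      ad_delta_sd = ad_delta_sd,
                      max_age = max_age,
                      scan_interval = scan_interval),
                 class = "phantom_params")
  # ventricle must stay strictly inside the (smaller-sex) brain ellipsoid at
  # the maximum configured age
  r_rel <- .ventricle_rel_radius(p, max_age)
  if (r_rel >= 0.95 * .brain_rel_radius(p, sex = 0)) {
    stop("ventricle (relative radius ", signif(r_rel, 3), ") would breach the ",
         "brain ellipsoid (relative radius ",
         signif(.brain_rel_radius(p, 0), 3), ") at max_age = ", max_age)
  }
  p
}

# ventricle semi-axis as a fraction of the largest grid axis
.ventricle_rel_radius <- function(params, age) {
  (params$ventricle_base_radius + params$ventricle_growth * age) /
    max(params$shape)
}

# brain semi-axis as a fraction of each grid axis (sex-scaled isotropically so
# brain-mask voxel counts differ by ~sex_scale between the sexes)
.brain_rel_radius <- function(params, sex) {
  sgn <- if (sex == 1) 1 else -1
  0.40 * (1 + sgn * params$sex_scale / 2)^(1 / 3)
}

.shell_rel_radius <- function(params, sex) {
  sgn <- if (sex == 1) 1 else -1
  0.47 * (1 + sgn * params$sex_scale / 2)^(1 / 3)
}

# squared normalised ellipsoid coordinate for every voxel
.ellipsoid_dist2 <- function(shape, semi_axes) {
  cx <- (shape + 1) / 2
  u1 <- ((seq_len(shape[1]) - cx[1]) / semi_axes[1])^2
  u2 <- ((seq_len(shape[2]) - cx[2]) / semi_axes[2])^2
  u3 <- ((seq_len(shape[3]) - cx[3]) / semi_axes[3])^2
  outer(outer(u1, u2, `+`), u3, `+`)
}

#' Render one age-encoded phantom volume
#'
#' Deterministic for a fixed `(age, sex, params, seed)`.  The returned
#' [volume_image] carries the ground-truth brain mask (interior of the shell,
#' ventricle included) in `$mask` and the full signal region (shell included)
#' in `$signal_mask`.
#'
#' @param age age in years to encode (>= 0).
#' @param sex 0 (female) or 1 (male).
#' @param params a [phantom_params].
#' @param seed integer seed driving noise and bias field.
#' @return A [volume_image] with `mask` and `signal_mask`.
#' @export
make_phantom <- function(age, sex, params = phantom_params(), seed = 1L) {
  stopifnot(inherits(params, "phantom_params"), age >= 0, sex %in% c(0, 1))
  shape <- params$shape
  r_rel <- .ventricle_rel_radius(params, age)
  b_rel <- .brain_rel_radius(params, sex)
  if (r_rel >= 0.95 * b_rel) {
    stop("age ", age, " makes the ventricle (relative radius ",
         signif(r_rel, 3), ") breach the brain ellipsoid (relative radius ",
         signif(b_rel, 3), ")")
  }
  d2_shell <- .ellipsoid_dist2(shape, .shell_rel_radius(params, sex) * shape)
  d2_brain <- .ellipsoid_dist2(shape, b_rel * shape)
  d2_vent <- .ellipsoid_dist2(shape, r_rel * max(shape) * shape / max(shape))
  in_shell <- d2_shell <= 1
  in_brain <- d2_brain <= 1
  in_vent <- d2_vent <= 1
  grid <- array(0, dim = shape)
  grid[in_shell] <- params$shell_intensity
  grid[in_brain] <- params$brain_intensity
  grid[in_vent & in_brain] <- params$ventricle_intensity
  with_seed(seed, {
    if (params$bias_amplitude > 0) {
      field <- .bias_field(shape, params$bias_amplitude)
      # unit mean over brain tissue: the overall intensity scale belongs to
      # the tissue, not the artifact (scale is unidentifiable otherwise)
      grid <- grid * (field / mean(field[in_brain]))
    }
    if (params$noise_sd > 0) {
      grid <- grid + array(stats::rnorm(prod(shape), sd = params$noise_sd), shape)
    }
  })
  out <- volume_image(grid, spacing = c(1, 1, 1), mask = in_brain)
  out$signal_mask <- in_shell
  out
}

# exponentiated centred random quadratic in normalised coordinates, scaled to
# the requested log-amplitude; the same multiplicative smooth-field model the
# bias-correction stage assumes
.bias_field <- function(shape, amplitude) {
  co <- stats::rnorm(9)
  t1 <- seq(-1, 1, length.out = shape[1])
  t2 <- seq(-1, 1, length.out = shape[2])
  t3 <- seq(-1, 1, length.out = shape[3])
  gx <- array(rep(t1, times = shape[2] * shape[3]), shape)
  gy <- array(rep(rep(t2, each = shape[1]), times = shape[3]), shape)
  gz <- array(rep(t3, each = shape[1] * shape[2]), shape)
  b <- co[1] * gx + co[2] * gy + co[3] * gz +
    co[4] * gx^2 + co[5] * gy^2 + co[6] * gz^2 +
    co[7] * gx * gy + co[8] * gx * gz + co[9] * gy * gz
  b <- b - mean(b)
  s <- stats::sd(as.vector(b))
  if (s > 0) b <- b * (amplitude / s)
  exp(b)
}

#' Generate a synthetic cohort of phantom scans
#'
#' Draws subject ages uniformly on `age_range`, assigns sexes at random and
#' marks `round(n_subjects * ad_fraction)` subjects as AD.  AD subjects are
#' rendered at an effective age `chronological + delta` with
#' `delta ~ Normal(ad_delta_mean, ad_delta_sd)` truncated at zero, but their
#' manifest age stays chronological — AD appears as accelerated aging, exactly
#' the premise of the brain-age-gap biomarker.  Repeated scans of one subject
#' are spaced `params$scan_interval` years apart.
#'
#' @param n_subjects number of subjects (>= 2 when `ad_fraction` is in (0,1)).
#' @param age_range `c(lo, hi)` years, `hi > lo`.
#' @param ad_fraction fraction of subjects labelled AD.
#' @param scans_per_subject scans per subject (>= 1).
#' @param params a [phantom_params].
#' @param seed integer seed; the cohort is a pure function of the arguments
#'   and this seed.
#' @param dir optional output directory; when given, NIfTI volumes,
#'   ground-truth masks and `manifest.csv` are written there.
#' @return A list with elements `cohort` (a [cohort]; `scan_path` points at
#'   the written files, or at `mem://` ids when `dir` is `NULL`), `volumes`
#'   (list of [volume_image]s in manifest order) and `delta` (per-subject
#'   aging offsets, 0 for CN).
#' @export
make_cohort <- function(n_subjects, age_range = c(20, 80), ad_fraction = 0,
                        scans_per_subject = 1L, params = phantom_params(),
                        seed = 1L, dir = NULL) {
  stopifnot(n_subjects >= 1, scans_per_subject >= 1,
            ad_fraction >= 0, ad_fraction <= 1)
  if (age_range[2] <= age_range[1]) {
    stop("age_range must satisfy hi > lo; got [", age_range[1], ", ",
         age_range[2], "]")
  }
  if (ad_fraction > 0 && ad_fraction < 1 && n_subjects < 2) {
    stop("need at least 2 subjects for a mixed CN/AD cohort")
  }
  n_ad <- round(n_subjects * ad_fraction)
  draws <- with_seed(seed, {
    ages <- stats::runif(n_subjects, age_range[1], age_range[2])
    sexes <- stats::rbinom(n_subjects, 1, 0.5)
    ad_ids <- if (n_ad > 0) sample(n_subjects, n_ad) else integer(0)
    delta <- rep(0, n_subjects)
    for (i in ad_ids) {
      repeat {  # Normal(ad_delta_mean, ad_delta_sd) truncated at 0
        d <- stats::rnorm(1, params$ad_delta_mean, params$ad_delta_sd)
        if (d >= 0) break
      }
      delta[i] <- d
    }
    list(ages = ages, sexes = sexes, ad_ids = ad_ids, delta = delta)
  })
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- vector("list", n_subjects * scans_per_subject)
  volumes <- vector("list", n_subjects * scans_per_subject)
  k <- 0L
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("subj%04d", i)
    dx <- if (i %in% draws$ad_ids) "AD" else "CN"
    for (s in seq_len(scans_per_subject)) {
      k <- k + 1L
      scan_age <- draws$ages[i] + (s - 1L) * params$scan_interval
      render_age <- scan_age + draws$delta[i]
      scan_seed <- (as.integer(seed) + i * 1009L + s * 101L) %% 2147483647L
      vol <- make_phantom(render_age, draws$sexes[i], params, seed = scan_seed)
      path <- if (is.null(dir)) {
        sprintf("mem://%s_scan%d", sid, s)
      } else {
        p <- file.path(dir, sprintf("%s_scan%d.nii.gz", sid, s))
        write_volume(vol, p)
        mask_vol <- volume_image(array(as.numeric(vol$mask), dim(vol$mask)))
        write_volume(mask_vol, file.path(dir, sprintf("%s_scan%d_mask.nii.gz", sid, s)))
        p
      }
      rows[[k]] <- data.frame(subject_id = sid, scan_path = path,
                              age = scan_age, sex = draws$sexes[i],
                              diagnosis = dx, stringsAsFactors = FALSE)
      volumes[[k]] <- vol
    }
  }
  records <- do.call(rbind, rows)
  ch <- cohort(records)
  if (!is.null(dir)) write_manifest(ch, file.path(dir, "manifest.csv"))
  names(draws$delta) <- sprintf("subj%04d", seq_len(n_subjects))
  list(cohort = ch, volumes = volumes, delta = draws$delta)
}
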