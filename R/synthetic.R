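# Seeded synthetic data: paired-modality cohorts whose class signal is split
# across a CT-like and an X-ray-like channel, and annular airway phantoms
# with closed-form ground truth.  The cohort emulates the pathology the
# networks are meant to detect -- a thickened bronchial wall with a narrowed
# lumen on CT, and global hyperlucency on the chest film -- on network-ready
# 28x28 arrays in [0,1].  A shared per-subject latent severity scales both
# channels so the modalities are correlated but not redundant.

#' Cohort specification
#'
#' @param n_subjects number of subjects.
#' @param copd_fraction fraction of subjects with label 1 (COPD), in (0,1).
#'   Default 58/108, the prevalence of the motivating 58-patient /
#'   50-control clinical cohort.
#' @param ct_effect nonnegative strength of the CT-channel class signal
#'   (wall thickening / lumen narrowing). 1 is a clearly visible remodeling.
#' @param xray_effect nonnegative strength of the X-ray-channel signal
#'   (global lucency shift).
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (images are clipped to \[0,1\] afterwards).
#' @param seed integer seed; regeneration with an identical spec is
#'   bit-identical.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 108L, copd_fraction = 58 / 108,
                        ct_effect = 1, xray_effect = 1,
                        noise_sd = 0.05, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1L) stop("n_subjects must be positive")
  if (!is.finite(copd_fraction) || copd_fraction <= 0 || copd_fraction >= 1)
    stop("copd_fraction must lie strictly between 0 and 1")
  if (ct_effect < 0 || xray_effect < 0) stop("effect strengths must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(n_subjects = n_subjects, copd_fraction = copd_fraction,
                 ct_effect = ct_effect, xray_effect = xray_effect,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' One subject's paired images and label
#'
#' @param subject_id identifier string.
#' @param ct_image,xray_image 28x28 numeric matrices with finite values in
#'   \[0,1\].
#' @param label 0 (healthy) or 1 (COPD).
#' @return An object of class `labeled_image_pair`.
#' @export
labeled_image_pair <- function(subject_id, ct_image, xray_image, label) {
  for (im in list(ct_image, xray_image)) {
    if (!is.matrix(im) || !all(dim(im) == c(28L, 28L)))
      stop("images must be 28x28 matrices")
    if (!all(is.finite(im)) || any(im < 0) || any(im > 1))
      stop("intensities must be finite and within [0,1]")
  }
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1")
  structure(list(subject_id = as.character(subject_id),
                 ct_image = ct_image, xray_image = xray_image,
                 label = as.integer(label)),
            class = "labeled_image_pair")
}

# radial distance of every pixel center from an image-center annulus
radial_grid <- function(size, cx = (size + 1) / 2, cy = (size + 1) / 2) {
  x <- matrix(seq_len(size), size, size)
  sqrt((x - cx)^2 + (t(x) - cy)^2)
}

# CT-like slice: dark lumen inside a bright airway wall on a soft-tissue
# background.  Severity (0 for healthy) thickens the wall outward and
# narrows the lumen, scaled by ct_effect.
ct_slice <- function(r, severity, ct_effect) {
  r_in <- max(1.5, 6 - 2 * ct_effect * severity)
  r_out <- min(12.5, 8 + 2.5 * ct_effect * severity)
  img <- matrix(0.30, nrow(r), ncol(r))
  img[r <= r_out] <- 0.85
  img[r <= r_in] <- 0.10
  img
}

# X-ray-like film: fixed rib-band texture over a vertical gradient; severity
# adds a global lucency (brightening) shift scaled by xray_effect.
xray_film <- function(severity, xray_effect, size = 28L) {
  rows <- matrix(seq_len(size), size, size)
  base <- 0.40 + 0.05 * (rows / size) + 0.10 * sin(2 * pi * rows / 7)
  base + 0.20 * xray_effect * severity
}

#' Generate a paired-modality cohort
#'
#' COPD subjects (label 1) draw a latent severity uniform on \[0.5, 1\] that
#' scales both channels' signals; healthy subjects have severity 0.  Each
#' image receives independent Gaussian noise of sd `noise_sd` and is clipped
#' to \[0,1\].  The number of COPD subjects is `round(n * copd_fraction)`.
#'
#' @param spec a [cohort_spec()].
#' @return list of [labeled_image_pair()] objects, with the generating spec
#'   attached as attribute `"spec"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  n_copd <- as.integer(round(n * spec$copd_fraction))
  if (n_copd < 1L || n_copd >= n)
    stop("copd_fraction leaves one class empty at this n_subjects")
  r <- radial_grid(28L)
  withr::with_seed(spec$seed, {
    labels <- sample(rep(c(1L, 0L), c(n_copd, n - n_copd)))
    pairs <- vector("list", n)
    for (i in seq_len(n)) {
      severity <- if (labels[i] == 1L) stats::runif(1, 0.5, 1) else 0
      ct <- ct_slice(r, severity, spec$ct_effect)
      xr <- xray_film(severity, spec$xray_effect)
      if (spec$noise_sd > 0) {
        ct <- ct + matrix(stats::rnorm(784L, 0, spec$noise_sd), 28L, 28L)
        xr <- xr + matrix(stats::rnorm(784L, 0, spec$noise_sd), 28L, 28L)
      }
      pairs[[i]] <- labeled_image_pair(
        sprintf("S%03d", i), clip01(ct), clip01(xr), labels[i])
    }
    structure(pairs, spec = spec)
  })
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Stratified train/test split
#'
#' Splits by label with largest-remainder apportioning so the overall train
#' size is `round(train_fraction * n)` and each class's ratio is preserved
#' to within one subject; membership is deterministic under `seed`.
#'
#' @param dataset list of [labeled_image_pair()] objects.
#' @param train_fraction fraction in (0,1).
#' @param seed integer seed.
#' @return list with elements `train` and `test` (disjoint, union = input).
#' @export
split_cohort <- function(dataset, train_fraction = 0.75, seed = 1L) {
  if (length(dataset) == 0L) stop("dataset is empty")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  labels <- vapply(dataset, function(p) p$label, integer(1))
  classes <- sort(unique(labels))
  n_total_train <- round(train_fraction * length(dataset))
  exact <- vapply(classes, function(cl) train_fraction * sum(labels == cl),
                  numeric(1))
  base <- floor(exact)
  rem <- n_total_train - sum(base)
  if (rem > 0) {
    # largest fractional remainder first; ties go to the larger class
    ord <- order(exact - base, vapply(classes, function(cl) sum(labels == cl),
                                      numeric(1)), decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  take <- withr::with_seed(as.integer(seed), {
    unlist(lapply(seq_along(classes), function(j) {
      idx <- which(labels == classes[j])
      k <- base[j]
      if (k < 1L || k >= length(idx))
        stop("train_fraction would leave a class empty in train or test")
      sample(idx, k)
    }))
  })
  list(train = dataset[sort(take)], test = dataset[-sort(take)])
}

#' Phantom specification for an annular airway cross-section
#'
#' @param image_size pixels per side.
#' @param center pair of pixel coordinates (defaults to the image center).
#' @param lumen_radius,outer_radius radii in pixels; `outer_radius >
#'   lumen_radius > 0`.
#' @param lumen_intensity,wall_intensity,background_intensity compartment
#'   intensities in \[0,1\]; the wall must be the brightest compartment.
#' @param noise_sd additive Gaussian noise sd.
#' @param pixel_size mm per pixel.
#' @param seed integer seed for the noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L, center = NULL,
                         lumen_radius = 8, outer_radius = 12,
                         lumen_intensity = 0.10, wall_intensity = 0.90,
                         background_intensity = 0.35,
                         noise_sd = 0, pixel_size = 1, seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 4L) stop("image_size too small")
  # integer default center: a disc centered between pixels undercounts by
  # ~3.5% at r = 8 under pixel-center membership, a lattice-centered one by
  # ~2%, which keeps discretization inside the documented error budget
  if (is.null(center)) center <- rep(ceiling(image_size / 2), 2L)
  if (!(outer_radius > lumen_radius && lumen_radius > 0))
    stop("need outer_radius > lumen_radius > 0")
  ints <- c(lumen_intensity, wall_intensity, background_intensity)
  if (any(ints < 0 | ints > 1)) stop("intensities must lie in [0,1]")
  if (!(wall_intensity > background_intensity && wall_intensity > lumen_intensity))
    stop("the wall must be the brightest compartment")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(image_size = image_size, center = as.numeric(center),
                 lumen_radius = lumen_radius, outer_radius = outer_radius,
                 lumen_intensity = lumen_intensity,
                 wall_intensity = wall_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, pixel_size = pixel_size,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate an annular airway phantom with analytic ground truth
#'
#' Pixel-center membership assigns each pixel to lumen (disc of
#' `lumen_radius`), wall (annulus up to `outer_radius`) or background, then
#' seeded Gaussian noise is added and the image clipped to \[0,1\].  Ground
#' truth uses the continuous geometry:
#' `true_LA = pi * (lumen_radius * pixel_size)^2`,
#' `true_WA = pi * ((outer_radius * pixel_size)^2 - (lumen_radius * pixel_size)^2)`,
#' `true_WA_percent = 100 * true_WA / (true_WA + true_LA)`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (matrix), `truth` (list `true_LA`, `true_WA`,
#'   `true_WA_percent`, in mm^2 / percent) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  r <- radial_grid(spec$image_size, spec$center[1], spec$center[2])
  img <- matrix(spec$background_intensity, spec$image_size, spec$image_size)
  img[r <= spec$outer_radius] <- spec$wall_intensity
  img[r <= spec$lumen_radius] <- spec$lumen_intensity
  if (spec$noise_sd > 0) {
    img <- withr::with_seed(spec$seed, {
      clip01(img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                          nrow(img), ncol(img)))
    })
  }
  la <- pi * (spec$lumen_radius * spec$pixel_size)^2
  wa <- pi * ((spec$outer_radius * spec$pixel_size)^2 -
                (spec$lumen_radius * spec$pixel_size)^2)
  list(image = img,
       truth = list(true_LA = la, true_WA = wa,
                    true_WA_percent = 100 * wa / (wa + la)),
       spec = spec)
}

# convenience accessors used across modules
cohort_labels <- function(dataset)
  vapply(dataset, function(p) p$label, integer(1))
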