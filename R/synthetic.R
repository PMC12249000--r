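# Synthetic two-class histology-like patch generator.
#
# Emulates, at desk scale, the contrasts that distinguish benign from
# malignant H&E patches: malignant patches have higher nuclear density,
# larger and more variable nucleus size, more eccentric (pleomorphic) nuclei,
# and spatial clustering (parent-offspring placement); benign patches have
# sparser, rounder, more uniform nuclei placed homogeneously. Per-patient
# random effects give every patient a consistent signature so patient-wise
# splitting is testable. Colors follow the H&E convention: pink stroma,
# dark blue-purple nuclei.

#' Synthetic dataset configuration
#'
#' Defaults define the package's canonical desk-scale dataset: 8 patients
#' per class, 12 images each (192 images), 96 px patches.
#'
#' @param patch_size patch side in pixels (>= 64).
#' @param n_patients_per_class patients per class.
#' @param images_per_patient images per patient.
#' @param benign_density,malignant_density expected nuclei per kilo-pixel
#'   (malignant must exceed benign).
#' @param benign_radius,malignant_radius mean/sd of nucleus radius in pixels.
#' @param malignant_eccentricity maximum axis ratio of malignant nuclei.
#' @param cluster_spread spatial scale (px) of malignant nucleus clusters.
#' @param stain_jitter_sd relative per-channel stain variation between
#'   images.
#' @param seed master seed; everything downstream derives from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(patch_size = 96L,
                             n_patients_per_class = 8L,
                             images_per_patient = 12L,
                             benign_density = 1.5,
                             malignant_density = 5.0,
                             benign_radius = c(mean = 4, sd = 0.6),
                             malignant_radius = c(mean = 5, sd = 1.8),
                             malignant_eccentricity = 2.5,
                             cluster_spread = 8,
                             stain_jitter_sd = 0.05,
                             seed = 1L) {
  if (patch_size < 64L)
    cs_stop("patch_size must be >= 64", "cellsage_config_error")
  if (malignant_density <= benign_density)
    cs_stop("malignant_density must exceed benign_density",
            "cellsage_config_error")
  if (benign_radius[["sd"]] < 0 || malignant_radius[["sd"]] < 0 ||
      stain_jitter_sd < 0)
    cs_stop("standard deviations must be >= 0", "cellsage_config_error")
  structure(list(patch_size = as.integer(patch_size),
                 n_patients_per_class = as.integer(n_patients_per_class),
                 images_per_patient = as.integer(images_per_patient),
                 benign_density = benign_density,
                 malignant_density = malignant_density,
                 benign_radius = benign_radius,
                 malignant_radius = malignant_radius,
                 malignant_eccentricity = malignant_eccentricity,
                 cluster_spread = cluster_spread,
                 stain_jitter_sd = stain_jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

STROMA_RGB <- c(230, 180, 200)
NUCLEUS_RGB <- c(90, 60, 130)
BENIGN_SUBTYPES <- c("adenosis", "fibroadenoma", "phyllodes_tumor",
                     "tubular_adenoma")
MALIGNANT_SUBTYPES <- c("ductal_carcinoma", "lobular_carcinoma",
                        "mucinous_carcinoma", "papillary_carcinoma")

#' Draw a synthetic patient
#'
#' A patient is a class label plus per-patient random effects (multiplicative
#' density shift, additive radius shift, additive stain offset) shared by all
#' of the patient's images.
#'
#' @param patient_id identifier string.
#' @param class_label `"benign"` or `"malignant"`.
#' @param config a [synthetic_config()].
#' @param draw_seed seed for the patient-effect draws.
#' @return an object of class `synthetic_patient`.
#' @export
synthetic_patient <- function(patient_id, class_label, config, draw_seed) {
  with_seed(draw_seed, {
    eff <- list(density_mult = exp(stats::rnorm(1, 0, 0.2)),
                radius_shift = stats::rnorm(1, 0, 0.4),
                stain_shift = stats::rnorm(3, 0, 0.03),
                subtype = sample(if (class_label == "benign") BENIGN_SUBTYPES
                                 else MALIGNANT_SUBTYPES, 1))
  })
  structure(list(patient_id = patient_id, class_label = class_label,
                 patient_effect = eff),
            class = "synthetic_patient")
}

#' Render one synthetic patch
#'
#' Pink stroma with additive Gaussian texture noise; dark elliptical nuclei
#' placed by a homogeneous Poisson process (benign) or a Thomas-type
#' parent-offspring cluster process with scale `cluster_spread` (malignant).
#' Nucleus radii follow the class distribution shifted by the patient effect.
#'
#' @param patient a [synthetic_patient()].
#' @param config a [synthetic_config()].
#' @param draw_seed seed for this patch.
#' @return H x W x 3 image in `[0, 255]`; attribute `n_nuclei` logs the
#'   placed nucleus count (the counting oracle for tests), `expected_nuclei`
#'   the process intensity.
#' @export
render_patch <- function(patient, config, draw_seed) {
  S <- config$patch_size
  mal <- patient$class_label == "malignant"
  dens <- (if (mal) config$malignant_density else config$benign_density) *
    patient$patient_effect$density_mult
  lambda <- dens * S * S / 1000
  rmean <- (if (mal) config$malignant_radius[["mean"]]
            else config$benign_radius[["mean"]]) +
    patient$patient_effect$radius_shift
  rsd <- if (mal) config$malignant_radius[["sd"]] else config$benign_radius[["sd"]]
  with_seed(draw_seed, {
    img <- array(rep(STROMA_RGB, each = S * S), c(S, S, 3L)) +
      array(stats::rnorm(S * S * 3, 0, 6), c(S, S, 3L))
    if (mal) {
      mu_off <- 3
      n_par <- stats::rpois(1, lambda / mu_off)
      cy <- stats::runif(n_par, 1, S); cx <- stats::runif(n_par, 1, S)
      n_off <- if (n_par > 0) stats::rpois(n_par, mu_off) else integer(0)
      ny <- rep(cy, n_off) + stats::rnorm(sum(n_off), 0, config$cluster_spread)
      nx <- rep(cx, n_off) + stats::rnorm(sum(n_off), 0, config$cluster_spread)
      keep <- ny >= 1 & ny <= S & nx >= 1 & nx <= S
      ny <- ny[keep]; nx <- nx[keep]
    } else {
      n <- stats::rpois(1, lambda)
      ny <- stats::runif(n, 1, S); nx <- stats::runif(n, 1, S)
    }
    n_nuc <- length(ny)
    if (n_nuc > 0) {
      radii <- pmax(stats::rnorm(n_nuc, rmean, rsd), 1.2)
      ecc <- if (mal) stats::runif(n_nuc, 1, config$malignant_eccentricity)
             else stats::runif(n_nuc, 1, 1.15)
      ang <- stats::runif(n_nuc, 0, pi)
      shade <- stats::rnorm(n_nuc, 0, 10)
      for (i in seq_len(n_nuc)) {
        a <- radii[i] * sqrt(ecc[i]); b <- radii[i] / sqrt(ecc[i])
        r <- ceiling(a) + 1L
        ys <- max(1L, floor(ny[i] - r)):min(S, ceiling(ny[i] + r))
        xs <- max(1L, floor(nx[i] - r)):min(S, ceiling(nx[i] + r))
        dy <- rep(ys - ny[i], times = length(xs))
        dx <- rep(xs - nx[i], each = length(ys))
        u <- dy * cos(ang[i]) + dx * sin(ang[i])
        v <- -dy * sin(ang[i]) + dx * cos(ang[i])
        inside <- (u / a)^2 + (v / b)^2 <= 1
        if (!any(inside)) next
        yy <- rep(ys, times = length(xs))[inside]
        xx <- rep(xs, each = length(ys))[inside]
        col <- clamp(NUCLEUS_RGB + shade[i], 0, 255)
        for (ch in 1:3) img[cbind(yy, xx, ch)] <- col[ch]
      }
    }
    img <- clamp(img, 0, 255)
    attr(img, "n_nuclei") <- n_nuc
    attr(img, "expected_nuclei") <- lambda
  })
  img
}

#' Perturb an image's stain appearance
#'
#' Applies a random per-channel affine perturbation in the Lab working space
#' (relative scale and shift with standard deviation `stain_jitter_sd`),
#' clipped back to the valid range. `stain_jitter_sd = 0` is the identity.
#'
#' @param image H x W x 3 image in `[0, 255]`.
#' @param stain_jitter_sd relative per-channel sd.
#' @param draw_seed seed for the perturbation draw.
#' @return perturbed image.
#' @export
stain_perturb <- function(image, stain_jitter_sd, draw_seed) {
  if (stain_jitter_sd == 0) return(image)
  d <- dim(image)
  with_seed(draw_seed, {
    scale <- exp(stats::rnorm(3, 0, stain_jitter_sd))
    shift <- stats::rnorm(3, 0, stain_jitter_sd * 10)
  })
  lab <- rgb255_to_lab(image)
  mu <- colMeans(lab)
  mapped <- sweep(sweep(lab, 2, mu), 2, scale, `*`)
  mapped <- sweep(mapped, 2, mu + shift, `+`)
  lab_to_rgb255(mapped, d[1], d[2])
}

#' The canonical reference patch
#'
#' A fixed benign patch (neutral patient effects, pinned seed) from which the
#' default stain profile is extracted.
#'
#' @return H x W x 3 image in `[0, 255]`.
#' @export
canonical_reference_patch <- function() {
  cfg <- synthetic_config()
  pt <- structure(list(patient_id = "REF", class_label = "benign",
                       patient_effect = list(density_mult = 1,
                                             radius_shift = 0,
                                             stain_shift = c(0, 0, 0),
                                             subtype = "fibroadenoma")),
                  class = "synthetic_patient")
  render_patch(pt, cfg, draw_seed = 20259L)
}

#' Generate a synthetic dataset on disk
#'
#' Writes PNG patches and a [load_manifest()]-compatible `manifest.csv` to
#' `out_dir`: per class, `n_patients_per_class` patients with
#' `images_per_patient` images each. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return the validated `dataset_index`, invisibly; the manifest is at
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(config, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    cs_stop("cannot create output directory %s", "cellsage_io_error", out_dir)
  n_pat <- 2L * config$n_patients_per_class
  n_img <- n_pat * config$images_per_patient
  seeds <- derive_seeds(config$seed, n_pat + n_img * 2L)
  rows <- list()
  si <- 0L
  img_i <- 0L
  for (cl in CLASS_LEVELS) {
    for (p in seq_len(config$n_patients_per_class)) {
      si <- si + 1L
      pid <- sprintf("%s_P%02d", toupper(substr(cl, 1, 1)), p)
      pat <- synthetic_patient(pid, cl, config, seeds[si])
      for (j in seq_len(config$images_per_patient)) {
        img_i <- img_i + 1L
        s1 <- seeds[n_pat + img_i]
        s2 <- seeds[n_pat + n_img + img_i]
        img <- render_patch(pat, config, s1)
        # patient-level stain signature + per-image jitter
        img <- clamp(img * (1 + rep(pat$patient_effect$stain_shift,
                                    each = config$patch_size^2)), 0, 255)
        img <- stain_perturb(img, config$stain_jitter_sd, s2)
        fn <- sprintf("%s_img%02d.png", pid, j)
        write_png(img, file.path(out_dir, fn))
        rows[[img_i]] <- data.frame(
          image_path = fn, patient_id = pid, class_label = cl,
          subtype = pat$patient_effect$subtype,
          magnification = MAGNIFICATIONS[(j - 1L) %% 4L + 1L])
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  invisible(load_manifest(file.path(out_dir, "manifest.csv")))
}
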