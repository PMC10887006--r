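# Seeded synthetic phantom cohorts. Two co-registered "modalities" are drawn
# per slice: modality 1 plays the role of CE-T1WI (shows the enhancement
# pattern), modality 2 plays T2-Flair (shows the edema extent). The three
# phenotypes caricature the classical appearances:
#   GBM-like   -- ring enhancement with a darker core on modality 1,
#                 moderate surrounding edema on modality 2;
#   SBM-like   -- small bright nodule on modality 1 with broad edema on
#                 modality 2;
#   PCNSL-like -- homogeneous bright mass on modality 1, narrow edema.
# Intensities are piecewise constant before additive Gaussian noise, so the
# ring-vs-homogeneous distinction requires spatial features, not just mean
# lesion intensity.

#' Phantom cohort specification
#'
#' @param image_size native phantom side length in pixels (default 128; the
#'   preprocessing chain rescales to the model grid).
#' @param noise_sd standard deviation of additive Gaussian noise, on the
#'   phantom's 0-1 intensity scale (default 0.05).
#' @param patients_per_class patients generated per tumor class.
#' @param slices_per_patient length-2 integer range of tumor-bearing slices
#'   per patient (inclusive).
#' @param background_slices length-2 integer range of tumor-free slices per
#'   patient (these carry an empty lesion mask and exercise the
#'   tumor-slice filtering rule).
#' @param seed cohort seed; together with the per-patient seed it fully
#'   determines every pixel.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 128, noise_sd = 0.05,
                         patients_per_class = 30,
                         slices_per_patient = c(3, 6),
                         background_slices = c(1, 2), seed = 1) {
  stopifnot(is_count(image_size, 32L), noise_sd >= 0,
            is_count(patients_per_class),
            length(slices_per_patient) == 2, length(background_slices) == 2)
  structure(list(image_size = as.integer(image_size), noise_sd = noise_sd,
                 patients_per_class = as.integer(patients_per_class),
                 slices_per_patient = as.integer(slices_per_patient),
                 background_slices = as.integer(background_slices),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

disk_mask <- function(n, cx, cy, rx, ry = rx) {
  x <- matrix(seq_len(n), n, n)
  y <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

jitter1 <- function(x, frac) x * stats::runif(1, 1 - frac, 1 + frac)

#' Generate one phantom patient
#'
#' Draws an elliptical brain, a class-dependent lesion with per-patient
#' jittered position, radius and intensity, per-slice radius modulation (as
#' if slicing through the lesion), additive Gaussian noise, and per-slice
#' lesion and brain masks. The record is a pure function of
#' `(spec$seed, patient_seed)`.
#'
#' @param phenotype `"GBM"`, `"SBM"` or `"PCNSL"`.
#' @param spec a [phantom_spec()].
#' @param patient_seed integer distinguishing patients.
#' @param patient_id id string (default derived from phenotype and seed).
#' @return A [patient_record] with native-resolution slices.
#' @export
generate_patient <- function(phenotype, spec, patient_seed,
                             patient_id = sprintf("%s_%04d", phenotype,
                                                  patient_seed)) {
  phenotype <- match.arg(phenotype, tumor_classes())
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  with_seed(derive_seed(spec$seed, patient_seed), {
    # brain ellipse
    bcx <- n / 2 + stats::runif(1, -2, 2)
    bcy <- n / 2 + stats::runif(1, -2, 2)
    brx <- jitter1(0.40 * n, 0.06)
    bry <- jitter1(0.34 * n, 0.06)
    bg_t1 <- jitter1(0.35, 0.08)
    bg_fl <- jitter1(0.30, 0.08)

    # lesion geometry: center well inside the brain
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0, 0.35)
    lcx <- bcx + cos(ang) * rad * brx
    lcy <- bcy + sin(ang) * rad * bry
    base_r <- switch(phenotype,
                     GBM = stats::runif(1, 0.11, 0.15) * n,
                     SBM = stats::runif(1, 0.045, 0.065) * n,
                     PCNSL = stats::runif(1, 0.08, 0.12) * n)
    edema_r <- switch(phenotype,
                      GBM = base_r * stats::runif(1, 1.3, 1.5),
                      SBM = base_r * stats::runif(1, 2.6, 3.4),
                      PCNSL = base_r * stats::runif(1, 1.1, 1.2))
    if (lcx - edema_r < 1 || lcx + edema_r > n ||
        lcy - edema_r < 1 || lcy + edema_r > n) {
      stop_mffc("lesion parameters exceed image bounds")
    }

    # per-class intensities (0-1 scale), jittered per patient
    ring_i <- jitter1(0.90, 0.06)   # enhancing rim / nodule / mass
    core_i <- jitter1(0.50, 0.06)   # GBM core: darker than rim, brighter
                                    # than background
    edema_i <- jitter1(0.62, 0.06)  # modality-2 hyperintensity
    lesion_fl <- jitter1(0.45, 0.08)

    nt <- sample(spec$slices_per_patient[1]:spec$slices_per_patient[2], 1)
    nb <- sample(spec$background_slices[1]:spec$background_slices[2], 1)
    slices <- vector("list", nt + nb)
    for (k in seq_len(nt)) {
      # slicing through the lesion shrinks the apparent radius off-center
      u <- if (nt == 1) 0 else (k - (nt + 1) / 2) / ((nt + 1) / 2)
      sc <- sqrt(pmax(1 - 0.6 * u^2, 0.4))
      cx <- lcx + stats::runif(1, -1.5, 1.5)
      cy <- lcy + stats::runif(1, -1.5, 1.5)
      r <- max(base_r * sc, 2.5)
      brain <- disk_mask(n, bcx, bcy, brx, bry)
      t1 <- matrix(0, n, n); t1[brain] <- bg_t1
      fl <- matrix(0, n, n); fl[brain] <- bg_fl
      lesion <- disk_mask(n, cx, cy, r) & brain
      edema <- disk_mask(n, cx, cy, max(edema_r * sc, r + 1)) & brain
      if (phenotype == "GBM") {
        core <- disk_mask(n, cx, cy, 0.55 * r)
        t1[lesion] <- ring_i
        t1[lesion & core] <- core_i
        fl[edema] <- edema_i
        fl[lesion] <- lesion_fl
      } else if (phenotype == "SBM") {
        fl[edema] <- edema_i
        fl[lesion] <- lesion_fl
        t1[lesion] <- ring_i
      } else {  # PCNSL: homogeneous mass, narrow edema
        fl[edema] <- edema_i * 0.85
        fl[lesion] <- lesion_fl
        t1[lesion] <- ring_i * 0.9
      }
      if (spec$noise_sd > 0) {
        t1 <- t1 + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
        fl <- fl + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
      }
      slices[[k]] <- list(t1ce = t1, flair = fl, mask = lesion, brain = brain)
    }
    for (k in nt + seq_len(nb)) {
      brain <- disk_mask(n, bcx, bcy, brx, bry)
      t1 <- matrix(0, n, n); t1[brain] <- bg_t1
      fl <- matrix(0, n, n); fl[brain] <- bg_fl
      if (spec$noise_sd > 0) {
        t1 <- t1 + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
        fl <- fl + matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
      }
      slices[[k]] <- list(t1ce = t1, flair = fl,
                          mask = matrix(FALSE, n, n), brain = brain)
    }
    patient_record(patient_id, phenotype, slices)
  })
}

#' Generate a balanced phantom cohort
#'
#' `3 * patients_per_class` records with unique ids and balanced labels,
#' fully determined by the spec.
#'
#' @param spec a [phantom_spec()].
#' @param dir optional directory; when given, each patient's modalities and
#'   lesion mask are written as NIfTI volumes and a `manifest.csv` is
#'   written alongside.
#' @return List of [patient_record]s with a `manifest` attribute.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  cohort <- list()
  ps <- 0L
  for (cl in tumor_classes()) {
    for (i in seq_len(spec$patients_per_class)) {
      ps <- ps + 1L
      cohort[[ps]] <- generate_patient(cl, spec, patient_seed = ps,
                                       patient_id = sprintf("%s_%03d", cl, i))
    }
  }
  attr(cohort, "manifest") <- cohort_manifest(cohort)
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a cohort to disk as NIfTI volumes plus a manifest
#'
#' @param cohort list of [patient_record]s.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort) {
    d <- dim(p$slices[[1]]$t1ce)
    nsl <- length(p$slices)
    stack <- function(field, default = 0) {
      array(unlist(lapply(p$slices, function(s) {
        v <- s[[field]]
        if (is.null(v)) matrix(default, d[1], d[2]) else v * 1
      })), dim = c(d, nsl))
    }
    write_volume(volume(stack("t1ce")),
                 file.path(dir, paste0(p$patient_id, "_t1ce.nii.gz")))
    write_volume(volume(stack("flair")),
                 file.path(dir, paste0(p$patient_id, "_flair.nii.gz")))
    write_volume(volume(stack("mask")),
                 file.path(dir, paste0(p$patient_id, "_mask.nii.gz")))
  }
  utils::write.csv(cohort_manifest(cohort), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
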