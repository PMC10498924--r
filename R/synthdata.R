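# Synthetic PET/CT phantom cohorts.
#
# The generator emulates the input contract of a head-and-neck PET/CT
# outcome study: hot primary tumors (and optional involved nodes) on a low
# uptake background, contrast-enhanced soft-tissue CT values near the 70 HU
# window center, binary GTVp/GTVn masks on a 1 mm isotropic grid, a clinical
# covariate table with realistic marginals, and binary OS/DFS endpoints
# drawn from a logistic model with planted, user-set effects.

#' Phantom cohort specification
#'
#' Captures every knob of the synthetic cohort in one validated object.
#' Defaults encode the study population this generator emulates: DFS event
#' rate 0.49 and OS event rate 0.41, SUV peak centered near 11 (tumor
#' amplitude uniform on 5-17 SUV), and clinical covariate marginals matching
#' the training cohort (e.g. 77% male, 65.5% oropharynx, 57.6% HPV-related).
#'
#' @param n_patients number of patients to simulate.
#' @param grid_shape voxels per axis (length 3).
#' @param voxel_size isotropic voxel edge in mm.
#' @param tumor_shape_params list: `semi_axes_range` (mm, min/max of each
#'   semi-axis), `deform_amplitude` (mean relative surface-deformation
#'   amplitude; each patient draws uniformly on 0..2x this value).
#' @param suv_params list: `background` SUV, `background_noise_sd`,
#'   `tumor_suv_range` (uniform draw of the tumor amplitude),
#'   `heterogeneity` (SUV scale of the smoothed texture field inside the
#'   tumor), `node_suv_range`.
#' @param ct_params list: `soft_tissue_hu` background mean,
#'   `structure_contrast` HU added inside tumor/nodes, `noise_sd`.
#' @param n_nodes_range integer range of involved node count.
#' @param outcome_coefficients named list with elements `dfs` and `os`,
#'   each a named numeric vector of log-odds on standardized ground-truth
#'   features (see [simulate_outcomes()]); the intercept is calibrated so
#'   the cohort event rate matches `event_rate_targets`.
#' @param event_rate_targets named fractions in (0,1) per endpoint.
#' @param seed integer master seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 25L,
                         grid_shape = c(48L, 48L, 48L),
                         voxel_size = 1.0,
                         tumor_shape_params = list(),
                         suv_params = list(),
                         ct_params = list(),
                         n_nodes_range = c(0L, 2L),
                         outcome_coefficients = NULL,
                         event_rate_targets = c(dfs = 0.49, os = 0.41),
                         seed = 1L) {
  shape_d <- list(semi_axes_range = c(8, 15), deform_amplitude = 0.1)
  suv_d <- list(background = 1.0, background_noise_sd = 0.1,
                tumor_suv_range = c(5, 17), heterogeneity = 1.5,
                node_suv_range = c(3, 8))
  ct_d <- list(soft_tissue_hu = 45, structure_contrast = 30, noise_sd = 10)
  shape_p <- utils::modifyList(shape_d, tumor_shape_params)
  suv_p <- utils::modifyList(suv_d, suv_params)
  ct_p <- utils::modifyList(ct_d, ct_params)
  if (is.null(outcome_coefficients)) {
    outcome_coefficients <- list(
      dfs = c(hpv_related = -1.0, stage_iii_iv = 0.7,
              suv_amplitude = 0.5, sphericity_deficit = 0.5),
      os = c(hpv_related = -0.8, stage_iii_iv = 0.8,
             suv_amplitude = 0.5, log_volume = 0.5))
  }
  spec <- structure(list(
    n_patients = as.integer(n_patients), grid_shape = as.integer(grid_shape),
    voxel_size = voxel_size, tumor_shape_params = shape_p,
    suv_params = suv_p, ct_params = ct_p,
    n_nodes_range = as.integer(n_nodes_range),
    outcome_coefficients = outcome_coefficients,
    event_rate_targets = event_rate_targets,
    clinical_marginals = list(
      age_mean = 60.2, age_sd = 7.7, male = 0.77,
      smoking_mean = 25.0, smoking_sd = 22.8,
      site = c(oral_cavity = 0.079, oropharynx = 0.655,
               hypopharynx = 0.115, larynx = 0.151),
      stage_iii_iv = 0.482, hpv_given_oropharynx = 0.576 / 0.655,
      grade_high = 0.691, charlson_1plus = 0.381),
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$n_patients >= 1L, length(spec$grid_shape) == 3L)
  if (any(spec$grid_shape <= 0L)) stop("grid_shape must be strictly positive")
  if (spec$voxel_size <= 0) stop("voxel_size must be > 0")
  tr <- spec$event_rate_targets
  if (any(tr <= 0 | tr >= 1)) stop("event_rate_targets must lie in (0,1)")
  invisible(spec)
}

#' Generate a deformed-ellipsoid tumor mask
#'
#' Draws an ellipsoid with the given semi-axes, optionally perturbed by a
#' smoothed Gaussian radial deformation field, and keeps the largest
#' 26-connected component so the region is always connected.
#'
#' @param semi_axes length-3 semi-axes in mm.
#' @param grid_shape voxels per axis.
#' @param spacing voxel size in mm (isotropic scalar or length 3).
#' @param deform_amplitude relative radial deformation amplitude (0 = exact
#'   ellipsoid).
#' @param center mask center in mm (defaults to the grid center).
#' @param seed RNG seed for the deformation field.
#' @return list with `mask` (3D 0/1 array) and `shape` (ground-truth
#'   `semi_axes`, `elongation` = ratio of second-largest to largest
#'   semi-axis, `center`, `deform_amplitude`).
#' @export
generate_tumor_mask <- function(semi_axes, grid_shape, spacing = 1,
                                deform_amplitude = 0, center = NULL,
                                seed = NULL) {
  stopifnot(length(semi_axes) == 3L, all(semi_axes > 0))
  spacing <- rep(spacing, length.out = 3L)
  extent <- grid_shape * spacing
  center <- center %||% (extent / 2)
  reach <- semi_axes * (1 + max(0, deform_amplitude) * 2)
  if (any(center - reach < 0) || any(center + reach > extent)) {
    stop(sprintf(
      "tumor semi-axes (%s mm) do not fit inside the %s mm grid at center (%s)",
      paste(round(semi_axes, 1), collapse = ", "),
      paste(round(extent, 1), collapse = "x"),
      paste(round(center, 1), collapse = ", ")))
  }
  ax <- (seq_len(grid_shape[1]) - 0.5) * spacing[1]
  ay <- (seq_len(grid_shape[2]) - 0.5) * spacing[2]
  az <- (seq_len(grid_shape[3]) - 0.5) * spacing[3]
  ux <- (ax - center[1]) / semi_axes[1]
  uy <- (ay - center[2]) / semi_axes[2]
  uz <- (az - center[3]) / semi_axes[3]
  r <- sqrt(outer(outer(ux^2, uy^2, `+`), uz^2, `+`))
  if (deform_amplitude > 0) {
    g <- with_seed(seed, smooth3d(array(rnorm(prod(grid_shape)), grid_shape),
                                  sigma = 3))
    g <- (g - mean(g)) / sd(g)
    mask <- (r <= 1 + deform_amplitude * g) * 1
  } else {
    mask <- (r <= 1) * 1
  }
  if (sum(mask) == 0) stop("deformation removed the whole tumor; lower the amplitude")
  lab <- .label_components26(array(ifelse(mask > 0, 1L, NA_integer_),
                                   dim(mask)), dim(mask))
  keep <- as.integer(names(which.max(table(lab[lab > 0]))))
  mask <- (lab == keep) * 1
  srt <- sort(semi_axes, decreasing = TRUE)
  list(mask = mask,
       shape = list(semi_axes = semi_axes, elongation = srt[2] / srt[1],
                    center = center, deform_amplitude = deform_amplitude))
}

#' Paint PET and CT volumes for a set of masks
#'
#' PET: tumor voxels carry `tumor_suv` plus a smoothed zero-mean texture
#' field scaled by `heterogeneity`; node voxels carry their node amplitude;
#' background voxels carry `background` plus white noise. Negative SUVs
#' after noise are clipped to 0 (count reported). CT: soft-tissue background
#' with added `structure_contrast` inside tumor/nodes plus white noise.
#'
#' @param gtvp binary tumor mask.
#' @param gtvn binary node mask (or `NULL` for none).
#' @param suv_params,ct_params parameter lists, see [phantom_spec()];
#'   `suv_params$tumor_suv` and `suv_params$node_suv` give the amplitudes.
#' @param seed RNG seed.
#' @return list `pet`, `ct`, `n_clipped`.
#' @export
paint_images <- function(gtvp, gtvn = NULL, suv_params, ct_params,
                         seed = NULL) {
  d <- dim(gtvp)
  if (is.null(gtvn)) gtvn <- array(0, d)
  stopifnot(identical(dim(gtvn), d))
  with_seed(seed, {
    pet <- array(suv_params$background, d)
    if (suv_params$background_noise_sd > 0)
      pet <- pet + array(rnorm(prod(d), 0, suv_params$background_noise_sd), d)
    node_only <- gtvn > 0 & gtvp == 0
    pet[node_only] <- suv_params$node_suv %||% 5
    pet[gtvp > 0] <- suv_params$tumor_suv
    if (suv_params$heterogeneity > 0) {
      tex <- smooth3d(array(rnorm(prod(d)), d), sigma = 1.5)
      tex <- (tex - mean(tex)) / sd(tex)
      any_mask <- gtvp > 0 | gtvn > 0
      pet[any_mask] <- pet[any_mask] + suv_params$heterogeneity * tex[any_mask]
    }
    n_clipped <- sum(pet < 0)
    if (n_clipped > 0) pet[pet < 0] <- 0

    ct <- array(ct_params$soft_tissue_hu, d)
    ct[gtvp > 0 | gtvn > 0] <- ct_params$soft_tissue_hu +
      ct_params$structure_contrast
    if (ct_params$noise_sd > 0)
      ct <- ct + array(rnorm(prod(d), 0, ct_params$noise_sd), d)
    list(pet = pet, ct = ct, n_clipped = n_clipped)
  })
}

#' Draw binary outcomes from a logistic model on planted features
#'
#' @param features numeric matrix of standardized features with column
#'   names.
#' @param coefficients named numeric vector of log-odds; an optional
#'   `"(Intercept)"` entry sets the intercept (default 0). Every other name
#'   must match a feature column.
#' @param seed RNG seed.
#' @return integer 0/1 vector of length `nrow(features)` (1 = event).
#' @export
simulate_outcomes <- function(features, coefficients, seed = NULL) {
  stopifnot(is.matrix(features), all(is.finite(coefficients)))
  icpt <- unname(coefficients["(Intercept)"])
  if (is.na(icpt)) icpt <- 0
  betas <- coefficients[setdiff(names(coefficients), "(Intercept)")]
  missing <- setdiff(names(betas), colnames(features))
  if (length(missing) > 0) {
    stop("coefficient names not present in features: ",
         paste(missing, collapse = ", "))
  }
  lp <- icpt + as.vector(features[, names(betas), drop = FALSE] %*% betas)
  with_seed(seed, as.integer(rbinom(length(lp), 1L, plogis(lp))))
}

# z-score columns; zero-variance columns are left centered only.
standardize_matrix <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  sweep(sweep(m, 2, mu), 2, s, "/")
}

# Calibrate the intercept so mean(plogis(b + lp)) hits the target rate.
calibrate_intercept <- function(lp, target) {
  stats::uniroot(function(b) mean(plogis(b + lp)) - target,
                 lower = -20, upper = 20)$root
}

sample_clinical <- function(n, m) {
  site <- sample(names(m$site), n, replace = TRUE, prob = m$site)
  data.frame(
    age = round(rnorm(n, m$age_mean, m$age_sd), 1),
    gender = ifelse(runif(n) < m$male, "male", "female"),
    smoking = round(rgamma_ms(n, m$smoking_mean, m$smoking_sd), 1),
    tumor_site = site,
    stage_group = ifelse(runif(n) < m$stage_iii_iv, "III-IV", "I-II"),
    hpv_related = as.integer(site == "oropharynx" &
                               runif(n) < m$hpv_given_oropharynx),
    histologic_grade_group = ifelse(runif(n) < m$grade_high, "high",
                                    "low/moderate"),
    charlson_group = ifelse(runif(n) < m$charlson_1plus, "1-6", "0"),
    stringsAsFactors = FALSE)
}

rgamma_ms <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

#' Generate a full phantom cohort
#'
#' Draws per-patient tumor geometry, uptake and clinical covariates, paints
#' PET/CT volumes, and generates both endpoints from the spec's planted
#' logistic models with intercepts calibrated to the target event rates.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_cohort`: list with `patients` (list of
#'   patient records), `ground_truth` (data frame of planted parameters and
#'   linear predictors), `clinical` (covariate + endpoint table) and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_phantom_spec(spec)
  n <- spec$n_patients
  seeds <- child_seeds(spec$seed, 4L * n + 2L)
  m <- spec$clinical_marginals
  shp <- spec$tumor_shape_params
  extent <- spec$grid_shape * spec$voxel_size

  clinical <- with_seed(seeds[[4L * n + 1L]], sample_clinical(n, m))
  clinical$patient_id <- sprintf("P%03d", seq_len(n))

  patients <- vector("list", n)
  gt <- vector("list", n)
  for (i in seq_len(n)) {
    # cap the semi-axis draw so every tumor (plus deformation reach and
    # center jitter) fits on the grid
    semi_hi <- min(shp$semi_axes_range[2],
                   (min(extent) / 2 - 2 - 1) / (1 + 2 * 2 * shp$deform_amplitude))
    semi_lo <- min(shp$semi_axes_range[1], semi_hi)
    draw <- with_seed(seeds[[i]], {
      list(semi = runif(3, semi_lo, semi_hi),
           deform = runif(1, 0, 2 * shp$deform_amplitude),
           suv = runif(1, spec$suv_params$tumor_suv_range[1],
                       spec$suv_params$tumor_suv_range[2]),
           n_nodes = sample(seq(spec$n_nodes_range[1],
                                spec$n_nodes_range[2]), 1L),
           node_suv = runif(1, spec$suv_params$node_suv_range[1],
                            spec$suv_params$node_suv_range[2]),
           jitter = runif(3, -2, 2))
    })
    tum <- generate_tumor_mask(draw$semi, spec$grid_shape, spec$voxel_size,
                               deform_amplitude = draw$deform,
                               center = extent / 2 + draw$jitter,
                               seed = seeds[[n + i]])
    gtvn <- array(0, spec$grid_shape)
    if (draw$n_nodes > 0) {
      gtvn <- with_seed(seeds[[2L * n + i]], {
        acc <- array(0, spec$grid_shape)
        for (k in seq_len(draw$n_nodes)) {
          for (try in 1:10) {
            ctr <- runif(3, 0.25, 0.75) * extent
            semi <- runif(3, 3, 6)
            if (any(ctr - semi * 1.2 < 0) || any(ctr + semi * 1.2 > extent))
              next
            nd <- generate_tumor_mask(semi, spec$grid_shape, spec$voxel_size,
                                      center = ctr)
            if (sum(nd$mask * tum$mask) == 0) {
              acc <- pmax(acc, nd$mask)
              break
            }
          }
        }
        acc
      })
    }
    sp <- spec$suv_params
    sp$tumor_suv <- draw$suv
    sp$node_suv <- draw$node_suv
    img <- paint_images(tum$mask, gtvn, sp, spec$ct_params,
                        seed = seeds[[3L * n + i]])
    patients[[i]] <- list(
      patient_id = clinical$patient_id[i],
      pet = img$pet, ct = img$ct,
      gtvp_mask = tum$mask, gtvn_mask = gtvn,
      spacing = rep(spec$voxel_size, 3L),
      clinical = clinical[i, , drop = FALSE])
    gt[[i]] <- data.frame(
      patient_id = clinical$patient_id[i],
      semi_a = draw$semi[1], semi_b = draw$semi[2], semi_c = draw$semi[3],
      elongation = tum$shape$elongation,
      sphericity_deficit = draw$deform,
      suv_amplitude = draw$suv,
      n_nodes = draw$n_nodes,
      volume_mm3 = sum(tum$mask) * spec$voxel_size^3)
  }
  gt <- do.call(rbind, gt)
  gt$log_volume <- log(gt$volume_mm3)

  feat <- cbind(
    as.matrix(gt[, c("suv_amplitude", "sphericity_deficit", "elongation",
                     "log_volume")]),
    hpv_related = clinical$hpv_related,
    stage_iii_iv = as.integer(clinical$stage_group == "III-IV"),
    age = clinical$age, smoking = clinical$smoking)
  featz <- standardize_matrix(feat)

  out_seeds <- child_seeds(seeds[[4L * n + 2L]], 2L)
  for (ep in c("dfs", "os")) {
    beta <- spec$outcome_coefficients[[ep]]
    beta <- beta[setdiff(names(beta), "(Intercept)")]
    lp <- if (length(beta) > 0)
      as.vector(featz[, names(beta), drop = FALSE] %*% beta) else rep(0, n)
    icpt <- calibrate_intercept(lp, spec$event_rate_targets[[ep]])
    lab <- simulate_outcomes(featz, c(beta, "(Intercept)" = icpt),
                             seed = out_seeds[[match(ep, c("dfs", "os"))]])
    clinical[[paste0(ep, "_event")]] <- lab
    gt[[paste0("lp_", ep)]] <- icpt + lp
  }
  for (i in seq_len(n)) {
    patients[[i]]$dfs_event <- clinical$dfs_event[i]
    patients[[i]]$os_event <- clinical$os_event[i]
    patients[[i]]$clinical <- clinical[i, , drop = FALSE]
    class(patients[[i]]) <- "patient_record"
    validate_patient_record(patients[[i]])
  }
  structure(list(patients = patients, ground_truth = gt,
                 clinical = clinical, spec = spec),
            class = "phantom_cohort")
}

#' Validate a patient record's invariants
#'
#' Checks that PET is nonnegative, masks are binary, GTVp is nonempty and
#' all volumes share dimensions.
#'
#' @param p a `patient_record`.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_patient_record <- function(p) {
  d <- dim(p$pet)
  if (!identical(dim(p$ct), d) || !identical(dim(p$gtvp_mask), d) ||
      !identical(dim(p$gtvn_mask), d))
    stop("pet/ct/masks must share dimensions")
  if (any(p$pet < 0)) stop("PET must be nonnegative")
  if (!all(p$gtvp_mask %in% c(0, 1)) || !all(p$gtvn_mask %in% c(0, 1)))
    stop("masks must be binary")
  if (sum(p$gtvp_mask) == 0) stop("GTVp mask is empty")
  invisible(p)
}

#' Write a phantom cohort to disk
#'
#' Per-patient NIfTI volumes (`pet.nii.gz`, `ct.nii.gz`, `gtvp.nii.gz`,
#' `gtvn.nii.gz`), a cohort-level `clinical.csv` (covariates + endpoints),
#' `ground_truth.csv`, and a `phantom_spec.json` sidecar.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$patients) {
    pd <- file.path(dir, p$patient_id)
    dir.create(pd, showWarnings = FALSE)
    write_nifti(p$pet, file.path(pd, "pet.nii.gz"), p$spacing)
    write_nifti(p$ct, file.path(pd, "ct.nii.gz"), p$spacing)
    write_nifti(p$gtvp_mask, file.path(pd, "gtvp.nii.gz"), p$spacing, "uint8")
    write_nifti(p$gtvn_mask, file.path(pd, "gtvn.nii.gz"), p$spacing, "uint8")
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  spec <- cohort$spec
  jsonlite::write_json(unclass(spec), file.path(dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `phantom_cohort` (without the ground-truth linear predictors if
#'   absent on disk).
#' @export
read_cohort <- function(dir) {
  clinical <- read.csv(file.path(dir, "clinical.csv"),
                       stringsAsFactors = FALSE)
  gt_path <- file.path(dir, "ground_truth.csv")
  gt <- if (file.exists(gt_path)) read.csv(gt_path) else NULL
  patients <- lapply(seq_len(nrow(clinical)), function(i) {
    id <- clinical$patient_id[i]
    pd <- file.path(dir, id)
    pet <- read_nifti(file.path(pd, "pet.nii.gz"))
    p <- structure(list(
      patient_id = id,
      pet = pet$vol,
      ct = read_nifti(file.path(pd, "ct.nii.gz"))$vol,
      gtvp_mask = read_nifti(file.path(pd, "gtvp.nii.gz"))$vol,
      gtvn_mask = read_nifti(file.path(pd, "gtvn.nii.gz"))$vol,
      spacing = pet$spacing,
      clinical = clinical[i, , drop = FALSE],
      dfs_event = clinical$dfs_event[i],
      os_event = clinical$os_event[i]), class = "patient_record")
    validate_patient_record(p)
  })
  spec_path <- file.path(dir, "phantom_spec.json")
  spec <- if (file.exists(spec_path))
    jsonlite::read_json(spec_path, simplifyVector = TRUE) else NULL
  structure(list(patients = patients, ground_truth = gt,
                 clinical = clinical, spec = spec),
            class = "phantom_cohort")
}
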