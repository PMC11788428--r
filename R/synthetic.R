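# Synthetic humanoid cohort generator.
#
# Real 3D-scan + DXA cohorts are restricted, so the pipeline is exercised on
# a procedural stand-in: a deterministic humanoid-ish template derived from
# a subdivided icosahedron, per-subject smooth radial morph fields with
# known latent parameters, a known sex-specific monotone-nonlinear
# shape -> composition function (with genuine quadratic terms), and retest
# perturbations emulating same-day duplicate scans. Topology constancy —
# the only property the pipeline actually requires of its meshes — holds by
# construction; anthropometric realism is not attempted.

#' Synthetic cohort specification
#'
#' Defaults define the package's reference synthetic study conditions.
#' Morph parameters are positive multiplicative factors centered at 1; the
#' composition functions are monotone increasing in each morph parameter on
#' the sampled domain and include quadratic terms, so a quadratic-kernel
#' regressor can genuinely outperform a linear one.
#'
#' @param n_subjects cohort size (default 300).
#' @param seed RNG seed; same seed + spec give identical output.
#' @param subdivision icosphere subdivision level of the template
#'   (vertex count `10 * 4^s + 2`; default 2 = 162 vertices).
#' @param morph_mean,morph_sd named length-5 vectors (scale, trunk, limb,
#'   adiposity, stature) of the lognormal-ish morph factor distributions.
#' @param retest_noise_sd_mm per-vertex Gaussian noise between duplicate
#'   scans (default 2 mm).
#' @param pose_jitter_mm amplitude of the smooth low-frequency pose
#'   displacement between duplicate scans (default 8 mm).
#' @param composition_noise_sd named per-target measurement noise SDs
#'   (target units).
#' @param age_range uniform age range in years.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 300L,
                           seed = 1L,
                           subdivision = 2L,
                           morph_mean = c(scale = 1, trunk = 1, limb = 1,
                                          adiposity = 1, stature = 1),
                           morph_sd = c(scale = 0.06, trunk = 0.12,
                                        limb = 0.10, adiposity = 0.25,
                                        stature = 0.05),
                           retest_noise_sd_mm = 2,
                           pose_jitter_mm = 8,
                           composition_noise_sd = c(
                             total_fat_mass = 0.5, total_lean_mass = 0.5,
                             visceral_fat_mass = 0.08, arm_lean_mass = 0.15,
                             leg_lean_mass = 0.25, percent_fat = 0.6,
                             trunk_fat_mass = 0.3, trunk_lean_mass = 0.3,
                             arm_fat_mass = 0.1, leg_fat_mass = 0.15),
                           age_range = c(20, 70)) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (any(morph_sd < 0) || retest_noise_sd_mm < 0 || pose_jitter_mm < 0 ||
        any(composition_noise_sd < 0)) {
    stop("all SDs must be >= 0")
  }
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 subdivision = as.integer(subdivision),
                 morph_mean = morph_mean, morph_sd = morph_sd,
                 retest_noise_sd_mm = retest_noise_sd_mm,
                 pose_jitter_mm = pose_jitter_mm,
                 composition_noise_sd = composition_noise_sd,
                 age_range = age_range),
            class = "synthetic_spec")
}

# ---- template --------------------------------------------------------------

# unit icosahedron (12 vertices, 20 faces), exact coordinates
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
             c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
             c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
             c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  list(vertices = v, faces = f)
}

# one Loop-style 4:1 topological subdivision, vertices projected to the sphere
subdivide_sphere <- function(v, f) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- unique(rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]),
                        cbind(f[, 3], f[, 1])))
  ek <- key(edges[, 1], edges[, 2])
  keep <- !duplicated(ek)
  edges <- edges[keep, , drop = FALSE]
  ek <- ek[keep]
  mid <- (v[edges[, 1] + 1, ] + v[edges[, 2] + 1, ]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  mid_idx <- stats::setNames(nrow(v) + seq_len(nrow(edges)) - 1L, ek)
  v2 <- rbind(v, mid)
  f2 <- matrix(0L, 0, 3)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
    ab <- mid_idx[[key(a, b)]]; bc <- mid_idx[[key(b, c_)]]; ca <- mid_idx[[key(c_, a)]]
    f2 <- rbind(f2, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
  }
  list(vertices = v2, faces = f2)
}

#' Deterministic humanoid-ish template mesh
#'
#' A subdivided icosphere deformed by fixed smooth fields into a vertically
#' elongated trunk with paired lower protrusions — enough body-like
#' asymmetry along the vertical axis for regional morph fields to act on,
#' while remaining a closed fixed-topology mesh. Repeated calls are
#' bit-identical.
#'
#' @param subdivision icosphere subdivision level (>= 0);
#'   `V = 10 * 4^subdivision + 2`.
#' @return a [triangle_mesh], millimetre units, roughly 1.7 m tall.
#' @export
make_template <- function(subdivision = 2L) {
  subdivision <- as.integer(subdivision)
  if (subdivision < 0L) stop("subdivision must be >= 0")
  ico <- icosahedron()
  v <- ico$vertices; f <- ico$faces
  s <- 0L
  while (s < subdivision) {
    sub <- subdivide_sphere(v, f)
    v <- sub$vertices; f <- sub$faces
    s <- s + 1L
  }
  # sphere -> humanoid-ish: y is vertical; elongate, taper, add leg-like
  # bulges below and shoulder widening above. All fields smooth in (y, theta).
  y <- v[, 2]
  theta <- atan2(v[, 3], v[, 1])
  radial <- 1 +
    0.35 * exp(-((y + 0.75) / 0.3)^2) * abs(sin(theta)) +  # lower bulges
    0.25 * exp(-((y - 0.45) / 0.35)^2) +                   # shoulders/chest
    -0.15 * exp(-(y / 0.2)^2)                              # waist taper
  out <- v
  out[, c(1, 3)] <- v[, c(1, 3)] * radial
  out[, 2] <- y * 1.0
  out <- out * c(155, 850, 135)[col(out)]  # mm half-extents
  triangle_mesh(out, f, name = sprintf("template_s%d", subdivision))
}

# signed volume of a closed mesh (mm^3), divergence theorem
mesh_volume <- function(mesh) {
  V <- mesh$vertices
  f <- mesh$faces + 1L
  a <- V[f[, 1], , drop = FALSE]
  b <- V[f[, 2], , drop = FALSE]
  c_ <- V[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(rowSums(a * cr)) / 6)
}

# ---- morph fields ----------------------------------------------------------

# Deform the template by the five positive morph factors. Displacements are
# smooth radial fields; every field strictly grows the body with its factor,
# keeping the shape -> size -> composition chain monotone.
apply_morphs <- function(template, m) {
  v <- template$vertices
  ymax <- max(abs(v[, 2]))
  yn <- v[, 2] / ymax                       # normalized height in [-1, 1]
  trunk_w <- exp(-((yn - 0.05) / 0.45)^2)   # mid-body band
  limb_w <- exp(-((yn + 0.75) / 0.3)^2) + exp(-((abs(yn) - 0.55) / 0.25)^2) * 0.5
  belly_w <- exp(-((yn + 0.1) / 0.25)^2)    # lower-trunk adiposity band
  radial_gain <- 1 +
    (m[["trunk"]] - 1) * trunk_w +
    (m[["limb"]] - 1) * limb_w +
    0.6 * (m[["adiposity"]] - 1) * belly_w +
    0.1 * (m[["adiposity"]] - 1)            # global soft-tissue component
  out <- v
  out[, c(1, 3)] <- v[, c(1, 3)] * radial_gain * m[["scale"]]
  out[, 2] <- v[, 2] * m[["stature"]] * m[["scale"]]
  out
}

# sex-specific monotone-nonlinear composition functions of the latent morphs
# and derived height/weight; quadratic adiposity terms are deliberate.
composition_truth <- function(m, sex, height_cm, weight_kg) {
  a <- m[["adiposity"]]; tr <- m[["trunk"]]; li <- m[["limb"]]
  male <- sex == "male"
  # fat fraction: monotone increasing in adiposity with genuine curvature —
  # the quadratic a^2 term is comparable to the linear one over the sampled
  # range — plus a trunk interaction; males leaner at equal morphs
  ffrac <- (if (male) 0.16 else 0.24) +
    0.05 * (a - 1) + 0.09 * (a^2 - 1) + 0.04 * (tr - 1) +
    0.05 * (a - 1) * (tr - 1)
  ffrac <- pmin(pmax(ffrac, 0.05), 0.55)
  fat <- ffrac * weight_kg
  lean <- (1 - ffrac) * weight_kg * 0.96    # remainder is bone/other
  visceral <- (if (male) 0.028 else 0.020) * weight_kg *
    (0.4 + 0.6 * a^2) * (0.7 + 0.3 * tr)
  arm_lean <- lean * (if (male) 0.125 else 0.105) * (0.7 + 0.3 * li)
  leg_lean <- lean * (if (male) 0.34 else 0.32) * (0.7 + 0.3 * li)
  trunk_fat <- fat * (0.48 + 0.08 * (tr - 1))
  arm_fat <- fat * 0.10 * (0.8 + 0.2 * li)
  leg_fat <- fat * (if (male) 0.30 else 0.34) * (0.8 + 0.2 * li)
  trunk_lean <- lean * 0.48 * (0.8 + 0.2 * tr)
  c(total_fat_mass = fat, total_lean_mass = lean,
    visceral_fat_mass = visceral, arm_lean_mass = arm_lean,
    leg_lean_mass = leg_lean, percent_fat = 100 * ffrac,
    trunk_fat_mass = trunk_fat, trunk_lean_mass = trunk_lean,
    arm_fat_mass = arm_fat, leg_fat_mass = leg_fat)
}

#' Sample a synthetic cohort
#'
#' Draws per-subject morph factors, deforms the template, derives height
#' from the vertical extent and weight from the enclosed volume at a fixed
#' tissue density, evaluates the sex-specific monotone composition
#' functions, and adds per-target measurement noise. Fully deterministic
#' under the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `meshes` (list of [triangle_mesh]), `records` (tibble:
#'   id, sex, height_cm, weight_kg, age_years + the 10 targets), `truth`
#'   (tibble of latent morph parameters), `template`.
#' @export
sample_population <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("spec must be a synthetic_spec")
  template <- make_template(spec$subdivision)
  set.seed(spec$seed)
  n <- spec$n_subjects
  pn <- names(spec$morph_mean)
  morphs <- vapply(pn, function(p) {
    pmax(stats::rnorm(n, spec$morph_mean[[p]], spec$morph_sd[[p]]), 0.3)
  }, numeric(n))
  if (n == 1L) morphs <- matrix(morphs, nrow = 1L, dimnames = list(NULL, pn))
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  meshes <- vector("list", n)
  height <- numeric(n)
  weight <- numeric(n)
  targ_mat <- matrix(0, n, 10L,
                     dimnames = list(NULL, composition_targets()))
  density_kg_mm3 <- 0.985e-6
  for (i in seq_len(n)) {
    m <- morphs[i, ]
    vi <- apply_morphs(template, m)
    mesh <- triangle_mesh(vi, template$faces, name = sprintf("subj%04d", i))
    meshes[[i]] <- mesh
    height[i] <- (max(vi[, 2]) - min(vi[, 2])) / 10  # mm -> cm
    weight[i] <- mesh_volume(mesh) * density_kg_mm3
    targ_mat[i, ] <- composition_truth(m, sex[i], height[i], weight[i])
  }
  noise <- vapply(composition_targets(), function(tn) {
    stats::rnorm(n, 0, spec$composition_noise_sd[[tn]])
  }, numeric(n))
  if (n == 1L) noise <- matrix(noise, nrow = 1L)
  targ_mat <- targ_mat + noise
  targ_mat[, "percent_fat"] <- pmin(pmax(targ_mat[, "percent_fat"], 0), 100)
  mass_cols <- setdiff(colnames(targ_mat), "percent_fat")
  targ_mat[, mass_cols] <- pmax(targ_mat[, mass_cols], 0)
  records <- tibble::tibble(id = sprintf("subj%04d", seq_len(n)),
                            sex = sex, height_cm = height,
                            weight_kg = weight, age_years = age)
  records <- dplyr::bind_cols(records, tibble::as_tibble(targ_mat))
  truth <- dplyr::bind_cols(tibble::tibble(id = records$id),
                            tibble::as_tibble(morphs))
  list(meshes = meshes, records = records, truth = truth, template = template)
}

# smooth low-frequency pose-like displacement field (bending + sway)
pose_field <- function(vertices, amplitude, phase) {
  y <- vertices[, 2]
  ymax <- max(abs(y))
  yn <- y / ymax
  dx <- amplitude * sin(pi * yn / 2 + phase[1]) * cos(phase[2])
  dz <- amplitude * sin(pi * yn / 2 + phase[3]) * sin(phase[2])
  unname(cbind(dx, 0, dz))
}

#' Generate the duplicate-scan partner of a mesh
#'
#' The original plus a smooth low-frequency pose displacement and per-vertex
#' Gaussian noise — emulating two same-day scans of one person. The same
#' `subject_seed` always yields the same perturbation.
#'
#' @param mesh a [triangle_mesh].
#' @param spec a [synthetic_spec()] (uses `pose_jitter_mm`,
#'   `retest_noise_sd_mm`).
#' @param subject_seed integer seed for this subject's perturbation.
#' @return the perturbed [triangle_mesh].
#' @export
make_retest_pair <- function(mesh, spec, subject_seed) {
  stopifnot_mesh(mesh)
  set.seed(as.integer(subject_seed))
  v <- mesh$vertices
  phase <- stats::runif(3, 0, 2 * pi)
  v <- v + pose_field(v, spec$pose_jitter_mm, phase)
  v <- v + matrix(stats::rnorm(length(v), 0, spec$retest_noise_sd_mm),
                  nrow(v), 3L)
  triangle_mesh(v, mesh$faces, name = paste0(mesh$name, "_retest"))
}

#' Generate a pose-varied pretraining corpus
#'
#' Few identities, many smooth pose-like deformations each — the structure
#' of a pose-varied pretraining dataset, where shape diversity comes from
#' articulation rather than identity.
#'
#' @param spec a [synthetic_spec()] (identities are drawn from its morph
#'   distributions under its seed).
#' @param n_individuals number of distinct underlying morphs (small).
#' @param n_poses poses per individual.
#' @param pose_amplitude_mm bending amplitude of the pose field
#'   (default 40 mm, well above retest jitter).
#' @return list: `meshes` (length `n_individuals * n_poses`), `identity`
#'   (integer vector mapping mesh to individual).
#' @export
make_pretrain_set <- function(spec, n_individuals = 2L, n_poses = 50L,
                              pose_amplitude_mm = 40) {
  template <- make_template(spec$subdivision)
  set.seed(spec$seed + 10000L)
  pn <- names(spec$morph_mean)
  meshes <- vector("list", n_individuals * n_poses)
  identity <- integer(n_individuals * n_poses)
  k <- 0L
  for (ind in seq_len(n_individuals)) {
    m <- vapply(pn, function(p) {
      pmax(stats::rnorm(1, spec$morph_mean[[p]], spec$morph_sd[[p]]), 0.3)
    }, numeric(1))
    base <- apply_morphs(template, m)
    for (po in seq_len(n_poses)) {
      phase <- stats::runif(3, 0, 2 * pi)
      amp <- stats::runif(1, 0.3, 1) * pose_amplitude_mm
      v <- base + pose_field(base, amp, phase)
      k <- k + 1L
      meshes[[k]] <- triangle_mesh(v, template$faces,
                                   name = sprintf("id%02d_pose%03d", ind, po))
      identity[k] <- ind
    }
  }
  list(meshes = meshes, identity = identity, template = template)
}
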