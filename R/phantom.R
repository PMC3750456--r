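#' Synthetic orbit phantom specification
#'
#' Describes a bilateral head phantom: two half-ellipsoid orbital cavities
#' wrapped in a bone shell inside a soft-tissue block, with an optional
#' blow-out fracture (displaced wall fragment adding a target volume), a
#' reconstructed state with residual shape deviation and a thin
#' high-intensity titanium-mesh sheet, and CT/CBCT-like intensity
#' profiles. All randomness (noise) is driven by `seed`.
#'
#' The default cavity is calibrated so the clipped (behind-the-rim) cavity
#' volume equals `cavity_volume_ml` = 26.6 ml analytically, the mean male
#' unaffected orbital volume; the default fracture adds 3.4 ml, the
#' largest posterior-ledge enlargement observed clinically.
#'
#' @param spacing_mm isotropic voxel spacing (default 0.5 mm).
#' @param cavity_volume_ml true clipped cavity volume of the unaffected
#'   side (half-ellipsoid, (2/3) pi a b c).
#' @param aspect length-3 semi-axis ratios (x = width, y = depth,
#'   z = height); scaled to reach `cavity_volume_ml`. The default is
#'   triaxial (wider than tall, deepest along the orbital axis), so the
#'   cavity has no rotational symmetry that would make surface
#'   registration degenerate.
#' @param asymmetry left/right linear scale ratio (1 = perfect mirror
#'   symmetry; left cavity volume scales with `asymmetry^3`).
#' @param affected_side side carrying the fracture/reconstruction.
#' @param fracture list: `wall` (`"floor"`/`"medial"`), `region`
#'   (`"anterior"`/`"central"`/`"posterior"`), `added_volume_ml`,
#'   `defect_gap_mm` (fracture-line width in the bone shell),
#'   `max_bulge_mm` (attainability cap), `sigma_deg` (angular extent).
#'   `NULL` for an intact phantom.
#' @param reconstruction list: `residual_amplitude_mm`, `wall`, `region`,
#'   `sigma_deg` — the residual deviation of the reconstructed wall from
#'   the ideal (mirror) shape.
#' @param implant list: `present`, `thickness_mm`, `intensity`.
#' @param intensities list: `soft`, `bone` base intensities.
#' @param bone_thickness_mm bone shell thickness.
#' @param modality_pre,modality_post `"CT"` or `"CBCT"` intensity profile
#'   for the pre-/post-operative image (CBCT: scaled intensities, more
#'   noise).
#' @param noise_sigma optional named override of the per-modality noise SD,
#'   e.g. `c(CT = 0, CBCT = 0)` for noiseless phantoms.
#' @param seed integer seed fixing all randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing_mm = 0.5,
                         cavity_volume_ml = 26.6,
                         aspect = c(1, 1.25, 0.9),
                         asymmetry = 1.0,
                         affected_side = "right",
                         fracture = list(wall = "floor", region = "anterior",
                                         added_volume_ml = 3.4,
                                         defect_gap_mm = 2.0,
                                         max_bulge_mm = 10,
                                         sigma_deg = 25),
                         reconstruction = list(residual_amplitude_mm = 1.5,
                                               wall = "floor",
                                               region = "anterior",
                                               sigma_deg = 18),
                         implant = list(present = TRUE, thickness_mm = 1.0,
                                        intensity = 3000),
                         intensities = list(soft = 40, bone = 1200),
                         bone_thickness_mm = 2.5,
                         modality_pre = "CT", modality_post = "CBCT",
                         noise_sigma = NULL,
                         seed = 1L) {
  stopifnot(spacing_mm > 0, cavity_volume_ml > 0, all(aspect > 0),
            asymmetry > 0, bone_thickness_mm > 0)
  affected_side <- match.arg(affected_side, c("right", "left"))
  if (!is.null(fracture)) {
    fracture$wall <- match.arg(fracture$wall, c("floor", "medial"))
    fracture$region <- match.arg(fracture$region,
                                 c("anterior", "central", "posterior"))
    fracture$added_volume_ml <- fracture$added_volume_ml %||% 3.4
    fracture$defect_gap_mm <- fracture$defect_gap_mm %||% 2.0
    fracture$max_bulge_mm <- fracture$max_bulge_mm %||% 10
    fracture$sigma_deg <- fracture$sigma_deg %||% 25
    # fracture lines spare the orbital rim (trapdoor-like hinged fragment);
    # a gap reaching the free rim edge could never be bridged by closing
    fracture$rim_sparing_mm <- fracture$rim_sparing_mm %||% 3
    stopifnot(fracture$added_volume_ml >= 0, fracture$defect_gap_mm >= 0,
              fracture$rim_sparing_mm >= 0)
  }
  if (!is.null(reconstruction)) {
    reconstruction$wall <- match.arg(reconstruction$wall, c("floor", "medial"))
    reconstruction$region <- match.arg(reconstruction$region,
                                       c("anterior", "central", "posterior"))
    reconstruction$residual_amplitude_mm <-
      reconstruction$residual_amplitude_mm %||% 1.5
    reconstruction$sigma_deg <- reconstruction$sigma_deg %||% 18
  }
  # semi-axes from the clipped-volume target: (2/3) pi a b c = V
  scale3 <- cavity_volume_ml * 1000 * 3 / (2 * pi) / prod(aspect)
  semi_axes <- aspect * scale3^(1 / 3)
  structure(list(spacing_mm = spacing_mm, cavity_volume_ml = cavity_volume_ml,
                 semi_axes = semi_axes, asymmetry = asymmetry,
                 affected_side = affected_side, fracture = fracture,
                 reconstruction = reconstruction, implant = implant,
                 intensities = intensities,
                 bone_thickness_mm = bone_thickness_mm,
                 modality_pre = modality_pre, modality_post = modality_post,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# CT: HU-like, low noise; CBCT: scaled-down uncalibrated intensities,
# noisier (qualitatively: lower dose).
modality_profile <- function(name, noise_override = NULL) {
  p <- switch(name,
              CT = list(scale = 1.0, sigma = 15),
              CBCT = list(scale = 0.8, sigma = 40),
              stop("unknown modality profile: ", name))
  if (!is.null(noise_override) && name %in% names(noise_override))
    p$sigma <- as.numeric(noise_override[[name]])
  p
}

# direction of a wall region's centre on the unit ellipsoid, given the
# semi-axes and the medial direction (unit vector toward the midline)
region_direction <- function(wall, region, semi_axes, medial_dir) {
  ay <- semi_axes[2]
  ystar <- -ay * c(anterior = 1 / 6, central = 1 / 2, posterior = 5 / 6)[[region]]
  lat <- sqrt(max(0, 1 - (ystar / ay)^2))
  u <- if (wall == "floor") c(0, ystar, -semi_axes[3] * lat)
  else medial_dir * semi_axes[1] * lat + c(0, ystar, 0)
  u / sqrt(sum(u^2))
}

# added cavity volume (ml) of an angular-Gaussian radial bulge of amplitude
# A (mm), by numerical integration over directions (posterior half only,
# matching the rim clip)
bulge_added_volume_ml <- function(A, semi_axes, u0, sigma_rad, nth = 96, nph = 96) {
  # orthonormal frame around u0
  e1 <- c(1, 0, 0)
  if (abs(sum(e1 * u0)) > 0.9) e1 <- c(0, 1, 0)
  e1 <- e1 - sum(e1 * u0) * u0
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u0[2] * e1[3] - u0[3] * e1[2], u0[3] * e1[1] - u0[1] * e1[3],
          u0[1] * e1[2] - u0[2] * e1[1])
  thmax <- min(pi, 5 * sigma_rad)
  th <- (seq_len(nth) - 0.5) / nth * thmax
  ph <- (seq_len(nph) - 0.5) / nph * 2 * pi
  g <- exp(-0.5 * (th / sigma_rad)^2)
  acc <- 0
  for (i in seq_along(th)) {
    dirs <- sin(th[i]) * (outer(cos(ph), e1) + outer(sin(ph), e2)) +
      cos(th[i]) * matrix(u0, nph, 3, byrow = TRUE)
    post <- dirs[, 2] < 0  # behind the rim plane
    if (!any(post)) next
    m <- sqrt((dirs[, 1] / semi_axes[1])^2 + (dirs[, 2] / semi_axes[2])^2 +
              (dirs[, 3] / semi_axes[3])^2)
    rb <- 1 / m
    a <- A * g[i]
    acc <- acc + sum(((rb[post] + a)^3 - rb[post]^3) / 3) * sin(th[i])
  }
  acc * (thmax / nth) * (2 * pi / nph) / 1000
}

# solve the bulge amplitude reaching the target added volume
calibrate_bulge <- function(target_ml, semi_axes, u0, sigma_rad, max_bulge_mm) {
  if (target_ml <= 0) return(0)
  vmax <- bulge_added_volume_ml(max_bulge_mm, semi_axes, u0, sigma_rad)
  if (vmax < target_ml)
    stop(sprintf(paste0("target added volume %.2f ml unattainable with bulge ",
                        "amplitude <= %.1f mm (attainable maximum %.2f ml)"),
                 target_ml, max_bulge_mm, vmax))
  stats::uniroot(function(A)
    bulge_added_volume_ml(A, semi_axes, u0, sigma_rad) - target_ml,
    c(0, max_bulge_mm), tol = 1e-6)$root
}

# per-side voxel geometry: signed radial excess s = |u| - Rb(u) (mm,
# negative inside the ideal cavity) and the angle (rad) from a bump
# direction, over the full grid, computed lazily per side
side_fields <- function(xs, ys, zs, center, semi_axes) {
  ux <- xs - center[1]; uy <- ys - center[2]; uz <- zs - center[3]
  U2 <- outer(outer(ux^2, uy^2, "+"), uz^2, "+")
  M2 <- outer(outer((ux / semi_axes[1])^2, (uy / semi_axes[2])^2, "+"),
              (uz / semi_axes[3])^2, "+")
  s <- sqrt(U2) * (1 - 1 / sqrt(M2))
  s[!is.finite(s)] <- -100
  list(s = s, U2 = U2, ux = ux, uy = uy, uz = uz)
}

angle_from <- function(fld, u0) {
  dotp <- outer(outer(fld$ux * u0[1], fld$uy * u0[2], "+"), fld$uz * u0[3], "+")
  cs <- dotp / sqrt(pmax(fld$U2, 1e-12))
  acos(pmin(1, pmax(-1, cs)))
}

#' Generate a paired unaffected/fractured/reconstructed orbit phantom
#'
#' Builds a pre-operative image (affected side fractured, other side
#' intact) and a post-operative image (affected side reconstructed, with
#' an optional implant sheet) of one bilateral head phantom, together with
#' full ground truth: cavity masks and volumes for all three states, bone
#' masks, landmarks, mirror plane, rim planes, bulge geometry and implant
#' voxels. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `orbit_phantom` with elements `preop`, `postop`
#'   ([volume_image()]s), `landmarks` ([landmark_set()]), `truth` (list),
#'   and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$spacing_mm
  ax <- spec$semi_axes
  th <- spec$bone_thickness_mm
  aff <- spec$affected_side
  una <- setdiff(c("right", "left"), aff)
  axes_of <- function(side) if (side == "left") ax * spec$asymmetry else ax
  cx_of <- function(side) {
    a1 <- axes_of(side)[1]
    (a1 + 7) * if (side == "right") 1 else -1
  }
  centers <- list(right = c(cx_of("right"), 0, 0), left = c(cx_of("left"), 0, 0))
  bulge_max <- if (!is.null(spec$fracture)) spec$fracture$max_bulge_mm else 0
  lo <- c(-(abs(cx_of("left")) + axes_of("left")[1] + th + 4),
          -(max(axes_of("right")[2], axes_of("left")[2]) + th + 4),
          -(max(axes_of("right")[3], axes_of("left")[3]) + bulge_max + th + 4))
  hi <- c(abs(cx_of("right")) + axes_of("right")[1] + th + 4,
          6,
          max(axes_of("right")[3], axes_of("left")[3]) + bulge_max + th + 4)
  # align voxel-cell faces with the rim (y = 0) and mirror (x = 0) planes:
  # centres sit at odd multiples of h/2, so clipping at those planes is
  # exact at every spacing (no half-cell quantisation of the rim cut)
  origin <- (floor(lo / h) + 0.5) * h
  dims <- as.integer(ceiling((hi - origin) / h)) + 1L
  xs <- origin[1] + (seq_len(dims[1]) - 1) * h
  ys <- origin[2] + (seq_len(dims[2]) - 1) * h
  zs <- origin[3] + (seq_len(dims[3]) - 1) * h
  post_rim <- function() outer(outer(rep(TRUE, dims[1]), ys < 0, "&"),
                               rep(TRUE, dims[3]), "&")
  behind <- post_rim()

  mk_state <- function(side, state) {
    # state: "intact", "fractured", "reconstructed"
    A <- axes_of(side)
    ctr <- centers[[side]]
    medial_dir <- c(-sign(ctr[1]), 0, 0)
    fld <- side_fields(xs, ys, zs, ctr, A)
    amp <- array(0, dims)
    extras <- list()
    if (state == "fractured" && !is.null(spec$fracture)) {
      fr <- spec$fracture
      u0 <- region_direction(fr$wall, fr$region, A, medial_dir)
      sg <- fr$sigma_deg * pi / 180
      Abulge <- calibrate_bulge(fr$added_volume_ml, A, u0, sg, fr$max_bulge_mm)
      ang <- angle_from(fld, u0)
      amp <- Abulge * exp(-0.5 * (ang / sg)^2)
      extras$bulge <- list(u0 = u0, sigma_rad = sg, amplitude_mm = Abulge)
      rb0 <- 1 / sqrt(sum((u0 / A)^2))      # boundary radius along u0
      deep <- outer(outer(rep(TRUE, dims[1]),
                          ys < -fr$rim_sparing_mm, "&"),
                    rep(TRUE, dims[3]), "&")
      extras$gap_band <- deep &               # fracture lines at the
        abs(ang - 2 * sg) <=                  # fragment border
        (fr$defect_gap_mm / 2) / rb0
    }
    if (state == "reconstructed" && !is.null(spec$reconstruction)) {
      rc <- spec$reconstruction
      u0 <- region_direction(rc$wall, rc$region, A, medial_dir)
      sg <- rc$sigma_deg * pi / 180
      ang <- angle_from(fld, u0)
      amp <- rc$residual_amplitude_mm * exp(-0.5 * (ang / sg)^2)
      extras$residual <- list(u0 = u0, sigma_rad = sg,
                              amplitude_mm = rc$residual_amplitude_mm)
      if (isTRUE(spec$implant$present)) {
        s_ex <- fld$s - amp
        extras$implant <- s_ex > 0 & s_ex <= spec$implant$thickness_mm &
          ang <= 2.5 * sg & behind
      }
    }
    s_ex <- fld$s - amp
    cavity <- s_ex <= 0 & behind
    shell <- s_ex > 0 & s_ex <= th & behind
    if (!is.null(extras$gap_band)) shell <- shell & !extras$gap_band
    c(list(cavity = cavity, shell = shell, center = ctr, axes = A), extras)
  }

  states_pre <- list()
  states_pre[[una]] <- mk_state(una, "intact")
  states_pre[[aff]] <- mk_state(aff, if (is.null(spec$fracture)) "intact" else "fractured")
  states_post <- list()
  states_post[[una]] <- states_pre[[una]]
  states_post[[aff]] <- mk_state(aff, if (is.null(spec$reconstruction)) "intact" else "reconstructed")

  compose <- function(states, modality) {
    prof <- modality_profile(modality, spec$noise_sigma)
    img <- array(spec$intensities$soft, dims)
    for (side in names(states)) {
      img[states[[side]]$shell] <- spec$intensities$bone
      imp <- states[[side]]$implant
      if (!is.null(imp)) img[imp] <- spec$implant$intensity
    }
    img <- img * prof$scale
    if (prof$sigma > 0)
      img <- img + array(stats::rnorm(prod(dims), 0, prof$sigma), dims)
    volume_image(img, rep(h, 3), origin)
  }
  set.seed(spec$seed)
  preop <- compose(states_pre, spec$modality_pre)
  postop <- compose(states_post, spec$modality_post)

  vox_ml <- h^3 / 1000
  mk_lm <- function(side) {
    A <- axes_of(side)
    ctr <- centers[[side]]
    lat <- c(sign(ctr[1]), 0, 0)
    list(L = ctr + lat * A[1], M = ctr - lat * A[1],
         apex = ctr + c(0, -A[2], 0))
  }
  landmarks <- landmark_set(right = mk_lm("right"), left = mk_lm("left"),
                            midline = rbind(c(0, 3, zs[length(zs)] - 6),
                                            c(0, lo[2] + 8, zs[length(zs)] - 10),
                                            c(0, 4, zs[1] + 8)))
  truth <- list(
    volumes_ml = c(
      unaffected = sum(states_pre[[una]]$cavity) * vox_ml,
      affected = sum(states_pre[[aff]]$cavity) * vox_ml,
      reconstructed = sum(states_post[[aff]]$cavity) * vox_ml),
    cavity_masks = list(
      unaffected = states_pre[[una]]$cavity,
      affected = states_pre[[aff]]$cavity,
      reconstructed = states_post[[aff]]$cavity),
    bone_mask_pre = states_pre[[una]]$shell | states_pre[[aff]]$shell,
    implant_mask = states_post[[aff]]$implant,
    mirror_plane = plane3(c(1, 0, 0), c(0, 0, 0)),
    rim_planes = list(right = plane3(c(0, 1, 0), centers$right),
                      left = plane3(c(0, 1, 0), centers$left)),
    centers = centers, semi_axes = list(right = axes_of("right"),
                                        left = axes_of("left")),
    bulge = states_pre[[aff]]$bulge,
    residual = states_post[[aff]]$residual,
    affected_side = aff, unaffected_side = una,
    spacing = rep(h, 3), origin = origin, dims = dims)
  structure(list(preop = preop, postop = postop, landmarks = landmarks,
                 truth = truth, spec = spec),
            class = "orbit_phantom")
}

#' @export
print.orbit_phantom <- function(x, ...) {
  v <- x$truth$volumes_ml
  cat(sprintf(paste0("orbit_phantom: %s voxels at %.2g mm; truth volumes ",
                     "unaffected %.2f / affected %.2f / reconstructed %.2f ml\n"),
              paste(x$truth$dims, collapse = "x"), x$spec$spacing_mm,
              v["unaffected"], v["affected"], v["reconstructed"]))
  invisible(x)
}

#' Ground-truth wall/third labels for a template mesh
#'
#' Paints the nine-region partition onto mesh vertices using the phantom's
#' analytic geometry (true centre, rim plane, medial direction), for
#' benchmarking data-driven labeling.
#'
#' @param phantom An `orbit_phantom`.
#' @param mesh A [surface_mesh()] in the affected side's frame (e.g. the
#'   mirrored template).
#' @param side which side's geometry to use (default the affected side).
#' @param thirds split walls into thirds (default TRUE).
#' @param rim_band_mm anterior band labeled `rim`.
#' @return A [region_labeling()].
#' @export
phantom_truth_labels <- function(phantom, mesh, side = NULL, thirds = TRUE,
                                 rim_band_mm = 1.5) {
  side <- side %||% phantom$truth$affected_side
  ctr <- phantom$truth$centers[[side]]
  A <- phantom$truth$semi_axes[[side]]
  v <- sweep(mesh$vertices, 2, ctr)
  medial <- c(-sign(ctr[1]), 0, 0)
  down <- c(0, 0, -1)
  rx <- v[, 1]; rz <- v[, 3]
  dots <- cbind(floor = -rz, roof = rz, medial = rx * medial[1],
                lateral = -rx * medial[1])
  label <- colnames(dots)[apply(dots, 1, which.max)]
  depth <- -v[, 2]
  if (thirds) {
    d <- depth / A[2]
    third <- ifelse(d < 1 / 3, "anterior", ifelse(d < 2 / 3, "central", "posterior"))
    wall <- label %in% c("medial", "floor", "lateral")
    label[wall] <- paste(label[wall], third[wall], sep = "_")
  }
  label[depth >= 0 & depth < rim_band_mm] <- "rim"
  label[depth < 0] <- "unassigned"
  region_labeling(label)
}

#' Generate a synthetic cohort of case records
#'
#' Draws `n` cases with the clinical composition of the study population:
#' gender 58:36 male:female, treatment group 60:34 Navi:conventional,
#' fracture classes 34/20/36/4 (anterior-central floor / posterior ledge /
#' complex medial / complex lateral). Unaffected CT volumes come from
#' gender-specific normals (male 26.6 +- 2.8 ml, female 25.2 +- 2.6 ml);
#' CBCT repeats the CT value with modality noise; fracture enlargement and
#' post-operative residuals are class- and group-dependent.
#'
#' @param n number of cases.
#' @param seed integer seed.
#' @param male_mean_sd,female_mean_sd unaffected CT volume (ml) mean/SD.
#' @param modality_sd SD of the CBCT-vs-CT measurement difference (ml).
#' @param navi_residual_mean,conv_residual_mean mean residual enlargement
#'   (ml) of the reconstructed vs unaffected orbit per group.
#' @param residual_sd SD of that residual.
#' @return A [cohort_records()] data.frame.
#' @export
generate_cohort <- function(n = 94, seed = 1L,
                            male_mean_sd = c(26.6, 2.8),
                            female_mean_sd = c(25.2, 2.6),
                            modality_sd = 0.4,
                            navi_residual_mean = 0.0,
                            conv_residual_mean = 0.3,
                            residual_sd = 0.5) {
  stopifnot(n >= 1)
  set.seed(seed)
  gender <- sample(c("male", "female"), n, replace = TRUE, prob = c(58, 36))
  group <- sample(treatment_groups(), n, replace = TRUE, prob = c(60, 34))
  fclass <- sample(fracture_classes(), n, replace = TRUE,
                   prob = c(34, 20, 36, 4))
  side <- sample(c("right", "left"), n, replace = TRUE, prob = c(52, 42))
  base <- ifelse(gender == "male",
                 stats::rnorm(n, male_mean_sd[1], male_mean_sd[2]),
                 stats::rnorm(n, female_mean_sd[1], female_mean_sd[2]))
  base <- pmax(base, 15)
  enlarge_mean <- c(anterior_central_floor = 0.3, floor_posterior_ledge = 2.0,
                    complex_medial = 1.5, complex_lateral = 1.0)[fclass]
  enlarge_sd <- c(anterior_central_floor = 0.3, floor_posterior_ledge = 0.8,
                  complex_medial = 0.7, complex_lateral = 0.5)[fclass]
  enlargement <- pmax(0, stats::rnorm(n, enlarge_mean, enlarge_sd))
  resid_mean <- ifelse(group == "Navi", navi_residual_mean, conv_residual_mean)
  residual <- stats::rnorm(n, resid_mean, residual_sd)
  records <- data.frame(
    case_id = sprintf("case_%03d", seq_len(n)),
    gender = gender, side = side, fracture_class = fclass, group = group,
    unaffected_CT = base,
    affected_CT = base + enlargement,
    unaffected_CBCT = base + stats::rnorm(n, 0, modality_sd),
    reconstructed_CBCT = base + residual + stats::rnorm(n, 0, modality_sd))
  cohort_records(records)
}
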