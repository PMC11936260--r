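#' Scene parameters for the synthetic z-stack generator
#'
#' Describes one acquisition: slice geometry, cell geometry, the punctate ROS
#' signal model, and the confocal noise model. Defaults emulate the imaging
#' setup the classifiers are built for: 1024 x 1024-pixel slices, 18-20
#' optical sections at a 0.5 um z-step, one actin-outlined cell per field and
#' a punctate ROS channel. Intensity statistics of the real data are unknown;
#' the distributional defaults here are synthetic stand-ins, documented in the
#' methods vignette.
#'
#' @param image_size_px Per-slice height = width in pixels.
#' @param n_slices Number of optical sections; `NULL` draws uniformly from
#'   18-20 per stack (the acquisition's stated range). Must lie in 1-64.
#' @param z_step_um Axial distance between sections (um).
#' @param pixel_size_um Lateral calibration (um per pixel).
#' @param cell_radius_um Length-2 range of the cell's in-plane semi-axes (um).
#' @param cortex_width_um Thickness of the bright cortical actin rim (um).
#' @param puncta_rate Expected number of ROS puncta per cell (Poisson mean).
#' @param puncta_intensity_mu Mean punctum peak amplitude (16-bit counts);
#'   amplitudes are log-normal with this expectation.
#' @param puncta_intensity_sigma Log-scale standard deviation of amplitudes.
#' @param puncta_sigma_um Gaussian spot width (um, isotropic in xy).
#' @param ros_diffuse_level Diffuse cytoplasmic ROS intensity (counts):
#'   CellROX-style signal is punctate on top of a dim whole-cell component,
#'   so the treatment multiplier also modulates how far the cell body rises
#'   above the background noise. Set to 0 for purely punctate signal.
#' @param background_level Additive background (counts).
#' @param read_noise_sigma Gaussian read-noise standard deviation (counts).
#' @param shot_noise If `TRUE`, pixel counts are Poisson-distributed around
#'   the noiseless signal + background.
#' @param z_attenuation Per-slice multiplicative signal decay (1 = none).
#' @param z_extent_factor Cell axial semi-extent in units of the acquired
#'   stack height; values well above 1 mean every optical section cuts the
#'   cell near its equator, smaller values shrink the end sections.
#' @param actin_amplitude Peak intensity of the cortical rim (counts).
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_size_px = 1024,
                         n_slices = NULL,
                         z_step_um = 0.5,
                         pixel_size_um = 0.25,
                         cell_radius_um = c(18, 26),
                         cortex_width_um = 1.5,
                         puncta_rate = 30,
                         puncta_intensity_mu = 3000,
                         puncta_intensity_sigma = 0.5,
                         puncta_sigma_um = 0.6,
                         ros_diffuse_level = 120,
                         background_level = 150,
                         read_noise_sigma = 40,
                         shot_noise = TRUE,
                         z_attenuation = 0.97,
                         z_extent_factor = 0.75,
                         actin_amplitude = 10000) {
  p <- list(
    image_size_px = as.integer(image_size_px), n_slices = n_slices,
    z_step_um = z_step_um, pixel_size_um = pixel_size_um,
    cell_radius_um = as.numeric(cell_radius_um),
    cortex_width_um = cortex_width_um, puncta_rate = puncta_rate,
    puncta_intensity_mu = puncta_intensity_mu,
    puncta_intensity_sigma = puncta_intensity_sigma,
    puncta_sigma_um = puncta_sigma_um,
    ros_diffuse_level = ros_diffuse_level,
    background_level = background_level,
    read_noise_sigma = read_noise_sigma, shot_noise = isTRUE(shot_noise),
    z_attenuation = z_attenuation, z_extent_factor = z_extent_factor,
    actin_amplitude = actin_amplitude
  )
  if (p$image_size_px <= 0 || p$z_step_um <= 0 || p$pixel_size_um <= 0 ||
      any(p$cell_radius_um <= 0) || p$cortex_width_um <= 0 ||
      p$puncta_sigma_um <= 0) {
    stop("all lengths must be positive", call. = FALSE)
  }
  if (!is.null(p$n_slices)) {
    p$n_slices <- as.integer(p$n_slices)
    if (p$n_slices < 1L || p$n_slices > 64L) {
      stop("n_slices must lie in [1, 64]", call. = FALSE)
    }
  }
  if (p$puncta_rate < 0) stop("puncta_rate must be >= 0", call. = FALSE)
  if (p$ros_diffuse_level < 0) {
    stop("ros_diffuse_level must be >= 0", call. = FALSE)
  }
  if (p$background_level < 0) stop("background_level must be >= 0", call. = FALSE)
  if (p$z_extent_factor <= 0) stop("z_extent_factor must be > 0", call. = FALSE)
  if (length(p$cell_radius_um) != 2L || diff(p$cell_radius_um) < 0) {
    stop("cell_radius_um must be an increasing length-2 range", call. = FALSE)
  }
  if (p$puncta_sigma_um > min(p$cell_radius_um)) {
    stop("puncta wider than the cell: reduce puncta_sigma_um", call. = FALSE)
  }
  structure(p, class = "scene_params")
}

#' Scene for classifier benchmarks: strong class separation
#'
#' A single-cell crop designed so that a multiplicative ROS effect survives
#' the classifier preprocessing. Per-slice min-max normalization followed by
#' histogram equalization is a rank transform, invariant to any monotone
#' per-image intensity map, so a pure intensity multiplier is only visible
#' where signal crosses the background noise floor. This scene therefore
#' puts the diffuse cytoplasmic component a few noise standard deviations
#' above background and the puncta amplitudes modestly above it: halving the
#' ROS signal turns a smooth, solid cell body with crisp puncta into a
#' grainy, faint one with fewer visible dots. The cell fills a realistic
#' fraction of a 128 um single-cell crop rendered natively at the
#' classifier's 256-pixel grid (downscaling would average away the very
#' noise interactions that carry the class signal), and spans the full
#' acquired z-range so end sections are not systematically low-signal.
#'
#' @param image_size_px,n_slices Crop geometry (defaults 256 px, 4 slices).
#' @param ... Further overrides passed to [scene_params()].
#' @return A [scene_params()] object.
#' @export
separable_scene <- function(image_size_px = 256, n_slices = 4, ...) {
  defaults <- list(image_size_px = image_size_px, n_slices = n_slices,
                   pixel_size_um = 0.5, cell_radius_um = c(30, 45),
                   puncta_rate = 45, puncta_intensity_mu = 150,
                   puncta_intensity_sigma = 0.35, puncta_sigma_um = 1.2,
                   ros_diffuse_level = 80, background_level = 150,
                   read_noise_sigma = 25, z_attenuation = 0.985,
                   z_extent_factor = 1.5)
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

#' Generate a labelled slice dataset for classifier benchmarks
#'
#' Convenience path from the generator straight to training data, in memory:
#' renders `n_per_group` cells per group of the design under `scene`,
#' z-slices the ROS channel and preprocesses every slice to 256 x 256.
#'
#' @param design An [effect_design()].
#' @param scene A [scene_params()]; defaults to [separable_scene()].
#' @param seed Master seed (per-cell seeds are derived from it).
#' @param out_size Processed slice side length.
#' @return A [slice_set()] with condition/treatment labels per slice.
#' @export
simulate_slice_dataset <- function(design, scene = separable_scene(),
                                   seed = 1, out_size = 256) {
  total <- sum(design$n)
  stopifnot(total > 0)
  seeds <- derive_seeds(seed, total)
  out <- list()
  i <- 0L
  for (g in seq_len(nrow(design))) {
    for (j in seq_len(design$n[g])) {
      i <- i + 1L
      id <- sprintf("%s_%s_%03d", design$condition[g], design$treatment[g], j)
      stack <- generate_cell_stack(scene, design[g, ], seed = seeds[i],
                                   cell_id = id)$stack
      out <- c(out, lapply(slice_stack(stack), preprocess_slice,
                           out_size = out_size,
                           condition = design$condition[g],
                           treatment = design$treatment[g]))
    }
  }
  slice_set(out)
}

#' Effect design: group sizes and condition/treatment effects
#'
#' Defines the six (condition x treatment) groups of the study design.
#' Each condition carries a baseline multiplier on the puncta rate and mean
#' punctum amplitude, a treatment effect multiplier `m` applied to the ROS
#' amplitude of CBD-treated cells (`m < 1`: CBD reduces ROS; `m = 1`: null),
#' and a spatial motif controlling where puncta sit inside the cell so the
#' three conditions are separable by a classifier.
#'
#' Defaults follow the qualitative pattern reported for these challenges:
#' CBD lowers the ROS signal under LPS and amyloid-beta (m = 0.6) but not
#' under GP120 (m = 1), and each condition gets a distinct motif.
#'
#' @param n_per_group Cells per (condition, treatment) group; scalar or a
#'   vector of 6 (ordered LPS, GP120, Abeta42 x control, CBD).
#' @param conditions Character vector of condition labels.
#' @param baseline_mult Per-condition multiplier on puncta rate and amplitude.
#' @param cbd_mult Per-condition CBD effect multiplier `m` (> 0).
#' @param motif Per-condition spatial motif, each one of `"peripheral"`,
#'   `"perinuclear"`, `"diffuse"`.
#' @return A data frame of class `effect_design` with one row per group and
#'   columns condition, treatment, n, rate_mult, intensity_mult, effect_mult,
#'   motif.
#' @export
effect_design <- function(n_per_group = 10,
                          conditions = c("LPS", "GP120", "Abeta42"),
                          baseline_mult = c(1.0, 1.1, 1.2),
                          cbd_mult = c(0.6, 1.0, 0.6),
                          motif = c("peripheral", "diffuse", "perinuclear")) {
  k <- length(conditions)
  stopifnot(length(baseline_mult) == k, length(cbd_mult) == k,
            length(motif) == k)
  if (any(baseline_mult <= 0) || any(cbd_mult <= 0)) {
    stop("multipliers must be > 0", call. = FALSE)
  }
  motif <- match.arg(motif, c("peripheral", "perinuclear", "diffuse"),
                     several.ok = TRUE)
  d <- data.frame(
    condition = rep(conditions, each = 2),
    treatment = rep(c("control", "CBD"), k),
    rate_mult = rep(baseline_mult, each = 2),
    intensity_mult = rep(baseline_mult, each = 2),
    effect_mult = as.vector(rbind(1, cbd_mult)),
    motif = rep(motif, each = 2),
    stringsAsFactors = FALSE
  )
  n <- rep_len(n_per_group, nrow(d))
  if (any(n < 0)) stop("group sizes must be >= 0", call. = FALSE)
  d$n <- as.integer(n)
  structure(d[, c("condition", "treatment", "n", "rate_mult",
                  "intensity_mult", "effect_mult", "motif")],
            class = c("effect_design", "data.frame"))
}

#' Two-channel z-stack container
#'
#' @param actin,ros Numeric (H, W, Z) arrays of nonnegative pixel counts.
#' @param pixel_size_um,z_step_um Physical calibration.
#' @param cell_id Identifier of the imaged cell.
#' @return An object of class `zstack`.
#' @export
zstack <- function(actin, ros, pixel_size_um, z_step_um, cell_id = "cell") {
  if (!identical(dim(actin), dim(ros))) {
    stop("actin and ros channels must share dimensions", call. = FALSE)
  }
  if (z_step_um <= 0) stop("z_step_um must be > 0", call. = FALSE)
  if (min(actin) < 0 || min(ros) < 0) {
    stop("pixel values must be >= 0", call. = FALSE)
  }
  structure(list(actin = actin, ros = ros, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, cell_id = cell_id),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$actin)
  cat(sprintf("<zstack %s> %d x %d px, %d slices, %.3g um/px, %.3g um z-step\n",
              x$cell_id, d[1], d[2], d[3], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

# Radial boundary function of the perturbed ellipse at angle theta.
cell_boundary_radius <- function(theta, a, b, theta0, harm_amp, harm_phase) {
  tr <- theta - theta0
  r <- a * b / sqrt((b * cos(tr))^2 + (a * sin(tr))^2)
  pert <- rep(0, length(theta))
  for (k in seq_along(harm_amp)) {
    pert <- pert + harm_amp[k] * cos((k + 1) * theta + harm_phase[k])
  }
  r * (1 + pert)
}

#' Generate one labelled synthetic two-channel cell stack
#'
#' Renders a single microglia-like cell: an ellipsoidal body whose in-plane
#' boundary is perturbed by low-order radial harmonics, a cortex-bright actin
#' channel, and a ROS channel of 3-D Gaussian puncta placed inside the cell
#' mask according to the group's spatial motif and scaled by its effect
#' multipliers. Confocal noise (optional Poisson shot noise plus Gaussian read
#' noise) and per-slice z-attenuation are applied on top; pixels are stored as
#' 16-bit counts clipped to [0, 65535]. Identical `(params, design, seed)`
#' give bit-identical output.
#'
#' @param params A [scene_params()] object.
#' @param design One row of an [effect_design()] (or an equivalent list with
#'   condition, treatment, rate_mult, intensity_mult, effect_mult, motif).
#' @param seed Integer seed; the stack is a pure function of its arguments.
#' @param cell_id Identifier stored in the stack and ground truth.
#' @return A list with components `stack` (a [zstack()]) and `truth`, the
#'   ground-truth record: 3-D cell `mask`, `area_um2` of the 2-D footprint,
#'   `true_integrated_ros` (sum of the noiseless ROS signal inside the mask),
#'   `puncta_count`, labels and the seed used.
#' @export
generate_cell_stack <- function(params, design, seed, cell_id = "cell_1") {
  stopifnot(inherits(params, "scene_params"))
  design <- as.list(design)
  with_seed(seed, {
    s <- params$image_size_px
    Z <- if (is.null(params$n_slices)) sample(18:20, 1) else params$n_slices
    px <- params$pixel_size_um

    # geometry
    ctr <- s / 2 + runif(2, -0.04, 0.04) * s
    ab <- runif(2, params$cell_radius_um[1], params$cell_radius_um[2]) / px
    theta0 <- runif(1, 0, pi)
    harm_amp <- runif(4, 0, 0.07)
    harm_phase <- runif(4, 0, 2 * pi)
    # the acquired z-range is centred on the cell and the cell is thicker
    # than the stack, so every optical section intersects it (smaller at the
    # stack edges)
    z0 <- (Z - 1) / 2
    cz <- max(Z * params$z_extent_factor, 0.6)

    xg <- seq_len(s) - ctr[1]
    yg <- seq_len(s) - ctr[2]
    dx <- matrix(xg, s, s)
    dy <- matrix(yg, s, s, byrow = TRUE)
    r <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    Rtheta <- matrix(cell_boundary_radius(as.vector(theta), ab[1], ab[2],
                                          theta0, harm_amp, harm_phase), s, s)

    sz <- sqrt(pmax(0, 1 - ((seq_len(Z) - 1 - z0) / cz)^2))
    atten <- params$z_attenuation^(seq_len(Z) - 1)
    cortex_px <- params$cortex_width_um / px

    mask <- array(FALSE, c(s, s, Z))
    actin_sig <- array(0, c(s, s, Z))
    for (z in seq_len(Z)) {
      if (sz[z] <= 0) next
      Rz <- Rtheta * sz[z]
      inside <- r <= Rz
      mask[, , z] <- inside
      # cortical rim hugs the inside of the membrane; the outward tail falls
      # off much faster so the actin outline does not overshoot the mask
      rim_w <- ifelse(inside, cortex_px, cortex_px / 4)
      rim <- params$actin_amplitude * exp(-0.5 * ((r - Rz) / rim_w)^2)
      actin_sig[, , z] <- (rim + 0.15 * params$actin_amplitude * inside) *
        atten[z]
    }
    if (!any(mask)) stop("degenerate geometry produced an empty cell mask",
                         call. = FALSE)

    # puncta
    lambda <- params$puncta_rate * design$rate_mult
    n_pts <- if (lambda > 0) rpois(1, lambda) else 0L
    amp_mean <- params$puncta_intensity_mu * design$intensity_mult *
      design$effect_mult
    sig_xy <- params$puncta_sigma_um / px
    sig_z <- params$puncta_sigma_um / params$z_step_um
    ros_sig <- array(0, c(s, s, Z))
    if (n_pts > 0) {
      amps <- rlnorm(n_pts,
                     meanlog = log(amp_mean) - params$puncta_intensity_sigma^2 / 2,
                     sdlog = params$puncta_intensity_sigma)
      thp <- runif(n_pts, 0, 2 * pi)
      u <- switch(design$motif,
                  peripheral  = rbeta(n_pts, 8, 2),
                  perinuclear = rbeta(n_pts, 2, 8),
                  diffuse     = sqrt(runif(n_pts)),
                  stop("unknown motif: ", design$motif, call. = FALSE))
      zw <- sz / sum(sz)
      zp <- sample.int(Z, n_pts, replace = TRUE, prob = zw)
      Rp <- cell_boundary_radius(thp, ab[1], ab[2], theta0,
                                 harm_amp, harm_phase) * sz[zp]
      xp <- ctr[1] + u * Rp * cos(thp)
      yp <- ctr[2] + u * Rp * sin(thp)
      wxy <- ceiling(3 * sig_xy)
      wz <- ceiling(3 * sig_z)
      for (i in seq_len(n_pts)) {
        xi <- max(1, round(xp[i]) - wxy):min(s, round(xp[i]) + wxy)
        yi <- max(1, round(yp[i]) - wxy):min(s, round(yp[i]) + wxy)
        zi <- max(1, zp[i] - wz):min(Z, zp[i] + wz)
        gx <- exp(-(xi - xp[i])^2 / (2 * sig_xy^2))
        gy <- exp(-(yi - yp[i])^2 / (2 * sig_xy^2))
        gz <- exp(-(zi - zp[i])^2 / (2 * sig_z^2))
        spot <- outer(gx, gy) # (x, y)
        for (j in seq_along(zi)) {
          ros_sig[xi, yi, zi[j]] <- ros_sig[xi, yi, zi[j]] +
            amps[i] * spot * gz[j]
        }
      }
      ros_sig <- sweep(ros_sig, 3, atten, `*`)
      ros_sig[!mask] <- 0 # puncta live inside the cell
    }
    diffuse <- params$ros_diffuse_level * design$intensity_mult *
      design$effect_mult
    if (diffuse > 0) {
      ros_sig <- ros_sig + sweep(mask * diffuse, 3, atten, `*`)
    }
    true_integrated_ros <- sum(ros_sig)

    add_noise <- function(signal) {
      lam <- signal + params$background_level
      out <- if (params$shot_noise) {
        array(rpois(length(lam), as.vector(lam)), dim(lam))
      } else lam
      if (params$read_noise_sigma > 0) {
        out <- out + rnorm(length(out), 0, params$read_noise_sigma)
      }
      array(pmin(pmax(round(out), 0), 65535), dim(lam))
    }
    stack <- zstack(add_noise(actin_sig), add_noise(ros_sig),
                    pixel_size_um = px, z_step_um = params$z_step_um,
                    cell_id = cell_id)
    footprint <- max_project(mask)
    truth <- list(
      cell_id = cell_id,
      condition = design$condition %||% NA_character_,
      treatment = design$treatment %||% NA_character_,
      mask = mask,
      area_px = sum(footprint),
      area_um2 = sum(footprint) * px^2,
      true_integrated_ros = true_integrated_ros,
      puncta_count = n_pts,
      n_slices = Z,
      seed = as.integer(seed)
    )
    list(stack = stack, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a labelled dataset of synthetic z-stacks on disk
#'
#' Renders one multi-page TIFF per cell for every group of the design (pages
#' interleave the two channels: actin, ros, actin, ros, ... by z, or two files
#' per cell under `layout = "split"`), plus `manifest.csv` and
#' `ground_truth.json` in `out_dir`. Group sizes match the design exactly;
#' per-cell seeds are derived reproducibly from `seed`.
#'
#' @param params A [scene_params()] object.
#' @param design An [effect_design()] data frame.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param layout `"interleaved"` (one TIFF per cell) or `"split"` (one TIFF
#'   per channel per cell).
#' @return Invisibly, a list with `manifest` (data frame: cell_id, path,
#'   condition, treatment, n_slices, seed) and `truth` (data frame of scalar
#'   ground-truth fields per cell).
#' @export
generate_dataset <- function(params, design, out_dir, seed,
                             layout = c("interleaved", "split")) {
  layout <- match.arg(layout)
  stopifnot(inherits(params, "scene_params"), is.data.frame(design))
  total <- sum(design$n)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir,
                                 call. = FALSE)
  seeds <- if (total > 0) derive_seeds(seed, total) else integer(0)
  manifest <- list(); truth <- list()
  i <- 0L
  for (g in seq_len(nrow(design))) {
    row <- design[g, ]
    for (j in seq_len(row$n)) {
      i <- i + 1L
      id <- sprintf("%s_%s_%03d", row$condition, row$treatment, j)
      gen <- generate_cell_stack(params, row, seed = seeds[i], cell_id = id)
      path <- file.path(out_dir, paste0(id, ".tif"))
      write_zstack(gen$stack, path, layout = layout)
      manifest[[i]] <- data.frame(
        cell_id = id, path = basename(path), condition = row$condition,
        treatment = row$treatment, n_slices = gen$truth$n_slices,
        seed = seeds[i], stringsAsFactors = FALSE
      )
      truth[[i]] <- data.frame(
        cell_id = id, condition = row$condition, treatment = row$treatment,
        area_px = gen$truth$area_px, area_um2 = gen$truth$area_um2,
        true_integrated_ros = gen$truth$true_integrated_ros,
        puncta_count = gen$truth$puncta_count,
        n_slices = gen$truth$n_slices, seed = seeds[i],
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(cell_id = character(), path = character(),
               condition = character(), treatment = character(),
               n_slices = integer(), seed = integer())
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(cell_id = character(), condition = character(),
               treatment = character(), area_px = numeric(),
               area_um2 = numeric(), true_integrated_ros = numeric(),
               puncta_count = integer(), n_slices = integer(),
               seed = integer())
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(truth_df, file.path(out_dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, truth = truth_df))
}

#' Write a two-channel z-stack as TIFF
#'
#' @param stack A [zstack()].
#' @param path Output path (`layout = "split"` appends `_actin`/`_ros`).
#' @param layout Page layout; see [generate_dataset()].
#' @return Invisibly, the path(s) written.
#' @export
write_zstack <- function(stack, path, layout = c("interleaved", "split")) {
  layout <- match.arg(layout)
  Z <- dim(stack$actin)[3]
  to_pages <- function(vol) lapply(seq_len(Z), function(z) vol[, , z] / 65535)
  if (layout == "interleaved") {
    pages <- vector("list", 2 * Z)
    pages[seq(1, 2 * Z, 2)] <- to_pages(stack$actin)
    pages[seq(2, 2 * Z, 2)] <- to_pages(stack$ros)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
    invisible(path)
  } else {
    pa <- sub("\\.tif{1,2}$", "_actin.tif", path)
    pr <- sub("\\.tif{1,2}$", "_ros.tif", path)
    tiff::writeTIFF(to_pages(stack$actin), pa, bits.per.sample = 16)
    tiff::writeTIFF(to_pages(stack$ros), pr, bits.per.sample = 16)
    invisible(c(pa, pr))
  }
}

#' Read a two-channel z-stack written by [write_zstack()]
#'
#' @param path Path to an interleaved TIFF, or length-2 vector
#'   (actin path, ros path) for split layout.
#' @param pixel_size_um,z_step_um Physical calibration to attach.
#' @param cell_id Identifier to attach.
#' @return A [zstack()].
#' @export
read_zstack <- function(path, pixel_size_um = 0.25, z_step_um = 0.5,
                        cell_id = NULL) {
  if (is.null(cell_id)) cell_id <- sub("\\.tif{1,2}$", "", basename(path[1]))
  to_vol <- function(pages) {
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) arr[, , z] <- round(pages[[z]] * 65535)
    arr
  }
  if (length(path) == 2L) {
    actin <- to_vol(tiff::readTIFF(path[1], all = TRUE))
    ros <- to_vol(tiff::readTIFF(path[2], all = TRUE))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) %% 2L != 0L) {
      stop("interleaved stack must have an even page count", call. = FALSE)
    }
    actin <- to_vol(pages[seq(1, length(pages), 2)])
    ros <- to_vol(pages[seq(2, length(pages), 2)])
  }
  zstack(actin, ros, pixel_size_um, z_step_um, cell_id)
}
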