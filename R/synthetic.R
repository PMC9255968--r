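#' Parameters of a synthetic sealing-zone layout
#'
#' The generator places actin cores with a Matern-style cluster process:
#' islet centers are drawn uniformly over the field (with mutual repulsion),
#' member cores are scattered around each center, and candidate cores that
#' violate the hard-core minimum separation are rejected and resampled.
#' Defaults emulate the morphometry of sealing zones imaged at super
#' resolution: core radii near 100 nm, nearest neighbors at 400-700 nm, and
#' islets of a few square micrometres containing on the order of 7 cores.
#'
#' @param field_size_nm numeric length-2, field width and height in nm.
#' @param n_islets number of islets.
#' @param islet_radius_nm mean islet extent (radius) in nm.
#' @param cores_per_islet_mean expected cores per islet (Poisson, min 1).
#' @param hard_core_nm minimum center-to-center core separation in nm.
#' @param core_radius_nm_mean,core_radius_nm_sd core radius distribution (nm).
#' @param base_intensity_mean,base_intensity_sd per-core baseline intensity
#'   (arbitrary units); peak spot amplitude above background when rendered.
#' @param seed integer seed; layouts are a pure function of parameters + seed.
#' @return a validated list of class \code{layout_params}.
#' @export
layout_params <- function(field_size_nm = c(10000, 10000),
                          n_islets = 12,
                          islet_radius_nm = 850,
                          cores_per_islet_mean = 7,
                          hard_core_nm = 400,
                          core_radius_nm_mean = 100,
                          core_radius_nm_sd = 15,
                          base_intensity_mean = 100,
                          base_intensity_sd = 10,
                          seed = 1L) {
  p <- list(field_size_nm = as.numeric(field_size_nm), n_islets = as.integer(n_islets),
            islet_radius_nm = islet_radius_nm, cores_per_islet_mean = cores_per_islet_mean,
            hard_core_nm = hard_core_nm, core_radius_nm_mean = core_radius_nm_mean,
            core_radius_nm_sd = core_radius_nm_sd, base_intensity_mean = base_intensity_mean,
            base_intensity_sd = base_intensity_sd, seed = as.integer(seed))
  if (length(p$field_size_nm) != 2 || any(p$field_size_nm <= 0))
    stop("layout_params: field_size_nm must be two positive lengths")
  if (p$n_islets < 0) stop("layout_params: n_islets must be >= 0")
  for (f in c("islet_radius_nm", "hard_core_nm", "core_radius_nm_mean"))
    if (p[[f]] <= 0) stop("layout_params: ", f, " must be positive")
  if (p$hard_core_nm >= 2 * p$islet_radius_nm)
    stop("layout_params: hard_core_nm must be < 2 * islet_radius_nm")
  class(p) <- "layout_params"
  p
}

#' Generate a ground-truth sealing-zone layout
#'
#' Places islet centers uniformly (rejected when closer than two islet
#' radii to a previous center, so islets are disjoint, with bounded
#' retries), then scatters a
#' Poisson number of cores per islet uniformly within the islet disc
#' (Matern-cluster offspring). Cores violating the hard-core separation
#' or falling outside the field are rejected and resampled up to a bounded
#' number of retries.
#'
#' @param params a \code{\link{layout_params}} object.
#' @return a \code{sz_layout}: list with \code{cores} (data.frame
#'   \code{core_id, islet_id, x_nm, y_nm, radius_nm, base_intensity}),
#'   \code{islets} (data.frame \code{islet_id, x_nm, y_nm, radius_nm}),
#'   \code{field_size_nm} and \code{params}.
#' @export
make_layout <- function(params) {
  stopifnot(inherits(params, "layout_params"))
  p <- params
  # feasibility: expected hard-core discs must not over-pack the field
  exp_cores <- p$n_islets * max(1, p$cores_per_islet_mean)
  disc_area <- pi * (p$hard_core_nm / 2)^2
  if (exp_cores * disc_area > 0.6 * prod(p$field_size_nm))
    stop("make_layout: unsatisfiable density - expected cores x hard-core disc area exceeds 60% of field area")
  set.seed(p$seed)
  W <- p$field_size_nm[1]; H <- p$field_size_nm[2]
  margin <- min(p$islet_radius_nm, min(W, H) / 4)
  icx <- icy <- numeric(0)
  for (i in seq_len(p$n_islets)) {
    for (try in seq_len(500)) {
      cx <- stats::runif(1, margin, W - margin)
      cy <- stats::runif(1, margin, H - margin)
      if (length(icx) == 0 ||
          min(sqrt((icx - cx)^2 + (icy - cy)^2)) >= 2 * p$islet_radius_nm) break
    }
    icx <- c(icx, cx); icy <- c(icy, cy)
  }
  cores <- list(); xs <- ys <- numeric(0)
  cid <- 0L
  edge_pad <- 2 * p$core_radius_nm_mean   # keep rendered spots inside the field
  for (i in seq_len(p$n_islets)) {
    n_i <- max(1L, stats::rpois(1, p$cores_per_islet_mean))
    for (j in seq_len(n_i)) {
      placed <- FALSE
      for (try in seq_len(300)) {
        # Matern-cluster offspring: uniform in the islet disc
        ang <- stats::runif(1, 0, 2 * pi)
        rr <- p$islet_radius_nm * sqrt(stats::runif(1))
        x <- icx[i] + rr * cos(ang)
        y <- icy[i] + rr * sin(ang)
        if (x < edge_pad || x > W - edge_pad || y < edge_pad || y > H - edge_pad) next
        if (length(xs) > 0 && min(sqrt((xs - x)^2 + (ys - y)^2)) < p$hard_core_nm) next
        placed <- TRUE; break
      }
      if (!placed) next   # bounded retries exhausted; islet gets fewer cores
      cid <- cid + 1L
      xs <- c(xs, x); ys <- c(ys, y)
      cores[[cid]] <- data.frame(
        core_id = cid, islet_id = i, x_nm = x, y_nm = y,
        radius_nm = max(30, stats::rnorm(1, p$core_radius_nm_mean, p$core_radius_nm_sd)),
        base_intensity = max(1, stats::rnorm(1, p$base_intensity_mean, p$base_intensity_sd)))
    }
  }
  cores <- if (cid > 0) do.call(rbind, cores) else
    data.frame(core_id = integer(0), islet_id = integer(0), x_nm = numeric(0),
               y_nm = numeric(0), radius_nm = numeric(0), base_intensity = numeric(0))
  islets <- data.frame(islet_id = seq_len(p$n_islets),
                       x_nm = icx[seq_len(p$n_islets)],
                       y_nm = icy[seq_len(p$n_islets)],
                       radius_nm = rep(p$islet_radius_nm, p$n_islets))
  structure(list(cores = cores, islets = islets,
                 field_size_nm = p$field_size_nm, params = p),
            class = "sz_layout")
}

#' Build a layout from explicit core coordinates
#'
#' Wraps user-supplied core positions (for example a measured core table, or
#' a deliberately arranged belt portion) in a ground-truth layout so that
#' the renderers and simulators can be used on them directly.
#'
#' @param x_nm,y_nm core coordinates (nm).
#' @param radius_nm,base_intensity per-core values, recycled.
#' @param field_size_nm field width and height (nm); default fits the cores
#'   with a 1 um margin.
#' @param islet_id per-core islet membership, recycled (default: one islet).
#' @param islet_radius_nm nominal islet radius recorded for each islet.
#' @return an \code{sz_layout}.
#' @export
layout_from_cores <- function(x_nm, y_nm, radius_nm = 100, base_intensity = 100,
                              field_size_nm = NULL, islet_id = 1L,
                              islet_radius_nm = 500) {
  n <- length(x_nm)
  stopifnot(length(y_nm) == n, n >= 1)
  if (is.null(field_size_nm))
    field_size_nm <- c(max(x_nm) + 1000, max(y_nm) + 1000)
  islet_id <- rep_len(as.integer(islet_id), n)
  cores <- data.frame(core_id = seq_len(n), islet_id = islet_id,
                      x_nm = x_nm, y_nm = y_nm,
                      radius_nm = rep_len(radius_nm, n),
                      base_intensity = rep_len(base_intensity, n))
  islets <- data.frame(islet_id = sort(unique(islet_id)),
                       x_nm = as.numeric(tapply(x_nm, islet_id, mean)),
                       y_nm = as.numeric(tapply(y_nm, islet_id, mean)),
                       radius_nm = islet_radius_nm)
  structure(list(cores = cores, islets = islets,
                 field_size_nm = as.numeric(field_size_nm),
                 params = layout_params(seed = 0L)),
            class = "sz_layout")
}

#' @export
print.sz_layout <- function(x, ...) {
  cat(sprintf("sz_layout: %d cores in %d islets on a %.3g x %.3g um field\n",
              nrow(x$cores), nrow(x$islets),
              x$field_size_nm[1] / 1000, x$field_size_nm[2] / 1000))
  invisible(x)
}

#' Noise model for rendered frames
#'
#' Poisson shot noise (applied to the noiseless expectation) plus additive
#' Gaussian read noise. With the default core amplitude of 100 and
#' \code{read_sd = 20} the peak signal-to-noise ratio is approximately 5.
#'
#' @param poisson apply Poisson shot noise to the expected image.
#' @param read_sd standard deviation of additive Gaussian read noise
#'   (intensity units); 0 disables.
#' @export
noise_model <- function(poisson = TRUE, read_sd = 20) {
  structure(list(poisson = poisson, read_sd = read_sd), class = "noise_model")
}

#' Marker geometry for a simulated protein channel
#'
#' @param name protein name.
#' @param lateral_model one of \code{"core_centered"} (cloud around cores),
#'   \code{"ring_at_offset_nm"} (annulus around cores) or
#'   \code{"islet_border"} (annulus around islet centers).
#' @param offset_nm ring radius for \code{ring_at_offset_nm} (nm).
#' @param lateral_sd_nm lateral scatter (cloud sd, or ring/border thickness).
#' @param axial_mean_nm mean height above the substrate (nm, >= 0).
#' @param axial_slope_nm_per_um height change per micrometre toward the cell
#'   interior (negative = declines interior-ward).
#' @param localization_precision_nm localization precision (nm, > 0).
#' @export
protein_spec <- function(name, lateral_model = c("core_centered", "ring_at_offset_nm", "islet_border"),
                         offset_nm = 300, lateral_sd_nm = 150,
                         axial_mean_nm = 100, axial_slope_nm_per_um = 0,
                         localization_precision_nm = 15) {
  lateral_model <- match.arg(lateral_model)
  if (localization_precision_nm <= 0) stop("protein_spec: precision must be > 0")
  if (axial_mean_nm < 0) stop("protein_spec: axial_mean_nm must be >= 0")
  structure(list(name = name, lateral_model = lateral_model, offset_nm = offset_nm,
                 lateral_sd_nm = lateral_sd_nm, axial_mean_nm = axial_mean_nm,
                 axial_slope_nm_per_um = axial_slope_nm_per_um,
                 localization_precision_nm = localization_precision_nm),
            class = "protein_spec")
}

#' Render a single frame from a ground-truth layout
#'
#' The actin channel is a sum of isotropic Gaussian spots on a diffuse
#' background. Each spot's sigma equals the core's nominal radius, so that
#' the inflection ring of the spot -- the first maximum of the
#' gradient-magnitude radial profile -- sits exactly at the nominal radius;
#' this makes the generator and the derivative-profile radius estimator
#' mutually consistent. Marker channels are rendered as Gaussian-profile
#' annuli around cores or islet centers according to the
#' \code{\link{protein_spec}} lateral model.
#'
#' @param layout an \code{sz_layout}.
#' @param channel \code{"actin"} or a \code{\link{protein_spec}}.
#' @param pixel_size_nm pixel size (nm); default 32.25.
#' @param psf_sigma_nm additional optical blur added in quadrature to the
#'   spot sigma (nm); 0 for none.
#' @param noise a \code{\link{noise_model}}, or \code{NULL} for noiseless.
#' @param background diffuse background level (intensity units).
#' @return an \code{\link{image2d}}.
#' @export
render_frame <- function(layout, channel = "actin", pixel_size_nm = 32.25,
                         psf_sigma_nm = 0, noise = noise_model(), background = 120) {
  stopifnot(inherits(layout, "sz_layout"))
  W <- ceiling(layout$field_size_nm[1] / pixel_size_nm)
  H <- ceiling(layout$field_size_nm[2] / pixel_size_nm)
  img <- matrix(background, H, W)
  cs <- layout$cores
  if (nrow(cs) > 0) {
    bad <- cs$x_nm < 0 | cs$x_nm > layout$field_size_nm[1] |
           cs$y_nm < 0 | cs$y_nm > layout$field_size_nm[2]
    if (any(bad))
      stop("render_frame: core(s) ", paste(cs$core_id[bad], collapse = ", "),
           " outside the field")
  }
  if (identical(channel, "actin")) {
    for (k in seq_len(nrow(cs))) {
      sig <- sqrt(cs$radius_nm[k]^2 + psf_sigma_nm^2) / pixel_size_nm
      img <- .add_gaussian_spot(img, nm_to_px(cs$x_nm[k], pixel_size_nm),
                                nm_to_px(cs$y_nm[k], pixel_size_nm),
                                sig, cs$base_intensity[k])
    }
  } else if (inherits(channel, "protein_spec")) {
    amp <- layout$params$base_intensity_mean
    w_px <- max(channel$lateral_sd_nm, 1) / pixel_size_nm
    if (channel$lateral_model == "islet_border") {
      for (k in seq_len(nrow(layout$islets))) {
        img <- .add_annulus(img, nm_to_px(layout$islets$x_nm[k], pixel_size_nm),
                            nm_to_px(layout$islets$y_nm[k], pixel_size_nm),
                            layout$islets$radius_nm[k] / pixel_size_nm, w_px, amp)
      }
    } else {
      r_ring <- if (channel$lateral_model == "ring_at_offset_nm")
        channel$offset_nm / pixel_size_nm else 0
      for (k in seq_len(nrow(cs))) {
        if (r_ring > 0) {
          img <- .add_annulus(img, nm_to_px(cs$x_nm[k], pixel_size_nm),
                              nm_to_px(cs$y_nm[k], pixel_size_nm), r_ring, w_px, amp)
        } else {
          img <- .add_gaussian_spot(img, nm_to_px(cs$x_nm[k], pixel_size_nm),
                                    nm_to_px(cs$y_nm[k], pixel_size_nm), w_px, amp)
        }
      }
    }
  } else stop("render_frame: channel must be 'actin' or a protein_spec")
  if (!is.null(noise)) {
    if (noise$poisson) img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                                     nrow(img), ncol(img))
    if (noise$read_sd > 0) img <- img + stats::rnorm(length(img), 0, noise$read_sd)
    img <- pmax(img, 0)
  }
  ch <- if (identical(channel, "actin")) "actin" else channel$name
  image2d(img, pixel_size_nm, ch)
}

# add A * exp(-d^2 / 2 sigma^2) centered at fractional pixel (cx, cy); separable
.add_gaussian_spot <- function(img, cx, cy, sigma_px, A) {
  r <- ceiling(4 * sigma_px)
  rows <- max(1, floor(cy - r)):min(nrow(img), ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(ncol(img), ceiling(cx + r))
  if (length(rows) == 0 || length(cols) == 0) return(img)
  gy <- exp(-(rows - cy)^2 / (2 * sigma_px^2))
  gx <- exp(-(cols - cx)^2 / (2 * sigma_px^2))
  img[rows, cols] <- img[rows, cols] + A * outer(gy, gx)
  img
}

# add A * exp(-(d - r0)^2 / 2 w^2): a Gaussian-profile ring
.add_annulus <- function(img, cx, cy, r0_px, w_px, A) {
  r <- ceiling(r0_px + 4 * w_px)
  rows <- max(1, floor(cy - r)):min(nrow(img), ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(ncol(img), ceiling(cx + r))
  if (length(rows) == 0 || length(cols) == 0) return(img)
  d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+"))
  img[rows, cols] <- img[rows, cols] + A * exp(-(d - r0_px)^2 / (2 * w_px^2))
  img
}

#' Oscillation specification for simulated movies
#'
#' Per-core intensity follows
#' \code{I_i(t) = base_i * (1 + sum_k a_k sin(2 pi f_k t + phi))} plus
#' multiplicative Gaussian noise, with phases shared per islet, independent
#' per core, or global, mirroring locally synchronized actin oscillations.
#' Default frequencies are the three periodicities seen in sealing-zone
#' actin (0.01, 0.04, 0.15 Hz) and the default cadence is 2.4 s over 160 s.
#'
#' @param components data.frame with columns \code{frequency_hz},
#'   \code{amplitude} (fraction of baseline, in [0, 1)).
#' @param phase_model \code{"islet_shared"}, \code{"independent"} or
#'   \code{"global"}.
#' @param noise_sd_fraction sd of per-timepoint multiplicative noise as a
#'   fraction of baseline.
#' @param dt_s frame interval (s).
#' @param n_frames number of frames (>= 2).
#' @export
osc_spec <- function(components = data.frame(frequency_hz = c(0.01, 0.04, 0.15),
                                             amplitude = c(0.30, 0.20, 0.10)),
                     phase_model = c("islet_shared", "independent", "global"),
                     noise_sd_fraction = 0.05, dt_s = 2.4, n_frames = 67) {
  phase_model <- match.arg(phase_model)
  stopifnot(n_frames >= 2, dt_s > 0)
  if (any(components$amplitude < 0 | components$amplitude >= 1))
    stop("osc_spec: amplitude fractions must be in [0, 1)")
  if (any(components$frequency_hz >= 1 / (2 * dt_s)))
    stop("osc_spec: frequencies must be below Nyquist = 1/(2 dt)")
  structure(list(components = components, phase_model = phase_model,
                 noise_sd_fraction = noise_sd_fraction, dt_s = dt_s,
                 n_frames = as.integer(n_frames)),
            class = "osc_spec")
}

#' Simulate an oscillating sealing-zone movie
#'
#' Renders one frame per time point with per-core amplitudes following the
#' oscillation model; negative intensities are clamped to zero and flagged.
#' The exact noiseless per-core signals are returned as ground truth.
#'
#' @param layout an \code{sz_layout}.
#' @param osc an \code{\link{osc_spec}}.
#' @param pixel_size_nm,psf_sigma_nm,noise,background passed to
#'   \code{\link{render_frame}}.
#' @param seed integer seed for phases and noise.
#' @return list with \code{stack} (an \code{\link{image_stack}}) and
#'   \code{truth}: list of \code{signals} (cores x T noiseless matrix),
#'   \code{phases}, \code{clamped} flag matrix, \code{time_s}, and the core
#'   table.
#' @export
simulate_movie <- function(layout, osc = osc_spec(), pixel_size_nm = 32.25,
                           psf_sigma_nm = 0, noise = noise_model(),
                           background = 120, seed = 1L) {
  stopifnot(inherits(layout, "sz_layout"), inherits(osc, "osc_spec"))
  set.seed(seed)
  cs <- layout$cores
  n <- nrow(cs); Tn <- osc$n_frames
  tt <- (seq_len(Tn) - 1) * osc$dt_s
  nk <- nrow(osc$components)
  grp <- switch(osc$phase_model,
                islet_shared = cs$islet_id,
                independent  = seq_len(n),
                global       = rep(1L, n))
  ngrp <- if (n > 0) max(grp) else 0L
  phases <- matrix(stats::runif(ngrp * nk, 0, 2 * pi), ngrp, nk)
  truth <- matrix(0, n, Tn)
  for (i in seq_len(n)) {
    mod <- rep(1, Tn)
    for (k in seq_len(nk))
      mod <- mod + osc$components$amplitude[k] *
        sin(2 * pi * osc$components$frequency_hz[k] * tt + phases[grp[i], k])
    truth[i, ] <- cs$base_intensity[i] * mod
  }
  clamped <- truth < 0
  truth[clamped] <- 0
  noisy <- truth
  if (osc$noise_sd_fraction > 0 && n > 0)
    noisy <- pmax(truth + matrix(stats::rnorm(n * Tn, 0,
                    osc$noise_sd_fraction * cs$base_intensity), n, Tn), 0)
  W <- ceiling(layout$field_size_nm[1] / pixel_size_nm)
  H <- ceiling(layout$field_size_nm[2] / pixel_size_nm)
  frames <- array(0, dim = c(H, W, Tn))
  lay_t <- layout
  for (t in seq_len(Tn)) {
    lay_t$cores$base_intensity <- if (n > 0) noisy[, t] else numeric(0)
    frames[, , t] <- render_frame(lay_t, "actin", pixel_size_nm, psf_sigma_nm,
                                  noise, background)$pixels
  }
  list(stack = image_stack(frames, pixel_size_nm, osc$dt_s),
       truth = list(signals = truth, phases = phases, clamped = clamped,
                    time_s = tt, cores = cs, phase_model = osc$phase_model))
}

#' Belt geometry: axis angle and interior side
#'
#' Describes the local orientation of the podosome belt / sealing zone for
#' one cell or ROI: the belt axis angle to the horizontal, and the unit
#' normal pointing toward the cell interior.
#'
#' @param angle_deg belt axis angle to the horizontal, degrees.
#' @param interior_side \code{+1} or \code{-1}: which normal
#'   (\code{s * (-sin a, cos a)}) points toward the cell interior.
#' @param cell cell/ROI identifier.
#' @return a \code{belt_geometry} with unit axis \code{u} and unit interior
#'   normal \code{normal}.
#' @export
belt_geometry <- function(angle_deg = 0, interior_side = 1, cell = "cell1") {
  stopifnot(interior_side %in% c(-1, 1))
  a <- angle_deg * pi / 180
  structure(list(cell = as.character(cell), angle_deg = angle_deg,
                 u = c(cos(a), sin(a)),
                 normal = interior_side * c(-sin(a), cos(a))),
            class = "belt_geometry")
}

#' Simulate 3D single-molecule localizations around cores
#'
#' Lateral positions follow the protein's lateral model; the axial position
#' is Gaussian around \code{axial_mean_nm} plus a linear trend along the
#' interior normal (slope in nm per um of signed interior distance from the
#' parent core), blurred by the localization precision.
#'
#' @param layout an \code{sz_layout} (must contain at least one core).
#' @param protein a \code{\link{protein_spec}}.
#' @param n_locs number of localizations (> 0).
#' @param belt_axis a \code{\link{belt_geometry}} giving the interior normal.
#' @param cell cell id stamped on the output.
#' @param seed integer seed.
#' @return a data.frame of class \code{loc_table} with columns
#'   \code{x_nm, y_nm, z_nm, protein, cell} plus ground-truth columns
#'   \code{true_core_id, true_d_interior_nm, true_z_mean_nm}.
#' @export
simulate_localizations <- function(layout, protein, n_locs, belt_axis = belt_geometry(),
                                   cell = "cell1", seed = 1L) {
  stopifnot(inherits(layout, "sz_layout"), inherits(protein, "protein_spec"),
            n_locs > 0)
  set.seed(seed)
  cs <- layout$cores
  if (nrow(cs) == 0) stop("simulate_localizations: layout has no cores")
  if (protein$lateral_model == "islet_border") {
    k <- sample.int(nrow(layout$islets), n_locs, replace = TRUE)
    ang <- stats::runif(n_locs, 0, 2 * pi)
    rad <- layout$islets$radius_nm[k] + stats::rnorm(n_locs, 0, protein$lateral_sd_nm)
    x <- layout$islets$x_nm[k] + rad * cos(ang)
    y <- layout$islets$y_nm[k] + rad * sin(ang)
    # attribute each localization to the nearest core for ground truth
    nn <- apply(cbind(x, y), 1, function(p)
      which.min((cs$x_nm - p[1])^2 + (cs$y_nm - p[2])^2))
    core_id <- cs$core_id[nn]
    refx <- cs$x_nm[nn]; refy <- cs$y_nm[nn]
  } else {
    k <- sample.int(nrow(cs), n_locs, replace = TRUE)
    if (protein$lateral_model == "ring_at_offset_nm") {
      ang <- stats::runif(n_locs, 0, 2 * pi)
      rad <- protein$offset_nm + stats::rnorm(n_locs, 0, protein$lateral_sd_nm)
      x <- cs$x_nm[k] + rad * cos(ang)
      y <- cs$y_nm[k] + rad * sin(ang)
    } else {
      x <- cs$x_nm[k] + stats::rnorm(n_locs, 0, protein$lateral_sd_nm)
      y <- cs$y_nm[k] + stats::rnorm(n_locs, 0, protein$lateral_sd_nm)
    }
    core_id <- cs$core_id[k]
    refx <- cs$x_nm[k]; refy <- cs$y_nm[k]
  }
  d_int <- (x - refx) * belt_axis$normal[1] + (y - refy) * belt_axis$normal[2]
  z_mean <- protein$axial_mean_nm + protein$axial_slope_nm_per_um * d_int / 1000
  z <- stats::rnorm(n_locs, z_mean, protein$localization_precision_nm)
  out <- data.frame(x_nm = x, y_nm = y, z_nm = z,
                    protein = protein$name, cell = as.character(cell),
                    true_core_id = core_id, true_d_interior_nm = d_int,
                    true_z_mean_nm = z_mean)
  class(out) <- c("loc_table", "data.frame")
  out
}

#' Write / read a ground-truth layout manifest
#'
#' Writes \code{cores.csv}, \code{islets.csv} and \code{manifest.json}
#' (parameters + seed) into \code{dir}; \code{read_layout()} reconstructs an
#' identical layout object.
#'
#' @param layout an \code{sz_layout}.
#' @param dir output directory (created if missing).
#' @export
write_layout <- function(layout, dir) {
  stopifnot(inherits(layout, "sz_layout"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(layout$cores, file.path(dir, "cores.csv"), row.names = FALSE)
  utils::write.csv(layout$islets, file.path(dir, "islets.csv"), row.names = FALSE)
  jsonlite::write_json(list(params = unclass(layout$params),
                            field_size_nm = layout$field_size_nm),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_layout
#' @export
read_layout <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  p <- man$params
  params <- layout_params(p$field_size_nm, p$n_islets, p$islet_radius_nm,
                          p$cores_per_islet_mean, p$hard_core_nm,
                          p$core_radius_nm_mean, p$core_radius_nm_sd,
                          p$base_intensity_mean, p$base_intensity_sd, p$seed)
  structure(list(cores = utils::read.csv(file.path(dir, "cores.csv")),
                 islets = utils::read.csv(file.path(dir, "islets.csv")),
                 field_size_nm = man$field_size_nm, params = params),
            class = "sz_layout")
}
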