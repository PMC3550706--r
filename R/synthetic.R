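#' Specification of a synthetic polar IVOCT phantom
#'
#' Describes a pullback of speckled, exponentially attenuating tissue in
#' polar coordinates with bright stent struts casting full-depth trailing
#' shadows, an optional guide wire with a continuous frame-to-frame
#' position, constant catheter ring artifact columns, and non-stented
#' margin frames. Geometry defaults to a desk-scale 128 x 256 frame
#' (scaled down from clinical 504 x 960 frames) so whole-pullback runs
#' stay fast; use [scale_parameters()] for matching detection thresholds.
#'
#' @param n_frames,n_alines,n_depth Pullback geometry.
#' @param lumen_radius Mean lumen radius in depth pixels.
#' @param lumen_eccentricity Amplitude of the sinusoidal lumen modulation
#'   (an eccentric lumen), in pixels.
#' @param lumen_phase Phase of the modulation in radians.
#' @param lumen_phase_drift Phase change per frame in radians: the
#'   eccentric lumen rotates along the pullback, as vessel geometry and
#'   catheter position change along a real artery. Without it every frame
#'   is geometrically identical and the strut closest to the catheter
#'   mimics a guide wire's continuity.
#' @param tissue_peak Tissue intensity at the lumen boundary before
#'   speckle.
#' @param attenuation Exponential intensity decay per depth pixel beyond
#'   the lumen.
#' @param speckle_cv Coefficient of variation of the multiplicative gamma
#'   speckle on tissue and shadows.
#' @param strut_speckle_cv Speckle CV on strut blobs (struts are specular
#'   reflectors; their speckle is weaker).
#' @param strut_taper Fractional intensity drop per depth pixel inside a
#'   strut blob, putting the blob maximum on its front edge.
#' @param strut_thickness Strut depth extent in pixels.
#' @param shadow_floor Mean intensity inside trailing shadows before
#'   speckle.
#' @param strut_layout `data.frame` with columns `frame_start`,
#'   `frame_end`, `aline`, `depth_offset` (front-edge depth relative to the
#'   lumen boundary at that A-line), `status` (`apposed`, `malapposed`,
#'   `covered` or `non_bright`), `brightness`, `width_alines`. `NULL`
#'   builds a default layout via [default_strut_layout()].
#' @param guide_wire `NULL`, or a list with `aline` (center row), `depth`
#'   (front-edge depth), `brightness`, `width_alines` and either
#'   `drift_per_frame` (linear row drift) or `amplitude` + `period`
#'   (sinusoidal row oscillation).
#' @param catheter_artifact_columns Depth columns holding constant bright
#'   vertical artifact lines.
#' @param catheter_artifact_intensity Intensity of those lines.
#' @param non_stented_margins Two counts of strut-free frames at the
#'   proximal/distal pullback ends (informational; the default layout
#'   respects them).
#' @param noise_level Maximum of the uniform background noise.
#' @param seed RNG seed making generation deterministic.
#' @param allow_overlap Permit struts/guide wire sharing A-lines in one
#'   frame (otherwise an error, as the detector assumes a single strut per
#'   A-line).
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(n_frames = 64, n_alines = 128, n_depth = 256,
                         lumen_radius = 60, lumen_eccentricity = 10,
                         lumen_phase = 0, lumen_phase_drift = 2 * pi / 32,
                         tissue_peak = 2500, attenuation = 0.005,
                         speckle_cv = 0.12, strut_speckle_cv = 0.08,
                         strut_taper = 0.1, strut_thickness = 4,
                         shadow_floor = 80,
                         strut_layout = NULL,
                         guide_wire = NULL,
                         catheter_artifact_columns = 4:8,
                         catheter_artifact_intensity = 3000,
                         non_stented_margins = c(0, 0),
                         noise_level = 40,
                         seed = 42,
                         allow_overlap = FALSE) {
  if (is.null(strut_layout)) {
    strut_layout <- default_strut_layout(
      n_struts = 8, n_alines = n_alines,
      frame_start = non_stented_margins[1] + 1L,
      frame_end = n_frames - non_stented_margins[2])
  }
  spec <- list(n_frames = n_frames, n_alines = n_alines, n_depth = n_depth,
               lumen_radius = lumen_radius,
               lumen_eccentricity = lumen_eccentricity,
               lumen_phase = lumen_phase,
               lumen_phase_drift = lumen_phase_drift,
               tissue_peak = tissue_peak, attenuation = attenuation,
               speckle_cv = speckle_cv, strut_speckle_cv = strut_speckle_cv,
               strut_taper = strut_taper, strut_thickness = strut_thickness,
               shadow_floor = shadow_floor,
               strut_layout = strut_layout, guide_wire = guide_wire,
               catheter_artifact_columns = catheter_artifact_columns,
               catheter_artifact_intensity = catheter_artifact_intensity,
               non_stented_margins = non_stented_margins,
               noise_level = noise_level, seed = seed,
               allow_overlap = allow_overlap)
  class(spec) <- "phantom_spec"
  spec
}

#' Default strut layout for a phantom
#'
#' Places `n_struts` struts at evenly spaced A-lines, all present over the
#' same frame range. Status determines the depth offset of the strut front
#' edge relative to the lumen boundary and a typical brightness:
#' `apposed` sits on the lumen (offset 0, 20000), `malapposed` floats in
#' the lumen (-25, 20000), `covered` lies under a neointimal tissue layer
#' (+12, 15000) and `non_bright` is deep and dim (+80, 2800), detectable
#' only through its shadow.
#'
#' @param n_struts Number of struts per frame.
#' @param n_alines Number of A-lines per frame.
#' @param frame_start,frame_end Frame range the struts occupy.
#' @param status Status per strut (recycled).
#' @param brightness Optional brightness per strut (recycled); `NULL`
#'   picks the status default.
#' @param width_alines Angular strut width (recycled).
#' @return A strut layout `data.frame` (see [phantom_spec()]).
#' @export
default_strut_layout <- function(n_struts, n_alines, frame_start, frame_end,
                                 status = "apposed", brightness = NULL,
                                 width_alines = 5) {
  offs <- c(apposed = 0, malapposed = -25, covered = 12, non_bright = 80)
  bright <- c(apposed = 20000, malapposed = 20000, covered = 15000,
              non_bright = 2800)
  if (n_struts == 0L) {
    return(data.frame(frame_start = integer(0), frame_end = integer(0),
                      aline = integer(0), depth_offset = numeric(0),
                      status = character(0), brightness = numeric(0),
                      width_alines = integer(0), stringsAsFactors = FALSE))
  }
  status <- rep_len(status, n_struts)
  bad <- setdiff(status, names(offs))
  if (length(bad)) stop("unknown strut status: ", paste(bad, collapse = ", "))
  if (is.null(brightness)) brightness <- unname(bright[status])
  data.frame(
    frame_start = frame_start, frame_end = frame_end,
    aline = round((seq_len(n_struts) - 0.5) * n_alines / n_struts),
    depth_offset = unname(offs[status]),
    status = status,
    brightness = rep_len(brightness, n_struts),
    width_alines = rep_len(width_alines, n_struts),
    stringsAsFactors = FALSE)
}

# multiplicative gamma speckle with unit mean and given CV
speckle <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  k <- 1 / cv^2
  stats::rgamma(n, shape = k, rate = k)
}

gw_center_row <- function(gw, f, n_alines) {
  a <- if (!is.null(gw$period)) {
    gw$aline + gw$amplitude * sin(2 * pi * (f - 1) / gw$period)
  } else {
    gw$aline + (if (is.null(gw$drift_per_frame)) 0 else gw$drift_per_frame) * (f - 1)
  }
  ((round(a) - 1) %% n_alines) + 1
}

band_rows <- function(center, width, n_alines) {
  h <- floor((width - 1) / 2)
  ((center - 1 + (-h:(width - 1 - h))) %% n_alines) + 1
}

#' Generate a phantom pullback with ground truth
#'
#' Renders the pullback described by a [phantom_spec()]: attenuating
#' speckled tissue beyond an eccentric lumen, bright strut blobs with
#' trailing shadows reaching the far depth edge, covered struts under a
#' tissue layer, malapposed struts floating in the lumen, an optional
#' continuously moving guide wire, constant catheter artifact columns and
#' uniform background noise. Generation is deterministic for a fixed spec
#' (including its seed).
#'
#' @param spec A `"phantom_spec"`.
#' @return A list with `pullback` (an `"oct_pullback"`), `truth` (strut
#'   record `data.frame` with an extra `status` column, one row per strut
#'   per frame giving the front-edge position) and `guide_wire_truth`
#'   (`data.frame` or `NULL`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n_a <- spec$n_alines; n_d <- spec$n_depth
  layout <- spec$strut_layout
  th <- spec$strut_thickness
  depth_grid <- outer(rep(1, n_a), seq_len(n_d))

  frames <- vector("list", spec$n_frames)
  truth <- list(); gw_truth <- list()
  for (f in seq_len(spec$n_frames)) {
    phase <- spec$lumen_phase + spec$lumen_phase_drift * (f - 1)
    lumen <- round(spec$lumen_radius + spec$lumen_eccentricity *
                     sin(2 * pi * seq_len(n_a) / n_a + phase))
    lumen <- pmax(2L, pmin(as.integer(lumen), n_d - 1L))
    depth_rel <- depth_grid - matrix(lumen, n_a, n_d)  # depth beyond lumen
    tissue_mask <- depth_rel >= 0
    decay <- spec$tissue_peak * exp(-spec$attenuation * pmax(depth_rel, 0))
    active <- which(layout$frame_start <= f & f <= layout$frame_end)
    # the detector assumes one strut per A-line: reject overlapping bands
    bands <- lapply(active, function(i)
      band_rows(layout$aline[i], layout$width_alines[i], n_a))
    if (!is.null(spec$guide_wire)) {
      gw <- spec$guide_wire
      bands <- c(bands, list(band_rows(gw_center_row(gw, f, n_a),
                                       gw$width_alines, n_a)))
    }
    all_rows <- unlist(bands)
    if (!spec$allow_overlap && anyDuplicated(all_rows))
      stop(sprintf("frame %d: struts/guide wire share A-lines; %s", f,
                   "set allow_overlap = TRUE to permit this"))

    M <- matrix(stats::runif(n_a * n_d, 0, spec$noise_level), n_a, n_d)
    sp <- matrix(speckle(n_a * n_d, spec$speckle_cv), n_a, n_d)
    M[tissue_mask] <- decay[tissue_mask] * sp[tissue_mask]

    paint_reflector <- function(M, rows, front, brightness, speckle_cv) {
      back <- min(front + th - 1L, n_d)
      cols <- front:back
      blob <- brightness * (1 - spec$strut_taper)^(seq_along(cols) - 1)
      for (a in rows) {
        M[a, cols] <- blob * speckle(length(cols), speckle_cv)
        if (back < n_d) {
          sh <- (back + 1L):n_d
          M[a, sh] <- spec$shadow_floor * speckle(length(sh), spec$speckle_cv)
        }
      }
      M
    }

    for (i in active) {
      front <- lumen[layout$aline[i]] + layout$depth_offset[i]
      front <- max(2L, min(as.integer(front), n_d - th))
      M <- paint_reflector(M, band_rows(layout$aline[i],
                                        layout$width_alines[i], n_a),
                           front, layout$brightness[i], spec$strut_speckle_cv)
      truth[[length(truth) + 1L]] <- data.frame(
        frame = f, aline = layout$aline[i], depth = front,
        status = layout$status[i], stringsAsFactors = FALSE)
    }
    if (!is.null(spec$guide_wire)) {
      gw <- spec$guide_wire
      gwc <- gw_center_row(gw, f, n_a)
      M <- paint_reflector(M, band_rows(gwc, gw$width_alines, n_a),
                           as.integer(gw$depth), gw$brightness,
                           spec$strut_speckle_cv)
      gw_truth[[length(gw_truth) + 1L]] <- data.frame(
        frame = f, aline = gwc, depth = as.integer(gw$depth))
    }
    if (length(spec$catheter_artifact_columns))
      M[, spec$catheter_artifact_columns] <- spec$catheter_artifact_intensity
    frames[[f]] <- matrix(as.integer(pmin(pmax(round(M), 0), 65535)), n_a, n_d)
  }

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(frame = integer(0), aline = integer(0), depth = integer(0),
               status = character(0), stringsAsFactors = FALSE)
  list(pullback = oct_pullback(frames),
       truth = truth_df,
       guide_wire_truth = if (length(gw_truth)) do.call(rbind, gw_truth) else NULL)
}

#' Canned phantom scenarios
#'
#' A named list of `"phantom_spec"`s spanning the situations the detector
#' must cope with: high-quality apposed struts, covered struts, malapposed
#' struts, a low-quality pullback (3x the speckle, half the strut
#' brightness), a pullback containing non-bright struts, and matched
#' pullbacks with and without a guide wire plus strut-free margin frames.
#' Each element carries an `expects` attribute summarising the property it
#' is built to exercise.
#'
#' @param n_frames Frames per phantom.
#' @param seed Base RNG seed; each scenario derives its own offset seed.
#' @return Named list of `"phantom_spec"` objects.
#' @export
standard_phantom_suite <- function(n_frames = 64, seed = 42) {
  gw <- list(aline = 16, amplitude = 8, period = 32, depth = 25,
             brightness = 20000, width_alines = 5)
  # struts leave an angular corridor for the oscillating wire, so strut
  # shadows and the wire shadow never become adjacent
  gw_layout <- default_strut_layout(6, 128, 13, n_frames - 12)
  gw_layout$aline <- c(36L, 52L, 68L, 84L, 100L, 116L)
  suite <- list(
    high_quality = phantom_spec(n_frames = n_frames, seed = seed),
    covered = phantom_spec(
      n_frames = n_frames, seed = seed + 1,
      strut_layout = default_strut_layout(8, 128, 1, n_frames,
                                          status = "covered")),
    malapposed = phantom_spec(
      n_frames = n_frames, seed = seed + 2,
      strut_layout = default_strut_layout(8, 128, 1, n_frames,
                                          status = "malapposed")),
    low_quality = phantom_spec(
      n_frames = n_frames, seed = seed + 3,
      speckle_cv = 0.36, strut_speckle_cv = 0.2,
      strut_layout = default_strut_layout(8, 128, 1, n_frames,
                                          brightness = 10000)),
    non_bright = phantom_spec(
      n_frames = n_frames, seed = seed + 4,
      strut_layout = default_strut_layout(
        8, 128, 1, n_frames,
        status = c(rep("apposed", 6), rep("non_bright", 2)))),
    guide_wire = phantom_spec(
      n_frames = n_frames, seed = seed + 5, guide_wire = gw,
      strut_layout = gw_layout, non_stented_margins = c(12, 12)),
    no_guide_wire = phantom_spec(
      n_frames = n_frames, seed = seed + 5,
      strut_layout = gw_layout, non_stented_margins = c(12, 12))
  )
  attr(suite$high_quality, "expects") <-
    list(sensitivity_min = 0.9, fp_ratio_max = 0.1)
  attr(suite$low_quality, "expects") <-
    list(speckle_ratio_vs_high = 3)
  attr(suite$guide_wire, "expects") <-
    list(guide_wire_present = TRUE, margins = c(12, 12))
  attr(suite$no_guide_wire, "expects") <-
    list(guide_wire_present = FALSE, margins = c(12, 12))
  suite
}

#' Read a phantom spec from YAML
#'
#' Scalar fields map directly to [phantom_spec()] arguments; an optional
#' `struts` sequence (records with the [default_strut_layout()] columns)
#' becomes the strut layout and an optional `guide_wire` mapping is passed
#' through.
#'
#' @param path YAML file.
#' @return A `"phantom_spec"`.
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("struts"))]
  if (!is.null(y$struts)) {
    args$strut_layout <- do.call(rbind, lapply(y$struts, function(s)
      as.data.frame(s, stringsAsFactors = FALSE)))
  }
  do.call(phantom_spec, args)
}
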