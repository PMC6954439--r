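#' Specification of a synthetic mitochondrial scene
#'
#' Describes a MitoTracker-like scene: bright curvilinear tubes (filaments
#' and rods) rendered as constant-width capsules along curvature-bounded
#' random walks, small bright discs (puncta), larger discs (swollen), on a
#' smooth background with signal-scaled shot-like noise plus additive
#' readout noise. Planted geometry keeps a guard margin around the class
#' thresholds (11 µm extension, 0.6 µm radius) so discretization cannot
#' flip an object's ground-truth class.
#'
#' @param shape Image dimensions in pixels, \code{c(rows, cols)}.
#' @param pixel_size Pixel edge length in µm; the default 0.065 µm matches
#'   Nyquist-sampled high-NA confocal imaging.
#' @param counts Named integer vector of planted objects per class
#'   (\code{filament}, \code{rod}, \code{punctum}, \code{swollen}).
#' @param filament_length_um,rod_length_um Ranges (µm) of planted geodesic
#'   tube lengths; must sit outside the 11 µm threshold by the guard
#'   margin.
#' @param punctum_radius_um,swollen_radius_um Ranges (µm) of planted disc
#'   radii; must sit outside the 0.6 µm threshold by the guard margin.
#' @param tube_width_um Tube (and minimum structure) width in µm; 0.5 µm
#'   is a typical mitochondrial tubule diameter.
#' @param background,foreground Mean background and foreground intensity
#'   levels (arbitrary camera units).
#' @param shot_gain Scale of the signal-dependent noise term
#'   \code{shot_gain * sqrt(intensity)}.
#' @param add_noise_sd Standard deviation of the additive noise term.
#' @param spacing_um Minimum spacing between planted objects (µm); must
#'   exceed the tube width.
#' @param guard Fractional guard margin around class thresholds.
#' @param seed Integer seed; identical specs generate identical scenes.
#' @param max_attempts Placement attempts per object before failing.
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(shape = c(512L, 512L), pixel_size = 0.065,
                       counts = c(filament = 5L, rod = 8L, punctum = 8L,
                                  swollen = 4L),
                       filament_length_um = c(12.5, 18),
                       rod_length_um = c(2.5, 9.5),
                       punctum_radius_um = c(0.25, 0.40),
                       swollen_radius_um = c(0.7, 1.1),
                       tube_width_um = 0.5,
                       background = 100, foreground = 400,
                       shot_gain = 1, add_noise_sd = 2,
                       spacing_um = 1.2, guard = 0.1,
                       seed = 1L, max_attempts = 300L) {
  check_pixel_size(pixel_size)
  counts <- counts[MORPH_CLASSES]
  counts[is.na(counts)] <- 0L
  names(counts) <- MORPH_CLASSES
  if (any(counts < 0)) stop("object counts must be >= 0")
  e_thr <- 11; r_thr <- 0.6
  if (filament_length_um[1L] <= e_thr * (1 + guard))
    stop("filament lengths must exceed ", e_thr * (1 + guard),
         " um (threshold + guard margin)")
  if (rod_length_um[2L] >= e_thr * (1 - guard))
    stop("rod lengths must stay below ", e_thr * (1 - guard),
         " um (threshold - guard margin)")
  if (punctum_radius_um[2L] >= r_thr * (1 - guard))
    stop("punctum radii must stay below ", r_thr * (1 - guard), " um")
  if (swollen_radius_um[1L] <= r_thr * (1 + guard))
    stop("swollen radii must exceed ", r_thr * (1 + guard), " um")
  if (spacing_um <= tube_width_um)
    stop("`spacing_um` must exceed `tube_width_um`")
  if (foreground <= background)
    stop("`foreground` must exceed `background`")
  structure(list(shape = as.integer(shape), pixel_size = pixel_size,
                 counts = counts,
                 filament_length_um = filament_length_um,
                 rod_length_um = rod_length_um,
                 punctum_radius_um = punctum_radius_um,
                 swollen_radius_um = swollen_radius_um,
                 tube_width_um = tube_width_um,
                 background = background, foreground = foreground,
                 shot_gain = shot_gain, add_noise_sd = add_noise_sd,
                 spacing_um = spacing_um, guard = guard,
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "scene_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Straight tube (capsule) mask
#'
#' A constant-width tube whose centreline is a straight segment of the
#' given geodesic length: the union of discs of radius width/2 stamped
#' along the segment. Used for boundary sweeps and renderer validation.
#'
#' @param length_um Centreline (geodesic) length in µm.
#' @param width_um Tube width in µm.
#' @param pixel_size Pixel edge length in µm.
#' @param angle Orientation in radians.
#' @return Logical mask matrix.
#' @export
synth_tube_mask <- function(length_um, width_um, pixel_size, angle = 0) {
  L <- length_um / pixel_size
  w2 <- width_um / 2 / pixel_size
  t <- seq(0, L, by = 0.25)
  if (t[length(t)] < L) t <- c(t, L)
  path <- cbind(row = t * sin(angle), col = t * cos(angle))
  stamp_path_mask(path, w2)
}

#' Disc mask
#'
#' @param radius_um Disc radius in µm.
#' @param pixel_size Pixel edge length in µm.
#' @return Logical mask matrix (pixel centres within the radius).
#' @export
synth_disc_mask <- function(radius_um, pixel_size) {
  r <- radius_um / pixel_size
  n <- 2L * ceiling(r) + 3L
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  d2 <= r^2
}

# Rasterize a polyline path (in px, arbitrary origin) dilated by radius w2:
# a mask just covering the stamped capsule, plus the path in mask coords.
stamp_path_mask <- function(path, w2) {
  pad <- ceiling(w2) + 2L
  r0 <- floor(min(path[, 1L])) - pad; c0 <- floor(min(path[, 2L])) - pad
  nr <- ceiling(max(path[, 1L])) - r0 + pad + 1L
  nc <- ceiling(max(path[, 2L])) - c0 + pad + 1L
  prow <- path[, 1L] - r0; pcol <- path[, 2L] - c0
  mask <- matrix(FALSE, nr, nc)
  # distance from each pixel centre (in the path bbox neighbourhood) to the
  # nearest path sample; sampled densely enough (<= 0.25 px) that the
  # union-of-discs and the true capsule differ by well under half a pixel
  rows <- seq_len(nr); cols <- seq_len(nc)
  near <- ceiling(w2) + 1L
  for (k in seq_along(prow)) {
    rr <- max(1L, floor(prow[k]) - near):min(nr, ceiling(prow[k]) + near)
    cc <- max(1L, floor(pcol[k]) - near):min(nc, ceiling(pcol[k]) + near)
    d2 <- outer((rr - prow[k])^2, (cc - pcol[k])^2, `+`)
    mask[rr, cc] <- mask[rr, cc] | (d2 <= w2^2)
  }
  attr(mask, "path") <- cbind(row = prow, col = pcol)
  mask
}

# Length of a continuous path measured in the discrete 8-connected metric
# the skeleton geodesic uses (axial steps 1, diagonal steps sqrt(2)): the
# grid geodesic (octagonal) distance between pixels is
# max(|dr|,|dc|) + (sqrt(2)-1) * min(|dr|,|dc|), summed over coarse samples
# of the centreline so local rasterization detours do not inflate it.
digital_path_length <- function(path, sample_px = 5) {
  d <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (total <= 0) return(0)
  at <- unique(c(seq(0, total, by = sample_px), total))
  pts <- round(cbind(stats::approx(s, path[, 1L], xout = at)$y,
                     stats::approx(s, path[, 2L], xout = at)$y))
  dd <- abs(diff(pts))
  sum(pmax(dd[, 1L], dd[, 2L]) + (sqrt(2) - 1) * pmin(dd[, 1L], dd[, 2L]))
}

# Curvature-bounded random-walk centreline of given geodesic length (px):
# a few circular-arc segments with small constant turn rates, so the
# centreline is smooth at the pixel scale and the rendered tube's skeleton
# follows it faithfully (white-noise headings would add pixel-scale jitter
# that thinning cannot reproduce).
random_tube_path <- function(length_px, max_turn = 0.01, step = 1) {
  n <- max(2L, ceiling(length_px / step) + 1L)
  n_seg <- 3L
  seg <- sort(c(0L, sample.int(n - 2L, n_seg - 1L), n - 1L))
  turns <- unlist(lapply(seq_len(n_seg), function(k)
    rep(stats::runif(1L, -max_turn, max_turn), seg[k + 1L] - seg[k])))
  theta <- stats::runif(1L, 0, 2 * pi) + cumsum(c(0, turns[-(n - 1L)]))
  steps <- cbind(sin(theta), cos(theta)) * step
  # trim to exact geodesic length
  lens <- c(0, cumsum(sqrt(rowSums(steps^2))))
  keep <- lens <= length_px
  pts <- rbind(c(0, 0), apply(steps, 2L, cumsum))[keep, , drop = FALSE]
  short <- length_px - lens[sum(keep)]
  if (short > 1e-9) {
    dir <- c(sin(theta[sum(keep)]), cos(theta[sum(keep)]))
    pts <- rbind(pts, pts[nrow(pts), ] + dir * short)
  }
  colnames(pts) <- c("row", "col")
  pts
}

# TRUE if non-adjacent path samples come closer than `clearance` px
# (self-overlapping tube => skeleton geodesic would not match the path).
path_self_intersects <- function(path, clearance, step = 1) {
  n <- nrow(path)
  if (n < 10L) return(FALSE)
  gap <- ceiling(2 * clearance / step) + 2L
  d <- as.matrix(stats::dist(path))
  near <- d < clearance
  near[abs(row(near) - col(near)) <= gap] <- FALSE
  any(near)
}

#' Generate a synthetic calibrated scene with ground truth
#'
#' Places the requested objects by rejection sampling with a minimum
#' spacing, renders them at the foreground level on a flat background,
#' applies the noise model, and returns a single-frame
#' \code{\link{image_stack}}, a \code{\link{cell_region}} covering the
#' whole scene, and the ground truth (one record per planted object plus
#' the planted label mask). Identical specs (same seed) produce
#' bit-identical output.
#'
#' @param spec A \code{\link{scene_spec}}.
#' @return A list with elements \code{stack}, \code{region}, \code{truth}
#'   (data frame: id, class, length_um, radius_um, area_um2),
#'   \code{truth_labels} (integer matrix of planted object labels) and
#'   \code{clean_mask} (noise-free foreground mask).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    ps <- spec$pixel_size
    nr <- spec$shape[1L]; nc <- spec$shape[2L]
    spacing_px <- spec$spacing_um / ps
    w2 <- spec$tube_width_um / 2 / ps
    occupied <- matrix(FALSE, nr, nc)
    labels <- matrix(0L, nr, nc)
    brush_sz <- 2L * ceiling(spacing_px) + 1L
    brush <- EBImage::makeBrush(brush_sz, shape = "disc")
    truth <- list()
    obj_id <- 0L
    plant <- function(class) {
      for (attempt in seq_len(spec$max_attempts)) {
        if (class %in% c("filament", "rod")) {
          rng <- if (class == "filament") spec$filament_length_um
                 else spec$rod_length_um
          len_um <- stats::runif(1L, rng[1L], rng[2L])
          path <- random_tube_path(len_um / ps)
          if (path_self_intersects(path, clearance = 2 * w2 + 2)) next
          m <- stamp_path_mask(path, w2)
          # ground-truth length in the same discrete metric the skeleton
          # geodesic is measured in; the continuous draw decides the class
          geom <- list(length_um = digital_path_length(path) * ps,
                       radius_um = NA_real_)
        } else {
          rng <- if (class == "punctum") spec$punctum_radius_um
                 else spec$swollen_radius_um
          rad_um <- stats::runif(1L, rng[1L], rng[2L])
          m <- synth_disc_mask(rad_um, ps)
          geom <- list(length_um = NA_real_, radius_um = rad_um)
        }
        mr <- nrow(m); mc <- ncol(m)
        if (mr > nr - 2L || mc > nc - 2L)
          stop("scene too small for a planted ", class)
        r0 <- sample.int(nr - mr - 1L, 1L)
        c0 <- sample.int(nc - mc - 1L, 1L)
        # spacing check: dilate the candidate by the minimum spacing in a
        # padded frame (so the dilation is not clipped at the bounding box)
        # and test it against the raw occupancy of earlier objects
        ext <- ceiling(spacing_px)
        mp <- matrix(FALSE, mr + 2L * ext, mc + 2L * ext)
        mp[(ext + 1L):(ext + mr), (ext + 1L):(ext + mc)] <- m
        dil <- t(EBImage::dilate(t(mp * 1), brush)) > 0
        wr <- (r0 + 1L - ext):(r0 + mr + ext)
        wc <- (c0 + 1L - ext):(c0 + mc + ext)
        inr <- wr >= 1L & wr <= nr; inc <- wc >= 1L & wc <= nc
        if (any(occupied[wr[inr], wc[inc]] & dil[inr, inc])) next
        rr <- (r0 + 1L):(r0 + mr); cc <- (c0 + 1L):(c0 + mc)
        occupied[rr, cc] <<- occupied[rr, cc] | m
        obj_id <<- obj_id + 1L
        sub <- labels[rr, cc]; sub[m] <- obj_id
        labels[rr, cc] <<- sub
        truth[[obj_id]] <<- data.frame(
          id = obj_id, class = class,
          length_um = geom$length_um, radius_um = geom$radius_um,
          area_um2 = sum(m) * ps^2,
          row0 = r0 + 1L, col0 = c0 + 1L,
          row1 = r0 + mr, col1 = c0 + mc)
        return(invisible(TRUE))
      }
      stop("could not place a ", class, " after ", spec$max_attempts,
           " attempts; relax counts, sizes or spacing")
    }
    # largest objects first so packing is feasible
    for (class in c("filament", "rod", "swollen", "punctum"))
      for (i in seq_len(spec$counts[[class]])) plant(class)
    clean <- labels > 0
    img <- matrix(spec$background, nr, nc)
    img[clean] <- spec$foreground
    noisy <- img + spec$shot_gain * sqrt(img) * stats::rnorm(nr * nc) +
      stats::rnorm(nr * nc, sd = spec$add_noise_sd)
    noisy <- pmax(noisy, 0)
    dim(noisy) <- c(nr, nc)
    list(
      stack = image_stack(list(noisy), ps, provenance = "synthetic scene"),
      region = cell_region(matrix(TRUE, nr, nc), cell_id = "scene"),
      truth = if (obj_id > 0L) do.call(rbind, truth) else
        data.frame(id = integer(), class = character(),
                   length_um = numeric(), radius_um = numeric(),
                   area_um2 = numeric(), row0 = integer(), col0 = integer(),
                   row1 = integer(), col1 = integer()),
      truth_labels = labels,
      clean_mask = clean
    )
  })
}

#' Write a synthetic scene to disk
#'
#' The image is stored as a 16-bit TIFF in camera counts (the file holds
#' counts / 65535, the convention for integer TIFFs); pixel size, the
#' intensity scale and the ground truth table go to a JSON sidecar; the
#' planted label mask goes to a second 16-bit TIFF. All files are plain
#' rasters/JSON readable by the pipeline.
#'
#' @param scene Output of \code{\link{generate_scene}}.
#' @param dir Output directory.
#' @param name Base name for the three files.
#' @return Named character vector of paths, invisibly.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(lapply(scene$stack$frames,
                         function(f) pmin(f / 65535, 1)),
                  img_path, bits.per.sample = 16L, reduce = FALSE)
  lab_path <- file.path(dir, paste0(name, "_truth_labels.tif"))
  tiff::writeTIFF(scene$truth_labels / 65535, lab_path,
                  bits.per.sample = 16L, reduce = FALSE)
  json_path <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(
    list(pixel_size_um = scene$stack$pixel_size, intensity_scale = 65535,
         truth = scene$truth),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, labels = lab_path, truth = json_path))
}

#' Compare detections with planted ground truth
#'
#' Matches each detected object to the planted object it overlaps most
#' (by pixel count); detections overlapping no planted object are false
#' positives, planted objects matched by no detection are misses. Reports
#' the class confusion matrix over matched objects and per-class recovery
#' (recall) rates.
#'
#' @param objects List of segmented objects (detections).
#' @param classes Character vector of predicted classes, parallel to
#'   \code{objects}.
#' @param truth Ground truth from \code{\link{generate_scene}} (needs
#'   \code{truth} and \code{truth_labels}), or an equivalent list.
#' @return A list with \code{confusion} (planted class x predicted class),
#'   \code{recall} (named per-class rates), \code{n_false_positive},
#'   \code{n_missed} and the per-detection \code{matches} data frame.
#' @export
evaluate_against_truth <- function(objects, classes, truth) {
  stopifnot(length(objects) == length(classes))
  lab <- truth$truth_labels
  tt <- truth$truth
  n_det <- length(objects)
  matches <- data.frame(detection = seq_len(n_det),
                        truth_id = rep(NA_integer_, n_det),
                        predicted = as.character(classes),
                        planted = rep(NA_character_, n_det),
                        overlap_px = rep(0L, n_det),
                        stringsAsFactors = FALSE)
  for (i in seq_along(objects)) {
    hits <- lab[objects[[i]]$coords]
    hits <- hits[hits > 0]
    if (length(hits) > 0L) {
      tb <- table(hits)
      best <- as.integer(names(tb)[which.max(tb)])
      matches$truth_id[i] <- best
      matches$planted[i] <- tt$class[tt$id == best]
      matches$overlap_px[i] <- max(tb)
    }
  }
  # if several detections map to one planted object, keep the largest overlap
  matched <- matches[!is.na(matches$truth_id), , drop = FALSE]
  if (nrow(matched) > 0L) {
    keep <- unlist(lapply(split(seq_len(nrow(matched)), matched$truth_id),
                          function(ix) ix[which.max(matched$overlap_px[ix])]))
    dup <- setdiff(seq_len(nrow(matched)), keep)
    if (length(dup) > 0L) {
      matches$truth_id[matches$detection %in% matched$detection[dup]] <- NA
      matched <- matched[keep, , drop = FALSE]
    }
  }
  confusion <- table(factor(matched$planted, levels = MORPH_CLASSES),
                     factor(matched$predicted, levels = MORPH_CLASSES))
  planted_n <- table(factor(tt$class, levels = MORPH_CLASSES))
  correct <- diag(confusion)
  recall <- as.numeric(ifelse(planted_n > 0,
                              correct / as.numeric(planted_n), NA_real_))
  names(recall) <- MORPH_CLASSES
  list(confusion = confusion, recall = recall,
       n_false_positive = sum(is.na(matches$truth_id)),
       n_missed = nrow(tt) - nrow(matched),
       matches = matches)
}
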