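#' Phantom radiograph specification
#'
#' Parameters of a synthetic long-bone radiograph: a bright diaphysis band on
#' a dark noisy background with a fracture discontinuity at a chosen axial
#' position. The phantom is deliberately minimal — enough structure for
#' detector smoke tests and saliency checks, with no claim of anatomical
#' fidelity.
#'
#' @param size Image size `c(height, width)` in pixels.
#' @param bone `"femur"`, `"leg"`, `"humerus"`, or `"forearm"` (sets the
#'   band width).
#' @param orientation `"low_y"` (proximal end at the top, default) or
#'   `"high_y"`.
#' @param position Fracture axial position as a fraction of bone length in
#'   \[0, 1\], measured from the top of the bone in image coordinates.
#' @param pattern Fracture pattern: `"transverse"`, `"oblique"`, `"spiral"`,
#'   `"comminuted"`, `"greenstick"`, or `"impacted"`.
#' @param noise Gaussian pixel-noise standard deviation.
#' @param seed Integer seed; a fixed seed gives a byte-identical image.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(size = c(128, 128),
                         bone = c("femur", "leg", "humerus", "forearm"),
                         orientation = c("low_y", "high_y"),
                         position = 0.5,
                         pattern = c("transverse", "oblique", "spiral",
                                     "comminuted", "greenstick", "impacted"),
                         noise = 0.03, seed = 1L) {
  bone <- match.arg(bone)
  orientation <- match.arg(orientation)
  pattern <- match.arg(pattern)
  if (!is.numeric(position) || position < 0 || position > 1)
    stop("fracture position must lie in [0, 1]", call. = FALSE)
  structure(list(size = size, bone = bone, orientation = orientation,
                 position = position, pattern = pattern, noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# band half-width as a fraction of image width, per bone group
.bone_halfwidth <- c(femur = 0.13, leg = 0.10, humerus = 0.10, forearm = 0.07)

#' Render a phantom radiograph
#'
#' Draws the diaphysis as a bright vertical band with smooth edges over a
#' dark noisy background, then carves the fracture at the requested axial
#' position: a dark gap for transverse/oblique/spiral patterns, a partial gap
#' for greenstick, a gap plus bright fragments for comminuted, and a
#' brightened overlap (no gap) for impacted fractures. The ground-truth box
#' tightly encloses the discontinuity, and the returned descriptor's
#' diaphyseal third is consistent with the axial position and orientation by
#' construction.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (numeric matrix in \[0, 1\]), `box`
#'   (`x_min, y_min, x_max, y_max`), `descriptor`
#'   (a [fracture_descriptor()]), and `bone_extent` (`y_start, y_end`).
#' @export
make_radiograph <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  with_seed(spec$seed, {
    cx <- w / 2 + runif(1, -w * 0.04, w * 0.04)
    bw <- .bone_halfwidth[[spec$bone]] * w
    y0 <- 0.08 * h; y1 <- 0.92 * h
    xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
    ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
    # smooth-edged band: intensity falls off over ~3 px at the cortex
    edge <- 1 / (1 + exp((abs(xs - cx) - bw) / 1.5))
    inbone <- edge * (ys >= y0) * (ys <= y1)
    img <- 0.12 + 0.55 * inbone
    # brighter cortex rims
    rim <- exp(-((abs(xs - cx) - bw) / 2)^2)
    img <- img + 0.12 * rim * (ys >= y0) * (ys <= y1)

    yc <- y0 + spec$position * (y1 - y0)
    gap <- max(4, 0.035 * h)
    mask <- switch(spec$pattern,
      transverse = abs(ys - yc) < gap / 2,
      oblique    = abs((ys - yc) - 0.5 * (xs - cx)) < gap / 2,
      spiral     = abs((ys - yc) - gap * sin((xs - cx) / bw * pi)) < gap / 2,
      comminuted = abs(ys - yc) < gap,
      greenstick = abs(ys - yc) < gap / 2 & xs >= cx,
      impacted   = abs(ys - yc) < gap)
    inband <- abs(xs - cx) < bw + 2
    if (spec$pattern == "impacted") {
      img[mask & inband] <- pmin(img[mask & inband] + 0.3, 1)
    } else {
      img[mask & inband] <- 0.16
      if (spec$pattern == "comminuted") {
        frag <- abs(ys - yc) < gap * 0.45 &
                abs(((xs - cx) %% (bw * 0.8)) - bw * 0.4) < bw * 0.18
        img[frag & inband] <- 0.55
      }
    }
    img <- img + rnorm(h * w, 0, spec$noise)
    img <- pmin(pmax(img, 0), 1)

    slant <- switch(spec$pattern, oblique = 0.5 * (bw + 2), spiral = gap, 0)
    half_h <- gap / 2 + 3 + slant
    if (spec$pattern %in% c("comminuted", "impacted")) half_h <- gap + 3
    x_lo <- if (spec$pattern == "greenstick") cx - 1 else cx - bw - 3
    box <- clip_box(c(x_lo, yc - half_h, cx + bw + 3, yc + half_h), w, h)

    third <- locate_third(box = c(0, yc - 1, 1, yc + 1),
                          bone_extent = c(y0, y1),
                          orientation = spec$orientation)
    d <- fracture_descriptor(bone = spec$bone, third = third,
                             impacted = spec$pattern == "impacted",
                             tags = spec$pattern)
    list(image = img, box = box, descriptor = d, bone_extent = c(y0, y1))
  })
}

# class -> admissible (bone, third, impacted) combinations under the rule
# engine, so sampled scenes can never contradict the recommender
.class_scenes <- list(
  I   = data.frame(bone = "femur", third = "proximal"),
  II  = data.frame(bone = c("femur", "leg", "humerus"), third = "mid"),
  III = data.frame(bone  = c("femur", "leg", "leg", "humerus", "humerus",
                             "forearm", "forearm", "forearm"),
                   third = c("distal", "proximal", "distal", "proximal",
                             "distal", "proximal", "mid", "distal")),
  IV  = expand.grid(bone = c("femur", "leg", "humerus", "forearm"),
                    third = c("proximal", "mid", "distal"),
                    stringsAsFactors = FALSE))

# axial-fraction sampling window per third (kept off the 1/3 boundaries)
.third_window <- list(proximal = c(0.05, 0.30), mid = c(0.36, 0.63),
                      distal = c(0.70, 0.95))

#' Largest-remainder apportionment
#'
#' Integer allocation of `n` items proportional to `weights`: floor
#' allocations topped up by largest fractional remainder (ties by index).
#'
#' @param n Total count.
#' @param weights Non-negative weights.
#' @return Integer vector summing to `n`.
#' @export
largest_remainder <- function(n, weights) {
  exact <- n * weights / sum(weights)
  base <- floor(exact)
  rem <- exact - base
  left <- n - sum(base)
  if (left > 0) {
    pr <- order(-rem, seq_along(rem))
    base[pr[seq_len(left)]] <- base[pr[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic fracture-detection dataset
#'
#' Renders phantom radiographs with ground-truth boxes and treatment-class
#' labels. Class labels are always derived from the sampled scene through the
#' rule engine ([recommend()]), so annotations and rules are consistent by
#' construction. The default class mix follows the clinical cohort totals
#' 522 : 1,004 : 1,485 : 1,004 (classes I-IV), under which class I is about
#' 13% of the data.
#'
#' @param n Total number of images.
#' @param mix Per-class weights for classes I-IV; default the cohort totals.
#' @param sites Character vector of acquisition-site labels cycled over
#'   images.
#' @param seed Integer seed; generation is fully reproducible.
#' @param dir Optional output directory; when given, PNG images, a
#'   COCO-style `annotations.json` and an `index.csv`
#'   (image_path, class_label, site_label) are written there.
#' @param image_size Image size `c(h, w)`.
#' @param noise Pixel-noise standard deviation passed to the phantoms.
#' @return A `synthetic_dataset` list: `images` (list of matrices),
#'   `annotations` (data frame: image_id, x_min, y_min, x_max, y_max, label,
#'   class), `index` (data frame), `descriptors` (list), `specs` (list).
#' @export
make_dataset <- function(n = 60,
                         mix = c(I = 522, II = 1004, III = 1485, IV = 1004),
                         sites = c("siteA", "siteB"),
                         seed = 1L, dir = NULL,
                         image_size = c(128, 128), noise = 0.03) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  counts <- largest_remainder(n, mix)
  classes <- rep(names(.class_scenes), counts)
  specs <- vector("list", n)
  with_seed(seed, {
    img_seeds <- sample.int(2^31 - 1, n)
    ord <- sample.int(n)           # interleave classes
    classes <- classes[ord]
    for (i in seq_len(n)) {
      cl <- classes[i]
      sc <- .class_scenes[[cl]]
      row <- sc[sample.int(nrow(sc), 1), ]
      win <- .third_window[[row$third]]
      pat <- if (cl == "IV") "impacted" else
        sample(c("transverse", "oblique", "spiral", "comminuted",
                 "greenstick"), 1)
      specs[[i]] <- phantom_spec(size = image_size, bone = row$bone,
                                 position = runif(1, win[1], win[2]),
                                 pattern = pat, noise = noise,
                                 seed = img_seeds[i])
    }
  })
  images <- vector("list", n)
  descriptors <- vector("list", n)
  ann <- vector("list", n)
  for (i in seq_len(n)) {
    r <- make_radiograph(specs[[i]])
    images[[i]] <- r$image
    descriptors[[i]] <- r$descriptor
    rec <- recommend(r$descriptor)
    stopifnot(rec$treatment_class == classes[i])
    ann[[i]] <- data.frame(image_id = i,
                           x_min = r$box[1], y_min = r$box[2],
                           x_max = r$box[3], y_max = r$box[4],
                           label = match(rec$treatment_class,
                                         c("I", "II", "III", "IV")),
                           class = rec$treatment_class)
  }
  annotations <- do.call(rbind, ann)
  index <- data.frame(image_id = seq_len(n),
                      image_path = sprintf("img_%04d.png", seq_len(n)),
                      class_label = classes,
                      site_label = rep_len(sites, n))
  ds <- structure(list(images = images, annotations = annotations,
                       index = index, descriptors = descriptors,
                       specs = specs, image_size = image_size),
                  class = "synthetic_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic long-bone dataset: %d images (%dx%d), classes: %s\n",
              length(x$images), x$image_size[1], x$image_size[2],
              paste(sprintf("%s=%d", names(table(x$index$class_label)),
                            table(x$index$class_label)), collapse = " ")))
  invisible(x)
}

#' Demographic fixture tables of the fracture cohort
#'
#' The packaged 1,410-patient cohort counts: gender by age band, fracture
#' location by age band, and mechanism of injury by age band, with the age
#' bands 18-24, 25-34, 34-44, 45-54, 55-64, >=65 as published. Location and
#' mechanism counts are the per-age totals rows; every margin sums to the
#' grand total of 1,410. (Two of the source tables print one internally
#' inconsistent subtotal — a femur row total of 405 against cells summing to
#' 402, and one bad-fall age cell — so the per-age totals, which are the
#' mutually consistent set, are the ones carried.)
#'
#' @return A `demographic_table`: list of matrices `gender` (2 x 6),
#'   `location` (5 x 6), `mechanism` (3 x 6) and `grand_total` (1410).
#' @export
demographics_fixture <- function() {
  bands <- c("18-24", "25-34", "34-44", "45-54", "55-64", ">=65")
  gender <- rbind(
    female = c(63, 78, 99, 104, 94, 84),
    male   = c(98, 266, 213, 133, 98, 80))
  location <- rbind(
    femur     = c(51, 87, 72, 65, 62, 65),
    leg       = c(54, 141, 126, 96, 54, 39),
    forearm   = c(34, 70, 60, 41, 46, 37),
    upper_arm = c(22, 29, 30, 25, 23, 17),
    multiple  = c(0, 17, 24, 10, 7, 6))
  mechanism <- rbind(
    bad_fall = c(64, 99, 100, 97, 87, 84),
    rti      = c(71, 210, 188, 116, 63, 39),
    others   = c(26, 35, 24, 24, 42, 41))
  colnames(gender) <- colnames(location) <- colnames(mechanism) <- bands
  structure(list(gender = gender, location = location, mechanism = mechanism,
                 grand_total = 1410L),
            class = "demographic_table")
}
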