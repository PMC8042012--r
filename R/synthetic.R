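#' Morphological class specification for the synthetic cell generator
#'
#' Describes one leukocyte class by the distribution of its rendered
#' morphology: nucleus-to-cell area fraction (the N:C ratio, the key
#' discriminator between blasts and mature cells), nuclear lobation (1 =
#' round nucleus, 2--5 = segmented), chromatin texture contrast, stain
#' colors, and cell size. All colors are RGB triples in `[0, 1]`.
#'
#' @param class_name class label.
#' @param nucleus_frac mean and sd of nucleus area / cell area, in (0, 1).
#' @param lobes integer range `c(min, max)` of nuclear lobe count.
#' @param chromatin_amp non-negative brightness noise amplitude inside the
#'   nucleus (0 = perfectly flat chromatin).
#' @param cytoplasm_color,nucleus_color,background_color RGB means.
#' @param color_sd per-image color jitter sd (applied to all three colors).
#' @param radius_frac mean and sd of cell radius / image half-width.
#' @param has_nucleus `FALSE` for anucleate fragments (thrombocytes).
#' @return an object of class `morphology_class_spec`.
#' @export
morphology_class_spec <- function(class_name,
                                  nucleus_frac = c(0.5, 0.05),
                                  lobes = c(1L, 1L),
                                  chromatin_amp = 0.05,
                                  cytoplasm_color = c(0.80, 0.75, 0.88),
                                  nucleus_color = c(0.35, 0.20, 0.50),
                                  background_color = c(0.95, 0.92, 0.95),
                                  color_sd = 0.03,
                                  radius_frac = c(0.5, 0.05),
                                  has_nucleus = TRUE) {
  if (length(lobes) == 1) lobes <- c(lobes, lobes)
  stopifnot(length(nucleus_frac) == 2, length(radius_frac) == 2,
            chromatin_amp >= 0, lobes[1] >= 1, lobes[1] <= lobes[2],
            all(cytoplasm_color >= 0 & cytoplasm_color <= 1),
            all(nucleus_color >= 0 & nucleus_color <= 1),
            all(background_color >= 0 & background_color <= 1))
  if (has_nucleus && (nucleus_frac[1] <= 0 || nucleus_frac[1] >= 1))
    stop("nucleus_frac mean must lie strictly in (0, 1) for nucleated classes")
  structure(list(class_name = class_name,
                 nucleus_frac = as.numeric(nucleus_frac),
                 lobes = as.integer(round(lobes)),
                 chromatin_amp = chromatin_amp,
                 cytoplasm_color = cytoplasm_color,
                 nucleus_color = nucleus_color,
                 background_color = background_color,
                 color_sd = color_sd,
                 radius_frac = as.numeric(radius_frac),
                 has_nucleus = isTRUE(has_nucleus)),
            class = "morphology_class_spec")
}

#' Built-in leukocyte class sets
#'
#' `mode = "binary"` gives a blast-like class (large round nucleus, high N:C
#' ratio, fine chromatin) versus a mature-lymphocyte-like class.
#' `mode = "six"` gives the six trainable diagnostic classes: lymphoblast,
#' atypical lymphocyte, typical lymphocyte, monocyte, segmented neutrophil
#' and thrombocyte. Parameter values follow standard cytology descriptions;
#' every one is overridable via [morphology_class_spec()].
#'
#' @param mode `"binary"` or `"six"`.
#' @return a named list of `morphology_class_spec` objects.
#' @export
leukocyte_classes <- function(mode = c("binary", "six")) {
  mode <- match.arg(mode)
  blast <- morphology_class_spec("blast",
    nucleus_frac = c(0.75, 0.05), lobes = 1, chromatin_amp = 0.04,
    nucleus_color = c(0.30, 0.15, 0.45), radius_frac = c(0.55, 0.05))
  lympho <- morphology_class_spec("nonblast",
    nucleus_frac = c(0.45, 0.06), lobes = 1, chromatin_amp = 0.10,
    radius_frac = c(0.42, 0.05))
  if (mode == "binary") return(list(blast = blast, nonblast = lympho))
  list(
    lymphoblast = morphology_class_spec("lymphoblast",
      nucleus_frac = c(0.75, 0.05), lobes = 1, chromatin_amp = 0.04,
      nucleus_color = c(0.30, 0.15, 0.45), radius_frac = c(0.55, 0.05)),
    lymphocyte_atypical = morphology_class_spec("lymphocyte_atypical",
      nucleus_frac = c(0.60, 0.06), lobes = 1, chromatin_amp = 0.08,
      radius_frac = c(0.50, 0.05)),
    lymphocyte_typical = morphology_class_spec("lymphocyte_typical",
      nucleus_frac = c(0.45, 0.06), lobes = 1, chromatin_amp = 0.10,
      radius_frac = c(0.42, 0.04)),
    monocyte = morphology_class_spec("monocyte",
      nucleus_frac = c(0.55, 0.06), lobes = 2, chromatin_amp = 0.06,
      nucleus_color = c(0.45, 0.30, 0.58), radius_frac = c(0.60, 0.05)),
    neutrophil_segmented = morphology_class_spec("neutrophil_segmented",
      nucleus_frac = c(0.32, 0.05), lobes = c(2, 5), chromatin_amp = 0.09,
      cytoplasm_color = c(0.88, 0.78, 0.82), radius_frac = c(0.50, 0.04)),
    thrombocyte = morphology_class_spec("thrombocyte",
      nucleus_frac = c(0.5, 0.05), has_nucleus = FALSE, chromatin_amp = 0,
      cytoplasm_color = c(0.70, 0.60, 0.80), radius_frac = c(0.18, 0.03)))
}

#' Configuration for a synthetic dataset
#'
#' @param classes list of [morphology_class_spec()] objects.
#' @param n_per_class images per class.
#' @param image_size square image side in pixels (>= 32).
#' @param effect_size in `[0, 1]`: 0 collapses every class onto the pooled
#'   mean morphology (classes indistinguishable by construction), 1 uses the
#'   full class-specific parameters.
#' @param distractors scatter red-cell-like discs in the background,
#'   emulating smear context around the centered leukocyte.
#' @param global_noise_sd per-pixel Gaussian sensor noise sd.
#' @param keep_masks keep the ground-truth nucleus/cell masks on each sample
#'   (needed by [measure_morphology()]).
#' @param seed integer seed; identical configs generate identical bytes.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(classes, n_per_class, image_size = 257L,
                             effect_size = 1, distractors = TRUE,
                             global_noise_sd = 0.01, keep_masks = TRUE,
                             seed = 1L) {
  if (image_size < 32)
    stop("configuration error: image_size must be at least 32 pixels")
  stopifnot(n_per_class >= 1, effect_size >= 0, effect_size <= 1,
            length(classes) >= 1)
  nm <- vapply(classes, function(s) s$class_name, character(1))
  names(classes) <- nm
  structure(list(classes = classes, n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 effect_size = effect_size, distractors = distractors,
                 global_noise_sd = global_noise_sd, keep_masks = keep_masks,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Interpolate every class's numeric morphology parameters between the pooled
# mean (effect 0) and the class-specific value (effect 1). Anucleate classes
# enter the pool with nucleus fraction 0; a class is rendered nucleated
# whenever its interpolated fraction exceeds 0.01.
interpolate_classes <- function(classes, effect_size) {
  to_vec <- function(s) c(if (s$has_nucleus) s$nucleus_frac[1] else 0,
                          s$nucleus_frac[2], s$lobes, s$chromatin_amp,
                          s$cytoplasm_color, s$nucleus_color,
                          s$background_color, s$color_sd, s$radius_frac)
  m <- vapply(classes, to_vec, numeric(17))
  pooled <- rowMeans(m)
  lapply(classes, function(s) {
    v <- pooled + effect_size * (to_vec(s) - pooled)
    s$nucleus_frac <- c(min(max(v[1], 0), 0.97), max(v[2], 0))
    s$has_nucleus <- v[1] > 0.01
    s$lobes <- pmax(1L, as.integer(round(v[3:4])))
    s$chromatin_amp <- max(v[5], 0)
    s$cytoplasm_color <- clip01(v[6:8])
    s$nucleus_color <- clip01(v[9:11])
    s$background_color <- clip01(v[12:14])
    s$color_sd <- max(v[15], 0)
    s$radius_frac <- c(min(max(v[16], 0.05), 0.95), max(v[17], 0))
    s
  })
}

# Truncated normal draw via rejection with a clamp fallback.
.rtruncn <- function(mean, sd, lo, hi) {
  for (i in 1:20) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Render one synthetic single-cell image
#'
#' Draws a centered elliptical cell on a stained-smear background, renders
#' the nucleus as `lobe_count` ellipses with chromatin brightness noise, adds
#' optional red-cell-like background distractors and global sensor noise, and
#' clips to `[0, 1]`. Uses the current R RNG stream; seed via the caller.
#'
#' @param class_spec a [morphology_class_spec()].
#' @param image_size square image side in pixels (>= 32).
#' @param distractors draw background discs.
#' @param global_noise_sd Gaussian noise sd added to the whole image last.
#' @param sample_id identifier stored on the sample.
#' @return an `image_sample`: list with `pixels` (`H x W x 3` in `[0, 1]`),
#'   `label`, `sample_id`, and attributes `nucleus_mask` / `cell_mask`
#'   (logical matrices).
#' @export
render_cell <- function(class_spec, image_size, distractors = FALSE,
                        global_noise_sd = 0.01, sample_id = "cell_001") {
  if (image_size < 32)
    stop("configuration error: image_size must be at least 32 pixels")
  n <- as.integer(image_size)
  # normalized centered coordinates in [-1, 1]
  ax <- (seq_len(n) - (n + 1) / 2) / ((n - 1) / 2)
  xg <- matrix(ax, n, n)              # varies along rows
  yg <- matrix(ax, n, n, byrow = TRUE)
  s <- class_spec
  img <- array(0, dim = c(n, n, 3))
  bg <- clip01(rnorm(3, s$background_color, s$color_sd))
  for (ch in 1:3) img[, , ch] <- bg[ch]

  if (distractors) {
    k <- rpois(1, 6)
    if (k > 0) for (d in seq_len(k)) {
      cx <- runif(1, -1, 1); cy <- runif(1, -1, 1)
      rr <- runif(1, 0.08, 0.16)
      dm <- ((xg - cx)^2 + (yg - cy)^2) <= rr^2
      dc <- clip01(rnorm(3, c(0.92, 0.60, 0.58), 0.04))
      # pale center mimics the erythrocyte central pallor
      pale <- ((xg - cx)^2 + (yg - cy)^2) <= (0.45 * rr)^2
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[dm] <- dc[ch]
        pl[pale] <- min(dc[ch] + 0.06, 1)
        img[, , ch] <- pl
      }
    }
  }

  # cell body: ellipse with mild eccentricity and random orientation
  r <- .rtruncn(s$radius_frac[1], s$radius_frac[2], 0.06, 0.95)
  ecc <- runif(1, 0, 0.15)
  a <- r * (1 + ecc); b <- r / (1 + ecc)
  phi <- runif(1, 0, 2 * pi)
  xr <- xg * cos(phi) + yg * sin(phi)
  yr <- -xg * sin(phi) + yg * cos(phi)
  cell_mask <- (xr / a)^2 + (yr / b)^2 <= 1
  cyt <- clip01(rnorm(3, s$cytoplasm_color, s$color_sd))
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[cell_mask] <- cyt[ch]
    img[, , ch] <- pl
  }

  nucleus_mask <- matrix(FALSE, n, n)
  if (s$has_nucleus && s$nucleus_frac[1] > 0.01) {
    frac <- .rtruncn(s$nucleus_frac[1], s$nucleus_frac[2], 0.02, 0.97)
    k <- if (s$lobes[1] == s$lobes[2]) s$lobes[1] else
      sample(seq(s$lobes[1], s$lobes[2]), 1)
    la <- sqrt(frac * a * b / k)  # per-lobe circle radius (normalized units)
    if (k == 1) {
      centers <- matrix(0, 1, 2)
      slack <- max(min(a, b) - la, 0)
      centers[1, ] <- runif(2, -0.3, 0.3) * slack
    } else {
      # lobes on a ring, spaced to avoid overlap where the cell allows it
      ring_needed <- 1.2 * la / sin(pi / k)
      ring_max <- max(min(a, b) - 1.1 * la, 0)
      ring <- min(ring_needed, ring_max)
      phase <- runif(1, 0, 2 * pi)
      ang <- phase + 2 * pi * (seq_len(k) - 1) / k
      centers <- cbind(ring * cos(ang), ring * sin(ang))
    }
    for (j in seq_len(nrow(centers))) {
      lr <- la * runif(1, 0.95, 1.05)
      nucleus_mask <- nucleus_mask |
        ((xr - centers[j, 1])^2 + (yr - centers[j, 2])^2 <= lr^2)
    }
    nucleus_mask <- nucleus_mask & cell_mask
    nuc <- clip01(rnorm(3, s$nucleus_color, s$color_sd))
    chrom <- if (s$chromatin_amp > 0)
      rnorm(sum(nucleus_mask), 0, s$chromatin_amp) else 0
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[nucleus_mask] <- nuc[ch] + chrom
      img[, , ch] <- pl
    }
  }

  if (global_noise_sd > 0)
    img <- img + rnorm(length(img), 0, global_noise_sd)
  img <- clip01(img)
  structure(list(pixels = img, label = s$class_name, sample_id = sample_id),
            nucleus_mask = nucleus_mask, cell_mask = cell_mask,
            class = "image_sample")
}

#' Generate a seeded synthetic labeled dataset
#'
#' Produces `n_per_class x length(classes)` images under the configuration's
#' seed; identical configurations yield bit-identical datasets.
#'
#' @param config a [synthetic_config()].
#' @return a `labeled_dataset`: list with `images` (`H x W x 3 x N` array),
#'   `labels` (factor), `sample_id` (character), `masks` (list of
#'   nucleus/cell mask pairs, if kept) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  classes <- interpolate_classes(config$classes, config$effect_size)
  n <- config$image_size
  total <- length(classes) * config$n_per_class
  images <- array(0, dim = c(n, n, 3, total))
  labels <- character(total)
  ids <- character(total)
  masks <- if (config$keep_masks) vector("list", total) else NULL
  with_seed(config$seed, {
    k <- 0
    for (cl in classes) {
      for (i in seq_len(config$n_per_class)) {
        k <- k + 1
        smp <- render_cell(cl, n, distractors = config$distractors,
                           global_noise_sd = config$global_noise_sd,
                           sample_id = sprintf("%s_%04d", cl$class_name, i))
        images[, , , k] <- smp$pixels
        labels[k] <- smp$label
        ids[k] <- smp$sample_id
        if (config$keep_masks)
          masks[[k]] <- list(nucleus = attr(smp, "nucleus_mask"),
                             cell = attr(smp, "cell_mask"))
      }
    }
  })
  labeled_dataset(images, factor(labels, levels = names(classes)), ids,
                  masks = masks, config = config)
}

#' Construct a labeled dataset container
#'
#' @param images `H x W x 3 x N` array of pixels in `[0, 1]`.
#' @param labels factor of length `N`.
#' @param sample_id unique identifiers, length `N`.
#' @param masks optional per-sample list of ground-truth masks.
#' @param config optional generating configuration.
#' @return an object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(images, labels, sample_id = NULL, masks = NULL,
                            config = NULL) {
  n <- dim(images)[4]
  sample_id <- sample_id %||% sprintf("sample_%04d", seq_len(n))
  stopifnot(length(labels) == n, length(sample_id) == n,
            !anyDuplicated(sample_id))
  structure(list(images = images, labels = as.factor(labels),
                 sample_id = as.character(sample_id), masks = masks,
                 config = config),
            class = "labeled_dataset")
}

#' @export
length.labeled_dataset <- function(x) dim(x$images)[4]

#' Subset a labeled dataset by sample index or id
#' @param x a `labeled_dataset`.
#' @param i integer indices or sample ids.
#' @param ... unused.
#' @export
`[.labeled_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_id)
  if (anyNA(i)) stop("unknown sample id in subset")
  labeled_dataset(x$images[, , , i, drop = FALSE],
                  droplevels_keep(x$labels, i),
                  x$sample_id[i],
                  masks = if (!is.null(x$masks)) x$masks[i] else NULL,
                  config = x$config)
}

# keep the full level set when subsetting (class order is part of the data)
droplevels_keep <- function(f, i) factor(f[i], levels = levels(f))

#' @export
print.labeled_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat("labeled_dataset: ", d[4], " images of ", d[1], "x", d[2], "x", d[3],
      "\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Measure morphology of one sample from ground-truth masks
#'
#' @param sample an `image_sample` (or `NULL` when both masks are given).
#' @param nucleus_mask logical matrix; defaults to the sample's own mask.
#' @param cell_mask logical matrix; defaults to the sample's own mask.
#' @return a list with `nucleus_area_fraction` (nucleus pixels / cell
#'   pixels), `lobe_count` (connected components of the nucleus mask) and
#'   `mean_cell_color` (RGB mean inside the cell, when pixels are available).
#' @export
measure_morphology <- function(sample = NULL,
                               nucleus_mask = attr(sample, "nucleus_mask"),
                               cell_mask = attr(sample, "cell_mask")) {
  stopifnot(is.matrix(nucleus_mask), is.matrix(cell_mask),
            all(dim(nucleus_mask) == dim(cell_mask)))
  n_cell <- sum(cell_mask)
  if (n_cell == 0)
    stop("undefined nucleus area fraction: empty cell mask")
  frac <- sum(nucleus_mask) / n_cell
  lobes <- if (any(nucleus_mask))
    max(EBImage::bwlabel(nucleus_mask * 1)) else 0L
  col <- NULL
  if (!is.null(sample) && !is.null(sample$pixels)) {
    col <- vapply(1:3, function(ch) mean(sample$pixels[, , ch][cell_mask]),
                  numeric(1))
  }
  list(nucleus_area_fraction = frac, lobe_count = as.integer(lobes),
       mean_cell_color = col)
}

#' Morphology table for a whole dataset
#'
#' @param dataset a `labeled_dataset` generated with `keep_masks = TRUE`.
#' @return a tibble with one row per sample: `sample_id`, `label`,
#'   `nucleus_area_fraction`, `lobe_count`.
#' @export
measure_dataset <- function(dataset) {
  if (is.null(dataset$masks))
    stop("dataset has no ground-truth masks (generate with keep_masks = TRUE)")
  rows <- lapply(seq_len(length(dataset)), function(i) {
    m <- measure_morphology(nucleus_mask = dataset$masks[[i]]$nucleus,
                            cell_mask = dataset$masks[[i]]$cell)
    tibble::tibble(sample_id = dataset$sample_id[i],
                   label = dataset$labels[i],
                   nucleus_area_fraction = m$nucleus_area_fraction,
                   lobe_count = m$lobe_count)
  })
  do.call(rbind, rows)
}
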