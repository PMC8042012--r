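#' Write a labeled dataset to disk
#'
#' Images go out as 8-bit PNGs, labels as a `filename,label` CSV, and (when
#' present) the generating configuration as YAML next to the data.
#'
#' @param dataset a `labeled_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(dataset$sample_id, ".png")
  for (i in seq_len(length(dataset)))
    png::writePNG(dataset$images[, , , i], file.path(dir, files[i]))
  write.csv(data.frame(filename = files,
                       label = as.character(dataset$labels)),
            file.path(dir, "labels.csv"), row.names = FALSE)
  if (!is.null(dataset$config)) {
    cfg <- dataset$config
    yaml::write_yaml(
      list(image_size = cfg$image_size, n_per_class = cfg$n_per_class,
           effect_size = cfg$effect_size, distractors = cfg$distractors,
           global_noise_sd = cfg$global_noise_sd, seed = cfg$seed,
           classes = lapply(cfg$classes, unclass)),
      file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Load a labeled image dataset from a directory and labels CSV
#'
#' Reads each image named in the CSV (header `filename,label`), decodes to
#' float RGB in `[0, 1]`, optionally enforces an expected square size, and
#' drops classes with fewer than `min_class_count` images (rare diagnostic
#' classes cannot support a training/validation split).
#'
#' @param image_dir directory containing the images.
#' @param labels_csv path to the labels CSV; defaults to `labels.csv` inside
#'   `image_dir`.
#' @param expected_size required image side in pixels, or `NULL` to accept
#'   the first image's size.
#' @param min_class_count drop classes with fewer images than this.
#' @param on_size_mismatch `"error"` or `"crop_pad"` (center-crop or pad
#'   with the image's border median to the expected size).
#' @return a `labeled_dataset`.
#' @export
load_dataset <- function(image_dir, labels_csv = file.path(image_dir, "labels.csv"),
                         expected_size = NULL, min_class_count = 0L,
                         on_size_mismatch = c("error", "crop_pad")) {
  on_size_mismatch <- match.arg(on_size_mismatch)
  tab <- read.csv(labels_csv, stringsAsFactors = FALSE)
  if (!all(c("filename", "label") %in% names(tab)))
    stop("labels CSV must have header 'filename,label'")
  dup <- tab$filename[duplicated(tab$filename)]
  if (length(dup)) stop("duplicate filename in labels table: '", dup[1], "'")
  tab <- filter_classes(tab, min_class_count)
  n <- nrow(tab)
  imgs <- vector("list", n)
  for (i in seq_len(n)) {
    path <- file.path(image_dir, tab$filename[i])
    if (!file.exists(path)) stop("missing image file: '", tab$filename[i], "'")
    img <- tryCatch(png::readPNG(path),
                    error = function(e) stop("unreadable image: '",
                                             tab$filename[i], "'"))
    if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
    if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]  # drop alpha
    imgs[[i]] <- img
  }
  expected_size <- expected_size %||% dim(imgs[[1]])[1]
  for (i in seq_len(n)) {
    d <- dim(imgs[[i]])
    if (d[1] != expected_size || d[2] != expected_size) {
      if (on_size_mismatch == "error")
        stop("image '", tab$filename[i], "' is ", d[1], "x", d[2],
             ", expected ", expected_size, "x", expected_size)
      imgs[[i]] <- .crop_pad(imgs[[i]], expected_size)
    }
  }
  images <- array(0, dim = c(expected_size, expected_size, 3, n))
  for (i in seq_len(n)) images[, , , i] <- imgs[[i]]
  labeled_dataset(images, factor(tab$label),
                  sample_id = sub("\\.[^.]+$", "", tab$filename))
}

.crop_pad <- function(img, size) {
  d <- dim(img)
  fill <- vapply(1:3, function(ch)
    median(c(img[1, , ch], img[d[1], , ch], img[, 1, ch], img[, d[2], ch])),
    numeric(1))
  out <- array(rep(fill, each = size * size), dim = c(size, size, 3))
  rh <- min(size, d[1]); rw <- min(size, d[2])
  sr <- (d[1] - rh) %/% 2; sc <- (d[2] - rw) %/% 2
  tr <- (size - rh) %/% 2; tc <- (size - rw) %/% 2
  out[tr + seq_len(rh), tc + seq_len(rw), ] <-
    img[sr + seq_len(rh), sc + seq_len(rw), 1:3]
  out
}

#' Drop classes below a minimum image count
#'
#' Diagnostic classes with too few images cannot be split across training,
#' validation and test sets; the standard threshold of five retains six of
#' the ten re-annotated leukocyte classes.
#'
#' @param labels_table data frame with a `label` column.
#' @param min_count minimum images per retained class.
#' @return the filtered table (attribute `dropped_classes` lists removals).
#' @export
filter_classes <- function(labels_table, min_count = 5L) {
  counts <- table(labels_table$label)
  keep <- names(counts)[counts >= min_count]
  out <- labels_table[labels_table$label %in% keep, , drop = FALSE]
  attr(out, "dropped_classes") <- setdiff(names(counts), keep)
  out
}

#' Published class counts of the re-annotated 250-image ALL dataset
#'
#' The expert re-annotation of the 250 single-cell images into ten
#' diagnostic types; shipped as a reference input for class bookkeeping
#' (the counts sum to 250, and the >= 5 filter retains six classes).
#'
#' @return a tibble with columns `class` and `n`.
#' @export
all_class_counts <- function() {
  tibble::tibble(
    class = c("basophil", "erythroblast", "eosinophil", "lymphoblast",
              "lymphocyte_atypical", "lymphocyte_typical", "metamyelocyte",
              "monocyte", "neutrophil_segmented", "thrombocyte"),
    n = c(1L, 1L, 2L, 126L, 12L, 52L, 1L, 5L, 22L, 28L))
}

#' Find exact pixel-level duplicate images
#'
#' Utility for dataset cleaning: groups images by summary statistics and
#' compares candidates pixel-for-pixel.
#'
#' @param dataset a `labeled_dataset`.
#' @return a tibble with `sample_id` and `duplicate_of` (first occurrence).
#' @export
find_duplicate_images <- function(dataset) {
  n <- length(dataset)
  key <- vapply(seq_len(n), function(i) {
    im <- dataset$images[, , , i]
    paste(format(c(mean(im), sd(im)), digits = 12), collapse = "|")
  }, character(1))
  dup_id <- character(0); dup_of <- character(0)
  for (g in unique(key[duplicated(key)])) {
    idx <- which(key == g)
    for (j in idx[-1]) {
      for (i in idx[idx < j]) {
        if (identical(dataset$images[, , , i], dataset$images[, , , j])) {
          dup_id <- c(dup_id, dataset$sample_id[j])
          dup_of <- c(dup_of, dataset$sample_id[i])
          break
        }
      }
    }
  }
  tibble::tibble(sample_id = dup_id, duplicate_of = dup_of)
}

# drop S3 classes recursively so configs serialize as plain JSON
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run byte-for-byte: the
#' configuration snapshot, the master seed, artifact paths, a timestamp and
#' the package version.
#'
#' @param path JSON output path.
#' @param config a `protocol_config` or `synthetic_config` (or plain list).
#' @param seed master seed of the run.
#' @param artifacts named character vector/list of output paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, artifacts = list()) {
  jsonlite::write_json(
    list(package = "cytocurve",
         version = as.character(utils::packageVersion("cytocurve")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed, config = strip_classes(config),
         artifacts = as.list(artifacts)),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}
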