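#' Construct a stimulus set for the invariant categorization task
#'
#' Enumerates the per-image metadata for a category / object-exemplar /
#' variation task. The default layout is 7 categories x 7 object exemplars
#' per category x 40 images per object (1960 images). Each image carries
#' variation parameters (position, scale over two octaves, 3D pose, and a
#' unique background seed) drawn once, deterministically from `seed`.
#'
#' @param n_categories number of object categories.
#' @param n_objects_per_category object exemplars per category.
#' @param n_images_per_object images (variation draws) per object exemplar.
#' @param seed integer seed controlling the variation parameter draws.
#' @return A `data.frame` of class `"stimulus_set"` with one row per image:
#'   `image_id` (dense, 0-based), `category`, `object_id` (factors; every
#'   object belongs to exactly one category), and variation columns
#'   `pos_x`, `pos_y`, `scale`, `pose_az`, `pose_el`, `background_seed`.
#' @examples
#' stim <- stimulus_set(2, 2, 3)
#' nrow(stim)  # 12
#' @export
stimulus_set <- function(n_categories = 7L,
                         n_objects_per_category = 7L,
                         n_images_per_object = 40L,
                         seed = 1L) {
  stopifnot(n_categories >= 1, n_objects_per_category >= 1,
            n_images_per_object >= 1)
  n_categories <- as.integer(n_categories)
  n_objects_per_category <- as.integer(n_objects_per_category)
  n_images_per_object <- as.integer(n_images_per_object)

  n_objects <- n_categories * n_objects_per_category
  n <- n_objects * n_images_per_object

  cat_labels <- sprintf("cat%02d", seq_len(n_categories))
  obj_labels <- sprintf("%s_obj%02d",
                        rep(cat_labels, each = n_objects_per_category),
                        rep(seq_len(n_objects_per_category), n_categories))

  category <- factor(rep(cat_labels, each = n_objects_per_category * n_images_per_object),
                     levels = cat_labels)
  object_id <- factor(rep(obj_labels, each = n_images_per_object),
                      levels = obj_labels)

  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  # two full octaves of scale, full-image translation, full-sphere pose
  df <- data.frame(
    image_id = 0:(n - 1L),
    category = category,
    object_id = object_id,
    pos_x = stats::runif(n, -1, 1),
    pos_y = stats::runif(n, -1, 1),
    scale = 2^stats::runif(n, -1, 1),
    pose_az = stats::runif(n, 0, 360),
    pose_el = 180 / pi * asin(stats::runif(n, -1, 1)),
    background_seed = seq_len(n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("stimulus_set", "data.frame")
  df
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("Stimulus set: %d images, %d categories, %d objects\n",
              nrow(x), nlevels(x$category), nlevels(x$object_id)))
  NextMethod()
}

validate_stimulus_set <- function(stimuli) {
  stopifnot(is.data.frame(stimuli),
            all(c("image_id", "category", "object_id") %in% names(stimuli)))
  if (anyDuplicated(stimuli$image_id) > 0)
    stop("stimulus set has duplicated image_id values")
  # each object maps to exactly one category
  map <- unique(stimuli[, c("category", "object_id")])
  if (anyDuplicated(map$object_id) > 0)
    stop("an object_id is assigned to more than one category")
  invisible(stimuli)
}

#' Read / write stimulus sets as CSV
#'
#' @param path file path.
#' @return `read_stimulus_set()` returns a `stimulus_set` data frame.
#' @export
read_stimulus_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$category <- factor(df$category)
  df$object_id <- factor(df$object_id)
  class(df) <- c("stimulus_set", "data.frame")
  validate_stimulus_set(df)
  df
}

#' @rdname read_stimulus_set
#' @param stimuli a `stimulus_set` data frame.
#' @export
write_stimulus_set <- function(stimuli, path) {
  utils::write.csv(as.data.frame(stimuli), path, row.names = FALSE)
  invisible(path)
}

# Run code under a temporary RNG state seeded with `seed`; returns a restore
# function. Keeps package functions reproducible without clobbering the
# caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}
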