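# Dataset bookkeeping: manifests, augmentation, balancing, splitting and
# label regrouping. A dataset is a data.frame of records (path, grade,
# origin, split); images stay on disk as PGM files and are loaded on demand.

#' Graded image set
#'
#' Light container over a record data.frame with columns `path` (PGM file),
#' `grade` (0..4), `origin` (`"original"` or `"augmented"`) and `split`
#' (`"train"`, `"val"`, `"test"` or `"unassigned"`).
#'
#' @param records data.frame with the four columns above.
#' @return object of class `graded_image_set` (a data.frame subclass).
#' @export
graded_image_set <- function(records) {
  need <- c("path", "grade", "origin", "split")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "))
  }
  if (!all(records$grade %in% 0:4)) stop("grades must be in 0..4")
  if (!all(records$origin %in% c("original", "augmented"))) {
    stop("origin must be 'original' or 'augmented'")
  }
  if (!all(records$split %in% c("train", "val", "test", "unassigned"))) {
    stop("invalid split value")
  }
  if (any(records$origin == "augmented" &
          !(records$split %in% c("train", "unassigned")))) {
    stop("augmented records may only live in the train split")
  }
  structure(as.data.frame(records), class = c("graded_image_set", "data.frame"))
}

#' Read a dataset manifest CSV
#'
#' @param path manifest CSV with columns `path, grade, origin, split`
#'   (missing `origin`/`split` default to `"original"`/`"unassigned"`);
#'   relative image paths are resolved against the manifest's directory.
#' @return a [graded_image_set].
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$origin)) df$origin <- "original"
  if (is.null(df$split)) df$split <- "unassigned"
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  graded_image_set(df)
}

#' Augmentation policy
#'
#' Random-transform ranges used to synthesise extra training images. The
#' defaults are the tuned values of the reference experiment: horizontal
#' flip on, rotation within +/- 25 degrees, width/height shifts within
#' +/- 22%/23% of the image side, zoom within +/- 25%.
#'
#' @param horizontal_flip flip left-right with probability 1/2.
#' @param rotation_range max absolute rotation in degrees.
#' @param width_shift_range max horizontal shift, fraction of width.
#' @param height_shift_range max vertical shift, fraction of height.
#' @param zoom_range max relative zoom in/out.
#' @return object of class `augment_policy`.
#' @export
augment_policy <- function(horizontal_flip = TRUE, rotation_range = 25,
                           width_shift_range = 0.22, height_shift_range = 0.23,
                           zoom_range = 0.25) {
  stopifnot(rotation_range >= 0, width_shift_range >= 0,
            height_shift_range >= 0, zoom_range >= 0, zoom_range < 1)
  structure(list(horizontal_flip = isTRUE(horizontal_flip),
                 rotation_range = rotation_range,
                 width_shift_range = width_shift_range,
                 height_shift_range = height_shift_range,
                 zoom_range = zoom_range),
            class = "augment_policy")
}

#' Randomly transform one image
#'
#' Draws a flip, rotation, shift and zoom uniformly within the policy ranges
#' and applies them as a single inverse-mapped affine transform with
#' bilinear interpolation and nearest-edge fill. Output shape equals input
#' shape; deterministic per seed. A policy with all ranges 0 and flip off is
#' the identity.
#'
#' @param image numeric matrix `image[row, col]`.
#' @param policy an [augment_policy].
#' @param seed integer seed.
#' @return transformed image, same dimensions.
#' @export
augment_image <- function(image, policy, seed) {
  stopifnot(inherits(policy, "augment_policy"))
  if (!is.matrix(image) || length(image) == 0L) stop("empty image")
  H <- nrow(image); W <- ncol(image)
  withr::with_seed(as.integer(seed), {
    flip <- policy$horizontal_flip && stats::runif(1) < 0.5
    theta <- stats::runif(1, -1, 1) * policy$rotation_range * pi / 180
    dx <- stats::runif(1, -1, 1) * policy$width_shift_range * W
    dy <- stats::runif(1, -1, 1) * policy$height_shift_range * H
    zoom <- 1 + stats::runif(1, -1, 1) * policy$zoom_range
  })
  if (!flip && theta == 0 && dx == 0 && dy == 0 && zoom == 1) return(image)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rr <- rep(seq_len(H), times = W) - cy
  cc <- rep(seq_len(W), each = H) - cx
  # inverse map: undo shift, then rotation/zoom about the centre
  u <- cc - dx
  v <- rr - dy
  src_c <- (cos(-theta) * u - sin(-theta) * v) / zoom + cx
  src_r <- (sin(-theta) * u + cos(-theta) * v) / zoom + cy
  if (flip) src_c <- W + 1 - src_c
  src_r <- pmin(pmax(src_r, 1), H)  # nearest-edge fill
  src_c <- pmin(pmax(src_c, 1), W)
  r0 <- pmin(floor(src_r), H - 1); c0 <- pmin(floor(src_c), W - 1)
  fr <- src_r - r0; fc <- src_c - c0
  at <- function(r, c) image[cbind(r, c)]
  out <- at(r0, c0) * (1 - fr) * (1 - fc) + at(r0 + 1, c0) * fr * (1 - fc) +
    at(r0, c0 + 1) * (1 - fr) * fc + at(r0 + 1, c0 + 1) * fr * fc
  matrix(out, H, W)
}

#' Balance class counts by augmentation and subsampling
#'
#' Brings every grade to exactly `target` training records: classes below
#' target are topped up with augmented copies of randomly chosen originals
#' of the same class (written as PGM files next to their sources, suffix
#' `_augNNNN`), classes above target are randomly subsampled without
#' replacement. Operates on the `train` split if one is assigned, otherwise
#' on all (unassigned) records, which are then treated as training data.
#' Records outside the operated split pass through untouched.
#'
#' @param gset a [graded_image_set]; every class present must have at least
#'   one original record in the operated split.
#' @param target per-class record count after balancing.
#' @param policy an [augment_policy] for the synthesised records.
#' @param seed integer seed.
#' @param out_dir directory for augmented images (default: alongside each
#'   source image).
#' @return a [graded_image_set] with exactly `target` records per class in
#'   the operated split.
#' @export
balance_classes <- function(gset, target, policy = augment_policy(),
                            seed = 1L, out_dir = NULL) {
  stopifnot(inherits(gset, "graded_image_set"), target >= 1)
  df <- as.data.frame(gset)
  has_split <- any(df$split == "train")
  work <- if (has_split) df$split == "train" else df$split == "unassigned"
  rest <- df[!work, , drop = FALSE]
  tr <- df[work, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no records to balance")
  grades <- sort(unique(tr$grade))
  if (any(tapply(tr$origin == "original", tr$grade, sum) == 0)) {
    stop("every class needs at least one original record")
  }
  pieces <- list()
  withr::with_seed(as.integer(seed), {
    for (g in grades) {
      cls <- tr[tr$grade == g, , drop = FALSE]
      n <- nrow(cls)
      if (n == target) {
        pieces[[length(pieces) + 1L]] <- cls
      } else if (n > target) {
        pieces[[length(pieces) + 1L]] <- cls[sample.int(n, target), ,
                                             drop = FALSE]
      } else {
        need <- target - n
        orig <- cls[cls$origin == "original", , drop = FALSE]
        src_idx <- sample.int(nrow(orig), need, replace = TRUE)
        aug_seeds <- sample.int(.Machine$integer.max - 1L, need)
        aug <- vector("list", need)
        for (i in seq_len(need)) {
          src <- orig[src_idx[i], ]
          img <- augment_image(read_pgm(src$path), policy, aug_seeds[i])
          dir <- if (is.null(out_dir)) dirname(src$path) else out_dir
          dir.create(dir, recursive = TRUE, showWarnings = FALSE)
          ap <- file.path(dir, sprintf(
            "%s_aug%04d.pgm",
            sub("\\.pgm$", "", basename(src$path)), i
          ))
          write_pgm(img, ap)
          aug[[i]] <- data.frame(path = ap, grade = g, origin = "augmented",
                                 split = src$split, stringsAsFactors = FALSE)
        }
        pieces[[length(pieces) + 1L]] <- rbind(cls, do.call(rbind, aug))
      }
    }
  })
  out <- rbind(rest, do.call(rbind, pieces))
  rownames(out) <- NULL
  graded_image_set(out)
}

#' Stratified train/validation/test split
#'
#' Randomly assigns every record to a split, stratified by grade so each
#' class appears in every subset in the requested proportions (within
#' rounding of one record). The default fractions follow the reference
#' experiment's implied proportions (about 0.50/0.17/0.33).
#'
#' @param gset a [graded_image_set].
#' @param fractions length-3 numeric `(train, val, test)`, each > 0, summing
#'   to 1 within 1e-6.
#' @param seed integer seed.
#' @return the [graded_image_set] with `split` assigned for every record.
#' @export
split_dataset <- function(gset, fractions = c(0.50, 0.17, 0.33), seed = 1L) {
  stopifnot(inherits(gset, "graded_image_set"), length(fractions) == 3L)
  if (any(fractions <= 0)) stop("all split fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  df <- as.data.frame(gset)
  withr::with_seed(as.integer(seed), {
    for (g in sort(unique(df$grade))) {
      idx <- which(df$grade == g)
      n <- length(idx)
      n_tr <- round(fractions[1] * n)
      n_va <- round(fractions[2] * n)
      if (n_tr + n_va > n) n_va <- n - n_tr
      idx <- sample(idx)
      df$split[idx] <- c(rep("train", n_tr), rep("val", n_va),
                         rep("test", n - n_tr - n_va))
    }
  })
  graded_image_set(df)
}

#' Regroup ordinal grades into coarser tasks
#'
#' `five` keeps grades 0..4; `three` maps \{0,1\} to healthy (0), \{2,3\} to
#' moderate (1) and \{4\} to severe (2); `two` maps \{0,1\} to healthy (0)
#' and \{2,3,4\} to unhealthy (1). Grade 1 is grouped with healthy because
#' it is only "doubtful" narrowing.
#'
#' @param grades integer vector of grades in 0..4.
#' @param task `"five"`, `"three"` or `"two"`.
#' @return integer vector of task labels (0-based).
#' @export
#' @examples
#' regroup_labels(0:4, "three")  # 0 0 1 1 2
regroup_labels <- function(grades, task = c("five", "three", "two")) {
  task <- match.arg(task)
  if (!all(grades %in% 0:4)) stop("grades must be in 0..4")
  g <- as.integer(grades)
  switch(task,
    five = g,
    three = ifelse(g <= 1L, 0L, ifelse(g <= 3L, 1L, 2L)),
    two = ifelse(g <= 1L, 0L, 1L)
  )
}

#' Number of classes for a task
#' @param task `"five"`, `"three"` or `"two"`.
#' @return 5, 3 or 2.
#' @export
task_num_classes <- function(task = c("five", "three", "two")) {
  switch(match.arg(task), five = 5L, three = 3L, two = 2L)
}

# load the images of selected records into an (H, W, C, N) array,
# replicating grayscale to `channels`
load_images <- function(gset, split = NULL, channels = 3L) {
  df <- as.data.frame(gset)
  if (!is.null(split)) df <- df[df$split %in% split, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records selected")
  first <- read_pgm(df$path[1])
  H <- nrow(first); W <- ncol(first)
  x <- array(0, c(H, W, channels, nrow(df)))
  for (i in seq_len(nrow(df))) {
    img <- if (i == 1L) first else read_pgm(df$path[i])
    for (ch in seq_len(channels)) x[, , ch, i] <- img
  }
  list(x = x, grade = df$grade, records = df)
}
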