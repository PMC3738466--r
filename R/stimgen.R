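#' Stimulus-set configuration
#'
#' Describes the composition of a synthetic set of isolated grayscale objects
#' on a uniform mid-gray background. The default composition totals 213
#' images: 94 twin pairs of real-world-like objects (188), 5 cars, 5 faces,
#' 5 abstract silhouettes, 5 texture patches, 1 blank frame and 4 low-contrast
#' variants of one object.
#'
#' @param n_twin_pairs number of twin pairs of object prototypes.
#' @param n_cars,n_faces,n_silhouettes,n_textures counts of the special
#'   multi-exemplar classes (each class forms one twin set).
#' @param n_blank number of blank (all-background) frames.
#' @param n_lowcontrast number of low-contrast variants of the first
#'   twin-pair object, rendered at decreasing nominal contrast.
#' @param frame_size side of the square image frame in pixels (>= 32).
#' @param background background gray level; object pixels never take exactly
#'   this value, so segmentation is an exact match and the strict inequalities
#'   of the contrast definition exclude the background.
#' @param lowcontrast_levels nominal contrast scaling factors for the
#'   low-contrast variants (strictly decreasing).
#' @param shape_families allowed shape families.
#' @return a `stim_config` list.
#' @export
stim_config <- function(n_twin_pairs = 94L, n_cars = 5L, n_faces = 5L,
                        n_silhouettes = 5L, n_textures = 5L, n_blank = 1L,
                        n_lowcontrast = 4L, frame_size = 64L,
                        background = 128,
                        lowcontrast_levels = c(0.10, 0.03, 0.02, 0.015),
                        shape_families = c("round", "horiz", "vert",
                                           "star", "pointy", "textured")) {
  counts <- c(n_twin_pairs = n_twin_pairs, n_cars = n_cars, n_faces = n_faces,
              n_silhouettes = n_silhouettes, n_textures = n_textures,
              n_blank = n_blank, n_lowcontrast = n_lowcontrast)
  if (any(counts < 0)) {
    stop("invalid composition: counts must be non-negative", call. = FALSE)
  }
  if (frame_size < 32) stop("frame_size must be >= 32", call. = FALSE)
  if (n_lowcontrast > length(lowcontrast_levels)) {
    stop("not enough lowcontrast_levels for n_lowcontrast", call. = FALSE)
  }
  if (n_lowcontrast > 0 && n_twin_pairs < 1) {
    stop(paste("invalid composition: low-contrast variants replicate the",
               "first twin-pair object, but n_twin_pairs is 0"), call. = FALSE)
  }
  structure(list(n_twin_pairs = as.integer(n_twin_pairs),
                 n_cars = as.integer(n_cars), n_faces = as.integer(n_faces),
                 n_silhouettes = as.integer(n_silhouettes),
                 n_textures = as.integer(n_textures),
                 n_blank = as.integer(n_blank),
                 n_lowcontrast = as.integer(n_lowcontrast),
                 frame_size = as.integer(frame_size),
                 background = background,
                 lowcontrast_levels = sort(lowcontrast_levels[seq_len(
                   max(n_lowcontrast, 0L))], decreasing = TRUE),
                 shape_families = shape_families),
            class = "stim_config")
}

# semantic labels; the first six are animate, the last five inanimate
.semantic_labels <- c("four_limbed_animals", "birds", "faces", "fishes",
                      "insects", "sea_invertebrates",
                      "trees", "vehicles", "tools", "music_instruments",
                      "buildings")
.animate_labels <- .semantic_labels[1:6]

# many-to-many map from semantic label to plausible shape families, so that
# semantic structure and shape structure can be decoupled by configuration
.semantic_shape_map <- list(
  four_limbed_animals = c("horiz", "pointy"),
  birds               = c("horiz", "round"),
  faces               = c("round"),
  fishes              = c("horiz"),
  insects             = c("pointy", "star"),
  sea_invertebrates   = c("star", "round"),
  trees               = c("vert", "star"),
  vehicles            = c("horiz", "vert"),
  tools               = c("vert", "pointy"),
  music_instruments   = c("vert", "horiz"),
  buildings           = c("vert", "textured")
)

## ------------------------------------------------------------------ rendering

# pixel-centre coordinate grids in [-1, 1] (rows = y downward, cols = x)
.grid_xy <- function(n) {
  u <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  list(x = matrix(u, n, n, byrow = TRUE), y = matrix(u, n, n))
}

# evaluate an object mask analytically at (possibly rotated/translated)
# coordinates; returns a logical matrix
.shape_mask <- function(family, par, x, y) {
  th <- par$rot * pi / 180
  xr <- cos(th) * (x - par$dx) + sin(th) * (y - par$dy)
  yr <- -sin(th) * (x - par$dx) + cos(th) * (y - par$dy)
  switch(family,
    round = (xr / par$a)^2 + (yr / par$b)^2 <= 1,
    horiz = (xr / par$a)^2 + (yr / par$b)^2 <= 1,
    vert  = (xr / par$a)^2 + (yr / par$b)^2 <= 1,
    pointy = {
      # isosceles triangle of half-width a and half-height b
      (abs(xr) <= par$a * (1 - (yr + par$b) / (2 * par$b))) &
        (yr >= -par$b) & (yr <= par$b)
    },
    star = {
      r <- sqrt(xr^2 + yr^2)
      ang <- atan2(yr, xr)
      r <= par$a * (1 + par$amp * cos(par$points * ang))
    },
    textured = abs(xr) <= par$a & abs(yr) <= par$b,
    stop("unknown shape family: ", family, call. = FALSE)
  )
}

# paint a two-tone object into a background frame; the split between the
# high and low tone is a half-plane through the object centre (or a dot /
# stripe pattern for textured objects)
.render_object <- function(family, par, frame_size, background) {
  g <- .grid_xy(frame_size)
  mask <- .shape_mask(family, par, g$x, g$y)
  img <- matrix(background, frame_size, frame_size)
  if (!any(mask)) return(list(image = img, mask = mask))
  if (family == "textured") {
    pat <- switch(par$pattern,
      dots = matrix(stats::runif(frame_size^2) < 0.5,
                    frame_size, frame_size),
      bars = ((g$x * cos(par$bar_angle) + g$y * sin(par$bar_angle)) *
                par$bar_freq) %% 1 < 0.5)
    hi <- mask & pat
    lo <- mask & !pat
  } else {
    split <- (cos(par$split_angle) * (g$x - par$dx) +
                sin(par$split_angle) * (g$y - par$dy)) >= 0
    hi <- mask & split
    lo <- mask & !split
  }
  img[hi] <- par$hi
  img[lo] <- par$lo
  list(image = img, mask = mask)
}

# draw prototype parameters for one object of a given family
.draw_params <- function(family) {
  area <- stats::runif(1, 0.05, 0.35)            # target area fraction
  par <- list(
    rot = 0, dx = stats::runif(1, -0.1, 0.1), dy = stats::runif(1, -0.1, 0.1),
    hi = stats::runif(1, 150, 240), lo = stats::runif(1, 20, 110),
    split_angle = stats::runif(1, 0, pi)
  )
  if (family %in% c("round", "horiz", "vert")) {
    ar <- switch(family, round = stats::runif(1, 1, 1.3),
                 horiz = stats::runif(1, 2.2, 4.5),
                 vert = stats::runif(1, 2.2, 4.5))
    # ellipse area fraction = pi*a*b/4 on the [-1,1]^2 frame
    b <- sqrt(4 * area / (pi * ar))
    a <- ar * b
    if (family == "vert") { tmp <- a; a <- b; b <- tmp }
    par$a <- min(a, 0.9); par$b <- min(b, 0.9)
  } else if (family == "pointy") {
    # triangle area fraction on the [-1,1]^2 frame is a*b/2
    ar <- stats::runif(1, 1.5, 3)
    b <- min(sqrt(2 * area * ar), 0.85)
    par$a <- min(2 * b / ar, 0.85); par$b <- b
    par$rot <- stats::runif(1, 0, 360)
  } else if (family == "star") {
    par$points <- sample(5:8, 1)
    par$amp <- stats::runif(1, 0.25, 0.5)
    par$a <- min(sqrt(area / pi) * 1.6, 0.6)
    par$rot <- stats::runif(1, 0, 360)
  } else if (family == "textured") {
    side <- sqrt(stats::runif(1, 0.3, 0.8))
    par$a <- side; par$b <- side
    par$pattern <- sample(c("dots", "bars"), 1)
    par$bar_angle <- stats::runif(1, 0, pi)
    par$bar_freq <- stats::runif(1, 3, 8)
  }
  par
}

# twin jitter: small rotation and contrast scaling around the prototype
.jitter_params <- function(par, family) {
  if (family != "textured") par$rot <- par$rot + stats::runif(1, -5, 5)
  sc <- stats::runif(1, 0.9, 1.1)
  par$hi <- 128 + (par$hi - 128) * sc
  par$lo <- 128 + (par$lo - 128) * sc
  par$dx <- par$dx + stats::runif(1, -0.03, 0.03)
  par$dy <- par$dy + stats::runif(1, -0.03, 0.03)
  par
}

## ------------------------------------------------------------------ generator

#' Generate a synthetic stimulus set
#'
#' Procedurally renders a set of isolated two-tone grayscale objects on a
#' uniform mid-gray background, organised into twin sets (near-identical
#' exemplars of a shared prototype, differing by small pose and contrast
#' jitter), plus cars, faces, abstract silhouettes, texture patches, a blank
#' frame, and low-contrast variants of one object. Shape families span round,
#' horizontally elongated, vertically elongated, star-like, pointy and
#' textured objects; semantic labels are assigned to shape families
#' many-to-many so that semantic and shape structure are not confounded by
#' construction. The same seed always yields a bit-identical set.
#'
#' @param config a [stim_config()].
#' @param seed integer seed.
#' @return a `StimulusSet`: list with `images` (list of numeric matrices,
#'   values in 0-255), `objects` (data frame with `object_id`, `twin_set_id`,
#'   `semantic_label`, `is_animate`, `shape_family`, `class`), `frame_size`
#'   and `background`.
#' @export
generate_stimulus_set <- function(config = stim_config(), seed = 1L) {
  stopifnot(inherits(config, "stim_config"))
  with_seed(seed, {
    fs <- config$frame_size
    bg <- config$background
    images <- list()
    meta <- list()
    twin_id <- 0L

    add <- function(img, twin, sem, fam, cls) {
      images[[length(images) + 1L]] <<- img
      meta[[length(meta) + 1L]] <<- data.frame(
        object_id = NA_character_, twin_set_id = twin,
        semantic_label = sem,
        is_animate = if (is.na(sem)) NA else sem %in% .animate_labels,
        shape_family = fam, class = cls, stringsAsFactors = FALSE)
    }

    clamp_bg <- function(img) {
      img <- pmin(pmax(img, 0), 255)
      img[abs(img - bg) < 0.5 & img != bg] <- bg + 1  # keep exact-match segmentation
      img
    }

    lowcontrast_proto <- NULL
    for (p in seq_len(config$n_twin_pairs)) {
      sem <- .semantic_labels[1L + (p - 1L) %% length(.semantic_labels)]
      fams <- intersect(.semantic_shape_map[[sem]], config$shape_families)
      if (length(fams) == 0) fams <- config$shape_families
      fam <- sample(fams, 1)
      proto <- .draw_params(fam)
      twin_id <- twin_id + 1L
      for (e in 1:2) {
        par <- .jitter_params(proto, fam)
        img <- clamp_bg(.render_object(fam, par, fs, bg)$image)
        add(img, twin_id, sem, fam, "twin_pair")
      }
      if (p == 1L) lowcontrast_proto <- list(fam = fam, par = proto)
    }

    special <- list(
      list(n = config$n_cars, fam = "horiz", sem = "vehicles", cls = "car"),
      list(n = config$n_faces, fam = "round", sem = "faces", cls = "face"),
      list(n = config$n_silhouettes, fam = "pointy", sem = NA_character_,
           cls = "silhouette"),
      list(n = config$n_textures, fam = "textured", sem = NA_character_,
           cls = "texture"))
    for (sp in special) {
      if (sp$n == 0) next
      twin_id <- twin_id + 1L
      proto <- .draw_params(sp$fam)
      for (e in seq_len(sp$n)) {
        par <- .jitter_params(proto, sp$fam)
        if (sp$cls == "silhouette") {
          # silhouettes are uniformly dark: a single tone below mid-gray,
          # which leaves the contrast measure undefined (as for real
          # black-on-gray cutouts)
          par$hi <- par$lo
        }
        img <- clamp_bg(.render_object(sp$fam, par, fs, bg)$image)
        add(img, twin_id, sp$sem, sp$fam, sp$cls)
      }
    }

    for (b in seq_len(config$n_blank)) {
      twin_id <- twin_id + 1L
      add(matrix(bg, fs, fs), twin_id, NA_character_, "blank", "blank")
    }

    if (config$n_lowcontrast > 0) {
      twin_id <- twin_id + 1L
      lp <- lowcontrast_proto
      for (lev in config$lowcontrast_levels) {
        par <- lp$par
        par$hi <- bg + (par$hi - bg) * lev
        par$lo <- bg + (par$lo - bg) * lev
        img <- pmin(pmax(.render_object(lp$fam, par, fs, bg)$image, 0), 255)
        add(img, twin_id, NA_character_, lp$fam, "lowcontrast")
      }
    }

    objects <- do.call(rbind, meta)
    objects$object_id <- sprintf("obj%03d", seq_len(nrow(objects)))
    rownames(objects) <- objects$object_id
    structure(list(images = images, objects = objects,
                   frame_size = fs, background = bg),
              class = "StimulusSet")
  })
}

#' @export
print.StimulusSet <- function(x, ...) {
  cat(sprintf("StimulusSet: %d images (%dx%d px, background %g)\n",
              length(x$images), x$frame_size, x$frame_size, x$background))
  cat(sprintf("  twin sets: %d; classes: %s\n",
              length(unique(x$objects$twin_set_id)),
              paste(names(table(x$objects$class)), collapse = ", ")))
  invisible(x)
}

#' Write a stimulus set to disk
#'
#' Writes one PNG per image plus a tab-delimited metadata table
#' (`objects.tsv`) with object id, twin-set id, semantic label and shape
#' family.
#'
#' @param stimset a `StimulusSet`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_stimulus_set <- function(stimset, dir) {
  stopifnot(inherits(stimset, "StimulusSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stimset$images)) {
    png::writePNG(stimset$images[[i]] / 255,
                  file.path(dir, paste0(stimset$objects$object_id[i], ".png")))
  }
  utils::write.table(
    stimset$objects[, c("object_id", "twin_set_id", "semantic_label",
                        "shape_family")],
    file.path(dir, "objects.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Semantic category scheme of a stimulus set
#'
#' Collects the labelled objects of a stimulus set into the semantic
#' category scheme (eleven subordinate categories, plus the animate and
#' inanimate superordinates).
#'
#' @param stimset a `StimulusSet`.
#' @return a `CategoryScheme` (see [category_scheme()]).
#' @export
semantic_scheme <- function(stimset) {
  ob <- stimset$objects
  cats <- lapply(.semantic_labels, function(l) {
    ob$object_id[!is.na(ob$semantic_label) & ob$semantic_label == l]
  })
  names(cats) <- .semantic_labels
  cats <- cats[vapply(cats, length, 1L) > 0]
  superord <- list(
    animate = unlist(cats[intersect(names(cats), .animate_labels)],
                     use.names = FALSE),
    inanimate = unlist(cats[setdiff(names(cats), .animate_labels)],
                       use.names = FALSE))
  category_scheme("semantic", cats, superordinates = superord)
}
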