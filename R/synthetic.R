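# Seeded synthetic fundus scenes with exact ground-truth masks.
#
# The generator emulates the troublesome traits of mobile-phone fundus
# photographs: a circular field of view on a dark background, a smooth
# illumination ramp, soft shadows, light-explosive highlights, thin dark
# curvilinear vessels, and hemorrhages rendered as concentric disks with
# more than one shade (the multishade structure that defeats single-pass
# thresholding).

#' Synthetic scene parameters
#'
#' @param seed RNG seed; scenes are bit-identical for a fixed seed.
#' @param size image size \code{c(rows, cols)}; the default mirrors the
#'   598 x 597 images of mobile-phone fundus photography.
#' @param illumination_gradient peak-to-peak amplitude of the smooth
#'   brightness ramp across the field of view.
#' @param shadow_count number of soft dark shadow patches.
#' @param shadow_darkness maximal fractional darkening inside a shadow.
#' @param light_blob_count number of light-explosive highlight spots.
#' @param vessel_count number of dark curvilinear vessels.
#' @param vessel_width vessel stroke width in pixels.
#' @param hemorrhage_specs list of hemorrhage specifications, each a list
#'   with \code{center} (\code{c(row, col)}, or \code{NULL} for a random
#'   position inside the retina), \code{radius} (pixels) and
#'   \code{shades}: multiplicative green-attenuation factors in (0, 1),
#'   strictly increasing from the innermost shade outward (darkest core
#'   first). A single factor gives a uniform lesion; two or more give a
#'   multishade lesion of concentric rings.
#' @return object of class \code{scene_params}.
#' @export
scene_params <- function(seed = 1L, size = c(598L, 597L),
                         illumination_gradient = 0.25,
                         shadow_count = 2L, shadow_darkness = 0.35,
                         light_blob_count = 1L,
                         vessel_count = 6L, vessel_width = 3L,
                         hemorrhage_specs = list()) {
  stopifnot(length(size) == 2L, all(size >= 32L),
            illumination_gradient >= 0, shadow_count >= 0,
            shadow_darkness >= 0, shadow_darkness < 1,
            light_blob_count >= 0, vessel_count >= 0, vessel_width >= 1)
  for (hs in hemorrhage_specs) {
    stopifnot(is.list(hs), !is.null(hs$radius), hs$radius > 0,
              !is.null(hs$shades), length(hs$shades) >= 1)
    if (any(hs$shades <= 0) || any(hs$shades >= 1))
      stop("hemorrhage shades must lie strictly inside (0, 1)")
    if (length(hs$shades) > 1 && any(diff(hs$shades) <= 0))
      stop("hemorrhage shades must increase strictly from core outward")
  }
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 illumination_gradient = illumination_gradient,
                 shadow_count = as.integer(shadow_count),
                 shadow_darkness = shadow_darkness,
                 light_blob_count = as.integer(light_blob_count),
                 vessel_count = as.integer(vessel_count),
                 vessel_width = as.integer(vessel_width),
                 hemorrhage_specs = hemorrhage_specs),
            class = "scene_params")
}

# Gaussian bump field centered at (r0, c0) with width sigma, on the
# precomputed coordinate grids.
.bump <- function(rr, cc, r0, c0, sigma) {
  exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sigma^2))
}

# Draw a gently curved vessel stroke; returns the logical mask, or NULL
# if it could not be placed without touching `avoid`.
.draw_vessel <- function(dm, radius, center, width, avoid, tries = 20L) {
  nr <- dm[1L]; nc <- dm[2L]
  rad <- (width - 1) / 2
  offs <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                      dc = -ceiling(rad):ceiling(rad))
  offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2 + 0.26, , drop = FALSE]
  for (k in seq_len(tries)) {
    ang0 <- runif(1, 0, 2 * pi)
    start_r <- center[1L] + runif(1, -0.5, 0.5) * radius
    start_c <- center[2L] + runif(1, -0.5, 0.5) * radius
    len <- round(runif(1, 0.6, 0.9) * radius)
    dir <- ang0
    r <- start_r; c <- start_c
    path_r <- numeric(len); path_c <- numeric(len)
    for (s in seq_len(len)) {
      dir <- dir + rnorm(1, 0, 0.03)
      r <- r + sin(dir); c <- c + cos(dir)
      path_r[s] <- r; path_c[s] <- c
    }
    pr <- round(path_r); pc <- round(path_c)
    inside <- (pr - center[1L])^2 + (pc - center[2L])^2 <= (0.92 * radius)^2 &
      pr >= 1 & pr <= nr & pc >= 1 & pc <= nc
    pr <- pr[inside]; pc <- pc[inside]
    if (length(pr) < 0.4 * len) next
    rows <- rep(pr, each = nrow(offs)) + offs$dr
    cols <- rep(pc, each = nrow(offs)) + offs$dc
    ok <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
    idx <- unique((cols[ok] - 1L) * nr + rows[ok])
    # keep vessels disjoint so each ground-truth component stays elongated
    grow <- expand.grid(dr = -2:2, dc = -2:2)
    nb_rows <- rep(((idx - 1L) %% nr) + 1L, each = nrow(grow)) + grow$dr
    nb_cols <- rep(((idx - 1L) %/% nr) + 1L, each = nrow(grow)) + grow$dc
    okn <- nb_rows >= 1 & nb_rows <= nr & nb_cols >= 1 & nb_cols <= nc
    nb <- unique((nb_cols[okn] - 1L) * nr + nb_rows[okn])
    if (any(avoid[nb])) next
    m <- matrix(FALSE, nr, nc)
    m[idx] <- TRUE
    return(m)
  }
  NULL
}

#' Generate one synthetic fundus scene
#'
#' Deterministically renders a fundus-like RGB image together with exact
#' hemorrhage, vessel and retina ground-truth masks. Lesions are applied
#' last and multiplicatively, so every hemorrhage pixel is strictly
#' darker in the green channel than the same scene rendered without
#' lesions (the lesion-free green plane is returned as
#' \code{clean_green}).
#'
#' @param params [scene_params()] object.
#' @return object of class \code{synthetic_scene}: list with
#'   \code{image}, \code{hemorrhage_mask}, \code{vessel_mask},
#'   \code{retina_mask}, \code{clean_green} and \code{params}.
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  nr <- params$size[1L]; nc <- params$size[2L]
  .with_seed(params$seed, {
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    cen <- c((nr + 1) / 2, (nc + 1) / 2)
    radius <- 0.47 * min(nr, nc)
    d2 <- (rr - cen[1L])^2 + (cc - cen[2L])^2
    retina <- d2 <= radius^2

    # base reddish fundus tint with a smooth illumination ramp + texture
    theta <- runif(1, 0, 2 * pi)
    ramp <- params$illumination_gradient *
      (cos(theta) * (cc - cen[2L]) + sin(theta) * (rr - cen[1L])) /
      (2 * radius)
    texture <- 0
    for (i in seq_len(4)) {
      texture <- texture + runif(1, -0.03, 0.03) *
        .bump(rr, cc, runif(1, 0.2, 0.8) * nr, runif(1, 0.2, 0.8) * nc,
              runif(1, 0.15, 0.3) * min(nr, nc))
    }
    light <- 1 + ramp + texture
    red <- .clip01(0.78 * light)
    green <- .clip01(0.50 * light)
    blue <- .clip01(0.24 * light)

    # soft shadows darken multiplicatively
    for (i in seq_len(params$shadow_count)) {
      ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0.45, 0.85) * radius
      sh <- .bump(rr, cc, cen[1L] + rad * sin(ang), cen[2L] + rad * cos(ang),
                  runif(1, 0.12, 0.22) * min(nr, nc))
      f <- 1 - params$shadow_darkness * sh
      red <- red * f; green <- green * f; blue <- blue * f
    }

    # light-explosive highlights push toward saturation
    for (i in seq_len(params$light_blob_count)) {
      ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0.2, 0.7) * radius
      hl <- 0.85 * .bump(rr, cc, cen[1L] + rad * sin(ang),
                         cen[2L] + rad * cos(ang),
                         runif(1, 0.06, 0.12) * min(nr, nc))
      red <- red + hl * (1 - red)
      green <- green + hl * (1 - green)
      blue <- blue + hl * (1 - blue)
    }

    # dark curvilinear vessels
    vessel_mask <- matrix(FALSE, nr, nc)
    for (i in seq_len(params$vessel_count)) {
      vm <- .draw_vessel(c(nr, nc), radius, cen, params$vessel_width,
                         vessel_mask)
      if (is.null(vm)) next
      vessel_mask <- vessel_mask | vm
    }
    red[vessel_mask] <- red[vessel_mask] * 0.55
    green[vessel_mask] <- green[vessel_mask] * 0.35
    blue[vessel_mask] <- blue[vessel_mask] * 0.50

    clean_green <- green

    # multishade hemorrhages: concentric disks, darkest shade innermost
    hem_mask <- matrix(FALSE, nr, nc)
    for (hs in params$hemorrhage_specs) {
      ctr <- hs$center
      if (is.null(ctr)) {
        ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, 0.6) * radius
        ctr <- c(cen[1L] + rad * sin(ang), cen[2L] + rad * cos(ang))
      }
      if ((ctr[1L] - cen[1L])^2 + (ctr[2L] - cen[2L])^2 > radius^2)
        stop("hemorrhage center lies outside the retina")
      k <- length(hs$shades)
      radii <- hs$radius * seq_len(k) / k
      hd2 <- (rr - ctr[1L])^2 + (cc - ctr[2L])^2
      for (j in rev(seq_len(k))) {   # outermost ring first, core overwrites
        disk <- hd2 <= radii[j]^2 & retina
        f <- hs$shades[j]
        green[disk] <- clean_green[disk] * f
        red[disk] <- red[disk] * (0.5 + 0.5 * f)
        blue[disk] <- blue[disk] * f
      }
      hem_mask <- hem_mask | (hd2 <= hs$radius^2 & retina)
    }

    img <- array(0, c(nr, nc, 3L))
    img[, , 1L] <- red * retina
    img[, , 2L] <- green * retina
    img[, , 3L] <- blue * retina
    structure(list(image = .clip01(img),
                   hemorrhage_mask = hem_mask,
                   vessel_mask = vessel_mask & retina,
                   retina_mask = retina,
                   clean_green = clean_green * retina,
                   params = params),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic fundus scene %dx%d (seed %d)\n",
              x$params$size[1], x$params$size[2], x$params$seed))
  cat(sprintf("  hemorrhage pixels: %d in %d lesion(s); vessel pixels: %d\n",
              sum(x$hemorrhage_mask), length(x$params$hemorrhage_specs),
              sum(x$vessel_mask)))
  invisible(x)
}

# Default randomized multishade lesion specification for benchmark scenes.
.random_hemorrhage_specs <- function(size) {
  n_lesion <- 1L + (runif(1) < 0.4)
  lapply(seq_len(n_lesion), function(i) {
    k <- sample(2:3, 1L)
    core <- runif(1, 0.18, 0.28)
    outer <- runif(1, 0.55, 0.68)
    shades <- seq(core, outer, length.out = k)
    list(center = NULL, radius = runif(1, 0.06, 0.12) * min(size),
         shades = shades)
  })
}

#' Simulate labeled blob HSV features
#'
#' Draws candidate-blob feature vectors from two class-conditional
#' distributions mirroring the color structure of fundus candidates:
#' hemorrhagic blobs are deep red (hue near the 0/1 wrap point) with low
#' brightness, nonhemorrhagic blobs (background texture, shadow edges,
#' highlight rims) are orange-yellow hued, brighter and more saturated.
#' With the default separation the two classes have a clear margin in
#' the (saturation, brightness) plane.
#'
#' @param n total number of blobs (split roughly evenly between classes).
#' @param seed RNG seed.
#' @param separation multiplier on the class mean separation; 1 gives a
#'   clearly separable set, 0 makes the classes identical.
#' @return data frame with \code{h_mean}, \code{s_mean}, \code{v_mean}
#'   and a factor \code{label}.
#' @export
simulate_blob_features <- function(n = 200L, seed = 1L, separation = 1) {
  stopifnot(n >= 2)
  n_hem <- n %/% 2L
  n_non <- n - n_hem
  .with_seed(seed, {
    hem <- data.frame(
      h_mean = (stats::rnorm(n_hem, 0.985, 0.01)) %% 1,
      s_mean = .clip01(stats::rnorm(n_hem, 0.60 - 0.22 * separation, 0.04)),
      v_mean = .clip01(stats::rnorm(n_hem, 0.62 - 0.35 * separation, 0.05)),
      label = "hemorrhagic")
    non <- data.frame(
      h_mean = (stats::rnorm(n_non, 0.07, 0.02)) %% 1,
      s_mean = .clip01(stats::rnorm(n_non, 0.60, 0.04)),
      v_mean = .clip01(stats::rnorm(n_non, 0.62, 0.05)),
      label = "nonhemorrhagic")
    out <- rbind(hem, non)
    out <- out[sample.int(nrow(out)), ]
    rownames(out) <- NULL
    out$label <- factor(out$label,
                        levels = c("nonhemorrhagic", "hemorrhagic"))
    out
  })
}

#' Generate a benchmark of synthetic scenes
#'
#' Produces a mixed set of hemorrhagic and nonhemorrhagic scenes with a
#' manifest of per-scene ground truth. Per-scene seeds are derived
#' deterministically from the master seed, so any single scene can be
#' regenerated in isolation from its manifest row.
#'
#' @param n_scenes number of scenes.
#' @param seed master seed.
#' @param size per-scene image size \code{c(rows, cols)}.
#' @param prop_hemorrhagic fraction of scenes containing hemorrhages
#'   (default 0.5, a 50-50 case mix).
#' @param ... further arguments passed to [scene_params()] for every
#'   scene (e.g. \code{vessel_count}).
#' @return object of class \code{fundus_benchmark}: list with
#'   \code{scenes} (list of \code{synthetic_scene}) and \code{manifest}
#'   (data frame with scene id, derived seed, hemorrhage presence and
#'   pixel counts).
#' @export
generate_benchmark <- function(n_scenes, seed = 1L, size = c(598L, 597L),
                               prop_hemorrhagic = 0.5, ...) {
  stopifnot(n_scenes >= 1)
  n_hem <- round(n_scenes * prop_hemorrhagic)
  hem_flag <- rep(FALSE, n_scenes)
  scene_seeds <- (as.integer(seed) + 7919L * seq_len(n_scenes)) %% 2147483629L
  .with_seed(seed, {
    hem_flag[sample.int(n_scenes, n_hem)] <- TRUE
  })
  scenes <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    specs <- if (hem_flag[i]) {
      .with_seed(scene_seeds[i] + 1L, .random_hemorrhage_specs(size))
    } else list()
    scenes[[i]] <- generate_scene(scene_params(
      seed = scene_seeds[i], size = size, hemorrhage_specs = specs, ...))
  }
  manifest <- data.frame(
    scene_id = seq_len(n_scenes),
    seed = scene_seeds,
    has_hemorrhage = hem_flag,
    n_hemorrhages = vapply(scenes, function(s)
      length(s$params$hemorrhage_specs), integer(1)),
    hemorrhage_pixels = vapply(scenes, function(s)
      sum(s$hemorrhage_mask), integer(1)),
    vessel_pixels = vapply(scenes, function(s)
      sum(s$vessel_mask), integer(1)))
  structure(list(scenes = scenes, manifest = manifest, seed = seed),
            class = "fundus_benchmark")
}

#' @export
print.fundus_benchmark <- function(x, ...) {
  cat(sprintf("synthetic fundus benchmark: %d scenes (seed %d), %d hemorrhagic\n",
              nrow(x$manifest), x$seed, sum(x$manifest$has_hemorrhage)))
  invisible(x)
}

#' Write a benchmark to disk
#'
#' Writes \code{scene_NNN.png} plus \code{_hem}, \code{_vessel} and
#' \code{_retina} mask PNGs and \code{manifest.csv} to a directory.
#'
#' @param bench \code{fundus_benchmark} object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "fundus_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(bench$scenes)) {
    s <- bench$scenes[[i]]
    stem <- file.path(dir, sprintf("scene_%03d", i))
    write_image(s$image, paste0(stem, ".png"))
    write_mask(s$hemorrhage_mask, paste0(stem, "_hem.png"))
    write_mask(s$vessel_mask, paste0(stem, "_vessel.png"))
    write_mask(s$retina_mask, paste0(stem, "_retina.png"))
  }
  write.csv(bench$manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}
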