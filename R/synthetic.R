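# Seeded generator of synthetic nodule-like image/mask fixtures.
#
# Five morphologies mirror the recurring segmentation challenges in chest
# CT: C1 a clearly bounded solitary nodule, C2 a sub-5-pixel nodule among
# vessel-like distractors, C3 a nodule adherent to a matched-intensity
# tubular structure, C4 a cavitary nodule (bright rim, dark core), and C5 a
# spiculated nodule with radiating extensions. One image pixel corresponds
# to one millimetre at the fixture scale, so the default diameters follow
# the representative clinical cases (14.83, 4.74, 19.79, 16.45, 25.31 mm).

.morphologies <- c("clear", "small", "adherent", "cavitary", "spiculated")

.default_diameters <- c(clear = 14.83, small = 4.74, adherent = 19.79,
                        cavitary = 16.45, spiculated = 25.31)

#' Specify a synthetic nodule fixture
#'
#' @param morphology one of `"clear"` (C1), `"small"` (C2), `"adherent"`
#'   (C3), `"cavitary"` (C4), `"spiculated"` (C5).
#' @param diameter_px nodule diameter in pixels (1 px = 1 mm); defaults to
#'   the representative diameter of the morphology. The small class
#'   requires `diameter_px < 5`.
#' @param center `(row, col)` nodule centre; defaults near the image centre
#'   with seeded jitter.
#' @param contrast nodule-to-background intensity difference in `[0, 1]`.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @param seed integer seed; fixtures are bitwise reproducible per
#'   spec + seed.
#' @param size image side in pixels.
#' @return list of class `nodule_spec`.
#' @export
nodule_spec <- function(morphology = "clear", diameter_px = NULL,
                        center = NULL, contrast = 0.6, noise_sigma = 0.05,
                        seed = 1L, size = 64L) {
  morphology <- match.arg(morphology, .morphologies)
  if (is.null(diameter_px)) diameter_px <- .default_diameters[[morphology]]
  if (diameter_px < 1) stop("diameter_px must be >= 1")
  if (morphology == "small" && diameter_px >= 5) {
    stop("small-morphology nodules must have diameter_px < 5")
  }
  if (!is.null(center) &&
      (any(center < 1) || any(center > size))) {
    stop("center must lie inside the image")
  }
  structure(list(morphology = morphology, diameter_px = diameter_px,
                 center = center, contrast = contrast,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 size = as.integer(size)),
            class = "nodule_spec")
}

# low-frequency background texture: a few random cosine waves
.background <- function(size) {
  r <- matrix(rep(seq_len(size), size), size)
  c <- t(r)
  bg <- matrix(0.15, size, size)
  for (k in 1:3) {
    f <- stats::runif(2, 0.01, 0.05)
    ph <- stats::runif(1, 0, 2 * pi)
    bg <- bg + 0.03 * cos(2 * pi * (f[1] * r + f[2] * c) + ph)
  }
  bg
}

# draw a curvilinear bright structure (vessel-like), returning an intensity
# field in [0, 1]; `avoid` is an optional (row, col, radius) exclusion zone
.vessel_field <- function(size, thickness = 1.5, avoid = NULL) {
  p0 <- stats::runif(2, 1, size)
  p1 <- stats::runif(2, 1, size)
  pc <- (p0 + p1) / 2 + stats::runif(2, -size / 4, size / 4)
  ts <- seq(0, 1, length.out = 4 * size)
  pts <- outer((1 - ts)^2, p0) + outer(2 * ts * (1 - ts), pc) +
    outer(ts^2, p1)
  r <- matrix(rep(seq_len(size), size), size)
  c <- t(r)
  d2 <- matrix(Inf, size, size)
  for (i in seq_along(ts)) {
    d2 <- pmin(d2, (r - pts[i, 1])^2 + (c - pts[i, 2])^2)
  }
  f <- exp(-d2 / (2 * thickness^2))
  if (!is.null(avoid)) {
    keep <- sqrt((r - avoid[1])^2 + (c - avoid[2])^2) > avoid[3]
    f <- f * keep
  }
  f
}

#' Generate one synthetic image/mask fixture
#'
#' Renders the morphology described by the spec onto a low-frequency
#' textured background, adds Gaussian noise to the image, and returns the
#' noiseless nodule support as the binary mask (distractor structures such
#' as vessels are never part of the mask). Deterministic per spec + seed;
#' the session RNG state is left untouched.
#'
#' @param spec a [nodule_spec()].
#' @return list of class `caaf_fixture` with `image` (H x W matrix in
#'   `[0, 1]`), `mask` (binary H x W matrix), and `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "nodule_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  size <- spec$size
  r0 <- spec$diameter_px / 2
  ctr <- spec$center
  if (is.null(ctr)) {
    margin <- min(size / 2 - 1, r0 + 4)
    ctr <- (size + 1) / 2 + stats::runif(2, -3, 3)
    ctr <- pmin(pmax(ctr, 1 + margin), size - margin)
  }
  rows <- matrix(rep(seq_len(size), size), size)
  cols <- t(rows)
  dx <- rows - ctr[1]
  dy <- cols - ctr[2]
  theta <- atan2(dy, dx)
  rho <- sqrt(dx^2 + dy^2)

  img <- .background(size)
  soft <- function(boundary) 1 / (1 + exp(-(boundary - rho) * 2.5))

  morph <- spec$morphology
  if (morph %in% c("clear", "small", "adherent")) {
    ecc <- stats::runif(1, 0.85, 1)
    ang <- stats::runif(1, 0, pi)
    u <- dx * cos(ang) + dy * sin(ang)
    v <- -dx * sin(ang) + dy * cos(ang)
    rho_e <- sqrt((u / 1)^2 + (v / ecc)^2)
    mask <- (rho_e <= r0) * 1
    blob <- 1 / (1 + exp(-(r0 - rho_e) * 2.5))
    img <- img + spec$contrast * blob
    if (morph == "small") {
      for (k in seq_len(2 + stats::rbinom(1, 1, 0.5))) {
        img <- img + spec$contrast *
          .vessel_field(size, avoid = c(ctr, r0 + 2))
      }
    }
    if (morph == "adherent") {
      # matched-intensity tube through the nodule rim
      ang_t <- stats::runif(1, 0, pi)
      off <- r0 * stats::runif(1, 0.6, 0.9)
      dist_line <- abs(dx * sin(ang_t) - dy * cos(ang_t) - off)
      tube <- 1 / (1 + exp(-(1.8 - dist_line) * 2.5))
      img <- img + spec$contrast * pmax(tube - blob, 0)
    }
  } else if (morph == "cavitary") {
    r_in <- 0.45 * r0
    mask <- (rho <= r0 & rho > r_in) * 1
    rim <- soft(r0) * (1 - 1 / (1 + exp(-(r_in - rho) * 2.5)))
    img <- img + spec$contrast * rim
    # dark core below the background level
    core <- 1 / (1 + exp(-(r_in - rho) * 2.5))
    img <- img - 0.08 * core
  } else { # spiculated
    n_spike <- sample(6:9, 1)
    ph <- stats::runif(1, 0, 2 * pi)
    r_theta <- r0 * (0.65 + 0.35 * cos(n_spike * theta + ph))
    mask <- (rho <= r_theta) * 1
    star <- 1 / (1 + exp(-(r_theta - rho) * 2.5))
    img <- img + spec$contrast * star
  }

  img <- img + stats::rnorm(size * size, 0, spec$noise_sigma)
  img <- pmin(pmax(img, 0), 1)
  if (!any(mask > 0)) {
    stop("degenerate spec: rendered mask has no foreground")
  }
  structure(list(image = img, mask = mask, spec = spec),
            class = "caaf_fixture")
}

#' Generate a seeded synthetic dataset
#'
#' Allocates `n` fixtures across morphologies by largest-remainder rounding
#' of the requested mix, derives one sub-seed per fixture from the master
#' seed by a fixed counter recurrence (so different master seeds yield
#' disjoint streams), and shuffles the class order deterministically.
#'
#' @param n number of fixtures.
#' @param morphology_mix named proportions over
#'   `c("clear","small","adherent","cavitary","spiculated")`; must sum to 1.
#'   Defaults to the uniform mix.
#' @param image_size image side in pixels.
#' @param seed master seed.
#' @param ... further arguments passed to [nodule_spec()] (e.g. `contrast`,
#'   `noise_sigma`).
#' @return list of `caaf_fixture` objects.
#' @export
generate_dataset <- function(n, morphology_mix = NULL, image_size = 64L,
                             seed = 1L, ...) {
  if (is.null(morphology_mix)) {
    morphology_mix <- stats::setNames(rep(1 / 5, 5), .morphologies)
  }
  morphology_mix <- morphology_mix[.morphologies[.morphologies %in%
                                                   names(morphology_mix)]]
  if (abs(sum(morphology_mix) - 1) > 1e-8) {
    stop("morphology_mix proportions must sum to 1")
  }
  # largest-remainder allocation
  raw <- n * morphology_mix
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  classes <- rep(names(counts), counts)
  # deterministic interleave without touching the session RNG
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  classes <- sample(classes)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  lapply(seq_len(n), function(i) {
    sub_seed <- (as.double(seed) * 1000003 + 7919 * i) %% 2147483647
    generate_fixture(nodule_spec(morphology = classes[i], seed = sub_seed,
                                 size = image_size, ...))
  })
}

#' Write fixtures as paired PNG files with a manifest
#'
#' Writes `img_0001.png` / `msk_0001.png` pairs plus `manifest.csv`
#' describing each fixture's spec.
#'
#' @param fixtures list of fixtures from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
write_fixtures <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(fixtures), function(i) {
    f <- fixtures[[i]]
    img_file <- sprintf("img_%04d.png", i)
    msk_file <- sprintf("msk_%04d.png", i)
    EBImage::writeImage(t(f$image), file.path(dir, img_file))
    EBImage::writeImage(t(f$mask), file.path(dir, msk_file))
    data.frame(id = i, image = img_file, mask = msk_file,
               morphology = f$spec$morphology,
               diameter_px = f$spec$diameter_px,
               contrast = f$spec$contrast,
               noise_sigma = f$spec$noise_sigma,
               seed = f$spec$seed, size = f$spec$size)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read an image/mask directory written by [write_fixtures()]
#'
#' @param dir directory containing `img_*.png`, `msk_*.png`, `manifest.csv`.
#' @return list of fixtures (masks re-binarized at 0.5).
#' @export
read_fixtures <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    read_gray <- function(path) {
      t(EBImage::imageData(EBImage::readImage(path)))
    }
    img <- read_gray(file.path(dir, manifest$image[i]))
    msk <- read_gray(file.path(dir, manifest$mask[i]))
    structure(list(image = img, mask = (msk >= 0.5) * 1,
                   spec = as.list(manifest[i, ])), class = "caaf_fixture")
  })
}
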