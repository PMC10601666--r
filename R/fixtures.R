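# Synthetic data generators: mosaic atlases, rendered two-channel sections
# with ground-truth cell tables, and whole dimorphic cohorts. Everything is a
# pure function of its arguments plus a seed, so downstream stages are
# testable without any external imagery.

#' Generate a synthetic mosaic atlas
#'
#' Each slice is an elliptical "brain" whose left half is partitioned into
#' contiguous nearest-seed (Voronoi) patches of the requested regions, then
#' mirrored about the midline so left/right hemispheres carry identical
#' labels. Leaf region ids are 1..n_regions; synthetic meta parents and the
#' root ("BRAIN") take the ids above them and never appear in a mask. Every
#' region appears in every slice.
#'
#' Hierarchy tiers: regions are assigned round-robin to synthetic "meta"
#' parents (one meta node per ~5 regions) so tier aggregation is exercised.
#'
#' @param n_slices number of coronal slices (>= 1).
#' @param n_regions number of leaf regions (>= 2).
#' @param image_size `c(height, width)` in pixels, each >= 32.
#' @param seed integer seed; same seed gives bit-identical masks.
#' @param ap_range AP coordinates of first/last slice, mm from bregma.
#' @return a `region_atlas`.
#' @export
make_synthetic_atlas <- function(n_slices, n_regions, image_size = c(96, 128),
                                 seed = 1L, ap_range = c(3.0, -4.0)) {
  stopifnot(n_slices >= 1, n_regions >= 2, length(image_size) == 2)
  h <- image_size[1]; w <- image_size[2]
  if (h < 32 || w < 32) stop("image_size must be at least 32x32")
  half_w <- w %/% 2
  # each region patch needs room; cap so nearest-seed patches stay non-empty
  if (n_regions > (h * half_w) / 64) {
    stop("n_regions = ", n_regions, " exceeds representable patches for ",
         h, "x", w, " slices")
  }

  leaf_ids <- seq_len(n_regions)
  n_meta <- max(1L, ceiling(n_regions / 5))
  meta_ids <- seq.int(n_regions + 1L, n_regions + n_meta)
  root_id <- n_regions + n_meta + 1L
  nodes <- rbind(
    data.frame(id = root_id, acronym = "BRAIN", name = "synthetic brain root",
               parent_id = NA_integer_, level_tag = "meta"),
    data.frame(id = meta_ids,
               acronym = sprintf("META%d", seq_len(n_meta)),
               name = sprintf("synthetic meta region %d", seq_len(n_meta)),
               parent_id = root_id, level_tag = "meta"),
    data.frame(id = leaf_ids,
               acronym = sprintf("R%d", seq_len(n_regions)),
               name = sprintf("synthetic region %d", seq_len(n_regions)),
               parent_id = meta_ids[((seq_len(n_regions) - 1L) %% n_meta) + 1L],
               level_tag = "leaf")
  )

  ap <- if (n_slices == 1) ap_range[1] else
    seq(ap_range[1], ap_range[2], length.out = n_slices)

  rng <- .seeded_rng(seed)
  slices <- lapply(seq_len(n_slices), function(si) {
    # elliptical brain footprint
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    inside <- ((yy - cy) / (0.45 * h))^2 + ((xx - cx) / (0.45 * w))^2 <= 1
    # nearest-seed partition of the left half; seeds are distinct in-brain
    # pixels, so every region owns at least its own seed pixel
    left_cols <- seq_len(half_w)
    in_left <- which(inside[, left_cols])
    pick <- rng$sample(in_left, n_regions)
    sy <- (pick - 1) %% h + 1
    sx <- (pick - 1) %/% h + 1
    lab <- matrix(0L, h, w)
    lx <- xx[, left_cols, drop = FALSE]
    ly <- yy[, left_cols, drop = FALSE]
    d2 <- array(0, dim = c(h, length(left_cols), n_regions))
    for (r in seq_len(n_regions)) {
      d2[, , r] <- (lx - sx[r])^2 + (ly - sy[r])^2
    }
    nearest <- apply(d2, c(1, 2), which.min)
    left_lab <- matrix(leaf_ids[nearest], h, length(left_cols))
    left_lab[!inside[, left_cols]] <- 0L
    lab[, left_cols] <- left_lab
    lab[, w - left_cols + 1L] <- left_lab  # mirror about midline_x = w/2
    storage.mode(lab) <- "integer"
    atlas_slice(lab, ap[si], pixel_size_um = 10, midline_x = w / 2)
  })
  region_atlas(nodes, slices)
}

# Small self-contained RNG wrapper: localizes set.seed so generators are pure
# functions of (args, seed) without clobbering the caller's RNG state.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  call_with <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(runif = call_with(stats::runif), rnorm = call_with(stats::rnorm),
       rpois = call_with(stats::rpois), sample = call_with(base::sample),
       rnbinom = call_with(stats::rnbinom))
}

#' Build a ground-truth cell table
#'
#' @param x,y 0-based pixel coordinates.
#' @param radius_px cell radii in pixels (> 0).
#' @param peak_intensity peak intensity above background.
#' @param channel `"helper"`, `"rabies"` or `"both"` per cell.
#' @param region_id atlas region id per cell.
#' @return a data.frame classed `truth_cells`; `is_starter` is derived
#'   (`channel == "both"`).
#' @export
truth_cells <- function(x, y, radius_px, peak_intensity, channel, region_id) {
  stopifnot(all(radius_px > 0),
            all(channel %in% c("helper", "rabies", "both")))
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   radius_px = as.numeric(radius_px),
                   peak_intensity = as.numeric(peak_intensity),
                   channel = as.character(channel),
                   region_id = as.integer(region_id),
                   is_starter = channel == "both")
  class(df) <- c("truth_cells", "data.frame")
  df
}

#' Render a two-channel section image from a truth table
#'
#' Each cell is drawn as a disk convolved with a Gaussian point-spread
#' function, scaled so its peak sits `peak_intensity` above background;
#' `"both"`-channel cells are drawn in helper and rabies channels. Additive
#' Gaussian background noise is applied per channel.
#'
#' @param cells a [truth_cells()] table (0-based coordinates).
#' @param image_size `c(height, width)`.
#' @param noise list with `background_mean`, `background_sd`, `psf_sigma_px`.
#' @param seed integer seed for the noise.
#' @return list with matrices `helper` and `rabies`.
#' @export
render_section <- function(cells, image_size,
                           noise = list(background_mean = 100,
                                        background_sd = 8, psf_sigma_px = 1),
                           seed = 1L) {
  h <- image_size[1]; w <- image_size[2]
  oob <- which(cells$x < 0 | cells$x > w - 1 | cells$y < 0 | cells$y > h - 1)
  if (length(oob)) {
    stop("cells out of image bounds at row(s): ", paste(oob, collapse = ", "))
  }
  rng <- .seeded_rng(seed)
  render_channel <- function(chan) {
    img <- matrix(rng$rnorm(h * w, noise$background_mean, noise$background_sd),
                  h, w)
    sel <- cells$channel %in% c(chan, "both")
    sig <- noise$psf_sigma_px
    for (i in which(sel)) {
      cx <- cells$x[i] + 1; cy <- cells$y[i] + 1  # to 1-based
      r <- cells$radius_px[i]
      ext <- ceiling(r + 4 * sig)
      rows <- max(1, floor(cy - ext)):min(h, ceiling(cy + ext))
      cols <- max(1, floor(cx - ext)):min(w, ceiling(cx + ext))
      d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, `+`))
      # radial profile of a disk blurred along the radius; peak == 1 center
      prof <- stats::pnorm((r - d) / sig) / stats::pnorm(r / sig)
      img[rows, cols] <- img[rows, cols] + cells$peak_intensity[i] * prof
    }
    pmax(img, 0)
  }
  list(helper = render_channel("helper"), rabies = render_channel("rabies"))
}

#' Specification of a synthetic two-sex cohort
#'
#' @param regions data.frame with `region_id`, `base_pps` (female
#'   presynaptic-per-starter rate, >= 0) and `male_multiplier` (> 0;
#'   multiplicative sex effect on PPS).
#' @param n_male,n_female hemisphere samples per sex (>= 1).
#' @param starter_mean mean starter count per hemisphere (> 0).
#' @param starter_target_region region receiving most starters.
#' @param spill_fraction fraction of starters scattered outside the target
#'   (default 0.1, so the 60%-in-target QC gate is exercisable both ways).
#' @param noise imaging noise parameters (used when rendering images).
#' @param overdispersion if > 0, negative-binomial counts with this
#'   dispersion (size = 1/overdispersion); 0 (default) gives Poisson counts.
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(regions, n_male = 7L, n_female = 7L,
                        starter_mean = 50, starter_target_region = 2L,
                        spill_fraction = 0.1,
                        noise = list(background_mean = 100, background_sd = 8,
                                     psf_sigma_px = 1),
                        overdispersion = 0, seed = 1L) {
  stopifnot(is.data.frame(regions),
            all(c("region_id", "base_pps", "male_multiplier") %in% names(regions)),
            all(regions$base_pps >= 0), all(regions$male_multiplier > 0),
            n_male >= 1, n_female >= 1, starter_mean > 0,
            spill_fraction >= 0, spill_fraction < 1)
  structure(list(regions = regions, n_male = as.integer(n_male),
                 n_female = as.integer(n_female), starter_mean = starter_mean,
                 starter_target_region = as.integer(starter_target_region),
                 spill_fraction = spill_fraction, noise = noise,
                 overdispersion = overdispersion, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a dimorphic cohort of hemisphere samples (counts only)
#'
#' Per hemisphere: total starters ~ Poisson(starter_mean) conditioned >= 1,
#' split (1 - spill) into the target region and spill across the others;
#' per region, presynaptic ~ Poisson(pps * starters) with
#' pps = base_pps * male_multiplier for males and base_pps for females.
#'
#' @param spec a [cohort_spec()].
#' @param atlas a `region_atlas` containing all spec region ids.
#' @return list with `samples` (list of [hemisphere_sample()]) and `truth`
#'   (data.frame of expected PPS per region and sex).
#' @export
simulate_cohort <- function(spec, atlas) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(atlas, "region_atlas"))
  bad <- setdiff(spec$regions$region_id, atlas$nodes$id)
  if (length(bad)) stop("spec region id(s) not in atlas: ", paste(bad, collapse = ", "))
  rng <- .seeded_rng(spec$seed)
  rids <- as.integer(spec$regions$region_id)
  others <- setdiff(rids, spec$starter_target_region)

  draw_count <- function(n, mu) {
    if (spec$overdispersion > 0) {
      rng$rnbinom(n, size = 1 / spec$overdispersion, mu = mu)
    } else {
      rng$rpois(n, mu)
    }
  }

  make_sample <- function(sex, idx) {
    total_starters <- 0L
    while (total_starters < 1L) total_starters <- rng$rpois(1, spec$starter_mean)
    n_spill <- if (length(others)) {
      sum(rng$runif(total_starters) < spec$spill_fraction)
    } else 0L
    starters <- stats::setNames(rep(0L, length(rids)), rids)
    starters[as.character(spec$starter_target_region)] <- total_starters - n_spill
    if (n_spill > 0) {
      sp <- rng$sample(as.character(others), n_spill, replace = TRUE)
      tab <- table(sp)
      starters[names(tab)] <- starters[names(tab)] + as.integer(tab)
    }
    rate <- spec$regions$base_pps *
      if (sex == "male") spec$regions$male_multiplier else 1
    presyn <- stats::setNames(as.integer(draw_count(length(rids), rate * total_starters)),
                              rids)
    hemisphere_sample(
      sample_id = sprintf("%s%d", toupper(substr(sex, 1, 1)), idx),
      sex = sex, target = "amygdala",
      side = if (idx %% 2 == 1) "left" else "right",
      starters = starters, presynaptic = presyn
    )
  }

  samples <- c(lapply(seq_len(spec$n_male), function(i) make_sample("male", i)),
               lapply(seq_len(spec$n_female), function(i) make_sample("female", i)))
  truth <- data.frame(
    region_id = rids,
    pps_male = spec$regions$base_pps * spec$regions$male_multiplier,
    pps_female = spec$regions$base_pps
  )
  list(samples = samples, truth = truth)
}

#' Place non-overlapping cells inside atlas regions of one slice
#'
#' Used to build image-level fixtures whose truth table is consistent with
#' the atlas: sampling is uniform over each region's pixels with a minimum
#' centre-to-centre spacing enforced by rejection.
#'
#' @param slice an `atlas_slice`.
#' @param counts named integer vector: region id -> number of cells.
#' @param channel channel label for all placed cells.
#' @param radius_px,peak_intensity cell rendering parameters.
#' @param min_spacing_px minimum distance between any two placed centres.
#' @param seed integer seed.
#' @return a [truth_cells()] table (0-based coordinates).
#' @export
place_cells <- function(slice, counts, channel, radius_px = 4,
                        peak_intensity = 80, min_spacing_px = 4 * radius_px,
                        seed = 1L) {
  rng <- .seeded_rng(seed)
  mask <- slice$label_mask
  pts <- matrix(numeric(0), 0, 2)
  out <- list()
  for (rid in names(counts)) {
    n <- counts[[rid]]
    if (n == 0) next
    idx <- which(mask == as.integer(rid))
    if (!length(idx)) stop("region ", rid, " absent from slice mask")
    rows <- (idx - 1) %% nrow(mask) + 1
    cols <- (idx - 1) %/% nrow(mask) + 1
    placed <- 0L; tries <- 0L
    while (placed < n && tries < 200L * n) {
      tries <- tries + 1L
      j <- rng$sample(length(idx), 1L)
      x <- cols[j] - 1 + rng$runif(1, -0.4, 0.4)
      y <- rows[j] - 1 + rng$runif(1, -0.4, 0.4)
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - x)^2 + (pts[, 2] - y)^2)) >= min_spacing_px) {
        pts <- rbind(pts, c(x, y))
        out[[length(out) + 1]] <- data.frame(x = x, y = y, region_id = as.integer(rid))
        placed <- placed + 1L
      }
    }
    if (placed < n) {
      stop("could not place ", n, " cells in region ", rid,
           " with spacing ", min_spacing_px, " px")
    }
  }
  if (!length(out)) {
    return(truth_cells(numeric(0), numeric(0), numeric(0), numeric(0),
                       character(0), integer(0)))
  }
  df <- do.call(rbind, out)
  truth_cells(df$x, df$y, radius_px, peak_intensity, channel, df$region_id)
}
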