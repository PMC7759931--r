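#' Generate a phantom lesion volume and mask
#'
#' Synthetic 3D intensity grids for exercising the extraction chain: a
#' spherical lesion mask (single connected component by construction) filled
#' with one of three textures — a constant intensity, a two-level 3D
#' checkerboard, or spatially correlated Gaussian noise (white noise
#' smoothed by a separable Gaussian kernel and rescaled to the target
#' standard deviation). Intensities are clipped to \[-1000, 1000\] HU. These
#' phantoms exercise the feature definitions, not CT anatomy or scanner
#' physics.
#'
#' @param shape voxel dimensions (length 3, each >= 3 recommended).
#' @param spacing voxel spacing in mm.
#' @param texture list: `list(type = "constant", value = 50)`,
#'   `list(type = "checker", period = 1, low = 0, high = 100)`, or
#'   `list(type = "noise", mean = 0, sd = 30, corr_length = 3)` (correlation
#'   length in voxels).
#' @param mask_radius sphere radius in mm (centered in the volume), or
#'   `NULL` for an all-ones mask.
#' @param seed integer seed (used by the noise texture).
#' @return list with `volume` (array), `mask` (logical array) and
#'   `spacing`.
#' @export
generate_lesion_phantom <- function(shape = c(24, 24, 24),
                                    spacing = c(1, 1, 1),
                                    texture = list(type = "constant",
                                                   value = 50),
                                    mask_radius = NULL, seed = 1) {
  stopifnot(length(shape) == 3, length(spacing) == 3)
  set.seed(seed)
  vol <- switch(texture$type,
    constant = array(texture$value, shape),
    checker = {
      period <- if (is.null(texture$period)) 1 else texture$period
      lv <- c(if (is.null(texture$low)) 0 else texture$low,
              if (is.null(texture$high)) 100 else texture$high)
      ci <- slice.index(array(0, shape), 1)
      cj <- slice.index(array(0, shape), 2)
      ck <- slice.index(array(0, shape), 3)
      par <- (floor((ci - 1) / period) + floor((cj - 1) / period) +
                floor((ck - 1) / period)) %% 2
      array(lv[par + 1], shape)
    },
    noise = {
      m <- if (is.null(texture$mean)) 0 else texture$mean
      s <- if (is.null(texture$sd)) 30 else texture$sd
      cl <- if (is.null(texture$corr_length)) 3 else texture$corr_length
      w <- array(rnorm(prod(shape)), shape)
      sm <- .gauss_smooth3(w, cl)
      sm <- sm - mean(sm)
      sdv <- sd(as.vector(sm))
      if (sdv > 0) sm <- sm / sdv
      m + s * sm
    },
    stop(sprintf("unknown texture type '%s'", texture$type), call. = FALSE)
  )
  vol <- pmin(pmax(vol, -1000), 1000)
  vol <- array(vol, shape)
  if (is.null(mask_radius)) {
    mask <- array(TRUE, shape)
  } else {
    ctr <- shape * spacing / 2
    ci <- (slice.index(vol, 1) - 0.5) * spacing[1]
    cj <- (slice.index(vol, 2) - 0.5) * spacing[2]
    ck <- (slice.index(vol, 3) - 0.5) * spacing[3]
    mask <- (ci - ctr[1])^2 + (cj - ctr[2])^2 + (ck - ctr[3])^2 <=
      mask_radius^2
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  list(volume = vol, mask = mask, spacing = spacing)
}

# Separable Gaussian smoothing with edge-replicated padding.
.gauss_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) {
    arr <- apply(arr, setdiff(1:3, ax), function(line) {
      padded <- c(rep(line[1], r), line, rep(line[length(line)], r))
      as.vector(stats::filter(padded, k, sides = 2))[(r + 1):(r + length(line))]
    })
    # apply collapses the chosen axis to the first dimension; restore order
    perm <- order(c(ax, setdiff(1:3, ax)))
    arr <- aperm(array(arr, c(d[ax], d[setdiff(1:3, ax)])), perm)
  }
  arr
}
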