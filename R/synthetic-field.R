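## Synthetic field rendering. Channels are built as photon-scale "signal"
## images per focal layer, defocus-blurred into each z-slice, then corrupted
## with Poisson shot noise + Gaussian read noise (standard camera model).

.discBrush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(ceiling(radius)) + 1L, shape = "disc")
}

## strip the EBImage Image class back to a plain matrix
.asMat <- function(img) {
  d <- dim(img)
  matrix(EBImage::imageData(img), d[1], d[2])
}

.gblurMat <- function(m, sigma) {
  if (sigma <= 0 || all(m == 0)) return(m)
  ## EBImage images are [x, y]; our matrices are [y, x] -- the blur is
  ## isotropic so no transpose is needed.
  .asMat(EBImage::gblur(EBImage::Image(m), sigma = sigma,
                           boundary = "replicate"))
}

## integer-shift with constant padding; new[y, x] = old[y - dy, x - dx]
.shiftMatrix <- function(m, dy, dx, pad) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(pad, H, W)
  ys <- max(1L, 1L + dy):min(H, H + dy)
  xs <- max(1L, 1L + dx):min(W, W + dx)
  if (length(ys) && length(xs))
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

## smoothed random-walk polylines, returned as a binary centre-line image
.rasterNeurites <- function(H, W, n_segments) {
  canvas <- matrix(0, H, W)
  n_steps <- round(0.9 * max(H, W))
  for (i in seq_len(max(0L, n_segments))) {
    y <- runif(1, 0.1 * H, 0.9 * H); x <- runif(1, 0.1 * W, 0.9 * W)
    theta <- runif(1, 0, 2 * pi)
    for (s in seq_len(n_steps)) {
      theta <- theta + rnorm(1, 0, 0.15)
      y <- y + sin(theta); x <- x + cos(theta)
      if (y < 1 || y > H || x < 1 || x > W) { # reflect at the border
        y <- min(max(y, 1), H); x <- min(max(x, 1), W)
        theta <- theta + pi / 2
      }
      canvas[round(y), round(x)] <- 1
    }
  }
  canvas
}

## 2-D Gaussian spot whose FWHM footprint matches the requested equivalent
## diameter (sigma = d / 2.355)
.addSpot <- function(img, cy, cx, d, amp) {
  sigma <- d / 2.355
  r <- ceiling(3 * sigma)
  ys <- max(1, cy - r):min(nrow(img), cy + r)
  xs <- max(1, cx - r):min(ncol(img), cx + r)
  g <- outer(ys - cy, xs - cx,
             function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  img[ys, xs] <- img[ys, xs] + amp * g
  img
}

## filled ellipse; with gradient = TRUE the interior carries a radial
## intensity falloff (bright centre), which both mimics real chromatin /
## soma staining and gives the nuclear and dendrite channels the sharply
## localized per-pixel correlation the MI alignment relies on
.addEllipse <- function(img, cy, cx, a, b, theta, amp, gradient = TRUE) {
  r <- ceiling(max(a, b))
  ys <- max(1, cy - r):min(nrow(img), cy + r)
  xs <- max(1, cx - r):min(ncol(img), cx + r)
  ct <- cos(theta); st <- sin(theta)
  for (y in ys) {
    dy <- y - cy; dxs <- xs - cx
    u <- (dy * ct + dxs * st) / a
    v <- (-dy * st + dxs * ct) / b
    rho2 <- u^2 + v^2
    hit <- rho2 <= 1
    val <- if (gradient) amp * (1 - 0.6 * rho2[hit]) else rep(amp, sum(hit))
    img[y, xs[hit]] <- pmax(img[y, xs[hit]], val)
  }
  img
}

#' Generate one synthetic three-channel field with ground truth
#'
#' Renders a field emulating the assay's structure: a curvilinear neurite
#' network (random-walk polylines dilated to \code{neurite_width} px with a
#' Gaussian intensity profile) in the dendrite channel; small Gaussian
#' puncta placed on and off the neurite mask in the presynaptic channel;
#' elliptical nuclei of two classes in the nuclear channel, with neuronal
#' nuclei additionally carrying a dendrite-channel soma blob. Objects are
#' distributed over up to three focal planes and defocus-blurred into the
#' remaining slices so that maximum projection is meaningful; acquisition
#' artifacts (channel shift, illumination gradient) are applied last.
#'
#' Identical \code{(spec, artifacts)} yield bit-identical output; the RNG
#' state of the caller is left untouched.
#'
#' @param spec a [FieldSpec-class].
#' @param artifacts an [ArtifactSpec-class] (default: no artifacts).
#' @param plate_id,well,field_index identifiers stamped on the output.
#' @return A list with components \code{stack} ([FieldStack-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @examples
#' fl <- generateField(fieldSpec(image_shape = c(96L, 96L), n_slices = 5L,
#'                               n_on_puncta = 15L, n_off_puncta = 5L,
#'                               n_neuronal_nuclei = 2L,
#'                               n_astrocyte_nuclei = 1L, seed = 7L))
#' fl$truth
#' @export
generateField <- function(spec, artifacts = artifactSpec(),
                          plate_id = "P1", well = "B02", field_index = 1L) {
  validObject(spec); validObject(artifacts)
  H <- spec@image_shape[1]; W <- spec@image_shape[2]
  px <- spec@pixel_size

  ## object budget: refuse fields too small to hold the request
  d_hi <- spec@punctum_diameter_range[2]
  nuc_px <- pi / 4 * ((c(rep(spec@neuronal_nucleus_diameter,
                              spec@n_neuronal_nuclei),
                         rep(spec@astrocyte_nucleus_diameter,
                             spec@n_astrocyte_nuclei)) / px)^2)
  budget <- (spec@n_on_puncta + spec@n_off_puncta) * (d_hi + 2)^2 +
    1.2 * sum(nuc_px)
  if (budget > 0.8 * H * W)
    stop("image too small to contain the requested objects")

  withr::with_seed(spec@seed, {
    ## --- neurites -------------------------------------------------------
    centre <- .rasterNeurites(H, W, spec@n_neurite_segments)
    mask <- if (any(centre > 0)) {
      .asMat(EBImage::dilate(EBImage::Image(centre),
                                .discBrush(spec@neurite_width / 2))) > 0
    } else matrix(FALSE, H, W)
    neurite_img <- .gblurMat(mask * spec@neurite_amplitude, 1)

    ## --- nuclei ---------------------------------------------------------
    n_nuc <- spec@n_neuronal_nuclei + spec@n_astrocyte_nuclei
    nuclei <- data.frame(y = numeric(0), x = numeric(0),
                         diameter = numeric(0), class = character(0),
                         stringsAsFactors = FALSE)
    nuc_img <- matrix(0, H, W); soma_img <- matrix(0, H, W)
    if (n_nuc > 0) {
      cls <- c(rep("neuronal", spec@n_neuronal_nuclei),
               rep("astrocytic", spec@n_astrocyte_nuclei))
      centres <- matrix(numeric(0), 0, 3) # cy, cx, semi-major
      for (i in seq_len(n_nuc)) {
        d_um <- if (cls[i] == "neuronal") spec@neuronal_nucleus_diameter
                else spec@astrocyte_nucleus_diameter
        d_px <- max(4, rnorm(1, d_um, 0.06 * d_um) / px)
        ratio <- if (cls[i] == "neuronal") runif(1, 0.85, 1)
                 else runif(1, 0.5, 0.7)
        a <- d_px / 2 / sqrt(ratio); b <- d_px / 2 * sqrt(ratio)
        if (2 * a + 2 >= min(H, W))
          stop("image too small to contain the requested nuclei")
        ## nuclei prefer to keep their distance (watershed separates
        ## touching ones) but real cultures clump: when a crowded field
        ## leaves no well-spaced position, the spacing requirement is
        ## relaxed progressively instead of failing the field
        placed <- FALSE
        for (factor in c(0.7, 0.5, 0.3, 0)) {
          for (try in 1:300) {
            cy <- round(runif(1, a + 1, H - a))
            cx <- round(runif(1, a + 1, W - a))
            if (nrow(centres) == 0 ||
                all(sqrt((centres[, 1] - cy)^2 + (centres[, 2] - cx)^2) >=
                      factor * (centres[, 3] + a))) { placed <- TRUE; break }
          }
          if (placed) break
        }
        if (!placed) stop("image too small to place nuclei without overlap")
        centres <- rbind(centres, c(cy, cx, a))
        theta <- runif(1, 0, pi)
        amp <- spec@nucleus_amplitude *
          (if (cls[i] == "neuronal") 1 else 0.45) * runif(1, 0.9, 1.1)
        nuc_img <- .addEllipse(nuc_img, cy, cx, a, b, theta, amp)
        if (cls[i] == "neuronal")   # distinct dendrite-positive soma
          soma_img <- .addEllipse(soma_img, cy, cx, a + 3, b + 3, theta,
                                  0.7 * spec@neurite_amplitude)
        nuclei <- rbind(nuclei, data.frame(
          y = cy - 1, x = cx - 1, diameter = d_px, class = cls[i],
          stringsAsFactors = FALSE))
      }
      ## in-focus PSF is ~1 px at 0.6 um/px with a x20 water objective
      nuc_img <- .gblurMat(nuc_img, 1)
      soma_img <- .gblurMat(soma_img, 1.2)
    }

    ## --- puncta ---------------------------------------------------------
    mask_idx <- which(mask)
    if (spec@n_on_puncta > length(mask_idx))
      stop("neurite mask too small for the requested on-neurite puncta")
    off_idx <- which(!mask)
    if (spec@n_off_puncta > length(off_idx))
      stop("image too small for the requested off-neurite puncta")
    syn_img <- matrix(0, H, W)
    puncta <- data.frame(y = numeric(0), x = numeric(0),
                         equivalent_diameter = numeric(0),
                         on_neurite = logical(0))
    place <- function(idx_pool, n, on) {
      if (n == 0L) return(invisible())
      sel <- idx_pool[sample.int(length(idx_pool), n)]
      cy <- ((sel - 1L) %% H) + 1L
      cx <- ((sel - 1L) %/% H) + 1L
      dd <- runif(n, spec@punctum_diameter_range[1],
                  spec@punctum_diameter_range[2])
      for (k in seq_len(n))
        syn_img <<- .addSpot(syn_img, cy[k], cx[k], dd[k],
                             spec@punctum_amplitude)
      puncta <<- rbind(puncta, data.frame(
        y = cy - 1, x = cx - 1, equivalent_diameter = dd, on_neurite = on))
      invisible()
    }
    place(mask_idx, spec@n_on_puncta, TRUE)
    place(off_idx, spec@n_off_puncta, FALSE)

    ## --- z-structure and noise ------------------------------------------
    nz <- spec@n_slices
    n_layers <- min(3L, nz)
    layer_slices <- unique(round(seq(1, nz, length.out = n_layers)))
    n_layers <- length(layer_slices)
    split_layers <- function(img) {
      ## assign rendered content to focal layers by vertical position so
      ## each layer holds a coherent subset of the image
      if (n_layers == 1L) return(list(img))
      bands <- cut(seq_len(H), breaks = n_layers, labels = FALSE)
      lapply(seq_len(n_layers), function(l) {
        out <- matrix(0, H, W); rows <- which(bands == l)
        out[rows, ] <- img[rows, ]; out
      })
    }
    layers <- list(nuclear = split_layers(nuc_img),
                   dendrite = split_layers(neurite_img + soma_img),
                   presynaptic = split_layers(syn_img))
    channels <- lapply(layers, function(lys) {
      st <- array(0, dim = c(nz, H, W))
      for (s in seq_len(nz)) {
        signal <- matrix(spec@background_level, H, W)
        for (l in seq_len(n_layers)) {
          defocus <- 0.3 + 0.8 * abs(s - layer_slices[l])
          signal <- signal + .gblurMat(lys[[l]], defocus)
        }
        noisy <- rpois(H * W, pmax(signal, 0)) +
          rnorm(H * W, 0, spec@noise_sd)
        st[s, , ] <- matrix(pmax(noisy, 0), H, W)
      }
      st
    })
    names(channels) <- c("nuclear", "dendrite", "presynaptic")

    stack <- new("FieldStack", plate_id = as.character(plate_id),
                 well = as.character(well),
                 field_index = as.integer(field_index),
                 channels = channels, pixel_size = px)
    stack <- applyArtifacts(stack, artifacts)
    truth <- new("GroundTruth", neurite_mask = mask * 1, puncta = puncta,
                 nuclei = nuclei, applied_shift = artifacts@channel_shift,
                 planted_density = if (sum(mask) > 0)
                   spec@n_on_puncta / sum(mask) else 0)
    list(stack = stack, truth = truth)
  })
}

#' Apply acquisition artifacts to a field stack
#'
#' Translates the non-reference channels (dendrite, presynaptic) by the
#' integer \code{channel_shift}, padding revealed edges at the slice
#' background level (slice median), then multiplies every channel by the
#' illumination gain plane \code{a + b*y + c*x} and optional radial
#' vignette.
#'
#' @param stack a [FieldStack-class].
#' @param artifacts an [ArtifactSpec-class].
#' @return The modified [FieldStack-class].
#' @export
applyArtifacts <- function(stack, artifacts) {
  validObject(artifacts)
  d <- dim(stack@channels[[1]]); H <- d[2]; W <- d[3]
  sh <- artifacts@channel_shift
  if (any(abs(sh) >= c(H, W)))
    stop("channel_shift exceeds image bounds")
  g <- artifacts@illumination_gradient
  yy <- matrix(0:(H - 1), H, W); xx <- matrix(0:(W - 1), H, W, byrow = TRUE)
  gain <- g[1] + g[2] * yy + g[3] * xx
  if (any(gain <= 0)) stop("illumination gain must stay positive")
  if (artifacts@vignette_strength > 0) {
    r2 <- ((yy - (H - 1) / 2)^2 + (xx - (W - 1) / 2)^2) /
      (((H - 1) / 2)^2 + ((W - 1) / 2)^2)
    gain <- gain * pmax(1 - artifacts@vignette_strength * r2, 0.05)
  }
  flat <- identical(unname(g), c(1, 0, 0)) && artifacts@vignette_strength == 0
  for (ch in names(stack@channels)) {
    arr <- stack@channels[[ch]]
    for (s in seq_len(d[1])) {
      sl <- matrix(arr[s, , ], H, W)
      if (ch != "nuclear" && any(sh != 0L))
        sl <- .shiftMatrix(sl, sh[1], sh[2], pad = median(sl))
      if (!flat) sl <- sl * gain
      arr[s, , ] <- sl
    }
    stack@channels[[ch]] <- arr
  }
  stack
}
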