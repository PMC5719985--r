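#' @importFrom EBImage gblur bwlabel otsu Image imageData readImage writeImage
NULL

stampBlob <- function(img, x, y, sigma, amp) {
  r <- ceiling(4 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  x0 <- max(1, round(x) - r); x1 <- min(nr, round(x) + r)
  y0 <- max(1, round(y) - r); y1 <- min(nc, round(y) + r)
  if (x0 > x1 || y0 > y1) return(img)
  xi <- x0:x1; yi <- y0:y1
  g <- outer(xi, yi, function(i, j)
    exp(-((i - x)^2 + (j - y)^2) / (2 * sigma^2)))
  img[xi, yi] <- img[xi, yi] + amp * g
  img
}

#' Lay out ground-truth cells on a jittered grid
#'
#' Places viable marker-positive, viable marker-negative and dead cells at
#' jittered grid positions with a guaranteed minimum spacing, so that
#' rendered nuclei of different cells do not merge or fall within each
#' other's fragment-grouping radius.
#'
#' @param nViablePos,nViableNeg,nDead cell counts per category
#' @param shape image dimensions in pixels
#' @param spacing grid spacing in pixels
#' @param jitter max uniform jitter per axis
#' @param seed RNG seed
#' @return data.frame with \code{x}, \code{y}, \code{viable},
#'   \code{marker_positive}
#' @export
layoutCells <- function(nViablePos, nViableNeg, nDead, shape = c(256, 256),
                        spacing = 32, jitter = 4, seed = 1L) {
  set.seed(seed)
  n <- nViablePos + nViableNeg + nDead
  margin <- spacing / 2
  gx <- seq(margin, shape[1] - margin, by = spacing)
  gy <- seq(margin, shape[2] - margin, by = spacing)
  sites <- expand.grid(x = gx, y = gy)
  if (n > nrow(sites))
    stop(sprintf("too many cells (%d) for a %dx%d image at spacing %g",
                 n, shape[1], shape[2], spacing))
  pick <- sites[sample(nrow(sites), n), ]
  data.frame(
    x = pick$x + stats::runif(n, -jitter, jitter),
    y = pick$y + stats::runif(n, -jitter, jitter),
    viable = rep(c(TRUE, TRUE, FALSE), c(nViablePos, nViableNeg, nDead)),
    marker_positive = rep(c(TRUE, FALSE, FALSE),
                          c(nViablePos, nViableNeg, nDead)))
}

#' Render a synthetic two-channel well image
#'
#' Intact (viable) nuclei are drawn as single Gaussian blobs in the DNA
#' channel; dead cells as 3-6 small displaced blobs of equal total intensity
#' (fragmented nuclei). Marker-positive cells receive an elevated
#' marker-channel blob, negatives a dim baseline one. Gaussian read noise is
#' added to both channels and intensities are clamped at zero.
#'
#' @param cells data.frame from [layoutCells()] (columns x, y, viable,
#'   marker_positive); dead cells may be marker-positive or negative, their
#'   marker signal follows \code{marker_positive}
#' @param shape image dimensions
#' @param nucleusSigma Gaussian radius of an intact nucleus, px
#' @param fragmentSigma radius of a fragment blob
#' @param fragmentSpread min/max displacement of fragments from the cell
#'   centre
#' @param noiseSd Gaussian read-noise standard deviation
#' @param markerHigh,markerLow marker-channel amplitudes for positive and
#'   negative cells
#' @param pixelSize micrometres per pixel (metadata only)
#' @param seed RNG seed
#' @return a \code{WellImage}: list with \code{dna}, \code{marker} (matrices),
#'   \code{pixel_size} and the ground \code{truth}
#' @export
renderWell <- function(cells, shape = c(256, 256), nucleusSigma = 3,
                       fragmentSigma = 1.5, fragmentSpread = c(5.5, 7.5),
                       noiseSd = 0.02, markerHigh = 0.8, markerLow = 0.05,
                       pixelSize = 1, seed = 1L) {
  set.seed(seed)
  dna <- matrix(0, shape[1], shape[2])
  marker <- matrix(0, shape[1], shape[2])
  if (nrow(cells)) {
    for (i in seq_len(nrow(cells))) {
      x <- cells$x[i]; y <- cells$y[i]
      if (cells$viable[i]) {
        dna <- stampBlob(dna, x, y, nucleusSigma, 1)
      } else {
        nf <- sample(3:5, 1)
        # equal total intensity: amplitude scales with sigma^2 ratio / nf
        amp <- (nucleusSigma^2 / fragmentSigma^2) / nf
        # near-even angular placement keeps fragments resolvable after
        # smoothing while staying inside the grouping radius
        ang <- 2 * pi * (seq_len(nf) - 1 + stats::runif(nf, -0.15, 0.15)) / nf +
          stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(nf, fragmentSpread[1], fragmentSpread[2])
        for (k in seq_len(nf))
          dna <- stampBlob(dna, x + rad[k] * cos(ang[k]),
                           y + rad[k] * sin(ang[k]), fragmentSigma, amp)
      }
      mamp <- if (cells$marker_positive[i]) markerHigh else markerLow
      marker <- stampBlob(marker, x, y, nucleusSigma * 1.3, mamp)
    }
  }
  dna <- pmax(dna + matrix(stats::rnorm(length(dna), 0, noiseSd),
                           shape[1], shape[2]), 0)
  marker <- pmax(marker + matrix(stats::rnorm(length(marker), 0, noiseSd),
                                 shape[1], shape[2]), 0)
  structure(list(dna = dna, marker = marker, pixel_size = pixelSize,
                 truth = cells), class = "WellImage")
}

polygonArea <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x * y[j] - x[j] * y)) / 2
}

objectSolidity <- function(px, py, npix) {
  if (npix < 3) return(1)
  h <- grDevices::chull(px, py)
  # convex polygon through pixel centres underestimates the pixelated area;
  # add the half-pixel rim (perimeter/2 + 1, Pick-style correction)
  hx <- px[h]; hy <- py[h]
  area <- polygonArea(hx, hy)
  per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  hullArea <- area + per / 2 + 1
  min(1, npix / hullArea)
}

#' Segment nuclei and group fragments in a well image
#'
#' Global Otsu threshold on the smoothed, max-normalised DNA channel,
#' connected components, removal of objects below the minimum area, and
#' grouping of nearby components (single-linkage on centroids within the
#' fragment-grouping radius) into cells. Each resulting cell records its
#' fragment count, total area, solidity (of its largest fragment, pixel area
#' over convex hull area) and mean marker-channel intensity. Max-normalising
#' before thresholding makes every call invariant to a common intensity
#' scaling of the channels.
#'
#' @param image a \code{WellImage} from [renderWell()] (or any list with
#'   \code{dna} and \code{marker} matrices)
#' @param smoothSigma Gaussian smoothing sigma, px
#' @param minArea discard components smaller than this, px
#' @param groupRadius fragment-grouping radius, px
#' @return data.frame of segmented cells: \code{label}, \code{x}, \code{y},
#'   \code{area}, \code{n_fragments}, \code{solidity},
#'   \code{marker_mean_intensity}
#' @export
segmentNuclei <- function(image, smoothSigma = 2, minArea = 30,
                          groupRadius = 15) {
  dna <- image$dna
  empty <- data.frame(label = integer(), x = numeric(), y = numeric(),
                      area = integer(), n_fragments = integer(),
                      solidity = numeric(), marker_mean_intensity = numeric())
  mx <- max(dna)
  if (mx <= 0) return(empty)
  sm <- imageData(gblur(Image(dna / mx), sigma = smoothSigma))
  th <- otsu(Image(sm))
  mask <- sm > th
  # scale-invariant blank guard: real nuclei are far brighter than
  # background, while thresholded pure noise splits into two similar levels
  fg <- mean(sm[mask]); bg <- mean(sm[!mask])
  if (!is.finite(fg) || fg < 4 * max(bg, .Machine$double.eps)) return(empty)
  lab <- imageData(bwlabel(Image(mask)))
  nObj <- max(lab)
  if (nObj == 0) return(empty)
  pix <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  areas <- tabulate(labs, nObj)
  keep <- which(areas >= minArea)
  if (!length(keep)) return(empty)
  cx <- vapply(keep, function(o) mean(pix[labs == o, 1]), 1)
  cy <- vapply(keep, function(o) mean(pix[labs == o, 2]), 1)
  # group fragments: single linkage on centroid distance
  grp <- if (length(keep) == 1) 1L else {
    hc <- stats::hclust(stats::dist(cbind(cx, cy)), method = "single")
    stats::cutree(hc, h = groupRadius)
  }
  marker <- image$marker
  out <- lapply(sort(unique(grp)), function(g) {
    objs <- keep[grp == g]
    aset <- areas[objs]
    big <- objs[which.max(aset)]
    sel <- labs == big
    sol <- objectSolidity(pix[sel, 1], pix[sel, 2], sum(sel))
    inGroup <- labs %in% objs
    mint <- mean(marker[pix[inGroup, , drop = FALSE]])
    data.frame(label = g, x = mean(cx[grp == g]), y = mean(cy[grp == g]),
               area = sum(aset), n_fragments = length(objs), solidity = sol,
               marker_mean_intensity = mint)
  })
  do.call(rbind, out)
}

#' Viability calls from nuclear morphology
#'
#' A cell is viable iff its nucleus is non-fragmented (one component), its
#' solidity is at least \code{solidityMin}, and its area lies inside the
#' admissible window.
#'
#' @param cells output of [segmentNuclei()]
#' @param solidityMin minimum solidity
#' @param areaRange admissible area window in px
#' @return the input with a logical \code{viable} column
#' @export
callViability <- function(cells, solidityMin = 0.85, areaRange = c(30, 400)) {
  cells$viable <- cells$n_fragments == 1 &
    cells$solidity >= solidityMin &
    cells$area >= areaRange[1] & cells$area <= areaRange[2]
  cells
}

otsu1d <- function(x, nbins = 64) {
  h <- tabulate(cut(x, breaks = nbins, labels = FALSE), nbins)
  edges <- seq(min(x), max(x), length.out = nbins + 1)
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  total <- sum(h)
  w0 <- cumsum(h); mu0 <- cumsum(h * mids)
  muT <- mu0[nbins]
  v <- vapply(seq_len(nbins - 1), function(k) {
    q0 <- w0[k] / total; q1 <- 1 - q0
    if (q0 == 0 || q1 == 0) return(NA_real_)
    m0 <- mu0[k] / w0[k]
    m1 <- (muT - mu0[k]) / (total - w0[k])
    q0 * q1 * (m0 - m1)^2
  }, numeric(1))
  bestVar <- max(v, na.rm = TRUE)
  # maxima plateau across an empty gap: split at the middle of the plateau,
  # at the upper edge of the chosen bin
  ks <- which(v >= bestVar - 1e-12)
  k <- ks[ceiling(length(ks) / 2)]
  list(threshold = edges[k + 1],
       separation = if (stats::var(x) > 0)
         bestVar / (stats::var(x) * (total - 1) / total) else 0)
}

#' Marker-positivity calls from cell-wise marker intensities
#'
#' Gating threshold by one-dimensional Otsu on the cells' mean marker
#' intensities. The Otsu split is only trusted when the putative positive
#' mode is at least \code{contrastMin} times brighter than the negative mode
#' (marker-positive cells are severalfold brighter under immunofluorescence);
#' otherwise the well is treated as unimodal and the gate falls back to the
#' fixed 0.99 intensity quantile with a 2x contrast requirement over the well
#' median, so that all-negative wells yield no positives. Both gates compare
#' intensity ratios, keeping every call invariant to a common intensity
#' scaling.
#'
#' @param cells output of [segmentNuclei()] / [callViability()]
#' @param contrastMin minimal high/low mode intensity ratio to trust the
#'   bimodal Otsu split
#' @param fallbackQuantile quantile for the unimodal fallback gate
#' @return the input with a logical \code{marker_positive} column
#' @export
callMarker <- function(cells, contrastMin = 3, fallbackQuantile = 0.99) {
  x <- cells$marker_mean_intensity
  if (!nrow(cells)) { cells$marker_positive <- logical(0); return(cells) }
  if (length(unique(x)) == 1) {
    cells$marker_positive <- FALSE
    return(cells)
  }
  ot <- otsu1d(x)
  hi <- x > ot$threshold
  contrast <- if (any(hi) && any(!hi))
    mean(x[hi]) / max(mean(x[!hi]), .Machine$double.eps) else 0
  if (contrast >= contrastMin) {
    cells$marker_positive <- hi
  } else {
    q <- stats::quantile(x, fallbackQuantile, names = FALSE)
    cells$marker_positive <- x > q & x > 2 * stats::median(x)
  }
  cells
}

#' Combine marker calls across channels with OR logic
#'
#' @param ... logical vectors of per-cell marker calls (e.g. CD34, CD117)
#' @return logical vector, TRUE where any marker is positive
#' @export
combineMarkersOr <- function(...) Reduce(`|`, list(...))

#' Convert segmented, gated cells of one well into a well-table row
#'
#' @param cells output of [callMarker()] after [callViability()]
#' @param patientId,plateId,well,drug,concentration,replicate,marker well
#'   annotations
#' @return one-row data.frame in the [readWellTable()] schema
#' @export
imageToWellRecord <- function(cells, patientId, plateId, well, drug,
                              concentration, replicate, marker) {
  data.frame(
    patient_id = patientId, plate_id = plateId, well = well, drug = drug,
    concentration_um = concentration, replicate = replicate, marker = marker,
    n_viable_marker_pos = sum(cells$viable & cells$marker_positive),
    n_viable_marker_neg = sum(cells$viable & !cells$marker_positive),
    n_total_cells = nrow(cells), stringsAsFactors = FALSE)
}

#' Write / read a two-channel well image as a TIFF stack
#'
#' Channels are stored jointly normalised to their common maximum (TIFF
#' stores intensities in [0, 1]); the relative scale between and within
#' channels is preserved, and every segmentation and gating call is invariant
#' to the absolute scale.
#'
#' @param image a \code{WellImage}
#' @param path TIFF path
#' @return \code{writeWellTiff}: the path, invisibly; \code{readWellTiff}: a
#'   \code{WellImage} (without ground truth)
#' @export
writeWellTiff <- function(image, path) {
  sc <- max(image$dna, image$marker, 1e-12)
  stack <- Image(array(c(image$dna / sc, image$marker / sc),
                       dim = c(dim(image$dna), 2)))
  writeImage(stack, path, type = "tiff", bits.per.sample = 32L)
  invisible(path)
}

#' @rdname writeWellTiff
#' @param path TIFF path
#' @param pixelSize micrometres per pixel
#' @export
readWellTiff <- function(path, pixelSize = 1) {
  img <- readImage(path)
  d <- imageData(img)
  structure(list(dna = d[, , 1], marker = d[, , 2], pixel_size = pixelSize,
                 truth = NULL), class = "WellImage")
}
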