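#' Container for a CT volume with lung mask
#'
#' @param hu 3-D numeric array of Hounsfield units.
#' @param mask Logical/0-1 array of the same shape marking lung voxels;
#'   default: all voxels.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm; default
#'   `c(0.5, 0.5, 5)`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(hu, mask = NULL, spacing = c(0.5, 0.5, 5)) {
  if (length(dim(hu)) != 3L) abort("`hu` must be a 3-D array.")
  if (is.null(mask)) mask <- array(TRUE, dim(hu))
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(hu), dim(mask))) {
    abort("`hu` and `mask` must have the same shape.")
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be three positive lengths (mm).")
  }
  if (any(mask)) {
    rng <- range(hu[mask])
    if (rng[1] < -1024 || rng[2] > 3071) {
      abort("masked HU values outside [-1024, 3071].")
    }
  }
  structure(list(hu = hu, mask = mask, spacing = as.numeric(spacing)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels | spacing %s mm | %d in mask\n",
              paste(dim(x$hu), collapse = "x"),
              paste(x$spacing, collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' Gas and tissue fractions from Hounsfield units
#'
#' Linear air/water mixture model: gas fraction `-HU/1000` clamped to
#' `[0, 1]`, tissue fraction its complement (water density 1 g/cm^3).
#'
#' @param hu Numeric vector or array of Hounsfield units.
#' @return List with elements `gas` and `tissue`, same shape as `hu`.
#' @examples
#' gas_tissue_fractions(c(-1000, -500, 0))
#' @export
gas_tissue_fractions <- function(hu) {
  gas <- pmin(pmax(-hu / 1000, 0), 1)
  list(gas = gas, tissue = 1 - gas)
}

aeration_bins <- tibble(
  compartment = factor(
    c("over_distended", "normally_aerated", "poorly_aerated", "atelectasis"),
    levels = c("over_distended", "normally_aerated", "poorly_aerated",
               "atelectasis")),
  hu_lo = c(-1000, -900, -500, -100),
  hu_hi = c(-901, -501, -101, 100)
)

#' Classify lung voxels into aeration compartments
#'
#' Bins masked voxels into the four functional aeration compartments by
#' Hounsfield density — over-distended `[-1000, -901]`, normally aerated
#' `[-900, -501]`, poorly aerated `[-500, -101]`, atelectasis/collapse
#' `[-100, +100]` — and reports voxel counts, volumes and tissue masses
#' (air/water mixture model). HU below -1000 are clamped to -1000; masked
#' voxels above +100 are excluded from the four classes and reported via
#' the `n_excluded` attribute.
#'
#' @param ct A [ct_volume()].
#' @return A tibble of class `aeration_report` with one row per
#'   compartment: `compartment`, `hu_lo`, `hu_hi`, `n_voxels`, `volume_ml`,
#'   `tissue_mass_g`, `volume_fraction`. Attributes: `a_n` and `o_n`
#'   (atelectatic and over-distended over normally aerated volume),
#'   `n_excluded`, `voxel_volume_ml`.
#' @examples
#' hu <- array(-900, c(4, 4, 2))
#' classify_aeration(ct_volume(hu))
#' @export
classify_aeration <- function(ct) {
  stopifnot(inherits(ct, "ct_volume"))
  if (!any(ct$mask)) abort("empty lung mask.")
  hu <- pmax(ct$hu[ct$mask], -1000)
  # closed integer bins as printed; half-integer breaks so integer HU land
  # exactly and the (-901, -900) style gaps cannot be hit
  cls <- cut(hu, breaks = c(-1000.5, -900.5, -500.5, -100.5, 100.5),
             labels = levels(aeration_bins$compartment))
  voxel_ml <- prod(ct$spacing) / 1000  # mm^3 -> mL
  tissue <- gas_tissue_fractions(hu)$tissue
  counts <- tabulate(cls, nbins = 4L)
  mass <- vapply(seq_len(4L), function(i) {
    sum(tissue[!is.na(cls) & as.integer(cls) == i]) * voxel_ml
  }, numeric(1))
  out <- aeration_bins
  out$n_voxels <- counts
  out$volume_ml <- counts * voxel_ml
  out$tissue_mass_g <- mass  # 1 g/cm^3 water density
  out$volume_fraction <- if (sum(counts) > 0) counts / sum(counts) else rep(NA_real_, 4)
  normal <- out$volume_ml[out$compartment == "normally_aerated"]
  class(out) <- c("aeration_report", class(out))
  attr(out, "a_n") <- out$volume_ml[out$compartment == "atelectasis"] / normal
  attr(out, "o_n") <- out$volume_ml[out$compartment == "over_distended"] / normal
  attr(out, "n_excluded") <- sum(is.na(cls))
  attr(out, "voxel_volume_ml") <- voxel_ml
  out
}

#' Atelectasis/normal and over-distension/normal volume ratios
#'
#' @param report An `aeration_report` from [classify_aeration()].
#' @return A one-row tibble with `a_n` and `o_n`.
#' @export
aeration_ratios <- function(report) {
  stopifnot(inherits(report, "aeration_report"))
  tibble(a_n = attr(report, "a_n"), o_n = attr(report, "o_n"))
}

#' @export
autoplot.aeration_report <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$compartment, .data$volume_ml)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Volume (mL)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

# Integer voxel offsets whose centre-to-centre physical distance lies in
# [r1, r2] mm. With the default spacing (0.5, 0.5, 5) the ring is purely
# in-plane because one slice step (5 mm) already exceeds r2.
ring_offsets <- function(spacing, r1, r2) {
  reach <- pmin(floor(r2 / spacing), 64)
  offs <- expand.grid(i = -reach[1]:reach[1], j = -reach[2]:reach[2],
                      k = -reach[3]:reach[3])
  d <- sqrt((offs$i * spacing[1])^2 + (offs$j * spacing[2])^2 +
              (offs$k * spacing[3])^2)
  offs <- offs[d >= r1 & d <= r2, , drop = FALSE]
  if (nrow(offs) == 0) {
    abort("configuration error: no voxel centres fall inside the ring radii.")
  }
  offs
}

# Shift a 3-D array by integer offset (i, j, k), zero-filling.
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1 + o):d[ax]
      src[[ax]] <- 1:(d[ax] - o)
    } else {
      dst[[ax]] <- 1:(d[ax] + o)
      src[[ax]] <- (1 - o):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Voxel-ring inhomogeneity index
#'
#' Computes, for every masked voxel, the ratio of the mean gas fraction of
#' the surrounding ring of voxels (centre-to-centre physical distance
#' between `r1` and `r2`) to the voxel's own gas fraction, the latter
#' floored at `gas_floor` to avoid blow-up in dense atelectasis. A voxel's
#' index is valid only when at least `min_coverage` of the geometric ring
#' lies inside the lung mask (ring voxels outside the mask or the array do
#' not contribute). An index above the pathologic threshold marks a voxel
#' whose surroundings are substantially better aerated than itself — a
#' stress-raiser interface.
#'
#' @param ct A [ct_volume()].
#' @param r1,r2 Inner and outer ring radii in mm (defaults 2.41 and 3.675).
#' @param gas_floor Floor on the voxel gas fraction (default 0.01).
#' @param min_coverage Minimum fraction of the geometric ring inside the
#'   mask for a valid index (default 0.5).
#' @return An object of class `inhomogeneity_map`: list with `index` (3-D
#'   array, `NA` where invalid), `valid` (logical array), `n_ring_offsets`,
#'   `h_ct` (pathologic:normal ratio at the default threshold 1.61), and
#'   the call parameters.
#' @export
cressoni_index <- function(ct, r1 = 2.41, r2 = 3.675, gas_floor = 0.01,
                           min_coverage = 0.5) {
  stopifnot(inherits(ct, "ct_volume"))
  if (!any(ct$mask)) abort("empty lung mask.")
  if (r1 >= r2) abort("`r1` must be smaller than `r2`.")
  offs <- ring_offsets(ct$spacing, r1, r2)
  gas <- gas_tissue_fractions(ct$hu)$gas
  gas[!ct$mask] <- 0
  m <- array(as.numeric(ct$mask), dim(ct$mask))
  ring_sum <- array(0, dim(gas))
  ring_cnt <- array(0, dim(gas))
  for (r in seq_len(nrow(offs))) {
    o <- c(offs$i[r], offs$j[r], offs$k[r])
    ring_sum <- ring_sum + shift_array(gas, o)
    ring_cnt <- ring_cnt + shift_array(m, o)
  }
  valid <- ct$mask & (ring_cnt >= min_coverage * nrow(offs))
  index <- array(NA_real_, dim(gas))
  voxel_gas <- pmax(gas_tissue_fractions(ct$hu)$gas, gas_floor)
  index[valid] <- (ring_sum[valid] / ring_cnt[valid]) / voxel_gas[valid]
  map <- structure(
    list(index = index, valid = valid, n_ring_offsets = nrow(offs),
         r1 = r1, r2 = r2, gas_floor = gas_floor,
         min_coverage = min_coverage, spacing = ct$spacing),
    class = "inhomogeneity_map"
  )
  map$h_ct <- h_ct(map)
  map
}

#' @export
print.inhomogeneity_map <- function(x, ...) {
  cat(sprintf(
    "<inhomogeneity_map> %d valid voxels | ring of %d offsets (%.2f-%.3f mm) | H_CT = %.3f\n",
    sum(x$valid), x$n_ring_offsets, x$r1, x$r2, x$h_ct))
  invisible(x)
}

#' CT heterogeneity score from an inhomogeneity map
#'
#' The ratio of pathologic voxels (inhomogeneity index above `threshold`)
#' to normal voxels (index at or below it), over valid voxels.
#'
#' @param map An [cressoni_index()] result.
#' @param threshold Pathologic threshold (default 1.61, the 95th percentile
#'   of a healthy control population).
#' @return Non-negative scalar; `Inf` (with a warning) when no normal
#'   voxels remain.
#' @export
h_ct <- function(map, threshold = 1.61) {
  stopifnot(inherits(map, "inhomogeneity_map"))
  idx <- map$index[map$valid]
  if (length(idx) == 0) abort("no valid voxels in inhomogeneity map.")
  n_path <- sum(idx > threshold)
  n_norm <- sum(idx <= threshold)
  if (n_norm == 0) {
    warn("no normal voxels below threshold; H_CT is infinite.")
    return(Inf)
  }
  n_path / n_norm
}

#' Read and write CT volumes as NIfTI
#'
#' `write_ct_volume()` writes the HU array and mask as a pair of `.nii.gz`
#' files carrying the voxel spacing; `read_ct_volume()` reads them back.
#'
#' @param ct A [ct_volume()].
#' @param hu_path,mask_path File paths (`.nii` or `.nii.gz`).
#' @return `write_ct_volume()` returns `hu_path` invisibly;
#'   `read_ct_volume()` returns a [ct_volume()].
#' @export
write_ct_volume <- function(ct, hu_path, mask_path) {
  stopifnot(inherits(ct, "ct_volume"))
  hu_img <- RNifti::asNifti(ct$hu)
  RNifti::pixdim(hu_img) <- ct$spacing
  RNifti::writeNifti(hu_img, hu_path)
  mask_img <- RNifti::asNifti(array(as.integer(ct$mask), dim(ct$mask)))
  RNifti::pixdim(mask_img) <- ct$spacing
  RNifti::writeNifti(mask_img, mask_path)
  invisible(hu_path)
}

#' @rdname write_ct_volume
#' @export
read_ct_volume <- function(hu_path, mask_path) {
  hu <- RNifti::readNifti(hu_path)
  mask <- RNifti::readNifti(mask_path)
  spacing <- RNifti::pixdim(hu)[1:3]
  ct_volume(array(as.numeric(hu), dim(hu)[1:3]),
            array(as.numeric(mask) > 0.5, dim(mask)[1:3]),
            spacing = spacing)
}
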