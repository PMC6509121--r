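#' Save a parameter map
#'
#' Writes a [parameter_map()] as a 3-slice volume (values, adjusted
#' R-squared, mask) in NIfTI (`.nii`/`.nii.gz`, double precision, lossless)
#' or multi-page TIFF (`.tif`/`.tiff`), chosen by extension. The TIFF
#' backend stores samples on [0, 1], so values are scaled by 1/10000 (ms)
#' and qualities affinely mapped from [-9, 1]; qualities below -9 (and the
#' `-Inf` failed-fit flag) are clamped to the lower sentinel. Relative
#' round-trip error through TIFF is below 1e-6; use NIfTI where exactness
#' matters.
#'
#' @param map A [parameter_map()].
#' @param path Output path ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
save_map <- function(map, path) {
  stopifnot(inherits(map, "parameter_map"))
  vol <- array(NA_real_, dim = c(dim(map$values), 3L))
  vol[, , 1] <- map$values
  vol[, , 2] <- map$quality
  vol[, , 3] <- as.numeric(map$mask)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(vol, datatype = "double"), path)
  } else if (grepl("\\.tiff?$", path)) {
    v <- vol[, , 1] / .TIFF_VSCALE
    v[!is.finite(v)] <- 0
    q <- (pmax(vol[, , 2], -9) + 9) / 10   # -Inf and NA collapse to 0
    q[!is.finite(q)] <- 0
    m <- vol[, , 3]; m[!is.finite(m)] <- 0
    if (any(v < 0 | v > 1))
      stop("TIFF map storage supports relaxation times up to ",
           .TIFF_VSCALE, " ms")
    tiff::writeTIFF(list(v, q, m), path, bits.per.sample = 32L, reduce = FALSE)
  } else stop("unsupported map format: ", path)
  invisible(path)
}

.TIFF_VSCALE <- 1e4

#' Load a parameter map
#'
#' Counterpart of [save_map()]. A file holding a single 2-D image is
#' interpreted as a values plane with an all-true mask (with a warning).
#'
#' @param path Map file written by [save_map()] (or a plain 2-D image).
#' @param modality Modality label to attach.
#' @return A [parameter_map()].
#' @export
load_map <- function(path, modality = "T2") {
  vol <- if (grepl("\\.nii(\\.gz)?$", path)) {
    unclass(as.array(RNifti::readNifti(path)))
  } else if (grepl("\\.tiff?$", path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != 3L)
      stop("format error: expected 3 planes (values, quality, mask)")
    m <- pages[[3]] > 0.5
    v <- pages[[1]] * .TIFF_VSCALE
    q <- pages[[2]] * 10 - 9
    q[pages[[2]] == 0] <- -Inf
    v[!m] <- NA_real_
    q[!m] <- NA_real_
    arr <- array(NA_real_, dim = c(dim(v), 3L))
    arr[, , 1] <- v; arr[, , 2] <- q; arr[, , 3] <- as.numeric(m)
    arr
  } else stop("unsupported map format: ", path)
  if (length(dim(vol)) == 2L) {
    warning("no quality/mask planes found; assuming an all-true mask")
    vol <- array(c(vol, matrix(1, nrow(vol), ncol(vol)),
                   matrix(1, nrow(vol), ncol(vol))),
                 dim = c(dim(vol), 3L))
  }
  if (dim(vol)[3] != 3L) stop("format error: expected 3 planes (values, quality, mask)")
  q <- vol[, , 2]
  q[is.na(q)] <- -Inf
  mask <- !is.na(vol[, , 3]) & vol[, , 3] > 0.5
  q[!mask] <- NA_real_
  parameter_map(vol[, , 1], q, mask, modality = modality)
}

#' Load a binary tissue mask
#'
#' Reads a mask from PNG (nonzero = tissue) or NIfTI (values > 0.5).
#'
#' @param path Mask file (`.png`, `.nii`, `.nii.gz`).
#' @return Logical matrix.
#' @export
load_mask <- function(path) {
  if (grepl("\\.png$", path)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img > 0.5
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    as.array(RNifti::readNifti(path)) > 0.5
  } else stop("unsupported mask format: ", path)
}

#' Dump a parameter map to CSV
#'
#' One row per fitted pixel: `row`, `col`, `value`, `adjusted_r2`.
#'
#' @param map A [parameter_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  idx <- which(map$mask, arr.ind = TRUE)
  utils::write.csv(
    data.frame(row = idx[, 1], col = idx[, 2],
               value = map$values[idx],
               adjusted_r2 = map$quality[idx]),
    path, row.names = FALSE)
  invisible(path)
}

#' Read/write an acquisition protocol as YAML
#'
#' YAML keys: `modality`, `timings_ms`, `TR_ms`, `TE_cutoff_ms`.
#'
#' @param path YAML file path.
#' @return [read_protocol()]: an [acquisition_protocol()].
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  acquisition_protocol(y$modality, y$timings_ms, TR = y$TR_ms,
                       TE_cutoff = if (is.null(y$TE_cutoff_ms)) 60 else y$TE_cutoff_ms)
}

#' @rdname read_protocol
#' @param protocol An [acquisition_protocol()] to write.
#' @export
write_protocol <- function(protocol, path) {
  yaml::write_yaml(list(modality = protocol$modality,
                        timings_ms = protocol$timings,
                        TR_ms = protocol$TR,
                        TE_cutoff_ms = protocol$TE_cutoff), path)
  invisible(path)
}

#' Read/write a global parameter set as YAML
#'
#' @param path YAML file path.
#' @return [read_parameter_set()]: a [global_parameter_set()].
#' @export
read_parameter_set <- function(path) {
  y <- yaml::read_yaml(path)
  global_parameter_set(
    do.call(material_parameters, y$material),
    weight_set(fluid = unlist(y$weights$fluid),
               collagen = unlist(y$weights$collagen)))
}

#' @rdname read_parameter_set
#' @param theta A [global_parameter_set()] to write.
#' @export
write_parameter_set <- function(theta, path) {
  yaml::write_yaml(
    list(material = unclass(theta$params),
         weights = list(fluid = as.numeric(theta$weights["f", ]),
                        collagen = as.numeric(theta$weights["co", ]))),
    path)
  invisible(path)
}

#' Read/write an equilibrium stress-strain curve as CSV
#'
#' Columns: `strain` (fraction), `nominal_stress_MPa`.
#'
#' @param path CSV file path.
#' @return [read_curve()]: data.frame with columns `strain`, `stress`.
#' @export
read_curve <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("strain", "nominal_stress_MPa") %in% names(d)))
    stop("format error: curve CSV needs columns strain, nominal_stress_MPa")
  data.frame(strain = d$strain, stress = d$nominal_stress_MPa)
}

#' @rdname read_curve
#' @param curve data.frame with columns `strain` and `stress` (MPa).
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(data.frame(strain = curve$strain,
                              nominal_stress_MPa = curve$stress),
                   path, row.names = FALSE)
  invisible(path)
}
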