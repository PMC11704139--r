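#' Read and write grayscale images as TIFF
#'
#' Images are stored as 32-bit float TIFF so that intensities in [0, 1] (and
#' slight noise excursions outside) round-trip exactly enough for scientific
#' use.  Multi-page stacks are written from / read into 3D arrays.
#'
#' TIFF storage holds [0, 1]-scaled 32-bit samples; images with values
#' outside that range (e.g. unclipped noisy observations) are affinely
#' mapped into it and the transform is recorded in a small JSON sidecar
#' (\code{<path>.range.json}) which \code{read_image_tiff} undoes, so the
#' round trip is faithful for any finite image.
#'
#' @param img Matrix (single image) or (H, W, n) array (stack).
#' @param path Output file path.
#' @return \code{write_image_tiff} returns \code{path} invisibly;
#'   \code{read_image_tiff} returns a matrix or a (H, W, n) array.
#' @export
write_image_tiff <- function(img, path) {
  stopifnot(all(is.finite(img)))
  sidecar <- paste0(path, ".range.json")
  if (file.exists(sidecar)) unlink(sidecar)
  r <- range(img)
  if (r[1] < 0 || r[2] > 1) {
    span <- max(r[2] - r[1], .Machine$double.eps)
    img <- (img - r[1]) / span
    writeLines(jsonlite::toJSON(list(lo = r[1], hi = r[1] + span),
                                auto_unbox = TRUE, digits = NA), sidecar)
  }
  if (length(dim(img)) == 3) {
    pages <- lapply(seq_len(dim(img)[3]), function(i) img[, , i])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    tiff::writeTIFF(unclass(as.matrix(img)), path, bits.per.sample = 32L,
                    reduce = FALSE)
  }
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  out <- if (length(pages) == 1) pages[[1]]
         else array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  sidecar <- paste0(path, ".range.json")
  if (file.exists(sidecar)) {
    rg <- jsonlite::fromJSON(readLines(sidecar))
    out <- rg$lo + out * (rg$hi - rg$lo)
  }
  out
}

#' Save and load an operator family container
#'
#' Serializes a family (variant tag, parameter ranges, optics constants
#' and/or bases) to a single self-contained JSON file with named datasets
#' \code{eigen_psf}, \code{space_variation} and \code{gamma_ranges}, plus
#' grid-size metadata.
#'
#' @param family An \code{\link{operator_family}}.
#' @param path File path (conventionally \code{.json}).
#' @return \code{write_family} returns \code{path} invisibly;
#'   \code{read_family} returns the \code{\link{operator_family}}.
#' @export
write_family <- function(family, path) {
  stopifnot(inherits(family, "operator_family"))
  obj <- list(container = "varblur-operator-family", version = 1L,
              variant = family$variant, p = family$p,
              gamma_ranges = family$ranges)
  if (!is.null(family$config)) {
    cf <- family$config
    obj$optics <- list(wavelength = cf$wavelength,
                       numerical_aperture = cf$numerical_aperture,
                       immersion_index = cf$immersion_index,
                       pixel_pitch = cf$pixel_pitch,
                       psf_grid_size = cf$psf_grid_size,
                       defocus_z = cf$defocus_z,
                       oversampling = cf$oversampling)
    obj$noll_indices <- family$noll_indices
  }
  if (!is.null(family$basis)) {
    obj$psf_grid <- dim(family$basis$kernels)[1:2]
    obj$eigen_psf <- lapply(seq_len(family$basis$M),
                            function(m) family$basis$kernels[, , m])
  }
  if (!is.null(family$sv_basis)) {
    obj$image_grid <- dim(family$sv_basis$maps)[1:2]
    obj$sv_orthonormal <- family$sv_basis$orthonormal
    obj$space_variation <- lapply(seq_len(family$sv_basis$M),
                                  function(m) family$sv_basis$maps[, , m])
  }
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_family
#' @export
read_family <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyMatrix = TRUE)
  if (!identical(obj$container, "varblur-operator-family"))
    stop("not a varblur operator family container: ", path)
  config <- NULL
  if (!is.null(obj$optics))
    config <- do.call(optical_config, obj$optics)
  basis <- NULL
  if (!is.null(obj$eigen_psf)) {
    ks <- obj$eigen_psf
    if (is.array(ks) && length(dim(ks)) == 3) {   # jsonlite may give (M, h, w)
      ks <- lapply(seq_len(dim(ks)[1]), function(m) ks[m, , ])
    }
    basis <- eigen_psf_basis(ks, check = FALSE)
  }
  sv <- NULL
  if (!is.null(obj$space_variation)) {
    vs <- obj$space_variation
    if (is.array(vs) && length(dim(vs)) == 3)
      vs <- lapply(seq_len(dim(vs)[1]), function(m) vs[m, , ])
    sv <- space_variation_basis(vs, orthonormal = isTRUE(obj$sv_orthonormal))
  }
  operator_family(obj$variant, ranges = matrix(obj$gamma_ranges, ncol = 2),
                  config = config, noll_indices = obj$noll_indices,
                  basis = basis, sv_basis = sv)
}

#' Save and load model checkpoints
#'
#' Weights are stored in R's native serialization with a JSON sidecar
#' (\code{<path>.json}) describing the architecture preset, the output
#' dimension and the seeds, so a checkpoint is self-describing.
#'
#' @param model An identification model or a prox network (or a list of prox
#'   networks).
#' @param path Checkpoint file path (conventionally \code{.rds}).
#' @return \code{save_checkpoint} returns \code{path} invisibly;
#'   \code{load_checkpoint} returns the model object.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  meta <- list(class = class(model))
  if (!is.null(model$arch)) meta$arch <- model$arch[c("preset", "p")]
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
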