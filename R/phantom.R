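#' Describe a digital phantom
#'
#' A piecewise-constant multi-class phantom: an integer label volume
#' (0 = background, which stays signal-free) and per-class tissue
#' parameters, plus a smooth multiplicative transmit-field (kappa) map.
#' When no label map is supplied, the classes are laid out as equal
#' slabs along the first axis of `dim`.
#'
#' @param classes list of per-class parameter lists, each with fields
#'   `t1`, `t2` (ms) and optional `rho` (complex, default 10),
#'   `d_omega` (Hz, default 0), `t2prime` (ms, default `Inf`).
#' @param dim volume dimensions (length 3).
#' @param label_map optional integer array of dimension `dim` with
#'   values in `0:length(classes)`.
#' @param kappa_range range of the smooth transmit-field map (applied
#'   as a linear ramp along the last axis).
#' @return An object of class `jsr_phantom_spec`.
#' @export
phantom_spec <- function(classes, dim = c(8, 8, 2), label_map = NULL,
                         kappa_range = c(0.85, 1.15)) {
  stopifnot(length(classes) >= 1, length(dim) == 3)
  classes <- lapply(classes, function(cl) {
    stopifnot(!is.null(cl$t1), !is.null(cl$t2))
    list(rho = as.complex(cl$rho %||% (10 + 0i)), t1 = cl$t1, t2 = cl$t2,
         d_omega = cl$d_omega %||% 0, t2prime = cl$t2prime %||% Inf)
  })
  if (is.null(label_map)) {
    ix <- rep(seq_along(classes), length.out = dim[1])
    label_map <- array(ix[slice.index(array(0, dim), 1)], dim)
  } else {
    label_map <- array(as.integer(label_map), dim)
    if (max(label_map) > length(classes) || min(label_map) < 0)
      stop("label_map values must lie in 0..number of classes")
  }
  kap <- seq(kappa_range[1], kappa_range[2], length.out = dim[3])
  kappa_map <- array(kap[slice.index(array(0, dim), 3)], dim)
  structure(list(classes = classes, dim = dim, label_map = label_map,
                 kappa_map = kappa_map),
            class = "jsr_phantom_spec")
}

#' Generate a digital phantom's image stacks
#'
#' Simulates every protocol acquisition over the phantom: each
#' foreground voxel's data vector is the concatenated forward model at
#' its class parameters and local transmit scale, plus seeded zero-mean
#' Gaussian channel noise (standard deviation from the noise model,
#' evaluated at the brightest class for the relative rule so the noise
#' floor is spatially uniform, as in a real acquisition). Background
#' voxels carry pure noise-free zero signal plus the same channel noise.
#'
#' @param spec a [phantom_spec()].
#' @param protocol a [protocol()].
#' @param noise a [noise_model()], or `NULL` for noiseless images.
#' @param seed integer seed; generation is bit-reproducible.
#' @param out_dir optional directory: images, truth maps and a JSON
#'   sidecar are persisted there as NIfTI/JSON.
#' @return An object of class `jsr_phantom`: `images` (a matrix
#'   `n_voxels` x `n_channels`), `label_map`, `kappa_map`, `truth`
#'   (per-parameter ground-truth volumes), `noise_sd`, `seed`,
#'   `protocol`, `spec`.
#' @export
make_phantom <- function(spec, protocol, noise = noise_model(), seed = 1,
                         out_dir = NULL) {
  stopifnot(inherits(spec, "jsr_phantom_spec"))
  cp <- compile_protocol(protocol)
  nchan <- cp$ns + 2L * cp$nb
  nvox <- prod(spec$dim)
  lab <- as.vector(spec$label_map)
  kap <- as.vector(spec$kappa_map)
  Y <- matrix(0, nvox, nchan)
  for (ci in seq_along(spec$classes)) {
    cl <- spec$classes[[ci]]
    vox <- which(lab == ci)
    if (length(vox) == 0) next
    th <- matrix(rep(c(Re(cl$rho), Im(cl$rho), cl$t1, cl$t2, cl$d_omega),
                     each = length(vox)), ncol = 5)
    Y[vox, ] <- forward_core(th, cp, kappa = kap[vox], t2prime = cl$t2prime)
  }
  sd_used <- 0
  if (!is.null(noise)) {
    rho_max <- max(vapply(spec$classes, function(cl) Mod(cl$rho), numeric(1)))
    sd_used <- if (noise$type == "constant") noise$sigma else noise$rel * rho_max
    Y <- with_seed(seed, Y + matrix(stats::rnorm(length(Y), sd = sd_used),
                                    nvox, nchan))
  }
  truth <- list(
    t1 = map_from_classes(spec, "t1"), t2 = map_from_classes(spec, "t2"),
    d_omega = map_from_classes(spec, "d_omega"),
    rho_mod = map_from_classes(spec, "rho", Mod),
    rho_arg = map_from_classes(spec, "rho", Arg))
  ph <- structure(list(images = Y, label_map = spec$label_map,
                       kappa_map = spec$kappa_map, truth = truth,
                       noise_sd = sd_used, seed = seed, protocol = protocol,
                       spec = spec),
                  class = "jsr_phantom")
  if (!is.null(out_dir)) write_phantom(ph, out_dir)
  ph
}

map_from_classes <- function(spec, field, f = identity) {
  vals <- c(0, vapply(spec$classes, function(cl) f(cl[[field]]), numeric(1)))
  array(vals[as.vector(spec$label_map) + 1L], spec$dim)
}

#' @export
print.jsr_phantom <- function(x, ...) {
  cat(sprintf("<digital phantom> %s voxels, %d classes, %d channels, noise sd %g (seed %d)\n",
              paste(x$spec$dim, collapse = "x"), length(x$spec$classes),
              ncol(x$images), x$noise_sd, x$seed))
  invisible(x)
}

# Persist a phantom: one NIfTI per channel (bSSFP channels are written as
# separate _re/_im volumes since complex NIfTI support is patchy), truth
# maps, kappa and label volumes, plus a JSON sidecar with the protocol,
# class parameters, noise sd and seed.
write_phantom <- function(ph, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cp <- compile_protocol(ph$protocol)
  d <- ph$spec$dim
  nm <- channel_names(cp)
  for (j in seq_along(nm))
    write_nifti_map(array(ph$images[, j], d),
                    file.path(out_dir, paste0("image_", nm[j], ".nii.gz")))
  for (t in names(ph$truth))
    write_nifti_map(ph$truth[[t]], file.path(out_dir, paste0("truth_", t, ".nii.gz")))
  write_nifti_map(ph$kappa_map, file.path(out_dir, "kappa.nii.gz"))
  write_nifti_map(ph$label_map + 0, file.path(out_dir, "labels.nii.gz"))
  write_protocol(ph$protocol, file.path(out_dir, "protocol.json"))
  side <- list(dim = d, noise_sd = ph$noise_sd, seed = ph$seed,
               classes = lapply(ph$spec$classes, function(cl)
                 list(rho_r = Re(cl$rho), rho_i = Im(cl$rho), t1 = cl$t1,
                      t2 = cl$t2, d_omega = cl$d_omega)),
               channels = nm)
  jsonlite::write_json(side, file.path(out_dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

channel_names <- function(cp) {
  c(sprintf("spgr%02d", seq_len(cp$ns)),
    as.vector(rbind(sprintf("bssfp%02d_re", seq_len(cp$nb)),
                    sprintf("bssfp%02d_im", seq_len(cp$nb)))))
}

#' Voxelwise joint fitting over image volumes
#'
#' Applies [fit_jsr()] independently to every masked voxel of an image
#' stack. Results do not depend on the processing order or on the chunk
#' partition (each voxel's fit is deterministic), so chunked and serial
#' runs are bit-identical.
#'
#' @param images matrix `n_voxels` x `n_channels` (as in a
#'   `jsr_phantom`), or a list of arrays of a common dimension, one per
#'   channel.
#' @param protocol a [protocol()].
#' @param kappa_map transmit-scale array/vector (recycled if length 1).
#' @param mask logical array/vector; `NULL` fits every voxel.
#' @param options a [fit_options()].
#' @param dim volume dimension for reshaping the output maps (taken
#'   from list inputs automatically).
#' @param chunk_size voxels per processing chunk.
#' @return List of maps: `t1`, `t2`, `d_omega`, `rho_mod`, `rho_arg`,
#'   `converged`; unmasked voxels are `NA`.
#' @export
voxelwise_fit <- function(images, protocol, kappa_map = 1, mask = NULL,
                          options = fit_options(), dim = NULL,
                          chunk_size = 1024) {
  if (is.list(images) && !is.matrix(images)) {
    dims <- lapply(images, function(a) base::dim(a) %||% length(a))
    if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
      stop("channel volumes have inconsistent dimensions")
    dim <- dim %||% dims[[1]]
    images <- do.call(cbind, lapply(images, as.vector))
  }
  cp <- compile_protocol(protocol)
  if (ncol(images) != cp$ns + 2L * cp$nb)
    stop(sprintf("images provide %d channels but the protocol predicts %d",
                 ncol(images), cp$ns + 2L * cp$nb))
  nvox <- nrow(images)
  kap <- rep(as.vector(kappa_map), length.out = nvox)
  msk <- if (is.null(mask)) rep(TRUE, nvox) else as.vector(mask)
  if (length(msk) != nvox) stop("mask length does not match the image volume")
  out <- matrix(NA_real_, nvox, 6,
                dimnames = list(NULL, c("t1", "t2", "d_omega", "rho_mod",
                                        "rho_arg", "converged")))
  idx <- which(msk)
  for (start in if (length(idx)) seq(1, length(idx), by = chunk_size) else integer(0)) {
    chunk <- idx[start:min(start + chunk_size - 1, length(idx))]
    for (v in chunk) {
      ft <- fit_jsr(images[v, ], protocol, kappa = kap[v], options = options)
      if (!is.null(ft$failure_reason)) next
      th <- ft$theta_hat
      out[v, ] <- c(th["t1"], th["t2"], th["d_omega"],
                    sqrt(th["rho_r"]^2 + th["rho_i"]^2),
                    atan2(th["rho_i"], th["rho_r"]), as.numeric(ft$converged))
    }
  }
  maps <- lapply(colnames(out), function(cn)
    if (is.null(dim)) out[, cn] else array(out[, cn], dim))
  stats::setNames(maps, colnames(out))
}
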