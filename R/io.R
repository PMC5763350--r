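#' Read and write protocols as YAML or JSON
#'
#' A protocol file is a list of acquisition entries under a `sequences`
#' key, each with fields `kind` (`spgr`/`bssfp`), `flip_deg`, `tr_ms`,
#' optional `te_ms` (defaulting to half the bSSFP TR), `phi_rf_deg`
#' (bSSFP) and `t_rf_ms`. The format is chosen by file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param p a [protocol()].
#' @param path file path.
#' @return `read_protocol()` returns a validated `jsr_protocol`;
#'   `write_protocol()` returns `path` invisibly.
#' @export
write_protocol <- function(p, path) {
  stopifnot(inherits(p, "jsr_protocol"))
  entries <- lapply(p, function(s) {
    e <- list(kind = s$kind, flip_deg = s$flip, tr_ms = s$tr, te_ms = s$te,
              t_rf_ms = s$t_rf)
    if (s$kind == "bssfp") e$phi_rf_deg <- s$phi_rf * 180 / pi
    e
  })
  doc <- list(sequences = entries)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else stop("unrecognised protocol format (use .yaml or .json): ", path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else stop("unrecognised protocol format (use .yaml or .json): ", path)
  if (is.null(doc$sequences)) stop("protocol file lacks a 'sequences' field: ", path)
  seqs <- lapply(seq_along(doc$sequences), function(i) {
    e <- doc$sequences[[i]]
    for (f in c("kind", "flip_deg", "tr_ms"))
      if (is.null(e[[f]]))
        stop(sprintf("sequence %d is missing required field '%s'", i, f))
    sequence_spec(e$kind, flip_deg = e$flip_deg, tr_ms = e$tr_ms,
                  te_ms = e$te_ms, phi_rf_deg = e$phi_rf_deg %||% 0,
                  t_rf_ms = e$t_rf_ms %||% 0)
  })
  protocol(seqs)
}

#' Read and write parameter maps as NIfTI-1 volumes
#'
#' Maps are written as float32 with the affine of the optional reference
#' image preserved; reading returns a plain numeric array with the NIfTI
#' attributes retained.
#'
#' @param x numeric array (2D/3D).
#' @param path file path (`.nii` or `.nii.gz`).
#' @param reference optional NIfTI image or array carrying the target
#'   geometry.
#' @return `read_nifti_map()` returns the image array;
#'   `write_nifti_map()` returns `path` invisibly.
#' @export
write_nifti_map <- function(x, path, reference = NULL) {
  img <- if (!is.null(reference)) RNifti::asNifti(x, reference = reference)
  else RNifti::asNifti(x)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_nifti_map
#' @export
read_nifti_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  RNifti::readNifti(path)
}
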