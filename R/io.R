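#' Read and write spectrum CSV files
#'
#' Spectra travel as two-column CSV (`wavelength_nm`, `intensity`).
#'
#' @param spectrum A `spectrum` tibble.
#' @param path File path.
#' @return `write_spectrum_csv()` returns `path` invisibly;
#'   `read_spectrum_csv()` returns a `spectrum` tibble.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(spectrum[, c("wavelength_nm", "intensity")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("wavelength_nm", "intensity") %in% names(df)))
  new_spectrum(df$wavelength_nm, df$intensity, meta = list(source = path))
}

#' Write a position ensemble with its JSON sidecar
#'
#' The heights go to a single-column CSV (`z_nm`); seed, hash and chain
#' count go to `<path>.json`.
#'
#' @param ensemble A [sample_chain_conformations()] ensemble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  utils::write.csv(ensemble["z_nm"], path, row.names = FALSE)
  sidecar <- list(
    seed = attr(ensemble, "seed"),
    n_chains = attr(ensemble, "n_chains"),
    spec_hash = attr(ensemble, "spec_hash")
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read and write QCM trace CSV files
#'
#' Traces travel as CSV (`time_s`, `delta_f_hz`); interval annotations as
#' a JSON sidecar `<path>.json`.
#'
#' @param trace A [qcm_trace()].
#' @param path CSV path.
#' @return `write_qcm_csv()` returns `path` invisibly; `read_qcm_csv()`
#'   returns a `qcm_trace`.
#' @export
write_qcm_csv <- function(trace, path) {
  utils::write.csv(trace[, c("time_s", "delta_f_hz")], path, row.names = FALSE)
  ann <- attr(trace, "annotations")
  if (!is.null(ann)) {
    jsonlite::write_json(ann, paste0(path, ".json"), digits = NA)
  }
  invisible(path)
}

#' @rdname write_qcm_csv
#' @export
read_qcm_csv <- function(path) {
  df <- utils::read.csv(path)
  ann_path <- paste0(path, ".json")
  ann <- if (file.exists(ann_path)) {
    tibble::as_tibble(jsonlite::read_json(ann_path, simplifyVector = TRUE))
  } else {
    NULL
  }
  qcm_trace(df$time_s, df$delta_f_hz, annotations = ann)
}
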