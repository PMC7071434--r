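#' Read and write recordings as columnar CSV
#'
#' One column per channel with a header row of channel ids: `1`..`35` for the
#' chest grid, `LA`/`RA`/`LL`, and `V1`..`V6`.  Sample values are microvolts.
#'
#' @param recording An `mc_recording`.
#' @param path Output file path.
#' @export
write_recording_csv <- function(recording, path) {
  m <- t(rbind(recording$chest, recording$limb, recording$precordial))
  df <- as.data.frame(m)
  names(df) <- c(rownames(recording$chest), rownames(recording$limb),
                 rownames(recording$precordial))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param fs Sampling rate of the stored samples (Hz).
#' @param subject_id,session_id Identifiers to attach.
#' @return `read_recording_csv()` returns an `mc_recording`.
#' @export
read_recording_csv <- function(path, fs, subject_id = NA, session_id = NA) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- t(as.matrix(df))
  chest_ids <- rownames(m)[grepl("^[0-9]+$", rownames(m))]
  chest_ids <- chest_ids[order(as.integer(chest_ids))]
  need <- c("LA", "RA", "LL", paste0("V", 1:6))
  if (!all(need %in% rownames(m)))
    stop("CSV is missing limb/precordial channels: ",
         paste(setdiff(need, rownames(m)), collapse = ", "), call. = FALSE)
  structure(list(fs = fs,
                 chest = m[chest_ids, , drop = FALSE],
                 limb = m[c("LA", "RA", "LL"), , drop = FALSE],
                 precordial = m[paste0("V", 1:6), , drop = FALSE],
                 subject_id = subject_id, session_id = session_id),
            class = "mc_recording")
}

#' Read / write a study configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), chosen by extension.  The
#' round-trip is lossless for the fields of [study_config()].
#'
#' @param path Config file path.
#' @export
read_study_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension: ", ext, call. = FALSE))
  do.call(study_config, raw)
}

#' @rdname read_study_config
#' @param config A [study_config()].
#' @export
write_study_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  switch(ext,
    yml = , yaml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                                pretty = TRUE),
    stop("unsupported config extension: ", ext, call. = FALSE))
  invisible(path)
}
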