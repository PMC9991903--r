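#' Waveform CSV schema
#'
#' Records are interchanged as plain CSV with the header
#' `time_s, flow_lps, volume_ml, p_pl_cmh2o, p_ab_cmh2o, p_act_psi[,
#' d_dia_cm]` plus a JSON metadata sidecar (`<path>.json`) carrying
#' `scenario`, `seed`, `fs`, `body_mass_kg` and `schema_version`. Time must
#' be strictly increasing and uniform to 1 ppm; required columns must be
#' NA-free. Unknown extra columns are tolerated and preserved in `meta`.
#'
#' @name waveform_file_schema
NULL

.schema_version <- "1"
.required_cols <- c("time_s", "flow_lps", "volume_ml", "p_pl_cmh2o",
                    "p_ab_cmh2o", "p_act_psi")

#' Write a waveform record to CSV (+ JSON sidecar)
#'
#' @param rec a [waveform_record()].
#' @param path output CSV path; the metadata sidecar is written to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(rec, path) {
  df <- data.frame(time_s = rec$t, flow_lps = rec$flow,
                   volume_ml = rec$volume, p_pl_cmh2o = rec$p_pl,
                   p_ab_cmh2o = rec$p_ab, p_act_psi = rec$p_act)
  if (!is.null(rec$d_dia)) df$d_dia_cm <- rec$d_dia
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(rec$meta, list(fs = rec$fs, schema_version = .schema_version))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a waveform record from CSV
#'
#' Validates the [waveform_file_schema]: missing required columns, NA in a
#' required column, or non-uniform time are rejected, naming the offending
#' rows. Extra columns are preserved under `meta$extra_columns`.
#'
#' @param path CSV path (JSON sidecar `<path>.json` read if present).
#' @return a [waveform_record()].
#' @export
read_waveform <- function(path) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(.required_cols, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  for (cc in .required_cols) {
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad))
      stop("non-finite values in '", cc, "' at rows: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  tt <- df$time_s
  fs <- if (length(tt) >= 2) 1 / stats::median(diff(tt)) else 1000
  if (length(tt) >= 2) {
    dtv <- diff(tt)
    bad <- which(abs(dtv - 1 / fs) > 1e-6 / fs)
    if (length(bad))
      stop("non-uniform time base at rows: ",
           paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$fs)) fs <- meta$fs
    meta$fs <- NULL
  }
  extra <- setdiff(names(df), c(.required_cols, "d_dia_cm"))
  if (length(extra)) meta$extra_columns <- df[extra]
  waveform_record(t = tt, flow = df$flow_lps, volume = df$volume_ml,
                  p_pl = df$p_pl_cmh2o, p_ab = df$p_ab_cmh2o,
                  p_act = df$p_act_psi, d_dia = df$d_dia_cm, fs = fs,
                  meta = meta)
}
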