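#' Read a MID table
#'
#' Reads a long-format isotopologue table in the package's CSV dialect:
#' required columns `sample_id, compound, isotopologue, value, value_type`
#' (UTF-8, header row), one row per sample x isotopologue, with
#' `value_type` either `"intensity"` (normalized on read) or `"fraction"`.
#' Extra columns (`condition`, `oxygen`, `tracer`, `acetate_spike_uM`,
#' `replicate`, ...) are carried through as per-sample metadata.
#'
#' @param path Path to the CSV file.
#' @return A list with one element per sample: `sample_id`, `mid` (a
#'   [mid()] object) and `metadata` (one-row data frame of the extra
#'   columns).
#' @export
read_mid_table <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "compound", "isotopologue", "value", "value_type")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("MID table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  meta_cols <- setdiff(names(tab), required)
  samples <- split(tab, tab$sample_id)
  lapply(samples, function(s) {
    sid <- s$sample_id[1]
    s <- s[order(s$isotopologue), , drop = FALSE]
    n <- max(s$isotopologue)
    if (!identical(as.integer(s$isotopologue), 0:n))
      stop(sprintf(
        "incomplete MID for sample '%s': isotopologue indices must be contiguous 0..n",
        sid), call. = FALSE)
    vt <- unique(s$value_type)
    if (length(vt) != 1L || !vt %in% c("intensity", "fraction"))
      stop(sprintf("sample '%s': unknown or mixed value_type (%s)",
                   sid, paste(vt, collapse = ", ")), call. = FALSE)
    m <- if (vt == "intensity") {
      normalize_intensities(s$value, compound_label = s$compound[1],
                            n_carbons = n)
    } else {
      tot <- sum(s$value)
      if (abs(tot - 1) > 0.01)
        message(sprintf(
          "sample '%s': fractions sum to %.4g; renormalizing", sid, tot))
      normalize_intensities(s$value, compound_label = s$compound[1],
                            n_carbons = n)
    }
    list(sample_id = sid, mid = m,
         metadata = s[1, meta_cols, drop = FALSE])
  })
}

#' Write a MID table
#'
#' Writes a long-format MID table with byte-stable formatting: numeric
#' values are printed at 6 significant digits, so identical tables always
#' produce identical files.
#'
#' @param tab Data frame in the MID CSV dialect (see [read_mid_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mid_table <- function(tab, path) {
  .write_csv_stable(tab, path)
}

# CSV writer with fixed 6-significant-digit float formatting; avoids
# locale- or precision-dependent bytes in outputs.
.write_csv_stable <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- out[[nm]]
      s <- ifelse(is.na(v), "", trimws(formatC(v, format = "g", digits = 6)))
      out[[nm]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
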