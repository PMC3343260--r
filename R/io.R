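#' Read and write long-format twin CSV files
#'
#' The on-disk interchange format is one row per individual with columns
#' `pair_id, zygosity, member, affected, bv, bv_cat, site, sex, age, icv`
#' (missing values as empty fields).  `write_twin_csv()` also writes a JSON
#' sidecar (`<path>.json`) recording generating parameters and seed when
#' supplied, so a dataset carries its provenance.
#'
#' @param data long-format twin data.
#' @param path CSV file path.
#' @param params optional list of generating parameters stored in the sidecar.
#' @return `read_twin_csv()` returns the data frame (with the sidecar, if
#'   present, attached as attribute `"provenance"`); `write_twin_csv()`
#'   returns `path` invisibly.
#' @export
write_twin_csv <- function(data, path, params = NULL) {
  cols <- intersect(c("pair_id", "zygosity", "member", "affected", "bv",
                      "bv_cat", "site", "sex", "age", "icv", "group"),
                    names(data))
  write.csv(data[cols], path, row.names = FALSE, na = "")
  if (!is.null(params))
    jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_twin_csv
#' @export
read_twin_csv <- function(path) {
  if (!file.exists(path))
    stop("twin CSV not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "zygosity", "member", "affected", "bv")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("twin CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"bv_cat" %in% names(d)) d$bv_cat <- NA_integer_
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(d, "provenance") <- jsonlite::read_json(side, simplifyVector = TRUE)
  d
}
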