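## Tabular serialization of sweep results. TSV with "NA" sentinels and 9
## significant digits: unambiguous for downstream tabular tooling and
## deterministic (identical runs give byte-identical files).

TSV_HEADER <- c("theta_value", "cora", "dlogY", "dlogYNF", "y_ss",
                "y_fb_pert", "y_nf_pert", "status")

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", vapply(x, function(v) format(v, digits = 9), character(1)))
}

#' Write a control-ratio sweep to TSV
#'
#' Tab-separated, one row per grid point in grid order, header
#' `theta_value  cora  dlogY  dlogYNF  y_ss  y_fb_pert  y_nf_pert  status`;
#' numbers carry 9 significant digits, undefined fields are written as `NA`.
#'
#' @param result a `cora_sweep` (or a single [cora_point()] row).
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_sweep_tsv <- function(result, path) {
  lines <- c(
    paste(TSV_HEADER, collapse = "\t"),
    vapply(seq_len(nrow(result)), function(i) {
      paste(c(fmt_num(result$theta_value[[i]]),
              fmt_num(result$cora[[i]]),
              fmt_num(result$dlog_y[[i]]),
              fmt_num(result$dlog_y_nf[[i]]),
              fmt_num(result$y_ss[[i]]),
              fmt_num(result$y_fb_pert[[i]]),
              fmt_num(result$y_nf_pert[[i]]),
              result$status[[i]]), collapse = "\t")
    }, character(1))
  )
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop(sprintf("cannot open \"%s\" for writing: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read back a sweep TSV
#'
#' @param path TSV file written by [write_sweep_tsv()].
#' @return a tibble with the package's column names.
#' @export
read_sweep_tsv <- function(path) {
  dat <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = c(rep("numeric", 7), "character"),
                           na.strings = "NA", check.names = FALSE)
  names(dat) <- c("theta_value", "cora", "dlog_y", "dlog_y_nf", "y_ss",
                  "y_fb_pert", "y_nf_pert", "status")
  tibble::as_tibble(dat)
}
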