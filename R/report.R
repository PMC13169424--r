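# Stage-output reporting: machine-readable CSV plus a human-readable
# text summary.  Byte-identical machine output for identical inputs/seeds.

.result_to_row <- function(x) {
  if (inherits(x, "echo_agreement")) return(as.data.frame(x))
  if (inherits(x, "yield_result")) {
    return(data.frame(parameter = x$parameter, ref_reader = x$ref_reader,
                      comp_reader = x$comp_reader, n_ref = x$n_ref,
                      n_comp = x$n_comp, n_common = x$n_common,
                      relative_yield_pct = x$relative_yield_pct,
                      stringsAsFactors = FALSE))
  }
  if (inherits(x, "rcv_result")) {
    return(data.frame(cv_analytic = x$cv_analytic,
                      cv_biological = x$cv_biological, z = x$z,
                      cv_total = x$cv_total, rcv_pct = x$rcv_pct,
                      stringsAsFactors = FALSE))
  }
  if (inherits(x, "roc_result")) {
    return(data.frame(auc = x$auc, ci_lo = x$ci[1], ci_hi = x$ci[2],
                      n_pos = x$n_pos, n_neg = x$n_neg,
                      stringsAsFactors = FALSE))
  }
  if (inherits(x, "delong_comparison")) {
    return(data.frame(auc1 = x$auc1, auc2 = x$auc2, z = x$z,
                      p_value = x$p_value, stringsAsFactors = FALSE))
  }
  if (inherits(x, "group_test")) {
    return(data.frame(method = x$method, statistic = x$statistic,
                      df = paste(x$df, collapse = "/"), p_value = x$p_value,
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(x)) return(x)
  stop("unsupported result type: ", paste(class(x), collapse = "/"))
}

#' Write a stage-results report
#'
#' Writes every result as one labelled block in a machine-readable CSV
#' (\code{<stem>.csv}, deterministic: identical inputs and seeds give
#' byte-identical files) and a human-readable text summary
#' (\code{<stem>.txt}).
#'
#' @param results non-empty named list of stage outputs
#'   (\code{echo_agreement}, \code{yield_result}, \code{rcv_result},
#'   \code{roc_result}, \code{delong_comparison}, \code{group_test}, or
#'   plain data frames).
#' @param path output stem or CSV path (a \code{.csv} extension is
#'   stripped to form the stem).
#' @return invisibly, the two file paths written.
#' @export
write_summary_report <- function(results, path) {
  if (!length(results)) stop("results must be non-empty")
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- paste0("result_", seq_along(results))
  stem <- sub("\\.csv$", "", path)
  rows <- lapply(names(results), function(nm) {
    df <- .result_to_row(results[[nm]])
    cbind(data.frame(result = nm, stringsAsFactors = FALSE),
          as.data.frame(lapply(df, function(col) {
            if (is.numeric(col)) format(col, digits = 15, trim = TRUE,
                                        scientific = FALSE) else col
          }), stringsAsFactors = FALSE))
  })
  con <- file(paste0(stem, ".csv"), open = "wb")
  on.exit(close(con), add = TRUE)
  for (df in rows) {
    write.csv(df, con, row.names = FALSE, na = "")
  }

  txt <- file(paste0(stem, ".txt"), open = "wb")
  on.exit(close(txt), add = TRUE)
  sink(txt); on.exit(sink(), add = TRUE, after = FALSE)
  for (nm in names(results)) {
    cat("== ", nm, " ==\n", sep = "")
    obj <- results[[nm]]
    if (is.data.frame(obj)) print(obj) else print(obj)
    cat("\n")
  }
  invisible(c(paste0(stem, ".csv"), paste0(stem, ".txt")))
}
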