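#' Write a current family as a delimited trace table with a JSON sidecar
#'
#' The trace table is a wide tab-separated file: column 1 is \code{time_ms},
#' one column per test potential labeled by its value in mV. The sidecar is a
#' JSON file holding the recording metadata (pH_o, pH_i, temperature_K,
#' configuration, protocol, any extras). Subsweeps, when present, go to a
#' second table \code{<table>.p4.tsv} with one column per (test potential,
#' subsweep) pair. The table round-trips bit-stably: values are written with
#' full precision.
#'
#' @param family A [current_family()].
#' @param table_path Path for the trace table (TSV).
#' @param meta_path Path for the metadata sidecar; default replaces the table
#'   extension with \code{.json}.
#' @return Invisibly, the paths written.
#' @export
write_current_family <- function(family, table_path, meta_path = NULL) {
  stopifnot(inherits(family, "current_family"))
  if (is.null(meta_path))
    meta_path <- paste0(tools::file_path_sans_ext(table_path), ".json")
  tab <- data.frame(time_ms = family$time_ms, family$traces,
                    check.names = FALSE)
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                     table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(pH_o = family$pH_o, pH_i = family$pH_i,
               temperature_K = family$temperature_K,
               configuration = family$configuration,
               protocol = unclass(family$protocol),
               extra = family$extra,
               has_subsweeps = !is.null(family$subsweeps))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(family$subsweeps)) {
    p4 <- do.call(cbind, family$subsweeps)
    colnames(p4) <- unlist(lapply(seq_along(family$protocol$test_mV), function(i)
      paste0(format(family$protocol$test_mV[i], trim = TRUE), ".s",
             seq_len(ncol(family$subsweeps[[i]])))))
    p4tab <- data.frame(time_ms = family$time_ms, p4, check.names = FALSE)
    utils::write.table(format(p4tab, digits = 17, trim = TRUE, scientific = FALSE),
                       paste0(table_path, ".p4.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(table = table_path, meta = meta_path))
}

#' Read a current family written by [write_current_family()]
#'
#' @param table_path Path of the trace table (TSV).
#' @param meta_path Path of the JSON metadata sidecar; default derived from
#'   \code{table_path}.
#' @return A [current_family()].
#' @export
read_current_family <- function(table_path, meta_path = NULL) {
  if (is.null(meta_path))
    meta_path <- paste0(tools::file_path_sans_ext(table_path), ".json")
  tab <- utils::read.table(table_path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pr <- meta$protocol
  protocol <- voltage_protocol(holding_mV = pr$holding_mV,
                               test_mV = pr$test_mV,
                               duration_ms = pr$duration_ms,
                               dt_ms = pr$dt_ms,
                               tail_mV = pr$tail_mV,
                               p4_n = if (is.null(pr$p4_n)) 0L else pr$p4_n,
                               p4_holding_mV = if (is.null(pr$p4_holding_mV))
                                 pr$holding_mV else pr$p4_holding_mV)
  subsweeps <- NULL
  if (isTRUE(meta$has_subsweeps)) {
    p4tab <- utils::read.table(paste0(table_path, ".p4.tsv"), header = TRUE,
                               sep = "\t", check.names = FALSE)
    labs <- sub("\\.s[0-9]+$", "", colnames(p4tab)[-1])
    subsweeps <- lapply(format(protocol$test_mV, trim = TRUE), function(v)
      as.matrix(p4tab[, -1, drop = FALSE][, labs == v, drop = FALSE]))
  }
  current_family(time_ms = tab$time_ms,
                 traces = as.matrix(tab[, -1, drop = FALSE]),
                 protocol = protocol,
                 pH_o = meta$pH_o, pH_i = meta$pH_i,
                 temperature_K = meta$temperature_K,
                 configuration = meta$configuration,
                 subsweeps = subsweeps,
                 extra = as.list(meta$extra))
}
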