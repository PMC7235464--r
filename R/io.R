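#' Write a simulation trace to CSV
#'
#' Long-format serialization: one row per (step, neuron) with membrane
#' potential, spike current and composite signal, plus a companion
#' one-row-per-event spike file (neuron, step). Output is deterministic:
#' identical traces produce byte-identical files.
#'
#' @param trace a `gt_trace`.
#' @param path output CSV path for the long-format trace.
#' @param spikes_path optional path for the spike-event CSV.
#' @return invisibly, the paths written.
#' @export
write_trace_csv <- function(trace, path, spikes_path = NULL) {
  M <- nrow(trace$v)
  T_ <- ncol(trace$v)
  df <- data.frame(
    step = rep(seq_len(T_), each = M),
    neuron = rep(seq_len(M), T_),
    v = as.vector(trace$v),
    psi = as.vector(trace$psi),
    s = as.vector(trace$s)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  paths <- path
  if (!is.null(spikes_path)) {
    ev <- data.frame(
      neuron = rep(seq_along(trace$spikes), lengths(trace$spikes)),
      step = unlist(trace$spikes, use.names = FALSE)
    )
    if (!nrow(ev)) ev <- data.frame(neuron = integer(0), step = integer(0))
    utils::write.csv(ev, spikes_path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, spikes_path)
  }
  invisible(paths)
}

#' Read a long-format trace CSV
#'
#' @param path CSV written by [write_trace_csv()].
#' @return list with M x T matrices `v`, `psi`, `s`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  M <- max(df$neuron)
  T_ <- max(df$step)
  shape <- function(col) matrix(col, nrow = M, ncol = T_)
  list(v = shape(df$v), psi = shape(df$psi), s = shape(df$s))
}

#' Write a flat key-value configuration file
#'
#' YAML-style `key: value` lines. Numeric vectors are serialized
#' comma-separated; logicals as `true`/`false`.
#'
#' @param config named list of scalars or numeric vectors.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gt_config <- function(config, path) {
  fmt <- function(x) {
    if (is.logical(x)) return(paste(ifelse(x, "true", "false"),
                                    collapse = ", "))
    paste(format(x, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = ", ")
  }
  lines <- vapply(names(config), function(k) {
    paste0(k, ": ", fmt(config[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Parses `key: value` lines written by [write_gt_config()] (or by hand).
#' Values are sniffed: `true`/`false` become logical, numeric-looking
#' scalars and comma-separated lists become numeric vectors, everything
#' else stays character. Lines starting with `#` and blank lines are
#' ignored.
#'
#' @param path configuration file path.
#' @return named list.
#' @export
read_gt_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regexpr(":", ln, fixed = TRUE)
    if (m < 0) stop("malformed config line: ", ln)
    key <- trimws(substr(ln, 1, m - 1))
    val <- trimws(substr(ln, m + 1, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    if (all(tolower(parts) %in% c("true", "false"))) {
      parsed <- tolower(parts) == "true"
    } else {
      num <- suppressWarnings(as.numeric(parts))
      parsed <- if (!anyNA(num)) num else val
    }
    out[[key]] <- parsed
  }
  out
}

#' Write an output manifest with content hashes
#'
#' Records every artifact of a protocol run with its md5 content hash, so
#' re-runs can be checked for byte-identical determinism.
#'
#' @param files character vector of file paths.
#' @param path manifest output path (CSV with columns `file`, `md5`).
#' @return invisibly, the manifest path.
#' @export
write_manifest <- function(files, path) {
  df <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  df <- df[order(df$file), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
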