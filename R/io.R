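#' Read a trait panel from delimited text
#'
#' Expects columns `name`, `unit`, `mean` and optionally `h2`. Comma or tab
#' delimited (auto-detected); decimal point only.
#'
#' @param path File path.
#' @param reference Reference trait name (default `"DryMatter"`).
#' @return A [trait_panel()].
#' @export
read_panel <- function(path, reference = "DryMatter") {
  df <- read_delim_auto(path)
  need <- c("name", "unit", "mean")
  if (!all(need %in% names(df))) {
    stop("panel file must have columns: ", paste(need, collapse = ", "))
  }
  trait_panel(df$name, df$unit, as.numeric(df$mean),
              h2 = if ("h2" %in% names(df)) as.numeric(df$h2) else NULL,
              reference = reference)
}

#' Write a trait panel to CSV
#'
#' @param panel A [trait_panel()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a labelled square matrix from delimited text
#'
#' The first row and first column carry trait labels. The matrix is
#' reordered to panel order; traits absent from the panel are dropped with a
#' warning; panel traits absent from the file are an error.
#'
#' @param path File path (comma or tab delimited, auto-detected).
#' @param panel A [trait_panel()] fixing trait order.
#' @return A labelled numeric n x n matrix in panel order.
#' @export
read_matrix <- function(path, panel) {
  df <- read_delim_auto(path)
  labels <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(M)) {
    suppressWarnings(storage.mode(M) <- "double")
    if (anyNA(M)) stop("non-numeric cell in matrix file ", path)
  }
  rownames(M) <- labels
  missing <- setdiff(panel$name, labels)
  if (length(missing)) {
    stop("matrix in ", path, " is missing panel trait(s): ",
         paste(missing, collapse = ", "))
  }
  if (!setequal(colnames(M), labels) || nrow(M) != ncol(M)) {
    if (!all(panel$name %in% colnames(M))) {
      stop("matrix in ", path, " is not square after label alignment")
    }
  }
  extra <- setdiff(labels, panel$name)
  if (length(extra)) {
    warning("dropping trait(s) not in panel: ", paste(extra, collapse = ", "))
  }
  M[panel$name, panel$name, drop = FALSE]
}

#' Write a labelled matrix to CSV
#'
#' @param M Labelled square matrix.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(M, path) {
  df <- data.frame(trait = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario from a YAML config
#'
#' Layout:
#' ```yaml
#' name: S1
#' gains:
#'   - {trait: DryMatter, value: 20, mode: percent}
#'   - {trait: DOYFS1, value: 44, mode: absolute}
#' ```
#' Mixed absolute/percent entries are supported within one scenario.
#'
#' @param path File path.
#' @return A [scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name)) stop("scenario config needs a 'name' field")
  if (is.null(cfg$gains) || length(cfg$gains) == 0L) {
    stop("scenario config needs a non-empty 'gains' list")
  }
  gains <- do.call(rbind, lapply(cfg$gains, function(g) {
    if (is.null(g$trait) || is.null(g$value)) {
      stop("each gain needs 'trait' and 'value'")
    }
    mode <- if (is.null(g$mode)) "absolute" else g$mode
    if (!mode %in% c("absolute", "percent")) {
      stop("unknown gain mode '", mode, "'")
    }
    data.frame(trait = g$trait, value = as.numeric(g$value), mode = mode,
               stringsAsFactors = FALSE)
  }))
  scenario(cfg$name, gains)
}

#' Write a scenario report to a delimited file
#'
#' One row per trait in panel order, with a comment header carrying the
#' scenario name, index SD, intensity, selected fraction, economic-value
#' ratios and monetization mode. Byte-deterministic for fixed input.
#'
#' @param report A `scenario_report` from [run_scenario()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  s <- report$solution
  ratios <- paste(names(report$econ_ratios),
                  format_econ_ratios(report$econ_ratios),
                  sep = "=", collapse = ";")
  writeLines(c(
    sprintf("# scenario: %s", report$scenario$name),
    sprintf("# sigma_I: %.6f", s$sigma_I),
    sprintf("# intensity: %.6f", s$i),
    sprintf("# selected_fraction: %.6f", s$p),
    sprintf("# econ_ratios: %s", ratios),
    sprintf("# monetize_mode: %s", report$monetize_mode)
  ), con)
  tab <- report$table
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.6g", x))
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a written scenario report
#'
#' @param path File written by [write_report()].
#' @return A list with `header` (named character) and `table` (data frame).
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- sub("^# ([^:]+): (.*)$", "\\1\t\\2", hdr)
  parts <- strsplit(kv, "\t", fixed = TRUE)
  header <- stats::setNames(vapply(parts, `[`, "", 2L),
                            vapply(parts, `[`, "", 1L))
  tab <- utils::read.csv(textConnection(lines[!startsWith(lines, "# ")]),
                         stringsAsFactors = FALSE)
  list(header = header, table = tab)
}

# comma/tab auto-detection on the first non-empty line; dot decimal only
read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
}
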