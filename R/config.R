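#' Read a key = value configuration file
#'
#' Parses the plain-text configuration format used for the shipped trial
#' and simulation defaults: `[section]` headers followed by `key = value`
#' lines.  Comma-separated values become numeric vectors when every
#' element parses as a number, otherwise character vectors.  Lines
#' starting with `#` (and blank lines) are ignored.
#'
#' @param path path to the configuration file.
#' @return A named list of sections; each section is a named list of
#'   parsed values.
#' @examples
#' cfg <- read_config(system.file("extdata", "sim.cfg", package = "stentflow"))
#' cfg$boundary$P_in_mmHg
#' @export
read_config <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (expected key = value): ", ln, call. = FALSE)
    }
    if (is.null(section)) stop("config entry before any [section]: ", ln, call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[section]][[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' Paths of the shipped default configuration files
#'
#' @return Named character vector with elements `trial` and `sim`.
#' @export
default_config_paths <- function() {
  c(trial = system.file("extdata", "trial.cfg", package = "stentflow"),
    sim = system.file("extdata", "sim.cfg", package = "stentflow"))
}
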