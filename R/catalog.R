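#' Step catalogs
#'
#' A step catalog is the ordered list of annotatable surgical steps: a tibble
#' with integer column `step_id` (unique, contiguous, 1-based) and character
#' column `step_name`. [default_catalog()] returns the built-in 21-step
#' robotic proctectomy card; [step_catalog()] builds a custom catalog (any
#' size >= 2) for other procedures.
#'
#' @param step_id Integer vector of step identifiers, `1..n` in order.
#' @param step_name Character vector of step names, same length.
#'
#' @return A tibble of class `step_catalog` with columns `step_id`,
#'   `step_name`.
#' @examples
#' default_catalog()
#' step_catalog(1:3, c("exposure", "dissection", "closure"))
#' @export
step_catalog <- function(step_id, step_name) {
  step_id <- as.integer(step_id)
  step_name <- as.character(step_name)
  cat <- tibble::tibble(step_id = step_id, step_name = step_name)
  validate_catalog(cat)
}

validate_catalog <- function(cat) {
  if (!all(c("step_id", "step_name") %in% names(cat))) {
    stop("catalog must have columns step_id and step_name", call. = FALSE)
  }
  cat$step_id <- as.integer(cat$step_id)
  n <- nrow(cat)
  if (n < 2) stop("catalog must contain at least 2 steps", call. = FALSE)
  if (!identical(cat$step_id, seq_len(n))) {
    stop("step_id must be unique, contiguous and 1-based, in order",
         call. = FALSE)
  }
  if (anyNA(cat$step_name) || any(cat$step_name == "")) {
    stop("step_name must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(cat$step_name)) {
    stop("step_name must be unique", call. = FALSE)
  }
  class(cat) <- unique(c("step_catalog", class(cat)))
  cat
}

# Table-ordered 21-step robotic proctectomy card. Step numbering is the one
# used throughout reports and chord diagrams (e.g. step 2 = IMA dissection,
# step 9 = medial-to-lateral rectal mobilization, step 17 = rectal
# transection, step 21 = colorectal anastomosis).
.rp_step_names <- c(
  "Initial Exposure",
  "IMA dissection",
  "Ligation & division of IMA",
  "IMV dissection",
  "Ligation & division of IMV",
  "Splenic flexure mobilization (medial-to-lateral)",
  "Splenic flexure mobilization (lateral-to-medial)",
  "Splenic flexure mobilization (supracolic)",
  "Rectal mobilization (medial-to-lateral)",
  "Descending & sigmoid colon mobilization (medial-to-lateral)",
  "Descending & sigmoid colon mobilization (lateral-to-medial)",
  "Posterior rectal dissection",
  "Anterior rectal dissection",
  "Right lateral rectal dissection",
  "Left lateral rectal dissection",
  "Division of the mesorectum",
  "Rectal transection",
  "Division of the mesocolon",
  "Proximal colon transection",
  "Testing for leak (optional)",
  "Colorectal anastomosis"
)

#' @rdname step_catalog
#' @export
default_catalog <- function() {
  step_catalog(seq_along(.rp_step_names), .rp_step_names)
}

#' Read or write a step catalog file
#'
#' Catalog files are delimited text with header `step_id,step_name`
#' (comma default, tab accepted).
#'
#' @param path File path.
#' @param catalog A `step_catalog`.
#' @return `read_catalog()` returns a `step_catalog`; `write_catalog()`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  df <- read_delimited(path, c("step_id", "step_name"))
  step_catalog(df$step_id, df$step_name)
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  catalog <- validate_catalog(catalog)
  readr::write_csv(catalog[, c("step_id", "step_name")], path)
  invisible(path)
}

# Short positional labels used on matrix axes and in chord exports.
step_labels <- function(catalog) paste0("S", catalog$step_id)

# Read a comma- or tab-delimited file, checking required columns.
# Delimiter is guessed from the header line.
read_delimited <- function(path, required_cols) {
  if (!file.exists(path)) {
    stop("cannot read file: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE, na = character())
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
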