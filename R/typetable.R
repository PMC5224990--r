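#' SYBYL atom-type table
#'
#' The Molprint2D encoding used throughout this package designates every atom
#' type by its 1-based position in an ordered list of the 53 Tripos SYBYL atom
#' types (`C.3` is 1, `C.2` is 2, `C.ar` is 3, ..., `Co.oh` is 53).  The
#' default table ships with the package as a plain CSV so the index/code
#' mapping is explicit and can be overridden with a custom file when another
#' dialect is needed.
#'
#' @param path Optional path to a two-column CSV (`index,code`) replacing the
#'   packaged table.  It must contain exactly 53 unique codes with contiguous
#'   1-based indices.
#' @return A data frame with columns `index` (integer) and `code` (character),
#'   of class `sybyl_type_table`.
#' @examples
#' tab <- sybyl_type_table()
#' tab$code[c(1, 2, 3, 53)]
#' @export
sybyl_type_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sybyl_types.csv", package = "fmosom",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("index", "code") %in% names(tab)))
    stop("SYBYL type table must have columns 'index' and 'code'")
  tab <- tab[order(tab$index), c("index", "code")]
  tab$index <- as.integer(tab$index)
  if (nrow(tab) != 53L)
    stop("SYBYL type table must have exactly 53 entries, got ", nrow(tab))
  if (anyDuplicated(tab$code))
    stop("SYBYL type table codes must be unique")
  if (!identical(tab$index, seq_len(53L)))
    stop("SYBYL type table indices must be 1..53 without gaps")
  class(tab) <- c("sybyl_type_table", "data.frame")
  tab
}

#' Map SYBYL type codes to table indices
#'
#' @param codes Character vector of SYBYL codes (e.g. `"C.ar"`).
#' @param table A [sybyl_type_table()].
#' @param strict If `TRUE` (default) an unknown code is an error; otherwise
#'   unknown codes map to `NA`.
#' @return Integer vector of 1-based type indices.
#' @export
sybyl_index <- function(codes, table = sybyl_type_table(), strict = TRUE) {
  idx <- match(codes, table$code)
  if (strict && anyNA(idx)) {
    bad <- unique(codes[is.na(idx)])
    stop("unknown SYBYL type code(s): ", paste(bad, collapse = ", "))
  }
  table$index[idx]
}

#' Map SYBYL type indices back to codes
#'
#' @param indices Integer vector of 1-based type indices.
#' @param table A [sybyl_type_table()].
#' @return Character vector of codes.
#' @export
sybyl_code <- function(indices, table = sybyl_type_table()) {
  if (any(indices < 1L | indices > nrow(table)))
    stop("type index out of range 1..", nrow(table))
  table$code[indices]
}
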