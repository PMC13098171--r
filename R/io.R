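#' Read and write abundance tables
#'
#' Abundance tables are delimited text with populations as rows and
#' communities as columns: the first column holds the population ID, an
#' optional `group` column holds the functional-group index, and every
#' remaining column is one community's integer abundance vector. The
#' delimiter is TAB for `.tsv` files and comma for `.csv` (or set `delim`).
#'
#' @param communities A single community tibble or a (optionally named) list
#'   of community tibbles sharing the same populations.
#' @param path File path; extension selects the delimiter unless `delim` is
#'   given.
#' @param delim Field delimiter; `NULL` = infer from the extension.
#' @return `write_abundance_table()` returns `path` invisibly;
#'   `read_abundance_table()` returns a named list of community tibbles
#'   (with a `group` column when the file has one).
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' comm <- generate_community(5, 100, seed = 1)
#' write_abundance_table(comm, p)
#' read_abundance_table(p)[[1]]
#' @export
write_abundance_table <- function(communities, path, delim = NULL) {
  if (is.data.frame(communities)) communities <- list(community1 = communities)
  communities <- lapply(communities, as_community)
  if (is.null(names(communities)) || any(names(communities) == "")) {
    names(communities) <- paste0("community", seq_along(communities))
  }
  base <- communities[[1]]
  out <- tibble::tibble(population = base$population)
  if (!is.null(base[["group"]])) out$group <- base$group
  for (nm in names(communities)) {
    cc <- communities[[nm]]
    if (!identical(cc$population, base$population)) {
      abort("all communities in one table must share the same populations")
    }
    out[[nm]] <- cc$abundance
  }
  readr::write_delim(out, path, delim = delim %||% delim_for(path))
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path, delim = NULL) {
  tb <- readr::read_delim(path, delim = delim %||% delim_for(path),
                          show_col_types = FALSE, progress = FALSE)
  has_group <- "group" %in% names(tb)
  value_cols <- setdiff(names(tb), c("population", "group"))
  out <- lapply(value_cols, function(nm) {
    cc <- tibble::tibble(population = tb$population,
                         abundance = as.integer(tb[[nm]]))
    if (has_group) cc$group <- as.integer(tb$group)
    as_community(cc)
  })
  setNames(out, value_cols)
}

#' Read and write interaction matrices
#'
#' Square delimited-text matrices with population IDs as both row and
#' column headers; entry `[i, j]` is the effect of population `j` on the
#' growth probability of population `i`.
#'
#' @param A A square numeric matrix with dimnames.
#' @inheritParams write_abundance_table
#' @return `write_interaction_matrix()` returns `path` invisibly;
#'   `read_interaction_matrix()` returns the matrix.
#' @export
write_interaction_matrix <- function(A, path, delim = NULL) {
  df <- tibble::as_tibble(A, rownames = "population")
  readr::write_delim(df, path, delim = delim %||% delim_for(path))
  invisible(path)
}

#' @rdname write_interaction_matrix
#' @export
read_interaction_matrix <- function(path, delim = NULL) {
  tb <- readr::read_delim(path, delim = delim %||% delim_for(path),
                          show_col_types = FALSE, progress = FALSE)
  A <- as.matrix(tb[, -1])
  rownames(A) <- tb[[1]]
  storage.mode(A) <- "double"
  A
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}
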