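#' Read a gene expression matrix from delimited text
#'
#' Expression data are genes-by-features tables: the first column holds the
#' gene identifier, every remaining column a numeric expression value (one
#' per sample, time point or replicate).
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter, `"\t"` by default.
#' @return A tibble with a character `gene_id` column followed by numeric
#'   feature columns, carrying a logical `normalized` attribute (`FALSE` on
#'   load). Row order is preserved.
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- readr::read_delim(
    path, delim = delimiter, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("expression file is empty or has no feature columns: ", path)
  }
  prob <- readr::problems(raw)
  if (nrow(prob) > 0L) {
    stop("ragged or malformed rows in ", path, " (first at line ",
         prob$row[1], ")")
  }
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- purrr::map(raw[-1], function(col) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x) & !is.na(col))
    if (length(bad) > 0L) {
      stop("non-numeric cell value '", col[bad[1]], "' at data row ", bad[1])
    }
    if (anyNA(x)) stop("missing value in expression matrix")
    x
  })
  out <- tibble::tibble(gene_id = ids, !!!vals)
  as_expression(out, normalized = FALSE)
}

#' Construct an expression tibble from a data frame or matrix
#'
#' @param x A data frame whose first column is the gene id (or a numeric
#'   matrix with rownames).
#' @param normalized Whether values are already min-max scaled to \[0, 1\].
#' @return An expression tibble (see [read_expression()]).
#' @export
as_expression <- function(x, normalized = FALSE) {
  if (is.matrix(x)) {
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("g", seq_len(nrow(x)))
    x <- tibble::as_tibble(as.data.frame(x), .name_repair = "minimal")
    x <- tibble::add_column(x, gene_id = ids, .before = 1)
  }
  x <- tibble::as_tibble(x)
  names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  if (anyDuplicated(x$gene_id)) stop("duplicate gene id(s)")
  if (ncol(x) < 2L) stop("expression data needs at least one feature column")
  if (!all(vapply(x[-1], is.numeric, logical(1)))) {
    stop("all feature columns must be numeric")
  }
  if (anyNA(x)) stop("missing values are not allowed in expression data")
  attr(x, "normalized") <- isTRUE(normalized)
  x
}

#' Min-max normalize each feature column to \[0, 1\]
#'
#' Each column is rescaled by `(x - min) / (max - min)`. A constant column
#' has no scale and maps to all zeros, which keeps every value inside the
#' prototype bounds \[0, 1\] used by the evolutionary search.
#'
#' @param expr An expression tibble.
#' @return The expression tibble rescaled, `normalized` attribute `TRUE`.
#' @export
normalize_minmax <- function(expr) {
  expr <- as_expression(expr, normalized = attr(expr, "normalized"))
  if (nrow(expr) < 2L) stop("need at least 2 genes to normalize")
  out <- dplyr::mutate(expr, dplyr::across(
    -"gene_id",
    function(x) {
      rng <- range(x)
      if (rng[1] == rng[2]) return(rep(0, length(x)))
      (x - rng[1]) / (rng[2] - rng[1])
    }
  ))
  as_expression(out, normalized = TRUE)
}

#' @keywords internal
expr_values <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$gene_id
  m
}

#' @keywords internal
is_normalized <- function(expr) isTRUE(attr(expr, "normalized"))
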