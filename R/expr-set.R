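#' Cell-by-gene expression container
#'
#' A lightweight container holding one or more named layers of a cells x genes
#' matrix (e.g. `"raw"` counts, `"volnorm"`, `"lognorm"`, `"scaled"`,
#' `"imputed"`). Rows are cells, columns are genes; all layers share the same
#' dimnames. Raw counts must be non-negative and all values finite.
#'
#' @param counts A cells x genes matrix (dense or [Matrix::sparseMatrix()])
#'   used as the `"raw"` layer.
#' @param cells,genes Optional character vectors of cell and gene identifiers;
#'   default to the dimnames of `counts`.
#' @return An object of class `expr_set`.
#' @export
expr_set <- function(counts, cells = rownames(counts), genes = colnames(counts)) {
  if (is.null(cells) || is.null(genes)) {
    abort("`counts` must have cell and gene identifiers (dimnames or arguments)")
  }
  counts <- as_layer_matrix(counts, cells, genes)
  if (anyDuplicated(cells)) abort("duplicate cell identifiers")
  if (anyDuplicated(genes)) abort("duplicate gene identifiers")
  check_layer_values(counts, "raw", nonnegative = TRUE)
  structure(
    list(cells = as.character(cells), genes = as.character(genes),
         layers = list(raw = counts)),
    class = "expr_set"
  )
}

as_layer_matrix <- function(m, cells, genes) {
  if (inherits(m, "Matrix")) {
    m <- as(as(m, "dMatrix"), "CsparseMatrix")  # pattern matrices -> numeric
  } else {
    m <- as.matrix(m)
  }
  if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
    abort(sprintf("matrix is %d x %d but %d cells and %d genes were given",
                  nrow(m), ncol(m), length(cells), length(genes)))
  }
  dimnames(m) <- list(cells, genes)
  m
}

check_layer_values <- function(m, name, nonnegative = FALSE) {
  vals <- if (inherits(m, "Matrix")) m@x else m
  if (length(vals) && any(!is.finite(vals))) {
    abort(sprintf("layer '%s' contains non-finite values", name))
  }
  if (nonnegative && length(vals) && any(vals < 0)) {
    abort(sprintf("layer '%s' contains negative values", name))
  }
  invisible(m)
}

#' @export
dim.expr_set <- function(x) c(length(x$cells), length(x$genes))

#' @export
dimnames.expr_set <- function(x) list(x$cells, x$genes)

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("<expr_set> %d cells x %d genes; layers: %s\n",
              length(x$cells), length(x$genes),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Access or add a layer of an expression set
#'
#' @param x An [expr_set()].
#' @param name Layer name.
#' @param dense Return a base dense matrix (default) or the stored form.
#' @return `expr_layer()` returns the cells x genes matrix of the layer.
#' @export
expr_layer <- function(x, name = "raw", dense = TRUE) {
  stopifnot(inherits(x, "expr_set"))
  if (!name %in% names(x$layers)) {
    abort(sprintf("layer '%s' not found (available: %s)", name,
                  paste(names(x$layers), collapse = ", ")))
  }
  m <- x$layers[[name]]
  if (dense && inherits(m, "Matrix")) m <- as.matrix(m)
  m
}

#' @rdname expr_layer
#' @param value A cells x genes matrix conforming to `x`.
#' @export
set_expr_layer <- function(x, name, value) {
  stopifnot(inherits(x, "expr_set"))
  value <- as_layer_matrix(value, x$cells, x$genes)
  check_layer_values(value, name, nonnegative = identical(name, "raw"))
  x$layers[[name]] <- value
  x
}

#' @rdname expr_layer
#' @export
has_expr_layer <- function(x, name) name %in% names(x$layers)

#' Subset an expression set by cells and/or genes
#'
#' @param x An [expr_set()].
#' @param i,j Cell / gene selectors: character identifiers, integer or
#'   logical indices. Missing means keep all.
#' @param ... Ignored.
#' @export
`[.expr_set` <- function(x, i, j, ...) {
  ci <- if (missing(i)) seq_along(x$cells) else resolve_index(i, x$cells, "cell")
  gj <- if (missing(j)) seq_along(x$genes) else resolve_index(j, x$genes, "gene")
  x$layers <- lapply(x$layers, function(m) m[ci, gj, drop = FALSE])
  x$cells <- x$cells[ci]
  x$genes <- x$genes[gj]
  x
}

resolve_index <- function(idx, ids, what) {
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) {
      abort(sprintf("unknown %s identifier(s): %s", what,
                    paste(head(idx[is.na(pos)], 5), collapse = ", ")))
    }
    pos
  } else if (is.logical(idx)) {
    which(idx)
  } else {
    as.integer(idx)
  }
}

#' Per-cell total signal of a layer
#'
#' @inheritParams expr_layer
#' @return Named numeric vector of per-cell row sums.
#' @export
cell_totals <- function(x, name = "raw") {
  m <- x$layers[[if (name %in% names(x$layers)) name else "raw"]]
  tot <- if (inherits(m, "Matrix")) Matrix::rowSums(m) else rowSums(m)
  setNames(as.numeric(tot), x$cells)
}
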