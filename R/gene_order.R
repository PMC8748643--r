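#' Signed circular gene order
#'
#' The unit of rearrangement comparison: an ordered sequence of
#' `(symbol, strand)` pairs around the (usually circular) mitochondrial
#' chromosome. Symbols are unique and canonical; two circular orders
#' compare equal under any rotation (no reflection — chromosome
#' orientation is fixed by the major strand).
#'
#' @param taxon text label for the genome the order came from.
#' @param symbols character vector of canonical gene symbols (unique).
#' @param strands character vector over `"+"`/`"-"`, same length.
#' @param topology `"circular"` or `"linear"`.
#' @param includes_cr whether the control region element is part of the
#'   order; inferred from `symbols` when missing.
#' @return an object of class `GeneOrder` with fields `taxon`, `elements`
#'   (data.frame `symbol`, `strand`), `topology`, `includes_cr`.
#' @export
gene_order <- function(taxon, symbols, strands, topology = "circular",
                       includes_cr = "CR" %in% symbols) {
  stopifnot(length(symbols) == length(strands))
  if (anyDuplicated(symbols)) {
    stop("gene order symbols must be unique; duplicated: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  }
  if (length(symbols) > 38L) stop("a mitogenome order has at most 38 elements")
  feature_class_of(symbols)  # validates vocabulary
  if (!all(strands %in% c("+", "-"))) stop("strands must be '+' or '-'")
  topology <- match.arg(topology, c("circular", "linear"))
  structure(list(taxon = taxon,
                 elements = data.frame(symbol = as.character(symbols),
                                       strand = as.character(strands),
                                       stringsAsFactors = FALSE),
                 topology = topology,
                 includes_cr = isTRUE(includes_cr)),
            class = "GeneOrder")
}

#' @export
print.GeneOrder <- function(x, ...) {
  cat("GeneOrder [", x$taxon, "] ", x$topology, ", ",
      nrow(x$elements), " elements\n", sep = "")
  cat(" ", format_gene_order(x), "\n")
  invisible(x)
}

#' @export
length.GeneOrder <- function(x) nrow(x$elements)

#' One-line text serialization of a gene order
#'
#' Bit-exact dialect: elements as `symbol strand` joined by `" , "`, e.g.
#' `"trnI + , trnQ - , trnM +"`.
#'
#' @param order a [gene_order()] object.
#' @return character scalar.
#' @export
format_gene_order <- function(order) {
  paste(paste(order$elements$symbol, order$elements$strand), collapse = " , ")
}

#' @rdname format_gene_order
#' @param path file to write to / read from.
#' @export
write_gene_order <- function(order, path) {
  writeLines(format_gene_order(order), path)
  invisible(path)
}

#' @rdname format_gene_order
#' @param taxon taxon label to attach on read (default: file stem).
#' @param topology topology to attach on read.
#' @export
read_gene_order <- function(path, taxon = NULL,
                            topology = "circular") {
  line <- trimws(readLines(path, warn = FALSE)[1])
  parse_gene_order(line,
                   taxon = taxon %||% sub("\\.[^.]*$", "", basename(path)),
                   topology = topology)
}

#' @rdname format_gene_order
#' @param text a serialized gene order line.
#' @export
parse_gene_order <- function(text, taxon = "order", topology = "circular") {
  parts <- strsplit(trimws(text), "\\s*,\\s*")[[1]]
  toks <- strsplit(parts, "\\s+")
  bad <- lengths(toks) != 2L
  if (any(bad)) stop("malformed gene order element(s): ",
                     paste(parts[bad], collapse = "; "))
  gene_order(taxon = taxon,
             symbols = vapply(toks, `[`, "", 1L),
             strands = vapply(toks, `[`, "", 2L),
             topology = topology)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rotate a circular order so element k comes first
rotate_order_elements <- function(el, k) {
  n <- nrow(el)
  if (n == 0L || k == 1L) return(el)
  idx <- c(k:n, seq_len(k - 1L))
  el[idx, , drop = FALSE]
}

#' Equality of gene orders
#'
#' Circular orders are compared up to rotation (never reflection); linear
#' orders element-wise. Strands must match.
#'
#' @param a,b [gene_order()] objects.
#' @return logical scalar.
#' @export
order_equal <- function(a, b) {
  ea <- a$elements; eb <- b$elements
  if (nrow(ea) != nrow(eb)) return(FALSE)
  n <- nrow(ea)
  if (n == 0L) return(TRUE)
  same <- function(x, y) all(x$symbol == y$symbol) && all(x$strand == y$strand)
  if (a$topology == "circular" && b$topology == "circular") {
    anchors <- which(eb$symbol == ea$symbol[1])
    for (k in anchors) {
      if (same(ea, rotate_order_elements(eb, k))) return(TRUE)
    }
    FALSE
  } else {
    same(ea, eb)
  }
}
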