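#' Hallmark axis used throughout the package
#'
#' The model tracks five hallmark variables: evasion of apoptosis (`Ha`),
#' growth-signal self-sufficiency / anti-growth insensitivity driving the
#' division trial (`Hd`), immortalization (`Hi`), angiogenesis (`Hb`) and
#' invasion/metastasis (`Him`).
#'
#' @return Character vector of the five hallmark column names, in canonical
#'   order.
#' @export
hallmark_names <- function() c("Ha", "Hd", "Hi", "Hb", "Him")

#' Construct a gene panel
#'
#' A gene panel is the ordered set of tumor-related genes whose binary
#' mutational states drive the hallmark variables. `cds_length` (bases) is
#' optional and, when present, length-weights the per-gene driver mutation
#' probability; `role` is carried as annotation (oncogene/suppressor) but does
#' not change the dynamics.
#'
#' @param genes Character vector of unique, non-empty gene names, or a data
#'   frame with columns `gene` and optionally `cds_length`, `role`.
#' @param cds_length Optional positive integer vector of coding lengths.
#' @param role Optional character vector; each element one of `"oncogene"`,
#'   `"suppressor"`, `"unspecified"`.
#' @return A tibble of class `gene_panel` with columns `gene`, `cds_length`,
#'   `role`.
#' @examples
#' gene_panel(c("APC", "KRAS", "TP53", "PIK3CA"))
#' @export
gene_panel <- function(genes, cds_length = NULL, role = NULL) {
  if (is.data.frame(genes)) {
    df <- genes
    stopifnot("gene" %in% names(df))
    genes <- df$gene
    if (is.null(cds_length) && "cds_length" %in% names(df)) cds_length <- df$cds_length
    if (is.null(role) && "role" %in% names(df)) role <- df$role
  }
  genes <- as.character(genes)
  if (length(genes) == 0 || anyNA(genes) || any(!nzchar(genes))) {
    stop("gene names must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("gene names must be unique", call. = FALSE)
  if (is.null(cds_length)) cds_length <- rep(NA_real_, length(genes))
  cds_length <- as.numeric(cds_length)
  if (any(!is.na(cds_length) & cds_length <= 0)) {
    stop("cds_length must be positive when present", call. = FALSE)
  }
  if (is.null(role)) role <- rep("unspecified", length(genes))
  role <- as.character(role)
  role[is.na(role) | !nzchar(role)] <- "unspecified"
  bad <- setdiff(unique(role), c("oncogene", "suppressor", "unspecified"))
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  out <- tibble::tibble(gene = genes, cds_length = cds_length, role = role)
  class(out) <- c("gene_panel", class(out))
  out
}

#' Read / write a gene panel as TSV
#'
#' The file format is tab-separated with header `gene  cds_length  role`;
#' the last two columns are optional.
#'
#' @param path File path.
#' @return `read_gene_panel()` returns a `gene_panel` tibble.
#' @export
read_gene_panel <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  gene_panel(df)
}

#' @rdname read_gene_panel
#' @param panel A `gene_panel`.
#' @export
write_gene_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a gene-by-hallmark weight matrix
#'
#' Weights link each gene's mutational indicator to each hallmark via a
#' linear combination: `H_h = sum_g w[g, h] * x[g]`. Columns with any
#' positive mass are normalized to sum to one so hallmark values live in
#' `[0, 1]` and can offset trial probabilities directly.
#'
#' @param weights A data frame with a `gene` column and one numeric column
#'   per hallmark (`Ha`, `Hd`, `Hi`, `Hb`, `Him`; missing hallmark columns
#'   are filled with zeros), or a numeric matrix with genes as rownames.
#' @param panel Optional `gene_panel`; when given, genes must match it
#'   (order is taken from the panel).
#' @param normalize Normalize hallmark columns to unit sum (default `TRUE`).
#' @return A tibble of class `hallmark_weights`: column `gene` plus the five
#'   hallmark columns.
#' @examples
#' hallmark_weights(data.frame(gene = c("APC", "KRAS"), Ha = c(0.7, 0.3)))
#' @export
hallmark_weights <- function(weights, panel = NULL, normalize = TRUE) {
  hn <- hallmark_names()
  if (is.matrix(weights)) {
    weights <- data.frame(gene = rownames(weights), weights, check.names = FALSE)
  }
  stopifnot(is.data.frame(weights), "gene" %in% names(weights))
  w <- tibble::as_tibble(weights)
  for (h in hn) if (!h %in% names(w)) w[[h]] <- 0
  w <- w[, c("gene", hn)]
  w$gene <- as.character(w$gene)
  if (anyDuplicated(w$gene)) stop("duplicate gene rows in weights", call. = FALSE)
  m <- as.matrix(w[, hn])
  if (anyNA(m)) stop("weights must not contain NA", call. = FALSE)
  if (any(m < 0)) stop("weights must be non-negative", call. = FALSE)
  if (!is.null(panel)) {
    if (!setequal(w$gene, panel$gene)) {
      stop("weight genes do not match the panel", call. = FALSE)
    }
    w <- w[match(panel$gene, w$gene), ]
  }
  if (normalize) w <- normalize_weights(w, warn = FALSE)
  class(w) <- unique(c("hallmark_weights", class(w)))
  w
}

#' Normalize hallmark weight columns
#'
#' Each hallmark column with positive sum is divided by its sum; all-zero
#' columns are left as zeros. Entries must be non-negative.
#'
#' @param weights A `hallmark_weights` tibble or compatible data frame.
#' @param warn Emit a warning naming the columns that were rescaled.
#' @return A `hallmark_weights` tibble with unit (or zero) column sums.
#' @export
normalize_weights <- function(weights, warn = TRUE) {
  hn <- hallmark_names()
  w <- weights
  m <- as.matrix(w[, hn])
  if (any(m < 0)) stop("weights must be non-negative", call. = FALSE)
  cs <- colSums(m)
  rescaled <- hn[cs > 0 & abs(cs - 1) > 1e-12]
  for (h in hn) if (cs[h] > 0) w[[h]] <- w[[h]] / cs[h]
  if (warn && length(rescaled)) {
    warning("renormalized hallmark column(s): ", paste(rescaled, collapse = ", "),
            call. = FALSE)
  }
  class(w) <- unique(c("hallmark_weights", class(w)))
  w
}

#' Read / write a hallmark weight table as TSV
#'
#' Format: tab-separated, header `gene  Ha  Hd  Hi  Hb  Him`, non-negative
#' real values. The reader normalizes each hallmark column to unit sum and
#' warns when a column needed rescaling.
#'
#' @param path File path.
#' @param panel Optional `gene_panel` to validate and order against.
#' @return `read_hallmark_weights()` returns a `hallmark_weights` tibble.
#' @export
read_hallmark_weights <- function(path, panel = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  hn <- intersect(hallmark_names(), names(df))
  m <- as.matrix(df[, hn, drop = FALSE])
  cs <- colSums(m)
  rescaled <- hn[cs > 0 & abs(cs - 1) > 1e-9]
  if (length(rescaled)) {
    warning("renormalized hallmark column(s): ", paste(rescaled, collapse = ", "),
            call. = FALSE)
  }
  hallmark_weights(df, panel = panel, normalize = TRUE)
}

#' @rdname read_hallmark_weights
#' @param weights A `hallmark_weights` tibble.
#' @export
write_hallmark_weights <- function(weights, path) {
  utils::write.table(as.data.frame(weights), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compute hallmark values from a genotype
#'
#' Each hallmark value is the linear combination of the gene mutation
#' indicators with the gene-to-hallmark weights:
#' `H_h = sum_g w[g, h] * x[g]`. With normalized weights every value lies in
#' `[0, 1]`; the all-mutated genotype attains 1 on every hallmark that has
#' any weight mass.
#'
#' @param weights A `hallmark_weights` tibble.
#' @param genotype Binary vector (0/1 or logical) over the weight table's
#'   gene order, or a bitstring such as `"1010"`.
#' @return A one-row tibble with columns `Ha`, `Hd`, `Hi`, `Hb`, `Him`.
#' @examples
#' w <- hallmark_weights(data.frame(gene = c("APC", "KRAS"), Ha = c(0.7, 0.3)))
#' compute_hallmarks(w, c(1, 0)) # Ha = 0.7
#' @export
compute_hallmarks <- function(weights, genotype) {
  v <- hallmarks_vec(weights, genotype)
  tibble::as_tibble(as.list(v))
}

# fast path: named numeric vector of the five hallmark values
hallmarks_vec <- function(weights, genotype) {
  if (is.character(genotype) && length(genotype) == 1) {
    genotype <- genotype_from_bitstring(genotype)
  }
  x <- as.numeric(genotype)
  if (length(x) != nrow(weights)) {
    stop("genotype length (", length(x), ") does not match panel size (",
         nrow(weights), ")", call. = FALSE)
  }
  if (anyNA(x) || any(x != 0 & x != 1)) {
    stop("genotype must be a 0/1 vector", call. = FALSE)
  }
  m <- as.matrix(weights[, hallmark_names()])
  drop(crossprod(m, x))
}

#' Nullify a gene's hallmark contributions
#'
#' Sets every hallmark weight of one gene to zero, leaving all other
#' entries untouched (no renormalization): the in-silico knockout removes
#' exactly that gene's contribution while the remaining genes keep their
#' estimated weights.
#'
#' @param weights A `hallmark_weights` tibble.
#' @param gene Gene name present in the table.
#' @return A `hallmark_weights` tibble with the gene's row zeroed.
#' @export
nullify_gene <- function(weights, gene) {
  i <- match(gene, weights$gene)
  if (is.na(i)) stop("gene not in panel: ", gene, call. = FALSE)
  for (h in hallmark_names()) weights[[h]][i] <- 0
  weights
}

genotype_from_bitstring <- function(s) {
  as.integer(strsplit(s, "", fixed = TRUE)[[1]])
}

genotype_to_bitstring <- function(x) {
  paste(as.integer(x), collapse = "")
}
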