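#' Variant allele frequencies of a simulated population
#'
#' Converts per-clone cell counts into per-gene variant allele frequencies,
#' the summary statistics used for ABC calibration. Under the
#' heterozygous-diploid convention each mutated cell contributes one mutant
#' allele out of `ploidy` total alleles, so
#' `VAF_g = (mutated cells) / (ploidy * total cells)` and a fully clonal
#' mutation maps to VAF = 0.5. An optional binomial read-sampling layer
#' (`depth`) adds sequencing noise; it is off by default.
#'
#' @param sim A `clone_sim` object, or a clones tibble with columns
#'   `genotype` (bitstring over the panel order), `n_cells`, `compartment`.
#' @param panel The [gene_panel()] the genotypes are indexed over.
#' @param compartment Which cells to pool: `"pooled"` (default; the bulk
#'   sequencing analogue), `"primary"` or `"metastatic"`.
#' @param ploidy Alleles per locus per cell (default 2).
#' @param depth Optional mean sequencing depth; when given, each VAF is
#'   replaced by `rbinom(1, depth, VAF) / depth` (uses the global RNG).
#' @return A tibble with columns `gene`, `vaf`, `n_cells_used`.
#' @examples
#' # 300 of 1000 cells carry the APC mutation -> VAF 0.15
#' clones <- tibble::tibble(genotype = c("10", "00"),
#'                          n_cells = c(300, 700),
#'                          compartment = "primary")
#' compute_vaf(clones, gene_panel(c("APC", "KRAS")))
#' @export
compute_vaf <- function(sim, panel, compartment = c("pooled", "primary", "metastatic"),
                        ploidy = 2, depth = NULL) {
  compartment <- match.arg(compartment)
  clones <- if (inherits(sim, "clone_sim")) sim$clones else tibble::as_tibble(sim)
  if (compartment != "pooled") {
    clones <- dplyr::filter(clones, .data$compartment == !!compartment)
  }
  clones <- dplyr::filter(clones, .data$n_cells > 0)
  N <- sum(clones$n_cells)
  if (N <= 0) {
    stop("no cells in compartment '", compartment, "': VAF undefined", call. = FALSE)
  }
  G <- matrix(vapply(clones$genotype, genotype_from_bitstring,
                     integer(nrow(panel)), USE.NAMES = FALSE),
              nrow = nrow(panel))           # genes x clones
  mutated <- drop(G %*% clones$n_cells)
  vaf <- mutated / (ploidy * N)
  if (!is.null(depth)) {
    vaf <- stats::rbinom(length(vaf), size = round(depth), prob = vaf) / round(depth)
  }
  tibble::tibble(gene = panel$gene, vaf = as.numeric(vaf), n_cells_used = N)
}

#' Compartment-resolved VAF table
#'
#' VAFs for the primary, metastatic and pooled compartments side by side;
#' compartments with no cells yield `NA`.
#'
#' @inheritParams compute_vaf
#' @return Tibble `gene`, `vaf_primary`, `vaf_metastatic`, `vaf_pooled`.
#' @export
vaf_table <- function(sim, panel, ploidy = 2) {
  one <- function(comp) {
    tryCatch(compute_vaf(sim, panel, comp, ploidy = ploidy)$vaf,
             error = function(e) rep(NA_real_, nrow(panel)))
  }
  tibble::tibble(gene = panel$gene,
                 vaf_primary = one("primary"),
                 vaf_metastatic = one("metastatic"),
                 vaf_pooled = one("pooled"))
}

#' Read / write observed VAFs
#'
#' TSV with header `gene  vaf` — the format a user would hand-extract from
#' a MAF/VCF-derived table.
#'
#' @param path File path.
#' @param panel Optional [gene_panel()] to validate and order against.
#' @return Tibble `gene`, `vaf`.
#' @export
read_observed_vaf <- function(path, panel = NULL) {
  df <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                            stringsAsFactors = FALSE))
  stopifnot(all(c("gene", "vaf") %in% names(df)))
  if (any(df$vaf < 0 | df$vaf > 1)) stop("VAFs must lie in [0, 1]", call. = FALSE)
  if (!is.null(panel)) {
    if (!setequal(df$gene, panel$gene)) stop("VAF genes do not match the panel", call. = FALSE)
    df <- df[match(panel$gene, df$gene), ]
  }
  df[, c("gene", "vaf")]
}

#' @rdname read_observed_vaf
#' @param vaf A tibble with columns `gene`, `vaf`.
#' @export
write_observed_vaf <- function(vaf, path) {
  utils::write.table(as.data.frame(vaf[, c("gene", "vaf")]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
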