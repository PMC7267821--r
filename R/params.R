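#' Simulation parameters
#'
#' Collects the per-step trial constants and run controls of the
#' branching-process simulator.
#'
#' @param a0 Base apoptosis probability per cell per step, in `[0, 1]`. The
#'   apoptosis hallmark lowers the realized probability to
#'   `clamp(a0 - Ha, 0, 1)`.
#' @param d0 Base division probability per cell per step, in `[0, 1]`;
#'   raised additively by the division hallmark `Hd`.
#' @param k0 Environmental (hallmark-independent) death probability per cell
#'   per step, in `[0, 1]`.
#' @param m0 Driver mutation probability per gene per daughter cell per
#'   division, in `[0, 1]`; length-weighted by `cds_length / mean(cds_length)`
#'   when the panel carries CDS lengths.
#' @param E0 Friction coefficient (1/cells) of the logistic division term
#'   applied to primary cells: division is scaled by `1 - E' * N_primary`
#'   with `E' = E0 / (1 + F * Hb)`.
#' @param F Angiogenesis relief factor (dimensionless, `>= 0`): how strongly
#'   the angiogenesis hallmark relaxes the friction coefficient.
#' @param c_max Replicative limit (maximum lineage divisions) before a cell
#'   must pass the immortalization survival trial with probability `Hi`.
#' @param N0 Initial number of cells (single unmutated primary clone by
#'   default).
#' @param t_max Maximum number of time steps.
#' @param N_cap Hard population cap; the run stops once total cells reach it.
#' @param seed Default RNG seed used by [run_simulation()] when no seed is
#'   passed explicitly.
#' @return A list of class `sim_params`.
#' @examples
#' sim_params(a0 = 0.2, d0 = 0.3)
#' @export
sim_params <- function(a0 = 0.2, d0 = 0.3, k0 = 0.05, m0 = 5e-4,
                       E0 = 1e-4, F = 10, c_max = 50, N0 = 1000,
                       t_max = 100, N_cap = 1e6, seed = 42L) {
  p <- list(a0 = a0, d0 = d0, k0 = k0, m0 = m0, E0 = E0, F = F,
            c_max = c_max, N0 = N0, t_max = t_max, N_cap = N_cap,
            seed = as.integer(seed))
  validate_sim_params(p)
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  for (nm in c("a0", "d0", "k0", "m0")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(nm, " must be a probability in [0, 1]", call. = FALSE)
    }
  }
  if (p$E0 < 0) stop("E0 must be >= 0", call. = FALSE)
  if (p$F < 0) stop("F must be >= 0", call. = FALSE)
  if (p$c_max < 0 || p$c_max != floor(p$c_max)) stop("c_max must be a non-negative integer", call. = FALSE)
  if (p$N0 < 1) stop("N0 must be >= 1", call. = FALSE)
  if (p$t_max < 1) stop("t_max must be >= 1", call. = FALSE)
  if (p$N_cap < 1) stop("N_cap must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-6s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read / write simulation parameters
#'
#' Accepts YAML or flat `key = value` / `key: value` text whose keys mirror
#' the [sim_params()] argument names; unknown keys are rejected.
#'
#' @param path File path.
#' @return `read_sim_params()` returns a `sim_params` object.
#' @export
read_sim_params <- function(path) {
  vals <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
  if (!is.list(vals)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    kv <- strsplit(lines, "[:=]", fixed = FALSE)
    vals <- stats::setNames(
      lapply(kv, function(x) as.numeric(trimws(x[2]))),
      vapply(kv, function(x) trimws(x[1]), "")
    )
  }
  known <- names(formals(sim_params))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown parameter key(s): ", paste(extra, collapse = ", "), call. = FALSE)
  do.call(sim_params, vals)
}

#' @rdname read_sim_params
#' @param params A `sim_params` object.
#' @export
write_sim_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Assemble a simulation configuration
#'
#' Binds parameters, gene panel, hallmark weights and the founding genotype
#' into the single object [run_simulation()] consumes. The panel, weight
#' table and genotype must agree on the gene axis.
#'
#' @param params A [sim_params()] object.
#' @param panel A [gene_panel()].
#' @param weights A [hallmark_weights()] table over the same genes.
#' @param initial_genotype Binary vector over the panel (default all zeros:
#'   an unmutated founding clone).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(params, panel, weights,
                       initial_genotype = rep(0L, nrow(panel))) {
  stopifnot(inherits(params, "sim_params"))
  panel <- gene_panel(panel)
  weights <- hallmark_weights(weights, panel = panel, normalize = FALSE)
  g <- as.integer(initial_genotype)
  if (length(g) != nrow(panel) || any(g != 0 & g != 1)) {
    stop("initial_genotype must be a 0/1 vector over the panel", call. = FALSE)
  }
  structure(list(params = params, panel = panel, weights = weights,
                 initial_genotype = g),
            class = "sim_config")
}
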