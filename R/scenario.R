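#' Specify a synthetic study scenario
#'
#' A scenario bundles everything needed to fabricate a self-consistent
#' input set for the simulator and for ABC calibration: the gene panel,
#' the true gene-to-hallmark weights, and the simulation parameters. The
#' default emulates a four-gene colorectal-cancer panel (APC, KRAS, TP53,
#' PIK3CA) in which TP53 contributes to two hallmarks at once (apoptosis
#' evasion and division), exercising the many-to-many gene-hallmark
#' mapping. The weights are illustrative, not biological claims.
#'
#' @param panel A [gene_panel()].
#' @param true_weights A `hallmark_weights` table: the generating truth.
#' @param params A [sim_params()] object; the default is a desk-scale
#'   configuration (500 founding cells, 50 steps) whose unmutated
#'   population slowly declines so that driver mutations are positively
#'   selected.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(panel = NULL, true_weights = NULL, params = NULL) {
  if (is.null(panel)) {
    panel <- gene_panel(c("APC", "KRAS", "TP53", "PIK3CA"),
                        cds_length = c(8532, 567, 1182, 3207),
                        role = c("suppressor", "oncogene", "suppressor",
                                 "oncogene"))
  }
  if (is.null(true_weights)) {
    true_weights <- hallmark_weights(
      data.frame(gene = c("APC", "KRAS", "TP53", "PIK3CA"),
                 Ha = c(0.6, 0, 0.4, 0),
                 Hd = c(0, 0.7, 0.3, 0),
                 Hi = c(0, 0, 0, 0),
                 Hb = c(0, 0, 0, 0),
                 Him = c(0, 0.3, 0, 0.7)),
      panel = panel)
  }
  if (is.null(params)) {
    params <- sim_params(a0 = 0.3, d0 = 0.4, k0 = 0.05, m0 = 2e-3,
                         E0 = 2e-4, F = 10, c_max = 60, N0 = 500,
                         t_max = 50, N_cap = 5e4, seed = 42L)
  }
  structure(list(panel = panel, true_weights = true_weights, params = params),
            class = "scenario_spec")
}

#' Generate a full synthetic input set on disk
#'
#' Writes the four input files a study needs — gene panel, weight table,
#' simulation config and an "observed" VAF table — plus a truth record. The
#' observed VAFs are produced by actually running the forward simulator at
#' the scenario's true weights; if that run goes extinct, new seeds derived
#' from `seed` are tried (up to `max_retries`) before erroring. The same
#' spec and seed always produce identical files.
#'
#' @param spec A [scenario_spec()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param max_retries Seeds to try when the truth run goes extinct.
#' @return Invisibly, a list with the file `paths`, the `observed` VAF
#'   tibble, the truth `sim` summary and the seed actually used.
#' @export
generate_scenario <- function(spec = scenario_spec(), dir, seed = 1L,
                              max_retries = 10) {
  stopifnot(inherits(spec, "scenario_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(spec$params, spec$panel, spec$true_weights)

  sim <- NULL
  used_seed <- NA_integer_
  for (k in seq_len(max_retries)) {
    s <- (as.integer(seed) + (k - 1L) * 7919L) %% .Machine$integer.max
    cand <- run_simulation(cfg, seed = s, log = FALSE)
    if (sum(cand$clones$n_cells) > 0) { sim <- cand; used_seed <- s; break }
  }
  if (is.null(sim)) {
    stop("simulation went extinct for every trial seed; scenario not viable",
         call. = FALSE)
  }
  observed <- compute_vaf(sim, spec$panel, "pooled")[, c("gene", "vaf")]

  paths <- list(
    genes = file.path(dir, "genes.tsv"),
    weights = file.path(dir, "weights.tsv"),
    config = file.path(dir, "config.yaml"),
    observed = file.path(dir, "observed_vaf.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_gene_panel(spec$panel, paths$genes)
  write_hallmark_weights(spec$true_weights, paths$weights)
  write_sim_params(spec$params, paths$config)
  write_observed_vaf(observed, paths$observed)
  truth <- as.data.frame(spec$true_weights)
  truth$observed_seed <- used_seed
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(paths = paths, observed = observed,
                 final = summarize_final(sim), seed = used_seed))
}
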