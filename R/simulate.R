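new_clone_rec <- function(clone_id, parent_id, genotype, n_cells, c,
                          compartment, birth_step,
                          mut_genes = character(0), mut_steps = integer(0)) {
  list(clone_id = clone_id, parent_id = parent_id,
       genotype = genotype, gkey = genotype_to_bitstring(genotype),
       n_cells = n_cells, c = c, compartment = compartment,
       birth_step = birth_step, mut_genes = mut_genes, mut_steps = mut_steps)
}

mutation_order_string <- function(mut_genes, mut_steps) {
  if (length(mut_genes) == 0) return("")
  paste(paste0(mut_genes, ":", mut_steps), collapse = ";")
}

#' Run a full clonal-evolution simulation
#'
#' Iterates the per-clone fate trials ([step_clone()]), division-time
#' mutation ([mutate_daughters()]) and invasion bookkeeping
#' ([apply_invasion()]) from a founding population of `N0` cells for up to
#' `t_max` steps. Hallmark values are recomputed (and cached) for every
#' distinct genotype. Clones are processed in `clone_id` order through one
#' global RNG stream, so a fixed seed and configuration reproduce the run
#' exactly. The run stops early on extinction (no cells left) or when the
#' population reaches `N_cap`.
#'
#' Clone identity is lineage-true: every new genotype founds a new clone,
#' and clones with equal genotypes but different parents stay distinct.
#' Clones that die are logged with `n_cells = 0` at the step they die and
#' dropped thereafter.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; defaults to `config$params$seed`.
#' @param log Record the full per-step per-clone evolution log (default
#'   `TRUE`; turn off for speed inside inference loops).
#' @return An object of class `clone_sim`: a list with
#'   \describe{
#'     \item{summary}{tibble, one row per executed step: `step`, `n_clones`,
#'       `N_primary`, `N_metastatic`.}
#'     \item{log}{tibble (or `NULL`), one row per step per clone: `step`,
#'       `clone_id`, `parent_id`, `genotype` bitstring, `n_cells`, `c`,
#'       `compartment`.}
#'     \item{clones}{tibble of surviving clones with lineage metadata and
#'       the `mutation_order` string (`gene:step` pairs, first to last).}
#'     \item{stopped}{why the run ended: `"extinction"`, `"cap"` or
#'       `"t_max"`.}
#'   }
#' @examples
#' cfg <- sim_config(
#'   sim_params(N0 = 100, t_max = 10, seed = 1),
#'   gene_panel(c("APC", "KRAS")),
#'   hallmark_weights(data.frame(gene = c("APC", "KRAS"),
#'                               Ha = c(0.7, 0.3), Hd = c(0.5, 0.5)))
#' )
#' sim <- run_simulation(cfg)
#' glance(sim)
#' @export
run_simulation <- function(config, seed = NULL, log = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  panel <- config$panel
  weights <- config$weights
  validate_sim_params(p)
  if (is.null(seed)) seed <- p$seed
  set.seed(as.integer(seed))

  m_gene <- gene_mutation_probs(panel, p)
  wmat <- as.matrix(weights[, hallmark_names()])
  hcache <- new.env(parent = emptyenv())
  hallmarks_for <- function(gkey, genotype) {
    h <- get0(gkey, envir = hcache)
    if (is.null(h)) {
      h <- drop(crossprod(wmat, as.numeric(genotype)))
      assign(gkey, h, envir = hcache)
    }
    h
  }

  clones <- list()
  clones[[1]] <- new_clone_rec(1L, NA_integer_, config$initial_genotype,
                               p$N0, 0L, "primary", 0L)
  next_id <- 2L
  live <- 1L
  met_lookup <- new.env(parent = emptyenv())  # (genotype, source clone) -> id

  summary_rows <- vector("list", p$t_max)
  log_rows <- if (log) vector("list", p$t_max) else NULL
  stopped <- "t_max"
  steps_run <- 0L

  for (t in seq_len(p$t_max)) {
    prim <- vapply(clones[live], function(cl) {
      if (cl$compartment == "primary") cl$n_cells else 0
    }, 0)
    N_primary <- sum(prim)

    snapshot <- live
    born <- integer(0)
    for (id in snapshot) {
      cl <- clones[[id]]
      if (cl$n_cells < 1) next
      H <- hallmarks_for(cl$gkey, cl$genotype)
      probs <- .trial_probs(H, p, cl$compartment, N_primary)
      cnt <- .step_counts(cl$n_cells, cl$c, probs, p, cl$compartment)

      daughters <- 2 * cnt$dividers
      mut <- .mutate_daughters(cl$genotype, daughters, m_gene)

      n_new <- cnt$survivors - cnt$dividers + mut$unmutated
      if (cnt$dividers > 0) cl$c <- cl$c + 1L

      # daughters inherit the incremented division counter
      for (m in mut$mutants) {
        kid <- new_clone_rec(next_id, id, m$genotype, m$n_cells, cl$c,
                             cl$compartment, t,
                             mut_genes = c(cl$mut_genes, panel$gene[m$new_genes]),
                             mut_steps = c(cl$mut_steps,
                                           rep(t, length(m$new_genes))))
        clones[[next_id]] <- kid
        born <- c(born, next_id)
        next_id <- next_id + 1L
      }

      if (cl$compartment == "primary" && cnt$invaders > 0) {
        inv <- min(cnt$invaders, n_new)
        if (inv > 0) {
          n_new <- n_new - inv
          key <- paste0(cl$gkey, "@", id)
          mid <- get0(key, envir = met_lookup)
          if (!is.null(mid) && clones[[mid]]$n_cells > 0) {
            clones[[mid]]$n_cells <- clones[[mid]]$n_cells + inv
          } else {
            met <- new_clone_rec(next_id, id, cl$genotype, inv, cl$c,
                                 "metastatic", t,
                                 mut_genes = cl$mut_genes,
                                 mut_steps = cl$mut_steps)
            clones[[next_id]] <- met
            assign(key, next_id, envir = met_lookup)
            born <- c(born, next_id)
            next_id <- next_id + 1L
          }
        }
      }

      cl$n_cells <- n_new
      clones[[id]] <- cl
    }

    present <- c(snapshot, born)
    ncells <- vapply(clones[present], `[[`, 0, "n_cells")
    alive <- present[ncells > 0]
    live <- sort(alive)

    comp <- vapply(clones[present], `[[`, "", "compartment")
    N_primary_end <- sum(ncells[comp == "primary"])
    N_met_end <- sum(ncells[comp == "metastatic"])
    summary_rows[[t]] <- c(step = t, n_clones = length(alive),
                           N_primary = N_primary_end,
                           N_metastatic = N_met_end)
    if (log) {
      log_rows[[t]] <- data.frame(
        step = t,
        clone_id = present,
        parent_id = vapply(clones[present], `[[`, 0L, "parent_id"),
        genotype = vapply(clones[present], `[[`, "", "gkey"),
        n_cells = ncells,
        c = vapply(clones[present], `[[`, 0L, "c"),
        compartment = comp,
        stringsAsFactors = FALSE
      )
    }
    steps_run <- t
    total <- N_primary_end + N_met_end
    if (total <= 0) { stopped <- "extinction"; break }
    if (total >= p$N_cap) { stopped <- "cap"; break }
  }

  summary <- tibble::as_tibble(do.call(rbind, summary_rows[seq_len(steps_run)]))
  log_tbl <- if (log) {
    tibble::as_tibble(dplyr::bind_rows(log_rows[seq_len(steps_run)]))
  } else NULL

  final <- if (length(live)) {
    dplyr::bind_rows(lapply(clones[live], function(cl) {
      tibble::tibble(
        clone_id = cl$clone_id, parent_id = cl$parent_id,
        genotype = cl$gkey, n_cells = cl$n_cells, c = cl$c,
        compartment = cl$compartment, birth_step = cl$birth_step,
        mutation_order = mutation_order_string(cl$mut_genes, cl$mut_steps)
      )
    }))
  } else {
    tibble::tibble(clone_id = integer(), parent_id = integer(),
                   genotype = character(), n_cells = numeric(), c = integer(),
                   compartment = character(), birth_step = integer(),
                   mutation_order = character())
  }

  structure(list(summary = summary, log = log_tbl, clones = final,
                 stopped = stopped, steps = steps_run,
                 config = config, seed = as.integer(seed)),
            class = "clone_sim")
}

#' Final aggregate counts of a simulation
#'
#' @param sim A `clone_sim` object (or its `clones` tibble).
#' @return One-row tibble: `N_primary`, `N_metastatic`, `n_clones` (clones
#'   with at least one cell).
#' @export
summarize_final <- function(sim) {
  clones <- if (inherits(sim, "clone_sim")) sim$clones else sim
  alive <- dplyr::filter(clones, .data$n_cells > 0)
  tibble::tibble(
    N_primary = sum(alive$n_cells[alive$compartment == "primary"]),
    N_metastatic = sum(alive$n_cells[alive$compartment == "metastatic"]),
    n_clones = nrow(alive)
  )
}

#' Order of gene dysfunction for surviving clones
#'
#' Reports, for each surviving clone, the genes of its lineage in the order
#' they were first impaired (first to last), with the hit step and the
#' clone's final cell count.
#'
#' @param sim A `clone_sim` object.
#' @return Tibble: `clone_id`, `n_cells`, `compartment`, `order` (the
#'   `gene:step;...` string, empty for unmutated clones), `genes` (list
#'   column of gene names in hit order).
#' @export
order_of_dysfunction <- function(sim) {
  stopifnot(inherits(sim, "clone_sim"))
  cl <- dplyr::filter(sim$clones, .data$n_cells > 0)
  genes <- lapply(cl$mutation_order, function(s) {
    if (!nzchar(s)) return(character(0))
    vapply(strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE),
           `[[`, "", 1)
  })
  tibble::tibble(clone_id = cl$clone_id, n_cells = cl$n_cells,
                 compartment = cl$compartment, order = cl$mutation_order,
                 genes = genes)
}

#' @export
print.clone_sim <- function(x, ...) {
  fin <- summarize_final(x)
  cat("Clonal-evolution simulation:", x$steps, "steps (stopped:", x$stopped, ")\n")
  cat(sprintf("  primary cells: %g  metastatic cells: %g  clones: %d\n",
              fin$N_primary, fin$N_metastatic, fin$n_clones))
  invisible(x)
}

#' Tidy a simulation into its evolution log
#'
#' @param x A `clone_sim` object.
#' @param ... Unused.
#' @return The per-step per-clone log tibble (falls back to the per-step
#'   summary when the run was executed with `log = FALSE`).
#' @method tidy clone_sim
#' @export
tidy.clone_sim <- function(x, ...) {
  if (!is.null(x$log)) x$log else x$summary
}

#' One-row summary of a simulation
#'
#' @param x A `clone_sim` object.
#' @param ... Unused.
#' @return One-row tibble: `steps`, `stopped`, `N_primary`, `N_metastatic`,
#'   `n_clones`.
#' @method glance clone_sim
#' @export
glance.clone_sim <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(steps = x$steps, stopped = x$stopped),
                   summarize_final(x))
}

#' Plot population trajectories of a simulation
#'
#' Primary cells, metastatic cells and clone count over time.
#'
#' @param object A `clone_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clone_sim
#' @export
autoplot.clone_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary,
                            c("N_primary", "N_metastatic", "n_clones"),
                            names_to = "series", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$count,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time step", y = "count", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Write simulation outputs as TSV files
#'
#' Writes the evolution log (`evolution_log.tsv`: one row per step per
#' clone), the per-step summary (`summary.tsv`) and the final-state table
#' (`final_state.tsv`, with the order-of-dysfunction string per surviving
#' clone) into a directory.
#'
#' @param sim A `clone_sim` object run with `log = TRUE`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim_outputs <- function(sim, dir) {
  stopifnot(inherits(sim, "clone_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(as.data.frame(df), file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sim$log)) tsv(sim$log, "evolution_log.tsv")
  tsv(sim$summary, "summary.tsv")
  fin <- dplyr::select(sim$clones, "clone_id", "genotype", "n_cells",
                       "compartment", order_of_dysfunction = "mutation_order")
  tsv(fin, "final_state.tsv")
  invisible(dir)
}
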