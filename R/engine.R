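clamp01 <- function(x) pmin(1, pmax(0, x))

# Per-gene driver mutation probability: m0 scaled by CDS length relative to
# the panel mean when lengths are available, uniform otherwise.
gene_mutation_probs <- function(panel, params) {
  L <- panel$cds_length
  if (all(is.na(L))) {
    rel <- rep(1, nrow(panel))
  } else {
    L[is.na(L)] <- mean(L, na.rm = TRUE)
    rel <- L / mean(L)
  }
  clamp01(params$m0 * rel)
}

# fast internal form: named numeric vector of the five trial probabilities
.trial_probs <- function(H, params, compartment, N_primary) {
  p_apoptosis <- clamp01(params$a0 - H[["Ha"]])
  p_env_death <- params$k0
  p_immortal <- clamp01(H[["Hi"]])
  p_invasion <- clamp01(H[["Him"]])
  base_div <- params$d0 + H[["Hd"]]
  if (compartment == "primary") {
    Eprime <- params$E0 / (1 + params$F * H[["Hb"]])
    p_division <- clamp01(base_div * (1 - Eprime * N_primary))
  } else {
    p_division <- clamp01(base_div)
  }
  c(p_apoptosis = p_apoptosis, p_env_death = p_env_death,
    p_division = p_division, p_immortal_survival = p_immortal,
    p_invasion = p_invasion)
}

#' Per-clone trial probabilities under hallmark interference
#'
#' Translates a clone's hallmark values into the five per-cell trial
#' probabilities for one time step:
#' \itemize{
#'   \item apoptosis: `clamp(a0 - Ha, 0, 1)` — the apoptosis hallmark lowers
#'     the base death-by-apoptosis probability;
#'   \item environmental death: `k0`, hallmark-independent;
#'   \item immortalization survival (applied only at the replicative limit):
#'     `Hi`;
#'   \item division: `clamp(d0 + Hd, 0, 1)` for metastatic cells; primary
#'     cells are additionally damped by logistic friction
#'     `(d0 + Hd) * (1 - E' * N_primary)` with `E' = E0 / (1 + F * Hb)`, so
#'     angiogenesis relieves the resource limitation;
#'   \item invasion/metastasis: `Him` (primary cells only).
#' }
#' All results are clamped into `[0, 1]`.
#'
#' @param hallmarks One-row data frame (or named vector) with `Ha`, `Hd`,
#'   `Hi`, `Hb`, `Him` in `[0, 1]`, as from [compute_hallmarks()].
#' @param params A [sim_params()] object.
#' @param compartment `"primary"` or `"metastatic"`.
#' @param N_primary Current number of primary-compartment cells (drives the
#'   friction term).
#' @return One-row tibble with columns `p_apoptosis`, `p_env_death`,
#'   `p_division`, `p_immortal_survival`, `p_invasion`.
#' @examples
#' trial_probabilities(
#'   data.frame(Ha = 0.2, Hd = 0, Hi = 0, Hb = 0, Him = 0),
#'   sim_params(a0 = 0.5), "primary", N_primary = 0
#' )
#' @export
trial_probabilities <- function(hallmarks, params, compartment = "primary",
                                N_primary = 0) {
  compartment <- match.arg(compartment, c("primary", "metastatic"))
  if (is.data.frame(hallmarks)) hallmarks <- unlist(hallmarks[1, hallmark_names()])
  stopifnot(all(hallmark_names() %in% names(hallmarks)), N_primary >= 0)
  tibble::as_tibble(as.list(.trial_probs(hallmarks, params, compartment, N_primary)))
}

# One step of sequential per-cell fate trials for a clone, aggregated as
# binomial draws (distributionally identical to per-cell Bernoulli trials).
# Order: apoptosis -> environmental death -> replicative-limit check
# (immortalization survival if c >= c_max) -> division -> invasion.
.step_counts <- function(n_cells, c, probs, params, compartment) {
  n <- n_cells
  a_deaths <- stats::rbinom(1, n, probs[["p_apoptosis"]])
  s1 <- n - a_deaths
  e_deaths <- stats::rbinom(1, s1, probs[["p_env_death"]])
  s2 <- s1 - e_deaths
  if (c >= params$c_max) {
    s3 <- stats::rbinom(1, s2, probs[["p_immortal_survival"]])
  } else {
    s3 <- s2
  }
  dividers <- stats::rbinom(1, s3, probs[["p_division"]])
  invaders <- if (compartment == "primary") {
    stats::rbinom(1, s3, probs[["p_invasion"]])
  } else 0L
  list(survivors = s3, dividers = dividers, invaders = invaders,
       deaths = n - s3)
}

#' Run one step of fate trials for a clone
#'
#' Puts every cell of a clone through the per-step trial sequence —
#' apoptosis, environmental death, immortalization survival when the clone
#' has reached the replicative limit, division, and (for primary clones)
#' invasion — using aggregated binomial draws over the clone's cells, which
#' is distributionally equivalent to independent per-cell Bernoulli trials.
#' Uses R's global RNG stream; seed via [set.seed()] or the driver.
#'
#' @param clone A list or one-row data frame with at least `n_cells` (>= 1),
#'   `c` (division counter) and `compartment`.
#' @param probs Trial probabilities, as from [trial_probabilities()].
#' @param params A [sim_params()] object.
#' @return One-row tibble with `survivors` (cells alive after the death
#'   trials), `dividers` (survivors that divide; `<= survivors`), `invaders`
#'   (survivors that invade; `<= survivors`) and `deaths`.
#' @export
step_clone <- function(clone, probs, params) {
  if (is.data.frame(clone)) clone <- as.list(clone[1, ])
  if (is.null(clone$n_cells) || clone$n_cells < 1) {
    stop("step_clone requires a clone with n_cells >= 1", call. = FALSE)
  }
  if (is.data.frame(probs)) probs <- unlist(probs[1, ])
  comp <- if (is.null(clone$compartment)) "primary" else clone$compartment
  cc <- if (is.null(clone$c)) 0 else clone$c
  res <- .step_counts(clone$n_cells, cc, probs, params, comp)
  tibble::as_tibble(res)
}

# Sample a hit pattern over free genes conditioned on at least one hit,
# sequentially with suffix no-hit products (exact conditional distribution).
.conditional_hits <- function(m_free) {
  k <- length(m_free)
  q_suffix <- rev(cumprod(rev(1 - m_free)))   # P(no hit among j..k)
  hits <- logical(k)
  hit_yet <- FALSE
  for (j in seq_len(k)) {
    if (hit_yet) {
      p <- m_free[j]
    } else if (j == k) {
      p <- 1
    } else {
      p <- m_free[j] / (1 - q_suffix[j])
    }
    hits[j] <- stats::runif(1) < p
    hit_yet <- hit_yet || hits[j]
  }
  hits
}

# Distribute daughter cells over new genotypes. Returns list(unmutated = count,
# mutants = list of list(genotype, n_cells, new_genes)).
.mutate_daughters <- function(genotype, daughters, m_gene) {
  free <- which(genotype == 0L)
  if (daughters == 0 || length(free) == 0) {
    return(list(unmutated = daughters, mutants = list()))
  }
  m_free <- m_gene[free]
  p_any <- 1 - prod(1 - m_free)
  n_mut <- stats::rbinom(1, daughters, p_any)
  mutants <- list()
  if (n_mut > 0) {
    grouped <- new.env(parent = emptyenv())
    for (i in seq_len(n_mut)) {
      hits <- .conditional_hits(m_free)
      g <- genotype
      g[free[hits]] <- 1L
      key <- genotype_to_bitstring(g)
      rec <- get0(key, envir = grouped)
      if (is.null(rec)) {
        rec <- list(genotype = g, n_cells = 0, new_genes = free[hits])
      }
      rec$n_cells <- rec$n_cells + 1
      assign(key, rec, envir = grouped)
    }
    mutants <- mget(ls(grouped), envir = grouped)
    names(mutants) <- NULL
  }
  list(unmutated = daughters - n_mut, mutants = mutants)
}

#' Mutate the daughter cells of a dividing clone
#'
#' Each division replaces one parent cell by two daughter cells; every
#' daughter independently acquires, for each not-yet-mutated gene `g`, a new
#' driver hit with probability `m0 * L_g / mean(L)` (CDS-length weighted when
#' lengths are present, uniform otherwise). Daughters sharing an identical
#' new genotype are grouped into one new clone; daughters without new hits
#' stay with the parent genotype.
#'
#' @param clone A list or one-row data frame with `genotype` (0/1 vector or
#'   bitstring) and `clone_id`.
#' @param dividers Number of divisions this step (the clone gains
#'   `2 * dividers` daughter cells in place of `dividers` parents).
#' @param panel The [gene_panel()].
#' @param params A [sim_params()] object.
#' @param step Current time step (recorded as the hit step of new mutations).
#' @return A tibble with one row per daughter genotype (including the
#'   unmutated parent genotype when any daughter stays unmutated): columns
#'   `genotype` (bitstring), `n_cells`, `new_genes` (list column of newly
#'   hit gene names).
#' @export
mutate_daughters <- function(clone, dividers, panel, params, step = 0L) {
  if (is.data.frame(clone)) clone <- as.list(clone[1, ])
  g <- clone$genotype
  if (is.character(g)) g <- genotype_from_bitstring(g)
  stopifnot(dividers >= 0, length(g) == nrow(panel))
  m_gene <- gene_mutation_probs(panel, params)
  res <- .mutate_daughters(as.integer(g), 2 * dividers, m_gene)
  rows <- list()
  if (res$unmutated > 0) {
    rows[[1]] <- tibble::tibble(genotype = genotype_to_bitstring(g),
                                n_cells = res$unmutated,
                                new_genes = list(character(0)))
  }
  for (m in res$mutants) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      genotype = genotype_to_bitstring(m$genotype),
      n_cells = m$n_cells,
      new_genes = list(panel$gene[m$new_genes])
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(genotype = character(), n_cells = numeric(),
                          new_genes = list()))
  }
  dplyr::bind_rows(rows)
}

#' Move invading cells into the metastatic compartment
#'
#' Splits `invaders` cells off a primary clone into a metastatic clone with
#' the same genotype and lineage metadata. Metastatic cells are never
#' subject to the logistic friction term afterwards.
#'
#' @param clone One-row data frame (or list) describing a primary clone.
#' @param invaders Number of cells to convert; must not exceed the clone's
#'   `n_cells`.
#' @return A list with `primary` (the clone with `invaders` cells removed)
#'   and `metastatic` (a new clone record, or `NULL` when `invaders == 0`).
#' @export
apply_invasion <- function(clone, invaders) {
  if (is.data.frame(clone)) clone <- as.list(clone[1, ])
  if (!identical(clone$compartment, "primary")) {
    stop("apply_invasion applies to primary clones only", call. = FALSE)
  }
  if (invaders > clone$n_cells) {
    stop("invaders exceed the clone's cell count", call. = FALSE)
  }
  primary <- clone
  primary$n_cells <- clone$n_cells - invaders
  metastatic <- NULL
  if (invaders > 0) {
    metastatic <- clone
    metastatic$n_cells <- invaders
    metastatic$compartment <- "metastatic"
    metastatic$parent_id <- clone$clone_id
  }
  list(primary = primary, metastatic = metastatic)
}
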