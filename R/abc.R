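#' Prior over gene-to-hallmark weights
#'
#' Builds the ABC prior from a template weight table: the participation
#' mask (which gene-hallmark weights are free) is taken from the nonzero
#' entries of the template, and each hallmark's free weights receive a flat
#' symmetric Dirichlet prior over the participating-gene simplex, so every
#' draw satisfies the unit-column-sum invariant of [hallmark_weights()].
#'
#' @param weights A `hallmark_weights` template; zero entries stay fixed at
#'   zero, positive entries mark free parameters.
#' @return An object of class `weight_prior` with elements `genes`, `mask`
#'   (genes x hallmarks logical matrix) and `sample()` (a function drawing
#'   one `hallmark_weights` table from the prior, using the global RNG).
#' @export
weight_prior <- function(weights) {
  hn <- hallmark_names()
  genes <- weights$gene
  mask <- as.matrix(weights[, hn]) > 0
  rownames(mask) <- genes
  sample_fn <- function() {
    m <- matrix(0, nrow = length(genes), ncol = length(hn),
                dimnames = list(genes, hn))
    for (h in seq_along(hn)) {
      free <- which(mask[, h])
      if (length(free)) {
        g <- stats::rgamma(length(free), shape = 1)
        m[free, h] <- g / sum(g)
      }
    }
    hallmark_weights(m, normalize = FALSE)
  }
  structure(list(genes = genes, mask = mask, sample = sample_fn),
            class = "weight_prior")
}

free_param_names <- function(mask) {
  hn <- colnames(mask)
  out <- character(0)
  for (h in hn) {
    g <- rownames(mask)[mask[, h]]
    if (length(g)) out <- c(out, paste0(h, ".", g))
  }
  out
}

# flatten the free entries of a weight table, in free_param_names order
free_vec <- function(weights, mask) {
  m <- as.matrix(weights[, colnames(mask)])
  rownames(m) <- weights$gene
  vals <- numeric(0)
  for (h in colnames(mask)) {
    g <- rownames(mask)[mask[, h]]
    vals <- c(vals, m[g, h])
  }
  stats::setNames(vals, free_param_names(mask))
}

# rebuild a hallmark_weights table from a named free-parameter vector
free_vec_to_weights <- function(v, mask) {
  m <- matrix(0, nrow = nrow(mask), ncol = ncol(mask),
              dimnames = dimnames(mask))
  for (h in colnames(mask)) {
    g <- rownames(mask)[mask[, h]]
    if (length(g)) m[g, h] <- v[paste0(h, ".", g)]
  }
  hallmark_weights(m, normalize = FALSE)
}

#' Bare rejection-ABC sampler
#'
#' Generic likelihood-free rejection sampling: draw parameters from a
#' prior, push each through a stochastic simulator producing summary
#' statistics, and keep the draws whose statistics fall closest to the
#' observed ones. [abc_rejection()] builds the full weight-calibration
#' workflow on top of this; the bare sampler is exposed so that any forward
#' model (e.g. an analytically tractable toy) can be plugged in.
#'
#' @param observed Numeric vector of observed summary statistics.
#' @param rprior Function of no arguments returning one parameter draw
#'   (any object).
#' @param simulate Function `(theta, seed)` returning a numeric vector of
#'   simulated summaries the same length as `observed`, or `NULL`/`NA` to
#'   score the draw as unusable (distance `Inf`).
#' @param n_proposals Number of prior draws.
#' @param tolerance Either `list(quantile = q)` (accept the closest fraction
#'   `q` of proposals) or `list(absolute = eps)` (accept distances
#'   `<= eps`).
#' @param distance Function of two numeric vectors; defaults to the
#'   Euclidean norm of their difference.
#' @param seed Integer seed for the whole sampling pass.
#' @return A list: `draws` (list of all parameter draws), `distances`,
#'   `accepted` (logical), `tolerance_value` (the realized cutoff).
#' @export
rejection_sampler <- function(observed, rprior, simulate, n_proposals,
                              tolerance = list(quantile = 0.1),
                              distance = NULL, seed = 1L) {
  stopifnot(n_proposals >= 1)
  if (is.null(distance)) distance <- function(a, b) sqrt(sum((a - b)^2))
  set.seed(as.integer(seed))
  draws <- vector("list", n_proposals)
  for (i in seq_len(n_proposals)) draws[[i]] <- rprior()
  sim_seeds <- sample.int(.Machine$integer.max, n_proposals)
  d <- rep(Inf, n_proposals)
  for (i in seq_len(n_proposals)) {
    s <- simulate(draws[[i]], sim_seeds[i])
    if (!is.null(s) && !anyNA(s)) d[i] <- distance(s, observed)
  }
  cutoff <- if (!is.null(tolerance$absolute)) {
    tolerance$absolute
  } else {
    stats::quantile(d[is.finite(d)], probs = tolerance$quantile,
                    names = FALSE, type = 7)
  }
  accepted <- is.finite(d) & d <= cutoff
  list(draws = draws, distances = d, accepted = accepted,
       tolerance_value = cutoff)
}

# forward map for ABC: mean pooled VAF over replicate seeds; NULL if any
# replicate ends in extinction (observed tumors imply survival)
simulate_pooled_vaf <- function(weights, config, seeds, ploidy = 2) {
  cfg <- config
  cfg$weights <- hallmark_weights(weights, panel = config$panel, normalize = FALSE)
  acc <- NULL
  for (s in seeds) {
    sim <- run_simulation(cfg, seed = s, log = FALSE)
    if (sum(sim$clones$n_cells) <= 0) return(NULL)
    v <- compute_vaf(sim, config$panel, "pooled", ploidy = ploidy)$vaf
    acc <- if (is.null(acc)) v else acc + v
  }
  acc / length(seeds)
}

#' Calibrate hallmark weights against observed VAFs by rejection ABC
#'
#' Draws candidate weight matrices from the simplex-flat prior, runs the
#' forward clonal-evolution simulator for each (averaging pooled VAFs over
#' `replicates` seeds), measures the Euclidean distance between simulated
#' and observed per-gene VAFs, and accepts the draws within tolerance.
#' Proposals whose simulations go extinct are scored at infinite distance
#' (an observed tumor implies a surviving population).
#'
#' @param observed Observed VAFs: tibble with `gene`, `vaf` (as from
#'   [read_observed_vaf()]) or a numeric vector in panel order.
#' @param prior A [weight_prior()]; defaults to the prior induced by the
#'   configuration's weight table.
#' @param config A [sim_config()] describing the forward simulator.
#' @param n_proposals Number of prior draws (default 1000).
#' @param tolerance `list(quantile = q)` or `list(absolute = eps)`; default
#'   accepts the closest 10 percent.
#' @param replicates Forward replicates per proposal whose VAFs are
#'   averaged (default 3; 1 is fastest).
#' @param ploidy Passed to [compute_vaf()].
#' @param seed Master seed for prior draws and per-proposal simulator seeds.
#' @return An object of class `clone_abc`: `draws` (tibble of all
#'   proposals: one column per free weight, `distance`, `accepted`),
#'   `accepted` (the accepted subset), `tolerance_value`, `n_proposals`,
#'   `mask`, and `map` (the [map_estimate()] weight table).
#' @seealso [map_estimate()], [nullification_battery()]
#' @export
abc_rejection <- function(observed, config, prior = NULL,
                          n_proposals = 1000,
                          tolerance = list(quantile = 0.1),
                          replicates = 3, ploidy = 2, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), n_proposals >= 1)
  if (is.null(prior)) prior <- weight_prior(config$weights)
  if (is.data.frame(observed)) {
    obs <- observed$vaf[match(config$panel$gene, observed$gene)]
    if (anyNA(obs)) stop("observed VAFs missing for some panel genes", call. = FALSE)
  } else {
    obs <- as.numeric(observed)
    if (length(obs) != nrow(config$panel)) {
      stop("observed VAF vector length does not match the panel", call. = FALSE)
    }
  }

  set.seed(as.integer(seed))
  draws <- vector("list", n_proposals)
  for (i in seq_len(n_proposals)) draws[[i]] <- prior$sample()
  sim_seeds <- matrix(sample.int(.Machine$integer.max, n_proposals * replicates),
                      nrow = n_proposals)
  d <- rep(Inf, n_proposals)
  for (i in seq_len(n_proposals)) {
    s <- simulate_pooled_vaf(draws[[i]], config, sim_seeds[i, ], ploidy)
    if (!is.null(s)) d[i] <- sqrt(sum((s - obs)^2))
  }

  cutoff <- if (!is.null(tolerance$absolute)) {
    tolerance$absolute
  } else {
    if (!any(is.finite(d))) {
      rlang::abort("all proposals went extinct: empty ABC posterior",
                   class = "hallmarksim_empty_posterior", distances = d)
    }
    stats::quantile(d[is.finite(d)], probs = tolerance$quantile,
                    names = FALSE, type = 7)
  }
  accepted <- is.finite(d) & d <= cutoff
  if (!any(accepted)) {
    rlang::abort(
      sprintf("no proposals accepted at tolerance %.4g (min distance %.4g)",
              cutoff, suppressWarnings(min(d))),
      class = "hallmarksim_empty_posterior", distances = d)
  }

  free_mat <- t(vapply(draws, free_vec, free_vec(draws[[1]], prior$mask),
                       mask = prior$mask))
  draw_tbl <- tibble::as_tibble(free_mat)
  draw_tbl$distance <- d
  draw_tbl$accepted <- accepted

  res <- structure(list(draws = draw_tbl,
                        accepted = draw_tbl[accepted, ],
                        tolerance_value = cutoff,
                        n_proposals = n_proposals,
                        n_accepted = sum(accepted),
                        mask = prior$mask,
                        observed = obs,
                        genes = config$panel$gene),
                   class = "clone_abc")
  res$map <- map_estimate(res)
  res
}

#' MAP weight estimate from an ABC posterior
#'
#' The mode of a kernel-density estimate computed per free parameter
#' (product approximation) over the accepted draws, projected back onto the
#' per-hallmark simplex constraints (each hallmark column renormalized over
#' its free entries). With fewer than 20 accepted draws the
#' minimum-distance draw is returned instead and flagged via the
#' `"map_method"` attribute (`"kde"` or `"min_distance"`).
#'
#' @param result A `clone_abc` object.
#' @return A `hallmark_weights` tibble with attribute `map_method`.
#' @export
map_estimate <- function(result) {
  stopifnot(inherits(result, "clone_abc"))
  acc <- result$accepted
  if (nrow(acc) == 0) stop("empty ABC posterior: no accepted draws", call. = FALSE)
  pn <- free_param_names(result$mask)
  if (nrow(acc) < 20) {
    best <- acc[which.min(acc$distance), ]
    v <- stats::setNames(as.numeric(best[1, pn]), pn)
    w <- free_vec_to_weights(v, result$mask)
    w <- project_simplex(w, result$mask)
    attr(w, "map_method") <- "min_distance"
    return(w)
  }
  v <- vapply(pn, function(nm) {
    x <- acc[[nm]]
    if (stats::sd(x) < 1e-12) return(x[1])
    dd <- stats::density(x, from = max(0, min(x) - 0.05),
                         to = min(1, max(x) + 0.05))
    dd$x[which.max(dd$y)]
  }, 0)
  w <- free_vec_to_weights(v, result$mask)
  w <- project_simplex(w, result$mask)
  attr(w, "map_method") <- "kde"
  w
}

# renormalize each hallmark column over its free entries to unit sum
project_simplex <- function(weights, mask) {
  for (h in colnames(mask)) {
    s <- sum(weights[[h]][mask[, h]])
    if (s > 0) weights[[h]] <- weights[[h]] / s
  }
  weights
}

#' @export
print.clone_abc <- function(x, ...) {
  cat(sprintf("Rejection-ABC posterior: %d / %d proposals accepted (tolerance %.4g)\n",
              x$n_accepted, x$n_proposals, x$tolerance_value))
  cat("MAP weights (", attr(x$map, "map_method"), "):\n", sep = "")
  print(tibble::as_tibble(x$map))
  invisible(x)
}

#' Tidy posterior summaries of an ABC fit
#'
#' @param x A `clone_abc` object.
#' @param ... Unused.
#' @return Tibble, one row per free weight: `hallmark`, `gene`, posterior
#'   `mean`, `sd`, quantiles `q025`, `q50`, `q975`, and the `map` value.
#' @method tidy clone_abc
#' @export
tidy.clone_abc <- function(x, ...) {
  pn <- free_param_names(x$mask)
  map_v <- free_vec(x$map, x$mask)
  purrr::map_dfr(pn, function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    v <- x$accepted[[nm]]
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(hallmark = parts[1],
                   gene = paste(parts[-1], collapse = "."),
                   mean = mean(v), sd = stats::sd(v),
                   q025 = q[1], q50 = q[2], q975 = q[3],
                   map = unname(map_v[nm]))
  })
}

#' One-row summary of an ABC fit
#'
#' @param x A `clone_abc` object.
#' @param ... Unused.
#' @return One-row tibble: `n_proposals`, `n_accepted`, `acceptance_rate`,
#'   `tolerance`, `min_distance`.
#' @method glance clone_abc
#' @export
glance.clone_abc <- function(x, ...) {
  tibble::tibble(n_proposals = x$n_proposals, n_accepted = x$n_accepted,
                 acceptance_rate = x$n_accepted / x$n_proposals,
                 tolerance = x$tolerance_value,
                 min_distance = min(x$draws$distance))
}

#' Plot ABC posterior marginals
#'
#' Histograms of the accepted draws for each free gene-hallmark weight.
#'
#' @param object A `clone_abc` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clone_abc
#' @export
autoplot.clone_abc <- function(object, ...) {
  pn <- free_param_names(object$mask)
  df <- tidyr::pivot_longer(object$accepted[, pn], dplyr::all_of(pn),
                            names_to = "parameter", values_to = "weight")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "weight", y = "accepted draws") +
    ggplot2::theme_minimal()
}

#' In-silico gene-nullification experiment battery
#'
#' Re-runs the simulator under the calibrated (e.g. MAP) weights — the
#' baseline — and once per gene with that gene's weights set to zero while
#' all other weights are kept, measuring the final numbers of primary tumor
#' cells, metastatic cells and clones. The same per-run seeds are shared
#' across conditions, so nullifying a gene with zero weights reproduces the
#' baseline runs exactly.
#'
#' @param map_weights The calibrated `hallmark_weights` table (baseline).
#' @param config A [sim_config()] (its weight table is replaced per
#'   condition).
#' @param genes Genes to nullify, one condition each (default: the whole
#'   panel).
#' @param n_runs Simulations per condition.
#' @param seed Master seed; per-run seeds are derived once and reused
#'   across conditions.
#' @return A tibble of class `nullification_battery`: `condition`
#'   (`"baseline"` or `"-GENE"`), `run`, `seed`, `N_primary`,
#'   `N_metastatic`, `n_clones`.
#' @export
nullification_battery <- function(map_weights, config, genes = NULL,
                                  n_runs = 50, seed = 1L) {
  stopifnot(inherits(config, "sim_config"), n_runs >= 1)
  if (is.null(genes)) genes <- config$panel$gene
  stopifnot(all(genes %in% config$panel$gene))
  base_w <- hallmark_weights(map_weights, panel = config$panel, normalize = FALSE)
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max, n_runs)

  conditions <- c("baseline", paste0("-", genes))
  weight_sets <- c(list(base_w), lapply(genes, nullify_gene, weights = base_w))

  out <- purrr::map2_dfr(conditions, weight_sets, function(cond, w) {
    cfg <- config
    cfg$weights <- w
    purrr::map_dfr(seq_len(n_runs), function(r) {
      sim <- run_simulation(cfg, seed = run_seeds[r], log = FALSE)
      dplyr::bind_cols(tibble::tibble(condition = cond, run = r,
                                      seed = run_seeds[r]),
                       summarize_final(sim))
    })
  })
  class(out) <- c("nullification_battery", class(out))
  out
}

#' Summarize a nullification battery
#'
#' @param x A `nullification_battery` tibble.
#' @param ... Unused.
#' @return Tibble of per-condition medians and quartiles of the three final
#'   counts.
#' @method glance nullification_battery
#' @export
glance.nullification_battery <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$condition),
    dplyr::across(c("N_primary", "N_metastatic", "n_clones"),
                  list(q25 = ~stats::quantile(.x, 0.25),
                       median = ~stats::median(.x),
                       q75 = ~stats::quantile(.x, 0.75))),
    .groups = "drop")
}

#' Plot a nullification battery
#'
#' Boxplots of the final primary, metastatic and clone counts per
#' condition, mirroring the knockout-experiment readout.
#'
#' @param object A `nullification_battery` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nullification_battery
#' @export
autoplot.nullification_battery <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("N_primary", "N_metastatic", "n_clones"),
                            names_to = "measure", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$count)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "final count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
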