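H0 <- function(Ha = 0, Hd = 0, Hi = 0, Hb = 0, Him = 0) {
  data.frame(Ha = Ha, Hd = Hd, Hi = Hi, Hb = Hb, Him = Him)
}

test_that("apoptosis interference follows a0 - Ha with clamping", {
  p <- sim_params(a0 = 0.5)
  expect_equal(trial_probabilities(H0(Ha = 0.2), p)$p_apoptosis, 0.3)
  # hallmark larger than the base probability clamps at zero
  expect_equal(trial_probabilities(H0(Ha = 0.9), p)$p_apoptosis, 0)
})

test_that("division friction and angiogenesis relief follow the logistic form", {
  # friction zeroes division exactly at N = 1/E0
  p <- sim_params(d0 = 0.35, E0 = 1e-3, F = 0)
  expect_equal(trial_probabilities(H0(), p, "primary", 1000)$p_division, 0)
  # worked example: (d0 + Hd) * (1 - E0/(1 + F*Hb) * N)
  p <- sim_params(d0 = 0.3, E0 = 1e-3, F = 1)
  pr <- trial_probabilities(H0(Hd = 0.1, Hb = 1), p, "primary", 500)
  expect_equal(pr$p_division, 0.4 * (1 - 0.0005 * 500))
  # metastatic clones feel no friction
  expect_equal(trial_probabilities(H0(Hd = 0.1, Hb = 1), p, "metastatic",
                                   500)$p_division, 0.4)
  # immortalization and invasion hallmarks pass through directly
  pr <- trial_probabilities(H0(Hi = 0.6, Him = 0.25), sim_params())
  expect_equal(pr$p_immortal_survival, 0.6)
  expect_equal(pr$p_invasion, 0.25)
})

test_that("all trial probabilities clamp into [0, 1] for adversarial inputs", {
  set.seed(7)
  for (i in 1:50) {
    p <- sim_params(a0 = runif(1), d0 = runif(1), k0 = runif(1),
                    E0 = runif(1, 0, 0.01), F = runif(1, 0, 20))
    H <- H0(runif(1), runif(1), runif(1), runif(1), runif(1))
    for (comp in c("primary", "metastatic")) {
      pr <- unlist(trial_probabilities(H, p, comp, sample(0:5000, 1)))
      expect_true(all(pr >= 0 & pr <= 1))
    }
  }
})

test_that("step_clone honors certain outcomes and count contracts", {
  p <- sim_params(c_max = 1e9)
  clone <- list(n_cells = 100, c = 0, compartment = "primary")
  zero <- H0()
  # no-op: all probabilities zero
  set.seed(1)
  r <- step_clone(clone, trial_probabilities(zero, sim_params(a0 = 0, d0 = 0,
                                                              k0 = 0, E0 = 0)), p)
  expect_equal(r$survivors, 100)
  expect_equal(r$dividers, 0)
  # certain apoptosis
  r <- step_clone(clone, trial_probabilities(zero, sim_params(a0 = 1)), p)
  expect_equal(r$survivors, 0)
  expect_error(step_clone(list(n_cells = 0, c = 0, compartment = "primary"),
                          trial_probabilities(zero, p), p),
               "n_cells >= 1")
  # dividers and invaders never exceed survivors
  set.seed(2)
  pr <- tibble::tibble(p_apoptosis = 0.3, p_env_death = 0.2, p_division = 0.9,
                       p_immortal_survival = 0, p_invasion = 0.9)
  for (i in 1:50) {
    r <- step_clone(list(n_cells = 20, c = 0, compartment = "primary"), pr, p)
    expect_lte(r$dividers, r$survivors)
    expect_lte(r$invaders, r$survivors)
    expect_equal(r$deaths, 20 - r$survivors)
  }
})

test_that("aggregated survival counts match binomial moments and distribution", {
  p <- sim_params(c_max = 1e9)
  pr <- tibble::tibble(p_apoptosis = 0.3, p_env_death = 0, p_division = 0,
                       p_immortal_survival = 0, p_invasion = 0)
  set.seed(5)
  n <- 1e5
  r <- step_clone(list(n_cells = n, c = 0, compartment = "primary"), pr, p)
  se <- sqrt(n * 0.3 * 0.7)
  expect_lt(abs(r$survivors - 0.7 * n), 4 * se)

  # distributional equivalence with per-cell Bernoulli trials at small n
  set.seed(6)
  small <- 5; reps <- 4000
  agg <- replicate(reps, step_clone(list(n_cells = small, c = 0,
                                         compartment = "primary"), pr, p)$survivors)
  obs <- tabulate(agg + 1, nbins = small + 1)
  expected <- dbinom(0:small, small, 0.7) * reps
  keep <- expected > 5
  chi <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_lt(chi, qchisq(0.999, df = sum(keep) - 1))
})

test_that("replicative limit gates survival through the immortalization trial", {
  p <- sim_params(c_max = 3)
  pr_die <- tibble::tibble(p_apoptosis = 0, p_env_death = 0, p_division = 0,
                           p_immortal_survival = 0, p_invasion = 0)
  pr_live <- dplyr::mutate(pr_die, p_immortal_survival = 1)
  at_limit <- list(n_cells = 50, c = 3, compartment = "primary")
  below <- list(n_cells = 50, c = 2, compartment = "primary")
  set.seed(8)
  expect_equal(step_clone(at_limit, pr_die, p)$survivors, 0)
  expect_equal(step_clone(at_limit, pr_live, p)$survivors, 50)
  expect_equal(step_clone(below, pr_die, p)$survivors, 50)
})

test_that("mutation at division hits unmutated genes at the stated rate", {
  panel <- four_gene_panel()
  clone <- list(clone_id = 1L, genotype = "0000")
  # zero mutation rate: every daughter keeps the parent genotype
  p0 <- sim_params(m0 = 0)
  set.seed(9)
  out <- mutate_daughters(clone, dividers = 50, panel, p0)
  expect_equal(nrow(out), 1)
  expect_equal(out$genotype, "0000")
  expect_equal(out$n_cells, 100)
  # certain mutation on a one-gene panel: every daughter joins the mutant clone
  p1 <- sim_params(m0 = 1)
  one <- gene_panel("G1")
  out <- mutate_daughters(list(clone_id = 1L, genotype = "0"), 25, one, p1)
  expect_equal(out$genotype, "1")
  expect_equal(out$n_cells, 50)
  expect_equal(out$new_genes[[1]], "G1")

  # uniform rates: mutant fraction matches 1 - (1 - m0)^4 within 4 sigma
  panel_u <- gene_panel(paste0("G", 1:4))
  pm <- sim_params(m0 = 0.01)
  set.seed(10)
  D <- 2e4
  out <- mutate_daughters(list(clone_id = 1L, genotype = "0000"), D / 2, panel_u, pm)
  frac <- 1 - out$n_cells[out$genotype == "0000"] / D
  p_any <- 1 - (1 - 0.01)^4
  expect_lt(abs(frac - p_any), 4 * sqrt(p_any * (1 - p_any) / D))

  # daughter totals always add up to 2 * dividers
  set.seed(12)
  for (i in 1:20) {
    out <- mutate_daughters(list(clone_id = 1L, genotype = "0000"), 200,
                            panel_u, sim_params(m0 = 0.05))
    expect_equal(sum(out$n_cells), 400)
  }
})

test_that("CDS-length weighting tilts the per-gene hit rate", {
  panel <- gene_panel(c("long", "short"), cds_length = c(9000, 1000))
  pm <- sim_params(m0 = 0.02)
  set.seed(13)
  cells <- c(long = 0, short = 0)
  for (i in 1:400) {
    out <- mutate_daughters(list(clone_id = 1L, genotype = "00"), 50, panel, pm)
    for (j in seq_len(nrow(out))) {
      for (g in out$new_genes[[j]]) cells[g] <- cells[g] + out$n_cells[j]
    }
  }
  # per-daughter hit rates are m0 * 1.8 vs m0 * 0.2: a 9:1 cell-count ratio
  expect_gt(cells[["long"]] / cells[["short"]], 6)
  expect_lt(cells[["long"]] / cells[["short"]], 13)
})

test_that("invasion moves cells to a metastatic clone and conserves counts", {
  clone <- list(clone_id = 7L, parent_id = 1L, genotype = "10", n_cells = 40,
                c = 2L, compartment = "primary")
  none <- apply_invasion(clone, 0)
  expect_null(none$metastatic)
  expect_equal(none$primary$n_cells, 40)
  res <- apply_invasion(clone, 15)
  expect_equal(res$primary$n_cells, 25)
  expect_equal(res$metastatic$n_cells, 15)
  expect_equal(res$metastatic$compartment, "metastatic")
  expect_equal(res$metastatic$genotype, "10")
  expect_equal(res$metastatic$parent_id, 7L)
  # total conversion empties the primary clone
  allin <- apply_invasion(clone, 40)
  expect_equal(allin$primary$n_cells, 0)
  expect_error(apply_invasion(clone, 41), "exceed")
  met <- clone; met$compartment <- "metastatic"
  expect_error(apply_invasion(met, 1), "primary")
})
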