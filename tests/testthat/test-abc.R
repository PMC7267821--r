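test_that("the weight prior draws valid simplex weights on the free mask", {
  w <- paired_weights()
  pr <- weight_prior(w)
  expect_equal(sum(pr$mask), 4)
  set.seed(51)
  for (i in 1:20) {
    d <- pr$sample()
    m <- as.matrix(d[, hallmark_names()])
    expect_true(all(m >= 0))
    expect_equal(m[!pr$mask], rep(0, sum(!pr$mask)))
    expect_equal(unname(colSums(m)[c("Ha", "Him")]), c(1, 1))
  }
})

test_that("rejection sampling accepts the exact self-match at zero tolerance", {
  # simulator is deterministic in theta: proposing the observed value wins
  obs <- c(0.4, 0.1)
  thetas <- list(c(0.1, 0.1), c(0.4, 0.1), c(0.9, 0.2))
  i <- 0
  res <- rejection_sampler(
    observed = obs,
    rprior = function() { i <<- i + 1; thetas[[(i - 1) %% 3 + 1]] },
    simulate = function(theta, seed) theta,
    n_proposals = 3,
    tolerance = list(absolute = 0))
  expect_equal(which(res$accepted), 2)
  expect_equal(res$distances[2], 0)
})

test_that("quantile 1 accepts every usable proposal and Inf marks failures", {
  res <- rejection_sampler(
    observed = 0.5,
    rprior = function() runif(1),
    simulate = function(theta, seed) if (theta > 0.9) NULL else theta,
    n_proposals = 200,
    tolerance = list(quantile = 1),
    seed = 3)
  expect_true(all(res$accepted[is.finite(res$distances)]))
  expect_false(any(res$accepted[!is.finite(res$distances)]))
  expect_true(all(res$distances[res$accepted] <= res$tolerance_value))
})

test_that("ABC on the forward simulator is reproducible and respects tolerance", {
  panel <- four_gene_panel()
  w <- paired_weights()
  cfg <- sim_config(recovery_params(), panel, w)
  obs <- c(0.3, 0.05, 0.1, 0.15)
  fit <- abc_rejection(obs, cfg, n_proposals = 60,
                       tolerance = list(quantile = 0.2), replicates = 1,
                       seed = 7)
  fit2 <- abc_rejection(obs, cfg, n_proposals = 60,
                        tolerance = list(quantile = 0.2), replicates = 1,
                        seed = 7)
  expect_identical(fit$draws, fit2$draws)
  expect_true(all(fit$accepted$distance <= fit$tolerance_value))
  expect_gte(fit$n_accepted, 1)
  td <- tidy(fit)
  expect_setequal(td$hallmark, c("Ha", "Him"))
  expect_equal(glance(fit)$n_proposals, 60)
  expect_s3_class(autoplot(fit), "ggplot")
  # observed table input is equivalent to the bare vector
  obs_tbl <- tibble::tibble(gene = panel$gene, vaf = obs)
  fit3 <- abc_rejection(obs_tbl, cfg, n_proposals = 60,
                        tolerance = list(quantile = 0.2), replicates = 1,
                        seed = 7)
  expect_identical(fit$draws, fit3$draws)
})

test_that("an unreachable absolute tolerance raises an empty-posterior error", {
  panel <- four_gene_panel()
  cfg <- sim_config(recovery_params(), panel, paired_weights())
  expect_error(
    abc_rejection(c(0.3, 0.05, 0.1, 0.15), cfg, n_proposals = 5,
                  tolerance = list(absolute = 0), replicates = 1, seed = 2),
    class = "hallmarksim_empty_posterior")
})

test_that("MAP estimation handles degenerate and unimodal posteriors", {
  w <- paired_weights()
  pr <- weight_prior(w)
  mk_res <- function(tbl) {
    structure(list(accepted = tbl, mask = pr$mask), class = "clone_abc")
  }
  pn <- c("Ha.APC", "Ha.TP53", "Him.KRAS", "Him.PIK3CA")
  # a single accepted draw is returned as-is (min-distance fallback)
  one <- tibble::as_tibble(as.list(stats::setNames(c(0.7, 0.3, 0.2, 0.8), pn)))
  one$distance <- 0.01
  m1 <- map_estimate(mk_res(one))
  expect_equal(attr(m1, "map_method"), "min_distance")
  expect_equal(m1$Ha[m1$gene == "APC"], 0.7)
  # identical draws collapse to that value under the KDE path
  many_same <- one[rep(1, 30), ]
  m2 <- map_estimate(mk_res(many_same))
  expect_equal(attr(m2, "map_method"), "kde")
  expect_equal(m2$Ha[m2$gene == "APC"], 0.7)
  # a unimodal cloud around a known truth lands within its spread
  set.seed(61)
  n <- 400
  cloud <- tibble::tibble(
    Ha.APC = pmin(1, pmax(0, rnorm(n, 0.7, 0.05))))
  cloud$Ha.TP53 <- 1 - cloud$Ha.APC
  cloud$Him.KRAS <- pmin(1, pmax(0, rnorm(n, 0.2, 0.05)))
  cloud$Him.PIK3CA <- 1 - cloud$Him.KRAS
  cloud$distance <- runif(n)
  m3 <- map_estimate(mk_res(cloud))
  expect_lt(abs(m3$Ha[m3$gene == "APC"] - 0.7), 0.05)
  expect_lt(abs(m3$Him[m3$gene == "KRAS"] - 0.2), 0.05)
  # simplex projection: hallmark columns sum to one over free entries
  expect_equal(sum(m3$Ha), 1)
  expect_equal(sum(m3$Him), 1)
})

test_that("toy-model ABC posterior approaches the analytic beta posterior", {
  # forward model: one draw from Binomial(n, p) / n; prior p ~ U(0, 1).
  # With x successes observed, the exact posterior is Beta(x + 1, n - x + 1).
  n <- 40; x_obs <- 12
  res <- rejection_sampler(
    observed = x_obs / n,
    rprior = function() runif(1),
    simulate = function(p, seed) rbinom(1, n, p) / n,
    n_proposals = 8000,
    tolerance = list(quantile = 0.02),
    seed = 71)
  acc <- unlist(res$draws[res$accepted])
  ks <- suppressWarnings(stats::ks.test(acc, function(q) pbeta(q, x_obs + 1,
                                                               n - x_obs + 1)))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("nullification battery shares seeds and isolates gene effects", {
  panel <- four_gene_panel()
  # PIK3CA is the sole invasion-weighted gene; APC carries apoptosis evasion;
  # KRAS carries no weight at all
  w <- hallmark_weights(
    data.frame(gene = panel$gene,
               Ha = c(1, 0, 0, 0),
               Hd = 0, Hi = 0, Hb = 0,
               Him = c(0, 0, 0, 1)),
    panel = panel, normalize = FALSE)
  p <- sim_params(a0 = 0.3, d0 = 0.4, k0 = 0.05, m0 = 5e-3, E0 = 5e-4, F = 0,
                  c_max = 1000, N0 = 150, t_max = 15, N_cap = 5000, seed = 1L)
  cfg <- sim_config(p, panel, w)
  bat <- nullification_battery(w, cfg, genes = c("KRAS", "PIK3CA"),
                               n_runs = 10, seed = 9)
  base <- dplyr::filter(bat, condition == "baseline")
  kras <- dplyr::filter(bat, condition == "-KRAS")
  pik <- dplyr::filter(bat, condition == "-PIK3CA")
  # nullifying a zero-weight gene reproduces the baseline runs exactly
  expect_identical(base[, c("N_primary", "N_metastatic", "n_clones")],
                   kras[, c("N_primary", "N_metastatic", "n_clones")])
  # nullifying the only invasion-weighted gene abolishes metastasis
  expect_true(all(pik$N_metastatic == 0))
  # shared per-run seeds across conditions
  expect_identical(base$seed, pik$seed)
  expect_s3_class(glance(bat), "tbl_df")
  expect_s3_class(autoplot(bat), "ggplot")
  # the battery itself is reproducible
  bat2 <- nullification_battery(w, cfg, genes = c("KRAS", "PIK3CA"),
                                n_runs = 10, seed = 9)
  expect_identical(tibble::as_tibble(bat), tibble::as_tibble(bat2))
})
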