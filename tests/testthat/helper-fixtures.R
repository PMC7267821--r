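# Shared fixtures: small panels, weight tables and configurations built in
# code so every test is self-contained.

two_gene_panel <- function() gene_panel(c("APC", "KRAS"))

four_gene_panel <- function() {
  gene_panel(c("APC", "KRAS", "TP53", "PIK3CA"),
             cds_length = c(8532, 567, 1182, 3207),
             role = c("suppressor", "oncogene", "suppressor", "oncogene"))
}

# weights with APC/TP53 on apoptosis and KRAS/PIK3CA on invasion; the
# dominant gene of each pair is configurable
paired_weights <- function(ha_dom = "APC", him_dom = "PIK3CA", dom = 0.8) {
  g <- c("APC", "KRAS", "TP53", "PIK3CA")
  w <- matrix(0, 4, 5, dimnames = list(g, hallmark_names()))
  w[c("APC", "TP53"), "Ha"] <- if (ha_dom == "APC") c(dom, 1 - dom) else c(1 - dom, dom)
  w[c("KRAS", "PIK3CA"), "Him"] <- if (him_dom == "KRAS") c(dom, 1 - dom) else c(1 - dom, dom)
  hallmark_weights(w, normalize = FALSE)
}

# a neutral configuration: no hallmark effects, tunable base rates
neutral_config <- function(a0 = 0, d0 = 0.2, k0 = 0, m0 = 0, E0 = 0, F = 0,
                           c_max = 1e9, N0 = 30, t_max = 10, N_cap = 1e9,
                           n_genes = 1) {
  panel <- gene_panel(paste0("G", seq_len(n_genes)))
  w <- hallmark_weights(
    data.frame(gene = panel$gene, Ha = rep(0, n_genes)), panel = panel)
  sim_config(sim_params(a0 = a0, d0 = d0, k0 = k0, m0 = m0, E0 = E0, F = F,
                        c_max = c_max, N0 = N0, t_max = t_max, N_cap = N_cap,
                        seed = 1L),
             panel, w)
}

# desk-scale configuration used for the ABC recovery experiments
recovery_params <- function() {
  sim_params(a0 = 0.35, d0 = 0.45, k0 = 0.05, m0 = 2e-3, E0 = 5e-4, F = 0,
             c_max = 1000, N0 = 200, t_max = 30, N_cap = 5000, seed = 1L)
}

random_weights <- function(panel, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::runif(nrow(panel) * 5), nrow(panel), 5,
              dimnames = list(panel$gene, hallmark_names()))
  hallmark_weights(m, normalize = TRUE)
}

all_genotypes <- function(n) {
  g <- expand.grid(rep(list(0:1), n))
  as.matrix(g[, rev(seq_len(n)), drop = FALSE])
}
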