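# Shared synthetic worlds for the test suite. All fixtures are built in
# code; no data files.

# A small cohort configuration over the first `n_regions` atlas labels.
small_config <- function(n_per_group = 30, n_regions = 8,
                         effects = NULL, noise_sd = "auto", seed = 1,
                         group_params = group_params_default(), ...) {
  regs <- region_names(n_regions)
  if (is.null(effects)) {
    effects <- data.frame(region = regs[c(1, 3)], mmse = c(2, -1.5),
                          faq = c(-3, 1))
  }
  cohort_config(n_per_group = n_per_group, n_regions = n_regions,
                group_params = group_params, effect_map = effects,
                confounder_coeffs = confounder_coeffs_default(n_regions),
                noise_sd = noise_sd, seed = seed, ...)
}

# Group parameters with identical score distributions and age ranges in
# every group: removes between-group heterogeneity so that signal and
# confounding are cleanly identifiable (the "low noise" worlds).
homogeneous_groups <- function(mmse_mean = 25, mmse_sd = 3,
                               faq_mean = 10, faq_sd = 3,
                               age_range = c(55, 90)) {
  gp <- group_params_default()
  for (g in names(gp)) {
    gp[[g]]$age_range <- age_range
    gp[[g]]$mmse_mean <- mmse_mean; gp[[g]]$mmse_sd <- mmse_sd
    gp[[g]]$mmse_range <- c(0, 30)
    gp[[g]]$faq_mean <- faq_mean; gp[[g]]$faq_sd <- faq_sd
    gp[[g]]$faq_range <- c(0, 30)
  }
  gp
}

# Linear-Gaussian sampler for hand-built DAG checks: `coefs` is a named
# list child -> named numeric vector of parent coefficients.
sample_dag <- function(n, vars, coefs, seed, noise_sd = 1) {
  with_seed <- getFromNamespace("with_seed", "petcog")
  with_seed(seed, {
    d <- as.data.frame(matrix(stats::rnorm(n * length(vars), 0, noise_sd),
                              n, length(vars), dimnames = list(NULL, vars)))
    for (child in names(coefs)) {
      for (parent in names(coefs[[child]])) {
        d[[child]] <- d[[child]] + coefs[[child]][[parent]] * d[[parent]]
      }
    }
    d
  })
}

# A tiny, fast network configuration used where the architecture, not the
# capacity, is under test.
tiny_net_config <- function(n_features, epochs = 50, lr = 3e-3,
                            batch_size = 8, ...) {
  cognet_config(n_features = n_features, attn_hidden = 8, embed_dim = 16,
                ff_dim = 32, n_heads = 2, head_hidden = 8, dropout = 0,
                lr = lr, epochs = epochs, batch_size = batch_size, ...)
}
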