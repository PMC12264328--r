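# Shared fixtures: all generated in code, sized for speed.

tiny_cohort <- function(n_per_group = 2, n_repeats = 2, seed = 7,
                        grid_shape = c(8, 48, 48), ...) {
  simulate_cohort(cohort_params(n_per_group = n_per_group, n_repeats = n_repeats,
                                grid_shape = grid_shape, seed = seed, ...))
}

random_stack <- function(dims = c(6, 6, 2), T_rep = 4, seed = 1) {
  withr::with_seed(seed, {
    structure(array(runif(prod(dims) * T_rep), c(dims, T_rep)),
              spacing = c(1, 1, 1), class = "prob_stack")
  })
}

# two-way ANOVA mean squares via stats::aov, as an independent ICC oracle
aov_icc <- function(M) {
  df <- data.frame(value = as.vector(M),
                   row = factor(rep(seq_len(nrow(M)), ncol(M))),
                   col = factor(rep(seq_len(ncol(M)), each = nrow(M))))
  an <- anova(aov(value ~ row + col, data = df))
  msr <- an["row", "Mean Sq"]; msc <- an["col", "Mean Sq"]
  mse <- an["Residuals", "Mean Sq"]
  list(
    consistency = (msr - mse) / msr,
    agreement = (msr - mse) / (msr + (msc - mse) / nrow(M))
  )
}

# feature table built directly (no imaging), for stability/discrim unit tests
synthetic_feature_table <- function(n_subjects = 6, n_repeats = 3,
                                    sources = c("GT", "CL_50"),
                                    f = c("featA", "featB"), seed = 1,
                                    noise = 0.1) {
  withr::with_seed(seed, {
    grid <- expand.grid(subject = seq_len(n_subjects), rep = seq_len(n_repeats),
                        src = sources, stringsAsFactors = FALSE)
    base <- rnorm(n_subjects, 10, 2)
    out <- tibble::tibble(
      subject_id = sprintf("S%02d", grid$subject),
      group = ifelse(grid$subject <= n_subjects / 2, "CKD", "HC"),
      repeat_index = grid$rep, mask_source = grid$src
    )
    for (fn in f) {
      out[[fn]] <- base[grid$subject] + rnorm(nrow(grid), 0, noise)
    }
    out
  })
}
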