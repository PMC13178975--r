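# small in-code fixtures shared across test files

make_pair <- function(n = 10, seed = 1, n_x = 1e5, n_y = 1e5) {
  set.seed(seed)
  summary_pair(
    tibble::tibble(
      variant_id = paste0("rs", seq_len(n)),
      beta_x = rnorm(n, 0, 0.02),
      se_x = runif(n, 0.003, 0.006),
      beta_y = rnorm(n, 0, 0.02),
      se_y = runif(n, 0.003, 0.006)
    ),
    n_x = n_x, n_y = n_y
  )
}

# write exposure/outcome files with allele columns; returns the two paths
write_gwas_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  exposure <- data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "A"),
    other_allele = c("G", "T", "T"),
    beta = c(0.10, -0.05, 0.02),
    standard_error = c(0.01, 0.02, 0.01),
    stringsAsFactors = FALSE
  )
  outcome <- data.frame(
    rsid = c("rs1", "rs2", "rs4"),
    effect_allele = c("G", "C", "A"),   # rs1 swapped relative to exposure
    other_allele = c("A", "T", "G"),
    beta = c(0.03, -0.01, 0.05),
    standard_error = c(0.01, 0.02, 0.01),
    stringsAsFactors = FALSE
  )
  ep <- file.path(dir, "exposure.tsv")
  op <- file.path(dir, "outcome.tsv")
  write.table(exposure, ep, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(outcome, op, sep = "\t", row.names = FALSE, quote = FALSE)
  list(exposure = ep, outcome = op)
}

# simulated instrument table with known causal effect, strong instruments
make_instruments <- function(n = 50, beta = 0.3, seed = 2,
                             se_x = 0.01, se_y = 0.01) {
  set.seed(seed)
  gamma <- runif(n, 0.6, 1.5)
  tibble::tibble(
    bx = gamma + rnorm(n, 0, se_x),
    se_x = se_x,
    by = beta * gamma + rnorm(n, 0, se_y),
    se_y = se_y
  )
}
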