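# Small shared fixtures, built once per test run.

tiny_spec <- function(noise_sd = 0.1, seed = 7L) {
  fixture_spec(n_drugs = 8L, n_cells = 5L,
               genes = c(expression = 60L, copy_number = 50L,
                         mutation = 40L, proteomics = 30L),
               noise_sd = noise_sd, seed = seed)
}

local({
  fx <- NULL
  tiny_fixture <<- function() {
    if (is.null(fx)) fx <<- generate_fixture(tiny_spec())
    fx
  }
})

# A handful of drugs for featurizer tests.
test_drugs <- function() {
  list(drug_record("d1", "CCO", c("T1", "T3")),
       drug_record("d2", "c1ccccc1", c("T2", "T5")),
       drug_record("d3", "CC(=O)OC1=CC=CC=C1C(=O)O", "T3"),
       drug_record("d4", "CN1C=NC2=C1C(=O)N(C(=O)N2C)C", character(0)))
}

write_temp_csv <- function(df, dir = tempdir(), name = "t.csv") {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Small multitask config for fast tests.
tiny_model_config <- function(...) {
  args <- list(encoder_hidden = c(16L, 8L), head_hidden = c(12L, 8L),
               attention_heads = 2L, learning_rate = 2e-3,
               batch_size = 64L, epochs = 30L)
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}
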