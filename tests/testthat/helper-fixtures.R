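# Fixtures built in code: random rules/datasets and small UCI-format files.

rand_rule <- function(n, consequent = NA_character_, cf = NA_real_) {
  fuzzy_rule(sample(0:14, n, replace = TRUE), consequent, cf)
}

rand_dataset <- function(m, n, classes = c("A", "B")) {
  weighted_dataset(matrix(stats::runif(m * n), m, n),
                   sample(classes, m, replace = TRUE))
}

# minimal UCI-dialect records (14 comma-separated fields, "?" missing)
uci_fixture_lines <- function() {
  c(
    "63,1,1,145,233,1,2,150,0,2.3,3,0,6,0",
    "67,1,4,160,286,0,2,108,1,1.5,2,3,3,2",
    "67,1,4,120,229,0,2,129,1,2.6,2,2,7,1",
    "37,1,3,130,250,0,0,187,0,3.5,3,0,3,0",
    "41,0,2,130,204,0,2,172,0,1.4,1,0,3,1",
    "56,1,2,120,236,0,0,178,0,0.8,1,0,3,0",
    "62,0,4,140,268,0,2,160,0,3.6,3,2,3,3",
    "57,0,4,120,354,0,0,163,1,0.6,1,0,3,0",
    "63,1,4,130,254,0,2,147,0,1.4,2,1,7,4",
    "53,1,4,140,203,1,2,155,1,3.1,3,0,7,1",
    "57,1,4,140,192,0,0,148,0,0.4,2,0,6,0",
    "56,0,2,140,294,0,2,153,0,1.3,2,?,3,0"
  )
}

write_uci_fixture <- function(path = tempfile(fileext = ".csv")) {
  writeLines(uci_fixture_lines(), path)
  path
}

# a quick, low-budget training configuration for plumbing tests
tiny_train_config <- function(seed = NULL) {
  train_config(K = 12, max_runs = 3,
               swarm = swarm_config(swarm_size = 6, B = 8, max_iter = 25),
               seed = seed)
}
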