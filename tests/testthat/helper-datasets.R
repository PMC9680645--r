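# deterministic random small-group datasets shared by the inference oracle
# tests; the frozen reference results in gh_oracle.csv were computed on
# exactly these datasets
oracle_datasets <- function(n_datasets = 100, seed = 872634) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n_datasets), function(i) {
    k <- sample(2:4, 1)
    ns <- sample(3:30, k, replace = TRUE)
    x <- unlist(lapply(seq_len(k), function(j) {
      rnorm(ns[j], mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    }))
    list(x = x, g = rep(letters[seq_len(k)], ns))
  })
}

# tiny statement fixture exercising every parse artifact
fixture_statement_lines <- function() {
  c("# ACCOUNT: checking,,",
    "2017-01-03,AMAZON MKTP,-12.50",
    ",US*1234,",
    "2017-01-04,PAYROLL DIRECT DEP,1500.00",
    "not-a-date,BROKEN ROW,-3.00",
    "# ACCOUNT: credit,,",
    "2017-01-05,COFFEE BAR,-4.25")
}
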