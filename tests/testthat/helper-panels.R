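# Shared fixtures built in code.

# A plausible male serum panel (ng/mL), canonical analyte order.
test_panel <- function(scale = 1) {
  steroid_panel(stats::setNames(
    scale * c(0.10, 3.0, 100, 0.40, 1.2, 4.5, 3.0, 1200, 1.0, 0.15),
    steroid_analytes()))
}

# Random strictly positive panel (log-normal around test_panel), seeded.
random_panel <- function(seed, sd = 0.3) {
  set.seed(seed)
  p <- test_panel() * exp(stats::rnorm(10, 0, sd))
  steroid_panel(p)
}

# Small three-class cohort with complete panels; each class's panels are
# jittered copies of a class prototype so classes are well separated.
toy_cohort <- function(n_per_class = 4, seed = 1, jitter_sd = 0.05) {
  set.seed(seed)
  protos <- list(
    PCa = test_panel() * c(1, 1, 1, 1, 0.4, 0.4, 0.5, 0.4, 1, 1.5),
    BPH = test_panel() * c(1, 1, 1.3, 1, 0.8, 0.7, 1, 1, 1, 0.8),
    HC  = test_panel())
  rows <- list()
  for (cls in names(protos)) {
    for (s in seq_len(n_per_class)) {
      p <- protos[[cls]] * exp(stats::rnorm(10, 0, jitter_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s-%02d", cls, s), class = cls,
        as.list(p), check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  steroid_cohort(do.call(rbind, rows))
}

# Independent cosine-similarity oracle used against similarity().
cosine01 <- function(a, b) {
  (1 + sum(a * b) / sqrt(sum(a^2) * sum(b^2))) / 2
}
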