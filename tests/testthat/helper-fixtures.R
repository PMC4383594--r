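# Fixture builders shared across the suite. Everything is generated in code;
# no data files ship with the tests.

# Two-subject excerpt in the shape of a long-format symptom file: two
# patients evaluated on four occasions each (8 rows).
excerpt_lines <- function() {
  c("PatientID\tDate\tMeasurement\tFatigue\tNausea\tSex",
    "1\t2010-01-01\t0\t2\t0\tM",
    "1\t2010-01-15\t14\t1\t0.5\tM",
    "1\t2010-06-30\t180\t0\t0\tM",
    "1\t2011-01-01\t365\t0\t0\tM",
    "2\t2010-02-01\t0\t5\t1\tF",
    "2\t2010-02-15\t14\t4\t0\tF",
    "2\t2010-07-31\t180\t2\t0\tF",
    "2\t2011-02-01\t365\t1\t0\tF")
}

write_excerpt <- function(lines = excerpt_lines()) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

excerpt_roles <- function(...) {
  var_roles(id = "PatientID", date = "Date", occasion = "Measurement",
            outcomes = c("Fatigue", "Nausea"), covariates = "Sex", ...)
}

excerpt_data <- function() {
  validate_roles(read_long_table(write_excerpt()), excerpt_roles())
}

small_cohort <- function(n = 30, q = 4, seed = 42, ...) {
  generate_em_like(sim_config(n_subjects = n, n_outcomes = q, ...),
                   seed = seed)
}

# Brute-force multiplicity adjustments straight from their definitions;
# oracles for the p.adjust-backed exports.
holm_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, val)
    adj[ord[i]] <- running
  }
  adj
}

bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[ord[i]] <- min(1, min(vapply(i:m, function(j) {
      m * p[ord[j]] / j
    }, numeric(1))))
  }
  adj
}

by_brute <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[ord[i]] <- min(1, min(vapply(i:m, function(j) {
      cm * m * p[ord[j]] / j
    }, numeric(1))))
  }
  adj
}
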